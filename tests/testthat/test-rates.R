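# Rate laws of the regulatory network: closed-form examples, limits, the
# anterior gate, and the differential edge-weight structure.

p0 <- default_parameters()

test_that("her transcription combines autorepression with Notch drive", {
  # full autorepression shuts transcription off
  expect_lt(transcription_rate_her(1e9, 100, p0), 1e-6)
  # unrepressed basal limit with the Notch term disabled
  p <- default_parameters(basal_her = 1, w_notch_her = 0)
  expect_equal(transcription_rate_her(0, 0, p), p$tc_her)
  # half-repressed, half-activated: tc * 0.5 * (0 + 1 * 0.5)
  p <- default_parameters(basal_her = 0, w_notch_her = 1)
  expect_equal(transcription_rate_her(p$K_hd_her, p$K_nicd_her, p),
               p$tc_her * 0.25)
  # monotone: decreasing in dimer, nondecreasing in NICD
  d <- seq(0, 500, by = 25)
  r <- transcription_rate_her(d, 50, p0)
  expect_true(all(diff(r) < 0))
  nic <- seq(0, 300, by = 20)
  expect_true(all(diff(transcription_rate_her(50, nic, p0)) >= 0))
})

test_that("delta transcription is pure Her repression", {
  expect_equal(transcription_rate_delta(0, p0), p0$tc_delta)
  expect_lt(transcription_rate_delta(1e9, p0), 1e-6)
  expect_equal(transcription_rate_delta(p0$K_hd_delta, p0), p0$tc_delta / 2)
})

test_that("mesp transcription is gated to the anterior compartment", {
  for (nicd in c(0, 50, 500)) {
    expect_identical(
      transcription_rate_mespa(nicd, 300, 10, FALSE, p0), 0)
    expect_identical(
      transcription_rate_mespb(nicd, 300, FALSE, p0), 0)
  }
  # no activator -> no transcription even in the anterior
  expect_equal(transcription_rate_mespa(0, 0, 0, TRUE, p0), 0)
  expect_equal(transcription_rate_mespb(0, 0, TRUE, p0), 0)
})

test_that("mespa rate matches its closed form at half-saturation", {
  p <- default_parameters(w_notch_a = 1, w_tbx_a = 0.2, K_tbx_a = 1500)
  expect_equal(
    transcription_rate_mespa(p$K_notch_a, 0, 0, TRUE, p),
    p$tc_mespa * 0.5)
  p2 <- default_parameters(w_tbx_b = 1, w_notch_b = 0.2)
  expect_equal(
    transcription_rate_mespb(0, p2$K_tbx_b, TRUE, p2),
    p2$tc_mespb * 0.5)
})

test_that("edge-weight asymmetry: Notch dominates mespa, Tbx6 dominates mespb", {
  x <- 150  # equal activator abundance
  notch_part_a <- p0$w_notch_a * hill_activation(x, p0$K_notch_a, p0$n_notch_a)
  tbx_part_a <- p0$w_tbx_a * hill_activation(x, p0$K_tbx_a, p0$n_tbx_a)
  expect_gt(notch_part_a, tbx_part_a)
  tbx_part_b <- p0$w_tbx_b * hill_activation(x, p0$K_tbx_b, p0$n_tbx_b)
  notch_part_b <- p0$w_notch_b * hill_activation(x, p0$K_notch_b, p0$n_notch_b)
  expect_gt(tbx_part_b, notch_part_b)
})

test_that("ripply transcription follows summed Mesp activation", {
  expect_equal(transcription_rate_ripply(0, 0, p0), 0)
  expect_equal(
    transcription_rate_ripply(p0$K_ripply_act / 2, p0$K_ripply_act / 2, p0),
    p0$tc_ripply / 2)
  # doubling Mespa at fixed Mespb never decreases the rate
  r1 <- transcription_rate_ripply(100, 200, p0)
  r2 <- transcription_rate_ripply(200, 200, p0)
  expect_gte(r2, r1)
})

test_that("Tbx6 balance: steady state, synthesis-only limit, Ripply removal", {
  ss <- p0$basal_tbx6 / p0$deg_tbx6
  expect_equal(tbx6_rate(ss, 0, p0), 0)
  expect_equal(tbx6_rate(0, 1e4, p0), p0$basal_tbx6)
  # direct evaluation: basal 10 - deg 5 - removal 5 = 0
  p <- default_parameters(basal_tbx6 = 10, deg_tbx6 = 0.1, k_rip = 0.2,
                          K_rip = 300, n_rip = 1)
  expect_equal(tbx6_rate(50, 300, p), 10 - 5 - 0.2 * 0.5 * 50)
  # strictly decreasing in Ripply
  r <- vapply(c(0, 100, 300, 900), function(rp) tbx6_rate(400, rp, p0),
              numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("NICD production saturates in neighbour Delta and is 0 without it", {
  expect_equal(nicd_production(0, p0), 0)
  expect_equal(nicd_production(p0$K_delta, p0), p0$k_nicd / 2)
  expect_lt(nicd_production(1e9, p0), p0$k_nicd + 1e-9)
})

test_that("rate laws stay finite and nonnegative on random inputs", {
  set.seed(7)
  for (i in 1:50) {
    x <- runif(4, 0, 1e4)
    vals <- c(
      transcription_rate_her(x[1], x[2], p0),
      transcription_rate_delta(x[1], p0),
      transcription_rate_mespa(x[1], x[2], x[3], TRUE, p0),
      transcription_rate_mespb(x[1], x[2], TRUE, p0),
      transcription_rate_ripply(x[1], x[2], p0),
      nicd_production(x[4], p0))
    expect_true(all(is.finite(vals)))
    expect_true(all(vals >= 0))
  }
})

test_that("negative concentrations are a domain error", {
  expect_error(transcription_rate_her(-1, 0, p0), "nonnegative")
  expect_error(transcription_rate_mespa(1, -2, 0, TRUE, p0), "nonnegative")
  expect_error(tbx6_rate(-5, 0, p0), "nonnegative")
  expect_error(nicd_production(-1, p0), "nonnegative")
})
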