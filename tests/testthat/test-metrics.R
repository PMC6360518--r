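# Metric checks on analytic signals and ground-truth fixtures.

test_that("estimate_period recovers known periods and signals their absence", {
  t <- seq(0, 300, by = 1)
  expect_equal(estimate_period(sin(2 * pi * t / 30), time = t), 30)
  expect_equal(estimate_period(100 + 7 * cos(2 * pi * t / 42), time = t), 42,
               tolerance = 1e-6)
  flat <- estimate_period(rep(1, 100), time = seq_len(100))
  expect_true(is.na(flat))
  expect_identical(attr(flat, "reason"), "no-period")
  expect_true(is.na(estimate_period(sin(2 * pi * t[1:50] / 45), time = t[1:50])))
})

test_that("estimate_period is affine-invariant and picks the dominant mode", {
  t <- seq(0, 600, by = 1)
  x <- sin(2 * pi * t / 30)
  expect_equal(estimate_period(5000 + 120 * x, time = t),
               estimate_period(x, time = t))
  mix <- 3 * sin(2 * pi * t / 30) + 1 * sin(2 * pi * t / 90)
  est <- estimate_period(mix, time = t)
  # independent oracle: first prominent autocorrelation peak
  ac <- stats::acf(mix, lag.max = 120, plot = FALSE)$acf[-1]
  pk <- which(diff(sign(diff(ac))) == -2) + 1
  oracle <- pk[ac[pk] > 0.5][1]
  expect_equal(est, oracle, tolerance = 0.05)
  expect_equal(est, 30, tolerance = 1)
})

test_that("estimate_amplitude halves the peak-trough excursion", {
  t <- seq(0, 300, by = 1)
  expect_equal(estimate_amplitude(5 + 3 * sin(2 * pi * t / 30)), 3,
               tolerance = 0.01)
  const <- estimate_amplitude(rep(4, 200))
  expect_identical(as.numeric(const), 0)
  expect_true(attr(const, "no_cycle"))
})

test_that("sync_index: locked = 1, antiphase = 0, random phases = 0.5", {
  fx <- generate_oscillators(50, phase_mode = "synchronized", seed = 1)
  expect_equal(sync_index(fx$series), 1)
  t <- seq(0, 200, by = 1)
  anti <- cbind(sin(2 * pi * t / 25), sin(2 * pi * t / 25 + pi))
  expect_equal(sync_index(anti), 0, tolerance = 1e-9)
  rnd <- generate_oscillators(100, phase_mode = "random", seed = 42,
                              duration_min = 240)
  expect_equal(sync_index(rnd$series), 0.5, tolerance = 0.05)
  # permutation invariance
  perm <- sample(ncol(rnd$series))
  expect_equal(sync_index(rnd$series[, perm]), sync_index(rnd$series))
  expect_error(sync_index(matrix(1, 10, 3)), "nonzero variance")
})

test_that("phase_order separates locked, wave, and random ensembles", {
  locked <- generate_oscillators(60, phase_mode = "synchronized", seed = 1)
  expect_gt(phase_order(locked$series, time = locked$time), 0.99)
  rnd <- generate_oscillators(100, phase_mode = "random", seed = 7,
                              duration_min = 300)
  expect_lt(phase_order(rnd$series, time = rnd$time), 0.3)
})

test_that("detect_stripes recovers constructed geometry exactly", {
  fx <- generate_stripe_field(50, 4, 10)
  st <- detect_stripes(fx$profile, cell_diameter_um = 8)
  expect_equal(st$width_cells, fx$truth$width_cells)
  expect_equal(st$anterior_edge_col, fx$truth$anterior_edge_col)
  expect_equal(attr(st, "interstripe_cells"), attr(fx$truth, "interstripe_cells"))
  expect_true(all(attr(st, "interstripe_cells") == 10))
  expect_equal(st$width_um, st$width_cells * 8)
  # zero-noise exactness across the geometry grid
  for (w in 1:6) for (s in c(5, 9, 15)) {
    if (s <= w) next
    fx <- generate_stripe_field(60, w, s)
    st <- detect_stripes(fx$profile, min_stripe_width = 1)
    expect_equal(st$width_cells, fx$truth$width_cells,
                 info = sprintf("w=%d s=%d", w, s))
    expect_equal(st$posterior_edge_col, fx$truth$posterior_edge_col)
  }
  expect_identical(nrow(detect_stripes(rep(0, 50))), 0L)
})

test_that("raising the stripe threshold never widens a stripe", {
  fx <- generate_stripe_field(60, 5, 12, noise_sigma_frac = 0.15, seed = 3)
  ths <- c(0.3, 0.5, 0.7, 0.9)
  widths <- lapply(ths, function(th)
    sum(detect_stripes(fx$profile, threshold_frac = th,
                       min_stripe_width = 1)$width_cells))
  expect_true(all(diff(unlist(widths)) <= 0))
})

test_that("stripe widths survive 10% noise in at least 95% of trials", {
  hits <- 0
  for (seed in 1:100) {
    fx <- generate_stripe_field(50, 4, 10, noise_sigma_frac = 0.10,
                                seed = seed)
    st <- detect_stripes(fx$profile)
    ok <- nrow(st) == nrow(fx$truth) &&
      all(abs(st$width_cells - fx$truth$width_cells) <= 1)
    hits <- hits + ok
  }
  expect_gte(hits, 95)
})

test_that("complementarity is signed correlation with a variance guard", {
  sq <- rep(c(1, 1, 0, 0), 6)
  expect_equal(complementarity(sq, 1 - sq), -1)
  expect_equal(complementarity(sq, sq), 1)
  expect_error(complementarity(sq, rep(2, length(sq))), "variance")
})

test_that("time_to_loss flags a clamped signal within one cycle, Inf otherwise", {
  fx <- generate_oscillators(8, period_min = 30, amplitude = 10, offset = 12,
                             duration_min = 900, seed = 2)
  clamped <- fx$series
  clamped[fx$time > 600, ] <- 0
  sim <- fixture_sim(clamped, "mespa_m")
  tl <- time_to_loss(sim, "mespa_m", seq_len(8), 0.1, t_ref = 600)
  expect_lte(tl, 30)
  intact <- fixture_sim(fx$series, "mespa_m")
  expect_identical(time_to_loss(intact, "mespa_m", seq_len(8), 0.1,
                                t_ref = 600), Inf)
  # array-scan oracle: first window centre whose windowed amplitude is
  # below 10% of the pre-onset baseline, recomputed by brute force
  m <- clamped
  tm <- fx$time
  centers <- tm[tm >= tm[1] + 15 & tm <= max(tm) - 15]
  amp <- vapply(centers, function(cc) {
    w <- m[tm >= cc - 15 & tm <= cc + 15, , drop = FALSE]
    mean((apply(w, 2, max) - apply(w, 2, min)) / 2)
  }, numeric(1))
  base <- mean(amp[centers >= 480 & centers <= 600])
  oracle <- centers[centers > 600 & amp < 0.1 * base][1] - 600
  expect_equal(tl, oracle)
})

test_that("time_to_desync: shared-rate cells never desynchronize, scrambled do", {
  fx <- generate_oscillators(12, period_min = 30, duration_min = 1000,
                             phase_mode = "synchronized", seed = 3)
  sim <- fixture_sim(fx$series, "her_m")
  expect_identical(time_to_desync(sim, "her_m", seq_len(12), 0.5, t_ref = 300),
                   Inf)
  rnd <- generate_oscillators(12, period_min = 30, duration_min = 1000,
                              phase_mode = "random", seed = 4)
  sim2 <- fixture_sim(rnd$series, "her_m")
  expect_lte(time_to_desync(sim2, "her_m", seq_len(12), 0.5, t_ref = 300), 70)
})
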