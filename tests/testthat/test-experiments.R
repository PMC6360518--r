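# Run-configuration IO, output archiving, kymograph rendering, and the
# experiment harness surface (the heavy biology lives in the acceptance
# suite).

test_that("run configs round-trip through strict YAML", {
  cfgr <- default_config()
  cfgr$parameters <- default_parameters(psd = 2.5)
  cfgr$protocol <- protocol_preset("dapt")
  cfgr$seed <- 42L
  f <- tempfile(fileext = ".yaml")
  write_config(cfgr, f)
  rt <- load_config(f)
  expect_equal(unclass(rt$parameters), unclass(cfgr$parameters))
  expect_equal(rt$protocol$actions, cfgr$protocol$actions)
  expect_equal(rt$seed, 42L)
  expect_equal(rt$thresholds, cfgr$thresholds)
})

test_that("config loading is fail-closed and names the offending key", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("t_end: 100", "bogus_key: 1"), f)
  expect_error(load_config(f), "bogus_key")
  writeLines(c("lattice:", "  n_diag: 3"), f)
  expect_error(load_config(f), "n_diag")
  writeLines(c("thresholds:", "  loss_fraq: 0.2"), f)
  expect_error(load_config(f), "loss_fraq")
})

test_that("write_outputs archives CSV/JSON with a consistent hash manifest", {
  sim <- small_run(t_end = 60, seed = 1)
  dir <- file.path(tempdir(), "segclock-out")
  man <- write_outputs(sim, metrics = list(period = 30), dir,
                       config = default_config())
  expect_true(all(file.exists(file.path(dir, man$file))))
  recomputed <- unname(tools::md5sum(file.path(dir, man$file)))
  expect_identical(man$md5, recomputed)
  long <- utils::read.csv(file.path(dir, "result_long.csv"))
  expect_named(long, c("time", "row", "col", "species", "abundance"))
  expect_setequal(unique(long$species), species_names())
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$metrics$period, 30)
})

test_that("sim_to_long is consistent with the abundance array", {
  sim <- small_run(t_end = 50, seed = 2)
  long <- sim_to_long(sim, every_min = 10, species = "her_m")
  i <- which(long$time == 30 & long$row == 1 & long$col == 3)
  cell <- cell_index(1, 3, sim$cfg)
  expect_equal(long$abundance[i],
               unname(sim$x[sim$time == 30, cell, "her_m"]))
})

test_that("kymographs render deterministically, black at zero", {
  sim <- small_run(t_end = 80, seed = 1)
  zero <- sim
  zero$x[] <- 0
  f0 <- tempfile(fileext = ".png")
  render_kymograph(zero, "her_m", f0, scale = 1)
  img <- png::readPNG(f0)
  expect_true(all(img == 0))
  f1 <- tempfile(fileext = ".png")
  f2 <- tempfile(fileext = ".png")
  render_kymograph(sim, c("her_m", "mespa_m"), f1, scale = 1)
  render_kymograph(sim, c("her_m", "mespa_m"), f2, scale = 1)
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
  img <- png::readPNG(f1)
  expect_equal(max(img[, , 1]), 1)     # max maps to full intensity
  expect_true(all(img[, , 3] == 0))    # two-species overlay: blue unused
  expect_error(render_kymograph(sim, "nonexistent", tempfile()), "unknown species")
  fs <- tempfile(fileext = ".png")
  render_snapshot(sim, "her_m", t = 50, path = fs, scale = 2)
  expect_true(file.exists(fs))
})

test_that("the experiment harness validates names and reports verdicts", {
  expect_error(run_experiment("frobnicate"), "unknown experiment")
  ex <- run_experiment("her_mutant", cfg = lattice_config(4, 16),
                       params = default_parameters(anterior_gate_col = 8,
                                                   cell_cv = 0.05),
                       t_end = 400, seed = 1)
  expect_s3_class(ex, "segclock_experiment")
  expect_named(ex$metrics)
  expect_true(is.logical(ex$checks))
  expect_output(print(ex), "her_mutant")
})
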