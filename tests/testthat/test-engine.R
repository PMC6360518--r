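# Integrator checks: history buffer semantics, closed-form limits, seeded
# reproducibility, nonnegativity, desynchronization without coupling, and
# a delay-oscillator onset test against an independent linear-stability
# oracle.

silent_params <- function(...) {
  default_parameters(tc_her = 0, tc_delta = 0, tc_mespa = 0, tc_mespb = 0,
                     tc_ripply = 0, psh = 0, psd = 0, psm_a = 0, psm_b = 0,
                     psr = 0, basal_tbx6 = 0, k_assoc = 0, k_nicd = 0,
                     cell_cv = 0, anterior_gate_col = 0, ...)
}

test_that("initial history fills the delay horizon and is seed-stable", {
  cfg <- lattice_config(2, 4)
  cp <- sample_cell_parameters(default_parameters(anterior_gate_col = 2), 8, 1)
  hz <- initial_history(cfg, cp, mode = "zeros", dt = 0.1)
  expect_true(all(hz$states == 0))
  expect_gte(hz$n_slots, 1 + 10 * max(unlist(
    default_parameters()[segclock:::.delay_param_names])))
  h1 <- initial_history(cfg, cp, mode = "low_uniform_random", seed = 9, eps = 1)
  h2 <- initial_history(cfg, cp, mode = "low_uniform_random", seed = 9, eps = 1)
  expect_identical(h1, h2)
  expect_true(all(h1$states >= 0 & h1$states <= 1))
  expect_error(initial_history(cfg, cp, mode = "gaussian"), "arg")
  # lookups before t = 0 return the initial state
  expect_identical(history_lookup(h1, step = 0, lag_steps = hz$n_slots - 1),
                   h1$states[, , 1])
})

test_that("a production-free species decays as x0 exp(-d t) within 1%", {
  cfg <- lattice_config(1, 2)
  p <- silent_params()
  cp <- sample_cell_parameters(p, 2, 1)
  sim <- integrate_lattice(cfg, cp, NULL, t_end = 20, dt = 0.01, seed = 7,
                           init_mode = "low_uniform_random", init_eps = 100)
  for (sp in c("her_m", "Delta", "Tbx6")) {
    d <- p[[c(her_m = "deg_m_her", Delta = "deg_p_delta",
              Tbx6 = "deg_tbx6")[[sp]]]]
    x0 <- sim$x[1, 1, sp]
    expected <- x0 * exp(-d * 20)
    expect_lt(abs(sim$x[sim$time == 20, 1, sp] - expected) / expected, 0.01)
  }
})

test_that("constant transcription with translation off reaches k/d within 1%", {
  cfg <- lattice_config(1, 2)
  p <- default_parameters(K_hd_her = 1e9, basal_her = 1, w_notch_her = 0,
                          psh = 0, psd = 0, cell_cv = 0, anterior_gate_col = 0)
  cp <- sample_cell_parameters(p, 2, 1)
  sim <- integrate_lattice(cfg, cp, NULL, t_end = 60, dt = 0.01, seed = 7)
  ss <- p$tc_her / p$deg_m_her
  expect_lt(abs(sim$x[sim$time == 60, 1, "her_m"] - ss) / ss, 0.01)
})

test_that("identical (config, protocol, seed, dt) gives bitwise-identical output", {
  a <- small_run(t_end = 120, seed = 5)
  b <- small_run(t_end = 120, seed = 5)
  expect_identical(a$x, b$x)
  c_ <- small_run(t_end = 120, seed = 6)
  expect_false(identical(a$x, c_$x))
})

test_that("abundances stay finite and nonnegative over a long run", {
  sim <- wt_run(1)
  expect_true(all(is.finite(sim$x)))
  expect_true(all(sim$x >= 0))
  expect_lt(sim$clip_frac, 0.001)
})

test_that("dt and delay misconfiguration are rejected", {
  cfg <- lattice_config(2, 4)
  cp <- sample_cell_parameters(default_parameters(anterior_gate_col = 2), 8, 1)
  expect_error(integrate_lattice(cfg, cp, NULL, t_end = 10, dt = 1.0, seed = 1),
               "delay")
  expect_error(integrate_lattice(cfg, cp, NULL, t_end = 0, dt = 0.1, seed = 1),
               "positive")
  expect_error(integrate_lattice(cfg, cp, NULL, t_end = 10, dt = 0.1, seed = 1,
                                 output_stride = 0.25), "multiple")
})

test_that("without Delta coupling, rate variability desynchronizes the clock", {
  cfg <- lattice_config(4, 12)
  p <- default_parameters(psd = 0, cell_cv = 0.07, anterior_gate_col = 10)
  cp <- sample_cell_parameters(p, 48, seed = 2)
  sim <- integrate_lattice(cfg, cp, NULL, t_end = 700, dt = 0.1, seed = 2)
  m <- sim_series(sim, "her_m", column_cells(0:9, cfg))
  tm <- attr(m, "time")
  early <- sync_index(m[tm >= 100 & tm <= 220, ])
  late <- sync_index(m[tm >= 580 & tm <= 700, ])
  expect_lt(late, early)
  expect_lt(late, 0.75)
})

test_that("her-loop oscillation onset matches the linear-stability oracle", {
  # Independent oracle: linearize the single-cell her subsystem
  # (mRNA m, protein P, dimer D) about its fixed point and compute the
  # spectral radius of the discretized delay system's transition matrix.
  p_for <- function(tau) silent_params(tc_her = 33, psh = 4.5, k_assoc = 0.01,
                                       basal_her = 1, w_notch_her = 0,
                                       tau_m_her = tau)
  oracle_unstable <- function(p, h = 0.05) {
    bm <- p$deg_m_her; bp <- p$deg_p_her; bd <- p$deg_dimer
    ka <- p$k_assoc; kd <- p$k_dissoc; a <- p$psh
    K <- p$K_hd_her; n <- p$n_hd_her; tc <- p$tc_her * p$basal_her
    Fd <- function(D) tc * hill_repression(D, K, n)
    # fixed point: solve D = ka P(m(D))^2 / (kd + bd)
    alpha <- 2 * ka * bd / (kd + bd)
    P_of <- function(m) (-bp + sqrt(bp^2 + 4 * alpha * a * m)) / (2 * alpha)
    g <- function(D) D - ka * P_of(Fd(D) / bm)^2 / (kd + bd)
    Ds <- stats::uniroot(g, c(1e-9, 1e9), tol = 1e-10)$root
    ms <- Fd(Ds) / bm; Ps <- P_of(ms)
    dF <- -tc * n * (Ds / K)^n / (Ds * (1 + (Ds / K)^n)^2)
    A <- rbind(c(-bm, 0, 0),
               c(0, -bp - 4 * ka * Ps, 2 * kd),
               c(0, 2 * ka * Ps, -(kd + bd)))
    L1 <- round(p$tau_m_her / h)   # m' reads D(t - tau_m)
    L2 <- round(p$tau_p_her / h)   # P' reads m(t - tau_p)
    L <- max(L1, L2)
    nv <- 3 * (L + 1)
    M <- matrix(0, nv, nv)
    M[1:3, 1:3] <- diag(3) + h * A
    M[1, 3 + 3 * (L1 - 1) + 3] <- h * dF        # D delayed by L1 steps
    M[2, 3 + 3 * (L2 - 1) + 1] <- h * a         # m delayed by L2 steps
    M[4:nv, 1:(nv - 3)] <- diag(nv - 3)         # shift history
    max(Mod(eigen(M, only.values = TRUE)$values)) > 1 + 1e-6
  }
  simulated_oscillates <- function(p) {
    cfg <- lattice_config(1, 1)
    cp <- sample_cell_parameters(p, 1, 1)
    sim <- integrate_lattice(cfg, cp, NULL, t_end = 800, dt = 0.1, seed = 1)
    # late window so that slowly decaying transients have died away
    x <- sim_series(sim, "her_m", 1, t_range = c(600, 800))[, 1]
    (max(x) - min(x)) / max(mean(x), 1e-9) > 0.05
  }
  taus <- c(2, 3, 4, 6.5)
  pred <- vapply(taus, function(tau) oracle_unstable(p_for(tau)), logical(1))
  obs <- vapply(taus, function(tau) simulated_oscillates(p_for(tau)), logical(1))
  # the oracle must separate the regimes and the engine must agree
  expect_true(any(pred) && !all(pred))
  expect_identical(obs, pred)
})
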