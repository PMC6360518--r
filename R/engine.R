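# Fixed-step delay-differential-equation integrator on the hexagonal cell
# lattice. Explicit Euler with a ring buffer of past lattice states; delays
# are rounded to the step grid. Deterministic given (config, cell table,
# protocol, seed, dt).

#' Initial history buffer
#'
#' Builds the pre-`t = 0` history required by the delayed terms: one lattice
#' state replicated across the whole delay horizon. `mode = "zeros"` starts
#' the tissue empty; `mode = "low_uniform_random"` seeds each (cell,
#' species) with an independent uniform draw in `[0, eps]` to break the
#' symmetry between cells.
#'
#' @param cfg A [lattice_config()].
#' @param cell_params A [sample_cell_parameters()] table (used for sizing).
#' @param mode `"zeros"` or `"low_uniform_random"`.
#' @param seed Integer seed for the random mode.
#' @param eps Upper bound of the uniform initial draws (molecules).
#' @param dt Integration step (min), used to size the buffer.
#' @return A `history_buffer`: list with the state array `states`
#'   (`n_cells x n_species x n_slots`), `dt`, and `n_slots` covering the
#'   longest model delay.
#' @export
initial_history <- function(cfg, cell_params, mode = c("zeros", "low_uniform_random"),
                            seed = 0, eps = 1, dt = 0.1) {
  mode <- match.arg(mode)
  p <- attr(cell_params, "nominal")
  n_cells <- nrow(cell_params)
  n_sp <- length(species_names())
  n_slots <- max_delay_steps(p, cfg, dt) + 1L
  init <- matrix(0, n_cells, n_sp)
  if (mode == "low_uniform_random") {
    with_seed(seed, {
      init[] <- stats::runif(n_cells * n_sp, 0, eps)
    })
  }
  states <- array(init, dim = c(n_cells, n_sp, n_slots),
                  dimnames = list(NULL, species_names(), NULL))
  structure(list(states = states, dt = dt, n_slots = n_slots, mode = mode),
            class = "history_buffer")
}

#' Look up a past lattice state
#'
#' @param buf A `history_buffer` as carried inside the integrator, with the
#'   current step index attached.
#' @param step Current step index (state at `t = step * dt` is stored).
#' @param lag_steps Nonnegative integer lag in steps, `< n_slots`.
#' @return The `n_cells x n_species` state matrix at `step - lag_steps`
#'   (the initial state for lookups before `t = 0`).
#' @export
history_lookup <- function(buf, step, lag_steps) {
  stopifnot(lag_steps >= 0, lag_steps < buf$n_slots)
  slot <- ((step - lag_steps) %% buf$n_slots) + 1L
  buf$states[, , slot]
}

# Longest delay in the model, in steps, including the anterior-most
# transcription delay under the period gradient.
max_delay_steps <- function(p, cfg, dt) {
  taus <- unlist(p[.delay_param_names])
  tau_her_max <- p$tau_m_her *
    (1 + p$period_grad * max(0, cfg$n_cols - 1 - p$grad_start_col))
  as.integer(max(round(c(taus, tau_her_max) / dt)))
}

#' Integrate the lattice model
#'
#' Advances all 13 species in every cell of the lattice by explicit
#' fixed-step Euler, reading delayed state from the history ring buffer,
#' coupling cells through the neighbour-averaged Delta protein, and applying
#' the perturbation protocol's time-windowed parameter modifications at
#' every step. Abundances are clipped at zero (clip events are counted and
#' a warning is raised if they exceed 0.1% of state updates, a sign that
#' `dt` is too coarse).
#'
#' @param cfg A [lattice_config()].
#' @param cell_params Per-cell parameter table from
#'   [sample_cell_parameters()].
#' @param protocol A [perturbation_protocol()] (or `NULL` / empty for
#'   wild-type).
#' @param t_end Simulated duration (min).
#' @param dt Integration step (min); must not exceed any nonzero model
#'   delay.
#' @param seed Integer seed used for the initial history.
#' @param init_mode Initial-history mode, see [initial_history()].
#' @param init_eps Scale of the random initial state (molecules).
#' @param output_stride Recording interval (min); must be a multiple of
#'   `dt`.
#' @return A `segclock_sim` object: list with `time` (recorded times, min),
#'   `species`, the abundance array `x` (`n_times x n_cells x n_species`),
#'   `cfg`, `cell_params`, `protocol`, `seed`, `dt`, and the clipped-update
#'   fraction `clip_frac`.
#' @examples
#' \donttest{
#' cfg <- lattice_config()
#' cp <- sample_cell_parameters(default_parameters(), 200, seed = 1)
#' sim <- integrate_lattice(cfg, cp, protocol_preset("wt"),
#'                          t_end = 300, seed = 1)
#' }
#' @export
integrate_lattice <- function(cfg, cell_params, protocol = NULL,
                              t_end, dt = 0.1, seed = 0,
                              init_mode = "low_uniform_random", init_eps = 1,
                              output_stride = 1) {
  stopifnot(inherits(cfg, "lattice_config"), inherits(cell_params, "cell_params"))
  p <- attr(cell_params, "nominal")
  if (dt <= 0 || t_end <= 0) stop("dt and t_end must be positive", call. = FALSE)
  taus <- unlist(p[.delay_param_names])
  if (any(taus > 0 & taus < dt)) {
    stop("dt must not exceed any nonzero delay", call. = FALSE)
  }
  stride_steps <- round(output_stride / dt)
  if (abs(stride_steps * dt - output_stride) > 1e-9) {
    stop("output_stride must be a multiple of dt", call. = FALSE)
  }
  if (is.null(protocol)) protocol <- perturbation_protocol()
  validate_protocol(protocol, cell_params)

  n_rows <- cfg$n_rows; n_cols <- cfg$n_cols
  n_cells <- n_rows * n_cols
  if (nrow(cell_params) != n_cells) {
    stop("cell_params has ", nrow(cell_params), " rows but the lattice has ",
         n_cells, " cells", call. = FALSE)
  }
  sp <- species_names()
  n_sp <- length(sp)
  si <- as.list(stats::setNames(seq_len(n_sp), sp))

  cols <- cell_columns(cfg)
  gate <- as.numeric(cols >= p$anterior_gate_col)
  W <- neighbor_weight_matrix(cfg)

  # Delays live on a fixed 0.1-min grid (so the effective delay does not
  # depend on dt) and are then expressed in integration steps.
  lag <- function(tau) as.integer(round(round(tau, 1) / dt))
  lag_m_her <- lag(p$tau_m_her *
                     (1 + p$period_grad * pmax(0, cols - p$grad_start_col)))
  lag_m_delta  <- lag(p$tau_m_delta)
  lag_m_mespa  <- lag(p$tau_m_mespa)
  lag_m_mespb  <- lag(p$tau_m_mespb)
  lag_m_ripply <- lag(p$tau_m_ripply)
  lag_p_her    <- lag(p$tau_p_her)
  lag_p_delta  <- lag(p$tau_p_delta)
  lag_p_mespa  <- lag(p$tau_p_mespa)
  lag_p_mespb  <- lag(p$tau_p_mespb)
  lag_p_ripply <- lag(p$tau_p_ripply)
  lag_nicd     <- lag(p$tau_nicd)

  buf <- initial_history(cfg, cell_params, mode = init_mode, seed = seed,
                         eps = init_eps, dt = dt)
  H <- buf$states
  nbuf <- buf$n_slots

  n_steps <- as.integer(round(t_end / dt))
  rec_times <- seq(0L, n_steps, by = stride_steps)
  n_rec <- length(rec_times)
  out <- array(NA_real_, dim = c(n_rec, n_cells, n_sp),
               dimnames = list(NULL, NULL, sp))
  out[1, , ] <- H[, , 1]
  rec_i <- 1L

  # piecewise-constant effective parameters: recompute only at protocol events
  events <- protocol_event_times(protocol)
  seg_i <- 0L  # forces initial computation
  cp_eff <- NULL
  cpl <- NULL
  refresh <- function(t) {
    cp_eff <<- apply_perturbation(cell_params, protocol, t)
    cpl <<- lapply(stats::setNames(colnames(cp_eff), colnames(cp_eff)),
                   function(nm) cp_eff[, nm])
  }
  segment_of <- function(t) sum(events <= t + 1e-9)

  cells <- seq_len(n_cells)
  i_dimer <- si$HerDimer; i_nicd <- si$NICD
  idx_her_dimer <- cbind(cells, i_dimer, 0L)
  idx_her_nicd <- cbind(cells, i_nicd, 0L)
  clip_count <- 0
  total_updates <- as.numeric(n_steps) * n_cells * n_sp

  X <- matrix(H[, , 1], n_cells, n_sp)  # current state, n_cells x n_sp
  slot_of <- function(s, l) ((s - l) %% nbuf) + 1L

  for (s in 0:(n_steps - 1L)) {
    t_now <- s * dt
    seg <- segment_of(t_now)
    if (seg != seg_i || is.null(cp_eff)) { refresh(t_now); seg_i <- seg }

    # --- delayed lookups -------------------------------------------------
    idx_her_dimer[, 3] <- slot_of(s, lag_m_her)
    idx_her_nicd[, 3] <- idx_her_dimer[, 3]
    dimer_her <- H[idx_her_dimer]
    nicd_her <- H[idx_her_nicd]
    dimer_delta <- H[, i_dimer, slot_of(s, lag_m_delta)]
    sl_ma <- slot_of(s, lag_m_mespa)
    nicd_ma <- H[, i_nicd, sl_ma]
    tbx6_ma <- H[, si$Tbx6, sl_ma]
    dimer_ma <- H[, i_dimer, sl_ma]
    sl_mb <- slot_of(s, lag_m_mespb)
    nicd_mb <- H[, i_nicd, sl_mb]
    tbx6_mb <- H[, si$Tbx6, sl_mb]
    sl_rp <- slot_of(s, lag_m_ripply)
    mespa_rp <- H[, si$Mespa, sl_rp]
    mespb_rp <- H[, si$Mespb, sl_rp]
    herm_d <- H[, si$her_m, slot_of(s, lag_p_her)]
    deltam_d <- H[, si$delta_m, slot_of(s, lag_p_delta)]
    mespam_d <- H[, si$mespa_m, slot_of(s, lag_p_mespa)]
    mespbm_d <- H[, si$mespb_m, slot_of(s, lag_p_mespb)]
    ripplym_d <- H[, si$ripply_m, slot_of(s, lag_p_ripply)]
    delta_nbr <- as.numeric(W %*% H[, si$Delta, slot_of(s, lag_nicd)])

    # --- rate laws -------------------------------------------------------
    her_m <- X[, si$her_m]; delta_m <- X[, si$delta_m]
    mespa_m <- X[, si$mespa_m]; mespb_m <- X[, si$mespb_m]
    ripply_m <- X[, si$ripply_m]
    Her <- X[, si$Her]; Delta <- X[, si$Delta]
    Mespa <- X[, si$Mespa]; Mespb <- X[, si$Mespb]
    Ripply <- X[, si$Ripply]; Tbx6 <- X[, si$Tbx6]
    Dimer <- X[, i_dimer]; Nicd <- X[, i_nicd]

    d_her_m <- transcription_rate_her(dimer_her, nicd_her, cpl) +
      cpl$hs_her_m_supply - cpl$deg_m_her * her_m
    d_delta_m <- transcription_rate_delta(dimer_delta, cpl) -
      cpl$deg_m_delta * delta_m
    d_mespa_m <- transcription_rate_mespa(nicd_ma, tbx6_ma, dimer_ma, gate, cpl) -
      cpl$deg_m_mespa * mespa_m
    d_mespb_m <- transcription_rate_mespb(nicd_mb, tbx6_mb, gate, cpl) -
      cpl$deg_m_mespb * mespb_m
    d_ripply_m <- transcription_rate_ripply(mespa_rp, mespb_rp, cpl) -
      cpl$deg_m_ripply * ripply_m

    # Her / dimer exchange is stiff when translation is boosted
    # (heat-shock overexpression): update this pair semi-implicitly
    # (linearly implicit in the new value, explicit in the partner),
    # which is first-order accurate like Euler but unconditionally stable.
    Her_new <- (Her + dt * (cpl$psh * herm_d + 2 * cpl$k_dissoc * Dimer)) /
      (1 + dt * (cpl$deg_p_her + 2 * cpl$k_assoc * Her))
    Dimer_new <- (Dimer + dt * cpl$k_assoc * Her * Her) /
      (1 + dt * (cpl$k_dissoc + cpl$deg_dimer))
    d_Delta <- cpl$psd * deltam_d - cpl$deg_p_delta * Delta
    d_Mespa <- cpl$psm_a * mespam_d - cpl$deg_p_mespa * Mespa
    d_Mespb <- cpl$psm_b * mespbm_d - cpl$deg_p_mespb * Mespb
    d_Ripply <- cpl$psr * ripplym_d - cpl$deg_p_ripply * Ripply
    d_Tbx6 <- tbx6_rate(Tbx6, Ripply, cpl)
    d_Nicd <- nicd_production(delta_nbr, cpl) - cpl$deg_nicd * Nicd

    Xn <- X + dt * cbind(d_her_m, d_delta_m, d_mespa_m, d_mespb_m, d_ripply_m,
                         0, d_Delta, d_Mespa, d_Mespb, d_Ripply, d_Tbx6,
                         0, d_Nicd, deparse.level = 0)
    Xn[, 6] <- Her_new
    Xn[, 12] <- Dimer_new
    neg <- Xn < 0
    if (any(neg)) {
      clip_count <- clip_count + sum(neg)
      Xn[neg] <- 0
    }
    if (s %% 500L == 0L && any(!is.finite(Xn))) {
      bad <- which(!is.finite(Xn), arr.ind = TRUE)[1, ]
      stop("state blow-up at t = ", t_now, " min (cell ", bad[1],
           ", species ", sp[bad[2]], ")", call. = FALSE)
    }
    X <- Xn
    H[, , ((s + 1L) %% nbuf) + 1L] <- X
    if ((s + 1L) %% stride_steps == 0L) {
      rec_i <- rec_i + 1L
      out[rec_i, , ] <- X
    }
  }
  if (any(!is.finite(X))) {
    stop("state blow-up by t_end", call. = FALSE)
  }
  clip_frac <- clip_count / total_updates
  if (clip_frac > 0.001) {
    warning(sprintf("%.2f%% of state updates clipped at zero; dt may be too coarse",
                    100 * clip_frac))
  }
  structure(list(
    time = rec_times * dt,
    species = sp,
    x = out,
    cfg = cfg,
    cell_params = cell_params,
    protocol = protocol,
    seed = seed,
    dt = dt,
    clip_frac = clip_frac
  ), class = "segclock_sim")
}

#' @export
print.segclock_sim <- function(x, ...) {
  cat("<segclock_sim> ", x$cfg$n_rows, "x", x$cfg$n_cols, " lattice, t = [0, ",
      max(x$time), "] min (", length(x$time), " snapshots), seed ", x$seed,
      "\n", sep = "")
  if (length(x$protocol$actions)) {
    cat("  protocol: ", format(x$protocol), "\n", sep = "")
  } else cat("  protocol: wild-type\n")
  invisible(x)
}

#' Extract a time-by-cell series from a simulation
#'
#' @param sim A `segclock_sim`.
#' @param species A single species name.
#' @param cells Integer cell indices (default all).
#' @param t_range Optional `c(t_min, t_max)` window (min).
#' @return Numeric matrix, rows = recorded times, columns = cells, with the
#'   time vector as attribute `time`.
#' @export
sim_series <- function(sim, species, cells = NULL, t_range = NULL) {
  isp <- species_index(species)
  if (is.null(cells)) cells <- seq_len(dim(sim$x)[2])
  keep <- rep(TRUE, length(sim$time))
  if (!is.null(t_range)) {
    keep <- sim$time >= t_range[1] & sim$time <= t_range[2]
  }
  m <- sim$x[keep, cells, isp, drop = FALSE]
  m <- matrix(m, nrow = sum(keep), ncol = length(cells))
  attr(m, "time") <- sim$time[keep]
  m
}

#' Row-averaged axial expression profile at one time
#'
#' @param sim A `segclock_sim`.
#' @param species A single species name.
#' @param t Time (min); the nearest recorded snapshot is used.
#' @return Numeric vector of length `n_cols`: mean abundance per column
#'   (posterior first).
#' @export
sim_profile <- function(sim, species, t) {
  isp <- species_index(species)
  it <- which.min(abs(sim$time - t))
  v <- sim$x[it, , isp]
  cols <- cell_columns(sim$cfg)
  as.numeric(tapply(v, cols, mean))
}
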