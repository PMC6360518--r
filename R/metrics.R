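# Oscillation and spatial-pattern metrics: period and amplitude from peak
# detection, a correlation-based synchronization index, perturbation timing
# readouts (time to expression loss / to desynchronization), stripe
# geometry, and her/mesp complementarity.

#' Detect peaks in a series
#'
#' Local maxima filtered by topographic prominence, expressed as a fraction
#' of the series range, to reject numerical ripple.
#'
#' @param x Numeric series.
#' @param min_prominence Minimum prominence as a fraction of
#'   `diff(range(x))` (default 0.2).
#' @return Integer indices of accepted peaks.
#' @export
find_peaks <- function(x, min_prominence = 0.2) {
  n <- length(x)
  if (n < 3) return(integer(0))
  rng <- diff(range(x))
  if (rng == 0) return(integer(0))
  d <- diff(x)
  # strict rises followed by falls; plateau tops take their first point
  sgn <- sign(d)
  sgn_nz <- sgn
  for (i in seq_along(sgn_nz)) if (sgn_nz[i] == 0 && i > 1) sgn_nz[i] <- sgn_nz[i - 1]
  cand <- which(diff(sgn_nz) < 0) + 1L
  cand <- cand[cand > 1 & cand < n]
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    h <- x[i]
    j <- i - 1; lmin <- h
    while (j >= 1 && x[j] <= h) { lmin <- min(lmin, x[j]); j <- j - 1 }
    if (j < 1) lmin <- min(x[1:i])
    j <- i + 1; rmin <- h
    while (j <= n && x[j] <= h) { rmin <- min(rmin, x[j]); j <- j + 1 }
    if (j > n) rmin <- min(x[i:n])
    prom <- h - max(lmin, rmin)
    keep[k] <- prom >= min_prominence * rng
  }
  cand[keep]
}

#' Estimate the oscillation period of a series
#'
#' Median of successive peak-to-peak intervals, with peaks required to have
#' prominence at least `min_prominence` of the series range. The estimate
#' is invariant to affine rescaling of the series.
#'
#' @param x Numeric abundance series, or a matrix with time in rows (the
#'   per-column medians are pooled with `median`).
#' @param time Time vector (min); defaults to the `time` attribute of `x`,
#'   else `0:(n-1)`.
#' @param min_prominence Peak prominence threshold (fraction of range).
#' @return Period in minutes, or `NA` (with a `"no-period"` message
#'   attribute) if fewer than 3 peaks are found.
#' @examples
#' t <- seq(0, 300, by = 1)
#' estimate_period(sin(2 * pi * t / 30), time = t)  # 30
#' @export
estimate_period <- function(x, time = NULL, min_prominence = 0.2) {
  if (is.matrix(x)) {
    tm <- time %||% attr(x, "time")
    per <- apply(x, 2, estimate_period, time = tm,
                 min_prominence = min_prominence)
    return(stats::median(per, na.rm = TRUE))
  }
  tm <- time %||% attr(x, "time") %||% seq_along(x) - 1
  pk <- find_peaks(x, min_prominence)
  if (length(pk) < 3) {
    return(structure(NA_real_, reason = "no-period"))
  }
  # sub-sample peak refinement: parabola through the peak and neighbours
  tpk <- vapply(pk, function(i) {
    if (i <= 1 || i >= length(x)) return(tm[i])
    y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den >= 0) return(tm[i])
    tm[i] + 0.5 * (y1 - y3) / den * (tm[i + 1] - tm[i])
  }, numeric(1))
  stats::median(diff(tpk))
}

#' Estimate oscillation amplitude
#'
#' Half the mean peak-to-trough excursion over the detected cycles.
#'
#' @inheritParams estimate_period
#' @return Amplitude in molecules; a constant (or cycle-free) series
#'   returns 0 with attribute `no_cycle = TRUE`.
#' @examples
#' t <- seq(0, 300, by = 1)
#' estimate_amplitude(5 + 3 * sin(2 * pi * t / 30))  # 3
#' @export
estimate_amplitude <- function(x, min_prominence = 0.2) {
  pk <- find_peaks(x, min_prominence)
  tr <- find_peaks(-x, min_prominence)
  if (!length(pk) || !length(tr)) {
    return(structure(0, no_cycle = TRUE))
  }
  (mean(x[pk]) - mean(x[tr])) / 2
}

#' Synchronization index of a cell population
#'
#' Mean pairwise Pearson correlation of the per-cell series, mapped to
#' `[0, 1]` via `(rbar + 1) / 2`: identical phases give 1, independent
#' random phases 0.5, perfect antiphase 0. Permutation-invariant over
#' cells; zero-variance cells are excluded.
#'
#' @param series Numeric matrix, rows = time points, columns = cells;
#'   should cover at least two oscillation periods.
#' @return Synchronization index in `[0, 1]`.
#' @export
sync_index <- function(series) {
  stopifnot(is.matrix(series), ncol(series) >= 2)
  sds <- apply(series, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  if (sum(keep) < 2) {
    stop("fewer than two cells with nonzero variance", call. = FALSE)
  }
  C <- stats::cor(series[, keep, drop = FALSE])
  rbar <- mean(C[lower.tri(C)])
  (rbar + 1) / 2
}

#' Kuramoto phase-order parameter of a cell population
#'
#' Assigns each cell a continuous oscillation phase by linear interpolation
#' between its detected expression peaks (one full cycle = 2*pi per
#' peak-to-peak interval, extrapolated beyond the first/last peak at the
#' local period) and returns `R(t) = |mean_j exp(i phi_j(t))|` averaged
#' over the requested times. R is 1 for perfectly phase-locked cells and
#' falls to ~`1/sqrt(n)` for fully random phases, so a threshold of 0.5
#' separates coherent from incoherent populations robustly -- unlike a
#' mean pairwise correlation, whose random-phase limit is its own
#' threshold.
#'
#' @param series Numeric matrix, rows = time points, columns = cells, with
#'   a `time` attribute (or evenly spaced rows).
#' @param time Time vector (min); defaults to the `time` attribute.
#' @param at Times at which to evaluate R (default: all of `time`).
#' @param min_prominence Peak prominence threshold passed to
#'   [find_peaks()].
#' @return Mean phase-order parameter over `at`, in `[0, 1]`. Cells with
#'   fewer than 2 usable peaks are excluded; if fewer than 2 cells remain
#'   the result is `NA`.
#' @export
phase_order <- function(series, time = NULL, at = NULL,
                        min_prominence = 0.2) {
  time <- time %||% attr(series, "time") %||% (seq_len(nrow(series)) - 1)
  at <- at %||% time
  ph <- phase_matrix(series, time, at, min_prominence)
  ok <- colSums(is.na(ph)) == 0
  if (sum(ok) < 2) return(NA_real_)
  z <- exp(1i * ph[, ok, drop = FALSE])
  mean(Mod(rowMeans(z)))
}

# Per-cell unwrapped oscillation phase (radians) at the requested times:
# linear interpolation of the cycle count between detected peaks,
# extrapolated at the local period beyond the first/last peak. Cells with
# fewer than 2 peaks give NA columns.
phase_matrix <- function(series, time, at = time, min_prominence = 0.2) {
  ph <- matrix(NA_real_, length(at), ncol(series))
  for (j in seq_len(ncol(series))) {
    pk <- find_peaks(series[, j], min_prominence)
    if (length(pk) < 2) next
    tp <- time[pk]
    k <- seq_along(tp) - 1
    cyc <- stats::approx(tp, k, xout = at, rule = 2)$y
    lo <- at < tp[1]
    cyc[lo] <- (at[lo] - tp[1]) / (tp[2] - tp[1])
    nn <- length(tp)
    hi <- at > tp[nn]
    cyc[hi] <- (nn - 1) + (at[hi] - tp[nn]) / (tp[nn] - tp[nn - 1])
    ph[, j] <- 2 * pi * cyc
  }
  ph
}

# Cells of a named region. "posterior" = columns 0..9 (the oscillating
# clock readout zone), "anterior" = columns >= anterior_gate_col.
region_cells <- function(sim, region, posterior_cols = 0:9) {
  if (is.numeric(region)) return(as.integer(region))
  p <- attr(sim$cell_params, "nominal")
  switch(region,
    posterior = column_cells(posterior_cols, sim$cfg),
    anterior = column_cells(p$anterior_gate_col:(sim$cfg$n_cols - 1), sim$cfg),
    stop("unknown region '", region, "'", call. = FALSE)
  )
}

# Mean per-cell sliding-window amplitude ((max - min) / 2 within the
# window, averaged over cells) at each window centre.
sliding_amplitude <- function(series, time, window) {
  centers <- time[time >= time[1] + window / 2 & time <= time[length(time)] - window / 2]
  amp <- vapply(centers, function(cc) {
    rows <- which(time >= cc - window / 2 & time <= cc + window / 2)
    w <- series[rows, , drop = FALSE]
    mean((apply(w, 2, max) - apply(w, 2, min)) / 2)
  }, numeric(1))
  list(center = centers, amplitude = amp)
}

#' Time from perturbation onset to loss of cyclic expression
#'
#' Tracks the mean per-cell cycle amplitude of a species in a region with a
#' sliding window of one nominal period, and reports how long after the
#' perturbation onset the amplitude first falls below `threshold_frac`
#' times its pre-perturbation baseline (the mean windowed amplitude over
#' the 120 min preceding onset).
#'
#' @param sim A `segclock_sim`.
#' @param species Species name (e.g. `"mespa_m"`).
#' @param region `"posterior"`, `"anterior"`, or a vector of cell indices.
#' @param threshold_frac Loss threshold as a fraction of baseline
#'   (default 0.1, the model's "barely detectable" criterion).
#' @param t_ref Perturbation onset (min).
#' @param window Sliding-window length (min; default one nominal 30-min
#'   period).
#' @param baseline_span Minutes before `t_ref` used for the baseline.
#' @return Elapsed minutes (window centre minus `t_ref`), or `Inf` if the
#'   amplitude never crosses the threshold before the end of the run.
#' @export
time_to_loss <- function(sim, species, region, threshold_frac = 0.1, t_ref,
                         window = 30, baseline_span = 120) {
  cells <- region_cells(sim, region)
  m <- sim_series(sim, species, cells)
  sa <- sliding_amplitude(m, attr(m, "time"), window)
  pre <- sa$center >= t_ref - baseline_span & sa$center <= t_ref
  if (!any(pre)) stop("no pre-perturbation window before t_ref", call. = FALSE)
  baseline <- mean(sa$amplitude[pre])
  if (baseline <= 0) stop("no pre-perturbation cycles (zero baseline amplitude)",
                          call. = FALSE)
  post <- which(sa$center > t_ref & sa$amplitude < threshold_frac * baseline)
  if (!length(post)) return(Inf)
  sa$center[post[1]] - t_ref
}

#' Time from perturbation onset to desynchronization
#'
#' Tracks the phase coherence of a region's cells in sliding windows of two
#' nominal periods after a perturbation and reports how long it takes to
#' first fall below `sync_threshold`. The default coherence measure is the
#' [phase_order()] parameter, whose incoherent limit (~`1/sqrt(n)`) lies
#' well below the 0.5 threshold so the crossing time is well defined; the
#' mean-pairwise-correlation [sync_index()] is available as an alternative
#' (its fully-randomized limit is 0.5 itself, so it measures only gross
#' departures from coherence).
#'
#' @inheritParams time_to_loss
#' @param sync_threshold Coherence threshold (default 0.5, the model's
#'   "pattern disrupted" criterion).
#' @param window Sliding-window length (min; default two nominal periods).
#' @param stride Window-centre spacing (min).
#' @param measure `"phase"` (default) or `"pearson"`.
#' @return Elapsed minutes (window centre minus `t_ref`), or `Inf` if the
#'   region never desynchronizes within the run.
#' @export
time_to_desync <- function(sim, species, region, sync_threshold = 0.5, t_ref,
                           window = 60, stride = 10,
                           measure = c("phase", "pearson")) {
  measure <- match.arg(measure)
  cells <- region_cells(sim, region)
  m <- sim_series(sim, species, cells)
  time <- attr(m, "time")
  centers <- seq(time[1] + window / 2, time[length(time)] - window / 2,
                 by = stride)
  centers <- centers[centers > t_ref]
  if (measure == "phase") {
    keep <- time >= t_ref   # phases reflect post-onset dynamics only
    mm <- m[keep, , drop = FALSE]
    tt <- time[keep]
    ph <- phase_matrix(mm, tt)
    ok <- colSums(is.na(ph)) == 0
    if (sum(ok) < 2) {
      stop("fewer than two cells with detectable cycles", call. = FALSE)
    }
    # local coherence among neighbouring cells: order parameter within
    # sliding column-window groups of >= 6 cells, averaged over groups.
    # A kinematic wave (smooth phase gradient) stays coherent;
    # salt-and-pepper desynchronization of neighbours does not.
    col_of <- cell_columns(sim$cfg)[cells]
    ucols <- sort(unique(col_of))
    w <- max(2, ceiling(6 / sim$cfg$n_rows))
    first <- ucols[seq_len(max(1, length(ucols) - w + 1))]
    groups <- lapply(first, function(cc) {
      which(ok & col_of >= cc & col_of < cc + w)
    })
    groups <- groups[vapply(groups, length, integer(1)) >= 2]
    if (!length(groups)) groups <- list(which(ok))
    z <- exp(1i * ph)
    r_t <- rowMeans(vapply(groups,
                           function(g) Mod(rowMeans(z[, g, drop = FALSE])),
                           numeric(nrow(ph))))
    for (cc in centers) {
      r <- mean(r_t[tt >= cc - window / 2 & tt <= cc + window / 2])
      if (!is.na(r) && r < sync_threshold) return(cc - t_ref)
    }
  } else {
    for (cc in centers) {
      rows <- which(time >= cc - window / 2 & time <= cc + window / 2)
      s <- tryCatch(sync_index(m[rows, , drop = FALSE]),
                    error = function(e) NA)
      if (!is.na(s) && s < sync_threshold) return(cc - t_ref)
    }
  }
  Inf
}

#' Detect expression stripes along the axis
#'
#' Thresholds a row-averaged axial profile at a fraction of its maximum
#' (the FWHM-style in situ criterion) and reports every run of at least
#' `min_stripe_width` supra-threshold columns as a stripe, with widths and
#' anterior-edge positions in cells and micrometres, plus the interstripe
#' distances between consecutive anterior edges.
#'
#' @param profile Numeric vector of per-column abundance (posterior
#'   first), e.g. from [sim_profile()].
#' @param threshold_frac Threshold as a fraction of `max(profile)`
#'   (default 0.5).
#' @param min_stripe_width Minimum stripe width in cells (default 2).
#' @param cell_diameter_um Column pitch for distance conversion.
#' @return A `stripe_set`: data frame with columns `posterior_edge_col`,
#'   `anterior_edge_col` (0-based), `width_cells`, `width_um`, ordered
#'   posterior to anterior, with interstripe distances (cells and um)
#'   as attributes `interstripe_cells` / `interstripe_um`. An all-zero
#'   profile yields an empty set.
#' @export
detect_stripes <- function(profile, threshold_frac = 0.5, min_stripe_width = 2,
                           cell_diameter_um = 8) {
  stopifnot(is.numeric(profile), threshold_frac > 0, threshold_frac <= 1)
  empty <- structure(
    data.frame(posterior_edge_col = integer(0), anterior_edge_col = integer(0),
               width_cells = integer(0), width_um = numeric(0)),
    interstripe_cells = numeric(0), interstripe_um = numeric(0),
    class = c("stripe_set", "data.frame"))
  mx <- max(profile)
  if (mx <= 0) return(empty)
  above <- profile >= threshold_frac * mx
  r <- rle(above)
  ends <- as.integer(cumsum(r$lengths))
  starts <- ends - as.integer(r$lengths) + 1L
  runs <- which(r$values & r$lengths >= min_stripe_width)
  if (!length(runs)) return(empty)
  post <- starts[runs] - 1L   # 0-based
  ant <- ends[runs] - 1L
  width <- ant - post + 1L
  inter <- diff(ant)
  structure(
    data.frame(posterior_edge_col = post, anterior_edge_col = ant,
               width_cells = width, width_um = width * cell_diameter_um),
    interstripe_cells = inter, interstripe_um = inter * cell_diameter_um,
    class = c("stripe_set", "data.frame"))
}

#' @export
print.stripe_set <- function(x, ...) {
  cat("<stripe_set> ", nrow(x), " stripe(s)\n", sep = "")
  if (nrow(x)) {
    print.data.frame(x, ...)
    cat("interstripe distances (cells):",
        paste(attr(x, "interstripe_cells"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' her/mesp complementarity of two axial profiles
#'
#' Pearson correlation of two per-column expression profiles over the
#' anterior region; complementary (mutually exclusive) striping gives a
#' strongly negative value.
#'
#' @param profile_a,profile_b Numeric per-column profiles of equal length
#'   (already restricted to the anterior columns).
#' @return Correlation in `[-1, 1]`.
#' @export
complementarity <- function(profile_a, profile_b) {
  stopifnot(length(profile_a) == length(profile_b))
  if (stats::sd(profile_a) == 0 || stats::sd(profile_b) == 0) {
    stop("profiles must have nonzero variance", call. = FALSE)
  }
  stats::cor(profile_a, profile_b)
}
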