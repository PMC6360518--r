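# Ground-truth synthetic inputs for validating the metrics: ideal striped
# axial profiles of known geometry, and phase-controlled oscillator
# ensembles of known period. Rectangular stripes and pure sinusoids are the
# zero-noise ideals; Gaussian noise (truncated at zero, since abundances
# are counts) is layered on top under a fixed seed.

#' Generate an ideal striped expression profile
#'
#' Rectangular stripes of a given width repeated at a given spacing along
#' the axis, starting at `first_col`, with optional seeded Gaussian noise.
#' The exact stripe geometry is returned alongside as a ground-truth
#' [detect_stripes()]-style `stripe_set`.
#'
#' @param n_cols Number of columns.
#' @param stripe_width_cells Stripe width (cells), >= 1.
#' @param spacing_cells Distance between consecutive stripe starts
#'   (cells), > width.
#' @param peak_value Stripe height (molecules).
#' @param noise_sigma_frac Gaussian noise s.d. as a fraction of
#'   `peak_value`.
#' @param first_col 0-based column of the first stripe's posterior edge.
#' @param seed Integer seed for the noise.
#' @return List with `profile` (length `n_cols`) and `truth` (a
#'   `stripe_set` of the noise-free geometry).
#' @examples
#' fx <- generate_stripe_field(50, 4, 10)
#' fx$truth$width_cells        # all 4
#' @export
generate_stripe_field <- function(n_cols, stripe_width_cells, spacing_cells,
                                  peak_value = 1, noise_sigma_frac = 0,
                                  first_col = 0, seed = 0) {
  stopifnot(stripe_width_cells >= 1, spacing_cells > stripe_width_cells,
            n_cols >= spacing_cells, noise_sigma_frac >= 0,
            first_col >= 0, first_col < n_cols)
  profile <- numeric(n_cols)
  starts <- seq(first_col, n_cols - 1, by = spacing_cells)
  starts <- starts[starts + stripe_width_cells - 1 <= n_cols - 1]
  for (s0 in starts) {
    profile[(s0 + 1):(s0 + stripe_width_cells)] <- peak_value
  }
  post <- as.integer(starts)
  ant <- as.integer(starts + stripe_width_cells - 1)
  truth <- structure(
    data.frame(posterior_edge_col = post, anterior_edge_col = ant,
               width_cells = ant - post + 1L,
               width_um = (ant - post + 1L) * 8),
    interstripe_cells = diff(ant), interstripe_um = diff(ant) * 8,
    class = c("stripe_set", "data.frame"))
  if (noise_sigma_frac > 0) {
    with_seed(seed, {
      profile <- pmax(0, profile +
                        stats::rnorm(n_cols, 0, noise_sigma_frac * peak_value))
    })
  }
  list(profile = profile, truth = truth)
}

#' Wrap a fixture series as a simulation result
#'
#' Embeds a time x cells abundance matrix (e.g. from
#' [generate_oscillators()]) into a `segclock_sim` object on a 1 x n_cells
#' lattice, with all other species zero, so the perturbation-timing metrics
#' ([time_to_loss()], [time_to_desync()]) exercise exactly the same code
#' path on ground-truth fixtures as on model output.
#'
#' @param series Numeric matrix, rows = time points, columns = cells, with
#'   a `time` attribute (minutes).
#' @param species Species slot to fill (default `"mespa_m"`).
#' @param anterior_gate_col Gate column recorded in the attached nominal
#'   parameters (default 0: every fixture cell counts as anterior).
#' @return A `segclock_sim` object.
#' @export
fixture_sim <- function(series, species = "mespa_m", anterior_gate_col = 0) {
  time <- attr(series, "time") %||% (seq_len(nrow(series)) - 1)
  n_cells <- ncol(series)
  cfg <- lattice_config(n_rows = 1, n_cols = n_cells)
  p <- default_parameters(cell_cv = 0, anterior_gate_col = anterior_gate_col)
  cp <- sample_cell_parameters(p, n_cells, seed = 0)
  x <- array(0, dim = c(length(time), n_cells, length(species_names())),
             dimnames = list(NULL, NULL, species_names()))
  x[, , species_index(species)] <- series
  structure(list(time = time, species = species_names(), x = x, cfg = cfg,
                 cell_params = cp, protocol = perturbation_protocol(),
                 seed = 0, dt = if (length(time) > 1) diff(time)[1] else 1,
                 clip_frac = 0),
            class = "segclock_sim")
}

#' Generate a phase-controlled oscillator ensemble
#'
#' Sinusoidal per-cell time series of a known period with one of three
#' phase structures: `synchronized` (all cells in phase), `random`
#' (independent uniform phases), or `gradient` (phase increasing linearly
#' across cells by one full cycle). Stands in for posterior-PSM clock
#' traces when testing the period and synchronization estimators.
#'
#' @param n_cells Number of cells.
#' @param period_min Oscillation period (min).
#' @param phase_mode `"synchronized"`, `"random"`, or `"gradient"`.
#' @param amplitude,offset Sinusoid amplitude and baseline (molecules).
#' @param noise_sigma_frac Gaussian noise s.d. as a fraction of
#'   `amplitude`.
#' @param duration_min Series length (min); must cover >= 4 periods.
#' @param dt Sampling interval (min).
#' @param seed Integer seed (phases and noise).
#' @return List with `series` (matrix time x cells, `time` attribute),
#'   `time`, and `phases` (each cell's true initial phase, radians).
#' @export
generate_oscillators <- function(n_cells, period_min = 30,
                                 phase_mode = c("synchronized", "random", "gradient"),
                                 amplitude = 1, offset = 2,
                                 noise_sigma_frac = 0,
                                 duration_min = 4 * period_min, dt = 1,
                                 seed = 0) {
  phase_mode <- match.arg(phase_mode)
  stopifnot(n_cells >= 1, period_min > 0, duration_min >= 4 * period_min,
            noise_sigma_frac >= 0, amplitude >= 0)
  time <- seq(0, duration_min, by = dt)
  phases <- switch(phase_mode,
    synchronized = rep(0, n_cells),
    random = with_seed(seed, stats::runif(n_cells, 0, 2 * pi)),
    gradient = seq(0, 2 * pi, length.out = n_cells + 1)[seq_len(n_cells)]
  )
  series <- offset + amplitude *
    sin(outer(time, rep(2 * pi / period_min, n_cells)) +
          matrix(phases, length(time), n_cells, byrow = TRUE))
  if (noise_sigma_frac > 0) {
    with_seed(seed + 1L, {
      series <- series +
        matrix(stats::rnorm(length(series), 0, noise_sigma_frac * amplitude),
               nrow(series), ncol(series))
    })
    series <- pmax(series, 0)
  }
  attr(series, "time") <- time
  list(series = series, time = time, phases = phases)
}
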