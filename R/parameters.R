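# Nominal model parameters, per-cell sampling, and flat YAML/JSON serialization.
#
# Units: abundances in molecules per cell, time in minutes. Rates are
# molecules.min^-1 (synthesis) or min^-1 (first-order turnover); delays in
# minutes; Hill half-saturation constants in molecules.

# Parameters subject to static cell-to-cell variability (the "rates"): all
# synthesis, turnover and complex-formation rate constants. Delays, Hill
# constants/coefficients, weights and geometry are shared by all cells.
.rate_param_names <- c(
  "tc_her", "tc_delta", "tc_mespa", "tc_mespb", "tc_ripply",
  "psh", "psd", "psm_a", "psm_b", "psr",
  "basal_tbx6",
  "deg_m_her", "deg_m_delta", "deg_m_mespa", "deg_m_mespb", "deg_m_ripply",
  "deg_p_her", "deg_p_delta", "deg_p_mespa", "deg_p_mespb", "deg_p_ripply",
  "deg_tbx6", "deg_dimer", "deg_nicd",
  "k_assoc", "k_dissoc", "k_nicd", "k_rip"
)

.delay_param_names <- c(
  "tau_m_her", "tau_m_delta", "tau_m_mespa", "tau_m_mespb", "tau_m_ripply",
  "tau_p_her", "tau_p_delta", "tau_p_mespa", "tau_p_mespb", "tau_p_ripply",
  "tau_nicd"
)

#' Nominal model parameters
#'
#' Returns the shipped default parameter set for the segmentation-network
#' model. The her/deltaC clock core follows the classical delayed
#' autorepression oscillator (transcription and translation delays of a few
#' to ~10 minutes, mRNA and protein half-lives of ~3 minutes), calibrated so
#' that the posterior clock period is ~30 min, the zebrafish somite rhythm.
#' The mesp/ripply/tbx6 tier encodes the anterior patterning network:
#' Notch activates mespa strongly and mespb weakly, Tbx6 activates mespb
#' strongly and mespa weakly (the differential "thick/thin arrow" edges),
#' Her dimer represses mespa directly, Mesp proteins activate ripply, and
#' Ripply drives Tbx6 removal.
#'
#' @param ... Named overrides of individual parameters.
#' @return An object of class `segclock_params`: a named list of scalars.
#' @details Key entries:
#' \describe{
#'   \item{tc_*}{maximal transcription rates (molecules/min).}
#'   \item{psh, psd, psm_a, psm_b, psr}{translation rates per mRNA
#'     (protein molecules/mRNA/min) for her, deltaC, mespa, mespb, ripply.}
#'   \item{deg_m_*, deg_p_*}{first-order mRNA / protein decay rates (1/min).}
#'   \item{tau_m_*, tau_p_*}{transcription / translation delays (min).}
#'   \item{k_assoc, k_dissoc}{Her homodimer association (1/molecule/min)
#'     and dissociation (1/min) rate constants.}
#'   \item{k_nicd, K_delta, tau_nicd, deg_nicd}{proteolytic NICD production
#'     driven by the neighbour-averaged Delta protein, its half-saturation,
#'     signalling delay and decay.}
#'   \item{basal_tbx6, deg_tbx6, k_rip, K_rip}{Tbx6 basal synthesis, decay
#'     and Ripply-dependent removal.}
#'   \item{w_*, K_*}{weights and half-saturation constants of the
#'     regulatory edges; the Notch->mespa and Tbx6->mespb edges are strong
#'     (large weight, low K), their counterparts weak.}
#'   \item{anterior_gate_col}{first column (0-based, posterior = 0) at which
#'     mesp transcription is permitted; a static stand-in for the FGF
#'     determination front.}
#'   \item{period_grad, grad_start_col}{fractional increase of the her
#'     transcription delay per column anterior of `grad_start_col`,
#'     producing the posterior-to-anterior slowing of the clock that turns
#'     the phase profile into kinematic waves; the posterior clock zone
#'     (columns < `grad_start_col`) oscillates at the uniform pace.}
#'   \item{cell_cv}{coefficient of variation of the static per-cell rate
#'     sampling (uniform distribution).}
#'   \item{cell_diameter_um}{physical column pitch used to report stripe
#'     geometry in micrometres.}
#' }
#' @examples
#' p <- default_parameters()
#' p$tc_her
#' default_parameters(psd = 0)$psd
#' @export
default_parameters <- function(...) {
  p <- list(
    # -- her / deltaC clock core -------------------------------------------
    tc_her      = 33,     # max her transcription
    tc_delta    = 33,
    psh         = 4.5,
    psd         = 4.5,
    deg_m_her   = 0.3,
    deg_m_delta = 0.23,
    deg_p_her   = 0.3,
    deg_p_delta = 0.23,
    tau_m_her   = 6.5,
    tau_p_her   = 1.7,
    hs_her_m_supply = 0,  # autorepression-independent her mRNA supply
                          # (heat-shock transgene pool; 0 in wild-type)
    tau_m_delta = 7.0,
    tau_p_delta = 4.0,
    # Her homodimer
    k_assoc     = 0.01,
    k_dissoc    = 0.1,
    deg_dimer   = 0.3,
    K_hd_her    = 50,    # HerDimer -| her
    n_hd_her    = 2,
    K_hd_delta  = 50,    # HerDimer -| delta
    n_hd_delta  = 2,
    basal_her   = 0.3,    # Notch-independent her transcription fraction
    w_notch_her = 0.7,
    K_nicd_her  = 60,
    n_nicd_her  = 2,
    # Delta/Notch juxtacrine signalling
    k_nicd      = 60,
    K_delta     = 1000,
    n_delta     = 2,
    tau_nicd    = 4.0,
    deg_nicd    = 0.3,
    # -- mesp tier ---------------------------------------------------------
    tc_mespa    = 30,
    tc_mespb    = 30,
    psm_a       = 4.5,
    psm_b       = 4.5,
    deg_m_mespa = 0.4,
    deg_m_mespb = 0.35,
    deg_p_mespa = 0.23,
    deg_p_mespb = 0.4,
    tau_m_mespa = 0.5,
    tau_m_mespb = 1.0,
    tau_p_mespa = 2.0,
    tau_p_mespb = 2.0,
    w_notch_a   = 1.0,    # strong Notch -> mespa
    K_notch_a   = 60,
    n_notch_a   = 2,
    w_tbx_a     = 0.15,   # weak Tbx6 -> mespa
    K_tbx_a     = 1500,
    n_tbx_a     = 2,
    w_tbx_b     = 1.0,    # strong Tbx6 -> mespb
    K_tbx_b     = 200,
    n_tbx_b     = 3,
    w_notch_b   = 0.2,    # weak Notch -> mespb
    K_notch_b   = 600,
    n_notch_b   = 2,
    K_hd_mespa  = 400,    # HerDimer -| mespa (direct clock repression)
    n_hd_mespa  = 2,
    # -- ripply / tbx6 -----------------------------------------------------
    tc_ripply    = 30,
    psr          = 4.5,
    deg_m_ripply = 0.4,
    deg_p_ripply = 0.4,
    tau_m_ripply = 2.0,
    tau_p_ripply = 2.0,
    K_ripply_act = 800,   # (Mespa + Mespb) -> ripply
    n_ripply_act = 2,
    basal_tbx6   = 60,
    deg_tbx6     = 0.15,
    k_rip        = 2.0,   # Ripply-dependent Tbx6 removal
    K_rip        = 600,
    n_rip        = 3,
    # -- tissue-level settings --------------------------------------------
    anterior_gate_col = 33,
    period_grad       = 0.008,
    grad_start_col    = 10,
    cell_cv           = 0.07,
    cell_diameter_um  = 8
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(overrides)] <- overrides
  }
  out <- structure(p, class = "segclock_params")
  validate_parameters(out)
  out
}

#' Validate a parameter set
#'
#' Checks nonnegativity of all rates, delays and Hill constants, Hill
#' coefficients >= 1, and the differential edge-weight structure of the
#' network (Notch->mespa stronger than Notch->mespb; Tbx6->mespb stronger
#' than Tbx6->mespa, both by weight and by half-saturation).
#'
#' @param p A `segclock_params` object.
#' @return `p`, invisibly; errors if invalid.
#' @export
validate_parameters <- function(p) {
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("all parameters must be numeric", call. = FALSE)
  v <- unlist(p)
  if (any(!is.finite(v))) stop("parameters must be finite", call. = FALSE)
  if (any(v < 0)) {
    stop("negative parameter(s): ",
         paste(names(v)[v < 0], collapse = ", "), call. = FALSE)
  }
  nn <- grep("^n_", names(p), value = TRUE)
  if (any(unlist(p[nn]) < 1)) stop("Hill coefficients must be >= 1", call. = FALSE)
  Ks <- grep("^K_", names(p), value = TRUE)
  if (any(unlist(p[Ks]) <= 0)) stop("Hill constants must be > 0", call. = FALSE)
  if (p$K_notch_a >= p$K_notch_b || p$w_notch_a <= p$w_notch_b) {
    stop("Notch->mespa must be the stronger Notch edge (lower K, higher weight)",
         call. = FALSE)
  }
  if (p$K_tbx_b >= p$K_tbx_a || p$w_tbx_b <= p$w_tbx_a) {
    stop("Tbx6->mespb must be the stronger Tbx6 edge (lower K, higher weight)",
         call. = FALSE)
  }
  if (p$cell_cv < 0) stop("cell_cv must be >= 0", call. = FALSE)
  if (p$anterior_gate_col < 0) stop("anterior_gate_col must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.segclock_params <- function(x, ...) {
  cat("<segclock_params> ", length(x), " parameters\n", sep = "")
  cat("  clock: tc_her=", x$tc_her, " tau_m_her=", x$tau_m_her,
      " psd=", x$psd, "\n", sep = "")
  cat("  tissue: anterior_gate_col=", x$anterior_gate_col,
      " cell_cv=", x$cell_cv, " period_grad=", x$period_grad, "\n", sep = "")
  invisible(x)
}

#' Sample static per-cell rate variability
#'
#' Draws one fixed parameter table for a population of cells: every rate
#' constant (synthesis, turnover, complex formation) of every cell is drawn
#' independently from a uniform distribution centred on its nominal value
#' with the requested coefficient of variation, i.e. on
#' `[nominal (1 - sqrt(3) cv), nominal (1 + sqrt(3) cv)]`, truncated at zero.
#' Delays, Hill constants/coefficients, edge weights and geometry are not
#' varied. The table is fixed for the lifetime of the cells: this static
#' rate heterogeneity is the model's pseudo-stochasticity.
#'
#' @param p Nominal `segclock_params`.
#' @param n_cells Number of cells (rows) to sample.
#' @param seed Integer seed; identical `(p, n_cells, seed)` gives an
#'   identical table.
#' @return A `cell_params` object: numeric matrix with one row per cell and
#'   one column per model parameter (non-rate parameters are replicated
#'   unchanged), with the nominal parameters kept as attribute `nominal`.
#' @export
sample_cell_parameters <- function(p, n_cells, seed) {
  stopifnot(inherits(p, "segclock_params"), n_cells >= 1)
  validate_parameters(p)
  nm <- names(p)
  tab <- matrix(rep(unlist(p), each = n_cells), nrow = n_cells,
                dimnames = list(NULL, nm))
  cv <- p$cell_cv
  if (cv > 0) {
    half <- sqrt(3) * cv
    if (half > 1) {
      warning("cell_cv ", cv, " implies a negative lower bound; ",
              "draws are truncated at 0")
    }
    with_seed(seed, {
      for (r in .rate_param_names) {
        nominal <- p[[r]]
        lo <- nominal * (1 - half)
        hi <- nominal * (1 + half)
        tab[, r] <- pmax(0, stats::runif(n_cells, lo, hi))
      }
    })
  }
  structure(tab, class = c("cell_params", "matrix", "array"), nominal = p)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so package sampling never disturbs the user's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  eval(code, envir = parent.frame())
}

#' Write / read a parameter set as flat YAML
#'
#' Parameters serialize to a flat name->value mapping using the model's
#' symbol names (`psd`, `psm_a`, `psm_b`, ...). Reading is fail-closed:
#' unknown keys are an error, and missing keys keep their defaults only when
#' `partial = TRUE`.
#'
#' @param p A `segclock_params` object.
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param partial Logical; if `FALSE` (default) the file must contain every
#'   parameter.
#' @return `write_parameters` returns `path` invisibly; `read_parameters`
#'   returns a `segclock_params` object.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "segclock_params"))
  vals <- lapply(unclass(p), function(x) unname(x))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path, partial = FALSE) {
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- default_parameters()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!partial) {
    missing <- setdiff(names(defaults), names(vals))
    if (length(missing)) {
      stop("missing parameter key(s) in ", path, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  do.call(default_parameters, lapply(vals, as.numeric))
}
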