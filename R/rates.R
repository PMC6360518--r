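# Regulatory rate laws of the segmentation network, as pure (vectorised)
# functions of possibly delayed state. These are the single source of truth
# for the network topology: the lattice integrator calls exactly these.

check_nonneg <- function(...) {
  args <- list(...)
  for (a in args) {
    if (any(!is.finite(a)) || any(a < 0)) {
      stop("concentrations must be finite and nonnegative", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' her transcription rate
#'
#' The clock pacemaker edge set: delayed autorepression by the Her homodimer
#' multiplying a Notch-stimulated activation term. The repressor and NICD
#' arguments are the state at `t - tau_m_her`.
#'
#' `rate = tc_her * hill_repression(HerDimer) * (basal_her +
#'  w_notch_her * hill_activation(NICD))`
#'
#' @param her_dimer_delayed Her homodimer abundance at `t - tau_m_her`.
#' @param nicd_delayed NICD abundance at `t - tau_m_her`.
#' @param p Parameters (`segclock_params` or a per-cell parameter row/table
#'   coerced to a list of vectors).
#' @return Transcription rate, molecules/min; strictly decreasing in the
#'   dimer, nondecreasing in NICD.
#' @export
transcription_rate_her <- function(her_dimer_delayed, nicd_delayed, p) {
  check_nonneg(her_dimer_delayed, nicd_delayed)
  p$tc_her *
    hill_repression(her_dimer_delayed, p$K_hd_her, p$n_hd_her) *
    (p$basal_her +
       p$w_notch_her * hill_activation(nicd_delayed, p$K_nicd_her, p$n_nicd_her))
}

#' deltaC transcription rate
#'
#' deltaC is repressed by the her genes, so Delta ligand production tracks
#' the clock in phase with her.
#'
#' @inheritParams transcription_rate_her
#' @return `tc_delta * hill_repression(HerDimer)`, molecules/min.
#' @export
transcription_rate_delta <- function(her_dimer_delayed, p) {
  check_nonneg(her_dimer_delayed)
  p$tc_delta * hill_repression(her_dimer_delayed, p$K_hd_delta, p$n_hd_delta)
}

#' mespa transcription rate
#'
#' The incoherent feedforward target: Notch activates mespa directly
#' (strong edge) and represses it indirectly through Notch-stimulated her;
#' Tbx6 contributes a weak activating input. Transcription is gated to the
#' anterior compartment (the static FGF determination front).
#'
#' @param nicd_delayed,tbx6_delayed,her_dimer_delayed State at
#'   `t - tau_m_mespa`.
#' @param is_anterior Logical (per cell): column >= `anterior_gate_col`.
#' @param p Parameters.
#' @return Transcription rate, molecules/min; exactly 0 for posterior cells.
#' @export
transcription_rate_mespa <- function(nicd_delayed, tbx6_delayed,
                                     her_dimer_delayed, is_anterior, p) {
  check_nonneg(nicd_delayed, tbx6_delayed, her_dimer_delayed)
  act <- p$w_notch_a * hill_activation(nicd_delayed, p$K_notch_a, p$n_notch_a) +
    p$w_tbx_a * hill_activation(tbx6_delayed, p$K_tbx_a, p$n_tbx_a)
  rate <- p$tc_mespa * act *
    hill_repression(her_dimer_delayed, p$K_hd_mespa, p$n_hd_mespa)
  rate * as.numeric(is_anterior)
}

#' mespb transcription rate
#'
#' mespb depends strongly on Tbx6 and weakly on Notch, with no direct Her
#' repression: its clock response is indirect (via ripply/Tbx6), matching
#' its delayed perturbation kinetics.
#'
#' @param nicd_delayed,tbx6_delayed State at `t - tau_m_mespb`.
#' @inheritParams transcription_rate_mespa
#' @return Transcription rate, molecules/min; exactly 0 for posterior cells.
#' @export
transcription_rate_mespb <- function(nicd_delayed, tbx6_delayed,
                                     is_anterior, p) {
  check_nonneg(nicd_delayed, tbx6_delayed)
  act <- p$w_tbx_b * hill_activation(tbx6_delayed, p$K_tbx_b, p$n_tbx_b) +
    p$w_notch_b * hill_activation(nicd_delayed, p$K_notch_b, p$n_notch_b)
  p$tc_mespb * act * as.numeric(is_anterior)
}

#' ripply transcription rate
#'
#' Activated by the summed Mesp proteins (either paralog group suffices),
#' closing the mesp -> ripply -| Tbx6 -> mespb negative feedback loop.
#'
#' @param mespa_prot_delayed,mespb_prot_delayed Protein abundances at
#'   `t - tau_m_ripply`.
#' @inheritParams transcription_rate_her
#' @return Transcription rate, molecules/min; nondecreasing in both inputs.
#' @export
transcription_rate_ripply <- function(mespa_prot_delayed, mespb_prot_delayed, p) {
  check_nonneg(mespa_prot_delayed, mespb_prot_delayed)
  p$tc_ripply * hill_activation(mespa_prot_delayed + mespb_prot_delayed,
                                p$K_ripply_act, p$n_ripply_act)
}

#' Net Tbx6 rate
#'
#' Tbx6 protein is synthesised at a constant basal rate, decays first-order,
#' and is additionally removed in a Ripply-dependent manner (Ripply reduces
#' the abundance of Tbx6 post-translationally).
#'
#' @param tbx6 Current Tbx6 abundance.
#' @param ripply_prot Current Ripply protein abundance.
#' @inheritParams transcription_rate_her
#' @return Net dTbx6/dt, molecules/min; with no Ripply the steady state is
#'   `basal_tbx6 / deg_tbx6`.
#' @export
tbx6_rate <- function(tbx6, ripply_prot, p) {
  check_nonneg(tbx6, ripply_prot)
  p$basal_tbx6 - p$deg_tbx6 * tbx6 -
    p$k_rip * hill_activation(ripply_prot, p$K_rip, p$n_rip) * tbx6
}

#' NICD production rate
#'
#' Proteolytic Notch activation driven by the Delta protein presented by a
#' cell's lattice neighbours, taken as the arithmetic mean over the
#' neighbour set at `t - tau_nicd` (a cell with no neighbours receives 0).
#'
#' @param neighbor_delta_mean Mean neighbour Delta abundance at
#'   `t - tau_nicd`.
#' @inheritParams transcription_rate_her
#' @return NICD production rate, molecules/min (NICD decays first-order at
#'   `deg_nicd` in the state equations).
#' @export
nicd_production <- function(neighbor_delta_mean, p) {
  check_nonneg(neighbor_delta_mean)
  p$k_nicd * hill_activation(neighbor_delta_mean, p$K_delta, p$n_delta)
}
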