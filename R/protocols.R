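# Declarative, time-windowed parameter perturbations. A protocol is a list
# of actions {param, action (set|multiply), value, t_on, t_off}; actions
# apply uniformly to all cells (mutants, bath-applied DAPT, and heat-shock
# induction are global exposures) and compose in list order.

#' Build a perturbation protocol
#'
#' @param actions A list of actions, each a list/vector with fields `param`
#'   (a model parameter name), `action` (`"set"` or `"multiply"`), `value`,
#'   `t_on` and `t_off` (minutes; `t_off = Inf` for permanent). An empty
#'   list is the wild-type protocol.
#' @param name Optional label.
#' @return A `perturbation_protocol` object.
#' @examples
#' dapt <- perturbation_protocol(list(
#'   list(param = "psd", action = "set", value = 0, t_on = 600, t_off = Inf)
#' ), name = "dapt")
#' @export
perturbation_protocol <- function(actions = list(), name = "wt") {
  acts <- lapply(actions, function(a) {
    a <- as.list(a)
    need <- c("param", "action", "value", "t_on", "t_off")
    miss <- setdiff(need, names(a))
    if (length(miss)) {
      stop("protocol action missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (!a$action %in% c("set", "multiply")) {
      stop("unknown protocol action '", a$action, "' (use set or multiply)",
           call. = FALSE)
    }
    a$value <- as.numeric(a$value)
    a$t_on <- as.numeric(a$t_on)
    a$t_off <- as.numeric(a$t_off)
    if (is.na(a$t_off)) a$t_off <- Inf
    if (a$t_on > a$t_off) stop("action has t_on > t_off", call. = FALSE)
    a[need]
  })
  structure(list(actions = acts, name = name), class = "perturbation_protocol")
}

#' @export
format.perturbation_protocol <- function(x, ...) {
  if (!length(x$actions)) return(paste0(x$name, " (no actions)"))
  paste0(x$name, ": ", paste(vapply(x$actions, function(a) {
    sprintf("%s %s %g on [%g, %g)", a$param, a$action, a$value, a$t_on, a$t_off)
  }, character(1)), collapse = "; "))
}

#' @export
print.perturbation_protocol <- function(x, ...) {
  cat("<perturbation_protocol> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Validate a protocol against a parameter table
#'
#' Every targeted parameter must exist in the model; delays and Hill
#' coefficients cannot be perturbed mid-run (they are structural).
#'
#' @param protocol A `perturbation_protocol`.
#' @param cell_params A `cell_params` table (or anything with the model's
#'   parameter columns).
#' @return The protocol, invisibly; errors on an unknown or structural
#'   target.
#' @export
validate_protocol <- function(protocol, cell_params) {
  stopifnot(inherits(protocol, "perturbation_protocol"))
  known <- colnames(cell_params)
  for (a in protocol$actions) {
    if (!a$param %in% known) {
      stop("protocol targets unknown parameter '", a$param, "'", call. = FALSE)
    }
    if (a$param %in% .delay_param_names || grepl("^n_", a$param)) {
      stop("protocol cannot modify structural parameter '", a$param, "'",
           call. = FALSE)
    }
  }
  invisible(protocol)
}

# Times at which the set of active actions changes.
protocol_event_times <- function(protocol) {
  if (!length(protocol$actions)) return(numeric(0))
  sort(unique(unlist(lapply(protocol$actions, function(a) {
    c(a$t_on, if (is.finite(a$t_off)) a$t_off)
  }))))
}

#' Effective per-cell parameters at a time
#'
#' Pure function: returns the nominal table with every action whose window
#' `[t_on, t_off)` contains `t` applied, in list order (`set` overrides the
#' per-cell value uniformly; `multiply` scales each cell's value).
#'
#' @param nominal A `cell_params` table.
#' @param protocol A `perturbation_protocol`.
#' @param t Time (min).
#' @return A parameter table of the same shape.
#' @export
apply_perturbation <- function(nominal, protocol, t) {
  validate_protocol(protocol, nominal)
  eff <- nominal
  for (a in protocol$actions) {
    if (t >= a$t_on && t < a$t_off) {
      eff[, a$param] <- switch(a$action,
        set = a$value,
        multiply = eff[, a$param] * a$value
      )
    }
  }
  eff
}

#' Named perturbation presets
#'
#' The model's in-silico experiments as ready-made protocols:
#' \describe{
#'   \item{wt}{no perturbation.}
#'   \item{notch_mutant}{`psd = 0` for the whole run (notch pathway null:
#'     no functional Delta ligand is ever made).}
#'   \item{dapt}{`psd = 0` from `t_on` (default 600 min) onwards, the
#'     gamma-secretase-inhibitor washout-free treatment.}
#'   \item{her_oe}{her translation (`psh`) multiplied by `fold` during a
#'     30-min heat-shock window starting at `t_on`.}
#'   \item{mespa_oe / mespb_oe}{`psm_a` / `psm_b` multiplied by `fold`
#'     during a 60-min window starting at `t_on`.}
#'   \item{ripply_oe}{`psr` multiplied by `fold` during a 60-min window.}
#'   \item{her_mutant}{her translation set to 0 for the whole run.}
#' }
#'
#' @param name Preset name.
#' @param fold Overexpression factor (default 20).
#' @param t_on Onset time (min; default 600, ignored by whole-run presets).
#' @param duration Window length (min); defaults to the preset's own
#'   convention (30 min for `her_oe`, 60 min for the mesp/ripply
#'   overexpressions).
#' @return A validated `perturbation_protocol`.
#' @examples
#' protocol_preset("dapt")
#' protocol_preset("mespb_oe", fold = 10)
#' @export
protocol_preset <- function(name, fold = 20, t_on = 600, duration = NULL) {
  presets <- c("wt", "notch_mutant", "dapt", "her_oe", "mespa_oe",
               "mespb_oe", "ripply_oe", "her_mutant")
  if (!name %in% presets) {
    stop("unknown preset '", name, "'; valid presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  act <- function(param, action, value, on, off) {
    list(param = param, action = action, value = value, t_on = on, t_off = off)
  }
  actions <- switch(name,
    wt = list(),
    notch_mutant = list(act("psd", "set", 0, 0, Inf)),
    dapt = list(act("psd", "set", 0, t_on, Inf)),
    her_oe = {
      off <- t_on + (duration %||% 30)
      # heat-shock induction: boosted translation of the transcript pool
      # plus an autorepression-independent transgene mRNA supply
      list(act("psh", "multiply", fold, t_on, off),
           act("hs_her_m_supply", "set", 33, t_on, off))
    },
    mespa_oe = list(act("psm_a", "multiply", fold, t_on,
                        t_on + (duration %||% 60))),
    mespb_oe = list(act("psm_b", "multiply", fold, t_on,
                        t_on + (duration %||% 60))),
    ripply_oe = list(act("psr", "multiply", fold, t_on,
                         t_on + (duration %||% 60))),
    her_mutant = list(act("psh", "set", 0, 0, Inf))
  )
  perturbation_protocol(actions, name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a protocol as YAML
#'
#' The schema is a mapping with `name` and a list `actions` of
#' `{param, action, value, t_on, t_off}`; `t_off: .inf` or the string
#' `"Inf"` denotes a permanent action. Every preset round-trips unchanged.
#'
#' @param protocol A `perturbation_protocol`.
#' @param path File path.
#' @return `write_protocol` returns `path` invisibly; `read_protocol`
#'   returns the protocol.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "perturbation_protocol"))
  obj <- list(name = protocol$name,
              actions = lapply(protocol$actions, function(a) {
                if (!is.finite(a$t_off)) a$t_off <- "Inf"
                a
              }))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- yaml::read_yaml(path)
  extra <- setdiff(names(obj), c("name", "actions"))
  if (length(extra)) {
    stop("unknown protocol key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  acts <- lapply(obj$actions %||% list(), function(a) {
    if (identical(a$t_off, "Inf") || identical(a$t_off, ".inf")) a$t_off <- Inf
    a
  })
  perturbation_protocol(acts, name = obj$name %||% "protocol")
}
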