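# Run configuration and output archiving. Configs are strict-schema YAML:
# unknown keys are an error, so a typo cannot silently fall back to a
# default. A run is reproducible from its archived config alone.

.config_keys <- c("lattice", "parameters", "protocol", "t_end", "dt",
                  "seed", "output_stride", "thresholds", "out_dir")
.lattice_keys <- c("n_rows", "n_cols", "cell_diameter_um")
.threshold_keys <- c("loss_frac", "sync_threshold", "stripe_threshold_frac",
                     "min_stripe_width")

#' Default run configuration
#'
#' @return A `run_config` list with the shipped defaults: the 4 x 50
#'   lattice, nominal parameters, wild-type protocol, 1200 simulated
#'   minutes at dt = 0.1 with 1-min output stride, and the default
#'   loss/desync/stripe thresholds.
#' @export
default_config <- function() {
  structure(list(
    lattice = list(n_rows = 4L, n_cols = 50L, cell_diameter_um = 8),
    parameters = default_parameters(),
    protocol = protocol_preset("wt"),
    t_end = 1200,
    dt = 0.1,
    seed = 1L,
    output_stride = 1,
    thresholds = list(loss_frac = 0.1, sync_threshold = 0.5,
                      stripe_threshold_frac = 0.5, min_stripe_width = 2L),
    out_dir = "."
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Fail-closed: any key not in the schema is an error naming the offending
#' key. `parameters` holds flat overrides of [default_parameters()];
#' `protocol` is either a preset name, a protocol file path, or an inline
#' `{name, actions}` mapping.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- default_config()
  if (!is.null(raw$lattice)) {
    unknown <- setdiff(names(raw$lattice), .lattice_keys)
    if (length(unknown)) {
      stop("unknown lattice key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg$lattice[names(raw$lattice)] <- raw$lattice
  }
  if (!is.null(raw$parameters)) {
    cfg$parameters <- do.call(default_parameters,
                              lapply(raw$parameters, as.numeric))
  }
  if (!is.null(raw$protocol)) {
    cfg$protocol <- if (is.character(raw$protocol)) {
      if (file.exists(raw$protocol)) read_protocol(raw$protocol)
      else protocol_preset(raw$protocol)
    } else {
      acts <- lapply(raw$protocol$actions %||% list(), function(a) {
        if (identical(a$t_off, "Inf")) a$t_off <- Inf
        a
      })
      perturbation_protocol(acts, name = raw$protocol$name %||% "protocol")
    }
  }
  for (k in c("t_end", "dt", "seed", "output_stride")) {
    if (!is.null(raw[[k]])) cfg[[k]] <- raw[[k]]
  }
  if (!is.null(raw$thresholds)) {
    unknown <- setdiff(names(raw$thresholds), .threshold_keys)
    if (length(unknown)) {
      stop("unknown threshold key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg$thresholds[names(raw$thresholds)] <- raw$thresholds
  }
  if (!is.null(raw$out_dir)) cfg$out_dir <- raw$out_dir
  cfg
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  obj <- list(
    lattice = config$lattice,
    parameters = lapply(unclass(config$parameters), unname),
    protocol = list(name = config$protocol$name,
                    actions = lapply(config$protocol$actions, function(a) {
                      if (!is.finite(a$t_off)) a$t_off <- "Inf"
                      a
                    })),
    t_end = config$t_end, dt = config$dt, seed = config$seed,
    output_stride = config$output_stride,
    thresholds = config$thresholds,
    out_dir = config$out_dir
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Run a simulation from a configuration
#'
#' @param config A `run_config` (from [load_config()] or
#'   [default_config()]).
#' @return A `segclock_sim`.
#' @export
run_config <- function(config) {
  cfg <- lattice_config(config$lattice$n_rows, config$lattice$n_cols,
                        config$lattice$cell_diameter_um)
  cp <- sample_cell_parameters(config$parameters,
                               cfg$n_rows * cfg$n_cols, config$seed)
  integrate_lattice(cfg, cp, config$protocol, t_end = config$t_end,
                    dt = config$dt, seed = config$seed,
                    output_stride = config$output_stride)
}

#' Simulation result as a long-format data frame
#'
#' @param sim A `segclock_sim`.
#' @param every_min Keep snapshots at this spacing (min) to bound the
#'   table size.
#' @param species Species subset (default all).
#' @return Data frame with columns `time`, `row`, `col`, `species`,
#'   `abundance` (`row`/`col` 0-based, posterior column 0).
#' @export
sim_to_long <- function(sim, every_min = 10, species = NULL) {
  species <- species %||% sim$species
  keep_t <- which(sim$time %% every_min == 0)
  cfg <- sim$cfg
  n_cells <- cfg$n_rows * cfg$n_cols
  rows <- rep((seq_len(n_cells) - 1L) %% cfg$n_rows, times = 1)
  cols <- cell_columns(cfg)
  do.call(rbind, lapply(species, function(spn) {
    m <- sim$x[keep_t, , species_index(spn)]
    data.frame(
      time = rep(sim$time[keep_t], times = n_cells),
      row = rep(rows, each = length(keep_t)),
      col = rep(cols, each = length(keep_t)),
      species = spn,
      abundance = as.vector(m)
    )
  }))
}

#' Archive a run's outputs
#'
#' Writes the long-format CSV, a JSON metric summary, the archived config,
#' and a manifest listing every artifact with its MD5 content hash.
#'
#' @param sim A `segclock_sim`.
#' @param metrics Named list/vector of scalar metrics (may be empty).
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` to archive alongside.
#' @param every_min CSV snapshot spacing (min).
#' @return Invisibly, the manifest as a data frame (`file`, `md5`).
#' @export
write_outputs <- function(sim, metrics = list(), dir, config = NULL,
                          every_min = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  csv <- file.path(dir, "result_long.csv")
  utils::write.csv(sim_to_long(sim, every_min = every_min), csv,
                   row.names = FALSE)
  files <- c(files, csv)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(list(seed = sim$seed, dt = sim$dt,
                            t_end = max(sim$time),
                            protocol = format(sim$protocol),
                            clip_frac = sim$clip_frac,
                            metrics = as.list(metrics)),
                       js, auto_unbox = TRUE, digits = NA)
  files <- c(files, js)
  if (!is.null(config)) {
    cfile <- file.path(dir, "config.yaml")
    write_config(config, cfile)
    files <- c(files, cfile)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"))
  invisible(manifest)
}
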