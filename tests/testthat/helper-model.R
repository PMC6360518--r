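# Shared fixtures and a lazy cache for expensive lattice runs, so that
# acceptance blocks that interrogate the same simulations (e.g. the
# Notch-inhibition time course) do not recompute them.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .run_cache)) assign(key, force(expr), .run_cache)
  get(key, .run_cache)
}

# Full-size wild-type run (4 x 50, 900 min) on the shipped defaults.
wt_run <- function(seed = 1) {
  cached(paste0("wt", seed), {
    cfg <- lattice_config()
    p <- default_parameters()
    cp <- sample_cell_parameters(p, cfg$n_rows * cfg$n_cols, seed)
    integrate_lattice(cfg, cp, protocol_preset("wt"), t_end = 900,
                      dt = 0.1, seed = seed)
  })
}

# Notch-inhibition (DAPT) run, 1200 min, psd = 0 from 600 min.
dapt_run <- function(seed) {
  cached(paste0("dapt", seed), {
    cfg <- lattice_config()
    p <- default_parameters()
    cp <- sample_cell_parameters(p, cfg$n_rows * cfg$n_cols, seed)
    integrate_lattice(cfg, cp, protocol_preset("dapt"), t_end = 1200,
                      dt = 0.1, seed = seed)
  })
}

# her heat-shock overexpression run (psh x20 + transgene supply, 600-630).
her_oe_run <- function(seed) {
  cached(paste0("heroe", seed), {
    cfg <- lattice_config()
    p <- default_parameters()
    cp <- sample_cell_parameters(p, cfg$n_rows * cfg$n_cols, seed)
    integrate_lattice(cfg, cp, protocol_preset("her_oe"), t_end = 1200,
                      dt = 0.1, seed = seed)
  })
}

# Small tissue for cheap engine checks.
small_run <- function(t_end = 300, seed = 1, preset = "wt", n_cols = 12, ...) {
  cfg <- lattice_config(4, n_cols)
  p <- default_parameters(anterior_gate_col = n_cols - 2, ...)
  cp <- sample_cell_parameters(p, cfg$n_rows * cfg$n_cols, seed)
  integrate_lattice(cfg, cp, protocol_preset(preset), t_end = t_end,
                    dt = 0.1, seed = seed)
}

anterior_cols_idx <- function(sim) {
  p <- attr(sim$cell_params, "nominal")
  (p$anterior_gate_col:(sim$cfg$n_cols - 1)) + 1L
}
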