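# Space-time rendering of simulation output: columns (posterior left) on
# the horizontal axis, time running down, intensity proportional to the
# row-averaged transcript number. Zero is black; the red/green overlay
# shows her against mesp, the complementary-stripe readout.

# time x columns intensity matrix for one species, normalized to [0, 1].
kymograph_matrix <- function(sim, species) {
  isp <- species_index(species)
  cols <- cell_columns(sim$cfg)
  m <- t(apply(sim$x[, , isp], 1, function(v) tapply(v, cols, mean)))
  mx <- max(m)
  if (mx > 0) m <- m / mx
  m
}

#' Render a kymograph to PNG
#'
#' One or two species: a single species maps to a grey-scale space-time
#' plot (maximum mapped to full intensity, zero to black); two species map
#' to the red and green channels of an overlay, the standard her (red) /
#' mesp (green) presentation. Output is pixel-deterministic given the
#' simulation.
#'
#' @param sim A `segclock_sim`.
#' @param species Character vector of 1 or 2 species names.
#' @param path Output PNG path.
#' @param scale Integer pixel upscaling per (column, snapshot).
#' @return `path`, invisibly.
#' @export
render_kymograph <- function(sim, species, path, scale = 3) {
  stopifnot(length(species) %in% c(1, 2))
  mats <- lapply(species, function(s) kymograph_matrix(sim, s))
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  img <- array(0, dim = c(h, w, 3))
  if (length(species) == 1) {
    img[, , 1] <- mats[[1]]; img[, , 2] <- mats[[1]]; img[, , 3] <- mats[[1]]
  } else {
    img[, , 1] <- mats[[1]]
    img[, , 2] <- mats[[2]]
  }
  if (scale > 1) {
    img <- img[rep(seq_len(h), each = scale), rep(seq_len(w), each = scale), ,
               drop = FALSE]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Render a lattice snapshot to PNG
#'
#' A single time point as a rows x columns heat map (posterior left),
#' grey-scale for one species or red/green overlay for two.
#'
#' @inheritParams render_kymograph
#' @param t Snapshot time (min); nearest recorded snapshot is used.
#' @export
render_snapshot <- function(sim, species, t, path, scale = 8) {
  stopifnot(length(species) %in% c(1, 2))
  it <- which.min(abs(sim$time - t))
  cfg <- sim$cfg
  grab <- function(s) {
    v <- sim$x[it, , species_index(s)]
    m <- matrix(v, cfg$n_rows, cfg$n_cols)
    mx <- max(m)
    if (mx > 0) m / mx else m
  }
  mats <- lapply(species, grab)
  img <- array(0, dim = c(cfg$n_rows, cfg$n_cols, 3))
  if (length(species) == 1) {
    for (k in 1:3) img[, , k] <- mats[[1]]
  } else {
    img[, , 1] <- mats[[1]]
    img[, , 2] <- mats[[2]]
  }
  img <- img[rep(seq_len(cfg$n_rows), each = scale),
             rep(seq_len(cfg$n_cols), each = scale), , drop = FALSE]
  png::writePNG(img, path)
  invisible(path)
}
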