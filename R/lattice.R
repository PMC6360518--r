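# Hexagonal lattice geometry. The tissue is a fixed grid of n_rows x n_cols
# cells in "even-r" offset coordinates (pointy-top hexagons, even rows
# shifted left). Column 0 is the posterior end of the PSM, column
# n_cols - 1 the anterior end. Cells are numbered 1..n_cells column-major
# (row fastest), so a block of posterior columns is contiguous.

#' Lattice configuration
#'
#' @param n_rows Number of rows (default 4).
#' @param n_cols Number of columns along the posterior->anterior axis
#'   (default 50).
#' @param cell_diameter_um Physical column pitch in micrometres, used to
#'   convert stripe geometry from cells to distance.
#' @return A `lattice_config` object.
#' @examples
#' cfg <- lattice_config()        # the 4 x 50 PSM
#' @export
lattice_config <- function(n_rows = 4, n_cols = 50, cell_diameter_um = 8) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_diameter_um > 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 offset_convention = "even-r", cell_diameter_um = cell_diameter_um),
            class = "lattice_config")
}

#' @export
print.lattice_config <- function(x, ...) {
  cat("<lattice_config> ", x$n_rows, " x ", x$n_cols,
      " hexagonal (", x$offset_convention, "), ",
      x$cell_diameter_um, " um/column\n", sep = "")
  invisible(x)
}

#' Cell index from (row, col)
#'
#' @param row,col 0-based row and column indices.
#' @param cfg A `lattice_config`.
#' @return 1-based cell index (column-major: row varies fastest).
#' @export
cell_index <- function(row, col, cfg) {
  stopifnot(all(row >= 0), all(row < cfg$n_rows),
            all(col >= 0), all(col < cfg$n_cols))
  as.integer(row + cfg$n_rows * col + 1L)
}

#' Cells of a column range
#'
#' @param cols 0-based column indices.
#' @param cfg A `lattice_config`.
#' @return Integer vector of 1-based cell indices in those columns.
#' @export
column_cells <- function(cols, cfg) {
  as.integer(outer(0:(cfg$n_rows - 1), cfg$n_rows * cols, `+`) + 1L)
}

#' Hexagonal neighbours of a cell
#'
#' Even-r offset convention, no wraparound: interior cells have 6
#' neighbours, edge and corner cells fewer. Adjacency is symmetric and
#' irreflexive.
#'
#' @param row,col 0-based indices of the focal cell.
#' @param cfg A `lattice_config`.
#' @return Integer vector of neighbour cell indices (1-based).
#' @examples
#' cfg <- lattice_config()
#' length(hex_neighbors(1, 25, cfg))  # interior cell: 6
#' @export
hex_neighbors <- function(row, col, cfg) {
  if (length(row) != 1 || length(col) != 1 ||
      row < 0 || row >= cfg$n_rows || col < 0 || col >= cfg$n_cols) {
    stop("cell index out of range", call. = FALSE)
  }
  if (row %% 2 == 0) {
    d <- rbind(c(0, -1), c(0, 1), c(-1, -1), c(-1, 0), c(1, -1), c(1, 0))
  } else {
    d <- rbind(c(0, -1), c(0, 1), c(-1, 0), c(-1, 1), c(1, 0), c(1, 1))
  }
  rr <- row + d[, 1]
  cc <- col + d[, 2]
  keep <- rr >= 0 & rr < cfg$n_rows & cc >= 0 & cc < cfg$n_cols
  cell_index(rr[keep], cc[keep], cfg)
}

# Row-stochastic neighbour-averaging matrix: (W %*% x)[i] is the arithmetic
# mean of x over the neighbours of cell i (0 for an isolated cell).
neighbor_weight_matrix <- function(cfg) {
  n <- cfg$n_rows * cfg$n_cols
  W <- matrix(0, n, n)
  for (col in 0:(cfg$n_cols - 1)) {
    for (row in 0:(cfg$n_rows - 1)) {
      i <- cell_index(row, col, cfg)
      nb <- hex_neighbors(row, col, cfg)
      if (length(nb)) W[i, nb] <- 1 / length(nb)
    }
  }
  W
}

# 0-based column of each cell, length n_cells.
cell_columns <- function(cfg) {
  rep(0:(cfg$n_cols - 1), each = cfg$n_rows)
}
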