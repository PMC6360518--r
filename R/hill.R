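#' Hill activation function
#'
#' Fractional promoter occupancy of an activating regulator, the canonical
#' saturating input nonlinearity used for every activating edge of the
#' segmentation network (Notch -> her, Notch -> mespa/mespb, Tbx6 -> mespa/mespb,
#' Mesp -> ripply, neighbour Delta -> NICD, Ripply -> Tbx6 removal).
#'
#' @param x Regulator concentration (molecules), nonnegative. Vectorised.
#' @param K Half-saturation constant (molecules), strictly positive.
#' @param n Hill coefficient, >= 1.
#' @return `x^n / (K^n + x^n)`, a dimensionless fraction in `[0, 1]`,
#'   monotone nondecreasing in `x`.
#' @examples
#' hill_activation(2, K = 1, n = 2)  # 0.8
#' @seealso [hill_repression()]
#' @export
hill_activation <- function(x, K, n) {
  check_hill_args(x, K, n)
  xn <- (x / K)^n
  xn / (1 + xn)
}

#' Hill repression function
#'
#' Fractional promoter activity under a repressor, used for the repressive
#' edges of the network (Her dimer on her, deltaC and mespa transcription).
#' Complementary to [hill_activation()]: at equal arguments the two sum to 1.
#'
#' @inheritParams hill_activation
#' @return `K^n / (K^n + x^n)`, a fraction in `[0, 1]`, monotone nonincreasing.
#' @examples
#' hill_repression(3, K = 1, n = 1)  # 0.25
#' @export
hill_repression <- function(x, K, n) {
  check_hill_args(x, K, n)
  xn <- (x / K)^n
  1 / (1 + xn)
}

check_hill_args <- function(x, K, n) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("Hill input concentration must be finite and nonnegative", call. = FALSE)
  }
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("Hill half-saturation constant K must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("Hill coefficient n must be finite and >= 1", call. = FALSE)
  }
  invisible(TRUE)
}
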