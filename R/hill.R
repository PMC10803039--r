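#' Hill activation and repression multipliers
#'
#' Bounded monotone multipliers used for all regulatory interactions among
#' the polarity proteins: `hill_up()` rises from 0 to 1 with half-saturation
#' at `K`, `hill_down()` is its complement, so
#' `hill_up(x, K, n) + hill_down(x, K, n) == 1`.
#'
#' @param x Regulator amount (nonnegative).
#' @param K Half-saturation constant (> 0), same units as `x`.
#' @param n Hill exponent (>= 1).
#' @return Multiplier in `[0, 1]`; vectorized over `x`.
#' @examples
#' hill_up(3, 1, 2)   # 9/10
#' hill_down(0, 1, 2) # 1
#' @export
hill_up <- function(x, K, n = 2) {
  stopifnot(K > 0, n >= 1)
  ifelse(x <= 0, 0, x^n / (K^n + x^n))
}

#' @rdname hill_up
#' @export
hill_down <- function(x, K, n = 2) {
  stopifnot(K > 0, n >= 1)
  ifelse(x <= 0, 1, K^n / (K^n + x^n))
}
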