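#' Logarithmically spaced measurement frequency grid
#'
#' Builds the sweep grid used by the impedance simulator. Points are
#' log-spaced so that the two decades between 1 and 100 kHz are sampled
#' evenly on a Bode axis; the default grid has 30 points spanning exactly
#' 1--100 kHz, matching one row of a 15 x 30 impedance matrix.
#'
#' @param f_min Lowest frequency in Hz (> 0).
#' @param f_max Highest frequency in Hz (>= `f_min`).
#' @param n Number of points (>= 1; >= 2 when `f_max > f_min`).
#' @return Numeric vector of class `frequency_grid`, strictly increasing,
#'   with first element exactly `f_min` and last exactly `f_max`.
#' @examples
#' frequency_grid(1e3, 1e5, 30)
#' @export
frequency_grid <- function(f_min = 1e3, f_max = 1e5, n = 30L) {
  if (!is.numeric(f_min) || !is.numeric(f_max) || length(f_min) != 1L ||
      length(f_max) != 1L || !is.finite(f_min) || !is.finite(f_max)) {
    stop("f_min and f_max must be finite scalars", call. = FALSE)
  }
  if (f_min <= 0) stop("f_min must be positive", call. = FALSE)
  if (f_max < f_min) stop("f_max must be >= f_min", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  if (f_max > f_min && n < 2L) {
    stop("n must be >= 2 when f_max > f_min", call. = FALSE)
  }
  if (n == 1L) {
    f <- f_min
  } else {
    f <- exp(seq(log(f_min), log(f_max), length.out = n))
    # pin the endpoints so they are exact, not within floating slack
    f[1L] <- f_min
    f[n] <- f_max
  }
  structure(f, class = c("frequency_grid", "numeric"))
}
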