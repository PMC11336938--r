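#' Electrode-skin contact model (Randles circuit)
#'
#' Parameters of a single electrode's contact with the skin: a series
#' skin/gel resistance `R_d`, and a charge-transfer resistance `R_e` in
#' parallel with the double-layer capacitance `C_dl`.
#'
#' @param R_d Series (skin/gel) resistance, ohm.
#' @param C_dl Double-layer capacitance, farad.
#' @param R_e Charge-transfer resistance, ohm.
#' @return An object of class `electrode_skin_model`.
#' @export
electrode_skin_model <- function(R_d, C_dl, R_e) {
  vals <- c(R_d = R_d, C_dl = C_dl, R_e = R_e)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("R_d, C_dl and R_e must all be strictly positive and finite",
         call. = FALSE)
  }
  structure(list(R_d = R_d, C_dl = C_dl, R_e = R_e),
            class = "electrode_skin_model")
}

#' Complex electrode-skin contact impedance
#'
#' Evaluates the contact impedance at frequency `f`. The default (Randles)
#' reading is \deqn{Z(\omega) = R_d + \frac{1}{j\omega C_{dl} + 1/R_e},
#' \quad \omega = 2\pi f,} i.e. the double-layer capacitance in parallel
#' with the charge-transfer resistance, in series with the skin/gel
#' resistance. Raising `C_dl` lowers the magnitude at any fixed frequency,
#' which is the mechanism exploited by high-capacitance electrode coatings.
#'
#' `literal = TRUE` evaluates the degenerate three-series-terms reading
#' `R_d + 1/(j w C_dl) + 1/R_e` (dimensionally inconsistent, exposed only
#' for comparison).
#'
#' @param model An [electrode_skin_model()].
#' @param f Frequency in Hz (vectorised, all > 0).
#' @param literal Use the literal series reading instead of the Randles
#'   parallel form. Default `FALSE`.
#' @return Complex impedance in ohm, same length as `f`. For the Randles
#'   form the real part lies in `[R_d, R_d + R_e]` and the imaginary part
#'   is non-positive.
#' @export
electrode_skin_impedance <- function(model, f, literal = FALSE) {
  stopifnot(inherits(model, "electrode_skin_model"))
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("f must be positive and finite", call. = FALSE)
  }
  w <- 2 * pi * f
  if (isTRUE(literal)) {
    return(model$R_d + 1 / (1i * w * model$C_dl) + 1 / model$R_e)
  }
  model$R_d + 1 / (1i * w * model$C_dl + 1 / model$R_e)
}

#' Cole-type tissue dispersion parameters
#'
#' Single-dispersion Cole model of a current path through tissue:
#' resistive plateaus `R0` (zero frequency) and `Rinf` (infinite
#' frequency) joined by a fractional-exponent relaxation centred at `fc`.
#' Lipid-rich tissue presents a higher low-frequency plateau because
#' intact lipid bilayers block low-frequency current, while lean hydrated
#' tissue is more conductive.
#'
#' @param R0 Zero-frequency path resistance, ohm (`R0 > Rinf`).
#' @param Rinf Infinite-frequency path resistance, ohm (> 0).
#' @param fc Characteristic frequency, Hz (> 0).
#' @param alpha Dispersion exponent in (0, 1]; 1 recovers a single-pole
#'   Debye relaxation.
#' @return An object of class `tissue_dispersion`.
#' @export
tissue_dispersion <- function(R0, Rinf, fc, alpha = 1) {
  if (!all(is.finite(c(R0, Rinf, fc, alpha)))) {
    stop("dispersion parameters must be finite", call. = FALSE)
  }
  if (Rinf <= 0 || R0 <= Rinf) {
    stop("need R0 > Rinf > 0", call. = FALSE)
  }
  if (fc <= 0) stop("fc must be positive", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  structure(list(R0 = R0, Rinf = Rinf, fc = fc, alpha = alpha),
            class = "tissue_dispersion")
}

#' Complex tissue-path impedance (Cole model)
#'
#' \deqn{Z(f) = R_\infty + \frac{R_0 - R_\infty}{1 + (jf/f_c)^\alpha}}
#' The magnitude is monotonically non-increasing in frequency, with
#' limits `R0` as `f -> 0` and `Rinf` as `f -> Inf`.
#'
#' @param d A [tissue_dispersion()].
#' @param f Frequency in Hz (vectorised, all > 0).
#' @return Complex impedance in ohm, same length as `f`.
#' @export
tissue_path_impedance <- function(d, f) {
  stopifnot(inherits(d, "tissue_dispersion"))
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("f must be positive and finite", call. = FALSE)
  }
  s <- (1i * f / d$fc)^d$alpha
  d$Rinf + (d$R0 - d$Rinf) / (1 + s)
}
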