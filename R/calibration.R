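# Standard-curve quantification: 6mA/dA ratios in ppm from MRM calibration
# and transcript copies per cell from a qPCR standard curve.

#' Fit a linear calibration curve
#'
#' Ordinary least squares of `response` on `amount`; with
#' `throughOrigin = TRUE` the intercept is fixed at zero.
#'
#' @param amount standard amounts (>= 2 distinct values).
#' @param response measured responses (same length).
#' @param analyte label stored on the curve.
#' @param xUnits,yUnits axis units (documentation only).
#' @param throughOrigin force the line through the origin.
#' @return A [CalibrationCurve-class].
#' @examples
#' fitCalibration(1:5, 2 * (1:5))  # slope 2, intercept 0, R2 = 1
#' @export
fitCalibration <- function(amount, response, analyte = "",
                           xUnits = "amount", yUnits = "response",
                           throughOrigin = FALSE) {
  if (length(amount) != length(response))
    stop("amount and response must have the same length")
  if (length(unique(amount)) < 2L)
    stop("at least 2 distinct standard amounts are required")
  if (throughOrigin) {
    fit <- lm(response ~ amount + 0)
    slope <- unname(coef(fit)[1]); intercept <- 0
  } else {
    fit <- lm(response ~ amount)
    slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  }
  ssRes <- sum(residuals(fit)^2)
  ssTot <- sum((response - mean(response))^2)
  r2 <- if (ssTot > 0) max(0, min(1, 1 - ssRes / ssTot)) else 1
  new("CalibrationCurve", slope = slope, intercept = intercept,
      r.squared = r2, analyte = analyte, xUnits = xUnits, yUnits = yUnits,
      n = length(amount))
}

# invert a calibration curve: amount at a given response
.invertCurve <- function(response, curve) {
  if (curve@slope == 0) stop("curve slope is zero; cannot invert")
  (response - curve@intercept) / curve@slope
}

#' Quantify the 6mA/dA ratio in ppm
#'
#' Inverts each analyte's calibration curve at the measured MRM peak area
#' and reports `amount_6mA / amount_dA * 1e6`. A 6mA amount inverted below
#' zero is clamped to 0 and flagged below the limit of detection; a
#' non-positive dA amount is an error (it is the denominator).
#'
#' @param area6mA,areaDA integrated MRM peak areas (>= 0).
#' @param curve6mA,curveDA [CalibrationCurve-class] objects for 6mA
#'   (transition m/z 266 to 150) and dA (252 to 136).
#' @return `data.frame` with `ppm` and `below_lod`.
#' @examples
#' c6 <- fitCalibration(c(0, 1), c(0, 2))   # y = 2x
#' cA <- fitCalibration(c(0, 1), c(0, 1))   # y = x
#' quantifyRatioPpm(4, 1e6, c6, cA)         # 2 ppm
#' @export
quantifyRatioPpm <- function(area6mA, areaDA, curve6mA, curveDA) {
  if (any(area6mA < 0) || any(areaDA < 0)) stop("areas must be >= 0")
  amt6 <- .invertCurve(area6mA, curve6mA)
  amtA <- .invertCurve(areaDA, curveDA)
  if (any(amtA <= 0))
    stop("inverted dA amount is not positive; cannot form the ratio")
  # tolerance absorbs float residue of the fitted coefficients at the
  # inversion's own scale
  eps <- 64 * .Machine$double.eps *
    pmax(1, abs(area6mA), abs(curve6mA@intercept)) / abs(curve6mA@slope)
  below <- amt6 <= eps
  amt6[below] <- 0
  data.frame(ppm = amt6 / amtA * 1e6, below_lod = below)
}

#' Transcript copies per cell from a qPCR standard curve
#'
#' The standard curve is Ct against log10 template copies. The sample Ct
#' is inverted to total copies, `10^((ct - intercept) / slope)`, and
#' divided by the number of cells in the quantified sample (500,000 by
#' default).
#'
#' @param ct sample Ct value(s).
#' @param ctCurve [CalibrationCurve-class] of Ct vs log10 copies (slope
#'   must be non-zero; negative for a diluting series).
#' @param nCells cells in the quantified sample (> 0).
#' @return Copies per cell (vectorized over `ct`).
#' @examples
#' curve <- fitCalibration(c(2, 8), 40 - 3.3219 * c(2, 8),
#'                         xUnits = "log10 copies", yUnits = "Ct")
#' copiesPerCell(20, curve)  # about 2.10
#' @export
copiesPerCell <- function(ct, ctCurve, nCells = 500000) {
  if (ctCurve@slope == 0) stop("standard-curve slope must be non-zero")
  if (nCells <= 0) stop("nCells must be positive")
  10^((ct - ctCurve@intercept) / ctCurve@slope) / nCells
}
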