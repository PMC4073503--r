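#' Construct a fermentation curve
#'
#' @param time Time since inoculation in hours, strictly increasing.
#' @param co2 Cumulative CO2 released, g per L.
#' @param rate Optional rate vector (g/L/h), same length as \code{time}.
#'
#' @return A [FermentationCurve-class].
#' @export
FermentationCurve <- function(time, co2, rate = numeric()) {
  methods::new("FermentationCurve", time = as.numeric(time),
               co2 = as.numeric(co2), rate = as.numeric(rate))
}

#' @describeIn FermentationCurve-class Time vector (h).
#' @param x,object A \code{FermentationCurve}.
#' @export
curveTime <- function(x) x@time

#' @describeIn FermentationCurve-class Cumulative CO2 (g/L).
#' @export
curveCO2 <- function(x) x@co2

#' @describeIn FermentationCurve-class Rate vector (g/L/h), length 0 if not
#'   yet computed.
#' @export
curveRate <- function(x) x@rate

setMethod("show", "FermentationCurve", function(object) {
  n <- length(object@time)
  cat("FermentationCurve:", n, "samples over",
      if (n) round(max(object@time), 2) else 0, "h; final CO2",
      if (n) round(object@co2[n], 3) else NA, "g/L\n")
})

#' Cumulative CO2 from fermenter mass loss
#'
#' Converts a fermenter mass series to cumulative CO2 per liter:
#' \code{co2(t) = (mass(0) - mass(t)) / volume}. The fermenter only loses
#' mass as CO2 escapes, so negative excursions of the cumulative series
#' (weighing jitter) are clamped to the running maximum; an excursion at
#' least as large as the weighing precision additionally raises a warning.
#'
#' @param time_h Measurement times in hours, strictly increasing, >= 2
#'   samples.
#' @param mass_g Fermenter mass in grams at each time.
#' @param volume_L Fermentation volume in liters.
#' @param precision_g Weighing precision in grams (default 0.01); used only
#'   for the clamp warning threshold.
#'
#' @return A [FermentationCurve-class].
#' @export
co2FromMass <- function(time_h, mass_g, volume_L, precision_g = 0.01) {
  if (length(time_h) < 2L) stop("need at least 2 samples")
  if (length(mass_g) != length(time_h))
    stop("time_h and mass_g must have equal length")
  if (any(diff(time_h) <= 0)) stop("time must be strictly increasing")
  if (volume_L <= 0) stop("volume_L must be positive")
  co2 <- (mass_g[1L] - mass_g) / volume_L
  mono <- cummax(co2)
  dip <- mono - co2
  if (any(dip >= precision_g / volume_L))
    warning("mass increase beyond weighing precision at ",
            sum(dip >= precision_g / volume_L), " sample(s); clamped")
  FermentationCurve(time_h, mono)
}

#' CO2 production rate by trailing-window polynomial fitting
#'
#' At each time point a degree-\code{degree} polynomial is fitted by least
#' squares to the trailing window of the last \code{window_points}
#' cumulative-CO2 samples, and its analytic first derivative at the window's
#' last time is reported. The first \code{window_points - 1} positions carry
#' \code{NA} (no complete trailing window exists there).
#'
#' @param curve A [FermentationCurve-class] with at least
#'   \code{window_points} samples.
#' @param window_points Trailing window size (default 10, the number of mass
#'   measurements smoothed per rate estimate).
#' @param degree Polynomial degree (default 2); requires
#'   \code{window_points >= degree + 1}.
#'
#' @return Numeric rate vector (g/L/h), same length as the curve.
#' @export
co2Rate <- function(curve, window_points = 10L, degree = 2L) {
  w <- as.integer(window_points)
  degree <- as.integer(degree)
  if (w < degree + 1L) stop("window_points must be >= degree + 1")
  tt <- curveTime(curve)
  cc <- curveCO2(curve)
  n <- length(tt)
  if (n < w) stop("curve has fewer samples (", n,
                  ") than window_points (", w, ")")
  rate <- rep(NA_real_, n)
  for (i in w:n) {
    j <- (i - w + 1L):i
    x <- tt[j] - tt[i]               # centered at the window end
    X <- outer(x, 0:degree, `^`)
    beta <- stats::lm.fit(X, cc[j])$coefficients
    rate[i] <- beta[2L]              # d/dt at x = 0
  }
  rate
}

#' Checkpoint phenotype from a fermentation curve
#'
#' Linear interpolation of cumulative CO2 at the phenotyping checkpoint
#' (default 89 h, the start of stationary phase in the study conditions).
#'
#' @param curve A [FermentationCurve-class].
#' @param checkpoint_h Checkpoint time in hours; must lie inside the curve's
#'   time range.
#'
#' @return Scalar cumulative CO2 (g/L) at the checkpoint.
#' @export
phenotypeAt <- function(curve, checkpoint_h = 89) {
  tt <- curveTime(curve)
  if (checkpoint_h < min(tt) || checkpoint_h > max(tt))
    stop("checkpoint ", checkpoint_h, " h lies outside the curve's range [",
         min(tt), ", ", max(tt), "]")
  stats::approx(tt, curveCO2(curve), xout = checkpoint_h)$y
}
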