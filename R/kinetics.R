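#' Fit a single-exponential decay to a dissociation time course
#'
#' Nonlinear least squares of \eqn{y(t) = a e^{-kt} + c}, the model for a
#' dissociation process with a single rate-limiting step. Initialization is
#' deterministic (c0 = last value, a0 = first - last, k0 = 1/time span) with
#' a fixed three-point multi-start grid on k0 guarding against local minima;
#' inverse-variance weighting is used when per-point standard deviations are
#' provided. A near-constant series (value range below three times the
#' median sd) is returned as the degenerate fit a = 0, k = 0, c = mean.
#'
#' @param series a [SizeTimeSeries-class] with >= 4 points, or a data.frame
#'   with columns `time_s` and `value` (optional `sd`, `temperature_K`).
#' @return a [DecayFit-class].
#' @export
#' @examples
#' tt <- seq(0, 1e5, length.out = 20)
#' ser <- new("SizeTimeSeries", times = tt, values = 5 * exp(-2e-5 * tt) + 4,
#'            sd = rep(0, 20), temperature = 295.15, replicate = "1",
#'            unit = "nm")
#' decayParameters(fitDecay(ser))
fitDecay <- function(series) {
  if (is.data.frame(series)) {
    series <- methods::new("SizeTimeSeries",
      times = series$time_s, values = series$value,
      sd = if (is.null(series$sd)) rep(0, nrow(series)) else series$sd,
      temperature = if (is.null(series$temperature_K)) NA_real_ else
        series$temperature_K[1],
      replicate = "1", unit = "nm")
  }
  tt <- series@times; y <- series@values; sd <- series@sd
  if (length(tt) < 4) stop("at least 4 time points required")

  medSd <- stats::median(sd)
  if (medSd > 0 && diff(range(y)) < 3 * medSd) {
    return(methods::new("DecayFit", a = 0, k = 0, c = mean(y),
                        covariance = matrix(0, 3, 3),
                        rmsResidual = stats::sd(y), degenerate = TRUE,
                        temperature = series@temperature))
  }

  w <- if (all(sd > 0)) 1 / sd^2 else rep(1, length(y))
  span <- diff(range(tt))
  c0 <- y[length(y)]; a0 <- y[1] - c0
  if (a0 == 0) a0 <- diff(range(y))
  best <- NULL
  for (k0 in c(1, 0.3, 3) / span) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-k * tt) + c,
                        data = data.frame(tt = tt, y = y),
                        start = list(a = a0, k = k0, c = c0),
                        weights = w,
                        lower = c(-Inf, 0, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(w * stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("decay fit did not converge from any start (n = ", length(tt),
         ", span = ", span, " s)")
  cf <- stats::coef(best$fit)
  cov <- tryCatch(stats::vcov(best$fit), error = function(e) matrix(NA, 3, 3))
  dimnames(cov) <- NULL
  methods::new("DecayFit", a = unname(cf["a"]), k = max(unname(cf["k"]), 0),
               c = unname(cf["c"]), covariance = cov,
               rmsResidual = sqrt(mean(stats::resid(best$fit)^2)),
               degenerate = FALSE, temperature = series@temperature)
}

#' Arrhenius regression of rate constants on inverse temperature
#'
#' Ordinary least squares of \eqn{\ln k} on \eqn{1/T}; the activation
#' energy is \eqn{E_a = -slope \cdot R} (reported in kJ/mol) and the
#' intercept is \eqn{\ln A}. Rate constants from different techniques
#' (hydrodynamic sizing, single-particle mass reporters) can be pooled by
#' tagging each point with its source.
#'
#' @param points data.frame with columns `temperature` (K), `k` (1/s) and
#'   optionally `source`; at least two distinct temperatures, all k > 0.
#' @return an [ArrheniusFit-class].
#' @export
#' @examples
#' kp <- kineticParams()
#' tt <- c(295.15, 303.15, 310.15)
#' fitArrhenius(data.frame(temperature = tt, k = arrheniusRate(kp, tt)))
fitArrhenius <- function(points) {
  if (any(points$k <= 0)) stop("all rate constants must be > 0")
  if (length(unique(points$temperature)) < 2)
    stop("at least two distinct temperatures required")
  if (is.null(points$source)) points$source <- "unknown"
  invT <- 1 / points$temperature
  fit <- stats::lm(log(points$k) ~ invT)
  slope <- unname(stats::coef(fit)[2])
  seSlope <- if (nrow(points) > 2) summary(fit)$coefficients[2, 2] else 0
  R <- micellabConstants$R_J
  methods::new("ArrheniusFit", ea = -slope * R / 1000,
               lnA = unname(stats::coef(fit)[1]),
               seEa = seSlope * R / 1000,
               points = points[c("temperature", "k", "source")])
}

#' Rate constant and dissociation time scale at a temperature
#'
#' Evaluates the fitted Arrhenius law,
#' \eqn{k = \exp(\ln A - E_a/(RT))}, and its inverse — the characteristic
#' dissociation time.
#'
#' @param fit an [ArrheniusFit-class].
#' @param temperature K.
#' @return named numeric c(k = 1/s, timescale = s).
#' @export
rateAndTimescale <- function(fit, temperature) {
  k <- exp(fit@lnA -
             fit@ea * 1000 / (micellabConstants$R_J * temperature))
  c(k = k, timescale = 1 / k)
}

#' Dissociation-kinetics pipeline: series to activation energy
#'
#' Convenience chain used for synthetic-data validation: fit every time
#' course with [fitDecay()], collect the (T, k) pairs, and run
#' [fitArrhenius()] on them. Degenerate (near-constant) series are dropped
#' with a warning, since they carry no rate information.
#'
#' @param seriesList list of [SizeTimeSeries-class].
#' @param source label attached to the points, default "MDS".
#' @return an [ArrheniusFit-class].
#' @export
arrheniusFromSeries <- function(seriesList, source = "MDS") {
  fits <- lapply(seriesList, fitDecay)
  deg <- vapply(fits, function(f) f@degenerate, logical(1))
  if (any(deg)) {
    warning(sum(deg), " degenerate series dropped from the Arrhenius fit")
    fits <- fits[!deg]
  }
  pts <- data.frame(
    temperature = vapply(fits, function(f) f@temperature, numeric(1)),
    k = vapply(fits, function(f) f@k, numeric(1)),
    source = source)
  fitArrhenius(pts)
}
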