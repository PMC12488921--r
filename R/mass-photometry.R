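#' Fit a contrast-to-mass calibration from standard proteins
#'
#' Single-particle scattering contrasts are proportional to particle mass;
#' the calibration line is fitted through the dominant contrast mode of each
#' standard protein of known mass (e.g. BSA 66 kDa, IgG 150 kDa,
#' thyroglobulin 669 kDa; a standard's dimer peak may be supplied as an
#' additional point). Peak location is a Gaussian fit to the contrast
#' histogram within +/-20 % of the expected position, which keeps dimer
#' satellites of the standards from biasing the peak.
#'
#' @param standards list of standards; each element is a list with `name`,
#'   `mass` (nominal mass, kDa) and `contrasts` (numeric vector of >= 50
#'   single-particle contrasts).
#' @param validMassMin lower limit of reliable mass quantification (kDa),
#'   reported with the curve; default 40.
#' @return a [CalibrationCurve-class].
#' @export
fitCalibration <- function(standards, validMassMin = 40) {
  masses <- vapply(standards, function(s) s$mass, numeric(1))
  if (length(unique(masses)) < 2)
    stop("calibration requires >= 2 standards with distinct masses")
  nev <- vapply(standards, function(s) length(s$contrasts), numeric(1))
  if (any(nev < 50))
    stop("each standard needs >= 50 events")

  slope0 <- stats::median(vapply(standards, function(s)
    stats::median(s$contrasts) / s$mass, numeric(1)))
  peaks <- vapply(standards, function(s)
    .locatePeak(s$contrasts, center = s$mass * slope0), numeric(1))

  ord <- order(masses)
  if (is.unsorted(peaks[ord], strictly = TRUE))
    stop("calibration error: peak contrasts are not monotone in mass")

  fit <- stats::lm(peaks ~ masses)
  names <- vapply(standards, function(s)
    if (is.null(s$name)) "" else s$name, character(1))
  methods::new("CalibrationCurve",
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               validMassMin = validMassMin,
               residualSd = sqrt(mean(stats::resid(fit)^2)),
               standards = data.frame(name = names, nominalMass = masses,
                                      peakContrast = peaks))
}

## Dominant-mode location: Gaussian fit to the histogram of values within
## +/-20% of the expected center; kernel-density mode as fallback/start.
.locatePeak <- function(x, center, window = 0.20) {
  xw <- x[x >= center * (1 - window) & x <= center * (1 + window)]
  if (length(xw) < 10) xw <- x
  d <- stats::density(xw)
  mode0 <- d$x[which.max(d$y)]
  h <- graphics::hist(xw, breaks = 30, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  fit <- tryCatch(
    stats::nls(y ~ A * exp(-(x - mu)^2 / (2 * sg^2)), data = df,
               start = list(A = max(df$y), mu = mode0,
                            sg = stats::sd(xw))),
    error = function(e) NULL)
  if (is.null(fit)) mode0 else unname(stats::coef(fit)["mu"])
}

#' Convert contrasts to masses with a calibration curve
#'
#' Inverts the calibration line, `mass = (contrast - intercept) / slope`.
#' Masses below the curve's reliable-quantification limit are flagged (via
#' the `"flagged"` attribute), never dropped: the sub-40 kDa regime is less
#' quantifiable but still informative (e.g. monomer-versus-dimer calls).
#'
#' @param contrasts numeric vector of single-particle contrasts.
#' @param calib a [CalibrationCurve-class].
#' @return numeric mass vector (kDa) with a logical attribute `"flagged"`
#'   marking entries below `validMassMin`.
#' @export
applyCalibration <- function(contrasts, calib) {
  if (calib@slope == 0) stop("calibration error: zero slope")
  mass <- (contrasts - calib@intercept) / calib@slope
  attr(mass, "flagged") <- mass < calib@validMassMin
  mass
}

#' Bin particle masses into a histogram
#'
#' Uniform bins anchored so that bin centers sit at integer multiples of the
#' bin width; with the default bin width equal to the monomer mass, each bin
#' center is an exact oligomer mass and the aggregation-number assignment
#' `N = round(mass / monomerMass)` is exact for noiseless data. Returns a
#' number-weighted histogram.
#'
#' @param masses particle masses (kDa).
#' @param monomerMass subunit mass (kDa), default 26.9.
#' @param binWidth bin width (kDa), default `monomerMass`.
#' @return a [MassHistogram-class] with `weighting = "number"`.
#' @export
#' @examples
#' h <- buildHistogram(c(269, 269, 538), monomerMass = 26.9)
#' binCounts(h)[binCenters(h) %in% c(269, 538)]
buildHistogram <- function(masses, monomerMass = 26.9,
                           binWidth = monomerMass) {
  if (binWidth <= 0) stop("binWidth must be > 0")
  if (length(masses) == 0) stop("cannot build a histogram from zero events")
  kLo <- floor(min(masses) / binWidth + 0.5) - 1L
  kHi <- ceiling(max(masses) / binWidth - 0.5) + 1L
  breaks <- (seq.int(kLo, kHi + 1L) - 0.5) * binWidth
  counts <- graphics::hist(masses, breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  methods::new("MassHistogram", breaks = breaks, counts = as.numeric(counts),
               weighting = "number", monomerMass = monomerMass,
               nEvents = length(masses))
}

#' Convert a number-weighted histogram to mass weighting
#'
#' Multiplies each bin count by its aggregation number
#' `N = round(binCenter / monomerMass)`, giving the mass-weighted
#' distribution that absorbance-based sedimentation data deliver natively.
#' Conversion conserves `sum(N * counts)` exactly and refuses to run twice.
#'
#' @param hist a number-weighted [MassHistogram-class].
#' @return a mass-weighted [MassHistogram-class].
#' @export
toMassWeighted <- function(hist) {
  if (weighting(hist) != "number")
    stop("histogram is already mass-weighted; refusing to weight twice")
  n <- round(binCenters(hist) / monomerMass(hist))
  methods::new("MassHistogram", breaks = hist@breaks,
               counts = hist@counts * n, weighting = "mass",
               monomerMass = hist@monomerMass, nEvents = hist@nEvents)
}

## Aggregation number of each bin of a histogram.
.binN <- function(hist) round(binCenters(hist) / monomerMass(hist))

#' Mean aggregation number of a mass histogram
#'
#' Mean of N over bins with `N >= nMin`, under the histogram's declared
#' weighting (the counts of a mass-weighted histogram already carry the
#' extra factor N). The default `nMin = 3` matches the oligomer (N > 2)
#' convention used for micelle statistics; the weighting is attached to the
#' result as an attribute so it is always reported together with the value.
#'
#' @param hist a [MassHistogram-class].
#' @param nMin smallest aggregation number included, default 3.
#' @return mean aggregation number, with attribute `"weighting"`.
#' @export
#' @examples
#' h <- buildHistogram(rep(c(269, 807), c(1, 1)), monomerMass = 26.9)
#' meanAggregationNumber(h, nMin = 3)                   # number-weighted 20
#' meanAggregationNumber(toMassWeighted(h), nMin = 3)   # mass-weighted 25
meanAggregationNumber <- function(hist, nMin = 3) {
  if (nMin < 1) stop("nMin must be >= 1")
  n <- .binN(hist)
  sel <- n >= nMin & binCounts(hist) > 0
  if (!any(sel))
    stop("undefined statistic: no occupied bins with N >= ", nMin)
  out <- sum(n[sel] * binCounts(hist)[sel]) / sum(binCounts(hist)[sel])
  attr(out, "weighting") <- weighting(hist)
  out
}

#' Total oligomer mass reporter
#'
#' Sum over bins with `N >= nMin` of count times bin mass, i.e. the total
#' mass of observed oligomers (N > 2 by default) during an acquisition.
#' Used as the dissociation-kinetics reporter for label-free data: the
#' reporter decays with the same single-exponential rate as the micelle
#' population.
#'
#' @param hist a number-weighted [MassHistogram-class].
#' @param nMin smallest aggregation number included, default 3.
#' @return summed oligomer mass (kDa).
#' @export
oligomerMassTotal <- function(hist, nMin = 3) {
  if (weighting(hist) != "number")
    stop("oligomerMassTotal expects a number-weighted histogram")
  n <- .binN(hist)
  sel <- n >= nMin
  sum(binCounts(hist)[sel] * binCenters(hist)[sel])
}

#' Gaussian peak width of a histogram region
#'
#' Fits a Gaussian to the bins inside `window` and reports the standard
#' deviation together with the full width at half maximum,
#' `FWHM = 2.355 * sigma` (the conventional rounding of
#' \eqn{2\sqrt{2\ln 2}}; the difference is < 0.02 %). Used e.g. to quantify
#' the mass uncertainty from the width of a monodisperse standard's peak.
#'
#' @param hist a [MassHistogram-class].
#' @param window numeric length-2 mass interval (kDa) containing the peak.
#' @return list with `sigma`, `fwhm`, `mu` (all kDa).
#' @export
gaussianPeakFwhm <- function(hist, window) {
  x <- binCenters(hist); y <- binCounts(hist)
  sel <- x >= window[1] & x <= window[2]
  if (sum(y[sel] > 0) < 5)
    stop("window must contain at least 5 occupied bins")
  x <- x[sel]; y <- y[sel]
  ## count modes on a lightly smoothed profile so bin noise near the peak
  ## does not register as extra maxima
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  loc <- which(diff(sign(diff(ys))) == -2) + 1L
  if (sum(ys[loc] > max(ys) / 2) > 1)
    warning("window looks non-unimodal; Gaussian fit may be poor")
  mu0 <- sum(x * y) / sum(y)
  sg0 <- sqrt(sum(y * (x - mu0)^2) / sum(y))
  fit <- stats::nls(y ~ A * exp(-(x - mu)^2 / (2 * sg^2)),
                    data = data.frame(x = x, y = y),
                    start = list(A = max(y), mu = mu0, sg = sg0))
  sg <- abs(unname(stats::coef(fit)["sg"]))
  list(sigma = sg, fwhm = micellabConstants$fwhm_factor * sg,
       mu = unname(stats::coef(fit)["mu"]))
}

#' Particle concentration from subunit concentration and mean N
#'
#' Dividing the total subunit concentration by the mean aggregation number
#' gives the number concentration of particles — the quantity that must
#' land in the ~10 nM range for single-particle counting after dilution.
#'
#' @param totalConc total concentration in monomer units (any unit).
#' @param meanN mean aggregation number, >= 1.
#' @return particle concentration, in the unit of `totalConc`.
#' @export
#' @examples
#' particleConcentration(200, 20)  # 10
particleConcentration <- function(totalConc, meanN) {
  if (any(meanN < 1)) stop("meanN must be >= 1")
  totalConc / meanN
}

#' Monomer-dimer equilibrium speciation
#'
#' Solves the association equilibrium \eqn{K_2 = c_2 / c_1^2} under mass
#' balance \eqn{c_1 + 2 c_2 = c_{total}} (positive root of the quadratic).
#' When the free monomer concentration is pinned (e.g. near the cmc), the
#' dimer concentration \eqn{K_2 c_1^2} is constant in total concentration —
#' the argument for why no dimer population appears above the cmc.
#'
#' @param cTotal total concentration (M), >= 0.
#' @param K2 association constant (1/M), >= 0.
#' @return named numeric c(c1, c2) in M.
#' @export
#' @examples
#' monomerDimer(2e-7, 1e6)
monomerDimer <- function(cTotal, K2) {
  if (cTotal < 0 || K2 < 0) stop("cTotal and K2 must be >= 0")
  if (K2 == 0) return(c(c1 = cTotal, c2 = 0))
  c1 <- (-1 + sqrt(1 + 8 * K2 * cTotal)) / (4 * K2)
  c2 <- K2 * c1^2
  if (cTotal > 0 && abs(c1 + 2 * c2 - cTotal) > 1e-12 * cTotal)
    stop("internal error: monomer-dimer mass balance violated")
  c(c1 = c1, c2 = c2)
}
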