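## CSV readers/writers for the package's tabular interchange formats.
## Columns carry their units in the header names; readers validate the
## schema and fail with the missing column named rather than guessing.

.requireCols <- function(df, cols, what) {
  names(df) <- tolower(names(df))
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("schema error in ", what, ": missing column(s) ",
         paste(miss, collapse = ", "))
  df
}

#' Read and write single-particle event tables
#'
#' Event CSV schema: `event_id, value, unit` where unit is `kDa` for
#' calibrated masses or `contrast` for raw contrasts (case-insensitive
#' headers). `readMPEvents` requires calibrated masses.
#'
#' @param events an [MPEventSet-class].
#' @param path CSV path.
#' @return `readMPEvents`: an [MPEventSet-class]; writers return the path
#'   invisibly.
#' @export
writeMPEvents <- function(events, path) {
  df <- data.frame(event_id = seq_along(events@measuredMass),
                   value = events@measuredMass, unit = "kDa")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMPEvents
#' @param monomerMass subunit mass (kDa) to attach, default 26.9.
#' @export
readMPEvents <- function(path, monomerMass = 26.9) {
  df <- .requireCols(utils::read.csv(path), c("event_id", "value", "unit"),
                     "event table")
  if (!all(tolower(df$unit) == "kda"))
    stop("unit error: event table must carry masses in kDa")
  methods::new("MPEventSet", measuredMass = df$value, trueN = NULL,
               seed = NA_integer_, duration = NA_real_,
               monomerMass = monomerMass)
}

#' Read and write mass histograms
#'
#' Histogram CSV schema: `bin_center_kda, count, weighting,
#' monomer_mass_kda`. The `weighting` column is part of the contract — a
#' histogram without a declared weighting is rejected.
#'
#' @param hist a [MassHistogram-class].
#' @param path CSV path.
#' @return `readMassHistogram`: a [MassHistogram-class].
#' @export
writeMassHistogram <- function(hist, path) {
  df <- data.frame(bin_center_kda = binCenters(hist),
                   count = binCounts(hist), weighting = weighting(hist),
                   monomer_mass_kda = monomerMass(hist))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMassHistogram
#' @export
readMassHistogram <- function(path) {
  df <- .requireCols(utils::read.csv(path),
                     c("bin_center_kda", "count", "weighting",
                       "monomer_mass_kda"), "histogram")
  centers <- df$bin_center_kda
  w <- if (length(centers) > 1) diff(centers[1:2]) else df$monomer_mass_kda[1]
  methods::new("MassHistogram",
               breaks = c(centers - w / 2, centers[length(centers)] + w / 2),
               counts = df$count, weighting = df$weighting[1],
               monomerMass = df$monomer_mass_kda[1],
               nEvents = NA_integer_)
}

#' Read and write sedimentation-coefficient distributions
#'
#' Sedimentation CSV schema: `s_svedberg, amplitude, temperature_k,
#' corrected`.
#'
#' @param dist a [SedimentationDistribution-class].
#' @param path CSV path.
#' @return `readSedDistribution`: a [SedimentationDistribution-class].
#' @export
writeSedDistribution <- function(dist, path) {
  utils::write.csv(
    data.frame(s_svedberg = sValues(dist), amplitude = amplitudes(dist),
               temperature_k = measurementTemperature(dist),
               corrected = isCorrectedTo20W(dist)),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSedDistribution
#' @export
readSedDistribution <- function(path) {
  df <- .requireCols(utils::read.csv(path),
                     c("s_svedberg", "amplitude", "temperature_k",
                       "corrected"), "sedimentation distribution")
  methods::new("SedimentationDistribution", sValues = df$s_svedberg,
               amplitudes = df$amplitude, temperature = df$temperature_k[1],
               correctedTo20W = as.logical(df$corrected[1]))
}

#' Read and write dissociation time series
#'
#' Series CSV schema: `time_s` (or `time_h`, converted to seconds on read),
#' `value, sd, temperature_c, replicate`. Multiple replicates/temperatures
#' may share one file; the reader splits them.
#'
#' @param seriesList list of [SizeTimeSeries-class].
#' @param path CSV path.
#' @return `readSizeSeries`: list of [SizeTimeSeries-class].
#' @export
writeSizeSeries <- function(seriesList, path) {
  rows <- do.call(rbind, lapply(seriesList, function(s)
    data.frame(time_s = s@times, value = s@values, sd = s@sd,
               temperature_c = s@temperature - 273.15,
               replicate = s@replicate, unit = s@unit)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSizeSeries
#' @export
readSizeSeries <- function(path) {
  df <- utils::read.csv(path)
  names(df) <- tolower(names(df))
  if ("time_h" %in% names(df) && !"time_s" %in% names(df))
    df$time_s <- df$time_h * 3600
  df <- .requireCols(df, c("time_s", "value", "sd", "temperature_c",
                           "replicate"), "size series")
  if (is.null(df$unit)) df$unit <- "nm"
  key <- interaction(df$temperature_c, df$replicate, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$time_s), ]
    methods::new("SizeTimeSeries", times = g$time_s, values = g$value,
                 sd = g$sd, temperature = g$temperature_c[1] + 273.15,
                 replicate = as.character(g$replicate[1]),
                 unit = as.character(g$unit[1]))
  })
}

#' Write a fused mass/s/R_H/density profile
#'
#' Fused-output CSV schema: `mass_kDa, s_svedberg, rh_nm, density_g_ml,
#' water_fraction, weight`.
#'
#' @param fused a [FusedDistribution-class].
#' @param path CSV path.
#' @export
writeFusedDistribution <- function(fused, path) {
  utils::write.csv(asDataFrame(fused), path, row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end analysis pipeline on synthetic data
#'
#' Executes the enabled stages in dependency order — simulate a population
#' and its measurements, build and weight the mass histogram, fuse it with
#' the (temperature-corrected) sedimentation distribution, run the
#' dissociation-kinetics chain, and evaluate the solution-chemistry
#' calculators — returning all artifacts plus a run log. One global seed is
#' expanded into per-stage substreams by stage name, so disabling one stage
#' does not shift the randomness of the others; identical config and seed
#' give identical numeric outputs.
#'
#' @param config nested list (or path to a JSON file with the same
#'   structure): `seed` (integer, required for stochastic stages); `stages`
#'   (character subset of simulate, histogram, fuse, kinetics, chem);
#'   optional blocks `population` (totalConc, pH, nEvents), `kinetics`
#'   (temperaturesC, replicates), `chem` (phosphate_mM, pH, saltIonic_mM);
#'   optional `outDir` to write CSV artifacts.
#' @return list with elements `artifacts` (named list) and `log`
#'   (data.frame of stage records with the per-stage seeds).
#' @export
#' @examples
#' res <- runPipeline(list(seed = 1, stages = c("simulate", "histogram"),
#'                         population = list(totalConc = 30, pH = "pH8",
#'                                           nEvents = 2000)))
#' res$log
runPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stages <- config$stages
  if (is.null(stages)) stages <- character()
  known <- c("simulate", "histogram", "fuse", "kinetics", "chem")
  if (length(bad <- setdiff(stages, known)))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stochastic <- intersect(stages, c("simulate", "kinetics"))
  if (length(stochastic) && is.null(config$seed))
    stop("a seed is required when stochastic stages are enabled")
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)

  art <- list()
  log <- data.frame(stage = character(), seed = integer(),
                    note = character())
  note <- function(stage, sd, msg)
    log <<- rbind(log, data.frame(stage = stage, seed = sd, note = msg))

  popCfg <- config$population
  totalConc <- if (is.null(popCfg$totalConc)) 30 else popCfg$totalConc
  pH <- if (is.null(popCfg$pH)) "pH8" else popCfg$pH
  nEvents <- if (is.null(popCfg$nEvents)) 1e4 else popCfg$nEvents

  if ("simulate" %in% stages) {
    sd1 <- stageSeed(seed, "simulate")
    art$population <- buildPopulation(populationParams(), totalConc, pH)
    art$events <- sampleMPEvents(art$population, nEvents, seed = sd1)
    art$sedDistribution <- forwardAUC(art$population)
    note("simulate", sd1, sprintf("%g events from %g uM %s", nEvents,
                                  totalConc, pH))
  }
  if ("histogram" %in% stages) {
    if (is.null(art$events))
      stop("orchestration error: 'histogram' needs the 'simulate' events")
    art$histogram <- buildHistogram(measuredMasses(art$events),
                                    monomerMass(art$events))
    art$massWeighted <- toMassWeighted(art$histogram)
    art$meanN <- meanAggregationNumber(art$massWeighted, nMin = 3)
    note("histogram", NA_integer_,
         sprintf("mass-weighted <N> = %.2f", art$meanN))
  }
  if ("fuse" %in% stages) {
    if (is.null(art$massWeighted) || is.null(art$sedDistribution))
      stop("orchestration error: 'fuse' needs 'histogram' and 'simulate'")
    sed20 <- correctS20W(art$sedDistribution)
    art$fused <- fuseDistributions(art$massWeighted, sed20)
    note("fuse", NA_integer_,
         sprintf("%d fused bins", length(art$fused@mass)))
  }
  if ("kinetics" %in% stages) {
    sd2 <- stageSeed(seed, "kinetics")
    kinCfg <- config$kinetics
    tempsC <- if (is.null(kinCfg$temperaturesC)) seq(22, 40, by = 3) else
      kinCfg$temperaturesC
    reps <- if (is.null(kinCfg$replicates)) 3 else kinCfg$replicates
    kp <- kineticParams()
    art$series <- simulateDissociation(kp, tempsC + 273.15,
                                       replicates = reps, seed = sd2)
    art$arrhenius <- arrheniusFromSeries(art$series)
    note("kinetics", sd2, sprintf("Ea = %.1f kJ/mol from %d series",
                                  art$arrhenius@ea, length(art$series)))
  }
  if ("chem" %in% stages) {
    chemCfg <- config$chem
    phos <- if (is.null(chemCfg$phosphate_mM)) 20 else chemCfg$phosphate_mM
    bufPH <- if (is.null(chemCfg$pH)) 8.0 else chemCfg$pH
    art$bufferSpecies <- phosphateSpeciation(phos, bufPH)
    art$ionicStrength <- ionicStrength(art$bufferSpecies)
    art$debyeLength <- debyeLength(
      if (is.null(chemCfg$saltIonic_mM)) art$ionicStrength else
        chemCfg$saltIonic_mM)
    note("chem", NA_integer_,
         sprintf("I = %.1f mM, Debye %.3f nm", art$ionicStrength,
                 art$debyeLength))
  }

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    o <- function(f) file.path(config$outDir, f)
    if (!is.null(art$events)) writeMPEvents(art$events, o("events.csv"))
    if (!is.null(art$massWeighted))
      writeMassHistogram(art$massWeighted, o("histogram_mass_weighted.csv"))
    if (!is.null(art$sedDistribution))
      writeSedDistribution(art$sedDistribution, o("sedimentation.csv"))
    if (!is.null(art$fused))
      writeFusedDistribution(art$fused, o("fused.csv"))
    if (!is.null(art$series)) writeSizeSeries(art$series, o("series.csv"))
    utils::write.csv(log, o("run_log.csv"), row.names = FALSE)
  }
  list(artifacts = art, log = log)
}
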