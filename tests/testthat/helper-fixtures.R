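# Fixtures are built in code; no stored data.

# A population containing a single N-mer species (plus optional monomer).
singleSpeciesPopulation <- function(N, monomerMass = 26.9, particleConc = 1,
                                    monomer = 0, waterFraction = 0.65) {
  new("MicellePopulation", nValues = as.integer(N),
      concentrations = particleConc, monomerConc = monomer,
      totalConc = monomer + N * particleConc, pH = "pH8",
      waterFraction = waterFraction, monomerMass = monomerMass)
}

# Exact (noise-free) mass-weighted histogram of a population: counts are
# N * C_N placed at the exact oligomer masses.
exactMassWeightedHistogram <- function(pop) {
  n <- aggregationNumbers(pop)
  cN <- numberConcentrations(pop)
  masses <- rep(n * monomerMass(pop), times = 1)
  h <- buildHistogram(rep(masses, pmax(round(cN / max(cN) * 1e4), 0)),
                      monomerMass(pop))
  toMassWeighted(h)
}

makeSeries <- function(times, values, sd = rep(0, length(times)),
                       temperature = 295.15, unit = "nm") {
  new("SizeTimeSeries", times = times, values = values, sd = sd,
      temperature = temperature, replicate = "1", unit = unit)
}

jb6SyntheticSequence <- function() {
  unname(readProteinSequence(
    system.file("extdata", "jb6b_synthetic.fasta", package = "micellab")))
}
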