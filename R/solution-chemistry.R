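#' Model-compound pKa set for protein charge calculations
#'
#' A standard published model-compound set (side chains D 3.5, E 4.2,
#' C 6.8, Y 10.3, H 6.6, K 10.5, R 12.0; N-terminus 8.0, C-terminus 3.3).
#' The set is a documented, swappable input — structure-based pKa shifts
#' are deliberately out of scope, so any complete set can be supplied.
#'
#' @param D,E,C,Y,H,K,R side-chain pKa values.
#' @param nTerm,cTerm terminal pKa values.
#' @param label provenance label carried with the set.
#' @return a named list of class `PKaSet`.
#' @export
#' @examples
#' pKaSet()
pKaSet <- function(D = 3.5, E = 4.2, C = 6.8, Y = 10.3, H = 6.6, K = 10.5,
                   R = 12.0, nTerm = 8.0, cTerm = 3.3,
                   label = "model-compound defaults") {
  vals <- c(D = D, E = E, C = C, Y = Y, H = H, K = K, R = R,
            nTerm = nTerm, cTerm = cTerm)
  if (any(vals <= 0 | vals >= 14)) stop("all pKa values must lie in (0, 14)")
  structure(as.list(vals), label = label, class = "PKaSet")
}

.aaCodes <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.residueCounts <- function(sequence) {
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(res), .aaCodes)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  table(factor(res, levels = .aaCodes))
}

#' Protein net charge at a given pH
#'
#' Henderson-Hasselbalch net charge with model pKa values:
#' \deqn{Z(pH) = \sum_{basic} \frac{1}{1 + 10^{pH - pK_a}}
#'             - \sum_{acidic} \frac{1}{1 + 10^{pK_a - pH}}}
#' with basic groups K, R, H and the N-terminus, and acidic groups D, E, C,
#' Y and the C-terminus.
#'
#' @param sequence amino-acid sequence (standard one-letter codes).
#' @param pH numeric pH value(s).
#' @param pkas a [pKaSet()].
#' @return net charge in elementary charges (vectorized over `pH`).
#' @export
#' @examples
#' netCharge("GG", 0)   # ~ +1: only the termini ionize
netCharge <- function(sequence, pH, pkas = pKaSet()) {
  counts <- .residueCounts(sequence)
  nBasic <- c(counts[["K"]], counts[["R"]], counts[["H"]], 1)
  pkBasic <- c(pkas$K, pkas$R, pkas$H, pkas$nTerm)
  nAcid <- c(counts[["D"]], counts[["E"]], counts[["C"]], counts[["Y"]], 1)
  pkAcid <- c(pkas$D, pkas$E, pkas$C, pkas$Y, pkas$cTerm)
  vapply(pH, function(p)
    sum(nBasic / (1 + 10^(p - pkBasic))) -
      sum(nAcid / (1 + 10^(pkAcid - p))), numeric(1))
}

#' Net-charge curve over a pH grid
#'
#' Vectorized [netCharge()]; the curve is strictly non-increasing in pH and
#' its zero crossing is the (model) isoelectric point.
#'
#' @inheritParams netCharge
#' @param pHGrid numeric grid within (0, 14).
#' @return data.frame with columns `pH`, `net_charge`.
#' @export
chargeCurve <- function(sequence, pHGrid = seq(1, 13, by = 0.1),
                        pkas = pKaSet()) {
  if (any(pHGrid <= 0 | pHGrid >= 14)) stop("pH grid must lie in (0, 14)")
  data.frame(pH = pHGrid, net_charge = netCharge(sequence, pHGrid, pkas))
}

#' Isoelectric point from the charge curve
#'
#' Bisection on the closed-form [netCharge()] curve.
#'
#' @inheritParams netCharge
#' @return pH at which the net charge crosses zero.
#' @export
isoelectricPoint <- function(sequence, pkas = pKaSet()) {
  f <- function(p) netCharge(sequence, p, pkas)
  if (f(0.01) < 0 || f(13.99) > 0)
    stop("charge curve does not cross zero in (0, 14)")
  stats::uniroot(f, c(0.01, 13.99), tol = 1e-9)$root
}

#' Phosphate-buffer speciation at a given pH
#'
#' Henderson-Hasselbalch speciation of total phosphate over
#' H3PO4 / H2PO4- / HPO4^2- / PO4^3- with the standard pKa triplet
#' (2.15, 7.21, 12.33); sodium is inferred by electroneutrality. Near pH 8
#' only pKa2 matters: it sets the H2PO4-/HPO4^2- ratio that dominates the
#' ionic strength of a sodium phosphate buffer.
#'
#' @param totalPhosphate total phosphate (mM), > 0.
#' @param pH in (0, 14).
#' @param pkaTriplet numeric length-3 phosphate pKa values.
#' @return data.frame with columns `name`, `charge`, `concentration_mM`
#'   (phosphate species plus Na+).
#' @export
#' @examples
#' phosphateSpeciation(20, 8.0)
phosphateSpeciation <- function(totalPhosphate, pH,
                                pkaTriplet = c(2.15, 7.21, 12.33)) {
  if (totalPhosphate <= 0) stop("totalPhosphate must be > 0")
  if (pH <= 0 || pH >= 14) stop("pH must lie in (0, 14)")
  h <- 10^(-pH)
  K1 <- 10^(-pkaTriplet[1]); K2 <- 10^(-pkaTriplet[2])
  K3 <- 10^(-pkaTriplet[3])
  denom <- h^3 + h^2 * K1 + h * K1 * K2 + K1 * K2 * K3
  frac <- c(h^3, h^2 * K1, h * K1 * K2, K1 * K2 * K3) / denom
  conc <- totalPhosphate * frac
  charge <- c(0L, -1L, -2L, -3L)
  na <- sum(abs(charge) * conc)
  data.frame(
    name = c("H3PO4", "H2PO4-", "HPO4 2-", "PO4 3-", "Na+"),
    charge = c(charge, 1L),
    concentration_mM = c(conc, na))
}

#' Ionic strength of an ion mixture
#'
#' \deqn{I = \frac{1}{2} \sum_i c_i z_i^2}
#' Warns when the mixture is not electroneutral (relative charge imbalance
#' above 1e-6), since a physical buffer must balance.
#'
#' @param species data.frame with columns `charge` and `concentration_mM`
#'   (e.g. from [phosphateSpeciation()]).
#' @return ionic strength in mM.
#' @export
#' @examples
#' ionicStrength(data.frame(charge = c(1, -1),
#'                          concentration_mM = c(150, 150)))  # 150
ionicStrength <- function(species) {
  net <- sum(species$charge * species$concentration_mM)
  scale <- sum(abs(species$charge) * species$concentration_mM)
  if (scale > 0 && abs(net) / scale > 1e-6)
    warning("species are not electroneutral (net ", signif(net, 3), " mM)")
  sum(species$concentration_mM * species$charge^2) / 2
}

#' Debye screening length
#'
#' \deqn{\kappa^{-1} = \sqrt{\frac{\varepsilon_r \varepsilon_0 k_B T}
#'   {2 N_A e^2 I}}}
#' computed from fundamental constants (I converted from mM to mol/m^3).
#' At 1 M 1:1 electrolyte and room temperature this is ~0.3 nm — shorter
#' than any protein dimension, so electrostatics are fully screened there.
#'
#' @param ionicStrengthmM ionic strength (mM), > 0.
#' @param temperature K, default 295.
#' @param epsR relative permittivity, default 78.5.
#' @return Debye length in nm.
#' @export
#' @examples
#' debyeLength(1000)  # ~0.30 nm
debyeLength <- function(ionicStrengthmM, temperature = 295, epsR = 78.5) {
  if (any(ionicStrengthmM <= 0)) stop("ionic strength must be > 0")
  cst <- micellabConstants
  iMolM3 <- ionicStrengthmM  # mM == mol/m^3
  sqrt(epsR * cst$eps0 * cst$kB * temperature /
         (2 * cst$avogadro * cst$e^2 * iMolM3)) * 1e9
}

#' Fit the refractive-index increment dn/dc
#'
#' Ordinary least squares of refractive index on mass concentration; the
#' slope (index units per mg/ml) times 1000 is dn/dc in ml/g. Similar
#' dn/dc between a standard and the analyte is what justifies mass-
#' proportional single-particle scattering signals.
#'
#' @param series data.frame with columns `conc_mg_ml` and `n` (>= 3
#'   concentrations spanning a nonzero range), e.g. from
#'   [simulateRefractometry()].
#' @param wavelength nm, default taken from the series if present.
#' @return a [DnDcFit-class].
#' @export
#' @examples
#' fitDnDc(simulateRefractometry(noiseSd = 0))
fitDnDc <- function(series, wavelength = NULL) {
  if (nrow(series) < 3) stop("at least 3 concentrations required")
  if (diff(range(series$conc_mg_ml)) <= 0)
    stop("rank-deficient design: concentrations span a zero range")
  if (is.null(wavelength))
    wavelength <- if (!is.null(series$wavelength_nm))
      series$wavelength_nm[1] else NA_real_
  fit <- stats::lm(n ~ conc_mg_ml, data = series)
  methods::new("DnDcFit", dndc = unname(stats::coef(fit)[2]) * 1000,
               n0 = unname(stats::coef(fit)[1]),
               rSquared = suppressWarnings(summary(fit)$r.squared),
               wavelength = wavelength)
}

#' Read a protein sequence from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning plain
#' character sequences for the charge calculators.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
readProteinSequence <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}
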