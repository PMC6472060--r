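#' Assign breeding-goal QTL to panel loci
#'
#' Samples `nPerChrom` QTL per chromosome uniformly from the panel's
#' segregating loci and draws their additive effects: i.i.d. standard
#' normal by default, or (gamma option) magnitudes from Gamma(shape, 1)
#' with a random sign, positive or negative with equal probability. The
#' effect scale is free because selection is rank-based truncation on true
#' breeding values.
#'
#' @param panel a [HaplotypePanel-class].
#' @param nPerChrom QTL per chromosome (full-scale default 1000, i.e.
#'   10,000 genome-wide).
#' @param effectDist `"normal"` or `"gamma"` (gamma shape 11 mirrors a
#'   pig-trait estimate).
#' @param gammaShape shape parameter for the gamma option.
#' @param exclude locus indices not eligible (e.g. already assigned).
#' @return list with `loci` (genome-wide indices, sorted) and `effects`.
#' @export
assignQTL <- function(panel, nPerChrom, effectDist = c("normal", "gamma"),
                      gammaShape = 11, exclude = integer()) {
  effectDist <- match.arg(effectDist)
  loci <- .samplePerChrom(panel@map, nPerChrom, eligible = setdiff(
    seq_len(nLoci(panel)), exclude))
  n <- length(loci)
  effects <- if (effectDist == "normal") rnorm(n)
             else rgamma(n, shape = gammaShape, scale = 1) *
                  sample(c(-1, 1), n, replace = TRUE)
  list(loci = loci, effects = effects)
}

## Sample nPerChrom eligible loci per chromosome, uniformly without
## replacement; errors report the per-chromosome shortfall.
.samplePerChrom <- function(map, nPerChrom, eligible) {
  byChrom <- split(eligible, map@locusChrom[eligible])
  counts <- vapply(as.character(seq_len(map@nChrom)),
                   function(c) length(byChrom[[c]]), 1L)
  if (any(counts < nPerChrom))
    stop(sprintf(
      "not enough eligible loci: need %d per chromosome, have [%s]",
      nPerChrom, paste(counts, collapse = ", ")))
  sort(unlist(lapply(seq_len(map@nChrom), function(c)
    sample(byChrom[[as.character(c)]], nPerChrom)), use.names = FALSE))
}

#' Assign fitness (deleterious) loci
#'
#' Samples `nPerChrom` fitness loci per chromosome from panel loci whose
#' founder derived-allele frequency is below `maxFounderFreq` (0.01 in
#' codominant setups, 0.1 in recessive setups), excluding the QTL. The
#' derived allele at each chosen locus is the deleterious allele.
#'
#' @param panel a [HaplotypePanel-class].
#' @param nPerChrom fitness loci per chromosome.
#' @param maxFounderFreq founder-frequency ceiling (exclusive).
#' @param exclude locus indices that may not be chosen (must include the
#'   QTL).
#' @return sorted genome-wide locus indices.
#' @export
assignFitnessLoci <- function(panel, nPerChrom, maxFounderFreq,
                              exclude = integer()) {
  eligible <- setdiff(which(panel@freqs < maxFounderFreq),
                      exclude)
  .samplePerChrom(panel@map, nPerChrom, eligible)
}

#' Draw selection coefficients from the three-class uniform mixture
#'
#' Each deleterious variant's selection coefficient is drawn from a mixture
#' of three uniform distributions with equal class probabilities: small
#' (0 < s < 1e-4), intermediate (1e-4 < s < 0.1) and large (0.1 < s < 1),
#' mirroring estimated distributions of deleterious effects in humans.
#'
#' @param n number of coefficients.
#' @return numeric vector of s values in (0, 1).
#' @export
drawSelectionCoefficients <- function(n) {
  stopifnot(n >= 1)
  class <- sample.int(3L, n, replace = TRUE)
  lo <- c(0, 1e-4, 0.1)[class]
  hi <- c(1e-4, 0.1, 1)[class]
  runif(n, lo, hi)
}

#' Build a trait architecture on a founder panel
#'
#' Convenience wrapper: assigns QTL and fitness loci (disjoint), draws QTL
#' effects and selection coefficients, and fixes the shared dominance
#' coefficient. Uses the current RNG stream.
#'
#' @param panel a [HaplotypePanel-class].
#' @param nQtlPerChrom,nFitnessPerChrom loci per chromosome per trait.
#' @param dominance shared h (0 recessive, 0.5 codominant).
#' @param maxFounderFreq founder-frequency ceiling for fitness loci.
#' @param effectDist,gammaShape passed to [assignQTL()].
#' @return a [TraitArchitecture-class].
#' @export
makeArchitecture <- function(panel, nQtlPerChrom, nFitnessPerChrom,
                             dominance, maxFounderFreq,
                             effectDist = "normal", gammaShape = 11) {
  qtl <- assignQTL(panel, nQtlPerChrom, effectDist, gammaShape)
  fit <- assignFitnessLoci(panel, nFitnessPerChrom, maxFounderFreq,
                           exclude = qtl$loci)
  new("TraitArchitecture",
      qtlLoci = qtl$loci, qtlEffects = qtl$effects,
      fitnessLoci = fit, selCoeffs = drawSelectionCoefficients(length(fit)),
      dominance = as.numeric(dominance))
}

#' Single-genotype fitness factor
#'
#' The contribution of one fitness locus to multiplicative fitness: 1 for
#' the homozygous wild type, \eqn{1 - hs} for the heterozygote and
#' \eqn{1 - s} for the mutant homozygote (s = 1 is a lethal allele).
#'
#' @param dosage derived-allele dosage, 0, 1 or 2 (vectorized).
#' @param s selection coefficient in [0, 1].
#' @param h dominance coefficient in [0, 1].
#' @return the fitness factor(s).
#' @examples
#' genotypeFitness(1, s = 0.4, h = 0.5)  # 0.8
#' genotypeFitness(2, s = 1, h = 0)      # lethal homozygote: 0
#' @export
genotypeFitness <- function(dosage, s, h) {
  if (any(!dosage %in% c(0, 1, 2)))
    stop("dosage must be 0, 1 or 2")
  stopifnot(all(s >= 0 & s <= 1), all(h >= 0 & h <= 1))
  ifelse(dosage == 0, 1, ifelse(dosage == 1, 1 - h * s, 1 - s))
}

#' Multiplicative individual fitness
#'
#' \eqn{w = \prod_i f(d_i, s_i, h)} over the fitness loci of the
#' architecture, with per-locus factors from [genotypeFitness()];
#' w lies in [0, 1].
#'
#' @param dosages dosage vector over the architecture's fitness loci, or a
#'   matrix (loci x individuals).
#' @param arch a [TraitArchitecture-class].
#' @return fitness value(s) in [0, 1].
#' @export
individualFitness <- function(dosages, arch) {
  if (is.matrix(dosages)) {
    stopifnot(nrow(dosages) == length(arch@fitnessLoci))
    apply(dosages, 2L, individualFitness, arch = arch)
  } else {
    stopifnot(length(dosages) == length(arch@fitnessLoci))
    prod(genotypeFitness(dosages, arch@selCoeffs, arch@dominance))
  }
}

#' True breeding value
#'
#' \eqn{\sum_i a_i d_i} over the architecture's QTL.
#'
#' @param dosages dosage vector over the QTL, or a matrix (loci x
#'   individuals).
#' @param arch a [TraitArchitecture-class].
#' @return breeding value(s).
#' @export
breedingValue <- function(dosages, arch) {
  if (is.matrix(dosages)) {
    stopifnot(nrow(dosages) == length(arch@qtlLoci))
    drop(crossprod(dosages, arch@qtlEffects))
  } else {
    stopifnot(length(dosages) == length(arch@qtlLoci))
    sum(arch@qtlEffects * dosages)
  }
}

#' Serialize / restore a trait architecture
#'
#' JSON round-trip of locus indices, QTL effects, selection coefficients
#' and the dominance coefficient, for replaying a run.
#'
#' @param arch a [TraitArchitecture-class].
#' @param path JSON file path.
#' @return `writeArchitecture` returns `path` invisibly; `readArchitecture`
#'   returns the restored [TraitArchitecture-class].
#' @export
writeArchitecture <- function(arch, path) {
  jsonlite::write_json(
    list(qtl_loci = arch@qtlLoci, qtl_effects = arch@qtlEffects,
         fitness_loci = arch@fitnessLoci, sel_coeffs = arch@selCoeffs,
         dominance = arch@dominance),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeArchitecture
#' @export
readArchitecture <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("TraitArchitecture",
      qtlLoci = as.integer(x$qtl_loci), qtlEffects = as.numeric(x$qtl_effects),
      fitnessLoci = as.integer(x$fitness_loci),
      selCoeffs = as.numeric(x$sel_coeffs),
      dominance = as.numeric(x$dominance))
}

setMethod("show", "TraitArchitecture", function(object) {
  cat("TraitArchitecture:", length(object@qtlLoci), "QTL,",
      length(object@fitnessLoci), "fitness loci, h =", object@dominance, "\n")
})
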