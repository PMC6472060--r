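## Population construction and the within-generation operations:
## viability selection, truncation selection of parents, dam-number rule,
## meiosis and recurrent deleterious mutation.

#' Assemble a founder population from a haplotype panel
#'
#' Pairs consecutive panel haplotypes into diploid individuals; if more
#' founders are requested than `nInd(panel)`, haplotype pairs are sampled
#' with replacement. Sex is assigned independently Bernoulli(1/2); fitness
#' and breeding values are computed from the architecture.
#'
#' @param panel a [HaplotypePanel-class].
#' @param arch a [TraitArchitecture-class].
#' @param nFounders number of diploid founders (default `nInd(panel)`).
#' @return a [Population-class] at generation 0, phase "founder".
#' @export
foundersToPopulation <- function(panel, arch, nFounders = nInd(panel)) {
  haps <- t(panel@alleles)  # loci x haplotypes
  nPairs <- ncol(haps) %/% 2L
  pick <- if (nFounders == nPairs) seq_len(nPairs)
          else sample.int(nPairs, nFounders, replace = TRUE)
  hapA <- haps[, 2L * pick - 1L, drop = FALSE]
  hapB <- haps[, 2L * pick, drop = FALSE]
  newPopulation(hapA, hapB, arch, map = panel@map,
                sire = rep(0L, nFounders), dam = rep(0L, nFounders),
                startId = 1L, generation = 0L, phase = "founder")
}

#' Build a population from haplotype matrices
#'
#' Low-level constructor: computes fitness and breeding values from the
#' architecture, draws sexes Bernoulli(1/2), and assigns sequential ids.
#'
#' @param hapA,hapB loci x individuals 0/1 integer matrices.
#' @param arch a [TraitArchitecture-class].
#' @param map the [GenomeMap-class].
#' @param sire,dam parent ids (0 = unknown).
#' @param startId first individual id.
#' @param generation,phase cohort labels.
#' @param sex optional sex vector ("M"/"F"); drawn at random if NULL.
#' @return a [Population-class].
#' @export
newPopulation <- function(hapA, hapB, arch, map, sire, dam, startId,
                          generation, phase, sex = NULL) {
  storage.mode(hapA) <- "integer"
  storage.mode(hapB) <- "integer"
  n <- ncol(hapA)
  if (is.null(sex)) sex <- c("F", "M")[rbinom(n, 1L, 0.5) + 1L]
  new("Population",
      hapA = hapA, hapB = hapB,
      id = seq.int(startId, length.out = n),
      sire = as.integer(sire), dam = as.integer(dam),
      sex = sex,
      bv = cpp_breeding_value(hapA, hapB, arch@qtlLoci - 1L, arch@qtlEffects),
      w = cpp_fitness(hapA, hapB, arch@fitnessLoci - 1L, arch@selCoeffs,
                      arch@dominance),
      generation = as.integer(generation), phase = phase, map = map)
}

#' @rdname nInd
#' @export
setMethod("nInd", "Population", function(x) ncol(x@hapA))

#' @rdname nLoci
#' @export
setMethod("nLoci", "Population", function(x) nrow(x@hapA))

#' @rdname alleleFreqs
#' @export
setMethod("alleleFreqs", "Population", function(x, loci = NULL) {
  cnt <- cpp_allele_counts(x@hapA, x@hapB)
  f <- cnt / (2 * nInd(x))
  if (is.null(loci)) f else f[loci]
})

#' @rdname meanFitness
#' @export
setMethod("meanFitness", "Population", function(x) {
  if (nInd(x) == 0L) stop("empty cohort")
  mean(x@w)
})

#' @rdname meanBV
#' @export
setMethod("meanBV", "Population", function(x) {
  if (nInd(x) == 0L) stop("empty cohort")
  mean(x@bv)
})

setMethod("show", "Population", function(object) {
  cat(sprintf(
    "Population: %d individuals (%d M / %d F), generation %d [%s]\n",
    nInd(object), sum(object@sex == "M"), sum(object@sex == "F"),
    object@generation, object@phase))
  if (nInd(object))
    cat(sprintf("  mean w = %.4f, mean bv = %.3f\n",
                mean(object@w), mean(object@bv)))
})

#' Subset a population
#'
#' @param x a [Population-class].
#' @param i individual (column) indices or a logical vector.
#' @param j,drop,... unused.
#' @return the subset [Population-class].
#' @export
setMethod("[", "Population", function(x, i, j, ..., drop = FALSE) {
  initialize(x,
             hapA = x@hapA[, i, drop = FALSE],
             hapB = x@hapB[, i, drop = FALSE],
             id = x@id[i], sire = x@sire[i], dam = x@dam[i],
             sex = x@sex[i], bv = x@bv[i], w = x@w[i])
})

#' Allele dosage at a set of loci
#'
#' @param pop a [Population-class].
#' @param loci genome-wide locus indices (1-based).
#' @return integer matrix, loci x individuals, entries 0/1/2.
#' @export
dosageAt <- function(pop, loci) {
  cpp_dosage(pop@hapA, pop@hapB, as.integer(loci) - 1L)
}

#' Export a population snapshot as plain text
#'
#' Writes the cohort's haplotypes as the TSV matrix interchange format
#' (two consecutive rows per individual) and the per-individual table
#' (id, sire, dam, sex, bv, w) as CSV.
#'
#' @param pop a [Population-class].
#' @param prefix output path prefix; writes `<prefix>_haplotypes.tsv` and
#'   `<prefix>_individuals.csv`.
#' @return the two file paths, invisibly.
#' @export
exportPopulation <- function(pop, prefix) {
  n <- nInd(pop)
  haps <- matrix(0L, nrow = 2L * n, ncol = nLoci(pop))
  haps[seq(1L, 2L * n, by = 2L), ] <- t(pop@hapA)
  haps[seq(2L, 2L * n, by = 2L), ] <- t(pop@hapB)
  colnames(haps) <- locusIds(pop@map)
  fHap <- paste0(prefix, "_haplotypes.tsv")
  fInd <- paste0(prefix, "_individuals.csv")
  data.table::fwrite(data.table::as.data.table(haps), fHap, sep = "\t")
  data.table::fwrite(data.frame(id = pop@id, sire = pop@sire,
                                dam = pop@dam, sex = pop@sex,
                                bv = pop@bv, w = pop@w,
                                generation = pop@generation,
                                phase = pop@phase),
                     fInd)
  invisible(c(haplotypes = fHap, individuals = fInd))
}

#' Natural (viability) selection
#'
#' Each individual survives independently with probability equal to its
#' fitness w: a uniform random number is drawn and the individual is
#' removed if it exceeds w. An empty survivor set is legal.
#'
#' @param pop a [Population-class] with fitness computed.
#' @return the surviving [Population-class].
#' @export
viabilitySelect <- function(pop) {
  pop[runif(nInd(pop)) <= pop@w]
}

#' Truncation selection of sires and dams
#'
#' Selects the `nSires` males and `nDams` females with the highest true
#' breeding values among survivors; ties are broken by ascending id
#' (stable).
#'
#' @param survivors a [Population-class] (post-viability).
#' @param nSires,nDams numbers to select.
#' @return list with Populations `sires` and `dams`.
#' @export
selectParents <- function(survivors, nSires, nDams) {
  males <- which(survivors@sex == "M")
  females <- which(survivors@sex == "F")
  if (length(males) < nSires || length(females) < nDams)
    stop(sprintf(
      "parent shortfall: need %d sires / %d dams, have %d males / %d females",
      nSires, nDams, length(males), length(females)))
  sires <- males[order(-survivors@bv[males], survivors@id[males])][seq_len(nSires)]
  dams <- females[order(-survivors@bv[females], survivors@id[females])][seq_len(nDams)]
  list(sires = survivors[sires], dams = survivors[dams])
}

#' Number of dams needed to reach the target population
#'
#' \eqn{\lceil targetPop / (progenyPerDam \cdot \bar w_{ref}) \rceil},
#' where \eqn{\bar w_{ref}} is the mean fitness frozen per replicate at the
#' start of historical breeding, so that the post-viability cohort reaches
#' the target size at that level of deleterious load.
#'
#' @param meanFitnessRef frozen reference mean fitness, in (0, 1].
#' @param targetPop target cohort size (5000 at full scale).
#' @param progenyPerDam litter size (10).
#' @return integer dam count.
#' @examples
#' computeNDams(0.8, 5000, 10)  # 625
#' @export
computeNDams <- function(meanFitnessRef, targetPop, progenyPerDam) {
  if (meanFitnessRef <= 0) stop("reference mean fitness must be > 0")
  as.integer(ceiling(targetPop / (progenyPerDam * meanFitnessRef)))
}

#' Gamete formation by meiosis
#'
#' For each requested gamete, per chromosome the crossover count is
#' Poisson(map length in Morgans), breakpoints are uniform (no
#' interference), the starting haplotype is chosen with probability 1/2,
#' and alleles are copied segment-wise from the active haplotype.
#'
#' @param pop parent [Population-class].
#' @param parents individual (column) indices of the parent of each gamete.
#' @return loci x gametes integer matrix.
#' @export
makeGametes <- function(pop, parents) {
  idx <- .chromIndex(pop@map)
  cpp_make_gametes(pop@hapA, pop@hapB, as.integer(parents),
                   idx$start, idx$end, pop@map@locusPos,
                   pop@map@chromLengthMorgans)
}

#' Recurrent deleterious mutation
#'
#' Applies mutation to new diploid genotypes: per individual and fitness
#' locus, with probability `rate` one uniformly chosen wild-type allele
#' copy at the locus (if any) flips 0 -> 1. Mutant alleles never revert and
#' QTL never mutate, so at the full-scale defaults (10,000 fitness loci,
#' rate 1e-4) each individual receives one expected de-novo deleterious
#' mutation. The per-cell Bernoulli trials are realised as a binomial event
#' count placed uniformly over (individual, locus) cells, an exactly
#' equivalent scheme.
#'
#' @param hapA,hapB loci x individuals matrices (modified copies returned).
#' @param fitnessLoci genome-wide indices of the mutable loci.
#' @param rate per-locus per-individual mutation rate.
#' @return list with `hapA`, `hapB` and `nMutations` (de-novo mutations
#'   actually placed; events hitting mutant homozygotes do not mutate).
#' @export
mutateGenotypes <- function(hapA, hapB, fitnessLoci, rate) {
  n <- ncol(hapA)
  nf <- length(fitnessLoci)
  if (rate <= 0 || nf == 0L || n == 0L)
    return(list(hapA = hapA, hapB = hapB, nMutations = 0L))
  nev <- rbinom(1L, n * nf, rate)
  if (nev == 0L)
    return(list(hapA = hapA, hapB = hapB, nMutations = 0L))
  cells <- sample.int(n * nf, nev)
  locus <- fitnessLoci[(cells - 1L) %% nf + 1L]
  ind <- (cells - 1L) %/% nf + 1L
  lin <- (ind - 1L) * nrow(hapA) + locus
  a <- hapA[lin]; b <- hapB[lin]
  bothWild <- a == 0L & b == 0L
  toA <- (bothWild & runif(nev) < 0.5) | (a == 0L & b == 1L)
  toB <- (bothWild & !toA) | (a == 1L & b == 0L)
  hapA[lin[toA]] <- 1L
  hapB[lin[toB]] <- 1L
  list(hapA = hapA, hapB = hapB, nMutations = sum(toA) + sum(toB))
}
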