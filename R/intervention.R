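## Deleterious-variant discovery with false positives, the five RAGE
## prioritization strategies, per-sire editing with editing mortality, and
## the three carrier-selection strategies.

#' Construct an edit policy
#'
#' @param strategy one of `"high_freq"`, `"low_freq"`,
#'   `"homozygote_deficit"`, `"intermediate_freq"`, `"random"`.
#' @param editsPerSire maximum edits per sire k (paper grid: 1, 5, 20).
#' @param freqThreshold exclusion threshold of the intermediate-frequency
#'   strategy (default 0.25).
#' @param mortality editing mortality m in [0, 1] (default 0, the main
#'   scenarios; paper also tests 0.1, 0.25, 0.5).
#' @param freqSource `"cohort"` (default) or `"sires"`: the population on
#'   which prioritization frequencies are computed (recomputed each future
#'   generation).
#' @return an [EditPolicy-class].
#' @export
editPolicy <- function(strategy, editsPerSire = 5L, freqThreshold = 0.25,
                       mortality = 0, freqSource = "cohort") {
  new("EditPolicy", strategy = strategy,
      editsPerSire = as.integer(editsPerSire),
      freqThreshold = freqThreshold, mortality = mortality,
      freqSource = freqSource)
}

#' Construct a carrier-selection policy
#'
#' @param mode load score used for ranking: `"total"`, `"het"` or `"hom"`.
#' @param nAvoid number of highest-load males avoided before sire
#'   selection (paper grid: 100, 250, 500).
#' @return a [CarrierPolicy-class].
#' @export
carrierPolicy <- function(mode = "total", nAvoid = 100L) {
  new("CarrierPolicy", mode = mode, nAvoid = as.integer(nAvoid))
}

#' Build the discovery panel of deleterious variants
#'
#' With discovery rate d and S segregating deleterious variants at the end
#' of historical breeding, the panel holds `round(d * S)` true deleterious
#' loci sampled uniformly and `S - round(d * S)` false positives sampled
#' uniformly from the neutral segregating loci, so its size equals S
#' (rounding is half-up, documented). The panel, and the seeded permutation
#' used by the random prioritization strategy, are frozen for all future
#' generations of the replicate.
#'
#' @param segregatingDeleterious locus indices of fitness loci segregating
#'   at panel construction.
#' @param neutralSegregating locus indices of segregating neutral
#'   (non-trait) loci, the false-positive pool.
#' @param d discovery rate in (0, 1].
#' @return a [DiscoveryPanel-class].
#' @export
buildDiscoveryPanel <- function(segregatingDeleterious, neutralSegregating,
                                d) {
  stopifnot(d > 0, d <= 1)
  S <- length(segregatingDeleterious)
  nTrue <- as.integer(floor(d * S + 0.5))  # round half up
  nFalse <- S - nTrue
  if (length(neutralSegregating) < nFalse)
    stop(sprintf(
      "false-positive quota (%d) exceeds the neutral segregating pool (%d)",
      nFalse, length(neutralSegregating)))
  trueLoci <- sort(sample(segregatingDeleterious, nTrue))
  falseLoci <- sort(sample(neutralSegregating, nFalse))
  loci <- c(trueLoci, falseLoci)
  new("DiscoveryPanel",
      loci = as.integer(loci),
      isTrue = rep(c(TRUE, FALSE), c(nTrue, nFalse)),
      discoveryRate = d,
      randomOrder = as.integer(sample(loci)))
}

setMethod("show", "DiscoveryPanel", function(object) {
  cat(sprintf(
    "DiscoveryPanel: %d loci (%d true deleterious, %d false positives), d = %g\n",
    length(object@loci), sum(object@isTrue), sum(!object@isTrue),
    object@discoveryRate))
})

#' Order panel variants for editing
#'
#' Restricts the discovery panel to variants segregating in the reference
#' cohort (only segregating variants are edited) and orders them according
#' to the policy's strategy:
#' \describe{
#'   \item{high_freq}{decreasing deleterious-allele frequency.}
#'   \item{low_freq}{increasing deleterious-allele frequency.}
#'   \item{homozygote_deficit}{decreasing expected-minus-observed count of
#'     derived homozygotes, expected = p^2 N over the reference cohort.}
#'   \item{intermediate_freq}{decreasing frequency after excluding variants
#'     with frequency above the threshold (0.25).}
#'   \item{random}{the panel's fixed per-replicate permutation.}
#' }
#' Frequency ties are broken by ascending locus index.
#'
#' @param panel a [DiscoveryPanel-class].
#' @param cohort the reference [Population-class] on which frequencies and
#'   homozygote counts are computed (post-viability candidates by default;
#'   see [editPolicy()]).
#' @param policy an [EditPolicy-class].
#' @return ordered vector of genome-wide locus indices.
#' @export
prioritize <- function(panel, cohort, policy) {
  D <- dosageAt(cohort, panel@loci)
  n <- nInd(cohort)
  freq <- .rowSums(D, nrow(D), ncol(D)) / (2 * n)
  seg <- freq > 0 & freq < 1
  loci <- panel@loci[seg]
  freq <- freq[seg]
  switch(policy@strategy,
    high_freq = loci[order(-freq, loci)],
    low_freq = loci[order(freq, loci)],
    homozygote_deficit = {
      obsHom <- .rowSums(D[seg, , drop = FALSE] == 2L, sum(seg), ncol(D))
      score <- freq^2 * n - obsHom
      loci[order(-score, loci)]
    },
    intermediate_freq = {
      keep <- freq <= policy@freqThreshold
      loci[keep][order(-freq[keep], loci[keep])]
    },
    random = panel@randomOrder[panel@randomOrder %in% loci]
  )
}

#' Edit sires to homozygous wild type at prioritized variants
#'
#' Walks the ordered variant list for each sire; at every locus where the
#' sire carries at least one derived allele, both alleles are set to wild
#' type (editing is error-free and germline, so edits are transmitted
#' through meiosis), counting one edit, until `k` edits have been made or
#' the list is exhausted. Fitness is recomputed after editing; breeding
#' values are untouched (QTL are never edited).
#'
#' @param sires a [Population-class] of selected sires.
#' @param orderedLoci prioritized locus vector from [prioritize()].
#' @param k maximum edits per sire.
#' @param arch the [TraitArchitecture-class] (for refreshing fitness and
#'   logging s).
#' @param panel the [DiscoveryPanel-class] (for logging the false-positive
#'   status).
#' @return list with `sires` (edited Population) and `log` (data.frame
#'   with sireId, locus, isTrue, s, preDosage).
#' @export
editSires <- function(sires, orderedLoci, k, arch, panel) {
  log <- list()
  if (k > 0L && length(orderedLoci)) {
    D <- dosageAt(sires, orderedLoci)
    sMap <- setNames(arch@selCoeffs, arch@fitnessLoci)
    isTrueMap <- setNames(panel@isTrue, panel@loci)
    for (j in seq_len(nInd(sires))) {
      carrier <- which(D[, j] > 0L)
      hit <- head(carrier, k)
      if (length(hit)) {
        loci <- orderedLoci[hit]
        log[[length(log) + 1L]] <- data.frame(
          sireId = sires@id[j], locus = loci,
          isTrue = unname(isTrueMap[as.character(loci)]),
          s = unname(sMap[as.character(loci)]),
          preDosage = D[hit, j])
        sires@hapA[loci, j] <- 0L
        sires@hapB[loci, j] <- 0L
      }
    }
  }
  sires@w <- cpp_fitness(sires@hapA, sires@hapB, arch@fitnessLoci - 1L,
                         arch@selCoeffs, arch@dominance)
  log <- if (length(log)) do.call(rbind, log)
         else data.frame(sireId = integer(), locus = integer(),
                         isTrue = logical(), s = numeric(),
                         preDosage = integer())
  list(sires = sires, log = log)
}

#' Apply editing mortality and replace dead sires
#'
#' Each sire that went through the editing procedure dies independently
#' with probability m and is replaced, in breeding-value rank order, by an
#' unedited lower-ranked candidate from the replacement pool (ties by
#' ascending id). The mortality parameter folds in both direct losses and
#' failed edits leading to culling; replacements are never edited.
#'
#' @param editedSires edited [Population-class] of sires.
#' @param replacementPool [Population-class] of unedited male candidates
#'   (disjoint from the sires).
#' @param m mortality rate in [0, 1].
#' @return list with `sires` (final Population) and `nReplaced`.
#' @export
applyEditingMortality <- function(editedSires, replacementPool, m) {
  n <- nInd(editedSires)
  dead <- runif(n) < m
  nDead <- sum(dead)
  if (nDead == 0L) return(list(sires = editedSires, nReplaced = 0L))
  if (nInd(replacementPool) < nDead)
    stop(sprintf(
      "replacement pool exhausted: %d dead sires, %d candidates (short %d)",
      nDead, nInd(replacementPool), nDead - nInd(replacementPool)))
  rank <- order(-replacementPool@bv, replacementPool@id)
  repl <- replacementPool[rank[seq_len(nDead)]]
  surv <- editedSires[!dead]
  list(sires = .bindPopulations(surv, repl), nReplaced = nDead)
}

## Concatenate two cohorts sharing a map (used for sire replacement).
.bindPopulations <- function(a, b) {
  initialize(a,
             hapA = cbind(a@hapA, b@hapA), hapB = cbind(a@hapB, b@hapB),
             id = c(a@id, b@id), sire = c(a@sire, b@sire),
             dam = c(a@dam, b@dam), sex = c(a@sex, b@sex),
             bv = c(a@bv, b@bv), w = c(a@w, b@w))
}

#' Deleterious load of individuals over the discovery panel
#'
#' Counts deleterious (derived) alleles over the panel loci: `total` is the
#' dosage sum, `het` counts alleles carried heterozygous (one per het
#' locus), `hom` counts alleles carried homozygous (two per derived
#' homozygous locus); total = het + hom always.
#'
#' @param pop a [Population-class].
#' @param panel a [DiscoveryPanel-class] (or any locus index vector via
#'   `loci`).
#' @param mode `"total"`, `"het"` or `"hom"`.
#' @param loci optional explicit locus indices overriding the panel.
#' @return integer load per individual.
#' @export
carrierLoad <- function(pop, panel, mode = c("total", "het", "hom"),
                        loci = NULL) {
  mode <- match.arg(mode)
  if (is.null(loci)) loci <- panel@loci
  D <- dosageAt(pop, loci)
  switch(mode,
    total = .colSums(D, nrow(D), ncol(D)),
    het = .colSums(D == 1L, nrow(D), ncol(D)),
    hom = 2L * .colSums(D == 2L, nrow(D), ncol(D)))
}

#' Remove the highest-load males before sire selection
#'
#' Removes exactly `nAvoid` males with the highest load under the policy's
#' mode; among equal loads at the cutoff, higher-id males are removed
#' first. Applies to male selection candidates only.
#'
#' @param males a [Population-class] of male candidates.
#' @param panel the [DiscoveryPanel-class] defining the load.
#' @param policy a [CarrierPolicy-class].
#' @return the filtered [Population-class].
#' @export
avoidCarriers <- function(males, panel, policy) {
  if (policy@nAvoid == 0L) return(males)
  if (policy@nAvoid >= nInd(males))
    stop(sprintf("cannot avoid %d carriers among %d males",
                 policy@nAvoid, nInd(males)))
  load <- carrierLoad(males, panel, policy@mode)
  drop <- order(-load, -males@id)[seq_len(policy@nAvoid)]
  males[-drop]
}
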