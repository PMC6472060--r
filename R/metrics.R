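## Evaluation metrics: load decomposition, fitness change versus baseline,
## relative change in genetic gain, distinct edited variants.

#' Deleterious load summary of a cohort
#'
#' Means over individuals of the three load components at the TRUE
#' deleterious loci (all fitness loci of the architecture, not the
#' discovery panel), plus the number of those loci still segregating
#' (0 < frequency < 1). Total load is the number of deleterious alleles
#' carried; het counts alleles carried heterozygous, hom counts alleles
#' carried homozygous (two per derived homozygote); total = het + hom.
#'
#' @param pop a non-empty [Population-class].
#' @param deleteriousLoci genome-wide indices of the fitness loci.
#' @return list with `total`, `het`, `hom` (mean loads) and `segregating`
#'   (count).
#' @export
loadSummary <- function(pop, deleteriousLoci) {
  if (nInd(pop) == 0L) stop("empty cohort")
  D <- dosageAt(pop, deleteriousLoci)
  n <- ncol(D)
  tot <- .colSums(D, nrow(D), n)
  het <- .colSums(D == 1L, nrow(D), n)
  cnt <- .rowSums(D, nrow(D), n)
  list(total = mean(tot), het = mean(het), hom = mean(tot - het),
       segregating = sum(cnt > 0 & cnt < 2 * n))
}

## Change in a records column from the first to the last future
## generation of one replicate result.
.futureDelta <- function(result, column) {
  fut <- result@records[result@records$phase == "future", ]
  if (!nrow(fut)) stop("result has no future-breeding records")
  fut[[column]][nrow(fut)] - fut[[column]][1L]
}

## Check that scenario and baseline replicate lists are seed-paired.
.checkPaired <- function(results, baselineResults) {
  if (length(results) != length(baselineResults))
    stop("scenario and baseline have different replicate counts")
  s1 <- vapply(results, function(r) r@seed, 1L)
  s2 <- vapply(baselineResults, function(r) r@seed, 1L)
  if (!identical(s1, s2))
    stop("scenario and baseline replicates are not seed-paired")
}

#' Fitness change relative to the baseline scenario
#'
#' For each seed-paired replicate, the change in mean fitness from the
#' first to the tenth generation of future breeding in the scenario minus
#' the same change in the baseline; reported as the mean over replicates
#' with its standard error.
#'
#' @param results list of [SimulationResult-class], one per replicate.
#' @param baselineResults the seed-paired baseline results.
#' @return list with `mean`, `sem`, and the per-replicate `deltas`.
#' @export
fitnessChangeVsBaseline <- function(results, baselineResults) {
  .checkPaired(results, baselineResults)
  d <- vapply(results, .futureDelta, 1, column = "meanFitness") -
       vapply(baselineResults, .futureDelta, 1, column = "meanFitness")
  list(mean = mean(d),
       sem = if (length(d) > 1L) stats::sd(d) / sqrt(length(d)) else 0,
       deltas = d)
}

#' Relative change in genetic gain of the breeding goal
#'
#' With G the change in mean breeding value from the first to the tenth
#' future generation, computes (G_scenario - G_baseline) / G_baseline per
#' seed-paired replicate — the change in gain expressed as a fraction of
#' the gain without editing or carrier selection — and reports the mean
#' and standard error over replicates.
#'
#' @inheritParams fitnessChangeVsBaseline
#' @return list with `mean`, `sem` and per-replicate `ratios`.
#' @export
relativeGainChange <- function(results, baselineResults) {
  .checkPaired(results, baselineResults)
  gS <- vapply(results, .futureDelta, 1, column = "meanBV")
  gB <- vapply(baselineResults, .futureDelta, 1, column = "meanBV")
  if (any(gB == 0)) stop("baseline gain is zero in at least one replicate")
  r <- (gS - gB) / gB
  list(mean = mean(r),
       sem = if (length(r) > 1L) stats::sd(r) / sqrt(length(r)) else 0,
       ratios = r)
}

#' Number of distinct variants edited
#'
#' Size of the union of edited locus ids over all sires and all future
#' generations of one replicate (Table-1 metric).
#'
#' @param result a [SimulationResult-class].
#' @return integer count (0 when nothing was edited).
#' @export
countDistinctEdits <- function(result) length(result@distinctEdited)
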