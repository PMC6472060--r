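## The generation cycle through the three phases (burn-in under natural
## selection with random mating; historical breeding with truncation
## selection; future breeding with an optional intervention), and the
## single-replicate runner with its historical snapshot.

## Expected fraction of segregating loci with derived frequency below
## `maxFreq` in a panel of nHap haplotypes, under the neutral site
## frequency spectrum P(i copies) proportional to 1/i.
.lowFreqFraction <- function(nHap, maxFreq) {
  cmax <- max(1L, ceiling(maxFreq * nHap) - 1L)
  sum(1 / seq_len(cmax)) / sum(1 / seq_len(nHap - 1L))
}

## Derive a child seed (< 2^31) from a replicate seed and a stage tag.
.deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647 + 1)
}

## Produce the offspring cohort from paired parents. sireCols[i] and
## damCols[i] name the parent columns of mating i; each mating contributes
## `progeny` offspring. Parent populations may be the same object.
.reproduce <- function(sires, dams, sireCols, damCols, progeny, arch, plan,
                       phase, generation, startId) {
  damIdx <- rep(damCols, each = progeny)
  sireIdx <- rep(sireCols, each = progeny)
  gamDam <- makeGametes(dams, damIdx)
  gamSire <- makeGametes(sires, sireIdx)
  if (phase %in% plan@mutationPhases) {
    mut <- mutateGenotypes(gamDam, gamSire, arch@fitnessLoci,
                           plan@mutationRate)
    gamDam <- mut$hapA
    gamSire <- mut$hapB
  }
  newPopulation(gamDam, gamSire, arch, map = dams@map,
                sire = sires@id[sireIdx], dam = dams@id[damIdx],
                startId = startId, generation = generation, phase = phase)
}

#' Advance the population by one generation
#'
#' Applies the per-generation event order: (1) viability selection on the
#' incoming cohort; (2) in future carrier scenarios, removal of high-load
#' males; (3) truncation selection of sires and dams (burn-in generations
#' instead pair parents uniformly at random); (4) in future RAGE scenarios,
#' genome editing of the selected sires followed by editing mortality and
#' replacement; (5) random sire-dam pairing with `progenyPerDam` offspring
#' per dam (burn-in: `progenyPerMating` per random mating); (6) meiosis,
#' recurrent deleterious mutation and random sex assignment for the
#' offspring.
#'
#' @param cohort the incoming (pre-viability) [Population-class].
#' @param plan a [PhasePlan-class].
#' @param arch a [TraitArchitecture-class].
#' @param phase `"burn_in"`, `"historical"` or `"future"`.
#' @param nMatings number of random matings (burn-in only).
#' @param nDams number of dams to select (historical/future; from
#'   [computeNDams()]).
#' @param hooks optional intervention hooks for future generations: a list
#'   with `panel` ([DiscoveryPanel-class]) and either `editPolicy` or
#'   `carrierPolicy`.
#' @param startId first id for the offspring cohort.
#' @return list with `survivors` (post-viability cohort, the population on
#'   which metrics are recorded), `offspring` (next cohort), `editLog`
#'   (data.frame, possibly empty) and `nReplaced`.
#' @export
advanceGeneration <- function(cohort, plan, arch, phase, nMatings = NULL,
                              nDams = NULL, hooks = NULL,
                              startId = max(cohort@id) + 1L) {
  survivors <- viabilitySelect(cohort)
  editLog <- NULL
  nReplaced <- 0L
  gen <- cohort@generation + 1L

  if (phase == "burn_in") {
    males <- which(survivors@sex == "M")
    females <- which(survivors@sex == "F")
    if (!length(males) || !length(females))
      stop("burn-in extinction: a sex has no survivors")
    damPick <- sample(females, nMatings, replace = TRUE)
    sirePick <- sample(males, nMatings, replace = TRUE)
    offspring <- .reproduce(survivors, survivors, sirePick, damPick,
                            plan@progenyPerMating, arch, plan, phase,
                            gen, startId)
  } else {
    candidates <- survivors
    if (!is.null(hooks$carrierPolicy)) {
      maleIdx <- which(candidates@sex == "M")
      keptMales <- avoidCarriers(candidates[maleIdx], hooks$panel,
                                 hooks$carrierPolicy)
      others <- candidates[setdiff(seq_len(nInd(candidates)), maleIdx)]
      candidates <- .bindPopulations(keptMales, others)
    }
    parents <- selectParents(candidates, plan@nSires, nDams)
    sires <- parents$sires
    if (!is.null(hooks$editPolicy)) {
      refCohort <- if (hooks$editPolicy@freqSource == "cohort") survivors
                   else sires
      ordered <- prioritize(hooks$panel, refCohort, hooks$editPolicy)
      ed <- editSires(sires, ordered, hooks$editPolicy@editsPerSire,
                      arch, hooks$panel)
      editLog <- ed$log
      sires <- ed$sires
      if (hooks$editPolicy@mortality > 0) {
        maleIdx <- which(survivors@sex == "M")
        pool <- survivors[maleIdx]
        pool <- pool[!pool@id %in% sires@id]
        mr <- applyEditingMortality(sires, pool, hooks$editPolicy@mortality)
        sires <- mr$sires
        nReplaced <- mr$nReplaced
      }
    }
    sireOf <- sample.int(nInd(sires), nDams, replace = TRUE)
    offspring <- .reproduce(sires, parents$dams, sireOf,
                            seq_len(nDams), plan@progenyPerDam, arch,
                            plan, phase, gen, startId)
  }
  list(survivors = survivors, offspring = offspring,
       editLog = editLog, nReplaced = nReplaced)
}

## One record row of per-generation metrics, on the post-viability cohort.
.recordRow <- function(survivors, arch, phase, generation, futureGen = NA) {
  ls <- loadSummary(survivors, arch@fitnessLoci)
  data.frame(generation = generation, phase = phase, futureGen = futureGen,
             meanFitness = meanFitness(survivors),
             meanBV = meanBV(survivors),
             cohortSize = nInd(survivors),
             segregatingDeleterious = ls$segregating,
             meanTotalLoad = ls$total, meanHetLoad = ls$het,
             meanHomLoad = ls$hom)
}

#' Run founders, burn-in and historical breeding for one replicate
#'
#' Executes the replicate up to the end of historical breeding and returns
#' the frozen snapshot from which every scenario of the replicate starts:
#' founder generation, trait-architecture setup, 15 generations of natural
#' selection (5 x 1000 then 10 x 500 random matings by default), and 20
#' generations of historical breeding with truncation selection of 25
#' sires and a dam number fixed by the mean fitness at the start of
#' historical breeding.
#'
#' @param config a [ScenarioConfig-class].
#' @param replicateSeed the replicate's seed (see [replicateSeeds()]).
#' @return a snapshot list: `cohort` (the pre-viability cohort entering
#'   future breeding), `arch`, `map`, `records` (generations 1 to 35),
#'   `wRef`, `nDams`, `neutralLoci`, `nextId`, `replicateSeed`.
#' @export
runHistoricalPhase <- function(config, replicateSeed) {
  plan <- config@plan
  nQtl <- config@nQtlPerChrom * config@nChrom
  nFit <- config@nFitnessPerChrom * config@nChrom
  ## Fitness loci must have founder frequency below the ceiling; size the
  ## panel by the expected low-frequency fraction of the neutral 1/i
  ## spectrum, with a 1.5x safety factor for sampling fluctuation. Loci
  ## not assigned to either trait form the neutral pool.
  fracLow <- .lowFreqFraction(config@nHaplotypes, config@maxFounderFreq)
  targetLoci <- nQtl + config@nNeutral + ceiling(1.5 * nFit / fracLow)

  template <- genomeMap(integer(), numeric(), nChrom = config@nChrom,
                        chromLengthMorgans = config@chromLengthMorgans,
                        chromLengthBp = config@chromLengthBp)
  panel <- simulateFounders(config@nHaplotypes, targetLoci,
                            demography = config@demography, map = template,
                            muPerLocus = if (is.na(config@founderMu)) NULL
                                         else config@founderMu,
                            burnFactor = config@founderBurnFactor,
                            oversample = config@founderOversample,
                            seed = replicateSeed)
  arch <- makeArchitecture(panel, config@nQtlPerChrom,
                           config@nFitnessPerChrom, config@dominance,
                           config@maxFounderFreq, config@effectDist,
                           config@gammaShape)
  neutralLoci <- setdiff(seq_len(nLoci(panel)),
                         c(arch@qtlLoci, arch@fitnessLoci))
  cohort <- foundersToPopulation(panel, arch, plan@founderPopSize)
  nextId <- nInd(cohort) + 1L

  records <- list()
  gen <- 0L
  burnPlan <- rep(c(plan@burnInMatings1, plan@burnInMatings2),
                  c(plan@burnInGens1, plan@burnInGens2))
  for (m in burnPlan) {
    step <- advanceGeneration(cohort, plan, arch, "burn_in", nMatings = m,
                              startId = nextId)
    gen <- gen + 1L
    records[[gen]] <- .recordRow(step$survivors, arch, "burn_in", gen)
    cohort <- step$offspring
    nextId <- nextId + nInd(cohort)
  }

  wRef <- meanFitness(cohort)  # frozen at the start of historical breeding
  nDams <- computeNDams(wRef, plan@targetPop, plan@progenyPerDam)
  for (i in seq_len(plan@historicalGens)) {
    step <- advanceGeneration(cohort, plan, arch, "historical",
                              nDams = nDams, startId = nextId)
    gen <- gen + 1L
    records[[gen]] <- .recordRow(step$survivors, arch, "historical", gen)
    cohort <- step$offspring
    nextId <- nextId + nInd(cohort)
  }

  list(cohort = cohort, arch = arch, map = panel@map,
       records = do.call(rbind, records), wRef = wRef, nDams = nDams,
       neutralLoci = neutralLoci, nextId = nextId,
       replicateSeed = as.integer(replicateSeed))
}

#' Run future breeding from a historical snapshot
#'
#' Seeds a fresh RNG stream derived from the replicate seed (identical for
#' every scenario of the replicate, so baseline and interventions start
#' from the same initial populations after historical breeding), builds
#' the discovery panel for intervention scenarios, and runs the configured
#' number of future generations with the intervention hooks active.
#'
#' @param snapshot a snapshot from [runHistoricalPhase()].
#' @param config a [ScenarioConfig-class] (its intervention slots select
#'   the scenario).
#' @return a [SimulationResult-class].
#' @export
runFuturePhase <- function(snapshot, config) {
  plan <- config@plan
  arch <- snapshot$arch
  set.seed(.deriveSeed(snapshot$replicateSeed, "future"))

  hooks <- NULL
  if (config@interventionType != "baseline") {
    freqs <- alleleFreqs(snapshot$cohort)
    segDel <- arch@fitnessLoci[freqs[arch@fitnessLoci] > 0 &
                               freqs[arch@fitnessLoci] < 1]
    segNeu <- snapshot$neutralLoci[freqs[snapshot$neutralLoci] > 0 &
                                   freqs[snapshot$neutralLoci] < 1]
    panel <- buildDiscoveryPanel(segDel, segNeu, config@discoveryRate)
    hooks <- switch(config@interventionType,
      rage = list(panel = panel, editPolicy = config@editPolicy),
      carriers = list(panel = panel, carrierPolicy = config@carrierPolicy))
  }

  cohort <- snapshot$cohort
  nextId <- snapshot$nextId
  records <- list()
  editLogs <- list()
  gen <- cohort@generation
  for (g in seq_len(plan@futureGens)) {
    step <- advanceGeneration(cohort, plan, arch, "future",
                              nDams = snapshot$nDams, hooks = hooks,
                              startId = nextId)
    gen <- gen + 1L
    records[[g]] <- .recordRow(step$survivors, arch, "future", gen,
                               futureGen = g)
    if (!is.null(step$editLog) && nrow(step$editLog))
      editLogs[[length(editLogs) + 1L]] <-
        cbind(generation = gen, step$editLog)
    cohort <- step$offspring
    nextId <- nextId + nInd(cohort)
  }

  editLog <- if (length(editLogs)) do.call(rbind, editLogs)
             else data.frame(generation = integer(), sireId = integer(),
                             locus = integer(), isTrue = logical(),
                             s = numeric(), preDosage = integer())
  new("SimulationResult",
      records = rbind(snapshot$records, do.call(rbind, records)),
      editLog = editLog,
      distinctEdited = sort(unique(editLog$locus)),
      scenario = config@name,
      replicate = NA_integer_,
      seed = snapshot$replicateSeed,
      config = configAsList(config))
}

#' Run one full replicate of a scenario
#'
#' Founder generation, burn-in, historical breeding and future breeding
#' under the configured intervention, end to end. The generation counter
#' runs to 45 at the defaults (15 + 20 + 10). Scenarios that share a
#' replicate seed are identical up to the end of historical breeding.
#'
#' @param config a [ScenarioConfig-class].
#' @param replicate replicate number (selects the seed derived from
#'   `config@masterSeed`).
#' @return a [SimulationResult-class].
#' @examples
#' \donttest{
#' cfg <- deskPreset(intervention = "baseline", nReplicates = 1)
#' res <- runReplicate(cfg, 1)
#' tail(resultRecords(res))
#' }
#' @export
runReplicate <- function(config, replicate = 1L) {
  seeds <- replicateSeeds(config@masterSeed, config@nReplicates)
  if (replicate < 1L || replicate > length(seeds))
    stop("replicate number out of range")
  snap <- runHistoricalPhase(config, seeds[replicate])
  res <- runFuturePhase(snap, config)
  res@replicate <- as.integer(replicate)
  res
}

setMethod("show", "SimulationResult", function(object) {
  r <- object@records
  cat(sprintf(
    "SimulationResult '%s' (replicate %s, seed %d): %d generations\n",
    object@scenario, object@replicate, object@seed, nrow(r)))
  fut <- r[r$phase == "future", ]
  if (nrow(fut))
    cat(sprintf(
      "  future breeding: mean w %.4f -> %.4f; %d distinct loci edited\n",
      fut$meanFitness[1], fut$meanFitness[nrow(fut)],
      length(object@distinctEdited)))
})

#' Per-generation records of a result
#' @param result a [SimulationResult-class].
#' @return the records data.frame (one row per generation).
#' @export
resultRecords <- function(result) result@records

#' Edit log of a result
#' @param result a [SimulationResult-class].
#' @return data.frame of individual edits (generation, sireId, locus,
#'   isTrue, s, preDosage).
#' @export
editLog <- function(result) result@editLog
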