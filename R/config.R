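## Scenario configuration, presets matching the study's scenario grid,
## JSON validation and replicate seed management.

#' Construct a phase plan
#'
#' Defaults are the full-scale breeding program: 5 burn-in generations of
#' 1000 random matings then 10 of 500, 20 generations of historical
#' breeding, 10 of future breeding, 25 sires, 10 progeny per dam, a target
#' population of 5000 and a deleterious mutation rate of 1e-4 per locus
#' (one expected de-novo mutation per individual at 10,000 fitness loci).
#'
#' @param burnInGens1,burnInMatings1,burnInGens2,burnInMatings2 burn-in
#'   blocks.
#' @param historicalGens,futureGens phase lengths.
#' @param nSires,progenyPerDam,targetPop selection and pedigree structure.
#' @param mutationRate per-locus per-individual mutation rate.
#' @param mutationPhases phases in which recurrent mutation acts; the
#'   default includes future breeding (restrict to
#'   `c("burn_in", "historical")` for the literal reading that mutation
#'   occurred during natural selection and historical breeding only).
#' @param founderPopSize diploid founders assembled from the panel.
#' @param progenyPerMating progeny per burn-in random mating.
#' @return a [PhasePlan-class].
#' @export
phasePlan <- function(burnInGens1 = 5L, burnInMatings1 = 1000L,
                      burnInGens2 = 10L, burnInMatings2 = 500L,
                      historicalGens = 20L, futureGens = 10L,
                      nSires = 25L, progenyPerDam = 10L,
                      targetPop = 5000L, mutationRate = 1e-4,
                      mutationPhases = c("burn_in", "historical", "future"),
                      founderPopSize = 2000L, progenyPerMating = 10L) {
  new("PhasePlan",
      burnInGens1 = as.integer(burnInGens1),
      burnInMatings1 = as.integer(burnInMatings1),
      burnInGens2 = as.integer(burnInGens2),
      burnInMatings2 = as.integer(burnInMatings2),
      historicalGens = as.integer(historicalGens),
      futureGens = as.integer(futureGens),
      nSires = as.integer(nSires),
      progenyPerDam = as.integer(progenyPerDam),
      targetPop = as.integer(targetPop),
      mutationRate = mutationRate,
      mutationPhases = mutationPhases,
      founderPopSize = as.integer(founderPopSize),
      progenyPerMating = as.integer(progenyPerMating))
}

#' Construct a scenario configuration
#'
#' All parameters of one scenario. The defaults are the full-scale setup:
#' 10 chromosomes of 1 Morgan / 6.75e8 bp, 1000 QTL and 1000 fitness loci
#' per chromosome, a 10,000-locus neutral pool, founder panel of 4000
#' haplotypes from a constant-Ne-100 history, normal QTL effects,
#' codominant variants (h = 0.5) with a founder-frequency ceiling of 0.01
#' (use h = 0 and 0.1 for the recessive setup), and a discovery rate of
#' 0.75.
#'
#' @param name scenario label.
#' @param intervention `"baseline"`, an [EditPolicy-class] (RAGE) or a
#'   [CarrierPolicy-class] (selection against carriers).
#' @param discoveryRate d in (0, 1].
#' @param dominance shared dominance coefficient h.
#' @param maxFounderFreq founder-frequency ceiling for fitness loci; if
#'   NULL, 0.01 when h >= 0.25 (codominant-like) and 0.1 otherwise.
#' @param nChrom,chromLengthMorgans,chromLengthBp genome structure.
#' @param demography a [Demography-class] for founder generation.
#' @param nHaplotypes,founderMu,founderBurnFactor,founderOversample founder
#'   generator parameters (`founderMu = NA` uses the theta-scaled default
#'   of [simulateFounders()]).
#' @param nQtlPerChrom,nFitnessPerChrom,nNeutral trait architecture sizes.
#' @param effectDist,gammaShape QTL effect distribution.
#' @param plan a [PhasePlan-class].
#' @param nReplicates,masterSeed replicate management.
#' @param scale preset label ("paper" or "desk"); @param lociScale,popScale
#'   recorded scale factors.
#' @return a validated [ScenarioConfig-class].
#' @export
scenarioConfig <- function(name = "baseline",
                           intervention = "baseline",
                           discoveryRate = 0.75,
                           dominance = 0.5,
                           maxFounderFreq = NULL,
                           nChrom = 10L,
                           chromLengthMorgans = 1,
                           chromLengthBp = 6.75e8,
                           demography = ragesim::demography(100),
                           nHaplotypes = 4000L,
                           founderMu = NA_real_,
                           founderBurnFactor = 10,
                           founderOversample = 30,
                           nQtlPerChrom = 1000L,
                           nFitnessPerChrom = 1000L,
                           nNeutral = 10000L,
                           effectDist = "normal",
                           gammaShape = 11,
                           plan = phasePlan(),
                           nReplicates = 50L,
                           masterSeed = 1L,
                           scale = "paper",
                           lociScale = 1,
                           popScale = 1) {
  if (is.null(maxFounderFreq))
    maxFounderFreq <- if (dominance >= 0.25) 0.01 else 0.1
  type <- "baseline"
  ep <- editPolicy("random", 0L)
  cp <- carrierPolicy("total", 0L)
  if (is(intervention, "EditPolicy")) {
    type <- "rage"; ep <- intervention
  } else if (is(intervention, "CarrierPolicy")) {
    type <- "carriers"; cp <- intervention
  } else if (!identical(intervention, "baseline")) {
    stop("intervention must be 'baseline', an EditPolicy or a CarrierPolicy")
  }
  new("ScenarioConfig",
      name = name, scale = scale,
      lociScale = lociScale, popScale = popScale,
      nChrom = as.integer(nChrom),
      chromLengthMorgans = chromLengthMorgans,
      chromLengthBp = chromLengthBp,
      demography = demography,
      nHaplotypes = as.integer(nHaplotypes),
      founderMu = founderMu,
      founderBurnFactor = founderBurnFactor,
      founderOversample = founderOversample,
      nQtlPerChrom = as.integer(nQtlPerChrom),
      nFitnessPerChrom = as.integer(nFitnessPerChrom),
      nNeutral = as.integer(nNeutral),
      effectDist = effectDist, gammaShape = gammaShape,
      dominance = dominance, maxFounderFreq = maxFounderFreq,
      plan = plan,
      interventionType = type, editPolicy = ep, carrierPolicy = cp,
      discoveryRate = discoveryRate,
      nReplicates = as.integer(nReplicates),
      masterSeed = as.integer(masterSeed))
}

#' Full-scale preset
#'
#' The study conditions at full scale: 10,000 QTL + 10,000 fitness loci,
#' founder panel of 4000 haplotypes, target population 5000, 25 sires,
#' 50 replicates. A full scenario grid at this scale is an overnight job.
#'
#' @param ... overrides passed to [scenarioConfig()].
#' @return a [ScenarioConfig-class].
#' @export
paperPreset <- function(...) {
  scenarioConfig(scale = "paper", ...)
}

#' Desk-scale preset
#'
#' Scaled-down study conditions for interactive use and test suites: loci
#' scaled by 1/10 (1000 QTL + 1000 fitness loci, 1000-locus neutral pool)
#' and population by 1/5 (founder panel 400 haplotypes, target population
#' 1000, 10 sires, burn-in matings 200 then 100), with identical rates and
#' thresholds. The scale factors are recorded in the configuration.
#'
#' @param ... overrides passed to [scenarioConfig()].
#' @return a [ScenarioConfig-class].
#' @export
deskPreset <- function(...) {
  args <- list(...)
  defaults <- list(
    nHaplotypes = 400L,
    nQtlPerChrom = 100L,
    nFitnessPerChrom = 100L,
    nNeutral = 1000L,
    plan = phasePlan(burnInMatings1 = 200L, burnInMatings2 = 100L,
                     targetPop = 1000L, nSires = 10L,
                     founderPopSize = 200L),
    scale = "desk", lociScale = 0.1, popScale = 0.2)
  do.call(scenarioConfig, modifyList(defaults, args))
}

#' Derive replicate seeds from a master seed
#'
#' Seeds are drawn as a deterministic function of the master seed
#' (`set.seed(masterSeed)` then `sample.int`), so that a scenario and its
#' baseline, or two reruns of the same grid, always share replicate seeds.
#'
#' @param masterSeed integer master seed.
#' @param n number of replicates.
#' @return integer vector of n distinct seeds (< 2^31).
#' @export
replicateSeeds <- function(masterSeed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(masterSeed)
  sample.int(2147483646L, n)
}

#' Echo a configuration as a plain list
#'
#' @param config a [ScenarioConfig-class].
#' @return a named list of the scalar configuration fields (used as the
#'   config echo inside [SimulationResult-class]).
#' @export
configAsList <- function(config) {
  list(name = config@name, scale = config@scale,
       interventionType = config@interventionType,
       strategy = if (config@interventionType == "rage")
         config@editPolicy@strategy
       else if (config@interventionType == "carriers")
         config@carrierPolicy@mode else NA_character_,
       editsPerSire = config@editPolicy@editsPerSire,
       mortality = config@editPolicy@mortality,
       nAvoid = config@carrierPolicy@nAvoid,
       discoveryRate = config@discoveryRate,
       dominance = config@dominance,
       maxFounderFreq = config@maxFounderFreq,
       nQtl = config@nQtlPerChrom * config@nChrom,
       nFitness = config@nFitnessPerChrom * config@nChrom,
       nSires = config@plan@nSires,
       targetPop = config@plan@targetPop,
       mutationRate = config@plan@mutationRate,
       masterSeed = config@masterSeed)
}

#' Validate a JSON scenario configuration
#'
#' Reads a JSON file (or literal JSON string) and builds a
#' [ScenarioConfig-class], filling every unspecified field with the
#' full-scale defaults (25 sires, 10 progeny per dam, target population
#' 5000, mutation rate 1e-4, founder-frequency ceilings 0.01/0.1,
#' intermediate-frequency threshold 0.25). Out-of-range values raise one
#' error listing all offending fields. An empty JSON object yields the
#' full default configuration.
#'
#' Recognised fields: `preset` ("paper"/"desk"), `name`, `n_replicates`,
#' `master_seed`, `dominance`, `max_founder_freq`, `discovery_rate`,
#' `effect_dist`, `gamma_shape`, `intervention` (object with `type` =
#' "baseline"/"rage"/"carriers" and the matching policy fields `strategy`,
#' `edits_per_sire`, `freq_threshold`, `mortality`, `freq_source`, `mode`,
#' `n_avoid`) and `plan` (any [phasePlan()] argument in snake_case).
#'
#' @param json path to a JSON file, or a JSON string.
#' @return a validated [ScenarioConfig-class].
#' @export
validateConfig <- function(json) {
  raw <- if (file.exists(json)) jsonlite::read_json(json)
         else jsonlite::parse_json(json)
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)

  preset <- raw$preset %||% "paper"
  chk(preset %in% c("paper", "desk"), "preset: must be 'paper' or 'desk'")
  maker <- if (identical(preset, "desk")) deskPreset else paperPreset
  args <- list()
  if (!is.null(raw$name)) args$name <- raw$name
  if (!is.null(raw$n_replicates)) {
    chk(raw$n_replicates >= 1, "n_replicates: must be >= 1")
    args$nReplicates <- raw$n_replicates
  }
  if (!is.null(raw$master_seed)) args$masterSeed <- raw$master_seed
  if (!is.null(raw$dominance)) {
    chk(raw$dominance >= 0 && raw$dominance <= 1,
        "dominance: must lie in [0, 1]")
    args$dominance <- raw$dominance
  }
  if (!is.null(raw$max_founder_freq)) {
    chk(raw$max_founder_freq > 0 && raw$max_founder_freq <= 1,
        "max_founder_freq: must lie in (0, 1]")
    args$maxFounderFreq <- raw$max_founder_freq
  }
  if (!is.null(raw$discovery_rate)) {
    chk(raw$discovery_rate > 0 && raw$discovery_rate <= 1,
        "discovery_rate: must lie in (0, 1]")
    args$discoveryRate <- raw$discovery_rate
  }
  if (!is.null(raw$effect_dist)) {
    chk(raw$effect_dist %in% c("normal", "gamma"),
        "effect_dist: must be 'normal' or 'gamma'")
    args$effectDist <- raw$effect_dist
  }
  if (!is.null(raw$gamma_shape)) {
    chk(raw$gamma_shape > 0, "gamma_shape: must be > 0")
    args$gammaShape <- raw$gamma_shape
  }
  if (!is.null(raw$plan)) {
    pn <- c(burn_in_gens1 = "burnInGens1", burn_in_matings1 = "burnInMatings1",
            burn_in_gens2 = "burnInGens2", burn_in_matings2 = "burnInMatings2",
            historical_gens = "historicalGens", future_gens = "futureGens",
            n_sires = "nSires", progeny_per_dam = "progenyPerDam",
            target_pop = "targetPop", mutation_rate = "mutationRate",
            mutation_phases = "mutationPhases",
            founder_pop_size = "founderPopSize",
            progeny_per_mating = "progenyPerMating")
    unknown <- setdiff(names(raw$plan), names(pn))
    chk(!length(unknown),
        paste0("plan: unknown fields ", paste(unknown, collapse = ", ")))
    planArgs <- raw$plan[intersect(names(raw$plan), names(pn))]
    names(planArgs) <- pn[names(planArgs)]
    if (!is.null(planArgs$mutationPhases))
      planArgs$mutationPhases <- unlist(planArgs$mutationPhases)
    if (identical(preset, "desk")) {
      base <- list(burnInMatings1 = 200L, burnInMatings2 = 100L,
                   targetPop = 1000L, nSires = 10L, founderPopSize = 200L)
      planArgs <- modifyList(base, planArgs)
    }
    args$plan <- tryCatch(do.call(phasePlan, planArgs),
                          error = function(e) {
                            chk(FALSE, paste0("plan: ", conditionMessage(e)))
                            phasePlan()
                          })
  }
  if (!is.null(raw$intervention)) {
    iv <- raw$intervention
    type <- iv$type %||% "baseline"
    chk(type %in% c("baseline", "rage", "carriers"),
        "intervention.type: must be baseline, rage or carriers")
    if (identical(type, "rage")) {
      strat <- iv$strategy %||% "random"
      chk(strat %in% .editStrategies,
          paste0("intervention.strategy: must be one of ",
                 paste(.editStrategies, collapse = ", ")))
      k <- iv$edits_per_sire %||% 5L
      chk(k >= 0, "intervention.edits_per_sire: must be >= 0")
      m <- iv$mortality %||% 0
      chk(m >= 0 && m <= 1, "intervention.mortality: must lie in [0, 1]")
      if (!length(errs))
        args$intervention <- editPolicy(strat, k,
                                        iv$freq_threshold %||% 0.25, m,
                                        iv$freq_source %||% "cohort")
    } else if (identical(type, "carriers")) {
      mode <- iv$mode %||% "total"
      chk(mode %in% c("total", "het", "hom"),
          "intervention.mode: must be total, het or hom")
      na <- iv$n_avoid %||% 100L
      chk(na >= 0, "intervention.n_avoid: must be >= 0")
      if (!length(errs)) args$intervention <- carrierPolicy(mode, na)
    }
  }
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  do.call(maker, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf(
    "ScenarioConfig '%s' [%s scale]: %s intervention, h = %g, d = %g\n",
    object@name, object@scale, object@interventionType, object@dominance,
    object@discoveryRate))
  cat(sprintf(
    "  %d QTL + %d fitness loci, %d sires, target population %d, %d replicates\n",
    object@nQtlPerChrom * object@nChrom,
    object@nFitnessPerChrom * object@nChrom,
    object@plan@nSires, object@plan@targetPop, object@nReplicates))
})
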