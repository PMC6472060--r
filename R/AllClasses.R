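## Central S4 classes. Haplotypes inside a Population are stored loci x
## individuals (column-contiguous gametes); a HaplotypePanel keeps the
## external haplotype-by-locus orientation of the TSV interchange format.

#' GenomeMap: chromosome structure and locus coordinates
#'
#' The coordinate system for recombination and locus indexing: chromosome
#' lengths in Morgans (and base pairs, for locus naming), and for every
#' locus its chromosome and genetic position. Loci are indexed 1-based
#' genome-wide, sorted by (chromosome, position); genetic positions live in
#' the half-open interval \eqn{[0, length)} of their chromosome.
#'
#' Defaults follow a genome of 10 chromosomes, each 1 Morgan long and
#' 6.75e8 bp.
#'
#' @slot nChrom number of chromosomes.
#' @slot chromLengthMorgans per-chromosome map length in Morgans.
#' @slot chromLengthBp per-chromosome physical length in base pairs.
#' @slot locusChrom chromosome index per locus (1-based).
#' @slot locusPos genetic position per locus, Morgans within chromosome.
#' @exportClass GenomeMap
setClass("GenomeMap",
  representation(
    nChrom = "integer",
    chromLengthMorgans = "numeric",
    chromLengthBp = "numeric",
    locusChrom = "integer",
    locusPos = "numeric"
  )
)

setValidity("GenomeMap", function(object) {
  msg <- character()
  if (length(object@chromLengthMorgans) != object@nChrom ||
      length(object@chromLengthBp) != object@nChrom)
    msg <- c(msg, "chromosome length vectors must have nChrom entries")
  if (length(object@locusChrom) != length(object@locusPos))
    msg <- c(msg, "locusChrom and locusPos must have equal length")
  if (length(object@locusChrom)) {
    if (any(object@locusChrom < 1L) ||
        any(object@locusChrom > object@nChrom)) {
      msg <- c(msg, "locusChrom out of range")
    } else {
      bad <- object@locusPos < 0 |
        object@locusPos >= object@chromLengthMorgans[object@locusChrom]
      if (any(bad))
        msg <- c(msg, sprintf("%d locus positions outside [0, chrom length)",
                              sum(bad)))
      o <- order(object@locusChrom, object@locusPos)
      if (!identical(o, seq_along(o)))
        msg <- c(msg, "loci must be sorted by (chromosome, position)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Demography: effective-size history for the founder generator
#'
#' Either a constant effective size, or a piecewise schedule of
#' (generations ago, Ne) breakpoints with sizes stepped through the
#' schedule by the forward Wright-Fisher burn-in. The historical default
#' used for founder generation is a constant Ne of 100 (the present-day
#' size of the piecewise history; see [paperDemography()]).
#'
#' @slot schedule data.frame with columns `generations_ago` (strictly
#'   decreasing toward the present) and `ne` (> 0).
#' @slot interpolate logical; request linear change on the 4*Ne*t scale
#'   between breakpoints. The stepped forward backend honours this only
#'   approximately (sizes change at breakpoints).
#' @slot constantNe single effective size overriding the schedule, or NA.
#' @exportClass Demography
setClass("Demography",
  representation(
    schedule = "data.frame",
    interpolate = "logical",
    constantNe = "numeric"
  )
)

setValidity("Demography", function(object) {
  msg <- character()
  if (!is.na(object@constantNe) && object@constantNe <= 0)
    msg <- c(msg, "constantNe must be > 0")
  if (nrow(object@schedule)) {
    if (!all(c("generations_ago", "ne") %in% names(object@schedule)))
      msg <- c(msg, "schedule needs columns generations_ago and ne")
    else {
      if (any(object@schedule$ne <= 0))
        msg <- c(msg, "all effective sizes must be > 0")
      ga <- object@schedule$generations_ago
      if (any(diff(ga) >= 0))
        msg <- c(msg, "generations_ago must be strictly decreasing")
    }
  } else if (is.na(object@constantNe)) {
    msg <- c(msg, "either a schedule or constantNe is required")
  }
  if (length(msg)) msg else TRUE
})

#' HaplotypePanel: founder (or current) haplotypes
#'
#' A binary haplotype-by-locus matrix: 0 is the wild-type (ancestral)
#' allele, 1 the derived allele. Downstream, the derived allele is always
#' the candidate deleterious allele. At creation every locus segregates
#' (derived frequency strictly between 0 and 1) and the number of
#' haplotypes is even so they can be paired into diploid founders.
#'
#' @slot alleles n_haplotypes x n_loci integer matrix of 0/1.
#' @slot map the [GenomeMap-class] the loci live on.
#' @slot freqs derived-allele frequency per locus (cached).
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
  representation(
    alleles = "matrix",
    map = "GenomeMap",
    freqs = "numeric"
  )
)

setValidity("HaplotypePanel", function(object) {
  msg <- character()
  if (ncol(object@alleles) != length(object@map@locusChrom))
    msg <- c(msg, "panel has a different locus count than its map")
  if (nrow(object@alleles) %% 2L != 0L)
    msg <- c(msg, "number of haplotypes must be even")
  if (!all(object@alleles %in% c(0L, 1L)))
    msg <- c(msg, "alleles must be 0/1")
  if (length(object@freqs) != ncol(object@alleles))
    msg <- c(msg, "freqs cache has wrong length")
  else if (length(object@freqs) &&
           (any(object@freqs <= 0) || any(object@freqs >= 1)))
    msg <- c(msg, "every locus must segregate (0 < freq < 1)")
  if (length(msg)) msg else TRUE
})

#' TraitArchitecture: QTL and fitness-locus assignment
#'
#' Locus indices and effects for the two independent traits: the additive
#' quantitative breeding-goal trait (QTL with effects \eqn{a_i}) and the
#' multiplicative fitness trait (loci with selection coefficients
#' \eqn{s_i \in [0, 1]} and a shared dominance coefficient \eqn{h}).
#' Genotype fitness at one locus is 1, \eqn{1 - hs}, or \eqn{1 - s} for
#' dosage 0, 1, 2; individual fitness is the product over fitness loci.
#'
#' @slot qtlLoci genome-wide locus indices of the QTL (1-based).
#' @slot qtlEffects additive effect per QTL.
#' @slot fitnessLoci locus indices of the fitness (deleterious) variants,
#'   disjoint from the QTL.
#' @slot selCoeffs selection coefficient s per fitness locus, in [0, 1].
#' @slot dominance shared dominance coefficient h in [0, 1]
#'   (0 = recessive, 0.5 = codominant).
#' @exportClass TraitArchitecture
setClass("TraitArchitecture",
  representation(
    qtlLoci = "integer",
    qtlEffects = "numeric",
    fitnessLoci = "integer",
    selCoeffs = "numeric",
    dominance = "numeric"
  )
)

setValidity("TraitArchitecture", function(object) {
  msg <- character()
  if (length(object@qtlLoci) != length(object@qtlEffects))
    msg <- c(msg, "qtlLoci and qtlEffects lengths differ")
  if (length(object@fitnessLoci) != length(object@selCoeffs))
    msg <- c(msg, "fitnessLoci and selCoeffs lengths differ")
  if (length(intersect(object@qtlLoci, object@fitnessLoci)))
    msg <- c(msg, "QTL and fitness loci must be disjoint")
  if (any(object@selCoeffs < 0) || any(object@selCoeffs > 1))
    msg <- c(msg, "selection coefficients must lie in [0, 1]")
  if (length(object@dominance) != 1L ||
      object@dominance < 0 || object@dominance > 1)
    msg <- c(msg, "dominance must be a single value in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Population: one cohort of diploid individuals
#'
#' Matrix-backed cohort: two haplotype matrices stored loci x individuals,
#' plus per-individual sex, true breeding value, fitness, ids and pedigree
#' links. Fitness `w` and breeding value `bv` are derived caches and always
#' equal the values recomputed from the genotypes and the architecture.
#'
#' @slot hapA,hapB L x N integer matrices of 0/1 alleles (columns are
#'   individuals).
#' @slot id,sire,dam integer identifiers (0 = unknown parent).
#' @slot sex character, "M" or "F".
#' @slot bv true breeding value per individual.
#' @slot w fitness (survival probability) per individual, in [0, 1].
#' @slot generation absolute generation counter (0 = founders).
#' @slot phase one of "founder", "burn_in", "historical", "future".
#' @slot map the [GenomeMap-class].
#' @exportClass Population
setClass("Population",
  representation(
    hapA = "matrix",
    hapB = "matrix",
    id = "integer",
    sire = "integer",
    dam = "integer",
    sex = "character",
    bv = "numeric",
    w = "numeric",
    generation = "integer",
    phase = "character",
    map = "GenomeMap"
  )
)

setValidity("Population", function(object) {
  msg <- character()
  n <- ncol(object@hapA)
  if (ncol(object@hapB) != n)
    msg <- c(msg, "hapA and hapB must have the same number of individuals")
  if (nrow(object@hapA) != length(object@map@locusChrom) ||
      nrow(object@hapB) != length(object@map@locusChrom))
    msg <- c(msg, "haplotype matrices do not match the map's locus count")
  for (s in c("id", "sire", "dam", "sex", "bv", "w"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("slot '%s' must have one entry per individual", s))
  if (anyDuplicated(object@id))
    msg <- c(msg, "individual ids must be unique")
  if (!all(object@sex %in% c("M", "F")))
    msg <- c(msg, "sex must be 'M' or 'F'")
  if (length(object@generation) != 1L || object@generation < 0L)
    msg <- c(msg, "generation must be a single non-negative integer")
  if (!object@phase %in% c("founder", "burn_in", "historical", "future"))
    msg <- c(msg, "unknown phase label")
  if (length(msg)) msg else TRUE
})

#' PhasePlan: generation counts and pedigree parameters
#'
#' The three-phase plan of the breeding program: burn-in under natural
#' selection only (5 generations of 1000 random matings, then 10 of 500),
#' 20 generations of historical breeding (natural selection plus truncation
#' selection of 25 sires and a computed number of dams), and 10 generations
#' of future breeding in which an intervention scenario may act. Each dam
#' has 10 progeny; the dam count is chosen to reach a population of 5000 at
#' the mean fitness observed at the start of historical breeding. Recurrent
#' deleterious mutation occurs at 1e-4 per fitness locus per individual.
#'
#' @slot burnInGens1,burnInMatings1 first burn-in block (5 x 1000).
#' @slot burnInGens2,burnInMatings2 second burn-in block (10 x 500).
#' @slot historicalGens,futureGens phase lengths (20, 10).
#' @slot nSires sires selected per generation (25).
#' @slot progenyPerDam litter size (10).
#' @slot targetPop target cohort size used to compute the dam count (5000).
#' @slot mutationRate per-locus per-individual deleterious mutation rate
#'   (1e-4, i.e. one expected de-novo mutation per individual at 10,000
#'   fitness loci).
#' @slot mutationPhases phases in which mutation acts (default all three).
#' @slot founderPopSize diploid founders assembled from the panel (2000).
#' @slot progenyPerMating progeny per burn-in random mating (10).
#' @exportClass PhasePlan
setClass("PhasePlan",
  representation(
    burnInGens1 = "integer", burnInMatings1 = "integer",
    burnInGens2 = "integer", burnInMatings2 = "integer",
    historicalGens = "integer", futureGens = "integer",
    nSires = "integer", progenyPerDam = "integer",
    targetPop = "integer", mutationRate = "numeric",
    mutationPhases = "character",
    founderPopSize = "integer", progenyPerMating = "integer"
  )
)

setValidity("PhasePlan", function(object) {
  msg <- character()
  counts <- c(object@burnInGens1, object@burnInMatings1, object@burnInGens2,
              object@burnInMatings2, object@historicalGens, object@futureGens,
              object@nSires, object@progenyPerDam, object@targetPop,
              object@founderPopSize, object@progenyPerMating)
  if (any(counts <= 0L)) msg <- c(msg, "all counts must be positive")
  if (object@mutationRate < 0 || object@mutationRate > 1)
    msg <- c(msg, "mutationRate must lie in [0, 1]")
  if (!all(object@mutationPhases %in% c("burn_in", "historical", "future")))
    msg <- c(msg, "mutationPhases must be a subset of burn_in/historical/future")
  if (length(msg)) msg else TRUE
})

#' DiscoveryPanel: discovered deleterious variants (with false positives)
#'
#' The set of variants "discovered" at the end of historical breeding: with
#' discovery rate d, a fraction d of the panel are true deleterious variants
#' sampled from the fitness loci segregating at that point, and a fraction
#' 1 - d are false positives sampled from neutral segregating loci, so that
#' the panel size equals the number of segregating deleterious variants.
#' The panel is frozen for all 10 future generations. The panel also
#' carries the seeded permutation used by the `random` prioritization
#' strategy, drawn once per replicate.
#'
#' @slot loci genome-wide locus indices of the panel.
#' @slot isTrue TRUE for genuine deleterious loci, FALSE for false positives.
#' @slot discoveryRate d in (0, 1].
#' @slot randomOrder a fixed permutation of `loci` for the random strategy.
#' @exportClass DiscoveryPanel
setClass("DiscoveryPanel",
  representation(
    loci = "integer",
    isTrue = "logical",
    discoveryRate = "numeric",
    randomOrder = "integer"
  )
)

setValidity("DiscoveryPanel", function(object) {
  msg <- character()
  if (length(object@loci) != length(object@isTrue))
    msg <- c(msg, "loci and isTrue lengths differ")
  if (object@discoveryRate <= 0 || object@discoveryRate > 1)
    msg <- c(msg, "discoveryRate must lie in (0, 1]")
  if (anyDuplicated(object@loci))
    msg <- c(msg, "panel loci must be unique")
  if (!setequal(object@randomOrder, object@loci))
    msg <- c(msg, "randomOrder must be a permutation of the panel loci")
  if (length(msg)) msg else TRUE
})

#' EditPolicy: RAGE strategy and editing parameters
#'
#' @slot strategy one of "high_freq", "low_freq", "homozygote_deficit",
#'   "intermediate_freq", "random".
#' @slot editsPerSire maximum edits per sire, k (paper grid: 1, 5, 20).
#' @slot freqThreshold exclusion threshold for the intermediate-frequency
#'   strategy (0.25).
#' @slot mortality probability m that an edited sire dies and is replaced
#'   by an unedited lower-ranked candidate.
#' @slot freqSource cohort used for allele/genotype frequencies in
#'   prioritization: "cohort" (post-viability candidates, recomputed each
#'   generation; default) or "sires" (the 25 selected sires only).
#' @exportClass EditPolicy
setClass("EditPolicy",
  representation(
    strategy = "character",
    editsPerSire = "integer",
    freqThreshold = "numeric",
    mortality = "numeric",
    freqSource = "character"
  )
)

.editStrategies <- c("high_freq", "low_freq", "homozygote_deficit",
                     "intermediate_freq", "random")

setValidity("EditPolicy", function(object) {
  msg <- character()
  if (!object@strategy %in% .editStrategies)
    msg <- c(msg, paste("strategy must be one of:",
                        paste(.editStrategies, collapse = ", ")))
  if (object@editsPerSire < 0L) msg <- c(msg, "editsPerSire must be >= 0")
  if (object@mortality < 0 || object@mortality > 1)
    msg <- c(msg, "mortality must lie in [0, 1]")
  if (!object@freqSource %in% c("cohort", "sires"))
    msg <- c(msg, "freqSource must be 'cohort' or 'sires'")
  if (length(msg)) msg else TRUE
})

#' CarrierPolicy: selection against carrier sires
#'
#' @slot mode load score: "total" (all deleterious alleles over the panel),
#'   "het" (alleles carried heterozygous), or "hom" (alleles carried
#'   homozygous).
#' @slot nAvoid number of highest-load male candidates removed before sire
#'   selection (paper grid: 100, 250, 500).
#' @exportClass CarrierPolicy
setClass("CarrierPolicy",
  representation(mode = "character", nAvoid = "integer")
)

setValidity("CarrierPolicy", function(object) {
  msg <- character()
  if (!object@mode %in% c("total", "het", "hom"))
    msg <- c(msg, "mode must be 'total', 'het' or 'hom'")
  if (object@nAvoid < 0L) msg <- c(msg, "nAvoid must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ScenarioConfig: all parameters of one simulation scenario
#'
#' Genome, founder-generator, trait-architecture, phase-plan and
#' intervention parameters plus replicate/seed management. Built with
#' [scenarioConfig()] or from JSON with [validateConfig()]; presets
#' [paperPreset()] (full scale) and [deskPreset()] (scaled down by 1/10 in
#' loci and 1/5 in population, scale factors recorded) fill the defaults.
#'
#' @slot name scenario label.
#' @slot scale "paper" or "desk".
#' @slot lociScale,popScale scale factors relative to the full-scale setup.
#' @slot nChrom,chromLengthMorgans,chromLengthBp genome parameters
#'   (per-chromosome scalars).
#' @slot demography [Demography-class] for the founder generator.
#' @slot nHaplotypes founder panel size.
#' @slot founderMu,founderBurnFactor,founderOversample Wright-Fisher founder
#'   backend: per-locus mutation rate, burn-in length in multiples of Ne,
#'   and candidate-locus oversampling factor.
#' @slot nQtlPerChrom,nFitnessPerChrom loci per chromosome for each trait.
#' @slot nNeutral size of the neutral locus pool (false-positive source).
#' @slot effectDist "normal" or "gamma"; @slot gammaShape shape for the
#'   gamma option (11).
#' @slot dominance shared h; @slot maxFounderFreq founder-frequency ceiling
#'   for fitness loci (0.01 codominant, 0.1 recessive).
#' @slot plan [PhasePlan-class].
#' @slot interventionType "baseline", "rage" or "carriers".
#' @slot editPolicy,carrierPolicy the active policy (ignored slots for the
#'   other types).
#' @slot discoveryRate d in (0, 1].
#' @slot nReplicates,masterSeed replicate management.
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  representation(
    name = "character",
    scale = "character",
    lociScale = "numeric",
    popScale = "numeric",
    nChrom = "integer",
    chromLengthMorgans = "numeric",
    chromLengthBp = "numeric",
    demography = "Demography",
    nHaplotypes = "integer",
    founderMu = "numeric",
    founderBurnFactor = "numeric",
    founderOversample = "numeric",
    nQtlPerChrom = "integer",
    nFitnessPerChrom = "integer",
    nNeutral = "integer",
    effectDist = "character",
    gammaShape = "numeric",
    dominance = "numeric",
    maxFounderFreq = "numeric",
    plan = "PhasePlan",
    interventionType = "character",
    editPolicy = "EditPolicy",
    carrierPolicy = "CarrierPolicy",
    discoveryRate = "numeric",
    nReplicates = "integer",
    masterSeed = "integer"
  )
)

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  if (!object@interventionType %in% c("baseline", "rage", "carriers"))
    msg <- c(msg, "interventionType must be baseline, rage or carriers")
  if (object@discoveryRate <= 0 || object@discoveryRate > 1)
    msg <- c(msg, "discoveryRate must lie in (0, 1]")
  if (!object@effectDist %in% c("normal", "gamma"))
    msg <- c(msg, "effectDist must be 'normal' or 'gamma'")
  if (object@dominance < 0 || object@dominance > 1)
    msg <- c(msg, "dominance must lie in [0, 1]")
  if (object@maxFounderFreq <= 0 || object@maxFounderFreq > 1)
    msg <- c(msg, "maxFounderFreq must lie in (0, 1]")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SimulationResult: per-generation records of one replicate run
#'
#' @slot records data.frame with one row per generation: generation, phase,
#'   futureGen (1-10 within future breeding, NA elsewhere), meanFitness,
#'   meanBV, cohortSize, segregatingDeleterious, meanTotalLoad, meanHetLoad,
#'   meanHomLoad.
#' @slot editLog data.frame of individual edits: generation, sireId, locus,
#'   isTrue, s, preDosage.
#' @slot distinctEdited cumulative set of distinct edited locus ids (empty
#'   for non-RAGE scenarios).
#' @slot scenario,replicate,seed labels of the run.
#' @slot config echo of the generating [ScenarioConfig-class] as a list.
#' @exportClass SimulationResult
setClass("SimulationResult",
  representation(
    records = "data.frame",
    editLog = "data.frame",
    distinctEdited = "integer",
    scenario = "character",
    replicate = "integer",
    seed = "integer",
    config = "list"
  )
)

setValidity("SimulationResult", function(object) {
  need <- c("generation", "phase", "futureGen", "meanFitness", "meanBV",
            "cohortSize", "segregatingDeleterious", "meanTotalLoad",
            "meanHetLoad", "meanHomLoad")
  if (!all(need %in% names(object@records)))
    return(paste("records is missing columns:",
                 paste(setdiff(need, names(object@records)), collapse = ", ")))
  TRUE
})
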