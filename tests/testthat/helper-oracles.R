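## Independent oracles and small fixtures, built in code.

## Brute-force multiplicative fitness: explicit per-locus loop.
oracleFitness <- function(dosages, s, h) {
  w <- 1
  for (i in seq_along(dosages)) {
    w <- w * switch(dosages[i] + 1L, 1, 1 - h * s[i], 1 - s[i])
  }
  w
}

## Brute-force breeding value.
oracleBV <- function(dosages, effects) {
  x <- 0
  for (i in seq_along(dosages)) x <- x + effects[i] * dosages[i]
  x
}

## Brute-force carrier loads.
oracleLoads <- function(dosages) {
  tot <- 0L; het <- 0L; hom <- 0L
  for (d in dosages) {
    tot <- tot + d
    if (d == 1L) het <- het + 1L
    if (d == 2L) hom <- hom + 2L
  }
  list(total = tot, het = het, hom = hom)
}

## Exact single-locus viability-selection recursion from Hardy-Weinberg
## genotype bookkeeping (p = deleterious-allele frequency).
oracleRecursionStep <- function(p, s, h) {
  q <- 1 - p
  wbar <- p^2 * (1 - s) + 2 * p * q * (1 - h * s) + q^2
  (p^2 * (1 - s) + p * q * (1 - h * s)) / wbar
}

## Deterministic trajectory plus a delta-method drift-variance envelope:
## var accumulates as V' = V * (dp'/dp)^2 + p(1-p) * perGenVar.
oracleTrajectory <- function(p0, s, h, generations, perGenVarFactor) {
  p <- numeric(generations)
  v <- numeric(generations)
  pc <- p0
  vc <- 0
  eps <- 1e-6
  for (t in seq_len(generations)) {
    grad <- (oracleRecursionStep(pc + eps, s, h) -
             oracleRecursionStep(pc - eps, s, h)) / (2 * eps)
    pc <- oracleRecursionStep(pc, s, h)
    vc <- vc * grad^2 + pc * (1 - pc) * perGenVarFactor
    p[t] <- pc
    v[t] <- vc
  }
  list(p = p, sd = sqrt(v))
}

## Independent single-locus Wright-Fisher chain for the neutral SFS: the
## marginal allele-count law of the founder backend (binomial resampling
## of 2N copies plus one-way per-copy mutation), vectorized over
## independent loci. No recombination machinery involved.
oracleWrightFisherSFS <- function(nLoci, ne, mu, generations) {
  x <- integer(nLoci)
  two_n <- 2L * ne
  for (g in seq_len(generations)) {
    x <- rbinom(nLoci, two_n, x / two_n)
    x <- x + rbinom(nLoci, two_n - x, mu)
  }
  x
}

## A one-chromosome map with a single locus (single-locus experiments).
singleLocusMap <- function() {
  genomeMap(1L, 0.5, nChrom = 1L, chromLengthMorgans = 1,
            chromLengthBp = 6.75e8)
}

## Architecture with one fitness locus (s, h) and no QTL.
singleLocusArch <- function(s, h) {
  new("TraitArchitecture", qtlLoci = integer(), qtlEffects = numeric(),
      fitnessLoci = 1L, selCoeffs = s, dominance = h)
}

## Population of n individuals at one locus with allele frequency p0.
singleLocusPop <- function(n, p0, arch, map = singleLocusMap()) {
  hapA <- matrix(rbinom(n, 1L, p0), nrow = 1L)
  hapB <- matrix(rbinom(n, 1L, p0), nrow = 1L)
  newPopulation(hapA, hapB, arch, map = map,
                sire = rep(0L, n), dam = rep(0L, n), startId = 1L,
                generation = 0L, phase = "founder")
}

## Small random population over an explicit map/architecture.
randomPopulation <- function(n, map, arch, freq = 0.3) {
  L <- nLoci(map)
  hapA <- matrix(rbinom(L * n, 1L, freq), nrow = L)
  hapB <- matrix(rbinom(L * n, 1L, freq), nrow = L)
  newPopulation(hapA, hapB, arch, map = map,
                sire = rep(0L, n), dam = rep(0L, n), startId = 1L,
                generation = 0L, phase = "founder")
}

## Random architecture over the first loci of a map.
randomArch <- function(map, nQtl, nFit, h, sMax = 0.5) {
  new("TraitArchitecture",
      qtlLoci = seq_len(nQtl),
      qtlEffects = rnorm(nQtl),
      fitnessLoci = seq.int(nQtl + 1L, nQtl + nFit),
      selCoeffs = runif(nFit, 0, sMax),
      dominance = h)
}

## A tiny end-to-end configuration for fast integration tests.
tinyConfig <- function(...) {
  deskPreset(
    nHaplotypes = 80L,
    nQtlPerChrom = 5L,
    nFitnessPerChrom = 5L,
    nNeutral = 200L,
    maxFounderFreq = 0.2,  # tiny panels cannot meet the 0.01 ceiling
    demography = demography(40),
    plan = phasePlan(burnInGens1 = 2L, burnInMatings1 = 40L,
                     burnInGens2 = 2L, burnInMatings2 = 25L,
                     historicalGens = 4L, futureGens = 4L,
                     nSires = 5L, targetPop = 200L,
                     founderPopSize = 40L),
    ...)
}
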