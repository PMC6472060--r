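## A cohort with hand-set dosages at a handful of panel loci.
dosagePop <- function(dosages, map = NULL) {
  ## dosages: loci x individuals matrix of 0/1/2
  L <- nrow(dosages); n <- ncol(dosages)
  if (is.null(map)) {
    set.seed(77)
    map <- randomGenomeMap(L)
  }
  hapA <- matrix(as.integer(dosages >= 1L), L, n)
  hapB <- matrix(as.integer(dosages == 2L), L, n)
  arch <- new("TraitArchitecture", qtlLoci = integer(),
              qtlEffects = numeric(), fitnessLoci = seq_len(L),
              selCoeffs = rep(0.1, L), dominance = 0.5)
  newPopulation(hapA, hapB, arch, map = map, sire = rep(0L, n),
                dam = rep(0L, n), startId = 1L, generation = 0L,
                phase = "future")
}

panelOf <- function(loci, isTrue = rep(TRUE, length(loci)), d = 0.75,
                    order = NULL) {
  new("DiscoveryPanel", loci = as.integer(loci), isTrue = isTrue,
      discoveryRate = d,
      randomOrder = as.integer(if (is.null(order)) sample(loci) else order))
}

test_that("discovery panels mix true and false loci by the discovery rate", {
  set.seed(41)
  p <- buildDiscoveryPanel(1:1000, 2001:4000, d = 0.75)
  expect_length(p@loci, 1000L)
  expect_equal(sum(p@isTrue), 750L)
  expect_equal(sum(!p@isTrue), 250L)
  expect_true(all(p@loci[p@isTrue] <= 1000))
  expect_true(all(p@loci[!p@isTrue] >= 2001))

  p1 <- buildDiscoveryPanel(1:100, 201:400, d = 1)
  expect_equal(sum(!p1@isTrue), 0L)

  ## round-half-up split: d = 0.5, S = 7 -> 4 true + 3 false
  p7 <- buildDiscoveryPanel(1:7, 101:200, d = 0.5)
  expect_equal(sum(p7@isTrue), 4L)
  expect_equal(sum(!p7@isTrue), 3L)

  expect_error(buildDiscoveryPanel(1:100, 1:10, d = 0.1), "neutral")
})

test_that("prioritization orders panel loci per strategy", {
  ## 3 loci, 10 individuals: freqs 0.4, 0.1, 0.2
  D <- rbind(c(2, 2, 2, 2, 0, 0, 0, 0, 0, 0),
             c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
             c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  pop <- dosagePop(D)
  pan <- panelOf(1:3, order = c(2L, 3L, 1L))
  expect_equal(prioritize(pan, pop, editPolicy("high_freq")), c(1L, 3L, 2L))
  expect_equal(prioritize(pan, pop, editPolicy("low_freq")), c(2L, 3L, 1L))
  ## intermediate: locus 1 (freq 0.4) excluded at the 0.25 threshold
  expect_equal(prioritize(pan, pop, editPolicy("intermediate_freq")),
               c(3L, 2L))
  ## random: the panel's frozen permutation, restricted to segregating loci
  expect_equal(prioritize(pan, pop, editPolicy("random")), c(2L, 3L, 1L))
  expect_equal(prioritize(pan, pop, editPolicy("random")), c(2L, 3L, 1L))

  ## fixed locus is absent from every strategy's list
  Dfix <- rbind(D, rep(2, 10))
  popFix <- dosagePop(Dfix)
  panFix <- panelOf(1:4, order = c(4L, 2L, 3L, 1L))
  for (st in c("high_freq", "low_freq", "homozygote_deficit",
               "intermediate_freq", "random"))
    expect_false(4L %in% prioritize(panFix, popFix, editPolicy(st)))
})

test_that("homozygote-deficit scores are expected minus observed", {
  ## locus 1: p = 0.2, N = 100, all carriers heterozygous -> score p^2 N = 4
  ## locus 2: p = 0.2 with 20 homozygotes -> score 4 - 20 < 0
  D <- rbind(c(rep(1, 40), rep(0, 60)),
             c(rep(2, 20), rep(0, 80)))
  pop <- dosagePop(D)
  pan <- panelOf(1:2)
  expect_equal(prioritize(pan, pop, editPolicy("homozygote_deficit")),
               c(1L, 2L))
})

test_that("editing walks the priority list and stops after k edits", {
  set.seed(42)
  map <- randomGenomeMap(10)
  arch <- new("TraitArchitecture", qtlLoci = integer(),
              qtlEffects = numeric(), fitnessLoci = 1:10,
              selCoeffs = seq(0.05, 0.5, length.out = 10), dominance = 0.5)
  ## sire heterozygous at loci 3 and 7, wild type elsewhere
  hapA <- matrix(0L, 10, 1); hapA[c(3, 7), 1] <- 1L
  sire <- newPopulation(hapA, matrix(0L, 10, 1), arch, map = map,
                        sire = 0L, dam = 0L, startId = 1L,
                        generation = 0L, phase = "future")
  pan <- panelOf(1:10)
  ordered <- 1:10
  ed <- editSires(sire, ordered, k = 1, arch, pan)
  expect_equal(nrow(ed$log), 1L)
  expect_equal(ed$log$locus, 3L)
  expect_equal(ed$log$preDosage, 1L)
  expect_equal(sum(ed$sires@hapA), 1L)  # locus 7 untouched

  ## wild-type sire: no edits
  wt <- newPopulation(matrix(0L, 10, 1), matrix(0L, 10, 1), arch,
                      map = map, sire = 0L, dam = 0L, startId = 1L,
                      generation = 0L, phase = "future")
  edWt <- editSires(wt, ordered, k = 20, arch, pan)
  expect_equal(nrow(edWt$log), 0L)
  expect_identical(edWt$sires@hapA, wt@hapA)

  ed2 <- editSires(sire, ordered, k = 20, arch, pan)
  expect_equal(ed2$log$locus, c(3L, 7L))
  expect_true(all(ed2$sires@hapA == 0L))
  ## fitness non-decreasing, and exact after removing the two factors
  expect_gte(ed2$sires@w, sire@w)
  expect_equal(ed2$sires@w, 1)
})

test_that("editing preserves breeding values and reduces load exactly", {
  set.seed(43)
  map <- randomGenomeMap(40)
  arch <- new("TraitArchitecture", qtlLoci = 1:10, qtlEffects = rnorm(10),
              fitnessLoci = 11:40, selCoeffs = runif(30, 0, 0.5),
              dominance = 0)
  pop <- randomPopulation(8, map, arch, freq = 0.4)
  pan <- panelOf(11:40)
  preLoad <- carrierLoad(pop, pan, "total")
  preBV <- pop@bv
  ordered <- prioritize(pan, pop, editPolicy("high_freq"))
  preDos <- dosageAt(pop, ordered)
  ed <- editSires(pop, ordered, k = 5, arch, pan)
  postLoad <- carrierLoad(ed$sires, pan, "total")
  expect_equal(ed$sires@bv, preBV)        # QTL untouched
  expect_true(all(ed$sires@w >= pop@w))   # only deleterious alleles removed
  for (j in seq_len(8)) {
    lg <- ed$log[ed$log$sireId == pop@id[j], ]
    expect_equal(preLoad[j] - postLoad[j], sum(lg$preDosage))
    expect_lte(nrow(lg), 5L)
  }
  ## edited sires are wild-type homozygous at their edited loci
  for (r in seq_len(nrow(ed$log))) {
    j <- match(ed$log$sireId[r], ed$sires@id)
    expect_equal(ed$sires@hapA[ed$log$locus[r], j], 0L)
    expect_equal(ed$sires@hapB[ed$log$locus[r], j], 0L)
  }
})

test_that("editing a false-positive locus leaves fitness unchanged", {
  set.seed(44)
  map <- randomGenomeMap(5)
  arch <- new("TraitArchitecture", qtlLoci = integer(),
              qtlEffects = numeric(), fitnessLoci = 1:2,
              selCoeffs = c(0.3, 0.3), dominance = 0.5)
  hapA <- matrix(0L, 5, 1); hapA[4, 1] <- 1L  # derived at neutral locus 4
  sire <- newPopulation(hapA, matrix(0L, 5, 1), arch, map = map,
                        sire = 0L, dam = 0L, startId = 1L,
                        generation = 0L, phase = "future")
  pan <- panelOf(c(1L, 4L), isTrue = c(TRUE, FALSE))
  ed <- editSires(sire, c(4L, 1L), k = 1, arch, pan)
  expect_equal(ed$log$locus, 4L)
  expect_false(ed$log$isTrue)
  expect_true(is.na(ed$log$s))
  expect_equal(ed$sires@w, sire@w)
})

test_that("editing mortality replaces dead sires from the ranked pool", {
  set.seed(45)
  map <- randomGenomeMap(5)
  arch <- new("TraitArchitecture", qtlLoci = 1L, qtlEffects = 1,
              fitnessLoci = 2L, selCoeffs = 0.1, dominance = 0)
  sires <- randomPopulation(25, map, arch)
  pool <- randomPopulation(200, map, arch)
  pool@id <- pool@id + 1000L

  m0 <- applyEditingMortality(sires, pool, m = 0)
  expect_identical(m0$sires@id, sires@id)
  expect_equal(m0$nReplaced, 0L)

  m1 <- applyEditingMortality(sires, pool, m = 1)
  expect_equal(nInd(m1$sires), 25L)
  expect_true(all(m1$sires@id > 1000L))
  ## replacements are the top-bv pool candidates
  expect_setequal(m1$sires@bv, sort(pool@bv, decreasing = TRUE)[1:25])

  reps <- replicate(200, applyEditingMortality(sires, pool, 0.5)$nReplaced)
  expect_lt(abs(mean(reps) - 12.5), 4 * sqrt(25 * 0.25 / 200))

  tiny <- pool[1:3]
  expect_error(applyEditingMortality(sires, tiny, m = 1), "exhausted")
})

test_that("carrier load counts alleles by zygosity and sums exactly", {
  ## het at 2 panel loci + derived-hom at 1 -> total 4, het 2, hom 2
  D <- matrix(c(1, 1, 2, 0), ncol = 1)
  pop <- dosagePop(D)
  pan <- panelOf(1:4)
  expect_equal(carrierLoad(pop, pan, "total"), 4)
  expect_equal(carrierLoad(pop, pan, "het"), 2)
  expect_equal(carrierLoad(pop, pan, "hom"), 2)
  wt <- dosagePop(matrix(0, 4, 1))
  for (m in c("total", "het", "hom"))
    expect_equal(carrierLoad(wt, pan, m), 0)

  set.seed(46)
  Dr <- matrix(sample(0:2, 30 * 20, replace = TRUE), 30, 20)
  popR <- dosagePop(Dr)
  panR <- panelOf(1:30)
  tot <- carrierLoad(popR, panR, "total")
  het <- carrierLoad(popR, panR, "het")
  hom <- carrierLoad(popR, panR, "hom")
  expect_equal(tot, het + hom)  # identity for every individual
  for (j in 1:20) {
    o <- oracleLoads(Dr[, j])
    expect_equal(tot[j], o$total)
    expect_equal(het[j], o$het)
    expect_equal(hom[j], o$hom)
  }
})

test_that("carrier avoidance removes exactly the highest-load males", {
  set.seed(47)
  map <- randomGenomeMap(20)
  arch <- new("TraitArchitecture", qtlLoci = integer(),
              qtlEffects = numeric(), fitnessLoci = 1:20,
              selCoeffs = rep(0.05, 20), dominance = 0)
  males <- randomPopulation(200, map, arch, freq = 0.3)
  pan <- panelOf(1:20)
  pol <- carrierPolicy("total", 50L)
  kept <- avoidCarriers(males, pan, pol)
  expect_equal(nInd(kept), 150L)
  loads <- carrierLoad(males, pan, "total")
  expect_lte(max(carrierLoad(kept, pan, "total")),
             sort(loads, decreasing = TRUE)[50])

  expect_identical(avoidCarriers(males, pan, carrierPolicy("total", 0L)),
                   males)
  expect_error(avoidCarriers(males, pan, carrierPolicy("total", 200L)),
               "cannot avoid")

  ## tie at the cutoff: the higher-id male is removed first
  D2 <- matrix(0L, 1, 4); D2[1, ] <- c(2L, 1L, 1L, 0L)
  tied <- dosagePop(D2)
  tied@sex <- rep("M", 4)
  keptT <- avoidCarriers(tied, panelOf(1L), carrierPolicy("total", 2L))
  expect_setequal(keptT@id, c(2L, 4L))  # ids 1 (load 2) and 3 (tied het) go
})
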