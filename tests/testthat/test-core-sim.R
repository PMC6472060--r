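test_that("viability selection is Bernoulli(w) per individual", {
  arch <- singleLocusArch(0, 0)
  set.seed(31)
  pop <- singleLocusPop(200, 0.5, arch)
  expect_equal(nInd(viabilitySelect(pop)), 200L)  # all w = 1
  pop0 <- pop; pop0@w[] <- 0
  expect_equal(nInd(viabilitySelect(pop0)), 0L)
  pop8 <- pop; pop8@w[] <- 0.8
  big <- do.call(cbind, rep(list(pop8@hapA), 50))
  popBig <- pop8
  popBig@hapA <- big; popBig@hapB <- big
  popBig@id <- seq_len(10000L); popBig@sire <- rep(0L, 10000L)
  popBig@dam <- rep(0L, 10000L); popBig@sex <- rep("F", 10000L)
  popBig@bv <- numeric(10000L); popBig@w <- rep(0.8, 10000L)
  surv <- nInd(viabilitySelect(popBig))
  expect_lt(abs(surv - 8000), 4 * sqrt(10000 * 0.16))
})

test_that("parent selection is truncation on bv with id tie-breaking", {
  arch <- singleLocusArch(0, 0)
  set.seed(32)
  pop <- singleLocusPop(6, 0.5, arch)
  pop@sex <- c("M", "M", "M", "F", "F", "F")
  pop@bv <- c(1, 5, 2, 3, 7, 7)
  ps <- selectParents(pop, nSires = 2, nDams = 2)
  expect_equal(ps$sires@bv, c(5, 2))
  ## dams tied at bv 7: lower id first
  expect_equal(ps$dams@id, c(5L, 6L))
  pop@bv[1:3] <- c(4, 4, 4)
  ps2 <- selectParents(pop, 2, 1)
  expect_equal(ps2$sires@id, c(1L, 2L))  # ties by ascending id
  expect_error(selectParents(pop, 4, 1), "shortfall")
})

test_that("dam numbers follow the frozen-fitness ceiling rule", {
  expect_equal(computeNDams(1, 5000, 10), 500L)
  expect_equal(computeNDams(0.8, 5000, 10), 625L)
  expect_equal(computeNDams(0.3, 5000, 10), 1667L)
  expect_error(computeNDams(0, 5000, 10), "> 0")
})

test_that("meiosis copies identical haplotypes verbatim", {
  set.seed(33)
  map <- randomGenomeMap(100)
  arch <- new("TraitArchitecture", qtlLoci = integer(),
              qtlEffects = numeric(), fitnessLoci = 1L, selCoeffs = 0,
              dominance = 0)
  h <- matrix(rbinom(100, 1, 0.5), ncol = 1)
  pop <- newPopulation(h, h, arch, map = map, sire = 0L, dam = 0L,
                       startId = 1L, generation = 0L, phase = "founder")
  g <- makeGametes(pop, rep(1L, 20))
  expect_true(all(g == as.vector(h)))
})

test_that("crossover counts match the one-Morgan Poisson expectation", {
  ## heterozygous parent (all-0 vs all-1 strands): strand switches along a
  ## gamete count the crossovers realised between consecutive loci
  set.seed(34)
  nl <- 200L
  map <- genomeMap(rep(1L, nl), sort(runif(nl)), nChrom = 1L,
                   chromLengthMorgans = 1)
  arch <- singleLocusArch(0, 0)
  arch@fitnessLoci <- 1L
  pop <- newPopulation(matrix(0L, nl, 1), matrix(1L, nl, 1), arch,
                       map = map, sire = 0L, dam = 0L, startId = 1L,
                       generation = 0L, phase = "founder")
  g <- makeGametes(pop, rep(1L, 20000))
  switches <- colSums(g[-1L, ] != g[-nl, ])
  expect_lt(abs(mean(switches) - 1.0), 0.03)
  ## loci at zero map distance never recombine
  map0 <- genomeMap(c(1L, 1L), c(0.3, 0.3), nChrom = 1L)
  pop0 <- newPopulation(matrix(0L, 2, 1), matrix(1L, 2, 1), arch,
                        map = map0, sire = 0L, dam = 0L, startId = 1L,
                        generation = 0L, phase = "founder")
  g0 <- makeGametes(pop0, rep(1L, 5000))
  expect_true(all(g0[1L, ] == g0[2L, ]))
})

test_that("mutation flips only wild-type copies at fitness loci", {
  set.seed(35)
  L <- 50L; n <- 200L
  hapA <- matrix(0L, L, n); hapB <- matrix(0L, L, n)
  ## rate 0: unchanged
  m0 <- mutateGenotypes(hapA, hapB, seq_len(L), 0)
  expect_identical(m0$hapA, hapA)
  expect_equal(m0$nMutations, 0L)
  ## homozygous-mutant loci never change
  hapA1 <- matrix(1L, L, n); hapB1 <- matrix(1L, L, n)
  m1 <- mutateGenotypes(hapA1, hapB1, seq_len(L), 0.5)
  expect_identical(m1$hapA, hapA1)
  expect_identical(m1$hapB, hapB1)
  expect_equal(m1$nMutations, 0L)
  ## expected de-novo count n * L * rate
  m2 <- mutateGenotypes(hapA, hapB, seq_len(L), 0.01)
  expect_lt(abs(m2$nMutations - 100), 4 * sqrt(100))
  expect_equal(sum(m2$hapA) + sum(m2$hapB), m2$nMutations)
  ## QTL (loci outside fitnessLoci) never mutate
  m3 <- mutateGenotypes(hapA, hapB, 1:10, 0.2)
  expect_true(all(m3$hapA[11:50, ] == 0L))
})

test_that("burn-in generations produce matings x progeny offspring", {
  cfg <- tinyConfig()
  set.seed(36)
  pan <- simulateFounders(80, 300, demography(40), seed = 12, burnFactor = 4)
  arch <- makeArchitecture(pan, 5, 5, 0.5, 0.3)
  pop <- foundersToPopulation(pan, arch, 40)
  step <- advanceGeneration(pop, cfg@plan, arch, "burn_in", nMatings = 30)
  expect_equal(nInd(step$offspring), 300L)  # 30 matings x 10 progeny
  expect_equal(step$offspring@generation, 1L)
  ## pedigree ids refer to parents
  expect_true(all(step$offspring@sire %in% step$survivors@id))
  expect_true(all(step$offspring@dam %in% step$survivors@id))
})

test_that("truncation selection raises mean breeding value over generations", {
  set.seed(37)
  pan <- simulateFounders(120, 400, demography(60), seed = 14, burnFactor = 4)
  arch <- makeArchitecture(pan, 10, 5, 0.5, 0.3)
  arch@selCoeffs[] <- 0  # neutral fitness: isolate artificial selection
  plan <- phasePlan(nSires = 5L, targetPop = 300L, founderPopSize = 200L)
  pop <- foundersToPopulation(pan, arch, 200)
  mbv <- meanBV(pop)
  for (i in 1:4) {
    step <- advanceGeneration(pop, plan, arch, "historical", nDams = 30)
    pop <- step$offspring
  }
  expect_gt(meanBV(pop), mbv)
})

test_that("population snapshots export and re-import as a panel", {
  set.seed(39)
  map <- randomGenomeMap(25)
  arch <- new("TraitArchitecture", qtlLoci = 1:5, qtlEffects = rnorm(5),
              fitnessLoci = 6:15, selCoeffs = runif(10, 0, 0.3),
              dominance = 0.5)
  pop <- randomPopulation(12, map, arch, freq = 0.4)
  prefix <- tempfile()
  files <- exportPopulation(pop, prefix)
  ind <- read.csv(files["individuals"])
  expect_equal(nrow(ind), 12L)
  expect_equal(ind$w, pop@w)
  pan <- suppressWarnings(importHaplotypes(files["haplotypes"], "matrix-tsv"))
  ## haplotype rows pair back into the same dosage matrix (segregating loci)
  seg <- which(alleleFreqs(pop) > 0 & alleleFreqs(pop) < 1)
  D1 <- dosageAt(pop, seg)
  D2 <- t(pan@alleles[seq(1, 23, 2), ] + pan@alleles[seq(2, 24, 2), ])
  expect_identical(unname(D2), unname(D1))
})

test_that("replicates are deterministic and scenario-paired", {
  cfg <- tinyConfig(nReplicates = 2, masterSeed = 99)
  r1 <- runReplicate(cfg, 1)
  r2 <- runReplicate(cfg, 1)
  expect_identical(resultRecords(r1), resultRecords(r2))
  ## generation counter: 4 + 4 + 4 historical/burn-in/future of the tiny plan
  expect_equal(max(resultRecords(r1)$generation), 12L)
  ## an intervention scenario shares the pre-future records
  cfgE <- tinyConfig(nReplicates = 2, masterSeed = 99,
                     intervention = editPolicy("random", 2),
                     discoveryRate = 0.75)
  rE <- runReplicate(cfgE, 1)
  pre <- resultRecords(r1)$phase != "future"
  expect_identical(resultRecords(rE)[pre, ], resultRecords(r1)[pre, ])
  ## a different replicate differs
  r3 <- runReplicate(cfg, 2)
  expect_false(identical(resultRecords(r3), resultRecords(r1)))
})

test_that("single-locus viability selection follows the exact recursion", {
  ## deterministic check at moderate size; the full-scale check lives in
  ## the acceptance suite
  s <- 0.3; h <- 0.5
  arch <- singleLocusArch(s, h)
  plan <- phasePlan(progenyPerMating = 1L, mutationRate = 0,
                    founderPopSize = 2000L)
  set.seed(38)
  pop <- singleLocusPop(20000, 0.3, arch)
  p0 <- unname(alleleFreqs(pop))
  traj <- oracleTrajectory(p0, s, h, 5, perGenVarFactor = 2 / (2 * 20000))
  for (t in 1:5) {
    step <- advanceGeneration(pop, plan, arch, "burn_in", nMatings = 20000)
    pop <- step$offspring
    expect_lt(abs(unname(alleleFreqs(pop)) - traj$p[t]), 4 * traj$sd[t])
  }
})
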