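## Construct a synthetic SimulationResult with a prescribed future-phase
## fitness/bv trajectory.
fakeResult <- function(wFuture, bvFuture, seed = 1L, scenario = "x",
                       editLoci = integer()) {
  n <- length(wFuture)
  rec <- data.frame(
    generation = seq_len(n + 2L), phase = c("historical", "historical",
                                            rep("future", n)),
    futureGen = c(NA, NA, seq_len(n)),
    meanFitness = c(1, 1, wFuture), meanBV = c(0, 0, bvFuture),
    cohortSize = 100L, segregatingDeleterious = 10L,
    meanTotalLoad = 1, meanHetLoad = 1, meanHomLoad = 0)
  el <- data.frame(generation = rep(3L, length(editLoci)),
                   sireId = seq_along(editLoci),
                   locus = as.integer(editLoci),
                   isTrue = rep(TRUE, length(editLoci)),
                   s = rep(0.1, length(editLoci)),
                   preDosage = rep(1L, length(editLoci)))
  new("SimulationResult", records = rec, editLog = el,
      distinctEdited = sort(unique(as.integer(editLoci))),
      scenario = scenario, replicate = 1L, seed = as.integer(seed),
      config = list())
}

test_that("cohort means match hand-computed values", {
  arch <- singleLocusArch(0.5, 0.5)
  set.seed(51)
  pop <- singleLocusPop(2, 0.5, arch)
  pop@w <- c(0.5, 1.0)
  expect_equal(meanFitness(pop), 0.75)
  pop@w <- c(1, 1)
  expect_equal(meanFitness(pop), 1)
  expect_error(meanFitness(pop[integer()]), "empty")
  pop@bv <- c(1, 3)
  expect_equal(meanBV(pop), 2)
})

test_that("load summary decomposes into het and hom components", {
  set.seed(52)
  map <- randomGenomeMap(30)
  arch <- new("TraitArchitecture", qtlLoci = integer(),
              qtlEffects = numeric(), fitnessLoci = 1:30,
              selCoeffs = rep(0.01, 30), dominance = 0)
  ## monomorphic wild type
  wt <- newPopulation(matrix(0L, 30, 5), matrix(0L, 30, 5), arch, map = map,
                      sire = rep(0L, 5), dam = rep(0L, 5), startId = 1L,
                      generation = 0L, phase = "founder")
  ls0 <- loadSummary(wt, 1:30)
  expect_equal(unlist(ls0), c(total = 0, het = 0, hom = 0, segregating = 0))

  ## single individual het at 3 loci
  hapA <- matrix(0L, 30, 1); hapA[1:3, 1] <- 1L
  one <- newPopulation(hapA, matrix(0L, 30, 1), arch, map = map, sire = 0L,
                       dam = 0L, startId = 1L, generation = 0L,
                       phase = "founder")
  ls1 <- loadSummary(one, 1:30)
  expect_equal(ls1$total, 3); expect_equal(ls1$het, 3)
  expect_equal(ls1$hom, 0)

  ## random cohort against the per-individual loop oracle
  pop <- randomPopulation(15, map, arch, freq = 0.4)
  ls <- loadSummary(pop, 1:30)
  D <- dosageAt(pop, 1:30)
  o <- sapply(seq_len(15), function(j) unlist(oracleLoads(D[, j])))
  expect_equal(ls$total, mean(o["total", ]))
  expect_equal(ls$het, mean(o["het", ]))
  expect_equal(ls$hom, mean(o["hom", ]))
  expect_equal(ls$total, ls$het + ls$hom)
})

test_that("fitness change versus baseline is a paired contrast", {
  b <- list(fakeResult(seq(1, 0.98, length.out = 10), 1:10, seed = 1),
            fakeResult(seq(1, 0.96, length.out = 10), 1:10, seed = 2))
  ## scenario identical to baseline: zero with zero SEM
  same <- fitnessChangeVsBaseline(b, b)
  expect_equal(same$mean, 0)
  expect_equal(same$sem, 0)

  ## scenario deltas 0.05, baseline deltas 0.02 -> +0.03
  s2 <- list(fakeResult(c(1, rep(1.02, 8), 1.05), 1:10, seed = 1),
             fakeResult(c(1, rep(1.01, 8), 1.05), 1:10, seed = 2))
  b2 <- list(fakeResult(c(1, rep(0.99, 8), 1.02), 1:10, seed = 1),
             fakeResult(c(1, rep(1.03, 8), 1.02), 1:10, seed = 2))
  fc <- fitnessChangeVsBaseline(s2, b2)
  expect_equal(fc$mean, 0.03)
  expect_equal(fc$deltas, c(0.03, 0.03))
  ## SEM equals sd/sqrt(n) of the replicate deltas
  s3 <- list(fakeResult(c(1, rep(1, 8), 1.06), 1:10, seed = 1),
             fakeResult(c(1, rep(1, 8), 1.02), 1:10, seed = 2))
  fc3 <- fitnessChangeVsBaseline(s3, b2)
  expect_equal(fc3$sem, sd(fc3$deltas) / sqrt(2))

  ## mismatched seeds are rejected
  bBad <- list(fakeResult(1:10 / 10, 1:10, seed = 9),
               fakeResult(1:10 / 10, 1:10, seed = 2))
  expect_error(fitnessChangeVsBaseline(s2, bBad), "seed-paired")
})

test_that("relative gain change is the fractional change in bv gain", {
  b <- list(fakeResult(rep(1, 10), seq(0, 9, 1), seed = 1),
            fakeResult(rep(1, 10), seq(0, 9, 1), seed = 2))
  sSame <- fitnessChangeVsBaseline(b, b)  # sanity: shared helper path
  expect_equal(sSame$mean, 0)
  rg0 <- relativeGainChange(b, b)
  expect_equal(rg0$mean, 0)
  ## G_s = 1.04 G_b -> +0.04
  s <- list(fakeResult(rep(1, 10), seq(0, 9.36, length.out = 10), seed = 1),
            fakeResult(rep(1, 10), seq(0, 9.36, length.out = 10), seed = 2))
  rg <- relativeGainChange(s, b)
  expect_equal(rg$mean, 0.04)
  bZero <- list(fakeResult(rep(1, 10), rep(5, 10), seed = 1),
                fakeResult(rep(1, 10), rep(5, 10), seed = 2))
  expect_error(relativeGainChange(s, bZero), "zero")
})

test_that("distinct edit counts use set semantics", {
  ## the same locus edited in 5 sires across generations counts once
  r <- fakeResult(rep(1, 10), 1:10, editLoci = rep(42L, 5))
  expect_equal(countDistinctEdits(r), 1L)
  r0 <- fakeResult(rep(1, 10), 1:10)
  expect_equal(countDistinctEdits(r0), 0L)
  r2 <- fakeResult(rep(1, 10), 1:10, editLoci = c(1L, 2L, 2L, 7L))
  expect_equal(countDistinctEdits(r2), 3L)
  ## matches a recount from the edit log
  expect_equal(countDistinctEdits(r2), length(unique(editLog(r2)$locus)))
})
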