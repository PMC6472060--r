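test_that("genome map validity enforces coordinates and sorting", {
  gm <- genomeMap(c(1L, 1L, 2L), c(0.1, 0.5, 0.2))
  expect_s4_class(gm, "GenomeMap")
  expect_equal(nLoci(gm), 3L)
  expect_error(genomeMap(c(1L, 1L), c(0.5, 0.1)), "sorted")
  expect_error(genomeMap(1L, 1.2), "outside")
  expect_error(genomeMap(3L, 0.1, nChrom = 2L), "out of range")
})

test_that("simulated founder panels meet the segregation contract", {
  pan <- simulateFounders(nHaplotypes = 200, targetLoci = 500,
                          demography = demography(100), seed = 11,
                          burnFactor = 5)
  expect_equal(nLoci(pan), 500L)
  expect_equal(nrow(pan@alleles), 200L)
  expect_true(all(pan@freqs > 0 & pan@freqs < 1))
  ## loci sorted along the map
  o <- order(pan@map@locusChrom, pan@map@locusPos)
  expect_identical(o, seq_along(o))
})

test_that("founder simulation is bitwise reproducible under a seed", {
  p1 <- simulateFounders(100, 200, demography(50), seed = 3, burnFactor = 4)
  p2 <- simulateFounders(100, 200, demography(50), seed = 3, burnFactor = 4)
  expect_identical(p1@alleles, p2@alleles)
  expect_identical(p1@map@locusPos, p2@map@locusPos)
  p3 <- simulateFounders(100, 200, demography(50), seed = 4, burnFactor = 4)
  expect_false(identical(p1@alleles, p3@alleles))
})

test_that("shortfall of segregating loci is an explicit error", {
  expect_error(
    simulateFounders(40, 500, demography(20), seed = 1, burnFactor = 2,
                     oversample = 1.05, muPerLocus = 1e-6),
    "segregating loci")
})

test_that("constant-Ne site frequency spectrum matches the neutral 1/i law", {
  ## Package panel: sample the whole population (n = 2 Ne = 200).
  ne <- 100L
  pan <- simulateFounders(nHaplotypes = 2L * ne, targetLoci = 2500,
                          demography = demography(ne), seed = 91)
  counts <- round(alleleFreqs(pan) * 2 * ne)
  n <- 2L * ne
  fracSingleton <- mean(counts == 1L)
  theory <- 1 / sum(1 / seq_len(n - 1L))

  ## Independent oracle: vectorized single-locus Wright-Fisher chains with
  ## the same marginal law (binomial resampling + one-way mutation).
  set.seed(4712)
  x <- oracleWrightFisherSFS(nLoci = 12000, ne = ne, mu = 2.5e-4,
                             generations = 10L * ne)
  xSeg <- x[x > 0 & x < n]
  oracleFrac <- mean(xSeg == 1L)

  se <- sqrt(theory * (1 - theory)) *
    sqrt(1 / length(counts) + 1 / length(xSeg))
  expect_lt(abs(fracSingleton - oracleFrac), 4 * se)
  expect_lt(abs(fracSingleton - theory), 0.035)

  ## Binned goodness of fit against the 1/i expectation (alpha = 0.01).
  ## The panel descends from only 2 Ne founders, so locus counts share one
  ## genealogy and are overdispersed relative to a multinomial; the GOF is
  ## computed on a locus subsample, where multinomial noise dominates.
  breaks <- c(0.5, 1.5, 2.5, 4.5, 8.5, 16.5, 40.5, n - 0.5)
  cumInv <- function(b) {
    k <- min(floor(b), n - 1L)
    if (k < 1) 0 else sum(1 / seq_len(k))
  }
  pExp <- diff(vapply(breaks, cumInv, 1)) / sum(1 / seq_len(n - 1L))
  set.seed(17)
  obs <- table(cut(sample(counts, 600), breaks))
  gof <- suppressWarnings(
    chisq.test(as.vector(obs), p = pExp, rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
})

test_that("haplotype matrix TSV round-trips and drops monomorphic columns", {
  set.seed(5)
  map <- randomGenomeMap(20)
  alleles <- matrix(rbinom(10 * 20, 1, 0.4), nrow = 10)
  alleles[, 3] <- c(rep(1L, 5), rep(0L, 5))  # keep segregating
  pan <- haplotypePanel(alleles, map)
  f <- tempfile(fileext = ".tsv")
  exportHaplotypes(pan, f)
  pan2 <- importHaplotypes(f, "matrix-tsv")
  expect_identical(unname(pan2@alleles), unname(pan@alleles))
  expect_equal(pan2@map@locusPos, pan@map@locusPos, tolerance = 1e-10)

  ## a monomorphic column is dropped with a warning naming the count
  alleles2 <- cbind(alleles, mono = 1L)
  df <- data.table::as.data.table(alleles2)
  names(df) <- c(locusIds(map), "c9:0.99")
  f2 <- tempfile(fileext = ".tsv")
  data.table::fwrite(df, f2, sep = "\t")
  expect_warning(pan3 <- importHaplotypes(f2, "matrix-tsv"),
                 "1 monomorphic")
  expect_equal(nLoci(pan3), 20L)
})

test_that("VCF import handles phase, and rejects bad records", {
  skip_if_not_installed("vcfR")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("chr1", "1000", ".", "A", "T", ".", "PASS", ".", "GT",
          "0|1", "1|1", sep = "\t"),
    paste("chr1", "2000", ".", "G", "C", ".", "PASS", ".", "GT",
          "0|0", "0|1", sep = "\t"))
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  set.seed(1)
  pan <- importHaplotypes(f, "vcf")
  expect_equal(dim(pan@alleles), c(4L, 2L))
  expect_equal(unname(pan@alleles[, 1]), c(0L, 1L, 1L, 1L))

  vcfTri <- vcf
  vcfTri[4] <- paste("chr1", "1000", ".", "A", "T,G", ".", "PASS", ".",
                     "GT", "0|1", "1|1", sep = "\t")
  fTri <- tempfile(fileext = ".vcf")
  writeLines(vcfTri, fTri)
  expect_error(importHaplotypes(fTri, "vcf"), "chr1:1000")

  vcfMiss <- vcf
  vcfMiss[5] <- paste("chr1", "2000", ".", "G", "C", ".", "PASS", ".",
                      "GT", "./.", "0|1", sep = "\t")
  fMiss <- tempfile(fileext = ".vcf")
  writeLines(vcfMiss, fMiss)
  expect_error(importHaplotypes(fMiss, "vcf"), "missing genotypes")
})

test_that("imported and simulated panels are interchangeable downstream", {
  pan <- simulateFounders(60, 120, demography(30), seed = 8, burnFactor = 4)
  f <- tempfile(fileext = ".tsv")
  exportHaplotypes(pan, f)
  pan2 <- importHaplotypes(f, "matrix-tsv")
  set.seed(2)
  arch1 <- makeArchitecture(pan, 2, 2, 0, 0.5)
  set.seed(2)
  arch2 <- makeArchitecture(pan2, 2, 2, 0, 0.5)
  expect_identical(arch1@fitnessLoci, arch2@fitnessLoci)
  expect_identical(arch1@qtlEffects, arch2@qtlEffects)
})
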