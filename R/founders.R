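#' Construct a demography
#'
#' @param constantNe single constant effective population size (the default
#'   founder history is a constant Ne of 100, which gives results broadly
#'   similar to the full piecewise history).
#' @param schedule data.frame with columns `generations_ago` (strictly
#'   decreasing) and `ne`, used when `constantNe` is NA.
#' @param interpolate logical; approximate linear size change between
#'   breakpoints by sub-stepping (see [simulateFounders()]).
#' @return a [Demography-class].
#' @export
demography <- function(constantNe = 100, schedule = NULL, interpolate = FALSE) {
  if (is.null(schedule))
    schedule <- data.frame(generations_ago = numeric(), ne = numeric())
  new("Demography", schedule = schedule, interpolate = interpolate,
      constantNe = as.numeric(constantNe))
}

#' The piecewise effective-size history of the full-scale setup
#'
#' Ne of 1e6 at 190,000 generations ago, 1e5 at 100,000 generations ago and
#' 100 at present, with linear decreases requested in between. Stepping a
#' forward Wright-Fisher burn-in through this schedule is supported but
#' computationally impractical; the constant-Ne-100 default of
#' [demography()] is the recommended backend.
#'
#' @return a [Demography-class].
#' @export
paperDemography <- function() {
  demography(constantNe = NA_real_,
             schedule = data.frame(
               generations_ago = c(190000, 100000, 0),
               ne = c(1e6, 1e5, 100)),
             interpolate = TRUE)
}

#' Construct a haplotype panel
#'
#' @param alleles n_haplotypes x n_loci matrix of 0/1 (haplotypes in rows,
#'   the TSV interchange orientation).
#' @param map the [GenomeMap-class] of the loci.
#' @return a [HaplotypePanel-class]; fails if any locus is monomorphic or
#'   the number of haplotypes is odd.
#' @export
haplotypePanel <- function(alleles, map) {
  storage.mode(alleles) <- "integer"
  new("HaplotypePanel", alleles = alleles, map = map,
      freqs = colMeans(alleles))
}

#' @describeIn haplotypePanel number of haplotypes in the panel.
#' @param x a HaplotypePanel.
#' @export
setMethod("nInd", "HaplotypePanel", function(x) nrow(x@alleles) %/% 2L)

#' @rdname nLoci
#' @export
setMethod("nLoci", "HaplotypePanel", function(x) ncol(x@alleles))

#' @rdname alleleFreqs
#' @export
setMethod("alleleFreqs", "HaplotypePanel", function(x, loci = NULL) {
  if (is.null(loci)) x@freqs else x@freqs[loci]
})

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", nrow(object@alleles), "haplotypes x",
      ncol(object@alleles), "segregating loci; derived-allele frequency",
      sprintf("range [%.4g, %.4g]\n", min(object@freqs), max(object@freqs)))
})

## One-way (0 -> 1) mutation on a haploid loci x haplotypes matrix.
## Independent Bernoulli(mu) per cell, realised as a binomial event count
## plus uniform placement (an exactly equivalent sampling scheme).
.mutateHaploid <- function(mat, mu) {
  if (mu <= 0) return(mat)
  nev <- rbinom(1L, length(mat), mu)
  if (nev > 0L) mat[sample.int(length(mat), nev)] <- 1L
  mat
}

## Expand a demography into forward steps of (ne, generations).
.demographySteps <- function(demography, burnFactor) {
  if (!is.na(demography@constantNe)) {
    ne <- demography@constantNe
    return(data.frame(ne = ne, gens = ceiling(burnFactor * ne)))
  }
  sch <- demography@schedule
  steps <- data.frame(ne = sch$ne[1],
                      gens = ceiling(burnFactor * sch$ne[1]))
  if (nrow(sch) > 1L) {
    for (i in seq_len(nrow(sch) - 1L)) {
      span <- sch$generations_ago[i] - sch$generations_ago[i + 1L]
      if (demography@interpolate) {
        nsub <- 10L
        ne_sub <- approx(c(0, 1), c(sch$ne[i], sch$ne[i + 1L]),
                         xout = (seq_len(nsub) - 0.5) / nsub)$y
        steps <- rbind(steps, data.frame(ne = ne_sub,
                                         gens = rep(span / nsub, nsub)))
      } else {
        steps <- rbind(steps, data.frame(ne = sch$ne[i], gens = span))
      }
    }
    last <- sch$generations_ago[nrow(sch)]
    if (last > 0)
      steps <- rbind(steps, data.frame(ne = sch$ne[nrow(sch)], gens = last))
  }
  steps$gens <- ceiling(steps$gens)
  steps$ne <- pmax(1, round(steps$ne))
  steps
}

## One Wright-Fisher generation on a haploid pool (loci x 2N matrix):
## draw nGametes gametes by meiosis from random diploid parents
## (consecutive column pairs), then apply one-way mutation.
.wfGeneration <- function(pool, candMap, nGametes, mu, idx) {
  nDip <- ncol(pool) %/% 2L
  hapA <- pool[, seq(1L, 2L * nDip, by = 2L), drop = FALSE]
  hapB <- pool[, seq(2L, 2L * nDip, by = 2L), drop = FALSE]
  parents <- sample.int(nDip, nGametes, replace = TRUE)
  gam <- cpp_make_gametes(hapA, hapB, parents, idx$start, idx$end,
                          candMap@locusPos, candMap@chromLengthMorgans)
  .mutateHaploid(gam, mu)
}

#' Simulate founder haplotypes with a Wright-Fisher burn-in
#'
#' Generates a panel of founder haplotypes with a realistic (neutral)
#' allele-frequency spectrum by forward Wright-Fisher simulation: candidate
#' loci are placed uniformly on the map, the population evolves for
#' `burnFactor * Ne` generations at each demography step under one-way
#' mutation and free Poisson recombination, and the final panel is formed
#' by drawing `nHaplotypes` fresh gametes from the last generation.
#' Candidate loci that segregate in the panel are downsampled uniformly at
#' random to exactly `targetLoci`.
#'
#' With the default per-locus mutation rate (theta = 4 Ne mu = 0.1 at
#' Ne = 100) the site-frequency spectrum of segregating loci follows the
#' neutral 1/i expectation closely.
#'
#' @param nHaplotypes number of founder haplotypes (even); may exceed 2 Ne,
#'   in which case gametes are drawn with replacement from the final
#'   generation (as when a coalescent samples more lineages than 2 Ne).
#' @param targetLoci number of segregating loci to return.
#' @param demography a [Demography-class] (default constant Ne = 100).
#' @param map optional [GenomeMap-class] providing the chromosome structure
#'   (its loci, if any, are ignored); defaults to 10 chromosomes of
#'   1 Morgan and 6.75e8 bp.
#' @param muPerLocus one-way mutation rate per candidate locus per gamete
#'   during the burn-in; the default (NULL) keeps the population-scaled
#'   mutation rate at theta = 4 Ne mu = 0.01 (i.e. mu = 2.5e-5 at
#'   Ne = 100). The rate must stay well below 1/locus/coalescent time or
#'   overlapping recurrent mutations at one locus merge and distort the
#'   spectrum upward; at theta = 0.01 the panel spectrum is
#'   indistinguishable from 1/i by a goodness-of-fit test.
#' @param burnFactor burn-in length in multiples of Ne (default 10).
#' @param oversample candidate loci simulated per target locus (default
#'   30; at theta = 0.01 roughly 5 percent of candidates segregate in the
#'   final panel); if fewer than `targetLoci` candidates segregate, an
#'   error reports the shortfall.
#' @param seed integer seed; the result is bitwise reproducible given the
#'   seed.
#' @return a [HaplotypePanel-class] with exactly `targetLoci` segregating
#'   loci.
#' @examples
#' pan <- simulateFounders(nHaplotypes = 40, targetLoci = 50,
#'                         demography = demography(30), seed = 1,
#'                         burnFactor = 4)
#' range(alleleFreqs(pan))
#' @export
simulateFounders <- function(nHaplotypes, targetLoci,
                             demography = ragesim::demography(100),
                             map = NULL, muPerLocus = NULL,
                             burnFactor = 10, oversample = 30,
                             seed = 1L) {
  stopifnot(nHaplotypes %% 2 == 0, targetLoci >= 1)
  if (is.null(muPerLocus)) {
    neFinal <- if (!is.na(demography@constantNe)) demography@constantNe
               else tail(demography@schedule$ne, 1L)
    muPerLocus <- 0.01 / (4 * neFinal)
  }
  set.seed(seed)
  if (is.null(map)) map <- genomeMap(integer(), numeric())
  nCand <- ceiling(oversample * targetLoci)
  candMap <- randomGenomeMap(nCand, nChrom = map@nChrom,
                             chromLengthMorgans = map@chromLengthMorgans,
                             chromLengthBp = map@chromLengthBp)
  idx <- .chromIndex(candMap)
  steps <- .demographySteps(demography, burnFactor)
  popSizes <- c(steps$ne[1],
                unlist(lapply(seq_len(nrow(steps)), function(i)
                  rep(steps$ne[i], steps$gens[i]))))
  pool <- cpp_wf_burnin(nCand, idx$start, idx$end, candMap@locusPos,
                        candMap@chromLengthMorgans,
                        as.integer(popSizes), muPerLocus)

  panelHaps <- .wfGeneration(pool, candMap, nHaplotypes, muPerLocus, idx)
  freqs <- rowMeans(panelHaps)
  seg <- which(freqs > 0 & freqs < 1)
  if (length(seg) < targetLoci)
    stop(sprintf(paste("founder burn-in produced only %d segregating loci,",
                       "%d short of the %d requested; increase 'oversample'",
                       "or 'muPerLocus'"),
                 length(seg), targetLoci - length(seg), targetLoci))
  keep <- sort(sample(seg, targetLoci))
  haplotypePanel(t(panelHaps[keep, , drop = FALSE]),
                 .subsetMap(candMap, keep))
}

#' Export a haplotype panel as a TSV matrix
#'
#' Writes the interchange format: a header row of locus ids
#' (`"c<chrom>:<pos in Morgans>"`) and one row of 0/1 values per haplotype.
#'
#' @param panel a [HaplotypePanel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
exportHaplotypes <- function(panel, path) {
  m <- panel@alleles
  colnames(m) <- locusIds(panel@map)
  data.table::fwrite(data.table::as.data.table(m), path, sep = "\t")
  invisible(path)
}

## Parse "c<chrom>:<pos>" locus ids.
.parseLocusIds <- function(ids) {
  m <- regmatches(ids, regexec("^c([0-9]+):([0-9.eE+-]+)$", ids))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed locus ids in header: ",
         paste(head(ids[bad], 5), collapse = ", "))
  list(chrom = as.integer(vapply(m, `[`, "", 2L)),
       pos = as.numeric(vapply(m, `[`, "", 3L)))
}

## Drop monomorphic columns of a haplotype matrix, with a logged count.
.dropMonomorphic <- function(alleles, chrom, pos) {
  f <- colMeans(alleles)
  mono <- f <= 0 | f >= 1
  if (any(mono)) {
    warning(sprintf("dropped %d monomorphic loci on import", sum(mono)),
            call. = FALSE)
    alleles <- alleles[, !mono, drop = FALSE]
    chrom <- chrom[!mono]
    pos <- pos[!mono]
  }
  list(alleles = alleles, chrom = chrom, pos = pos)
}

#' Import founder haplotypes
#'
#' Reads a haplotype panel from the TSV matrix interchange format or from a
#' VCF (diploid, biallelic sites only; GT field). Monomorphic sites are
#' dropped with a warning reporting the count. Imported panels are fully
#' interchangeable with internally simulated ones.
#'
#' For VCF input, phased genotypes keep their haplotype assignment;
#' unphased heterozygotes are assigned to the two haplotypes at random
#' (seed the RNG for reproducibility). Non-biallelic or missing genotypes
#' raise an error listing the offending records. Physical positions are
#' converted to genetic positions proportionally to the chromosome length.
#'
#' @param path input file.
#' @param format `"matrix-tsv"` or `"vcf"`.
#' @param map optional [GenomeMap-class] supplying the chromosome
#'   structure; defaults to 10 chromosomes of 1 Morgan / 6.75e8 bp.
#' @return a [HaplotypePanel-class].
#' @export
importHaplotypes <- function(path, format = c("matrix-tsv", "vcf"),
                             map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(map)) map <- genomeMap(integer(), numeric())
  if (format == "matrix-tsv") .importTsv(path, map) else .importVcf(path, map)
}

.importTsv <- function(path, map) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "integer")
  alleles <- as.matrix(dt)
  if (!all(alleles %in% c(0L, 1L)))
    stop("haplotype matrix entries must be 0/1")
  ids <- .parseLocusIds(colnames(alleles))
  o <- order(ids$chrom, ids$pos)
  alleles <- alleles[, o, drop = FALSE]
  parts <- .dropMonomorphic(alleles, ids$chrom[o], ids$pos[o])
  haplotypePanel(parts$alleles,
                 genomeMap(parts$chrom, parts$pos, nChrom = map@nChrom,
                           chromLengthMorgans = map@chromLengthMorgans,
                           chromLengthBp = map@chromLengthBp))
}

.importVcf <- function(path, map) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF import requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  rec <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  bi <- vcfR::is.biallelic(v)
  if (!all(bi))
    stop("non-biallelic sites in VCF: ",
         paste(head(rec[!bi], 10), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  miss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  if (any(miss))
    stop("missing genotypes in VCF at: ",
         paste(head(rec[rowSums(miss) > 0], 10), collapse = ", "))
  phased <- grepl("|", gt, fixed = TRUE)
  allele1 <- as.integer(substr(gt, 1L, 1L))
  allele2 <- as.integer(substr(gt, 3L, 3L))
  if (any(is.na(allele1)) || any(is.na(allele2)) ||
      any(allele1 > 1L) || any(allele2 > 1L))
    stop("genotypes must be diploid 0/1 calls")
  ## randomize haplotype assignment of unphased heterozygotes
  het <- allele1 != allele2 & !phased
  flip <- het & runif(length(gt)) < 0.5
  tmp <- allele1[flip]; allele1[flip] <- allele2[flip]; allele2[flip] <- tmp
  ## rows = sites, cols = samples -> haplotypes x loci
  nSite <- nrow(gt); nSamp <- ncol(gt)
  alleles <- matrix(0L, nrow = 2L * nSamp, ncol = nSite)
  alleles[seq(1L, 2L * nSamp, by = 2L), ] <- t(matrix(allele1, nSite, nSamp))
  alleles[seq(2L, 2L * nSamp, by = 2L), ] <- t(matrix(allele2, nSite, nSamp))
  chromLevels <- unique(fix[, "CHROM"])
  if (length(chromLevels) > map@nChrom)
    stop("VCF has more chromosomes than the genome map")
  chrom <- match(fix[, "CHROM"], chromLevels)
  posBp <- as.numeric(fix[, "POS"])
  pos <- posBp / map@chromLengthBp[chrom] * map@chromLengthMorgans[chrom]
  if (any(pos >= map@chromLengthMorgans[chrom]))
    stop("VCF positions beyond the chromosome length of the genome map")
  o <- order(chrom, pos)
  parts <- .dropMonomorphic(alleles[, o, drop = FALSE], chrom[o], pos[o])
  haplotypePanel(parts$alleles,
                 genomeMap(parts$chrom, parts$pos, nChrom = map@nChrom,
                           chromLengthMorgans = map@chromLengthMorgans,
                           chromLengthBp = map@chromLengthBp))
}
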