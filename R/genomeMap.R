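#' Construct a genome map
#'
#' @param locusChrom integer chromosome index per locus (1-based).
#' @param locusPos numeric genetic position per locus in Morgans, within
#'   the half-open interval `[0, chromosome length)`.
#' @param nChrom number of chromosomes (default 10).
#' @param chromLengthMorgans per-chromosome map length in Morgans, recycled
#'   (default 1).
#' @param chromLengthBp per-chromosome physical length in bp, recycled
#'   (default 6.75e8).
#' @return a [GenomeMap-class]. Loci must already be sorted by
#'   (chromosome, position).
#' @examples
#' gm <- genomeMap(locusChrom = c(1L, 1L, 2L), locusPos = c(0.1, 0.5, 0.2))
#' nLoci(gm)
#' @export
genomeMap <- function(locusChrom, locusPos, nChrom = 10L,
                      chromLengthMorgans = 1, chromLengthBp = 6.75e8) {
  new("GenomeMap",
      nChrom = as.integer(nChrom),
      chromLengthMorgans = rep_len(as.numeric(chromLengthMorgans), nChrom),
      chromLengthBp = rep_len(as.numeric(chromLengthBp), nChrom),
      locusChrom = as.integer(locusChrom),
      locusPos = as.numeric(locusPos))
}

#' Draw a genome map with uniformly placed loci
#'
#' Distributes `nLociTotal` loci uniformly at random across the genome
#' (each locus lands on a chromosome with probability proportional to its
#' map length, then uniformly along it) and sorts them. Uses the current
#' RNG stream.
#'
#' @param nLociTotal total number of loci.
#' @inheritParams genomeMap
#' @return a [GenomeMap-class].
#' @export
randomGenomeMap <- function(nLociTotal, nChrom = 10L,
                            chromLengthMorgans = 1, chromLengthBp = 6.75e8) {
  lenM <- rep_len(as.numeric(chromLengthMorgans), nChrom)
  chrom <- sample.int(nChrom, nLociTotal, replace = TRUE, prob = lenM)
  pos <- runif(nLociTotal, 0, lenM[chrom])
  o <- order(chrom, pos)
  genomeMap(chrom[o], pos[o], nChrom = nChrom,
            chromLengthMorgans = chromLengthMorgans,
            chromLengthBp = chromLengthBp)
}

#' @describeIn genomeMap number of loci on the map.
#' @param x a GenomeMap.
#' @export
setMethod("nLoci", "GenomeMap", function(x) length(x@locusChrom))

#' Locus identifiers of a map
#'
#' `"c<chrom>:<pos>"` with the genetic position in Morgans at full
#' precision, the header format of the haplotype matrix TSV interchange.
#'
#' @param map a [GenomeMap-class].
#' @return character vector, one id per locus.
#' @export
locusIds <- function(map) {
  sprintf("c%d:%.12g", map@locusChrom, map@locusPos)
}

## 0-based per-chromosome locus index ranges for the C++ kernels.
.chromIndex <- function(map) {
  n <- nLoci(map)
  start <- integer(map@nChrom)
  end <- integer(map@nChrom)
  if (n) {
    tab <- tabulate(map@locusChrom, nbins = map@nChrom)
    end <- cumsum(tab)
    start <- end - tab
  }
  list(start = as.integer(start), end = as.integer(end))
}

## Subset a map to a set of loci (kept in map order).
.subsetMap <- function(map, loci) {
  loci <- sort(as.integer(loci))
  genomeMap(map@locusChrom[loci], map@locusPos[loci], nChrom = map@nChrom,
            chromLengthMorgans = map@chromLengthMorgans,
            chromLengthBp = map@chromLengthBp)
}

setMethod("show", "GenomeMap", function(object) {
  cat("GenomeMap:", object@nChrom, "chromosomes,",
      sum(object@chromLengthMorgans), "Morgans total,",
      nLoci(object), "loci\n")
})
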