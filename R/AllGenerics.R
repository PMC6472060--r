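#' Number of individuals
#' @param x a [Population-class].
#' @return integer count.
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))

#' Number of loci
#' @param x a [GenomeMap-class], [HaplotypePanel-class] or
#'   [Population-class].
#' @return integer count.
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' Derived-allele frequencies
#'
#' Frequency of the derived (candidate deleterious) allele per locus,
#' computed over all haplotypes.
#'
#' @param x a [HaplotypePanel-class] or [Population-class].
#' @param loci optional locus indices (default: all loci).
#' @return numeric vector of frequencies.
#' @export
setGeneric("alleleFreqs", function(x, loci = NULL) standardGeneric("alleleFreqs"))

#' Mean fitness of a cohort
#' @param x a [Population-class].
#' @return mean of the individual fitness values w.
#' @export
setGeneric("meanFitness", function(x) standardGeneric("meanFitness"))

#' Mean true breeding value of a cohort
#' @param x a [Population-class].
#' @return mean of the true breeding values.
#' @export
setGeneric("meanBV", function(x) standardGeneric("meanBV"))
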