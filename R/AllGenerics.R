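#' @include AllClasses.R
NULL

#' @rdname SnpPanel-accessors
#' @export
setGeneric("locusIds", function(x) standardGeneric("locusIds"))

#' @rdname SnpPanel-accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname SnpPanel-accessors
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname SnpGenotypes-accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname SnpGenotypes-accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname SnpGenotypes-accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname SnpGenotypes-accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname SnpGenotypes-accessors
#' @export
setGeneric("panel", function(x) standardGeneric("panel"))

#' Genotype-state probabilities per locus and population
#'
#' @param x a \linkS4class{PopulationFrequencies}.
#' @param population optional population label; if given, returns the
#'   loci x 3 matrix for that population.
#' @return 3-d array or matrix of genotype-state probabilities.
#' @export
setGeneric("genotypeFrequencies",
  function(x, population = NULL) standardGeneric("genotypeFrequencies"))

#' Allele frequencies
#'
#' For a \linkS4class{PopulationFrequencies}, the loci x population matrix
#' of P(allele_a) derived from the genotype probabilities. For a
#' \linkS4class{SnpGenotypes}, estimates a \linkS4class{PopulationFrequencies}
#' from observed (non-missing) calls.
#'
#' @param x object to extract or estimate frequencies from.
#' @param ... unused.
#' @export
setGeneric("alleleFrequencies",
  function(x, ...) standardGeneric("alleleFrequencies"))

#' @rdname GenotypingSuccess-accessors
#' @export
setGeneric("successRates", function(x) standardGeneric("successRates"))

#' @rdname CvReport-accessors
#' @export
setGeneric("cvResults", function(x) standardGeneric("cvResults"))

#' @rdname CvReport-accessors
#' @export
setGeneric("cvSummary", function(x) standardGeneric("cvSummary"))

#' @rdname CvReport-accessors
#' @export
setGeneric("totalTests", function(x) standardGeneric("totalTests"))
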