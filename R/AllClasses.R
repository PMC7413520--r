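#' @import methods
NULL

GENOTYPE_STATES <- c("HOM_A", "HET", "HOM_B")

#' SnpPanel: an ordered set of diallelic SNP loci
#'
#' A panel is the ordered list of loci genotyped together, each with its two
#' observed alleles. \code{allele_a} is the reference allele of each locus:
#' genotype dosages throughout the package count copies of \code{allele_a},
#' so \code{HOM_A} = dosage 2, \code{HET} = 1, \code{HOM_B} = 0.
#'
#' @slot locusId character vector of unique locus identifiers.
#' @slot alleleA single-character nucleotide symbol per locus.
#' @slot alleleB single-character nucleotide symbol per locus; always
#'   different from \code{alleleA} (strictly diallelic panel).
#' @aliases SnpPanel-class
#' @exportClass SnpPanel
setClass("SnpPanel",
  slots = c(locusId = "character", alleleA = "character", alleleB = "character"))

setValidity("SnpPanel", function(object) {
  msg <- character()
  n <- length(object@locusId)
  if (length(object@alleleA) != n || length(object@alleleB) != n)
    msg <- c(msg, "locusId, alleleA and alleleB must have equal length")
  if (anyDuplicated(object@locusId))
    msg <- c(msg, "locus identifiers must be unique within a panel")
  if (n > 0) {
    if (!all(nchar(object@alleleA) == 1L) || !all(nchar(object@alleleB) == 1L))
      msg <- c(msg, "alleles must be single-character symbols")
    if (any(object@alleleA == object@alleleB))
      msg <- c(msg, "each locus must carry two distinct alleles")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SnpPanel
#'
#' @param locusId character vector of locus identifiers.
#' @param alleleA,alleleB single-character allele symbols, one per locus.
#' @return A \linkS4class{SnpPanel}.
#' @examples
#' SnpPanel(c("rs1", "rs2"), c("G", "C"), c("T", "A"))
#' @export
SnpPanel <- function(locusId, alleleA, alleleB) {
  new("SnpPanel", locusId = as.character(locusId),
      alleleA = as.character(alleleA), alleleB = as.character(alleleB))
}

#' SnpGenotypes: individuals x loci genotype calls with population labels
#'
#' The universal exchange object between pipeline stages. Calls are stored as
#' the dosage of each locus's \code{allele_a}: 2 (\code{HOM_A}), 1
#' (\code{HET}), 0 (\code{HOM_B}) or \code{NA} (missing). Genotypes are
#' unordered allele pairs; heterozygotes carry no phase.
#'
#' @slot calls integer matrix, individuals in rows (rownames = individual
#'   ids), loci in columns (colnames = panel locus ids), values 0/1/2/NA.
#' @slot population character vector of population labels, one per
#'   individual (e.g. \code{"wolf"}, \code{"dog"}, or \code{"unknown"} for
#'   query individuals).
#' @slot panel the \linkS4class{SnpPanel} the calls refer to.
#' @aliases SnpGenotypes-class
#' @exportClass SnpGenotypes
setClass("SnpGenotypes",
  slots = c(calls = "matrix", population = "character", panel = "SnpPanel"))

setValidity("SnpGenotypes", function(object) {
  msg <- character()
  if (ncol(object@calls) != length(object@panel@locusId))
    msg <- c(msg, "calls must have one column per panel locus")
  else if (!identical(colnames(object@calls), object@panel@locusId))
    msg <- c(msg, "calls column names must equal the panel locus ids, in order")
  if (length(object@population) != nrow(object@calls))
    msg <- c(msg, "one population label per individual is required")
  v <- object@calls[!is.na(object@calls)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    msg <- c(msg, "calls must be allele_a dosages in {0, 1, 2} or NA")
  if (nrow(object@calls) > 0 && is.null(rownames(object@calls)))
    msg <- c(msg, "individual ids (rownames of calls) are required")
  if (anyDuplicated(rownames(object@calls)))
    msg <- c(msg, "individual ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a SnpGenotypes object
#'
#' @param calls numeric matrix of allele_a dosages (0/1/2/NA), individuals in
#'   rows, loci in columns. Column names must match the panel loci.
#' @param population character vector of population labels, recycled if of
#'   length one.
#' @param panel a \linkS4class{SnpPanel}.
#' @return A \linkS4class{SnpGenotypes}.
#' @export
SnpGenotypes <- function(calls, population, panel) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(colnames(calls)) && ncol(calls) == length(panel@locusId))
    colnames(calls) <- panel@locusId
  if (is.null(rownames(calls)) && nrow(calls) > 0)
    rownames(calls) <- sprintf("ind_%03d", seq_len(nrow(calls)))
  if (length(population) == 1L) population <- rep(population, nrow(calls))
  new("SnpGenotypes", calls = calls, population = as.character(population),
      panel = panel)
}

#' PopulationFrequencies: genotype and allele frequencies per locus and population
#'
#' Houses, per (locus, population), the probabilities of the three genotype
#' states and the derived allele frequencies. Allele frequencies are always
#' computed from the genotype probabilities, P(allele_a) = P(HOM_A) +
#' P(HET)/2, so the two representations cannot drift apart.
#'
#' @slot panel the \linkS4class{SnpPanel} (loci with frequency data).
#' @slot freq 3-d numeric array \code{[locus, genotype state, population]}
#'   with genotype states \code{HOM_A, HET, HOM_B}; each locus x population
#'   triple sums to 1 within rounding tolerance.
#' @slot sampleSize named numeric vector of individuals per population.
#' @aliases PopulationFrequencies-class
#' @exportClass PopulationFrequencies
setClass("PopulationFrequencies",
  slots = c(panel = "SnpPanel", freq = "array", sampleSize = "numeric"))

setValidity("PopulationFrequencies", function(object) {
  msg <- character()
  d <- dim(object@freq)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "freq must be a [locus, 3 genotype states, population] array")
  else {
    if (!identical(dimnames(object@freq)[[1]], object@panel@locusId))
      msg <- c(msg, "freq locus dimension must match the panel")
    if (!identical(dimnames(object@freq)[[2]], GENOTYPE_STATES))
      msg <- c(msg, "genotype states must be HOM_A, HET, HOM_B")
    if (any(object@freq < 0 | object@freq > 1, na.rm = TRUE))
      msg <- c(msg, "genotype probabilities must lie in [0, 1]")
    sums <- apply(object@freq, c(1, 3), sum)
    # printed tables are rounded to 3 decimals: allow 0.002 slack
    if (any(abs(sums - 1) > 0.002 + 1e-9))
      msg <- c(msg, "genotype probabilities must sum to 1 (within 0.002)")
    pops <- dimnames(object@freq)[[3]]
    if (length(object@sampleSize) &&
        !all(pops %in% names(object@sampleSize)))
      msg <- c(msg, "sampleSize must be named by population")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PopulationFrequencies object
#'
#' @param panel a \linkS4class{SnpPanel}.
#' @param freq numeric array \code{[locus, state, population]} of genotype
#'   probabilities; state order \code{HOM_A, HET, HOM_B}.
#' @param sampleSize named numeric vector of per-population sample sizes
#'   (optional, used for reporting only).
#' @return A \linkS4class{PopulationFrequencies}.
#' @export
PopulationFrequencies <- function(panel, freq, sampleSize = numeric()) {
  dimnames(freq)[[1]] <- panel@locusId
  dimnames(freq)[[2]] <- GENOTYPE_STATES
  new("PopulationFrequencies", panel = panel, freq = freq,
      sampleSize = sampleSize)
}

#' GenotypingSuccess: one-time genotyping success per locus and population
#'
#' The proportion of samples yielding a complete, unambiguous genotype at a
#' locus on the first attempt, used for QC filtering of the panel.
#'
#' @slot success numeric matrix, loci in rows, populations in columns,
#'   values in [0, 1].
#' @slot sampleSize named numeric vector of samples per population.
#' @aliases GenotypingSuccess-class
#' @exportClass GenotypingSuccess
setClass("GenotypingSuccess",
  slots = c(success = "matrix", sampleSize = "numeric"))

setValidity("GenotypingSuccess", function(object) {
  msg <- character()
  if (any(object@success < 0 | object@success > 1, na.rm = TRUE))
    msg <- c(msg, "success rates must lie in [0, 1]")
  if (is.null(rownames(object@success)) || is.null(colnames(object@success)))
    msg <- c(msg, "success matrix needs locus rownames and population colnames")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypingSuccess table
#'
#' @param success numeric matrix of one-time success proportions with locus
#'   rownames and population colnames.
#' @param sampleSize named numeric vector of per-population sample sizes.
#' @return A \linkS4class{GenotypingSuccess}.
#' @export
GenotypingSuccess <- function(success, sampleSize = numeric()) {
  new("GenotypingSuccess", success = as.matrix(success),
      sampleSize = sampleSize)
}

#' SnpClassifier: a fitted population-assignment model
#'
#' Either a naive Bayes classifier over per-locus genotype states (Laplace
#' smoothing \code{alpha}) or a linear discriminant classifier on
#' allele-fraction features (pooled covariance ridged by \code{epsilon}).
#' Both use equal class priors.
#'
#' @slot model \code{"naive_bayes"} or \code{"lda"}.
#' @slot populations character vector of class labels, in training order.
#' @slot loci character vector of locus ids the model uses.
#' @slot panel the training \linkS4class{SnpPanel}.
#' @slot fit list of fitted parameters (naive Bayes: smoothed genotype-state
#'   probability array; LDA: class means and regularised pooled covariance).
#' @slot alpha,epsilon the smoothing/regularisation constants used.
#' @aliases SnpClassifier-class
#' @exportClass SnpClassifier
setClass("SnpClassifier",
  slots = c(model = "character", populations = "character",
            loci = "character", panel = "SnpPanel", fit = "list",
            alpha = "numeric", epsilon = "numeric"))

#' CvReport: aggregated cross-validation results
#'
#' @slot mode \code{"monte_carlo"} or \code{"kfold"}.
#' @slot results data.frame with one row per (test, population) giving the
#'   per-test accuracy (Monte-Carlo) or mean correct-class membership
#'   (K-fold).
#' @slot membership data.frame of per-individual held-out membership
#'   probabilities (K-fold mode; empty for Monte-Carlo).
#' @slot summary data.frame of per-condition (and per-population) mean and
#'   SD accuracies/memberships.
#' @slot totalTests integer count of assignment tests executed.
#' @slot config list echoing the configuration that produced the report.
#' @aliases CvReport-class
#' @exportClass CvReport
setClass("CvReport",
  slots = c(mode = "character", results = "data.frame",
            membership = "data.frame", summary = "data.frame",
            totalTests = "integer", config = "list"))
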