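#' @include AllGenerics.R
NULL

#' Accessors for SnpPanel
#'
#' @param x a \linkS4class{SnpPanel} (or an object carrying one).
#' @return \code{locusIds}: character vector of locus ids; \code{nLoci}:
#'   integer; \code{alleles}: data.frame with columns \code{locus_id},
#'   \code{allele_a}, \code{allele_b}.
#' @name SnpPanel-accessors
NULL

#' @rdname SnpPanel-accessors
#' @export
setMethod("locusIds", "SnpPanel", function(x) x@locusId)

#' @rdname SnpPanel-accessors
#' @export
setMethod("nLoci", "SnpPanel", function(x) length(x@locusId))

#' @rdname SnpPanel-accessors
#' @export
setMethod("alleles", "SnpPanel", function(x)
  data.frame(locus_id = x@locusId, allele_a = x@alleleA,
             allele_b = x@alleleB, stringsAsFactors = FALSE))

#' Subset a panel to a set of loci (kept in panel order)
#'
#' @param x a \linkS4class{SnpPanel}.
#' @param i character vector of locus ids or logical/integer index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "SnpPanel", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    bad <- setdiff(i, x@locusId)
    if (length(bad))
      stop("unknown loci: ", paste(bad, collapse = ", "))
    i <- which(x@locusId %in% i)   # panel order, not request order
  }
  SnpPanel(x@locusId[i], x@alleleA[i], x@alleleB[i])
})

setMethod("show", "SnpPanel", function(object) {
  cat("SnpPanel with", nLoci(object), "diallelic loci\n")
  a <- alleles(object)
  n <- min(nrow(a), 6L)
  if (n > 0)
    cat(paste0("  ", a$locus_id[seq_len(n)], " [", a$allele_a[seq_len(n)],
               "/", a$allele_b[seq_len(n)], "]", collapse = "\n"), "\n")
  if (nrow(a) > n) cat("  ...\n")
})

#' Accessors for SnpGenotypes
#'
#' @param x a \linkS4class{SnpGenotypes}.
#' @return \code{genotypeCalls}: integer dosage matrix (copies of allele_a,
#'   NA = missing); \code{populations}: character labels per individual;
#'   \code{individualIds}: rownames; \code{nIndividuals}: integer;
#'   \code{panel}: the \linkS4class{SnpPanel}.
#' @name SnpGenotypes-accessors
NULL

#' @rdname SnpGenotypes-accessors
#' @export
setMethod("genotypeCalls", "SnpGenotypes", function(x) x@calls)

#' @rdname SnpGenotypes-accessors
#' @export
setMethod("populations", "SnpGenotypes", function(x) x@population)

#' @rdname SnpGenotypes-accessors
#' @export
setMethod("individualIds", "SnpGenotypes", function(x) rownames(x@calls))

#' @rdname SnpGenotypes-accessors
#' @export
setMethod("nIndividuals", "SnpGenotypes", function(x) nrow(x@calls))

#' @rdname SnpGenotypes-accessors
#' @export
setMethod("panel", "SnpGenotypes", function(x) x@panel)

#' @rdname SnpGenotypes-accessors
#' @export
setMethod("nLoci", "SnpGenotypes", function(x) length(x@panel@locusId))

#' @rdname SnpGenotypes-accessors
#' @export
setMethod("locusIds", "SnpGenotypes", function(x) x@panel@locusId)

#' Subset genotypes by individuals and/or loci
#'
#' @param x a \linkS4class{SnpGenotypes}.
#' @param i individuals (index, logical or ids).
#' @param j loci (index, logical or locus ids; locus ids keep panel order).
#' @param ...,drop ignored.
#' @export
setMethod("[", "SnpGenotypes", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@calls))
  if (missing(j)) j <- seq_len(ncol(x@calls))
  if (is.character(j)) {
    bad <- setdiff(j, x@panel@locusId)
    if (length(bad))
      stop("unknown loci: ", paste(bad, collapse = ", "))
    j <- which(x@panel@locusId %in% j)
  }
  if (is.character(i)) i <- match(i, rownames(x@calls))
  new("SnpGenotypes", calls = x@calls[i, j, drop = FALSE],
      population = x@population[i], panel = x@panel[j])
})

setMethod("show", "SnpGenotypes", function(object) {
  cat("SnpGenotypes:", nIndividuals(object), "individuals x",
      nLoci(object), "loci\n")
  tb <- table(object@population)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  nm <- sum(is.na(object@calls))
  if (nm > 0)
    cat("  missing calls:", nm,
        sprintf("(%.1f%%)", 100 * nm / length(object@calls)), "\n")
})

#' @rdname genotypeFrequencies
#' @export
setMethod("genotypeFrequencies", "PopulationFrequencies",
  function(x, population = NULL) {
    if (is.null(population)) return(x@freq)
    if (!population %in% dimnames(x@freq)[[3]])
      stop("population not present: ", population)
    m <- x@freq[, , population, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    dimnames(m) <- dimnames(x@freq)[1:2]
    m
  })

#' @rdname alleleFrequencies
#' @export
setMethod("alleleFrequencies", "PopulationFrequencies", function(x, ...) {
  apply(x@freq, c(1, 3), function(v) v["HOM_A"] + v["HET"] / 2)
})

#' @rdname SnpPanel-accessors
#' @export
setMethod("locusIds", "PopulationFrequencies", function(x) x@panel@locusId)

#' @rdname SnpGenotypes-accessors
#' @export
setMethod("panel", "PopulationFrequencies", function(x) x@panel)

#' @rdname SnpGenotypes-accessors
#' @export
setMethod("populations", "PopulationFrequencies",
  function(x) dimnames(x@freq)[[3]])

#' Per-population sample sizes
#'
#' @param x a \linkS4class{PopulationFrequencies} or
#'   \linkS4class{GenotypingSuccess}.
#' @export
sampleSizes <- function(x) x@sampleSize

setMethod("show", "PopulationFrequencies", function(object) {
  cat("PopulationFrequencies:", nLoci(object@panel), "loci x",
      length(populations(object)), "populations (",
      paste(populations(object), collapse = ", "), ")\n")
  if (length(object@sampleSize))
    cat("  sample sizes:",
        paste(sprintf("%s n=%g", names(object@sampleSize),
                      object@sampleSize), collapse = ", "), "\n")
})

#' Accessors for GenotypingSuccess
#'
#' @param x a \linkS4class{GenotypingSuccess}.
#' @return \code{successRates}: numeric matrix, loci x populations.
#' @name GenotypingSuccess-accessors
NULL

#' @rdname GenotypingSuccess-accessors
#' @export
setMethod("successRates", "GenotypingSuccess", function(x) x@success)

#' @rdname SnpPanel-accessors
#' @export
setMethod("locusIds", "GenotypingSuccess", function(x) rownames(x@success))

setMethod("show", "GenotypingSuccess", function(object) {
  cat("GenotypingSuccess:", nrow(object@success), "loci x",
      ncol(object@success), "populations (",
      paste(colnames(object@success), collapse = ", "), ")\n")
})

#' Accessors for CvReport
#'
#' @param x a \linkS4class{CvReport}.
#' @return \code{cvResults}: per-test results data.frame; \code{cvSummary}:
#'   aggregated mean/SD per condition; \code{totalTests}: number of
#'   assignment tests executed.
#' @name CvReport-accessors
NULL

#' @rdname CvReport-accessors
#' @export
setMethod("cvResults", "CvReport", function(x) x@results)

#' @rdname CvReport-accessors
#' @export
setMethod("cvSummary", "CvReport", function(x) x@summary)

#' @rdname CvReport-accessors
#' @export
setMethod("totalTests", "CvReport", function(x) x@totalTests)

setMethod("show", "CvReport", function(object) {
  cat(sprintf("CvReport (%s): %d assignment tests\n", object@mode,
              object@totalTests))
  print(utils::head(object@summary, 12))
  if (nrow(object@summary) > 12) cat("  ...\n")
})
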