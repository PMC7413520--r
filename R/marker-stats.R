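#' @include accessors.R
NULL

#' Estimate genotype and allele frequencies from observed genotypes
#'
#' Genotype-state probabilities are the observed proportions over
#' non-missing calls per (locus, population); allele frequencies follow as
#' P(allele_a) = P(HOM_A) + P(HET)/2.
#'
#' @param x a \linkS4class{SnpGenotypes} with population labels.
#' @param ... unused.
#' @return A \linkS4class{PopulationFrequencies}; \code{sampleSize} records
#'   the number of individuals per population.
#' @rdname alleleFrequencies
#' @export
setMethod("alleleFrequencies", "SnpGenotypes", function(x, ...) {
  pops <- unique(populations(x))
  L <- nLoci(x)
  arr <- array(NA_real_, dim = c(L, 3, length(pops)),
               dimnames = list(locusIds(x), GENOTYPE_STATES, pops))
  calls <- genotypeCalls(x)
  for (p in pops) {
    sub <- calls[populations(x) == p, , drop = FALSE]
    for (k in seq_len(L)) {
      v <- sub[, k]
      v <- v[!is.na(v)]
      if (!length(v))
        stop(sprintf(
          "no non-missing calls at locus %s for population %s",
          locusIds(x)[k], p), call. = FALSE)
      arr[k, , p] <- c(mean(v == 2), mean(v == 1), mean(v == 0))
    }
  }
  ns <- vapply(pops, function(p) sum(populations(x) == p), numeric(1))
  PopulationFrequencies(panel(x), arr, sampleSize = ns)
})

#' Per-locus allele-frequency differentials between two populations
#'
#' For each locus: the within-population differential
#' |P(allele_a) - P(allele_b)| for both populations, the between-population
#' differential |P_pop1(allele) - P_pop2(allele)| (identical whichever
#' allele is used, by diallelic complement symmetry), and Nei's Gst.
#' Differentials are computed from the genotype-state probabilities, the
#' primary representation, not from separately rounded allele columns.
#'
#' @param freqs a \linkS4class{PopulationFrequencies}.
#' @param pop1,pop2 the two population labels to contrast.
#' @return A list with \code{perLocus} (data.frame, one row per locus:
#'   \code{locus_id}, \code{p1}, \code{p2}, \code{within_pop1},
#'   \code{within_pop2}, \code{between}, \code{fst}) and \code{summary}
#'   (data.frame of mean, sample SD, min, max for each differential across
#'   loci).
#' @examples
#' bp <- loadBundledPanel()
#' ds <- differentialSummary(bp$frequencies, "wolf", "dog")
#' ds$summary
#' @export
differentialSummary <- function(freqs, pop1, pop2) {
  stopifnot(is(freqs, "PopulationFrequencies"))
  for (p in c(pop1, pop2))
    if (!p %in% populations(freqs))
      stop("population not present: ", p, call. = FALSE)
  pa <- alleleFrequencies(freqs)
  p1 <- pa[, pop1]; p2 <- pa[, pop2]
  perLocus <- data.frame(
    locus_id = locusIds(freqs),
    p1 = p1, p2 = p2,
    within_pop1 = abs(2 * p1 - 1),
    within_pop2 = abs(2 * p2 - 1),
    between = abs(p1 - p2),
    fst = vapply(locusIds(freqs),
                 function(l) locusFst(freqs, pop1, pop2, l), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(
    c("within_pop1", "within_pop2", "between"), function(col) {
      v <- perLocus[[col]]
      data.frame(differential = col, mean = mean(v), sd = stats::sd(v),
                 min = min(v), max = max(v), stringsAsFactors = FALSE)
    }))
  list(perLocus = perLocus, summary = summ)
}

#' Nei's Gst for one locus between two populations
#'
#' Two-population fixation index with equal population weights:
#' with mean allele frequency \eqn{\bar p = (p_1 + p_2)/2}, total expected
#' heterozygosity \eqn{H_T = 2 \bar p (1 - \bar p)}, mean within-population
#' heterozygosity \eqn{H_S = [2 p_1 (1 - p_1) + 2 p_2 (1 - p_2)]/2}, then
#' \eqn{G_{st} = (H_T - H_S) / H_T}, defined as 0 when \eqn{H_T = 0}
#' (no variation anywhere). Equals 0 for identical frequencies and 1 for a
#' fixed difference, and is invariant to which allele is counted.
#'
#' @param freqs a \linkS4class{PopulationFrequencies}.
#' @param pop1,pop2 population labels.
#' @param locus locus id.
#' @return Gst value in [0, 1].
#' @examples
#' bp <- loadBundledPanel()
#' locusFst(bp$frequencies, "wolf", "dog", "rs22835438")
#' @export
locusFst <- function(freqs, pop1, pop2, locus) {
  stopifnot(is(freqs, "PopulationFrequencies"))
  if (!locus %in% locusIds(freqs))
    stop("unknown locus: ", locus, call. = FALSE)
  pa <- alleleFrequencies(freqs)
  gstFromP(pa[locus, pop1], pa[locus, pop2])
}

gstFromP <- function(p1, p2) {
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  if (ht == 0) return(0)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  (ht - hs) / ht
}

round_half_up <- function(x) floor(x + 0.5)

#' Select the top-Fst fraction of loci
#'
#' Loci are ranked by Fst descending (ties broken by locus id ascending)
#' and the top \code{round(fraction * n)} (round-half-up, floor of 1 locus)
#' are returned. \code{fraction = 1} returns every locus in panel order.
#'
#' @param stats the \code{perLocus} data.frame of
#'   \code{\link{differentialSummary}} (columns \code{locus_id},
#'   \code{fst}), or anything coercible to one.
#' @param fraction value in (0, 1].
#' @return character vector of selected locus ids.
#' @export
selectTopFstLoci <- function(stats, fraction) {
  stats <- as.data.frame(stats)
  if (length(fraction) != 1 || is.na(fraction) ||
      fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  if (fraction == 1) return(stats$locus_id)
  nsel <- max(1L, round_half_up(fraction * nrow(stats)))
  ord <- order(-stats$fst, stats$locus_id)
  stats$locus_id[ord][seq_len(nsel)]
}

#' QC-filter panel loci on one-time genotyping success
#'
#' A locus is retained iff its one-time genotyping success is at least
#' \code{threshold} in every population (an "overall" column, if present,
#' is a derived average and is not used for filtering).
#'
#' @param success a \linkS4class{GenotypingSuccess}.
#' @param threshold proportion in (0, 1]; default 0.90.
#' @return data.frame with columns \code{locus_id}, \code{retained},
#'   \code{reason}.
#' @examples
#' bp <- loadBundledPanel()
#' qc <- qcFilterLoci(bp$success)
#' qc[!qc$retained, ]
#' @export
qcFilterLoci <- function(success, threshold = 0.90) {
  stopifnot(is(success, "GenotypingSuccess"))
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  s <- successRates(success)
  popCols <- setdiff(colnames(s), "overall")
  sp <- s[, popCols, drop = FALSE]
  retained <- apply(sp >= threshold, 1, all)
  reason <- ifelse(retained, "pass", vapply(seq_len(nrow(sp)), function(i) {
    bad <- popCols[sp[i, ] < threshold]
    paste0("success < ", format(threshold), " in ",
           paste(sprintf("%s (%.3f)", bad, sp[i, bad]), collapse = ", "))
  }, character(1)))
  data.frame(locus_id = rownames(s), retained = unname(retained),
             reason = unname(reason), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Average one-time genotyping success over a locus subset
#'
#' Per-population means are unweighted means of per-locus success over the
#' subset; the overall value is the unweighted mean of the per-population
#' means.
#'
#' @param success a \linkS4class{GenotypingSuccess}.
#' @param loci character vector of locus ids (non-empty subset of the
#'   table's loci).
#' @return named numeric vector: one mean per population plus
#'   \code{overall}.
#' @examples
#' bp <- loadBundledPanel()
#' keep <- qcFilterLoci(bp$success)
#' successSummary(bp$success, keep$locus_id[keep$retained])
#' @export
successSummary <- function(success, loci) {
  stopifnot(is(success, "GenotypingSuccess"))
  if (!length(loci)) stop("locus subset must be non-empty", call. = FALSE)
  s <- successRates(success)
  bad <- setdiff(loci, rownames(s))
  if (length(bad))
    stop("unknown loci: ", paste(bad, collapse = ", "), call. = FALSE)
  popCols <- setdiff(colnames(s), "overall")
  m <- colMeans(s[loci, popCols, drop = FALSE])
  c(m, overall = mean(m))
}
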