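#' @include accessors.R
NULL

#' Pairwise Euclidean genetic distances between individuals
#'
#' Distance between two individuals is the Euclidean distance between their
#' genotype one-hot encodings: \eqn{d = \sqrt{2 m}} where \eqn{m} is the
#' number of loci at which the two carry different genotype states. With a
#' complete 12-locus panel, d therefore takes values in
#' \{sqrt(0), sqrt(2), ..., sqrt(24)\}.
#'
#' Missing data: with \code{missing = "complete"} (default, appropriate for
#' reference databases genotyped to completion) any missing call is an
#' error. With \code{missing = "pairwise"} the mismatch count uses
#' pairwise-complete loci only and the distance is rescaled by
#' \code{sqrt(nLoci / nComplete)}; a pair with no complete locus gets NA.
#'
#' @param x a \linkS4class{SnpGenotypes}.
#' @param missing \code{"complete"} or \code{"pairwise"}.
#' @return symmetric numeric matrix with zero diagonal, individuals as
#'   dimnames.
#' @examples
#' bp <- loadBundledPanel()
#' g <- simulatePopulation(bp$frequencies, "wolf", n = 5, seed = 3)
#' pairwiseDistances(g)
#' @export
pairwiseDistances <- function(x, missing = c("complete", "pairwise")) {
  missing <- match.arg(missing)
  calls <- genotypeCalls(x)
  n <- nrow(calls); L <- ncol(calls)
  if (missing == "complete" && anyNA(calls))
    stop("genotype matrix contains missing calls; use missing = \"pairwise\"",
         call. = FALSE)
  mism <- matrix(0, n, n)
  comp <- matrix(0, n, n)
  for (k in seq_len(L)) {
    v <- calls[, k]
    ok <- outer(!is.na(v), !is.na(v), "&")
    ne <- outer(v, v, "!=")
    ne[!ok] <- FALSE
    mism <- mism + ne
    comp <- comp + ok
  }
  d <- sqrt(2 * mism)
  if (missing == "pairwise") {
    d <- d * sqrt(L / comp)
    d[comp == 0] <- NA_real_
    diag(d) <- 0
  }
  dimnames(d) <- list(rownames(calls), rownames(calls))
  d
}

# split the unordered pairs of a distance matrix by population membership
distance_pairs <- function(d, labels, pop1, pop2) {
  stopifnot(nrow(d) == length(labels))
  idx1 <- which(labels == pop1); idx2 <- which(labels == pop2)
  if (length(idx1) + length(idx2) != length(labels))
    stop("every individual must be labelled ", pop1, " or ", pop2,
         call. = FALSE)
  upper <- function(i, j) {
    if (!length(i) || !length(j)) return(numeric(0))
    as.vector(d[i, j, drop = FALSE])
  }
  within <- function(i) {
    if (length(i) < 2) return(numeric(0))
    dd <- d[i, i, drop = FALSE]
    dd[upper.tri(dd)]
  }
  list(intra_pop1 = within(idx1), intra_pop2 = within(idx2),
       inter = upper(idx1, idx2))
}

summ_row <- function(label, v, method, level = 0.95) {
  if (!length(v))
    return(data.frame(label = label, n_pairs = 0L, mean = NA_real_,
                      sd = NA_real_, min = NA_real_, max = NA_real_,
                      lower95 = NA_real_, upper95 = NA_real_,
                      stringsAsFactors = FALSE))
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "normal") {
    lo <- mean(v) - z * stats::sd(v); hi <- mean(v) + z * stats::sd(v)
  } else {
    q <- stats::quantile(v, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE)
    lo <- q[1]; hi <- q[2]
  }
  data.frame(label = label, n_pairs = length(v), mean = mean(v),
             sd = stats::sd(v), min = min(v), max = max(v),
             lower95 = lo, upper95 = hi, stringsAsFactors = FALSE)
}

#' Intra- and inter-population distance summaries
#'
#' Partitions all unordered pairs of individuals into within-population-1,
#' within-population-2, their union (overall intra) and between-population
#' sets, and summarises each: pair count, mean, sample SD, range and 95%
#' bounds of the distance distribution. With n1 and n2 individuals the
#' intra sets hold choose(n1,2) and choose(n2,2) pairs and the inter set
#' n1*n2. A population with fewer than 2 individuals yields an undefined
#' (all-NA) intra summary.
#'
#' @param d distance matrix from \code{\link{pairwiseDistances}}.
#' @param labels population label per individual (matrix row order).
#' @param pop1,pop2 the two population labels.
#' @param method how the 95% bounds are formed: \code{"normal"}
#'   (mean +/- 1.96 SD of the distance distribution, default) or
#'   \code{"percentile"} (empirical 2.5%/97.5% quantiles).
#' @return data.frame with rows \code{intra_pop1}, \code{intra_pop2},
#'   \code{intra_overall}, \code{inter}.
#' @export
distanceSummaries <- function(d, labels, pop1, pop2,
                              method = c("normal", "percentile")) {
  method <- match.arg(method)
  pr <- distance_pairs(d, labels, pop1, pop2)
  rbind(summ_row("intra_pop1", pr$intra_pop1, method),
        summ_row("intra_pop2", pr$intra_pop2, method),
        summ_row("intra_overall", c(pr$intra_pop1, pr$intra_pop2), method),
        summ_row("inter", pr$inter, method))
}

#' Welch's t-test between intra- and inter-population distance sets
#'
#' Two-sample unequal-variance t-test treating each pairwise distance as an
#' observation, testing whether between-population distances exceed
#' within-population distances. Positive t means inter > intra.
#'
#' @param intra numeric vector of pooled within-population distances.
#' @param inter numeric vector of between-population distances.
#' @return list with \code{t}, \code{df}, \code{p} (two-sided) and
#'   \code{degenerate} (TRUE when both sets have zero variance, in which
#'   case t is undefined and returned as NA).
#' @export
welchSeparationTest <- function(intra, inter) {
  if (!length(intra) || !length(inter))
    stop("both distance sets must be non-empty", call. = FALSE)
  if (stats::sd(intra) == 0 && stats::sd(inter) == 0)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                degenerate = TRUE))
  tt <- stats::t.test(inter, intra, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Separation gap between intra- and inter-population distances
#'
#' The difference between the lower 95% bound of the inter-population
#' distance distribution and the upper 95% bound of the overall
#' intra-population distribution. A positive gap means the two 95%
#' intervals are disjoint (low false-assignment risk); both bound methods
#' are exposed because they can disagree near overlap.
#'
#' @param intra numeric vector of pooled intra-population distances.
#' @param inter numeric vector of inter-population distances.
#' @param method \code{"normal"} (mean +/- 1.96 SD) or \code{"percentile"}
#'   (empirical quantiles).
#' @return list with \code{gap}, \code{intra_upper95}, \code{inter_lower95}
#'   and \code{method}.
#' @export
separationGap <- function(intra, inter,
                          method = c("normal", "percentile")) {
  method <- match.arg(method)
  si <- summ_row("intra", intra, method)
  se <- summ_row("inter", inter, method)
  list(gap = se$lower95 - si$upper95, intra_upper95 = si$upper95,
       inter_lower95 = se$lower95, method = method)
}
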