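#' @include accessors.R
NULL

HYBRID_TOL <- 1e-7

#' Fit a population-assignment classifier
#'
#' Two models, both with equal class priors (assignment is between exactly
#' two candidate subspecies with no prior weighting):
#' \describe{
#'   \item{naive_bayes}{Per (population, locus) genotype-state
#'     probabilities with Laplace smoothing:
#'     (count + alpha) / (n + 3 alpha) over the three genotype states.
#'     Smoothing keeps log-likelihoods finite when a state is unobserved
#'     in training, reproducing the multiplied per-locus likelihoods of
#'     the assignment framework without zero-clamping.}
#'   \item{lda}{Linear discriminant analysis on allele-fraction features
#'     (0/0.5/1 per locus): class means plus pooled within-class
#'     covariance with \code{epsilon} added to the diagonal, so loci fixed
#'     within both training groups (common in this panel) do not make the
#'     covariance singular.}
#' }
#'
#' @param training a \linkS4class{SnpGenotypes} with at least two
#'   populations of at least two individuals each.
#' @param model \code{"naive_bayes"} or \code{"lda"}.
#' @param alpha Laplace pseudo-count for naive Bayes (default 1; must be
#'   > 0 whenever a genotype state has zero training count).
#' @param epsilon ridge added to the pooled covariance diagonal for LDA
#'   (default 1e-6).
#' @param loci optional locus subset to train on (default: all panel
#'   loci).
#' @return A \linkS4class{SnpClassifier}.
#' @examples
#' bp <- loadBundledPanel()
#' ref <- rbind2(simulatePopulation(bp$frequencies, "wolf", 80, seed = 1),
#'               simulatePopulation(bp$frequencies, "dog", 90, seed = 2))
#' fitClassifier(ref, "naive_bayes")
#' @export
fitClassifier <- function(training, model = c("naive_bayes", "lda"),
                          alpha = 1, epsilon = 1e-6, loci = NULL) {
  model <- match.arg(model)
  stopifnot(is(training, "SnpGenotypes"))
  if (is.null(loci)) loci <- locusIds(training)
  if (!length(loci)) stop("empty locus subset", call. = FALSE)
  bad <- setdiff(loci, locusIds(training))
  if (length(bad))
    stop("training data lacks loci: ", paste(bad, collapse = ", "),
         call. = FALSE)
  pops <- unique(populations(training))
  if (length(pops) < 2)
    stop("training data must contain at least two populations",
         call. = FALSE)
  cnt <- table(populations(training))
  if (any(cnt < 2))
    stop("every training population needs at least 2 individuals",
         call. = FALSE)
  sub <- training[, loci]
  calls <- genotypeCalls(sub)

  if (model == "naive_bayes") {
    if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
    L <- length(loci)
    probs <- array(NA_real_, dim = c(L, 3, length(pops)),
                   dimnames = list(loci, GENOTYPE_STATES, pops))
    zero <- FALSE
    for (p in pops) {
      pc <- calls[populations(sub) == p, , drop = FALSE]
      for (k in seq_len(L)) {
        v <- pc[, k]; v <- v[!is.na(v)]
        counts <- c(sum(v == 2), sum(v == 1), sum(v == 0))
        if (any(counts == 0)) zero <- TRUE
        probs[k, , p] <- (counts + alpha) / (length(v) + 3 * alpha)
      }
    }
    if (zero && alpha == 0)
      warning("some genotype states have zero training count and ",
              "alpha = 0: posteriors may degenerate to 0/1 or NaN")
    fit <- list(probs = probs)
  } else {
    if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
    if (anyNA(calls))
      stop("LDA training requires complete genotypes ",
           "(re-genotype or drop incomplete individuals)", call. = FALSE)
    X <- calls / 2   # allele-fraction features
    L <- ncol(X)
    means <- matrix(NA_real_, length(pops), L,
                    dimnames = list(pops, loci))
    pooled <- matrix(0, L, L)
    for (p in pops) {
      Xp <- X[populations(sub) == p, , drop = FALSE]
      means[p, ] <- colMeans(Xp)
      pooled <- pooled + crossprod(sweep(Xp, 2, colMeans(Xp)))
    }
    pooled <- pooled / (nrow(X) - length(pops))
    pooled <- pooled + diag(epsilon, L)
    fit <- list(means = means, cov = pooled)
  }
  new("SnpClassifier", model = model, populations = pops, loci = loci,
      panel = panel(sub), fit = fit, alpha = alpha, epsilon = epsilon)
}

setMethod("show", "SnpClassifier", function(object) {
  cat(sprintf("SnpClassifier: %s over %d loci; classes: %s\n",
              object@model, length(object@loci),
              paste(object@populations, collapse = ", ")))
})

# log density of a multivariate normal restricted to observed coordinates
lda_loglik <- function(xObs, muObs, covObs) {
  ch <- chol(covObs)
  z <- backsolve(ch, xObs - muObs, transpose = TRUE)
  -sum(log(diag(ch))) - 0.5 * sum(z^2) -
    0.5 * length(xObs) * log(2 * pi)
}

#' Membership probabilities for query individuals
#'
#' For each query individual, the per-population log-likelihood is summed
#' over the model's loci with a non-missing call (missing loci contribute
#' nothing), and memberships are the likelihoods normalised under equal
#' priors. An individual missing at every model locus is flagged
#' unassignable (NA memberships). Under naive Bayes, an individual whose
#' maximum membership falls below 1 - 1e-7 is annotated as a possible
#' hybrid -- intermediate genotypes depress the winning posterior by many
#' orders of magnitude relative to pure individuals; the flag is purely
#' advisory.
#'
#' @param object a fitted \linkS4class{SnpClassifier}.
#' @param query a \linkS4class{SnpGenotypes} covering the model's loci.
#' @return data.frame with one row per query individual:
#'   \code{individual_id}, one membership column per population
#'   (summing to 1), \code{predicted} (argmax; ties broken by training
#'   population order), per-population log-likelihood columns
#'   (\code{loglik_*}), \code{unassignable} and \code{possible_hybrid}.
#' @export
membershipProbabilities <- function(object, query) {
  stopifnot(is(object, "SnpClassifier"), is(query, "SnpGenotypes"))
  bad <- setdiff(object@loci, locusIds(query))
  if (length(bad))
    stop("query lacks model loci: ", paste(bad, collapse = ", "),
         call. = FALSE)
  sub <- query[, object@loci]
  calls <- genotypeCalls(sub)
  pops <- object@populations
  n <- nrow(calls)
  ll <- matrix(NA_real_, n, length(pops), dimnames = list(NULL, pops))

  for (i in seq_len(n)) {
    obs <- which(!is.na(calls[i, ]))
    if (!length(obs)) next
    if (object@model == "naive_bayes") {
      stateIdx <- 3L - calls[i, obs]   # dosage 2/1/0 -> state col 1/2/3
      for (p in pops) {
        pr <- object@fit$probs[obs, , p, drop = FALSE]
        ll[i, p] <- sum(log(pr[cbind(seq_along(obs), stateIdx, 1L)]))
      }
    } else {
      xObs <- calls[i, obs] / 2
      covObs <- object@fit$cov[obs, obs, drop = FALSE]
      for (p in pops)
        ll[i, p] <- lda_loglik(xObs, object@fit$means[p, obs], covObs)
    }
  }

  member <- matrix(NA_real_, n, length(pops), dimnames = list(NULL, pops))
  for (i in seq_len(n)) {
    if (anyNA(ll[i, ])) next
    w <- exp(ll[i, ] - max(ll[i, ]))
    member[i, ] <- w / sum(w)
  }
  unassignable <- apply(is.na(member), 1, any)
  predicted <- rep(NA_character_, n)
  hybrid <- rep(FALSE, n)
  for (i in which(!unassignable)) {
    predicted[i] <- pops[which.max(member[i, ])]  # first max: label order
    hybrid[i] <- object@model == "naive_bayes" &&
      max(member[i, ]) < 1 - HYBRID_TOL
  }

  out <- data.frame(individual_id = individualIds(sub),
                    stringsAsFactors = FALSE)
  for (p in pops) out[[p]] <- member[, p]
  out$predicted <- predicted
  for (p in pops) out[[paste0("loglik_", p)]] <- ll[, p]
  out$unassignable <- unassignable
  out$possible_hybrid <- hybrid
  out
}

#' Per-population assignment accuracy
#'
#' @param results data.frame from \code{\link{membershipProbabilities}}.
#' @param trueLabels optional character vector of true population labels
#'   (same order as \code{results}); without it, no accuracies can be
#'   computed and NULL is returned.
#' @return data.frame with one row per true population plus an
#'   \code{overall} row: \code{population}, \code{n}, \code{n_correct},
#'   \code{accuracy}.
#' @export
assignmentAccuracy <- function(results, trueLabels = NULL) {
  if (is.null(trueLabels)) return(NULL)
  stopifnot(length(trueLabels) == nrow(results))
  ok <- results$predicted == trueLabels
  pops <- unique(trueLabels)
  rows <- lapply(pops, function(p) {
    idx <- trueLabels == p
    data.frame(population = p, n = sum(idx),
               n_correct = sum(ok[idx], na.rm = TRUE),
               accuracy = mean(ok[idx], na.rm = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  rbind(rows, data.frame(population = "overall", n = length(ok),
                         n_correct = sum(ok, na.rm = TRUE),
                         accuracy = mean(ok), stringsAsFactors = FALSE))
}

#' Combine two genotype matrices over the same panel
#'
#' @param x,y \linkS4class{SnpGenotypes} objects sharing a panel.
#' @return a \linkS4class{SnpGenotypes} with the rows of both.
#' @export
setMethod("rbind2", signature("SnpGenotypes", "SnpGenotypes"),
  function(x, y) {
    if (!identical(locusIds(x), locusIds(y)))
      stop("genotype matrices cover different panels", call. = FALSE)
    new("SnpGenotypes",
        calls = rbind(genotypeCalls(x), genotypeCalls(y)),
        population = c(populations(x), populations(y)),
        panel = panel(x))
  })
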