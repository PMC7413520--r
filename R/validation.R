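#' @include assignment.R marker-stats.R distance.R simulate.R
NULL

# stratified training draw: per population, round-half-up(prop * n) without
# replacement; validated before any computation so a bad grid fails fast
check_cv_sizes <- function(popCounts, proportions) {
  for (prop in proportions) {
    nTrain <- round_half_up(prop * popCounts)
    if (any(nTrain < 2))
      stop("training proportion ", prop,
           " leaves fewer than 2 training individuals in a population",
           call. = FALSE)
    if (any(popCounts - nTrain < 1))
      stop("training proportion ", prop,
           " leaves an empty test set for a population", call. = FALSE)
  }
}

# rank loci by Gst computed on TRAINING data only and take the top fraction;
# fraction 1 keeps the full panel in panel order (no test-set leakage)
select_training_loci <- function(train, pop1, pop2, fraction) {
  if (fraction == 1) return(locusIds(train))
  fr <- alleleFrequencies(train)
  ds <- differentialSummary(fr, pop1, pop2)
  selectTopFstLoci(ds$perLocus, fraction)
}

#' Monte-Carlo cross-validation of assignment accuracy
#'
#' Repeated stratified random splits: for each combination of training
#' proportion and locus fraction, and for each of \code{nResamples}
#' resamples, the stated proportion of individuals is drawn from each
#' population (without replacement) as training data; per-locus Fst is
#' computed on the training data only and the top-fraction loci selected;
#' the classifier (LDA by default, as used to build the predictive models)
#' is fitted on the training individuals at those loci and the held-out
#' individuals are assigned. With the defaults (3 proportions x 4 locus
#' fractions x 30 resamples) this executes 360 assignment tests.
#'
#' @param reference a \linkS4class{SnpGenotypes} with exactly two
#'   populations.
#' @param seed integer seed; the full grid is deterministic given the seed.
#' @param trainProportions proportions of each population used for
#'   training (default 0.5, 0.7, 0.9).
#' @param locusFractions top-Fst locus fractions (default 0.10, 0.25,
#'   0.50, 1).
#' @param nResamples resamples per combination (default 30).
#' @param model,alpha,epsilon classifier configuration (see
#'   \code{\link{fitClassifier}}); default model \code{"lda"}.
#' @return A \linkS4class{CvReport} (mode \code{"monte_carlo"}); results
#'   hold one row per (test, population) with the held-out accuracy.
#' @export
monteCarloCv <- function(reference, seed,
                         trainProportions = c(0.5, 0.7, 0.9),
                         locusFractions = c(0.10, 0.25, 0.50, 1.0),
                         nResamples = 30, model = "lda",
                         alpha = 1, epsilon = 1e-6) {
  stopifnot(is(reference, "SnpGenotypes"))
  pops <- unique(populations(reference))
  if (length(pops) != 2)
    stop("Monte-Carlo CV expects exactly two populations", call. = FALSE)
  labels <- populations(reference)
  popCounts <- vapply(pops, function(p) sum(labels == p), numeric(1))
  check_cv_sizes(popCounts, trainProportions)

  rows <- list()
  with_seed(seed, {
    for (prop in trainProportions) {
      for (frac in locusFractions) {
        for (r in seq_len(nResamples)) {
          trainIdx <- unlist(lapply(pops, function(p) {
            idx <- which(labels == p)
            sample(idx, round_half_up(prop * length(idx)))
          }))
          testIdx <- setdiff(seq_along(labels), trainIdx)
          stopifnot(length(intersect(trainIdx, testIdx)) == 0)
          train <- reference[trainIdx, ]
          loci <- select_training_loci(train, pops[1], pops[2], frac)
          fit <- fitClassifier(train, model = model, alpha = alpha,
                               epsilon = epsilon, loci = loci)
          res <- membershipProbabilities(fit, reference[testIdx, ])
          acc <- assignmentAccuracy(res, labels[testIdx])
          acc <- acc[acc$population %in% pops, ]
          rows[[length(rows) + 1L]] <- data.frame(
            train_proportion = prop, locus_fraction = frac, resample = r,
            n_loci = length(loci), population = acc$population,
            n_test = acc$n, n_correct = acc$n_correct,
            accuracy = acc$accuracy, stringsAsFactors = FALSE)
        }
      }
    }
  })
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(accuracy ~ train_proportion + locus_fraction +
                                population, data = results,
                              FUN = function(v) c(mean = mean(v),
                                                  sd = stats::sd(v)))
  summary <- cbind(summary[, 1:3],
                   mean = summary$accuracy[, "mean"],
                   sd = summary$accuracy[, "sd"])
  nTests <- length(trainProportions) * length(locusFractions) * nResamples
  new("CvReport", mode = "monte_carlo", results = results,
      membership = data.frame(), summary = summary,
      totalTests = as.integer(nTests),
      config = list(seed = seed, trainProportions = trainProportions,
                    locusFractions = locusFractions,
                    nResamples = nResamples, model = model,
                    alpha = alpha, epsilon = epsilon))
}

# balanced fold labels for n individuals: sizes differ by at most one
fold_sizes <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' K-fold cross-validation of membership probability
#'
#' Individuals of each population are shuffled and divided into K groups of
#' near-equal size (differing by at most one). For each locus fraction,
#' each group in turn is assigned by a model built on the remaining K-1
#' groups (Fst ranking and locus selection recomputed on the training
#' folds only). Each (fold, locus fraction) combination is one assignment
#' test: the defaults (K = 3, 4, 5 crossed with 4 locus fractions) give
#' (3+4+5) x 4 = 48 tests. The default classifier is naive Bayes, the
#' model used for membership probabilities.
#'
#' @inheritParams monteCarloCv
#' @param kValues numbers of folds (default 3, 4, 5); every population
#'   must have at least \code{max(kValues)} individuals.
#' @return A \linkS4class{CvReport} (mode \code{"kfold"}); the
#'   \code{membership} slot holds per-individual held-out membership of
#'   the individual's true population for every test, the summary the
#'   per-condition and per-population aggregates.
#' @export
kfoldCv <- function(reference, seed, kValues = c(3, 4, 5),
                    locusFractions = c(0.10, 0.25, 0.50, 1.0),
                    model = "naive_bayes", alpha = 1, epsilon = 1e-6) {
  stopifnot(is(reference, "SnpGenotypes"))
  pops <- unique(populations(reference))
  if (length(pops) != 2)
    stop("K-fold CV expects exactly two populations", call. = FALSE)
  labels <- populations(reference)
  popCounts <- vapply(pops, function(p) sum(labels == p), numeric(1))
  if (any(max(kValues) > popCounts))
    stop("K exceeds the size of a population", call. = FALSE)

  rows <- list(); mem <- list()
  with_seed(seed, {
    for (k in kValues) {
      # stratified fold labels, random shuffle within population
      fold <- integer(length(labels))
      for (p in pops) {
        idx <- sample(which(labels == p))
        fold[idx] <- rep(seq_len(k), times = fold_sizes(length(idx), k))
      }
      for (frac in locusFractions) {
        for (f in seq_len(k)) {
          testIdx <- which(fold == f)
          trainIdx <- which(fold != f)
          stopifnot(length(intersect(trainIdx, testIdx)) == 0)
          train <- reference[trainIdx, ]
          loci <- select_training_loci(train, pops[1], pops[2], frac)
          fit <- fitClassifier(train, model = model, alpha = alpha,
                               epsilon = epsilon, loci = loci)
          res <- membershipProbabilities(fit, reference[testIdx, ])
          trueP <- labels[testIdx]
          mcorr <- vapply(seq_len(nrow(res)),
                          function(i) res[[trueP[i]]][i], numeric(1))
          mem[[length(mem) + 1L]] <- data.frame(
            k = k, locus_fraction = frac, fold = f,
            individual_id = res$individual_id, population = trueP,
            membership_correct = mcorr, predicted = res$predicted,
            stringsAsFactors = FALSE)
          acc <- assignmentAccuracy(res, trueP)
          accP <- acc[acc$population %in% pops, ]
          rows[[length(rows) + 1L]] <- data.frame(
            k = k, locus_fraction = frac, fold = f, n_loci = length(loci),
            population = accP$population, n_test = accP$n,
            mean_membership = vapply(accP$population, function(p)
              mean(mcorr[trueP == p]), numeric(1)),
            accuracy = accP$accuracy, stringsAsFactors = FALSE)
        }
      }
    }
  })
  results <- do.call(rbind, rows)
  membership <- do.call(rbind, mem)
  perCond <- stats::aggregate(
    membership_correct ~ k + locus_fraction + population,
    data = membership, FUN = function(v) c(mean = mean(v),
                                           sd = stats::sd(v)))
  perCond <- cbind(perCond[, 1:3],
                   mean = perCond$membership_correct[, "mean"],
                   sd = perCond$membership_correct[, "sd"])
  overall <- do.call(rbind, lapply(pops, function(p) {
    v <- membership$membership_correct[membership$population == p]
    data.frame(k = NA_real_, locus_fraction = NA_real_, population = p,
               mean = mean(v), sd = stats::sd(v), stringsAsFactors = FALSE)
  }))
  nTests <- sum(kValues) * length(locusFractions)
  new("CvReport", mode = "kfold", results = results,
      membership = membership, summary = rbind(perCond, overall),
      totalTests = as.integer(nTests),
      config = list(seed = seed, kValues = kValues,
                    locusFractions = locusFractions, model = model,
                    alpha = alpha, epsilon = epsilon))
}

#' Blind-test assignment of known-origin query individuals
#'
#' Fits the classifier (naive Bayes by default, the model used for blind
#' assignments) on the full reference and assigns every query individual.
#' Query population labels are never used for prediction; when present
#' (and not \code{"unknown"}) they are used to summarise correctness and
#' the membership probabilities of the correct and incorrect classes.
#'
#' @param reference a \linkS4class{SnpGenotypes} reference database.
#' @param query a \linkS4class{SnpGenotypes} of individuals to assign.
#' @param model,alpha,epsilon,loci classifier configuration (see
#'   \code{\link{fitClassifier}}).
#' @return list with \code{results} (per-individual memberships),
#'   \code{accuracy} (per-population counts, NULL when query labels are
#'   unknown) and \code{summary} (per-population mean/SD membership of the
#'   correct and of the incorrect class).
#' @export
blindTest <- function(reference, query, model = "naive_bayes",
                      alpha = 1, epsilon = 1e-6, loci = NULL) {
  fit <- fitClassifier(reference, model = model, alpha = alpha,
                       epsilon = epsilon, loci = loci)
  res <- membershipProbabilities(fit, query)
  labels <- populations(query)
  known <- nrow(res) > 0 && all(labels %in% fit@populations)
  if (!known)
    return(list(results = res, accuracy = NULL, summary = NULL))
  acc <- assignmentAccuracy(res, labels)
  summ <- do.call(rbind, lapply(fit@populations, function(p) {
    idx <- labels == p
    corr <- res[[p]][idx]
    other <- setdiff(fit@populations, p)
    incorr <- unlist(res[idx, other, drop = FALSE])
    data.frame(population = p, n = sum(idx),
               n_correct = sum(res$predicted[idx] == p),
               membership_correct_mean = mean(corr),
               membership_correct_sd = if (sum(idx) > 1) stats::sd(corr)
                                       else NA_real_,
               membership_incorrect_mean = mean(incorr),
               membership_incorrect_sd = if (length(incorr) > 1)
                 stats::sd(incorr) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(results = res, accuracy = acc, summary = summ)
}

default_validation_config <- function() {
  list(seed = 1L,
       reference = list(source = "simulate-from-fixture",
                        nWolf = 80L, nDog = 90L),
       query = list(nWolf = 17L, nDog = 18L),
       stages = c("qc", "stats", "distances", "monte_carlo", "kfold",
                  "blind"),
       qc = list(threshold = 0.90),
       monte_carlo = list(trainProportions = c(0.5, 0.7, 0.9),
                          locusFractions = c(0.10, 0.25, 0.50, 1.0),
                          nResamples = 30L, model = "lda"),
       kfold = list(kValues = c(3, 4, 5),
                    locusFractions = c(0.10, 0.25, 0.50, 1.0),
                    model = "naive_bayes"),
       blind = list(model = "naive_bayes", alpha = 1))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full validation workflow
#'
#' Executes the validation stages in order -- QC filtering, marker
#' statistics, distance separation, Monte-Carlo CV, K-fold CV and blind
#' testing -- against either a genotype file or references simulated from
#' the bundled frequency database, writing one CSV/JSON per stage plus a
#' combined JSON summary and a run manifest (seeds and configuration) to
#' \code{outdir}. A fixed master seed makes the whole bundle reproducible;
#' per-stage child seeds are derived from it and logged.
#'
#' @param config a configuration list, or path to a YAML/JSON file
#'   mirroring one. Any subset of the default configuration (see the
#'   package vignette) may be supplied; \code{stages} selects which stages
#'   run.
#' @param outdir output directory (created if needed).
#' @return (invisibly) a list with each executed stage's in-memory result.
#' @export
runFullValidation <- function(config = list(), outdir) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  cfg <- merge_config(default_validation_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  childSeeds <- list(wolf = seed + 1L, dog = seed + 2L,
                     queryWolf = seed + 3L, queryDog = seed + 4L,
                     monte_carlo = seed + 10L, kfold = seed + 20L)

  bundle <- loadBundledPanel()
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("validation stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("qc" %in% cfg$stages) {
    qc <- stage("qc", qcFilterLoci(bundle$success, cfg$qc$threshold))
    utils::write.csv(qc, file.path(outdir, "qc.csv"), row.names = FALSE)
    out$qc <- qc
  }

  # reference genotypes: simulated from the fixture or read from file
  ref <- stage("reference", {
    if (identical(cfg$reference$source, "simulate-from-fixture")) {
      rbind2(simulatePopulation(bundle$frequencies, "wolf",
                                cfg$reference$nWolf,
                                seed = childSeeds$wolf,
                                idPrefix = "ref_wolf"),
             simulatePopulation(bundle$frequencies, "dog",
                                cfg$reference$nDog,
                                seed = childSeeds$dog,
                                idPrefix = "ref_dog"))
    } else {
      readGenotypeTable(cfg$reference$path, bundle$frequencies@panel,
                        format = cfg$reference$format)
    }
  })
  out$reference <- ref

  if ("stats" %in% cfg$stages) {
    st <- stage("stats", {
      fr <- alleleFrequencies(ref)
      differentialSummary(fr, "wolf", "dog")
    })
    utils::write.csv(st$perLocus, file.path(outdir, "marker_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(st$summary,
                     file.path(outdir, "marker_stats_summary.csv"),
                     row.names = FALSE)
    out$stats <- st
  }

  if ("distances" %in% cfg$stages) {
    dres <- stage("distances", {
      d <- pairwiseDistances(ref)
      summ <- distanceSummaries(d, populations(ref), "wolf", "dog")
      pr <- distance_pairs(d, populations(ref), "wolf", "dog")
      intra <- c(pr$intra_pop1, pr$intra_pop2)
      wt <- welchSeparationTest(intra, pr$inter)
      gaps <- list(normal = separationGap(intra, pr$inter, "normal"),
                   percentile = separationGap(intra, pr$inter,
                                              "percentile"))
      list(summary = summ, welch = wt, gaps = gaps)
    })
    utils::write.csv(dres$summary,
                     file.path(outdir, "distance_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(welch = dres$welch, gaps = dres$gaps),
                         file.path(outdir, "distance_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    out$distances <- dres
  }

  if ("monte_carlo" %in% cfg$stages) {
    mc <- stage("monte_carlo", do.call(monteCarloCv, c(
      list(reference = ref, seed = childSeeds$monte_carlo),
      cfg$monte_carlo)))
    utils::write.csv(cvResults(mc), file.path(outdir, "mc_cv.csv"),
                     row.names = FALSE)
    out$monte_carlo <- mc
  }

  if ("kfold" %in% cfg$stages) {
    kf <- stage("kfold", do.call(kfoldCv, c(
      list(reference = ref, seed = childSeeds$kfold), cfg$kfold)))
    utils::write.csv(cvResults(kf), file.path(outdir, "kfold_cv.csv"),
                     row.names = FALSE)
    out$kfold <- kf
  }

  if ("blind" %in% cfg$stages) {
    bl <- stage("blind", {
      query <- rbind2(
        simulatePopulation(bundle$frequencies, "wolf", cfg$query$nWolf,
                           seed = childSeeds$queryWolf,
                           idPrefix = "query_wolf"),
        simulatePopulation(bundle$frequencies, "dog", cfg$query$nDog,
                           seed = childSeeds$queryDog,
                           idPrefix = "query_dog"))
      do.call(blindTest, c(list(reference = ref, query = query),
                           cfg$blind))
    })
    utils::write.csv(bl$results, file.path(outdir, "blind.csv"),
                     row.names = FALSE)
    out$blind <- bl
  }

  summary <- list(
    seed = seed, childSeeds = childSeeds, stages = cfg$stages,
    nReference = nIndividuals(ref),
    mcTests = if (!is.null(out$monte_carlo)) totalTests(out$monte_carlo),
    kfoldTests = if (!is.null(out$kfold)) totalTests(out$kfold),
    blindCorrect = if (!is.null(out$blind) && !is.null(out$blind$accuracy))
      out$blind$accuracy)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(package = "canidassign",
                   version = as.character(utils::packageVersion("canidassign")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   config = cfg, childSeeds = childSeeds)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out)
}
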