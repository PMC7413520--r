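bp <- loadBundledPanel()

# independent enumeration oracle: smoothed per-locus probabilities computed
# straight from counts, joint likelihood as an explicit product over loci
enumerate_posteriors <- function(train, query, alpha) {
  pops <- unique(populations(train))
  L <- nLoci(train)
  probTab <- lapply(pops, function(p) {
    m <- genotypeCalls(train)[populations(train) == p, , drop = FALSE]
    sapply(seq_len(L), function(k) {
      v <- m[, k]; v <- v[!is.na(v)]
      (c(sum(v == 2), sum(v == 1), sum(v == 0)) + alpha) /
        (length(v) + 3 * alpha)
    })   # 3 x L, rows HOM_A/HET/HOM_B
  })
  names(probTab) <- pops
  t(apply(genotypeCalls(query), 1, function(row) {
    lik <- vapply(pops, function(p) {
      prod(vapply(seq_len(L), function(k) {
        if (is.na(row[k])) 1 else probTab[[p]][3 - row[k], k]
      }, numeric(1)))
    }, numeric(1))
    lik / sum(lik)
  }))
}

test_that("naive Bayes smoothing matches the Laplace closed form", {
  pan <- toy_panel(1)
  train <- toy_genotypes(matrix(c(rep(2L, 80), rep(0L, 90)), ncol = 1),
                         c(rep("wolf", 80), rep("dog", 90)), pan)
  fit <- fitClassifier(train, "naive_bayes", alpha = 1)
  expect_equal(fit@fit$probs["rs01", "HOM_A", "wolf"], 81 / 83)
  expect_equal(fit@fit$probs["rs01", "HOM_B", "wolf"], 1 / 83)
  # alpha = 0 with no zero counts gives the raw proportions
  train2 <- toy_genotypes(matrix(c(2L, 1L, 0L, 2L, 0L, 1L), ncol = 1),
                          rep(c("a", "b"), each = 3), pan)
  fit2 <- fitClassifier(train2, "naive_bayes", alpha = 0)
  expect_equal(unname(fit2@fit$probs["rs01", , "a"]), c(1, 1, 1) / 3)
  expect_warning(fitClassifier(train, "naive_bayes", alpha = 0), "zero")
})

test_that("single-locus heterozygote posterior equals the two-term Bayes ratio", {
  pan <- toy_panel(1)
  train <- toy_genotypes(matrix(c(2L, 1L, 0L, 0L), ncol = 1),
                         c("a", "a", "b", "b"), pan)
  fit <- fitClassifier(train, "naive_bayes", alpha = 1)
  # P(HET|a) = (1+1)/(2+3) = 2/5, P(HET|b) = (0+1)/(2+3) = 1/5
  q <- toy_genotypes(matrix(1L, 1, 1), "unknown", pan)
  res <- membershipProbabilities(fit, q)
  expect_equal(res$a, (2 / 5) / (2 / 5 + 1 / 5))
  expect_equal(res$b, 1 / 3)
})

test_that("posteriors normalise, permute with labels, and ignore missing loci", {
  freqs <- toy_two_pop_freqs()
  train <- rbind2(simulatePopulation(freqs, "popA", 30, seed = 3),
                  simulatePopulation(freqs, "popB", 30, seed = 4))
  query <- simulatePopulation(freqs, "popA", 20, seed = 5)
  for (model in c("naive_bayes", "lda")) {
    fit <- fitClassifier(train, model)
    res <- membershipProbabilities(fit, query)
    expect_true(all(abs(res$popA + res$popB - 1) < 1e-9))
    expect_true(all(is.finite(res$loglik_popA)))
    # swapping population labels swaps membership columns exactly
    swapped <- SnpGenotypes(genotypeCalls(train),
                            c(popA = "popB", popB = "popA")[populations(train)],
                            panel(train))
    fitSw <- fitClassifier(swapped, model)
    resSw <- membershipProbabilities(fitSw, query)
    # the class called popA now carries popB's data, so columns swap
    expect_equal(res$popA, resSw$popB, tolerance = 1e-9)
    expect_equal(res$popB, resSw$popA, tolerance = 1e-9)
  }
  # missing loci contribute nothing: posterior from remaining loci only
  fit <- fitClassifier(train, "naive_bayes")
  calls <- genotypeCalls(query)
  calls[, 2:3] <- NA
  qMiss <- SnpGenotypes(calls, populations(query), panel(query))
  resMiss <- membershipProbabilities(fit, qMiss)
  resOne <- membershipProbabilities(
    fitClassifier(train, "naive_bayes", loci = "rs01"), query)
  expect_equal(resMiss$popA, resOne$popA, tolerance = 1e-12)
  # individual missing everywhere is flagged unassignable
  calls[1, ] <- NA
  resNA <- membershipProbabilities(fit,
    SnpGenotypes(calls, populations(query), panel(query)))
  expect_true(resNA$unassignable[1])
  expect_true(is.na(resNA$predicted[1]))
})

test_that("naive Bayes agrees with exhaustive enumeration on small panels", {
  freqs <- toy_two_pop_freqs()
  train <- rbind2(simulatePopulation(freqs, "popA", 25, seed = 7),
                  simulatePopulation(freqs, "popB", 25, seed = 8))
  # query covers every possible 3-locus genotype combination
  combos <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  storage.mode(combos) <- "integer"
  query <- toy_genotypes(combos, "unknown", toy_panel(3))
  for (alpha in c(1, 0.5)) {
    fit <- fitClassifier(train, "naive_bayes", alpha = alpha)
    res <- membershipProbabilities(fit, query)
    oracle <- enumerate_posteriors(train, query, alpha)
    expect_equal(res$popA, unname(oracle[, "popA"]), tolerance = 1e-12)
  }
})

test_that("naive Bayes matches e1071 on identical training data", {
  freqs <- toy_two_pop_freqs()
  # equal class sizes so e1071's empirical priors equal our flat priors
  train <- rbind2(simulatePopulation(freqs, "popA", 40, seed = 9),
                  simulatePopulation(freqs, "popB", 40, seed = 10))
  query <- rbind2(simulatePopulation(freqs, "popA", 15, seed = 11),
                  simulatePopulation(freqs, "popB", 15, seed = 12))
  toFactors <- function(g)
    as.data.frame(lapply(as.data.frame(genotypeCalls(g)),
                         factor, levels = 0:2))
  nb <- e1071::naiveBayes(toFactors(train),
                          factor(populations(train)), laplace = 1)
  ours <- membershipProbabilities(
    fitClassifier(train, "naive_bayes", alpha = 1), query)
  theirs <- predict(nb, toFactors(query), type = "raw")
  expect_equal(ours$popA, unname(theirs[, "popA"]), tolerance = 1e-6)
})

test_that("LDA matches MASS::lda posteriors on well-conditioned data", {
  freqs <- toy_two_pop_freqs()
  train <- rbind2(simulatePopulation(freqs, "popA", 60, seed = 13),
                  simulatePopulation(freqs, "popB", 60, seed = 14))
  query <- rbind2(simulatePopulation(freqs, "popA", 20, seed = 15),
                  simulatePopulation(freqs, "popB", 20, seed = 16))
  fit <- fitClassifier(train, "lda", epsilon = 1e-10)
  ours <- membershipProbabilities(fit, query)
  X <- encodeGenotypes(train, "allele_fraction")
  ml <- MASS::lda(X, grouping = populations(train), prior = c(0.5, 0.5))
  post <- predict(ml, encodeGenotypes(query, "allele_fraction"))$posterior
  expect_equal(ours$popA, unname(post[, "popA"]), tolerance = 1e-6)
})

test_that("LDA handles degenerate geometry via the ridge", {
  # two classes with identical feature distributions: posteriors ~ 0.5
  pan <- toy_panel(2)
  calls <- matrix(rep(c(2L, 0L, 1L, 1L), 2), 4, 2)
  train <- toy_genotypes(rbind(calls, calls),
                         rep(c("a", "b"), each = 4), pan)
  fit <- fitClassifier(train, "lda")
  res <- membershipProbabilities(fit,
    toy_genotypes(matrix(c(1L, 1L), 1, 2), "unknown", pan))
  expect_equal(res$a, 0.5, tolerance = 1e-6)
  # loci fixed in both classes (zero within-class variance) must not error
  fixedTrain <- rbind2(
    simulatePopulation(bp$frequencies, "wolf", 20, seed = 17),
    simulatePopulation(bp$frequencies, "dog", 20, seed = 18))
  expect_s4_class(fitClassifier(fixedTrain, "lda"), "SnpClassifier")
})

test_that("hybrids sit between the reference posteriors and get flagged", {
  ref <- simulate_reference(bp, 60, 60, seed = 19)
  fit <- fitClassifier(ref, "naive_bayes")
  f1 <- simulateF1Hybrids(bp$frequencies, "wolf", "dog", 30, seed = 20)
  res <- membershipProbabilities(fit, f1)
  expect_gt(mean(res$possible_hybrid), 0.8)
  pure <- simulatePopulation(bp$frequencies, "wolf", 30, seed = 21)
  resPure <- membershipProbabilities(fit, pure)
  expect_lt(mean(resPure$possible_hybrid), 0.3)
})

test_that("accuracy bookkeeping counts correct assignments per population", {
  res <- data.frame(individual_id = letters[1:10],
                    predicted = c(rep("dog", 9), "wolf"))
  acc <- assignmentAccuracy(res, rep("dog", 10))
  expect_equal(acc$accuracy[acc$population == "dog"], 0.9)
  expect_equal(acc$n_correct[acc$population == "overall"], 9)
  expect_null(assignmentAccuracy(res, NULL))
})

test_that("classifier preconditions are enforced", {
  pan <- toy_panel(2)
  one <- toy_genotypes(matrix(1L, 3, 2), "only", pan)
  expect_error(fitClassifier(one, "naive_bayes"), "two populations")
  small <- toy_genotypes(matrix(1L, 3, 2), c("a", "a", "b"), pan)
  expect_error(fitClassifier(small, "naive_bayes"), "at least 2")
  ok <- toy_genotypes(matrix(1L, 4, 2), c("a", "a", "b", "b"), pan)
  expect_error(fitClassifier(ok, "naive_bayes", loci = character(0)),
               "empty locus subset")
  expect_error(fitClassifier(ok, "naive_bayes", loci = "rs99"), "lacks")
})
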