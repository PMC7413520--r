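bp <- loadBundledPanel()

test_that("Monte-Carlo CV executes the configured grid deterministically", {
  ref <- simulate_reference(bp, 30, 30, seed = 41)
  mc <- monteCarloCv(ref, seed = 1, trainProportions = c(0.5, 0.7),
                     locusFractions = c(0.25, 1.0), nResamples = 3)
  expect_s4_class(mc, "CvReport")
  expect_equal(totalTests(mc), 2 * 2 * 3)
  res <- cvResults(mc)
  expect_equal(nrow(res), 2 * 2 * 3 * 2)   # one row per test x population
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  expect_true(all(res$n_loci[res$locus_fraction == 0.25] == 3))
  expect_true(all(res$n_loci[res$locus_fraction == 1] == 12))
  mc2 <- monteCarloCv(ref, seed = 1, trainProportions = c(0.5, 0.7),
                      locusFractions = c(0.25, 1.0), nResamples = 3)
  expect_identical(cvResults(mc), cvResults(mc2))
  mc3 <- monteCarloCv(ref, seed = 2, trainProportions = c(0.5, 0.7),
                      locusFractions = c(0.25, 1.0), nResamples = 3)
  expect_false(identical(cvResults(mc), cvResults(mc3)))
})

test_that("CV rejects grids that empty a training or test set", {
  ref <- simulate_reference(bp, 5, 5, seed = 43)
  expect_error(monteCarloCv(ref, seed = 1, trainProportions = 1.0),
               "empty test set")
  expect_error(monteCarloCv(ref, seed = 1, trainProportions = 0.2),
               "fewer than 2")
  expect_error(kfoldCv(ref, seed = 1, kValues = 6), "exceeds")
  one <- simulatePopulation(bp$frequencies, "wolf", 10, seed = 1)
  expect_error(monteCarloCv(one, seed = 1), "two populations")
})

test_that("perfectly separated populations score accuracy 1 in every cell", {
  pan <- toy_panel(3)
  # disjoint fixed genotypes at every locus
  a <- toy_genotypes(matrix(2L, 12, 3), "a", pan, prefix = "a")
  b <- toy_genotypes(matrix(0L, 12, 3), "b", pan, prefix = "b")
  ref <- rbind2(a, b)
  mc <- monteCarloCv(ref, seed = 5, trainProportions = 0.5,
                     locusFractions = c(1 / 3, 1.0), nResamples = 5,
                     model = "naive_bayes")
  expect_true(all(cvResults(mc)$accuracy == 1))
  kf <- kfoldCv(ref, seed = 5, kValues = 3, locusFractions = 1.0)
  expect_true(all(cvResults(kf)$accuracy == 1))
  expect_true(all(cvResults(kf)$mean_membership > 0.99))
})

test_that("locus selection sees training data only", {
  ref <- simulate_reference(bp, 30, 30, seed = 47)
  trainIdx <- c(1:20, 31:50)
  testIdx <- setdiff(1:60, trainIdx)
  loci1 <- canidassign:::select_training_loci(ref[trainIdx, ],
                                              "wolf", "dog", 0.25)
  # corrupt every held-out genotype; the selected subset must not move
  calls <- genotypeCalls(ref)
  calls[testIdx, ] <- 2L - calls[testIdx, ]
  refCorrupt <- SnpGenotypes(calls, populations(ref), panel(ref))
  loci2 <- canidassign:::select_training_loci(refCorrupt[trainIdx, ],
                                              "wolf", "dog", 0.25)
  expect_identical(loci1, loci2)
})

test_that("K-fold CV builds balanced stratified folds and counts tests", {
  ref <- simulate_reference(bp, 80, 90, seed = 53)
  kf <- kfoldCv(ref, seed = 2, kValues = 3, locusFractions = 1.0)
  expect_equal(totalTests(kf), 3)
  # n = 80 in 3 folds: sizes 27/27/26 per population
  mem <- kf@membership
  wolfFold <- table(mem$fold[mem$population == "wolf"])
  expect_setequal(as.integer(wolfFold), c(27, 27, 26))
  dogFold <- table(mem$fold[mem$population == "dog"])
  expect_true(all(as.integer(dogFold) == 30))
  # every individual held out exactly once per (k, fraction)
  expect_equal(sort(unique(table(mem$individual_id))), 1)
  expect_equal(nrow(mem), 170)
  # deterministic rerun
  kf2 <- kfoldCv(ref, seed = 2, kValues = 3, locusFractions = 1.0)
  expect_identical(kf@membership, kf2@membership)
  expect_equal(canidassign:::fold_sizes(80, 3), c(27, 27, 26))
})

test_that("blind test summarises correctness without using query labels", {
  ref <- simulate_reference(bp, 40, 40, seed = 59)
  # a query identical to a reference individual follows its population
  q1 <- ref[1, ]
  q1 <- SnpGenotypes(genotypeCalls(q1), "unknown", panel(q1))
  bt <- blindTest(ref, q1)
  expect_equal(bt$results$predicted, populations(ref)[1])
  expect_null(bt$accuracy)   # unknown labels: no correctness summary
  # empty query
  empty <- ref[integer(0), ]
  bt0 <- blindTest(ref, empty)
  expect_equal(nrow(bt0$results), 0)
  # labelled queries produce per-population summaries
  q <- rbind2(simulatePopulation(bp$frequencies, "wolf", 6, seed = 61),
              simulatePopulation(bp$frequencies, "dog", 6, seed = 62))
  bt2 <- blindTest(ref, q)
  expect_s3_class(bt2$summary, "data.frame")
  expect_equal(bt2$summary$n, c(6, 6))
  expect_true(all(bt2$summary$membership_correct_mean >
                    bt2$summary$membership_incorrect_mean))
})

test_that("full validation bundle is reproducible and configurable", {
  cfg <- list(seed = 11,
              reference = list(source = "simulate-from-fixture",
                               nWolf = 25L, nDog = 25L),
              query = list(nWolf = 4L, nDog = 4L),
              monte_carlo = list(trainProportions = 0.5,
                                 locusFractions = 1.0, nResamples = 2L),
              kfold = list(kValues = 3, locusFractions = 1.0))
  out1 <- withr::local_tempdir()
  res1 <- runFullValidation(cfg, out1)
  expect_true(all(file.exists(file.path(out1,
    c("qc.csv", "marker_stats.csv", "distance_summary.csv", "mc_cv.csv",
      "kfold_cv.csv", "blind.csv", "summary.json", "manifest.json")))))
  summ <- jsonlite::read_json(file.path(out1, "summary.json"),
                              simplifyVector = TRUE)
  expect_equal(summ$mcTests, 2)
  expect_equal(summ$kfoldTests, 3)
  out2 <- withr::local_tempdir()
  runFullValidation(cfg, out2)
  for (f in c("qc.csv", "mc_cv.csv", "kfold_cv.csv", "blind.csv"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  # omitting a stage drops exactly that section
  cfg$stages <- c("qc", "stats")
  out3 <- withr::local_tempdir()
  res3 <- runFullValidation(cfg, out3)
  expect_false(file.exists(file.path(out3, "blind.csv")))
  expect_null(res3$blind)
  # a YAML config file round-trips through the same path
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  out4 <- withr::local_tempdir()
  expect_no_error(runFullValidation(yml, out4))
})
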