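bp <- loadBundledPanel()

test_that("frequency estimation matches exact small cases", {
  g <- toy_genotypes(matrix(c(1L, 1L, 1L), 3, 1), "x", toy_panel(1))
  fr <- alleleFrequencies(g)
  expect_equal(unname(alleleFrequencies(fr)[1, "x"]), 0.5)   # all HET
  g2 <- toy_genotypes(matrix(0L, 1, 1), "y", toy_panel(1))
  expect_equal(unname(alleleFrequencies(alleleFrequencies(g2))[1, "y"]), 0)
  # missing calls are excluded from the denominator
  g3 <- toy_genotypes(matrix(c(2L, 2L, NA, 0L), 4, 1), "z", toy_panel(1))
  expect_equal(unname(genotypeFrequencies(alleleFrequencies(g3), "z")),
               c(2 / 3, 0, 1 / 3), ignore_attr = TRUE)
  gAllMiss <- toy_genotypes(matrix(NA_integer_, 2, 1), "w", toy_panel(1))
  expect_error(alleleFrequencies(gAllMiss), "no non-missing")
})

test_that("estimated frequencies recover the generating table", {
  n <- 8000
  for (p in c("wolf", "dog")) {
    g <- simulatePopulation(bp$frequencies, p, n, seed = 31)
    est <- genotypeFrequencies(alleleFrequencies(g), p)
    src <- genotypeFrequencies(bp$frequencies, p)
    src <- src / rowSums(src)
    se <- sqrt(src * (1 - src) / n)
    expect_true(all(abs(est - src) <= 3 * se + 1e-12))
  }
})

test_that("differential summary reproduces the published table", {
  ds <- differentialSummary(bp$frequencies, "wolf", "dog")
  # every printed between-population differential, to printing precision
  expect_true(all(abs(ds$perLocus$between -
                        unname(bp$printedDifferentials)) <= 0.001))
  s <- ds$summary
  expect_lt(abs(s$mean[s$differential == "between"] - 0.797), 0.001)
  expect_lt(abs(s$sd[s$differential == "between"] - 0.080), 0.001)
  expect_lt(abs(s$min[s$differential == "between"] - 0.640), 0.001)
  expect_lt(abs(s$max[s$differential == "between"] - 0.889), 0.001)
  expect_lt(abs(s$mean[s$differential == "within_pop1"] - 0.939), 0.001)
  expect_lt(abs(s$mean[s$differential == "within_pop2"] - 0.656), 0.001)
  # two identical populations: all differentials vanish
  pan <- toy_panel(2)
  same <- matrix(c(0.5, 0.3, 0.2, 0.2, 0.5, 0.3), 2, 3, byrow = TRUE)
  dsSame <- differentialSummary(toy_freqs(pan, a = same, b = same), "a", "b")
  expect_true(all(dsSame$perLocus$between == 0))
  expect_true(all(dsSame$perLocus$fst == 0))
})

test_that("Gst has its analytic limits and symmetries", {
  pan <- toy_panel(1)
  mk <- function(p1, p2) {
    toy_freqs(pan, a = matrix(c(p1, 0, 1 - p1), 1, 3),
              b = matrix(c(p2, 0, 1 - p2), 1, 3))
  }
  expect_equal(locusFst(mk(0.4, 0.4), "a", "b", "rs01"), 0)
  expect_equal(locusFst(mk(1, 0), "a", "b", "rs01"), 1)
  expect_equal(locusFst(mk(0, 0), "a", "b", "rs01"), 0)  # H_T = 0 case
  # frozen hand computation: p1 = 1, p2 = 0.111
  # H_T = 0.4938395, H_S = 0.0986790, Gst = 0.8001800
  expect_equal(locusFst(mk(1, 0.111), "a", "b", "rs01"), 0.80018,
               tolerance = 1e-5)
  # complement symmetry: counting the other allele gives the same Gst
  for (pp in list(c(0.9, 0.2), c(0.63, 0.18), c(0.5, 0.01))) {
    f1 <- locusFst(mk(pp[1], pp[2]), "a", "b", "rs01")
    f2 <- locusFst(mk(1 - pp[1], 1 - pp[2]), "a", "b", "rs01")
    expect_equal(f1, f2)
  }
  # monotone separation: fixed mean frequency, growing |p1 - p2|
  deltas <- seq(0.05, 0.45, by = 0.05)
  vals <- vapply(deltas, function(d)
    locusFst(mk(0.5 + d, 0.5 - d), "a", "b", "rs01"), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("top-Fst selection sizes and ties follow round-half-up rules", {
  ds <- differentialSummary(bp$frequencies, "wolf", "dog")$perLocus
  expect_length(selectTopFstLoci(ds, 0.10), 1)   # round(1.2) = 1
  expect_length(selectTopFstLoci(ds, 0.25), 3)
  expect_length(selectTopFstLoci(ds, 0.50), 6)
  expect_identical(selectTopFstLoci(ds, 1.0), ds$locus_id)  # panel order
  top1 <- selectTopFstLoci(ds, 0.10)
  expect_equal(top1, ds$locus_id[which.max(ds$fst)])
  # ties broken by locus id ascending
  tied <- data.frame(locus_id = c("rsB", "rsA", "rsC"),
                     fst = c(0.5, 0.5, 0.1))
  expect_equal(selectTopFstLoci(tied, 1 / 3), "rsA")
  expect_error(selectTopFstLoci(ds, 0), "fraction")
  expect_error(selectTopFstLoci(ds, 1.2), "fraction")
  # floor of one locus even for tiny fractions
  expect_length(selectTopFstLoci(ds, 0.01), 1)
})

test_that("QC filtering retains loci meeting the threshold in every population", {
  qc <- qcFilterLoci(bp$success, threshold = 0.90)
  expect_equal(sum(qc$retained), 12)
  expect_equal(qc$locus_id[!qc$retained], "rs22103787")
  expect_match(qc$reason[!qc$retained], "dog \\(0.444\\)")
  # permissive threshold keeps all 13
  qc0 <- qcFilterLoci(bp$success, threshold = 1e-6)
  expect_equal(sum(qc0$retained), 13)
  # threshold 1.0: only loci at 1.000 in both wolf and dog
  qc1 <- qcFilterLoci(bp$success, threshold = 1.0)
  expect_setequal(qc1$locus_id[qc1$retained],
                  c("rs23249721", "rs24198287", "rs24863098"))
})

test_that("success averaging reproduces the published panel means", {
  qc <- qcFilterLoci(bp$success)
  keep <- qc$locus_id[qc$retained]
  m <- successSummary(bp$success, keep)
  expect_equal(round(unname(m["wolf"]), 3), 0.990)
  expect_equal(round(unname(m["dog"]), 3), 0.993)
  expect_equal(round(unname(m["overall"]), 3), 0.991)
  # all-1 subset averages to exactly 1
  ones <- c("rs23249721", "rs24198287", "rs24863098")
  expect_equal(unname(successSummary(bp$success, ones)),
               c(1, 1, 1), ignore_attr = TRUE)
  expect_error(successSummary(bp$success, character(0)), "non-empty")
})
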