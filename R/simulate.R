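#' @include accessors.R
NULL

# run code under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# one uniform per (individual, locus), consumed individuals-major
uniform_grid <- function(n, L, draws = 1L) {
  matrix(stats::runif(n * L * draws), n, L * draws, byrow = TRUE)
}

normalise_probs <- function(p) p / sum(p)

#' Simulate reference individuals from a population frequency table
#'
#' Draws individuals i.i.d. per locus from a population's genotype-state
#' distribution, emulating reference groups sampled from the frequency
#' database. Loci are simulated independently (linkage equilibrium). Two
#' modes: \code{"genotype_freq"} (default) samples the three genotype-state
#' probabilities directly, preserving any departure from Hardy-Weinberg
#' proportions present in the table; \code{"hwe"} draws the allele_a dosage
#' as Binomial(2, P(allele_a)). The two modes have the same limiting
#' genotype distribution exactly when the table's genotype probabilities
#' satisfy Hardy-Weinberg proportions.
#'
#' @param freqs a \linkS4class{PopulationFrequencies}.
#' @param population population label present in \code{freqs}.
#' @param n number of individuals (positive).
#' @param seed integer seed; fully determines the output.
#' @param mode \code{"genotype_freq"} or \code{"hwe"}.
#' @param missingness optional \linkS4class{GenotypingSuccess}; when given,
#'   calls are masked via \code{\link{applyMissingness}} (with a seed
#'   derived from \code{seed}).
#' @param idPrefix prefix for generated individual ids.
#' @return A \linkS4class{SnpGenotypes} with all individuals labelled
#'   \code{population}.
#' @examples
#' bp <- loadBundledPanel()
#' wolves <- simulatePopulation(bp$frequencies, "wolf", n = 80, seed = 7)
#' table(genotypeCalls(wolves)[, "rs22835438"])  # locus fixed in wolf
#' @export
simulatePopulation <- function(freqs, population, n, seed,
                               mode = c("genotype_freq", "hwe"),
                               missingness = NULL,
                               idPrefix = population) {
  mode <- match.arg(mode)
  stopifnot(is(freqs, "PopulationFrequencies"))
  if (!population %in% populations(freqs))
    stop("population not present in frequency table: ", population,
         call. = FALSE)
  if (length(n) != 1 || is.na(n) || n <= 0 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  L <- nLoci(panel(freqs))
  gf <- genotypeFrequencies(freqs, population)

  calls <- with_seed(seed, {
    u <- uniform_grid(n, L)
    out <- matrix(NA_integer_, n, L)
    for (k in seq_len(L)) {
      if (mode == "genotype_freq") {
        pr <- normalise_probs(gf[k, ])
        # HOM_A below pr[1], HET below pr[1]+pr[2], else HOM_B
        out[, k] <- ifelse(u[, k] < pr["HOM_A"], 2L,
                           ifelse(u[, k] < pr["HOM_A"] + pr["HET"], 1L, 0L))
      } else {
        pr <- normalise_probs(gf[k, ])
        pa <- pr["HOM_A"] + pr["HET"] / 2
        out[, k] <- as.integer(stats::qbinom(u[, k], 2, pa))
      }
    }
    out
  })
  rownames(calls) <- sprintf("%s_%04d", idPrefix, seq_len(n))
  colnames(calls) <- locusIds(freqs)
  g <- SnpGenotypes(calls, population, panel(freqs))
  if (!is.null(missingness))
    g <- applyMissingness(g, missingness, seed = seed + 1L)
  g
}

#' Simulate first-generation (F1) hybrids between two populations
#'
#' Each individual receives, at every locus, one allele drawn from
#' population a's allele frequencies and one from population b's, the
#' genotype of a first-generation cross under random mating between the two
#' gene pools. Used to probe how intermediate genotypes behave under
#' assignment (the advisory hybrid flag).
#'
#' @param freqs a \linkS4class{PopulationFrequencies} covering both parent
#'   populations (or a second table via \code{freqsB}).
#' @param populationA,populationB parent population labels.
#' @param n number of hybrids.
#' @param seed integer seed.
#' @param freqsB optional second \linkS4class{PopulationFrequencies} for
#'   \code{populationB}; defaults to \code{freqs}.
#' @param label population label for the output (default \code{"F1"}).
#' @return A \linkS4class{SnpGenotypes}.
#' @export
simulateF1Hybrids <- function(freqs, populationA, populationB, n, seed,
                              freqsB = freqs, label = "F1") {
  stopifnot(is(freqs, "PopulationFrequencies"),
            is(freqsB, "PopulationFrequencies"))
  if (!populationA %in% populations(freqs))
    stop("population not present: ", populationA, call. = FALSE)
  if (!populationB %in% populations(freqsB))
    stop("population not present: ", populationB, call. = FALSE)
  if (!identical(locusIds(freqs), locusIds(freqsB)))
    stop("parent frequency tables must cover the same panel loci",
         call. = FALSE)
  if (length(n) != 1 || is.na(n) || n <= 0 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  L <- nLoci(panel(freqs))
  pA <- alleleFrequencies(freqs)[, populationA]
  pB <- alleleFrequencies(freqsB)[, populationB]

  calls <- with_seed(seed, {
    # two allele draws per cell; consumption order: individual, locus, allele
    u <- uniform_grid(n, L, draws = 2L)
    uA <- u[, seq(1, 2 * L, by = 2), drop = FALSE]
    uB <- u[, seq(2, 2 * L, by = 2), drop = FALSE]
    dosA <- 1L * sweep(uA, 2, pA, "<")
    dosB <- 1L * sweep(uB, 2, pB, "<")
    dosA + dosB
  })
  rownames(calls) <- sprintf("%s_%04d", label, seq_len(n))
  colnames(calls) <- locusIds(freqs)
  SnpGenotypes(calls, label, panel(freqs))
}

#' Mask genotype calls according to per-locus genotyping success rates
#'
#' Each call is independently set missing with probability
#' 1 - success(locus, population), emulating one-time genotyping failure.
#' The input object is not modified.
#'
#' @param x a \linkS4class{SnpGenotypes}.
#' @param success a \linkS4class{GenotypingSuccess} covering the panel loci
#'   and every population label present in \code{x}.
#' @param seed integer seed.
#' @return A new \linkS4class{SnpGenotypes} with some calls set to NA.
#' @export
applyMissingness <- function(x, success, seed) {
  stopifnot(is(x, "SnpGenotypes"), is(success, "GenotypingSuccess"))
  s <- successRates(success)
  missLoci <- setdiff(locusIds(x), rownames(s))
  if (length(missLoci))
    stop("success table lacks loci: ", paste(missLoci, collapse = ", "),
         call. = FALSE)
  pops <- populations(x)
  missPops <- setdiff(unique(pops), colnames(s))
  if (length(missPops))
    stop("success table lacks populations: ",
         paste(missPops, collapse = ", "), call. = FALSE)
  n <- nIndividuals(x); L <- nLoci(x)
  calls <- genotypeCalls(x)
  if (n == 0) return(x)
  pFail <- 1 - s[locusIds(x), pops, drop = FALSE]   # loci x individuals
  drop <- with_seed(seed, uniform_grid(n, L) < t(pFail))
  calls[drop] <- NA_integer_
  SnpGenotypes(calls, pops, panel(x))
}
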