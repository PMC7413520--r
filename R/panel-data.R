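#' @include accessors.R
NULL

read_fixture <- function(file) {
  path <- system.file("extdata", file, package = "canidassign",
                      mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path))
    stop("bundled fixture not found: ", file,
         " (corrupted installation?)", call. = FALSE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Load the bundled wolf/dog SNP panel and its published frequency database
#'
#' Returns the 13-locus diallelic panel together with the one-time
#' genotyping success table (13 loci, wolf n = 97 / dog n = 108) and the
#' reference genotype/allele frequency database (the 12 retained loci, wolf
#' n = 80 / dog n = 90). The discarded locus rs22103787 has success data but
#' no frequency data, so it can be QC-filtered but not simulated.
#'
#' @return A list with elements \code{panel} (\linkS4class{SnpPanel}, 13
#'   loci), \code{frequencies} (\linkS4class{PopulationFrequencies}, 12
#'   loci), \code{success} (\linkS4class{GenotypingSuccess}, 13 loci) and
#'   \code{printedDifferentials} (named numeric vector: the published
#'   between-population allele frequency differences, for cross-checking).
#' @examples
#' bp <- loadBundledPanel()
#' nLoci(bp$panel)
#' alleleFrequencies(bp$frequencies)["rs22835438", ]
#' @export
loadBundledPanel <- function() {
  loci <- read_fixture("panel_loci.tsv")
  succ <- read_fixture("genotyping_success.tsv")
  freq <- read_fixture("reference_frequencies.tsv")
  if (!identical(sort(loci$locus_id), sort(succ$locus_id)))
    stop("fixture mismatch: panel loci and success table disagree")
  if (!all(freq$locus_id %in% loci$locus_id))
    stop("fixture mismatch: frequency table lists unknown loci")

  fullPanel <- SnpPanel(loci$locus_id, loci$allele_a, loci$allele_b)
  freqPanel <- fullPanel[freq$locus_id]
  freq <- freq[match(locusIds(freqPanel), freq$locus_id), ]

  arr <- array(NA_real_, dim = c(nrow(freq), 3, 2),
               dimnames = list(freq$locus_id, GENOTYPE_STATES,
                               c("wolf", "dog")))
  arr[, , "wolf"] <- as.matrix(freq[, c("wolf_hom_a", "wolf_het", "wolf_hom_b")])
  arr[, , "dog"] <- as.matrix(freq[, c("dog_hom_a", "dog_het", "dog_hom_b")])
  frequencies <- PopulationFrequencies(freqPanel, arr,
                                       sampleSize = c(wolf = 80, dog = 90))

  # internal consistency of the bundle: printed allele columns must agree
  # with the genotype-derived frequencies to printing precision
  pa <- alleleFrequencies(frequencies)
  printed <- cbind(wolf = freq$wolf_p_a, dog = freq$dog_p_a)
  if (any(abs(pa - printed) > 0.002 + 1e-9))
    stop("corrupted fixture: allele and genotype frequencies disagree")

  succ <- succ[match(loci$locus_id, succ$locus_id), ]
  sm <- as.matrix(succ[, c("wolf", "dog", "overall")])
  rownames(sm) <- succ$locus_id
  success <- GenotypingSuccess(sm,
                               sampleSize = c(wolf = 97, dog = 108,
                                              overall = 205))

  pd <- freq$printed_diff
  names(pd) <- freq$locus_id
  list(panel = fullPanel, frequencies = frequencies, success = success,
       printedDifferentials = pd)
}
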