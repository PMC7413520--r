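# small in-code fixtures shared across the suite

toy_panel <- function(L = 3) {
  SnpPanel(sprintf("rs%02d", seq_len(L)), rep("G", L), rep("T", L))
}

# freq spec: list of per-population L x 3 matrices (HOM_A, HET, HOM_B)
toy_freqs <- function(panel, ...) {
  popList <- list(...)
  arr <- array(NA_real_, dim = c(nLoci(panel), 3, length(popList)),
               dimnames = list(locusIds(panel), NULL, names(popList)))
  for (p in names(popList))
    arr[, , p] <- popList[[p]]
  PopulationFrequencies(panel, arr)
}

# genotype matrix straight from a dosage matrix
toy_genotypes <- function(dosages, population,
                          panel = toy_panel(ncol(dosages)), prefix = "i") {
  colnames(dosages) <- locusIds(panel)
  rownames(dosages) <- sprintf("%s%03d", prefix, seq_len(nrow(dosages)))
  SnpGenotypes(dosages, population, panel)
}

# two well-separated but polymorphic toy populations over 3 loci
toy_two_pop_freqs <- function() {
  A <- matrix(c(0.7, 0.2, 0.1,
                0.6, 0.3, 0.1,
                0.5, 0.4, 0.1), nrow = 3, byrow = TRUE)
  B <- matrix(c(0.1, 0.2, 0.7,
                0.1, 0.3, 0.6,
                0.1, 0.4, 0.5), nrow = 3, byrow = TRUE)
  toy_freqs(toy_panel(3), popA = A, popB = B)
}

simulate_reference <- function(bp, nWolf = 80, nDog = 90, seed = 1) {
  rbind2(simulatePopulation(bp$frequencies, "wolf", nWolf, seed = seed),
         simulatePopulation(bp$frequencies, "dog", nDog, seed = seed + 1))
}
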