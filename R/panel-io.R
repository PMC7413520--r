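#' @include accessors.R
NULL

MISSING_CSV <- "--"

genotype_string <- function(dosage, a, b) {
  out <- rep(MISSING_CSV, length(dosage))
  out[!is.na(dosage) & dosage == 2] <- paste0(a, a)
  out[!is.na(dosage) & dosage == 1] <- paste0(a, b)
  out[!is.na(dosage) & dosage == 0] <- paste0(b, b)
  out
}

parse_genotype_strings <- function(cells, locus, a, b) {
  up <- toupper(trimws(cells))
  out <- rep(NA_integer_, length(up))
  out[up == paste0(a, a)] <- 2L
  out[up %in% c(paste0(a, b), paste0(b, a))] <- 1L   # unordered pair
  out[up == paste0(b, b)] <- 0L
  bad <- which(is.na(out) & up != MISSING_CSV)
  if (length(bad))
    stop(sprintf(
      "invalid genotype '%s' at locus %s, row %d (expected alleles %s/%s or '--')",
      cells[bad[1]], locus, bad[1], a, b), call. = FALSE)
  out
}

#' Read a genotype table from CSV or Genepop
#'
#' CSV dialect: one row per individual, columns \code{individual_id},
#' \code{population}, then one two-character genotype string per locus
#' (e.g. \code{"GT"}; order-insensitive; missing = \code{"--"}). Genepop
#' dialect: one locus id per line (or a comma-separated list), individuals
#' in \code{POP} blocks with 2-digit allele codes (01 = allele_a,
#' 02 = allele_b, 00 = missing). Population labels for Genepop blocks are
#' taken from a \code{pops: a,b} annotation on the title line when present
#' (written by \code{\link{writeGenotypeTable}}), else \code{POP1},
#' \code{POP2}, ...
#'
#' @param path file to read.
#' @param panel the \linkS4class{SnpPanel} declaring the expected loci and
#'   allele pairs.
#' @param format \code{"csv"} or \code{"genepop"}.
#' @return A \linkS4class{SnpGenotypes}.
#' @seealso \code{\link{writeGenotypeTable}}
#' @export
readGenotypeTable <- function(path, panel, format = c("csv", "genepop")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") read_genotype_csv(path, panel)
  else read_genotype_genepop(path, panel)
}

read_genotype_csv <- function(path, panel) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  need <- c("individual_id", "population", locusIds(panel))
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("genotype table lacks required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  al <- alleles(panel)
  calls <- matrix(NA_integer_, nrow(df), nLoci(panel),
                  dimnames = list(df$individual_id, locusIds(panel)))
  for (k in seq_len(nLoci(panel)))
    calls[, k] <- parse_genotype_strings(df[[al$locus_id[k]]],
                                         al$locus_id[k],
                                         al$allele_a[k], al$allele_b[k])
  SnpGenotypes(calls, df$population, panel)
}

read_genotype_genepop <- function(path, panel) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("not a Genepop file: ", path, call. = FALSE)
  title <- lines[1]
  popLabels <- NULL
  m <- regmatches(title, regexec("pops:\\s*([^;]+)", title))[[1]]
  if (length(m) == 2) popLabels <- trimws(strsplit(m[2], ",")[[1]])

  body <- lines[-1]
  popAt <- which(toupper(trimws(body)) == "POP")
  if (!length(popAt)) stop("Genepop file has no POP block", call. = FALSE)
  locusLines <- trimws(body[seq_len(popAt[1] - 1)])
  loci <- trimws(unlist(strsplit(locusLines[nzchar(locusLines)], ",")))
  miss <- setdiff(locusIds(panel), loci)
  if (length(miss))
    stop("Genepop locus list lacks panel loci: ",
         paste(miss, collapse = ", "), call. = FALSE)

  ids <- character(); pops <- character(); rows <- list()
  block <- 0L
  for (i in seq(popAt[1], length(body))) {
    ln <- trimws(body[i])
    if (!nzchar(ln)) next
    if (toupper(ln) == "POP") { block <- block + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) != 2)
      stop("malformed Genepop sample line: ", ln, call. = FALSE)
    id <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop("Genepop sample ", id, " has ", length(codes),
           " genotypes for ", length(loci), " loci", call. = FALSE)
    dos <- vapply(codes, function(code) {
      if (nchar(code) != 4)
        stop("expected 4-digit Genepop genotype, got '", code, "'",
             call. = FALSE)
      a1 <- substr(code, 1, 2); a2 <- substr(code, 3, 4)
      if (a1 == "00" || a2 == "00") return(NA_integer_)
      if (!all(c(a1, a2) %in% c("01", "02")))
        stop("unknown Genepop allele code in '", code,
             "' (diallelic panel uses 01/02/00)", call. = FALSE)
      sum(c(a1, a2) == "01")
    }, integer(1), USE.NAMES = FALSE)
    names(dos) <- loci
    ids <- c(ids, id)
    pops <- c(pops, if (!is.null(popLabels) && block <= length(popLabels))
      popLabels[block] else paste0("POP", block))
    rows[[length(rows) + 1L]] <- dos[locusIds(panel)]
  }
  calls <- do.call(rbind, rows)
  if (is.null(calls))
    calls <- matrix(NA_integer_, 0, nLoci(panel),
                    dimnames = list(NULL, locusIds(panel)))
  rownames(calls) <- ids
  SnpGenotypes(calls, pops, panel)
}

#' Write a genotype table to CSV or Genepop
#'
#' Round-trips with \code{\link{readGenotypeTable}}: reading a written file
#' reproduces the calls, individual ids and population labels. The Genepop
#' format requires individuals grouped in per-population \code{POP} blocks,
#' so rows are emitted grouped by population (original order within each
#' population); population labels are recorded on the title line.
#'
#' @param x a \linkS4class{SnpGenotypes}.
#' @param path output file.
#' @param format \code{"csv"} or \code{"genepop"}.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeTable <- function(x, path, format = c("csv", "genepop")) {
  format <- match.arg(format)
  if (format == "csv") write_genotype_csv(x, path)
  else write_genotype_genepop(x, path)
  invisible(path)
}

write_genotype_csv <- function(x, path) {
  al <- alleles(panel(x))
  df <- data.frame(individual_id = as.character(individualIds(x)),
                   population = as.character(populations(x)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (k in seq_len(nrow(al)))
    df[[al$locus_id[k]]] <- genotype_string(genotypeCalls(x)[, k],
                                            al$allele_a[k], al$allele_b[k])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

write_genotype_genepop <- function(x, path) {
  pops <- populations(x)
  if (nrow(genotypeCalls(x)) > 0 && (anyNA(pops) || any(!nzchar(pops))))
    stop("Genepop output requires a declared population for every individual",
         call. = FALSE)
  popOrder <- unique(pops)
  header <- c(paste0("canidassign genotypes; pops: ",
                     paste(popOrder, collapse = ",")),
              locusIds(x))
  lines <- header
  for (p in popOrder) {
    lines <- c(lines, "POP")
    for (i in which(pops == p)) {
      dos <- genotypeCalls(x)[i, ]
      codes <- ifelse(is.na(dos), "0000",
                      c("0202", "0102", "0101")[dos + 1L])
      lines <- c(lines, paste0(individualIds(x)[i], " , ",
                               paste(codes, collapse = " ")))
    }
  }
  writeLines(lines, path)
}

#' Encode genotype calls as a numeric feature matrix
#'
#' Three encodings of the per-locus genotype state: \code{dosage} (count of
#' allele_a, 0/1/2), \code{allele_fraction} (dosage/2, 0/0.5/1, the feature
#' space of the LDA classifier) and \code{genotype_onehot} (three 0/1
#' indicator columns per locus, under which squared Euclidean distance
#' between individuals equals twice the number of genotype-mismatched loci).
#'
#' @param x a \linkS4class{SnpGenotypes}.
#' @param scheme encoding scheme.
#' @param allowMissing if \code{FALSE} (default), missing calls are an
#'   error; if \code{TRUE} they propagate as \code{NA} in every derived
#'   column (masked output).
#' @return numeric matrix, individuals in rows.
#' @examples
#' bp <- loadBundledPanel()
#' g <- simulatePopulation(bp$frequencies, "wolf", n = 4, seed = 1)
#' encodeGenotypes(g, "allele_fraction")
#' @export
encodeGenotypes <- function(x,
                            scheme = c("dosage", "genotype_onehot",
                                       "allele_fraction"),
                            allowMissing = FALSE) {
  scheme <- match.arg(scheme)
  calls <- genotypeCalls(x)
  if (!allowMissing && anyNA(calls))
    stop("genotype matrix contains missing calls; ",
         "set allowMissing = TRUE for masked output", call. = FALSE)
  if (scheme == "dosage") {
    out <- calls + 0.0
  } else if (scheme == "allele_fraction") {
    out <- calls / 2
  } else {
    L <- ncol(calls)
    out <- matrix(NA_real_, nrow(calls), 3L * L)
    colnames(out) <- paste(rep(colnames(calls), each = 3),
                           rep(GENOTYPE_STATES, L), sep = ".")
    for (k in seq_len(L)) {
      d <- calls[, k]
      block <- cbind(as.numeric(d == 2), as.numeric(d == 1),
                     as.numeric(d == 0))
      out[, (3 * k - 2):(3 * k)] <- block
    }
    rownames(out) <- rownames(calls)
  }
  out
}
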