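# Shared in-code fixtures: tiny genotype tables and registries used across
# test files. All data are built programmatically; nothing is read from disk
# except files the tests themselves write to tempdir().

# fully diagnostic 4-locus registry: allele "01" fixed in ME, "02" in MT
diag_registry <- function(L = 4L) {
  loci <- paste0("L", seq_len(L))
  biallelic_registry(stats::setNames(rep(0, L), loci),
                     stats::setNames(rep(1, L), loci))
}

diag_freqs <- function(L = 4L) {
  loci <- paste0("L", seq_len(L))
  biallelic_freqs(stats::setNames(rep(0, L), loci),
                  stats::setNames(rep(1, L), loci))
}

# pooled_table with the given dosage matrix, bypassing raw genotypes
pooled_fixture <- function(dosage, registry = NULL, sample_id = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); L <- ncol(dosage)
  loci <- paste0("L", seq_len(L))
  colnames(dosage) <- loci
  ids <- sprintf("i%03d", seq_len(n))
  rownames(dosage) <- ids
  if (is.null(registry))
    registry <- biallelic_registry(stats::setNames(rep(0.1, L), loci),
                                   stats::setNames(rep(0.9, L), loci))
  structure(list(dosage = dosage, individuals = ids, loci = loci,
                 sample_id = sample_id %||% rep("s1", n),
                 site_id = rep("s1", n), substrate = rep("unknown", n),
                 registry = registry),
            class = "pooled_table")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# small two-sample, 4-locus raw genotype table with one missing cell
tiny_table <- function() {
  loci <- c("Est-D", "Gpi", "Pgm", "Odh")
  a1 <- rbind(c("01", "01", "02", "01"),
              c("02", "02", "02", "02"),
              c("01", "02", "01", "01"),
              c("02", "02", "02", NA),
              c("01", "01", "01", "01"),
              c("02", "01", "02", "02"))
  a2 <- rbind(c("01", "02", "02", "01"),
              c("02", "02", "02", "02"),
              c("01", "01", "01", "02"),
              c("02", "02", "01", NA),
              c("01", "01", "01", "01"),
              c("02", "02", "02", "02"))
  genotype_table(paste0("ind", 1:6), loci, a1, a2,
                 sample_id = rep(c("A", "B"), each = 3L),
                 substrate = c("algae", "bottom", "algae",
                               "bottom", "algae", "bottom"))
}

# brute-force T-score: recount T alleles from raw labels via the registry
brute_tscore <- function(table, registry) {
  vapply(seq_along(table$individuals), function(i) {
    tot <- 0L; any_scored <- FALSE
    for (j in seq_along(table$loci)) {
      a <- c(table$a1[i, j], table$a2[i, j])
      if (anyNA(a)) next
      any_scored <- TRUE
      tot <- tot + sum(registry$pooling[[table$loci[j]]][a] == "T")
    }
    if (any_scored) tot else NA_integer_
  }, integer(1))
}
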