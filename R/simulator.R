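#' Ancestry classes
#'
#' The six genotypic classes used in calibration simulations, and their
#' compound mapping: purebreds map to themselves, all hybrid classes
#' (F1, F2 and the two first-generation backcrosses) to `"HYBRID"`.
#'
#' @format `ANCESTRY_CLASSES` is a character vector of the six class names;
#'   `compound_class(cls)` maps them to `ME` / `MT` / `HYBRID`.
#' @export
ANCESTRY_CLASSES <- c("ME", "MT", "F1", "F2", "BC_ME", "BC_MT")

#' @rdname ANCESTRY_CLASSES
#' @param cls character vector of ancestry class names.
#' @return character vector over `{ME, MT, HYBRID}`.
#' @export
compound_class <- function(cls) {
  bad <- setdiff(cls, ANCESTRY_CLASSES)
  if (length(bad)) stop("unknown ancestry class: ", paste(bad, collapse = ","))
  ifelse(cls %in% c("ME", "MT"), cls, "HYBRID")
}

#' Expected MT-ancestry proportion of each class
#' @param cls character vector of ancestry class names.
#' @return numeric vector in \[0, 1\].
#' @export
class_ancestry <- function(cls) {
  a <- c(ME = 0, MT = 1, F1 = 0.5, F2 = 0.5, BC_ME = 0.25, BC_MT = 0.75)
  bad <- setdiff(cls, names(a))
  if (length(bad)) stop("unknown ancestry class: ", paste(bad, collapse = ","))
  unname(a[cls])
}

check_freqs <- function(freqs) {
  for (tax in c("me", "mt")) {
    if (is.null(freqs[[tax]])) stop("freqs must have elements 'me' and 'mt'")
    for (l in names(freqs[[tax]]))
      if (abs(sum(freqs[[tax]][[l]]) - 1) > 1e-6)
        stop("frequencies at ", l, " (", tax, ") do not sum to 1")
  }
  if (!identical(names(freqs$me), names(freqs$mt)))
    stop("parental frequency tables must cover the same loci")
  invisible(freqs)
}

#' Parental frequency tables for bi-allelic loci
#'
#' Builds the `freqs` structure used by the simulator from per-locus
#' compound T-frequencies, with alleles labelled `"01"` (E) and `"02"` (T).
#'
#' @param t_me,t_mt named per-locus compound T-frequencies for the two taxa.
#' @return list with per-taxon, per-locus named allele frequency vectors.
#' @export
biallelic_freqs <- function(t_me, t_mt) {
  loci <- names(t_me)
  check_freqs(list(
    me = stats::setNames(lapply(loci, function(l)
      c("01" = 1 - t_me[[l]], "02" = t_me[[l]])), loci),
    mt = stats::setNames(lapply(loci, function(l)
      c("01" = 1 - t_mt[[l]], "02" = t_mt[[l]])), loci)))
}

#' Default study allele frequencies
#'
#' Four partially diagnostic bi-allelic loci named after the allozyme panel
#' (Est-D, Gpi, Pgm, Odh), with compound T-frequency differentials of
#' 0.95, 0.90, 0.80 and 0.75 between the parental taxa and a nearly pure
#' ME reference, mirroring the 70-95% differential range of such panels.
#'
#' @return a `freqs` list as in [biallelic_freqs()].
#' @export
default_freqs <- function() {
  biallelic_freqs(
    t_me = c("Est-D" = 0.02, "Gpi" = 0.05, "Pgm" = 0.10, "Odh" = 0.05),
    t_mt = c("Est-D" = 0.97, "Gpi" = 0.95, "Pgm" = 0.90, "Odh" = 0.80))
}

#' Registry matching a simulator frequency table
#' @param freqs a `freqs` list (see [biallelic_freqs()]).
#' @return an `allele_registry` built from the generating frequencies.
#' @export
registry_from_freqs <- function(freqs) {
  check_freqs(freqs)
  build_registry(ref_me = freqs$me, ref_mt = freqs$mt)
}

#' Draw one gamete from a parent of known class
#'
#' An ME or MT parent contributes, independently at every locus, an allele
#' drawn from that taxon's frequencies. An F1 parent contributes per locus
#' either its ME-derived or its MT-derived allele with probability 1/2,
#' independently across loci (free recombination between the unlinked loci).
#'
#' @param class_parent one of `"ME"`, `"MT"`, `"F1"`.
#' @param freqs parental frequency tables (see [biallelic_freqs()]).
#' @param n number of gametes.
#' @return character matrix `n` x loci of allele labels.
#' @export
draw_gamete <- function(class_parent, freqs, n = 1L) {
  check_freqs(freqs)
  loci <- names(freqs$me)
  draw_from <- function(tab, n) sample(names(tab), n, TRUE, prob = tab)
  out <- matrix(NA_character_, n, length(loci),
                dimnames = list(NULL, loci))
  for (j in seq_along(loci)) {
    l <- loci[j]
    out[, j] <- switch(class_parent,
      ME = draw_from(freqs$me[[l]], n),
      MT = draw_from(freqs$mt[[l]], n),
      F1 = ifelse(stats::runif(n) < 0.5,
                  draw_from(freqs$me[[l]], n),
                  draw_from(freqs$mt[[l]], n)),
      stop("gametes are drawn from ME, MT or F1 parents only"))
  }
  out
}

parent_pair <- function(cls) {
  switch(cls,
         ME = c("ME", "ME"), MT = c("MT", "MT"), F1 = c("ME", "MT"),
         F2 = c("F1", "F1"), BC_ME = c("F1", "ME"), BC_MT = c("F1", "MT"),
         stop("unknown ancestry class: ", cls))
}

#' Simulate genotypes of one known ancestry class
#'
#' Genotypes are formed by uniting two gametes: same-taxon gametes for
#' purebreds, one ME and one MT gamete for F1, two F1 gametes for F2, and
#' an F1 plus a purebred gamete for the backcrosses.
#'
#' @param cls one of the six [ANCESTRY_CLASSES].
#' @param n number of individuals (>= 1).
#' @param freqs parental frequency tables.
#' @param id_prefix prefix for generated individual IDs.
#' @param sample_id sample label for the cohort.
#' @return a `labeled_cohort`: list with `table` (a [genotype_table()]),
#'   `true_class`, `freqs`.
#' @export
simulate_class <- function(cls, n, freqs, id_prefix = cls,
                           sample_id = "sim") {
  stopifnot(n >= 1)
  pp <- parent_pair(cls)
  g1 <- draw_gamete(pp[1L], freqs, n)
  g2 <- draw_gamete(pp[2L], freqs, n)
  tab <- genotype_table(sprintf("%s_%04d", id_prefix, seq_len(n)),
                        names(freqs$me), g1, g2,
                        sample_id = rep(sample_id, n))
  structure(list(table = tab, true_class = rep(cls, n), freqs = freqs),
            class = "labeled_cohort")
}

#' Compose a mixed calibration sample of known ancestry
#'
#' Concatenates simulated cohorts of the six classes in the requested
#' counts (defaults 80:80:10:10:10:10, i.e. N = 200 with 40% of each
#' purebred and 20% assorted hybrids) and shuffles individual order. The
#' seed is recorded in the result; class counts always match the request
#' exactly.
#'
#' @param freqs parental frequency tables.
#' @param counts named integer vector over [ANCESTRY_CLASSES].
#' @param seed RNG seed (required).
#' @param sample_id sample label.
#' @return a `labeled_cohort` with an extra `seed` element.
#' @export
compose_mixture <- function(freqs,
                            counts = c(ME = 80, MT = 80, F1 = 10, F2 = 10,
                                       BC_ME = 10, BC_MT = 10),
                            seed, sample_id = "mix") {
  if (missing(seed)) stop("a seed is required")
  stopifnot(all(counts >= 0), all(names(counts) %in% ANCESTRY_CLASSES))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  parts <- lapply(names(counts)[counts > 0], function(cls)
    simulate_class(cls, counts[[cls]], freqs,
                   id_prefix = paste0(sample_id, "_", cls),
                   sample_id = sample_id))
  tab <- do.call(rbind_tables, lapply(parts, `[[`, "table"))
  true_class <- unlist(lapply(parts, `[[`, "true_class"))
  ord <- sample.int(length(true_class))
  structure(list(table = subset_individuals(tab, ord),
                 true_class = true_class[ord], freqs = freqs, seed = seed),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat("labeled_cohort:", length(x$true_class), "individuals (",
      paste(sprintf("%s=%d", names(table(x$true_class)),
                    as.integer(table(x$true_class))), collapse = ", "), ")\n")
  invisible(x)
}

#' Write a labeled cohort as Genepop plus a labels TSV
#'
#' @param cohort a `labeled_cohort`.
#' @param genepop_path,labels_path output paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, genepop_path, labels_path) {
  write_genepop(cohort$table, genepop_path)
  utils::write.table(
    data.frame(id = cohort$table$individuals,
               true_class = cohort$true_class,
               seed = if (is.null(cohort$seed)) NA else cohort$seed),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genepop_path, labels_path))
}
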