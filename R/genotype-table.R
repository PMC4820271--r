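#' Multilocus co-dominant genotype table
#'
#' The basic container for raw genotypes: one row per individual, one column
#' per locus, each cell an unordered pair of allele labels (or missing).
#' Individuals carry sample, site and substrate metadata. Alleles are kept as
#' character labels exactly as read (e.g. Genepop codes `"01"`, `"105"`), so
#' no information is lost before pooling.
#'
#' @param individuals character vector of unique individual IDs.
#' @param loci character vector of locus names (length >= 1).
#' @param a1,a2 character matrices (`length(individuals)` x `length(loci)`)
#'   holding the two allele labels of each genotype. A missing genotype has
#'   `NA` in both matrices at that cell.
#' @param sample_id character vector, one sample ID per individual.
#' @param site_id character vector of site IDs (defaults to `sample_id`).
#' @param substrate character vector with values `"algae"`, `"bottom"` or
#'   `"unknown"` (default).
#'
#' @return An object of class `genotype_table`: a list with elements
#'   `individuals`, `loci`, `a1`, `a2`, `sample_id`, `site_id`, `substrate`.
#' @export
genotype_table <- function(individuals, loci, a1, a2, sample_id,
                           site_id = sample_id,
                           substrate = rep("unknown", length(individuals))) {
  individuals <- as.character(individuals)
  loci <- as.character(loci)
  stopifnot(length(loci) >= 1L, !anyDuplicated(individuals))
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "character"; storage.mode(a2) <- "character"
  n <- length(individuals)
  if (!all(dim(a1) == c(n, length(loci))) || !all(dim(a2) == c(n, length(loci))))
    stop("allele matrices must be individuals x loci")
  # a genotype is either complete (two labels) or fully missing
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("genotype cells must have both alleles or neither (", sum(half),
         " half-missing cells)")
  substrate <- match.arg(as.character(substrate),
                         c("algae", "bottom", "unknown"), several.ok = TRUE)
  if (length(sample_id) != n || length(site_id) != n || length(substrate) != n)
    stop("metadata vectors must have one entry per individual")
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  structure(list(individuals = individuals, loci = loci, a1 = a1, a2 = a2,
                 sample_id = as.character(sample_id),
                 site_id = as.character(site_id),
                 substrate = substrate),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$individuals), "individuals,",
      length(x$loci), "loci (", paste(x$loci, collapse = ", "), "),",
      length(unique(x$sample_id)), "samples\n")
  invisible(x)
}

#' Number of individuals in a genotype table
#' @param table a `genotype_table`.
#' @return integer count.
#' @export
n_individuals <- function(table) length(table$individuals)

#' Subset a genotype table by individual
#'
#' @param table a `genotype_table`.
#' @param i logical, integer or character index over individuals.
#' @return a `genotype_table` restricted to the selected individuals.
#' @export
subset_individuals <- function(table, i) {
  if (is.character(i)) i <- match(i, table$individuals)
  genotype_table(table$individuals[i], table$loci,
                 table$a1[i, , drop = FALSE], table$a2[i, , drop = FALSE],
                 table$sample_id[i], table$site_id[i], table$substrate[i])
}

#' Combine genotype tables over individuals
#' @param ... `genotype_table` objects sharing the same locus panel.
#' @return a single `genotype_table`.
#' @export
rbind_tables <- function(...) {
  tabs <- list(...)
  loci <- tabs[[1L]]$loci
  for (t in tabs) if (!identical(t$loci, loci)) stop("locus panels differ")
  genotype_table(
    unlist(lapply(tabs, `[[`, "individuals")), loci,
    do.call(rbind, lapply(tabs, `[[`, "a1")),
    do.call(rbind, lapply(tabs, `[[`, "a2")),
    unlist(lapply(tabs, `[[`, "sample_id")),
    unlist(lapply(tabs, `[[`, "site_id")),
    unlist(lapply(tabs, `[[`, "substrate")))
}
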