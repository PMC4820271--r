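#' Build a compound-allele registry from parental reference frequencies
#'
#' At partially diagnostic loci the many electromorph alleles are pooled into
#' two compound categories: T (trossulus-like) and E (edulis-like). An allele
#' is pooled into T when its reference frequency in the pure MT population is
#' strictly greater than in the pure ME population, and into E otherwise;
#' exact ties go to E with a warning. The registry also stores, per locus,
#' the compound T-allele frequency in each reference taxon (the sum of its
#' T-pooled allele frequencies), used to rescale observed frequencies.
#'
#' @param ref_me,ref_mt named lists, one element per locus, each a named
#'   numeric vector of allele frequencies in the pure ME (resp. MT) reference
#'   population. Both must cover the same loci and each vector must sum to 1
#'   (tolerance 1e-6). Alleles absent from a vector count as frequency 0.
#' @return an object of class `allele_registry`: list with `loci`, `pooling`
#'   (per locus a named character vector of `"E"`/`"T"`), and `ref` (a
#'   data.frame with columns `locus`, `t_me`, `t_mt`).
#' @export
build_registry <- function(ref_me, ref_mt) {
  loci <- names(ref_me)
  if (!setequal(loci, names(ref_mt)))
    stop("reference tables must cover the same loci")
  pooling <- list(); t_me <- t_mt <- numeric(length(loci))
  for (k in seq_along(loci)) {
    l <- loci[k]
    fe <- ref_me[[l]]; ft <- ref_mt[[l]]
    for (v in list(fe, ft))
      if (abs(sum(v) - 1) > 1e-6)
        stop("allele frequencies at locus ", l, " do not sum to 1")
    alleles <- union(names(fe), names(ft))
    fe_full <- stats::setNames(fe[alleles], alleles); fe_full[is.na(fe_full)] <- 0
    ft_full <- stats::setNames(ft[alleles], alleles); ft_full[is.na(ft_full)] <- 0
    grp <- ifelse(ft_full > fe_full, "T", "E")
    if (any(tie <- ft_full == fe_full & ft_full > 0))
      warning("locus ", l, ": allele(s) ", paste(alleles[tie], collapse = ","),
              " have equal reference frequencies; pooled as E")
    pooling[[l]] <- stats::setNames(grp, alleles)
    t_me[k] <- sum(fe_full[grp == "T"])
    t_mt[k] <- sum(ft_full[grp == "T"])
  }
  if (any(t_mt <= t_me))
    stop("reference compound T-frequency must exceed the ME reference at ",
         "every locus; offending: ",
         paste(loci[t_mt <= t_me], collapse = ","))
  structure(list(loci = loci, pooling = pooling,
                 ref = data.frame(locus = loci, t_me = t_me, t_mt = t_mt,
                                  stringsAsFactors = FALSE)),
            class = "allele_registry")
}

#' @export
print.allele_registry <- function(x, ...) {
  cat("allele_registry over", length(x$loci), "loci\n")
  print(x$ref, row.names = FALSE)
  invisible(x)
}

#' Registry for strictly bi-allelic loci
#'
#' Convenience constructor for simulated or fully pooled data where each
#' locus carries exactly the two compound alleles, labelled `"01"` (E) and
#' `"02"` (T).
#'
#' @param t_me,t_mt named numeric vectors of per-locus compound T-allele
#'   frequencies in the ME and MT reference populations.
#' @return an `allele_registry`.
#' @export
biallelic_registry <- function(t_me, t_mt) {
  loci <- names(t_me)
  build_registry(
    ref_me = stats::setNames(lapply(loci, function(l)
      c("01" = 1 - t_me[[l]], "02" = t_me[[l]])), loci),
    ref_mt = stats::setNames(lapply(loci, function(l)
      c("01" = 1 - t_mt[[l]], "02" = t_mt[[l]])), loci))
}

#' Write / read a registry as a YAML config
#'
#' @param registry an `allele_registry`.
#' @param path file path.
#' @return `write_registry`: `path` invisibly; `read_registry`: the registry.
#' @export
write_registry <- function(registry, path) {
  obj <- list(loci = lapply(seq_along(registry$loci), function(k) {
    l <- registry$loci[k]
    list(name = l,
         pooling = as.list(registry$pooling[[l]]),
         t_me = registry$ref$t_me[k], t_mt = registry$ref$t_mt[k])
  }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  obj <- yaml::read_yaml(path)
  loci <- vapply(obj$loci, `[[`, "", "name")
  pooling <- lapply(obj$loci, function(e) unlist(e$pooling))
  names(pooling) <- loci
  structure(list(loci = loci, pooling = pooling,
                 ref = data.frame(locus = loci,
                                  t_me = vapply(obj$loci, `[[`, 0, "t_me"),
                                  t_mt = vapply(obj$loci, `[[`, 0, "t_mt"),
                                  stringsAsFactors = FALSE)),
            class = "allele_registry")
}

#' Pool raw genotypes into compound T-allele dosages
#'
#' Converts each genotype into the count of T-pooled alleles it carries
#' (0, 1 or 2); missing genotypes propagate as `NA`.
#'
#' @param table a [genotype_table()].
#' @param registry an [build_registry()] result resolving every observed
#'   allele. An unresolvable allele is an error, never silently dropped.
#' @return an object of class `pooled_table`: list with `dosage` (integer
#'   matrix individuals x loci), `individuals`, `loci`, `sample_id`,
#'   `site_id`, `substrate` and the `registry` used.
#' @export
pool <- function(table, registry) {
  common <- intersect(table$loci, registry$loci)
  if (!all(table$loci %in% registry$loci))
    stop("registry lacks loci: ",
         paste(setdiff(table$loci, registry$loci), collapse = ","))
  dos <- matrix(NA_integer_, nrow = length(table$individuals),
                ncol = length(table$loci),
                dimnames = list(table$individuals, table$loci))
  for (j in seq_along(table$loci)) {
    l <- table$loci[j]
    map <- registry$pooling[[l]]
    for (m in list(table$a1[, j], table$a2[, j])) {
      seen <- unique(m[!is.na(m)])
      unknown <- setdiff(seen, names(map))
      if (length(unknown))
        stop("unresolvable allele(s) at ", l, ": ",
             paste(unknown, collapse = ","))
    }
    dos[, j] <- (map[table$a1[, j]] == "T") + (map[table$a2[, j]] == "T")
  }
  structure(list(dosage = dos, individuals = table$individuals,
                 loci = table$loci, sample_id = table$sample_id,
                 site_id = table$site_id, substrate = table$substrate,
                 registry = registry),
            class = "pooled_table")
}

#' @export
print.pooled_table <- function(x, ...) {
  cat("pooled_table:", nrow(x$dosage), "individuals x", ncol(x$dosage),
      "loci (T-allele dosages)\n")
  invisible(x)
}

#' Subset a pooled table by individual
#' @param pooled a `pooled_table`.
#' @param i index over individuals (logical, integer or character).
#' @return a `pooled_table`.
#' @export
subset_pooled <- function(pooled, i) {
  if (is.character(i)) i <- match(i, pooled$individuals)
  structure(list(dosage = pooled$dosage[i, , drop = FALSE],
                 individuals = pooled$individuals[i], loci = pooled$loci,
                 sample_id = pooled$sample_id[i], site_id = pooled$site_id[i],
                 substrate = pooled$substrate[i], registry = pooled$registry),
            class = "pooled_table")
}

#' Per-individual hybrid index (T-score)
#'
#' The T-score of an individual is the number of T-pooled alleles summed
#' over its scored loci; with four complete loci it ranges from 0 (pure ME)
#' to 8 (pure MT). Individuals with missing loci keep their partial sum and
#' the number of scored loci is reported alongside.
#'
#' @param pooled a [pool()]ed table.
#' @return data.frame with columns `id`, `t_score` (NA when no locus is
#'   scored), `n_loci_scored`.
#' @export
t_score <- function(pooled) {
  n_scored <- rowSums(!is.na(pooled$dosage))
  ts <- rowSums(pooled$dosage, na.rm = TRUE)
  ts[n_scored == 0L] <- NA_real_
  if (any(n_scored == 0L))
    warning(sum(n_scored == 0L), " individual(s) with no scored locus are unscorable")
  data.frame(id = pooled$individuals, t_score = as.integer(ts),
             n_loci_scored = as.integer(n_scored),
             stringsAsFactors = FALSE)
}

#' Observed compound T-allele frequencies per locus
#'
#' @param pooled a `pooled_table` (typically one sample).
#' @return named numeric vector of observed T-frequencies (allele counts over
#'   non-missing genotypes); `NaN` for loci with no data.
#' @export
compound_t_freqs <- function(pooled) {
  colSums(pooled$dosage, na.rm = TRUE) / (2 * colSums(!is.na(pooled$dosage)))
}

#' Sample-level scaled T-frequency
#'
#' Per locus the observed compound T-frequency is rescaled linearly to the
#' interval from 0 to 1 between the two parental reference frequencies,
#' `(f_obs - f_ME) / (f_MT - f_ME)`, clipped into \[0, 1\] when observations
#' fall outside the reference range; the rescaled values are then averaged
#' over loci (scale-then-average).
#'
#' @param pooled a `pooled_table` holding one sample (subset first).
#' @return scalar in \[0, 1\].
#' @export
t_frequency <- function(pooled) {
  if (all(is.na(pooled$dosage))) stop("no scored individuals")
  f_obs <- compound_t_freqs(pooled)
  ref <- pooled$registry$ref
  ref <- ref[match(pooled$loci, ref$locus), ]
  denom <- ref$t_mt - ref$t_me
  usable <- denom > 0 & !is.nan(f_obs)
  if (any(!usable & !is.nan(f_obs)))
    warning("locus with equal reference frequencies excluded from T-frequency")
  scaled <- (f_obs[usable] - ref$t_me[usable]) / denom[usable]
  if (any(scaled < 0 | scaled > 1)) {
    message("observed frequencies outside the reference range clipped to [0,1]")
    scaled <- pmin(pmax(scaled, 0), 1)
  }
  mean(scaled)
}

#' Allele frequency table for a sample
#'
#' Raw per-locus allele frequencies from allele counts over non-missing
#' genotypes; when a registry is supplied, the compound pooling of each
#' allele and per-locus compound T-frequencies are included.
#'
#' @param table a [genotype_table()] (typically one sample).
#' @param registry optional `allele_registry`.
#' @return data.frame with columns `locus`, `allele`, `count`, `freq` and
#'   (with a registry) `pooled`; loci with no scored genotypes are omitted.
#'   The per-locus compound T-frequencies are attached as attribute
#'   `"t_freq"` when a registry is given.
#' @export
allele_frequencies <- function(table, registry = NULL) {
  rows <- list()
  t_freq <- c()
  for (j in seq_along(table$loci)) {
    l <- table$loci[j]
    alleles <- c(table$a1[, j], table$a2[, j])
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) == 0L) next
    tab <- table(alleles)
    df <- data.frame(locus = l, allele = names(tab),
                     count = as.integer(tab),
                     freq = as.numeric(tab) / length(alleles),
                     stringsAsFactors = FALSE)
    if (!is.null(registry)) {
      df$pooled <- unname(registry$pooling[[l]][df$allele])
      t_freq[l] <- sum(df$freq[df$pooled == "T"])
    }
    rows[[l]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(registry)) attr(out, "t_freq") <- t_freq
  out
}
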