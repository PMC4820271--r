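#' Two-population Bayesian admixture model (Gibbs sampler)
#'
#' Infers, from raw multi-allele genotypes and with no prior population
#' information, the ancestry proportion of every individual with respect to
#' two latent parental populations, together with the parental allele
#' frequencies. This is the classic admixture model with uncorrelated
#' frequencies: each allele copy of individual `i` has a latent origin
#' `z` in population 1 with probability `q_i`, and given its origin is drawn
#' from that population's frequencies at the locus. The sampler alternates
#' \itemize{
#'  \item `z | q, p`: independent categorical draws per allele copy,
#'  \item `p | z`: Dirichlet(`lambda` + origin-specific allele counts) per
#'    locus per population,
#'  \item `q | z`: Beta(`alpha` + copies from pop 1, `alpha` + copies from
#'    pop 2).
#' }
#' The individual score (ISS) is the posterior mean of `q` over the kept
#' iterations. Population labels are arbitrary until [orient_labels()] is
#' applied. `alpha` is fixed by default (reproducibility); a Metropolis
#' update of a common `alpha` is available with `update_alpha = TRUE`.
#'
#' A split-half heuristic compares mean ISS over the first and second halves
#' of the kept iterations and warns (not fails) when more than 5% of
#' individuals differ by more than 0.1.
#'
#' @param table a [genotype_table()] with raw (not pooled) genotypes.
#' @param k number of parental populations; only 2 is supported.
#' @param burn_in,keep numbers of discarded and kept MCMC sweeps
#'   (defaults 30000 / 50000).
#' @param alpha symmetric Beta prior parameter for `q` (default 1).
#' @param lambda Dirichlet prior parameter for allele frequencies (default 1).
#' @param seed RNG seed (required).
#' @param update_alpha update `alpha` by a Metropolis step with uniform
#'   prior on (0, 10\] (default `FALSE`).
#' @return object of class `admixture_fit`: `iss` (named, ancestry in
#'   population 1), `freqs` (per population, per locus named frequency
#'   vectors), `individuals`, `sample_id`, `loci`, `mcmc` (settings and
#'   diagnostics), `oriented = FALSE`.
#' @export
fit_admixture <- function(table, k = 2, burn_in = 30000, keep = 50000,
                          alpha = 1.0, lambda = 1.0, seed,
                          update_alpha = FALSE) {
  if (k != 2) stop("only k = 2 is supported")
  if (missing(seed)) stop("a seed is required")
  n <- length(table$individuals)
  if (n < 2L) stop("need at least 2 individuals")
  L <- length(table$loci)
  # integer-coded allele copies, missing dropped per copy
  alleles <- lapply(seq_len(L), function(j)
    sort(unique(c(table$a1[, j], table$a2[, j])), na.last = NA))
  copies <- lapply(seq_len(L), function(j) {
    lapply(list(table$a1[, j], table$a2[, j]), function(col) {
      idx <- which(!is.na(col))
      list(ind = idx, a = match(col[idx], alleles[[j]]))
    })
  })
  m_tot <- integer(n)                       # scored copies per individual
  for (j in seq_len(L)) for (cp in copies[[j]])
    m_tot[cp$ind] <- m_tot[cp$ind] + 1L
  if (any(m_tot == 0L)) stop("individual(s) with no scored locus")
  ka <- lengths(alleles)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  q <- stats::runif(n, 0.3, 0.7)
  p <- lapply(seq_len(L), function(j) {
    m <- matrix(stats::rgamma(2L * ka[j], 1), nrow = 2L)
    m / rowSums(m)
  })
  q_acc <- q_acc1 <- q_acc2 <- numeric(n)
  p_acc <- lapply(seq_len(L), function(j) matrix(0, 2L, ka[j]))
  alpha_cur <- alpha; alpha_acc <- 0; alpha_trace <- numeric(0)
  half <- keep %/% 2L
  total <- burn_in + keep
  for (it in seq_len(total)) {
    n1 <- numeric(n)
    for (j in seq_len(L)) {
      p1 <- p[[j]][1L, ]; p2 <- p[[j]][2L, ]
      c1 <- c2 <- numeric(ka[j])
      for (cp in copies[[j]]) {
        w1 <- q[cp$ind] * p1[cp$a]
        w2 <- (1 - q[cp$ind]) * p2[cp$a]
        z1 <- stats::runif(length(cp$a)) * (w1 + w2) < w1
        n1[cp$ind] <- n1[cp$ind] + z1
        c1 <- c1 + tabulate(cp$a[z1], ka[j])
        c2 <- c2 + tabulate(cp$a[!z1], ka[j])
      }
      g1 <- stats::rgamma(ka[j], lambda + c1)
      g2 <- stats::rgamma(ka[j], lambda + c2)
      p[[j]] <- rbind(g1 / sum(g1), g2 / sum(g2))
    }
    q <- stats::rbeta(n, alpha_cur + n1, alpha_cur + (m_tot - n1))
    # guard against degenerate 0/1 draws that would freeze z
    q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
    if (update_alpha) {
      prop <- alpha_cur + stats::rnorm(1, 0, 0.25)
      if (prop > 0 && prop <= 10) {
        lr <- sum(stats::dbeta(q, prop, prop, log = TRUE)) -
          sum(stats::dbeta(q, alpha_cur, alpha_cur, log = TRUE))
        if (log(stats::runif(1)) < lr) {
          alpha_cur <- prop; alpha_acc <- alpha_acc + 1
        }
      }
    }
    if (it > burn_in) {
      q_acc <- q_acc + q
      if (it - burn_in <= half) q_acc1 <- q_acc1 + q else q_acc2 <- q_acc2 + q
      for (j in seq_len(L)) p_acc[[j]] <- p_acc[[j]] + p[[j]]
      if (update_alpha) alpha_trace <- c(alpha_trace, alpha_cur)
    }
  }
  iss <- q_acc / keep
  disc <- abs(q_acc1 / half - q_acc2 / (keep - half))
  frac_bad <- mean(disc > 0.1)
  if (frac_bad > 0.05)
    warning(sprintf(paste0("possible non-convergence: split-half ISS ",
                           "discrepancy > 0.1 for %.1f%% of individuals"),
                    100 * frac_bad))
  freqs <- lapply(1:2, function(pop)
    stats::setNames(lapply(seq_len(L), function(j)
      stats::setNames(p_acc[[j]][pop, ] / keep, alleles[[j]])), table$loci))
  structure(list(iss = stats::setNames(iss, table$individuals),
                 freqs = freqs, individuals = table$individuals,
                 sample_id = table$sample_id, loci = table$loci,
                 mcmc = list(burn_in = burn_in, keep = keep, seed = seed,
                             alpha = if (update_alpha)
                               mean(alpha_trace) else alpha,
                             update_alpha = update_alpha,
                             alpha_accept = if (update_alpha)
                               alpha_acc / total else NA_real_,
                             split_half_frac = frac_bad),
                 oriented = FALSE),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit (k = 2):", length(x$iss), "individuals,",
      length(x$loci), "loci;",
      if (x$oriented) "oriented to MT\n" else "unoriented labels\n")
  cat(sprintf("  ISS range %.3f-%.3f; burn-in %d, kept %d, seed %s\n",
              min(x$iss), max(x$iss), x$mcmc$burn_in, x$mcmc$keep,
              format(x$mcmc$seed)))
  invisible(x)
}

#' Orient admixture population labels toward MT
#'
#' The two latent populations of [fit_admixture()] are exchangeable (label
#' switching). This resolves them by the compound T-allele frequency: the
#' population whose estimated frequencies, pooled through the registry and
#' averaged over loci, carry more T-alleles is labelled MT, and ISS is
#' re-expressed as the MT-ancestry proportion. Idempotent.
#'
#' @param fit an `admixture_fit`.
#' @param registry an `allele_registry` resolving the fitted alleles.
#' @return the fit with `iss` = MT ancestry and `oriented = TRUE`;
#'   `freqs[[1]]` is MT, `freqs[[2]]` ME.
#' @export
orient_labels <- function(fit, registry) {
  tf <- vapply(1:2, function(pop) {
    per <- vapply(fit$loci, function(l) {
      f <- fit$freqs[[pop]][[l]]
      map <- registry$pooling[[l]]
      unknown <- setdiff(names(f), names(map))
      if (length(unknown)) stop("registry cannot pool allele(s) ",
                                paste(unknown, collapse = ","), " at ", l)
      sum(f[map[names(f)] == "T"])
    }, 0)
    mean(per)
  }, 0)
  if (tf[1L] == tf[2L])
    stop("populations have equal compound T-frequencies; orient manually")
  if (tf[2L] > tf[1L]) {
    fit$iss <- 1 - fit$iss
    fit$freqs <- fit$freqs[2:1]
  }
  fit$oriented <- TRUE
  fit
}

#' Population (sample) ancestry scores
#'
#' The PSS of a sample is the arithmetic mean of its members' ISS.
#'
#' @param fit an `admixture_fit` (usually [orient_labels()]ed).
#' @param grouping sample membership: a character/factor vector aligned with
#'   `fit$individuals` (default the fit's `sample_id`).
#' @return named numeric vector, one PSS per sample (empty samples omitted
#'   with a warning).
#' @export
pss <- function(fit, grouping = fit$sample_id) {
  if (length(grouping) != length(fit$iss))
    stop("grouping must assign each individual to exactly one sample")
  grouping <- as.character(grouping)
  lv <- unique(grouping)
  empty <- setdiff(lv, grouping)   # only possible with factor input
  if (length(empty)) warning("empty sample(s) omitted: ",
                             paste(empty, collapse = ","))
  vapply(split(fit$iss, factor(grouping, levels = lv)), mean, 0)
}
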