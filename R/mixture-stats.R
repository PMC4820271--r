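#' Per-locus heterozygote deficit F_IS
#'
#' On the pooled bi-allelic scale, `F_IS = 1 - H_obs / H_exp` with `H_obs`
#' the observed proportion of compound heterozygotes (dosage 1) and
#' `H_exp = 2p(1-p)` from the sample compound T-frequency `p`. No
#' small-sample correction is applied. Positive values indicate a Wahlund
#' heterozygote deficit, as produced by mixing differentiated populations;
#' panmictic equilibrium samples are close to 0.
#'
#' @param pooled a `pooled_table` holding one sample.
#' @return list with `per_locus` (named vector; `NA` for monomorphic loci,
#'   excluded from the mean with a warning) and `mean`.
#' @export
fis <- function(pooled) {
  dos <- pooled$dosage
  per <- vapply(seq_len(ncol(dos)), function(j) {
    x <- dos[, j]; x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    p <- mean(x) / 2
    h_exp <- 2 * p * (1 - p)
    if (h_exp == 0) return(NA_real_)
    1 - mean(x == 1L) / h_exp
  }, 0)
  names(per) <- pooled$loci
  if (anyNA(per))
    warning("F_IS undefined at monomorphic/underpopulated loci: ",
            paste(pooled$loci[is.na(per)], collapse = ","))
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Composite inter-locus disequilibrium correlation R'
#'
#' For each locus pair the phase-free (Burrows) composite disequilibrium
#' between T-allele dosages is computed and standardised following Weir:
#' `Delta / sqrt((p1 q1 + D1)(p2 q2 + D2))`, where `Delta` is half the
#' (population-denominator) dosage covariance and `D_i = P_hom,i - p_i^2`
#' is the within-locus Hardy-Weinberg departure. With the departures folded
#' in this equals the Pearson correlation of the dosage vectors. Values are
#' elevated in mixtures of differentiated populations.
#'
#' @param pooled a `pooled_table` holding one sample.
#' @return list with `per_pair` (named vector over locus pairs; `NA` when a
#'   locus is monomorphic or fewer than 3 complete pairs exist) and `mean`.
#' @export
r_prime <- function(pooled) {
  L <- ncol(pooled$dosage)
  prs <- utils::combn(L, 2L)
  per <- apply(prs, 2L, function(ij) {
    x <- pooled$dosage[, ij[1L]]; y <- pooled$dosage[, ij[2L]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L) return(NA_real_)
    p1 <- mean(x) / 2; p2 <- mean(y) / 2
    delta <- (mean(x * y) - mean(x) * mean(y)) / 2      # Burrows Delta
    d1 <- mean(x == 2L) - p1^2                          # within-locus departure
    d2 <- mean(y == 2L) - p2^2
    v1 <- p1 * (1 - p1) + d1
    v2 <- p2 * (1 - p2) + d2
    if (v1 <= 0 || v2 <= 0) return(NA_real_)
    delta / sqrt(v1 * v2)
  })
  names(per) <- apply(prs, 2L, function(ij)
    paste(pooled$loci[ij], collapse = ":"))
  if (anyNA(per))
    warning("R' undefined for pairs with a monomorphic locus: ",
            paste(names(per)[is.na(per)], collapse = ","))
  list(per_pair = per, mean = mean(per, na.rm = TRUE))
}

#' Disequilibrium maxima under a non-interbreeding mixture
#'
#' For each locus the mixing proportion `m` is solved from
#' `f_obs = m f_MT + (1-m) f_ME` (clipped to \[0, 1\]); `m_hat` is the mean
#' over usable loci. The maximal heterozygote deficit expected in a physical
#' mixture with those average frequencies is the Wahlund closed form
#' `1 - [m 2f_MT(1-f_MT) + (1-m) 2f_ME(1-f_ME)] / [2 p (1-p)]` per locus
#' (with `p` the pooled frequency), averaged over loci. The maximal
#' composite correlation uses the mixture's expected dosage covariances
#' under within-component equilibrium, at the single proportion `m_hat`,
#' averaged over pairs. Both maxima equal 1 for fully diagnostic loci at a
#' 50:50 mixture and 0 for a pure sample.
#'
#' @param mean_t_freqs named numeric vector of observed compound
#'   T-frequencies per locus (raw scale), e.g. [compound_t_freqs()].
#' @param registry an `allele_registry` with the parental references.
#' @return list `fis_max`, `r_max`, `m_hat`, `m_per_locus`.
#' @export
mixture_maxima <- function(mean_t_freqs, registry) {
  ref <- registry$ref[match(names(mean_t_freqs), registry$ref$locus), ]
  if (anyNA(ref$locus)) stop("registry lacks loci: ",
                             paste(names(mean_t_freqs)[is.na(ref$locus)], collapse = ","))
  fmt <- ref$t_mt; fme <- ref$t_me
  usable <- (fmt - fme) > 0 & !is.nan(mean_t_freqs)
  if (!any(usable)) stop("no usable locus for mixture maxima")
  fmt <- fmt[usable]; fme <- fme[usable]
  fobs <- pmin(pmax(mean_t_freqs[usable], fme), fmt)
  m <- (fobs - fme) / (fmt - fme)
  m_hat <- mean(m)
  # Wahlund maximum per locus at the locus-specific m
  pbar <- m * fmt + (1 - m) * fme
  het_mix <- m * 2 * fmt * (1 - fmt) + (1 - m) * 2 * fme * (1 - fme)
  het_tot <- 2 * pbar * (1 - pbar)
  fis_l <- ifelse(het_tot > 0, 1 - het_mix / het_tot, 0)
  # pairwise dosage correlation of the two-component mixture at m_hat
  mm <- m_hat
  mu <- 2 * (mm * fmt + (1 - mm) * fme)
  ex2 <- mm * (2 * fmt * (1 - fmt) + 4 * fmt^2) +
    (1 - mm) * (2 * fme * (1 - fme) + 4 * fme^2)
  v <- ex2 - mu^2
  L <- length(fmt)
  if (L >= 2L) {
    prs <- utils::combn(L, 2L)
    r_l <- apply(prs, 2L, function(ij) {
      i <- ij[1L]; j <- ij[2L]
      cv <- 4 * mm * (1 - mm) * (fmt[i] - fme[i]) * (fmt[j] - fme[j])
      if (v[i] <= 0 || v[j] <= 0) return(0)
      cv / sqrt(v[i] * v[j])
    })
    r_max <- mean(r_l)
  } else r_max <- NA_real_
  list(fis_max = mean(fis_l), r_max = r_max, m_hat = m_hat,
       m_per_locus = stats::setNames(m, names(mean_t_freqs)[usable]))
}

new_tscore_distribution <- function(p, provenance) {
  stopifnot(all(p >= -1e-12), abs(sum(p) - 1) < 1e-9)
  structure(stats::setNames(pmax(p, 0) / sum(pmax(p, 0)),
                            0:(length(p) - 1L)),
            provenance = provenance, class = "tscore_distribution")
}

#' @export
print.tscore_distribution <- function(x, ...) {
  cat("T-score distribution (", attr(x, "provenance"), ")\n", sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Expected T-score distribution under local panmixia
#'
#' Under Hardy-Weinberg equilibrium the dosage at locus `l` is
#' Binomial(2, t_l); the total T-score distribution is the convolution
#' across loci.
#'
#' @param t_freqs numeric vector of per-locus compound T-frequencies in
#'   \[0, 1\].
#' @return a `tscore_distribution` over scores `0 .. 2 * length(t_freqs)`.
#' @export
expected_tscore_panmixia <- function(t_freqs) {
  stopifnot(all(t_freqs >= 0 & t_freqs <= 1))
  d <- 1
  for (t in t_freqs) d <- convolve_dist(d, stats::dbinom(0:2, 2, t))
  new_tscore_distribution(d, "panmixia")
}

#' Expected T-score distribution in a non-interbreeding mixture
#'
#' A physical mixture (proportion `m` of MT) of the two parental taxa, each
#' internally panmictic at its reference frequencies, without interbreeding.
#'
#' @param m mixing proportion of the MT component, in \[0, 1\].
#' @param registry an `allele_registry` with the parental references.
#' @return a `tscore_distribution`.
#' @export
expected_tscore_mixture <- function(m, registry) {
  stopifnot(m >= 0, m <= 1)
  d_mt <- expected_tscore_panmixia(registry$ref$t_mt)
  d_me <- expected_tscore_panmixia(registry$ref$t_me)
  new_tscore_distribution(m * unclass(d_mt) + (1 - m) * unclass(d_me),
                          "mixture")
}

convolve_dist <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <-
      out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

#' Monte-Carlo exact goodness-of-fit test for T-score counts
#'
#' Compares observed T-score counts with an expected distribution using the
#' chi-square statistic as the measure of dissimilarity and a Monte-Carlo
#' reference distribution: replicates are drawn multinomially from the
#' expected distribution at the observed sample size. Adjacent score
#' categories are pooled until every pooled category has expected count of
#' at least 1; the same pooling is applied to observed and simulated counts.
#' The p-value uses the add-one estimator
#' `(1 + #\{chi2_sim >= chi2_obs\}) / (1 + n_reps)`, so it is never exactly 0.
#'
#' @param observed_counts integer vector of counts over scores `0 .. 2L`.
#' @param expected a `tscore_distribution` (or probability vector) of the
#'   same length.
#' @param n_reps number of Monte-Carlo replicates (default 2000).
#' @param seed RNG seed (required, recorded in the result).
#' @return list of class `exact_test_result`: `chi2_observed`, `p_value`,
#'   `n_reps`, `seed`.
#' @export
mc_exact_test <- function(observed_counts, expected, n_reps = 2000, seed) {
  if (missing(seed)) stop("a seed is required")
  probs <- as.numeric(expected)
  stopifnot(length(observed_counts) == length(probs), n_reps >= 1,
            sum(observed_counts) >= 1)
  N <- sum(observed_counts)
  exp_counts <- probs * N
  # pool adjacent positive-expectation categories left-to-right until the
  # pooled expectation reaches 1; a light trailing group is folded back.
  # Zero-probability categories are kept apart: observations there make the
  # statistic infinite rather than being absorbed into a neighbour.
  pos <- exp_counts > 0
  grp <- integer(length(probs)); g <- 1L; acc <- 0
  for (i in which(pos)) {
    grp[i] <- g
    acc <- acc + exp_counts[i]
    if (acc >= 1) { g <- g + 1L; acc <- 0 }
  }
  if (acc > 0 && acc < 1 && g > 1L) grp[grp == g] <- g - 1L
  pool_counts <- function(x) as.numeric(rowsum(x[pos], grp[pos]))
  eg <- pool_counts(exp_counts)
  chi2 <- function(x) {
    if (any(x[!pos] > 0)) return(Inf)
    og <- pool_counts(as.numeric(x))
    sum((og - eg)^2 / eg)
  }
  obs_chi2 <- chi2(as.numeric(observed_counts))
  old <- .Random.seed_save()
  set.seed(seed)
  sims <- stats::rmultinom(n_reps, N, probs)
  sim_chi2 <- apply(sims, 2L, chi2)
  .Random.seed_restore(old)
  p <- if (is.infinite(obs_chi2)) 1 / (1 + n_reps) else
    (1 + sum(sim_chi2 >= obs_chi2)) / (1 + n_reps)
  structure(list(chi2_observed = obs_chi2, p_value = p,
                 n_reps = n_reps, seed = seed),
            class = "exact_test_result")
}

#' @export
print.exact_test_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo exact test: chi2 = %.3f, p = %.4g (%d reps, seed %s)\n",
              x$chi2_observed, x$p_value, x$n_reps, format(x$seed)))
  invisible(x)
}

#' Full disequilibrium report for one sample
#'
#' Bundles the observed F_IS and R' with their non-interbreeding-mixture
#' maxima and the inferred mixing proportion.
#'
#' @param pooled a `pooled_table` holding one sample.
#' @return list of class `diseq_report`: `fis_per_locus`, `fis_mean`,
#'   `r_per_pair`, `r_mean`, `fis_max`, `r_max`, `m_hat`.
#' @export
diseq_report <- function(pooled) {
  f <- fis(pooled)
  r <- r_prime(pooled)
  mx <- mixture_maxima(compound_t_freqs(pooled), pooled$registry)
  structure(list(fis_per_locus = f$per_locus, fis_mean = f$mean,
                 r_per_pair = r$per_pair, r_mean = r$mean,
                 fis_max = mx$fis_max, r_max = mx$r_max, m_hat = mx$m_hat),
            class = "diseq_report")
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
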