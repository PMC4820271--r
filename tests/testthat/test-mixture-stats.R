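test_that("F_IS hits its closed-form values on canonical samples", {
  # 5 individuals dosage 0 + 5 dosage 2: complete mixture, F_IS = 1
  ps <- pooled_fixture(matrix(rep(c(0L, 2L), each = 5), ncol = 1))
  expect_equal(fis(ps)$per_locus[["L1"]], 1)
  # all heterozygotes: F_IS = -1
  ph <- pooled_fixture(matrix(rep(1L, 10), ncol = 1))
  expect_equal(fis(ph)$per_locus[["L1"]], -1)
  # monomorphic locus excluded from the mean with warning
  pm <- pooled_fixture(cbind(rep(2L, 6), rep(c(0L, 2L), 3)))
  expect_warning(f <- fis(pm), "monomorphic")
  expect_true(is.na(f$per_locus[["L1"]]))
  expect_equal(f$mean, 1)
})

test_that("F_IS of a large Hardy-Weinberg sample is near zero", {
  set.seed(301)
  d <- vapply(c(0.5, 0.4, 0.6, 0.5), function(p) rbinom(1e4, 2, p),
              integer(1e4))
  f <- fis(pooled_fixture(d))
  expect_lt(abs(f$mean), 0.02)
})

test_that("F_IS and R' match brute-force genotype counting on small fixtures", {
  # independent oracle: direct counting over the genotype list
  d <- rbind(c(2L, 2L), c(2L, 1L), c(1L, 1L), c(0L, 0L), c(0L, 1L),
             c(2L, 2L), c(0L, 0L), c(1L, 2L), c(2L, 2L), c(0L, 0L))
  ps <- pooled_fixture(d)
  for (j in 1:2) {
    x <- d[, j]
    p <- sum(x) / (2 * length(x))
    f_brute <- 1 - mean(x == 1L) / (2 * p * (1 - p))
    expect_equal(fis(ps)$per_locus[[paste0("L", j)]], f_brute)
  }
  # composite correlation equals the Pearson correlation of dosages once
  # the within-locus departures are folded into the standardisation
  n <- nrow(d)
  r_pearson <- stats::cor(d[, 1L], d[, 2L]) # n-1 denominators cancel
  expect_equal(unname(r_prime(ps)$per_pair), r_pearson)
})

test_that("R' is 1 for perfectly associated loci and ~0 after permutation", {
  d <- rbind(matrix(2L, 5, 4), matrix(0L, 5, 4))
  r <- r_prime(pooled_fixture(d))
  expect_equal(unname(r$per_pair), rep(1, 6))
  expect_equal(r$mean, 1)
  # permutation oracle: independently permuted dosage columns decorrelate
  set.seed(77)
  big <- vapply(1:4, function(j) sample(rep(c(0L, 1L, 2L), length.out = 3000)),
                integer(3000))
  expect_lt(abs(r_prime(pooled_fixture(big))$mean), 0.05)
})

test_that("mixture maxima reach 1 for diagnostic loci and vanish for pure samples", {
  reg <- diag_registry()
  mx <- mixture_maxima(stats::setNames(rep(0.5, 4), paste0("L", 1:4)), reg)
  expect_equal(mx$fis_max, 1)
  expect_equal(mx$r_max, 1)
  expect_equal(mx$m_hat, 0.5)
  # pure samples: m = 0 or 1 gives no Wahlund effect
  for (f in c(0, 1)) {
    mx0 <- mixture_maxima(stats::setNames(rep(f, 4), paste0("L", 1:4)), reg)
    expect_equal(mx0$fis_max, 0)
    expect_equal(mx0$r_max, 0)
  }
})

test_that("Wahlund maximum matches the closed form for partial diagnosticity", {
  # refs 0.1/0.9 at m = 0.5: 1 - 0.18/0.5 = 0.64
  loci <- paste0("L", 1:4)
  reg <- biallelic_registry(stats::setNames(rep(0.1, 4), loci),
                            stats::setNames(rep(0.9, 4), loci))
  mx <- mixture_maxima(stats::setNames(rep(0.5, 4), loci), reg)
  expect_equal(mx$fis_max, 1 - 0.18 / 0.5)
})

test_that("maxima are largest near a balanced mixture", {
  loci <- paste0("L", 1:4)
  reg <- biallelic_registry(stats::setNames(c(0.02, 0.05, 0.1, 0.05), loci),
                            stats::setNames(c(0.97, 0.95, 0.9, 0.8), loci))
  ms <- seq(0, 1, by = 0.1)
  vals <- vapply(ms, function(m) {
    f <- m * reg$ref$t_mt + (1 - m) * reg$ref$t_me
    mixture_maxima(stats::setNames(f, loci), reg)$fis_max
  }, 0)
  # with unequal reference pairs the peak sits near (not exactly at) 0.5
  expect_true(abs(ms[which.max(vals)] - 0.5) <= 0.1)
  expect_gt(vals[ms == 0.5], max(vals[ms <= 0.2], vals[ms >= 0.8]))
  expect_equal(vals[1L], 0)
  expect_equal(vals[length(vals)], 0)
})

test_that("empirical disequilibrium of a 50:50 mixture approaches the maxima", {
  # parameter recovery: simulate a large physical mixture without
  # interbreeding and compare observed F_IS / R' with the computed maxima
  set.seed(88)
  freqs <- default_freqs()
  reg <- registry_from_freqs(freqs)
  mix <- compose_mixture(freqs, counts = c(ME = 2000, MT = 2000), seed = 88)
  pooled <- pool(mix$table, reg)
  dr <- diseq_report(pooled)
  expect_equal(dr$fis_mean, dr$fis_max, tolerance = 0.05)
  expect_equal(dr$r_mean, dr$r_max, tolerance = 0.05)
})

test_that("panmictic T-score distribution equals full genotype enumeration", {
  d1 <- expected_tscore_panmixia(0.5)
  expect_equal(as.numeric(d1), c(0.25, 0.5, 0.25))
  # 4 loci at t = 0.5: P(score = 4) = 70/256, against full 3^4 enumeration
  t <- c(0.5, 0.5, 0.5, 0.5)
  d4 <- expected_tscore_panmixia(t)
  expect_equal(d4[["4"]], 70 / 256)
  enum <- numeric(9)
  for (g in seq_len(3^4) - 1L) {
    ds <- (g %/% 3^(0:3)) %% 3
    pr <- prod(stats::dbinom(ds, 2, t))
    enum[sum(ds) + 1L] <- enum[sum(ds) + 1L] + pr
  }
  expect_equal(as.numeric(d4), enum)
  # heterogeneous frequencies against the same enumeration oracle
  t2 <- c(0.1, 0.35, 0.7, 0.95)
  d_h <- expected_tscore_panmixia(t2)
  enum2 <- numeric(9)
  for (g in seq_len(3^4) - 1L) {
    ds <- (g %/% 3^(0:3)) %% 3
    pr <- prod(stats::dbinom(ds, 2, t2))
    enum2[sum(ds) + 1L] <- enum2[sum(ds) + 1L] + pr
  }
  expect_equal(as.numeric(d_h), enum2)
  # degenerate: all-zero frequencies give a point mass at score 0
  d0 <- expected_tscore_panmixia(rep(0, 4))
  expect_equal(as.numeric(d0), c(1, rep(0, 8)))
})

test_that("T-score distributions sum to 1 and preserve the mean", {
  set.seed(12)
  for (rep in 1:20) {
    t <- runif(4)
    d <- expected_tscore_panmixia(t)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_equal(sum(as.numeric(names(d)) * d), 2 * sum(t), tolerance = 1e-9)
  }
})

test_that("mixture T-score distribution interpolates the parental components", {
  loci <- paste0("L", 1:4)
  reg <- biallelic_registry(stats::setNames(rep(0.1, 4), loci),
                            stats::setNames(rep(0.9, 4), loci))
  me_dist <- expected_tscore_panmixia(rep(0.1, 4))
  expect_equal(as.numeric(expected_tscore_mixture(0, reg)), as.numeric(me_dist))
  # fully diagnostic, m = 0.5: all mass at the extreme scores
  regd <- diag_registry()
  dd <- expected_tscore_mixture(0.5, regd)
  expect_equal(dd[["0"]], 0.5)
  expect_equal(dd[["8"]], 0.5)
  expect_equal(sum(dd[2:8]), 0)
  # refs 0.1/0.9, m = 0.3: brute-force two-component enumeration
  m <- 0.3
  enum <- numeric(9)
  for (g in seq_len(3^4) - 1L) {
    ds <- (g %/% 3^(0:3)) %% 3
    pr <- m * prod(stats::dbinom(ds, 2, 0.9)) +
      (1 - m) * prod(stats::dbinom(ds, 2, 0.1))
    enum[sum(ds) + 1L] <- enum[sum(ds) + 1L] + pr
  }
  expect_equal(as.numeric(expected_tscore_mixture(m, reg)), enum)
})

test_that("Monte-Carlo exact test behaves at the extremes", {
  expected <- expected_tscore_panmixia(rep(0.5, 4))
  obs <- round(unclass(expected) * 256)
  res <- mc_exact_test(obs, expected, n_reps = 200, seed = 1)
  expect_equal(res$chi2_observed, 0)
  expect_equal(res$p_value, 1)
  # maximal discrepancy: observations where the null puts zero mass
  point0 <- c(1, rep(0, 8))  # point mass at score 0
  obs8 <- c(rep(0, 8), 50)
  res8 <- mc_exact_test(obs8, point0, n_reps = 200, seed = 1)
  expect_equal(res8$p_value, 1 / 201)
  # determinism by seed
  obs2 <- c(30, 10, 5, 2, 1, 2, 5, 10, 30)
  r1 <- mc_exact_test(obs2, expected, n_reps = 500, seed = 9)
  r2 <- mc_exact_test(obs2, expected, n_reps = 500, seed = 9)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("Monte-Carlo p-values are super-uniform under the null", {
  set.seed(55)
  expected <- expected_tscore_panmixia(c(0.3, 0.5, 0.6, 0.4))
  pvals <- replicate(200, {
    obs <- as.integer(stats::rmultinom(1, 60, unclass(expected)))
    mc_exact_test(obs, expected, n_reps = 199,
                  seed = sample.int(1e6, 1))$p_value
  })
  for (alpha in c(0.05, 0.1, 0.25))
    expect_lte(mean(pvals <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 200))
})
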