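test_that("Genepop round-trip preserves genotypes, missingness and grouping", {
  tab <- tiny_table()
  f <- tempfile(fileext = ".gen")
  write_genepop(tab, f)
  back <- read_genepop(f)
  expect_equal(length(back$individuals), 6L)
  expect_equal(back$loci, tab$loci)
  expect_equal(unname(back$a1), unname(tab$a1))
  expect_equal(unname(back$a2), unname(tab$a2))
  # grouping: same partition of individuals into samples
  expect_equal(as.integer(factor(back$sample_id)),
               as.integer(factor(tab$sample_id)))
  # missing genotype came back missing
  expect_true(is.na(back$a1[4L, "Odh"]) && is.na(back$a2[4L, "Odh"]))
})

test_that("Genepop reader handles 3-digit coding and all-zero missing codes", {
  f <- tempfile(fileext = ".gen")
  writeLines(c("three-digit fixture", "locA", "locB", "POP",
               "x1 , 101102 000000", "x2 , 102102 101101"), f)
  tab <- read_genepop(f)
  expect_equal(tab$a1[1L, "locA"], "101")
  expect_equal(tab$a2[1L, "locA"], "102")
  expect_true(is.na(tab$a1[1L, "locB"]))
  expect_equal(tab$a2[2L, "locB"], "101")
})

test_that("malformed Genepop input raises parse errors", {
  f <- tempfile(fileext = ".gen")
  writeLines(c("no pop line", "locA", "x1 , 0101"), f)
  expect_error(read_genepop(f), "POP")
  writeLines(c("odd allele width", "locA", "POP", "x1 , 011"), f)
  expect_error(read_genepop(f), "4 or 6")
  writeLines(c("wrong count", "locA", "locB", "POP", "x1 , 0101"), f)
  expect_error(read_genepop(f), "2 loci")
})

test_that("tabular dialect round-trips including substrate metadata", {
  tab <- tiny_table()
  f <- tempfile(fileext = ".tsv")
  write_genotype_tsv(tab, f)
  back <- read_genotype_tsv(f)
  expect_equal(back$individuals, tab$individuals)
  expect_equal(unname(back$a1), unname(tab$a1))
  expect_equal(back$substrate, tab$substrate)
  expect_equal(back$sample_id, tab$sample_id)
})

test_that("registry pools alleles by the strictly-greater-in-MT rule", {
  reg <- build_registry(
    ref_me = list(l1 = c(a = 0.9, b = 0.1)),
    ref_mt = list(l1 = c(a = 0.1, b = 0.9)))
  expect_equal(reg$pooling$l1[["a"]], "E")
  expect_equal(reg$pooling$l1[["b"]], "T")
  expect_equal(reg$ref$t_me, 0.1)
  expect_equal(reg$ref$t_mt, 0.9)

  # three alleles: pairwise comparison per allele
  reg3 <- build_registry(
    ref_me = list(l1 = c(a = 0.8, b = 0.15, c = 0.05)),
    ref_mt = list(l1 = c(a = 0.05, b = 0.05, c = 0.90)))
  expect_equal(unname(reg3$pooling$l1[c("a", "b", "c")]), c("E", "E", "T"))

  # tie rule: equal frequencies pooled as E, with a warning
  expect_warning(
    reg_tie <- build_registry(
      ref_me = list(l1 = c(a = 0.5, b = 0.3, c = 0.2)),
      ref_mt = list(l1 = c(a = 0.1, b = 0.3, c = 0.6))),
    "equal reference")
  expect_equal(reg_tie$pooling$l1[["b"]], "E")
})

test_that("registry rejects non-normalised input and YAML round-trips", {
  expect_error(build_registry(ref_me = list(l1 = c(a = 0.5, b = 0.4)),
                              ref_mt = list(l1 = c(a = 0.1, b = 0.9))),
               "sum to 1")
  reg <- registry_from_freqs(default_freqs())
  f <- tempfile(fileext = ".yaml")
  write_registry(reg, f)
  back <- read_registry(f)
  expect_equal(back$loci, reg$loci)
  expect_equal(back$pooling, reg$pooling)
  expect_equal(back$ref$t_mt, reg$ref$t_mt)
})

test_that("pooling yields T-allele dosages and errors on unknown alleles", {
  tab <- tiny_table()
  reg <- biallelic_registry(
    t_me = c("Est-D" = 0.02, "Gpi" = 0.05, "Pgm" = 0.10, "Odh" = 0.05),
    t_mt = c("Est-D" = 0.97, "Gpi" = 0.95, "Pgm" = 0.90, "Odh" = 0.80))
  pooled <- pool(tab, reg)
  expect_equal(unname(pooled$dosage[1L, ]), c(0L, 1L, 2L, 0L))
  expect_equal(unname(pooled$dosage[2L, ]), c(2L, 2L, 2L, 2L))
  expect_true(is.na(pooled$dosage[4L, "Odh"]))
  bad <- tab
  bad$a1[1L, 1L] <- "99"
  expect_error(pool(bad, reg), "unresolvable")
})

test_that("pooling conserves allele counts at every locus", {
  set.seed(42)
  freqs <- default_freqs()
  reg <- registry_from_freqs(freqs)
  mix <- compose_mixture(freqs, seed = 5)
  pooled <- pool(mix$table, reg)
  for (j in seq_along(pooled$loci)) {
    d <- pooled$dosage[, j]
    d <- d[!is.na(d)]
    expect_equal(sum(d) + sum(2L - d), 2L * length(d))
  }
})

test_that("T-scores equal brute-force recounts and track missing loci", {
  reg <- biallelic_registry(
    t_me = c("Est-D" = 0.02, "Gpi" = 0.05, "Pgm" = 0.10, "Odh" = 0.05),
    t_mt = c("Est-D" = 0.97, "Gpi" = 0.95, "Pgm" = 0.90, "Odh" = 0.80))
  tab <- tiny_table()
  sc <- t_score(pool(tab, reg))
  expect_equal(sc$t_score, unname(brute_tscore(tab, reg)))
  expect_equal(sc$n_loci_scored[4L], 3L)
  expect_equal(sc$t_score[2L], 8L)     # full MT homozygote
  expect_equal(sc$t_score[5L], 0L)     # full ME homozygote

  # direct-summation example: dosages (2,1,0,NA) -> 3 over 3 loci
  ps <- pooled_fixture(rbind(c(2L, 1L, 0L, NA)))
  s1 <- t_score(ps)
  expect_equal(s1$t_score, 3L)
  expect_equal(s1$n_loci_scored, 3L)
  # F1-like dosages (1,1,1,1) -> 4
  expect_equal(t_score(pooled_fixture(rbind(rep(1L, 4))))$t_score, 4L)
  # all-missing individual flagged unscorable
  expect_warning(s0 <- t_score(pooled_fixture(rbind(rep(NA_integer_, 4)))),
                 "unscorable")
  expect_true(is.na(s0$t_score))
})

test_that("scaled T-frequency hits 0, 1 and the midpoint on reference data", {
  # refs 0.1/0.9 at every locus
  reg <- biallelic_registry(stats::setNames(rep(0.1, 4), paste0("L", 1:4)),
                            stats::setNames(rep(0.9, 4), paste0("L", 1:4)))
  # observed exactly at ME refs: 10 individuals, per locus T-freq 0.1
  d_me <- do.call(rbind, replicate(10, c(0L, 0L, 0L, 0L), simplify = FALSE))
  d_me[1L, ] <- 2L                      # 2/20 alleles T = 0.1
  expect_equal(t_frequency(pooled_fixture(d_me, reg)), 0)
  # observed at MT refs
  d_mt <- do.call(rbind, replicate(10, c(2L, 2L, 2L, 2L), simplify = FALSE))
  d_mt[1L, ] <- 0L
  expect_equal(t_frequency(pooled_fixture(d_mt, reg)), 1)
  # midpoint: observed 0.5 with refs 0.1/0.9 -> 0.5
  d_mid <- rbind(c(2L, 2L, 2L, 2L), c(0L, 0L, 0L, 0L))
  expect_equal(t_frequency(pooled_fixture(d_mid, reg)), 0.5)
})

test_that("T-frequency is monotone in observed frequencies and clips overshoot", {
  reg <- biallelic_registry(stats::setNames(c(0.1, 0.2, 0.1, 0.3), paste0("L", 1:4)),
                            stats::setNames(c(0.9, 0.8, 0.95, 0.7), paste0("L", 1:4)))
  base <- pooled_fixture(rbind(c(1L, 1L, 1L, 1L), c(1L, 1L, 1L, 1L)), reg)
  up <- pooled_fixture(rbind(c(2L, 1L, 1L, 1L), c(1L, 1L, 1L, 1L)), reg)
  expect_gt(t_frequency(up), t_frequency(base))
  # all dosage 2 overshoots the MT reference at every locus -> clipped to 1
  hi <- pooled_fixture(rbind(c(2L, 2L, 2L, 2L), c(2L, 2L, 2L, 2L)), reg)
  expect_equal(suppressMessages(t_frequency(hi)), 1)
})

test_that("allele frequencies come from counts and sum to 1 per locus", {
  tab <- tiny_table()
  reg <- biallelic_registry(
    t_me = c("Est-D" = 0.02, "Gpi" = 0.05, "Pgm" = 0.10, "Odh" = 0.05),
    t_mt = c("Est-D" = 0.97, "Gpi" = 0.95, "Pgm" = 0.90, "Odh" = 0.80))
  af <- allele_frequencies(tab, reg)
  for (l in unique(af$locus))
    expect_equal(sum(af$freq[af$locus == l]), 1)
  # count oracle: dosages (2,1,1,0) -> T-freq 4/8
  ps <- pooled_fixture(rbind(2L, 1L, 1L, 0L))
  expect_equal(unname(compound_t_freqs(ps)[1L]), 0.5)
  # locus with all genotypes missing is omitted
  tab2 <- tiny_table()
  tab2$a1[, "Gpi"] <- NA_character_
  tab2$a2[, "Gpi"] <- NA_character_
  af2 <- allele_frequencies(tab2)
  expect_false("Gpi" %in% af2$locus)
})
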