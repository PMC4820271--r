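test_that("T-score bands assign 0-1 to ME, 2-6 to hybrids, 7-8 to MT", {
  expect_equal(classify_by_tscore(c(0, 1, 2, 4, 6, 7, 8)),
               c("ME", "ME", "HYBRID", "HYBRID", "HYBRID", "MT", "MT"))
  # individuals with fewer than 4 scored loci are left unclassified
  sc <- data.frame(t_score = c(3L, 3L), n_loci_scored = c(4L, 3L))
  expect_equal(classify_by_tscore(sc), c("HYBRID", NA))
})

test_that("performance matches a hand-computed confusion table", {
  truth <- c(rep("ME", 10), rep("MT", 10), rep("HYBRID", 10))
  pred <- c(rep("ME", 9), "HYBRID",
            rep("MT", 10),
            rep("HYBRID", 8), "ME", "ME")
  pr <- performance(truth, pred)
  expect_equal(unname(pr$efficiency[c("ME", "MT", "HYBRID")]),
               c(0.9, 1.0, 0.8))
  expect_equal(unname(pr$accuracy[c("ME", "MT", "HYBRID")]),
               c(9 / 11, 1.0, 8 / 9))
  expect_equal(pr$overall, mean(c(0.9, 1, 0.8)) * mean(c(9 / 11, 1, 8 / 9)))
  # perfect prediction
  expect_equal(performance(truth, truth)$overall, 1)
  # everything predicted hybrid: hybrid efficiency 1, purebreds 0
  expect_warning(ph <- performance(truth, rep("HYBRID", 30)),
                 "never predicted")
  expect_equal(unname(ph$efficiency[c("ME", "MT", "HYBRID")]), c(0, 0, 1))
})

test_that("threshold calibration achieves the nominal efficiency by construction", {
  set.seed(41)
  iss <- c(runif(100, 0, 0.05), runif(100, 0.95, 1), runif(60, 0.2, 0.8))
  truth <- c(rep("ME", 100), rep("MT", 100), rep("HYBRID", 60))
  for (cr in c("pure95", "pure90", "hyb95", "hyb90")) {
    rule <- calibrate_thresholds(iss, truth, cr)
    expect_lt(rule$lower, rule$upper)
    pred <- classify_by_iss(iss, rule)
    pr <- performance(truth, pred)
    e <- if (grepl("95", cr)) 0.95 else 0.90
    targets <- if (startsWith(cr, "pure")) c("ME", "MT") else "HYBRID"
    n_min <- min(table(truth)[targets])
    # achieved efficiency >= nominal minus one rank unit
    for (tg in targets)
      expect_gte(pr$efficiency[[tg]], e - 1 / n_min)
  }
})

test_that("well-separated ISS yield pure95 thresholds enclosing the purebreds", {
  iss <- c(seq(0, 0.05, length.out = 50), seq(0.95, 1, length.out = 50),
           seq(0.3, 0.7, length.out = 30))
  truth <- c(rep("ME", 50), rep("MT", 50), rep("HYBRID", 30))
  rule <- calibrate_thresholds(iss, truth, "pure95")
  expect_lte(rule$lower, 0.05)
  expect_gte(rule$upper, 0.95)
  pr <- performance(truth, classify_by_iss(iss, rule))
  # nominal efficiency up to one rank unit of the percentile
  expect_gte(pr$efficiency[["ME"]], 0.95 - 1 / 50)
  expect_gte(pr$efficiency[["MT"]], 0.95 - 1 / 50)
})

test_that("degenerate hybrid distribution makes the hybrid criterion infeasible", {
  iss <- c(runif(20, 0, 0.1), runif(20, 0.9, 1), rep(0.5, 20))
  truth <- c(rep("ME", 20), rep("MT", 20), rep("HYBRID", 20))
  expect_error(calibrate_thresholds(iss, truth, "hyb95"), "infeasible")
})

test_that("ISS classification partitions [0,1] with boundaries toward purebreds", {
  rule <- structure(list(lower = 0.062, upper = 0.916, criterion_id = "pure95"),
                    class = "threshold_rule")
  expect_equal(classify_by_iss(c(0.01, 0.5, 0.99), rule),
               c("ME", "HYBRID", "MT"))
  expect_equal(classify_by_iss(0.062, rule), "ME")   # boundary inclusive
  expect_equal(classify_by_iss(0.916, rule), "MT")
  # partition property: every value in [0,1] gets exactly one class
  grid <- seq(0, 1, by = 0.001)
  cls <- classify_by_iss(grid, rule)
  expect_false(anyNA(cls))
  expect_true(all(cls %in% c("ME", "HYBRID", "MT")))
  expect_true(!is.unsorted(match(cls, c("ME", "HYBRID", "MT"))))
})

test_that("criterion selection maximises overall performance and breaks ties", {
  set.seed(42)
  iss <- c(rbeta(150, 1, 30), rbeta(150, 30, 1), runif(60, 0.15, 0.85))
  truth <- c(rep("ME", 150), rep("MT", 150), rep("HYBRID", 60))
  sel <- select_best_criterion(iss, truth)
  ov <- vapply(sel$reports, `[[`, 0, "overall")
  expect_equal(sel$best$criterion_id, names(ov)[which.max(ov)])
  # single feasible criterion is returned trivially
  sel1 <- select_best_criterion(iss, truth, criteria = "pure95")
  expect_equal(sel1$best$criterion_id, "pure95")
  # tie in overall performance resolves toward higher hybrid efficiency
  iss_sym <- c(rep(0.02, 50), rep(0.98, 50), rep(c(0.3, 0.7), 25))
  truth_sym <- c(rep("ME", 50), rep("MT", 50), rep("HYBRID", 50))
  expect_message(
    sel2 <- select_best_criterion(iss_sym, truth_sym,
                                  criteria = c("pure95", "pure90")),
    "tie")
  expect_true(sel2$best$criterion_id %in% c("pure95", "pure90"))
})

test_that("T-score and calibrated ISS classification agree on simulated purebreds", {
  # consistency is a property of the average behaviour; single replicates
  # carry percentile rank noise, so agreement is pooled over replicates
  freqs <- default_freqs()
  reg <- registry_from_freqs(freqs)
  agree <- n_pure <- 0
  for (s in 61:64) {
    mix <- compose_mixture(freqs, seed = s)
    fit <- orient_labels(
      fit_admixture(mix$table, burn_in = 5000, keep = 10000,
                    seed = s + 1000), reg)
    truth <- compound_class(mix$true_class)
    rule <- calibrate_thresholds(fit$iss, truth, "pure95")
    pred_iss <- classify_by_iss(fit$iss, rule)
    pred_ts <- classify_by_tscore(t_score(pool(mix$table, reg)))
    pure <- truth %in% c("ME", "MT")
    agree <- agree + sum(pred_iss[pure] == pred_ts[pure])
    n_pure <- n_pure + sum(pure)
  }
  expect_gte(agree / n_pure, 0.9)
})
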