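#' Run the full hybrid-zone analysis
#'
#' Orchestrates the whole pipeline in the order of a field study analysis:
#' pooling into compound alleles, per-sample hybrid-index and
#' disequilibrium statistics with mixture maxima and Monte-Carlo exact
#' tests against both null models, Bayesian admixture ancestry (ISS / PSS),
#' threshold calibration on simulated known-ancestry mixtures,
#' per-individual classification, and the morpho-ecological summaries when
#' shell and quadrat tables are supplied. Each stage failure is re-thrown
#' with the stage name; partial results computed before the failure are
#' attached to the error condition.
#'
#' @param genotypes a [genotype_table()] or a [generate_study()] bundle (in
#'   which case `registry`, `shells` and `quadrats` are taken from it).
#' @param registry an `allele_registry`.
#' @param shells optional morphology data.frame (columns `id`, `site`,
#'   `substrate`, `L`, `l`, `a`).
#' @param quadrats optional quadrat data.frame (columns `site`, `substrate`,
#'   `count`, `tuft_weight`, `total_algae_weight`).
#' @param mcmc list with `burn_in`, `keep` and optionally `update_alpha`
#'   for [fit_admixture()]; the pipeline's fits update the ancestry prior
#'   concentration by default, as a hybrid-zone sample is strongly bimodal.
#' @param exact_test_reps Monte-Carlo replicates for the exact tests
#'   (default 2000).
#' @param calibration `NULL` to skip threshold calibration, or a list with
#'   `n_replicates` (default 6), `counts` (mixture composition), `criteria`
#'   and `mode`: `"joint"` (default) co-analyzes each simulated cohort with
#'   the empirical genotypes so calibration ISS share the empirical scale;
#'   `"simulated_only"` fits the cohorts alone.
#' @param iss optional precomputed named ISS vector; skips the MCMC stage.
#' @param n_boot bootstrap replicates for the substrate contrast.
#' @param seed master seed (required); all stage seeds derive from it.
#' @param out_dir optional directory; when given, every report is written
#'   as TSV and the run configuration as YAML.
#' @return list of class `hz_run`: `sample_summary`, `allele_freqs`,
#'   `classification`, `iss`, `pss`, `calibration`, `morphology`
#'   (concordance, densities, substrate contrast) and `seeds`.
#' @export
run_full <- function(genotypes, registry = NULL, shells = NULL,
                     quadrats = NULL,
                     mcmc = list(burn_in = 30000, keep = 50000),
                     exact_test_reps = 2000,
                     calibration = list(n_replicates = 6),
                     iss = NULL, n_boot = 1000, seed, out_dir = NULL) {
  if (missing(seed)) stop("a seed is required")
  if (inherits(genotypes, "synthetic_study")) {
    bundle <- genotypes
    genotypes <- bundle$genotypes
    if (is.null(registry)) registry <- bundle$registry
    if (is.null(shells)) shells <- bundle$shells
    if (is.null(quadrats)) quadrats <- bundle$quadrats
  }
  if (is.null(registry)) stop("a registry is required")
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  seeds <- list(exact = sample.int(2^31 - 1, 1), admix = sample.int(2^31 - 1, 1),
                calib = sample.int(2^31 - 1, 1), boot = sample.int(2^31 - 1, 1))
  out <- list(seeds = seeds)

  pooled <- stage("pool", pool(genotypes, registry))
  scores <- stage("t_score", t_score(pooled))

  out$allele_freqs <- stage("allele_frequencies", {
    do.call(rbind, lapply(unique(genotypes$sample_id), function(s) {
      af <- allele_frequencies(
        subset_individuals(genotypes, genotypes$sample_id == s), registry)
      cbind(sample = s, af)
    }))
  })

  out$sample_summary <- stage("sample_stats", {
    do.call(rbind, lapply(unique(pooled$sample_id), function(s) {
      sub <- subset_pooled(pooled, pooled$sample_id == s)
      dr <- suppressWarnings(diseq_report(sub))
      tf <- suppressMessages(t_frequency(sub))
      obs <- tabulate(scores$t_score[pooled$sample_id == s &
                                       scores$n_loci_scored ==
                                         length(pooled$loci)] + 1L,
                      2L * length(pooled$loci) + 1L)
      pan <- expected_tscore_panmixia(compound_t_freqs(sub))
      mix <- expected_tscore_mixture(dr$m_hat, registry)
      na_test <- list(chi2_observed = NA_real_, p_value = NA_real_)
      et_pan <- if (sum(obs) > 0)
        mc_exact_test(obs, pan, exact_test_reps, seeds$exact) else na_test
      et_mix <- if (sum(obs) > 0)
        mc_exact_test(obs, mix, exact_test_reps, seeds$exact) else na_test
      data.frame(sample = s, n = sum(pooled$sample_id == s),
                 t_frequency = tf, fis_mean = dr$fis_mean,
                 r_mean = dr$r_mean, fis_max = dr$fis_max,
                 r_max = dr$r_max, m_hat = dr$m_hat,
                 chi2_panmixia = et_pan$chi2_observed,
                 p_panmixia = et_pan$p_value,
                 chi2_mixture = et_mix$chi2_observed,
                 p_mixture = et_mix$p_value, stringsAsFactors = FALSE)
    }))
  })

  if (is.null(iss)) {
    fit <- stage("admixture", {
      f <- fit_admixture(genotypes, burn_in = mcmc$burn_in,
                         keep = mcmc$keep, seed = seeds$admix,
                         update_alpha = mcmc$update_alpha %||% TRUE)
      orient_labels(f, registry)
    })
    iss <- fit$iss
    out$pss <- pss(fit)
    out$sample_summary$pss <-
      out$pss[match(out$sample_summary$sample, names(out$pss))]
  } else {
    out$pss <- vapply(split(iss[genotypes$individuals],
                            genotypes$sample_id), mean, 0)
    out$sample_summary$pss <-
      out$pss[match(out$sample_summary$sample, names(out$pss))]
  }
  out$iss <- iss

  class_iss <- rep(NA_character_, length(genotypes$individuals))
  if (!is.null(calibration)) {
    out$calibration <- stage("calibration", {
      calibrate_from_simulations(
        registry = registry,
        empirical = if ((calibration$mode %||% "joint") == "joint")
          genotypes else NULL,
        freqs = registry_freqs_or(calibration$freqs, registry),
        n_replicates = calibration$n_replicates %||% 6,
        counts = calibration$counts %||%
          c(ME = 80, MT = 80, F1 = 10, F2 = 10, BC_ME = 10, BC_MT = 10),
        criteria = calibration$criteria %||%
          c("pure95", "hyb95", "pure90", "hyb90"),
        mcmc = mcmc, seed = seeds$calib)
    })
    class_iss <- classify_by_iss(iss[genotypes$individuals],
                                 out$calibration$best)
  }

  out$classification <- stage("classification", data.frame(
    id = genotypes$individuals, sample = genotypes$sample_id,
    site = genotypes$site_id, substrate = genotypes$substrate,
    t_score = scores$t_score, n_loci_scored = scores$n_loci_scored,
    class_tscore = classify_by_tscore(scores),
    iss = unname(iss[genotypes$individuals]), class_iss = class_iss,
    stringsAsFactors = FALSE))

  out$morphology <- stage("morphology", {
    mor <- NULL
    if (!is.null(shells)) {
      shells$z <- z_index(shells$a, shells$l)
      shells$morphotype <- morphotype(shells$z)
      cls <- out$classification
      use_cls <- if (all(is.na(cls$class_iss))) cls$class_tscore else
        cls$class_iss
      m <- match(shells$id, cls$id)
      conc <- concordance(use_cls[m][!is.na(m)],
                          shells$morphotype[!is.na(m)],
                          hybrids = "separate")
      contrast_morph <- suppressWarnings(substrate_contrast(
        shells$site, shells$substrate,
        as.numeric(shells$morphotype == "T"),
        n_boot = n_boot, seed = seeds$boot))
      mor <- list(shells = shells, concordance = conc,
                  substrate_contrast_morph = contrast_morph)
    }
    cls <- out$classification
    ok <- cls$n_loci_scored > 0 & cls$substrate %in% c("algae", "bottom")
    if (any(ok))
      mor$substrate_contrast_genetic <- suppressWarnings(substrate_contrast(
        cls$site[ok], cls$substrate[ok],
        cls$t_score[ok] / (2 * cls$n_loci_scored[ok]),
        n_boot = n_boot, seed = seeds$boot))
    if (!is.null(quadrats)) {
      dens <- vapply(seq_len(nrow(quadrats)), function(i) {
        qr <- quadrats[i, ]
        if (qr$substrate == "bottom") density_bottom(qr$count)$density
        else density_algae(qr$count, qr$tuft_weight,
                           qr$total_algae_weight)$density
      }, 0)
      mor$densities <- cbind(quadrats, density = dens)
    }
    mor
  })

  if (!is.null(out_dir)) stage("write", write_run(out, out_dir))
  structure(out, class = "hz_run")
}

registry_freqs_or <- function(freqs, registry) {
  if (!is.null(freqs)) return(freqs)
  # reconstruct bi-allelic generator frequencies from the compound refs
  biallelic_freqs(
    t_me = stats::setNames(registry$ref$t_me, registry$ref$locus),
    t_mt = stats::setNames(registry$ref$t_mt, registry$ref$locus))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hz_run <- function(x, ...) {
  cat("hz_run:", nrow(x$classification), "individuals,",
      nrow(x$sample_summary), "samples\n")
  if (!is.null(x$calibration))
    cat("  best threshold criterion:", x$calibration$best$criterion_id,
        sprintf("(%.4f / %.4f)\n", x$calibration$best$lower,
                x$calibration$best$upper))
  invisible(x)
}

write_run <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(out$sample_summary, "sample_summary.tsv")
  wt(out$allele_freqs, "allele_frequencies.tsv")
  wt(out$classification, "classification.tsv")
  if (!is.null(out$calibration)) {
    cal <- out$calibration
    rows <- do.call(rbind, lapply(names(cal$iss_reports), function(cr) {
      rep <- cal$iss_reports[[cr]]; rule <- cal$rules[[cr]]
      data.frame(criterion = cr, lower = rule$lower, upper = rule$upper,
                 eff_me = rep$efficiency[["ME"]],
                 eff_mt = rep$efficiency[["MT"]],
                 eff_hybrid = rep$efficiency[["HYBRID"]],
                 acc_me = rep$accuracy[["ME"]],
                 acc_mt = rep$accuracy[["MT"]],
                 acc_hybrid = rep$accuracy[["HYBRID"]],
                 overall = rep$overall, stringsAsFactors = FALSE)
    }))
    if (!is.null(rows)) wt(rows, "calibration_report.tsv")
  }
  if (!is.null(out$morphology$shells)) wt(out$morphology$shells, "shells.tsv")
  if (!is.null(out$morphology$densities))
    wt(out$morphology$densities, "densities.tsv")
  if (!is.null(out$morphology$substrate_contrast_genetic))
    wt(out$morphology$substrate_contrast_genetic,
       "substrate_contrast_genetic.tsv")
  yaml::write_yaml(out$seeds, file.path(dir, "seeds.yaml"))
  invisible(dir)
}

#' Calibrate ISS thresholds from simulated known-ancestry mixtures
#'
#' Composes `n_replicates` simulated mixtures of the six ancestry classes
#' and obtains ISS for their individuals from admixture fits, either
#' jointly with the empirical genotypes (`empirical` supplied: each
#' replicate cohort is co-analyzed with the full empirical table, so the
#' simulated ISS share the empirical fit's scale — the limited size of the
#' added cohort keeps its influence on the empirical data small) or from
#' simulated-only fits (`empirical = NULL`). The pooled labeled ISS are
#' then used to calibrate every criterion and pick the best by overall
#' performance.
#'
#' @param registry an `allele_registry` used to orient fits.
#' @param empirical optional [genotype_table()] for joint fits.
#' @param freqs simulator parental frequencies.
#' @param n_replicates,counts,criteria,mcmc,seed as in
#'   [run_calibration_experiment()].
#' @return list: `best`, `rules`, `iss_reports`, `iss`, `true_class`,
#'   `mode` (`"joint"` or `"simulated_only"`).
#' @export
calibrate_from_simulations <- function(registry, empirical = NULL,
                                       freqs, n_replicates = 6,
                                       counts = c(ME = 80, MT = 80, F1 = 10,
                                                  F2 = 10, BC_ME = 10,
                                                  BC_MT = 10),
                                       criteria = c("pure95", "hyb95",
                                                    "pure90", "hyb90"),
                                       mcmc = list(burn_in = 30000,
                                                   keep = 50000),
                                       seed) {
  if (missing(seed)) stop("a seed is required")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rep_seeds <- matrix(sample.int(2^31 - 1, 2L * n_replicates), ncol = 2L)
  iss_all <- numeric(0); truth_all <- character(0)
  for (r in seq_len(n_replicates)) {
    mix <- compose_mixture(freqs, counts, seed = rep_seeds[r, 1L],
                           sample_id = paste0("simcal", r))
    tab <- if (is.null(empirical)) mix$table else
      rbind_tables(empirical, mix$table)
    fit <- orient_labels(
      fit_admixture(tab, burn_in = mcmc$burn_in, keep = mcmc$keep,
                    seed = rep_seeds[r, 2L],
                    update_alpha = mcmc$update_alpha %||% TRUE), registry)
    iss_all <- c(iss_all, unname(fit$iss[mix$table$individuals]))
    truth_all <- c(truth_all, compound_class(mix$true_class))
  }
  sel <- select_best_criterion(iss_all, truth_all, criteria)
  list(best = sel$best, rules = sel$rules, iss_reports = sel$reports,
       iss = iss_all, true_class = truth_all,
       mode = if (is.null(empirical)) "simulated_only" else "joint",
       seed = seed)
}

#' Calibration experiment: five classification methods compared
#'
#' Re-runs the simulation-calibration design: six (by default) replicate
#' mixtures of the six ancestry classes in proportions 80:80:10:10:10:10
#' (N = 200) are simulated; every individual is classified by the direct
#' T-score rule (method 1), and the admixture model is fitted to each
#' replicate to obtain ISS, from which the four threshold criteria
#' (methods 2-5: 95%/90% purebred or hybrid efficiency) are calibrated on
#' the pooled labeled ISS and scored. Efficiency, accuracy and overall
#' performance are pooled over replicates; the best-performing criterion is
#' flagged.
#'
#' @param freqs parental frequency tables for the simulator.
#' @param n_replicates number of replicate mixtures (default 6).
#' @param counts class composition per mixture.
#' @param criteria threshold criteria to compare.
#' @param mcmc list with `burn_in`, `keep` for the admixture fits; set
#'   `mcmc = NULL` to skip the ISS methods (T-score only).
#' @param seed master seed (required).
#' @return list: `tscore_report` (pooled `performance_report` of method 1),
#'   `tscore_overall_by_rep` (per-replicate overall, for the spread),
#'   `iss_reports` (per criterion), `rules`, `best` (best `threshold_rule`
#'   by overall performance), `iss`, `true_class` (pooled calibration data),
#'   `seed`.
#' @export
run_calibration_experiment <- function(freqs = default_freqs(),
                                       n_replicates = 6,
                                       counts = c(ME = 80, MT = 80, F1 = 10,
                                                  F2 = 10, BC_ME = 10,
                                                  BC_MT = 10),
                                       criteria = c("pure95", "hyb95",
                                                    "pure90", "hyb90"),
                                       mcmc = list(burn_in = 30000,
                                                   keep = 50000),
                                       seed) {
  if (missing(seed)) stop("a seed is required")
  registry <- registry_from_freqs(freqs)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rep_seeds <- matrix(sample.int(2^31 - 1, 2L * n_replicates),
                      ncol = 2L)
  truth_all <- pred_ts_all <- character(0)
  iss_all <- numeric(0)
  ov_by_rep <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    mix <- compose_mixture(freqs, counts, seed = rep_seeds[r, 1L])
    truth <- compound_class(mix$true_class)
    scores <- t_score(pool(mix$table, registry))
    pred <- classify_by_tscore(scores)
    ov_by_rep[r] <- performance(truth, pred)$overall
    truth_all <- c(truth_all, truth)
    pred_ts_all <- c(pred_ts_all, pred)
    if (!is.null(mcmc)) {
      fit <- fit_admixture(mix$table, burn_in = mcmc$burn_in,
                           keep = mcmc$keep, seed = rep_seeds[r, 2L])
      fit <- orient_labels(fit, registry)
      iss_all <- c(iss_all, unname(fit$iss))
    }
  }
  out <- list(tscore_report = performance(truth_all, pred_ts_all),
              tscore_overall_by_rep = ov_by_rep,
              true_class = truth_all, seed = seed)
  if (!is.null(mcmc)) {
    sel <- select_best_criterion(iss_all, truth_all, criteria)
    out$iss <- iss_all
    out$iss_reports <- sel$reports
    out$rules <- sel$rules
    out$best <- sel$best
  }
  out
}
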