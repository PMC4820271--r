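#' Classify individuals by their T-score
#'
#' With four partially diagnostic loci, individuals with T-scores 0-1 are
#' assigned to ME, 7-8 to MT and the intermediate scores 2-6 to compound
#' hybrids. Individuals with fewer than `min_loci` scored loci are left
#' unclassified (`NA`): the score band edges are meaningful only for the
#' full panel and no rescaling is attempted.
#'
#' @param scores a data.frame from [t_score()] (columns `t_score`,
#'   `n_loci_scored`), or a plain numeric vector of scores on 4 full loci.
#' @param min_loci minimum scored loci for classification (default 4).
#' @return character vector over `{ME, HYBRID, MT, NA}`.
#' @export
classify_by_tscore <- function(scores, min_loci = 4L) {
  if (is.data.frame(scores)) {
    s <- scores$t_score
    ok <- scores$n_loci_scored >= min_loci
  } else {
    s <- as.numeric(scores)
    ok <- rep(TRUE, length(s))
  }
  out <- rep(NA_character_, length(s))
  ok <- ok & !is.na(s)
  out[ok & s <= 1] <- "ME"
  out[ok & s >= 2 & s <= 6] <- "HYBRID"
  out[ok & s >= 7] <- "MT"
  out
}

#' Efficiency, accuracy and overall performance of a classification
#'
#' Per compound class: efficiency is the proportion of individuals truly in
#' the class that are assigned to it (recall); accuracy is the proportion of
#' individuals assigned to the class that truly belong to it (precision).
#' Overall performance is the mean efficiency over the three classes
#' multiplied by the mean accuracy. A class never predicted has undefined
#' accuracy and contributes 1 to the mean with a warning. Pairs with `NA`
#' predictions are dropped with a warning.
#'
#' @param true_labels,predicted character vectors over
#'   `{ME, MT, HYBRID}` (equal length); all three classes must occur in
#'   `true_labels`.
#' @return object of class `performance_report`: named `efficiency` and
#'   `accuracy` vectors, `overall`, and the 3x3 `confusion` table
#'   (rows = truth).
#' @export
performance <- function(true_labels, predicted) {
  stopifnot(length(true_labels) == length(predicted))
  classes <- c("ME", "MT", "HYBRID")
  if (!all(classes %in% true_labels))
    stop("all three compound classes must be present in the truth")
  if (anyNA(predicted)) {
    warning(sum(is.na(predicted)), " unclassified individual(s) dropped")
    keep <- !is.na(predicted)
    true_labels <- true_labels[keep]; predicted <- predicted[keep]
  }
  conf <- table(factor(true_labels, classes), factor(predicted, classes))
  eff <- diag(conf) / rowSums(conf)
  acc <- diag(conf) / colSums(conf)
  if (anyNA(acc)) {
    warning("class(es) never predicted, accuracy taken as 1: ",
            paste(classes[is.na(acc)], collapse = ","))
    acc[is.na(acc)] <- 1
  }
  structure(list(efficiency = eff, accuracy = acc,
                 overall = mean(eff) * mean(acc), confusion = conf),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("efficiency:", paste(sprintf("%s %.3f", names(x$efficiency),
                                   x$efficiency), collapse = ", "), "\n")
  cat("accuracy:  ", paste(sprintf("%s %.3f", names(x$accuracy),
                                   x$accuracy), collapse = ", "), "\n")
  cat(sprintf("overall performance: %.3f\n", x$overall))
  invisible(x)
}

#' Calibrate ISS classification thresholds on labeled simulations
#'
#' Derives the two ISS thresholds (ME/hybrid and hybrid/MT) from the ISS of
#' simulated individuals of known ancestry so that a target efficiency is
#' achieved for either the purebreds or the hybrids:
#' \itemize{
#'  \item `pure95` / `pure90`: the lower threshold is the e-th percentile of
#'    true-ME ISS and the upper the (100-e)-th percentile of true-MT ISS
#'    (e = 95 or 90), so at least e% of each purebred class is captured;
#'  \item `hyb95` / `hyb90`: the thresholds are the ((100-e)/2)-th and
#'    (100-(100-e)/2)-th percentiles of true-hybrid ISS, splitting the
#'    missed fraction symmetrically between the tails.
#' }
#' Percentiles use the linear-interpolation convention
#' (`stats::quantile(type = 7)`); threshold values are sensitive to it.
#'
#' @param iss numeric ISS values of calibration individuals.
#' @param true_class their compound classes (`ME`/`MT`/`HYBRID`).
#' @param criterion one of `"pure95"`, `"hyb95"`, `"pure90"`, `"hyb90"`.
#' @return object of class `threshold_rule`: `lower`, `upper`,
#'   `criterion_id`. An error if the calibrated `lower >= upper`
#'   (criterion infeasible on these data).
#' @export
calibrate_thresholds <- function(iss, true_class,
                                 criterion = c("pure95", "hyb95",
                                               "pure90", "hyb90")) {
  criterion <- match.arg(criterion)
  stopifnot(length(iss) == length(true_class))
  e <- if (grepl("95", criterion)) 0.95 else 0.90
  if (startsWith(criterion, "pure")) {
    me <- iss[true_class == "ME"]; mt <- iss[true_class == "MT"]
    if (!length(me) || !length(mt)) stop("both purebred classes required")
    lower <- unname(stats::quantile(me, e, type = 7))
    upper <- unname(stats::quantile(mt, 1 - e, type = 7))
  } else {
    hy <- iss[true_class == "HYBRID"]
    if (!length(hy)) stop("hybrid class required")
    tail <- (1 - e) / 2
    lower <- unname(stats::quantile(hy, tail, type = 7))
    upper <- unname(stats::quantile(hy, 1 - tail, type = 7))
  }
  if (lower >= upper)
    stop("criterion ", criterion, " infeasible: lower (", signif(lower, 4),
         ") >= upper (", signif(upper, 4), ")")
  structure(list(lower = lower, upper = upper, criterion_id = criterion),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("threshold_rule [%s]: ME <= %.4f < HYBRID < %.4f <= MT\n",
              x$criterion_id, x$lower, x$upper))
  invisible(x)
}

#' Classify individuals by ISS thresholds
#'
#' `iss <= lower` is ME, `iss >= upper` is MT, anything in between HYBRID:
#' boundary values go to the purebred classes.
#'
#' @param iss numeric vector of individual ancestry scores in \[0, 1\].
#' @param rule a [calibrate_thresholds()] rule.
#' @return character vector over `{ME, HYBRID, MT}`.
#' @export
classify_by_iss <- function(iss, rule) {
  stopifnot(inherits(rule, "threshold_rule"), all(iss >= 0 & iss <= 1, na.rm = TRUE))
  out <- rep("HYBRID", length(iss))
  out[iss <= rule$lower] <- "ME"
  out[iss >= rule$upper] <- "MT"
  out[is.na(iss)] <- NA_character_
  out
}

#' Select the best threshold criterion
#'
#' Calibrates every requested criterion on the labeled ISS, re-scores the
#' calibration individuals under each rule, and returns the rule with the
#' maximal overall performance; ties are broken toward the rule with higher
#' hybrid efficiency (logged via message).
#'
#' @param iss,true_class as in [calibrate_thresholds()].
#' @param criteria character vector of criteria to compare (default all 4).
#' @return list with `best` (a `threshold_rule`), `reports` (a
#'   `performance_report` per feasible criterion) and `rules`.
#' @export
select_best_criterion <- function(iss, true_class,
                                  criteria = c("pure95", "hyb95",
                                               "pure90", "hyb90")) {
  rules <- list(); reports <- list()
  for (cr in criteria) {
    rule <- tryCatch(calibrate_thresholds(iss, true_class, cr),
                     error = function(e) NULL)
    if (is.null(rule)) next
    rules[[cr]] <- rule
    reports[[cr]] <- performance(true_class, classify_by_iss(iss, rule))
  }
  if (!length(rules)) stop("no feasible criterion")
  ov <- vapply(reports, `[[`, 0, "overall")
  best_ov <- max(ov)
  cand <- names(ov)[ov == best_ov]
  if (length(cand) > 1L) {
    hyb_eff <- vapply(cand, function(cr)
      reports[[cr]]$efficiency[["HYBRID"]], 0)
    cand <- cand[which.max(hyb_eff)]
    message("overall-performance tie resolved toward higher hybrid ",
            "efficiency: ", cand)
  }
  list(best = rules[[cand[1L]]], reports = reports, rules = rules)
}
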