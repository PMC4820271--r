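#' Shell Z-index
#'
#' The dark prismatic strip under the ligament is scored by `Z = a / l`,
#' where `l` is the umbo-to-posterior-ligament distance and `a` the distance
#' from the umbo to the anterior end of the strip (`a = 0` when the strip is
#' unbroken, `a = l` when it is absent).
#'
#' @param a,l measurements in mm; requires `l > 0` and `0 <= a <= l`.
#' @return numeric vector of Z values in \[0, 1\].
#' @export
z_index <- function(a, l) {
  if (any(l <= 0)) stop("measurement error: l must be positive")
  if (any(a < 0 | a > l)) stop("measurement error: need 0 <= a <= l")
  a / l
}

#' Shell morphotype from the Z-index
#'
#' `Z = 0` (an unbroken dark strip) defines the T-morphotype; any `Z > 0`
#' (strip broken or absent) the E-morphotype. The threshold is exactly zero:
#' at the 0.1 mm measurement resolution any detected gap yields `Z > 0`.
#'
#' @param z numeric Z values in \[0, 1\].
#' @return character vector over `{"T", "E"}`.
#' @export
morphotype <- function(z) {
  stopifnot(all(z >= 0 & z <= 1, na.rm = TRUE))
  ifelse(z == 0, "T", "E")
}

#' Genotype-morphotype concordance
#'
#' How well the single shell character recovers the genetic classification.
#' For the two purebred classes: efficiency is the proportion carrying the
#' expected morphotype (T for MT, E for ME); accuracy is the proportion of
#' each morphotype that carries the corresponding genetic class; overall is
#' mean efficiency times mean accuracy. Hybrids are excluded by default or
#' reported separately (their T-morphotype frequency).
#'
#' @param classes compound genetic classes (`ME`/`MT`/`HYBRID`).
#' @param morphotypes `"T"`/`"E"` per individual.
#' @param hybrids `"exclude"` (default) or `"separate"`.
#' @return list with `efficiency` (named MT, ME), `accuracy` (named T, E),
#'   `overall`, and with `hybrids = "separate"` also `hybrid_t_freq`.
#' @export
concordance <- function(classes, morphotypes,
                        hybrids = c("exclude", "separate")) {
  hybrids <- match.arg(hybrids)
  stopifnot(length(classes) == length(morphotypes))
  hy <- classes == "HYBRID"
  out <- list()
  if (hybrids == "separate")
    out$hybrid_t_freq <- if (any(hy)) mean(morphotypes[hy] == "T") else NA_real_
  cl <- classes[!hy]; mo <- morphotypes[!hy]
  if (!any(cl == "MT") || !any(cl == "ME"))
    warning("a purebred class is empty; its statistics are omitted")
  eff <- c(MT = if (any(cl == "MT")) mean(mo[cl == "MT"] == "T") else NA,
           ME = if (any(cl == "ME")) mean(mo[cl == "ME"] == "E") else NA)
  acc <- c(T = if (any(mo == "T")) mean(cl[mo == "T"] == "MT") else NA,
           E = if (any(mo == "E")) mean(cl[mo == "E"] == "ME") else NA)
  out$efficiency <- eff
  out$accuracy <- acc
  out$overall <- mean(eff, na.rm = TRUE) * mean(acc, na.rm = TRUE)
  out
}

#' Mussel density from a bottom core sample
#'
#' Bottom quadrats use a square core frame (16 x 16 cm by default) placed on
#' a mussel patch; density is the count divided by the frame area.
#'
#' @param count number of mussels in the core (>= 0).
#' @param core_side side of the square core in metres (default 0.16).
#' @return list of class `density_estimate`: `substrate`, `density`
#'   (individuals per m2), `area`.
#' @export
density_bottom <- function(count, core_side = 0.16) {
  stopifnot(count >= 0, core_side > 0)
  structure(list(substrate = "bottom", density = count / core_side^2,
                 area = core_side^2),
            class = "density_estimate")
}

#' Mussel density from an algal-frame sample
#'
#' Algae quadrats use a larger frame (50 x 50 cm, 0.25 m2 by default); all
#' algae in the frame are weighed, mussels are counted on one selected tuft
#' only, and the count is scaled by the weight ratio of all algae to the
#' tuft before dividing by the frame area.
#'
#' @param tuft_count mussels counted on the selected tuft (>= 0).
#' @param tuft_weight weight of the selected tuft (> 0, same unit as total).
#' @param total_algae_weight total algae weight in the frame
#'   (>= `tuft_weight`).
#' @param frame_area frame area in m2 (default 0.25).
#' @return a `density_estimate` with the weights recorded.
#' @export
density_algae <- function(tuft_count, tuft_weight, total_algae_weight,
                          frame_area = 0.25) {
  stopifnot(tuft_count >= 0, frame_area > 0)
  if (tuft_weight <= 0 || total_algae_weight < tuft_weight)
    stop("measurement error: need 0 < tuft_weight <= total_algae_weight")
  structure(list(substrate = "algae",
                 density = tuft_count * (total_algae_weight / tuft_weight) /
                   frame_area,
                 area = frame_area, tuft_weight = tuft_weight,
                 total_algae_weight = total_algae_weight),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("%s density: %.1f individuals/m2\n", x$substrate, x$density))
  invisible(x)
}

#' Substrate contrast in T-character frequency
#'
#' For each site with both substrates sampled, the difference (algae minus
#' bottom) in the mean of a per-individual T-measure: e.g. T-allele dosage
#' scaled to \[0, 1\] for genotypes, or a 0/1 T-morphotype indicator.
#' A percentile bootstrap over individuals (resampled within substrate
#' groups) gives the confidence interval.
#'
#' @param site,substrate,value aligned vectors: site ID, `"algae"`/
#'   `"bottom"`, and the numeric T-measure per individual.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed (required).
#' @param conf confidence level (default 0.95).
#' @return data.frame with one row per usable site: `site`, `n_algae`,
#'   `n_bottom`, `diff`, `ci_lo`, `ci_hi`; single-substrate sites skipped
#'   with a warning. Attributes `n_boot` and `seed` record the protocol.
#' @export
substrate_contrast <- function(site, substrate, value, n_boot = 1000, seed,
                               conf = 0.95) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(length(site) == length(substrate),
            length(site) == length(value))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list()
  for (s in unique(site)) {
    va <- value[site == s & substrate == "algae"]
    vb <- value[site == s & substrate == "bottom"]
    if (!length(va) || !length(vb)) {
      warning("site ", s, " lacks one substrate; skipped")
      next
    }
    boot <- replicate(n_boot,
      mean(sample(va, replace = TRUE)) - mean(sample(vb, replace = TRUE)))
    qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2))
    rows[[s]] <- data.frame(site = s, n_algae = length(va),
                            n_bottom = length(vb),
                            diff = mean(va) - mean(vb),
                            ci_lo = unname(qs[1L]), ci_hi = unname(qs[2L]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  out
}
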