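#' Configuration for a synthetic hybrid-zone study
#'
#' Defines the conditions of a complete simulated survey: a panel of
#' partially diagnostic loci, a set of sites along an ancestry gradient,
#' ancestry-linked shell morphology, substrate preferences and quadrat
#' density protocols. The defaults emulate the White Sea study design: 31
#' sites spanning sample-level MT ancestry from about 0.02 to 0.93, ~20%
#' hybrids where both taxa meet, T-morphotype emission probabilities of
#' 0.80 for purebred MT and 0.03 for purebred ME (interpolated linearly in
#' ancestry for hybrids), ME shells on average 20% longer than MT, MT
#' favoured on algal substrate, and six quadrats (3 algae + 3 bottom) per
#' site.
#'
#' @param freqs parental allele frequency tables ([default_freqs()]).
#' @param sites data.frame with columns `site` and `target` (MT-ancestry
#'   proportion aimed for); default [default_sites()].
#' @param n_per_site individuals genotyped per site (default 30).
#' @param hybrid_fraction maximal hybrid fraction, realised as
#'   `hybrid_fraction * 4 s (1 - s)` at a site with target ancestry `s`
#'   (hybrids require both parental taxa; default 0.20).
#' @param p_t_mt,p_t_me probability of the T-morphotype for purebred MT and
#'   ME (defaults 0.80 and 0.03).
#' @param shell_mean_mt mean MT shell length in mm (default 30); ME is 20%
#'   longer, hybrids interpolate in ancestry.
#' @param shell_cv lognormal coefficient of variation of shell length
#'   (default 0.3).
#' @param substrate_slope log-odds slope of algae use on (ancestry - 1/2)
#'   (default 2: P(algae) = 0.73 for MT, 0.27 for ME).
#' @param bottom_density,algae_density true densities in individuals per m2
#'   (defaults 3000 and 1200).
#' @param n_quadrats quadrats per substrate per site (default 3).
#' @param seed master seed (required); the config plus seed fully
#'   determines the generated study.
#' @return list of class `study_config`.
#' @export
study_config <- function(freqs = default_freqs(), sites = default_sites(),
                         n_per_site = 30, hybrid_fraction = 0.20,
                         p_t_mt = 0.80, p_t_me = 0.03,
                         shell_mean_mt = 30, shell_cv = 0.3,
                         substrate_slope = 2,
                         bottom_density = 3000, algae_density = 1200,
                         n_quadrats = 3, seed) {
  if (missing(seed)) stop("a seed is required")
  check_freqs(freqs)
  stopifnot(all(c("site", "target") %in% names(sites)),
            all(sites$target >= 0 & sites$target <= 1),
            hybrid_fraction >= 0, hybrid_fraction <= 1,
            p_t_mt >= 0, p_t_mt <= 1, p_t_me >= 0, p_t_me <= 1,
            n_per_site >= 1, n_quadrats >= 0)
  structure(list(freqs = freqs, sites = sites, n_per_site = n_per_site,
                 hybrid_fraction = hybrid_fraction, p_t_mt = p_t_mt,
                 p_t_me = p_t_me, shell_mean_mt = shell_mean_mt,
                 shell_cv = shell_cv, substrate_slope = substrate_slope,
                 bottom_density = bottom_density,
                 algae_density = algae_density, n_quadrats = n_quadrats,
                 seed = seed),
            class = "study_config")
}

#' Default site layout
#'
#' 31 sites with target MT-ancestry proportions evenly spanning 0.02-0.93,
#' the sample-level ancestry range a two-taxon mosaic hybrid zone survey
#' typically covers.
#'
#' @return data.frame with columns `site`, `target`.
#' @export
default_sites <- function() {
  data.frame(site = sprintf("S%02d", 1:31),
             target = seq(0.02, 0.93, length.out = 31),
             stringsAsFactors = FALSE)
}

site_composition <- function(target, n, hybrid_fraction) {
  h_frac <- hybrid_fraction * 4 * target * (1 - target)
  n_hyb <- round(n * h_frac)
  n_hyb <- n_hyb - (n_hyb %% 4)         # split evenly over 4 hybrid classes
  per_h <- n_hyb %/% 4L
  n_mt <- round(target * n - 0.5 * n_hyb)
  n_mt <- max(0L, min(n - n_hyb, n_mt))
  n_me <- n - n_hyb - n_mt
  c(ME = n_me, MT = n_mt, F1 = per_h, F2 = per_h,
    BC_ME = per_h, BC_MT = per_h)
}

#' Generate a complete synthetic study
#'
#' Per site: genotypes of the composed ancestry classes (via the
#' known-ancestry simulator), shell records with Z drawn from
#' class-conditional morphotype emissions, a substrate label drawn from the
#' ancestry-dependent odds model, and quadrat count tables consistent with
#' the configured densities. Everything is reproducible from the config
#' seed.
#'
#' @param config a [study_config()].
#' @return list of class `synthetic_study`: `genotypes` (one
#'   [genotype_table()] over all sites; `sample_id` = site), `truth`
#'   (data.frame id, site, true_class, true_ancestry, t_morph_drawn),
#'   `shells` (data.frame id, site, substrate, L, l, a, z, morphotype),
#'   `quadrats` (data.frame site, substrate, quadrat, count, tuft_weight,
#'   total_algae_weight), `registry`, `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  tabs <- list(); truth <- list(); shells <- list(); quads <- list()
  for (r in seq_len(nrow(config$sites))) {
    s <- config$sites$site[r]
    counts <- site_composition(config$sites$target[r], config$n_per_site,
                               config$hybrid_fraction)
    if (sum(counts) != config$n_per_site)
      stop("infeasible composition at site ", s)
    mix <- compose_mixture(config$freqs, counts,
                           seed = sample.int(.Machine$integer.max, 1L),
                           sample_id = s)
    anc <- class_ancestry(mix$true_class)
    n <- length(anc)
    # substrate from the log-odds model
    p_algae <- stats::plogis(config$substrate_slope * (anc - 0.5))
    subst <- ifelse(stats::runif(n) < p_algae, "algae", "bottom")
    tab <- mix$table
    tab$substrate <- subst
    tab$site_id <- rep(s, n)
    tabs[[s]] <- tab
    # morphotype emission, linear in ancestry between the purebred rates
    p_t <- config$p_t_me + (config$p_t_mt - config$p_t_me) * anc
    is_t <- stats::runif(n) < p_t
    z <- ifelse(is_t, 0, stats::rbeta(n, 1.5, 3))
    # shell length: ME 20% longer than MT, lognormal noise
    mu <- config$shell_mean_mt * (1 + 0.2 * (1 - anc))
    sdlog <- sqrt(log(1 + config$shell_cv^2))
    L <- stats::rlnorm(n, log(mu) - sdlog^2 / 2, sdlog)
    l <- round(0.5 * L, 1)
    a <- round(z * l, 1)
    z_meas <- z_index(a, l)
    shells[[s]] <- data.frame(id = tab$individuals, site = s,
                              substrate = subst, L = round(L, 1), l = l,
                              a = a, z = z_meas,
                              morphotype = morphotype(z_meas),
                              stringsAsFactors = FALSE)
    truth[[s]] <- data.frame(id = tab$individuals, site = s,
                             true_class = mix$true_class,
                             true_ancestry = anc, t_morph_drawn = is_t,
                             stringsAsFactors = FALSE)
    if (config$n_quadrats > 0) {
      qb <- data.frame(site = s, substrate = "bottom",
                       quadrat = seq_len(config$n_quadrats),
                       count = stats::rpois(config$n_quadrats,
                                            config$bottom_density * 0.16^2),
                       tuft_weight = NA_real_,
                       total_algae_weight = NA_real_,
                       stringsAsFactors = FALSE)
      tot_w <- stats::runif(config$n_quadrats, 0.8, 2.0)
      frac <- stats::runif(config$n_quadrats, 0.2, 0.5)
      qa <- data.frame(site = s, substrate = "algae",
                       quadrat = seq_len(config$n_quadrats),
                       count = stats::rpois(config$n_quadrats,
                                            config$algae_density * 0.25 * frac),
                       tuft_weight = round(tot_w * frac, 3),
                       total_algae_weight = round(tot_w, 3),
                       stringsAsFactors = FALSE)
      quads[[s]] <- rbind(qb, qa)
    }
  }
  genotypes <- do.call(rbind_tables, unname(tabs))
  structure(list(genotypes = genotypes,
                 truth = do.call(rbind, unname(truth)),
                 shells = do.call(rbind, unname(shells)),
                 quadrats = if (length(quads)) do.call(rbind, unname(quads))
                            else NULL,
                 registry = registry_from_freqs(config$freqs),
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", length(x$genotypes$individuals), "individuals at",
      nrow(x$config$sites), "sites (seed", format(x$config$seed), ")\n")
  invisible(x)
}

#' Truth manifest of a synthetic study
#'
#' One row per simulated individual with its true ancestry class, true
#' ancestry proportion and the morphotype emission draw, enabling
#' parameter-recovery scoring of any downstream analysis.
#'
#' @param bundle a [generate_study()] result.
#' @param path optional TSV output path.
#' @return the manifest data.frame (invisibly when written to `path`).
#' @export
truth_manifest <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "synthetic_study"))
  man <- bundle$truth
  man$compound_class <- compound_class(man$true_class)
  if (!is.null(path)) {
    utils::write.table(man, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(man))
  }
  man
}

#' Write a synthetic study to disk
#'
#' Genepop genotypes, morphology TSV, quadrat TSV, truth manifest and the
#' exact configuration (YAML) for auditable reproduction.
#'
#' @param bundle a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genepop(bundle$genotypes, file.path(dir, "genotypes.gen"))
  utils::write.table(bundle$shells, file.path(dir, "shells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$quadrats))
    utils::write.table(bundle$quadrats, file.path(dir, "quadrats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  truth_manifest(bundle, file.path(dir, "truth.tsv"))
  write_registry(bundle$registry, file.path(dir, "registry.yaml"))
  cfg <- bundle$config
  yaml::write_yaml(list(
    n_per_site = cfg$n_per_site, hybrid_fraction = cfg$hybrid_fraction,
    p_t_mt = cfg$p_t_mt, p_t_me = cfg$p_t_me,
    shell_mean_mt = cfg$shell_mean_mt, shell_cv = cfg$shell_cv,
    substrate_slope = cfg$substrate_slope,
    bottom_density = cfg$bottom_density,
    algae_density = cfg$algae_density, n_quadrats = cfg$n_quadrats,
    seed = cfg$seed,
    sites = cfg$sites), file.path(dir, "config.yaml"))
  invisible(dir)
}
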