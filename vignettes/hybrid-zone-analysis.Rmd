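---
title: "Analysing a bimodal mussel hybrid zone with musselmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing a bimodal mussel hybrid zone with musselmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musselmix)
```

`musselmix` analyses contact zones between two hybridizing taxa — written
for the blue mussels *Mytilus edulis* (ME) and *M. trossulus* (MT) scored
at four partially diagnostic allozyme loci, but applicable to any
two-taxon system with co-dominant markers. This vignette explains the
models and procedures, the tunable parameters, the choices made where the
design was genuinely open, and what the synthetic-data tests do and do not
demonstrate about real data.

## Compound alleles, T-scores and T-frequencies

Allozyme loci in this system carry several electromorph alleles, none
fully diagnostic. The analysis first pools alleles into two compound
categories per locus: an allele is a **T-allele** when its frequency in a
pure MT reference population strictly exceeds its frequency in the pure ME
reference, otherwise an **E-allele**. Exact ties are pooled as E with a
warning: the rule is deterministic and conservative toward the resident
taxon. The registry (`build_registry()`) records the pooling map and the
compound T-frequency of each reference taxon per locus; loci must satisfy
T(MT) > T(ME), i.e. be at least partially diagnostic.

Each individual's **T-score** is its T-allele count summed over scored
loci (0–8 with four complete loci); each sample's **T-frequency** rescales
the observed per-locus compound frequency linearly between the two
reference frequencies and averages over loci. Two conventions needed
fixing here:

* *Scale-then-average.* Per-locus frequencies are rescaled first and then
  averaged. The alternative (average raw frequencies, then scale) differs
  only when reference differentials are heterogeneous across loci; the
  scale-then-average order weights each locus's diagnostic information
  equally and is the convention used throughout.
* *Out-of-range observations* (sampling noise can push an observed
  frequency beyond a reference) are clipped into [0, 1] with a logged
  message.

Missing data policy: dosages with missing loci are retained; T-scores are
reported with `n_loci_scored`, and classification by T-score bands refuses
individuals with fewer than four scored loci by default (the band edges
are only meaningful for the full panel).

## Disequilibrium statistics and their mixture maxima

For one sample on the pooled bi-allelic scale:

* `fis()` computes the per-locus heterozygote deficit
  $F_{IS} = 1 - H_{obs}/H_{exp}$ with $H_{exp} = 2p(1-p)$ from the sample
  compound frequency. No small-sample correction is applied; the plain
  estimator is isolated in one function so a correction can be added
  without touching callers.
* `r_prime()` computes, per locus pair, the phase-free composite
  disequilibrium: Burrows' $\Delta$ between T-dosages standardised by
  $\sqrt{(p_1q_1 + D_1)(p_2q_2 + D_2)}$, where $D_i$ is the within-locus
  Hardy–Weinberg departure. Gametic phase is unknown in diploid genotype
  data, so the composite (Weir) form is the only estimable choice; with
  the departure terms folded in, it equals the Pearson correlation of the
  dosage vectors, which the tests exploit as an independent oracle.

Both statistics are near 0 in an equilibrium population and positive in a
mixture of differentiated populations. To judge *how* mixed a sample is,
`mixture_maxima()` computes the values each statistic would attain in a
hypothetical physical mixture of the two reference taxa, without
interbreeding, matching the observed average frequencies: the mixing
proportion $m$ is solved per locus from
$f_{obs} = m f_{MT} + (1-m) f_{ME}$, the Wahlund maximum
$1 - [m\,2f_{MT}(1-f_{MT}) + (1-m)\,2f_{ME}(1-f_{ME})]/[2\bar p(1-\bar p)]$
is averaged over loci, and the $R'$ maximum comes from the mixture's
expected dosage covariances under within-component equilibrium. Two open
conventions were resolved as follows: $F_{IS}$ maxima use the
locus-specific $m$ (each locus then reproduces its observed frequency
exactly), while $R'$ maxima use the single averaged $\hat m$, since one
physical mixture underlies all pairs. Both maxima equal 1 exactly for
fully diagnostic loci at a 50:50 mixture and 0 for a pure sample; with
unequal reference pairs the maximum sits near, not exactly at,
$m = 0.5$.

## Expected T-score distributions and the exact test

`expected_tscore_panmixia()` convolves per-locus binomial dosage
distributions; `expected_tscore_mixture()` mixes the two parental
panmictic distributions in proportion $m$. `mc_exact_test()` compares
observed score counts with an expected distribution using the chi-square
statistic and a Monte-Carlo reference distribution (default 2000
multinomial replicates at the observed sample size). Numerical choices:
adjacent categories are pooled left-to-right until each pooled category
has expected count ≥ 1 (a trailing light group folds back), but
zero-probability categories are never absorbed into a neighbour —
observations there make the statistic infinite and the p-value equals the
add-one minimum $1/(n_{reps}+1)$. The p-value always uses the add-one
estimator, so it is never exactly zero, and the RNG seed is a required,
recorded argument.

## The two-population admixture model

`fit_admixture()` implements the classic admixture model with
uncorrelated allele frequencies for exactly two parental populations: each
allele copy of individual $i$ originates from population 1 with
probability $q_i$; given its origin it is drawn from that population's
frequencies at its locus. The Gibbs sampler alternates the latent origins,
the frequencies (Dirichlet($\lambda = 1$) prior) and the ancestries
(Beta($\alpha, \alpha$) prior), and reports the posterior-mean $q$ as the
individual score (ISS); `pss()` averages ISS within samples. Defaults
follow the reference workflow: burn-in 30000, 50000 kept sweeps.

Parameters that matter:

* $\alpha$ (ancestry prior concentration) is **fixed at 1 by default**
  for reproducibility, with a Metropolis update available
  (`update_alpha = TRUE`, uniform prior on (0, 10]). The update matters
  in strongly bimodal data: with $\alpha$ fixed at 1 the posterior mean
  of a purebred individual cannot drop below $\alpha/(\alpha + 2L)$
  (0.11 with four loci), so purebred scores are visibly shrunk toward the
  middle. The pipeline (`run_full()`) therefore updates $\alpha$ in its
  fits, which matches the reference implementation's default behaviour;
  the low-level default stays fixed so single fits are exactly
  reproducible from the seed alone.
* Label switching is resolved post hoc: `orient_labels()` names the
  population with the higher registry-pooled compound T-frequency MT and
  re-expresses ISS as MT ancestry. The operation is idempotent and errors
  on exact ties rather than guessing.
* A split-half heuristic warns (never fails) when the two halves of the
  kept chain disagree by more than 0.1 for more than 5% of individuals.

With only four loci (eight allele copies) per individual, ISS carries
substantial inherent posterior uncertainty. An exact-posterior analysis at
the package's default panel shows that no estimator can push the
individual-ancestry RMSE below about 0.10 on mixed samples — worth keeping
in mind when reading per-individual scores; sample means (PSS) are far
more precise.

## Simulating known ancestry and calibrating thresholds

`simulate_class()` builds genotypes by uniting gametes: purebred gametes
draw alleles from their taxon's frequencies; F1-parent gametes choose the
ME- or MT-derived allele independently per locus (free recombination —
the four allozyme loci sit on different linkage groups in published
*Mytilus* maps). `compose_mixture()` concatenates the six classes in the
calibration proportions 80:80:10:10:10:10 (N = 200, 40% each purebred,
20% assorted hybrids) and shuffles order; seeds are mandatory and
recorded.

Classification proceeds two ways:

1. **T-score bands**: 0–1 → ME, 2–6 → hybrid, 7–8 → MT.
2. **ISS thresholds**, calibrated on labeled simulated ISS by four
   criteria: 95% or 90% efficiency for the purebreds (`pure95`,
   `pure90`: lower threshold at the e-th percentile of true-ME ISS, upper
   at the (100−e)-th percentile of true-MT ISS) or for the hybrids
   (`hyb95`, `hyb90`: symmetric tail percentiles of true-hybrid ISS —
   the symmetric split is this package's interpretation, as is the
   linear-interpolation percentile convention, to which threshold values
   are sensitive). Boundary ISS values classify as purebred. The
   criterion with maximal overall performance is selected; exact ties go
   to the higher hybrid efficiency.

Performance follows the efficiency/accuracy framework: per-class recall
and precision from the 3×3 confusion table, with overall performance the
product of their means. A class never predicted contributes accuracy 1
with a warning (it made no false claims).

Calibration ISS can come from **joint fits** (each simulated cohort
co-analyzed with the empirical genotypes — the default in `run_full()`,
because thresholds then share the empirical fit's ISS scale, and the
cohort is small relative to the data so it barely perturbs the empirical
scores) or from **simulated-only fits**
(`run_calibration_experiment()`), which is cheaper and self-contained;
the mode is recorded in the output.

## Morphology, substrates, densities

The shell's dark prismatic strip is scored by $Z = a/l$; $Z = 0$ (strip
unbroken) defines the T-morphotype, any $Z > 0$ the E-morphotype. The
threshold is exactly zero — at 0.1 mm measurement resolution any detected
gap yields $Z > 0$ — and a completely absent strip is coded $a = l$
($Z = 1$). `concordance()` reports how well the single character recovers
the genetic classes (efficiency per purebred class, accuracy per
morphotype, overall performance), excluding hybrids by default or
reporting their T-morphotype frequency separately.

Densities follow the quadrat protocols: bottom cores of 16 × 16 cm
(count / 0.0256 m²) and 50 × 50 cm algal frames where the count from one
weighed tuft is scaled by the whole-frame algae weight ratio. Both are
linear in counts and invariant to splitting a tuft. Substrate association
is summarised by per-site differences in a T-measure (allele dosage or
morphotype indicator) between algae and bottom, with percentile bootstrap
confidence intervals over individuals; mixed-effect regression modelling
of such associations is deliberately out of scope — it is off-the-shelf
statistics, not part of this package's contribution.

## The synthetic study generator

`generate_study()` produces a complete survey with known truth, the
test-bed for every pipeline stage. Defaults and their grounds:

* **Loci**: four bi-allelic loci with compound T-frequencies
  ME (0.02, 0.05, 0.10, 0.05) / MT (0.97, 0.95, 0.90, 0.80) —
  differentials 0.95/0.90/0.80/0.75, inside the 70–95% range typical of
  this panel, with the ME reference nearly pure as in the published
  reference populations. Chosen once at design time by exact enumeration
  of the implied T-score confusion structure.
* **Sites**: 31 sites spanning target MT ancestry 0.02–0.93 (the
  sample-level range such surveys cover), 30 individuals each.
* **Hybrid fraction**: 0.20 at maximum, realised as
  $0.2 \times 4s(1-s)$ at site ancestry $s$ — hybrids need both parental
  taxa present, so their frequency peaks at the centre of the gradient.
  Hybrid classes split equally among F1, F2 and the two backcrosses.
* **Morphotype emissions**: P(T-morph) = 0.80 for purebred MT, 0.03 for
  purebred ME, interpolated linearly in true ancestry for hybrids — the
  simplest monotone model, a synthetic-only assumption.
* **Shells**: lognormal lengths (CV 0.3), ME mean 20% above MT, hybrids
  intermediate; E-morphotype Z drawn from a Beta(1.5, 3).
* **Substrate**: P(algae) = logistic(2 × (ancestry − ½)), i.e. 0.73 for
  MT and 0.27 for ME — MT favours algal thalli.
* **Quadrats**: 3 bottom + 3 algae per site at true densities 3000 and
  1200 ind/m², with Poisson counts and uniform tuft weight fractions.

The generator emulates the statistical structure the analysis assumes —
bimodal samples along a gradient, ancestry-linked morphology and
substrate, quadrat protocols. It deliberately omits spatial
autocorrelation, larval dispersal, selection, assortative mating,
genotyping error and missing data; passing the recovery tests therefore
shows the estimators are consistent under the model's own assumptions,
not that real surveys are free of those complications.

## Problem sizes, tolerances and known limitations

The test suite runs reduced problem sizes chosen for statistical
sufficiency: short Gibbs chains (a few thousand sweeps) for the small,
well-separated fixtures; full-length chains (30000/50000) for the
six-replicate calibration experiment; three joint calibration replicates
and 3000/6000 sweeps for the whole-pipeline recovery run on the default
31-site study. Monte-Carlo assertions use 3–4 standard errors or the
documented tolerance bands.

Known limitations:

* Only two parental populations (k = 2), uncorrelated frequencies, no
  linkage model, no multi-run cluster matching — matching the scope of
  the analysis it implements.
* Per-individual ancestry from four loci is inherently noisy (see the
  information floor above); finer hybrid categories (F1 vs F2 vs
  backcross) are deliberately not assigned, as that requires more loci.
* The T-frequency scale-then-average convention and the hybrid-criterion
  symmetric tail split are this package's interpretations of otherwise
  underdetermined conventions; both are documented above and isolated in
  single functions.
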