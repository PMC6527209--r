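---
title: "Methods: detecting microbial exchange across aerodigestive sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting microbial exchange across aerodigestive sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In children with oropharyngeal dysphagia, swallowed or refluxed material can
carry microbes between the oropharynx, the stomach, and the lungs. Given 16S
OTU tables from several body sites of the same patients — bronchoalveolar
lavage ("lung"), oropharyngeal swab, gastric fluid, and stool — `aerodx`
asks three questions:

1. How similar are communities *within* a patient across sites, compared to
   the *same* site across patients?
2. Which individual OTUs look *exchanged* between two sites — present in
   both, with abundances that rise and fall together across patients?
3. Does aspiration status modulate these relationships, and can it be
   predicted from them?

# Beta diversity

Similarity is measured with the Jensen-Shannon distance (JSD): for
relative-abundance profiles $p$ and $q$ with mixture $m = (p+q)/2$,

$$\mathrm{JSD}(p, q) = \sqrt{\tfrac12 D(p \,\|\, m) + \tfrac12 D(q \,\|\, m)},$$

with Kullback-Leibler divergences $D$ taken in base-2 logarithms and
$0 \log 0 = 0$. Base 2 bounds the distance in $[0, 1]$ (0 = identical
communities, 1 = disjoint support) and makes it a proper metric on the
simplex; the logarithm base is a package choice, made so that "close to 1"
means maximally different. No pseudocounts are needed because the mixture
$m$ is positive wherever either profile is. Bray-Curtis is available as an
alternative metric (via `vegan`), and `permanova()` wraps
`vegan::adonis2()` for whole-community site effects.

Cross-patient comparisons (`across_patient_distances()`,
`within_vs_across()`) are restricted to sample pairs from the same
sequencing batch, so batch effects cannot masquerade as between-person
variability; within-patient pairs are never split across batches by design
(each patient is sequenced in one batch). Group summaries report medians,
matching the skewed, bounded nature of JSD.

# Exchanged OTUs

The core statistic is a first-order partial Spearman correlation. For an
OTU and a site pair $(a, b)$, take the patients (among those with all three
aerodigestive sites sequenced) where the OTU is present (relative abundance
$> 0$) in *both* sites; let $x$ and $y$ be its abundances in the two sites
for those patients and $z$ its abundances in the third site (zeros
retained). With Spearman correlations $r_{xy}, r_{xz}, r_{zy}$ (average
ranks on ties),

$$\rho_{xy \cdot z} = \frac{r_{xy} - r_{xz} r_{zy}}
{\sqrt{(1 - r_{xz}^2)(1 - r_{zy}^2)}}.$$

Partialling on the third site discounts correlation that merely reflects a
patient-wide carriage effect visible everywhere. Numerical conventions:
a constant $z$ contributes $r_{xz} = r_{zy} = 0$, so the partial falls back
to the plain Spearman correlation; a constant $x$ or $y$, or a
rank-collinear $z$ ($|r| = 1$ within $10^{-12}$), makes the statistic
not computable and the OTU is skipped.

Significance comes from a permutation null: $y$ is shuffled uniformly 2000
times while $(x, z)$ stay paired — breaking both the $x$–$y$ and $z$–$y$
associations, which is the null of no exchange beyond what the third site
explains — and the p-value is the fraction of null statistics *strictly
larger* than the observed one. The test is one-sided in the upper tail
because exchange is a positive-association hypothesis; with the strict
inequality and the plain proportion, $p = 0$ is attainable and the raw
proportions are what Benjamini-Hochberg correction is applied to. Only
OTUs co-occurring in at least 10 patients are tested, the BH family is the
tested OTUs of one site pair, and `q < 0.1` defines "exchanged". All
permutations for a scan flow from one seed, so results are reproducible
bit for bit.

Two calibrations guard the count of detections. `null_calibration()`
shuffles patient identities independently for each OTU within each site and
re-runs the whole detection (10 rounds by default; the round count is a
package choice, configurable). And the synthetic null cohort (below) gives
a cohort-level null in which the median number of detections per site pair
should be at most a couple.

`cooccurrence_prevalence()` reports, per exchanged OTU, the percentage of a
patient group carrying it in both sites of a pair;
`differential_prevalence()` compares two groups with a paired t-test on
log10 prevalences, replacing a zero prevalence by the half-patient
pseudo-prevalence $100 \times 0.5 / n_\text{group}$ (the choice of floor is
the package's; the test needs finite logs and half a patient is the natural
resolution limit of a prevalence estimated from $n$ patients).

# Group statistics and classifiers

Aspiration contrasts use Wilcoxon rank-sum tests on within-patient JSD and
on per-sample alpha diversity (Shannon in base 2, Gini-Simpson, and the
classic Chao1 estimator $S_{obs} + F_1^2 / 2F_2$ with the
$F_1(F_1-1)/2$ correction when no doubletons exist — the uncorrected form
is used deliberately, so the worked arithmetic matches the estimator's
textbook definition). Patients with untested aspiration status are excluded
from contrasts, never imputed; aspiration and penetration form one
"aspirator" class. Differential abundance uses Kruskal-Wallis per taxon
(kept even for two groups) with BH correction within each (site, rank)
family; taxa constant across all samples of a site are dropped and
reported rather than tested.

Random forests (1000 trees; `randomForest`) provide two evaluation
surfaces. Site classifiers use 5-fold cross-validation whose folds
partition *patients*, so both samples of a patient sit on the same side of
every split — the audit is part of the test suite. Aspiration classifiers
use leave-one-out evaluation: for each patient, a forest trained on all
others predicts the held-out aspiration probability; pooled LOO
probabilities give the ROC AUC (computed by the Mann-Whitney
normalization, cross-checked against trapezoidal ROC integration) and a
Fisher exact p-value on the 2×2 confusion matrix of hard calls at
probability 0.5 (the threshold is a package choice; a confusion matrix
needs one). Feature encodings: site-tagged relative abundances
("community"), 0/1 presence of exchanged OTUs in one site, or the
concordance code — 1 when an OTU is present in both or absent in both
sites, 0 otherwise.

# The synthetic cohort generator

No sequence data are bundled; every analysis is exercised on synthetic
cohorts with planted ground truth (`generate_cohort()`). The generative
model is Dirichlet-multinomial, chosen for transparency — the statistics
above are rank- and distance-based, so no particular parametric family is
assumed by the analysis:

* A log-normal rank-abundance pool for lung/gastric communities and a
  second pool for the oropharyngeal core, sharing 70% of their log-scale
  variance so that the sites share predominant members, as real
  aerodigestive communities do.
* Each patient has a sparse patient base drawn around the lung/gastric
  pool (`person_concentration`, default 40); the patient's lung and
  gastric compositions are drawn around that shared base
  (`site_concentration`, default 50). This makes lung and gastric
  communities person-specific — similar within a patient, highly variable
  across patients. Oropharyngeal compositions are drawn around the single
  shared core (`core_concentration`, default 75), hence conserved across
  people.
* Exchanged OTUs (default 20 per site pair, disjoint across pairs) are
  selected from the prevalent members of both pools — real exchanged taxa
  are common genera, and prevalence is what lets the detector's
  10-patient co-occurrence filter see them. The link is a Gaussian-copula
  rank remap: among patients where the donor site carries the OTU, the
  recipient site's existing abundances are re-ordered to follow a noisy
  copy of the donor's ranks with latent correlation
  $2\sin(\pi \rho_s / 6)$, targeting a within-patient Spearman correlation
  of `exchange_strength` (default 0.8). The remap preserves each site's
  marginal abundances exactly, so planting changes association structure,
  not composition.
* Aspirator lungs are a convex mixture of the patient's own oropharynx
  (weight `aspiration_mixing`, default 0.6) and the latent lung. The
  default effect size is a synthetic calibration chosen to make the
  planted effect detectable at the cohort's size; it is not an estimate of
  any clinical quantity.
* Counts are multinomial at 10,000 reads per sample with an independent
  dropout probability (default 0.05) applied to present OTUs; batch labels
  are assigned round-robin over patients (two batches by default); cohort
  composition defaults to 66 patients — 25 aspirators, 23 non-aspirators,
  18 untested — each with all three aerodigestive sites.

`null_cohort()` regenerates the same design with `exchange_strength = 0`,
`aspiration_mixing = 0`, and *independent* lung and gastric patient bases,
so all sites are independent given their per-site compositions — the
testbed for false-positive calibration.

What the generator does *not* emulate: real taxonomies or phylogeny,
sequencing error, abundance-dependent dropout, within-site replicate
structure, or longitudinal sampling. Passing the planted-truth suites
therefore shows that the statistics recover the association structure they
target at realistic sparsity and depth — not that any particular clinical
effect size in real cohorts is reproduced.

# Problem sizes and numerical choices

The validation suites run at the cohort's own scale: 66 patients × 3
sites × 200 OTUs, 2000 permutations per OTU, 10 null-cohort seeds for the
exchange null calibration, 5 seeds for planted-truth recovery, and
20 seeds for classifier null sweeps (forest size 200 in the null sweeps,
where only the chance level is at stake; 1000 elsewhere). Tolerances:
oracle equivalences at $10^{-12}$; the metric triangle inequality at
$10^{-9}$ (accumulated square-root rounding); relative-abundance columns
must sum to 1 within $10^{-9}$. Ties are handled by average ranks
throughout. Degenerate inputs — constant vectors, all-zero samples,
single-class labels, all-tied paired differences — error or are flagged
explicitly rather than silently producing numbers.

One deliberate asymmetry: on cohorts that *do* carry an aspiration mixing
effect or the shared lung-gastric patient base, exchange detection
reports more associations than the planted list. Those are genuine
within-patient couplings created by the cohort's own structure, so
planted-truth error rates are measured on cohorts generated without
mixing; the analysis scripts note this where it is visible.
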