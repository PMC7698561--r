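---
title: "Variable selection in untargeted metabolomics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable selection in untargeted metabolomics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Untargeted LC-MS metabolomics of a treated cohort produces a feature table
with thousands of (m/z, retention time) peaks per sample, of which only a
small, internally correlated set responds to the treatment. Two families of
variable selection are in routine use: *all-relevant* selectors (univariate
tests, VIP, significance multivariate correlation) that try to report every
feature associated with the response, and *sparse* selectors (CARS-PLS-DA,
sparse PLS-DA) that return a minimal discriminative subset. Because
metabolites within a pathway are strongly correlated, a sparse selector can
reach perfect classification while reporting none of the mechanistically
relevant features — it may prefer any correlated stand-in. Downstream
pathway analysis, which needs as many true hits as possible, then fails
silently.

`metaboselect` implements both families inside one validated pipeline —
preprocessing, double cross-validation, m/z-to-pathway annotation with
permutation validation, and correlation-network analysis — together with a
synthetic paired-cohort generator with known ground truth, so the failure
mode of sparsity is demonstrable and testable without patient data.

## The synthetic cohort

`generate_cohort()` emulates a paired clinical design: `n_patients = 14`
sampled before and during treatment, each sample injected in duplicate, and
a pooled QC sample after every 9th or 10th injection (alternating). The
generative model works on the log-intensity scale:

* per-feature baseline `~ Normal(log 5e4, 1)`;
* a per-(feature, patient) random effect with sd `patient_sd = 0.15`;
* a condition effect equal to the log fold change on responsive features
  (defaults: a 10-feature block with folds 1.94–9.5, the range reported for
  the confirmed treatment metabolites);
* block correlation from two patient-level latent factors — one shared
  equally by the block, one whose loadings scale with the effect sizes
  (`kappa = 0.1`); the shared loading is solved so the weakest feature
  pair's population correlation sits 0.05 above the configured target
  (`cor = 0.7`);
* multiplicative log-normal measurement noise with `noise_cv = 0.15`
  (a typical post-correction technical CV for plasma LC-MS), independent
  per injection — duplicates differ only by this noise and by drift;
* a smooth per-feature multiplicative drift over injection order
  (low-order polynomial shape, amplitude `0.15`);
* zeros drawn with a logistic probability that decreases with the
  underlying intensity (`missing_rate = 0.10` overall).

QC samples are the noise-free population mean profile plus technical noise
and drift, as a pooled QC would be. Block features are placed on adduct
m/z values (M+H, M−H, M+Na) of the packaged vitamin-B3 reference
metabolites within ±0.3 ppm; `n_proxy_features = 15` proxies carry a
scaled copy (gain U(0.6, 2.4)) of the block's treatment signal but sit at
m/z values at least 20 ppm from any reference adduct, so they can never be
annotated. A further 30% of the null features are placed on adducts of the
non-spiked reference pathways with mass errors U(−4, 4) ppm, which makes
the annotated feature count grow with the matching tolerance as it does in
real data.

Two noise settings deserve a note. First, the defaults deliberately keep
individual variability much smaller than the treatment difference — that
is the regime the study design presumes, and it is what lets every method
classify held-out patients perfectly. Second, with only 14 patients the
realized pairwise correlation of two block features fluctuates by roughly
±0.1 around its population value; the generator therefore targets the
configured correlation *plus* a small margin, and the weakest observed
pair on the default cohort still clears `cor − 0.1`. Pushing the latent
variance high enough to pin *every* pair above the target for arbitrary
seeds would simultaneously bury the weak-fold features' sMC significance;
the chosen balance reflects the data regime the pipeline is meant for.

What the generator does **not** emulate: isotope envelopes, raw
chromatograms, inter-batch effects (the design is single-batch),
adduct-level redundancy of null features, and retention-time structure
(RT is carried through but never used for matching). Passing tests on
this cohort therefore say nothing about peak picking or alignment
quality, and nothing about regimes where biological variability rivals
the treatment effect.

## Preprocessing

`preprocess_fit()` / `preprocess_apply()` implement the chain with a
strict train/apply split so it can sit inside cross-validation:

1. **Filters** (strict boundaries): more than 20% zeros over the study
   samples, any zero in a QC sample, m/z outside [70, 700], RT outside
   [0.4, 16] min. A feature with exactly 20% zeros or m/z exactly 70 is
   retained.
2. **QC-SVR drift correction**: per feature, a radial-basis support
   vector regression of QC intensity on injection order (kernel width =
   inverse injection-order range, cost 1, epsilon tube = 0.1 QC MAD);
   intensities are rescaled by median(QC)/f(order). Curves are evaluated
   over the whole run so held-out samples at any injection order can be
   corrected. With fewer than 5 QCs the stage warns and passes through.
3. **PQN** against the per-feature median of the QC samples; quotients
   use non-zero entries only, so the order relative to imputation is
   immaterial.
4. **KNN imputation** (k = 10): neighbors are samples, distance is the
   Euclidean distance over features observed in both, scaled by the
   number of shared features; each zero becomes the mean of the k
   nearest donors that observed that feature. Held-out samples draw
   donors from the training set only.
5. **glog** `g(x) = ln((x + sqrt(x^2 + lambda))/2)` with lambda tuned on
   the QC replicates by minimizing the profile negative log-likelihood
   `N log(RSS/N) + sum log(x^2 + lambda)` (residual QC variance in
   transformed space with the Jacobian term) over a log-spaced grid with
   local refinement. A plain "minimize QC variance" criterion is
   degenerate — it decreases monotonically in lambda — so the Jacobian
   term is essential, not optional.
6. **Mean centering** with training means; no scaling is applied.

`average_duplicates()` collapses duplicate injections before the
univariate route; the multivariate routes use the duplicates directly.
Per-feature fold changes are medians over patients of the
during/before ratio of duplicate means, computed on the raw
(pre-glog, post-normalization) scale.

## Selection routes

* **Paired Wilcoxon + BH.** The signed-rank p-value is exact up to
  n = 25 pairs (dynamic-programming convolution over doubled midranks,
  zero differences dropped), so the n = 14 floor is 2/2^14 ≈ 1.22e-4.
  Benjamini–Hochberg runs as the classic step-up rule and reports the
  realized cutoff (the largest rejected p). A paired sign test is
  available as an option; both give the same floor when every
  difference has one sign.
* **OPLS-DA + VIP.** The number of orthogonal components (0–5) is tuned
  by inner-CV DQ²; VIP is computed on the equivalent PLS model with
  1 + n_ortho components (training predictions of the two models are
  identical for a single response). Selection threshold VIP > 1, the
  field convention; the mean squared VIP is exactly 1 by construction.
* **WRT-PLS + sMC.** The component count comes from a weight
  randomization test: per deflated component the statistic `||X'y||` is
  compared with 500 permutations of y using the add-one estimator, and
  components are kept while p < 0.05 — no inner CV. sMC then F-tests
  each feature's regression on the target-projection score
  `t_TP = X b/||b||` with `F = SSR/(SSE/nu)` and selects
  `F > F_crit(alpha)` at alpha 0.01 or 3e-7. The residual degrees of
  freedom default to n − 2 but are a configuration knob: printed
  critical values in the source study (7.06 and 32.99) correspond to
  nu = 62, while the nominal design gives 54, and the exact modeled
  sample count is not recoverable.
* **CARS-PLS-DA** (2 latent variables): per run, features are ranked by
  |b|; an exponentially decreasing schedule (all features at run 1,
  2/p at run 50) fixes how many survive; adaptive reweighted sampling
  (draws proportional to |b|, with replacement, deduplicated, refilled
  from the top pool if the draw collapses below the viable model size)
  picks the next subset; each run is scored by inner-CV DQ² and the
  best run wins, ties toward the smaller subset.
* **Sparse PLS-DA** (1 latent variable): the weight vector X'y is
  soft-thresholded so exactly k entries survive; k is tuned on inner-CV
  DQ² over a small grid, ties toward smaller k.

DQ² is the discriminant Q²: residuals of predictions beyond their class
label (ŷ > 1 for class +1, ŷ < −1 for class −1) are set to zero before
`1 − SSE/TSS`. Consequently DQ² is never below the classic Q².

## Double cross-validation

`run_double_cv()` wraps everything in the validation scheme of the
study: a 5-fold outer loop repeated 10 times estimates accuracy; a
4-fold inner loop tunes hyperparameters by DQ². Folds are drawn at the
*patient* level — both conditions and both duplicates of a patient stay
on one side of every split. The source design does not state this, but
sample-level folds would leak duplicate correlation straight into the
accuracy estimate, so patient-level stratification is the only defensible
reading; it is the single most consequential inferred decision in the
package. QC samples never enter folds; they are available to every
preprocessing fit. Preprocessing state (including imputation donors and
centering means) is re-estimated from each training fold, and the
leakage property — perturbing test-fold intensities leaves all trained
state bit-identical — is asserted in the test suite. Per-method
consensus sets are intersections of the 50 per-split selections, the
analog of "selected in all iterations". A selection that returns no
features marks the split as failed and scores it at the majority-class
accuracy rather than aborting.

## Annotation, enrichment, permutation validation

`annotate_features()` matches observed m/z values against ten adduct
rules (six of them the *primary ions*: M+H, M+Na, M−H2O+H, M−H, M−2H,
M−H2O−H) at 1, 3 or 5 ppm, polarity-gated. Neutral masses come from
exact monoisotopic element masses; adduct gains and losses use the
Mummichog convention's rounded group constants (H2O 18.0106,
NH3 17.0265, Na−H 21.9820, K−H 37.9559, Cl 34.9689, acetate 59.0133)
with proton mass 1.00727646 — these constants, not exact-mass
arithmetic, reproduce the published 4-decimal adduct table.
`enforce_primary_ions()` keeps a metabolite only if at least one hit is
primary; non-primary hits of retained metabolites stay as corroboration.

Enrichment builds a 2×2 table per pathway over the annotated metabolite
background and scores it with the right-tail Fisher exact test plus the
EASE variant (overlap reduced by one, floored at zero), which is always
at least as conservative. Permutation validation permutes the
*p-value vector across features* — the literal reading of the procedure;
the m/z structure and hence the annotation stay fixed — recomputes each
pathway's significance 100 times, and reports the fraction of
permutations more significant than the observed value. A genuinely
enriched pathway returns 0.

The packaged reference (`inst/extdata/mini_metabolite_reference.tsv`) is
a miniature curated table of ~50 real metabolites with elemental
formulas across four pathways (vitamin B3, arachidonic acid,
methionine–cysteine, purine). It replaces the full external pathway
database, which is out of scope; `load_metabolite_reference()` accepts
any user reference in the same schema and cross-checks stored masses
against formula-derived ones at 1e-4 Da.

## Network and report

`correlation_network()` computes Pearson correlations between selected
features over the study samples on the post-glog, pre-centering scale
(the scale is a package decision; the source does not state it) and
keeps edges with |r| ≥ 0.8. `connected_components()` orders components
by size. On the default cohort the largest component contains the full
causal block plus all proxies — the synthetic analog of the study's
single highly connected network. `significance_scatter()` emits the
per-feature (−log10 p, sMC F, selection flags) table behind the
univariate-vs-multivariate comparison plot; plotting itself is left to
the caller (`ggplot2` is suggested, not imported).

## Numerical choices and degenerate inputs

* Class codes are −1/+1 (`before`/`during`); a predicted value of
  exactly 0 classifies as +1, deterministically.
* PLS is NIPALS with X-deflation; for a single response each component
  is closed-form, and the regression vector is `b = W (P'W)^{-1} q`.
  Requesting more components than the effective rank raises an error.
* sMC features exactly proportional to the target projection get
  F = Inf, p = 0 rather than a division error.
* The WRT permutation p-value can never be 0 (add-one estimator).
* Missingness is encoded as intensity 0 and nothing else; any other
  token is a hard read error. TSV output prints doubles at full
  precision so a write/read cycle is bit-identical.
* All stochastic routines (generator, WRT, CARS, sPLS tuning, folds,
  permutation validation) take explicit seeds and are reproducible.

## Problem sizes used by the tests

The test suite runs the full default cohort (2000 features, 62
injections) through the complete double CV for the headline comparison,
and uses reduced cohorts (10 patients, 40–300 features) for unit-level
properties; the WRT type-I calibration uses 200 replicates of a 20×30
null problem, and the chance-level double-CV check uses a 300-feature
cohort with no treatment effect over 2 outer iterations. These sizes are
the package's choice of a compact but non-trivial demonstration; the
pipeline itself has no scale assumptions beyond memory.

## Known limitations

* The generator's proxies are constructed to correlate with the block;
  real confounders can be subtler (partial correlation, RT-dependent
  co-elution) and are not modeled.
* The sign test / signed-rank distinction matters only under ties;
  zero differences are dropped in both, which discards information when
  many exact zeros occur.
* CARS is Monte Carlo: on small feature sets its run-to-run variability
  is substantial, and its inner-CV DQ² plateaus over supersets of the
  informative features, so "the" optimal subset is not identifiable —
  only its quality is.
* Enrichment treats metabolites as exchangeable within the background;
  no weighting by detectability or adduct multiplicity is attempted.
* Single-batch design only; inter-batch correction is out of scope.
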