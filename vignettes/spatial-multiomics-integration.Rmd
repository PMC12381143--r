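---
title: "Methods: compartment-resolved integration of transcriptomes and proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment-resolved integration of transcriptomes and proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratomics)
```

# The analysis problem

Microdissected brain tissue yields paired measurements of the same
genes at two molecular levels: RNA-seq counts and DIA proteomics log2
intensities, across compartments (hippocampal subregions CA1/CA2-3/DG,
or the four CA1 strata SO/SP/SR/SLM) with biological replicates, plus
paired sorted/unsorted synaptosome fractions (P3/P2). The questions the
pipeline answers are: which molecules are enriched where; which
contaminants ride along with sorted synaptosomes; how tightly protein
spatial profiles track their mRNAs, and whether the decoupled ones are
explained by protein turnover; where co-enrichment suggests local
translation versus somatic synthesis and trafficking; and whether the
compartment proteomes are separable enough to classify.

This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does
not emulate.

# Count model and differential enrichment

Counts are modeled as negative binomial,
$K_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g)$ with
$\log \mu_{gj} = \log s_j + x_j^\top \beta_g$, where $x_j$ encodes a
two-level group factor (the contrast) and an additive replicate
blocking factor. Size factors use the median-of-ratios estimator and
are rescaled to unit geometric mean — the overall scale of size factors
is arbitrary, and the convention makes results exactly reproducible and
the estimator a fixed point on normalized counts.

Dispersion estimation proceeds in three steps:

1. **Gene-wise moments.** The residual variance $v_g$ of normalized
   counts around the fitted design (ordinary linear projection) gives
   $\hat\alpha_g = \max\{(v_g - \overline{1/s}\,\bar\mu_g)/\bar\mu_g^2,\ 10^{-8}\}$.
   Using residuals rather than the raw variance matters: genuine group
   effects must not masquerade as dispersion, or power collapses for
   exactly the genes of interest. The $\overline{1/s}\,\bar\mu_g$ term is
   the Poisson contribution under size-factor scaling.
2. **Trend.** A robust (Huber) regression of $\hat\alpha_g$ on
   $1/\bar\mu_g$ across genes gives the mean-dispersion trend
   $\alpha_{tr}(\mu) = a_1/\mu + a_0$, floored at $10^{-8}$.
3. **Shrinkage.** The final dispersion is the geometric mean
   $\exp\{(\log \hat\alpha_g + c + \log \alpha_{tr}(\bar\mu_g))/2\}$,
   with trend-only substitution when $\hat\alpha_g$ sits at the floor.
   The correction $c = \log(d/2) - \psi(d/2)$ (residual df $d$) undoes
   the downward bias of averaging a log-variance
   ($E[\log v] = \log \sigma^2 + \psi(d/2) - \log(d/2)$ for chi-square
   variance estimates); without it the Wald test is measurably
   anti-conservative at 7-vs-7 sample sizes.

The GLM is fit by IRLS with working weights $\mu/(1 + \alpha\mu)$
(convergence $\max|\Delta\beta| < 10^{-8}$, at most 100 iterations;
non-convergent or all-zero genes are flagged untestable, never silently
dropped), and the contrast is tested by a two-sided normal Wald test
with BH adjustment. In the large-count, small-dispersion limit this
reproduces the two-sample Poisson z statistic, which the test suite
checks against the closed form.

Enrichment calls combine significance and effect size: $q < \alpha$
and $\log_2\mathrm{FC} \ge 0.1$, with $\alpha = 0.01$ for tissue and
$0.05$ for synaptosome comparisons. The 0.1 threshold is deliberately
permissive — it excludes only near-zero effects. Two contrast schemes
are supported: one-vs-rest (each compartment against the pooled others;
the default for strata) and pairwise intersection (enriched only if
significant against *every* other compartment; the subregion
convention). Depletion calls mirror enrichment with
$\log_2\mathrm{FC} \le -0.1$; a feature can never be both in one
compartment.

# Protein model

Log2 intensities are first rlr-normalized: each sample is regressed on
the per-feature median reference profile (pairwise-complete) by Huber
M-estimation (tuning constant 1.345, up to 50 IRLS iterations), and the
fitted affine map is inverted, $x' = (x - a)/b$. Exact-fit samples fall
back to OLS, which coincides with the Huber solution when residuals
vanish (the robust scale estimate degenerates there). A non-positive
slope or non-convergence aborts with the offending sample named.
Idempotence is exact on affinely related samples and approximate (the
median reference shifts slightly) on noisy data.

Differential testing uses a protein-level moderated linear model.
Features are first valid-value filtered per contrast (at least
`min_quant` non-missing values in *each* group, the "filter by
contrast" convention of DIA pipelines). Per protein, OLS on the
available values gives $\hat\beta_g$, residual variance $s_g^2$ with
df $d_g$; the prior $(d_0, s_0^2)$ is fitted by matching the first two
moments of $\log s_g^2$ using digamma/trigamma identities (trigamma
inverted by Newton iteration); the moderated variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ yields
$t = \hat\beta / (\tilde s_g \sqrt{v_c})$ on $d_0 + d_g$ df. When all
residual variances coincide the prior df diverges and the test becomes
a z-test with the common variance. Proteins with $d_g = 0$ fall back to
the prior variance with a warning.

iBAQ values divide linear-scale intensity by the count of theoretical
tryptic peptides with length in [7, 35]. Digestion follows Trypsin/P —
cleavage after every K or R *including* before proline — because that
is the rule used to build DIA spectral libraries; counting uses 0
missed cleavages (canonical iBAQ), exposed as a flag since
identification settings often allow 2. Distinct peptides are counted
once.

# Contaminant filtering

P3-vs-P2 tests run per compartment with the molecule-appropriate model;
a feature significantly enriched in the unsorted fraction
($q < 0.05$, $\log_2\mathrm{FC}(P3/P2) \le -0.1$) in *any* compartment
is listed, with provenance. One list per molecule level. A caveat the
package documents deliberately: each compartment's list controls FDR at
0.05, but the union accumulates false positives across compartments
while true contaminants are shared, so the realized fraction of false
listings in the union sits above the per-compartment FDR (empirically
around 8% under the default synthetic conditions). Any stricter bound
would require lowering the per-compartment threshold, which the
filtering thresholds deliberately mirror from the synaptosome
enrichment convention.

# Integration statistics

*Population correlation* relates mean log2 normalized counts to mean
log2 iBAQ per gene, within each stratum and "overall" (per-gene grand
mean across strata — one value per gene, chosen over pooled stacking so
the overall scope is not dominated by between-stratum structure).
Complete pairs only; scopes with fewer than 3 pairs are flagged rather
than reported.

*Profile-correlation classification* computes, per shared gene, the
Pearson correlation between its 4-point mean mRNA and protein profiles,
classifying $r \ge 0.9$ as positive and $r \le -0.9$ as negative. With
only 4 profile points no p-value is attached — under independence $r$
is uniform on $[-1, 1]$ at $n = 4$, so roughly 10% of uncoupled genes
land in the two classes by chance; the thresholds are configuration,
and class counts are monotone in them. Zero-variance profiles are
flagged with class "neither".

*Half-life comparison* joins the classes to a gene-to-half-life
reference and runs a tie-corrected Kruskal–Wallis test followed by
Dunn's post hoc z tests with Bonferroni adjustment, over the groups
"all" (every mapped gene), "positive" and "negative". The "all" group
intentionally overlaps the class groups — its members re-enter the
pooled ranking — mirroring the three-box comparison convention; the
groups are therefore not independent, which affects interpretation, not
computation. For very small groups, where the $\chi^2$ reference is a
rough approximation, a Monte-Carlo permutation p-value is available
(`p_method = "permutation"`).

*Co-enrichment mapping* cross-tabulates genes enriched at both levels
by (mRNA compartment, protein compartment); genes enriched in several
compartments contribute to every applicable cell (the alluvial-flow
semantics). Per cell, translatome label proportions are computed over
labeled genes, with unlabeled genes counted separately.

*Gene-set overrepresentation* is the one-sided hypergeometric tail
against the custom background of all genes identified in the
experiment, BH-adjusted, significance at FDR < 0.05, sets below 3
in-background members skipped. GO-graph-aware redundancy simplification
is out of scope.

*Fold-change z-scores* standardize each gene's log2 fold changes across
strata (sample SD); constant rows become zero and are flagged. Per-set
long-format extractions feed ridge-plot-style summaries.

# PLS-DA

NIPALS PLS2 on autoscaled predictors (zero-variance columns removed)
with one-hot, column-centered class indicators: per component, the
X-weight is normalized $X^\top u$, scores $t = Xw$, Y-loadings
$q = Y^\top t / t^\top t$, iterated to $\|\Delta t\| < 10^{-10}$ (at
most 500 iterations), then X and Y are deflated by $t p^\top$ and
$t q^\top$. The first weight vector equals the dominant left singular
vector of the X–Y cross-covariance; at full rank the fitted values
reproduce OLS — both are test-suite checks. Prediction assigns the
class with the largest fitted indicator.

Cross-validation is stratified within class, 3-fold, repeated (15
repeats by default; the strata convention in the source domain uses
100), with preprocessing refit inside each training fold so no
information leaks. The oneSE rule picks the smallest component count
whose mean accuracy is within one standard error (computed across the
best count's fold-by-repeat accuracies) of the best mean — the standard
oneSE convention. Accuracy is the metric. VIP scores satisfy
$\overline{\mathrm{VIP}^2} = 1$ exactly; the 0–100 display scale is
$100 \cdot \mathrm{VIP}/\max(\mathrm{VIP})$, a choice made here because
the source convention prints the range without defining the transform —
raw VIPs are always emitted alongside.

# The synthetic-data generator

The generator defines the study conditions: 2000 genes, four strata,
7 replicates, 10% of genes enriched per compartment at +1 log2 unit,
log-normal NB dispersions (geometric mean 0.05), log-normal size
factors (SD 0.15, geometric mean 1), protein noise SD 0.25 log2 units,
5% missingness, coupling fractions (0.2 positive, 0.15 negative),
contaminant fraction 10% at +2 log2 units in P2, half-life base 192 h
(a week-scale neuronal proteome) with log-slope 0.5 against the
coupling coefficient. Defaults were chosen once for realism and
testability and are all exposed in `sim_config()`.

Construction details that matter:

- The protein compartment profile is
  $\gamma_g = A(\rho_g z_g + \sqrt{1-\rho_g^2}\, e_g)$ with $z_g$ the
  standardized planted mRNA profile, $e_g$ an independent standardized
  profile and $A$ the effect amplitude, so the expected mRNA–protein
  profile correlation equals $\rho_g \in \{+1, 0, -1\}$ by class.
- Coupled genes without a planted enrichment block receive a random
  mRNA compartment profile of the same amplitude: a profile correlation
  is only observable for spatially varying mRNAs, so coupling without
  an mRNA profile would be vacuous. Recovery tests therefore evaluate
  enrichment-call FDR against threshold-based truth derived from the
  planted profile matrix, not only the block assignments.
- Baseline protein abundance is partially coupled to baseline mRNA
  abundance (correlation 0.35), giving the modest population-level
  correlation typical of neural tissue.
- Missingness is abundance-linked (MNAR-lite): the lowest-intensity
  tercile is twice as likely missing as the rest, at the configured
  overall rate — DIA missingness is abundance-dependent, and this makes
  the valid-value filter meaningfully testable.
- Coupling-null genes still carry protein profiles (the $e_g$ term), so
  a *protein* null simulation requires `effect_lfc = 0`, not merely
  zero enrichment fractions.

What the generator does **not** emulate: peptide-level quantification
and roll-up, protein-group ambiguity (features are one gene symbol
throughout, and inputs must arrive pre-resolved), batch and run-order
effects, compositional distortions of sequencing, library-preparation
biases, spatial bleed-over between adjacent strata, and cell-type
mixtures. Passing recovery tests therefore demonstrates correctness of
the statistical machinery under the stated generative model — not
robustness to every artifact of real tissue data.

# Numerical choices and degenerate inputs

- IRLS (NB): tolerance $10^{-8}$, 100 iterations, linear predictor
  clamped to $\pm 30$; Huber fits: 50 iterations, $k = 1.345$; NIPALS:
  $10^{-10}$, 500 iterations; trigamma inversion: Newton, relative
  tolerance $10^{-10}$.
- All-zero genes, rank-deficient per-protein designs, zero-variance
  profiles and empty scopes are flagged, never silently dropped.
- Ties in rank tests use the $\sum(t^3 - t)$ correction in both H and
  the Dunn variance; prediction ties in PLS-DA resolve to the first
  class (deterministic).
- Tables are TSV, UTF-8, '.' decimal, `NA` for missing on write
  (empty or `NA` accepted on read); values are written with 15
  significant digits so round trips preserve 12.
- Every stochastic stage takes an explicit seed; pipeline reruns with
  identical configuration and seed are byte-identical.

# Problem sizes used by the test suite

Module tests run on matrices of tens to hundreds of features. The
acceptance-style checks use the study-scale defaults: 2000 genes with
7-vs-7 null simulations for calibration, 5000 proteins for prior
recovery, 20 generator seeds for the half-life direction check, and the
full default pipeline (run twice) for byte-level determinism. These
sizes are the package's chosen balance between statistical resolution
and a test suite that runs in minutes on a laptop.

# Known limitations

- Effect-size shrinkage (adaptive-prior estimators and sign-error-based
  s-values) is not implemented; unshrunk Wald estimates with BH
  q-values stand in at the same thresholds, which preserves the
  recovery behavior tested here but reports noisier fold changes for
  low-count genes.
- The moderated linear model operates at protein level; peptide-level
  inference methods would be needed for peptide-resolved inputs.
- The union contaminant list does not control the FDR of the union (see
  above).
- ORA treats genes as exchangeable; no redundancy simplification across
  overlapping sets.
- PLS-DA requires complete cases, so its feature space shrinks with
  missingness; this mirrors the source convention rather than imputing.
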