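---
title: "Multi-ancestry polygenic risk scores: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-ancestry polygenic risk scores: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Polygenic risk scores (PRS) summarize inherited disease liability as a
weighted sum of effect-allele dosages, `S_i = sum_j d_ij w_j`.  For
Alzheimer disease, the largest training GWAS are overwhelmingly of European
ancestry, and a score trained in one ancestry transfers poorly to others
because allele frequencies, LD structure and (to a lesser degree) effect
sizes differ.  `multiprs` implements a pipeline for building a single
multi-ancestry PRS from several ancestry-specific GWAS, evaluating it, and
transferring it unchanged to external cohorts:

1. **Per-study construction** — native LD clumping + p-value thresholding
   (C+T) over a parameter grid, with the most *stable* candidate selected
   by coefficient of variation across random unrelated tuning subsets.
2. **Combination** — three strategies: *meta-analysis first* (fixed-effects
   inverse-variance meta-analysis of the source GWAS, then one C+T score),
   *unweighted summation* `PRS_1 + ... + PRS_K`, and *weighted summation*
   `w_1 PRS_1 + ... + w_K PRS_K` with the `w_k` trained in an independent
   cohort (one logistic regression per source; the PRS coefficient is the
   weight — the "PRSsum Simple" recipe).
3. **Evaluation** — logistic regression of case status on the standardized
   PRS (OR per 1 SD with Wald CI) plus AUC computed on an unrelated subset,
   with a composite ranking rule AUC, then OR, then p.
4. **Masking and transfer** — the APOE region (chr19:44,905,791-44,909,393,
   GRCh38) plus a 1 Mb flank is excluded so the score captures the
   polygenic background rather than the single dominant locus; the best
   strategy is collapsed to one per-variant weight table and applied to
   external cohorts with a *frozen* scaling reference (mean/SD from the
   evaluation cohort), never refit.

Because the cohorts such a study uses are access-restricted, the package
ships a first-class synthetic-data module that reproduces their
*statistical* structure, so every stage is testable end to end.

## The synthetic cohorts

**Allele frequencies.** Ancestral frequencies are uniform on (0.05, 0.95);
each ancestry drifts by the Balding–Nichols model,
`af ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`, so `E[af] = p` and
`Var[af] = F p (1-p)`.  Defaults use three groups — a large European-like
group (F = 0.02), an admixed African-like group (F = 0.12) and an
East-Asian-like group (F = 0.10) — coarse but standard drift magnitudes.

**LD.** Haplotypes come from a latent Gaussian with block-constant
correlation (default blocks of 10 variants, ρ = 0.7, 5 kb spacing),
thresholded at the ancestry-specific allele-frequency quantile; a dosage is
the sum of two haplotypes.  This gives high within-block and ~zero
cross-block dosage r², which is exactly what clumping needs to be
exercised.  It is *not* a coalescent model: there is no recombination
gradient, no allele-age/frequency coupling, and cross-ancestry LD
differences arise only through frequencies.  Conclusions about *relative*
method behaviour carry over; absolute transferability numbers do not.

**Effects.** A causal set (default 20% of variants) is shared across
ancestries; causal effects are multivariate normal with cross-ancestry
correlation 0.8 (in the range reported for common-variant architectures
across continental groups).  Effects are rescaled by a single common
factor so the mean liability-scale genetic variance equals `h2`
(default 0.3, a typical non-APOE common-variant estimate).  A common
factor, rather than per-ancestry factors, keeps a perfectly correlated
architecture exactly identical across ancestries; per-ancestry `h2` then
varies slightly with drift, which is the lesser distortion.  One
designated variant plays APOE: it sits inside the real APOE interval on
chr19, gets a liability effect of 0.45 per allele (odds ratio near 3) in
every ancestry, and an ancestral frequency of 0.15 (a typical ε4
frequency).

**Phenotypes.** Liability = centered genetic score + 0.15·(standardized
age) + 0.1·(centered sex) + a protective ε2-like term (frequency 0.08,
effect −0.3, drawn on the allele slots left free by ε4) + Gaussian
residual scaled so total variance is ~1; cases exceed
`qnorm(1 - prevalence)`.  Prevalence defaults to 0.25 — these are
case-enriched referral cohorts, not the general population.  Ages are
truncated normal on [60, 95] to match age-60+ analyses.  Ten synthetic
PCs are attached; the leading ones encode ancestry contrasts.

**Summary statistics.** `"regression"` mode fits per-variant logistic
regressions (dosage + standardized age + sex) — the honest but slow route.
`"analytic"` mode emulates a large-n GWAS: the LD-aware marginal liability
effect is estimated from reference genotypes, mapped to the logistic scale
by the first-order factor `dnorm(qnorm(1-K))/(K(1-K))`, and observed with
noise `se = 1/sqrt(n 2 af (1-af) v)`, `v = K(1-K)`.  Analytic mode ignores
the correlation *between* marginal estimates induced by LD; downstream
clumping de-correlates the retained variants, so this is acceptable for
pipeline emulation (and is validated against regression mode in the
tests).  The default training sources emulate three large European GWAS
(effective n 300k/250k/200k) and one smaller East-Asian GWAS (30k).

**Relatedness.** Sibling pairs are generated by Mendelian transmission
from dosages (allele ~ Binomial(1, d/2) per parent); kinship tables record
0.25 for sib and parent–offspring pairs.  This supports the kinship < 0.04
unrelated filter without simulating full pedigrees.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| C+T clumping r² | {0.1, 0.2, 0.3} | standard grid |
| C+T windows | {100, 250, 500} kb, center-to-center (PLINK convention) | standard grid |
| p-value ladder | 5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5 | an 8-rung ladder spanning genome-wide significance to 0.5; fully configurable |
| CV subsets `k` | 5 | stability estimate with usable per-subset n |
| kinship threshold | 0.04 | approximately third-degree relatives |
| QC | MAF ≤ 0.01 removed (boundary exclusive); missing rate > 1% removed | WGS PRS practice |
| APOE mask | chr19:44,905,791–44,909,393 ± 1 Mb | see below |
| weight fit mode | `"marginal"` | see below |

## Design decisions where the design was open

* **"1 Mb window of APOE"** is read as a ±1 Mb *flank* around the gene
  (distance-from-gene), not a 1 Mb total window; both are expressible via
  `mask_region(flank_bp =)`, the flank is the default.
* **Marginal vs joint weight training.** The summation weights default to
  one logistic regression per source ("derived separately"); a `"joint"`
  mode (all sources in one model) is first-class because with correlated
  source scores the two estimands differ.  Negative weights pass through
  unconstrained.
* **Clumping tie-breaks.** Equal p-values are broken by (chrom, pos)
  ascending, making the output invariant to input row order and identical
  across platforms.
* **CV denominator.** `cv = sd/|mean|`; candidates whose per-subset effect
  flips sign have a small |mean| and blow up the cv, so they lose
  naturally — no special-casing of unstable signs.
* **Meta-analysis union rule.** A variant present in any subset of studies
  is meta-analyzed over the studies that carry it (weights 1/se²); nothing
  requires complete overlap.
* **Palindromic variants** (A/T, C/G) are always dropped at harmonization;
  no frequency-based strand inference.  Conservative and deterministic.
* **Variant identity** is (chrom, pos) with an allele-compatibility check;
  IDs are annotation only.  Positions are formatted fixed-point in keys so
  integer/double storage (e.g. after a TSV round trip) cannot split keys.
* **Duplicate keys in a weight table are an error**, never averaged —
  silent averaging hides construction bugs.
* **Plain logistic regression on the unrelated subset** stands in for
  kinship-random-effect mixed models throughout: the unrelated-subset
  route is already required for AUC, and extending it to estimation keeps
  the package free of GLMM machinery.  Output metadata records the
  covariates actually used.
* **Separation** in a logistic fit (e.g. a tiny APOE-genotype stratum) is
  a hard error; stratified drivers skip such strata with a logged reason
  rather than reporting a Firth-style fallback the rest of the pipeline
  does not use.
* **Ranking rule.** AUC (desc), then OR per SD (desc), then p (asc), then
  model label — a deterministic composite of the three reported criteria.
* **Tuning subsets** are a simple random split of the unrelated tuning
  cohort, not ancestry-stratified.

## Numerical notes

* Logistic fits are IRLS (`stats::glm`, tolerance 1e-8, ≤ 100 iterations);
  Wald CIs `exp(b ± 1.96 se)`; two-sided normal p-values, clamped away
  from exact 0.
* AUC uses the midrank Mann–Whitney formulation (ties contribute ½) and is
  tested against exhaustive pair enumeration at 1e-12.
* Standardization is `(x - mean)/sd` with the (n−1)-denominator SD; a
  constant score vector is an error, surfaced where it arises (e.g. the
  degenerate `x + (−x)` unweighted sum).
* All generators are bit-reproducible given a seed; composite drivers
  derive per-stage child seeds deterministically, and pipeline runs write
  a manifest with md5 hashes of every artifact so reruns can be compared
  byte for byte.

## Problem sizes used by the tests and the acceptance script

The shipped analyses run at desk scale, chosen so the full battery
completes in minutes on one core while every statistical check retains
power: 1,200 variants (blocks of 10), cohorts of ~1,400–3,800 samples
across three ancestries for the pipeline drivers; 2,000 variants and
n = 20,000 training cohorts for the weight-recovery study; n = 10,000
evaluation cohorts for the strategy-selection study.  Effect sizes at this
scale are intentionally *larger* than a realistic genome-wide setting (the
same h² is concentrated in ~240 causal variants instead of tens of
thousands), so ORs per SD around 2–3 and AUCs around 0.8 in the synthetic
world are expected and carry no claim about real cohorts.

## Known limitations

* No admixture tracts, local ancestry, X chromosome or imputation
  uncertainty in the generator; LD is block-stylized.
* The liability-to-logistic mapping in analytic sumstats mode is
  first-order and degrades for large per-variant effects.
* Bayesian shrinkage weighting (LDPred2/PRS-CS/PRS-CSx) is consumed as
  external weight tables, not re-implemented.
* Mixed-model association and ordinal/longitudinal outcome models are out
  of scope; continuous traits get OLS via `fit_linear_assoc`.
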