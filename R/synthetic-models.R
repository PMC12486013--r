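#' Ancestry drift model
#'
#' Describes a set of ancestry groups as Balding-Nichols drift from a common
#' ancestral population: ancestry-specific allele frequencies are drawn
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral frequency `p`, with
#' one drift coefficient `F` (Fst) per group.
#'
#' @param labels character vector of unique ancestry names.
#' @param fst drift coefficient per ancestry, each in \[0, 1).
#' @param af_range ancestral allele-frequency range `(low, high)` in (0, 1).
#' @return An `ancestry_model` list.
#' @export
ancestry_model <- function(labels, fst, af_range = c(0.05, 0.95)) {
  if (anyDuplicated(labels)) stop("ancestry labels must be unique")
  if (length(fst) == 1L) fst <- rep(fst, length(labels))
  if (length(fst) != length(labels)) stop("one fst per ancestry label")
  if (any(fst < 0 | fst >= 1)) stop("fst must lie in [0, 1)")
  if (length(af_range) != 2L || af_range[1] <= 0 || af_range[2] >= 1 ||
      af_range[1] > af_range[2])
    stop("af_range must satisfy 0 < low <= high < 1")
  structure(list(labels = as.character(labels), fst = as.numeric(fst),
                 af_range = as.numeric(af_range)),
            class = "ancestry_model")
}

#' LD block specification
#'
#' Variants are partitioned (within chromosome, in index order) into blocks of
#' `block_size`; haplotypes are generated from a latent Gaussian with
#' block-constant correlation `rho`, so realized dosage LD is high within and
#' ~zero across blocks.  This is a deliberately simple stand-in for cohort LD
#' sufficient to exercise clumping; it is not a coalescent model.
#'
#' @param block_size variants per block (positive integer).
#' @param rho latent within-block correlation in \[0, 1).
#' @param spacing_bp base pairs between adjacent variants.
#' @return An `ld_block_spec` list.
#' @export
ld_block_spec <- function(block_size = 10L, rho = 0.7, spacing_bp = 5000L) {
  if (!is_count(block_size)) stop("block_size must be a positive integer")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (!is_count(spacing_bp)) stop("spacing_bp must be a positive integer")
  structure(list(block_size = as.integer(block_size), rho = as.numeric(rho),
                 spacing_bp = as.integer(spacing_bp)),
            class = "ld_block_spec")
}

#' Polygenic effect architecture
#'
#' Spike-and-slab architecture with a causal set shared across ancestries,
#' per-ancestry effects drawn multivariate normal with cross-ancestry
#' correlation, variance scaled to a target liability-scale heritability,
#' plus one designated large-effect ("APOE-like") variant.
#'
#' Defaults mirror what is commonly estimated for late-onset Alzheimer
#' disease outside APOE: modest common-variant heritability (`h2 = 0.3`),
#' high but imperfect cross-ancestry genetic correlation (0.8), and an
#' APOE-proxy liability effect of 0.45 per allele (odds ratio near 3 at
#' typical prevalence).
#'
#' @param n_causal_fraction fraction of variants that are causal, in (0, 1\].
#' @param h2 liability-scale genetic variance in \[0, 1).
#' @param cross_ancestry_corr genetic effect correlation across ancestries.
#' @param apoe_like_effect liability-scale per-allele effect of the
#'   designated large-effect variant.
#' @return An `effect_model` list.
#' @export
effect_model <- function(n_causal_fraction = 0.2, h2 = 0.3,
                         cross_ancestry_corr = 0.8, apoe_like_effect = 0.45) {
  if (n_causal_fraction <= 0 || n_causal_fraction > 1)
    stop("n_causal_fraction must lie in (0, 1]")
  if (h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)")
  if (abs(cross_ancestry_corr) > 1)
    stop("cross_ancestry_corr must lie in [-1, 1]")
  structure(list(n_causal_fraction = n_causal_fraction, h2 = h2,
                 cross_ancestry_corr = cross_ancestry_corr,
                 apoe_like_effect = apoe_like_effect),
            class = "effect_model")
}

#' Liability-threshold phenotype model
#'
#' Case/control status arises from a latent liability: centered genetic score
#' plus standardized age and centered sex effects, an independently simulated
#' protective epsilon2-like allele count, and a Gaussian residual scaled so
#' the total liability variance is ~1; cases exceed the `qnorm(1 - prevalence)`
#' threshold.  Ages are drawn truncated normal on `age_range` (the analyses
#' this emulates are restricted to age 60+).
#'
#' @param prevalence case probability, strictly inside (0, 1).  Default 0.25:
#'   case-enriched referral cohorts, not population prevalence.
#' @param age_effect,sex_effect liability-scale effects of standardized age
#'   and centered sex.
#' @param age_mean,age_sd,age_range age distribution in years.
#' @param e2_freq,e2_effect allele frequency and (protective) liability
#'   effect of the independently simulated epsilon2-like allele.
#' @return A `liability_model` list.
#' @export
liability_model <- function(prevalence = 0.25, age_effect = 0.15,
                            sex_effect = 0.1, age_mean = 75, age_sd = 7,
                            age_range = c(60, 95), e2_freq = 0.08,
                            e2_effect = -0.3) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly inside (0, 1)")
  if (e2_freq < 0 || e2_freq >= 1) stop("e2_freq must lie in [0, 1)")
  structure(list(prevalence = prevalence, age_effect = age_effect,
                 sex_effect = sex_effect, age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range, e2_freq = e2_freq,
                 e2_effect = e2_effect),
            class = "liability_model")
}
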