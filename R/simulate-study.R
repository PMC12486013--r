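#' Simulate a complete multi-study PRS world
#'
#' One call builds everything the training/validation pipeline consumes:
#' drifted per-ancestry allele frequencies, a shared polygenic architecture
#' with an APOE-like large-effect locus, per-source GWAS summary statistics
#' (analytic large-n emulation by default), and genotype + phenotype +
#' kinship tables for the reference (LD panel), tuning, training
#' (weight-derivation), evaluation and validation cohorts.  Cohorts are
#' mutually disjoint by sample id; tuning and evaluation cohorts include
#' sibling pairs so relatedness filters have work to do.
#'
#' The defaults emulate the statistical shape of a multi-ancestry
#' Alzheimer study: three ancestry groups (a large European-like, an
#' admixed African-like with stronger drift, an East-Asian-like), three
#' large European-ancestry training GWAS plus one smaller East-Asian GWAS,
#' case-enriched cohorts, and desk-scale sample sizes.
#'
#' @param m_variants number of variants.
#' @param ancestry an [ancestry_model()].
#' @param ld an [ld_block_spec()].
#' @param effect an [effect_model()].
#' @param liability a [liability_model()].
#' @param sources list of source GWAS specs: `list(label=, ancestry=,
#'   n_effective=)`; add `null = TRUE` for a study whose true effects are
#'   all zero (an uninformative source).
#' @param cohort_sizes named list (`reference`, `tuning`, `training`,
#'   `evaluation`, `validation`) of named per-ancestry sample counts.
#' @param n_related_pairs named list of sibling-pair counts appended to
#'   cohorts.
#' @param apoe_ancestral_af ancestral frequency of the APOE-like locus
#'   (default 0.15, a typical epsilon4 frequency).
#' @param seed master integer seed; every sub-step derives its own stream.
#' @return List with `variant_index`, `afs`, `effects`, `sources`
#'   (label/ancestry/sumstats), and `cohorts` (each `geno`, `phen`, `kin`).
#' @export
simulate_prs_study <- function(
    m_variants = 1200,
    ancestry = ancestry_model(c("EA", "AA", "EAS"),
                              fst = c(0.02, 0.12, 0.10)),
    ld = ld_block_spec(),
    effect = effect_model(),
    liability = liability_model(),
    sources = list(
      list(label = "EUR_gwas1", ancestry = "EA", n_effective = 300000),
      list(label = "EUR_gwas2", ancestry = "EA", n_effective = 200000),
      list(label = "EUR_gwas3", ancestry = "EA", n_effective = 250000),
      list(label = "EAS_gwas", ancestry = "EAS", n_effective = 30000)),
    cohort_sizes = list(
      reference = c(EA = 800, AA = 500, EAS = 300),
      tuning = c(EA = 800, AA = 400, EAS = 200),
      training = c(EA = 2500, AA = 1000, EAS = 300),
      evaluation = c(EA = 1800, AA = 800, EAS = 250),
      validation = c(EA = 800, AA = 400, EAS = 200)),
    n_related_pairs = list(tuning = 30, evaluation = 50),
    apoe_ancestral_af = 0.15,
    seed = 1L) {
  p0 <- draw_ancestral_frequencies(m_variants, ancestry,
                                   seed = derive_seed(seed, 1))
  ## the designated APOE-like locus (last variant) gets a realistic
  ## epsilon4-like ancestral frequency rather than a uniform draw
  p0[m_variants] <- apoe_ancestral_af
  afs <- drift_frequencies(p0, ancestry, seed = derive_seed(seed, 2))
  vindex <- make_variant_index(m_variants, ld, afs = afs,
                               seed = derive_seed(seed, 3))
  effects <- draw_true_effects(vindex, effect, seed = derive_seed(seed, 4))

  cohorts <- list()
  ci <- 0L
  for (nm in names(cohort_sizes)) {
    ci <- ci + 1L
    sizes <- cohort_sizes[[nm]]
    sizes <- sizes[names(sizes) %in% colnames(afs)]
    G <- simulate_genotypes(afs, ld, sizes, seed = derive_seed(seed, 10 + ci),
                            variant_index = vindex)
    ## prefix ids so cohorts are disjoint by construction
    G$samples$sample_id <- paste(nm, G$samples$sample_id, sep = ".")
    rownames(G$dosages) <- G$samples$sample_id
    kin <- data.frame(id1 = character(0), id2 = character(0),
                      kinship = numeric(0), stringsAsFactors = FALSE)
    npair <- n_related_pairs[[nm]] %||% 0
    if (npair > 0) {
      rel <- simulate_related_pairs(G, npair,
                                    seed = derive_seed(seed, 40 + ci))
      off <- rel$offspring
      off$samples$sample_id <- paste(nm, off$samples$sample_id, sep = ".")
      rownames(off$dosages) <- off$samples$sample_id
      kin <- rel$kinship
      kin$id1 <- ifelse(grepl("^sib", kin$id1), paste(nm, kin$id1, sep = "."),
                        kin$id1)
      kin$id2 <- ifelse(grepl("^sib", kin$id2), paste(nm, kin$id2, sep = "."),
                        kin$id2)
      G <- gm_rbind(G, off)
    }
    phen <- simulate_phenotypes(G, effects, liability,
                                seed = derive_seed(seed, 70 + ci),
                                cohort_label = nm)
    cohorts[[nm]] <- list(geno = G, phen = phen, kin = kin)
  }

  ref <- cohorts$reference$geno
  src_out <- list()
  for (k in seq_along(sources)) {
    sp <- sources[[k]]
    Ga <- gm_subset(ref, sample_ids =
                      ref$samples$sample_id[ref$samples$ancestry ==
                                              sp$ancestry])
    eff_k <- if (isTRUE(sp$null)) rep(0, nrow(vindex))
             else effects[, sp$ancestry]
    ss <- simulate_sumstats(Ga, mode = "analytic",
                            seed = derive_seed(seed, 100 + k),
                            effects = eff_k,
                            n_effective = sp$n_effective,
                            prevalence = liability$prevalence,
                            study_label = sp$label,
                            ancestry_label = sp$ancestry)
    src_out[[sp$label]] <- list(label = sp$label, ancestry = sp$ancestry,
                                n_effective = sp$n_effective, sumstats = ss)
  }

  list(variant_index = vindex, afs = afs, effects = effects,
       sources = src_out, cohorts = cohorts, seed = seed,
       models = list(ancestry = ancestry, ld = ld, effect = effect,
                     liability = liability))
}
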