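# Small in-code fixtures shared across test files.

# Hand-built genotype matrix: `dosages` is samples x variants.
tiny_gm <- function(dosages, chrom = NULL, pos = NULL, afs = NULL,
                    ancestry = "EA") {
  m <- ncol(dosages)
  n <- nrow(dosages)
  v <- data.frame(chrom = chrom %||% rep("1", m),
                  pos = pos %||% (1000 * seq_len(m)),
                  id = sprintf("s%03d", seq_len(m)),
                  effect_allele = "A", other_allele = "G",
                  stringsAsFactors = FALSE)
  if (!is.null(afs)) v[[paste0("af_", ancestry)]] <- afs
  genotype_matrix(dosages,
                  v,
                  data.frame(sample_id = sprintf("i%03d", seq_len(n)),
                             ancestry = ancestry, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weight table over a genotype matrix's variants.
wt_for <- function(G, weights, rows = seq_along(weights)) {
  v <- G$variants[rows, , drop = FALSE]
  weight_table(data.frame(chrom = v$chrom, pos = v$pos, id = v$id,
                          effect_allele = v$effect_allele,
                          other_allele = v$other_allele, weight = weights,
                          stringsAsFactors = FALSE))
}

# Random hard-call dosage matrix with AFs bounded away from 0/1.
random_dosages <- function(n, m, seed) {
  set.seed(seed)
  af <- runif(m, 0.1, 0.9)
  matrix(rbinom(n * m, 2, rep(af, each = n)), n, m)
}

# Small single-ancestry world for scoring/association tests.
small_cohort <- function(n = 500, m = 80, seed = 7, h2 = 0.4,
                         prevalence = 0.3) {
  anc <- ancestry_model("EA", fst = 0.02)
  ld <- ld_block_spec(block_size = 5, rho = 0.5, spacing_bp = 5000)
  p0 <- draw_ancestral_frequencies(m, anc, seed = seed)
  afs <- drift_frequencies(p0, anc, seed = seed + 1)
  vi <- make_variant_index(m, ld, afs = afs, seed = seed + 2)
  G <- simulate_genotypes(afs, ld, c(EA = n), seed = seed + 3,
                          variant_index = vi)
  eff <- draw_true_effects(vi, effect_model(h2 = h2), seed = seed + 4)
  phen <- simulate_phenotypes(G, eff, liability_model(prevalence = prevalence),
                              seed = seed + 5)
  list(G = G, phen = phen, effects = eff, vi = vi, afs = afs, ld = ld)
}
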