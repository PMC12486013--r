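test_that("ancestral frequency draws honour the range, the mean and the seed", {
  am <- ancestry_model(c("EA", "AA"), fst = c(0.02, 0.1),
                       af_range = c(0.5, 0.5))
  expect_equal(draw_ancestral_frequencies(5, am, seed = 1), rep(0.5, 5))

  am2 <- ancestry_model("EA", fst = 0.02, af_range = c(0.05, 0.95))
  p <- draw_ancestral_frequencies(1e4, am2, seed = 11)
  se <- sqrt(0.9^2 / 12 / 1e4)  # uniform(0.05, 0.95) variance / m
  expect_lt(abs(mean(p) - 0.5), 3 * se)

  expect_identical(draw_ancestral_frequencies(100, am2, seed = 3),
                   draw_ancestral_frequencies(100, am2, seed = 3))
  expect_error(ancestry_model("EA", fst = 1), "fst")
  expect_error(ancestry_model(c("a", "a"), fst = 0), "unique")
})

test_that("drift matches Balding-Nichols moments and F=0 is the identity", {
  am0 <- ancestry_model("EA", fst = 0)
  p <- runif(50, 0.2, 0.8)
  expect_equal(drift_frequencies(p, am0, seed = 1)[, "EA"], p)

  am <- ancestry_model("X", fst = 0.1)
  d <- drift_frequencies(rep(0.5, 1e4), am, seed = 5)[, 1]
  # E = 0.5, Var = F p (1-p) = 0.025
  expect_lt(abs(mean(d) - 0.5), 3 * sqrt(0.025 / 1e4))
  expect_lt(abs(var(d) - 0.025) / 0.025, 0.10)

  am2 <- ancestry_model(c("low", "high"), fst = c(0.01, 0.2))
  d2 <- drift_frequencies(rep(0.5, 1e4), am2, seed = 6)
  expect_lt(abs(var(d2[, "low"]) - 0.01 * 0.25) / (0.01 * 0.25), 0.15)
  expect_lt(abs(var(d2[, "high"]) - 0.2 * 0.25) / (0.2 * 0.25), 0.15)
})

test_that("block-LD genotypes have the requested LD and allele frequencies", {
  ld0 <- ld_block_spec(block_size = 5, rho = 0, spacing_bp = 1000)
  afs <- matrix(runif(20, 0.3, 0.7), 20, 1, dimnames = list(NULL, "EA"))
  G0 <- simulate_genotypes(afs, ld0, c(EA = 5000), seed = 2)
  r2 <- cor(G0$dosages[, 1:5])^2
  expect_lt(mean(r2[upper.tri(r2)]), 0.01)

  ld9 <- ld_block_spec(block_size = 5, rho = 0.99, spacing_bp = 1000)
  afs5 <- matrix(0.5, 10, 1, dimnames = list(NULL, "EA"))
  G9 <- simulate_genotypes(afs5, ld9, c(EA = 5000), seed = 3)
  adj <- sapply(1:4, function(j) cor(G9$dosages[, j], G9$dosages[, j + 1])^2)
  expect_true(all(adj > 0.8))
  # across blocks ~ 0
  expect_lt(cor(G9$dosages[, 1], G9$dosages[, 6])^2, 0.01)

  # empirical AF within 3 binomial se for nearly all variants
  afs2 <- matrix(runif(50, 0.1, 0.9), 50, 1, dimnames = list(NULL, "EA"))
  G2 <- simulate_genotypes(afs2, ld0, c(EA = 2000), seed = 4,
                           variant_index = make_variant_index(50, ld0,
                                                              afs = afs2,
                                                              seed = 9))
  emp <- colMeans(G2$dosages) / 2
  se <- sqrt(afs2[, 1] * (1 - afs2[, 1]) / (2 * 2000))
  expect_gte(mean(abs(emp - afs2[, 1]) < 3 * se), 0.95)

  expect_identical(simulate_genotypes(afs5, ld9, c(EA = 50), seed = 8)$dosages,
                   simulate_genotypes(afs5, ld9, c(EA = 50), seed = 8)$dosages)
})

test_that("true effects respect correlation, heritability and the APOE proxy", {
  am <- ancestry_model(c("EA", "AA"), fst = c(0.02, 0.1))
  ld <- ld_block_spec()
  afs <- drift_frequencies(draw_ancestral_frequencies(2000, am, seed = 1),
                           am, seed = 2)
  vi <- make_variant_index(2000, ld, afs = afs, seed = 3)

  B1 <- draw_true_effects(vi, effect_model(cross_ancestry_corr = 1), seed = 4)
  expect_equal(B1[, "EA"], B1[, "AA"], tolerance = 1e-12,
               ignore_attr = TRUE)

  Bh <- draw_true_effects(vi, effect_model(n_causal_fraction = 1, h2 = 0.3,
                                           cross_ancestry_corr = 0.5),
                          seed = 5)
  cc <- attr(Bh, "causal")
  expect_lt(abs(cor(Bh[cc, "EA"], Bh[cc, "AA"]) - 0.5), 0.05)
  # realized liability genetic variance of the polygenic background ~ h2
  # (common scale across groups; the APOE proxy sits on top of it)
  vg <- sapply(c("EA", "AA"), function(a)
    sum(Bh[cc, a]^2 * 2 * vi[[paste0("af_", a)]][cc] *
          (1 - vi[[paste0("af_", a)]][cc])))
  expect_equal(mean(vg), 0.3, tolerance = 1e-10)

  B0 <- draw_true_effects(vi, effect_model(h2 = 0, apoe_like_effect = 0.4),
                          seed = 6)
  apoe <- attr(B0, "apoe_index")
  expect_true(all(B0[-apoe, ] == 0))
  expect_true(all(B0[apoe, ] == 0.4))
})

test_that("liability phenotypes hit the prevalence and the null is null", {
  w <- small_cohort(n = 20000, m = 60, seed = 21, h2 = 0.3, prevalence = 0.1)
  frac <- mean(w$phen$ad_status)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 20000))

  # null architecture: no mean genetic-score difference between cases/controls
  am <- ancestry_model("EA", fst = 0.02)
  ld <- ld_block_spec()
  afs <- drift_frequencies(draw_ancestral_frequencies(100, am, seed = 1),
                           am, seed = 2)
  vi <- make_variant_index(100, ld, afs = afs, seed = 3)
  G <- simulate_genotypes(afs, ld, c(EA = 8000), seed = 4, variant_index = vi)
  B <- draw_true_effects(vi, effect_model(h2 = 0, apoe_like_effect = 0),
                         seed = 5)
  phen <- simulate_phenotypes(G, B,
                              liability_model(prevalence = 0.2,
                                              age_effect = 0, sex_effect = 0,
                                              e2_effect = 0), seed = 6)
  gs <- as.numeric(G$dosages %*% rnorm(100))  # arbitrary score: independent
  z <- (mean(gs[phen$ad_status == 1]) - mean(gs[phen$ad_status == 0])) /
    sqrt(var(gs) * (1 / sum(phen$ad_status) + 1 / sum(1 - phen$ad_status)))
  expect_lt(abs(z), 3)

  # doubling the APOE-like effect increases the case/control dosage gap
  gap <- function(beta, seed) {
    diffs <- sapply(seq_len(10), function(r) {
      Bx <- draw_true_effects(vi, effect_model(h2 = 0.1,
                                               apoe_like_effect = beta),
                              seed = seed + r)
      ph <- simulate_phenotypes(G, Bx, liability_model(prevalence = 0.2),
                                seed = 100 + r)
      d <- G$dosages[, attr(Bx, "apoe_index")]
      mean(d[ph$ad_status == 1]) - mean(d[ph$ad_status == 0])
    })
    mean(diffs)
  }
  expect_gt(gap(0.6, seed = 40), gap(0.3, seed = 40))
})

test_that("epsilon4/epsilon2 counts are jointly consistent", {
  w <- small_cohort(n = 2000, m = 40, seed = 33)
  expect_true(all(w$phen$apoe_e4_count + w$phen$apoe_e2_count <= 2))
  expect_true(all(w$phen$age >= 60 & w$phen$age <= 95))
})

test_that("regression and analytic summary statistics agree and are calibrated", {
  # type-I error at null variants
  am <- ancestry_model("EA", fst = 0.02)
  ld <- ld_block_spec(block_size = 5, rho = 0, spacing_bp = 1000)
  afs <- drift_frequencies(draw_ancestral_frequencies(1000, am, seed = 1),
                           am, seed = 2)
  vi <- make_variant_index(1000, ld, afs = afs, apoe_like = FALSE, seed = 3)
  G <- simulate_genotypes(afs, ld, c(EA = 2000), seed = 4, variant_index = vi)
  B <- matrix(0, 1000, 1, dimnames = list(vi$id, "EA"))
  phen <- simulate_phenotypes(G, B, liability_model(prevalence = 0.3),
                              seed = 5)
  ss <- simulate_sumstats(G, phen, mode = "regression", seed = 6)
  frac <- mean(ss$p < 0.05, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))

  # analytic mode, vanishing noise: beta equals the mapped marginal effect
  w <- small_cohort(n = 3000, m = 100, seed = 51, h2 = 0.4, prevalence = 0.25)
  ss_inf <- simulate_sumstats(w$G, mode = "analytic", seed = 7,
                              effects = w$effects[, "EA"],
                              n_effective = 1e14, prevalence = 0.25)
  D <- sweep(w$G$dosages, 2, colMeans(w$G$dosages))
  marg <- as.numeric(crossprod(D, D %*% w$effects[, "EA"])) / nrow(D) /
    colMeans(D^2)
  expect_equal(ss_inf$beta, unname(liability_logistic_slope(0.25) * marg),
               tolerance = 1e-4)

  # cross-mode concordance on causal variants at n = 20000; effects kept
  # modest (polygenic regime) where the first-order liability-to-logistic
  # mapping is accurate
  big <- small_cohort(n = 20000, m = 200, seed = 61, h2 = 0.3,
                      prevalence = 0.25)
  ss_r <- simulate_sumstats(big$G, big$phen, mode = "regression", seed = 8)
  ss_a <- simulate_sumstats(big$G, mode = "analytic", seed = 9,
                            effects = big$effects[, "EA"],
                            n_effective = 20000, prevalence = 0.25)
  cc <- attr(big$effects, "causal")
  agree <- abs(ss_r$beta[cc] - ss_a$beta[cc]) <
    2 * sqrt(ss_r$se[cc]^2 + ss_a$se[cc]^2)
  expect_gte(mean(agree, na.rm = TRUE), 0.9)
})

test_that("sibling pairs obey Mendelian constraints and kinship bookkeeping", {
  afs <- matrix(0.5, 1e4, 1, dimnames = list(NULL, "EA"))
  ld <- ld_block_spec(block_size = 1, rho = 0, spacing_bp = 100)
  vi <- make_variant_index(1e4, ld, afs = afs, apoe_like = FALSE, seed = 2)
  G <- simulate_genotypes(afs, ld, c(EA = 20), seed = 1, variant_index = vi)
  rel <- simulate_related_pairs(G, n_pairs = 2, seed = 3)

  # both parents 0 at a variant -> both sibs 0 there
  zero <- G$dosages[1, ] == 0 & G$dosages[2, ] == 0
  expect_true(all(rel$offspring$dosages[c(1, 3), zero] == 0))

  # sib-sib dosage correlation across variants ~ 0.5 (constant AF design)
  r <- cor(rel$offspring$dosages[1, ], rel$offspring$dosages[3, ])
  expect_lt(abs(r - 0.5), 0.05)

  kin <- rel$kinship
  expect_true(all(kin$kinship == 0.25))
  sib <- kin[grepl("^sibA", kin$id1) & grepl("^sibB", kin$id2), ]
  expect_equal(nrow(sib), 2)
})
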