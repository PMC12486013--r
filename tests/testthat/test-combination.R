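# Build a source PRS matrix directly from standardized columns.
mk_M <- function(M, labels = colnames(M)) {
  structure(list(sample_ids = sprintf("i%04d", seq_len(nrow(M))),
                 M = `colnames<-`(M, labels),
                 scalings = setNames(lapply(labels, function(l)
                   scaling_reference(0, 1, "unit")), labels),
                 labels = labels),
            class = "source_prs_matrix")
}

mk_phen <- function(y, n = length(y)) {
  phen <- data.frame(sample_id = sprintf("i%04d", seq_len(n)), ancestry = "EA",
                     ad_status = y, age = rnorm(n, 75, 5),
                     sex = rbinom(n, 1, 0.5), apoe_e4_count = 0L,
                     apoe_e2_count = 0L, cohort_label = "train")
  for (p in paste0("PC", 1:10)) phen[[p]] <- rnorm(n, 0, 0.1)
  phen
}

test_that("summation weights recover an informative/null source split", {
  set.seed(1)
  n <- 12000
  P <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("info", "null")))
  liab <- 0.8 * scale(P[, 1]) + rnorm(n, 0, sqrt(1 - 0.64))
  y <- as.integer(liab > qnorm(0.7))
  M <- mk_M(scale(P), labels = c("info", "null"))
  phen <- mk_phen(y)
  mod_m <- train_combination_weights(M, phen, fit_mode = "marginal")
  mod_j <- train_combination_weights(M, phen, fit_mode = "joint")
  for (mod in list(mod_m, mod_j)) {
    expect_gt(mod$weights["info"] / mod$weight_se["info"], 5)
    expect_lt(abs(mod$weights["null"]), 2 * mod$weight_se["null"])
  }
  expect_equal(mod_m$fit_metadata$fit_mode, "marginal")

  # permuted phenotype: both weights consistent with zero in most replicates
  nulls <- 0L
  for (r in 1:10) {
    set.seed(700 + r)
    yp <- sample(y)
    modp <- train_combination_weights(M, mk_phen(yp), fit_mode = "marginal")
    nulls <- nulls + all(abs(modp$weights) < 3 * modp$weight_se)
  }
  expect_gte(nulls, 9)
})

test_that("duplicated sources are reported as collinear in joint mode", {
  set.seed(2)
  n <- 2000
  x <- rnorm(n)
  M <- mk_M(cbind(a = x, b = x + rnorm(n, 0, 1e-6)))
  y <- rbinom(n, 1, plogis(0.5 * x))
  expect_warning(mod <- train_combination_weights(M, mk_phen(y),
                                                  fit_mode = "joint"),
                 "collinear")
  expect_true(mod$fit_metadata$collinear_sources)
})

test_that("weighted and unweighted combination do the stated arithmetic", {
  set.seed(3)
  n <- 500
  M <- mk_M(matrix(rnorm(4 * n), n, 4,
                   dimnames = list(NULL, paste0("s", 1:4))))
  mod <- structure(list(source_labels = M$labels,
                        weights = setNames(c(1, 0, 0, 0), M$labels),
                        weight_se = setNames(rep(0.1, 4), M$labels),
                        per_source_scaling = M$scalings,
                        final_scaling = scaling_reference(0, 1, "unit"),
                        fit_metadata = list()),
                   class = "combination_model")
  expect_equal(combine_weighted(M, mod)$score, M$M[, 1], ignore_attr = TRUE)

  mod$weights[] <- 0.7
  wsum <- combine_weighted(M, mod, standardize = FALSE)
  expect_equal(wsum$score, as.numeric(M$M %*% rep(0.7, 4)), tolerance = 1e-12)
  usum <- combine_unweighted(M)
  expect_equal(cor(wsum$score, usum$score), 1, tolerance = 1e-12)

  # random weights match independent hand computation
  set.seed(4)
  mod$weights[] <- rnorm(4)
  hand <- as.numeric(M$M %*% mod$weights)
  expect_equal(combine_weighted(M, mod, standardize = FALSE)$score, hand,
               tolerance = 1e-12)

  # label mismatch is a hard error
  M2 <- mk_M(M$M, labels = paste0("x", 1:4))
  expect_error(combine_weighted(M2, mod), "labels")

  # degenerate sum x + (-x) surfaces the sd = 0 error
  M3 <- mk_M(cbind(a = M$M[, 1], b = -M$M[, 1]))
  expect_error(combine_unweighted(M3), "sd|constant")

  # single source: unweighted sum is the source up to standardization
  M4 <- mk_M(M$M[, 1, drop = FALSE], labels = "only")
  u4 <- combine_unweighted(M4)
  expect_equal(cor(u4$score, M$M[, 1]), 1, tolerance = 1e-12)
})

test_that("collapsed variant weights reproduce the weighted combination", {
  # single source, unit weight and sd: collapsed table equals the source
  G <- tiny_gm(random_dosages(50, 12, seed = 5))
  set.seed(6)
  t1 <- wt_for(G, rnorm(6), rows = 1:6)
  mod1 <- structure(list(source_labels = "a",
                         weights = c(a = 1), weight_se = c(a = 0.1),
                         per_source_scaling = list(a = scaling_reference(0, 1)),
                         final_scaling = NULL, fit_metadata = list()),
                    class = "combination_model")
  col1 <- collapse_to_variant_weights(mod1, list(a = t1))
  expect_equal(col1$weight, t1$weight)
  expect_equal(col1$id, t1$id)

  # shared variant: weighted sum of per-source contributions
  t2 <- wt_for(G, c(0.3, -0.1), rows = 6:7)   # variant 6 shared with t1
  mod2 <- structure(list(source_labels = c("a", "b"),
                         weights = c(a = 0.5, b = 2),
                         weight_se = c(a = 0.1, b = 0.1),
                         per_source_scaling = list(
                           a = scaling_reference(0, 2),
                           b = scaling_reference(0, 4)),
                         final_scaling = NULL, fit_metadata = list()),
                    class = "combination_model")
  col2 <- collapse_to_variant_weights(mod2, list(a = t1, b = t2))
  shared <- col2$weight[col2$id == G$variants$id[6]]
  expect_equal(shared, 0.5 * t1$weight[6] / 2 + 2 * 0.3 / 4)

  # random two-source instances: cohort scores correlate ~1 with the
  # weighted combination of standardized per-source scores
  for (r in 1:5) {
    set.seed(800 + r)
    Gx <- tiny_gm(random_dosages(200, 30, seed = 800 + r))
    ta <- wt_for(Gx, rnorm(20), rows = 1:20)
    tb <- wt_for(Gx, rnorm(20), rows = 11:30)
    tabs <- list(a = ta, b = tb)
    Mx <- build_source_prs_matrix(Gx, tabs)
    modx <- structure(list(source_labels = c("a", "b"),
                           weights = setNames(rnorm(2), c("a", "b")),
                           weight_se = setNames(c(0.1, 0.1), c("a", "b")),
                           per_source_scaling = Mx$scalings,
                           final_scaling = NULL, fit_metadata = list()),
                      class = "combination_model")
    wsum <- combine_weighted(Mx, modx, standardize = FALSE)
    colx <- collapse_to_variant_weights(modx, tabs)
    sc <- score_prs(Gx, colx)
    expect_gt(cor(sc$score, wsum$score), 0.999999)
  }
})

test_that("combination models survive a JSON round trip", {
  mod <- structure(list(source_labels = c("a", "b"),
                        weights = c(a = 0.12345678901234, b = -0.5),
                        weight_se = c(a = 0.01, b = 0.02),
                        per_source_scaling = list(
                          a = scaling_reference(0.1, 1.2, "eval"),
                          b = scaling_reference(-0.3, 0.8, "eval")),
                        final_scaling = scaling_reference(1.5, 2.5, "eval"),
                        fit_metadata = list(fit_mode = "marginal", n = 100)),
                   class = "combination_model")
  f <- tempfile(fileext = ".json")
  write_combination_model(mod, f)
  back <- read_combination_model(f)
  expect_equal(back$weights, mod$weights)
  expect_equal(back$per_source_scaling$a$sd, 1.2)
  expect_equal(back$final_scaling$mean, 1.5)
  expect_equal(back$fit_metadata$fit_mode, "marginal")
})
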