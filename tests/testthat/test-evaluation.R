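test_that("unrelated-set selection is independent and maximal", {
  ids <- sprintf("p%02d", 1:10)
  expect_equal(select_unrelated(ids, NULL), ids)
  empty <- data.frame(id1 = character(0), id2 = character(0),
                      kinship = numeric(0))
  expect_equal(select_unrelated(ids, empty), ids)

  sib <- data.frame(id1 = "p01", id2 = "p02", kinship = 0.25)
  kept <- select_unrelated(ids, sib)
  expect_equal(length(kept), 9)
  expect_equal(sum(c("p01", "p02") %in% kept), 1)

  # random graphs checked by the exhaustive oracle
  for (r in 1:20) {
    set.seed(500 + r)
    n <- 30
    ids <- sprintf("s%02d", 1:n)
    npair <- sample(5:40, 1)
    kin <- data.frame(id1 = ids[sample(n, npair, replace = TRUE)],
                      id2 = ids[sample(n, npair, replace = TRUE)],
                      kinship = sample(c(0.01, 0.05, 0.125, 0.25), npair,
                                       replace = TRUE))
    kin <- kin[kin$id1 != kin$id2, ]
    kept <- select_unrelated(ids, kin, threshold = 0.04)
    expect_equal(oracle_check_unrelated(kept, ids, kin, 0.04), "ok")
  }
})

test_that("logistic association recovers simulated effects and matches optim", {
  set.seed(1)
  n <- 20000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.8 + 0.33 * x))  # OR per SD ~ 1.39
  fit <- fit_logistic_assoc(y, x, prs_standardized = FALSE)
  expect_lt(abs(fit$beta_per_sd - 0.33), 2 * fit$se)
  expect_true(fit$ci_low <= fit$or_per_sd && fit$or_per_sd <= fit$ci_high)

  # cross-check against a generic ML optimizer on a small instance
  set.seed(2)
  n2 <- 300
  x2 <- rnorm(n2); c2 <- rnorm(n2)
  y2 <- rbinom(n2, 1, plogis(-0.5 + 0.4 * x2 + 0.2 * c2))
  f2 <- fit_logistic_assoc(y2, x2, covariates = data.frame(c = c2),
                           prs_standardized = TRUE)
  X <- cbind(1, x2, c2)
  o <- optim(c(0, 0, 0), logistic_negll, X = X, y = y2, method = "BFGS",
             control = list(reltol = 1e-14))
  expect_equal(f2$beta_per_sd, o$par[2], tolerance = 1e-5)

  expect_error(fit_logistic_assoc(y2, rep(1, n2)), "variance")
  expect_error(fit_logistic_assoc(rep(1, 10), rnorm(10)), "both classes")
  # complete separation is refused
  ysep <- as.integer(x2 > 0)
  expect_error(fit_logistic_assoc(ysep, x2, prs_standardized = TRUE),
               "separation|converge")
})

test_that("linear association matches the normal equations", {
  set.seed(3)
  n <- 200
  x <- as.numeric(scale(rnorm(n)))
  y <- 2 * x + rnorm(n, 0, 1e-8)
  f <- fit_linear_assoc(y, x)
  expect_equal(f$estimate, 2, tolerance = 1e-6)
  expect_lt(f$p, 1e-100)

  y2 <- rnorm(n); c2 <- rnorm(n)
  f2 <- fit_linear_assoc(y2, x, covariates = data.frame(c = c2))
  X <- cbind(1, x, c2)
  beta_hat <- solve(crossprod(X), crossprod(X, y2))
  expect_equal(f2$estimate, beta_hat[2], tolerance = 1e-10)

  expect_error(fit_linear_assoc(rep(1, n), x), "constant")
})

test_that("AUC equals exhaustive pair enumeration and handles edge cases", {
  expect_equal(compute_auc(c(2, 3, 0, 1), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(4)
  for (r in 1:20) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # with ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(compute_auc(scores, y), oracle_auc(scores, y),
                 tolerance = 1e-12)
  }
  expect_error(compute_auc(1:5, rep(1, 5)), "classes")

  # unrelated_only filters through select_unrelated
  ids <- c("a", "b", "c", "d")
  kin <- data.frame(id1 = "a", id2 = "b", kinship = 0.25)
  auc <- compute_auc(c(10, 20, 5, 1), c(1, 1, 0, 0), unrelated_only = TRUE,
                     kin = kin, sample_ids = ids)
  expect_equal(auc, 1.0)  # whichever sib is kept beats both controls
})

test_that("AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- rnorm(200)
  y <- rbinom(200, 1, plogis(scores))
  expect_equal(compute_auc(scores, y),
               as.numeric(suppressMessages(pROC::auc(y, scores))),
               tolerance = 1e-12)
})

test_that("stratified analyses drop the axis covariate and skip degenerate strata", {
  w <- small_cohort(n = 3000, m = 60, seed = 41, h2 = 0.5)
  prs <- score_prs(w$G, wt_for(w$G, w$effects[, "EA"]))
  prs <- standardize(prs, fit_reference_stats(prs))

  res <- stratify_assoc(prs, w$phen, axis = "sex")
  expect_equal(sort(res$stratum_label), c("sex=0", "sex=1"))
  expect_false(any(grepl("sex", res$covariates_used)))

  # two identical strata give identical results
  phen2 <- rbind(w$phen, w$phen)
  phen2$sex <- rep(c(0, 1), each = nrow(w$phen))
  phen2$sample_id <- make.unique(phen2$sample_id)
  prs2 <- rbind(prs, prs)
  prs2$sample_id <- phen2$sample_id
  attr(prs2, "provenance") <- attr(prs, "provenance")
  res2 <- stratify_assoc(prs2, phen2, axis = "sex")
  expect_equal(res2$beta_per_sd[1], res2$beta_per_sd[2], tolerance = 1e-10)
  expect_equal(res2$auc[1], res2$auc[2], tolerance = 1e-12)

  # a cases-only stratum is skipped with a reason
  phen3 <- w$phen
  phen3$ad_status[phen3$sex == 1] <- 1
  res3 <- stratify_assoc(prs, phen3, axis = "sex")
  expect_equal(nrow(res3), 1)
  expect_match(attr(res3, "skipped"), "sex=1")

  # apoe strata pool the epsilon2 genotypes
  res4 <- stratify_assoc(prs, w$phen, axis = "apoe_genotype")
  expect_true(all(res4$stratum_label %in%
                    c("e2/e2+e2/e3", "e2/e4", "e3/e3", "e3/e4", "e4/e4")))
})

test_that("a PRS x stratum interaction shows up as a larger stratum OR", {
  wins <- 0L
  for (r in 1:10) {
    set.seed(600 + r)
    n <- 2000
    x <- rnorm(n)
    grp <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x * grp))  # effect only in group 1
    phen <- data.frame(sample_id = sprintf("i%04d", 1:n), ancestry = "EA",
                       ad_status = y, age = rnorm(n, 75, 5), sex = grp,
                       apoe_e4_count = 0L, apoe_e2_count = 0L,
                       cohort_label = "c")
    for (p in paste0("PC", 1:10)) phen[[p]] <- rnorm(n, 0, 0.1)
    prs <- structure(data.frame(sample_id = phen$sample_id, score = x,
                                n_variants_used = 1L),
                     class = c("prs_vector", "data.frame"))
    res <- stratify_assoc(prs, phen, axis = "sex")
    o1 <- res$or_per_sd[res$stratum_label == "sex=1"]
    o0 <- res$or_per_sd[res$stratum_label == "sex=0"]
    wins <- wins + (length(o1) == 1 && length(o0) == 1 && o1 > o0)
  }
  expect_gte(wins, 9)
})

test_that("model ranking follows AUC, then OR, then p", {
  r1 <- data.frame(model_label = "a", stratum_label = "all", n_cases = 10,
                   n_controls = 10, beta_per_sd = log(1.3), se = 0.1,
                   or_per_sd = 1.3, ci_low = 1, ci_high = 2, p = 0.01,
                   auc = 0.7, covariates_used = "")
  expect_equal(attr(rank_models(r1), "selected"), "a")

  r2 <- r1; r2$model_label <- "b"; r2$or_per_sd <- 1.5
  both <- rbind(r1, r2)
  ranked <- rank_models(both)
  expect_equal(ranked$model_label, c("b", "a"))  # equal AUC, larger OR first

  r3 <- r1; r3$model_label <- "c"; r3$auc <- 0.75; r3$or_per_sd <- 1.1
  ranked3 <- rank_models(rbind(both, r3))
  expect_equal(ranked3$model_label[1], "c")  # AUC dominates
})
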