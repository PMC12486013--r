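#' Select a maximal unrelated sample subset
#'
#' Greedy removal on the relatedness graph: while any pair with kinship at
#' or above `threshold` remains, the individual with the most related
#' partners is dropped (ties broken by sample id).  Dropped individuals
#' with no retained partner are re-added, so the result is maximal: no pair
#' at/above threshold remains and no dropped individual can be restored.
#'
#' @param samples character vector of sample ids.
#' @param kin kinship table (`id1`, `id2`, `kinship`); absent pairs mean 0.
#'   `NULL` means everyone is unrelated.
#' @param threshold kinship cutoff; pairs `>= threshold` are related
#'   (default 0.04, approximately third-degree relatives).
#' @return Character vector of retained sample ids (original order).
#' @export
select_unrelated <- function(samples, kin = NULL, threshold = 0.04) {
  if (threshold <= 0) stop("threshold must be positive")
  if (is.null(kin) || nrow(kin) == 0) return(samples)
  e <- kin[kin$kinship >= threshold &
             kin$id1 %in% samples & kin$id2 %in% samples, , drop = FALSE]
  e <- e[e$id1 != e$id2, , drop = FALSE]
  if (nrow(e) == 0) return(samples)
  retained <- samples
  dropped <- character(0)
  repeat {
    act <- e[e$id1 %in% retained & e$id2 %in% retained, , drop = FALSE]
    if (nrow(act) == 0) break
    deg <- table(c(act$id1, act$id2))
    worst <- names(deg)[deg == max(deg)]
    victim <- sort(worst)[1]
    retained <- setdiff(retained, victim)
    dropped <- c(dropped, victim)
  }
  ## maximality pass: re-add dropped individuals with no retained partner
  for (d in sort(dropped)) {
    partners <- c(e$id2[e$id1 == d], e$id1[e$id2 == d])
    if (!any(partners %in% retained)) retained <- c(retained, d)
  }
  samples[samples %in% retained]
}

eval_result_row <- function(model_label, stratum_label, n_cases, n_controls,
                            beta, se, p, auc = NA_real_, covariates_used = "") {
  data.frame(model_label = model_label, stratum_label = stratum_label,
             n_cases = n_cases, n_controls = n_controls,
             beta_per_sd = beta, se = se, or_per_sd = exp(beta),
             ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
             p = p, auc = auc, covariates_used = covariates_used,
             stringsAsFactors = FALSE)
}

#' Logistic association of a binary outcome with a PRS
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()],
#' `epsilon = 1e-8`, up to 100 iterations) of the outcome on the PRS plus
#' covariates.  The PRS is standardized internally (and noted) when its SD
#' differs from 1, so the reported effect is per 1 SD; Wald 95% CI
#' `exp(beta +/- 1.96 se)` and two-sided Wald p.  Non-convergence or
#' (quasi-)separation is a hard error.
#'
#' @param outcome binary vector (0/1) with both classes present.
#' @param prs a `prs_vector` or numeric vector.
#' @param covariates data.frame of covariates (factors allowed), or `NULL`.
#' @param model_label,stratum_label labels for the result row.
#' @param prs_standardized is the PRS already on a reference SD scale?
#'   Default `NULL` auto-detects: a `prs_vector` whose provenance records a
#'   scaling reference is taken as standardized (so a frozen external
#'   scaling is honoured); anything else is standardized internally to the
#'   local cohort and noted.
#' @return One-row `EvalResult` data.frame (auc `NA`); fitted case
#'   probabilities in attribute `fitted`.
#' @export
fit_logistic_assoc <- function(outcome, prs, covariates = NULL,
                               model_label = "model", stratum_label = "all",
                               prs_standardized = NULL) {
  x <- if (is.data.frame(prs)) prs$score else as.numeric(prs)
  if (length(unique(outcome)) < 2) stop("outcome must have both classes")
  sdx <- sd(x)
  if (!is.finite(sdx) || sdx == 0) stop("PRS has no variance")
  if (is.null(prs_standardized)) {
    prov <- attr(prs, "provenance")
    prs_standardized <- !is.null(prov$scaling) &&
      !identical(prov$scaling, "raw")
  }
  standardized_internally <- !prs_standardized
  z <- if (standardized_internally) (x - mean(x)) / sdx else x
  dat <- data.frame(y = outcome, prs = z)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covariates <- covariates[, vapply(covariates,
                                      function(v) length(unique(v)) > 1, TRUE),
                             drop = FALSE]
    if (ncol(covariates)) dat <- cbind(dat, covariates)
  }
  fit <- suppressWarnings(glm(y ~ ., data = dat, family = binomial(),
                              control = glm.control(epsilon = 1e-8,
                                                    maxit = 100)))
  if (!fit$converged) stop("logistic fit did not converge")
  sm <- summary(fit)$coefficients
  if (!"prs" %in% rownames(sm)) stop("PRS dropped from design (aliased)")
  b <- sm["prs", 1]; s <- sm["prs", 2]
  eta <- abs(predict(fit, type = "link"))
  if (s > 50 || max(eta) > 30)
    stop("possible separation in logistic fit (|eta| max = ",
         round(max(eta), 1), ", se = ", signif(s, 3), ")")
  res <- eval_result_row(model_label, stratum_label,
                         n_cases = sum(outcome == 1),
                         n_controls = sum(outcome == 0),
                         beta = b, se = s, p = wald_p(b, s),
                         covariates_used = paste(setdiff(names(dat),
                                                         c("y", "prs")),
                                                 collapse = ","))
  attr(res, "fitted") <- unname(fitted(fit))
  attr(res, "standardized_internally") <- standardized_internally
  res
}

#' Linear association of a continuous outcome with a PRS
#'
#' Ordinary least squares of the outcome on the PRS (standardized
#' internally as in [fit_logistic_assoc()]) plus covariates; t-based CI and
#' p for the per-SD effect.  A rank-deficient design that drops the PRS is
#' an error.
#'
#' @inheritParams fit_logistic_assoc
#' @param outcome continuous vector.
#' @return One-row data.frame: `estimate`, `se`, `ci_low`, `ci_high`, `p`.
#' @export
fit_linear_assoc <- function(outcome, prs, covariates = NULL,
                             model_label = "model", stratum_label = "all") {
  x <- if (is.data.frame(prs)) prs$score else as.numeric(prs)
  if (sd(outcome) == 0) stop("outcome is constant")
  sdx <- sd(x)
  if (!is.finite(sdx) || sdx == 0) stop("PRS has no variance")
  z <- (x - mean(x)) / sdx
  dat <- data.frame(y = outcome, prs = z)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  fit <- lm(y ~ ., data = dat)
  sm <- summary(fit)$coefficients
  if (!"prs" %in% rownames(sm) || anyNA(coef(fit)["prs"]))
    stop("rank-deficient design: PRS aliased")
  b <- sm["prs", 1]; s <- sm["prs", 2]
  df <- fit$df.residual
  tq <- qt(0.975, df)
  data.frame(model_label = model_label, stratum_label = stratum_label,
             n = nrow(dat), estimate = b, se = s,
             ci_low = b - tq * s, ci_high = b + tq * s,
             p = 2 * pt(-abs(b / s), df), stringsAsFactors = FALSE)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' `AUC = P(score_case > score_control) + 0.5 P(tie)`, computed from
#' midranks.  With `unrelated_only = TRUE` the samples are first reduced to
#' an unrelated subset via [select_unrelated()].
#'
#' @param scores numeric scores (fitted probabilities or raw PRS).
#' @param outcome binary vector (0/1).
#' @param unrelated_only restrict to unrelated individuals first?
#' @param kin kinship table (needed when `unrelated_only`).
#' @param sample_ids sample ids aligned with `scores` (needed when
#'   `unrelated_only`).
#' @return Scalar AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, outcome, unrelated_only = FALSE, kin = NULL,
                        sample_ids = NULL) {
  if (unrelated_only) {
    if (is.null(sample_ids)) stop("sample_ids needed for unrelated_only")
    keep <- sample_ids %in% select_unrelated(sample_ids, kin)
    scores <- scores[keep]; outcome <- outcome[keep]
  }
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes required for AUC")
  r <- rank(scores)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate one PRS model: association plus AUC on unrelated samples
#'
#' Convenience wrapper fitting [fit_logistic_assoc()] on the unrelated
#' subset and filling the `auc` column from the fitted model
#' probabilities.
#'
#' @param prs a `prs_vector`.
#' @param phen phenotype table with `sample_id`, `ad_status` and covariate
#'   columns.
#' @param kin kinship table or `NULL`.
#' @param covariates covariate column names (non-constant subset used).
#' @param model_label,stratum_label labels.
#' @param kin_threshold relatedness cutoff.
#' @return One-row `EvalResult` data.frame with AUC.
#' @export
evaluate_model <- function(prs, phen, kin = NULL,
                           covariates = c("age", "sex", "ancestry",
                                          paste0("PC", 1:10),
                                          "apoe_e4_count", "apoe_e2_count"),
                           model_label = "model", stratum_label = "all",
                           kin_threshold = 0.04) {
  unrel <- select_unrelated(phen$sample_id, kin, threshold = kin_threshold)
  keep <- phen$sample_id %in% unrel
  phen <- phen[keep, , drop = FALSE]
  stopifnot(identical(prs$sample_id[keep], phen$sample_id))
  covariates <- intersect(covariates, names(phen))
  covs <- phen[, covariates, drop = FALSE]
  for (nm in intersect(c("ancestry", "cohort_label"), names(covs)))
    covs[[nm]] <- factor(covs[[nm]])
  prov <- attr(prs, "provenance")
  res <- fit_logistic_assoc(phen$ad_status, prs$score[keep], covs,
                            model_label = model_label,
                            stratum_label = stratum_label,
                            prs_standardized = !is.null(prov$scaling) &&
                              !identical(prov$scaling, "raw"))
  res$auc <- compute_auc(attr(res, "fitted"), phen$ad_status)
  res
}

#' APOE genotype label from allele counts
#'
#' @param e4,e2 epsilon4 and epsilon2 allele counts in \{0, 1, 2\}.
#' @return Character vector of genotype labels (e.g. "e3/e4").
#' @export
apoe_genotype_of <- function(e4, e2) {
  out <- rep("e3/e3", length(e4))
  out[e2 == 2] <- "e2/e2"
  out[e2 == 1 & e4 == 0] <- "e2/e3"
  out[e2 == 1 & e4 == 1] <- "e2/e4"
  out[e2 == 0 & e4 == 1] <- "e3/e4"
  out[e2 == 0 & e4 == 2] <- "e4/e4"
  out
}

#' Stratified association analyses
#'
#' Runs [evaluate_model()] within strata defined by sex, APOE genotype
#' (with the sparse epsilon2 genotypes pooled as "e2/e2+e2/e3"), or
#' ancestry.  The stratification covariate is removed from the stratum
#' models; strata missing an outcome class are skipped with a logged
#' reason.
#'
#' @param prs a `prs_vector` aligned with `phen`.
#' @param phen phenotype table.
#' @param axis `"sex"`, `"apoe_genotype"` or `"ancestry"`.
#' @param kin kinship table or `NULL`.
#' @param covariates base covariate set (axis columns are removed).
#' @param model_label model name for the result rows.
#' @return data.frame of `EvalResult` rows; skipped strata in attribute
#'   `skipped`.
#' @export
stratify_assoc <- function(prs, phen, axis = c("sex", "apoe_genotype",
                                               "ancestry"),
                           kin = NULL,
                           covariates = c("age", "sex", "ancestry",
                                          paste0("PC", 1:10),
                                          "apoe_e4_count", "apoe_e2_count"),
                           model_label = "model") {
  axis <- match.arg(axis)
  groups <- switch(axis,
    sex = paste0("sex=", phen$sex),
    apoe_genotype = {
      g <- apoe_genotype_of(phen$apoe_e4_count, phen$apoe_e2_count)
      g[g %in% c("e2/e2", "e2/e3")] <- "e2/e2+e2/e3"
      g
    },
    ancestry = phen$ancestry)
  drop_cols <- switch(axis,
    sex = "sex",
    apoe_genotype = c("apoe_e4_count", "apoe_e2_count"),
    ancestry = "ancestry")
  covariates <- setdiff(covariates, drop_cols)
  out <- list(); skipped <- character(0)
  for (g in sort(unique(groups))) {
    i <- which(groups == g)
    if (length(unique(phen$ad_status[i])) < 2) {
      skipped <- c(skipped, sprintf("%s: single outcome class", g))
      next
    }
    prs_i <- prs[i, , drop = FALSE]
    attr(prs_i, "provenance") <- attr(prs, "provenance")
    row <- tryCatch(
      evaluate_model(prs_i, phen[i, , drop = FALSE],
                     kin = kin, covariates = covariates,
                     model_label = model_label, stratum_label = g),
      error = function(e) {
        skipped <<- c(skipped, sprintf("%s: %s", g, conditionMessage(e)))
        NULL
      })
    if (!is.null(row)) out[[length(out) + 1L]] <- row
  }
  res <- if (length(out)) do.call(rbind, out) else eval_result_row(
    character(0), character(0), integer(0), integer(0), numeric(0),
    numeric(0), numeric(0))[0, ]
  structure(res, skipped = skipped)
}

#' Rank evaluated models and pick the best
#'
#' Default composite rule: AUC (descending), then OR per SD (descending),
#' then p (ascending), final ties by model label.  The full ordering is
#' returned with the rule recorded.
#'
#' @param results data.frame of `EvalResult` rows (same outcome/cohort).
#' @param rule character vector naming the ranking keys in order; only the
#'   default `c("auc", "or_per_sd", "p")` composite is implemented.
#' @return `results` reordered with a `rank` column; the selected model
#'   label in attribute `selected`.
#' @export
rank_models <- function(results, rule = c("auc", "or_per_sd", "p")) {
  if (!nrow(results)) stop("no results to rank")
  ord <- order(-results$auc, -results$or_per_sd, results$p,
               results$model_label)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, selected = out$model_label[1], rule = rule)
}
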