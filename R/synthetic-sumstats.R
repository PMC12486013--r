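## Fast logistic fit via glm.fit; returns beta and Wald se for one column.
logistic_beta_se <- function(X, y, col = 2L) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  if (!fit$converged) return(c(NA_real_, NA_real_))
  W <- fit$weights
  XtWX <- crossprod(X * sqrt(W))
  cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(cov)) return(c(NA_real_, NA_real_))
  c(fit$coefficients[col], sqrt(diag(cov))[col])
}

#' Slope of the liability-to-observed logistic mapping
#'
#' First-order factor converting a small liability-scale effect into the
#' marginal log-odds effect of a logistic regression on the thresholded
#' outcome: `dnorm(qnorm(1 - prevalence)) / (prevalence (1 - prevalence))`.
#'
#' @param prevalence case probability.
#' @return Scalar conversion factor.
#' @export
liability_logistic_slope <- function(prevalence) {
  dnorm(qnorm(1 - prevalence)) / (prevalence * (1 - prevalence))
}

#' Simulate GWAS summary statistics for one study
#'
#' `"regression"` mode fits a per-variant logistic regression of case status
#' on dosage, standardized age and sex, reporting the Wald beta/se/p.
#' `"analytic"` mode emulates a large-`n` GWAS without individual-level
#' fitting: the LD-aware true marginal liability effect is estimated from
#' the supplied genotypes, mapped to the logistic scale via
#' [liability_logistic_slope()], and observed with noise
#' `se = 1 / sqrt(n_effective * 2 af (1 - af) * v)` where `v` defaults to
#' `prevalence (1 - prevalence)`.  Analytic mode ignores LD-induced
#' correlation between the marginal estimates themselves; downstream
#' clumping de-correlates the retained variants.
#'
#' @param G a single-ancestry [genotype_matrix()].
#' @param phen phenotype table from [simulate_phenotypes()] (regression
#'   mode).
#' @param mode `"regression"` or `"analytic"`.
#' @param seed integer seed (optional).
#' @param effects liability effect vector for this ancestry (analytic mode).
#' @param n_effective stated GWAS sample size (analytic mode).
#' @param prevalence case probability of the emulated GWAS (analytic mode).
#' @param var_factor variance factor `v`; default `prevalence (1 -
#'   prevalence)`.
#' @param study_label,ancestry_label provenance labels.
#' @return A summary-statistics data.frame (see [read_sumstats()]) with
#'   attributes `study_label` and `ancestry_label`; monomorphic variants get
#'   `NA` beta/se and are flagged in attribute `monomorphic`.
#' @export
simulate_sumstats <- function(G, phen = NULL,
                              mode = c("regression", "analytic"),
                              seed = NULL, effects = NULL,
                              n_effective = NULL, prevalence = NULL,
                              var_factor = NULL,
                              study_label = "study", ancestry_label = NULL) {
  mode <- match.arg(mode)
  if (length(unique(G$samples$ancestry)) != 1L)
    stop("simulate_sumstats expects a single-ancestry cohort per call")
  ancestry_label <- ancestry_label %||% G$samples$ancestry[1]
  set_seed_if(seed)
  D <- G$dosages
  m <- ncol(D)
  af <- colMeans(D, na.rm = TRUE) / 2
  mono <- !is.finite(af) | af <= 0 | af >= 1
  ss <- G$variants[, c("chrom", "pos", "id", "effect_allele", "other_allele")]
  if (mode == "regression") {
    if (is.null(phen)) stop("regression mode needs phenotypes")
    y <- phen$ad_status
    z_age <- as.numeric(scale(phen$age))
    sex <- phen$sex
    beta <- se <- rep(NA_real_, m)
    nv <- integer(m)
    for (j in seq_len(m)) {
      if (mono[j]) { nv[j] <- sum(!is.na(D[, j])); next }
      d <- D[, j]
      ok <- !is.na(d)
      nv[j] <- sum(ok)
      X <- cbind(1, d[ok], z_age[ok], sex[ok])
      bs <- logistic_beta_se(X, y[ok])
      beta[j] <- bs[1]; se[j] <- bs[2]
    }
    ss$beta <- beta; ss$se <- se
    ss$p <- wald_p(beta, se)
    ss$n <- nv
    ss$af <- af
  } else {
    if (is.null(effects) || is.null(n_effective) || is.null(prevalence))
      stop("analytic mode needs effects, n_effective and prevalence")
    v <- var_factor %||% (prevalence * (1 - prevalence))
    Xc <- sweep(D, 2, colMeans(D))
    vj <- colMeans(Xc^2)
    marg <- as.numeric(crossprod(Xc, Xc %*% effects)) / nrow(D) / vj
    marg[mono | vj == 0] <- NA_real_
    cfac <- liability_logistic_slope(prevalence)
    se <- 1 / sqrt(n_effective * 2 * af * (1 - af) * v)
    se[mono] <- NA_real_
    beta <- cfac * marg + rnorm(m) * se
    ss$beta <- beta; ss$se <- se
    ss$p <- wald_p(beta, se)
    ss$n <- as.numeric(n_effective)
    ss$af <- af
  }
  rownames(ss) <- NULL
  structure(ss, study_label = study_label, ancestry_label = ancestry_label,
            monomorphic = ss$id[mono])
}
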