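#' Draw per-ancestry true liability effects
#'
#' A causal set common to all ancestries is drawn; causal effects are
#' multivariate normal across ancestries with equicorrelation
#' `cross_ancestry_corr`, then rescaled per ancestry so the liability-scale
#' genetic variance `sum_j beta_j^2 2 p_j (1 - p_j)` equals `h2` (the
#' designated APOE-like variant is excluded from the rescaling and receives
#' `apoe_like_effect` in every ancestry).
#'
#' @param variant_index variant index with `af_<ancestry>` columns.
#' @param model an [effect_model()].
#' @param seed integer seed (optional).
#' @return `m x K` matrix of liability effects, with attributes `causal`
#'   (logical vector) and `apoe_index` (column index of the APOE-like
#'   variant, or `NA`).
#' @export
draw_true_effects <- function(variant_index, model, seed = NULL) {
  set_seed_if(seed)
  af_cols <- grep("^af_", names(variant_index), value = TRUE)
  if (length(af_cols) == 0)
    stop("variant_index must carry af_<ancestry> columns")
  labels <- sub("^af_", "", af_cols)
  m <- nrow(variant_index)
  K <- length(labels)
  apoe_idx <- match("APOE_proxy", variant_index$id)
  eligible <- setdiff(seq_len(m), apoe_idx)
  n_causal <- max(1L, round(model$n_causal_fraction * length(eligible)))
  causal <- rep(FALSE, m)
  causal[sample(eligible, n_causal)] <- TRUE
  B <- matrix(0, m, K, dimnames = list(variant_index$id, labels))
  if (model$h2 > 0) {
    r <- model$cross_ancestry_corr
    Sigma <- matrix(r, K, K); diag(Sigma) <- 1
    ## eigen square root: robust to the singular r = 1 / r = -1 boundaries
    ev <- eigen(Sigma, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), K)
    raw <- matrix(rnorm(n_causal * K), n_causal, K) %*% t(L)
    B[causal, ] <- raw
    ## one common scale factor (mean genetic variance across ancestries):
    ## per-ancestry rescaling would decorrelate perfectly correlated
    ## architectures, so h2 is matched on average and only approximately
    ## per ancestry (AF drift makes the difference small)
    vg <- vapply(seq_len(K), function(k) {
      p <- variant_index[[af_cols[k]]]
      sum(B[causal, k]^2 * 2 * p[causal] * (1 - p[causal]))
    }, numeric(1))
    if (any(vg <= 0)) stop("target h2 infeasible: zero genetic variance")
    B <- B * sqrt(model$h2 / mean(vg))
  }
  if (!is.na(apoe_idx)) B[apoe_idx, ] <- model$apoe_like_effect
  structure(B, causal = causal, apoe_index = apoe_idx)
}

truncated_normal <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm((lo - mean) / sd), pnorm((hi - mean) / sd))
  mean + sd * qnorm(u)
}

## Genetic liability score using each sample's ancestry-matched effect column.
genetic_score <- function(G, effects) {
  if (is.null(dim(effects))) effects <- matrix(effects, ncol = 1)
  g <- numeric(nrow(G$dosages))
  for (a in unique(G$samples$ancestry)) {
    i <- which(G$samples$ancestry == a)
    col <- if (ncol(effects) == 1) 1 else match(a, colnames(effects))
    if (is.na(col)) stop("no effect column for ancestry ", a)
    D <- G$dosages[i, , drop = FALSE]
    if (anyNA(D)) D[is.na(D)] <- 0
    g[i] <- as.numeric(D %*% effects[, col])
  }
  g
}

#' Simulate liability-threshold phenotypes
#'
#' Liability = centered genetic score + age/sex effects + epsilon2-like
#' effect + Gaussian residual scaled so the total variance is ~1; cases are
#' samples whose liability exceeds `qnorm(1 - prevalence)`.  The APOE-like
#' epsilon4 count is the dosage of the designated variant; the epsilon2
#' count is drawn on the remaining allele slots.  Ten synthetic ancestry
#' PCs are attached (leading PCs separate ancestries, the rest are noise).
#'
#' @param G a [genotype_matrix()].
#' @param effects effect matrix from [draw_true_effects()] (or one vector).
#' @param liability a [liability_model()].
#' @param seed integer seed (optional).
#' @param cohort_label cohort name stored per sample.
#' @return data.frame with one row per sample: `ad_status`, `age`, `sex`,
#'   `apoe_e4_count`, `apoe_e2_count`, `cohort_label`, `PC1`..`PC10`,
#'   `liability_true`, plus ids and ancestry.
#' @export
simulate_phenotypes <- function(G, effects, liability, seed = NULL,
                                cohort_label = "cohort") {
  set_seed_if(seed)
  n <- nrow(G$dosages)
  g <- genetic_score(G, effects)
  gc <- g - mean(g)
  age <- truncated_normal(n, liability$age_mean, liability$age_sd,
                          liability$age_range[1], liability$age_range[2])
  z_age <- as.numeric(scale(age))
  sex <- rbinom(n, 1, 0.5)
  apoe_idx <- attr(effects, "apoe_index")
  e4 <- if (!is.null(apoe_idx) && !is.na(apoe_idx)) {
    d <- G$dosages[, apoe_idx]
    d[is.na(d)] <- 0L
    as.integer(round(d))
  } else rbinom(n, 2, 0.15)
  e2 <- rbinom(n, pmax(2L - e4, 0L), liability$e2_freq)
  e2c <- e2 - mean(e2)
  det_part <- gc + liability$age_effect * z_age +
    liability$sex_effect * (sex - 0.5) + liability$e2_effect * e2c
  resid_var <- max(1 - var(det_part), 0.02)
  liab <- det_part + rnorm(n, 0, sqrt(resid_var))
  status <- as.integer(liab > qnorm(1 - liability$prevalence))
  ## synthetic ancestry axes: leading PCs encode group contrasts plus noise
  anc <- factor(G$samples$ancestry)
  pcs <- matrix(rnorm(n * 10, 0, 0.3), n, 10,
                dimnames = list(NULL, paste0("PC", 1:10)))
  if (nlevels(anc) > 1) {
    Mm <- model.matrix(~ anc)[, -1, drop = FALSE]
    for (j in seq_len(min(ncol(Mm), 10)))
      pcs[, j] <- pcs[, j] + 2 * Mm[, j]
  }
  out <- data.frame(sample_id = G$samples$sample_id,
                    ancestry = G$samples$ancestry,
                    ad_status = status, age = age, sex = sex,
                    apoe_e4_count = e4, apoe_e2_count = e2,
                    cohort_label = cohort_label,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pcs))
  out$liability_true <- liab
  out
}

#' Simulate sibling pairs by Mendelian transmission
#'
#' Consecutive samples of `G_parents` are paired as parents; each pair
#' produces two offspring, each inheriting one allele per parent drawn
#' Binomial(1, dosage/2).  The kinship table records 0.25 for sib pairs and
#' 0.25 for each parent-offspring pair (absent pairs mean 0).
#'
#' @param G_parents a [genotype_matrix()] with hard-call dosages.
#' @param n_pairs number of sibling pairs (uses the first `2 n_pairs`
#'   parents).
#' @param seed integer seed (optional).
#' @return list with `offspring` (a `genotype_matrix`) and `kinship`
#'   (data.frame `id1`, `id2`, `kinship`).
#' @export
simulate_related_pairs <- function(G_parents, n_pairs, seed = NULL) {
  set_seed_if(seed)
  D <- G_parents$dosages
  if (anyNA(D)) stop("parents must have complete hard-call dosages")
  if (nrow(D) < 2 * n_pairs) stop("not enough parents for requested pairs")
  m <- ncol(D)
  fa <- D[seq(1, 2 * n_pairs, by = 2), , drop = FALSE]
  mo <- D[seq(2, 2 * n_pairs, by = 2), , drop = FALSE]
  child <- function() {
    a1 <- matrix(rbinom(length(fa), 1, fa / 2), nrow(fa), m)
    a2 <- matrix(rbinom(length(mo), 1, mo / 2), nrow(mo), m)
    a1 + a2
  }
  c1 <- child(); c2 <- child()
  storage.mode(c1) <- "integer"; storage.mode(c2) <- "integer"
  fid <- G_parents$samples$sample_id[seq(1, 2 * n_pairs, by = 2)]
  mid <- G_parents$samples$sample_id[seq(2, 2 * n_pairs, by = 2)]
  anc <- G_parents$samples$ancestry[seq(1, 2 * n_pairs, by = 2)]
  ids1 <- paste0("sibA_", seq_len(n_pairs))
  ids2 <- paste0("sibB_", seq_len(n_pairs))
  off <- genotype_matrix(rbind(c1, c2), G_parents$variants,
                         data.frame(sample_id = c(ids1, ids2),
                                    ancestry = rep(anc, 2),
                                    stringsAsFactors = FALSE))
  kin <- rbind(
    data.frame(id1 = ids1, id2 = ids2, kinship = 0.25),
    data.frame(id1 = fid, id2 = ids1, kinship = 0.25),
    data.frame(id1 = fid, id2 = ids2, kinship = 0.25),
    data.frame(id1 = mid, id2 = ids1, kinship = 0.25),
    data.frame(id1 = mid, id2 = ids2, kinship = 0.25))
  list(offspring = off, kinship = kin)
}
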