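#' Pairwise LD as squared dosage correlation
#'
#' Composite LD: squared Pearson correlation of the two dosage columns.
#' A monomorphic variant has undefined correlation and is treated as
#' r2 = 0 with a warning.
#'
#' @param G_reference a [genotype_matrix()] (the LD reference panel).
#' @param i,j variant ids or column indices.
#' @return Scalar r-squared in \[0, 1\].
#' @export
ld_r2 <- function(G_reference, i, j) {
  ix <- if (is.character(i)) match(i, G_reference$variants$id) else i
  jx <- if (is.character(j)) match(j, G_reference$variants$id) else j
  x <- G_reference$dosages[, ix]; y <- G_reference$dosages[, jx]
  if (var(x, na.rm = TRUE) == 0 || var(y, na.rm = TRUE) == 0) {
    warning("monomorphic variant in ld_r2; returning 0")
    return(0)
  }
  cor(x, y, use = "complete.obs")^2
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unclumped variant with the smallest p-value as an
#' index variant (ties broken by chromosome then position, so the result is
#' invariant to input row order), then removes all unclumped variants on
#' the same chromosome within `window_kb` (center-to-center, PLINK
#' convention) whose reference-panel r-squared with the index is at least
#' `r2_threshold`.  Output is the retained (index) records ordered by
#' (chrom, pos).
#'
#' @param ss summary statistics harmonized to `G_reference`'s index.
#' @param G_reference LD reference panel ([genotype_matrix()]).
#' @param r2_threshold clumping r-squared threshold in (0, 1).
#' @param window_kb window half-width in kilobases.
#' @return The subset of `ss` rows retained as index variants.
#' @export
clump <- function(ss, G_reference, r2_threshold, window_kb) {
  usable <- is.finite(ss$beta) & is.finite(ss$se) & is.finite(ss$p)
  if (!all(usable)) ss <- ss[usable, , drop = FALSE]
  gi <- match(variant_key(ss), variant_key(G_reference$variants))
  if (anyNA(gi)) stop("summary statistics not harmonized to the reference: ",
                      sum(is.na(gi)), " variant(s) missing")
  n <- nrow(ss)
  if (n == 0) return(ss)
  D <- G_reference$dosages[, gi, drop = FALSE]
  D <- sweep(D, 2, colMeans(D))
  sds <- sqrt(colMeans(D^2))
  ord <- order(ss$p, ss$chrom, ss$pos)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  win <- window_kb * 1000
  nr <- nrow(D)
  for (v in ord) {
    if (!alive[v]) next
    keep[v] <- TRUE
    alive[v] <- FALSE
    cand <- which(alive & ss$chrom == ss$chrom[v] &
                    abs(ss$pos - ss$pos[v]) <= win)
    if (!length(cand)) next
    if (sds[v] == 0) next  # monomorphic index clumps nothing
    r <- as.numeric(crossprod(D[, v], D[, cand, drop = FALSE])) /
      (nr * sds[v] * sds[cand])
    r[!is.finite(r)] <- 0
    alive[cand[r^2 >= r2_threshold]] <- FALSE
  }
  out <- ss[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, study_label = attr(ss, "study_label"),
            params = list(r2_threshold = r2_threshold, window_kb = window_kb))
}

#' Clumping + thresholding grid specification
#'
#' Defaults instantiate the standard C+T search: clumping r-squared
#' \{0.1, 0.2, 0.3\}, windows \{100, 250, 500\} kb, and an eight-rung
#' p-value ladder spanning 5e-8 to 0.5.
#'
#' @param r2_thresholds,windows_kb,p_thresholds grid axes.
#' @return A `ct_grid_spec` list.
#' @export
ct_grid_spec <- function(r2_thresholds = c(0.1, 0.2, 0.3),
                         windows_kb = c(100, 250, 500),
                         p_thresholds = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01,
                                          0.05, 0.1, 0.5)) {
  stopifnot(all(r2_thresholds > 0 & r2_thresholds < 1),
            all(windows_kb > 0),
            all(p_thresholds > 0 & p_thresholds <= 1))
  structure(list(r2_thresholds = r2_thresholds, windows_kb = windows_kb,
                 p_thresholds = sort(p_thresholds)),
            class = "ct_grid_spec")
}

#' Build the C+T candidate grid
#'
#' For each (r2, window) pair the summary statistics are clumped once; each
#' p-value threshold then retains the index variants with `p <= threshold`,
#' weighted by their GWAS beta.  Candidates that retain no variant are kept
#' with `n_variants = 0` and flagged.
#'
#' @param ss harmonized summary statistics.
#' @param G_reference LD reference panel.
#' @param grid a [ct_grid_spec()].
#' @return List of `ct_candidate` objects (weight_table, params,
#'   n_variants), length `|r2| * |windows| * |p|`.
#' @export
build_ct_grid <- function(ss, G_reference, grid = ct_grid_spec()) {
  src <- attr(ss, "study_label") %||% "sumstats"
  out <- list()
  for (r2 in grid$r2_thresholds) {
    for (wkb in grid$windows_kb) {
      clumped <- clump(ss, G_reference, r2, wkb)
      for (pt in grid$p_thresholds) {
        sel <- clumped[clumped$p <= pt, , drop = FALSE]
        wt <- weight_table(
          data.frame(chrom = sel$chrom, pos = sel$pos, id = sel$id,
                     effect_allele = sel$effect_allele,
                     other_allele = sel$other_allele, weight = sel$beta,
                     stringsAsFactors = FALSE),
          provenance = list(source = src, method = "CT",
                            params = sprintf("r2=%g,window=%gkb,p<=%g",
                                             r2, wkb, pt)))
        out[[length(out) + 1L]] <- structure(
          list(weight_table = wt,
               params = list(r2 = r2, window_kb = wkb, p_threshold = pt),
               n_variants = nrow(sel), empty = nrow(sel) == 0),
          class = "ct_candidate")
      }
    }
  }
  structure(out, class = "ct_grid", study_label = src)
}

#' Select the most stable C+T candidate by coefficient of variation
#'
#' The tuning cohort is reduced to an unrelated set (kinship below
#' `kin_threshold`) and split into `k` random equal subsets.  For every
#' candidate, each subset gets a logistic regression of case status on the
#' standardized candidate PRS plus covariates; the candidate minimizing
#' `cv = sd(beta) / |mean(beta)|` across subsets is selected (candidates
#' whose effect flips sign across subsets get a large cv and lose
#' naturally).  Deterministic given `seed`.
#'
#' @param candidates a `ct_grid` (list of candidates).
#' @param G_tune tuning-cohort genotypes.
#' @param phen tuning-cohort phenotypes.
#' @param kin kinship table (`id1`, `id2`, `kinship`), or `NULL`.
#' @param k number of subsets (default 5).
#' @param seed integer seed for the subset split.
#' @param covariates phenotype columns used as covariates; defaults to age,
#'   sex, 10 PCs and the epsilon4/epsilon2 counts (mirroring the
#'   weight-training model).
#' @param kin_threshold relatedness cutoff (default 0.04).
#' @return A `cv_selection_report`: per-candidate table (params,
#'   n_variants, per-subset betas, mean, sd, cv), `selected` index, `k`,
#'   `seed`.
#' @export
cv_select <- function(candidates, G_tune, phen, kin = NULL, k = 5L,
                      seed = 1L,
                      covariates = c("age", "sex", paste0("PC", 1:10),
                                     "apoe_e4_count", "apoe_e2_count"),
                      kin_threshold = 0.04) {
  if (k < 2) stop("k must be at least 2")
  unrel <- select_unrelated(phen$sample_id, kin, threshold = kin_threshold)
  keep <- phen$sample_id %in% unrel
  phen <- phen[keep, , drop = FALSE]
  G_tune <- gm_subset(G_tune, sample_ids = phen$sample_id)
  n <- nrow(phen)
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), n))
  covariates <- intersect(covariates, names(phen))
  covs <- phen[, covariates, drop = FALSE]
  covs <- covs[, vapply(covs, function(x) length(unique(x)) > 1, TRUE),
               drop = FALSE]
  res <- lapply(candidates, function(cand) {
    if (cand$n_variants == 0)
      return(list(betas = rep(NA_real_, k), mean = NA_real_, sd = NA_real_,
                  cv = NA_real_))
    prs <- score_prs(G_tune, cand$weight_table)
    sdv <- sd(prs$score)
    if (!is.finite(sdv) || sdv == 0)
      return(list(betas = rep(NA_real_, k), mean = NA_real_, sd = NA_real_,
                  cv = NA_real_))
    z <- standardize(prs, fit_reference_stats(prs, "tuning"))
    betas <- vapply(seq_len(k), function(f) {
      i <- fold == f
      dat <- cbind(data.frame(y = phen$ad_status[i], prs = z$score[i]),
                   covs[i, , drop = FALSE])
      fit <- suppressWarnings(glm(y ~ ., data = dat, family = binomial()))
      if (!fit$converged) return(NA_real_)
      unname(coef(fit)["prs"])
    }, numeric(1))
    mu <- mean(betas); s <- sd(betas)
    list(betas = betas, mean = mu, sd = s,
         cv = if (is.finite(mu) && mu != 0) s / abs(mu) else Inf)
  })
  cvs <- vapply(res, function(r) r$cv %||% NA_real_, numeric(1))
  finite <- which(is.finite(cvs))
  if (!length(finite)) stop("no candidate yielded a finite cv")
  selected <- finite[which.min(cvs[finite])]
  tab <- data.frame(
    candidate = seq_along(candidates),
    r2 = vapply(candidates, function(c) c$params$r2, numeric(1)),
    window_kb = vapply(candidates, function(c) c$params$window_kb, numeric(1)),
    p_threshold = vapply(candidates, function(c) c$params$p_threshold,
                         numeric(1)),
    n_variants = vapply(candidates, function(c) c$n_variants, numeric(1)),
    mean_beta = vapply(res, function(r) r$mean, numeric(1)),
    sd_beta = vapply(res, function(r) r$sd, numeric(1)),
    cv = cvs)
  structure(list(table = tab,
                 betas = lapply(res, `[[`, "betas"),
                 selected = selected, k = as.integer(k),
                 seed = as.integer(seed),
                 n_unrelated = n),
            class = "cv_selection_report")
}

#' @export
print.cv_selection_report <- function(x, ...) {
  sel <- x$table[x$selected, ]
  cat(sprintf(
    "cv_selection_report: %d candidates, k=%d subsets (n=%d unrelated)\n",
    nrow(x$table), x$k, x$n_unrelated))
  cat(sprintf("  selected: r2=%g window=%gkb p<=%g (%d variants, cv=%.3f)\n",
              sel$r2, sel$window_kb, sel$p_threshold, sel$n_variants, sel$cv))
  invisible(x)
}
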