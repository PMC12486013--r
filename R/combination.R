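#' Build a standardized per-source PRS matrix
#'
#' Scores a cohort with each source weight table and standardizes every
#' column against its per-source scaling reference (fit on this cohort
#' when `scalings` is `NULL`, e.g. the evaluation cohort that anchors the
#' scale for later transfer).
#'
#' @param G a [genotype_matrix()].
#' @param tables named list of [weight_table()]s (one per source GWAS).
#' @param scalings named list of [scaling_reference()]s, or `NULL` to fit
#'   here.
#' @param missing_policy passed to [score_prs()].
#' @return A `source_prs_matrix`: `sample_ids`, matrix `M` (one
#'   standardized column per source), `scalings`, `labels`.
#' @export
build_source_prs_matrix <- function(G, tables, scalings = NULL,
                                    missing_policy = "mean_impute") {
  labels <- names(tables)
  if (is.null(labels) || any(labels == ""))
    stop("source weight tables must be named")
  fit_here <- is.null(scalings)
  if (fit_here) scalings <- vector("list", length(labels))
  M <- matrix(NA_real_, nrow(G$dosages), length(labels),
              dimnames = list(G$samples$sample_id, labels))
  for (k in seq_along(labels)) {
    prs <- score_prs(G, tables[[k]], missing_policy = missing_policy)
    if (fit_here)
      scalings[[k]] <- fit_reference_stats(prs, cohort_label = "fit_cohort")
    M[, k] <- standardize(prs, scalings[[k]])$score
  }
  names(scalings) <- labels
  structure(list(sample_ids = G$samples$sample_id, M = M,
                 scalings = scalings, labels = labels),
            class = "source_prs_matrix")
}

#' Train per-source summation weights in an independent cohort
#'
#' In `"marginal"` mode (default, the PRSsum-Simple procedure) each source
#' PRS gets its own logistic regression of case status on that PRS plus
#' covariates; the PRS coefficient is that source's summation weight
#' `w_k`.  `"joint"` mode enters all source PRSs in one regression.
#' Near-collinear sources in joint mode are detected and reported in the
#' fit metadata.  Negative weights are allowed and passed through.
#'
#' @param M a [build_source_prs_matrix()] result on the training cohort.
#' @param phen training-cohort phenotypes.
#' @param fit_mode `"marginal"` or `"joint"`.
#' @param covariates phenotype columns used as covariates (defaults mirror
#'   the weight-training model: age, sex, ancestry, cohort, 10 PCs,
#'   epsilon4/epsilon2 counts; constant columns are dropped).
#' @return A `combination_model`: source labels, weights (and their SEs),
#'   per-source scalings, `final_scaling` (`NULL` until anchored, see
#'   [combine_weighted()]), fit metadata.
#' @export
train_combination_weights <- function(M, phen,
                                      fit_mode = c("marginal", "joint"),
                                      covariates = c("age", "sex", "ancestry",
                                                     "cohort_label",
                                                     paste0("PC", 1:10),
                                                     "apoe_e4_count",
                                                     "apoe_e2_count")) {
  fit_mode <- match.arg(fit_mode)
  stopifnot(inherits(M, "source_prs_matrix"))
  if (!identical(M$sample_ids, phen$sample_id))
    stop("PRS matrix and phenotypes are not aligned")
  covariates <- intersect(covariates, names(phen))
  covs <- phen[, covariates, drop = FALSE]
  for (nm in intersect(c("ancestry", "cohort_label"), names(covs)))
    covs[[nm]] <- factor(covs[[nm]])
  covs <- covs[, vapply(covs, function(x) length(unique(x)) > 1, TRUE),
               drop = FALSE]
  y <- phen$ad_status
  K <- length(M$labels)
  w <- se <- setNames(numeric(K), M$labels)
  collinear <- FALSE
  if (fit_mode == "marginal") {
    for (k in seq_len(K)) {
      dat <- cbind(data.frame(y = y, prs = M$M[, k]), covs)
      fit <- suppressWarnings(glm(y ~ ., data = dat, family = binomial(),
                                  control = glm.control(epsilon = 1e-8,
                                                        maxit = 100)))
      if (!fit$converged)
        stop("weight training did not converge for source ", M$labels[k])
      sm <- summary(fit)$coefficients
      w[k] <- sm["prs", 1]; se[k] <- sm["prs", 2]
    }
  } else {
    cm <- cor(M$M)
    collinear <- any(abs(cm[upper.tri(cm)]) > 0.999)
    if (collinear)
      warning("near-collinear source PRSs in joint weight training")
    prs_df <- as.data.frame(M$M)
    names(prs_df) <- paste0("prs_", M$labels)
    dat <- cbind(data.frame(y = y), prs_df, covs)
    fit <- suppressWarnings(glm(y ~ ., data = dat, family = binomial(),
                                control = glm.control(epsilon = 1e-8,
                                                      maxit = 100)))
    if (!fit$converged) stop("joint weight training did not converge")
    sm <- summary(fit)$coefficients
    for (k in seq_len(K)) {
      nm <- paste0("prs_", M$labels[k])
      if (!nm %in% rownames(sm))
        stop("source dropped from joint fit (aliased): ", M$labels[k])
      w[k] <- sm[nm, 1]; se[k] <- sm[nm, 2]
    }
  }
  structure(list(source_labels = M$labels, weights = w, weight_se = se,
                 per_source_scaling = M$scalings, final_scaling = NULL,
                 fit_metadata = list(training_cohort =
                                       phen$cohort_label[1] %||% "training",
                                     covariates = names(covs),
                                     fit_mode = fit_mode,
                                     n = length(y),
                                     collinear_sources = collinear)),
            class = "combination_model")
}

#' Weighted summation of standardized source PRSs
#'
#' `S = sum_k w_k PRS_k` over the model's sources, then standardized by
#' the model's `final_scaling` (set `standardize = FALSE` to obtain the
#' raw sum, e.g. to anchor the final scaling in a reference cohort).
#'
#' @param M a `source_prs_matrix` whose columns were standardized with the
#'   model's per-source scalings.
#' @param model a [train_combination_weights()] result.
#' @param standardize apply `model$final_scaling`?
#' @return A `prs_vector`.
#' @export
combine_weighted <- function(M, model, standardize = TRUE) {
  stopifnot(inherits(model, "combination_model"))
  if (!identical(M$labels, model$source_labels))
    stop("source labels of PRS matrix and model do not match")
  s <- as.numeric(M$M %*% model$weights)
  out <- data.frame(sample_id = M$sample_ids, score = s,
                    n_variants_used = NA_integer_, stringsAsFactors = FALSE)
  out <- structure(out,
                   provenance = list(combination = "weighted",
                                     weights = model$weights,
                                     scaling = "raw"),
                   class = c("prs_vector", "data.frame"))
  if (standardize) {
    if (is.null(model$final_scaling))
      stop("model has no final_scaling; fit one with fit_reference_stats ",
           "or call with standardize = FALSE")
    out <- standardize(out, model$final_scaling)
  }
  out
}

#' Unweighted summation of standardized source PRSs
#'
#' Simple sum of the standardized columns, then standardized (against
#' `scaling` when given, else against its own mean/SD).
#'
#' @param M a `source_prs_matrix`.
#' @param scaling optional frozen [scaling_reference()].
#' @return A `prs_vector` with the applied scaling in attribute
#'   `scaling_used`.
#' @export
combine_unweighted <- function(M, scaling = NULL) {
  s <- rowSums(M$M)
  out <- data.frame(sample_id = M$sample_ids, score = s,
                    n_variants_used = NA_integer_, stringsAsFactors = FALSE)
  out <- structure(out,
                   provenance = list(combination = "unweighted",
                                     scaling = "raw"),
                   class = c("prs_vector", "data.frame"))
  if (is.null(scaling)) scaling <- fit_reference_stats(out, "self")
  out <- standardize(out, scaling)
  attr(out, "scaling_used") <- scaling
  out
}

#' Collapse a combination model to a single per-variant weight table
#'
#' Per variant, the collapsed weight is `sum_k w_k beta_jk / sd_k` over the
#' sources containing it, where `sd_k` is the per-source scaling SD.
#' Scoring a cohort with the collapsed table equals the weighted
#' combination of per-source scores up to an additive constant (the means
#' of the per-source scalings), so correlations and per-SD effects are
#' identical; re-anchoring via a scaling reference absorbs the constant.
#'
#' @param model a `combination_model`.
#' @param source_tables named list of [weight_table()]s matching the
#'   model's sources, harmonized to one reference.
#' @return A [weight_table()]; allele-orientation conflicts between source
#'   tables are a hard error.
#' @export
collapse_to_variant_weights <- function(model, source_tables) {
  stopifnot(inherits(model, "combination_model"))
  if (!identical(sort(names(source_tables)), sort(model$source_labels)))
    stop("source table names must match the model's source labels")
  acc <- NULL
  for (k in model$source_labels) {
    tb <- source_tables[[k]]
    sdk <- model$per_source_scaling[[k]]$sd
    part <- data.frame(chrom = tb$chrom, pos = tb$pos, id = tb$id,
                       effect_allele = tb$effect_allele,
                       other_allele = tb$other_allele,
                       w = model$weights[[k]] * tb$weight / sdk,
                       stringsAsFactors = FALSE)
    if (is.null(acc)) { acc <- part; next }
    key_a <- variant_key(acc); key_p <- variant_key(part)
    j <- match(key_p, key_a)
    new <- is.na(j)
    shared <- which(!new)
    if (length(shared)) {
      ja <- j[shared]
      same <- part$effect_allele[shared] == acc$effect_allele[ja] &
        part$other_allele[shared] == acc$other_allele[ja]
      swap <- part$effect_allele[shared] == acc$other_allele[ja] &
        part$other_allele[shared] == acc$effect_allele[ja]
      if (any(!same & !swap))
        stop("allele-orientation conflict between source tables")
      add <- part$w[shared]
      add[swap] <- -add[swap]
      acc$w[ja] <- acc$w[ja] + add
    }
    if (any(new)) acc <- rbind(acc, part[new, , drop = FALSE])
  }
  acc <- acc[order(acc$chrom, acc$pos), , drop = FALSE]
  weight_table(
    data.frame(chrom = acc$chrom, pos = acc$pos, id = acc$id,
               effect_allele = acc$effect_allele,
               other_allele = acc$other_allele, weight = acc$w,
               stringsAsFactors = FALSE),
    provenance = list(method = "collapsed_weighted_sum",
                      sources = model$source_labels,
                      weights = model$weights))
}

#' Persist / restore a combination model as JSON
#'
#' @param model a `combination_model`.
#' @param path JSON path.
#' @return `path` invisibly; `read_combination_model()` returns the model.
#' @export
write_combination_model <- function(model, path) {
  obj <- list(source_labels = model$source_labels,
              weights = as.list(model$weights),
              weight_se = as.list(model$weight_se),
              per_source_scaling = lapply(model$per_source_scaling,
                                          unclass),
              final_scaling = if (!is.null(model$final_scaling))
                unclass(model$final_scaling),
              fit_metadata = model$fit_metadata)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), path)
  invisible(path)
}

#' @rdname write_combination_model
#' @export
read_combination_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- lapply(obj$per_source_scaling, function(s)
    scaling_reference(s$mean, s$sd, s$cohort_label))
  fs <- if (!is.null(obj$final_scaling))
    scaling_reference(obj$final_scaling$mean, obj$final_scaling$sd,
                      obj$final_scaling$cohort_label)
  structure(list(source_labels = obj$source_labels,
                 weights = unlist(obj$weights),
                 weight_se = unlist(obj$weight_se),
                 per_source_scaling = sc, final_scaling = fs,
                 fit_metadata = obj$fit_metadata),
            class = "combination_model")
}
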