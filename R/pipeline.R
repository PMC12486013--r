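#' Pipeline configuration
#'
#' Bundles every input of the training -> combination -> evaluation ->
#' validation flow.  Cohort slots are lists with elements `geno`
#' ([genotype_matrix()]), `phen` (phenotype table) and optionally `kin`
#' (kinship table); `sources` is a named list of summary-statistics tables
#' (one per training GWAS).  Seeds are explicit — there is no wall-clock
#' default.
#'
#' @param sources named list of summary statistics.
#' @param source_ancestry named character vector mapping each source to the
#'   ancestry whose reference-panel subset estimates its LD (sources
#'   missing from the map use the full reference).
#' @param reference LD reference cohort (list with `geno`).
#' @param tuning,training,evaluation cohort lists (see above).
#' @param validation optional held-out cohort list.
#' @param grid a [ct_grid_spec()].
#' @param mask a [genomic_region()] to exclude (default [apoe_region()]);
#'   `NULL` disables masking.
#' @param mask_flank_bp mask flank (default 1 Mb).
#' @param fit_mode combination weight fit mode, `"marginal"` or `"joint"`.
#' @param k_folds tuning subsets for CV selection (default 5).
#' @param kin_threshold relatedness cutoff (default 0.04).
#' @param covariates covariate columns for evaluation models.
#' @param seed master integer seed.
#' @param out_dir output directory for artifacts and the manifest, or
#'   `NULL` to keep everything in memory.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(sources, source_ancestry = NULL, reference,
                            tuning, training, evaluation, validation = NULL,
                            grid = ct_grid_spec(), mask = apoe_region(),
                            mask_flank_bp = 1e6,
                            fit_mode = c("marginal", "joint"), k_folds = 5L,
                            kin_threshold = 0.04,
                            covariates = c("age", "sex", "ancestry",
                                           paste0("PC", 1:10),
                                           "apoe_e4_count", "apoe_e2_count"),
                            seed, out_dir = NULL) {
  fit_mode <- match.arg(fit_mode)
  if (missing(seed) || is.null(seed))
    stop("seed must be explicit (no wall-clock default)")
  if (is.null(names(sources)) || any(names(sources) == ""))
    stop("sources must be a named list")
  structure(list(sources = sources, source_ancestry = source_ancestry,
                 reference = reference, tuning = tuning, training = training,
                 evaluation = evaluation, validation = validation,
                 grid = grid, mask = mask, mask_flank_bp = mask_flank_bp,
                 fit_mode = fit_mode, k_folds = as.integer(k_folds),
                 kin_threshold = kin_threshold, covariates = covariates,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Build a pipeline config from a simulated study world
#'
#' @param world a [simulate_prs_study()] result.
#' @param ... passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
config_from_world <- function(world, ...) {
  pipeline_config(
    sources = lapply(world$sources, `[[`, "sumstats"),
    source_ancestry = vapply(world$sources, `[[`, character(1), "ancestry"),
    reference = world$cohorts$reference,
    tuning = world$cohorts$tuning,
    training = world$cohorts$training,
    evaluation = world$cohorts$evaluation,
    validation = world$cohorts$validation,
    seed = world$seed, ...)
}

check_disjoint_cohorts <- function(cfg) {
  ids <- list(tuning = cfg$tuning$geno$samples$sample_id,
              training = cfg$training$geno$samples$sample_id,
              evaluation = cfg$evaluation$geno$samples$sample_id)
  if (!is.null(cfg$validation))
    ids$validation <- cfg$validation$geno$samples$sample_id
  nm <- names(ids)
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    ov <- intersect(ids[[i]], ids[[j]])
    if (length(ov))
      stop("cohorts must be disjoint by sample id: ", nm[j], " and ", nm[i],
           " share ", length(ov), " sample(s)")
  }
  invisible(TRUE)
}

ancestry_reference <- function(cfg, src_label) {
  ref <- cfg$reference$geno
  a <- cfg$source_ancestry[[src_label]] %||% NA_character_
  if (!is.na(a) && a %in% ref$samples$ancestry)
    gm_subset(ref, sample_ids =
                ref$samples$sample_id[ref$samples$ancestry == a])
  else ref
}

#' Run the training half of the pipeline
#'
#' Per source GWAS: harmonize to the reference variant index, build the
#' C+T candidate grid against an ancestry-matched LD reference, and select
#' the most stable candidate by CV in the tuning cohort.  Build the three
#' combination strategies — meta-analysis-first (meta-analyze the
#' harmonized sources, then C+T + CV selection), unweighted summation, and
#' weighted summation with weights trained in the independent training
#' cohort — mask the APOE region out of every weight table, standardize
#' each strategy PRS against the evaluation cohort, evaluate
#' (OR per SD + AUC on unrelated samples) and rank them.  The best
#' strategy is collapsed to a single per-variant weight table with a
#' frozen evaluation-cohort scaling reference for external validation.
#'
#' @param cfg a [pipeline_config()].
#' @return List of artifacts: `source_tables`, `cv_reports`, `meta_table`,
#'   `combination_model`, strategy `prs` vectors, `results` (ranked
#'   EvalResult table), `best`, `collapsed_table`, `frozen_scaling`, and
#'   `manifest` (also written to `out_dir` when set).
#' @export
run_training <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  check_disjoint_cohorts(cfg)
  vindex <- cfg$reference$geno$variants
  harmonized <- lapply(cfg$sources, harmonize_to_reference, vindex)
  source_tables <- list(); cv_reports <- list()
  for (k in seq_along(harmonized)) {
    lab <- names(harmonized)[k]
    refk <- ancestry_reference(cfg, lab)
    grid <- build_ct_grid(harmonized[[k]], refk, cfg$grid)
    rep <- cv_select(grid, cfg$tuning$geno, cfg$tuning$phen,
                     kin = cfg$tuning$kin, k = cfg$k_folds,
                     seed = derive_seed(cfg$seed, 200 + k),
                     kin_threshold = cfg$kin_threshold)
    source_tables[[lab]] <- grid[[rep$selected]]$weight_table
    cv_reports[[lab]] <- rep
  }
  meta_ss <- meta_analyze_fixed(harmonized)
  meta_grid <- build_ct_grid(meta_ss, cfg$reference$geno, cfg$grid)
  meta_rep <- cv_select(meta_grid, cfg$tuning$geno, cfg$tuning$phen,
                        kin = cfg$tuning$kin, k = cfg$k_folds,
                        seed = derive_seed(cfg$seed, 299),
                        kin_threshold = cfg$kin_threshold)
  meta_table <- meta_grid[[meta_rep$selected]]$weight_table
  cv_reports[["META"]] <- meta_rep

  if (!is.null(cfg$mask)) {
    source_tables <- lapply(source_tables, mask_region, region = cfg$mask,
                            flank_bp = cfg$mask_flank_bp)
    meta_table <- mask_region(meta_table, region = cfg$mask,
                              flank_bp = cfg$mask_flank_bp)
  }

  ## per-source scalings anchored in the evaluation cohort, then applied to
  ## the independent training cohort for weight derivation
  G_eval <- cfg$evaluation$geno
  eval_scalings <- lapply(source_tables, function(tb)
    fit_reference_stats(score_prs(G_eval, tb), cohort_label = "evaluation"))
  M_train <- build_source_prs_matrix(cfg$training$geno, source_tables,
                                     scalings = eval_scalings)
  model <- train_combination_weights(M_train, cfg$training$phen,
                                     fit_mode = cfg$fit_mode)
  M_eval <- build_source_prs_matrix(G_eval, source_tables,
                                    scalings = eval_scalings)
  raw_w <- combine_weighted(M_eval, model, standardize = FALSE)
  model$final_scaling <- fit_reference_stats(raw_w, "evaluation")
  prs_weighted <- standardize(raw_w, model$final_scaling)
  prs_unweighted <- combine_unweighted(M_eval)
  meta_prs_raw <- score_prs(G_eval, meta_table)
  meta_scaling <- fit_reference_stats(meta_prs_raw, "evaluation")
  prs_meta <- standardize(meta_prs_raw, meta_scaling)

  results <- rbind(
    evaluate_model(prs_meta, cfg$evaluation$phen, kin = cfg$evaluation$kin,
                   covariates = cfg$covariates, model_label = "meta_first",
                   kin_threshold = cfg$kin_threshold),
    evaluate_model(prs_unweighted, cfg$evaluation$phen,
                   kin = cfg$evaluation$kin, covariates = cfg$covariates,
                   model_label = "unweighted_sum",
                   kin_threshold = cfg$kin_threshold),
    evaluate_model(prs_weighted, cfg$evaluation$phen,
                   kin = cfg$evaluation$kin, covariates = cfg$covariates,
                   model_label = "weighted_sum",
                   kin_threshold = cfg$kin_threshold))
  ranked <- rank_models(results)
  best <- attr(ranked, "selected")

  collapsed <- switch(best,
    weighted_sum = collapse_to_variant_weights(model, source_tables),
    unweighted_sum = {
      unit <- model
      unit$weights[] <- 1
      collapse_to_variant_weights(unit, source_tables)
    },
    meta_first = meta_table)
  frozen_scaling <- fit_reference_stats(score_prs(G_eval, collapsed),
                                        cohort_label = "evaluation")

  art <- list(source_tables = source_tables, cv_reports = cv_reports,
              meta_table = meta_table, combination_model = model,
              prs = list(meta_first = prs_meta,
                         unweighted_sum = prs_unweighted,
                         weighted_sum = prs_weighted),
              results = ranked, best = best, collapsed_table = collapsed,
              frozen_scaling = frozen_scaling, seed = cfg$seed)
  art$manifest <- build_manifest(cfg, art)
  if (!is.null(cfg$out_dir)) write_training_artifacts(art, cfg$out_dir)
  art
}

build_manifest <- function(cfg, art) {
  counts <- list(
    n_variants_reference = nrow(cfg$reference$geno$variants),
    n_tuning = nrow(cfg$tuning$geno$dosages),
    n_training = nrow(cfg$training$geno$dosages),
    n_evaluation = nrow(cfg$evaluation$geno$dosages),
    n_variants_per_source = lapply(art$source_tables, nrow),
    n_variants_meta = nrow(art$meta_table),
    n_variants_collapsed = nrow(art$collapsed_table))
  list(seed = cfg$seed, fit_mode = cfg$fit_mode,
       mask = if (!is.null(cfg$mask))
         sprintf("%s:%g-%g+/-%gbp", cfg$mask$chrom, cfg$mask$start,
                 cfg$mask$end, cfg$mask_flank_bp) else "none",
       counts = counts, best = art$best,
       weights = as.list(art$combination_model$weights),
       frozen_scaling = unclass(art$frozen_scaling))
}

#' Write training artifacts and a hash manifest
#'
#' Weight tables, the combination model, the frozen scaling, the ranked
#' results table and the CV selection tables are written under `out_dir`;
#' `manifest.json` records the seed, stage counts and the md5 of every
#' artifact file, so reruns can be compared byte for byte.
#'
#' @param art a [run_training()] artifact list.
#' @param out_dir output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_training_artifacts <- function(art, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (lab in names(art$source_tables))
    write_weight_table(art$source_tables[[lab]],
                       file.path(out_dir, paste0("weights_", lab, ".tsv")))
  write_weight_table(art$meta_table, file.path(out_dir, "weights_META.tsv"))
  write_weight_table(art$collapsed_table,
                     file.path(out_dir, "weights_collapsed_best.tsv"))
  write_combination_model(art$combination_model,
                          file.path(out_dir, "combination_model.json"))
  write_scaling_reference(art$frozen_scaling,
                          file.path(out_dir, "frozen_scaling.json"))
  write.table(art$results, file.path(out_dir, "strategy_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (lab in names(art$cv_reports))
    write.table(art$cv_reports[[lab]]$table,
                file.path(out_dir, paste0("cv_selection_", lab, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  md5 <- tools::md5sum(file.path(out_dir, files))
  names(md5) <- files
  manifest <- art$manifest
  manifest$files <- as.list(md5)
  path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Validate the frozen PRS in a held-out cohort
#'
#' Scores the validation cohort with the collapsed best weight table,
#' applies the frozen evaluation-cohort scaling reference (never refit
#' here — there is no code path that refits it), and runs the evaluation
#' battery including sex strata.
#'
#' @param cfg a [pipeline_config()] with a `validation` cohort.
#' @param artifacts a [run_training()] result.
#' @return data.frame of EvalResult rows (overall + sex strata).
#' @export
run_validation <- function(cfg, artifacts) {
  if (is.null(cfg$validation)) stop("config has no validation cohort")
  check_disjoint_cohorts(cfg)
  G <- cfg$validation$geno
  phen <- cfg$validation$phen
  prs <- standardize(score_prs(G, artifacts$collapsed_table),
                     artifacts$frozen_scaling)
  overall <- evaluate_model(prs, phen, kin = cfg$validation$kin,
                            covariates = cfg$covariates,
                            model_label = paste0(artifacts$best,
                                                 "_validation"),
                            kin_threshold = cfg$kin_threshold)
  strata <- stratify_assoc(prs, phen, axis = "sex",
                           kin = cfg$validation$kin,
                           covariates = cfg$covariates,
                           model_label = paste0(artifacts$best,
                                                "_validation"))
  out <- rbind(overall, strata)
  rownames(out) <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(out, file.path(cfg$out_dir, "validation_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
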