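#' Per-variant scoring weight table
#'
#' @param df data.frame with columns `chrom`, `pos`, `id`, `effect_allele`,
#'   `other_allele`, `weight`.
#' @param provenance list describing where the weights came from (source
#'   GWAS, construction method, parameter string, masks applied).
#' @return A `weight_table` data.frame.  Duplicate (chrom, pos) keys are a
#'   hard error (silent averaging hides construction bugs), as are
#'   non-finite weights.
#' @export
weight_table <- function(df, provenance = list()) {
  need <- c("chrom", "pos", "id", "effect_allele", "other_allele", "weight")
  if (!all(need %in% names(df)))
    stop("weight table needs columns: ", paste(need, collapse = ", "))
  df <- df[, need, drop = FALSE]
  if (anyDuplicated(variant_key(df)))
    stop("duplicate variant keys in weight table")
  if (nrow(df) > 0 && any(!is.finite(df$weight)))
    stop("weights must be finite")
  rownames(df) <- NULL
  structure(df, provenance = provenance, class = c("weight_table", "data.frame"))
}

#' Write / read weight tables (PGS-Catalog-compatible column set)
#'
#' TSV with header CHR, POS, ID, EA, OA, WEIGHT (a superset-compatible
#' layout for published scoring files, whose `effect_weight` maps to
#' WEIGHT via the `dialect` of [read_weight_table()]).
#'
#' @param w a [weight_table()].
#' @param path output path (".gz" supported).
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(w, path) {
  out <- data.frame(CHR = w$chrom, POS = as.integer(round(w$pos)), ID = w$id,
                    EA = w$effect_allele, OA = w$other_allele,
                    WEIGHT = w$weight)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_table
#' @param dialect named character vector of extra column aliases
#'   (e.g. `c(effect_weight = "weight")`).
#' @export
read_weight_table <- function(path, dialect = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  raw <- read.delim(con, stringsAsFactors = FALSE, check.names = FALSE)
  al <- list(chrom = c("chr", "chrom", "chr_name"),
             pos = c("pos", "chr_position", "position"),
             id = c("id", "rsid", "snp"),
             effect_allele = c("ea", "effect_allele", "a1"),
             other_allele = c("oa", "other_allele", "a2"),
             weight = c("weight", "effect_weight", "beta"))
  if (!is.null(dialect))
    for (i in seq_along(dialect))
      al[[unname(dialect[i])]] <- c(tolower(names(dialect)[i]),
                                    al[[unname(dialect[i])]])
  lower <- tolower(names(raw))
  out <- list()
  for (canon in names(al)) {
    hit <- which(lower %in% al[[canon]])
    if (!length(hit)) stop("weight table column missing: ", canon)
    out[[canon]] <- raw[[hit[1]]]
  }
  df <- data.frame(out, stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos)
  df$weight <- as.numeric(df$weight)
  weight_table(df, provenance = list(source = basename(path)))
}

#' Compute polygenic scores from a weight table
#'
#' `S_i = sum_j dosage_ij * weight_j` over the weight-table variants found
#' in `G` (matched on (chrom, pos); allele-swapped records contribute with
#' negated weight).  Missing dosages are mean-imputed as `2 * AF` (using
#' the sample's ancestry-specific `af_<ancestry>` column when present,
#' otherwise the empirical frequency), or omitted per sample with
#' `missing_policy = "omit"`.
#'
#' @param G a [genotype_matrix()].
#' @param w a [weight_table()] harmonized to `G`'s variant index.
#' @param missing_policy `"mean_impute"` (default) or `"omit"`.
#' @return A `prs_vector` data.frame (`sample_id`, `score`,
#'   `n_variants_used`) with provenance attributes; zero matched variants
#'   is a hard error.
#' @export
score_prs <- function(G, w, missing_policy = c("mean_impute", "omit")) {
  missing_policy <- match.arg(missing_policy)
  idx <- match(variant_key(w), variant_key(G$variants))
  hit <- !is.na(idx)
  if (!any(hit))
    stop("no weight-table variants found in the genotype matrix; ",
         "check harmonization")
  wv <- w$weight[hit]
  gi <- idx[hit]
  ea <- G$variants$effect_allele[gi]; oa <- G$variants$other_allele[gi]
  same <- w$effect_allele[hit] == ea & w$other_allele[hit] == oa
  swap <- w$effect_allele[hit] == oa & w$other_allele[hit] == ea
  if (any(!same & !swap))
    stop("allele-incompatible variants between weight table and genotypes")
  wv[swap] <- -wv[swap]
  D <- G$dosages[, gi, drop = FALSE]
  n_used <- rep.int(sum(hit), nrow(D))
  if (anyNA(D)) {
    if (missing_policy == "mean_impute") {
      af <- impute_af(G, gi)
      for (j in seq_len(ncol(D))) {
        na <- is.na(D[, j])
        if (any(na)) D[na, j] <- 2 * af[na, j]
      }
    } else {
      n_used <- n_used - rowSums(is.na(D))
      D[is.na(D)] <- 0
    }
  }
  score <- as.numeric(D %*% wv)
  prs <- data.frame(sample_id = G$samples$sample_id, score = score,
                    n_variants_used = n_used, stringsAsFactors = FALSE)
  structure(prs,
            provenance = list(weights = attr(w, "provenance"),
                              scaling = "raw",
                              missing_policy = missing_policy,
                              n_skipped = sum(!hit)),
            class = c("prs_vector", "data.frame"))
}

## Per-sample x per-variant imputation frequency for score_prs.
impute_af <- function(G, gi) {
  af_cols <- paste0("af_", G$samples$ancestry)
  have <- af_cols %in% names(G$variants)
  emp <- colMeans(G$dosages[, gi, drop = FALSE], na.rm = TRUE) / 2
  emp[!is.finite(emp)] <- 0.5
  out <- matrix(rep(emp, each = nrow(G$dosages)), nrow(G$dosages))
  if (any(have)) {
    for (a in unique(G$samples$ancestry)) {
      col <- paste0("af_", a)
      if (col %in% names(G$variants)) {
        rows <- G$samples$ancestry == a
        out[rows, ] <- rep(G$variants[[col]][gi], each = sum(rows))
      }
    }
  }
  out
}

#' Genomic region
#'
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param label region name.
#' @return A `genomic_region` list.
#' @export
genomic_region <- function(chrom, start, end, label = "region") {
  if (start > end) stop("region start must be <= end")
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end), label = label),
            class = "genomic_region")
}

#' The APOE gene region (GRCh38)
#'
#' chr19:44,905,791-44,909,393; the conventional mask for isolating the
#' polygenic background of Alzheimer disease excludes a 1 Mb flank around
#' this interval.
#'
#' @return A [genomic_region()].
#' @export
apoe_region <- function() genomic_region("19", 44905791, 44909393, "APOE")

#' Mask a genomic region out of a weight table
#'
#' Removes variants with `chrom == region$chrom` and position within
#' `[start - flank_bp, end + flank_bp]` (inclusive); the mask is recorded
#' in the table's provenance.
#'
#' @param w a [weight_table()].
#' @param region a [genomic_region()]; default [apoe_region()].
#' @param flank_bp flank in base pairs on each side (default 1 Mb).
#' @return Masked `weight_table`.
#' @export
mask_region <- function(w, region = apoe_region(), flank_bp = 1e6) {
  drop <- w$chrom == region$chrom &
    w$pos >= region$start - flank_bp & w$pos <= region$end + flank_bp
  prov <- attr(w, "provenance") %||% list()
  prov$masks <- c(prov$masks,
                  sprintf("%s:%s-%s+/-%gbp (%d removed)", region$chrom,
                          region$start, region$end, flank_bp, sum(drop)))
  weight_table(w[!drop, , drop = FALSE], provenance = prov)
}

#' Scaling reference (frozen mean/SD of a PRS in a reference cohort)
#'
#' @param mean,sd reference statistics; `sd` must be positive.
#' @param cohort_label cohort the statistics were fit in.
#' @return A `scaling_reference` list.
#' @export
scaling_reference <- function(mean, sd, cohort_label = "reference") {
  if (!is.finite(sd) || sd <= 0) stop("scaling reference requires sd > 0")
  structure(list(mean = mean, sd = sd, cohort_label = cohort_label),
            class = "scaling_reference")
}

#' Fit a scaling reference from a PRS vector
#'
#' Mean and (n-1)-denominator SD of the scores; constant scores are an
#' error.
#'
#' @param prs a `prs_vector` (or numeric vector).
#' @param cohort_label cohort name.
#' @return A [scaling_reference()].
#' @export
fit_reference_stats <- function(prs, cohort_label = "reference") {
  x <- if (is.data.frame(prs)) prs$score else as.numeric(prs)
  if (length(x) < 2) stop("need at least 2 samples to fit reference stats")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("constant scores: sd is zero")
  scaling_reference(mean(x), s, cohort_label)
}

#' Standardize a PRS against a frozen scaling reference
#'
#' `(score - mean) / sd`.  Association z-statistics downstream are
#' invariant to this affine transform; it matters for transferring effect
#' sizes per SD across cohorts.
#'
#' @param prs a `prs_vector`.
#' @param ref a [scaling_reference()].
#' @return Standardized `prs_vector` with updated provenance.
#' @export
standardize <- function(prs, ref) {
  stopifnot(inherits(ref, "scaling_reference"))
  out <- prs
  out$score <- (prs$score - ref$mean) / ref$sd
  prov <- attr(prs, "provenance") %||% list()
  prov$scaling <- ref$cohort_label
  attr(out, "provenance") <- prov
  out
}
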