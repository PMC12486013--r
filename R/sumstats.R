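## Canonical summary-statistics columns and their common aliases.
sumstats_aliases <- function() {
  list(chrom = c("chrom", "chr", "chromosome", "#chrom"),
       pos = c("pos", "bp", "position", "base_pair_location"),
       id = c("id", "snp", "rsid", "variant_id", "markername"),
       effect_allele = c("effect_allele", "ea", "a1", "allele1"),
       other_allele = c("other_allele", "oa", "a2", "allele2",
                        "non_effect_allele", "reference_allele"),
       beta = c("beta", "b", "effect", "effect_size"),
       se = c("se", "standard_error", "stderr"),
       p = c("p", "pval", "p_value", "pvalue"),
       n = c("n", "n_total", "sample_size"),
       af = c("af", "eaf", "effect_allele_frequency", "freq", "maf"))
}

#' Read GWAS summary statistics from TSV
#'
#' Reads a (optionally gzipped) tab-separated file into the canonical
#' per-variant schema (`chrom`, `pos`, `id`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `p`, `n`, `af`).  Column names are matched
#' case-insensitively against built-in aliases; `dialect` supplies extra
#' mappings (named character vector, foreign name -> canonical name).  Rows
#' whose beta or se cannot be parsed (or with `se <= 0`) are dropped with a
#' message.
#'
#' @param path file path (".gz" handled transparently).
#' @param dialect optional named character vector of column aliases.
#' @param study_label,ancestry_label provenance labels stored as attributes.
#' @return Summary-statistics data.frame.
#' @export
read_sumstats <- function(path, dialect = NULL, study_label = NULL,
                          ancestry_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  raw <- read.delim(con, stringsAsFactors = FALSE, check.names = FALSE)
  al <- sumstats_aliases()
  if (!is.null(dialect)) {
    for (i in seq_along(dialect)) {
      canon <- unname(dialect[i])
      al[[canon]] <- c(tolower(names(dialect)[i]), al[[canon]])
    }
  }
  lower <- tolower(names(raw))
  out <- list()
  for (canon in names(al)) {
    hit <- which(lower %in% al[[canon]])
    if (length(hit) == 0) {
      if (canon %in% c("id")) { out[[canon]] <- NA_character_; next }
      stop("required column missing from ", basename(path), ": ", canon)
    }
    out[[canon]] <- raw[[hit[1]]]
  }
  ss <- data.frame(out, stringsAsFactors = FALSE)
  ss$chrom <- as.character(ss$chrom)
  for (nm in c("pos", "beta", "se", "p", "n", "af"))
    ss[[nm]] <- suppressWarnings(as.numeric(ss[[nm]]))
  bad <- !is.finite(ss$beta) | !is.finite(ss$se) | ss$se <= 0
  if (any(bad)) {
    message("read_sumstats: dropped ", sum(bad),
            " row(s) with unparseable beta/se")
    ss <- ss[!bad, , drop = FALSE]
  }
  rownames(ss) <- NULL
  structure(ss, study_label = study_label, ancestry_label = ancestry_label,
            n_dropped_unparseable = sum(bad))
}

#' Write summary statistics to TSV
#'
#' Columns written: CHR, POS, ID, EA, OA, BETA, SE, P, N, EAF; gzipped when
#' `path` ends in ".gz".
#'
#' @param ss summary-statistics data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(CHR = ss$chrom, POS = as.integer(round(ss$pos)),
                    ID = ss$id,
                    EA = ss$effect_allele, OA = ss$other_allele,
                    BETA = ss$beta, SE = ss$se, P = ss$p, N = ss$n,
                    EAF = ss$af)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Variant QC filter specification
#'
#' Defaults follow standard WGS PRS practice: variants with minor allele
#' frequency at or below 0.01, or per-variant missing rate above 1%, are
#' excluded (both boundaries as stated: MAF <= bound removed, missing-rate
#' > bound removed).
#'
#' @param maf_min MAF bound (exclusive retention: MAF must exceed it).
#' @param missing_max missing-rate bound (inclusive retention).
#' @return A `variant_filter_spec` list.
#' @export
variant_filter_spec <- function(maf_min = 0.01, missing_max = 0.01) {
  stopifnot(maf_min >= 0, maf_min <= 1, missing_max >= 0, missing_max <= 1)
  structure(list(maf_min = maf_min, missing_max = missing_max),
            class = "variant_filter_spec")
}

#' QC-filter the variants of a genotype matrix
#'
#' Removes variants with empirical MAF `<= maf_min` or missing genotype
#' rate `> missing_max`; variant order is preserved.
#'
#' @param G a [genotype_matrix()].
#' @param spec a [variant_filter_spec()].
#' @return Filtered `genotype_matrix` with attribute `n_removed`.
#' @export
qc_filter_variants <- function(G, spec = variant_filter_spec()) {
  D <- G$dosages
  miss <- colMeans(is.na(D))
  af <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[!is.finite(maf)] <- 0
  keep <- maf > spec$maf_min & miss <= spec$missing_max
  out <- gm_subset(G, variant_idx = which(keep))
  attr(out, "n_removed") <- sum(!keep)
  out
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize summary statistics to a reference variant index
#'
#' Variants are matched on (chrom, pos).  Records whose alleles match the
#' reference orientation pass through; records with effect/other swapped
#' have beta negated, af reflected and alleles reoriented; strand-ambiguous
#' palindromic (A/T, C/G) records and allele-incompatible or unmatched
#' records are dropped.  Drop counts by reason are stored in attribute
#' `harmonization_log`.  The operation is idempotent.
#'
#' @param ss summary-statistics data.frame.
#' @param variant_index reference variant index (unique (chrom, pos) keys).
#' @return Harmonized summary statistics in reference allele orientation.
#' @export
harmonize_to_reference <- function(ss, variant_index) {
  if (anyDuplicated(variant_key(variant_index)))
    stop("reference variant index has duplicate (chrom, pos) keys")
  idx <- match(variant_key(ss), variant_key(variant_index))
  matched <- !is.na(idx)
  pal <- is_palindromic(ss$effect_allele, ss$other_allele)
  ref_ea <- variant_index$effect_allele[idx]
  ref_oa <- variant_index$other_allele[idx]
  same <- matched & !pal & ss$effect_allele == ref_ea & ss$other_allele == ref_oa
  swap <- matched & !pal & ss$effect_allele == ref_oa & ss$other_allele == ref_ea
  incompat <- matched & !pal & !same & !swap
  keep <- same | swap
  out <- ss[keep, , drop = FALSE]
  sw <- swap[keep]
  out$beta[sw] <- -out$beta[sw]
  out$af[sw] <- 1 - out$af[sw]
  ea <- out$effect_allele
  out$effect_allele[sw] <- out$other_allele[sw]
  out$other_allele[sw] <- ea[sw]
  rownames(out) <- NULL
  structure(out,
            study_label = attr(ss, "study_label"),
            ancestry_label = attr(ss, "ancestry_label"),
            harmonization_log = list(
              n_input = nrow(ss), n_kept = nrow(out), n_swapped = sum(sw),
              ambiguous_dropped = sum(pal & matched),
              incompatible_dropped = sum(incompat),
              unmatched_dropped = sum(!matched)))
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' For every variant present in at least one study:
#' `beta* = sum(beta_i / se_i^2) / sum(1 / se_i^2)`,
#' `se* = sqrt(1 / sum(1 / se_i^2))`, two-sided normal p, `n* = sum(n_i)`,
#' and af* the n-weighted mean frequency.  Studies must already be
#' harmonized to a common reference orientation.
#'
#' @param studies list of harmonized summary-statistics data.frames.
#' @return Meta-analyzed summary statistics (study label "META").
#' @export
meta_analyze_fixed <- function(studies) {
  if (!length(studies)) stop("need at least one study")
  all <- do.call(rbind, lapply(studies, function(s)
    s[, c("chrom", "pos", "id", "effect_allele", "other_allele",
          "beta", "se", "p", "n", "af")]))
  ok <- is.finite(all$beta) & is.finite(all$se) & all$se > 0
  all <- all[ok, , drop = FALSE]
  key <- variant_key(all)
  first <- !duplicated(key)
  ## allele orientation must agree across studies for a shared key
  ori <- tapply(paste(all$effect_allele, all$other_allele),
                key, function(x) length(unique(x)))
  if (any(ori > 1))
    stop("allele orientation conflict across studies; harmonize first")
  w <- 1 / all$se^2
  sw <- rowsum(w, key)
  swb <- rowsum(w * all$beta, key)
  sn <- rowsum(as.numeric(all$n), key)
  saf <- rowsum(all$af * as.numeric(all$n), key)
  out <- all[first, c("chrom", "pos", "id", "effect_allele", "other_allele")]
  k <- match(variant_key(out), rownames(sw))
  out$beta <- as.numeric(swb[k] / sw[k])
  out$se <- as.numeric(1 / sqrt(sw[k]))
  out$p <- wald_p(out$beta, out$se)
  out$n <- as.numeric(sn[k])
  out$af <- as.numeric(saf[k] / sn[k])
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, study_label = "META",
            n_studies = length(studies))
}
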