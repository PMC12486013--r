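#' Genotype dosage matrix
#'
#' Container for effect-allele dosages with a variant index and a sample
#' table.  Dosages are samples x variants, hard calls in \{0, 1, 2\} or
#' continuous in \[0, 2\]; `NA` marks missing genotypes.  The variant index
#' carries 1-based positions, allele labels and (optionally) per-ancestry
#' allele frequency columns named `af_<ancestry>`.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#' @param variants data.frame with columns `chrom`, `pos`, `id`,
#'   `effect_allele`, `other_allele` (one row per column of `dosages`).
#' @param samples data.frame with columns `sample_id` and `ancestry`
#'   (one row per row of `dosages`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, samples) {
  stopifnot(is.matrix(dosages), is.data.frame(variants), is.data.frame(samples))
  need_v <- c("chrom", "pos", "id", "effect_allele", "other_allele")
  if (!all(need_v %in% names(variants)))
    stop("variant index must have columns: ", paste(need_v, collapse = ", "))
  if (!all(c("sample_id", "ancestry") %in% names(samples)))
    stop("sample table must have columns sample_id, ancestry")
  if (nrow(variants) != ncol(dosages) || nrow(samples) != nrow(dosages))
    stop("dosage dimensions do not match variant/sample tables")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  ok_allele <- function(a) all(a %in% c("A", "C", "G", "T"))
  if (!ok_allele(variants$effect_allele) || !ok_allele(variants$other_allele))
    stop("alleles must be one of A, C, G, T")
  if (any(variants$effect_allele == variants$other_allele))
    stop("effect_allele must differ from other_allele")
  for (ch in unique(variants$chrom)) {
    if (is.unsorted(variants$pos[variants$chrom == ch]))
      stop("positions must be non-decreasing within chromosome ", ch)
  }
  if (anyDuplicated(variant_key(variants)))
    stop("duplicate (chrom, pos) keys in variant index")
  dimnames(dosages) <- list(samples$sample_id, variants$id)
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  tab <- table(x$samples$ancestry)
  cat("  ancestries:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples or variants
#'
#' @param G a [genotype_matrix()].
#' @param sample_ids character vector of sample ids to keep (in this order).
#' @param variant_idx integer or logical index into the variant table.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
gm_subset <- function(G, sample_ids = NULL, variant_idx = NULL) {
  d <- G$dosages; v <- G$variants; s <- G$samples
  if (!is.null(sample_ids)) {
    i <- match(sample_ids, s$sample_id)
    if (anyNA(i)) stop("unknown sample ids in subset")
    d <- d[i, , drop = FALSE]; s <- s[i, , drop = FALSE]
  }
  if (!is.null(variant_idx)) {
    d <- d[, variant_idx, drop = FALSE]; v <- v[variant_idx, , drop = FALSE]
  }
  rownames(s) <- NULL; rownames(v) <- NULL
  genotype_matrix(d, v, s)
}

## Stack two genotype matrices with identical variant indexes (row bind).
gm_rbind <- function(A, B) {
  stopifnot(identical(A$variants$id, B$variants$id))
  genotype_matrix(rbind(A$dosages, B$dosages), A$variants,
                  rbind(A$samples, B$samples))
}
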