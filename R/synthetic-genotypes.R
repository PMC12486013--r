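#' Draw ancestral allele frequencies
#'
#' @param m_variants number of variants.
#' @param model an [ancestry_model()] (supplies the ancestral AF range).
#' @param seed integer seed (optional).
#' @return Numeric vector of length `m_variants`, uniform on the model's
#'   `af_range`.
#' @export
draw_ancestral_frequencies <- function(m_variants, model, seed = NULL) {
  if (!is_count(m_variants)) stop("m_variants must be a positive integer")
  if (!inherits(model, "ancestry_model")) stop("model must be an ancestry_model")
  set_seed_if(seed)
  runif(m_variants, model$af_range[1], model$af_range[2])
}

#' Drift allele frequencies per ancestry (Balding-Nichols)
#'
#' Each ancestry's frequency is `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the
#' ancestral frequency `p`, so `E[af] = p` and `Var[af] = F p (1-p)`.
#' `F = 0` returns the ancestral frequencies unchanged.  Results are clamped
#' away from 0/1 so downstream thresholds stay finite.
#'
#' @param ancestral_afs ancestral frequencies in (0, 1).
#' @param model an [ancestry_model()].
#' @param seed integer seed (optional).
#' @return Matrix `m x K` with one column per ancestry label.
#' @export
drift_frequencies <- function(ancestral_afs, model, seed = NULL) {
  if (any(ancestral_afs <= 0 | ancestral_afs >= 1))
    stop("ancestral frequencies must lie strictly inside (0, 1)")
  set_seed_if(seed)
  m <- length(ancestral_afs)
  out <- matrix(NA_real_, m, length(model$labels),
                dimnames = list(NULL, model$labels))
  for (k in seq_along(model$labels)) {
    F <- model$fst[k]
    out[, k] <- if (F == 0) {
      ancestral_afs
    } else {
      rbeta(m, ancestral_afs * (1 - F) / F, (1 - ancestral_afs) * (1 - F) / F)
    }
  }
  pmin(pmax(out, 1e-4), 1 - 1e-4)
}

#' Build a variant index for simulated genotypes
#'
#' Variants are placed on chromosome "1" at `spacing_bp` intervals; when
#' `apoe_like = TRUE` the last variant becomes a designated large-effect
#' locus on chromosome "19" inside the APOE gene (GRCh38), so region
#' masking is exercised on realistic coordinates.  Allele pairs are drawn
#' from non-palindromic combinations (no A/T or C/G) unless
#' `palindromic_fraction > 0`.
#'
#' @param m_variants number of variants.
#' @param ld an [ld_block_spec()] (supplies spacing).
#' @param afs optional `m x K` per-ancestry AF matrix; appended as
#'   `af_<ancestry>` columns.
#' @param apoe_like place the last variant inside APOE on chr19?
#' @param palindromic_fraction fraction of variants given strand-ambiguous
#'   (A/T or C/G) allele pairs; default 0.
#' @param seed integer seed (optional).
#' @return data.frame variant index.
#' @export
make_variant_index <- function(m_variants, ld, afs = NULL, apoe_like = TRUE,
                               palindromic_fraction = 0, seed = NULL) {
  set_seed_if(seed)
  m <- m_variants
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("G", "A"),
                 c("C", "T"), c("G", "T"), c("T", "C"), c("T", "G"))
  pal <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  pick <- pairs[sample.int(nrow(pairs), m, replace = TRUE), , drop = FALSE]
  if (palindromic_fraction > 0) {
    is_pal <- runif(m) < palindromic_fraction
    if (any(is_pal))
      pick[is_pal, ] <- pal[sample.int(nrow(pal), sum(is_pal), replace = TRUE), ]
  }
  v <- data.frame(chrom = "1", pos = ld$spacing_bp * seq_len(m),
                  id = sprintf("var%05d", seq_len(m)),
                  effect_allele = pick[, 1], other_allele = pick[, 2],
                  stringsAsFactors = FALSE)
  if (apoe_like) {
    v$chrom[m] <- "19"; v$pos[m] <- 44907000L; v$id[m] <- "APOE_proxy"
    ## keep the designated locus non-palindromic so it survives harmonization
    v$effect_allele[m] <- "C"; v$other_allele[m] <- "T"
  }
  if (!is.null(afs)) {
    stopifnot(nrow(afs) == m)
    for (a in colnames(afs)) v[[paste0("af_", a)]] <- afs[, a]
  }
  v
}

block_ids <- function(variants, block_size) {
  ids <- integer(nrow(variants))
  off <- 0L
  for (ch in unique(variants$chrom)) {
    i <- which(variants$chrom == ch)
    ids[i] <- off + (seq_along(i) - 1L) %/% block_size + 1L
    off <- max(ids[i])
  }
  ids
}

#' Simulate genotype dosages with block LD
#'
#' Per haplotype, a latent standard normal with block-constant correlation
#' `rho` is thresholded at the ancestry-specific AF quantile; the dosage is
#' the sum of two independent haplotypes.  Within-block dosage r-squared
#' grows with `rho` and is ~0 across blocks.
#'
#' @param afs `m x K` per-ancestry AF matrix (columns named by ancestry).
#' @param ld an [ld_block_spec()].
#' @param n_per_ancestry named integer vector of sample counts per ancestry.
#' @param seed integer seed (optional).
#' @param variant_index optional variant index (from [make_variant_index()]);
#'   built with defaults when omitted.
#' @param missing_rate fraction of dosages set missing at random (default 0).
#' @return A [genotype_matrix()] with hard-call dosages.
#' @export
simulate_genotypes <- function(afs, ld, n_per_ancestry, seed = NULL,
                               variant_index = NULL, missing_rate = 0) {
  if (any(afs <= 0 | afs >= 1)) stop("allele frequencies must lie in (0, 1)")
  set_seed_if(seed)
  m <- nrow(afs)
  if (is.null(variant_index))
    variant_index <- make_variant_index(m, ld, afs = afs, seed = NULL)
  anc <- names(n_per_ancestry)
  if (is.null(anc) || !all(anc %in% colnames(afs)))
    stop("n_per_ancestry must be named by ancestry present in afs")
  blk <- block_ids(variant_index, ld$block_size)
  nblk <- max(blk)
  rho <- ld$rho
  dos_list <- vector("list", length(anc))
  smp_list <- vector("list", length(anc))
  for (k in seq_along(anc)) {
    a <- anc[k]; n <- as.integer(n_per_ancestry[[a]])
    thr <- qnorm(afs[, a])
    D <- matrix(0L, n, m)
    for (h in 1:2) {
      U <- matrix(rnorm(n * nblk), n, nblk)
      Z <- sqrt(rho) * U[, blk, drop = FALSE] +
        sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
      D <- D + (Z <= rep(thr, each = n))
    }
    storage.mode(D) <- "integer"
    dos_list[[k]] <- D
    smp_list[[k]] <- data.frame(sample_id = sprintf("%s_%05d", a, seq_len(n)),
                                ancestry = a, stringsAsFactors = FALSE)
  }
  D <- do.call(rbind, dos_list)
  if (missing_rate > 0) {
    miss <- runif(length(D)) < missing_rate
    D[miss] <- NA_integer_
  }
  genotype_matrix(D, variant_index, do.call(rbind, smp_list))
}
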