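#' Write / read a genotype matrix as TSV files
#'
#' Three files are written under `prefix`: `<prefix>_dosages.tsv`
#' (samples x variants, sample_id first column), `<prefix>_variants.tsv`
#' and `<prefix>_samples.tsv`.  Append ".gz" to `prefix` components via
#' `gz = TRUE`.
#'
#' @param G a [genotype_matrix()].
#' @param prefix output path prefix.
#' @param gz gzip the files?
#' @return Named character vector of the written paths, invisibly.
#' @export
write_genotype_tsv <- function(G, prefix, gz = FALSE) {
  ext <- if (gz) ".tsv.gz" else ".tsv"
  paths <- c(dosages = paste0(prefix, "_dosages", ext),
             variants = paste0(prefix, "_variants", ext),
             samples = paste0(prefix, "_samples", ext))
  wr <- function(df, path) {
    con <- if (gz) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  dd <- data.frame(sample_id = G$samples$sample_id, G$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  wr(dd, paths["dosages"])
  wr(G$variants, paths["variants"])
  wr(G$samples, paths["samples"])
  invisible(paths)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(prefix, gz = FALSE) {
  ext <- if (gz) ".tsv.gz" else ".tsv"
  rd <- function(path) {
    con <- if (gz) gzfile(path) else file(path)
    read.delim(con, stringsAsFactors = FALSE, check.names = FALSE)
  }
  dd <- rd(paste0(prefix, "_dosages", ext))
  v <- rd(paste0(prefix, "_variants", ext))
  s <- rd(paste0(prefix, "_samples", ext))
  v$chrom <- as.character(v$chrom)
  D <- as.matrix(dd[, -1, drop = FALSE])
  genotype_matrix(D, v, s)
}

#' Write a minimal dosage VCF
#'
#' VCFv4.2 with one FORMAT field (`DS`, effect-allele dosage).  REF is the
#' other allele and ALT the effect allele, so DS counts ALT copies.
#'
#' @param G a [genotype_matrix()].
#' @param path output path (".gz" writes through gzfile).
#' @return `path`, invisibly.
#' @export
write_vcf_dosage <- function(G, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect allele dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$samples$sample_id),
                     collapse = "\t")), con)
  v <- G$variants
  D <- G$dosages
  body <- vapply(seq_len(nrow(v)), function(j) {
    ds <- D[, j]
    ds <- ifelse(is.na(ds), ".", format(ds, trim = TRUE))
    paste(c(v$chrom[j], sprintf("%.0f", v$pos[j]), v$id[j], v$other_allele[j],
            v$effect_allele[j], ".", "PASS", ".", "DS", ds), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Write / read phenotype and kinship tables as TSV
#'
#' @param phen,kin data.frames as produced by [simulate_phenotypes()] and
#'   [simulate_related_pairs()].
#' @param path file path (".gz" supported).
#' @return `path` invisibly (writers); the data.frame (readers).
#' @export
write_phenotypes_tsv <- function(phen, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(phen, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  read.delim(con, stringsAsFactors = FALSE)
}

#' @rdname write_phenotypes_tsv
#' @export
write_kinship_tsv <- function(kin, path) {
  out <- data.frame(ID1 = kin$id1, ID2 = kin$id2, KIN = kin$kinship)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_kinship_tsv <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  raw <- read.delim(con, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  data.frame(id1 = as.character(raw$id1), id2 = as.character(raw$id2),
             kinship = as.numeric(raw$kin %||% raw$kinship),
             stringsAsFactors = FALSE)
}

#' Persist / restore a scaling reference as JSON
#'
#' @param ref a [scaling_reference()].
#' @param path JSON path.
#' @export
write_scaling_reference <- function(ref, path) {
  writeLines(jsonlite::toJSON(unclass(ref), auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}

#' @rdname write_scaling_reference
#' @export
read_scaling_reference <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaling_reference(x$mean, x$sd, x$cohort_label)
}
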