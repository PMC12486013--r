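#!/usr/bin/env Rscript

# Step 2: per-source PRS construction from the flat files written by step 1.
# For every source GWAS: harmonize to the reference variant index, build the
# full clumping + thresholding grid (r2 in {0.1, 0.2, 0.3}, windows
# {100, 250, 500} kb, eight p-value rungs from 5e-8 to 0.5), and pick the
# candidate whose association effect is most stable across five random
# unrelated tuning subsets (minimum coefficient of variation).
#
# Input:  results/data/     Output: results/prs/

library(multiprs)

SEED <- 2026L
ind <- "results/data"
out <- "results/prs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ref <- read_genotype_tsv(file.path(ind, "reference"), gz = TRUE)
tune <- read_genotype_tsv(file.path(ind, "tuning"), gz = TRUE)
tune_ph <- read_phenotypes_tsv(file.path(ind, "tuning_pheno.tsv.gz"))
tune_kin <- read_kinship_tsv(file.path(ind, "tuning_kinship.tsv"))

src_files <- list.files(ind, pattern = "^sumstats_.*\\.tsv\\.gz$")
grid <- ct_grid_spec()

for (f in src_files) {
  lab <- sub("^sumstats_(.*)\\.tsv\\.gz$", "\\1", f)
  ss <- read_sumstats(file.path(ind, f), study_label = lab)
  h <- harmonize_to_reference(ss, ref$variants)
  log <- attr(h, "harmonization_log")
  cat(sprintf("%s: %d/%d variants harmonized (%d ambiguous, %d unmatched)\n",
              lab, log$n_kept, log$n_input, log$ambiguous_dropped,
              log$unmatched_dropped))
  cands <- build_ct_grid(h, ref, grid)
  rep <- cv_select(cands, tune, tune_ph, kin = tune_kin, k = 5,
                   seed = SEED + 100)
  sel <- rep$table[rep$selected, ]
  cat(sprintf("  selected r2=%g window=%gkb p<=%g: %d variants, cv=%.3f\n",
              sel$r2, sel$window_kb, sel$p_threshold, sel$n_variants, sel$cv))
  write.table(rep$table, file.path(out, paste0("cv_grid_", lab, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_weight_table(cands[[rep$selected]]$weight_table,
                     file.path(out, paste0("best_", lab, ".tsv")))
}

cat("Done: per-source C+T selections under", out, "\n")
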