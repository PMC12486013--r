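#!/usr/bin/env Rscript

# Step 1: simulate the multi-ancestry study world and persist it as flat
# files, exactly the shapes the real pipeline would read: per-source GWAS
# summary statistics, genotype dosage tables, phenotype tables and kinship
# tables for each cohort (reference / tuning / training / evaluation /
# validation).
#
# Output: results/data/

library(multiprs)

SEED <- 2026L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

world <- simulate_prs_study(seed = SEED)

cat("Simulated", nrow(world$variant_index), "variants across",
    length(unique(world$variant_index$chrom)), "chromosomes\n")

for (lab in names(world$sources)) {
  src <- world$sources[[lab]]
  path <- file.path(out, paste0("sumstats_", lab, ".tsv.gz"))
  write_sumstats(src$sumstats, path)
  cat(sprintf("source %-10s (%s, n_eff = %d): %d variants -> %s\n",
              lab, src$ancestry, src$n_effective, nrow(src$sumstats),
              basename(path)))
}

for (nm in names(world$cohorts)) {
  co <- world$cohorts[[nm]]
  write_genotype_tsv(co$geno, file.path(out, nm), gz = TRUE)
  write_phenotypes_tsv(co$phen, file.path(out, paste0(nm, "_pheno.tsv.gz")))
  write_kinship_tsv(co$kin, file.path(out, paste0(nm, "_kinship.tsv")))
  cat(sprintf("cohort %-10s: n = %4d (%d cases, %d related pairs on file)\n",
              nm, nrow(co$phen), sum(co$phen$ad_status),
              sum(co$kin$kinship >= 0.25 & grepl("sibA", co$kin$id1))))
}

# a dosage VCF for the validation cohort, for tools that prefer VCF input
write_vcf_dosage(world$cohorts$validation$geno,
                 file.path(out, "validation.vcf.gz"))

cat("Done: study data under", out, "\n")
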