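# The flipping-SNP screen: call genotype flips against the cohort
# consensus, count hom->het flips in 100-kb windows, and flag candidate
# horizontal-transfer regions by joint MAD/Cook's-distance outlier
# detection.

source("analysis/00_config.R")

man <- run_pipeline(CONFIG, stages = "screen", outdir = OUTDIR)

scan <- readRDS(file.path(OUTDIR, "scan.rds"))
if (nrow(scan$regions) == 0L) {
  cat("No horizontal transfer detected.\n")
} else {
  cat("Candidate regions (one row per tumor and region):\n")
  print(scan$regions[, c("chrom", "start", "end", "sample_id",
                         "n_flipping_snps")])
  cat("Tumors flagged:",
      paste(sort(unique(scan$regions$sample_id)), collapse = ", "), "\n")
}
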