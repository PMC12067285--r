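# Genotype every tumor at every panel site through the purity/copy-number
# mixture model and form the cohort consensus state per site.

source("analysis/00_config.R")

man <- run_pipeline(CONFIG, stages = "genotype", outdir = OUTDIR)

g <- readRDS(file.path(OUTDIR, "genotypes.rds"))
cat("Consensus states:\n")
print(table(g$cons))
cat("Written: genotype_states.tsv\n")
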