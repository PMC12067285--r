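# Simulate the synthetic transmissible-cancer cohort: germline panel read
# counts for 47 tumors and matched hosts, copy-number segments, breakpoint
# junctions, origin-labelled somatic mutations, and allele-level RNA counts,
# with the full ground truth recorded alongside.

source("analysis/00_config.R")

man <- run_pipeline(CONFIG, stages = "simulate", outdir = OUTDIR)

cohort <- readRDS(file.path(OUTDIR, "cohort.rds"))
cat("Simulated", sum(cohort$samples$type == "tumor"), "tumors (",
    length(cohort$truth$carrier_ids), "carriers ) over",
    nrow(cohort$panel$sites), "panel sites;",
    nrow(cohort$somatic$mutations), "somatic mutation records\n")
cat("Outputs under", OUTDIR, "\n")
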