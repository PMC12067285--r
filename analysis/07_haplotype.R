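# Infer the donor haplotype carried by the transferred element: subtract
# the parental allele dosage (from the non-carrier consensus) from carrier
# read counts inside the step segments and call the extra copy's allele by
# summed likelihood across carriers.

source("analysis/00_config.R")

man <- run_pipeline(CONFIG, stages = "haplotype", outdir = OUTDIR)
ht <- attr(man, "results")$haplotype
cat("Sites evaluated:", nrow(ht), " determined:",
    sum(ht$ht_allele != "undetermined"), "\n")

# concordance with the simulation's donor genotypes
cohort <- readRDS(file.path(OUTDIR, "cohort.rds"))
truth <- cohort$truth$donor_genotypes
det <- ht$ht_allele != "undetermined"
m <- match(ht$site, truth$site)
true_allele <- ifelse(truth$donor_alt[m] == 1L, "alt", "ref")
cat(sprintf("Concordance with planted donor haplotype: %.4f\n",
            mean(ht$ht_allele[det] == true_allele[det])))
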