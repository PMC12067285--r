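# Date the transferred element with the CpG C>T molecular clock: estimate
# the parental per-copy density from non-carrier tumors in the step
# segments, subtract it from carrier counts to isolate the transferred
# copy's density, and convert to years at the per-copy rate.

source("analysis/00_config.R")

man <- run_pipeline(CONFIG, stages = "date", outdir = OUTDIR)
est <- attr(man, "results")$date
print(est)
cat("Planted acquisition time:", CONFIG$ht_acquisition_years, "years\n")
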