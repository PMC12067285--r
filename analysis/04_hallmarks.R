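# Validate each candidate region with the three hallmarks of horizontal
# transfer: a +1 integer copy-number step in carriers, somatic mutations at
# dosage 1/3 (not 2/3) in copy-number-3 regions, and a per-copy mutation
# density deficit in the footprint relative to its flanks.

source("analysis/00_config.R")

man <- run_pipeline(CONFIG, stages = "hallmarks", outdir = OUTDIR)

reps <- attr(man, "results")$hallmarks
for (hr in reps) {
  cat(sprintf(
    "region %s:%d-%d  cn step pass: %s | VAF 2/3 fraction: %.3f (pass %s) | mean per-copy deficit: %.1f%%\n",
    hr$region$chrom, hr$region$start, hr$region$end,
    hr$cn_step$pass, hr$vaf_pattern$fraction_two_thirds, hr$vaf_pattern$pass,
    mean(vapply(hr$density, function(d) d$percent_reduction, numeric(1)))))
}
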