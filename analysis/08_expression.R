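# Allelic deconvolution of bulk RNA counts: attribute informative-allele
# reads to the transferred element, the cancer parental chromosomes or
# infiltrating host cells, normalize per genomic copy, and compare the
# element's per-gene expression against the cancer and host programs.

source("analysis/00_config.R")

man <- run_pipeline(CONFIG, stages = "expression", outdir = OUTDIR)
dec <- attr(man, "results")$expression
cat("(gene, source) records:\n")
print(table(dec$records$source))
cat(sprintf("element vs cancer: r = %.3f (p = %.2g, slope = %.2f)\n",
            dec$ht_vs_cancer$r, dec$ht_vs_cancer$p_value,
            dec$ht_vs_cancer$slope))
cat(sprintf("element vs host:   r = %.3f (p = %.2g)\n",
            dec$ht_vs_host$r, dec$ht_vs_host$p_value))
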