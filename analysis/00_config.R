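# Shared settings for the analysis workflow. Every script can be run on its
# own from the repository root (Rscript analysis/01_simulate.R ...); stages
# communicate through results/pipeline/.

library(hgtscreen)

SEED <- 1L
OUTDIR <- "results/pipeline"
dir.create(OUTDIR, showWarnings = FALSE, recursive = TRUE)

# Study-scale cohort: 47 tumors (7-tumor carrier clade), depth 77x,
# a three-block 8-Mb element on a 339-Mb four-chromosome genome.
CONFIG <- sim_config(seed = SEED)
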