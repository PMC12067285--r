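# Reduced cohort configuration for module tests: the same model and noise
# structure as the default study-scale configuration, but a smaller genome,
# fewer tumors and fewer panel sites so that each simulation runs in about
# a second. The planted element still occupies < 3% of screening windows.
small_config <- function(seed = 1L, ...) {
  defaults <- list(
    n_tumors = 24L, clade_sizes = c(4L, 20L), carrier_clade = 1L,
    chrom_lengths = c("7" = 30e6, "1" = 25e6, "8" = 25e6),
    ht_blocks = data.frame(
      chrom = c("7", "1"), start = c(10000001, 5000001),
      end = c(12000000, 6000000), orientation = c("+", "-"),
      stringsAsFactors = FALSE),
    n_sites = 40000L, rna_genes = 160L, somatic_flank_mb = 2,
    seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# default planted clock densities, shared across clock tests
PARENTAL_DENSITY <- 2.21e-3
HT_DENSITY <- 6.89e-4
RATE_PER_COPY <- 3.435e-7
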