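test_that("config validation rejects impossible settings", {
  expect_error(small_config(clade_sizes = c(5L, 20L)), "sum to n_tumors")
  expect_error(small_config(founder_het_rate = 1.2), "\\[0, 1\\]")
  expect_error(small_config(purity_range = c(0, 0.9)), "purity_range")
  expect_error(small_config(ht_acquisition_years = 3000,
                            clade_split_years = 2006), "must not exceed")
  expect_error(small_config(ht_blocks = data.frame(
    chrom = c("7", "7"), start = c(1e6 + 1, 2e6 + 1), end = c(3e6, 4e6),
    orientation = c("+", "+"))), "overlap")
})

test_that("zero somatic rate yields an empty mutation origin set", {
  co <- simulate_cohort(small_config(seed = 2, somatic_rate_per_copy = 0),
                        components = c("cn", "somatic"))
  expect_identical(length(co$truth$per_mutation_origin), 0L)
  expect_identical(nrow(co$somatic$mutations), 0L)
})

test_that("identical config and seed reproduce identical cohorts", {
  cfg <- small_config(seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$panel$ref_reads, b$panel$ref_reads)
  expect_identical(a$panel$alt_reads, b$panel$alt_reads)
  expect_identical(a$cn, b$cn)
  expect_identical(a$junctions, b$junctions)
  expect_identical(a$somatic$mutations, b$somatic$mutations)
  expect_identical(a$rna, b$rna)
})

test_that("a 47-tumor cohort with a 7-tumor carrier clade has 7 carriers and a +1 copy step", {
  cfg <- sim_config(n_tumors = 47L, clade_sizes = c(7L, 40L),
                    carrier_clade = 1L, seed = 3)
  co <- simulate_cohort(cfg, components = "cn")
  expect_length(co$truth$carrier_ids, 7L)
  # carrier/non-carrier CN difference inside every planted block is exactly +1
  blocks <- co$truth$planted_blocks
  tumors <- co$samples$sample_id[co$samples$type == "tumor"]
  for (i in seq_len(nrow(blocks))) {
    mid <- floor((blocks$start[i] + blocks$end[i]) / 2)
    cn_at <- vapply(tumors, function(id) {
      s <- co$cn[co$cn$sample == id & co$cn$chrom == blocks$chrom[i] &
                   co$cn$start <= mid & co$cn$end >= mid, ]
      s$total_cn[1]
    }, numeric(1))
    carrier <- tumors %in% co$truth$carrier_ids
    expect_true(all(cn_at[carrier] == 3L) && all(cn_at[!carrier] == 2L))
  }
})

test_that("founder heterozygosity matches its binomial sampling rate", {
  cfg <- small_config(seed = 4, n_sites = 10000L, founder_het_rate = 0.3)
  co <- simulate_cohort(cfg, components = "panel")
  het_frac <- mean(co$truth$founder_dosage == 1L)
  sd3 <- 3 * sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(het_frac - 0.3), sd3)
})

test_that("emit_read_counts follows the purity mixture model", {
  # heterozygous site at purity 1: alt fraction near 1/2
  rc <- emit_read_counts(1, 2, 1, 0, depth_mean = 10000, seed = 1)
  expect_lt(abs(rc$alt_reads / (rc$ref_reads + rc$alt_reads) - 0.5),
            3 * sqrt(0.25 / 10000))
  # absent allele in tumor and host: no alternate reads
  rc0 <- emit_read_counts(rep(0, 50), 2, 0.9, 0, depth_mean = 80, seed = 2)
  expect_true(all(rc0$alt_reads == 0))
  # dosage 1 of CN 3 at purity 0.8 with a heterozygous host:
  # expected fraction (0.8 + 0.2) / (2.4 + 0.4) = 0.357
  rc3 <- emit_read_counts(rep(1, 4000), 3, 0.8, 1, depth_mean = 80, seed = 3)
  vafs <- rc3$alt_reads / (rc3$ref_reads + rc3$alt_reads)
  expect_lt(abs(mean(vafs) - 1 / 2.8), 3 * sd(vafs) / sqrt(4000))
  expect_error(emit_read_counts(1, 2, 0, 0, 80), "purity")
  expect_error(emit_read_counts(3, 2, 1, 0, 80), "alt_copies")
})

test_that("somatic burden per copy matches rate times branch length", {
  # Poisson oracle on a reduced cohort: the per-copy per-site density on a
  # non-carrier's parental chromosomes is rate * lineage age
  cfg0 <- small_config(n_tumors = 6L, clade_sizes = c(2L, 4L))
  reps <- 8L
  dens <- ht_dens <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- small_config(seed = 100 + r, n_tumors = 6L,
                        clade_sizes = c(2L, 4L))
    co <- simulate_cohort(cfg, components = c("cn", "somatic"))
    reg_len <- sum(cfg$somatic_regions$end - cfg$somatic_regions$start + 1)
    mm <- mutations_for_sample(co$somatic$mutations, "T06",
                               co$truth$clades[["T06"]])
    dens[r] <- nrow(mm) / (2 * reg_len)
    ht <- co$somatic$mutations[co$somatic$mutations$origin == "ht_haplotype" &
                                 !is.na(co$somatic$mutations$sample) &
                                 co$somatic$mutations$sample == "T01", ]
    blk_len <- sum(cfg$ht_blocks$end - cfg$ht_blocks$start + 1)
    ht_dens[r] <- nrow(ht) / blk_len
  }
  exp_par <- cfg0$somatic_rate_per_copy * cfg0$lineage_age_years
  se <- sd(dens) / sqrt(reps)
  expect_lt(abs(mean(dens) - exp_par), 2 * se)
  # transferred-copy density equals rate * acquisition time
  exp_ht <- cfg0$somatic_rate_per_copy * cfg0$ht_acquisition_years
  se_ht <- sd(ht_dens) / sqrt(reps)
  expect_lt(abs(mean(ht_dens) - exp_ht), 2 * se_ht)
})

test_that("clock-count generator plants the requested densities", {
  sim <- simulate_clock_counts(7, 40, n_bins = 5000, cpg_per_bin = 10,
                               parental_density = PARENTAL_DENSITY,
                               ht_density = HT_DENSITY, seed = 9)
  expect_identical(dim(sim$counts), c(5000L, 47L))
  lam_nc <- PARENTAL_DENSITY * 2 * sum(sim$cpg_sites)
  tot_nc <- colSums(sim$counts[, sim$noncarriers])
  expect_lt(abs(mean(tot_nc) - lam_nc), 3 * sd(tot_nc) / sqrt(40))
})
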