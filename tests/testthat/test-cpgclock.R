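seg4 <- function(sample, cn, chrom = "7", start = 1, end = 10e6)
  data.frame(chrom = chrom, start = start, end = end, sample = sample,
             total_cn = cn, stringsAsFactors = FALSE)

test_that("informative segments need a low-copy modal state and a +1 step", {
  carriers <- paste0("C", 1:3); noncarriers <- paste0("N", 1:5)
  mk <- function(cn_car, cn_non) rbind(
    do.call(rbind, lapply(carriers, seg4, cn = cn_car)),
    do.call(rbind, lapply(noncarriers, seg4, cn = cn_non)))
  expect_identical(nrow(select_informative_segments(mk(3L, 2L), carriers,
                                                    noncarriers)), 1L)
  # modal non-carrier state must be 0, 1 or 2
  expect_identical(nrow(select_informative_segments(mk(4L, 3L), carriers,
                                                    noncarriers)), 0L)
  # step must be exactly one
  expect_identical(nrow(select_informative_segments(mk(3L, 1L), carriers,
                                                    noncarriers)), 0L)
  sel <- select_informative_segments(mk(2L, 1L), carriers, noncarriers)
  expect_identical(sel$cn_noncarrier, 1L)
})

test_that("parental density is per-copy normalized and zero for empty input", {
  counts <- matrix(0L, 10, 3, dimnames = list(NULL, paste0("N", 1:3)))
  cpg <- rep(10, 10)
  pd <- parental_density(counts, cpg, 2L, paste0("N", 1:3))
  expect_equal(pd$mean, 0)
  # doubling both counts and copy number leaves the density unchanged
  set.seed(2)
  counts2 <- matrix(rpois(30, 5), 10, 3,
                    dimnames = list(NULL, paste0("N", 1:3)))
  a <- parental_density(counts2, cpg, 2L, paste0("N", 1:3))
  b <- parental_density(2L * counts2, cpg, 4L, paste0("N", 1:3))
  expect_equal(a$mean, b$mean)
  expect_equal(a$per_bin, b$per_bin)
})

test_that("the subtraction estimator recovers planted clock densities", {
  sim <- simulate_clock_counts(7, 40, n_bins = 4e4, cpg_per_bin = 10,
                               parental_density = PARENTAL_DENSITY,
                               ht_density = HT_DENSITY, seed = 11)
  par <- parental_density(sim$counts, sim$cpg_sites, sim$parental_cn,
                          sim$noncarriers)
  expect_lt(abs(par$mean - PARENTAL_DENSITY), 2 * par$se)
  ht <- ht_density(sim$counts, sim$cpg_sites, par$per_bin, sim$parental_cn,
                   sim$carriers)
  expect_lt(abs(ht$d_h - HT_DENSITY), 2 * ht$se)
  expect_true(ht$range[1] <= ht$d_h && ht$d_h <= ht$range[2])
})

test_that("a freshly transferred copy dates to approximately zero", {
  sim <- simulate_clock_counts(7, 40, n_bins = 2e4, ht_density = 0,
                               parental_density = PARENTAL_DENSITY,
                               seed = 12)
  par <- parental_density(sim$counts, sim$cpg_sites, sim$parental_cn,
                          sim$noncarriers)
  ht <- ht_density(sim$counts, sim$cpg_sites, par$per_bin, sim$parental_cn,
                   sim$carriers)
  expect_lt(abs(ht$d_h), 2 * ht$se)
  expect_gte(ht$d_h_reported, 0)
})

test_that("a duplication decoy inherits the parental density, not zero", {
  # the extra copy is a parental duplicate as old as the lineage: the
  # subtraction estimator attributes a parental-level density to it,
  # cleanly separating old duplication from recent transfer
  cfg <- small_config(seed = 13, decoy_duplication = TRUE,
                      decoy_duplication_years = 6434)
  co <- simulate_cohort(cfg, components = c("cn", "somatic"))
  est <- estimate_ht_age(co)
  expect_gt(est$ht$d_h, est$parental$mean - 4 * est$ht$se)
  expect_gt(est$ht$d_h, 5 * est$ht$se)   # far from zero
})

test_that("density converts to years exactly at the published rate", {
  expect_identical(density_to_years(6.89e-4, 0, 6.87e-7)$age_years, 2006)
  expect_identical(density_to_years(7.96e-4, 0, 6.87e-7)$age_years, 2317)
  expect_identical(density_to_years(0, 0, 6.87e-7)$age_years, 0)
  expect_error(density_to_years(6.89e-4, 0, 0), "positive")
  # linearity: halving the rate doubles the age exactly
  a <- density_to_years(6.89e-4, 1e-5, 6.87e-7)
  b <- density_to_years(6.89e-4, 1e-5, 6.87e-7 / 2)
  expect_equal(b$age_raw, 2 * a$age_raw)
  expect_equal(b$ci_years, 2 * a$ci_years)
})

test_that("the dating CI covers the planted acquisition time", {
  planted_years <- 2000
  covered <- 0L
  for (r in 1:20) {
    sim <- simulate_clock_counts(7, 40, n_bins = 2e4,
                                 parental_density = PARENTAL_DENSITY,
                                 ht_density = RATE_PER_COPY * planted_years,
                                 seed = 400 + r)
    par <- parental_density(sim$counts, sim$cpg_sites, sim$parental_cn,
                            sim$noncarriers)
    ht <- ht_density(sim$counts, sim$cpg_sites, par$per_bin,
                     sim$parental_cn, sim$carriers)
    age <- density_to_years(ht$d_h, ht$se)
    if (age$ci_years[1] <= planted_years &&
        planted_years <= age$ci_years[2]) covered <- covered + 1L
  }
  expect_gte(covered, 17L)
})

test_that("end-to-end cohort dating recovers the planted acquisition time", {
  cfg <- small_config(seed = 14)
  co <- simulate_cohort(cfg, components = c("cn", "somatic"))
  est <- estimate_ht_age(co)
  # trunk mutations are a single Poisson realization shared by every tumor,
  # so the across-tumor SE misses that component; include it explicitly
  n_cpg <- sum(cfg$ht_blocks$end - cfg$ht_blocks$start + 1) *
    cfg$cpg_fraction
  trunk_sd <- sqrt(cfg$somatic_rate_per_copy *
                     (cfg$lineage_age_years - cfg$clade_split_years) *
                     2 * n_cpg) / (2 * n_cpg)
  expect_lt(abs(est$parental$mean - PARENTAL_DENSITY),
            3 * (est$parental$se + trunk_sd))
  expect_true(est$age$ci_years[1] <= 2006 && 2006 <= est$age$ci_years[2])
})
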