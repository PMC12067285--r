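# build a minimal genotype structure around hand-written states
mini_geno <- function(states) {
  list(state = states)
}

test_that("flip calls record conflicts with the consensus, in both directions", {
  sites <- data.frame(chrom = "7", pos = c(1e6, 2e6, 3e6),
                      ref_allele = "A", alt_allele = "C",
                      stringsAsFactors = FALSE)
  states <- cbind(T1 = c("het", "hom_ref", "het"),
                  T2 = c("hom_ref", "hom_ref", "het"),
                  T3 = c("hom_ref", "het", "het"))
  cons <- c("hom", "hom", "het")
  # permissive het filter so all three sites are eligible
  fl <- call_flipping_snps(mini_geno(states), cons, sites,
                           min_het_fraction = 0)
  expect_identical(fl$direction[fl$sample_id == "T1" & fl$pos == 1e6],
                   "hom_to_het")
  expect_identical(fl$direction[fl$sample_id == "T3" & fl$pos == 2e6],
                   "hom_to_het")
  # a tumor agreeing with the consensus makes no call
  expect_false(any(fl$sample_id == "T2"))
  # het -> hom direction
  states2 <- cbind(T1 = c("het", "het", "hom_alt"))
  fl2 <- call_flipping_snps(mini_geno(states2), cons, sites,
                            min_het_fraction = 0)
  expect_identical(fl2$direction[fl2$pos == 3e6], "het_to_hom")
})

test_that("an all-zero flip landscape yields no candidate regions", {
  empty <- data.frame(site = integer(0), chrom = character(0),
                      pos = integer(0), sample_id = character(0),
                      direction = character(0), stringsAsFactors = FALSE)
  scan <- detect_candidate_regions(empty, c("7" = 50e6), c("T1", "T2"))
  expect_identical(nrow(scan$regions), 0L)
})

test_that("null flip noise produces almost no false-positive regions", {
  # Poisson(0.2) background in every window, no planted element; across
  # 100 seeds the family-wise count of reported regions stays <= 5
  n_fp <- 0L
  chrom_lengths <- c("1" = 200e6)   # 2,000 windows
  for (s in 1:100) {
    set.seed(2000 + s)
    rows <- list()
    for (tum in c("T1", "T2", "T3", "T4", "T5")) {
      cnt <- rpois(2000, 0.2)
      nz <- which(cnt > 0)
      if (!length(nz)) next
      pos <- rep((nz - 1) * 1e5 + 50000, cnt[nz])
      rows[[tum]] <- data.frame(site = seq_along(pos), chrom = "1",
                                pos = pos, sample_id = tum,
                                direction = "hom_to_het",
                                stringsAsFactors = FALSE)
    }
    flips <- do.call(rbind, rows)
    scan <- detect_candidate_regions(flips, chrom_lengths,
                                     sprintf("T%d", 1:5))
    n_fp <- n_fp + nrow(scan$regions)
  }
  expect_lte(n_fp, 5L)
})

test_that("carriers are flagged with the planted block recovered; non-carriers are not", {
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    cfg <- small_config(seed = 300 + s)
    co <- simulate_cohort(cfg, components = c("panel", "cn"))
    scan <- run_flipping_screen(co)
    flagged <- sort(unique(scan$regions$sample_id))
    expect_identical(flagged, sort(co$truth$carrier_ids))
    # the 2-Mb chr7 block is recovered at >= 95% reciprocal overlap
    blk <- cfg$ht_blocks[cfg$ht_blocks$chrom == "7", ]
    r7 <- scan$regions[scan$regions$chrom == "7", ]
    for (i in seq_len(nrow(r7))) {
      ov <- min(r7$end[i], blk$end) - max(r7$start[i], blk$start) + 1
      total <- total + 1L
      if (ov / max(r7$end[i] - r7$start[i] + 1, blk$end - blk$start + 1)
          >= 0.95) hits <- hits + 1L
    }
    # per-site sensitivity: at the flip-defining sites (founder homozygous,
    # donor allele different), carriers are called hom -> het
    sites <- co$panel$sites
    donor <- co$truth$donor_genotypes
    founder <- co$truth$founder_dosage
    flip_sites <- donor$site[founder[donor$site] %in% c(0L, 2L) &
                               donor$donor_alt != founder[donor$site] / 2L]
    car <- co$truth$carrier_ids[1]
    called <- scan$flips$site[scan$flips$sample_id == car &
                                scan$flips$direction == "hom_to_het"]
    expect_gt(mean(flip_sites %in% called), 0.90)
  }
  expect_gte(hits / total, 0.95)
})

test_that("screen output is invariant to sample and chromosome order", {
  cfg <- small_config(seed = 31)
  co <- simulate_cohort(cfg, components = c("panel", "cn"))
  geno <- genotype_cohort(co$panel, co$samples, co$cn)
  cons <- consensus_state(geno$state)
  flips <- call_flipping_snps(geno, cons, co$panel$sites)
  tumors <- co$samples$sample_id[co$samples$type == "tumor"]
  base <- detect_candidate_regions(flips, cfg$chrom_lengths, tumors)
  perm <- detect_candidate_regions(flips[sample(nrow(flips)), ],
                                   cfg$chrom_lengths[c(3, 1, 2)],
                                   rev(tumors))
  sort_regions <- function(r)
    r[order(r$chrom, r$start, r$sample_id),
      c("chrom", "start", "end", "sample_id", "n_flipping_snps")]
  a <- sort_regions(base$regions); b <- sort_regions(perm$regions)
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("region flip counts agree with the flip calls they contain", {
  cfg <- small_config(seed = 32)
  co <- simulate_cohort(cfg, components = c("panel", "cn"))
  scan <- run_flipping_screen(co)
  for (i in seq_len(nrow(scan$regions))) {
    r <- scan$regions[i, ]
    n <- sum(scan$flips$sample_id == r$sample_id &
               scan$flips$chrom == r$chrom &
               scan$flips$pos >= r$start & scan$flips$pos <= r$end)
    expect_identical(r$n_flipping_snps, n)
  }
})
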