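test_that("informative alleles are those unique to one source", {
  # allele present in host, cancer and the element: not informative
  r <- find_informative_alleles(host_dosage = 1L, cancer_dosage = 1L,
                                ht_allele = 1L)
  expect_false(r$informative[r$allele == "alt"])
  # allele carried only by the transferred haplotype: informative, 1 copy
  r2 <- find_informative_alleles(host_dosage = 0L, cancer_dosage = 0L,
                                 ht_allele = 1L)
  alt2 <- r2[r2$allele == "alt", ]
  expect_true(alt2$informative)
  expect_identical(alt2$source, "HT")
  expect_identical(alt2$copy_number, 1L)
  # without the element as a source, a host-only allele is informative
  r3 <- find_informative_alleles(host_dosage = 2L, cancer_dosage = 0L,
                                 ht_allele = NA)
  alt3 <- r3[r3$allele == "alt", ]
  expect_identical(alt3$source, "host")
  expect_identical(alt3$copy_number, 2L)
})

test_that("informative-allele enumeration agrees with brute force", {
  set.seed(21)
  n <- 1e4
  host <- sample(0:2, n, replace = TRUE)
  canc <- sample(0:2, n, replace = TRUE)
  ht <- sample(c(0L, 1L, NA), n, replace = TRUE)
  out <- find_informative_alleles(host, canc, 2L, ht)
  for (allele in c("ref", "alt")) {
    sub <- out[out$allele == allele, ]
    cnt <- cbind(
      HT = ifelse(is.na(ht), 0L, if (allele == "alt") ht else 1L - ht),
      cancer = if (allele == "alt") canc else 2L - canc,
      host = if (allele == "alt") host else 2L - host)
    n_src <- rowSums(cnt > 0)
    expect_identical(sub$informative, n_src == 1L)
    idx <- which(n_src == 1L)
    src <- colnames(cnt)[apply(cnt[idx, ] > 0, 1L, which)]
    expect_identical(sub$source[idx], src)
    expect_identical(sub$copy_number[idx], cnt[cbind(idx, match(src, colnames(cnt)))])
  }
})

test_that("per-copy expression divides by copy number and size factor", {
  obs <- data.frame(
    gene = c("G1", "G1"), source = "cancer", sample = c("S1", "S2"),
    count = c(30, 60), copy_number = c(1L, 2L), stringsAsFactors = FALSE)
  sf <- c(S1 = 1, S2 = 1)
  rec <- per_copy_expression(obs, sf, min_reads = 1)
  # 30 reads on a 1-copy allele equal 60 reads on a 2-copy allele
  expect_equal(rec$mean_per_copy, 30)
  expect_identical(rec$n_tumors, 2L)
})

test_that("median-of-ratios matches the hand computation and rescaling cancels", {
  counts <- rbind(c(100, 200), c(50, 100), c(10, 20), c(80, 160))
  colnames(counts) <- c("S1", "S2")
  sf <- size_factors(counts)
  # every gene ratio is exactly sqrt(2) apart: sf proportional to (1, 2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # per-copy expression identical across the two scaled samples
  obs <- data.frame(gene = paste0("G", c(1, 1)), source = "cancer",
                    sample = c("S1", "S2"), count = c(100, 200),
                    copy_number = 1L, stringsAsFactors = FALSE)
  rec <- per_copy_expression(obs, sf, min_reads = 1)
  expect_equal(rec$ci_lo, rec$mean_per_copy)   # both observations equal
  # independent cross-check of the size factors
  dsf <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(sf / sf[1]), unname(dsf / dsf[1]), tolerance = 1e-8)
})

test_that("compare_sources fits OLS with Pearson correlation", {
  x <- c(1, 2, 3, 4, 5)
  r <- compare_sources(x, x)
  expect_equal(r$r, 1)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_true(is.na(compare_sources(x, rep(2, 5))$r))
  expect_true(is.na(compare_sources(x[1:2], x[1:2])$r))
})

test_that("independent programs show null correlation at 73 genes", {
  n_small <- 0L
  for (s in 1:100) {
    set.seed(600 + s)
    a <- rlnorm(73); b <- rlnorm(73)
    if (abs(compare_sources(a, b)$r) < 0.3) n_small <- n_small + 1L
  }
  expect_gte(n_small, 95L)
})

test_that("element expression follows the cancer program, not the host program", {
  wins <- 0L
  for (s in 1:60) {
    co <- simulate_cohort(small_config(seed = 800 + s,
                                       clade_sizes = c(7L, 17L)),
                          components = "rna")
    dec <- deconvolve_expression(co)
    if (is.na(dec$ht_vs_cancer$r) || is.na(dec$ht_vs_host$r)) next
    wins <- wins + (dec$ht_vs_cancer$r > dec$ht_vs_host$r)
  }
  expect_gte(wins, 57L)
})

test_that("element per-copy means agree with cancer per-copy means", {
  n_overlap <- 0L; n_total <- 0L
  for (s in 1:5) {
    co <- simulate_cohort(small_config(seed = 900 + s,
                                       clade_sizes = c(7L, 17L)),
                          components = "rna")
    dec <- deconvolve_expression(co)
    r <- dec$records
    m <- dec$means
    g <- rownames(m)[!is.na(m[, "HT"]) & !is.na(m[, "cancer"])]
    rc <- r[r$source == "cancer" & r$gene %in% g, ]
    rh <- r[r$source == "HT" & r$gene %in% g, ]
    rc <- rc[match(g, rc$gene), ]; rh <- rh[match(g, rh$gene), ]
    ok <- !is.na(rh$ci_lo) & !is.na(rc$ci_lo)
    n_total <- n_total + sum(ok)
    n_overlap <- n_overlap + sum(rh$ci_hi[ok] >= rc$ci_lo[ok] &
                                   rc$ci_hi[ok] >= rh$ci_lo[ok])
  }
  expect_gte(n_overlap / n_total, 0.9)
})

test_that("pooling order does not change reported means", {
  co <- simulate_cohort(small_config(seed = 77, clade_sizes = c(7L, 17L)),
                        components = "rna")
  dec1 <- deconvolve_expression(co)
  rna2 <- co$rna[order(co$rna$sample, co$rna$gene), ]
  co2 <- co; co2$rna <- rna2
  dec2 <- deconvolve_expression(co2)
  a <- dec1$records[order(dec1$records$gene, dec1$records$source), ]
  b <- dec2$records[order(dec2$records$gene, dec2$records$source), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})
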