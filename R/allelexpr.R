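#' Find alleles informative about a single expression source
#'
#' An allele at a biallelic exonic site is informative for a tumor when it
#' is carried by exactly one of the three DNA sources present in the biopsy:
#' the transferred element (one haploid copy, carriers only), the cancer
#' parental chromosomes, or the infiltrating matched-host cells. Reads from
#' an informative allele can be attributed to that source alone.
#'
#' All arguments are vectorized over sites; dosages are allele copy counts
#' within each source (`NA` `ht_allele` means the element does not cover the
#' site or the tumor is not a carrier, so the element is not a source
#' there).
#'
#' @param host_dosage host alternate-allele copies (0..2).
#' @param cancer_dosage cancer parental alternate copies (0..parental CN).
#' @param cancer_cn parental copy number (default 2).
#' @param ht_allele transferred-copy alternate indicator (0, 1 or `NA`).
#' @return data.frame per site and allele (`allele` in `ref`/`alt`) with
#'   `informative`, `source` (`HT`, `cancer`, `host` or `NA`), and
#'   `copy_number` of the allele in its source.
#' @export
find_informative_alleles <- function(host_dosage, cancer_dosage,
                                     cancer_cn = 2L, ht_allele = NA) {
  m <- max(length(host_dosage), length(cancer_dosage), length(ht_allele))
  host_dosage <- rep_len(host_dosage, m)
  cancer_dosage <- rep_len(cancer_dosage, m)
  cancer_cn <- rep_len(cancer_cn, m)
  ht_allele <- rep_len(ht_allele, m)

  one <- function(allele) {
    host_c <- if (allele == "alt") host_dosage else 2L - host_dosage
    canc_c <- if (allele == "alt") cancer_dosage else cancer_cn - cancer_dosage
    ht_c <- ifelse(is.na(ht_allele), 0L,
                   if (allele == "alt") ht_allele else 1L - ht_allele)
    present <- cbind(HT = ht_c > 0, cancer = canc_c > 0, host = host_c > 0)
    n_src <- rowSums(present)
    src <- rep(NA_character_, m)
    cpn <- rep(NA_integer_, m)
    inf <- n_src == 1L
    for (s in colnames(present)) {
      hit <- inf & present[, s]
      src[hit] <- s
      cpn[hit] <- switch(s, HT = ht_c, cancer = canc_c, host = host_c)[hit]
    }
    data.frame(site = seq_len(m), allele = allele, informative = inf,
               source = src, copy_number = cpn, stringsAsFactors = FALSE)
  }
  out <- rbind(one("ref"), one("alt"))
  out[order(out$site, out$allele), , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across genes of
#' the ratio of a sample's count to the geometric mean of that gene's
#' counts across samples (genes with a zero count in any sample are dropped
#' from the reference, as in the standard count-normalization scheme).
#'
#' @param count_matrix genes x samples numeric matrix.
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(count_matrix) {
  logs <- log(count_matrix)
  use <- rowSums(!is.finite(logs)) == 0
  if (!any(use)) stop("no gene has nonzero counts in every sample")
  ref <- rowMeans(logs[use, , drop = FALSE])
  apply(logs[use, , drop = FALSE], 2L, function(x) exp(stats::median(x - ref)))
}

#' Per-copy expression of informative alleles pooled across tumors
#'
#' Divides informative-allele read counts by per-sample size factors and by
#' the allele's copy number in its source, then pools observations of the
#' same (gene, source) across tumors: mean, SEM-based 95% CI (Student-t
#' quantile, so that few-tumor records get honestly wide intervals; a
#' single-tumor record has an undefined CI) and the number of tumors
#' pooled. Genes with fewer than `min_reads` total informative reads in a
#' source are not reported.
#'
#' @param observations data.frame with columns `gene`, `source`, `sample`,
#'   `count`, `copy_number` (one row per informative allele observation).
#' @param size_factors named per-sample factors (e.g. [size_factors()]);
#'   samples with a zero factor are excluded with a warning.
#' @param min_reads minimum total raw reads per (gene, source) (default 5).
#' @return data.frame with `gene`, `source`, `mean_per_copy`, `ci_lo`,
#'   `ci_hi`, `n_tumors`.
#' @export
per_copy_expression <- function(observations, size_factors, min_reads = 5) {
  sf <- size_factors[observations$sample]
  if (any(is.na(sf))) stop("missing size factor for some samples")
  bad <- names(size_factors)[size_factors == 0]
  if (length(bad)) {
    warning("excluding samples with zero size factor: ",
            paste(bad, collapse = ", "))
    keep <- !observations$sample %in% bad
    observations <- observations[keep, , drop = FALSE]
    sf <- sf[keep]
  }
  per_copy <- observations$count / sf / observations$copy_number
  key <- interaction(observations$gene, observations$source, drop = TRUE)
  tot_reads <- tapply(observations$count, key, sum)
  mean_pc <- tapply(per_copy, key, mean)
  sem <- tapply(per_copy, key, function(x)
    if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_)
  n <- tapply(per_copy, key, length)
  tq <- stats::qt(0.975, pmax(as.numeric(n) - 1, 1))
  parts <- do.call(rbind, strsplit(names(mean_pc), ".", fixed = TRUE))
  out <- data.frame(gene = parts[, 1], source = parts[, 2],
                    mean_per_copy = as.numeric(mean_pc),
                    ci_lo = as.numeric(mean_pc) - tq * as.numeric(sem),
                    ci_hi = as.numeric(mean_pc) + tq * as.numeric(sem),
                    n_tumors = as.integer(n),
                    stringsAsFactors = FALSE)
  out <- out[as.numeric(tot_reads) >= min_reads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare per-gene expression means between two sources
#'
#' Ordinary least-squares regression of one source's per-gene means on the
#' other's, with Pearson correlation and its two-sided test.
#'
#' @param x,y numeric vectors of per-gene means (matched genes).
#' @return list with `slope`, `intercept`, `r`, `r_squared`, `p_value`,
#'   `n_genes`. With fewer than 3 genes, or zero variance in either vector,
#'   the correlation is reported as `NA`.
#' @export
compare_sources <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                r_squared = NA_real_, p_value = NA_real_, n_genes = n))
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, n_genes = n)
}

#' Allelic expression deconvolution of a simulated cohort
#'
#' Builds informative-allele observations from a cohort's RNA component and
#' its ground-truth genotype configurations, normalizes and pools them, and
#' compares transferred-element expression against the cancer and host
#' programs.
#'
#' @param cohort an `ht_cohort` with the `rna` component.
#' @param min_reads per-(gene, source) read floor (see
#'   [per_copy_expression()]).
#' @return list with `records` (pooled [per_copy_expression()] table),
#'   `ht_vs_cancer` and `ht_vs_host` ([compare_sources()] results) and the
#'   per-gene mean matrix `means`.
#' @export
deconvolve_expression <- function(cohort, min_reads = 5) {
  rna <- cohort$rna
  tr <- cohort$truth$rna_truth
  carriers <- cohort$truth$carrier_ids

  # genes x samples total-count matrix for size factors; genes on the
  # transferred element are excluded from the reference set since their
  # dosage differs between carriers and non-carriers (control-gene
  # normalization)
  tot <- tapply(rna$ref_count + rna$alt_count,
                list(rna$gene, rna$sample), sum)
  off_element <- tr$gene[!tr$in_block]
  ref_genes <- intersect(rownames(tot), off_element)
  sf <- size_factors(tot[ref_genes, , drop = FALSE])

  gi <- match(rna$gene, tr$gene)
  si <- match(rna$sample, colnames(tr$host_dosage))
  is_car <- rna$sample %in% carriers
  ht_al <- ifelse(is_car, tr$ht_allele[gi], NA_integer_)
  info <- find_informative_alleles(
    host_dosage = tr$host_dosage[cbind(gi, si)],
    cancer_dosage = tr$cancer_dosage[gi],
    cancer_cn = 2L, ht_allele = ht_al)
  info_ref <- info[info$allele == "ref", ]
  info_alt <- info[info$allele == "alt", ]
  obs <- rbind(
    data.frame(gene = rna$gene, source = info_ref$source,
               sample = rna$sample, count = rna$ref_count,
               copy_number = info_ref$copy_number,
               informative = info_ref$informative,
               stringsAsFactors = FALSE),
    data.frame(gene = rna$gene, source = info_alt$source,
               sample = rna$sample, count = rna$alt_count,
               copy_number = info_alt$copy_number,
               informative = info_alt$informative,
               stringsAsFactors = FALSE))
  obs <- obs[obs$informative & !is.na(obs$source), , drop = FALSE]

  rec <- per_copy_expression(obs[, c("gene", "source", "sample", "count",
                                     "copy_number")], sf,
                             min_reads = min_reads)
  means <- tapply(rec$mean_per_copy, list(rec$gene, rec$source), mean)
  cmp <- function(a, b) {
    if (!all(c(a, b) %in% colnames(means)))
      return(compare_sources(numeric(0), numeric(0)))
    compare_sources(means[, a], means[, b])
  }
  list(records = rec, means = means,
       ht_vs_cancer = cmp("cancer", "HT"),
       ht_vs_host = cmp("host", "HT"))
}
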