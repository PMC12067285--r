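#' Infer the transferred haplotype's allele at biallelic sites
#'
#' At panel sites inside copy-number step segments, the parental alternate
#' allele dosage `a_p` is taken from the non-carrier consensus genotype
#' scaled to the parental copy number (hom reference = 0, het = half the
#' copies, hom alternate = all copies). For each carrier, the binomial
#' log-likelihood of its alternate reads is computed under alternate dosage
#' `a_p` versus `a_p + 1` of `c = parental_cn + 1` total copies, through the
#' tumor's purity mixture with its matched host dosage. Log-likelihood
#' differences are summed across carriers; the transferred allele is the
#' alternate if the summed difference exceeds `llr_threshold`, the reference
#' if it is below `-llr_threshold`, and undetermined otherwise (or when the
#' carrier copy number is inconsistent across tumors at the site).
#'
#' Following the screen's design the site set is restricted to transversion
#' variants by default (`transversions_only`), the substitution class least
#' affected by recurrent mutation.
#'
#' @param counts a `site_counts` object (tumor and host columns).
#' @param genotypes output of [genotype_cohort()].
#' @param samples sample sheet.
#' @param cn_segments per-sample copy-number segments.
#' @param carriers carrier tumor ids.
#' @param step_segments intervals where carriers have the extra copy
#'   (e.g. from [select_informative_segments()]; needs `chrom`, `start`,
#'   `end` and optionally `cn_noncarrier`).
#' @param transversions_only restrict to sites flagged `transversion`
#'   (default TRUE; requires that column in `counts$sites`).
#' @param llr_threshold absolute summed log-likelihood ratio needed for a
#'   call (default 3, a conventional strong-evidence cutoff).
#' @param min_depth minimum per-carrier depth for a site to contribute.
#' @return data.frame with one row per evaluated site: `site` (row index in
#'   `counts$sites`), `chrom`, `pos`, `ht_allele` (`"ref"`, `"alt"`,
#'   `"undetermined"`), `llr` (summed, alt minus ref), `parental_dosage`,
#'   `n_carriers_used`, `reason` for undetermined calls.
#' @export
infer_ht_genotypes <- function(counts, genotypes, samples, cn_segments,
                               carriers, step_segments,
                               transversions_only = TRUE,
                               llr_threshold = 3, min_depth = 15L) {
  sites <- counts$sites
  tumors <- samples[samples$type == "tumor", , drop = FALSE]
  noncarriers <- setdiff(tumors$sample_id, carriers)

  in_step <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(step_segments)))
    in_step <- in_step | (sites$chrom == step_segments$chrom[i] &
                            sites$pos >= step_segments$start[i] &
                            sites$pos <= step_segments$end[i])
  keep <- in_step
  if (transversions_only) {
    if (is.null(sites$transversion))
      stop("transversions_only requires a 'transversion' site column")
    keep <- keep & sites$transversion
  }
  idx <- which(keep)
  if (!length(idx))
    return(data.frame(site = integer(0), chrom = character(0),
                      pos = integer(0), ht_allele = character(0),
                      llr = numeric(0), parental_dosage = integer(0),
                      n_carriers_used = integer(0), reason = character(0),
                      stringsAsFactors = FALSE))

  # parental dosage from the non-carrier consensus at each site
  nc_states <- genotypes$state[idx, noncarriers, drop = FALSE]
  cons <- consensus_state(nc_states)
  nc_k <- genotypes$alt_copies[idx, noncarriers, drop = FALSE]
  # modal non-carrier alt copies resolves hom_ref (0) vs hom_alt (cn)
  a_p <- vapply(seq_along(idx), function(i) {
    if (cons[i] == "undetermined") return(NA_integer_)
    modal_value(nc_k[i, ])
  }, integer(1))
  c_par <- vapply(seq_along(idx), function(i)
    modal_value(genotypes$total_cn[idx[i], noncarriers]), integer(1))

  m <- length(idx)
  llr <- numeric(m); n_used <- integer(m)
  cn_consistent <- rep(TRUE, m)
  for (id in carriers) {
    j <- match(id, tumors$sample_id)
    p <- tumors$purity[j]
    cn_car <- genotypes$total_cn[idx, id]
    g_h <- genotypes$host_dosage[idx, id]
    alt <- counts$alt_reads[idx, id]
    dep <- counts$ref_reads[idx, id] + alt
    ok <- dep >= min_depth & !is.na(cn_car) & !is.na(a_p) &
      cn_car == c_par + 1L
    cn_consistent <- cn_consistent & (is.na(cn_car) | cn_car == c_par + 1L)
    if (!any(ok)) next
    pr0 <- mixture_prob(pmin(a_p[ok], cn_car[ok]), cn_car[ok], p, 2 * g_h[ok])
    pr1 <- mixture_prob(pmin(a_p[ok] + 1L, cn_car[ok]), cn_car[ok], p,
                        2 * g_h[ok])
    ll0 <- stats::dbinom(alt[ok], dep[ok], pr0, log = TRUE)
    ll1 <- stats::dbinom(alt[ok], dep[ok], pr1, log = TRUE)
    llr[ok] <- llr[ok] + (ll1 - ll0)
    n_used[ok] <- n_used[ok] + 1L
  }

  call <- rep("undetermined", m)
  reason <- rep("", m)
  callable <- !is.na(a_p) & n_used > 0L & cn_consistent
  call[callable & llr > llr_threshold] <- "alt"
  call[callable & llr < -llr_threshold] <- "ref"
  reason[is.na(a_p)] <- "no parental consensus"
  reason[!cn_consistent] <- "inconsistent carrier copy number"
  reason[callable & abs(llr) <= llr_threshold] <- "insufficient evidence"
  reason[!is.na(a_p) & n_used == 0L & cn_consistent] <- "no carrier coverage"

  data.frame(site = idx, chrom = sites$chrom[idx], pos = sites$pos[idx],
             ht_allele = call, llr = llr, parental_dosage = a_p,
             n_carriers_used = n_used, reason = reason,
             stringsAsFactors = FALSE)
}
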