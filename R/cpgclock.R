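#' Select copy-number step segments informative for clock dating
#'
#' Keeps segments whose modal copy-number state among non-carrier tumors is
#' 0, 1 or 2 and whose modal state among carriers is exactly one integer
#' higher. In such segments the single extra carrier copy is attributed
#' wholly to the transferred haplotype.
#'
#' @param cn_segments per-sample segments (`chrom`, `start`, `end`,
#'   `sample`, `total_cn`).
#' @param carriers,noncarriers sample id vectors.
#' @return data.frame of selected intervals with columns `chrom`, `start`,
#'   `end`, `cn_carrier`, `cn_noncarrier` (empty if none qualify).
#' @export
select_informative_segments <- function(cn_segments, carriers, noncarriers) {
  # evaluation intervals: union of breakpoints across all samples
  out <- list()
  for (ch in unique(cn_segments$chrom)) {
    segs <- cn_segments[cn_segments$chrom == ch, , drop = FALSE]
    bounds <- sort(unique(c(segs$start, segs$end + 1)))
    if (length(bounds) < 2L) next
    iv <- data.frame(start = bounds[-length(bounds)], end = bounds[-1] - 1)
    for (i in seq_len(nrow(iv))) {
      mid <- floor((iv$start[i] + iv$end[i]) / 2)
      cn_at <- function(ids) vapply(ids, function(id) {
        s <- segs[segs$sample == id & segs$start <= mid & segs$end >= mid, ]
        if (nrow(s)) as.integer(s$total_cn[1]) else NA_integer_
      }, integer(1))
      cn_c <- modal_value(cn_at(carriers))
      cn_n <- modal_value(cn_at(noncarriers))
      if (!is.na(cn_c) && !is.na(cn_n) && cn_n %in% 0:2 &&
          cn_c == cn_n + 1L)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = iv$start[i], end = iv$end[i],
          cn_carrier = cn_c, cn_noncarrier = cn_n,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), cn_carrier = integer(0),
                      cn_noncarrier = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  # merge adjacent intervals with identical states
  keep <- list(); cur <- res[1, ]
  for (i in seq_len(nrow(res))[-1]) {
    r <- res[i, ]
    if (r$chrom == cur$chrom && r$start == cur$end + 1 &&
        r$cn_carrier == cur$cn_carrier && r$cn_noncarrier == cur$cn_noncarrier)
      cur$end <- r$end
    else { keep[[length(keep) + 1L]] <- cur; cur <- r }
  }
  keep[[length(keep) + 1L]] <- cur
  res <- do.call(rbind, keep)
  rownames(res) <- NULL
  res
}

#' Parental per-copy CpG C>T mutation density from non-carrier tumors
#'
#' Per bin, the mean over non-carrier tumors of
#' `count / (cpg_sites * parental_copies)`; the cohort summary is the mean
#' of per-tumor densities (each tumor's total count over total
#' `cpg_sites * copies`) with a normal-approximation 95% CI across tumors.
#' Bins with zero CpG sites are excluded.
#'
#' @param counts matrix of per-bin CpG C>T mutation counts (bins x tumors).
#' @param cpg_sites CpG sites per bin.
#' @param parental_cn parental copy number per bin (scalar or vector).
#' @param noncarriers column names of the non-carrier tumors.
#' @return list with `per_bin` (mean density per bin), `per_tumor`,
#'   `mean`, `se`, `ci` (95%), `n_bins`.
#' @export
parental_density <- function(counts, cpg_sites, parental_cn, noncarriers) {
  parental_cn <- rep_len(parental_cn, length(cpg_sites))
  use <- cpg_sites > 0 & parental_cn > 0
  cnt <- counts[use, noncarriers, drop = FALSE]
  denom <- cpg_sites[use] * parental_cn[use]
  per_bin <- rowMeans(cnt / denom)
  per_tumor <- colSums(cnt) / sum(denom)
  m <- mean(per_tumor)
  se <- stats::sd(per_tumor) / sqrt(length(per_tumor))
  list(per_bin = per_bin, per_tumor = per_tumor, mean = m, se = se,
       ci = c(m - 1.96 * se, m + 1.96 * se), n_bins = sum(use))
}

#' Transferred-haplotype mutation density by parental-count subtraction
#'
#' For each carrier tumor and bin, subtracts the expected parental mutation
#' count (the non-carrier per-bin per-copy density times the parental copy
#' number times the bin's CpG sites) from the observed count; the residual
#' count is attributed to the single transferred copy. The per-carrier
#' density is the total residual divided by total CpG sites; the estimate is
#' their mean, with SE across carriers and the per-carrier range. Negative
#' residuals are retained (sampling noise); only the reported value is
#' clamped at zero, the raw value is kept.
#'
#' @param counts matrix of per-bin counts (bins x tumors).
#' @param cpg_sites CpG sites per bin.
#' @param parental_per_bin per-bin parental per-copy densities
#'   (`$per_bin` of [parental_density()], aligned to the bins used there).
#' @param parental_cn parental copy number per bin (scalar or vector).
#' @param carriers column names of the carrier tumors.
#' @return list with `per_carrier`, `d_h` (raw mean), `d_h_reported`
#'   (clamped at 0), `se`, `range`.
#' @export
ht_density <- function(counts, cpg_sites, parental_per_bin, parental_cn,
                       carriers) {
  parental_cn <- rep_len(parental_cn, length(cpg_sites))
  use <- cpg_sites > 0 & parental_cn > 0
  cnt <- counts[use, carriers, drop = FALSE]
  expected <- parental_per_bin * parental_cn[use] * cpg_sites[use]
  if (length(expected) != nrow(cnt))
    stop("parental_per_bin must align with the bins with CpG sites")
  resid <- cnt - expected
  per_carrier <- colSums(resid) / sum(cpg_sites[use])
  d_h <- mean(per_carrier)
  se <- stats::sd(per_carrier) / sqrt(length(per_carrier))
  list(per_carrier = per_carrier, d_h = d_h,
       d_h_reported = max(d_h, 0), se = se,
       range = range(per_carrier))
}

#' Convert a per-copy CpG C>T density to an age in years
#'
#' With a diploid-genome mutation rate `rate_diploid` (mutations per site
#' per year), the per-copy rate is `rate_diploid / 2` and the age is
#' `d_h / r`, rounded to the nearest year for reporting; the 95% CI is
#' `(d_h +/- 1.96 * se) / r`, propagating the SE of the transferred-copy
#' density.
#'
#' @param d_h per-CpG-site per-copy density on the transferred copy.
#' @param se standard error of `d_h` (across carrier tumors).
#' @param rate_diploid mutation rate per site per year per diploid genome
#'   (default 6.87e-7).
#' @return list with `age_years` (rounded), `age_raw`, `ci_years`,
#'   `rate_per_copy`.
#' @export
density_to_years <- function(d_h, se = 0, rate_diploid = 6.87e-7) {
  if (rate_diploid <= 0) stop("rate_diploid must be positive")
  r <- rate_diploid / 2
  age <- d_h / r
  ci <- (d_h + c(-1.96, 1.96) * se) / r
  list(age_years = round(age), age_raw = age, ci_years = ci,
       rate_per_copy = r)
}

#' Bin CpG C>T mutation counts of a simulated cohort over step segments
#'
#' Builds the per-bin per-tumor count matrix the clock estimators consume
#' from a simulated cohort's mutation table: 1-kb bins tiling the selected
#' segments, counting each tumor's CpG-context mutations per bin. The CpG
#' sites per bin are the expected count under the generator's CpG model,
#' `1000 * cpg_fraction`.
#'
#' @param cohort an `ht_cohort` with the `somatic` component.
#' @param segments intervals to bin (e.g. from
#'   [select_informative_segments()]).
#' @param bin_kb bin width in kb (default 1).
#' @return list with `counts` (bins x tumors), `cpg_sites`, `parental_cn`
#'   (per bin, the non-carrier modal state), `bins` (coordinates).
#' @export
cpg_bin_counts <- function(cohort, segments, bin_kb = 1) {
  w <- bin_kb * 1000
  tumors <- cohort$samples$sample_id[cohort$samples$type == "tumor"]
  bins <- do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
    s0 <- seq(segments$start[i], segments$end[i], by = w)
    s0 <- s0[s0 + w - 1 <= segments$end[i]]
    if (!length(s0)) return(NULL)
    data.frame(chrom = segments$chrom[i], start = s0, end = s0 + w - 1,
               parental_cn = segments$cn_noncarrier[i] %||% 2L,
               stringsAsFactors = FALSE)
  }))
  if (is.null(bins) || !nrow(bins)) stop("no bins fit inside the segments")
  muts <- cohort$somatic$mutations
  muts <- muts[muts$cpg, , drop = FALSE]
  counts <- matrix(0L, nrow(bins), length(tumors),
                   dimnames = list(NULL, tumors))
  key <- paste(bins$chrom, bins$start)
  for (j in seq_along(tumors)) {
    mm <- mutations_for_sample(muts, tumors[j],
                               cohort$truth$clades[tumors[j]])
    if (!nrow(mm)) next
    mkey <- paste(mm$chrom, ((mm$pos - 1) %/% w) * w + 1)
    tb <- table(mkey)
    hit <- match(names(tb), key)
    ok <- !is.na(hit)
    counts[hit[ok], j] <- as.integer(tb[ok])
  }
  cpg_sites <- rep(cohort$config$cpg_fraction * w, nrow(bins))
  list(counts = counts, cpg_sites = cpg_sites,
       parental_cn = bins$parental_cn, bins = bins)
}

#' Date the transferred element in a simulated cohort end to end
#'
#' Chains [select_informative_segments()], [cpg_bin_counts()],
#' [parental_density()], [ht_density()] and [density_to_years()].
#'
#' @param cohort an `ht_cohort` with `somatic` and `cn` components.
#' @param rate_diploid diploid mutation rate per site per year.
#' @return list of class `clock_estimate` with the parental and transferred
#'   density summaries and the age estimate.
#' @export
estimate_ht_age <- function(cohort, rate_diploid = 6.87e-7) {
  carriers <- cohort$truth$carrier_ids
  tumors <- cohort$samples$sample_id[cohort$samples$type == "tumor"]
  noncarriers <- setdiff(tumors, carriers)
  segs <- select_informative_segments(cohort$cn, carriers, noncarriers)
  if (!nrow(segs)) stop("no informative step segments")
  bb <- cpg_bin_counts(cohort, segs)
  par <- parental_density(bb$counts, bb$cpg_sites, bb$parental_cn,
                          noncarriers)
  ht <- ht_density(bb$counts, bb$cpg_sites, par$per_bin, bb$parental_cn,
                   carriers)
  age <- density_to_years(ht$d_h, ht$se, rate_diploid)
  structure(list(segments = segs, parental = par, ht = ht, age = age),
            class = "clock_estimate")
}

#' @export
print.clock_estimate <- function(x, ...) {
  cat(sprintf(
    "clock_estimate: parental %.3g (95%% CI %.3g-%.3g), transferred %.3g (SE %.3g)\n",
    x$parental$mean, x$parental$ci[1], x$parental$ci[2], x$ht$d_h, x$ht$se))
  cat(sprintf("  age %d years (95%% CI %d-%d)\n", x$age$age_years,
              round(x$age$ci_years[1]), round(x$age$ci_years[2])))
  invisible(x)
}
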