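#' Call flipping SNPs against the lineage consensus
#'
#' A flipping SNP is a germline panel site whose genotype in one tumor
#' conflicts with the consensus state of the lineage: heterozygous where the
#' lineage is homozygous (`hom_to_het`) or homozygous where the lineage is
#' heterozygous (`het_to_hom`). Calls are restricted to sites that (a) have
#' a determined consensus, (b) sit in copy number >= 2 for the tumor (sites
#' below are `missing` upstream) and (c) lie in regions that retain both
#' parental homologues, operationalized as eligibility windows in which at
#' least `min_het_fraction` of consensus-determined sites are heterozygous
#' (a horizontally transferred haplotype in a region that lost one parental
#' homologue is indistinguishable from simple loss of heterozygosity, so
#' such regions are excluded by design).
#'
#' @param genotypes output of [genotype_cohort()] (matrices sites x tumors).
#' @param consensus per-site consensus from [consensus_state()].
#' @param sites site table (`chrom`, `pos`).
#' @param min_het_fraction minimum heterozygous fraction among determined
#'   sites in an eligibility window (default 0.1).
#' @param het_window_kb eligibility window width in kb (default 1000).
#' @return data.frame of flip calls: `site` (row index), `chrom`, `pos`,
#'   `sample_id`, `direction`.
#' @export
call_flipping_snps <- function(genotypes, consensus, sites,
                               min_het_fraction = 0.1,
                               het_window_kb = 1000) {
  state <- state_codes(genotypes$state)
  stopifnot(nrow(state) == length(consensus), nrow(state) == nrow(sites))

  # retained-heterozygosity eligibility per window
  w <- het_window_kb * 1000
  win_key <- paste(sites$chrom, (sites$pos - 1) %/% w)
  det <- consensus != "undetermined"
  het_frac <- tapply(consensus[det] == "het", win_key[det], mean)
  eligible <- det & (het_frac[win_key] >= min_het_fraction)
  eligible[is.na(eligible)] <- FALSE

  rows <- list()
  for (j in seq_len(ncol(state))) {
    st <- state[, j]
    up <- eligible & consensus == "hom" & st == 2L
    dn <- eligible & consensus == "het" & (st == 1L | st == 3L)
    if (any(up))
      rows[[length(rows) + 1L]] <- data.frame(
        site = which(up), chrom = sites$chrom[up], pos = sites$pos[up],
        sample_id = colnames(state)[j], direction = "hom_to_het",
        stringsAsFactors = FALSE)
    if (any(dn))
      rows[[length(rows) + 1L]] <- data.frame(
        site = which(dn), chrom = sites$chrom[dn], pos = sites$pos[dn],
        sample_id = colnames(state)[j], direction = "het_to_hom",
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(site = integer(0), chrom = character(0),
                      pos = integer(0), sample_id = character(0),
                      direction = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect candidate horizontal-transfer regions from flipping-SNP density
#'
#' Tiles each chromosome with fixed-width windows, counts `hom_to_het`
#' flipping SNPs per window and tumor, and flags windows that are outliers
#' by two criteria jointly: a robust z score
#' `0.6745 * (x - median) / MAD > z_min` computed over the tumor's own
#' genome-wide window counts, and a Cook's distance above `4 / n_windows`
#' from an ordinary least-squares regression of the tumor's window counts
#' on the cohort-median window profile (which isolates tumor-specific
#' excess from shared artefacts). Flagged windows separated by at most
#' `merge_gap_kb` are clustered, and a cluster becomes a candidate region
#' when it contains a run of at least `min_run` consecutive flagged windows
#' (isolated flagged windows never seed a region on their own, but do
#' extend a neighbouring one). Only `hom_to_het` flips seed regions — the
#' signature of an introduced haplotype — while `het_to_hom` flips are
#' reported upstream but do not trigger detection.
#'
#' When the MAD is zero (flipping is rare enough that most windows are
#' empty) the robust z is undefined; the window criterion falls back to a
#' Poisson upper-tail test with robust rate `max(median, 0.1)` at tail
#' probability `tail_p`.
#'
#' @param flips flip calls from [call_flipping_snps()].
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param tumor_ids tumors screened (columns of the count matrix; tumors
#'   with zero flips still participate in the cohort median).
#' @param window_kb window width in kb (default 100).
#' @param z_min robust z threshold (default 3.5).
#' @param min_run minimum run of consecutive flagged windows (default 3).
#' @param merge_gap_kb maximum gap between merged runs in kb (default 500).
#' @param tail_p Poisson upper-tail probability for the MAD = 0 fallback.
#' @return list of class `flip_scan`: `regions` (data.frame `chrom`,
#'   `start`, `end`, `sample_id`, `peak_z`, `n_flipping_snps`,
#'   `flip_density_per_mb`) and `windows` (per-window per-tumor statistics).
#' @export
detect_candidate_regions <- function(flips, chrom_lengths, tumor_ids,
                                     window_kb = 100, z_min = 3.5,
                                     min_run = 3L, merge_gap_kb = 500,
                                     tail_p = 1e-3) {
  w <- window_kb * 1000
  chroms <- names(chrom_lengths)
  n_win_chr <- ceiling(chrom_lengths / w)
  offset <- c(0, cumsum(n_win_chr))[seq_along(chroms)]
  names(offset) <- chroms
  n_windows <- sum(n_win_chr)
  if (n_windows < 100L)
    warning("fewer than 100 windows genome-wide; MAD may be unstable")

  win_tab <- data.frame(
    chrom = rep(chroms, n_win_chr),
    start = unlist(lapply(n_win_chr, function(k) (seq_len(k) - 1) * w + 1),
                   use.names = FALSE),
    stringsAsFactors = FALSE)
  win_tab$end <- pmin(win_tab$start + w - 1,
                      chrom_lengths[win_tab$chrom])

  counts <- matrix(0L, n_windows, length(tumor_ids),
                   dimnames = list(NULL, tumor_ids))
  up <- flips[flips$direction == "hom_to_het" &
                flips$sample_id %in% tumor_ids, , drop = FALSE]
  if (nrow(up)) {
    gw <- offset[up$chrom] + (up$pos - 1) %/% w + 1
    sj <- match(up$sample_id, tumor_ids)
    tab <- table(factor(gw, levels = seq_len(n_windows)),
                 factor(sj, levels = seq_along(tumor_ids)))
    counts <- counts + as.integer(tab)
    dim(counts) <- c(n_windows, length(tumor_ids))
    colnames(counts) <- tumor_ids
  }
  med_profile <- apply(counts, 1L, stats::median)

  win_rows <- list(); reg_rows <- list()
  for (j in seq_along(tumor_ids)) {
    x <- counts[, j]
    med <- stats::median(x)
    madv <- stats::mad(x)   # scaled MAD; z = (x - med) / mad
    if (madv > 0) {
      z <- (x - med) / madv
      z_flag <- z > z_min
    } else {
      lam <- max(med, 0.1)
      pv <- stats::ppois(x - 1, lam, lower.tail = FALSE)
      z <- stats::qnorm(pv, lower.tail = FALSE)
      z[is.infinite(z)] <- sign(z[is.infinite(z)]) * 38   # double precision tail
      z_flag <- pv < tail_p
    }
    fit <- stats::lm(x ~ med_profile)
    cd <- stats::cooks.distance(fit)
    cd_flag <- cd > 4 / n_windows
    flag <- z_flag & cd_flag

    win_rows[[j]] <- data.frame(
      chrom = win_tab$chrom, start = win_tab$start, end = win_tab$end,
      sample_id = tumor_ids[j], flip_count = x, robust_z = z,
      cooks_distance = as.numeric(cd), flagged = flag,
      stringsAsFactors = FALSE)

    for (ch in chroms) {
      idx <- which(win_tab$chrom == ch)
      f <- flag[idx]
      if (!any(f)) next
      # cluster flagged windows separated by at most merge_gap, then keep
      # clusters seeded by a run of >= min_run consecutive flagged windows
      fi <- which(f)
      gap_win <- merge_gap_kb * 1000 / w
      cluster <- cumsum(c(1L, diff(fi) > gap_win + 1L))
      merged <- do.call(rbind, lapply(split(fi, cluster), function(ii) {
        runs <- rle(diff(c(-10L, ii)) == 1L)
        max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) + 1L
          else 1L
        if (max_run < min_run) return(NULL)
        data.frame(s = min(ii), e = max(ii))
      }))
      if (is.null(merged)) next
      for (i in seq_len(nrow(merged))) {
        wi <- idx[merged$s[i]:merged$e[i]]
        r_start <- win_tab$start[wi[1]]
        r_end <- win_tab$end[wi[length(wi)]]
        n_f <- sum(flips$sample_id == tumor_ids[j] & flips$chrom == ch &
                     flips$pos >= r_start & flips$pos <= r_end)
        reg_rows[[length(reg_rows) + 1L]] <- data.frame(
          chrom = ch, start = r_start, end = r_end,
          sample_id = tumor_ids[j], peak_z = max(z[wi]),
          n_flipping_snps = n_f,
          flip_density_per_mb = n_f / ((r_end - r_start + 1) / 1e6),
          stringsAsFactors = FALSE)
      }
    }
  }
  regions <- if (length(reg_rows)) do.call(rbind, reg_rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               sample_id = character(0), peak_z = numeric(0),
               n_flipping_snps = integer(0), flip_density_per_mb = numeric(0),
               stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  structure(list(regions = regions, windows = do.call(rbind, win_rows)),
            class = "flip_scan")
}

#' Run the full flipping-SNP screen on a simulated or loaded cohort
#'
#' Convenience wrapper chaining [genotype_cohort()], [consensus_state()],
#' [call_flipping_snps()] and [detect_candidate_regions()].
#'
#' @param cohort an `ht_cohort` (or any list with `panel`, `samples`, `cn`
#'   and a `config` holding `chrom_lengths`).
#' @param ... passed to [detect_candidate_regions()].
#' @param min_depth,min_het_fraction forwarded to the upstream steps.
#' @return a `flip_scan` object (see [detect_candidate_regions()]), with the
#'   flip calls attached as element `flips`.
#' @export
run_flipping_screen <- function(cohort, min_depth = 15L,
                                min_het_fraction = 0.1, ...) {
  geno <- genotype_cohort(cohort$panel, cohort$samples, cohort$cn,
                          min_depth = min_depth)
  cons <- consensus_state(geno$state)
  flips <- call_flipping_snps(geno, cons, cohort$panel$sites,
                              min_het_fraction = min_het_fraction)
  scan <- detect_candidate_regions(
    flips, cohort$config$chrom_lengths,
    tumor_ids = cohort$samples$sample_id[cohort$samples$type == "tumor"], ...)
  scan$flips <- flips
  scan$genotypes <- geno
  scan$consensus <- cons
  scan
}
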