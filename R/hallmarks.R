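#' Integer copy-number step between carrier and non-carrier tumors
#'
#' For every copy-number interval intersecting the candidate region
#' (boundaries are the union of segment breakpoints of all tumors), computes
#' the modal integer copy-number state in the carrier group minus the modal
#' state in the non-carrier group. The hallmark passes iff every
#' intersecting interval steps by exactly +1. A modal tie in either group
#' marks the interval indeterminate (and fails the hallmark).
#'
#' @param region list or one-row data.frame with `chrom`, `start`, `end`.
#' @param cn_segments per-sample segments (`chrom`, `start`, `end`,
#'   `sample`, `total_cn`).
#' @param carriers,noncarriers sample id vectors.
#' @return list with `intervals` (data.frame `start`, `end`, `cn_carrier`,
#'   `cn_noncarrier`, `step`, `indeterminate`) and `pass`.
#' @export
copy_number_step <- function(region, cn_segments, carriers, noncarriers) {
  segs <- clip_segments(cn_segments, region$chrom, region$start, region$end)
  if (!nrow(segs)) stop("no copy-number segments intersect the region")
  bounds <- sort(unique(c(region$start, segs$start, segs$end + 1,
                          region$end + 1)))
  bounds <- bounds[bounds >= region$start & bounds <= region$end + 1]
  iv <- data.frame(start = bounds[-length(bounds)], end = bounds[-1] - 1)

  cn_of <- function(ids, mid) {
    vapply(ids, function(id) {
      s <- segs[segs$sample == id & segs$start <= mid & segs$end >= mid, ]
      if (nrow(s)) as.integer(s$total_cn[1]) else NA_integer_
    }, integer(1))
  }
  iv$cn_carrier <- NA_integer_; iv$cn_noncarrier <- NA_integer_
  for (i in seq_len(nrow(iv))) {
    mid <- floor((iv$start[i] + iv$end[i]) / 2)
    iv$cn_carrier[i] <- modal_value(cn_of(carriers, mid))
    iv$cn_noncarrier[i] <- modal_value(cn_of(noncarriers, mid))
  }
  iv$step <- iv$cn_carrier - iv$cn_noncarrier
  iv$indeterminate <- is.na(iv$cn_carrier) | is.na(iv$cn_noncarrier)
  list(intervals = iv,
       pass = !any(iv$indeterminate) && all(iv$step == 1L))
}

#' Somatic VAF dosage pattern test in copy-number-3 regions
#'
#' In a region of carrier copy number 3, somatic mutations sitting on one of
#' the two retained parental copies, or on a mutation-free introduced
#' haplotype, are expected at corrected VAF 1/3. A recent duplication of a
#' parental chromosome would instead place pre-duplication mutations on 2 of
#' the 3 copies (VAF 2/3). Per mutation, binomial log-likelihoods of the two
#' dosages are compared (summed over the tumors observing the mutation,
#' under each tumor's purity mixture); the hallmark passes iff the fraction
#' of mutations favoring dosage 2/3 is below `max_two_thirds`.
#'
#' @param mutation_id identifier grouping observations of one mutation.
#' @param alt_reads,depth per-observation read counts.
#' @param purity per-observation tumor purity.
#' @param tumor_cn per-observation total copy number (3 in the screened
#'   regions).
#' @param max_two_thirds pass threshold on the 2/3-dosage fraction
#'   (default 0.05).
#' @param min_mutations minimum distinct mutations for a determination
#'   (default 10).
#' @return list with `fraction_two_thirds`, `pass` (`NA` = undetermined),
#'   `n_mutations`, and `per_mutation` log-likelihood differences
#'   (`ll_two_thirds - ll_one_third` per mutation).
#' @export
vaf_pattern_test <- function(mutation_id, alt_reads, depth, purity,
                             tumor_cn = 3L, max_two_thirds = 0.05,
                             min_mutations = 10L) {
  m <- length(alt_reads)
  stopifnot(length(mutation_id) == m, length(depth) == m)
  purity <- rep_len(purity, m)
  tumor_cn <- rep_len(tumor_cn, m)
  ll1 <- stats::dbinom(alt_reads, depth,
                       mixture_prob(1L, tumor_cn, purity, 0), log = TRUE)
  ll2 <- stats::dbinom(alt_reads, depth,
                       mixture_prob(2L, tumor_cn, purity, 0), log = TRUE)
  dll <- tapply(ll2 - ll1, mutation_id, sum)
  n_mut <- length(dll)
  if (n_mut < min_mutations)
    return(list(fraction_two_thirds = NA_real_, pass = NA,
                n_mutations = n_mut, per_mutation = dll))
  frac <- mean(dll > 0)
  list(fraction_two_thirds = frac, pass = frac < max_two_thirds,
       n_mutations = n_mut, per_mutation = dll)
}

#' Per-copy mutation-density contrast between a footprint and its flanks
#'
#' Counts one tumor's somatic mutations in non-overlapping windows
#' (default 10 kb) tiling the candidate region (the footprint) and in an
#' equal number of windows immediately flanking it, split evenly between the
#' two sides and truncated at chromosome ends (fewer flank windows than
#' footprint windows are used, and flagged, when the chromosome is too
#' short). Window counts are normalized by the tumor's total copy number at
#' the window, and the two sets of per-copy densities are compared with a
#' two-sided Welch t test.
#'
#' @param region list with `chrom`, `start`, `end`.
#' @param mutations data.frame of this tumor's mutations (`chrom`, `pos`).
#' @param cn_segments this tumor's copy-number segments (may contain other
#'   samples; filtered by `sample_id`).
#' @param sample_id tumor to evaluate.
#' @param chrom_length length of `region$chrom` (for flank truncation).
#' @param window_kb window width in kb (default 10).
#' @return list with `density_footprint`, `density_flank` (per-window
#'   per-copy densities), `mean_footprint`, `mean_flank`,
#'   `percent_reduction` (`100 * (1 - mean_footprint / mean_flank)`),
#'   `t_statistic`, `p_value`, `flank_imbalance`.
#' @export
mutation_density_contrast <- function(region, mutations, cn_segments,
                                      sample_id, chrom_length,
                                      window_kb = 10) {
  w <- window_kb * 1000
  fp_starts <- seq(region$start, region$end, by = w)
  fp_starts <- fp_starts[fp_starts + w - 1 <= region$end]
  n_fp <- length(fp_starts)
  if (n_fp == 0L) stop("region shorter than one window")

  n_side <- ceiling(n_fp / 2)
  left_starts <- region$start - w * seq_len(n_side)
  left_starts <- left_starts[left_starts >= 1]
  right_starts <- region$end + 1 + w * (seq_len(n_side) - 1L)
  right_starts <- right_starts[right_starts + w - 1 <= chrom_length]
  fl_starts <- c(rev(left_starts), right_starts)
  # if one side is truncated, take up to n_fp windows total from what remains
  if (length(fl_starts) > n_fp)
    fl_starts <- fl_starts[seq_len(n_fp)]
  flank_imbalance <- length(fl_starts) < n_fp
  if (!length(fl_starts)) stop("no flanking windows available")

  pos <- mutations$pos[mutations$chrom == region$chrom]
  segs <- cn_segments[cn_segments$sample == sample_id &
                        cn_segments$chrom == region$chrom, , drop = FALSE]
  dens <- function(starts) {
    cnt <- integer(length(starts))
    idx <- findInterval(pos, starts)
    ok <- idx >= 1L & pos <= starts[pmax(idx, 1L)] + w - 1
    tb <- tabulate(idx[ok], nbins = length(starts))
    mid <- starts + w %/% 2
    cn <- rep(NA_real_, length(starts))
    for (i in seq_len(nrow(segs)))
      cn[mid >= segs$start[i] & mid <= segs$end[i]] <- segs$total_cn[i]
    tb / cn
  }
  d_fp <- dens(fp_starts)
  d_fl <- dens(fl_starts)
  tt <- stats::t.test(d_fp, d_fl)   # Welch, two-sided
  list(density_footprint = d_fp, density_flank = d_fl,
       mean_footprint = mean(d_fp, na.rm = TRUE),
       mean_flank = mean(d_fl, na.rm = TRUE),
       percent_reduction = 100 * (1 - mean(d_fp, na.rm = TRUE) /
                                    mean(d_fl, na.rm = TRUE)),
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       flank_imbalance = flank_imbalance)
}

#' Somatic mutations carried by one tumor
#'
#' Expands the cohort mutation table (trunk / clade / private /
#' ht_haplotype scoping) to the subset present in a given tumor.
#'
#' @param mutations mutation table from [simulate_cohort()] (`$somatic$mutations`).
#' @param sample_id tumor id.
#' @param clade the tumor's clade label (used for clade-scoped mutations).
#' @return the subset of rows carried by the tumor.
#' @export
mutations_for_sample <- function(mutations, sample_id, clade) {
  keep <- mutations$scope == "all" |
    (mutations$scope == clade) |
    (mutations$scope == "sample" & !is.na(mutations$sample) &
       mutations$sample == sample_id)
  mutations[keep, , drop = FALSE]
}

#' Dosage of somatic mutations in a carrier tumor region
#'
#' Normal case: every somatic mutation sits on a single chromosome copy
#' (dosage 1), including mutations accumulated on the transferred haplotype.
#' In a duplication decoy cohort, mutations predating the duplication
#' (trunk and clade eras) that sit on the duplicated parental copy are
#' present on 2 of the 3 copies.
#'
#' @param mutations rows from [mutations_for_sample()].
#' @param is_carrier whether the tumor carries the extra copy.
#' @param decoy_duplication whether the cohort is a duplication decoy.
#' @return integer dosage vector.
#' @export
mutation_dosage <- function(mutations, is_carrier, decoy_duplication = FALSE) {
  d <- rep(1L, nrow(mutations))
  if (is_carrier && decoy_duplication) {
    pre <- mutations$origin %in% c("trunk", "clade") & mutations$copy == "P1"
    d[pre] <- 2L
  }
  d
}

#' Full hallmark report for one candidate region
#'
#' Runs the three validation hallmarks on a simulated cohort: integer
#' copy-number step, somatic VAF dosage pattern (pooled across carriers,
#' with read counts drawn from the purity mixture at the cohort depth), and
#' the per-copy mutation-density contrast per carrier.
#'
#' @param region list with `chrom`, `start`, `end`.
#' @param cohort an `ht_cohort` with `somatic` and `cn` components.
#' @param window_kb density window width in kb.
#' @param seed seed for the read-count draws of the VAF pattern test.
#' @return list of class `hallmark_report` with elements `region`,
#'   `cn_step`, `vaf_pattern`, `density` (per-carrier contrasts) and
#'   `density_noncarrier` (one reference non-carrier contrast).
#' @export
hallmark_report <- function(region, cohort, window_kb = 10, seed = 1L) {
  truth <- cohort$truth
  tumors <- cohort$samples[cohort$samples$type == "tumor", ]
  carriers <- truth$carrier_ids
  noncarriers <- setdiff(tumors$sample_id, carriers)

  cns <- copy_number_step(region, cohort$cn, carriers, noncarriers)

  muts <- cohort$somatic$mutations
  in_reg <- function(m) m[m$chrom == region$chrom & m$pos >= region$start &
                            m$pos <= region$end, , drop = FALSE]
  set.seed(seed)
  obs <- list()
  for (id in carriers) {
    mm <- in_reg(mutations_for_sample(muts, id, truth$clades[id]))
    if (!nrow(mm)) next
    dos <- mutation_dosage(mm, TRUE, truth$decoy_duplication)
    p <- unname(truth$true_purity[id])
    rc <- emit_read_counts(dos, 3L, p, 0, cohort$samples$mean_depth[1])
    obs[[id]] <- data.frame(
      mutation_id = paste(mm$chrom, mm$pos, mm$origin, mm$copy,
                          ifelse(mm$scope == "sample", mm$sample, mm$scope)),
      alt_reads = rc$alt_reads, depth = rc$ref_reads + rc$alt_reads,
      purity = p, stringsAsFactors = FALSE)
  }
  vp <- if (length(obs)) {
    ob <- do.call(rbind, obs)
    vaf_pattern_test(ob$mutation_id, ob$alt_reads, ob$depth, ob$purity)
  } else list(fraction_two_thirds = NA_real_, pass = NA, n_mutations = 0L)

  chrom_len <- cohort$config$chrom_lengths[[region$chrom]]
  dens <- lapply(carriers, function(id) {
    mm <- mutations_for_sample(muts, id, truth$clades[id])
    mutation_density_contrast(region, mm, cohort$cn, id, chrom_len,
                              window_kb = window_kb)
  })
  names(dens) <- carriers
  ref_nc <- noncarriers[1]
  dens_nc <- if (!is.na(ref_nc)) {
    mm <- mutations_for_sample(muts, ref_nc, truth$clades[ref_nc])
    mutation_density_contrast(region, mm, cohort$cn, ref_nc, chrom_len,
                              window_kb = window_kb)
  } else NULL

  structure(list(region = region, cn_step = cns, vaf_pattern = vp,
                 density = dens, density_noncarrier = dens_nc),
            class = "hallmark_report")
}
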