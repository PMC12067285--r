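#' Per-site, per-sample allele read counts
#'
#' Container for biallelic site read counts across samples: a site table and
#' two integer matrices of reference and alternate read depths with one
#' column per sample.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based),
#'   `ref_allele`, `alt_allele` (extra annotation columns are kept).
#' @param ref_reads,alt_reads integer matrices, sites x samples, with
#'   matching column names.
#' @return an object of class `site_counts`.
#' @export
site_counts <- function(sites, ref_reads, alt_reads) {
  stopifnot(all(c("chrom", "pos", "ref_allele", "alt_allele") %in% names(sites)),
            nrow(sites) == nrow(ref_reads), nrow(sites) == nrow(alt_reads),
            identical(colnames(ref_reads), colnames(alt_reads)))
  if (min(ref_reads) < 0 || min(alt_reads) < 0)
    stop("read counts must be non-negative")
  structure(list(sites = sites, ref_reads = ref_reads, alt_reads = alt_reads,
                 samples = colnames(ref_reads)),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat("site_counts:", nrow(x$sites), "sites x", length(x$samples), "samples\n")
  invisible(x)
}

#' Observed variant allele fractions
#'
#' @param x a `site_counts` object.
#' @param samples optional subset of sample names.
#' @return matrix of alt/(ref+alt); `NaN` where depth is zero.
#' @export
vaf <- function(x, samples = NULL) {
  stopifnot(inherits(x, "site_counts"))
  cols <- samples %||% x$samples
  x$alt_reads[, cols, drop = FALSE] /
    (x$ref_reads[, cols, drop = FALSE] + x$alt_reads[, cols, drop = FALSE])
}

#' Correct an observed VAF for tumor purity and local copy number
#'
#' Inverts the host/tumor read mixture: with purity `p`, tumor copy number
#' `c_t` and host alternate-dosage fraction `g_h` (0, 1/2 or 1, i.e. host
#' alternate copies divided by 2), the corrected VAF is
#' `(vaf_obs * D - 2 * (1 - p) * g_h) / (p * c_t)` with
#' `D = p * c_t + 2 * (1 - p)`, clamped to `[0, 1]`. At purity 1 this is the
#' identity.
#'
#' @param vaf_obs observed VAF (vectorized).
#' @param purity tumor purity in (0, 1].
#' @param tumor_cn tumor total copy number (>= 1).
#' @param host_dosage_fraction host alternate dosage fraction in \{0, 0.5, 1\}.
#' @return corrected VAF in `[0, 1]`; `NA` input propagates (zero-depth
#'   sites should be passed as `NA`).
#' @export
correct_vaf <- function(vaf_obs, purity, tumor_cn, host_dosage_fraction) {
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
  if (any(tumor_cn < 1)) stop("tumor_cn must be >= 1")
  D <- purity * tumor_cn + 2 * (1 - purity)
  out <- (vaf_obs * D - 2 * (1 - purity) * host_dosage_fraction) /
    (purity * tumor_cn)
  pmin(pmax(out, 0), 1)
}

#' Classify a tumor genotype from read counts by binomial likelihood
#'
#' Selects the alternate allele copy number `k` in `0..tumor_cn` maximizing
#' the binomial likelihood of the observed alternate reads at success
#' probability `(p*k + (1-p)*2*g_h) / D`, the purity mixture of tumor and
#' host dosage, flattened by a per-base sequencing error rate
#' (`e + (1 - 2e) * prob`), so that a homozygous state tolerates occasional
#' stray reads of the other allele. The state is `het` iff
#' `0 < k < tumor_cn`. Confidence is the log-likelihood ratio of the best
#' against the second-best `k`. Sites with depth below `min_depth`, or with
#' `tumor_cn < 2` (the screen is restricted to regions retaining at least
#' two copies), are reported `missing`.
#'
#' All arguments are vectorized over sites.
#'
#' @param ref_reads,alt_reads read counts.
#' @param purity tumor purity in (0, 1].
#' @param tumor_cn tumor total copy number.
#' @param host_dosage_fraction host alternate dosage fraction in \{0, 0.5, 1\}.
#' @param min_depth minimum depth for a call (default 15).
#' @param error_rate per-base sequencing error rate (default 0.005).
#' @return data.frame with columns `state` (`hom_ref`, `het`, `hom_alt`,
#'   `missing`), `alt_copies`, `total_cn`, `confidence`.
#' @export
classify_genotype <- function(ref_reads, alt_reads, purity, tumor_cn,
                              host_dosage_fraction, min_depth = 15L,
                              error_rate = 0.005) {
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
  m <- max(length(ref_reads), length(alt_reads), length(purity),
           length(tumor_cn), length(host_dosage_fraction))
  ref_reads <- rep_len(as.integer(ref_reads), m)
  alt_reads <- rep_len(as.integer(alt_reads), m)
  purity <- rep_len(purity, m)
  tumor_cn <- rep_len(as.integer(tumor_cn), m)
  tumor_cn[is.na(tumor_cn)] <- 0L   # outside all segments -> missing
  g_h <- rep_len(host_dosage_fraction, m)
  depth <- ref_reads + alt_reads

  core <- classify_core(alt_reads, depth, purity, tumor_cn, g_h, min_depth,
                        error_rate)
  data.frame(state = decode_state(core$state), alt_copies = core$alt_copies,
             total_cn = tumor_cn, confidence = core$confidence,
             stringsAsFactors = FALSE)
}

# integer-coded genotype classification; see classify_genotype for the
# model. Codes: 0 missing, 1 hom_ref, 2 het, 3 hom_alt.
classify_core <- function(alt_reads, depth, purity, tumor_cn, g_h,
                          min_depth, error_rate = 0.005) {
  m <- length(alt_reads)
  purity <- rep_len(purity, m)
  tumor_cn <- rep_len(tumor_cn, m)
  g_h <- rep_len(g_h, m)
  # log-likelihood up to the k-independent binomial coefficient, which
  # cancels in every comparison below
  score_at <- function(a, d, p) {
    if (p <= 0) { ll <- rep(-Inf, length(a)); ll[a == 0L] <- 0; return(ll) }
    if (p >= 1) { ll <- rep(-Inf, length(a)); ll[a == d] <- 0; return(ll) }
    a * log(p) + (d - a) * log1p(-p)
  }
  best_k <- integer(m); best_ll <- rep(-Inf, m); second_ll <- rep(-Inf, m)
  key <- if (length(unique(purity)) == 1L && all(g_h * 2 == round(g_h * 2)))
    as.integer(tumor_cn * 10L + g_h * 2) else
      match(paste(tumor_cn, g_h, purity), unique(paste(tumor_cn, g_h, purity)))
  for (kk in unique(key)) {
    ii <- which(key == kk)
    cc <- tumor_cn[ii[1]]; gg <- g_h[ii[1]]; pp <- purity[ii[1]]
    a <- alt_reads[ii]; d <- depth[ii]
    S <- vapply(0:max(cc, 0L), function(k)
      score_at(a, d, seq_error_adjust(mixture_prob(k, cc, pp, 2 * gg),
                                      error_rate)),
      numeric(length(ii)))
    if (is.null(dim(S))) S <- matrix(S, nrow = 1L)
    o1 <- max.col(S, ties.method = "first")
    rows <- seq_len(nrow(S))
    bl <- S[cbind(rows, o1)]
    S[cbind(rows, o1)] <- -Inf
    sl <- if (ncol(S) > 1L) S[cbind(rows, max.col(S, ties.method = "first"))]
      else rep(-Inf, nrow(S))
    best_k[ii] <- o1 - 1L; best_ll[ii] <- bl; second_ll[ii] <- sl
  }
  state <- rep(2L, m)
  state[best_k == 0L] <- 1L
  state[best_k == tumor_cn & tumor_cn > 0L] <- 3L
  confidence <- best_ll - second_ll
  missing <- depth < min_depth | tumor_cn < 2L
  state[missing] <- 0L
  best_k[missing] <- NA_integer_
  confidence[missing] <- NA_real_
  list(state = state, alt_copies = best_k, confidence = confidence)
}

#' Decode integer genotype-state codes to labels
#'
#' The package stores genotype states internally as integers (0 missing,
#' 1 hom_ref, 2 het, 3 hom_alt) for speed; this converts them back.
#'
#' @param code integer vector or matrix of state codes.
#' @return character of the same shape.
#' @export
decode_state <- function(code) {
  out <- c("missing", "hom_ref", "het", "hom_alt")[code + 1L]
  if (!is.null(dim(code))) dim(out) <- dim(code)
  dimnames(out) <- dimnames(code)
  out
}

# accept either coded or labelled states
state_codes <- function(states) {
  if (is.numeric(states)) return(states)
  out <- match(states, c("missing", "hom_ref", "het", "hom_alt")) - 1L
  dim(out) <- dim(states)
  dimnames(out) <- dimnames(states)
  out
}

#' Consensus heterozygous/homozygous state across tumors of a lineage
#'
#' A site's consensus is the strict majority of non-missing homozygous
#' versus heterozygous calls. A tie, or non-missing calls in fewer than
#' `min_coverage` of the tumors, leaves the site `undetermined`.
#'
#' @param states matrix (sites x tumors) of genotype states as produced by
#'   [classify_genotype()] / [genotype_cohort()] — labelled or
#'   integer-coded — or a vector for one site.
#' @param min_coverage minimum fraction of tumors with non-missing calls
#'   (default 0.8).
#' @return character vector of `"hom"`, `"het"` or `"undetermined"` per site.
#' @export
consensus_state <- function(states, min_coverage = 0.8) {
  states <- state_codes(states)
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  n <- ncol(states)
  n_hom <- rowSums(states == 1L | states == 3L)
  n_het <- rowSums(states == 2L)
  covered <- (n_hom + n_het) / n >= min_coverage
  out <- rep("undetermined", nrow(states))
  out[covered & n_hom > n_het] <- "hom"
  out[covered & n_het > n_hom] <- "het"
  out
}

#' Genotype every tumor of a cohort against its local copy number
#'
#' Pipeline step over a `site_counts` object: looks up each tumor's copy
#' number at each site from its segments, takes the host alternate dosage
#' from the matched host's own genotype call (hosts are assumed diploid;
#' if the host column is absent the dosage is estimated as twice the host
#' VAF rounded to the nearest of 0, 1/2, 1 — here, from the tumor's
#' host-free model), and classifies each (site, tumor) genotype.
#'
#' @param counts a `site_counts` object containing tumor and host columns.
#' @param samples sample sheet with columns `sample_id`, `type`, `host_id`,
#'   `purity`.
#' @param cn_segments per-sample copy-number segments (`chrom`, `start`,
#'   `end`, `sample`, `total_cn`).
#' @param min_depth minimum depth for a call.
#' @return list with matrices `state`, `alt_copies`, `total_cn`,
#'   `confidence` (sites x tumors) and `host_dosage` used.
#' @export
genotype_cohort <- function(counts, samples, cn_segments, min_depth = 15L) {
  stopifnot(inherits(counts, "site_counts"))
  tums <- samples[samples$type == "tumor", , drop = FALSE]
  ns <- nrow(counts$sites)
  dn <- list(NULL, tums$sample_id)
  state <- matrix(0L, ns, nrow(tums), dimnames = dn)
  altc <- matrix(NA_integer_, ns, nrow(tums), dimnames = dn)
  cnm <- matrix(NA_integer_, ns, nrow(tums), dimnames = dn)
  conf <- matrix(NA_real_, ns, nrow(tums), dimnames = dn)
  hostd <- matrix(NA_real_, ns, nrow(tums), dimnames = dn)
  for (i in seq_len(nrow(tums))) {
    id <- tums$sample_id[i]
    cn <- cn_at_sites(counts$sites, cn_segments, id)
    cn[is.na(cn)] <- 0L
    host <- tums$host_id[i]
    if (!is.na(host) && host %in% counts$samples) {
      ha <- counts$alt_reads[, host]; hr <- counts$ref_reads[, host]
      hcall <- classify_core(ha, hr + ha, purity = 1,
                             tumor_cn = rep(2L, ns), g_h = 0,
                             min_depth = min_depth)
      g_h <- hcall$alt_copies / 2
      nas <- is.na(g_h)
      if (any(nas)) {
        hv <- ha[nas] / (ha[nas] + hr[nas])
        g_h[nas] <- round(2 * hv) / 2
        g_h[is.na(g_h)] <- 0
      }
    } else {
      ta <- counts$alt_reads[, id]; tr <- counts$ref_reads[, id]
      g_h <- round(2 * ta / (ta + tr)) / 2
      g_h[is.na(g_h)] <- 0
      g_h <- pmin(pmax(g_h, 0), 1)
    }
    ta <- counts$alt_reads[, id]; tr <- counts$ref_reads[, id]
    cl <- classify_core(ta, tr + ta, purity = tums$purity[i], tumor_cn = cn,
                        g_h = g_h, min_depth = min_depth)
    state[, i] <- cl$state
    altc[, i] <- cl$alt_copies
    cnm[, i] <- cn
    conf[, i] <- cl$confidence
    hostd[, i] <- g_h
  }
  cnm[cnm == 0L] <- NA_integer_
  list(state = state, alt_copies = altc, total_cn = cnm, confidence = conf,
       host_dosage = hostd)
}

#' Copy number at each site for one sample
#'
#' @param sites site table with `chrom` and `pos`.
#' @param cn_segments per-sample segments.
#' @param sample_id sample to look up.
#' @return integer vector of total copy number per site (`NA` outside all
#'   segments).
#' @keywords internal
cn_at_sites <- function(sites, cn_segments, sample_id) {
  segs <- cn_segments[cn_segments$sample == sample_id, , drop = FALSE]
  out <- rep(NA_integer_, nrow(sites))
  for (ch in unique(segs$chrom)) {
    s <- segs[segs$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    here <- which(sites$chrom == ch)
    if (!length(here)) next
    idx <- findInterval(sites$pos[here], s$start)
    valid <- idx >= 1L & sites$pos[here] <= s$end[pmax(idx, 1L)]
    out[here[valid]] <- s$total_cn[idx[valid]]
  }
  out
}
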