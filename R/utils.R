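#' Modal integer value of a vector
#'
#' Most frequent value; ties are reported as `NA` so that callers can mark
#' the segment indeterminate rather than silently picking a state.
#'
#' @param x integer vector (NAs dropped).
#' @return the modal value, or `NA` on a tie or when `x` is empty.
#' @keywords internal
modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_integer_)
  tb <- table(x)
  top <- tb[tb == max(tb)]
  if (length(top) > 1L) return(NA_integer_)
  as.integer(names(top))
}

#' Intersect an interval with a set of segments
#'
#' @param chrom,start,end query interval (1-based, inclusive).
#' @param segments data.frame with columns chrom, start, end (same convention).
#' @return the rows of `segments` overlapping the query, with start/end
#'   clipped to the query.
#' @keywords internal
clip_segments <- function(segments, chrom, start, end) {
  hit <- segments$chrom == chrom & segments$start <= end & segments$end >= start
  out <- segments[hit, , drop = FALSE]
  if (nrow(out)) {
    out$start <- pmax(out$start, start)
    out$end <- pmin(out$end, end)
  }
  out
}

#' Derive a stream of child seeds from one integer seed
#'
#' Used so that independently generated components of a simulation are
#' reproducible regardless of which other components are requested.
#' All seeds stay below 2^31.
#'
#' @param seed integer scalar.
#' @param n number of child seeds.
#' @keywords internal
child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Mixture success probability for tumor-derived reads
#'
#' Expected alternate-read fraction at a site in a bulk tumor biopsy that is
#' a mixture of cancer cells (purity `p`, `k` alternate copies of `c` total)
#' and host cells (diploid, `h` alternate copies of 2).
#'
#' @param k alternate allele copies in the cancer cell.
#' @param c_t total copy number in the cancer cell.
#' @param p tumor purity in (0, 1].
#' @param h host alternate allele dosage in \{0, 1, 2\}.
#' @return expected alternate read fraction.
#' @keywords internal
mixture_prob <- function(k, c_t, p, h) {
  (p * k + (1 - p) * h) / (p * c_t + 2 * (1 - p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flatten a read success probability by a sequencing error rate
#'
#' `e + (1 - 2e) * prob`: a state expecting no reads of an allele still
#' tolerates error reads at rate `e`.
#'
#' @param prob expected allele fraction.
#' @param e per-base error rate.
#' @keywords internal
seq_error_adjust <- function(prob, e) e + (1 - 2 * e) * prob

#' Exact binomial sampling grouped by identical (size, prob) pairs
#'
#' Equivalent to `rbinom(length(depth), depth, prob)` but routes each group
#' of identical arguments through the scalar-argument sampler, which is
#' several-fold faster than the vector path; the site probabilities of the
#' read model take only a handful of distinct values, so grouping is cheap.
#'
#' @param depth integer sizes.
#' @param prob success probabilities (few distinct values expected).
#' @return integer vector of draws.
#' @keywords internal
rbinom_grouped <- function(depth, prob) {
  n <- length(depth)
  prob <- rep_len(prob, n)
  if (length(unique(prob)) > 200L) return(stats::rbinom(n, depth, prob))
  o <- order(prob, depth, method = "radix")
  ps <- prob[o]; ds <- depth[o]
  brk <- which(ps[-1] != ps[-n] | ds[-1] != ds[-n])
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  vals <- integer(n)
  for (j in seq_along(starts)) {
    s <- starts[j]; e <- ends[j]
    p <- ps[s]
    if (p <= 0) next                      # vals already 0
    else if (p >= 1) vals[s:e] <- ds[s]
    else vals[s:e] <- stats::rbinom(e - s + 1L, ds[s], p)
  }
  out <- integer(n)
  out[o] <- vals
  out
}
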