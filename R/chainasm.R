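#' Assemble the transferred element's block chain from breakpoint junctions
#'
#' Given the copy-number step segments implicated by the screen and a set of
#' breakpoint junctions, walks the derivative structure as a simple chain:
#' starting from a seed terminus, alternate between traversing a segment and
#' hopping across the junction matched to its exit end, until an end with no
#' partner junction is reached. Each visited segment is emitted as an
#' oriented block; a block is `"-"` when entered via its right end.
#'
#' Breakends are matched to segment ends (segment start = left end, segment
#' end = right end) on the same chromosome within `tol` base pairs —
#' copy-number breakpoints are window-resolution, so exact agreement is not
#' expected. Junctions with a breakend that matches no segment end are
#' dropped (recorded in the result). A breakend matched by two or more
#' junctions breaks the simple-chain assumption and is an error; a walk that
#' returns to its starting end is reported as a circular element, not an
#' error.
#'
#' @param junctions data.frame with columns `chrom1`, `pos1`, `side1`,
#'   `chrom2`, `pos2`, `side2`, `support`.
#' @param segments data.frame of step segments (`chrom`, `start`, `end`).
#' @param seed_terminus optional list `(chrom, pos, side)` naming the free
#'   segment end to start from; default: the free end on the
#'   alphabetically/numerically first chromosome, smallest position.
#' @param tol breakend-to-segment-end matching tolerance in bp
#'   (default 5000).
#' @param min_support minimum junction read support (default 3).
#' @param centromeres named vector of centromere positions per chromosome
#'   (default 1 for every chromosome seen, i.e. acrocentric).
#' @param chrom_lengths optional named vector for telomeric terminus
#'   annotation.
#' @param terminus_tol distance within which a terminus is called
#'   centromeric/telomeric (default 1e6).
#' @return object of class `ht_chain`: list with `blocks` (data.frame
#'   `chrom`, `start`, `end`, `orientation`, `order`), `circular`,
#'   `termini` (annotations of the two chain ends), `dropped_junctions`.
#' @export
assemble_chain <- function(junctions, segments, seed_terminus = NULL,
                           tol = 5000, min_support = 3L,
                           centromeres = NULL, chrom_lengths = NULL,
                           terminus_tol = 1e6) {
  segments <- as.data.frame(segments)
  junctions <- junctions[junctions$support >= min_support, , drop = FALSE]
  ns <- nrow(segments)
  if (ns == 0L) stop("no segments to assemble")

  ends <- data.frame(
    seg = rep(seq_len(ns), 2L),
    side = rep(c("left", "right"), each = ns),
    chrom = rep(segments$chrom, 2L),
    pos = c(segments$start, segments$end),
    stringsAsFactors = FALSE)
  end_key <- function(seg, side) paste0(seg, ":", side)

  match_end <- function(chrom, pos, side_hint) {
    cand <- which(ends$chrom == chrom & abs(ends$pos - pos) <= tol)
    if (!length(cand)) return(NA_integer_)
    if (length(cand) > 1L) {
      hinted <- cand[ends$side[cand] == side_hint]
      if (length(hinted) == 1L) return(hinted)
      d <- abs(ends$pos[cand] - pos)
      nearest <- cand[d == min(d)]
      if (length(nearest) > 1L)
        stop("ambiguous breakend at ", chrom, ":", pos,
             " matches multiple segment ends within tolerance")
      return(nearest)
    }
    cand
  }

  partner <- stats::setNames(vector("list", 2L * ns),
                             end_key(ends$seg, ends$side))
  dropped <- integer(0)
  for (i in seq_len(nrow(junctions))) {
    a <- match_end(junctions$chrom1[i], junctions$pos1[i], junctions$side1[i])
    b <- match_end(junctions$chrom2[i], junctions$pos2[i], junctions$side2[i])
    if (is.na(a) || is.na(b)) { dropped <- c(dropped, i); next }
    ka <- end_key(ends$seg[a], ends$side[a])
    kb <- end_key(ends$seg[b], ends$side[b])
    for (kk in list(c(ka, kb), c(kb, ka))) {
      if (!is.null(partner[[kk[1]]]))
        stop("branching at breakend ", kk[1],
             ": matched by junctions ", partner[[kk[1]]]$junction, " and ", i)
      partner[[kk[1]]] <- list(key = kk[2], junction = i)
    }
  }

  free <- names(partner)[vapply(partner, is.null, logical(1))]
  circular_input <- length(free) == 0L
  if (is.null(seed_terminus)) {
    if (circular_input) {
      start_key <- end_key(1L, "left")
    } else {
      fseg <- as.integer(sub(":.*", "", free))
      fside <- sub(".*:", "", free)
      fpos <- ifelse(fside == "left", segments$start[fseg],
                     segments$end[fseg])
      ord <- order(segments$chrom[fseg], fpos, fside)
      start_key <- free[ord[1]]
    }
  } else {
    idx <- match_end(seed_terminus$chrom, seed_terminus$pos,
                     seed_terminus$side %||% "left")
    if (is.na(idx)) stop("seed terminus matches no segment end")
    start_key <- end_key(ends$seg[idx], ends$side[idx])
  }

  blocks <- list()
  visited <- logical(ns)
  cur <- start_key
  circular <- FALSE
  repeat {
    seg_i <- as.integer(sub(":.*", "", cur))
    side_in <- sub(".*:", "", cur)
    if (visited[seg_i]) { circular <- TRUE; break }
    visited[seg_i] <- TRUE
    blocks[[length(blocks) + 1L]] <- data.frame(
      chrom = segments$chrom[seg_i], start = segments$start[seg_i],
      end = segments$end[seg_i],
      orientation = if (side_in == "left") "+" else "-",
      stringsAsFactors = FALSE)
    side_out <- if (side_in == "left") "right" else "left"
    nxt <- partner[[end_key(seg_i, side_out)]]
    if (is.null(nxt)) { last_key <- end_key(seg_i, side_out); break }
    cur <- nxt$key
  }
  blocks <- do.call(rbind, blocks)
  blocks$order <- seq_len(nrow(blocks))
  rownames(blocks) <- NULL

  annot <- function(key) {
    seg_i <- as.integer(sub(":.*", "", key))
    side <- sub(".*:", "", key)
    chrom <- segments$chrom[seg_i]
    pos <- if (side == "left") segments$start[seg_i] else segments$end[seg_i]
    cen <- if (!is.null(centromeres) && chrom %in% names(centromeres))
      centromeres[[chrom]] else 1
    type <- "internal"
    if (abs(pos - cen) <= terminus_tol) type <- "centromeric"
    else if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths) &&
             abs(pos - chrom_lengths[[chrom]]) <= terminus_tol)
      type <- "telomeric"
    list(chrom = chrom, pos = pos, side = side, type = type)
  }
  termini <- if (circular) list() else
    list(start = annot(start_key), end = annot(last_key))

  structure(list(blocks = blocks, circular = circular, termini = termini,
                 dropped_junctions = dropped),
            class = "ht_chain")
}

#' Summarize an assembled element chain
#'
#' @param chain an `ht_chain` from [assemble_chain()].
#' @return list with `n_blocks`, `n_chromosomes`, `total_length` (sum of
#'   block lengths in bp), `termini` and `circular`.
#' @export
summarize_element <- function(chain) {
  stopifnot(inherits(chain, "ht_chain"))
  b <- chain$blocks
  if (!nrow(b)) stop("empty chain")
  list(n_blocks = nrow(b),
       n_chromosomes = length(unique(b$chrom)),
       total_length = sum(b$end - b$start + 1),
       termini = chain$termini,
       circular = chain$circular)
}

#' @export
print.ht_chain <- function(x, ...) {
  s <- summarize_element(x)
  cat("ht_chain:", s$n_blocks, "blocks on", s$n_chromosomes,
      "chromosomes,", round(s$total_length / 1e6, 2), "Mb",
      if (x$circular) "(circular)" else "", "\n")
  invisible(x)
}
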