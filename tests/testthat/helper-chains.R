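# Random simple-chain generator and an exhaustive search oracle for chain
# assembly. The oracle enumerates every segment ordering and orientation
# consistent with the junction set by depth-first extension (each partial
# chain is extended only through a junction matching its exit end, which is
# exactly the set of orderings a full enumeration would retain).

random_chain_case <- function(seed, max_blocks = 8L) {
  set.seed(seed)
  n <- sample(2:max_blocks, 1L)
  chroms <- as.character(sample(1:38, n, replace = TRUE))
  # non-overlapping blocks: lay them out on distinct 10-Mb lanes
  start <- (seq_len(n) - 1L) * 10e6 + sample(1e6, n)
  len <- sample(2e5:3e6, n)
  blocks <- data.frame(chrom = chroms, start = start,
                       end = start + len - 1L,
                       orientation = sample(c("+", "-"), n, replace = TRUE),
                       stringsAsFactors = FALSE)
  exit_end <- function(b) if (b$orientation == "+")
    list(pos = b$end, side = "right") else list(pos = b$start, side = "left")
  entry_end <- function(b) if (b$orientation == "+")
    list(pos = b$start, side = "left") else list(pos = b$end, side = "right")
  junctions <- do.call(rbind, lapply(seq_len(n - 1L), function(i) {
    a <- blocks[i, ]; b <- blocks[i + 1L, ]
    ea <- exit_end(a); eb <- entry_end(b)
    data.frame(chrom1 = a$chrom, pos1 = ea$pos, side1 = ea$side,
               chrom2 = b$chrom, pos2 = eb$pos, side2 = eb$side,
               support = 10L, stringsAsFactors = FALSE)
  }))
  segs <- blocks[sample.int(n), c("chrom", "start", "end")]   # shuffle input
  rownames(segs) <- NULL
  list(blocks = blocks, junctions = junctions, segments = segs)
}

# exhaustive oracle: all maximal chains (ordering + orientations) consistent
# with the junctions; returns a canonical key per chain
chain_oracle <- function(junctions, segments) {
  n <- nrow(segments)
  end_pos <- function(i, side) if (side == "left") segments$start[i] else
    segments$end[i]
  # junction lookup: which (segment, side) pairs are joined
  jmatch <- function(chrom, pos, side) {
    hit <- (junctions$chrom1 == chrom & junctions$pos1 == pos &
              junctions$side1 == side)
    hit2 <- (junctions$chrom2 == chrom & junctions$pos2 == pos &
               junctions$side2 == side)
    list(as1 = which(hit), as2 = which(hit2))
  }
  partner_of <- function(i, side) {
    m <- jmatch(segments$chrom[i], end_pos(i, side), side)
    out <- list()
    for (j in m$as1) {
      ends2 <- if (junctions$side2[j] == "left") segments$start else
        segments$end
      hit <- which(segments$chrom == junctions$chrom2[j] &
                     ends2 == junctions$pos2[j])
      for (h in hit) out[[length(out) + 1L]] <-
          list(seg = h, side = junctions$side2[j])
    }
    for (j in m$as2) {
      ends1 <- if (junctions$side1[j] == "left") segments$start else
        segments$end
      hit <- which(segments$chrom == junctions$chrom1[j] &
                     ends1 == junctions$pos1[j])
      for (h in hit) out[[length(out) + 1L]] <-
          list(seg = h, side = junctions$side1[j])
    }
    out
  }
  chains <- list()
  extend <- function(order, orients, used) {
    i <- order[length(order)]
    side_out <- if (orients[length(orients)] == "+") "right" else "left"
    nxt <- partner_of(i, side_out)
    nxt <- Filter(function(x) !used[x$seg], nxt)
    if (!length(nxt)) {
      chains[[length(chains) + 1L]] <<- list(order = order, orients = orients)
      return(invisible())
    }
    for (x in nxt) {
      used2 <- used; used2[x$seg] <- TRUE
      extend(c(order, x$seg), c(orients,
                                if (x$side == "left") "+" else "-"), used2)
    }
  }
  for (i in seq_len(n)) for (ori in c("+", "-")) {
    # only start from a free end (maximal chains)
    side_in <- if (ori == "+") "left" else "right"
    if (length(partner_of(i, side_in))) next
    used <- rep(FALSE, n); used[i] <- TRUE
    extend(i, ori, used)
  }
  vapply(chains, function(ch) paste(
    segments$chrom[ch$order], segments$start[ch$order], ch$orients,
    collapse = ";"), character(1))
}

chain_key <- function(chain, segments = NULL) {
  b <- chain$blocks
  paste(b$chrom, b$start, b$orientation, collapse = ";")
}
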