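test_that("two segments joined by one junction assemble in junction orientation", {
  segs <- data.frame(chrom = c("1", "2"), start = c(1e6, 5e6),
                     end = c(2e6, 6e6), stringsAsFactors = FALSE)
  j <- data.frame(chrom1 = "1", pos1 = 2e6, side1 = "right",
                  chrom2 = "2", pos2 = 6e6, side2 = "right",
                  support = 10L, stringsAsFactors = FALSE)
  ch <- assemble_chain(j, segs,
                       seed_terminus = list(chrom = "1", pos = 1e6,
                                            side = "left"))
  expect_identical(ch$blocks$chrom, c("1", "2"))
  # the second block is entered through its right end: inverted
  expect_identical(ch$blocks$orientation, c("+", "-"))
  expect_false(ch$circular)
  s <- summarize_element(ch)
  expect_identical(s$n_blocks, 2L)
  expect_equal(s$total_length, (2e6 - 1e6 + 1) + (6e6 - 5e6 + 1))
})

test_that("a single block summarizes to itself", {
  segs <- data.frame(chrom = "5", start = 1, end = 1e6)
  no_j <- data.frame(chrom1 = character(0), pos1 = integer(0),
                     side1 = character(0), chrom2 = character(0),
                     pos2 = integer(0), side2 = character(0),
                     support = integer(0), stringsAsFactors = FALSE)
  ch <- assemble_chain(no_j, segs)
  s <- summarize_element(ch)
  expect_identical(s$n_blocks, 1L)
  expect_identical(s$n_chromosomes, 1L)
  expect_equal(s$total_length, 1e6)
})

test_that("the packaged element fixture assembles into the published topology", {
  # synthetic stand-in fixture matching the published summary: 11 blocks
  # from six chromosomes, ~15 Mb, centromere to centromere
  jf <- system.file("extdata", "nht1_junctions_synthetic.bedpe",
                    package = "hgtscreen")
  sf <- system.file("extdata", "nht1_step_segments_synthetic.bed",
                    package = "hgtscreen")
  j <- read_junctions_bedpe(jf)
  segs <- utils::read.table(sf, col.names = c("chrom", "start", "end",
                                              "name"),
                            colClasses = c("character", "integer",
                                           "integer", "character"))
  segs$start <- segs$start + 1L
  ch <- assemble_chain(j, segs,
                       seed_terminus = list(chrom = "21", pos = 1,
                                            side = "left"),
                       centromeres = c("21" = 1, "7" = 1))
  s <- summarize_element(ch)
  expect_identical(s$n_blocks, 11L)
  expect_identical(s$n_chromosomes, 6L)
  expect_equal(s$total_length, 15e6)
  expect_identical(ch$termini$start$type, "centromeric")
  expect_identical(ch$termini$end$type, "centromeric")
  expect_identical(ch$termini$start$chrom, "21")
  expect_identical(ch$termini$end$chrom, "7")

  # palindromic symmetry: seeding from the other terminus reverses the
  # chain and flips every orientation
  ch2 <- assemble_chain(j, segs,
                        seed_terminus = list(chrom = "7", pos = 1,
                                             side = "left"),
                        centromeres = c("21" = 1, "7" = 1))
  expect_identical(ch2$blocks$start, rev(ch$blocks$start))
  expect_identical(ch2$blocks$orientation,
                   rev(ifelse(ch$blocks$orientation == "+", "-", "+")))
})

test_that("assembly matches the exhaustive-search oracle on random chains", {
  for (s in 1:100) {
    case <- random_chain_case(seed = 9000 + s, max_blocks = 8L)
    ch <- assemble_chain(case$junctions, case$segments, tol = 0)
    keys <- chain_oracle(case$junctions, case$segments)
    # the oracle finds exactly the chain and its reverse
    rev_blocks <- ch$blocks[rev(seq_len(nrow(ch$blocks))), ]
    rev_blocks$orientation <- ifelse(rev_blocks$orientation == "+", "-", "+")
    expect_setequal(keys, c(chain_key(ch),
                            chain_key(list(blocks = rev_blocks))))
    expect_identical(nrow(ch$blocks), nrow(case$blocks))
  }
})

test_that("breakend matching tolerates window-resolution jitter", {
  case <- random_chain_case(seed = 77, max_blocks = 6L)
  j <- case$junctions
  set.seed(1)
  j$pos1 <- j$pos1 + sample(-2000:2000, nrow(j), replace = TRUE)
  j$pos2 <- j$pos2 + sample(-2000:2000, nrow(j), replace = TRUE)
  ch0 <- assemble_chain(case$junctions, case$segments, tol = 0)
  ch <- assemble_chain(j, case$segments, tol = 5000)
  expect_identical(ch$blocks[, c("chrom", "start", "end", "orientation")],
                   ch0$blocks[, c("chrom", "start", "end", "orientation")])
  expect_equal(summarize_element(ch)$total_length,
               summarize_element(ch0)$total_length)
})

test_that("branching breakends error and circular chains are reported", {
  segs <- data.frame(chrom = c("1", "2", "3"), start = c(1e6, 5e6, 9e6),
                     end = c(2e6, 6e6, 10e6), stringsAsFactors = FALSE)
  j <- data.frame(
    chrom1 = c("1", "1"), pos1 = c(2e6, 2e6), side1 = "right",
    chrom2 = c("2", "3"), pos2 = c(5e6, 9e6), side2 = "left",
    support = 10L, stringsAsFactors = FALSE)
  expect_error(assemble_chain(j, segs), "branching")

  jc <- data.frame(
    chrom1 = c("1", "2"), pos1 = c(2e6, 6e6), side1 = "right",
    chrom2 = c("2", "1"), pos2 = c(5e6, 1e6), side2 = "left",
    support = 10L, stringsAsFactors = FALSE)
  ch <- assemble_chain(jc, segs[1:2, ])
  expect_true(ch$circular)

  # junctions below the support floor are ignored
  jw <- data.frame(chrom1 = "1", pos1 = 2e6, side1 = "right",
                   chrom2 = "2", pos2 = 5e6, side2 = "left",
                   support = 1L, stringsAsFactors = FALSE)
  ch1 <- assemble_chain(jw, segs[1:2, ],
                        seed_terminus = list(chrom = "1", pos = 1e6,
                                             side = "left"))
  expect_identical(nrow(ch1$blocks), 1L)
})

test_that("simulated planted chains summarize to the truth", {
  cfg <- small_config(seed = 41)
  co <- simulate_cohort(cfg, components = c("cn", "junctions"))
  blocks <- co$truth$planted_blocks
  segs <- blocks[, c("chrom", "start", "end")]
  first <- blocks[1, ]
  seed_t <- if (first$orientation == "+")
    list(chrom = first$chrom, pos = first$start, side = "left") else
      list(chrom = first$chrom, pos = first$end, side = "right")
  ch <- assemble_chain(co$junctions, segs, seed_terminus = seed_t)
  s <- summarize_element(ch)
  expect_identical(s$n_blocks, nrow(blocks))
  expect_equal(s$total_length, sum(blocks$end - blocks$start + 1))
  expect_identical(ch$blocks$orientation, blocks$orientation)
})
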