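#' Write per-site allele counts as TSV
#'
#' Wide layout: `chrom`, `pos`, `ref_allele`, `alt_allele`, any extra site
#' annotation columns, then `<sample>.ref` / `<sample>.alt` read-depth pairs.
#'
#' @param counts a `site_counts` object.
#' @param path output file.
#' @export
write_site_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "site_counts"))
  wide <- counts$sites
  for (s in counts$samples) {
    wide[[paste0(s, ".ref")]] <- counts$ref_reads[, s]
    wide[[paste0(s, ".alt")]] <- counts$alt_reads[, s]
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-site allele counts from TSV
#'
#' @param path file written by [write_site_counts_tsv()].
#' @return a `site_counts` object.
#' @export
read_site_counts_tsv <- function(path) {
  wide <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = c(chrom = "character"))
  ref_cols <- grep("\\.ref$", names(wide), value = TRUE)
  alt_cols <- grep("\\.alt$", names(wide), value = TRUE)
  samples <- sub("\\.ref$", "", ref_cols)
  stopifnot(identical(samples, sub("\\.alt$", "", alt_cols)))
  sites <- wide[, setdiff(names(wide), c(ref_cols, alt_cols)), drop = FALSE]
  refm <- as.matrix(wide[, ref_cols, drop = FALSE])
  altm <- as.matrix(wide[, alt_cols, drop = FALSE])
  colnames(refm) <- samples; colnames(altm) <- samples
  site_counts(sites, refm, altm)
}

#' Write per-site allele counts as a multi-sample VCF
#'
#' Minimal VCF 4.2 with one sample column per tumor and host and an
#' `AD`-style allele-depth FORMAT (`GT` is left unphased-missing; the
#' screen's genotypes derive from depths, copy number and purity, not from
#' an upstream caller). The plain text is bgzip-compatible.
#'
#' @param counts a `site_counts` object.
#' @param path output file.
#' @export
write_site_counts_vcf <- function(counts, path) {
  stopifnot(inherits(counts, "site_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=hgtscreen",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", counts$samples), collapse = "\t")), con)
  s <- counts$sites
  geno <- matrix(paste0("./.:", counts$ref_reads, ",", counts$alt_reads),
                 nrow = nrow(s))
  body <- cbind(s$chrom, s$pos, ".", s$ref_allele, s$alt_allele, ".",
                "PASS", ".", "GT:AD", geno)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write or read per-sample copy-number segments as BED
#'
#' Disk layout is 0-based half-open (`chrom`, `start`, `end`, `sample`,
#' `total_cn`); in memory the package uses 1-based inclusive coordinates.
#'
#' @param segments in-memory segment data.frame.
#' @param path file path.
#' @export
write_cn_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = sprintf("%d", as.integer(segments$start - 1)),
                    end = sprintf("%d", as.integer(segments$end)),
                    sample = segments$sample,
                    total_cn = segments$total_cn)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_cn_bed
#' @export
read_cn_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "sample",
                                         "total_cn"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "integer"))
  data.frame(chrom = bed$chrom, start = bed$start + 1L, end = bed$end,
             sample = bed$sample, total_cn = bed$total_cn,
             stringsAsFactors = FALSE)
}

#' Write or read breakpoint junctions as BEDPE
#'
#' One line per junction; the two breakends occupy the paired interval
#' columns (0-based half-open, single-base intervals) and the strand
#' columns encode the breakend sides (`+` = right end of a segment,
#' `-` = left end).
#'
#' @param junctions data.frame with `chrom1`, `pos1`, `side1`, `chrom2`,
#'   `pos2`, `side2`, `support`.
#' @param path file path.
#' @export
write_junctions_bedpe <- function(junctions, path) {
  side2strand <- function(s) ifelse(s == "right", "+", "-")
  bed <- data.frame(
    chrom1 = junctions$chrom1,
    start1 = sprintf("%d", as.integer(junctions$pos1 - 1)),
    end1 = sprintf("%d", as.integer(junctions$pos1)),
    chrom2 = junctions$chrom2,
    start2 = sprintf("%d", as.integer(junctions$pos2 - 1)),
    end2 = sprintf("%d", as.integer(junctions$pos2)),
    name = sprintf("J%03d", seq_len(nrow(junctions))),
    score = junctions$support,
    strand1 = side2strand(junctions$side1),
    strand2 = side2strand(junctions$side2))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_junctions_bedpe
#' @export
read_junctions_bedpe <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "integer", "integer",
                                          "character", "integer",
                                          "character", "character"))
  names(bed) <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                  "name", "score", "strand1", "strand2")
  data.frame(
    chrom1 = bed$chrom1, pos1 = bed$end1,
    side1 = ifelse(bed$strand1 == "+", "right", "left"),
    chrom2 = bed$chrom2, pos2 = bed$end2,
    side2 = ifelse(bed$strand2 == "+", "right", "left"),
    support = bed$score, stringsAsFactors = FALSE)
}

#' Write an assembled chain as ordered BED plus a connection map JSON
#'
#' @param chain an `ht_chain`.
#' @param bed_path ordered BED output (orientation in the strand column,
#'   order index in the score column).
#' @param json_path optional connection-map JSON mirroring the block
#'   adjacency.
#' @export
write_chain <- function(chain, bed_path, json_path = NULL) {
  b <- chain$blocks
  bed <- data.frame(chrom = b$chrom, start = sprintf("%d", as.integer(b$start - 1)),
                    end = sprintf("%d", as.integer(b$end)),
                    name = sprintf("block_%02d", b$order), score = b$order,
                    strand = b$orientation)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(json_path)) {
    s <- summarize_element(chain)
    jsonlite::write_json(
      list(n_blocks = s$n_blocks, n_chromosomes = s$n_chromosomes,
           total_length = s$total_length, circular = chain$circular,
           termini = chain$termini, blocks = b),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bed_path)
}

#' Write a cohort's ground truth as JSON
#'
#' @param truth an `ht_truth` object.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Write an inferred haplotype as a haploid-genotype VCF
#'
#' @param ht_calls output of [infer_ht_genotypes()].
#' @param sites the site table the calls index into.
#' @param path output file.
#' @export
write_haplotype_vcf <- function(ht_calls, sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=hgtscreen haplotype inference",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Haploid genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "HT"), collapse = "\t")), con)
  gt <- c(ref = "0", alt = "1", undetermined = ".")[ht_calls$ht_allele]
  s <- sites[ht_calls$site, , drop = FALSE]
  body <- cbind(s$chrom, s$pos, ".", s$ref_allele, s$alt_allele, ".",
                "PASS", ".", "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
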