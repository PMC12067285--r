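#' Configuration for a synthetic transmissible-cancer cohort
#'
#' Builds and validates the configuration of the cohort generator. The
#' generator emulates the genetic structure a horizontal-transfer screen
#' relies on: a clonal founder germline shared by every tumor, two divergent
#' tumor clades, somatic mutations accumulating as a CpG C>T clock along a
#' simplified transmission tree, integer copy-number segments, a planted
#' multi-block horizontally transferred haplotype from a divergent donor
#' genome, and binomial read sampling under per-tumor purity and depth.
#'
#' Defaults mirror the CTVT cohort: 47 tumors split into a 7-tumor carrier
#' clade (CTVT-A) and a 40-tumor non-carrier clade (CTVT-B-G); sequencing
#' depth 77x; a per-copy mutation rate of 3.435e-7 per site per year; clade
#' divergence and element acquisition 2,006 years before present; lineage
#' age 6,434 years, so that parental chromosome copies carry a per-CpG-site
#' density of 2.21e-3 and the transferred haplotype 6.89e-4. A three-block
#' element chain whose largest block spans 5.5 Mb is planted.
#'
#' The genome spans four chromosomes at their real lengths (~339 Mb total)
#' so that the planted element occupies under 3 percent of the screening
#' windows, matching the sparsity regime the genome-wide outlier statistics
#' assume; somatic mutations are simulated only inside `somatic_regions`
#' (by default the planted blocks plus 5-Mb flanks), the only intervals any
#' downstream analysis reads mutations from.
#'
#' @param n_tumors number of tumors.
#' @param clade_sizes integer vector of clade sizes summing to `n_tumors`.
#' @param carrier_clade index of the clade carrying the transferred element,
#'   or `NA` for a null cohort with no transfer.
#' @param founder_het_rate probability that a panel SNP is heterozygous in
#'   the founder animal.
#' @param donor_divergence probability that the donor haploid allele at a
#'   panel SNP is redrawn uniformly from the site's two alleles.
#' @param somatic_rate_per_copy somatic mutations per site per year per
#'   chromosome copy.
#' @param cpg_fraction fraction of sites in CpG context; also sets the
#'   number of CpG sites per kilobase (`1000 * cpg_fraction`) used by the
#'   molecular clock.
#' @param lineage_age_years age of the cancer lineage (years before present).
#' @param clade_split_years time of the clade divergence (years before
#'   present); must not exceed `lineage_age_years`.
#' @param ht_acquisition_years time of element acquisition (years before
#'   present); must not exceed `clade_split_years`.
#' @param ht_blocks data.frame of planted blocks with columns `chrom`,
#'   `start`, `end`, `orientation` (`"+"`/`"-"`), in chain order. Intervals
#'   are 1-based inclusive and must not overlap within a chromosome.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param somatic_regions data.frame (`chrom`, `start`, `end`) of intervals
#'   in which somatic mutations are simulated; `NULL` (default) uses the
#'   planted blocks extended by `somatic_flank_mb` on each side.
#' @param somatic_flank_mb flank added around each block for the default
#'   `somatic_regions` (default 5).
#' @param cn_profile baseline copy-number segments (data.frame `chrom`,
#'   `start`, `end`, `total_cn`); default diploid everywhere.
#' @param purity_range interval in (0, 1] from which per-tumor purity is
#'   drawn uniformly.
#' @param mean_depth mean sequencing depth (reads); depth is Poisson.
#' @param n_sites number of germline panel SNP sites across the genome.
#' @param rna_genes number of genes simulated for allelic expression.
#' @param decoy_duplication if `TRUE`, the carrier clade's extra copy inside
#'   the blocks is a duplication of a parental chromosome rather than a
#'   horizontally transferred haplotype (a negative-control cohort that
#'   shows the copy-number step without the transfer hallmarks).
#' @param decoy_duplication_years age of the decoy duplication (years before
#'   present); defaults to `ht_acquisition_years`.
#' @param seed integer seed; all randomness in the generator derives from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_tumors = 47L,
                       clade_sizes = c(7L, 40L),
                       carrier_clade = 1L,
                       founder_het_rate = 0.3,
                       donor_divergence = 0.3,
                       somatic_rate_per_copy = 3.435e-7,
                       cpg_fraction = 0.01,
                       lineage_age_years = 6434,
                       clade_split_years = 2006,
                       ht_acquisition_years = 2006,
                       ht_blocks = default_ht_blocks(),
                       chrom_lengths = c("1" = 122.7e6, "7" = 80.9e6,
                                         "8" = 74.3e6, "9" = 61.1e6),
                       somatic_regions = NULL,
                       somatic_flank_mb = 5,
                       cn_profile = NULL,
                       purity_range = c(0.8, 0.95),
                       mean_depth = 77,
                       n_sites = 160000L,
                       rna_genes = 240L,
                       decoy_duplication = FALSE,
                       decoy_duplication_years = NULL,
                       seed = 1L) {
  cfg <- list(
    n_tumors = as.integer(n_tumors), clade_sizes = as.integer(clade_sizes),
    carrier_clade = if (is.na(carrier_clade)) NA_integer_ else as.integer(carrier_clade),
    founder_het_rate = founder_het_rate, donor_divergence = donor_divergence,
    somatic_rate_per_copy = somatic_rate_per_copy, cpg_fraction = cpg_fraction,
    lineage_age_years = lineage_age_years, clade_split_years = clade_split_years,
    ht_acquisition_years = ht_acquisition_years,
    ht_blocks = ht_blocks, chrom_lengths = chrom_lengths,
    somatic_regions = somatic_regions, somatic_flank_mb = somatic_flank_mb,
    cn_profile = cn_profile, purity_range = purity_range,
    mean_depth = mean_depth, n_sites = as.integer(n_sites),
    rna_genes = as.integer(rna_genes),
    decoy_duplication = isTRUE(decoy_duplication),
    decoy_duplication_years = decoy_duplication_years %||% ht_acquisition_years,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  if (is.null(cfg$cn_profile)) {
    cfg$cn_profile <- data.frame(
      chrom = names(chrom_lengths), start = 1,
      end = unname(chrom_lengths), total_cn = 2L,
      stringsAsFactors = FALSE)
  }
  if (is.null(cfg$somatic_regions)) {
    b <- cfg$ht_blocks
    if (!is.null(b) && nrow(b)) {
      fl <- somatic_flank_mb * 1e6
      cfg$somatic_regions <- data.frame(
        chrom = b$chrom,
        start = pmax(1, b$start - fl),
        end = pmin(unname(chrom_lengths[b$chrom]), b$end + fl),
        stringsAsFactors = FALSE)
    } else {
      cfg$somatic_regions <- data.frame(
        chrom = names(chrom_lengths)[1], start = 1,
        end = min(unname(chrom_lengths)[1], 2e7), stringsAsFactors = FALSE)
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Default planted element blocks
#'
#' Three blocks in chain order: a 5.5-Mb block on chromosome 7 (entered from
#' its left end), a 1.5-Mb inverted block on chromosome 1 and a 1.0-Mb block
#' on chromosome 8. Coordinates are aligned to the 100-kb screening grid.
#'
#' @return data.frame with columns chrom, start, end, orientation.
#' @export
default_ht_blocks <- function() {
  data.frame(
    chrom = c("7", "1", "8"),
    start = c(30000001, 60000001, 20000001),
    end = c(35500000, 61500000, 21000000),
    orientation = c("+", "-", "+"),
    stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  stopif <- function(cond, msg) if (cond) stop("invalid sim_config: ", msg, call. = FALSE)
  stopif(cfg$n_tumors < 1L, "n_tumors must be positive")
  stopif(any(cfg$clade_sizes < 0L), "clade sizes must be non-negative")
  stopif(sum(cfg$clade_sizes) != cfg$n_tumors, "clade sizes must sum to n_tumors")
  stopif(!is.na(cfg$carrier_clade) &&
           (cfg$carrier_clade < 1L || cfg$carrier_clade > length(cfg$clade_sizes)),
         "carrier_clade out of range")
  for (p in c("founder_het_rate", "donor_divergence", "cpg_fraction"))
    stopif(cfg[[p]] < 0 || cfg[[p]] > 1, paste(p, "must be in [0, 1]"))
  stopif(cfg$somatic_rate_per_copy < 0, "somatic_rate_per_copy must be >= 0")
  stopif(cfg$ht_acquisition_years > cfg$clade_split_years,
         "ht_acquisition_years must not exceed clade_split_years")
  stopif(cfg$clade_split_years > cfg$lineage_age_years,
         "clade_split_years must not exceed lineage_age_years")
  stopif(length(cfg$purity_range) != 2L || cfg$purity_range[1] <= 0 ||
           cfg$purity_range[2] > 1 || diff(cfg$purity_range) < 0,
         "purity_range must be an ordered interval in (0, 1]")
  stopif(cfg$mean_depth <= 0, "mean_depth must be positive")
  stopif(is.null(names(cfg$chrom_lengths)) || any(cfg$chrom_lengths <= 0),
         "chrom_lengths must be a named vector of positive lengths")
  b <- cfg$ht_blocks
  if (!is.null(b) && nrow(b)) {
    stopif(!all(c("chrom", "start", "end", "orientation") %in% names(b)),
           "ht_blocks needs chrom/start/end/orientation")
    stopif(any(b$end <= b$start), "ht_blocks must have end > start")
    stopif(!all(b$chrom %in% names(cfg$chrom_lengths)),
           "ht_blocks reference unknown chromosomes")
    for (ch in unique(b$chrom)) {
      bb <- b[b$chrom == ch, , drop = FALSE]
      bb <- bb[order(bb$start), , drop = FALSE]
      stopif(nrow(bb) > 1L && any(bb$start[-1] <= bb$end[-nrow(bb)]),
             "ht_blocks overlap within a chromosome")
    }
  }
  invisible(cfg)
}

#' Simulate a synthetic transmissible-cancer cohort
#'
#' Generates, deterministically given `config$seed`, the inputs of the
#' horizontal-transfer screen together with a full ground-truth record:
#' per-site read counts for tumors and matched hosts (`panel`), per-tumor
#' integer copy-number segments (`cn`), breakpoint junctions encoding the
#' planted block chain (`junctions`), somatic mutations labelled by their
#' phylogenetic origin (`somatic`) and per-allele RNA read counts (`rna`).
#'
#' The transmission tree is a two-clade star: a trunk shared by all tumors,
#' an optional shared carrier-clade branch between the clade split and the
#' element acquisition, and private branches to each tumor. The transferred
#' haplotype enters the carrier clade ancestor free of somatic mutations and
#' accumulates them privately thereafter, so its expected per-site per-copy
#' density is `somatic_rate_per_copy * ht_acquisition_years`.
#'
#' @param config a [sim_config()] object.
#' @param components character subset of
#'   `c("panel", "cn", "junctions", "somatic", "rna")`; each component is
#'   reproducible on its own, so skipping expensive ones does not change
#'   the others.
#' @return a list of class `ht_cohort` with elements `samples` (sample
#'   sheet), `panel` (a `site_counts` object), `cn`, `junctions`, `somatic`,
#'   `rna` and `truth` (class `ht_truth`).
#' @export
simulate_cohort <- function(config,
                            components = c("panel", "cn", "junctions",
                                           "somatic", "rna")) {
  stopifnot(inherits(config, "sim_config"))
  components <- match.arg(components, several.ok = TRUE)
  seeds <- child_seeds(config$seed, 6L)

  n <- config$n_tumors
  tumor_ids <- sprintf("T%02d", seq_len(n))
  host_ids <- sprintf("H%02d", seq_len(n))
  clade_idx <- rep(seq_along(config$clade_sizes), config$clade_sizes)
  clade_lab <- paste0("clade", LETTERS[clade_idx])
  carriers <- if (is.na(config$carrier_clade)) character(0) else
    tumor_ids[clade_idx == config$carrier_clade]

  set.seed(seeds[1])
  purity <- stats::runif(n, config$purity_range[1], config$purity_range[2])
  names(purity) <- tumor_ids
  samples <- data.frame(
    sample_id = c(tumor_ids, host_ids),
    type = rep(c("tumor", "host"), each = n),
    lineage = c(clade_lab, rep("host", n)),
    host_id = c(host_ids, host_ids),
    purity = c(purity, rep(1, n)),
    mean_depth = config$mean_depth,
    stringsAsFactors = FALSE)

  blocks <- config$ht_blocks
  if (is.na(config$carrier_clade)) blocks <- blocks[0, , drop = FALSE]

  out <- list(samples = samples, config = config)
  truth <- list(carrier_ids = carriers,
                planted_blocks = blocks,
                true_purity = purity,
                clades = stats::setNames(clade_lab, tumor_ids),
                decoy_duplication = config$decoy_duplication)

  cn <- sim_cn_segments(config, tumor_ids, carriers, blocks)
  truth$true_cn <- cn
  if ("cn" %in% components) out$cn <- cn

  if ("panel" %in% components) {
    pan <- sim_panel(config, tumor_ids, host_ids, carriers, purity, blocks,
                     seed = seeds[2])
    out$panel <- pan$counts
    truth$donor_genotypes <- pan$donor
    truth$founder_dosage <- pan$founder
  }
  if ("junctions" %in% components)
    out$junctions <- sim_junctions(blocks, seed = seeds[3])
  if ("somatic" %in% components) {
    out$somatic <- sim_somatic(config, tumor_ids, carriers, clade_lab, blocks,
                               seed = seeds[4])
    truth$per_mutation_origin <- out$somatic$origin
  }
  if ("rna" %in% components) {
    rna <- sim_rna(config, tumor_ids, carriers, purity, blocks, seed = seeds[5])
    out$rna <- rna$counts
    truth$rna_truth <- rna$truth
  }
  class(truth) <- "ht_truth"
  out$truth <- truth
  class(out) <- "ht_cohort"
  out
}

# ---- components ------------------------------------------------------------

sim_cn_segments <- function(config, tumor_ids, carriers, blocks) {
  base <- config$cn_profile
  rows <- vector("list", length(tumor_ids))
  for (i in seq_along(tumor_ids)) {
    id <- tumor_ids[i]
    segs <- base
    if (id %in% carriers && nrow(blocks)) {
      pieces <- list()
      for (j in seq_len(nrow(segs))) {
        s <- segs[j, ]
        bb <- blocks[blocks$chrom == s$chrom &
                       blocks$start <= s$end & blocks$end >= s$start, , drop = FALSE]
        if (!nrow(bb)) { pieces[[length(pieces) + 1L]] <- s; next }
        bb <- bb[order(bb$start), , drop = FALSE]
        cur <- s$start
        for (k in seq_len(nrow(bb))) {
          b0 <- max(bb$start[k], s$start); b1 <- min(bb$end[k], s$end)
          if (b0 > cur)
            pieces[[length(pieces) + 1L]] <- data.frame(
              chrom = s$chrom, start = cur, end = b0 - 1, total_cn = s$total_cn)
          pieces[[length(pieces) + 1L]] <- data.frame(
            chrom = s$chrom, start = b0, end = b1, total_cn = s$total_cn + 1L)
          cur <- b1 + 1
        }
        if (cur <= s$end)
          pieces[[length(pieces) + 1L]] <- data.frame(
            chrom = s$chrom, start = cur, end = s$end, total_cn = s$total_cn)
      }
      segs <- do.call(rbind, pieces)
    }
    segs$sample <- id
    rows[[i]] <- segs
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "sample", "total_cn")]
}

sim_panel <- function(config, tumor_ids, host_ids, carriers, purity, blocks,
                      seed) {
  set.seed(seed)
  n_sites <- config$n_sites
  chroms <- names(config$chrom_lengths)
  chrom <- sample(chroms, n_sites, replace = TRUE,
                  prob = config$chrom_lengths / sum(config$chrom_lengths))
  pos <- floor(stats::runif(n_sites, 1, config$chrom_lengths[chrom] + 1))
  ord <- order(match(chrom, chroms), pos)
  chrom <- chrom[ord]; pos <- pos[ord]

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L +
                  sample.int(3L, n_sites, replace = TRUE)) %% 4L + 1L]
  sites <- data.frame(
    chrom = chrom, pos = as.integer(pos), ref_allele = ref, alt_allele = alt,
    cpg = stats::rbinom(n_sites, 1L, config$cpg_fraction) == 1L,
    transversion = stats::rbinom(n_sites, 1L, 1 / 3) == 1L,
    stringsAsFactors = FALSE)

  in_block <- rep(FALSE, n_sites)
  if (nrow(blocks))
    for (j in seq_len(nrow(blocks)))
      in_block <- in_block | (chrom == blocks$chrom[j] &
                                pos >= blocks$start[j] & pos <= blocks$end[j])

  # founder germline: dosage of the alternate allele on the two parental copies
  het <- stats::rbinom(n_sites, 1L, config$founder_het_rate) == 1L
  founder <- integer(n_sites)
  founder[het] <- 1L
  founder[!het] <- 2L * stats::rbinom(sum(!het), 1L, 0.5)
  hap1_alt <- integer(n_sites)                   # allele on parental copy 1
  hap1_alt[het] <- stats::rbinom(sum(het), 1L, 0.5)
  hap1_alt[!het] <- founder[!het] / 2L

  # donor haploid genome: copy of parental haplotype 1, redrawn uniformly
  # from the site's two alleles with probability donor_divergence
  redraw <- stats::rbinom(n_sites, 1L, config$donor_divergence) == 1L
  donor_alt <- hap1_alt
  donor_alt[redraw] <- stats::rbinom(sum(redraw), 1L, 0.5)

  # matched-host germlines at population allele frequencies (two Bernoulli
  # draws per genotype; runif comparison is much faster than rbinom here)
  n <- length(tumor_ids)
  f_pop <- stats::runif(n_sites, 0.05, 0.95)
  host_dosage <- matrix(0L, n_sites, n)
  for (i in seq_len(n))
    host_dosage[, i] <- (stats::runif(n_sites) < f_pop) +
      (stats::runif(n_sites) < f_pop)

  decoy <- config$decoy_duplication
  extra_alt <- if (decoy) hap1_alt else donor_alt

  n_tot <- 2L * n
  refm <- matrix(0L, n_sites, n_tot)
  altm <- matrix(0L, n_sites, n_tot)
  for (i in seq_len(n)) {
    is_car <- tumor_ids[i] %in% carriers
    k <- founder + if (is_car) extra_alt * in_block else 0L
    c_t <- rep(2L, n_sites) + if (is_car) as.integer(in_block) else 0L
    pr <- mixture_prob(k, c_t, purity[i], host_dosage[, i])
    d <- stats::rpois(n_sites, config$mean_depth)
    a <- rbinom_grouped(d, pr)
    altm[, i] <- a; refm[, i] <- d - a
    dh <- stats::rpois(n_sites, config$mean_depth)
    ah <- rbinom_grouped(dh, host_dosage[, i] / 2)
    altm[, n + i] <- ah; refm[, n + i] <- dh - ah
  }
  ids <- c(tumor_ids, host_ids)
  colnames(refm) <- ids; colnames(altm) <- ids

  donor <- data.frame(site = which(in_block),
                      donor_alt = donor_alt[in_block])
  counts <- site_counts(sites, refm, altm)
  list(counts = counts, donor = donor, founder = founder)
}

sim_junctions <- function(blocks, seed) {
  set.seed(seed)
  if (nrow(blocks) < 2L)
    return(data.frame(chrom1 = character(0), pos1 = integer(0),
                      side1 = character(0), chrom2 = character(0),
                      pos2 = integer(0), side2 = character(0),
                      support = integer(0), stringsAsFactors = FALSE))
  # consecutive blocks in chain order share a junction between the exit end
  # of one and the entry end of the next ("+" blocks are entered at their
  # left end, "-" blocks at their right end)
  exit_end <- function(b) if (b$orientation == "+")
    list(pos = b$end, side = "right") else list(pos = b$start, side = "left")
  entry_end <- function(b) if (b$orientation == "+")
    list(pos = b$start, side = "left") else list(pos = b$end, side = "right")
  rows <- lapply(seq_len(nrow(blocks) - 1L), function(i) {
    a <- blocks[i, ]; b <- blocks[i + 1L, ]
    ea <- exit_end(a); eb <- entry_end(b)
    data.frame(chrom1 = a$chrom, pos1 = ea$pos, side1 = ea$side,
               chrom2 = b$chrom, pos2 = eb$pos, side2 = eb$side,
               support = 5L + stats::rpois(1L, 5), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

sim_somatic <- function(config, tumor_ids, carriers, clade_lab, blocks, seed) {
  set.seed(seed)
  rate <- config$somatic_rate_per_copy
  regions <- config$somatic_regions
  reg_len <- regions$end - regions$start + 1
  G <- sum(reg_len)   # mutations are simulated only inside somatic_regions
  block_len <- if (nrow(blocks)) sum(blocks$end - blocks$start + 1) else 0
  split <- config$clade_split_years
  acq <- config$ht_acquisition_years
  carrier_clade_lab <- if (length(carriers))
    clade_lab[match(carriers[1], tumor_ids)] else NA_character_

  draw_positions <- function(m) {
    ri <- sample.int(nrow(regions), m, replace = TRUE, prob = reg_len)
    pos <- floor(stats::runif(m, regions$start[ri], regions$end[ri] + 1))
    data.frame(chrom = regions$chrom[ri], pos = as.integer(pos),
               cpg = stats::runif(m) < config$cpg_fraction,
               stringsAsFactors = FALSE)
  }
  draw_block_positions <- function(m) {
    w <- blocks$end - blocks$start + 1
    bi <- sample.int(nrow(blocks), m, replace = TRUE, prob = w)
    pos <- floor(stats::runif(m, blocks$start[bi], blocks$end[bi] + 1))
    data.frame(chrom = blocks$chrom[bi], pos = as.integer(pos),
               cpg = stats::runif(m) < config$cpg_fraction,
               stringsAsFactors = FALSE)
  }
  mk <- function(df, origin, scope, sample, copy) {
    if (!nrow(df)) return(NULL)
    cbind(df, origin = origin, scope = scope, sample = sample, copy = copy,
          stringsAsFactors = FALSE)
  }

  rows <- list()
  # trunk: origin -> clade split, shared by every tumor, two parental copies
  m <- stats::rpois(1L, rate * (config$lineage_age_years - split) * G * 2)
  rows$trunk <- mk(draw_positions(m), "trunk", "all", NA_character_,
                   sample(c("P1", "P2"), m, replace = TRUE))
  # carrier-clade branch: split -> acquisition, shared by carriers only
  if (length(carriers) && split > acq) {
    m <- stats::rpois(1L, rate * (split - acq) * G * 2)
    rows$clade <- mk(draw_positions(m), "clade", carrier_clade_lab,
                     NA_character_, sample(c("P1", "P2"), m, replace = TRUE))
  }
  # private branches: clade MRCA -> present (MRCA is the acquisition time in
  # the carrier clade, the split in the others)
  priv <- lapply(seq_along(tumor_ids), function(i) {
    yrs <- if (tumor_ids[i] %in% carriers) acq else split
    m <- stats::rpois(1L, rate * yrs * G * 2)
    mk(draw_positions(m), "private", "sample", tumor_ids[i],
       sample(c("P1", "P2"), m, replace = TRUE))
  })
  # transferred haplotype: mutation-free at acquisition, then accumulates
  # privately on the single extra copy inside the planted blocks
  htrows <- NULL
  if (length(carriers) && block_len > 0 && !config$decoy_duplication) {
    htrows <- lapply(carriers, function(id) {
      m <- stats::rpois(1L, rate * acq * block_len * 1)
      mk(draw_block_positions(m), "ht_haplotype", "sample", id, "HT")
    })
  }
  # decoy duplication: the extra copy is a parental duplicate that has been
  # diverging since decoy_duplication_years, so it carries its own private
  # mutations at dosage 1 (pre-duplication mutations sit at dosage 2)
  duprows <- NULL
  if (length(carriers) && block_len > 0 && config$decoy_duplication) {
    dup_years <- config$decoy_duplication_years
    duprows <- lapply(carriers, function(id) {
      m <- stats::rpois(1L, rate * dup_years * block_len * 1)
      mk(draw_block_positions(m), "private", "sample", id, "DUP")
    })
  }
  all_rows <- c(rows, priv, htrows, duprows)
  all_rows <- all_rows[!vapply(all_rows, is.null, logical(1))]
  muts <- if (length(all_rows)) do.call(rbind, all_rows) else
    data.frame(chrom = character(0), pos = integer(0), cpg = logical(0),
               origin = character(0), scope = character(0),
               sample = character(0), copy = character(0),
               stringsAsFactors = FALSE)
  rownames(muts) <- NULL
  list(mutations = muts, origin = muts$origin,
       carrier_clade = carrier_clade_lab)
}

sim_rna <- function(config, tumor_ids, carriers, purity, blocks, seed) {
  set.seed(seed)
  ng <- config$rna_genes
  n <- length(tumor_ids)
  chroms <- names(config$chrom_lengths)
  # the expression analysis targets genes on the transferred element, so a
  # fixed fraction of simulated genes is placed inside the planted blocks;
  # kept below one half so that the median-of-ratios size factors are
  # anchored by genes whose dosage is identical in carriers and
  # non-carriers (in the real genome the element is a negligible fraction
  # of the transcriptome)
  in_block <- if (nrow(blocks)) stats::runif(ng) < 0.3 else rep(FALSE, ng)
  chrom <- character(ng); pos <- numeric(ng)
  if (any(in_block)) {
    wl <- blocks$end - blocks$start + 1
    bi <- sample.int(nrow(blocks), sum(in_block), replace = TRUE, prob = wl)
    chrom[in_block] <- blocks$chrom[bi]
    pos[in_block] <- floor(stats::runif(sum(in_block), blocks$start[bi],
                                        blocks$end[bi] + 1))
  }
  n_out <- sum(!in_block)
  if (n_out) {
    chrom[!in_block] <- sample(chroms, n_out, replace = TRUE,
                               prob = config$chrom_lengths /
                                 sum(config$chrom_lengths))
    pos[!in_block] <- floor(stats::runif(n_out, 1,
                                         config$chrom_lengths[chrom[!in_block]] + 1))
  }
  gene <- sprintf("G%03d", seq_len(ng))

  cancer_dosage <- ifelse(stats::rbinom(ng, 1L, config$founder_het_rate) == 1L,
                          1L, 2L * stats::rbinom(ng, 1L, 0.5))
  ht_allele <- ifelse(in_block, stats::rbinom(ng, 1L, 0.5), NA_integer_)
  f_pop <- stats::runif(ng, 0.05, 0.95)
  host_dosage <- matrix(stats::rbinom(ng * n, 2L, rep(f_pop, n)), ng, n,
                        dimnames = list(gene, tumor_ids))

  mu <- stats::rlnorm(ng, meanlog = log(50), sdlog = 1)   # cancer program
  nu <- stats::rlnorm(ng, meanlog = log(50), sdlog = 1)   # host program
  size_factor <- stats::runif(n, 0.5, 2)
  names(size_factor) <- tumor_ids

  p_row <- matrix(purity, ng, n, byrow = TRUE)
  lam_alt <- p_row * mu * cancer_dosage +
    (1 - p_row) * nu * host_dosage
  lam_ref <- p_row * mu * (2L - cancer_dosage) +
    (1 - p_row) * nu * (2L - host_dosage)
  if (length(carriers) && !config$decoy_duplication) {
    car_col <- tumor_ids %in% carriers
    ht_term <- ifelse(in_block & !is.na(ht_allele), mu, 0)
    add_alt <- outer(ht_term * ifelse(is.na(ht_allele), 0L, ht_allele),
                     as.numeric(car_col)) * p_row
    add_ref <- outer(ht_term * ifelse(is.na(ht_allele), 0L, 1L - ht_allele),
                     as.numeric(car_col)) * p_row
    lam_alt <- lam_alt + add_alt
    lam_ref <- lam_ref + add_ref
  }
  sf_row <- matrix(size_factor, ng, n, byrow = TRUE)
  ref_count <- stats::rpois(ng * n, as.vector(sf_row * lam_ref))
  alt_count <- stats::rpois(ng * n, as.vector(sf_row * lam_alt))
  counts <- data.frame(
    gene = rep(gene, n), chrom = rep(chrom, n), pos = rep(pos, n),
    sample = rep(tumor_ids, each = ng),
    ref_count = ref_count, alt_count = alt_count,
    stringsAsFactors = FALSE)
  truth <- list(gene = gene, chrom = chrom, pos = pos, in_block = in_block,
                cancer_dosage = cancer_dosage, ht_allele = ht_allele,
                host_dosage = host_dosage, mu = mu, nu = nu,
                size_factor = size_factor)
  list(counts = counts, truth = truth)
}

#' Sample read counts at one or more sites under the purity mixture model
#'
#' Depth is Poisson around `depth_mean`; alternate reads are binomial with
#' success probability
#' `(purity * alt_copies + (1 - purity) * host_dosage) /
#'  (purity * total_cn + 2 * (1 - purity))`,
#' the expected alternate fraction of a bulk biopsy mixing cancer cells with
#' diploid host cells.
#'
#' @param alt_copies alternate allele copies in the cancer cell (0..total_cn).
#' @param total_cn total copy number in the cancer cell.
#' @param purity tumor purity in (0, 1].
#' @param host_dosage alternate allele copies (of 2) in the host cells.
#' @param depth_mean mean sequencing depth.
#' @param seed optional integer seed.
#' @return data.frame with columns `ref_reads` and `alt_reads`.
#' @export
emit_read_counts <- function(alt_copies, total_cn, purity, host_dosage,
                             depth_mean, seed = NULL) {
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
  if (any(alt_copies < 0 | alt_copies > total_cn))
    stop("alt_copies must be between 0 and total_cn")
  if (any(host_dosage < 0 | host_dosage > 2))
    stop("host_dosage must be between 0 and 2")
  if (!is.null(seed)) set.seed(seed)
  m <- max(length(alt_copies), length(total_cn), length(purity),
           length(host_dosage))
  pr <- mixture_prob(rep_len(alt_copies, m), rep_len(total_cn, m),
                     rep_len(purity, m), rep_len(host_dosage, m))
  depth <- stats::rpois(m, depth_mean)
  alt <- stats::rbinom(m, depth, pr)
  data.frame(ref_reads = depth - alt, alt_reads = alt)
}

#' Simulate per-bin CpG C>T mutation counts with planted clock densities
#'
#' A focused generator for the molecular-clock estimators: tumors are
#' observed over 1-kb bins inside copy-number step segments; non-carrier
#' counts are Poisson with mean `parental_density * parental_cn * cpg_sites`
#' per bin, carriers additionally accumulate `ht_density * cpg_sites` on
#' their single extra haplotype copy.
#'
#' @param n_carriers,n_noncarriers tumor counts per group.
#' @param n_bins number of 1-kb bins.
#' @param cpg_per_bin mean CpG sites per bin (bin totals are Poisson).
#' @param parental_cn parental copy number inside the step segments.
#' @param parental_density planted parental per-CpG-site per-copy density.
#' @param ht_density planted per-CpG-site density on the transferred copy.
#' @param seed integer seed.
#' @return list with `counts` (bins x tumors matrix), `cpg_sites` (per bin),
#'   `parental_cn`, `carriers`, `noncarriers` and the planted densities.
#' @export
simulate_clock_counts <- function(n_carriers = 7L, n_noncarriers = 40L,
                                  n_bins = 20000L, cpg_per_bin = 10,
                                  parental_cn = 2L,
                                  parental_density = 2.21e-3,
                                  ht_density = 6.89e-4,
                                  seed = 1L) {
  set.seed(as.integer(seed))
  cpg <- stats::rpois(n_bins, cpg_per_bin)
  carriers <- sprintf("A%02d", seq_len(n_carriers))
  noncarriers <- sprintf("B%02d", seq_len(n_noncarriers))
  lam_par <- parental_density * parental_cn * cpg
  counts <- matrix(0L, n_bins, n_carriers + n_noncarriers,
                   dimnames = list(NULL, c(carriers, noncarriers)))
  for (j in seq_len(n_carriers))
    counts[, j] <- stats::rpois(n_bins, lam_par + ht_density * cpg)
  for (j in seq_len(n_noncarriers))
    counts[, n_carriers + j] <- stats::rpois(n_bins, lam_par)
  list(counts = counts, cpg_sites = cpg, parental_cn = parental_cn,
       carriers = carriers, noncarriers = noncarriers,
       parental_density = parental_density, ht_density = ht_density)
}
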