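#' Run the horizontal-transfer analysis pipeline
#'
#' Executes the stages `simulate`, `genotype`, `screen`, `hallmarks`,
#' `chain`, `date`, `haplotype`, `expression` in dependency order, writing
#' each stage's outputs under `outdir` and recording a run manifest (config
#' digest, seeds, per-file md5 digests, package version). A subset of
#' stages may be requested when the upstream outputs already exist in
#' `outdir`; a missing upstream output raises an error naming the stage it
#' should have come from.
#'
#' Downstream stages act on the carriers *detected* by the screen, not the
#' simulation truth; on a null cohort the screen is empty, the pipeline
#' reports that no horizontal transfer was detected, and the
#' carrier-dependent stages are skipped.
#'
#' @param config a [sim_config()]; its `seed` drives all randomness.
#' @param stages character subset of the stage names (default: all).
#' @param outdir output directory (created if needed).
#' @return the run manifest (list of class `run_manifest`), invisibly;
#'   stage results are attached as attribute `"results"`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "genotype", "screen",
                                    "hallmarks", "chain", "date",
                                    "haplotype", "expression"),
                         outdir = tempfile("hgtscreen_run")) {
  all_stages <- c("simulate", "genotype", "screen", "hallmarks", "chain",
                  "date", "haplotype", "expression")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  state_path <- function(name) file.path(outdir, paste0(name, ".rds"))
  need <- function(name, from) {
    if (!file.exists(state_path(name)))
      stop("missing upstream output '", name, "': run stage '", from,
           "' first", call. = FALSE)
    readRDS(state_path(name))
  }
  files <- character(0)
  log_msg <- function(...) message("[hgtscreen] ", ...)
  notes <- character(0)

  if ("simulate" %in% stages) {
    t0 <- Sys.time()
    cohort <- simulate_cohort(config)
    saveRDS(cohort, state_path("cohort"))
    write_site_counts_tsv(cohort$panel, file.path(outdir, "site_counts.tsv"))
    write_site_counts_vcf(cohort$panel, file.path(outdir, "site_counts.vcf"))
    write_cn_bed(cohort$cn, file.path(outdir, "cn_segments.bed"))
    write_junctions_bedpe(cohort$junctions,
                          file.path(outdir, "junctions.bedpe"))
    write_truth_json(cohort$truth, file.path(outdir, "truth.json"))
    utils::write.table(cohort$samples, file.path(outdir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, file.path(outdir, c(
      "site_counts.tsv", "site_counts.vcf", "cn_segments.bed",
      "junctions.bedpe", "truth.json", "samples.tsv")))
    log_msg("simulate: ", nrow(cohort$panel$sites), " sites, ",
            config$n_tumors, " tumors (",
            round(as.numeric(Sys.time() - t0, units = "secs"), 1), "s)")
  }

  results <- list()
  if ("genotype" %in% stages) {
    cohort <- need("cohort", "simulate")
    geno <- genotype_cohort(cohort$panel, cohort$samples, cohort$cn)
    cons <- consensus_state(geno$state)
    saveRDS(list(geno = geno, cons = cons), state_path("genotypes"))
    gt <- data.frame(cohort$panel$sites[, c("chrom", "pos")],
                     consensus = cons, decode_state(geno$state),
                     check.names = FALSE)
    utils::write.table(gt, file.path(outdir, "genotype_states.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, file.path(outdir, "genotype_states.tsv"))
    log_msg("genotype: ", sum(cons != "undetermined"),
            " sites with determined consensus")
  }
  if ("screen" %in% stages) {
    cohort <- need("cohort", "simulate")
    g <- need("genotypes", "genotype")
    flips <- call_flipping_snps(g$geno, g$cons, cohort$panel$sites)
    scan <- detect_candidate_regions(
      flips, cohort$config$chrom_lengths,
      cohort$samples$sample_id[cohort$samples$type == "tumor"])
    scan$flips <- flips
    saveRDS(scan, state_path("scan"))
    utils::write.table(scan$regions,
                       file.path(outdir, "candidate_regions.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(scan$windows, file.path(outdir, "window_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, file.path(outdir, c("candidate_regions.bed",
                                          "window_stats.tsv")))
    if (nrow(scan$regions) == 0L) {
      notes <- c(notes, "no horizontal transfer detected")
      log_msg("screen: no horizontal transfer detected")
    } else {
      log_msg("screen: ", nrow(scan$regions), " candidate regions in ",
              length(unique(scan$regions$sample_id)), " tumors")
    }
  }

  carrier_stage <- function(name, fn) {
    cohort <- need("cohort", "simulate")
    scan <- need("scan", "screen")
    if (nrow(scan$regions) == 0L) {
      notes <<- c(notes, paste0(name, ": skipped, no transfer detected"))
      log_msg(name, ": skipped (no transfer detected)")
      return(NULL)
    }
    carriers <- sort(unique(scan$regions$sample_id))
    fn(cohort, scan, carriers)
  }

  if ("hallmarks" %in% stages) {
    results$hallmarks <- carrier_stage("hallmarks", function(cohort, scan, carriers) {
      regs <- scan$regions[!duplicated(scan$regions[, c("chrom", "start", "end")]), ]
      reps <- lapply(seq_len(nrow(regs)), function(i)
        hallmark_report(as.list(regs[i, c("chrom", "start", "end")]),
                        cohort, seed = config$seed))
      jsonlite::write_json(
        lapply(reps, function(r) list(
          region = r$region, cn_step_pass = r$cn_step$pass,
          vaf_fraction_two_thirds = r$vaf_pattern$fraction_two_thirds,
          vaf_pass = r$vaf_pattern$pass,
          mean_percent_reduction = mean(vapply(
            r$density, function(d) d$percent_reduction, numeric(1))))),
        file.path(outdir, "hallmarks.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      files <<- c(files, file.path(outdir, "hallmarks.json"))
      log_msg("hallmarks: ", length(reps), " regions evaluated")
      reps
    })
  }
  if ("chain" %in% stages) {
    results$chain <- carrier_stage("chain", function(cohort, scan, carriers) {
      noncarriers <- setdiff(
        cohort$samples$sample_id[cohort$samples$type == "tumor"], carriers)
      segs <- select_informative_segments(cohort$cn, carriers, noncarriers)
      if (!nrow(segs)) return(NULL)
      chain <- assemble_chain(cohort$junctions, segs)
      write_chain(chain, file.path(outdir, "chain.bed"),
                  file.path(outdir, "chain.json"))
      files <<- c(files, file.path(outdir, c("chain.bed", "chain.json")))
      s <- summarize_element(chain)
      log_msg("chain: ", s$n_blocks, " blocks, ",
              round(s$total_length / 1e6, 2), " Mb")
      chain
    })
  }
  if ("date" %in% stages) {
    results$date <- carrier_stage("date", function(cohort, scan, carriers) {
      est <- estimate_ht_age(cohort)
      jsonlite::write_json(
        list(parental_density = est$parental$mean,
             parental_ci = est$parental$ci,
             ht_density = est$ht$d_h_reported, ht_density_raw = est$ht$d_h,
             ht_se = est$ht$se, ht_range = est$ht$range,
             age_years = est$age$age_years, age_ci = est$age$ci_years),
        file.path(outdir, "clock.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      files <<- c(files, file.path(outdir, "clock.json"))
      log_msg("date: ", est$age$age_years, " years (95% CI ",
              round(est$age$ci_years[1]), "-", round(est$age$ci_years[2]), ")")
      est
    })
  }
  if ("haplotype" %in% stages) {
    results$haplotype <- carrier_stage("haplotype", function(cohort, scan, carriers) {
      g <- need("genotypes", "genotype")
      noncarriers <- setdiff(
        cohort$samples$sample_id[cohort$samples$type == "tumor"], carriers)
      segs <- select_informative_segments(cohort$cn, carriers, noncarriers)
      if (!nrow(segs)) return(NULL)
      ht <- infer_ht_genotypes(cohort$panel, g$geno, cohort$samples,
                               cohort$cn, carriers, segs)
      write_haplotype_vcf(ht, cohort$panel$sites,
                          file.path(outdir, "ht_haplotype.vcf"))
      utils::write.table(ht, file.path(outdir, "ht_haplotype.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <<- c(files, file.path(outdir, c("ht_haplotype.vcf",
                                             "ht_haplotype.tsv")))
      log_msg("haplotype: ", sum(ht$ht_allele != "undetermined"),
              " of ", nrow(ht), " sites determined")
      ht
    })
  }
  if ("expression" %in% stages) {
    cohort <- need("cohort", "simulate")
    dec <- deconvolve_expression(cohort)
    utils::write.table(dec$records, file.path(outdir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(ht_vs_cancer = dec$ht_vs_cancer, ht_vs_host = dec$ht_vs_host),
      file.path(outdir, "expression_scatter.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    files <- c(files, file.path(outdir, c("expression.tsv",
                                          "expression_scatter.json")))
    results$expression <- dec
    log_msg("expression: ", nrow(dec$records), " (gene, source) records")
  }

  cfg_json <- file.path(outdir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)
  files <- unique(c(cfg_json, files))
  manifest <- structure(list(
    config_digest = unname(tools::md5sum(cfg_json)),
    seed = config$seed,
    stages = stages,
    outputs = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE),
    notes = notes,
    package_version = as.character(utils::packageVersion("hgtscreen"))),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  attr(manifest, "results") <- results
  attr(manifest, "outdir") <- outdir
  invisible(manifest)
}
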