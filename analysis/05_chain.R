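# Assemble the transferred element's block structure by walking breakpoint
# junctions between the copy-number step segments, and assemble the
# packaged synthetic fixture with the published 11-block topology.

source("analysis/00_config.R")

man <- run_pipeline(CONFIG, stages = "chain", outdir = OUTDIR)
chain <- attr(man, "results")$chain
cat("Simulated cohort element: ")
print(chain)

# the packaged fixture (synthetic coordinates, published summary topology)
j <- read_junctions_bedpe(system.file("extdata",
                                      "nht1_junctions_synthetic.bedpe",
                                      package = "hgtscreen"))
segs <- utils::read.table(
  system.file("extdata", "nht1_step_segments_synthetic.bed",
              package = "hgtscreen"),
  col.names = c("chrom", "start", "end", "name"),
  colClasses = c("character", "integer", "integer", "character"))
segs$start <- segs$start + 1L
fx <- assemble_chain(j, segs,
                     seed_terminus = list(chrom = "21", pos = 1,
                                          side = "left"),
                     centromeres = c("21" = 1, "7" = 1))
cat("Fixture element: ")
print(fx)
write_chain(fx, file.path(OUTDIR, "fixture_chain.bed"),
            file.path(OUTDIR, "fixture_chain.json"))
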