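# Shared end-to-end fixture: one full-size simulated study (two ~1 Mb
# genomes, 50 ancestral + 50 lineage fossils at target identity 0.5, trap
# and split insertions) run through calibration, fossil finding and dating.
# Built lazily once per test run.

acceptance_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(seed = 73)
    world <- simulate_world(cfg)
    set.seed(74)
    model <- calibrate_evalue(default_model())
    dir <- file.path(tempdir(), "acceptance-world")
    paths <- emit(world, dir)
    cdsA <- read_cds(paths[["gffA"]])
    cdsB <- read_cds(paths[["gffB"]])
    rmskA <- read_repeatmasker(paths[["rmskA"]], "out")
    blocks <- read_maf(paths[["maf"]])
    calls <- run_find(world$genomes$A, world$proteins, model,
                      cds = cdsA$cds, rmsk = rmskA)
    ages <- run_ages(calls, list(B = blocks), clade_map("B", "old"),
                     cds1 = cdsA$cds, cds2_by_genome = list(B = cdsB$cds),
                     genes = cdsA$genes, rmsk = rmskA)
    cache <<- list(cfg = cfg, world = world, model = model, paths = paths,
                   calls = calls, ages = ages, blocks = blocks)
    cache
  }
})

# calls covering >= 30% of a planted interval (detection at the same
# coverage convention the conservation test uses); empty when not detected
calls_matching_truth <- function(calls, f) {
  ov <- which(calls$seq_id == f$seq_id & calls$start < f$A_end &
                calls$end > f$A_start)
  cov <- sum(pmin(calls$end[ov], f$A_end) -
               pmax(calls$start[ov], f$A_start))
  if (length(ov) && cov >= 0.3 * (f$A_end - f$A_start)) ov else integer(0)
}
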