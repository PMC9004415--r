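# Pipeline drivers: configuration, the fossil-finding stage chain, the
# conservation/dating stage chain, the reversed-genome decoy control, and
# the machine-readable run manifest.

#' Pipeline configuration
#'
#' All thresholds of the published procedure in one validated list.  The
#' significance threshold is expressed per Gbp of searched DNA (default 1
#' expected false hit per 1e9 bp); coverage bounds are fractions.
#'
#' @param max_evalue_per_Gbp expected false hits per 1e9 bp of genome
#' @param max_coding_frac coding-coverage removal bound (exclusive)
#' @param max_te_frac host-gene-vs-TE removal bound (exclusive)
#' @param conserved_min_frac conservation threshold (inclusive)
#' @param link_max_gap,link_max_between,link_min_links linked-alignment
#'   filter parameters
#' @param pid_max training-set amino-acid identity ceiling
#' @param tectonic_min_sep,tectonic_max_sep split-pair separation window
#' @param excluded_name_patterns exapted-protein name substrings
#' @param exempt_classes annotation classes exempt from the host-vs-TE rule
#' @param seed RNG seed used wherever the pipeline needs randomness
#' @return a `pf_pipeline_config` list
#' @export
pipeline_config <- function(max_evalue_per_Gbp = 1,
                            max_coding_frac = 0.10,
                            max_te_frac = 0.10,
                            conserved_min_frac = 0.30,
                            link_max_gap = 1e6,
                            link_max_between = 5L,
                            link_min_links = 2L,
                            pid_max = 0.50,
                            tectonic_min_sep = 30000L,
                            tectonic_max_sep = 3000000L,
                            excluded_name_patterns =
                              c("_HSgene", "_Hsa_", "UN-GIN", "_Xtr_eg_tp"),
                            exempt_classes = c("Low_complexity",
                                               "Simple_repeat"),
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$max_evalue_per_Gbp > 0,
            cfg$max_coding_frac >= 0, cfg$max_coding_frac <= 1,
            cfg$max_te_frac >= 0, cfg$max_te_frac <= 1,
            cfg$conserved_min_frac >= 0, cfg$conserved_min_frac <= 1,
            cfg$link_max_gap > 0, cfg$link_max_between >= 0,
            cfg$link_min_links >= 0, cfg$pid_max > 0, cfg$pid_max <= 1,
            cfg$tectonic_min_sep >= 0,
            cfg$tectonic_min_sep <= cfg$tectonic_max_sep)
  structure(cfg, class = "pf_pipeline_config")
}

pf_log <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Find fossil calls in a genome
#'
#' The fixed stage chain: exclude exapted proteins, stop-augment, align,
#' filter by genome-wide significance, keep only the strongest of
#' overlapping homologies, remove calls >10% covered by coding annotation,
#' and drop host-gene calls mostly covered by annotated TE.  Per-stage
#' in/out counts are logged and attached as attribute `"stage_counts"`.
#'
#' @param genome DNA sequence tibble
#' @param proteins protein sequence tibble (no stop symbols yet); an
#'   optional `source_class` column classifies calls
#' @param model a `pf_scoring_model` (calibrate first for honest E-values)
#' @param cds annotation tibble of coding intervals (optional)
#' @param rmsk annotation tibble of repeat annotations (optional; used by
#'   the host-gene-vs-TE filter)
#' @param cfg a `pf_pipeline_config`
#' @param max_evalue_genome override the genome-wide E-value cutoff
#'   (default `max_evalue_per_Gbp * genome_len / 1e9`)
#' @param verbose log per-stage counts to stderr
#' @param ... passed to [align_local()]
#' @return a fossil-call tibble with attribute `"stage_counts"`
#' @export
run_find <- function(genome, proteins, model, cds = NULL, rmsk = NULL,
                     cfg = pipeline_config(), max_evalue_genome = NULL,
                     verbose = FALSE, ...) {
  check_seq_tbl(genome, "dna")
  counts <- c(proteins_in = nrow(proteins))
  prots <- exclude_exapted_proteins(proteins,
                                    patterns = cfg$excluded_name_patterns)
  counts["proteins_kept"] <- nrow(prots)
  pf_log(verbose, "proteins: %d in, %d after exapted-name exclusion",
         nrow(proteins), nrow(prots))
  genome_len <- sum(nchar(genome$residues))
  e_max <- max_evalue_genome %||%
    (cfg$max_evalue_per_Gbp * genome_len / 1e9)
  if (nrow(prots) == 0L) {
    out <- empty_calls()
    attr(out, "stage_counts") <- counts
    return(out)
  }
  prots_aug <- append_stop(prots[, c("id", "residues", "kind")])
  total_prot <- sum(nchar(prots_aug$residues))
  min_score <- min_score_for_evalue(model, e_max, genome_len, total_prot)
  alns <- align_local(genome, prots_aug, model, min_score = min_score,
                      genome_len = genome_len, ...)
  counts["alignments"] <- nrow(alns)
  alns <- dplyr::filter(alns, .data$evalue_genome <= e_max)
  counts["significant"] <- nrow(alns)
  pf_log(verbose, "alignments: %d raw, %d at E_genome <= %.3g",
         counts[["alignments"]], nrow(alns), e_max)
  pc <- if ("source_class" %in% names(proteins))
    proteins[, c("id", "source_class")] else NULL
  calls <- alignments_to_calls(alns, pc)
  calls <- drop_weaker_overlaps(calls)
  counts["after_overlap"] <- nrow(calls)
  if (!is.null(cds)) {
    calls <- remove_coding_overlaps(calls, cds,
                                    max_frac = cfg$max_coding_frac)
  }
  counts["after_coding"] <- nrow(calls)
  if (!is.null(rmsk)) {
    calls <- filter_hostgene_vs_te(calls, rmsk,
                                   max_frac = cfg$max_te_frac,
                                   exempt_classes = cfg$exempt_classes)
  }
  counts["after_hostgene_vs_te"] <- nrow(calls)
  pf_log(verbose,
         "calls: %d after overlap, %d after coding, %d after host-vs-TE",
         counts[["after_overlap"]], counts[["after_coding"]],
         counts[["after_hostgene_vs_te"]])
  attr(calls, "stage_counts") <- counts
  calls
}

#' Date fossil calls and report ancient-fossil structure
#'
#' Prunes each genome pair's blocks of coding overlap, applies the
#' linked-alignment filter, profiles conservation, assigns ages, and also
#' reports tectonic split-pairs and unknown-repeat classifications.
#'
#' @param calls fossil-call tibble (focal genome)
#' @param blocks_by_genome named list of raw block tibbles (focal genome on
#'   the g1 side), one per comparison genome
#' @param cmap clade map from [clade_map()]
#' @param cds1 CDS annotation of the focal genome
#' @param cds2_by_genome named list of CDS annotations per comparison
#'   genome (missing entries: no pruning on that side)
#' @param genes gene-model tibble for nearest-gene context (optional)
#' @param rmsk repeat annotations for unknown-repeat classification
#'   (optional)
#' @param cfg a `pf_pipeline_config`
#' @param verbose log per-stage counts
#' @return list: `report` (age-report tibble), `ages`, `profile`,
#'   `tectonic`, `unknown_repeats`, `blocks` (filtered, per genome),
#'   `stage_counts`
#' @export
run_ages <- function(calls, blocks_by_genome, cmap, cds1 = NULL,
                     cds2_by_genome = NULL, genes = NULL, rmsk = NULL,
                     cfg = pipeline_config(), verbose = FALSE) {
  if (is.data.frame(blocks_by_genome))
    blocks_by_genome <- setNames(list(blocks_by_genome),
                                 cmap$genome[1])
  counts <- c()
  filtered <- list()
  for (g in names(blocks_by_genome)) {
    b <- blocks_by_genome[[g]]
    counts[paste0(g, "_blocks_in")] <- nrow(b)
    b <- prune_coding(b, cds1 %||% empty_annotations(),
                      (cds2_by_genome[[g]] %||% empty_annotations()))
    counts[paste0(g, "_after_prune")] <- nrow(b)
    b <- link_filter(b, max_gap = cfg$link_max_gap,
                     max_between = cfg$link_max_between,
                     min_links = cfg$link_min_links)
    counts[paste0(g, "_after_link")] <- nrow(b)
    pf_log(verbose, "%s blocks: %d in, %d after pruning, %d after linking",
           g, counts[[paste0(g, "_blocks_in")]],
           counts[[paste0(g, "_after_prune")]], nrow(b))
    filtered[[g]] <- b
  }
  cp <- conservation_profile(calls, filtered, cmap,
                             min_frac = cfg$conserved_min_frac)
  gene_ctx <- if (!is.null(genes) && nrow(calls))
    nearest_gene(calls, genes) else NULL
  report <- age_report(calls, cp$ages, gene_ctx)
  tect <- tectonic_pairs(calls, min_sep = cfg$tectonic_min_sep,
                         max_sep = cfg$tectonic_max_sep)
  unk <- if (!is.null(rmsk)) classify_unknown_repeats(rmsk, calls) else NULL
  list(report = report, ages = cp$ages, profile = cp$profile,
       tectonic = tect, unknown_repeats = unk, blocks = filtered,
       stage_counts = counts)
}

#' Reversed-genome decoy control
#'
#' Runs the alignment and significance stages against the reversed (but not
#' complemented) genome: every hit is by construction spurious, so the
#' count estimates the false-positive rate of the search at the chosen
#' threshold.
#'
#' @inheritParams run_find
#' @return one-row tibble: n_hits, genome_bp, rate_per_gbp, e_max
#' @export
run_decoy <- function(genome, proteins, model, cfg = pipeline_config(),
                      max_evalue_genome = NULL, verbose = FALSE, ...) {
  decoy <- reverse_decoy(genome)
  genome_len <- sum(nchar(decoy$residues))
  e_max <- max_evalue_genome %||%
    (cfg$max_evalue_per_Gbp * genome_len / 1e9)
  calls <- run_find(decoy, proteins, model, cds = NULL, rmsk = NULL,
                    cfg = cfg, max_evalue_genome = e_max,
                    verbose = verbose, ...)
  tibble::tibble(n_hits = nrow(calls), genome_bp = genome_len,
                 rate_per_gbp = nrow(calls) / (genome_len / 1e9),
                 e_max = e_max)
}

#' Machine-readable run manifest
#'
#' Records the configuration hash, input checksums (md5 for files, value
#' hashes for in-memory objects), and per-stage counts.  Deliberately
#' timestamp-free: identical inputs give a byte-identical manifest.
#'
#' @param cfg a `pf_pipeline_config`
#' @param inputs named list of file paths and/or R objects
#' @param stage_counts named numeric vector
#' @return a list; write with [write_manifest()]
#' @export
run_manifest <- function(cfg, inputs = list(), stage_counts = c()) {
  sums <- lapply(inputs, function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x))
      unname(tools::md5sum(x))
    else rlang::hash(x)
  })
  list(config = unclass(cfg), config_hash = rlang::hash(unclass(cfg)),
       input_checksums = sums,
       stage_counts = as.list(stage_counts))
}

#' @rdname run_manifest
#' @param manifest list from [run_manifest()]
#' @param path output JSON path
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' End-to-end pipeline over files on disk
#'
#' Reads the genome, protein, annotation and alignment files, calibrates
#' the scoring model (seeded from the configuration), finds fossil calls,
#' dates them against the comparison genome, and writes calls (BED + MAF),
#' the age report (TSV), tectonic pairs, and the run manifest into
#' `out_dir`.  Reruns with identical inputs and seed are byte-identical.
#'
#' @param files named list/vector with elements `genome`, `proteins`, and
#'   optionally `cds`, `rmsk`, `maf`, `cds2`
#' @param cfg a `pf_pipeline_config`
#' @param out_dir output directory
#' @param comparison_genome name for the comparison genome in the clade map
#' @param age_label clade label for the comparison genome
#' @param verbose log stage counts
#' @return named vector of output paths, invisibly; the result list as
#'   attribute `"results"`
#' @export
run_pipeline <- function(files, cfg = pipeline_config(), out_dir,
                         comparison_genome = "B", age_label = "old",
                         verbose = FALSE) {
  for (k in c("genome", "proteins"))
    if (is.null(files[[k]]) || !file.exists(files[[k]]))
      stop("missing input: ", k)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_fasta(files$genome, kind = "dna")
  proteins <- read_fasta(files$proteins, kind = "protein")
  cds <- if (!is.null(files$cds)) read_cds(files$cds) else NULL
  rmsk <- if (!is.null(files$rmsk))
    read_repeatmasker(files$rmsk, "out") else NULL

  set.seed(cfg$seed)
  model <- calibrate_evalue(default_model(pid = cfg$pid_max))
  calls <- run_find(genome, proteins, model, cds = cds$cds, rmsk = rmsk,
                    cfg = cfg, verbose = verbose)
  outputs <- c(calls_bed = file.path(out_dir, "calls.bed"))
  write_bed(calls, outputs[["calls_bed"]])
  results <- list(calls = calls, model = model)

  if (!is.null(files$maf)) {
    blocks <- read_maf(files$maf)
    cds2 <- if (!is.null(files$cds2)) read_cds(files$cds2)$cds else NULL
    cmap <- clade_map(comparison_genome, age_label)
    ages <- run_ages(calls, setNames(list(blocks), comparison_genome),
                     cmap, cds1 = cds$cds,
                     cds2_by_genome = setNames(list(cds2),
                                               comparison_genome),
                     genes = cds$genes, rmsk = rmsk, cfg = cfg,
                     verbose = verbose)
    outputs["report_tsv"] <- file.path(out_dir, "age_report.tsv")
    write_age_report(ages$report, outputs[["report_tsv"]])
    outputs["tectonic_tsv"] <- file.path(out_dir, "tectonic_pairs.tsv")
    write.table(ages$tectonic, outputs[["tectonic_tsv"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$ages <- ages
  }

  sc <- attr(calls, "stage_counts")
  if (!is.null(results$ages))
    sc <- c(sc, results$ages$stage_counts)
  manifest <- run_manifest(cfg, as.list(files), sc)
  outputs["manifest"] <- file.path(out_dir, "manifest.json")
  write_manifest(manifest, outputs[["manifest"]])
  structure(invisible(outputs), results = results)
}
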