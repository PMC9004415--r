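small_cfg <- function(seed = 5) {
  sim_config(seed = seed, genome_length = 150000, n_chrom = 2,
             n_ancestral_fossils = 8, n_lineage_fossils = 8,
             n_conserved_background = 24, n_split_fossils = 1,
             split_gap_range = c(30000, 40000), n_trap_insertions = 1,
             n_genes = 4, n_te_proteins = 10, n_host_proteins = 3,
             exapted_n = 2, n_inversions = 1)
}

test_that("one seed determines every emitted byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- emit(simulate_world(small_cfg()), d1)
  p2 <- emit(simulate_world(small_cfg()), d2)
  for (k in names(p1)) {
    expect_identical(readBin(p1[k], "raw", file.size(p1[k])),
                     readBin(p2[k], "raw", file.size(p2[k])),
                     info = k)
  }
  # and a different seed changes the genome
  p3 <- emit(simulate_world(small_cfg(seed = 6)), withr::local_tempdir())
  expect_false(identical(readLines(p1["genomeA"]), readLines(p3["genomeA"])))
})

test_that("protein library has configured counts and composition", {
  cfg <- sim_config(seed = 9, n_te_proteins = 30, n_host_proteins = 10,
                    exapted_n = 4, protein_length_mean = 300)
  set.seed(cfg$seed)
  lib <- make_protein_library(cfg)
  expect_equal(nrow(lib), 44L)
  expect_equal(sum(grepl("^TE:", lib$source_class) & !lib$exapted), 30L)
  expect_equal(sum(lib$source_class == "host_gene"), 10L)
  expect_equal(sum(lib$exapted), 4L)
  expect_equal(nrow(exclude_exapted_proteins(lib)), 40L)
  # residue composition within 3.5 sigma of the generator frequencies
  res <- paste(lib$residues, collapse = "")
  N <- nchar(res)
  expect_gte(N, 1e4)
  q <- as.numeric(table(factor(pf_codon_aa(), levels = AA_ORDER)))[1:20] / 64
  q <- q / sum(q)
  obs <- table(factor(strsplit(res, "")[[1]], levels = AA_ORDER[1:20]))
  z <- (as.numeric(obs) - N * q) / sqrt(N * q * (1 - q))
  expect_true(all(abs(z) < 3.5))
})

test_that("planting at identity 1 with zero rates reproduces the protein", {
  cfg <- sim_config(seed = 10, target_aa_identity = 1, indel_rate = 0,
                    frameshift_per_fossil = 0, stop_per_fossil = 0)
  set.seed(1)
  genome <- seq_tbl("chr", random_dna_str(5000))
  prot <- seq_tbl("P1", "MKVLHEWRT", kind = "protein")
  out <- plant_fossil(genome, prot, cfg)
  expect_false(out$truth$disrupted)
  ins <- substr(out$genome$residues, out$truth$start + 1, out$truth$end)
  if (out$truth$strand == "-") ins <- revcomp(ins)
  cods <- substring(ins, seq(1, nchar(ins), 3), seq(3, nchar(ins), 3))
  aa <- paste(translate_codon(cods), collapse = "")
  expect_equal(aa, "MKVLHEWRT*")
  expect_equal(out$truth$aa_identity, 1.0)
})

test_that("realized identity tracks the target over 200 plantings", {
  cfg <- sim_config(seed = 11, target_aa_identity = 0.5)
  set.seed(2)
  ids <- replicate(200, {
    f <- paleofossil:::make_fossil_seq(random_protein_str(120), cfg)
    f$aa_identity
  })
  expect_lt(abs(mean(ids) - 0.5), 0.05)
})

test_that("planted frameshifts mark the truth as disrupted", {
  cfg <- sim_config(seed = 12, frameshift_per_fossil = 2,
                    stop_per_fossil = 0)
  set.seed(3)
  # Poisson(2) can be zero; force a draw with frameshifts
  repeat {
    f <- paleofossil:::make_fossil_seq(random_protein_str(100), cfg)
    if (f$n_frameshifts > 0) break
  }
  expect_true(f$disrupted)
})

test_that("insertion avoids forbidden zones and errors when impossible", {
  cfg <- sim_config(seed = 13)
  set.seed(4)
  genome <- seq_tbl("chr", random_dna_str(1000))
  prot <- seq_tbl("P1", "MKV", kind = "protein")
  avoid <- tibble::tibble(start = 100L, end = 900L)
  out <- plant_fossil(genome, prot, cfg, avoid = avoid)
  expect_true(out$truth$start <= 100L || out$truth$start >= 900L)
  all_blocked <- tibble::tibble(start = -1L, end = 1002L)
  expect_error(plant_fossil(genome, prot, cfg, avoid = all_blocked),
               "no insertion position")
})

test_that("zero divergence yields identical descendants", {
  cfg <- sim_config(seed = 14, genome_length = 60000, n_chrom = 2,
                    n_ancestral_fossils = 4, n_lineage_fossils = 0,
                    n_conserved_background = 10, n_split_fossils = 0,
                    n_trap_insertions = 0, n_genes = 2, n_inversions = 0,
                    divergence_subst_rate = 0, conserved_subst_rate = 0,
                    divergence_indel_rate = 0)
  world <- simulate_world(cfg)
  expect_identical(world$genomes$A$residues, world$genomes$B$residues)
  expect_true(all(world$truth$true_age == "old"))
  # every ancestral fossil is fully covered by a true block
  for (i in seq_len(nrow(world$truth))) {
    f <- world$truth[i, ]
    b <- world$blocks[world$blocks$g1_seq == f$seq_id, ]
    expect_equal(bitmap_covered(f$A_start, f$A_end, b$g1_start, b$g1_end),
                 f$A_end - f$A_start)
  }
})

test_that("truth labels ages by construction and split pairs lie in range", {
  world <- simulate_world(small_cfg(seed = 15))
  tr <- world$truth
  expect_true(all(tr$true_age[tr$kind %in% c("ancestral", "split_half")] ==
                    "old"))
  expect_true(all(tr$true_age[tr$kind %in% c("lineage", "trap")] == "—"))
  sh <- tr[tr$kind == "split_half" & !is.na(tr$A_start), ]
  expect_equal(nrow(sh), 2L)
  gap <- max(sh$A_start) - min(sh$A_end[sh$A_end <= max(sh$A_start)])
  expect_gte(gap, 30000L)
  expect_lte(gap, 40000L)
  expect_equal(unique(sh$split_gap), gap)
  # trap insertions: present in both genomes, never in the true block set
  traps <- tr[tr$is_trap, ]
  expect_equal(nrow(traps), 2L)
  tb <- world$blocks[world$blocks$trap, ]
  expect_equal(nrow(tb), 1L)
  ntb <- world$blocks[!world$blocks$trap, ]
  expect_false(any(startsWith(ntb$g1_seq, "chrTrap")))
})

test_that("substitution counts match binomial expectations within 3 sigma", {
  cfg <- sim_config(seed = 16, genome_length = 120000, n_chrom = 2,
                    n_ancestral_fossils = 0, n_lineage_fossils = 0,
                    n_conserved_background = 0, n_split_fossils = 0,
                    n_trap_insertions = 0, n_genes = 0, n_inversions = 0,
                    divergence_indel_rate = 0,
                    divergence_subst_rate = 0.08)
  world <- simulate_world(cfg)
  a <- strsplit(world$genomes$A$residues[1], "")[[1]]
  # descendant vs an independent lineage: both mutated at rate r, so the
  # expected disagreement fraction is 2r(1-r) + small back-mutation terms
  b <- strsplit(world$genomes$B$residues[1], "")[[1]]
  n <- length(a)
  diff_obs <- sum(a != b)
  r <- 0.08
  # P(differ) = 2r(1-r) + r^2 * (2/3)
  p <- 2 * r * (1 - r) + r^2 * 2 / 3
  expect_lt(abs(diff_obs - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("emitted files round-trip through the package readers", {
  world <- simulate_world(small_cfg(seed = 17))
  dir <- withr::local_tempdir()
  paths <- emit(world, dir)
  gA <- read_fasta(paths["genomeA"], kind = "dna")
  expect_identical(gA$residues, world$genomes$A$residues)
  blocks <- read_maf(paths["maf"])
  expect_equal(nrow(blocks), nrow(world$blocks))
  expect_equal(blocks$g1_start, world$blocks$g1_start)
  expect_equal(blocks$strand, world$blocks$strand)
  rmsk <- read_repeatmasker(paths["rmskA"], "out")
  expect_gt(nrow(rmsk), 0L)
  # every truth interval lies within its genome
  tr <- world$truth
  lens <- setNames(nchar(gA$residues), gA$id)
  inA <- tr[!is.na(tr$A_start), ]
  expect_true(all(inA$A_start >= 0 & inA$A_end <= lens[inA$seq_id]))
  # known-subset size is exact
  n_te_inA <- sum(!is.na(tr$A_start) & grepl("^TE:", tr$source_class))
  expect_equal(sum(rmsk$class_family != "Unknown"),
               round(world$cfg$known_fraction * n_te_inA))
})
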