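# Synthetic two-genome worlds with planted ground truth: an ancestral
# genome carrying decayed protein fossils, two descendant lineages with
# independent divergence, lineage-specific young insertions, independent
# same-family insertions at homologous loci (the classic non-homologous
# insertion trap), and ancestral fossils split into distant pairs by
# younger insertions.
#
# Coordinate bookkeeping is event-based: every lineage-specific change is
# an insertion or deletion anchored in root (ancestor) coordinates, so true
# orthologous blocks and per-genome fossil intervals fall out of the same
# piece table that materializes each genome.

#' Simulation configuration
#'
#' Defaults describe the study conditions exercised throughout the test
#' suite: two ~1 Mb descendant genomes, 50 ancestral + 50 lineage-specific
#' fossils decayed to ~50% amino-acid identity with frameshift/stop
#' disruption rates giving ~71% disrupted fossils, a handful of trap and
#' split insertions, and matching decoy annotations.
#'
#' @param seed master RNG seed (integer)
#' @param genome_length total root genome length (bp)
#' @param n_chrom number of ordinary chromosomes (a trap chromosome is
#'   added when `n_trap_insertions > 0`)
#' @param n_te_proteins,n_host_proteins library sizes
#' @param exapted_n extra TE proteins given exapted-gene names
#' @param protein_length_mean,protein_length_sd library length distribution
#'   (residues, minimum 100; TE polyproteins and transposases run to
#'   hundreds of residues)
#' @param n_ancestral_fossils,n_lineage_fossils planted fossil counts
#'   (ancestral = shared; lineage = per descendant genome)
#' @param target_aa_identity expected amino-acid identity of planted
#'   fossils to their source protein
#' @param indel_rate per-codon whole-codon indel rate inside fossils
#' @param frameshift_per_fossil,stop_per_fossil Poisson means of planted
#'   +-1 frameshifts and premature stop codons per fossil
#' @param divergence_subst_rate,conserved_subst_rate per-bp substitution
#'   rates per lineage outside/inside conserved segments
#' @param divergence_indel_rate per-bp small-indel event rate per lineage
#'   (lengths 1-10 bp, outside genes and conserved segments)
#' @param n_split_fossils ancestral fossils split in genome A by an
#'   insertion of length drawn from `split_gap_range`
#' @param split_gap_range split insertion length range (bp)
#' @param n_trap_insertions independent same-family insertions at
#'   homologous loci of both genomes (no conserved flanks)
#' @param n_conserved_background freestanding conserved segments (the
#'   linkage scaffold)
#' @param n_inversions background conserved segments inverted in genome B
#' @param n_genes decoy gene models per genome (root-anchored)
#' @param nm_fraction fraction of genes given NM_ accessions (rest XR_)
#' @param known_fraction fraction of planted fossils with RepeatMasker-like
#'   records
#' @param n_unknown_instances class-"Unknown" repeat records placed over
#'   fossils of one family (0 disables)
#' @param cds_overlap_frac fraction of lineage-A fossils partially
#'   overlapped by decoy CDS (half just under, half just over the 10%
#'   removal boundary)
#' @param gc genome G+C fraction
#' @return a `pf_sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1e6,
                       n_chrom = 4L,
                       n_te_proteins = 20L,
                       n_host_proteins = 6L,
                       exapted_n = 3L,
                       protein_length_mean = 220,
                       protein_length_sd = 60,
                       n_ancestral_fossils = 50L,
                       n_lineage_fossils = 50L,
                       target_aa_identity = 0.5,
                       indel_rate = 0.01,
                       frameshift_per_fossil = 0.7,
                       stop_per_fossil = 0.55,
                       divergence_subst_rate = 0.08,
                       conserved_subst_rate = 0.02,
                       divergence_indel_rate = 5e-4,
                       n_split_fossils = 5L,
                       split_gap_range = c(30000, 80000),
                       n_trap_insertions = 3L,
                       n_conserved_background = 120L,
                       n_inversions = 2L,
                       n_genes = 15L,
                       nm_fraction = 0.7,
                       known_fraction = 0.6,
                       n_unknown_instances = 4L,
                       cds_overlap_frac = 0.08,
                       gc = 0.41) {
  cfg <- as.list(environment())
  rates <- c(cfg$target_aa_identity, cfg$indel_rate,
             cfg$divergence_subst_rate, cfg$conserved_subst_rate,
             cfg$divergence_indel_rate, cfg$gc, cfg$known_fraction,
             cfg$cds_overlap_frac, cfg$nm_fraction)
  stopifnot(all(rates >= 0 & rates <= 1), cfg$target_aa_identity > 0,
            cfg$split_gap_range[1] <= cfg$split_gap_range[2])
  structure(cfg, class = "pf_sim_config")
}

sim_te_taxonomy <- function() {
  c("LINE/CR1", "LINE/L2", "LINE/L1", "LINE/RTE", "LTR/Gypsy",
    "DNA/hAT-Tag1", "DNA/PIF-Harbinger", "DNA/Polinton", "DNA/Crypton-A",
    "LINE/Penelope")
}

random_dna <- function(n, gc) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# mildly biased codon usage: earlier synonymous codons preferred
codon_usage <- function() {
  aa <- pf_codon_aa()
  w <- numeric(64)
  for (a in unique(aa)) {
    ii <- which(aa == a)
    w[ii] <- rev(seq_along(ii)) + 0.5
    w[ii] <- w[ii] / sum(w[ii])
  }
  w
}

#' Generate the synthetic protein library
#'
#' TE proteins carry a class/family from a small fixed taxonomy and ids in
#' RepeatMasker style (`CR1-3_SIM_pol`); host proteins are `HOSTP<i>_SIM`;
#' `exapted_n` extra entries get names containing the exapted-gene marker
#' substrings so the exclusion stage has something to do.  Residues are
#' drawn i.i.d. from the uniform-codon-usage amino-acid background.
#'
#' @param cfg a `pf_sim_config`
#' @return sequence tibble with extra columns `source_class` and `exapted`
#' @export
make_protein_library <- function(cfg) {
  q <- as.numeric(table(factor(pf_codon_aa(), levels = AA_ORDER))) / 64
  draw <- function(n) {
    len <- pmax(100L, as.integer(round(
      stats::rnorm(n, cfg$protein_length_mean, cfg$protein_length_sd))))
    vapply(len, function(l)
      paste(sample(AA_ORDER[1:20], l, replace = TRUE, prob = q[1:20]),
            collapse = ""), character(1))
  }
  fams <- sim_te_taxonomy()
  te_fam <- fams[1 + (seq_len(cfg$n_te_proteins) - 1L) %% length(fams)]
  te_id <- sprintf("%s-%d_SIM_pol", sub(".*/", "", te_fam),
                   seq_len(cfg$n_te_proteins))
  host_id <- sprintf("HOSTP%d_SIM", seq_len(cfg$n_host_proteins))
  exa_pat <- c("_HSgene", "_Hsa_", "UN-GIN", "_Xtr_eg_tp")
  exa_id <- sprintf("L1%s_p%d",
                    exa_pat[1 + (seq_len(cfg$exapted_n) - 1L) %% 4],
                    seq_len(cfg$exapted_n))
  tibble::tibble(
    id = c(te_id, host_id, exa_id),
    residues = draw(cfg$n_te_proteins + cfg$n_host_proteins + cfg$exapted_n),
    kind = "protein",
    source_class = c(paste0("TE:", te_fam),
                     rep("host_gene", cfg$n_host_proteins),
                     rep("TE:LINE/L1", cfg$exapted_n)),
    exapted = c(rep(FALSE, cfg$n_te_proteins + cfg$n_host_proteins),
                rep(TRUE, cfg$exapted_n)))
}

# BLOSUM62 conditional substitution distribution (20 aa), cached
sim_subst_cond <- function() {
  b62 <- get_blosum62()[AA_ORDER[1:20], AA_ORDER[1:20]]
  q <- as.numeric(table(factor(pf_codon_aa(), levels = AA_ORDER)))[1:20] / 61
  joint <- outer(q, q) * 2^(b62 / 2)
  sweep(joint, 2, colSums(joint), "/")
}

# Decay one protein into a fossil DNA sequence: codon-usage-biased reverse
# translation, per-site substitution to the target identity, whole-codon
# indels, premature stops, and +-1 frameshifts (disruptions placed in the
# middle 10-90% so local alignment can see them).
make_fossil_seq <- function(protein_res, cfg,
                            target_identity = cfg$target_aa_identity,
                            allow_indels = TRUE) {
  aa <- strsplit(protein_res, "")[[1]]
  m <- length(aa)
  usage <- codon_usage()
  codons <- pf_codons()
  aa_of <- pf_codon_aa()
  cond <- sim_subst_cond()
  pick_codon <- function(a) {
    ii <- which(aa_of == a)
    if (length(ii) == 1L) codons[ii]
    else sample(codons[ii], 1, prob = usage[ii])
  }
  keep <- runif(m) < target_identity
  out_aa <- aa
  for (i in which(!keep)) {
    p <- cond[, aa[i]]
    p[aa[i]] <- 0
    out_aa[i] <- sample(AA_ORDER[1:20], 1, prob = p / sum(p))
  }
  cods <- vapply(out_aa, pick_codon, character(1))
  cods <- c(cods, sample(c("TAA", "TGA", "TAG"), 1))  # ancestral stop codon
  # premature stops
  n_stop <- rpois(1, cfg$stop_per_fossil)
  mid <- seq(max(2L, round(0.1 * m)), max(2L, round(0.9 * m)))
  if (n_stop > 0) {
    at <- sample(mid, min(n_stop, length(mid)))
    cods[at] <- sample(c("TAA", "TGA", "TAG"), length(at), replace = TRUE)
    n_stop <- length(at)
  }
  # whole-codon indels (gap columns, frame preserved)
  if (allow_indels && cfg$indel_rate > 0) {
    del <- which(runif(length(cods)) < cfg$indel_rate / 2)
    del <- setdiff(del, length(cods))
    if (length(del)) cods <- cods[-del]
    ins_at <- which(runif(length(cods)) < cfg$indel_rate / 2)
    if (length(ins_at))
      for (k in rev(ins_at))
        cods <- append(cods, sample(codons, 1), after = k)
  }
  s <- paste(cods, collapse = "")
  # +-1 frameshifts at codon boundaries in the middle of the fossil
  n_fs <- rpois(1, cfg$frameshift_per_fossil)
  fs_done <- 0L
  for (k in seq_len(n_fs)) {
    at <- 3L * sample(seq(max(2L, round(0.1 * nchar(s) / 3)),
                          max(2L, round(0.9 * nchar(s) / 3))), 1)
    if (runif(1) < 0.5) {
      s <- paste0(substr(s, 1, at), sample(DNA_BASES, 1),
                  substr(s, at + 1, nchar(s)))      # +1: extra nucleotide
    } else {
      s <- paste0(substr(s, 1, at - 1), substr(s, at + 1, nchar(s)))  # -1
    }
    fs_done <- fs_done + 1L
  }
  list(seq = s, n_frameshifts = fs_done, n_stops = n_stop,
       aa_identity = mean(keep), disrupted = (fs_done + n_stop) > 0)
}

#' Plant a single decayed fossil into a DNA sequence
#'
#' Standalone form of the decay-and-insert step: reverse-translates the
#' protein with codon-usage bias, substitutes residues to the target
#' identity, injects the configured frameshifts and premature stops, and
#' inserts the result (on a random strand) at a uniformly chosen position
#' outside `avoid` zones.
#'
#' @param genome one-record DNA sequence tibble
#' @param protein one-record protein sequence tibble (no stop symbol)
#' @param cfg a `pf_sim_config`
#' @param avoid optional tibble of start/end zones the insertion point must
#'   not fall in (masked or coding regions); after 100 failed picks an
#'   error is raised
#' @return list with `genome` (modified tibble) and `truth` (one-row
#'   tibble: seq_id, start, end, strand, protein_id, n_frameshifts,
#'   n_stops, disrupted, aa_identity)
#' @export
plant_fossil <- function(genome, protein, cfg, avoid = NULL) {
  check_seq_tbl(genome, "dna")
  stopifnot(nrow(genome) == 1L, nrow(protein) == 1L)
  if (grepl("\\*", protein$residues))
    stop("protein must not be stop-augmented for planting")
  fos <- make_fossil_seq(protein$residues, cfg)
  strand <- sample(c("+", "-"), 1)
  ins <- if (strand == "+") fos$seq else revcomp(fos$seq)
  L <- nchar(genome$residues)
  pos <- NA
  for (try in seq_len(100L)) {
    cand <- sample.int(L + 1L, 1) - 1L
    bad <- !is.null(avoid) && nrow(avoid) > 0 &&
      any(avoid$start < cand & cand < avoid$end)
    if (!bad) { pos <- cand; break }
  }
  if (is.na(pos)) stop("no insertion position found outside avoid zones")
  genome$residues <- paste0(substr(genome$residues, 1, pos), ins,
                            substr(genome$residues, pos + 1, L))
  list(genome = genome,
       truth = tibble::tibble(
         seq_id = genome$id, start = pos, end = pos + nchar(ins),
         strand = strand, protein_id = protein$id,
         n_frameshifts = fos$n_frameshifts, n_stops = fos$n_stops,
         disrupted = fos$disrupted, aa_identity = fos$aa_identity))
}

# sample n interval starts of width w in [0, L) avoiding `busy` intervals
# (tibble start/end) and each other; errors after too many rejections
sample_free_intervals <- function(n, w, L, busy, min_dist = 0L,
                                  max_tries = 2000L) {
  out_s <- integer(0); out_e <- integer(0)
  bs <- busy$start; be <- busy$end
  tries <- 0L
  while (length(out_s) < n && tries < max_tries) {
    tries <- tries + 1L
    wi <- if (length(w) == 1L) w else sample(w, 1)
    if (L - wi <= 1L) next
    s <- sample.int(L - wi, 1) - 1L
    e <- s + wi
    if (length(bs) && any(bs < e + min_dist & be > s - min_dist)) next
    if (length(out_s) && any(out_s < e + min_dist & out_e > s - min_dist))
      next
    out_s <- c(out_s, s); out_e <- c(out_e, e)
    bs <- c(bs, s); be <- c(be, e)
  }
  if (length(out_s) < n)
    stop("could not place ", n, " intervals of width ~", w[1],
         " in length ", L)
  tibble::tibble(start = out_s, end = out_e)
}

#' Build the ancestral world
#'
#' Root chromosomes with planted ancestral fossils, freestanding conserved
#' segments (the linkage scaffold, two flanking each ancestral fossil plus
#' a scattered background), and root-anchored decoy gene models.  The trap
#' chromosome, when present, carries no conserved segments.
#'
#' @param cfg a `pf_sim_config`
#' @return an ancestor world list (root sequences, proteins, fossils,
#'   conserved segments, genes)
#' @export
build_ancestor <- function(cfg) {
  n_ord <- cfg$n_chrom
  n_trap <- cfg$n_trap_insertions
  # each trap gets its own scaffold with no conserved segments, so its
  # deceptive inter-genome alignment is isolated (no linkable neighbours)
  trap_total <- if (n_trap > 0) as.integer(0.08 * cfg$genome_length) else 0L
  trap_each <- if (n_trap > 0) max(20000L, trap_total %/% n_trap) else 0L
  ord_len <- as.integer((cfg$genome_length - trap_each * n_trap) / n_ord)
  chrom_names <- c(paste0("chr", seq_len(n_ord)),
                   if (n_trap > 0) paste0("chrTrap", seq_len(n_trap)))
  chrom_len <- c(rep(ord_len, n_ord), rep(trap_each, n_trap))
  root <- setNames(lapply(chrom_len, random_dna, gc = cfg$gc), chrom_names)

  proteins <- make_protein_library(cfg)
  plantable <- proteins[!proteins$exapted, , drop = FALSE]

  # decoy genes: 2-3 exons, CDS inside exons, on ordinary chromosomes
  genes <- list()
  for (gi in seq_len(cfg$n_genes)) {
    chrom <- chrom_names[1 + (gi - 1L) %% n_ord]
    genes[[gi]] <- tibble::tibble(chrom = chrom, width = sample(3000:8000, 1))
  }
  genes <- dplyr::bind_rows(genes)

  busy <- setNames(lapply(chrom_names, function(ch)
    tibble::tibble(start = integer(), end = integer())), chrom_names)
  gene_models <- list()
  for (gi in seq_len(nrow(genes))) {
    ch <- genes$chrom[gi]
    span <- sample_free_intervals(1, genes$width[gi],
                                  chrom_len[match(ch, chrom_names)],
                                  busy[[ch]], min_dist = 500L)
    busy[[ch]] <- dplyr::bind_rows(busy[[ch]], span)
    n_ex <- sample(2:3, 1)
    bounds <- sort(sample(seq(span$start + 200L, span$end - 200L), 2 * n_ex - 2))
    ex_s <- c(span$start, bounds[seq(2, length(bounds), 2)])
    ex_e <- c(bounds[seq(1, length(bounds), 2)], span$end)
    acc <- if (runif(1) < cfg$nm_fraction)
      sprintf("NM_%06d", gi) else sprintf("XR_%06d", gi)
    cds <- tibble::tibble(start = ex_s + 30L, end = pmax(ex_s + 31L, ex_e - 30L))
    gene_models[[gi]] <- tibble::tibble(
      gene_name = sprintf("GENE%d", gi), accession = acc, seq_id = ch,
      start = span$start, end = span$end,
      strand = sample(c("+", "-"), 1),
      exons = list(tibble::tibble(start = ex_s, end = ex_e)),
      cds = list(cds))
  }
  gene_models <- dplyr::bind_rows(
    c(list(tibble::tibble(
      gene_name = character(), accession = character(),
      seq_id = character(), start = integer(), end = integer(),
      strand = character(), exons = list(), cds = list())),
      gene_models))

  # ancestral fossils: anchors on ordinary chromosomes, away from genes
  fossils <- list()
  cons <- list()
  for (fi in seq_len(cfg$n_ancestral_fossils)) {
    ch <- chrom_names[1 + (fi - 1L) %% n_ord]
    p <- plantable[sample.int(nrow(plantable), 1), ]
    fos <- make_fossil_seq(p$residues, cfg)
    anchor <- sample_free_intervals(1, 2L, chrom_len[match(ch, chrom_names)],
                                    busy[[ch]], min_dist = 400L)
    busy[[ch]] <- dplyr::bind_rows(busy[[ch]], anchor)
    strand <- sample(c("+", "-"), 1)
    fossils[[fi]] <- tibble::tibble(
      fossil_id = sprintf("anc%03d", fi), kind = "ancestral",
      protein_id = p$id, source_class = p$source_class,
      chrom = ch, anchor = anchor$start, strand = strand,
      seq = if (strand == "+") fos$seq else revcomp(fos$seq),
      n_frameshifts = fos$n_frameshifts, n_stops = fos$n_stops,
      disrupted = fos$disrupted, aa_identity = fos$aa_identity,
      true_age = "old", split_partner = NA_character_, is_trap = FALSE)
    # two flanking conserved elements on each side, within link distance
    for (side in 1:2) {
      fl <- sample_free_intervals(
        2, sample(100:300, 2, replace = TRUE),
        chrom_len[match(ch, chrom_names)], busy[[ch]], min_dist = 50L)
      busy[[ch]] <- dplyr::bind_rows(busy[[ch]], fl)
      cons[[length(cons) + 1L]] <- tibble::tibble(
        chrom = ch, start = fl$start, end = fl$end, inverted = FALSE)
    }
  }
  fossils <- dplyr::bind_rows(fossils)

  # background conserved segments on ordinary chromosomes
  for (k in seq_len(cfg$n_conserved_background)) {
    ch <- chrom_names[1 + (k - 1L) %% n_ord]
    seg <- sample_free_intervals(1, sample(100:400, 1),
                                 chrom_len[match(ch, chrom_names)],
                                 busy[[ch]], min_dist = 50L)
    busy[[ch]] <- dplyr::bind_rows(busy[[ch]], seg)
    cons[[length(cons) + 1L]] <- tibble::tibble(
      chrom = ch, start = seg$start, end = seg$end, inverted = FALSE)
  }
  conserved <- dplyr::bind_rows(
    tibble::tibble(chrom = character(), start = integer(),
                   end = integer(), inverted = logical()),
    cons)
  conserved <- dplyr::arrange(conserved, .data$chrom, .data$start)
  # a few background segments are inverted in lineage B
  if (cfg$n_inversions > 0 && nrow(conserved) > cfg$n_inversions) {
    inv <- sample.int(nrow(conserved), cfg$n_inversions)
    conserved$inverted[inv] <- TRUE
  }

  list(cfg = cfg, chrom_names = chrom_names, chrom_len = chrom_len,
       root = root, proteins = proteins, fossils = fossils,
       conserved = conserved, genes = gene_models, busy = busy)
}

# apply per-lineage substitutions to one root chromosome; conserved
# segments and gene spans mutate at the slow rate
substitute_chrom <- function(s, L, cons_zones, gene_zones, cfg) {
  rate <- rep(cfg$divergence_subst_rate, L)
  slow <- function(z) {
    for (i in seq_len(nrow(z))) {
      lo <- max(1L, z$start[i] + 1L); hi <- min(L, z$end[i])
      if (lo <= hi) rate[lo:hi] <<- cfg$conserved_subst_rate
    }
  }
  slow(cons_zones); slow(gene_zones)
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(L) < rate)
  if (length(hit)) ch[hit] <- mutate_bases(ch[hit])
  paste(ch, collapse = "")
}

# vectorized substitution: each base becomes one of the other three
mutate_bases <- function(b) {
  bi <- match(toupper(b), DNA_BASES)
  alt <- rbind(c("C", "G", "T"), c("A", "G", "T"),
               c("A", "C", "T"), c("A", "C", "G"))
  pick <- sample.int(3L, length(b), replace = TRUE)
  out <- b
  ok <- !is.na(bi)
  out[ok] <- alt[cbind(bi[ok], pick[ok])]
  out
}

# substitute within a fossil/insert sequence at the conserved (slow) rate
substitute_insert <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) ch[hit] <- mutate_bases(ch[hit])
  paste(ch, collapse = "")
}

# materialize one chromosome of one genome from its substituted root
# string and sorted event table; returns sequence + piece table
materialize_chrom <- function(root_sub, events) {
  L <- nchar(root_sub)
  # deletions sort before insertions at the same position ("del" < "ins"),
  # which realizes an inversion as delete-then-reinsert-reversed
  ev <- events[order(events$pos, events$type), , drop = FALSE]
  pieces <- list(); seqs <- character(0)
  cur <- 0L; g <- 0L
  add_root <- function(a, b) {
    if (b > a) {
      pieces[[length(pieces) + 1L]] <<- tibble::tibble(
        kind = "root", root_start = a, root_end = b, id = NA_character_,
        g_start = g, g_end = g + (b - a))
      seqs <<- c(seqs, substr(root_sub, a + 1L, b))
      g <<- g + (b - a)
    }
  }
  for (i in seq_len(nrow(ev))) {
    add_root(cur, ev$pos[i])
    cur <- max(cur, ev$pos[i])
    if (ev$type[i] == "ins") {
      w <- nchar(ev$content[i])
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        kind = "ins", root_start = ev$pos[i], root_end = ev$pos[i],
        id = ev$id[i], g_start = g, g_end = g + w)
      seqs <- c(seqs, ev$content[i])
      g <- g + w
    } else {  # del
      cur <- ev$pos[i] + ev$len[i]
    }
  }
  add_root(cur, L)
  list(seq = paste(seqs, collapse = ""),
       pieces = dplyr::bind_rows(pieces))
}

# map a root interval [s,e) through a piece table to genome coordinates
map_root_interval <- function(pieces, s, e) {
  rp <- pieces[pieces$kind == "root" & pieces$root_start < e &
                 pieces$root_end > s, , drop = FALSE]
  if (nrow(rp) == 0L) return(NULL)
  gs <- min(rp$g_start + pmax(0L, s - rp$root_start))
  ge <- max(rp$g_start + (pmin(e, rp$root_end) - rp$root_start))
  c(gs, ge)
}

#' Evolve two descendant genomes from an ancestral world
#'
#' Applies independent per-lineage substitutions and small indels, plants
#' lineage-specific fossils, inserts the trap copies (independently decayed
#' same-family elements at a homologous locus of the conserved-segment-free
#' trap chromosome), splits selected ancestral fossils in genome A by a
#' long younger insertion, inverts selected background segments in genome
#' B, and emits the true orthologous blocks (conserved segments + shared
#' ancestral fossils) plus the deceptive trap blocks, flagged `trap`.
#'
#' @param anc ancestor world from [build_ancestor()]
#' @param cfg a `pf_sim_config`
#' @return world list: `genomes` (named seq tibbles A/B), `truth` (per
#'   fossil: intervals in each genome or NA), `blocks` (A-vs-B block tibble
#'   with `trap` flag), `genes` (per-genome gene tibbles), plus the pieces
#'   of `anc`
#' @export
evolve_pair <- function(anc, cfg = anc$cfg) {
  chrom_names <- anc$chrom_names
  chrom_len <- setNames(anc$chrom_len, chrom_names)
  plantable <- anc$proteins[!anc$proteins$exapted, , drop = FALSE]
  te_only <- plantable[grepl("^TE:", plantable$source_class), , drop = FALSE]

  # choose split fossils (genome A) among the longer TE elements, so both
  # halves remain comfortably detectable and the pair scan (which compares
  # TE class/family) can see them, and the trap family up-front
  split_ids <- character(0)
  if (cfg$n_split_fossils > 0) {
    te_f <- anc$fossils[grepl("^TE:", anc$fossils$source_class), ,
                        drop = FALSE]
    w <- nchar(te_f$seq)
    cand <- te_f$fossil_id[w >= stats::quantile(w, 0.75)]
    split_ids <- sample(cand, min(cfg$n_split_fossils, length(cand)))
  }
  trap_fam <- te_only[sample.int(nrow(te_only), 1), ]
  trap_chroms <- chrom_names[startsWith(chrom_names, "chrTrap")]
  trap_anchor <- vapply(trap_chroms, function(ch)
    sample.int(chrom_len[[ch]] - 2L, 1) - 1L, integer(1))

  lineage_rows <- list()
  trap_rows <- list()
  genomes <- list(); pieces_all <- list(); events_all <- list()

  for (g in c("A", "B")) {
    events <- setNames(lapply(chrom_names, function(ch)
      tibble::tibble(pos = integer(), type = character(), len = integer(),
                     content = character(), id = character())),
      chrom_names)
    busy <- anc$busy

    # ancestral fossil insertions (shared anchors, per-lineage decay drift;
    # split insertion applied inside the A copy)
    for (fi in seq_len(nrow(anc$fossils))) {
      f <- anc$fossils[fi, ]
      s <- substitute_insert(f$seq, cfg$conserved_subst_rate)
      id <- f$fossil_id
      if (g == "A" && id %in% split_ids) {
        gap <- sample(seq(cfg$split_gap_range[1], cfg$split_gap_range[2]), 1)
        at <- as.integer(nchar(s) * runif(1, 0.4, 0.6))
        s <- paste0(substr(s, 1, at), random_dna(gap, cfg$gc),
                    substr(s, at + 1, nchar(s)))
        id <- paste0(id, "|split:", at, ":", gap)
      }
      events[[f$chrom]] <- dplyr::bind_rows(
        events[[f$chrom]],
        tibble::tibble(pos = f$anchor, type = "ins", len = 0L,
                       content = s, id = id))
    }

    # lineage-specific young fossils
    for (k in seq_len(cfg$n_lineage_fossils)) {
      ch <- chrom_names[1 + (k - 1L) %% cfg$n_chrom]
      p <- plantable[sample.int(nrow(plantable), 1), ]
      fos <- make_fossil_seq(p$residues, cfg)
      anchor <- sample_free_intervals(1, 2L, chrom_len[[ch]],
                                      busy[[ch]], min_dist = 300L)
      busy[[ch]] <- dplyr::bind_rows(busy[[ch]], anchor)
      strand <- sample(c("+", "-"), 1)
      id <- sprintf("lin%s%03d", g, k)
      lineage_rows[[id]] <- tibble::tibble(
        fossil_id = id, kind = "lineage", protein_id = p$id,
        source_class = p$source_class, chrom = ch, anchor = anchor$start,
        strand = strand, genome = g,
        n_frameshifts = fos$n_frameshifts, n_stops = fos$n_stops,
        disrupted = fos$disrupted, aa_identity = fos$aa_identity,
        true_age = "—", split_partner = NA_character_, is_trap = FALSE)
      events[[ch]] <- dplyr::bind_rows(
        events[[ch]],
        tibble::tibble(pos = anchor$start, type = "ins", len = 0L,
                       content = if (strand == "+") fos$seq else
                         revcomp(fos$seq), id = id))
    }

    # trap insertions: same family, same homologous locus, independent
    # decay per lineage (substitution-only so the deceptive block is
    # ungapped)
    for (k in seq_along(trap_anchor)) {
      ch <- trap_chroms[k]
      fos <- make_fossil_seq(trap_fam$residues, cfg, allow_indels = FALSE)
      id <- sprintf("trap%02d_%s", k, g)
      trap_rows[[id]] <- tibble::tibble(
        fossil_id = sprintf("trap%02d", k), kind = "trap",
        protein_id = trap_fam$id, source_class = trap_fam$source_class,
        chrom = ch, anchor = trap_anchor[k], strand = "+",
        genome = g, n_frameshifts = fos$n_frameshifts,
        n_stops = fos$n_stops, disrupted = fos$disrupted,
        aa_identity = fos$aa_identity, true_age = "—",
        split_partner = NA_character_, is_trap = TRUE)
      events[[ch]] <- dplyr::bind_rows(
        events[[ch]],
        tibble::tibble(pos = trap_anchor[k], type = "ins", len = 0L,
                       content = fos$seq, id = sprintf("trap%02d", k)))
    }

    # inversions in lineage B: conserved segment replaced by its reverse
    # complement (modelled as deletion + insertion at the same spot)
    if (g == "B") {
      invs <- anc$conserved[anc$conserved$inverted, , drop = FALSE]
      for (i in seq_len(nrow(invs))) {
        z <- invs[i, ]
        events[[z$chrom]] <- dplyr::bind_rows(
          events[[z$chrom]],
          tibble::tibble(pos = z$start, type = "del",
                         len = z$end - z$start, content = NA_character_,
                         id = NA_character_),
          tibble::tibble(pos = z$start, type = "ins", len = 0L,
                         content = revcomp(substr(anc$root[[z$chrom]],
                                                  z$start + 1L, z$end)),
                         id = paste0("inv:", z$chrom, ":", z$start)))
      }
    }

    # small background indels outside genes/conserved/planted zones
    for (ch in chrom_names) {
      L <- chrom_len[[ch]]
      n_ind <- rbinom(1, L, cfg$divergence_indel_rate)
      if (n_ind > 0) {
        zones <- dplyr::bind_rows(
          busy[[ch]],
          tibble::tibble(start = events[[ch]]$pos - 12L,
                         end = events[[ch]]$pos + pmax(events[[ch]]$len,
                                                       0L) + 12L))
        spots <- sample_free_intervals(n_ind, 11L, L, zones, min_dist = 2L,
                                       max_tries = 50L * n_ind + 2000L)
        for (r in seq_len(nrow(spots))) {
          w <- sample(1:10, 1)
          if (runif(1) < 0.5) {
            events[[ch]] <- dplyr::bind_rows(
              events[[ch]],
              tibble::tibble(pos = spots$start[r], type = "del", len = w,
                             content = NA_character_, id = NA_character_))
          } else {
            events[[ch]] <- dplyr::bind_rows(
              events[[ch]],
              tibble::tibble(pos = spots$start[r], type = "ins", len = 0L,
                             content = random_dna(w, cfg$gc),
                             id = NA_character_))
          }
        }
      }
    }

    # materialize
    gseq <- character(0); pieces <- list()
    for (ch in chrom_names) {
      cz <- anc$conserved[anc$conserved$chrom == ch, , drop = FALSE]
      gz <- anc$genes[anc$genes$seq_id == ch, , drop = FALSE]
      root_sub <- substitute_chrom(anc$root[[ch]], chrom_len[[ch]],
                                   cz, gz, cfg)
      mat <- materialize_chrom(root_sub, events[[ch]])
      gseq[ch] <- mat$seq
      pieces[[ch]] <- mat$pieces
    }
    genomes[[g]] <- seq_tbl(names(gseq), unname(gseq), kind = "dna")
    pieces_all[[g]] <- pieces
    events_all[[g]] <- events
  }

  world <- list(cfg = cfg, anc = anc, genomes = genomes,
                pieces = pieces_all,
                lineage_rows = lineage_rows, trap_rows = trap_rows,
                split_ids = split_ids)
  world$truth <- build_truth(world)
  world$blocks <- build_blocks(world)
  world$genes <- build_genome_genes(world)
  world
}

# locate every planted fossil in each genome from the piece tables
build_truth <- function(world) {
  anc <- world$anc
  rows <- list(tibble::tibble(
    fossil_id = character(), kind = character(), protein_id = character(),
    source_class = character(), seq_id = character(), strand = character(),
    A_start = integer(), A_end = integer(), B_start = integer(),
    B_end = integer(), disrupted = logical(), n_frameshifts = integer(),
    n_stops = integer(), aa_identity = numeric(), true_age = character(),
    split_partner = character(), split_gap = integer(),
    is_trap = logical()))
  find_piece <- function(g, ch, id_prefix) {
    p <- world$pieces[[g]][[ch]]
    p[p$kind == "ins" & !is.na(p$id) &
        (p$id == id_prefix | startsWith(p$id, paste0(id_prefix, "|"))), ,
      drop = FALSE]
  }
  for (fi in seq_len(nrow(anc$fossils))) {
    f <- anc$fossils[fi, ]
    iv <- list()
    halves <- NULL
    for (g in c("A", "B")) {
      p <- find_piece(g, f$chrom, f$fossil_id)
      iv[[g]] <- c(p$g_start[1], p$g_end[1])
      if (g == "A" && grepl("\\|split:", p$id[1])) {
        sp <- as.integer(strsplit(sub(".*\\|split:", "", p$id[1]),
                                  ":")[[1]])
        halves <- c(at = sp[1], gap = sp[2])
      }
    }
    if (is.null(halves)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fossil_id = f$fossil_id, kind = "ancestral",
        protein_id = f$protein_id, source_class = f$source_class,
        seq_id = f$chrom, strand = f$strand,
        A_start = iv$A[1], A_end = iv$A[2],
        B_start = iv$B[1], B_end = iv$B[2],
        disrupted = f$disrupted, n_frameshifts = f$n_frameshifts,
        n_stops = f$n_stops, aa_identity = f$aa_identity,
        true_age = "old", split_partner = NA_character_,
        split_gap = NA_integer_, is_trap = FALSE)
    } else {
      ida <- paste0(f$fossil_id, ".L"); idb <- paste0(f$fossil_id, ".R")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fossil_id = c(ida, idb), kind = "split_half",
        protein_id = f$protein_id, source_class = f$source_class,
        seq_id = f$chrom, strand = f$strand,
        A_start = c(iv$A[1], iv$A[1] + halves[["at"]] + halves[["gap"]]),
        A_end = c(iv$A[1] + halves[["at"]], iv$A[2]),
        B_start = c(iv$B[1], NA), B_end = c(iv$B[2], NA),
        disrupted = f$disrupted, n_frameshifts = f$n_frameshifts,
        n_stops = f$n_stops, aa_identity = f$aa_identity,
        true_age = "old", split_partner = c(idb, ida),
        split_gap = halves[["gap"]], is_trap = FALSE)
    }
  }
  for (r in world$lineage_rows) {
    p <- find_piece(r$genome, r$chrom, r$fossil_id)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      fossil_id = r$fossil_id, kind = "lineage",
      protein_id = r$protein_id, source_class = r$source_class,
      seq_id = r$chrom, strand = r$strand,
      A_start = if (r$genome == "A") p$g_start[1] else NA_integer_,
      A_end = if (r$genome == "A") p$g_end[1] else NA_integer_,
      B_start = if (r$genome == "B") p$g_start[1] else NA_integer_,
      B_end = if (r$genome == "B") p$g_end[1] else NA_integer_,
      disrupted = r$disrupted, n_frameshifts = r$n_frameshifts,
      n_stops = r$n_stops, aa_identity = r$aa_identity,
      true_age = "—", split_partner = NA_character_,
      split_gap = NA_integer_, is_trap = FALSE)
  }
  for (r in world$trap_rows) {
    p <- find_piece(r$genome, r$chrom, r$fossil_id)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      fossil_id = paste0(r$fossil_id, "_", r$genome), kind = "trap",
      protein_id = r$protein_id, source_class = r$source_class,
      seq_id = r$chrom, strand = "+",
      A_start = if (r$genome == "A") p$g_start[1] else NA_integer_,
      A_end = if (r$genome == "A") p$g_end[1] else NA_integer_,
      B_start = if (r$genome == "B") p$g_start[1] else NA_integer_,
      B_end = if (r$genome == "B") p$g_end[1] else NA_integer_,
      disrupted = r$disrupted, n_frameshifts = r$n_frameshifts,
      n_stops = r$n_stops, aa_identity = r$aa_identity,
      true_age = "—", split_partner = NA_character_,
      split_gap = NA_integer_, is_trap = TRUE)
  }
  dplyr::bind_rows(rows)
}

# true orthologous blocks (conserved segments + shared ancestral fossils)
# and the deceptive trap blocks
build_blocks <- function(world) {
  anc <- world$anc
  rows <- list(tibble::tibble(
    g1_seq = character(), g1_start = integer(), g1_end = integer(),
    g2_seq = character(), g2_start = integer(), g2_end = integer(),
    strand = character(), score = numeric(), trap = logical()))
  add_block <- function(ch, a, b, strand, trap) {
    if (is.null(a) || is.null(b)) return()
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      g1_seq = ch, g1_start = as.integer(a[1]), g1_end = as.integer(a[2]),
      g2_seq = ch, g2_start = as.integer(b[1]), g2_end = as.integer(b[2]),
      strand = strand, score = as.numeric(a[2] - a[1]) * 2, trap = trap)
  }
  for (i in seq_len(nrow(anc$conserved))) {
    z <- anc$conserved[i, ]
    a <- map_root_interval(world$pieces$A[[z$chrom]], z$start, z$end)
    if (z$inverted) {
      p <- world$pieces$B[[z$chrom]]
      ip <- p[p$kind == "ins" & !is.na(p$id) &
                p$id == paste0("inv:", z$chrom, ":", z$start), ,
              drop = FALSE]
      add_block(z$chrom, a, c(ip$g_start[1], ip$g_end[1]), "-", FALSE)
    } else {
      b <- map_root_interval(world$pieces$B[[z$chrom]], z$start, z$end)
      add_block(z$chrom, a, b, "+", FALSE)
    }
  }
  tr <- world$truth
  anc_rows <- tr[tr$kind %in% c("ancestral", "split_half"), , drop = FALSE]
  for (i in seq_len(nrow(anc_rows))) {
    f <- anc_rows[i, ]
    if (f$kind == "ancestral") {
      add_block(f$seq_id, c(f$A_start, f$A_end), c(f$B_start, f$B_end),
                "+", FALSE)
    } else if (!is.na(f$B_start)) {
      # split fossil: the two A halves both align into the intact B copy
      partner <- anc_rows[anc_rows$fossil_id == f$split_partner, ]
      wl <- f$A_end - f$A_start
      add_block(f$seq_id, c(f$A_start, f$A_end),
                c(f$B_start, f$B_start + wl), "+", FALSE)
      wr <- partner$A_end - partner$A_start
      add_block(f$seq_id, c(partner$A_start, partner$A_end),
                c(f$B_end - wr, f$B_end), "+", FALSE)
    }
  }
  traps <- tr[tr$is_trap, , drop = FALSE]
  tA <- traps[!is.na(traps$A_start), ]
  tB <- traps[!is.na(traps$B_start), ]
  for (i in seq_len(nrow(tA))) {
    base <- sub("_A$", "", tA$fossil_id[i])
    j <- match(paste0(base, "_B"), tB$fossil_id)
    if (!is.na(j)) {
      wa <- tA$A_end[i] - tA$A_start[i]
      wb <- tB$B_end[j] - tB$B_start[j]
      w <- min(wa, wb)
      add_block(tA$seq_id[i], c(tA$A_start[i], tA$A_start[i] + w),
                c(tB$B_start[j], tB$B_start[j] + w), "+", TRUE)
    }
  }
  dplyr::bind_rows(rows)
}

# per-genome gene models mapped through the piece tables, plus the decoy
# CDS overlapping lineage-A fossils around the 10% boundary
build_genome_genes <- function(world) {
  anc <- world$anc
  cfg <- world$cfg
  out <- list()
  for (g in c("A", "B")) {
    rows <- list()
    for (i in seq_len(nrow(anc$genes))) {
      gm <- anc$genes[i, ]
      pc <- world$pieces[[g]][[gm$seq_id]]
      span <- map_root_interval(pc, gm$start, gm$end)
      if (is.null(span)) next
      mapiv <- function(tb) {
        m <- lapply(seq_len(nrow(tb)), function(k)
          map_root_interval(pc, tb$start[k], tb$end[k]))
        m <- m[!vapply(m, is.null, logical(1))]
        tibble::tibble(start = as.integer(vapply(m, `[`, numeric(1), 1)),
                       end = as.integer(vapply(m, `[`, numeric(1), 2)))
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_name = gm$gene_name, accession = gm$accession,
        seq_id = gm$seq_id, start = as.integer(span[1]),
        end = as.integer(span[2]),
        strand = gm$strand, exons = list(mapiv(gm$exons[[1]])),
        cds = list(mapiv(gm$cds[[1]])))
    }
    out[[g]] <- dplyr::bind_rows(rows)
  }
  # decoy CDS over lineage-A fossils: alternate just-under / just-over the
  # 10% coding-coverage boundary
  linA <- world$truth[world$truth$kind == "lineage" &
                        !is.na(world$truth$A_start), , drop = FALSE]
  n_decoy <- round(cfg$cds_overlap_frac * nrow(linA))
  if (n_decoy > 0) {
    pick <- linA[sample.int(nrow(linA), n_decoy), , drop = FALSE]
    for (i in seq_len(nrow(pick))) {
      f <- pick[i, ]
      w <- f$A_end - f$A_start
      frac <- if (i %% 2 == 0) 0.08 else 0.15
      ce <- f$A_start + max(2L, as.integer(round(frac * w)))
      cs <- max(0L, f$A_start - 200L)
      out$A <- dplyr::bind_rows(out$A, tibble::tibble(
        gene_name = sprintf("DECOY%d", i),
        accession = sprintf("XR_D%05d", i),
        seq_id = f$seq_id, start = cs, end = ce + 10L, strand = "+",
        exons = list(tibble::tibble(start = cs, end = ce + 10L)),
        cds = list(tibble::tibble(start = cs, end = ce))))
    }
  }
  out
}

#' Simulate a complete two-genome world
#'
#' Seeds the RNG from `cfg$seed`, builds the ancestor, evolves both
#' lineages, and attaches the RepeatMasker-like annotation tables.  One
#' integer seed determines every emitted byte.
#'
#' @param cfg a `pf_sim_config`
#' @return a world list (see [evolve_pair()]), plus `rmsk` per genome and
#'   `proteins`
#' @export
simulate_world <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  anc <- build_ancestor(cfg)
  world <- evolve_pair(anc, cfg)
  world$proteins <- anc$proteins
  world$rmsk <- build_rmsk(world)
  world
}

# RepeatMasker-like annotation for genome A: a `known_fraction` subset of
# planted fossils with their class/family, plus class-"Unknown" records
# over fossils of the most common family (the unknown-repeat test case)
build_rmsk <- function(world) {
  cfg <- world$cfg
  tr <- world$truth
  inA <- tr[!is.na(tr$A_start) & grepl("^TE:", tr$source_class), ,
            drop = FALSE]
  n_known <- round(cfg$known_fraction * nrow(inA))
  known <- inA[sample.int(nrow(inA), n_known), , drop = FALSE]
  ann <- tibble::tibble(
    seq_id = known$seq_id, start = known$A_start, end = known$A_end,
    strand = known$strand, name = known$protein_id,
    class_family = sub("^TE:", "", known$source_class))
  if (cfg$n_unknown_instances > 0) {
    fams <- sub("^TE:", "", inA$source_class)
    top <- names(sort(table(fams), decreasing = TRUE))[1]
    cand <- inA[fams == top, , drop = FALSE]
    n <- min(cfg$n_unknown_instances, nrow(cand))
    u <- cand[sample.int(nrow(cand), n), , drop = FALSE]
    ann <- dplyr::bind_rows(ann, tibble::tibble(
      seq_id = u$seq_id, start = u$A_start, end = u$A_end,
      strand = u$strand, name = "UNK-1", class_family = "Unknown"))
    attr(ann, "unknown_true_type") <- top
  }
  list(A = ann)
}

#' Write a simulated world to disk
#'
#' Emits FASTA for both genomes and the protein library, GFF3 gene models
#' per genome, a RepeatMasker-style `.out` for genome A, the true A-vs-B
#' MAF (including deceptive trap blocks, as a real aligner would produce),
#' and the ground-truth TSV.  Deterministic given the world.
#'
#' @param world a world from [simulate_world()]
#' @param dir output directory (created if needed)
#' @return named character vector of file paths
#' @export
emit <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_fasta(world$genomes$A, fp("genomeA.fa"))
  write_fasta(world$genomes$B, fp("genomeB.fa"))
  prot <- world$proteins[, c("id", "residues", "kind")]
  write_fasta(prot, fp("proteins.fa"))
  write_gff3(world$genes$A, fp("genomeA.gff3"))
  write_gff3(world$genes$B, fp("genomeB.gff3"))
  write_repeatmasker(world$rmsk$A, fp("genomeA.rmsk.out"), "out")
  blocks <- world$blocks[, setdiff(names(world$blocks), "trap")]
  write_maf_blocks(blocks, fp("A_B.maf"), world$genomes$A, world$genomes$B)
  tr <- world$truth
  tcon <- file(fp("truth.tsv"), "wb")
  writeLines(paste(names(tr), collapse = "\t"), tcon, sep = "\n")
  writeLines(do.call(paste, c(lapply(tr, function(x)
    ifelse(is.na(x), "NA", as.character(x))), sep = "\t")), tcon, sep = "\n")
  close(tcon)
  c(genomeA = fp("genomeA.fa"), genomeB = fp("genomeB.fa"),
    proteins = fp("proteins.fa"), gffA = fp("genomeA.gff3"),
    gffB = fp("genomeB.gff3"), rmskA = fp("genomeA.rmsk.out"),
    maf = fp("A_B.maf"), truth = fp("truth.tsv"))
}
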