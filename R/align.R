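# Frameshift-aware local DNA-to-protein alignment: R orchestration around
# the C++ DP core, with both-strand search, exact mode for small inputs and
# seed-and-extend mode for genome-scale inputs.

# walk an ops vector to rebuild per-column codon/aa detail; `s` is the
# sequence on the aligned strand, coordinates are strand-relative 0-based
ops_to_columns <- function(ops, s, dna_start, prot, prot_start) {
  op_names <- c("codon_aa", "codon_gap", "gap_aa", "fs+", "fs-")
  pos <- dna_start
  pj <- prot_start
  n <- length(ops)
  codon <- character(n)
  aa <- character(n)
  opc <- op_names[ops]
  for (k in seq_len(n)) {
    if (ops[k] == 1L) {            # codon <-> aa
      codon[k] <- substr(s, pos + 1, pos + 3)
      aa[k] <- substr(prot, pj + 1, pj + 1)
      pos <- pos + 3; pj <- pj + 1
    } else if (ops[k] == 2L) {     # codon <-> gap
      codon[k] <- substr(s, pos + 1, pos + 3)
      aa[k] <- NA_character_
      pos <- pos + 3
    } else if (ops[k] == 3L) {     # gap <-> aa
      codon[k] <- NA_character_
      aa[k] <- substr(prot, pj + 1, pj + 1)
      pj <- pj + 1
    } else if (ops[k] == 4L) {     # +1 frameshift: one nucleotide skipped
      codon[k] <- substr(s, pos + 1, pos + 1)  # the skipped nucleotide
      aa[k] <- NA_character_
      pos <- pos + 1
    } else {                       # -1 frameshift: frame steps back one nt
      codon[k] <- NA_character_; aa[k] <- NA_character_
      pos <- pos - 1
    }
  }
  tibble::tibble(op = opc, codon = codon, aa = aa)
}

# recompute an alignment score from its columns under a model (used by the
# invariant tests; independent of the DP traceback bookkeeping)
alignment_score <- function(columns, model) {
  sc <- 0
  prev_gap <- FALSE
  for (k in seq_len(nrow(columns))) {
    op <- columns$op[k]
    if (op == "codon_aa") {
      ai <- match(columns$aa[k], AA_ORDER)
      cod <- toupper(columns$codon[k])
      ci <- match(cod, pf_codons())
      sc <- sc + if (is.na(ci)) model$min_aa_score[ai]
                 else model$subst[ci, ai]
      prev_gap <- FALSE
    } else if (op %in% c("codon_gap", "gap_aa")) {
      sc <- sc - model$gap_extend - if (prev_gap) 0L else model$gap_open
      prev_gap <- TRUE
    } else {
      sc <- sc - model$frameshift
      prev_gap <- FALSE
    }
  }
  sc
}

empty_alignments <- function() {
  tibble::tibble(
    dna_id = character(), dna_start = integer(), dna_end = integer(),
    strand = character(), prot_id = character(), prot_start = integer(),
    prot_end = integer(), score = integer(), evalue_chrom = numeric(),
    evalue_genome = numeric(), aa_identity = numeric(), columns = list())
}

#' Frameshift-aware local alignment of DNA against a protein library
#'
#' Searches both strands of each DNA record for local alignments to each
#' protein under a 64 x 21 codon scoring model with affine gaps and
#' single-nucleotide frameshifts.  Small inputs are aligned by exact dynamic
#' programming; genome-scale inputs use exact 4-residue translated seeds
#' (never started inside soft-masked lowercase runs), gapless X-drop
#' extension, and windowed exact DP around surviving seeds.
#'
#' Within one (protein, strand, DNA record) search, reported alignments never
#' share a DNA base with a stronger one; overlap resolution across proteins
#' is a separate downstream step ([drop_weaker_overlaps()]).
#'
#' @param dna sequence tibble of DNA records (lowercase = soft-masked)
#' @param proteins sequence tibble of stop-augmented proteins
#'   (see [append_stop()])
#' @param model a `pf_scoring_model`
#' @param min_score minimum reported alignment score (> 0)
#' @param mode `"auto"` (exact below `exact_max_bp`), `"exact"`, or
#'   `"seeded"`
#' @param genome_len total genome length for per-genome E-values; defaults
#'   to the summed length of `dna`
#' @param exact_max_bp DNA length cutoff for exact mode under `"auto"`
#' @param seed_gate minimum gapless extension score for a seed to spawn a
#'   DP window
#' @param window_pad bp added on both sides of a surviving seed's extent
#' @param seed_xdrop score drop terminating gapless seed extension
#' @param max_alignments cap on alignments per (record, strand, protein)
#' @return a tibble of alignments with one list-column `columns` holding the
#'   per-column detail (`op`, `codon`, `aa`)
#' @export
align_local <- function(dna, proteins, model, min_score,
                        mode = c("auto", "exact", "seeded"),
                        genome_len = NULL, exact_max_bp = 20000L,
                        seed_gate = 40L, window_pad = 60L,
                        seed_xdrop = 20L, max_alignments = 50L) {
  mode <- match.arg(mode)
  check_seq_tbl(dna, "dna")
  check_seq_tbl(proteins, "protein")
  stopifnot(min_score > 0)
  if (nrow(proteins) == 0L || nrow(dna) == 0L) return(empty_alignments())
  total_prot <- sum(nchar(proteins$residues))
  if (is.null(genome_len)) genome_len <- sum(nchar(dna$residues))
  prot_raw <- lapply(proteins$residues, aa_to_raw)
  codon2aa <- pf_codon2aa_idx()

  out <- list()
  for (d in seq_len(nrow(dna))) {
    dlen <- nchar(dna$residues[d])
    use_exact <- switch(mode, exact = TRUE, seeded = FALSE,
                        auto = dlen <= exact_max_bp)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") dna$residues[d] else revcomp(dna$residues[d])
      if (use_exact) {
        windows <- tibble::tibble(prot = seq_len(nrow(proteins)) - 1L,
                                  wstart = 0L, wend = dlen)
      } else {
        raw <- pf_seed_windows(s, prot_raw, model$subst, codon2aa,
                               seed_len = 4L, gate = seed_gate,
                               pad = window_pad, xdrop = seed_xdrop)
        if (nrow(raw) == 0L) next
        windows <- dplyr::bind_rows(lapply(
          split(raw, raw$prot), function(g) {
            r <- IRanges::reduce(IRanges::IRanges(g$wstart + 1L, g$wend))
            tibble::tibble(prot = g$prot[1],
                           wstart = IRanges::start(r) - 1L,
                           wend = IRanges::end(r))
          }))
      }
      for (w in seq_len(nrow(windows))) {
        p <- windows$prot[w] + 1L
        ws <- windows$wstart[w]; we <- windows$wend[w]
        hits <- pf_dp_align(substr(s, ws + 1, we), prot_raw[[p]],
                            model$subst, model$min_aa_score,
                            model$gap_open, model$gap_extend,
                            model$frameshift, min_score, max_alignments)
        for (h in hits) {
          rs <- h$dna_start + ws; re <- h$dna_end + ws  # strand-relative
          cols <- ops_to_columns(h$ops, s, rs, proteins$residues[p],
                                 h$prot_start)
          fs <- if (strand == "+") rs else dlen - re
          fe <- if (strand == "+") re else dlen - rs
          ec <- evalue(h$score, dlen, total_prot, model)
          out[[length(out) + 1L]] <- tibble::tibble(
            dna_id = dna$id[d], dna_start = fs, dna_end = fe,
            strand = strand, prot_id = proteins$id[p],
            prot_start = h$prot_start, prot_end = h$prot_end,
            score = h$score, evalue_chrom = ec,
            evalue_genome = per_genome_evalue(ec, dlen, genome_len),
            aa_identity = aa_identity_columns(cols),
            columns = list(cols))
        }
      }
    }
  }
  if (length(out) == 0L) return(empty_alignments())
  res <- dplyr::bind_rows(out)
  # deterministic order; ties by lower start, then protein, then '+' strand
  dplyr::arrange(res, .data$dna_id, .data$dna_start, .data$prot_id,
                 dplyr::desc(.data$strand))
}

aa_identity_columns <- function(columns) {
  cc <- columns[columns$op == "codon_aa", , drop = FALSE]
  if (nrow(cc) == 0L) stop("alignment has no codon/amino-acid columns")
  # ambiguous codons never count as identical
  tr <- translate_codon(cc$codon)
  mean(!is.na(tr) & tr == cc$aa)
}

#' Amino-acid identity of alignments
#'
#' Fraction of codon/amino-acid columns whose codon translates exactly to
#' the aligned residue; gap and frameshift columns are excluded from the
#' denominator.
#'
#' @param alignments an alignment tibble from [align_local()]
#' @return numeric vector, one value per alignment
#' @export
aa_identity <- function(alignments) {
  vapply(alignments$columns, aa_identity_columns, numeric(1))
}

#' Reverse (but do not complement) genome sequences as a decoy
#'
#' The reversed genome has the same composition and repeat structure as the
#' real one but no true protein homology, so hits against it estimate the
#' false-positive rate of the whole search.
#'
#' @param genome sequence tibble of DNA records
#' @return sequence tibble with reversed residues and ids suffixed `"_rev"`
#' @export
reverse_decoy <- function(genome) {
  check_seq_tbl(genome, "dna")
  dplyr::mutate(genome,
                id = paste0(sub("_rev$", "", .data$id),
                            ifelse(grepl("_rev$", .data$id), "", "_rev")),
                residues = rev_string(.data$residues))
}

alignment_disrupted <- function(columns) {
  if (any(columns$op %in% c("fs+", "fs-"))) return(TRUE)
  cc <- columns[columns$op == "codon_aa", , drop = FALSE]
  tr <- translate_codon(cc$codon)
  any(!is.na(tr) & tr == "*" & cc$aa != "*")
}

#' Frameshift / premature-stop disruption statistics
#'
#' An alignment is disrupted when it contains at least one frameshift or at
#' least one codon that translates to a stop aligned to a non-stop residue —
#' the signature of lost coding function.
#'
#' @param alignments an alignment tibble from [align_local()]
#' @return one-row tibble with `n`, `n_disrupted`, `frac_disrupted`
#'   (`frac_disrupted` is `NA` when `n == 0`)
#' @export
disruption_stats <- function(alignments) {
  n <- nrow(alignments)
  if (n == 0L)
    return(tibble::tibble(n = 0L, n_disrupted = 0L, frac_disrupted = NA_real_))
  dis <- vapply(alignments$columns, alignment_disrupted, logical(1))
  tibble::tibble(n = n, n_disrupted = sum(dis), frac_disrupted = mean(dis))
}

#' Soft-mask simple sequence by dinucleotide entropy
#'
#' Lowercases every window of `window` bp whose dinucleotide entropy falls
#' below `min_bits`, so simple sequence cannot seed alignments.  Input
#' lowercase is preserved.
#'
#' @param dna sequence tibble of DNA records
#' @param window window length in bp
#' @param min_bits entropy threshold in bits
#' @return the tibble with masked residues
#' @export
mask_simple <- function(dna, window = 20L, min_bits = 1.0) {
  check_seq_tbl(dna, "dna")
  dplyr::mutate(dna, residues = vapply(
    .data$residues, pf_mask_entropy, character(1),
    window = as.integer(window), min_bits = min_bits, USE.NAMES = FALSE))
}

#' Dot-matrix style view of one translated alignment
#' @param alignments alignment tibble; the first row is drawn
#' @param ... unused
#' @return a ggplot
#' @export
plot_alignment <- function(alignments, ...) {
  stopifnot(nrow(alignments) >= 1)
  cols <- alignments$columns[[1]]
  tr <- translate_codon(cols$codon)
  d <- dplyr::mutate(
    tibble::as_tibble(cols), column = dplyr::row_number(),
    kind = dplyr::case_when(
      .data$op %in% c("fs+", "fs-") ~ "frameshift",
      .data$op != "codon_aa" ~ "gap",
      !is.na(tr) & tr == "*" & .data$aa != "*" ~ "premature stop",
      !is.na(tr) & tr == .data$aa ~ "identity",
      TRUE ~ "substitution"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$column, y = 1, fill = .data$kind)) +
    ggplot2::geom_tile(height = 0.6) +
    ggplot2::scale_fill_manual(values = c(
      identity = "grey20", substitution = "grey70", gap = "white",
      frameshift = "firebrick", `premature stop` = "orange")) +
    ggplot2::labs(x = "alignment column", y = NULL,
                  title = paste(alignments$dna_id[1], "vs",
                                alignments$prot_id[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
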