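# From raw translated alignments to the fossil-call set: protein-name
# exclusion, strongest-overlap retention, coding-overlap removal, the
# host-gene-vs-TE filter, and the novelty classifiers.

empty_calls <- function() {
  tibble::tibble(seq_id = character(), start = integer(), end = integer(),
                 strand = character(), protein_id = character(),
                 source_class = character(), score = integer(),
                 evalue_genome = numeric(), disrupted = logical(),
                 provenance = character())
}

#' Convert alignments into fossil calls
#'
#' @param alignments alignment tibble from [align_local()]
#' @param protein_classes tibble with `id` and `source_class`
#'   (`"TE:<class/family>"` or `"host_gene"`); proteins not listed get
#'   `source_class = NA`
#' @return a fossil-call tibble
#' @export
alignments_to_calls <- function(alignments, protein_classes = NULL) {
  if (nrow(alignments) == 0L) return(empty_calls())
  sc <- if (is.null(protein_classes)) NA_character_ else
    protein_classes$source_class[match(alignments$prot_id,
                                       protein_classes$id)]
  tibble::tibble(
    seq_id = alignments$dna_id, start = alignments$dna_start,
    end = alignments$dna_end, strand = alignments$strand,
    protein_id = alignments$prot_id, source_class = sc,
    score = alignments$score, evalue_genome = alignments$evalue_genome,
    disrupted = vapply(alignments$columns, alignment_disrupted, logical(1)),
    provenance = "direct")
}

# class of a TE call ("LINE" from "TE:LINE/CR1"); NA for host-gene calls
call_te_class <- function(source_class) {
  ifelse(grepl("^TE:", source_class),
         sub("/.*$", "", sub("^TE:", "", source_class)), NA_character_)
}

call_te_class_family <- function(source_class) {
  ifelse(grepl("^TE:", source_class), sub("^TE:", "", source_class),
         NA_character_)
}

#' Exclude exapted proteins from a library by name
#'
#' TE protein libraries include proteins of genes exapted *from* TEs; hits
#' to those are real homologies but not fossils, so the proteins are dropped
#' before alignment.  Matching is by fixed substring.
#'
#' @param proteins sequence tibble
#' @param patterns substrings marking exapted-gene entries
#' @return the tibble without matching records
#' @export
exclude_exapted_proteins <- function(
    proteins,
    patterns = c("_HSgene", "_Hsa_", "UN-GIN", "_Xtr_eg_tp")) {
  hit <- Reduce(`|`, lapply(patterns, function(p)
    grepl(p, proteins$id, fixed = TRUE)), rep(FALSE, nrow(proteins)))
  proteins[!hit, , drop = FALSE]
}

#' Keep only the strongest of overlapping fossil calls
#'
#' Greedy by descending score: a call is kept iff it shares no genomic base
#' (on either strand) with an already-kept call.  Ties break by lower
#' genome-wide E-value, then lower start, then protein id.  The output is
#' overlap-free.
#'
#' @param calls fossil-call tibble
#' @return the kept calls, in the original column order
#' @export
drop_weaker_overlaps <- function(calls) {
  if (nrow(calls) <= 1L) return(calls)
  ord <- order(-calls$score, calls$evalue_genome, calls$start,
               calls$protein_id)
  kept <- logical(nrow(calls))
  ks <- split(integer(0), character(0))  # per-seq kept starts/ends
  kstart <- list(); kend <- list()
  for (i in ord) {
    sq <- calls$seq_id[i]
    s <- calls$start[i]; e <- calls$end[i]
    ov <- FALSE
    if (!is.null(kstart[[sq]]))
      ov <- any(kstart[[sq]] < e & kend[[sq]] > s)
    if (!ov) {
      kept[i] <- TRUE
      kstart[[sq]] <- c(kstart[[sq]], s)
      kend[[sq]] <- c(kend[[sq]], e)
    }
  }
  calls[kept, , drop = FALSE]
}

#' Remove calls overlapped too much by protein-coding annotation
#'
#' A call is removed iff strictly more than `max_frac` of its bases are
#' covered by the union of CDS intervals (strand-agnostic): exactly 10%
#' coverage is kept.
#'
#' @param calls fossil-call tibble
#' @param cds_intervals annotation tibble of CDS intervals
#' @param max_frac maximum tolerated covered fraction
#' @return the surviving calls
#' @export
remove_coding_overlaps <- function(calls, cds_intervals, max_frac = 0.10) {
  stopifnot(max_frac >= 0, max_frac <= 1)
  if (nrow(calls) == 0L) return(calls)
  frac <- coverage_fraction(calls, cds_intervals, same_strand = FALSE)
  calls[frac <= max_frac, , drop = FALSE]
}

#' Drop host-gene calls that are mostly annotated TE
#'
#' Host-gene protein-coding segments that themselves evolved from TEs (e.g.
#' SINE-derived exons) produce true but unwanted homologies; a host-gene
#' call is removed iff more than `max_frac` of it is covered by RepeatMasker
#' records whose class is not in `exempt_classes`.  TE calls pass through
#' untouched.
#'
#' @param calls fossil-call tibble
#' @param rmsk annotation tibble of RepeatMasker records
#' @param max_frac maximum tolerated covered fraction
#' @param exempt_classes annotation classes ignored by the rule
#' @return the surviving calls
#' @export
filter_hostgene_vs_te <- function(calls, rmsk, max_frac = 0.10,
                                  exempt_classes = c("Low_complexity",
                                                     "Simple_repeat")) {
  if (nrow(calls) == 0L) return(calls)
  host <- calls$source_class == "host_gene"
  if (!any(host, na.rm = TRUE)) return(calls)
  te_ann <- rmsk[!(parse_class_family(rmsk$class_family)$class %in%
                     exempt_classes), , drop = FALSE]
  frac <- rep(0, nrow(calls))
  hh <- which(host)
  frac[hh] <- coverage_fraction(calls[hh, , drop = FALSE], te_ann,
                                same_strand = FALSE)
  calls[!(host %in% TRUE & frac > max_frac), , drop = FALSE]
}

te_known_classes_filter <- function(rmsk) {
  cls <- parse_class_family(rmsk$class_family)$class
  !(cls %in% c("Unknown", "Low_complexity", "Simple_repeat"))
}

#' Genome-census novelty: is a TE call mostly unannotated?
#'
#' A TE fossil is novel iff at most `max_frac` of it is covered by
#' RepeatMasker TE annotations with a *known* class/family on the *same*
#' strand; records of class `"Unknown"` do not count against novelty.
#'
#' @param calls fossil-call tibble (TE calls)
#' @param rmsk annotation tibble
#' @param max_frac coverage tolerance (novel up to and including it)
#' @return logical vector, `TRUE` = novel
#' @export
classify_novelty_table1 <- function(calls, rmsk, max_frac = 0.10) {
  if (nrow(calls) == 0L) return(logical(0))
  known <- rmsk[te_known_classes_filter(rmsk), , drop = FALSE]
  coverage_fraction(calls, known, same_strand = TRUE) <= max_frac
}

#' Strict "not new" rule for a TE call
#'
#' A TE fossil is "not new" iff it has nonzero overlap with a same-strand
#' annotation of the same class (LINE, LTR, DNA, ...).  One shared base
#' suffices.
#'
#' @param calls fossil-call tibble (TE calls with parseable class)
#' @param rmsk annotation tibble
#' @return logical vector, `TRUE` = not new
#' @export
classify_not_new <- function(calls, rmsk) {
  if (nrow(calls) == 0L) return(logical(0))
  cls <- call_te_class(calls$source_class)
  if (anyNA(cls))
    stop("call without parseable TE class: ",
         calls$source_class[is.na(cls)][1])
  ann_cls <- parse_class_family(rmsk$class_family)$class
  vapply(seq_len(nrow(calls)), function(i) {
    a <- rmsk[ann_cls == cls[i] & rmsk$seq_id == calls$seq_id[i] &
                rmsk$strand == calls$strand[i], , drop = FALSE]
    any(a$start < calls$end[i] & a$end > calls$start[i])
  }, logical(1))
}

#' Pseudogene novelty for host-gene calls
#'
#' A host-gene fossil is novel iff at most `max_frac` of it overlaps known
#' pseudogenes on the same strand.
#'
#' @param calls fossil-call tibble (host-gene calls)
#' @param known_pseudogenes annotation tibble
#' @param max_frac coverage tolerance
#' @return logical vector, `TRUE` = novel
#' @export
pseudogene_novelty <- function(calls, known_pseudogenes, max_frac = 0.10) {
  if (nrow(calls) == 0L) return(logical(0))
  coverage_fraction(calls, known_pseudogenes, same_strand = TRUE) <= max_frac
}
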