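# Shared alphabets, translation tables, and small sequence utilities.

# amino-acid alphabet used throughout: 20 residues plus the stop symbol '*'
AA_ORDER <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*")

DNA_BASES <- c("A", "C", "G", "T")

# 64 codons in index order (A=0, C=1, G=2, T=3; idx = 16*b1 + 4*b2 + b3)
pf_codons <- function() {
  b <- DNA_BASES
  as.vector(vapply(b, function(x1)
    vapply(b, function(x2)
      paste0(x1, x2, b), character(4)), matrix("", 4, 4)))
}

# codon -> amino-acid character (stops map to '*'), standard genetic code
pf_codon_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[pf_codons()])
}

# codon index (0-based) -> amino-acid index (0-based in AA_ORDER)
pf_codon2aa_idx <- function() {
  match(pf_codon_aa(), AA_ORDER) - 1L
}

# amino-acid string -> raw vector of 0-based AA_ORDER indices (for C++ calls)
aa_to_raw <- function(x) {
  idx <- match(strsplit(x, "")[[1]], AA_ORDER)
  if (anyNA(idx)) {
    bad <- unique(strsplit(x, "")[[1]][is.na(idx)])
    stop("invalid amino-acid letter(s): ", paste(bad, collapse = ", "))
  }
  as.raw(idx - 1L)
}

translate_codon <- function(codon) {
  tab <- setNames(pf_codon_aa(), pf_codons())
  unname(tab[toupper(codon)])
}

#' Reverse-complement a DNA string, preserving soft-masking case
#' @param x character vector of DNA strings
#' @return character vector
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", s)
    rawToChar(rev(charToRaw(comp)))
  }, character(1), USE.NAMES = FALSE)
}

# reverse WITHOUT complementing (decoy construction)
rev_string <- function(x) {
  vapply(x, function(s) rawToChar(rev(charToRaw(s))), character(1),
         USE.NAMES = FALSE)
}

# validate a sequence tibble (id, residues, kind)
check_seq_tbl <- function(x, kind = NULL) {
  stopifnot(is.data.frame(x), all(c("id", "residues", "kind") %in% names(x)))
  if (anyDuplicated(x$id))
    stop("duplicate sequence id: ", x$id[duplicated(x$id)][1])
  if (!is.null(kind) && !all(x$kind == kind))
    stop("expected all records of kind '", kind, "'")
  invisible(x)
}

#' Construct a sequence tibble
#'
#' The package-wide container for sequences: one row per record with columns
#' `id`, `residues` and `kind` (`"dna"` or `"protein"`).  Lowercase DNA
#' letters mark soft-masked positions and are preserved everywhere.
#'
#' @param id character vector of unique record names
#' @param residues character vector of sequences
#' @param kind `"dna"`, `"protein"`, or `NULL` to guess per record
#' @return a tibble with columns id, residues, kind
#' @export
seq_tbl <- function(id, residues, kind = NULL) {
  if (is.null(kind)) {
    kind <- ifelse(
      grepl("^[ACGTNacgtn]*$", residues), "dna", "protein")
  }
  out <- tibble::tibble(id = as.character(id),
                        residues = as.character(residues),
                        kind = kind)
  check_seq_tbl(out)
  out
}

# interval gap between [s1,e1) and [s2,e2): 0 if they touch or overlap
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

# per-base coverage of [start,end) by the union of covering intervals,
# via IRanges (half-open coordinates are converted at the boundary)
covered_bases <- function(start, end, cov_start, cov_end) {
  if (length(cov_start) == 0L) return(rep(0L, length(start)))
  cov <- IRanges::reduce(IRanges::IRanges(cov_start + 1L, cov_end))
  q <- IRanges::IRanges(start + 1L, end)
  hits <- IRanges::findOverlaps(q, cov)
  w <- IRanges::width(IRanges::pintersect(
    q[S4Vectors::queryHits(hits)], cov[S4Vectors::subjectHits(hits)]))
  out <- rep(0L, length(start))
  if (length(hits)) {
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.integer(agg)
  }
  out
}

# coverage fraction of calls (seq_id,start,end) by annotation intervals,
# optionally restricted to the same strand
coverage_fraction <- function(calls, ann, same_strand = FALSE) {
  if (nrow(calls) == 0L) return(numeric(0))
  frac <- numeric(nrow(calls))
  if (nrow(ann) == 0L) return(frac)
  key <- if (same_strand) paste(calls$seq_id, calls$strand)
         else calls$seq_id
  akey <- if (same_strand) paste(ann$seq_id, ann$strand) else ann$seq_id
  for (k in unique(key)) {
    ci <- which(key == k)
    ai <- which(akey == k)
    frac[ci] <- covered_bases(calls$start[ci], calls$end[ci],
                              ann$start[ai], ann$end[ai]) /
      (calls$end[ci] - calls$start[ci])
  }
  frac
}

# deterministic integer sub-seed derived from a master seed (< 2^31)
sub_seed <- function(seed, k) {
  (as.integer(seed) * 1103L + as.integer(k) * 12347L) %% 2147483563L
}
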