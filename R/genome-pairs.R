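# Reducing pairwise genome alignments to confident orthologous context:
# one-to-one selection, zero-tolerance coding pruning, the linked-alignment
# graph filter that defeats non-homologous TE insertions, and block-level
# interval projection between genomes.

#' Reduce blocks to most-similar one-to-one alignments
#'
#' Greedy by descending score: a block is kept iff it overlaps no kept block
#' on *either* genome, so every base of each genome is covered at most once.
#'
#' @param blocks block tibble (g1_seq/g1_start/g1_end, g2_*, strand, score)
#' @return the kept blocks
#' @export
make_one_to_one <- function(blocks) {
  if (nrow(blocks) <= 1L) return(blocks)
  ord <- order(-blocks$score, blocks$g1_seq, blocks$g1_start,
               blocks$g2_seq, blocks$g2_start)
  kept <- logical(nrow(blocks))
  k1s <- list(); k1e <- list(); k2s <- list(); k2e <- list()
  for (i in ord) {
    s1 <- blocks$g1_seq[i]; s2 <- blocks$g2_seq[i]
    ov <- FALSE
    if (!is.null(k1s[[s1]]))
      ov <- any(k1s[[s1]] < blocks$g1_end[i] & k1e[[s1]] > blocks$g1_start[i])
    if (!ov && !is.null(k2s[[s2]]))
      ov <- any(k2s[[s2]] < blocks$g2_end[i] & k2e[[s2]] > blocks$g2_start[i])
    if (!ov) {
      kept[i] <- TRUE
      k1s[[s1]] <- c(k1s[[s1]], blocks$g1_start[i])
      k1e[[s1]] <- c(k1e[[s1]], blocks$g1_end[i])
      k2s[[s2]] <- c(k2s[[s2]], blocks$g2_start[i])
      k2e[[s2]] <- c(k2e[[s2]], blocks$g2_end[i])
    }
  }
  blocks[kept, , drop = FALSE]
}

#' Remove blocks touching protein-coding annotation in either genome
#'
#' Zero tolerance: one shared base with a CDS interval of genome 1 *or*
#' genome 2 removes the block.  This guards the conservation test against
#' alignment overshoot near coding exons.
#'
#' @param blocks block tibble
#' @param cds1,cds2 annotation tibbles of CDS intervals per genome
#' @return the surviving blocks
#' @export
prune_coding <- function(blocks, cds1, cds2) {
  if (nrow(blocks) == 0L) return(blocks)
  ov_side <- function(seqs, starts, ends, cds) {
    if (nrow(cds) == 0L) return(rep(FALSE, length(starts)))
    vapply(seq_along(starts), function(i) {
      a <- cds[cds$seq_id == seqs[i], , drop = FALSE]
      any(a$start < ends[i] & a$end > starts[i])
    }, logical(1))
  }
  bad <- ov_side(blocks$g1_seq, blocks$g1_start, blocks$g1_end, cds1) |
    ov_side(blocks$g2_seq, blocks$g2_start, blocks$g2_end, cds2)
  blocks[!bad, , drop = FALSE]
}

# per-genome linkage test between two blocks, given midpoint ranks
blocks_linked <- function(blocks, i, j, max_gap, max_between,
                          rank1, rank2) {
  if (blocks$g1_seq[i] != blocks$g1_seq[j] ||
      blocks$g2_seq[i] != blocks$g2_seq[j]) return(FALSE)
  gap1 <- interval_gap(blocks$g1_start[i], blocks$g1_end[i],
                       blocks$g1_start[j], blocks$g1_end[j])
  gap2 <- interval_gap(blocks$g2_start[i], blocks$g2_end[i],
                       blocks$g2_start[j], blocks$g2_end[j])
  if (gap1 > max_gap || gap2 > max_gap) return(FALSE)
  abs(rank1[i] - rank1[j]) - 1L <= max_between &&
    abs(rank2[i] - rank2[j]) - 1L <= max_between
}

#' Discard isolated alignments (the linked-alignment filter)
#'
#' Two blocks are linked iff, in *both* genomes, they lie on the same
#' sequence, their interval gap is at most `max_gap` bp, and at most
#' `max_between` other blocks of the input set lie strictly between them
#' (by midpoint order on that sequence).  Blocks are retained iff they are
#' linked, directly or indirectly, to at least `min_links` others — i.e.
#' their connected component has at least `min_links + 1` blocks.  Isolated
#' high-scoring alignments are typically non-homologous insertions of one
#' TE family into homologous loci, not shared ancestral sequence.
#'
#' @param blocks one-to-one block tibble
#' @param max_gap maximum interval gap (bp) in each genome
#' @param max_between maximum number of intervening blocks in each genome
#' @param min_links minimum number of (transitively) linked partners
#' @return the retained blocks, with a `component` column added
#' @export
link_filter <- function(blocks, max_gap = 1e6, max_between = 5L,
                        min_links = 2L) {
  n <- nrow(blocks)
  if (n == 0L) return(dplyr::mutate(blocks, component = integer(0)))
  mid1 <- (blocks$g1_start + blocks$g1_end) / 2
  mid2 <- (blocks$g2_start + blocks$g2_end) / 2
  rank1 <- integer(n); rank2 <- integer(n)
  for (sq in unique(blocks$g1_seq)) {
    ii <- which(blocks$g1_seq == sq)
    rank1[ii] <- rank(mid1[ii], ties.method = "first")
  }
  for (sq in unique(blocks$g2_seq)) {
    ii <- which(blocks$g2_seq == sq)
    rank2[ii] <- rank(mid2[ii], ties.method = "first")
  }
  # candidate pairs: g1 rank distance <= max_between + 1 on the same seq
  edges <- list()
  for (sq in unique(blocks$g1_seq)) {
    ii <- which(blocks$g1_seq == sq)
    ii <- ii[order(rank1[ii])]
    for (a in seq_along(ii)) {
      for (b in seq_len(min(max_between + 1L, length(ii) - a))) {
        i <- ii[a]; j <- ii[a + b]
        if (blocks_linked(blocks, i, j, max_gap, max_between, rank1, rank2))
          edges[[length(edges) + 1L]] <- c(i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, unlist(edges))
  comp <- igraph::components(g)
  keep <- comp$csize[comp$membership] >= min_links + 1L
  out <- blocks[keep, , drop = FALSE]
  out$component <- comp$membership[keep]
  out
}

#' Project an interval through one-to-one blocks to the other genome
#'
#' Block-level mapping: the union of genome-1 spans of blocks overlapping
#' the genome-2 interval, clipped proportionally at block ends (reversed
#' within the span for `-` blocks).  Returns a zero-row tibble when no
#' block overlaps; an interval whose overlapping blocks map to different
#' genome-1 sequences yields none, with a warning.
#'
#' @param interval one-row tibble/list with seq_id, start, end (genome-2
#'   coordinates)
#' @param blocks one-to-one block tibble
#' @return tibble with seq_id, start, end in genome-1 coordinates (0 or 1
#'   row)
#' @export
project_interval <- function(interval, blocks) {
  none <- tibble::tibble(seq_id = character(), start = integer(),
                         end = integer())
  ov <- blocks[blocks$g2_seq == interval$seq_id &
                 blocks$g2_start < interval$end &
                 blocks$g2_end > interval$start, , drop = FALSE]
  if (nrow(ov) == 0L) return(none)
  if (length(unique(ov$g1_seq)) > 1L) {
    warning("interval maps to multiple genome-1 sequences; no projection")
    return(none)
  }
  pieces <- lapply(seq_len(nrow(ov)), function(i) {
    b <- ov[i, ]
    c2 <- max(interval$start, b$g2_start)
    d2 <- min(interval$end, b$g2_end)
    w1 <- b$g1_end - b$g1_start
    w2 <- b$g2_end - b$g2_start
    if (b$strand == "+") {
      lo <- b$g1_start + floor((c2 - b$g2_start) * w1 / w2)
      hi <- b$g1_start + ceiling((d2 - b$g2_start) * w1 / w2)
    } else {
      lo <- b$g1_start + floor((b$g2_end - d2) * w1 / w2)
      hi <- b$g1_start + ceiling((b$g2_end - c2) * w1 / w2)
    }
    c(lo, hi)
  })
  lo <- min(vapply(pieces, `[`, numeric(1), 1))
  hi <- max(vapply(pieces, `[`, numeric(1), 2))
  tibble::tibble(seq_id = ov$g1_seq[1], start = as.integer(lo),
                 end = as.integer(max(hi, lo + 1)))
}
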