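# Independent oracles and random-instance generators shared across tests.
# These deliberately share no code with the implementation paths they check.

AA21 <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*")

# ---- exhaustive-enumeration oracle for the translated aligner ------------
# Recursively tries every local alignment (start point and column
# sequence) under the model definition: alignments start/end with a codon
# column, frameshifts only between codon columns, affine gap runs never
# switch side without an intervening codon column.
oracle_best_score <- function(dna, prot, model) {
  n <- nchar(dna); m <- nchar(prot)
  if (n < 3 || m < 1) return(-Inf)
  codons <- rownames(model$subst)
  S <- function(i_end, j) {
    cod <- toupper(substr(dna, i_end - 2, i_end))
    a <- match(substr(prot, j, j), AA21)
    ci <- match(cod, codons)
    if (is.na(ci)) model$min_aa_score[a] else model$subst[ci, a]
  }
  best <- -Inf
  rec <- function(i, j, sc, state) {
    if (state == "M" && sc > best) best <<- sc
    if (i + 3 <= n && j < m) rec(i + 3, j + 1, sc + S(i + 3, j + 1), "M")
    if (state == "M") {
      if (i + 4 <= n && j < m)
        rec(i + 4, j + 1, sc - model$frameshift + S(i + 4, j + 1), "M")
      if (i >= 1 && i + 2 <= n && j < m)
        rec(i + 2, j + 1, sc - model$frameshift + S(i + 2, j + 1), "M")
    }
    if (state != "I" && j < m)
      rec(i, j + 1,
          sc - model$gap_extend - if (state == "D") 0 else model$gap_open,
          "D")
    if (state != "D" && i + 3 <= n)
      rec(i + 3, j,
          sc - model$gap_extend - if (state == "I") 0 else model$gap_open,
          "I")
  }
  for (i0 in 0:(n - 3)) for (j0 in 0:(m - 1))
    rec(i0 + 3, j0 + 1, S(i0 + 3, j0 + 1), "M")
  best
}

# best score over both strands, as align_local reports it
oracle_best_both_strands <- function(dna, prot, model) {
  max(oracle_best_score(dna, prot, model),
      oracle_best_score(revcomp(dna), prot, model))
}

# ---- per-base bitmap coverage oracle -------------------------------------
bitmap_covered <- function(start, end, cov_start, cov_end) {
  if (end <= start) return(0L)
  bits <- rep(FALSE, end - start)
  for (k in seq_along(cov_start)) {
    lo <- max(start, cov_start[k]); hi <- min(end, cov_end[k])
    if (hi > lo) bits[(lo - start + 1):(hi - start)] <- TRUE
  }
  sum(bits)
}

# ---- O(n^2) reference for strongest-overlap retention --------------------
oracle_drop_weaker <- function(calls) {
  ord <- order(-calls$score, calls$evalue_genome, calls$start,
               calls$protein_id)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (calls$seq_id[i] == calls$seq_id[j] &&
          calls$start[i] < calls$end[j] && calls$end[i] > calls$start[j]) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  calls[sort(kept), , drop = FALSE]
}

# ---- O(n^2) reference for one-to-one block selection ---------------------
oracle_one_to_one <- function(blocks) {
  ord <- order(-blocks$score, blocks$g1_seq, blocks$g1_start,
               blocks$g2_seq, blocks$g2_start)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if ((blocks$g1_seq[i] == blocks$g1_seq[j] &&
           blocks$g1_start[i] < blocks$g1_end[j] &&
           blocks$g1_end[i] > blocks$g1_start[j]) ||
          (blocks$g2_seq[i] == blocks$g2_seq[j] &&
           blocks$g2_start[i] < blocks$g2_end[j] &&
           blocks$g2_end[i] > blocks$g2_start[j])) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  blocks[sort(kept), , drop = FALSE]
}

# ---- brute-force link filter: all-pairs graph + components ---------------
oracle_link_filter <- function(blocks, max_gap = 1e6, max_between = 5,
                               min_links = 2) {
  n <- nrow(blocks)
  if (n == 0) return(blocks)
  mid1 <- (blocks$g1_start + blocks$g1_end) / 2
  mid2 <- (blocks$g2_start + blocks$g2_end) / 2
  gap <- function(s1, e1, s2, e2) max(0, max(s1, s2) - min(e1, e2))
  between <- function(mids, seqs, i, j) {
    lo <- min(mids[i], mids[j]); hi <- max(mids[i], mids[j])
    length(setdiff(which(seqs == seqs[i] & mids > lo & mids < hi),
                   c(i, j)))
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (blocks$g1_seq[i] != blocks$g1_seq[j]) next
    if (blocks$g2_seq[i] != blocks$g2_seq[j]) next
    g1 <- gap(blocks$g1_start[i], blocks$g1_end[i],
              blocks$g1_start[j], blocks$g1_end[j])
    g2 <- gap(blocks$g2_start[i], blocks$g2_end[i],
              blocks$g2_start[j], blocks$g2_end[j])
    if (g1 > max_gap || g2 > max_gap) next
    b1 <- between(mid1, blocks$g1_seq, i, j)
    b2 <- between(mid2, blocks$g2_seq, i, j)
    if (b1 <= max_between && b2 <= max_between) adj[i, j] <- adj[j, i] <- TRUE
  }
  # connected components by repeated BFS
  comp <- rep(0L, n); cc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cc <- cc + 1L
    queue <- s; comp[s] <- cc
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cc
      queue <- c(queue, nb)
    }
  }
  size <- table(comp)
  blocks[size[as.character(comp)] >= min_links + 1, , drop = FALSE]
}

# ---- O(n^2) reference for tectonic pairs ---------------------------------
oracle_tectonic_count <- function(calls, min_sep = 30000, max_sep = 3e6) {
  fam <- sub("^TE:", "", calls$source_class)
  fam[!grepl("^TE:", calls$source_class)] <- NA
  cnt <- 0L
  n <- nrow(calls)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || is.na(fam[i]) || is.na(fam[j])) next
    if (calls$seq_id[i] != calls$seq_id[j] || fam[i] != fam[j]) next
    sep <- max(0, max(calls$start[i], calls$start[j]) -
                 min(calls$end[i], calls$end[j]))
    if (sep >= min_sep && sep <= max_sep) cnt <- cnt + 1L
  }
  cnt
}

# ---- random-instance generators ------------------------------------------
random_calls <- function(n, n_seq = 3, span = 10000, max_w = 400,
                         classes = c("TE:LINE/CR1", "TE:LTR/Gypsy",
                                     "host_gene")) {
  s <- sample.int(span, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  tibble::tibble(
    seq_id = paste0("c", sample.int(n_seq, n, replace = TRUE)),
    start = s, end = s + w,
    strand = sample(c("+", "-"), n, replace = TRUE),
    protein_id = paste0("p", sample.int(8, n, replace = TRUE)),
    source_class = sample(classes, n, replace = TRUE),
    score = sample.int(500, n, replace = TRUE),
    evalue_genome = stats::runif(n), disrupted = FALSE,
    provenance = "direct")
}

random_blocks <- function(n, n_seq = 2, span = 50000, max_w = 900) {
  s1 <- sample.int(span, n, replace = TRUE) - 1L
  s2 <- sample.int(span, n, replace = TRUE) - 1L
  w1 <- sample.int(max_w, n, replace = TRUE)
  w2 <- pmax(10L, as.integer(w1 * stats::runif(n, 0.8, 1.2)))
  tibble::tibble(
    g1_seq = paste0("a", sample.int(n_seq, n, replace = TRUE)),
    g1_start = s1, g1_end = s1 + w1,
    g2_seq = paste0("b", sample.int(n_seq, n, replace = TRUE)),
    g2_start = s2, g2_end = s2 + w2,
    strand = sample(c("+", "-"), n, replace = TRUE),
    score = stats::runif(n, 1, 1000))
}

random_annotations <- function(n, n_seq = 3, span = 10000, max_w = 500,
                               classes = c("LINE/CR1", "LINE/L2",
                                           "LTR/Gypsy", "Unknown",
                                           "Simple_repeat",
                                           "Low_complexity")) {
  s <- sample.int(span, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  tibble::tibble(
    seq_id = paste0("c", sample.int(n_seq, n, replace = TRUE)),
    start = s, end = s + w,
    strand = sample(c("+", "-"), n, replace = TRUE),
    name = paste0("rep", seq_len(n)),
    class_family = sample(classes, n, replace = TRUE))
}

random_dna_str <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein_str <- function(n, with_stop = FALSE) {
  s <- paste(sample(AA21[1:20], n, replace = TRUE), collapse = "")
  if (with_stop) paste0(s, "*") else s
}

# a tiny scoring model shared across aligner tests (cheap to build)
test_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- default_model()
    m
  }
})
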