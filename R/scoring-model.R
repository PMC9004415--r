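# The 64 x 21 codon-to-amino-acid scoring model: construction from column
# counts, a BLOSUM62-derived default, and Karlin-Altschul significance
# parameters (lambda from the matrix by root finding, K calibrated by
# random-sequence simulation).

new_scoring_model <- function(subst, gap_open, gap_extend, frameshift,
                              lambda, k, scale_t, bg_codon, bg_aa) {
  stopifnot(is.matrix(subst), nrow(subst) == 64, ncol(subst) == 21)
  dimnames(subst) <- list(pf_codons(), AA_ORDER)
  structure(
    list(subst = subst,
         gap_open = as.integer(gap_open),
         gap_extend = as.integer(gap_extend),
         frameshift = as.integer(frameshift),
         lambda = lambda, k = k, scale_t = scale_t,
         bg_codon = bg_codon, bg_aa = bg_aa,
         # conservative wildcard: an ambiguous codon scores the minimum
         # over all codons for the aligned amino acid
         min_aa_score = as.integer(apply(subst, 2, min))),
    class = "pf_scoring_model")
}

# solve sum_c,a p_c q_a exp(lambda * s_ca) = 1 for lambda > 0
solve_lambda <- function(subst, bg_codon, bg_aa) {
  w <- outer(bg_codon, bg_aa)
  f <- function(l) sum(w * exp(l * subst)) - 1
  # expected score must be negative and at least one score positive
  if (sum(w * subst) >= 0)
    stop("scoring matrix has non-negative expected score under background")
  if (max(subst) <= 0)
    stop("scoring matrix has no positive score")
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, c(1e-6, upper), tol = 1e-9)$root
}

#' Build a scoring model from codon/amino-acid column counts
#'
#' Scores are integer log-odds: `round(scale_t * ln(P(codon, aa) /
#' (p_codon * q_aa)))`, where the joint probability comes from the supplied
#' counts plus a pseudocount.  Gap and frameshift costs are derived from
#' event frequencies by the same rule, as costs `round(-scale_t * ln(freq))`.
#' The E-value scale `lambda` is solved from the matrix and the backgrounds;
#' `k` starts at a nominal value and can be refined with [calibrate_evalue()].
#'
#' @param column_counts 64 x 21 numeric matrix of observed (codon, amino
#'   acid) alignment-column counts; rows in codon index order, columns in
#'   `ACDEFGHIKLMNPQRSTVWY*` order
#' @param background_codon length-64 codon background probability vector
#' @param background_aa length-21 amino-acid background probability vector
#' @param pseudocount added to every cell before normalising
#' @param scale_t log-odds temperature (score units per nat)
#' @param gap_open_freq,gap_extend_freq,frameshift_freq event frequencies
#'   turned into integer costs by the same log-odds rule
#' @return an object of class `pf_scoring_model`
#' @export
model_from_counts <- function(column_counts, background_codon, background_aa,
                              pseudocount = 0.5, scale_t = 3,
                              gap_open_freq = 0.01, gap_extend_freq = 0.3,
                              frameshift_freq = 0.004) {
  stopifnot(is.matrix(column_counts),
            nrow(column_counts) == 64, ncol(column_counts) == 21)
  if (any(column_counts < 0)) stop("negative counts")
  if (sum(column_counts) == 0) stop("zero total counts")
  if (abs(sum(background_codon) - 1) > 1e-6 ||
      abs(sum(background_aa) - 1) > 1e-6)
    stop("backgrounds must be probability vectors")
  zero_bg <- outer(background_codon == 0, background_aa == 0, "|")
  if (any(zero_bg & column_counts > 0))
    stop("zero background probability with nonzero count")

  p <- column_counts + pseudocount
  p <- p / sum(p)
  lo <- log(p / outer(background_codon, background_aa))
  lo[!is.finite(lo)] <- log(1e-12)
  subst <- round(scale_t * lo)
  mode(subst) <- "integer"

  cost <- function(freq) max(1L, as.integer(round(-scale_t * log(freq))))
  gap_open <- cost(gap_open_freq)
  gap_extend <- cost(gap_extend_freq)
  frameshift <- cost(frameshift_freq)

  lambda <- solve_lambda(subst, background_codon, background_aa)
  new_scoring_model(subst, gap_open, gap_extend, frameshift,
                    lambda = lambda, k = 0.05, scale_t = scale_t,
                    bg_codon = background_codon, bg_aa = background_aa)
}

#' Default scoring model for degraded protein fossils
#'
#' Built from BLOSUM62 target frequencies mixed with an identity component:
#' a fossil codon either still encodes the aligned amino acid (probability
#' `pid`, spread uniformly over its synonymous codons) or encodes a residue
#' drawn from the BLOSUM62 conditional substitution distribution.  Stop
#' codons pair strongly with the appended `*` symbol, so fossil stop codons
#' can be matched, and weakly with amino acids (premature stops are allowed
#' but penalised).  The codon background is uniform (random DNA).
#'
#' @param pid expected amino-acid identity of the fossils being sought
#' @param scale_t log-odds temperature
#' @inheritParams model_from_counts
#' @return a `pf_scoring_model`
#' @export
default_model <- function(pid = 0.5, scale_t = 3,
                          gap_open_freq = 0.01, gap_extend_freq = 0.3,
                          frameshift_freq = 0.004) {
  b62 <- get_blosum62()[AA_ORDER, AA_ORDER]
  aa_of_codon <- pf_codon_aa()
  n_syn <- table(factor(aa_of_codon, levels = AA_ORDER))

  # amino-acid background: uniform-codon-usage marginal
  q <- as.numeric(n_syn) / 64
  names(q) <- AA_ORDER

  # BLOSUM62 target frequencies (half-bit scores): J ~ q_a q_b 2^(s/2)
  joint <- outer(q, q) * 2^(b62 / 2)
  joint <- joint / sum(joint)
  cond <- sweep(joint, 2, colSums(joint), "/")  # P(descendant | source)

  counts <- matrix(0, 64, 21, dimnames = list(pf_codons(), AA_ORDER))
  for (ci in seq_len(64)) {
    d <- aa_of_codon[ci]                     # residue the codon encodes now
    counts[ci, ] <- q * ((pid * (d == AA_ORDER)) / n_syn[[d]] +
                         (1 - pid) * cond[d, ] / n_syn[[d]])
  }
  counts <- counts / sum(counts) * 1e6

  model_from_counts(counts,
                    background_codon = rep(1 / 64, 64),
                    background_aa = q,
                    pseudocount = 1e-4, scale_t = scale_t,
                    gap_open_freq = gap_open_freq,
                    gap_extend_freq = gap_extend_freq,
                    frameshift_freq = frameshift_freq)
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Refit the scoring model from alignments (one-pass training)
#'
#' Mirrors the usual train-on-your-own-data loop in simplified one-pass
#' form: align the genome to the protein library with a starting model,
#' keep alignments whose amino-acid identity does not exceed `pid_max`
#' (focusing the fit on old, decayed fossils), count the observed
#' (codon, amino acid) columns and gap/frameshift events, and rebuild the
#' model from those counts.
#'
#' @param genome,proteins sequence tibbles (see [seq_tbl()])
#' @param model starting `pf_scoring_model`
#' @param pid_max training-set identity ceiling (default 0.5)
#' @param min_score score threshold for the training alignments
#' @param ... passed to [align_local()]
#' @return a new `pf_scoring_model`
#' @export
train_model <- function(genome, proteins, model = default_model(),
                        pid_max = 0.5, min_score = 60, ...) {
  alns <- align_local(genome, proteins, model, min_score = min_score, ...)
  alns <- dplyr::filter(alns, .data$aa_identity <= pid_max)
  if (nrow(alns) == 0) stop("no training alignments at identity <= pid_max")
  counts <- matrix(0, 64, 21, dimnames = list(pf_codons(), AA_ORDER))
  n_gap_open <- 0; n_gap_cols <- 0; n_fs <- 0; n_cols <- 0
  for (cols in alns$columns) {
    cc <- dplyr::filter(cols, .data$op == "codon_aa",
                        !grepl("[^ACGTacgt]", .data$codon))
    ti <- cbind(match(toupper(cc$codon), pf_codons()),
                match(cc$aa, AA_ORDER))
    for (r in seq_len(nrow(ti))) counts[ti[r, 1], ti[r, 2]] <-
        counts[ti[r, 1], ti[r, 2]] + 1
    isgap <- cols$op %in% c("codon_gap", "gap_aa")
    n_gap_cols <- n_gap_cols + sum(isgap)
    n_gap_open <- n_gap_open + sum(isgap & !c(FALSE, isgap[-length(isgap)]))
    n_fs <- n_fs + sum(cols$op %in% c("fs+", "fs-"))
    n_cols <- n_cols + nrow(cols)
  }
  model_from_counts(counts,
                    background_codon = model$bg_codon,
                    background_aa = model$bg_aa,
                    scale_t = model$scale_t,
                    gap_open_freq = max(n_gap_open, 1) / n_cols,
                    gap_extend_freq =
                      max(n_gap_cols - n_gap_open, 1) / max(n_gap_cols, 2),
                    frameshift_freq = max(n_fs, 1) / n_cols)
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = k * dna_len * total_protein_len * exp(-lambda * score)`: the expected
#' number of chance local alignments scoring at least `score` between a DNA
#' sequence of length `dna_len` and a protein database totalling
#' `total_protein_len` residues.  This is the per-chromosome E-value; scale
#' to the whole genome with [per_genome_evalue()].
#'
#' @param score alignment score(s), non-negative
#' @param dna_len searched DNA length (bp)
#' @param total_protein_len summed protein library length (residues)
#' @param model a `pf_scoring_model` supplying `lambda` and `k`
#' @return numeric E-value(s)
#' @export
evalue <- function(score, dna_len, total_protein_len, model) {
  stopifnot(all(score >= 0), dna_len > 0, total_protein_len > 0)
  model$k * dna_len * total_protein_len * exp(-model$lambda * score)
}

#' Rescale a per-chromosome E-value to the whole genome
#'
#' Search E-values are computed per chromosome; genome-wide significance
#' multiplies by the ratio of genome length to chromosome length.
#'
#' @param evalue_chrom per-chromosome E-value(s)
#' @param chrom_len chromosome length (bp)
#' @param genome_len total genome length (bp)
#' @return numeric per-genome E-value(s)
#' @export
per_genome_evalue <- function(evalue_chrom, chrom_len, genome_len) {
  stopifnot(chrom_len > 0, chrom_len <= genome_len)
  evalue_chrom * genome_len / chrom_len
}

# minimum score whose per-genome E-value is <= e_max
min_score_for_evalue <- function(model, e_max, genome_len, total_protein_len) {
  s <- log(model$k * genome_len * total_protein_len / e_max) / model$lambda
  max(1L, as.integer(ceiling(s)))
}

#' Calibrate E-value parameters by random-sequence search simulation
#'
#' Fits the Gumbel location/scale of the *reported* optimal local score of
#' the package's own search (seeded, by default, exactly as genome-scale
#' searches run) between random DNA and random protein sets drawn from the
#' model backgrounds, by moment matching, and writes the implied `lambda`
#' and `k` back into the model.  Calibrating the search that is actually
#' run — heuristics included — makes the E-value the expected number of
#' *reported* chance hits, which is the quantity the significance threshold
#' speaks about.
#'
#' @param model a `pf_scoring_model`
#' @param n_sims number of random (DNA, protein set) search replicates
#' @param dna_len random DNA length per replicate
#' @param prot_len,n_prots random protein library shape per replicate
#' @param mode search mode used for calibration (match the downstream
#'   searches)
#' @param min_score floor for the per-replicate maximum; replicates
#'   reporting nothing are dropped with a warning when common
#' @param ... passed to [align_local()] (e.g. `seed_gate`)
#' @return the model with calibrated `lambda` and `k`; per-replicate scores
#'   are attached as attribute `"calibration_scores"`
#' @export
calibrate_evalue <- function(model, n_sims = 60, dna_len = 50000,
                             prot_len = 150, n_prots = 10,
                             mode = "seeded", min_score = 40L, ...) {
  scores <- vapply(seq_len(n_sims), function(i) {
    dna <- paste(sample(pf_codons(), ceiling(dna_len / 3), replace = TRUE,
                        prob = model$bg_codon), collapse = "")
    dna <- substr(dna, 1, dna_len)
    prots <- seq_tbl(
      paste0("p", seq_len(n_prots)),
      vapply(seq_len(n_prots), function(j)
        paste(sample(AA_ORDER[1:20], prot_len, replace = TRUE,
                     prob = model$bg_aa[1:20]), collapse = ""),
        character(1)),
      kind = "protein")
    al <- align_local(seq_tbl("d", dna), append_stop(prots), model,
                      min_score = min_score, mode = mode, ...)
    if (nrow(al)) max(al$score) else NA_real_
  }, numeric(1))
  miss <- is.na(scores)
  if (mean(miss) > 0.2)
    warning("calibration: ", sum(miss), "/", n_sims,
            " replicates reported no alignment; raise dna_len")
  s <- scores[!miss]
  mu_hat <- mean(s)
  lambda <- pi / (sd(s) * sqrt(6))
  gammae <- 0.5772156649
  mu <- mu_hat - gammae / lambda
  k <- exp(lambda * mu) / (dna_len * n_prots * (prot_len + 1))
  model$lambda <- lambda
  model$k <- k
  attr(model, "calibration_scores") <- scores
  model
}

#' Write / read a scoring model as a plain-text parameter file
#'
#' Key-value header (gap costs, frameshift cost, lambda, K, scale) followed
#' by the 64 x 21 score matrix, one codon row per line.  Externally trained
#' parameter files in this layout are accepted verbatim.
#'
#' @param model a `pf_scoring_model`
#' @param path file path
#' @return `path` invisibly / a `pf_scoring_model`
#' @export
write_model <- function(model, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    sprintf("gap_open %d", model$gap_open),
    sprintf("gap_extend %d", model$gap_extend),
    sprintf("frameshift %d", model$frameshift),
    sprintf("lambda %.10g", model$lambda),
    sprintf("k %.10g", model$k),
    sprintf("scale_t %.10g", model$scale_t),
    paste("matrix", paste(AA_ORDER, collapse = " ")))
  rows <- vapply(seq_len(64), function(i)
    paste(pf_codons()[i], paste(model$subst[i, ], collapse = " ")),
    character(1))
  writeLines(c(hdr, rows), con, sep = "\n")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- function(key) {
    l <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    as.numeric(sub(paste0("^", key, " +"), "", l))
  }
  mstart <- grep("^matrix ", lines)
  subst <- matrix(0L, 64, 21)
  for (i in seq_len(64)) {
    f <- strsplit(lines[mstart + i], " +")[[1]]
    stopifnot(f[1] == pf_codons()[i])
    subst[i, ] <- as.integer(f[-1])
  }
  q <- as.numeric(table(factor(pf_codon_aa(), levels = AA_ORDER))) / 64
  new_scoring_model(subst, kv("gap_open"), kv("gap_extend"),
                    kv("frameshift"), lambda = kv("lambda"), k = kv("k"),
                    scale_t = kv("scale_t"),
                    bg_codon = rep(1 / 64, 64), bg_aa = q)
}

#' @export
print.pf_scoring_model <- function(x, ...) {
  cat("<pf_scoring_model> 64 x 21 codon/amino-acid log-odds matrix\n")
  cat(sprintf("  scale_t = %g, gap = %d + %d*k, frameshift = %d\n",
              x$scale_t, x$gap_open, x$gap_extend, x$frameshift))
  cat(sprintf("  lambda = %.4f, K = %.4g\n", x$lambda, x$k))
  invisible(x)
}

#' Tidy a scoring model into a long tibble
#' @param x a `pf_scoring_model`
#' @param ... unused
#' @return tibble with columns codon, aa, score
#' @export
tidy.pf_scoring_model <- function(x, ...) {
  tibble::tibble(
    codon = rep(pf_codons(), times = 21),
    aa = rep(AA_ORDER, each = 64),
    score = as.vector(x$subst))
}

#' One-row summary of a scoring model
#' @param x a `pf_scoring_model`
#' @param ... unused
#' @return one-row tibble
#' @export
glance.pf_scoring_model <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, k = x$k, scale_t = x$scale_t,
                 gap_open = x$gap_open, gap_extend = x$gap_extend,
                 frameshift = x$frameshift,
                 max_score = max(x$subst), min_score = min(x$subst))
}

#' Heatmap of the 64 x 21 substitution matrix
#' @param object a `pf_scoring_model`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.pf_scoring_model <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$aa, levels = AA_ORDER),
    y = factor(.data$codon, levels = rev(pf_codons())),
    fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "amino acid", y = "codon", fill = "score") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
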