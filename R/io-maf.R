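# MAF interchange: pairwise genome-alignment blocks and the translated
# (DNA-vs-protein) dialect with explicit frameshift columns.
#
# Translated-dialect text encoding, per alignment column:
#   codon <-> aa   : 3 nt in the DNA row, residue in the protein row
#   codon <-> gap  : 3 nt / '-'
#   gap <-> aa     : '---' / residue
#   +1 frameshift  : '\' + skipped nt / '-'
#   -1 frameshift  : '/' / '-'   (the next codon re-uses one nucleotide)
# MAF starts are strand-relative (converted to forward-strand absolute
# coordinates at the read boundary); unknown line types q/p/i are skipped.

empty_blocks <- function() {
  tibble::tibble(g1_seq = character(), g1_start = integer(),
                 g1_end = integer(), g2_seq = character(),
                 g2_start = integer(), g2_end = integer(),
                 strand = character(), score = numeric())
}

parse_maf_blocks <- function(lines) {
  a_idx <- grep("^a(\\s|$)", lines)
  blocks <- vector("list", length(a_idx))
  for (b in seq_along(a_idx)) {
    i <- a_idx[b]
    srows <- list()
    j <- i + 1L
    while (j <= length(lines) && !grepl("^a(\\s|$)", lines[j])) {
      if (grepl("^s\\s", lines[j]))
        srows[[length(srows) + 1L]] <- strsplit(trimws(lines[j]), "\\s+")[[1]]
      j <- j + 1L
    }
    if (length(srows) != 2L)
      stop("MAF block ", b, " does not have exactly two s lines")
    sc <- sub("^a\\s*(score=([-0-9.eE+]+))?.*$", "\\2", lines[i])
    attrs <- lines[i]
    blocks[[b]] <- list(score = suppressWarnings(as.numeric(sc)),
                        a_line = attrs, s1 = srows[[1]], s2 = srows[[2]],
                        index = b)
  }
  blocks
}

maf_forward_start <- function(start, size, strand, src_size) {
  ifelse(strand == "-", src_size - start - size, start)
}

#' Read a MAF file
#'
#' Pairwise MAF (two DNA rows per block) yields a block tibble; the
#' translated dialect (second row protein) yields an alignment tibble in the
#' same shape as [align_local()] output, with frameshift columns restored.
#' The dialect is detected per file.  Strand-relative MAF starts are
#' converted to forward-strand absolute coordinates.
#'
#' @param path MAF file
#' @return a block tibble or an alignment tibble
#' @export
read_maf <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[!grepl("^#", lines)]
  blocks <- parse_maf_blocks(lines)
  if (length(blocks) == 0L) return(empty_blocks())
  translated <- any(vapply(blocks, function(b) {
    txt <- gsub("-", "", b$s2[7])
    grepl("[^ACGTNacgtn]", txt) || grepl("[\\\\/]", b$s1[7])
  }, logical(1)))
  if (translated) read_maf_translated(blocks) else read_maf_pairwise(blocks)
}

read_maf_pairwise <- function(blocks) {
  rows <- lapply(blocks, function(b) {
    s1 <- b$s1; s2 <- b$s2
    if (nchar(s1[7]) != nchar(s2[7]))
      stop("row-length mismatch in MAF block ", b$index)
    st1 <- as.integer(s1[3]); sz1 <- as.integer(s1[4])
    st2 <- as.integer(s2[3]); sz2 <- as.integer(s2[4])
    f1 <- maf_forward_start(st1, sz1, s1[5], as.integer(s1[6]))
    f2 <- maf_forward_start(st2, sz2, s2[5], as.integer(s2[6]))
    tibble::tibble(
      g1_seq = s1[2], g1_start = f1, g1_end = f1 + sz1,
      g2_seq = s2[2], g2_start = f2, g2_end = f2 + sz2,
      strand = if (s1[5] == s2[5]) "+" else "-",
      score = b$score %||% NA_real_)
  })
  dplyr::bind_rows(rows)
}

read_maf_translated <- function(blocks) {
  rows <- lapply(blocks, function(b) {
    sd <- b$s1; sp <- b$s2
    dtxt <- sd[7]; ptxt <- sp[7]
    cols <- decode_translated_text(dtxt, ptxt, b$index)
    nt_used <- sum(cols$op %in% c("codon_aa", "codon_gap")) * 3L +
      sum(cols$op == "fs+") - sum(cols$op == "fs-")
    aa_used <- sum(cols$op %in% c("codon_aa", "gap_aa"))
    dsz <- as.integer(sd[4]); psz <- as.integer(sp[4])
    if (nt_used != dsz || aa_used != psz)
      stop("row-length mismatch in MAF block ", b$index)
    dstart <- maf_forward_start(as.integer(sd[3]), dsz, sd[5],
                                as.integer(sd[6]))
    ec <- as.numeric(sub(".*e_chrom=([-0-9.eE+]+).*", "\\1", b$a_line))
    eg <- as.numeric(sub(".*e_genome=([-0-9.eE+]+).*", "\\1", b$a_line))
    tibble::tibble(
      dna_id = sd[2], dna_start = dstart, dna_end = dstart + dsz,
      strand = sd[5], prot_id = sp[2],
      prot_start = as.integer(sp[3]), prot_end = as.integer(sp[3]) + psz,
      score = as.integer(b$score), evalue_chrom = ec, evalue_genome = eg,
      aa_identity = aa_identity_columns(cols), columns = list(cols))
  })
  dplyr::bind_rows(rows)
}

decode_translated_text <- function(dtxt, ptxt, block_index) {
  dp <- 1L
  ops <- character(0); codons <- character(0); aas <- character(0)
  for (k in seq_len(nchar(ptxt))) {
    pc <- substr(ptxt, k, k)
    dc <- substr(dtxt, dp, dp)
    if (dc == "\\") {
      ops <- c(ops, "fs+"); codons <- c(codons, substr(dtxt, dp + 1, dp + 1))
      aas <- c(aas, NA); dp <- dp + 2L
      next
    }
    if (dc == "/") {
      ops <- c(ops, "fs-"); codons <- c(codons, NA); aas <- c(aas, NA)
      dp <- dp + 1L
      next
    }
    if (dc == "-") {
      if (substr(dtxt, dp, dp + 2) != "---")
        stop("bad gap column in MAF block ", block_index)
      ops <- c(ops, "gap_aa"); codons <- c(codons, NA); aas <- c(aas, pc)
      dp <- dp + 3L
    } else {
      cod <- substr(dtxt, dp, dp + 2)
      if (nchar(cod) < 3L)
        stop("truncated codon in MAF block ", block_index)
      if (pc == "-") {
        ops <- c(ops, "codon_gap"); codons <- c(codons, cod); aas <- c(aas, NA)
      } else {
        ops <- c(ops, "codon_aa"); codons <- c(codons, cod); aas <- c(aas, pc)
      }
      dp <- dp + 3L
    }
  }
  if (dp != nchar(dtxt) + 1L)
    stop("row-length mismatch in MAF block ", block_index)
  tibble::tibble(op = ops, codon = codons, aa = aas)
}

encode_translated_text <- function(cols) {
  dchunk <- character(nrow(cols)); pchunk <- character(nrow(cols))
  for (k in seq_len(nrow(cols))) {
    op <- cols$op[k]
    if (op == "codon_aa") { dchunk[k] <- cols$codon[k]; pchunk[k] <- cols$aa[k] }
    else if (op == "codon_gap") { dchunk[k] <- cols$codon[k]; pchunk[k] <- "-" }
    else if (op == "gap_aa") { dchunk[k] <- "---"; pchunk[k] <- cols$aa[k] }
    else if (op == "fs+") {
      nt <- if (is.na(cols$codon[k])) "N" else cols$codon[k]
      dchunk[k] <- paste0("\\", nt); pchunk[k] <- ""
    } else { dchunk[k] <- "/"; pchunk[k] <- "" }
  }
  # frameshift columns merge visually with the protein row's next column:
  # the protein row carries '-' for them so both rows stay parseable
  pch <- ifelse(cols$op %in% c("fs+", "fs-"), "-", pchunk)
  list(dna = paste(dchunk, collapse = ""), prot = paste(pch, collapse = ""))
}

#' Write pairwise blocks as MAF
#'
#' When genome tibbles are supplied the s-line texts carry the real
#' sequences (reverse-complemented for `-` blocks); otherwise `N` filler of
#' the right widths is written.  Blocks with unequal side widths get `-`
#' padding so both rows have equal text length.
#'
#' @param blocks block tibble
#' @param path output file
#' @param genome1,genome2 optional sequence tibbles to take row text from
#' @return `path`, invisibly
#' @export
write_maf_blocks <- function(blocks, path, genome1 = NULL, genome2 = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##maf version=1", con, sep = "\n")
  seqlen <- function(g, id) nchar(g$residues[match(id, g$id)])
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    w1 <- b$g1_end - b$g1_start; w2 <- b$g2_end - b$g2_start
    src1 <- if (!is.null(genome1)) seqlen(genome1, b$g1_seq) else b$g1_end
    src2 <- if (!is.null(genome2)) seqlen(genome2, b$g2_seq) else b$g2_end
    t1 <- if (!is.null(genome1))
      toupper(substr(genome1$residues[match(b$g1_seq, genome1$id)],
                     b$g1_start + 1L, b$g1_end))
    else strrep("N", w1)
    t2raw <- if (!is.null(genome2))
      toupper(substr(genome2$residues[match(b$g2_seq, genome2$id)],
                     b$g2_start + 1L, b$g2_end))
    else strrep("N", w2)
    t2 <- if (b$strand == "-") revcomp(t2raw) else t2raw
    W <- max(nchar(t1), nchar(t2))
    t1 <- paste0(t1, strrep("-", W - nchar(t1)))
    t2 <- paste0(t2, strrep("-", W - nchar(t2)))
    st2 <- if (b$strand == "-") src2 - b$g2_end else b$g2_start
    writeLines(c(
      sprintf("a score=%g", b$score),
      sprintf("s %s %d %d + %d %s", b$g1_seq, b$g1_start, w1, src1, t1),
      sprintf("s %s %d %d %s %d %s", b$g2_seq, st2, w2, b$strand, src2, t2),
      ""), con, sep = "\n")
  }
  invisible(path)
}

#' Write translated alignments as MAF
#'
#' @param alignments alignment tibble from [align_local()]
#' @param path output file
#' @param genome optional sequence tibble (for source sizes; otherwise the
#'   alignment end is used)
#' @param protein_lengths optional named vector of protein lengths
#' @return `path`, invisibly
#' @export
write_maf_translated <- function(alignments, path, genome = NULL,
                                 protein_lengths = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##maf version=1", con, sep = "\n")
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    txt <- encode_translated_text(a$columns[[1]])
    src <- if (!is.null(genome)) nchar(genome$residues[match(a$dna_id, genome$id)])
      else a$dna_end
    psz <- if (!is.null(protein_lengths)) protein_lengths[[a$prot_id]]
      else a$prot_end
    dsz <- a$dna_end - a$dna_start
    st <- if (a$strand == "-") src - a$dna_end else a$dna_start
    writeLines(c(
      sprintf("a score=%d e_chrom=%g e_genome=%g", a$score, a$evalue_chrom,
              a$evalue_genome),
      sprintf("s %s %d %d %s %d %s", a$dna_id, st, dsz, a$strand, src,
              txt$dna),
      sprintf("s %s %d %d + %d %s", a$prot_id, a$prot_start,
              a$prot_end - a$prot_start, psz, txt$prot),
      ""), con, sep = "\n")
  }
  invisible(path)
}
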