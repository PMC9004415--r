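# GFF3 gene models: reading via rtracklayer with conversion to 0-based
# half-open tibbles, a hand-rolled writer for simulator output, and the
# CDS-union extraction the coding filters consume.

#' Read protein-coding annotation from GFF3
#'
#' Parses gene/mRNA/exon/CDS features with Parent links.  GFF3 1-based
#' inclusive coordinates become 0-based half-open.  Returns both the CDS
#' intervals merged per (sequence, strand) — what the coding-overlap filters
#' consume — and per-transcript gene models with exon/CDS lists.  A CDS
#' without a parent transcript is kept as an orphan interval with a warning.
#'
#' @param path GFF3 file
#' @return list with `cds` (annotation tibble, class_family `"CDS"`) and
#'   `genes` (tibble: gene_name, accession, seq_id, start, end, strand,
#'   exons, cds list-columns of start/end tibbles)
#' @export
read_cds <- function(path) {
  gr <- rtracklayer::import(path)
  parent <- if (is.null(gr$Parent)) rep(NA_character_, length(gr)) else
    vapply(as.list(gr$Parent), function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1))
  opt <- function(x) if (is.null(x)) rep(NA_character_, length(gr)) else
    as.character(x)
  d <- tibble::tibble(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = opt(gr$ID),
    parent = parent,
    gene = opt(gr$gene),
    name = opt(gr$Name))

  mrna <- dplyr::filter(d, .data$type %in% c("mRNA", "transcript"))
  cds_rows <- dplyr::filter(d, .data$type == "CDS")
  exon_rows <- dplyr::filter(d, .data$type == "exon")
  gene_rows <- dplyr::filter(d, .data$type == "gene")

  orphan <- !(cds_rows$parent %in% mrna$id)
  if (any(orphan))
    warning(sum(orphan), " CDS feature(s) without a parent transcript; ",
            "kept as orphan intervals")

  genes <- dplyr::bind_rows(lapply(seq_len(nrow(mrna)), function(i) {
    m <- mrna[i, ]
    ex <- dplyr::filter(exon_rows, .data$parent == m$id)
    cd <- dplyr::filter(cds_rows, .data$parent == m$id)
    ex <- dplyr::arrange(ex, .data$start)
    g <- dplyr::filter(gene_rows, .data$id == m$parent)
    gene_name <- if (nrow(g) && !is.na(g$gene[1])) g$gene[1]
      else if (!is.na(m$gene)) m$gene
      else if (nrow(g) && !is.na(g$name[1])) g$name[1]
      else m$id
    tibble::tibble(
      gene_name = gene_name,
      accession = if (!is.na(m$name)) m$name else m$id,
      seq_id = m$seq_id, start = m$start, end = m$end, strand = m$strand,
      exons = list(ex[, c("start", "end")]),
      cds = list(cd[, c("start", "end")]))
  }))

  cds_merged <- if (nrow(cds_rows)) {
    dplyr::bind_rows(lapply(
      split(cds_rows, paste(cds_rows$seq_id, cds_rows$strand)),
      function(g) {
        r <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
        tibble::tibble(seq_id = g$seq_id[1],
                       start = IRanges::start(r) - 1L,
                       end = IRanges::end(r), strand = g$strand[1],
                       name = "CDS", class_family = "CDS")
      }))
  } else empty_annotations()
  list(cds = dplyr::arrange(cds_merged, .data$seq_id, .data$start),
       genes = genes)
}

#' Introns of a gene model
#' @param gene one row of the `genes` tibble from [read_cds()]
#' @return tibble of intron start/end (0-based half-open), possibly empty
#' @export
gene_introns <- function(gene) {
  ex <- dplyr::arrange(gene$exons[[1]], .data$start)
  if (nrow(ex) < 2L)
    return(tibble::tibble(start = integer(), end = integer()))
  tibble::tibble(start = ex$end[-nrow(ex)], end = ex$start[-1])
}

#' Write gene models as GFF3 (simulator/fixture writer)
#' @param genes tibble as produced by [read_cds()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- paste0("gene", i)
    mid <- paste0("rna", i)
    row9 <- function(type, s, e, attr)
      sprintf("%s\t.\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$seq_id, type, s + 1L, e, g$strand, attr)
    out <- c(
      row9("gene", g$start, g$end,
           sprintf("ID=%s;gene=%s", gid, g$gene_name)),
      row9("mRNA", g$start, g$end,
           sprintf("ID=%s;Parent=%s;gene=%s;Name=%s", mid, gid,
                   g$gene_name, g$accession)))
    ex <- g$exons[[1]]
    for (k in seq_len(nrow(ex)))
      out <- c(out, row9("exon", ex$start[k], ex$end[k],
                         sprintf("ID=%s.e%d;Parent=%s", mid, k, mid)))
    cd <- g$cds[[1]]
    for (k in seq_len(nrow(cd)))
      out <- c(out, row9("CDS", cd$start[k], cd$end[k],
                         sprintf("ID=%s.c%d;Parent=%s", mid, k, mid)))
    writeLines(out, con, sep = "\n")
  }
  invisible(path)
}
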