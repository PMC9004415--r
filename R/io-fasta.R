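# FASTA reading/writing on the package's sequence tibble, plus the
# stop-symbol augmentation applied to every protein before alignment.

#' Read a FASTA file into a sequence tibble
#'
#' Record order and lowercase (soft-masking) are preserved; CRLF line
#' endings are tolerated.  Duplicate ids and empty sequences are errors.
#'
#' @param path FASTA file
#' @param kind force `"dna"` or `"protein"`; default guesses per record
#' @return a sequence tibble (see [seq_tbl()])
#' @export
read_fasta <- function(path, kind = NULL) {
  stopifnot(file.exists(path))
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not FASTA: ", path)
  id <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  if (any(id == "")) stop("empty FASTA id in ", path)
  if (anyDuplicated(id))
    stop("duplicate FASTA id: ", id[duplicated(id)][1])
  grp <- cumsum(hdr)
  res <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                collapse = "")
  res <- res[match(seq_along(id), as.integer(names(res)))]
  res[is.na(res)] <- ""
  if (any(res == ""))
    stop("empty sequence for id: ", id[res == ""][1])
  seq_tbl(id, unname(res), kind)
}

#' Write a sequence tibble as FASTA
#'
#' Sequences are wrapped at `width` characters (the package's normalized
#' form, so `write_fasta(read_fasta(f))` is byte-identical for normalized
#' input).
#'
#' @param seqs sequence tibble
#' @param path output file
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  check_seq_tbl(seqs)
  con <- file(path, "wb")  # binary: no platform CRLF surprises
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    s <- seqs$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", seqs$id[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Append the stop symbol `*` to proteins
#'
#' Fossil stop codons can then be matched to the protein's terminus.
#' Already-terminated or empty input is an error: augmentation is applied
#' exactly once, never silently repeated.
#'
#' @param proteins sequence tibble of protein records
#' @return the tibble with `*` appended to every sequence
#' @export
append_stop <- function(proteins) {
  check_seq_tbl(proteins, "protein")
  if (any(nchar(proteins$residues) == 0L)) stop("empty protein sequence")
  if (any(grepl("\\*", proteins$residues)))
    stop("protein already contains a stop symbol: ",
         proteins$id[grepl("\\*", proteins$residues)][1])
  dplyr::mutate(proteins, residues = paste0(.data$residues, "*"))
}
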