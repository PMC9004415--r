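# RepeatMasker annotations (.out and UCSC rmsk-table dialects), BED6, and
# the class/family taxonomy helpers.  All coordinates are normalized to
# 0-based half-open on the forward strand at the read boundary.

empty_annotations <- function() {
  tibble::tibble(seq_id = character(), start = integer(), end = integer(),
                 strand = character(), name = character(),
                 class_family = character())
}

#' Parse "class/family" strings
#'
#' @param class_family character vector like `"LINE/CR1"`, `"Unknown"`,
#'   `"CDS"`
#' @return tibble with columns `class` and `family` (`NA` when absent)
#' @export
parse_class_family <- function(class_family) {
  tibble::tibble(
    class = sub("/.*$", "", class_family),
    family = ifelse(grepl("/", class_family),
                    sub("^[^/]*/", "", class_family), NA_character_))
}

#' Read RepeatMasker annotations
#'
#' Supports the classic `.out` layout (3 header lines, whitespace-separated,
#' 1-based inclusive coordinates, strand `C` meaning reverse) and the UCSC
#' rmsk tab table (`genoStart`/`genoEnd`, already 0-based half-open).  Both
#' are normalized to 0-based half-open with strand `+`/`-`.
#'
#' @param path annotation file
#' @param dialect `"out"` or `"rmsk_table"`
#' @return annotation tibble: seq_id, start, end, strand, name, class_family
#' @export
read_repeatmasker <- function(path, dialect = c("out", "rmsk_table")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  if (dialect == "out") {
    body <- lines[-seq_len(min(3L, length(lines)))]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0L) return(empty_annotations())
    recs <- lapply(seq_along(body), function(i) {
      f <- strsplit(trimws(body[i]), "\\s+")[[1]]
      if (length(f) < 11L || is.na(suppressWarnings(as.integer(f[6]))))
        stop("unparseable RepeatMasker .out line ", i + 3L, ": ", body[i])
      tibble::tibble(seq_id = f[5],
                     start = as.integer(f[6]) - 1L,
                     end = as.integer(f[7]),
                     strand = if (f[9] == "C") "-" else "+",
                     name = f[10], class_family = f[11])
    })
    dplyr::bind_rows(recs)
  } else {
    header <- strsplit(lines[1], "\t")[[1]]
    need <- c("genoName", "genoStart", "genoEnd", "strand", "repName",
              "repClass", "repFamily")
    if (!all(need %in% header))
      stop("rmsk table lacks columns: ",
           paste(setdiff(need, header), collapse = ", "))
    body <- lines[-1]
    body <- body[nzchar(body)]
    if (length(body) == 0L) return(empty_annotations())
    recs <- lapply(seq_along(body), function(i) {
      f <- strsplit(body[i], "\t")[[1]]
      if (length(f) != length(header) ||
          is.na(suppressWarnings(as.integer(f[match("genoStart", header)]))))
        stop("unparseable rmsk table line ", i + 1L, ": ", body[i])
      g <- setNames(f, header)
      cf <- if (is.na(g["repFamily"]) || g["repFamily"] %in% c("", g["repClass"]))
        g[["repClass"]] else paste0(g[["repClass"]], "/", g[["repFamily"]])
      tibble::tibble(seq_id = g[["genoName"]],
                     start = as.integer(g[["genoStart"]]),
                     end = as.integer(g[["genoEnd"]]),
                     strand = g[["strand"]],
                     name = g[["repName"]], class_family = cf)
    })
    dplyr::bind_rows(recs)
  }
}

#' Write annotations in a RepeatMasker dialect (fixture/export writer)
#'
#' @param ann annotation tibble
#' @param path output file
#' @param dialect `"out"` or `"rmsk_table"`
#' @return `path`, invisibly
#' @export
write_repeatmasker <- function(ann, path, dialect = c("out", "rmsk_table")) {
  dialect <- match.arg(dialect)
  if (dialect == "out") {
    hdr <- c(
      "   SW  perc perc perc  query     position in query    matching repeat",
      "score  div. del. ins.  sequence  begin end (left)     repeat class/family begin end (left) ID",
      "")
    body <- vapply(seq_len(nrow(ann)), function(i) {
      sprintf("%5d %5.1f %4.1f %4.1f  %s %d %d (0) %s %s %s %d %d (0) %d",
              1000L, 20.0, 1.0, 1.0, ann$seq_id[i], ann$start[i] + 1L,
              ann$end[i], if (ann$strand[i] == "-") "C" else "+",
              ann$name[i], ann$class_family[i], 1L,
              ann$end[i] - ann$start[i], i)
    }, character(1))
    writeLines(c(hdr, body), path)
  } else {
    cf <- parse_class_family(ann$class_family)
    hdr <- paste(c("bin", "swScore", "milliDiv", "milliDel", "milliIns",
                   "genoName", "genoStart", "genoEnd", "genoLeft", "strand",
                   "repName", "repClass", "repFamily", "repStart", "repEnd",
                   "repLeft", "id"), collapse = "\t")
    body <- vapply(seq_len(nrow(ann)), function(i) {
      paste(c(0L, 1000L, 200L, 10L, 10L, ann$seq_id[i], ann$start[i],
              ann$end[i], 0L, ann$strand[i], ann$name[i], cf$class[i],
              ifelse(is.na(cf$family[i]), cf$class[i], cf$family[i]),
              1L, ann$end[i] - ann$start[i], 0L, i), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Read a BED6 file as an annotation tibble
#' @param path BED file (first 6 columns used)
#' @return annotation tibble (BED name in `name`, score dropped,
#'   `class_family` = `"."`)
#' @export
read_bed <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) return(empty_annotations())
  f <- do.call(rbind, strsplit(lines, "\t"))
  tibble::tibble(seq_id = f[, 1], start = as.integer(f[, 2]),
                 end = as.integer(f[, 3]),
                 strand = if (ncol(f) >= 6) f[, 6] else "+",
                 name = if (ncol(f) >= 4) f[, 4] else ".",
                 class_family = ".")
}

#' Write intervals as BED6
#' @param x tibble with seq_id, start, end, strand, name; an optional
#'   `score` column feeds BED column 5 (0 otherwise)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bed <- function(x, path) {
  score <- if ("score" %in% names(x)) as.integer(pmin(1000, x$score)) else
    rep(0L, nrow(x))
  nm <- if ("name" %in% names(x)) x$name else
    if ("protein_id" %in% names(x)) x$protein_id else rep(".", nrow(x))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", x$seq_id, x$start, x$end,
                     nm, score, x$strand), path)
  invisible(path)
}
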