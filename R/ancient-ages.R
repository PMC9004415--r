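# Dating fossils by conservation across genome pairs, classifying unknown
# repeats, long-range split-pair detection ("genome tectonics"), nearest
# genes, and the tabular age report.

#' Build a clade map
#'
#' Orders comparison genomes by the age of the last common ancestor they
#' share with the focal genome, young to old (e.g. Amniote < Tetrapod <
#' Sarcopterygian < Gnathostome).  A fossil conserved in several genomes is
#' dated by the *oldest* label among them.
#'
#' @param genomes character vector of genome names
#' @param age_labels same-length character vector of clade labels
#' @param label_order unique labels, youngest first; defaults to the order
#'   of first appearance in `age_labels`
#' @return a clade-map tibble with attribute `"label_order"`
#' @export
clade_map <- function(genomes, age_labels, label_order = unique(age_labels)) {
  stopifnot(length(genomes) == length(age_labels),
            !anyDuplicated(genomes), all(age_labels %in% label_order))
  out <- tibble::tibble(genome = genomes, age_label = age_labels)
  attr(out, "label_order") <- label_order
  out
}

#' Conservation profile and age of fossil calls
#'
#' For each call and each comparison genome, the covered fraction of the
#' call by the (coding-pruned, link-filtered) alignment blocks to that
#' genome; a call is conserved in a genome when at least `min_frac` of it is
#' covered.  The age is the oldest clade label among conserved genomes, or
#' `"—"` when there is none.
#'
#' @param calls fossil-call tibble (focal-genome coordinates = block g1
#'   side)
#' @param blocks_by_genome named list of block tibbles, one per comparison
#'   genome
#' @param cmap clade map from [clade_map()]
#' @param min_frac conservation threshold (default 0.30, inclusive)
#' @return list with `profile` (long tibble: call, genome,
#'   covered_fraction, conserved) and `ages` (tibble: call, age)
#' @export
conservation_profile <- function(calls, blocks_by_genome, cmap,
                                 min_frac = 0.30) {
  gnames <- names(blocks_by_genome)
  missing <- setdiff(gnames, cmap$genome)
  if (length(missing))
    stop("genome absent from clade map: ", paste(missing, collapse = ", "))
  lab_order <- attr(cmap, "label_order")
  prof <- dplyr::bind_rows(lapply(gnames, function(g) {
    b <- blocks_by_genome[[g]]
    ann <- tibble::tibble(seq_id = b$g1_seq, start = b$g1_start,
                          end = b$g1_end)
    frac <- if (nrow(calls)) coverage_fraction(calls, ann) else numeric(0)
    tibble::tibble(call = seq_len(nrow(calls)), genome = g,
                   covered_fraction = frac,
                   conserved = frac >= min_frac)
  }))
  ages <- vapply(seq_len(nrow(calls)), function(i) {
    cons <- prof$genome[prof$call == i & prof$conserved]
    if (length(cons) == 0L) return("—")
    labs <- cmap$age_label[match(cons, cmap$genome)]
    lab_order[max(match(labs, lab_order))]
  }, character(1))
  list(profile = prof,
       ages = tibble::tibble(call = seq_len(nrow(calls)), age = ages))
}

#' Classify one unknown repeat family by fossil overlap
#'
#' A repeat of unknown type inherits a TE type when its genomic instances
#' have large (>= `min_overlap_bp`) and consistent (>= `min_consistency`
#' agreement over >= `min_instances` qualifying overlaps) overlaps with TE
#' protein fossils of one class/family.
#'
#' @param repeat_name name of the unknown repeat
#' @param instances annotation tibble of that repeat's genomic copies
#' @param fossils fossil-call tibble (TE calls)
#' @param min_overlap_bp minimum overlap to qualify
#' @param min_consistency minimum fraction agreeing on one type
#' @param min_instances minimum number of qualifying overlaps
#' @return one-row tibble: repeat_name, te_type (`NA` = unclassified),
#'   n_overlaps, consistency
#' @export
classify_unknown_repeat <- function(repeat_name, instances, fossils,
                                    min_overlap_bp = 100L,
                                    min_consistency = 0.80,
                                    min_instances = 3L) {
  fam <- call_te_class_family(fossils$source_class)
  te <- fossils[!is.na(fam), , drop = FALSE]
  fam <- fam[!is.na(fam)]
  types <- character(0)
  for (i in seq_len(nrow(instances))) {
    same <- te$seq_id == instances$seq_id[i]
    ovl <- pmin(te$end, instances$end[i]) - pmax(te$start, instances$start[i])
    hit <- same & ovl >= min_overlap_bp
    types <- c(types, fam[hit])
  }
  unclassified <- tibble::tibble(repeat_name = repeat_name,
                                 te_type = NA_character_,
                                 n_overlaps = length(types),
                                 consistency = NA_real_)
  if (length(types) < min_instances) return(unclassified)
  tt <- sort(table(types), decreasing = TRUE)
  consistency <- tt[1] / length(types)
  if (consistency < min_consistency) {
    unclassified$consistency <- unname(consistency)
    return(unclassified)
  }
  tibble::tibble(repeat_name = repeat_name, te_type = names(tt)[1],
                 n_overlaps = length(types),
                 consistency = unname(consistency))
}

#' Classify all unknown repeat families in an annotation set
#' @param rmsk annotation tibble; records with class `"Unknown"` are grouped
#'   by name
#' @param fossils fossil-call tibble
#' @param ... passed to [classify_unknown_repeat()]
#' @return tibble, one row per unknown repeat family
#' @export
classify_unknown_repeats <- function(rmsk, fossils, ...) {
  unk <- rmsk[parse_class_family(rmsk$class_family)$class == "Unknown", ,
              drop = FALSE]
  if (nrow(unk) == 0L)
    return(tibble::tibble(repeat_name = character(), te_type = character(),
                          n_overlaps = integer(), consistency = numeric()))
  dplyr::bind_rows(lapply(split(unk, unk$name), function(g)
    classify_unknown_repeat(g$name[1], g, fossils, ...)))
}

#' Long-range same-type fossil pairs (genome tectonics)
#'
#' All unordered pairs of same-sequence fossil calls of equal TE
#' class/family whose end-to-start separation lies within
#' `[min_sep, max_sep]` — candidate fragments of one ancestral element that
#' drifted apart through younger insertions.
#'
#' @param calls fossil-call tibble
#' @param min_sep,max_sep separation window in bp (default 30 kb – 3 Mb)
#' @return tibble of pairs sorted by separation: seq_id, type, call_a,
#'   call_b, a_start, a_end, b_start, b_end, separation_bp
#' @export
tectonic_pairs <- function(calls, min_sep = 30000L, max_sep = 3000000L) {
  out <- tibble::tibble(seq_id = character(), type = character(),
                        call_a = integer(), call_b = integer(),
                        a_start = integer(), a_end = integer(),
                        b_start = integer(), b_end = integer(),
                        separation_bp = integer())
  fam <- call_te_class_family(calls$source_class)
  idx <- which(!is.na(fam))
  if (length(idx) < 2L) return(out)
  rows <- list()
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (b <= a) next
      i <- idx[a]; j <- idx[b]
      if (calls$seq_id[i] != calls$seq_id[j] || fam[i] != fam[j]) next
      sep <- interval_gap(calls$start[i], calls$end[i],
                          calls$start[j], calls$end[j])
      if (sep < min_sep || sep > max_sep) next
      first_i <- calls$start[i] <= calls$start[j]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seq_id = calls$seq_id[i], type = fam[i],
        call_a = if (first_i) i else j, call_b = if (first_i) j else i,
        a_start = min(calls$start[i], calls$start[j]),
        a_end = if (first_i) calls$end[i] else calls$end[j],
        b_start = if (first_i) calls$start[j] else calls$start[i],
        b_end = max(calls$end[i], calls$end[j]),
        separation_bp = as.integer(sep))
    }
  }
  if (length(rows) == 0L) return(out)
  dplyr::arrange(dplyr::bind_rows(rows), .data$separation_bp)
}

#' Nearest gene and genomic context of fossil calls
#'
#' Genes are first restricted to accessions starting with
#' `accession_filter` (curated protein-coding models).  A call lying wholly
#' inside an intron is `intronic`, reported with that intron's length;
#' otherwise it is `intergenic`, reported with the nearest gene (minimum
#' distance to the gene span, ties to the lower gene start) and the gap
#' between the two flanking gene spans in kb (`NA` when the call has no
#' gene on one side).
#'
#' @param calls fossil-call tibble
#' @param genes gene-model tibble from [read_cds()]
#' @param accession_filter accession prefix to keep
#' @return tibble: nearest_gene, relation, intergene_length_kb,
#'   intron_length_kb (one row per call)
#' @export
nearest_gene <- function(calls, genes, accession_filter = "NM_") {
  g <- genes[startsWith(genes$accession, accession_filter), , drop = FALSE]
  if (nrow(g) == 0L) stop("no genes left after accession filtering")
  out <- lapply(seq_len(nrow(calls)), function(i) {
    cs <- calls$start[i]; ce <- calls$end[i]
    gs <- g[g$seq_id == calls$seq_id[i], , drop = FALSE]
    if (nrow(gs) == 0L)
      return(tibble::tibble(nearest_gene = NA_character_,
                            relation = "intergenic",
                            intergene_length_kb = NA_real_,
                            intron_length_kb = NA_real_))
    # intronic?
    for (k in order(gs$start)) {
      if (gs$start[k] <= cs && ce <= gs$end[k]) {
        intr <- gene_introns(gs[k, ])
        hit <- which(intr$start <= cs & ce <= intr$end)
        if (length(hit)) {
          return(tibble::tibble(
            nearest_gene = gs$gene_name[k], relation = "intronic",
            intergene_length_kb = NA_real_,
            intron_length_kb = round((intr$end[hit[1]] -
                                        intr$start[hit[1]]) / 1000, 1)))
        }
      }
    }
    dist <- pmax(0L, pmax(gs$start - ce, cs - gs$end))
    k <- order(dist, gs$start)[1]
    prev_end <- suppressWarnings(max(gs$end[gs$end <= cs]))
    next_start <- suppressWarnings(min(gs$start[gs$start >= ce]))
    ig <- if (is.finite(prev_end) && is.finite(next_start))
      round((next_start - prev_end) / 1000, 1) else NA_real_
    tibble::tibble(nearest_gene = gs$gene_name[k], relation = "intergenic",
                   intergene_length_kb = ig, intron_length_kb = NA_real_)
  })
  dplyr::bind_rows(out)
}

age_report_columns <- c("type", "aligned_protein", "chromosome", "start",
                        "length_bp", "nearest_gene", "intergene_length_kb",
                        "intron_length_kb", "found_in", "evalue", "age")

#' Tabular fossil-age report
#'
#' One row per call with the reporting columns used for anciently conserved
#' fossils: type, aligned protein, chromosome, 0-based start, length,
#' nearest-gene context, the genome the fossil was found in (provenance),
#' genome-wide E-value, and the conservation age label.
#'
#' @param calls fossil-call tibble
#' @param ages `ages` tibble from [conservation_profile()]
#' @param gene_context optional tibble from [nearest_gene()]
#' @return report tibble in fixed column order
#' @export
age_report <- function(calls, ages, gene_context = NULL) {
  n <- nrow(calls)
  fam <- call_te_class_family(calls$source_class)
  if (is.null(gene_context))
    gene_context <- tibble::tibble(nearest_gene = rep(NA_character_, n),
                                   relation = rep(NA_character_, n),
                                   intergene_length_kb = rep(NA_real_, n),
                                   intron_length_kb = rep(NA_real_, n))
  tibble::tibble(
    type = ifelse(is.na(fam), "host_gene", fam),
    aligned_protein = calls$protein_id,
    chromosome = calls$seq_id,
    start = calls$start,
    length_bp = calls$end - calls$start,
    nearest_gene = gene_context$nearest_gene,
    intergene_length_kb = gene_context$intergene_length_kb,
    intron_length_kb = gene_context$intron_length_kb,
    found_in = calls$provenance,
    evalue = calls$evalue_genome,
    age = if (n) ages$age[match(seq_len(n), ages$call)] else character(0))
}

#' Write / read the age report as TSV
#' @param report report tibble from [age_report()]
#' @param path file path
#' @return `path` invisibly / the report tibble
#' @export
write_age_report <- function(report, path) {
  stopifnot(identical(names(report), age_report_columns))
  con <- file(path, "wb")
  on.exit(close(con))
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  writeLines(paste(age_report_columns, collapse = "\t"), con, sep = "\n")
  if (nrow(report))
    writeLines(do.call(paste, c(lapply(report, fmt), sep = "\t")), con,
               sep = "\n")
  invisible(path)
}

#' @rdname write_age_report
#' @export
read_age_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(lines[1], "\t")[[1]]
  stopifnot(identical(hdr, age_report_columns))
  if (length(lines) == 1L) {
    out <- tibble::tibble(!!!setNames(
      list(character(), character(), character(), integer(), integer(),
           character(), numeric(), numeric(), character(), numeric(),
           character()), age_report_columns))
    return(out)
  }
  f <- strsplit(lines[-1], "\t")
  f <- lapply(f, function(x) c(x, rep("", length(hdr) - length(x))))
  m <- do.call(rbind, f)
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
  tibble::tibble(
    type = m[, 1], aligned_protein = m[, 2], chromosome = m[, 3],
    start = as.integer(m[, 4]), length_bp = as.integer(m[, 5]),
    nearest_gene = ifelse(m[, 6] == "", NA, m[, 6]),
    intergene_length_kb = num(m[, 7]), intron_length_kb = num(m[, 8]),
    found_in = m[, 9], evalue = num(m[, 10]), age = m[, 11])
}

#' Fossil-call track plot along one sequence
#' @param calls fossil-call tibble
#' @param seq_id sequence to draw (default: first)
#' @return a ggplot
#' @export
plot_calls <- function(calls, seq_id = NULL) {
  seq_id <- seq_id %||% calls$seq_id[1]
  d <- dplyr::filter(calls, .data$seq_id == !!seq_id)
  d$class <- ifelse(is.na(call_te_class(d$source_class)), "host_gene",
                    call_te_class(d$source_class))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start / 1000, xend = .data$end / 1000,
      y = .data$class, yend = .data$class, colour = .data$strand),
      linewidth = 3) +
    ggplot2::labs(x = paste(seq_id, "position (kb)"), y = NULL) +
    ggplot2::theme_minimal()
}
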