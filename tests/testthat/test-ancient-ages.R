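vert_cmap <- function() {
  clade_map(c("alligator", "turtle", "frog", "coelacanth", "chimera"),
            c("Amniote", "Amniote", "Tetrapod", "Sarcopterygian",
              "Gnathostome"),
            c("Amniote", "Tetrapod", "Sarcopterygian", "Gnathostome"))
}

one_call <- function(start = 0L, end = 100L, sq = "chr1") {
  x <- random_calls(1)
  x$seq_id <- sq; x$start <- start; x$end <- end; x$strand <- "+"
  x$source_class <- "TE:LINE/CR1"
  x
}

cov_blocks <- function(frac, sq = "chr1", call_w = 100L) {
  w <- as.integer(round(frac * call_w))
  tibble::tibble(g1_seq = sq, g1_start = 0L, g1_end = w,
                 g2_seq = "o1", g2_start = 0L, g2_end = w,
                 strand = "+", score = 1)
}

test_that("conservation is inclusive at 30% and strict below", {
  cmap <- vert_cmap()
  call <- one_call(0L, 1000L)
  p30 <- conservation_profile(call, list(turtle = cov_blocks(0.30, call_w = 1000L)),
                              cmap)
  expect_true(p30$profile$conserved)
  expect_equal(p30$ages$age, "Amniote")
  p299 <- conservation_profile(call,
                               list(turtle = cov_blocks(0.299, call_w = 1000L)),
                               cmap)
  expect_false(p299$profile$conserved)
  expect_equal(p299$ages$age, "—")
})

test_that("the oldest conserved clade wins", {
  cmap <- vert_cmap()
  call <- one_call()
  b <- cov_blocks(0.5)
  p1 <- conservation_profile(call, list(turtle = b), cmap)
  expect_equal(p1$ages$age, "Amniote")
  p2 <- conservation_profile(call, list(turtle = b, chimera = b), cmap)
  expect_equal(p2$ages$age, "Gnathostome")
  expect_error(conservation_profile(call, list(zebrafish = b), cmap),
               "absent from clade map")
})

test_that("age labels are monotone under added conserved genomes", {
  cmap <- vert_cmap()
  ord <- attr(cmap, "label_order")
  set.seed(71)
  for (rep in 1:50) {
    call <- one_call(0L, 500L)
    gset <- sample(cmap$genome, sample(1:4, 1))
    bl <- setNames(lapply(gset, function(g)
      cov_blocks(runif(1), call_w = 500L)), gset)
    a1 <- conservation_profile(call, bl, cmap)$ages$age
    extra <- sample(setdiff(cmap$genome, gset), 1)
    bl2 <- c(bl, setNames(list(cov_blocks(runif(1, 0.3, 1),
                                          call_w = 500L)), extra))
    a2 <- conservation_profile(call, bl2, cmap)$ages$age
    r <- function(a) if (a == "—") 0L else match(a, ord)
    expect_gte(r(a2), r(a1))
  }
})

test_that("unknown repeats classify on large consistent fossil overlap", {
  # the reference behavior: >= 3 instances overlapping >= 100 bp fossils of
  # one family give that family
  inst <- tibble::tibble(seq_id = "chr1",
                         start = c(0L, 1000L, 2000L, 3000L) * 10L,
                         end = c(0L, 1000L, 2000L, 3000L) * 10L + 400L,
                         strand = "+", name = "UCON84-like",
                         class_family = "Unknown")
  fos <- random_calls(4)
  fos$seq_id <- "chr1"
  fos$start <- inst$start + 50L
  fos$end <- inst$start + 350L
  fos$source_class <- "TE:DNA/PIF-Harbinger"
  got <- classify_unknown_repeat("UCON84-like", inst, fos)
  expect_equal(got$te_type, "DNA/PIF-Harbinger")
  # 50/50 split between two types: unclassified
  fos2 <- fos
  fos2$source_class <- rep(c("TE:DNA/PIF-Harbinger", "TE:LINE/CR1"), 2)
  expect_true(is.na(classify_unknown_repeat("u", inst, fos2)$te_type))
  # only 2 qualifying overlaps: unclassified
  expect_true(is.na(classify_unknown_repeat("u", inst[1:2, ], fos)$te_type))
  # sub-threshold overlap widths never qualify
  thin <- dplyr::mutate(fos, end = start + 99L)
  expect_true(is.na(classify_unknown_repeat("u", inst, thin)$te_type))
})

test_that("classification never fires below the consistency threshold", {
  set.seed(72)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    s <- seq(0L, by = 10000L, length.out = n)
    inst <- tibble::tibble(seq_id = "chr1", start = s, end = s + 500L,
                           strand = "+", name = "u", class_family = "Unknown")
    fos <- random_calls(n)
    fos$seq_id <- "chr1"; fos$start <- s; fos$end <- s + 500L
    fos$source_class <- sample(c("TE:LINE/CR1", "TE:LTR/Gypsy"), n,
                               replace = TRUE)
    got <- classify_unknown_repeat("u", inst, fos)
    top <- max(table(sub("^TE:", "", fos$source_class))) / n
    if (top < 0.80) expect_true(is.na(got$te_type))
    else expect_equal(got$te_type,
                      names(which.max(table(sub("^TE:", "",
                                                fos$source_class)))))
  }
})

test_that("tectonic pairs respect the separation window and type equality", {
  calls <- random_calls(2)
  calls$seq_id <- "chr3"
  calls$source_class <- "TE:DNA/Polinton"
  calls$start <- c(0L, 44500L); calls$end <- c(500L, 45000L)
  # 44 kb separation: reported
  tp <- tectonic_pairs(calls)
  expect_equal(nrow(tp), 1L)
  expect_equal(tp$separation_bp, 44000L)
  expect_equal(tp$type, "DNA/Polinton")
  # 29,999 bp: below the window
  calls2 <- dplyr::mutate(calls,
                          start = c(0L, 30499L), end = c(500L, 30999L))
  expect_equal(nrow(tectonic_pairs(calls2)), 0L)
  # exactly 30,000: in
  calls3 <- dplyr::mutate(calls,
                          start = c(0L, 30500L), end = c(500L, 31000L))
  expect_equal(nrow(tectonic_pairs(calls3)), 1L)
  # cross-type: never
  calls4 <- calls
  calls4$source_class <- c("TE:DNA/Polinton", "TE:LINE/CR1")
  expect_equal(nrow(tectonic_pairs(calls4)), 0L)
})

test_that("tectonic pair count matches the O(n^2) oracle on 500 calls", {
  set.seed(73)
  calls <- random_calls(500, n_seq = 2, span = 4000000L, max_w = 600,
                        classes = c("TE:LINE/CR1", "TE:DNA/Polinton",
                                    "TE:LTR/Gypsy", "host_gene"))
  tp <- tectonic_pairs(calls)
  expect_equal(nrow(tp), oracle_tectonic_count(calls))
  expect_true(all(diff(tp$separation_bp) >= 0))
  expect_true(all(tp$separation_bp >= 30000 & tp$separation_bp <= 3e6))
})

test_that("nearest-gene context distinguishes intronic from intergenic", {
  genes <- tibble::tibble(
    gene_name = c("ALPHA", "BETA", "GAMMA"),
    accession = c("NM_1", "NM_2", "XR_3"),
    seq_id = "chr1",
    start = c(1000L, 60000L, 8000L), end = c(21000L, 80000L, 9000L),
    strand = "+",
    exons = list(tibble::tibble(start = c(1000L, 11000L),
                                end = c(2000L, 21000L)),
                 tibble::tibble(start = 60000L, end = 80000L),
                 tibble::tibble(start = 8000L, end = 9000L)),
    cds = list(tibble::tibble(start = 1100L, end = 1900L),
               tibble::tibble(start = 60100L, end = 79900L),
               tibble::tibble(start = 8100L, end = 8900L)))
  # call inside ALPHA's intron (2000..11000)
  g1 <- nearest_gene(one_call(5000L, 5200L), genes)
  expect_equal(g1$relation, "intronic")
  expect_equal(g1$nearest_gene, "ALPHA")
  expect_equal(g1$intron_length_kb, 9.0)
  expect_true(is.na(g1$intergene_length_kb))
  # call between ALPHA and BETA, nearer BETA; XR_ gene at 8-9 kb ignored
  g2 <- nearest_gene(one_call(50000L, 50100L), genes)
  expect_equal(g2$relation, "intergenic")
  expect_equal(g2$nearest_gene, "BETA")
  expect_equal(g2$intergene_length_kb, 39.0)
  # the XR_ gene would be nearest to a call at 8-9 kb, but is filtered out
  g3 <- nearest_gene(one_call(9100L, 9200L), genes)
  expect_equal(g3$nearest_gene, "ALPHA")
  expect_error(nearest_gene(one_call(), genes, accession_filter = "ZZ_"),
               "no genes")
})

test_that("age reports round-trip through their TSV form", {
  # empty report: header only
  empty <- age_report(random_calls(0),
                      tibble::tibble(call = integer(), age = character()))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_age_report(empty, f)
  expect_equal(length(readLines(f)), 1L)
  expect_equal(nrow(read_age_report(f)), 0L)

  set.seed(74)
  calls <- random_calls(30)
  ages <- tibble::tibble(call = 1:30,
                         age = sample(c("Amniote", "Tetrapod", "—"), 30,
                                      replace = TRUE))
  rep1 <- age_report(calls, ages)
  expect_equal(nrow(rep1), 30L)
  write_age_report(rep1, f)
  back <- read_age_report(f)
  expect_equal(back$start, rep1$start)
  expect_equal(back$age, rep1$age)
  expect_equal(back$evalue, rep1$evalue, tolerance = 1e-12)
  expect_equal(back$type, rep1$type)
})
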