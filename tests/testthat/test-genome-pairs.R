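test_that("one-to-one selection drops overlaps on either genome", {
  b <- random_blocks(2)
  b$g1_seq <- "a1"; b$g1_start <- c(0L, 50L); b$g1_end <- c(100L, 150L)
  b$g2_seq <- c("b1", "b2"); b$g2_start <- c(0L, 0L); b$g2_end <- c(100L, 100L)
  b$score <- c(5, 3)
  expect_equal(make_one_to_one(b)$score, 5)
  # overlap only in genome 2: lower-scoring still dropped
  b2 <- b
  b2$g1_seq <- c("a1", "a2")
  b2$g2_seq <- "b1"
  expect_equal(make_one_to_one(b2)$score, 5)
})

test_that("one-to-one matches the O(n^2) oracle and has no double coverage", {
  set.seed(61)
  blocks <- random_blocks(500)
  got <- make_one_to_one(blocks)
  expect_equal(got, oracle_one_to_one(blocks))
  for (sq in unique(got$g1_seq)) {
    g <- got[got$g1_seq == sq, ]
    expect_equal(bitmap_covered(0L, 60000L, g$g1_start, g$g1_end),
                 sum(g$g1_end - g$g1_start))
  }
  for (sq in unique(got$g2_seq)) {
    g <- got[got$g2_seq == sq, ]
    expect_equal(bitmap_covered(0L, 60000L, g$g2_start, g$g2_end),
                 sum(g$g2_end - g$g2_start))
  }
})

test_that("coding pruning is zero-tolerance in either genome", {
  b <- random_blocks(1)
  b$g1_seq <- "a1"; b$g1_start <- 0L; b$g1_end <- 100L
  b$g2_seq <- "b1"; b$g2_start <- 0L; b$g2_end <- 100L
  none <- tibble::tibble(seq_id = character(), start = integer(),
                         end = integer(), strand = character(),
                         name = character(), class_family = character())
  cds2 <- tibble::tibble(seq_id = "b1", start = 99L, end = 200L,
                         strand = "+", name = "CDS", class_family = "CDS")
  expect_equal(nrow(prune_coding(b, none, cds2)), 0L)   # 1 bp in g2 only
  expect_equal(nrow(prune_coding(b, none, none)), 1L)
  set.seed(62)
  blocks <- random_blocks(200)
  cds1 <- random_annotations(20, n_seq = 2)
  cds1$seq_id <- sub("^c", "a", cds1$seq_id)
  kept <- prune_coding(blocks, cds1, none)
  ov <- vapply(seq_len(nrow(blocks)), function(i) {
    a <- cds1[cds1$seq_id == blocks$g1_seq[i], ]
    any(a$start < blocks$g1_end[i] & a$end > blocks$g1_start[i])
  }, logical(1))
  expect_equal(kept, blocks[!ov, ])
})

test_that("link filter retains triads and removes pairs", {
  mk <- function(starts) {
    n <- length(starts)
    tibble::tibble(g1_seq = "a1", g1_start = starts, g1_end = starts + 100L,
                   g2_seq = "b1", g2_start = starts, g2_end = starts + 100L,
                   strand = "+", score = 1)
  }
  three <- mk(c(0L, 5000L, 10000L))
  expect_equal(nrow(link_filter(three)), 3L)
  two <- mk(c(0L, 5000L))
  expect_equal(nrow(link_filter(two)), 0L)
})

test_that("link filter matches brute force, including exact boundaries", {
  set.seed(63)
  for (rep in 1:6) {
    blocks <- random_blocks(200, n_seq = 2, span = 4e6, max_w = 2000)
    got <- link_filter(blocks)
    ref <- oracle_link_filter(blocks)
    expect_equal(got[, names(blocks)], ref)
  }
  # gap exactly 1e6 links; one bp more does not (with a third block close by)
  mk3 <- function(gap) {
    s <- c(0L, 200L, 400L + gap)
    tibble::tibble(g1_seq = "a1", g1_start = s, g1_end = s + 200L,
                   g2_seq = "b1", g2_start = s, g2_end = s + 200L,
                   strand = "+", score = 1)
  }
  expect_equal(nrow(link_filter(mk3(1000000L))), 3L)
  expect_equal(nrow(link_filter(mk3(1000001L))), 0L)
  # exactly 5 intervening blocks still links the far pair; 6 does not.
  # 8 blocks: the outer pair (0, 7) has 6 between -> unlinked, but chains
  # keep everything in one component either way; verify against oracle
  s <- seq(0L, 1400L, by = 200L)
  chain <- tibble::tibble(g1_seq = "a1", g1_start = s, g1_end = s + 100L,
                          g2_seq = "b1", g2_start = s, g2_end = s + 100L,
                          strand = "+", score = 1)
  expect_equal(link_filter(chain)[, names(chain)],
               oracle_link_filter(chain))
  # isolate the between-count rule: 7 blocks where only the outer pair can
  # link in g2 (others are far away in g2); 5 between in g1 -> linked
  g2pos <- c(0L, seq(3e6, 3e6 + 5 * 2e6, by = 2e6)[1:5], 1500L)
  seven <- tibble::tibble(
    g1_seq = "a1", g1_start = seq(0L, 1500L, by = 250L),
    g1_end = seq(0L, 1500L, by = 250L) + 100L,
    g2_seq = "b1", g2_start = g2pos, g2_end = g2pos + 100L,
    strand = "+", score = 1)
  expect_equal(link_filter(seven)[, names(seven)],
               oracle_link_filter(seven))
})

test_that("link filter is monotone under syntenic additions", {
  # a new block that sits consistently in both genomes either links to its
  # neighbours (preserving connectivity when it raises a between-count past
  # the limit) or changes nothing; retained blocks stay retained
  syntenic <- function(n, span = 5e5) {
    s <- sort(sample.int(span, n))
    j <- sample(-200:200, n, replace = TRUE)
    tibble::tibble(g1_seq = "a1", g1_start = s, g1_end = s + 300L,
                   g2_seq = "b1", g2_start = s + j, g2_end = s + j + 300L,
                   strand = "+", score = 1)
  }
  set.seed(64)
  for (rep in 1:10) {
    blocks <- syntenic(40)
    base <- link_filter(blocks)
    extra <- dplyr::bind_rows(blocks, syntenic(1))
    grown <- link_filter(extra)
    key <- function(x) paste(x$g1_start, x$g1_end, x$g2_start)
    expect_true(all(key(base) %in% key(grown)))
  }
})

test_that("interval projection maps through blocks with strand arithmetic", {
  b <- tibble::tibble(g1_seq = "a1", g1_start = 1000L, g1_end = 1400L,
                      g2_seq = "b1", g2_start = 200L, g2_end = 600L,
                      strand = "+", score = 1)
  # wholly inside a '+' block: linear offset
  p <- project_interval(list(seq_id = "b1", start = 300L, end = 350L), b)
  expect_equal(p$start, 1100L)
  expect_equal(p$end, 1150L)
  # '-' block: reversed within the g1 span
  bm <- dplyr::mutate(b, strand = "-")
  pm <- project_interval(list(seq_id = "b1", start = 200L, end = 250L), bm)
  expect_equal(pm$start, 1350L)
  expect_equal(pm$end, 1400L)
  # no overlapping block: none
  expect_equal(nrow(project_interval(list(seq_id = "b1", start = 5000L,
                                          end = 5100L), b)), 0L)
  # blocks on different g1 sequences: none with warning
  b2 <- dplyr::bind_rows(b, dplyr::mutate(b, g1_seq = "a2",
                                          g2_start = 500L, g2_end = 900L))
  expect_warning(
    none <- project_interval(list(seq_id = "b1", start = 300L, end = 700L),
                             b2),
    "multiple")
  expect_equal(nrow(none), 0L)
})

test_that("projecting then back-projecting contains the original", {
  set.seed(65)
  blocks <- random_blocks(40, n_seq = 1, span = 40000, max_w = 800)
  blocks <- make_one_to_one(blocks)
  swap <- tibble::tibble(
    g1_seq = blocks$g2_seq, g1_start = blocks$g2_start,
    g1_end = blocks$g2_end, g2_seq = blocks$g1_seq,
    g2_start = blocks$g1_start, g2_end = blocks$g1_end,
    strand = blocks$strand, score = blocks$score)
  good <- 0L
  for (rep in 1:300) {
    b <- blocks[sample.int(nrow(blocks), 1), ]
    w <- b$g2_end - b$g2_start
    lo <- b$g2_start + sample.int(max(w - 2, 1), 1) - 1L
    hi <- min(b$g2_end, lo + sample.int(w, 1))
    if (hi <= lo) next
    fwd <- project_interval(list(seq_id = b$g2_seq, start = lo, end = hi),
                            blocks)
    if (nrow(fwd) == 0) next
    back <- suppressWarnings(
      project_interval(list(seq_id = fwd$seq_id, start = fwd$start,
                            end = fwd$end), swap))
    if (nrow(back) == 0) next
    expect_lte(back$start, lo)
    expect_gte(back$end, hi)
    good <- good + 1L
  }
  expect_gte(good, 100L)
})
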