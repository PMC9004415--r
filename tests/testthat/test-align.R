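test_that("a perfect reverse-translated fossil aligns exactly", {
  m <- test_model()
  prot <- "MKV*"
  best <- vapply(strsplit(prot, "")[[1]], function(a)
    pf_codons()[which.max(m$subst[, a])], character(1))
  dna <- paste(best, collapse = "")
  al <- align_local(seq_tbl("d", dna), seq_tbl("p", prot, kind = "protein"),
                    m, min_score = 5, mode = "exact")
  al <- al[al$strand == "+", ]
  expect_equal(nrow(al), 1L)
  expect_equal(al$score,
               sum(vapply(strsplit(prot, "")[[1]], function(a)
                 max(m$subst[, a]), numeric(1))))
  expect_equal(al$dna_start, 0L)
  expect_equal(al$dna_end, 12L)
  expect_equal(aa_identity(al), 1.0)
  expect_false(any(al$columns[[1]]$op != "codon_aa"))
})

test_that("a single deleted nucleotide induces exactly one -1 frameshift", {
  m <- test_model()
  expect_lt(m$frameshift, m$gap_open + m$gap_extend)
  prot <- "MKVLAEWH*"
  best <- vapply(strsplit(prot, "")[[1]], function(a)
    pf_codons()[which.max(m$subst[, a])], character(1))
  dna0 <- paste(best, collapse = "")
  dna1 <- paste0(substr(dna0, 1, 13), substr(dna0, 15, nchar(dna0)))
  al <- align_local(seq_tbl("d", dna1), seq_tbl("p", prot, kind = "protein"),
                    m, min_score = 10, mode = "exact")
  al <- al[which.max(al$score), ]
  ops <- al$columns[[1]]$op
  expect_equal(sum(ops == "fs-"), 1L)
  expect_equal(sum(ops == "fs+"), 0L)
  # nucleotide bookkeeping: 3 per codon column, -1 per fs-
  expect_equal(3L * sum(ops %in% c("codon_aa", "codon_gap")) - 1L,
               al$dna_end - al$dna_start)
})

test_that("optimal score equals exhaustive enumeration on random instances", {
  m <- test_model()
  set.seed(301)
  for (rep in 1:60) {
    n <- sample(6:18, 1); pl <- sample(1:5, 1)
    dna <- random_dna_str(n)
    prot <- paste(sample(AA21, pl, TRUE, prob = c(rep(1, 20), 2) / 22),
                  collapse = "")
    ob <- oracle_best_score(dna, prot, m)
    hits <- paleofossil:::pf_dp_align(
      dna, paleofossil:::aa_to_raw(prot), m$subst, m$min_aa_score,
      m$gap_open, m$gap_extend, m$frameshift, 1L, 1L)
    dp <- if (length(hits)) hits[[1]]$score else -Inf
    expect_identical(as.numeric(dp),
                     as.numeric(if (is.finite(ob) && ob >= 1) ob else -Inf),
                     info = paste(dna, prot))
  }
})

test_that("reported scores recompute from their columns under the model", {
  m <- test_model()
  set.seed(302)
  for (rep in 1:25) {
    dna <- random_dna_str(60)
    prot <- random_protein_str(12, with_stop = TRUE)
    al <- align_local(seq_tbl("d", dna),
                      seq_tbl("p", prot, kind = "protein"),
                      m, min_score = 5, mode = "exact")
    for (i in seq_len(nrow(al)))
      expect_equal(paleofossil:::alignment_score(al$columns[[i]], m),
                   al$score[i])
  }
})

test_that("strand symmetry: aligning the reverse complement flips labels", {
  m <- test_model()
  set.seed(303)
  dna <- random_dna_str(300)
  prot <- seq_tbl("p", random_protein_str(25, with_stop = TRUE),
                  kind = "protein")
  a1 <- align_local(seq_tbl("d", dna), prot, m, min_score = 15,
                    mode = "exact")
  a2 <- align_local(seq_tbl("d", revcomp(dna)), prot, m, min_score = 15,
                    mode = "exact")
  ord <- function(x) x[order(x$dna_start, x$strand, x$score), ]
  a1 <- ord(a1); a2 <- ord(a2)
  expect_equal(nrow(a1), nrow(a2))
  L <- nchar(dna)
  expect_equal(sort(a1$score), sort(a2$score))
  expect_equal(sort(a1$evalue_chrom), sort(a2$evalue_chrom))
  # intervals map through x -> L - x with strands flipped
  flip <- tibble::tibble(dna_start = L - a2$dna_end,
                         dna_end = L - a2$dna_start,
                         strand = ifelse(a2$strand == "+", "-", "+"),
                         score = a2$score)
  flip <- flip[order(flip$dna_start, flip$strand, flip$score), ]
  expect_equal(a1$dna_start, flip$dna_start)
  expect_equal(a1$strand, flip$strand)
})

test_that("seeds never start in soft-masked runs but may extend into them", {
  m <- test_model()
  set.seed(304)
  prot <- random_protein_str(40, with_stop = TRUE)
  best <- vapply(strsplit(prot, "")[[1]], function(a)
    pf_codons()[which.max(m$subst[, a])], character(1))
  fossil <- paste(best, collapse = "")
  bg <- random_dna_str(4000)
  dna_plain <- paste0(bg, fossil, random_dna_str(4000))
  pr <- seq_tbl("p", prot, kind = "protein")
  hit <- align_local(seq_tbl("d", dna_plain), pr, m, min_score = 50,
                     mode = "seeded")
  expect_gte(nrow(hit), 1L)
  # fully lowercased fossil: no seeds can start, so no alignment
  dna_masked <- paste0(bg, tolower(fossil), random_dna_str(4000))
  miss <- align_local(seq_tbl("d", dna_masked), pr, m, min_score = 50,
                      mode = "seeded")
  expect_equal(nrow(miss), 0L)
  # masking only the left half: seeding happens on the open half and the
  # alignment extends into the masked run
  half <- nchar(fossil) %/% 2
  dna_half <- paste0(bg, tolower(substr(fossil, 1, half)),
                     substr(fossil, half + 1, nchar(fossil)),
                     random_dna_str(4000))
  part <- align_local(seq_tbl("d", dna_half), pr, m, min_score = 50,
                      mode = "seeded")
  expect_gte(nrow(part), 1L)
  expect_lt(min(part$dna_start), 4000 + half)
})

test_that("hard-masking soft-masked runs can only lower scores", {
  m <- test_model()
  set.seed(305)
  prot <- seq_tbl("p", random_protein_str(30, with_stop = TRUE),
                  kind = "protein")
  best <- vapply(strsplit(prot$residues, "")[[1]], function(a)
    pf_codons()[which.max(m$subst[, a])], character(1))
  fossil <- paste(best, collapse = "")
  soft <- paste0(random_dna_str(2000),
                 substr(fossil, 1, 45), tolower(substr(fossil, 46, 90)),
                 random_dna_str(2000))
  hard <- gsub("[acgt]", "N", soft)
  a_soft <- align_local(seq_tbl("d", soft), prot, m, min_score = 30,
                        mode = "seeded")
  a_hard <- align_local(seq_tbl("d", hard), prot, m, min_score = 30,
                        mode = "seeded")
  expect_lte(max(c(a_hard$score, 0)), max(c(a_soft$score, 0)))
})

test_that("amino-acid identity counts only codon/aa columns", {
  m <- test_model()
  prot <- "MKW*"
  best <- vapply(strsplit(prot, "")[[1]], function(a)
    pf_codons()[which.max(m$subst[, a])], character(1))
  al <- align_local(seq_tbl("d", paste(best, collapse = "")),
                    seq_tbl("p", prot, kind = "protein"), m,
                    min_score = 5, mode = "exact")
  al <- al[al$strand == "+", ]
  expect_equal(aa_identity(al), 1.0)
  # all-mismatch columns give identity 0
  cols <- tibble::tibble(op = rep("codon_aa", 3),
                         codon = c("GCA", "GCA", "GCA"),
                         aa = c("W", "K", "M"))
  expect_equal(paleofossil:::aa_identity_columns(cols), 0.0)
  expect_error(paleofossil:::aa_identity_columns(
    tibble::tibble(op = "gap_aa", codon = NA, aa = "K")),
    "no codon")
  # recount oracle over simulated alignments
  set.seed(306)
  for (rep in 1:300) {
    k <- sample(1:20, 1)
    ops <- sample(c("codon_aa", "codon_gap", "gap_aa"), k, TRUE,
                  prob = c(0.7, 0.15, 0.15))
    if (!any(ops == "codon_aa")) ops[1] <- "codon_aa"
    codon <- ifelse(ops == "gap_aa", NA,
                    vapply(seq_len(k), function(i)
                      paste(sample(c("A", "C", "G", "T"), 3, TRUE),
                            collapse = ""), character(1)))
    aa <- ifelse(ops == "codon_gap", NA, sample(AA21, k, TRUE))
    cols <- tibble::tibble(op = ops, codon = codon, aa = aa)
    cc <- cols[cols$op == "codon_aa", ]
    gc_map <- Biostrings::GENETIC_CODE
    naive <- mean(unname(gc_map[cc$codon]) == cc$aa)
    expect_equal(paleofossil:::aa_identity_columns(cols), naive)
  }
})

test_that("reverse_decoy reverses without complementing and involutes", {
  g <- seq_tbl("chr1", "ACGT")
  d <- reverse_decoy(g)
  expect_equal(d$residues, "TGCA")
  expect_equal(d$id, "chr1_rev")
  dd <- reverse_decoy(d)
  expect_equal(dd$residues, "ACGT")
  expect_equal(dd$id, "chr1")  # the suffix toggles: decoy of decoy = original
})

test_that("disruption statistics flag frameshifts and premature stops", {
  clean <- tibble::tibble(op = "codon_aa", codon = "ATG", aa = "M")
  stopc <- tibble::tibble(op = c("codon_aa", "codon_aa"),
                          codon = c("TAA", "ATG"), aa = c("K", "M"))
  fsal <- tibble::tibble(op = c("codon_aa", "fs+", "codon_aa"),
                         codon = c("ATG", "A", "ATG"),
                         aa = c("M", NA, "M"))
  stop_ok <- tibble::tibble(op = "codon_aa", codon = "TAA", aa = "*")
  al <- tibble::tibble(columns = list(clean, stopc, fsal, stop_ok))
  st <- disruption_stats(al)
  expect_equal(st$n, 4L)
  expect_equal(st$n_disrupted, 2L)  # TAA-vs-K and the frameshift; TAA-vs-* is fine
  expect_equal(st$frac_disrupted, 0.5)
  empty <- disruption_stats(al[0, ])
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$frac_disrupted))
})

test_that("disruption fraction tracks the planting rate on simulated fossils", {
  # young (well-aligning) fossils so nearly every planted frameshift/stop
  # is inside a reported alignment; 1,000 plantings
  m <- test_model()
  set.seed(308)
  cfg <- sim_config(seed = 308, target_aa_identity = 0.7)
  n <- 1000
  truth_dis <- logical(n); obs_dis <- logical(n)
  for (i in seq_len(n)) {
    prot <- seq_tbl("p", random_protein_str(150), kind = "protein")
    fos <- paleofossil:::make_fossil_seq(prot$residues, cfg)
    truth_dis[i] <- fos$disrupted
    dna <- paste0(random_dna_str(300), fos$seq, random_dna_str(300))
    al <- align_local(seq_tbl("d", dna), append_stop(prot), m,
                      min_score = 40, mode = "exact")
    obs_dis[i] <- nrow(al) > 0 && disruption_stats(al)$n_disrupted > 0
  }
  expect_lt(abs(mean(obs_dis) - mean(truth_dis)), 0.02)
})

test_that("entropy masking lowercases simple sequence", {
  s <- paste0(random_dna_str(100), strrep("AT", 30), random_dna_str(100))
  set.seed(307)
  masked <- mask_simple(seq_tbl("d", s), window = 20, min_bits = 1.0)
  mid <- substr(masked$residues, 111, 150)
  expect_true(grepl("^[acgt]+$", mid))
  expect_true(grepl("[ACGT]", substr(masked$residues, 1, 80)))
})
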