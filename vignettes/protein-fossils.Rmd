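---
title: "Finding and dating protein fossils: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding and dating protein fossils: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the alignment and significance model, the filter chain, the dating
procedure, the synthetic data that exercises all of it, and the decisions
taken where the design was genuinely open.

## The problem

A protein fossil is a genomic segment descended from protein-coding DNA
that no longer codes: a decayed transposable-element (TE) gene or a dead
host-gene copy. Old fossils have drifted far below the detection range of
DNA-to-DNA comparison, and even protein-level search is hampered because a
fossil evolves *without* amino-acid constraint — it accumulates frameshifts
and premature stop codons that standard protein aligners treat as fatal.
The package therefore detects fossils with an aligner in which frameshifts
and stop codons are ordinary, scoreable events, and then dates them by
conservation across genome pairs under an orthology filter that is robust
to the pitfalls of TE biology.

## Alignment model

### Scoring

Alignments are scored under a 64 × 21 integer matrix indexed by codon and
amino acid (the 20 residues plus the stop symbol `*`, which is appended to
every library protein so that fossil stop codons at the protein's terminus
can be matched). Scores are log-odds,

\[ s(c, a) = \mathrm{round}\left(t \cdot \ln \frac{P(c,a)}{p_c\,q_a}\right), \]

with temperature `scale_t` (default 3 score units per nat). A codon-level
matrix is strictly richer than a 20 × 20 amino-acid matrix: it can prefer
`AAC`→`N` alignments over `TCA`→`N`, reflecting which codons mutate into
which.

The default matrix (`default_model()`) mixes an identity component with
BLOSUM62-derived substitution probabilities: with probability `pid`
(default 0.5, the identity regime the pipeline targets) the fossil codon
still encodes the aligned residue, spread over synonymous codons;
otherwise the encoded residue is drawn from the BLOSUM62 conditional.
Stop codons pair strongly with `*` and weakly with residues, so premature
stops inside a fossil cost a little but do not break an alignment.
`model_from_counts()` builds a matrix from observed column counts, and
`train_model()` closes the loop in simplified one-pass form: align with a
starting model, keep alignments with amino-acid identity ≤ `pid_max`
(focusing the fit on old fossils, not recent paralogs), recount, refit.
Externally trained parameter files are read verbatim by `read_model()`.

### Gaps and frameshifts

A gap of length $L$ costs `gap_open + L·gap_extend` (defaults 14 + 4·L,
derived from event frequencies by the same log-odds rule). A frameshift is
its own column type, permitted only between codon columns, costing
`frameshift` (default 17) and shifting the reading frame by +1 nt (one
nucleotide skipped) or −1 nt (the next codon re-uses a nucleotide). The
default cost ordering `frameshift < gap_open + gap_extend` means a single
deleted nucleotide is explained by one `fs−` column rather than a spurious
gap pair; this ordering is asserted in the tests. Local alignments start
and end with a codon column, so frameshifts are never terminal and
end-gaps are never reported.

Degenerate input: a codon containing `N` scores the *minimum* over all 64
codons for the aligned residue — ambiguity can only hurt a score, never
help it, which makes hard-masking monotone (a tested invariant).

### Exact and seeded search

Small problems are solved by exact dynamic programming over three state
matrices (codon column, residue-gap, codon-gap), with deterministic
traceback preferences (match from match, then from either gap state, then
fresh start, then frameshifts) and deterministic best-cell tie-breaks.
The DP optimum is pinned, exactly, to a brute-force enumeration oracle on
hundreds of random small instances.

Genome-scale searches use seed-and-extend: exact 4-residue matches between
the DNA's codon-wise translation and the protein library, gapless X-drop
extension, and exact DP in a window around seeds whose extension score
reaches `seed_gate` (default 40). Seeds never start inside soft-masked
(lowercase) runs, though alignments may extend into them — the
simple-sequence contract; `mask_simple()` provides a dinucleotide-entropy
masking pass (windows of 20 nt under 1.0 bit) for unmasked input. Multiple
alignments per window are found greedily: best first, then best in the
remaining DNA on each side, so reported alignments never share DNA within
one (protein, strand) search.

### Significance

E-values take the Karlin–Altschul form
$E = K \cdot m \cdot n \cdot e^{-\lambda S}$ per chromosome, rescaled
genome-wide by `genome_len / chrom_len`. The matrix-implied λ (solved by
root-finding from the ungapped model) ignores gaps, frameshifts and the
seeding heuristic, so `calibrate_evalue()` instead fits λ and K by Gumbel
moment matching on the optimal *reported* scores of the actual seeded
search over random sequences drawn from the model backgrounds. Calibrating
the search that is run — heuristics included — makes the E-value the
expected number of *reported* chance hits, which is what a significance
threshold speaks about. The default threshold is one expected false hit
per 10⁹ bp of searched DNA (`max_evalue_per_Gbp = 1`). The calibration is
validated two ways: reversed-(not complemented)-genome decoys, which keep
composition and repeat structure but destroy real homology, produce hit
counts within a factor of three of the E-value expectation across 20
replicates.

## The filter chain

`run_find()` applies, in order and with logged in/out counts:

1. **Exapted-name exclusion** — TE protein libraries contain proteins of
   host genes that were exapted *from* TEs; hits to them are true
   homologies but not fossils. Entries whose names contain any of the
   configurable marker substrings (`_HSgene`, `_Hsa_`, `UN-GIN`,
   `_Xtr_eg_tp`) are dropped before alignment.
2. **Significance filter** at the genome-wide E-value cutoff.
3. **Strongest-overlap retention** — where homologies overlap in the
   genome, only the strongest is kept (greedy by score; ties by lower
   E-value, lower start, protein id). Overlap is strand-agnostic: one
   locus gets one best explanation. The output is provably overlap-free
   and matches a quadratic reference implementation on random inputs.
4. **Coding removal** — calls strictly more than 10% covered by the union
   of CDS intervals are removed (exactly 10% is kept; the boundary is
   pinned in tests). Coverage is per-base over the interval union, never
   double-counted, and strand-agnostic (a fossil's overlap with coding
   DNA does not depend on the annotation's strand).
5. **Host-vs-TE removal** — host-gene calls more than 10% covered by
   RepeatMasker records other than `Low_complexity` and `Simple_repeat`
   are removed: they are usually real homologies to TE-derived coding
   exons, which are not fossils. TE calls pass untouched.

The chain is idempotent — re-running the filters changes nothing — and
only ever removes calls.

Novelty classification is strand-*specific*, as befits questions about
particular insertions: the census rule (novel iff ≤10% covered by
same-strand annotations of known class/family; `Unknown` records do not
count), the strict rule (not new iff a single same-strand same-class base
overlaps), and the pseudogene rule (novel iff ≤10% same-strand pseudogene
coverage).

## Dating by linked orthologous context

Raw pairwise genome alignments are reduced in three steps.

1. `make_one_to_one()`: greedy best-first selection so that every base of
   either genome is covered at most once — one-to-one, most-similar
   alignments enrich for orthology.
2. `prune_coding()`: zero tolerance — one base of CDS overlap in either
   genome removes a block. Alignments overshoot near conserved coding
   exons, and overshoot is exactly what fakes fossil conservation.
3. `link_filter()`: two blocks are linked iff, in *both* genomes, they lie
   on the same sequence, at most `max_gap` (10⁶) bp apart, with at most
   `max_between` (5) other blocks strictly between them (by midpoint order
   on that sequence); blocks are retained iff their connected component
   has more than `min_links` (2) other members. The literal all-pairs
   reading is implemented (and checked against a brute-force graph
   construction, including the boundary cases of a gap of exactly 10⁶ and
   exactly five intervening blocks); the production path only enumerates
   rank-adjacent candidates, which is equivalent because linking bounds
   the rank distance.

Why linkage? Two genomes can each acquire an *independent* insertion of
the same TE family at homologous loci. The two inserts are genuine
homologs — all copies of a family share ancestry — but the *insertions*
are not, and a naive overlap test would date the insertion to the genomes'
common ancestor. An isolated high-identity alignment with no alignable
flanking context within a megabase is exactly this signature, and the
filter removes it. Strand is deliberately **not** required to match for
linking: small inversions inside conserved blocks are real.

A fossil is **conserved** in a genome when at least 30% of it is covered
by the surviving blocks (inclusive at 30.0%, tested at 29.9% vs 30.0%),
and its age is the *oldest* clade label among conserving genomes under a
user-supplied `clade_map()` (e.g. Amniote < Tetrapod < Sarcopterygian <
Gnathostome), `"—"` when none. Age assignment is monotone: adding a
conserved genome can only keep or increase an age.

Additional results machinery:

* `classify_unknown_repeat()` — a repeat family of unknown type inherits a
  TE type when ≥3 of its instances overlap TE protein fossils by ≥100 bp
  and ≥80% of those overlaps agree on one class/family. The thresholds
  are config keys; they quantify "large and consistent" in the absence of
  published numbers, and the reference behaviour (a PIF/Harbinger-derived
  unknown repeat) is a test case.
* `tectonic_pairs()` — all unordered same-sequence pairs of equal TE
  class/family separated end-to-start by 30–3,000 kb. End-to-start (gap)
  rather than midpoint distance is used because "drifted apart" describes
  the intervening sequence. Host-gene calls carry no TE type and do not
  pair.
* `nearest_gene()` — genes restricted to curated (`NM_`) accessions; a
  call wholly inside an intron is reported with that intron's length,
  otherwise the nearest gene span wins (ties to the lower start) and the
  flanking-gene gap is reported in kb.

## The synthetic study

`simulate_world()` builds a two-genome world with full ground truth; its
defaults *are* the study conditions used by the end-to-end tests and the
acceptance script:

* a ~1 Mb root genome over 4 chromosomes (plus one small scaffold per
  trap insertion), G+C 0.41;
* a library of 20 TE proteins (10 class/families), 6 host proteins and 3
  exapted-named entries, lengths ~N(220, 60) truncated at 100 residues —
  TE polyproteins and transposases run to hundreds of residues, and the
  exclusion stage needs named victims;
* 50 ancestral fossils planted in the root and 50 lineage-specific
  fossils per descendant, decayed to a target amino-acid identity of 0.5
  by codon-usage-biased reverse translation plus BLOSUM62-conditional
  residue substitution, with Poisson(0.7) frameshifts and Poisson(0.55)
  premature stops per fossil (≈71% disrupted, matching the disruption
  rates reported for real host-gene fossil sets) placed in the middle
  10–90% so local alignment can see them, and whole-codon indels at 0.01
  per codon;
* per-lineage divergence: substitutions at 0.08/bp (0.02 inside conserved
  segments and genes), small indels at 5 × 10⁻⁴/bp outside conserved
  segments and genes, a few background-segment inversions in lineage B;
* conserved segments: each ancestral fossil is itself conserved
  (exaptation is the reason it is findable at all) and flanked by four
  100–300 bp conserved elements within link distance, plus 120 scattered
  background segments — the linkage scaffold;
* **traps**: independent decays of one TE family inserted at the same
  root coordinate of both lineages, each on its own scaffold with no
  conserved segments, plus a deceptive alignment block between the two
  copies in the emitted MAF (a real aligner would produce it, since the
  copies are homologous sequences). The dating stage must reject these:
  each deceptive block is alone on its scaffold pair, so the link filter
  removes it. Placing each trap on its own scaffold realizes "no
  alignable flanking context"; several traps on one small scaffold would
  link *each other*, which is not a failure of the filter but a different
  (and at this scale unrealistic) scenario.
* **splits**: 5 ancestral TE fossils from the upper length quartile are
  interrupted in lineage A by a 30–80 kb random insertion near their
  middle, producing same-family pairs the tectonic scan must report.
  Long elements are chosen because both halves must remain independently
  detectable — which is also the realistic regime, since observed drifted
  pairs come from large elements.

Event bookkeeping is root-anchored: every lineage change is an insertion
or deletion in ancestor coordinates, so true orthologous blocks, fossil
intervals and gene models in each genome fall out of the same piece table
that materializes the sequences, and everything round-trips through the
emitted FASTA/GFF3/RepeatMasker/MAF files byte-deterministically per seed.

What the simulation does *not* emulate: real TE sequence models (fossils
are reverse-translations of random proteins, so there are no family
consensus structures, no terminal repeats, no nested real-family
insertions), alignment noise in the inter-genome MAF (true blocks are
emitted, so dating errors measure the filters, not an aligner),
population processes, or genome-scale repeat density. Passing the
end-to-end tests therefore demonstrates the correctness and calibration
of the pipeline's logic under its stated model, not performance parity on
real vertebrate genomes.

**Recovery convention.** A planted fossil counts as recovered when calls
cover at least 30% of its interval — the same coverage convention the
conservation test uses. Old fossils are legitimately reported as several
fragment calls (local alignment breaks at heavily decayed stretches, and
a frameshift column is only worth paying for when both sides support it),
so single-call overlap would misclassify genuinely detected fossils as
missed.

## Numerical and reproducibility choices

* Integer scores throughout the DP; all coordinates 0-based half-open on
  the forward strand internally, converted at every I/O boundary (1-based
  inclusive RepeatMasker `.out` and GFF3; strand-relative MAF starts).
* Deterministic tie-breaks everywhere a greedy order could be ambiguous:
  calls by (score, E-value, start, protein id); blocks by (score, g1
  position, g2 position); DP traceback by fixed transition preference.
* One integer seed determines every simulator byte; pipeline runs write a
  timestamp-free manifest (config hash, input checksums, stage counts) so
  identical inputs yield byte-identical outputs — asserted in the tests.
* E-value calibration uses 60 replicates of a 50 kb random search; the
  end-to-end study uses two ~1 Mb genomes; decoy validation uses 20
  replicates of 100 kb. These sizes keep the full test suite and the
  acceptance script within a few minutes on one CPU while leaving every
  statistical check comfortable margins.

## Open decisions and limitations

* The multi-genome clade map is exercised with constructed block sets in
  the tests; the simulator itself builds a two-taxon world (labels
  `old`/`—`). Chaining the evolver into a four-genome phylogeny was
  considered and deliberately not built: nested branch-sharing of
  insertion events adds substantial machinery while the dating logic it
  would exercise (oldest-conserved-clade selection, monotonicity) is
  fully covered by direct construction.
* The linked-alignment filter is monotone under *syntenic* additions (a
  consistently placed new block either links to its neighbours or changes
  nothing). An adversarial non-syntenic block can break an existing link
  by raising a between-count without substituting connectivity; the tests
  pin the syntenic property.
* The one-pass trainer is a fixed-point simplification of full iterative
  maximum-likelihood fitting; with alignments held fixed the two agree,
  and externally trained parameter files are accepted for exact parity.
* `-1`-frameshift columns re-use one nucleotide of the previous codon;
  the re-read nucleotide is scored as part of the new codon. Other
  conventions (scoring the 2-nt codon against a reduced alphabet) exist;
  this one keeps the DP exact and the column algebra simple
  (3 nt per codon column, ±1 per frameshift).
* Seeded search trades sensitivity for speed below the significance
  threshold; its retention is folded into the calibrated K, so E-values
  remain honest, but scores just above `seed_gate` are found less often
  than exact DP would find them. Searches under ~20 kb default to exact
  DP.
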