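# paleofossil

Genomes are littered with *protein fossils*: fragments of formerly
protein-coding DNA, mostly from transposable elements (TEs) and decayed host
genes. The older a fossil, the more substitutions, insertions, deletions,
frameshifts and premature stop codons separate it from its source protein —
and the harder it is to find with tools tuned for living proteins.
`paleofossil` implements a fossil-hunting pipeline for people who study TE
evolution, exaptation and ancient conserved elements:

* **frameshift-aware local DNA-to-protein alignment** under a 64 × 21
  codon-to-amino-acid log-odds model (a codon can prefer one synonymous
  codon of a residue over another), with affine gaps and ±1-nucleotide
  frameshifts *inside* matches;
* **significance** in Karlin–Altschul form, `E = K·m·n·e^(−λS)`, with λ and
  K calibrated against the search actually run, per-chromosome E-values
  rescaled genome-wide, and a reversed-(not complemented)-genome decoy as
  the false-positive control;
* the **fossil-call filter chain**: exclusion of exapted proteins by name,
  strongest-overlap retention, removal of calls >10% covered by coding
  annotation, and removal of host-gene calls mostly covered by annotated TE;
* **orthology-aware dating**: pairwise genome alignments reduced to
  one-to-one blocks, pruned of coding overlap, and passed through a
  *linked-alignment filter* (a block is kept only if linked — within 1 Mb
  and at most 5 intervening blocks, in both genomes — directly or
  indirectly to at least two others). A fossil is conserved in a genome
  when ≥30% of it is covered by the surviving blocks; its age is the
  oldest clade among conserving genomes. The linkage rule defeats the
  classic trap of independent insertions of one TE family into homologous
  loci of two genomes;
* **unknown-repeat classification** by large, consistent overlap with TE
  protein fossils; **genome tectonics** (same-type fossil pairs 30–3,000 kb
  apart, candidate fragments of one drifted element); nearest-gene context;
* a **synthetic-genome simulator** that plants decayed fossils with known
  ground truth (ancestral, lineage-specific, trap, and split fossils) in a
  two-genome world, so the whole pipeline is testable without downloads.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on the scoring model, `autoplot()` / `plot_*()` for figures.

## Worked example

```r
library(paleofossil)

# a small simulated study: two descendant genomes with planted fossils
world <- simulate_world(sim_config(seed = 7, genome_length = 3e5,
                                   n_ancestral_fossils = 15,
                                   n_lineage_fossils = 15, n_chrom = 3,
                                   n_conserved_background = 40,
                                   n_split_fossils = 2,
                                   split_gap_range = c(30000, 50000),
                                   n_trap_insertions = 2, n_genes = 8))
paths <- emit(world, "simout")

set.seed(11)
model <- calibrate_evalue(default_model())
calls <- run_find(world$genomes$A, world$proteins, model,
                  cds = read_cds(paths["gffA"])$cds,
                  rmsk = read_repeatmasker(paths["rmskA"], "out"),
                  verbose = TRUE)
#> proteins: 29 in, 26 after exapted-name exclusion
#> alignments: 35 raw, 35 at E_genome <= 0.000393
#> calls: 35 after overlap, 34 after coding, 34 after host-vs-TE

ages <- run_ages(calls, list(B = read_maf(paths["maf"])),
                 clade_map("B", "old"),
                 cds1 = read_cds(paths["gffA"])$cds,
                 cds2_by_genome = list(B = read_cds(paths["gffB"])$cds),
                 rmsk = read_repeatmasker(paths["rmskA"], "out"))
ages$unknown_repeats
#> # A tibble: 1 × 4
#>   repeat_name te_type      n_overlaps consistency
#>   <chr>       <chr>             <int>       <dbl>
#> 1 UNK-1       DNA/hAT-Tag1          4           1
```

The run recovered all 13 planted ancestral fossils with age `"old"`, dated
every lineage-specific fossil `"—"` (no conservation), rejected both trap
insertions, and classified the planted unknown repeat `UNK-1` to its true
family. `ages$report` is the tabular age report (type, aligned protein,
coordinates, nearest gene, E-value, age); `ages$tectonic` lists same-type
pairs in the 30 kb – 3 Mb window.

A thin command-line front end ships in `exec/`:

```sh
paleofossil simulate --seed 7 --out simout
paleofossil ages --genome simout/genomeA.fa --proteins simout/proteins.fa \
    --maf simout/A_B.maf --gff simout/genomeA.gff3 \
    --gff2 simout/genomeB.gff3 --rmsk simout/genomeA.rmsk.out --out results
```

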