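---
title: "Methods: plastid genome structure, diversity and repeat analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastid genome structure, diversity and repeat analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastome)
```

This vignette documents the models, algorithms and numerical choices behind
each analysis in the package. The running example throughout is the built-in
synthetic plastome, a 33 kb genome with a known construction ledger:

```{r}
gen <- generate_synthetic_plastome(seed = 42)
rec <- gen$record
rec
```

# The genome model

A `genome_record` is a circular DNA sequence plus a list of features
(gene/CDS/tRNA/rRNA/...). Internally all coordinates are **0-based,
half-open** and may describe intervals that span the origin; the GenBank
reader and writer convert to and from 1-based inclusive coordinates at the
file boundary. A feature holds a `parts` table (start, end, strand, part id):
one row per contiguous piece, where a single exon that crosses the origin is
stored as two rows sharing one logical `part` id. Pieces are kept in
*biological* (transcript) order, so `extract_feature_sequence()` simply
extracts each piece, reverse-complements minus-strand pieces, and
concatenates.

`rotate_circular()` remaps every feature modulo the genome length, and
rotation followed by the inverse rotation is exactly the identity — the test
suite relies on this to show that every downstream analysis is
rotation-invariant.

The GenBank parser is hand-written because no package available in this
environment parses local flat files with full feature location grammar
(`complement(join(...))`, origin-spanning intervals). The writer emits a
fixed `01-JAN-2024` date so output is byte-stable; reading a written file and
writing it again reproduces the file exactly.

# Quadripartite structure detection

Plastomes are organized as LSC–IRb–SSC–IRa, where the two IR arms are exact
(or near-exact) reverse complements. `find_inverted_repeats()` finds the
longest pair of exact inverted repeats by seed-and-extend:

1. Probe windows of length `seed_length/2` are sampled every `seed_length/2`
   bases around the circle. This is the key numerical choice: with windows
   of length *w* sampled at stride *w*, every arm of length ≥ `2w =
   seed_length` must contain one fully aligned probe, so detection of arms at
   or above `seed_length` is a guarantee, not a heuristic. (Sampling windows
   of length `seed_length` at stride `seed_length/2` — the more obvious
   construction — does *not* give this guarantee for arms of exactly
   `seed_length`.)
2. Each probe is matched against the reverse complement of the whole
   sequence (via `Biostrings::matchPattern` on the sequence plus a wrapped
   prefix, to cover origin-spanning arms).
3. Each seed pair is extended to maximal exact arms by block-doubling
   comparison, with anti-diagonal bookkeeping so that all seeds of one
   repeat are extended only once.

The default `seed_length = 1000` reflects the canonical plastid IR
(typically 15–30 kb); 1000 bp is small enough to catch highly reduced IRs
and large enough that random 33–160 kb sequences have essentially zero
probability of a spurious hit. Of the two single-copy gaps between the arms,
the longer is labeled LSC and the shorter SSC; the arm following the LSC in
cyclic order is IRb.

**Orientation conventions.** `adjust_sequence()` normalizes a genome so that
comparisons across records are meaningful:

* `"LSC"` rotates so the LSC begins at position 0;
* `"SSC"` additionally reverse-complements the SSC span in place when it is
  not "forward". SSC-forward is operationalized as: the strand of *ndhF*
  (or, absent *ndhF*, the majority strand of genes whose midpoint falls in
  the SSC) is minus — the common plastome convention;
* `"RP"` reverse-complements the whole genome first, then rotates.

All modes remap feature coordinates, and re-running detection on adjusted
output reproduces identical region lengths (tested over 20 random
rotations/orientations).

```{r}
st <- find_inverted_repeats(rec$seq)
st
classify_regions(st, rec)[c("starts_at_LSC", "ssc_forward")]
```

# Nucleotide diversity

`extract_regions()` decomposes an annotated genome into genes (spliced,
strand-resolved) and intergenic spacers (gaps between consecutive gene spans
in circular order, named `geneA-geneB`). `collect_shared_regions()` keeps
regions present **exactly once in every record** — IR-duplicated genes such
as the rRNAs drop out here, matching the single-copy restriction used in
sliding-window diversity studies.

`compute_pi()` implements Nei–Li nucleotide diversity: the mean per-site
pairwise difference, `sum(d_ij) / (choose(n,2) * L')`. Columns containing a
gap or `N` are excluded entirely by default (*complete deletion*, the DnaSP
default, which makes π comparable across pairs); `deletion = "pairwise"`
instead drops such sites per pair, which uses more data but lets different
pairs be measured on different site sets. Both are exposed because published
π values differ depending on this choice.

`pi_pipeline()` is the batch driver: read a directory of GenBank files,
normalize each to LSC orientation (records whose IR has been eroded below
the exact-match seed — for example heavily mutated simulations — are kept
as-is rather than failing the batch), collect shared regions, align each
region via an external command template (`"mafft --auto {in} > {out}"`)
when lengths differ, and report per-region π ordered by genomic midpoint.

# Codon usage

`collect_cds_for_rscu()` applies the usual hygiene filters before codon
counting: duplicate gene names (IR copies) are counted once, and CDS shorter
than 300 bp, out of frame, or not starting with ATG are dropped (short or
RNA-edited genes distort codon statistics). `compute_rscu()` then pools
codons over all retained CDS, trims each terminal stop codon, and computes
`RSCU(c) = x_c / (family_total / family_size)` under translation table 11
(bacterial/plastid). Stop codons are excluded from the table; the
single-codon families ATG and TGG have RSCU 1 by construction. A conserved
invariant — Σ RSCU over a synonym family equals the family size — is
enforced to 1e-9 in the tests.

# Repeat detection

**SSRs.** `find_ssrs()` reports perfect tandem repeats of 1–6 bp motifs
using MISA-style minimum unit counts (10/6/5/4/4/4 for mono- through
hexanucleotides). The implementation builds, for each period *k*, the match
vector `s[i] == s[i+k]` and run-length encodes it; a maximal period-*k* run
of total length *R* holds `R %/% k` whole units. Two disambiguation rules
keep the output canonical: a run whose unit has a smaller period is reported
only under the smaller period (so `(AT)8` is a dinucleotide repeat, never a
tetranucleotide), and motifs are canonicalized to the lexicographic minimum
over rotations of the motif and of its reverse complement. `N` never
matches.

**Long repeats.** `find_lsrs()` finds maximal exact repeat pairs of the four
REPuter classes — forward, palindromic (reverse complement), reverse, and
complement — with arms ≥ `min_arm` (default 30 bp, the REPuter default used
in plastome papers). Seeds are exact `min_arm`-mers found by hashing; query
k-mers for the non-forward classes are taken from transformed copies of the
whole sequence, so seed lookup stays linear. Seeds on one (anti-)diagonal
are clustered and extended once per cluster. Geometry conventions: forward
and complement arms may overlap (tandem duplications), while palindromic and
reverse arms are kept disjoint — a hairpin with no loop yields abutting
arms, and a symmetric center is clipped to `run_length %/% 2`. Both
detectors are validated against exhaustive brute-force oracles (full
diagonal/anti-diagonal scans) in the acceptance tests.

`locate_context()` classifies any interval by its midpoint as exon, intron,
or IGS (priority exon > intron > IGS), naming the gene or the flanking gene
pair:

```{r}
find_ssrs_record(rec)
```

# Phylogenetic matrix preparation

`extract_shared_cds()` collects genes present single-copy (after
deduplicating byte-identical IR copies) in every record, optionally
translated to protein with table 11; genes with divergent IR copies or, in
protein mode, internal stops, are dropped with a warning rather than
silently included. `concatenate_matrix()` concatenates per-gene alignments
in alphabetical order and returns a 1-based partition table;
`write_supermatrix()` emits FASTA, relaxed PHYLIP and a RAxML-style
partition file. Alignment and tree inference are deliberately delegated to
external programs.

# Format conversion

`to_tbl()` writes NCBI 5-column feature tables (1-based; minus strand as
start > stop; qualifiers restricted to gene/product/codon_start/
transl_table). `to_mvista()` writes the mVISTA annotation dialect, labeling
tRNA/rRNA parts `utr` since mVISTA has no RNA class. `to_fasta()` wraps at
70 columns.

# The synthetic generator

`generate_synthetic_plastome()` builds study genomes with a known truth
ledger: a quadripartite layout (`small`: 20 kb LSC / 2.5 kb IR / 8 kb SSC;
`plastome-like`: 86/25/18 kb), nine named genes placed at equal gaps
(including an intron-bearing *atpF* and a minus-strand *ndhF* in the SSC),
one SSR of each motif length planted in distinct contexts, one 40 bp forward
repeat pair, and IRa as the exact reverse complement of IRb with mirrored
*rrn16* annotation.

Because random background sequence can spontaneously contain repeats, the
generator *rejection-samples*: it regenerates (up to 1000 attempts, then
errors) until the package's own detectors reproduce the planted plan
exactly — every SSR, the forward repeat pair, and the IR boundaries.
Junction bases and repeat flanks are fixed to non-matching bases so planted
elements cannot extend past their intended coordinates. All randomness
derives from the single `seed` argument. `generate_population()` adds
independent point substitutions at a per-site rate (scalar, or per region)
with annotations carried over — no indels, so populations remain
alignment-free for π testing. Expected pairwise difference between two
genomes mutated at rate *p* is `2p(1-p) + (2/3)p²`, which the tests recover
within 3 Monte-Carlo standard errors.

What the generator does **not** emulate: realistic gene content (a real
plastome has ~130 genes), base composition gradients, indels,
rearrangements, or codon-level selection. It is a correctness instrument,
not an evolutionary simulator.

# Problem sizes and runtime

All algorithms are run in the tests on 33 kb genomes (structure detection on
154 kb completes in ~3 s; SSR and long-repeat scans are linear and take well
under a second at 33 kb). The brute-force oracles used for validation are
quadratic and are applied to ≤ 5 kb inputs.

# Limitations

* IR detection requires *exact* arm identity; genomes whose IRs differ by
  even one substitution report the longest exact sub-arm. This is by design
  (it makes the guarantee testable) but differs from aligner-based boundary
  tools that tolerate mismatches.
* π is computed from substitutions only; alignment columns with gaps are
  handled by deletion, not by indel models.
* The GenBank parser covers the feature-location grammar used in plastome
  records (`join`, `complement`, origin-spanning spans); it is not a full
  INSDC parser (no external references or fuzzy `<`/`>` positions).
* mVISTA export flattens RNA genes to `utr` blocks, as the format requires.
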