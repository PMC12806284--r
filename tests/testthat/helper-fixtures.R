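# Shared fixtures, built in code. The synthetic plastome is expensive enough
# to be worth caching across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture_plastome <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- plastome::generate_synthetic_plastome(seed = 42L)
  }
  .fixture_cache$small
}

# A tiny hand-built annotated circle for coordinate arithmetic tests.
# 60 bp, two plus-strand genes and one minus-strand gene.
tiny_record <- function() {
  seq <- paste0("ATGAAATAA",          # geneA CDS 0..9 (+)
                "CCCCC",              # IGS 9..14
                "ATGTTTTGA",          # geneB CDS 14..23 (+)
                "GGGGG",              # IGS 23..28
                strrep("ACGT", 8))    # filler 28..60
  fa <- function(kind, name, start, end, strand) {
    plastome::feature_annotation(kind, name,
      data.frame(start = start, end = end, strand = strand, part = 1L))
  }
  plastome::genome_record("tiny", seq, list(
    fa("gene", "geneA", 0L, 9L, "+"), fa("CDS", "geneA", 0L, 9L, "+"),
    fa("gene", "geneB", 14L, 23L, "+"), fa("CDS", "geneB", 14L, 23L, "+"),
    fa("gene", "geneC", 30L, 54L, "-"), fa("CDS", "geneC", 30L, 54L, "-")))
}

# One CDS-bearing record from a raw coding sequence laid at a given offset.
cds_record <- function(cds_seq, strand = "+", pad = 10L, name = "g1") {
  L <- pad + nchar(cds_seq) + pad
  ins <- if (strand == "+") cds_seq else plastome::revcomp(cds_seq)
  seq <- paste0(strrep("C", pad), ins, strrep("G", pad))
  parts <- data.frame(start = pad, end = pad + nchar(cds_seq),
                      strand = strand, part = 1L)
  plastome::genome_record("toy", seq, list(
    plastome::feature_annotation("gene", name, parts),
    plastome::feature_annotation("CDS", name, parts)))
}

# Quadripartite raw sequence with planted exact IR arms and junction bases
# fixed so the arms are not extendable past the construction joints.
planted_ir_seq <- function(lsc, ir, ssc) {
  block <- function(n) paste0("A", random_seq(n - 2L), "A")
  irb <- random_seq(ir)
  paste0(block(lsc), irb, block(ssc), plastome::revcomp(irb))
}
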