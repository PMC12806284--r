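test_that("pi matches hand-computed values on small alignments", {
  # pairs: (AAAA,AAAT)=1, (AAAA,AATT)=2, (AAAT,AATT)=1 -> 4 / (3 pairs * 4 bp)
  r <- compute_pi(c("AAAA", "AAAT", "AATT"))
  expect_equal(r$pi, 1 / 3)
  expect_equal(r$var_sites, 2L)
  expect_equal(r$sites_used, 4L)
  expect_equal(compute_pi(c("ACGT", "ACGT"))$pi, 0)
  # two sequences: pi is just the per-site difference fraction
  expect_equal(compute_pi(c("AAAAAAAAAA", "AATAAAATAA"))$pi, 0.2)
})

test_that("complete and pairwise deletion treat gap columns differently", {
  aln <- c("AAA", "A-A", "AAT")
  comp <- compute_pi(aln, deletion = "complete")
  expect_equal(comp$sites_used, 2L)     # middle column dropped for everyone
  expect_equal(comp$pi, 1 / 3)          # 2 diffs / (3 pairs * 2 sites)
  pw <- compute_pi(aln, deletion = "pairwise")
  expect_equal(pw$pi, (0 / 2 + 1 / 3 + 1 / 2) / 3)   # per-pair site counts
  # N is treated like a gap
  expect_equal(compute_pi(c("ANA", "AAA"))$sites_used, 2L)
})

test_that("pi input validation", {
  expect_error(compute_pi("ACGT"), "at least 2")
  expect_error(compute_pi(c("ACGT", "ACG")), "unequal")
  expect_error(compute_pi(c("----", "AAAA")), "no ungapped")
})

test_that("region extraction finds genes and the intergenic spacers between them", {
  reg <- extract_regions(tiny_record())
  genes <- reg[reg$kind == "gene", ]
  igs <- reg[reg$kind == "IGS", ]
  expect_equal(genes$name, c("geneA", "geneB", "geneC"))
  expect_equal(genes$seq[genes$name == "geneA"], "ATGAAATAA")
  # minus-strand gene comes out reverse-complemented
  rec <- tiny_record()
  expect_equal(genes$seq[genes$name == "geneC"],
               revcomp(substr(rec$seq, 31, 54)))
  expect_equal(igs$name, c("geneA-geneB", "geneB-geneC", "geneC-geneA"))
  expect_equal(igs$seq[igs$name == "geneA-geneB"], "CCCCC")
  expect_equal(igs$start, c(9, 23, 54))
  expect_equal(igs$length, c(5, 7, 6))  # geneC-geneA wraps the origin
  expect_equal(igs$seq[igs$name == "geneC-geneA"],
               paste0(substr(rec$seq, 55, 60)))
})

test_that("region extraction is rotation invariant", {
  rec <- tiny_record()
  ref <- extract_regions(rec)
  ref <- ref[order(ref$name), c("name", "kind", "length", "seq")]
  for (off in c(5L, 20L, 47L)) {
    got <- extract_regions(rotate_circular(rec, off))
    got <- got[order(got$name), c("name", "kind", "length", "seq")]
    rownames(ref) <- rownames(got) <- NULL
    expect_equal(got, ref)
  }
})

test_that("overlapping genes produce no IGS between them", {
  fa <- function(kind, name, start, end, strand) {
    feature_annotation(kind, name,
      data.frame(start = start, end = end, strand = strand, part = 1L))
  }
  rec <- genome_record("ov", strrep("ACGT", 15), list(
    fa("gene", "g1", 0L, 20L, "+"), fa("gene", "g2", 10L, 30L, "+"),
    fa("gene", "g3", 40L, 50L, "+")))
  reg <- extract_regions(rec)
  expect_false("g1-g2" %in% reg$name)
  expect_true(all(c("g2-g3", "g3-g1") %in% reg$name))
})

test_that("shared regions are single-copy everywhere and ordered by position", {
  g <- fixture_plastome()
  pop <- generate_population(g$record, n = 3, rates = 0.005, seed = 7L)
  shared <- collect_shared_regions(pop)
  nms <- names(shared)
  # rrn16 occurs twice (IR copies) and is excluded; its flanking IGS survive
  expect_false("rrn16" %in% nms)
  expect_true(all(c("psbA", "matK", "atpF", "rbcL", "ndhF", "ccsA",
                    "trnH-GUG", "petB") %in% nms))
  expect_true("trnH-GUG-psbA" %in% nms)
  mids <- vapply(shared, attr, numeric(1), "midpoint")
  expect_true(all(diff(mids) > 0))
  for (s in shared) {
    expect_equal(names(s), vapply(pop, `[[`, character(1), "id"))
    expect_equal(length(unique(nchar(s))), 1L)  # substitutions only
  }
})

test_that("the pi pipeline recovers a single planted substitution", {
  g <- fixture_plastome()
  rec <- g$record
  # plant one substitution in the middle of rbcL (a plus-strand LSC gene)
  rb <- g$ledger$genes[g$ledger$genes$name == "rbcL", ]
  pos <- as.integer((rb$start + rb$end) %/% 2)
  mut <- rec
  old <- substr(mut$seq, pos + 1L, pos + 1L)
  substr(mut$seq, pos + 1L, pos + 1L) <- setdiff(c("A", "C", "G", "T"), old)[1]
  mut$id <- "mutant"
  dir <- withr::local_tempdir()
  write_genbank(rec, file.path(dir, "base.gb"))
  write_genbank(mut, file.path(dir, "mutant.gb"))
  out_dir <- file.path(dir, "regions")
  res <- pi_pipeline(dir, out_dir = out_dir)
  expect_true(all(c("region", "kind", "n", "aln_len", "var_sites", "pi") %in%
                    names(res)))
  expect_true(all(res$n == 2L))
  hit <- res[res$region == "rbcL", ]
  expect_equal(hit$var_sites, 1L)
  expect_equal(hit$pi, 1 / hit$aln_len)
  expect_true(all(res$pi[res$region != "rbcL"] == 0))
  expect_true(all(diff(res$midpoint) > 0))
  # per-region FASTA files were written and re-read as pre-aligned input
  expect_true(file.exists(file.path(out_dir, "rbcL.fasta")))
  res2 <- pi_pipeline(out_dir, pre_aligned = TRUE)
  expect_equal(res2$pi[res2$region == "rbcL"], hit$pi)
})

test_that("mean pipeline pi tracks the simulated substitution rate", {
  g <- fixture_plastome()
  pop <- generate_population(g$record, n = 4, rates = 0.01, seed = 99L)
  dir <- withr::local_tempdir()
  for (r in pop) write_genbank(r, file.path(dir, paste0(r$id, ".gb")))
  res <- pi_pipeline(dir)
  # expected pairwise difference when each copy mutates independently at
  # p = 0.01: 2p(1-p) + (2/3)p^2 ~= 0.0199
  w <- weighted.mean(res$pi, res$aln_len)
  expect_gt(w, 0.012)
  expect_lt(w, 0.028)
})
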