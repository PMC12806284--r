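test_that("a minimal hand-written GenBank file parses into the expected model", {
  seq <- paste(rep("acgtacgtac", 12), collapse = "")  # 120 bp
  gb <- c(
    "LOCUS       demo                 120 bp    DNA     circular PLN 01-JAN-2024",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "                     /organism=\"test\"",
    "     CDS             11..100",
    "                     /gene=\"xyz\"",
    "ORIGIN",
    sprintf("%9d %s", seq(1, 120, 60),
            vapply(seq(1, 120, 60), function(p) {
              paste(substring(seq, seq(p, p + 50, 10), seq(p + 9, p + 59, 10)),
                    collapse = " ")
            }, character(1))),
    "//")
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, tf)
  rec <- read_genbank(tf)
  expect_equal(rec$length, 120L)
  expect_true(rec$circular)
  expect_equal(length(rec$features), 1L)
  f <- rec$features[[1]]
  expect_equal(f$kind, "CDS")
  expect_equal(f$name, "xyz")
  expect_equal(f$parts$start, 10L)   # 1-based 11..100 -> 0-based [10, 100)
  expect_equal(f$parts$end, 100L)
  expect_equal(nchar(extract_feature_sequence(rec, f)), 90L)
})

test_that("complement(join()) locations carry minus strand in biological order", {
  gb <- c(
    "LOCUS       demo2                60 bp    DNA     circular PLN 01-JAN-2024",
    "FEATURES             Location/Qualifiers",
    "     CDS             complement(join(11..20,31..40))",
    "                     /gene=\"rev\"",
    "ORIGIN",
    sprintf("%9d %s", 1, paste(substring(strrep("acgtgtgtac", 6),
                                         seq(1, 51, 10), seq(10, 60, 10)),
                               collapse = " ")),
    "//")
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, tf)
  rec <- read_genbank(tf)
  f <- rec$features[[1]]
  expect_equal(f$parts$strand, c("-", "-"))
  # biological order: the downstream interval comes first on the minus strand
  expect_equal(f$parts$start, c(30L, 10L))
  expect_equal(f$parts$end, c(40L, 20L))
  # manual coordinate arithmetic on the fixture sequence
  manual <- revcomp(paste0(substr(rec$seq, 11, 20), substr(rec$seq, 31, 40)))
  expect_identical(extract_feature_sequence(rec, f), manual)
})

test_that("the synthetic generator output round-trips through GenBank I/O", {
  g <- fixture_plastome()
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g$record, tf)
  back <- read_genbank(tf)
  expect_identical(back$seq, g$record$seq)
  expect_identical(back$id, g$record$id)
  expect_equal(length(back$features), length(g$record$features))
  for (i in seq_along(back$features)) {
    a <- g$record$features[[i]]
    b <- back$features[[i]]
    expect_identical(b$kind, a$kind)
    expect_identical(b$name, a$name)
    expect_identical(b$parts[, c("start", "end", "strand")],
                     a$parts[, c("start", "end", "strand")])
  }
})

test_that("FASTA reading normalizes case and U, rejects duplicates and junk", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt"), tf)
  expect_identical(read_fasta(tf), c(x = "ACGT"))
  writeLines(c(">w", "ACGUA", "CGU"), tf)
  expect_identical(unname(read_fasta(tf)), "ACGTACGT")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), tf)
  expect_error(read_fasta(tf), "duplicate")
  writeLines(c(">b", "ACXT"), tf)
  expect_error(read_fasta(tf), "non-IUPAC")
  writeLines(character(), tf)
  expect_error(read_fasta(tf), "empty")
})

test_that("FASTA writing wraps at 70 columns and round-trips", {
  tf <- withr::local_tempfile(fileext = ".fa")
  s <- strrep("ACGTA", 30)   # 150 bp
  write_fasta(c(`id with spaces` = s), tf)
  lines <- readLines(tf)
  expect_equal(lines[1], ">id with spaces")
  expect_equal(nchar(lines[2:4]), c(70L, 70L, 10L))
  expect_identical(read_fasta(tf)[["id with spaces"]], s)
})

test_that("feature extraction follows strand and part order", {
  rec <- genome_record("r", "AACGTTAA")
  plus <- feature_annotation("gene", "p",
    data.frame(start = 2L, end = 6L, strand = "+", part = 1L))
  minus <- feature_annotation("gene", "m",
    data.frame(start = 2L, end = 6L, strand = "-", part = 1L))
  expect_identical(extract_feature_sequence(rec, plus), "CGTT")
  expect_identical(extract_feature_sequence(rec, minus), "AACG")
  outside <- feature_annotation("gene", "o",
    data.frame(start = 2L, end = 6L, strand = "+", part = 1L))
  outside$parts$end <- 99L
  expect_error(extract_feature_sequence(rec, outside), "outside")
})

test_that("rotation is the identity at 0, inverts, and preserves extraction", {
  rec <- tiny_record()
  expect_identical(rotate_circular(rec, 0L), rec)
  k <- 17L
  back <- rotate_circular(rotate_circular(rec, k), rec$length - k)
  expect_identical(back$seq, rec$seq)
  expect_equal(lapply(back$features, `[[`, "parts"),
               lapply(rec$features, `[[`, "parts"))
  ref <- lapply(rec$features, function(f) extract_feature_sequence(rec, f))
  names(ref) <- vapply(rec$features, function(f) paste(f$kind, f$name), "")
  set.seed(11)
  for (off in sample.int(rec$length - 1L, 100, replace = TRUE)) {
    rot <- rotate_circular(rec, off)
    got <- lapply(rot$features, function(f) extract_feature_sequence(rot, f))
    names(got) <- vapply(rot$features, function(f) paste(f$kind, f$name), "")
    expect_identical(got[sort(names(got))], ref[sort(names(ref))])
  }
  expect_error(rotate_circular(rec, rec$length), "offset")
})

test_that("reverse complement is an involution", {
  set.seed(3)
  for (s in replicate(20, random_seq(sample(1:200, 1)))) {
    expect_identical(revcomp(revcomp(s)), s)
  }
  expect_identical(revcomp("ACGTN"), "NACGT")
})

test_that("origin-spanning features extract the contiguous circular window", {
  rec <- tiny_record()
  # rotate so geneB (14..23) spans the origin
  rot <- rotate_circular(rec, 18L)
  f <- Filter(function(x) x$kind == "CDS" && x$name == "geneB", rot$features)[[1]]
  expect_equal(nrow(f$parts), 2L)
  expect_equal(length(unique(f$parts$part)), 1L)   # one logical part, split
  orig <- Filter(function(x) x$kind == "CDS" && x$name == "geneB",
                 rec$features)[[1]]
  expect_identical(extract_feature_sequence(rot, f),
                   extract_feature_sequence(rec, orig))
})
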