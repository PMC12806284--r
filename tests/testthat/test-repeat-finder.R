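test_that("canonical motifs minimize over rotations and reverse complement", {
  expect_equal(canonical_motif("A"), "A")
  expect_equal(canonical_motif("T"), "A")        # revcomp rotation
  expect_equal(canonical_motif("TTA"), "AAT")
  expect_equal(canonical_motif("GGC"), "CCG")
  expect_equal(canonical_motif("GA"), "AG")
  expect_error(canonical_motif("ATAT"), "smaller period")
  expect_error(canonical_motif("AAAAAAA"), "length")
  expect_error(canonical_motif("ANA"), "ACGT")
})

test_that("SSR detection respects thresholds, maximality and coordinates", {
  pad <- "GCTAGCTGAC"   # repeat-free padding
  # exactly at threshold: reported; one unit short: not
  expect_equal(nrow(find_ssrs(paste0(pad, strrep("A", 10), "C", pad))), 1L)
  expect_equal(nrow(find_ssrs(paste0(pad, strrep("A", 9), "C", pad))), 0L)
  hit <- find_ssrs(paste0(pad, strrep("AT", 7), "GG", pad))
  expect_equal(hit$motif, "AT")
  expect_equal(hit$unit, "AT")
  expect_equal(hit$motif_length, 2L)
  expect_equal(hit$count, 7L)
  expect_equal(hit$start, 10L)           # 0-based, after the 10 bp pad
  expect_equal(hit$end, 24L)
  # whole units only: a trailing partial unit is not counted
  hit <- find_ssrs(paste0(pad, strrep("ACG", 5), "AT", pad))
  expect_equal(hit$count, 5L)
  expect_equal(hit$end - hit$start, 15L)
})

test_that("SSR smallest-period rule and N handling", {
  pad <- "GCTAGCTGAC"
  # (AT)x8 is a run under period 2 and under period 4; only the 2-mer reports
  hits <- find_ssrs(paste0(pad, strrep("AT", 8), "GG", pad))
  expect_equal(hits$motif_length, 2L)
  # N splits a run: neither half reaches the mono threshold
  expect_equal(nrow(find_ssrs(paste0(pad, "AAAAANAAAAA", pad))), 0L)
  # a long poly-A containing no N at the ends
  hits <- find_ssrs(paste0(strrep("A", 12), "C", pad))
  expect_equal(hits$start, 0L)
  expect_equal(hits$count, 12L)
})

test_that("fixture SSRs match the generator ledger, including contexts", {
  g <- fixture_plastome()
  got <- find_ssrs_record(g$record)
  led <- g$ledger$ssrs
  rownames(got) <- rownames(led) <- NULL
  expect_equal(got[names(led)], led)
  expect_equal(got$context[got$motif == "AGC"], "intron")
  expect_equal(got$context_name[got$motif == "AGC"], "atpF")
  expect_equal(got$context_name[got$unit == "C"], "ndhF-ccsA")
})

test_that("locate_context prioritizes exon over intron over IGS", {
  g <- fixture_plastome()
  rec <- g$record
  genes <- g$ledger$genes
  rb <- genes[genes$name == "rbcL", ]
  expect_equal(locate_context(c(rb$start + 10, rb$start + 20), rec),
               list(context = "exon", name = "rbcL"))
  # atpF has one intron; a point between its exons is intronic
  atpf <- Filter(function(f) f$kind == "CDS" && identical(f$name, "atpF"),
                 rec$features)[[1]]
  iv <- atpf$parts[order(atpf$parts$start), ]
  mid <- (iv$end[1] + iv$start[2]) %/% 2
  expect_equal(locate_context(c(mid, mid + 1), rec),
               list(context = "intron", name = "atpF"))
  # unannotated record falls through to an unnamed IGS
  bare <- genome_record("bare", strrep("ACGT", 30))
  expect_equal(locate_context(c(5, 10), bare),
               list(context = "IGS", name = NA_character_))
})

test_that("each LSR type is found with exact arms on planted sequences", {
  set.seed(201)
  arm <- random_seq(50L)
  # flank bases chosen per type so the planted arms cannot extend past them
  mk <- function(second, l1, r1, l2, r2) {
    paste0(random_seq(100L), l1, arm, r1, random_seq(150L), l2, second, r2,
           random_seq(100L))
  }
  cases <- list(
    forward = list(arm, "C", "G", "T", "A"),
    palindromic = list(revcomp(arm), "A", "A", "A", "A"),
    reverse = list(plastome:::string_reverse(arm), "C", "G", "T", "A"),
    complement = list(plastome:::complement_str(arm), "A", "A", "A", "A"))
  for (type in names(cases)) {
    s <- do.call(mk, cases[[type]])
    hits <- find_lsrs(s, min_arm = 30L, types = type)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$type, type)
    expect_equal(hits$length, 50L)
    expect_equal(hits$start1, 101L)
    expect_equal(hits$start2, 303L)
  }
  # arm of exactly min_arm is still reported
  s <- do.call(mk, cases$forward)
  expect_equal(find_lsrs(s, min_arm = 50L, types = "forward")$length, 50L)
  expect_equal(nrow(find_lsrs(s, min_arm = 51L, types = "forward")), 0L)
})

test_that("tandem forward repeats may overlap; palindromic arms never do", {
  set.seed(202)
  # first and last unit bases fixed so the 'A' flanks block extension
  u <- paste0("C", random_seq(38L), "G")
  # tandem duplication: forward arms at offset 40 overlap over 40 bp runs
  s <- paste0("A", random_seq(60L), "A", strrep(u, 3), "A", random_seq(60L), "A")
  f <- find_lsrs(s, min_arm = 40L, types = "forward")
  # two maximal pairs: units 1+2 vs 2+3 (overlapping arms) and unit 1 vs 3
  expect_equal(nrow(f), 2L)
  expect_equal(f$length[f$start2 - f$start1 == 40L], 80L)
  expect_equal(f$length[f$start2 - f$start1 == 80L], 40L)
  # perfect hairpin with no loop: arms abut but do not overlap
  h <- paste0("A", random_seq(60L), "A", u, revcomp(u), "A", random_seq(60L), "A")
  p <- find_lsrs(h, min_arm = 30L, types = "palindromic")
  expect_equal(nrow(p), 1L)
  expect_equal(p$length, 40L)
  expect_equal(p$end1, p$start2)
})

test_that("LSR finder agrees with the exhaustive oracle on random sequences", {
  set.seed(203)
  norm <- function(d) {
    d <- d[order(d$type, d$start1, d$start2, d$length), ]
    rownames(d) <- NULL
    d
  }
  for (rep in 1:6) {
    n <- sample(300:900, 1)
    # low-complexity alphabet makes spontaneous repeats likely
    s <- paste(sample(c("A", "C", "G", "T", "A", "T"), n, replace = TRUE),
               collapse = "")
    if (rep == 6) substr(s, 50, 60) <- "NNNNNNNNNNN"
    got <- norm(find_lsrs(s, min_arm = 12L))
    want <- norm(brute_lsrs(s, min_arm = 12L))
    expect_equal(got, want)
  }
})

test_that("SSR finder agrees with the exhaustive oracle on random sequences", {
  set.seed(204)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "A", "A", "T", "N"),
                      sample(200:2000, 1), replace = TRUE), collapse = "")
    got <- find_ssrs(s)
    want <- brute_ssrs(s)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("fixture LSRs are the planted forward pair plus the IR itself", {
  g <- fixture_plastome()
  hits <- find_lsrs_record(g$record, min_arm = 30L)
  fwd <- hits[hits$type == "forward", ]
  led <- g$ledger$lsrs
  rownames(fwd) <- rownames(led) <- NULL
  expect_equal(fwd[names(led)], led)
  pal <- hits[hits$type == "palindromic", ]
  reg <- g$ledger$regions
  expect_equal(pal$length, reg$length[reg$region == "IRb"])
  expect_equal(pal$start1, reg$start[reg$region == "IRb"])
  expect_equal(pal$start2, reg$start[reg$region == "IRa"])
  expect_equal(pal$name1, "rrn16")
  expect_equal(nrow(hits), 2L)
})
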