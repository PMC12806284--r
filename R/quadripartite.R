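# Quadripartite (LSC/IRb/SSC/IRa) structure detection by seed-and-extend
# inverted-repeat search, and sequence orientation normalization.

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

new_quadripartite <- function(regions, ir_length, seed_length) {
  structure(list(regions = regions, ir_length = ir_length,
                 seed_length = seed_length),
            class = "quadripartite_structure")
}

#' @export
print.quadripartite_structure <- function(x, ...) {
  cat("<quadripartite_structure> IR arm", x$ir_length, "bp\n")
  print(x$regions)
  invisible(x)
}

# Extend an inverted-repeat seed pair to the maximal exact hit. Arms are
# [a1, a1+len) and [a2, a2+len) on the circle, related by
# seq[a2 + k] == complement(seq[a1 + len - 1 - k]). Extension grows both
# arms together on each flank while the identity holds, by geometric block
# probing (block halving on mismatch) so long plastid IRs extend quickly.
extend_ir_pair <- function(seq, a1, a2, len) {
  L <- nchar(seq)
  gap_inner <- (a2 - (a1 + len)) %% L   # span a1-arm end -> a2-arm start
  gap_outer <- (a1 - (a2 + len)) %% L   # span a2-arm end -> a1-arm start
  # inner: grow a1-arm right and a2-arm left
  repeat {
    if (gap_inner < 2L) break
    budget <- gap_inner %/% 2L
    b <- min(1024L, budget)
    grew <- FALSE
    while (b >= 1L) {
      lhs <- seq_window(seq, (a1 + len) %% L, b)
      rhs <- seq_window(seq, (a2 - b) %% L, b)
      if (lhs == revcomp(rhs)) {
        a2 <- (a2 - b) %% L
        len <- len + b
        gap_inner <- gap_inner - 2L * b
        grew <- TRUE
        break
      }
      b <- b %/% 2L
    }
    if (!grew) break
  }
  # outer: grow a1-arm left and a2-arm right
  repeat {
    if (gap_outer < 2L) break
    budget <- gap_outer %/% 2L
    b <- min(1024L, budget)
    grew <- FALSE
    while (b >= 1L) {
      lhs <- seq_window(seq, (a1 - b) %% L, b)
      rhs <- seq_window(seq, (a2 + len) %% L, b)
      if (rhs == revcomp(lhs)) {
        a1 <- (a1 - b) %% L
        len <- len + b
        gap_outer <- gap_outer - 2L * b
        grew <- TRUE
        break
      }
      b <- b %/% 2L
    }
    if (!grew) break
  }
  list(a1 = as.integer(a1), a2 = as.integer(a2), len = as.integer(len),
       gap_inner = as.integer(gap_inner), gap_outer = as.integer(gap_outer))
}

#' Detect the quadripartite structure of a plastid genome
#'
#' Seed-and-extend search for the longest pair of exact inverted repeats.
#' Probe windows of length `seed_length/2` are sampled every `seed_length/2`
#' bases around the circle, so every inverted-repeat arm of at least
#' `seed_length` contains a fully aligned probe and is guaranteed to be found;
#' each seed pair is then extended base-exactly to its maximal arms. The two
#' arms become IRb/IRa; the longer single-copy span between them is labeled
#' LSC, the shorter SSC, in cyclic order LSC, IRb, SSC, IRa.
#'
#' @param seq DNA string (circular), length > 2 * seed_length.
#' @param seed_length minimum guaranteed-detected arm length (default 1000 bp).
#' @return a `quadripartite_structure` (regions data.frame with region, start
#'   (0-based), end, length; `end` may wrap past the origin), or `NULL` when
#'   no inverted repeat of at least `seed_length` exists.
#' @export
find_inverted_repeats <- function(seq, seed_length = 1000L) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L <= 2L * seed_length) {
    stop("sequence (", L, " bp) must be longer than twice the seed length")
  }
  w <- max(1L, seed_length %/% 2L)
  starts <- seq(0L, L - 1L, by = w)
  subject <- Biostrings::DNAString(paste0(seq, substr(seq, 1L, w)))
  hits <- list()
  seen_diag <- integer()
  for (i in starts) {
    probe <- seq_window(seq, i, w)
    if (grepl("N", probe, fixed = TRUE)) next
    m <- Biostrings::start(Biostrings::matchPattern(revcomp(probe), subject))
    for (j1 in m) {
      j <- (j1 - 1L) %% L
      if (j == i) next
      d <- (i + j + w - 1L) %% L   # anti-diagonal invariant of the pairing
      # skip seeds that lie on the anti-diagonal of an already-extended hit
      if (length(seen_diag) && any(seen_diag == d)) next
      # skip overlapping windows (self-palindromic seeds)
      if ((j - i) %% L < w || (i - j) %% L < w) next
      ext <- extend_ir_pair(seq, i, j, w)
      seen_diag <- c(seen_diag, (ext$a1 + ext$a2 + ext$len - 1L) %% L, d)
      if (ext$len >= seed_length) hits[[length(hits) + 1L]] <- ext
    }
  }
  if (length(hits) == 0L) return(NULL)
  lens <- vapply(hits, `[[`, integer(1), "len")
  best <- hits[lens == max(lens)]
  if (length(best) > 1L) {
    # tie-break: arms most distant on the circle
    dist <- vapply(best, function(h) min(h$gap_inner, h$gap_outer), integer(1))
    best <- best[order(-dist)]
  }
  h <- best[[1L]]
  if (h$gap_inner == 0L || h$gap_outer == 0L) {
    stop("degenerate genome: inverted-repeat arms abut after extension")
  }
  a1 <- h$a1; a2 <- h$a2; len <- h$len
  inner_start <- (a1 + len) %% L
  outer_start <- (a2 + len) %% L
  if (h$gap_outer >= h$gap_inner) {
    # outer gap is LSC; the arm following it (a1) is IRb
    regions <- data.frame(
      region = c("LSC", "IRb", "SSC", "IRa"),
      start = c(outer_start, a1, inner_start, a2),
      length = c(h$gap_outer, len, h$gap_inner, len))
  } else {
    regions <- data.frame(
      region = c("LSC", "IRb", "SSC", "IRa"),
      start = c(inner_start, a2, outer_start, a1),
      length = c(h$gap_inner, len, h$gap_outer, len))
  }
  regions$end <- (regions$start + regions$length) %% L
  new_quadripartite(regions[, c("region", "start", "end", "length")],
                    ir_length = len, seed_length = seed_length)
}

region_sequence <- function(seq, structure, region) {
  iv <- structure$regions[structure$regions$region == region, ]
  seq_window(seq, iv$start, iv$length)
}

# Strand of ndhF (or majority strand of genes whose midpoint lies in SSC).
ssc_strand_call <- function(record, structure) {
  L <- record$length
  ssc <- structure$regions[structure$regions$region == "SSC", ]
  in_ssc <- function(pos) ((pos - ssc$start) %% L) < ssc$length
  genes <- features_of_kind(record, "gene")
  ndhf <- Filter(function(f) identical(f$name, "ndhF"), genes)
  if (length(ndhf)) return(ndhf[[1L]]$parts$strand[1L])
  strands <- character()
  for (f in genes) {
    sp <- feature_span(f)
    mid <- ((sp[1] + sp[2]) %/% 2L) %% L
    if (in_ssc(mid)) strands <- c(strands, f$parts$strand[1L])
  }
  if (length(strands) == 0L) return(NA_character_)
  names(sort(table(strands), decreasing = TRUE))[1L]
}

#' Classify a detected structure relative to a record's orientation
#'
#' Reports whether position 0 is the LSC start and whether the SSC is in
#' "forward" orientation. SSC-forward is operationalized as: the strand of
#' ndhF (or, absent ndhF, the majority strand of SSC genes) is minus — the
#' common plastome convention.
#'
#' @param structure a `quadripartite_structure`.
#' @param record the [genome_record()] it was detected on.
#' @return list: starts_at_LSC, ssc_forward (NA when no SSC genes), and a
#'   regions data.frame with length and GC per region.
#' @export
classify_regions <- function(structure, record) {
  regions <- structure$regions
  regions$gc <- vapply(seq_len(nrow(regions)), function(i)
    gc_fraction(seq_window(record$seq, regions$start[i], regions$length[i])),
    numeric(1))
  strand <- ssc_strand_call(record, structure)
  list(starts_at_LSC = regions$start[regions$region == "LSC"] == 0L,
       ssc_forward = if (is.na(strand)) NA else strand == "-",
       regions = regions)
}

# Reverse-complement the SSC span of a record in place, remapping features
# fully inside it. Features straddling an SSC junction are left untouched
# with a warning.
flip_ssc <- function(record, structure) {
  L <- record$length
  ssc <- structure$regions[structure$regions$region == "SSC", ]
  S <- ssc$start
  E <- S + ssc$length               # assumes LSC-first orientation: no wrap
  stopifnot(E <= L)
  newseq <- paste0(substr(record$seq, 1L, S),
                   revcomp(substr(record$seq, S + 1L, E)),
                   substr(record$seq, E + 1L, L))
  feats <- lapply(record$features, function(f) {
    iv <- part_intervals(f, L)
    inside <- iv$gstart >= S & (iv$gstart + iv$glen) <= E
    if (all(inside)) {
      iv$strand <- ifelse(iv$strand == "+", "-", "+")
      new_gstart <- S + (E - (iv$gstart + iv$glen))
      iv$gstart <- new_gstart
      iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]  # keep biological order
      parts <- do.call(rbind, lapply(seq_len(nrow(iv)), function(i)
        pieces_from_interval(iv$part[i], iv$gstart[i], iv$glen[i], iv$strand[i], L)))
      feature_annotation(f$kind, f$name, parts, f$qualifiers)
    } else if (any(inside)) {
      warning("feature '", f$name, "' straddles an SSC junction; left unmapped")
      f
    } else {
      f
    }
  })
  genome_record(record$id, newseq, feats, circular = record$circular)
}

#' Normalize the orientation of a plastid genome
#'
#' Modes: `"LSC"` rotates the genome so the LSC starts at position 0;
#' `"SSC"` additionally reverse-complements the SSC span in place when it is
#' not in forward orientation; `"RP"` reverse-complements the whole genome and
#' then rotates so the LSC starts at position 0. Feature coordinates are
#' remapped in every mode.
#'
#' @param record a [genome_record()].
#' @param mode one of "LSC", "SSC", "RP".
#' @param seed_length seed length for structure detection.
#' @return the adjusted [genome_record()].
#' @export
adjust_sequence <- function(record, mode = c("LSC", "SSC", "RP"),
                            seed_length = 1000L) {
  mode <- match.arg(mode)
  st <- find_inverted_repeats(record$seq, seed_length)
  if (is.null(st)) {
    stop("no inverted repeat of >= ", seed_length, " bp detected; this genome ",
         "lacks a canonical quadripartite structure and cannot be adjusted")
  }
  if (mode == "RP") {
    record <- revcomp_record(record)
    st <- find_inverted_repeats(record$seq, seed_length)
  }
  lsc_start <- st$regions$start[st$regions$region == "LSC"]
  if (lsc_start != 0L) {
    record <- rotate_circular(record, lsc_start)
    st <- find_inverted_repeats(record$seq, seed_length)
  }
  if (mode == "SSC") {
    cls <- classify_regions(st, record)
    if (isFALSE(cls$ssc_forward)) record <- flip_ssc(record, st)
  }
  record
}
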