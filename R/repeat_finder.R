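# Perfect microsatellite (SSR) detection with MISA-style unit-count
# thresholds, genomic-context localization, and long-repeat (LSR) detection
# by seed-and-extend for forward/palindromic/reverse/complement repeat pairs.

#' Default SSR unit-count thresholds
#'
#' Minimum repeat units per motif length: 10 for mononucleotides, 6 for
#' dinucleotides, 5 for trinucleotides, 4 for tetra-, penta- and
#' hexanucleotides.
#' @export
default_ssr_thresholds <- c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 4L,
                            `5` = 4L, `6` = 4L)

smallest_period <- function(x) {
  n <- nchar(x)
  for (p in seq_len(n)) {
    if (n %% p == 0L && x == strrep(substr(x, 1L, p), n %/% p)) return(p)
  }
  n
}

string_reverse <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' Canonical form of an SSR motif
#'
#' The lexicographically smallest string among all rotations of the motif and
#' all rotations of its reverse complement. Motifs that are a whole-number
#' repetition of a shorter unit are rejected with an error (they belong to
#' the shorter unit's class).
#'
#' @param motif DNA string over ACGT, length 1-6.
#' @return canonical motif string.
#' @export
canonical_motif <- function(motif) {
  k <- nchar(motif)
  if (k < 1L || k > 6L) stop("motif length must be 1-6")
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be over ACGT")
  if (smallest_period(motif) < k) {
    stop("motif '", motif, "' has a smaller period; reclassify under the ",
         smallest_period(motif), "-mer class")
  }
  rc <- revcomp(motif)
  rotations <- function(x) {
    vapply(seq_len(k), function(i)
      paste0(substr(x, i, k), substr(x, 1L, i - 1L)), character(1))
  }
  min(c(rotations(motif), rotations(rc)))
}

#' Find perfect microsatellites (SSRs)
#'
#' Reports all maximal perfect tandem repeats with unit length 1-6 whose
#' whole-unit repeat count reaches the class threshold. A run whose unit has
#' a smaller period is reported only under the smaller period's class; `N`
#' never matches; coordinates are 0-based half-open and cover whole repeat
#' units only.
#'
#' @param seq DNA string over ACGTN.
#' @param thresholds named vector, motif length ("1".."6") to minimum units.
#' @return data.frame: motif (canonical), unit (as observed), motif_length,
#'   count, start, end.
#' @export
find_ssrs <- function(seq, thresholds = default_ssr_thresholds) {
  seq <- toupper(seq)
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  valid <- chars %in% c("A", "C", "G", "T")
  hits <- list()
  for (k in as.integer(names(thresholds))) {
    thr <- thresholds[[as.character(k)]]
    if (n < k * thr) next
    idx <- seq_len(n - k)
    m <- chars[idx] == chars[idx + k] & valid[idx] & valid[idx + k]
    r <- rle(m)
    pos <- cumsum(c(1L, r$lengths))
    for (q in which(r$values)) {
      i <- pos[q]                     # 1-based run start
      run_len <- r$lengths[q] + k     # total period-k run length
      count <- run_len %/% k
      if (count < thr) next
      unit <- substr(seq, i, i + k - 1L)
      if (smallest_period(unit) < k) next
      hits[[length(hits) + 1L]] <- data.frame(
        motif = canonical_motif(unit), unit = unit, motif_length = k,
        count = count, start = i - 1L, end = i - 1L + count * k,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(motif = character(), unit = character(),
                      motif_length = integer(), count = integer(),
                      start = integer(), end = integer()))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$motif_length), ]
  rownames(out) <- NULL
  out
}

#' Locate an interval in its genomic context
#'
#' Classifies the interval midpoint as exon (inside any exon part of a
#' CDS/tRNA/rRNA/exon feature), intron (inside a gene span but not an exon)
#' or IGS (named after the flanking genes), with priority exon > intron > IGS.
#'
#' @param interval numeric (start, end), 0-based half-open.
#' @param record an annotated [genome_record()].
#' @return list(context = "exon"|"intron"|"IGS", name = gene or "a-b").
#' @export
locate_context <- function(interval, record) {
  L <- record$length
  mid <- (floor((interval[1] + interval[2]) / 2)) %% L
  in_circ <- function(start, len) ((mid - start) %% L) < len
  for (f in features_of_kind(record, c("CDS", "tRNA", "rRNA", "exon"))) {
    iv <- part_intervals(f, L)
    for (r in seq_len(nrow(iv))) {
      if (in_circ(iv$gstart[r], iv$glen[r])) {
        nm <- if (!is.na(f$name)) f$name else "(unnamed)"
        return(list(context = "exon", name = nm))
      }
    }
  }
  genes <- Filter(function(f) !is.na(f$name), features_of_kind(record, "gene"))
  spans <- if (length(genes)) t(vapply(genes, gene_circular_span, numeric(2), L = L))
           else matrix(numeric(0), ncol = 2)
  for (i in seq_along(genes)) {
    if (in_circ(spans[i, "start"], spans[i, "len"])) {
      return(list(context = "intron", name = genes[[i]]$name))
    }
  }
  if (length(genes) >= 2L) {
    ord <- order(spans[, "start"])
    genes <- genes[ord]
    spans <- spans[ord, , drop = FALSE]
    nmax <- length(genes)
    for (i in seq_len(nmax)) {
      j <- if (i == nmax) 1L else i + 1L
      gap_start <- (spans[i, "start"] + spans[i, "len"]) %% L
      gap_len <- (spans[j, "start"] - gap_start) %% L
      if (gap_len > 0 && in_circ(gap_start, gap_len)) {
        return(list(context = "IGS",
                    name = paste0(genes[[i]]$name, "-", genes[[j]]$name)))
      }
    }
  }
  list(context = "IGS", name = NA_character_)
}

#' Find SSRs in a record with genomic context
#'
#' @param record an annotated [genome_record()].
#' @param thresholds see [find_ssrs()].
#' @return [find_ssrs()] output plus context and context_name columns.
#' @export
find_ssrs_record <- function(record, thresholds = default_ssr_thresholds) {
  hits <- find_ssrs(record$seq, thresholds)
  if (nrow(hits) == 0L) {
    hits$context <- character()
    hits$context_name <- character()
    return(hits)
  }
  ctx <- lapply(seq_len(nrow(hits)), function(i)
    locate_context(c(hits$start[i], hits$end[i]), record))
  hits$context <- vapply(ctx, `[[`, character(1), "context")
  hits$context_name <- vapply(ctx, `[[`, character(1), "name")
  hits
}

## ---------------------------------------------------------------------------
## Long sequence repeats

complement_str <- function(x) chartr("ACGTN", "TGCAN", x)

# Per-base pair extension for one repeat type. a1 < a2 are 1-based arm
# starts; arms stay within [1, n]; anti-diagonal types keep arms disjoint.
extend_lsr <- function(chars, a1, a2, len, type, n) {
  eq <- function(x, y) !is.na(x) && !is.na(y) && x != "N" && y != "N" &&
    switch(type,
           forward = x == y,
           complement = x == complement_str(y),
           palindromic = x == complement_str(y),
           reverse = x == y)
  if (type %in% c("forward", "complement")) {
    while (a1 > 1L && a2 > 1L && a2 - 1L > a1 - 1L &&
           eq(chars[a1 - 1L], chars[a2 - 1L])) {
      a1 <- a1 - 1L; a2 <- a2 - 1L; len <- len + 1L
    }
    while (a1 + len <= n && a2 + len <= n &&
           eq(chars[a1 + len], chars[a2 + len])) {
      len <- len + 1L
    }
  } else {
    # arm1 grows right while arm2 grows left (inner), then arm1 left / arm2
    # right (outer); arms stay disjoint (each inner step closes the gap by 2)
    while (a2 - (a1 + len) >= 2L && eq(chars[a1 + len], chars[a2 - 1L])) {
      a2 <- a2 - 1L; len <- len + 1L
    }
    while (a1 > 1L && a2 + len <= n && a1 + len <= a2 &&
           eq(chars[a1 - 1L], chars[a2 + len])) {
      a1 <- a1 - 1L; len <- len + 1L
    }
  }
  list(a1 = a1, a2 = a2, len = len)
}

# Cluster seed pairs that lie on one (anti-)diagonal into runs of consecutive
# arm1 starts; one extension per run suffices for exact repeats.
cluster_reps <- function(i, j, diagonal) {
  ord <- order(diagonal, i)
  i <- i[ord]; j <- j[ord]; diagonal <- diagonal[ord]
  new_run <- c(TRUE, diff(i) != 1L | diff(diagonal) != 0L)
  keep <- which(new_run)
  list(i = i[keep], j = j[keep])
}

#' Find long sequence repeats (LSRs)
#'
#' Maximal exact repeat pairs with arms of at least `min_arm` bp, found by
#' seed-and-extend with seed length `min_arm`. Types: forward (identical
#' arms), palindromic (reverse complement), reverse (reversed), complement
#' (complemented). Trivial self matches are excluded and nested sub-maximal
#' hits are suppressed; `N` never matches. The search is linear on the given
#' sequence; coordinates are 0-based half-open.
#'
#' @param seq DNA string, length >= 2 * min_arm.
#' @param min_arm minimum arm length in bp (default 30).
#' @param types subset of c("forward", "palindromic", "reverse", "complement").
#' @return data.frame: type, length, start1, end1, start2, end2.
#' @export
find_lsrs <- function(seq, min_arm = 30L,
                      types = c("forward", "palindromic", "reverse", "complement")) {
  types <- match.arg(types, several.ok = TRUE)
  seq <- toupper(seq)
  n <- nchar(seq)
  w <- as.integer(min_arm)
  if (n < 2L * w) stop("sequence shorter than 2 * min_arm")
  chars <- strsplit(seq, "")[[1]]
  np <- n - w + 1L
  starts <- seq_len(np)
  kmer <- substring(seq, starts, starts + w - 1L)
  has_n <- grepl("N", kmer, fixed = TRUE)
  f <- factor(kmer)
  lev <- levels(f)
  # query k-mers per type, via whole-sequence transforms
  rcseq <- revcomp(seq)
  rseq <- paste(rev(chars), collapse = "")
  cseq <- complement_str(seq)
  query_for <- function(type) {
    switch(type,
           forward = kmer,
           complement = substring(cseq, starts, starts + w - 1L),
           palindromic = substring(rcseq, n - starts - w + 2L, n - starts + 1L),
           reverse = substring(rseq, n - starts - w + 2L, n - starts + 1L))
  }
  groups <- split(starts[!has_n], f[!has_n])
  out <- list()
  for (type in types) {
    qk <- query_for(type)
    gi <- match(qk, lev)
    idx <- which(!is.na(gi) & !has_n)
    if (type == "forward") {
      cnt <- tabulate(f[!has_n], nbins = length(lev))
      idx <- idx[cnt[gi[idx]] >= 2L]
    }
    cand <- vector("list", length(idx))
    for (q in seq_along(idx)) {
      i <- idx[q]
      js <- groups[[gi[i]]]
      js <- if (type %in% c("forward", "complement")) js[js > i]
            else js[js >= i + w]
      if (length(js)) cand[[q]] <- cbind(i, js)
    }
    cand <- do.call(rbind, cand)
    if (is.null(cand) || nrow(cand) == 0L) next
    cand_i <- cand[, 1L]
    cand_j <- cand[, 2L]
    diagonal <- if (type %in% c("forward", "complement")) cand_j - cand_i
                else cand_i + cand_j
    reps <- cluster_reps(cand_i, cand_j, diagonal)
    hits <- lapply(seq_along(reps$i), function(q) {
      ext <- extend_lsr(chars, reps$i[q], reps$j[q], w, type, n)
      if (ext$len < w) return(NULL)
      data.frame(type = type, length = ext$len,
                 start1 = ext$a1 - 1L, end1 = ext$a1 - 1L + ext$len,
                 start2 = ext$a2 - 1L, end2 = ext$a2 - 1L + ext$len,
                 stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, hits)
    if (!is.null(hits)) out[[type]] <- unique(hits)
  }
  if (length(out) == 0L) {
    return(data.frame(type = character(), length = integer(),
                      start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer()))
  }
  res <- do.call(rbind, out)
  res <- unique(res)
  res <- res[order(res$type, res$start1, res$start2), ]
  rownames(res) <- NULL
  res
}

#' Find LSRs in a record with genomic context for both arms
#'
#' @param record an annotated [genome_record()].
#' @param min_arm,types see [find_lsrs()].
#' @return [find_lsrs()] output plus context1/name1/context2/name2 columns.
#' @export
find_lsrs_record <- function(record, min_arm = 30L,
                             types = c("forward", "palindromic", "reverse",
                                       "complement")) {
  hits <- find_lsrs(record$seq, min_arm, types)
  if (nrow(hits) == 0L) {
    hits$context1 <- character(); hits$name1 <- character()
    hits$context2 <- character(); hits$name2 <- character()
    return(hits)
  }
  c1 <- lapply(seq_len(nrow(hits)), function(i)
    locate_context(c(hits$start1[i], hits$end1[i]), record))
  c2 <- lapply(seq_len(nrow(hits)), function(i)
    locate_context(c(hits$start2[i], hits$end2[i]), record))
  hits$context1 <- vapply(c1, `[[`, character(1), "context")
  hits$name1 <- vapply(c1, `[[`, character(1), "name")
  hits$context2 <- vapply(c2, `[[`, character(1), "context")
  hits$name2 <- vapply(c2, `[[`, character(1), "name")
  hits
}
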