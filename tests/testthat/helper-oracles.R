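# Independent brute-force oracles used to validate the seed-and-extend and
# run-length detectors. These deliberately use a different computation path:
# exhaustive (start, unit, count) enumeration for SSRs and full
# diagonal/anti-diagonal scans for repeats.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Exhaustive SSR scan: test every (start, unit) pair by direct substring
# comparison against strrep(unit, count).
brute_ssrs <- function(seq, thresholds = plastome::default_ssr_thresholds) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  hits <- list()
  for (k in as.integer(names(thresholds))) {
    thr <- thresholds[[as.character(k)]]
    if (n < k * thr) next
    starts <- seq_len(n - k * thr + 1L)
    units <- substring(seq, starts, starts + k - 1L)
    cand <- substring(seq, starts, starts + k * thr - 1L) == strrep(units, thr) &
      grepl("^[ACGT]+$", units)
    for (i in starts[cand]) {
      unit <- substring(seq, i, i + k - 1L)
      # maximality on the left: the period-k run must not extend
      if (i > 1L) {
        a <- chars[i - 1L]; b <- chars[i - 1L + k]
        if (a == b && a %in% c("A", "C", "G", "T")) next
      }
      # smallest-period rule
      periodic <- FALSE
      for (p in seq_len(k - 1L)) {
        if (k %% p == 0L && unit == strrep(substr(unit, 1L, p), k %/% p)) {
          periodic <- TRUE; break
        }
      }
      if (periodic) next
      count <- thr
      while (i + (count + 1L) * k - 1L <= n &&
             substring(seq, i + count * k, i + (count + 1L) * k - 1L) == unit) {
        count <- count + 1L
      }
      hits[[length(hits) + 1L]] <- data.frame(
        motif = plastome::canonical_motif(unit), unit = unit, motif_length = k,
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

# Exhaustive maximal-repeat scan over every diagonal (forward/complement) or
# anti-diagonal (palindromic/reverse), O(n^2) total.
brute_lsrs <- function(seq, min_arm,
                       types = c("forward", "palindromic", "reverse", "complement")) {
  n <- nchar(seq)
  chars <- strsplit(toupper(seq), "")[[1]]
  comp <- chartr("ACGTN", "TGCAN", chars)
  ok <- chars %in% c("A", "C", "G", "T")
  hits <- list()
  runs_of <- function(m) {
    r <- rle(m)
    pos <- cumsum(c(1L, r$lengths))
    data.frame(start = pos[which(r$values)],
               len = r$lengths[r$values])
  }
  for (type in types) {
    if (type %in% c("forward", "complement")) {
      target <- if (type == "forward") chars else comp
      for (d in seq_len(n - 1L)) {
        idx <- seq_len(n - d)
        m <- chars[idx] == target[idx + d] & ok[idx] & ok[idx + d]
        if (!any(m)) next
        r <- runs_of(m)
        r <- r[r$len >= min_arm, , drop = FALSE]
        for (q in seq_len(nrow(r))) {
          i <- r$start[q]
          hits[[length(hits) + 1L]] <- data.frame(
            type = type, length = r$len[q],
            start1 = i - 1L, end1 = i - 1L + r$len[q],
            start2 = i + d - 1L, end2 = i + d - 1L + r$len[q],
            stringsAsFactors = FALSE)
        }
      }
    } else {
      target <- if (type == "palindromic") comp else chars
      for (A in seq(2L, 2L * n)) {       # pairing p + q == A (1-based)
        p <- seq(max(1L, A - n), min(n, A - 1L))
        if (length(p) == 0L) next
        q <- A - p
        m <- chars[p] == target[q] & ok[p] & ok[q] & p != q
        if (!any(m)) next
        r <- runs_of(m)
        for (z in seq_len(nrow(r))) {
          p0 <- p[1L] + r$start[z] - 1L
          R <- r$len[z]
          p1 <- p0 + R - 1L
          q_start <- A - p1
          if (p0 > q_start) next          # the mirror-image duplicate run
          len <- if (q_start <= p1) R %/% 2L else R
          if (len < min_arm) next
          hits[[length(hits) + 1L]] <- data.frame(
            type = type, length = len,
            start1 = p0 - 1L, end1 = p0 - 1L + len,
            start2 = A - p0 - len, end2 = A - p0,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(type = character(), length = integer(),
                      start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer()))
  }
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$type, out$start1, out$start2), ]
  rownames(out) <- NULL
  out
}

# Exhaustive circular inverted-repeat scan: maximal run over every circular
# anti-diagonal class. Returns NULL or list(len, arm_starts) for the longest
# inverted-repeat pair (0-based arm starts, modulo n).
brute_max_inverted_repeat <- function(seq, min_len) {
  n <- nchar(seq)
  chars <- strsplit(toupper(seq), "")[[1]]
  comp <- chartr("ACGTN", "TGCAN", chars)
  ok <- chars %in% c("A", "C", "G", "T")
  best <- NULL
  idx0 <- seq_len(n) - 1L
  for (A in 0L:(n - 1L)) {
    q0 <- (A - idx0) %% n
    m <- chars == comp[q0 + 1L] & ok & ok[q0 + 1L] & idx0 != q0
    if (!any(m)) next
    # circular runs: rotate so the vector does not wrap
    r <- rle(m)
    if (length(r$lengths) > 1L && r$values[1L] && r$values[length(r$values)]) {
      shift <- r$lengths[length(r$lengths)]
      m <- c(m[(n - shift + 1L):n], m[seq_len(n - shift)])
      offset <- -shift
      r <- rle(m)
    } else offset <- 0L
    pos <- cumsum(c(1L, r$lengths))
    for (z in which(r$values)) {
      R <- r$lengths[z]
      p0 <- (pos[z] - 1L + offset) %% n          # 0-based run start
      p1 <- p0 + R - 1L
      q_start <- (A - p1) %% n
      # centered (self-paired) runs get clipped to disjoint arms
      len <- if (((q_start - p0) %% n) < R) R %/% 2L else R
      if (len < min_len) next
      if (is.null(best) || len > best$len) {
        best <- list(len = len,
                     arm_starts = sort(c(p0, (A - p0 - len + 1L) %% n)))
      }
    }
  }
  best
}
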