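# Conversion of annotated records to NCBI 5-column feature tables (tbl),
# FASTA, and the mVISTA annotation dialect.

TBL_QUALIFIERS <- c("gene", "product", "codon_start", "transl_table")

#' Convert a record to an NCBI 5-column feature table
#'
#' Coordinates are 1-based inclusive; minus-strand intervals are written
#' start > stop. The feature key appears on the first interval line; joined
#' intervals continue on coordinate-only lines; qualifier lines are
#' tab-indented. Qualifiers are limited to gene, product, codon_start and
#' transl_table (passed through verbatim when present).
#'
#' @param record a [genome_record()].
#' @return character scalar (the tbl text).
#' @export
to_tbl <- function(record) {
  lines <- sprintf(">Feature %s", record$id)
  for (f in record$features) {
    p <- f$parts
    for (i in seq_len(nrow(p))) {
      coords <- if (p$strand[i] == "+") c(p$start[i] + 1L, p$end[i])
                else c(p$end[i], p$start[i] + 1L)
      key <- if (f$kind == "misc") "misc_feature" else f$kind
      lines <- c(lines, if (i == 1L) sprintf("%d\t%d\t%s", coords[1], coords[2], key)
                        else sprintf("%d\t%d", coords[1], coords[2]))
    }
    quals <- f$qualifiers
    if (!is.na(f$name) && !("gene" %in% names(quals))) {
      quals <- c(stats::setNames(f$name, "gene"), quals)
    }
    quals <- quals[names(quals) %in% TBL_QUALIFIERS]
    for (i in seq_along(quals)) {
      lines <- c(lines, sprintf("\t\t\t%s\t%s", names(quals)[i], quals[[i]]))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

# Parse tbl text back into a coordinate table (round-trip audit helper).
parse_tbl <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!startsWith(lines, ">Feature")]
  rows <- list()
  key <- NA_character_
  for (l in lines) {
    if (startsWith(l, "\t\t\t")) next
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 3L) key <- parts[3]
    a <- as.integer(parts[1]); b <- as.integer(parts[2])
    rows[[length(rows) + 1L]] <- data.frame(
      key = key, start = min(a, b) - 1L, end = max(a, b),
      strand = if (a <= b) "+" else "-", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Convert a record to mVISTA annotation format
#'
#' Per gene, one header line `start end >|< name` (1-based, `>` for plus
#' strand), followed by one `start end exon` line per exon part of its
#' CDS; tRNA/rRNA parts are labeled `utr` (mVISTA has no RNA class).
#' A record with no genes yields empty output with a warning.
#'
#' @param record a [genome_record()].
#' @return character scalar (the mVISTA annotation text).
#' @export
to_mvista <- function(record) {
  genes <- Filter(function(f) !is.na(f$name), features_of_kind(record, "gene"))
  if (length(genes) == 0L) {
    warning("record '", record$id, "' has no gene features; empty mVISTA output")
    return("")
  }
  lines <- character()
  for (g in genes) {
    sp <- feature_span(g)
    arrow <- if (g$parts$strand[1] == "+") ">" else "<"
    lines <- c(lines, sprintf("%d %d %s %s", sp[1] + 1L, sp[2], arrow, g$name))
    sf <- splice_feature_for(record, g$name)
    label <- if (!is.null(sf) && sf$kind %in% c("tRNA", "rRNA")) "utr" else "exon"
    if (is.null(sf)) sf <- g
    p <- sf$parts[order(sf$parts$start), , drop = FALSE]
    for (i in seq_len(nrow(p))) {
      lines <- c(lines, sprintf("%d %d %s", p$start[i] + 1L, p$end[i], label))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Convert a record to FASTA text
#'
#' @param record a [genome_record()].
#' @return character scalar: id line plus 70-column wrapped sequence.
#' @export
to_fasta <- function(record) {
  starts <- seq(1L, record$length, by = 70L)
  body <- substring(record$seq, starts, pmin(starts + 69L, record$length))
  paste0(">", record$id, "\n", paste(body, collapse = "\n"), "\n")
}
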