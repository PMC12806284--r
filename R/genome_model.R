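# Core data model: annotated circular genomes with 0-based half-open internal
# coordinates. GenBank I/O converts to/from 1-based inclusive at the boundary.

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings (IUPAC letters).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

valid_dna <- function(x) {
  grepl("^[ACGTNRYSWKMBDHV]*$", x)
}

#' Construct a feature annotation
#'
#' A feature is a kind (gene, CDS, tRNA, rRNA, exon, intron or misc), a gene
#' name, and an ordered set of located parts. Parts are stored in biological
#' (transcript) order; each row of `parts` is one in-range piece with 0-based
#' half-open `start`/`end`, a `strand` and a `part` id. Two pieces sharing a
#' `part` id are the two halves of one origin-spanning interval on a circular
#' genome.
#'
#' @param kind feature kind, one of gene, CDS, tRNA, rRNA, exon, intron, misc.
#' @param name gene symbol (character scalar, may be NA).
#' @param parts data.frame with columns start, end, strand, and optionally part.
#' @param qualifiers named character vector of GenBank qualifiers.
#' @return an object of class `feature_annotation`.
#' @export
feature_annotation <- function(kind, name, parts, qualifiers = character()) {
  kind <- match.arg(kind, c("gene", "CDS", "tRNA", "rRNA", "exon", "intron", "misc"))
  stopifnot(is.data.frame(parts), nrow(parts) >= 1L,
            all(c("start", "end", "strand") %in% names(parts)))
  if (is.null(parts$part)) parts$part <- seq_len(nrow(parts))
  parts$start <- as.integer(parts$start)
  parts$end <- as.integer(parts$end)
  if (any(parts$start >= parts$end)) {
    stop("feature '", name, "': every stored piece must satisfy start < end")
  }
  if (!all(parts$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  rownames(parts) <- NULL
  structure(list(kind = kind, name = as.character(name),
                 parts = parts[, c("start", "end", "strand", "part")],
                 qualifiers = qualifiers),
            class = "feature_annotation")
}

feature_span <- function(feature) {
  c(min(feature$parts$start), max(feature$parts$end))
}

sort_features <- function(features) {
  if (length(features) == 0L) return(features)
  left <- vapply(features, function(f) min(f$parts$start), integer(1))
  features[order(left)]
}

#' Construct a genome record
#'
#' @param id record identifier.
#' @param seq DNA string; uppercased, U converted to T.
#' @param features list of [feature_annotation()] objects.
#' @param circular logical; plastomes are circular by default.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(id, seq, features = list(), circular = TRUE) {
  seq <- chartr("u", "T", toupper(seq))
  seq <- chartr("U", "T", seq)
  if (nchar(seq) == 0L) stop("empty sequence for record '", id, "'")
  if (!valid_dna(seq)) stop("record '", id, "' contains non-IUPAC characters")
  len <- nchar(seq)
  for (f in features) {
    if (any(f$parts$start < 0L) || any(f$parts$end > len)) {
      stop("feature '", f$name, "' has coordinates outside [0, ", len, ")")
    }
  }
  structure(list(id = as.character(id), seq = seq, length = len,
                 circular = isTRUE(circular),
                 features = sort_features(features)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s, %d features\n",
              x$id, x$length, if (x$circular) "circular" else "linear",
              length(x$features)))
  invisible(x)
}

# Circular substring: 0-based half-open [start, start+len), wrapping at origin.
seq_window <- function(seq, start, len) {
  L <- nchar(seq)
  start <- start %% L
  if (start + len <= L) {
    substr(seq, start + 1L, start + len)
  } else {
    paste0(substr(seq, start + 1L, L), substr(seq, 1L, start + len - L))
  }
}

# One circular interval per logical part: (part, gstart, glen, strand).
# For an origin-split part the genome start is the piece that touches the
# sequence end (strand '+': first stored piece; strand '-': last stored piece).
part_intervals <- function(feature, L) {
  p <- feature$parts
  out <- lapply(unique(p$part), function(id) {
    rows <- p[p$part == id, , drop = FALSE]
    strand <- rows$strand[1]
    if (nrow(rows) == 1L) {
      data.frame(part = id, gstart = rows$start, glen = rows$end - rows$start,
                 strand = strand)
    } else if (nrow(rows) == 2L) {
      first <- if (strand == "+") rows[1, ] else rows[2, ]
      stopifnot(first$end == L)
      data.frame(part = id, gstart = first$start,
                 glen = sum(rows$end - rows$start), strand = strand)
    } else {
      stop("logical part split into more than two pieces")
    }
  })
  do.call(rbind, out)
}

# Re-emit the stored pieces (in biological order) for one circular interval.
pieces_from_interval <- function(part, gstart, glen, strand, L) {
  if (gstart + glen <= L) {
    data.frame(start = gstart, end = gstart + glen, strand = strand, part = part)
  } else {
    a <- data.frame(start = gstart, end = L, strand = strand, part = part)
    b <- data.frame(start = 0L, end = gstart + glen - L, strand = strand, part = part)
    if (strand == "+") rbind(a, b) else rbind(b, a)
  }
}

#' Extract the spliced, strand-resolved sequence of a feature
#'
#' Parts are concatenated in stored (biological) order; minus-strand parts are
#' reverse-complemented; origin-spanning parts yield the contiguous circular
#' subsequence.
#'
#' @param record a [genome_record()].
#' @param feature a [feature_annotation()] belonging to the record.
#' @return DNA string.
#' @export
extract_feature_sequence <- function(record, feature) {
  p <- feature$parts
  if (any(p$start < 0L) || any(p$end > record$length)) {
    stop("feature interval outside [0, ", record$length, ")")
  }
  pieces <- vapply(seq_len(nrow(p)), function(i) {
    s <- substr(record$seq, p$start[i] + 1L, p$end[i])
    if (p$strand[i] == "-") revcomp(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}

#' Rotate a circular genome
#'
#' Moves the origin to `offset`: the new sequence is
#' `seq[offset:] + seq[:offset]` and all feature coordinates shift by
#' `-offset` modulo the length. Parts that come to span the origin are stored
#' split; previously split parts that become contiguous are merged.
#'
#' @param record a circular [genome_record()].
#' @param offset integer in `[0, length)`.
#' @return the rotated [genome_record()].
#' @export
rotate_circular <- function(record, offset) {
  offset <- as.integer(offset)
  if (offset < 0L || offset >= record$length) {
    stop("offset must be in [0, ", record$length, ")")
  }
  if (!record$circular) stop("cannot rotate a linear record")
  if (offset == 0L) return(record)
  L <- record$length
  newseq <- paste0(substr(record$seq, offset + 1L, L), substr(record$seq, 1L, offset))
  feats <- lapply(record$features, function(f) {
    iv <- part_intervals(f, L)
    iv$gstart <- (iv$gstart - offset) %% L
    parts <- do.call(rbind, lapply(seq_len(nrow(iv)), function(i) {
      pieces_from_interval(iv$part[i], iv$gstart[i], iv$glen[i], iv$strand[i], L)
    }))
    feature_annotation(f$kind, f$name, parts, f$qualifiers)
  })
  genome_record(record$id, newseq, feats, circular = TRUE)
}

# Reverse complement a whole record, remapping features (coordinates mirrored,
# strands flipped; biological part order is preserved).
revcomp_record <- function(record) {
  L <- record$length
  feats <- lapply(record$features, function(f) {
    iv <- part_intervals(f, L)
    iv$gstart <- (L - (iv$gstart + iv$glen)) %% L
    iv$strand <- ifelse(iv$strand == "+", "-", "+")
    parts <- do.call(rbind, lapply(seq_len(nrow(iv)), function(i) {
      pieces_from_interval(iv$part[i], iv$gstart[i], iv$glen[i], iv$strand[i], L)
    }))
    feature_annotation(f$kind, f$name, parts, f$qualifiers)
  })
  genome_record(record$id, revcomp(record$seq), feats, circular = record$circular)
}

## ---------------------------------------------------------------------------
## FASTA

#' Read a FASTA file
#'
#' @param path FASTA file with one or more records.
#' @return named character vector of uppercased DNA sequences (U normalized
#'   to T). Duplicate ids or non-IUPAC characters are errors.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("FASTA file does not start with '>': ", path)
  grp <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  if (length(seqs) != length(ids)) stop("FASTA record with no sequence in ", path)
  seqs <- chartr("U", "T", toupper(gsub("\\s", "", seqs)))
  bad <- !valid_dna(seqs)
  if (any(bad)) stop("non-IUPAC characters in record(s): ",
                     paste(ids[bad], collapse = ", "))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA (70-column wrap)
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## GenBank flat file

# Split a location string on top-level commas (commas not inside parentheses).
split_top_level <- function(x) {
  chars <- strsplit(x, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  cuts <- which(chars == "," & depth == 0L)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  vapply(seq_along(starts), function(i)
    paste(chars[starts[i]:ends[i]], collapse = ""), character(1))
}

parse_loc_node <- function(x, loc) {
  if (startsWith(x, "complement(")) {
    df <- parse_loc_node(substr(x, 12L, nchar(x) - 1L), loc)
    df$strand <- ifelse(df$strand == "+", "-", "+")
    df[rev(seq_len(nrow(df))), , drop = FALSE]
  } else if (startsWith(x, "join(") || startsWith(x, "order(")) {
    inner <- substr(x, regexpr("(", x, fixed = TRUE) + 1L, nchar(x) - 1L)
    do.call(rbind, lapply(split_top_level(inner), parse_loc_node, loc = loc))
  } else {
    m <- regmatches(x, regexec("^(\\d+)(\\.\\.(\\d+))?$", x))[[1]]
    if (length(m) == 0L) stop("cannot parse location '", loc, "' (near '", x, "')")
    s1 <- as.integer(m[2])
    e1 <- if (is.na(m[4]) || m[4] == "") s1 else as.integer(m[4])
    if (e1 < s1) stop("location '", loc, "': end before start")
    data.frame(start = s1 - 1L, end = e1, strand = "+")
  }
}

# Parse a GenBank location into stored pieces (biological order) and assign
# logical-part ids, merging origin-spanning join pieces into one part.
parse_location <- function(loc, genome_len) {
  clean <- gsub("[<>]", "", gsub("\\s", "", loc))
  df <- parse_loc_node(clean, loc)
  rownames(df) <- NULL
  part <- integer(nrow(df))
  part[1] <- 1L
  if (nrow(df) > 1L) {
    for (i in 2:nrow(df)) {
      prev <- df[i - 1L, ]
      cur <- df[i, ]
      joins <- prev$strand == cur$strand &&
        ((cur$strand == "+" && prev$end == genome_len && cur$start == 0L) ||
         (cur$strand == "-" && prev$start == 0L && cur$end == genome_len))
      part[i] <- if (joins) part[i - 1L] else part[i - 1L] + 1L
    }
  }
  df$part <- part
  df
}

# Render a location string from stored pieces.
format_location <- function(parts) {
  fmt1 <- function(s, e) if (e - s == 1L) as.character(e) else paste0(s + 1L, "..", e)
  if (all(parts$strand == "-")) {
    rows <- parts[rev(seq_len(nrow(parts))), , drop = FALSE]
    core <- vapply(seq_len(nrow(rows)), function(i) fmt1(rows$start[i], rows$end[i]),
                   character(1))
    inner <- if (length(core) > 1L) paste0("join(", paste(core, collapse = ","), ")") else core
    paste0("complement(", inner, ")")
  } else if (all(parts$strand == "+")) {
    core <- vapply(seq_len(nrow(parts)), function(i) fmt1(parts$start[i], parts$end[i]),
                   character(1))
    if (length(core) > 1L) paste0("join(", paste(core, collapse = ","), ")") else core
  } else {
    # trans-spliced mixed strands: per logical part, in biological order
    segs <- vapply(unique(parts$part), function(id) {
      rows <- parts[parts$part == id, , drop = FALSE]
      if (rows$strand[1] == "-") {
        rows <- rows[rev(seq_len(nrow(rows))), , drop = FALSE]
        core <- vapply(seq_len(nrow(rows)), function(i) fmt1(rows$start[i], rows$end[i]),
                       character(1))
        inner <- if (length(core) > 1L) paste0("join(", paste(core, collapse = ","), ")") else core
        paste0("complement(", inner, ")")
      } else {
        core <- vapply(seq_len(nrow(rows)), function(i) fmt1(rows$start[i], rows$end[i]),
                       character(1))
        if (length(core) > 1L) paste0("join(", paste(core, collapse = ","), ")") else core
      }
    }, character(1))
    paste0("join(", paste(segs, collapse = ","), ")")
  }
}

#' Read a GenBank flat file
#'
#' Parses the first record of a GenBank flat file into a [genome_record()].
#' Gene, CDS, tRNA, rRNA, exon and intron features are captured with their
#' join/complement locations; other feature keys (except `source`, which is
#' dropped) become kind `misc`. The sequence is uppercased and origin-spanning
#' join locations are normalized into flagged split parts.
#'
#' @param path GenBank file.
#' @return a [genome_record()].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("not a GenBank flat file (no LOCUS line): ", path)
  locus_i <- locus_i[1]
  toks <- strsplit(trimws(lines[locus_i]), "\\s+")[[1]]
  id <- toks[2]
  bp_i <- which(toks == "bp")
  declared_len <- if (length(bp_i)) as.integer(toks[bp_i[1] - 1L]) else NA_integer_
  circular <- any(tolower(toks) == "circular")
  if (!circular && !any(tolower(toks) == "linear")) circular <- TRUE

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  end_i <- grep("^//", lines)
  if (length(orig_i) == 0L) stop("GenBank file has no ORIGIN section: ", path)
  orig_i <- orig_i[1]
  end_i <- if (length(end_i)) end_i[1] else length(lines) + 1L

  seq <- paste(gsub("[^A-Za-z]", "", lines[(orig_i + 1L):(end_i - 1L)]), collapse = "")
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence in ", path)
  if (!is.na(declared_len) && nchar(seq) != declared_len) {
    warning("LOCUS length (", declared_len, ") != sequence length (", nchar(seq),
            ") in ", path)
  }
  L <- nchar(seq)

  features <- list()
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1L):(orig_i - 1L)]
    # group lines into feature entries: a new entry has a key in columns 6-20
    is_new <- grepl("^ {5}\\S", block)
    keep <- is_new | grepl("^ {21}", block)
    block <- block[keep]
    is_new <- is_new[keep]
    grp <- cumsum(is_new)
    for (g in unique(grp[is_new])) {
      ls <- block[grp == g]
      key <- trimws(substr(ls[1], 6L, 20L))
      body <- c(trimws(substr(ls[1], 21L, nchar(ls[1]))),
                trimws(substring(ls[-1], 22L)))
      # location: body lines up to the first qualifier ("/...")
      qstart <- which(startsWith(body, "/"))
      loc_lines <- if (length(qstart)) body[seq_len(qstart[1] - 1L)] else body
      qual_lines <- if (length(qstart)) body[qstart[1]:length(body)] else character()
      loc <- paste(loc_lines, collapse = "")
      # stitch multi-line qualifier values back together
      quals <- character()
      qnames <- character()
      for (q in qual_lines) {
        if (startsWith(q, "/")) {
          eq <- regexpr("=", q, fixed = TRUE)
          if (eq > 0L) {
            qnames <- c(qnames, substr(q, 2L, eq - 1L))
            quals <- c(quals, substr(q, eq + 1L, nchar(q)))
          } else {
            qnames <- c(qnames, substr(q, 2L, nchar(q)))
            quals <- c(quals, "")
          }
        } else if (length(quals)) {
          quals[length(quals)] <- paste(quals[length(quals)], q)
        }
      }
      quals <- gsub('^"|"$', "", quals)
      names(quals) <- qnames
      if (key == "source") next
      kind <- if (key %in% c("gene", "CDS", "tRNA", "rRNA", "exon", "intron")) key else "misc"
      parts <- tryCatch(parse_location(loc, L),
                        error = function(e) stop("in ", path, ", feature '", key,
                                                 "': ", conditionMessage(e)))
      name <- if ("gene" %in% qnames) trimws(quals[["gene"]]) else NA_character_
      features <- c(features, list(feature_annotation(kind, name, parts, quals)))
    }
  }
  genome_record(id, seq, features, circular = circular)
}

#' Write a genome record to a GenBank flat file
#'
#' Output is byte-stable across runs (a fixed date field is used).
#'
#' @param record a [genome_record()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (record$circular) "circular" else "linear  "
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s PLN 01-JAN-2024",
                     record$id, record$length, topo), con)
  writeLines(sprintf("DEFINITION  %s chloroplast genome.", record$id), con)
  writeLines(sprintf("ACCESSION   %s", record$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  write_feat <- function(key, loc, quals) {
    lead <- sprintf("     %-16s", key)
    # wrap location at commas to keep lines < 80 columns
    while (nchar(loc) > 58L) {
      commas <- which(strsplit(substr(loc, 1L, 58L), "")[[1]] == ",")
      if (length(commas) == 0L) break
      cut <- max(commas)
      writeLines(paste0(lead, substr(loc, 1L, cut)), con)
      loc <- substr(loc, cut + 1L, nchar(loc))
      lead <- strrep(" ", 21L)
    }
    writeLines(paste0(lead, loc), con)
    for (i in seq_along(quals)) {
      v <- quals[[i]]
      nm <- names(quals)[i]
      line <- if (nzchar(v) && !grepl("^\\d+$", v)) {
        sprintf("                     /%s=\"%s\"", nm, v)
      } else if (nzchar(v)) {
        sprintf("                     /%s=%s", nm, v)
      } else {
        sprintf("                     /%s", nm)
      }
      writeLines(line, con)
    }
  }
  write_feat("source", paste0("1..", record$length),
             c(organism = "synthetic construct"))
  for (f in record$features) {
    quals <- f$qualifiers
    if (!is.na(f$name) && !("gene" %in% names(quals))) {
      quals <- c(stats::setNames(f$name, "gene"), quals)
    }
    key <- if (f$kind == "misc") "misc_feature" else f$kind
    write_feat(key, format_location(f$parts), quals)
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$seq)
  for (pos in seq(1L, nchar(s), by = 60L)) {
    chunk_starts <- seq(pos, min(pos + 59L, nchar(s)), by = 10L)
    blocks <- substring(s, chunk_starts, pmin(chunk_starts + 9L, nchar(s)))
    writeLines(sprintf("%9d %s", pos, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

# GC fraction of a DNA string (ambiguity codes other than N count as N, i.e.
# they are excluded from neither numerator nor denominator adjustments: only
# A/C/G/T positions enter the denominator).
gc_fraction <- function(seq) {
  counts <- table(strsplit(seq, "")[[1]])
  acgt <- sum(counts[names(counts) %in% c("A", "C", "G", "T")])
  if (acgt == 0L) return(NA_real_)
  sum(counts[names(counts) %in% c("G", "C")]) / acgt
}

# Features of a record by kind.
features_of_kind <- function(record, kinds) {
  Filter(function(f) f$kind %in% kinds, record$features)
}
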