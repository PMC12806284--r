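# Batch nucleotide diversity (Nei-Li pi) over shared gene and intergenic
# spacer (IGS) regions across a set of annotated plastomes.

# Covering circular interval (start, length) of a gene feature.
gene_circular_span <- function(feature, L) {
  iv <- part_intervals(feature, L)
  # try both the direct frame and a half-rotated frame, keep the shorter span
  span_in_frame <- function(shift) {
    s <- (iv$gstart - shift) %% L
    e <- s + iv$glen
    c(start = min(s), len = max(e) - min(s))
  }
  a <- span_in_frame(0L)
  b <- span_in_frame(L %/% 2L)
  if (b["len"] < a["len"]) {
    c(start = (b[["start"]] + L %/% 2L) %% L, len = b[["len"]])
  } else {
    c(start = a[["start"]], len = a[["len"]])
  }
}

# The feature used to splice a named gene: its CDS/tRNA/rRNA record if
# present (introns removed), else the gene feature itself.
splice_feature_for <- function(record, name) {
  for (kind in c("CDS", "tRNA", "rRNA")) {
    for (f in features_of_kind(record, kind)) {
      if (!is.na(f$name) && f$name == name) return(f)
    }
  }
  NULL
}

#' Extract gene and intergenic-spacer regions from a record
#'
#' One region per annotated gene (spliced and strand-resolved) and one per
#' non-empty gap between consecutive gene spans in circular order. IGS regions
#' are named `"geneA-geneB"` after their flanking genes in genomic order;
#' zero-length gaps are omitted and overlapping genes produce no IGS.
#'
#' @param record an annotated [genome_record()] with at least 2 genes.
#' @return data.frame: name, kind (gene/IGS), start, length (circular
#'   interval of the region), seq, record_id.
#' @export
extract_regions <- function(record) {
  genes <- features_of_kind(record, "gene")
  genes <- Filter(function(f) !is.na(f$name), genes)
  if (length(genes) < 2L) {
    stop("record '", record$id, "' has fewer than 2 annotated genes")
  }
  L <- record$length
  spans <- t(vapply(genes, gene_circular_span, numeric(2), L = L))
  ord <- order(spans[, "start"])
  genes <- genes[ord]
  spans <- spans[ord, , drop = FALSE]
  rows <- list()
  for (i in seq_along(genes)) {
    f <- genes[[i]]
    sf <- splice_feature_for(record, f$name)
    if (is.null(sf)) sf <- f
    rows[[length(rows) + 1L]] <- data.frame(
      name = f$name, kind = "gene",
      start = spans[i, "start"], length = spans[i, "len"],
      seq = extract_feature_sequence(record, sf),
      record_id = record$id, stringsAsFactors = FALSE)
  }
  n <- length(genes)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    gap_start <- (spans[i, "start"] + spans[i, "len"]) %% L
    gap_len <- (spans[j, "start"] - gap_start) %% L
    # overlap detection: next gene starts inside the current span
    overlap <- ((spans[j, "start"] - spans[i, "start"]) %% L) < spans[i, "len"]
    if (gap_len == 0L || overlap) next
    # a wrap-around artifact: the 'gap' must not cover any gene start
    other_starts <- spans[-c(i), "start", drop = TRUE]
    covers_gene <- any(((other_starts - gap_start) %% L) < gap_len)
    if (covers_gene) next
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(genes[[i]]$name, "-", genes[[j]]$name), kind = "IGS",
      start = gap_start, length = gap_len,
      seq = seq_window(record$seq, gap_start, gap_len),
      record_id = record$id, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collect regions shared single-copy across all records
#'
#' Keeps only region names present exactly once in every record. Each element
#' of the result is a character vector of the region's sequences, named by
#' record id and ordered as the input; attributes `kind` and `midpoint` carry
#' the region class and its midpoint coordinate on the first record.
#'
#' @param records list of at least 2 [genome_record()] objects.
#' @return named list of character vectors.
#' @export
collect_shared_regions <- function(records) {
  if (length(records) < 2L) stop("need at least 2 records")
  region_tabs <- lapply(records, extract_regions)
  single_copy_names <- lapply(region_tabs, function(tab) {
    cnt <- table(tab$name)
    names(cnt)[cnt == 1L]
  })
  shared <- Reduce(intersect, single_copy_names)
  ref <- region_tabs[[1L]]
  L1 <- records[[1L]]$length
  out <- list()
  for (nm in shared) {
    seqs <- vapply(seq_along(records), function(k) {
      tab <- region_tabs[[k]]
      tab$seq[tab$name == nm]
    }, character(1))
    names(seqs) <- vapply(records, `[[`, character(1), "id")
    i <- match(nm, ref$name)
    attr(seqs, "kind") <- ref$kind[i]
    attr(seqs, "midpoint") <- (ref$start[i] + ref$length[i] / 2) %% L1
    out[[nm]] <- seqs
  }
  # stable genomic order on the reference record
  mids <- vapply(out, attr, numeric(1), "midpoint")
  out[order(mids)]
}

#' Nucleotide diversity of an alignment (Nei-Li pi)
#'
#' Columns containing any gap (`-`) or `N` are excluded entirely (complete
#' deletion, the DnaSP default) unless `deletion = "pairwise"`. Over the
#' remaining columns, pi is the mean per-site pairwise difference:
#' `sum(d_ij) / (choose(n, 2) * L')`.
#'
#' @param alignment character vector of >= 2 equal-length gapped DNA strings.
#' @param deletion "complete" (default) or "pairwise" handling of gap/N sites.
#' @return list: n, aln_len, sites_used, var_sites, pi.
#' @export
compute_pi <- function(alignment, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  n <- length(alignment)
  if (n < 2L) stop("need at least 2 sequences")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) stop("alignment rows have unequal lengths")
  L <- lens[1L]
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  npairs <- n * (n - 1) / 2
  if (deletion == "complete") {
    keep <- colSums(valid) == n
    if (!any(keep)) stop("no ungapped columns in alignment")
    m2 <- m[, keep, drop = FALSE]
    # pairwise differences per column from base counts
    diffs_per_col <- apply(m2, 2, function(col) {
      cnt <- tabulate(match(col, c("A", "C", "G", "T")), 4L)
      npairs - sum(choose(cnt, 2))
    })
    pi <- sum(diffs_per_col) / (npairs * sum(keep))
    list(n = n, aln_len = L, sites_used = sum(keep),
         var_sites = sum(diffs_per_col > 0), pi = pi)
  } else {
    tot_d <- 0
    tot_sites <- 0
    var_cols <- logical(L)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ok <- valid[i, ] & valid[j, ]
        if (!any(ok)) stop("a sequence pair shares no ungapped columns")
        d <- m[i, ok] != m[j, ok]
        tot_d <- tot_d + sum(d) / sum(ok)
        var_cols[which(ok)[d]] <- TRUE
      }
    }
    list(n = n, aln_len = L, sites_used = sum(colSums(valid) >= 2),
         var_sites = sum(var_cols), pi = tot_d / npairs)
  }
}

run_aligner <- function(template, infile, outfile) {
  cmd <- gsub("{out}", shQuote(outfile),
              gsub("{in}", shQuote(infile), template, fixed = TRUE), fixed = TRUE)
  status <- system(cmd, ignore.stdout = TRUE, ignore.stderr = TRUE)
  if (status != 0L || !file.exists(outfile)) {
    stop("aligner command failed: ", cmd)
  }
  outfile
}

#' Batch pi over shared regions of a genome set
#'
#' Reads every GenBank file in `path` (or, with `pre_aligned = TRUE`, every
#' FASTA alignment), normalizes orientation (LSC mode; skipped for genomes
#' without a detectable quadripartite structure), extracts shared single-copy
#' gene/IGS regions, aligns each region with the external `aligner` command
#' template (e.g. `"mafft --auto {in} > {out}"`; unnecessary when region
#' sequences are already equal-length), computes pi, and orders results by
#' genomic midpoint on the first genome.
#'
#' @param path directory of .gb/.gbk files, or of aligned .fa/.fasta files
#'   when `pre_aligned = TRUE`.
#' @param aligner external command template with `{in}`/`{out}` placeholders,
#'   or NULL for unaligned equal-length input.
#' @param pre_aligned treat `path` as per-region FASTA alignments.
#' @param out_dir optional directory to write per-region FASTA files.
#' @param deletion gap handling passed to [compute_pi()].
#' @return data.frame: region, kind, n, aln_len, var_sites, pi, midpoint.
#' @export
pi_pipeline <- function(path, aligner = NULL, pre_aligned = FALSE,
                        out_dir = NULL, deletion = "complete") {
  if (pre_aligned) {
    files <- list.files(path, pattern = "\\.(fa|fasta)$", full.names = TRUE)
    if (length(files) == 0L) stop("no FASTA alignments found in ", path)
    rows <- lapply(sort(files), function(f) {
      aln <- read_fasta(f)
      r <- compute_pi(unname(aln), deletion = deletion)
      data.frame(region = sub("\\.(fa|fasta)$", "", basename(f)), kind = NA,
                 n = r$n, aln_len = r$aln_len, var_sites = r$var_sites,
                 pi = r$pi, midpoint = NA_real_, stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  files <- sort(list.files(path, pattern = "\\.(gb|gbk|genbank)$", full.names = TRUE))
  if (length(files) < 2L) stop("need at least 2 GenBank files in ", path)
  records <- lapply(files, read_genbank)
  records <- lapply(records, function(r) {
    tryCatch(adjust_sequence(r, "LSC"), error = function(e) r)
  })
  shared <- collect_shared_regions(records)
  rows <- list()
  tmp <- tempfile("piwork")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  for (nm in names(shared)) {
    seqs <- shared[[nm]]
    safe <- gsub("[^A-Za-z0-9._-]", "_", nm)
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_fasta(seqs, file.path(out_dir, paste0(safe, ".fasta")))
    }
    aln <- if (!is.null(aligner)) {
      infile <- file.path(tmp, paste0(safe, ".fasta"))
      outfile <- file.path(tmp, paste0(safe, ".aln.fasta"))
      write_fasta(seqs, infile)
      unname(read_fasta(run_aligner(aligner, infile, outfile)))
    } else {
      if (length(unique(nchar(seqs))) != 1L) {
        stop("region '", nm, "' has unequal sequence lengths and no aligner ",
             "was given; pass aligner = \"mafft --auto {in} > {out}\" or ",
             "provide pre-aligned input")
      }
      unname(seqs)
    }
    r <- compute_pi(aln, deletion = deletion)
    rows[[length(rows) + 1L]] <- data.frame(
      region = nm, kind = attr(seqs, "kind"), n = r$n, aln_len = r$aln_len,
      var_sites = r$var_sites, pi = r$pi,
      midpoint = attr(seqs, "midpoint"), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$midpoint), ]
  rownames(out) <- NULL
  out
}
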