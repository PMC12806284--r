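# Annotation QC: CDS integrity checks, annotation comparison, genome stats.
# Stop codons follow translation table 11 (bacterial/plastid): TAA, TAG, TGA.

STOP_CODONS <- c("TAA", "TAG", "TGA")

finding <- function(record_id, gene, category, detail, severity) {
  data.frame(record_id = record_id, gene = gene, category = category,
             detail = detail, severity = severity, stringsAsFactors = FALSE)
}

empty_findings <- function() {
  data.frame(record_id = character(), gene = character(), category = character(),
             detail = character(), severity = character(), stringsAsFactors = FALSE)
}

# Resolve the gene name of a CDS: gene qualifier, then locus_tag, then the
# name of a gene feature containing the CDS span.
cds_gene_name <- function(record, cds) {
  if (!is.na(cds$name) && nzchar(cds$name)) return(cds$name)
  lt <- cds$qualifiers[["locus_tag"]]
  if (!is.null(lt) && nzchar(lt)) return(lt)
  span <- feature_span(cds)
  for (g in features_of_kind(record, "gene")) {
    gs <- feature_span(g)
    if (gs[1] <= span[1] && gs[2] >= span[2] && !is.na(g$name)) return(g$name)
  }
  "(unnamed CDS)"
}

#' Check the CDS annotations of a record
#'
#' For every CDS (spliced, strand-resolved) reports: `non_atg_start` when the
#' first codon is not ATG (a warning, since RNA-edited GTG/ACG starts occur in
#' plastids), `missing_stop` when the last codon is not TAA/TAG/TGA,
#' `internal_stop` when an in-frame stop occurs before the final codon, and
#' `length_not_multiple_of_3`. Gene names occurring more often than an
#' inverted-repeat pair can explain (more than twice) yield `duplicate_name`;
#' trans-spliced (mixed-strand) features yield `parse_warning`.
#'
#' @param record a [genome_record()].
#' @return data.frame with columns record_id, gene, category, detail, severity.
#' @export
check_record <- function(record) {
  out <- list()
  cds <- features_of_kind(record, "CDS")
  if (length(cds) == 0L) {
    return(finding(record$id, NA_character_, "parse_warning",
                   "record has no CDS features", "warning"))
  }
  for (f in cds) {
    gene <- cds_gene_name(record, f)
    s <- extract_feature_sequence(record, f)
    n <- nchar(s)
    if (n %% 3L != 0L) {
      out[[length(out) + 1L]] <- finding(record$id, gene, "length_not_multiple_of_3",
                                         sprintf("spliced length %d", n), "error")
    }
    first <- substr(s, 1L, 3L)
    if (first != "ATG") {
      out[[length(out) + 1L]] <- finding(record$id, gene, "non_atg_start",
                                         sprintf("starts with %s", first), "warning")
    }
    ncod <- n %/% 3L
    if (ncod >= 1L) {
      codons <- substring(s, seq(1L, ncod * 3L, by = 3L), seq(3L, ncod * 3L, by = 3L))
      if (!codons[ncod] %in% STOP_CODONS) {
        out[[length(out) + 1L]] <- finding(record$id, gene, "missing_stop",
                                           sprintf("ends with %s", codons[ncod]),
                                           "error")
      }
      internal <- which(codons[-ncod] %in% STOP_CODONS)
      if (length(internal)) {
        out[[length(out) + 1L]] <- finding(record$id, gene, "internal_stop",
                                           sprintf("in-frame stop at codon %s",
                                                   paste(internal, collapse = ",")),
                                           "error")
      }
    }
    if (length(unique(f$parts$strand)) > 1L) {
      out[[length(out) + 1L]] <- finding(record$id, gene, "parse_warning",
                                         "trans-spliced (mixed-strand) CDS; parts kept in file order",
                                         "warning")
    }
  }
  nm <- vapply(cds, function(f) cds_gene_name(record, f), character(1))
  tab <- table(nm)
  for (g in names(tab)[tab > 2L]) {
    out[[length(out) + 1L]] <- finding(record$id, g, "duplicate_name",
                                       sprintf("%d CDS copies", tab[[g]]), "warning")
  }
  if (length(out) == 0L) return(empty_findings())
  do.call(rbind, out)
}

#' Compare gene annotations between two records
#'
#' Set differences by gene name; genes shared by both are additionally
#' compared on part count and strand.
#'
#' @param query,reference [genome_record()] objects.
#' @return list with `query_only`, `reference_only` (character vectors) and
#'   `differing` (data.frame: gene, query_parts, ref_parts, query_strand,
#'   ref_strand for shared genes whose structure differs).
#' @export
compare_annotations <- function(query, reference) {
  gene_table <- function(rec) {
    gf <- features_of_kind(rec, "gene")
    if (length(gf) == 0L) gf <- Filter(function(f) !is.na(f$name), rec$features)
    nm <- vapply(gf, function(f) f$name, character(1))
    keep <- !is.na(nm)
    list(names = nm[keep], feats = gf[keep])
  }
  q <- gene_table(query)
  r <- gene_table(reference)
  query_only <- sort(setdiff(q$names, r$names))
  reference_only <- sort(setdiff(r$names, q$names))
  shared <- intersect(q$names, r$names)
  diffs <- list()
  for (g in shared) {
    fq <- q$feats[[match(g, q$names)]]
    fr <- r$feats[[match(g, r$names)]]
    np_q <- length(unique(fq$parts$part))
    np_r <- length(unique(fr$parts$part))
    st_q <- fq$parts$strand[1]
    st_r <- fr$parts$strand[1]
    if (np_q != np_r || st_q != st_r) {
      diffs[[length(diffs) + 1L]] <- data.frame(
        gene = g, query_parts = np_q, ref_parts = np_r,
        query_strand = st_q, ref_strand = st_r, stringsAsFactors = FALSE)
    }
  }
  differing <- if (length(diffs)) do.call(rbind, diffs) else
    data.frame(gene = character(), query_parts = integer(), ref_parts = integer(),
               query_strand = character(), ref_strand = character())
  list(query_only = query_only, reference_only = reference_only,
       differing = differing)
}

#' Genome statistics
#'
#' Gene counts by class, unique gene count (inverted-repeat duplicates
#' collapsed by name), exon/intron counts per gene, and GC content (overall
#' and per quadripartite region when a structure is supplied).
#'
#' @param record a [genome_record()].
#' @param structure optional result of [find_inverted_repeats()].
#' @return list with fields total_genes, unique_genes, class_counts,
#'   gene_table (data.frame: gene, class, exons, introns), gc, gc_by_region.
#' @export
summarize_genome <- function(record, structure = NULL) {
  genes <- features_of_kind(record, "gene")
  nm <- vapply(genes, function(f) ifelse(is.na(f$name), "(unnamed)", f$name),
               character(1))
  class_of <- function(name) {
    for (kind in c("CDS", "tRNA", "rRNA")) {
      for (f in features_of_kind(record, kind)) {
        if (!is.na(f$name) && f$name == name) {
          return(switch(kind, CDS = "protein_coding", tRNA = "tRNA", rRNA = "rRNA"))
        }
      }
    }
    "other"
  }
  exon_count <- function(name) {
    for (kind in c("CDS", "tRNA", "rRNA")) {
      for (f in features_of_kind(record, kind)) {
        if (!is.na(f$name) && f$name == name) return(length(unique(f$parts$part)))
      }
    }
    1L
  }
  cls <- vapply(nm, class_of, character(1))
  exons <- vapply(nm, exon_count, integer(1))
  gene_table <- data.frame(gene = nm, class = cls, exons = exons,
                           introns = pmax(exons - 1L, 0L), stringsAsFactors = FALSE)
  gc_by_region <- NULL
  if (!is.null(structure)) {
    gc_by_region <- vapply(c("LSC", "IRb", "SSC", "IRa"), function(rg) {
      iv <- structure$regions[structure$regions$region == rg, ]
      gc_fraction(seq_window(record$seq, iv$start, iv$length))
    }, numeric(1))
  }
  list(total_genes = length(genes),
       unique_genes = length(unique(nm)),
       class_counts = c(protein_coding = sum(cls == "protein_coding"),
                        tRNA = sum(cls == "tRNA"),
                        rRNA = sum(cls == "rRNA"),
                        other = sum(cls == "other")),
       gene_table = gene_table[order(gene_table$gene), ],
       gc = gc_fraction(record$seq),
       gc_by_region = gc_by_region)
}
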