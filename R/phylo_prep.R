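# Preparation of shared-gene matrices and concatenated supermatrices for
# phylogenetic inference. Alignment and tree building are delegated to
# external programs; only their inputs are produced here.

translate_cds <- function(s, code = "11") {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(s),
    genetic.code = Biostrings::getGeneticCode(code),
    if.fuzzy.codon = "solve"))
  sub("\\*$", "", aa)
}

#' Extract shared single-copy CDS (or protein) sequences across records
#'
#' Genes present single-copy in every record are kept. Inverted-repeat
#' duplicated genes with byte-identical spliced copies are deduplicated
#' silently; genes with divergent copies in any record are dropped with a
#' warning. In protein mode, CDS are translated with table 11 and the
#' terminal stop trimmed; gene/record pairs with internal stop codons or
#' out-of-frame lengths cause the gene to be dropped from protein mode.
#'
#' @param records list of >= 2 [genome_record()] objects.
#' @param molecule "CDS" or "protein".
#' @return list: molecule, ids, genes (named list, gene -> named character
#'   vector of one sequence per record, in input order).
#' @export
extract_shared_cds <- function(records, molecule = c("CDS", "protein")) {
  molecule <- match.arg(molecule)
  if (length(records) < 2L) stop("need at least 2 records")
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate record ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  per_record <- lapply(records, function(rec) {
    cds <- features_of_kind(rec, "CDS")
    nm <- vapply(cds, function(f) cds_gene_name(rec, f), character(1))
    seqs <- vapply(cds, function(f) extract_feature_sequence(rec, f), character(1))
    out <- character()
    for (g in unique(nm)) {
      copies <- unique(seqs[nm == g])
      if (length(copies) == 1L) {
        out[g] <- copies
      } else {
        warning("gene '", g, "' has divergent copies in record '", rec$id,
                "'; dropped")
      }
    }
    out
  })
  shared <- Reduce(intersect, lapply(per_record, names))
  if (molecule == "protein") {
    keep <- character()
    for (g in shared) {
      ok <- TRUE
      for (k in seq_along(records)) {
        s <- per_record[[k]][[g]]
        if (nchar(s) %% 3L != 0L) { ok <- FALSE; break }
        aa <- translate_cds(s)
        if (grepl("*", aa, fixed = TRUE)) { ok <- FALSE; break }
      }
      if (ok) keep <- c(keep, g)
      else warning("gene '", g, "' dropped from protein mode (internal stop ",
                   "or out-of-frame length)")
    }
    shared <- keep
  }
  if (length(shared) == 0L) stop("no shared single-copy genes across records")
  genes <- lapply(stats::setNames(shared, shared), function(g) {
    s <- vapply(per_record, `[[`, character(1), g)
    if (molecule == "protein") s <- vapply(s, translate_cds, character(1))
    stats::setNames(unname(s), ids)
  })
  list(molecule = molecule, ids = ids, genes = genes)
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Genes are concatenated in alphabetical order regardless of input order;
#' a 1-based inclusive partition table maps each gene to its column interval.
#'
#' @param aligned named list: gene -> named character vector of equal-length
#'   gapped sequences, the same id set for every gene.
#' @return list: ids, matrix (named character vector of concatenated rows),
#'   partitions (data.frame gene, start, end).
#' @export
concatenate_matrix <- function(aligned) {
  if (length(aligned) == 0L) stop("no gene alignments supplied")
  aligned <- aligned[order(names(aligned))]
  ids <- sort(names(aligned[[1L]]))
  for (g in names(aligned)) {
    rows <- aligned[[g]]
    if (!setequal(names(rows), ids)) {
      stop("gene '", g, "' does not cover the same id set as the others")
    }
    if (length(unique(nchar(rows))) != 1L) {
      stop("gene '", g, "' alignment rows have unequal lengths")
    }
  }
  mat <- stats::setNames(rep("", length(ids)), ids)
  parts <- list()
  col <- 0L
  for (g in names(aligned)) {
    rows <- aligned[[g]][ids]
    len <- nchar(rows[[1L]])
    mat <- paste0(mat, rows)
    parts[[length(parts) + 1L]] <- data.frame(gene = g, start = col + 1L,
                                              end = col + len)
    col <- col + len
  }
  names(mat) <- ids
  list(ids = ids, matrix = mat, partitions = do.call(rbind, parts))
}

#' Write a supermatrix as FASTA, relaxed PHYLIP and a RAxML-style partition file
#'
#' @param sm result of [concatenate_matrix()].
#' @param prefix output path prefix; writes `<prefix>.fasta`, `<prefix>.phy`
#'   and `<prefix>.partitions`.
#' @param datatype partition data type label (default "DNA").
#' @return invisibly, the three paths.
#' @export
write_supermatrix <- function(sm, prefix, datatype = "DNA") {
  fa <- paste0(prefix, ".fasta")
  phy <- paste0(prefix, ".phy")
  part <- paste0(prefix, ".partitions")
  write_fasta(sm$matrix, fa)
  con <- file(phy, "w")
  writeLines(sprintf(" %d %d", length(sm$matrix), nchar(sm$matrix[[1L]])), con)
  writeLines(sprintf("%s  %s", names(sm$matrix), sm$matrix), con)
  close(con)
  writeLines(sprintf("%s, %s = %d-%d", datatype, sm$partitions$gene,
                     sm$partitions$start, sm$partitions$end), part)
  invisible(c(fa, phy, part))
}

#' Merge whole genomes into one multi-FASTA after orientation adjustment
#'
#' Each record is first normalized to canonical orientation (LSC mode;
#' records without a detectable quadripartite structure are kept as-is with
#' a warning).
#'
#' @param records list of >= 2 [genome_record()] objects with unique ids.
#' @param mode orientation mode passed to [adjust_sequence()].
#' @return named character vector of sequences (write with [write_fasta()]).
#' @export
merge_whole_genomes <- function(records, mode = "LSC") {
  if (length(records) < 2L) stop("need at least 2 records")
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  adj <- lapply(records, function(r) {
    tryCatch(adjust_sequence(r, mode),
             error = function(e) {
               warning("record '", r$id, "' not adjusted: ", conditionMessage(e))
               r
             })
  })
  stats::setNames(vapply(adj, `[[`, character(1), "seq"), ids)
}
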