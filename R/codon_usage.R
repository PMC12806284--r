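# Relative synonymous codon usage (RSCU) from plastome protein-coding genes.

#' CDS filtering for codon-usage analysis
#'
#' Splices and strand-resolves every CDS, then drops: CDS shorter than
#' `min_length`, CDS whose length is not a multiple of 3, CDS not starting
#' with ATG, and duplicate gene names (the first occurrence is kept, so each
#' inverted-repeat-duplicated gene is counted once).
#'
#' @param record a [genome_record()] with CDS features.
#' @param min_length minimum spliced CDS length in bp (default 300).
#' @return named character vector of retained CDS sequences, with attribute
#'   `dropped` (data.frame gene/reason). Zero survivors is an error.
#' @export
collect_cds_for_rscu <- function(record, min_length = 300L) {
  cds <- features_of_kind(record, "CDS")
  if (length(cds) == 0L) stop("record '", record$id, "' has no CDS features")
  kept <- character()
  dropped <- list()
  for (f in cds) {
    gene <- cds_gene_name(record, f)
    s <- extract_feature_sequence(record, f)
    reason <- NULL
    if (gene %in% names(kept)) reason <- "duplicate gene name"
    else if (nchar(s) < min_length) reason <- sprintf("length %d < %d", nchar(s), min_length)
    else if (nchar(s) %% 3L != 0L) reason <- "length not a multiple of 3"
    else if (substr(s, 1L, 3L) != "ATG") reason <- "non-ATG start"
    if (is.null(reason)) {
      kept[gene] <- s
    } else {
      dropped[[length(dropped) + 1L]] <- data.frame(gene = gene, reason = reason,
                                                    stringsAsFactors = FALSE)
    }
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(gene = character(), reason = character())
  if (length(kept) == 0L) {
    stop("no CDS passed the RSCU filters:\n",
         paste(sprintf("  %s: %s", dropped$gene, dropped$reason), collapse = "\n"))
  }
  attr(kept, "dropped") <- dropped
  kept
}

#' Relative synonymous codon usage
#'
#' Codons are pooled over all CDS (the terminal stop codon of each CDS is
#' trimmed before counting). For codon c in synonym family F,
#' `rscu(c) = x_c / (sum(x_F) / |F|)`. Stop codons are excluded from the
#' table; the single-codon families ATG (Met) and TGG (Trp) are reported with
#' RSCU 1 when observed. Families with zero total get RSCU 0 and are flagged.
#'
#' @param cds_set character vector of CDS sequences (length multiple of 3).
#' @param code NCBI translation table id (default "11", bacterial/plastid).
#' @return data.frame: codon, aa, count, family_size, rscu, zero_family.
#' @export
compute_rscu <- function(cds_set, code = "11") {
  if (any(nchar(cds_set) %% 3L != 0L)) {
    stop("every CDS length must be a multiple of 3")
  }
  gc_map <- Biostrings::getGeneticCode(code)
  codons_all <- unlist(lapply(cds_set, function(s) {
    ncod <- nchar(s) %/% 3L
    cods <- substring(s, seq(1L, by = 3L, length.out = ncod),
                      seq(3L, by = 3L, length.out = ncod))
    # trim the terminal stop codon
    if (ncod > 0L && gc_map[cods[ncod]] %in% "*" ) cods <- cods[-ncod]
    cods
  }), use.names = FALSE)
  codons_all <- codons_all[codons_all %in% names(gc_map)]
  counts <- table(factor(codons_all, levels = names(gc_map)))
  tab <- data.frame(codon = names(gc_map), aa = unname(gc_map),
                    count = as.integer(counts), stringsAsFactors = FALSE)
  tab <- tab[tab$aa != "*", ]
  fam_size <- table(tab$aa)
  fam_total <- tapply(tab$count, tab$aa, sum)
  tab$family_size <- as.integer(fam_size[tab$aa])
  ft <- as.numeric(fam_total[tab$aa])
  tab$zero_family <- ft == 0
  tab$rscu <- ifelse(tab$zero_family, 0, tab$count / (ft / tab$family_size))
  rownames(tab) <- NULL
  tab[order(tab$aa, tab$codon), c("codon", "aa", "count", "family_size",
                                  "rscu", "zero_family")]
}
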