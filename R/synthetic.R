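# Deterministic synthetic-plastome generator with a machine-readable truth
# ledger. Emits annotated quadripartite genomes (LSC + IRb + SSC + IRa with
# IRa = revcomp(IRb)) carrying planted genes (valid ORFs, optional introns),
# planted SSRs with known genomic context, and a planted dispersed repeat
# pair. Backgrounds are rejection-sampled until every analysis module
# reproduces the ledger exactly.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random ORF: ATG + (len/3 - 2) random sense codons + TAA.
random_orf <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1L, paste, collapse = "")
  sense <- setdiff(codons, c(STOP_CODONS, "ATG"))
  paste0("ATG", paste(sample(sense, len %/% 3L - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

substr_set <- function(s, start0, value) {
  # overwrite s at 0-based position start0
  paste0(substr(s, 1L, start0), value,
         substr(s, start0 + nchar(value) + 1L, nchar(s)))
}

# A flank base that cannot extend a period-k run whose forbidden char is `bad`.
break_base <- function(bad) setdiff(c("A", "C", "G", "T"), bad)[1L]

default_gene_plan <- function() {
  list(
    LSC = list(
      list(name = "trnH-GUG", kind = "tRNA", len = 74L,  strand = "+", intron = 0L),
      list(name = "psbA",     kind = "CDS",  len = 1062L, strand = "-", intron = 0L),
      list(name = "matK",     kind = "CDS",  len = 900L,  strand = "+", intron = 0L),
      list(name = "atpF",     kind = "CDS",  len = 555L,  strand = "+", intron = 700L),
      list(name = "rbcL",     kind = "CDS",  len = 1428L, strand = "+", intron = 0L),
      list(name = "petB",     kind = "CDS",  len = 648L,  strand = "+", intron = 0L)),
    IRb = list(
      list(name = "rrn16",    kind = "rRNA", len = 1490L, strand = "+", intron = 0L)),
    SSC = list(
      list(name = "ndhF",     kind = "CDS",  len = 1500L, strand = "-", intron = 0L),
      list(name = "ccsA",     kind = "CDS",  len = 960L,  strand = "-", intron = 0L)))
}

# planted SSRs: unit, count, and where (region gap index or intron gene)
default_ssr_plan <- function() {
  list(
    list(unit = "AACGTC", count = 4L, where = "LSC", gap = 2L),
    list(unit = "A",      count = 12L, where = "LSC", gap = 3L),
    list(unit = "AT",     count = 7L,  where = "LSC", gap = 4L),
    list(unit = "AGC",    count = 6L,  where = "intron", gene = "atpF"),
    list(unit = "AACT",   count = 5L,  where = "LSC", gap = 5L),
    list(unit = "AACAT",  count = 4L,  where = "LSC", gap = 6L),
    list(unit = "C",      count = 10L, where = "SSC", gap = 2L))
}

build_attempt <- function(lsc_len, ir_len, ssc_len, gene_plan, ssr_plan,
                          lsr_arm, id) {
  L <- lsc_len + 2L * ir_len + ssc_len
  region_start <- c(LSC = 0L, IRb = lsc_len, SSC = lsc_len + ir_len,
                    IRa = lsc_len + ir_len + ssc_len)
  region_len <- c(LSC = lsc_len, IRb = ir_len, SSC = ssc_len, IRa = ir_len)

  # lay genes out left-to-right in each region with equal gaps
  features <- list()
  gene_rows <- list()
  layout <- list()   # per region: gap intervals and gene order
  seqs <- list()
  for (rg in c("LSC", "IRb", "SSC")) {
    plan <- gene_plan[[rg]]
    rlen <- region_len[[rg]]
    footprint <- sum(vapply(plan, function(g) g$len + g$intron, numeric(1)))
    ngap <- length(plan) + 1L
    gap <- (rlen - footprint) %/% ngap
    if (gap < 60L) stop("region ", rg, " too small for its gene plan")
    bg <- random_dna(rlen)
    pos <- gap                       # region-relative 0-based cursor
    gaps <- data.frame(idx = 1L, start = 0L, end = gap)
    for (gi in seq_along(plan)) {
      g <- plan[[gi]]
      orf <- if (g$kind == "CDS") random_orf(g$len) else random_dna(g$len)
      gene_start <- pos
      gene_len <- g$len + g$intron
      if (g$intron > 0L) {
        e1 <- (g$len * 2L) %/% 3L    # split point inside the coding sequence
        e2 <- g$len - e1
        ins <- if (g$strand == "+") {
          paste0(substr(orf, 1L, e1), random_dna(g$intron),
                 substr(orf, e1 + 1L, g$len))
        } else {
          ro <- revcomp(orf)
          paste0(substr(ro, 1L, e2), random_dna(g$intron),
                 substr(ro, e2 + 1L, g$len))
        }
        abs_start <- region_start[[rg]] + gene_start
        left_len <- if (g$strand == "+") e1 else e2
        p_left <- c(abs_start, abs_start + left_len)
        p_right <- c(abs_start + left_len + g$intron, abs_start + gene_len)
        parts <- if (g$strand == "+") {
          data.frame(start = c(p_left[1], p_right[1]),
                     end = c(p_left[2], p_right[2]), strand = "+", part = 1:2)
        } else {
          # biological order: downstream exon first on the minus strand
          data.frame(start = c(p_right[1], p_left[1]),
                     end = c(p_right[2], p_left[2]), strand = "-", part = 1:2)
        }
        bg <- substr_set(bg, gene_start, ins)
        features <- c(features, list(
          feature_annotation("gene", g$name,
                             data.frame(start = abs_start, end = abs_start + gene_len,
                                        strand = g$strand, part = 1L)),
          feature_annotation(g$kind, g$name, parts)))
      } else {
        ins <- if (g$strand == "+") orf else revcomp(orf)
        abs_start <- region_start[[rg]] + gene_start
        bg <- substr_set(bg, gene_start, ins)
        parts <- data.frame(start = abs_start, end = abs_start + gene_len,
                            strand = g$strand, part = 1L)
        features <- c(features, list(
          feature_annotation("gene", g$name, parts),
          feature_annotation(g$kind, g$name, parts)))
      }
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        name = g$name, kind = g$kind, region = rg,
        start = region_start[[rg]] + gene_start,
        end = region_start[[rg]] + gene_start + gene_len,
        strand = g$strand, exons = if (g$intron > 0L) 2L else 1L,
        stringsAsFactors = FALSE)
      pos <- pos + gene_len
      gaps <- rbind(gaps, data.frame(idx = gi + 1L, start = pos, end = pos + gap))
      pos <- pos + gap
    }
    layout[[rg]] <- gaps
    seqs[[rg]] <- bg
  }

  # plant SSRs (region-relative, centered in their assigned gap/intron)
  ssr_rows <- list()
  plant <- function(region, rel_start, unit, count, context, context_name) {
    run <- strrep(unit, count)
    k <- nchar(unit)
    s <- seqs[[region]]
    s <- substr_set(s, rel_start, run)
    s <- substr_set(s, rel_start - 1L, break_base(substr(unit, k, k)))
    s <- substr_set(s, rel_start + nchar(run), break_base(substr(unit, 1L, 1L)))
    seqs[[region]] <<- s
    abs_start <- region_start[[region]] + rel_start
    ssr_rows[[length(ssr_rows) + 1L]] <<- data.frame(
      motif = canonical_motif(unit), unit = unit, motif_length = k,
      count = count, start = abs_start, end = abs_start + count * k,
      context = context, context_name = context_name, stringsAsFactors = FALSE)
  }
  gene_df <- do.call(rbind, gene_rows)
  flank_name <- function(region, gap_idx) {
    plan <- gene_plan[[region]]
    left <- if (gap_idx == 1L) NA else plan[[gap_idx - 1L]]$name
    right <- if (gap_idx > length(plan)) NA else plan[[gap_idx]]$name
    if (is.na(left)) {
      # circularly previous gene (last gene of the preceding region)
      prev <- switch(region, LSC = "rrn16", IRb = tail_name(gene_plan$LSC),
                     SSC = "rrn16", IRa = tail_name(gene_plan$SSC))
      left <- prev
    }
    if (is.na(right)) {
      nxt <- switch(region, LSC = head_name(gene_plan$IRb),
                    IRb = head_name(gene_plan$SSC), SSC = "rrn16")
      right <- nxt
    }
    paste0(left, "-", right)
  }
  for (p in ssr_plan) {
    runlen <- nchar(p$unit) * p$count
    if (p$where == "intron") {
      row <- gene_df[gene_df$name == p$gene, ]
      g <- Filter(function(x) x$name == p$gene, gene_plan[[row$region]])[[1L]]
      e1 <- (g$len * 2L) %/% 3L
      if (g$strand != "+") e1 <- g$len - e1
      intron_start <- (row$start - region_start[[row$region]]) + e1
      rel <- intron_start + (g$intron - runlen) %/% 2L
      plant(row$region, rel, p$unit, p$count, "intron", p$gene)
    } else {
      gaps <- layout[[p$where]]
      gp <- gaps[gaps$idx == p$gap, ]
      rel <- gp$start + (gp$end - gp$start - runlen) %/% 2L
      plant(p$where, rel, p$unit, p$count, "IGS", flank_name(p$where, p$gap))
    }
  }

  # plant one forward long-repeat pair in the last LSC gap
  gaps <- layout$LSC
  gp <- gaps[gaps$idx == max(gaps$idx), ]
  width <- gp$end - gp$start
  a1 <- gp$start + width %/% 4L
  a2 <- gp$start + (3L * width) %/% 4L
  arm <- substr(seqs$LSC, a1 + 1L, a1 + lsr_arm)
  s <- substr_set(seqs$LSC, a2, arm)
  # maximality: the bases flanking the two copies must differ pairwise
  if (substr(s, a1, a1) == substr(s, a2, a2)) {
    s <- substr_set(s, a2 - 1L, break_base(substr(s, a1, a1)))
  }
  r1 <- a1 + lsr_arm + 1L
  r2 <- a2 + lsr_arm + 1L
  if (substr(s, r1, r1) == substr(s, r2, r2)) {
    s <- substr_set(s, r2 - 1L, break_base(substr(s, r1, r1)))
  }
  seqs$LSC <- s
  lsr_row <- data.frame(type = "forward", length = lsr_arm,
                        start1 = a1, end1 = a1 + lsr_arm,
                        start2 = a2, end2 = a2 + lsr_arm, stringsAsFactors = FALSE)

  # junction bases: block IR extension beyond the construction joints
  seqs$LSC <- substr_set(seqs$LSC, 0L, "A")
  seqs$LSC <- substr_set(seqs$LSC, lsc_len - 1L, "A")
  seqs$SSC <- substr_set(seqs$SSC, 0L, "A")
  seqs$SSC <- substr_set(seqs$SSC, ssc_len - 1L, "A")

  ira <- revcomp(seqs$IRb)
  seq <- paste0(seqs$LSC, seqs$IRb, seqs$SSC, ira)
  stopifnot(nchar(seq) == L)

  # mirror IRb gene annotations into IRa
  ira_start <- region_start[["IRa"]]
  irb_start <- region_start[["IRb"]]
  for (g in gene_plan$IRb) {
    row <- gene_df[gene_df$name == g$name & gene_df$region == "IRb", ]
    off_start <- row$start - irb_start
    off_end <- row$end - irb_start
    m_start <- ira_start + (ir_len - off_end)
    m_end <- ira_start + (ir_len - off_start)
    strand2 <- if (row$strand == "+") "-" else "+"
    parts <- data.frame(start = m_start, end = m_end, strand = strand2, part = 1L)
    features <- c(features, list(
      feature_annotation("gene", g$name, parts),
      feature_annotation(g$kind, g$name, parts)))
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      name = g$name, kind = g$kind, region = "IRa", start = m_start,
      end = m_end, strand = strand2, exons = 1L, stringsAsFactors = FALSE)
  }

  record <- genome_record(id, seq, features, circular = TRUE)
  regions <- data.frame(region = names(region_start),
                        start = unname(region_start),
                        end = unname(region_start + region_len),
                        length = unname(region_len), stringsAsFactors = FALSE)
  list(record = record,
       ledger = list(regions = regions,
                     genes = do.call(rbind, gene_rows),
                     ssrs = do.call(rbind, ssr_rows),
                     lsrs = lsr_row))
}

tail_name <- function(plan) plan[[length(plan)]]$name
head_name <- function(plan) plan[[1L]]$name

#' Generate a synthetic annotated plastome with a truth ledger
#'
#' Builds LSC + IRb + SSC + IRa with IRa the exact reverse complement of IRb,
#' genes written as valid ORFs (ATG...stop, no internal stops, optional
#' introns), planted SSRs of every motif class in known contexts, and one
#' planted forward repeat pair. The random background is rejection-sampled
#' (up to `max_tries` attempts) until the SSR, long-repeat and
#' inverted-repeat detectors reproduce the plant plan exactly, so the ledger
#' is verifiable against the emitted sequence by direct inspection. The same
#' seed yields byte-identical output.
#'
#' @param preset "small" (default; 33 kb: LSC 20000, IR 2500, SSC 8000) or
#'   "plastome-like" (154 kb: LSC 86000, IR 25000, SSC 18000).
#' @param seed integer seed driving all randomness.
#' @param lsc_length,ir_length,ssc_length region sizes in bp (override preset).
#' @param id record identifier.
#' @param detection_seed inverted-repeat seed length the genome is screened
#'   against (default 1000).
#' @param lsr_arm arm length of the planted forward repeat (default 40).
#' @param max_tries rejection-sampling cap; exceeding it is an error.
#' @return list(record = [genome_record()], ledger = list(regions, genes,
#'   ssrs, lsrs, seed)).
#' @export
generate_synthetic_plastome <- function(preset = c("small", "plastome-like"),
                                        seed = 42L,
                                        lsc_length = NULL, ir_length = NULL,
                                        ssc_length = NULL,
                                        id = "synthetic_plastome",
                                        detection_seed = 1000L,
                                        lsr_arm = 40L, max_tries = 1000L) {
  preset <- match.arg(preset)
  sizes <- if (preset == "small") c(20000L, 2500L, 8000L)
           else c(86000L, 25000L, 18000L)
  lsc <- if (is.null(lsc_length)) sizes[1] else as.integer(lsc_length)
  ir <- if (is.null(ir_length)) sizes[2] else as.integer(ir_length)
  ssc <- if (is.null(ssc_length)) sizes[3] else as.integer(ssc_length)
  if (lsc <= 0L || ir <= 0L || ssc <= 0L) stop("region sizes must be positive")
  if (ir < detection_seed) stop("IR length must be >= the detection seed length")
  if (lsc < ssc) stop("LSC must be at least as long as SSC")
  gene_plan <- default_gene_plan()
  ssr_plan <- default_ssr_plan()

  for (attempt in seq_len(max_tries)) {
    sub_seed <- (as.numeric(seed) * 7919 + attempt) %% 2147483647
    built <- with_seed(sub_seed, build_attempt(lsc, ir, ssc, gene_plan,
                                               ssr_plan, lsr_arm, id))
    rec <- built$record
    led <- built$ledger
    # closure screens: detectors must reproduce the plan exactly
    ssr_hits <- find_ssrs(rec$seq)
    plan_tab <- led$ssrs[order(led$ssrs$start),
                         c("motif", "unit", "motif_length", "count", "start", "end")]
    rownames(plan_tab) <- NULL
    ok_ssr <- isTRUE(all.equal(ssr_hits, plan_tab, check.attributes = FALSE))
    st <- find_inverted_repeats(rec$seq, detection_seed)
    ok_ir <- !is.null(st) && st$ir_length == ir &&
      all(st$regions$start[match(c("LSC", "IRb", "SSC", "IRa"),
                                 st$regions$region)] ==
            led$regions$start[match(c("LSC", "IRb", "SSC", "IRa"),
                                    led$regions$region)])
    ok_lsr <- TRUE
    if (ok_ssr && ok_ir) {
      lsr_hits <- find_lsrs(rec$seq, min_arm = min(30L, lsr_arm))
      fwd <- lsr_hits[lsr_hits$type == "forward", ]
      pal <- lsr_hits[lsr_hits$type == "palindromic", ]
      ok_lsr <- nrow(fwd) == 1L && fwd$start1 == led$lsrs$start1 &&
        fwd$start2 == led$lsrs$start2 && fwd$length == led$lsrs$length &&
        nrow(pal) == 1L && pal$length == ir &&
        nrow(lsr_hits[lsr_hits$type %in% c("reverse", "complement"), ]) == 0L
    }
    if (ok_ssr && ok_ir && ok_lsr) {
      led$seed <- seed
      led$attempt <- attempt
      return(list(record = rec, ledger = led))
    }
  }
  stop("could not generate a clean synthetic plastome in ", max_tries,
       " attempts; relax the plan or change the seed")
}

#' Generate a mutated population from a base genome
#'
#' Applies independent point substitutions (no indels) at a per-site rate,
#' either one genome-wide rate or one rate per quadripartite region.
#' Annotations are carried over unchanged, so the genomes stay alignment-free
#' comparable position by position.
#'
#' @param base a [genome_record()].
#' @param n number of genomes (>= 2).
#' @param rates single per-site substitution rate in `[0, 0.2]`, or a named
#'   vector `c(LSC=, IRb=, SSC=, IRa=)`.
#' @param seed integer seed.
#' @param structure optional `quadripartite_structure` (required for
#'   per-region rates; detected from the sequence when omitted).
#' @return list of n [genome_record()] objects, ids suffixed `_1..n`.
#' @export
generate_population <- function(base, n, rates, seed = 1L, structure = NULL) {
  if (n < 2L) stop("n must be >= 2")
  if (any(rates < 0) || any(rates > 0.2)) stop("rates must be in [0, 0.2]")
  L <- base$length
  site_rate <- rep(NA_real_, L)
  if (length(rates) == 1L && is.null(names(rates))) {
    site_rate[] <- rates
  } else {
    if (is.null(structure)) structure <- find_inverted_repeats(base$seq)
    if (is.null(structure)) stop("per-region rates need a detectable structure")
    for (i in seq_len(nrow(structure$regions))) {
      rg <- structure$regions$region[i]
      if (!rg %in% names(rates)) stop("no rate given for region ", rg)
      idx0 <- (structure$regions$start[i] + seq_len(structure$regions$length[i]) - 1L) %% L
      site_rate[idx0 + 1L] <- rates[[rg]]
    }
  }
  chars <- strsplit(base$seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    lapply(seq_len(n), function(k) {
      mut <- which(stats::runif(L) < site_rate & chars %in% bases)
      newchars <- chars
      for (i in mut) {
        newchars[i] <- sample(setdiff(bases, chars[i]), 1L)
      }
      genome_record(paste0(base$id, "_", k), paste(newchars, collapse = ""),
                    base$features, circular = base$circular)
    })
  })
}
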