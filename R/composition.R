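# Nucleotide composition, strand-asymmetry skews, codon usage / RSCU,
# start/stop codon inference, and circular spacer/overlap accounting.

#' Count bases in a nucleotide string
#'
#' @param seq Nucleotide string.
#' @return A list of class `base_counts` with components `A`, `C`, `G`,
#'   `T`, `N` (ambiguity codes and `N` are pooled into `N` and excluded
#'   from skew denominators) and `total` (= A+C+G+T).
#' @export
base_counts <- function(seq) {
  ch <- seq_chars(toupper(seq))
  tab <- table(factor(ch, levels = c("A", "C", "G", "T")))
  n_other <- length(ch) - sum(tab)
  structure(
    list(A = unname(tab[["A"]]), C = unname(tab[["C"]]),
         G = unname(tab[["G"]]), T = unname(tab[["T"]]),
         N = n_other, total = sum(tab)),
    class = "base_counts"
  )
}

#' AT and GC skew
#'
#' AT skew = (A - T)/(A + T); GC skew = (G - C)/(G + C).  A zero
#' denominator yields `NA` (undefined skew).
#'
#' @param counts A [base_counts()] object (or a string, which is counted
#'   first).
#' @return Dimensionless skew in `[-1, 1]`, or `NA`.
#' @export
at_skew <- function(counts) {
  if (is.character(counts)) counts <- base_counts(counts)
  d <- counts$A + counts$T
  if (d == 0) return(NA_real_)
  (counts$A - counts$T) / d
}

#' @rdname at_skew
#' @export
gc_skew <- function(counts) {
  if (is.character(counts)) counts <- base_counts(counts)
  d <- counts$G + counts$C
  if (d == 0) return(NA_real_)
  (counts$G - counts$C) / d
}

#' @rdname at_skew
#' @export
at_content <- function(counts) {
  if (is.character(counts)) counts <- base_counts(counts)
  if (counts$total == 0) return(NA_real_)
  100 * (counts$A + counts$T) / counts$total
}

summarise_partition <- function(partition, seq) {
  bc <- base_counts(seq)
  data.frame(partition = partition, length = bc$total + bc$N,
             at_content = at_content(bc), at_skew = at_skew(bc),
             gc_skew = gc_skew(bc), stringsAsFactors = FALSE)
}

# coding-sense concatenation of a kind of gene, in annotation order
concat_partition <- function(record, genes) {
  paste(vapply(genes, function(g) extract_gene_sequence(record, g),
               character(1)), collapse = "")
}

#' Per-partition composition summary
#'
#' Computes AT content and AT/GC skews for the whole genome (forward
#' strand), the coding-sense concatenations of PCGs, tRNAs and rRNAs, the
#' A+T-rich region, and the three codon positions of the PCG concatenation
#' (reading-frame positions, i.e. coding-sense).
#'
#' @param record A [mitogenome_record()].
#' @return A data frame with columns `partition`, `length`, `at_content`,
#'   `at_skew`, `gc_skew`.
#' @export
composition_by_partition <- function(record) {
  ann <- record$annotations
  out <- list(summarise_partition("whole", record$sequence))
  parts <- list(PCGs = ann$name[ann$kind == "PCG"],
                tRNAs = ann$name[ann$kind == "tRNA"],
                rRNAs = ann$name[ann$kind == "rRNA"])
  pcg_seq <- NULL
  for (p in names(parts)) {
    genes <- parts[[p]]
    if (!length(genes)) {
      warning("partition ", p, " missing from record; summary omitted")
      next
    }
    s <- concat_partition(record, genes)
    if (p == "PCGs") pcg_seq <- s
    out[[length(out) + 1L]] <- summarise_partition(p, s)
  }
  if ("AT_rich" %in% ann$name) {
    out[[length(out) + 1L]] <-
      summarise_partition("AT_rich", extract_gene_sequence(record, "AT_rich"))
  } else {
    warning("partition AT_rich missing from record; summary omitted")
  }
  if (!is.null(pcg_seq)) {
    # per-gene framing: codon position assigned within each PCG separately
    pcgs <- ann$name[ann$kind == "PCG"]
    pos_seq <- c("1" = "", "2" = "", "3" = "")
    for (g in pcgs) {
      s <- seq_chars(extract_gene_sequence(record, g))
      pos <- ((seq_along(s) - 1L) %% 3L) + 1L
      for (k in 1:3) pos_seq[[as.character(k)]] <-
        paste0(pos_seq[[as.character(k)]], collapse_chars(s[pos == k]))
    }
    for (k in 1:3) {
      out[[length(out) + 1L]] <-
        summarise_partition(paste0("codon_pos_", k), pos_seq[[as.character(k)]])
    }
  }
  do.call(rbind, out)
}

# codons of a CDS in coding sense, dropping the (possibly partial) stop
cds_codons <- function(cds, gene = "") {
  n <- nchar(cds)
  n_full <- n %/% 3L
  if (n_full == 0L) return(character(0))
  starts <- seq(1L, by = 3L, length.out = n_full)
  codons <- substring(cds, starts, starts + 2L)
  gc <- mito_genetic_code()
  aa <- gc[codons]
  # trailing complete stop codon excluded; partial trailing bases already
  # dropped by integer division
  if (!is.na(aa[n_full]) && identical(unname(aa[n_full]), "*")) {
    codons <- codons[-n_full]
    aa <- aa[-n_full]
  }
  internal_stop <- which(!is.na(aa) & aa == "*")
  if (length(internal_stop)) {
    warning("internal stop codon in ", gene, " at codon position(s) ",
            paste(internal_stop, collapse = ", "))
  }
  codons
}

#' Codon usage over all protein-coding genes
#'
#' Counts codons of the 13 PCGs in coding sense under the invertebrate
#' mitochondrial code.  Stop codons and trailing partial codons are
#' excluded; codons containing ambiguity characters are dropped.
#'
#' @param record A [mitogenome_record()].
#' @return Named integer vector of codon counts over the 62 sense codons.
#' @export
codon_usage <- function(record) {
  ann <- record$annotations
  pcgs <- ann$name[ann$kind == "PCG"]
  codons <- unlist(lapply(pcgs, function(g)
    cds_codons(extract_gene_sequence(record, g), g)), use.names = FALSE)
  codons <- codons[!grepl("[^ACGT]", codons)]
  gc <- mito_genetic_code()
  sense <- names(gc)[gc != "*"]
  tab <- table(factor(codons, levels = sense))
  stats::setNames(as.integer(tab), sense)
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c = count(c) x family degeneracy / total family count.
#' Synonymous families follow the invertebrate mitochondrial code; families
#' with zero observations get RSCU 0 for every member.
#'
#' @param counts Named codon count vector as from [codon_usage()].
#' @return Data frame of class `rscu_table` with columns `codon`,
#'   `amino_acid`, `count`, `rscu`.
#' @export
rscu <- function(counts) {
  gc <- mito_genetic_code()
  fams <- synonymous_families()
  rows <- lapply(names(fams), function(aa) {
    cods <- sort(fams[[aa]])
    cnt <- ifelse(is.na(counts[cods]), 0L, counts[cods])
    tot <- sum(cnt)
    val <- if (tot > 0) cnt * length(cods) / tot else rep(0, length(cods))
    data.frame(codon = cods, amino_acid = aa, count = as.integer(cnt),
               rscu = as.numeric(val), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rscu_table", "data.frame")
  out
}

#' Start and stop codon of a protein-coding gene
#'
#' The start codon is the first codon of the coding-sense sequence; the
#' stop is inferred from the sequence length modulo 3 and the terminal
#' bases: a complete TAA/TAG when in frame, or the partial stops `"T-"`
#' (one trailing T) and `"TA-"` (trailing TA) completed by
#' polyadenylation.
#'
#' @param record A [mitogenome_record()].
#' @param gene A PCG name.
#' @return List with elements `start` and `stop`; unknown terminal
#'   patterns are reported verbatim.
#' @export
detect_start_stop <- function(record, gene) {
  cds <- extract_gene_sequence(record, gene)
  n <- nchar(cds)
  start <- substr(cds, 1L, 3L)
  rem <- n %% 3L
  stop_codon <- if (rem == 1L) {
    tail1 <- substr(cds, n, n)
    if (tail1 == "T") "T-" else paste0(tail1, "-")
  } else if (rem == 2L) {
    tail2 <- substr(cds, n - 1L, n)
    if (tail2 == "TA") "TA-" else paste0(tail2, "-")
  } else {
    substr(cds, n - 2L, n)
  }
  list(start = start, stop = stop_codon)
}

#' Intergenic spacers and gene overlaps on the circular genome
#'
#' Walks consecutive annotations around the ring (the A+T-rich region is
#' treated as an annotated region, so its interior never counts as an
#' intergenic spacer).  A positive gap between consecutive annotations is
#' a spacer; a negative gap is an overlap.
#'
#' @param record A [mitogenome_record()].
#' @return A list of class `spacer_overlap_report` with data frames
#'   `spacers` and `overlaps` (`upstream`, `downstream`, `length`), plus
#'   `total_spacer_bp`, `n_spacer_locations`, `total_overlap_bp`,
#'   `n_overlap_locations`.
#' @export
spacers_and_overlaps <- function(record) {
  ann <- record$annotations
  if (is.unsorted(ann$start)) {
    warning("annotations unsorted; sorting by start")
    ann <- ann[order(ann$start), , drop = FALSE]
  }
  n <- nrow(ann)
  # effective linear end, allowing wrap
  ends <- ifelse(ann$wraps_origin, ann$end + record$length, ann$end)
  sp <- ov <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    nxt_start <- if (i == n) ann$start[j] + record$length else ann$start[j]
    gap <- nxt_start - ends[i]
    if (gap > 0) {
      sp[[length(sp) + 1L]] <- data.frame(
        upstream = ann$name[i], downstream = ann$name[j], length = gap,
        stringsAsFactors = FALSE)
    } else if (gap < 0) {
      ov[[length(ov) + 1L]] <- data.frame(
        upstream = ann$name[i], downstream = ann$name[j], length = -gap,
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(upstream = character(0), downstream = character(0),
                      length = integer(0), stringsAsFactors = FALSE)
  spacers <- if (length(sp)) do.call(rbind, sp) else empty
  overlaps <- if (length(ov)) do.call(rbind, ov) else empty
  structure(
    list(spacers = spacers, overlaps = overlaps,
         total_spacer_bp = sum(spacers$length),
         n_spacer_locations = nrow(spacers),
         total_overlap_bp = sum(overlaps$length),
         n_overlap_locations = nrow(overlaps)),
    class = "spacer_overlap_report"
  )
}

#' @export
print.spacer_overlap_report <- function(x, ...) {
  cat("Spacers:", x$total_spacer_bp, "bp at", x$n_spacer_locations,
      "locations\n")
  cat("Overlaps:", x$total_overlap_bp, "bp at", x$n_overlap_locations,
      "locations\n")
  invisible(x)
}

#' Write composition / codon-usage / spacer tables as TSV
#'
#' @param x A data frame (e.g. from [composition_by_partition()] or
#'   [rscu()]) or a [spacers_and_overlaps()] report.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(x, path) {
  if (inherits(x, "spacer_overlap_report")) {
    sp <- x$spacers; sp$type <- if (nrow(sp)) "spacer" else character(0)
    ov <- x$overlaps; ov$type <- if (nrow(ov)) "overlap" else character(0)
    x <- rbind(sp, ov)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
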