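# Assembly of partitioned supermatrices from per-gene alignments.
#
# Four dataset variants are supported:
#   P123RNA          all PCG codon positions + tRNAs + rRNAs
#   P12RNA           PCG positions 1+2 only + tRNAs + rRNAs
#   P123RNAexc3genes P123RNA without atp8, nad4l, nad6
#   P12RNAexc3genes  P12RNA without atp8, nad4l, nad6
# Genes are concatenated in a fixed canonical order (PCGs alphabetical,
# then tRNAs, then rRNAs).

#' Supermatrix dataset variants
#'
#' @return Character vector of the four variant labels.
#' @export
supermatrix_variants <- function() {
  c("P123RNA", "P12RNA", "P123RNAexc3genes", "P12RNAexc3genes")
}

#' Genes excluded by the `exc3genes` variants
#'
#' The protein-coding genes screened out as saturation-prone in the
#' `*exc3genes` dataset variants.
#'
#' @return Character vector of gene names.
#' @export
excluded_saturated_genes <- function() c("atp8", "nad4l", "nad6")

variant_spec <- function(variant) {
  variant <- match.arg(variant, supermatrix_variants())
  list(drop_pos3 = variant %in% c("P12RNA", "P12RNAexc3genes"),
       drop_genes = if (grepl("exc3genes", variant))
         excluded_saturated_genes() else character(0))
}

#' Trim stop codons from a protein-coding alignment
#'
#' Removes the trailing partial stop bases (alignment length not divisible
#' by 3) and, when the final in-frame column triplet is a stop codon in
#' every ungapped sequence, the complete terminal stop, leaving an
#' alignment whose length is divisible by 3.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @return The trimmed alignment.
#' @export
strip_stop_codons <- function(aln) {
  L <- unique(nchar(aln))
  stopifnot(length(L) == 1L)
  L3 <- L - (L %% 3L)
  aln <- substr(aln, 1L, L3)
  if (L3 >= 3L) {
    gc <- mito_genetic_code()
    last <- toupper(substr(aln, L3 - 2L, L3))
    known <- last[!grepl("[^ACGT]", last)]
    if (length(known) && all(gc[known] == "*")) {
      aln <- substr(aln, 1L, L3 - 3L)
    }
  }
  aln
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' PCG alignments must be in frame (length divisible by 3); codon-position
#' masks are derived from reading frame 0.  Taxa missing from a gene are
#' padded with gaps (with a warning).  The `"P12*"` variants drop every
#' third codon position; the `"*exc3genes"` variants drop atp8, nad4l and
#' nad6 entirely.
#'
#' @param alignments Named list: gene -> alignment (named character vector
#'   of equal-length aligned sequences).
#' @param variant One of [supermatrix_variants()].
#' @return An object of class `supermatrix`: `taxa`, `seqs` (named
#'   character vector), `length`, `variant`, `scheme` (see
#'   [build_scheme()]), and `genes` (concatenation metadata).
#' @export
concatenate <- function(alignments, variant = "P123RNA") {
  vs <- variant_spec(variant)
  stopifnot(is.list(alignments), length(names(alignments)) > 0L)
  genes <- names(alignments)
  unknown <- setdiff(genes, canonical_genes())
  if (length(unknown)) {
    stop("unknown gene(s) in alignment set: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  order_genes <- c(sort(intersect(genes, mito_pcgs())),
                   sort(intersect(genes, mito_trnas())),
                   sort(intersect(genes, mito_rrnas())))
  order_genes <- setdiff(order_genes, vs$drop_genes)

  taxa <- sort(unique(unlist(lapply(alignments, names))))
  pieces <- stats::setNames(rep(list(character(0)), length(taxa)), taxa)
  blocks <- list()
  offset <- 0L
  for (g in order_genes) {
    aln <- alignments[[g]]
    L <- unique(nchar(aln))
    if (length(L) != 1L) {
      stop("alignment for ", g, " has unequal sequence lengths", call. = FALSE)
    }
    kind <- gene_kind(g)
    if (kind == "PCG") {
      if (L %% 3L != 0L) {
        stop("frame violation: ", g, " alignment length ", L,
             " is not divisible by 3", call. = FALSE)
      }
      keep <- if (vs$drop_pos3) {
        which(((seq_len(L) - 1L) %% 3L) != 2L)
      } else {
        seq_len(L)
      }
    } else {
      keep <- seq_len(L)
    }
    missing_taxa <- setdiff(taxa, names(aln))
    if (length(missing_taxa)) {
      warning("gene ", g, ": taxa padded with gaps: ",
              paste(missing_taxa, collapse = ", "))
    }
    for (tx in taxa) {
      s <- if (tx %in% names(aln)) aln[[tx]] else
        strrep("-", L)
      ch <- seq_chars(s)[keep]
      pieces[[tx]] <- c(pieces[[tx]], collapse_chars(ch))
    }
    blocks[[length(blocks) + 1L]] <- list(
      gene = g, kind = kind, offset = offset, n_sites = length(keep),
      n_pos = if (kind == "PCG") (if (vs$drop_pos3) 2L else 3L) else NA_integer_)
    offset <- offset + length(keep)
  }
  seqs <- vapply(pieces, paste, character(1), collapse = "")
  sm <- structure(
    list(taxa = taxa, seqs = seqs, length = offset, variant = variant,
         genes = blocks, scheme = NULL),
    class = "supermatrix"
  )
  sm$scheme <- build_scheme(sm)
  sm
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("supermatrix (", x$variant, "): ", length(x$taxa), " taxa x ",
      x$length, " sites, ", nrow(x$scheme), " partitions\n", sep = "")
  invisible(x)
}

#' Build the partition scheme of a supermatrix
#'
#' One block per retained PCG codon position and one per RNA gene.  With
#' all codon positions a complete 37-gene matrix yields 13x3 + 22 + 2 = 63
#' blocks; without third positions, 13x2 + 22 + 2 = 50.
#'
#' @param sm A [concatenate()] supermatrix.
#' @return Data frame of class `partition_scheme`: `name`, `start`, `end`
#'   (1-based inclusive), `stride`, `phase`, `type`, `n_sites`.
#' @export
build_scheme <- function(sm) {
  rows <- list()
  for (b in sm$genes) {
    if (b$kind == "PCG") {
      np <- b$n_pos
      for (pos in seq_len(np)) {
        rows[[length(rows) + 1L]] <- data.frame(
          name = paste0(b$gene, "_pos", pos),
          start = b$offset + pos, end = b$offset + b$n_sites,
          stride = np, phase = pos,
          type = paste0("PCG_pos", pos),
          n_sites = b$n_sites %/% np,
          stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        name = b$gene, start = b$offset + 1L, end = b$offset + b$n_sites,
        stride = 1L, phase = 1L,
        type = if (b$kind == "tRNA") "tRNA" else "rRNA",
        n_sites = b$n_sites, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("partition_scheme", "data.frame")
  out
}

#' Write a partition scheme as NEXUS charsets or RAxML-style blocks
#'
#' @param scheme A [build_scheme()] data frame.
#' @param path Output path.
#' @param dialect `"nexus_charset"` (`charset name = a-b\3;` inside a sets
#'   block) or `"raxml_style"` (`DNA, name = a-b\3`).
#' @return `path`, invisibly.
#' @export
write_partitions <- function(scheme, path,
                             dialect = c("nexus_charset", "raxml_style")) {
  dialect <- match.arg(dialect)
  if (!nrow(scheme)) stop("empty partition scheme", call. = FALSE)
  rng <- function(i) {
    if (scheme$stride[i] > 1L) {
      sprintf("%d-%d\\%d", scheme$start[i], scheme$end[i], scheme$stride[i])
    } else {
      sprintf("%d-%d", scheme$start[i], scheme$end[i])
    }
  }
  lines <- if (dialect == "nexus_charset") {
    c("#nexus", "begin sets;",
      vapply(seq_len(nrow(scheme)), function(i)
        sprintf("  charset %s = %s;", scheme$name[i], rng(i)), character(1)),
      "end;")
  } else {
    vapply(seq_len(nrow(scheme)), function(i)
      sprintf("DNA, %s = %s", scheme$name[i], rng(i)), character(1))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a partition file written by [write_partitions()]
#'
#' @param path Partition file.
#' @return A `partition_scheme`-shaped data frame (`name`, `start`, `end`,
#'   `stride`, `phase`).
#' @export
read_partitions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("charset|^DNA,", lines)]
  rows <- lapply(lines, function(ln) {
    m <- regmatches(ln, regexec(
      "(?:charset|DNA,)\\s+(\\S+)\\s*=\\s*(\\d+)-(\\d+)(?:\\\\(\\d+))?", ln))[[1L]]
    if (!length(m)) return(NULL)
    start <- as.integer(m[3L]); stride <- if (nzchar(m[5L])) as.integer(m[5L]) else 1L
    data.frame(name = m[2L], start = start, end = as.integer(m[4L]),
               stride = stride,
               phase = if (stride > 1L) ((start - 1L) %% stride) + 1L else 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract one partition's alignment from a supermatrix
#'
#' @param sm A [concatenate()] supermatrix.
#' @param name A block name from the scheme.
#' @return Named character vector of the block's sites.
#' @export
partition_sites <- function(sm, name) {
  sc <- sm$scheme
  i <- match(name, sc$name)
  if (is.na(i)) stop("no such partition: ", name, call. = FALSE)
  idx <- seq(sc$start[i], sc$end[i], by = sc$stride[i])
  vapply(sm$seqs, function(s) collapse_chars(seq_chars(s)[idx]), character(1))
}

#' Write a supermatrix as relaxed PHYLIP and/or FASTA
#'
#' @param sm A [concatenate()] supermatrix.
#' @param path Output path.
#' @param format `"phylip"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_supermatrix <- function(sm, path, format = c("phylip", "fasta")) {
  format <- match.arg(format)
  if (format == "fasta") {
    write_alignment(sm$seqs, path)
  } else {
    lines <- c(sprintf("%d %d", length(sm$taxa), sm$length),
               sprintf("%s  %s", format(sm$taxa, width = max(nchar(sm$taxa))),
                       sm$seqs))
    writeLines(lines, path)
  }
  invisible(path)
}
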