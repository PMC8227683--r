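# GenBank flat-file and 5-column feature-table I/O for mitogenome records.
#
# GenBank uses 1-based inclusive coordinates; internally everything is
# 0-based half-open on the forward strand.  Features crossing the circular
# origin are written as join(a..L,1..b).

genbank_location <- function(start, end, strand, wraps, len) {
  loc <- if (wraps) {
    sprintf("join(%d..%d,1..%d)", start + 1L, len, end)
  } else {
    sprintf("%d..%d", start + 1L, end)
  }
  if (strand == "N") sprintf("complement(%s)", loc) else loc
}

feature_key_for <- function(kind) {
  switch(kind, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
         control = "misc_feature", "misc_feature")
}

# product strings emitted for tRNAs; the codon-family note disambiguates
# the leucine/serine isoacceptors on re-reading
trna_product <- function(name) {
  aa <- substr(name, 4L, 4L)
  full <- c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe", G = "Gly",
            H = "His", I = "Ile", K = "Lys", L = "Leu", M = "Met", N = "Asn",
            P = "Pro", Q = "Gln", R = "Arg", S = "Ser", T = "Thr", V = "Val",
            W = "Trp", Y = "Tyr")
  paste0("tRNA-", full[[aa]])
}

trna_family_note <- function(name) {
  fam <- c(trnL1 = "CUN", trnL2 = "UUR", trnS1 = "AGN", trnS2 = "UCN")
  if (name %in% names(fam)) paste0("codons recognized: ", fam[[name]]) else NULL
}

#' Write a mitogenome record as a GenBank flat file
#'
#' @param record A [mitogenome_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  ann <- record$annotations
  len <- record$length
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     circular INV",
            gsub("[^A-Za-z0-9_.]", "_", record$taxon), len),
    sprintf("DEFINITION  %s mitochondrion, complete genome.", record$taxon),
    "SOURCE      mitochondrion",
    sprintf("  ORGANISM  %s", record$taxon),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", len),
    sprintf("                     /organism=\"%s\"", record$taxon)
  )
  qline <- function(key, val) sprintf("                     /%s=\"%s\"", key, val)
  for (i in seq_len(nrow(ann))) {
    key <- feature_key_for(ann$kind[i])
    loc <- genbank_location(ann$start[i], ann$end[i], ann$strand[i],
                            ann$wraps_origin[i], len)
    out <- c(out, sprintf("     %-15s %s", key, loc))
    nm <- ann$name[i]
    if (ann$kind[i] == "tRNA") {
      out <- c(out, qline("product", trna_product(nm)))
      note <- trna_family_note(nm)
      if (!is.null(note)) out <- c(out, qline("note", note))
      out <- c(out, qline("gene", nm))
    } else if (ann$kind[i] == "control") {
      out <- c(out, qline("note", "A+T-rich region"))
    } else {
      out <- c(out, qline("gene", nm))
      if (ann$kind[i] == "PCG") out <- c(out, qline("transl_table", "5"))
    }
  }
  out <- c(out, "ORIGIN")
  seqlo <- tolower(record$sequence)
  starts <- seq(1L, len, by = 60L)
  for (s in starts) {
    chunk <- substr(seqlo, s, min(s + 59L, len))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", s, paste(blocks, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

parse_genbank_location <- function(loc, len) {
  strand <- "J"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraps <- FALSE
  if (grepl("^join\\(", loc)) {
    parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",", fixed = TRUE)[[1L]]
    iv <- do.call(rbind, lapply(parts, function(p) {
      as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    }))
    start <- iv[1L, 1L] - 1L
    end <- iv[nrow(iv), 2L]
    wraps <- TRUE
  } else {
    iv <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1L]])
    start <- iv[1L] - 1L
    end <- iv[2L]
  }
  list(start = start, end = end, strand = strand, wraps = wraps)
}

#' Read a GenBank flat file into a mitogenome record
#'
#' Understands CDS/tRNA/rRNA/misc_feature/D-loop features with plain,
#' `complement()` and origin-spanning `join()` locations; gene names are
#' normalized to the canonical alphabet via [normalize_gene_name()].
#'
#' @param path GenBank flat file.
#' @return A [mitogenome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  org_i <- grep("^  ORGANISM", lines)
  taxon <- if (length(org_i)) {
    trimws(sub("^  ORGANISM\\s+", "", lines[org_i[1L]]))
  } else {
    trimws(sub("\\s+\\d+ bp.*$", "", sub("^LOCUS\\s+", "", lines[1L])))
  }
  fi <- grep("^FEATURES", lines)[1L]
  oi <- grep("^ORIGIN", lines)[1L]
  if (is.na(fi) || is.na(oi)) stop("not a GenBank flat file: ", path, call. = FALSE)
  term <- grep("^//", lines)
  last <- if (length(term)) term[term > oi][1L] - 1L else length(lines)
  seq <- toupper(gsub("[^A-Za-z]", "", paste(lines[(oi + 1L):last], collapse = "")))
  len <- nchar(seq)

  feat_lines <- lines[(fi + 1L):(oi - 1L)]
  is_new <- grepl("^     \\S", feat_lines)
  idx <- cumsum(is_new)
  feats <- split(feat_lines, idx)

  names_ <- starts <- ends <- strands <- character(0)
  starts <- ends <- integer(0)
  wraps <- logical(0)
  for (fl in feats) {
    head <- fl[1L]
    key <- sub("^\\s+", "", substr(head, 1L, 20L))
    key <- trimws(key)
    loc_str <- trimws(substr(head, 21L, nchar(head)))
    # continuation of a multi-line location (no qualifiers expected between)
    j <- 2L
    while (j <= length(fl) && !grepl("^\\s+/", fl[j])) {
      loc_str <- paste0(loc_str, trimws(fl[j]))
      j <- j + 1L
    }
    if (key %in% c("source")) next
    quals <- character(0)
    if (j <= length(fl)) {
      qlines <- fl[seq(j, length(fl))]
      qlines <- qlines[grepl("^\\s+/", qlines)]
      for (q in qlines) {
        q <- sub("^\\s+/", "", q)
        kv <- regmatches(q, regexec("^([A-Za-z_]+)=?\"?([^\"]*)\"?$", q))[[1L]]
        if (length(kv) == 3L) quals[kv[2L]] <- kv[3L]
      }
    }
    kind <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                   misc_feature = "control", D_loop = "control", NA)
    if (is.na(kind)) next
    raw <- qual_get(quals, "gene") %||% qual_get(quals, "product") %||%
      qual_get(quals, "note") %||% NA_character_
    if (is.na(raw)) {
      if (kind == "control") raw <- "AT_rich" else
        stop("feature without name qualifiers in ", path, call. = FALSE)
    }
    if (kind == "control" && !grepl("trn", raw, ignore.case = TRUE)) raw <- "AT_rich"
    nm <- normalize_gene_name(raw, quals)
    loc <- parse_genbank_location(loc_str, len)
    if (loc$start > len || loc$end > len) {
      stop("coordinate error: feature ", nm, " outside sequence bounds",
           call. = FALSE)
    }
    names_ <- c(names_, nm)
    starts <- c(starts, loc$start)
    ends <- c(ends, loc$end)
    strands <- c(strands, loc$strand)
    wraps <- c(wraps, loc$wraps)
  }
  if (anyDuplicated(names_)) {
    stop("annotation conflict: duplicate gene name(s) in ", path, ": ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "),
         call. = FALSE)
  }
  ann <- gene_annotation(names_, starts, ends, strands)
  ann$wraps_origin <- wraps | ann$wraps_origin
  mitogenome_record(taxon, seq, ann)
}

#' Write a (FASTA + 5-column feature table) pair
#'
#' The table follows the NCBI tbl convention: tab-separated start/end/key
#' lines (1-based inclusive, reversed coordinates on the minority strand)
#' with qualifier continuation lines.
#'
#' @param record A [mitogenome_record()].
#' @param fasta_path,table_path Output paths.
#' @return `table_path`, invisibly.
#' @export
write_feature_table <- function(record, fasta_path, table_path) {
  dna <- Biostrings::DNAStringSet(stats::setNames(record$sequence, record$taxon))
  Biostrings::writeXStringSet(dna, fasta_path)
  ann <- record$annotations
  out <- sprintf(">Feature %s", record$taxon)
  for (i in seq_len(nrow(ann))) {
    key <- feature_key_for(ann$kind[i])
    if (ann$wraps_origin[i]) {
      iv <- rbind(c(ann$start[i] + 1L, record$length), c(1L, ann$end[i]))
    } else {
      iv <- rbind(c(ann$start[i] + 1L, ann$end[i]))
    }
    if (ann$strand[i] == "N") iv <- iv[rev(seq_len(nrow(iv))), c(2L, 1L), drop = FALSE]
    out <- c(out, sprintf("%d\t%d\t%s", iv[1L, 1L], iv[1L, 2L], key))
    if (nrow(iv) > 1L) out <- c(out, sprintf("%d\t%d", iv[-1L, 1L], iv[-1L, 2L]))
    out <- c(out, sprintf("\t\t\tgene\t%s", ann$name[i]))
    if (ann$kind[i] == "tRNA") {
      out <- c(out, sprintf("\t\t\tproduct\t%s", trna_product(ann$name[i])))
      note <- trna_family_note(ann$name[i])
      if (!is.null(note)) out <- c(out, sprintf("\t\t\tnote\t%s", note))
    }
  }
  writeLines(out, table_path)
  invisible(table_path)
}

#' Read a (FASTA + 5-column feature table) pair
#'
#' @param fasta_path FASTA file with one sequence.
#' @param table_path 5-column feature table as written by
#'   [write_feature_table()].
#' @return A [mitogenome_record()].
#' @export
read_feature_table <- function(fasta_path, table_path) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  seq <- as.character(dna[[1L]])
  len <- nchar(seq)
  lines <- readLines(table_path, warn = FALSE)
  taxon <- sub("^>Feature\\s+", "", lines[1L])
  lines <- lines[-1L]
  recs <- list()
  cur <- NULL
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) >= 3L && nzchar(f[1L]) && nzchar(f[3L])) {
      if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
      cur <- list(iv = rbind(as.integer(f[1:2])), key = f[3L], quals = character(0))
    } else if (length(f) == 2L && nzchar(f[1L])) {
      cur$iv <- rbind(cur$iv, as.integer(f[1:2]))
    } else if (length(f) == 5L) {
      cur$quals[f[4L]] <- f[5L]
    }
  }
  if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
  ann_rows <- lapply(recs, function(r) {
    strand <- if (r$iv[1L, 1L] > r$iv[1L, 2L]) "N" else "J"
    iv <- r$iv
    if (strand == "N") iv <- iv[rev(seq_len(nrow(iv))), c(2L, 1L), drop = FALSE]
    start <- iv[1L, 1L] - 1L
    end <- iv[nrow(iv), 2L]
    kind <- switch(r$key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA", "control")
    raw <- qual_get(r$quals, "gene") %||% qual_get(r$quals, "product") %||%
      "AT_rich"
    nm <- normalize_gene_name(raw, r$quals)
    data.frame(name = nm, start = start, end = end, strand = strand,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, ann_rows)
  if (anyDuplicated(tab$name)) {
    stop("annotation conflict: duplicate gene name(s) in ", table_path,
         call. = FALSE)
  }
  ann <- gene_annotation(tab$name, tab$start, tab$end, tab$strand)
  mitogenome_record(taxon, seq, ann)
}

#' Write a TSV summary of a record's annotations
#'
#' @param record A [mitogenome_record()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(record, path) {
  ann <- record$annotations
  ann$length <- annotation_length(ann, record$length)
  ann$taxon <- record$taxon
  utils::write.table(
    ann[, c("taxon", "name", "kind", "start", "end", "strand",
            "wraps_origin", "length")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
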