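# MitogenomeRecord: a circular sequence plus strand-aware gene annotations.
# Coordinates are 0-based half-open on the forward (J) strand; an annotation
# with start >= end is flagged wraps_origin and spans the circular origin.

#' Construct a gene annotation table
#'
#' @param name Canonical gene names (see [canonical_genes()]; `"AT_rich"`
#'   marks the control region).
#' @param start,end 0-based half-open coordinates on the forward strand.
#'   `start >= end` denotes an annotation wrapping the circular origin.
#' @param strand `"J"` (majority strand, forward) or `"N"` (minority,
#'   reverse complement).
#' @return A data frame with columns `name`, `start`, `end`, `strand`,
#'   `kind`, `wraps_origin`.
#' @export
gene_annotation <- function(name, start, end, strand = "J") {
  stopifnot(length(name) == length(start), length(start) == length(end))
  strand <- rep_len(strand, length(name))
  if (!all(strand %in% c("J", "N"))) {
    stop("strand must be 'J' or 'N'", call. = FALSE)
  }
  data.frame(
    name = as.character(name),
    start = as.integer(start),
    end = as.integer(end),
    strand = strand,
    kind = gene_kind(as.character(name)),
    wraps_origin = as.integer(start) >= as.integer(end),
    stringsAsFactors = FALSE
  )
}

#' Construct a mitogenome record
#'
#' @param taxon Taxon label.
#' @param sequence Circular nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param annotations Annotation data frame from [gene_annotation()].
#' @return An object of class `MitogenomeRecord`.
#' @export
mitogenome_record <- function(taxon, sequence, annotations) {
  stopifnot(is_scalar_chr(taxon), is_scalar_chr(sequence))
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  len <- nchar(sequence)
  bad <- annotations$start < 0L | annotations$start > len |
    annotations$end < 0L | annotations$end > len
  if (any(bad)) {
    stop("coordinate error: annotations outside [0, ", len, "]: ",
         paste(annotations$name[bad], collapse = ", "), call. = FALSE)
  }
  # duplicate names are tolerated here so that validate_record() can report
  # them; the file readers raise annotation-conflict errors instead
  annotations <- annotations[order(annotations$start), , drop = FALSE]
  rownames(annotations) <- NULL
  structure(
    list(taxon = taxon, sequence = sequence, length = len,
         annotations = annotations),
    class = "MitogenomeRecord"
  )
}

#' @export
print.MitogenomeRecord <- function(x, ...) {
  cat("MitogenomeRecord:", x$taxon, "\n")
  cat("  length:", x$length, "bp;", nrow(x$annotations), "annotations\n")
  k <- table(x$annotations$kind)
  cat("  ", paste(names(k), k, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

annotation_length <- function(ann, genome_length) {
  ifelse(ann$wraps_origin,
         genome_length - ann$start + ann$end,
         ann$end - ann$start)
}

#' Normalize a raw gene label to its canonical name
#'
#' Maps the gene/product strings found in GenBank records (e.g. `"COI"`,
#' `"cytochrome b"`, `"12S ribosomal RNA"`, `"tRNA-Leu"`) onto the canonical
#' 37-gene alphabet plus `"AT_rich"`.  The leucine and serine isoacceptors
#' are split using, in order of precedence: an explicit L1/L2/S1/S2 tag in
#' the label, an `anticodon` qualifier, then a codon-recognized note such
#' as `"(UUR)"`.
#'
#' @param raw Raw label.
#' @param qualifiers Optional named character vector of feature qualifiers
#'   (`anticodon`, `note`, `product`, ...).
#' @return A canonical gene identifier.
#' @export
normalize_gene_name <- function(raw, qualifiers = character()) {
  stopifnot(is_scalar_chr(raw))
  key <- tolower(gsub("[-_ .+]+", "", raw))
  syn <- gene_synonym_table()
  if (key %in% names(syn)) return(unname(syn[[key]]))

  m <- regmatches(key, regexec("^trna?-?([a-z]{3}|[a-z])([12]?)$", key))[[1L]]
  if (length(m)) {
    aa <- m[2L]
    if (nchar(aa) == 3L) aa <- unname(aa3_to_1()[aa])
    if (!is.na(aa)) {
      aa <- toupper(aa)
      iso <- m[3L]
      if (aa %in% c("L", "S")) {
        if (iso %in% c("1", "2")) return(paste0("trn", aa, iso))
        return(disambiguate_ls(aa, qualifiers, raw))
      }
      hit <- trna_by_aa()[aa]
      if (!is.na(hit)) return(unname(hit))
    }
  }
  stop("unknown gene name: '", raw, "'", call. = FALSE)
}

disambiguate_ls <- function(aa, qualifiers, raw) {
  ac <- qual_get(qualifiers, "anticodon")
  if (!is.null(ac)) {
    ac <- chartr("T", "U", toupper(gsub(".*[:(]?([ACGTUacgtu]{3})\\)?$", "\\1", ac)))
    hit <- trna_anticodon_table()[ac]
    if (!is.na(hit) && substr(hit, 4L, 4L) == aa) return(unname(hit))
  }
  note <- paste(qual_get(qualifiers, "note") %||% "",
                qual_get(qualifiers, "product") %||% "")
  note <- toupper(chartr("T", "U", note))
  fam <- regmatches(note, regexec("(CUN|UUR|AGN|UCN)", note))[[1L]]
  if (length(fam)) {
    hit <- trna_codon_family_table()[fam[2L]]
    if (substr(hit, 4L, 4L) == aa) return(unname(hit))
  }
  stop("cannot disambiguate isoacceptor for '", raw,
       "': no anticodon or codon-family qualifier", call. = FALSE)
}

# lower-cased, squashed synonym -> canonical name
gene_synonym_table <- function() {
  tab <- c(
    cox1 = "cox1", coi = "cox1", co1 = "cox1", coxi = "cox1",
    "cytochromecoxidasesubuniti" = "cox1", "cytochromecoxidasesubunit1" = "cox1",
    cox2 = "cox2", coii = "cox2", co2 = "cox2", coxii = "cox2",
    "cytochromecoxidasesubunitii" = "cox2", "cytochromecoxidasesubunit2" = "cox2",
    cox3 = "cox3", coiii = "cox3", co3 = "cox3", coxiii = "cox3",
    "cytochromecoxidasesubunitiii" = "cox3", "cytochromecoxidasesubunit3" = "cox3",
    cob = "cob", cytb = "cob", "cytochromeb" = "cob",
    "cytochromebapoenzyme" = "cob",
    atp6 = "atp6", atpase6 = "atp6", "atpsynthasef0subunit6" = "atp6",
    atp8 = "atp8", atpase8 = "atp8", "atpsynthasef0subunit8" = "atp8",
    nad1 = "nad1", nd1 = "nad1", "nadhdehydrogenasesubunit1" = "nad1",
    nad2 = "nad2", nd2 = "nad2", "nadhdehydrogenasesubunit2" = "nad2",
    nad3 = "nad3", nd3 = "nad3", "nadhdehydrogenasesubunit3" = "nad3",
    nad4 = "nad4", nd4 = "nad4", "nadhdehydrogenasesubunit4" = "nad4",
    nad4l = "nad4l", nd4l = "nad4l", "nadhdehydrogenasesubunit4l" = "nad4l",
    nad5 = "nad5", nd5 = "nad5", "nadhdehydrogenasesubunit5" = "nad5",
    nad6 = "nad6", nd6 = "nad6", "nadhdehydrogenasesubunit6" = "nad6",
    rrns = "rrnS", srrna = "rrnS", "12srrna" = "rrnS",
    "12sribosomalrna" = "rrnS", "smallsubunitribosomalrna" = "rrnS",
    rrnl = "rrnL", lrrna = "rrnL", "16srrna" = "rrnL",
    "16sribosomalrna" = "rrnL", "largesubunitribosomalrna" = "rrnL",
    atrich = "AT_rich", "at-rich" = "AT_rich", "a+trichregion" = "AT_rich",
    "atrichregion" = "AT_rich", "controlregion" = "AT_rich",
    dloop = "AT_rich", "d-loop" = "AT_rich", "putativecontrolregion" = "AT_rich"
  )
  canon <- c(mito_pcgs(), mito_rrnas(), mito_trnas(), "AT_rich")
  extra <- stats::setNames(canon, tolower(canon))
  c(tab, extra[!names(extra) %in% names(tab)])
}

#' Extract a gene sequence in coding sense
#'
#' Slices the annotated interval (crossing the origin if flagged) and
#' reverse-complements it for minority-strand (`N`) genes.
#'
#' @param record A [mitogenome_record()].
#' @param gene Canonical gene identifier.
#' @return Nucleotide string in coding sense.
#' @export
extract_gene_sequence <- function(record, gene) {
  ann <- record$annotations
  i <- match(gene, ann$name)
  if (is.na(i)) stop("gene not found in record: ", gene, call. = FALSE)
  s <- circular_slice(record$sequence, ann$start[i], ann$end[i], record$length)
  if (ann$strand[i] == "N") revcomp(s) else s
}

#' Validate completeness of a mitogenome record
#'
#' Checks the annotated gene set against the canonical 37-gene alphabet,
#' reports same-strand protein-coding overlaps beyond a limit, and flags
#' protein-coding genes whose first codon is not ATN (warning-level only).
#'
#' @param record A [mitogenome_record()].
#' @param max_pcg_overlap Largest tolerated same-strand PCG/PCG overlap (bp).
#' @return A list of class `mito_validation` with elements `missing`,
#'   `extra`, `duplicated`, `n_genes`, `large_overlaps`, `non_atn_starts`,
#'   `has_control_region`, `complete`.
#' @export
validate_record <- function(record, max_pcg_overlap = 8L) {
  ann <- record$annotations
  genes <- ann$name[ann$name != "AT_rich"]
  want <- canonical_genes()
  missing <- setdiff(want, genes)
  extra <- setdiff(genes, want)
  dup <- unique(genes[duplicated(genes)])

  pcg <- ann[!is.na(ann$kind) & ann$kind == "PCG", , drop = FALSE]
  large <- character(0)
  if (nrow(pcg) > 1L) {
    for (i in seq_len(nrow(pcg) - 1L)) {
      for (j in seq(i + 1L, nrow(pcg))) {
        if (pcg$strand[i] != pcg$strand[j]) next
        ov <- min(pcg$end[i], pcg$end[j]) - max(pcg$start[i], pcg$start[j])
        if (ov > max_pcg_overlap) {
          large <- c(large, paste0(pcg$name[i], "/", pcg$name[j], ":", ov, "bp"))
        }
      }
    }
  }
  non_atn <- character(0)
  for (g in intersect(pcg$name, mito_pcgs())) {
    cds <- extract_gene_sequence(record, g)
    if (nchar(cds) >= 3L && !grepl("^AT[ACGT]", cds)) non_atn <- c(non_atn, g)
  }
  structure(
    list(missing = missing, extra = extra, duplicated = dup,
         n_genes = length(unique(genes)),
         large_overlaps = large, non_atn_starts = non_atn,
         has_control_region = "AT_rich" %in% ann$name,
         complete = length(missing) == 0L && length(dup) == 0L &&
           length(extra) == 0L),
    class = "mito_validation"
  )
}

#' @export
print.mito_validation <- function(x, ...) {
  cat("Mitogenome validation:", if (x$complete) "complete" else "INCOMPLETE", "\n")
  cat("  genes annotated:", x$n_genes, "of", length(canonical_genes()), "\n")
  if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  if (length(x$extra)) cat("  extra:", paste(x$extra, collapse = ", "), "\n")
  if (length(x$duplicated)) cat("  duplicated:", paste(x$duplicated, collapse = ", "), "\n")
  if (length(x$large_overlaps)) cat("  large PCG overlaps:", paste(x$large_overlaps, collapse = ", "), "\n")
  if (length(x$non_atn_starts)) cat("  non-ATN starts:", paste(x$non_atn_starts, collapse = ", "), "\n")
  invisible(x)
}
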