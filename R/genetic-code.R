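# Canonical gene alphabet and the invertebrate mitochondrial genetic code.

#' Canonical mitochondrial gene names
#'
#' The 37-gene alphabet of the typical insect mitogenome: 13 protein-coding
#' genes, 22 tRNAs (with the two leucine and two serine isoacceptors
#' disambiguated as trnL1/trnL2 and trnS1/trnS2), and the two rRNAs.
#' `"AT_rich"` names the non-coding control region and is not part of the
#' 37-gene set.
#'
#' @return Character vector of canonical names.
#' @export
canonical_genes <- function() {
  c(mito_pcgs(), mito_trnas(), mito_rrnas())
}

#' @rdname canonical_genes
#' @export
mito_pcgs <- function() {
  c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
    "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6")
}

#' @rdname canonical_genes
#' @export
mito_trnas <- function() {
  c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH", "trnI",
    "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP", "trnQ", "trnR",
    "trnS1", "trnS2", "trnT", "trnV", "trnW", "trnY")
}

#' @rdname canonical_genes
#' @export
mito_rrnas <- function() c("rrnL", "rrnS")

# kind of each canonical gene
gene_kind <- function(name) {
  ifelse(name %in% mito_pcgs(), "PCG",
    ifelse(name %in% mito_trnas(), "tRNA",
      ifelse(name %in% mito_rrnas(), "rRNA",
        ifelse(name == "AT_rich", "control", NA_character_))))
}

#' Invertebrate mitochondrial genetic code
#'
#' Translation table 5 as a named character vector mapping codons (DNA
#' alphabet) to one-letter amino acids, with `*` for stops.
#'
#' @return Named character vector of length 64.
#' @export
mito_genetic_code <- function() {
  gc <- Biostrings::getGeneticCode("SGC4")  # NCBI table 5
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

# synonymous families (excluding stops) under table 5: list aa -> codons
synonymous_families <- function() {
  gc <- mito_genetic_code()
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

# Anticodon -> canonical tRNA name for the standard invertebrate
# mitochondrial tRNA set.  trnK and trnS1 admit two anticodons seen across
# arthropod mitogenomes.
trna_anticodon_table <- function() {
  c(UGC = "trnA", GCA = "trnC", GUC = "trnD", UUC = "trnE", GAA = "trnF",
    UCC = "trnG", GUG = "trnH", GAU = "trnI", CUU = "trnK", UUU = "trnK",
    UAG = "trnL1", UAA = "trnL2", CAU = "trnM", GUU = "trnN", UGG = "trnP",
    UUG = "trnQ", UCG = "trnR", GCU = "trnS1", UCU = "trnS1", UGA = "trnS2",
    UGU = "trnT", UAC = "trnV", UCA = "trnW", GUA = "trnY")
}

# codon families recognized by the four ambiguous isoacceptors
trna_codon_family_table <- function() {
  c(CUN = "trnL1", UUR = "trnL2", AGN = "trnS1", UCN = "trnS2")
}

# single-letter amino acid -> unambiguous tRNA (L and S handled separately)
trna_by_aa <- function() {
  c(A = "trnA", C = "trnC", D = "trnD", E = "trnE", F = "trnF", G = "trnG",
    H = "trnH", I = "trnI", K = "trnK", M = "trnM", N = "trnN", P = "trnP",
    Q = "trnQ", R = "trnR", T = "trnT", V = "trnV", W = "trnW", Y = "trnY")
}

aa3_to_1 <- function() {
  c(ala = "A", arg = "R", asn = "N", asp = "D", cys = "C", gln = "Q",
    glu = "E", gly = "G", his = "H", ile = "I", leu = "L", lys = "K",
    met = "M", phe = "F", pro = "P", ser = "S", thr = "T", trp = "W",
    tyr = "Y", val = "V")
}
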