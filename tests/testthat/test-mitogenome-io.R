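test_that("gene name normalization maps GenBank dialects to canonical names", {
  expect_equal(normalize_gene_name("COI"), "cox1")
  expect_equal(normalize_gene_name("cytochrome c oxidase subunit II"), "cox2")
  expect_equal(normalize_gene_name("cytochrome b"), "cob")
  expect_equal(normalize_gene_name("ND4L"), "nad4l")
  expect_equal(normalize_gene_name("s-rRNA"), "rrnS")
  expect_equal(normalize_gene_name("16S ribosomal RNA"), "rrnL")
  expect_equal(normalize_gene_name("D-loop"), "AT_rich")
  expect_equal(normalize_gene_name("tRNA-Ala"), "trnA")
  expect_equal(normalize_gene_name("trnW"), "trnW")
  # isoacceptor disambiguation: explicit tag > anticodon > codon family
  expect_equal(normalize_gene_name("trnL1"), "trnL1")
  expect_equal(
    normalize_gene_name("tRNA-Ser", c(anticodon = "(pos:1..3,aa:Ser,seq:gct)")),
    "trnS1")
  expect_equal(normalize_gene_name("tRNA-Ser", c(anticodon = "tga")), "trnS2")
  expect_equal(normalize_gene_name("tRNA-Leu", c(note = "codons recognized: UUR")),
               "trnL2")
  expect_equal(normalize_gene_name("tRNA-Leu", c(note = "(CUN)")), "trnL1")
  expect_error(normalize_gene_name("frobnicase"), "unknown gene name")
  expect_error(normalize_gene_name("tRNA-Ser"), "disambiguate")
})

test_that("gene sequences are extracted strand- and circularity-aware", {
  seqstr <- "AAAACGTACGTTTTGGGCCAAT"
  ann <- gene_annotation(c("cox1", "trnA", "trnY"),
                         c(10L, 2L, 18L), c(16L, 8L, 4L),
                         c("J", "N", "J"))
  rec <- mitogenome_record("toy", seqstr, ann)
  expect_equal(extract_gene_sequence(rec, "cox1"), substr(seqstr, 11, 16))
  expect_equal(extract_gene_sequence(rec, "trnA"), revcomp(substr(seqstr, 3, 8)))
  # wraps the origin: [18, 4) on a 22 bp ring
  wrapped <- extract_gene_sequence(rec, "trnY")
  expect_equal(nchar(wrapped), 22L - 18L + 4L)
  rotated <- paste0(substr(seqstr, 19, 22), substr(seqstr, 1, 18))
  expect_equal(wrapped, substr(rotated, 1, 8))
  expect_error(extract_gene_sequence(rec, "nad2"), "not found")
})

test_that("extracted length equals end - start modulo circularity", {
  rec <- fixture_record()
  ann <- rec$annotations
  for (i in seq_len(nrow(ann))) {
    expected <- if (ann$wraps_origin[i]) {
      rec$length - ann$start[i] + ann$end[i]
    } else {
      ann$end[i] - ann$start[i]
    }
    expect_equal(nchar(extract_gene_sequence(rec, ann$name[i])), expected)
  }
})

test_that("record validation reports missing, extra and duplicated genes", {
  rec <- fixture_record()
  v <- validate_record(rec)
  expect_true(v$complete)
  expect_equal(v$n_genes, 37L)
  expect_length(v$missing, 0L)
  expect_true(v$has_control_region)

  ann <- rec$annotations
  v2 <- validate_record(
    mitogenome_record(rec$taxon, rec$sequence,
                      ann[ann$name != "trnR", ]))
  expect_equal(v2$missing, "trnR")
  expect_false(v2$complete)

  dup <- ann[ann$name == "cox1", ]
  dup$name <- "cox1"
  v3 <- validate_record(
    mitogenome_record(rec$taxon, rec$sequence, rbind(ann, dup)))
  expect_equal(v3$duplicated, "cox1")
})

test_that("GenBank round trip is identity on canonical fields", {
  rec <- fixture_record()
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, gb)
  back <- read_genbank(gb)
  expect_identical(back$taxon, rec$taxon)
  expect_identical(back$sequence, rec$sequence)
  expect_identical(back$annotations, rec$annotations)
})

test_that("GenBank I/O handles complement and origin-spanning features", {
  set.seed(1)
  seqstr <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                  collapse = "")
  ann <- gene_annotation(c("cox1", "trnY"), c(10L, 90L), c(40L, 5L),
                         c("J", "N"))
  rec <- mitogenome_record("wrapper", seqstr, ann)
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, gb)
  back <- read_genbank(gb)
  expect_identical(back$annotations, rec$annotations)
  expect_true(back$annotations$wraps_origin[back$annotations$name == "trnY"])
  expect_equal(extract_gene_sequence(back, "trnY"),
               extract_gene_sequence(rec, "trnY"))
})

test_that("duplicate gene names in a GenBank file raise an annotation conflict", {
  rec <- fixture_record()
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, gb)
  lines <- readLines(gb)
  cds <- grep("^     CDS", lines)[1L]
  dup_block <- lines[cds:(cds + 2L)]
  writeLines(append(lines, dup_block, after = cds + 2L), gb)
  expect_error(read_genbank(gb), "annotation conflict")
})

test_that("feature-table pairs round trip", {
  rec <- fixture_record()
  fa <- withr::local_tempfile(fileext = ".fasta")
  tbl <- withr::local_tempfile(fileext = ".tbl")
  write_feature_table(rec, fa, tbl)
  back <- read_feature_table(fa, tbl)
  expect_identical(back$taxon, rec$taxon)
  expect_identical(back$sequence, rec$sequence)
  expect_identical(back$annotations, rec$annotations)
})

test_that("out-of-bounds annotations are rejected", {
  expect_error(
    mitogenome_record("bad", "ACGTACGT",
                      gene_annotation("cox1", 2L, 20L)),
    "coordinate error")
})
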