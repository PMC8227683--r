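# toy alignment sets with fixed lengths: 13 PCGs of 300, 22 tRNAs of 70,
# 2 rRNAs of 1000
toy_alignments <- function(n_taxa = 3L, seed = 9L) {
  set.seed(seed)
  taxa <- paste0("t", seq_len(n_taxa))
  mk <- function(L) {
    stats::setNames(replicate(n_taxa, paste(
      sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")), taxa)
  }
  alns <- c(lapply(stats::setNames(mito_pcgs(), mito_pcgs()),
                   function(g) mk(300L)),
            lapply(stats::setNames(mito_trnas(), mito_trnas()),
                   function(g) mk(70L)),
            lapply(stats::setNames(mito_rrnas(), mito_rrnas()),
                   function(g) mk(1000L)))
  alns
}

test_that("supermatrix lengths follow the variant arithmetic", {
  alns <- toy_alignments()
  expect_equal(concatenate(alns, "P123RNA")$length, 13L * 300L + 22L * 70L + 2000L)
  expect_equal(concatenate(alns, "P12RNA")$length, 13L * 200L + 22L * 70L + 2000L)
  expect_equal(concatenate(alns, "P123RNAexc3genes")$length, 7440L - 3L * 300L)
  expect_equal(concatenate(alns, "P12RNAexc3genes")$length,
               10L * 200L + 22L * 70L + 2000L)
  sm <- concatenate(alns, "P123RNA")
  expect_true(all(nchar(sm$seqs) == sm$length))
})

test_that("partition schemes carry the canonical block counts", {
  alns <- toy_alignments()
  expect_equal(nrow(concatenate(alns, "P123RNA")$scheme), 63L)
  expect_equal(nrow(concatenate(alns, "P12RNA")$scheme), 50L)
  expect_equal(nrow(concatenate(alns, "P123RNAexc3genes")$scheme), 54L)
  expect_equal(nrow(concatenate(alns, "P12RNAexc3genes")$scheme), 44L)
})

test_that("block sizes conserve the supermatrix site count", {
  alns <- toy_alignments()
  for (v in supermatrix_variants()) {
    sm <- concatenate(alns, v)
    expect_equal(sum(sm$scheme$n_sites), sm$length)
    # blocks are disjoint and cover every site exactly once
    covered <- integer(sm$length)
    for (i in seq_len(nrow(sm$scheme))) {
      idx <- seq(sm$scheme$start[i], sm$scheme$end[i], by = sm$scheme$stride[i])
      covered[idx] <- covered[idx] + 1L
    }
    expect_true(all(covered == 1L))
  }
})

test_that("dropping third positions commutes with concatenation", {
  alns <- toy_alignments()
  direct <- concatenate(alns, "P12RNA")
  full <- concatenate(alns, "P123RNA")
  # mask third positions of every PCG block out of the full supermatrix
  drop <- logical(full$length)
  for (i in seq_len(nrow(full$scheme))) {
    if (full$scheme$type[i] == "PCG_pos3") {
      idx <- seq(full$scheme$start[i], full$scheme$end[i],
                 by = full$scheme$stride[i])
      drop[idx] <- TRUE
    }
  }
  masked <- vapply(full$seqs, function(s)
    paste(strsplit(s, "")[[1L]][!drop], collapse = ""), character(1))
  expect_identical(unname(masked[direct$taxa]), unname(direct$seqs))
})

test_that("missing taxa are padded with gaps and residues conserved", {
  alns <- toy_alignments()
  alns[["trnW"]] <- alns[["trnW"]][-1L]     # drop taxon t1 from one gene
  expect_warning(sm <- concatenate(alns, "P123RNA"), "padded")
  expect_equal(sm$length, 7440L)
  gapless <- sum(strsplit(sm$seqs[["t1"]], "")[[1L]] != "-")
  expect_equal(gapless, 7440L - 70L)
})

test_that("frame violations are reported by gene name", {
  alns <- toy_alignments()
  alns[["cox1"]] <- stats::setNames(substr(alns[["cox1"]], 1L, 299L),
                                    names(alns[["cox1"]]))
  expect_error(concatenate(alns, "P123RNA"), "cox1")
})

test_that("partition files round trip in both dialects", {
  alns <- toy_alignments()
  sm <- concatenate(alns, "P12RNA")
  nex <- withr::local_tempfile(fileext = ".nex")
  rax <- withr::local_tempfile(fileext = ".txt")
  write_partitions(sm$scheme, nex, "nexus_charset")
  write_partitions(sm$scheme, rax, "raxml_style")
  for (f in c(nex, rax)) {
    back <- read_partitions(f)
    expect_equal(back$name, sm$scheme$name)
    expect_equal(back$start, sm$scheme$start)
    expect_equal(back$end, sm$scheme$end)
    expect_equal(back$stride, sm$scheme$stride)
  }
  expect_match(readLines(nex)[3L], "charset atp6_pos1 = 1-200\\\\2;", fixed = FALSE)
  expect_error(write_partitions(sm$scheme[0L, ], nex), "empty")
})

test_that("stop codons are stripped before concatenation", {
  aln <- c(t1 = "ATGAAATAA", t2 = "ATGCCCTAA")
  expect_equal(unname(strip_stop_codons(aln)), c("ATGAAA", "ATGCCC"))
  part <- c(t1 = "ATGAAAT", t2 = "ATGCCCT")
  expect_equal(unname(strip_stop_codons(part)), c("ATGAAA", "ATGCCC"))
  keep <- c(t1 = "ATGAAA", t2 = "ATGCCC")
  expect_equal(unname(strip_stop_codons(keep)), unname(keep))
})

test_that("partition sites can be extracted back out of the supermatrix", {
  alns <- toy_alignments()
  sm <- concatenate(alns, "P123RNA")
  cox1_pos2 <- partition_sites(sm, "cox1_pos2")
  manual <- vapply(alns[["cox1"]], function(s)
    paste(strsplit(s, "")[[1L]][seq(2L, 300L, by = 3L)], collapse = ""),
    character(1))
  expect_identical(cox1_pos2[sm$taxa], manual[sm$taxa])
})
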