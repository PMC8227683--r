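test_that("base counts separate ambiguity codes from ACGT", {
  bc <- base_counts("AATT")
  expect_equal(c(bc$A, bc$C, bc$G, bc$T), c(2L, 0L, 0L, 2L))
  bc0 <- base_counts("")
  expect_equal(bc0$total, 0L)
  bcn <- base_counts("ACGTN")
  expect_equal(bcn$N, 1L)
  expect_equal(bcn$total, 4L)
})

test_that("skews follow their defining formulas and sentinel rules", {
  expect_equal(at_skew(base_counts("AATT")), 0)
  expect_equal(at_skew(base_counts("AAAT")), 0.5)
  expect_equal(gc_skew(base_counts("GGGC")), 0.5)
  expect_true(is.na(at_skew(base_counts("GGCC"))))
  expect_true(is.na(gc_skew(base_counts("AATT"))))
  expect_equal(at_content("AAAA"), 100)
  expect_equal(at_skew("AAAA"), 1)
})

test_that("skews are antisymmetric under base exchange and reverse complement", {
  set.seed(7)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 200, replace = TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.35, 0.05)), collapse = "")
    swapped <- chartr("ATGC", "TACG", s)
    expect_equal(at_skew(swapped), -at_skew(s))
    expect_equal(gc_skew(swapped), -gc_skew(s))
    expect_equal(at_skew(revcomp(s)), -at_skew(s))
    expect_equal(gc_skew(revcomp(s)), -gc_skew(s))
  }
})

test_that("partition summaries reflect the generator's composition targets", {
  rec <- fixture_record()
  comp <- composition_by_partition(rec)
  expect_setequal(comp$partition,
                  c("whole", "PCGs", "tRNAs", "rRNAs", "AT_rich",
                    "codon_pos_1", "codon_pos_2", "codon_pos_3"))
  whole <- comp[comp$partition == "whole", ]
  expect_lt(abs(whole$at_content - 82), 2.5)
  expect_true(all(comp$at_skew >= -1 & comp$at_skew <= 1))
  expect_gt(comp$at_content[comp$partition == "AT_rich"],
            comp$at_content[comp$partition == "PCGs"])
  # reverse-complementing the genome negates the whole-genome skews
  flipped <- mitogenome_record(rec$taxon, revcomp(rec$sequence),
                               rec$annotations)
  comp2 <- composition_by_partition(flipped)
  expect_equal(comp2$at_skew[comp2$partition == "whole"], -whole$at_skew)
  expect_equal(comp2$gc_skew[comp2$partition == "whole"], -whole$gc_skew)
})

test_that("codon usage counts coding-sense codons and excludes stops", {
  ann <- gene_annotation("cox1", 0L, 9L)
  rec <- mitogenome_record("toy", "ATGTTATAA", ann)
  cu <- codon_usage(rec)
  expect_equal(unname(cu["ATG"]), 1L)
  expect_equal(unname(cu["TTA"]), 1L)
  expect_equal(sum(cu), 2L)  # TAA excluded entirely
  expect_false("TAA" %in% names(cu))

  # trailing partial stop: last nucleotide ignored
  rec2 <- mitogenome_record("toy", "ATGTTAT",
                            gene_annotation("cox1", 0L, 7L))
  expect_equal(sum(codon_usage(rec2)), 2L)

  # internal stop triggers a warning naming the gene
  rec3 <- mitogenome_record("toy", "ATGTAATTA",
                            gene_annotation("cox1", 0L, 9L))
  expect_warning(codon_usage(rec3), "internal stop.*cox1")
})

test_that("RSCU satisfies its defining identities", {
  cu <- codon_usage(fixture_record())
  tab <- rscu(cu)
  expect_true(all(tab$rscu >= 0))
  # count conservation: sum over family of rscu * total/degeneracy = total
  for (aa in unique(tab$amino_acid)) {
    fam <- tab[tab$amino_acid == aa, ]
    tot <- sum(fam$count)
    if (tot > 0) {
      expect_equal(sum(fam$rscu) * tot / nrow(fam), tot, tolerance = 1e-9)
      expect_equal(mean(fam$rscu), 1, tolerance = 1e-9)
    } else {
      expect_true(all(fam$rscu == 0))
    }
  }
  # degenerate cases
  counts <- stats::setNames(rep(0L, nrow(tab)), tab$codon)
  leu <- tab$codon[tab$amino_acid == "L"]
  counts[leu] <- 5L
  even <- rscu(counts)
  expect_true(all(even$rscu[even$amino_acid == "L"] == 1))
  counts[leu] <- 0L
  counts["TTA"] <- 12L
  solo <- rscu(counts)
  expect_equal(solo$rscu[solo$codon == "TTA"], 6)
})

test_that("start and stop codons are inferred including partial stops", {
  mk <- function(cds) mitogenome_record("toy", cds,
                                        gene_annotation("cox1", 0L, nchar(cds)))
  expect_equal(detect_start_stop(mk("ATGAAATAA"), "cox1"),
               list(start = "ATG", stop = "TAA"))
  expect_equal(detect_start_stop(mk("ATTAAATAG"), "cox1"),
               list(start = "ATT", stop = "TAG"))
  expect_equal(detect_start_stop(mk("ATGAAAT"), "cox1"),
               list(start = "ATG", stop = "T-"))
  expect_equal(detect_start_stop(mk("ATGAAATA"), "cox1"),
               list(start = "ATG", stop = "TA-"))
  # generator's planted partial stops surface as T-
  rec <- fixture_record()
  expect_equal(detect_start_stop(rec, "cob")$stop, "T-")
  expect_match(detect_start_stop(rec, "cox1")$start, "^AT[ACGT]$")
})

test_that("spacers and overlaps are accounted on the ring", {
  seqstr <- strrep("ACGT", 25)
  # abutting genes: nothing reported at that junction
  rec <- mitogenome_record("toy", seqstr,
                           gene_annotation(c("cox1", "cox2", "cox3"),
                                           c(0L, 10L, 30L), c(10L, 20L, 90L)))
  rep_ <- spacers_and_overlaps(rec)
  expect_equal(rep_$total_spacer_bp, 10L + 10L)  # 20-30 gap and 90->100->0 wrap
  expect_equal(rep_$n_spacer_locations, 2L)
  expect_equal(rep_$total_overlap_bp, 0L)

  rec2 <- mitogenome_record("toy", seqstr,
                            gene_annotation(c("cox1", "cox2"),
                                            c(0L, 8L), c(10L, 100L)))
  rep2 <- spacers_and_overlaps(rec2)
  expect_equal(rep2$total_overlap_bp, 2L)
  expect_equal(rep2$overlaps$upstream, "cox1")
})

test_that("spacer and overlap totals are invariant under origin rotation", {
  rec <- fixture_record()
  base <- spacers_and_overlaps(rec)
  for (shift in c(13L, 500L, 2222L)) {
    rot <- spacers_and_overlaps(rotate_record(rec, shift))
    expect_equal(rot$total_spacer_bp, base$total_spacer_bp)
    expect_equal(rot$n_spacer_locations, base$n_spacer_locations)
    expect_equal(rot$total_overlap_bp, base$total_overlap_bp)
  }
})
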