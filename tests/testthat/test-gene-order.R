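test_that("the ancestral pancrustacean order has the canonical structure", {
  anc <- ancestral_pancrustacean_order()
  expect_length(anc$genes, 37L)
  expect_setequal(anc$genes, canonical_genes())
  # IQM cluster with trnQ on the minority strand
  i <- match(c("trnI", "trnQ", "trnM"), anc$genes)
  expect_equal(diff(i), c(1L, 1L))
  expect_equal(anc$signs[i], c(1L, -1L, 1L))
  # ARNS1EF cluster in order, trnF on the minority strand
  j <- match(c("trnA", "trnR", "trnN", "trnS1", "trnE", "trnF"), anc$genes)
  expect_equal(diff(j), rep(1L, 5L))
  expect_equal(anc$signs[j], c(1L, 1L, 1L, 1L, 1L, -1L))
  # WCY cluster
  k <- match(c("trnW", "trnC", "trnY"), anc$genes)
  expect_equal(diff(k), c(1L, 1L))
})

test_that("gene orders are extracted and rotation-normalized from records", {
  rec <- fixture_record()
  anc <- ancestral_pancrustacean_order()
  go <- gene_order_of(rec)
  expect_identical(go$genes, anc$genes)
  expect_identical(go$signs, anc$signs)
  # a record whose file origin falls mid-genome yields the same order
  rot <- gene_order_of(rotate_record(rec, 4000L))
  expect_identical(rot$genes, go$genes)
  expect_identical(rot$signs, go$signs)
})

test_that("signed token strings round trip", {
  anc <- ancestral_pancrustacean_order()
  expect_identical(parse_gene_order(format_gene_order(anc))$genes, anc$genes)
  expect_identical(parse_gene_order(format_gene_order(anc))$signs, anc$signs)
  expect_match(format_gene_order(anc), "^cox1 trnL2")
  expect_match(format_gene_order(anc), "-trnQ")
})

test_that("no events are inferred between identical orders", {
  anc <- ancestral_pancrustacean_order()
  expect_length(infer_events(anc, anc), 0L)
  rec <- fixture_record()
  expect_length(infer_events(gene_order_of(rec), anc), 0L)
})

test_that("the ARNS1EF rearrangement is a single reverse transposition of trnR", {
  anc <- ancestral_pancrustacean_order()
  q <- apply_events(anc, list(
    structure(list(kind = "reverse_transposition", genes = "trnR",
                   from_context = c("trnA", "trnN"),
                   to_context = c("trnE", "trnF"), cluster = "ARNS1EF"),
              class = "rearrangement_event")))
  ev <- infer_events(q, anc)
  expect_length(ev, 1L)
  expect_equal(ev[[1L]]$kind, "reverse_transposition")
  expect_equal(ev[[1L]]$genes, "trnR")
  expect_equal(ev[[1L]]$cluster, "ARNS1EF")
  expect_equal(q$signs[match("trnR", q$genes)], -1L)
})

test_that("replaying inferred events reproduces the query order", {
  anc <- ancestral_pancrustacean_order()
  meg <- megabelesesinae_order()
  ev <- infer_events(meg, anc)
  replayed <- apply_events(anc, ev)
  expect_identical(replayed$genes, meg$genes)
  expect_identical(replayed$signs, meg$signs)
  # property over random small permutations
  genes <- paste0("g", 1:6)
  ref <- gene_order(genes, rep(1L, 6L))
  set.seed(11)
  for (rep in 1:40) {
    perm <- c(1L, 1L + sample(5L))
    sgn <- sample(c(-1L, 1L), 6L, replace = TRUE)
    q <- gene_order(genes[perm], sgn)
    ev <- infer_events(q, ref, depth = 3L)
    if (length(ev) == 1L && ev[[1L]]$kind == "unresolved_block") next
    rp <- apply_events(ref, ev)
    expect_identical(rp$genes, q$genes)
    expect_identical(rp$signs, q$signs)
  }
})

test_that("inferred event counts match the brute-force minimum (sampled)", {
  genes <- paste0("g", 1:5)
  ref <- gene_order(genes, rep(1L, 5L))
  tab <- oracle_distance_table(5L, depth = 3L)
  set.seed(23)
  for (rep in 1:60) {
    qv <- c(sample(c(1L, -1L), 1L),
            (1L + sample(4L)) * sample(c(-1L, 1L), 4L, replace = TRUE))
    q <- gene_order(genes[abs(qv)], sign(qv))
    ev <- infer_events(q, ref, depth = 3L)
    mine <- if (length(ev) == 1L && ev[[1L]]$kind == "unresolved_block")
      NA_integer_ else length(ev)
    oracle <- tab[[paste(qv, collapse = " ")]]
    if (is.null(oracle)) {
      expect_true(is.na(mine))
    } else {
      expect_equal(mine, oracle)
    }
  }
})

test_that("orders beyond the search depth yield a single unresolved block", {
  genes <- paste0("g", 1:8)
  ref <- gene_order(genes, rep(1L, 8L))
  q <- gene_order(genes[c(1, 3, 2, 5, 4, 7, 6, 8)],
                  c(1L, -1L, 1L, -1L, 1L, -1L, 1L, -1L))
  ev <- infer_events(q, ref, depth = 1L)
  expect_length(ev, 1L)
  expect_equal(ev[[1L]]$kind, "unresolved_block")
  expect_true(all(c("g2", "g7") %in% ev[[1L]]$genes))
})

test_that("events shared by a clade are flagged synapomorphic", {
  anc <- ancestral_pancrustacean_order()
  meg <- megabelesesinae_order()
  orders <- lapply(sprintf("c%d", 1:4), function(tx)
    gene_order(meg$genes, meg$signs, tx))
  shared <- shared_derived_events(orders, anc, clade = sprintf("c%d", 1:4))
  expect_true(all(shared$n_taxa == 4L))
  expect_true(all(shared$synapomorphic))
  expect_setequal(unique(shared$cluster), c("IQM", "ARNS1EF"))

  # an outsider carrying the same events breaks the flag
  orders2 <- c(orders, list(gene_order(meg$genes, meg$signs, "intruder")))
  shared2 <- shared_derived_events(orders2, anc, clade = sprintf("c%d", 1:4))
  expect_false(any(shared2$synapomorphic))

  empty <- shared_derived_events(list(), anc, clade = "c1")
  expect_equal(nrow(empty), 0L)
})

test_that("event inference is invariant under rotation of the query", {
  anc <- ancestral_pancrustacean_order()
  meg <- megabelesesinae_order()
  ev1 <- infer_events(meg, anc)
  rot <- gene_order(c(meg$genes[15:37], meg$genes[1:14]),
                    c(meg$signs[15:37], meg$signs[1:14]), meg$taxon)
  ev2 <- infer_events(rot, anc)
  expect_equal(vapply(ev1, format, character(1)),
               vapply(ev2, format, character(1)))
})
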