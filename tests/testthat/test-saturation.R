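test_that("p-distance uses pairwise deletion", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("AAAA", "AATT"), 0.5)
  expect_equal(p_distance("AA-A", "AAGA"), 0)        # gap site excluded
  expect_equal(p_distance("AANA", "AAGA"), 0)        # ambiguity excluded
  expect_true(is.na(p_distance("----", "AAAA")))
  expect_error(p_distance("AAA", "AAAA"), "length")
})

test_that("discrete gamma categories are mean-preserving", {
  for (alpha in c(0.2, 0.75, 2, 50)) {
    r <- discrete_gamma_rates(alpha, 4L)
    expect_length(r, 4L)
    expect_equal(mean(r), 1)
    expect_true(all(diff(r) > 0))
  }
  # large shape approaches rate homogeneity
  expect_lt(max(abs(discrete_gamma_rates(1e6, 4L) - 1)), 1e-2)
})

test_that("GTR+G+I distance reduces to Jukes-Cantor in the equal-rate limit", {
  mod <- gtr_model(rep(0.25, 4), rep(1, 6), alpha = 1e6, p_inv = 0)
  set.seed(31)
  for (p_target in c(0.1, 0.3, 0.5)) {
    n <- 20000L
    a <- sample.int(4L, n, replace = TRUE)
    b <- a
    nm <- round(n * p_target)
    idx <- sample.int(n, nm)
    b[idx] <- ((a[idx] - 1L + sample.int(3L, nm, replace = TRUE)) %% 4L) + 1L
    d <- gtr_gi_distance(a, b, mod)
    p <- p_distance(a, b)
    jc <- -0.75 * log(1 - 4 * p / 3)
    expect_lt(abs(as.numeric(d) - jc), 1e-3)
  }
})

test_that("corrected distances dominate p-distances and are symmetric", {
  mod <- gtr_model(c(0.36, 0.1, 0.08, 0.46), c(1, 5, 1, 1, 8, 1),
                   alpha = 0.75, p_inv = 0.1)
  set.seed(17)
  for (rep in 1:15) {
    n <- 500L
    a <- sample.int(4L, n, replace = TRUE, prob = mod$pi)
    b <- a
    idx <- sample.int(n, sample(50:350, 1L))
    b[idx] <- sample.int(4L, length(idx), replace = TRUE)
    d <- as.numeric(gtr_gi_distance(a, b, mod))
    expect_gte(d, p_distance(a, b) - 1e-6)
    expect_equal(d, as.numeric(gtr_gi_distance(b, a, mod)), tolerance = 1e-6)
  }
  expect_equal(as.numeric(gtr_gi_distance("ACGT", "ACGT", mod)), 0)
})

test_that("distance estimates converge to the true divergence", {
  mod <- gtr_model(c(0.36, 0.1, 0.08, 0.46), c(1, 5, 1, 1, 8, 1),
                   alpha = 0.9, p_inv = 0)
  true_d <- 0.5
  set.seed(53)
  rmse <- sapply(c(1000L, 10000L, 50000L), function(n) {
    errs <- sapply(1:3, function(rep) {
      rates <- mod$gamma_rates[sample.int(4L, n, replace = TRUE)]
      a <- sample.int(4L, n, replace = TRUE, prob = mod$pi)
      b <- vapply(seq_len(n), function(i) {
        P <- mitocomp:::gtr_pmat(mod, true_d * rates[i])
        sample.int(4L, 1L, prob = P[a[i], ])
      }, integer(1))
      as.numeric(gtr_gi_distance(a, b, mod)) - true_d
    })
    sqrt(mean(errs^2))
  })
  expect_lt(rmse[3], 0.05)
  expect_lt(rmse[3], rmse[1])
})

test_that("model estimation contracts hold on degenerate input", {
  expect_error(estimate_model(c(a = "AAAA")), "at least two")
  expect_error(suppressWarnings(estimate_model(c(a = "AAAA", b = "AAAA"))),
               "degenerate")
  expect_warning(
    try(estimate_model(c(a = "ACGTACGTACGTAAA", b = "ACGAACGTACTTAAA"),
                       n_starts = 1L, n_rounds = 1L, maxit = 20L),
        silent = TRUE),
    "identifiable")
})

test_that("the saturation screen separates slow from saturated partitions", {
  set.seed(71)
  tr <- ape::rtree(10L, br = function(k) stats::runif(k, 0.1, 0.4))
  mod <- gtr_model(rep(0.25, 4), rep(1, 6), alpha = 1, p_inv = 0)
  simulate_partition <- function(mult, n_sites) {
    cfgseqs <- matrix(0L, 10L, n_sites)
    S <- mitocomp:::sim_sites(tr, mod, rep(mult, n_sites))
    seqs <- apply(S[1:10, , drop = FALSE], 1L, function(x)
      paste(c("A", "C", "G", "T")[x], collapse = ""))
    stats::setNames(seqs, tr$tip.label)
  }
  parts <- list(slow = simulate_partition(0.1, 800L),
                fast = simulate_partition(25, 800L))
  rep_ <- saturation_screen(parts, mod, bottom_k = 1L)
  expect_equal(nrow(rep_), 2L)
  r_slow <- rep_$r[rep_$partition == "slow"]
  r_fast <- rep_$r[rep_$partition == "fast"]
  expect_gt(r_slow, 0.99)
  expect_lt(r_fast, r_slow)
  expect_true(rep_$flagged[rep_$partition == "fast"])

  # constant-distance partitions are excluded with a warning
  const <- stats::setNames(rep("ACGTACGT", 4L), paste0("t", 1:4))
  expect_warning(out <- saturation_screen(list(flat = const), mod),
                 "constant|fewer")
  expect_equal(nrow(out), 0L)
})

test_that("distance matrices and PHYLIP output are consistent", {
  sim <- fixture_sim()
  aln <- sapply(sim$tree$tip.label, function(tx)
    paste(vapply(sim$genes[c("cox1", "rrnS")], function(g) g[[tx]],
                 character(1)), collapse = ""))
  Dp <- p_distance_matrix(aln)
  expect_true(isSymmetric(Dp))
  expect_true(all(diag(Dp) == 0))
  mod <- gtr_model(rep(0.25, 4))
  Dc <- gtr_distance_matrix(aln, mod)
  expect_true(all(Dc >= Dp - 1e-6))
  f <- withr::local_tempfile(fileext = ".dist")
  write_phylip_distances(Dc, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1L])), nrow(Dc))
  expect_length(lines, nrow(Dc) + 1L)
})
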