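# Substitution-saturation screening: uncorrected p-distances, pairwise
# maximum-likelihood distances under GTR+Gamma+I, and per-partition
# correlation between the two.
#
# Alignments are named character vectors of equal-length sequences
# (names = taxa).  Gaps and ambiguity codes are excluded pairwise.

encode_seq <- function(s) {
  m <- match(seq_chars(toupper(s)), c("A", "C", "G", "T"))
  m
}

as_alignment_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  stopifnot(is.character(aln), !is.null(names(aln)))
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("alignment sequences differ in length", call. = FALSE)
  do.call(rbind, lapply(aln, encode_seq))
}

#' Discrete-gamma category rates
#'
#' `k` mean-preserving categories of a gamma(shape = alpha, rate = alpha)
#' rate distribution: equal-probability bins, each represented by its
#' conditional mean, so that the category mean is exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param k Number of categories.
#' @return Numeric vector of `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  stopifnot(alpha > 0, k >= 1L)
  if (k == 1L) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  r <- k * diff(stats::pgamma(b, shape = alpha + 1, rate = alpha))
  r / mean(r)
}

#' Construct a GTR+Gamma+I substitution model
#'
#' General time-reversible rate matrix with discrete-gamma rate
#' heterogeneity and a proportion of invariant sites.  The rate matrix is
#' normalized so that the expected substitution rate across the
#' non-invariant mixture is 1, i.e. branch lengths/distances are in
#' expected substitutions per site.
#'
#' @param pi Base frequencies (A, C, G, T); must be positive and sum to 1.
#' @param rates Exchangeabilities (AC, AG, AT, CG, CT, GT); GT is the
#'   reference and is conventionally 1.
#' @param alpha Gamma shape (dimensionless, > 0).
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @param k Number of discrete gamma categories (default 4).
#' @return An object of class `gtr_model` carrying the eigendecomposition
#'   of the normalized rate matrix and the category rates.
#' @export
gtr_model <- function(pi = rep(0.25, 4), rates = rep(1, 6), alpha = 1,
                      p_inv = 0, k = 4L) {
  stopifnot(length(pi) == 4L, all(pi > 0), abs(sum(pi) - 1) < 1e-8,
            length(rates) == 6L, all(rates > 0), alpha > 0,
            p_inv >= 0, p_inv < 1)
  pi <- as.numeric(pi) / sum(pi)
  # symmetric exchangeability matrix, order AC AG AT CG CT GT
  R <- matrix(0, 4, 4,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  R["A", "C"] <- R["C", "A"] <- rates[1]
  R["A", "G"] <- R["G", "A"] <- rates[2]
  R["A", "T"] <- R["T", "A"] <- rates[3]
  R["C", "G"] <- R["G", "C"] <- rates[4]
  R["C", "T"] <- R["T", "C"] <- rates[5]
  R["G", "T"] <- R["T", "G"] <- rates[6]
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / (mu * (1 - p_inv))
  # reversible eigendecomposition via pi^(1/2) symmetrization
  sp <- sqrt(pi)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((S + t(S)) / 2, symmetric = TRUE)
  U <- diag(1 / sp) %*% eig$vectors
  W <- t(eig$vectors) %*% diag(sp)
  structure(
    list(pi = pi, rates = as.numeric(rates), alpha = alpha, p_inv = p_inv,
         k = as.integer(k), gamma_rates = discrete_gamma_rates(alpha, k),
         U = U, W = W, lambda = eig$values),
    class = "gtr_model"
  )
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("GTR+G+I model\n")
  cat("  pi:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat("  rates (AC AG AT CG CT GT):",
      paste(sprintf("%.3f", x$rates), collapse = " "), "\n")
  cat(sprintf("  alpha: %.3f  p_inv: %.3f  k: %d\n", x$alpha, x$p_inv, x$k))
  invisible(x)
}

# transition probability matrix at distance t (per-category rate applied
# by the caller)
gtr_pmat <- function(model, t) {
  P <- model$U %*% (exp(model$lambda * t) * model$W)
  P[P < 0] <- 0
  P
}

# joint site-pattern probability matrix at distance d (4x4)
gtr_joint <- function(model, d) {
  M <- matrix(0, 4, 4)
  for (c_ in seq_len(model$k)) {
    M <- M + gtr_pmat(model, d * model$gamma_rates[c_])
  }
  M <- (1 - model$p_inv) / model$k * (model$pi * M)
  diag(M) <- diag(M) + model$p_inv * model$pi
  M
}

pair_counts <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  matrix(tabulate((a[ok] - 1L) * 4L + b[ok], 16L), 4, 4, byrow = TRUE)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among sites where both sequences carry an
#' unambiguous base (pairwise deletion of gaps and ambiguity codes).
#'
#' @param a,b Aligned sequences (strings of equal length).
#' @return Proportion in `[0, 1)`, or `NA` when no site is comparable.
#' @export
p_distance <- function(a, b) {
  ea <- if (is.character(a)) encode_seq(a) else a
  eb <- if (is.character(b)) encode_seq(b) else b
  if (length(ea) != length(eb)) stop("sequences differ in length", call. = FALSE)
  ok <- !is.na(ea) & !is.na(eb)
  n <- sum(ok)
  if (n == 0L) return(NA_real_)
  sum(ea[ok] != eb[ok]) / n
}

pair_loglik <- function(N, model, d) {
  M <- gtr_joint(model, d)
  use <- N > 0
  if (any(M[use] <= 0)) return(-Inf)
  sum(N[use] * log(M[use]))
}

#' Maximum-likelihood pairwise distance under GTR+Gamma+I
#'
#' Maximizes the pairwise likelihood of the observed site-pattern counts
#' over the distance `d` by bracketed one-dimensional search.  Distances
#' reaching the cap are returned with a `saturated` attribute.
#'
#' @param a,b Aligned sequences.
#' @param model A [gtr_model()].
#' @param max_dist Distance cap (substitutions/site; default 10).
#' @param tol Convergence tolerance on `d` (default 1e-8).
#' @return Distance in substitutions/site (`NA` when no site is
#'   comparable), with attribute `saturated` set when capped.
#' @export
gtr_gi_distance <- function(a, b, model, max_dist = 10, tol = 1e-8) {
  ea <- if (is.character(a)) encode_seq(a) else a
  eb <- if (is.character(b)) encode_seq(b) else b
  if (length(ea) != length(eb)) stop("sequences differ in length", call. = FALSE)
  N <- pair_counts(ea, eb)
  if (sum(N) == 0) return(NA_real_)
  if (sum(N) == sum(diag(N))) return(0)
  opt <- stats::optimize(function(d) pair_loglik(N, model, d),
                         interval = c(tol, max_dist), maximum = TRUE,
                         tol = tol)
  d <- opt$maximum
  # flag likelihood still rising at the cap
  if (d > max_dist * (1 - 1e-3) &&
      pair_loglik(N, model, max_dist) >= pair_loglik(N, model, d) - 1e-9) {
    d <- max_dist
    attr(d, "saturated") <- TRUE
  }
  d
}

#' Pairwise distance matrices for an alignment
#'
#' @param aln Alignment (named character vector of equal-length strings).
#' @param model A [gtr_model()] (for `gtr_distance_matrix`).
#' @param ... Passed to [gtr_gi_distance()].
#' @return Symmetric matrix with taxa as dimnames; attribute `kind` is
#'   `"p"` or `"gtr_gi"`.
#' @export
p_distance_matrix <- function(aln) {
  M <- as_alignment_matrix(aln)
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  if (is.null(rownames(M)) && is.character(aln)) {
    dimnames(D) <- list(names(aln), names(aln))
  }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    D[i, j] <- D[j, i] <- p_distance(M[i, ], M[j, ])
  }
  attr(D, "kind") <- "p"
  D
}

#' @rdname p_distance_matrix
#' @export
gtr_distance_matrix <- function(aln, model, ...) {
  M <- as_alignment_matrix(aln)
  n <- nrow(M)
  nms <- rownames(M) %||% names(aln)
  D <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    D[i, j] <- D[j, i] <- as.numeric(gtr_gi_distance(M[i, ], M[j, ], model, ...))
  }
  attr(D, "kind") <- "gtr_gi"
  D
}

#' Estimate a GTR+Gamma+I model from a multiple alignment
#'
#' Base frequencies are taken empirically; exchangeabilities, gamma shape
#' and invariant proportion maximize the sum of pairwise log-likelihoods
#' with each pair's distance jointly optimized (composite pairwise
#' likelihood).  The optimization alternates between re-estimating all
#' pairwise distances at the current parameters and Nelder-Mead updates of
#' the parameters at fixed distances, from several deterministic starts
#' spread across the gamma-shape / invariant-proportion ridge.
#'
#' @param aln Alignment (named character vector or encoded matrix).
#' @param k Gamma categories.
#' @param max_pairs Pairs are subsampled to at most this many for the
#'   optimization (deterministically, given `seed`).
#' @param n_starts Number of optimization starts (diverse alpha/p_inv).
#' @param n_rounds Coordinate-ascent rounds per start.
#' @param maxit Nelder-Mead iteration cap per parameter update.
#' @param seed Seed controlling pair subsampling and start jitter.
#' @return A fitted [gtr_model()] with a `logLik` attribute (the composite
#'   pairwise log-likelihood at the optimum).
#' @export
estimate_model <- function(aln, k = 4L, max_pairs = 60L, n_starts = 4L,
                           n_rounds = 4L, maxit = 300L, seed = 1L) {
  M <- as_alignment_matrix(aln)
  n <- nrow(M)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  if (n == 2L) {
    warning("two-sequence alignment: GTR+G+I parameters are weakly ",
            "identifiable")
  }
  counts <- tabulate(M[!is.na(M)], 4L)
  if (any(counts == 0)) stop("degenerate alignment: some base never observed",
                             call. = FALSE)
  pi <- counts / sum(counts)
  pairs <- utils::combn(n, 2L)
  if (ncol(pairs) > max_pairs) {
    old <- .Random.seed_save()
    set.seed(derive_seed(seed, 17L))
    pairs <- pairs[, sort(sample.int(ncol(pairs), max_pairs)), drop = FALSE]
    .Random.seed_restore(old)
  }
  Ns <- lapply(seq_len(ncol(pairs)), function(c_) {
    pair_counts(M[pairs[1L, c_], ], M[pairs[2L, c_], ])
  })
  Ns <- Ns[vapply(Ns, function(N) sum(N) > 0 && sum(N) > sum(diag(N)),
                  logical(1))]
  if (!length(Ns)) stop("degenerate alignment: no variable pair ",
                        "(constant or identical sequences)", call. = FALSE)

  make_model <- function(theta) {
    gtr_model(pi, c(exp(theta[1:5]), 1), min(exp(theta[6]), 500),
              stats::plogis(theta[7]), k)
  }
  update_dists <- function(mod, tol = 1e-6) {
    vapply(Ns, function(N) {
      stats::optimize(function(d) pair_loglik(N, mod, d),
                      interval = c(1e-8, 10), maximum = TRUE,
                      tol = tol)$maximum
    }, numeric(1))
  }
  ll_at <- function(mod, ds) {
    sum(vapply(seq_along(Ns), function(j) pair_loglik(Ns[[j]], mod, ds[j]),
               numeric(1)))
  }

  base_starts <- list(
    c(rep(0, 5), log(0.5), stats::qlogis(0.05)),
    c(rep(0, 5), log(1.5), stats::qlogis(0.15)),
    c(rep(0, 5), log(5), stats::qlogis(0.3)),
    c(rep(0, 5), log(0.2), stats::qlogis(0.3))
  )
  old <- .Random.seed_save()
  set.seed(derive_seed(seed, 43L))
  starts <- lapply(seq_len(n_starts), function(i) {
    s0 <- base_starts[[((i - 1L) %% length(base_starts)) + 1L]]
    if (i > length(base_starts)) s0 <- s0 + stats::rnorm(7L, 0, 0.4)
    s0
  })
  .Random.seed_restore(old)

  best <- NULL
  for (s0 in starts) {
    theta <- s0
    ds <- update_dists(make_model(theta))
    for (r in seq_len(n_rounds)) {
      fit <- stats::optim(theta, function(th) {
        mod <- make_model(th)
        -ll_at(mod, ds)
      }, method = "Nelder-Mead",
      control = list(maxit = maxit, reltol = 1e-9))
      theta <- fit$par
      ds <- update_dists(make_model(theta))
    }
    ll <- ll_at(make_model(theta), ds)
    if (is.null(best) || ll > best$ll) best <- list(theta = theta, ll = ll)
  }
  mod <- make_model(best$theta)
  attr(mod, "logLik") <- best$ll
  mod
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Substitution-saturation screen across partitions
#'
#' For each partition, correlates the model-corrected (GTR+Gamma+I)
#' pairwise distances with the uncorrected p-distances over the
#' lower-triangle pairs.  Partitions with correlation below `threshold`,
#' or ranking in the bottom `bottom_k`, are flagged as saturated.
#'
#' @param partitions Named list of alignments.
#' @param models A single [gtr_model()] applied to all partitions, or a
#'   named list parallel to `partitions`.
#' @param threshold Correlation below which a partition is flagged.
#' @param bottom_k Number of lowest-correlation partitions always flagged.
#' @param method Correlation type: `"pearson"` (default) or `"spearman"`.
#' @return Data frame of class `saturation_report`: `partition`, `r`,
#'   `n_pairs`, `mean_p`, `mean_corrected`, `flagged`.
#' @export
saturation_screen <- function(partitions, models, threshold = 0.9,
                              bottom_k = 3L, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.list(partitions), length(names(partitions)) == length(partitions))
  single <- inherits(models, "gtr_model")
  rows <- list()
  for (p in names(partitions)) {
    mod <- if (single) models else models[[p]]
    Dp <- p_distance_matrix(partitions[[p]])
    Dc <- gtr_distance_matrix(partitions[[p]], mod)
    lp <- Dp[lower.tri(Dp)]
    lc <- Dc[lower.tri(Dc)]
    ok <- !is.na(lp) & !is.na(lc)
    if (sum(ok) < 3L) {
      warning("partition ", p, " has fewer than 3 usable pairs; excluded")
      next
    }
    lp <- lp[ok]; lc <- lc[ok]
    r <- if (stats::sd(lp) == 0 || stats::sd(lc) == 0) NA_real_ else
      stats::cor(lp, lc, method = method)
    if (is.na(r)) {
      warning("partition ", p, " has constant distances; excluded")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      partition = p, r = r, n_pairs = sum(ok), mean_p = mean(lp),
      mean_corrected = mean(lc), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(partition = character(0), r = numeric(0),
                      n_pairs = integer(0), mean_p = numeric(0),
                      mean_corrected = numeric(0), flagged = logical(0))
    class(out) <- c("saturation_report", "data.frame")
    return(out)
  }
  rk <- rank(out$r, ties.method = "first")
  out$flagged <- out$r < threshold | rk <= min(bottom_k, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("saturation_report", "data.frame")
  out
}

#' Write a distance matrix as square PHYLIP
#'
#' @param D Symmetric distance matrix with taxon dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_distances <- function(D, path) {
  n <- nrow(D)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(sprintf("%-10s", rownames(D)[i]),
                      paste(sprintf("%.6f", D[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write aligned FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_alignment
#' @param aln Named character vector of equal-length sequences.
#' @export
write_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln), path)
  invisible(path)
}
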