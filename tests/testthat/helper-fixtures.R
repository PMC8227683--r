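# Shared fixtures (built in code, cached per session) and independent
# oracles used across the test files.

.fixture_env <- new.env(parent = emptyenv())

# a small but complete synthetic dataset reused by many tests
fixture_sim <- function(seed = 3L, scale = 0.1, n_taxa = 8L) {
  key <- paste("sim", seed, scale, n_taxa, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_mitogenomes(
      sim_config(seed = seed, gene_length_scale = scale, n_taxa = n_taxa))
  }
  .fixture_env[[key]]
}

fixture_record <- function(taxon = "t02", ...) fixture_sim(...)$records[[taxon]]

# rotate the circular origin of a record by `shift` bp (annotations and
# sequence move together)
rotate_record <- function(rec, shift) {
  L <- rec$length
  shift <- shift %% L
  seq2 <- paste0(substr(rec$sequence, shift + 1L, L),
                 substr(rec$sequence, 1L, shift))
  ann <- rec$annotations
  st <- (ann$start - shift) %% L
  en <- ann$end - shift
  en <- ifelse(en <= 0L, en + L, en)
  en[en > L] <- en[en > L] - L
  mitogenome_record(rec$taxon, seq2, gene_annotation(ann$name, st, en, ann$strand))
}

## ------------------------------------------------------------------
## independent brute-force oracle for rearrangement events: explicit word
## surgery, breadth-first from the reference word

oracle_event_list <- function(n) {
  evs <- list()
  for (i in 1:n) for (j in i:n) {
    evs[[length(evs) + 1L]] <- list(kind = "inv", i = i, j = j)
  }
  for (i in 1:n) for (j in i:n) {
    L <- j - i + 1L
    if (L == n) next
    for (p in 0:(n - L)) {
      if (p == i - 1L) next
      evs[[length(evs) + 1L]] <- list(kind = "tr", i = i, j = j, p = p)
      evs[[length(evs) + 1L]] <- list(kind = "rt", i = i, j = j, p = p)
    }
  }
  evs
}

oracle_apply_event <- function(s, e) {
  if (e$kind == "inv") {
    s[e$i:e$j] <- -rev(s[e$i:e$j])
    return(s)
  }
  blk <- s[e$i:e$j]
  rest <- s[-(e$i:e$j)]
  if (e$kind == "rt") blk <- -rev(blk)
  append(rest, blk, after = e$p)
}

# full table of minimal event counts from the identity word, up to `depth`
# events, for every reachable signed word of length n.  Event actions are
# derived from their images of the identity word (a first-principles
# recovery of the action as a signed position map), then applied in bulk.
oracle_distance_table <- function(n, depth = 3L) {
  key <- paste("oracle", n, depth, sep = "_")
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  id <- seq_len(n)
  evs <- oracle_event_list(n)
  images <- lapply(evs, function(e) oracle_apply_event(id, e))
  perms <- lapply(images, abs)
  sgns <- lapply(images, sign)
  env <- new.env(parent = emptyenv())
  env[[paste(id, collapse = " ")]] <- 0L
  frontier <- matrix(id, ncol = 1L)
  for (d in seq_len(depth)) {
    kids <- vector("list", length(evs))
    for (k in seq_along(evs)) {
      kids[[k]] <- frontier[perms[[k]], , drop = FALSE] * sgns[[k]]
    }
    allk <- do.call(cbind, kids)
    keys <- do.call(paste, as.data.frame(t(allk)))
    known <- !vapply(mget(keys, envir = env, ifnotfound = list(NULL)),
                     is.null, logical(1))
    keep <- which(!known & !duplicated(keys))
    for (t in keep) env[[keys[t]]] <- d
    frontier <- allk[, keep, drop = FALSE]
    if (!ncol(frontier)) break
  }
  .fixture_env[[key]] <- env
  env
}

# enumerate all signed words of length n whose first element is +-1
all_signed_words <- function(n) {
  perm_list <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (r in perm_list(v[-i])) out[[length(out) + 1L]] <- c(v[i], r)
    }
    out
  }
  rest <- perm_list(seq(2L, n))
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n - 1L)))
  out <- list()
  for (s1 in c(1L, -1L)) {
    for (p in rest) {
      for (r in seq_len(nrow(signs))) {
        out[[length(out) + 1L]] <- c(s1, p * signs[r, ])
      }
    }
  }
  out
}

## ------------------------------------------------------------------
## independent bipartition oracle for Robinson-Foulds

oracle_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  labs <- sort(tree$tip.label)
  edges <- tree$edge
  internal <- which(edges[, 2L] > n)
  sigs <- character(0)
  for (k in internal) {
    # all tips below the child end of edge k
    side_nodes <- edges[k, 2L]
    repeat {
      new_nodes <- setdiff(edges[edges[, 1L] %in% side_nodes, 2L], side_nodes)
      if (!length(new_nodes)) break
      side_nodes <- c(side_nodes, new_nodes)
    }
    tips <- sort(tree$tip.label[side_nodes[side_nodes <= n]])
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    comp <- setdiff(labs, tips)
    canon <- if (labs[1L] %in% tips) tips else comp
    sigs <- c(sigs, paste(canon, collapse = "|"))
  }
  unique(sigs)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# random additive distance matrix from a random tree
random_tree_and_dist <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 0.5))
  list(tree = tr, D = stats::cophenetic(tr))
}
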