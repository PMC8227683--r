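# Distance-based tree estimation and topology checks.  Trees are ape
# "phylo" objects throughout; newick I/O goes through ape.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration.  Ties in the Q-criterion are
#' broken by lexicographic taxon-pair order of the current node labels;
#' negative branch lengths are clamped to zero with the deficit moved to
#' the sibling branch.
#'
#' @param D Symmetric distance matrix with taxon dimnames (no `NA`).
#' @return An unrooted `phylo` tree (one trifurcating internal node).
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (any(is.na(D) | !is.finite(D))) {
    bad <- which(is.na(D) | !is.finite(D), arr.ind = TRUE)
    bad <- bad[bad[, 1L] < bad[, 2L], , drop = FALSE]
    stop("undefined distances for pair(s): ",
         paste(apply(bad, 1L, function(ij)
           paste(rownames(D)[ij[1L]], colnames(D)[ij[2L]], sep = "-")),
           collapse = ", "), call. = FALSE)
  }
  labels <- rownames(D)
  # node bookkeeping: tips 1..n; internal nodes appended as n+1, n+2, ...
  active <- seq_len(n)          # row indices into D
  node_id <- seq_len(n)         # ape node numbers for active rows
  node_lab <- labels            # for deterministic tie-breaking
  next_internal <- n + 1L
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0)

  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pl <- cbind(pmin(node_lab[cand[, 1L]], node_lab[cand[, 2L]]),
                pmax(node_lab[cand[, 1L]], node_lab[cand[, 2L]]))
    o <- order(pl[, 1L], pl[, 2L])[1L]
    i <- cand[o, 1L]; j <- cand[o, 2L]
    dij <- Dm[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    # clamp negatives, moving the deficit to the sibling
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    if (li < 0) li <- 0
    if (lj < 0) lj <- 0
    new_node <- next_internal
    next_internal <- next_internal + 1L
    edges <- rbind(edges, c(new_node, node_id[i]), c(new_node, node_id[j]))
    lens <- c(lens, li, lj)
    # distances from the new node to remaining taxa
    keep <- setdiff(seq_len(m), c(i, j))
    dnew <- (Dm[i, keep] + Dm[j, keep] - dij) / 2
    gi <- active[i]
    D[gi, active[keep]] <- dnew
    D[active[keep], gi] <- dnew
    node_id[i] <- new_node
    node_lab[i] <- paste0("(", min(node_lab[i], node_lab[j]), ",",
                          max(node_lab[i], node_lab[j]), ")")
    active <- active[-j]
    node_id <- node_id[-j]
    node_lab <- node_lab[-j]
  }
  # final trifurcation
  Dm <- D[active, active, drop = FALSE]
  l1 <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
  l2 <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
  l3 <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
  root <- next_internal
  edges <- rbind(edges, c(root, node_id[1]), c(root, node_id[2]),
                 c(root, node_id[3]))
  lens <- c(lens, max(l1, 0), max(l2, 0), max(l3, 0))
  # renumber internal nodes to ape convention (root = n+1, increasing)
  internal <- sort(unique(edges[edges > n]))
  remap <- integer(max(internal))
  remap[rev(internal)] <- n + seq_along(internal)
  e2 <- edges
  e2[e2 > n] <- remap[e2[e2 > n]]
  tr <- structure(list(edge = e2, edge.length = lens,
                       tip.label = labels, Nnode = length(internal)),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Is a taxon set monophyletic after outgroup rooting?
#'
#' @param tree A `phylo` tree containing `taxa` and `outgroup`.
#' @param taxa Character vector of taxon labels (a singleton is
#'   monophyletic by convention).
#' @param outgroup Tip label to root on.
#' @return `TRUE` iff `taxa` form an exact clade on the rooted tree.
#' @export
is_monophyletic <- function(tree, taxa, outgroup) {
  unknown <- setdiff(c(taxa, outgroup), tree$tip.label)
  if (length(unknown)) {
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(taxa) <= 1L) return(TRUE)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::is.monophyletic(rooted, taxa)
}

#' Robinson-Foulds distance between two trees
#'
#' The number of non-trivial bipartitions present in exactly one of the
#' two unrooted topologies; 0 iff the topologies are identical.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets", call. = FALSE)
  }
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# canonical string signatures of the non-trivial bipartitions of an
# unrooted tree
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  labs <- sort(tree$tip.label)
  n <- length(labs)
  parts <- ape::prop.part(tree)
  sigs <- character(0)
  for (p in parts) {
    side <- sort(tree$tip.label[p])
    if (length(side) <= 1L || length(side) >= n - 1L) next
    comp <- setdiff(labs, side)
    canon <- if (labs[1L] %in% side) side else comp
    sigs <- c(sigs, paste(canon, collapse = "|"))
  }
  unique(sigs)
}

#' Read / write newick trees
#'
#' Thin wrappers over ape's newick I/O.
#'
#' @param path File path.
#' @return A `phylo` tree (`read_newick`) or `path` (`write_newick`).
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree A `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
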