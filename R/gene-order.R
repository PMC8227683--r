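# Mitochondrial gene orders as circular signed permutations, and inference
# of the rearrangement events (transposition, inversion, reverse
# transposition of single genes or contiguous blocks) separating a genome
# from a reference arrangement.
#
# Orders are compared in an anchored frame: both orders are rotated so the
# reference's first gene (cox1 for the ancestral arrangement) sits at
# position 1, and events act on the resulting linear word.  Reflection is
# never applied -- strand identity is meaningful.

#' Construct a gene order
#'
#' @param genes Character vector of gene names (each exactly once).
#' @param signs Integer vector of +1 (majority/J strand) / -1 (minority/N).
#' @param taxon Taxon label.
#' @return An object of class `gene_order`.
#' @export
gene_order <- function(genes, signs = rep(1L, length(genes)), taxon = "") {
  stopifnot(length(genes) == length(signs), all(signs %in% c(-1L, 1L)))
  if (anyDuplicated(genes)) {
    stop("order-extraction error: duplicated gene(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(taxon = taxon, genes = as.character(genes),
                 signs = as.integer(signs)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat("gene_order", if (nzchar(x$taxon)) paste0("(", x$taxon, ")"), ":\n  ",
      format_gene_order(x), "\n")
  invisible(x)
}

#' Rotate a circular gene order so `anchor` comes first
#'
#' @param order A [gene_order()].
#' @param anchor Gene name to place at position 1 (default `"cox1"`).
#' @return The rotated [gene_order()].
#' @export
rotate_to_anchor <- function(order, anchor = "cox1") {
  i <- match(anchor, order$genes)
  if (is.na(i)) stop("anchor gene not in order: ", anchor, call. = FALSE)
  n <- length(order$genes)
  idx <- ((seq_len(n) + i - 2L) %% n) + 1L
  gene_order(order$genes[idx], order$signs[idx], order$taxon)
}

#' One-line signed token representation
#'
#' Genes are space-separated; minority-strand genes carry a `-` prefix
#' (e.g. `"cox1 trnM -trnQ trnI nad2 ..."`).
#'
#' @param order A [gene_order()].
#' @return A single string.
#' @export
format_gene_order <- function(order) {
  paste(ifelse(order$signs < 0L, paste0("-", order$genes), order$genes),
        collapse = " ")
}

#' @rdname format_gene_order
#' @param x A signed token string.
#' @param taxon Taxon label for the parsed order.
#' @export
parse_gene_order <- function(x, taxon = "") {
  tok <- strsplit(trimws(x), "\\s+")[[1L]]
  neg <- startsWith(tok, "-")
  gene_order(sub("^-", "", tok), ifelse(neg, -1L, 1L), taxon)
}

#' The ancestral pancrustacean gene order
#'
#' The inferred ancestral 37-gene arrangement of Pancrustacea (shared with
#' *Drosophila* and most insects), anchored at cox1 in J orientation.  The
#' rearrangement hotspot clusters I-Q-M, A-R-N-S1-E-F and W-C-Y appear with
#' their canonical strands (trnQ, trnC, trnY and trnF on the minority
#' strand).  The A+T-rich region is not part of the gene order.
#'
#' @return A [gene_order()] of the 37 genes.
#' @export
ancestral_pancrustacean_order <- function() {
  parse_gene_order(paste(
    "cox1 trnL2 cox2 trnK trnD atp8 atp6 cox3 trnG nad3",
    "trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4l",
    "trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS",
    "trnI -trnQ trnM nad2 trnW -trnC -trnY"),
    taxon = "ancestral_pancrustacean")
}

#' The shared Megabelesesinae gene order
#'
#' The ancestral arrangement modified by the two tRNA rearrangements shared
#' by *Cladiucha* and *Megabeleses*: the IQM cluster rearranged as M-Q-I
#' (trnQ inverted to the majority strand, trnM and trnI transposed) and the
#' ARNS1EF cluster rearranged as A-N-S1-E-R-F with trnR on the minority
#' strand (a reverse transposition of trnR upstream of trnF).
#'
#' @param taxon Taxon label for the returned order.
#' @return A [gene_order()] of the 37 genes.
#' @export
megabelesesinae_order <- function(taxon = "megabelesesinae") {
  parse_gene_order(paste(
    "cox1 trnL2 cox2 trnK trnD atp8 atp6 cox3 trnG nad3",
    "trnA trnN trnS1 trnE -trnR -trnF -nad5 -trnH -nad4 -nad4l",
    "trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS",
    "trnM trnQ trnI nad2 trnW -trnC -trnY"),
    taxon = taxon)
}

#' Extract the gene order of an annotated record
#'
#' Annotations are sorted by start position on the ring, the A+T-rich
#' region is excluded, and the order is rotated to the anchor gene.
#'
#' @param record A [mitogenome_record()].
#' @param anchor Anchor gene (default cox1).
#' @return A [gene_order()].
#' @export
gene_order_of <- function(record, anchor = "cox1") {
  ann <- record$annotations
  ann <- ann[ann$name != "AT_rich", , drop = FALSE]
  if (anyDuplicated(ann$name)) {
    stop("order-extraction error: duplicate gene annotations", call. = FALSE)
  }
  ord <- gene_order(ann$name, ifelse(ann$strand == "J", 1L, -1L),
                    record$taxon)
  rotate_to_anchor(ord, anchor)
}

## ---------------------------------------------------------------------
## event engine: signed words over 1..n, reference relabelled to identity

# Enumerate all distinct event actions on a word of length n.  An action is
# new[t] = sgn[t] * old[idx[t]].  Events are sorted canonically (fewest
# genes moved first, then kind, then coordinates) so that searches discover
# a deterministic representative among ties.
event_actions <- function(n) {
  ck <- paste0("acts", n)
  cached <- .rearr_cache[[ck]]
  if (!is.null(cached)) return(cached)
  idx_l <- list(); sgn_l <- list()
  kind <- character(0); ii <- jj <- pp <- nm <- integer(0)
  base <- seq_len(n)
  add <- function(idx, sgn, k, i, j, p, L) {
    idx_l[[length(idx_l) + 1L]] <<- idx
    sgn_l[[length(sgn_l) + 1L]] <<- sgn
    kind <<- c(kind, k); ii <<- c(ii, i); jj <<- c(jj, j)
    pp <<- c(pp, p); nm <<- c(nm, L)
  }
  for (i in base) for (j in i:n) {
    idx <- base; idx[i:j] <- j:i
    sgn <- rep(1L, n); sgn[i:j] <- -1L
    add(idx, sgn, "inversion", i, j, NA_integer_, j - i + 1L)
  }
  for (i in base) for (j in i:n) {
    L <- j - i + 1L
    if (L == n) next
    rest <- base[-(i:j)]
    for (p in 0:(n - L)) {
      if (p == i - 1L) next  # identity placement / in-place inversion
      idx <- append(rest, i:j, after = p)
      add(idx, rep(1L, n), "transposition", i, j, p, L)
      idxr <- append(rest, j:i, after = p)
      sgnr <- rep(1L, n); sgnr[(p + 1L):(p + L)] <- -1L
      add(idxr, sgnr, "reverse_transposition", i, j, p, L)
    }
  }
  o <- order(nm, match(kind, c("inversion", "transposition",
                               "reverse_transposition")), ii, jj, pp)
  IDX <- do.call(rbind, idx_l)[o, , drop = FALSE]
  SGN <- do.call(rbind, sgn_l)[o, , drop = FALSE]
  E <- nrow(IDX)
  INVIDX <- matrix(0L, E, n); INVSGN <- matrix(1L, E, n)
  for (e in seq_len(E)) {
    INVIDX[e, IDX[e, ]] <- base
    INVSGN[e, IDX[e, ]] <- SGN[e, ]
  }
  out <- list(n = n, E = E, IDX = IDX, SGN = SGN, INVIDX = INVIDX,
              INVSGN = INVSGN,
              meta = data.frame(kind = kind[o], i = ii[o], j = jj[o], p = pp[o],
                                nmoved = nm[o], stringsAsFactors = FALSE))
  .rearr_cache[[ck]] <- out
  out
}

state_key <- function(s) paste(s, collapse = " ")

# vectorized keys for a states matrix (one state per column)
state_keys <- function(M) {
  do.call(paste, as.data.frame(t(M)))
}

apply_event <- function(acts, e, s) acts$SGN[e, ] * s[acts$IDX[e, ]]

# all children of state s: n x E matrix, one event per column
expand_state <- function(acts, s, inverse = FALSE) {
  if (inverse) {
    matrix(s[t(acts$INVIDX)], nrow = acts$n) * t(acts$INVSGN)
  } else {
    matrix(s[t(acts$IDX)], nrow = acts$n) * t(acts$SGN)
  }
}

# package-level cache of identity-side BFS balls, keyed by word length
.rearr_cache <- new.env(parent = emptyenv())

# BFS ball around the identity word under forward events, to depth `depth`.
# env entries: key -> list(d, ev, parent).
identity_ball <- function(acts, depth, node_budget) {
  key <- paste0("n", acts$n)
  ball <- .rearr_cache[[key]]
  if (is.null(ball)) {
    env <- new.env(parent = emptyenv())
    id <- seq_len(acts$n)
    env[[state_key(id)]] <- list(d = 0L, ev = NA_integer_, parent = NA_character_)
    ball <- list(env = env, depth = 0L,
                 frontier = matrix(id, ncol = 1L),
                 frontier_keys = state_key(id), n_states = 1L)
  }
  while (ball$depth < depth) {
    nf <- ncol(ball$frontier)
    kids_l <- vector("list", nf)
    for (ci in seq_len(nf)) {
      kids_l[[ci]] <- expand_state(acts, ball$frontier[, ci])
    }
    kids <- do.call(cbind, kids_l)
    kk <- state_keys(kids)
    evs <- rep(seq_len(acts$E), nf)
    par <- rep(ball$frontier_keys, each = acts$E)
    seen <- !vapply(mget(kk, envir = ball$env, ifnotfound = list(NULL)),
                    is.null, logical(1))
    keep <- which(!seen & !duplicated(kk))
    d1 <- ball$depth + 1L
    for (t in keep) {
      ball$env[[kk[t]]] <- list(d = d1, ev = evs[t], parent = par[t])
    }
    ball$frontier <- kids[, keep, drop = FALSE]
    ball$frontier_keys <- kk[keep]
    ball$depth <- d1
    ball$n_states <- ball$n_states + length(keep)
    .rearr_cache[[key]] <- ball
    if (ball$n_states > node_budget) return(NULL)
  }
  ball
}

# Bidirectional search for a minimal event sequence identity -> q.
# Returns list of event records (ev id + the state each was applied to),
# or NULL if no solution within `depth`.
search_events <- function(q, depth, node_budget = 400000L) {
  n <- length(q)
  if (identical(q, seq_len(n))) return(list())
  acts <- event_actions(n)
  a_max <- as.integer(ceiling(depth / 2))
  b_max <- as.integer(floor(depth / 2))

  # query-side ball under inverse events; env: key -> list(d, ev, next_key)
  benv <- new.env(parent = emptyenv())
  qk <- state_key(q)
  benv[[qk]] <- list(d = 0L, ev = NA_integer_, next_key = NA_character_)
  b_front <- list(list(states = matrix(q, ncol = 1L), keys = qk))

  aball <- identity_ball(acts, 0L, node_budget)

  best <- NULL
  for (t in seq_len(depth)) {
    for (b in 0:min(t, b_max)) {
      a <- t - b
      if (a > a_max) next
      if (a > aball$depth) {
        aball <- identity_ball(acts, a, node_budget)
        if (is.null(aball)) return(NULL)
      }
      if (b >= length(b_front)) {
        prev <- b_front[[length(b_front)]]
        m <- ncol(prev$states)
        kids_l <- vector("list", m)
        for (ci in seq_len(m)) {
          kids_l[[ci]] <- expand_state(acts, prev$states[, ci], inverse = TRUE)
        }
        kids <- do.call(cbind, kids_l)
        kk <- state_keys(kids)
        evs <- rep(seq_len(acts$E), m)
        nxt <- rep(prev$keys, each = acts$E)
        seen <- !vapply(mget(kk, envir = benv, ifnotfound = list(NULL)),
                        is.null, logical(1))
        keep <- which(!seen & !duplicated(kk))
        if (length(keep) > node_budget) return(NULL)
        db <- length(b_front)
        for (ti in keep) {
          benv[[kk[ti]]] <- list(d = db, ev = evs[ti], next_key = nxt[ti])
        }
        b_front[[db + 1L]] <- list(states = kids[, keep, drop = FALSE],
                                   keys = kk[keep])
      }
      # meets: states at exactly depth b on query side and depth a in aball
      bk <- b_front[[b + 1L]]$keys
      hits <- mget(bk, envir = aball$env, ifnotfound = list(NULL))
      for (ix in seq_along(bk)) {
        hit <- hits[[ix]]
        if (!is.null(hit) && hit$d == a) {
          cand <- reconstruct_path(acts, aball$env, benv, bk[ix])
          if (is.null(best) || path_before(cand, best)) best <- cand
        }
      }
    }
    if (!is.null(best)) return(best)
  }
  NULL
}

# path = list of list(ev, state); canonical comparison: fewer total genes
# moved wins, then lexicographically smaller event-id sequence
path_before <- function(p1, p2) {
  acts_nm <- function(p) sum(vapply(p, function(x) x$nmoved, numeric(1)))
  g1 <- acts_nm(p1); g2 <- acts_nm(p2)
  if (g1 != g2) return(g1 < g2)
  e1 <- vapply(p1, function(x) x$ev, integer(1))
  e2 <- vapply(p2, function(x) x$ev, integer(1))
  for (k in seq_len(min(length(e1), length(e2)))) {
    if (e1[k] != e2[k]) return(e1[k] < e2[k])
  }
  length(e1) < length(e2)
}

reconstruct_path <- function(acts, aenv, benv, meet_key) {
  # identity -> meet
  a_events <- integer(0)
  k <- meet_key
  repeat {
    node <- aenv[[k]]
    if (is.na(node$ev)) break
    a_events <- c(node$ev, a_events)
    k <- node$parent
  }
  # meet -> query (events stored on the source state)
  b_events <- integer(0)
  k <- meet_key
  repeat {
    node <- benv[[k]]
    if (node$d == 0L) break
    b_events <- c(b_events, node$ev)
    k <- node$next_key
  }
  evs <- c(a_events, b_events)
  # replay from identity, recording the state each event applied to
  s <- seq_len(acts$n)
  out <- vector("list", length(evs))
  for (i in seq_along(evs)) {
    out[[i]] <- list(ev = evs[i], state = s,
                     nmoved = acts$meta$nmoved[evs[i]])
    s <- apply_event(acts, evs[i], s)
  }
  out
}

## ---------------------------------------------------------------------
## strip reduction and independent-window decomposition

# Collapse maximal common strips.  q is a signed word with reference
# identity; runs with q[i+1] == q[i] + 1 are common strips (a negative run
# -b..-a is block a..b traversed inverted).  Returns the reduced word plus
# the gene-index blocks each reduced symbol stands for.
reduce_strips <- function(q) {
  n <- length(q)
  run_id <- cumsum(c(TRUE, q[-1L] != q[-n] + 1L))
  runs <- split(seq_len(n), run_id)
  lo <- vapply(runs, function(r) min(abs(q[r])), integer(1))
  hi <- vapply(runs, function(r) max(abs(q[r])), integer(1))
  sgn <- vapply(runs, function(r) if (q[r[1L]] < 0L) -1L else 1L, integer(1))
  rank <- match(lo, sort(lo))
  reduced <- integer(length(runs))
  reduced[seq_along(runs)] <- sgn * rank
  blocks <- vector("list", length(runs))
  for (k in seq_along(runs)) blocks[[rank[k]]] <- lo[k]:hi[k]  # ref indices
  list(word = reduced, blocks = blocks)
}

# Cut a permutation word into independent windows at prefix points where
# the set of absolute values equals the set of positions.
window_cuts <- function(q) {
  cummax_abs <- cummax(abs(q))
  which(cummax_abs == seq_along(q))
}

## ---------------------------------------------------------------------

hotspot_cluster <- function(genes) {
  if (all(genes %in% c("trnI", "trnQ", "trnM"))) return("IQM")
  if (all(genes %in% c("trnA", "trnR", "trnN", "trnS1", "trnE", "trnF"))) {
    return("ARNS1EF")
  }
  if (all(genes %in% c("trnW", "trnC", "trnY"))) return("WCY")
  "other"
}

new_event <- function(kind, genes, from_context, to_context) {
  structure(list(kind = kind, genes = genes,
                 from_context = from_context, to_context = to_context,
                 cluster = hotspot_cluster(genes)),
            class = "rearrangement_event")
}

#' @export
print.rearrangement_event <- function(x, ...) {
  cat(sprintf("%s[%s] (%s) %s|%s -> %s|%s\n", x$kind,
              paste(x$genes, collapse = ","), x$cluster,
              x$from_context[1L], x$from_context[2L],
              x$to_context[1L], x$to_context[2L]))
  invisible(x)
}

#' @export
format.rearrangement_event <- function(x, ...) {
  sprintf("%s[%s]", x$kind, paste(x$genes, collapse = ","))
}

# decode an engine path (on a reduced word) into rearrangement_event
# objects expressed in gene names.  `blocks` maps reduced symbols to
# reference gene-name vectors.
decode_events <- function(path, acts, ref_genes, blocks) {
  sym_genes <- function(v) {
    g <- blocks[[abs(v)]]
    if (v < 0L) rev(g) else g
  }
  word_flank <- function(state, pos, side) {
    # gene name adjacent to position range on the given side, "" at edges
    if (side == "left") {
      if (pos < 1L) return("")
      g <- sym_genes(state[pos]); ref_genes[g[length(g)]]
    } else {
      if (pos > length(state)) return("")
      g <- sym_genes(state[pos]); ref_genes[g[1L]]
    }
  }
  out <- vector("list", length(path))
  for (k in seq_along(path)) {
    ev <- path[[k]]$ev
    s <- path[[k]]$state
    m <- acts$meta[ev, ]
    block_syms <- s[m$i:m$j]
    genes <- unlist(lapply(block_syms, function(v) ref_genes[sym_genes(v)]),
                    use.names = FALSE)
    from_ctx <- c(word_flank(s, m$i - 1L, "left"),
                  word_flank(s, m$j + 1L, "right"))
    s_after <- apply_event(acts, ev, s)
    if (m$kind == "inversion") {
      to_ctx <- from_ctx
    } else {
      L <- m$j - m$i + 1L
      to_ctx <- c(word_flank(s_after, m$p, "left"),
                  word_flank(s_after, m$p + L + 1L, "right"))
    }
    out[[k]] <- new_event(m$kind, genes, from_ctx, to_ctx)
  }
  out
}

#' Infer rearrangement events between two gene orders
#'
#' Finds a minimal-cardinality sequence of events over the vocabulary
#' transposition / inversion / reverse transposition (single genes or
#' contiguous blocks) transforming `reference` into `query`.  Both orders
#' are rotated into the reference-anchored frame, shared gene blocks are
#' collapsed, and the reduced signed permutation is searched exhaustively
#' (bidirectional breadth-first) up to `depth` events.  Ties are broken by
#' total genes moved, then by a canonical event ordering.  If no solution
#' exists within `depth` (or the search exceeds its node budget), a single
#' `unresolved_block` event covering the smallest discordant interval is
#' returned.
#'
#' @param query,reference [gene_order()] objects over the same gene set.
#' @param depth Maximum number of events searched (default 4).
#' @param max_window Reduced windows larger than this are not searched and
#'   yield `unresolved_block` (default 12).
#' @param decompose_over Reduced words longer than this are first cut into
#'   independent discordant windows solved separately (default 7).
#' @return List of `rearrangement_event` objects (empty when the orders
#'   agree).
#' @export
infer_events <- function(query, reference, depth = 4L, max_window = 12L,
                         decompose_over = 7L) {
  if (!setequal(query$genes, reference$genes)) {
    stop("query and reference are over different gene alphabets", call. = FALSE)
  }
  anchor <- reference$genes[1L]
  q <- rotate_to_anchor(query, anchor)
  r <- reference
  ref_genes <- r$genes
  # relabel: reference becomes identity
  qv <- match(q$genes, ref_genes) *
    ifelse(q$signs == r$signs[match(q$genes, ref_genes)], 1L, -1L)
  # sign convention: value sign is flip relative to reference strand
  n <- length(qv)
  if (identical(qv, seq_len(n))) return(list())

  red <- reduce_strips(qv)
  w <- red$word
  m <- length(w)

  unresolved <- function() {
    bad <- which(qv != seq_len(n))
    genes <- ref_genes[min(bad):max(bad)]
    list(new_event("unresolved_block", genes,
                   c(if (min(bad) > 1L) ref_genes[min(bad) - 1L] else "",
                     if (max(bad) < n) ref_genes[max(bad) + 1L] else ""),
                   c("", "")))
  }

  solve_window <- function(wword, wblocks, budget) {
    # wword: reduced signed word with identity reference 1..k
    if (length(wword) > max_window) return(NULL)
    path <- search_events(wword, budget)
    if (is.null(path)) return(NULL)
    decode_events(path, event_actions(length(wword)), ref_genes, wblocks)
  }

  if (m > decompose_over) {
    cuts <- window_cuts(w)
    starts <- c(1L, cuts[-length(cuts)] + 1L)
    events <- list()
    left <- depth
    for (k in seq_along(cuts)) {
      seg <- starts[k]:cuts[k]
      if (length(seg) == 1L && w[seg] == seg) next  # fixed point
      sub <- w[seg] - (starts[k] - 1L) * sign(w[seg])
      subblocks <- red$blocks[starts[k]:cuts[k]]
      ev <- solve_window(sub, subblocks, left)
      if (is.null(ev)) return(unresolved())
      left <- left - length(ev)
      if (left < 0L) return(unresolved())
      events <- c(events, ev)
    }
    return(events)
  }
  ev <- solve_window(w, red$blocks, depth)
  if (is.null(ev)) return(unresolved()) else ev
}

#' Replay rearrangement events on a gene order
#'
#' Applies each event in sequence: an inversion flips the strand of the
#' named block in place; a (reverse) transposition removes the block and
#' reinserts it at the recorded target context ((reversed and
#' strand-flipped for reverse transpositions).
#'
#' @param reference A [gene_order()] to start from.
#' @param events List of `rearrangement_event`s as returned by
#'   [infer_events()].
#' @return The rearranged [gene_order()].
#' @export
apply_events <- function(reference, events) {
  genes <- reference$genes
  signs <- reference$signs
  for (ev in events) {
    if (ev$kind == "unresolved_block") {
      stop("cannot replay an unresolved_block event", call. = FALSE)
    }
    pos <- match(ev$genes, genes)
    if (anyNA(pos) || any(diff(pos) != 1L)) {
      stop("event block not contiguous in current order: ",
           paste(ev$genes, collapse = ","), call. = FALSE)
    }
    i <- pos[1L]; j <- pos[length(pos)]
    if (ev$kind == "inversion") {
      genes[i:j] <- genes[j:i]
      signs[i:j] <- -signs[j:i]
      next
    }
    blk_g <- genes[i:j]; blk_s <- signs[i:j]
    genes <- genes[-(i:j)]; signs <- signs[-(i:j)]
    if (ev$kind == "reverse_transposition") {
      blk_g <- rev(blk_g); blk_s <- -rev(blk_s)
    }
    left <- ev$to_context[1L]
    p <- if (left == "") 0L else match(left, genes)
    if (is.na(p)) stop("replay context gene not found: ", left, call. = FALSE)
    genes <- append(genes, blk_g, after = p)
    signs <- append(signs, blk_s, after = p)
  }
  gene_order(genes, signs, reference$taxon)
}

event_signature <- function(ev) {
  paste(ev$kind, paste(ev$genes, collapse = ","),
        paste(ev$to_context, collapse = "|"), sep = ";")
}

#' Events shared across taxa, with synapomorphy flagging
#'
#' Infers events for every order against the reference and groups
#' identical events (same kind, genes and target context) across taxa.
#' When `clade` is given, an event carried by every clade member and by no
#' other taxon is flagged synapomorphic.
#'
#' @param orders List of [gene_order()] objects (taxon labels must be set).
#' @param reference Reference [gene_order()].
#' @param clade Optional character vector of taxon labels declaring a clade.
#' @param ... Passed on to [infer_events()].
#' @return A data frame with one row per distinct event: `event`, `kind`,
#'   `genes`, `cluster`, `taxa` (comma-joined), `n_taxa`, `synapomorphic`.
#' @export
shared_derived_events <- function(orders, reference, clade = NULL, ...) {
  if (!length(orders)) {
    return(data.frame(event = character(0), kind = character(0),
                      genes = character(0), cluster = character(0),
                      taxa = character(0), n_taxa = integer(0),
                      synapomorphic = logical(0), stringsAsFactors = FALSE))
  }
  per_taxon <- lapply(orders, function(o) infer_events(o, reference, ...))
  taxa <- vapply(orders, function(o) o$taxon, character(1))
  sig_map <- list()
  for (k in seq_along(orders)) {
    for (ev in per_taxon[[k]]) {
      sig <- event_signature(ev)
      if (is.null(sig_map[[sig]])) sig_map[[sig]] <- list(ev = ev, taxa = character(0))
      sig_map[[sig]]$taxa <- c(sig_map[[sig]]$taxa, taxa[k])
    }
  }
  rows <- lapply(sig_map, function(x) {
    syn <- if (is.null(clade)) NA else
      setequal(x$taxa, clade)
    data.frame(event = format(x$ev), kind = x$ev$kind,
               genes = paste(x$ev$genes, collapse = ","),
               cluster = x$ev$cluster,
               taxa = paste(sort(x$taxa), collapse = ","),
               n_taxa = length(x$taxa), synapomorphic = syn,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write inferred events as TSV
#'
#' @param events Named list: taxon -> list of events, or a data frame from
#'   [shared_derived_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  if (is.data.frame(events)) {
    utils::write.table(events, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  rows <- list()
  for (taxon in names(events)) {
    for (ev in events[[taxon]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = taxon, kind = ev$kind,
        genes = paste(ev$genes, collapse = ","), cluster = ev$cluster,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon = character(0), kind = character(0),
               genes = character(0), cluster = character(0))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
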