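# Synthetic mitogenome generator: a birth (Yule) tree, per-gene aligned
# sequences evolved under GTR+Gamma+I with per-gene and per-codon-position
# rate multipliers, and fully annotated circular genomes with planted tRNA
# rearrangements on a designated clade.
#
# The generator emulates the structure of sawfly-like insect mitogenomes:
# ~80-83% AT, strand-asymmetric base frequencies, in-frame PCGs under the
# invertebrate mitochondrial code with ATN starts and complete or partial
# (T-) stops, fast third codon positions (saturating on deep trees), and
# elevated rates for atp8/nad4l/nad6.

#' Default simulation configuration
#'
#' @param n_taxa Total number of taxa including the outgroup and the
#'   planted clade (default 20).
#' @param clade_size Size of the planted clade (default 4).
#' @param depth Ingroup root-to-tip height in expected substitutions/site
#'   at rate multiplier 1 (default 0.3).
#' @param birth_rate Yule birth rate (shape parameter only; the tree is
#'   rescaled to `depth`).
#' @param at_weight Target AT fraction of the genome (default 0.82).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param ... Overrides for any other configuration field.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 20L, clade_size = 4L, depth = 0.3,
                       birth_rate = 1, at_weight = 0.82, seed = 1L, ...) {
  cfg <- list(
    n_taxa = as.integer(n_taxa),
    clade_size = as.integer(clade_size),
    depth = depth,
    clade_depth_frac = 0.25,
    birth_rate = birth_rate,
    at_weight = at_weight,
    seed = as.integer(seed),
    outgroup = "out",
    clade_label = "planted_clade",
    # substitution process shared across genes (mito-like: strong
    # transition bias), with discrete-gamma heterogeneity and a class of
    # invariant sites
    rates = c(AC = 1, AG = 5, AT = 1, CG = 1, CT = 8, GT = 1),
    alpha = 0.75,
    p_inv = 0.1,
    k = 4L,
    # per-codon-position multipliers (PCGs) and RNA-gene multiplier;
    # third positions are fast enough to saturate at the default depth
    pos_mult = c(1, 0.5, 20),
    rna_mult = 0.4,
    # elevated whole-gene multipliers for the saturation-prone genes
    gene_mult = c(atp8 = 3, nad4l = 3, nad6 = 3),
    # stationary base frequencies (A, C, G, T) by partition class; J/N
    # coding-sense frequencies differ to induce the strand skews
    freqs = list(
      pcg_J = c(A = 0.364, C = 0.100, G = 0.080, T = 0.456),
      pcg_N = c(A = 0.420, C = 0.070, G = 0.110, T = 0.400),
      rna_J = c(A = 0.430, C = 0.080, G = 0.090, T = 0.400),
      rna_N = c(A = 0.400, C = 0.075, G = 0.105, T = 0.420),
      at_rich = c(A = 0.50, C = 0.04, G = 0.04, T = 0.42),
      spacer = c(A = 0.45, C = 0.06, G = 0.06, T = 0.43)
    ),
    # gene lengths (bp); PCG lengths are in-frame coding lengths without
    # the stop codon
    pcg_lengths = c(atp6 = 675, atp8 = 159, cob = 1140, cox1 = 1536,
                    cox2 = 684, cox3 = 786, nad1 = 936, nad2 = 1023,
                    nad3 = 351, nad4 = 1338, nad4l = 288, nad5 = 1719,
                    nad6 = 522),
    trna_length_range = c(60L, 71L),
    rrna_lengths = c(rrnL = 1300L, rrnS = 780L),
    partial_stop_genes = c("cob", "nad4"),
    at_rich_length_range = c(300L, 800L),
    spacer_range = c(0L, 20L),
    planted_events = default_planted_events(),
    gene_length_scale = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "sim_config")
}

#' Default planted rearrangement events
#'
#' The two hotspot rearrangements characteristic of Megabelesesinae-like
#' mitogenomes, expressed as replayable events on the ancestral order: the
#' IQM cluster rearranged to M-Q-I (trnI transposed after trnM, trnQ
#' reverse-transposed between them, ending on the majority strand) and
#' trnR reverse-transposed upstream of trnF in the ARNS1EF cluster.
#'
#' @return List of `rearrangement_event` objects.
#' @export
default_planted_events <- function() {
  list(
    new_event("transposition", "trnI", c("rrnS", "trnQ"), c("trnM", "nad2")),
    new_event("reverse_transposition", "trnQ", c("rrnS", "trnM"),
              c("trnM", "trnI")),
    new_event("reverse_transposition", "trnR", c("trnA", "trnN"),
              c("trnE", "trnF"))
  )
}

#' Simulate a Yule tree with a planted clade and an outgroup
#'
#' A pure-birth ingroup tree is simulated and rescaled to `depth`; one tip
#' is replaced by a `clade_size`-tip pure-birth subtree (the planted
#' clade, tips `c1..`), and the outgroup is attached at the root with a
#' branch of length `depth`.  Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `phylo` tree with `n_taxa` tips.
#' @export
simulate_tree <- function(config) {
  cfg <- config
  if (cfg$n_taxa < 3L) stop("n_taxa must be at least 3", call. = FALSE)
  n_in <- cfg$n_taxa - 1L                       # ingroup size
  n_bb <- n_in - cfg$clade_size + 1L            # backbone tips
  if (n_bb < 3L) {
    stop("n_taxa too small: need at least clade_size + 3 taxa ",
         "(backbone of 3, plus the outgroup)", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 1L))
  scale_to_depth <- function(tr, d) {
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * (d / h)
    tr
  }
  bb <- ape::rphylo(n_bb, birth = cfg$birth_rate, death = 0)
  bb$tip.label <- sprintf("t%02d", seq_len(n_bb))
  bb <- scale_to_depth(bb, cfg$depth * (1 - cfg$clade_depth_frac))
  if (cfg$clade_size >= 2L) {
    cl <- ape::rphylo(cfg$clade_size, birth = cfg$birth_rate, death = 0)
    cl$tip.label <- sprintf("c%d", seq_len(cfg$clade_size))
    cl <- scale_to_depth(cl, cfg$depth * cfg$clade_depth_frac * 0.8)
    cl$root.edge <- cfg$depth * cfg$clade_depth_frac * 0.2
    host <- which(bb$tip.label == "t01")
    ingroup <- ape::bind.tree(bb, cl, where = host)
  } else {
    ingroup <- bb
    ingroup$tip.label[1L] <- "c1"
  }
  add_outgroup(ingroup, cfg$outgroup, stem = cfg$depth * 0.1,
               og_branch = cfg$depth * 1.1)
}

# join an outgroup tip and an ingroup tree under a new root
add_outgroup <- function(ing, label, stem, og_branch) {
  n <- ape::Ntip(ing)
  e <- ing$edge
  e[e > n] <- e[e > n] + 2L          # shift internal ids; old root n+1 -> n+3
  root <- n + 2L                      # new root (ape wants Ntip+1)
  edge <- rbind(c(root, n + 1L),      # outgroup tip
                c(root, n + 3L),      # ingroup stem
                e)
  tr <- structure(
    list(edge = edge,
         edge.length = c(og_branch, stem, ing$edge.length),
         tip.label = c(ing$tip.label, label),
         Nnode = ing$Nnode + 1L),
    class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

clade_taxa <- function(config) sprintf("c%d", seq_len(config$clade_size))

# length table for every gene under a config (deterministic under seed)
gene_length_table <- function(cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 2L))
  sc <- cfg$gene_length_scale
  pcg <- pmax(3L * ceiling(cfg$pcg_lengths * sc / 3L), 9L)
  trna <- stats::setNames(
    sample(seq(cfg$trna_length_range[1L], cfg$trna_length_range[2L]),
           length(mito_trnas()), replace = TRUE),
    mito_trnas())
  rrna <- pmax(round(cfg$rrna_lengths * sc), 50L)
  c(as.list(pcg), as.list(trna), as.list(rrna))
}

gene_class_freqs <- function(cfg, gene) {
  anc <- ancestral_pancrustacean_order()
  sgn <- anc$signs[match(gene, anc$genes)]
  kind <- gene_kind(gene)
  if (kind == "PCG") {
    if (sgn > 0L) cfg$freqs$pcg_J else cfg$freqs$pcg_N
  } else {
    if (sgn > 0L) cfg$freqs$rna_J else cfg$freqs$rna_N
  }
}

gene_rate_mult <- function(cfg, gene) {
  base <- if (gene %in% names(cfg$gene_mult)) cfg$gene_mult[[gene]] else 1
  if (gene_kind(gene) == "PCG") base else base * cfg$rna_mult
}

# Simulate a set of sites (columns) down the tree under `model` with
# per-site rates.  Returns an integer matrix: rows = all nodes (tips
# first, ape numbering), columns = sites.  Root states may be supplied.
sim_sites <- function(tree, model, site_rates, root_states = NULL) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  m <- length(site_rates)
  S <- matrix(NA_integer_, n_node, m)
  root <- n_tip + 1L
  S[root, ] <- root_states %||%
    sample(1:4, m, replace = TRUE, prob = model$pi)
  tr <- ape::reorder.phylo(tree, "cladewise")
  edges <- tr$edge
  elens <- tr$edge.length
  groups <- split(seq_len(m), site_rates)
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1L]; child <- edges[k, 2L]; t_ <- elens[k]
    S[child, ] <- S[par, ]
    for (g in groups) {
      r <- site_rates[g[1L]]
      if (r == 0 || t_ == 0) next
      P <- gtr_pmat(model, t_ * r)
      Pc <- t(apply(P, 1L, cumsum))
      s <- S[par, g]
      u <- stats::runif(length(g))
      S[child, g] <- 1L + (u > Pc[s, 1L]) + (u > Pc[s, 2L]) + (u > Pc[s, 3L])
    }
  }
  S
}

# per-site rate draw: invariant class + discrete gamma, times multiplier
draw_site_rates <- function(cfg, model, n, mult) {
  cat_rates <- model$gamma_rates
  inv <- stats::runif(n) < cfg$p_inv
  r <- cat_rates[sample.int(cfg$k, n, replace = TRUE)] * mult
  r[inv] <- 0
  r
}

#' Evolve per-gene aligned sequences along a tree
#'
#' Sites evolve under a GTR+Gamma+I process with class-specific stationary
#' frequencies (inducing the configured AT bias and strand skews) and
#' per-gene / per-codon-position rate multipliers.  PCGs are generated in
#' frame: the start codon is an invariant ATN, the stop is an invariant
#' TAA (or a partial `T-` for `config$partial_stop_genes`), and any codon
#' producing an in-frame stop at a tip is resimulated (codon-level
#' rejection).
#'
#' @param tree A `phylo` tree (tips = taxa).
#' @param config A [sim_config()].
#' @return Named list: gene -> named character vector of aligned (gap-free)
#'   tip sequences.
#' @export
evolve_genes <- function(tree, config) {
  cfg <- config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 3L))
  lens <- gene_length_table(cfg)
  bases <- c("A", "C", "G", "T")
  gc5 <- mito_genetic_code()
  stops <- names(gc5)[gc5 == "*"]
  n_tip <- length(tree$tip.label)
  out <- list()
  for (gene in canonical_genes()) {
    pi <- gene_class_freqs(cfg, gene)
    model <- gtr_model(pi / sum(pi), cfg$rates, cfg$alpha, 0, cfg$k)
    mult <- gene_rate_mult(cfg, gene)
    L <- lens[[gene]]
    if (gene_kind(gene) == "PCG") {
      n_codon <- L %/% 3L                     # includes the start codon
      body <- n_codon - 1L
      rates <- c(0, 0, 0,                     # invariant ATN start
                 draw_site_rates(cfg, model,  3L * body,
                                 rep(cfg$pos_mult, body) * mult))
      # root: start codon ATN, then stop-free codons
      atn <- paste0("AT", bases)
      start_codon <- sample(atn, 1L, prob = pi[c("A", "C", "G", "T")])
      root <- integer(3L * n_codon)
      root[1:3] <- match(seq_chars(start_codon), bases)
      for (ci in seq_len(body)) {
        repeat {
          cand <- sample(1:4, 3L, replace = TRUE, prob = pi)
          if (!(collapse_chars(bases[cand]) %in% stops)) break
        }
        root[3L * ci + 1:3] <- cand
      }
      S <- sim_sites(tree, model, rates, root)
      # codon-level rejection of in-frame stops (TAA/TAG, i.e. T,A,A|G
      # under the invertebrate code) at any tip
      tipS <- S[seq_len(n_tip), , drop = FALSE]
      codmat <- matrix(seq_len(3L * n_codon), nrow = 3L)
      find_bad <- function(M) {
        is_stop <- M[, codmat[1L, ], drop = FALSE] == 4L &
          M[, codmat[2L, ], drop = FALSE] == 1L &
          (M[, codmat[3L, ], drop = FALSE] == 1L |
             M[, codmat[3L, ], drop = FALSE] == 3L)
        bad <- which(colSums(is_stop) > 0L)
        setdiff(bad, 1L)  # the invariant ATN start is never a stop anyway
      }
      for (round in 1:60) {
        bad <- find_bad(tipS)
        if (!length(bad)) break
        for (ci in bad) {
          cols <- codmat[, ci]
          repeat {
            cand <- sample(1:4, 3L, replace = TRUE, prob = pi)
            if (!(collapse_chars(bases[cand]) %in% stops)) break
          }
          S2 <- sim_sites(tree, model, rates[cols], cand)
          tipS[, cols] <- S2[seq_len(n_tip), , drop = FALSE]
        }
      }
      # append the stop: complete TAA or partial trailing T
      stop_chunk <- if (gene %in% cfg$partial_stop_genes) "T" else "TAA"
      seqs <- apply(tipS, 1L, function(x)
        paste0(collapse_chars(bases[x]), stop_chunk))
    } else {
      rates <- draw_site_rates(cfg, model, L, mult)
      S <- sim_sites(tree, model, rates)
      seqs <- apply(S[seq_len(n_tip), , drop = FALSE], 1L,
                    function(x) collapse_chars(bases[x]))
    }
    out[[gene]] <- stats::setNames(seqs, tree$tip.label)
  }
  out
}

random_seq <- function(n, freqs) {
  if (n <= 0L) return("")
  collapse_chars(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                        prob = freqs[c("A", "C", "G", "T")]))
}

#' Assemble annotated circular genomes from evolved gene sequences
#'
#' Lays each taxon's genes on the ring in the ancestral order -- or, for
#' members of the planted clade, the order obtained by replaying
#' `config$planted_events` -- inserting random intergenic spacers, and an
#' A+T-rich control region downstream of rrnS.  Minority-strand genes are
#' reverse-complemented onto the forward strand.
#'
#' @param tree The simulated tree (defines the taxon set).
#' @param gene_seqs Output of [evolve_genes()].
#' @param config A [sim_config()].
#' @param dir Optional output directory: GenBank, FASTA and feature-table
#'   files are written there.
#' @return Named list of [mitogenome_record()] objects.
#' @export
emit_mitogenomes <- function(tree, gene_seqs, config, dir = NULL) {
  cfg <- config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 4L))
  taxa <- tree$tip.label
  cl <- clade_taxa(cfg)
  missing_cl <- setdiff(cl, taxa)
  if (length(cfg$planted_events) && length(missing_cl)) {
    stop("planted events reference unknown clade taxa: ",
         paste(missing_cl, collapse = ", "), call. = FALSE)
  }
  anc <- ancestral_pancrustacean_order()
  rearranged <- if (length(cfg$planted_events)) {
    apply_events(anc, cfg$planted_events)
  } else {
    anc
  }
  records <- list()
  for (tx in taxa) {
    ord <- if (tx %in% cl) rearranged else anc
    seq_parts <- character(0)
    names_ <- character(0); starts <- integer(0); ends <- integer(0)
    strands <- character(0)
    pos <- 0L
    for (gi in seq_along(ord$genes)) {
      g <- ord$genes[gi]
      coding <- gene_seqs[[g]][[tx]]
      genomic <- if (ord$signs[gi] < 0L) revcomp(coding) else coding
      names_ <- c(names_, g)
      starts <- c(starts, pos)
      ends <- c(ends, pos + nchar(genomic))
      strands <- c(strands, if (ord$signs[gi] < 0L) "N" else "J")
      seq_parts <- c(seq_parts, genomic)
      pos <- pos + nchar(genomic)
      # control region directly downstream of rrnS
      if (g == "rrnS") {
        at_len <- sample(seq(cfg$at_rich_length_range[1L],
                             cfg$at_rich_length_range[2L]), 1L)
        names_ <- c(names_, "AT_rich")
        starts <- c(starts, pos)
        ends <- c(ends, pos + at_len)
        strands <- c(strands, "J")
        seq_parts <- c(seq_parts, random_seq(at_len, cfg$freqs$at_rich))
        pos <- pos + at_len
      }
      sp_len <- sample(seq(cfg$spacer_range[1L], cfg$spacer_range[2L]), 1L)
      if (sp_len > 0L && gi < length(ord$genes)) {
        seq_parts <- c(seq_parts, random_seq(sp_len, cfg$freqs$spacer))
        pos <- pos + sp_len
      }
    }
    rec <- mitogenome_record(tx, paste(seq_parts, collapse = ""),
                             gene_annotation(names_, starts, ends, strands))
    records[[tx]] <- rec
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (tx in names(records)) {
      write_genbank(records[[tx]], file.path(dir, paste0(tx, ".gb")))
      write_feature_table(records[[tx]],
                          file.path(dir, paste0(tx, ".fasta")),
                          file.path(dir, paste0(tx, ".tbl")))
    }
  }
  records
}

# YAML-safe form of a sim_config: named vectors become maps (yaml drops
# names of atomic vectors otherwise), events become plain lists
config_as_yaml_list <- function(cfg) {
  out <- unclass(cfg)
  for (f in c("rates", "gene_mult", "pcg_lengths", "rrna_lengths")) {
    if (!is.null(out[[f]])) out[[f]] <- as.list(out[[f]])
  }
  out$freqs <- lapply(out$freqs, as.list)
  out$planted_events <- lapply(out$planted_events, function(e) {
    list(kind = e$kind, genes = e$genes,
         from_context = e$from_context, to_context = e$to_context)
  })
  out
}

#' Run the full generator: tree, gene alignments, genomes
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (newick, per-gene FASTA, GenBank,
#'   and a YAML manifest echoing the configuration).
#' @return List with `tree`, `genes` (per-gene alignments), `records`,
#'   and `config`.
#' @export
simulate_mitogenomes <- function(config = sim_config(), dir = NULL) {
  tree <- simulate_tree(config)
  genes <- evolve_genes(tree, config)
  records <- emit_mitogenomes(tree, genes, config,
                              dir = if (is.null(dir)) NULL else
                                file.path(dir, "genomes"))
  if (!is.null(dir)) {
    dir.create(file.path(dir, "alignments"), recursive = TRUE,
               showWarnings = FALSE)
    write_newick(tree, file.path(dir, "tree.nwk"))
    for (g in names(genes)) {
      write_alignment(genes[[g]],
                      file.path(dir, "alignments", paste0(g, ".fasta")))
    }
    yaml::write_yaml(config_as_yaml_list(config),
                     file.path(dir, "config.yaml"))
  }
  list(tree = tree, genes = genes, records = records, config = config)
}
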