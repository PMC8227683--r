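# Pipeline orchestration: run the analysis stages as subcommands driven by
# a single YAML configuration, with a reproducible run manifest.

pipeline_subcommands <- function() {
  c("simulate", "summarize", "rearrange", "saturation", "build-dataset",
    "njtree", "all")
}

load_pipeline_config <- function(config) {
  if (is.null(config)) return(sim_config())
  if (inherits(config, "sim_config")) return(config)
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    known <- names(sim_config())
    ev <- raw$planted_events
    raw$planted_events <- NULL
    extra <- setdiff(names(raw), known)
    if (length(extra)) {
      stop("unknown config key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    # YAML maps/sequences come back as lists; restore numeric vectors
    vecfields <- c("rates", "pos_mult", "gene_mult", "pcg_lengths",
                   "rrna_lengths", "trna_length_range",
                   "at_rich_length_range", "spacer_range")
    for (f in intersect(vecfields, names(raw))) raw[[f]] <- unlist(raw[[f]])
    if (!is.null(raw$freqs)) raw$freqs <- lapply(raw$freqs, unlist)
    cfg <- do.call(sim_config, raw[intersect(names(raw), known)])
    if (!is.null(ev)) {
      cfg$planted_events <- lapply(ev, function(e) {
        new_event(e$kind, unlist(e$genes),
                  unlist(e$from_context), unlist(e$to_context))
      })
    }
    return(cfg)
  }
  stop("config must be NULL, a sim_config, or a YAML path", call. = FALSE)
}

# model used for distance correction in the pipeline: configured
# substitution parameters with partition-empirical base frequencies
pipeline_model <- function(cfg, aln) {
  M <- as_alignment_matrix(aln)
  counts <- tabulate(M[!is.na(M)], 4L)
  counts[counts == 0L] <- 1L
  gtr_model(counts / sum(counts), cfg$rates, cfg$alpha, cfg$p_inv, cfg$k)
}

# per-gene x codon-position partitions used by the saturation stage
saturation_partitions <- function(genes) {
  parts <- list()
  for (g in intersect(names(genes), mito_pcgs())) {
    aln <- strip_stop_codons(genes[[g]])
    L <- unique(nchar(aln))
    for (pos in 1:3) {
      idx <- seq(pos, L, by = 3L)
      parts[[paste0(g, "_pos", pos)]] <-
        vapply(aln, function(s) collapse_chars(seq_chars(s)[idx]),
               character(1))
    }
  }
  for (g in intersect(names(genes), c(mito_trnas(), mito_rrnas()))) {
    parts[[g]] <- genes[[g]]
  }
  parts
}

stage_summarize <- function(records, dir) {
  comp <- do.call(rbind, lapply(names(records), function(tx) {
    x <- composition_by_partition(records[[tx]])
    cbind(taxon = tx, x)
  }))
  write_composition_tsv(comp, file.path(dir, "composition.tsv"))
  ru <- do.call(rbind, lapply(names(records), function(tx) {
    x <- rscu(codon_usage(records[[tx]]))
    cbind(taxon = tx, as.data.frame(x))
  }))
  write_composition_tsv(ru, file.path(dir, "rscu.tsv"))
  so <- do.call(rbind, lapply(names(records), function(tx) {
    rep_ <- spacers_and_overlaps(records[[tx]])
    data.frame(taxon = tx,
               total_spacer_bp = rep_$total_spacer_bp,
               n_spacer_locations = rep_$n_spacer_locations,
               total_overlap_bp = rep_$total_overlap_bp,
               n_overlap_locations = rep_$n_overlap_locations)
  }))
  write_composition_tsv(so, file.path(dir, "spacers_overlaps.tsv"))
  ss <- do.call(rbind, lapply(names(records), function(tx) {
    pcgs <- records[[tx]]$annotations$name[records[[tx]]$annotations$kind == "PCG"]
    do.call(rbind, lapply(pcgs, function(g) {
      x <- detect_start_stop(records[[tx]], g)
      data.frame(taxon = tx, gene = g, start = x$start, stop = x$stop)
    }))
  }))
  write_composition_tsv(ss, file.path(dir, "start_stop.tsv"))
  c("composition.tsv", "rscu.tsv", "spacers_overlaps.tsv", "start_stop.tsv")
}

stage_rearrange <- function(records, cfg, dir) {
  anc <- ancestral_pancrustacean_order()
  orders <- lapply(records, gene_order_of)
  ev <- lapply(orders, infer_events, reference = anc)
  write_events_tsv(ev, file.path(dir, "events.tsv"))
  shared <- shared_derived_events(orders, anc, clade = clade_taxa(cfg))
  write_events_tsv(shared, file.path(dir, "shared_events.tsv"))
  writeLines(vapply(orders, format_gene_order, character(1)),
             file.path(dir, "gene_orders.txt"))
  c("events.tsv", "shared_events.tsv", "gene_orders.txt")
}

stage_saturation <- function(genes, cfg, dir) {
  parts <- saturation_partitions(genes)
  models <- lapply(parts, function(a) pipeline_model(cfg, a))
  rep_ <- saturation_screen(parts, models)
  write_composition_tsv(as.data.frame(rep_),
                        file.path(dir, "saturation.tsv"))
  "saturation.tsv"
}

stage_build_dataset <- function(genes, dir) {
  stripped <- genes
  for (g in intersect(names(stripped), mito_pcgs())) {
    stripped[[g]] <- strip_stop_codons(stripped[[g]])
  }
  outs <- character(0)
  for (v in supermatrix_variants()) {
    sm <- concatenate(stripped, v)
    write_supermatrix(sm, file.path(dir, paste0(v, ".phy")), "phylip")
    write_supermatrix(sm, file.path(dir, paste0(v, ".fasta")), "fasta")
    write_partitions(sm$scheme, file.path(dir, paste0(v, ".charsets.nex")),
                     "nexus_charset")
    write_partitions(sm$scheme, file.path(dir, paste0(v, ".partitions.txt")),
                     "raxml_style")
    outs <- c(outs, paste0(v, c(".phy", ".fasta", ".charsets.nex",
                                ".partitions.txt")))
  }
  outs
}

stage_njtree <- function(genes, cfg, dir) {
  stripped <- genes
  for (g in intersect(names(stripped), mito_pcgs())) {
    stripped[[g]] <- strip_stop_codons(stripped[[g]])
  }
  sm <- concatenate(stripped, "P12RNA")
  mod <- pipeline_model(cfg, sm$seqs)
  D <- gtr_distance_matrix(sm$seqs, mod)
  write_phylip_distances(D, file.path(dir, "P12RNA.gtr.dist"))
  tr <- nj_tree(D)
  write_newick(tr, file.path(dir, "njtree.nwk"))
  c("P12RNA.gtr.dist", "njtree.nwk")
}

#' Run the analysis pipeline
#'
#' Subcommands: `simulate` (generate the synthetic dataset), `summarize`
#' (composition, RSCU, start/stop, spacer tables), `rearrange` (gene
#' orders and rearrangement events vs the ancestral arrangement),
#' `saturation` (per-gene/per-position saturation screen), `build-dataset`
#' (the four supermatrix variants plus partition files), `njtree`
#' (GTR-corrected NJ tree from P12RNA), or `all`.  Every stage reads its
#' inputs from the configuration-driven simulation (or, for `summarize`,
#' from GenBank files passed via `genbank`), writes under `out_dir`, and a
#' JSON run manifest is emitted.
#'
#' @param subcommand One of the stage names above.
#' @param config `NULL` (defaults), a [sim_config()], or a YAML file path.
#' @param out_dir Output directory (created if needed).
#' @param genbank Optional character vector of GenBank files; when given,
#'   `summarize`/`rearrange` run on these records instead of simulating.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(subcommand, config = NULL, out_dir = "mitocomp_out",
                         genbank = NULL) {
  if (length(subcommand) != 1L || !subcommand %in% pipeline_subcommands()) {
    stop("usage error: unknown subcommand '", paste(subcommand, collapse = " "),
         "'; expected one of ", paste(pipeline_subcommands(), collapse = ", "),
         call. = FALSE)
  }
  cfg <- load_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)

  need_sim <- is.null(genbank) ||
    subcommand %in% c("simulate", "saturation", "build-dataset", "njtree", "all")
  sim <- NULL
  records <- NULL
  if (!is.null(genbank)) {
    records <- lapply(genbank, read_genbank)
    names(records) <- vapply(records, function(r) r$taxon, character(1))
  }
  if (need_sim) {
    sim <- simulate_mitogenomes(cfg, dir = if (subcommand %in% c("simulate", "all"))
      file.path(out_dir, "simulate") else NULL)
    if (is.null(records)) records <- sim$records
  }
  if (subcommand %in% c("simulate", "all")) {
    outputs <- c(outputs, file.path("simulate", "tree.nwk"))
  }
  if (subcommand %in% c("summarize", "all")) {
    d <- file.path(out_dir, "summarize")
    dir.create(d, showWarnings = FALSE)
    outputs <- c(outputs, file.path("summarize", stage_summarize(records, d)))
  }
  if (subcommand %in% c("rearrange", "all")) {
    d <- file.path(out_dir, "rearrange")
    dir.create(d, showWarnings = FALSE)
    outputs <- c(outputs, file.path("rearrange", stage_rearrange(records, cfg, d)))
  }
  if (subcommand %in% c("saturation", "all")) {
    d <- file.path(out_dir, "saturation")
    dir.create(d, showWarnings = FALSE)
    outputs <- c(outputs, file.path("saturation",
                                    stage_saturation(sim$genes, cfg, d)))
  }
  if (subcommand %in% c("build-dataset", "all")) {
    d <- file.path(out_dir, "dataset")
    dir.create(d, showWarnings = FALSE)
    outputs <- c(outputs, file.path("dataset", stage_build_dataset(sim$genes, d)))
  }
  if (subcommand %in% c("njtree", "all")) {
    d <- file.path(out_dir, "njtree")
    dir.create(d, showWarnings = FALSE)
    outputs <- c(outputs, file.path("njtree", stage_njtree(sim$genes, cfg, d)))
  }

  cfg_tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config_as_yaml_list(cfg), cfg_tmp)
  manifest <- list(
    tool = "mitocomp",
    version = tryCatch(as.character(utils::packageVersion("mitocomp")),
                       error = function(e) "unknown"),
    subcommand = subcommand,
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_tmp)),
    inputs = if (is.null(genbank)) list() else
      as.list(stats::setNames(unname(tools::md5sum(genbank)), genbank)),
    outputs = outputs
  )
  unlink(cfg_tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
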