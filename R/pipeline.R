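# End-to-end orchestration: simulate (or ingest) proteomes, similarity,
# homolog + ortholog clustering, per-family alignment and block
# filtering, the four matrix types, NJ/MP(/ML) trees with bootstrap and
# composite support dots, and the COG guild comparison -- one seeded,
# reproducible run with a manifest.

# per-family aligned + filtered alignments (rows renamed to genome ids)
gp_family_alignments <- function(families, proteomes, scheme, cfg) {
  params <- block_filter_params(cfg$min_conserved_fraction,
                                cfg$high_conserved_fraction,
                                cfg$max_nonconserved_run,
                                cfg$min_block_len, cfg$allow_gap_columns)
  seqs_of <- function(rows) {
    s <- vapply(seq_len(nrow(rows)), function(i)
      proteomes[[rows$genome_id[i]]]$genes[[rows$gene_id[i]]], "")
    setNames(s, rows$genome_id)
  }
  out <- list()
  for (fid in unique(families$family_id)) {
    rows <- families[families$family_id == fid, , drop = FALSE]
    if (nrow(rows) < 2) next
    aln <- progressive_align(seqs_of(rows), scheme, k = cfg$kmer)
    fb <- suppressWarnings(filter_blocks(aln, params))
    if (!is.null(fb$alignment)) out[[fid]] <- fb$alignment
  }
  out
}

# NJ/MP(/ML) trees with bootstrap supports and the composite annotation
gp_tree_set <- function(cm, cfg, seed, label) {
  methods <- c("nj", "mp", if (cfg$run_ml) "ml")
  trees <- list()
  supports <- list()
  for (i in seq_along(methods)) {
    me <- methods[i]
    tr <- switch(me,
      nj = neighbor_joining(pairwise_distances(cm, gp_default_dist(cm))),
      mp = parsimony_search(cm, seed = seed + i,
                            restarts = cfg$nni_restarts)$tree,
      ml = ml_search(cm, seed = seed + i)$tree)
    trees[[me]] <- tr
    if (cfg$bootstrap_reps > 0)
      supports[[me]] <- bootstrap_support(cm, me,
                                          n_reps = cfg$bootstrap_reps,
                                          seed = seed + 100 + i,
                                          reference = trees[[1]])
  }
  annotated <- if (length(supports))
    annotate_support(trees[[1]], supports) else NULL
  list(label = label, trees = trees, supports = supports,
       annotated = annotated)
}

#' Run the whole pipeline
#'
#' Executes simulate -> similarity -> cluster -> align/filter ->
#' matrices -> trees/support -> COG comparison as a single reproducible
#' run. Per-stage seeds are derived from the global seed by fixed
#' offsets, so stages are independently reproducible. Artifacts are
#' written under `out_dir`; matrix dimensions are logged as
#' "N genes and M characters".
#'
#' @param config A [pipeline_config()] (or list of overrides).
#' @param out_dir Output directory (default: a fresh temporary
#'   directory).
#' @param proteomes Optional named list of [proteome()] objects to
#'   analyse instead of simulating (then `guild_of` must be given for
#'   the COG stage).
#' @param guild_of Optional named genome -> guild ("K"/"r") vector;
#'   defaults to the simulation truth.
#' @return A run manifest (list): config, seed, matrix dimensions, file
#'   paths, per-stage timings, the trees, the guild comparison and (for
#'   simulated runs) the truth.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile(),
                         proteomes = NULL, guild_of = NULL) {
  if (!inherits(config, "gp_config")) config <- pipeline_config(config)
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- c()
  tick <- function(stage) {
    el <- as.numeric(Sys.time() - t0, units = "secs")
    timings[[stage]] <<- round(el, 2)
    t0 <<- Sys.time()
    gp_log("stage ", stage, " done (", round(el, 1), "s)")
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline halted in stage '", name, "': ",
           conditionMessage(e), call. = FALSE))
    tick(name)
    res
  }
  gp_log("resolved config: ",
         paste(names(cfg), unlist(lapply(cfg, format)), sep = "=",
               collapse = " "))
  truth <- NULL
  if (is.null(proteomes)) {
    if (!cfg$simulate)
      stop("no proteomes given and simulation disabled")
    sim <- stage("simulate", {
      s <- simulate_dataset(n_taxa = cfg$n_taxa, seed = cfg$seed,
                            mean_branch = cfg$mean_branch,
                            root_len = cfg$root_len,
                            n_core = cfg$n_core,
                            n_accessory = cfg$n_accessory,
                            gain_rate = cfg$gain_rate,
                            loss_rate = cfg$loss_rate,
                            dup_prob = cfg$dup_prob,
                            guild_mode = cfg$guild_mode,
                            p_specific = cfg$p_specific,
                            marker_cog = cfg$marker_cog)
      write_simulation(s, file.path(out_dir, "simulated"))
      s
    })
    proteomes <- sim$proteomes
    truth <- sim$truth
    if (is.null(guild_of)) guild_of <- truth$guild_of
  }
  scheme <- scoring_scheme(gap_open = cfg$gap_open,
                           gap_extend = cfg$gap_extend,
                           karlin_lambda = cfg$karlin_lambda,
                           karlin_k = cfg$karlin_k)
  hits <- stage("similarity", {
    h <- all_vs_all(proteomes, scheme, e_max = cfg$e_max)
    write_similarity_table(h, file.path(out_dir, "hits.tsv"))
    h
  })
  homologs <- stage("cluster_homolog", {
    graph <- build_homolog_graph(hits, e_max = cfg$e_max,
                                 weight_cap = cfg$weight_cap)
    graph <- gp_graph_add_nodes(graph, unlist(lapply(proteomes, function(p)
      gp_key(p$genome_id, names(p$genes))), use.names = FALSE))
    fam <- mcl(graph, inflation = cfg$homolog_inflation,
               prune_below = cfg$mcl_prune, tol = cfg$mcl_tol,
               max_iter = cfg$mcl_max_iter)
    write_membership_tsv(fam, file.path(out_dir, "homolog_families.tsv"))
    fam
  })
  orthologs <- stage("cluster_ortholog", {
    fam <- ortholog_families(hits, proteomes,
                             inflation = cfg$ortholog_inflation,
                             e_max = cfg$e_max,
                             weight_cap = cfg$weight_cap)
    fam <- remove_inparalogs(fam, hits,
                             drop_multicopy_families =
                               cfg$drop_multicopy_families)
    write_membership_tsv(fam, file.path(out_dir, "ortholog_families.tsv"))
    fam
  })
  alignments <- stage("align_filter",
                      gp_family_alignments(orthologs, proteomes, scheme,
                                           cfg))
  genomes <- vapply(proteomes, `[[`, "", "genome_id")
  mats <- stage("matrices", {
    sm <- build_supermatrix(alignments, min_seqs = cfg$min_seqs)
    red <- reduce_matrix(sm, cfg$quartets_per_partition, cfg$min_info,
                         seed = cfg$seed + 7L)
    core <- suppressWarnings(build_core_matrix(alignments, genomes))
    gene_content <- build_content_matrix(homologs, genomes)
    orth_content <- build_content_matrix(orthologs, genomes)
    out <- list(supermatrix = sm, reduced = red, core = core,
                gene_content = gene_content,
                ortholog_content = orth_content)
    for (nm in names(out)) {
      m <- out[[nm]]
      if (is.null(m)) next
      gp_log(nm, ": ", nrow(m$partitions), " genes and ", ncol(m$mat),
             " characters")
      if (m$alphabet == "binary") {
        write_content_tsv(m, file.path(out_dir, paste0(nm, ".tsv")))
      } else {
        write_phylip_relaxed(m, file.path(out_dir, paste0(nm, ".phy")))
        write_partitions(m, file.path(out_dir, paste0(nm, ".partitions")))
      }
    }
    out
  })
  tree_sets <- stage("trees", {
    ts <- list()
    off <- 1000L
    for (nm in names(mats)) {
      if (is.null(mats[[nm]])) next
      ts[[nm]] <- gp_tree_set(mats[[nm]], cfg, seed = cfg$seed + off, nm)
      off <- off + 50L
      for (me in names(ts[[nm]]$trees))
        write_newick(ts[[nm]]$trees[[me]],
                     file.path(out_dir, paste0(nm, "_", me, ".nwk")))
      if (!is.null(ts[[nm]]$annotated))
        write.table(ts[[nm]]$annotated$table,
                    file.path(out_dir, paste0(nm, "_support.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    ts
  })
  comparison <- stage("cogs", {
    profs <- lapply(proteomes, category_percentages)
    cmp <- if (!is.null(guild_of) &&
                 all(c("K", "r") %in% guild_of[genomes])) {
      gc <- guild_comparison(profs, guild_of, alpha = cfg$alpha,
                             min_diff = cfg$min_diff)
      write_guild_comparison(gc, file.path(out_dir,
                                           "guild_comparison.tsv"))
      gc
    } else NULL
    mr <- tryCatch(marker_ratio(proteomes, cfg$marker_cog, guild_of),
                   error = function(e) NULL)
    list(profiles = profs, comparison = cmp, marker = mr)
  })
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    config = unclass(cfg), seed = cfg$seed,
    n_genomes = length(proteomes),
    matrix_dims = lapply(mats, function(m) if (is.null(m)) NULL else
      c(genes = nrow(m$partitions), characters = ncol(m$mat))),
    artifacts = setNames(as.list(unname(tools::md5sum(files))),
                         basename(files)),
    timings = timings,
    out_dir = out_dir)
  jsonlite::write_json(manifest[c("config", "seed", "n_genomes",
                                  "matrix_dims", "artifacts", "timings")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  c(manifest, list(matrices = mats, tree_sets = tree_sets,
                   cogs = comparison, truth = truth,
                   proteomes = proteomes, hits = hits,
                   homologs = homologs, orthologs = orthologs,
                   alignments = alignments))
}
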