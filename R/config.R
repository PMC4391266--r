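# Run configuration: a single flat list of stage parameters, read from
# YAML. Unknown keys are rejected; every run logs the resolved values.

#' Default pipeline configuration
#'
#' All stage parameters with their defaults. Clustering uses an E-value
#' cutoff of 1e-5 with inflation 2.0 for homolog (TribeMCL-style) families
#' and 1.5 for ortholog families; the block filter and aligner defaults
#' follow the published GBLOCKS / gapped-BLOSUM62 settings; simulation
#' defaults are documented in the methods vignette.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    # simulation
    simulate = TRUE, n_taxa = 12L, mean_branch = 0.08,
    n_core = 20L, n_accessory = 30L, gain_rate = 0.3, loss_rate = 0.3,
    dup_prob = 0.05, root_len = 100L, guild_mode = "clade",
    p_specific = 0.8,
    # similarity
    gap_open = 11, gap_extend = 1, karlin_lambda = 0.267,
    karlin_k = 0.041, e_max = 1e-5,
    # clustering
    weight_cap = 200, homolog_inflation = 2.0, ortholog_inflation = 1.5,
    mcl_prune = 1e-6, mcl_tol = 1e-8, mcl_max_iter = 200L,
    drop_multicopy_families = FALSE,
    # alignment + block filter
    kmer = 3L, min_conserved_fraction = 0.5, high_conserved_fraction = 0.85,
    max_nonconserved_run = 8L, min_block_len = 10L,
    allow_gap_columns = FALSE,
    # matrices
    min_seqs = 4L, quartets_per_partition = 100L, min_info = 0.25,
    # trees
    bootstrap_reps = 100L, nni_restarts = 3L, run_ml = FALSE,
    # COG guild comparison
    alpha = 0.05, min_diff = 1.0, marker_cog = "COG2124"
  )
}

#' Build a validated pipeline configuration
#'
#' @param ... Overrides of [default_config()] entries. Unknown keys are an
#'   error.
#' @return Named list with class `gp_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- default_config()
  ov <- list(...)
  if (length(ov) == 1 && is.list(ov[[1]]) && is.null(names(ov)[1]))
    ov <- ov[[1]]
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  with(cfg, {
    stopifnot(n_taxa >= 3, mean_branch > 0, n_core >= 0, n_accessory >= 0,
              gain_rate >= 0, loss_rate >= 0, dup_prob >= 0, dup_prob < 1,
              root_len >= 30, guild_mode %in% c("clade", "convergent"),
              p_specific > 0, p_specific <= 1,
              gap_open > 0, gap_extend > 0, e_max >= 0, weight_cap > 0,
              homolog_inflation > 1, ortholog_inflation > 1,
              min_conserved_fraction >= 0.5, min_conserved_fraction <= 1,
              high_conserved_fraction >= 0.5, high_conserved_fraction <= 1,
              max_nonconserved_run >= 0, min_block_len >= 1,
              min_seqs >= 1, quartets_per_partition >= 1,
              min_info >= 0, min_info <= 1,
              bootstrap_reps >= 0, nni_restarts >= 0,
              alpha > 0, alpha < 1, min_diff >= 0)
  })
  structure(cfg, class = "gp_config")
}

#' Read a YAML configuration file
#' @param path YAML file of parameter overrides.
#' @return Validated `gp_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pipeline_config(yaml::read_yaml(path))
}

# stderr logging with levels
gp_log <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, paste0(...)))
}
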