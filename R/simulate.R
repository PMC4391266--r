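# Genome-evolution simulator: a known species tree, gene families evolving
# by gain/loss/duplication, planted guild-specific COG signatures, and
# sequence divergence by a stationary i.i.d.-site replacement process.
# Provides the ground truth against which the whole pipeline is validated.

#' Simulate a species tree (Yule topology, exponential branch lengths)
#'
#' Pure-birth topology: starting from two lineages, a uniformly chosen
#' extant lineage splits until `n_taxa` are reached. Branch lengths are
#' i.i.d. exponential with the given mean (expected substitutions/site),
#' floored at `min_branch` so that every split is identifiable from
#' desk-scale sequence data (an exponential draw can otherwise be
#' arbitrarily close to zero, leaving a split that no method can
#' recover). Deterministic given the seed.
#'
#' @param n_taxa Number of genomes (>= 3).
#' @param seed Integer seed.
#' @param mean_branch Mean branch length.
#' @param min_branch Branch-length floor (default 0.02).
#' @return A rooted binary ape `phylo` with tips `G01`, `G02`, ...
#' @export
simulate_species_tree <- function(n_taxa, seed, mean_branch = 0.1,
                                  min_branch = 0.02) {
  if (n_taxa < 3) stop("n_taxa must be at least 3")
  stopifnot(mean_branch > 0, min_branch >= 0, min_branch < mean_branch)
  set.seed(seed)
  # nested-list topology; leaves are integer creation ids
  node <- list(1L, 2L)
  n_leaves <- 2L
  split_leaf <- function(nd, target) {
    if (is.integer(nd))
      return(if (nd == target) list(nd, n_leaves) else nd)
    list(split_leaf(nd[[1]], target), split_leaf(nd[[2]], target))
  }
  while (n_leaves < n_taxa) {
    target <- sample.int(n_leaves, 1)
    n_leaves <- n_leaves + 1L
    node <- split_leaf(node, target)
  }
  lab <- sprintf(paste0("G%0", max(2, nchar(n_taxa)), "d"),
                 seq_len(n_taxa))
  deparse_nwk <- function(nd) {
    bl <- max(rexp(1, 1 / mean_branch), min_branch)
    if (is.integer(nd)) return(sprintf("%s:%.8f", lab[nd], bl))
    sprintf("(%s,%s):%.8f", deparse_nwk(nd[[1]]), deparse_nwk(nd[[2]]), bl)
  }
  nwk <- sprintf("(%s,%s);", deparse_nwk(node[[1]]), deparse_nwk(node[[2]]))
  ape::read.tree(text = nwk)
}

#' Per-guild COG category profiles of the two trophic guilds
#'
#' Default expected percentages of genes per genome in each functional
#' category for slow-growing oligotrophs (K-strategists) versus
#' fast-responding copiotrophs (r-strategists), together with the mean
#' copy number of the cytochrome-P450-like marker family (COG2124) whose
#' K:r abundance ratio is about 11.
#'
#' @return List with named percentage vectors `K` and `r` (category
#'   letters as names) and `marker_mean_copies` (named numeric, K and r).
#' @export
default_guild_profiles <- function() {
  K <- c(E = 8, G = 3, D = 1, N = 2, M = 6, H = 5, V = 1, C = 7, P = 6,
         U = 3, I = 7, F = 2, O = 5, L = 5, Q = 4, T = 3, K = 5, J = 6)
  r <- c(E = 7, G = 6, D = 1, N = 3, M = 6, H = 5, V = 2, C = 6, P = 6,
         U = 4, I = 3, F = 2, O = 5, L = 4, Q = 2, T = 6, K = 7, J = 6)
  list(K = K, r = r, marker_mean_copies = c(K = 1.1, r = 0.1))
}

# assign guilds to tips: "clade" splits at the root, "convergent"
# alternates K/r across the cladewise tip order (guild signal orthogonal
# to the species tree)
gp_assign_guilds <- function(tree, guild_mode) {
  tips <- tree$tip.label
  if (guild_mode == "convergent") {
    g <- rep(c("K", "r"), length.out = length(tips))
  } else {
    root <- length(tips) + 1L
    child1 <- tree$edge[tree$edge[, 1] == root, 2][1]
    side1 <- if (child1 <= length(tips)) tips[child1] else
      tips[phangorn::Descendants(tree, child1, "tips")[[1]]]
    g <- ifelse(tips %in% side1, "K", "r")
  }
  setNames(g, tips)
}

# telegraph (two-state gain/loss) process along one branch
gp_telegraph <- function(state, t, gain_rate, loss_rate) {
  pos <- 0
  repeat {
    rate <- if (state) loss_rate else gain_rate
    if (rate <= 0) break
    pos <- pos + rexp(1, rate)
    if (pos >= t) break
    state <- !state
  }
  state
}

#' Simulate gene-family structure along a species tree
#'
#' Three family kinds are planted. Core single-copy families are present
#' exactly once in every genome. Accessory families come in a shared pool
#' (present at the root with probability 0.5, presence toggling by a
#' gain/loss telegraph process along branches) and in guild-specific
#' pools (present with probability `p_specific` in genomes of their
#' guild, absent elsewhere) that carry the planted guild signal. Present
#' accessory families are independently duplicated with probability
#' `dup_prob` (creating an inparalog copy). One guild-marker
#' family has Poisson copy numbers with guild-specific means.
#'
#' Category letters are assigned so that the expected per-genome category
#' percentages match the guild profiles: the common pool (core + shared
#' accessory) draws categories from the pointwise minimum of the two
#' profiles, each guild-specific pool from that guild's excess, and pool
#' sizes are solved so the expected proportions agree (see the methods
#' vignette).
#'
#' @param tree Species tree ([simulate_species_tree()]).
#' @param guild_of Named vector mapping tip to "K"/"r"; `NULL` assigns by
#'   `guild_mode`.
#' @param n_core,n_accessory Family counts (accessory = shared +
#'   guild-specific pools).
#' @param gain_rate,loss_rate Telegraph rates per unit branch length.
#' @param dup_prob Per-genome duplication probability (0 <= p < 1).
#' @param guild_profiles As [default_guild_profiles()].
#' @param seed Integer seed.
#' @param guild_mode "clade" or "convergent" (used when `guild_of` is
#'   NULL).
#' @param p_specific Presence probability of a guild-specific family in
#'   its own guild.
#' @param marker_cog Marker family COG id.
#' @param n_markers Number of marker families (0 or 1; 0 omits the
#'   marker, giving a dataset with no within-genome duplicates when
#'   `dup_prob = 0`).
#' @return A `sim_truth` list: `species_tree`, `guild_of`, `families`
#'   (family_id, kind, category, cog_id, guild), `copy_number` (families
#'   x genomes integer matrix), `profiles`.
#' @export
simulate_families <- function(tree, guild_of = NULL, n_core = 20,
                              n_accessory = 30, gain_rate = 0.3,
                              loss_rate = 0.3, dup_prob = 0.05,
                              guild_profiles = default_guild_profiles(),
                              seed = 1, guild_mode = "clade",
                              p_specific = 0.8,
                              marker_cog = "COG2124", n_markers = 1L) {
  stopifnot(gain_rate >= 0, loss_rate >= 0, dup_prob >= 0, dup_prob < 1,
            n_markers %in% 0:1)
  if (sum(guild_profiles$K) > 100 || sum(guild_profiles$r) > 100)
    stop("guild profiles must not sum to more than 100 percent")
  set.seed(seed)
  if (is.null(guild_of)) guild_of <- gp_assign_guilds(tree, guild_mode)
  tips <- tree$tip.label
  stopifnot(setequal(names(guild_of), tips))
  guild_of <- guild_of[tips]

  cats <- sort(union(names(guild_profiles$K), names(guild_profiles$r)))
  PK <- setNames(rep(0, length(cats)), cats); PK[names(guild_profiles$K)] <- guild_profiles$K
  Pr <- setNames(rep(0, length(cats)), cats); Pr[names(guild_profiles$r)] <- guild_profiles$r
  m <- pmin(PK, Pr); eK <- PK - m; er <- Pr - m
  M <- sum(m); EK <- sum(eK); Er <- sum(er)
  # stationary presence probability of the shared-accessory telegraph
  p_sh <- if (gain_rate + loss_rate > 0)
    gain_rate / (gain_rate + loss_rate) else 0.5
  # solve pool sizes so expected common : guild-excess gene counts per
  # genome are M : E_g  (common = core + shared accessory)
  if (EK + Er > 0 && M > 0) {
    a <- (EK + Er) / (M * p_specific)
    n_sh <- max(0, round((n_accessory - n_core * a) / (1 + p_sh * a)))
    common <- n_core + n_sh * p_sh
    nK <- round(common * EK / (M * p_specific))
    nr <- round(common * Er / (M * p_specific))
    if (n_sh + nK + nr > n_accessory) {
      sc <- n_accessory / (n_sh + nK + nr)
      n_sh <- floor(n_sh * sc); nK <- floor(nK * sc); nr <- floor(nr * sc)
    }
    n_sh <- n_accessory - nK - nr
  } else {
    n_sh <- n_accessory; nK <- 0L; nr <- 0L
  }

  draw_cat <- function(n, wts) {
    if (n == 0) return(character())
    if (sum(wts) <= 0) return(rep(names(wts)[1], n))
    sample(names(wts), n, replace = TRUE, prob = wts)
  }
  fam <- data.frame(
    kind = c(rep("core_single_copy", n_core), rep("accessory", n_sh),
             rep("accessory", nK), rep("accessory", nr),
             rep("guild_marker", n_markers)),
    category = c(draw_cat(n_core, m), draw_cat(n_sh, m),
                 draw_cat(nK, eK), draw_cat(nr, er),
                 rep("Q", n_markers)),
    guild = c(rep(NA_character_, n_core + n_sh), rep("K", nK),
              rep("r", nr), rep(NA_character_, n_markers)),
    stringsAsFactors = FALSE)
  nf <- nrow(fam)
  fam$family_id <- sprintf("F%05d", seq_len(nf))
  fam$cog_id <- sprintf("COG%04d", 1000 + seq_len(nf))
  fam$cog_id[fam$kind == "guild_marker"] <- marker_cog
  fam <- fam[, c("family_id", "kind", "category", "cog_id", "guild")]

  cn <- matrix(0L, nf, length(tips), dimnames = list(fam$family_id, tips))
  cn[fam$kind == "core_single_copy", ] <- 1L
  # shared accessory: telegraph along the tree
  shared <- which(fam$kind == "accessory" & is.na(fam$guild))
  if (length(shared)) {
    edge <- tree$edge; elen <- tree$edge.length
    root <- length(tips) + 1L
    n_nodes <- max(edge)
    preord <- ape::reorder.phylo(tree, "cladewise")
    for (f in shared) {
      state <- logical(n_nodes)
      state[root] <- runif(1) < 0.5
      for (k in seq_len(nrow(preord$edge))) {
        p <- preord$edge[k, 1]; ch <- preord$edge[k, 2]
        state[ch] <- gp_telegraph(state[p], preord$edge.length[k],
                                  gain_rate, loss_rate)
      }
      cn[f, ] <- as.integer(state[seq_along(tips)])
    }
  }
  # guild-specific accessory: Bernoulli within the guild
  spec <- which(fam$kind == "accessory" & !is.na(fam$guild))
  for (f in spec) {
    own <- guild_of == fam$guild[f]
    cn[f, own] <- rbinom(sum(own), 1, p_specific)
  }
  # inparalog duplications of present accessory families
  acc <- which(fam$kind == "accessory")
  if (dup_prob > 0 && length(acc)) {
    pres <- cn[acc, , drop = FALSE] == 1L
    dup <- matrix(rbinom(length(pres), 1, dup_prob), nrow(pres))
    cn[acc, ][pres] <- cn[acc, ][pres] + as.integer(dup[pres])
  }
  # guild marker: Poisson copies with guild-specific mean
  mk <- which(fam$kind == "guild_marker")
  if (length(mk)) {
    mm <- guild_profiles$marker_mean_copies
    cn[mk, ] <- rpois(length(tips), mm[guild_of])
  }
  structure(list(species_tree = tree, guild_of = guild_of,
                 families = fam, copy_number = cn,
                 profiles = guild_profiles),
            class = "sim_truth")
}

# substitute along a branch: Poisson(t * L) events at uniform sites,
# replacement residues drawn from the stationary frequencies
gp_mutate <- function(seq_int, t, freqs) {
  L <- length(seq_int)
  k <- rpois(1, t * L)
  if (k > 0) {
    sites <- sample.int(L, k, replace = TRUE)
    seq_int[sites] <- sample.int(length(freqs), k, replace = TRUE,
                                 prob = freqs)
  }
  seq_int
}

#' Evolve protein sequences for every gene family of a simulation
#'
#' Each family gets a random root sequence over the 20 amino acids
#' (uniform stationary frequencies); along each branch of length t,
#' Poisson(t*L) substitution events hit uniform sites with replacement
#' residues drawn from the stationary frequencies. Inparalog copies
#' branch off the terminal branch at a duplication point drawn uniformly
#' and evolve independently afterwards. Guild-specific families, absent
#' from part of the tree, still evolve along the full tree; only the
#' genomes with nonzero copy number emit genes.
#'
#' @param truth A `sim_truth` from [simulate_families()].
#' @param root_len Root sequence length (>= 30).
#' @param seed Integer seed.
#' @return List with `proteomes` (named list of [proteome()], annotations
#'   attached from the truth) and `membership` (data frame family_id,
#'   genome_id, gene_id).
#' @export
evolve_sequences <- function(truth, root_len = 100, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"), root_len >= 30)
  set.seed(seed)
  tree <- truth$species_tree
  tips <- tree$tip.label
  freqs <- rep(1 / 20, 20)
  aa <- gp_aa_letters[1:20]
  preord <- ape::reorder.phylo(tree, "cladewise")
  root <- length(tips) + 1L
  n_nodes <- max(tree$edge)
  genes <- setNames(vector("list", length(tips)), tips)
  memb <- list()
  term_edge <- match(seq_along(tips), preord$edge[, 2])
  for (f in seq_len(nrow(truth$families))) {
    fid <- truth$families$family_id[f]
    seqs <- vector("list", n_nodes)
    seqs[[root]] <- sample.int(20, root_len, replace = TRUE, prob = freqs)
    for (k in seq_len(nrow(preord$edge))) {
      p <- preord$edge[k, 1]; ch <- preord$edge[k, 2]
      seqs[[ch]] <- gp_mutate(seqs[[p]], preord$edge.length[k], freqs)
    }
    for (tip in seq_along(tips)) {
      copies <- truth$copy_number[f, tip]
      if (copies < 1) next
      gname <- tips[tip]
      out <- list(seqs[[tip]])
      if (copies > 1) {
        # extra copies: duplication points uniform on the terminal branch
        t_term <- preord$edge.length[term_edge[tip]]
        parent <- preord$edge[term_edge[tip], 1]
        us <- sort(runif(copies - 1))
        cur <- seqs[[parent]]; pos <- 0
        for (u in us) {
          cur <- gp_mutate(cur, (u - pos) * t_term, freqs)
          out <- c(out, list(gp_mutate(cur, (1 - u) * t_term, freqs)))
          pos <- u
        }
      }
      ids <- sprintf("%s_%s_%d", gname, fid, seq_len(copies))
      strs <- vapply(out, function(s) paste(aa[s], collapse = ""), "")
      genes[[gname]] <- c(genes[[gname]], setNames(strs, ids))
      memb[[length(memb) + 1L]] <-
        data.frame(family_id = fid, genome_id = gname, gene_id = ids,
                   stringsAsFactors = FALSE)
    }
  }
  membership <- do.call(rbind, memb)
  proteomes <- lapply(tips, function(g) {
    gm <- membership[membership$genome_id == g, , drop = FALSE]
    fi <- match(gm$family_id, truth$families$family_id)
    ann <- data.frame(gene_id = gm$gene_id,
                      cog_id = truth$families$cog_id[fi],
                      categories = truth$families$category[fi],
                      stringsAsFactors = FALSE)
    proteome(g, genes[[g]], annotations = ann)
  })
  names(proteomes) <- tips
  list(proteomes = proteomes, membership = membership)
}

#' Simulate a complete proteome dataset with known truth
#'
#' Convenience wrapper chaining [simulate_species_tree()],
#' [simulate_families()] and [evolve_sequences()] with per-stage seeds
#' derived from one master seed.
#'
#' @param n_taxa Number of genomes.
#' @param seed Master seed.
#' @param mean_branch Mean branch length.
#' @param root_len Sequence length.
#' @param ... Passed to [simulate_families()].
#' @return List with `truth`, `proteomes`, `membership`.
#' @export
simulate_dataset <- function(n_taxa = 12, seed = 1, mean_branch = 0.08,
                             root_len = 100, min_branch = 0.02, ...) {
  tree <- simulate_species_tree(n_taxa, seed = seed,
                                mean_branch = mean_branch,
                                min_branch = min_branch)
  truth <- simulate_families(tree, seed = seed + 1L, ...)
  ev <- evolve_sequences(truth, root_len = root_len, seed = seed + 2L)
  list(truth = truth, proteomes = ev$proteomes,
       membership = ev$membership)
}

#' Write a simulated dataset to a directory
#'
#' Emits per-genome FASTA, per-genome annotation TSV, the true species
#' tree (Newick), the family membership TSV and the guild map TSV.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in sim$proteomes) {
    write_proteome_fasta(p, file.path(dir, paste0(p$genome_id, ".faa")))
    write_cog_annotations(p$annotations,
                          file.path(dir, paste0(p$genome_id, ".cog.tsv")))
  }
  write_newick(sim$truth$species_tree, file.path(dir, "species_tree.nwk"))
  write.table(sim$membership, file.path(dir, "membership.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(genome_id = names(sim$truth$guild_of),
                         guild = unname(sim$truth$guild_of)),
              file.path(dir, "guilds.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
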