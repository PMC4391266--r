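# Family building: TribeMCL-style Markov clustering of the symmetrized
# -log10(E) similarity graph (homolog families) and reciprocal-best-hit /
# inparalog graphs clustered the same way (ortholog families), followed by
# inparalog removal.

#' Build the weighted homolog graph from a hit table
#'
#' TribeMCL weighting: for each unordered gene pair the edge weight is the
#' mean over the two hit directions of `-log10(E)` capped at `weight_cap`
#' (`E = 0` counts as the cap; a missing direction contributes 0 to the
#' mean). Hits with `E > e_max` and self hits are excluded.
#'
#' @param hits Hit data frame ([all_vs_all()] /
#'   [read_similarity_table()]).
#' @param e_max E-value threshold (default 1e-5).
#' @param weight_cap Cap on `-log10(E)` (default 200).
#' @return A `gp_graph`: list with `nodes` (data frame genome_id, gene_id,
#'   key) and `edges` (data frame key1, key2, weight; key1 < key2).
#' @export
build_homolog_graph <- function(hits, e_max = 1e-5, weight_cap = 200) {
  qk <- gp_key(hits$query_genome, hits$query_gene)
  sk <- gp_key(hits$subject_genome, hits$subject_gene)
  keep <- hits$evalue <= e_max & qk != sk
  qk <- qk[keep]; sk <- sk[keep]
  w1 <- pmin(ifelse(hits$evalue[keep] == 0, weight_cap,
                    -log10(hits$evalue[keep])), weight_cap)
  k1 <- pmin(qk, sk); k2 <- pmax(qk, sk)
  pair <- paste(k1, k2, sep = "\r")
  # mean over both directions; a present direction contributes w, an
  # absent one 0, denominator always 2
  wsum <- tapply(w1, pair, sum)
  nodes_key <- sort(unique(c(qk, sk)))
  nodes <- if (length(nodes_key)) {
    nk <- do.call(rbind, strsplit(nodes_key, "\t", fixed = TRUE))
    data.frame(genome_id = nk[, 1], gene_id = nk[, 2], key = nodes_key,
               stringsAsFactors = FALSE)
  } else data.frame(genome_id = character(), gene_id = character(),
                    key = character(), stringsAsFactors = FALSE)
  edges <- if (length(wsum)) {
    ek <- do.call(rbind, strsplit(names(wsum), "\r", fixed = TRUE))
    data.frame(key1 = ek[, 1], key2 = ek[, 2],
               weight = as.numeric(wsum) / 2, stringsAsFactors = FALSE)
  } else data.frame(key1 = character(), key2 = character(),
                    weight = numeric(), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "gp_graph")
}

# include isolated nodes explicitly
gp_graph_add_nodes <- function(graph, keys) {
  extra <- setdiff(keys, graph$nodes$key)
  if (length(extra)) {
    nk <- do.call(rbind, strsplit(extra, "\t", fixed = TRUE))
    graph$nodes <- rbind(graph$nodes,
                         data.frame(genome_id = nk[, 1], gene_id = nk[, 2],
                                    key = extra, stringsAsFactors = FALSE))
    graph$nodes <- graph$nodes[order(graph$nodes$key), , drop = FALSE]
  }
  graph
}

# Dense MCL on one connected component (weight matrix W, nodes in
# columns). Returns a list of integer index vectors (clusters).
gp_mcl_component <- function(W, inflation, expansion, prune_below, tol,
                             max_iter) {
  n <- ncol(W)
  if (n == 1) return(list(1L))
  loops <- apply(W, 2, max)
  loops[loops <= 0] <- 1
  diag(W) <- loops
  M <- sweep(W, 2, colSums(W), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    prev <- M
    for (e in seq_len(expansion - 1)) M <- M %*% M
    M <- M ^ inflation
    M[M < prune_below] <- 0
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2, cs, "/")
    if (max(abs(M - prev)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter,
            " iterations; clustering the current matrix")
  adj <- (M > 0) | (t(M) > 0)
  comp <- gp_components(adj)
  split(seq_len(n), comp)
}

# connected components of a logical adjacency matrix (BFS)
gp_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Markov clustering (MCL) of a weighted gene graph
#'
#' A from-scratch MCL in the TribeMCL setup: self loops equal to each
#' node's maximum incident weight (1 for isolated nodes), column
#' normalization, then alternating expansion (matrix power) and inflation
#' (entrywise power + renormalization) with pruning until idempotence.
#' Clusters are the connected components of the nonzero attractor-overlap
#' pattern of the limit matrix. The graph is split into connected
#' components first; MCL runs densely per component, which is equivalent
#' and fast at desk scale.
#'
#' @param graph A `gp_graph` from [build_homolog_graph()].
#' @param inflation Inflation exponent (default 2.0, the homolog-family
#'   setting; ortholog families use 1.5).
#' @param expansion Expansion power (default 2).
#' @param prune_below Entries below this are zeroed each iteration.
#' @param tol Idempotence tolerance (max entry change).
#' @param max_iter Iteration cap (warning + current clustering on hit).
#' @param kind Family kind label for the output.
#' @return Membership data frame with columns `family_id`, `genome_id`,
#'   `gene_id`, `kind`; families are a partition of the graph's nodes,
#'   numbered in lexicographic order of their smallest member key.
#' @export
mcl <- function(graph, inflation = 2.0, expansion = 2L,
                prune_below = 1e-6, tol = 1e-8, max_iter = 200L,
                kind = "homolog") {
  stopifnot(inherits(graph, "gp_graph"), nrow(graph$nodes) > 0)
  nodes <- graph$nodes[order(graph$nodes$key), , drop = FALSE]
  key <- nodes$key
  n <- length(key)
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("key1", "key2")], directed = FALSE,
    vertices = data.frame(name = key))
  comp <- igraph::components(g)$membership[key]
  clusters <- list()
  for (cid in sort(unique(comp))) {
    idx <- which(comp == cid)
    sub <- key[idx]
    W <- matrix(0, length(idx), length(idx), dimnames = list(sub, sub))
    sel <- graph$edges$key1 %in% sub & graph$edges$key2 %in% sub
    e <- graph$edges[sel, , drop = FALSE]
    W[cbind(match(e$key1, sub), match(e$key2, sub))] <- e$weight
    W[cbind(match(e$key2, sub), match(e$key1, sub))] <- e$weight
    cl <- gp_mcl_component(W, inflation, expansion, prune_below, tol,
                           max_iter)
    clusters <- c(clusters, lapply(cl, function(ix) idx[ix]))
  }
  # deterministic family numbering: by smallest member key
  ord <- order(vapply(clusters, function(ix) min(key[ix]), ""))
  clusters <- clusters[ord]
  sizes <- lengths(clusters)
  fam <- sprintf("F%05d", rep(seq_along(clusters), sizes))
  ix <- unlist(clusters)
  data.frame(family_id = fam, genome_id = nodes$genome_id[ix],
             gene_id = nodes$gene_id[ix], kind = kind,
             stringsAsFactors = FALSE)
}

#' Ortholog families from reciprocal best hits with inparalog edges
#'
#' Ortholog edges connect reciprocal best hits between genome pairs (best
#' by E-value, ties broken by bit score then lexicographic subject id).
#' Inparalog edges connect within-genome gene pairs whose E-value is at
#' most the worse of the two genes' best between-genome E-values (genes
#' with no between-genome hit count as +Inf, so any within-genome hit
#' qualifies). Edge weights follow the [build_homolog_graph()] convention
#' and the combined graph is clustered by [mcl()]; families are reported
#' before inparalog removal.
#'
#' @param hits Hit data frame.
#' @param proteomes List of [proteome()] objects (defines the gene
#'   universe; genes without qualifying edges become singletons).
#' @param inflation MCL inflation (default 1.5, the ortholog-family
#'   setting).
#' @param e_max,weight_cap As in [build_homolog_graph()].
#' @return Membership data frame (`kind = "ortholog"`).
#' @export
ortholog_families <- function(hits, proteomes, inflation = 1.5,
                              e_max = 1e-5, weight_cap = 200) {
  stopifnot(length(proteomes) >= 2)
  hits <- hits[hits$evalue <= e_max, , drop = FALSE]
  qk <- gp_key(hits$query_genome, hits$query_gene)
  sk <- gp_key(hits$subject_genome, hits$subject_gene)
  self <- qk == sk
  hits <- hits[!self, , drop = FALSE]; qk <- qk[!self]; sk <- sk[!self]
  between <- hits$query_genome != hits$subject_genome
  # best between-genome hit per (query gene, subject genome)
  bt <- hits[between, , drop = FALSE]
  qkb <- qk[between]; skb <- sk[between]
  ord <- order(qkb, bt$subject_genome, bt$evalue, -bt$bitscore,
               bt$subject_gene)
  bt <- bt[ord, , drop = FALSE]; qkb <- qkb[ord]; skb <- skb[ord]
  first <- !duplicated(paste(qkb, bt$subject_genome, sep = "\r"))
  best <- data.frame(q = qkb[first], s = skb[first],
                     stringsAsFactors = FALSE)
  # reciprocal best hits
  fwd <- paste(best$q, best$s, sep = "\r")
  bwd <- paste(best$s, best$q, sep = "\r")
  rbh <- best[fwd %in% bwd, , drop = FALSE]
  rbh <- rbh[rbh$q < rbh$s, , drop = FALSE]   # one row per unordered pair
  # best between-genome E per gene (over all genomes)
  bestE <- tapply(bt$evalue, qkb, min)
  # inparalog edges
  within <- !between
  wq <- qk[within]; ws <- sk[within]
  wE <- hits$evalue[within]
  thr <- pmax(ifelse(is.na(bestE[wq]), Inf, bestE[wq]),
              ifelse(is.na(bestE[ws]), Inf, bestE[ws]))
  ip <- wE <= thr
  ipq <- wq[ip]; ips <- ws[ip]
  ipair <- unique(data.frame(q = pmin(ipq, ips), s = pmax(ipq, ips),
                             stringsAsFactors = FALSE))
  edges <- rbind(rbh, ipair)
  # weights per build_homolog_graph on the full hit table
  g <- build_homolog_graph(hits, e_max = e_max, weight_cap = weight_cap)
  wkey <- paste(g$edges$key1, g$edges$key2, sep = "\r")
  ekey <- paste(edges$q, edges$s, sep = "\r")
  w <- g$edges$weight[match(ekey, wkey)]
  w[is.na(w)] <- 0
  all_keys <- unlist(lapply(proteomes, function(p)
    gp_key(p$genome_id, names(p$genes))), use.names = FALSE)
  nk <- do.call(rbind, strsplit(sort(all_keys), "\t", fixed = TRUE))
  og <- structure(list(
    nodes = data.frame(genome_id = nk[, 1], gene_id = nk[, 2],
                       key = sort(all_keys), stringsAsFactors = FALSE),
    edges = data.frame(key1 = edges$q, key2 = edges$s, weight = w,
                       stringsAsFactors = FALSE)),
    class = "gp_graph")
  mcl(og, inflation = inflation, kind = "ortholog")
}

#' Remove inparalogs from ortholog families
#'
#' Within each family, every genome contributing more than one member is
#' reduced to the member with the greatest summed bit score to the
#' family's members in other genomes (ties broken by lexicographically
#' smaller gene id). Alternatively, `drop_multicopy_families = TRUE`
#' removes every family that has a multi-copy genome outright (the other
#' reading of "inparalogs were removed").
#'
#' @param families Membership data frame from [ortholog_families()].
#' @param hits Hit data frame (for the bit scores).
#' @param drop_multicopy_families Drop whole families instead of keeping a
#'   representative gene.
#' @return Membership data frame with at most one member per genome per
#'   family.
#' @export
remove_inparalogs <- function(families, hits,
                              drop_multicopy_families = FALSE) {
  fam_split <- split(seq_len(nrow(families)), families$family_id)
  hk <- paste(gp_key(hits$query_genome, hits$query_gene),
              gp_key(hits$subject_genome, hits$subject_gene), sep = "\r")
  bs <- tapply(hits$bitscore, hk, max)
  keep <- logical(nrow(families))
  for (rows in fam_split) {
    gmem <- families$genome_id[rows]
    multi <- unique(gmem[duplicated(gmem)])
    if (!length(multi)) { keep[rows] <- TRUE; next }
    if (drop_multicopy_families) next
    keys <- gp_key(gmem, families$gene_id[rows])
    keep[rows[!(gmem %in% multi)]] <- TRUE
    for (g in multi) {
      cand <- rows[gmem == g]
      others <- keys[gmem != g]
      score <- vapply(cand, function(r) {
        k <- gp_key(families$genome_id[r], families$gene_id[r])
        v <- bs[paste(k, others, sep = "\r")]
        sum(v, na.rm = TRUE)
      }, 0)
      best <- cand[order(-score, families$gene_id[cand])][1]
      keep[best] <- TRUE
    }
  }
  families[keep, , drop = FALSE]
}
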