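# Independent oracles used across the suite. Each is a deliberately
# simple, self-contained re-derivation (quadratic-space DP, exhaustive
# enumeration, dense iteration) kept free of the package's own code
# paths.

# -- local alignment: full three-matrix affine Smith-Waterman ------------
oracle_sw <- function(a, b, submat, gap_open, gap_extend) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(E[i, j - 1] - gap_extend,
                   H[i, j - 1] - gap_open - gap_extend)
    F[i, j] <- max(F[i - 1, j] - gap_extend,
                   H[i - 1, j] - gap_open - gap_extend)
    H[i, j] <- max(0, H[i - 1, j - 1] + submat[A[i - 1], B[j - 1]],
                   E[i, j], F[i, j])
  }
  max(H)
}

# -- global affine alignment score (for the progressive aligner) ---------
oracle_global <- function(a, b, submat, gap_open, gap_extend) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  H <- matrix(-Inf, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  H[1, 1] <- 0
  for (j in 2:(n + 1)) {
    E[1, j] <- -gap_open - gap_extend * (j - 1)
    H[1, j] <- E[1, j]
  }
  for (i in 2:(m + 1)) {
    F[i, 1] <- -gap_open - gap_extend * (i - 1)
    H[i, 1] <- F[i, 1]
  }
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(E[i, j - 1] - gap_extend,
                   H[i, j - 1] - gap_open - gap_extend)
    F[i, j] <- max(F[i - 1, j] - gap_extend,
                   H[i - 1, j] - gap_open - gap_extend)
    H[i, j] <- max(H[i - 1, j - 1] + submat[A[i - 1], B[j - 1]],
                   E[i, j], F[i, j])
  }
  H[m + 1, n + 1]
}

# -- dense MCL run to convergence (no pruning, no component split) -------
oracle_mcl <- function(W, inflation = 2, max_iter = 500) {
  n <- ncol(W)
  loops <- apply(W, 2, max)
  loops[loops <= 0] <- 1
  diag(W) <- loops
  M <- sweep(W, 2, colSums(W), "/")
  for (it in seq_len(max_iter)) {
    prev <- M
    M <- M %*% M
    M <- M ^ inflation
    M <- sweep(M, 2, colSums(M), "/")
    if (max(abs(M - prev)) < 1e-12) break
  }
  adj <- (M > 1e-9) | t(M > 1e-9)
  comp <- integer(n); cur <- 0
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1; queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0)
      comp[nb] <- cur; queue <- c(queue, nb)
    }
  }
  unname(split(seq_len(n), comp))
}

# -- exhaustive parsimony: minimum changes over all internal labelings ---
oracle_parsimony <- function(tree, states) {
  # states: named character vector (tips); alphabet = observed states
  alpha <- sort(unique(states))
  n_tip <- length(tree$tip.label)
  internal <- sort(unique(tree$edge[, 1]))
  grid <- expand.grid(rep(list(alpha), length(internal)),
                      stringsAsFactors = FALSE)
  lab <- character(max(tree$edge))
  lab[seq_len(n_tip)] <- states[tree$tip.label]
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab[internal] <- unlist(grid[r, ])
    cost <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, cost)
  }
  best
}

# -- exhaustive 2-state Mk likelihood by summing over internal states ----
oracle_loglik_binary <- function(tree, states) {
  # P(same) = (1 + exp(-2t))/2 under the normalized 2-state Mk model
  ptrans <- function(same, t) if (same) (1 + exp(-2 * t)) / 2 else
    (1 - exp(-2 * t)) / 2
  n_tip <- length(tree$tip.label)
  internal <- sort(unique(tree$edge[, 1]))
  grid <- expand.grid(rep(list(c("0", "1")), length(internal)),
                      stringsAsFactors = FALSE)
  lab <- character(max(tree$edge))
  lab[seq_len(n_tip)] <- states[tree$tip.label]
  root <- n_tip + 1
  total <- 0
  for (r in seq_len(nrow(grid))) {
    lab[internal] <- unlist(grid[r, ])
    pr <- 0.5  # stationary frequency at the root
    for (k in seq_len(nrow(tree$edge))) {
      a <- lab[tree$edge[k, 1]]; b <- lab[tree$edge[k, 2]]
      pr <- pr * ptrans(a == b, tree$edge.length[k])
    }
    total <- total + pr
  }
  log(total)
}

# -- RF distance by explicit bipartition enumeration ---------------------
oracle_rf <- function(t1, t2) {
  biparts <- function(tr) {
    tr <- ape::unroot(tr)
    tips <- sort(tr$tip.label)
    n_tip <- length(tr$tip.label)
    keys <- character()
    for (nd in setdiff(unique(tr$edge[, 2]), seq_len(n_tip))) {
      cl <- tr$tip.label[unlist(phangorn::Descendants(tr, nd, "tips"))]
      if (length(cl) <= 1 || length(cl) >= n_tip - 1) next
      if (tips[1] %in% cl) cl <- setdiff(tr$tip.label, cl)
      keys <- c(keys, paste(sort(cl), collapse = "|"))
    }
    unique(keys)
  }
  b1 <- biparts(t1); b2 <- biparts(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# -- random helpers ------------------------------------------------------
random_aa <- function(n, len) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  len <- rep(len, length.out = n)
  vapply(seq_len(n), function(i)
    paste(sample(aa, len[i], replace = TRUE), collapse = ""), "")
}

# minimal annotated proteome with given per-category gene counts
toy_profile_proteome <- function(id, counts, total = sum(counts) + 5) {
  genes <- setNames(rep("MKVLA", total), sprintf("%s_g%03d", id,
                                                 seq_len(total)))
  if (sum(counts) > 0) {
    cats <- rep(names(counts), counts)
    ann <- data.frame(gene_id = names(genes)[seq_along(cats)],
                      cog_id = sprintf("COG%04d", seq_along(cats)),
                      categories = cats, stringsAsFactors = FALSE)
  } else ann <- NULL
  proteome(id, genes, annotations = ann)
}
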