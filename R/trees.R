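# Tree inference on every matrix type: corrected distances + neighbor
# joining, Fitch parsimony with NNI search, likelihood (LG + discrete
# gamma for protein, 2-state Mk for binary matrices), column-resampling
# bootstrap, and the composite multi-method support-dot annotation used
# on the published figures.

#' Distance model for pairwise distances
#'
#' `p` is the raw mismatch fraction; `felsenstein_nt` applies the
#' F81-type correction d = -B ln(1 - p/B) with B = 1 - sum(pi^2) (0.75
#' for uniform base frequencies); `pam_aa` is Kimura's PAM-approximating
#' protein distance d = -ln(1 - p - 0.2 p^2). Distances at or beyond the
#' formula's domain saturate at `d_max`.
#'
#' @param kind "p", "felsenstein_nt" or "pam_aa".
#' @param B Compositional factor for `felsenstein_nt`, in (0, 1].
#' @param d_max Saturation ceiling (default 5.0).
#' @return Object of class `gp_dist_model`.
#' @export
distance_model <- function(kind = c("p", "felsenstein_nt", "pam_aa"),
                           B = 0.75, d_max = 5.0) {
  kind <- match.arg(kind)
  stopifnot(B > 0, B <= 1, d_max > 0)
  structure(list(kind = kind, B = B, d_max = d_max),
            class = "gp_dist_model")
}

#' Pairwise distances between the rows of a matrix or alignment
#'
#' Pairs are compared over columns where both rows are non-missing
#' (`?` and `-` count as missing); a pair with no comparable columns is
#' an error naming the pair.
#'
#' @param x A [char_matrix()] or [gp_alignment()].
#' @param model A [distance_model()].
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(x, model = distance_model()) {
  mat <- if (inherits(x, "char_matrix")) x$mat else unclass(x)
  stopifnot(nrow(mat) >= 2)
  n <- nrow(mat)
  ok <- !(mat == "?" | mat == "-")
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  sat <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    if (!any(comp))
      stop("no comparable columns for pair ", rownames(mat)[i], " / ",
           rownames(mat)[j])
    p <- mean(mat[i, comp] != mat[j, comp])
    dd <- switch(model$kind,
      p = p,
      felsenstein_nt = {
        if (p >= model$B) { sat <- TRUE; model$d_max }
        else -model$B * log(1 - p / model$B)
      },
      pam_aa = {
        arg <- 1 - p - 0.2 * p^2
        if (arg <= 0) { sat <- TRUE; model$d_max } else -log(arg)
      })
    if (dd > model$d_max) { sat <- TRUE; dd <- model$d_max }
    d[i, j] <- d[j, i] <- dd
  }
  if (sat) warning("saturated distance(s) set to d_max = ", model$d_max)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration; negative branch lengths are clamped to zero
#' with a warning. For an additive input the path metric of the output
#' reproduces the input.
#'
#' @param d Symmetric distance matrix (>= 3 taxa).
#' @return Unrooted ape `phylo`.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  stopifnot(nrow(d) >= 3)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

# --- Fitch parsimony (bitmask implementation) ------------------------------

# encode a character matrix as integer bitmask matrix (rows = taxa);
# fully ambiguous symbols get the all-states mask
gp_state_masks <- function(cm) {
  if (cm$alphabet == "binary") {
    alpha <- c("0", "1"); full <- 3L
  } else {
    alpha <- gp_aa_letters[1:20]; full <- bitwShiftL(1L, 20L) - 1L
  }
  m <- match(cm$mat, alpha)
  masks <- ifelse(is.na(m), full, bitwShiftL(1L, m - 1L))
  matrix(as.integer(masks), nrow(cm$mat),
         dimnames = list(rownames(cm$mat), NULL))
}

#' Fitch parsimony score of a tree on a character matrix
#'
#' Sum over columns of the set-intersection change counts of the Fitch
#' algorithm; `?`, `-` and (for protein) `X` are treated as fully
#' ambiguous. The score is independent of rooting.
#'
#' @param tree ape `phylo` whose tips are the matrix taxa.
#' @param cm A [char_matrix()].
#' @return Integer parsimony score.
#' @export
parsimony_score <- function(tree, cm) {
  stopifnot(inherits(cm, "char_matrix"),
            setequal(tree$tip.label, cm$taxa))
  masks <- gp_state_masks(cm)
  # collapse to unique site patterns
  pat <- apply(masks, 2, paste, collapse = "\r")
  upat <- !duplicated(pat)
  wts <- as.integer(table(pat)[pat[upat]])
  masks <- masks[, upat, drop = FALSE]
  n_tip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  node_mask <- matrix(0L, max(tree$edge), ncol(masks))
  node_mask[seq_len(n_tip), ] <- masks[tree$tip.label, , drop = FALSE]
  seen <- logical(max(tree$edge))
  seen[seq_len(n_tip)] <- TRUE
  changes <- integer(ncol(masks))
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1]; ch <- post$edge[k, 2]
    if (!seen[par]) {
      node_mask[par, ] <- node_mask[ch, ]
      seen[par] <- TRUE
    } else {
      inter <- bitwAnd(node_mask[par, ], node_mask[ch, ])
      zero <- inter == 0L
      changes[zero] <- changes[zero] + 1L
      inter[zero] <- bitwOr(node_mask[par, zero], node_mask[ch, zero])
      node_mask[par, ] <- inter
    }
  }
  sum(changes * wts)
}

# LG exchangeability matrix (cached); fetched via phangorn's model
# table. Passing Q explicitly (rather than model = "LG") keeps the
# empirical +F frequencies through optim.pml.
gp_lg_Q <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      Q <- NULL
      phangorn:::getModelAA("LG", bf = FALSE, Q = TRUE)
      cache <<- Q
    }
    cache
  }
})

# pml fit under the pipeline's models (LG+F+Gamma(k) or 2-state Mk)
gp_pml <- function(tree, cm, k = 4, shape = 1) {
  dat <- gp_phyDat(cm)
  if (cm$alphabet == "binary") phangorn::pml(tree, dat)
  else phangorn::pml(tree, dat, Q = gp_lg_Q(),
                     bf = phangorn::baseFreq(dat), k = k, shape = shape)
}

# convert a char_matrix to phangorn phyDat
gp_phyDat <- function(cm) {
  if (cm$alphabet == "binary")
    phangorn::phyDat(cm$mat, type = "USER", levels = c("0", "1"),
                     ambiguity = "?")
  else
    phangorn::phyDat(cm$mat, type = "AA")
}

# default distance model for a matrix alphabet
gp_default_dist <- function(cm) {
  if (cm$alphabet == "binary") distance_model("p")
  else distance_model("pam_aa")
}

# NJ starting tree for searches
gp_start_tree <- function(cm) {
  neighbor_joining(pairwise_distances(cm, gp_default_dist(cm)))
}

#' Maximum-parsimony tree search (Fitch criterion, NNI hill climb)
#'
#' Steepest-descent nearest-neighbour interchanges from a
#' neighbour-joining starting tree, with seeded random-restart
#' perturbations; the reported score is a local minimum no worse than the
#' start score.
#'
#' @param cm A [char_matrix()].
#' @param start Starting tree (default: NJ on the default distance).
#' @param seed Integer seed for the restart perturbations.
#' @param restarts Number of perturbed restarts (default 3).
#' @return List with `tree` (ape `phylo`) and `score`.
#' @export
parsimony_search <- function(cm, start = NULL, seed = 1, restarts = 3) {
  set.seed(seed)
  dat <- gp_phyDat(cm)
  if (is.null(start)) start <- gp_start_tree(cm)
  run <- function(tr) {
    res <- phangorn::optim.parsimony(tr, dat, method = "fitch",
                                     rearrangements = "NNI", trace = 0)
    list(tree = res, score = parsimony_score(res, cm))
  }
  best <- run(start)
  for (r in seq_len(restarts)) {
    pert <- phangorn::rNNI(start, moves = 2)
    cand <- run(pert)
    if (cand$score < best$score) best <- cand
  }
  best
}

#' Log likelihood of a tree under the pipeline's substitution models
#'
#' Protein matrices: LG exchangeabilities with empirical (+F) amino-acid
#' frequencies and 4-category discrete-gamma rate heterogeneity. Binary
#' matrices: the 2-state Mk model. Likelihoods are computed by the
#' pruning algorithm (via phangorn) with `?` integrating over states;
#' the value is invariant to root placement.
#'
#' @param tree ape `phylo` with positive branch lengths.
#' @param cm A [char_matrix()].
#' @param shape Gamma shape (protein only; default 1).
#' @param k Number of gamma categories (default 4; 1 disables).
#' @return Log likelihood.
#' @export
log_likelihood <- function(tree, cm, shape = 1, k = 4) {
  stopifnot(ncol(cm$mat) > 0)
  tree$edge.length <- pmax(tree$edge.length, 1e-8)
  fit <- gp_pml(tree, cm, k = k, shape = shape)
  ll <- as.numeric(stats::logLik(fit))
  if (!is.finite(ll)) stop("non-finite log likelihood")
  ll
}

#' Maximum-likelihood tree search
#'
#' Optimizes branch lengths, gamma shape (protein) and topology (NNI)
#' from a neighbour-joining start under the models of
#' [log_likelihood()].
#'
#' @param cm A [char_matrix()].
#' @param start Starting tree (default NJ).
#' @param seed Integer seed.
#' @param k Gamma categories for protein matrices.
#' @return List with `tree`, `logLik`.
#' @export
ml_search <- function(cm, start = NULL, seed = 1, k = 4) {
  set.seed(seed)
  if (is.null(start)) start <- gp_start_tree(cm)
  start$edge.length <- pmax(start$edge.length, 1e-6)
  fit <- gp_pml(start, cm, k = k)
  fit <- phangorn::optim.pml(fit, optNni = TRUE, optEdge = TRUE,
                             optGamma = cm$alphabet != "binary" && k > 1,
                             control = phangorn::pml.control(trace = 0))
  list(tree = fit$tree, logLik = as.numeric(stats::logLik(fit)))
}

# --- bipartitions, bootstrap, support annotation ---------------------------

# canonical keys of the non-trivial bipartitions of a tree: the side not
# containing the lexicographically smallest taxon, tips sorted and joined
gp_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  anchor <- min(tips)
  n_tip <- length(tips)
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(n_tip))
  keys <- character()
  for (nd in internal) {
    clade <- tips[phangorn::Descendants(tree, nd, "tips")[[1]]]
    if (length(clade) <= 1 || length(clade) >= n_tip - 1) next
    if (anchor %in% clade) clade <- setdiff(tips, clade)
    keys <- c(keys, paste(sort(clade), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for the bipartitions of a reference tree
#'
#' Columns are resampled with replacement to the original width
#' (site-level for sequence matrices; for content matrices the columns
#' are families, so this is family-level resampling), a replicate tree is
#' inferred per resample, and the support of a bipartition is the
#' percentage of replicate trees containing it. Seeded and reproducible.
#'
#' @param cm A [char_matrix()].
#' @param method "nj", "mp" or "ml".
#' @param n_reps Replicates (the study convention is 1000; scale down
#'   for desk-size runs).
#' @param seed Integer seed.
#' @param reference Reference tree (default: the tree inferred from the
#'   unresampled matrix by the same method).
#' @param dist_model Distance model for NJ replicates (default: the
#'   matrix alphabet's default, PAM for protein and p for binary).
#' @return Named numeric vector of support percentages keyed by
#'   bipartition, with attributes `reference` (the tree) and `method`.
#' @export
bootstrap_support <- function(cm, method = c("nj", "mp", "ml"),
                              n_reps = 1000, seed = 1,
                              reference = NULL, dist_model = NULL) {
  method <- match.arg(method)
  stopifnot(n_reps >= 1)
  if (is.null(dist_model)) dist_model <- gp_default_dist(cm)
  set.seed(seed)
  infer <- function(m) {
    switch(method,
      nj = neighbor_joining(pairwise_distances(m, dist_model)),
      mp = parsimony_search(m, seed = sample.int(1e6, 1),
                            restarts = 0)$tree,
      ml = ml_search(m, seed = sample.int(1e6, 1))$tree)
  }
  if (is.null(reference)) reference <- infer(cm)
  ref_splits <- gp_splits(reference)
  counts <- setNames(numeric(length(ref_splits)), ref_splits)
  w <- ncol(cm$mat)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(w, w, replace = TRUE)
    rm <- char_matrix(cm$mat[, cols, drop = FALSE], cm$alphabet)
    rep_tree <- infer(rm)
    hit <- ref_splits %in% gp_splits(rep_tree)
    counts[hit] <- counts[hit] + 1
  }
  out <- 100 * counts / n_reps
  attr(out, "reference") <- reference
  attr(out, "method") <- method
  out
}

#' Composite multi-method support annotation (figure dot convention)
#'
#' For each internal edge of the reference tree, let c be the number of
#' methods whose bootstrap support is at least 95%. The edge is marked
#' black when all m methods reach 95%, white when at least ceiling(2m/3)
#' but not all do, otherwise hollow when at least one method reaches 75%
#' (printing, in the fixed method order, the values >= 75), and unmarked
#' otherwise. This single rule reproduces the published conventions for
#' m = 3 (white = 2), m = 4 (white = 3) and m = 6 (white = 4 or 5).
#'
#' @param reference ape `phylo`.
#' @param supports Named list (fixed method order) of support vectors as
#'   returned by [bootstrap_support()]; every method must provide a value
#'   for every internal edge of the reference.
#' @return A `supported_tree`: list with `tree`, `methods` and `table`
#'   (one row per bipartition: per-method percentages, `n_ge95`,
#'   `category`, `printed`).
#' @export
annotate_support <- function(reference, supports) {
  stopifnot(is.list(supports), length(supports) >= 1,
            !is.null(names(supports)))
  m <- length(supports)
  splits <- gp_splits(reference)
  vals <- sapply(supports, function(s) {
    if (!all(splits %in% names(s)))
      stop("a method is missing support values for some internal edge")
    unname(s[splits])
  })
  vals <- matrix(vals, nrow = length(splits),
                 dimnames = list(splits, names(supports)))
  c95 <- rowSums(vals >= 95)
  cat_of <- ifelse(c95 == m, "black",
            ifelse(c95 >= ceiling(2 * m / 3), "white",
            ifelse(rowSums(vals >= 75) > 0, "hollow", "none")))
  printed <- vapply(seq_along(splits), function(i) {
    if (cat_of[i] != "hollow") return("")
    v <- vals[i, ]
    paste(sprintf("%.0f", v[v >= 75]), collapse = "/")
  }, "")
  structure(list(tree = reference, methods = names(supports),
                 table = data.frame(split = splits, vals, n_ge95 = c95,
                                    category = unname(cat_of),
                                    printed = printed,
                                    stringsAsFactors = FALSE,
                                    check.names = FALSE)),
            class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat("<supported_tree> ", length(x$tree$tip.label), " tips, methods: ",
      paste(x$methods, collapse = ", "), "\n", sep = "")
  print(table(x$table$category))
  invisible(x)
}

#' Plot a supported tree with its composite support dots
#' @param x A `supported_tree`.
#' @param ... Passed to `ape::plot.phylo`.
#' @export
plot_supported_tree <- function(x, ...) {
  stopifnot(inherits(x, "supported_tree"))
  tr <- x$tree
  ape::plot.phylo(tr, ...)
  n_tip <- length(tr$tip.label)
  internal <- setdiff(unique(tr$edge[, 2]), seq_len(n_tip))
  for (nd in internal) {
    clade <- tr$tip.label[phangorn::Descendants(tr, nd, "tips")[[1]]]
    if (min(tr$tip.label) %in% clade)
      clade <- setdiff(tr$tip.label, clade)
    key <- paste(sort(clade), collapse = "|")
    row <- x$table[x$table$split == key, ]
    if (!nrow(row) || row$category == "none") next
    pch <- switch(row$category, black = 16, white = 21, hollow = 1)
    ape::nodelabels(node = nd, pch = pch, bg = "white")
    if (row$category == "hollow" && nzchar(row$printed))
      ape::nodelabels(row$printed, node = nd, adj = c(0.5, 1.5),
                      frame = "none", cex = 0.6)
  }
  invisible(x)
}

#' Robinson-Foulds distance between two trees
#'
#' Number of bipartitions present in exactly one of the two trees (same
#' leaf set required).
#'
#' @param tree1,tree2 ape `phylo` objects.
#' @return Integer RF distance.
#' @export
rf_distance <- function(tree1, tree2) {
  if (!setequal(tree1$tip.label, tree2$tip.label))
    stop("trees must share the same leaf set")
  as.integer(phangorn::RF.dist(ape::unroot(tree1), ape::unroot(tree2)))
}
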