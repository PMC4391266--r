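# Progressive multiple alignment of gene families (k-mer guide distances,
# NJ guide tree, profile-profile merges by global affine-gap DP) and
# conserved-block filtering of the resulting alignments.

#' Alignment container
#'
#' A character matrix of single characters, rows = taxa (rownames),
#' equal-width rows, gap symbol `-`.
#'
#' @param mat Character matrix with rownames.
#' @return Object of class `gp_alignment`.
#' @export
gp_alignment <- function(mat) {
  stopifnot(is.matrix(mat), is.character(mat), !is.null(rownames(mat)),
            ncol(mat) > 0)
  structure(mat, class = "gp_alignment")
}

#' @export
print.gp_alignment <- function(x, ...) {
  cat("<alignment> ", nrow(x), " rows x ", ncol(x), " columns\n", sep = "")
  invisible(x)
}

# k-mer set of one sequence
gp_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, 1:(n - k + 1), k:n))
}

# fraction-of-shared-kmers distance matrix
gp_kmer_dist <- function(seqs, k) {
  sets <- lapply(seqs, gp_kmers, k = k)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    denom <- min(length(sets[[i]]), length(sets[[j]]))
    sh <- if (denom > 0)
      length(intersect(sets[[i]], sets[[j]])) / denom else 0
    d[i, j] <- d[j, i] <- 1 - sh
  }
  d
}

# profile (residue frequency matrix, 22 = 20 aa + X + gap) of an alignment
gp_profile <- function(aln, alpha) {
  K <- length(alpha)
  apply(unclass(aln), 2, function(col) {
    tabulate(match(col, alpha), K) / length(col)
  })
}

# merge two alignments with the profile DP; returns the merged alignment
gp_merge_alignments <- function(A, B, smp, alpha, gap_open, gap_extend) {
  pa <- gp_profile(A, alpha); pb <- gp_profile(B, alpha)
  if (!is.matrix(pa)) pa <- matrix(pa, ncol = 1)
  if (!is.matrix(pb)) pb <- matrix(pb, ncol = 1)
  r <- cpp_profile_align(pa, pb, smp, gap_open, gap_extend)
  w <- length(r$ia)
  take <- function(M, idx) {
    out <- matrix("-", nrow(M), w, dimnames = list(rownames(M), NULL))
    out[, idx > 0] <- M[, idx[idx > 0], drop = FALSE]
    out
  }
  gp_alignment(rbind(take(unclass(A), r$ia), take(unclass(B), r$ib)))
}

#' Progressive multiple alignment of a gene family
#'
#' Guide tree: neighbor joining on 1 - shared-k-mer-fraction distances
#' (midpoint-rooted); profiles are merged bottom-up by global affine-gap
#' dynamic programming with expected sum-of-pairs substitution scores.
#' Deterministic; no iterative refinement.
#'
#' @param seqs Named character vector of amino-acid sequences (a single
#'   sequence is returned unchanged as a width-L alignment).
#' @param scheme A [scoring_scheme()].
#' @param k k-mer length for guide distances (default 3).
#' @return A [gp_alignment()]; de-gapping any row reproduces its input.
#' @export
progressive_align <- function(seqs, scheme = scoring_scheme(), k = 3) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  lapply(seqs, gp_encode_aa)  # alphabet validation
  alpha <- c(gp_aa_letters, "-")
  K <- length(alpha)
  smp <- matrix(0, K, K)
  smp[seq_len(K - 1), seq_len(K - 1)] <- scheme$submat
  one <- function(nm) gp_alignment(matrix(strsplit(seqs[[nm]], "")[[1]],
                                          nrow = 1,
                                          dimnames = list(nm, NULL)))
  n <- length(seqs)
  if (n == 1) return(one(names(seqs)))
  merge2 <- function(A, B)
    gp_merge_alignments(A, B, smp, alpha, scheme$gap_open,
                        scheme$gap_extend)
  if (n == 2) {
    res <- merge2(one(names(seqs)[1]), one(names(seqs)[2]))
  } else {
    d <- gp_kmer_dist(seqs, k)
    guide <- phangorn::midpoint(ape::nj(as.dist(d)))
    align_node <- function(node) {
      if (node <= n) return(one(guide$tip.label[node]))
      kids <- guide$edge[guide$edge[, 1] == node, 2]
      Reduce(merge2, lapply(kids, align_node))
    }
    res <- align_node(length(guide$tip.label) + 1L)
  }
  gp_alignment(unclass(res)[names(seqs), , drop = FALSE])
}

#' Block-filter parameters (simplified GBLOCKS)
#'
#' Defaults follow the published GBLOCKS defaults: a column is conserved
#' when strictly more than half the rows share a residue and highly
#' conserved at 85%; nonconserved stretches longer than 8 columns are
#' removed, blocks are trimmed to highly conserved end columns, and
#' blocks shorter than 10 columns are dropped. Gap-containing columns are
#' removed unless `allow_gap_columns`.
#'
#' @param min_conserved_fraction,high_conserved_fraction Fractions between
#'   0.5 and 1.
#' @param max_nonconserved_run,min_block_len Positive lengths.
#' @param allow_gap_columns Keep columns containing gaps.
#' @return List of class `gp_block_params`.
#' @export
block_filter_params <- function(min_conserved_fraction = 0.5,
                                high_conserved_fraction = 0.85,
                                max_nonconserved_run = 8,
                                min_block_len = 10,
                                allow_gap_columns = FALSE) {
  stopifnot(min_conserved_fraction >= 0.5, min_conserved_fraction <= 1,
            high_conserved_fraction >= 0.5, high_conserved_fraction <= 1,
            max_nonconserved_run >= 0, min_block_len >= 1)
  structure(list(min_conserved_fraction = min_conserved_fraction,
                 high_conserved_fraction = high_conserved_fraction,
                 max_nonconserved_run = max_nonconserved_run,
                 min_block_len = min_block_len,
                 allow_gap_columns = allow_gap_columns),
            class = "gp_block_params")
}

#' Filter an alignment to its conserved blocks
#'
#' Columns are classified by the majority-residue count: highly
#' conserved, conserved, or nonconserved; gap-containing columns are
#' removed when `allow_gap_columns` is FALSE. Maximal runs of
#' nonconserved/removed columns longer than `max_nonconserved_run` are
#' removed entirely; remaining contiguous stretches are trimmed inward to
#' highly conserved end columns and dropped when shorter than
#' `min_block_len`. When everything is filtered, an empty result is
#' returned with a warning (not an error).
#'
#' @param aln A [gp_alignment()].
#' @param params A [block_filter_params()].
#' @return List with `alignment` (filtered [gp_alignment()] or NULL when
#'   empty) and `kept` (strictly increasing column indices into the
#'   input).
#' @export
filter_blocks <- function(aln, params = block_filter_params()) {
  stopifnot(inherits(aln, "gp_alignment"))
  mat <- unclass(aln)
  n <- nrow(mat); w <- ncol(mat)
  cons_thr <- floor(n * params$min_conserved_fraction) + 1
  high_thr <- ceiling(n * params$high_conserved_fraction)
  status <- character(w)
  for (j in seq_len(w)) {
    col <- mat[, j]
    if (!params$allow_gap_columns && any(col == "-")) {
      status[j] <- "gap"; next
    }
    mx <- max(tabulate(match(col[col != "-"], gp_aa_letters),
                       length(gp_aa_letters)), 0)
    status[j] <- if (mx >= high_thr) "high"
      else if (mx >= cons_thr) "cons" else "noncons"
  }
  kept <- status != "gap"
  bad <- status %in% c("gap", "noncons")
  r <- rle(bad)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (i in which(r$values & r$lengths > params$max_nonconserved_run))
    kept[starts[i]:ends[i]] <- FALSE
  # blocks: contiguous kept stretches; trim to highly conserved ends
  r2 <- rle(kept)
  e2 <- cumsum(r2$lengths); s2 <- e2 - r2$lengths + 1
  for (i in which(r2$values)) {
    idx <- s2[i]:e2[i]
    hi <- idx[status[idx] == "high"]
    if (!length(hi)) { kept[idx] <- FALSE; next }
    kept[idx[idx < min(hi) | idx > max(hi)]] <- FALSE
    if (max(hi) - min(hi) + 1 < params$min_block_len)
      kept[idx] <- FALSE
  }
  keep_idx <- which(kept)
  if (!length(keep_idx)) {
    warning("block filter removed every column")
    return(list(alignment = NULL, kept = integer()))
  }
  list(alignment = gp_alignment(mat[, keep_idx, drop = FALSE]),
       kept = keep_idx)
}

#' Minimum pairwise percent identity within an alignment
#'
#' For each pair of rows, identity is the fraction of columns where both
#' rows are non-gap and identical, over columns where both are non-gap,
#' times 100. Pairs with no comparable columns are excluded with a
#' warning; if all pairs are excluded this is an error. Used for the
#' rank heuristic that members of one order share roughly >= 85% 16S
#' identity.
#'
#' @param aln A [gp_alignment()].
#' @param taxa Subset of row names (default: all rows).
#' @return Minimum percent identity over pairs.
#' @export
min_pairwise_identity <- function(aln, taxa = rownames(aln)) {
  stopifnot(inherits(aln, "gp_alignment"), length(taxa) >= 2,
            all(taxa %in% rownames(aln)))
  mat <- unclass(aln)[taxa, , drop = FALSE]
  best <- Inf; any_ok <- FALSE
  for (i in seq_len(length(taxa) - 1)) for (j in (i + 1):length(taxa)) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok)) {
      warning("no comparable columns for pair ", taxa[i], " / ", taxa[j])
      next
    }
    any_ok <- TRUE
    best <- min(best, 100 * mean(mat[i, ok] == mat[j, ok]))
  }
  if (!any_ok) stop("no pair has comparable columns")
  best
}
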