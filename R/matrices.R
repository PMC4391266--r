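# The four character matrices: supermatrix (>= 4 sequences per included
# alignment), information-filtered supermatrix (quartet-resolution score,
# organism deletion disallowed), core-genes matrix (families complete and
# single-copy in every genome), and binary gene-/ortholog-content
# matrices.

#' Character matrix container
#'
#' Taxa x characters with a partition map. Protein matrices use `?` for a
#' taxon absent from a partition (distinct from the indel gap `-`);
#' binary matrices contain only 0/1.
#'
#' @param mat Character matrix (rows = taxa, rownames set).
#' @param alphabet "protein" or "binary".
#' @param partitions Data frame with columns `partition_id`, `family_id`,
#'   `start`, `end` (1-based inclusive, tiling the width). Default: one
#'   partition spanning the matrix.
#' @return Object of class `char_matrix` with fields `taxa`, `alphabet`,
#'   `mat`, `partitions`, `missing`.
#' @export
char_matrix <- function(mat, alphabet = c("protein", "binary"),
                        partitions = NULL) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), ncol(mat) > 0)
  if (is.null(partitions))
    partitions <- data.frame(partition_id = "p1", family_id = NA_character_,
                             start = 1L, end = ncol(mat),
                             stringsAsFactors = FALSE)
  if (is.null(partitions$family_id))
    partitions$family_id <- partitions$partition_id
  stopifnot(partitions$start[1] == 1,
            all(partitions$end >= partitions$start),
            partitions$end[nrow(partitions)] == ncol(mat))
  if (nrow(partitions) > 1)
    stopifnot(all(partitions$start[-1] ==
                    partitions$end[-nrow(partitions)] + 1))
  if (alphabet == "binary" && !all(mat %in% c("0", "1")))
    stop("binary matrix entries must be 0/1 with no missing data")
  structure(list(taxa = rownames(mat), alphabet = alphabet, mat = mat,
                 partitions = partitions,
                 missing = if (alphabet == "protein") "?" else NA),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("<char_matrix> ", x$alphabet, ": ", length(x$taxa), " taxa x ",
      ncol(x$mat), " characters in ", nrow(x$partitions),
      " partition(s)\n", sep = "")
  invisible(x)
}

#' Extract one partition's columns
#' @param cm A [char_matrix()].
#' @param partition_id Partition to extract.
#' @return Character submatrix.
#' @export
partition_columns <- function(cm, partition_id) {
  p <- cm$partitions[cm$partitions$partition_id == partition_id, ]
  stopifnot(nrow(p) == 1)
  cm$mat[, p$start:p$end, drop = FALSE]
}

#' Concatenate filtered alignments into a supermatrix
#'
#' Alignments with at least `min_seqs` rows are concatenated in
#' lexicographic family-id order; the taxon set is the union over
#' included alignments and a taxon absent from an alignment is filled
#' with `?` across that partition. Each alignment must hold at most one
#' sequence per genome (guaranteed after inparalog removal) -- a
#' violation is a hard error.
#'
#' @param alignments Named list of [gp_alignment()] objects; names are
#'   family ids, rownames of each alignment are genome ids.
#' @param min_seqs Minimum rows for inclusion (default 4).
#' @return A protein [char_matrix()] with one partition per included
#'   family.
#' @export
build_supermatrix <- function(alignments, min_seqs = 4) {
  stopifnot(length(alignments) > 0, !is.null(names(alignments)))
  for (nm in names(alignments)) {
    rn <- rownames(alignments[[nm]])
    if (anyDuplicated(rn))
      stop("alignment ", nm, " holds more than one sequence for genome ",
           rn[duplicated(rn)][1], " (inparalog removal missed)")
  }
  inc <- names(alignments)[vapply(alignments, nrow, 0L) >= min_seqs]
  inc <- sort(inc)
  if (!length(inc)) stop("no alignment has at least ", min_seqs, " rows")
  taxa <- sort(unique(unlist(lapply(alignments[inc], rownames))))
  widths <- vapply(alignments[inc], ncol, 0L)
  ends <- cumsum(widths); starts <- ends - widths + 1L
  mat <- matrix("?", length(taxa), sum(widths),
                dimnames = list(taxa, NULL))
  for (i in seq_along(inc)) {
    a <- unclass(alignments[[inc[i]]])
    mat[rownames(a), starts[i]:ends[i]] <- a
  }
  char_matrix(mat, "protein",
              data.frame(partition_id = inc, family_id = inc,
                         start = starts, end = ends,
                         stringsAsFactors = FALSE))
}

# parsimony score of one site pattern (4 states a,b,c,d as characters,
# '?'/'-' fully ambiguous) on quartet topology ((1,2),(3,4))
gp_quartet_cost <- function(s, pair) {
  amb <- s %in% c("?", "-")
  sets <- ifelse(amb, NA, s)      # NA = full set
  fitch2 <- function(x, y) {
    if (is.na(x)) return(list(set = y, cost = 0L))
    if (is.na(y)) return(list(set = x, cost = 0L))
    if (x == y) list(set = x, cost = 0L) else
      list(set = paste0(x, y), cost = 1L)   # union as multi-char string
  }
  i <- pair; o <- setdiff(1:4, pair)
  L <- fitch2(sets[i[1]], sets[i[2]])
  R <- fitch2(sets[o[1]], sets[o[2]])
  inter <- if (is.na(L$set) || is.na(R$set)) TRUE else
    any(strsplit(L$set, "")[[1]] %in% strsplit(R$set, "")[[1]])
  L$cost + R$cost + if (inter) 0L else 1L
}

#' Drop relatively uninformative partitions (information filter)
#'
#' A simplified stand-in for tree-likeness-based gene filtering: per
#' partition the information score is the fraction of sampled 4-taxon
#' subsets (drawn among taxa with data in that partition) for which
#' exactly one of the three quartet topologies has strictly minimal
#' parsimony score on the partition's columns. Partitions scoring below
#' `min_info` are dropped -- except that a partition is retained when its
#' removal would leave some taxon with zero non-missing columns (organism
#' deletion is disallowed). Partitions with fewer than 4 covered taxa
#' score 0 by definition. Deterministic given the seed.
#'
#' @param cm Supermatrix ([char_matrix()], >= 4 taxa).
#' @param quartets_per_partition Sampled quartets per partition.
#' @param min_info Score threshold between 0 and 1.
#' @param seed Integer seed.
#' @return Filtered [char_matrix()]; attribute `info_scores` holds the
#'   per-partition scores.
#' @export
reduce_matrix <- function(cm, quartets_per_partition = 100,
                          min_info = 0.25, seed = 1) {
  stopifnot(inherits(cm, "char_matrix"), length(cm$taxa) >= 4)
  set.seed(seed)
  np <- nrow(cm$partitions)
  scores <- setNames(numeric(np), cm$partitions$partition_id)
  covered <- matrix(FALSE, length(cm$taxa), np,
                    dimnames = list(cm$taxa, cm$partitions$partition_id))
  for (p in seq_len(np)) {
    sub <- cm$mat[, cm$partitions$start[p]:cm$partitions$end[p],
                  drop = FALSE]
    has <- rowSums(sub != "?") > 0
    covered[, p] <- has
    idx <- which(has)
    if (length(idx) < 4) { scores[p] <- 0; next }
    resolved <- 0L
    for (q in seq_len(quartets_per_partition)) {
      four <- sample(idx, 4)
      pat <- sub[four, , drop = FALSE]
      pat <- pat[, colSums(pat == "?") == 0, drop = FALSE]
      if (ncol(pat) == 0) next
      upat <- table(apply(pat, 2, paste, collapse = ""))
      costs <- vapply(list(c(1, 2), c(1, 3), c(1, 4)), function(pr) {
        sum(vapply(names(upat), function(s)
          gp_quartet_cost(strsplit(s, "")[[1]], pr), 0L) * as.integer(upat))
      }, 0)
      if (sum(costs == min(costs)) == 1) resolved <- resolved + 1L
    }
    scores[p] <- resolved / quartets_per_partition
  }
  drop <- scores < min_info
  # no-organism-deletion rule: keep partitions whose removal would erase
  # a taxon; process candidates in increasing score order
  for (p in order(scores)) {
    if (!drop[p]) next
    keep_others <- !drop; keep_others[p] <- FALSE
    if (any(rowSums(covered[, keep_others, drop = FALSE]) == 0 &
              covered[, p])) {
      drop[p] <- FALSE
      gp_log("partition ", cm$partitions$partition_id[p],
             " retained despite score ", signif(scores[p], 3),
             ": removal would delete an organism")
    }
  }
  if (all(drop)) {
    drop[which.max(scores)] <- FALSE
    gp_log("all partitions scored below min_info; keeping the best one")
  }
  keep <- which(!drop)
  cols <- unlist(lapply(keep, function(p)
    cm$partitions$start[p]:cm$partitions$end[p]))
  widths <- cm$partitions$end[keep] - cm$partitions$start[keep] + 1L
  ends <- cumsum(widths); starts <- ends - widths + 1L
  out <- char_matrix(cm$mat[, cols, drop = FALSE], cm$alphabet,
                     data.frame(partition_id = cm$partitions$partition_id[keep],
                                family_id = cm$partitions$family_id[keep],
                                start = starts, end = ends,
                                stringsAsFactors = FALSE))
  attr(out, "info_scores") <- scores
  out
}

#' Concatenate the complete single-copy families into a core-genes matrix
#'
#' Includes exactly those alignments whose rows are one sequence per
#' genome for every genome in `genomes`; the result has no missing
#' symbols. An empty matrix (with a warning) results when no family
#' qualifies.
#'
#' @param alignments Named list of [gp_alignment()] (names = family ids,
#'   rows = genome ids).
#' @param genomes Character vector of all pipeline genome ids.
#' @return A protein [char_matrix()] or NULL when no family qualifies.
#' @export
build_core_matrix <- function(alignments, genomes) {
  ok <- vapply(alignments, function(a) {
    rn <- rownames(a)
    length(rn) == length(genomes) && setequal(rn, genomes) &&
      !anyDuplicated(rn)
  }, TRUE)
  inc <- sort(names(alignments)[ok])
  if (!length(inc)) {
    warning("no alignment is complete and single-copy for every genome")
    return(NULL)
  }
  taxa <- sort(unname(genomes))
  widths <- vapply(alignments[inc], ncol, 0L)
  ends <- cumsum(widths); starts <- ends - widths + 1L
  mat <- matrix(NA_character_, length(taxa), sum(widths),
                dimnames = list(taxa, NULL))
  for (i in seq_along(inc)) {
    a <- unclass(alignments[[inc[i]]])
    mat[rownames(a), starts[i]:ends[i]] <- a
  }
  char_matrix(mat, "protein",
              data.frame(partition_id = inc, family_id = inc,
                         start = starts, end = ends,
                         stringsAsFactors = FALSE))
}

#' Binary gene-/ortholog-content matrix from family membership
#'
#' One column per family in lexicographic family-id order; entry 1 iff
#' the genome has at least one member (presence, not count). All-0/all-1
#' columns are retained and flagged in the `constant` attribute.
#'
#' @param families Membership data frame (family_id, genome_id, gene_id).
#' @param genomes All genome ids (rows of the matrix).
#' @return A binary [char_matrix()] whose partitions are the families.
#' @export
build_content_matrix <- function(families, genomes) {
  stopifnot(nrow(families) > 0)
  fams <- sort(unique(families$family_id))
  taxa <- sort(unname(genomes))
  mat <- matrix("0", length(taxa), length(fams),
                dimnames = list(taxa, NULL))
  mat[cbind(match(families$genome_id, taxa),
            match(families$family_id, fams))] <- "1"
  cm <- char_matrix(mat, "binary",
                    data.frame(partition_id = fams, family_id = fams,
                               start = seq_along(fams),
                               end = seq_along(fams),
                               stringsAsFactors = FALSE))
  ones <- colSums(mat == "1")
  attr(cm, "constant") <- fams[ones == 0 | ones == length(taxa)]
  cm
}
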