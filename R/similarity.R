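# All-vs-all protein similarity: exact Smith-Waterman local alignment with
# affine gaps, Karlin-Altschul E-values, and the hit table the clustering
# stages consume. Stands in for an external BLAST search so the pipeline
# runs self-contained; precomputed BLAST tables can be ingested instead
# via read_similarity_table().

#' Optimal local alignment score and identity of two protein sequences
#'
#' Exact Smith-Waterman with affine gaps (no heuristics). Symmetric in its
#' arguments.
#'
#' @param a,b Amino-acid strings over the 20 standard residues plus X.
#' @param scheme A [scoring_scheme()].
#' @return List with `score` (raw optimal score), `pident` (percent
#'   identical positions over aligned columns, gaps included in the
#'   denominator) and `align_len` (aligned columns). An empty optimal
#'   alignment (score 0) has `pident = 0`, `align_len = 0`.
#' @export
local_align_score <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  r <- cpp_sw_align(gp_encode_aa(a), gp_encode_aa(b), scheme$submat,
                    scheme$gap_open, scheme$gap_extend)
  list(score = r$score,
       pident = if (r$columns > 0) 100 * r$identical / r$columns else 0,
       align_len = r$columns)
}

#' Karlin-Altschul E-value of a raw local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`; monotone decreasing in the score
#' and linear in both sequence lengths.
#'
#' @param score Raw alignment score.
#' @param m,n Query and subject (database) lengths.
#' @param scheme A [scoring_scheme()] supplying lambda and K.
#' @return E-value.
#' @export
evalue <- function(score, m, n, scheme = scoring_scheme()) {
  stopifnot(m > 0, n > 0)
  scheme$karlin_k * m * n * exp(-scheme$karlin_lambda * score)
}

# bit score from a raw score (standard Karlin-Altschul conversion)
gp_bitscore <- function(score, scheme) {
  (scheme$karlin_lambda * score - log(scheme$karlin_k)) / log(2)
}

#' All-vs-all similarity search over a set of proteomes
#'
#' Aligns every unordered gene pair (within- and between-genome; self
#' pairs excluded) with exact Smith-Waterman and reports every ordered
#' pair whose E-value is at most `e_max`, in lexicographic order of
#' (query genome, query gene, subject genome, subject gene). Within-genome
#' hits are retained deliberately: they drive inparalog detection.
#'
#' @param proteomes List of [proteome()] objects (at least 2).
#' @param scheme A [scoring_scheme()].
#' @param e_max E-value threshold (default 1e-5).
#' @return Hit data frame as in [read_similarity_table()], plus a
#'   `raw_score` column.
#' @export
all_vs_all <- function(proteomes, scheme = scoring_scheme(),
                       e_max = 1e-5) {
  stopifnot(length(proteomes) >= 2)
  genome <- rep(vapply(proteomes, `[[`, "", "genome_id"),
                vapply(proteomes, function(p) length(p$genes), 0L))
  gene <- unlist(lapply(proteomes, function(p) names(p$genes)),
                 use.names = FALSE)
  seqs <- unlist(lapply(proteomes, `[[`, "genes"), use.names = FALSE)
  n <- length(seqs)
  if (e_max <= 0 || n < 2) return(gp_empty_hits())
  enc <- lapply(seqs, gp_encode_aa)
  lens <- nchar(seqs)
  scores <- cpp_sw_all_pairs(enc, scheme$submat, scheme$gap_open,
                             scheme$gap_extend)
  # pair order emitted by cpp_sw_all_pairs: (1,2),(1,3),...,(1,n),(2,3),...
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  ev <- evalue(scores, lens[i], lens[j], scheme)
  keep <- which(ev <= e_max)
  if (!length(keep)) return(gp_empty_hits())
  pid <- alen <- numeric(length(keep))
  for (k in seq_along(keep)) {
    p <- keep[k]
    r <- cpp_sw_align(enc[[i[p]]], enc[[j[p]]], scheme$submat,
                      scheme$gap_open, scheme$gap_extend)
    pid[k] <- if (r$columns > 0) 100 * r$identical / r$columns else 0
    alen[k] <- r$columns
  }
  one <- data.frame(query_genome = genome[i[keep]],
                    query_gene = gene[i[keep]],
                    subject_genome = genome[j[keep]],
                    subject_gene = gene[j[keep]],
                    pident = pid, align_len = alen, evalue = ev[keep],
                    bitscore = gp_bitscore(scores[keep], scheme),
                    raw_score = scores[keep], stringsAsFactors = FALSE)
  rev <- one
  rev[c("query_genome", "query_gene")] <-
    one[c("subject_genome", "subject_gene")]
  rev[c("subject_genome", "subject_gene")] <-
    one[c("query_genome", "query_gene")]
  hits <- rbind(one, rev)
  hits[order(hits$query_genome, hits$query_gene, hits$subject_genome,
             hits$subject_gene), , drop = FALSE]
}

gp_empty_hits <- function() {
  data.frame(query_genome = character(), query_gene = character(),
             subject_genome = character(), subject_gene = character(),
             pident = numeric(), align_len = numeric(),
             evalue = numeric(), bitscore = numeric(),
             raw_score = numeric(), stringsAsFactors = FALSE)
}
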