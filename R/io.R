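# Readers/writers for the external representations the pipeline touches:
# 12-column similarity tables (BLAST outfmt-6 dialect), relaxed PHYLIP,
# partition files, aligned FASTA, Newick, content-matrix and membership
# TSVs, and the structured run configuration.

#' Read an all-vs-all similarity table (BLAST outfmt-6 dialect)
#'
#' Tab-separated, at least 12 columns per row: qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' Extra columns are ignored; row order is preserved.
#'
#' @param path Tabular file.
#' @param gene2genome Named character vector mapping gene id to genome id;
#'   every gene id in the table must be resolvable.
#' @return Data frame of hits with columns `query_genome`, `query_gene`,
#'   `subject_genome`, `subject_gene`, `pident`, `align_len`, `evalue`,
#'   `bitscore`.
#' @export
read_similarity_table <- function(path, gene2genome) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12))
    stop("similarity table format error at line ", which(nf < 12)[1],
         ": expected >= 12 tab-separated columns, got ", nf[nf < 12][1])
  grab <- function(i) vapply(parts, `[[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(grab(i)))
    if (anyNA(v))
      stop("unparseable ", what, " at line ", which(is.na(v))[1])
    v
  }
  qg <- grab(1); sg <- grab(2)
  unknown <- setdiff(unique(c(qg, sg)), names(gene2genome))
  if (length(unknown))
    stop("gene id(s) not in gene-to-genome map: ",
         paste(head(unknown, 5), collapse = ", "))
  data.frame(query_genome = unname(gene2genome[qg]), query_gene = qg,
             subject_genome = unname(gene2genome[sg]), subject_gene = sg,
             pident = num(3, "pident"), align_len = num(4, "length"),
             evalue = num(11, "evalue"), bitscore = num(12, "bitscore"),
             stringsAsFactors = FALSE)
}

#' Write hits in the 12-column tabular similarity format
#'
#' Columns the pipeline does not track (mismatch, gapopen, coordinates)
#' are written as 0 so built-in and external search output are
#' interchangeable on re-ingestion.
#'
#' @param hits Data frame as returned by [all_vs_all()] or
#'   [read_similarity_table()].
#' @param path Output file.
#' @export
write_similarity_table <- function(hits, path) {
  out <- data.frame(hits$query_gene, hits$subject_gene,
                    sprintf("%.2f", hits$pident), hits$align_len,
                    0L, 0L, 0L, 0L, 0L, 0L,
                    format(hits$evalue, digits = 3, scientific = TRUE),
                    format(hits$bitscore, digits = 4))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a character matrix in relaxed PHYLIP format
#' @param cm A [char_matrix()].
#' @param path Output file.
#' @export
write_phylip_relaxed <- function(cm, path) {
  stopifnot(inherits(cm, "char_matrix"))
  if (any(grepl("\\s", cm$taxa))) stop("taxon names contain whitespace")
  rows <- apply(cm$mat, 1, paste, collapse = "")
  writeLines(c(paste(length(cm$taxa), ncol(cm$mat)),
               paste(format(cm$taxa, width = max(nchar(cm$taxa)) + 2),
                     rows)), path)
  invisible(path)
}

#' Read a relaxed PHYLIP file as a character matrix
#' @param path PHYLIP file.
#' @param alphabet "protein" or "binary".
#' @return A [char_matrix()] (single partition spanning the full width).
#' @export
read_phylip_relaxed <- function(path, alphabet = "protein") {
  lines <- readLines(path)
  hd <- scan(text = lines[1], quiet = TRUE)
  body <- lines[-1][nzchar(lines[-1])]
  toks <- regmatches(body, regexpr("^\\S+", body))
  seqs <- gsub("\\s", "", sub("^\\S+\\s+", "", body))
  if (length(toks) != hd[1] || any(nchar(seqs) != hd[2]))
    stop("malformed PHYLIP file: ", path)
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- toks
  char_matrix(mat, alphabet = alphabet)
}

#' Write the partition table of a character matrix (RAxML-style)
#'
#' One line per partition, 1-based inclusive coordinates:
#' `WAG, <partition_id> = <start>-<end>` for protein matrices and
#' `BIN, ... ` for binary ones.
#'
#' @param cm A [char_matrix()].
#' @param path Output file.
#' @export
write_partitions <- function(cm, path) {
  stopifnot(inherits(cm, "char_matrix"))
  tag <- if (cm$alphabet == "protein") "WAG" else "BIN"
  writeLines(sprintf("%s, %s = %d-%d", tag, cm$partitions$partition_id,
                     cm$partitions$start, cm$partitions$end), path)
  invisible(path)
}

#' Read a partition file written by [write_partitions()]
#' @param path Partition file.
#' @return Data frame with columns `partition_id`, `start`, `end`.
#' @export
read_partitions <- function(path) {
  lines <- readLines(path)
  m <- regmatches(lines,
                  regexec("^\\S+, (\\S+) = (\\d+)-(\\d+)$", lines))
  if (any(lengths(m) != 4)) stop("malformed partition file: ", path)
  data.frame(partition_id = vapply(m, `[[`, "", 2),
             start = as.integer(vapply(m, `[[`, "", 3)),
             end = as.integer(vapply(m, `[[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Read / write Newick trees
#'
#' Thin wrappers around ape preserving numeric internal-node (support)
#' labels.
#'
#' @param path Newick file.
#' @return `read_newick()` returns an ape `phylo`.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree An ape `phylo` (internal `node.label` written as support).
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write an alignment as aligned FASTA
#' @param aln A `gp_alignment` (character matrix, rows = taxa).
#' @param path Output file.
#' @export
write_alignment_fasta <- function(aln, path) {
  rows <- apply(unclass(aln), 1, paste, collapse = "")
  writeLines(paste0(">", rownames(aln), "\n", rows), path)
  invisible(path)
}

#' Read aligned FASTA as a gp_alignment
#' @param path Aligned FASTA file.
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  if (length(unique(nchar(seqs))) != 1)
    stop("rows of an alignment must have equal width: ", path)
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- sub("\\s.*$", "", names(ss))
  gp_alignment(mat)
}

#' Write a binary content matrix as TSV
#'
#' Header row of family ids; one row per genome, 0/1 entries.
#' @param cm A binary [char_matrix()].
#' @param path Output file.
#' @export
write_content_tsv <- function(cm, path) {
  stopifnot(inherits(cm, "char_matrix"), cm$alphabet == "binary")
  d <- as.data.frame(cm$mat, stringsAsFactors = FALSE)
  names(d) <- cm$partitions$family_id
  d <- cbind(genome_id = cm$taxa, d)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary content matrix written by [write_content_tsv()]
#' @param path TSV file.
#' @export
read_content_tsv <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                  colClasses = "character")
  mat <- as.matrix(d[, -1, drop = FALSE])
  rownames(mat) <- d$genome_id
  fam <- colnames(mat)
  colnames(mat) <- NULL
  char_matrix(mat, alphabet = "binary",
              partitions = data.frame(partition_id = fam, family_id = fam,
                                      start = seq_along(fam),
                                      end = seq_along(fam),
                                      stringsAsFactors = FALSE))
}

#' Write family membership as TSV (family_id, genome_id, gene_id)
#' @param families Membership data frame from [mcl()] /
#'   [ortholog_families()].
#' @param path Output file.
#' @export
write_membership_tsv <- function(families, path) {
  write.table(families[, c("family_id", "genome_id", "gene_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a family membership TSV
#' @param path TSV file.
#' @param kind "homolog" or "ortholog" label to attach.
#' @export
read_membership_tsv <- function(path, kind = "homolog") {
  d <- read.table(path, sep = "\t", header = TRUE,
                  colClasses = "character")
  d$kind <- kind
  d
}
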