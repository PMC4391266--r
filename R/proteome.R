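# The proteome container: one genome's identifier, its protein sequences
# and (optionally) per-gene COG annotations.

#' Construct a proteome
#'
#' @param genome_id Short unique genome label (no whitespace).
#' @param genes Named character vector of amino-acid sequences; names are
#'   gene identifiers, unique within the genome.
#' @param annotations Optional data frame with columns `gene_id`, `cog_id`
#'   (e.g. "COG2124") and `categories` (one or more single-letter COG
#'   functional category codes, e.g. "I" or "IQ").
#' @return An object of class `proteome`.
#' @export
proteome <- function(genome_id, genes, annotations = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1,
            !grepl("\\s", genome_id))
  if (is.null(names(genes)) || anyNA(names(genes)) || any(names(genes) == ""))
    stop("all genes must be named")
  dup <- names(genes)[duplicated(names(genes))]
  if (length(dup))
    stop("duplicate gene id(s) in genome ", genome_id, ": ",
         paste(unique(dup), collapse = ", "))
  if (any(nchar(genes) == 0))
    stop("empty sequence(s) in genome ", genome_id, ": ",
         paste(names(genes)[nchar(genes) == 0], collapse = ", "))
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    stopifnot(all(c("gene_id", "cog_id", "categories") %in%
                    names(annotations)))
    missing <- setdiff(annotations$gene_id, names(genes))
    if (length(missing))
      stop("annotated gene id(s) not present in genome ", genome_id, ": ",
           paste(missing, collapse = ", "))
    bad <- setdiff(unlist(strsplit(annotations$categories, "")),
                   cog_categories())
    if (length(bad))
      stop("unknown COG category letter(s): ", paste(bad, collapse = ", "))
  }
  structure(list(genome_id = genome_id, genes = genes,
                 annotations = annotations), class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat("<proteome> ", x$genome_id, ": ", length(x$genes), " genes",
      if (!is.null(x$annotations))
        paste0(", ", nrow(x$annotations), " annotated"),
      "\n", sep = "")
  invisible(x)
}

#' Read a protein FASTA file as a proteome
#'
#' The header token before the first whitespace becomes the gene id,
#' sequences are uppercased and a terminal `*` (stop) is stripped; an
#' internal `*` is an error.
#'
#' @param path FASTA file.
#' @param genome_id Genome label; defaults to the file name without
#'   extension.
#' @return A [proteome()].
#' @export
read_proteome_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  if (any(ids == "")) stop("empty FASTA header in ", path)
  seqs <- sub("\\*$", "", seqs)
  if (any(grepl("*", seqs, fixed = TRUE)))
    stop("internal '*' in sequence(s): ",
         paste(ids[grepl("*", seqs, fixed = TRUE)], collapse = ", "))
  names(seqs) <- ids
  proteome(genome_id, seqs)
}

#' Write a proteome to a protein FASTA file
#' @param x A [proteome()].
#' @param path Output file.
#' @export
write_proteome_fasta <- function(x, path) {
  stopifnot(inherits(x, "proteome"))
  writeLines(paste0(">", names(x$genes), "\n", unname(x$genes)), path)
  invisible(path)
}

#' Read per-gene COG annotations from a TSV file
#'
#' Expected columns (no header): gene_id, cog_id, category letter(s).
#'
#' @param path TSV file.
#' @return Data frame with columns `gene_id`, `cog_id`, `categories`.
#' @export
read_cog_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("gene_id", "cog_id", "categories"),
                  colClasses = "character", quote = "")
  bad <- setdiff(unlist(strsplit(d$categories, "")), cog_categories())
  if (length(bad))
    stop("unknown COG category letter(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  d
}

#' Write per-gene COG annotations to TSV
#' @param annotations Data frame as in [read_cog_annotations()].
#' @param path Output file.
#' @export
write_cog_annotations <- function(annotations, path) {
  write.table(annotations[, c("gene_id", "cog_id", "categories")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# internal key joining genome and gene id (tab never occurs in ids)
gp_key <- function(genome, gene) paste(genome, gene, sep = "\t")
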