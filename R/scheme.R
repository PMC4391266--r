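# Amino-acid alphabet and the scoring scheme used by the built-in aligner.

# 20 standard residues plus X (unknown); the only letters the pipeline
# accepts in protein sequences.
gp_aa_letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Scoring scheme for the built-in pairwise aligner
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul statistical parameters used to convert raw
#' Smith-Waterman scores into E-values. Defaults are the published gapped
#' BLOSUM62 settings (open 11 / extend 1, lambda = 0.267, K = 0.041). A gap
#' of length k costs `gap_open + k * gap_extend`.
#'
#' @param matrix Substitution matrix name (only "BLOSUM62" is bundled) or a
#'   symmetric numeric matrix with the 20 amino-acid letters plus `X` in
#'   its dimnames.
#' @param gap_open,gap_extend Positive gap penalties.
#' @param karlin_lambda,karlin_k Positive Karlin-Altschul parameters.
#' @return An object of class `gp_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, karlin_lambda = 0.267,
                           karlin_k = 0.041) {
  if (is.character(matrix)) {
    stopifnot(matrix == "BLOSUM62")
    sub <- gp_blosum62()
  } else {
    sub <- as.matrix(matrix)
    if (!all(gp_aa_letters %in% rownames(sub)))
      stop("substitution matrix must cover the 20 amino acids plus X")
    sub <- sub[gp_aa_letters, gp_aa_letters]
  }
  if (!isTRUE(all.equal(sub, t(sub))))
    stop("substitution matrix must be symmetric")
  stopifnot(gap_open > 0, gap_extend > 0, karlin_lambda > 0, karlin_k > 0)
  structure(list(submat = sub, gap_open = gap_open, gap_extend = gap_extend,
                 karlin_lambda = karlin_lambda, karlin_k = karlin_k),
            class = "gp_scheme")
}

# BLOSUM62 restricted to the pipeline alphabet, from Biostrings.
gp_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[gp_aa_letters, gp_aa_letters]
    }
    cache
  }
})

# Encode an amino-acid string as 0-based indices into the scheme alphabet.
# Unknown letters are an error (alphabet violation).
gp_encode_aa <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, gp_aa_letters)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("sequence contains letters outside the amino-acid alphabet: ",
         paste(bad, collapse = ", "))
  }
  idx - 1L
}
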