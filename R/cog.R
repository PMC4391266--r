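# COG functional-category profiling of genomes and the guild comparison:
# per-genome category percentages, rank-sum deviation labels for the
# K-strategist vs r-strategist contrast, and marker-COG copy ratios.

#' The 25 standard single-letter COG functional categories
#' @return Character vector of category letters.
#' @export
cog_categories <- function() {
  c("J", "A", "K", "L", "B", "D", "Y", "V", "T", "M", "N", "Z", "W",
    "U", "O", "C", "G", "E", "F", "H", "I", "P", "Q", "R", "S")
}

#' Per-genome COG category percentages
#'
#' Counts genes per functional category; the denominator is the total
#' number of protein-coding genes of the genome, so unannotated genes
#' contribute to the denominator only. A gene annotated with several
#' category letters (e.g. "IQ") counts once in each listed category
#' without changing the denominator.
#'
#' @param x A [proteome()] with (possibly partial) annotations.
#' @return A `cog_profile`: list with `genome_id`, `total_genes`,
#'   `counts` and `percent` (named by category letter).
#' @export
category_percentages <- function(x) {
  stopifnot(inherits(x, "proteome"))
  total <- length(x$genes)
  if (total == 0) stop("proteome ", x$genome_id, " has zero genes")
  cats <- cog_categories()
  counts <- setNames(integer(length(cats)), cats)
  if (!is.null(x$annotations) && nrow(x$annotations)) {
    letters <- unlist(strsplit(x$annotations$categories, ""))
    tb <- table(factor(letters, levels = cats))
    counts[] <- as.integer(tb)
  }
  structure(list(genome_id = x$genome_id, total_genes = total,
                 counts = counts, percent = 100 * counts / total),
            class = "cog_profile")
}

#' Guild comparison of COG category profiles
#'
#' For each category, per-genome percentages of the two guilds are
#' compared with a two-sided rank-sum (Wilcoxon) test; a category is
#' labeled `+` in the guild with the larger mean and `-` in the other
#' when p < `alpha` and the absolute mean difference is at least
#' `min_diff` percentage points. Labels are antisymmetric by
#' construction. With fewer than 2 genomes in a guild, labels are
#' suppressed (means still reported) with a warning.
#'
#' @param profiles List of `cog_profile` objects ([category_percentages()]).
#' @param guild_of Named vector mapping genome_id to "K"/"r".
#' @param alpha Significance level (default 0.05).
#' @param min_diff Minimum absolute mean difference in percentage points
#'   (default 1.0).
#' @return A `guild_comparison`: data frame with one row per category
#'   (category, mean_K, mean_r, rounded means, labels, p-value).
#' @export
guild_comparison <- function(profiles, guild_of, alpha = 0.05,
                             min_diff = 1.0) {
  ids <- vapply(profiles, `[[`, "", "genome_id")
  stopifnot(all(ids %in% names(guild_of)))
  g <- unname(guild_of[ids])
  stopifnot(all(g %in% c("K", "r")), "K" %in% g, "r" %in% g)
  pm <- t(vapply(profiles, `[[`, numeric(length(cog_categories())),
                 "percent"))
  test_ok <- sum(g == "K") >= 2 && sum(g == "r") >= 2
  if (!test_ok)
    warning("a guild has fewer than 2 genomes; labels suppressed")
  rows <- lapply(cog_categories(), function(cc) {
    vK <- pm[g == "K", cc]; vr <- pm[g == "r", cc]
    mK <- mean(vK); mr <- mean(vr)
    p <- if (test_ok && (length(unique(c(vK, vr))) > 1))
      suppressWarnings(wilcox.test(vK, vr, exact = FALSE)$p.value)
    else NA_real_
    lab <- if (!is.na(p) && p < alpha && abs(mK - mr) >= min_diff) {
      if (mK > mr) c("+", "-") else c("-", "+")
    } else c("", "")
    data.frame(category = cc, mean_K = mK, mean_r = mr,
               mean_K_rounded = round(mK), mean_r_rounded = round(mr),
               label_K = lab[1], label_r = lab[2], p_value = p,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("guild_comparison",
                                            "data.frame"))
}

#' Mean copy number and guild ratio of a marker COG
#'
#' Mean copies per genome of `cog_id` in each guild and their ratio
#' (K over r); a zero r-guild mean is reported as an infinite ratio with
#' a flag. The cytochrome-P450 marker COG2124 is expected around 11:1 in
#' favour of the K-strategists.
#'
#' @param proteomes List of annotated [proteome()] objects.
#' @param cog_id Marker COG id (e.g. "COG2124"); must be annotated in at
#'   least one genome.
#' @param guild_of Named vector genome_id -> "K"/"r".
#' @return List with `mean_K`, `mean_r`, `ratio`, `infinite` flag and
#'   per-genome `copies`.
#' @export
marker_ratio <- function(proteomes, cog_id, guild_of) {
  ids <- vapply(proteomes, `[[`, "", "genome_id")
  copies <- vapply(proteomes, function(p) {
    if (is.null(p$annotations)) return(0)
    sum(p$annotations$cog_id == cog_id)
  }, 0)
  names(copies) <- ids
  if (sum(copies) == 0)
    stop("marker ", cog_id, " is not annotated in any genome")
  g <- unname(guild_of[ids])
  mean_K <- mean(copies[g == "K"]); mean_r <- mean(copies[g == "r"])
  inf <- mean_r == 0
  list(mean_K = mean_K, mean_r = mean_r,
       ratio = if (inf) Inf else mean_K / mean_r,
       infinite = inf, copies = copies)
}

#' Write a guild comparison as TSV (category, mean/label per guild)
#' @param comparison A `guild_comparison`.
#' @param path Output file.
#' @export
write_guild_comparison <- function(comparison, path) {
  write.table(as.data.frame(comparison), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
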