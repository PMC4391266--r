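# small helper: constant-sequence alignment over given taxa
const_aln <- function(taxa, width, letter = "A") {
  gp_alignment(matrix(letter, length(taxa), width,
                      dimnames = list(taxa, NULL)))
}

test_that("supermatrix applies the four-sequence rule and ? fill", {
  alns <- list(fA = const_aln(paste0("g", 1:5), 10),
               fB = const_aln(paste0("g", 2:5), 20),
               fC = const_aln(paste0("g", 1:3), 30))
  sm <- build_supermatrix(alns, min_seqs = 4)
  expect_equal(ncol(sm$mat), 30)              # widths 10 + 20
  expect_equal(nrow(sm$partitions), 2)
  expect_setequal(sm$taxa, paste0("g", 1:5))  # union of fA, fB
  # g1 is absent from fB: its row is '?' across that partition
  expect_true(all(partition_columns(sm, "fB")["g1", ] == "?"))
  expect_true(all(partition_columns(sm, "fA")["g1", ] == "A"))
  # per-taxon non-? counts equal summed widths of covering partitions
  expect_equal(sum(sm$mat["g1", ] != "?"), 10)
  expect_equal(sum(sm$mat["g2", ] != "?"), 30)

  # min_seqs = 1 includes everything
  sm1 <- build_supermatrix(alns, min_seqs = 1)
  expect_equal(ncol(sm1$mat), 60)
  expect_equal(nrow(sm1$partitions), 3)

  # width equals the sum of included alignment widths
  expect_equal(ncol(sm1$mat), sum(vapply(alns, ncol, 0L)))

  # duplicated genome within one alignment is a hard error
  dup <- rbind(const_aln("g1", 5), const_aln("g1", 5))
  expect_error(build_supermatrix(c(alns, list(fD = gp_alignment(dup)))),
               "inparalog")
})

test_that("information filter drops constant partitions, keeps clean splits", {
  taxa <- paste0("t", 1:4)
  # partition 1: constant columns -> unresolvable, score 0
  p1 <- matrix("A", 4, 15, dimnames = list(taxa, NULL))
  # partition 2: 15 columns perfectly matching the quartet split t1t2|t3t4
  p2 <- matrix("A", 4, 15, dimnames = list(taxa, NULL))
  p2[3:4, ] <- "R"
  cm <- char_matrix(cbind(p1, p2), "protein",
                    data.frame(partition_id = c("pA", "pB"),
                               family_id = c("pA", "pB"),
                               start = c(1L, 16L), end = c(15L, 30L)))
  red <- reduce_matrix(cm, quartets_per_partition = 60, min_info = 0.25,
                       seed = 5)
  sc <- attr(red, "info_scores")
  expect_equal(unname(sc["pA"]), 0)
  expect_equal(unname(sc["pB"]), 1)  # every quartet resolved
  expect_equal(red$partitions$partition_id, "pB")
  expect_equal(ncol(red$mat), 15)

  # exhaustive oracle on the clean-split partition: for any quartet the
  # matching topology is strictly best under parsimony
  states <- setNames(p2[, 1], taxa)
  quart <- c("t1", "t2", "t3", "t4")
  trees <- lapply(c("((t1,t2),(t3,t4));", "((t1,t3),(t2,t4));",
                    "((t1,t4),(t2,t3));"),
                  function(s) ape::read.tree(text = s))
  costs <- vapply(trees, oracle_parsimony, 0, states = states[quart])
  expect_equal(sum(costs == min(costs)), 1)
})

test_that("no-organism-deletion rule protects sole-coverage partitions", {
  taxa <- paste0("t", 1:6)
  p1 <- matrix("A", 6, 15, dimnames = list(taxa, NULL))
  p1[4:6, ] <- "R"
  # partition pX: constant, but the only one covering taxon t7
  p2 <- matrix("A", 7, 12, dimnames = list(c(taxa, "t7"), NULL))
  mat <- matrix("?", 7, 27, dimnames = list(c(taxa, "t7"), NULL))
  mat[taxa, 1:15] <- p1
  mat[, 16:27] <- p2
  cm <- char_matrix(mat, "protein",
                    data.frame(partition_id = c("pGood", "pX"),
                               family_id = c("pGood", "pX"),
                               start = c(1L, 16L), end = c(15L, 27L)))
  red <- reduce_matrix(cm, quartets_per_partition = 40, min_info = 0.25,
                       seed = 6)
  expect_true("pX" %in% red$partitions$partition_id)  # protected
  expect_true(all(rowSums(red$mat != "?") > 0))
})

test_that("core matrix takes exactly the complete single-copy families", {
  genomes <- paste0("g", 1:3)
  alns <- list(A = const_aln(genomes, 40),
               B = const_aln(genomes[-2], 25),
               C = const_aln(genomes, 60))
  core <- build_core_matrix(alns, genomes)
  expect_equal(core$partitions$partition_id, c("A", "C"))
  expect_equal(ncol(core$mat), 100)
  expect_equal(nrow(core$partitions), 2)
  expect_false(any(core$mat == "?"))   # zero missing symbols

  # no qualifying family: empty result with a warning
  expect_warning(none <- build_core_matrix(alns["B"], genomes), "no")
  expect_null(none)
})

test_that("content matrices encode presence (not counts) per family", {
  fam <- data.frame(
    family_id = c("f1", "f1", "f2", "f2", "f3", "f1"),
    genome_id = c("g1", "g2", "g2", "g3", "g1", "g1"),
    gene_id = c("a", "b", "c", "d", "e", "a2"),
    stringsAsFactors = FALSE)
  cm <- build_content_matrix(fam, c("g1", "g2", "g3"))
  expect_equal(cm$alphabet, "binary")
  rows <- apply(cm$mat, 1, paste, collapse = "")
  expect_equal(unname(rows[c("g1", "g2", "g3")]),
               c("101", "110", "010"))
  # g1 has two copies in f1 but the entry is still 1 (presence)
  expect_equal(unname(cm$mat["g1", 1]), "1")
  # column sums equal family genome coverage from the membership table
  cov <- vapply(split(fam$genome_id, fam$family_id),
                function(g) length(unique(g)), 0L)
  expect_equal(unname(colSums(cm$mat == "1")), unname(cov))

  # singleton family: a single 1
  single <- build_content_matrix(fam[fam$family_id == "f3", ],
                                 c("g1", "g2", "g3"))
  expect_equal(sum(single$mat == "1"), 1)

  # constant columns are retained and flagged
  allg <- data.frame(family_id = "fx", genome_id = c("g1", "g2", "g3"),
                     gene_id = c("x1", "x2", "x3"),
                     stringsAsFactors = FALSE)
  cmc <- build_content_matrix(allg, c("g1", "g2", "g3"))
  expect_equal(attr(cmc, "constant"), "fx")
})
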