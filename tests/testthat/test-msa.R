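degap <- function(aln, nm) paste(unclass(aln)[nm, unclass(aln)[nm, ] != "-"],
                                 collapse = "")

test_that("identical sequences align gap-free at full width", {
  s <- random_aa(1, 40)
  aln <- progressive_align(setNames(c(s, s), c("x", "y")))
  expect_equal(ncol(aln), 40)
  expect_false(any(unclass(aln) == "-"))
})

test_that("pairwise merges reach the global affine DP optimum", {
  sch <- scoring_scheme()
  aln <- progressive_align(c(x = "ACDE", y = "ACE"), sch)
  # score the produced alignment columns
  score_aln <- function(aln) {
    sc <- 0; in_gap <- FALSE
    for (j in seq_len(ncol(aln))) {
      a <- unclass(aln)[1, j]; b <- unclass(aln)[2, j]
      if (a != "-" && b != "-") {
        sc <- sc + sch$submat[a, b]; in_gap <- FALSE
      } else {
        sc <- sc + sch$gap_extend * -1 - (if (!in_gap) sch$gap_open else 0)
        in_gap <- TRUE
      }
    }
    sc
  }
  expect_equal(score_aln(aln),
               oracle_global("ACDE", "ACE", sch$submat, 11, 1))
  set.seed(81)
  for (i in 1:10) {
    a <- random_aa(1, sample(6:15, 1)); b <- random_aa(1, sample(6:15, 1))
    aln <- progressive_align(setNames(c(a, b), c("x", "y")), sch)
    expect_equal(score_aln(aln),
                 oracle_global(a, b, sch$submat, 11, 1))
  }
})

test_that("de-gapping any row reproduces its input (randomized)", {
  set.seed(82)
  for (i in 1:5) {
    n <- sample(3:6, 1)
    seqs <- setNames(random_aa(n, sample(20:40, n)), paste0("s", 1:n))
    aln <- progressive_align(seqs)
    expect_setequal(rownames(aln), names(seqs))
    for (nm in names(seqs)) expect_equal(degap(aln, nm), seqs[[nm]])
    # deterministic
    expect_identical(unclass(progressive_align(seqs)), unclass(aln))
  }
  # single sequence comes back unchanged
  one <- progressive_align(c(solo = "MKVLW"))
  expect_equal(ncol(one), 5)
})

test_that("block filtering applies the gap, run and length rules", {
  # a column with a single gap is removed under defaults
  base <- matrix("A", 10, 30, dimnames = list(paste0("t", 1:10), NULL))
  g <- base; g[1, 15] <- "-"
  fb <- filter_blocks(gp_alignment(g))
  expect_false(15 %in% fb$kept)
  expect_setequal(fb$kept, setdiff(1:30, 15))

  # 12 identical columns flanking 9 mixed columns: the 9-run is removed
  set.seed(83)
  mixed <- matrix(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
                           "I"), 10 * 9, TRUE), 10, 9)
  m <- cbind(base[, 1:12], mixed, base[, 1:12])
  fb2 <- filter_blocks(gp_alignment(`rownames<-`(m, paste0("t", 1:10))))
  expect_setequal(fb2$kept, c(1:12, 22:33))

  # but a mixed run of 8 or fewer columns inside a block is kept
  m8 <- cbind(base[, 1:12], mixed[, 1:8], base[, 1:12])
  fb3 <- filter_blocks(gp_alignment(`rownames<-`(m8, paste0("t", 1:10))))
  expect_setequal(fb3$kept, 1:32)

  # fully conserved alignment passes unchanged
  fb4 <- filter_blocks(gp_alignment(base))
  expect_equal(fb4$kept, 1:30)
  expect_equal(unclass(fb4$alignment), base)

  # everything filtered is a warning, not an error
  allgap <- matrix(c("A", "-"), 2, 20,
                   dimnames = list(c("a", "b"), NULL))
  expect_warning(fb5 <- filter_blocks(gp_alignment(allgap)), "every")
  expect_null(fb5$alignment)
  expect_equal(fb5$kept, integer())
})

test_that("kept columns satisfy the conservation predicate (scan oracle)", {
  set.seed(84)
  any_kept <- 0
  for (rep in 1:5) {
    n <- 8
    mat <- matrix(sample(c("A", "R", "N", "-"), n * 60, TRUE,
                         prob = c(0.72, 0.12, 0.12, 0.04)), n, 60,
                  dimnames = list(paste0("t", 1:n), NULL))
    p <- block_filter_params()
    fb <- suppressWarnings(filter_blocks(gp_alignment(mat), p))
    if (!length(fb$kept)) next
    any_kept <- any_kept + 1
    expect_true(all(diff(fb$kept) > 0))
    conserved <- vapply(seq_len(ncol(mat)), function(j) {
      col <- mat[, j]
      !any(col == "-") && max(table(col)) >= floor(n / 2) + 1
    }, TRUE)
    for (j in fb$kept) expect_false(any(mat[, j] == "-"))  # gap rule
    # independent scan: kept nonconserved columns only occur in runs of
    # at most max_nonconserved_run, and every kept block is long enough
    blocks <- split(fb$kept, cumsum(c(1, diff(fb$kept) != 1)))
    for (b in blocks) {
      expect_gte(length(b), p$min_block_len)
      runs <- rle(conserved[b])
      bad <- runs$lengths[!runs$values]
      if (length(bad)) expect_lte(max(bad), p$max_nonconserved_run)
    }
  }
  expect_gte(any_kept, 1)  # the scan exercised at least one alignment
})

test_that("minimum pairwise identity matches direct counts", {
  a <- gp_alignment(matrix(c("A", "A", "A", "A",
                             "A", "A", "A", "T"), 2, byrow = TRUE,
                           dimnames = list(c("x", "y"), NULL)))
  expect_equal(min_pairwise_identity(a), 75)

  ident <- gp_alignment(matrix("A", 3, 10,
                               dimnames = list(c("x", "y", "z"), NULL)))
  expect_equal(min_pairwise_identity(ident), 100)

  # three rows with pairwise identities 100, 90, 90: minimum is 90
  m <- matrix("A", 3, 10, dimnames = list(c("x", "y", "z"), NULL))
  m[3, 1] <- "T"
  expect_equal(min_pairwise_identity(gp_alignment(m)), 90)

  # pairs compared over mutually non-gap columns only
  g <- matrix(c("A", "A", "-", "A"), 2, 2,
              dimnames = list(c("x", "y"), NULL))
  expect_equal(min_pairwise_identity(gp_alignment(g)), 100)

  # no comparable columns anywhere is an error
  dis <- matrix(c("A", "-", "-", "A"), 2, 2,
                dimnames = list(c("x", "y"), NULL))
  expect_warning(expect_error(min_pairwise_identity(gp_alignment(dis)),
                              "comparable"))
})
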