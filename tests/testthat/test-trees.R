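aln_from <- function(rows) {
  gp_alignment(do.call(rbind, lapply(rows, function(s)
    strsplit(s, "")[[1]])) |> `rownames<-`(names(rows)))
}

test_that("distance corrections match their closed forms", {
  rows <- c(x = "AAAAAAAAAA", y = "AAAAAAATTT")  # p = 0.3
  a <- aln_from(rows)
  expect_equal(pairwise_distances(a, distance_model("p"))["x", "y"], 0.3)
  expect_equal(
    pairwise_distances(a, distance_model("felsenstein_nt"))["x", "y"],
    -0.75 * log(1 - 0.3 / 0.75))  # 0.3831 for B = 0.75
  rows10 <- c(x = "AAAAAAAAAA", y = "AAAAAAAAAT")  # p = 0.1
  expect_equal(
    pairwise_distances(aln_from(rows10),
                       distance_model("pam_aa"))["x", "y"],
    -log(1 - 0.1 - 0.2 * 0.01))   # 0.1076

  # p = 0 gives 0 for every model; diagonal is 0
  same <- aln_from(c(x = "AAAA", y = "AAAA"))
  for (k in c("p", "felsenstein_nt", "pam_aa"))
    expect_equal(pairwise_distances(same, distance_model(k))["x", "y"], 0)

  # saturation hits the ceiling with a warning
  far <- aln_from(c(x = "AAAAAAAAAA", y = "TTTTTTTTTT"))
  expect_warning(
    d <- pairwise_distances(far, distance_model("felsenstein_nt")),
    "saturated")
  expect_equal(d["x", "y"], 5.0)

  # '?' and '-' columns are excluded pairwise
  q <- aln_from(c(x = "AAC?", y = "A-TT"))   # comparable: cols 1 and 3
  expect_equal(pairwise_distances(q, distance_model("p"))["x", "y"], 0.5)

  # a pair with no comparable columns is an error naming the pair
  bad <- aln_from(c(x = "A?", y = "?A"))
  expect_error(pairwise_distances(bad, distance_model("p")), "x / y")
})

test_that("neighbor joining inverts additive distances", {
  true <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  d <- cophenetic(true)
  nj <- neighbor_joining(d)
  expect_equal(rf_distance(nj, true), 0)             # AB|CD recovered
  expect_equal(max(abs(cophenetic(nj)[rownames(d), colnames(d)] - d)),
               0, tolerance = 1e-9)

  # 3 taxa: closed-form branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(d3)
  expect_equal(sort(t3$edge.length), c(1, 2, 3))

  # deterministic under ties (ultrametric with symmetry)
  du <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(du) <- 0
  expect_identical(ape::write.tree(neighbor_joining(du)),
                   ape::write.tree(neighbor_joining(du)))

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2,
                                       dimnames = list(c("A", "B"),
                                                       c("A", "B")))))
})

bin_cm <- function(mat) char_matrix(mat, "binary")

test_that("Fitch scores match direct examples and the enumeration oracle", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  cm1 <- bin_cm(matrix(c("0", "0", "1", "1"), 4,
                       dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_equal(parsimony_score(tr, cm1), 1)
  cm2 <- bin_cm(matrix(c("0", "1", "0", "1"), 4,
                       dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_equal(parsimony_score(tr, cm2), 2)

  set.seed(91)
  for (i in 1:25) {
    n <- sample(5:7, 1)
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    w <- 6
    mat <- matrix(sample(c("0", "1"), n * w, TRUE), n,
                  dimnames = list(paste0("t", 1:n), NULL))
    cm <- bin_cm(mat)
    oracle <- sum(vapply(seq_len(w), function(j)
      oracle_parsimony(tr, setNames(mat[, j], rownames(mat))), 0))
    expect_equal(parsimony_score(tr, cm), oracle)
    # independent library cross-check
    pd <- phangorn::phyDat(mat, type = "USER", levels = c("0", "1"))
    expect_equal(parsimony_score(tr, cm), phangorn::fitch(tr, pd))
  }
})

test_that("ambiguous states integrate over the alphabet in Fitch scores", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  pcm <- char_matrix(matrix(c("M", "?", "K", "K"), 4,
                            dimnames = list(c("A", "B", "C", "D"), NULL)),
                     "protein")
  expect_equal(parsimony_score(tr, pcm), 1)
  pcm2 <- char_matrix(matrix(c("M", "-", "M", "K", "K", "X"), 6,
                             dimnames = list(paste0("t", 1:6), NULL)),
                      "protein")
  tr6 <- ape::read.tree(text = "(((t1,t2),t3),((t4,t5),t6));")
  expect_equal(parsimony_score(tr6, pcm2), 1)
})

test_that("parsimony search never worsens the start score", {
  set.seed(92)
  mat <- matrix(sample(c("0", "1"), 8 * 40, TRUE), 8,
                dimnames = list(paste0("t", 1:8), NULL))
  cm <- bin_cm(mat)
  start <- neighbor_joining(pairwise_distances(cm, distance_model("p")))
  res <- parsimony_search(cm, start = start, seed = 1, restarts = 2)
  expect_lte(res$score, parsimony_score(start, cm))
  expect_equal(res$score, parsimony_score(res$tree, cm))
})

test_that("pruning likelihood equals state enumeration and ignores rooting", {
  set.seed(93)
  for (i in 1:5) {
    tr <- ape::rtree(4, tip.label = c("A", "B", "C", "D"))
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.8)
    states <- setNames(sample(c("0", "1"), 4, TRUE), c("A", "B", "C", "D"))
    cm <- bin_cm(matrix(states, 4, dimnames = list(names(states), NULL)))
    expect_equal(log_likelihood(tr, cm),
                 oracle_loglik_binary(tr, states), tolerance = 1e-8)
    # root placement invariance
    rr <- ape::root(ape::unroot(tr), outgroup = "C", resolve.root = TRUE)
    expect_equal(log_likelihood(tr, cm), log_likelihood(rr, cm),
                 tolerance = 1e-8)
  }
  # two leaves, zero branch length, identical states: stationary freq
  tr2 <- ape::read.tree(text = "(A:0,B:0);")
  tr2$edge.length <- c(0, 0)
  cm2 <- bin_cm(matrix(c("0", "0"), 2, dimnames = list(c("A", "B"), NULL)))
  expect_equal(log_likelihood(tr2, cm2), log(0.5), tolerance = 1e-6)
})

test_that("protein likelihood is finite and improves under ML search", {
  set.seed(94)
  sim <- simulate_dataset(n_taxa = 5, seed = 7, n_core = 4,
                          n_accessory = 0, root_len = 60)
  h <- all_vs_all(sim$proteomes)
  ort <- remove_inparalogs(ortholog_families(h, sim$proteomes), h)
  alns <- guildphylo:::gp_family_alignments(ort, sim$proteomes,
                                            scoring_scheme(),
                                            pipeline_config())
  cm <- build_supermatrix(alns, min_seqs = 4)
  start <- suppressWarnings(gp_start <- neighbor_joining(
    pairwise_distances(cm, distance_model("pam_aa"))))
  ll0 <- log_likelihood(start, cm)
  expect_true(is.finite(ll0))
  res <- ml_search(cm, start = start, seed = 1)
  expect_gte(res$logLik, ll0 - 1e-6)
  expect_equal(rf_distance(res$tree, sim$truth$species_tree), 0)
})

test_that("bootstrap support is seeded and calibrated", {
  # every column supports AB|CD: support 100 at 100 reps
  taxa <- c("A", "B", "C", "D", "E")
  mat <- matrix("0", 5, 40, dimnames = list(taxa, NULL))
  mat[c("A", "B"), ] <- "1"
  cm <- bin_cm(mat)
  s <- bootstrap_support(cm, "nj", n_reps = 100, seed = 3)
  # split AB|CDE is keyed by the side without the anchor taxon A
  expect_equal(unname(s["C|D|E"]), 100)

  # same seed, identical table
  s2 <- bootstrap_support(cm, "nj", n_reps = 100, seed = 3)
  expect_identical(s, s2)

  # 50/50 conflicting columns: support near 50 (binomial oracle)
  conf <- cbind(matrix(rep(c("1", "1", "0", "0", "0"), 30), 5),
                matrix(rep(c("1", "0", "1", "0", "0"), 30), 5))
  rownames(conf) <- taxa
  ref <- ape::read.tree(text = "(((A,B),C),(D,E));")
  s3 <- bootstrap_support(bin_cm(conf), "nj", n_reps = 400, seed = 4,
                          reference = ref)
  p <- unname(s3["C|D|E"]) / 100
  se <- sqrt(0.25 / 400)
  expect_lt(abs(p - 0.5), 3 * se + 0.05)
})

test_that("composite dots reproduce the three figure-legend rules", {
  ref <- ape::read.tree(text = "((A,B),(C,D));")
  mk <- function(...) {
    vals <- list(...)
    lapply(seq_along(vals), function(i) c("C|D" = vals[[i]]))
  }
  annotate1 <- function(...) {
    v <- mk(...)
    names(v) <- paste0("m", seq_along(v))
    annotate_support(ref, v)$table
  }
  # m = 3: all three at 95+ -> black
  expect_equal(annotate1(96, 97, 95)$category, "black")
  # m = 3: exactly two at 95+ -> white
  expect_equal(annotate1(96, 97, 60)$category, "white")
  # m = 6: four at 95+ -> white
  expect_equal(annotate1(96, 96, 97, 95, 60, 70)$category, "white")
  # m = 3: only values >= 75 printed on hollow dots
  t3 <- annotate1(80, 74, 60)
  expect_equal(t3$category, "hollow")
  expect_equal(t3$printed, "80")
  # below 75 everywhere: unmarked
  expect_equal(annotate1(70, 60, 50)$category, "none")
  # a missing method value is an error
  expect_error(annotate_support(ref, list(m1 = c("X|Y" = 99))),
               "missing")
})

test_that("RF distances match bipartition enumeration", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  t2 <- ape::read.tree(text = "((A,C),(B,D),E);")
  expect_equal(rf_distance(t1, t1), 0)
  # t1 carries splits AB and CD, t2 carries AC and BD: none shared
  expect_equal(rf_distance(t1, t2), 4)
  expect_equal(rf_distance(t1, t2), rf_distance(t2, t1))
  expect_equal(rf_distance(t1, t2), oracle_rf(t1, t2))
  set.seed(95)
  for (i in 1:10) {
    a <- ape::rtree(7, tip.label = paste0("t", 1:7))
    b <- ape::rtree(7, tip.label = paste0("t", 1:7))
    expect_equal(rf_distance(a, b), oracle_rf(a, b))
  }
  expect_error(rf_distance(t1, ape::rtree(4)), "leaf set")
})
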