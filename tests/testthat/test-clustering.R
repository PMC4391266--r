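# convenience: build a hit table row
hit_row <- function(qg, q, sg, s, e, bit = 100) {
  data.frame(query_genome = qg, query_gene = q, subject_genome = sg,
             subject_gene = s, pident = 50, align_len = 100,
             evalue = e, bitscore = bit, stringsAsFactors = FALSE)
}

# symmetric pair of hits
hit_pair <- function(qg, q, sg, s, e, bit = 100)
  rbind(hit_row(qg, q, sg, s, e, bit), hit_row(sg, s, qg, q, e, bit))

# gp_graph from an explicit weighted edge list over single-genome nodes
toy_graph <- function(edges) {
  keys <- sort(unique(c(edges$a, edges$b)))
  structure(list(
    nodes = data.frame(genome_id = rep("g", length(keys)), gene_id = keys,
                       key = paste("g", keys, sep = "\t"),
                       stringsAsFactors = FALSE),
    edges = data.frame(key1 = paste("g", pmin(edges$a, edges$b),
                                    sep = "\t"),
                       key2 = paste("g", pmax(edges$a, edges$b),
                                    sep = "\t"),
                       weight = edges$w, stringsAsFactors = FALSE)),
    class = "gp_graph")
}

clusters_of <- function(fam) {
  unname(lapply(split(fam$gene_id, fam$family_id), sort))
}

has_cluster <- function(clusters, members)
  any(vapply(clusters, identical, TRUE, y = sort(members)))

test_that("homolog graph weights follow the TribeMCL convention", {
  h <- hit_pair("A", "x", "B", "y", 1e-30)
  g <- build_homolog_graph(h)
  expect_equal(g$edges$weight, 30)

  g0 <- build_homolog_graph(hit_pair("A", "x", "B", "y", 0))
  expect_equal(g0$edges$weight, 200)          # E = 0 capped

  g1 <- build_homolog_graph(hit_row("A", "x", "B", "y", 1e-40))
  expect_equal(g1$edges$weight, 20)           # one direction missing

  # hits above the threshold and self hits are excluded
  ge <- build_homolog_graph(rbind(hit_pair("A", "x", "B", "y", 1e-3),
                                  hit_row("A", "x", "A", "x", 1e-80)))
  expect_equal(nrow(ge$edges), 0)
})

test_that("MCL separates weakly bridged cliques and merges uniform ones", {
  # single isolated node
  g <- structure(list(
    nodes = data.frame(genome_id = "g", gene_id = "n1", key = "g\tn1",
                       stringsAsFactors = FALSE),
    edges = data.frame(key1 = character(), key2 = character(),
                       weight = numeric(), stringsAsFactors = FALSE)),
    class = "gp_graph")
  fam <- mcl(g)
  expect_equal(nrow(fam), 1)

  # two 3-cliques (weight 30) joined by a weight-0.5 bridge
  cl <- expand.grid(a = c("a1", "a2", "a3"), b = c("a1", "a2", "a3"),
                    stringsAsFactors = FALSE)
  cl <- cl[cl$a < cl$b, ]
  cl2 <- cl; cl2$a <- sub("a", "b", cl2$a); cl2$b <- sub("a", "b", cl2$b)
  edges <- rbind(cbind(cl, w = 30), cbind(cl2, w = 30),
                 data.frame(a = "a1", b = "b1", w = 0.5))
  fam <- mcl(toy_graph(edges))
  got <- clusters_of(fam)
  expect_equal(length(got), 2)
  expect_true(has_cluster(got, c("a1", "a2", "a3")))

  # agreement with the independent dense-matrix oracle
  nodes <- sort(unique(c(edges$a, edges$b)))
  W <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  W[cbind(edges$a, edges$b)] <- edges$w
  W <- pmax(W, t(W))
  ocl <- lapply(oracle_mcl(W, 2), function(ix) sort(nodes[ix]))
  expect_setequal(got, ocl)

  # complete uniform graph collapses to one cluster
  cg <- expand.grid(a = paste0("n", 1:5), b = paste0("n", 1:5),
                    stringsAsFactors = FALSE)
  cg <- cbind(cg[cg$a < cg$b, ], w = 10)
  expect_equal(length(clusters_of(mcl(toy_graph(cg)))), 1)
})

test_that("MCL output partitions the nodes and ignores node order", {
  set.seed(71)
  nodes <- paste0("n", sprintf("%02d", 1:12))
  pairs <- t(combn(nodes, 2))
  sel <- runif(nrow(pairs)) < 0.3
  edges <- data.frame(a = pairs[sel, 1], b = pairs[sel, 2],
                      w = round(runif(sum(sel), 1, 50), 1),
                      stringsAsFactors = FALSE)
  g <- toy_graph(edges)
  base <- clusters_of(mcl(g))
  expect_setequal(unlist(base), nodes)
  expect_equal(sum(lengths(base)), 12)  # disjoint cover
  for (perm in 1:5) {
    ord <- sample(nrow(edges))
    gp <- toy_graph(edges[ord, ])
    expect_setequal(clusters_of(mcl(gp)), base)
  }
})

test_that("ortholog families come from RBHs plus inparalog edges", {
  # two genomes, one family, no duplicates: single RBH
  h <- hit_pair("A", "a1", "B", "b1", 1e-50)
  prot <- list(proteome("A", c(a1 = "MKV")), proteome("B", c(b1 = "MKV")))
  fam <- ortholog_families(h, prot)
  expect_equal(clusters_of(fam), list(c("a1", "b1")))

  # recent duplicate pair a1/a2 with a1-a2 closer than either is to b1
  h2 <- rbind(hit_pair("A", "a1", "A", "a2", 1e-80, bit = 300),
              hit_pair("A", "a1", "B", "b1", 1e-40, bit = 200),
              hit_pair("A", "a2", "B", "b1", 1e-38, bit = 190))
  prot2 <- list(proteome("A", c(a1 = "MKV", a2 = "MKV")),
                proteome("B", c(b1 = "MKV")))
  fam2 <- ortholog_families(h2, prot2)
  expect_equal(clusters_of(fam2), list(c("a1", "a2", "b1")))

  # within-genome pair worse than both genes' best between-genome hits
  # is not an inparalog edge
  h3 <- rbind(hit_pair("A", "a1", "A", "a2", 1e-10),
              hit_pair("A", "a1", "B", "b1", 1e-40),
              hit_pair("A", "a2", "B", "b2", 1e-42))
  prot3 <- list(proteome("A", c(a1 = "MKV", a2 = "MKV")),
                proteome("B", c(b1 = "MKV", b2 = "MKV")))
  fam3 <- ortholog_families(h3, prot3)
  expect_false(has_cluster(clusters_of(fam3), c("a1", "a2")))

  # asymmetric best hits make no RBH edge
  h4 <- rbind(hit_row("A", "a1", "B", "b1", 1e-50),
              hit_row("B", "b1", "A", "a2", 1e-60),
              hit_row("A", "a2", "B", "b2", 1e-70),
              hit_row("B", "b2", "A", "a1", 1e-45))
  prot4 <- prot3
  fam4 <- ortholog_families(h4, prot4)
  expect_false(any(vapply(clusters_of(fam4), function(cl)
    all(c("a1", "b1") %in% cl), TRUE)))
})

test_that("inparalog removal keeps the best-connected representative", {
  fam <- data.frame(family_id = "F00001",
                    genome_id = c("A", "A", "B"),
                    gene_id = c("a1", "a2", "b1"),
                    kind = "ortholog", stringsAsFactors = FALSE)
  h <- rbind(hit_pair("A", "a1", "B", "b1", 1e-50, bit = 500),
             hit_pair("A", "a2", "B", "b1", 1e-45, bit = 450))
  out <- remove_inparalogs(fam, h)
  expect_setequal(out$gene_id, c("a1", "b1"))

  # exact tie: lexicographically smaller gene id wins
  h_tie <- rbind(hit_pair("A", "a1", "B", "b1", 1e-50, bit = 500),
                 hit_pair("A", "a2", "B", "b1", 1e-50, bit = 500))
  out_tie <- remove_inparalogs(fam, h_tie)
  expect_setequal(out_tie$gene_id, c("a1", "b1"))

  # one member per genome: unchanged
  fam1 <- fam[c(1, 3), ]
  expect_equal(remove_inparalogs(fam1, h), fam1)

  # alternative reading: drop whole multi-copy families
  expect_equal(nrow(remove_inparalogs(fam, h,
                                      drop_multicopy_families = TRUE)), 0)
})
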