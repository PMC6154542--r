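test_that("Jaccard similarity ignores shared absences", {
  expect_equal(jaccard_similarity(c(1, 1, 0, 1), c(1, 0, 0, 1)), 2 / 3)
  expect_equal(jaccard_similarity(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(jaccard_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(jaccard_similarity(c(0, 0), c(0, 0)), "all-zero")
})

test_that("similarity matrices are symmetric, unit-diagonal and match vegan", {
  set.seed(41)
  m <- make_bm(matrix(rbinom(120, 1, 0.6), 8, 15))
  s <- similarity_matrix(m)
  expect_true(isSymmetric(unname(s)))
  expect_equal(unname(diag(s)), rep(1, 8))
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(s[i, j], jaccard_similarity(m$scores[i, ], m$scores[j, ]))

  skip_if_not_installed("vegan")
  vd <- as.matrix(vegan::vegdist(m$scores, method = "jaccard",
                                 binary = TRUE))
  expect_equal(unname(jaccard_distance(m)), unname(vd))

  bad <- make_bm(rbind(c(1, 1), c(0, 0)))
  expect_error(similarity_matrix(bad), "i02")
})

test_that("UPGMA reproduces hand-worked and brute-force agglomerations", {
  # two leaves at distance 0.4 -> one node at height 0.2
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(t2$heights, 0.2)
  expect_equal(unname(cophenetic_distances(t2)["A", "B"]), 0.4)

  # 4-leaf worked example: ((A,B),(C,D)) with root height 0.4
  d4 <- matrix(0.8, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4["A", "B"] <- d4["B", "A"] <- 0.2
  d4["C", "D"] <- d4["D", "C"] <- 0.3
  diag(d4) <- 0
  t4 <- upgma(d4)
  expect_equal(sort(t4$heights), c(0.1, 0.15, 0.4))
  cp <- cophenetic_distances(t4)
  expect_equal(unname(cp["A", "B"]), 0.2)
  expect_equal(unname(cp["C", "D"]), 0.3)
  expect_equal(unname(cp["A", "C"]), 0.8)
  expect_identical(cut_upgma(t4, 2), c(A = 1L, B = 1L, C = 2L, D = 2L))

  # random matrices vs the O(n^4) recomputation oracle and stats::hclust
  for (s in 1:4) {
    set.seed(s)
    n <- sample(6:10, 1)
    x <- matrix(runif(n * 5), n)
    d <- as.matrix(dist(x))
    t <- upgma(d)
    expect_equal(unname(cophenetic_distances(t)),
                 brute_upgma_cophenetic(d))
    h <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(unname(as.matrix(stats::cophenetic(h))),
                 unname(cophenetic_distances(t)))
    expect_true(all(diff(t$heights) >= -1e-12))  # no inversions
  }
})

test_that("UPGMA recovers an ultrametric input exactly", {
  d4 <- matrix(0.8, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4["A", "B"] <- d4["B", "A"] <- 0.2
  d4["C", "D"] <- d4["D", "C"] <- 0.3
  diag(d4) <- 0
  t <- upgma(d4)
  expect_equal(unname(cophenetic_distances(t)), unname(d4))
})

test_that("cutting the synthetic tree at four groups recovers the populations", {
  g <- generate_band_matrix(seed = 9)
  t <- upgma(jaccard_distance(g$matrix), labels = g$matrix$individual_ids)
  grp <- cut_upgma(t, 4)
  expect_gte(rand_index(grp, as.integer(factor(g$matrix$population))), 0.95)
})

test_that("band bootstrap gives near-certain support to well-separated clusters", {
  # near-fixed private bands make the two clusters unambiguous
  specs <- list(population_spec("A", n_individuals = 8, private_band_count = 15,
                                divergence = 0, common_range = c(0.85, 0.95)),
                population_spec("B", n_individuals = 8, private_band_count = 15,
                                divergence = 0, common_range = c(0.85, 0.95)))
  counts <- c(P1 = 20L, P2 = 20L)
  for (s in 1:3) {
    g <- generate_band_matrix(specs, seed = s, band_counts = counts)
    t <- bootstrap_support(g$matrix, replicates = 150, seed = 100 + s)
    # the bipartition separating the two populations is an internal node
    # whose clade is one population; find it through the cut
    grp <- cut_upgma(t, 2)
    expect_gte(rand_index(grp, as.integer(factor(g$matrix$population))),
               0.95)
    # supports of the two population clades
    phy <- t$phylo
    tips_by_clade <- lapply(seq_len(phy$Nnode) + length(t$labels),
                            function(nd) sort(ape::extract.clade(phy, nd)$tip.label))
    popA <- sort(g$matrix$individual_ids[g$matrix$population == "A"])
    popB <- sort(g$matrix$individual_ids[g$matrix$population == "B"])
    hit <- which(vapply(tips_by_clade, function(tp)
      identical(tp, popA) || identical(tp, popB), NA))
    expect_gte(length(hit), 1)
    expect_true(all(t$support[hit] >= 95))
  }
})

test_that("bootstrap is deterministic given a seed and trivial with one band", {
  set.seed(43)
  m <- make_bm(matrix(rbinom(80, 1, 0.5), 8, 10))
  t1 <- bootstrap_support(m, replicates = 120, seed = 5)
  t2 <- bootstrap_support(m, replicates = 120, seed = 5)
  expect_identical(t1$support, t2$support)

  one <- make_bm(matrix(1, 4, 1))
  tb <- bootstrap_support(one, replicates = 100, seed = 1)
  expect_true(all(tb$support == 100))
})

test_that("Newick export round-trips topology, heights and supports", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  f <- withr::local_tempfile()
  write_newick(upgma(d2), f)
  txt <- readLines(f)
  expect_match(txt, "^\\(A:0\\.2,B:0\\.2\\);$")

  set.seed(47)
  m <- make_bm(matrix(rbinom(70, 1, 0.5), 7, 10))
  t <- bootstrap_support(m, replicates = 100, seed = 2)
  f2 <- withr::local_tempfile()
  write_newick(t, f2)
  back <- ape::read.tree(f2)
  expect_true(ape::all.equal.phylo(back, t$phylo, use.edge.length = FALSE))
  # heights: root-to-leaf path equals the original root height
  depths <- ape::node.depth.edgelength(back)
  expect_equal(max(depths[seq_len(7)]), max(t$heights), tolerance = 1e-9)
  # supports re-attach to the same clades (node numbering may differ)
  clade_labels <- function(phy) {
    n_tip <- length(phy$tip.label)
    sets <- vapply(seq_len(phy$Nnode) + n_tip, function(nd)
      paste(sort(ape::extract.clade(phy, nd)$tip.label), collapse = "|"),
      "")
    stats::setNames(phy$node.label, sets)
  }
  a <- clade_labels(back); b <- clade_labels(t$phylo)
  expect_identical(a[sort(names(a))], b[sort(names(b))])
})
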