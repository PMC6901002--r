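four_taxon_matrix <- function() {
  d <- matrix(6, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2
  diag(d) <- 0
  d
}

test_that("UPGMA reproduces the hand-run four-taxon agglomeration", {
  t <- upgma(four_taxon_matrix())
  # heights: cherries at 1, root at 3; branch lengths follow
  expect_identical(to_newick(t),
    "((A:1.000000,B:1.000000):2.000000,(C:1.000000,D:1.000000):2.000000);")
  depths <- leaf_depths(t)
  expect_true(all(abs(depths - 3) < 1e-12))
})

test_that("UPGMA trees are ultrametric and match average-linkage clustering", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:9, 1)
    d <- matrix(runif(n * n, 1, 10), n, n)
    d <- d + t(d)
    diag(d) <- 0
    dimnames(d) <- list(paste0("S", 1:n), paste0("S", 1:n))
    t <- upgma(d)
    depths <- leaf_depths(t)
    expect_lt(diff(range(depths)) / max(depths), 1e-9)
    expect_setequal(tree_leaves(t), rownames(d))
    # independent route: stats::hclust average linkage; the cophenetic
    # distance equals twice our node heights, i.e. the leaf-to-leaf path sum
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    coph <- as.matrix(stats::cophenetic(hc))
    ours <- tree_distances(t)[rownames(coph), colnames(coph)]
    expect_equal(ours, coph, tolerance = 1e-9)
  }
})

test_that("tree builders validate their input matrix", {
  d3 <- four_taxon_matrix()[1:3, 1:3]
  expect_error(upgma(d3), "at least 4 genomes")
  expect_error(neighbor_joining(d3), "at least 4 genomes")
  neg <- four_taxon_matrix(); neg["A", "B"] <- neg["B", "A"] <- -1
  expect_error(upgma(neg), "negative")
  asym <- four_taxon_matrix(); asym["A", "B"] <- 5
  expect_error(upgma(asym), "symmetric")
  expect_error(neighbor_joining(asym), "symmetric")
})

test_that("neighbour-joining recovers a known additive quartet exactly", {
  # quartet AB|CD with leaf branches A=1, B=2, C=3, D=4 and internal edge 1:
  # pairwise path sums give the additive matrix below
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  t <- neighbor_joining(d)
  expect_length(t$children, 3L)  # trifurcating root encodes the unrooted tree
  expect_equal(tree_distances(t)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  # the split AB|CD is present
  expect_true("A|B" %in% tree_splits(t) || "C|D" %in% tree_splits(t))
  # same unrooted split as UPGMA finds on its example matrix
  expect_true(same_unrooted_topology(t, neighbor_joining(four_taxon_matrix())))
})

test_that("neighbour-joining on an equidistant matrix gives equal leaf branches", {
  d <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  t <- neighbor_joining(d)
  lens <- vapply(t$children, function(ch) ch$length, numeric(1))
  # star-like: all terminal branches equal (internal edge length 0)
  leaf_edges <- unlist(lapply(t$children, function(ch) {
    if (length(ch$node$children) == 0L) ch$length else
      vapply(ch$node$children, function(g) g$length, numeric(1))
  }))
  expect_true(all(abs(leaf_edges - 1) < 1e-12))
})

test_that("neighbour-joining agrees with an independent implementation", {
  skip_if_not_installed("ape")
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(5:10, 1)
    base <- generate_additive_matrix(n, seed)$matrix
    noisy <- unclass(base) + matrix(runif(n * n, 0, 0.05), n, n)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    ours <- neighbor_joining(noisy)
    ref <- ape::nj(stats::as.dist(noisy))
    ours_ape <- ape::read.tree(text = to_newick(ours, precision = 10))
    expect_equal(ape::dist.topo(ape::unroot(ours_ape), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("Newick output and parsing round-trip topology and branch lengths", {
  cherry <- parse_newick("(A:1,B:1);")
  expect_identical(to_newick(cherry), "(A:1.000000,B:1.000000);")

  am <- generate_additive_matrix(9, 17)
  t <- neighbor_joining(am$matrix)
  rt <- parse_newick(to_newick(t, precision = 9))
  expect_true(same_unrooted_topology(t, rt))
  expect_equal(tree_distances(rt)[rownames(am$matrix), colnames(am$matrix)],
               unclass(am$matrix), tolerance = 1e-6, ignore_attr = TRUE)

  # reserved characters in labels are quoted and recovered
  withspace <- upgma(`dimnames<-`(four_taxon_matrix(),
    list(c("pop one", "pop(2)", "pop;3", "pop'4"),
         c("pop one", "pop(2)", "pop;3", "pop'4"))))
  nwk <- to_newick(withspace)
  expect_match(nwk, "'pop one'", fixed = TRUE)
  expect_setequal(tree_leaves(parse_newick(nwk)),
                  c("pop one", "pop(2)", "pop;3", "pop'4"))
})
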