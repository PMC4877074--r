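three_leaf_matrix <- function() {
  matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

random_distance_matrix <- function(k) {
  pts <- matrix(stats::rnorm(k * 3), k)
  rownames(pts) <- sprintf("L%02d", seq_len(k))
  as.matrix(stats::dist(pts))
}

collect_heights <- function(node) {
  if (is.null(node$children)) return(numeric(0))
  c(node$height, unlist(lapply(node$children, collect_heights)))
}

node_sets_for_test <- function(node) {
  if (is.null(node$children)) return(list(node$label))
  kids <- lapply(node$children, node_sets_for_test)
  own <- unlist(lapply(kids, function(k) unlist(k[1])))
  c(list(sort(own)), unlist(kids, recursive = FALSE))
}

test_that("UPGMA reproduces the hand-worked merges", {
  t <- upgma(three_leaf_matrix())
  expect_identical(to_newick(t), "((A:1,B:1):3,C:4);")
  # two labels: a single cherry at height d/2
  m2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("B", "A"), c("B", "A")))
  expect_identical(to_newick(upgma(m2)), "(A:1.5,B:1.5);")
})

test_that("UPGMA heights match the reference average-linkage implementation", {
  set.seed(43)
  for (rep in 1:10) {
    k <- sample(4:12, 1)
    m <- random_distance_matrix(k)
    t <- upgma(m)
    hc <- stats::hclust(stats::as.dist(m), method = "average")
    # our node heights are half the merge distances
    heights <- sort(collect_heights(t$root))
    expect_equal(heights, sort(hc$height) / 2, tolerance = 1e-9)
  }
})

test_that("UPGMA trees are ultrametric on fuzzed matrices", {
  set.seed(47)
  for (rep in 1:10) {
    m <- random_distance_matrix(sample(3:15, 1))
    t <- upgma(m)
    depths <- leaf_path_lengths(t)
    expect_identical(sort(names(depths)), t$labels)
    expect_lt(max(depths) - min(depths), 1e-12)
    expect_equal(unname(depths[1]), t$root$height)
  }
})

test_that("UPGMA is invariant to input label order", {
  set.seed(53)
  m <- random_distance_matrix(8)
  t0 <- upgma(m)
  for (rep in 1:5) {
    p <- sample(8)
    tp <- upgma(m[p, p])
    expect_equal(sort(collect_heights(tp$root)),
                 sort(collect_heights(t0$root)))
    expect_identical(to_newick(tp), to_newick(t0))
  }
})

test_that("UPGMA rejects malformed matrices", {
  m <- three_leaf_matrix()
  m[1, 2] <- NA
  expect_error(upgma(m), "non-finite")
  m <- three_leaf_matrix()
  m[1, 2] <- -1; m[2, 1] <- -1
  expect_error(upgma(m), "negative")
  expect_error(upgma(matrix(0, 1, 1, dimnames = list("A", "A"))),
               "at least 2")
})

test_that("Newick output round-trips through a third-party reader", {
  skip_if_not_installed("ape")
  set.seed(59)
  m <- random_distance_matrix(7)
  t <- upgma(m)
  ph <- ape::read.tree(text = to_newick(t))
  expect_identical(sort(ph$tip.label), t$labels)
  # clades survive the round trip: every internal node's leaf set matches
  ours <- lapply(node_sets_for_test(t$root), sort)
  theirs <- lapply(ape::prop.part(ph), function(i) sort(ph$tip.label[i]))
  for (s in theirs)
    expect_true(any(vapply(ours, identical, TRUE, y = s)))
  # branch lengths preserve the ultrametric depths
  depths <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
  expect_lt(max(depths) - min(depths), 1e-8)
})

test_that("cluster purity detects clean and swapped families", {
  fam6 <- data.frame(label = c("a1", "a2", "a3", "b1", "b2", "b3"),
                     family = rep(c("A", "B"), each = 3))
  # perfectly grouped: two clean clusters, nothing misplaced
  m <- matrix(5, 6, 6, dimnames = list(fam6$label, fam6$label))
  diag(m) <- 0
  m[1:3, 1:3] <- 1; m[4:6, 4:6] <- 1; diag(m) <- 0
  pur <- cluster_purity(upgma(m), fam6)
  expect_identical(pur$clean_clusters, 2L)
  expect_identical(pur$misplaced, character(0))

  # one leaf swapped into the other family's clade
  m2 <- matrix(5, 6, 6, dimnames = list(fam6$label, fam6$label))
  grp <- c(1, 1, 2, 2, 2, 2)  # a3 sits with the b's
  for (i in 1:6) for (j in 1:6) if (grp[i] == grp[j]) m2[i, j] <- 1
  diag(m2) <- 0
  pur2 <- cluster_purity(upgma(m2), fam6)
  expect_identical(length(pur2$misplaced), 1L)
  expect_identical(pur2$misplaced, "a3")

  expect_error(cluster_purity(upgma(m), fam6[-1, ]),
               "unknown leaf label")
})

test_that("UPGMA on the nine-virus reference matrix groups the similar trio", {
  f <- system.file("extdata", "virus9_reference_matrix.phylip",
                   package = "rnacurve")
  t <- upgma(read_phylip(f))
  sets <- lapply(node_sets_for_test(t$root), sort)
  expect_true(any(vapply(sets, identical, TRUE,
                         y = c("AVII", "EMV-3", "LRMV-3"))))
})
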