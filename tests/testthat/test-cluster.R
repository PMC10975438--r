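fp_from_levels <- function(levels) {
  out <- tibble::tibble(center_ppm = seq_along(levels), level = levels)
  class(out) <- c("nmr_fingerprint", class(out))
  out
}

test_that("distances: identical fingerprints, single-coordinate case, oracle", {
  f <- fp_from_levels(c(3, 1, 4, 1, 5))
  d0 <- distance_matrix(list(f, f, f))
  expect_true(all(d0 == 0))

  g <- fp_from_levels(c(3, 1, 104, 1, 5))
  expect_equal(distance_matrix(list(f, g))[1, 2], 100)

  set.seed(12)
  fps <- lapply(1:6, function(i) fp_from_levels(sample(0:100, 20, TRUE)))
  d <- distance_matrix(fps)
  for (i in 1:6) {
    for (j in 1:6) {
      expect_equal(d[i, j],
                   sqrt(sum((fps[[i]]$level - fps[[j]]$level)^2)))
    }
  }
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("length mismatches and invalid distance inputs are rejected", {
  expect_error(distance_matrix(list(fp_from_levels(1:3),
                                    fp_from_levels(1:4))),
               class = "cinnamr_bad_fingerprint")
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(hierarchical_cluster(bad), class = "cinnamr_bad_distance")
  neg <- matrix(c(0, -1, -1, 0), 2)
  expect_error(hierarchical_cluster(neg), class = "cinnamr_bad_distance")
})

test_that("small trees merge as expected", {
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- hierarchical_cluster(d2)
  expect_equal(t2$hclust$height, 3)

  x <- c(0, 1, 10)
  d3 <- as.matrix(dist(x))
  t3 <- hierarchical_cluster(d3, linkage = "single")
  expect_equal(sort(t3$hclust$merge[1, ]), c(-2, -1))
  expect_true(all(diff(t3$hclust$height) >= 0))
})

test_that("purity behaves at the trivial bounds", {
  set.seed(4)
  fps <- lapply(1:8, function(i) fp_from_levels(sample(0:100, 10, TRUE)))
  tree <- hierarchical_cluster(distance_matrix(fps))
  expect_equal(cluster_purity(tree, rep("x", 8), 3), 1)
  expect_equal(cluster_purity(tree, sample(c("x", "y"), 8, TRUE), 8), 1)
  expect_error(cluster_purity(tree, rep("x", 8), 0), class = "cinnamr_bad_k")

  # two clusters, each half-and-half of two labels
  m <- rbind(matrix(0, 4, 5), matrix(100, 4, 5))
  treem <- hierarchical_cluster(as.matrix(dist(m)))
  labels <- c("A", "A", "B", "B", "A", "A", "B", "B")
  expect_equal(cluster_purity(treem, labels, 2), 0.5)
})

test_that("purity is invariant to label renaming", {
  set.seed(5)
  fps <- lapply(1:9, function(i) fp_from_levels(sample(0:100, 12, TRUE)))
  tree <- hierarchical_cluster(distance_matrix(fps))
  labels <- rep(c("p", "q", "r"), each = 3)
  renamed <- c(p = "z1", q = "z2", r = "z3")[labels]
  for (k in 1:5) {
    expect_equal(cluster_purity(tree, labels, k),
                 cluster_purity(tree, renamed, k))
  }
})

test_that("input order does not change distances or the k-cut partition", {
  set.seed(6)
  fps <- lapply(1:10, function(i) fp_from_levels(sample(0:100, 15, TRUE)))
  perm <- sample(10)
  d1 <- distance_matrix(fps)
  d2 <- distance_matrix(fps[perm])
  expect_equal(unname(d2), unname(d1[perm, perm]))

  cl1 <- stats::cutree(hierarchical_cluster(d1)$hclust, k = 3)
  cl2 <- stats::cutree(hierarchical_cluster(d2)$hclust, k = 3)
  tab <- table(cl1[perm], cl2)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("well-separated species profiles cluster purely at k = 3", {
  coh <- generate_cohort(separated_profiles(), 4, toy_params(), seed = 21)
  fps <- lapply(coh$spectra, fingerprint_spectrum)
  ids <- vapply(coh$spectra, function(s) attr(s, "meta")$sample_id, "")
  tree <- hierarchical_cluster(distance_matrix(fps))
  labels <- sub("^(Cin_[a-z]+)_.*$", "\\1", ids)
  expect_equal(cluster_purity(tree, labels, 3), 1)
})

test_that("newick export round-trips topology", {
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(export_newick(hierarchical_cluster(d2)), "(a:0.5,b:0.5);")

  set.seed(8)
  fps <- lapply(1:7, function(i) fp_from_levels(sample(0:100, 10, TRUE)))
  names(fps) <- letters[1:7]
  tree <- hierarchical_cluster(distance_matrix(fps))
  phy <- ape::read.tree(text = export_newick(tree))
  expect_setequal(phy$tip.label, letters[1:7])
  expect_equal(ape::dist.topo(ape::unroot(phy),
                              ape::unroot(ape::as.phylo(tree$hclust))), 0,
               ignore_attr = TRUE)
})
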