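test_that("rank-2 data is fully explained by two components", {
  set.seed(3)
  a <- matrix(rnorm(12), 6, 2)
  b <- matrix(rnorm(32), 2, 16)
  m <- a %*% b + 5
  rownames(m) <- paste0("Cin_veru_", sprintf("%02d", 1:6))
  tbl <- make_conc_table(abs(m), rep("C. verum", 6))
  ord <- pca_ordination(tbl, scaling = "center")
  expect_equal(sum(ord$var_explained_pct[1:2]), 100, tolerance = 1e-8)
})

test_that("variance percentages are sane and reconstruction is exact", {
  ord <- pca_ordination(load_concentration_table())
  v <- ord$var_explained_pct
  expect_true(all(diff(v) <= 1e-10))
  expect_true(all(v >= 0))
  expect_lte(sum(v), 100 + 1e-6)
  expect_lte(length(v), 16)

  s <- as.matrix(ord$scores[, -(1:2)])
  l <- as.matrix(ord$loadings[, -1])
  expect_equal(unname(s %*% t(l)), unname(ord$scaled_matrix),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("ordination is invariant to sample order and sign-stabilized", {
  tbl <- load_concentration_table()
  ord1 <- pca_ordination(tbl)
  set.seed(10)
  ids <- unique(tbl$sample_id)
  perm_tbl <- tbl[order(match(tbl$sample_id, sample(ids))), ]
  ord2 <- pca_ordination(perm_tbl)
  expect_equal(ord1$var_explained_pct, ord2$var_explained_pct,
               tolerance = 1e-9)
  # sign convention: largest-|loading| per component is positive
  l <- as.matrix(ord1$loadings[, -1])
  expect_true(all(l[cbind(apply(abs(l), 2, which.max), seq_len(ncol(l)))] > 0))
})

test_that("zero-variance columns are dropped with a warning under autoscale", {
  m <- matrix(abs(rnorm(5 * 16)) + 1, 5, 16)
  m[, 4] <- 2 # constant column
  rownames(m) <- paste0("Cin_cass_", sprintf("%02d", 1:5))
  tbl <- make_conc_table(m, rep("C. cassia", 5))
  expect_warning(ord <- pca_ordination(tbl), "zero-variance")
  expect_equal(nrow(ord$loadings), 15)
})

test_that("the scaling sweep reports all standard options", {
  sw <- pca_scaling_sweep(load_concentration_table())
  expect_setequal(sw$scaling, c("none", "center", "autoscale", "pareto"))
  expect_true(all(sw$pc12_pct > 0 & sw$pc12_pct <= 100))
})

test_that("nearest-centroid calls separated cohorts perfectly", {
  coh <- generate_cohort(separated_profiles(), 4, toy_params(), seed = 31)
  q <- quantify_cohort(coh$spectra)
  calls <- nearest_centroid_classify(q)
  expect_true(all(calls$predicted == calls$species))
  loo <- nearest_centroid_classify(q, loo = TRUE)
  expect_equal(attr(loo, "accuracy"), 1)
})

test_that("ties between identical centroids break lexicographically", {
  m <- matrix(1, 4, 16)
  rownames(m) <- c("Cin_cass_01", "Cin_cass_02", "Cin_veru_01", "Cin_veru_02")
  tbl <- make_conc_table(m, c("C. cassia", "C. cassia",
                              "C. verum", "C. verum"))
  calls <- nearest_centroid_classify(tbl)
  expect_true(all(calls$predicted == "C. cassia"))
  expect_true(all(calls$tie))
})

test_that("species with fewer than 2 training samples are rejected", {
  m <- matrix(abs(rnorm(3 * 16)), 3, 16)
  rownames(m) <- c("Cin_cass_01", "Cin_cass_02", "Cin_veru_01")
  tbl <- make_conc_table(m, c("C. cassia", "C. cassia", "C. verum"))
  expect_error(nearest_centroid_classify(tbl),
               class = "cinnamr_bad_training")
})

test_that("authentication ratios compute and flag undefined denominators", {
  tbl <- load_concentration_table()
  r20 <- ratio_features(dplyr::filter(tbl, sample_id == "Cin_cass_20"))
  cc <- r20$value[r20$ratio == "coumarin:cinnamaldehyde"]
  expect_equal(cc, 9.2 / 0.35, tolerance = 1e-12)
  expect_equal(round(cc, 2), 26.29)

  # cinnamaldehyde is ND for Cin_cass_11 -> ratio undefined, no error
  r11 <- ratio_features(dplyr::filter(tbl, sample_id == "Cin_cass_11"))
  expect_false(r11$defined[r11$ratio == "coumarin:cinnamaldehyde"])
  expect_true(is.na(r11$value[r11$ratio == "coumarin:cinnamaldehyde"]))

  eq <- make_conc_table(matrix(2, 1, 16), "C. verum")
  req <- ratio_features(eq)
  ratios_only <- req[req$ratio != "eugenol", ]
  expect_true(all(ratios_only$value == 1))
})

test_that("tidy, glance and autoplot accessors work on fitted objects", {
  ord <- pca_ordination(load_concentration_table())
  td <- tidy(ord)
  expect_true(all(c("sample_id", "species", "PC1") %in% names(td)))
  gl <- glance(ord)
  expect_equal(gl$n_samples, 48)
  expect_equal(gl$pc12_pct, sum(ord$var_explained_pct[1:2]))
  expect_s3_class(autoplot(ord), "ggplot")

  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), NULL))
  tree <- hierarchical_cluster(d)
  expect_equal(nrow(tidy(tree)), 1)
  expect_equal(glance(tree)$n_leaves, 2)
})
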