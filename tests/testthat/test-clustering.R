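test_that("Euclidean distances match a double-loop oracle", {
  expr <- data.frame(sample_id = c("a", "b"), class_label = "X",
                     x = c(0, 3), y = c(0, 4))
  expect_equal(as.numeric(euclidean_distances(expr)), 5) # 3-4-5 triangle
  set.seed(12)
  e2 <- data.frame(sample_id = paste0("s", 1:6), class_label = "X",
                   m1 = rnorm(6), m2 = rnorm(6), m3 = rnorm(6))
  D <- as.matrix(euclidean_distances(e2))
  for (i in 1:6) for (j in 1:6) {
    ref <- sqrt(sum((unlist(e2[i, 3:5]) - unlist(e2[j, 3:5]))^2))
    expect_equal(D[i, j], ref, tolerance = 1e-12)
  }
  e2$m2[2] <- NA
  expect_error(euclidean_distances(e2), "s2")
})

test_that("WPGMA reproduces the hand-executed merge sequence", {
  lk <- wpgma_linkage(abc_dist())
  # merge (A,B) at 2; d(AB, C) = (4 + 6) / 2 = 5
  expect_equal(lk$height, c(2, 5))
  expect_equal(lk$merge[1, ], c(-1, -2))
  # two leaves at distance 3 -> single merge at 3
  d2 <- stats::as.dist(matrix(c(0, 3, 3, 0), 2,
                              dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(wpgma_linkage(d2)$height, 3)
  expect_error(wpgma_linkage(stats::dist(1)), "at least 2")
})

test_that("WPGMA and UPGMA agree with the base-R hierarchical clustering reference", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    d <- random_dist(n)
    lk <- wpgma_linkage(d)
    ref <- hclust(d, method = "mcquitty")
    expect_equal(sort(lk$height), sort(ref$height), tolerance = 1e-12)
    up <- wpgma_linkage(d, method = "upgma")
    ref2 <- hclust(d, method = "average")
    expect_equal(sort(up$height), sort(ref2$height), tolerance = 1e-12)
    # cut partitions match too (labels may differ -> compare co-membership)
    for (k in c(2, n - 1)) {
      mine <- cut_tree(lk, k)
      theirs <- cutree(ref, k)
      expect_identical(outer(mine, mine, "=="), outer(theirs, theirs, "=="))
    }
  }
})

test_that("merge heights are non-decreasing on metric inputs", {
  set.seed(33)
  for (i in 1:20) {
    lk <- wpgma_linkage(random_dist(sample(4:10, 1)))
    expect_true(all(diff(lk$height) >= -1e-12))
  }
})

test_that("sample order does not change merge heights or performance", {
  set.seed(55)
  expr <- data.frame(sample_id = paste0("s", 1:9),
                     class_label = rep(c("CTR", "A", "B"), each = 3),
                     m1 = rnorm(9, rep(c(0, 2, 4), each = 3), 0.2),
                     m2 = rnorm(9, rep(c(0, -2, 1), each = 3), 0.2))
  perm <- sample(9)
  lk1 <- wpgma_linkage(euclidean_distances(expr))
  lk2 <- wpgma_linkage(euclidean_distances(expr[perm, ]))
  expect_equal(sort(lk1$height), sort(lk2$height))
  p1 <- cluster_performance(cut_tree(lk1, 3), expr$class_label, "CTR")
  p2 <- cluster_performance(cut_tree(lk2, 3), expr$class_label[perm], "CTR")
  expect_equal(p1$per_class, p2$per_class)
})

test_that("tree cutting spans the trivial cuts and nests", {
  set.seed(8)
  d <- random_dist(7)
  lk <- wpgma_linkage(d)
  expect_equal(length(unique(cut_tree(lk, 1))), 1L)
  expect_equal(length(unique(cut_tree(lk, 7))), 7L)
  expect_error(cut_tree(lk, 0), "between")
  # k-cut refines the (k-1)-cut
  for (k in 2:7) {
    fine <- cut_tree(lk, k); coarse <- cut_tree(lk, k - 1)
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
  }
  # the 3-leaf example at k = 2 gives {A,B} vs {C}
  cl <- cut_tree(wpgma_linkage(abc_dist()), 2)
  expect_equal(unname(cl[c("A", "B")]), c(1, 1))
  expect_false(cl[["C"]] == cl[["A"]])
})

test_that("cluster performance scores sensitivity, specificity and pooled rates", {
  # perfect clustering
  p <- cluster_performance(c(1, 1, 2, 2), c("CTR", "CTR", "D", "D"), "CTR")
  expect_equal(p$per_class$sensitivity_percent, c(100, 100))
  expect_equal(p$specificity_percent, 100)
  expect_equal(p$pooled_sensitivity_percent, 100)
  # 19 of 20 positives recovered -> 95%
  truth <- c(rep("D", 20), rep("CTR", 5))
  labels <- c(rep(1, 19), 2, rep(2, 5))
  p2 <- cluster_performance(labels, truth, "CTR")
  expect_equal(p2$per_class$sensitivity_percent[p2$per_class$class == "D"], 95)
  # degenerate single cluster mapped to the larger cohort
  p3 <- cluster_performance(rep(1, 6), c(rep("CTR", 4), "D", "D"), "CTR")
  expect_equal(p3$specificity_percent, 100)
  expect_equal(p3$per_class$sensitivity_percent[p3$per_class$class == "D"], 0)
  expect_error(cluster_performance(1:3, c("a", "b")), "length")
})
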