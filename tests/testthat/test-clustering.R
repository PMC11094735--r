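test_that("molecule distances are Euclidean row distances", {
  vals <- matrix(c(0, 3, 0, 4), 2, 2,
                 dimnames = list(c("X", "Y"), c("A", "B")))
  m <- fe_matrix(vals)
  expect_equal(as.numeric(molecule_distance_matrix(m)), 5)
  expect_equal(as.numeric(molecule_distance_matrix(m, "rms")), 5 / sqrt(2))

  set.seed(8)
  x <- matrix(rnorm(30), 6, 5,
              dimnames = list(paste0("m", 1:6), paste0("s", 1:5)))
  d <- as.matrix(molecule_distance_matrix(fe_matrix(x)))
  for (i in 1:6) for (j in 1:6)
    expect_equal(d[i, j], sqrt(sum((x[i, ] - x[j, ])^2)))
})

test_that("identical fingerprints are at distance zero and merge first", {
  x <- matrix(rnorm(20), 4, 5)
  x[2, ] <- x[1, ]
  rownames(x) <- paste0("m", 1:4); colnames(x) <- paste0("s", 1:5)
  d <- molecule_distance_matrix(fe_matrix(x))
  expect_equal(as.matrix(d)["m1", "m2"], 0)
  tree <- ward_linkage(d)
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))
  expect_equal(tree$height[1], 0)
})

test_that("two points merge at their distance; far pairs merge before the
           cross merge", {
  x <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  tree <- ward_linkage(stats::dist(x))
  expect_equal(tree$height, 5)

  y <- rbind(c(0, 0), c(0, 0.1), c(10, 0), c(10, 0.1))
  rownames(y) <- paste0("p", 1:4)
  tree <- ward_linkage(stats::dist(y))
  sigs <- hclust_signatures(tree)
  expect_setequal(sigs[1:2], c("1,2", "3,4"))
  expect_equal(sigs[3], "1,2,3,4")
})

test_that("Ward merge sequence and heights match the exhaustive oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    rownames(x) <- paste0("i", seq_len(n))
    tree <- ward_linkage(stats::dist(x))
    orc <- oracle_ward(x)
    expect_identical(hclust_signatures(tree), orc$signatures)
    expect_equal(tree$height, orc$heights, tolerance = 1e-9)
  }
})

test_that("Ward heights are monotone and cuts form a laminar family", {
  set.seed(7)
  x <- matrix(rnorm(60), 12, 5)
  rownames(x) <- paste0("m", 1:12)
  tree <- ward_linkage(stats::dist(x))
  expect_true(all(diff(tree$height) >= -1e-12))
  for (k in 1:11) {
    pk <- cut_tree(tree, k)
    pk1 <- cut_tree(tree, k + 1)
    # k+1 refines k: each k+1 cluster sits inside one k cluster, and
    # exactly one k cluster is split in two
    tab <- table(pk, pk1)
    expect_true(all(colSums(tab > 0) == 1))
    expect_equal(sum(rowSums(tab > 0) == 2), 1)
  }
  expect_equal(unname(cut_tree(tree, 12)), 1:12)
  expect_true(all(cut_tree(tree, 1) == 1))
  expect_error(cut_tree(tree, 0), "out of range")
})

test_that("clustering is invariant to row order up to relabeling", {
  sim <- default_sim(seed = 5)
  m <- sim$matrix
  perm <- sample(m$molecule_ids)
  mp <- fe_subset(m, molecules = perm)
  p1 <- cut_tree(ward_linkage(molecule_distance_matrix(m)), 3)
  p2 <- cut_tree(ward_linkage(molecule_distance_matrix(mp)), 3)
  expect_equal(adjusted_rand_index(p1, p2), 1)
  k1 <- kmeans_partition(m, 3, seed = 2)$partition
  k2 <- kmeans_partition(mp, 3, seed = 2)$partition
  expect_equal(adjusted_rand_index(k1, k2), 1)
})

test_that("rms normalization rescales heights but not the merge order", {
  sim <- default_sim(seed = 2)
  t1 <- ward_linkage(molecule_distance_matrix(sim$matrix))
  t2 <- ward_linkage(molecule_distance_matrix(sim$matrix, "rms"))
  expect_identical(hclust_signatures(t1), hclust_signatures(t2))
  expect_equal(t2$height, t1$height / sqrt(33), tolerance = 1e-12)
})

test_that("k-means recovers separated blobs and degenerates correctly", {
  x <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 30), 10, 2))
  rownames(x) <- paste0("p", 1:20)
  km <- kmeans_partition(x, 2, seed = 4)
  expect_equal(adjusted_rand_index(km$partition, rep(1:2, each = 10)), 1)

  kn <- kmeans_partition(x, 20, seed = 4)
  expect_equal(kn$inertia, 0)
  expect_error(kmeans_partition(x, 21), "exceeds")
})

test_that("k-means and Ward agree on strongly separated planted groups", {
  sim <- default_sim(seed = 9)
  pw <- cut_tree(ward_linkage(molecule_distance_matrix(sim$matrix)), 3)
  pk <- kmeans_partition(sim$matrix, 3, seed = 9)$partition
  expect_equal(adjusted_rand_index(pw, pk), 1)
  expect_equal(adjusted_rand_index(pk, sim$planted$molecule_group), 1)
})

test_that("the inertia elbow curve is non-increasing and finds k = 3", {
  sim <- default_sim(seed = 12)
  curve <- inertia_curve(sim$matrix, ks = 1:8, seed = 3)
  expect_true(all(diff(curve$inertia) <= 1e-8))
  expect_true(all(curve$inertia >= 0))
  expect_equal(curve$suggested_k, 3)
})

test_that("PCA spectrum identifies planted dimensionality", {
  # identical rows: nothing above noise after centering
  x <- matrix(5, 6, 4, dimnames = list(paste0("m", 1:6), paste0("s", 1:4)))
  pv <- pca_variance(x)
  expect_equal(pv$n_components_estimate, 0L)
  expect_true(all(pv$explained_variance_ratio == 0))

  # planted rank-1 structure dominates
  set.seed(30)
  u <- rnorm(20); v <- rnorm(10)
  x1 <- outer(u, v) + matrix(rnorm(200, sd = 1e-3), 20, 10)
  rownames(x1) <- paste0("m", 1:20); colnames(x1) <- paste0("s", 1:10)
  pv1 <- pca_variance(x1)
  expect_gt(pv1$explained_variance_ratio[1], 0.99)
  expect_equal(pv1$n_components_estimate, 1L)
  expect_true(all(diff(pv1$explained_variance_ratio) <= 1e-12))

  # the default synthetic study has three dominant components
  pv3 <- pca_variance(default_sim(seed = 4)$matrix)
  expect_equal(pv3$n_components_estimate, 3L)
  expect_gt(sum(pv3$explained_variance_ratio[1:3]), 0.95)
})

test_that("representatives are the members closest to their centroid", {
  x <- rbind(a = c(0, 0), b = c(2, 0), c = c(1, 10), d = c(1, 0))
  colnames(x) <- c("s1", "s2")
  part <- c(a = 1, b = 1, d = 1, c = 2)
  reps <- select_representatives(x, part)
  expect_identical(as.character(reps), c("d", "c"))  # d is the centroid
  # tie: a and b equidistant from centroid when d is removed
  reps2 <- select_representatives(x[c("a", "b", "c"), ],
                                  c(a = 1, b = 1, c = 2))
  expect_identical(as.character(reps2[1]), "a")  # input order breaks ties
  expect_error(select_representatives(x, part[1:2]), "exactly")
})

test_that("newick export preserves leaves and cluster structure", {
  sim <- default_sim(seed = 6)
  tree <- ward_linkage(molecule_distance_matrix(sim$matrix))
  nwk <- as_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, sim$matrix$molecule_ids)
  p <- withr::local_tempfile(fileext = ".nwk")
  as_newick(tree, p)
  expect_true(file.exists(p))
})
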