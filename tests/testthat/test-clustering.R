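test_that("Jaccard distance matches hand-enumerated set overlaps", {
  expect_equal(jaccard_distance(c("GH2"), c("GH147")), 1.0)
  expect_equal(jaccard_distance(c("GH13_8", "GH77", "Sulf"),
                                c("GH13_8", "GH77")), 1 - 2 / 3)
  expect_equal(jaccard_distance(c("A", "B", "C"), c("A", "B", "C")), 0)
  # copy-aware (Ruzicka): 1 - sum(min)/sum(max)
  expect_equal(jaccard_distance(c(A = 2L, B = 1L), c(A = 1L, C = 1L),
                                mode = "copy_aware"), 1 - 1 / 4)
  expect_error(jaccard_distance(character(0), c("A")), "empty")
})

test_that("pairwise Jaccard properties hold on random compositions", {
  set.seed(7)
  for (rep in 1:50) {
    m <- random_matrix(2, features = LETTERS[1:8], max_copies = 3L)
    a <- m[1, ][m[1, ] > 0]; b <- m[2, ][m[2, ] > 0]
    for (mode in c("presence", "copy_aware")) {
      d_ab <- jaccard_distance(a, b, mode)
      expect_equal(d_ab, jaccard_distance(b, a, mode))
      expect_gte(d_ab, 0); expect_lte(d_ab, 1)
      expect_equal(jaccard_distance(a, a, mode), 0)
    }
  }
})

test_that("matrix distances agree with the pairwise definition", {
  set.seed(8)
  m <- random_matrix(12, features = LETTERS[1:6], max_copies = 3L)
  for (mode in c("presence", "copy_aware")) {
    D <- as.matrix(composition_distances(m, mode))
    for (i in 1:11) for (j in (i + 1):12) {
      expect_equal(D[i, j],
                   jaccard_distance(m[i, ][m[i, ] > 0], m[j, ][m[j, ] > 0],
                                    mode))
    }
  }
})

test_that("average-linkage merges match a pen-and-paper UPGMA oracle", {
  # three items at mutual distance 1: both merges at height 1
  d3 <- stats::as.dist(matrix(1, 3, 3) - diag(3))
  t3 <- linkage_tree(d3)
  expect_equal(t3$height, c(1, 1))
  # hand-worked 4x4 instance
  D <- matrix(0, 4, 4)
  D[1, 2] <- D[2, 1] <- 0.2
  D[1, 3] <- D[3, 1] <- 0.6; D[2, 3] <- D[3, 2] <- 0.8
  D[1, 4] <- D[4, 1] <- 1.0; D[2, 4] <- D[4, 2] <- 0.9
  D[3, 4] <- D[4, 3] <- 0.4
  tree <- linkage_tree(stats::as.dist(D))
  expect_equal(sort(tree$height), oracle_upgma_heights(D))
  # random instances
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    M <- matrix(stats::runif(n * n), n, n); M <- (M + t(M)) / 2; diag(M) <- 0
    expect_equal(sort(linkage_tree(stats::as.dist(M))$height),
                 oracle_upgma_heights(M), tolerance = 1e-12)
  }
  # identical items merge first at height 0
  m <- toy_matrix(list(c("A", "B"), c("A", "B"), c("C")))
  t0 <- linkage_tree(composition_distances(m, "presence"))
  expect_equal(min(t0$height), 0)
  # single item: degenerate leaf, not an error
  leaf <- linkage_tree(stats::dist(matrix(0, 1, 2)))
  expect_equal(cut_at_mismatch(leaf, 0)$n_clusters, 1L)
})

test_that("the union-find tree cut agrees with stats::cutree", {
  set.seed(59)
  for (rep in 1:20) {
    n <- sample(3:20, 1)
    M <- matrix(stats::runif(n * n), n, n); M <- (M + t(M)) / 2; diag(M) <- 0
    tree <- stats::hclust(stats::as.dist(M), method = "average")
    for (h in stats::runif(3)) {
      a <- stats::cutree(tree, h = h)
      b <- cut_at_mismatch(tree, 100 * h)$labels
      expect_equal(length(unique(paste(a, b))), length(unique(a)))
    }
  }
})

test_that("tree cuts at mismatch thresholds behave as specified", {
  m <- toy_matrix(list(c("A", "B"), c("A", "B"), c("A", "C")))
  expect_equal(cluster_compositions(m, 0)$n_clusters, 2L)
  expect_equal(cluster_compositions(m, 100)$n_clusters, 1L)
  # d({A,B},{A,C}) = 2/3: separate at 50%, together at 70%
  m2 <- toy_matrix(list(c("A", "B"), c("A", "C")))
  expect_equal(cluster_compositions(m2, 50)$n_clusters, 2L)
  expect_equal(cluster_compositions(m2, 70)$n_clusters, 1L)
  # cut rule is inclusive: merge height exactly at the threshold joins
  expect_equal(cluster_compositions(m2, 100 * 2 / 3)$n_clusters, 1L)
})

test_that("0% clustering equals exact-equality grouping", {
  set.seed(13)
  for (rep in 1:25) {
    m <- random_matrix(sample(4:40, 1), features = LETTERS[1:5])
    cl <- cluster_compositions(m, 0, "presence")
    oracle <- oracle_equal_groups(m, "presence")
    expect_equal(cl$n_clusters, length(unique(oracle)))
    # same partition, not just same count
    expect_equal(length(unique(paste(cl$labels, oracle))),
                 cl$n_clusters)
    expect_equal(cl$n_clusters, enumerate_unique(m, "presence")$n_unique)
  }
})

test_that("cluster counts never increase with the mismatch threshold", {
  set.seed(17)
  for (rep in 1:10) {
    m <- random_matrix(sample(10:50, 1), features = LETTERS[1:6])
    curve <- unique_vs_threshold(m, thresholds = seq(0, 100, by = 10))
    expect_true(all(diff(curve$n_clusters) <= 0))
    expect_equal(curve$n_clusters[1], enumerate_unique(m)$n_unique)
    expect_equal(curve$n_clusters[curve$mismatch_percent == 100], 1L)
  }
})

test_that("deduplicated clustering matches clustering all rows", {
  set.seed(19)
  m <- random_matrix(40, features = LETTERS[1:5])
  for (t in c(0, 20, 40)) {
    dedup <- cluster_compositions(m, t, "presence")
    # direct clustering of all rows, duplicates included
    rownames(m) <- sprintf("L%03d", seq_len(nrow(m)))
    full_tree <- linkage_tree(composition_distances(m, "presence"))
    full <- cut_at_mismatch(full_tree, t)
    expect_equal(dedup$n_clusters, full$n_clusters)
    if (t == 0) {
      # at 0% the partitions are identical up to label renaming; at
      # higher cuts tied merge heights may be resolved in a different
      # order by the two routes, so only the counts are compared
      expect_equal(length(unique(paste(dedup$labels,
                                       full$labels[names(dedup$labels)]))),
                   dedup$n_clusters)
    }
  }
})

test_that("perturbed archetypes collapse into their parents at 25%", {
  # 10 archetypes of 8 features; each perturbed copy swaps one feature,
  # d(parent, variant) = 2/9 < 0.25
  set.seed(23)
  pool <- paste0("F", 1:40)
  arch <- lapply(1:10, function(i) sample(pool, 8))
  comps <- list()
  for (a in arch) {
    comps <- c(comps, list(a, a))
    variant <- a
    variant[sample(8, 1)] <- sample(setdiff(pool, a), 1)
    comps <- c(comps, list(variant))
  }
  m <- toy_matrix(comps)
  n0 <- cluster_compositions(m, 0)$n_clusters
  n25 <- cluster_compositions(m, 25)$n_clusters
  expect_gt(n0, n25)
  expect_equal(n25, 10L)
})
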