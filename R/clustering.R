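# Jaccard clustering of compositions ------------------------------------------
#
# Compositions are compared by Jaccard distance (presence/absence) or its
# weighted Ruzicka form (copy-aware), clustered with average linkage
# (UPGMA) and the tree cut at a mismatch threshold expressed as a
# percentage: cut height h = mismatch_percent / 100. Clustering operates
# on the deduplicated set of unique compositions; membership maps back to
# all PULs, which leaves cluster counts unchanged and the 0% cut equal to
# exact-equality grouping.

# Tolerance added to the cut height so that merges at exactly h are
# included despite floating-point height error.
CUT_EPS <- 1e-9

#' Jaccard distance between two composition vectors
#'
#' Presence mode: `1 - |a n b| / |a u b|` on feature sets. Copy-aware
#' mode: the weighted (Ruzicka) form
#' `1 - sum(min(a_f, b_f)) / sum(max(a_f, b_f))`.
#'
#' @param a,b named integer vectors (feature -> count) or character
#'   vectors of feature labels (presence mode only).
#' @param mode `"presence"` or `"copy_aware"`.
#' @return Distance in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b, mode = c("presence", "copy_aware")) {
  mode <- match.arg(mode)
  if (is.character(a)) a <- stats::setNames(rep(1L, length(unique(a))), unique(a))
  if (is.character(b)) b <- stats::setNames(rep(1L, length(unique(b))), unique(b))
  if (length(a) == 0L || length(b) == 0L) {
    stop("Jaccard distance is undefined for an empty composition",
         call. = FALSE)
  }
  feats <- union(names(a), names(b))
  av <- stats::setNames(rep(0L, length(feats)), feats); av[names(a)] <- a
  bv <- stats::setNames(rep(0L, length(feats)), feats); bv[names(b)] <- b
  if (mode == "presence") { av <- pmin(av, 1L); bv <- pmin(bv, 1L) }
  1 - sum(pmin(av, bv)) / sum(pmax(av, bv))
}

#' Pairwise composition distances for a matrix
#'
#' Thin wrapper over [vegan::vegdist()] (`method = "jaccard"`, binary in
#' presence mode; the quantitative form equals the Ruzicka weighted
#' Jaccard).
#'
#' @param matrix composition matrix (rows = loci).
#' @param mode `"presence"` or `"copy_aware"`.
#' @return A `dist` object.
#' @export
composition_distances <- function(matrix, mode = c("presence", "copy_aware")) {
  mode <- match.arg(mode)
  if (any(rowSums(matrix) == 0)) {
    stop("composition matrix has empty rows", call. = FALSE)
  }
  vegan::vegdist(matrix, method = "jaccard", binary = (mode == "presence"))
}

#' Average-linkage tree over composition distances
#'
#' UPGMA merge tree via [stats::hclust()] (`method = "average"`);
#' deterministic for a given distance matrix. A single item yields a
#' degenerate single-leaf tree rather than an error.
#'
#' @param distances a `dist` object.
#' @return An `hclust` tree, or a list of class `pul_leaf` for one item.
#' @export
linkage_tree <- function(distances) {
  n <- attr(distances, "Size")
  if (is.null(n)) stop("linkage_tree() expects a dist object", call. = FALSE)
  if (n < 2L) {
    return(structure(list(labels = attr(distances, "Labels"), n = n),
                     class = "pul_leaf"))
  }
  stats::hclust(distances, method = "average")
}

# Cut an hclust tree at height h (inclusive, with CUT_EPS slack) by
# union-find over the merge list. Unlike stats::cutree this tolerates the
# epsilon-scale height inversions that floating-point average linkage can
# produce.
cut_tree_labels <- function(tree, h) {
  if (inherits(tree, "pul_leaf")) {
    lab <- if (is.null(tree$labels)) as.character(seq_len(tree$n)) else tree$labels
    return(stats::setNames(rep(1L, tree$n), lab))
  }
  merge <- tree$merge
  n <- nrow(merge) + 1L
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  node_rep <- integer(nrow(merge))
  for (k in seq_len(nrow(merge))) {
    ra <- if (merge[k, 1L] < 0L) -merge[k, 1L] else node_rep[merge[k, 1L]]
    rb <- if (merge[k, 2L] < 0L) -merge[k, 2L] else node_rep[merge[k, 2L]]
    if (tree$height[k] <= h + CUT_EPS) parent[find(rb)] <- find(ra)
    node_rep[k] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))
  names(labels) <- tree$labels
  labels
}

#' Cut a composition tree at a mismatch threshold
#'
#' Clusters are subtrees whose merge heights do not exceed
#' `mismatch_percent / 100` (inclusive), so a 0% cut reproduces
#' exact-equality grouping.
#'
#' @param tree tree from [linkage_tree()].
#' @param mismatch_percent allowed composition mismatch, in `[0, 100]`.
#' @return A `pul_clusters`: list with `params`, `labels` (named integer
#'   vector item -> cluster id) and `n_clusters`.
#' @export
cut_at_mismatch <- function(tree, mismatch_percent) {
  stopifnot(mismatch_percent >= 0, mismatch_percent <= 100)
  labels <- cut_tree_labels(tree, mismatch_percent / 100)
  structure(list(
    params = list(mismatch_percent = mismatch_percent, linkage = "average"),
    labels = labels,
    n_clusters = length(unique(labels))
  ), class = "pul_clusters")
}

#' Cluster the rows of a composition matrix
#'
#' Deduplicates rows to their unique compositions, builds the
#' average-linkage Jaccard tree over those, cuts at the requested
#' mismatch threshold, and maps cluster membership back to every row.
#'
#' @inheritParams composition_distances
#' @inheritParams cut_at_mismatch
#' @return A `pul_clusters` with one label per matrix row.
#' @export
cluster_compositions <- function(matrix, mismatch_percent,
                                 mode = c("presence", "copy_aware")) {
  mode <- match.arg(mode)
  keys <- composition_keys(matrix, mode)
  uniq <- !duplicated(keys)
  um <- matrix[uniq, , drop = FALSE]
  rownames(um) <- keys[uniq]
  tree <- linkage_tree(composition_distances(um, mode))
  cut <- cut_at_mismatch(tree, mismatch_percent)
  labels <- cut$labels[keys]
  names(labels) <- rownames(matrix)
  structure(list(
    params = list(mismatch_percent = mismatch_percent, linkage = "average",
                  mode = mode),
    labels = labels,
    n_clusters = length(unique(labels))
  ), class = "pul_clusters")
}

#' Unique-PUL counts over a sweep of mismatch thresholds
#'
#' @inheritParams composition_distances
#' @param thresholds ascending mismatch percentages (default 0-50 by 10).
#' @return data.frame with `mismatch_percent` and `n_clusters`
#'   (non-increasing; the value at 0 equals [enumerate_unique()]'s
#'   `n_unique`).
#' @export
unique_vs_threshold <- function(matrix, thresholds = seq(0, 50, by = 10),
                                mode = c("presence", "copy_aware")) {
  mode <- match.arg(mode)
  stopifnot(!is.unsorted(thresholds))
  keys <- composition_keys(matrix, mode)
  uniq <- !duplicated(keys)
  um <- matrix[uniq, , drop = FALSE]
  tree <- linkage_tree(composition_distances(um, mode))
  n <- vapply(thresholds, function(t) {
    length(unique(cut_tree_labels(tree, t / 100)))
  }, integer(1))
  data.frame(mismatch_percent = thresholds, n_clusters = n)
}
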