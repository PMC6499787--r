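# Shared fixtures and independent oracles.

# Build a gene table from a compact spec: each element "category" or
# "category:family" or "category:family:strand" / "category::strand".
toy_genes <- function(..., genome = "G1", replicon = "R1") {
  specs <- c(...)
  parts <- strsplit(specs, ":", fixed = TRUE)
  rows <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    data.frame(genome_id = genome, replicon_id = replicon,
               gene_ordinal = i,
               strand = if (length(p) >= 3L && nzchar(p[3L])) p[3L] else "+",
               category = p[1L],
               family_label = if (length(p) >= 2L) p[2L] else "",
               protein_id = sprintf("p%03d", i),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Wrap a gene table as a single pre-classified locus.
toy_locus <- function(genes, id = "L1") {
  locus <- list(locus_id = id, genome_id = genes$genome_id[1],
                replicon_id = genes$replicon_id[1], genes = genes,
                n_sus_pairs = sum(pulscape::find_sus_pairs(genes)$n_pairs),
                entry = "sus", locus_class = NA_character_)
  class(locus) <- "pul_locus"
  locus$locus_class <- pulscape::classify_locus(locus)
  locus
}

# Composition matrix from a list of feature vectors (presence) or named
# count vectors (copy-aware).
toy_matrix <- function(comps) {
  vecs <- lapply(comps, function(cc) {
    if (is.character(cc)) stats::setNames(rep(1L, length(cc)), cc) else cc
  })
  names(vecs) <- sprintf("L%03d", seq_along(vecs))
  feats <- sort(unique(unlist(lapply(vecs, names))))
  m <- matrix(0L, length(vecs), length(feats),
              dimnames = list(names(vecs), feats))
  for (i in seq_along(vecs)) m[i, names(vecs[[i]])] <- as.integer(vecs[[i]])
  m
}

# Brute-force grouping oracle: pairwise exact-equality of rows.
oracle_equal_groups <- function(m, mode = "presence") {
  n <- nrow(m)
  labels <- integer(n)
  next_label <- 0L
  for (i in seq_len(n)) {
    found <- 0L
    for (j in seq_len(i - 1L)) {
      eq <- if (mode == "presence") all((m[i, ] > 0) == (m[j, ] > 0))
            else all(m[i, ] == m[j, ])
      if (eq) { found <- labels[j]; break }
    }
    if (found == 0L) { next_label <- next_label + 1L; found <- next_label }
    labels[i] <- found
  }
  labels
}

# Recursive, definition-based OSA distance with memoisation; independent
# of the package's dynamic-programming implementation.
oracle_osa <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == 0L) j else if (j == 0L) i else {
      cost <- if (a[i] == b[j]) 0L else 1L
      v <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
               rec(i - 1L, j - 1L) + cost)
      if (i > 1L && j > 1L && a[i] == b[j - 1L] && a[i - 1L] == b[j]) {
        v <- min(v, rec(i - 2L, j - 2L) + 1L)
      }
      v
    }
    memo[[key]] <- val
    val
  }
  rec(length(a), length(b))
}

# Pen-and-paper UPGMA: iteratively merge the closest pair, averaging
# distances weighted by cluster size; returns sorted merge heights.
oracle_upgma_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); bd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii < jj && D[active[ii], active[jj]] < bd) {
        bd <- D[active[ii], active[jj]]; best <- c(active[ii], active[jj])
      }
    }
    heights <- c(heights, bd)
    i <- best[1]; j <- best[2]
    new_d <- (sizes[i] * D[i, active] + sizes[j] * D[j, active]) /
      (sizes[i] + sizes[j])
    D[i, active] <- new_d; D[active, i] <- new_d
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
    D[i, i] <- 0
  }
  sort(heights)
}

# Random composition matrix over a small alphabet.
random_matrix <- function(n, features = LETTERS[1:6], max_copies = 1L) {
  comps <- lapply(seq_len(n), function(i) {
    k <- sample(seq_along(features), 1L)
    f <- sample(features, k)
    stats::setNames(sample(seq_len(max_copies), k, replace = TRUE), f)
  })
  toy_matrix(comps)
}

# All strings of lengths 1..max_len over an alphabet.
all_strings <- function(alphabet, max_len) {
  out <- character(0)
  cur <- ""
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, apply(grid, 1L, paste, collapse = ""))
  }
  out
}
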