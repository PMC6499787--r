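# Locus detection and sorting -------------------------------------------------
#
# A PUL is anchored on a susC/susD gene pair: a susC and a susD at
# consecutive ordinals on the same strand. Tandem repeats (trsusCD) are
# maximal alternating runs C,D,C,D,... on one strand and are treated as a
# single multi-pair anchor. Loci are delimited by extending outward from
# each anchor over degradative genes, allowing at most `max_gap`
# intervening non-degradative genes.

#' Find susC/D pair anchors on one replicon
#'
#' Scans a position-sorted gene table of a single replicon for susC/susD
#' genes at consecutive ordinals on the same strand. Maximal alternating
#' runs (C,D,C,D,...) are merged into one multi-pair anchor; pairs are
#' accepted in either textual order (reverse-strand loci appear D-then-C
#' in a position-sorted table).
#'
#' @param genes data.frame of one replicon, ordered by `gene_ordinal`.
#' @return data.frame with columns `start`, `end` (row indices of the
#'   anchor span) and `n_pairs`; zero rows when no anchor exists.
#' @export
find_sus_pairs <- function(genes) {
  n <- nrow(genes)
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_pairs = integer(0))
  if (n == 0L) return(empty)
  is_sus <- genes$category %in% c("susC", "susD")
  out <- list()
  i <- 1L
  while (i <= n) {
    if (!is_sus[i]) { i <- i + 1L; next }
    j <- i
    while (j + 1L <= n &&
           is_sus[j + 1L] &&
           genes$strand[j + 1L] == genes$strand[j] &&
           genes$category[j + 1L] != genes$category[j] &&
           genes$gene_ordinal[j + 1L] == genes$gene_ordinal[j] + 1L) {
      j <- j + 1L
    }
    run_len <- j - i + 1L
    n_pairs <- run_len %/% 2L
    if (n_pairs >= 1L) {
      out[[length(out) + 1L]] <- c(start = i, end = j, n_pairs = n_pairs)
    }
    i <- j + 1L
  }
  if (length(out) == 0L) return(empty)
  as.data.frame(do.call(rbind, out))
}

# Orphan seeds: susC/susD genes not covered by any pair anchor. Orphans
# separated by <= max_gap non-sus genes merge into one seed, so that e.g.
# susC,<other>,susD forms a single (rejected) locus.
find_orphan_seeds <- function(genes, anchors, max_gap) {
  n <- nrow(genes)
  covered <- rep(FALSE, n)
  if (nrow(anchors) > 0L) {
    for (k in seq_len(nrow(anchors))) {
      covered[anchors$start[k]:anchors$end[k]] <- TRUE
    }
  }
  idx <- which(genes$category %in% c("susC", "susD") & !covered)
  if (length(idx) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_pairs = integer(0)))
  }
  starts <- idx[1L]
  ends <- idx[1L]
  if (length(idx) > 1L) {
    for (k in 2L:length(idx)) {
      gap <- genes$gene_ordinal[idx[k]] -
        genes$gene_ordinal[ends[length(ends)]] - 1L
      blocked <- nrow(anchors) > 0L &&
        any(anchors$start <= idx[k] - 1L & anchors$end >= ends[length(ends)] + 1L)
      if (gap <= max_gap && !blocked) {
        ends[length(ends)] <- idx[k]
      } else {
        starts <- c(starts, idx[k])
        ends <- c(ends, idx[k])
      }
    }
  }
  data.frame(start = starts, end = ends, n_pairs = 0L)
}

# Extend one seed outward over degradative genes, bridging at most
# max_gap consecutive non-degradative genes, without entering another
# seed's core span (`blocked`).
extend_seed <- function(genes, seed_start, seed_end, blocked, max_gap) {
  n <- nrow(genes)
  degr <- genes$category %in% DEGRADATIVE_CATEGORIES
  lo <- seed_start
  gap <- 0L
  p <- seed_start - 1L
  while (p >= 1L && gap <= max_gap && !blocked[p]) {
    if (degr[p]) { lo <- p; gap <- 0L } else gap <- gap + 1L
    p <- p - 1L
  }
  hi <- seed_end
  gap <- 0L
  p <- seed_end + 1L
  while (p <= n && gap <= max_gap && !blocked[p]) {
    if (degr[p]) { hi <- p; gap <- 0L } else gap <- gap + 1L
    p <- p + 1L
  }
  c(lo, hi)
}

# Resolve overlapping extensions of consecutive seeds: each contested
# gene goes to the nearer seed core, an exact midpoint to the upstream
# (lower-ordinal) seed. Endpoints are then trimmed back to degradative
# genes so loci never end on claimed-but-empty positions.
resolve_spans <- function(spans, seeds, degr) {
  k <- nrow(seeds)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      if (spans[i, 2L] >= spans[i + 1L, 1L]) {
        contested <- spans[i + 1L, 1L]:spans[i, 2L]
        d_up <- contested - seeds$end[i]
        d_down <- seeds$start[i + 1L] - contested
        to_up <- contested[d_up <= d_down]
        to_down <- contested[d_up > d_down]
        spans[i, 2L] <- max(c(seeds$end[i], to_up))
        spans[i + 1L, 1L] <- min(c(seeds$start[i + 1L], to_down))
      }
    }
  }
  for (i in seq_len(k)) {
    while (spans[i, 1L] < seeds$start[i] && !degr[spans[i, 1L]]) {
      spans[i, 1L] <- spans[i, 1L] + 1L
    }
    while (spans[i, 2L] > seeds$end[i] && !degr[spans[i, 2L]]) {
      spans[i, 2L] <- spans[i, 2L] - 1L
    }
  }
  spans
}

new_locus <- function(genes, lo, hi, n_pairs, entry = c("sus", "cazyme")) {
  entry <- match.arg(entry)
  g <- genes[lo:hi, , drop = FALSE]
  rownames(g) <- NULL
  locus <- list(
    locus_id = sprintf("%s.%s.L%05d", g$genome_id[1L], g$replicon_id[1L],
                       g$gene_ordinal[1L]),
    genome_id = g$genome_id[1L],
    replicon_id = g$replicon_id[1L],
    genes = g,
    n_sus_pairs = as.integer(n_pairs),
    entry = entry,
    locus_class = NA_character_
  )
  class(locus) <- "pul_locus"
  locus$locus_class <- classify_locus(locus)
  locus
}

#' Delimit loci around susC/D seeds on a gene table
#'
#' Splits the gene table by (genome, replicon), finds susC/D pair anchors
#' and orphan susC/D seeds, and extends each seed outward over degradative
#' genes (GH/PL/CE/sulfatase/peptidase), stopping when more than `max_gap`
#' consecutive non-degradative genes separate the frontier from the next
#' degradative gene. Competing seeds split genes at the midpoint (exact
#' midpoint to the upstream seed), so loci never overlap. Optionally also
#' returns clusters of CAZyme genes with no susC/D seed at all.
#'
#' @param genes a validated gene table (see [validate_gene_table()]).
#' @param max_gap maximum number of consecutive non-degradative genes
#'   bridged during extension (default 2).
#' @param include_cazyme_clusters also emit susC/D-less CAZyme clusters
#'   (class `CAZYME_CLUSTER_NO_SUSCD`)?
#' @return List of `pul_locus` objects, each already classified.
#' @export
build_loci <- function(genes, max_gap = 2L, include_cazyme_clusters = TRUE) {
  stopifnot(max_gap >= 0L)
  loci <- list()
  split_key <- paste(genes$genome_id, genes$replicon_id, sep = "\r")
  for (chunk in split(seq_len(nrow(genes)), split_key)) {
    g <- genes[chunk, , drop = FALSE]
    rownames(g) <- NULL
    anchors <- find_sus_pairs(g)
    orphans <- find_orphan_seeds(g, anchors, max_gap)
    seeds <- rbind(anchors, orphans)
    if (nrow(seeds) > 0L) {
      seeds <- seeds[order(seeds$start), , drop = FALSE]
      core <- rep(FALSE, nrow(g))
      for (k in seq_len(nrow(seeds))) core[seeds$start[k]:seeds$end[k]] <- TRUE
      spans <- matrix(0L, nrow(seeds), 2L)
      for (k in seq_len(nrow(seeds))) {
        blocked <- core
        blocked[seeds$start[k]:seeds$end[k]] <- FALSE
        spans[k, ] <- extend_seed(g, seeds$start[k], seeds$end[k], blocked,
                                  max_gap)
      }
      spans <- resolve_spans(spans, seeds,
                             g$category %in% DEGRADATIVE_CATEGORIES)
      for (k in seq_len(nrow(seeds))) {
        loci[[length(loci) + 1L]] <-
          new_locus(g, spans[k, 1L], spans[k, 2L], seeds$n_pairs[k], "sus")
      }
    } else {
      spans <- matrix(0L, 0L, 2L)
    }
    if (include_cazyme_clusters) {
      in_locus <- rep(FALSE, nrow(g))
      if (nrow(spans) > 0L) {
        for (k in seq_len(nrow(spans))) in_locus[spans[k, 1L]:spans[k, 2L]] <- TRUE
      }
      caz <- which(g$category %in% CAZYME_CATEGORIES & !in_locus)
      if (length(caz) > 0L) {
        run_start <- caz[1L]; run_end <- caz[1L]
        flush <- function(s, e) {
          loci[[length(loci) + 1L]] <<- new_locus(g, s, e, 0L, "cazyme")
        }
        if (length(caz) > 1L) {
          for (k in 2L:length(caz)) {
            if (caz[k] - run_end - 1L <= max_gap &&
                !any(in_locus[run_end:caz[k]])) {
              run_end <- caz[k]
            } else {
              flush(run_start, run_end)
              run_start <- caz[k]; run_end <- caz[k]
            }
          }
        }
        flush(run_start, run_end)
      }
    }
  }
  loci
}

#' Classify one locus
#'
#' Classification follows the sorting pipeline for susC/D-containing loci:
#' a locus with no same-strand adjacent susC/susD pair is `REJECTED`; a
#' merged tandem anchor with two or more pairs gives `TRSUSCD_PUL`;
#' otherwise a locus without any GH/PL/CE gene is `NO_CAZYME` and the rest
#' are `PUL`. Loci built around CAZyme runs with no susC/D gene at all
#' (the separate entry path of [build_loci()]) are
#' `CAZYME_CLUSTER_NO_SUSCD`.
#'
#' @param locus a `pul_locus`.
#' @return One of `r paste(LOCUS_CLASSES, collapse = ", ")`.
#' @export
classify_locus <- function(locus) {
  g <- locus$genes
  if (is.null(g) || nrow(g) == 0L) {
    stop("cannot classify an empty locus", call. = FALSE)
  }
  has_sus <- any(g$category %in% c("susC", "susD"))
  has_caz <- any(g$category %in% CAZYME_CATEGORIES)
  if (!has_sus) return("CAZYME_CLUSTER_NO_SUSCD")
  n_pairs <- locus$n_sus_pairs
  if (is.null(n_pairs) || is.na(n_pairs)) {
    n_pairs <- sum(find_sus_pairs(g)$n_pairs)
  }
  if (n_pairs < 1L) return("REJECTED")
  if (n_pairs >= 2L) return("TRSUSCD_PUL")
  if (!has_caz) return("NO_CAZYME")
  "PUL"
}

#' Sort a dataset into classified loci
#'
#' Runs locus delimitation and classification over a whole dataset and
#' tallies the classes: rejected loci (no adjacent same-strand susC/D
#' pair), tandem-repeat susC/D loci, susC/D loci without any CAZyme,
#' canonical PULs, and (optionally) CAZyme clusters lacking susC/D.
#'
#' @param dataset a `pul_dataset` from [read_gene_table()] or
#'   [simulate_dataset()], or a bare validated gene table.
#' @inheritParams build_loci
#' @return A `pul_sort`: list with `loci` (list of `pul_locus`), `table`
#'   (one row per locus: id, genome, replicon, class, `n_sus_pairs`,
#'   `has_cazyme`, gene span) and `summary` (class counts).
#' @export
sort_dataset <- function(dataset, max_gap = 2L,
                         include_cazyme_clusters = TRUE) {
  genes <- if (is.data.frame(dataset)) dataset else dataset$genes
  loci <- build_loci(genes, max_gap = max_gap,
                     include_cazyme_clusters = include_cazyme_clusters)
  tab <- loci_table(loci)
  cls <- tab$locus_class
  summary <- list(
    n_loci_total = nrow(tab),
    n_rejected = sum(cls == "REJECTED"),
    n_trsuscd = sum(cls == "TRSUSCD_PUL"),
    n_no_cazyme = sum(cls == "NO_CAZYME"),
    n_puls = sum(cls == "PUL"),
    n_cazyme_clusters_no_suscd = sum(cls == "CAZYME_CLUSTER_NO_SUSCD"),
    n_puls_for_composition = sum(cls == "PUL" |
                                   (cls == "TRSUSCD_PUL" & tab$has_cazyme))
  )
  structure(list(loci = loci, table = tab, summary = summary,
                 max_gap = max_gap),
            class = "pul_sort")
}

loci_table <- function(loci) {
  if (length(loci) == 0L) {
    return(data.frame(locus_id = character(0), genome_id = character(0),
                      replicon_id = character(0), locus_class = character(0),
                      n_sus_pairs = integer(0), n_genes = integer(0),
                      has_cazyme = logical(0), start_ordinal = integer(0),
                      end_ordinal = integer(0)))
  }
  do.call(rbind, lapply(loci, function(l) {
    data.frame(locus_id = l$locus_id, genome_id = l$genome_id,
               replicon_id = l$replicon_id, locus_class = l$locus_class,
               n_sus_pairs = l$n_sus_pairs, n_genes = nrow(l$genes),
               has_cazyme = any(l$genes$category %in% CAZYME_CATEGORIES),
               start_ordinal = min(l$genes$gene_ordinal),
               end_ordinal = max(l$genes$gene_ordinal),
               stringsAsFactors = FALSE)
  }))
}

#' Select the loci that enter the composition analysis
#'
#' Canonical PULs plus, by default, tandem-repeat susC/D loci that encode
#' at least one CAZyme (these are kept for the composition analysis while
#' a flag preserves their identity for tandem-specific statistics).
#'
#' @param sorted a `pul_sort` from [sort_dataset()].
#' @param include_trsuscd keep CAZyme-bearing tandem loci?
#' @return List of `pul_locus`.
#' @export
pul_loci <- function(sorted, include_trsuscd = TRUE) {
  keep <- vapply(sorted$loci, function(l) {
    l$locus_class == "PUL" ||
      (include_trsuscd && l$locus_class == "TRSUSCD_PUL" &&
         any(l$genes$category %in% CAZYME_CATEGORIES))
  }, logical(1))
  sorted$loci[keep]
}

#' @export
print.pul_sort <- function(x, ...) {
  s <- x$summary
  cat("susC/D locus sort:", s$n_loci_total, "loci\n")
  cat("  rejected (no adjacent same-strand pair):", s$n_rejected, "\n")
  cat("  tandem-repeat susC/D (trsusCD):         ", s$n_trsuscd, "\n")
  cat("  susC/D without CAZyme:                  ", s$n_no_cazyme, "\n")
  cat("  PULs:                                   ", s$n_puls, "\n")
  cat("  CAZyme clusters without susC/D:         ",
      s$n_cazyme_clusters_no_suscd, "\n")
  invisible(x)
}
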