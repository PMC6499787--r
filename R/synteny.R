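# Gene-order (synteny) scoring ------------------------------------------------
#
# Gene order in a PUL is translated into a string of single-character
# symbols, one per retained gene (CAZymes, sulfatases, peptidases, the
# susC/D transporters and regulators; everything else is ignored), and
# pairs of strings are compared with a normalized optimal-string-alignment
# (restricted Damerau-Levenshtein) similarity: 1 means identical order,
# values near 0 mean no order conservation.

SYNTENY_CATEGORIES <- c("GH", "PL", "CE", "sulfatase", "peptidase",
                        "susC", "susD", "regulator")

# Printable symbol pool for synteny alphabets (93 symbols).
SYMBOL_POOL <- strsplit(paste0(
  "abcdefghijklmnopqrstuvwxyzABCDEFGHIJKLMNOPQRSTUVWXYZ0123456789",
  "!#$%&()*+,-./:;<=>?@[]^_`{}~"), "")[[1]]

# Synteny feature key of one gene: (sub)family for CAZymes, broad class
# for sulfatases/peptidases, the category itself for susC/susD/regulator.
synteny_key <- function(category, family_label) {
  ifelse(category %in% CAZYME_CATEGORIES, family_label,
         ifelse(category == "sulfatase", SULF_FEATURE,
                ifelse(category == "peptidase", PEPT_FEATURE,
                       ifelse(category %in% c("susC", "susD", "regulator"),
                              category, NA_character_))))
}

#' Build a symbol map for a set of loci
#'
#' Assigns one printable character per retained feature over the union of
#' features in the given loci; susC and susD always receive distinct
#' symbols. The same map must be shared by all loci in one comparison.
#'
#' @param loci list of `pul_locus` objects.
#' @return Named character vector, feature key -> symbol.
#' @export
make_symbol_map <- function(loci) {
  keys <- unlist(lapply(loci, function(l) {
    synteny_key(l$genes$category, l$genes$family_label)
  }))
  keys <- sort(unique(keys[!is.na(keys)]))
  if (length(keys) > length(SYMBOL_POOL)) {
    stop("more than ", length(SYMBOL_POOL),
         " distinct features in one synteny comparison", call. = FALSE)
  }
  stats::setNames(SYMBOL_POOL[seq_along(keys)], keys)
}

#' Encode the gene order of a locus as a symbol string
#'
#' One symbol per retained gene (categories GH/PL/CE, sulfatase,
#' peptidase, susC, susD, regulator) in `gene_ordinal` order; duplicate
#' genes of the same family share a symbol; other categories are dropped.
#'
#' @param locus a `pul_locus`.
#' @param symbol_map feature -> symbol map from [make_symbol_map()].
#' @return Single character string.
#' @export
encode_order <- function(locus, symbol_map) {
  g <- locus$genes
  keys <- synteny_key(g$category, g$family_label)
  keys <- keys[!is.na(keys)]
  if (length(keys) == 0L) {
    stop("locus ", locus$locus_id, " has no retained gene to encode",
         call. = FALSE)
  }
  unmapped <- setdiff(unique(keys), names(symbol_map))
  if (length(unmapped) > 0L) {
    stop("feature(s) missing from the symbol map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  paste(symbol_map[keys], collapse = "")
}

#' Optimal string alignment (restricted Damerau-Levenshtein) distance
#'
#' Edit distance with unit-cost substitutions, insertions, deletions and
#' adjacent transpositions, each substring edited at most once.
#'
#' @param s1,s2 character strings.
#' @return Non-negative integer distance.
#' @export
osa_distance <- function(s1, s2) {
  a <- utf8ToInt(s1)
  b <- utf8ToInt(s2)
  n <- length(a)
  m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (a[i] == b[j]) 0L else 1L
      best <- min(d[i, j + 1L] + 1L,      # deletion
                  d[i + 1L, j] + 1L,      # insertion
                  d[i, j] + cost)         # substitution / match
      if (i > 1L && j > 1L && a[i] == b[j - 1L] && a[i - 1L] == b[j]) {
        best <- min(best, d[i - 1L, j - 1L] + 1L)  # transposition
      }
      d[i + 1L, j + 1L] <- best
    }
  }
  d[n + 1L, m + 1L]
}

reverse_string <- function(s) {
  paste(rev(strsplit(s, "")[[1L]]), collapse = "")
}

#' Normalized synteny similarity between two symbol strings
#'
#' `1 - d_OSA(s1, s2) / max(nchar(s1), nchar(s2))`, in `[0, 1]`. Gene
#' order is strand-relative, so the default also compares against the
#' reversed second string and keeps the larger similarity
#' (`orientation = "both"`); `"strict"` compares the strings as stored.
#'
#' @param s1,s2 non-empty symbol strings.
#' @param orientation `"both"` (orientation-invariant) or `"strict"`.
#' @return Similarity in `[0, 1]`; 1 means identical order.
#' @export
synteny_similarity <- function(s1, s2, orientation = c("both", "strict")) {
  orientation <- match.arg(orientation)
  if (nchar(s1) == 0L || nchar(s2) == 0L) {
    stop("synteny similarity is undefined for empty strings", call. = FALSE)
  }
  denom <- max(nchar(s1), nchar(s2))
  sim <- 1 - osa_distance(s1, s2) / denom
  if (orientation == "both") {
    sim <- max(sim, 1 - osa_distance(s1, reverse_string(s2)) / denom)
  }
  sim
}

#' Median pairwise synteny within one composition cluster
#'
#' Computes all pairwise similarities between the loci of one cluster
#' (typically loci of identical CAZyme composition) and returns the
#' median, the per-pair table and, when genome metadata is supplied, the
#' taxonomic span of each pair (same genus / same class / across
#' classes). A singleton cluster has no pairs; its median is `NA`.
#'
#' @param loci list of `pul_locus` in one cluster.
#' @param meta optional genome metadata data.frame (see
#'   [read_gene_table()]).
#' @param orientation passed to [synteny_similarity()].
#' @return List with `median_similarity`, `n_loci` and `pairs`
#'   (data.frame: locus_a, locus_b, similarity, and `tax_span` when
#'   metadata is given).
#' @export
cluster_synteny <- function(loci, meta = NULL,
                            orientation = c("both", "strict")) {
  orientation <- match.arg(orientation)
  k <- length(loci)
  if (k < 2L) {
    return(list(median_similarity = NA_real_, n_loci = k,
                pairs = data.frame(locus_a = character(0),
                                   locus_b = character(0),
                                   similarity = numeric(0))))
  }
  map <- make_symbol_map(loci)
  enc <- vapply(loci, encode_order, character(1), symbol_map = map)
  ids <- vapply(loci, function(l) l$locus_id, character(1))
  genomes <- vapply(loci, function(l) l$genome_id, character(1))
  pairs <- t(utils::combn(k, 2L))
  sims <- apply(pairs, 1L, function(p) {
    synteny_similarity(enc[p[1L]], enc[p[2L]], orientation)
  })
  out <- data.frame(locus_a = ids[pairs[, 1L]], locus_b = ids[pairs[, 2L]],
                    similarity = sims, stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    gi <- match(genomes, meta$genome_id)
    span <- function(p) {
      i <- gi[p[1L]]; j <- gi[p[2L]]
      if (is.na(i) || is.na(j)) NA_character_
      else if (meta$genus[i] == meta$genus[j]) "same_genus"
      else if (meta$taxon_class[i] == meta$taxon_class[j]) "same_class"
      else "across_classes"
    }
    out$tax_span <- apply(pairs, 1L, span)
  }
  list(median_similarity = stats::median(sims), n_loci = k, pairs = out)
}

#' Per-cluster synteny table
#'
#' Convenience wrapper: given classified loci and a cluster labelling of
#' their composition matrix rows, computes [cluster_synteny()] for every
#' cluster with at least two members.
#'
#' @param loci list of `pul_locus` whose ids appear in `labels`.
#' @param labels named integer vector (locus id -> cluster id), e.g. from
#'   [cluster_compositions()].
#' @inheritParams cluster_synteny
#' @return data.frame: cluster, size, median_similarity.
#' @export
synteny_by_cluster <- function(loci, labels, meta = NULL,
                               orientation = c("both", "strict")) {
  orientation <- match.arg(orientation)
  ids <- vapply(loci, function(l) l$locus_id, character(1))
  loci <- loci[ids %in% names(labels)]
  ids <- ids[ids %in% names(labels)]
  by_cluster <- split(seq_along(loci), labels[ids])
  rows <- lapply(names(by_cluster), function(cl) {
    members <- loci[by_cluster[[cl]]]
    if (length(members) < 2L) return(NULL)
    cs <- cluster_synteny(members, meta = meta, orientation = orientation)
    data.frame(cluster = cl, size = cs$n_loci,
               median_similarity = cs$median_similarity,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(cluster = character(0), size = integer(0),
                      median_similarity = numeric(0)))
  }
  do.call(rbind, rows)
}
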