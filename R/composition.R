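# CAZyme composition profiling ------------------------------------------------

# Map one gene row to its composition feature key, or NA for genes that
# contribute nothing (susC/susD, regulators, phosphodiesterases, other).
feature_key <- function(category, family_label) {
  ifelse(category %in% CAZYME_CATEGORIES, family_label,
         ifelse(category == "sulfatase", SULF_FEATURE,
                ifelse(category == "peptidase", PEPT_FEATURE,
                       NA_character_)))
}

#' Composition vector of one PUL
#'
#' Collapses the genes of a PUL to its degradative feature profile:
#' GH/PL/CE genes map to their (sub)family label, all sulfatase genes to
#' the single broad feature `Sulf` and all peptidase genes to `Pept`;
#' susC/susD, regulators and other genes contribute nothing. In
#' presence/absence mode every feature gets value 1; in copy-aware mode
#' the per-feature gene counts are kept.
#'
#' @param locus a `pul_locus` with class `PUL` or `TRSUSCD_PUL`.
#' @param vocabulary feature vocabulary; labels outside it are an error.
#' @param mode `"presence"` or `"copy_aware"`.
#' @return Named integer vector (feature -> 1 or copy count), sorted by
#'   feature label.
#' @export
composition_vector <- function(locus, vocabulary = default_vocabulary(),
                               mode = c("presence", "copy_aware")) {
  mode <- match.arg(mode)
  if (!locus$locus_class %in% c("PUL", "TRSUSCD_PUL")) {
    stop("composition is defined for PUL/TRSUSCD_PUL loci, not ",
         locus$locus_class, call. = FALSE)
  }
  g <- locus$genes
  keys <- feature_key(g$category, g$family_label)
  keys <- keys[!is.na(keys) & keys != ""]
  if (length(keys) == 0L) {
    stop("locus ", locus$locus_id, " has no degradative feature", call. = FALSE)
  }
  unknown <- setdiff(unique(keys), vocabulary)
  if (length(unknown) > 0L) {
    stop("feature label(s) outside the vocabulary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- table(keys)
  v <- as.integer(counts)
  names(v) <- names(counts)
  if (mode == "presence") v[] <- 1L
  v[order(names(v))]
}

#' Build a loci-by-feature composition matrix
#'
#' @param puls list of `pul_locus` objects, or a list of named integer
#'   vectors as returned by [composition_vector()] (named by locus id).
#' @param vocabulary feature vocabulary.
#' @param mode `"presence"` (binary cells) or `"copy_aware"` (gene
#'   counts).
#' @param full_vocabulary keep all vocabulary columns (default: restrict
#'   to features observed at least once)?
#' @return Integer matrix, rows in input order named by locus id, columns
#'   the sorted feature vocabulary.
#' @export
build_matrix <- function(puls, vocabulary = default_vocabulary(),
                         mode = c("presence", "copy_aware"),
                         full_vocabulary = FALSE) {
  mode <- match.arg(mode)
  if (length(puls) == 0L) {
    stop("cannot build a composition matrix from zero PULs", call. = FALSE)
  }
  vecs <- lapply(puls, function(p) {
    if (inherits(p, "pul_locus")) {
      composition_vector(p, vocabulary, mode)
    } else p
  })
  ids <- vapply(seq_along(puls), function(i) {
    p <- puls[[i]]
    if (inherits(p, "pul_locus")) p$locus_id
    else if (!is.null(names(puls))) names(puls)[i]
    else sprintf("locus_%04d", i)
  }, character(1))
  feats <- sort(unique(unlist(lapply(vecs, names))))
  if (full_vocabulary) feats <- sort(vocabulary)
  m <- matrix(0L, nrow = length(vecs), ncol = length(feats),
              dimnames = list(ids, feats))
  for (i in seq_along(vecs)) m[i, names(vecs[[i]])] <- vecs[[i]]
  m
}

# Canonical group key of one matrix row: sorted feature list, with copy
# counts appended in copy-aware mode. Stable across runs and row orders.
composition_keys <- function(matrix, mode = c("presence", "copy_aware")) {
  mode <- match.arg(mode)
  feats <- colnames(matrix)
  apply(matrix, 1L, function(r) {
    nz <- which(r > 0L)
    if (mode == "presence") paste(feats[nz], collapse = "|")
    else paste(sprintf("%s:%d", feats[nz], r[nz]), collapse = "|")
  })
}

#' Enumerate unique PUL compositions
#'
#' Groups PULs into equivalence classes under exact equality of their
#' feature set (presence mode) or feature multiset (copy-aware mode).
#' "Groups" have at least two members, "singletons" exactly one; the
#' number of unique PULs is groups plus singletons.
#'
#' @param matrix composition matrix from [build_matrix()].
#' @param mode equality on sets (`"presence"`) or multisets
#'   (`"copy_aware"`).
#' @return A `pul_unique_summary`: list with `n_puls`, `n_groups_ge2`,
#'   `n_singletons`, `n_unique` and `group_membership` (named list
#'   composition key -> locus ids, largest groups first).
#' @export
enumerate_unique <- function(matrix, mode = c("presence", "copy_aware")) {
  mode <- match.arg(mode)
  keys <- composition_keys(matrix, mode)
  groups <- split(rownames(matrix), keys)
  sizes <- lengths(groups)
  groups <- groups[order(-sizes, names(groups))]
  sizes <- lengths(groups)
  structure(list(
    n_puls = nrow(matrix),
    n_groups_ge2 = sum(sizes >= 2L),
    n_singletons = sum(sizes == 1L),
    n_unique = length(groups),
    group_membership = groups,
    mode = mode
  ), class = "pul_unique_summary")
}

#' @export
print.pul_unique_summary <- function(x, ...) {
  cat(sprintf(
    "%d PULs -> %d unique compositions (%s mode): %d groups (>=2) + %d singletons\n",
    x$n_puls, x$n_unique, x$mode, x$n_groups_ge2, x$n_singletons))
  invisible(x)
}

#' Single-family PUL statistics
#'
#' A single-family PUL encodes exactly one distinct CAZyme (sub)family;
#' presence of the broad Sulf/Pept features does not disqualify it (they
#' are not CAZyme families) but is reported. Single-family PULs are
#' binned by the copy number of their family's gene, and a per-family
#' duplication rate (fraction of that family's single-family PULs with at
#' least two copies) is computed.
#'
#' @param matrix copy-aware composition matrix.
#' @return List with `n_single_family`, `one_copy`, `two_copies`,
#'   `more_than_two`, `with_sulf_pept`, and `per_family` (data.frame:
#'   family, n, n_duplicated, duplication_rate).
#' @export
single_family_stats <- function(matrix) {
  feats <- colnames(matrix)
  caz <- !feats %in% c(SULF_FEATURE, PEPT_FEATURE)
  caz_counts <- matrix[, caz, drop = FALSE]
  n_fam <- rowSums(caz_counts > 0L)
  single <- which(n_fam == 1L)
  if (length(single) == 0L) {
    return(list(n_single_family = 0L, one_copy = 0L, two_copies = 0L,
                more_than_two = 0L, with_sulf_pept = 0L,
                per_family = data.frame(family = character(0), n = integer(0),
                                        n_duplicated = integer(0),
                                        duplication_rate = numeric(0))))
  }
  fam_idx <- apply(caz_counts[single, , drop = FALSE] > 0L, 1L, which)
  fam <- colnames(caz_counts)[fam_idx]
  copies <- caz_counts[cbind(single, fam_idx)]
  sulf_pept <- rowSums(matrix[single, !caz, drop = FALSE] > 0L) > 0L
  per_family <- do.call(rbind, lapply(split(copies, fam), function(cp) {
    data.frame(n = length(cp), n_duplicated = sum(cp >= 2L),
               duplication_rate = mean(cp >= 2L))
  }))
  per_family <- data.frame(family = rownames(per_family), per_family,
                           row.names = NULL, stringsAsFactors = FALSE)
  list(
    n_single_family = length(single),
    one_copy = sum(copies == 1L),
    two_copies = sum(copies == 2L),
    more_than_two = sum(copies > 2L),
    with_sulf_pept = sum(sulf_pept),
    per_family = per_family[order(-per_family$duplication_rate,
                                  per_family$family), ]
  )
}

#' Median number of (sub)families per PUL
#'
#' Median of the per-PUL count of distinct features, with a confidence
#' interval from the Wilcoxon signed-rank procedure (see
#' [median_ci_wilcoxon()]). By default only CAZyme (sub)families are
#' counted; `include_sulf_pept = TRUE` also counts the broad Sulf/Pept
#' features.
#'
#' @param matrix presence-mode composition matrix.
#' @param include_sulf_pept count Sulf/Pept as families?
#' @param conf.level confidence level.
#' @return List with `median`, `lo`, `hi`, `conf.level` and the per-PUL
#'   counts in `counts`.
#' @export
families_per_pul <- function(matrix, include_sulf_pept = FALSE,
                             conf.level = 0.95) {
  feats <- colnames(matrix)
  keep <- if (include_sulf_pept) rep(TRUE, length(feats))
          else !feats %in% c(SULF_FEATURE, PEPT_FEATURE)
  counts <- rowSums(matrix[, keep, drop = FALSE] > 0L)
  ci <- median_ci_wilcoxon(counts, conf.level = conf.level)
  c(ci, list(counts = counts))
}
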