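# Contingency-table statistics ------------------------------------------------

#' Build a contingency table with expected counts
#'
#' Wraps an observed count matrix with its marginals, total and expected
#' counts `E_ij = RowMarginal_i * ColumnMarginal_j / n` (always computed,
#' never supplied).
#'
#' @param O matrix of non-negative integer counts.
#' @param row_labels,col_labels optional dimension labels.
#' @return A `pul_contingency`: list with `O`, `E`, `n`, `row_marginal`,
#'   `col_marginal`.
#' @export
contingency_table <- function(O, row_labels = NULL, col_labels = NULL) {
  O <- as.matrix(O)
  if (any(O < 0) || any(O != round(O))) {
    stop("observed counts must be non-negative integers", call. = FALSE)
  }
  if (!is.null(row_labels)) rownames(O) <- row_labels
  if (!is.null(col_labels)) colnames(O) <- col_labels
  n <- sum(O)
  if (n == 0) stop("contingency table sums to zero", call. = FALSE)
  rm_ <- rowSums(O)
  cm_ <- colSums(O)
  E <- outer(rm_, cm_) / n
  structure(list(O = O, E = E, n = n, row_marginal = rm_, col_marginal = cm_),
            class = "pul_contingency")
}

#' Adjusted standardized residuals of a contingency table
#'
#' Per-cell statistic
#' `(O - E) / sqrt(E * (1 - RowMarginal/n) * (1 - ColumnMarginal/n))`;
#' a positive sign marks over-representation, a negative sign
#' under-representation. Approximately standard normal under homogeneity.
#'
#' @param table a `pul_contingency` (or a plain count matrix).
#' @return Matrix of residuals.
#' @export
adjusted_residuals <- function(table) {
  if (!inherits(table, "pul_contingency")) table <- contingency_table(table)
  if (any(table$row_marginal == 0) || any(table$col_marginal == 0)) {
    stop("adjusted residuals are undefined with a zero marginal",
         call. = FALSE)
  }
  with(table, (O - E) /
         sqrt(E * (1 - row_marginal / n) *
                rep(1 - col_marginal / n, each = nrow(O))))
}

#' Pearson chi-squared homogeneity test
#'
#' Pearson's chi-squared with `(r-1)(c-1)` degrees of freedom and no
#' continuity correction. Cells with expected count below 5 trigger a
#' warning (not an alternative test).
#'
#' @param table a `pul_contingency` or count matrix.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
chi2_test <- function(table) {
  if (!inherits(table, "pul_contingency")) table <- contingency_table(table)
  if (any(table$row_marginal == 0) || any(table$col_marginal == 0)) {
    stop("chi-squared test is undefined with a zero marginal", call. = FALSE)
  }
  if (nrow(table$O) < 2L || ncol(table$O) < 2L) {
    stop("chi-squared homogeneity test needs at least a 2x2 table",
         call. = FALSE)
  }
  if (any(table$E < 5)) {
    warning("expected count below 5 in ", sum(table$E < 5),
            " cell(s); chi-squared approximation may be poor", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table$O, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Annotate genes with their in-PUL status and feature key
#'
#' Marks every degradative gene of a dataset as lying inside a PUL
#' (classes `PUL`/`TRSUSCD_PUL` of the sort result) or outside, and
#' attaches its composition feature key. This is the gene-level tally
#' behind the family enrichment tests.
#'
#' @param dataset a `pul_dataset` or gene table.
#' @param sorted matching `pul_sort` from [sort_dataset()].
#' @return data.frame of degradative genes with columns `feature` and
#'   `in_pul`.
#' @export
annotate_in_pul <- function(dataset, sorted) {
  genes <- if (is.data.frame(dataset)) dataset else dataset$genes
  genes <- genes[genes$category %in% DEGRADATIVE_CATEGORIES, , drop = FALSE]
  genes$feature <- feature_key(genes$category, genes$family_label)
  tab <- sorted$table
  tab <- tab[tab$locus_class %in% c("PUL", "TRSUSCD_PUL"), , drop = FALSE]
  genes$in_pul <- FALSE
  if (nrow(tab) > 0L) {
    for (k in seq_len(nrow(tab))) {
      hit <- genes$genome_id == tab$genome_id[k] &
        genes$replicon_id == tab$replicon_id[k] &
        genes$gene_ordinal >= tab$start_ordinal[k] &
        genes$gene_ordinal <= tab$end_ordinal[k]
      genes$in_pul[hit] <- TRUE
    }
  }
  rownames(genes) <- NULL
  genes
}

#' 2x2 contingency table for one family's PUL representation
#'
#' Rows: genes of the given feature vs genes of all other degradative
#' features; columns: inside vs outside PULs. Counting is at the gene
#' level.
#'
#' @param annotated output of [annotate_in_pul()].
#' @param feature a feature label (family, subfamily, `Sulf` or `Pept`).
#' @return A `pul_contingency`.
#' @export
family_contingency <- function(annotated, feature) {
  if (!feature %in% annotated$feature) {
    stop("feature ", feature, " absent from the dataset", call. = FALSE)
  }
  is_f <- annotated$feature == feature
  O <- rbind(c(sum(is_f & annotated$in_pul), sum(is_f & !annotated$in_pul)),
             c(sum(!is_f & annotated$in_pul), sum(!is_f & !annotated$in_pul)))
  if (any(colSums(O) == 0)) {
    stop("degenerate table: one compartment (in/out of PULs) is empty",
         call. = FALSE)
  }
  contingency_table(O, row_labels = c(feature, "other"),
                    col_labels = c("in_pul", "outside_pul"))
}

#' Family-by-family PUL enrichment scan
#'
#' For every feature, builds the 2x2 gene-level table, computes the
#' adjusted standardized residual of the (feature, in-PUL) cell and the
#' chi-squared p-value, and adds Benjamini-Hochberg q-values (an
#' extension; raw p-values are reported alongside).
#'
#' @param annotated output of [annotate_in_pul()].
#' @param min_genes skip features with fewer genes in total (default 5).
#' @return data.frame: feature, n_in_pul, n_outside, residual (sign +
#'   means over-represented in PULs), chi2, p.value, q.value.
#' @export
family_enrichment <- function(annotated, min_genes = 5L) {
  feats <- sort(unique(annotated$feature))
  rows <- lapply(feats, function(f) {
    is_f <- annotated$feature == f
    if (sum(is_f) < min_genes) return(NULL)
    tab <- tryCatch(family_contingency(annotated, f),
                    error = function(e) NULL)
    if (is.null(tab)) return(NULL)
    res <- adjusted_residuals(tab)[1L, 1L]
    ht <- suppressWarnings(chi2_test(tab))
    data.frame(feature = f, n_in_pul = tab$O[1L, 1L],
               n_outside = tab$O[1L, 2L], residual = res,
               chi2 = ht$statistic, p.value = ht$p.value,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(feature = character(0), n_in_pul = integer(0),
                      n_outside = integer(0), residual = numeric(0),
                      chi2 = numeric(0), p.value = numeric(0),
                      q.value = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$q.value <- stats::p.adjust(out$p.value, method = "BH")
  out[order(out$residual), ]
}

#' Genus-level enrichment of tandem-repeat susC/D loci
#'
#' Tests whether trsusCD loci are proportionally more abundant in one
#' genus than in the others: rows are genera (or the focal genus vs
#' `other`), columns tandem vs single-pair susC/D loci, counted over all
#' anchored loci (at least one adjacent same-strand pair).
#'
#' @param sorted a `pul_sort`.
#' @param meta genome metadata with a `genus` column.
#' @param focal_genus optional genus to collapse the table to 2x2
#'   against all others.
#' @return List with `table` (`pul_contingency`), `chi2` (test result)
#'   and `residuals`.
#' @export
genus_trsuscd_test <- function(sorted, meta, focal_genus = NULL) {
  tab <- sorted$table
  tab <- tab[tab$n_sus_pairs >= 1L, , drop = FALSE]
  genus <- meta$genus[match(tab$genome_id, meta$genome_id)]
  keep <- !is.na(genus) & genus != ""
  if (any(!keep)) {
    warning(sum(!keep), " locus/loci dropped for missing genus",
            call. = FALSE)
  }
  tab <- tab[keep, , drop = FALSE]
  genus <- genus[keep]
  if (!is.null(focal_genus)) {
    genus <- ifelse(genus == focal_genus, focal_genus, "other")
  }
  if (length(unique(genus)) < 2L) {
    stop("genus enrichment test needs at least two genera", call. = FALSE)
  }
  tandem <- factor(ifelse(tab$n_sus_pairs >= 2L, "trsusCD", "single_pair"),
                   levels = c("trsusCD", "single_pair"))
  O <- table(genus, tandem)
  ct <- contingency_table(unclass(O))
  list(table = ct, chi2 = chi2_test(ct), residuals = adjusted_residuals(ct))
}

#' Median with Wilcoxon signed-rank confidence interval
#'
#' Confidence interval for the center of a (assumed symmetric)
#' distribution by inversion of the one-sample Wilcoxon signed-rank test
#' (the Hodges-Lehmann construction of [stats::wilcox.test()]). A
#' constant sample yields a zero-width interval.
#'
#' @param values numeric vector, length at least 2.
#' @param conf.level confidence level (default 0.95).
#' @return List with `median`, `lo`, `hi`, `conf.level`.
#' @export
median_ci_wilcoxon <- function(values, conf.level = 0.95) {
  if (length(values) < 2L) {
    stop("need at least two values for a confidence interval", call. = FALSE)
  }
  med <- stats::median(values)
  if (diff(range(values)) == 0) {
    return(list(median = med, lo = med, hi = med, conf.level = conf.level))
  }
  ht <- suppressWarnings(stats::wilcox.test(values, conf.int = TRUE,
                                            conf.level = conf.level))
  list(median = med, lo = ht$conf.int[1L], hi = ht$conf.int[2L],
       conf.level = conf.level)
}
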