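# Domain constants ----------------------------------------------------------

#' Gene categories recognized in a gene table
#'
#' Functional categories a gene row may carry: the susC/D transporter pair
#' that anchors a polysaccharide utilization locus (PUL), the degradative
#' CAZyme classes (GH = glycoside hydrolase, PL = polysaccharide lyase,
#' CE = carbohydrate esterase), the broad sulfatase/peptidase/
#' phosphodiesterase categories, regulators, and everything else.
#'
#' @format Character vector of valid category tokens.
#' @export
GENE_CATEGORIES <- c("susC", "susD", "GH", "PL", "CE", "sulfatase",
                     "peptidase", "phosphodiesterase", "regulator", "other")

#' @rdname GENE_CATEGORIES
#' @export
CAZYME_CATEGORIES <- c("GH", "PL", "CE")

#' @rdname GENE_CATEGORIES
#' @export
DEGRADATIVE_CATEGORIES <- c("GH", "PL", "CE", "sulfatase", "peptidase")

# Families for which subfamily labels (e.g. "GH13_8") are meaningful; all
# other families carry plain labels.
SUBFAMILY_FAMILIES <- c("GH5", "GH13", "GH30", "GH43")

GENE_TABLE_COLUMNS <- c("genome_id", "replicon_id", "gene_ordinal", "strand",
                        "category", "family_label", "protein_id")
GENOME_META_COLUMNS <- c("genome_id", "taxon_class", "genus", "species",
                         "habitat")

LOCUS_CLASSES <- c("PUL", "TRSUSCD_PUL", "NO_CAZYME", "REJECTED",
                   "CAZYME_CLUSTER_NO_SUSCD")

# Feature keys for the two broad non-CAZyme degradative categories.
SULF_FEATURE <- "Sulf"
PEPT_FEATURE <- "Pept"

# Validation ----------------------------------------------------------------

#' Validate a gene table
#'
#' Checks the typed invariants of a gene table: required columns, known
#' category tokens, strand symbols, family labels present exactly for
#' GH/PL/CE genes, subfamily suffixes restricted to GH5/GH13/GH30/GH43,
#' uniqueness of gene ordinals within a replicon, and (optionally) that
#' every family label belongs to a feature vocabulary. Offending rows are
#' listed in the error message; rows are never silently dropped.
#'
#' @param genes data.frame with columns `genome_id`, `replicon_id`,
#'   `gene_ordinal`, `strand`, `category`, `family_label`, `protein_id`.
#' @param vocabulary optional character vector of allowed feature labels
#'   (families/subfamilies plus `"Sulf"` and `"Pept"`).
#' @return The validated gene table, ordered by (genome, replicon, ordinal),
#'   invisibly classed as `pul_genes`.
#' @export
validate_gene_table <- function(genes, vocabulary = NULL) {
  stopifnot(is.data.frame(genes))
  missing_cols <- setdiff(GENE_TABLE_COLUMNS, names(genes))
  if (length(missing_cols) > 0L) {
    stop("gene table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  genes$genome_id <- as.character(genes$genome_id)
  genes$replicon_id <- as.character(genes$replicon_id)
  genes$gene_ordinal <- as.integer(genes$gene_ordinal)
  genes$strand <- as.character(genes$strand)
  genes$category <- as.character(genes$category)
  genes$family_label <- as.character(genes$family_label)
  genes$family_label[is.na(genes$family_label)] <- ""
  genes$protein_id <- as.character(genes$protein_id)

  bad_cat <- which(!genes$category %in% GENE_CATEGORIES)
  if (length(bad_cat) > 0L) {
    stop("unknown category token(s) ",
         paste(unique(genes$category[bad_cat]), collapse = ", "),
         " at row(s) ", paste(utils::head(bad_cat, 10L), collapse = ", "),
         call. = FALSE)
  }
  bad_strand <- which(!genes$strand %in% c("+", "-"))
  if (length(bad_strand) > 0L) {
    stop("strand must be '+' or '-'; offending row(s): ",
         paste(utils::head(bad_strand, 10L), collapse = ", "), call. = FALSE)
  }
  if (anyNA(genes$gene_ordinal) || any(genes$gene_ordinal < 1L)) {
    stop("gene_ordinal must be a positive integer", call. = FALSE)
  }

  is_caz <- genes$category %in% CAZYME_CATEGORIES
  no_label <- which(is_caz & genes$family_label == "")
  if (length(no_label) > 0L) {
    stop("GH/PL/CE gene(s) without a family label at row(s): ",
         paste(utils::head(no_label, 10L), collapse = ", "), call. = FALSE)
  }
  stray_label <- which(!is_caz & genes$family_label != "")
  if (length(stray_label) > 0L) {
    stop("family_label only allowed for GH/PL/CE genes; row(s): ",
         paste(utils::head(stray_label, 10L), collapse = ", "), call. = FALSE)
  }

  lab <- genes$family_label[is_caz]
  has_sub <- grepl("_[0-9]+$", lab)
  base_fam <- sub("_[0-9]+$", "", lab)
  bad_sub <- which(is_caz)[has_sub & !(base_fam %in% SUBFAMILY_FAMILIES)]
  if (length(bad_sub) > 0L) {
    stop("subfamily suffix only allowed for ",
         paste(SUBFAMILY_FAMILIES, collapse = "/"),
         "; offending label(s): ",
         paste(unique(genes$family_label[bad_sub]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(vocabulary)) {
    unknown <- which(is_caz)[!lab %in% vocabulary]
    if (length(unknown) > 0L) {
      stop("family label(s) absent from the vocabulary: ",
           paste(unique(genes$family_label[unknown]), collapse = ", "),
           call. = FALSE)
    }
  }

  key <- paste(genes$genome_id, genes$replicon_id, genes$gene_ordinal,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("duplicate gene_ordinal within a replicon at row(s): ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  }

  ord <- order(genes$genome_id, genes$replicon_id, genes$gene_ordinal)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  class(genes) <- c("pul_genes", "data.frame")
  invisible(genes)
}

validate_genome_meta <- function(meta) {
  stopifnot(is.data.frame(meta))
  missing_cols <- setdiff(GENOME_META_COLUMNS, names(meta))
  if (length(missing_cols) > 0L) {
    stop("genome metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cn in GENOME_META_COLUMNS) {
    meta[[cn]] <- as.character(meta[[cn]])
    meta[[cn]][is.na(meta[[cn]])] <- ""
  }
  if (anyDuplicated(meta$genome_id)) {
    stop("duplicate genome_id in genome metadata", call. = FALSE)
  }
  rownames(meta) <- NULL
  meta
}

# Readers / writers ----------------------------------------------------------

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8",
                    na.strings = NULL)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
}

#' Read a gene table (and optional genome metadata) from TSV
#'
#' @param path path to a tab-separated gene table with columns `genome_id`,
#'   `replicon_id`, `gene_ordinal`, `strand`, `category`, `family_label`,
#'   `protein_id`.
#' @param meta_path optional path to a genome metadata table with columns
#'   `genome_id`, `taxon_class`, `genus`, `species`, `habitat`.
#' @param vocabulary optional feature vocabulary (character vector or path
#'   to a one-label-per-line file); family labels outside it are rejected.
#' @return A `pul_dataset`: list with `genes` (validated gene table) and
#'   `meta` (metadata data.frame or `NULL`).
#' @export
read_gene_table <- function(path, meta_path = NULL, vocabulary = NULL) {
  if (is.character(vocabulary) && length(vocabulary) == 1L &&
      file.exists(vocabulary)) {
    vocabulary <- read_vocabulary(vocabulary)
  }
  genes <- read_tsv(path)
  genes <- validate_gene_table(genes, vocabulary = vocabulary)
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- validate_genome_meta(read_tsv(meta_path))
    extra <- setdiff(unique(genes$genome_id), meta$genome_id)
    if (length(extra) > 0L) {
      stop("genome(s) in gene table absent from metadata: ",
           paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(genes = genes, meta = meta), class = "pul_dataset")
}

#' Write a dataset back to TSV
#'
#' @param dataset a `pul_dataset` (or plain list with `genes`/`meta`).
#' @param path output path for the gene table.
#' @param meta_path optional output path for genome metadata.
#' @return Invisibly, the paths written.
#' @export
write_gene_table <- function(dataset, path, meta_path = NULL) {
  genes <- if (is.data.frame(dataset)) dataset else dataset$genes
  write_tsv(as.data.frame(genes), path)
  if (!is.null(meta_path) && !is.null(dataset$meta)) {
    write_tsv(dataset$meta, meta_path)
  }
  invisible(c(path, meta_path))
}

#' Read / write a feature vocabulary
#'
#' A vocabulary is a plain text file with one feature label per line:
#' CAZyme families and subfamilies plus the broad `Sulf` and `Pept`
#' categories. Labels outside the vocabulary fail validation rather than
#' being accepted silently.
#'
#' @param path file path.
#' @return Character vector of labels.
#' @export
read_vocabulary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- readLines(path, encoding = "UTF-8")
  v <- trimws(v)
  v[nzchar(v)]
}

#' @rdname read_vocabulary
#' @param vocabulary character vector of labels.
#' @export
write_vocabulary <- function(vocabulary, path) {
  writeLines(vocabulary, path, useBytes = TRUE)
  invisible(path)
}

#' Built-in feature vocabulary
#'
#' A compact vocabulary of GH/PL/CE families (with subfamilies for GH5,
#' GH13, GH30 and GH43) plus the broad `Sulf` and `Pept` features, used by
#' the synthetic-data generator and examples. Real analyses should load
#' the full family list for their annotation source with
#' [read_vocabulary()].
#'
#' @return Character vector of feature labels.
#' @export
default_vocabulary <- function() {
  gh_plain <- c(1:4, 9, 10, 16, 18, 20, 23:29, 31:33, 35:36, 38:39, 42, 51,
                53, 55, 63, 73, 76:78, 88:89, 92, 95, 97, 99, 105:110, 115,
                117, 123, 130, 144, 146:151)
  gh <- paste0("GH", gh_plain)
  sub5 <- paste0("GH5_", c(2, 4, 7, 13, 46))
  sub13 <- paste0("GH13_", c(8, 9, 14, 36, 38, 39))
  sub30 <- paste0("GH30_", 1:4)
  sub43 <- paste0("GH43_", c(1, 2, 4, 8, 10, 12, 24, 29))
  pl <- paste0("PL", c(1, 6:9, 11:13, 17, 27, 28, 29, 33, 38, 40))
  ce <- paste0("CE", c(1:4, 6:12, 15))
  sort(c(gh, sub5, sub13, sub30, sub43, pl, ce, SULF_FEATURE, PEPT_FEATURE))
}

# Composition matrix IO -------------------------------------------------------

#' Write / read a composition matrix as TSV
#'
#' The on-disk format is tab-separated: first column `locus_id`, then one
#' column per feature in sorted vocabulary order, cells 0/1 in
#' presence/absence mode or non-negative gene counts in copy-aware mode.
#' The pair of functions round-trips losslessly.
#'
#' @param matrix integer matrix with locus ids as row names and feature
#'   labels as column names (as built by [build_matrix()]).
#' @param path file path.
#' @return `write_composition_matrix` invisibly returns the path;
#'   `read_composition_matrix` returns the integer matrix.
#' @export
write_composition_matrix <- function(matrix, path) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0L || ncol(matrix) == 0L) {
    stop("composition matrix is empty; refusing to write", call. = FALSE)
  }
  df <- data.frame(locus_id = rownames(matrix),
                   matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_composition_matrix
#' @export
read_composition_matrix <- function(path) {
  df <- read_tsv(path)
  if (!"locus_id" %in% names(df)) {
    stop("composition matrix file lacks a locus_id column", call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "locus_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$locus_id
  m
}
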