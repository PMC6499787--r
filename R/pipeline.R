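# End-to-end pipeline ---------------------------------------------------------

#' Run the full PUL analysis pipeline
#'
#' Orchestrates sort -> compose -> cluster -> synteny -> enrichment ->
#' rarefaction over one dataset and aggregates the headline numbers into
#' a single report. The configuration is a plain named list (or a path to
#' a YAML file with the same keys):
#'
#' * `genes`, `genomes`, `vocabulary`: input paths, or `simulate`: a
#'   [sim_config()] (list form accepted) to generate the input instead;
#' * `max_gap` (default 2), `thresholds` (default 0,10,20,50),
#'   `rarefaction` (`list(sizes =, replicates =, mismatch_percents =)` or
#'   `FALSE` to skip), `run_synteny`, `run_enrichment`, `seed`;
#' * `out`: optional output directory for stage TSVs and `report.json`.
#'
#' @param config named list or YAML file path.
#' @return The report: a named list with the sort summary, unique-PUL
#'   summaries in both modes, the threshold curve, single-family
#'   statistics, families-per-PUL median and CI, synteny medians,
#'   enrichment tables and rarefaction trends. Written as `report.json`
#'   when `out` is set.
#' @export
run_all <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    max_gap = 2L, thresholds = c(0, 10, 20, 50),
    run_synteny = TRUE, run_enrichment = TRUE,
    rarefaction = list(replicates = 10L, mismatch_percents = c(0, 20)),
    seed = 1L, out = NULL
  ), config)

  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    if (!inherits(sim, "pul_sim_config")) sim <- do.call(sim_config, sim)
    dataset <- simulate_dataset(sim)
    vocabulary <- sim$vocabulary
  } else {
    if (is.null(cfg$genes)) {
      stop("config needs either 'genes' (input path) or 'simulate'",
           call. = FALSE)
    }
    vocabulary <- if (!is.null(cfg$vocabulary)) {
      if (length(cfg$vocabulary) == 1L && file.exists(cfg$vocabulary))
        read_vocabulary(cfg$vocabulary) else cfg$vocabulary
    } else default_vocabulary()
    dataset <- read_gene_table(cfg$genes, meta_path = cfg$genomes,
                               vocabulary = vocabulary)
  }

  sorted <- sort_dataset(dataset, max_gap = cfg$max_gap)
  puls <- pul_loci(sorted)
  if (length(puls) == 0L) stop("stage compose: no PULs in dataset",
                               call. = FALSE)
  mat_p <- build_matrix(puls, vocabulary = vocabulary, mode = "presence")
  mat_c <- build_matrix(puls, vocabulary = vocabulary, mode = "copy_aware")
  uniq_p <- enumerate_unique(mat_p, "presence")
  uniq_c <- enumerate_unique(mat_c, "copy_aware")
  curve <- unique_vs_threshold(mat_p, cfg$thresholds, "presence")
  sf <- single_family_stats(mat_c)
  fpp <- families_per_pul(mat_p)

  report <- list(
    sort = sorted$summary,
    unique = list(
      presence = uniq_p[c("n_puls", "n_groups_ge2", "n_singletons",
                          "n_unique")],
      copy_aware = uniq_c[c("n_puls", "n_groups_ge2", "n_singletons",
                            "n_unique")]
    ),
    threshold_curve = curve,
    single_family = sf[c("n_single_family", "one_copy", "two_copies",
                         "more_than_two")],
    families_per_pul = fpp[c("median", "lo", "hi")],
    seed = cfg$seed
  )

  if (isTRUE(cfg$run_synteny)) {
    labels0 <- cluster_compositions(mat_p, 0, "presence")$labels
    syn <- synteny_by_cluster(puls, labels0, meta = dataset$meta)
    report$synteny <- list(
      n_clusters_scored = nrow(syn),
      median_of_medians = if (nrow(syn)) stats::median(syn$median_similarity)
                          else NA_real_
    )
  } else syn <- NULL

  if (isTRUE(cfg$run_enrichment)) {
    annotated <- annotate_in_pul(dataset, sorted)
    enr <- family_enrichment(annotated)
    report$enrichment <- list(
      n_features_tested = nrow(enr),
      most_underrepresented = if (nrow(enr)) enr$feature[1L] else NA_character_
    )
    if (!is.null(dataset$meta) &&
        length(unique(dataset$meta$genus)) >= 2L &&
        sum(sorted$table$n_sus_pairs >= 2L) > 0L) {
      gt <- suppressWarnings(genus_trsuscd_test(sorted, dataset$meta))
      report$trsuscd_genus_chi2 <- gt$chi2
    }
  } else enr <- NULL

  if (!isFALSE(cfg$rarefaction)) {
    rf <- cfg$rarefaction
    genome_of <- vapply(puls, function(l) l$genome_id, character(1))
    report$rarefaction <- lapply(rf$mismatch_percents, function(t) {
      curve <- resample_unique_counts(
        mat_p, genome_of, sizes = rf$sizes,
        replicates = rf$replicates, mismatch_percent = t,
        mode = "presence", seed = cfg$seed)
      trend <- fit_poly2(curve)
      list(mismatch_percent = t, sizes = curve$sizes,
           medians = curve$medians,
           trend_coefficients = as.list(trend$coefficients))
    })
    names(report$rarefaction) <- paste0("mismatch_",
                                        rf$mismatch_percents)
  }

  if (!is.null(cfg$out)) {
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    write_tsv(sorted$table, file.path(cfg$out, "loci.tsv"))
    write_composition_matrix(mat_p, file.path(cfg$out, "matrix_presence.tsv"))
    write_composition_matrix(mat_c, file.path(cfg$out, "matrix_copies.tsv"))
    write_tsv(curve, file.path(cfg$out, "threshold_curve.tsv"))
    if (!is.null(syn) && nrow(syn)) {
      write_tsv(syn, file.path(cfg$out, "synteny.tsv"))
    }
    if (!is.null(enr) && nrow(enr)) {
      write_tsv(enr, file.path(cfg$out, "enrichment.tsv"))
    }
    jsonlite::write_json(report, file.path(cfg$out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
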