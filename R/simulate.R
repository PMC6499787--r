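# Synthetic susC/D-locus gene tables with ground truth ------------------------
#
# The generator emulates the structure of a susC/D-locus corpus: genomes
# carry loci anchored on adjacent same-strand susC/D pairs, each PUL
# drawing its CAZyme content from one of K archetype compositions with
# long-tailed archetype abundances, plus tandem-repeat (trsusCD) anchors,
# CAZyme-free susC/D loci, broken (rejected) anchors, filler genes between
# loci and occasional CAZyme genes outside loci. Everything is traceable
# to a ground-truth table, and a given seed reproduces the tables
# byte-for-byte.

GENUS_POOL <- data.frame(
  genus = c("Bacteroides", "Prevotella", "Alistipes", "Parabacteroides",
            "Flavobacterium", "Polaribacter", "Zobellia",
            "Cytophaga", "Algoriphagus", "Spirosoma"),
  taxon_class = c(rep("Bacteroidia", 4), rep("Flavobacteriia", 3),
                  rep("Cytophagia", 3)),
  habitat = c("gut", "gut", "gut", "gut", "marine", "marine", "marine",
              "soil", "marine", "soil"),
  stringsAsFactors = FALSE
)

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale corpus with the structural rates of a
#' real susC/D-locus collection: ~10.7% of loci have broken anchors,
#' ~3.3% tandem-repeat anchors, half of the anchored loci carry no CAZyme,
#' archetype sizes follow a shifted Poisson giving a median near 3.5
#' families per PUL, archetype abundances are geometric (long-tailed),
#' and per-family duplication is set so roughly 40% of PULs carry a
#' duplicated family.
#'
#' @param n_genomes number of genomes.
#' @param n_archetypes number K of archetype compositions.
#' @param vocabulary feature vocabulary (must include `Sulf`/`Pept`).
#' @param archetype_size_lambda Poisson rate; archetype sizes are
#'   `1 + rpois(lambda)` families.
#' @param archetype_size optional fixed archetype size (overrides the
#'   Poisson draw); scalar or length-K vector.
#' @param loci_per_genome_lambda Poisson rate; each genome carries
#'   `1 + rpois(lambda)` susC/D loci.
#' @param loci_per_genome optional fixed number of susC/D loci per genome
#'   (overrides the Poisson draw).
#' @param p_family_swap probability a PUL replaces one archetype family
#'   with a random other family.
#' @param p_family_drop probability a PUL loses one family (if it has at
#'   least two).
#' @param p_dup_prone archetype-level probability that a family is
#'   duplication-prone: its gene is carried in two copies (rarely three)
#'   by every locus of that archetype.
#' @param p_duplicate per-locus, per-family probability of deviating from
#'   the archetype's duplication profile (gaining or losing the extra
#'   copy).
#' @param trsuscd_fraction probability an anchored locus gets a tandem
#'   (C,D,C,D) anchor.
#' @param p_no_cazyme_locus probability an anchored locus carries no
#'   CAZyme gene.
#' @param p_reject probability a locus gets a broken anchor (no adjacent
#'   same-strand pair).
#' @param order_conservation `"conserved"` (archetype gene order) or
#'   `"shuffled"` (random order per locus).
#' @param genus_enrichment optional `list(genus =, multiplier =)`
#'   multiplying the tandem-anchor probability in one genus.
#' @param p_outside_cazyme_run expected number (Poisson) of CAZyme runs
#'   outside loci per genome.
#' @param p_regulator probability an anchored locus carries a regulator
#'   gene next to its anchor.
#' @param seed RNG seed.
#' @return A `pul_sim_config` list.
#' @export
sim_config <- function(n_genomes = 150L, n_archetypes = 40L,
                       vocabulary = default_vocabulary(),
                       archetype_size_lambda = 2.7,
                       archetype_size = NULL,
                       loci_per_genome_lambda = 7,
                       loci_per_genome = NULL,
                       p_family_swap = 0.05, p_family_drop = 0.05,
                       p_dup_prone = 0.13, p_duplicate = 0.015,
                       trsuscd_fraction = 0.033,
                       p_no_cazyme_locus = 0.5,
                       p_reject = 0.107,
                       order_conservation = c("conserved", "shuffled"),
                       genus_enrichment = NULL,
                       p_outside_cazyme_run = 1.5,
                       p_regulator = 0.4,
                       seed = 1L) {
  order_conservation <- match.arg(order_conservation)
  probs <- c(p_family_swap, p_family_drop, p_dup_prone, p_duplicate,
             trsuscd_fraction, p_no_cazyme_locus, p_reject, p_regulator)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_genomes >= 1L, n_archetypes >= 1L)
  caz <- setdiff(vocabulary, c(SULF_FEATURE, PEPT_FEATURE))
  if (length(caz) < 2L) {
    stop("vocabulary must contain at least two CAZyme features",
         call. = FALSE)
  }
  if (!is.null(archetype_size) && max(archetype_size) > length(caz)) {
    stop("vocabulary smaller than the maximum archetype size", call. = FALSE)
  }
  structure(list(
    n_genomes = as.integer(n_genomes),
    n_archetypes = as.integer(n_archetypes),
    vocabulary = vocabulary,
    archetype_size_lambda = archetype_size_lambda,
    archetype_size = archetype_size,
    loci_per_genome_lambda = loci_per_genome_lambda,
    loci_per_genome = if (is.null(loci_per_genome)) NULL
                      else as.integer(loci_per_genome),
    p_family_swap = p_family_swap, p_family_drop = p_family_drop,
    p_dup_prone = p_dup_prone, p_duplicate = p_duplicate,
    trsuscd_fraction = trsuscd_fraction,
    p_no_cazyme_locus = p_no_cazyme_locus,
    p_reject = p_reject,
    order_conservation = order_conservation,
    genus_enrichment = genus_enrichment,
    p_outside_cazyme_run = p_outside_cazyme_run,
    p_regulator = p_regulator,
    seed = as.integer(seed)
  ), class = "pul_sim_config")
}

# One gene row (list form, bound into a data.frame at the end).
sim_gene <- function(genome, replicon, ordinal, strand, category,
                     family = "") {
  list(genome_id = genome, replicon_id = replicon,
       gene_ordinal = ordinal, strand = strand, category = category,
       family_label = family,
       protein_id = sprintf("%s_p%05d", genome, ordinal))
}

# Draw the noised composition of one PUL from its archetype. Duplication
# follows the archetype's duplication-prone profile (inherited, so loci
# of one archetype mostly share their copy numbers) with a small
# per-locus deviation rate. Returns a list: features (ordered), copies
# (per feature) and the noise events.
noise_archetype <- function(features, prone, caz_pool, cfg) {
  events <- character(0)
  if (length(features) >= 2L && stats::runif(1) < cfg$p_family_drop) {
    drop <- sample.int(length(features), 1L)
    events <- c(events, paste0("drop:", features[drop]))
    features <- features[-drop]
    prone <- prone[-drop]
  }
  if (stats::runif(1) < cfg$p_family_swap) {
    pos <- sample.int(length(features), 1L)
    candidates <- setdiff(caz_pool, features)
    if (length(candidates) > 0L) {
      repl <- sample(candidates, 1L)
      events <- c(events, paste0("swap:", features[pos], ">", repl))
      features[pos] <- repl
      prone[pos] <- 1L
    }
  }
  copies <- prone  # archetype copy profile (1, 2 or 3 per family)
  flip <- stats::runif(length(features)) < cfg$p_duplicate
  copies[flip] <- ifelse(copies[flip] == 1L, 2L, 1L)
  if (any(flip)) {
    events <- c(events, paste0("dup:", features[flip], "x", copies[flip]))
  }
  list(features = features, copies = copies, events = events)
}

#' Generate a synthetic gene-table dataset with ground truth
#'
#' @param config a `pul_sim_config` from [sim_config()].
#' @return A `pul_sim` (also a valid `pul_dataset`): list with `genes`
#'   (validated gene table), `meta` (genome metadata), `truth` (one row
#'   per emitted locus: span, expected class, archetype id, noise
#'   events), `archetypes` (named list archetype id -> feature vector)
#'   and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- config
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  caz_pool <- setdiff(cfg$vocabulary, c(SULF_FEATURE, PEPT_FEATURE))
  K <- cfg$n_archetypes
  sizes <- if (!is.null(cfg$archetype_size)) {
    rep_len(as.integer(cfg$archetype_size), K)
  } else {
    pmin(1L + stats::rpois(K, cfg$archetype_size_lambda), length(caz_pool))
  }
  # archetype compositions are kept distinct as sets, so K is the true
  # number of unique compositions under zero noise
  archetypes <- list()
  seen <- character(0)
  for (s in sizes) {
    repeat {
      cand <- sample(caz_pool, s)
      key <- paste(sort(cand), collapse = "|")
      if (!key %in% seen) { seen <- c(seen, key); break }
    }
    archetypes[[length(archetypes) + 1L]] <- cand
  }
  names(archetypes) <- sprintf("A%03d", seq_len(K))
  # archetype copy profile: duplication-prone families carry 2 (or,
  # rarely, 3) gene copies in every locus of that archetype
  dup_prone <- lapply(sizes, function(s) {
    ifelse(stats::runif(s) < cfg$p_dup_prone,
           2L + stats::rbinom(s, 1L, 0.1), 1L)
  })
  names(dup_prone) <- names(archetypes)
  # long-tailed archetype abundances: a few very frequent compositions
  weights <- 0.92^(seq_len(K) - 1L)
  weights <- weights / sum(weights)

  gpool <- GENUS_POOL[sample.int(nrow(GENUS_POOL), cfg$n_genomes,
                                 replace = TRUE), ]
  meta <- data.frame(
    genome_id = sprintf("G%04d", seq_len(cfg$n_genomes)),
    taxon_class = gpool$taxon_class,
    genus = gpool$genus,
    species = sprintf("%s sp%04d", gpool$genus, seq_len(cfg$n_genomes)),
    habitat = gpool$habitat,
    stringsAsFactors = FALSE
  )

  genes <- vector("list", 0L)
  truth <- vector("list", 0L)
  serial <- 0L

  for (gi in seq_len(cfg$n_genomes)) {
    genome <- meta$genome_id[gi]
    replicon <- "chr1"
    ordinal <- 0L
    emit <- function(category, strand, family = "") {
      ordinal <<- ordinal + 1L
      genes[[length(genes) + 1L]] <<-
        sim_gene(genome, replicon, ordinal, strand, category, family)
    }
    filler <- function() {
      for (k in seq_len(sample(4:9, 1L))) emit("other", sample(c("+", "-"), 1L))
    }
    tr_prob <- cfg$trsuscd_fraction
    if (!is.null(cfg$genus_enrichment) &&
        meta$genus[gi] == cfg$genus_enrichment$genus) {
      tr_prob <- min(1, tr_prob * cfg$genus_enrichment$multiplier)
    }
    n_loci <- if (!is.null(cfg$loci_per_genome)) cfg$loci_per_genome
              else 1L + stats::rpois(1L, cfg$loci_per_genome_lambda)
    n_outside <- stats::rpois(1L, cfg$p_outside_cazyme_run)
    outside_slots <- if (n_outside > 0L && n_loci > 0L) {
      sample.int(n_loci, min(n_outside, n_loci), replace = FALSE)
    } else integer(0)

    for (li in seq_len(n_loci)) {
      filler()
      if (li %in% outside_slots) {
        # CAZyme run outside any susC/D locus
        start <- ordinal + 1L
        fams <- sample(caz_pool, sample(1:3, 1L))
        s <- sample(c("+", "-"), 1L)
        for (f in fams) emit(sample(CAZYME_CATEGORIES[startsWith(f, CAZYME_CATEGORIES)], 1L), s, f)
        serial <- serial + 1L
        truth[[length(truth) + 1L]] <- list(
          serial = serial, genome_id = genome, replicon_id = replicon,
          start_ordinal = start, end_ordinal = ordinal,
          expected_class = "CAZYME_CLUSTER_NO_SUSCD",
          archetype = NA_character_, n_pairs = 0L,
          features = paste(sort(fams), collapse = "|"), events = "")
        filler()
      }
      start <- ordinal + 1L
      s <- sample(c("+", "-"), 1L)
      rejected <- stats::runif(1) < cfg$p_reject
      if (rejected) {
        variant <- sample(3L, 1L)
        if (variant == 1L) {            # susC, other, susD (non-adjacent)
          emit("susC", s); emit("other", s); emit("susD", s)
        } else if (variant == 2L) {     # adjacent pair on opposite strands
          emit("susC", s); emit("susD", if (s == "+") "-" else "+")
        } else {                        # lone susC
          emit("susC", s)
        }
        serial <- serial + 1L
        truth[[length(truth) + 1L]] <- list(
          serial = serial, genome_id = genome, replicon_id = replicon,
          start_ordinal = start, end_ordinal = ordinal,
          expected_class = "REJECTED", archetype = NA_character_,
          n_pairs = 0L, features = "", events = "")
        next
      }
      tandem <- stats::runif(1) < tr_prob
      n_pairs <- if (tandem) 2L + stats::rbinom(1L, 1L, 0.1) else 1L
      no_caz <- stats::runif(1) < cfg$p_no_cazyme_locus
      arch <- NA_character_
      enzymes <- character(0)
      copies <- integer(0)
      events <- ""
      if (!no_caz) {
        arch <- sample(names(archetypes), 1L, prob = weights)
        nz <- noise_archetype(archetypes[[arch]], dup_prone[[arch]],
                              caz_pool, cfg)
        enzymes <- nz$features
        copies <- nz$copies
        events <- paste(nz$events, collapse = ";")
        if (cfg$order_conservation == "shuffled" && length(enzymes) > 1L) {
          p <- sample.int(length(enzymes))
          enzymes <- enzymes[p]; copies <- copies[p]
        }
      }
      # expand duplicates to one gene per copy, duplicates adjacent
      enzyme_genes <- rep(enzymes, times = if (length(copies)) copies else 0L)
      extra <- character(0)  # non-CAZyme degradative content
      if (no_caz && stats::runif(1) < 0.11) {
        extra <- sample(c("sulfatase", "peptidase"), 1L)
      } else if (no_caz && stats::runif(1) < 0.04) {
        extra <- "phosphodiesterase"
      }
      regulator <- stats::runif(1) < cfg$p_regulator
      anchor_cats <- rep(c("susC", "susD"), n_pairs)
      block <- list()
      add <- function(category, family = "") {
        block[[length(block) + 1L]] <<- c(category, family)
      }
      if (s == "+") {
        for (a in anchor_cats) add(a)
        if (regulator) add("regulator")
        for (f in enzyme_genes) {
          add(CAZYME_CATEGORIES[startsWith(f, CAZYME_CATEGORIES)][1L], f)
        }
        for (e in extra) add(e)
      } else {
        for (e in rev(extra)) add(e)
        for (f in rev(enzyme_genes)) {
          add(CAZYME_CATEGORIES[startsWith(f, CAZYME_CATEGORIES)][1L], f)
        }
        if (regulator) add("regulator")
        for (a in rev(anchor_cats)) add(a)
      }
      # occasionally interleave one non-degradative gene inside the locus,
      # but never inside the susC/D anchor run
      anchor_span <- if (s == "+") seq_len(2L * n_pairs)
                     else (length(block) - 2L * n_pairs + 1L):length(block)
      insertable <- setdiff(2:length(block), setdiff(anchor_span, min(anchor_span)))
      insert_at <- if (length(insertable) > 0L && stats::runif(1) < 0.15) {
        if (length(insertable) == 1L) insertable else sample(insertable, 1L)
      } else 0L
      for (bi in seq_along(block)) {
        if (bi == insert_at) emit("other", s)
        emit(block[[bi]][1L], s, block[[bi]][2L])
      }
      expected <- if (n_pairs >= 2L) "TRSUSCD_PUL"
                  else if (length(enzyme_genes) == 0L) "NO_CAZYME"
                  else "PUL"
      serial <- serial + 1L
      truth[[length(truth) + 1L]] <- list(
        serial = serial, genome_id = genome, replicon_id = replicon,
        start_ordinal = start, end_ordinal = ordinal,
        expected_class = expected, archetype = arch, n_pairs = n_pairs,
        features = paste(sort(unique(enzymes)), collapse = "|"),
        events = events)
    }
    filler()
  }

  genes <- do.call(rbind, lapply(genes, function(g)
    as.data.frame(g, stringsAsFactors = FALSE)))
  genes <- validate_gene_table(genes, vocabulary = cfg$vocabulary)
  truth <- do.call(rbind, lapply(truth, function(t)
    as.data.frame(t, stringsAsFactors = FALSE)))
  structure(list(genes = genes, meta = meta, truth = truth,
                 archetypes = archetypes, dup_prone = dup_prone,
                 config = cfg),
            class = c("pul_sim", "pul_dataset"))
}

#' Compare pipeline output against simulation ground truth
#'
#' Matches every ground-truth locus to the detected locus overlapping its
#' gene span, tabulates class confusion, and scores archetype recovery:
#' `k_hat` is the cluster count of the detected PUL compositions at the
#' given mismatch threshold, `k_true` the number of distinct archetypes
#' actually emitted as PULs, and `purity` the weighted fraction of each
#' cluster belonging to its majority archetype.
#'
#' @param sim a `pul_sim` from [simulate_dataset()].
#' @param sorted a `pul_sort` from running [sort_dataset()] on `sim`.
#' @param mismatch_percent threshold for archetype recovery (default 0).
#' @param mode composition mode.
#' @return List with `k_true`, `k_hat`, `k_error`, `purity`, `confusion`
#'   (truth class x detected class table) and `n_unmatched`.
#' @export
recovery_report <- function(sim, sorted, mismatch_percent = 0,
                            mode = c("presence", "copy_aware")) {
  mode <- match.arg(mode)
  truth <- sim$truth
  det <- sorted$table
  match_locus <- function(k) {
    hit <- which(det$genome_id == truth$genome_id[k] &
                   det$replicon_id == truth$replicon_id[k] &
                   det$start_ordinal <= truth$end_ordinal[k] &
                   det$end_ordinal >= truth$start_ordinal[k])
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }
  idx <- vapply(seq_len(nrow(truth)), match_locus, integer(1))
  matched <- !is.na(idx)
  confusion <- table(truth = truth$expected_class[matched],
                     detected = det$locus_class[idx[matched]])

  puls <- pul_loci(sorted)
  if (length(puls) == 0L) {
    stop("no PULs detected; cannot score archetype recovery", call. = FALSE)
  }
  mat <- build_matrix(puls, vocabulary = sim$config$vocabulary, mode = mode)
  clusters <- cluster_compositions(mat, mismatch_percent, mode)
  # archetype of each detected PUL, via the span match in reverse
  arch_of <- rep(NA_character_, nrow(det))
  arch_of[idx[matched]] <- truth$archetype[matched]
  arch <- arch_of[match(names(clusters$labels), det$locus_id)]
  ok <- !is.na(arch)
  purity <- if (any(ok)) {
    by_cl <- split(arch[ok], clusters$labels[ok])
    sum(vapply(by_cl, function(a) max(table(a)), numeric(1))) / sum(ok)
  } else NA_real_
  k_true <- length(unique(stats::na.omit(truth$archetype)))
  list(k_true = k_true, k_hat = clusters$n_clusters,
       k_error = clusters$n_clusters - k_true, purity = purity,
       confusion = confusion, n_unmatched = sum(!matched))
}
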