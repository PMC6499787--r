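test_that("susC/D anchors require adjacency on one strand", {
  expect_equal(find_sus_pairs(toy_genes("susC", "susD"))$n_pairs, 1L)
  # tandem repeat merges into one multi-pair anchor
  a <- find_sus_pairs(toy_genes("susC", "susD", "susC", "susD"))
  expect_equal(nrow(a), 1L)
  expect_equal(a$n_pairs, 2L)
  # a gene between the pair, or opposite strands, breaks the anchor
  expect_equal(nrow(find_sus_pairs(toy_genes("susC", "GH:GH2", "susD"))), 0L)
  expect_equal(nrow(find_sus_pairs(toy_genes("susC::+", "susD::-"))), 0L)
  # reverse-strand loci appear D-then-C; still one anchor
  expect_equal(find_sus_pairs(toy_genes("susD::-", "susC::-"))$n_pairs, 1L)
  # alternating run with a trailing odd gene: still one anchor, 1 pair
  a3 <- find_sus_pairs(toy_genes("susC", "susD", "susC"))
  expect_equal(a3$n_pairs, 1L)
  expect_equal(nrow(find_sus_pairs(toy_genes("GH:GH2", "other"))), 0L)
})

test_that("locus extension stops after max_gap non-degradative genes", {
  g <- toy_genes("susC", "susD", "GH:GH2")
  loci <- build_loci(g, max_gap = 2)
  expect_equal(length(loci), 1L)
  expect_equal(nrow(loci[[1]]$genes), 3L)  # GH included, gap 0

  g2 <- toy_genes("susC", "susD", "other", "other", "other", "GH:GH2")
  loci2 <- build_loci(g2, max_gap = 2, include_cazyme_clusters = FALSE)
  expect_equal(max(loci2[[1]]$genes$gene_ordinal), 2L)  # gap 3 > 2

  g3 <- toy_genes("susC", "susD", "other", "other", "GH:GH2")
  loci3 <- build_loci(g3, max_gap = 2)
  expect_equal(max(loci3[[1]]$genes$gene_ordinal), 5L)  # gap 2 <= 2
})

test_that("two anchors with flanking CAZymes give disjoint loci", {
  g <- toy_genes("GH:GH2", "susC", "susD", "GH:GH3",
                 "other", "other", "other", "other",
                 "GH:GH10", "susC", "susD", "GH:GH16")
  loci <- build_loci(g, max_gap = 2)
  expect_equal(length(loci), 2L)
  spans <- lapply(loci, function(l) range(l$genes$gene_ordinal))
  expect_equal(spans[[1]], c(1L, 4L))
  expect_equal(spans[[2]], c(9L, 12L))
  # brute-force check: no gene belongs to both loci
  expect_length(intersect(seq(spans[[1]][1], spans[[1]][2]),
                          seq(spans[[2]][1], spans[[2]][2])), 0L)
})

test_that("locus classification follows the sorting rules", {
  expect_equal(toy_locus(toy_genes("susC", "susD", "GH:GH2"))$locus_class,
               "PUL")
  expect_equal(toy_locus(toy_genes("susC", "susD", "sulfatase"))$locus_class,
               "NO_CAZYME")
  expect_equal(
    toy_locus(toy_genes("susC", "susD", "susC", "susD", "GH:GH2"))$locus_class,
    "TRSUSCD_PUL")
  expect_equal(toy_locus(toy_genes("susC", "other", "susD"))$locus_class,
               "REJECTED")
  expect_equal(toy_locus(toy_genes("GH:GH2", "GH:GH3"))$locus_class,
               "CAZYME_CLUSTER_NO_SUSCD")
  empty <- list(genes = data.frame())
  class(empty) <- "pul_locus"
  expect_error(classify_locus(empty), "empty")
})

test_that("a hand-built table of five loci is sorted correctly", {
  g <- rbind(
    toy_genes("susC", "other", "susD"),                         # REJECTED
    toy_genes("susC", "susD", "susC", "susD", "GH:GH2"),        # TRSUSCD
    toy_genes("susC", "susD", "GH:GH10", "PL:PL1"),             # PUL
    toy_genes("susD::-", "susC::-", "CE:CE1:-"),                # PUL (rev)
    toy_genes("susC", "susD", "regulator")                      # NO_CAZYME
  )
  # re-space the blocks along one replicon with wide filler gaps
  blocks <- list(1:3, 4:8, 9:12, 13:15, 16:18)
  rows <- list(); ordinal <- 0L
  for (b in blocks) {
    for (k in 1:6) {
      ordinal <- ordinal + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = "G1", replicon_id = "R1", gene_ordinal = ordinal,
        strand = "+", category = "other", family_label = "",
        protein_id = sprintf("f%03d", ordinal), stringsAsFactors = FALSE)
    }
    for (i in b) {
      ordinal <- ordinal + 1L
      r <- g[i, ]; r$gene_ordinal <- ordinal
      rows[[length(rows) + 1L]] <- r
    }
  }
  genes <- validate_gene_table(do.call(rbind, rows))
  sorted <- sort_dataset(genes)
  s <- sorted$summary
  expect_equal(s$n_loci_total, 5L)
  expect_equal(s$n_rejected, 1L)
  expect_equal(s$n_trsuscd, 1L)
  expect_equal(s$n_no_cazyme, 1L)
  expect_equal(s$n_puls, 2L)
  expect_equal(s$n_puls_for_composition, 3L)  # trsusCD with CAZyme included
})

test_that("sorting an empty or all-PUL dataset gives consistent counts", {
  empty <- validate_gene_table(toy_genes("other", "other"))
  s0 <- sort_dataset(empty)$summary
  expect_equal(s0$n_loci_total, 0L)
  expect_equal(s0$n_puls, 0L)

  sim <- simulate_dataset(sim_config(
    n_genomes = 5, n_archetypes = 4, seed = 2, p_reject = 0,
    p_no_cazyme_locus = 0, trsuscd_fraction = 0, p_outside_cazyme_run = 0))
  s <- sort_dataset(sim)$summary
  expect_equal(s$n_puls, s$n_loci_total)
})

test_that("classification is a partition and summary counts add up", {
  sim <- simulate_dataset(sim_config(n_genomes = 25, seed = 5))
  sorted <- sort_dataset(sim)
  expect_equal(nrow(sorted$table), length(sorted$loci))
  expect_true(all(sorted$table$locus_class %in% LOCUS_CLASSES))
  s <- sorted$summary
  expect_equal(s$n_rejected + s$n_trsuscd + s$n_no_cazyme + s$n_puls +
                 s$n_cazyme_clusters_no_suscd, s$n_loci_total)
})

test_that("reversing gene order and flipping strands preserves classes", {
  sim <- simulate_dataset(sim_config(n_genomes = 10, seed = 9))
  fwd <- sort_dataset(sim)$summary
  g <- as.data.frame(sim$genes)
  for (gid in unique(g$genome_id)) {
    sel <- g$genome_id == gid
    n <- max(g$gene_ordinal[sel])
    g$gene_ordinal[sel] <- n + 1L - g$gene_ordinal[sel]
  }
  g$strand <- ifelse(g$strand == "+", "-", "+")
  rev_sorted <- sort_dataset(validate_gene_table(g))$summary
  expect_equal(rev_sorted, fwd)
})

test_that("tandem classification ignores which pair comes first", {
  a <- toy_locus(toy_genes("susC", "susD", "susC", "susD", "GH:GH2"))
  b <- toy_locus(toy_genes("GH:GH2", "susC", "susD", "susC", "susD"))
  expect_equal(a$locus_class, "TRSUSCD_PUL")
  expect_equal(b$locus_class, a$locus_class)
})
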