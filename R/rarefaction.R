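# Genome-resampling rarefaction -----------------------------------------------
#
# How does the number of unique PULs grow with the number of genomes
# analyzed? Genomes are subsampled without replacement at increasing
# sample sizes, the pooled PULs are counted at a composition mismatch
# threshold, replicate medians are taken, and a second-order polynomial
# fitted to the (size, median) pairs gives the saturation trend.

#' Unique-PUL counts under genome resampling
#'
#' For each sample size and replicate, draws that many genomes without
#' replacement, pools their PUL compositions and counts unique PULs at
#' the given mismatch threshold (exact-equality grouping at 0%, tree cut
#' otherwise). A master seed spawns one substream per (size, replicate)
#' cell, so the full curve is reproducible bit-for-bit and independent of
#' evaluation order.
#'
#' @param matrix composition matrix (rows = PULs).
#' @param genome_ids character vector, the genome of each matrix row.
#' @param sizes genome-sample sizes; default ~15 roughly log-spaced values
#'   from 1 to the genome count.
#' @param replicates number of replicate draws per size (default 10).
#' @param mismatch_percent composition mismatch threshold (default 0).
#' @param mode `"presence"` or `"copy_aware"`.
#' @param seed master RNG seed.
#' @return A `pul_rarefaction`: list with `sizes`, `replicates` (size x
#'   replicate matrix of counts), `medians`, `mismatch_percent`, `mode`,
#'   `seed`.
#' @export
resample_unique_counts <- function(matrix, genome_ids, sizes = NULL,
                                   replicates = 10L, mismatch_percent = 0,
                                   mode = c("presence", "copy_aware"),
                                   seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(nrow(matrix) == length(genome_ids))
  genomes <- unique(genome_ids)
  if (is.null(sizes)) {
    sizes <- unique(round(exp(seq(0, log(length(genomes)), length.out = 15L))))
  }
  sizes <- as.integer(sizes)
  if (any(sizes < 0L) || any(sizes > length(genomes))) {
    stop("sample sizes must lie between 0 and the number of genomes (",
         length(genomes), ")", call. = FALSE)
  }
  keys <- composition_keys(matrix, mode)
  count_unique <- function(rows) {
    if (length(rows) == 0L) return(0L)
    if (mismatch_percent == 0) return(length(unique(keys[rows])))
    sub <- matrix[rows, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    cluster_compositions(sub, mismatch_percent, mode)$n_clusters
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  substreams <- sample.int(.Machine$integer.max, length(sizes) * replicates)
  counts <- matrix(0L, nrow = length(sizes), ncol = replicates,
                   dimnames = list(size = sizes, replicate = NULL))
  cell <- 0L
  for (si in seq_along(sizes)) {
    for (r in seq_len(replicates)) {
      cell <- cell + 1L
      set.seed(substreams[cell])
      picked <- sample(genomes, sizes[si], replace = FALSE)
      counts[si, r] <- count_unique(which(genome_ids %in% picked))
    }
  }
  structure(list(sizes = sizes, replicates = counts,
                 medians = apply(counts, 1L, stats::median),
                 mismatch_percent = mismatch_percent, mode = mode,
                 seed = seed),
            class = "pul_rarefaction")
}

#' Quadratic trend of a rarefaction curve
#'
#' Least-squares second-order polynomial on the (size, median) pairs via
#' [stats::lm()].
#'
#' @param curve a `pul_rarefaction`, or a data.frame/list with `sizes`
#'   and `medians`.
#' @return A `pul_polytrend`: list with `coefficients` (a0, a1, a2),
#'   `fitted`, `rss` and the fitted size range.
#' @export
fit_poly2 <- function(curve) {
  x <- curve$sizes
  y <- curve$medians
  if (length(unique(x)) < 3L) {
    stop("quadratic fit needs at least 3 distinct sizes", call. = FALSE)
  }
  fit <- stats::lm(y ~ x + I(x^2))
  co <- unname(stats::coef(fit))
  structure(list(coefficients = c(a0 = co[1L], a1 = co[2L], a2 = co[3L]),
                 fitted = unname(stats::fitted(fit)),
                 rss = sum(stats::residuals(fit)^2),
                 size_range = range(x)),
            class = "pul_polytrend")
}

#' Evaluate a quadratic trend at new sizes
#'
#' Polynomial evaluation `a0 + a1*x + a2*x^2`; values outside the fitted
#' size range are flagged as extrapolations via the `"extrapolated"`
#' attribute.
#'
#' @param trend a `pul_polytrend` from [fit_poly2()].
#' @param size numeric vector of genome counts.
#' @return Predicted unique-PUL counts with attribute `extrapolated`.
#' @export
extrapolate <- function(trend, size) {
  co <- trend$coefficients
  out <- co[["a0"]] + co[["a1"]] * size + co[["a2"]] * size^2
  attr(out, "extrapolated") <- size < trend$size_range[1L] |
    size > trend$size_range[2L]
  out
}
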