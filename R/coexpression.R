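# Mutual-information coexpression inference: all-pairs MI on equal-frequency
# rank bins (copula transform), a permutation-calibrated significance
# threshold with right-tail exponential extrapolation for very small
# p-values, and data-processing-inequality (DPI) pruning of the weakest edge
# in each MI triangle.

#' Expression matrix loader
#'
#' Reads a TSV whose first column holds gene identifiers and whose header
#' row holds sample identifiers. Rows with any missing value are rejected.
#'
#' @param path TSV path.
#' @return numeric matrix, genes in rows (rownames), samples in columns.
#' @export
load_expression <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1L]]
  if (anyNA(m)) {
    bad <- rownames(m)[apply(m, 1L, anyNA)]
    stop("missing values in expression rows: ", paste(head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  if (ncol(m) < 8L) stop("need >= 8 samples for MI estimation", call. = FALSE)
  m
}

#' Coexpression inference parameters
#'
#' @param mi_pvalue significance level for the MI permutation null
#'   (default 1e-7).
#' @param dpi_tolerance DPI tolerance in \[0, 1\] (default 0.15).
#' @param n_permutations null draws used to calibrate the MI threshold
#'   (default 1e5; levels below `1/n_permutations` are reached by right-tail
#'   exponential extrapolation unless `exact_tail = TRUE`).
#' @param bins number of equal-frequency bins, or `"auto"` for
#'   `round(n_samples^(1/3))`.
#' @param seed integer seed driving the permutation null.
#' @param exact_tail require a fully empirical quantile (then
#'   `n_permutations` must be at least `1/mi_pvalue`).
#' @return list of class `coexpression_params`.
#' @export
coexpression_params <- function(mi_pvalue = 1e-7, dpi_tolerance = 0.15,
                                n_permutations = 1e5, bins = "auto",
                                seed = 1L, exact_tail = FALSE) {
  stopifnot(mi_pvalue > 0, mi_pvalue <= 1, dpi_tolerance >= 0, dpi_tolerance <= 1,
            n_permutations >= 1)
  if (exact_tail && n_permutations < 1 / mi_pvalue)
    stop("exact tail calibration needs n_permutations >= 1/mi_pvalue", call. = FALSE)
  structure(list(mi_pvalue = mi_pvalue, dpi_tolerance = dpi_tolerance,
                 n_permutations = as.integer(n_permutations), bins = bins,
                 seed = as.integer(seed), exact_tail = exact_tail),
            class = "coexpression_params")
}

auto_bins <- function(n, bins) {
  if (identical(bins, "auto")) max(2L, as.integer(round(n^(1 / 3)))) else as.integer(bins)
}

rank_bins <- function(x, bins) {
  # equal-frequency bins on ranks; constant input collapses to one bin
  r <- rank(x, ties.method = "first")
  ceiling(r * bins / length(x))
}

#' Mutual information on equal-frequency rank bins
#'
#' Plug-in MI (in nats) of the joint histogram over `bins` equal-frequency
#' bins of the ranks of each input. Because only ranks enter, the estimate
#' is invariant under strictly monotone transforms of either variable. A
#' constant vector occupies a single bin and yields MI = 0.
#'
#' @param x,y numeric vectors of equal length >= 8.
#' @param bins number of bins or `"auto"`.
#' @return nonnegative MI estimate in nats.
#' @export
mutual_information <- function(x, y, bins = "auto") {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 8L) stop("need >= 8 observations", call. = FALSE)
  b <- auto_bins(n, bins)
  constant <- function(v) length(unique(v)) == 1L
  bx <- if (constant(x)) rep(1L, n) else rank_bins(x, b)
  by <- if (constant(y)) rep(1L, n) else rank_bins(y, b)
  joint <- table(bx, by) / n
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  max(mi, 0)
}

#' Permutation-calibrated MI significance threshold
#'
#' Draws `n_permutations` MI values between independent random permutations
#' (the rank-bin estimator depends only on ranks, so permuted ranks are the
#' exact null) and returns the MI value whose null exceedance probability is
#' `mi_pvalue`. When `mi_pvalue < 1/n_permutations` the right tail is
#' extrapolated by fitting an exponential to exceedances over the 99th
#' percentile of the null sample.
#'
#' @param n_samples number of expression samples.
#' @param params a [coexpression_params()].
#' @param return_null also return the null draws (for audit) as
#'   `attr(, "null")`.
#' @return numeric threshold (MI, nats), deterministic given `params$seed`.
#' @export
mi_threshold <- function(n_samples, params, return_null = FALSE) {
  stopifnot(inherits(params, "coexpression_params"))
  if (params$mi_pvalue >= 1) return(0)
  b <- auto_bins(n_samples, params$bins)
  null <- withr_seed(params$seed, {
    vapply(seq_len(params$n_permutations), function(i) {
      mutual_information(sample.int(n_samples), sample.int(n_samples), bins = b)
    }, numeric(1))
  })
  thr <- if (params$mi_pvalue >= 1 / params$n_permutations || params$exact_tail) {
    as.numeric(quantile(null, 1 - params$mi_pvalue, type = 1))
  } else {
    u <- as.numeric(quantile(null, 0.99, type = 1))
    exc <- null[null > u] - u
    lambda <- 1 / mean(exc)  # exponential MLE on the top-1% exceedances
    u + log(0.01 / params$mi_pvalue) / lambda
  }
  if (return_null) attr(thr, "null") <- null
  thr
}

# run code under a temporary RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Data-processing-inequality pruning of an MI edge set
#'
#' For every triangle (i, j, k) in the weighted gene-gene graph, the weakest
#' edge (i, k) is marked for removal iff
#' `MI_ik < min(MI_ij, MI_jk) * (1 - tolerance)`. Marking is evaluated
#' against the pre-pruning weights (two-pass mark-then-delete), so the
#' result does not depend on edge order, and pruning is idempotent.
#'
#' @param mi_edges data frame with columns `source`, `target`, `score`
#'   (MI > 0); undirected, one row per pair.
#' @param tolerance DPI tolerance in \[0, 1\].
#' @return the input data frame with marked edges removed.
#' @export
apply_dpi <- function(mi_edges, tolerance = 0.15) {
  stopifnot(tolerance >= 0, tolerance <= 1)
  if (nrow(mi_edges) == 0L) return(mi_edges)
  a <- pmin(mi_edges$source, mi_edges$target)
  b <- pmax(mi_edges$source, mi_edges$target)
  w <- setNames(mi_edges$score, paste(a, b, sep = "\r"))
  wkey <- function(p, q) paste(pmin(p, q), pmax(p, q), sep = "\r")
  nbrs <- split(c(b, a), c(a, b))
  drop <- character(0)
  for (j in names(nbrs)) {
    nb <- nbrs[[j]]
    if (length(nb) < 2L) next
    for (pair in asplit(combn(sort(nb), 2L), 2L)) {
      i <- pair[1L]; k <- pair[2L]
      ik <- wkey(i, k)
      if (is.na(w[ik])) next
      thr <- min(w[wkey(i, j)], w[wkey(j, k)]) * (1 - tolerance)
      if (w[ik] < thr) drop <- c(drop, ik)
    }
  }
  keep <- !(paste(a, b, sep = "\r") %in% drop)
  out <- mi_edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer gene-gene coexpression edges from an expression matrix
#'
#' All-pairs MI over the gene rows, thresholded at the permutation-null
#' level of `params$mi_pvalue`, then DPI-pruned at `params$dpi_tolerance`.
#'
#' @param matrix_ numeric expression matrix (genes x samples, rownames =
#'   gene ids) as returned by [load_expression()].
#' @param catalog a [node_catalog()] containing the genes.
#' @param params a [coexpression_params()].
#' @return An [edge_store()] of `gene-gene` edges scored by MI.
#' @export
infer_coexpression <- function(matrix_, catalog, params = coexpression_params()) {
  if (nrow(matrix_) < 3L) stop("need at least 3 genes", call. = FALSE)
  genes <- rownames(matrix_)
  thr <- mi_threshold(ncol(matrix_), params)
  pairs <- combn(seq_len(nrow(matrix_)), 2L)
  mi <- vapply(seq_len(ncol(pairs)), function(c_) {
    mutual_information(matrix_[pairs[1L, c_], ], matrix_[pairs[2L, c_], ],
                       bins = params$bins)
  }, numeric(1))
  keep <- mi > thr
  edges <- data.frame(source = genes[pairs[1L, keep]], target = genes[pairs[2L, keep]],
                      score = mi[keep], relation = rep("gene-gene", sum(keep)),
                      stringsAsFactors = FALSE)
  message(sprintf("MI threshold %.4f nats: kept %d/%d pairs before DPI",
                  thr, nrow(edges), ncol(pairs)))
  edges <- apply_dpi(edges, params$dpi_tolerance)
  edge_store(edges, catalog)
}
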