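# Statistical comparisons used around the network: a permutation test for
# miRNA-target enrichment in a candidate gene set, a one-sided
# Kolmogorov-Smirnov comparison of similarity-score distributions, Fisher's
# exact test (explicit hypergeometric construction), a shared-annotation
# 2x2 test, and Benjamini-Hochberg FDR adjustment.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped to 1, in the original order. Thin
#' validated wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector with values in (0, 1].
#' @return adjusted values, same order and length.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Permutation test of miRNA-target enrichment in a candidate set
#'
#' For each miRNA, `observed` is the number of its targets inside the
#' candidate set. The null redraws `|candidates|` genes uniformly without
#' replacement from the universe `n_perm` times and recounts; the empirical
#' p-value uses the add-one correction (r + 1)/(N + 1) with r = draws
#' reaching the observed count. The summary pairs each miRNA's observed
#' count with its null mean in a paired t-test (one plausible reading of an
#' across-miRNA comparison; the per-miRNA empirical p-values are the primary
#' output).
#'
#' @param targets_of named list: miRNA -> character vector of target genes.
#' @param candidates candidate gene set (must be a subset of `universe`).
#' @param universe background gene universe.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `results` (data frame: `mirna`, `observed`,
#'   `null_mean`, `empirical_p`, `n_permutations`, `seed`) and `summary`
#'   (paired t-test of observed vs null mean across miRNAs, or NULL when
#'   fewer than 2 miRNAs).
#' @export
permutation_target_enrichment <- function(targets_of, candidates, universe,
                                          n_perm = 10000L, seed = 1L) {
  stopifnot(n_perm >= 1L)
  if (!all(candidates %in% universe))
    stop("candidates must be a subset of the universe", call. = FALSE)
  mirnas <- sort(names(targets_of))
  tg <- lapply(targets_of[mirnas], function(t_) intersect(unique(t_), universe))
  observed <- vapply(tg, function(t_) sum(t_ %in% candidates), integer(1))
  nulls <- withr_seed(seed, {
    counts <- matrix(0L, nrow = n_perm, ncol = length(mirnas))
    for (r in seq_len(n_perm)) {
      draw <- sample(universe, length(candidates), replace = FALSE)
      counts[r, ] <- vapply(tg, function(t_) sum(t_ %in% draw), integer(1))
    }
    counts
  })
  r_ge <- colSums(nulls >= matrix(observed, nrow = n_perm, ncol = length(mirnas),
                                  byrow = TRUE))
  res <- data.frame(mirna = mirnas, observed = observed,
                    null_mean = colMeans(nulls),
                    empirical_p = (r_ge + 1) / (n_perm + 1),
                    n_permutations = n_perm, seed = seed,
                    stringsAsFactors = FALSE, row.names = NULL)
  summary_ <- if (length(mirnas) >= 2L && stats::sd(res$observed - res$null_mean) > 0)
    t.test(res$observed, res$null_mean, paired = TRUE, alternative = "greater")
  else NULL
  list(results = res, summary = summary_)
}

ecdf_right <- function(sample_, x) {
  # right-continuous ECDF evaluated at x
  vapply(x, function(v) mean(sample_ <= v), numeric(1))
}

#' One-sided Kolmogorov-Smirnov test: is `a` stochastically greater?
#'
#' Statistic D+ = sup_x (F_b(x) - F_a(x)) over right-continuous empirical
#' CDFs (ties allowed), with the asymptotic one-sided p-value
#' exp(-2 D^2 n_a n_b / (n_a + n_b)). Identical samples give exactly
#' (D = 0, p = 1).
#'
#' @param scores_a,scores_b non-empty numeric vectors.
#' @return named vector `c(D =, p =)`.
#' @export
ks_greater <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) > 0, length(scores_b) > 0)
  grid <- sort(unique(c(scores_a, scores_b)))
  D <- max(ecdf_right(scores_b, grid) - ecdf_right(scores_a, grid))
  D <- max(D, 0)
  na <- length(scores_a); nb <- length(scores_b)
  p <- min(1, exp(-2 * D^2 * na * nb / (na + nb)))
  c(D = D, p = p)
}

#' 2x2 contingency table constructor
#'
#' Layout: rows = condition (e.g. observed/null), columns = outcome
#' (e.g. shared/unshared): `a` = row1/col1, `b` = row1/col2, `c` =
#' row2/col1, `d` = row2/col2.
#'
#' @param a,b,c_,d nonnegative counts, at least one nonzero.
#' @return object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c_, d) {
  v <- c(a = a, b = b, c = c_, d = d)
  if (any(!is.finite(v)) || any(v < 0) || all(v == 0))
    stop("counts must be finite, nonnegative, not all zero", call. = FALSE)
  structure(as.list(v), class = "contingency_2x2")
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional inference on the hypergeometric distribution of cell
#' `a` given fixed margins. `"greater"` sums the upper tail P(A >= a);
#' `"two-sided"` sums the probabilities of all tables no more likely than
#' the observed one (with a 1 + 1e-7 relative tolerance on "no more
#' likely"). The odds ratio reported is the sample (cross-product) estimate
#' `(a d) / (b c)`.
#'
#' @param table_ a [contingency_2x2()].
#' @param alternative `"greater"` or `"two-sided"`.
#' @return named vector `c(odds_ratio =, p =)`.
#' @export
fisher_exact <- function(table_, alternative = c("greater", "two-sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(table_, "contingency_2x2"))
  a <- table_$a; b <- table_$b; c_ <- table_$c; d <- table_$d
  m <- a + b          # row-1 margin
  n_ <- c_ + d        # row-2 margin
  k <- a + c_         # col-1 margin
  lo <- max(0L, k - n_); hi <- min(m, k)
  support <- lo:hi
  dens <- dhyper(support, m, n_, k)
  p <- if (alternative == "greater") {
    sum(dens[support >= a])
  } else {
    sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
  }
  or <- (a * d) / (b * c_)
  c(odds_ratio = or, p = min(1, p))
}

#' Shared-annotation enrichment between observed and null pair lists
#'
#' A pair "shares" annotation iff its two term sets intersect (or are
#' identical in `mode = "exact"`). Builds the 2x2 table
#' (observed/null x shared/unshared) and applies one-sided
#' [fisher_exact()] for "observed pairs share more".
#'
#' @param observed_pairs,null_pairs two-column matrices or data frames of id
#'   pairs.
#' @param annotation named list: id -> character vector of terms. Pairs with
#'   an unannotated member are dropped with a message.
#' @param mode `"overlap"` (default) or `"exact"`.
#' @return list with `table` (the [contingency_2x2()]), `odds_ratio`, `p`.
#' @export
shared_annotation_test <- function(observed_pairs, null_pairs, annotation,
                                   mode = c("overlap", "exact")) {
  mode <- match.arg(mode)
  shares <- function(pairs) {
    pairs <- as.matrix(pairs)
    ann1 <- annotation[pairs[, 1L]]
    ann2 <- annotation[pairs[, 2L]]
    known <- !vapply(ann1, is.null, logical(1)) & !vapply(ann2, is.null, logical(1))
    if (any(!known))
      message(sprintf("dropped %d pair(s) with unannotated members", sum(!known)))
    if (!any(known)) return(NULL)
    mapply(function(x, y) {
      if (mode == "overlap") length(intersect(x, y)) > 0
      else setequal(x, y)
    }, ann1[known], ann2[known])
  }
  so <- shares(observed_pairs)
  sn <- shares(null_pairs)
  if (is.null(so) || is.null(sn))
    stop("all pairs unannotated in one of the lists", call. = FALSE)
  tab <- contingency_2x2(sum(so), sum(!so), sum(sn), sum(!sn))
  ft <- fisher_exact(tab, "greater")
  list(table = tab, odds_ratio = unname(ft["odds_ratio"]), p = unname(ft["p"]))
}
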