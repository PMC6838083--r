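# Pairwise equivalence testing of Cq log-ratios between two groups.
#
# Cq is a log2-scale quantity, so the difference Cq(a) - Cq(b) within a
# sample is the log2 ratio of the two genes' expressions; compositional
# loading shifts (a constant added to all genes of a sample) cancel in it.

#' Per-sample Cq differences for one gene pair
#'
#' Computes d_s = Cq(gene_a) - Cq(gene_b) for every sample where both genes
#' are present, carrying group labels over. Samples missing either gene are
#' excluded (complete-pairs analysis).
#'
#' @param matrix A [cq_matrix()].
#' @param gene_a,gene_b Gene names (columns of the matrix).
#' @return A list of class `pair_difference_series`: `gene_a`, `gene_b`,
#'   `d` (named numeric vector), `group` (character vector), `n_per_group`
#'   and `testable` (`TRUE` when every group retains at least two samples).
#' @export
pair_differences <- function(matrix, gene_a, gene_b) {
  stopifnot(inherits(matrix, "cq_matrix"))
  missing_genes <- setdiff(c(gene_a, gene_b), colnames(matrix$cq))
  if (length(missing_genes))
    stop_input_error("gene '%s' not present in the Cq matrix", missing_genes[1L])
  d <- matrix$cq[, gene_a] - matrix$cq[, gene_b]
  keep <- !is.na(d)
  group_levels <- unique(unname(matrix$groups))
  grp <- matrix$groups[keep]
  n_per_group <- vapply(group_levels, function(g) sum(grp == g), integer(1L))
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 d = d[keep], group = unname(grp),
                 group_levels = group_levels,
                 n_per_group = n_per_group,
                 testable = all(n_per_group >= 2L)),
            class = "pair_difference_series")
}

#' Two one-sided t-tests (TOST) of equivalence for one gene pair
#'
#' Tests whether the between-group change of the pairwise log-ratio lies
#' inside the equivalence region \[-delta, +delta\] (cycles). Assuming
#' Gaussian Cq differences with equal variance in the two groups, the
#' estimate is the difference of group means of d, its standard error comes
#' from the pooled variance with n1 + n2 - 2 degrees of freedom, and the
#' TOST p-value is the larger of the two one-sided t p-values against
#' H0: effect <= -delta and H0: effect >= +delta. Rejection at level alpha
#' is exactly equivalent to the (1 - 2 alpha) confidence interval being
#' contained in \[-delta, +delta\].
#'
#' @param series A [pair_differences()] result.
#' @param delta Equivalence half-width in cycles (> 0).
#' @param alpha Nominal one-sided level used for the reported confidence
#'   interval (level 1 - 2 alpha); default 0.05 gives the 90% CI.
#' @param variance_mode Only `"pooled"` (equal variances) is implemented.
#' @return A list of class `equivalence_result`: `gene_a`, `gene_b`,
#'   `delta`, `estimate` (mean d in second group minus first group), `se`,
#'   `df`, `ci_low`, `ci_high`, `p_tost`, `n1`, `n2`, `alpha`.
#' @export
tost_pair <- function(series, delta, alpha = 0.05,
                      variance_mode = c("pooled")) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(inherits(series, "pair_difference_series"), delta > 0,
            alpha > 0, alpha < 0.5)
  if (length(series$group_levels) != 2L)
    stop_input_error(
      "equivalence testing is defined for exactly 2 groups, found %d",
      length(series$group_levels))
  if (!series$testable)
    stop_input_error("pair (%s, %s) is untestable: fewer than 2 samples in a group",
                     series$gene_a, series$gene_b)
  g1 <- series$group_levels[1L]
  g2 <- series$group_levels[2L]
  d1 <- series$d[series$group == g1]
  d2 <- series$d[series$group == g2]
  n1 <- length(d1); n2 <- length(d2)
  df <- n1 + n2 - 2L
  estimate <- mean(d2) - mean(d1)
  s2 <- ((n1 - 1L) * stats::var(d1) + (n2 - 1L) * stats::var(d2)) / df
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    p <- if (abs(estimate) < delta) 0 else 1
    ci <- c(estimate, estimate)
  } else {
    p_lower <- stats::pt((estimate + delta) / se, df, lower.tail = FALSE)
    p_upper <- stats::pt((estimate - delta) / se, df)
    p <- max(p_lower, p_upper)
    tcrit <- stats::qt(1 - alpha, df)
    ci <- estimate + c(-1, 1) * tcrit * se
  }
  structure(list(gene_a = series$gene_a, gene_b = series$gene_b,
                 delta = delta, estimate = estimate, se = se, df = df,
                 ci_low = ci[1L], ci_high = ci[2L], p_tost = p,
                 n1 = n1, n2 = n2, alpha = alpha),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    "Equivalence test %s / %s (delta = %g Cq)\n  estimate %.4f, %g%% CI [%.4f, %.4f], p_tost = %.4g\n",
    x$gene_a, x$gene_b, x$delta, x$estimate, 100 * (1 - 2 * x$alpha),
    x$ci_low, x$ci_high, x$p_tost))
  invisible(x)
}

#' Equivalence tests for all gene pairs
#'
#' Runs [tost_pair()] on every unordered pair of genes in the matrix.
#' Pairs with fewer than two usable samples in some group are kept in the
#' table flagged `testable = FALSE` with `NA` statistics (distinct from
#' p = 1): they can never contribute a graph edge.
#'
#' @param matrix A [cq_matrix()] with exactly two groups.
#' @param delta Equivalence half-width in cycles.
#' @param alpha One-sided level for reported CIs; default 0.05.
#' @return Data frame of class `equivalence_pairs` with one row per pair and
#'   columns `gene_a`, `gene_b`, `estimate`, `se`, `df`, `ci_low`,
#'   `ci_high`, `p_tost`, `n1`, `n2`, `testable`; attributes `delta`,
#'   `genes`, `group_levels`, `alpha`.
#' @export
all_pairs <- function(matrix, delta, alpha = 0.05) {
  stopifnot(inherits(matrix, "cq_matrix"))
  genes <- colnames(matrix$cq)
  if (length(genes) < 2L)
    stop_input_error("need at least 2 genes, found %d", length(genes))
  if (length(unique(matrix$groups)) != 2L)
    stop_input_error(
      "equivalence testing is defined for exactly 2 groups, found %d",
      length(unique(matrix$groups)))
  pairs <- utils::combn(genes, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    s <- pair_differences(matrix, pairs[1L, k], pairs[2L, k])
    if (!s$testable)
      return(data.frame(gene_a = s$gene_a, gene_b = s$gene_b,
                        estimate = NA_real_, se = NA_real_, df = NA_integer_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_tost = NA_real_,
                        n1 = s$n_per_group[1L], n2 = s$n_per_group[2L],
                        testable = FALSE, stringsAsFactors = FALSE))
    r <- tost_pair(s, delta, alpha = alpha)
    data.frame(gene_a = r$gene_a, gene_b = r$gene_b, estimate = r$estimate,
               se = r$se, df = r$df, ci_low = r$ci_low, ci_high = r$ci_high,
               p_tost = r$p_tost, n1 = r$n1, n2 = r$n2, testable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "delta") <- delta
  attr(out, "alpha") <- alpha
  attr(out, "genes") <- genes
  attr(out, "group_levels") <- unique(unname(matrix$groups))
  class(out) <- c("equivalence_pairs", "data.frame")
  out
}

#' Write pairwise equivalence results as TSV
#'
#' @param pairs An [all_pairs()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  cols <- c("gene_a", "gene_b", "estimate", "se", "df", "ci_low", "ci_high",
            "p_tost", "n1", "n2")
  utils::write.table(as.data.frame(pairs)[, cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Fold change corresponding to an equivalence half-width
#'
#' At 100% amplification efficiency a Cq difference of `delta` cycles is a
#' `2^delta` fold change in expression; e.g. `delta = 0.5` corresponds to a
#' 1.414-fold change.
#'
#' @param delta Cq difference in cycles.
#' @return `2^delta`.
#' @export
fold_change <- function(delta) 2^delta
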