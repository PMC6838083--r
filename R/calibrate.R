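# Monte-Carlo calibration of the per-test rejection cutoff.
#
# Under the null "no set of genes is truly equivalent" we simulate Cq data
# in the least-favorable "fence" configuration: gene g receives a group-2
# expression shift of g * delta, so every adjacent gene pair sits exactly on
# the boundary of the equivalence region and no pair is truly equivalent.
# The cutoff is the largest per-test level at which the probability of any
# spurious clique of three or more genes stays below the target family-wise
# level. A clique of >= 3 nodes exists if and only if the graph contains a
# triangle, which is what the simulation checks.

#' Specify a cutoff calibration
#'
#' @param n_genes Number of candidate genes (>= 3).
#' @param group_sizes Integer vector `c(n1, n2)` of samples per group
#'   (each >= 2).
#' @param delta Equivalence half-width in cycles (> 0).
#' @param residual_sd Within-group standard deviation, in cycles, of the
#'   pairwise Cq differences under the null; typically estimated from the
#'   data with [estimate_residual_sd()].
#' @param n_sim Number of simulated null datasets; default 10000.
#' @param target_fwer Maximum tolerated probability of a spurious clique of
#'   more than two genes; default 0.05.
#' @param seed Integer RNG seed making the calibration reproducible.
#' @param null_model Null-data generator; only `"fence"` ships.
#' @return A list of class `calibration_spec`.
#' @export
calibration_spec <- function(n_genes, group_sizes, delta = 0.5, residual_sd,
                             n_sim = 10000L, target_fwer = 0.05, seed = 1L,
                             null_model = c("fence")) {
  null_model <- match.arg(null_model)
  stopifnot(n_genes >= 3L, length(group_sizes) == 2L, all(group_sizes >= 2L),
            delta > 0, residual_sd >= 0, n_sim >= 1L,
            target_fwer > 0, target_fwer <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 group_sizes = as.integer(group_sizes), delta = delta,
                 residual_sd = residual_sd, n_sim = as.integer(n_sim),
                 target_fwer = target_fwer, seed = as.integer(seed),
                 null_model = null_model),
            class = "calibration_spec")
}

#' Pooled within-group SD of pairwise Cq differences
#'
#' For every gene pair, the variance of d = Cq(a) - Cq(b) is pooled over the
#' two groups (complete pairs only); the returned value is the square root
#' of the mean pooled variance across all pairs. It is the data-informed
#' default for `residual_sd` in [calibration_spec()].
#'
#' @param matrix A [cq_matrix()] with two groups.
#' @return A single SD in cycles.
#' @export
estimate_residual_sd <- function(matrix) {
  stopifnot(inherits(matrix, "cq_matrix"))
  groups <- unique(unname(matrix$groups))
  stopifnot(length(groups) == 2L)
  genes <- colnames(matrix$cq)
  pairs <- utils::combn(length(genes), 2L)
  s2 <- vapply(seq_len(ncol(pairs)), function(k) {
    d <- matrix$cq[, pairs[1L, k]] - matrix$cq[, pairs[2L, k]]
    v <- df <- 0
    for (g in groups) {
      dg <- d[matrix$groups == g]
      dg <- dg[!is.na(dg)]
      if (length(dg) >= 2L) {
        v <- v + (length(dg) - 1L) * stats::var(dg)
        df <- df + length(dg) - 1L
      }
    }
    if (df > 0) v / df else NA_real_
  }, numeric(1L))
  sqrt(mean(s2, na.rm = TRUE))
}

#' Simulate one null (fence) Cq dataset
#'
#' Generates a samples-by-genes Cq matrix in which gene g carries a group-2
#' shift of `g * delta`, so consecutive genes differ by exactly delta and no
#' pair is truly equivalent at margin delta. Per-cell noise is iid Gaussian
#' with SD `residual_sd / sqrt(2)`, so pairwise differences have the
#' requested within-group SD.
#'
#' @param spec A [calibration_spec()].
#' @param replicate_seed Seed for this replicate.
#' @return A [cq_matrix()] with groups `g1`, `g2`.
#' @export
simulate_null_dataset <- function(spec, replicate_seed = spec$seed) {
  stopifnot(inherits(spec, "calibration_spec"))
  set.seed(replicate_seed)
  G <- spec$n_genes
  n1 <- spec$group_sizes[1L]; n2 <- spec$group_sizes[2L]
  n <- n1 + n2
  baseline <- 25
  cell_sd <- spec$residual_sd / sqrt(2)
  vals <- matrix(stats::rnorm(n * G, baseline, cell_sd), n, G)
  shift <- spec$delta * seq_len(G)
  vals[(n1 + 1):n, ] <- sweep(vals[(n1 + 1):n, , drop = FALSE], 2L, shift, `+`)
  dimnames(vals) <- list(sprintf("S%03d", seq_len(n)),
                         sprintf("G%02d", seq_len(G)))
  cq_matrix(vals, stats::setNames(rep(c("g1", "g2"), c(n1, n2)),
                                  rownames(vals)))
}

# Vectorised fast path: TOST p-values for all pairs in each of n_sim
# simulated fence datasets. Returns an n_sim x n_pairs matrix; RNG state is
# taken from spec$seed so repeated calls are bit-identical.
null_pair_pvalues <- function(spec) {
  set.seed(spec$seed)
  G <- spec$n_genes
  n1 <- spec$group_sizes[1L]; n2 <- spec$group_sizes[2L]
  df <- n1 + n2 - 2L
  cell_sd <- spec$residual_sd / sqrt(2)
  idx <- utils::combn(G, 2L)
  ii <- idx[1L, ]; jj <- idx[2L, ]
  shift <- spec$delta * seq_len(G)
  true_diff <- shift[jj] - shift[ii]
  fac <- sqrt(1 / n1 + 1 / n2)
  out <- matrix(NA_real_, spec$n_sim, length(ii))
  for (s in seq_len(spec$n_sim)) {
    X1 <- matrix(stats::rnorm(n1 * G, 0, cell_sd), n1, G)
    X2 <- matrix(stats::rnorm(n2 * G, 0, cell_sd), n2, G)
    m1 <- colMeans(X1); m2 <- colMeans(X2)
    C1 <- stats::cov(X1); C2 <- stats::cov(X2)
    est <- (m2[jj] - m2[ii]) + true_diff - (m1[jj] - m1[ii])
    s2d <- ((n1 - 1L) * (C1[cbind(ii, ii)] + C1[cbind(jj, jj)] -
                           2 * C1[cbind(ii, jj)]) +
            (n2 - 1L) * (C2[cbind(ii, ii)] + C2[cbind(jj, jj)] -
                           2 * C2[cbind(ii, jj)])) / df
    se <- sqrt(s2d) * fac
    p <- pmax(stats::pt((est + spec$delta) / se, df, lower.tail = FALSE),
              stats::pt((est - spec$delta) / se, df))
    zero <- se == 0  # degenerate draws: TOST decided by the estimate alone
    if (any(zero)) p[zero] <- as.numeric(abs(est[zero]) >= spec$delta)
    out[s, ] <- p
  }
  attr(out, "pair_i") <- ii
  attr(out, "pair_j") <- jj
  out
}

has_triangle <- function(p, cutoff, G, ii, jj) {
  edge <- p < cutoff
  if (sum(edge) < 3L) return(FALSE)
  A <- matrix(FALSE, G, G)
  A[cbind(ii[edge], jj[edge])] <- TRUE
  A <- A | t(A)
  any((A %*% A)[A] > 0)
}

#' Probability of a spurious clique of three or more genes
#'
#' Fraction of simulated null (fence) datasets whose equivalence graph, at
#' the given per-test cutoff, contains any clique of at least three nodes
#' (equivalently, a triangle). Reproducible for a fixed `spec$seed`.
#'
#' @param spec A [calibration_spec()].
#' @param cutoff Per-test rejection threshold in (0, 1].
#' @param pvalues Optional precomputed matrix from the internal simulation
#'   path, reused across cutoffs (common random numbers).
#' @return A probability in `[0, 1]`.
#' @export
spurious_clique_probability <- function(spec, cutoff, pvalues = NULL) {
  stopifnot(inherits(spec, "calibration_spec"), cutoff >= 0, cutoff <= 1)
  if (cutoff == 0) return(0)
  if (is.null(pvalues)) pvalues <- null_pair_pvalues(spec)
  ii <- attr(pvalues, "pair_i"); jj <- attr(pvalues, "pair_j")
  mean(vapply(seq_len(nrow(pvalues)), function(s)
    has_triangle(pvalues[s, ], cutoff, spec$n_genes, ii, jj), logical(1L)))
}

#' Calibrate the per-test cutoff for a target family-wise level
#'
#' Finds, by bisection over a grid of resolution `grid_resolution`, the
#' largest cutoff whose spurious-clique probability does not exceed
#' `spec$target_fwer`. All cutoffs are evaluated on the same simulated
#' p-values (common random numbers), which makes the search monotone and
#' the result deterministic for a fixed seed.
#'
#' @param spec A [calibration_spec()].
#' @param grid_resolution Cutoff grid step; default 0.001.
#' @return A list of class `calibration_result`: `cutoff`, `achieved_fwer`,
#'   `mc_se` (binomial Monte-Carlo standard error), `ok` (`FALSE` when even
#'   the smallest grid cutoff exceeds the target), `n_sim`, `seed` and the
#'   echoed `spec`.
#' @export
calibrate_cutoff <- function(spec, grid_resolution = 0.001) {
  stopifnot(inherits(spec, "calibration_spec"),
            grid_resolution > 0, grid_resolution <= 1)
  pv <- null_pair_pvalues(spec)
  K <- as.integer(round(1 / grid_resolution))
  prob_at <- function(k) spurious_clique_probability(spec, k * grid_resolution, pv)
  # largest k in 0..K with prob <= target (prob is non-decreasing in k)
  lo <- 0L; hi <- K
  if (prob_at(K) <= spec$target_fwer) {
    lo <- K
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (prob_at(mid) <= spec$target_fwer) lo <- mid else hi <- mid
    }
  }
  ok <- lo >= 1L
  cutoff <- max(lo, 1L) * grid_resolution
  achieved <- prob_at(max(lo, 1L))
  structure(list(cutoff = cutoff, achieved_fwer = achieved,
                 mc_se = sqrt(achieved * (1 - achieved) / spec$n_sim),
                 ok = ok, n_sim = spec$n_sim, seed = spec$seed, spec = spec),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Calibrated cutoff: p < %g (%d genes, groups %d/%d, delta = %g)\n",
    x$cutoff, x$spec$n_genes, x$spec$group_sizes[1L], x$spec$group_sizes[2L],
    x$spec$delta))
  cat(sprintf("  achieved spurious-clique probability %.4f (MC SE %.4f, %d sims)\n",
              x$achieved_fwer, x$mc_se, x$n_sim))
  if (!x$ok)
    cat("  warning: even the smallest grid cutoff exceeds the target level\n")
  invisible(x)
}
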