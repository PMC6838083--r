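# geNorm and NormFinder stability rankings, reimplemented for side-by-side
# comparison with the clique selection. Cq values are treated directly as
# log2-scale quantities (100% amplification efficiency), so the "expression
# log-ratio" of two genes is simply the difference of their Cq.

pairwise_sd_matrix <- function(values, strict) {
  genes <- colnames(values)
  G <- length(genes)
  S <- matrix(NA_real_, G, G, dimnames = list(genes, genes))
  for (a in seq_len(G - 1L)) for (b in (a + 1L):G) {
    d <- values[, a] - values[, b]
    d <- d[!is.na(d)]
    if (length(d) < 2L) {
      if (strict) stop_input_error(
        "fewer than 2 complete samples for pair (%s, %s)", genes[a], genes[b])
      next
    }
    S[a, b] <- S[b, a] <- stats::sd(d)
  }
  S
}

#' geNorm stability ranking
#'
#' A gene's M value is the mean, over all partner genes, of the
#' across-sample standard deviation of its pairwise Cq differences
#' (log2 expression ratios). The least stable gene (largest M) is removed
#' and M recomputed, iterating until two genes remain; those two cannot be
#' ordered further and are jointly ranked best. Lower M means more stable.
#'
#' @param matrix A [cq_matrix()]; group labels are not used.
#' @param strict If `TRUE`, refuse missing cells; otherwise pairwise
#'   standard deviations use complete pairs of samples.
#' @return A list of class `stability_ranking`: `method = "geNorm"`,
#'   `ranking` (data frame `gene`, `stability` — the gene's M at its removal
#'   step — and `rank`, with the final pair sharing rank 1) and
#'   `exclusion_trace` (data frame `step`, `gene`, `m_at_removal`).
#' @export
genorm_rank <- function(matrix, strict = FALSE) {
  stopifnot(inherits(matrix, "cq_matrix"))
  values <- matrix$cq
  if (strict && anyNA(values))
    stop_input_error("missing cells not allowed in strict mode")
  if (ncol(values) < 3L)
    stop_input_error("geNorm needs at least 3 genes, found %d", ncol(values))
  active <- colnames(values)
  removed <- character(0L)
  m_removed <- numeric(0L)
  while (length(active) > 2L) {
    S <- pairwise_sd_matrix(values[, active, drop = FALSE], strict)
    M <- rowMeans(S, na.rm = TRUE)
    worst_m <- max(M)
    ties <- names(M)[M == worst_m]
    worst <- sort(ties)[length(ties)]  # deterministic: last alphabetically
    removed <- c(removed, worst)
    m_removed <- c(m_removed, worst_m)
    active <- setdiff(active, worst)
  }
  final_m <- pairwise_sd_matrix(values[, active, drop = FALSE], strict)[1L, 2L]
  best <- sort(active)
  ranking <- data.frame(
    gene = c(best, rev(removed)),
    stability = c(final_m, final_m, rev(m_removed)),
    rank = c(1L, 1L, seq.int(3L, length.out = length(removed))),
    stringsAsFactors = FALSE)
  structure(list(method = "geNorm", ranking = ranking,
                 exclusion_trace = data.frame(
                   step = seq_along(removed), gene = removed,
                   m_at_removal = m_removed, stringsAsFactors = FALSE)),
            class = "stability_ranking")
}

#' NormFinder stability ranking (two-group model)
#'
#' Implements the model-based variance decomposition behind NormFinder for
#' a two-group design. Each sample is centered on its mean Cq across genes
#' (absorbing compositional loading); per gene and group the intra-group
#' variance is estimated with the correction `k/(k-2) * (v - vbar/(k-1))`
#' for the centering (k genes), and the inter-group bias is shrunk towards
#' zero by the ratio of its between-gene dispersion to its sampling
#' variance. The stability value averages, over groups, the absolute shrunk
#' bias plus its posterior standard deviation; lower is more stable.
#'
#' @param matrix A [cq_matrix()] with exactly two groups, each with at least
#'   3 samples, and at least 3 genes.
#' @param strict If `TRUE`, refuse missing cells; otherwise samples with any
#'   missing gene are dropped (casewise-complete).
#' @return A list of class `stability_ranking`: `method = "NormFinder"`,
#'   `ranking` (data frame `gene`, `stability`, `rank`, most stable first)
#'   and `details` (per gene and group: bias, shrunk bias, intra-group
#'   variance).
#' @export
normfinder_rank <- function(matrix, strict = FALSE) {
  stopifnot(inherits(matrix, "cq_matrix"))
  values <- matrix$cq
  groups <- matrix$groups
  if (anyNA(values)) {
    if (strict) stop_input_error("missing cells not allowed in strict mode")
    keep <- stats::complete.cases(values)
    values <- values[keep, , drop = FALSE]
    groups <- groups[keep]
  }
  glev <- unique(unname(groups))
  if (length(glev) != 2L)
    stop_input_error(paste(
      "NormFinder (grouped) needs exactly 2 groups, found %d;",
      "note that samples with missing cells are dropped first -",
      "consider excluding genes with failed triplicates"), length(glev))
  k <- ncol(values)
  if (k < 3L)
    stop_input_error("NormFinder needs at least 3 genes, found %d", k)
  ng <- vapply(glev, function(g) sum(groups == g), integer(1L))
  if (any(ng < 3L))
    stop_input_error("each group needs at least 3 samples for variance estimation")
  z <- values - rowMeans(values)  # remove per-sample loading
  zbar <- vapply(glev, function(g)
    colMeans(z[groups == g, , drop = FALSE]), numeric(k))
  v <- vapply(glev, function(g)
    apply(z[groups == g, , drop = FALSE], 2L, stats::var), numeric(k))
  sigma2 <- sapply(seq_along(glev), function(gi) {
    pmax((k / (k - 2)) * (v[, gi] - mean(v[, gi]) / (k - 1)), 0)
  })
  d <- zbar - rowMeans(zbar)  # inter-group bias per gene and group
  samp_var <- sweep(sigma2, 2L, ng, `/`)
  gamma2 <- max(0, sum(d^2) / ((k - 1) * (length(glev) - 1)) - mean(samp_var))
  shrink <- gamma2 / (gamma2 + samp_var)
  shrink[!is.finite(shrink)] <- 0
  d_shrunk <- d * shrink
  post_var <- samp_var * shrink
  stability <- rowMeans(abs(d_shrunk) + sqrt(post_var))
  ord <- order(stability, colnames(values))
  ranking <- data.frame(gene = colnames(values)[ord],
                        stability = unname(stability[ord]),
                        rank = seq_len(k), stringsAsFactors = FALSE)
  structure(list(method = "NormFinder", ranking = ranking,
                 details = list(groups = glev, bias = d,
                                shrunk_bias = d_shrunk,
                                intra_group_variance = sigma2,
                                gamma2 = gamma2)),
            class = "stability_ranking")
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat(sprintf("%s stability ranking (%d genes, lower = more stable)\n",
              x$method, nrow(x$ranking)))
  print(utils::head(x$ranking, 10L), row.names = FALSE)
  if (nrow(x$ranking) > 10L) cat("  ...\n")
  invisible(x)
}

#' Compare the clique selection with stability rankings
#'
#' For each ranking, reports the rank position of every clique-selected
#' gene and the overlap between the selection and the ranking's top-k,
#' where k is the selection size.
#'
#' @param selection A [select_reference_genes()] result.
#' @param rankings A list of [genorm_rank()] / [normfinder_rank()] results
#'   (a single ranking is accepted too).
#' @return A list of class `selection_comparison`: `k` and one entry per
#'   method with `positions` (data frame `gene`, `rank`; `NA` rank for a
#'   selected gene the ranking does not cover, e.g. one excluded for
#'   missing data), `overlap_top_k` and `n_covered`.
#' @export
compare_selections <- function(selection, rankings) {
  stopifnot(inherits(selection, "reference_selection"))
  if (inherits(rankings, "stability_ranking")) rankings <- list(rankings)
  k <- length(selection$selected)
  per_method <- lapply(rankings, function(r) {
    stopifnot(inherits(r, "stability_ranking"))
    rk <- r$ranking
    pos <- rk$rank[match(selection$selected, rk$gene)]
    top_k <- rk$gene[seq_len(min(k, nrow(rk)))]
    list(method = r$method,
         positions = data.frame(gene = selection$selected, rank = pos,
                                stringsAsFactors = FALSE),
         overlap_top_k = sum(selection$selected %in% top_k),
         n_covered = sum(!is.na(pos)))
  })
  names(per_method) <- vapply(per_method, `[[`, character(1L), "method")
  structure(list(k = k, methods = per_method),
            class = "selection_comparison")
}

#' @export
print.selection_comparison <- function(x, ...) {
  cat(sprintf("Selection of %d gene(s) vs rankings:\n", x$k))
  for (m in x$methods) {
    cat(sprintf("  %s: %d/%d in top-%d; ranks %s%s\n", m$method,
                m$overlap_top_k, x$k, x$k,
                paste(sort(m$positions$rank), collapse = ", "),
                if (m$n_covered < x$k)
                  sprintf(" (%d selected gene(s) not ranked)",
                          x$k - m$n_covered) else ""))
  }
  invisible(x)
}

#' Write a stability ranking as TSV
#'
#' @param ranking A `stability_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path) {
  df <- ranking$ranking
  df$method <- ranking$method
  utils::write.table(df[, c("gene", "stability", "rank", "method")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
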