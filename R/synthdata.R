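# Synthetic replicate-level Cq data with known ground truth.
#
# The generative model mirrors the assumed structure of real RT-qPCR data:
#   Cq(sample s, gene g, replicate r) =
#     baseline_g + group_effect_g * 1[s in group 2] + loading_s
#     + individual_{s,g} + analytical_{s,g,r}
# where loading_s is a compositional shift common to all genes of a sample
# (it cancels from every pairwise difference), individual noise is the
# biological inter-individual variation and analytical noise the technical
# replicate scatter. Sporadic outliers and failed/late reactions are
# injected explicitly on top.

#' Specify a synthetic Cq dataset
#'
#' @param n_genes Number of genes.
#' @param group_sizes Integer vector `c(n1, n2)`.
#' @param baseline_cq Per-gene baseline Cq in cycles; default evenly spread
#'   over \[14, 30\].
#' @param group_effects Per-gene group-2 expression shift in cycles.
#' @param planted_set Indices of genes sharing one common group effect (the
#'   true reference set); they must all carry exactly equal effects.
#' @param delta_design Margin (cycles) by which every non-planted effect
#'   must differ from each other and from the planted effect, so ground
#'   truth is unambiguous; default 0.5.
#' @param sample_loading_sd SD (cycles) of the per-sample compositional
#'   loading shift; default 0.5.
#' @param inter_individual_sd Per-gene (or scalar) SD (cycles) of the
#'   biological inter-individual noise; default 0.5.
#' @param analytical_sd SD (cycles) of per-replicate technical noise;
#'   default 0.1.
#' @param n_replicates Technical replicates per reaction; default 3.
#' @param outlier_rate Probability that a single replicate receives an
#'   additive outlier; default 0.
#' @param outlier_magnitude Cycles added to outlier replicates; default 5.
#' @param failure_rate Probability that a triplicate contains a failed
#'   replicate (undetected or detected after 32 cycles); default 0.
#' @param seed Integer RNG seed.
#' @param gene_names,sample_names Optional identifier vectors.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes, group_sizes,
                           baseline_cq = NULL, group_effects = NULL,
                           planted_set = integer(0L), delta_design = 0.5,
                           sample_loading_sd = 0.5, inter_individual_sd = 0.5,
                           analytical_sd = 0.1, n_replicates = 3L,
                           outlier_rate = 0, outlier_magnitude = 5,
                           failure_rate = 0, seed = 1L,
                           gene_names = NULL, sample_names = NULL) {
  n_genes <- as.integer(n_genes)
  group_sizes <- as.integer(group_sizes)
  stopifnot(n_genes >= 2L, length(group_sizes) == 2L, all(group_sizes >= 1L),
            n_replicates >= 1L, delta_design > 0,
            sample_loading_sd >= 0, analytical_sd >= 0,
            outlier_rate >= 0, outlier_rate <= 1,
            failure_rate >= 0, failure_rate <= 1)
  if (is.null(baseline_cq))
    baseline_cq <- seq(14, 30, length.out = n_genes)
  if (is.null(group_effects)) group_effects <- rep(0, n_genes)
  stopifnot(length(baseline_cq) == n_genes, length(group_effects) == n_genes)
  inter_individual_sd <- rep_len(inter_individual_sd, n_genes)
  stopifnot(all(inter_individual_sd >= 0))
  planted_set <- sort(unique(as.integer(planted_set)))
  if (length(planted_set)) {
    if (any(planted_set < 1L) || any(planted_set > n_genes))
      stop_input_error("planted_set indices out of range 1..%d", n_genes)
    if (length(unique(group_effects[planted_set])) != 1L)
      stop_input_error("planted genes must share exactly one group effect")
    others <- group_effects[-planted_set]
    ref <- group_effects[planted_set][1L]
    gaps <- abs(c(outer(others, others, `-`)[upper.tri(diag(length(others)))],
                  others - ref))
    if (length(gaps) && any(gaps <= delta_design))
      stop_input_error(
        "non-planted effects must differ pairwise and from the planted effect by more than delta_design = %g",
        delta_design)
  }
  if (is.null(gene_names)) gene_names <- sprintf("G%02d", seq_len(n_genes))
  n <- sum(group_sizes)
  if (is.null(sample_names)) sample_names <- sprintf("S%03d", seq_len(n))
  stopifnot(length(gene_names) == n_genes, length(sample_names) == n,
            !anyDuplicated(gene_names), !anyDuplicated(sample_names))
  structure(list(n_genes = n_genes, group_sizes = group_sizes,
                 baseline_cq = baseline_cq, group_effects = group_effects,
                 planted_set = planted_set, delta_design = delta_design,
                 sample_loading_sd = sample_loading_sd,
                 inter_individual_sd = inter_individual_sd,
                 analytical_sd = analytical_sd,
                 n_replicates = as.integer(n_replicates),
                 outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude,
                 failure_rate = failure_rate, seed = as.integer(seed),
                 gene_names = gene_names, sample_names = sample_names),
            class = "synthetic_spec")
}

#' Generate a synthetic replicate-level Cq dataset
#'
#' Draws all noise components under the spec's seed (bit-identical output
#' for a fixed seed) and returns both the long-format table and a truth
#' record holding every generated component.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_cq`: `table` (a [raw_cq_table()]) and
#'   `truth` (baselines, effects, planted set, per-sample loading,
#'   individual noise matrix, outlier and failure positions, group labels).
#' @export
generate_cq <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  G <- spec$n_genes
  n1 <- spec$group_sizes[1L]; n2 <- spec$group_sizes[2L]
  n <- n1 + n2
  R <- spec$n_replicates
  group <- rep(c("control", "case"), c(n1, n2))
  loading <- stats::rnorm(n, 0, spec$sample_loading_sd)
  indiv <- matrix(stats::rnorm(n * G), n, G,
                  dimnames = list(spec$sample_names, spec$gene_names))
  indiv <- sweep(indiv, 2L, spec$inter_individual_sd, `*`)
  # long table in sample-major, then gene, then replicate order
  s_idx <- rep(seq_len(n), each = G * R)
  g_idx <- rep(rep(seq_len(G), each = R), times = n)
  r_idx <- rep(seq_len(R), times = n * G)
  cq <- spec$baseline_cq[g_idx] +
    spec$group_effects[g_idx] * (group[s_idx] == "case") +
    loading[s_idx] + indiv[cbind(s_idx, g_idx)] +
    stats::rnorm(n * G * R, 0, spec$analytical_sd)
  is_outlier <- stats::runif(n * G * R) < spec$outlier_rate
  cq[is_outlier] <- cq[is_outlier] + spec$outlier_magnitude
  # failures: with probability failure_rate per triplicate, one random
  # replicate is either undetected or detected after 32 cycles
  trip_fail <- stats::runif(n * G) < spec$failure_rate
  fail_rep <- sample.int(R, n * G, replace = TRUE)
  fail_undetected <- stats::runif(n * G) < 0.5
  fail_late_cq <- stats::runif(n * G, 32.5, 39.5)
  trip_of <- (s_idx - 1L) * G + g_idx
  hit <- trip_fail[trip_of] & r_idx == fail_rep[trip_of]
  cq[hit & fail_undetected[trip_of]] <- NA_real_
  cq[hit & !fail_undetected[trip_of]] <- fail_late_cq[trip_of][hit & !fail_undetected[trip_of]]
  table <- raw_cq_table(spec$sample_names[s_idx], group[s_idx],
                        spec$gene_names[g_idx], r_idx, cq)
  truth <- list(
    baseline_cq = stats::setNames(spec$baseline_cq, spec$gene_names),
    group_effects = stats::setNames(spec$group_effects, spec$gene_names),
    planted_genes = spec$gene_names[spec$planted_set],
    delta_design = spec$delta_design,
    groups = stats::setNames(group, spec$sample_names),
    loading = stats::setNames(loading, spec$sample_names),
    individual_noise = indiv,
    outliers = data.frame(sample = spec$sample_names[s_idx[is_outlier]],
                          gene = spec$gene_names[g_idx[is_outlier]],
                          replicate = r_idx[is_outlier],
                          stringsAsFactors = FALSE),
    failures = data.frame(
      sample = spec$sample_names[s_idx[hit]],
      gene = spec$gene_names[g_idx[hit]],
      replicate = r_idx[hit],
      undetected = fail_undetected[trip_of][hit],
      stringsAsFactors = FALSE),
    seed = spec$seed)
  structure(list(table = table, truth = truth, spec = spec),
            class = "synthetic_cq")
}

#' Paper-like synthetic preset: 30 genes, groups of 14 and 26
#'
#' A stylised configuration emulating a 30-gene human reference panel run in
#' triplicate on 14 control and 26 case samples: analytical SD 0.1 cycles,
#' per-gene inter-individual SD spanning 0.25-2 cycles (stable genes at the
#' low end), loading SD 0.5, sporadic outliers (+5 cycles, affecting about
#' 1% of triplicates) and about 1% failed triplicates. Seven planted genes share a
#' zero group effect; the remaining effects are spaced more than 0.5 cycles
#' apart so the ground-truth reference set is unambiguous.
#'
#' @param seed Integer RNG seed stored in the spec.
#' @return A [synthetic_spec()].
#' @export
paper_like_preset <- function(seed = 1L) {
  G <- 30L
  planted <- 1:7
  effects <- numeric(G)
  k <- seq_len(G - 7L)
  effects[-planted] <- ceiling(k / 2) * 0.6 * (-1)^k
  sds <- numeric(G)
  sds[planted] <- seq(0.25, 0.4, length.out = 7L)
  sds[-planted] <- seq(0.45, 2, length.out = G - 7L)
  synthetic_spec(n_genes = G, group_sizes = c(14L, 26L),
                 baseline_cq = seq(14, 30, length.out = G),
                 group_effects = effects, planted_set = planted,
                 delta_design = 0.5, sample_loading_sd = 0.5,
                 inter_individual_sd = sds, analytical_sd = 0.1,
                 n_replicates = 3L, outlier_rate = 0.003,
                 outlier_magnitude = 5, failure_rate = 0.01, seed = seed)
}

#' Write a synthetic truth record as JSON
#'
#' @param synth A [generate_cq()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(synth, path) {
  stopifnot(inherits(synth, "synthetic_cq"))
  tr <- synth$truth
  tr$individual_noise <- NULL  # bulky; recoverable from seed + spec
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
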