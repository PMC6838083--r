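# Shared fixtures and independent oracles built in code.

# Write a long-dialect CSV from vectors; returns the path.
write_long_csv <- function(sample, group, gene, replicate, cq,
                           path = tempfile(fileext = ".csv")) {
  df <- data.frame(sample = sample, group = group, gene = gene,
                   replicate = replicate, cq = cq, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  path
}

# Long table for a single triplicate per (sample, gene) combination.
triplicate_table <- function(values_by_key) {
  # values_by_key: named list "sample|gene" -> replicate values (NA = undetected)
  rows <- do.call(rbind, lapply(names(values_by_key), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    v <- values_by_key[[k]]
    data.frame(sample = parts[1L], group = parts[3L] %||na% "A",
               gene = parts[2L], replicate = seq_along(v), cq = v,
               stringsAsFactors = FALSE)
  }))
  raw_cq_table(rows$sample, rows$group, rows$gene, rows$replicate, rows$cq)
}

`%||na%` <- function(a, b) if (is.na(a)) b else a

# Build a cq_matrix directly from a samples x genes matrix plus group sizes.
make_matrix <- function(values, n1, n2, groups = c("ctl", "pat")) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("G%02d", seq_len(ncol(values)))
  cq_matrix(values, stats::setNames(rep(groups, c(n1, n2)), rownames(values)))
}

# Two-group matrix holding one gene pair with prescribed per-sample
# differences: gene A carries the d values, gene B is flat at 20.
pair_matrix <- function(d1, d2) {
  d <- c(d1, d2)
  make_matrix(cbind(A = 20 + d, B = rep(20, length(d))),
              length(d1), length(d2))
}

# Fake all_pairs() table with prescribed p-values (lower-triangle order of
# combn) for graph-construction tests.
make_pairs_table <- function(genes, p_values, delta = 0.5) {
  cmb <- utils::combn(genes, 2L)
  stopifnot(length(p_values) == ncol(cmb))
  out <- data.frame(gene_a = cmb[1L, ], gene_b = cmb[2L, ],
                    estimate = 0, se = 0.1, df = 38L, ci_low = -0.2,
                    ci_high = 0.2, p_tost = p_values, n1 = 14L, n2 = 26L,
                    testable = !is.na(p_values), stringsAsFactors = FALSE)
  attr(out, "delta") <- delta
  attr(out, "alpha") <- 0.05
  attr(out, "genes") <- genes
  attr(out, "group_levels") <- c("ctl", "pat")
  class(out) <- c("equivalence_pairs", "data.frame")
  out
}

# Random graph as a pairs table with edge probability p_edge.
random_pairs_table <- function(n_nodes, p_edge) {
  genes <- sprintf("N%02d", seq_len(n_nodes))
  n_pairs <- choose(n_nodes, 2L)
  p <- ifelse(stats::runif(n_pairs) < p_edge, 0.01, 0.99)
  make_pairs_table(genes, p)
}

# Exhaustive maximal-clique oracle over all 2^n subsets, using bitmasks.
# Returns cliques as a sorted list of sorted character vectors.
brute_force_cliques <- function(graph) {
  genes <- graph$nodes
  n <- length(genes)
  stopifnot(n <= 16L)
  adj <- matrix(FALSE, n, n)
  if (nrow(graph$edges)) {
    i <- match(graph$edges$gene_a, genes)
    j <- match(graph$edges$gene_b, genes)
    adj[cbind(i, j)] <- adj[cbind(j, i)] <- TRUE
  }
  nb_self <- vapply(seq_len(n), function(v)
    sum(bitwShiftL(1L, which(adj[v, ]) - 1L)) + bitwShiftL(1L, v - 1L),
    integer(1L))
  masks <- seq_len(bitwShiftL(1L, n) - 1L)
  in_mask <- vapply(seq_len(n), function(v)
    bitwAnd(masks, bitwShiftL(1L, v - 1L)) > 0L, logical(length(masks)))
  covers <- vapply(seq_len(n), function(v)
    bitwAnd(masks, nb_self[v]) == masks, logical(length(masks)))
  is_clique <- rowSums(in_mask & !covers) == 0L
  maximal <- is_clique
  for (v in seq_len(n)) {
    grown <- bitwOr(masks, bitwShiftL(1L, v - 1L))
    maximal <- maximal & (in_mask[, v] | !is_clique[grown])
  }
  cl <- lapply(masks[maximal], function(m)
    sort(genes[bitwAnd(bitwShiftL(1L, seq_len(n) - 1L), m) > 0L]))
  cl[order(vapply(cl, paste, character(1L), collapse = "\r"))]
}

sort_cliques <- function(cl) {
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, paste, character(1L), collapse = "\r"))]
}

# Literal straight-loop transcription of the grouped NormFinder estimator,
# kept deliberately naive as an independent oracle.
naive_normfinder <- function(values, groups) {
  glev <- unique(groups)
  k <- ncol(values)
  z <- values
  for (s in seq_len(nrow(values))) z[s, ] <- values[s, ] - mean(values[s, ])
  zbar <- matrix(0, k, 2)
  v <- matrix(0, k, 2)
  ng <- numeric(2)
  for (gi in 1:2) {
    rows <- which(groups == glev[gi])
    ng[gi] <- length(rows)
    for (j in seq_len(k)) {
      zbar[j, gi] <- mean(z[rows, j])
      v[j, gi] <- stats::var(z[rows, j])
    }
  }
  sigma2 <- matrix(0, k, 2)
  for (gi in 1:2) {
    vbar <- mean(v[, gi])
    for (j in seq_len(k))
      sigma2[j, gi] <- max((k / (k - 2)) * (v[j, gi] - vbar / (k - 1)), 0)
  }
  d <- matrix(0, k, 2)
  for (j in seq_len(k)) for (gi in 1:2)
    d[j, gi] <- zbar[j, gi] - mean(zbar[j, ])
  samp_var <- sigma2
  for (gi in 1:2) samp_var[, gi] <- sigma2[, gi] / ng[gi]
  gamma2 <- max(0, sum(d^2) / (k - 1) - mean(samp_var))
  stab <- numeric(k)
  for (j in seq_len(k)) {
    acc <- 0
    for (gi in 1:2) {
      sh <- gamma2 / (gamma2 + samp_var[j, gi])
      if (!is.finite(sh)) sh <- 0
      acc <- acc + abs(d[j, gi] * sh) + sqrt(samp_var[j, gi] * sh)
    }
    stab[j] <- acc / 2
  }
  stats::setNames(stab, colnames(values))
}

# Direct-arithmetic geNorm M values for the full gene set.
naive_genorm_m <- function(values) {
  genes <- colnames(values)
  M <- stats::setNames(numeric(length(genes)), genes)
  for (j in genes) {
    sds <- c()
    for (kk in setdiff(genes, j))
      sds <- c(sds, stats::sd(values[, j] - values[, kk]))
    M[j] <- mean(sds)
  }
  M
}

# Synthetic spec for the planted 6-of-15 recovery scenario: six stable genes
# (zero group effect, inter-individual SD at the low end of the observed
# range) among nine unstable genes whose effects are spaced 1.0 cycles
# apart, with technical noise, outliers and failures at realistic rates.
recovery_spec <- function(seed) {
  effects <- numeric(15L)
  k <- 1:9
  effects[7:15] <- ceiling(k / 2) * (-1)^k   # -1, 1, -2, 2, ... cycles
  sds <- c(rep(0.25, 6L), seq(0.5, 2, length.out = 9L))
  synthetic_spec(n_genes = 15L, group_sizes = c(14L, 26L),
                 baseline_cq = seq(14, 28, length.out = 15L),
                 group_effects = effects, planted_set = 1:6,
                 delta_design = 0.5, sample_loading_sd = 0.5,
                 inter_individual_sd = sds, analytical_sd = 0.1,
                 n_replicates = 3L, outlier_rate = 0.003,
                 outlier_magnitude = 5, failure_rate = 0.005, seed = seed)
}

# One full selection run on a recovery dataset at a fixed cutoff.
run_selection <- function(spec, delta = 0.5, cutoff = 0.3) {
  synth <- generate_cq(spec)
  m <- average_triplicates(synth$table)
  sel <- select_reference_genes(build_graph(all_pairs(m, delta), cutoff))
  list(selected = sel$selected, planted = synth$truth$planted_genes,
       selection = sel)
}
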