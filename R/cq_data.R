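# Reading, quality control and summarisation of raw Cq tables.

#' Markers accepted as "undetected" amplification
#'
#' Cell contents (after trimming whitespace, case-insensitive) that are read
#' as an undetected reaction rather than a numeric Cq: the empty string,
#' `"NA"`, `"Undetermined"` and `"ND"`.
#'
#' @format Character vector of lower-case markers.
#' @export
UNDETECTED_MARKERS <- c("", "na", "undetermined", "nd")

stop_input_error <- function(msg, ...) {
  stop(structure(
    class = c("cliqueref_input_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

is_undetected_marker <- function(x) {
  tolower(trimws(x)) %in% UNDETECTED_MARKERS
}

#' Construct a replicate-level Cq table
#'
#' A `raw_cq_table` holds one record per (sample, gene, replicate) with the
#' sample's group label and the measured Cq in cycles; `NA` Cq means the
#' reaction did not reach the detection threshold ("undetected").
#'
#' @param sample Character vector of sample identifiers.
#' @param group Character vector of group labels, one per record; each sample
#'   must carry a single group label throughout.
#' @param gene Character vector of gene names.
#' @param replicate Integer replicate indices (>= 1).
#' @param cq Numeric Cq values in cycles (> 0), `NA` for undetected.
#' @return A data frame of class `raw_cq_table` with columns `sample`,
#'   `group`, `gene`, `replicate`, `cq` and attributes `sample_levels`,
#'   `gene_levels`, `group_levels` recording first-seen order.
#' @export
raw_cq_table <- function(sample, group, gene, replicate, cq) {
  sample <- as.character(sample)
  group <- as.character(group)
  gene <- as.character(gene)
  replicate <- as.integer(replicate)
  cq <- as.numeric(cq)
  lens <- lengths(list(sample, group, gene, replicate, cq))
  n <- max(lens)
  if (any(lens != n & lens != 1L))
    stop_input_error("all record fields must have length %d or 1", n)
  sample <- rep_len(sample, n); group <- rep_len(group, n)
  gene <- rep_len(gene, n); replicate <- rep_len(replicate, n)
  cq <- rep_len(cq, n)
  if (any(is.na(replicate)) || any(replicate < 1L))
    stop_input_error("replicate indices must be integers >= 1")
  if (any(!is.na(cq) & cq <= 0))
    stop_input_error("Cq values must be positive cycles (or undetected)")
  key <- paste(sample, gene, replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop_input_error("duplicate record for (sample, gene, replicate) = (%s)",
                     gsub("\r", ", ", dup, fixed = TRUE))
  }
  g_per_sample <- tapply(group, sample, function(g) length(unique(g)))
  if (any(g_per_sample > 1L))
    stop_input_error("sample '%s' is assigned to more than one group",
                     names(g_per_sample)[g_per_sample > 1L][1L])
  out <- data.frame(sample = sample, group = group, gene = gene,
                    replicate = replicate, cq = cq,
                    stringsAsFactors = FALSE)
  attr(out, "sample_levels") <- unique(sample)
  attr(out, "gene_levels") <- unique(gene)
  attr(out, "group_levels") <- unique(group)
  class(out) <- c("raw_cq_table", "data.frame")
  out
}

#' Construct a samples-by-genes matrix of averaged Cq
#'
#' @param values Numeric matrix, samples in rows, genes in columns, with
#'   `dimnames`; `NA` marks missing cells (failed or absent triplicates).
#' @param groups Named character vector of group labels, one per sample row.
#' @param qc Optional triplicate QC data frame (see [average_triplicates()]).
#' @return An object of class `cq_matrix`: a list with elements `cq`,
#'   `groups` and `qc`.
#' @export
cq_matrix <- function(values, groups, qc = NULL) {
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)))
    stop_input_error("`values` must be a matrix with sample and gene dimnames")
  groups <- groups[rownames(values)]
  if (any(is.na(groups)))
    stop_input_error("every sample row needs a group label")
  if (any(!is.na(values) & (!is.finite(values) | values <= 0)))
    stop_input_error("present Cq values must be finite and > 0")
  structure(list(cq = values, groups = stats::setNames(as.character(groups),
                                                       rownames(values)),
                 qc = qc),
            class = "cq_matrix")
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat(sprintf("Cq matrix: %d samples x %d genes, groups: %s\n",
              nrow(x$cq), ncol(x$cq),
              paste(sprintf("%s (n=%d)", names(table(x$groups)),
                            as.integer(table(x$groups))), collapse = ", ")))
  cat(sprintf("missing cells: %d", sum(is.na(x$cq))), "\n")
  invisible(x)
}

infer_sep <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a Cq table from CSV/TSV
#'
#' Two dialects are supported. `"long"` expects columns `sample`, `group`,
#' `gene`, `replicate`, `cq` (one row per technical replicate) and returns a
#' [raw_cq_table()]. `"wide"` expects one row per sample with columns
#' `sample`, `group` and one column per gene holding pre-averaged Cq, and
#' returns a [cq_matrix()]. Undetected reactions may be written as an empty
#' cell, `NA`, `Undetermined` or `ND` (case-insensitive); sample and gene
#' ordering is preserved as first seen.
#'
#' @param path Path to the file; the separator is inferred from the
#'   extension (`.tsv`/`.txt` tab, otherwise comma) unless `sep` is given.
#' @param dialect `"long"` or `"wide"`.
#' @param sep Optional field separator override.
#' @return A `raw_cq_table` (long) or `cq_matrix` (wide).
#' @export
read_cq_table <- function(path, dialect = c("long", "wide"), sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input_error("file not found: %s", path)
  if (is.null(sep)) sep <- infer_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = NULL,
                           quote = "\"", comment.char = "", fill = FALSE)
  if (dialect == "long") parse_long_cq(raw) else parse_wide_cq(raw)
}

parse_cq_values <- function(x, where) {
  cq <- rep(NA_real_, length(x))
  detected <- !is_undetected_marker(x)
  cq[detected] <- suppressWarnings(as.numeric(x[detected]))
  bad <- detected & is.na(cq)
  if (any(bad))
    stop_input_error(
      "non-numeric Cq '%s' (%s) is not a recognised undetected marker",
      x[bad][1L], where[bad][1L])
  cq
}

parse_long_cq <- function(raw) {
  wanted <- c("sample", "group", "gene", "replicate", "cq")
  names(raw) <- tolower(names(raw))
  if (!setequal(names(raw), wanted) || length(names(raw)) != length(wanted))
    stop_input_error(
      "long dialect requires exactly the columns %s; found %s",
      paste(wanted, collapse = ", "), paste(names(raw), collapse = ", "))
  rep_idx <- suppressWarnings(as.integer(raw$replicate))
  if (any(is.na(rep_idx)))
    stop_input_error("non-integer replicate index '%s'",
                     raw$replicate[is.na(rep_idx)][1L])
  cq <- parse_cq_values(raw$cq, paste0("sample ", raw$sample, ", gene ",
                                       raw$gene, ", replicate ", raw$replicate))
  raw_cq_table(raw$sample, raw$group, raw$gene, rep_idx, cq)
}

parse_wide_cq <- function(raw) {
  names(raw)[tolower(names(raw)) %in% c("sample", "group")] <-
    tolower(names(raw)[tolower(names(raw)) %in% c("sample", "group")])
  if (!all(c("sample", "group") %in% names(raw)))
    stop_input_error("wide dialect requires 'sample' and 'group' columns")
  genes <- names(raw)[!names(raw) %in% c("sample", "group")]
  if (length(genes) == 0L) stop_input_error("wide table has no gene columns")
  if (anyDuplicated(genes))
    stop_input_error("duplicated gene column '%s'", genes[duplicated(genes)][1L])
  if (anyDuplicated(raw$sample))
    stop_input_error("duplicated sample row '%s'",
                     raw$sample[duplicated(raw$sample)][1L])
  vals <- sapply(genes, function(g)
    parse_cq_values(raw[[g]], paste0("sample ", raw$sample, ", gene ", g)))
  vals <- matrix(as.numeric(vals), nrow = nrow(raw),
                 dimnames = list(raw$sample, genes))
  cq_matrix(vals, stats::setNames(raw$group, raw$sample))
}

triplicate_groups <- function(table) {
  split(seq_len(nrow(table)), paste(table$sample, table$gene, sep = "\r"))
}

#' Flag failed triplicates
#'
#' A triplicate (all replicates of one sample x gene) is labelled failed when
#' at least one replicate is undetected or detected after `max_cq` cycles.
#' Failed triplicates never contribute an averaged Cq.
#'
#' @param table A [raw_cq_table()].
#' @param max_cq Detection limit in cycles; default 32.
#' @return Data frame with one row per triplicate: `sample`, `gene`,
#'   `failed`, `n_replicates`.
#' @export
flag_failures <- function(table, max_cq = 32) {
  stopifnot(inherits(table, "raw_cq_table"))
  idx <- triplicate_groups(table)
  keys <- do.call(rbind, strsplit(names(idx), "\r", fixed = TRUE))
  failed <- vapply(idx, function(i) {
    v <- table$cq[i]
    any(is.na(v)) || any(v > max_cq)
  }, logical(1L))
  out <- data.frame(sample = keys[, 1L], gene = keys[, 2L],
                    failed = unname(failed),
                    n_replicates = lengths(idx), stringsAsFactors = FALSE)
  out[order(match(out$sample, attr(table, "sample_levels")),
            match(out$gene, attr(table, "gene_levels"))), , drop = FALSE]
}

#' Average technical replicates with single-outlier elimination
#'
#' For every non-failed triplicate, when the replicate standard deviation
#' (n-1 denominator) exceeds `sd_threshold`, the single value with the
#' greatest absolute deviation from the triplicate mean is eliminated (ties
#' broken towards the larger replicate index) before averaging. The rule is
#' applied once, never iterated. Failed triplicates yield missing cells.
#'
#' @param table A [raw_cq_table()].
#' @param sd_threshold Cycle threshold above which one outlier is dropped;
#'   default 0.5.
#' @param max_cq Detection limit used to flag failures first; default 32.
#' @return A [cq_matrix()] whose `qc` element has one row per triplicate:
#'   `sample`, `gene`, `failed`, `dropped_replicate` (NA when nothing was
#'   dropped), `raw_sd` (SD of the full triplicate, NA when any replicate is
#'   undetected), `n_used` (replicates averaged, 0 for failed).
#' @export
average_triplicates <- function(table, sd_threshold = 0.5, max_cq = 32) {
  stopifnot(inherits(table, "raw_cq_table"))
  flags <- flag_failures(table, max_cq = max_cq)
  key <- function(s, g) paste(s, g, sep = "\r")
  failed <- stats::setNames(flags$failed, key(flags$sample, flags$gene))
  idx <- triplicate_groups(table)
  idx <- idx[key(flags$sample, flags$gene)]  # align with flag order
  samples <- attr(table, "sample_levels")
  genes <- attr(table, "gene_levels")
  vals <- matrix(NA_real_, length(samples), length(genes),
                 dimnames = list(samples, genes))
  n_trip <- nrow(flags)
  dropped <- rep(NA_integer_, n_trip)
  raw_sd <- rep(NA_real_, n_trip)
  n_used <- integer(n_trip)
  for (t in seq_len(n_trip)) {
    i <- idx[[t]]
    v <- table$cq[i]
    r <- table$replicate[i]
    if (!anyNA(v) && length(v) >= 2L) raw_sd[t] <- stats::sd(v)
    if (flags$failed[t]) next
    if (length(v) >= 2L && raw_sd[t] > sd_threshold) {
      dev <- abs(v - mean(v))
      worst <- which(dev == max(dev))
      worst <- worst[which.max(r[worst])]  # tie: larger replicate index
      dropped[t] <- r[worst]
      v <- v[-worst]
    }
    if (length(v) < 1L) next
    vals[flags$sample[t], flags$gene[t]] <- mean(v)
    n_used[t] <- length(v)
  }
  qc <- flags
  qc$dropped_replicate <- dropped
  qc$raw_sd <- raw_sd
  qc$n_used <- n_used
  group_of <- tapply(table$group, table$sample, `[`, 1L)
  cq_matrix(vals, stats::setNames(as.character(group_of[samples]), samples),
            qc = qc)
}

#' Intra-assay and inter-individual variability summaries
#'
#' Intra-assay variability is the per (sample, gene) standard deviation of
#' the raw technical replicates, computed only for non-failed triplicates
#' with at least two replicates. Inter-individual variability is the per
#' (gene, group) standard deviation of the averaged Cq. Both use the n-1
#' denominator; groups with fewer than two usable samples report `NA`.
#'
#' @param table A [raw_cq_table()].
#' @param matrix The matching [cq_matrix()] from [average_triplicates()].
#' @return A list of class `variability_summary` with data frames
#'   `intra_assay` (`sample`, `gene`, `sd`, `n`) and `inter_individual`
#'   (`gene`, `group`, `sd`, `n`).
#' @export
variability_summary <- function(table, matrix) {
  stopifnot(inherits(table, "raw_cq_table"), inherits(matrix, "cq_matrix"))
  qc <- matrix$qc
  ok <- !qc$failed & qc$n_replicates >= 2L
  idx <- triplicate_groups(table)
  k_ok <- paste(qc$sample[ok], qc$gene[ok], sep = "\r")
  intra <- data.frame(sample = qc$sample[ok], gene = qc$gene[ok],
                      sd = vapply(idx[k_ok],
                                  function(i) stats::sd(table$cq[i]),
                                  numeric(1L)),
                      n = lengths(idx[k_ok]), stringsAsFactors = FALSE,
                      row.names = NULL)
  groups <- unique(matrix$groups)
  genes <- colnames(matrix$cq)
  inter <- expand.grid(gene = genes, group = groups,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats_ <- mapply(function(g, gr) {
    v <- matrix$cq[matrix$groups == gr, g]
    v <- v[!is.na(v)]
    c(if (length(v) >= 2L) stats::sd(v) else NA_real_, length(v))
  }, inter$gene, inter$group)
  inter$sd <- stats_[1L, ]
  inter$n <- as.integer(stats_[2L, ])
  structure(list(intra_assay = intra, inter_individual = inter),
            class = "variability_summary")
}

#' Write an averaged Cq matrix as wide CSV
#'
#' @param matrix A [cq_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cq_matrix <- function(matrix, path) {
  df <- data.frame(sample = rownames(matrix$cq),
                   group = unname(matrix$groups),
                   matrix$cq, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write the triplicate QC report as TSV
#'
#' @param matrix A [cq_matrix()] carrying QC records, or the QC data frame
#'   itself.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(matrix, path) {
  qc <- if (inherits(matrix, "cq_matrix")) matrix$qc else matrix
  if (is.null(qc)) stop_input_error("no QC records to write")
  cols <- c("sample", "gene", "failed", "dropped_replicate", "raw_sd", "n_used")
  utils::write.table(qc[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a replicate-level Cq table as long CSV
#'
#' @param table A [raw_cq_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(table, path) {
  df <- as.data.frame(table)
  df$cq <- ifelse(is.na(df$cq), "Undetermined", sprintf("%.12g", df$cq))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
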