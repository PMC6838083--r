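# Equivalence graph, maximal-clique enumeration and reference set selection.

#' Build the equivalence graph from pairwise test results
#'
#' Nodes are the candidate genes; an edge joins two genes if and only if
#' their equivalence test was testable and significant with
#' `p_tost < cutoff` (strict inequality).
#'
#' @param pairs An [all_pairs()] table.
#' @param cutoff Per-test rejection threshold in (0, 1].
#' @return A list of class `equivalence_graph`: `nodes`, `edges` (data frame
#'   `gene_a`, `gene_b`, `p_tost`), `delta`, `cutoff`, `group_levels`.
#' @export
build_graph <- function(pairs, cutoff) {
  stopifnot(inherits(pairs, "equivalence_pairs"),
            is.numeric(cutoff), cutoff > 0, cutoff <= 1)
  keep <- pairs$testable & !is.na(pairs$p_tost) & pairs$p_tost < cutoff
  edges <- as.data.frame(pairs)[keep, c("gene_a", "gene_b", "p_tost")]
  rownames(edges) <- NULL
  structure(list(nodes = attr(pairs, "genes"), edges = edges,
                 delta = attr(pairs, "delta"), cutoff = cutoff,
                 group_levels = attr(pairs, "group_levels")),
            class = "equivalence_graph")
}

#' @export
print.equivalence_graph <- function(x, ...) {
  cat(sprintf("Equivalence graph: %d genes, %d edges (delta = %g, p < %g)\n",
              length(x$nodes), nrow(x$edges), x$delta, x$cutoff))
  invisible(x)
}

adjacency_matrix <- function(graph) {
  g <- graph$nodes
  A <- matrix(FALSE, length(g), length(g), dimnames = list(g, g))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$gene_a, g)
    j <- match(graph$edges$gene_b, g)
    A[cbind(i, j)] <- TRUE
    A[cbind(j, i)] <- TRUE
  }
  A
}

# Bron-Kerbosch with pivoting on integer node sets.
bron_kerbosch <- function(adj) {
  n <- nrow(adj)
  out <- vector("list", 0L)
  nb <- lapply(seq_len(n), function(v) which(adj[v, ]))
  recurse <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- R
      return(invisible())
    }
    pool <- c(P, X)
    pivot <- pool[which.max(vapply(pool, function(u)
      length(intersect(P, nb[[u]])), integer(1L)))]
    for (v in setdiff(P, nb[[pivot]])) {
      recurse(c(R, v), intersect(P, nb[[v]]), intersect(X, nb[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  recurse(integer(0L), seq_len(n), integer(0L))
  out
}

#' Enumerate all maximal cliques of the equivalence graph
#'
#' Uses a pivoting Bron-Kerbosch recursion. Isolated nodes are returned as
#' singleton cliques. Genes within each clique are sorted alphabetically;
#' cliques are ordered by decreasing size, then alphabetically.
#'
#' @param graph An [build_graph()] result.
#' @return List of character vectors, one per inclusion-maximal clique.
#' @export
maximal_cliques <- function(graph) {
  stopifnot(inherits(graph, "equivalence_graph"))
  if (!length(graph$nodes)) return(list())
  adj <- adjacency_matrix(graph)
  cliques <- lapply(bron_kerbosch(adj), function(ix) sort(graph$nodes[ix]))
  key <- vapply(cliques, paste, character(1L), collapse = "\r")
  cliques[order(-lengths(cliques), key)]
}

#' Select the reference gene set from the equivalence graph
#'
#' The reference set is the intersection of all maximum-cardinality maximal
#' cliques. A single maximum clique is returned whole; with several, only
#' the genes common to all of them are selected. The selection is flagged
#' unreliable when the maximum clique is smaller than
#' `min_reliable_clique` (pairs and triangles arise too easily by chance at
#' permissive cutoffs), and ambiguous when the intersection is empty.
#'
#' @param graph An [build_graph()] result.
#' @param min_reliable_clique Smallest maximum-clique size considered
#'   reliable; default 4.
#' @return A list of class `reference_selection`: `maximal_cliques`,
#'   `maximum_size`, `maximum_cliques`, `selected`, `isolated` (degree-0
#'   genes), `ambiguous`, `reliable`, plus the graph's `delta` and `cutoff`.
#' @export
select_reference_genes <- function(graph, min_reliable_clique = 4L) {
  stopifnot(inherits(graph, "equivalence_graph"))
  cliques <- maximal_cliques(graph)
  maximum_size <- if (length(cliques)) max(lengths(cliques)) else 0L
  maxcl <- cliques[lengths(cliques) == maximum_size]
  selected <- if (length(maxcl)) sort(Reduce(intersect, maxcl)) else character(0L)
  deg <- table(factor(c(graph$edges$gene_a, graph$edges$gene_b),
                      levels = graph$nodes))
  structure(list(maximal_cliques = cliques,
                 maximum_size = maximum_size,
                 maximum_cliques = maxcl,
                 selected = selected,
                 isolated = graph$nodes[deg == 0L],
                 ambiguous = length(selected) == 0L && maximum_size > 0L,
                 reliable = maximum_size >= min_reliable_clique,
                 min_reliable_clique = as.integer(min_reliable_clique),
                 delta = graph$delta, cutoff = graph$cutoff),
            class = "reference_selection")
}

#' @export
print.reference_selection <- function(x, ...) {
  cat(sprintf("Reference selection (delta = %g, p < %g)\n", x$delta, x$cutoff))
  cat(sprintf("  %d maximal clique(s), maximum size %d (%d at maximum)\n",
              length(x$maximal_cliques), x$maximum_size,
              length(x$maximum_cliques)))
  if (x$ambiguous) {
    cat("  selection ambiguous: maximum cliques share no gene\n")
  } else {
    cat(sprintf("  selected (%d): %s\n", length(x$selected),
                paste(x$selected, collapse = ", ")))
  }
  if (!x$reliable)
    cat(sprintf("  warning: maximum clique < %d genes, selection unreliable\n",
                x$min_reliable_clique))
  if (length(x$isolated))
    cat(sprintf("  isolated genes: %s\n", paste(x$isolated, collapse = ", ")))
  invisible(x)
}

#' Profile the selection across equivalence half-widths
#'
#' Re-runs testing, graph building and selection for each delta of an
#' ascending grid, and annotates every gene with the smallest delta at
#' which it enters the selected set (its entry delta). The order of entry
#' is a partial stability ranking: genes entering at smaller delta are
#' proven stable under a stricter definition of "no change".
#'
#' @param matrix A [cq_matrix()] with two groups.
#' @param deltas Ascending vector of equivalence half-widths (cycles).
#' @param cutoff Either a single p cutoff, a vector matching `deltas`, or a
#'   function `function(delta)` returning the cutoff to use at that delta.
#' @param min_reliable_clique Passed to [select_reference_genes()].
#' @param alpha Passed to [all_pairs()].
#' @return A list of class `delta_profile`: `deltas`, `cutoffs`,
#'   `selections` (one [select_reference_genes()] result per delta) and
#'   `entry` (data frame `gene`, `entry_delta`, `NA` when never selected).
#' @export
delta_profile <- function(matrix, deltas, cutoff, min_reliable_clique = 4L,
                          alpha = 0.05) {
  stopifnot(inherits(matrix, "cq_matrix"), length(deltas) >= 1L,
            !is.unsorted(deltas), all(deltas > 0))
  cutoffs <- if (is.function(cutoff)) vapply(deltas, cutoff, numeric(1L))
             else rep_len(cutoff, length(deltas))
  selections <- lapply(seq_along(deltas), function(k) {
    pairs <- all_pairs(matrix, deltas[k], alpha = alpha)
    select_reference_genes(build_graph(pairs, cutoffs[k]),
                           min_reliable_clique = min_reliable_clique)
  })
  genes <- colnames(matrix$cq)
  entry <- vapply(genes, function(g) {
    hit <- which(vapply(selections, function(s) g %in% s$selected, logical(1L)))
    if (length(hit)) deltas[min(hit)] else NA_real_
  }, numeric(1L))
  structure(list(deltas = deltas, cutoffs = cutoffs, selections = selections,
                 entry = data.frame(gene = genes, entry_delta = unname(entry),
                                    stringsAsFactors = FALSE)),
            class = "delta_profile")
}

node_classes <- function(graph, selection) {
  cls <- stats::setNames(rep("other", length(graph$nodes)), graph$nodes)
  if (!is.null(selection)) {
    in_max <- unique(unlist(selection$maximum_cliques))
    cls[in_max] <- "member"
    cls[selection$selected] <- "core"
  }
  cls
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export the equivalence graph
#'
#' Writes the graph, optionally annotated with the selection's node classes
#' (`core`: in all maximum cliques; `member`: in at least one maximum-size
#' clique; `other`), as GraphML, Graphviz DOT or a TSV edge list. Edges
#' carry their TOST p-value.
#'
#' @param graph An [build_graph()] result.
#' @param selection Optional [select_reference_genes()] result.
#' @param format One of `"graphml"`, `"dot"`, `"edge_tsv"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, selection = NULL,
                         format = c("graphml", "dot", "edge_tsv"), path) {
  stopifnot(inherits(graph, "equivalence_graph"))
  format <- match.arg(format)
  cls <- node_classes(graph, selection)
  e <- graph$edges
  lines <- switch(format,
    graphml = c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "  <key id=\"d0\" for=\"node\" attr.name=\"class\" attr.type=\"string\"/>",
      "  <key id=\"d1\" for=\"edge\" attr.name=\"p_tost\" attr.type=\"double\"/>",
      "  <key id=\"d2\" for=\"node\" attr.name=\"name\" attr.type=\"string\"/>",
      "  <graph id=\"equivalence\" edgedefault=\"undirected\">",
      sprintf(paste0("    <node id=\"%s\"><data key=\"d0\">%s</data>",
                     "<data key=\"d2\">%s</data></node>"),
              xml_escape(graph$nodes), cls, xml_escape(graph$nodes)),
      if (nrow(e)) sprintf(
        "    <edge source=\"%s\" target=\"%s\"><data key=\"d1\">%.10g</data></edge>",
        xml_escape(e$gene_a), xml_escape(e$gene_b), e$p_tost),
      "  </graph>", "</graphml>"),
    dot = c(
      "graph equivalence {",
      sprintf("  \"%s\" [class=\"%s\"];", graph$nodes, cls),
      if (nrow(e)) sprintf("  \"%s\" -- \"%s\" [label=\"%.3g\"];",
                           e$gene_a, e$gene_b, e$p_tost),
      "}"),
    edge_tsv = c("gene_a\tgene_b\tp_tost",
                 if (nrow(e)) sprintf("%s\t%s\t%.10g",
                                      e$gene_a, e$gene_b, e$p_tost)))
  writeLines(lines, path)
  invisible(path)
}

#' Write the selection report as TSV
#'
#' One row per gene with its membership class, isolation flag and entry in
#' the selected set.
#'
#' @param selection A [select_reference_genes()] result.
#' @param graph The matching [build_graph()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(selection, graph, path) {
  cls <- node_classes(graph, selection)
  df <- data.frame(gene = graph$nodes,
                   selected = graph$nodes %in% selection$selected,
                   class = unname(cls),
                   isolated = graph$nodes %in% selection$isolated,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
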