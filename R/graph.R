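#' Build the peptide-peptide graph from protein membership
#'
#' Peptides are nodes; two peptides are connected if they share at least one
#' parent protein. Each protein therefore contributes a full clique over its
#' peptides, and proteins linked by shared (non-unique) peptides merge into a
#' single connected component. Self-edges are not stored (the attention layer
#' adds self-connections internally); peptides sharing several proteins get a
#' single undirected edge.
#'
#' @param ds a [peptide_dataset()].
#' @param max_edges_per_protein optional cap on the number of edges a single
#'   protein clique may contribute; if a protein's clique exceeds it, edges
#'   are subsampled uniformly at random (seeded). `Inf` (default) keeps the
#'   exact full-clique construction.
#' @param seed seed used only when subsampling capped cliques.
#' @return Object of class `peptide_graph` with `node_ids` (row order of the
#'   dataset), `edges` (m x 2 integer matrix, `i < j`, deduplicated) and `n`.
#' @export
build_peptide_graph <- function(ds, max_edges_per_protein = Inf, seed = 1L) {
  stopifnot(inherits(ds, "peptide_dataset"))
  n <- length(ds$peptide_ids)
  prot_of <- ds$protein_groups
  members <- split(rep(seq_len(n), lengths(prot_of)), unlist(prot_of))
  if (is.finite(max_edges_per_protein)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  edge_list <- lapply(members, function(idx) {
    k <- length(idx)
    if (k < 2L) return(NULL)
    pairs <- t(utils::combn(sort(idx), 2L))
    if (nrow(pairs) > max_edges_per_protein)
      pairs <- pairs[sample(nrow(pairs), max_edges_per_protein), , drop = FALSE]
    pairs
  })
  edges <- do.call(rbind, edge_list)
  if (is.null(edges)) {
    edges <- matrix(integer(), 0L, 2L)
  } else {
    key <- (edges[, 1L] - 1) * n + edges[, 2L]
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  colnames(edges) <- c("i", "j")
  structure(list(node_ids = ds$peptide_ids, edges = edges, n = n),
            class = "peptide_graph")
}

#' @export
print.peptide_graph <- function(x, ...) {
  cat(sprintf("peptide_graph: %d nodes, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' Neighbors of a node in a peptide graph
#' @param g a `peptide_graph`.
#' @param node node index (row number) or peptide id.
#' @return Integer vector of neighbor indices (no self).
#' @export
graph_neighbors <- function(g, node) {
  if (is.character(node)) node <- match(node, g$node_ids)
  sort(unique(c(g$edges[g$edges[, 1L] == node, 2L],
                g$edges[g$edges[, 2L] == node, 1L])))
}

#' Connected components of a peptide graph
#'
#' Proteins with shared peptides merge into a single component; singleton
#' proteins' peptides appear as singleton components (or small cliques).
#'
#' @param g a `peptide_graph`.
#' @return List of character vectors of peptide ids, one per component,
#'   ordered by decreasing size.
#' @export
connected_components <- function(g) {
  comp <- if (nrow(g$edges)) {
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    if (igraph::vcount(ig) < g$n)
      ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
    igraph::components(ig)$membership
  } else seq_len(g$n)
  parts <- split(g$node_ids, comp)
  parts[order(-lengths(parts))]
}

#' Summary statistics of a peptide graph
#'
#' @param g a `peptide_graph`.
#' @return list with `n_nodes`, `n_edges`, `component_sizes` (table of
#'   component-size counts) and `max_clique_contribution` (largest number of
#'   edges any single protein clique could contribute, from component data).
#' @export
graph_stats <- function(g) {
  comps <- connected_components(g)
  sizes <- lengths(comps)
  deg <- tabulate(as.vector(g$edges), nbins = g$n)
  list(n_nodes = g$n, n_edges = nrow(g$edges),
       component_sizes = table(sizes),
       n_components = length(comps),
       max_degree = if (g$n) max(deg) else 0L,
       n_isolated = sum(deg == 0L))
}

#' Export the edge list as a two-column TSV of peptide ids
#' @param g a `peptide_graph`.
#' @param path output path.
#' @export
write_edge_list <- function(g, path) {
  write.table(data.frame(from = g$node_ids[g$edges[, 1L]],
                         to = g$node_ids[g$edges[, 2L]]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
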