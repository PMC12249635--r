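#' Build the trait-specific node-weighted network
#'
#' Restricts a base interaction network to the genes that are both present
#' in the edge list and scored, and assigns node weights
#' w = -log10(max(p, p_floor)). Genes that lose all their edges in the
#' restriction are dropped (diffusion needs degree >= 1); counts of kept
#' nodes and edges are logged.
#'
#' @param edges data.frame of undirected edges (`from`, `to`).
#' @param scores Gene score data.frame (`gene_id`, `p_value`).
#' @param p_floor Floor applied to p before the log so p = 0 cannot produce
#'   an infinite weight.
#' @return A `weighted_network`: list with `genes`, `edges`, `weights`
#'   (named, -log10 p), and `graph` (igraph).
#' @export
build_weighted_network <- function(edges, scores, p_floor = 1e-300) {
  keep_genes <- intersect(union(edges$from, edges$to), scores$gene_id)
  if (length(keep_genes) == 0L) {
    stop("no genes shared between the edge list and the score table",
         call. = FALSE)
  }
  e <- edges[edges$from %in% keep_genes & edges$to %in% keep_genes, ,
             drop = FALSE]
  e <- e[e$from != e$to, , drop = FALSE]
  genes <- sort(intersect(keep_genes, union(e$from, e$to)))
  if (length(genes) == 0L) {
    stop("network restriction left no connected genes", call. = FALSE)
  }
  p <- stats::setNames(scores$p_value, scores$gene_id)[genes]
  w <- -log10(pmax(p, p_floor))
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = data.frame(name = genes))
  msg_log("build_weighted_network",
          "restricted to %d genes / %d edges (from %d scored genes, %d input edges)",
          length(genes), nrow(e), nrow(scores), nrow(edges))
  structure(list(genes = genes, edges = e, weights = w, graph = g),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network> %d genes, %d edges; weight range [%.3g, %.3g]\n",
              length(x$genes), nrow(x$edges), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Restrict a weighted network to its largest connected component
#'
#' Diffusion assumes a connected graph. If several components tie for the
#' maximum size, the component containing the lexicographically smallest
#' gene id is retained, making the restriction deterministic.
#'
#' @param network A `weighted_network`.
#' @return A `weighted_network` on the largest component.
#' @export
largest_connected_component <- function(network) {
  comp <- igraph::components(network$graph)
  if (comp$no == 1L) return(network)
  max_size <- max(comp$csize)
  cand <- which(comp$csize == max_size)
  first_gene <- vapply(cand, function(k) {
    min(network$genes[comp$membership == k])
  }, "")
  pick <- cand[order(first_gene)[1L]]
  keep <- network$genes[comp$membership == pick]
  msg_log("largest_connected_component",
          "%d components; keeping %d of %d genes", comp$no,
          length(keep), length(network$genes))
  e <- network$edges[network$edges$from %in% keep &
                       network$edges$to %in% keep, , drop = FALSE]
  structure(list(genes = sort(keep), edges = e,
                 weights = network$weights[sort(keep)],
                 graph = igraph::induced_subgraph(
                   network$graph, which(network$genes %in% keep))),
            class = "weighted_network")
}
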