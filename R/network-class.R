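#' Construct a ceRNA network object
#'
#' A `cerna_network` is a simple undirected graph with typed nodes
#' (miRNA / lncRNA / mRNA, or `"other"` for generic test graphs), typed edges,
#' optional per-edge provenance (the crosstalk triplets that contributed the
#' edge) and a condition label (`"global"` or e.g. `"stageIII"`).
#'
#' Edges are canonicalized with `from < to` lexicographically; self-loops and
#' duplicates are rejected. When both endpoints have molecular classes, the
#' edge type must pair them consistently (`miRNA-mRNA`, `miRNA-lncRNA`,
#' `lncRNA-mRNA`).
#'
#' @param nodes Tibble/data frame with columns `id`, `class`.
#' @param edges Tibble/data frame with columns `from`, `to` and optionally
#'   `edge_type` and `triplets` (list column of contributing triplet ids).
#' @param condition Condition label, default `"global"`.
#' @return A `cerna_network` object.
#' @export
cerna_network <- function(nodes, edges, condition = "global") {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "class") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop("duplicated node ids", call. = FALSE)
  if (!all(nodes$class %in% c("miRNA", "lncRNA", "mRNA", "other"))) {
    stop("node class must be miRNA/lncRNA/mRNA/other", call. = FALSE)
  }
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    if (any(edges$from == edges$to)) stop("self-loops are not allowed", call. = FALSE)
    bad <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(bad) > 0) {
      stop("edge endpoint(s) absent from node table: ",
           paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
    }
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    if (anyDuplicated(paste(edges$from, edges$to))) {
      stop("duplicate edges are not allowed", call. = FALSE)
    }
    cls <- stats::setNames(nodes$class, nodes$id)
    derived <- derive_edge_type(cls[edges$from], cls[edges$to])
    if (!"edge_type" %in% names(edges)) {
      edges$edge_type <- derived
    } else if (any(edges$edge_type != derived)) {
      stop("edge_type inconsistent with endpoint classes", call. = FALSE)
    }
  } else {
    edges <- tibble::tibble(from = character(), to = character(),
                            edge_type = character())
  }
  structure(list(nodes = nodes, edges = edges, condition = condition),
            class = "cerna_network")
}

derive_edge_type <- function(c1, c2) {
  purrr::map2_chr(c1, c2, function(a, b) {
    pair <- sort(c(a, b))
    if ("other" %in% pair) return("generic")
    if (identical(pair, c("mRNA", "miRNA"))) return("miRNA-mRNA")
    if (identical(pair, c("lncRNA", "miRNA"))) return("miRNA-lncRNA")
    if (identical(pair, c("lncRNA", "mRNA"))) return("lncRNA-mRNA")
    "generic"
  })
}

#' @export
print.cerna_network <- function(x, ...) {
  counts <- table(x$nodes$class)
  cat(sprintf("<cerna_network> condition=%s: %d nodes (%s), %d edges\n",
              x$condition, nrow(x$nodes),
              paste(sprintf("%s=%d", names(counts), counts), collapse = " "),
              nrow(x$edges)))
  invisible(x)
}

#' Convert a ceRNA network to an igraph graph
#' @param net A `cerna_network`.
#' @return An undirected `igraph` graph with `class` vertex attribute.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("from", "to")], directed = FALSE,
    vertices = net$nodes[, c("id", "class")]
  )
}

#' Node and edge counts of a ceRNA network
#' @param x A `cerna_network`.
#' @param ... Unused.
#' @return One-row tibble with `condition`, total and per-class node counts,
#'   and `n_edges`.
#' @method glance cerna_network
#' @export
glance.cerna_network <- function(x, ...) {
  tibble::tibble(
    condition = x$condition,
    n_nodes = nrow(x$nodes),
    n_mirna = sum(x$nodes$class == "miRNA"),
    n_lncrna = sum(x$nodes$class == "lncRNA"),
    n_mrna = sum(x$nodes$class == "mRNA"),
    n_edges = nrow(x$edges)
  )
}

#' Edge table of a ceRNA network
#' @param x A `cerna_network`.
#' @param ... Unused.
#' @return The edge tibble (`from`, `to`, `edge_type`, provenance if present).
#' @method tidy cerna_network
#' @export
tidy.cerna_network <- function(x, ...) x$edges

#' Write a ceRNA network as an edge list plus node-class sidecar
#' @param net A `cerna_network`.
#' @param edge_path,node_path Output TSV paths.
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(net, edge_path, node_path) {
  ed <- net$edges
  if ("triplets" %in% names(ed)) {
    ed$triplets <- vapply(ed$triplets, paste, character(1), collapse = ",")
  }
  utils::write.table(ed, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edge_path)
}
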