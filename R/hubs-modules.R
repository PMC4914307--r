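round_half_up <- function(x) floor(x + 0.5)

#' Identify per-class hub nodes
#'
#' Sorts all nodes by degree (computed on the full heterogeneous network) and
#' takes, within each molecular class, the top `fraction` by degree. The
#' target count per class is the nearest integer to `fraction * class_size`
#' with halves rounded up; ties at the cutoff degree are broken by
#' lexicographic node id.
#'
#' @param net A `cerna_network`.
#' @param fraction Top fraction per class (default 0.05).
#' @return A `hub_set`: list with `hubs` (tibble `class`, `id`, `degree`,
#'   `rank_in_class`), `fraction`, `rounding` (`"half_up"`) and `cutoffs`
#'   (named vector of cutoff degrees per class).
#' @export
identify_hubs <- function(net, fraction = 0.05) {
  stopifnot(inherits(net, "cerna_network"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)", call. = FALSE)
  cent <- node_centralities(net)
  hubs <- cent |>
    dplyr::group_by(.data$class) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$id, .by_group = TRUE) |>
    dplyr::mutate(rank_in_class = dplyr::row_number(),
                  n_take = round_half_up(fraction * dplyr::n())) |>
    dplyr::filter(.data$rank_in_class <= .data$n_take) |>
    dplyr::ungroup() |>
    dplyr::select("class", "id", "degree", "rank_in_class")
  cutoffs <- hubs |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(cutoff = min(.data$degree), .groups = "drop")
  structure(
    list(hubs = hubs, fraction = fraction, rounding = "half_up",
         cutoffs = stats::setNames(cutoffs$cutoff, cutoffs$class)),
    class = "hub_set"
  )
}

#' @export
print.hub_set <- function(x, ...) {
  counts <- table(x$hubs$class)
  cat(sprintf("<hub_set> top %.1f%% by degree: %s\n", 100 * x$fraction,
              paste(sprintf("%s=%d", names(counts), counts), collapse = " ")))
  invisible(x)
}

#' Hub table of a hub set
#' @param x A `hub_set`.
#' @param ... Unused.
#' @return Tibble with `class`, `id`, `degree`, `rank_in_class`.
#' @method tidy hub_set
#' @export
tidy.hub_set <- function(x, ...) x$hubs

#' Hub ids of one class
#' @param x A `hub_set`.
#' @param class Molecular class.
#' @return Character vector of hub ids (possibly empty).
#' @export
hub_ids <- function(x, class) {
  x$hubs$id[x$hubs$class == class]
}

# --- MCODE -----------------------------------------------------------------

# vertex weighting: weight(v) = k * density of the highest k-core of the
# closed neighborhood of v; nodes below the degree cutoff score 0
mcode_weights <- function(g, degree_cutoff = 2) {
  deg <- igraph::degree(g)
  vapply(seq_len(igraph::vcount(g)), function(v) {
    if (deg[v] < degree_cutoff) return(0)
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    k <- max(core)
    if (k == 0) return(0)
    kc <- igraph::induced_subgraph(sub, which(core >= k))
    dens <- igraph::edge_density(kc)
    if (is.nan(dens)) dens <- 0
    k * dens
  }, numeric(1))
}

#' Mine dense network modules with the MCODE algorithm
#'
#' Implements molecular complex detection: (1) each vertex is weighted by the
#' core number of the highest k-core of its closed neighborhood times the
#' density of that k-core; (2) complexes grow outward from the highest-weight
#' unused seed, including neighbors whose weight is at least
#' `(1 - node_score_cutoff)` times the seed weight, up to `max_depth` hops;
#' (3) complexes not containing a 2-core are discarded, and with
#' `haircut = TRUE` each complex is trimmed to its 2-core; `fluff` optionally
#' adds back neighbors whose closed-neighborhood density exceeds
#' `fluff_density`. Complexes are scored by density times size and ranked by
#' decreasing score (ties by decreasing size, then seed id).
#'
#' @param net A `cerna_network`.
#' @param degree_cutoff Minimum degree for a vertex to receive weight
#'   (default 2).
#' @param node_score_cutoff Inclusion tolerance relative to the seed weight
#'   (default 0.2).
#' @param max_depth Maximum distance from the seed (default 100).
#' @param haircut Trim each complex to its 2-core (default `TRUE`).
#' @param fluff Add high-density boundary neighbors (default `FALSE`).
#' @param fluff_density Density threshold for fluff (default 0.5).
#' @return Tibble with one row per module: `rank`, `seed`, `size`, `density`,
#'   `score`, `members` (list column).
#' @export
mcode_modules <- function(net, degree_cutoff = 2, node_score_cutoff = 0.2,
                          max_depth = 100, haircut = TRUE, fluff = FALSE,
                          fluff_density = 0.5) {
  stopifnot(inherits(net, "cerna_network"))
  if (nrow(net$edges) == 0) return(empty_modules())
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  w <- mcode_weights(g, degree_cutoff)
  ids <- igraph::V(g)$name
  order_idx <- order(-w, ids)
  used <- rep(FALSE, n)
  complexes <- list()
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  for (seed in order_idx) {
    if (used[seed] || w[seed] <= 0) next
    thresh <- (1 - node_score_cutoff) * w[seed]
    members <- seed
    used[seed] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < max_depth) {
      nxt <- unique(unlist(lapply(frontier, function(v) as.integer(adj[[v]]))))
      nxt <- nxt[!used[nxt] & w[nxt] >= thresh]
      if (length(nxt) == 0) break
      used[nxt] <- TRUE
      members <- c(members, nxt)
      frontier <- nxt
      depth <- depth + 1
    }
    complexes[[length(complexes) + 1]] <- list(seed = ids[seed], members = members)
  }
  out <- purrr::map_dfr(complexes, function(cx) {
    sub <- igraph::induced_subgraph(g, cx$members)
    core <- igraph::coreness(sub)
    if (max(core) < 2) return(NULL)  # no 2-core: discard
    if (haircut) {
      keep <- which(core >= 2)
      sub <- igraph::induced_subgraph(sub, keep)
    }
    if (fluff) {
      mem <- match(igraph::V(sub)$name, ids)
      boundary <- setdiff(unique(unlist(lapply(mem, function(v) as.integer(adj[[v]])))), mem)
      add <- boundary[vapply(boundary, function(v) {
        nb <- c(v, as.integer(adj[[v]]))
        d <- igraph::edge_density(igraph::induced_subgraph(g, nb))
        !is.nan(d) && d > fluff_density
      }, logical(1))]
      if (length(add) > 0) sub <- igraph::induced_subgraph(g, c(mem, add))
    }
    size <- igraph::vcount(sub)
    dens <- igraph::edge_density(sub)
    tibble::tibble(seed = cx$seed, size = size, density = dens,
                   score = dens * size,
                   members = list(sort(igraph::V(sub)$name)))
  })
  if (nrow(out) == 0) return(empty_modules())
  out <- dplyr::arrange(out, dplyr::desc(.data$score), dplyr::desc(.data$size),
                        .data$seed)
  out$rank <- seq_len(nrow(out))
  dplyr::select(out, "rank", "seed", "size", "density", "score", "members")
}

empty_modules <- function() {
  tibble::tibble(rank = integer(), seed = character(), size = integer(),
                 density = numeric(), score = numeric(), members = list())
}

# --- enrichment ------------------------------------------------------------

#' Hypergeometric enrichment of a gene set in a selection
#'
#' Upper-tail hypergeometric test: with universe size `N`, gene-set size `K`
#' (restricted to the universe), selection size `n` and overlap `k`, the
#' p-value is `P(X >= k)`; fold enrichment is `(k/n) / (K/N)`.
#'
#' @param selection Selected node ids (must all lie in `universe`).
#' @param set_members Gene-set member ids.
#' @param universe Background ids.
#' @param set_name Label for the output row.
#' @return One-row tibble: `set_name`, `k`, `K`, `n`, `N`, `p`, `fold`.
#' @export
hypergeometric_enrichment <- function(selection, set_members, universe,
                                      set_name = "set") {
  selection <- unique(selection)
  universe <- unique(universe)
  if (length(selection) == 0 || length(universe) == 0) {
    stop("selection and universe must be nonempty", call. = FALSE)
  }
  outside <- setdiff(selection, universe)
  if (length(outside) > 0) {
    stop("selection contains id(s) outside the universe: ",
         paste(utils::head(outside, 3), collapse = ", "), call. = FALSE)
  }
  K <- length(intersect(set_members, universe))
  if (K == 0) stop("gene set has no members in the universe", call. = FALSE)
  N <- length(universe)
  n <- length(selection)
  k <- length(intersect(selection, intersect(set_members, universe)))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- (k / n) / (K / N)
  tibble::tibble(set_name = set_name, k = k, K = K, n = n, N = N,
                 p = p, fold = fold)
}

#' Enrichment of many gene sets in a selection
#'
#' Runs [hypergeometric_enrichment()] for each set in a long-format gene-set
#' table and ranks results by ascending p; sets without members in the
#' universe are skipped.
#'
#' @param selection Selected node ids.
#' @param sets Tibble with columns `set_name`, `member_id`.
#' @param universe Background ids.
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg adjusted
#'   p-values in an extra `p_adj` column.
#' @return Tibble of enrichment rows, ranked ascending by `p`, with `rank`.
#' @export
enrich_gene_sets <- function(selection, sets, universe, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  res <- sets |>
    dplyr::group_by(.data$set_name) |>
    dplyr::group_map(function(rows, key) {
      if (length(intersect(rows$member_id, universe)) == 0) return(NULL)
      hypergeometric_enrichment(selection, rows$member_id, universe,
                                set_name = key$set_name)
    }) |>
    purrr::list_rbind()
  if (nrow(res) == 0) return(res)
  res <- dplyr::arrange(res, .data$p, .data$set_name)
  res$rank <- seq_len(nrow(res))
  if (adjust == "BH") res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Partition hubs by their sharing pattern across conditions
#'
#' Given per-condition hub sets, partitions the union of hubs of one class
#' into nodes shared by all conditions, nodes shared by some (but not all),
#' and condition-specific nodes.
#'
#' @param hub_sets Named list of `hub_set` objects (or of character id
#'   vectors), one per condition; at least 2 conditions.
#' @param class Molecular class to compare (ignored for plain id vectors).
#' @return Tibble with `id`, `conditions` (list column), `n_conditions`,
#'   `pattern` in `{"shared_all", "pairwise_shared", "condition_specific"}`;
#'   pattern counts are attached as attribute `"counts"`.
#' @export
stage_hub_comparison <- function(hub_sets, class = "lncRNA") {
  if (length(hub_sets) < 2) stop("need at least 2 conditions", call. = FALSE)
  sets <- purrr::map(hub_sets, function(h) {
    if (inherits(h, "hub_set")) hub_ids(h, class) else as.character(h)
  })
  all_ids <- sort(unique(unlist(sets)))
  n_cond <- length(sets)
  out <- purrr::map_dfr(all_ids, function(id) {
    conds <- names(sets)[vapply(sets, function(s) id %in% s, logical(1))]
    tibble::tibble(
      id = id, conditions = list(conds), n_conditions = length(conds),
      pattern = if (length(conds) == n_cond) "shared_all"
                else if (length(conds) > 1) "pairwise_shared"
                else "condition_specific"
    )
  })
  attr(out, "counts") <- table(factor(out$pattern, levels = c(
    "shared_all", "pairwise_shared", "condition_specific")))
  out
}

#' Guilt-by-association function inference for a lncRNA
#'
#' Collects the mRNA-class neighborhood of a lncRNA in the ceRNA network —
#' nodes within distance 2 along miRNA-mediated edges, or direct neighbors
#' when the network carries lncRNA-mRNA edges — and tests each annotation
#' set for hypergeometric enrichment in that neighborhood. Results are ranked
#' ascending by p; the top-ranked annotation is the inferred function.
#'
#' @param net A `cerna_network`.
#' @param lncrna_id A lncRNA node id present in the network.
#' @param annotation_sets Tibble with columns `set_name`, `member_id`.
#' @param universe Background ids (default: all mRNA nodes in the network).
#' @param distance Neighborhood radius; default 1 if the network has
#'   lncRNA-mRNA edges, else 2.
#' @return Tibble of enrichment rows ranked by `p`, with a `top` flag on the
#'   first row; zero rows (with a warning) when the lncRNA has no mRNA
#'   neighbors.
#' @export
neighbor_function_inference <- function(net, lncrna_id, annotation_sets,
                                        universe = NULL, distance = NULL) {
  stopifnot(inherits(net, "cerna_network"))
  if (!lncrna_id %in% net$nodes$id) {
    stop("lncRNA '", lncrna_id, "' not in the network", call. = FALSE)
  }
  if (is.null(distance)) {
    distance <- if (any(net$edges$edge_type == "lncRNA-mRNA")) 1L else 2L
  }
  if (is.null(universe)) universe <- net$nodes$id[net$nodes$class == "mRNA"]
  g <- as_igraph(net)
  nb <- igraph::ego(g, order = distance, nodes = lncrna_id)[[1]]
  nb_ids <- setdiff(igraph::V(g)$name[as.integer(nb)], lncrna_id)
  selection <- intersect(nb_ids, net$nodes$id[net$nodes$class == "mRNA"])
  selection <- intersect(selection, universe)
  if (length(selection) == 0) {
    warning("lncRNA '", lncrna_id, "' has no mRNA neighbors", call. = FALSE)
    return(tibble::tibble())
  }
  res <- enrich_gene_sets(selection, annotation_sets, universe)
  if (nrow(res) > 0) res$top <- res$rank == 1L
  res
}
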