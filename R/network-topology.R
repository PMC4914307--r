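net_cc <- function(g) {
  if (igraph::vcount(g) == 0) return(NA_real_)
  mean(igraph::transitivity(g, type = "local", isolates = "zero"))
}

net_cpl <- function(g) {
  igraph::mean_distance(g, unconnected = TRUE)
}

#' Topological summary of a ceRNA network
#'
#' Computes the global statistics used to characterize a ceRNA network:
#' clustering coefficient (mean local clustering; degree-0/1 nodes contribute
#' 0), characteristic path length (mean shortest-path length over connected
#' ordered pairs), diameter (largest finite distance), radius (minimum
#' eccentricity within the largest component), density `2E/(N(N-1))`, average
#' neighbors `2E/N`, number of components, and degree heterogeneity
#' (coefficient of variation of the degree sequence). The small-world index
#' is filled in when a [randomization_test()] result covering CC and CPL is
#' supplied.
#'
#' @param net A `cerna_network`.
#' @param randomization Optional result of [randomization_test()] with both
#'   `"CC"` and `"CPL"` rows, used to compute the small-world index.
#' @return One-row tibble.
#' @export
topology_summary <- function(net, randomization = NULL) {
  stopifnot(inherits(net, "cerna_network"))
  if (nrow(net$nodes) == 0) stop("empty network", call. = FALSE)
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  comps <- igraph::components(g)
  big <- igraph::induced_subgraph(g, which(comps$membership == which.max(comps$csize)))
  cc <- net_cc(g)
  cpl <- net_cpl(g)
  sigma <- NA_real_
  if (!is.null(randomization) &&
      all(c("CC", "CPL") %in% randomization$metric)) {
    # undefined (NA, not an error) when e.g. a triangle-free network has CC = 0
    sigma <- tryCatch(small_world_index(
      cc, cpl,
      randomization$null_mean[randomization$metric == "CC"],
      randomization$null_mean[randomization$metric == "CPL"]
    ), error = function(e) NA_real_)
  }
  tibble::tibble(
    condition = net$condition,
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    clustering_coefficient = cc,
    characteristic_path_length = cpl,
    small_world_index = sigma,
    avg_neighbors = 2 * igraph::ecount(g) / igraph::vcount(g),
    n_components = comps$no,
    diameter = igraph::diameter(g, unconnected = TRUE),
    radius = igraph::radius(big),
    density = igraph::edge_density(g),
    heterogeneity = stats::sd(deg) / mean(deg)
  )
}

#' Per-node centralities
#'
#' Degree, betweenness, closeness and local clustering per node. Betweenness
#' is normalized by `(N-1)(N-2)/2` over the full graph; closeness is
#' normalized and computed within components (isolated nodes get `NA`);
#' local clustering of degree-0/1 nodes is 0.
#'
#' @param net A `cerna_network`.
#' @return Tibble with columns `id`, `class`, `degree`, `betweenness`,
#'   `closeness`, `clustering`.
#' @export
node_centralities <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  if (nrow(net$nodes) == 0) stop("empty network", call. = FALSE)
  g <- as_igraph(net)
  cl <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  tibble::tibble(
    id = igraph::V(g)$name,
    class = igraph::V(g)$class,
    degree = as.numeric(igraph::degree(g)),
    betweenness = unname(igraph::betweenness(g, normalized = TRUE)),
    closeness = unname(ifelse(is.nan(cl), NA_real_, cl)),
    clustering = unname(igraph::transitivity(g, type = "local", isolates = "zero"))
  )
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Rewires the network with `n_swap_multiples * E` attempted double-edge
#' swaps, rejecting swaps that would create self-loops or duplicate edges —
#' and, when `respect_classes` is on, edges whose endpoint-class pairing does
#' not occur in the original network (so null networks of a ceRNA graph stay
#' consistent with its tripartite layering). The degree sequence is exactly
#' preserved. Deterministic under `seed`.
#'
#' @param net A `cerna_network` with >= 2 edges.
#' @param n_swap_multiples Attempted swaps per edge (default 10).
#' @param respect_classes Keep endpoint-class pairings of the original
#'   network (default `TRUE`; has no effect when all classes are `"other"`).
#' @param seed Integer seed.
#' @return A rewired `cerna_network`; if no swap was accepted a copy is
#'   returned with a warning.
#' @export
degree_preserving_randomize <- function(net, n_swap_multiples = 10,
                                        respect_classes = TRUE, seed = 1L) {
  stopifnot(inherits(net, "cerna_network"))
  E <- nrow(net$edges)
  if (E < 2) stop("need at least 2 edges to rewire", call. = FALSE)
  from <- net$edges$from
  to <- net$edges$to
  cls <- stats::setNames(net$nodes$class, net$nodes$id)
  allowed <- unique(paste(pmin(cls[from], cls[to]), pmax(cls[from], cls[to])))
  pair_ok <- function(a, b) {
    !respect_classes ||
      paste(min(cls[[a]], cls[[b]]), max(cls[[a]], cls[[b]])) %in% allowed
  }
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (k in ekey(from, to)) assign(k, TRUE, envir = seen)
  accepted <- 0L
  withr::with_seed(seed, {
    for (att in seq_len(ceiling(n_swap_multiples * E))) {
      ij <- sample.int(E, 2L)
      a <- from[ij[1]]; b <- to[ij[1]]
      c_ <- from[ij[2]]; d <- to[ij[2]]
      if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      # proposed new edges: a-d and c_-b
      if (a == d || c_ == b) next
      k1 <- ekey(a, d); k2 <- ekey(c_, b)
      if (k1 == k2 || exists(k1, envir = seen) || exists(k2, envir = seen)) next
      if (!pair_ok(a, d) || !pair_ok(c_, b)) next
      rm(list = c(ekey(a, b), ekey(c_, d)), envir = seen)
      assign(k1, TRUE, envir = seen)
      assign(k2, TRUE, envir = seen)
      from[ij[1]] <- min(a, d); to[ij[1]] <- max(a, d)
      from[ij[2]] <- min(c_, b); to[ij[2]] <- max(c_, b)
      accepted <- accepted + 1L
    }
  })
  if (accepted == 0L) {
    warning("no valid double-edge swap exists; returning the network unchanged",
            call. = FALSE)
  }
  out <- cerna_network(net$nodes, tibble::tibble(from = from, to = to),
                       condition = net$condition)
  # degree sequence must be exactly preserved on every run
  deg_of <- function(e) table(factor(c(e$from, e$to), levels = net$nodes$id))
  stopifnot(identical(deg_of(net$edges), deg_of(out$edges)))
  out
}

#' Empirical significance of topology metrics against a degree-preserving null
#'
#' Generates `replicates` degree-preserving random networks and compares the
#' observed clustering coefficient and/or characteristic path length against
#' the null distribution. The empirical p-value uses the add-one correction
#' `(#{null beyond observed} + 1) / (replicates + 1)` so it is never exactly
#' zero; direction `"greater"` counts null values above the observed metric
#' (the usual choice for CC), `"less"` counts below (useful for CPL when the
#' observed value exceeds the null).
#'
#' @param net A `cerna_network`.
#' @param metrics Subset of `c("CC", "CPL")`.
#' @param replicates Number of random networks (default 1000).
#' @param seed Integer seed.
#' @param direction `"greater"` (default) or `"less"`.
#' @param n_swap_multiples,respect_classes Passed to
#'   [degree_preserving_randomize()].
#' @return Tibble with one row per metric: `metric`, `observed`, `null_mean`,
#'   `empirical_p`, `direction`, `replicates`, `null_values` (list column),
#'   `seed`.
#' @export
randomization_test <- function(net, metrics = c("CC", "CPL"), replicates = 1000,
                               seed = 1L, direction = c("greater", "less"),
                               n_swap_multiples = 10, respect_classes = TRUE) {
  direction <- match.arg(direction)
  metrics <- match.arg(metrics, c("CC", "CPL"), several.ok = TRUE)
  if (replicates < 10) warning("fewer than 10 replicates gives a very coarse p",
                               call. = FALSE)
  g <- as_igraph(net)
  observed <- c(CC = net_cc(g), CPL = net_cpl(g))[metrics]
  nulls <- matrix(NA_real_, nrow = replicates, ncol = length(metrics),
                  dimnames = list(NULL, metrics))
  for (i in seq_len(replicates)) {
    rnet <- suppressWarnings(degree_preserving_randomize(
      net, n_swap_multiples = n_swap_multiples,
      respect_classes = respect_classes, seed = seed + i))
    rg <- as_igraph(rnet)
    if ("CC" %in% metrics) nulls[i, "CC"] <- net_cc(rg)
    if ("CPL" %in% metrics) nulls[i, "CPL"] <- net_cpl(rg)
  }
  purrr::map_dfr(metrics, function(m) {
    null <- nulls[, m]
    exceed <- if (direction == "greater") sum(null > observed[[m]])
              else sum(null < observed[[m]])
    tibble::tibble(metric = m, observed = observed[[m]], null_mean = mean(null),
                   empirical_p = (exceed + 1) / (replicates + 1),
                   direction = direction, replicates = replicates,
                   null_values = list(null), seed = seed)
  })
}

#' Small-world index
#'
#' `sigma = (CC / CC_r) / (CPL / CPL_r)`, where `CC_r` and `CPL_r` are the
#' mean clustering coefficient and characteristic path length of the
#' degree-preserving random ensemble. Values above 1 indicate small-world
#' organization.
#'
#' @param cc,cpl Observed clustering coefficient and path length (> 0).
#' @param cc_r,cpl_r Null-ensemble means (> 0).
#' @return The small-world index (a single number).
#' @export
small_world_index <- function(cc, cpl, cc_r, cpl_r) {
  vals <- c(cc, cpl, cc_r, cpl_r)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all inputs to the small-world index must be positive and finite",
         call. = FALSE)
  }
  (cc / cc_r) / (cpl / cpl_r)
}

#' Wilcoxon rank-sum comparison of a centrality between node groups
#'
#' Compares the values of one column of a per-node table between nodes inside
#' and outside a given group (e.g. known disease genes vs the rest), using the
#' two-sided Wilcoxon rank-sum test with tie correction.
#'
#' @param node_table Tibble from [node_centralities()] (or any per-node table
#'   with an `id` column).
#' @param column Name of the numeric column to compare.
#' @param group_ids Node ids forming the first group.
#' @return One-row tibble: `column`, `n_in`, `n_out`, `mean_in`, `mean_out`,
#'   `W`, `p`.
#' @export
compare_groups_wilcoxon <- function(node_table, column, group_ids) {
  stopifnot(column %in% names(node_table))
  inside <- node_table$id %in% group_ids
  x <- node_table[[column]][inside]
  y <- node_table[[column]][!inside]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both node groups must be nonempty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  tibble::tibble(column = column, n_in = length(x), n_out = length(y),
                 mean_in = mean(x), mean_out = mean(y),
                 W = unname(wt$statistic), p = wt$p.value)
}
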