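# Independent brute-force oracles and small fixture builders. Everything here
# is written from first principles (base R, adjacency matrices, longhand
# formulas) so it shares no code path with the package implementation.

mk_expr <- function(values, class, prefix = "s") {
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("%s%02d", prefix, seq_len(ncol(values)))
  }
  expression_matrix(values, class)
}

mk_clinical <- function(sample_ids, os = NULL, event = NULL, ...) {
  n <- length(sample_ids)
  tibble::tibble(
    sample_id = sample_ids,
    os_months = if (is.null(os)) seq(10, 10 + n - 1) else os,
    event = if (is.null(event)) rep(c(1L, 0L), length.out = n) else as.integer(event),
    ...
  )
}

mk_matched <- function(mir, lnc, mrna, clinical = NULL) {
  samples <- colnames(mir)
  if (is.null(clinical)) clinical <- mk_clinical(samples)
  align_matched_set(mk_expr(mir, "miRNA"), mk_expr(lnc, "lncRNA"),
                    mk_expr(mrna, "mRNA"), clinical)
}

# a generic graph network from an edge matrix (node class "other")
mk_net <- function(edges, nodes = NULL) {
  edges <- matrix(as.character(edges), ncol = 2)
  if (is.null(nodes)) nodes <- sort(unique(as.vector(edges)))
  cerna_network(tibble::tibble(id = nodes, class = "other"),
                tibble::tibble(from = edges[, 1], to = edges[, 2]))
}

# longhand Pearson r (sample covariance over the product of sample sds)
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) / (n - 1) /
    (stats::sd(x) * stats::sd(y))
}

# exhaustive triple-nested-loop triplet caller
oracle_triplets <- function(set, mrna_cat, lncrna_cat, threshold, min_shared = 1) {
  lnc <- unclass(set$lncrna); mrna <- unclass(set$mrna)
  out <- list()
  for (l in rownames(lnc)) {
    for (g in rownames(mrna)) {
      if (stats::sd(lnc[l, ]) == 0 || stats::sd(mrna[g, ]) == 0) next
      r <- oracle_pearson(lnc[l, ], mrna[g, ])
      if (r <= threshold) next
      shared <- character(0)
      for (m in unique(c(mrna_cat$mirna_id, lncrna_cat$mirna_id))) {
        hits_g <- any(mrna_cat$mirna_id == m & mrna_cat$target_id == g)
        hits_l <- any(lncrna_cat$mirna_id == m & lncrna_cat$target_id == l)
        if (hits_g && hits_l) shared <- c(shared, m)
      }
      if (length(shared) >= min_shared) {
        out[[length(out) + 1]] <- tibble::tibble(
          lncrna_id = l, mrna_id = g, r_lnc_mrna = r,
          shared_mirnas = list(sort(shared)))
      }
    }
  }
  if (length(out) == 0) return(tibble::tibble(lncrna_id = character(),
                                              mrna_id = character()))
  df <- do.call(rbind, out)
  df[order(df$lncrna_id, df$mrna_id), ]
}

# adjacency matrix of a cerna_network, nodes in net$nodes$id order
adj_matrix <- function(net) {
  ids <- net$nodes$id
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(net$edges))) {
    A[net$edges$from[i], net$edges$to[i]] <- 1L
    A[net$edges$to[i], net$edges$from[i]] <- 1L
  }
  A
}

# all-pairs BFS distances
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    visited <- rep(FALSE, n); visited[s] <- TRUE
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] == 1))))
      nxt <- nxt[!visited[nxt]]
      if (length(nxt) == 0) break
      D[s, nxt] <- d
      visited[nxt] <- TRUE
      frontier <- nxt
    }
  }
  D
}

# global statistics from scratch: triangle counting + BFS
oracle_topology <- function(net) {
  A <- adj_matrix(net)
  n <- nrow(A)
  deg <- rowSums(A)
  cc_local <- vapply(seq_len(n), function(v) {
    if (deg[v] < 2) return(0)
    nb <- which(A[v, ] == 1)
    links <- sum(A[nb, nb]) / 2
    links / choose(deg[v], 2)
  }, numeric(1))
  D <- oracle_distances(A)
  finite <- D[upper.tri(D)][is.finite(D[upper.tri(D)])]
  comp_of <- function() {
    lab <- rep(NA_integer_, n); k <- 0
    for (s in seq_len(n)) {
      if (!is.na(lab[s])) next
      k <- k + 1
      lab[is.finite(D[s, ])] <- k
    }
    lab
  }
  lab <- comp_of()
  ecc <- apply(D, 1, function(d) max(d[is.finite(d)]))
  big <- which(lab == which.max(tabulate(lab)))
  ecc_big <- apply(D[big, big, drop = FALSE], 1, function(d) max(d[is.finite(d)]))
  list(
    n_nodes = n, n_edges = sum(A) / 2,
    cc = mean(cc_local), cc_local = cc_local,
    cpl = mean(finite),
    diameter = max(finite),
    radius = min(ecc_big),
    density = sum(A) / (n * (n - 1)),
    n_components = max(lab),
    avg_neighbors = mean(deg),
    heterogeneity = stats::sd(deg) / mean(deg)
  )
}

# betweenness via sigma counting on the BFS DAG; normalized by (n-1)(n-2)/2
oracle_betweenness <- function(net) {
  A <- adj_matrix(net)
  n <- nrow(A)
  D <- oracle_distances(A)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (d in sort(unique(D[s, is.finite(D[s, ]) & D[s, ] > 0]))) {
      for (v in which(D[s, ] == d)) {
        preds <- which(A[v, ] == 1 & D[s, ] == d - 1)
        sigma[s, v] <- sum(sigma[s, preds])
      }
    }
  }
  bc <- vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    tot
  }, numeric(1))
  stats::setNames(bc / ((n - 1) * (n - 2) / 2), rownames(A))
}

# core numbers by iterative peeling on an adjacency matrix
oracle_coreness <- function(A) {
  n <- nrow(A)
  core <- rep(0L, n)
  alive <- rep(TRUE, n)
  k <- 0L
  while (any(alive)) {
    deg <- rowSums(A[, alive, drop = FALSE])[alive]
    if (min(deg) > k) k <- min(deg)
    v <- which(alive)[which(deg <= k)[1]]
    core[v] <- k
    alive[v] <- FALSE
  }
  core
}

# direct transcription of molecular complex detection on adjacency matrices
oracle_mcode <- function(net, degree_cutoff = 2, node_score_cutoff = 0.2,
                         max_depth = 100, haircut = TRUE) {
  A <- adj_matrix(net)
  ids <- rownames(A)
  n <- nrow(A)
  dens <- function(S) {
    if (length(S) < 2) return(0)
    sum(A[S, S]) / (length(S) * (length(S) - 1))
  }
  w <- vapply(seq_len(n), function(v) {
    if (sum(A[v, ]) < degree_cutoff) return(0)
    nb <- c(v, which(A[v, ] == 1))
    core <- oracle_coreness(A[nb, nb, drop = FALSE])
    k <- max(core)
    if (k == 0) return(0)
    k * dens(nb[core >= k])
  }, numeric(1))
  used <- rep(FALSE, n)
  complexes <- list()
  for (seedv in order(-w, ids)) {
    if (used[seedv] || w[seedv] <= 0) next
    thr <- (1 - node_score_cutoff) * w[seedv]
    members <- seedv; used[seedv] <- TRUE
    frontier <- seedv; depth <- 0
    while (length(frontier) > 0 && depth < max_depth) {
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] == 1))))
      nxt <- nxt[!used[nxt] & w[nxt] >= thr]
      if (length(nxt) == 0) break
      used[nxt] <- TRUE
      members <- c(members, nxt)
      frontier <- nxt
      depth <- depth + 1
    }
    core <- oracle_coreness(A[members, members, drop = FALSE])
    if (max(core) < 2) next
    if (haircut) members <- members[core >= 2]
    complexes[[length(complexes) + 1]] <- list(
      members = sort(ids[members]),
      score = dens(members) * length(members))
  }
  complexes[order(-vapply(complexes, `[[`, numeric(1), "score"))]
}

# upper-tail hypergeometric mass by explicit summation of binomials
oracle_hyper_p <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
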