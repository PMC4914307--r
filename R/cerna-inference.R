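#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation between two expression vectors, with the
#' two-sided p-value from the t approximation on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length n >= 3, both non-constant.
#' @return One-row tibble with columns `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# p-values for a matrix of correlations, t approximation with n-2 df
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = n - 2)
}

# drop constant rows, reporting how many were removed
drop_constant_rows <- function(m, label) {
  keep <- matrixStats_rowSds(m) > 0
  if (any(!keep)) {
    message(sum(!keep), " constant ", label, " row(s) dropped before correlation")
  }
  m[keep, , drop = FALSE]
}

matrixStats_rowSds <- function(m) {
  apply(m, 1L, stats::sd)
}

#' Percentile threshold of the overall lncRNA-mRNA correlation distribution
#'
#' Computes Pearson correlations for all lncRNA x mRNA pairs in the matched
#' set (exhaustively) and returns the requested percentile of that
#' distribution. Used as the positive-correlation cutoff for candidate
#' crosstalk pairs; constant expression rows are dropped first.
#'
#' @param set A `matched_set`.
#' @param percentile Percentile in (0, 100], default 99.
#' @return The threshold (a single number).
#' @export
correlation_threshold <- function(set, percentile = 99) {
  stopifnot(inherits(set, "matched_set"))
  lnc <- drop_constant_rows(unclass(set$lncrna), "lncRNA")
  mrna <- drop_constant_rows(unclass(set$mrna), "mRNA")
  if (nrow(lnc) < 2 || nrow(mrna) < 2) {
    stop("need at least 2 non-constant lncRNAs and mRNAs", call. = FALSE)
  }
  r <- stats::cor(t(lnc), t(mrna))
  unname(stats::quantile(as.vector(r), probs = percentile / 100, type = 7))
}

#' Find candidate lncRNA-mRNA ceRNA crosstalk pairs
#'
#' A candidate crosstalk pair is an (lncRNA, mRNA) pair whose expression
#' correlation exceeds `threshold` and which shares at least `min_shared`
#' miRNAs across the two validated interaction catalogs.
#'
#' @param set A `matched_set`.
#' @param mrna_cat,lncrna_cat Interaction catalogs (tibbles with `mirna_id`,
#'   `target_id`) for miRNA->mRNA and miRNA->lncRNA interactions.
#' @param threshold Positive-correlation cutoff in (-1, 1); see
#'   [correlation_threshold()].
#' @param min_shared Minimum number of shared miRNAs (default 1).
#' @return Tibble of candidate triplets: `lncrna_id`, `mrna_id`,
#'   `r_lnc_mrna`, `shared_mirnas` (list column), `n_shared`, `status`.
#' @export
find_candidate_triplets <- function(set, mrna_cat, lncrna_cat, threshold,
                                    min_shared = 1L) {
  stopifnot(inherits(set, "matched_set"))
  if (threshold <= -1 || threshold >= 1) stop("threshold must lie in (-1, 1)", call. = FALSE)
  if (min_shared < 1) stop("min_shared must be >= 1", call. = FALSE)
  lnc <- drop_constant_rows(unclass(set$lncrna), "lncRNA")
  mrna <- drop_constant_rows(unclass(set$mrna), "mRNA")
  mir_of_lnc <- split(lncrna_cat$mirna_id, lncrna_cat$target_id)
  mir_of_mrna <- split(mrna_cat$mirna_id, mrna_cat$target_id)

  r <- stats::cor(t(lnc), t(mrna))
  hits <- which(r > threshold, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty_triplets())
  out <- purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    l <- rownames(lnc)[hits[i, 1]]
    g <- rownames(mrna)[hits[i, 2]]
    shared <- intersect(mir_of_lnc[[l]], mir_of_mrna[[g]])
    if (length(shared) < min_shared) return(NULL)
    tibble::tibble(lncrna_id = l, mrna_id = g,
                   r_lnc_mrna = r[hits[i, 1], hits[i, 2]],
                   shared_mirnas = list(sort(shared)),
                   n_shared = length(shared), status = "candidate")
  })
  if (nrow(out) == 0) return(empty_triplets())
  dplyr::arrange(out, .data$lncrna_id, .data$mrna_id)
}

empty_triplets <- function() {
  tibble::tibble(lncrna_id = character(), mrna_id = character(),
                 r_lnc_mrna = numeric(), shared_mirnas = list(),
                 n_shared = integer(), status = character())
}

#' Filter candidate crosstalk pairs to functional ones
#'
#' A candidate becomes functional when at least one of its shared miRNAs is
#' negatively co-expressed with both the lncRNA and the mRNA. Under the
#' default rule (`"p05"`) negativity requires r < 0 with two-sided p < 0.05 on
#' both arms; `"sign"` requires only r < 0. The retained shared-miRNA set is
#' pruned to the miRNAs passing the rule.
#'
#' @param candidates Tibble from [find_candidate_triplets()].
#' @param set The same `matched_set` the candidates were derived from.
#' @param rule `"p05"` (default) or `"sign"`.
#' @param alpha Two-sided significance level for the `"p05"` rule.
#' @return Tibble of functional triplets with the candidate columns plus a
#'   `mirna_detail` list column (per shared miRNA: `mirna_id`, `r_mir_mrna`,
#'   `p_mir_mrna`, `r_mir_lnc`, `p_mir_lnc`, `passes`); `status` is
#'   `"functional"` and `shared_mirnas` holds only passing miRNAs.
#' @export
filter_functional_triplets <- function(candidates, set, rule = c("p05", "sign"),
                                       alpha = 0.05) {
  rule <- match.arg(rule)
  stopifnot(inherits(set, "matched_set"))
  if (nrow(candidates) == 0) {
    out <- empty_triplets()
    out$mirna_detail <- list()
    return(out)
  }
  mir <- unclass(set$mirna); lnc <- unclass(set$lncrna); mrna <- unclass(set$mrna)
  need_mir <- unique(unlist(candidates$shared_mirnas))
  missing <- c(setdiff(candidates$lncrna_id, rownames(lnc)),
               setdiff(candidates$mrna_id, rownames(mrna)),
               setdiff(need_mir, rownames(mir)))
  if (length(missing) > 0) {
    stop("candidate references molecule(s) absent from the matched set: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  n <- ncol(mir)
  out <- purrr::pmap_dfr(candidates, function(lncrna_id, mrna_id, r_lnc_mrna,
                                              shared_mirnas, n_shared, status, ...) {
    mirs <- shared_mirnas
    r_mm <- drop(stats::cor(t(mir[mirs, , drop = FALSE]), mrna[mrna_id, ]))
    r_ml <- drop(stats::cor(t(mir[mirs, , drop = FALSE]), lnc[lncrna_id, ]))
    detail <- tibble::tibble(
      mirna_id = mirs,
      r_mir_mrna = r_mm, p_mir_mrna = cor_pvalue(r_mm, n),
      r_mir_lnc = r_ml, p_mir_lnc = cor_pvalue(r_ml, n)
    )
    detail$passes <- if (rule == "sign") {
      detail$r_mir_mrna < 0 & detail$r_mir_lnc < 0
    } else {
      detail$r_mir_mrna < 0 & detail$r_mir_lnc < 0 &
        detail$p_mir_mrna < alpha & detail$p_mir_lnc < alpha
    }
    if (!any(detail$passes)) return(NULL)
    tibble::tibble(lncrna_id = lncrna_id, mrna_id = mrna_id,
                   r_lnc_mrna = r_lnc_mrna,
                   shared_mirnas = list(detail$mirna_id[detail$passes]),
                   n_shared = sum(detail$passes),
                   status = "functional", mirna_detail = list(detail))
  })
  if (nrow(out) == 0) {
    out <- empty_triplets()
    out$mirna_detail <- list()
  }
  out
}

#' Assemble a ceRNA network from functional crosstalk triplets
#'
#' Default edge semantics add, for every triplet and every retained shared
#' miRNA, the miRNA-mRNA and miRNA-lncRNA edges (the mediator-centred view);
#' `cerna_edges = TRUE` additionally adds the direct lncRNA-mRNA edge.
#' Duplicate edges are collapsed and carry the full list of contributing
#' triplets as provenance.
#'
#' @param functional Tibble of functional triplets.
#' @param cerna_edges Also add lncRNA-mRNA edges? Default `FALSE`.
#' @param condition Condition label for the network.
#' @return A `cerna_network`.
#' @export
assemble_network <- function(functional, cerna_edges = FALSE, condition = "global") {
  if (nrow(functional) == 0) {
    warning("no functional triplets; returning an empty network", call. = FALSE)
    return(cerna_network(tibble::tibble(id = character(), class = character()),
                         tibble::tibble(from = character(), to = character()),
                         condition = condition))
  }
  if (!all(functional$status == "functional")) {
    stop("assemble_network expects functional triplets", call. = FALSE)
  }
  trip_id <- paste(functional$lncrna_id, functional$mrna_id, sep = "|")
  raw <- purrr::map_dfr(seq_len(nrow(functional)), function(i) {
    mirs <- functional$shared_mirnas[[i]]
    e <- dplyr::bind_rows(
      tibble::tibble(from = mirs, to = functional$mrna_id[i]),
      tibble::tibble(from = mirs, to = functional$lncrna_id[i])
    )
    if (cerna_edges) {
      e <- dplyr::bind_rows(e, tibble::tibble(from = functional$lncrna_id[i],
                                              to = functional$mrna_id[i]))
    }
    e$triplet <- trip_id[i]
    e
  })
  swap <- raw$from > raw$to
  tmp <- raw$from[swap]; raw$from[swap] <- raw$to[swap]; raw$to[swap] <- tmp
  edges <- raw |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(triplets = list(sort(unique(.data$triplet))), .groups = "drop")
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = unique(unlist(functional$shared_mirnas)), class = "miRNA"),
    tibble::tibble(id = unique(functional$lncrna_id), class = "lncRNA"),
    tibble::tibble(id = unique(functional$mrna_id), class = "mRNA")
  )
  cerna_network(nodes, edges, condition = condition)
}

#' Run the full crosstalk inference on a matched set
#'
#' Convenience wrapper: percentile threshold (or a fixed override), candidate
#' search, functional filtering and network assembly.
#'
#' @param set A `matched_set`.
#' @param mrna_cat,lncrna_cat Interaction catalogs.
#' @param percentile Percentile for the correlation threshold (default 99);
#'   ignored when `threshold` is given.
#' @param threshold Optional fixed correlation cutoff.
#' @param min_shared Minimum shared miRNAs per pair.
#' @param rule Negativity rule, `"p05"` or `"sign"`.
#' @param cerna_edges Add lncRNA-mRNA edges to the network?
#' @param condition Condition label.
#' @return List with `threshold`, `candidates`, `functional`, `network`.
#' @export
infer_cerna_network <- function(set, mrna_cat, lncrna_cat, percentile = 99,
                                threshold = NULL, min_shared = 1L,
                                rule = "p05", cerna_edges = FALSE,
                                condition = "global") {
  if (is.null(threshold)) threshold <- correlation_threshold(set, percentile)
  candidates <- find_candidate_triplets(set, mrna_cat, lncrna_cat,
                                        threshold, min_shared)
  functional <- filter_functional_triplets(candidates, set, rule = rule)
  network <- suppressWarnings(
    assemble_network(functional, cerna_edges = cerna_edges, condition = condition))
  list(threshold = threshold, candidates = candidates,
       functional = functional, network = network)
}

#' Restrict a matched set to a subset of samples
#' @param set A `matched_set`.
#' @param sample_ids Sample ids to keep (>= 3 required).
#' @return A `matched_set` on the requested samples.
#' @export
subset_matched <- function(set, sample_ids) {
  stopifnot(inherits(set, "matched_set"))
  keep <- intersect(matched_samples(set), sample_ids)
  align_matched_set(
    expression_matrix(unclass(set$mirna)[, keep, drop = FALSE], "miRNA"),
    expression_matrix(unclass(set$lncrna)[, keep, drop = FALSE], "lncRNA"),
    expression_matrix(unclass(set$mrna)[, keep, drop = FALSE], "mRNA"),
    set$clinical[set$clinical$sample_id %in% keep, , drop = FALSE]
  )
}

#' Infer condition-specific ceRNA networks
#'
#' Re-runs the full inference (threshold, candidates, functional filter,
#' assembly) independently on each subgroup of samples defined by a clinical
#' field (e.g. tumor stage). Groups with fewer than 3 samples are skipped
#' with a warning.
#'
#' @param set A `matched_set`.
#' @param mrna_cat,lncrna_cat Interaction catalogs.
#' @param group_by Name of the clinical column to split on (default
#'   `"stage"`).
#' @param ... Passed to [infer_cerna_network()].
#' @return Named list of `cerna_network` objects, one per condition.
#' @export
condition_specific_networks <- function(set, mrna_cat, lncrna_cat,
                                        group_by = "stage", ...) {
  stopifnot(inherits(set, "matched_set"))
  if (!group_by %in% names(set$clinical)) {
    stop("clinical field '", group_by, "' not found", call. = FALSE)
  }
  groups <- split(set$clinical$sample_id, set$clinical[[group_by]])
  out <- list()
  for (g in names(groups)) {
    if (length(groups[[g]]) < 3) {
      warning("group '", g, "' has fewer than 3 samples; skipped", call. = FALSE)
      next
    }
    sub <- subset_matched(set, groups[[g]])
    out[[g]] <- infer_cerna_network(sub, mrna_cat, lncrna_cat,
                                    condition = g, ...)$network
  }
  out
}

#' Write a triplet table to TSV
#' @param triplets Candidate or functional triplet tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_triplets <- function(triplets, path) {
  flat <- triplets
  flat$shared_mirnas <- vapply(flat$shared_mirnas, paste, character(1), collapse = ",")
  flat$mirna_detail <- NULL
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
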