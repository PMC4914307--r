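#' Specification for a synthetic matched-expression cohort
#'
#' Describes the cohort the generator emulates: three matched expression
#' layers with planted ceRNA triplets (an lncRNA and an mRNA positively
#' co-expressed because both are repressed by the same miRNAs), background
#' molecules that are pure noise, stage labels, and overall survival drawn
#' from an exponential proportional-hazards model with planted lncRNA
#' coefficients.
#'
#' @param n_samples Number of patients.
#' @param n_mirna,n_lncrna,n_mrna Molecules per class.
#' @param n_planted_triplets Number of planted lncRNA-mRNA crosstalk pairs.
#' @param shared_mirnas_per_triplet Shared miRNAs mediating each planted pair.
#' @param coupling_strength Magnitude in (0, 1] of the latent miRNA-activity
#'   loading on planted lncRNA/mRNA rows; larger means stronger (positive)
#'   lncRNA-mRNA and (negative) miRNA-target correlations.
#' @param noise_sd Standard deviation of the additive noise on planted rows.
#' @param stage_proportions Named proportions over stages II/III/IV (sum 1).
#' @param planted_cox_coefficients Named numeric vector of log-hazard
#'   coefficients per planted lncRNA id (names may also be given as indices
#'   1..n_planted_triplets via `lnc<i>` ids produced by the generator).
#' @param baseline_hazard Exponential baseline hazard (events per month).
#' @param censoring_rate Independent exponential censoring rate (per month).
#' @param n_decoy_mrna,n_decoy_lncrna Decoy interaction pairs attached to
#'   background molecules only, so ground truth stays unambiguous.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 200,
                           n_mirna = 60, n_lncrna = 80, n_mrna = 150,
                           n_planted_triplets = 20,
                           shared_mirnas_per_triplet = 2,
                           coupling_strength = 0.9,
                           noise_sd = 0.3,
                           stage_proportions = c(II = 0.15, III = 0.70, IV = 0.15),
                           planted_cox_coefficients = c(lnc001 = 0.6, lnc002 = -0.6),
                           baseline_hazard = 0.015,
                           censoring_rate = 0.01,
                           n_decoy_mrna = 200, n_decoy_lncrna = 100,
                           seed = 1L) {
  spec <- list(
    n_samples = n_samples, n_mirna = n_mirna, n_lncrna = n_lncrna,
    n_mrna = n_mrna, n_planted_triplets = n_planted_triplets,
    shared_mirnas_per_triplet = shared_mirnas_per_triplet,
    coupling_strength = coupling_strength, noise_sd = noise_sd,
    stage_proportions = stage_proportions,
    planted_cox_coefficients = planted_cox_coefficients,
    baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
    n_decoy_mrna = n_decoy_mrna, n_decoy_lncrna = n_decoy_lncrna,
    seed = as.integer(seed)
  )
  counts <- unlist(spec[c("n_samples", "n_mirna", "n_lncrna", "n_mrna",
                          "n_planted_triplets", "shared_mirnas_per_triplet")])
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (abs(sum(stage_proportions) - 1) > 1e-8) {
    stop("stage_proportions must sum to 1", call. = FALSE)
  }
  if (coupling_strength <= 0 || coupling_strength > 1) {
    stop("coupling_strength must lie in (0, 1]", call. = FALSE)
  }
  if (n_planted_triplets > n_lncrna || n_planted_triplets > n_mrna) {
    stop("more planted triplets than lncRNAs or mRNAs", call. = FALSE)
  }
  if (n_planted_triplets * shared_mirnas_per_triplet > n_mirna) {
    stop("planted triplets require more miRNAs than n_mirna", call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

synthetic_ids <- function(spec) {
  list(
    mirna = sprintf("mir%03d", seq_len(spec$n_mirna)),
    lncrna = sprintf("lnc%03d", seq_len(spec$n_lncrna)),
    mrna = sprintf("gene%03d", seq_len(spec$n_mrna))
  )
}

#' Generate a synthetic matched cohort with ground truth
#'
#' For each planted triplet a latent miRNA-activity vector `m` is drawn
#' i.i.d. standard normal across samples; its shared miRNA rows are
#' `m + noise`, and the planted lncRNA and mRNA rows are
#' `-coupling_strength * m + noise`, so the lncRNA-mRNA correlation is
#' positive while both correlate negatively with the mediating miRNAs.
#' Background rows are i.i.d. standard normal. Interaction catalogs contain
#' the planted miRNA->target pairs plus decoy pairs among background
#' molecules. Survival times are exponential under a proportional-hazards
#' model with linear predictor `sum(coefficient * lncRNA expression)` and
#' independent exponential censoring. Deterministic under `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `set` (a `matched_set`), `mirna_mrna` and
#'   `mirna_lncrna` (interaction catalogs), and `truth` (planted triplets,
#'   coefficients and stage assignments).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ids <- synthetic_ids(spec)
  n <- spec$n_samples
  samples <- sprintf("s%04d", seq_len(n))

  withr::with_seed(spec$seed, {
    mir <- matrix(stats::rnorm(spec$n_mirna * n), spec$n_mirna, n,
                  dimnames = list(ids$mirna, samples))
    lnc <- matrix(stats::rnorm(spec$n_lncrna * n), spec$n_lncrna, n,
                  dimnames = list(ids$lncrna, samples))
    mrna <- matrix(stats::rnorm(spec$n_mrna * n), spec$n_mrna, n,
                  dimnames = list(ids$mrna, samples))

    s <- spec$shared_mirnas_per_triplet
    planted <- purrr::map(seq_len(spec$n_planted_triplets), function(t) {
      m <- stats::rnorm(n)
      mir_idx <- ((t - 1L) * s + 1L):(t * s)
      for (j in mir_idx) {
        mir[j, ] <<- m + stats::rnorm(n, sd = spec$noise_sd)
      }
      lnc[t, ] <<- -spec$coupling_strength * m + stats::rnorm(n, sd = spec$noise_sd)
      mrna[t, ] <<- -spec$coupling_strength * m + stats::rnorm(n, sd = spec$noise_sd)
      tibble::tibble(lncrna_id = ids$lncrna[t], mrna_id = ids$mrna[t],
                     shared_mirnas = list(ids$mirna[mir_idx]))
    }) |> purrr::list_rbind()

    cat_mrna <- planted |>
      dplyr::select("mrna_id", "shared_mirnas") |>
      tidyr::unnest("shared_mirnas") |>
      dplyr::transmute(mirna_id = .data$shared_mirnas, target_id = .data$mrna_id,
                       target_class = "mRNA")
    cat_lnc <- planted |>
      dplyr::select("lncrna_id", "shared_mirnas") |>
      tidyr::unnest("shared_mirnas") |>
      dplyr::transmute(mirna_id = .data$shared_mirnas, target_id = .data$lncrna_id,
                       target_class = "lncRNA")

    # decoys only among background molecules (index > planted range)
    bg_mir <- ids$mirna[(spec$n_planted_triplets * s + 1L):spec$n_mirna]
    bg_lnc <- ids$lncrna[(spec$n_planted_triplets + 1L):spec$n_lncrna]
    bg_mrna <- ids$mrna[(spec$n_planted_triplets + 1L):spec$n_mrna]
    decoys <- function(targets, k, class) {
      pool <- expand.grid(mirna_id = bg_mir, target_id = targets,
                          stringsAsFactors = FALSE)
      pick <- pool[sample.int(nrow(pool), min(k, nrow(pool))), ]
      tibble::tibble(mirna_id = pick$mirna_id, target_id = pick$target_id,
                     target_class = class)
    }
    cat_mrna <- dplyr::distinct(dplyr::bind_rows(
      cat_mrna, decoys(bg_mrna, spec$n_decoy_mrna, "mRNA")))
    cat_lnc <- dplyr::distinct(dplyr::bind_rows(
      cat_lnc, decoys(bg_lnc, spec$n_decoy_lncrna, "lncRNA")))

    stages <- sample(names(spec$stage_proportions), n, replace = TRUE,
                     prob = spec$stage_proportions)
    coefs <- spec$planted_cox_coefficients
    missing_coef <- setdiff(names(coefs), ids$lncrna)
    if (length(missing_coef) > 0) {
      stop("planted_cox_coefficients name unknown lncRNA(s): ",
           paste(missing_coef, collapse = ", "), call. = FALSE)
    }
    lp <- if (length(coefs) > 0) {
      drop(coefs %*% lnc[names(coefs), , drop = FALSE])
    } else rep(0, n)
    death <- stats::rexp(n, rate = spec$baseline_hazard * exp(lp))
    cens <- stats::rexp(n, rate = spec$censoring_rate)
    clinical <- tibble::tibble(
      sample_id = samples,
      os_months = pmin(death, cens),
      event = as.integer(death <= cens),
      age = round(pmin(90, pmax(30, stats::rnorm(n, 60, 10)))),
      stage = stages,
      grade = sample(c("G1/G2", "G3/G4"), n, replace = TRUE, prob = c(0.2, 0.8)),
      residual = sample(c("0-10mm", ">10mm"), n, replace = TRUE, prob = c(0.6, 0.4))
    )
  })

  set <- align_matched_set(
    expression_matrix(mir, "miRNA"),
    expression_matrix(lnc, "lncRNA"),
    expression_matrix(mrna, "mRNA"),
    clinical
  )
  list(
    set = set,
    mirna_mrna = cat_mrna,
    mirna_lncrna = cat_lnc,
    truth = list(
      planted_triplets = planted,
      planted_cox_coefficients = spec$planted_cox_coefficients,
      stage_assignments = stats::setNames(clinical$stage, clinical$sample_id)
    )
  )
}

#' Write a synthetic cohort to disk in pipeline input formats
#'
#' Writes the three expression TSVs, the two interaction edge lists, the
#' clinical TSV and a `ground_truth.json` into `dir`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$set$mirna, file.path(dir, "mirna.tsv"))
  write_expression_matrix(cohort$set$lncrna, file.path(dir, "lncrna.tsv"))
  write_expression_matrix(cohort$set$mrna, file.path(dir, "mrna.tsv"))
  write_interactions(cohort$mirna_mrna, file.path(dir, "mirna_mrna.tsv"))
  write_interactions(cohort$mirna_lncrna, file.path(dir, "mirna_lncrna.tsv"))
  write_clinical(cohort$set$clinical, file.path(dir, "clinical.tsv"))
  truth <- cohort$truth
  truth$planted_triplets <- purrr::pmap(truth$planted_triplets, function(lncrna_id, mrna_id, shared_mirnas) {
    list(lncrna_id = lncrna_id, mrna_id = mrna_id, shared_mirnas = shared_mirnas)
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Deterministic small test graphs
#'
#' Fixture graphs with known topology, used to exercise the network
#' statistics, randomization and module-mining code:
#' \describe{
#'   \item{`clique5_plus_3_singletons`}{A 5-clique plus 3 isolated nodes
#'     (8 nodes, 10 edges).}
#'   \item{`ring_lattice_20_k4`}{Ring lattice on 20 nodes, each connected to
#'     its 2 nearest neighbors on both sides (degree 4, 40 edges).}
#'   \item{`er_fixed_12`}{A fixed (deterministically seeded) Erdos-Renyi-like
#'     graph on 12 nodes with 18 edges.}
#'   \item{`barbell`}{Two 4-cliques joined through a single bridge node
#'     (9 nodes, 14 edges).}
#'   \item{`cycle4`}{The 4-cycle (4 nodes, 4 edges, no triangles).}
#' }
#'
#' @param name Fixture name.
#' @return A `cerna_network` with node class `"other"`.
#' @export
toy_graph <- function(name) {
  fixtures <- c("clique5_plus_3_singletons", "ring_lattice_20_k4",
                "er_fixed_12", "barbell", "cycle4")
  if (!name %in% fixtures) {
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "), call. = FALSE)
  }
  ed <- switch(
    name,
    clique5_plus_3_singletons = {
      list(nodes = sprintf("v%d", 1:8),
           edges = t(utils::combn(sprintf("v%d", 1:5), 2)))
    },
    ring_lattice_20_k4 = {
      nodes <- sprintf("v%02d", 1:20)
      e <- purrr::map_dfr(1:20, function(i) {
        tibble::tibble(a = i, b = c(i %% 20 + 1, (i + 1) %% 20 + 1))
      })
      list(nodes = nodes, edges = cbind(nodes[e$a], nodes[e$b]))
    },
    er_fixed_12 = {
      nodes <- sprintf("v%02d", 1:12)
      pairs <- withr::with_seed(42L, {
        all <- t(utils::combn(12, 2))
        all[sample.int(nrow(all), 18), ]
      })
      list(nodes = nodes, edges = cbind(nodes[pairs[, 1]], nodes[pairs[, 2]]))
    },
    barbell = {
      a <- sprintf("a%d", 1:4); b <- sprintf("b%d", 1:4)
      e <- rbind(t(utils::combn(a, 2)), t(utils::combn(b, 2)),
                 c("a1", "br"), c("br", "b1"))
      list(nodes = c(a, b, "br"), edges = e)
    },
    cycle4 = {
      nodes <- sprintf("v%d", 1:4)
      list(nodes = nodes,
           edges = rbind(c("v1", "v2"), c("v2", "v3"), c("v3", "v4"), c("v1", "v4")))
    }
  )
  cerna_network(
    nodes = tibble::tibble(id = ed$nodes, class = "other"),
    edges = tibble::tibble(from = ed$edges[, 1], to = ed$edges[, 2]),
    condition = name
  )
}
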