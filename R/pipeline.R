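pipeline_schema <- list(
  seed = NULL,
  inputs = c("mirna", "lncrna", "mrna", "clinical", "mirna_mrna",
             "mirna_lncrna", "gene_sets"),
  simulate = c("n_samples", "n_mirna", "n_lncrna", "n_mrna",
               "n_planted_triplets", "shared_mirnas_per_triplet",
               "coupling_strength", "noise_sd", "stage_proportions",
               "planted_cox_coefficients", "baseline_hazard", "censoring_rate",
               "n_decoy_mrna", "n_decoy_lncrna"),
  infer = c("percentile", "threshold", "min_shared", "rule", "cerna_edges", "by"),
  topology = c("replicates", "metrics", "n_swap_multiples", "respect_classes"),
  hubs = c("fraction"),
  modules = c("degree_cutoff", "node_score_cutoff", "max_depth", "haircut",
              "fluff"),
  prognosis = c("signature", "covariates", "roc_time", "rate_times",
                "stratify_by", "stratify_split")
)

#' Read and validate a pipeline configuration
#'
#' Loads a YAML configuration describing either file inputs (`inputs:`) or a
#' synthetic cohort (`simulate:`) plus per-stage tunables, and validates it
#' against the known schema before any computation; unknown keys are
#' rejected.
#'
#' @param path Path to the YAML file, or a pre-parsed list.
#' @return A validated `pipeline_config` list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), names(pipeline_schema))
  if (length(unknown) > 0) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (sec in intersect(names(cfg), names(pipeline_schema))) {
    allowed <- pipeline_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad) > 0) {
      stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(cfg$inputs) && is.null(cfg$simulate)) {
    stop("config needs either an 'inputs' or a 'simulate' section", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "pipeline_config")
}

# documented per-stage seed derivation from the single pipeline seed
stage_seed <- function(seed, stage) {
  seed + c(simulate = 0L, topology = 1000L, randomize = 2000L)[[stage]]
}

#' Run the full ceRNA analysis pipeline
#'
#' Executes inference, topology with randomization, hub/module/enrichment
#' analysis and (when survival data and a signature are available) the
#' prognosis stage, writing all intermediate tables under `out_dir`. Every
#' run writes `run_info.json` with the config hash and seed; reruns with the
#' same config are bit-identical for the deterministic stages.
#'
#' @param config A `pipeline_config` (or path to one).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the main in-memory results: `network`,
#'   `topology`, `randomization`, `hubs`, `modules`, `enrichment`,
#'   `condition_networks`, `prognosis`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(sim_args$stage_proportions)) {
      sim_args$stage_proportions <- unlist(sim_args$stage_proportions)
    }
    if (!is.null(sim_args$planted_cox_coefficients)) {
      sim_args$planted_cox_coefficients <- unlist(sim_args$planted_cox_coefficients)
    }
    spec <- do.call(synthetic_spec, c(sim_args, list(seed = stage_seed(seed, "simulate"))))
    cohort <- generate_cohort(spec)
    set <- cohort$set
    mrna_cat <- cohort$mirna_mrna
    lncrna_cat <- cohort$mirna_lncrna
    gene_sets <- NULL
  } else {
    ins <- config$inputs
    set <- align_matched_set(
      read_expression_matrix(ins$mirna, "miRNA"),
      read_expression_matrix(ins$lncrna, "lncRNA"),
      read_expression_matrix(ins$mrna, "mRNA"),
      read_clinical(ins$clinical)
    )
    mrna_cat <- read_interactions(ins$mirna_mrna, "mRNA")
    lncrna_cat <- read_interactions(ins$mirna_lncrna, "lncRNA")
    gene_sets <- if (!is.null(ins$gene_sets)) read_gene_sets(ins$gene_sets) else NULL
  }

  icfg <- config$infer %||% list()
  inf <- infer_cerna_network(
    set, mrna_cat, lncrna_cat,
    percentile = icfg$percentile %||% 99,
    threshold = icfg$threshold,
    min_shared = icfg$min_shared %||% 1L,
    rule = icfg$rule %||% "p05",
    cerna_edges = isTRUE(icfg$cerna_edges)
  )
  write_triplets(inf$candidates, file.path(out_dir, "candidate_triplets.tsv"))
  write_triplets(inf$functional, file.path(out_dir, "functional_triplets.tsv"))
  write_network(inf$network, file.path(out_dir, "network_edges.tsv"),
                file.path(out_dir, "network_nodes.tsv"))

  cond_nets <- NULL
  if (!is.null(icfg$by)) {
    cond_nets <- condition_specific_networks(
      set, mrna_cat, lncrna_cat, group_by = icfg$by,
      percentile = icfg$percentile %||% 99, threshold = icfg$threshold,
      min_shared = icfg$min_shared %||% 1L, rule = icfg$rule %||% "p05",
      cerna_edges = isTRUE(icfg$cerna_edges))
    for (cn in names(cond_nets)) {
      write_network(cond_nets[[cn]],
                    file.path(out_dir, paste0("network_", cn, "_edges.tsv")),
                    file.path(out_dir, paste0("network_", cn, "_nodes.tsv")))
    }
  }

  tcfg <- config$topology %||% list()
  rand <- NULL
  topo <- NULL
  if (nrow(inf$network$edges) >= 2) {
    rand <- randomization_test(
      inf$network, metrics = tcfg$metrics %||% c("CC", "CPL"),
      replicates = tcfg$replicates %||% 1000,
      seed = stage_seed(seed, "randomize"),
      n_swap_multiples = tcfg$n_swap_multiples %||% 10,
      respect_classes = tcfg$respect_classes %||% TRUE)
    topo <- topology_summary(inf$network, randomization = rand)
    utils::write.table(topo, file.path(out_dir, "topology_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      dplyr::select(rand, -"null_values"),
      file.path(out_dir, "randomization.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  hubs <- NULL; modules <- NULL; enrichment <- NULL
  if (nrow(inf$network$nodes) > 0) {
    hubs <- identify_hubs(inf$network, fraction = (config$hubs %||% list())$fraction %||% 0.05)
    utils::write.table(tidy(hubs), file.path(out_dir, "hubs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mcfg <- config$modules %||% list()
    modules <- mcode_modules(
      inf$network,
      degree_cutoff = mcfg$degree_cutoff %||% 2,
      node_score_cutoff = mcfg$node_score_cutoff %||% 0.2,
      max_depth = mcfg$max_depth %||% 100,
      haircut = mcfg$haircut %||% TRUE, fluff = isTRUE(mcfg$fluff))
    mod_out <- modules
    mod_out$members <- vapply(mod_out$members, paste, character(1), collapse = ",")
    utils::write.table(mod_out, file.path(out_dir, "modules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(gene_sets) && nrow(gene_sets) > 0) {
      enrichment <- enrich_gene_sets(tidy(hubs)$id, gene_sets,
                                     universe = inf$network$nodes$id,
                                     adjust = "BH")
      utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  prog <- NULL
  pcfg <- config$prognosis %||% list()
  signature <- pcfg$signature
  if (is.null(signature) && !is.null(hubs)) signature <- hub_ids(hubs, "lncRNA")
  signature <- intersect(unlist(signature), rownames(set$lncrna))
  if (length(signature) >= 1 && sum(set$clinical$event) >= 2) {
    model <- fit_risk_model(set$lncrna, set$clinical, signature_ids = signature,
                            covariates = pcfg$covariates)
    scores <- risk_scores(model, set$lncrna)
    groups <- dichotomize(scores, cutoff = model$cutoff)
    surv <- km_logrank(groups, set$clinical,
                       rate_times = pcfg$rate_times %||% 60)
    roc <- time_dependent_roc(scores, set$clinical,
                              eval_time = pcfg$roc_time %||% 60)
    ctab <- cox_table(set$clinical, groups)
    utils::write.table(groups, file.path(out_dir, "risk_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(surv$curves, file.path(out_dir, "km_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ctab, file.path(out_dir, "cox_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(roc$points, file.path(out_dir, "roc_points.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    strat <- NULL
    if (!is.null(pcfg$stratify_by)) {
      strat <- stratified_analysis(scores, set$clinical,
                                   stratify_by = pcfg$stratify_by,
                                   split = pcfg$stratify_split,
                                   cutoff = model$cutoff)
    }
    prog <- list(model = model, scores = scores, groups = groups,
                 survival = surv, roc = roc, cox_table = ctab,
                 stratified = strat)
  }

  jsonlite::write_json(
    list(config_hash = digest::digest(unclass(config)), seed = seed,
         stages = c("infer", "topology", "hubs", "modules",
                    if (!is.null(enrichment)) "enrichment",
                    if (!is.null(prog)) "prognosis")),
    file.path(out_dir, "run_info.json"), auto_unbox = TRUE)

  invisible(list(set = set, inference = inf, network = inf$network,
                 topology = topo, randomization = rand, hubs = hubs,
                 modules = modules, enrichment = enrichment,
                 condition_networks = cond_nets, prognosis = prog))
}
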