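#' Fit a lncRNA risk-score model by Cox regression
#'
#' Fits a multivariate Cox proportional-hazards model of overall survival on
#' the expression of the signature lncRNAs (optionally adjusting for clinical
#' covariates), and stores the lncRNA coefficients as the risk-score weights.
#' The risk-score cutoff is set to the median training risk score.
#'
#' @param expr An `expr_matrix` (lncRNA class) containing the signature rows.
#' @param clinical Clinical tibble with `sample_id`, `os_months`, `event`.
#' @param signature_ids LncRNA ids forming the signature; default all rows of
#'   `expr`.
#' @param covariates Optional clinical column names to adjust for.
#' @param ties Tie handling for the partial likelihood: `"breslow"` (default)
#'   or `"efron"`.
#' @return A `risk_model`: list with `lncrna_ids`, `coefficients`, `cutoff`,
#'   `fit` (the `coxph` object) and `training` summary.
#' @export
fit_risk_model <- function(expr, clinical, signature_ids = NULL,
                           covariates = NULL, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(inherits(expr, "expr_matrix"))
  clinical <- validate_clinical(clinical)
  if (is.null(signature_ids)) signature_ids <- rownames(expr)
  missing <- setdiff(signature_ids, rownames(expr))
  if (length(missing) > 0) {
    stop("signature lncRNA(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  shared <- intersect(colnames(expr), clinical$sample_id)
  clin <- clinical[match(shared, clinical$sample_id), ]
  if (sum(clin$event) < 2) stop("need at least 2 events to fit", call. = FALSE)
  x <- t(unclass(expr)[signature_ids, shared, drop = FALSE])
  safe <- make.names(signature_ids)
  colnames(x) <- safe
  df <- data.frame(os_months = clin$os_months, event = clin$event, x,
                   check.names = FALSE)
  if (!is.null(covariates)) df <- cbind(df, clin[, covariates, drop = FALSE])
  form <- stats::as.formula(paste(
    "survival::Surv(os_months, event) ~",
    paste(c(safe, covariates), collapse = " + ")))
  fit <- survival::coxph(form, data = df, ties = ties)
  if (!is.null(fit$info) || any(is.na(stats::coef(fit)[safe]))) {
    stop("Cox fit did not converge or produced undefined coefficients",
         call. = FALSE)
  }
  coefs <- stats::setNames(stats::coef(fit)[safe], signature_ids)
  model <- structure(
    list(lncrna_ids = signature_ids, coefficients = coefs, cutoff = NA_real_,
         fit = fit, ties = ties,
         training = list(n = length(shared), n_events = sum(clin$event))),
    class = "risk_model"
  )
  model$cutoff <- stats::median(risk_scores(model, expr)$score[
    match(shared, risk_scores(model, expr)$sample_id)])
  model
}

#' Build a risk model from fixed coefficients
#'
#' Wraps externally supplied Cox coefficients (e.g. published signature
#' weights) as a `risk_model` without refitting; the cutoff may be given or
#' computed later from scores.
#'
#' @param coefficients Named numeric vector (names = lncRNA ids).
#' @param cutoff Risk-score cutoff (default `NA`, set from a cohort median
#'   via [dichotomize()]).
#' @return A `risk_model`.
#' @export
risk_model_from_coefficients <- function(coefficients, cutoff = NA_real_) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  structure(
    list(lncrna_ids = names(coefficients), coefficients = coefficients,
         cutoff = cutoff, fit = NULL, ties = NA_character_, training = NULL),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %d lncRNAs, cutoff = %s\n", length(x$lncrna_ids),
              format(x$cutoff, digits = 4)))
  invisible(x)
}

#' Coefficients of a risk model
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return Tibble with `lncrna_id`, `coefficient`, and `HR` (exp coefficient).
#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) {
  tibble::tibble(lncrna_id = x$lncrna_ids,
                 coefficient = unname(x$coefficients),
                 HR = exp(unname(x$coefficients)))
}

#' One-row summary of a risk model
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return Tibble with `n_lncrna`, `cutoff`, training `n` and `n_events`.
#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(n_lncrna = length(x$lncrna_ids), cutoff = x$cutoff,
                 n = x$training$n %||% NA_integer_,
                 n_events = x$training$n_events %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample risk scores
#'
#' The risk score of sample s is the linear combination
#' `sum_i W_i * Exp_i(s)` of signature-lncRNA expression weighted by the Cox
#' coefficients.
#'
#' @param model A `risk_model`.
#' @param expr An `expr_matrix` containing every signature lncRNA.
#' @return Tibble with `sample_id`, `score`.
#' @export
risk_scores <- function(model, expr) {
  stopifnot(inherits(model, "risk_model"))
  missing <- setdiff(model$lncrna_ids, rownames(expr))
  if (length(missing) > 0) {
    stop("expression matrix lacks signature lncRNA(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sc <- drop(model$coefficients %*% unclass(expr)[model$lncrna_ids, , drop = FALSE])
  tibble::tibble(sample_id = colnames(expr), score = unname(sc))
}

#' Dichotomize risk scores into high- and low-risk groups
#'
#' Scores strictly above the cutoff are `"high"`, scores at or below it are
#' `"low"` (so with the cohort median and an odd number of distinct scores
#' the low group is the larger one). `cutoff = "median"` uses the cohort
#' median (even n: mean of the central pair).
#'
#' @param scores Tibble with `sample_id`, `score` (from [risk_scores()]).
#' @param cutoff A number, or `"median"` (default).
#' @return Tibble with `sample_id`, `score`, `group` (factor low/high);
#'   the cutoff used is attached as attribute `"cutoff"`.
#' @export
dichotomize <- function(scores, cutoff = "median") {
  if (nrow(scores) < 2) stop("need at least 2 samples", call. = FALSE)
  if (identical(cutoff, "median")) cutoff <- stats::median(scores$score)
  if (length(unique(scores$score)) == 1) {
    stop("all risk scores identical: degenerate split", call. = FALSE)
  }
  out <- dplyr::mutate(scores, group = factor(
    ifelse(.data$score > cutoff, "high", "low"), levels = c("low", "high")))
  attr(out, "cutoff") <- cutoff
  out
}

#' Kaplan-Meier curves and log-rank comparison between groups
#'
#' Product-limit survival estimate per group, median overall survival
#' (earliest time the estimate drops to 0.5 or below), the two-sided log-rank
#' test, survival rates at requested times, and the between-group hazard
#' ratio with Wald 95% CI from a one-covariate Cox model.
#'
#' @param groups Tibble with `sample_id`, `group` (e.g. from
#'   [dichotomize()]).
#' @param clinical Clinical tibble.
#' @param rate_times Times (months) at which to report survival rates
#'   (default 60, the 5-year rate).
#' @return A `survival_comparison`: list with `curves` (tibble: `group`,
#'   `time`, `surv`, `n_risk`, `n_event`), `medians`, `rates`, `logrank`
#'   (`chisq`, `df`, `p`), `hazard_ratio` (`HR`, `lower`, `upper`, `p`), and
#'   `n` per group.
#' @export
km_logrank <- function(groups, clinical, rate_times = 60) {
  clinical <- validate_clinical(clinical)
  df <- dplyr::inner_join(groups, clinical, by = "sample_id")
  if (nrow(df) == 0) stop("no samples shared between groups and clinical", call. = FALSE)
  df$group <- droplevels(factor(df$group))
  if (nlevels(df$group) < 2) stop("need at least 2 groups", call. = FALSE)
  ev <- tapply(df$event, df$group, sum)
  if (any(ev == 0)) {
    warning("group(s) without events: ", paste(names(ev)[ev == 0], collapse = ", "),
            call. = FALSE)
  }
  sf <- survival::survfit(survival::Surv(os_months, event) ~ group, data = df)
  strata_grp <- rep(sub("^group=", "", names(sf$strata)), sf$strata)
  curves <- tibble::tibble(group = strata_grp, time = sf$time, surv = sf$surv,
                           n_risk = sf$n.risk, n_event = sf$n.event)
  medians <- curves |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(median_os = if (any(.data$surv <= 0.5))
      min(.data$time[.data$surv <= 0.5]) else NA_real_, .groups = "drop")
  rates <- purrr::map_dfr(rate_times, function(t0) {
    curves |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(rate = if (any(.data$time <= t0))
                         .data$surv[max(which(.data$time <= t0))] else 1,
                       .groups = "drop") |>
      dplyr::mutate(time = t0, .before = "rate")
  })
  sd_ <- survival::survdiff(survival::Surv(os_months, event) ~ group, data = df)
  p <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1, lower.tail = FALSE)
  hr <- NULL
  if (nlevels(df$group) == 2) {
    cx <- suppressWarnings(
      survival::coxph(survival::Surv(os_months, event) ~ group, data = df))
    s <- summary(cx)
    hr <- tibble::tibble(HR = unname(s$conf.int[1, "exp(coef)"]),
                         lower = unname(s$conf.int[1, "lower .95"]),
                         upper = unname(s$conf.int[1, "upper .95"]),
                         p = unname(s$coefficients[1, "Pr(>|z|)"]))
  }
  structure(
    list(curves = curves, medians = medians, rates = rates,
         logrank = tibble::tibble(chisq = sd_$chisq, df = length(sd_$n) - 1, p = p),
         hazard_ratio = hr,
         n = dplyr::count(df, .data$group, name = "n")),
    class = "survival_comparison"
  )
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat("<survival_comparison>\n")
  med <- dplyr::left_join(x$n, x$medians, by = "group")
  for (i in seq_len(nrow(med))) {
    cat(sprintf("  %s: n=%d, median OS=%s months\n", med$group[i], med$n[i],
                format(med$median_os[i], digits = 4)))
  }
  cat(sprintf("  log-rank chisq=%.3f (df=%d), p=%.3g\n",
              x$logrank$chisq, x$logrank$df, x$logrank$p))
  invisible(x)
}

#' Summary of a survival comparison
#' @param x A `survival_comparison`.
#' @param ... Unused.
#' @return One-row tibble: log-rank statistic/p plus hazard ratio and CI when
#'   two groups were compared.
#' @method glance survival_comparison
#' @export
glance.survival_comparison <- function(x, ...) {
  out <- x$logrank
  if (!is.null(x$hazard_ratio)) {
    out <- dplyr::bind_cols(out, dplyr::rename(x$hazard_ratio, hr_p = "p"))
  }
  out
}

#' KM curve points of a survival comparison
#' @param x A `survival_comparison`.
#' @param ... Unused.
#' @return The curves tibble.
#' @method tidy survival_comparison
#' @export
tidy.survival_comparison <- function(x, ...) x$curves

#' Univariate and multivariate Cox regression tables
#'
#' Fits one univariate Cox model per covariate (including the risk score or
#' risk group) and one joint multivariate model, reporting hazard ratios,
#' Wald 95% confidence intervals and p-values. Categorical covariates use
#' stated reference levels (stage II, grade G1/G2, residual 0-10mm, risk
#' group low). Samples with missing values are dropped per fit.
#'
#' @param clinical Clinical tibble.
#' @param risk Tibble with `sample_id` and either `score` (continuous) or
#'   `group`.
#' @param covariates Clinical columns to include (default
#'   `c("age", "stage", "grade", "residual")`, intersected with available
#'   columns).
#' @return Tibble: `block` (univariate/multivariate), `term`, `HR`, `lower`,
#'   `upper`, `p`, `n`.
#' @export
cox_table <- function(clinical, risk,
                      covariates = c("age", "stage", "grade", "residual")) {
  clinical <- validate_clinical(clinical)
  covariates <- intersect(covariates, names(clinical))
  df <- dplyr::inner_join(clinical, risk, by = "sample_id")
  risk_term <- if ("score" %in% names(risk)) "score" else "group"
  if (risk_term == "group") df$group <- factor(df$group, levels = c("low", "high"))
  if ("stage" %in% covariates) df$stage <- stats::relevel(factor(df$stage), ref = "II")
  if ("grade" %in% covariates) df$grade <- stats::relevel(factor(df$grade), ref = "G1/G2")
  if ("residual" %in% covariates) df$residual <- stats::relevel(factor(df$residual), ref = "0-10mm")
  terms <- c(risk_term, covariates)
  fit_block <- function(vars, block) {
    form <- stats::as.formula(paste("survival::Surv(os_months, event) ~",
                                    paste(vars, collapse = " + ")))
    fit <- tryCatch(survival::coxph(form, data = df),
                    error = function(e) NULL, warning = function(w) {
                      suppressWarnings(survival::coxph(form, data = df))
                    })
    if (is.null(fit)) {
      return(tibble::tibble(block = block, term = paste(vars, collapse = "+"),
                            HR = NA_real_, lower = NA_real_, upper = NA_real_,
                            p = NA_real_, n = NA_integer_, note = "fit failed"))
    }
    s <- summary(fit)
    tibble::tibble(block = block, term = rownames(s$coefficients),
                   HR = unname(s$conf.int[, "exp(coef)"]),
                   lower = unname(s$conf.int[, "lower .95"]),
                   upper = unname(s$conf.int[, "upper .95"]),
                   p = unname(s$coefficients[, "Pr(>|z|)"]),
                   n = s$n, note = NA_character_)
  }
  uni <- purrr::map_dfr(terms, function(v) fit_block(v, "univariate"))
  multi <- fit_block(terms, "multivariate")
  dplyr::bind_rows(uni, multi)
}

# product-limit survival estimate at one time point
km_at <- function(time, event, t0) {
  ut <- sort(unique(time[event == 1 & time <= t0]))
  s <- 1
  for (t in ut) {
    d <- sum(time == t & event == 1)
    r <- sum(time >= t)
    s <- s * (1 - d / r)
  }
  s
}

#' Time-dependent ROC curve for a censored survival outcome
#'
#' Cumulative-cases / dynamic-controls ROC at `eval_time`: for each score
#' threshold c, sensitivity and specificity are estimated from within-group
#' Kaplan-Meier survival via Bayes' rule,
#' `sens = (1 - S(t | X > c)) P(X > c) / (1 - S(t))` and
#' `spec = S(t | X <= c) P(X <= c) / S(t)`. The AUC is the trapezoidal area
#' under sensitivity versus 1 - specificity.
#'
#' @param scores Tibble with `sample_id`, `score`.
#' @param clinical Clinical tibble.
#' @param eval_time Evaluation time in months (default 60).
#' @return A `td_roc`: list with `auc`, `eval_time`, and `points` (tibble
#'   `threshold`, `sensitivity`, `specificity`).
#' @export
time_dependent_roc <- function(scores, clinical, eval_time = 60) {
  clinical <- validate_clinical(clinical)
  df <- dplyr::inner_join(scores, clinical, by = "sample_id")
  if (eval_time <= 0 || eval_time > max(df$os_months)) {
    stop("eval_time must lie within observed follow-up", call. = FALSE)
  }
  s_all <- km_at(df$os_months, df$event, eval_time)
  if (s_all >= 1) stop("no cases by eval_time", call. = FALSE)
  if (s_all <= 0) stop("no controls by eval_time", call. = FALSE)
  cuts <- sort(unique(df$score))
  thresholds <- c(-Inf, cuts)
  pts <- purrr::map_dfr(thresholds, function(cc) {
    above <- df$score > cc
    p_above <- mean(above)
    s_above <- if (any(above)) km_at(df$os_months[above], df$event[above], eval_time) else 1
    s_below <- if (any(!above)) km_at(df$os_months[!above], df$event[!above], eval_time) else 1
    sens <- (1 - s_above) * p_above / (1 - s_all)
    spec <- s_below * (1 - p_above) / s_all
    tibble::tibble(threshold = cc,
                   sensitivity = min(max(sens, 0), 1),
                   specificity = min(max(spec, 0), 1))
  })
  ord <- order(pts$threshold, decreasing = TRUE)  # natural ROC path
  fpr <- (1 - pts$specificity)[ord]
  tpr <- pts$sensitivity[ord]
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(auc = auc, eval_time = eval_time, points = pts),
            class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("<td_roc> AUC = %.3f at t = %g months\n", x$auc, x$eval_time))
  invisible(x)
}

#' ROC points of a time-dependent ROC
#' @param x A `td_roc`.
#' @param ... Unused.
#' @return The points tibble.
#' @method tidy td_roc
#' @export
tidy.td_roc <- function(x, ...) x$points

#' AUC summary of a time-dependent ROC
#' @param x A `td_roc`.
#' @param ... Unused.
#' @return One-row tibble with `auc`, `eval_time`.
#' @method glance td_roc
#' @export
glance.td_roc <- function(x, ...) tibble::tibble(auc = x$auc, eval_time = x$eval_time)

#' Stratified survival analysis of a risk score
#'
#' Splits the cohort into strata by a clinical field (numeric fields by a
#' cutpoint, categorical fields by explicit level groupings), then within
#' each stratum dichotomizes scores at the global cutoff and runs the
#' KM / log-rank comparison. Strata with fewer than 2 samples or fewer than
#' 2 score groups are skipped with a warning.
#'
#' @param scores Tibble with `sample_id`, `score`.
#' @param clinical Clinical tibble.
#' @param stratify_by Clinical column name.
#' @param split For numeric fields, a single cutpoint (strata `<=` and `>`);
#'   for categorical fields, a named list mapping stratum label to the levels
#'   it contains (default: one stratum per level).
#' @param cutoff Global risk-score cutoff (default the cohort median).
#' @param rate_times Passed to [km_logrank()].
#' @return Named list of `survival_comparison` objects, one per stratum.
#' @export
stratified_analysis <- function(scores, clinical, stratify_by, split = NULL,
                                cutoff = "median", rate_times = 60) {
  clinical <- validate_clinical(clinical)
  if (!stratify_by %in% names(clinical)) {
    stop("clinical field '", stratify_by, "' not found", call. = FALSE)
  }
  if (identical(cutoff, "median")) cutoff <- stats::median(scores$score)
  vals <- clinical[[stratify_by]]
  strata <- if (is.numeric(vals) && is.numeric(split)) {
    lab <- ifelse(vals <= split, paste0(stratify_by, "<=", split),
                  paste0(stratify_by, ">", split))
    split(clinical$sample_id, lab)
  } else if (is.list(split)) {
    purrr::map(split, function(lv) clinical$sample_id[vals %in% lv])
  } else {
    split(clinical$sample_id, vals)
  }
  out <- list()
  for (snm in names(strata)) {
    ids <- strata[[snm]]
    if (length(ids) < 2) {
      warning("stratum '", snm, "' has fewer than 2 samples; skipped", call. = FALSE)
      next
    }
    sc <- scores[scores$sample_id %in% ids, ]
    grp <- tryCatch(dichotomize(sc, cutoff = cutoff), error = function(e) NULL)
    if (is.null(grp) || nlevels(droplevels(grp$group)) < 2) {
      warning("stratum '", snm, "' has a degenerate score split; skipped",
              call. = FALSE)
      next
    }
    out[[snm]] <- km_logrank(grp, clinical[clinical$sample_id %in% ids, ],
                             rate_times = rate_times)
  }
  out
}

#' Two-group patient split by hierarchical clustering of signature expression
#'
#' Agglomerative clustering of samples on per-gene z-scored expression
#' (Euclidean distance, complete linkage by default); the dendrogram is cut
#' at its first bifurcation, yielding exactly two nonempty groups.
#'
#' @param expr An `expr_matrix` restricted to the signature lncRNAs.
#' @param method Linkage method for [stats::hclust()] (default
#'   `"complete"`).
#' @param scale_rows Z-score each gene before clustering (default `TRUE`).
#' @return Tibble with `sample_id`, `cluster` (factor `"1"`/`"2"`); the
#'   `hclust` object is attached as attribute `"hclust"`.
#' @export
cluster_split <- function(expr, method = "complete", scale_rows = TRUE) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (ncol(expr) < 2) stop("need at least 2 samples to cluster", call. = FALSE)
  m <- unclass(expr)
  if (scale_rows) {
    sds <- apply(m, 1, stats::sd)
    m <- (m - rowMeans(m)) / ifelse(sds == 0, 1, sds)
  }
  hc <- stats::hclust(stats::dist(t(m)), method = method)
  cl <- stats::cutree(hc, k = 2)
  out <- tibble::tibble(sample_id = colnames(expr),
                        cluster = factor(cl[colnames(expr)]))
  attr(out, "hclust") <- hc
  out
}
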