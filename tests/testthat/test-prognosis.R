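test_that("risk scores are the exact linear combination of expression", {
  coefs <- c(l1 = 0.5, l2 = -2)
  model <- risk_model_from_coefficients(coefs)
  m <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("l1", "l2"), c("s1", "s2")))
  expr <- expression_matrix(m, "lncRNA")
  sc <- risk_scores(model, expr)
  expect_equal(sc$score, c(0.5 * 1 - 2 * 2, 0.5 * 3 - 2 * 4))

  # all-zero coefficients give all-zero scores
  z <- risk_model_from_coefficients(c(l1 = 0, l2 = 0))
  expect_equal(risk_scores(z, expr)$score, c(0, 0))

  # doubling one expression value moves the score by exactly W_i * Exp_i
  m2 <- m; m2["l1", "s1"] <- 2 * m["l1", "s1"]
  sc2 <- risk_scores(model, expression_matrix(m2, "lncRNA"))
  expect_equal(sc2$score[1] - sc$score[1], 0.5 * 1)

  expect_error(risk_scores(model, expression_matrix(
    matrix(1, 1, 1, dimnames = list("l1", "s1")), "lncRNA")), "l2")
})

test_that("the packaged example signature reproduces its coefficient sum on unit expression", {
  path <- system.file("extdata", "example_signature.tsv", package = "cernet")
  tab <- utils::read.delim(path)
  coefs <- stats::setNames(tab$coefficient, tab$lncrna_id)
  model <- risk_model_from_coefficients(coefs)
  ones <- expression_matrix(
    matrix(1, nrow = length(coefs), ncol = 1,
           dimnames = list(names(coefs), "s1")), "lncRNA")
  expect_equal(risk_scores(model, ones)$score, sum(tab$coefficient))
  expect_equal(risk_scores(model, ones)$score, -2.717428818, tolerance = 1e-9)
})

test_that("median dichotomization splits strictly-above vs at-or-below", {
  sc <- tibble::tibble(sample_id = paste0("s", 1:4), score = c(1, 2, 3, 4))
  gr <- dichotomize(sc)
  expect_equal(as.character(gr$group), c("low", "low", "high", "high"))

  # 401 distinct scores -> 200 high / 201 low at the median
  sc401 <- tibble::tibble(sample_id = sprintf("s%03d", 1:401),
                          score = sample(seq_len(401)))
  g401 <- dichotomize(sc401)
  expect_equal(sum(g401$group == "high"), 200)
  expect_equal(sum(g401$group == "low"), 201)

  # cutoff above the maximum -> everyone low
  all_low <- dichotomize(sc, cutoff = 99)
  expect_true(all(all_low$group == "low"))
  expect_error(dichotomize(tibble::tibble(sample_id = c("a", "b"),
                                          score = c(1, 1))), "degenerate")
  # invariance under a strictly increasing transform of scores and cutoff
  gr2 <- dichotomize(dplyr::mutate(sc, score = exp(score)),
                     cutoff = exp(attr(gr, "cutoff")))
  expect_equal(gr2$group, gr$group)
})

test_that("KM estimator and log-rank match a hand-computed 8-subject life table", {
  clin <- tibble::tibble(
    sample_id = paste0("p", 1:8),
    os_months = c(5, 10, 15, 20, 8, 12, 18, 25),
    event = c(1L, 1L, 0L, 1L, 0L, 1L, 1L, 1L))
  grp <- tibble::tibble(sample_id = paste0("p", 1:8),
                        group = rep(c("A", "B"), each = 4))
  res <- km_logrank(grp, clin, rate_times = 12)

  # product-limit estimates computed longhand
  a <- res$curves[res$curves$group == "A", ]
  expect_equal(a$surv[a$time == 5], 3 / 4)
  expect_equal(a$surv[a$time == 10], 3 / 4 * 2 / 3)
  expect_equal(a$surv[a$time == 20], 0)
  b <- res$curves[res$curves$group == "B", ]
  expect_equal(b$surv[b$time == 12], 2 / 3)
  expect_equal(b$surv[b$time == 18], 1 / 3)

  expect_equal(res$medians$median_os[res$medians$group == "A"], 10)
  expect_equal(res$medians$median_os[res$medians$group == "B"], 18)

  # log-rank by observed-vs-expected arithmetic:
  # E_A = 1/2+1/2+2/5+1/3+1/2, V = 1/4+1/4+6/25+2/9+1/4
  e_a <- 0.5 + 0.5 + 0.4 + 1 / 3 + 0.5
  v <- 0.25 + 0.25 + 0.24 + 2 / 9 + 0.25
  chisq <- (3 - e_a)^2 / v
  expect_equal(res$logrank$chisq, chisq, tolerance = 1e-10)
  expect_equal(res$logrank$p, stats::pchisq(chisq, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # 12-month survival rates from the curves
  expect_equal(res$rates$rate[res$rates$group == "A" & res$rates$time == 12],
               1 / 2)
})

test_that("KM reduces to closed forms in degenerate designs", {
  # identical groups -> chisq 0, p 1
  clin <- mk_clinical(paste0("s", 1:8), os = rep(c(3, 6, 9, 12), 2),
                      event = rep(1L, 8))
  grp <- tibble::tibble(sample_id = paste0("s", 1:8),
                        group = rep(c("A", "B"), each = 4))
  clin$os_months <- c(3, 6, 9, 12, 3, 6, 9, 12)
  res <- km_logrank(grp, clin)
  expect_equal(res$logrank$chisq, 0, tolerance = 1e-12)
  expect_equal(res$logrank$p, 1)

  # no censoring, A all die at 1 and B at 2
  clin2 <- mk_clinical(paste0("s", 1:8), os = rep(c(1, 2), each = 4),
                       event = rep(1L, 8))
  res2 <- km_logrank(grp, clin2)
  expect_equal(res2$medians$median_os, c(1, 2))
  expect_equal(res2$curves$surv[res2$curves$group == "A"], 0)

  # without censoring the KM curve is the empirical survival function
  set.seed(51)
  t3 <- round(rexp(30, 0.1), 3)
  clin3 <- mk_clinical(sprintf("s%02d", 1:30), os = t3, event = rep(1L, 30))
  grp3 <- tibble::tibble(sample_id = sprintf("s%02d", 1:30), group = "A")
  grp3 <- dplyr::bind_rows(grp3, tibble::tibble(sample_id = "extra", group = "B"))
  clin3 <- dplyr::bind_rows(clin3, tibble::tibble(sample_id = "extra",
                                                  os_months = 1, event = 1L))
  res3 <- km_logrank(grp3, clin3)
  ca <- res3$curves[res3$curves$group == "A", ]
  expect_equal(ca$surv, sapply(ca$time, function(t0) mean(t3 > t0)))
})

test_that("Cox fitting recovers planted coefficients and the two-group rate ratio", {
  # planted (+1, -1, 0): signs and small bias over 20 seeds
  est <- sapply(1:20, function(s) {
    co <- generate_cohort(synthetic_spec(
      n_samples = 300,
      planted_cox_coefficients = c(lnc001 = 1, lnc002 = -1, lnc003 = 0),
      seed = 100L + s))
    m <- fit_risk_model(co$set$lncrna, co$set$clinical,
                        signature_ids = c("lnc001", "lnc002", "lnc003"))
    m$coefficients
  })
  bias <- rowMeans(est) - c(1, -1, 0)
  expect_true(all(abs(bias) < 0.15))
  expect_true(mean(est["lnc001", ] > 0) >= 0.95)
  expect_true(mean(est["lnc002", ] < 0) >= 0.95)

  # binary exposure with exponential survival: HR CI covers the rate ratio
  set.seed(61)
  n <- 300
  rate <- rep(c(0.02, 0.04), each = n / 2)
  clin <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                         os_months = rexp(n, rate), event = 1L)
  grp <- tibble::tibble(sample_id = clin$sample_id,
                        group = factor(rep(c("low", "high"), each = n / 2),
                                       levels = c("low", "high")))
  res <- km_logrank(grp, clin)
  expect_true(res$hazard_ratio$lower < 2 && 2 < res$hazard_ratio$upper)

  # degenerate inputs
  expr1 <- expression_matrix(matrix(rnorm(10), 1, 10,
    dimnames = list("l1", sprintf("s%02d", 1:10))), "lncRNA")
  clin0 <- mk_clinical(sprintf("s%02d", 1:10), event = rep(0L, 10))
  expect_error(fit_risk_model(expr1, clin0), "2 events")
})

test_that("cox_table reports univariate and multivariate blocks with planted HR", {
  set.seed(62)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  clin <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:n),
    os_months = rexp(n, 0.02 * exp(log(2) * x)),
    event = 1L,
    age = round(rnorm(n, 60, 8)),
    stage = sample(c("II", "III", "IV"), n, TRUE),
    grade = sample(c("G1/G2", "G3/G4"), n, TRUE),
    residual = sample(c("0-10mm", ">10mm"), n, TRUE))
  risk <- tibble::tibble(sample_id = clin$sample_id,
                         group = ifelse(x == 1, "high", "low"))
  tab <- cox_table(clin, risk)
  expect_setequal(unique(tab$block), c("univariate", "multivariate"))
  uni <- tab[tab$block == "univariate" & tab$term == "grouphigh", ]
  expect_true(uni$lower < 2 && 2 < uni$upper)
  expect_true(all(tab$lower <= tab$HR + 1e-12 & tab$HR <= tab$upper + 1e-12,
                  na.rm = TRUE))
  # stage II is the reference: only III and IV rows appear
  expect_true(all(c("stageIII", "stageIV") %in% tab$term))
  expect_false("stageII" %in% tab$term)
})

test_that("time-dependent ROC attains its closed-form extremes and the
           zero-censoring empirical AUC", {
  # perfect separation, no censoring before eval time
  clin <- tibble::tibble(sample_id = sprintf("s%02d", 1:20),
                         os_months = c(rep(10, 10), rep(100, 10)),
                         event = rep(1L, 20))
  sc <- tibble::tibble(sample_id = clin$sample_id,
                       score = c(rnorm(10, 10), rnorm(10, -10)))
  roc <- time_dependent_roc(sc, clin, eval_time = 50)
  expect_equal(roc$auc, 1)

  # with zero censoring the estimator equals the empirical Mann-Whitney AUC
  set.seed(63)
  n <- 200
  s <- rnorm(n)
  clin2 <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                          os_months = rexp(n, 0.02 * exp(0.8 * s)),
                          event = 1L)
  sc2 <- tibble::tibble(sample_id = clin2$sample_id, score = s)
  t0 <- 40
  roc2 <- time_dependent_roc(sc2, clin2, eval_time = t0)
  case <- clin2$os_months <= t0
  pairs <- outer(s[case], s[!case], function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(roc2$auc, mean(pairs), tolerance = 1e-10)

  # uninformative scores hover near 0.5
  sc3 <- tibble::tibble(sample_id = clin2$sample_id,
                        score = rnorm(n))
  roc3 <- time_dependent_roc(sc3, clin2, eval_time = t0)
  expect_lt(abs(roc3$auc - 0.5), 0.12)

  expect_error(time_dependent_roc(sc2, clin2, eval_time = 1e6), "follow-up")
})

test_that("stratified analysis partitions the cohort and finds stratum-specific effects", {
  co <- generate_cohort(synthetic_spec(n_samples = 200, seed = 71L))
  model <- fit_risk_model(co$set$lncrna, co$set$clinical,
                          signature_ids = c("lnc001", "lnc002"))
  sc <- risk_scores(model, co$set$lncrna)
  strat <- stratified_analysis(sc, co$set$clinical, stratify_by = "age",
                               split = 65, cutoff = model$cutoff)
  ns <- vapply(strat, function(s) sum(s$n$n), numeric(1))
  expect_equal(sum(ns), 200)

  # constant stratification field reproduces the global comparison
  clin_const <- dplyr::mutate(co$set$clinical, grade = "G3/G4")
  s1 <- stratified_analysis(sc, clin_const, stratify_by = "grade",
                            cutoff = model$cutoff)
  expect_equal(length(s1), 1)
  glob <- km_logrank(dichotomize(sc, model$cutoff), co$set$clinical)
  expect_equal(s1[[1]]$logrank$chisq, glob$logrank$chisq)

  # planted effect only in stratum A: its log-rank p is smaller in most seeds
  hits <- vapply(1:20, function(s) {
    set.seed(200 + s)
    n <- 200
    score <- rnorm(n)
    stratum <- rep(c("A", "B"), each = n / 2)
    rate <- ifelse(stratum == "A", 0.02 * exp(1.2 * score), 0.02)
    clin <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                           os_months = rexp(n, rate), event = 1L,
                           stage = stratum)
    scr <- tibble::tibble(sample_id = clin$sample_id, score = score)
    st <- stratified_analysis(scr, clin, stratify_by = "stage")
    st$A$logrank$p < st$B$logrank$p
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("hierarchical cluster split recovers planted sample blobs", {
  set.seed(81)
  blob <- cbind(matrix(rnorm(10 * 15, mean = 3), 10),
                matrix(rnorm(10 * 15, mean = -3), 10))
  rownames(blob) <- sprintf("l%02d", 1:10)
  colnames(blob) <- sprintf("s%02d", 1:30)
  expr <- expression_matrix(blob, "lncRNA")
  cs <- cluster_split(expr, scale_rows = FALSE)
  expect_equal(length(unique(cs$cluster[1:15])), 1)
  expect_equal(length(unique(cs$cluster[16:30])), 1)
  expect_equal(nlevels(droplevels(cs$cluster)), 2)
  expect_true(all(table(cs$cluster) > 0))

  # duplicated samples co-cluster
  dup <- expression_matrix(cbind(blob, blob + 1e-9) |>
    `colnames<-`(sprintf("d%02d", 1:60)), "lncRNA")
  cd <- cluster_split(dup)
  expect_equal(cd$cluster[1:30], cd$cluster[31:60], ignore_attr = TRUE)
})
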