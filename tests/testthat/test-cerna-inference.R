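test_that("pearson correlation matches longhand arithmetic and closed forms", {
  expect_equal(pearson_correlation(1:4, 1:4)$r, 1)
  expect_equal(pearson_correlation(1:4, -(1:4))$r, -1)
  x <- c(1, 2, 3, 5); y <- c(2, 1, 4, 5)
  got <- pearson_correlation(x, y)
  expect_equal(got$r, oracle_pearson(x, y))
  # two-sided t approximation on n-2 df
  tt <- got$r * sqrt((4 - 2) / (1 - got$r^2))
  expect_equal(got$p, 2 * stats::pt(-abs(tt), 2))
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "3")
})

test_that("correlation threshold is a percentile of the exhaustive pair distribution", {
  set.seed(20)
  lnc <- matrix(rnorm(30), 3, 10, dimnames = list(paste0("l", 1:3), NULL))
  mrna <- matrix(rnorm(30), 3, 10, dimnames = list(paste0("g", 1:3), NULL))
  colnames(lnc) <- colnames(mrna) <- sprintf("s%02d", 1:10)
  mir <- matrix(rnorm(20), 2, 10,
                dimnames = list(c("m1", "m2"), colnames(lnc)))
  set <- mk_matched(mir, lnc, mrna)
  all_r <- as.vector(outer(1:3, 1:3, Vectorize(function(i, j)
    oracle_pearson(lnc[i, ], mrna[j, ]))))
  expect_equal(correlation_threshold(set, 100), max(all_r))
  expect_equal(correlation_threshold(set, 99),
               unname(stats::quantile(all_r, 0.99)))
  expect_equal(correlation_threshold(set, 50),
               unname(stats::quantile(all_r, 0.5)))
})

test_that("candidate calling enforces both the correlation and shared-miRNA rules", {
  set.seed(21)
  n <- 20
  m <- rnorm(n)
  mir <- rbind(m1 = m + rnorm(n, sd = 0.1), m2 = rnorm(n))
  lnc <- rbind(l1 = -m + rnorm(n, sd = 0.1), l2 = rnorm(n))
  mrna <- rbind(g1 = -m + rnorm(n, sd = 0.1), g2 = rnorm(n))
  colnames(mir) <- colnames(lnc) <- colnames(mrna) <- sprintf("s%02d", 1:n)
  set <- mk_matched(mir, lnc, mrna)
  cat_m <- tibble::tibble(mirna_id = c("m1", "m2"), target_id = c("g1", "g2"),
                          target_class = "mRNA")
  cat_l <- tibble::tibble(mirna_id = c("m1", "m2"), target_id = c("l1", "l1"),
                          target_class = "lncRNA")

  cand <- find_candidate_triplets(set, cat_m, cat_l, threshold = 0.5)
  expect_equal(cand$lncrna_id, "l1")
  expect_equal(cand$mrna_id, "g1")
  expect_equal(cand$shared_mirnas[[1]], "m1")

  # high correlation but no shared miRNA -> excluded
  cat_l2 <- tibble::tibble(mirna_id = "m2", target_id = "l1",
                           target_class = "lncRNA")
  expect_equal(nrow(find_candidate_triplets(set, cat_m, cat_l2, 0.5)), 0)

  # shared miRNAs but r below threshold -> excluded
  expect_equal(nrow(find_candidate_triplets(set, cat_m, cat_l, 0.9999)), 0)
})

test_that("candidate calling equals the brute-force triple loop on a random instance", {
  set.seed(22)
  n <- 15
  mir <- matrix(rnorm(8 * n), 8, n, dimnames = list(sprintf("m%d", 1:8), NULL))
  lnc <- matrix(rnorm(10 * n), 10, n, dimnames = list(sprintf("l%d", 1:10), NULL))
  mrna <- matrix(rnorm(12 * n), 12, n, dimnames = list(sprintf("g%d", 1:12), NULL))
  colnames(mir) <- colnames(lnc) <- colnames(mrna) <- sprintf("s%02d", 1:n)
  set <- mk_matched(mir, lnc, mrna)
  cat_m <- tibble::tibble(
    mirna_id = sample(rownames(mir), 30, TRUE),
    target_id = sample(rownames(mrna), 30, TRUE), target_class = "mRNA") |>
    dplyr::distinct()
  cat_l <- tibble::tibble(
    mirna_id = sample(rownames(mir), 20, TRUE),
    target_id = sample(rownames(lnc), 20, TRUE), target_class = "lncRNA") |>
    dplyr::distinct()
  for (thr in c(-0.5, 0, 0.3)) {
    got <- find_candidate_triplets(set, cat_m, cat_l, thr)
    want <- oracle_triplets(set, cat_m, cat_l, thr)
    expect_equal(got$lncrna_id, want$lncrna_id)
    expect_equal(got$mrna_id, want$mrna_id)
    if (nrow(got) > 0) {
      expect_equal(got$r_lnc_mrna, want$r_lnc_mrna)
      expect_equal(got$shared_mirnas, want$shared_mirnas)
    }
  }
})

test_that("candidate set shrinks monotonically in threshold and min_shared", {
  co <- generate_cohort(synthetic_spec(n_samples = 60, seed = 9L))
  set <- co$set
  keys <- function(df) paste(df$lncrna_id, df$mrna_id)
  prev <- NULL
  for (thr in c(0.1, 0.3, 0.5, 0.7)) {
    cur <- find_candidate_triplets(set, co$mirna_mrna, co$mirna_lncrna, thr)
    if (!is.null(prev)) expect_true(all(keys(cur) %in% keys(prev)))
    prev <- cur
  }
  a1 <- find_candidate_triplets(set, co$mirna_mrna, co$mirna_lncrna, 0.3, 1)
  a2 <- find_candidate_triplets(set, co$mirna_mrna, co$mirna_lncrna, 0.3, 2)
  expect_true(all(keys(a2) %in% keys(a1)))
})

test_that("functional filter applies the negativity rule and is a subset of candidates", {
  set.seed(23)
  n <- 20
  m <- rnorm(n)
  mir <- rbind(mneg = m + rnorm(n, sd = 0.1), mpos = -m + rnorm(n, sd = 0.1))
  lnc <- rbind(l1 = -m + rnorm(n, sd = 0.1))
  mrna <- rbind(g1 = -m + rnorm(n, sd = 0.1))
  colnames(mir) <- colnames(lnc) <- colnames(mrna) <- sprintf("s%02d", 1:n)
  set <- mk_matched(mir, lnc, mrna)
  mk_cats <- function(mirs) list(
    m = tibble::tibble(mirna_id = mirs, target_id = "g1", target_class = "mRNA"),
    l = tibble::tibble(mirna_id = mirs, target_id = "l1", target_class = "lncRNA"))

  # positively co-expressed shared miRNA only -> dropped
  cats <- mk_cats("mpos")
  cand <- find_candidate_triplets(set, cats$m, cats$l, 0.5)
  expect_equal(nrow(cand), 1)
  expect_equal(nrow(filter_functional_triplets(cand, set)), 0)

  # negative shared miRNA retained; pruning keeps only passing miRNAs
  cats2 <- mk_cats(c("mneg", "mpos"))
  cand2 <- find_candidate_triplets(set, cats2$m, cats2$l, 0.5)
  fun2 <- filter_functional_triplets(cand2, set)
  expect_equal(nrow(fun2), 1)
  expect_equal(fun2$shared_mirnas[[1]], "mneg")
  expect_equal(fun2$status, "functional")
  expect_true(all(paste(fun2$lncrna_id, fun2$mrna_id) %in%
                  paste(cand2$lncrna_id, cand2$mrna_id)))

  # candidate referencing unknown molecules -> error
  bad <- cand2
  bad$lncrna_id <- "ghost"
  expect_error(filter_functional_triplets(bad, set), "ghost")
})

test_that("borderline negative correlation passes sign-only but not the p<0.05 rule", {
  # build a pair with r ~ -0.05 at n = 20 on the miRNA arms
  set.seed(31)
  n <- 20
  repeat {
    m <- rnorm(n)
    l <- -0.05 * scale(m)[, 1] + rnorm(n)
    g <- l + rnorm(n, sd = 0.2)
    r_ml <- cor(m, l); r_mg <- cor(m, g)
    if (r_ml < 0 && r_ml > -0.2 && r_mg < 0 && r_mg > -0.2 && cor(l, g) > 0.5) break
  }
  mir <- rbind(m1 = m); lnc <- rbind(l1 = l); mrna <- rbind(g1 = g)
  colnames(mir) <- colnames(lnc) <- colnames(mrna) <- sprintf("s%02d", 1:n)
  set <- mk_matched(mir, lnc, mrna)
  cat_m <- tibble::tibble(mirna_id = "m1", target_id = "g1", target_class = "mRNA")
  cat_l <- tibble::tibble(mirna_id = "m1", target_id = "l1", target_class = "lncRNA")
  cand <- find_candidate_triplets(set, cat_m, cat_l, 0.3)
  expect_equal(nrow(cand), 1)
  expect_equal(nrow(filter_functional_triplets(cand, set, rule = "sign")), 1)
  expect_equal(nrow(filter_functional_triplets(cand, set, rule = "p05")), 0)
})

test_that("network assembly uses the documented edge semantics and provenance", {
  trip <- tibble::tibble(
    lncrna_id = "l1", mrna_id = "g1", r_lnc_mrna = 0.8,
    shared_mirnas = list("m1"), n_shared = 1L, status = "functional")
  net <- assemble_network(trip)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  net2 <- assemble_network(trip, cerna_edges = TRUE)
  expect_equal(nrow(net2$edges), 3)
  expect_true("lncRNA-mRNA" %in% net2$edges$edge_type)

  # shared miRNA-mRNA edge collapses with both triplets as provenance
  trip2 <- dplyr::bind_rows(trip, dplyr::mutate(trip, lncrna_id = "l2"))
  net3 <- assemble_network(trip2)
  e <- net3$edges[net3$edges$from == "g1" & net3$edges$to == "m1", ]
  expect_equal(nrow(e), 1)
  expect_setequal(e$triplets[[1]], c("l1|g1", "l2|g1"))

  expect_warning(empty <- assemble_network(empty_triplets()), "empty")
  expect_equal(nrow(empty$nodes), 0)
})

test_that("inference recovers planted triplets on the default synthetic cohort", {
  co <- generate_cohort(synthetic_spec())
  inf <- infer_cerna_network(co$set, co$mirna_mrna, co$mirna_lncrna)
  truth_keys <- paste(co$truth$planted_triplets$lncrna_id,
                      co$truth$planted_triplets$mrna_id)
  got_keys <- paste(inf$functional$lncrna_id, inf$functional$mrna_id)
  expect_gte(mean(truth_keys %in% got_keys), 0.9)
  expect_lte(mean(!got_keys %in% truth_keys), 0.1)
  # threshold lies below every planted-pair correlation
  planted_r <- inf$functional$r_lnc_mrna[got_keys %in% truth_keys]
  expect_true(all(planted_r > inf$threshold))
})

test_that("condition-specific networks only see their own samples", {
  # triplet correlated only within stage-IV samples
  set.seed(41)
  n2 <- 15; n4 <- 15
  m4 <- rnorm(n4)
  mir <- rbind(m1 = c(rnorm(n2), m4 + rnorm(n4, sd = 0.1)))
  lnc <- rbind(l1 = c(rnorm(n2), -m4 + rnorm(n4, sd = 0.1)),
               l2 = rnorm(n2 + n4))
  mrna <- rbind(g1 = c(rnorm(n2), -m4 + rnorm(n4, sd = 0.1)),
                g2 = rnorm(n2 + n4))
  samples <- sprintf("s%02d", seq_len(n2 + n4))
  colnames(mir) <- colnames(lnc) <- colnames(mrna) <- samples
  clin <- mk_clinical(samples, stage = rep(c("II", "IV"), c(n2, n4)))
  set <- align_matched_set(mk_expr(mir, "miRNA"), mk_expr(lnc, "lncRNA"),
                           mk_expr(mrna, "mRNA"), clin)
  cat_m <- tibble::tibble(mirna_id = "m1", target_id = "g1", target_class = "mRNA")
  cat_l <- tibble::tibble(mirna_id = "m1", target_id = "l1", target_class = "lncRNA")
  nets <- condition_specific_networks(set, cat_m, cat_l, group_by = "stage",
                                      threshold = 0.5)
  expect_true("l1" %in% nets$IV$nodes$id)
  expect_false("l1" %in% nets$II$nodes$id)

  # permuting the stage-II samples leaves the stage-IV network unchanged
  perm <- c(sample(1:n2), (n2 + 1):(n2 + n4))
  set_p <- align_matched_set(
    mk_expr(mir[, perm, drop = FALSE] |> `colnames<-`(samples), "miRNA"),
    mk_expr(lnc[, perm, drop = FALSE] |> `colnames<-`(samples), "lncRNA"),
    mk_expr(mrna[, perm, drop = FALSE] |> `colnames<-`(samples), "mRNA"),
    clin)
  nets_p <- condition_specific_networks(set_p, cat_m, cat_l, group_by = "stage",
                                        threshold = 0.5)
  expect_equal(nets_p$IV$edges, nets$IV$edges)

  # a single group reproduces the global run on that subset
  clin1 <- mk_clinical(samples, stage = rep("III", n2 + n4))
  set1 <- align_matched_set(mk_expr(mir, "miRNA"), mk_expr(lnc, "lncRNA"),
                            mk_expr(mrna, "mRNA"), clin1)
  nets1 <- condition_specific_networks(set1, cat_m, cat_l, group_by = "stage",
                                       threshold = 0.5)
  glob <- infer_cerna_network(set1, cat_m, cat_l, threshold = 0.5)
  expect_equal(nets1$III$edges, glob$network$edges)
})
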