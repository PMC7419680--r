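test_that("CTLA-4 adjustment reduces to centering with constant covariates and zeroes residual structure", {
  # constant covariates: adjusted = ctla4 minus its mean
  d <- tibble::tibble(sample = sprintf("s%d", 1:20),
                      ctla4 = rnorm(20, 5),
                      estimate_score = 1, cd4_score = 2, cd8_score = 3)
  # constant design is collinear by construction -> error path
  expect_error(adjust_ctla4(d), "collinear")

  set.seed(42)
  n <- 200
  est <- rnorm(n); lymph <- rnorm(n)
  d2 <- tibble::tibble(
    sample = sprintf("s%03d", 1:n),
    estimate_score = est,
    cd4_score = lymph + rnorm(n, sd = 0.3),
    cd8_score = lymph + rnorm(n, sd = 0.3),
    ctla4 = 0.8 * est + 0.5 * lymph + rnorm(n, sd = 0.1))
  fit <- adjust_ctla4(d2)
  expect_lt(abs(cor(fit$data$adjusted, est)), 0.05)
  expect_lt(abs(sum(fit$data$adjusted)), 1e-10)
  # oracle: residuals of lm on the same draw
  oracle <- residuals(lm(ctla4 ~ estimate_score + cd4_score * cd8_score,
                         data = d2))
  expect_equal(fit$data$adjusted, unname(oracle), tolerance = 1e-12)
  # product mode uses a single combined covariate
  fitp <- adjust_ctla4(d2, mode = "product")
  oracle_p <- residuals(lm(ctla4 ~ estimate_score + I(cd4_score * cd8_score),
                           data = d2))
  expect_equal(fitp$data$adjusted, unname(oracle_p), tolerance = 1e-12)
  expect_equal(nrow(tidy(fit)), 5L)  # intercept, est, cd4, cd8, cd4:cd8
  expect_equal(glance(fit)$nobs, n)
})

test_that("median dichotomization follows the strictly-greater rule", {
  expect_equal(as.character(dichotomize(c(1, 2, 3, 4))),
               c("Low", "Low", "High", "High"))
  expect_equal(as.character(dichotomize(c(1, 2, 2, 3))),
               c("Low", "Low", "Low", "High"))
  expect_error(dichotomize(c(2, 2, 2)), "identical")
  # counting identity: the High/Low imbalance is bounded by the samples tied
  # with the median (each tie moves one sample from High to Low)
  set.seed(8)
  for (rep in 1:20) {
    v <- sample(1:6, 15, replace = TRUE)
    lab <- dichotomize(v)
    n_tied <- sum(v == median(v))
    expect_lte(abs(sum(lab == "High") - sum(lab == "Low")), 2 * n_tied)
    if (n_tied == 0) {
      expect_equal(sum(lab == "High"), sum(lab == "Low"))
    }
  }
})

test_that("cluster assignment crosses the two axes with asymmetric activated-like flags", {
  d <- tibble::tibble(
    sample = c("s1", "s2", "s3", "s4"),
    adjusted_ctla4 = c(10, 9, 1, 2),
    erk_score = c(5, 1, 5, 1),
    akt_score = c(1, 5, 1, 5))
  cl <- assign_clusters(d)
  expect_equal(as.character(cl$erk_cluster), c("HH", "HL", "LH", "LL"))
  expect_equal(as.character(cl$akt_cluster), c("HL", "HH", "LL", "LH"))
  # checkpoint-high + ERK-enriched + AKT-low is activated-like on both axes
  expect_true(cl$activated_like_erk[1] && cl$activated_like_akt[1])
  # CTLA-4 Low samples are never activated-like
  expect_false(any(cl$activated_like_erk[3:4]))
  expect_false(any(cl$activated_like_akt[3:4]))
  # the four groups partition the cohort
  expect_equal(sum(table(cl$erk_cluster)), nrow(d))

  # invariance to affine transforms of adjusted CTLA-4; sign swap flips erk only
  cl2 <- assign_clusters(dplyr::mutate(d, adjusted_ctla4 = 3 * adjusted_ctla4 - 7))
  expect_equal(cl2$erk_cluster, cl$erk_cluster)
  cl3 <- assign_clusters(dplyr::mutate(d, erk_score = -erk_score))
  expect_equal(as.character(cl3$erk_status),
               ifelse(cl$erk_status == "High", "Low", "High"))
  expect_equal(cl3$ctla4_status, cl$ctla4_status)
  expect_equal(cl3$akt_cluster, cl$akt_cluster)
})

test_that("stratification recovers planted clusters on the synthetic cohort", {
  sim <- demo_cohort()
  scaled <- mad_scale(sim$expression)
  pt <- estimate_scores(scaled, sim$gene_sets[["STROMAL_SIGNATURE"]],
                        sim$gene_sets[["IMMUNE_SIGNATURE"]])
  suppressMessages(kept <- filter_by_purity(pt, 0.60))
  sub <- expr_matrix(unclass(scaled)[, kept])
  infil <- infiltration_scores(sub, sim$gene_sets[["CD4_LYMPHOCYTE"]],
                               sim$gene_sets[["CD8_LYMPHOCYTE"]])
  adj_in <- dplyr::left_join(
    tibble::tibble(sample = kept, ctla4 = unclass(sub)["CTLA4", ]),
    dplyr::left_join(infil, pt[, c("sample", "estimate_score")], by = "sample"),
    by = "sample")
  adj <- adjust_ctla4(adj_in)
  erk <- combine_axis_scores(ssgsea(sub, sets_with_role(sim$gene_sets, "erk_axis")))
  akt <- combine_axis_scores(ssgsea(sub, sets_with_role(sim$gene_sets, "akt_axis")))
  cl <- assign_clusters(tibble::tibble(
    sample = adj$data$sample, adjusted_ctla4 = adj$data$adjusted,
    erk_score = unname(erk[adj$data$sample]),
    akt_score = unname(akt[adj$data$sample])))
  m <- match(cl$sample, sim$truth$sample)
  expect_gte(mean(as.character(cl$erk_cluster) == sim$truth$erk_cluster[m]), 0.95)
  expect_gte(mean(as.character(cl$akt_cluster) == sim$truth$akt_cluster[m]), 0.95)
})
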