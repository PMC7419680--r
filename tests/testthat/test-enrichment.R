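test_that("ssGSEA matches the hand-summation oracle on small instances", {
  # frozen 4-gene example: values (4,3,2,1), set = top two genes, alpha 0.25
  m <- make_expr(matrix(c(4, 3, 2, 1), ncol = 1), genes = paste0("g", 1:4))
  got <- ssgsea_score(m, c("G1", "G2"), alpha = 0.25)
  expect_equal(unname(got), 2.0179723833, tolerance = 1e-10)

  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    v <- rnorm(n)
    names(v) <- sprintf("G%02d", seq_len(n))
    set_genes <- sample(names(v), sample(2:(n - 2), 1))
    m <- make_expr(matrix(v, ncol = 1), genes = names(v))
    expect_equal(unname(ssgsea_score(m, set_genes)),
                 oracle_ssgsea(v, set_genes), tolerance = 1e-10)
  }
})

test_that("ssGSEA is rank-invariant and orders top vs bottom sets correctly", {
  v <- c(6, 5, 4, 3, 2, 1)
  m <- make_expr(cbind(v, exp(v)), genes = paste0("g", 1:6),
                 samples = c("raw", "mono"))
  top <- ssgsea_score(m, c("G1", "G2"))
  expect_equal(top[["raw"]], top[["mono"]], tolerance = 1e-12)
  bottom <- ssgsea_score(m, c("G5", "G6"))
  expect_gt(top[["raw"]], bottom[["raw"]])
  expect_error(ssgsea_score(m, c("ZZZ")), "no set genes")

  # property: invariance under strictly monotone transforms on random draws
  set.seed(12)
  base <- rnorm(30)
  names(base) <- sprintf("G%02d", 1:30)
  sg <- sample(names(base), 8)
  for (f in list(function(x) 3 * x + 2, function(x) exp(x),
                 function(x) rank(x))) {
    m2 <- make_expr(cbind(base, f(base)), genes = names(base),
                    samples = c("a", "b"))
    sc <- ssgsea_score(m2, sg)
    expect_equal(sc[["a"]], sc[["b"]], tolerance = 1e-10)
  }
})

test_that("axis combination standardizes, averages, and denoises a shared signal", {
  # single set: combined equals the standardized score
  s1 <- c(a = 1, b = 3, c = 5)
  one <- combine_axis_scores(cbind(set1 = s1))
  expect_equal(unname(one), as.vector(scale(s1)), ignore_attr = TRUE)
  # identical sets: combined equals either standardized vector
  two <- combine_axis_scores(cbind(set1 = s1, set2 = s1))
  expect_equal(two, one)
  # zero-variance set excluded with warning
  expect_warning(
    z <- combine_axis_scores(cbind(set1 = s1, flat = c(a = 1, b = 1, c = 1))),
    "zero-variance")
  expect_equal(z, one)

  # planted common signal + independent noise: combining beats each single set
  set.seed(77)
  signal <- rnorm(200)
  sets <- sapply(1:3, function(i) signal + rnorm(200, sd = 1.2))
  rownames(sets) <- sprintf("S%03d", 1:200)
  comb <- combine_axis_scores(sets)
  r_comb <- cor(comb, signal)
  r_each <- apply(sets, 2, cor, y = signal)
  expect_true(all(r_comb > r_each))
})

test_that("GSEA nominal p on 4v4 instances equals exhaustive enumeration", {
  set.seed(9)
  for (rep in 1:3) {
    vals <- matrix(rnorm(40 * 8), 40, 8,
                   dimnames = list(sprintf("G%02d", 1:40), sprintf("S%d", 1:8)))
    set_genes <- sprintf("G%02d", 1:8)
    vals[set_genes, 1:4] <- vals[set_genes, 1:4] + 6  # strong planted shift
    labels <- factor(rep(c("grp1", "grp2"), each = 4),
                     levels = c("grp1", "grp2"))
    gs <- gene_set_collection(list(PLANTED = set_genes,
                                   RANDOM = sprintf("G%02d", 31:40)))
    res <- gsea(make_expr(vals, genes = rownames(vals),
                          samples = colnames(vals)),
                labels, gs, n_perm = 1000)
    expect_true(attr(res, "exhaustive"))
    expect_equal(attr(res, "n_perm"), 70L)
    for (nm in c("PLANTED", "RANDOM")) {
      orc <- oracle_gsea_exhaustive_p(vals, rep(c(TRUE, FALSE), each = 4),
                                      if (nm == "PLANTED") set_genes
                                      else sprintf("G%02d", 31:40))
      row <- res[res$set == nm, ]
      expect_equal(row$es, orc$es, tolerance = 1e-12)
      expect_equal(row$p, orc$p, tolerance = 1e-12)
    }
    planted <- res[res$set == "PLANTED", ]
    expect_gt(planted$nes, 0)
    # smallest achievable two-sided exhaustive p: the observed assignment and
    # its mirror image share the extreme |ES|
    expect_equal(planted$p, 2 / 70, tolerance = 1e-12)
  }
})

test_that("GSEA enrichment scores agree with an independent preranked implementation", {
  skip_if_not_installed("fgsea")
  set.seed(21)
  vals <- matrix(rnorm(50 * 10), 50, 10,
                 dimnames = list(sprintf("G%02d", 1:50), sprintf("S%d", 1:10)))
  g1 <- rep(c(TRUE, FALSE), each = 5)
  met <- oracle_metric(vals, g1)
  ord <- names(met)[order(-met, names(met))]
  stats_vec <- met[ord]
  for (rep in 1:5) {
    sg <- sample(rownames(vals), 10)
    ours <- oracle_es(met, sg)  # same ES definition the package uses
    theirs <- fgsea::calcGseaStat(stats_vec,
                                  selectedStats = which(ord %in% sg),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("GSEA guards degenerate label inputs and flips sign with the reference", {
  m <- random_expr(30, 8, seed = 3)
  gs <- gene_set_collection(list(S = rownames(m)[1:6]))
  expect_error(gsea(m, rep("same", 8), gs), "two groups")
  expect_error(gsea(m, c("a", rep("b", 7)), gs), "at least 2")

  lab <- factor(rep(c("x", "y"), each = 4), levels = c("x", "y"))
  res_xy <- gsea(m, lab, gs)
  res_yx <- gsea(m, factor(lab, levels = c("y", "x")), gs)
  expect_equal(res_xy$es, -res_yx$es, tolerance = 1e-10)
})

test_that("GSEA nominal p is calibrated for label-independent sets", {
  # sampled-null mode on a random set: p should be roughly uniform; check the
  # rejection rate at 0.05 over seeded replicates
  set.seed(55)
  hits <- 0; reps <- 200
  for (i in seq_len(reps)) {
    vals <- matrix(rnorm(20 * 12), 20, 12,
                   dimnames = list(sprintf("G%02d", 1:20), sprintf("S%d", 1:12)))
    lab <- factor(rep(c("a", "b"), each = 6))
    gs <- gene_set_collection(list(S = sample(rownames(vals), 6)))
    p <- gsea(make_expr(vals, genes = rownames(vals),
                        samples = colnames(vals)),
              lab, gs, n_perm = 200, seed = i)$p
    hits <- hits + (p <= 0.05)
  }
  expect_gt(hits / reps, 0.01)
  expect_lt(hits / reps, 0.10)
})
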