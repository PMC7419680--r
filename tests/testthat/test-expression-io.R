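test_that("TSV and GCT round-trips reproduce the matrix, and NA rows are dropped", {
  m <- make_expr(matrix(c(1, 2, 3, 4, 5, 6), nrow = 3),
                 genes = c("TP53", "GZMA", "PRF1"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gct <- withr::local_tempfile(fileext = ".gct")
  write_expression(m, tsv, "tsv")
  write_expression(m, gct, "gct")
  back_tsv <- read_expression(tsv, "tsv")
  back_gct <- read_expression(gct, "gct")
  expect_equal(unclass(back_tsv), unclass(m), ignore_attr = TRUE)
  expect_equal(dimnames(back_tsv), dimnames(m))
  expect_equal(unclass(back_gct), unclass(back_tsv), ignore_attr = TRUE)
  expect_length(provenance(back_tsv), 0)

  # one NA cell drops that gene row and counts it
  vals <- matrix(c(1, NA, 3, 4, 5, 6), nrow = 3,
                 dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  em <- expr_matrix(vals)
  expect_equal(nrow(em), 2L)
  expect_equal(attr(em, "n_dropped"), 1L)
  expect_setequal(rownames(em), c("A", "C"))
})

test_that("malformed GCT headers and duplicate sample ids are rejected", {
  bad <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#9.9", "3\t2"), bad)
  expect_error(read_expression(bad, "gct"), "#1.2")
  vals <- matrix(1:4, 2, dimnames = list(c("A", "B"), c("s1", "s1")))
  expect_error(expr_matrix(vals), "duplicate sample")
})

test_that("probe collapse keeps the highest-IQR probe, first in file order on ties", {
  vals <- rbind(p1 = c(1, 1, 1, 1), p2 = c(0, 2, 4, 6),
                p3 = c(5, 6, 7, 8), p4 = c(9, 10, 11, 12))
  colnames(vals) <- sprintf("S%d", 1:4)
  m <- expr_matrix(vals)
  map <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    symbol = c("GENE1", "GENE1", "GENE2", "GENE2"))
  out <- collapse_probes(m, map)
  expect_equal(nrow(out), 2L)
  # GENE1: IQR 0 vs 3 -> p2 wins; GENE2: tie in IQR -> p3 (file order) wins
  expect_equal(unname(unclass(out)["GENE1", ]), c(0, 2, 4, 6))
  expect_equal(unname(unclass(out)["GENE2", ]), c(5, 6, 7, 8))
  expect_true("collapsed" %in% provenance(out))

  # brute-force oracle over several random instances with planted ties
  set.seed(5)
  for (rep in 1:5) {
    nv <- matrix(rnorm(40), 10, 4,
                 dimnames = list(sprintf("pr%02d", 1:10), sprintf("S%d", 1:4)))
    nv[6, ] <- nv[2, ]  # exact tie pair mapping to the same symbol
    map2 <- data.frame(probe_id = rownames(nv),
                       symbol = rep(sprintf("G%d", 1:5), each = 2))
    got <- collapse_probes(expr_matrix(nv), map2)
    for (sym in unique(map2$symbol)) {
      rows <- which(map2$symbol == sym)
      iqrs <- apply(nv[rows, , drop = FALSE], 1, IQR)
      best <- rows[which.max(iqrs)]  # which.max = first max = file order
      expect_equal(unname(unclass(got)[sym, ]), unname(nv[best, ]))
    }
  }

  # single-probe genes pass through; unmapped probes are dropped with warning
  expect_warning(
    out2 <- collapse_probes(m, map[-1, ]),
    "absent from map")
  expect_equal(nrow(out2), 2L)
})

test_that("MAD scaling matches the consistency-constant formula and is idempotent", {
  m <- make_expr(matrix(c(1, 2, 3), ncol = 1))
  out <- mad_scale(m)
  expect_equal(unname(unclass(out)[, 1]),
               c(-0.67449076, 0, 0.67449076), tolerance = 1e-7)
  # scaled columns: median 0, mad (with constant) 1
  big <- random_expr(50, 4, seed = 2)
  sc <- mad_scale(big)
  expect_equal(unname(apply(unclass(sc), 2, median)), rep(0, 4))
  expect_equal(unname(apply(unclass(sc), 2, mad)), rep(1, 4))
  twice <- mad_scale(sc)
  expect_equal(unclass(twice), unclass(sc), tolerance = 1e-12, ignore_attr = TRUE)
  # constant sample column -> error naming the sample
  const <- make_expr(cbind(c(1, 1, 1), c(1, 2, 3)), samples = c("flat", "ok"))
  expect_error(mad_scale(const), "flat")
})

test_that("median centering zeroes row medians and gene intersection sorts and aligns", {
  m <- make_expr(matrix(c(1, 2, 3, 7, 8, 9), nrow = 2, byrow = TRUE),
                 genes = c("A", "B"), samples = c("s1", "s2", "s3"))
  cen <- median_center(m)
  expect_equal(unname(unclass(cen)["A", ]), c(-1, 0, 1))
  expect_equal(unname(apply(unclass(cen), 1, median)), c(0, 0))
  expect_equal(unclass(median_center(cen)), unclass(cen), ignore_attr = TRUE)

  m1 <- make_expr(matrix(1:6, 3), genes = c("A", "B", "C"))
  m2 <- make_expr(matrix(1:6, 3), genes = c("B", "C", "D"))
  out <- intersect_genes(list(m1, m2))
  expect_equal(rownames(out[[1]]), c("B", "C"))
  expect_equal(rownames(out[[2]]), c("B", "C"))
  # order-insensitive in membership
  rev_out <- intersect_genes(list(m2, m1))
  expect_setequal(rownames(rev_out[[1]]), rownames(out[[1]]))
  m3 <- make_expr(matrix(1:6, 3), genes = c("E", "F", "G"))
  expect_error(intersect_genes(list(m1, m3)), "empty")
})

test_that("log-CPM matches direct evaluation and is depth-invariant at high counts", {
  one <- make_expr(matrix(c(999999, 1), ncol = 1), genes = c("A", "B"))
  lc <- counts_to_logcpm(one, prior = 0.5)
  expect_equal(unclass(lc)["A", 1], 19.931566, tolerance = 1e-5)
  # doubling depth changes log-CPM by < 0.01 at counts >= 100
  counts <- make_expr(matrix(c(100, 250, 900, 200, 500, 1800), ncol = 2))
  l1 <- unclass(counts_to_logcpm(counts))[, 1]
  l2 <- unclass(counts_to_logcpm(counts))[, 2]
  expect_lt(max(abs(l1 - l2)), 0.01)
  neg <- make_expr(matrix(c(-1, 5), ncol = 1))
  expect_error(counts_to_logcpm(neg), "negative")
})
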