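# Shared fixtures, built in code at test time.

make_expr <- function(values, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  m <- as.matrix(values)
  dimnames(m) <- list(genes, samples)
  expr_matrix(m)
}

# deterministic background matrix with named marker genes on top
random_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  make_expr(matrix(rnorm(n_genes * n_samples, 6, 1.5), n_genes, n_samples))
}

# one default-size synthetic cohort, computed once per test run
demo_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(
        simulate_cohort(cohort_config(n_samples = 400, seed = 101)))
    }
    cache
  }
})

table2_fixture <- function(which) {
  path <- system.file("extdata", paste0("table2_", which, ".csv"),
                      package = "tnbcstrat")
  read_contingency(path)
}
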