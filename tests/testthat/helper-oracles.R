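# Independent brute-force oracles. These deliberately re-derive each quantity
# with the most literal algorithm available (explicit loops, exhaustive
# enumeration) and never call the package functions they are used to check.

# ssGSEA running sum, written as a position-by-position loop
oracle_ssgsea <- function(values, set_genes, alpha = 0.25) {
  stopifnot(!is.null(names(values)))
  ord <- names(values)[order(-values, names(values))]
  n <- length(values)
  in_set <- ord %in% set_genes
  w_total <- 0
  for (i in seq_len(n)) if (in_set[i]) w_total <- w_total + (n - i + 1)^alpha
  p_in <- 0; p_out <- 0; es <- 0
  n_out <- sum(!in_set)
  for (i in seq_len(n)) {
    if (in_set[i]) p_in <- p_in + (n - i + 1)^alpha / w_total
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  es
}

# signal-to-noise metric and weighted KS enrichment score, loop form
oracle_metric <- function(vals, g1) {
  out <- numeric(nrow(vals))
  for (g in seq_len(nrow(vals))) {
    a <- vals[g, g1]; b <- vals[g, !g1]
    m1 <- mean(a); m2 <- mean(b)
    s1 <- max(sd(a), 0.2 * abs(m1), 1e-8)
    s2 <- max(sd(b), 0.2 * abs(m2), 1e-8)
    out[g] <- (m1 - m2) / (s1 + s2)
  }
  names(out) <- rownames(vals)
  out
}

oracle_es <- function(metric, set_genes, weight_p = 1) {
  ord <- names(metric)[order(-metric, names(metric))]
  m_sorted <- metric[ord]
  hit <- ord %in% set_genes
  nr <- sum(abs(m_sorted[hit])^weight_p)
  n_miss <- sum(!hit)
  run <- 0; best <- 0
  for (i in seq_along(ord)) {
    if (hit[i]) {
      run <- run + if (nr > 0) abs(m_sorted[i])^weight_p / nr else 1 / sum(hit)
    } else {
      run <- run - 1 / n_miss
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# exhaustive phenotype-permutation nominal p for one gene set
oracle_gsea_exhaustive_p <- function(vals, g1, set_genes, weight_p = 1) {
  n <- ncol(vals); n1 <- sum(g1)
  obs <- oracle_es(oracle_metric(vals, g1), set_genes, weight_p)
  assigns <- utils::combn(n, n1, simplify = FALSE)
  null_es <- vapply(assigns, function(ix) {
    g <- logical(n); g[ix] <- TRUE
    oracle_es(oracle_metric(vals, g), set_genes, weight_p)
  }, numeric(1))
  list(es = obs, p = mean(abs(null_es) >= abs(obs) * (1 - 1e-9)),
       null = null_es)
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of rank assignments
oracle_wilcox_p <- function(x, y) {
  n <- length(x) + length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  subsets <- utils::combn(n, length(x), simplify = FALSE)
  w_all <- vapply(subsets, function(ix) {
    sum(seq_len(n)[ix]) - length(x) * (length(x) + 1) / 2
  }, numeric(1))
  mu <- length(x) * length(y) / 2
  if (w_obs > mu) p <- 2 * mean(w_all >= w_obs)
  else if (w_obs < mu) p <- 2 * mean(w_all <= w_obs)
  else p <- 1
  min(1, p)
}

# Fisher exact p by enumeration of all tables with the observed margins
oracle_fisher_enum <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  log_fact <- lgamma(seq_len(sum(tab) + 1))
  lf <- function(k) log_fact[k + 1]
  log_prob <- function(m) {
    sum(lf(rowSums(m))) + sum(lf(colSums(m))) - lf(sum(m)) - sum(lf(m))
  }
  tables <- list()
  fill <- function(m, r, c) {
    if (r == nrow(tab)) {
      last <- cs - colSums(m[seq_len(r - 1), , drop = FALSE])
      if (all(last >= 0) && sum(last) == rs[r]) {
        m[r, ] <- last
        tables[[length(tables) + 1]] <<- m
      }
      return(invisible())
    }
    rem_cols <- cs - colSums(m[seq_len(r - 1), , drop = FALSE])
    cells <- expand_counts(rs[r], pmin(rem_cols, rs[r]))
    for (row in cells) {
      m[r, ] <- row
      fill(m, r + 1, c)
    }
  }
  expand_counts <- function(total, caps) {
    if (length(caps) == 1) {
      if (total <= caps[1]) return(list(total)) else return(list())
    }
    out <- list()
    for (k in 0:min(total, caps[1])) {
      for (rest in expand_counts(total - k, caps[-1])) {
        out[[length(out) + 1]] <- c(k, rest)
      }
    }
    out
  }
  m0 <- matrix(0L, nrow(tab), ncol(tab))
  fill(m0, 1, 1)
  lp <- vapply(tables, log_prob, numeric(1))
  lp_obs <- log_prob(tab)
  sum(exp(lp[lp <= lp_obs + 1e-7]))
}

# brute-force non-negative least squares over support subsets (small K only)
oracle_nnls <- function(ref, mix) {
  k <- ncol(ref)
  best <- NULL
  for (sz in seq_len(k)) {
    for (sup in utils::combn(k, sz, simplify = FALSE)) {
      co <- tryCatch(stats::coef(stats::lm.fit(ref[, sup, drop = FALSE], mix)),
                     error = function(e) NULL)
      if (is.null(co) || any(is.na(co)) || any(co < -1e-10)) next
      resid <- mix - ref[, sup, drop = FALSE] %*% co
      rss <- sum(resid^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        w <- numeric(k); w[sup] <- pmax(co, 0)
        best <- list(w = w, rss = rss)
      }
    }
  }
  best$w
}
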