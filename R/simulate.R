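#' Synthetic cohort configuration
#'
#' Bundles the generative parameters of the synthetic TNBC cohort. Expression
#' is built on the log scale as a common tumor base profile plus
#' block-structured marker shifts plus Gaussian noise:
#' stromal/immune signature blocks carry the planted purity (their amplitudes
#' are calibrated at run time against the package's own ssGSEA response so
#' the ESTIMATE cosine formula approximately returns the planted purity),
#' cell-type marker blocks carry Dirichlet immune fractions scaled by total
#' immune content, and the CTLA-4 gene and ERK/AKT axis gene sets carry the
#' planted cluster labels as symmetric mean shifts (High `+shift`, Low
#' `-shift`, in units of the noise sd).
#'
#' @param n_samples cohort size (default 400).
#' @param n_genes number of genes (default 5000; at least 1500).
#' @param purity_range uniform bounds for planted purity (default 0.3-0.95).
#' @param celltypes immune cell-type names for the deconvolution blocks.
#' @param dirichlet_conc Dirichlet concentration for immune fractions.
#' @param ctla4_shift planted CTLA-4 mean shift, in noise-sd units, applied
#'   as +shift (High) / -shift (Low) (default 2.5, so that the High/Low
#'   separation of 5 sd keeps the single-gene misclassification floor of a
#'   median split well under the 5% recovery budget).
#' @param axis_shift planted ERK/AKT gene set mean shift, +/- in noise-sd
#'   units (default 1).
#' @param noise_sd Gaussian noise standard deviation (default 1).
#' @param responder_prob per-cluster probability that a sample is a
#'   responder, named by ERK-axis cluster.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 400L, n_genes = 5000L,
                          purity_range = c(0.3, 0.95),
                          celltypes = c("T_CD4", "T_CD8", "NK", "B_CELL", "MONO"),
                          dirichlet_conc = rep(2, length(celltypes)),
                          ctla4_shift = 2.5, axis_shift = 1, noise_sd = 1,
                          responder_prob = c(HH = 0.61, HL = 0.40,
                                             LH = 0.50, LL = 0.50),
                          seed = 1L) {
  stopifnot(n_samples >= 8L, n_genes >= 1500L,
            length(purity_range) == 2L, purity_range[1L] < purity_range[2L],
            purity_range[1L] > 0, purity_range[2L] < 1,
            length(dirichlet_conc) == length(celltypes),
            all(dirichlet_conc > 0),
            is.finite(ctla4_shift), is.finite(axis_shift), noise_sd > 0,
            all(c("HH", "HL", "LH", "LL") %in% names(responder_prob)))
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 purity_range = purity_range, celltypes = celltypes,
                 dirichlet_conc = dirichlet_conc, ctla4_shift = ctla4_shift,
                 axis_shift = axis_shift, noise_sd = noise_sd,
                 responder_prob = responder_prob, seed = as.integer(seed)),
            class = "cohort_config")
}

# block layout over gene indices; names are stable across runs
cohort_blocks <- function(n_genes, celltypes) {
  sizes <- c(stromal = 150L, immune = 150L, cd4 = 50L, cd8 = 50L,
             erk1 = 40L, erk2 = 40L, erk3 = 40L,
             akt1 = 40L, akt2 = 40L, akt3 = 40L,
             prolif = 30L, tis = 20L, trm = 20L, isc = 20L)
  ct_sizes <- stats::setNames(rep(40L, length(celltypes)),
                              paste0("ct_", celltypes))
  sizes <- c(sizes, ct_sizes)
  marker_genes <- c("CTLA4", "CD80", "CD86", "GZMA", "PRF1")
  total <- sum(sizes) + length(marker_genes)
  stopifnot(n_genes >= total + 100L)
  gene_ids <- c(marker_genes,
                sprintf("G%05d", seq_len(n_genes - length(marker_genes))))
  idx <- length(marker_genes)
  blocks <- list()
  for (nm in names(sizes)) {
    blocks[[nm]] <- gene_ids[(idx + 1L):(idx + sizes[[nm]])]
    idx <- idx + sizes[[nm]]
  }
  list(gene_ids = gene_ids, blocks = blocks, markers = marker_genes)
}

# invert the ssGSEA response of a marker block on the base profile: returns a
# function mapping a target enrichment score to the block amplitude. The
# response is measured under the generator's own noise (averaged over a few
# replicates) so that noise-induced shrinkage near saturation does not bias
# the planted purity.
amplitude_calibration <- function(mu, gene_ids, block, noise_sd,
                                  amp_grid = seq(-16, 24, by = 1),
                                  n_rep = 6L) {
  pos <- match(block, gene_ids)
  scores <- vapply(amp_grid, function(a) {
    mean(vapply(seq_len(n_rep), function(r) {
      v <- mu + stats::rnorm(length(mu), 0, noise_sd)
      v[pos] <- v[pos] + a
      m <- matrix(v, ncol = 1L, dimnames = list(gene_ids, "cal"))
      unname(ssgsea_score(expr_matrix(m), block))
    }, numeric(1L)))
  }, numeric(1L))
  s <- cummax(scores)  # enforce monotone response before inverting
  keep <- !duplicated(s)
  stats::approxfun(s[keep], amp_grid[keep], rule = 2L)
}

#' Simulate a ground-truth TNBC expression cohort
#'
#' Generates a log-scale bulk expression matrix with planted purity, immune
#' fractions, CTLA-4/ERK/AKT cluster labels, and responder labels, together
#' with matching stand-in gene sets and a cell-type signature matrix so every
#' downstream stage runs unmodified. Bit-identical under a fixed seed.
#'
#' @param config a [cohort_config()].
#' @return List with elements `expression` ([expr_matrix()]), `truth`
#'   (tibble of per-sample planted values), `gene_sets`
#'   ([gene_set_collection()]), `signature_matrix` (gene-by-celltype
#'   matrix), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  lay <- cohort_blocks(config$n_genes, config$celltypes)
  b <- lay$blocks
  mu <- stats::rnorm(config$n_genes, mean = 6, sd = 1.5)
  names(mu) <- lay$gene_ids

  # planted truth ------------------------------------------------------
  purity <- stats::runif(n, config$purity_range[1L], config$purity_range[2L])
  immune_total <- (1 - purity) / 2  # immune and stromal split the non-tumor half
  frac <- t(vapply(seq_len(n), function(i) {
    g <- stats::rgamma(length(config$celltypes), shape = config$dirichlet_conc)
    g / sum(g)
  }, numeric(length(config$celltypes))))
  colnames(frac) <- config$celltypes
  half <- function() sample(rep_len(c("High", "Low"), n))
  ctla4_status <- half(); erk_status <- half(); akt_status <- half()
  erk_cluster <- paste0(substr(ctla4_status, 1, 1), substr(erk_status, 1, 1))
  akt_cluster <- paste0(substr(ctla4_status, 1, 1), substr(akt_status, 1, 1))
  responder <- stats::rbinom(n, 1L, config$responder_prob[erk_cluster]) == 1L

  # purity-calibrated stromal/immune amplitudes -------------------------
  est_target <- (acos(purity) - 0.6049872018) / 0.0001467884
  amp_str <- amplitude_calibration(mu, lay$gene_ids, b$stromal,
                                   config$noise_sd)(est_target / 2)
  amp_imm <- amplitude_calibration(mu, lay$gene_ids, b$immune,
                                   config$noise_sd)(est_target / 2)

  # assemble expression -------------------------------------------------
  sgn <- function(status) ifelse(status == "High", 1, -1)
  sd0 <- config$noise_sd
  x <- matrix(mu, nrow = config$n_genes, ncol = n,
              dimnames = list(lay$gene_ids, sprintf("S%04d", seq_len(n))))
  add_block <- function(x, genes, per_sample) {
    x[genes, ] <- x[genes, ] + rep(per_sample, each = length(genes))
    x
  }
  x <- add_block(x, b$stromal, amp_str)
  x <- add_block(x, b$immune, amp_imm)
  x <- add_block(x, b$cd4, 12 * immune_total * frac[, "T_CD4"])
  x <- add_block(x, b$cd8, 12 * immune_total * frac[, "T_CD8"])
  for (ct in config$celltypes) {
    x <- add_block(x, b[[paste0("ct_", ct)]], 25 * immune_total * frac[, ct])
  }
  for (nm in c("erk1", "erk2", "erk3")) {
    x <- add_block(x, b[[nm]], sgn(erk_status) * config$axis_shift * sd0)
  }
  for (nm in c("akt1", "akt2", "akt3")) {
    x <- add_block(x, b[[nm]], sgn(akt_status) * config$axis_shift * sd0)
  }
  x["CTLA4", ] <- x["CTLA4", ] + sgn(ctla4_status) * config$ctla4_shift * sd0 +
    8 * immune_total
  x["CD80", ] <- x["CD80", ] + 0.8 * sgn(ctla4_status) + 4 * immune_total
  x["CD86", ] <- x["CD86", ] + 0.9 * sgn(ctla4_status) + 4 * immune_total
  cyt_drive <- 10 * immune_total * (frac[, "T_CD8"] + frac[, "NK"])
  x["GZMA", ] <- x["GZMA", ] + cyt_drive
  x["PRF1", ] <- x["PRF1", ] + cyt_drive
  x <- add_block(x, b$prolif, ifelse(erk_cluster == "HH", -0.7, 0))
  x <- add_block(x, b$tis, 6 * immune_total + 0.4 * (ctla4_status == "High"))
  x <- add_block(x, b$trm, 6 * immune_total * frac[, "T_CD8"] +
                   0.4 * (erk_cluster == "HH"))
  x <- add_block(x, b$isc, 2 * as.numeric(responder) + 4 * immune_total)
  x <- x + matrix(stats::rnorm(length(x), 0, sd0), nrow = nrow(x))

  # companion objects ---------------------------------------------------
  sets <- gene_set_collection(
    list(ERK_CASCADE_UP = b$erk1, ERK_TARGETS = b$erk2, ERK_CASCADE = b$erk3,
         AKT_MTOR = b$akt1, AKT_TARGETS_CYTO = b$akt2, AKT_TARGETS_NUC = b$akt3,
         STROMAL_SIGNATURE = b$stromal, IMMUNE_SIGNATURE = b$immune,
         CD4_LYMPHOCYTE = b$cd4, CD8_LYMPHOCYTE = b$cd8,
         PROLIFERATION = b$prolif, TIS = b$tis, TRM = b$trm,
         ANTI_CTLA4_IS = b$isc),
    roles = c(rep("erk_axis", 3L), rep("akt_axis", 3L),
              rep("generic", 2L), rep("signature", 2L), rep("signature", 4L))
  )
  ct_sets <- gene_set_collection(
    stats::setNames(lapply(config$celltypes,
                           function(ct) b[[paste0("ct_", ct)]]),
                    config$celltypes),
    roles = "immune_celltype")
  sets <- gene_set_collection(c(unclass(sets), unclass(ct_sets)),
                              roles = c(attr(sets, "roles"),
                                        attr(ct_sets, "roles")))
  ref_genes <- unlist(lapply(config$celltypes,
                             function(ct) b[[paste0("ct_", ct)]]),
                      use.names = FALSE)
  ref <- vapply(config$celltypes, function(ct) {
    v <- mu[ref_genes]
    own <- ref_genes %in% b[[paste0("ct_", ct)]]
    v[own] <- v[own] + 10
    v
  }, numeric(length(ref_genes)))
  rownames(ref) <- ref_genes

  truth <- tibble::tibble(
    sample = colnames(x),
    purity = purity,
    immune_total = immune_total,
    ctla4_status = ctla4_status,
    erk_status = erk_status,
    akt_status = akt_status,
    erk_cluster = erk_cluster,
    akt_cluster = akt_cluster,
    responder = responder,
    seed = config$seed
  )
  truth <- dplyr::bind_cols(
    truth,
    tibble::as_tibble(frac * immune_total, .name_repair = ~ paste0("frac_", .x))
  )

  list(expression = expr_matrix(x), truth = truth, gene_sets = sets,
       signature_matrix = ref, config = config)
}

#' Simulate a clinical table with planted associations
#'
#' Emulates the structure of a small immunohistochemistry cohort: a CTLA-4
#' membrane score (`TC0`-`TC3`), tumor stage, smoking history, and
#' chemotherapy setting, with configurable odds ratios linking CTLA-4
#' positivity (TC1-TC3 vs TC0) to each covariate. Odds ratio 1 (the default)
#' plants no association.
#'
#' @param n number of cases.
#' @param score_probs probabilities of `TC0`-`TC3` (must sum to 1).
#' @param or named list/vector of odds ratios for `smoking`, `chemotherapy`
#'   and (Early-stage vs later) `stage` in CTLA-4-expressing vs negative
#'   cases.
#' @param seed integer seed.
#' @return A tibble (`case`, `score`, `expressing`, `stage`, `smoking`,
#'   `chemotherapy`).
#' @export
simulate_clinical_table <- function(n,
                                    score_probs = c(TC0 = 0.30, TC1 = 0.14,
                                                    TC2 = 0.42, TC3 = 0.14),
                                    or = c(stage = 1, smoking = 1,
                                           chemotherapy = 1),
                                    seed = 1L) {
  if (abs(sum(score_probs) - 1) > 1e-8) {
    stop("score probabilities must sum to 1", call. = FALSE)
  }
  stopifnot(all(c("TC0", "TC1", "TC2", "TC3") %in% names(score_probs)),
            all(or > 0))
  set.seed(seed)
  score <- sample(names(score_probs), n, replace = TRUE, prob = score_probs)
  expressing <- score != "TC0"
  shift_odds <- function(p0, o) (o * p0 / (1 - p0)) / (1 + o * p0 / (1 - p0))
  draw2 <- function(p, levels) {
    factor(ifelse(stats::runif(n) < p, levels[1L], levels[2L]), levels = levels)
  }
  p_smoke <- ifelse(expressing, shift_odds(0.4, or[["smoking"]]), 0.4)
  p_chemo <- ifelse(expressing, shift_odds(0.5, or[["chemotherapy"]]), 0.5)
  stage_base <- c(Early = 0.36, `Locally advanced` = 0.50, Metastasis = 0.14)
  pr_exp <- stage_base
  pr_exp["Early"] <- shift_odds(stage_base[["Early"]], or[["stage"]])
  pr_exp[-1L] <- stage_base[-1L] / sum(stage_base[-1L]) * (1 - pr_exp["Early"])
  stage <- character(n)
  stage[expressing] <- sample(names(stage_base), sum(expressing),
                              replace = TRUE, prob = pr_exp)
  stage[!expressing] <- sample(names(stage_base), sum(!expressing),
                               replace = TRUE, prob = stage_base)
  tibble::tibble(
    case = sprintf("C%03d", seq_len(n)),
    score = factor(score, levels = names(score_probs)),
    expressing = expressing,
    stage = factor(stage, levels = names(stage_base)),
    smoking = draw2(p_smoke, c("Yes", "No")),
    chemotherapy = draw2(p_chemo, c("Neoadyuvant", "Non-neoadyuvant"))
  )
}
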