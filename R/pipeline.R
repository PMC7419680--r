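#' Pipeline configuration
#'
#' A single configuration drives the end-to-end analysis. Either a synthetic
#' cohort is generated (`simulate` block: any [cohort_config()] arguments) or
#' file inputs are named (`inputs` block: `expression` TSV/GCT, `gene_sets`
#' GMT, optional `signature_matrix` TSV). All tuning knobs have defaults
#' matching the published procedure: purity gate 0.60 (strict), CD4*CD8
#' interaction-expansion adjustment, ssGSEA weight 0.25, 1000 permutations
#' for GSEA and deconvolution.
#'
#' @param config a named list or a path to a YAML file with the fields
#'   above plus `purity_threshold`, `covariate_mode`, `alpha`, `n_perm`,
#'   `seed`, `out_dir`.
#' @return Validated config list with class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(simulate = NULL, inputs = NULL, purity_threshold = 0.60,
                   covariate_mode = "interaction_expansion", alpha = 0.25,
                   n_perm = 1000L, seed = 1L, out_dir = NULL,
                   n_train = 148L)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    cfg$simulate <- list()
  }
  if (!is.null(cfg$inputs)) {
    for (f in c("expression", "gene_sets", "signature_matrix")) {
      p <- cfg$inputs[[f]]
      if (!is.null(p) && !file.exists(p)) {
        stop("input file not found: ", f, " = ", p, call. = FALSE)
      }
    }
    if (is.null(cfg$inputs$expression) || is.null(cfg$inputs$gene_sets)) {
      stop("inputs must name at least `expression` and `gene_sets`",
           call. = FALSE)
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the stratification pipeline end to end
#'
#' Stages, in order: ingest or simulate the cohort; per-sample MAD scaling;
#' stromal/immune scoring and the purity gate; CD4/CD8 infiltration scoring
#' and immune adjustment of CTLA-4; ERK/AKT axis combination and
#' median-split cluster assignment; signature scores (CYT, TIS,
#' proliferation, TRM, anti-CTLA-4 immune score) with Wilcoxon comparisons
#' against the HH reference; permutation GSEA of the activated-like
#' contrast; nu-SVR immune deconvolution; responder training/prediction and
#' cluster enrichment. Per-stage tables are written as TSV plus one
#' machine-readable JSON summary when `out_dir` is set.
#'
#' @param config a [pipeline_config()], or anything it accepts.
#' @return A list of per-stage results plus `summary` (the JSON content),
#'   invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  log_counts <- list()

  # ingest -------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$simulate)
    cohort <- do.call(cohort_config, sim_args)
    sim <- simulate_cohort(cohort)
    expr <- sim$expression; sets <- sim$gene_sets
    ref <- sim$signature_matrix; truth <- sim$truth
  } else {
    fmt <- if (grepl("\\.gct$", cfg$inputs$expression, ignore.case = TRUE))
      "gct" else "tsv"
    expr <- read_expression(cfg$inputs$expression, format = fmt)
    sets <- read_gmt(cfg$inputs$gene_sets)
    ref <- NULL; truth <- NULL
    if (!is.null(cfg$inputs$signature_matrix)) {
      tab <- utils::read.delim(cfg$inputs$signature_matrix, check.names = FALSE)
      ref <- as.matrix(tab[, -1L]); rownames(ref) <- tab[[1L]]
    }
  }
  log_counts$n_total <- ncol(expr)

  scaled <- mad_scale(expr)

  # purity gate ---------------------------------------------------------
  need_sets <- c("STROMAL_SIGNATURE", "IMMUNE_SIGNATURE", "CD4_LYMPHOCYTE",
                 "CD8_LYMPHOCYTE")
  if (!all(need_sets %in% names(sets))) {
    stop("gene sets must include ", paste(need_sets, collapse = ", "),
         call. = FALSE)
  }
  purity_tbl <- estimate_scores(scaled, sets[["STROMAL_SIGNATURE"]],
                                sets[["IMMUNE_SIGNATURE"]], alpha = cfg$alpha)
  retained <- filter_by_purity(purity_tbl, cfg$purity_threshold)
  log_counts$n_retained <- length(retained)
  if (length(retained) < 16L) stop("purity gate retained too few samples",
                                   call. = FALSE)
  sub <- expr_matrix(as_expr_values(scaled)[, retained, drop = FALSE],
                     provenance = provenance(scaled))

  # adjustment and stratification --------------------------------------
  infil <- infiltration_scores(sub, sets[["CD4_LYMPHOCYTE"]],
                               sets[["CD8_LYMPHOCYTE"]], alpha = cfg$alpha)
  if (!"CTLA4" %in% rownames(sub)) stop("CTLA4 not measured", call. = FALSE)
  adj_in <- dplyr::left_join(
    tibble::tibble(sample = colnames(sub), ctla4 = as_expr_values(sub)["CTLA4", ]),
    dplyr::left_join(infil,
                     purity_tbl[, c("sample", "estimate_score")], by = "sample"),
    by = "sample")
  adj <- adjust_ctla4(adj_in, mode = cfg$covariate_mode)
  erk_scores <- combine_axis_scores(ssgsea(sub, sets_with_role(sets, "erk_axis"),
                                           alpha = cfg$alpha))
  akt_scores <- combine_axis_scores(ssgsea(sub, sets_with_role(sets, "akt_axis"),
                                           alpha = cfg$alpha))
  clusters <- assign_clusters(tibble::tibble(
    sample = adj$data$sample,
    adjusted_ctla4 = adj$data$adjusted,
    erk_score = unname(erk_scores[adj$data$sample]),
    akt_score = unname(akt_scores[adj$data$sample])
  ))

  # signature scores ----------------------------------------------------
  sig_names <- intersect(c("PROLIFERATION", "TIS", "TRM", "ANTI_CTLA4_IS"),
                         names(sets))
  score_list <- c(list(CYT = cytolytic_score(sub)),
                  stats::setNames(lapply(sig_names, function(nm)
                    mean_signature_score(sub, sets[[nm]])), sig_names))
  scores_tbl <- purrr::map_dfr(names(score_list), function(nm) {
    tibble::tibble(sample = names(score_list[[nm]]), signature = nm,
                   score = unname(score_list[[nm]]))
  })
  comparisons <- purrr::map_dfr(names(score_list), function(nm) {
    dplyr::mutate(compare_groups(score_list[[nm]], clusters, axis = "erk"),
                  signature = nm, .before = 1L)
  })

  # GSEA of the activated-like contrast (HH vs HL) ---------------------
  hh_hl <- clusters$sample[clusters$erk_cluster %in% c("HH", "HL")]
  gsea_tbl <- NULL
  if (length(hh_hl) >= 8L) {
    centered <- median_center(expr_matrix(
      as_expr_values(sub)[, hh_hl, drop = FALSE],
      provenance = provenance(sub)))
    lab <- factor(
      as.character(clusters$erk_cluster[match(hh_hl, clusters$sample)]),
      levels = c("HH", "HL"))
    gsea_sets <- sets[setdiff(names(sets),
                              c("STROMAL_SIGNATURE", "IMMUNE_SIGNATURE"))]
    gsea_tbl <- gsea(centered, lab, gsea_sets, n_perm = cfg$n_perm,
                     seed = cfg$seed)
  }

  # deconvolution -------------------------------------------------------
  deconv <- NULL
  if (!is.null(ref)) {
    deconv <- deconvolve(sub, ref, n_perm = cfg$n_perm, seed = cfg$seed)
  }

  # responder model -----------------------------------------------------
  responder <- NULL
  if (!is.null(truth)) {
    feats <- tidyr::pivot_wider(scores_tbl, id_cols = "sample",
                                names_from = "signature",
                                values_from = "score")
    lab_all <- factor(ifelse(
      truth$responder[match(feats$sample, truth$sample)],
      "responder", "non_responder"))
    set.seed(cfg$seed)
    n_train <- min(cfg$n_train, floor(nrow(feats) / 2))
    train_idx <- sample(nrow(feats), n_train)
    model <- train_responder(feats[train_idx, ], lab_all[train_idx],
                             seed = cfg$seed)
    pred <- predict_responders(model, feats[-train_idx, ])
    names(pred) <- feats$sample[-train_idx]
    enrich <- responder_enrichment(pred, clusters, axis = "erk")
    responder <- list(model = model, predictions = pred, enrichment = enrich)
  }

  cluster_sizes <- as.list(table(clusters$erk_cluster))
  summary <- list(
    seed = cfg$seed,
    n_total = log_counts$n_total,
    n_retained = log_counts$n_retained,
    purity_threshold = cfg$purity_threshold,
    erk_cluster_sizes = cluster_sizes,
    akt_cluster_sizes = as.list(table(clusters$akt_cluster)),
    score_medians = lapply(split(scores_tbl$score, scores_tbl$signature),
                           stats::median),
    comparison_p = stats::setNames(as.list(comparisons$p),
                                   paste(comparisons$signature,
                                         comparisons$cluster, sep = "_vs_")),
    responder_p = if (!is.null(responder) && nrow(responder$enrichment))
      responder$enrichment$p[[1L]] else NULL
  )

  res <- list(purity = purity_tbl, retained = retained,
              infiltration = infil, adjustment = adj, clusters = clusters,
              scores = scores_tbl, comparisons = comparisons,
              gsea = gsea_tbl, deconvolution = deconv,
              responder = responder, truth = truth, summary = summary,
              config = cfg)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(tbl, nm) utils::write.table(
      tbl, file.path(cfg$out_dir, nm), sep = "\t", quote = FALSE,
      row.names = FALSE)
    w(purity_tbl, "purity.tsv")
    w(clusters, "clusters.tsv")
    w(scores_tbl, "scores.tsv")
    w(comparisons, "comparisons.tsv")
    if (!is.null(gsea_tbl)) w(gsea_tbl, "gsea.tsv")
    if (!is.null(deconv)) w(tidy(deconv), "deconvolution.tsv")
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}
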