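# End-to-end orchestration over the synthetic bundle, and TSV export.

#' Run the full analysis pipeline on a synthetic bundle
#'
#' Executes every stage in order: logistic CPP fitting, reference
#' statistics, interaction scoring and Warburg classification, profile
#' selection and recursive EM clustering, per-leaf GO enrichment, GTA scans
#' in both media, differential expression and UES/OES calling per
#' cell-line panel, and homology matching into the prediction table.
#' Every stage is also exported individually, so this function is a thin,
#' reproducible composition: all artifacts are regenerable from the
#' configuration and master seed alone.
#'
#' @param config a [sim_config()]; its `seed` drives the whole run.
#' @param bundle optionally a pre-built [simulate_bundle()] (must match
#'   `config`); built from `config` when `NULL`.
#' @param z_threshold enhancer/suppressor and profile-selection cutoff.
#' @param gta_value_threshold,gta_score_threshold GTA filter cutoffs.
#' @param alpha differential-expression significance level.
#' @param k_max,n_restarts,min_size,max_depth clustering controls (see
#'   [remc()]).
#' @return list of class `"phenogi_run"` with elements `bundle`, `cpps`,
#'   `refstats`, `scores`, `warburg`, `profiles`, `clusters`, `enrichment`,
#'   `gta`, `de`, `predictions`, `config`.
#' @export
run_pipeline <- function(config = sim_config(), bundle = NULL,
                         z_threshold = 2, gta_value_threshold = 2,
                         gta_score_threshold = 2, alpha = 0.05,
                         k_max = 8, n_restarts = 10, min_size = 8,
                         max_depth = 4) {
  if (is.null(bundle)) bundle <- simulate_bundle(config)
  cpps <- fit_cpps(bundle$phenomic$timeseries)
  refstats <- reference_stats(cpps)
  scores <- score_interactions(cpps, refstats, threshold = z_threshold)
  warburg <- classify_warburg(scores)
  profiles <- select_profiles(scores, threshold = z_threshold)
  clusters <- if (nrow(profiles) >= 2)
    remc(profiles, k_max = k_max, n_restarts = n_restarts,
         min_size = min_size, max_depth = max_depth,
         seed = child_seed(config$seed, 6L)) else NULL
  universe <- unique(scores$strain_id[!scores$no_growth_d0])
  enrichment <- NULL
  if (!is.null(clusters)) {
    enrichment <- do.call(rbind, lapply(names(clusters$leaves), function(nm) {
      e <- enrich_terms(clusters$leaves[[nm]], bundle$go, universe)
      if (nrow(e)) cbind(cluster = nm, e) else NULL
    }))
  }
  sig_enrich <- enrichment[!is.na(enrichment$p_adj) &
                             enrichment$p_adj < 0.05, , drop = FALSE]
  gta <- do.call(rbind, lapply(unique(scores$medium), function(m)
    gta_scan(scores, bundle$go, m,
             value_threshold = gta_value_threshold,
             score_threshold = gta_score_threshold,
             enrichment = sig_enrich)))
  de <- lapply(bundle$pharmaco, function(p)
    call_ues_oes(differential_expression(p$expression, p$sensitivity,
                                         p$tissue, stratify = TRUE),
                 alpha = alpha))
  predictions <- match_predictions(scores, bundle$homology, de)
  structure(list(bundle = bundle, cpps = cpps, refstats = refstats,
                 scores = scores, warburg = warburg, profiles = profiles,
                 clusters = clusters, enrichment = enrichment, gta = gta,
                 de = de, predictions = predictions, config = config),
            class = "phenogi_run")
}

#' @export
print.phenogi_run <- function(x, ...) {
  calls <- table(factor(x$scores$call, c("enhancer", "suppressor", "none",
                                         "conflict")))
  cat("Phenomic drug-gene interaction run\n")
  cat(sprintf("  cultures fitted: %d (%d no-growth)\n", nrow(x$cpps),
              sum(x$cpps$growth_flag == "no_growth")))
  cat(sprintf("  strain-medium scores: %d  [enh %d | sup %d | none %d | conflict %d]\n",
              nrow(x$scores), calls[1], calls[2], calls[3], calls[4]))
  cat(sprintf("  profiles selected: %d; clusters: %s\n", nrow(x$profiles),
              if (is.null(x$clusters)) "none" else
                length(x$clusters$leaves)))
  cat(sprintf("  GTA significant terms: %d; predictions: %d (%d priority)\n",
              sum(x$gta$significant), nrow(x$predictions),
              sum(x$predictions$priority)))
  invisible(x)
}

#' Write all pipeline artifacts as tab-separated files
#'
#' Long-format TSV, UTF-8, `"."` decimal, `NA` as empty field, plus a
#' plain-text run manifest recording the seed, thresholds and package
#' version.
#'
#' @param run a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "", fileEncoding = "UTF-8")
    p
  }
  paths <- c(
    wt(run$cpps, "cpps.tsv"),
    wt(run$refstats$ref_int, "ref_int.tsv"),
    wt(run$scores, "interaction_scores.tsv"),
    wt(run$warburg, "warburg_classes.tsv"),
    wt(data.frame(gene = rownames(run$profiles), run$profiles,
                  check.names = FALSE), "profiles.tsv"),
    if (!is.null(run$clusters)) wt(run$clusters$membership,
                                   "cluster_membership.tsv"),
    if (!is.null(run$enrichment)) wt(run$enrichment, "enrichment.tsv"),
    wt(run$gta, "gta.tsv"),
    wt(run$predictions, "predictions.tsv"))
  manifest <- c(
    sprintf("phenogi version: %s",
            as.character(utils::packageVersion("phenogi"))),
    sprintf("seed: %d", run$config$seed),
    sprintf("n_strains: %d", run$config$n_strains),
    sprintf("doses: %s", paste(run$config$doses, collapse = ",")),
    sprintf("generated: deterministic from config + seed"))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(c(paths, file.path(dir, "manifest.txt")))
}
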