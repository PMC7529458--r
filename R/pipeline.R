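#' Pipeline run configuration
#'
#' Collects every threshold of the analysis in one place so a run is fully
#' described by its configuration and seed: the localization cutoff (>0.75),
#' the minimum valid replicate count (2), the cluster count (4, or the
#' iterative selection with its 2 percent minimum cluster fraction), the
#' clustering iterations/restarts (10/1 for one condition, 25/2 for two),
#' the endpoint conversion (60 min horizon, 50/60 min columns, 0.85
#' correction), the steady-state fold threshold (2), the dependence factor
#' (1.5, i.e. >50 percent longer), and the motif significance level (0.05).
#' Unknown keys are rejected.
#'
#' @param min_localization Exclusive localization-probability cutoff.
#' @param min_valid Minimum valid replicates per averaged cell.
#' @param k Cluster count for fixed-k runs.
#' @param auto_k Use iterative cluster-count selection instead of fixed `k`.
#' @param k_min,min_cluster_fraction Parameters of [select_k()].
#' @param iterations,restarts k-means refinement parameters.
#' @param reference_ids,reference_mode Coverage-filter references (skipped
#'   when `reference_ids` is `NULL`).
#' @param endpoint_minutes,endpoints,correction Endpoint half-life
#'   parameters (see [endpoint_half_life()]).
#' @param fold_threshold Steady-state fold-change threshold.
#' @param dependence_factor Phosphatase-dependence ratio threshold.
#' @param alpha Motif significance level.
#' @param motif_mode,n_samples Motif enrichment mode and sampling depth.
#' @param crossmix_mode Cross-mix adjustment mode.
#' @param seed Master seed governing every stochastic stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(min_localization = 0.75, min_valid = 2,
                       k = 4, auto_k = FALSE, k_min = 3,
                       min_cluster_fraction = 0.02,
                       iterations = 10, restarts = 1,
                       reference_ids = NULL,
                       reference_mode = "count",
                       endpoint_minutes = 60, endpoints = c(50, 60),
                       correction = 0.85,
                       fold_threshold = 2, dependence_factor = 1.5,
                       alpha = 0.05, motif_mode = "sampling",
                       n_samples = 2000, crossmix_mode = "global",
                       seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

preprocess_sites <- function(set, config) {
  filtered <- filter_sites(set, min_localization = config$min_localization)
  imp <- impute_ratios(filtered$sites)
  m <- average_replicates(imp$set, min_valid = config$min_valid)
  coverage_removed <- 0L
  if (!is.null(config$reference_ids)) {
    rf <- reference_filter(m, config$reference_ids, mode = config$reference_mode)
    m <- rf$matrix
    coverage_removed <- rf$report$removed[["coverage"]]
  }
  m <- zero_fill(m)
  list(matrix = m, sites = imp$set,
       report = list(filter = filtered$report, imputed = imp$n_imputed,
                     coverage_removed = coverage_removed,
                     zero_filled = attr(m, "n_zero_filled")))
}

#' Run the full single- or two-condition analysis
#'
#' Executes, in order: site filtering, per-replicate imputation, replicate
#' averaging, optional reference-profile coverage filtering, zero-filling,
#' kinetic clustering with half-life estimation, motif enrichment, and —
#' when a perturbed condition is supplied — cross-mix adjustment, joint
#' clustering, the phosphatase-dependence comparison and the steady-state
#' fold-change screen. Protein sets, when given, additionally get
#' endpoint-based destruction classification. Fully reproducible given the
#' configuration seed.
#'
#' @param sites Control-condition [phospho_sites()].
#' @param config A [run_config()].
#' @param proteins Optional [protein_set()] for endpoint half-lives.
#' @param perturbed_sites Optional perturbed-condition [phospho_sites()].
#' @param crossmix Optional [crossmix_table()] linking the conditions
#'   (required with `perturbed_sites`).
#' @param out_dir Optional directory; when given, result tables and a
#'   machine-readable JSON summary are written there.
#' @return An object of class `pipeline_result`: list with `matrix`,
#'   `clustering`, `motifs`, `summary` and, depending on inputs,
#'   `protein_half_lives`, `comparison`, `steady_state`.
#' @export
run_pipeline <- function(sites, config = run_config(), proteins = NULL,
                         perturbed_sites = NULL, crossmix = NULL,
                         out_dir = NULL) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  two_condition <- !is.null(perturbed_sites)
  if (two_condition && is.null(crossmix))
    stop("a two-condition run requires a cross-mix table")

  pre <- preprocess_sites(sites, config)
  out <- list(config = config)

  if (!two_condition) {
    m <- pre$matrix
    clustering <- cluster_profiles(m, k = config$k,
                                   iterations = config$iterations,
                                   restarts = config$restarts,
                                   seed = config$seed)
    motifs <- summarize_cluster_motifs(pre$sites, clustering,
                                       alpha = config$alpha,
                                       mode = config$motif_mode,
                                       n_samples = config$n_samples,
                                       seed = config$seed)
    out$matrix <- m
  } else {
    pre_b <- preprocess_sites(perturbed_sites, config)
    adj <- crosswise_adjust(pre_b$matrix, crossmix, mode = config$crossmix_mode)
    joint <- concatenate_conditions(pre$matrix, adj)
    ordering <- attr(joint$matrix, "condition_split")$a
    if (config$auto_k) {
      sel <- select_k(joint$matrix, k_min = config$k_min,
                      min_cluster_fraction = config$min_cluster_fraction,
                      iterations = config$iterations, restarts = config$restarts,
                      seed = config$seed, ordering_columns = ordering)
      clustering <- sel$result
    } else {
      clustering <- cluster_profiles(joint$matrix, k = config$k,
                                     iterations = config$iterations,
                                     restarts = config$restarts,
                                     seed = config$seed,
                                     ordering_columns = ordering)
    }
    motifs <- summarize_cluster_motifs(pre$sites, clustering,
                                       alpha = config$alpha,
                                       mode = config$motif_mode,
                                       n_samples = config$n_samples,
                                       seed = config$seed)
    out$matrix <- joint$matrix
    out$noisy_ids <- joint$noisy_ids
    out$comparison <- compare_conditions(clustering, joint$matrix,
                                         dependence_factor = config$dependence_factor)
    out$steady_state <- steady_state_fold_change(pre$matrix, adj,
                                                 threshold = config$fold_threshold)
  }
  out$clustering <- clustering
  out$motifs <- motifs

  if (!is.null(proteins)) {
    pf <- filter_proteins(proteins)
    pim <- impute_ratios(pf$proteins)
    pm <- average_replicates(pim$set, min_valid = config$min_valid)
    out$protein_half_lives <- endpoint_half_life(
      pm, endpoint_minutes = config$endpoint_minutes,
      endpoints = config$endpoints, correction = config$correction)
  }

  out$summary <- pipeline_summary(out, pre)
  class(out) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_results(out, out_dir)
  out
}

pipeline_summary <- function(out, pre) {
  cl <- out$clustering
  s <- list(
    sites_input = pre$report$filter$input,
    sites_removed = as.list(pre$report$filter$removed),
    cells_imputed = pre$report$imputed,
    coverage_removed = pre$report$coverage_removed,
    cells_zero_filled = pre$report$zero_filled,
    sites_clustered = length(cl$assignments),
    k = cl$k,
    cluster_half_lives = stats::setNames(as.list(cl$clusters$half_life),
                                         cl$clusters$label),
    seed = out$config$seed,
    thresholds = list(min_localization = out$config$min_localization,
                      min_valid = out$config$min_valid,
                      correction = out$config$correction,
                      endpoint_minutes = out$config$endpoint_minutes,
                      fold_threshold = out$config$fold_threshold,
                      dependence_factor = out$config$dependence_factor,
                      alpha = out$config$alpha))
  if (!is.null(out$comparison)) {
    s$dependent_clusters <- out$comparison$cluster[out$comparison$dependent]
    s$noisy_sites <- length(out$noisy_ids)
  }
  if (!is.null(out$steady_state))
    s$steady_state_flagged <- length(out$steady_state$flagged)
  if (!is.null(out$protein_half_lives))
    s$proteins_by_destruction_class <-
      as.list(table(out$protein_half_lives$class))
  s
}

write_pipeline_results <- function(out, out_dir) {
  window <- max(out$matrix$timepoints)
  tables <- list(
    cluster_assignments = data.frame(id = names(out$clustering$assignments),
                                     cluster = unname(out$clustering$assignments),
                                     stringsAsFactors = FALSE),
    cluster_half_lives = out$clustering$clusters)
  for (lab in names(out$motifs$enrichments)) {
    enr <- out$motifs$enrichments[[lab]]
    if (!is.null(enr))
      tables[[paste0("motif_", gsub("[^A-Za-z0-9]", "_", lab))]] <-
        as.data.frame(enr)
  }
  if (!is.null(out$comparison))
    tables$condition_comparison <- as.data.frame(out$comparison)
  if (!is.null(out$steady_state))
    tables$steady_state <- data.frame(
      id = names(out$steady_state$fold_changes),
      fold_change = unname(out$steady_state$fold_changes),
      flagged = names(out$steady_state$fold_changes) %in% out$steady_state$flagged,
      stringsAsFactors = FALSE)
  if (!is.null(out$protein_half_lives))
    tables$protein_half_lives <- out$protein_half_lives
  write_results(tables, out_dir, window = window)
  summary_clean <- out$summary
  summary_clean$cluster_half_lives <- lapply(summary_clean$cluster_half_lives,
                                             function(h) if (is.infinite(h)) sprintf(">%g", window) else h)
  jsonlite::write_json(summary_clean, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d sites clustered into %d groups\n",
              x$summary$sites_clustered, x$summary$k))
  print(x$clustering)
  invisible(x)
}
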