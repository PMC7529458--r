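# Kinetic clustering: agglomerative clustering (Euclidean distance, average
# linkage) cut at k, refined by Lloyd k-means from the agglomerative
# centroids plus seeded random restarts. The hybrid honors both the
# hierarchical-clustering procedure and its iteration/restart parameters
# while staying deterministic under a seed. Zero-filled cells participate in
# the distance as real values.

#' Cluster ratio profiles into kinetic classes
#'
#' Partitions the rows of a zero-filled ratio matrix into `k` clusters and
#' relabels the clusters by ascending half-life of their mean profile. With
#' `k = 4` and exactly one never-decaying cluster the canonical kinetic
#' names early / intermediate / late / stable are assigned; otherwise
#' clusters are named `C1..Ck` in half-life order, infinite last.
#'
#' @param m A [ratio_matrix()] without missing values (see [zero_fill()]).
#' @param k Number of clusters (at least 2, at most the row count).
#' @param iterations k-means refinement iterations (10 for a single
#'   condition, 25 when comparing two, following the original analysis).
#' @param restarts Number of seeded random k-means restarts in addition to
#'   the agglomerative initialization (1 and 2 respectively).
#' @param seed Integer seed governing the restarts.
#' @param ordering_columns Optional column indices used when computing the
#'   per-cluster half-life for label ordering (e.g. the control half of a
#'   concatenated two-condition matrix); defaults to all columns.
#' @return An object of class `cluster_result`: `k`, `assignments` (named
#'   vector row id to cluster label), `clusters` (data frame of label, n,
#'   half_life), `profiles` (per-cluster mean/SEM data frames) and `seed`.
#' @export
cluster_profiles <- function(m, k, iterations = 10, restarts = 1, seed = 1,
                             ordering_columns = NULL) {
  values <- m$values
  if (anyNA(values))
    stop("matrix contains missing values; apply zero_fill() before clustering")
  n <- nrow(values)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k exceeds the number of rows")

  hc <- stats::hclust(stats::dist(values, method = "euclidean"),
                      method = "average")
  assign0 <- stats::cutree(hc, k = k)
  centers <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(values[assign0 == g, , drop = FALSE])))

  run_kmeans <- function(centers_or_k) {
    tryCatch(
      suppressWarnings(stats::kmeans(values, centers = centers_or_k,
                                     iter.max = max(iterations, 1),
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
  }

  best_assign <- assign0
  best_wss <- within_cluster_ss(values, assign0)
  km <- run_kmeans(centers)
  if (!is.null(km) && sum(km$withinss) < best_wss) {
    best_assign <- km$cluster
    best_wss <- sum(km$withinss)
  }
  if (restarts > 0) {
    for (j in seq_len(restarts)) {
      km_j <- with_seed(derive_seed(seed, 100L + j), run_kmeans(k))
      if (!is.null(km_j) && length(unique(km_j$cluster)) == k &&
          sum(km_j$withinss) < best_wss) {
        best_assign <- km_j$cluster
        best_wss <- sum(km_j$withinss)
      }
    }
  }

  finalize_cluster_result(m, best_assign, k, seed, ordering_columns)
}

within_cluster_ss <- function(values, assign) {
  total <- 0
  for (g in unique(assign)) {
    v <- values[assign == g, , drop = FALSE]
    total <- total + sum(sweep(v, 2, colMeans(v))^2)
  }
  total
}

finalize_cluster_result <- function(m, assign, k, seed, ordering_columns) {
  values <- m$values
  if (is.null(ordering_columns)) ordering_columns <- seq_len(ncol(values))
  tp <- m$timepoints[ordering_columns]

  groups <- sort(unique(assign))
  info <- lapply(groups, function(g) {
    members <- values[assign == g, ordering_columns, drop = FALSE]
    chl <- tryCatch(cluster_half_life(members, tp), error = function(e) NULL)
    hl <- if (is.null(chl) || is.na(chl$half_life)) Inf else chl$half_life
    list(group = g, n = sum(assign == g), half_life = hl)
  })
  hls <- vapply(info, `[[`, numeric(1), "half_life")
  sizes <- vapply(info, `[[`, numeric(1), "n")
  ord <- order(hls, -sizes)

  labels <- cluster_labels(hls[ord], k)
  label_of_group <- stats::setNames(labels, vapply(info[ord], `[[`, numeric(1), "group"))
  assignments <- stats::setNames(unname(label_of_group[as.character(assign)]),
                                 rownames(values))

  profiles <- stats::setNames(lapply(info[ord], function(x) {
    members <- values[assign == x$group, , drop = FALSE]
    sem <- if (nrow(members) == 1L) rep(0, ncol(members))
           else apply(members, 2, stats::sd) / sqrt(nrow(members))
    data.frame(timepoint = m$timepoints, mean = colMeans(members), sem = sem)
  }), labels)

  structure(list(
    k = k,
    assignments = assignments,
    clusters = data.frame(label = labels, n = sizes[ord],
                          half_life = hls[ord], stringsAsFactors = FALSE),
    profiles = profiles,
    seed = seed,
    ordering_columns = ordering_columns),
    class = "cluster_result")
}

cluster_labels <- function(sorted_half_lives, k) {
  if (k == 4 && sum(is.infinite(sorted_half_lives)) == 1)
    return(c("early", "intermediate", "late", "stable"))
  sprintf("C%d", seq_len(k))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster result: k = %d, %d rows\n", x$k, length(x$assignments)))
  df <- x$clusters
  df$half_life <- ifelse(is.infinite(df$half_life), "> window",
                         sprintf("%.2f min", df$half_life))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Iteratively choose the number of clusters
#'
#' Starting from `k_min`, the cluster count is increased until a partition
#' produces a random grouping containing very few identifications: the
#' largest `k` for which every cluster still holds at least
#' `min_cluster_fraction` of the rows is accepted, and the first violating
#' `k` rejected. Used when comparing conditions, where the appropriate
#' number of groupings is not known in advance.
#'
#' @inheritParams cluster_profiles
#' @param k_min Smallest cluster count tried (default 3).
#' @param k_max Largest cluster count tried (default `min(12, rows - 1)`).
#' @param min_cluster_fraction Minimum fraction of rows per cluster
#'   (default 0.02).
#' @return List with `k` (the accepted count) and `result` (its
#'   `cluster_result`).
#' @export
select_k <- function(m, k_min = 3, k_max = NULL, min_cluster_fraction = 0.02,
                     iterations = 25, restarts = 2, seed = 1,
                     ordering_columns = NULL) {
  n <- nrow(m$values)
  if (is.null(k_max)) k_max <- max(k_min, min(12, n - 1))
  min_size <- min_cluster_fraction * n
  accepted <- NULL
  for (k in seq(k_min, k_max)) {
    res <- cluster_profiles(m, k, iterations = iterations, restarts = restarts,
                            seed = seed, ordering_columns = ordering_columns)
    if (min(res$clusters$n) >= min_size) {
      accepted <- list(k = k, result = res)
    } else {
      break
    }
  }
  if (is.null(accepted)) {
    warning(sprintf("no k in [%d, %d] keeps every cluster above %.1f%% of rows; returning k = %d",
                    k_min, k_max, 100 * min_cluster_fraction, k_min))
    accepted <- list(k = k_min,
                     result = cluster_profiles(m, k_min, iterations = iterations,
                                               restarts = restarts, seed = seed,
                                               ordering_columns = ordering_columns))
  }
  accepted
}

#' Concatenate two conditions into a joint matrix for clustering
#'
#' Rows quantified in both conditions are joined as
#' `[control timepoints | perturbed timepoints]` profiles for joint
#' clustering; rows present in only one condition are diverted to a noisy
#' category rather than silently dropped.
#'
#' @param m_a,m_b [ratio_matrix()] objects for the two conditions.
#' @return List with `matrix` (the joint `ratio_matrix`, carrying a
#'   `condition_split` attribute describing the two column blocks) and
#'   `noisy_ids` (row ids present in only one condition).
#' @export
concatenate_conditions <- function(m_a, m_b) {
  ids_a <- rownames(m_a$values)
  ids_b <- rownames(m_b$values)
  shared <- intersect(ids_a, ids_b)
  if (length(shared) == 0L) stop("conditions share no row identifiers")
  noisy <- setdiff(union(ids_a, ids_b), shared)
  values <- cbind(m_a$values[shared, , drop = FALSE],
                  m_b$values[shared, , drop = FALSE])
  # Joint column coordinates: the two grids back-to-back; the original
  # timepoints are recovered through the condition_split attribute.
  joint_tp <- c(m_a$timepoints, max(m_a$timepoints) + m_b$timepoints + 1)
  colnames(values) <- make.unique(c(format_timepoint(m_a$timepoints),
                                    format_timepoint(m_b$timepoints)))
  joint <- ratio_matrix(values, joint_tp,
                        condition = paste(m_a$condition, m_b$condition, sep = "+"))
  attr(joint, "condition_split") <- list(
    a = seq_along(m_a$timepoints),
    b = length(m_a$timepoints) + seq_along(m_b$timepoints),
    timepoints_a = m_a$timepoints, timepoints_b = m_b$timepoints,
    condition_a = m_a$condition, condition_b = m_b$condition)
  list(matrix = joint, noisy_ids = noisy)
}

#' Apply the phosphatase-dependence rule to a joint clustering
#'
#' For every cluster of a jointly clustered two-condition matrix, the
#' average phospho-site half-life is computed separately on the control and
#' perturbed sub-profiles (`"mean-of-fits"` by default: each member is
#' fitted and the finite half-lives averaged). A cluster is flagged as
#' phosphatase-dependent when the perturbed half-life is more than
#' `dependence_factor` times the control half-life (strict inequality), or
#' when the perturbed half-life is the greater-than-window sentinel while
#' the control half-life is finite.
#'
#' @param result A `cluster_result` computed on a joint matrix.
#' @param joint The joint [ratio_matrix()] from [concatenate_conditions()].
#' @param dependence_factor Ratio threshold (default 1.5, i.e. a half-life
#'   more than 50 percent longer).
#' @param mode Half-life convention passed to [cluster_half_life()].
#' @return An object of class `comparison_result`: data frame with one row
#'   per cluster (`cluster`, `n`, `control_half_life`,
#'   `perturbed_half_life`, `ratio`, `dependent`).
#' @export
compare_conditions <- function(result, joint, dependence_factor = 1.5,
                               mode = c("mean-of-fits", "fit-of-mean")) {
  mode <- match.arg(mode)
  split <- attr(joint, "condition_split")
  if (is.null(split))
    stop("joint matrix lacks a condition_split; use concatenate_conditions()")
  rows <- lapply(result$clusters$label, function(lab) {
    ids <- names(result$assignments)[result$assignments == lab]
    v <- joint$values[ids, , drop = FALSE]
    hl_a <- cluster_half_life(v[, split$a, drop = FALSE], split$timepoints_a,
                              mode = mode)$half_life
    hl_b <- cluster_half_life(v[, split$b, drop = FALSE], split$timepoints_b,
                              mode = mode)$half_life
    ratio <- if (is.finite(hl_a) && is.finite(hl_b)) hl_b / hl_a else NA_real_
    dependent <- (is.finite(hl_a) && is.finite(hl_b) &&
                    hl_b > dependence_factor * hl_a) ||
                 (is.finite(hl_a) && is.infinite(hl_b))
    data.frame(cluster = lab, n = length(ids), control_half_life = hl_a,
               perturbed_half_life = hl_b, ratio = ratio,
               dependent = dependent, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("comparison_result", "data.frame"),
            dependence_factor = dependence_factor, mode = mode)
}
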