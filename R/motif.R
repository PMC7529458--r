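# Position-specific residue enrichment of cluster sequence windows against a
# background set, in the iceLogo style: per (position, residue), the
# experimental frequency is compared with the sampling distribution of the
# frequency in same-sized subsets of the reference set, and only differences
# with p < alpha are considered.

#' Build an aligned sequence-window set
#'
#' @param windows Character vector of aligned odd-length windows over the 20
#'   amino acids plus `_` padding, centered on the phospho-residue. May also
#'   be a [phospho_sites()] object, whose windows are used.
#' @param assignments Optional named cluster assignment vector (site id to
#'   label) as produced by [cluster_profiles()]; with `cluster`, restricts
#'   the set to one cluster.
#' @param cluster Optional cluster label to select.
#' @param width Optional target width; wider stored windows are trimmed
#'   symmetrically around the center.
#' @return An object of class `window_set` with `windows` and `center`
#'   (index of position 0).
#' @export
build_window_set <- function(windows, assignments = NULL, cluster = NULL,
                             width = NULL) {
  meta_ids <- NULL
  if (inherits(windows, "phospho_sites")) {
    meta_ids <- windows$meta$site_id
    windows <- windows$meta$sequence_window
  }
  if (!is.null(cluster)) {
    if (is.null(assignments)) stop("selecting a cluster requires assignments")
    ids <- names(assignments)[assignments == cluster]
    if (is.null(meta_ids)) stop("selecting a cluster requires a phospho_sites input")
    windows <- windows[match(ids, meta_ids)]
    windows <- windows[!is.na(windows)]
  }
  if (length(windows)) {
    wl <- unique(nchar(windows))
    if (length(wl) > 1L) stop("all windows must have the same length")
    if (wl %% 2 == 0) stop("windows must have odd length")
    if (!is.null(width)) {
      if (width %% 2 == 0 || width > wl)
        stop("width must be odd and no wider than the stored windows")
      trim <- (wl - width) / 2
      windows <- substr(windows, trim + 1, wl - trim)
      wl <- width
    }
  } else {
    wl <- if (is.null(width)) 0L else width
  }
  structure(list(windows = windows,
                 center = if (length(windows)) (wl + 1) / 2 else NA_integer_),
            class = "window_set")
}

as_window_set <- function(x, width = NULL) {
  if (inherits(x, "window_set")) x else build_window_set(x, width = width)
}

window_char_matrix <- function(ws) {
  do.call(rbind, strsplit(ws$windows, "", fixed = TRUE))
}

# Per-position residue frequencies over the 20 amino acids, excluding
# padding from the denominator so truncated windows at protein termini do
# not dilute the composition. Returns a 20 x width matrix plus the
# non-padding count per position.
position_frequencies <- function(chars) {
  width <- ncol(chars)
  freq <- matrix(0, nrow = length(AMINO_ACIDS), ncol = width,
                 dimnames = list(AMINO_ACIDS, NULL))
  n_eff <- integer(width)
  for (p in seq_len(width)) {
    col <- chars[, p]
    col <- col[col != PAD_CHAR]
    n_eff[p] <- length(col)
    if (length(col))
      freq[, p] <- tabulate(factor(col, levels = AMINO_ACIDS),
                            nbins = length(AMINO_ACIDS)) / length(col)
  }
  list(freq = freq, n_eff = n_eff)
}

#' Position-specific residue enrichment against a reference set
#'
#' For every window position and residue, compares the experimental
#' frequency with the distribution of frequencies in reference subsets of
#' the experimental size. In `"sampling"` mode (the iceLogo approach) that
#' distribution is estimated from `n_samples` seeded random draws; in
#' `"analytic"` mode it is the binomial normal approximation
#' `sd = sqrt(mu (1 - mu) / n)`, which is deterministic. Two-sided normal
#' p-values are reported, significance is `p < alpha`, and the percent
#' difference `100 (f_exp - mu)` is the signed effect size. When a residue
#' is absent from (or fixed in) the reference the sampling sd is zero; such
#' cells carry an infinite z sentinel and are significant exactly when the
#' experimental frequency differs.
#'
#' @param experimental,reference [build_window_set()] objects (or character
#'   vectors of windows) of equal width; both non-empty.
#' @param alpha Significance level (default 0.05).
#' @param mode `"sampling"` or `"analytic"`.
#' @param n_samples Number of reference subsets drawn in sampling mode.
#' @param seed Seed for the sampling draws (output is bit-identical for a
#'   fixed seed).
#' @return An object of class `motif_enrichment`: data frame with columns
#'   `position` (offset from the phospho-residue), `residue`, `freq_exp`,
#'   `freq_ref`, `pct_diff`, `z`, `p_value`, `significant`.
#' @export
enrichment <- function(experimental, reference, alpha = 0.05,
                       mode = c("sampling", "analytic"), n_samples = 2000,
                       seed = 1) {
  mode <- match.arg(mode)
  experimental <- as_window_set(experimental)
  reference <- as_window_set(reference)
  if (length(experimental$windows) == 0L || length(reference$windows) == 0L)
    stop("both window sets must be non-empty")
  if (nchar(experimental$windows[1]) != nchar(reference$windows[1]))
    stop("experimental and reference windows must have the same width")

  exp_chars <- window_char_matrix(experimental)
  ref_chars <- window_char_matrix(reference)
  width <- ncol(exp_chars)
  fe <- position_frequencies(exp_chars)

  if (mode == "analytic") {
    fr <- position_frequencies(ref_chars)
    mu <- fr$freq
    sigma <- sqrt(mu * (1 - mu) / rep(pmax(fe$n_eff, 1), each = nrow(mu)))
  } else {
    n_exp <- nrow(exp_chars)
    n_ref <- nrow(ref_chars)
    codes <- matrix(match(ref_chars, c(AMINO_ACIDS, PAD_CHAR)),
                    nrow = n_ref, ncol = width)
    acc <- matrix(0, nrow = length(AMINO_ACIDS), ncol = width)
    acc2 <- matrix(0, nrow = length(AMINO_ACIDS), ncol = width)
    with_seed(derive_seed(seed, 7L), {
      for (s in seq_len(n_samples)) {
        idx <- sample.int(n_ref, n_exp, replace = TRUE)
        sub <- codes[idx, , drop = FALSE]
        for (p in seq_len(width)) {
          counts <- tabulate(sub[, p], nbins = length(AMINO_ACIDS) + 1L)
          denom <- n_exp - counts[length(AMINO_ACIDS) + 1L]
          f <- if (denom > 0) counts[seq_along(AMINO_ACIDS)] / denom else
            rep(0, length(AMINO_ACIDS))
          acc[, p] <- acc[, p] + f
          acc2[, p] <- acc2[, p] + f * f
        }
      }
    })
    mu <- acc / n_samples
    sigma <- sqrt(pmax(acc2 / n_samples - mu^2, 0))
  }

  z <- (fe$freq - mu) / sigma
  zero_sd <- !is.finite(z) | sigma == 0
  z[zero_sd] <- ifelse(fe$freq[zero_sd] > mu[zero_sd], Inf,
                       ifelse(fe$freq[zero_sd] < mu[zero_sd], -Inf, 0))
  p <- 2 * stats::pnorm(-abs(z))
  p[is.infinite(z)] <- 0

  offsets <- seq_len(width) - experimental$center
  out <- data.frame(
    position = rep(offsets, each = length(AMINO_ACIDS)),
    residue = rep(AMINO_ACIDS, times = width),
    freq_exp = as.vector(fe$freq),
    freq_ref = as.vector(mu),
    pct_diff = 100 * as.vector(fe$freq - mu),
    z = as.vector(z),
    p_value = as.vector(p),
    stringsAsFactors = FALSE)
  out$significant <- out$p_value < alpha
  structure(out, class = c("motif_enrichment", "data.frame"),
            alpha = alpha, mode = mode,
            n_experimental = nrow(exp_chars), n_reference = nrow(ref_chars))
}

#' Per-cluster motif enrichment against the all-clustered background
#'
#' Runs [enrichment()] for every cluster's sequence windows against the
#' windows of all clustered sites (the negative set), and reports the
#' central-residue (S/T/Y) composition per cluster as a separate statistic.
#'
#' @param sites The [phospho_sites()] set the clustering was computed from.
#' @param result A `cluster_result` whose assignments refer to `sites`.
#' @param alpha Significance level.
#' @param mode,n_samples,seed Passed to [enrichment()].
#' @param width Optional window width (see [build_window_set()]).
#' @return List with `enrichments` (named list of `motif_enrichment`, one
#'   per cluster) and `central_composition` (data frame of cluster, n and
#'   S/T/Y fractions).
#' @export
summarize_cluster_motifs <- function(sites, result, alpha = 0.05,
                                     mode = c("sampling", "analytic"),
                                     n_samples = 2000, seed = 1, width = NULL) {
  mode <- match.arg(mode)
  assignments <- result$assignments
  background <- build_window_set(
    sites$meta$sequence_window[sites$meta$site_id %in% names(assignments)],
    width = width)
  labels <- result$clusters$label
  enrichments <- stats::setNames(lapply(labels, function(lab) {
    ws <- build_window_set(sites, assignments, cluster = lab, width = width)
    if (length(ws$windows) == 0L) return(NULL)
    enrichment(ws, background, alpha = alpha, mode = mode,
               n_samples = n_samples, seed = seed)
  }), labels)
  central <- do.call(rbind, lapply(labels, function(lab) {
    ws <- build_window_set(sites, assignments, cluster = lab, width = width)
    res <- substr(ws$windows, ws$center, ws$center)
    data.frame(cluster = lab, n = length(res),
               S = mean(res == "S"), T = mean(res == "T"), Y = mean(res == "Y"),
               stringsAsFactors = FALSE)
  }))
  list(enrichments = enrichments, central_composition = central)
}
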