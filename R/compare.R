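#' Cross-mix ratio table
#'
#' Holds the per-entity H/L ratios measured in cross-mixed t0 samples (equal
#' quantities of the light-labelled t0 of one condition and the
#' heavy-labelled t0 of the other), which quantify the steady-state offset
#' between two conditions, plus their global geometric mean used as a
#' fallback adjustment factor.
#'
#' @param entity_id Entity identifiers.
#' @param ratio Positive cross-mix H/L ratios, one per entity.
#' @return An object of class `crossmix_table`.
#' @export
crossmix_table <- function(entity_id, ratio) {
  if (length(entity_id) != length(ratio))
    stop("entity_id and ratio must have equal length")
  if (any(!is.finite(ratio) | ratio <= 0))
    stop("cross-mix ratios must be positive")
  if (anyDuplicated(entity_id)) stop("duplicate entity_id in cross-mix table")
  structure(list(ratios = stats::setNames(as.numeric(ratio), entity_id),
                 global_mean = geometric_mean(ratio)),
            class = "crossmix_table")
}

#' @export
print.crossmix_table <- function(x, ...) {
  cat(sprintf("Cross-mix table: %d entities, global mean ratio %.4g\n",
              length(x$ratios), x$global_mean))
  invisible(x)
}

#' Rescale a perturbed condition onto the control scale
#'
#' Divides every perturbed ratio by the entity's cross-mix ratio
#' (`mode = "per-entity"`) or by the global mean cross-mix ratio
#' (`mode = "global"`, the per-experiment fallback used when individual
#' cross-mix quantifications are unusable). Entities without cross-mix
#' coverage in per-entity mode fall back to the global mean with a warning.
#'
#' @param m The perturbed-condition [ratio_matrix()].
#' @param crossmix A [crossmix_table()].
#' @param mode `"per-entity"` or `"global"`.
#' @return The adjusted `ratio_matrix`.
#' @export
crosswise_adjust <- function(m, crossmix, mode = c("per-entity", "global")) {
  mode <- match.arg(mode)
  ids <- rownames(m$values)
  if (mode == "global") {
    factors <- rep(crossmix$global_mean, length(ids))
  } else {
    factors <- unname(crossmix$ratios[ids])
    uncovered <- is.na(factors)
    if (any(uncovered)) {
      warning(sprintf("%d entit%s lack cross-mix coverage; using the global mean ratio",
                      sum(uncovered), if (sum(uncovered) == 1) "y" else "ies"))
      factors[uncovered] <- crossmix$global_mean
    }
  }
  m$values <- m$values / factors
  m
}

#' Steady-state phosphorylation fold changes between conditions
#'
#' The steady-state level is the t = 0 ratio. Per entity shared between the
#' control matrix and the (already crosswise-adjusted) perturbed matrix, the
#' fold change is perturbed t0 over control t0; entities whose fold change
#' strictly exceeds `threshold` (default 2: steady-state phosphorylation
#' more than doubled) are flagged as candidate pre-anaphase phosphatase
#' substrates. Entities with a non-positive or missing control t0 are
#' skipped with a warning.
#'
#' @param control A control [ratio_matrix()].
#' @param perturbed The adjusted perturbed [ratio_matrix()].
#' @param threshold Strict fold-change threshold (default 2).
#' @return An object of class `steady_state_result`: list with
#'   `fold_changes` (named numeric), `flagged` (entity ids) and `threshold`.
#' @export
steady_state_fold_change <- function(control, perturbed, threshold = 2) {
  if (control$timepoints[1] != 0 || perturbed$timepoints[1] != 0)
    stop("both matrices must include a t = 0 column first")
  shared <- intersect(rownames(control$values), rownames(perturbed$values))
  if (length(shared) == 0L) stop("matrices share no entities")
  t0_c <- control$values[shared, 1]
  t0_p <- perturbed$values[shared, 1]
  usable <- !is.na(t0_c) & t0_c > 0 & !is.na(t0_p)
  if (any(!usable))
    warning(sprintf("%d entities skipped (missing or non-positive t0)",
                    sum(!usable)))
  fc <- stats::setNames(t0_p[usable] / t0_c[usable], shared[usable])
  structure(list(fold_changes = fc,
                 flagged = names(fc)[fc > threshold],
                 threshold = threshold),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("Steady-state comparison: %d entities, %d flagged (fold change > %g)\n",
              length(x$fold_changes), length(x$flagged), x$threshold))
  invisible(x)
}
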