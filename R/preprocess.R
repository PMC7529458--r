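#' Filter phospho-site records on flags and localization confidence
#'
#' Removes contaminants, reverse-database (decoy) identifications, sites
#' identified by modification site only, and sites whose localization
#' probability is not strictly greater than `min_localization`. Each removed
#' record is tallied under the first rule that catches it, in the order
#' contaminant, reverse, site-only, localization, so that removed plus
#' retained equals the input count.
#'
#' @param set A [phospho_sites()] object.
#' @param min_localization Exclusive localization-probability threshold
#'   (default 0.75: a site at exactly 0.75 is removed).
#' @return List with `sites` (the filtered set) and `report` (a
#'   `filter_report`).
#' @export
filter_sites <- function(set, min_localization = 0.75) {
  m <- set$meta
  loc_fail <- is.na(m$localization_prob) | m$localization_prob <= min_localization
  rule <- rep(NA_character_, nrow(m))
  rule[loc_fail] <- "localization"
  rule[m$site_only] <- "site_only"
  rule[m$reverse] <- "reverse"
  rule[m$contaminant] <- "contaminant"
  keep <- is.na(rule)
  counts <- c(contaminant = sum(rule == "contaminant", na.rm = TRUE),
              reverse = sum(rule == "reverse", na.rm = TRUE),
              site_only = sum(rule == "site_only", na.rm = TRUE),
              localization = sum(rule == "localization", na.rm = TRUE))
  list(sites = subset_records(set, keep),
       report = filter_report(input = nrow(m), removed = counts))
}

#' Filter protein records on decoy and contaminant flags
#'
#' @param set A [protein_set()] object.
#' @return List with `proteins` and `report`.
#' @export
filter_proteins <- function(set) {
  m <- set$meta
  rule <- rep(NA_character_, nrow(m))
  rule[m$reverse] <- "reverse"
  rule[m$contaminant] <- "contaminant"
  keep <- is.na(rule)
  counts <- c(contaminant = sum(rule == "contaminant", na.rm = TRUE),
              reverse = sum(rule == "reverse", na.rm = TRUE))
  list(proteins = subset_records(set, keep),
       report = filter_report(input = nrow(m), removed = counts))
}

filter_report <- function(input, removed, imputed = 0L, zero_filled = 0L) {
  structure(list(input = input, removed = removed,
                 retained = input - sum(removed),
                 imputed = imputed, zero_filled = zero_filled),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: %d in, %d retained\n", x$input, x$retained))
  for (nm in names(x$removed))
    cat(sprintf("  removed (%s): %d\n", nm, x$removed[[nm]]))
  if (x$imputed > 0) cat(sprintf("  imputed cells: %d\n", x$imputed))
  if (x$zero_filled > 0) cat(sprintf("  zero-filled cells: %d\n", x$zero_filled))
  invisible(x)
}

#' Replace isolated missing values in a ratio time series
#'
#' A single missing value is replaced by the mean of its two neighbours, or
#' by the single adjacent value when it sits at the first or last timepoint.
#' Runs of two or more consecutive missing values are left untouched (they
#' more likely represent a true absence than a missed quantification), and
#' present values are never altered.
#'
#' @param x Numeric vector ordered by timepoint; `NA` marks missing.
#' @return Vector of the same length with isolated gaps filled.
#' @export
impute_missing <- function(x) {
  n <- length(x)
  if (n == 0L || !anyNA(x)) return(x)
  miss <- is.na(x)
  if (all(miss)) return(x)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- x
  for (i in which(r$values & r$lengths == 1L)) {
    p <- starts[i]
    if (p == 1L) {
      out[p] <- x[2L]
    } else if (p == n) {
      out[p] <- x[n - 1L]
    } else {
      out[p] <- (x[p - 1L] + x[p + 1L]) / 2
    }
  }
  out
}

#' Impute isolated missing values in every replicate series of a record set
#'
#' Applies [impute_missing()] per record and replicate, before replicate
#' averaging, so each replicate's kinetics are preserved.
#'
#' @param set A [phospho_sites()] or [protein_set()] object.
#' @return List with `set` (imputed) and `n_imputed` (count of filled cells).
#' @export
impute_ratios <- function(set) {
  arr <- set$ratios
  n_before <- sum(is.na(arr))
  for (i in seq_len(dim(arr)[1]))
    for (r in seq_len(dim(arr)[2]))
      arr[i, r, ] <- impute_missing(arr[i, r, ])
  set$ratios <- arr
  list(set = set, n_imputed = n_before - sum(is.na(arr)))
}

#' Average replicate ratios per timepoint
#'
#' The t/t0 ratio for each timepoint is the arithmetic mean over replicates,
#' kept only when at least `min_valid` replicates contribute a value;
#' otherwise the cell is missing. Contribution counts are recorded as
#' provenance.
#'
#' @param set A [phospho_sites()] or [protein_set()] object (normally after
#'   [impute_ratios()]).
#' @param min_valid Minimum number of valid replicate values per cell
#'   (default 2).
#' @return A [ratio_matrix()].
#' @export
average_replicates <- function(set, min_valid = 2) {
  arr <- set$ratios
  if (dim(arr)[2] != length(set$design$replicates))
    stop("replicate dimension does not match the design")
  counts <- apply(!is.na(arr), c(1, 3), sum)
  sums <- apply(arr, c(1, 3), function(v) sum(v, na.rm = TRUE))
  values <- sums / counts
  values[counts < min_valid] <- NA_real_
  rownames(values) <- entity_ids(set)
  ratio_matrix(values, set$design$timepoints, provenance = counts,
               condition = set$design$condition)
}

#' Filter rows on temporal coverage relative to reference profiles
#'
#' Retains rows quantified at least as completely over time as designated
#' reference profiles (e.g. CCNB1 for proteolysis, PRC1-pT481 for
#' dephosphorylation). In `"count"` mode a row must have at least as many
#' non-missing timepoints as every reference row; in `"mask"` mode its
#' non-missing timepoints must cover every timepoint at which every
#' reference is quantified. Both readings of the coverage rule are provided
#' because the underlying procedure is ambiguous; `"count"` is the default.
#'
#' @param m A [ratio_matrix()].
#' @param reference_ids Row identifiers of the reference profiles; all must
#'   be present in `m`.
#' @param mode `"count"` or `"mask"`.
#' @return List with `matrix` (filtered) and `report`.
#' @export
reference_filter <- function(m, reference_ids, mode = c("count", "mask")) {
  mode <- match.arg(mode)
  absent <- setdiff(reference_ids, rownames(m$values))
  if (length(absent))
    stop("reference row(s) absent from matrix: ", paste(absent, collapse = ", "))
  present <- !is.na(m$values)
  if (mode == "count") {
    need <- max(rowSums(present[reference_ids, , drop = FALSE]))
    keep <- rowSums(present) >= need
  } else {
    ref_mask <- apply(present[reference_ids, , drop = FALSE], 2, all)
    keep <- apply(present, 1, function(p) all(p[ref_mask]))
  }
  list(matrix = subset_matrix_rows(m, keep),
       report = filter_report(input = nrow(m$values),
                              removed = c(coverage = sum(!keep))))
}

#' Replace remaining missing cells with 0
#'
#' Applied after the coverage filter so the clustering algorithm can operate
#' on complete rows; remaining gaps are runs of consecutive missing values
#' treated as true zeros. Idempotent.
#'
#' @param m A [ratio_matrix()].
#' @return The matrix with every missing cell set to 0 and the count of
#'   filled cells in attribute `"n_zero_filled"`.
#' @export
zero_fill <- function(m) {
  n <- sum(is.na(m$values))
  m$values[is.na(m$values)] <- 0
  attr(m, "n_zero_filled") <- n
  m
}

#' Scale a profile to a starting ratio of one
#'
#' @param x Numeric profile ordered by timepoint; the first value must be
#'   positive.
#' @return `x / x[1]`.
#' @export
normalize_to_start <- function(x) {
  if (length(x) == 0L) stop("empty profile")
  if (is.na(x[1]) || x[1] <= 0)
    stop("profile value at t = 0 must be positive to normalize")
  x / x[1]
}
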