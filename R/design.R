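#' Default mitotic-exit sampling grid
#'
#' Dense sampling every 30 s from 0 to 10 min after CDK inhibition, then
#' sparser points out to 60 min. All times in minutes.
#'
#' @return Numeric vector of timepoints.
#' @export
default_timepoints <- function() {
  c(seq(0, 10, by = 0.5), 12.5, 15, 20, 30, 40, 50, 60)
}

#' Describe the layout of a ratio time course
#'
#' A time-course design records the timepoint grid, the replicate labels, the
#' condition name and the naming pattern of the per-(replicate, timepoint)
#' ratio columns in MaxQuant-style tables. Under the dimethyl-labeling scheme
#' all timepoints carry the heavy label and the t = 0 sample the light label,
#' so the H/L ratio at time t measures level(t)/level(0).
#'
#' @param timepoints Strictly increasing times in minutes, first must be 0;
#'   at least 3 required.
#' @param replicates Character vector of replicate labels.
#' @param condition Condition label (e.g. `"control"`).
#' @param ratio_col_pattern Column-name template with `{rep}` and `{time}`
#'   placeholders. MaxQuant itself names ratio columns
#'   `"Ratio H/L normalized <experiment>"`; the experiment part is free text,
#'   so the pattern is configurable.
#' @return An object of class `time_course_design`.
#' @export
time_course_design <- function(timepoints = default_timepoints(),
                               replicates = paste0("R", 1:4),
                               condition = "control",
                               ratio_col_pattern = "Ratio H/L normalized {rep}_T{time}") {
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) < 3L) stop("design invalid: at least 3 timepoints required")
  if (timepoints[1] != 0) stop("design invalid: timepoint 0 must be present and first")
  if (any(diff(timepoints) <= 0)) stop("design invalid: timepoints must be strictly increasing")
  if (length(replicates) < 1L) stop("design invalid: at least one replicate required")
  if (anyDuplicated(replicates)) stop("design invalid: duplicate replicate labels")
  structure(
    list(timepoints = timepoints,
         replicates = as.character(replicates),
         condition = condition,
         ratio_col_pattern = ratio_col_pattern),
    class = "time_course_design")
}

format_timepoint <- function(t) sprintf("%g", t)

#' Ratio column names implied by a design
#'
#' @param design A [time_course_design()].
#' @return Character matrix with one row per replicate and one column per
#'   timepoint.
#' @export
ratio_column_names <- function(design) {
  out <- matrix("", nrow = length(design$replicates), ncol = length(design$timepoints),
                dimnames = list(design$replicates, format_timepoint(design$timepoints)))
  for (r in seq_along(design$replicates)) {
    for (t in seq_along(design$timepoints)) {
      x <- gsub("{rep}", design$replicates[r], design$ratio_col_pattern, fixed = TRUE)
      out[r, t] <- gsub("{time}", format_timepoint(design$timepoints[t]), x, fixed = TRUE)
    }
  }
  out
}

#' @export
print.time_course_design <- function(x, ...) {
  cat(sprintf("Time-course design (%s): %d timepoints (%g-%g min), %d replicates\n",
              x$condition, length(x$timepoints), min(x$timepoints),
              max(x$timepoints), length(x$replicates)))
  invisible(x)
}
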