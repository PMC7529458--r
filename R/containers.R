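#' Ratio matrix: entities x timepoints of averaged t/t0 ratios
#'
#' The analysis-ready container produced by [average_replicates()]: one row
#' per phospho-site or protein, one column per timepoint, holding the
#' replicate-averaged H/L ratio (which, under the labeling scheme, is the
#' t/t0 level). `provenance` counts how many replicates contributed to each
#' cell.
#'
#' @param values Numeric matrix (rows = entities, columns = timepoints) with
#'   row names; `NA` marks missing cells.
#' @param timepoints Times in minutes, one per column.
#' @param provenance Optional integer matrix of contributing replicate counts.
#' @param condition Condition label.
#' @return An object of class `ratio_matrix`.
#' @export
ratio_matrix <- function(values, timepoints, provenance = NULL, condition = "control") {
  values <- as.matrix(values)
  if (ncol(values) != length(timepoints))
    stop("column count must equal the number of timepoints")
  if (is.null(rownames(values))) stop("values must carry entity row names")
  if (any(values < 0, na.rm = TRUE)) stop("ratio values must be non-negative")
  colnames(values) <- format_timepoint(timepoints)
  structure(
    list(values = values, timepoints = as.numeric(timepoints),
         provenance = provenance, condition = condition),
    class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf("Ratio matrix (%s): %d rows x %d timepoints, %d missing cells\n",
              x$condition, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.ratio_matrix <- function(x) dim(x$values)

subset_matrix_rows <- function(m, keep) {
  ratio_matrix(m$values[keep, , drop = FALSE], m$timepoints,
               provenance = if (!is.null(m$provenance)) m$provenance[keep, , drop = FALSE],
               condition = m$condition)
}

#' Construct a phospho-site record set
#'
#' Holds per-site identity (accession, gene, position, residue, localization
#' probability, sequence window, decoy/contaminant flags) together with the
#' per-replicate, per-timepoint H/L ratio array.
#'
#' @param meta Data frame with columns `site_id`, `protein_id`, `gene_name`,
#'   `position`, `residue`, `localization_prob`, `sequence_window`,
#'   `reverse`, `contaminant`, `site_only`.
#' @param ratios Numeric array `sites x replicates x timepoints`; `NA` marks
#'   missing quantifications; present values must be positive.
#' @param design The [time_course_design()] the ratios follow.
#' @return An object of class `phospho_sites`.
#' @export
phospho_sites <- function(meta, ratios, design) {
  required <- c("site_id", "protein_id", "gene_name", "position", "residue",
                "localization_prob", "sequence_window", "reverse",
                "contaminant", "site_only")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("site metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$site_id))
    stop("duplicate site_id: ", meta$site_id[duplicated(meta$site_id)][1])
  wl <- nchar(meta$sequence_window)
  if (any(wl %% 2 == 0)) stop("sequence windows must have odd length")
  centre <- substr(meta$sequence_window, (wl + 1) / 2, (wl + 1) / 2)
  bad <- centre != meta$residue & centre != PAD_CHAR
  if (any(bad))
    stop("central window residue disagrees with annotated residue for ",
         meta$site_id[bad][1])
  if (any(meta$localization_prob < 0 | meta$localization_prob > 1, na.rm = TRUE))
    stop("localization_prob must lie in [0, 1]")
  if (any(ratios <= 0, na.rm = TRUE)) stop("present ratios must be positive")
  check_ratio_dims(nrow(meta), ratios, design)
  rownames(meta) <- NULL
  structure(list(meta = meta, ratios = ratios, design = design),
            class = "phospho_sites")
}

#' Construct a protein-group record set
#'
#' @param meta Data frame with columns `protein_id`, `gene_name`, `reverse`,
#'   `contaminant`.
#' @inheritParams phospho_sites
#' @return An object of class `protein_set`.
#' @export
protein_set <- function(meta, ratios, design) {
  required <- c("protein_id", "gene_name", "reverse", "contaminant")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("protein metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$protein_id))
    stop("duplicate protein_id: ", meta$protein_id[duplicated(meta$protein_id)][1])
  if (any(ratios <= 0, na.rm = TRUE)) stop("present ratios must be positive")
  check_ratio_dims(nrow(meta), ratios, design)
  rownames(meta) <- NULL
  structure(list(meta = meta, ratios = ratios, design = design),
            class = "protein_set")
}

check_ratio_dims <- function(n, ratios, design) {
  d <- dim(ratios)
  if (length(d) != 3L ||
      d[1] != n ||
      d[2] != length(design$replicates) ||
      d[3] != length(design$timepoints))
    stop("ratio array must be entities x replicates x timepoints and match the design")
  invisible(TRUE)
}

#' @export
print.phospho_sites <- function(x, ...) {
  cat(sprintf("Phospho-site set: %d sites, %d replicates, %d timepoints (%s)\n",
              nrow(x$meta), dim(x$ratios)[2], dim(x$ratios)[3], x$design$condition))
  invisible(x)
}

#' @export
print.protein_set <- function(x, ...) {
  cat(sprintf("Protein set: %d proteins, %d replicates, %d timepoints (%s)\n",
              nrow(x$meta), dim(x$ratios)[2], dim(x$ratios)[3], x$design$condition))
  invisible(x)
}

#' Keep a subset of records in a site or protein set
#' @noRd
subset_records <- function(set, keep) {
  set$meta <- set$meta[keep, , drop = FALSE]
  rownames(set$meta) <- NULL
  set$ratios <- set$ratios[keep, , , drop = FALSE]
  set
}

entity_ids <- function(set) {
  if (inherits(set, "phospho_sites")) set$meta$site_id else set$meta$protein_id
}
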