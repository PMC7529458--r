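# MaxQuant-dialect tables: tab-separated UTF-8, '+' marks in flag columns,
# "NaN" (or empty / non-positive) ratio cells meaning "not quantified".

SITE_ID_COL <- "id"
SITE_COLUMNS <- c("Protein", "Gene names", "Position", "Amino acid",
                  "Localization prob", "Sequence window", "Reverse",
                  "Potential contaminant", "Only identified by site")
PROTEIN_ID_COL <- "Protein IDs"
PROTEIN_COLUMNS <- c("Gene names", "Reverse", "Potential contaminant")

flag_mark <- function(x) ifelse(x, "+", "")
parse_flag <- function(x) !is.na(x) & trimws(as.character(x)) == "+"

# Non-positive or unparseable ratio cells denote non-quantification, never a
# true zero: H/L ratios are strictly positive quantities.
parse_ratio <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v[!is.finite(v) | v <= 0] <- NA_real_
  v
}

flatten_ratio_columns <- function(ratios, design) {
  cols <- ratio_column_names(design)
  out <- list()
  for (r in seq_along(design$replicates))
    for (t in seq_along(design$timepoints))
      out[[cols[r, t]]] <- ratios[, r, t]
  out
}

#' Render a phospho-site set as a MaxQuant-dialect data frame
#'
#' @param set A [phospho_sites()] object.
#' @return Data frame with identity columns and one ratio column per
#'   (replicate, timepoint), named per the design's column pattern.
#' @export
as_site_table <- function(set) {
  m <- set$meta
  base <- data.frame(
    id = m$site_id, Protein = m$protein_id, `Gene names` = m$gene_name,
    Position = m$position, `Amino acid` = m$residue,
    `Localization prob` = m$localization_prob,
    `Sequence window` = m$sequence_window,
    Reverse = flag_mark(m$reverse),
    `Potential contaminant` = flag_mark(m$contaminant),
    `Only identified by site` = flag_mark(m$site_only),
    check.names = FALSE, stringsAsFactors = FALSE)
  cbind(base, as.data.frame(flatten_ratio_columns(set$ratios, set$design),
                            check.names = FALSE, optional = TRUE))
}

#' Render a protein set as a MaxQuant-dialect data frame
#'
#' @param set A [protein_set()] object.
#' @return Data frame in the protein-groups dialect.
#' @export
as_protein_table <- function(set) {
  m <- set$meta
  base <- data.frame(
    `Protein IDs` = m$protein_id, `Gene names` = m$gene_name,
    Reverse = flag_mark(m$reverse),
    `Potential contaminant` = flag_mark(m$contaminant),
    check.names = FALSE, stringsAsFactors = FALSE)
  cbind(base, as.data.frame(flatten_ratio_columns(set$ratios, set$design),
                            check.names = FALSE, optional = TRUE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NaN", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character",
                    quote = "", comment.char = "", na.strings = NULL,
                    fileEncoding = "UTF-8")
}

#' Write a simulated dataset to disk in the dialect the readers consume
#'
#' Emits the phospho-site table, the protein table, the ground-truth tables
#' and a JSON echo of the configuration. Byte-identical across runs for a
#' fixed seed.
#'
#' @param sim A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    sites = file.path(dir, "phospho_sites.txt"),
    proteins = file.path(dir, "protein_groups.txt"),
    truth_sites = file.path(dir, "ground_truth_sites.tsv"),
    truth_proteins = file.path(dir, "ground_truth_proteins.tsv"),
    config = file.path(dir, "sim_config.json"))
  write_tsv(as_site_table(sim$sites), paths["sites"])
  write_tsv(as_protein_table(sim$proteins), paths["proteins"])
  truth_sites <- sim$truth$sites
  truth_sites$half_life <- format_half_life(truth_sites$half_life,
                                            max(sim$config$timepoints))
  write_tsv(truth_sites, paths["truth_sites"])
  truth_prot <- sim$truth$proteins
  truth_prot$half_life <- format_half_life(truth_prot$half_life,
                                           max(sim$config$timepoints))
  write_tsv(truth_prot, paths["truth_proteins"])
  cfg <- sim$config
  cfg$class_specs <- lapply(cfg$class_specs, function(s) {
    s <- unclass(s)
    s$composition <- unclass(s$composition)
    s
  })
  jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(paths)
}

require_columns <- function(df, cols, path) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop(sprintf("%s lacks mandatory column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
}

read_ratio_array <- function(df, design, path) {
  cols <- ratio_column_names(design)
  require_columns(df, as.vector(cols), path)
  arr <- array(NA_real_, dim = c(nrow(df), length(design$replicates),
                                 length(design$timepoints)))
  for (r in seq_along(design$replicates))
    for (t in seq_along(design$timepoints))
      arr[, r, t] <- parse_ratio(df[[cols[r, t]]])
  arr
}

#' Read a MaxQuant-style phospho-site table
#'
#' Parses the identity columns and the per-(replicate, timepoint) ratio
#' columns named by the design's column pattern. Unparseable or non-positive
#' ratio cells become missing values; flags are read from '+' marks; row
#' order is preserved.
#'
#' @param path Path to a tab-separated site table.
#' @param design A [time_course_design()] describing the ratio columns.
#' @return A [phospho_sites()] object.
#' @export
read_site_table <- function(path, design) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read_tsv(path)
  require_columns(df, c(SITE_ID_COL, SITE_COLUMNS), path)
  if (anyDuplicated(df[[SITE_ID_COL]]))
    stop("duplicate site id in ", path, ": ",
         df[[SITE_ID_COL]][duplicated(df[[SITE_ID_COL]])][1])
  meta <- data.frame(
    site_id = df[[SITE_ID_COL]],
    protein_id = df[["Protein"]],
    gene_name = df[["Gene names"]],
    position = as.integer(df[["Position"]]),
    residue = df[["Amino acid"]],
    localization_prob = suppressWarnings(as.numeric(df[["Localization prob"]])),
    sequence_window = df[["Sequence window"]],
    reverse = parse_flag(df[["Reverse"]]),
    contaminant = parse_flag(df[["Potential contaminant"]]),
    site_only = parse_flag(df[["Only identified by site"]]),
    stringsAsFactors = FALSE)
  phospho_sites(meta, read_ratio_array(df, design, path), design)
}

#' Read a MaxQuant-style protein-groups table
#'
#' @inheritParams read_site_table
#' @return A [protein_set()] object.
#' @export
read_protein_table <- function(path, design) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read_tsv(path)
  require_columns(df, c(PROTEIN_ID_COL, PROTEIN_COLUMNS), path)
  if (anyDuplicated(df[[PROTEIN_ID_COL]]))
    stop("duplicate protein id in ", path, ": ",
         df[[PROTEIN_ID_COL]][duplicated(df[[PROTEIN_ID_COL]])][1])
  meta <- data.frame(
    protein_id = df[[PROTEIN_ID_COL]],
    gene_name = df[["Gene names"]],
    reverse = parse_flag(df[["Reverse"]]),
    contaminant = parse_flag(df[["Potential contaminant"]]),
    stringsAsFactors = FALSE)
  protein_set(meta, read_ratio_array(df, design, path), design)
}

#' Read a reference identifier list
#'
#' One identifier per line; `#` starts a comment; whitespace is trimmed,
#' duplicates collapsed, case preserved.
#'
#' @param path Path to a plain-text list.
#' @return Character vector of unique identifiers.
#' @export
read_reference_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  ids <- unique(lines[nzchar(lines)])
  if (length(ids) == 0L) warning("reference list is empty: ", path)
  ids
}

#' Write result tables to a directory
#'
#' Each table is written as `<name>.tsv` with a stable column order; columns
#' whose name contains `half_life` have infinite values serialized as the
#' `">W"` sentinel, `W` being `window` minutes. Output is byte-for-byte
#' reproducible given identical inputs.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param window Observation window in minutes used for the half-life
#'   sentinel.
#' @return Named character vector of written paths, invisibly.
#' @export
write_results <- function(tables, out_dir, window = 60) {
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("result tables must be named")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    df <- tables[[nm]]
    for (col in grep("half_life", names(df), value = TRUE))
      df[[col]] <- format_half_life(df[[col]], window)
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(df, p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Read back a result table written by [write_results()]
#'
#' Numeric columns are restored and half-life sentinel strings (`">W"`)
#' parsed back to `Inf`, so that `read_result_table(write_results(x))`
#' round-trips.
#'
#' @param path Path to a result TSV.
#' @return Data frame.
#' @export
read_result_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = c("NA", "NaN"), fileEncoding = "UTF-8")
  for (col in grep("half_life", names(df), value = TRUE))
    df[[col]] <- parse_half_life(df[[col]])
  df
}
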