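# Shared in-code fixtures: tiny record sets and matrices built fresh per test.

tiny_design <- function(timepoints = c(0, 2, 5, 10, 20, 40, 60),
                        replicates = c("R1", "R2")) {
  time_course_design(timepoints, replicates, condition = "control")
}

# A small phospho-site set with hand-set windows and per-replicate ratios.
# `profiles` is a list of noiseless per-site trajectories; both replicates
# get identical values unless `ratios` overrides the full array.
make_sites <- function(profiles, design = tiny_design(),
                       localization = NULL, reverse = NULL,
                       contaminant = NULL, site_only = NULL,
                       windows = NULL, ratios = NULL) {
  n <- length(profiles)
  if (is.null(localization)) localization <- rep(0.99, n)
  if (is.null(reverse)) reverse <- rep(FALSE, n)
  if (is.null(contaminant)) contaminant <- rep(FALSE, n)
  if (is.null(site_only)) site_only <- rep(FALSE, n)
  if (is.null(windows)) windows <- rep("AAAAAAASAAAAAAA", n)
  meta <- data.frame(
    site_id = sprintf("S%03d", seq_len(n)),
    protein_id = sprintf("P%03d", seq_len(n)),
    gene_name = sprintf("G%03d", seq_len(n)),
    position = seq_len(n) + 10L,
    residue = substr(windows, (nchar(windows) + 1) / 2, (nchar(windows) + 1) / 2),
    localization_prob = localization,
    sequence_window = windows,
    reverse = reverse, contaminant = contaminant, site_only = site_only,
    stringsAsFactors = FALSE)
  if (is.null(ratios)) {
    nt <- length(design$timepoints)
    nr <- length(design$replicates)
    ratios <- array(NA_real_, dim = c(n, nr, nt))
    for (i in seq_len(n)) for (r in seq_len(nr)) ratios[i, r, ] <- profiles[[i]]
  }
  phospho_sites(meta, ratios, design)
}

# A ratio matrix straight from a named list of profiles.
make_matrix <- function(profiles, timepoints = c(0, 2, 5, 10, 20, 40, 60),
                        condition = "control") {
  values <- do.call(rbind, profiles)
  rownames(values) <- names(profiles)
  ratio_matrix(values, timepoints, condition = condition)
}

# Independent re-statement of the single-missing-value rule, written as a
# per-position scan (the implementation works on runs); used as the oracle.
impute_oracle <- function(x) {
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    if (!is.na(x[i])) next
    if (i > 1 && is.na(x[i - 1])) next
    if (i < n && is.na(x[i + 1])) next
    if (i == 1) {
      if (n >= 2) out[i] <- x[2]
    } else if (i == n) {
      out[i] <- x[n - 1]
    } else {
      out[i] <- (x[i - 1] + x[i + 1]) / 2
    }
  }
  out
}
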