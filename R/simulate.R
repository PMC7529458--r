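#' Sequence-window composition model for a kinetic class
#'
#' Describes how sequence windows are drawn for sites of one kinetic class:
#' the identity of the central phospho-residue and multiplicative biases on
#' basic (K/R) and acidic (D/E) residues in the flanks, applied on top of the
#' human-proteome background frequencies and renormalized per position.
#'
#' @param central Named probabilities for the central residue over S/T/Y;
#'   must sum to 1.
#' @param basic_bias,acidic_bias Multiplicative enrichment factors for K/R
#'   and D/E in the flanking positions (1 = background).
#' @param bias_positions Window offsets (e.g. `1:3` for the three positions
#'   downstream of the phospho-residue) the biases apply to; `NULL` applies
#'   them to every flank position.
#' @return An object of class `class_composition`.
#' @export
class_composition <- function(central = c(S = 0.75, T = 0.23, Y = 0.02),
                              basic_bias = 1, acidic_bias = 1,
                              bias_positions = NULL) {
  if (!setequal(names(central), c("S", "T", "Y")))
    stop("central composition must name S, T and Y")
  if (abs(sum(central) - 1) > 1e-8)
    stop("central residue probabilities must sum to 1")
  if (basic_bias < 0 || acidic_bias < 0) stop("biases must be non-negative")
  structure(list(central = central[c("S", "T", "Y")],
                 basic_bias = basic_bias, acidic_bias = acidic_bias,
                 bias_positions = bias_positions),
            class = "class_composition")
}

#' Specification of one kinetic class of phospho-sites
#'
#' @param name One of `"early"`, `"intermediate"`, `"late"`, `"stable"`.
#' @param fraction Proportion of simulated sites in this class.
#' @param half_life True half-life in minutes of the decaying component
#'   (`Inf` for stable sites, whose trajectory is constant 1).
#' @param plateau Asymptotic ratio in `[0, 0.5)` for decaying classes, so
#'   that the y = 0.5 crossing exists.
#' @param composition A [class_composition()].
#' @return An object of class `kinetic_class_spec`.
#' @export
kinetic_class_spec <- function(name, fraction, half_life, plateau = 0,
                               composition = class_composition()) {
  if (!name %in% c("early", "intermediate", "late", "stable"))
    stop("class name must be one of early, intermediate, late, stable")
  if (fraction < 0 || fraction > 1) stop("class fraction must lie in [0, 1]")
  if (half_life <= 0) stop("half-life must be positive")
  if (is.finite(half_life) && (plateau < 0 || plateau >= 0.5))
    stop("plateau must lie in [0, 0.5) for finite-half-life classes")
  structure(list(name = name, fraction = fraction, half_life = half_life,
                 plateau = plateau, composition = composition),
            class = "kinetic_class_spec")
}

#' Default kinetic classes of dephosphorylation
#'
#' Four equal classes with half-lives 5, 13.5 and 46 min plus a stable class,
#' the cluster half-lives observed for mitotic exit triggered by CDK
#' inhibition. Compositions encode the observed sequence trends: early sites
#' are threonine-centred with basic enrichment and acidic de-enrichment,
#' stable sites are serine-centred with downstream (+1..+3) acidic
#' enrichment, and the trend is graded in between.
#'
#' @return List of four [kinetic_class_spec()] objects.
#' @export
default_class_specs <- function() {
  list(
    kinetic_class_spec("early", 0.25, 5, 0,
      class_composition(central = c(S = 0.30, T = 0.68, Y = 0.02),
                        basic_bias = 1.6, acidic_bias = 0.4)),
    kinetic_class_spec("intermediate", 0.25, 13.5, 0,
      class_composition(central = c(S = 0.55, T = 0.43, Y = 0.02),
                        basic_bias = 1.2, acidic_bias = 0.7)),
    kinetic_class_spec("late", 0.25, 46, 0,
      class_composition(central = c(S = 0.75, T = 0.23, Y = 0.02))),
    kinetic_class_spec("stable", 0.25, Inf, 0,
      class_composition(central = c(S = 0.85, T = 0.13, Y = 0.02),
                        basic_bias = 0.8, acidic_bias = 2.0,
                        bias_positions = 1:3))
  )
}

#' Default degraded-protein specifications
#'
#' A handful of destroyed proteins against a stable proteome background,
#' mirroring the tiers of anaphase proteolysis: rapid cyclin-B1-like and
#' geminin-like destruction, intermediate Aurora-A/TPX2-like destruction
#' after a short lag, and slow PLK1-like destruction.
#'
#' @return List of `(identifier, half-life minutes, lag minutes)` entries.
#' @export
default_degraded_proteins <- function() {
  list(list(id = "DEG_CCNB1", half_life = 10, lag = 0),
       list(id = "DEG_GMNN",  half_life = 15, lag = 0),
       list(id = "DEG_AURKA", half_life = 60, lag = 5),
       list(id = "DEG_TPX2",  half_life = 60, lag = 5),
       list(id = "DEG_PLK1",  half_life = 150, lag = 10))
}

#' Simulation configuration
#'
#' Defines a two-label ratio time-course experiment with known ground truth:
#' the sampling grid, replicate count, kinetic classes, proteome background
#' plus degraded proteins, multiplicative lognormal ratio noise, a
#' first-order missing-value run model, and (optionally) a second, perturbed
#' condition linked to the control through a multiplicative t0 offset and a
#' per-class half-life scaling.
#'
#' @param timepoints Sampling grid in minutes, starting at 0.
#' @param n_replicates Number of replicate time courses.
#' @param class_specs List of [kinetic_class_spec()]; fractions must sum to 1.
#' @param n_sites Number of phospho-sites.
#' @param n_proteins Number of stable background proteins (degraded proteins
#'   from `degraded_protein_specs` are appended).
#' @param degraded_protein_specs List of `(id, half_life, lag)` entries.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   ratio noise.
#' @param missing_rate Baseline probability that a quantification is missing.
#' @param missing_run_prob Probability that a missing value extends into a
#'   run (first-order model), creating the consecutive-missing cases the
#'   imputation rule must leave untouched.
#' @param seed Integer random seed; the whole simulation is deterministic
#'   given the seed.
#' @param condition_offset Multiplicative t0 offset of the perturbed
#'   condition relative to control (`NULL` for single-condition designs).
#' @param perturbed_half_life_scale Factor applied to every finite class
#'   half-life in the perturbed condition (e.g. 2 for a phosphatase-depleted
#'   condition in which dephosphorylation is twice as slow).
#' @param window_width Width of the sequence windows (odd; default 15,
#'   positions -7..+7).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(timepoints = default_timepoints(),
                       n_replicates = 4,
                       class_specs = default_class_specs(),
                       n_sites = 1000,
                       n_proteins = 300,
                       degraded_protein_specs = default_degraded_proteins(),
                       noise_cv = 0.15,
                       missing_rate = 0.05,
                       missing_run_prob = 0.3,
                       seed = 1,
                       condition_offset = NULL,
                       perturbed_half_life_scale = 1,
                       window_width = 15) {
  cfg <- structure(
    list(timepoints = as.numeric(timepoints), n_replicates = n_replicates,
         class_specs = class_specs, n_sites = n_sites, n_proteins = n_proteins,
         degraded_protein_specs = degraded_protein_specs, noise_cv = noise_cv,
         missing_rate = missing_rate, missing_run_prob = missing_run_prob,
         seed = seed, condition_offset = condition_offset,
         perturbed_half_life_scale = perturbed_half_life_scale,
         window_width = window_width),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(config) {
  tp <- config$timepoints
  if (length(tp) < 3L || tp[1] != 0 || any(diff(tp) <= 0))
    stop("invalid config: timepoints must be strictly increasing and start at 0")
  if (config$n_replicates < 1) stop("invalid config: n_replicates must be >= 1")
  fr <- vapply(config$class_specs, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop("invalid config: class fractions must sum to 1")
  for (p in c("missing_rate", "missing_run_prob"))
    if (config[[p]] < 0 || config[[p]] > 1)
      stop(sprintf("invalid config: %s must lie in [0, 1]", p))
  if (config$noise_cv < 0) stop("invalid config: noise_cv must be non-negative")
  if (config$window_width %% 2 == 0 || config$window_width < 3)
    stop("invalid config: window_width must be odd and >= 3")
  if (!is.null(config$condition_offset) && config$condition_offset <= 0)
    stop("invalid config: condition_offset must be positive")
  if (config$perturbed_half_life_scale <= 0)
    stop("invalid config: perturbed_half_life_scale must be positive")
  invisible(config)
}

#' Noiseless plateau-plus-one-phase-decay trajectory
#'
#' `y(t) = P + (1 - P) exp(-t ln 2 / h)`; constant 1 for infinite half-life.
#' @param t Times in minutes.
#' @param half_life Half-life in minutes of the decaying component.
#' @param plateau Asymptote `P`.
#' @return Numeric vector of ratios.
#' @export
decay_trajectory <- function(t, half_life, plateau = 0) {
  if (is.infinite(half_life)) return(rep(1, length(t)))
  plateau + (1 - plateau) * exp(-t * log(2) / half_life)
}

delayed_decay_trajectory <- function(t, half_life, lag) {
  ifelse(t < lag, 1, exp(-(t - lag) * log(2) / half_life))
}

# Per-position flank residue probabilities under a composition model.
flank_residue_probs <- function(comp, offset) {
  p <- BACKGROUND_AA_FREQ
  apply_bias <- is.null(comp$bias_positions) || offset %in% comp$bias_positions
  if (apply_bias) {
    p[BASIC_RESIDUES] <- p[BASIC_RESIDUES] * comp$basic_bias
    p[ACIDIC_RESIDUES] <- p[ACIDIC_RESIDUES] * comp$acidic_bias
  }
  p / sum(p)
}

draw_windows <- function(n, comp, width) {
  if (n == 0L) return(character(0))
  half <- (width - 1) / 2
  mat <- matrix("", nrow = n, ncol = width)
  for (p in seq_len(width)) {
    offset <- p - (half + 1)
    if (offset == 0) {
      mat[, p] <- sample(names(comp$central), n, replace = TRUE, prob = comp$central)
    } else {
      mat[, p] <- sample(AMINO_ACIDS, n, replace = TRUE,
                         prob = flank_residue_probs(comp, offset))
    }
  }
  apply(mat, 1, paste0, collapse = "")
}

# First-order missingness: a value is missing with `rate`; a missing value
# extends into a run with `run_prob`.
draw_missing_mask <- function(n_entity, n_rep, n_time, rate, run_prob) {
  mask <- array(FALSE, dim = c(n_entity, n_rep, n_time))
  if (rate <= 0 || n_entity == 0L) return(mask)
  u <- array(stats::runif(n_entity * n_rep * n_time),
             dim = c(n_entity, n_rep, n_time))
  mask[, , 1] <- u[, , 1] < rate
  for (t in seq_len(n_time)[-1]) {
    p <- ifelse(mask[, , t - 1], run_prob, rate)
    mask[, , t] <- u[, , t] < p
  }
  mask
}

apply_noise_and_missing <- function(traj, n_rep, config) {
  n <- nrow(traj); nt <- ncol(traj)
  ratios <- array(rep(traj, times = n_rep), dim = c(n, nt, n_rep))
  ratios <- aperm(ratios, c(1, 3, 2))     # entities x replicates x timepoints
  if (config$noise_cv > 0)
    ratios <- ratios * array(lognormal_noise(n * n_rep * nt, config$noise_cv),
                             dim = c(n, n_rep, nt))
  mask <- draw_missing_mask(n, n_rep, nt, config$missing_rate,
                            config$missing_run_prob)
  ratios[mask] <- NA_real_
  ratios
}

# Fixed nuisance rates of the simulated search output (decoy hits,
# contaminants, site-only identifications, localization confidence). These
# exercise the filtering rules without being kinetic parameters.
SIM_REVERSE_RATE <- 0.01
SIM_CONTAMINANT_RATE <- 0.01
SIM_SITE_ONLY_RATE <- 0.005
SIM_LOCALIZATION_SHAPE <- 8  # localization_prob ~ Beta(8, 1)

#' Simulate a two-label ratio time-course dataset with known ground truth
#'
#' Generates a phospho-site set and a protein set following the configured
#' kinetic classes, noise and missingness models, in the same layout the
#' MaxQuant-dialect readers consume. Site identity (class membership,
#' sequence windows, protein assignment, flags) is drawn from the master
#' seed, while noise and missingness are drawn from a condition-specific
#' stream: simulating `"control"` and `"perturbed"` from the same config
#' yields the same entities measured under two conditions, with every finite
#' half-life multiplied by `perturbed_half_life_scale` and every ratio by
#' `condition_offset` in the perturbed condition.
#'
#' @param config A [sim_config()].
#' @param condition `"control"` or `"perturbed"` (the latter requires
#'   `condition_offset`).
#' @return A list of class `sim_dataset` with elements `sites`
#'   ([phospho_sites()]), `proteins` ([protein_set()]), `truth` (data frames
#'   `sites` and `proteins` holding class, true half-life and window), and
#'   `config`.
#' @export
simulate_dataset <- function(config, condition = c("control", "perturbed")) {
  condition <- match.arg(condition)
  validate_sim_config(config)
  if (condition == "perturbed" && is.null(config$condition_offset))
    stop("perturbed condition requested but config has no condition_offset")

  ns <- config$n_sites
  nt <- length(config$timepoints)
  nr <- config$n_replicates
  specs <- config$class_specs
  class_names <- vapply(specs, `[[`, character(1), "name")

  bg_protein_ids <- sprintf("PROT%04d", seq_len(config$n_proteins))
  deg_ids <- vapply(config$degraded_protein_specs, `[[`, character(1), "id")

  # --- identity stream: shared between conditions --------------------------
  identity <- with_seed(config$seed, {
    cls <- sample(class_names, ns, replace = TRUE,
                  prob = vapply(specs, `[[`, numeric(1), "fraction"))
    windows <- character(ns)
    for (s in specs) {
      idx <- which(cls == s$name)
      windows[idx] <- draw_windows(length(idx), s$composition, config$window_width)
    }
    centre_pos <- (config$window_width + 1) / 2
    meta <- data.frame(
      site_id = sprintf("SITE%05d", seq_len(ns)),
      protein_id = sample(bg_protein_ids, ns, replace = TRUE),
      gene_name = NA_character_,
      position = sample(16:1500, ns, replace = TRUE),
      residue = substr(windows, centre_pos, centre_pos),
      localization_prob = stats::rbeta(ns, SIM_LOCALIZATION_SHAPE, 1),
      sequence_window = windows,
      reverse = stats::runif(ns) < SIM_REVERSE_RATE,
      contaminant = stats::runif(ns) < SIM_CONTAMINANT_RATE,
      site_only = stats::runif(ns) < SIM_SITE_ONLY_RATE,
      stringsAsFactors = FALSE)
    meta$gene_name <- sub("PROT", "GENE", meta$protein_id)
    list(cls = cls, meta = meta)
  })

  spec_by_name <- stats::setNames(specs, class_names)
  scale <- if (condition == "perturbed") config$perturbed_half_life_scale else 1
  hl <- vapply(identity$cls, function(cn) spec_by_name[[cn]]$half_life, numeric(1)) * scale
  pl <- vapply(identity$cls, function(cn) spec_by_name[[cn]]$plateau, numeric(1))

  site_traj <- t(vapply(seq_len(ns),
                        function(i) decay_trajectory(config$timepoints, hl[i], pl[i]),
                        numeric(nt)))

  protein_ids <- c(bg_protein_ids, deg_ids)
  prot_hl <- c(rep(Inf, config$n_proteins),
               vapply(config$degraded_protein_specs, `[[`, numeric(1), "half_life") * scale)
  prot_lag <- c(rep(0, config$n_proteins),
                vapply(config$degraded_protein_specs, `[[`, numeric(1), "lag"))
  prot_traj <- t(vapply(seq_along(protein_ids), function(i) {
    if (is.infinite(prot_hl[i])) rep(1, nt)
    else delayed_decay_trajectory(config$timepoints, prot_hl[i], prot_lag[i])
  }, numeric(nt)))

  # --- measurement stream: condition-specific ------------------------------
  cond_seed <- derive_seed(config$seed, if (condition == "control") 1L else 2L)
  offset <- if (condition == "perturbed") config$condition_offset else 1
  measured <- with_seed(cond_seed, {
    sr <- apply_noise_and_missing(site_traj, nr, config) * offset
    pr <- apply_noise_and_missing(prot_traj, nr, config) * offset
    list(sites = sr, proteins = pr)
  })

  design <- time_course_design(config$timepoints, paste0("R", seq_len(nr)),
                               condition = condition)
  prot_meta <- data.frame(
    protein_id = protein_ids,
    gene_name = sub("PROT", "GENE", sub("DEG_", "", protein_ids)),
    reverse = FALSE, contaminant = FALSE, stringsAsFactors = FALSE)

  # True half-life of a site = time its noiseless trajectory crosses 0.5.
  crossing <- ifelse(is.infinite(hl) | pl >= 0.5, Inf,
                     log((1 - pl) / (0.5 - pl)) / (log(2) / hl))
  truth <- list(
    sites = data.frame(site_id = identity$meta$site_id, class = identity$cls,
                       half_life = crossing,
                       window = identity$meta$sequence_window,
                       stringsAsFactors = FALSE),
    proteins = data.frame(protein_id = protein_ids,
                          degraded = is.finite(prot_hl),
                          half_life = prot_lag + prot_hl,
                          stringsAsFactors = FALSE))

  structure(list(sites = phospho_sites(identity$meta, measured$sites, design),
                 proteins = protein_set(prot_meta, measured$proteins, design),
                 truth = truth, config = config, condition = condition),
            class = "sim_dataset")
}

#' Simulate cross-mixed t0 samples linking two conditions
#'
#' Cross-mixed samples combine equal quantities of the light-labelled t0 of
#' one condition with the heavy-labelled t0 of the other, so their H/L
#' ratios measure the steady-state offset between conditions. The simulated
#' ratios equal `condition_offset` times lognormal noise.
#'
#' @param config A [sim_config()] with a non-`NULL` `condition_offset`.
#' @return A [crossmix_table()] covering every simulated phospho-site.
#' @export
simulate_crossmix <- function(config) {
  validate_sim_config(config)
  if (is.null(config$condition_offset))
    stop("cross-mix simulation requires a two-condition config (condition_offset set)")
  ids <- sprintf("SITE%05d", seq_len(config$n_sites))
  ratios <- with_seed(derive_seed(config$seed, 3L),
                      config$condition_offset * lognormal_noise(config$n_sites, config$noise_cv))
  crossmix_table(ids, ratios)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset (%s): %d sites, %d proteins, seed %s\n",
              x$condition, nrow(x$sites$meta), nrow(x$proteins$meta),
              format(x$config$seed)))
  invisible(x)
}
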