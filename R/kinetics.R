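# Plateau-plus-one-phase-decay model: y(t) = P + (y0 - P) exp(-K t).
# Half-life is defined as the time the fitted curve crosses the absolute
# value y = 0.5 (not the midpoint between y0 and the plateau).

one_phase_decay <- function(t, y0, plateau, K) plateau + (y0 - plateau) * exp(-K * t)

# Fixed multi-start initial values: Prism-style fits are not reproducible
# bit-for-bit, so determinism comes from a fixed grid of starts followed by
# bounded least squares; best residual sum of squares wins.
FIT_START_K <- log(2) / c(2, 10, 40)
FIT_START_P <- c(0, 0.25)

#' Fit a plateau-plus-one-phase-decay curve to a normalized profile
#'
#' Bounded least squares of `y(t) = P + (y0 - P) exp(-K t)` with
#' `0 <= P < y0` and `K >= 0`, from a fixed grid of starting values
#' (deterministic; identical inputs give bit-identical fits). The profile is
#' expected to be normalized to a starting ratio of one
#' ([normalize_to_start()]); by default `y0` is fixed at 1, with a free-`y0`
#' mode available for diagnostics.
#'
#' @param y Profile values; missing entries are dropped.
#' @param timepoints Times in minutes, same length as `y`.
#' @param fix_y0 Fix the initial ratio at `y0` (default) or fit it.
#' @param y0 Initial ratio when fixed (default 1).
#' @return An object of class `decay_fit` with elements `y0`, `plateau`,
#'   `K` (per minute), `rss`, `converged`, `n_points` and `half_life`
#'   (minutes; `Inf` when the curve never crosses 0.5).
#' @export
fit_one_phase_decay <- function(y, timepoints, fix_y0 = TRUE, y0 = 1) {
  if (length(y) != length(timepoints))
    stop("profile and timepoints must have equal length")
  keep <- is.finite(y)
  if (sum(keep) < 4L) stop("at least 4 quantified timepoints are required to fit")
  tt <- timepoints[keep]
  yy <- y[keep]

  # Degenerate constant profile: no decay, K = 0 exactly.
  if (all(abs(yy - yy[1]) < 1e-12)) {
    fit <- new_decay_fit(y0 = yy[1], plateau = 0, K = 0, rss = 0,
                         converged = TRUE, n_points = length(yy),
                         fix_y0 = fix_y0)
    return(fit)
  }

  rss_fixed <- function(par) {
    r <- yy - one_phase_decay(tt, y0, par[1], par[2])
    sum(r * r)
  }
  rss_free <- function(par) {
    r <- yy - one_phase_decay(tt, par[3], par[1], par[2])
    sum(r * r)
  }

  best <- NULL
  for (K0 in FIT_START_K) {
    for (P0 in FIT_START_P) {
      res <- if (fix_y0) {
        tryCatch(stats::optim(c(P0, K0), rss_fixed, method = "L-BFGS-B",
                              lower = c(0, 0), upper = c(y0 - 1e-9, Inf),
                              control = list(factr = 10, maxit = 500)),
                 error = function(e) NULL)
      } else {
        tryCatch(stats::optim(c(P0, K0, max(yy)), rss_free, method = "L-BFGS-B",
                              lower = c(0, 0, 1e-6),
                              upper = c(Inf, Inf, Inf),
                              control = list(factr = 10, maxit = 500)),
                 error = function(e) NULL)
      }
      if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
    }
  }
  if (is.null(best))
    return(new_decay_fit(y0 = y0, plateau = NA_real_, K = NA_real_,
                         rss = NA_real_, converged = FALSE,
                         n_points = length(yy), fix_y0 = fix_y0))

  par <- best$par
  # Gauss-Newton polish for full precision on low-noise profiles; port may
  # report false convergence on flat regions, which the RSS guard handles.
  polish <- tryCatch(suppressWarnings({
    if (fix_y0) {
      fit <- stats::nls(yy ~ one_phase_decay(tt, y0, P, K),
                        start = list(P = par[1], K = max(par[2], 1e-12)),
                        algorithm = "port",
                        lower = c(P = 0, K = 0), upper = c(P = y0 - 1e-9, K = Inf),
                        control = stats::nls.control(maxiter = 200, warnOnly = TRUE,
                                                     scaleOffset = 1))
      cf <- stats::coef(fit)
      c(cf[["P"]], cf[["K"]])
    } else {
      fit <- stats::nls(yy ~ one_phase_decay(tt, Y0, P, K),
                        start = list(P = par[1], K = max(par[2], 1e-12), Y0 = par[3]),
                        algorithm = "port",
                        lower = c(P = 0, K = 0, Y0 = 1e-6),
                        control = stats::nls.control(maxiter = 200, warnOnly = TRUE,
                                                     scaleOffset = 1))
      cf <- stats::coef(fit)
      c(cf[["P"]], cf[["K"]], cf[["Y0"]])
    }
  }), error = function(e) NULL)
  if (!is.null(polish)) {
    rss_new <- if (fix_y0) rss_fixed(polish) else rss_free(polish)
    if (is.finite(rss_new) && rss_new <= best$value) {
      par <- polish
      best$value <- rss_new
    }
  }

  new_decay_fit(y0 = if (fix_y0) y0 else par[3],
                plateau = par[1], K = par[2], rss = best$value,
                converged = best$convergence == 0 || !is.null(polish),
                n_points = length(yy), fix_y0 = fix_y0)
}

new_decay_fit <- function(y0, plateau, K, rss, converged, n_points, fix_y0) {
  fit <- structure(list(y0 = y0, plateau = plateau, K = K, rss = rss,
                        converged = converged, n_points = n_points,
                        fix_y0 = fix_y0, half_life = NA_real_),
                   class = "decay_fit")
  if (converged) fit$half_life <- half_life_from_fit(fit)
  fit
}

#' @export
print.decay_fit <- function(x, ...) {
  hl <- if (is.infinite(x$half_life)) "> window" else sprintf("%.3f min", x$half_life)
  cat(sprintf("One-phase decay fit: y0 = %.4g, plateau = %.4g, K = %.4g /min, half-life %s (rss %.3g, %s)\n",
              x$y0, x$plateau, x$K, hl, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Half-life from a fitted decay curve
#'
#' The time at which the fitted curve crosses the absolute value y = 0.5:
#' `t = ln((y0 - P) / (0.5 - P)) / K`. When the plateau is at or above 0.5,
#' or the rate constant is zero, the curve never reaches 0.5 and the
#' half-life is `Inf` (serialized as the "greater than window" sentinel).
#' A profile starting at or below 0.5 has half-life 0.
#'
#' @param fit A converged `decay_fit`.
#' @return Half-life in minutes, possibly `Inf`.
#' @export
half_life_from_fit <- function(fit) {
  if (!inherits(fit, "decay_fit")) stop("fit must be a decay_fit")
  if (!fit$converged) stop("cannot read a half-life off a non-converged fit")
  if (fit$y0 <= 0.5) return(0)
  if (fit$K <= 0 || fit$plateau >= 0.5) return(Inf)
  log((fit$y0 - fit$plateau) / (0.5 - fit$plateau)) / fit$K
}

#' Cluster mean profile, fit and half-life
#'
#' Builds the per-timepoint mean and standard error of the mean over member
#' profiles, normalizes the mean profile to a starting ratio of one, fits
#' the decay model and reads off the half-life (`mode = "fit-of-mean"`, the
#' default). The alternative `mode = "mean-of-fits"` fits every member
#' profile individually and averages the finite half-lives, the convention
#' used for perturbation comparisons.
#'
#' Half-lives are only reported within the observation window: a fitted 0.5
#' crossing beyond the last timepoint is an extrapolation and becomes the
#' greater-than-window sentinel `Inf`.
#'
#' @param members Numeric matrix of member profiles (rows = members,
#'   columns = timepoints); must be non-empty.
#' @param timepoints Times in minutes.
#' @param mode `"fit-of-mean"` or `"mean-of-fits"`.
#' @return List with `profile` (data frame of timepoint, mean, sem), `fit`
#'   (the `decay_fit` for fit-of-mean mode), `half_life`, `n_members` and
#'   `mode`.
#' @export
cluster_half_life <- function(members, timepoints,
                              mode = c("fit-of-mean", "mean-of-fits")) {
  mode <- match.arg(mode)
  members <- as.matrix(members)
  if (nrow(members) == 0L) stop("empty cluster")
  mean_prof <- colMeans(members)
  sem <- if (nrow(members) == 1L) rep(0, ncol(members))
         else apply(members, 2, stats::sd) / sqrt(nrow(members))
  profile <- data.frame(timepoint = timepoints, mean = mean_prof, sem = sem)

  window <- max(timepoints)
  apply_window <- function(h) ifelse(!is.na(h) & h > window, Inf, h)

  if (mode == "fit-of-mean") {
    fit <- fit_one_phase_decay(normalize_to_start(mean_prof), timepoints)
    hl <- if (fit$converged) apply_window(fit$half_life) else NA_real_
    return(list(profile = profile, fit = fit, half_life = hl,
                n_members = nrow(members), mode = mode))
  }

  hls <- apply(members, 1, function(p) {
    if (is.na(p[1]) || p[1] <= 0) return(NA_real_)
    f <- tryCatch(fit_one_phase_decay(normalize_to_start(p), timepoints),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) NA_real_ else apply_window(f$half_life)
  })
  finite <- hls[is.finite(hls)]
  hl <- if (length(finite)) mean(finite) else Inf
  list(profile = profile, fit = NULL, half_life = hl,
       n_members = nrow(members), mode = mode, member_half_lives = hls)
}

#' Endpoint-based protein half-lives from a fractionated time course
#'
#' Per timepoint column, the column median is subtracted and a correction of
#' `correction` added to remove negative values; the adjusted ratios at the
#' endpoint timepoints (50 and 60 min by default, averaged because the
#' 60-min samples ran consistently high) give the fraction of protein
#' remaining, converted to a half-life under first-order decay:
#' `h = endpoint_minutes * ln 2 / (-ln f)`. Fractions at or above 1 give the
#' stable sentinel `Inf`; fractions are clamped below at `1e-6`.
#'
#' @param m A replicate-averaged protein [ratio_matrix()].
#' @param endpoint_minutes Time horizon of the remaining fraction (default
#'   60 min).
#' @param endpoints Timepoints (minutes) whose adjusted ratios are averaged
#'   into the endpoint fraction.
#' @param correction Constant added after median subtraction (default 0.85).
#' @return Data frame with `id`, `endpoint_fraction`, `half_life` and
#'   `class` (see [classify_destruction()]).
#' @export
endpoint_half_life <- function(m, endpoint_minutes = 60, endpoints = c(50, 60),
                               correction = 0.85) {
  idx <- match(endpoints, m$timepoints)
  if (anyNA(idx))
    stop("endpoint timepoint(s) absent from matrix: ",
         paste(endpoints[is.na(idx)], collapse = ", "))
  med <- apply(m$values, 2, stats::median, na.rm = TRUE)
  adj <- sweep(m$values, 2, med) + correction
  f <- rowMeans(adj[, idx, drop = FALSE], na.rm = TRUE)
  f[is.nan(f)] <- NA_real_
  hl <- ifelse(is.na(f), NA_real_,
               ifelse(f >= 1, Inf,
                      endpoint_minutes * log(2) / (-log(pmax(f, 1e-6)))))
  data.frame(id = rownames(m$values), endpoint_fraction = f, half_life = hl,
             class = classify_destruction(hl), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Classify protein destruction by half-life
#'
#' Bins: half-life up to 60 min means destruction fast enough to matter for
#' anaphase; 60 min to 2 h places proteolysis in telophase or early G1; 2 h
#' to 5 h in the subsequent G1; anything slower (or never crossing 0.5) is
#' stable.
#'
#' @param half_life Half-lives in minutes (`Inf` allowed, `NA` propagated).
#' @return Character vector of classes: `"anaphase"`,
#'   `"telophase/early G1"`, `"G1"`, `"stable"`.
#' @export
classify_destruction <- function(half_life) {
  if (any(half_life < 0, na.rm = TRUE)) stop("half-life cannot be negative")
  out <- rep(NA_character_, length(half_life))
  ok <- !is.na(half_life)
  out[ok & half_life <= 60] <- "anaphase"
  out[ok & half_life > 60 & half_life <= 120] <- "telophase/early G1"
  out[ok & half_life > 120 & half_life <= 300] <- "G1"
  out[ok & half_life > 300] <- "stable"
  out
}
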