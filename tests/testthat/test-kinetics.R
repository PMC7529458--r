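grid <- default_timepoints()

test_that("noiseless decay parameters are recovered to high precision", {
  y <- decay_trajectory(grid, 5, 0.2)   # K = ln2/5, plateau 0.2
  fit <- fit_one_phase_decay(y, grid)
  expect_lt(abs(fit$plateau - 0.2), 1e-6)
  expect_lt(abs(fit$K - log(2) / 5) / (log(2) / 5), 1e-6)
  pure <- decay_trajectory(grid, 10, 0)
  fit2 <- fit_one_phase_decay(pure, grid)
  expect_lt(abs(fit2$K - log(2) / 10) / (log(2) / 10), 1e-6)
  expect_lt(fit2$plateau, 1e-6)
})

test_that("a constant profile has zero rate and a sentinel half-life", {
  fit <- fit_one_phase_decay(rep(1, length(grid)), grid)
  expect_equal(fit$K, 0)
  expect_true(is.infinite(fit$half_life))
  expect_true(fit$converged)
})

test_that("fitting is deterministic and requires at least four points", {
  set.seed(4)
  y <- decay_trajectory(grid, 8, 0.1) * exp(rnorm(length(grid), 0, 0.05))
  expect_identical(fit_one_phase_decay(y, grid), fit_one_phase_decay(y, grid))
  expect_error(fit_one_phase_decay(c(1, .6, .4), c(0, 5, 10)), "at least 4")
})

test_that("the half-life is the y = 0.5 crossing of the fitted curve", {
  mkfit <- function(P, K, y0 = 1)
    structure(list(y0 = y0, plateau = P, K = K, converged = TRUE),
              class = "decay_fit")
  expect_equal(half_life_from_fit(mkfit(0, log(2) / 5)), 5)
  # closed form ln(0.8/0.3)/(ln2/5), cross-checked numerically below
  expect_equal(half_life_from_fit(mkfit(0.2, log(2) / 5)),
               log(0.8 / 0.3) / (log(2) / 5), tolerance = 1e-12)
  root <- uniroot(function(t) 0.2 + 0.8 * exp(-log(2) / 5 * t) - 0.5,
                  c(0, 1e3), tol = 1e-12)$root
  expect_equal(half_life_from_fit(mkfit(0.2, log(2) / 5)), root,
               tolerance = 1e-8)
  # a plateau at or above 0.5 never crosses
  expect_true(is.infinite(half_life_from_fit(mkfit(0.6, 1))))
  expect_true(is.infinite(half_life_from_fit(mkfit(0.2, 0))))
  expect_error(half_life_from_fit(structure(list(converged = FALSE),
                                            class = "decay_fit")),
               "non-converged")
})

test_that("cluster half-life summarizes member profiles", {
  p <- decay_trajectory(grid, 6, 0)
  same <- rbind(p, p, p)
  chl <- cluster_half_life(same, grid)
  expect_equal(chl$half_life, 6, tolerance = 1e-6)
  expect_equal(chl$profile$sem, rep(0, length(grid)))
  # mixed half-lives: the 0.5 crossing of the averaged curve lies between
  mix <- rbind(decay_trajectory(grid, 4, 0), decay_trajectory(grid, 6, 0))
  hl_mix <- cluster_half_life(mix, grid)$half_life
  crossing <- uniroot(function(t)
    (exp(-log(2) / 4 * t) + exp(-log(2) / 6 * t)) / 2 - 0.5, c(0, 60),
    tol = 1e-12)$root
  expect_gt(hl_mix, 4); expect_lt(hl_mix, 6)
  expect_equal(hl_mix, crossing, tolerance = 0.02)
  # single member: mean profile is the member, SEM 0 by convention
  single <- cluster_half_life(matrix(p, nrow = 1), grid)
  expect_equal(single$profile$mean, p)
  expect_equal(single$profile$sem, rep(0, length(grid)))
  expect_error(cluster_half_life(matrix(numeric(0), nrow = 0, ncol = 5), grid),
               "empty")
  # mean-of-fits mode averages finite member half-lives
  mof <- cluster_half_life(mix, grid, mode = "mean-of-fits")
  expect_equal(mof$half_life, 5, tolerance = 1e-4)
})

test_that("endpoint fractions convert to half-lives under first-order decay", {
  tps <- c(0, 10, 20, 30, 40, 50, 60)
  base <- rep(0.85, 7)  # three background rows pin every column median at 0.85
  mk <- function(target) {
    make_matrix(list(bg1 = base, bg2 = base, bg3 = base, target = target),
                timepoints = tps)
  }
  half <- endpoint_half_life(mk(c(0.85, 0.85, 0.85, 0.85, 0.85, 0.5, 0.5)))
  expect_equal(half$half_life[half$id == "target"], 60)
  quarter <- endpoint_half_life(mk(c(0.85, 0.85, 0.85, 0.85, 0.85, 0.25, 0.25)))
  expect_equal(quarter$half_life[quarter$id == "target"], 30)
  # a row sitting exactly at the medians gets the 0.85 correction throughout
  at_median <- endpoint_half_life(mk(base))
  expect_equal(at_median$endpoint_fraction[at_median$id == "target"], 0.85)
  expect_equal(at_median$half_life[at_median$id == "target"],
               60 * log(2) / (-log(0.85)), tolerance = 1e-12)
  # fractions at or above 1 are stable
  up <- endpoint_half_life(mk(c(0.85, 0.85, 0.85, 0.85, 0.85, 1.1, 1.1)))
  expect_true(is.infinite(up$half_life[up$id == "target"]))
  expect_error(endpoint_half_life(mk(base), endpoints = c(55, 60)), "55")
})

test_that("endpoint half-life is monotone decreasing in the remaining fraction", {
  tps <- c(0, 10, 20, 30, 40, 50, 60)
  base <- rep(0.85, 7)
  fractions <- seq(0.1, 0.95, by = 0.05)
  hl <- vapply(fractions, function(f) {
    m <- make_matrix(list(bg1 = base, bg2 = base, bg3 = base,
                          target = c(rep(0.85, 5), f, f)), timepoints = tps)
    endpoint_half_life(m)$half_life[4]
  }, numeric(1))
  expect_true(all(diff(hl) > 0))
})

test_that("destruction classes honor the 60 min / 2 h / 5 h thresholds", {
  expect_equal(classify_destruction(c(59, 60, 61, 120, 121, 300, 301, Inf)),
               c("anaphase", "anaphase", "telophase/early G1",
                 "telophase/early G1", "G1", "G1", "stable", "stable"))
  expect_equal(classify_destruction(NA_real_), NA_character_)
  expect_error(classify_destruction(-1), "negative")
})
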