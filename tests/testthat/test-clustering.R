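grid <- default_timepoints()

# 40 profiles from the four kinetic templates with slight multiplicative
# jitter (so distances are non-degenerate), in scrambled order.
planted_matrix <- function(seed = 1, jitter = 0.02, n_per = 10) {
  templates <- list(early = decay_trajectory(grid, 5, 0),
                    intermediate = decay_trajectory(grid, 13.5, 0),
                    late = decay_trajectory(grid, 46, 0),
                    stable = rep(1, length(grid)))
  set.seed(seed)
  rows <- list(); truth <- character(0)
  for (nm in names(templates)) {
    for (i in seq_len(n_per)) {
      rows[[paste(nm, i, sep = "_")]] <-
        templates[[nm]] * exp(rnorm(length(grid), 0, jitter))
      truth[paste(nm, i, sep = "_")] <- nm
    }
  }
  ord <- sample(length(rows))
  list(matrix = make_matrix(rows[ord], timepoints = grid), truth = truth[ord])
}

test_that("planted kinetic classes are recovered perfectly", {
  pm <- planted_matrix()
  res <- cluster_profiles(pm$matrix, k = 4, seed = 1)
  expect_equal(adjusted_rand_index(res$assignments[names(pm$truth)], pm$truth), 1)
  # independent ARI implementation agrees
  expect_equal(mclust::adjustedRandIndex(res$assignments[names(pm$truth)], pm$truth), 1)
  # canonical labels follow ascending half-life
  expect_equal(res$clusters$label, c("early", "intermediate", "late", "stable"))
  expect_true(all(diff(res$clusters$half_life[1:3]) > 0))
  expect_true(is.infinite(res$clusters$half_life[4]))
  # every retained row assigned exactly once
  expect_setequal(names(res$assignments), rownames(pm$matrix$values))
})

test_that("degenerate cluster requests are rejected", {
  pm <- planted_matrix()
  expect_error(cluster_profiles(pm$matrix, k = 1), "at least 2")
  expect_error(cluster_profiles(pm$matrix, k = 1000), "exceeds")
  holey <- pm$matrix; holey$values[1, 1] <- NA
  expect_error(cluster_profiles(holey, k = 4), "zero_fill")
})

test_that("duplicate rows always co-cluster", {
  pm <- planted_matrix(jitter = 0.05)
  m <- pm$matrix
  m$values <- rbind(m$values, dup_a = m$values[1, ], dup_b = m$values[1, ])
  res <- cluster_profiles(m, k = 4, seed = 1)
  expect_equal(unname(res$assignments["dup_a"]), unname(res$assignments["dup_b"]))
  expect_equal(unname(res$assignments["dup_a"]),
               unname(res$assignments[rownames(pm$matrix$values)[1]]))
})

test_that("row order only permutes labels, never the partition", {
  pm <- planted_matrix(seed = 3)
  res1 <- cluster_profiles(pm$matrix, k = 4, restarts = 0, seed = 1)
  perm <- sample(nrow(pm$matrix$values))
  m2 <- make_matrix(setNames(
    lapply(perm, function(i) pm$matrix$values[i, ]),
    rownames(pm$matrix$values)[perm]), timepoints = grid)
  res2 <- cluster_profiles(m2, k = 4, restarts = 0, seed = 1)
  common <- names(res1$assignments)
  expect_equal(adjusted_rand_index(res1$assignments[common],
                                   res2$assignments[common]), 1)
})

test_that("iterative k selection stops before splintering", {
  pm <- planted_matrix(jitter = 0.01)
  sel <- select_k(pm$matrix, k_min = 3, min_cluster_fraction = 0.15, seed = 1)
  expect_equal(sel$k, 4)
  expect_true(all(sel$result$clusters$n >= 0.15 * nrow(pm$matrix$values)))
  # uniform noise never supports a confident split: falls back to k_min
  set.seed(9)
  noise <- make_matrix(setNames(
    lapply(1:60, function(i) runif(length(grid), 0, 1.5)),
    sprintf("r%02d", 1:60)), timepoints = grid)
  sel2 <- suppressWarnings(select_k(noise, k_min = 3, min_cluster_fraction = 0.4,
                                    seed = 1))
  expect_equal(sel2$k, 3)
})

test_that("condition concatenation joins shared rows and diverts singletons", {
  tps <- c(0, 2, 5, 10, 20, 40, 60)
  a <- make_matrix(list(s1 = decay_trajectory(tps, 5, 0),
                        s2 = decay_trajectory(tps, 20, 0),
                        only_a = rep(1, 7)), timepoints = tps)
  b <- make_matrix(list(s1 = decay_trajectory(tps, 10, 0),
                        s2 = decay_trajectory(tps, 40, 0)),
                   timepoints = tps, condition = "perturbed")
  joint <- concatenate_conditions(a, b)
  expect_setequal(rownames(joint$matrix$values), c("s1", "s2"))
  expect_equal(joint$noisy_ids, "only_a")
  expect_equal(ncol(joint$matrix$values), 14L)
  # identical matrices double the columns with no noisy rows
  j2 <- concatenate_conditions(a, a)
  expect_equal(ncol(j2$matrix$values), 14L)
  expect_length(j2$noisy_ids, 0L)
  disjoint <- make_matrix(list(z9 = rep(1, 7)), timepoints = tps)
  expect_error(concatenate_conditions(a, disjoint), "share no row")
})

test_that("the dependence rule is a strict 1.5-fold threshold", {
  # exercised through handcrafted joint clusters with exact member fits
  tps <- seq(0, 60, by = 2.5)
  mk_block <- function(h) decay_trajectory(tps, h, 0)
  a <- make_matrix(list(x1 = mk_block(10), x2 = mk_block(10),
                        y1 = mk_block(30), y2 = mk_block(30)), timepoints = tps)
  b <- make_matrix(list(x1 = mk_block(14.9), x2 = mk_block(14.9),
                        y1 = mk_block(60), y2 = mk_block(60)),
                   timepoints = tps, condition = "perturbed")
  joint <- concatenate_conditions(a, b)
  res <- cluster_profiles(joint$matrix, k = 2, seed = 1,
                          ordering_columns = attr(joint$matrix, "condition_split")$a)
  cmp <- compare_conditions(res, joint$matrix)
  got <- setNames(cmp$dependent, cmp$cluster)
  # 14.9/10 = 1.49 -> not dependent; 60/30 = 2 -> dependent
  slow <- cmp$cluster[which.max(cmp$control_half_life)]
  fast <- cmp$cluster[which.min(cmp$control_half_life)]
  expect_false(got[[fast]])
  expect_true(got[[slow]])
  # a perturbed sentinel with finite control also flags dependence
  b2 <- make_matrix(list(x1 = rep(1, length(tps)), x2 = rep(1, length(tps)),
                         y1 = mk_block(30), y2 = mk_block(30)),
                    timepoints = tps, condition = "perturbed")
  joint2 <- concatenate_conditions(a, b2)
  res2 <- cluster_profiles(joint2$matrix, k = 2, seed = 1,
                           ordering_columns = attr(joint2$matrix, "condition_split")$a)
  cmp2 <- compare_conditions(res2, joint2$matrix)
  expect_true(any(cmp2$dependent & is.infinite(cmp2$perturbed_half_life)))
})
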