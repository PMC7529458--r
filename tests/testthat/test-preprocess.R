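test_that("single missing values are replaced per the time-series rules", {
  expect_equal(impute_missing(c(1.0, NA, 0.6, 0.5)), c(1.0, 0.8, 0.6, 0.5))
  expect_equal(impute_missing(c(NA, 0.9, 0.8)), c(0.9, 0.9, 0.8))
  expect_equal(impute_missing(c(0.9, 0.8, NA)), c(0.9, 0.8, 0.8))
  # runs of two or more stay missing
  expect_equal(impute_missing(c(1.0, NA, NA, 0.4)), c(1.0, NA, NA, 0.4))
  expect_equal(impute_missing(c(NA, NA, 0.4)), c(NA, NA, 0.4))
  # all-missing series returned unchanged
  expect_equal(impute_missing(c(NA_real_, NA, NA)), c(NA_real_, NA, NA))
})

test_that("imputation never alters present values nor fills runs", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    x <- runif(n, 0.1, 2)
    x[runif(n) < 0.35] <- NA
    got <- impute_missing(x)
    expect_equal(got, impute_oracle(x))
    present <- !is.na(x)
    expect_equal(got[present], x[present])
    r <- rle(is.na(x))
    long_runs <- r$values & r$lengths >= 2
    if (any(long_runs)) {
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (j in which(long_runs)) expect_true(all(is.na(got[starts[j]:ends[j]])))
    }
  }
})

test_that("site filtering removes flags and low-confidence localizations", {
  set <- make_sites(rep(list(rep(1, 7)), 4),
                    localization = c(0.75, 0.76, 0.99, 0.60),
                    contaminant = c(FALSE, FALSE, TRUE, FALSE))
  res <- filter_sites(set)
  # 0.75 is excluded (strict >0.75), 0.76 retained, contaminant removed
  expect_equal(res$sites$meta$site_id, "S002")
  expect_equal(res$report$removed[["localization"]], 2L)
  expect_equal(res$report$removed[["contaminant"]], 1L)
  expect_equal(res$report$retained + sum(res$report$removed), res$report$input)
  # idempotence
  again <- filter_sites(res$sites)
  expect_equal(again$sites$meta, res$sites$meta)
  expect_equal(sum(again$report$removed), 0L)
})

test_that("replicate averaging requires enough valid values", {
  des <- tiny_design(timepoints = c(0, 5, 10), replicates = paste0("R", 1:4))
  ratios <- array(NA_real_, dim = c(1, 4, 3))
  ratios[1, , 1] <- c(0.5, 0.7, NA, NA)    # two valid -> mean
  ratios[1, , 2] <- c(0.4, NA, NA, NA)     # one valid -> missing
  ratios[1, , 3] <- rep(0.3, 4)            # four identical -> identical
  set <- make_sites(list(rep(1, 3)), design = des, ratios = ratios)
  m <- average_replicates(set, min_valid = 2)
  expect_equal(unname(m$values[1, ]), c(0.6, NA, 0.3))
  expect_equal(unname(m$provenance[1, ]), c(2, 1, 4))
})

test_that("reference coverage filtering supports count and mask readings", {
  profiles <- list(
    ref  = c(1, .8, NA, .5, NA, .2, .1),   # 5 of 7 present
    full = c(1, .9, .8, .7, .6, .5, .4),   # 7 of 7
    thin = c(1, NA, NA, .5, NA, NA, NA),   # 2 of 7
    offs = c(1, .8, .7, .6, .5, .4, NA))   # 6 of 7 but missing where ref present
  m <- make_matrix(profiles)
  count <- reference_filter(m, "ref", mode = "count")
  expect_setequal(rownames(count$matrix$values), c("ref", "full", "offs"))
  mask <- reference_filter(m, "ref", mode = "mask")
  # offs lacks t=60, where the reference is quantified
  expect_setequal(rownames(mask$matrix$values), c("ref", "full"))
  # the reference itself is always retained
  expect_true("ref" %in% rownames(mask$matrix$values))
  expect_error(reference_filter(m, "nope"), "nope")
})

test_that("zero fill replaces every gap and is idempotent", {
  m <- make_matrix(list(a = c(1, NA, .5, NA, NA, .2, .1),
                        b = c(1, .9, .8, .7, .6, .5, .4)))
  z <- zero_fill(m)
  expect_equal(sum(is.na(z$values)), 0L)
  expect_equal(attr(z, "n_zero_filled"), 3L)
  expect_equal(unname(z$values["a", 2]), 0)
  z2 <- zero_fill(z)
  expect_equal(z2$values, z$values)
  expect_equal(attr(z2, "n_zero_filled"), 0L)
})

test_that("profiles normalize to a starting ratio of one", {
  expect_equal(normalize_to_start(c(0.8, 0.4, 0.2)), c(1, 0.5, 0.25))
  expect_equal(normalize_to_start(c(1, .7, .3)), c(1, .7, .3))
  expect_equal(normalize_to_start(c(3, 3, 3)), c(1, 1, 1))
  expect_error(normalize_to_start(c(0, 1, 2)), "positive")
  expect_error(normalize_to_start(c(NA, 1, 2)), "positive")
})
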