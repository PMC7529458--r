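test_that("noiseless trajectories follow the decay model exactly", {
  cfg <- sim_config(n_sites = 3, n_proteins = 2, noise_cv = 0,
                    missing_rate = 0, seed = 7,
                    class_specs = list(kinetic_class_spec("early", 1, 5, 0)),
                    degraded_protein_specs = list())
  sim <- simulate_dataset(cfg)
  t5 <- which(cfg$timepoints == 5)
  expect_equal(unname(sim$sites$ratios[, , t5]), matrix(0.5, 3, 4))
  expect_equal(unname(sim$sites$ratios[, , 1]), matrix(1, 3, 4))
  # stable proteins stay at ratio 1 throughout
  expect_true(all(sim$proteins$ratios == 1))
})

test_that("degraded proteins follow delayed-exponential destruction", {
  cfg <- sim_config(n_sites = 2, n_proteins = 1, noise_cv = 0,
                    missing_rate = 0, seed = 1,
                    degraded_protein_specs = list(
                      list(id = "DEG_A", half_life = 10, lag = 5)))
  sim <- simulate_dataset(cfg)
  i <- which(sim$proteins$meta$protein_id == "DEG_A")
  tp <- cfg$timepoints
  expect_equal(sim$proteins$ratios[i, 1, tp <= 5], rep(1, sum(tp <= 5)))
  t15 <- which(tp == 15)
  expect_equal(sim$proteins$ratios[i, 1, t15], 0.5)  # lag 5 + half-life 10
  expect_equal(sim$truth$proteins$half_life[i], 15)
})

test_that("a fixed seed gives byte-identical written tables", {
  cfg <- sim_config(n_sites = 40, n_proteins = 10, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("class counts are multinomial around the configured fractions", {
  cfg <- sim_config(n_sites = 1000, seed = 11)
  sim <- simulate_dataset(cfg)
  counts <- table(sim$truth$sites$class)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.25)  # binomial 99% band per class
  for (cl in c("early", "intermediate", "late", "stable")) {
    expect_gte(counts[[cl]], bounds[1])
    expect_lte(counts[[cl]], bounds[2])
  }
})

test_that("control and perturbed conditions share identities but scale kinetics", {
  cfg <- sim_config(n_sites = 50, noise_cv = 0, missing_rate = 0, seed = 3,
                    condition_offset = 1.5, perturbed_half_life_scale = 2)
  a <- simulate_dataset(cfg, "control")
  b <- simulate_dataset(cfg, "perturbed")
  expect_identical(a$sites$meta, b$sites$meta)
  expect_equal(b$truth$sites$half_life, 2 * a$truth$sites$half_life)
  # at t0 the perturbed ratios carry the condition offset
  expect_equal(unname(b$sites$ratios[, , 1]),
               1.5 * unname(a$sites$ratios[, , 1]))
})

test_that("missingness does not perturb the values that remain present", {
  base <- sim_config(n_sites = 30, noise_cv = 0, missing_rate = 0, seed = 5)
  holey <- sim_config(n_sites = 30, noise_cv = 0, missing_rate = 0.3,
                      missing_run_prob = 0.5, seed = 5)
  full <- simulate_dataset(base)$sites$ratios
  sparse <- simulate_dataset(holey)$sites$ratios
  present <- !is.na(sparse)
  expect_true(any(!present))
  expect_equal(sparse[present], full[present])
})

test_that("class-conditional window composition is recovered", {
  cfg <- sim_config(n_sites = 800, seed = 13)
  tr <- simulate_dataset(cfg)$truth$sites
  basic_freq <- function(w) {
    flanks <- paste0(substr(w, 1, 7), substr(w, 9, 15))
    mean(unlist(strsplit(flanks, "")) %in% c("K", "R"))
  }
  expect_gt(basic_freq(tr$window[tr$class == "early"]),
            basic_freq(tr$window[tr$class == "stable"]))
  centre <- substr(tr$window, 8, 8)
  expect_gt(mean(centre[tr$class == "early"] == "T"),
            mean(centre[tr$class == "stable"] == "T"))
})

test_that("invalid configurations are rejected with the violated invariant named", {
  expect_error(sim_config(timepoints = c(1, 2, 3)), "start at 0")
  expect_error(sim_config(n_replicates = 0), "n_replicates")
  expect_error(sim_config(missing_rate = 1.2), "missing_rate")
  expect_error(sim_config(class_specs = list(kinetic_class_spec("early", 0.5, 5))),
               "fractions must sum to 1")
  expect_error(kinetic_class_spec("early", 0.5, 5, plateau = 0.6), "plateau")
  expect_error(kinetic_class_spec("rapid", 0.5, 5), "class name")
})

test_that("cross-mix ratios reflect the condition offset", {
  cfg0 <- sim_config(n_sites = 20, noise_cv = 0, seed = 2, condition_offset = 1)
  expect_equal(unname(simulate_crossmix(cfg0)$ratios), rep(1, 20))
  cfg2 <- sim_config(n_sites = 20, noise_cv = 0, seed = 2, condition_offset = 2)
  expect_equal(unname(simulate_crossmix(cfg2)$ratios), rep(2, 20))
  cfg <- sim_config(n_sites = 500, noise_cv = 0.05, seed = 2,
                    condition_offset = 1.3)
  gm <- exp(mean(log(simulate_crossmix(cfg)$ratios)))
  expect_lt(abs(gm - 1.3) / 1.3, 0.02)
  # single-condition config cannot produce a cross-mix
  expect_error(simulate_crossmix(sim_config(n_sites = 5)), "condition_offset")
})
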