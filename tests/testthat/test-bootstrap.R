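test_that("bootstrap is deterministic under a fixed seed", {
  co <- simulate_cohort(sim_config(n = 40, seed = 8))
  a <- bootstrap_parameters(co, B = 100, seed = 5)
  b <- bootstrap_parameters(co, B = 100, seed = 5)
  expect_identical(a$r$estimates, b$r$estimates)
  expect_identical(a$R0$se, b$R0$se)
  c2 <- bootstrap_parameters(co, B = 100, seed = 6)
  expect_false(identical(a$r$estimates, c2$r$estimates))
})

test_that("a cohort of identical individuals bootstraps to zero SE", {
  so <- tiny_stage_order()
  one <- function(id) ind_rows(id, "F",
                               c("L1", "L1", "pupa", "adult_female",
                                 "adult_female"),
                               c(0, 0, 0, 30, 20))
  co <- cohort_table(do.call(rbind, lapply(sprintf("i%02d", 1:10), one)), so)
  bs <- bootstrap_parameters(co, B = 50, seed = 1)
  for (p in c("r", "lambda", "R0", "T")) {
    expect_equal(bs[[p]]$se, 0)
    expect_equal(bs[[p]]$ci_low, bs[[p]]$ci_high)
    expect_equal(bs[[p]]$n_valid, 50L)
  }
  expect_equal(bs$R0$mean, 50)   # every individual lays exactly 50 eggs
})

test_that("bootstrap replicates match a direct life-table recomputation", {
  # the fast per-individual-day path must equal resample + life_table
  co <- simulate_cohort(sim_config(n = 25, seed = 14))
  ids <- unique(co$individual_id)
  set.seed(42)
  idx <- sample(length(ids), length(ids), replace = TRUE)
  rs <- resample_cohort(co, ids[idx])
  direct <- population_parameters(rs)
  mats <- twosexlt:::individual_day_matrices(co)
  fast <- twosexlt:::params_from_rows(mats, idx)
  expect_equal(unname(fast["r"]), direct$r, tolerance = 1e-9)
  expect_equal(unname(fast["R0"]), direct$R0, tolerance = 1e-12)
  expect_equal(unname(fast["T"]), direct$T, tolerance = 1e-9)
})

test_that("bootstrap SE shrinks with cohort size", {
  ses <- vapply(c(50, 200, 800), function(n) {
    co <- simulate_cohort(det_config(n = n, seed = n))
    bootstrap_parameters(co, B = 400, seed = 1)$r$se
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("bootstrap SE approximates the sampling SD of r across cohorts", {
  cfg <- function(seed) det_config(n = 100, seed = seed)
  co <- simulate_cohort(cfg(1))
  se_boot <- bootstrap_parameters(co, B = 600, seed = 2)$r$se
  r_hat <- vapply(1:300, function(s) {
    population_parameters(age_schedules(simulate_cohort(cfg(1000 + s))))$r
  }, numeric(1))
  expect_lt(abs(se_boot - sd(r_hat)) / sd(r_hat), 0.25)
})

test_that("paired test: identical cohorts give p = 1, swap flips the sign only", {
  so <- tiny_stage_order()
  one <- function(id) ind_rows(id, "F",
                               c("L1", "pupa", "adult_female"), c(0, 0, 12))
  co <- cohort_table(do.call(rbind, lapply(sprintf("i%02d", 1:8), one)), so)
  res <- paired_bootstrap_test(co, co, B = 60, seed = 3)
  for (p in names(res)) {
    expect_equal(res[[p]]$p_value, 1)
    expect_equal(res[[p]]$diff_se, 0)
    expect_equal(res[[p]]$diff_mean, 0)
  }

  a <- simulate_cohort(det_config(n = 60, seed = 51))
  b <- simulate_cohort(det_config(n = 60, seed = 52, fecundity = 1200))
  ab <- paired_bootstrap_test(a, b, B = 300, seed = 7)
  ba <- paired_bootstrap_test(b, a, B = 300, seed = 7)
  for (p in names(ab)) {
    expect_equal(ab[[p]]$p_value, ba[[p]]$p_value)
    expect_equal(ab[[p]]$diff_mean, -ba[[p]]$diff_mean, tolerance = 1e-9)
  }
})

test_that("paired test detects a real difference in r", {
  # two diets with clearly different fecundity -> r differs by many SEs
  a <- simulate_cohort(det_config(n = 100, seed = 61))
  b <- simulate_cohort(det_config(n = 100, seed = 62, fecundity = 600))
  se <- bootstrap_parameters(a, B = 300, seed = 1)$r$se
  ra <- population_parameters(age_schedules(a))$r
  rb <- population_parameters(age_schedules(b))$r
  expect_gt(abs(ra - rb), 5 * se)
  res <- paired_bootstrap_test(a, b, B = 2000, seed = 8)
  expect_lt(res$r$p_value, 0.05)
})

test_that("a sterile cohort cannot support the bootstrap", {
  so <- tiny_stage_order()
  co <- cohort_table(rbind(ind_rows("a", "U", c("L1", "L1")),
                           ind_rows("b", "U", c("L1"))), so)
  expect_error(bootstrap_parameters(co, B = 10, seed = 1),
               "cannot support bootstrap")
})
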