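test_that("age-stage tabulation counts cells and fecundity directly", {
  so <- tiny_stage_order()
  co <- cohort_table(rbind(ind_rows("a", "U", c("L1", "L1")),
                           ind_rows("b", "U", c("L1", "L1"))), so)
  m <- build_age_stage_matrix(co)
  expect_identical(m$nxj["0", "L1"], 2L)
  expect_identical(m$nxj["1", "L1"], 2L)
  expect_identical(sum(m$nxj), 4L)

  # one female laying 50 eggs at age 10 in the adult-female stage
  fem <- ind_rows("f", "F",
                  c(rep("L1", 5), rep("pupa", 4), rep("adult_female", 3)),
                  c(rep(0, 10), 50, 0))
  m2 <- build_age_stage_matrix(cohort_table(fem, so))
  expect_equal(m2$fxj["10", "adult_female"], 50)
  expect_equal(m2$fxj["11", "adult_female"], 0)
})

test_that("sxj is nxj / n01 with s[0,1] = 1 and a non-increasing row sum", {
  m <- list(nxj = matrix(80L, 1, 1), n01 = 100L)
  expect_equal(compute_sxj(m, 100), matrix(0.8, 1, 1))
  expect_error(compute_sxj(m, 0), "n01")

  co <- simulate_cohort(sim_config(n = 40, seed = 11))
  mat <- build_age_stage_matrix(co)
  expect_equal(mat$sxj[1, 1], 1)
  lx <- unname(compute_lx(mat))
  expect_true(all(diff(lx) <= 1e-12))
  expect_equal(lx[1], 1)
})

test_that("mx mixes stage fecundities by survival weight, 0/0 defined as 0", {
  # two adult stages alive at one age: s = .4/.4, f = 50/0 -> mx = 25
  so <- tiny_stage_order()
  days_f <- c("L1", "adult_female")
  days_m <- c("L1", "adult_male")
  rows <- rbind(
    ind_rows("f1", "F", days_f, c(0, 50)), ind_rows("f2", "F", days_f, c(0, 50)),
    ind_rows("m1", "M", days_m), ind_rows("m2", "M", days_m),
    ind_rows("u1", "U", "L1"))
  co <- cohort_table(rows, stage_order(c("L1", "adult_female", "adult_male"),
                                       sexed_from = NULL))
  mat <- build_age_stage_matrix(co)
  mx <- unname(compute_mx(mat))
  expect_equal(mx[2], (0.4 * 50) / 0.8)
  # ages past everyone's death do not occur; append an artificial zero row
  expect_equal(compute_mx(list(sxj = matrix(0, 1, 2),
                               fxj = matrix(c(10, 0), 1, 2))), 0)
})

test_that("R0, T and lambda follow their defining formulas", {
  sch <- data.frame(age = 0:2, lx = c(1, .8, .5), mx = c(0, 10, 20))
  sch$lxmx <- sch$lx * sch$mx
  expect_equal(compute_R0(sch), 18)
  expect_equal(compute_R0(data.frame(lxmx = numeric(3))), 0)
  expect_equal(compute_T(18, 0.2), log(18) / 0.2)
  expect_equal(compute_T(exp(1), 1), 1)
  expect_true(is.na(compute_T(2, 0)))
  expect_error(compute_T(0, 0.1), "positive")
  expect_equal(compute_lambda(0), 1)
  expect_equal(compute_lambda(log(2) / 2), sqrt(2))
  for (r in c(-1, -0.1, 0.05, 0.5))
    expect_lt(abs(log(compute_lambda(r)) - r), 1e-15)
})

test_that("solve_r finds the unique Euler-Lotka root", {
  # R0 = 1 forces r = 0
  sch1 <- data.frame(age = 0:1, lxmx = c(0, 1))
  expect_lt(abs(solve_r(sch1)), 1e-12)
  # single reproducing age: closed form r = ln(2)/2
  sch2 <- data.frame(age = 0:1, lxmx = c(0, 2))
  expect_equal(solve_r(sch2), log(2) / 2, tolerance = 1e-10)
  # declining population
  sch3 <- data.frame(age = 0:1, lxmx = c(0, 0.5))
  expect_equal(solve_r(sch3), -log(2) / 2, tolerance = 1e-10)
  expect_error(solve_r(data.frame(age = 0, lxmx = 0)), "no reproduction")
})

test_that("life expectancy counts the current day and starts at mean lifespan", {
  so <- tiny_stage_order()
  # every individual lives exactly 30 days
  rows <- rbind(ind_rows("a", "M", c(rep("L1", 10), rep("pupa", 10),
                                     rep("adult_male", 10))),
                ind_rows("b", "M", c(rep("L1", 10), rep("pupa", 10),
                                     rep("adult_male", 10))))
  e <- compute_exj(cohort_table(rows, so))
  expect_equal(e["0", "L1"], 30)
  expect_equal(e["29", "adult_male"], 1)   # last day alive

  co <- simulate_cohort(sim_config(n = 60, seed = 2))
  e2 <- compute_exj(co)
  expect_equal(e2["0", "L1"], oracle_mean_lifespan(co), tolerance = 1e-12)
})

test_that("reproductive value recursion: v[0,1] = lambda, sterile path = 0", {
  co <- simulate_cohort(sim_config(n = 60, seed = 9))
  lt <- life_table(co)
  expect_equal(lt$vxj[1, 1], lt$parameters$lambda, tolerance = 1e-9)
  # males can never reproduce: their cells carry zero reproductive value
  vm <- lt$vxj[, "adult_male"]
  expect_true(all(vm[!is.na(vm)] == 0))

  # two-age toy schedule: hand evaluation of the same recursion
  so <- stage_order(c("L1", "adult_female", "adult_male"), sexed_from = NULL)
  toy <- cohort_table(ind_rows("f", "F", c("L1", "adult_female"), c(0, 2)), so)
  r <- solve_r(age_schedules(toy))
  v <- compute_vxj(toy, r)
  # at the reproducing cell: e^{r(1+1)} * e^{-r(1+1)} * f = f = 2
  expect_equal(v["1", "adult_female"], 2, tolerance = 1e-12)
  expect_equal(v["0", "L1"], exp(r), tolerance = 1e-12)
})
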