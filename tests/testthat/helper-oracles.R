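# Naive brute-force reimplementations used as independent oracles.
# Deliberately written as direct loops over individuals, sharing no code
# with the package internals.

oracle_sxj <- function(cohort) {
  so <- attr(cohort, "stage_order")
  n01 <- attr(cohort, "n01")
  ages <- 0:max(cohort$age_day)
  out <- matrix(0, length(ages), length(so),
                dimnames = list(ages, unclass(so)))
  for (i in seq_len(nrow(cohort))) {
    x <- cohort$age_day[i]
    j <- cohort$stage[i]
    out[x + 1, j] <- out[x + 1, j] + 1
  }
  out / n01
}

oracle_lx <- function(cohort) {
  n01 <- attr(cohort, "n01")
  ages <- 0:max(cohort$age_day)
  sapply(ages, function(x) sum(cohort$age_day == x)) / n01
}

oracle_mx <- function(cohort) {
  ages <- 0:max(cohort$age_day)
  sapply(ages, function(x) {
    alive <- sum(cohort$age_day == x)
    if (alive == 0) 0 else sum(cohort$eggs[cohort$age_day == x]) / alive
  })
}

oracle_R0 <- function(cohort) sum(cohort$eggs) / attr(cohort, "n01")

# Euler-Lotka residual; root located by a coarse-then-fine grid scan and
# polished by uniroot inside the 2e-6 bracketing interval
oracle_r <- function(cohort) {
  lx <- oracle_lx(cohort)
  mx <- oracle_mx(cohort)
  age <- seq_along(lx) - 1
  f <- function(r) sum(exp(-r * (age + 1)) * lx * mx) - 1
  grid <- seq(-2, 2, by = 1e-3)
  v <- vapply(grid, f, numeric(1))
  k <- which(v[-1] * v[-length(v)] <= 0)[1]
  fine <- seq(grid[k], grid[k + 1], by = 1e-6)
  vf <- vapply(fine, f, numeric(1))
  kf <- which(vf[-1] * vf[-length(vf)] <= 0)[1]
  stats::uniroot(f, c(fine[kf], fine[kf + 1]), tol = 1e-14)$root
}

oracle_mean_lifespan <- function(cohort) {
  deaths <- tapply(cohort$age_day, cohort$individual_id, max)
  mean(deaths + 1)
}

# hand-built three-stage cohort: ids/sex/day-by-day rows
tiny_stage_order <- function() {
  stage_order(c("L1", "pupa", "adult_female", "adult_male"))
}

# one individual's rows
ind_rows <- function(id, sex, stages, eggs = NULL) {
  n <- length(stages)
  if (is.null(eggs)) eggs <- rep(0L, n)
  data.frame(individual_id = id, sex = sex, age_day = 0:(n - 1),
             stage = stages, eggs = eggs, stringsAsFactors = FALSE)
}

# a small deterministic-duration simulator config for closed-form work
det_config <- function(n = 100, seed = 1, fecundity = 2650,
                       survival_scale = 1) {
  s <- c(L1 = 0.985, L2 = 0.99, L3 = 0.995, L4 = 0.995, L5 = 0.995,
         L6 = 0.995, pupa = 0.99, adult_female = 0.99, adult_male = 0.99)
  s <- 1 - (1 - s) * survival_scale
  sim_config(
    n = n, seed = seed,
    durations = list(L1 = 3, L2 = 3, L3 = 4, L4 = 4, L5 = 2, L6 = 4,
                     pupa = 10, adult_female = 17, adult_male = 14),
    survival = s, fecundity = fecundity)
}
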