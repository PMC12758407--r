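#' Tabulate a cohort into an age-stage matrix
#'
#' Counts, for every age x (days) and stage j, the number of individuals
#' alive in that cell, the age-stage survival rate `sxj = nxj / n01`
#' (probability that a newborn is alive and in stage j at age x), and the
#' age-stage fecundity `fxj` (mean eggs laid per individual in the cell;
#' non-zero only for the adult-female stage).
#'
#' @param cohort A [cohort_table()].
#' @return An object of class `"age_stage_matrix"`: a list with integer
#'   matrix `nxj`, numeric matrices `sxj` and `fxj` (rows = ages 0..max
#'   age, columns = stages), `n01`, `max_age` and the `stage_order`.
#' @examples
#' co <- simulate_cohort(sim_config(n = 30, seed = 1))
#' m <- build_age_stage_matrix(co)
#' m$sxj[1, 1]   # 1: all newborns start at age 0 in the first stage
#' @export
build_age_stage_matrix <- function(cohort) {
  if (!inherits(cohort, "cohort_table"))
    cohort <- cohort_table(cohort)
  if (nrow(cohort) == 0L) stop("empty cohort")
  so <- attr(cohort, "stage_order")
  n01 <- attr(cohort, "n01")
  max_age <- max(cohort$age_day)
  ages <- 0:max_age
  af <- factor(cohort$age_day, levels = ages)
  sf <- factor(cohort$stage, levels = unclass(so))
  nxj <- table(af, sf)
  nxj <- matrix(as.integer(nxj), nrow = length(ages),
                dimnames = list(age = ages, stage = unclass(so)))
  eggs <- tapply(cohort$eggs, list(af, sf), sum, default = 0L)
  fxj <- ifelse(nxj > 0L, eggs / nxj, 0)
  dimnames(fxj) <- dimnames(nxj)
  out <- structure(list(nxj = nxj, fxj = fxj, n01 = n01,
                        max_age = max_age, stage_order = so),
                   class = "age_stage_matrix")
  out$sxj <- compute_sxj(out, n01)
  out
}

#' Age-stage survival rates sxj = nxj / n01
#'
#' @param matrix An `age_stage_matrix` (the `nxj` counts are used).
#' @param n01 Number of newborns that entered the life table.
#' @return Numeric matrix of survival rates in `[0, 1]`.
#' @export
compute_sxj <- function(matrix, n01 = matrix$n01) {
  if (!is.numeric(n01) || n01 <= 0) stop("n01 must be a positive count")
  matrix$nxj / n01
}

#' Age-specific survival lx
#'
#' `lx` is the probability of surviving from entry into the life table to
#' age x, pooled over stages and sexes: the row sums of `sxj`.
#'
#' @param matrix An `age_stage_matrix`.
#' @return Numeric vector indexed by age 0..max_age.
#' @export
compute_lx <- function(matrix) {
  rowSums(matrix$sxj)
}

#' Age-specific fecundity mx
#'
#' Mean eggs laid per individual *surviving* to age x (both sexes pooled,
#' which is what distinguishes the two-sex table from female-only
#' methods): `mx = sum_j(sxj * fxj) / sum_j(sxj)`. Ages with no survivors
#' have `mx` defined as 0 so they contribute nothing downstream.
#'
#' @param matrix An `age_stage_matrix`.
#' @return Numeric vector indexed by age.
#' @export
compute_mx <- function(matrix) {
  lx <- rowSums(matrix$sxj)
  num <- rowSums(matrix$sxj * matrix$fxj)
  ifelse(lx > 0, num / lx, 0)
}

#' Age schedules lx, mx and their product
#'
#' @param matrix An `age_stage_matrix` (or a cohort, which is tabulated
#'   first).
#' @return A data frame of class `"age_schedules"` with columns `age`,
#'   `lx`, `mx`, `lxmx`.
#' @export
age_schedules <- function(matrix) {
  if (inherits(matrix, "cohort_table")) matrix <- build_age_stage_matrix(matrix)
  lx <- compute_lx(matrix)
  mx <- compute_mx(matrix)
  structure(data.frame(age = 0:matrix$max_age, lx = lx, mx = mx,
                       lxmx = lx * mx, row.names = NULL),
            class = c("age_schedules", "data.frame"))
}

#' Net reproductive rate R0 = sum(lx * mx)
#'
#' Expected lifetime offspring per individual entering the life table.
#'
#' @param schedules An [age_schedules()] data frame (or anything with an
#'   `lxmx` column).
#' @return Non-negative number.
#' @export
compute_R0 <- function(schedules) {
  sum(schedules$lxmx)
}

euler_lotka_residual <- function(r, age, lxmx) {
  sum(exp(-r * (age + 1)) * lxmx) - 1
}

#' Intrinsic rate of increase r (Euler-Lotka equation)
#'
#' Solves `sum_x exp(-r (x + 1)) lx mx = 1` for r, with the age index
#' starting at 0 and a one-day census interval (hence the `x + 1`
#' exponent). The residual is strictly decreasing in r, so the root is
#' unique; it is found by bracketed bisection (bracket grown outward by
#' doubling from `[-1, 1]`), which is derivative-free and robust to spiky
#' `lxmx` schedules.
#'
#' @param schedules An [age_schedules()] data frame.
#' @param tol Absolute tolerance on the Euler-Lotka residual.
#' @return The intrinsic rate of increase, per day.
#' @export
solve_r <- function(schedules, tol = 1e-12) {
  .solve_r(schedules$age, schedules$lxmx, tol)
}

.solve_r <- function(age, lxmx, tol = 1e-12) {
  if (sum(lxmx) <= 0) stop("no reproduction; r undefined")
  f <- function(r) euler_lotka_residual(r, age, lxmx)
  lo <- -1; hi <- 1
  while (f(lo) < 0) { lo <- lo * 2; if (lo < -700) stop("no lower bracket") }
  while (f(hi) > 0) { hi <- hi * 2; if (hi > 700) stop("no upper bracket") }
  # f is strictly decreasing: f(lo) >= 0 >= f(hi)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol) return(mid)
    if (fm > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Mean generation time T = ln(R0) / r
#'
#' Time needed for a population at its stable age-stage distribution,
#' growing at rate r, to multiply by R0.
#'
#' @param R0 Net reproductive rate (> 0).
#' @param r Intrinsic rate of increase (non-zero).
#' @return Generation time in days; `NA_real_` when r = 0 (the ratio is
#'   0/0 there, so the quantity is undefined rather than infinite).
#' @export
compute_T <- function(R0, r) {
  if (!is.finite(R0) || R0 <= 0) stop("R0 must be positive")
  if (r == 0) return(NA_real_)
  log(R0) / r
}

#' Finite rate of increase lambda = exp(r)
#'
#' Per-day population multiplier once the stable age-stage distribution
#' is reached.
#'
#' @param r Intrinsic rate of increase.
#' @return `exp(r)`.
#' @export
compute_lambda <- function(r) exp(r)

#' Population parameters r, lambda, R0, T of a cohort
#'
#' @param x A `cohort_table`, `age_stage_matrix` or `age_schedules`
#'   object.
#' @param tol Residual tolerance passed to [solve_r()].
#' @return A list of class `"population_parameters"` with elements `r`,
#'   `lambda`, `R0`, `T` (all per day except `R0`, offspring per
#'   individual). When the cohort has no reproduction, `R0` is 0 and `r`,
#'   `lambda`, `T` are `NA`.
#' @export
population_parameters <- function(x, tol = 1e-12) {
  sch <- if (inherits(x, "age_schedules")) x else age_schedules(x)
  R0 <- compute_R0(sch)
  if (R0 <= 0) {
    out <- list(r = NA_real_, lambda = NA_real_, R0 = R0, T = NA_real_)
  } else {
    r <- solve_r(sch, tol = tol)
    out <- list(r = r, lambda = compute_lambda(r), R0 = R0,
                T = compute_T(R0, r))
  }
  structure(out, class = "population_parameters")
}

#' @export
print.population_parameters <- function(x, digits = 6, ...) {
  cat("Population parameters (age-stage, two-sex life table)\n")
  cat(sprintf("  r      = %.*g  d^-1   (intrinsic rate of increase)\n",
              digits, x$r))
  cat(sprintf("  lambda = %.*g  d^-1   (finite rate of increase)\n",
              digits, x$lambda))
  cat(sprintf("  R0     = %.*g  offspring/individual\n", digits, x$R0))
  cat(sprintf("  T      = %.*g  d      (mean generation time)\n",
              digits, x$T))
  invisible(x)
}

# rows (one per individual): death age and per-day occupancy, used by the
# expectancy/reproductive-value recursions and the bootstrap fast path
individual_paths <- function(cohort) {
  ids <- cohort_ids(cohort)
  f <- factor(cohort$individual_id, levels = ids)
  list(ids = ids,
       age = split(cohort$age_day, f),
       stage = split(cohort$stage, f),
       eggs = split(cohort$eggs, f),
       death_age = vapply(split(cohort$age_day, f), max, integer(1)))
}

#' Age-stage life expectancy exj
#'
#' Expected remaining lifetime (in days, counting the current day: an
#' individual on its last day of life has expectancy 1) of an individual
#' currently at age x and stage j, obtained by forward accumulation of
#' the empirical conditional survival of the individuals observed in that
#' cell. `exj` at age 0, stage 1 equals the cohort's mean lifespan.
#'
#' @param cohort A [cohort_table()].
#' @return Numeric matrix (ages x stages); cells never visited by any
#'   individual are `NA`.
#' @export
compute_exj <- function(cohort) {
  if (!inherits(cohort, "cohort_table")) cohort <- cohort_table(cohort)
  so <- attr(cohort, "stage_order")
  max_age <- max(cohort$age_day)
  # remaining days for each individual-day, then average within cells:
  # sum_{i >= x} P(alive at i | alive at (x, j)) telescopes to the mean
  # of (death age - x + 1) over the cell's members
  death <- stats::ave(cohort$age_day, cohort$individual_id, FUN = max)
  remaining <- death - cohort$age_day + 1L
  af <- factor(cohort$age_day, levels = 0:max_age)
  sf <- factor(cohort$stage, levels = unclass(so))
  exj <- tapply(remaining, list(af, sf), mean, default = NA_real_)
  dimnames(exj) <- list(age = 0:max_age, stage = unclass(so))
  exj
}

#' Age-stage reproductive value vxj
#'
#' Discounted expected future offspring of an individual at age x, stage
#' j: `vxj = exp(r (x+1)) / sxj * sum_{i >= x} exp(-r (i+1)) *
#' sum_y s'_{iy|xj} f_iy`, where `s'_{iy|xj}` is the empirical survival
#' to (i, y) conditional on being alive at (x, j) and `f_iy` is the
#' cohort's age-stage fecundity. Conditioning on a newborn recovers the
#' Euler-Lotka sum, so `v[0, 1] = lambda` exactly.
#'
#' @param cohort A [cohort_table()].
#' @param r Intrinsic rate of increase of the same cohort (from
#'   [solve_r()]); supplied explicitly so bootstrap replicates can reuse
#'   their own r.
#' @return Numeric matrix (ages x stages); unvisited cells are `NA`.
#' @export
compute_vxj <- function(cohort, r = NULL) {
  if (!inherits(cohort, "cohort_table")) cohort <- cohort_table(cohort)
  mat <- build_age_stage_matrix(cohort)
  if (is.null(r)) r <- solve_r(age_schedules(mat))
  so <- attr(cohort, "stage_order")
  stages <- unclass(so)
  max_age <- mat$max_age
  paths <- individual_paths(cohort)
  n <- length(paths$ids)
  # per-individual discounted stream of cohort cell fecundities:
  # g_k(i) = exp(-r (i+1)) * f_{i, stage_k(i)}, accumulated from the tail
  tail_sum <- vector("list", n)
  for (k in seq_len(n)) {
    age <- paths$age[[k]]
    stg <- match(paths$stage[[k]], stages)
    g <- exp(-r * (age + 1)) * mat$fxj[cbind(age + 1L, stg)]
    tail_sum[[k]] <- rev(cumsum(rev(g)))
  }
  v <- matrix(NA_real_, nrow = max_age + 1L, ncol = length(stages),
              dimnames = list(age = 0:max_age, stage = stages))
  acc <- matrix(0, nrow = max_age + 1L, ncol = length(stages))
  for (k in seq_len(n)) {
    age <- paths$age[[k]]
    stg <- match(paths$stage[[k]], stages)
    cells <- cbind(age + 1L, stg)
    acc[cells] <- acc[cells] + tail_sum[[k]]
  }
  pos <- mat$nxj > 0L
  v[pos] <- exp(r * (as.integer(rownames(v))[row(v)[pos]] + 1)) *
    acc[pos] / mat$nxj[pos]
  v
}

#' Full age-stage two-sex life table of a cohort
#'
#' One-stop analysis: tabulates the cohort, derives the age schedules,
#' solves the Euler-Lotka equation and computes the age-stage life
#' expectancy and reproductive value matrices.
#'
#' @param cohort A [cohort_table()] (or a plain data frame in the cohort
#'   layout).
#' @param stage_order Stage order used if `cohort` is a plain data frame.
#' @param tol Residual tolerance for [solve_r()].
#' @return A list of class `"two_sex_life_table"` with elements `matrix`
#'   (the `age_stage_matrix`), `schedules`, `parameters`, `exj`, `vxj`
#'   and `n01`.
#' @examples
#' lt <- life_table(simulate_cohort(sim_config(n = 50, seed = 42)))
#' lt$parameters
#' @export
life_table <- function(cohort, stage_order = twosexlt::stage_order(),
                       tol = 1e-12) {
  if (!inherits(cohort, "cohort_table"))
    cohort <- cohort_table(cohort, stage_order)
  mat <- build_age_stage_matrix(cohort)
  sch <- age_schedules(mat)
  par <- population_parameters(sch, tol = tol)
  vxj <- if (is.na(par$r)) NULL else compute_vxj(cohort, par$r)
  structure(list(matrix = mat, schedules = sch, parameters = par,
                 exj = compute_exj(cohort), vxj = vxj,
                 n01 = attr(cohort, "n01")),
            class = "two_sex_life_table")
}

#' @export
print.two_sex_life_table <- function(x, ...) {
  cat("Age-stage two-sex life table: n01 =", x$n01,
      "individuals, max age", x$matrix$max_age, "d\n")
  print(x$parameters)
  cat(sprintf("  e[0,1] = %.4g d (mean lifespan)\n", x$exj[1, 1]))
  invisible(x)
}
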