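#' Configure the cohort simulator
#'
#' The simulator generates per-individual life histories with the
#' statistical structure the life table analysis assumes: each individual
#' walks the pre-adult stages in order, spends a sampled number of days
#' in each, survives every day with a stage-specific daily probability,
#' is sexed at pupation, and -- if female -- lays eggs along a unimodal
#' daily schedule after a pre-oviposition period.
#'
#' Stage durations are either fixed (a single integer per stage) or
#' shifted negative-binomial: `duration = 1 + NB(size, mu = mean - 1)`,
#' so every stage lasts at least one day. A female's daily egg counts are
#' a discretized Gaussian kernel over the oviposition window, scaled by
#' largest-remainder rounding so that a female surviving her full adult
#' span lays exactly `fecundity` eggs.
#'
#' The defaults emulate a noctuid moth (six larval instars, pupa, adult)
#' with a larval span near 19.5 d, a pupal span near 10.5 d, survival to
#' pupation near 0.84 and a mean total fecundity of about 2,650 eggs per
#' female -- a plausible rearing phenotype, not a fit to any data set.
#'
#' @param n Cohort size (newborns at age 0, stage 1). Default 100,
#'   matching a typical rearing design of five groups of 20 larvae.
#' @param stage_order A [stage_order()]; the last two stages are the
#'   sexed adults and receive sex-specific durations.
#' @param durations Named list over the pre-adult stages plus
#'   `adult_female`/`adult_male`: each element a single positive integer
#'   (fixed duration, days) or `c(mean =, size =)` for the shifted
#'   negative-binomial.
#' @param survival Named numeric vector of daily survival probabilities
#'   in (0, 1], one per stage (adults included).
#' @param female_fraction Probability that an individual is female,
#'   applied at pupation (entry into the penultimate pre-adult stage's
#'   successor); individuals dying earlier keep sex `"U"`.
#' @param fecundity Expected total eggs per fully surviving female.
#' @param preoviposition Days after adult emergence before laying starts.
#' @param oviposition_days Length of the laying window, days.
#' @param fecundity_peak,fecundity_spread Peak day (within the laying
#'   window, 1-based) and Gaussian spread of the daily egg kernel.
#' @param seed Integer seed making the cohort reproducible.
#' @return A list of class `"sim_config"`.
#' @seealso [simulate_cohort()], [expected_schedules()]
#' @export
sim_config <- function(n = 100,
                       stage_order = twosexlt::stage_order(),
                       durations = list(
                         L1 = c(mean = 3, size = 12),
                         L2 = c(mean = 3, size = 12),
                         L3 = c(mean = 4, size = 12),
                         L4 = c(mean = 4, size = 12),
                         L5 = c(mean = 2, size = 12),
                         L6 = c(mean = 4, size = 12),
                         pupa = c(mean = 10, size = 20),
                         adult_female = c(mean = 17, size = 10),
                         adult_male = c(mean = 14, size = 10)),
                       survival = c(L1 = 0.985, L2 = 0.99, L3 = 0.995,
                                    L4 = 0.995, L5 = 0.995, L6 = 0.995,
                                    pupa = 0.99, adult_female = 1,
                                    adult_male = 1),
                       female_fraction = 0.5,
                       fecundity = 2650,
                       preoviposition = 2,
                       oviposition_days = 14,
                       fecundity_peak = 5,
                       fecundity_spread = 3,
                       seed = NULL) {
  so <- as_stage_order(stage_order)
  stages <- unclass(so)
  if (length(stages) < 3L)
    stop("the simulator needs at least one pre-adult stage")
  if (!setequal(names(durations), stages))
    stop("'durations' must name every stage exactly once")
  if (!setequal(names(survival), stages))
    stop("'survival' must name every stage exactly once")
  for (s in stages) {
    d <- durations[[s]]
    if (length(d) == 1L) {
      if (is.na(d) || d < 1 || d != round(d))
        stop("fixed duration for stage '", s, "' must be a positive integer")
    } else {
      if (!all(c("mean", "size") %in% names(d)) || d[["mean"]] < 1 ||
          d[["size"]] <= 0)
        stop("stochastic duration for stage '", s,
             "' needs mean >= 1 and size > 0")
    }
    p <- survival[[s]]
    if (is.na(p) || p <= 0 || p > 1)
      stop("daily survival for stage '", s, "' must be in (0, 1]")
  }
  if (n < 1 || n != round(n)) stop("'n' must be a positive integer")
  if (female_fraction < 0 || female_fraction > 1)
    stop("'female_fraction' must be in [0, 1]")
  if (fecundity < 0) stop("'fecundity' must be >= 0")
  if (preoviposition < 0 || preoviposition != round(preoviposition))
    stop("'preoviposition' must be a non-negative integer")
  if (oviposition_days < 1) stop("'oviposition_days' must be >= 1")
  if (fecundity_spread <= 0) stop("'fecundity_spread' must be > 0")
  structure(list(n = as.integer(n), stage_order = so,
                 durations = durations, survival = survival[stages],
                 female_fraction = female_fraction, fecundity = fecundity,
                 preoviposition = as.integer(preoviposition),
                 oviposition_days = as.integer(oviposition_days),
                 fecundity_peak = fecundity_peak,
                 fecundity_spread = fecundity_spread, seed = seed),
            class = "sim_config")
}

# daily egg counts over the oviposition window: discretized Gaussian,
# largest-remainder rounding so the counts sum exactly to `total`
fecundity_kernel <- function(total, days, peak, spread) {
  if (total <= 0) return(integer(days))
  w <- exp(-((seq_len(days) - peak)^2) / (2 * spread^2))
  x <- total * w / sum(w)
  fl <- floor(x)
  rem <- round(total) - sum(fl)
  if (rem > 0) {
    extra <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

sample_duration <- function(spec, n) {
  if (length(spec) == 1L) rep(as.integer(spec), n)
  else as.integer(1L + stats::rnbinom(n, size = spec[["size"]],
                                      mu = spec[["mean"]] - 1))
}

#' Simulate a rearing cohort
#'
#' Draws `config$n` individual life histories under the model described
#' in [sim_config()] and returns them as a validated [cohort_table()].
#' The same seed always yields the identical cohort.
#'
#' @param config A [sim_config()].
#' @return A `cohort_table`.
#' @examples
#' co <- simulate_cohort(sim_config(n = 20, seed = 7))
#' life_table(co)$parameters
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  so <- config$stage_order
  stages <- unclass(so)
  beta <- length(stages)
  female <- attr(so, "female"); male <- attr(so, "male")
  pre_adult <- stages[seq_len(beta - 2L)]
  n <- config$n
  pupal_stage <- pre_adult[length(pre_adult)]

  # per-stage durations for everyone, then per-stage survived days:
  # within a stage of duration D and daily survival p, the individual
  # either completes the stage (prob p^D) or its last day alive is day k
  # of the stage (prob p^(k-1) (1 - p))
  dur <- vapply(pre_adult, function(s) sample_duration(config$durations[[s]], n),
                integer(n))
  dur <- matrix(dur, nrow = n, dimnames = list(NULL, pre_adult))
  sex <- rep("U", n)
  kernel <- fecundity_kernel(config$fecundity, config$oviposition_days,
                             config$fecundity_peak, config$fecundity_spread)

  rows_id <- rows_sex <- rows_stage <- vector("list", n)
  rows_age <- rows_eggs <- vector("list", n)
  for (k in seq_len(n)) {
    stage_days <- integer(0); alive <- TRUE
    for (s in pre_adult) {
      if (!alive) break
      if (s == pupal_stage)   # sex observable at pupation
        sex[k] <- if (stats::runif(1) < config$female_fraction) "F" else "M"
      D <- dur[k, s]
      p <- config$survival[[s]]
      lived <- if (p == 1) D else {
        g <- 1L + stats::rgeom(1, 1 - p)   # day of death within the stage
        if (g > D) D else { alive <- FALSE; g }
      }
      stage_days <- c(stage_days, rep(match(s, stages), lived))
    }
    eggs_day <- integer(0)
    if (alive) {                            # adult stage, sex-specific
      ad <- if (sex[k] == "F") female else male
      D <- sample_duration(config$durations[[ad]], 1L)
      p <- config$survival[[ad]]
      lived <- if (p == 1) D else {
        g <- 1L + stats::rgeom(1, 1 - p)
        if (g > D) D else g
      }
      stage_days <- c(stage_days, rep(match(ad, stages), lived))
      if (sex[k] == "F") {
        eggs_day <- integer(lived)
        lay <- seq_len(lived) - config$preoviposition   # kernel day index
        ok <- lay >= 1 & lay <= config$oviposition_days
        eggs_day[ok] <- kernel[lay[ok]]
      }
    }
    len <- length(stage_days)
    rows_id[[k]] <- rep(sprintf("ind%04d", k), len)
    rows_age[[k]] <- 0:(len - 1L)
    rows_stage[[k]] <- stages[stage_days]
    e <- integer(len)
    if (length(eggs_day)) e[(len - length(eggs_day) + 1L):len] <- eggs_day
    rows_eggs[[k]] <- e
    rows_sex[[k]] <- rep(sex[k], len)
  }
  cohort_table(data.frame(
    individual_id = unlist(rows_id), sex = unlist(rows_sex),
    age_day = unlist(rows_age), stage = unlist(rows_stage),
    eggs = unlist(rows_eggs), stringsAsFactors = FALSE), so)
}

#' Closed-form expected schedules for deterministic-duration configs
#'
#' When every stage duration in the configuration is fixed, the survival
#' and fecundity schedules have a closed form: `lx` is the running
#' product of the daily survival along the (sex-specific) deterministic
#' stage path, and `mx` mixes the female egg kernel with the female /
#' male survivorship weights. The true population parameters follow by
#' feeding these schedules to the same estimators used on data, so a
#' simulated cohort's estimates can be checked against known truth.
#'
#' @param config A [sim_config()] with fixed (length-1 integer)
#'   durations for every stage.
#' @return A list of class `"expected_schedules"`: `schedules` (an
#'   [age_schedules()] data frame), `true_r`, `true_lambda`, `true_R0`,
#'   `true_T` (`NA` for the rate-based ones when fecundity is 0).
#' @export
expected_schedules <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(lengths(config$durations) != 1L))
    stop("closed form requires deterministic durations")
  so <- config$stage_order
  stages <- unclass(so)
  beta <- length(stages)
  female <- attr(so, "female"); male <- attr(so, "male")
  pre_adult <- stages[seq_len(beta - 2L)]

  path_for <- function(adult) {
    s <- unlist(lapply(c(pre_adult, adult), function(st)
      rep(st, config$durations[[st]])))
    s
  }
  daily_surv <- function(path) config$survival[path]
  # alive at age x <=> survived days 0..x-1; ages run 0..length(path)-1
  surv_curve <- function(path) {
    p <- daily_surv(path)
    c(1, cumprod(p))[seq_along(path)]
  }
  pf <- path_for(female); pm <- path_for(male)
  max_age <- max(length(pf), length(pm)) - 1L
  ages <- 0:max_age
  lf <- c(surv_curve(pf), rep(0, max_age + 1L - length(pf)))
  lm_ <- c(surv_curve(pm), rep(0, max_age + 1L - length(pm)))
  phi <- config$female_fraction
  lx <- phi * lf + (1 - phi) * lm_

  kernel <- fecundity_kernel(config$fecundity, config$oviposition_days,
                             config$fecundity_peak, config$fecundity_spread)
  eggs_f <- numeric(max_age + 1L)   # eggs laid at age x by a female alive then
  adult_start <- sum(vapply(pre_adult, function(st)
    config$durations[[st]], numeric(1)))  # age of first adult day
  for (a in seq_along(pf)) {
    x <- a - 1L
    if (pf[a] == female) {
      lay <- (a - adult_start) - config$preoviposition
      if (lay >= 1 && lay <= config$oviposition_days)
        eggs_f[x + 1L] <- kernel[lay]
    }
  }
  mx <- ifelse(lx > 0, phi * lf * eggs_f / lx, 0)
  sch <- structure(data.frame(age = ages, lx = lx, mx = mx, lxmx = lx * mx,
                              row.names = NULL),
                   class = c("age_schedules", "data.frame"))
  R0 <- compute_R0(sch)
  if (R0 > 0) {
    r <- solve_r(sch)
    out <- list(schedules = sch, true_r = r, true_lambda = compute_lambda(r),
                true_R0 = R0, true_T = compute_T(R0, r))
  } else {
    out <- list(schedules = sch, true_r = NA_real_, true_lambda = NA_real_,
                true_R0 = 0, true_T = NA_real_)
  }
  structure(out, class = "expected_schedules")
}
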