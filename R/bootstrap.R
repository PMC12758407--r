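# Bootstrap inference for the population parameters.
#
# The resampling unit is the individual: a bootstrap replicate draws n01
# whole life histories with replacement and recomputes r, lambda, R0, T.
# Only lx and mx enter those parameters, so replicates are formed from
# precomputed per-individual daily alive/egg matrices rather than by
# rebuilding the full age-stage tabulation -- identical results, far
# cheaper.

# n x (max_age + 1) matrices: alive indicator and eggs laid per day
individual_day_matrices <- function(cohort) {
  ids <- cohort_ids(cohort)
  n <- length(ids)
  max_age <- max(cohort$age_day)
  i <- match(cohort$individual_id, ids)
  j <- cohort$age_day + 1L
  alive <- matrix(0, n, max_age + 1L)
  eggs <- matrix(0, n, max_age + 1L)
  alive[cbind(i, j)] <- 1
  eggs[cbind(i, j)] <- cohort$eggs
  list(alive = alive, eggs = eggs, n = n, age = 0:max_age)
}

params_from_rows <- function(mats, idx, tol = 1e-10) {
  n <- length(idx)
  lx <- colSums(mats$alive[idx, , drop = FALSE]) / n
  lxmx <- colSums(mats$eggs[idx, , drop = FALSE]) / n
  R0 <- sum(lxmx)
  if (R0 <= 0)
    return(c(r = NA_real_, lambda = NA_real_, R0 = R0, T = NA_real_))
  r <- .solve_r(mats$age, lxmx, tol)
  c(r = r, lambda = exp(r), R0 = R0, T = log(R0) / r)
}

# independent per-iteration substreams: iteration b always sees the same
# RNG state regardless of execution order
iteration_seeds <- function(seed, B) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, B)
}

#' Bootstrap means, standard errors and CIs of population parameters
#'
#' Resamples `n01` individuals with replacement `B` times, recomputing
#' r, lambda, R0 and T for each replicate. Replicates in which no
#' reproducing female was drawn (R0 = 0) are flagged invalid and
#' excluded from the moments; their count is reported via `n_valid`.
#'
#' @param cohort A [cohort_table()].
#' @param B Number of bootstrap iterations (the rearing literature's
#'   convention is 100,000; smaller values are adequate for standard
#'   errors).
#' @param seed Integer seed; the same seed always reproduces the same
#'   estimates, independent of iteration order.
#' @param ci_level Coverage of the percentile confidence interval.
#' @return A named list (class `"bootstrap_results"`) over parameters
#'   `r`, `lambda`, `R0`, `T`; each element has `estimates` (length B,
#'   `NA` for invalid draws), `mean`, `se`, `ci_low`, `ci_high`,
#'   `n_valid`.
#' @examples
#' co <- simulate_cohort(sim_config(n = 50, seed = 3))
#' bootstrap_parameters(co, B = 200, seed = 1)$r$se
#' @export
bootstrap_parameters <- function(cohort, B = 2000, seed = NULL,
                                 ci_level = 0.95) {
  if (!inherits(cohort, "cohort_table")) cohort <- cohort_table(cohort)
  if (B < 1) stop("B must be >= 1")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)")
  mats <- individual_day_matrices(cohort)
  seeds <- iteration_seeds(seed, B)
  draws <- matrix(NA_real_, B, 4,
                  dimnames = list(NULL, c("r", "lambda", "R0", "T")))
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    idx <- sample.int(mats$n, mats$n, replace = TRUE)
    draws[b, ] <- params_from_rows(mats, idx)
  }
  valid <- !is.na(draws[, "r"])
  if (!any(valid)) stop("cohort cannot support bootstrap: all ",
                        B, " resamples had no reproduction")
  a <- (1 - ci_level) / 2
  out <- lapply(colnames(draws), function(p) {
    est <- draws[, p]
    v <- est[valid]
    list(parameter = p, estimates = est,
         mean = mean(v), se = stats::sd(v),
         ci_low = unname(stats::quantile(v, a)),
         ci_high = unname(stats::quantile(v, 1 - a)),
         n_valid = sum(valid))
  })
  names(out) <- colnames(draws)
  structure(out, B = B, ci_level = ci_level, class = "bootstrap_results")
}

#' @export
print.bootstrap_results <- function(x, digits = 5, ...) {
  cat("Bootstrap (B = ", attr(x, "B"), ", valid = ", x[[1]]$n_valid,
      ", ", round(100 * attr(x, "ci_level")), "% percentile CI)\n", sep = "")
  for (p in names(x))
    cat(sprintf("  %-6s mean %.*g  se %.*g  CI [%.*g, %.*g]\n", p,
                digits, x[[p]]$mean, digits, x[[p]]$se,
                digits, x[[p]]$ci_low, digits, x[[p]]$ci_high))
  invisible(x)
}

#' Paired bootstrap test comparing two cohorts
#'
#' In each iteration both cohorts are resampled independently and the
#' difference `d_b = theta_A - theta_B` is recorded for each population
#' parameter. The two-sided p-value is the sign-count form
#' `p = 2 min(#\{d <= 0\}, #\{d >= 0\}) / B_valid`, clamped to at most
#' 1; it is symmetric under swapping the two cohorts. Iterations where
#' either resample has no reproduction are dropped from `B_valid`.
#'
#' @param cohort_a,cohort_b Two [cohort_table()] objects (e.g. two diet
#'   treatments).
#' @param B Number of paired iterations.
#' @param seed Integer seed.
#' @return A named list (class `"paired_bootstrap_results"`) over `r`,
#'   `lambda`, `R0`, `T`; each element holds `diff_mean`, `diff_se`,
#'   `p_value`, `B`, `n_valid`.
#' @export
paired_bootstrap_test <- function(cohort_a, cohort_b, B = 2000,
                                  seed = NULL) {
  if (!inherits(cohort_a, "cohort_table")) cohort_a <- cohort_table(cohort_a)
  if (!inherits(cohort_b, "cohort_table")) cohort_b <- cohort_table(cohort_b)
  if (B < 1) stop("B must be >= 1")
  ma <- individual_day_matrices(cohort_a)
  mb <- individual_day_matrices(cohort_b)
  # each cohort's resampling stream is keyed to a content fingerprint,
  # not to argument position, so swapping the cohorts exactly negates
  # every difference (p-values and |moments| are swap-invariant)
  fp <- function(m) paste(m$n, ncol(m$alive), sum(m$eggs), sum(m$alive),
                          sep = "|")
  flip <- fp(ma) > fp(mb)
  if (flip) { tmp <- ma; ma <- mb; mb <- tmp }
  seeds <- iteration_seeds(seed, B)
  d <- matrix(NA_real_, B, 4,
              dimnames = list(NULL, c("r", "lambda", "R0", "T")))
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    ia <- sample.int(ma$n, ma$n, replace = TRUE)
    ib <- sample.int(mb$n, mb$n, replace = TRUE)
    d[b, ] <- params_from_rows(ma, ia) - params_from_rows(mb, ib)
  }
  if (flip) d <- -d
  valid <- !is.na(d[, "r"])
  if (!any(valid)) stop("cohorts cannot support bootstrap: all ",
                        B, " paired resamples invalid")
  out <- lapply(colnames(d), function(p) {
    v <- d[valid, p]
    pv <- min(1, 2 * min(sum(v <= 0), sum(v >= 0)) / length(v))
    list(parameter = p, diff_mean = mean(v), diff_se = stats::sd(v),
         p_value = pv, B = B, n_valid = length(v))
  })
  names(out) <- colnames(d)
  structure(out, class = "paired_bootstrap_results")
}

#' @export
print.paired_bootstrap_results <- function(x, digits = 5, ...) {
  cat("Paired bootstrap test (B =", x[[1]]$B, ", valid =",
      x[[1]]$n_valid, ")\n")
  for (p in names(x))
    cat(sprintf("  %-6s diff %.*g  se %.*g  p = %.4g\n", p,
                digits, x[[p]]$diff_mean, digits, x[[p]]$diff_se,
                x[[p]]$p_value))
  invisible(x)
}
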