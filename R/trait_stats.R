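# One-way ANOVA + Tukey HSD + compact letter display: the presentation
# machinery behind developmental-trait tables (mean +/- SE with lowercase
# letters; groups sharing a letter are not significantly different).

# insert-and-absorb compact letter display. `groups` are ordered by
# descending mean; `sig` is a 2-column character matrix of significantly
# different pairs. Returns a letter string per group, "a" anchored on
# the largest mean.
cld_insert_absorb <- function(groups, sig) {
  cols <- list(groups)
  if (length(sig)) {
    for (k in seq_len(nrow(sig))) {
      g1 <- sig[k, 1]; g2 <- sig[k, 2]
      hit <- which(vapply(cols, function(s) g1 %in% s && g2 %in% s,
                          logical(1)))
      for (h in hit) {
        s <- cols[[h]]
        cols[[h]] <- setdiff(s, g1)
        cols[[length(cols) + 1L]] <- setdiff(s, g2)
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(cols))
      for (i in seq_along(cols)) for (j in seq_along(cols))
        if (i != j && keep[i] && keep[j] &&
            all(cols[[i]] %in% cols[[j]]) &&
            !(length(cols[[i]]) == length(cols[[j]]) && i > j))
          keep[i] <- FALSE
      cols <- cols[keep]
    }
  }
  # order columns by the rank of their highest-mean member
  first <- vapply(cols, function(s) min(match(s, groups)), numeric(1))
  cols <- cols[order(first)]
  lab <- letters[seq_along(cols)]
  out <- vapply(groups, function(g)
    paste(lab[vapply(cols, function(s) g %in% s, logical(1))],
          collapse = ""), character(1))
  out
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Classical one-way ANOVA across groups followed by all pairwise
#' Tukey-Kramer comparisons (unequal group sizes allowed) and an
#' insert-and-absorb compact letter display at level `alpha`. Letters
#' are assigned in descending-mean order ("a" on the largest mean);
#' groups sharing any letter are not significantly different.
#'
#' @param data Data frame with columns `group` and `value` (additional
#'   columns are ignored), or a named list of numeric vectors.
#' @param alpha Significance level for the Tukey comparisons.
#' @param trait Optional trait name carried into the result.
#' @return A list of class `"anova_tukey"`: `F`, `df_between`,
#'   `df_within`, `p`, `table` (group, n, mean, se, letters, in
#'   descending-mean order), `tukey` (pairwise differences and adjusted
#'   p-values), `alpha`. With zero within-group variance `F` is 0 (all
#'   means equal, every group lettered "a") or `Inf` (means differ,
#'   all letters distinct).
#' @examples
#' d <- data.frame(group = rep(c("CK", "d15"), each = 5),
#'                 value = c(20.1, 20.3, 19.8, 20.2, 20.0,
#'                           19.5, 19.6, 19.4, 19.7, 19.5))
#' anova_tukey(d, trait = "larval duration (d)")
#' @export
anova_tukey <- function(data, alpha = 0.05, trait = NULL) {
  if (is.list(data) && !is.data.frame(data))
    data <- data.frame(
      group = rep(names(data), lengths(data)),
      value = unlist(data, use.names = FALSE))
  stopifnot(all(c("group", "value") %in% names(data)))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  data <- data[!is.na(data$value), c("group", "value")]
  data$group <- as.character(data$group)
  ng <- table(data$group)
  if (length(ng) < 2L) stop("need at least two groups")
  if (any(ng < 2L))
    stop("group(s) with fewer than 2 observations: ",
         paste(names(ng)[ng < 2L], collapse = ", "))

  means <- tapply(data$value, data$group, mean)
  sds <- tapply(data$value, data$group, stats::sd)
  ord <- order(means, decreasing = TRUE)
  groups <- names(means)[ord]
  k <- length(groups)
  df1 <- k - 1L
  df2 <- nrow(data) - k
  ssw <- sum((ng - 1L) * sds^2)

  if (ssw == 0) {
    if (diff(range(means)) == 0) {
      Fv <- 0; p <- 1
      letters_out <- rep("a", k)
      tk <- NULL
    } else {
      Fv <- Inf; p <- 0
      letters_out <- letters[seq_len(k)]
      tk <- NULL
    }
  } else {
    data$group <- factor(data$group)
    fit <- stats::aov(value ~ group, data = data)
    an <- summary(fit)[[1]]
    Fv <- an[["F value"]][1]
    p <- an[["Pr(>F)"]][1]
    tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    pair_names <- strsplit(rownames(tuk), "-", fixed = TRUE)
    tk <- data.frame(
      group1 = vapply(pair_names, `[`, character(1), 1),
      group2 = vapply(pair_names, `[`, character(1), 2),
      diff = tuk[, "diff"], p_adj = tuk[, "p adj"], row.names = NULL)
    sig <- as.matrix(tk[tk$p_adj < alpha, c("group1", "group2")])
    letters_out <- cld_insert_absorb(groups, sig)
  }
  tab <- data.frame(group = groups,
                    n = as.integer(ng[groups]),
                    mean = as.numeric(means[groups]),
                    se = as.numeric(sds[groups] / sqrt(ng[groups])),
                    letters = letters_out, row.names = NULL)
  structure(list(trait = trait, F = Fv, df_between = df1, df_within = df2,
                 p = p, table = tab, tukey = tk, alpha = alpha),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, digits = 4, ...) {
  if (!is.null(x$trait)) cat("Trait:", x$trait, "\n")
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.*g, p = %.4g (Tukey HSD at %g)\n",
              x$df_between, x$df_within, digits, x$F, x$p, x$alpha))
  tab <- x$table
  tab$mean_se <- sprintf("%.*g +/- %.*g %s", digits, tab$mean,
                         digits, tab$se, tab$letters)
  print.data.frame(tab[, c("group", "n", "mean_se")], row.names = FALSE)
  invisible(x)
}

#' Trait table for several traits at once
#'
#' Applies [anova_tukey()] per trait of a tidy data frame, mirroring the
#' mean +/- SE + letters layout of developmental-duration tables.
#'
#' @param data Data frame with columns `trait`, `group`, `value`.
#' @param alpha Significance level.
#' @return Data frame with one row per trait x group: `trait`, `group`,
#'   `n`, `mean`, `se`, `letters`, plus `F`, `df_between`, `df_within`,
#'   `p` repeated within trait.
#' @export
trait_table <- function(data, alpha = 0.05) {
  stopifnot(all(c("trait", "group", "value") %in% names(data)))
  out <- lapply(split(data, data$trait), function(d) {
    a <- anova_tukey(d, alpha = alpha, trait = d$trait[1])
    cbind(trait = d$trait[1], a$table,
          F = a$F, df_between = a$df_between,
          df_within = a$df_within, p = a$p)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
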