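#' Assemble and validate a cohort of individual life histories
#'
#' A cohort table is the raw input of the two-sex life table: one row per
#' individual per day alive, from age 0 (the day the individual entered
#' the life table) until its last day alive. Both sexes and individuals
#' dying before sex determination (sex `"U"`) are retained -- no
#' female-only survivorship correction is applied; that is the defining
#' property of the age-stage two-sex method.
#'
#' @param data Data frame with columns `individual_id`, `sex` (one of
#'   `"F"`, `"M"`, `"U"`), `age_day` (integer, starting at 0 with no
#'   gaps), `stage` (a label from `stage_order`) and `eggs` (non-negative
#'   integer daily egg count; only adult females may have `eggs > 0`).
#' @param stage_order A [stage_order()] object (or character vector of
#'   stage labels passed to it).
#' @param .lines Optional integer vector of source line numbers (used by
#'   [read_cohort_csv()] for line-addressed diagnostics).
#' @return A validated data frame of class `"cohort_table"` with
#'   attributes `stage_order` and `n01` (the number of newborns that
#'   entered the table at age 0, stage 1).
#' @seealso [read_cohort_csv()], [simulate_cohort()], [life_table()]
#' @export
cohort_table <- function(data, stage_order = twosexlt::stage_order(),
                         .lines = NULL) {
  so <- as_stage_order(stage_order)
  req <- c("individual_id", "sex", "age_day", "stage", "eggs")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)[req]
  if (nrow(data) == 0L) stop("empty cohort")

  data$individual_id <- as.character(data$individual_id)
  data$sex <- as.character(data$sex)
  data$stage <- as.character(data$stage)
  data$age_day <- as.integer(data$age_day)
  data$eggs <- as.integer(data$eggs)
  lines <- if (is.null(.lines)) rep(NA_integer_, nrow(data)) else .lines

  at <- function(i) {
    if (is.na(lines[i])) sprintf("row %d", i) else sprintf("line %d", lines[i])
  }
  bad_sex <- which(!data$sex %in% c("F", "M", "U"))
  if (length(bad_sex))
    stop(sprintf("invalid sex '%s' for individual '%s' (%s)",
                 data$sex[bad_sex[1]], data$individual_id[bad_sex[1]],
                 at(bad_sex[1])))
  bad_stage <- which(!data$stage %in% unclass(so))
  if (length(bad_stage))
    stop(sprintf("unknown stage label '%s' for individual '%s' (%s)",
                 data$stage[bad_stage[1]], data$individual_id[bad_stage[1]],
                 at(bad_stage[1])))
  if (anyNA(data$age_day) || any(data$age_day < 0L))
    stop("age_day must be a non-negative integer")
  if (anyNA(data$eggs) || any(data$eggs < 0L))
    stop("eggs must be a non-negative integer")

  # per-individual invariants, in input order of first appearance
  ids <- unique(data$individual_id)
  ord <- order(match(data$individual_id, ids), data$age_day)
  data <- data[ord, ]
  lines <- lines[ord]
  rownames(data) <- NULL
  idx <- split(seq_len(nrow(data)), factor(data$individual_id, levels = ids))
  stage_rank <- match(data$stage, unclass(so))
  female <- attr(so, "female")
  sexed_from <- attr(so, "sexed_from")
  sexed_rank <- if (is.null(sexed_from)) NA_integer_ else
    match(sexed_from, unclass(so))

  for (id in ids) {
    i <- idx[[id]]
    age <- data$age_day[i]
    if (anyDuplicated(age))
      stop(sprintf("duplicated age_day %d for individual '%s' (%s)",
                   age[anyDuplicated(age)], id, at(i[anyDuplicated(age)])))
    if (age[1] != 0L)
      stop(sprintf("individual '%s' does not start at age 0 (%s)",
                   id, at(i[1])))
    gap <- which(diff(age) != 1L)
    if (length(gap))
      stop(sprintf(
        "gap in age_day sequence for individual '%s': %d followed by %d (%s)",
        id, age[gap[1]], age[gap[1] + 1L], at(i[gap[1] + 1L])))
    if (data$stage[i[1]] != unclass(so)[1])
      stop(sprintf("individual '%s' does not enter at stage '%s' (%s)",
                   id, unclass(so)[1], at(i[1])))
    reg <- which(diff(stage_rank[i]) < 0L)
    if (length(reg))
      stop(sprintf(
        "stage regression for individual '%s': '%s' after '%s' (%s)",
        id, data$stage[i[reg[1] + 1L]], data$stage[i[reg[1]]],
        at(i[reg[1] + 1L])))
    sx <- unique(data$sex[i])
    if (length(sx) > 1L)
      stop(sprintf("inconsistent sex for individual '%s'", id))
    laid <- which(data$eggs[i] > 0L)
    if (length(laid)) {
      if (sx != "F")
        stop(sprintf("eggs recorded for non-female individual '%s' (%s)",
                     id, at(i[laid[1]])))
      off <- which(data$eggs[i] > 0L & data$stage[i] != female)
      if (length(off))
        stop(sprintf(
          "eggs recorded outside the adult-female stage for '%s' (%s)",
          id, at(i[off[1]])))
    }
    if (sx == "U" && !is.na(sexed_rank) && any(stage_rank[i] >= sexed_rank))
      stop(sprintf(
        "individual '%s' has sex 'U' but reached stage '%s' (%s)",
        id, sexed_from, at(i[which(stage_rank[i] >= sexed_rank)[1]])))
    if (sx != "F" && data$stage[i[length(i)]] == female)
      stop(sprintf("non-female individual '%s' in adult-female stage", id))
    if (sx == "F" && any(data$stage[i] == attr(so, "male")))
      stop(sprintf("female individual '%s' in adult-male stage", id))
  }

  structure(data, stage_order = so, n01 = length(ids),
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  so <- attr(x, "stage_order")
  cat("Cohort table: ", attr(x, "n01"), " individuals, ",
      nrow(x), " individual-days, max age ", max(x$age_day), "\n", sep = "")
  sx <- table(x$sex[!duplicated(x$individual_id)])
  cat("  sex: ", paste(names(sx), as.integer(sx), sep = "=", collapse = ", "),
      "; total eggs: ", sum(x$eggs), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

cohort_ids <- function(cohort) unique(cohort$individual_id)

#' Subset a cohort by individual, with replacement allowed
#'
#' Builds a new cohort containing the life histories of the selected
#' individuals. Selecting the same individual several times duplicates its
#' whole history under fresh ids; this is the resampling primitive of the
#' life table bootstrap (the resampling unit is the individual, never the
#' individual-day).
#'
#' @param cohort A [cohort_table()].
#' @param ids Character vector of individual ids, possibly repeated.
#' @return A `cohort_table` with `length(ids)` individuals.
#' @export
resample_cohort <- function(cohort, ids) {
  rows <- split(seq_len(nrow(cohort)),
                factor(cohort$individual_id, levels = cohort_ids(cohort)))
  take <- rows[ids]
  out <- cohort[unlist(take, use.names = FALSE), ]
  out$individual_id <- rep(sprintf("b%06d", seq_along(ids)),
                           lengths(take))
  rownames(out) <- NULL
  # resampled rows satisfy the invariants by construction
  structure(out, stage_order = attr(cohort, "stage_order"),
            n01 = length(ids), class = c("cohort_table", "data.frame"))
}
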