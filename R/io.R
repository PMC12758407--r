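#' Read a cohort from a long-format CSV file
#'
#' Expected layout (UTF-8, comma-separated, header required): one row
#' per individual-day with columns `individual_id`, `sex` (`F`/`M`/`U`),
#' `age_day`, `stage`, `eggs` (optional; defaults to 0). All
#' [cohort_table()] invariants are enforced on load and violations are
#' reported with the offending file line.
#'
#' @param path Path to the CSV file.
#' @param stage_order A [stage_order()].
#' @return A `cohort_table`.
#' @export
read_cohort_csv <- function(path, stage_order = twosexlt::stage_order()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("empty cohort: ", path)
  req <- c("individual_id", "sex", "age_day", "stage")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  if (is.null(d$eggs)) d$eggs <- 0L
  cohort_table(d, stage_order, .lines = seq_len(nrow(d)) + 1L)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort_csv()]: a written cohort reads back
#' identically.
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[
    c("individual_id", "sex", "age_day", "stage", "eggs")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a life table analysis to disk
#'
#' Writes a flat key-value parameter report (`parameters.txt`) plus CSV
#' matrices for `sxj`, the age schedules (`lx`, `mx`, `lxmx`), `exj` and
#' `vxj` into a directory.
#'
#' @param lt A [life_table()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_life_table <- function(lt, dir) {
  stopifnot(inherits(lt, "two_sex_life_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- lt$parameters
  kv <- c(sprintf("n01 %d", lt$n01),
          sprintf("max_age %d", lt$matrix$max_age),
          sprintf("r %.10g", p$r), sprintf("lambda %.10g", p$lambda),
          sprintf("R0 %.10g", p$R0), sprintf("T %.10g", p$T))
  writeLines(kv, file.path(dir, "parameters.txt"))
  wm <- function(m, f) {
    d <- as.data.frame(m)
    d <- cbind(age = 0:lt$matrix$max_age, d)
    utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  }
  wm(lt$matrix$sxj, "sxj.csv")
  utils::write.csv(lt$schedules, file.path(dir, "schedules.csv"),
                   row.names = FALSE)
  wm(lt$exj, "exj.csv")
  if (!is.null(lt$vxj)) wm(lt$vxj, "vxj.csv")
  invisible(dir)
}
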