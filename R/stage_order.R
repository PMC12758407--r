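#' Define the ordered developmental stages of a cohort
#'
#' An age-stage, two-sex life table tracks individuals jointly by age (in
#' days) and developmental stage. Stages are strictly ordered and the final
#' two are the sexed adult stages. The default order describes a noctuid
#' moth reared from first instar: six larval instars, pupa, then adult
#' female and adult male (beta = 9 stages).
#'
#' @param stages Character vector of unique stage labels in developmental
#'   order. The adult stages must be the last two entries.
#' @param female,male Labels of the adult-female and adult-male stages.
#' @param sexed_from Label of the stage at which sex becomes observable
#'   (pupation in most rearing protocols), or `NULL` to skip the related
#'   validation. Individuals dying before this stage carry sex `"U"`.
#' @return An object of class `"stage_order"`: the stage labels with
#'   attributes `female`, `male`, `sexed_from` and `beta` (number of
#'   stages).
#' @examples
#' stage_order()                      # L1..L6, pupa, adult_female, adult_male
#' stage_order(c("egg", "L1", "adult_female", "adult_male"),
#'             sexed_from = "adult_female")
#' @export
stage_order <- function(stages = c(paste0("L", 1:6), "pupa",
                                   "adult_female", "adult_male"),
                        female = "adult_female",
                        male = "adult_male",
                        sexed_from = if ("pupa" %in% stages) "pupa" else NULL) {
  stages <- as.character(stages)
  if (length(stages) < 2L)
    stop("a stage order needs at least two stages (beta >= 2)")
  if (anyDuplicated(stages))
    stop("stage labels must be unique")
  if (!female %in% stages || !male %in% stages)
    stop("adult female/male labels must be among the stages")
  n <- length(stages)
  if (!setequal(stages[c(n - 1L, n)], c(female, male)))
    stop("the sexed adult stages must be the final two stages")
  if (!is.null(sexed_from) && !sexed_from %in% stages)
    stop("'sexed_from' must be one of the stages")
  structure(stages,
            female = female, male = male,
            sexed_from = sexed_from, beta = n,
            class = "stage_order")
}

#' @export
print.stage_order <- function(x, ...) {
  cat("Stage order (beta = ", attr(x, "beta"), "): ",
      paste(unclass(x), collapse = " -> "), "\n", sep = "")
  cat("  adult female: ", attr(x, "female"),
      "   adult male: ", attr(x, "male"), "\n", sep = "")
  invisible(x)
}

as_stage_order <- function(x) {
  if (inherits(x, "stage_order")) return(x)
  stage_order(x)
}
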