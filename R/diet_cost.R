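# Artificial-diet formulation costs for S. litura mass rearing.
#
# Ingredient unit prices are not available, so the per-formulation cost
# (yuan per batch) is bundled data, not recomputed from prices. Every
# formulation shares the fixed additive set: vitamin C 4 g, niptibet
# 2 g, sorbic acid 2 g, cholesterol 0.8 g.

DIET_FIXTURE_MD5 <- "fb3c1a59a702287db5b82de6c9972839"

DIET_ADDITIVES <- c(vitamin_C_g = 4, niptibet_g = 2,
                    sorbic_acid_g = 2, cholesterol_g = 0.8)

#' Load the bundled artificial-diet formulation table
#'
#' Eighteen experimental formulations (named `"1"` to `"17"`) plus the
#' control diet `"CK"`. Each varies the maize/soybean split and the
#' yeast/wheat-bran split (each pair summing to 100 g) and carries its
#' batch cost in yuan and its cost tier (`high`, `medium`, `low`).
#'
#' @return A data frame of class `"diet_formulations"` with columns
#'   `name`, `tier`, `maize_g`, `soybean_g`, `yeast_g`, `wheat_bran_g`,
#'   `cost`, and the fixed additive masses as attribute `additives`.
#' @examples
#' d <- load_formulations()
#' d[d$name == "15", ]
#' @export
load_formulations <- function() {
  path <- system.file("extdata", "diet_formulations.csv",
                      package = "twosexlt", mustWork = TRUE)
  if (unname(tools::md5sum(path)) != DIET_FIXTURE_MD5)
    stop("diet formulation fixture corrupted (checksum mismatch)")
  d <- utils::read.csv(path, colClasses = c(name = "character"))
  stopifnot(all(d$maize_g + d$soybean_g == 100),
            all(d$yeast_g + d$wheat_bran_g == 100),
            all(d$cost > 0))
  structure(d, additives = DIET_ADDITIVES,
            class = c("diet_formulations", "data.frame"))
}

get_formulation <- function(x, table = NULL) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single formulation row")
    return(x)
  }
  if (is.null(table)) table <- load_formulations()
  row <- table[table$name == as.character(x), ]
  if (nrow(row) != 1L) stop("unknown formulation '", x, "'")
  row
}

#' Compare the cost of two diet formulations
#'
#' Computes the absolute saving (yuan) and the relative reduction (%)
#' of a candidate formulation against a reference:
#' `relative_reduction_pct = 100 * (ref - cand) / ref`. Savings are
#' rounded to two decimals (yuan) and the percentage to `round_to`
#' decimals, the precision at which such comparisons are reported.
#'
#' @param reference,candidate Formulation names (looked up in the
#'   bundled table) or single rows of [load_formulations()].
#' @param round_to Decimal places for the percentage.
#' @return A list of class `"cost_comparison"`: `reference`,
#'   `candidate`, `absolute_diff` (yuan; positive when the candidate is
#'   cheaper), `relative_reduction_pct`.
#' @examples
#' compare_costs("CK", "15")   # the control against the maize-only diet
#' @export
compare_costs <- function(reference, candidate, round_to = 1) {
  tab <- load_formulations()
  ref <- get_formulation(reference, tab)
  cand <- get_formulation(candidate, tab)
  if (ref$cost == 0) stop("reference cost is zero")
  diff <- ref$cost - cand$cost
  structure(list(reference = ref$name, candidate = cand$name,
                 reference_cost = ref$cost, candidate_cost = cand$cost,
                 absolute_diff = round(diff, 2),
                 relative_reduction_pct = round(100 * diff / ref$cost,
                                                round_to)),
            class = "cost_comparison")
}

#' @export
print.cost_comparison <- function(x, ...) {
  cat(sprintf(
    "Diet cost: %s (%.2f yuan) vs %s (%.2f yuan): saves %.2f yuan (%.1f%%)\n",
    x$reference, x$reference_cost, x$candidate, x$candidate_cost,
    x$absolute_diff, x$relative_reduction_pct))
  invisible(x)
}

#' Rank formulations by cost
#'
#' @param formulations A [load_formulations()] data frame (default: the
#'   bundled table).
#' @return The same rows stably sorted by ascending cost, keeping the
#'   `tier` labels.
#' @export
rank_by_cost <- function(formulations = load_formulations()) {
  if (nrow(formulations) == 0L) stop("no formulations to rank")
  out <- formulations[order(formulations$cost), ]
  rownames(out) <- NULL
  out
}
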