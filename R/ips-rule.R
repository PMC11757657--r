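#' Case-level infiltration pattern score from three slide scores
#'
#' Each case is characterised by three tumor-containing slides, individually
#' scored from 1 to 5 by the infiltration pattern observed at the
#' tumor-parenchyma interface. The case label is assigned by the total of the
#' three scores: total 3-6 is non/minimally infiltrative (IPS1), 7-9 is
#' moderately infiltrative (IPS2), and 10-15 is highly infiltrative (IPS3).
#' The three bands partition all attainable totals, so the rule is total over
#' its domain.
#'
#' @param scores Integer vector of exactly three slide scores, each in 1..5.
#' @return A length-1 factor with levels `IPS1`, `IPS2`, `IPS3`.
#' @examples
#' case_ips_from_slide_scores(c(1, 1, 1)) # IPS1
#' case_ips_from_slide_scores(c(3, 3, 3)) # IPS2
#' case_ips_from_slide_scores(c(5, 5, 5)) # IPS3
#' @export
case_ips_from_slide_scores <- function(scores) {
  if (length(scores) != 3L) {
    abort("`scores` must contain exactly three slide scores")
  }
  if (!is.numeric(scores) || anyNA(scores) || any(scores != as.integer(scores))) {
    abort("slide scores must be integers")
  }
  if (any(scores < 1 | scores > 5)) {
    abort("slide scores must be in 1..5")
  }
  total <- sum(scores)
  label <- if (total <= 6) "IPS1" else if (total <= 9) "IPS2" else "IPS3"
  ips_factor(label)
}

#' Summarise the class composition of a case manifest
#'
#' @param cases A data frame with an `ips_label` column (one row per case).
#' @return A tibble with one row per IPS class: `ips_label`, count `n`, and
#'   `percent` of cases (rounded to one decimal, the convention used for
#'   cohort tables).
#' @export
summarize_cohort <- function(cases) {
  stopifnot(is.data.frame(cases), "ips_label" %in% names(cases))
  lab <- ips_factor(cases$ips_label)
  n <- as.integer(table(lab))
  tibble(
    ips_label = ips_levels(),
    n = n,
    percent = round(100 * n / sum(n), 1)
  )
}
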