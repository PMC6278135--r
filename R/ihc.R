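#' Categorize H3K27me3 immunohistochemistry
#'
#' A tumor shows *intact* H3K27me3 expression when strictly more than
#' `cutoff` percent of tumor cells are labeled (default 80%), and *reduced*
#' expression when 0 to `cutoff` percent are labeled (the boundary belongs
#' to reduced). Staining is evaluable only if endothelial cells in the
#' tissue retained reactivity; records with a failed endothelial control are
#' `not_evaluable` regardless of the percentage. Staining intensity plays no
#' role.
#'
#' @param records Tibble with `sample_id`, `percent_labeled` in \[0, 100\]
#'   and optionally `control_ok` (logical; assumed `TRUE` when absent).
#' @param cutoff Percent-labeled cutoff (default 80).
#' @return The records with a `category` column
#'   (`intact` / `reduced` / `not_evaluable`).
#' @export
ihc_categorize <- function(records, cutoff = 80) {
  records <- tibble::as_tibble(records)
  if (!"control_ok" %in% names(records)) records$control_ok <- TRUE
  p <- records$percent_labeled
  if (any(is.na(p)) || any(p < 0 | p > 100)) {
    abort("percent_labeled must lie in [0, 100]")
  }
  records$category <- dplyr::case_when(
    !records$control_ok ~ "not_evaluable",
    p > cutoff ~ "intact",
    TRUE ~ "reduced"
  )
  records
}

#' Predict PFA/PFB from H3K27me3 staining
#'
#' Intact H3K27me3 expression predicts PFB and reduced expression predicts
#' PFA (loss of H3K27me3 marks PFA); non-evaluable stainings are propagated.
#'
#' @param records Tibble from [ihc_categorize()], or raw records (then
#'   categorized first with `cutoff`).
#' @inheritParams ihc_categorize
#' @return The records with a `prediction` column
#'   (`PFA` / `PFB` / `not_evaluable`).
#' @export
ihc_predict_subgroup <- function(records, cutoff = 80) {
  records <- tibble::as_tibble(records)
  if (!"category" %in% names(records)) {
    records <- ihc_categorize(records, cutoff)
  }
  records$prediction <- dplyr::case_when(
    records$category == "intact" ~ "PFB",
    records$category == "reduced" ~ "PFA",
    TRUE ~ "not_evaluable"
  )
  records
}
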