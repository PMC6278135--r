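# broom-style tidiers for the fitted objects.

#' Tidy a beta fit
#'
#' @param x A `beta_fit`.
#' @param ... Unused.
#' @return One-row tibble with the gene, class, shapes, fitted mean (as a
#'   percentage) and sample size.
#' @exportS3Method generics::tidy
#' @export
tidy.beta_fit <- function(x, ...) {
  tibble::tibble(gene = x$gene, class = x$class, alpha = x$alpha,
                 beta = x$beta, mean_percent = 100 * beta_fit_mean(x),
                 n = x$n_observations, loglik = x$loglik)
}

#' @rdname tidy.beta_fit
#' @exportS3Method generics::tidy
#' @export
tidy.beta_fits <- function(x, ...) {
  purrr::map_dfr(x$fit, tidy)
}

#' Tidy a threshold rule
#'
#' @param x A `threshold_rule`.
#' @param ... Unused.
#' @return Tibble with one row per gene (`gene`, `threshold`, `mode`).
#' @exportS3Method generics::tidy
#' @export
tidy.threshold_rule <- function(x, ...) {
  tibble::tibble(gene = names(x$thresholds),
                 threshold = unname(x$thresholds), mode = x$mode)
}

#' Tidy a confusion matrix
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Tibble in long form (`truth`, `prediction`, `n`).
#' @exportS3Method generics::tidy
#' @export
tidy.confusion_matrix <- function(x, ...) {
  neg <- setdiff(c("PFA", "PFB"), x$positive)
  tibble::tibble(
    truth = c(x$positive, x$positive, neg, neg),
    prediction = c(x$positive, neg, x$positive, neg),
    n = c(x$tp, x$fn, x$fp, x$tn)
  )
}

#' @rdname tidy.confusion_matrix
#' @exportS3Method generics::glance
#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 positive = x$positive)
}

#' Tidy / summarize a trained classifier
#'
#' `tidy()` returns the selected per-gene thresholds; `glance()` one row
#' with the selected mode and sensitivity/specificity on both partitions.
#'
#' @param x A `pfb_classifier` from [train_pfb_classifier()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.pfb_classifier <- function(x, ...) {
  tidy(x$rule)
}

#' @rdname tidy.pfb_classifier
#' @exportS3Method generics::glance
#' @export
glance.pfb_classifier <- function(x, ...) {
  tibble::tibble(
    mode = x$rule$mode,
    n_train = nrow(x$split$train),
    n_validation = nrow(x$split$validation),
    sens_train = x$confusion$train$sensitivity,
    spec_train = x$confusion$train$specificity,
    sens_validation = x$confusion$validation$sensitivity,
    spec_validation = x$confusion$validation$specificity
  )
}
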