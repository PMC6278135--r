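#' Remove sex-chromosome probes
#'
#' Drops every probe mapped to chrX or chrY, the standard first filter for
#' methylation-based tumor classification (on the full 450K annotation of
#' 485,512 probes this removes the 11,551 sex-chromosome probes and keeps
#' 473,961).
#'
#' @param annotation Tibble with at least `probe_id` and `chrom`
#'   (`"chr1"`..`"chr22"`, `"chrX"`, `"chrY"`).
#' @return The autosomal rows of `annotation`, order preserved, as a
#'   `marker_set` tibble whose `criterion` attribute records the rule.
#' @export
filter_autosomal <- function(annotation) {
  if (nrow(annotation) == 0) abort("annotation is empty")
  assert_chromosomes(annotation$chrom)
  keep <- !(annotation$chrom %in% c("chrX", "chrY"))
  new_marker_set(annotation[keep, , drop = FALSE],
                 criterion = "autosomal probes (chrom not in {chrX, chrY})")
}

#' Select high-variance CpG-island probes
#'
#' The clustering probe set: CpG-island probes whose across-sample standard
#' deviation of beta values exceeds `sd_threshold` (strictly; default 0.25,
#' the SD > 0.25 criterion used for two-group classification). SD uses the
#' unbiased n-1 estimator over non-missing values; probes with fewer than
#' two observations are dropped with a message. The SD is computed over
#' exactly the samples present in `beta` -- subset the matrix first if a
#' different cohort should drive the selection.
#'
#' @param beta Wide beta-value tibble (`probe_id` + one column per sample).
#' @param annotation Probe annotation with `probe_id` and `cpg_island`.
#' @param sd_threshold Non-negative SD cutoff (strict `>`).
#' @return `marker_set` tibble with `probe_id` and the computed `sd`.
#' @export
select_high_sd_island_probes <- function(beta, annotation,
                                         sd_threshold = 0.25) {
  if (sd_threshold < 0) abort("sd_threshold must be >= 0")
  m <- wide_to_matrix(beta)
  if (ncol(m) < 2) abort("at least 2 samples are required to compute an SD")
  island <- annotation$probe_id[annotation$cpg_island]
  m <- m[rownames(m) %in% island, , drop = FALSE]
  nobs <- rowSums(!is.na(m))
  dropped <- sum(nobs < 2)
  if (dropped > 0) {
    inform(paste0(dropped, " probe(s) with <2 non-missing values dropped"))
  }
  ok <- nobs >= 2
  m <- m[ok, , drop = FALSE]
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  sds <- sqrt(ss / (nobs[ok] - 1))
  sel <- sds > sd_threshold
  new_marker_set(
    tibble::tibble(probe_id = rownames(m)[sel], sd = unname(sds[sel])),
    criterion = sprintf("CpG-island probes with across-sample SD > %g (n-1 denominator)",
                        sd_threshold)
  )
}

#' Select subgroup-separated marker probes
#'
#' Probes hypermethylated in PFA (mean beta >= `hyper_mean_min`, default
#' 0.5) and hypomethylated in PFB (mean beta <= `hypo_mean_max`, default
#' 0.2); both boundaries inclusive. Means ignore missing values.
#'
#' @inheritParams select_high_sd_island_probes
#' @param labels Tibble with `sample_id` and `subgroup` (`"PFA"`/`"PFB"`),
#'   or a named character vector of subgroups.
#' @param hyper_mean_min,hypo_mean_max Mean-beta bounds.
#' @return `marker_set` tibble with `probe_id`, `mean_pfa`, `mean_pfb`.
#' @export
select_subgroup_markers <- function(beta, labels, hyper_mean_min = 0.5,
                                    hypo_mean_max = 0.2) {
  if (is.data.frame(labels)) {
    labels <- setNames(labels$subgroup, labels$sample_id)
  }
  m <- wide_to_matrix(beta)
  labels <- labels[colnames(m)]
  for (cls in c("PFA", "PFB")) {
    if (!any(labels == cls, na.rm = TRUE)) {
      abort(paste0("class absent from labels: ", cls))
    }
  }
  mean_pfa <- rowMeans(m[, which(labels == "PFA"), drop = FALSE], na.rm = TRUE)
  mean_pfb <- rowMeans(m[, which(labels == "PFB"), drop = FALSE], na.rm = TRUE)
  sel <- !is.na(mean_pfa) & !is.na(mean_pfb) &
    mean_pfa >= hyper_mean_min & mean_pfb <= hypo_mean_max
  new_marker_set(
    tibble::tibble(probe_id = rownames(m)[sel],
                   mean_pfa = unname(mean_pfa[sel]),
                   mean_pfb = unname(mean_pfb[sel])),
    criterion = sprintf("mean beta (PFA) >= %g and mean beta (PFB) <= %g",
                        hyper_mean_min, hypo_mean_max)
  )
}
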