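#' Control-based probe QC for copy-number estimation
#'
#' Copy-number profiles from methylation-array intensities need stable
#' probes. Per probe, the total signal (methylated + unmethylated) is
#' computed in each normal-reference control; probes whose across-control
#' median total falls outside the inclusive `[lower_q, upper_q]` quantile
#' band over probes, or whose across-control median absolute deviation
#' exceeds the `mad_q` quantile over probes, are excluded. Quantiles use
#' linear interpolation (default type 7); the MAD is unscaled (constant 1),
#' which cannot change the set excluded by a quantile cut.
#'
#' @param meth,unmeth Wide intensity tibbles (`probe_id` + one column per
#'   control sample) with identical probe and sample sets.
#' @param lower_q,upper_q,mad_q Quantile bounds (defaults 0.05, 0.95, 0.8).
#' @return `marker_set` tibble of retained probes with `median_total` and
#'   `mad_total`.
#' @export
probe_qc <- function(meth, unmeth, lower_q = 0.05, upper_q = 0.95,
                     mad_q = 0.8) {
  mm <- wide_to_matrix(meth)
  um <- wide_to_matrix(unmeth)
  check_intensity_pair(mm, um)
  if (ncol(mm) < 2) abort("probe QC requires at least 2 control samples")
  total <- mm + um
  med <- apply(total, 1, median)
  madv <- apply(total, 1, function(x) median(abs(x - median(x))))
  band <- quantile(med, c(lower_q, upper_q), names = FALSE)
  mad_cut <- quantile(madv, mad_q, names = FALSE)
  keep <- med >= band[1] & med <= band[2] & madv <= mad_cut
  new_marker_set(
    tibble::tibble(probe_id = rownames(total)[keep],
                   median_total = unname(med[keep]),
                   mad_total = unname(madv[keep])),
    criterion = sprintf(
      "control median total within [Q%g, Q%g]; control MAD <= Q%g",
      lower_q, upper_q, mad_q)
  )
}

check_intensity_pair <- function(mm, um) {
  if (!identical(dim(mm), dim(um)) ||
      !identical(rownames(mm), rownames(um)) ||
      !identical(colnames(mm), colnames(um))) {
    abort("methylated and unmethylated matrices must share probes and samples")
  }
  if (any(mm < 0, na.rm = TRUE) || any(um < 0, na.rm = TRUE)) {
    abort("intensities must be non-negative")
  }
  invisible(TRUE)
}

#' Per-probe log2 copy-number profile of one sample
#'
#' For each QC-passing probe the sample's total signal is compared to the
#' median total signal of the controls, `log2((sample + offset) /
#' (control median + offset))`, and the whole profile is then centered by
#' subtracting its median, so the profile median is 0 and any global
#' scaling of the sample's intensities cancels.
#'
#' @inheritParams probe_qc
#' @param sample_id Column of `meth`/`unmeth` to profile.
#' @param control_ids Columns used as normal references.
#' @param qc `marker_set` from [probe_qc()] (or character probe ids).
#' @param annotation Probe annotation (`probe_id`, `chrom`, `pos`, `arm`)
#'   joined onto the profile for arm-level work.
#' @param offset Added to numerator and denominator before the ratio to
#'   avoid log of zero (default 1 intensity unit).
#' @return Tibble of class `cn_profile` with `probe_id`, `chrom`, `pos`,
#'   `arm`, `log2_ratio`, ordered by position, and a `sample_id` attribute.
#' @export
log2_profile <- function(meth, unmeth, sample_id, control_ids, qc,
                         annotation, offset = 1) {
  mm <- wide_to_matrix(meth)
  um <- wide_to_matrix(unmeth)
  check_intensity_pair(mm, um)
  cols <- colnames(mm)
  if (!sample_id %in% cols) abort(paste0("sample not found: ", sample_id))
  missing_ctrl <- setdiff(control_ids, cols)
  if (length(missing_ctrl) > 0) {
    abort(paste0("control sample(s) not found: ",
                 paste(missing_ctrl, collapse = ", ")))
  }
  ids <- intersect(marker_ids(qc), rownames(mm))
  if (length(ids) == 0) abort("QC probe set is empty")
  total <- mm + um
  sample_total <- total[ids, sample_id]
  ctrl_median <- apply(total[ids, control_ids, drop = FALSE], 1, median)
  denom <- ctrl_median + offset
  if (any(denom <= 0)) {
    abort(paste0("non-positive control median (after offset) at probe(s): ",
                 paste(head(ids[denom <= 0], 5), collapse = ", ")))
  }
  lr <- log2((sample_total + offset) / denom)
  lr <- lr - median(lr)
  out <- tibble::tibble(probe_id = ids, log2_ratio = unname(lr)) |>
    dplyr::inner_join(
      dplyr::select(annotation, "probe_id", "chrom", "pos", "arm"),
      by = "probe_id"
    ) |>
    dplyr::select("probe_id", "chrom", "pos", "arm", "log2_ratio") |>
    dplyr::arrange(match(.data$chrom, valid_chromosomes()), .data$pos)
  attr(out, "sample_id") <- sample_id
  attr(out, "offset") <- offset
  class(out) <- c("cn_profile", class(out))
  out
}

#' Arm-level copy-number calls
#'
#' Summarizes a centered log2 profile per chromosome arm: the arm is called
#' `"gain"` if its median log2 ratio is at least `gain_threshold`, `"loss"`
#' if at most `loss_threshold`, `"neutral"` otherwise, and
#' `"insufficient_probes"` when fewer than `min_probes` probes map to the
#' arm (the probe count is always reported).
#'
#' @param profile A `cn_profile` from [log2_profile()].
#' @param arms Optional character vector restricting which arms are called
#'   (e.g. `"1q"`); default all arms in the profile.
#' @param gain_threshold,loss_threshold Median log2-ratio cutoffs
#'   (defaults +0.15 / -0.15).
#' @param min_probes Minimum probes per arm for a call (default 20).
#' @return Tibble with `arm`, `n_probes`, `median_log2`, `call`.
#' @export
call_arms <- function(profile, arms = NULL, gain_threshold = 0.15,
                      loss_threshold = -0.15, min_probes = 20) {
  tbl <- profile
  if (!is.null(arms)) {
    missing_arm <- setdiff(arms, unique(tbl$arm))
    if (length(missing_arm) > 0) {
      abort(paste0("arm(s) absent from profile: ",
                   paste(missing_arm, collapse = ", ")))
    }
    tbl <- dplyr::filter(tbl, .data$arm %in% arms)
  }
  tbl |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(n_probes = dplyr::n(),
                     median_log2 = median(.data$log2_ratio),
                     .groups = "drop") |>
    dplyr::mutate(call = dplyr::case_when(
      .data$n_probes < min_probes ~ "insufficient_probes",
      .data$median_log2 >= gain_threshold ~ "gain",
      .data$median_log2 <= loss_threshold ~ "loss",
      TRUE ~ "neutral"
    ))
}

#' Chromosome-instability flag from copy-number oscillation
#'
#' A proxy for chromothripsis-like instability: along one chromosome
#' (position order) the log2 ratios are median-smoothed with a 5-probe
#' window, discretized to loss/neutral/gain at `-amp_threshold` /
#' `+amp_threshold`, and the number of state transitions is counted. The
#' chromosome is flagged unstable when the transition count reaches
#' `min_transitions`.
#'
#' @inheritParams call_arms
#' @param chroms Chromosomes to test (default all in the profile).
#' @param amp_threshold Absolute log2 ratio above which a smoothed probe
#'   counts as gained/lost (default 0.3).
#' @param min_transitions Transitions needed to flag (default 10).
#' @param window Running-median window, an odd probe count (default 5).
#' @return Tibble with `chrom`, `n_probes`, `transitions`, `unstable`.
#' @export
instability_flag <- function(profile, chroms = NULL, amp_threshold = 0.3,
                             min_transitions = 10, window = 5) {
  if (is.null(chroms)) chroms <- unique(profile$chrom)
  missing_chrom <- setdiff(chroms, unique(profile$chrom))
  if (length(missing_chrom) > 0) {
    abort(paste0("chromosome(s) absent from profile: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  purrr::map_dfr(chroms, function(ch) {
    x <- dplyr::arrange(dplyr::filter(profile, .data$chrom == ch), .data$pos)
    lr <- x$log2_ratio
    sm <- if (length(lr) >= window) {
      as.numeric(runmed(lr, window, endrule = "median"))
    } else {
      lr
    }
    state <- ifelse(sm >= amp_threshold, 1L,
                    ifelse(sm <= -amp_threshold, -1L, 0L))
    transitions <- if (length(state) > 1) sum(diff(state) != 0L) else 0L
    tibble::tibble(chrom = ch, n_probes = length(lr),
                   transitions = as.integer(transitions),
                   unstable = transitions >= min_transitions)
  })
}

#' @export
print.cn_profile <- function(x, ...) {
  cat("<cn_profile> sample ", attr(x, "sample_id"), ", ", nrow(x),
      " probes (median-centered log2 ratios)\n", sep = "")
  NextMethod()
}
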