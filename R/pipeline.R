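#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Defaults are the values
#' the analysis is defined with: SD > 0.25 island probe selection, marker
#' mean bounds 0.5/0.2, copy-number QC quantiles 0.05/0.95 and MAD 0.8,
#' arm-call thresholds +/-0.15 with >= 20 probes, instability rule +/-0.3
#' with >= 10 transitions (window 5), a 1:2 train:validation split, beta-fit
#' clipping 1e-3, and the 80% H3K27me3 cutoff.
#'
#' @param cohort A [cohort_config()] used when the `simulate` stage is on.
#' @param input_dir Read a cohort written by [write_cohort()] from here
#'   instead of simulating (used when `stages$simulate` is `FALSE`).
#' @param stages Named list of logical toggles: `simulate`,
#'   `select_probes`, `cluster`, `cnv`, `classifier`, `ihc`.
#' @param sd_threshold,hyper_mean_min,hypo_mean_max Probe-selection knobs.
#' @param qc_lower_q,qc_upper_q,qc_mad_q Copy-number probe QC quantiles.
#' @param cn_offset Intensity offset for [log2_profile()].
#' @param gain_threshold,loss_threshold,min_probes Arm-call knobs.
#' @param amp_threshold,min_transitions,window Instability-flag knobs.
#' @param train_fraction,clip Classifier knobs.
#' @param ihc_cutoff H3K27me3 percent-labeled cutoff.
#' @param seed Seed driving the simulation and the stratified split.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            input_dir = NULL,
                            stages = list(simulate = TRUE,
                                          select_probes = TRUE,
                                          cluster = TRUE,
                                          cnv = TRUE,
                                          classifier = TRUE,
                                          ihc = TRUE),
                            sd_threshold = 0.25,
                            hyper_mean_min = 0.5,
                            hypo_mean_max = 0.2,
                            qc_lower_q = 0.05,
                            qc_upper_q = 0.95,
                            qc_mad_q = 0.8,
                            cn_offset = 1,
                            gain_threshold = 0.15,
                            loss_threshold = -0.15,
                            min_probes = 20,
                            amp_threshold = 0.3,
                            min_transitions = 10,
                            window = 5,
                            train_fraction = 1 / 3,
                            clip = 1e-3,
                            ihc_cutoff = 80,
                            seed = 1L) {
  defaults <- list(simulate = TRUE, select_probes = TRUE, cluster = TRUE,
                   cnv = TRUE, classifier = TRUE, ihc = TRUE)
  stages <- utils::modifyList(defaults, as.list(stages))
  cfg <- list(cohort = cohort, input_dir = input_dir, stages = stages,
              sd_threshold = sd_threshold, hyper_mean_min = hyper_mean_min,
              hypo_mean_max = hypo_mean_max, qc_lower_q = qc_lower_q,
              qc_upper_q = qc_upper_q, qc_mad_q = qc_mad_q,
              cn_offset = cn_offset, gain_threshold = gain_threshold,
              loss_threshold = loss_threshold, min_probes = min_probes,
              amp_threshold = amp_threshold,
              min_transitions = min_transitions, window = window,
              train_fraction = train_fraction, clip = clip,
              ihc_cutoff = ihc_cutoff, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the classification pipeline end to end
#'
#' Executes, in order and subject to the stage toggles: simulate (or load) a
#' cohort, select probes (autosomal filter, SD > threshold on CpG islands,
#' subgroup markers), two-group clustering with PFA/PFB labeling,
#' copy-number profiles with 1q-gain arm calls and a chromosome-11
#' instability flag, training and selection of the three-gene threshold
#' rule, and the H3K27me3 rule. A machine-readable report collecting every
#' confusion matrix, threshold, arm call and the selected rule -- plus the
#' full effective configuration -- is returned and optionally written as
#' JSON. A stage failure halts the run with the stage name; the partial
#' report written so far is still persisted when `out_json` is given.
#'
#' @param config A [pipeline_config()].
#' @param out_json Optional path for the JSON report.
#' @param cohort Optional pre-built cohort (skips simulate/load).
#' @return The report, a nested list, invisibly classed `pipeline_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_json = NULL,
                         cohort = NULL) {
  report <- list(config = config_as_list(config))
  persist <- function() {
    if (!is.null(out_json)) {
      jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null", force = TRUE)
    }
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      persist()
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  st <- config$stages

  if (is.null(cohort)) {
    if (st$simulate) {
      cohort <- run_stage("simulate", {
        cc <- config$cohort
        cc$seed <- config$seed
        generate_cohort(cc)
      })
      report$simulate <- list(
        n_samples = nrow(cohort$sample_sheet),
        n_probes = nrow(cohort$annotation),
        subgroups = as.list(table(cohort$sample_sheet$subgroup))
      )
    } else if (!is.null(config$input_dir)) {
      cohort <- run_stage("load", read_cohort(config$input_dir))
    }
  }
  if (is.null(cohort)) {
    persist()
    return(invisible(structure(report, class = "pipeline_report")))
  }

  tumors <- dplyr::filter(cohort$sample_sheet,
                          .data$subgroup %in% c("PFA", "PFB"))
  tumor_beta <- cohort$beta[c("probe_id", tumors$sample_id)]

  sd_markers <- NULL
  if (st$select_probes) {
    sel <- run_stage("select_probes", {
      autosomal <- filter_autosomal(cohort$annotation)
      sd_markers <- select_high_sd_island_probes(
        tumor_beta, autosomal, config$sd_threshold)
      subgroup_markers <- select_subgroup_markers(
        tumor_beta, tumors, config$hyper_mean_min, config$hypo_mean_max)
      list(autosomal = autosomal, sd = sd_markers,
           subgroup = subgroup_markers)
    })
    sd_markers <- sel$sd
    report$select_probes <- list(
      n_total = nrow(cohort$annotation),
      n_autosomal = nrow(sel$autosomal),
      n_sex_removed = nrow(cohort$annotation) - nrow(sel$autosomal),
      n_high_sd_island = nrow(sel$sd),
      n_subgroup_markers = nrow(sel$subgroup),
      sd_threshold = config$sd_threshold
    )
  }

  if (st$cluster) {
    labeled <- run_stage("cluster", {
      markers <- sd_markers
      if (is.null(markers) || nrow(markers) == 0) {
        abort("no clustering probes available (run select_probes first)")
      }
      asg <- hierarchical_cluster(tumor_beta, markers, k = 2)
      assign_subgroup_labels(asg, tumor_beta, markers)
    })
    agreement <- dplyr::inner_join(labeled, tumors, by = "sample_id")
    report$cluster <- list(
      linkage = attr(labeled, "linkage"),
      metric = attr(labeled, "metric"),
      cluster_mean_marker_beta = as.list(attr(labeled, "cluster_means")),
      assignments = dplyr::select(
        tibble::as_tibble(labeled), "sample_id", "cluster", "subgroup"),
      agreement_with_truth =
        mean(agreement$subgroup.x == agreement$subgroup.y)
    )
  }

  if (st$cnv) {
    cn <- run_stage("cnv", {
      controls <- cohort$sample_sheet$sample_id[
        cohort$sample_sheet$subgroup == "CONTROL"]
      if (length(controls) < 2) {
        abort("copy-number stage requires at least 2 control samples")
      }
      qc <- probe_qc(cohort$intensities$meth[c("probe_id", controls)],
                     cohort$intensities$unmeth[c("probe_id", controls)],
                     config$qc_lower_q, config$qc_upper_q, config$qc_mad_q)
      profiles <- lapply(tumors$sample_id, function(s) {
        log2_profile(cohort$intensities$meth, cohort$intensities$unmeth,
                     s, controls, qc, cohort$annotation,
                     offset = config$cn_offset)
      })
      names(profiles) <- tumors$sample_id
      arm_calls <- purrr::imap_dfr(profiles, function(p, s) {
        dplyr::mutate(
          call_arms(p, gain_threshold = config$gain_threshold,
                    loss_threshold = config$loss_threshold,
                    min_probes = config$min_probes),
          sample_id = s, .before = 1L)
      })
      instab <- purrr::imap_dfr(profiles, function(p, s) {
        dplyr::mutate(
          instability_flag(p, chroms = "chr11",
                           amp_threshold = config$amp_threshold,
                           min_transitions = config$min_transitions,
                           window = config$window),
          sample_id = s, .before = 1L)
      })
      list(n_qc = nrow(qc), arm_calls = arm_calls, instability = instab)
    })
    gains_1q <- dplyr::filter(cn$arm_calls, .data$arm == "1q",
                              .data$call == "gain")
    report$cnv <- list(
      n_qc_probes = cn$n_qc,
      arm_calls = cn$arm_calls,
      samples_with_1q_gain = gains_1q$sample_id,
      chr11_instability = cn$instability
    )
  }

  if (st$classifier) {
    clf <- run_stage("classifier", {
      train_pfb_classifier(cohort$gene_panel,
                           train_fraction = config$train_fraction,
                           seed = config$seed, clip = config$clip)
    })
    report$classifier <- list(
      fits = tidy(clf$fits),
      thresholds = as.list(clf$rule$thresholds),
      selected_mode = clf$rule$mode,
      candidate_evaluation = attr(clf$rule, "evaluation"),
      confusion_train = glance(clf$confusion$train),
      confusion_validation = glance(clf$confusion$validation)
    )
  }

  if (st$ihc) {
    ihc_res <- run_stage("ihc", {
      pred <- ihc_predict_subgroup(cohort$ihc, cutoff = config$ihc_cutoff)
      joined <- dplyr::inner_join(
        pred, cohort$sample_sheet[c("sample_id", "subgroup")],
        by = "sample_id")
      evaluable <- dplyr::filter(joined, .data$prediction != "not_evaluable")
      cm <- confusion_matrix(evaluable$subgroup, evaluable$prediction)
      list(pred = pred, cm = cm)
    })
    report$ihc <- list(
      cutoff = config$ihc_cutoff,
      categories = as.list(table(ihc_res$pred$category)),
      confusion = glance(ihc_res$cm)
    )
  }

  persist()
  invisible(structure(report, class = "pipeline_report"))
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$cohort <- unclass(out$cohort)
  out
}
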