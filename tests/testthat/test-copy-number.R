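# Build wide intensity tibbles from a total-intensity matrix, splitting the
# total into methylated/unmethylated halves (the split is irrelevant to
# copy number, which only sees the sum).
intensity_pair <- function(total, frac = 0.5) {
  list(
    meth = dplyr::bind_cols(tibble::tibble(probe_id = rownames(total)),
                            tibble::as_tibble(total * frac)),
    unmeth = dplyr::bind_cols(tibble::tibble(probe_id = rownames(total)),
                              tibble::as_tibble(total * (1 - frac)))
  )
}

test_that("probe QC keeps everything under degenerate uniformity", {
  total <- matrix(1000, 50, 3,
                  dimnames = list(paste0("p", 1:50), paste0("c", 1:3)))
  ip <- intensity_pair(total)
  qc <- probe_qc(ip$meth, ip$unmeth)
  expect_equal(nrow(qc), 50)
  expect_error(probe_qc(ip$meth[1], ip$unmeth[1]))  # no controls
  expect_error(probe_qc(ip$meth[1:2], ip$unmeth[1:2]), "2 control")
})

test_that("probe QC excludes planted extremes, matching a brute-force loop", {
  set.seed(7)
  total <- matrix(rlnorm(100 * 4, log(1000), 0.05), 100, 4,
                  dimnames = list(sprintf("p%03d", 1:100), paste0("c", 1:4)))
  hot <- sample(100, 5)
  cold <- sample(setdiff(1:100, hot), 5)
  total[hot, ] <- total[hot, ] * 50
  total[cold, ] <- total[cold, ] / 50
  ip <- intensity_pair(total)
  qc <- probe_qc(ip$meth, ip$unmeth)
  expect_true(all(!rownames(total)[c(hot, cold)] %in% qc$probe_id))

  # explicit-loop recomputation of both filters
  med <- madv <- numeric(100)
  for (i in 1:100) {
    med[i] <- median(total[i, ])
    madv[i] <- median(abs(total[i, ] - median(total[i, ])))
  }
  band <- quantile(med, c(0.05, 0.95))
  keep <- med >= band[1] & med <= band[2] & madv <= quantile(madv, 0.8)
  expect_setequal(qc$probe_id, rownames(total)[keep])
  # distinct medians: at most the 5th-95th band can survive
  expect_lte(nrow(qc) / 100, 0.90)
})

test_that("probe QC is invariant to probe and control order", {
  set.seed(8)
  total <- matrix(rlnorm(60 * 4, log(800), 0.2), 60, 4,
                  dimnames = list(sprintf("p%02d", 1:60), paste0("c", 1:4)))
  ip <- intensity_pair(total)
  qc1 <- probe_qc(ip$meth, ip$unmeth)
  shuf <- sample(60)
  ip2 <- intensity_pair(total[shuf, c(3, 1, 4, 2)])
  qc2 <- probe_qc(ip2$meth, ip2$unmeth)
  expect_setequal(qc1$probe_id, qc2$probe_id)
})

fixture_profile <- function(total_sample, total_controls, annotation) {
  ids <- rownames(total_controls)
  total <- cbind(total_sample, total_controls)
  colnames(total)[1] <- "tumor"
  ip <- intensity_pair(total)
  qc <- probe_qc(ip$meth[c("probe_id", colnames(total_controls))],
                 ip$unmeth[c("probe_id", colnames(total_controls))],
                 lower_q = 0, upper_q = 1, mad_q = 1)
  log2_profile(ip$meth, ip$unmeth, "tumor", colnames(total_controls), qc,
               annotation)
}

flat_annotation <- function(n, chrom = "chr2") {
  half <- ceiling(n / 2)
  tibble::tibble(probe_id = sprintf("p%04d", 1:n), chrom = chrom,
                 pos = (1:n) * 1000L,
                 arm = paste0(sub("chr", "", chrom),
                              ifelse(1:n <= half, "p", "q")))
}

test_that("a sample identical to the controls has an all-zero profile", {
  n <- 100
  ctrl <- matrix(1000, n, 3, dimnames = list(sprintf("p%04d", 1:n),
                                             paste0("c", 1:3)))
  prof <- fixture_profile(ctrl[, 1, drop = FALSE], ctrl, flat_annotation(n))
  expect_equal(prof$log2_ratio, rep(0, n))
  expect_equal(median(prof$log2_ratio), 0, tolerance = 1e-9)
  expect_equal(call_arms(prof, min_probes = 10)$call, c("neutral", "neutral"))
})

test_that("doubling 1q intensities yields a 1q median log2 ratio near 1", {
  n <- 2000
  ann <- tibble::tibble(
    probe_id = sprintf("p%04d", 1:n),
    chrom = rep(c("chr1", "chr2"), c(400, 1600)),
    pos = c(1:400, 1:1600) * 1000L,
    arm = c(rep(c("1p", "1q"), each = 200), rep(c("2p", "2q"), each = 800))
  )
  ctrl <- matrix(1000, n, 3, dimnames = list(ann$probe_id, paste0("c", 1:3)))
  smp <- ctrl[, 1, drop = FALSE]
  smp[ann$arm == "1q", ] <- smp[ann$arm == "1q", ] * 2
  prof <- fixture_profile(smp, ctrl, ann)
  calls <- call_arms(prof)
  expect_lt(abs(calls$median_log2[calls$arm == "1q"] - 1), 0.05)
  expect_equal(calls$call[calls$arm == "1q"], "gain")
  expect_equal(calls$call[calls$arm != "1q"], rep("neutral", 3))
  expect_equal(median(prof$log2_ratio), 0, tolerance = 1e-9)
})

test_that("global intensity scaling leaves the centered profile unchanged", {
  set.seed(11)
  n <- 500
  ann <- flat_annotation(n)
  ctrl <- matrix(rlnorm(n * 4, log(1200), 0.1), n, 4,
                 dimnames = list(ann$probe_id, paste0("c", 1:4)))
  smp <- matrix(rlnorm(n, log(1200), 0.1), n, 1,
                dimnames = list(ann$probe_id, "s"))
  p1 <- fixture_profile(smp, ctrl, ann)
  p2 <- fixture_profile(smp * 7.3, ctrl, ann)
  # the 1-unit offset perturbs ratios by ~1/(intensity * ln 2) ~ 1e-4, so
  # invariance under the default offset is near-exact, not bitwise (the
  # exact-invariance contract is tested below with a zero offset)
  expect_equal(p2$log2_ratio, p1$log2_ratio, tolerance = 1e-3)

  p3 <- fixture_profile(smp * 7.3, ctrl, dplyr::mutate(ann, arm = "2q"))
  expect_equal(median(p3$log2_ratio), 0, tolerance = 1e-9)
})

test_that("exact scale invariance holds with a zero offset", {
  set.seed(12)
  n <- 200
  ann <- flat_annotation(n)
  ctrl <- matrix(rlnorm(n * 3, log(900), 0.1), n, 3,
                 dimnames = list(ann$probe_id, paste0("c", 1:3)))
  smp <- matrix(rlnorm(n, log(900), 0.1), n, 1,
                dimnames = list(ann$probe_id, "s"))
  total <- cbind(s = smp, ctrl)
  colnames(total)[1] <- "tumor"
  ip <- intensity_pair(total)
  qc <- probe_qc(ip$meth[c("probe_id", colnames(ctrl))],
                 ip$unmeth[c("probe_id", colnames(ctrl))],
                 lower_q = 0, upper_q = 1, mad_q = 1)
  p1 <- log2_profile(ip$meth, ip$unmeth, "tumor", colnames(ctrl), qc, ann,
                     offset = 0)
  ip2 <- intensity_pair(cbind(tumor = total[, 1] * 1e3, total[, -1]))
  p2 <- log2_profile(ip2$meth, ip2$unmeth, "tumor", colnames(ctrl), qc, ann,
                     offset = 0)
  expect_equal(p2$log2_ratio, p1$log2_ratio, tolerance = 1e-9)
})

test_that("arm gain calls recover generator truth across 20 seeds", {
  hits <- 0L
  total_calls <- 0L
  for (s in 1:20) {
    cfg <- cohort_config(n_pfa = 5, n_pfb = 2, n_controls = 4,
                         n_probes_total = 8800, n_sex_probes = 0,
                         n_island_probes = 100, n_marker_probes = 20,
                         frac_pfa_1q_gain = 0.5, gain_log2_shift = 0.5,
                         seed = 500 + s)
    coh <- generate_cohort(cfg)
    ctrl <- coh$sample_sheet$sample_id[coh$sample_sheet$subgroup == "CONTROL"]
    qc <- probe_qc(coh$intensities$meth[c("probe_id", ctrl)],
                   coh$intensities$unmeth[c("probe_id", ctrl)])
    tumors <- dplyr::filter(coh$sample_sheet, subgroup != "CONTROL")
    for (i in seq_len(nrow(tumors))) {
      prof <- log2_profile(coh$intensities$meth, coh$intensities$unmeth,
                           tumors$sample_id[i], ctrl, qc, coh$annotation)
      calls <- call_arms(prof)
      gained_arms <- calls$arm[calls$call == "gain"]
      truth <- if (tumors$has_1q_gain[i]) "1q" else character(0)
      expect_equal(gained_arms, truth,
                   label = paste("seed", 500 + s, tumors$sample_id[i]))
      hits <- hits + as.integer(identical(gained_arms, truth))
      total_calls <- total_calls + 1L
    }
  }
  expect_equal(hits, total_calls)  # sensitivity and specificity both 1.0
})

test_that("too few probes on an arm yields an insufficient-probes call", {
  n <- 25
  ann <- flat_annotation(n)  # 13 on 2p, 12 on 2q
  ctrl <- matrix(1000, n, 2, dimnames = list(ann$probe_id, c("c1", "c2")))
  prof <- fixture_profile(ctrl[, 1, drop = FALSE], ctrl, ann)
  calls <- call_arms(prof, min_probes = 20)
  expect_equal(unique(calls$call), "insufficient_probes")
  expect_equal(sum(calls$n_probes), n)
  expect_error(call_arms(prof, arms = "7q"), "absent")
})

test_that("instability flag counts oscillation transitions", {
  # flat chromosome: no transitions
  n <- 200
  ann <- flat_annotation(n, "chr11")
  ctrl <- matrix(1000, n, 3, dimnames = list(ann$probe_id, paste0("c", 1:3)))
  flat <- fixture_profile(ctrl[, 1, drop = FALSE], ctrl, ann)
  res <- instability_flag(flat, "chr11")
  expect_equal(res$transitions, 0L)
  expect_false(res$unstable)

  # 40 alternating blocks at +/-0.8 log2 units
  smp <- ctrl[, 1, drop = FALSE]
  block <- rep(rep(c(2^0.8, 2^-0.8), 20), each = 5)
  smp[, 1] <- smp[, 1] * block
  osc <- fixture_profile(smp, ctrl, ann)
  res <- instability_flag(osc, "chr11")
  expect_gte(res$transitions, 10)
  expect_true(res$unstable)

  # one step gain mid-chromosome: a single transition, no flag
  smp2 <- ctrl[, 1, drop = FALSE]
  smp2[101:200, 1] <- smp2[101:200, 1] * 2
  step <- fixture_profile(smp2, ctrl, ann)
  res <- instability_flag(step, "chr11")
  expect_equal(res$transitions, 1L)
  expect_false(res$unstable)

  expect_error(instability_flag(flat, "chr7"), "absent")
})
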