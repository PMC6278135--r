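#' Generate a synthetic posterior-fossa ependymoma cohort
#'
#' Draws a reproducible cohort with the statistical structure the analysis
#' stages assume: a 450K-like probe annotation (autosomes chr1-chr22 split
#' into p/q arms, sex-chromosome probes, a CpG-island subset containing
#' subgroup-separated marker probes), a beta-value matrix, paired
#' methylated/unmethylated intensity matrices consistent with the beta
#' values, arm-level 1q-gain copy-number states in a fraction of PFA
#' samples, a three-gene pyrosequencing panel (CRIP1, DRD4, LBX2) with
#' per-class beta-distributed methylation percentages, and H3K27me3
#' immunohistochemistry percent-labeled-nuclei values.
#'
#' Marker-probe beta values are drawn from `pfa_marker_beta` for PFA samples
#' and `pfb_marker_beta` for PFB samples (controls use the background
#' distribution); all other values come from `background_beta`. Total probe
#' intensity is log-normal, `LogNormal(log(base_intensity) + shift * log 2,
#' intensity_noise_sd)` with `shift = gain_log2_shift` on 1q probes of
#' 1q-gain samples and 0 elsewhere; the methylated channel is the sample's
#' beta value times the total, so `beta = meth / (meth + unmeth)` exactly
#' (beta offset 0).
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `sample_sheet`,
#'   `annotation`, `beta`, `intensities` (list with `meth` and `unmeth`),
#'   `gene_panel`, `ihc` (all tibbles; matrices are wide, `probe_id` first)
#'   and the `config` used.
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_pfa = 6, n_pfb = 3, n_controls = 2,
#'   n_probes_total = 300, n_sex_probes = 20,
#'   n_island_probes = 60, n_marker_probes = 20, seed = 7
#' ))
#' dplyr::count(cohort$sample_sheet, subgroup)
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  cfg <- config

  sample_sheet <- with_block_seed(cfg$seed, 1L, make_sample_sheet(cfg))
  annotation <- make_annotation(cfg)
  beta <- with_block_seed(cfg$seed, 2L,
                          make_beta_matrix(cfg, sample_sheet, annotation))
  intensities <- with_block_seed(cfg$seed, 3L,
                                 make_intensities(cfg, sample_sheet,
                                                  annotation, beta))
  gene_panel <- with_block_seed(cfg$seed, 4L,
                                make_gene_panel(cfg, sample_sheet))
  ihc <- with_block_seed(cfg$seed, 5L, make_ihc(cfg, sample_sheet))

  structure(
    list(sample_sheet = sample_sheet, annotation = annotation, beta = beta,
         intensities = intensities, gene_panel = gene_panel, ihc = ihc,
         config = cfg),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$sample_sheet), " samples x ",
      nrow(x$annotation), " probes (seed ", x$config$seed, ")\n", sep = "")
  print(dplyr::count(x$sample_sheet, .data$subgroup))
  invisible(x)
}

make_sample_sheet <- function(cfg) {
  n <- cfg$n_pfa + cfg$n_pfb + cfg$n_controls
  if (n == 0) {
    return(tibble::tibble(sample_id = character(), subgroup = character(),
                          age = numeric(), has_1q_gain = logical()))
  }
  subgroup <- rep(c("PFA", "PFB", "CONTROL"),
                  c(cfg$n_pfa, cfg$n_pfb, cfg$n_controls))
  sample_id <- c(sprintf("PFA%03d", seq_len(cfg$n_pfa)),
                 sprintf("PFB%03d", seq_len(cfg$n_pfb)),
                 sprintf("CTRL%03d", seq_len(cfg$n_controls)))
  # Ages carry clinical flavor only: PFA onset median ~4 y, PFB ~30 y.
  age <- numeric(n)
  age[subgroup == "PFA"] <- pmax(0, round(rlnorm(cfg$n_pfa, log(4), 0.6)))
  age[subgroup == "PFB"] <- pmax(1, round(rlnorm(cfg$n_pfb, log(30), 0.4)))
  age[subgroup == "CONTROL"] <- NA_real_
  has_1q_gain <- logical(n)
  has_1q_gain[subgroup == "PFA"] <-
    rbinom(cfg$n_pfa, 1L, cfg$frac_pfa_1q_gain) == 1L
  tibble::tibble(sample_id = sample_id, subgroup = subgroup, age = age,
                 has_1q_gain = has_1q_gain)
}

# Deterministic probe map: autosomal probes round-robin over chr1..chr22,
# each chromosome split into p and q halves; sex probes appended on
# chrX/chrY. Island probes (and the marker subset at their head) are the
# first autosomal probes in id order, hence spread over all arms.
make_annotation <- function(cfg) {
  n_auto <- cfg$n_probes_total - cfg$n_sex_probes
  empty <- tibble::tibble(probe_id = character(), chrom = character(),
                          pos = integer(), arm = character(),
                          cpg_island = logical(), is_marker = logical())
  if (cfg$n_probes_total == 0) return(empty)
  rows <- list()
  if (n_auto > 0) {
    chrom_idx <- rep_len(1:22, n_auto)
    within <- stats::ave(seq_len(n_auto), chrom_idx, FUN = seq_along)
    per_chrom <- tabulate(chrom_idx, 22L)
    half <- ceiling(per_chrom / 2)
    arm_side <- ifelse(within <= half[chrom_idx], "p", "q")
    rows$auto <- tibble::tibble(
      probe_id = sprintf("cg%08d", seq_len(n_auto)),
      chrom = paste0("chr", chrom_idx),
      pos = within * 10000L,
      arm = paste0(chrom_idx, arm_side),
      cpg_island = seq_len(n_auto) <= cfg$n_island_probes,
      is_marker = seq_len(n_auto) <= cfg$n_marker_probes
    )
  }
  if (cfg$n_sex_probes > 0) {
    n_x <- ceiling(cfg$n_sex_probes / 2)
    n_y <- cfg$n_sex_probes - n_x
    sex_chrom <- rep(c("chrX", "chrY"), c(n_x, n_y))
    within <- c(seq_len(n_x), seq_len(n_y))
    half <- c(ceiling(n_x / 2), ceiling(n_y / 2))[match(sex_chrom,
                                                        c("chrX", "chrY"))]
    rows$sex <- tibble::tibble(
      probe_id = sprintf("cg%08d", n_auto + seq_len(cfg$n_sex_probes)),
      chrom = sex_chrom,
      pos = within * 10000L,
      arm = paste0(sub("^chr", "", sex_chrom),
                   ifelse(within <= half, "p", "q")),
      cpg_island = FALSE,
      is_marker = FALSE
    )
  }
  dplyr::bind_rows(rows)
}

make_beta_matrix <- function(cfg, sample_sheet, annotation) {
  n_probes <- nrow(annotation)
  n_samples <- nrow(sample_sheet)
  m <- matrix(NA_real_, nrow = n_probes, ncol = n_samples,
              dimnames = list(annotation$probe_id, sample_sheet$sample_id))
  if (n_probes * n_samples > 0) {
    m[] <- rbeta(n_probes * n_samples,
                 cfg$background_beta[1], cfg$background_beta[2])
    marker <- which(annotation$is_marker)
    for (cls in c("PFA", "PFB")) {
      cols <- which(sample_sheet$subgroup == cls)
      if (length(marker) > 0 && length(cols) > 0) {
        shp <- if (cls == "PFA") cfg$pfa_marker_beta else cfg$pfb_marker_beta
        m[marker, cols] <- rbeta(length(marker) * length(cols),
                                 shp[1], shp[2])
      }
    }
  }
  matrix_to_wide(m)
}

make_intensities <- function(cfg, sample_sheet, annotation, beta) {
  b <- wide_to_matrix(beta)
  n_probes <- nrow(b)
  n_samples <- ncol(b)
  shift <- matrix(0, n_probes, n_samples)
  gained <- which(sample_sheet$has_1q_gain)
  on_1q <- which(annotation$arm == "1q")
  if (length(gained) > 0 && length(on_1q) > 0) {
    shift[on_1q, gained] <- cfg$gain_log2_shift
  }
  total <- matrix(
    rlnorm(n_probes * n_samples,
           meanlog = log(cfg$base_intensity) + as.vector(shift) * log(2),
           sdlog = cfg$intensity_noise_sd),
    n_probes, n_samples, dimnames = dimnames(b)
  )
  meth <- total * b
  unmeth <- total * (1 - b)
  list(meth = matrix_to_wide(meth), unmeth = matrix_to_wide(unmeth))
}

make_gene_panel <- function(cfg, sample_sheet) {
  tumors <- dplyr::filter(sample_sheet, .data$subgroup %in% c("PFA", "PFB"))
  out <- tibble::tibble(sample_id = tumors$sample_id,
                        subgroup = tumors$subgroup)
  for (g in panel_genes()) {
    v <- numeric(nrow(tumors))
    for (cls in c("PFA", "PFB")) {
      idx <- which(tumors$subgroup == cls)
      shp <- cfg$gene_panel_dists[[g]][[cls]]
      v[idx] <- 100 * rbeta(length(idx), shp[1], shp[2])
    }
    out[[g]] <- v
  }
  dplyr::relocate(out, "subgroup", .after = dplyr::last_col())
}

draw_uniform_mixture <- function(n, mix) {
  if (n == 0) return(numeric(0))
  w <- mix$weight / sum(mix$weight)
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  runif(n, mix$lower[comp], mix$upper[comp])
}

make_ihc <- function(cfg, sample_sheet) {
  tumors <- dplyr::filter(sample_sheet, .data$subgroup %in% c("PFA", "PFB"))
  pct <- numeric(nrow(tumors))
  for (cls in c("PFA", "PFB")) {
    idx <- which(tumors$subgroup == cls)
    pct[idx] <- draw_uniform_mixture(length(idx), cfg$ihc_dists[[cls]])
  }
  tibble::tibble(sample_id = tumors$sample_id, percent_labeled = pct,
                 control_ok = rep(TRUE, nrow(tumors)))
}
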