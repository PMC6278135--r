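#' Configuration for the synthetic ependymoma cohort generator
#'
#' Collects and validates every tunable of [generate_cohort()]. Defaults
#' describe a posterior-fossa cohort of 45 PFA and 15 PFB tumors plus six
#' normal-cerebellum copy-number controls on a scaled-down 450K-like array
#' (10,000 probes). Marker probes are CpG-island probes whose methylation
#' separates the subgroups: hypermethylated in PFA (Beta(8, 6), mean 0.571)
#' and hypomethylated in PFB (Beta(1, 15), mean 0.0625), so that the
#' downstream mean-beta criteria (PFA mean >= 0.5, PFB mean <= 0.2) hold for
#' planted markers.
#'
#' @param n_pfa,n_pfb,n_controls Sample counts per class; controls are
#'   copy-neutral normal references used only for copy-number work.
#' @param n_probes_total Total number of array probes.
#' @param n_sex_probes Probes placed on chrX/chrY (removed by
#'   [filter_autosomal()]).
#' @param n_island_probes Autosomal probes flagged as CpG-island probes.
#' @param n_marker_probes Island probes with subgroup-separated methylation;
#'   must not exceed `n_island_probes`.
#' @param pfa_marker_beta,pfb_marker_beta,background_beta Length-2 positive
#'   shape pairs `(alpha, beta)` of the beta distributions that marker-probe
#'   values are drawn from in each subgroup, and that all remaining
#'   (background) values are drawn from in every sample.
#' @param gene_panel_dists Named list `CRIP1`, `DRD4`, `LBX2`, each a list
#'   with elements `PFA` and `PFB` holding `(alpha, beta)` shape pairs on the
#'   \[0,1\] scale; pyrosequencing percentages are 100 x draws.
#' @param frac_pfa_1q_gain Fraction of PFA samples carrying a 1q gain.
#' @param gain_log2_shift Expected log2 shift of total probe intensity on the
#'   gained arm.
#' @param base_intensity Baseline expected total (methylated + unmethylated)
#'   signal per probe.
#' @param intensity_noise_sd Standard deviation (log scale) of the
#'   multiplicative log-normal intensity noise.
#' @param ihc_dists Named list `PFA`, `PFB`; each a tibble-able list with
#'   vectors `weight`, `lower`, `upper` describing a mixture of uniforms for
#'   percent labeled nuclei (H3K27me3 immunohistochemistry).
#' @param seed Integer seed; one global seed drives deterministic per-block
#'   sub-streams, so adding a data block never perturbs earlier blocks.
#'
#' @return A validated list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_pfa = 45,
                          n_pfb = 15,
                          n_controls = 6,
                          n_probes_total = 10000,
                          n_sex_probes = 250,
                          n_island_probes = 2000,
                          n_marker_probes = 100,
                          pfa_marker_beta = c(8, 6),
                          pfb_marker_beta = c(1, 15),
                          background_beta = c(5, 5),
                          gene_panel_dists = default_gene_panel_dists(),
                          frac_pfa_1q_gain = 0.3,
                          gain_log2_shift = 0.5,
                          base_intensity = 3000,
                          intensity_noise_sd = 0.1,
                          ihc_dists = default_ihc_dists(),
                          seed = 1L) {
  cfg <- list(
    n_pfa = n_pfa, n_pfb = n_pfb, n_controls = n_controls,
    n_probes_total = n_probes_total, n_sex_probes = n_sex_probes,
    n_island_probes = n_island_probes, n_marker_probes = n_marker_probes,
    pfa_marker_beta = pfa_marker_beta, pfb_marker_beta = pfb_marker_beta,
    background_beta = background_beta, gene_panel_dists = gene_panel_dists,
    frac_pfa_1q_gain = frac_pfa_1q_gain, gain_log2_shift = gain_log2_shift,
    base_intensity = base_intensity,
    intensity_noise_sd = intensity_noise_sd,
    ihc_dists = ihc_dists, seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

panel_genes <- function() c("CRIP1", "DRD4", "LBX2")

#' @rdname cohort_config
#' @export
default_gene_panel_dists <- function() {
  one <- list(PFA = c(8, 6), PFB = c(1, 15))
  list(CRIP1 = one, DRD4 = one, LBX2 = one)
}

#' @rdname cohort_config
#' @export
default_ihc_dists <- function() {
  list(
    PFA = list(weight = c(0.38, 0.62), lower = c(0, 5), upper = c(5, 50)),
    PFB = list(weight = c(0.867, 0.133), lower = c(81, 10), upper = c(100, 60))
  )
}

validate_cohort_config <- function(cfg) {
  counts <- c("n_pfa", "n_pfb", "n_controls", "n_probes_total",
              "n_sex_probes", "n_island_probes", "n_marker_probes")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != floor(v)) {
      abort(paste0("configuration error: '", f,
                   "' must be a single non-negative integer"))
    }
  }
  if (cfg$n_sex_probes + cfg$n_island_probes > cfg$n_probes_total) {
    abort("configuration error: 'n_sex_probes' + 'n_island_probes' exceeds 'n_probes_total'")
  }
  if (cfg$n_marker_probes > cfg$n_island_probes) {
    abort("configuration error: 'n_marker_probes' exceeds 'n_island_probes'")
  }
  shapes <- list(pfa_marker_beta = cfg$pfa_marker_beta,
                 pfb_marker_beta = cfg$pfb_marker_beta,
                 background_beta = cfg$background_beta)
  for (nm in names(shapes)) {
    v <- shapes[[nm]]
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) ||
        any(v <= 0)) {
      abort(paste0("configuration error: '", nm,
                   "' must be two positive beta shape parameters"))
    }
  }
  for (g in panel_genes()) {
    d <- cfg$gene_panel_dists[[g]]
    if (is.null(d)) {
      abort(paste0("configuration error: 'gene_panel_dists' lacks gene ", g))
    }
    for (cls in c("PFA", "PFB")) {
      v <- d[[cls]]
      if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) ||
          any(v <= 0)) {
        abort(paste0("configuration error: 'gene_panel_dists$", g, "$", cls,
                     "' must be two positive beta shape parameters"))
      }
    }
  }
  for (f in c("frac_pfa_1q_gain")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(paste0("configuration error: '", f, "' must lie in [0, 1]"))
    }
  }
  for (f in c("base_intensity", "intensity_noise_sd")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort(paste0("configuration error: '", f, "' must be non-negative"))
    }
  }
  for (cls in c("PFA", "PFB")) {
    d <- cfg$ihc_dists[[cls]]
    ok <- is.list(d) && all(c("weight", "lower", "upper") %in% names(d)) &&
      length(d$weight) == length(d$lower) &&
      length(d$lower) == length(d$upper) &&
      all(d$weight >= 0) && sum(d$weight) > 0 &&
      all(d$lower <= d$upper) && all(d$lower >= 0) && all(d$upper <= 100)
    if (!ok) {
      abort(paste0("configuration error: 'ihc_dists$", cls,
                   "' must be a weight/lower/upper uniform mixture on [0, 100]"))
    }
  }
  invisible(cfg)
}
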