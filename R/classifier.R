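#' Stratified train/validation split
#'
#' Splits labeled gene-panel records into a training and a validation set
#' while maintaining the PFA:PFB ratio: within each class,
#' `round(train_fraction * n)` samples (half away from zero) are drawn
#' without replacement into training and the rest form the validation set.
#' With 123 records (90 PFA, 33 PFB) at the default 1:2 fraction this gives
#' 41 training (30 PFA, 11 PFB) and 82 validation (60 PFA, 22 PFB).
#' Membership is a deterministic function of `seed` and of the set of
#' sample ids (ids are sorted within class before sampling, so permuting
#' the input rows does not change the split).
#'
#' @param records Tibble with `sample_id` and `true_subgroup` or `subgroup`
#'   in `{"PFA","PFB"}` (no missing labels).
#' @param train_fraction Fraction per class assigned to training
#'   (default 1/3, i.e. a 1:2 split).
#' @param seed Integer seed for the within-class draws.
#' @param allow_empty_class Keep going when a class ends up absent from one
#'   partition (default `FALSE`: error).
#' @return List with tibbles `train` and `validation`; disjoint and jointly
#'   exhaustive.
#' @export
stratified_split <- function(records, train_fraction = 1 / 3, seed = 1L,
                             allow_empty_class = FALSE) {
  records <- normalize_panel_records(records)
  if (any(is.na(records$subgroup)) ||
      !all(records$subgroup %in% c("PFA", "PFB"))) {
    abort("every record must be labeled PFA or PFB")
  }
  if (anyDuplicated(records$sample_id) > 0) abort("duplicate sample ids")
  train_ids <- character(0)
  for (cls in c("PFA", "PFB")) {
    ids <- sort(records$sample_id[records$subgroup == cls])
    n_train <- floor(train_fraction * length(ids) + 0.5)  # half away from 0
    picked <- with_block_seed(seed, match(cls, c("PFA", "PFB")), {
      sample(ids, n_train)
    })
    if (!allow_empty_class &&
        (n_train == 0 || n_train == length(ids))) {
      abort(paste0("class absent from a partition: ", cls,
                   " (set allow_empty_class = TRUE to permit)"))
    }
    train_ids <- c(train_ids, picked)
  }
  list(
    train = records[records$sample_id %in% train_ids, , drop = FALSE],
    validation = records[!records$sample_id %in% train_ids, , drop = FALSE]
  )
}

normalize_panel_records <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"subgroup" %in% names(records) && "true_subgroup" %in% names(records)) {
    records <- dplyr::rename(records, subgroup = "true_subgroup")
  }
  if (!"sample_id" %in% names(records)) abort("records need a sample_id column")
  records
}

#' Fit a beta distribution to methylation percentages
#'
#' Maximum-likelihood fit of a beta distribution to pyrosequencing
#' methylation percentages of one gene in one subgroup. Values are scaled
#' to \[0,1\] and clipped to `[clip, 1 - clip]` before fitting; shapes are
#' estimated by `optim` (L-BFGS-B on log shapes) from a method-of-moments
#' start.
#'
#' @param values Numeric methylation percentages in \[0, 100\], length >= 2.
#' @param gene,class Optional labels stored on the fit.
#' @param clip Clipping bound on the \[0,1\] scale (default 1e-3).
#' @return Object of class `beta_fit`: `gene`, `class`, `alpha`, `beta`,
#'   `n_observations`, `loglik`, `fit_method`, `clip`.
#' @export
fit_beta <- function(values, gene = NA_character_, class = NA_character_,
                     clip = 1e-3) {
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("beta fit requires at least 2 values")
  if (any(values < 0 | values > 100)) {
    abort("methylation percentages must lie in [0, 100]")
  }
  x <- pmin(pmax(values / 100, clip), 1 - clip)
  if (diff(range(x)) < .Machine$double.eps^0.5) {
    abort("degenerate fit: all values identical after clipping")
  }
  m <- mean(x)
  v <- stats::var(x)
  v <- min(v, m * (1 - m) * 0.999)  # keep moment start feasible
  common <- m * (1 - m) / v - 1
  start <- log(pmax(c(m * common, (1 - m) * common), 1e-6))
  nll <- function(p) -sum(dbeta(x, exp(p[1]), exp(p[2]), log = TRUE))
  opt <- optim(start, nll, method = "L-BFGS-B",
               lower = log(1e-6), upper = log(1e6))
  shapes <- exp(opt$par)
  structure(
    list(gene = gene, class = class, alpha = shapes[1], beta = shapes[2],
         n_observations = length(values), loglik = -opt$value,
         fit_method = "mle (L-BFGS-B, method-of-moments start)",
         clip = clip),
    class = "beta_fit"
  )
}

beta_fit_mean <- function(fit) fit$alpha / (fit$alpha + fit$beta)

#' @export
print.beta_fit <- function(x, ...) {
  cat("<beta_fit> ", x$gene, "/", x$class, ": Beta(",
      signif(x$alpha, 4), ", ", signif(x$beta, 4), "), mean ",
      signif(100 * beta_fit_mean(x), 4), "% (n = ", x$n_observations,
      ")\n", sep = "")
  invisible(x)
}

#' Fit per-gene, per-class beta distributions on a training set
#'
#' @param records Labeled gene-panel tibble (columns `sample_id`, the gene
#'   columns, `subgroup`).
#' @param genes Gene columns to fit (default CRIP1, DRD4, LBX2).
#' @inheritParams fit_beta
#' @return Tibble of class `beta_fits` with one row per gene x class
#'   (`gene`, `class`, `alpha`, `beta`, `n`) and a list-column `fit`.
#' @export
fit_gene_panel <- function(records, genes = panel_genes(), clip = 1e-3) {
  records <- normalize_panel_records(records)
  missing_gene <- setdiff(genes, names(records))
  if (length(missing_gene) > 0) {
    abort(paste0("gene column(s) missing: ",
                 paste(missing_gene, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(gene = genes, class = c("PFA", "PFB"))
  fits <- purrr::pmap(grid, function(gene, class) {
    fit_beta(records[[gene]][records$subgroup == class], gene, class, clip)
  })
  out <- dplyr::mutate(
    grid,
    alpha = purrr::map_dbl(fits, "alpha"),
    beta = purrr::map_dbl(fits, "beta"),
    n = purrr::map_int(fits, "n_observations"),
    fit = fits
  )
  class(out) <- c("beta_fits", class(out))
  out
}

#' Likelihood-ratio threshold between two fitted beta densities
#'
#' The methylation percentage at which the fitted PFA and PFB densities are
#' equal (likelihood ratio 1); below it the PFB density dominates. The
#' log-density difference is evaluated on a 0.01-percent grid over (0, 100)
#' and the sign change nearest the inter-mean interval is refined by
#' bisection.
#'
#' @param fit_pfa,fit_pfb `beta_fit` objects; the PFB mean must be below
#'   the PFA mean (PFB is hypomethylated at these genes).
#' @return Threshold as a percent in (0, 100).
#' @export
lr_threshold <- function(fit_pfa, fit_pfb) {
  mu_a <- beta_fit_mean(fit_pfa)
  mu_b <- beta_fit_mean(fit_pfb)
  if (!(mu_b < mu_a)) {
    abort("PFB fitted mean must be below the PFA fitted mean")
  }
  ldiff <- function(x) {
    dbeta(x, fit_pfa$alpha, fit_pfa$beta, log = TRUE) -
      dbeta(x, fit_pfb$alpha, fit_pfb$beta, log = TRUE)
  }
  grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  d <- ldiff(grid)
  # sign changes between consecutive non-zero grid values; exact zeros on
  # the grid are absorbed into a single bracketing interval
  nz <- which(d != 0)
  chg <- which(sign(d[nz[-length(nz)]]) != sign(d[nz[-1]]))
  exact <- which(d == 0)
  if (length(chg) == 0 && length(exact) == 0) {
    abort("no likelihood-ratio crossover in (0, 100)")
  }
  lo <- grid[nz[chg]]
  hi <- grid[nz[chg + 1]]
  mid <- (lo + hi) / 2
  # distance of each crossover from the inter-mean interval (0 if inside)
  dist_to <- pmax(mu_b - mid, mid - mu_a, 0)
  inside <- which(dist_to == 0)
  if (length(inside) > 1) {
    abort("multiple likelihood-ratio crossovers inside the inter-mean interval")
  }
  pick <- if (length(inside) == 1) inside else which.min(dist_to)
  if (length(pick) == 0) {
    x_star <- grid[exact[1]]
  } else {
    x_star <- uniroot(ldiff, lower = lo[pick], upper = hi[pick],
                      tol = .Machine$double.eps^0.5)$root
  }
  100 * x_star
}

#' Three-gene threshold rule
#'
#' A classification rule: a gene "suggests PFB" when the sample's
#' methylation percentage is strictly below that gene's threshold, and the
#' rule calls the sample PFB when enough genes suggest it (`"all"`: every
#' gene; `"majority"`: more than half; `"any"`: at least one). Everything
#' not called PFB is PFA.
#'
#' @param thresholds Named numeric vector of per-gene thresholds, strictly
#'   inside (0, 100), e.g. `c(CRIP1 = 25, DRD4 = 11, LBX2 = 23)`.
#' @param mode `"all"`, `"majority"` or `"any"`.
#' @param provenance Optional free-text record of how the rule was derived.
#' @return Object of class `threshold_rule`.
#' @export
threshold_rule <- function(thresholds, mode = c("all", "majority", "any"),
                           provenance = NULL) {
  mode <- match.arg(mode)
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds)))) {
    abort("thresholds must be named by gene")
  }
  if (any(!is.finite(thresholds)) || any(thresholds <= 0) ||
      any(thresholds >= 100)) {
    abort("thresholds must lie strictly inside (0, 100)")
  }
  structure(list(thresholds = thresholds, mode = mode,
                 provenance = provenance),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat("<threshold_rule> mode \"", x$mode, "\"; PFB if methylation < ",
      paste(sprintf("%s: %.3g%%", names(x$thresholds), x$thresholds),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Candidate rules from fitted likelihoods
#'
#' Derives the per-gene likelihood-ratio thresholds from a [fit_gene_panel()]
#' result and returns the three combination-rule candidates (`all`,
#' `majority`, `any`) sharing those thresholds.
#'
#' @param fits A `beta_fits` tibble with both classes for every gene.
#' @return Named list of three `threshold_rule` objects.
#' @export
candidate_rules <- function(fits) {
  genes <- unique(fits$gene)
  thresholds <- vapply(genes, function(g) {
    fa <- fits$fit[fits$gene == g & fits$class == "PFA"][[1]]
    fb <- fits$fit[fits$gene == g & fits$class == "PFB"][[1]]
    lr_threshold(fa, fb)
  }, numeric(1))
  names(thresholds) <- genes
  prov <- "likelihood-ratio crossover of per-gene beta fits on training data"
  setNames(
    lapply(c("all", "majority", "any"), function(m) {
      threshold_rule(thresholds, m, provenance = prov)
    }),
    c("all", "majority", "any")
  )
}

#' Predict PFA/PFB for gene-panel records
#'
#' @param records Gene-panel tibble containing every gene named in the
#'   rule's thresholds (values in \[0, 100\], no missing values).
#' @param rule A [threshold_rule()].
#' @return The records with `n_suggest_pfb` and `prediction` columns added.
#' @export
predict_subgroup <- function(records, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  records <- normalize_panel_records(records)
  genes <- names(rule$thresholds)
  missing_gene <- setdiff(genes, names(records))
  if (length(missing_gene) > 0) {
    abort(paste0("gene value(s) missing: ",
                 paste(missing_gene, collapse = ", ")))
  }
  vals <- as.matrix(records[genes])
  if (anyNA(vals)) abort("missing gene values in records")
  suggests <- sweep(vals, 2, rule$thresholds[genes], `<`)  # strict <
  n_pfb <- rowSums(suggests)
  needed <- switch(rule$mode,
                   all = length(genes),
                   majority = floor(length(genes) / 2) + 1,
                   any = 1L)
  out <- records
  out$n_suggest_pfb <- as.integer(n_pfb)
  out$prediction <- ifelse(n_pfb >= needed, "PFB", "PFA")
  out
}

#' @rdname predict_subgroup
#' @param object,newdata,... S3 method interface: `predict(rule, records)`.
#' @export
predict.threshold_rule <- function(object, newdata, ...) {
  predict_subgroup(newdata, object)
}

#' Confusion matrix with PFB as the positive class
#'
#' @param truth,prediction Equal-length vectors of labels in
#'   `{"PFA","PFB"}`.
#' @param positive Positive class (default `"PFB"`, the class the threshold
#'   rules call).
#' @return Object of class `confusion_matrix` with counts `tp`, `fp`, `tn`,
#'   `fn` and derived `sensitivity` and `specificity` (`NA` when undefined,
#'   never 0).
#' @export
confusion_matrix <- function(truth, prediction, positive = "PFB") {
  if (length(truth) != length(prediction)) {
    abort("truth and prediction must have equal length")
  }
  labs <- c("PFA", "PFB")
  if (!all(truth %in% labs) || !all(prediction %in% labs)) {
    abort("labels must be PFA or PFB")
  }
  pos <- positive
  tp <- sum(truth == pos & prediction == pos)
  fp <- sum(truth != pos & prediction == pos)
  tn <- sum(truth != pos & prediction != pos)
  fn <- sum(truth == pos & prediction != pos)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn, positive = pos,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> positive = ", x$positive, "\n", sep = "")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c(x$positive, "other"),
                              predicted = c(x$positive, "other")))
  print(m)
  cat("sensitivity = ", signif(x$sensitivity, 4),
      ", specificity = ", signif(x$specificity, 4), "\n", sep = "")
  invisible(x)
}

#' Evaluate predictions against true labels
#'
#' Convenience wrapper: runs [predict_subgroup()] and tabulates the result
#' against the records' `subgroup` labels.
#'
#' @inheritParams predict_subgroup
#' @return A [confusion_matrix()].
#' @export
evaluate_rule <- function(records, rule) {
  records <- normalize_panel_records(records)
  pred <- predict_subgroup(records, rule)
  confusion_matrix(pred$subgroup, pred$prediction)
}

#' Select the rule candidate by PFB specificity
#'
#' Replays each candidate on the training and validation sets and returns
#' the one maximizing, lexicographically: (1) the minimum of the two PFB
#' specificities, (2) their sum, (3) conservativeness of the mode (`all`
#' over `majority` over `any`, i.e. the mode that calls PFB least often).
#'
#' @param candidates List of `threshold_rule` objects.
#' @param train,validation Labeled gene-panel tibbles.
#' @return The winning `threshold_rule`, with an `evaluation` attribute
#'   holding the per-candidate specificity table.
#' @export
select_rule <- function(candidates, train, validation) {
  if (length(candidates) == 0) abort("no rule candidates supplied")
  mode_rank <- c(all = 1, majority = 2, any = 3)
  scores <- purrr::map_dfr(candidates, function(r) {
    sp_tr <- evaluate_rule(train, r)$specificity
    sp_va <- evaluate_rule(validation, r)$specificity
    if (is.na(sp_tr) || is.na(sp_va)) {
      abort("specificity undefined (no true-PFA cases in a partition)")
    }
    tibble::tibble(mode = r$mode, spec_train = sp_tr, spec_validation = sp_va)
  })
  ord <- order(-pmin(scores$spec_train, scores$spec_validation),
               -(scores$spec_train + scores$spec_validation),
               mode_rank[scores$mode])
  best <- candidates[[ord[1]]]
  attr(best, "evaluation") <- scores
  best
}

#' Train the three-gene PFB prediction rule end to end
#'
#' Splits labeled records 1:2 (stratified), fits per-gene per-class beta
#' distributions on the training third, derives likelihood-ratio
#' thresholds, builds the `all`/`majority`/`any` candidates, and selects
#' the rule with the highest PFB specificities on both partitions.
#'
#' @inheritParams stratified_split
#' @inheritParams fit_gene_panel
#' @return Object of class `pfb_classifier`: `split`, `fits`, `rule`,
#'   `candidates`, `confusion` (list with `train` and `validation`), and
#'   the settings used.
#' @export
train_pfb_classifier <- function(records, genes = panel_genes(),
                                 train_fraction = 1 / 3, seed = 1L,
                                 clip = 1e-3) {
  split <- stratified_split(records, train_fraction, seed)
  fits <- fit_gene_panel(split$train, genes, clip)
  candidates <- candidate_rules(fits)
  rule <- select_rule(candidates, split$train, split$validation)
  structure(
    list(split = split, fits = fits, candidates = candidates, rule = rule,
         confusion = list(train = evaluate_rule(split$train, rule),
                          validation = evaluate_rule(split$validation, rule)),
         settings = list(genes = genes, train_fraction = train_fraction,
                         seed = seed, clip = clip)),
    class = "pfb_classifier"
  )
}

#' @export
print.pfb_classifier <- function(x, ...) {
  cat("<pfb_classifier> trained on ", nrow(x$split$train), " / validated on ",
      nrow(x$split$validation), " samples\n", sep = "")
  print(x$rule)
  cat("training:   sens ", signif(x$confusion$train$sensitivity, 4),
      ", spec ", signif(x$confusion$train$specificity, 4), "\n", sep = "")
  cat("validation: sens ", signif(x$confusion$validation$sensitivity, 4),
      ", spec ", signif(x$confusion$validation$specificity, 4), "\n",
      sep = "")
  invisible(x)
}
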