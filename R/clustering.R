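#' Two-group hierarchical clustering of beta values
#'
#' Agglomerative clustering of samples on a marker-restricted beta-value
#' matrix: Euclidean distances between sample profiles, Ward linkage
#' (`hclust` method `"ward.D2"`), tree cut at `k` groups. Missing beta
#' values are imputed by the probe mean before distances are computed
#' (reported with a message). The result is deterministic for fixed input.
#'
#' @param beta Wide beta-value tibble (`probe_id` + one column per sample).
#' @param markers A `marker_set` (or character vector of probe ids) to
#'   restrict the matrix to, e.g. from [select_high_sd_island_probes()].
#' @param k Number of clusters to cut the tree at (default 2: PFA vs PFB).
#' @param linkage,metric Linkage method for [stats::hclust()] and distance
#'   metric for [stats::dist()]; recorded in the result's provenance.
#' @return A tibble of class `cluster_assignment` with columns `sample_id`
#'   and `cluster` (integers `1..k`), plus attributes `linkage`, `metric`,
#'   `k`, `hclust` (the dendrogram) and `marker_ids`.
#' @export
hierarchical_cluster <- function(beta, markers, k = 2,
                                 linkage = "ward.D2", metric = "euclidean") {
  ids <- marker_ids(markers)
  if (length(ids) == 0) abort("marker set is empty")
  m <- wide_to_matrix(beta)
  m <- m[rownames(m) %in% ids, , drop = FALSE]
  if (nrow(m) == 0) abort("no marker probes found in the beta matrix")
  if (ncol(m) < k) abort(paste0("k = ", k, " exceeds the number of samples"))
  n_missing <- sum(is.na(m))
  if (n_missing > 0) {
    inform(paste0(n_missing, " missing beta value(s) imputed by probe mean"))
    mu <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 1]]
  }
  hc <- hclust(dist(t(m), method = metric), method = linkage)
  cl <- cutree(hc, k = k)
  out <- tibble::tibble(sample_id = colnames(m), cluster = unname(cl))
  attr(out, "linkage") <- linkage
  attr(out, "metric") <- metric
  attr(out, "k") <- k
  attr(out, "hclust") <- hc
  attr(out, "marker_ids") <- intersect(ids, rownames(m))
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' Label the two clusters as PFA and PFB
#'
#' PFA tumors carry increased CpG-island methylation, so of the two clusters
#' the one with the higher mean beta over the marker probes is labeled PFA
#' and the other PFB. The labeling depends only on cluster membership and
#' marker methylation, so it is invariant to sample order, probe order and
#' to how the two cluster indices were numbered.
#'
#' @param assignment A `cluster_assignment` from [hierarchical_cluster()]
#'   with exactly two clusters.
#' @param beta The beta-value tibble the clustering was computed on.
#' @param markers Marker set used for the mean (usually the clustering set).
#' @return The assignment tibble with a `subgroup` column added and a
#'   `cluster_means` attribute (named mean marker beta per cluster).
#' @export
assign_subgroup_labels <- function(assignment, beta, markers) {
  clusters <- sort(unique(assignment$cluster))
  if (length(clusters) != 2) {
    abort("subgroup labeling requires exactly two clusters")
  }
  ids <- marker_ids(markers)
  m <- wide_to_matrix(beta)
  m <- m[rownames(m) %in% ids, assignment$sample_id, drop = FALSE]
  means <- vapply(clusters, function(cl) {
    cols <- which(assignment$cluster == cl)
    mean(m[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(1))
  names(means) <- as.character(clusters)
  if (isTRUE(all.equal(means[1], means[2], check.attributes = FALSE))) {
    abort("cluster mean marker methylation is equal; subgroup labels unresolved")
  }
  pfa_cluster <- clusters[which.max(means)]
  out <- assignment
  out$subgroup <- ifelse(out$cluster == pfa_cluster, "PFA", "PFB")
  attr(out, "cluster_means") <- means
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", nrow(x), " samples, k = ", attr(x, "k"),
      " (", attr(x, "linkage"), " linkage, ", attr(x, "metric"),
      " distance)\n", sep = "")
  NextMethod()
}
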