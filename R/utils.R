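# Internal helpers shared across modules.

# Deterministic per-block sub-seed so that adding a generated data block
# never perturbs draws of earlier blocks. Kept below 2^31 - 1.
derive_seed <- function(seed, block) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(as.double(seed)) * 48271 + block * 9973) %% 2147483646) + 1L
}

with_block_seed <- function(seed, block, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, block))
  force(expr)
}

valid_chromosomes <- function() c(paste0("chr", 1:22), "chrX", "chrY")

assert_chromosomes <- function(chrom) {
  bad <- setdiff(unique(chrom), valid_chromosomes())
  if (length(bad) > 0) {
    abort(paste0(
      "unknown chromosome label(s): ", paste(head(bad, 5), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

# Wide beta/intensity tibble (probe_id + one column per sample) -> matrix.
wide_to_matrix <- function(x, id_col = "probe_id") {
  stopifnot(id_col %in% names(x))
  ids <- x[[id_col]]
  if (anyDuplicated(ids) > 0) abort("duplicate probe identifiers")
  m <- as.matrix(x[setdiff(names(x), id_col)])
  rownames(m) <- ids
  m
}

matrix_to_wide <- function(m, id_col = "probe_id") {
  out <- tibble::tibble(rownames(m) %||% character(nrow(m)))
  names(out) <- id_col
  dplyr::bind_cols(out, tibble::as_tibble(m, .name_repair = "minimal"))
}

# A marker set is a tibble of probes carrying a free-text record of the
# rule that produced it.
new_marker_set <- function(tbl, criterion) {
  if (anyDuplicated(tbl$probe_id) > 0) abort("duplicate probes in marker set")
  attr(tbl, "criterion") <- criterion
  class(tbl) <- c("marker_set", class(tbl))
  tbl
}

marker_ids <- function(markers) {
  if (is.character(markers)) return(markers)
  if (is.data.frame(markers)) return(markers$probe_id)
  abort("markers must be a character vector or a tibble with a probe_id column")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("<marker_set> ", nrow(x), " probes\n", sep = "")
  crit <- attr(x, "criterion")
  if (!is.null(crit)) cat("criterion: ", crit, "\n", sep = "")
  NextMethod()
}
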