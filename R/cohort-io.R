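#' Write and read a cohort as delimited files
#'
#' `write_cohort()` emits the plain-text files every other stage reads:
#' `beta_matrix.tsv`, `probe_annotation.tsv`, `intensities_meth.tsv`,
#' `intensities_unmeth.tsv` (wide, `probe_id` first column),
#' `sample_sheet.csv`, `gene_panel.csv` and `ihc.csv`. `read_cohort()`
#' reverses it; the pair round-trips a generated cohort losslessly (readr
#' writes doubles with shortest round-trip precision).
#'
#' @param cohort A `synthetic_cohort` (or a compatible list of tibbles).
#' @param dir Directory to write to / read from; created if absent.
#' @return `write_cohort()` returns the file paths invisibly;
#'   `read_cohort()` returns a `synthetic_cohort`-like list (without the
#'   generator `config`).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", dir))
  }
  paths <- cohort_paths(dir)
  readr::write_tsv(cohort$beta, paths$beta)
  readr::write_tsv(cohort$annotation, paths$annotation)
  readr::write_tsv(cohort$intensities$meth, paths$meth)
  readr::write_tsv(cohort$intensities$unmeth, paths$unmeth)
  readr::write_csv(cohort$sample_sheet, paths$sample_sheet)
  readr::write_csv(cohort$gene_panel, paths$gene_panel)
  readr::write_csv(cohort$ihc, paths$ihc)
  invisible(unlist(paths))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  paths <- cohort_paths(dir)
  missing <- !file.exists(unlist(paths))
  if (any(missing)) {
    abort(paste0("missing cohort file(s): ",
                 paste(basename(unlist(paths))[missing], collapse = ", ")))
  }
  ann_cols <- readr::cols(
    probe_id = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), arm = readr::col_character(),
    cpg_island = readr::col_logical(), is_marker = readr::col_logical()
  )
  wide_cols <- readr::cols(probe_id = readr::col_character(),
                           .default = readr::col_double())
  structure(
    list(
      sample_sheet = readr::read_csv(
        paths$sample_sheet, show_col_types = FALSE,
        col_types = readr::cols(sample_id = readr::col_character(),
                                subgroup = readr::col_character(),
                                age = readr::col_double(),
                                has_1q_gain = readr::col_logical())
      ),
      annotation = readr::read_tsv(paths$annotation, col_types = ann_cols),
      beta = readr::read_tsv(paths$beta, col_types = wide_cols),
      intensities = list(
        meth = readr::read_tsv(paths$meth, col_types = wide_cols),
        unmeth = readr::read_tsv(paths$unmeth, col_types = wide_cols)
      ),
      gene_panel = readr::read_csv(
        paths$gene_panel, show_col_types = FALSE,
        col_types = readr::cols(sample_id = readr::col_character(),
                                subgroup = readr::col_character(),
                                .default = readr::col_double())
      ),
      ihc = readr::read_csv(
        paths$ihc, show_col_types = FALSE,
        col_types = readr::cols(sample_id = readr::col_character(),
                                percent_labeled = readr::col_double(),
                                control_ok = readr::col_logical())
      )
    ),
    class = "synthetic_cohort"
  )
}

cohort_paths <- function(dir) {
  list(
    beta = file.path(dir, "beta_matrix.tsv"),
    annotation = file.path(dir, "probe_annotation.tsv"),
    meth = file.path(dir, "intensities_meth.tsv"),
    unmeth = file.path(dir, "intensities_unmeth.tsv"),
    sample_sheet = file.path(dir, "sample_sheet.csv"),
    gene_panel = file.path(dir, "gene_panel.csv"),
    ihc = file.path(dir, "ihc.csv")
  )
}
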