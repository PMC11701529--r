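## End-to-end report: reproduce the standard clonal-analysis table set from
## a clone matrix (plus optional expression data) in one deterministic call.

#' Run the full clonal-analysis report
#'
#' From a clone matrix, emits the standard result tables: clone sizes,
#' per-cell-type barcode statistics, the fate map, fate-bias calls and
#' their summary, the lineage correlation matrix and its Newick dendrogram.
#' When a count matrix, cell metadata and a bias contrast are supplied, a
#' fate-bias differential table is added. Reruns with identical inputs are
#' bit-reproducible; on any stage failure the partial output directory is
#' removed.
#'
#' @param clone_matrix a [clone_matrix()] or a path readable by
#'   [read_clone_matrix()].
#' @param out_dir output directory (created if needed).
#' @param counts optional `count_matrix` for the differential stage.
#' @param cells optional cell metadata data frame (`cell_id`, `cell_type`,
#'   `clone_id`) for the differential stage.
#' @param cell_type,bias_a,bias_b differential contrast (see
#'   [fate_bias_diff()]); all three must be given to run that stage.
#' @param alpha fate-bias FDR threshold; default 0.05.
#' @param p_cut,lfc_cut differential significance thresholds.
#' @param targets optional named list of target label sets for
#'   [clone_fate_bias()].
#' @param verbose log the effective settings and stage progress to stderr.
#' @return named character vector of written file paths, invisibly.
#' @export
run_report <- function(clone_matrix, out_dir, counts = NULL, cells = NULL,
                       cell_type = NULL, bias_a = NULL, bias_b = NULL,
                       alpha = 0.05, p_cut = 0.05, lfc_cut = 0.5,
                       targets = NULL, verbose = TRUE) {
  log <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  if (is.character(clone_matrix)) clone_matrix <- read_clone_matrix(clone_matrix)
  stopifnot(inherits(clone_matrix, "clone_matrix"))
  fresh <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_result_table(df, path)
    written[[name]] <<- path
  }
  log("run_report: %d clones x %d cell types; alpha=%g p_cut=%g lfc_cut=%g",
      nrow(clone_matrix), ncol(clone_matrix), alpha, p_cut, lfc_cut)
  stage <- "clone_sizes"
  tryCatch({
    emit(clone_sizes(clone_matrix), "clone_sizes.tsv")
    emit(barcode_statistics(clone_matrix), "barcode_statistics.tsv")

    stage <- "fate_mapping"
    fm <- fate_mapping(clone_matrix)
    emit(data.frame(clone_id = rownames(fm), unclass(fm),
                    check.names = FALSE), "fate_map.tsv")

    stage <- "clone_fate_bias"
    fb <- clone_fate_bias(clone_matrix, targets = targets, alpha = alpha)
    emit(fb$calls, "fate_bias_calls.tsv")
    emit(summarize_fate_bias(fb), "fate_bias_summary.tsv")

    stage <- "lineage_relationship"
    lc <- suppressWarnings(lineage_relationship(clone_matrix))
    emit(data.frame(cell_type = lc$labels, lc$rho, check.names = FALSE),
         "lineage_correlation.tsv")
    nwk <- file.path(out_dir, "lineage_tree.nwk")
    writeLines(lineage_tree(lc), nwk)
    written[["lineage_tree.nwk"]] <- nwk

    if (!is.null(counts) && !is.null(cells) && !is.null(cell_type) &&
        !is.null(bias_a) && !is.null(bias_b)) {
      stage <- "fate_bias_diff"
      log("differential stage: %s, %s vs %s", cell_type, bias_a, bias_b)
      dr <- fate_bias_diff(counts, cells, fb, cell_type, bias_a, bias_b,
                           p_cut = p_cut, lfc_cut = lfc_cut)
      emit(dr, "fate_bias_diff.tsv")
    } else {
      log("differential stage skipped (no counts/cells/contrast supplied)")
    }
  }, error = function(e) {
    unlink(unlist(written))
    if (fresh) unlink(out_dir, recursive = TRUE)
    .stopf("run_report failed at stage '%s': %s", stage, conditionMessage(e))
  })
  log("run_report: wrote %d files to %s", length(written), out_dir)
  invisible(unlist(written))
}
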