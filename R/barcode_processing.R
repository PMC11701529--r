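## Barcode resolution and clone-level quality metrics. scLT assays sometimes
## attach several barcodes to one cell index (sequencing error, ambient
## barcodes, true multi-infection); a dominance policy resolves each cell to
## at most one clone before any clonal statistic is computed.

#' Barcode resolution policy
#'
#' A cell carrying several barcodes is kept only when its top barcode clearly
#' dominates: top count >= `min_dominance` x second count and top count >=
#' `min_count`. Single-barcode cells are kept whenever the count reaches
#' `min_count`.
#'
#' @param min_dominance required top/second count ratio, >= 1; default 2.
#' @param min_count minimum count of the winning barcode, >= 1; default 1.
#' @return list of class `resolution_policy`.
#' @export
resolution_policy <- function(min_dominance = 2, min_count = 1) {
  if (!is.numeric(min_dominance) || min_dominance < 1)
    .stopf("min_dominance must be >= 1")
  if (!is.numeric(min_count) || min_count < 1)
    .stopf("min_count must be >= 1")
  structure(list(min_dominance = min_dominance,
                 min_count = as.integer(min_count)),
            class = "resolution_policy")
}

#' Resolve raw barcode-cell assignments to unique clones
#'
#' @param assignments data frame with columns `cell_id`, `barcode_id`,
#'   `count` (one row per cell x barcode observation; counts >= 1; barcodes
#'   distinct within a cell).
#' @param policy a [resolution_policy()].
#' @return data frame (`cell_id`, `barcode_id`) with one row per kept cell,
#'   in first-appearance order of the input cells. Cells failing the
#'   dominance rule are dropped. The result is independent of input row
#'   order; exact count ties for the top barcode fail dominance unless
#'   `min_dominance == 1`, in which case the lexicographically smallest
#'   barcode wins.
#' @export
resolve_barcodes <- function(assignments, policy = resolution_policy()) {
  stopifnot(inherits(policy, "resolution_policy"), is.data.frame(assignments))
  for (col in c("cell_id", "barcode_id", "count"))
    if (is.null(assignments[[col]]))
      .stopf("assignments is missing column '%s'", col)
  if (nrow(assignments) == 0L) .stopf("empty assignment table")
  cnt <- assignments$count
  if (any(!is.finite(cnt)) || any(cnt < 1) || any(cnt != round(cnt)))
    .stopf("assignment counts must be integers >= 1")
  cid <- as.character(assignments$cell_id)
  bid <- as.character(assignments$barcode_id)
  if (anyDuplicated(paste0(cid, "\r", bid)))
    .stopf("duplicate barcode within a cell")
  # order within cell by count desc then barcode id, take top two per cell
  ord <- order(match(cid, unique(cid)), -cnt, bid)
  cid <- cid[ord]; bid <- bid[ord]; cnt <- cnt[ord]
  first <- !duplicated(cid)
  top_count <- cnt[first]
  top_barcode <- bid[first]
  # second entry per cell: first occurrence among the non-top rows
  rest <- which(!first)
  second_of <- rest[!duplicated(cid[rest])]
  second_count <- rep(0, sum(first))
  second_count[match(cid[second_of], cid[first])] <- cnt[second_of]
  keep <- top_count >= policy$min_count &
    top_count >= policy$min_dominance * second_count
  data.frame(cell_id = cid[first][keep], barcode_id = top_barcode[keep],
             stringsAsFactors = FALSE)
}

#' Filter high-confidence clones
#'
#' Barcodes that label more than one cell at the initial barcoding stage
#' cannot mark the descendants of a single progenitor and are removed before
#' clonal analysis. Filtering requires explicit initial-stage cell counts:
#' without them the matrix is returned unchanged, since late time points
#' alone cannot distinguish a large clone from a multi-progenitor barcode.
#'
#' @param clone_matrix a [clone_matrix()].
#' @param initial_counts named integer vector, initial-stage cell count per
#'   clone id; must cover every clone in the matrix. `NULL` (default) skips
#'   filtering.
#' @param max_initial_cells clones with more initial cells than this are
#'   dropped; default 1 (true single-progenitor clones).
#' @return the filtered [clone_matrix()].
#' @export
filter_high_confidence <- function(clone_matrix, initial_counts = NULL,
                                   max_initial_cells = 1) {
  stopifnot(inherits(clone_matrix, "clone_matrix"))
  if (is.null(initial_counts)) return(clone_matrix)
  ids <- rownames(clone_matrix)
  unknown <- setdiff(names(initial_counts), ids)
  if (length(unknown) > 0L)
    .stopf("initial_counts has unknown clone id: %s", unknown[1L])
  missing <- setdiff(ids, names(initial_counts))
  if (length(missing) > 0L)
    .stopf("initial_counts does not cover clone id: %s", missing[1L])
  keep <- initial_counts[ids] <= max_initial_cells
  if (!any(keep)) .stopf("no clone passes the initial-stage filter")
  out <- clone_matrix[keep, , drop = FALSE]
  class(out) <- class(clone_matrix)
  out
}

#' Barcode detection quality summary
#'
#' @param cells data frame of cell records (one row per assayed cell, column
#'   `cell_id`).
#' @param resolved resolved barcode map: data frame (`cell_id`,
#'   `barcode_id`) from [resolve_barcodes()], or a named character vector.
#' @return list of class `quality_summary`: `n_cells`, `n_barcoded_cells`,
#'   `n_unique_barcodes`, `detection_rate` (= barcoded / assayed cells).
#' @export
quality_summary <- function(cells, resolved) {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) == 0L) .stopf("no cells")
  if (is.data.frame(resolved)) {
    keys <- as.character(resolved$cell_id)
    bcs <- as.character(resolved$barcode_id)
  } else {
    keys <- names(resolved)
    bcs <- as.character(resolved)
  }
  if (!all(keys %in% as.character(cells$cell_id)))
    .stopf("resolved map contains cell ids absent from the cell table")
  structure(list(n_cells = nrow(cells),
                 n_barcoded_cells = length(keys),
                 n_unique_barcodes = length(unique(bcs)),
                 detection_rate = length(keys) / nrow(cells)),
            class = "quality_summary")
}

#' @export
print.quality_summary <- function(x, ...) {
  cat(sprintf(paste0("quality_summary: %d cells, %d barcoded (detection rate",
                     " %.3f), %d unique barcodes\n"),
              x$n_cells, x$n_barcoded_cells, x$detection_rate,
              x$n_unique_barcodes))
  invisible(x)
}

#' Clone sizes
#'
#' Clone size is the number of cells carrying the same clonal barcode (the
#' row sum of the clone matrix); `n_cell_types` counts the labels in which
#' the clone was observed.
#'
#' @param clone_matrix a [clone_matrix()].
#' @return data frame (`clone_id`, `size`, `n_cell_types`) sorted by
#'   descending size, ties broken lexicographically on clone id.
#' @export
clone_sizes <- function(clone_matrix) {
  stopifnot(inherits(clone_matrix, "clone_matrix"))
  size <- rowSums(clone_matrix)
  df <- data.frame(clone_id = rownames(clone_matrix),
                   size = as.integer(size),
                   n_cell_types = as.integer(rowSums(clone_matrix > 0)),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$size, df$clone_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-cell-type barcode statistics
#'
#' @param clone_matrix a [clone_matrix()].
#' @return data frame (`cell_type`, `n_unique_barcodes`, `n_barcoded_cells`):
#'   per column, the number of clones observed there and the total barcoded
#'   cells.
#' @export
barcode_statistics <- function(clone_matrix) {
  stopifnot(inherits(clone_matrix, "clone_matrix"))
  data.frame(cell_type = colnames(clone_matrix),
             n_unique_barcodes = as.integer(colSums(clone_matrix > 0)),
             n_barcoded_cells = as.integer(colSums(clone_matrix)),
             stringsAsFactors = FALSE)
}
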