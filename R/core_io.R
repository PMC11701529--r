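## Domain containers and readers/writers for every external format the
## pipeline touches: clone matrices (TSV/CSV), count matrices (MTX + name
## files), peak regions (BED), motifs (JASPAR/MEME), FASTA via Biostrings.

#' Construct a clone matrix
#'
#' A clone matrix is the central object of clonal analysis: an integer matrix
#' of cell counts with one row per clone (lineage barcode) and one column per
#' cell type (or other grouping label such as time point). Row sums are clone
#' sizes; the rows are the "barcode signatures" used for fate-bias testing and
#' lineage-relationship inference.
#'
#' All-zero rows carry no information (a clone with no observed cells) and are
#' dropped with a warning, so a valid `clone_matrix` never contains one.
#'
#' @param counts integer matrix (or coercible) of non-negative cell counts,
#'   clones in rows, labels in columns.
#' @param clone_ids,column_labels row / column identifiers; default to the
#'   dimnames of `counts`. Must be unique.
#' @return an integer matrix of class `"clone_matrix"`.
#' @seealso [read_clone_matrix()], [build_clone_matrix()]
#' @export
clone_matrix <- function(counts, clone_ids = rownames(counts),
                         column_labels = colnames(counts)) {
  m <- as.matrix(counts)
  if (is.null(clone_ids) || is.null(column_labels))
    .stopf("clone_matrix needs clone ids and column labels")
  if (anyDuplicated(clone_ids))
    .stopf("duplicate clone id: %s", clone_ids[duplicated(clone_ids)][1L])
  if (anyDuplicated(column_labels))
    .stopf("duplicate column label: %s",
           column_labels[duplicated(column_labels)][1L])
  if (!is.numeric(m) || any(!is.finite(m)))
    .stopf("clone matrix entries must be finite numbers")
  if (any(m < 0) || any(m != round(m)))
    .stopf("clone matrix entries must be non-negative integers")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(clone_ids, column_labels)
  zero <- rowSums(m) == 0L
  if (any(zero)) {
    .warnf("dropping %d all-zero clone row(s): %s", sum(zero),
           paste(utils::head(clone_ids[zero], 5L), collapse = ", "))
    m <- m[!zero, , drop = FALSE]
  }
  if (nrow(m) == 0L) .stopf("clone matrix has no non-empty clone")
  class(m) <- c("clone_matrix", class(m))
  m
}

#' @export
print.clone_matrix <- function(x, ...) {
  cat(sprintf("clone_matrix: %d clones x %d labels, %d cells\n",
              nrow(x), ncol(x), sum(x)))
  y <- x
  class(y) <- "matrix"
  print(utils::head(y, 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more clones\n", nrow(x) - 10L))
  invisible(x)
}

#' Read a clone matrix from a delimited file
#'
#' Expects a header row of column labels and a first column of clone ids.
#' Tab- and comma-separated files are both accepted; [write_clone_matrix()]
#' always writes tabs. All-zero rows are dropped with a warning.
#'
#' @param path file path.
#' @return a [clone_matrix()].
#' @export
read_clone_matrix <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl(",", header) && !grepl("\t", header)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) .stopf("%s: need a clone-id column plus count columns", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    .stopf("%s: duplicate clone id '%s'", path, ids[duplicated(ids)][1L])
  labs <- colnames(df)[-1L]
  vals <- suppressWarnings(
    vapply(df[-1L], function(col) as.numeric(col), numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, labs))
  bad <- which(is.na(vals) | vals < 0 | vals != round(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    .stopf("%s: non-integer or negative count at clone '%s', column '%s'",
           path, ids[bad[1L, 1L]], labs[bad[1L, 2L]])
  clone_matrix(vals)
}

#' Write a clone matrix as TSV
#'
#' @param x a [clone_matrix()].
#' @param path output path; first column is `clone_id`, then one column per
#'   label, tab-separated.
#' @return `path`, invisibly.
#' @export
write_clone_matrix <- function(x, path) {
  stopifnot(inherits(x, "clone_matrix"))
  df <- data.frame(clone_id = rownames(x),
                   unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a clone matrix from clone-assigned cells
#'
#' Tabulates cells per clone and per grouping label. Category order is
#' first-appearance order in the input, preserved in the output for
#' determinism.
#'
#' @param cells data frame of cell records with columns `cell_id`, `clone_id`
#'   and the grouping column (`cell_type` or `group`). Cells with `NA`
#'   `clone_id` are ignored.
#' @param by grouping column: `"cell_type"` (default) or `"group"`.
#' @return a [clone_matrix()]; its grand total equals the number of
#'   clone-assigned input cells.
#' @export
build_clone_matrix <- function(cells, by = c("cell_type", "group")) {
  by <- match.arg(by)
  stopifnot(is.data.frame(cells))
  for (col in c("cell_id", "clone_id", by))
    if (is.null(cells[[col]])) .stopf("cells is missing column '%s'", col)
  keep <- !is.na(cells$clone_id)
  if (!any(keep)) .stopf("no clone-assigned cells")
  cl <- as.character(cells$clone_id[keep])
  lab <- as.character(cells[[by]][keep])
  if (anyNA(lab)) .stopf("missing '%s' label on a clone-assigned cell", by)
  tab <- table(factor(cl, levels = unique(cl)),
               factor(lab, levels = unique(lab)))
  clone_matrix(unclass(tab))
}

#' Read / write a sparse count matrix (MatrixMarket + name files)
#'
#' Counts are stored as features x cells MatrixMarket sparse matrices with
#' one-id-per-line feature and cell name files, the standard single-cell
#' exchange layout.
#'
#' @param mtx path to the `.mtx` file.
#' @param features,cells paths to the row / column name files.
#' @param modality `"rna"` (gene-by-cell) or `"atac"` (peak-by-cell).
#' @return a `count_matrix`: list with `values` (sparse dgCMatrix with
#'   dimnames), `feature_ids`, `cell_ids`, `modality`.
#' @export
read_count_matrix <- function(mtx, features, cells,
                              modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  fid <- readLines(features)
  cid <- readLines(cells)
  if (length(fid) != nrow(m))
    .stopf("%s: %d feature names for %d rows", features, length(fid), nrow(m))
  if (length(cid) != ncol(m))
    .stopf("%s: %d cell names for %d columns", cells, length(cid), ncol(m))
  if (any(m@x < 0) || any(!is.finite(m@x)))
    .stopf("%s: counts must be finite and non-negative", mtx)
  dimnames(m) <- list(fid, cid)
  structure(list(values = m, feature_ids = fid, cell_ids = cid,
                 modality = modality),
            class = "count_matrix")
}

#' @rdname read_count_matrix
#' @param x a `count_matrix`.
#' @param prefix output prefix: writes `<prefix>.mtx`,
#'   `<prefix>.features.txt`, `<prefix>.cells.txt`.
#' @export
write_count_matrix <- function(x, prefix) {
  stopifnot(inherits(x, "count_matrix"))
  Matrix::writeMM(x$values, paste0(prefix, ".mtx"))
  writeLines(x$feature_ids, paste0(prefix, ".features.txt"))
  writeLines(x$cell_ids, paste0(prefix, ".cells.txt"))
  invisible(prefix)
}

#' Read / write peak regions (BED)
#'
#' BED semantics throughout: 0-based half-open `[start, end)` coordinates;
#' strand is ignored (peaks are unstranded). Columns beyond the fourth are
#' ignored on read; a missing name column yields `peak_<line>` ids.
#'
#' @param path BED file path.
#' @return data frame of class `peak_regions` with columns `chrom`, `start`,
#'   `end`, `peak_id`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(#|track\\b|browser\\b)", lines)
  lines <- lines[keep]
  if (length(lines) == 0L) .stopf("%s: no records", path)
  parts <- strsplit(lines, "[ \t]+")
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (length(f) < 3L) .stopf("%s line %d: fewer than 3 fields", path, i)
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end))
      .stopf("%s line %d: non-integer coordinates", path, i)
    if (start < 0L || start >= end)
      .stopf("%s line %d: need 0 <= start < end", path, i)
    out[[i]] <- data.frame(
      chrom = f[1L], start = start, end = end,
      peak_id = if (length(f) >= 4L) f[4L] else sprintf("peak_%d", i))
  }
  df <- do.call(rbind, out)
  class(df) <- c("peak_regions", class(df))
  df
}

#' @rdname read_bed
#' @param regions a `peak_regions` data frame.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("chrom", "start", "end", "peak_id") %in% names(regions)))
  writeLines(sprintf("%s\t%d\t%d\t%s", regions$chrom,
                     as.integer(regions$start), as.integer(regions$end),
                     regions$peak_id), path)
  invisible(path)
}

#' Construct a position weight matrix
#'
#' @param motif_id identifier.
#' @param matrix 4 x L numeric matrix of per-position base probabilities (or
#'   counts, normalized on construction), rows in A, C, G, T order.
#' @param background length-4 background base probabilities; uniform default.
#' @return list of class `pwm` with probability columns summing to 1.
#' @export
pwm <- function(motif_id, matrix, background = rep(0.25, 4)) {
  m <- base::as.matrix(matrix)
  if (nrow(m) != 4L || ncol(m) < 1L) .stopf("PWM must be 4 x L with L >= 1")
  if (any(m < 0) || any(!is.finite(m))) .stopf("PWM entries must be >= 0")
  cs <- colSums(m)
  if (any(cs <= 0)) .stopf("PWM has an empty column")
  m <- sweep(m, 2L, cs, "/")
  background <- background / sum(background)
  rownames(m) <- c("A", "C", "G", "T")
  structure(list(motif_id = as.character(motif_id), matrix = m,
                 background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- paste(rownames(x$matrix)[apply(x$matrix, 2L, which.max)],
                collapse = "")
  cat(sprintf("pwm %s: length %d, consensus %s\n",
              x$motif_id, ncol(x$matrix), cons))
  invisible(x)
}

#' Read motifs from JASPAR or MEME text
#'
#' Both dialects are plain text: JASPAR uses `>ID name` headers with four
#' `A [ ... ]` count rows; MEME minimal format uses `MOTIF` blocks with a
#' `letter-probability matrix` section and an optional `Background letter
#' frequencies` line. Count matrices are normalized to probability columns.
#'
#' @param path motif file.
#' @param format `"auto"` (default, sniffed from content), `"jaspar"` or
#'   `"meme"`.
#' @return list of [pwm()] objects, named by motif id.
#' @export
read_motifs <- function(path, format = c("auto", "jaspar", "meme")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto")
    format <- if (any(grepl("^MEME version|^letter-probability matrix",
                            lines))) "meme" else "jaspar"
  if (format == "jaspar") .read_jaspar(lines, path) else .read_meme(lines, path)
}

.read_jaspar <- function(lines, path) {
  starts <- grep("^>", lines)
  if (length(starts) == 0L) .stopf("%s: no JASPAR '>' header found", path)
  out <- list()
  for (s in starts) {
    hdr <- sub("^>\\s*", "", lines[s])
    id <- strsplit(hdr, "[ \t]+")[[1L]][1L]
    rows <- lines[(s + 1L):min(s + 4L, length(lines))]
    if (length(rows) < 4L) .stopf("%s line %d: truncated JASPAR record", path, s)
    vals <- lapply(seq_along(rows), function(i) {
      r <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", rows[i])
      v <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1L]]))
      if (anyNA(v)) .stopf("%s line %d: malformed matrix row", path, s + i)
      v
    })
    if (length(unique(lengths(vals))) != 1L)
      .stopf("%s line %d: ragged JASPAR matrix", path, s)
    out[[id]] <- pwm(id, do.call(rbind, vals))
  }
  out
}

.read_meme <- function(lines, path) {
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) > 0L && bgl[1L] < length(lines)) {
    toks <- strsplit(trimws(lines[bgl[1L] + 1L]), "\\s+")[[1L]]
    v <- suppressWarnings(as.numeric(toks[c(FALSE, TRUE)]))
    if (length(v) == 4L && !anyNA(v)) bg <- v
  }
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L) .stopf("%s: no MEME 'MOTIF' block found", path)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(sub("^MOTIF", "", lines[s])), "\\s+")[[1L]][1L]
    lp <- s + grep("^letter-probability matrix",
                   lines[(s + 1L):length(lines)])[1L]
    if (is.na(lp)) .stopf("%s line %d: MOTIF without probability matrix", path, s)
    rows <- list()
    i <- lp + 1L
    while (i <= length(lines) && grepl("^\\s*[0-9.eE+-]", lines[i])) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
      if (length(v) != 4L || anyNA(v))
        .stopf("%s line %d: malformed probability row", path, i)
      rows[[length(rows) + 1L]] <- v
      i <- i + 1L
    }
    if (length(rows) == 0L) .stopf("%s line %d: empty probability matrix", path, lp)
    out[[id]] <- pwm(id, t(do.call(rbind, rows)), background = bg)
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pwms list of [pwm()] objects.
#' @param path output path.
#' @export
write_motifs <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- pwms[[1L]]$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       ncol(p$matrix)), con)
    apply(p$matrix, 2L, function(col)
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4]),
                 con))
    writeLines("", con)
  }
  invisible(path)
}

#' Write a result table as TSV
#'
#' Fixed column order, no quoting, floats at 6 significant digits — the
#' output dialect of every table the pipeline emits.
#'
#' @param df data frame.
#' @param path output path.
#' @export
write_result_table <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
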