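test_that("clone matrix reading validates, drops empty clones, round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clone_id\tT1\tT2", "c1\t2\t0", "c2\t1\t1", "c3\t0\t0"), path)
  expect_warning(cm <- read_clone_matrix(path), "all-zero")
  expect_identical(rownames(cm), c("c1", "c2"))
  expect_identical(unname(unclass(cm)[2, ]), c(1L, 1L))

  # comma dialect accepted on read
  pcsv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("clone_id,T1,T2", "c1,2,0", "c2,1,1"), pcsv)
  expect_identical(unclass(read_clone_matrix(pcsv)), unclass(cm))

  # round trip: write tab, read back, counts identical
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_clone_matrix(cm, p2)
  expect_identical(unclass(read_clone_matrix(p2)), unclass(cm))

  # duplicate clone id and bad cells are format errors naming the culprit
  pdup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clone_id\tT1", "c1\t2", "c1\t3"), pdup)
  expect_error(read_clone_matrix(pdup), "duplicate clone id 'c1'")
  pbad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clone_id\tT1\tT2", "c1\t2\t-1"), pbad)
  expect_error(read_clone_matrix(pbad), "clone 'c1', column 'T2'")
  pfrac <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clone_id\tT1", "c1\t1.5"), pfrac)
  expect_error(read_clone_matrix(pfrac), "non-integer")
})

test_that("build_clone_matrix counts clone-assigned cells and conserves totals", {
  cells <- data.frame(cell_id = paste0("cell", 1:4),
                      clone_id = c("c1", "c1", "c2", "c2"),
                      cell_type = c("T1", "T1", "T1", "T2"))
  cm <- build_clone_matrix(cells)
  expect_identical(unname(unclass(cm)),
                   matrix(c(2L, 1L, 0L, 1L), 2))
  expect_identical(rownames(cm), c("c1", "c2"))

  # by = "group" partitions with the identical logic
  cells$group <- cells$cell_type
  expect_identical(unclass(build_clone_matrix(cells, by = "group")),
                   unclass(cm))

  # conservation on a larger random set, NA clones ignored
  set.seed(11)
  n <- 500
  big <- data.frame(cell_id = sprintf("b%03d", 1:n),
                    clone_id = ifelse(runif(n) < 0.8,
                                      sprintf("cl%02d", sample(40, n, TRUE)),
                                      NA),
                    cell_type = sample(LETTERS[1:5], n, TRUE))
  expect_equal(sum(build_clone_matrix(big)), sum(!is.na(big$clone_id)))
  expect_error(build_clone_matrix(big[is.na(big$clone_id), ]),
               "no clone-assigned cells")
})

test_that("BED reader follows 0-based half-open semantics and flags bad lines", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tp1", "chr2\t0\t50\tp2"), path)
  bed <- read_bed(path)
  expect_identical(bed$start, c(100L, 0L))
  expect_identical(bed$end, c(200L, 50L))
  expect_identical(bed$peak_id, c("p1", "p2"))

  p2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(bed, p2)
  expect_identical(read_bed(p2), bed)

  pbad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tp1", "chr1\t300\t250\tp2"), pbad)
  expect_error(read_bed(pbad), "line 2")
  pshort <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100", pshort)
  expect_error(read_bed(pshort), "line 1")
})

test_that("MTX count matrices round-trip with all nonzeros preserved", {
  set.seed(3)
  m <- Matrix::rsparsematrix(30, 20, density = 0.2)
  m@x <- abs(round(m@x * 10))
  cm <- structure(list(values = methods::as(m, "CsparseMatrix"),
                       feature_ids = sprintf("g%02d", 1:30),
                       cell_ids = sprintf("c%02d", 1:20),
                       modality = "rna"), class = "count_matrix")
  dimnames(cm$values) <- list(cm$feature_ids, cm$cell_ids)
  prefix <- file.path(withr::local_tempdir(), "cnt")
  write_count_matrix(cm, prefix)
  back <- read_count_matrix(paste0(prefix, ".mtx"),
                            paste0(prefix, ".features.txt"),
                            paste0(prefix, ".cells.txt"))
  expect_equal(as.matrix(back$values), as.matrix(cm$values))
  expect_identical(back$modality, "rna")
  expect_error(read_count_matrix(paste0(prefix, ".mtx"),
                                 paste0(prefix, ".cells.txt"),
                                 paste0(prefix, ".cells.txt")),
               "feature names")
})

test_that("JASPAR and MEME motif parsing normalize to probability columns", {
  pj <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 test",
               "A [ 10  0  5 ]",
               "C [  0 10  5 ]",
               "G [  0  0  5 ]",
               "T [  0  0  5 ]"), pj)
  ms <- read_motifs(pj)
  expect_named(ms, "M1")
  expect_equal(colSums(ms$M1$matrix), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(ms$M1$matrix["A", 1]), 1)
  expect_equal(ms$M1$matrix[, 3], c(A = .25, C = .25, G = .25, T = .25))

  # MEME round trip through write_motifs preserves probabilities
  pm <- withr::local_tempfile(fileext = ".meme")
  write_motifs(ms, pm)
  back <- read_motifs(pm)
  expect_equal(back$M1$matrix, ms$M1$matrix, tolerance = 1e-5)
  expect_error(read_motifs(withr::local_tempfile(lines = "nonsense")),
               "no JASPAR")
})
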