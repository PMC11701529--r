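## Synthetic scLT experiment generator with a planted ground-truth ledger.
## Emulates a lentiviral-barcoding (LARRY-style) experiment: clones seeded
## in a progenitor pool, propagated multinomially into daughter cell types
## with a configurable fraction of fate-biased clones, barcode detection
## dropout, multi-barcode noise cells, NB expression counts with planted
## DE between bias groups, and peak sequences with a planted motif.

#' Simulation configuration
#'
#' Defaults emulate the demonstration experiment scale: HSPC progenitors
#' plus six mature haematopoietic types, ~2,000 clones (~10,000 cells),
#' 30% of clones fate-biased with 0.8 target occupancy, 80% barcode
#' detection.
#'
#' @param n_clones number of seeded clones.
#' @param clone_size_meanlog,clone_size_sdlog log-normal clone-size
#'   parameters (sizes rounded, minimum 1 cell).
#' @param cell_types named numeric vector of background cell-type
#'   proportions (normalized internally).
#' @param frac_biased_clones fraction of clones with a planted fate bias.
#' @param bias_strength target-type occupancy probability of biased clones,
#'   in (0, 1]; the remainder follows the background proportions of the
#'   other types.
#' @param detection_rate per-cell barcode detection probability.
#' @param frac_multibarcode_cells fraction of detected cells that also
#'   carry a second, weaker barcode (resolvable by the default dominance
#'   policy).
#' @param frac_multiprogenitor_barcodes fraction of barcodes that labelled
#'   two progenitors at the initial stage (removed by
#'   [filter_high_confidence()]).
#' @param n_genes,n_de_genes,de_log2fc,nb_dispersion RNA panel size, number
#'   of planted DE genes between the two largest bias groups, their
#'   absolute log2 fold change, and the NB dispersion (var = mu + disp *
#'   mu^2). `n_genes = 0` skips the expression stage.
#' @param n_motifs,n_regions_fg,n_regions_bg,region_length,motif_plant_fg,motif_plant_bg
#'   motif benchmark: number of PWMs (the first is planted), region counts
#'   and length, and the planting rates of the first motif's consensus in
#'   foreground / background regions. `n_motifs = 0` skips this stage.
#' @param seed integer seed (mandatory); all stages derive their own
#'   substream from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_clones = 2000,
                       clone_size_meanlog = 1.3,
                       clone_size_sdlog = 0.8,
                       cell_types = c(HSPC = 0.40, Mono = 0.15, Neu = 0.15,
                                      Ery = 0.10, Lymphoid = 0.10,
                                      Baso = 0.05, DC = 0.05),
                       frac_biased_clones = 0.3,
                       bias_strength = 0.8,
                       detection_rate = 0.8,
                       frac_multibarcode_cells = 0.05,
                       frac_multiprogenitor_barcodes = 0.05,
                       n_genes = 200, n_de_genes = 20, de_log2fc = 2,
                       nb_dispersion = 0.5,
                       n_motifs = 5, n_regions_fg = 50, n_regions_bg = 50,
                       region_length = 100,
                       motif_plant_fg = 0.8, motif_plant_bg = 0.1,
                       seed) {
  if (missing(seed)) .stopf("sim_config requires an explicit seed")
  if (!is.numeric(seed) || seed != round(seed) || abs(seed) >= 2^31 - 100)
    .stopf("seed must be an integer with |seed| < 2^31 - 100")
  fr <- c(frac_biased_clones, detection_rate, frac_multibarcode_cells,
          frac_multiprogenitor_barcodes, motif_plant_fg, motif_plant_bg)
  if (any(fr < 0) || any(fr > 1)) .stopf("fractions must lie in [0, 1]")
  if (detection_rate <= 0) .stopf("detection_rate must be > 0")
  if (bias_strength <= 0 || bias_strength > 1)
    .stopf("bias_strength must lie in (0, 1]")
  if (is.null(names(cell_types)) || any(cell_types < 0) ||
      sum(cell_types) <= 0)
    .stopf("cell_types must be a named vector of non-negative proportions")
  if (length(cell_types) < 2L && frac_biased_clones > 0)
    .stopf("fate bias needs at least 2 cell types")
  if (n_de_genes > n_genes) .stopf("n_de_genes exceeds n_genes")
  if (n_de_genes > 0 && frac_biased_clones == 0)
    .stopf("planted DE needs biased clones (frac_biased_clones > 0)")
  cfg <- list(n_clones = as.integer(n_clones),
              clone_size_meanlog = clone_size_meanlog,
              clone_size_sdlog = clone_size_sdlog,
              cell_types = cell_types / sum(cell_types),
              frac_biased_clones = frac_biased_clones,
              bias_strength = bias_strength,
              detection_rate = detection_rate,
              frac_multibarcode_cells = frac_multibarcode_cells,
              frac_multiprogenitor_barcodes = frac_multiprogenitor_barcodes,
              n_genes = as.integer(n_genes),
              n_de_genes = as.integer(n_de_genes),
              de_log2fc = de_log2fc, nb_dispersion = nb_dispersion,
              n_motifs = as.integer(n_motifs),
              n_regions_fg = as.integer(n_regions_fg),
              n_regions_bg = as.integer(n_regions_bg),
              region_length = as.integer(region_length),
              motif_plant_fg = motif_plant_fg,
              motif_plant_bg = motif_plant_bg,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# run fn under a stage-specific RNG substream, restoring the caller's RNG
.with_stage_seed <- function(seed, stage, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((seed + stage * 1000003L) %% (2^31 - 1))
  fn()
}

#' Simulate a complete scLT experiment
#'
#' Generates every input the pipeline consumes plus a ground-truth ledger:
#' raw barcode-cell assignments, cell metadata, the clone matrix of
#' detected cells, initial-stage barcode counts, an RNA count matrix with
#' planted DE genes between the two largest fate-bias groups, and a motif
#' benchmark (peaks BED, region FASTA-ready sequences, MEME motifs) with
#' one planted motif. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, all components are
#'   written as plain-text files (TSV, MTX, BED, FASTA, MEME) alongside the
#'   truth ledger.
#' @return list of class `sim_experiment`: `config`, `assignments`,
#'   `cells` (observable metadata), `clone_matrix`, `initial_counts`,
#'   `counts` (`count_matrix` or `NULL`), `regions`, `sequences`, `motifs`,
#'   and `truth` (list of `clones`, `cells`, `genes`, `regions`,
#'   `planted_motif`).
#' @export
simulate_experiment <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  types <- names(cfg$cell_types)

  ## stage 1: clone truth ----------------------------------------------
  clones <- .with_stage_seed(cfg$seed, 1L, function() {
    size <- pmax(1L, as.integer(round(stats::rlnorm(
      cfg$n_clones, cfg$clone_size_meanlog, cfg$clone_size_sdlog))))
    n_biased <- floor(cfg$frac_biased_clones * cfg$n_clones)
    biased <- rep(FALSE, cfg$n_clones)
    biased[sample.int(cfg$n_clones, n_biased)] <- TRUE
    target <- rep(NA_character_, cfg$n_clones)
    target[biased] <- sample(types, sum(biased), replace = TRUE)
    n_multi <- floor(cfg$frac_multiprogenitor_barcodes * cfg$n_clones)
    multi <- rep(FALSE, cfg$n_clones)
    multi[sample.int(cfg$n_clones, n_multi)] <- TRUE
    data.frame(clone_id = sprintf("clone_%04d", seq_len(cfg$n_clones)),
               size = size, biased = biased, target = target,
               multiprogenitor = multi, stringsAsFactors = FALSE)
  })
  initial_counts <- stats::setNames(1L + clones$multiprogenitor,
                                    clones$clone_id)

  ## stage 2: cells (multinomial propagation into cell types) ----------
  cells_truth <- .with_stage_seed(cfg$seed, 2L, function() {
    type_of <- unlist(lapply(seq_len(nrow(clones)), function(i) {
      pr <- cfg$cell_types
      if (clones$biased[i]) {
        tg <- clones$target[i]
        pr[] <- (1 - cfg$bias_strength) * pr / sum(pr[types != tg])
        pr[tg] <- cfg$bias_strength
      }
      sample(types, clones$size[i], replace = TRUE, prob = pr)
    }))
    n <- length(type_of)
    data.frame(cell_id = sprintf("cell_%05d", seq_len(n)),
               clone_id = rep(clones$clone_id, clones$size),
               cell_type = type_of, stringsAsFactors = FALSE)
  })

  ## stage 3: detection dropout and multi-barcode noise -----------------
  det <- .with_stage_seed(cfg$seed, 3L, function() {
    n <- nrow(cells_truth)
    detected <- stats::runif(n) < cfg$detection_rate
    primary_count <- 2L + stats::rpois(n, 3)
    multib <- detected & stats::runif(n) < cfg$frac_multibarcode_cells
    second_clone <- rep(NA_character_, n)
    second_count <- rep(NA_integer_, n)
    if (any(multib)) {
      second_clone[multib] <- sample(clones$clone_id, sum(multib),
                                     replace = TRUE)
      # weaker than half the primary: resolvable under the default policy
      second_count[multib] <- vapply(primary_count[multib], function(pc)
        sample.int(max(1L, pc %/% 2L), 1L), integer(1))
    }
    list(detected = detected, primary_count = primary_count,
         multibarcode = multib, second_clone = second_clone,
         second_count = second_count)
  })
  cells_truth$detected <- det$detected
  cells_truth$multibarcode <- det$multibarcode

  prim <- data.frame(cell_id = cells_truth$cell_id[det$detected],
                     barcode_id = cells_truth$clone_id[det$detected],
                     count = det$primary_count[det$detected],
                     stringsAsFactors = FALSE)
  mb <- which(det$multibarcode & det$second_clone != cells_truth$clone_id)
  sec <- data.frame(cell_id = cells_truth$cell_id[mb],
                    barcode_id = det$second_clone[mb],
                    count = det$second_count[mb],
                    stringsAsFactors = FALSE)
  assignments <- rbind(prim, sec)
  assignments <- assignments[order(match(assignments$cell_id,
                                         cells_truth$cell_id),
                                   assignments$barcode_id), ]
  rownames(assignments) <- NULL

  cells <- data.frame(cell_id = cells_truth$cell_id,
                      cell_type = cells_truth$cell_type,
                      sample = "S1", group = "t1",
                      stringsAsFactors = FALSE)

  obs <- cells_truth[cells_truth$detected, , drop = FALSE]
  cm <- build_clone_matrix(obs, by = "cell_type")

  ## stage 4: RNA counts with planted DE between bias groups ------------
  counts <- NULL
  genes_truth <- NULL
  if (cfg$n_genes > 0L) {
    res <- .with_stage_seed(cfg$seed, 4L, function() {
      base_mu <- stats::rgamma(cfg$n_genes, shape = 2, rate = 0.5) + 0.5
      gene_id <- sprintf("gene_%04d", seq_len(cfg$n_genes))
      tg_tab <- sort(table(clones$target), decreasing = TRUE)
      g <- data.frame(gene_id = gene_id, base_mean = base_mu,
                      de = FALSE, log2fc = 0,
                      up_in = NA_character_, stringsAsFactors = FALSE)
      t1 <- t2 <- NULL
      if (cfg$n_de_genes > 0L) {
        if (length(tg_tab) < 2L)
          .stopf("planted DE needs clones biased toward >= 2 targets")
        t1 <- names(tg_tab)[1L]; t2 <- names(tg_tab)[2L]
        de_idx <- seq_len(cfg$n_de_genes)
        g$de[de_idx] <- TRUE
        half <- de_idx <= cfg$n_de_genes / 2
        g$up_in[de_idx] <- ifelse(half[de_idx], t1, t2)
        g$log2fc[de_idx] <- cfg$de_log2fc
      }
      keep <- cells_truth$detected
      cl <- match(cells_truth$clone_id[keep], clones$clone_id)
      cell_target <- ifelse(clones$biased[cl], clones$target[cl], "none")
      nc <- sum(keep)
      mu <- matrix(rep(base_mu, nc), nrow = cfg$n_genes)
      if (cfg$n_de_genes > 0L) {
        for (side in c(t1, t2)) {
          gi <- which(g$de & g$up_in == side)
          ci <- which(cell_target == side)
          if (length(gi) > 0L && length(ci) > 0L)
            mu[gi, ci] <- mu[gi, ci] * 2^cfg$de_log2fc
        }
      }
      vals <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / cfg$nb_dispersion),
                     nrow = cfg$n_genes)
      cm_counts <- structure(
        list(values = methods::as(Matrix::Matrix(vals, sparse = TRUE),
                                  "CsparseMatrix"),
             feature_ids = gene_id,
             cell_ids = cells_truth$cell_id[keep], modality = "rna"),
        class = "count_matrix")
      dimnames(cm_counts$values) <- list(gene_id, cm_counts$cell_ids)
      list(counts = cm_counts, genes = g, t1 = t1, t2 = t2)
    })
    counts <- res$counts
    genes_truth <- res$genes
    attr(genes_truth, "bias_groups") <- c(res$t1, res$t2)
  }

  ## stage 5: motif benchmark -------------------------------------------
  regions <- NULL; sequences <- NULL; motifs <- NULL; regions_truth <- NULL
  if (cfg$n_motifs > 0L) {
    res <- .with_stage_seed(cfg$seed, 5L, function() {
      bases <- c("A", "C", "G", "T")
      make_pwm <- function(id, L, sharp) {
        cons <- sample(4L, L, replace = TRUE)
        m <- matrix((1 - sharp) / 3, 4L, L)
        m[cbind(cons, seq_len(L))] <- sharp
        pwm(id, m)
      }
      motifs <- c(list(make_pwm("planted_motif", 8L, 0.94)),
                  lapply(seq_len(cfg$n_motifs - 1L), function(i)
                    make_pwm(sprintf("decoy_%02d", i), 8L, 0.94)))
      names(motifs) <- vapply(motifs, `[[`, character(1), "motif_id")
      consensus <- paste(bases[apply(motifs[[1L]]$matrix, 2L, which.max)],
                         collapse = "")
      n_all <- cfg$n_regions_fg + cfg$n_regions_bg
      set <- rep(c("fg", "bg"), c(cfg$n_regions_fg, cfg$n_regions_bg))
      plant_p <- ifelse(set == "fg", cfg$motif_plant_fg, cfg$motif_plant_bg)
      planted <- stats::runif(n_all) < plant_p
      seqs <- vapply(seq_len(n_all), function(i) {
        s <- sample(bases, cfg$region_length, replace = TRUE)
        if (planted[i]) {
          at <- sample.int(cfg$region_length - nchar(consensus) + 1L, 1L)
          s[at:(at + nchar(consensus) - 1L)] <- strsplit(consensus, "")[[1L]]
        }
        paste(s, collapse = "")
      }, character(1))
      ids <- sprintf("%s_region_%03d", set, stats::ave(
        seq_len(n_all), set, FUN = seq_along))
      names(seqs) <- ids
      regions <- data.frame(chrom = "chrSim",
                            start = (seq_len(n_all) - 1L) *
                              (cfg$region_length + 10L),
                            end = (seq_len(n_all) - 1L) *
                              (cfg$region_length + 10L) + cfg$region_length,
                            peak_id = ids, stringsAsFactors = FALSE)
      class(regions) <- c("peak_regions", class(regions))
      list(motifs = motifs, sequences = seqs, regions = regions,
           regions_truth = data.frame(peak_id = ids, set = set,
                                      planted = planted,
                                      stringsAsFactors = FALSE))
    })
    motifs <- res$motifs; sequences <- res$sequences
    regions <- res$regions; regions_truth <- res$regions_truth
  }

  out <- structure(
    list(config = cfg, assignments = assignments, cells = cells,
         clone_matrix = cm, initial_counts = initial_counts,
         counts = counts, regions = regions, sequences = sequences,
         motifs = motifs,
         truth = list(clones = clones, cells = cells_truth,
                      genes = genes_truth, regions = regions_truth,
                      planted_motif = if (!is.null(motifs))
                        motifs[[1L]]$motif_id else NULL)),
    class = "sim_experiment")
  if (!is.null(dir)) .write_experiment(out, dir)
  out
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(
    "sim_experiment: %d clones, %d cells (%d detected), %d cell types\n",
    nrow(x$truth$clones), nrow(x$cells), sum(x$truth$cells$detected),
    length(x$config$cell_types)))
  invisible(x)
}

.write_experiment <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_result_table(x$assignments, p("assignments.tsv"))
  write_result_table(x$cells, p("cells.tsv"))
  write_clone_matrix(x$clone_matrix, p("clone_matrix.tsv"))
  write_result_table(data.frame(clone_id = names(x$initial_counts),
                                initial_cells = unname(x$initial_counts)),
                     p("initial_counts.tsv"))
  write_result_table(x$truth$clones, p("truth_clones.tsv"))
  write_result_table(x$truth$cells, p("truth_cells.tsv"))
  if (!is.null(x$counts)) {
    write_count_matrix(x$counts, p("counts"))
    write_result_table(x$truth$genes, p("truth_genes.tsv"))
  }
  if (!is.null(x$motifs)) {
    write_bed(x$regions, p("peaks.bed"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(x$sequences), p("peaks.fa"))
    write_motifs(x$motifs, p("motifs.meme"))
    write_result_table(x$truth$regions, p("truth_regions.tsv"))
  }
  invisible(dir)
}
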