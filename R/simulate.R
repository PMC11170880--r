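# Synthetic labelled gene-activity (and optional peak-level) data with
# planted cell-type programs. Counts are negative binomial: gene g in a
# cell of type t has mean baseline_mean * effect_fold^{s(g,t)} with
# s = +1 for t's up-markers, -1 for its down-markers, 0 otherwise, and a
# fixed dispersion (NB size). Marker blocks are disjoint across types and
# directions. In peak mode every gene's per-cell count is split
# multinomially across 1-3 synthetic peaks placed wholly inside the
# gene's accessibility window, so projecting the peak matrix back through
# compute_gene_activity() reproduces the activity matrix exactly.

#' Configuration for the synthetic dataset generator
#'
#' @param n_cell_types number of cell types.
#' @param cells_per_type cells simulated per type.
#' @param n_genes total genes; must accommodate the disjoint marker
#'   blocks.
#' @param n_up_markers,n_down_markers planted markers per type.
#' @param effect_fold multiplier on marker means (down-markers divide);
#'   1 means no planted structure.
#' @param baseline_mean negative-binomial mean of background genes.
#' @param dispersion negative-binomial size parameter.
#' @param peak_mode also emit a consistent peak-level matrix.
#' @param seed integer seed; the generator is deterministic given the
#'   config.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_cell_types = 3L, cells_per_type = 200L,
                              n_genes = 2000L, n_up_markers = 100L,
                              n_down_markers = 100L, effect_fold = 4,
                              baseline_mean = 2, dispersion = 2,
                              peak_mode = FALSE, seed = 1L) {
  cfg <- list(n_cell_types = as.integer(n_cell_types),
              cells_per_type = as.integer(cells_per_type),
              n_genes = as.integer(n_genes),
              n_up_markers = as.integer(n_up_markers),
              n_down_markers = as.integer(n_down_markers),
              effect_fold = effect_fold, baseline_mean = baseline_mean,
              dispersion = dispersion, peak_mode = isTRUE(peak_mode),
              seed = as.integer(seed))
  if (cfg$n_cell_types < 1L || cfg$cells_per_type < 1L || cfg$n_genes < 1L)
    stop("n_cell_types, cells_per_type and n_genes must be positive")
  if (cfg$effect_fold < 1) stop("effect_fold must be >= 1")
  if (cfg$baseline_mean <= 0 || cfg$dispersion <= 0)
    stop("baseline_mean and dispersion must be positive")
  if (cfg$n_up_markers < 0L || cfg$n_down_markers < 0L)
    stop("marker counts must be non-negative")
  need <- cfg$n_cell_types * (cfg$n_up_markers + cfg$n_down_markers)
  if (need > cfg$n_genes)
    stop("disjoint marker blocks need ", need, " genes but n_genes is ",
         cfg$n_genes)
  structure(cfg, class = "simulation_config")
}

#' Simulate a labelled gene-activity dataset with planted programs
#'
#' @param config a [simulation_config()].
#' @return object of class `simulated_dataset`: `list(activity, peaks,
#'   truth_labels, planted, annotations, config)`. `activity` (and
#'   `peaks`, in peak mode) are raw-layer [count_matrix] objects;
#'   `truth_labels` is a named character vector; `planted` is a gene-set
#'   data.frame with weights `log2(effect_fold)` (unit weights when
#'   `effect_fold` is 1); `annotations` locates each gene on a synthetic
#'   genome for window building.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  nt <- config$n_cell_types; npc <- config$cells_per_type
  ng <- config$n_genes; nc <- nt * npc

  genes <- sprintf("gene%05d", seq_len(ng))
  barcodes <- sprintf("cell%05d", seq_len(nc))
  types <- sprintf("type%02d", seq_len(nt))
  truth <- stats::setNames(rep(types, each = npc), barcodes)

  # disjoint marker blocks at the head of the gene list
  nu <- config$n_up_markers; nd <- config$n_down_markers
  up_idx <- down_idx <- vector("list", nt)
  offset <- 0L
  for (t in seq_len(nt)) {
    up_idx[[t]] <- seq_len(nu) + offset
    down_idx[[t]] <- seq_len(nd) + offset + nu
    offset <- offset + nu + nd
  }

  mu <- matrix(config$baseline_mean, nrow = ng, ncol = nt)
  for (t in seq_len(nt)) {
    mu[up_idx[[t]], t] <- config$baseline_mean * config$effect_fold
    mu[down_idx[[t]], t] <- config$baseline_mean / config$effect_fold
  }

  # synthetic genome layout: 100 genes per chromosome, 10 kb apart, body
  # 2 kb, + strand; default 2 kb upstream windows are therefore disjoint
  chrom <- sprintf("chrS%02d", (seq_len(ng) - 1L) %/% 100L + 1L)
  gstart <- ((seq_len(ng) - 1L) %% 100L) * 10000L + 5000L
  gend <- gstart + 2000L
  annotations <- data.frame(gene_id = genes, gene_name = genes,
                            chrom = chrom, start = gstart, end = gend,
                            strand = "+", stringsAsFactors = FALSE)

  sim <- with_seed(config$seed, {
    counts <- matrix(0L, nrow = ng, ncol = nc)
    for (t in seq_len(nt)) {
      cols <- seq_len(npc) + (t - 1L) * npc
      counts[, cols] <- stats::rnbinom(ng * npc, mu = mu[, t],
                                       size = config$dispersion)
    }
    dimnames(counts) <- list(genes, barcodes)

    peaks <- NULL
    if (config$peak_mode) {
      n_peaks <- sample(1:3, ng, replace = TRUE)
      rows <- vector("list", ng)
      names_out <- vector("list", ng)
      win_start <- gstart - 2000L       # default upstream window origin
      for (g in seq_len(ng)) {
        k <- n_peaks[g]
        # k equal-width peaks tiling the 4 kb window
        bnd <- win_start[g] + round(seq(0L, 4000L, length.out = k + 1L))
        pk_names <- sprintf("%s:%d-%d", chrom[g],
                            bnd[seq_len(k)], bnd[seq_len(k) + 1L])
        cnt <- counts[g, ]
        split_mat <- matrix(0L, nrow = k, ncol = nc)
        rem <- cnt
        if (k > 1L) {
          for (i in seq_len(k - 1L)) {
            drawn <- stats::rbinom(nc, rem, 1 / (k - i + 1))
            split_mat[i, ] <- drawn
            rem <- rem - drawn
          }
        }
        split_mat[k, ] <- rem
        rows[[g]] <- split_mat
        names_out[[g]] <- pk_names
      }
      pk_mat <- do.call(rbind, rows)
      dimnames(pk_mat) <- list(unlist(names_out), barcodes)
      peaks <- count_matrix(pk_mat, layer = "raw", feature_kind = "peak")
    }
    list(counts = counts, peaks = peaks)
  })

  w <- log2(config$effect_fold)
  if (w <= 0) w <- 1                    # null generator: unit weights
  planted <- do.call(rbind, lapply(seq_len(nt), function(t) {
    rbind(
      if (nu > 0L) data.frame(cell_type = types[t], direction = "up",
                              gene = genes[up_idx[[t]]], weight = w,
                              stringsAsFactors = FALSE),
      if (nd > 0L) data.frame(cell_type = types[t], direction = "down",
                              gene = genes[down_idx[[t]]], weight = w,
                              stringsAsFactors = FALSE)
    )
  }))
  planted <- if (is.null(planted)) NULL else gene_sets(planted)

  structure(list(
    activity = count_matrix(sim$counts, layer = "raw",
                            feature_kind = "gene"),
    peaks = sim$peaks,
    truth_labels = truth,
    planted = planted,
    annotations = annotations,
    config = config
  ), class = "simulated_dataset")
}

#' @method print simulated_dataset
#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(paste0("<simulated_dataset> %d genes x %d cells, %d types",
                     ", effect_fold=%g%s\n"),
              nrow(x$activity$values), ncol(x$activity$values),
              x$config$n_cell_types, x$config$effect_fold,
              if (!is.null(x$peaks)) sprintf(", %d peaks",
                                             nrow(x$peaks$values)) else ""))
  invisible(x)
}

#' Named simulation fixtures
#'
#' Three fixed scenarios used throughout the test suite and examples:
#' `tiny` (2 types x 20 cells x 50 genes, 5/5 markers, 4-fold; fast unit
#' tests), `null` (4 types x 500 cells x 500 genes, 50/50 markers at
#' effect_fold 1; calibration checks — planted sets carry no signal), and
#' `benchmark` (3 types x 200 cells x 2000 genes, 100/100 markers,
#' 4-fold, baseline 2, dispersion 2; recovery and end-to-end checks).
#'
#' @param name fixture name.
#' @param seed optional seed override (e.g. to draw an independent
#'   replicate of the same scenario).
#' @param peak_mode optional peak-mode override.
#' @return A `simulated_dataset`.
#' @export
make_fixture <- function(name = c("tiny", "null", "benchmark"),
                         seed = NULL, peak_mode = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = simulation_config(n_cell_types = 2, cells_per_type = 20,
                             n_genes = 50, n_up_markers = 5,
                             n_down_markers = 5, effect_fold = 4,
                             baseline_mean = 2, dispersion = 2, seed = 11),
    null = simulation_config(n_cell_types = 4, cells_per_type = 500,
                             n_genes = 500, n_up_markers = 50,
                             n_down_markers = 50, effect_fold = 1,
                             baseline_mean = 2, dispersion = 2, seed = 23),
    benchmark = simulation_config(n_cell_types = 3, cells_per_type = 200,
                                  n_genes = 2000, n_up_markers = 100,
                                  n_down_markers = 100, effect_fold = 4,
                                  baseline_mean = 2, dispersion = 2,
                                  seed = 7)
  )
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(peak_mode)) cfg$peak_mode <- isTRUE(peak_mode)
  simulate_dataset(cfg)
}
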