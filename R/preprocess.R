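# Quality filtering, library-size log-normalization, variable-feature
# selection and per-gene scaling. Filter thresholds default to "off"; the
# values used in practice for droplet data are of the order min_counts
# 1000 with an upper bound of 25,000 (RNA) or 100,000 (ATAC) counts,
# min_features 200 per cell, and features kept when present in >= 100
# cells.

filter_report <- function(cells_in, cells_kept, features_in, features_kept,
                          thresholds) {
  structure(list(cells_in = cells_in, cells_kept = cells_kept,
                 features_in = features_in, features_kept = features_kept,
                 thresholds = thresholds),
            class = "filter_report")
}

#' @method print filter_report
#' @export
print.filter_report <- function(x, ...) {
  thr <- paste(names(x$thresholds), unlist(x$thresholds),
               sep = "=", collapse = ", ")
  cat(sprintf("<filter_report> cells %d -> %d, features %d -> %d (%s)\n",
              x$cells_in, x$cells_kept, x$features_in, x$features_kept,
              if (nzchar(thr)) thr else "no thresholds"))
  invisible(x)
}

#' Filter cells on total counts and detected features
#'
#' Keeps cells with total counts within `[min_counts, max_counts]` and at
#' least `min_features` features with nonzero counts; any `NULL` threshold
#' is skipped. The feature list is unchanged.
#'
#' @param m raw-layer [count_matrix].
#' @param min_counts,max_counts,min_features thresholds, or `NULL` to skip.
#' @return `list(matrix = count_matrix, report = filter_report)`.
#' @export
filter_cells <- function(m, min_counts = NULL, max_counts = NULL,
                         min_features = NULL) {
  stopifnot_cm(m, layer = "raw")
  v <- cm_values(m)
  totals <- Matrix::colSums(v)
  nfeat <- Matrix::colSums(v != 0)
  keep <- rep(TRUE, ncol(v))
  if (!is.null(min_counts)) keep <- keep & totals >= min_counts
  if (!is.null(max_counts)) keep <- keep & totals <= max_counts
  if (!is.null(min_features)) keep <- keep & nfeat >= min_features
  if (!any(keep))
    stop("all cells removed by filtering; review the thresholds")
  rep <- filter_report(ncol(v), sum(keep), nrow(v), nrow(v),
                       list(min_counts = min_counts, max_counts = max_counts,
                            min_features = min_features))
  list(matrix = count_matrix(v[, keep, drop = FALSE], layer = "raw",
                             feature_kind = cm_feature_kind(m)),
       report = rep)
}

#' Filter features on the number of cells expressing them
#'
#' @param m raw-layer [count_matrix].
#' @param min_cells keep features nonzero in at least this many cells.
#' @return `list(matrix = count_matrix, report = filter_report)`.
#' @export
filter_features <- function(m, min_cells) {
  stopifnot_cm(m, layer = "raw")
  v <- cm_values(m)
  keep <- Matrix::rowSums(v != 0) >= min_cells
  if (!any(keep))
    stop("all features removed by filtering; review min_cells")
  rep <- filter_report(ncol(v), ncol(v), nrow(v), sum(keep),
                       list(min_cells = min_cells))
  list(matrix = count_matrix(v[keep, , drop = FALSE], layer = "raw",
                             feature_kind = cm_feature_kind(m)),
       report = rep)
}

#' Library-size log-normalization
#'
#' Each value `v` in a cell with total counts `T` becomes
#' `log(1 + v * scale_factor / T)` (natural log). All-zero cells map to
#' zeros.
#'
#' @param m raw-layer [count_matrix].
#' @param scale_factor positive library-size target (default `1e4`).
#' @return A [count_matrix] with `layer = "normalized"`.
#' @export
log_normalize <- function(m, scale_factor = 1e4) {
  stopifnot_cm(m, layer = "raw")
  if (scale_factor <= 0) stop("scale_factor must be positive")
  v <- cm_values(m)
  if (length(v@x) && min(v@x) < 0) stop("negative values in raw input")
  totals <- Matrix::colSums(v)
  totals[totals == 0] <- 1           # all-zero cells stay all-zero
  out <- v %*% Matrix::Diagonal(x = scale_factor / totals)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(v)
  count_matrix(out, layer = "normalized",
               feature_kind = cm_feature_kind(m))
}

row_stats <- function(v) {
  n <- ncol(v)
  mu <- Matrix::rowMeans(v)
  if (n < 2L) return(list(mean = mu, var = rep(0, nrow(v))))
  ssq <- Matrix::rowSums(v^2)
  var <- pmax(0, (ssq - n * mu^2) / (n - 1))
  list(mean = mu, var = var)
}

#' Select highly variable features by binned dispersion
#'
#' Features are ranked by a standardized dispersion: genes are binned into
#' `n_bins` equal-occupancy bins of mean normalized value; within each bin
#' the dispersion (variance / mean) is z-scored, and features with larger
#' z come first. Only features with positive variance are eligible; ties
#' are broken by feature order.
#'
#' @param m normalized-layer [count_matrix].
#' @param n number of features to select (default 2000; capped at the
#'   number of positive-variance features).
#' @param n_bins number of mean bins (default 20).
#' @return character vector of selected feature names, most variable first.
#' @export
select_variable_features <- function(m, n = 2000, n_bins = 20) {
  stopifnot_cm(m, layer = "normalized")
  if (n < 1) stop("n must be >= 1")
  st <- row_stats(cm_values(m))
  eligible <- which(st$var > 0 & st$mean > 0)
  if (!length(eligible)) return(character(0))
  mu <- st$mean[eligible]
  disp <- st$var[eligible] / mu
  r <- rank(mu, ties.method = "first")
  # keep every bin at >= 2 members so the within-bin z-score is defined
  n_bins_eff <- max(1L, min(n_bins, length(eligible) %/% 2L))
  bin <- ceiling(r * n_bins_eff / length(eligible))
  z <- disp
  for (b in unique(bin)) {
    idx <- bin == b
    s <- stats::sd(disp[idx])
    z[idx] <- if (sum(idx) < 2L || s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  ord <- order(-z, seq_along(z))
  cm_features(m)[eligible[ord][seq_len(min(n, length(eligible)))]]
}

#' Center and scale features
#'
#' Restricts the matrix to `features` and transforms each row to mean 0,
#' standard deviation 1 (constant rows become all-zero), clipping values
#' to `[-clip, clip]`.
#'
#' @param m normalized-layer [count_matrix].
#' @param features features to keep (subset of `cm_features(m)`).
#' @param clip magnitude at which scaled values are clipped (default 10).
#' @return A [count_matrix] with `layer = "scaled"`.
#' @export
scale_center <- function(m, features, clip = 10) {
  stopifnot_cm(m, layer = "normalized")
  if (length(features) == 0L) stop("empty feature list")
  missing <- setdiff(features, cm_features(m))
  if (length(missing))
    stop("features not in matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  x <- as.matrix(cm_values(m)[features, , drop = FALSE])
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  x <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  x[sdv == 0, ] <- 0
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  count_matrix(x, layer = "scaled", feature_kind = cm_feature_kind(m))
}
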