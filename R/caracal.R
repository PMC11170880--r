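# Cell typing: combine per-direction set scores into one score per cell
# type, label cells by the top score, optionally gate RNA-based scores by
# ATAC-based scores, and evaluate against reference labels.

#' Combine up- and down-regulated set scores
#'
#' The combined cell-type score is the up-score plus the inverse of the
#' down-score: `up + (1 - down)`, in [0, 2]. A cell strongly enriched for
#' a type's up-regulated genes and depleted of its down-regulated genes
#' scores near 2.
#'
#' @param up,down numeric vectors/matrices in [0, 1] (recycled as in
#'   arithmetic).
#' @return `up + (1 - down)`.
#' @export
combine_up_down <- function(up, down) {
  if (any(!is.finite(up)) || any(!is.finite(down)) ||
      any(up < 0 | up > 1) || any(down < 0 | down > 1))
    stop("up and down scores must lie in [0, 1]")
  up + (1 - down)
}

#' Score every cell for every cell type
#'
#' Runs [score_gene_set()] for each cell type's up-set and (when present)
#' down-set, and combines them with [combine_up_down()]. A cell type
#' without a down-set has its down-score pinned at 1 (contributing 0) and
#' is flagged `up_only`; a cell type without an up-set is an error.
#'
#' @param m [count_matrix] in the layer named by `params$input_layer`.
#' @param sets gene-set data.frame ([gene_sets()]).
#' @param params a [vam_params()] object.
#' @return object of class `cell_type_scores`: `list(barcodes, cell_types,
#'   up, down, combined, up_only)` with cell x type matrices; `combined`
#'   lies in [0, 2].
#' @export
score_cell_types <- function(m, sets, params = vam_params()) {
  sets <- gene_sets(sets)
  types <- unique(sets$cell_type)
  missing_up <- types[!types %in% sets$cell_type[sets$direction == "up"]]
  if (length(missing_up))
    stop("cell type(s) without an up-regulated set: ",
         paste(missing_up, collapse = ", "))

  nc <- length(cm_barcodes(m))
  up <- down <- matrix(NA_real_, nrow = nc, ncol = length(types),
                       dimnames = list(cm_barcodes(m), types))
  up_only <- stats::setNames(logical(length(types)), types)
  for (ct in types) {
    up_set <- sets[sets$cell_type == ct & sets$direction == "up", ]
    up[, ct] <- score_gene_set(m, up_set, params)$scores
    down_set <- sets[sets$cell_type == ct & sets$direction == "down", ]
    if (nrow(down_set)) {
      down[, ct] <- score_gene_set(m, down_set, params)$scores
    } else {
      down[, ct] <- 1
      up_only[ct] <- TRUE
    }
  }
  structure(list(barcodes = cm_barcodes(m), cell_types = types,
                 up = up, down = down,
                 combined = combine_up_down(up, down),
                 up_only = up_only),
            class = "cell_type_scores")
}

#' @method print cell_type_scores
#' @export
print.cell_type_scores <- function(x, ...) {
  cat(sprintf("<cell_type_scores> %d cells x %d cell types (%s)\n",
              length(x$barcodes), length(x$cell_types),
              paste(x$cell_types, collapse = ", ")))
  invisible(x)
}

combined_matrix <- function(scores) {
  if (inherits(scores, "cell_type_scores")) return(scores$combined)
  if (is.matrix(scores)) {
    if (is.null(rownames(scores)) || is.null(colnames(scores)))
      stop("score matrix needs barcode row names and cell-type column names")
    return(scores)
  }
  stop("scores must be a cell_type_scores object or a named matrix")
}

#' Assign a cell-type label to each cell
#'
#' Each cell is labelled by its top-scoring cell type. The margin is the
#' gap between the best and second-best score (0 with a single type);
#' exact ties pick the lexicographically smallest type and set the tie
#' flag. Cells whose top score falls below `min_score` are labelled
#' `"unassigned"`.
#'
#' @param scores a `cell_type_scores` object or a cell x type matrix with
#'   dimnames.
#' @param min_score minimum top score to assign a label (default 0).
#' @return data.frame with columns `barcode`, `label`, `top_score`,
#'   `margin`, `tie`.
#' @export
assign_labels <- function(scores, min_score = 0) {
  cmb <- combined_matrix(scores)
  types <- colnames(cmb)
  n <- nrow(cmb)
  label <- character(n); top <- numeric(n); margin <- numeric(n)
  tie <- logical(n)
  for (i in seq_len(n)) {
    row <- cmb[i, ]
    mx <- max(row)
    cand <- types[row == mx]
    tie[i] <- length(cand) > 1L
    label[i] <- min(cand)
    top[i] <- mx
    margin[i] <- if (length(row) > 1L) mx - sort(row, decreasing = TRUE)[2L] else 0
  }
  label[top < min_score] <- "unassigned"
  data.frame(barcode = rownames(cmb), label = label, top_score = top,
             margin = margin, tie = tie, stringsAsFactors = FALSE)
}

#' Gate RNA-based scores by ATAC-based scores
#'
#' The integrated score is the RNA score multiplied by a binary indicator
#' of the ATAC score strictly exceeding the median of all cells' ATAC
#' scores for that cell type: `out(i,j) = rna(i,j) * [atac(i,j) > Med_j]`.
#' Cells exactly at the median gate to 0.
#'
#' @param rna,atac cell x type score matrices with matching barcode row
#'   names and cell-type column names (`atac` is reordered to match
#'   `rna`).
#' @return the gated cell x type matrix, with the per-type medians
#'   attached as `attr(, "medians")`.
#' @export
integrate_scores <- function(rna, atac) {
  if (!is.matrix(rna) || !is.matrix(atac))
    stop("rna and atac must be matrices")
  if (is.null(dimnames(rna)) || is.null(dimnames(atac)))
    stop("score matrices need barcode and cell-type dimnames")
  if (!setequal(rownames(rna), rownames(atac)) ||
      !setequal(colnames(rna), colnames(atac)) ||
      nrow(rna) != nrow(atac) || ncol(rna) != ncol(atac))
    stop("rna and atac matrices must cover the same barcodes and cell types")
  atac <- atac[rownames(rna), colnames(rna), drop = FALSE]
  med <- apply(atac, 2L, stats::median)
  gate <- sweep(atac, 2L, med, `>`)
  out <- rna * gate
  attr(out, "medians") <- med
  out
}

#' Compare predicted labels with reference labels
#'
#' Computes the confusion matrix over the union of the two label
#' vocabularies and the agreement fraction over the shared barcodes;
#' cells present on only one side are excluded and counted.
#'
#' @param predicted label table from [assign_labels()] (or any data.frame
#'   with `barcode` and `label` columns, or a named character vector).
#' @param truth reference labels: named character vector or two-column
#'   data.frame (barcode, label).
#' @return `list(confusion, agreement, n_shared, n_only_predicted,
#'   n_only_truth)`; `confusion` has predicted labels in rows and
#'   reference labels in columns.
#' @export
evaluate_labels <- function(predicted, truth) {
  if (is.data.frame(predicted)) {
    if (!all(c("barcode", "label") %in% names(predicted)))
      stop("predicted needs columns barcode and label")
    pred <- stats::setNames(predicted$label, predicted$barcode)
  } else {
    pred <- as_label_map(predicted)
  }
  tru <- as_label_map(truth)
  shared <- intersect(names(pred), names(tru))
  if (!length(shared)) stop("no shared barcodes between predicted and truth")
  vocab <- sort(union(pred[shared], tru[shared]))
  confusion <- table(
    predicted = factor(pred[shared], levels = vocab),
    truth = factor(tru[shared], levels = vocab)
  )
  list(confusion = confusion,
       agreement = mean(pred[shared] == tru[shared]),
       n_shared = length(shared),
       n_only_predicted = length(pred) - length(shared),
       n_only_truth = length(tru) - length(shared))
}
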