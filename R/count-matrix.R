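#' Sparse feature-by-cell count container
#'
#' Lightweight container for the matrices moved through the pipeline: a
#' sparse feature x cell matrix plus a processing-layer tag (`raw`,
#' `normalized` or `scaled`) and a feature-kind tag (`gene` or `peak`).
#' Features are row names, cell barcodes are column names; both must be
#' unique. The `raw` layer must be non-negative.
#'
#' @param values matrix or Matrix, features in rows, cells in columns, with
#'   row and column names set.
#' @param layer processing layer of `values`.
#' @param feature_kind whether rows are genes or peaks (peak names follow
#'   the `"chrom:start-end"` / `"chrom-start-end"` dialects, 0-based
#'   half-open coordinates).
#' @return A `count_matrix` object.
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(c("A", "B", "C"), c("c1", "c2")))
#' count_matrix(m)
#' @export
count_matrix <- function(values,
                         layer = c("raw", "normalized", "scaled"),
                         feature_kind = c("gene", "peak")) {
  layer <- match.arg(layer)
  feature_kind <- match.arg(feature_kind)
  values <- as_dgc(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("count_matrix values need feature (row) and barcode (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate cell barcodes: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (layer == "raw" && length(values@x) && min(values@x) < 0)
    stop("raw counts must be non-negative")
  structure(list(values = values, layer = layer, feature_kind = feature_kind),
            class = "count_matrix")
}

#' @method print count_matrix
#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d %ss x %d cells [layer=%s]\n",
              nrow(x$values), x$feature_kind, ncol(x$values), x$layer))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$values)

#' @rdname count_matrix
#' @param m a `count_matrix`.
#' @export
cm_values <- function(m) m$values

#' @rdname count_matrix
#' @export
cm_features <- function(m) rownames(m$values)

#' @rdname count_matrix
#' @export
cm_barcodes <- function(m) colnames(m$values)

#' @rdname count_matrix
#' @export
cm_layer <- function(m) m$layer

#' @rdname count_matrix
#' @export
cm_feature_kind <- function(m) m$feature_kind

is_count_matrix <- function(x) inherits(x, "count_matrix")

stopifnot_cm <- function(m, layer = NULL, what = "input") {
  if (!is_count_matrix(m)) stop(what, " must be a count_matrix")
  if (!is.null(layer) && !cm_layer(m) %in% layer)
    stop(what, " must be in layer ", paste(layer, collapse = "/"),
         " (got ", cm_layer(m), ")")
  invisible(m)
}
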