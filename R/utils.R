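# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's RNG stream. seed = NULL runs the code as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# coerce anything matrix-like to a numeric dgCMatrix, keeping dimnames
as_dgc <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  x <- methods::as(x, "CsparseMatrix")
  x <- methods::as(x, "generalMatrix")
  methods::as(x, "dMatrix")
}

# labels arrive either as a named character vector (names = barcodes) or a
# two-column data.frame (barcode, label); normalise to a named vector
as_label_map <- function(labels) {
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2L)
      stop("label table needs at least two columns (barcode, label)")
    out <- as.character(labels[[2L]])
    names(out) <- as.character(labels[[1L]])
    return(out)
  }
  if (is.null(names(labels)) || any(names(labels) == ""))
    stop("labels must be named by cell barcode")
  stats::setNames(as.character(labels), names(labels))
}
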