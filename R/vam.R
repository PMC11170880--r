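# Variance-adjusted gene-set scoring.
#
# Each cell receives, per weighted gene set, a squared distance from the
# origin in the space of the set's genes, with each gene's axis shrunk by
# its sample variance (a diagonal Mahalanobis-type distance measured from
# zero, so absence of signal means distance zero). The null distribution
# of the distance is estimated by breaking within-cell coordination:
# every set gene's values are independently resampled across cells. A
# gamma distribution fitted to the null distances converts each observed
# distance into its null-CDF value, a score in [0, 1] that is comparable
# across gene sets of different sizes and admits p = 1 - score.

#' Parameters for variance-adjusted set scoring
#'
#' @param n_permutations number of synthetic null cells (default 1000;
#'   at least 100 is required for a stable gamma fit).
#' @param gamma_fit gamma fitting method, method of moments (default) or
#'   maximum likelihood.
#' @param variance_floor lower bound on per-gene variance estimates.
#' @param seed integer seed driving the null resampling.
#' @param input_layer matrix layer the distances are computed on. The
#'   distance is anchored at zero, so the normalized layer is the
#'   meaningful default; scaled input is accepted but centering removes
#'   the origin anchoring.
#' @return object of class `vam_params`.
#' @export
vam_params <- function(n_permutations = 1000L,
                       gamma_fit = c("method_of_moments", "mle"),
                       variance_floor = 1e-8,
                       seed = 1L,
                       input_layer = c("normalized", "scaled")) {
  gamma_fit <- match.arg(gamma_fit)
  input_layer <- match.arg(input_layer)
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 100L)
    stop("n_permutations must be at least 100 for a usable null")
  if (variance_floor <= 0) stop("variance_floor must be positive")
  structure(list(n_permutations = n_permutations, gamma_fit = gamma_fit,
                 variance_floor = variance_floor, seed = as.integer(seed),
                 input_layer = input_layer),
            class = "vam_params")
}

set_label <- function(set) {
  ct <- unique(set$cell_type %||% "set")
  dir <- unique(set$direction %||% "")
  paste(ct, dir)
}

#' Variance-adjusted distances for one gene set
#'
#' For cell `i` over the retained set genes `k` with weights rescaled to
#' mean 1, `d2_i = sum_k w_k * x_ik^2 / max(var_k, floor)` where `var_k`
#' is the gene's sample variance across cells. Null distances use the
#' same weights and variances on a matrix in which each gene's values are
#' independently resampled across cells (seeded), with
#' `n_permutations` synthetic null cells.
#'
#' @param m [count_matrix] in the layer named by `params$input_layer`.
#' @param set one weighted gene set: data.frame with columns `gene` and
#'   `weight` (rows for a single cell type and direction).
#' @param params a [vam_params()] object.
#' @return `list(observed, null, genes, weights, variances)`; `observed`
#'   is named by barcode.
#' @export
compute_vam_distances <- function(m, set, params = vam_params()) {
  stopifnot_cm(m, layer = params$input_layer)
  genes <- as.character(set$gene)
  w <- as.numeric(set$weight)
  if (any(w <= 0)) stop("gene-set weights must be strictly positive")
  present <- genes %in% cm_features(m)
  if (!any(present))
    stop("no gene of set '", set_label(set), "' is present in the matrix")
  if (!all(present))
    warning("dropping ", sum(!present), " set gene(s) absent from the ",
            "matrix: ",
            paste(utils::head(genes[!present], 5L), collapse = ", "))
  genes <- genes[present]
  w <- w[present]
  w <- w / mean(w)                      # mean-1 weights: scale invariance

  X <- as.matrix(cm_values(m)[genes, , drop = FALSE])
  st <- row_stats(cm_values(m)[genes, , drop = FALSE])
  s2 <- pmax(st$var, params$variance_floor)

  coef <- w / s2
  observed <- as.numeric(colSums(coef * X^2))
  names(observed) <- cm_barcodes(m)

  nperm <- params$n_permutations
  null_d <- with_seed(params$seed, {
    Xn <- matrix(0, nrow = length(genes), ncol = nperm)
    for (k in seq_along(genes))
      Xn[k, ] <- sample(X[k, ], nperm, replace = TRUE)
    as.numeric(colSums(coef * Xn^2))
  })

  list(observed = observed, null = null_d, genes = genes, weights = w,
       variances = s2)
}

#' Fit a gamma distribution to null distances
#'
#' @param x non-negative values (at least 100, with positive mean and
#'   variance).
#' @param method `"method_of_moments"` (shape = mean^2/var,
#'   rate = mean/var) or `"mle"` (Newton iterations on the profile
#'   likelihood in the shape, initialized at the moment estimates,
#'   tolerance 1e-10 on the gradient).
#' @return `list(shape, rate)`, both positive.
#' @export
fit_gamma <- function(x, method = c("method_of_moments", "mle")) {
  method <- match.arg(method)
  if (length(x) < 100L)
    stop("need at least 100 null values to fit the gamma")
  mu <- mean(x)
  v <- stats::var(x)
  if (!is.finite(mu) || mu <= 0)
    stop("null distances must have positive mean")
  if (!is.finite(v) || v <= 0)
    stop("null distances are constant; increase n_permutations")
  shape <- mu^2 / v
  rate <- mu / v
  if (method == "mle") {
    xp <- x[x > 0]
    if (length(xp) < length(x))
      warning("dropping ", length(x) - length(xp),
              " zero null distance(s) for the gamma MLE")
    s <- log(mean(xp)) - mean(log(xp))
    a <- shape
    for (i in seq_len(100L)) {
      g <- log(a) - digamma(a) - s
      if (abs(g) < 1e-10) break
      a <- a - g / (1 / a - trigamma(a))
      if (!is.finite(a) || a <= 0) { a <- shape; break }
    }
    shape <- a
    rate <- a / mean(xp)
  }
  list(shape = shape, rate = rate)
}

#' Score every cell for one weighted gene set
#'
#' Maps each cell's variance-adjusted distance through the CDF of the
#' gamma distribution fitted to the null distances, yielding a score in
#' [0, 1]; `1 - score` is the corresponding p-value.
#'
#' @inheritParams compute_vam_distances
#' @return `list(scores, p_values, distances, gamma_shape, gamma_rate,
#'   genes)`; `scores` is named by barcode.
#' @export
score_gene_set <- function(m, set, params = vam_params()) {
  d <- compute_vam_distances(m, set, params)
  fit <- fit_gamma(d$null, params$gamma_fit)
  scores <- stats::pgamma(d$observed, shape = fit$shape, rate = fit$rate)
  list(scores = scores, p_values = 1 - scores, distances = d$observed,
       gamma_shape = fit$shape, gamma_rate = fit$rate, genes = d$genes)
}
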