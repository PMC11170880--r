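# One-vs-rest differential activity and weighted gene-set construction.
#
# For each candidate cell type the reference matrix is split into that
# type's cells versus all others; each gene is tested with a Wilcoxon
# rank-sum test and ranked by log2 fold-change of the back-transformed
# mean normalized activity. The top (most positive) and bottom (most
# negative) genes become the up- and down-regulated weighted gene sets,
# weighted by |log2FC|.

#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks are used for ties. When the smaller group has more than 8
#' observations the tie-corrected normal approximation with continuity
#' correction is used; otherwise the exact tie-aware null distribution of
#' the rank sum is computed (via a generating-function convolution,
#' equivalent to enumerating all assignments of ranks to groups). For
#' very large samples with a tiny group (total above 200) the normal
#' approximation is used throughout.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return `list(statistic, p_value)`; `statistic` is the Mann-Whitney U
#'   for the first sample.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both groups must be non-empty")
  n <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2

  if (min(nx, ny) > 8L || n > 200L) {
    p <- wrs_normal_p(U, r, nx, ny)
  } else {
    p <- wrs_exact_p(W, r, nx)
  }
  list(statistic = U, p_value = p)
}

# normal approximation with tie-corrected variance + continuity correction
wrs_normal_p <- function(U, r, nx, ny) {
  n <- nx + ny
  tab <- table(r)
  tie_term <- sum(tab^3 - tab)
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- max(0, abs(U - nx * ny / 2) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}

# exact two-sided p for the rank sum W with midranks: distribution of the
# sum of nx doubled midranks over all C(n, nx) subsets, by DP convolution
wrs_exact_p <- function(W, r, nx) {
  n <- length(r)
  dr <- as.integer(round(2 * r))       # doubled midranks are integers
  S <- sum(dr)
  k <- nx
  # dp[j + 1, s + 1] = number of j-subsets with doubled-rank sum s
  dp <- matrix(0, nrow = k + 1L, ncol = S + 1L)
  dp[1L, 1L] <- 1
  for (ri in dr) {
    jmax <- min(k, nrow(dp) - 1L)
    for (j in seq(jmax, 1L)) {
      src <- seq_len(S + 1L - ri)
      dp[j + 1L, src + ri] <- dp[j + 1L, src + ri] + dp[j, src]
    }
  }
  counts <- dp[k + 1L, ]
  sums <- (seq_len(S + 1L) - 1L) / 2   # back to midrank scale
  mu <- nx * (n + 1) / 2
  dev <- abs(W - mu)
  extreme <- abs(sums - mu) >= dev - 1e-9
  sum(counts[extreme]) / sum(counts)
}

#' One-vs-rest differential gene activity
#'
#' Tests every sufficiently expressed gene for differential normalized
#' activity between cells of `target` and all other labelled cells.
#' `log2fc` is `log2((mean(expm1(v_in)) + 1) / (mean(expm1(v_out)) + 1))`
#' on the normalized values, p-values come from [wilcoxon_rank_sum()] and
#' are Bonferroni-adjusted over the tested genes. A gene is tested only if
#' nonzero in at least `min_pct` of either group.
#'
#' @param m normalized-layer [count_matrix].
#' @param labels barcode-to-cell-type mapping (named character vector or
#'   two-column data.frame).
#' @param target the cell type to contrast against all others.
#' @param min_pct minimum nonzero fraction in either group (default 0.01).
#' @return data.frame with columns `gene`, `cell_type`, `log2fc`,
#'   `p_value`, `adj_p_value`, `pct_in`, `pct_out`, in feature order.
#' @export
differential_activity <- function(m, labels, target, min_pct = 0.01) {
  stopifnot_cm(m, layer = "normalized")
  map <- as_label_map(labels)
  bcs <- intersect(cm_barcodes(m), names(map))
  if (length(bcs) < length(cm_barcodes(m)))
    warning(length(cm_barcodes(m)) - length(bcs),
            " cell(s) without a label are ignored")
  if (!length(bcs)) stop("no labelled cells found in the matrix")
  lab <- map[bcs]
  if (length(unique(lab)) < 2L)
    stop("need at least two distinct labels for one-vs-rest testing")
  if (!target %in% lab) stop("target cell type not present: ", target)

  v <- cm_values(m)[, bcs, drop = FALSE]
  in_idx <- which(lab == target)
  out_idx <- which(lab != target)
  # cells x genes with fast column (gene) access
  tv <- Matrix::t(v)

  genes <- cm_features(m)
  n_in <- length(in_idx); n_out <- length(out_idx)
  res <- vector("list", length(genes))
  for (j in seq_along(genes)) {
    col <- tv[, j]
    xin <- col[in_idx]; xout <- col[out_idx]
    pct_in <- sum(xin != 0) / n_in
    pct_out <- sum(xout != 0) / n_out
    if (max(pct_in, pct_out) < min_pct) next
    l2fc <- log2((mean(expm1(xin)) + 1) / (mean(expm1(xout)) + 1))
    p <- wilcoxon_rank_sum(xin, xout)$p_value
    res[[j]] <- c(j, l2fc, p, pct_in, pct_out)
  }
  res <- do.call(rbind, res)
  if (is.null(res)) stop("no gene passed the min_pct expression filter")
  out <- data.frame(
    gene = genes[res[, 1L]],
    cell_type = target,
    log2fc = res[, 2L],
    p_value = res[, 3L],
    adj_p_value = pmin(1, res[, 3L] * nrow(res)),
    pct_in = res[, 4L],
    pct_out = res[, 5L],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Build weighted up/down gene sets from differential activity
#'
#' Per cell type, the up-set holds the `n_genes` genes with the largest
#' positive log2 fold-change and the down-set the `n_genes` genes with the
#' most negative; each gene is weighted by the magnitude of its fold
#' change (`|log2fc|` by default, or `2^|log2fc|` with
#' `weight_scale = "fc"`). Ties in log2fc are broken by smaller p-value,
#' then gene name. Fewer qualifying genes yield a smaller set with a
#' warning; a direction with no qualifying gene is omitted entirely (the
#' scoring layer then treats it as absent).
#'
#' @param records output of [differential_activity()] for one or more cell
#'   types (a single data.frame or a list of them).
#' @param n_genes set size per direction (default 100).
#' @param weight_scale weight by `|log2fc|` (default) or by the raw fold
#'   change `2^|log2fc|`.
#' @return gene-set data.frame as in [gene_sets()].
#' @export
build_cell_type_gene_sets <- function(records, n_genes = 100,
                                      weight_scale = c("log2fc", "fc")) {
  weight_scale <- match.arg(weight_scale)
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (is.data.frame(records)) records <- list(records)
  rec <- do.call(rbind, records)

  pick <- function(df, dir) {
    sub <- if (dir == "up") df[df$log2fc > 0, , drop = FALSE]
           else df[df$log2fc < 0, , drop = FALSE]
    sgn <- if (dir == "up") -1 else 1
    sub <- sub[order(sgn * sub$log2fc, sub$p_value, sub$gene), , drop = FALSE]
    utils::head(sub, n_genes)
  }

  out <- list()
  for (ct in unique(rec$cell_type)) {
    df <- rec[rec$cell_type == ct, , drop = FALSE]
    for (dir in c("up", "down")) {
      sel <- pick(df, dir)
      if (nrow(sel) == 0L) {
        warning("no ", dir, "-regulated gene for cell type ", ct,
                "; omitting that set")
        next
      }
      if (nrow(sel) < n_genes)
        warning(dir, "-set for ", ct, " has only ", nrow(sel),
                " gene(s) (requested ", n_genes, ")")
      w <- abs(sel$log2fc)
      if (weight_scale == "fc") w <- 2^w
      out[[paste(ct, dir)]] <- data.frame(
        cell_type = ct, direction = dir, gene = sel$gene, weight = w,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no gene set could be built")
  gene_sets(do.call(rbind, out))
}
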