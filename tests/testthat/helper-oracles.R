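# Independent brute-force oracles and small fixture builders used across
# the suite. Everything here is deliberately naive so it checks the
# package's vectorised implementations from a different angle.

# dense matrix (with dimnames) -> count_matrix
mk_cm <- function(mat, layer = "raw", kind = "gene") {
  count_matrix(mat, layer = layer, feature_kind = kind)
}

# named gene x cell matrix with default names
named_mat <- function(values, ngenes, ncells, genes = NULL, cells = NULL) {
  matrix(values, nrow = ngenes, ncol = ncells,
         dimnames = list(genes %||% paste0("g", seq_len(ngenes)),
                         cells %||% paste0("c", seq_len(ncells))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(P x G) all-pairs half-open interval overlap: peaks/windows are
# data.frames with chrom/start/end; counts is peaks x cells
oracle_gene_activity <- function(peak_df, counts, win_df) {
  out <- matrix(0, nrow = nrow(win_df), ncol = ncol(counts),
                dimnames = list(win_df$gene, colnames(counts)))
  for (g in seq_len(nrow(win_df))) {
    for (p in seq_len(nrow(peak_df))) {
      if (peak_df$chrom[p] == win_df$chrom[g] &&
          peak_df$start[p] < win_df$end[g] &&
          win_df$start[g] < peak_df$end[p]) {
        out[g, ] <- out[g, ] + counts[p, ]
      }
    }
  }
  out
}

# exact two-sided Wilcoxon p by enumerating every assignment of the
# pooled observations' ranks to the first group (midranks for ties)
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  mu <- nx * (length(pooled) + 1) / 2
  obs <- abs(sum(r[seq_len(nx)]) - mu)
  combos <- utils::combn(length(pooled), nx)
  stats <- abs(colSums(matrix(r[combos], nrow = nx)) - mu)
  mean(stats >= obs - 1e-9)
}

# elementwise reference implementation of the median gating rule
oracle_integrate <- function(rna, atac) {
  out <- rna
  for (j in seq_len(ncol(rna))) {
    med <- stats::median(atac[, j])
    for (i in seq_len(nrow(rna))) {
      out[i, j] <- if (atac[i, j] > med) rna[i, j] else 0
    }
  }
  out
}

# random peak/window instance on a couple of chromosomes
random_overlap_instance <- function(n_peaks, n_genes) {
  chroms <- c("chrA", "chrB")
  pk_chrom <- sample(chroms, n_peaks, replace = TRUE)
  pk_start <- sample.int(5000L, n_peaks, replace = TRUE)
  pk_width <- sample.int(300L, n_peaks, replace = TRUE)
  peak_names <- sprintf("%s:%d-%d", pk_chrom, pk_start, pk_start + pk_width)
  # peak names must be unique for the count matrix
  while (anyDuplicated(peak_names)) {
    d <- which(duplicated(peak_names))
    pk_start[d] <- pk_start[d] + sample.int(500L, length(d), replace = TRUE)
    peak_names <- sprintf("%s:%d-%d", pk_chrom, pk_start, pk_start + pk_width)
  }
  n_cells <- sample(2:6, 1L)
  counts <- named_mat(rpois(n_peaks * n_cells, 3), n_peaks, n_cells,
                      genes = peak_names)
  w_chrom <- sample(chroms, n_genes, replace = TRUE)
  w_start <- sample.int(5000L, n_genes, replace = TRUE)
  w_width <- sample.int(800L, n_genes, replace = TRUE)
  windows <- data.frame(gene = paste0("g", seq_len(n_genes)),
                        chrom = w_chrom, start = w_start,
                        end = w_start + w_width,
                        stringsAsFactors = FALSE)
  list(
    peaks = mk_cm(counts, kind = "peak"),
    peak_df = data.frame(chrom = pk_chrom, start = pk_start,
                         end = pk_start + pk_width,
                         stringsAsFactors = FALSE),
    counts = counts,
    windows = windows
  )
}
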