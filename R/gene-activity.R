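# Peak -> gene activity projection.
#
# Chromatin-accessibility peaks are attributed to genes by summing, per
# cell, the counts of every peak that overlaps the gene body extended a
# fixed distance upstream of the transcription start site. All coordinates
# are 0-based half-open; two intervals overlap iff they share at least one
# base (a.start < b.end AND b.start < a.end).

#' Parse peak feature names into genomic intervals
#'
#' Accepts both common dialects, `"chr1:100-200"` and `"chr1-100-200"`,
#' with 0-based half-open coordinates.
#'
#' @param features character vector of peak names.
#' @return data.frame with columns `peak_id`, `chrom`, `start`, `end`, in
#'   input order.
#' @export
parse_peak_intervals <- function(features) {
  m <- regmatches(features, regexec(peak_regex, features))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("feature name(s) do not parse as peaks: ",
         paste(utils::head(features[bad], 5L), collapse = ", "))
  parts <- do.call(rbind, m)
  out <- data.frame(
    peak_id = features,
    chrom = parts[, 2L],
    start = as.integer(parts[, 3L]),
    end = as.integer(parts[, 4L]),
    stringsAsFactors = FALSE
  )
  bad <- out$start >= out$end
  if (any(bad))
    stop("peak(s) with start >= end: ",
         paste(utils::head(features[bad], 5L), collapse = ", "))
  out
}

#' Build per-gene accessibility windows
#'
#' The window of a gene is its annotated body extended `upstream_bp` bases
#' upstream: `[start - upstream_bp, end)` on the `+` (or unknown) strand,
#' `[start, end + upstream_bp)` on the `-` strand, clipped at the
#' chromosome origin. Duplicate gene names keep the longest annotation
#' (with a warning).
#'
#' @param annotations data.frame as returned by [read_gene_annotations()].
#' @param upstream_bp non-negative upstream extension in base pairs
#'   (default 2000).
#' @param use which annotation column names the gene.
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
build_gene_windows <- function(annotations, upstream_bp = 2000,
                               use = c("gene_name", "gene_id")) {
  use <- match.arg(use)
  if (!is.data.frame(annotations) || nrow(annotations) == 0L)
    stop("empty annotation list")
  if (upstream_bp < 0) stop("upstream_bp must be non-negative")
  gene <- as.character(annotations[[use]])
  strand <- as.character(annotations$strand)
  start <- ifelse(strand == "-",
                  annotations$start,
                  pmax(0L, annotations$start - as.integer(upstream_bp)))
  end <- ifelse(strand == "-",
                annotations$end + as.integer(upstream_bp),
                annotations$end)
  win <- data.frame(gene = gene, chrom = as.character(annotations$chrom),
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(win$gene)) {
    dups <- unique(win$gene[duplicated(win$gene)])
    warning(length(dups), " duplicated gene name(s); keeping the longest ",
            "annotation for each")
    len <- win$end - win$start
    keep <- order(-len)                 # longest first, ties by input order
    win <- win[keep, , drop = FALSE]
    win <- win[!duplicated(win$gene), , drop = FALSE]
    win <- win[order(match(win$gene, gene)), , drop = FALSE]
  }
  rownames(win) <- NULL
  win
}

#' Project peak counts to gene activity
#'
#' `activity(g, c)` is the sum over all peaks overlapping gene `g`'s
#' window of their counts in cell `c`. A peak overlapping several windows
#' contributes its full count to each; genes with no overlapping peak are
#' kept as all-zero rows.
#'
#' @param peaks a [count_matrix] with `feature_kind = "peak"`, raw layer.
#' @param windows data.frame from [build_gene_windows()].
#' @return A gene x cell [count_matrix] with `layer = "raw"`.
#' @export
compute_gene_activity <- function(peaks, windows) {
  stopifnot_cm(peaks, layer = "raw", what = "peaks")
  if (cm_feature_kind(peaks) != "peak")
    stop("peaks must have feature_kind 'peak'")
  if (!is.data.frame(windows) || nrow(windows) == 0L)
    stop("need at least one gene window")

  pk <- parse_peak_intervals(cm_features(peaks))
  # 0-based half-open -> 1-based closed; >=1 shared base is then plain
  # closed-interval overlap
  pk_gr <- GenomicRanges::GRanges(
    pk$chrom, IRanges::IRanges(pk$start + 1L, pk$end))
  win_gr <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start + 1L, windows$end))
  # disjoint chromosome sets are a valid no-overlap case, not a warning
  hits <- suppressWarnings(GenomicRanges::findOverlaps(win_gr, pk_gr))

  incidence <- Matrix::sparseMatrix(
    i = S4Vectors::queryHits(hits),
    j = S4Vectors::subjectHits(hits),
    x = 1,
    dims = c(nrow(windows), nrow(pk))
  )
  act <- incidence %*% cm_values(peaks)
  dimnames(act) <- list(windows$gene, cm_barcodes(peaks))
  count_matrix(act, layer = "raw", feature_kind = "gene")
}
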