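#' Read a 10x-style Matrix Market count directory
#'
#' Loads a triplet directory (`matrix.mtx`, `features.tsv` or `genes.tsv`,
#' `barcodes.tsv`, each optionally gzipped) into a [count_matrix] with
#' `layer = "raw"`. The feature kind is inferred: if at least 90% of feature
#' names parse as peak strings (`"chrom:start-end"` or `"chrom-start-end"`)
#' the matrix is tagged `peak`, otherwise `gene`. Duplicate feature names
#' are disambiguated by suffixing `.1`, `.2`, ... (with a warning) so the
#' matrix shape is preserved.
#'
#' @param dir path to the directory holding the triplet files.
#' @param feature_column which column of the features file carries the
#'   identifier to use. Default: column 2 when the file has two or more
#'   columns (the gene-symbol column of 10x `features.tsv`), else column 1.
#' @return A [count_matrix] with `layer = "raw"`.
#' @seealso [write_counts_10x()]
#' @export
read_counts_10x <- function(dir, feature_column = NULL) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  mtx <- find_10x_file(dir, c("matrix.mtx"))
  feat <- find_10x_file(dir, c("features.tsv", "genes.tsv", "features.txt"))
  bc <- find_10x_file(dir, c("barcodes.tsv", "barcodes.txt"))

  values <- as_dgc(Matrix::readMM(open_maybe_gz(mtx)))
  feat_tab <- utils::read.delim(feat, header = FALSE,
                                colClasses = "character", quote = "")
  barcodes <- readLines(bc)
  barcodes <- barcodes[nzchar(barcodes)]

  fc <- feature_column %||% (if (ncol(feat_tab) >= 2L) 2L else 1L)
  if (fc > ncol(feat_tab))
    stop("feature file ", basename(feat), " has no column ", fc)
  features <- feat_tab[[fc]]

  if (nrow(values) != length(features))
    stop(sprintf("matrix header says %d features but %s lists %d",
                 nrow(values), basename(feat), length(features)))
  if (ncol(values) != length(barcodes))
    stop(sprintf("matrix header says %d cells but %s lists %d",
                 ncol(values), basename(bc), length(barcodes)))

  if (anyDuplicated(features)) {
    dups <- unique(features[duplicated(features)])
    warning("disambiguating ", length(dups),
            " duplicated feature name(s) by suffixing: ",
            paste(utils::head(dups, 5L), collapse = ", "),
            if (length(dups) > 5L) ", ...")
    features <- make.unique(features, sep = ".")
  }
  dimnames(values) <- list(features, barcodes)

  kind <- if (peak_parse_rate(features) >= 0.9) "peak" else "gene"
  count_matrix(values, layer = "raw", feature_kind = kind)
}

#' Write a count matrix as a 10x-style triplet directory
#'
#' @param m a [count_matrix].
#' @param dir output directory (created if needed). Writes plain-text
#'   `matrix.mtx`, `features.tsv`, `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_counts_10x <- function(m, dir) {
  stopifnot_cm(m)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm_values(m), file.path(dir, "matrix.mtx"))
  writeLines(cm_features(m), file.path(dir, "features.tsv"))
  writeLines(cm_barcodes(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

find_10x_file <- function(dir, stems) {
  for (stem in stems) {
    for (cand in file.path(dir, c(stem, paste0(stem, ".gz")))) {
      if (file.exists(cand)) return(cand)
    }
  }
  stop("missing file in ", dir, ": expected one of ",
       paste(stems, collapse = ", "), " (optionally .gz)")
}

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

peak_regex <- "^(.*)[:-]([0-9]+)-([0-9]+)$"

peak_parse_rate <- function(features) {
  if (!length(features)) return(0)
  mean(grepl(peak_regex, features))
}

#' Read gene annotations from GTF or BED
#'
#' Returns one record per annotation row with 0-based half-open
#' coordinates. GTF input keeps only rows with feature type `"gene"` and
#' converts from 1-based inclusive (start-1, end); BED coordinates are
#' already 0-based half-open and are taken as-is. Unknown strand (`"*"` or
#' missing) defaults to `"+"` with a warning; records with `start >= end`
#' are dropped with a warning.
#'
#' @param path annotation file (plain or gzipped).
#' @param format `"gtf"` or `"bed"`.
#' @return data.frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
read_gene_annotations <- function(path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(
    {
      if (format == "gtf")
        rtracklayer::import(path, format = "gtf", feature.type = "gene")
      else
        rtracklayer::import(path, format = "bed")
    },
    error = function(e) stop("failed to parse ", format, " file ", path,
                             ": ", conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0L)
    stop("zero usable records in ", path,
         if (format == "gtf") " (no rows with feature type 'gene')" else "")

  md <- S4Vectors::mcols(gr)
  if (format == "gtf") {
    gene_id <- as.character(md$gene_id %||% rep(NA_character_, length(gr)))
    gene_name <- as.character(md$gene_name %||% gene_id)
    gene_name[is.na(gene_name)] <- gene_id[is.na(gene_name)]
    if (anyNA(gene_id))
      stop("GTF gene records without gene_id in ", path)
  } else {
    if (is.null(md$name))
      stop("BED file ", path, " needs at least 4 columns (name in column 4)")
    gene_id <- gene_name <- as.character(md$name)
  }

  strand <- as.character(BiocGenerics::strand(gr))
  n_unknown <- sum(strand == "*")
  if (n_unknown > 0L) {
    warning(n_unknown, " record(s) with unknown strand default to '+'")
    strand[strand == "*"] <- "+"
  }

  out <- data.frame(
    gene_id = gene_id,
    gene_name = gene_name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # to 0-based half-open
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
  bad <- out$start >= out$end
  if (any(bad)) {
    warning("dropping ", sum(bad), " record(s) with start >= end")
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("zero usable records in ", path)
  rownames(out) <- NULL
  out
}

#' Weighted cell-type gene sets: construction and I/O
#'
#' A gene-set table has one row per (cell type, direction, gene) with a
#' strictly positive weight; `direction` is `"up"` or `"down"`. Within a
#' cell type the up and down sets are disjoint and no gene repeats within
#' a set. The on-disk format is TSV with header columns `cell_type`,
#' `direction`, `gene`, `weight`; writing then reading reproduces the
#' table (order preserved within each set).
#'
#' @param x data.frame with columns `cell_type`, `direction`, `gene`,
#'   `weight`.
#' @return `gene_sets()` returns the validated data.frame;
#'   `read_gene_sets()` the table read from `path`; `write_gene_sets()`
#'   `path`, invisibly.
#' @export
gene_sets <- function(x) {
  need <- c("cell_type", "direction", "gene", "weight")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("gene sets need columns: ", paste(need, collapse = ", "))
  x <- x[, need, drop = FALSE]
  x$cell_type <- as.character(x$cell_type)
  x$direction <- as.character(x$direction)
  x$gene <- as.character(x$gene)
  x$weight <- as.numeric(x$weight)
  bad_dir <- !x$direction %in% c("up", "down")
  if (any(bad_dir))
    stop("unknown direction token(s): ",
         paste(unique(x$direction[bad_dir]), collapse = ", "))
  bad_w <- !is.finite(x$weight) | x$weight <= 0
  if (any(bad_w))
    stop("non-positive or missing weight at row(s): ",
         paste(utils::head(which(bad_w), 5L), collapse = ", "))
  key <- paste(x$cell_type, x$direction, x$gene, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate gene within a set: ",
         paste(utils::head(x$gene[duplicated(key)], 5L), collapse = ", "))
  for (ct in unique(x$cell_type)) {
    up <- x$gene[x$cell_type == ct & x$direction == "up"]
    dn <- x$gene[x$cell_type == ct & x$direction == "down"]
    both <- intersect(up, dn)
    if (length(both))
      stop("up and down sets overlap for cell type ", ct, ": ",
           paste(utils::head(both, 5L), collapse = ", "))
  }
  rownames(x) <- NULL
  x
}

#' @rdname gene_sets
#' @param path TSV file path.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, quote = "",
                           colClasses = "character")
  need <- c("cell_type", "direction", "gene", "weight")
  if (!all(need %in% names(tab)))
    stop("gene-set file ", path, " must have header columns: ",
         paste(need, collapse = ", "))
  tab <- tab[, need, drop = FALSE]
  w <- suppressWarnings(as.numeric(tab$weight))
  bad <- is.na(w) | w <= 0
  if (any(bad))
    stop("non-positive or unparseable weight in ", path, " at data row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  tab$weight <- w
  gene_sets(tab)
}

#' @rdname gene_sets
#' @param sets gene-set data.frame (validated on write).
#' @export
write_gene_sets <- function(sets, path) {
  sets <- gene_sets(sets)
  utils::write.table(sets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Import GMT gene sets as unit-weight sets
#'
#' Convenience importer for plain GMT files, which carry no per-gene
#' weights: every gene receives weight 1 and the given direction.
#'
#' @param path GMT file.
#' @param direction direction to assign to every imported set.
#' @return gene-set data.frame as in [gene_sets()].
#' @export
read_gmt <- function(path, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  rows <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("GMT line with fewer than 3 fields in ", path)
    data.frame(cell_type = parts[1L], direction = direction,
               gene = unique(parts[-(1:2)]), weight = 1,
               stringsAsFactors = FALSE)
  })
  gene_sets(do.call(rbind, rows))
}

#' Read / write per-cell label tables
#'
#' Label files are CSV with a header; the first column is the barcode, the
#' second the label (additional columns such as `top_score`, `margin`,
#' `tie` are preserved on write and ignored on read beyond being kept).
#'
#' @param path CSV file.
#' @return `read_labels()`: a data.frame whose first two columns are
#'   `barcode` and `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("label file needs at least 2 columns: ", path)
  names(tab)[1:2] <- c("barcode", "label")
  tab$barcode <- as.character(tab$barcode)
  tab$label <- as.character(tab$label)
  if (anyDuplicated(tab$barcode))
    stop("duplicate barcodes in label file: ", path)
  tab
}

#' @rdname read_labels
#' @param labels data.frame with barcode in column 1 and label in column 2.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
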