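#' Count matrix container
#'
#' Lightweight S3 container for a genes x samples matrix of read counts, the
#' substrate of every pipeline stage. Samples carry either a time label
#' (hours into constant darkness) or a condition/replicate label.
#'
#' @param counts numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param times numeric vector of sampling times in hours (one per column),
#'   or `NULL` for condition designs.
#' @param condition character/factor vector of condition labels per column,
#'   or `NULL` for time courses.
#' @param assay assay tag, one of `"rna"`, `"rnapii"`, `"generic"`.
#' @param normalized logical, whether counts have been size-factor scaled.
#' @param size_factors per-sample size factors, or `NULL` if not yet computed.
#' @return an object of class `ccg_counts`.
#' @export
ccg_counts <- function(counts, times = NULL, condition = NULL,
                       assay = c("rna", "rnapii", "generic"),
                       normalized = FALSE, size_factors = NULL) {
  assay <- match.arg(assay)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene_%04d", seq_len(nrow(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(times)) {
    stopifnot(length(times) == ncol(counts))
    if (is.null(colnames(counts)))
      colnames(counts) <- sprintf("t%02d", round(times))
  }
  if (!is.null(condition)) stopifnot(length(condition) == ncol(counts))
  if (!is.null(size_factors)) stopifnot(all(size_factors > 0))
  structure(list(counts = counts, times = times,
                 condition = condition, assay = assay,
                 normalized = normalized, size_factors = size_factors),
            class = "ccg_counts")
}

#' @export
print.ccg_counts <- function(x, ...) {
  cat(sprintf("<ccg_counts> %d genes x %d samples, assay=%s, %s\n",
              nrow(x$counts), ncol(x$counts), x$assay,
              if (x$normalized) "normalized" else "raw"))
  if (!is.null(x$times))
    cat("  times (h): ", paste(x$times, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.ccg_counts <- function(x) dim(x$counts)

gene_ids <- function(x) rownames(x$counts)

subset_genes <- function(x, keep) {
  x$counts <- x$counts[keep, , drop = FALSE]
  x
}

#' Median-of-ratios size factors
#'
#' Per gene, the reference is the geometric mean of its counts across samples
#' (genes with any zero count are excluded from the reference set); each
#' sample's size factor is the median over genes of count/reference.
#'
#' @param x a `ccg_counts` object (raw counts) or a numeric matrix.
#' @return named numeric vector of positive per-sample size factors.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
#' size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(x) {
  m <- if (inherits(x, "ccg_counts")) x$counts else as.matrix(x)
  if (ncol(m) < 2) stop("need at least 2 samples")
  ok <- rowSums(m == 0) == 0
  if (!any(ok)) stop("no gene has nonzero counts in every sample")
  lm_ <- log(m[ok, , drop = FALSE])
  ref <- rowMeans(lm_)            # log geometric mean
  sf <- exp(apply(lm_ - ref, 2, median))
  names(sf) <- colnames(m)
  sf
}

#' Normalize counts by size factors
#'
#' @param x a `ccg_counts` object with raw counts.
#' @param sf optional precomputed size factors; computed from `x` if missing.
#' @return `x` with counts divided by size factors and `normalized = TRUE`.
#' @export
normalize_counts <- function(x, sf = NULL) {
  stopifnot(inherits(x, "ccg_counts"))
  if (x$normalized) return(x)
  if (is.null(sf)) sf <- size_factors(x)
  x$counts <- sweep(x$counts, 2, sf, "/")
  x$size_factors <- sf
  x$normalized <- TRUE
  x
}

#' Write / read a count matrix as TSV
#'
#' Columns are `t00,t02,...` for time courses or `<cond>_<rep>` for condition
#' designs; the first column `gene_id` is the row key.
#'
#' @param x a `ccg_counts` object.
#' @param path output file path.
#' @return `write_counts_tsv` returns `path` invisibly; `read_counts_tsv`
#'   returns a `ccg_counts` object (times parsed from `tNN` column names).
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "ccg_counts"))
  cn <- colnames(x$counts)
  if (is.null(cn) && !is.null(x$times))
    cn <- sprintf("t%02d", round(x$times))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  names(df)[-1] <- cn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param assay assay tag for the object read back.
#' @export
read_counts_tsv <- function(path, assay = "generic") {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  cn <- colnames(m)
  times <- if (all(grepl("^t[0-9]+$", cn))) as.numeric(sub("^t", "", cn))
           else NULL
  ccg_counts(m, times = times, assay = assay)
}
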