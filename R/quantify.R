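# Read counting and the bespoke filter chain: exonic / 3'-terminal-window
# counting by the 5'-base rule, the overlap influence factor, low-expression
# and ChIP background filters.

# Count 5' read positions falling into per-gene interval sets.
# intervals: data.frame(gene_id, chrom, start, end) 0-based half-open.
count_positions <- function(reads, intervals, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(reads$sample))
  gene_ids <- unique(intervals$gene_id)
  m <- matrix(0L, length(gene_ids), length(samples),
              dimnames = list(gene_ids, samples))
  unassigned <- 0L
  p5 <- read_5prime(reads)
  for (chr in unique(reads$chrom)) {
    ri <- which(reads$chrom == chr)
    iv <- intervals[intervals$chrom == chr, , drop = FALSE]
    if (nrow(iv) == 0) { unassigned <- unassigned + length(ri); next }
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(p5[ri] + 1L, width = 1L),
      IRanges::IRanges(iv$start + 1L, iv$end))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    unassigned <- unassigned + sum(!seq_along(ri) %in% unique(q))
    if (length(q)) {
      # a read overlapping two exons of the same gene counts once
      key <- unique(data.frame(read = ri[q], gene = iv$gene_id[s]))
      tab <- table(factor(key$gene, levels = gene_ids),
                   factor(reads$sample[key$read], levels = samples))
      m <- m + as.matrix(unclass(tab))
    }
  }
  list(counts = m, unassigned = unassigned)
}

#' Count reads in annotated exons
#'
#' A read is assigned to a gene if its 5'-most aligned base (strand-aware)
#' lies within any exon of the gene; a read whose 5' base falls in exons of
#' two overlapping genes increments both (contamination is handled downstream
#' by the influence filter). Counting is unstranded with respect to the gene.
#'
#' @param reads data.frame of read intervals
#'   (`chrom, start, end, sample, strand`), 0-based half-open.
#' @param annotation a `gene_annotation`.
#' @param assay assay tag for the result.
#' @param times optional per-sample times (hours) for the result.
#' @return `ccg_counts` (genes x samples); reads assigned to no exon or to an
#'   unannotated chromosome are tallied in the `unassigned` attribute.
#' @export
count_exonic <- function(reads, annotation, assay = "rna", times = NULL) {
  stopifnot(inherits(annotation, "gene_annotation"))
  res <- count_positions(reads, annotation$exons)
  # keep annotation gene order
  m <- res$counts[match(annotation$genes$gene_id, rownames(res$counts)), ,
                  drop = FALSE]
  out <- ccg_counts(m, times = times, assay = assay)
  attr(out, "unassigned") <- res$unassigned
  out
}

#' Count reads in 3'-terminal windows
#'
#' The window is the `window_bp` interval ending at the gene's 3' end in
#' transcription orientation: `[end - window_bp, end)` on the plus strand,
#' `[start, start + window_bp)` on the minus strand, truncated at the gene
#' boundary for genes shorter than the window. Read assignment uses the
#' 5'-base rule. This quantifies elongating/terminating polymerase occupancy,
#' which accumulates toward gene ends.
#'
#' @inheritParams count_exonic
#' @param window_bp window length (default 500).
#' @return `ccg_counts` with assay `"rnapii"`.
#' @export
count_terminal_window <- function(reads, annotation, window_bp = 500,
                                  times = NULL) {
  stopifnot(window_bp > 0, inherits(annotation, "gene_annotation"))
  g <- annotation$genes
  win <- data.frame(
    gene_id = g$gene_id, chrom = g$chrom,
    start = ifelse(g$strand == "-", g$start,
                   pmax(g$start, g$end - window_bp)),
    end = ifelse(g$strand == "-", pmin(g$end, g$start + window_bp),
                 g$end),
    stringsAsFactors = FALSE)
  res <- count_positions(reads, win)
  m <- res$counts[match(g$gene_id, rownames(res$counts)), , drop = FALSE]
  out <- ccg_counts(m, times = times, assay = "rnapii")
  attr(out, "unassigned") <- res$unassigned
  attr(out, "windows") <- win
  out
}

#' Overlap influence factor
#'
#' Ratio of a gene's overall read density to its density outside regions
#' shared with neighbouring genes:
#' `Influence = (G / L_G) / ((G - O) / (L_G - L_O))`, where `G` is the read
#' count mapped to the gene, `L_G` the gene length, `O` the read count in
#' the overlap region and `L_O` the overlap length. Values much above 1 flag
#' read contamination from a neighbour.
#'
#' @param G total read count of the gene (`G >= O`).
#' @param L_G gene length in bp (`L_G > L_O`).
#' @param O read count in the overlap region.
#' @param L_O overlap length in bp.
#' @return the influence ratio; 1 when there is no overlap (`O = L_O = 0`),
#'   `Inf` when all reads sit in the overlap (`G = O > 0`). Vectorized.
#' @examples
#' influence_factor(100, 1000, 60, 200)  # 2
#' @export
influence_factor <- function(G, L_G, O, L_O) {
  if (any(O > G)) stop("O cannot exceed G")
  if (any(L_O >= L_G)) stop("L_O must be smaller than L_G")
  if (any(O < 0) || any(L_O < 0)) stop("O and L_O must be non-negative")
  ifelse(O == 0 & L_O == 0, 1,
         ifelse(G == O & G > 0, Inf,
                (G / L_G) / ((G - O) / (L_G - L_O))))
}

#' Remove overlap-contaminated genes
#'
#' Computes each gene's influence factor on counts summed over all samples of
#' the assay (one decision per gene) and removes genes whose factor strictly
#' exceeds the threshold. `O` comes from read-level data when `reads` is
#' given, or from an `overlap_counts` matrix (as attached by
#' [simulate_timecourse()]).
#'
#' @param counts `ccg_counts` (raw, before normalization).
#' @param annotation a `gene_annotation`.
#' @param reads optional read data.frame used to count overlap-region reads.
#' @param overlap_counts optional genes x samples matrix of overlap-region
#'   read counts (used when `reads` is absent; defaults to the counts'
#'   `overlap_counts` attribute).
#' @param threshold removal threshold (strictly greater than; default 2).
#' @return filtered `ccg_counts`; the per-gene report (gene, G, O, L_G, L_O,
#'   influence, removed) is attached as attribute `filter_report`.
#' @export
apply_influence_filter <- function(counts, annotation, reads = NULL,
                                   overlap_counts = NULL, threshold = 2) {
  stopifnot(inherits(counts, "ccg_counts"),
            inherits(annotation, "gene_annotation"))
  if (counts$normalized) stop("apply before normalization")
  ids <- gene_ids(counts)
  g <- annotation$genes[match(ids, annotation$genes$gene_id), ]
  L_G <- g$end - g$start
  ovreg <- gene_overlap_regions(annotation)
  L_O <- setNames(rep(0L, length(ids)), ids)
  for (gid in names(ovreg))
    if (gid %in% ids)
      L_O[gid] <- sum(ovreg[[gid]]$end - ovreg[[gid]]$start)
  G <- rowSums(counts$counts)
  O <- setNames(rep(0, length(ids)), ids)
  if (!is.null(reads)) {
    iv <- do.call(rbind, lapply(names(ovreg), function(gid)
      cbind(gene_id = gid, ovreg[[gid]])))
    if (!is.null(iv) && nrow(iv) > 0) {
      res <- count_positions(reads, iv, samples = colnames(counts$counts))
      O[rownames(res$counts)] <- rowSums(res$counts)
    }
  } else {
    oc <- overlap_counts %||% attr(counts, "overlap_counts")
    if (!is.null(oc)) O[rownames(oc)] <- rowSums(oc)
  }
  infl <- influence_factor(G, L_G, O, L_O)
  removed <- infl > threshold          # Inf > any finite threshold
  report <- data.frame(gene_id = ids, G = G, O = O, L_G = L_G, L_O = L_O,
                       influence = infl, removed = removed,
                       row.names = NULL, stringsAsFactors = FALSE)
  out <- subset_genes(counts, !removed)
  attr(out, "filter_report") <- report
  attr(out, "overlap_counts") <- attr(counts, "overlap_counts")
  out
}

#' Remove lowly expressed genes
#'
#' Ranks genes by mean normalized count across samples and drops the lowest
#' `quantile` fraction (`floor(n * quantile)` genes). Ties are broken by
#' stable input order: among equal means, earlier genes are removed first.
#'
#' @param counts normalized `ccg_counts`.
#' @param quantile fraction to remove (default 0.20).
#' @return filtered `ccg_counts` with a `filter_report` attribute.
#' @export
filter_low_expression <- function(counts, quantile = 0.20) {
  stopifnot(inherits(counts, "ccg_counts"),
            quantile >= 0, quantile < 1)
  if (!counts$normalized) stop("normalize counts first (size factors)")
  n <- nrow(counts$counts)
  k <- floor(n * quantile)
  means <- rowMeans(counts$counts)
  o <- order(means)                       # stable: ties keep input order
  removed_idx <- o[seq_len(k)]
  removed <- seq_len(n) %in% removed_idx
  out <- subset_genes(counts, !removed)
  attr(out, "filter_report") <- data.frame(
    gene_id = gene_ids(counts), mean_norm = means, removed = removed,
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' ChIP background filter from non-coding windows
#'
#' Samples `n_windows` non-overlapping windows of `window_bp` from regions at
#' least `min_gene_distance` bp from any gene, counts the RNAPII-S2P reads
#' falling into each (5'-base rule), and takes the median window count as the
#' background cutoff. Genes whose median terminal-window count across time
#' points is below the cutoff are removed.
#'
#' @param counts terminal-window `ccg_counts` for the RNAPII-S2P assay.
#' @param reads the RNAPII-S2P read set used for counting.
#' @param annotation a `gene_annotation` (with chromosome lengths).
#' @param n_windows number of background windows (default 2000, capped at
#'   what fits; an error if fewer than `min_windows` fit).
#' @param min_gene_distance minimum distance from any gene (default 1000 bp).
#' @param window_bp window size (default 500).
#' @param seed RNG seed for window placement.
#' @param min_windows minimum acceptable number of placeable windows.
#' @return filtered `ccg_counts`; attributes `background_cutoff`,
#'   `background_counts` and `filter_report`.
#' @export
chip_background_filter <- function(counts, reads, annotation,
                                   n_windows = 2000,
                                   min_gene_distance = 1000,
                                   window_bp = 500, seed = 1,
                                   min_windows = 20) {
  stopifnot(inherits(counts, "ccg_counts"),
            inherits(annotation, "gene_annotation"))
  # candidate slots: tile the gene-free space of each chromosome
  slots <- list()
  for (chr in names(annotation$chrom_lengths)) {
    len <- annotation$chrom_lengths[[chr]]
    g <- annotation$genes[annotation$genes$chrom == chr, , drop = FALSE]
    excl <- IRanges::reduce(IRanges::IRanges(
      pmax(g$start - min_gene_distance, 0) + 1L,
      pmin(g$end + min_gene_distance, len)))
    free <- IRanges::setdiff(IRanges::IRanges(1L, len), excl)
    for (j in seq_along(free)) {
      s <- IRanges::start(free)[j] - 1L; e <- IRanges::end(free)[j]
      nslot <- (e - s) %/% window_bp
      if (nslot > 0)
        slots[[length(slots) + 1L]] <- data.frame(
          chrom = chr, start = s + (seq_len(nslot) - 1L) * window_bp,
          stringsAsFactors = FALSE)
    }
  }
  slots <- if (length(slots)) do.call(rbind, slots) else
    data.frame(chrom = character(), start = integer())
  if (nrow(slots) < min_windows)
    stop("genome too small to place background windows at this distance")
  take <- min(n_windows, nrow(slots))
  pick <- with_seed(seed, sample(nrow(slots), take))
  win <- data.frame(gene_id = sprintf("bgwin_%05d", seq_len(take)),
                    chrom = slots$chrom[pick], start = slots$start[pick],
                    end = slots$start[pick] + window_bp,
                    stringsAsFactors = FALSE)
  bg <- count_positions(reads, win, samples = colnames(counts$counts))
  bg_total <- rowSums(bg$counts)
  cutoff <- median(bg_total / ncol(counts$counts))  # per-sample scale
  signal <- apply(counts$counts, 1, median)
  removed <- signal < cutoff
  out <- subset_genes(counts, !removed)
  attr(out, "background_cutoff") <- cutoff
  attr(out, "background_counts") <- bg_total
  attr(out, "filter_report") <- data.frame(
    gene_id = gene_ids(counts), median_signal = signal, removed = removed,
    row.names = NULL, stringsAsFactors = FALSE)
  out
}
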