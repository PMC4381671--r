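#' Gene annotation container
#'
#' Gene models with exon structure on one or more chromosomes. Coordinates
#' are stored 0-based half-open internally; GFF3 I/O converts to/from the
#' 1-based closed convention at the boundary.
#'
#' @param genes data.frame with columns `gene_id, chrom, start, end, strand`
#'   (0-based half-open, strand `"+"`/`"-"`).
#' @param exons data.frame with columns `gene_id, chrom, start, end`.
#' @param chrom_lengths named integer vector of chromosome lengths; inferred
#'   as `max(end)` per chromosome when missing.
#' @return an object of class `gene_annotation` with a precomputed pairwise
#'   `overlaps` table (gene_id, partner_id, start, end, length) from
#'   unstranded gene-span intersection.
#' @export
gene_annotation <- function(genes, exons, chrom_lengths = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)),
            all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
  if (any(genes$end <= genes$start)) stop("gene end must exceed start")
  ex <- merge(exons, genes[, c("gene_id", "start", "end")],
              by = "gene_id", suffixes = c("", ".g"))
  if (any(ex$start < ex$start.g | ex$end > ex$end.g))
    stop("exons must lie within their gene span")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(genes$end, genes$chrom, max)
    chrom_lengths <- setNames(as.integer(chrom_lengths),
                              names(chrom_lengths))
  }
  ann <- structure(list(genes = genes, exons = exons,
                        chrom_lengths = chrom_lengths),
                   class = "gene_annotation")
  ann$overlaps <- compute_overlaps(ann)
  ann
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d genes, %d exons, %d chromosome(s), %d overlap record(s)\n",
              nrow(x$genes), nrow(x$exons), length(x$chrom_lengths),
              nrow(x$overlaps)))
  invisible(x)
}

# Pairwise gene-span overlaps (unstranded), one row per ordered (gene,
# partner) pair.
compute_overlaps <- function(ann) {
  g <- ann$genes
  out <- list()
  for (chr in unique(g$chrom)) {
    gi <- g[g$chrom == chr, ]
    if (nrow(gi) < 2) next
    ir <- IRanges::IRanges(start = gi$start + 1L, end = gi$end)
    hits <- IRanges::findOverlaps(ir, drop.self = TRUE,
                                  drop.redundant = FALSE)
    if (length(hits) == 0) next
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    os <- pmax(gi$start[q], gi$start[s])
    oe <- pmin(gi$end[q], gi$end[s])
    out[[chr]] <- data.frame(gene_id = gi$gene_id[q],
                             partner_id = gi$gene_id[s],
                             chrom = chr, start = os, end = oe,
                             length = oe - os,
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(), partner_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), length = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Per-gene aggregate overlap: reduced union of all overlap spans, with total
# length L_O.
gene_overlap_regions <- function(ann) {
  ov <- ann$overlaps
  if (nrow(ov) == 0) return(split(ov, character(0)))
  lapply(split(ov, ov$gene_id), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(chrom = d$chrom[1],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
}

#' Write / read annotation as GFF3
#'
#' Emits `gene` and `exon` features with `ID`/`Parent` attributes, 1-based
#' closed coordinates.
#'
#' @param ann a `gene_annotation` object.
#' @param path file path.
#' @return `write_gff3` returns `path` invisibly; `read_gff3` a
#'   `gene_annotation`.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  g <- ann$genes; e <- ann$exons
  e <- e[order(match(e$gene_id, g$gene_id), e$start), ]
  gr_g <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id)
  strand_e <- g$strand[match(e$gene_id, g$gene_id)]
  gr_e <- GenomicRanges::GRanges(
    e$chrom, IRanges::IRanges(e$start + 1L, e$end), strand = strand_e,
    type = "exon", ID = paste0(e$gene_id, ".exon",
                               unlist(lapply(table(factor(e$gene_id, levels = unique(e$gene_id))), seq_len))),
    Parent = e$gene_id)
  gr <- c(gr_g, gr_e)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr),
                 S4Vectors::mcols(gr)$type == "exon")]
  GenomeInfoDb::seqlengths(gr) <- ann$chrom_lengths[
    GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  gg <- gr[is_gene]
  genes <- data.frame(
    gene_id = as.character(S4Vectors::mcols(gg)$ID),
    chrom = as.character(GenomicRanges::seqnames(gg)),
    start = GenomicRanges::start(gg) - 1L,
    end = GenomicRanges::end(gg),
    strand = as.character(GenomicRanges::strand(gg)),
    stringsAsFactors = FALSE)
  ge <- gr[md$type == "exon"]
  parent <- as.character(unlist(S4Vectors::mcols(ge)$Parent))
  exons <- data.frame(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(ge)),
    start = GenomicRanges::start(ge) - 1L,
    end = GenomicRanges::end(ge),
    stringsAsFactors = FALSE)
  sl <- GenomeInfoDb::seqlengths(gr)
  cl <- if (all(!is.na(sl))) sl else NULL
  gene_annotation(genes, exons, chrom_lengths = cl)
}

#' Write / read read positions as BED6
#'
#' Reads are intervals whose 5'-most base (strand-aware) is the position used
#' for counting; the BED `name` field carries the sample label.
#'
#' @param reads data.frame with columns `chrom, start, end, sample, strand`
#'   (0-based half-open).
#' @param path file path.
#' @return `write_bed` returns `path` invisibly; `read_bed` the data.frame.
#' @export
write_bed <- function(reads, path) {
  gr <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(reads$start + 1L, reads$end),
    strand = reads$strand, name = reads$sample, score = 0L)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             sample = S4Vectors::mcols(gr)$name,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

# 5'-most aligned base of each read (0-based position).
read_5prime <- function(reads) {
  ifelse(reads$strand == "-", reads$end - 1L, reads$start)
}
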