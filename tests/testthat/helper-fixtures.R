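# Shared fixtures, all built in code.

tiny_times <- seq(0, 22, by = 2)

# Two genes overlapping by 200 bp plus a disjoint two-exon gene, with
# coordinates simple enough for hand enumeration.
tiny_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 2800L, 500L),
    end   = c(3000L, 4800L, 2500L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gB", "gC", "gC"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(1000L, 2800L, 500L, 1700L),
    end   = c(3000L, 4800L, 1100L, 2500L),
    stringsAsFactors = FALSE)
  gene_annotation(genes, exons,
                  chrom_lengths = c(chr1 = 20000L, chr2 = 20000L))
}

# One read per row; plus-strand reads of length 10 whose 5' base is `pos`.
reads_at <- function(pos, chrom = "chr1", sample = "t00", strand = "+") {
  n <- length(pos)
  data.frame(chrom = rep_len(chrom, n),
             start = ifelse(rep_len(strand, n) == "-", pos - 9L, pos),
             end = ifelse(rep_len(strand, n) == "-", pos + 1L, pos + 10L),
             sample = rep_len(sample, n), strand = rep_len(strand, n),
             stringsAsFactors = FALSE)
}

# Noiseless NB-free cosine series on the standard sampling grid.
cosine_series <- function(mean_log = 5, A = 0.55, phase = 6, period = 22,
                          times = tiny_times) {
  round(exp(mean_log + A * cos(2 * pi / period * (times - phase))))
}

# Independent brute-force NB exact test: double loop over (a, b) outcomes,
# deliberately naive (no vectorization tricks shared with the implementation).
brute_exact_pvalue <- function(gt, gc, var_fn) {
  s <- gt + gc
  if (s == 0) return(1)
  m <- s / 2
  v <- var_fn(m)
  f <- function(x) {
    if (v <= m) dpois(x, m)
    else dnbinom(x, mu = m, size = m^2 / (v - m))
  }
  fobs <- f(gt) * f(gc)
  num <- 0; den <- 0
  for (a in 0:s) {
    fab <- f(a) * f(s - a)
    den <- den + fab
    if (fab <= fobs * (1 + 1e-10)) num <- num + fab
  }
  num / den
}
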