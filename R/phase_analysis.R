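# Integration of RNA and RNAPII-S2P rhythm results: concordance groups,
# the robust-oscillator set, dawn/dusk composition, cross-genotype phase
# shifts and set overlaps.

#' Classify genes into transcription/RNA concordance groups
#'
#' Group 1: RNA and RNAPII-S2P phases agree within the tolerance and at
#' least one profile is significantly rhythmic. Group 2: significantly
#' rhythmic RNAPII-S2P with RNA either non-significant or out of phase
#' (rhythmic transcription of a stable transcript). Group 3: significantly
#' rhythmic RNA with RNAPII-S2P non-significant or out of phase. Precedence
#' is Group 1, then 2, then 3 (concordance first); genes significant in
#' neither assay are `none`. The groups partition the genes significant in
#' at least one assay.
#'
#' @param rna,chip rhythm tables (e.g. from [rhythm_analysis()]) with
#'   columns `gene`, `p_value`, `phase`.
#' @param alpha significance threshold (default 0.05).
#' @param in_phase_tol_hours circular phase-agreement tolerance (default 3).
#' @param period period for circular arithmetic (default 22).
#' @return data.frame: gene, p_rna, p_chip, phase_rna, phase_chip,
#'   phase_diff, in_phase, group (`"1"`, `"2"`, `"3"`, `"none"`),
#'   both_significant. Genes present in only one table are excluded and
#'   recorded in the `excluded` attribute.
#' @export
classify_groups <- function(rna, chip, alpha = 0.05,
                            in_phase_tol_hours = 3, period = 22) {
  shared <- intersect(rna$gene, chip$gene)
  excluded <- setdiff(union(rna$gene, chip$gene), shared)
  r <- rna[match(shared, rna$gene), ]
  c_ <- chip[match(shared, chip$gene), ]
  pd <- phase_difference(r$phase, c_$phase, period)
  in_phase <- !is.na(pd) & pd <= in_phase_tol_hours
  sig_r <- r$p_value < alpha
  sig_c <- c_$p_value < alpha
  group <- ifelse(in_phase & (sig_r | sig_c), "1",
           ifelse(sig_c, "2",
           ifelse(sig_r, "3", "none")))
  out <- data.frame(gene = shared, p_rna = r$p_value, p_chip = c_$p_value,
                    phase_rna = r$phase, phase_chip = c_$phase,
                    phase_diff = pd, in_phase = in_phase, group = group,
                    both_significant = sig_r & sig_c,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  attr(out, "group_sizes") <- c(table(factor(group,
                                             c("1", "2", "3", "none"))),
                                both = sum(sig_r & sig_c))
  out
}

#' Robust-oscillator set
#'
#' Genes with fold amplitude strictly above `amp_threshold` and FDR strictly
#' below `fdr_threshold` - the high-confidence clock-controlled set.
#'
#' @param fits data.frame with `gene`, `fold_amplitude` and an `fdr` column
#'   (e.g. from [assign_fdr()]).
#' @param amp_threshold fold-amplitude threshold (default 3, strict `>`).
#' @param fdr_threshold FDR threshold (default 0.05, strict `<`).
#' @return character vector of gene ids.
#' @export
robust_oscillators <- function(fits, amp_threshold = 3,
                               fdr_threshold = 0.05) {
  fits$gene[fits$fold_amplitude > amp_threshold &
              fits$fdr < fdr_threshold]
}

#' Phase comparison between two conditions
#'
#' For genes rhythmic in condition A, records both fitted phases, the signed
#' circular shift B - A, a similar/shifted classification at the given
#' tolerance, and whether the gene's rhythm in B is itself significant.
#' Genes not expressed (absent) in B are dropped and counted.
#'
#' @param fits_A,fits_B rhythm tables with `gene`, `phase`, `p_value`.
#' @param rhythmic_A character vector of genes rhythmic in A.
#' @param similar_tol_hours absolute-shift threshold separating `similar`
#'   from `shifted` (default 4).
#' @param period period for circular arithmetic (default 22).
#' @return data.frame (PhaseShiftRecord): gene, phase_A, phase_B, shift
#'   (signed hours, `|shift| <= period/2`), classification, rhythmic_in_B;
#'   attribute `n_dropped` counts genes absent from B.
#' @export
compare_phase_between_conditions <- function(fits_A, fits_B, rhythmic_A,
                                             similar_tol_hours = 4,
                                             period = 22) {
  keep <- rhythmic_A[rhythmic_A %in% fits_B$gene]
  a <- fits_A[match(keep, fits_A$gene), ]
  b <- fits_B[match(keep, fits_B$gene), ]
  shift <- phase_shift_signed(a$phase, b$phase, period)
  out <- data.frame(
    gene = keep, phase_A = a$phase, phase_B = b$phase, shift = shift,
    classification = ifelse(abs(shift) <= similar_tol_hours,
                            "similar", "shifted"),
    rhythmic_in_B = b$p_value < 0.05,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!rhythmic_A %in% fits_B$gene)
  out
}

#' Overlap summary of two gene sets
#'
#' Set sizes, intersection/differences, hypergeometric enrichment p-value of
#' the overlap, and optional phase histograms in 2 h bins (rose-plot table).
#'
#' @param set_A,set_B character vectors of gene ids (subsets of `universe`).
#' @param universe character vector, the shared gene universe.
#' @param phases_A,phases_B optional named phase vectors (CT hours) for the
#'   histogram export.
#' @param period period for the phase bins (default 22).
#' @param bin_hours histogram bin width (default 2).
#' @return list with `n_A`, `n_B`, `n_intersect`, `n_A_only`, `n_B_only`,
#'   `n_universe`, `p_hypergeometric`, and `phase_hist_A`/`phase_hist_B`
#'   data.frames (bin start, count) when phases are given.
#' @export
overlap_summary <- function(set_A, set_B, universe,
                            phases_A = NULL, phases_B = NULL,
                            period = 22, bin_hours = 2) {
  if (!all(set_A %in% universe) || !all(set_B %in% universe))
    stop("sets must be subsets of the universe")
  set_A <- unique(set_A); set_B <- unique(set_B)
  k <- length(intersect(set_A, set_B))
  N <- length(universe)
  p_hyp <- phyper(k - 1, length(set_A), N - length(set_A),
                  length(set_B), lower.tail = FALSE)
  hist_tab <- function(ph) {
    if (is.null(ph)) return(NULL)
    br <- seq(0, period, by = bin_hours)
    if (br[length(br)] < period) br <- c(br, period)
    idx <- findInterval(ph %% period, br, rightmost.closed = TRUE,
                        all.inside = TRUE)
    data.frame(bin_start = br[-length(br)],
               count = tabulate(idx, nbins = length(br) - 1))
  }
  list(n_A = length(set_A), n_B = length(set_B), n_intersect = k,
       n_A_only = length(setdiff(set_A, set_B)),
       n_B_only = length(setdiff(set_B, set_A)),
       n_universe = N, p_hypergeometric = p_hyp,
       phase_hist_A = hist_tab(phases_A), phase_hist_B = hist_tab(phases_B))
}
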