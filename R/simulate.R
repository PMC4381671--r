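#' Simulation configuration
#'
#' The stated world of the synthetic generator: 12 time points at 2 h spacing
#' over one ~22 h free-running cycle in constant darkness, negative-binomial
#' counts with a smooth mean-variance relation, a dawn/dusk bimodal phase
#' mixture, a light-inflated t = 0 subset, overlapping gene pairs with read
#' bleed-through, and RNA rhythms derived from transcription rhythms through
#' first-order degradation kinetics.
#'
#' Rhythms are log-linear cosines: mu_g(t) = m_g * exp(A_g cos(w (t - phi_g)))
#' with w = 2 pi / period, so the peak/trough fold amplitude is exp(2 A_g).
#'
#' @param n_genes number of genes.
#' @param n_timepoints number of samples (default 12).
#' @param dt_hours sampling interval in hours (default 2).
#' @param period_hours free-running period (default 22).
#' @param frac_rhythmic fraction of rhythmic genes.
#' @param phase_mixture list with dawn/dusk circular component means (CT
#'   hours), weight of the dawn component, and wrapped-normal sd (hours).
#' @param amplitude_dist function(n) drawing fold amplitudes (>= 1); default
#'   lognormal, median 2.5.
#' @param mean_expr_dist function(n) drawing baseline mean counts; default
#'   lognormal, median 200.
#' @param dispersion_fn function(mu) returning the NB variance; default
#'   var = mu + phi(mu) mu^2 with phi(mu) = phi0 (1 + c/mu), phi0 = 0.05,
#'   c = 5 (dispersion decreasing with mean).
#' @param frac_light_spike fraction of genes whose t = 0 mean is inflated.
#' @param light_spike_factor multiplicative t = 0 inflation (default 4).
#' @param n_overlap_pairs number of overlapping gene pairs in the toy
#'   annotation.
#' @param overlap_bp length of each overlap region (default 200).
#' @param bleed_rate bleed-through read density in the overlap region, as a
#'   fraction of the weaker partner's local read density (default 0.3).
#' @param degradation_rate_dist function(n) drawing RNA turnover rates k in
#'   1/hour; default lognormal around a ~2 h half-life, spanning roughly
#'   0.5-8 h half-lives as typical for fungal mRNAs.
#' @param archetype_mix named proportions over the rhythmic-gene archetypes
#'   `concordant` (fast turnover, in-phase RNA), `stable_transcript` (slow
#'   turnover: delayed, blunted RNA rhythm) and `rna_only` (RNA rhythm with
#'   flat transcription).
#' @param seed master RNG seed; every generator call derives its own stream.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000,
                       n_timepoints = 12,
                       dt_hours = 2,
                       period_hours = 22,
                       frac_rhythmic = 0.35,
                       phase_mixture = list(dawn_mean = 0, dusk_mean = 11,
                                            dawn_weight = 0.5, sd_hours = 1.5),
                       amplitude_dist = function(n)
                         exp(rlnorm(n, meanlog = log(log(2.5)), sdlog = 0.4)),
                       mean_expr_dist = function(n)
                         rlnorm(n, meanlog = log(200), sdlog = 1.2),
                       dispersion_fn = function(mu)
                         mu + (0.05 * (1 + 5 / mu)) * mu^2,
                       frac_light_spike = 0.10,
                       light_spike_factor = 4,
                       n_overlap_pairs = 0,
                       overlap_bp = 200,
                       bleed_rate = 0.3,
                       degradation_rate_dist = function(n)
                         rlnorm(n, meanlog = log(0.35), sdlog = 0.6),
                       archetype_mix = c(concordant = 0.6,
                                         stable_transcript = 0.2,
                                         rna_only = 0.2),
                       seed = 1) {
  cfg <- list(n_genes = n_genes, n_timepoints = n_timepoints,
              dt_hours = dt_hours, period_hours = period_hours,
              frac_rhythmic = frac_rhythmic, phase_mixture = phase_mixture,
              amplitude_dist = amplitude_dist,
              mean_expr_dist = mean_expr_dist,
              dispersion_fn = dispersion_fn,
              frac_light_spike = frac_light_spike,
              light_spike_factor = light_spike_factor,
              n_overlap_pairs = n_overlap_pairs, overlap_bp = overlap_bp,
              bleed_rate = bleed_rate,
              degradation_rate_dist = degradation_rate_dist,
              archetype_mix = archetype_mix, seed = seed)
  stopifnot(cfg$frac_rhythmic >= 0, cfg$frac_rhythmic <= 1,
            cfg$period_hours > 0, cfg$n_timepoints >= 4,
            cfg$frac_light_spike >= 0, cfg$frac_light_spike <= 1,
            cfg$n_overlap_pairs >= 0)
  structure(cfg, class = "sim_config")
}

sim_times <- function(config) seq(0, by = config$dt_hours,
                                  length.out = config$n_timepoints)

#' Closed-form RNA response to a sinusoidal transcription rhythm
#'
#' For first-order turnover dR/dt = s(t) - k R with log-sinusoidal drive of
#' angular frequency w = 2 pi / period, the stationary RNA rhythm is an
#' attenuated, delayed copy of the transcription rhythm:
#' attenuation = k / sqrt(k^2 + w^2), delay = atan(w / k) / w hours.
#' Slow turnover (small k, long half-life) therefore yields a delayed,
#' blunted RNA abundance rhythm even when transcription cycles strongly.
#'
#' @param k degradation rate in 1/hour (> 0), vectorized.
#' @param period period in hours (> 0).
#' @return list with numeric `attenuation` in (0, 1] and `delay_hours` in
#'   `[0, period/4)`.
#' @examples
#' w <- 2 * pi / 22
#' kinetic_rna_response(w, 22)  # attenuation 1/sqrt(2), delay 22/8 = 2.75 h
#' @export
kinetic_rna_response <- function(k, period = 22) {
  if (any(k <= 0)) stop("degradation rate k must be positive")
  if (period <= 0) stop("period must be positive")
  w <- 2 * pi / period
  list(attenuation = k / sqrt(k^2 + w^2),
       delay_hours = atan(w / k) / w)
}

#' Simulate per-gene ground truth
#'
#' @param config a `sim_config`.
#' @return data.frame (TruthTable) with per-gene columns: `gene_id`,
#'   `is_rhythmic`, `group_archetype` (`concordant`, `stable_transcript`,
#'   `rna_only`, `arrhythmic`), `true_phase` (transcription phase, CT hours),
#'   `true_fold_amplitude` (1 for arrhythmic genes), `baseline_mean`,
#'   `light_spike`, `k` (degradation rate 1/h), and the kinetically derived
#'   `rna_phase` / `rna_fold_amplitude`, plus `de_log2fc` (0; filled by
#'   [simulate_condition_pair()]).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "truth"), {
    n <- config$n_genes
    P <- config$period_hours
    ids <- sprintf("gene_%04d", seq_len(n))
    n_r <- round(n * config$frac_rhythmic)
    is_rhythmic <- c(rep(TRUE, n_r), rep(FALSE, n - n_r))
    mix <- config$archetype_mix / sum(config$archetype_mix)
    arch <- rep("arrhythmic", n)
    if (n_r > 0)
      arch[seq_len(n_r)] <- sample(names(mix), n_r, replace = TRUE,
                                   prob = mix)
    pm <- config$phase_mixture
    dawn <- runif(n) < pm$dawn_weight
    phase <- (ifelse(dawn, pm$dawn_mean, pm$dusk_mean) +
                rnorm(n, 0, pm$sd_hours)) %% P
    fold <- pmax(1, config$amplitude_dist(n))
    fold[!is_rhythmic] <- 1
    phase[!is_rhythmic] <- NA_real_
    m <- config$mean_expr_dist(n)
    spike <- runif(n) < config$frac_light_spike
    k <- config$degradation_rate_dist(n)
    # archetype-consistent turnover: concordant genes get fast turnover
    # (half-life <~ 1.5 h), stable-transcript genes slow turnover
    k[arch == "concordant"] <- pmax(k[arch == "concordant"], 0.5)
    k[arch == "stable_transcript"] <-
      pmin(pmax(k[arch == "stable_transcript"] * 0.1, 0.02), 0.08)
    kin <- kinetic_rna_response(k, P)
    A_tx <- log(fold) / 2
    rna_fold <- ifelse(arch == "rna_only", fold, exp(2 * A_tx * kin$attenuation))
    rna_phase <- ifelse(arch == "rna_only", phase,
                        (phase + kin$delay_hours) %% P)
    rna_fold[!is_rhythmic] <- 1
    rna_phase[!is_rhythmic] <- NA_real_
    data.frame(gene_id = ids, is_rhythmic = is_rhythmic,
               group_archetype = arch, true_phase = phase,
               true_fold_amplitude = fold, baseline_mean = m,
               light_spike = spike, k = k,
               rna_phase = rna_phase, rna_fold_amplitude = rna_fold,
               de_log2fc = 0, stringsAsFactors = FALSE)
  })
}

#' Build a toy annotation for simulated reads
#'
#' Lays `n_genes` gene models on toy chromosomes (up to 100 genes each).
#' The first `2 * n_overlap_pairs` genes form consecutive overlapping pairs
#' sharing `overlap_bp` of sequence (single-exon, so the shared region is
#' exonic in both partners); remaining genes are disjoint two-exon models.
#' Deterministic given `config$seed`.
#'
#' @param config a `sim_config`.
#' @param gene_length_bp gene span length (default 1500).
#' @param spacing_bp intergenic gap (default 3000, leaving room for
#'   background windows).
#' @return a `gene_annotation`.
#' @export
build_toy_annotation <- function(config, gene_length_bp = 1500,
                                 spacing_bp = 3000) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  npairs <- config$n_overlap_pairs
  if (n < 2 * npairs)
    stop("n_genes must be at least 2 * n_overlap_pairs")
  if (config$overlap_bp >= gene_length_bp)
    stop("overlap_bp must be smaller than gene_length_bp")
  with_seed(derive_seed(config$seed, "annotation"), {
    ids <- sprintf("gene_%04d", seq_len(n))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    chrom <- paste0("toy_chr", (seq_len(n) - 1) %/% 100 + 1)
    genes <- vector("list", n)
    exons <- vector("list", n)
    pos <- setNames(rep(spacing_bp, length(unique(chrom))), unique(chrom))
    in_pair <- seq_len(n) <= 2 * npairs
    for (i in seq_len(n)) {
      ch <- chrom[i]
      second_of_pair <- in_pair[i] && i %% 2 == 0 && chrom[i - 1] == ch
      start <- if (second_of_pair) {
        genes[[i - 1]]$end - config$overlap_bp
      } else pos[ch]
      end <- start + gene_length_bp
      genes[[i]] <- data.frame(gene_id = ids[i], chrom = ch,
                               start = start, end = end,
                               strand = strand[i],
                               stringsAsFactors = FALSE)
      if (in_pair[i]) {
        exons[[i]] <- data.frame(gene_id = ids[i], chrom = ch,
                                 start = start, end = end,
                                 stringsAsFactors = FALSE)
      } else {
        # two exons with an intron in the middle third
        e1 <- floor(gene_length_bp / 3)
        i2 <- floor(gene_length_bp * 2 / 3)
        exons[[i]] <- data.frame(gene_id = ids[i], chrom = ch,
                                 start = c(start, start + i2),
                                 end = c(start + e1, end),
                                 stringsAsFactors = FALSE)
      }
      pos[ch] <- end + spacing_bp
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)
    cl <- tapply(genes$end, genes$chrom, max) + spacing_bp
    gene_annotation(genes, exons,
                    chrom_lengths = setNames(as.integer(cl), names(cl)))
  })
}

#' Expected (noiseless) count matrix for one assay
#'
#' The deterministic mean surface the NB sampler draws around: baseline
#' times the log-cosine rhythm, with RNA means attenuated/delayed through
#' the degradation kinetics and t = 0 light spikes applied. Useful for
#' noiseless-limit checks of downstream estimators.
#'
#' @param truth TruthTable from [simulate_truth()].
#' @param config a `sim_config`.
#' @param assay `"rna"` or `"rnapii"`.
#' @return genes x times numeric matrix of expected counts.
#' @export
expected_counts <- function(truth, config, assay = c("rna", "rnapii")) {
  truth_mean_matrix(truth, config, match.arg(assay))
}

# Expected count matrix (genes x times) for one assay, before noise.
truth_mean_matrix <- function(truth, config, assay) {
  t <- sim_times(config)
  P <- config$period_hours
  w <- 2 * pi / P
  n <- nrow(truth)
  mu <- matrix(truth$baseline_mean, n, length(t))
  if (assay == "rnapii") {
    has <- truth$is_rhythmic & truth$group_archetype != "rna_only"
    A <- log(truth$true_fold_amplitude) / 2
    ph <- truth$true_phase
  } else {
    has <- truth$is_rhythmic
    A <- log(truth$rna_fold_amplitude) / 2
    ph <- truth$rna_phase
  }
  idx <- which(has)
  if (length(idx))
    mu[idx, ] <- mu[idx, ] *
      exp(outer(A[idx], rep(1, length(t))) *
            cos(w * outer(-ph[idx], t, "+")))
  mu[truth$light_spike, 1] <- mu[truth$light_spike, 1] *
    config$light_spike_factor
  dimnames(mu) <- list(truth$gene_id, sprintf("t%02d", round(t)))
  mu
}

nb_draw <- function(mu, config) {
  v <- config$dispersion_fn(mu)
  if (any(v < mu - 1e-9)) stop("dispersion_fn returned variance < mean")
  out <- mu
  pois <- v <= mu * (1 + 1e-12)
  out[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    size <- mu[!pois]^2 / (v[!pois] - mu[!pois])
    out[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = size)
  }
  out
}

#' Simulate a count time course
#'
#' Counts are NB draws around mu_g(t) = m_g exp(A_g cos(w (t - phi_g))); RNA
#' means are additionally attenuated and delayed through
#' [kinetic_rna_response()] using each gene's degradation rate, and t = 0
#' means of light-spiked genes are inflated by the configured factor. When
#' the annotation contains overlapping pairs, bleed-through reads landing in
#' the shared region are added to both partners' counts (Poisson draws at
#' `bleed_rate` times the weaker partner's local density) and returned in the
#' `overlap_counts` attribute for the influence filter.
#'
#' @param truth TruthTable from [simulate_truth()].
#' @param config a `sim_config`.
#' @param assay `"rna"` or `"rnapii"`.
#' @param annotation optional `gene_annotation` (needed for bleed-through).
#' @return a `ccg_counts` with attribute `overlap_counts` (genes x samples
#'   matrix of reads falling in overlap regions).
#' @export
simulate_timecourse <- function(truth, config, assay = c("rna", "rnapii"),
                                annotation = NULL) {
  assay <- match.arg(assay)
  stopifnot(inherits(config, "sim_config"))
  mu <- truth_mean_matrix(truth, config, assay)
  with_seed(derive_seed(config$seed, paste0("timecourse_", assay)), {
    y <- matrix(nb_draw(c(mu), config), nrow = nrow(mu),
                dimnames = dimnames(mu))
    ov <- matrix(0, nrow(y), ncol(y), dimnames = dimnames(y))
    if (!is.null(annotation) && nrow(annotation$overlaps) > 0) {
      L_G <- annotation$genes$end - annotation$genes$start
      names(L_G) <- annotation$genes$gene_id
      pairs <- annotation$overlaps
      pairs <- pairs[pairs$gene_id < pairs$partner_id, , drop = FALSE]
      for (r in seq_len(nrow(pairs))) {
        g1 <- pairs$gene_id[r]; g2 <- pairs$partner_id[r]
        L_O <- pairs$length[r]
        for (s in seq_len(ncol(y))) {
          # read-through from each partner into the shared region; every
          # such read lies in both genes' exons, so it counts to both
          dens <- y[g1, s] / (L_G[g1] - L_O) + y[g2, s] / (L_G[g2] - L_O)
          nb <- rpois(1, config$bleed_rate * dens * L_O)
          ov[g1, s] <- ov[g1, s] + nb
          ov[g2, s] <- ov[g2, s] + nb
        }
      }
      y <- y + ov
    }
    out <- ccg_counts(y, times = sim_times(config), assay = assay)
    attr(out, "overlap_counts") <- ov
    out
  })
}

#' Emit per-read BED positions consistent with a simulated count matrix
#'
#' Base reads (counts minus overlap reads) get 5' positions uniform over the
#' gene's exonic bases outside any overlap region; overlap reads get 5'
#' positions uniform over the shared region, once per physical read (the
#' exonic counting rule then assigns each to both partners, reproducing the
#' emitted matrix exactly on recount). Reads are 50 bp on the gene's strand.
#'
#' @param counts `ccg_counts` from [simulate_timecourse()] (with its
#'   `overlap_counts` attribute).
#' @param annotation the matching `gene_annotation`.
#' @param config a `sim_config` (for the seed).
#' @param read_length_bp read length (default 50).
#' @return data.frame of reads (`chrom, start, end, sample, strand`).
#' @export
simulate_reads <- function(counts, annotation, config, read_length_bp = 50) {
  stopifnot(inherits(counts, "ccg_counts"),
            inherits(annotation, "gene_annotation"))
  ovc <- attr(counts, "overlap_counts")
  if (is.null(ovc)) ovc <- counts$counts * 0
  ovreg <- gene_overlap_regions(annotation)
  samples <- colnames(counts$counts)
  g <- annotation$genes
  with_seed(derive_seed(config$seed, paste0("reads_", counts$assay)), {
    out <- list()
    for (i in seq_len(nrow(g))) {
      gid <- g$gene_id[i]
      ex <- annotation$exons[annotation$exons$gene_id == gid, , drop = FALSE]
      exonic <- unlist(lapply(seq_len(nrow(ex)),
                              function(j) seq(ex$start[j], ex$end[j] - 1L)))
      ovr <- ovreg[[gid]]
      ovpos <- if (is.null(ovr)) integer(0) else
        unlist(lapply(seq_len(nrow(ovr)),
                      function(j) seq(ovr$start[j], ovr$end[j] - 1L)))
      basepos <- setdiff(exonic, ovpos)
      for (s in seq_along(samples)) {
        n_base <- counts$counts[gid, s] - ovc[gid, s]
        if (n_base > 0)
          out[[length(out) + 1L]] <- data.frame(
            chrom = g$chrom[i],
            p5 = sample(basepos, n_base, replace = TRUE),
            sample = samples[s], strand = g$strand[i],
            stringsAsFactors = FALSE)
      }
    }
    # overlap reads: one physical read per pair event, counted to both genes
    pairs <- annotation$overlaps
    pairs <- pairs[pairs$gene_id < pairs$partner_id, , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      gid <- pairs$gene_id[r]
      ovr_pos <- seq(pairs$start[r], pairs$end[r] - 1L)
      for (s in seq_along(samples)) {
        nov <- ovc[gid, s]
        if (nov > 0)
          out[[length(out) + 1L]] <- data.frame(
            chrom = pairs$chrom[r],
            p5 = sample(ovr_pos, nov, replace = TRUE),
            sample = samples[s],
            strand = g$strand[match(gid, g$gene_id)],
            stringsAsFactors = FALSE)
      }
    }
    reads <- do.call(rbind, out)
    minus <- reads$strand == "-"
    start <- ifelse(minus, reads$p5 - read_length_bp + 1L, reads$p5)
    data.frame(chrom = reads$chrom, start = pmax(start, 0L),
               end = pmax(start, 0L) + read_length_bp,
               sample = reads$sample, strand = reads$strand,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a two-condition replicate design
#'
#' Paired count matrices with shared per-gene baselines; the treatment mean
#' is scaled by 2^log2fc per gene. NB noise via the config dispersion.
#'
#' @param truth TruthTable; its `de_log2fc` column is set from `effect_model`.
#' @param config a `sim_config`.
#' @param effect_model numeric vector of per-gene log2 fold changes, or a
#'   function(truth) returning one (0 = not differentially expressed).
#' @param n_reps replicates per condition (default 3).
#' @return list with `treat`, `control` (`ccg_counts`) and the updated
#'   `truth`.
#' @export
simulate_condition_pair <- function(truth, config, effect_model = 0,
                                    n_reps = 3) {
  stopifnot(inherits(config, "sim_config"))
  lfc <- if (is.function(effect_model)) effect_model(truth) else
    rep_len(effect_model, nrow(truth))
  truth$de_log2fc <- lfc
  with_seed(derive_seed(config$seed, "condition_pair"), {
    n <- nrow(truth)
    mu_c <- matrix(truth$baseline_mean, n, n_reps)
    mu_t <- mu_c * 2^lfc
    ctrl <- matrix(nb_draw(c(mu_c), config), n,
                   dimnames = list(truth$gene_id,
                                   sprintf("control_%d", seq_len(n_reps))))
    trt <- matrix(nb_draw(c(mu_t), config), n,
                  dimnames = list(truth$gene_id,
                                  sprintf("treat_%d", seq_len(n_reps))))
    list(treat = ccg_counts(trt, condition = rep("treat", n_reps)),
         control = ccg_counts(ctrl, condition = rep("control", n_reps)),
         truth = truth)
  })
}
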