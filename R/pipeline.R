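# End-to-end orchestration: simulate -> count/filter -> rhythms -> fdr ->
# differential expression -> phase analysis, with one master seed, every
# intermediate written as TSV/JSON, and a manifest with file hashes so runs
# are auditably bit-reproducible.

#' Pipeline configuration
#'
#' Defaults echo the reference protocol: 500 bp terminal windows, influence
#' threshold 2, low-expression quantile 0.2, detection period range 18-26 h,
#' fixed 22 h fit period, alpha 0.05, 500 time-point shuffles.
#'
#' @param n_genes synthetic gene count (default 3000).
#' @param seed master seed; all stage streams derive from it.
#' @param out_dir output directory.
#' @param n_shuffles FDR shuffles (default 500; scale down for quick runs).
#' @param window_bp terminal window (default 500).
#' @param influence_threshold overlap filter threshold (default 2; `Inf`
#'   disables).
#' @param low_expr_quantile low-expression quantile (default 0.2; 0
#'   disables).
#' @param period_range detection period range (default c(18, 26)).
#' @param fit_period fixed sine-fit period (default 22).
#' @param alpha significance threshold (default 0.05).
#' @param in_phase_tol_hours Group-1 phase-agreement tolerance (default 3).
#' @param similar_tol_hours cross-condition similar/shifted tolerance
#'   (default 4).
#' @param de_frac fraction of genes differentially expressed in the
#'   simulated condition pair (default 0.1).
#' @param de_log2fc magnitude of simulated DE effects (default 2).
#' @param condition_shift_frac fraction of rhythmic genes whose phase is
#'   shifted in the simulated second genotype (default 0.34).
#' @param condition_shift_hours size of that shift (default 10).
#' @param sim_overrides named list passed on to [sim_config()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_genes = 3000, seed = 1,
                            out_dir = tempfile("ccgpipe_run_"),
                            n_shuffles = 500, window_bp = 500,
                            influence_threshold = 2,
                            low_expr_quantile = 0.2,
                            period_range = c(18, 26), fit_period = 22,
                            alpha = 0.05, in_phase_tol_hours = 3,
                            similar_tol_hours = 4,
                            de_frac = 0.1, de_log2fc = 2,
                            condition_shift_frac = 0.34,
                            condition_shift_hours = 10,
                            sim_overrides = list()) {
  stopifnot(n_genes >= 10, n_shuffles >= 1, window_bp > 0,
            influence_threshold > 0, low_expr_quantile >= 0,
            low_expr_quantile < 1, alpha > 0, alpha < 1,
            period_range[1] < period_range[2], fit_period > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

curve_table <- function(curve) {
  data.frame(x = curve$x,
             f_ob = curve$observed$fn(curve$x),
             f_bg = curve$background$fn(curve$x),
             fdr_raw = curve$fdr_raw, fdr = curve$fdr)
}

#' Run the full pipeline on a synthetic bundle
#'
#' Executes simulate, filter, rhythm, FDR, differential-expression and
#' phase-analysis stages in order, writing every intermediate table under
#' `config$out_dir` and a JSON manifest with parameters, per-stage row
#' counts, headline statistics and md5 hashes of every output file. All
#' randomness derives from the master seed, so two runs with the same config
#' produce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list; also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log_ <- list()
  stage <- function(name, nin, nout)
    log_[[length(log_) + 1]] <<- list(stage = name, rows_in = nin,
                                      rows_out = nout)

  # --- simulate -------------------------------------------------------------
  sc <- do.call(sim_config, modifyList(
    list(n_genes = config$n_genes, seed = config$seed,
         n_overlap_pairs = max(2, round(config$n_genes * 0.01))),
    config$sim_overrides))
  truth <- simulate_truth(sc)
  ann <- build_toy_annotation(sc)
  rna <- simulate_timecourse(truth, sc, "rna", annotation = ann)
  chip <- simulate_timecourse(truth, sc, "rnapii", annotation = ann)
  write_gff3(ann, out("annotation.gff3"))
  jsonlite::write_json(truth, out("truth.json"), digits = NA)
  write_counts_tsv(rna, out("counts_rna.tsv"))
  write_counts_tsv(chip, out("counts_rnapii.tsv"))
  stage("simulate", config$n_genes, config$n_genes)

  # --- filter ---------------------------------------------------------------
  filt <- list()
  filter_assay <- function(x, label) {
    n0 <- nrow(x$counts)
    x <- apply_influence_filter(x, ann,
                                threshold = config$influence_threshold)
    filt[[label]] <<- attr(x, "filter_report")
    x <- normalize_counts(x)
    if (label == "rna" && config$low_expr_quantile > 0)
      x <- filter_low_expression(x, config$low_expr_quantile)
    stage(paste0("filter_", label), n0, nrow(x$counts))
    x
  }
  rna_f <- filter_assay(rna, "rna")
  chip_f <- filter_assay(chip, "rnapii")
  # chip background filter needs read-level input; counts-first runs skip it
  stage("chip_background_filter", nrow(chip_f$counts), nrow(chip_f$counts))
  shared <- intersect(gene_ids(rna_f), gene_ids(chip_f))
  rna_f <- subset_genes(rna_f, match(shared, gene_ids(rna_f)))
  chip_f <- subset_genes(chip_f, match(shared, gene_ids(chip_f)))
  write_tsv(do.call(rbind, lapply(names(filt), function(l)
    cbind(assay = l, filt[[l]]))), out("filter_report.tsv"))
  write_counts_tsv(rna_f, out("counts_rna_filtered.tsv"))
  write_counts_tsv(chip_f, out("counts_rnapii_filtered.tsv"))

  # --- rhythms --------------------------------------------------------------
  rh <- list(
    rna = rhythm_analysis(rna_f, config$period_range, config$fit_period,
                          config$alpha, raw_counts = rna),
    rnapii = rhythm_analysis(chip_f, config$period_range,
                             config$fit_period, config$alpha,
                             raw_counts = chip))
  write_tsv(rh$rna, out("rhythms_rna.tsv"))
  write_tsv(rh$rnapii, out("rhythms_rnapii.tsv"))
  stage("rhythms", length(shared), sum(rh$rna$rhythmic))

  # --- fdr ------------------------------------------------------------------
  fdr_tables <- list()
  for (assay in c("rna", "rnapii")) {
    tab <- rh[[assay]]
    cts <- if (assay == "rna") rna_f else chip_f
    called <- tab[tab$rhythmic, ]
    amp_obs <- log2(called$fold_amplitude)
    cov_obs <- log10(pmax(called$coverage, 0.5))
    brk <- list(amplitude = default_bins(amp_obs),
                coverage = default_bins(cov_obs))
    obs <- list(amplitude = occurrence_histogram(amp_obs, brk$amplitude),
                coverage = occurrence_histogram(cov_obs, brk$coverage))
    bg <- shuffle_occurrence(cts, brk, n_shuffles = config$n_shuffles,
                             seed = derive_seed(config$seed,
                                                paste0("fdr_", assay)),
                             alpha = config$alpha,
                             fit_period = config$fit_period)
    curves <- lapply(c(amplitude = "amplitude", coverage = "coverage"),
                     function(s) fdr_curve(fit_decay(obs[[s]]),
                                           fit_decay(bg[[s]]),
                                           weight = weight_occupancy(obs[[s]]),
                                           stratifier = s))
    for (s in names(curves))
      write_tsv(curve_table(curves[[s]]),
                out(sprintf("fdr_curve_%s_%s.tsv", s, assay)))
    tab <- assign_fdr(tab, curves$amplitude, curves$coverage)
    fdr_tables[[assay]] <- tab
    write_tsv(tab[, c("gene", "fold_amplitude", "coverage",
                      "fdr_amplitude", "fdr_coverage", "fdr")],
              out(sprintf("gene_fdr_%s.tsv", assay)))
  }
  stage("fdr", length(shared), length(shared))

  # --- differential expression ---------------------------------------------
  lfc <- with_seed(derive_seed(config$seed, "de_effects"), {
    v <- numeric(config$n_genes)
    hit <- runif(config$n_genes) < config$de_frac
    v[hit] <- sample(c(-1, 1), sum(hit), TRUE) * config$de_log2fc
    v
  })
  pair <- simulate_condition_pair(truth, sc, effect_model = lfc)
  de <- run_de(pair$treat, pair$control, alpha = config$alpha)
  write_tsv(de, out("de_results.tsv"))
  stage("de", config$n_genes, sum(de$call != 0))

  # --- phase analysis -------------------------------------------------------
  groups <- classify_groups(rh$rna, rh$rnapii, config$alpha,
                            config$in_phase_tol_hours, config$fit_period)
  write_tsv(groups, out("groups.tsv"))
  robust <- robust_oscillators(fdr_tables$rna)
  rhythmic_rna <- rh$rna$gene[rh$rna$rhythmic]
  rhythmic_chip <- rh$rnapii$gene[rh$rnapii$rhythmic]
  ov <- overlap_summary(rhythmic_rna, rhythmic_chip, shared,
                        phases_A = rh$rna$phase[rh$rna$rhythmic],
                        phases_B = rh$rnapii$phase[rh$rnapii$rhythmic],
                        period = config$fit_period)
  jsonlite::write_json(ov, out("overlap_summary.json"), auto_unbox = TRUE,
                       digits = NA)

  # second genotype: shift a fraction of rhythmic genes' phases, resimulate
  truth_B <- with_seed(derive_seed(config$seed, "genotype_B"), {
    tb <- truth
    hit <- tb$is_rhythmic & runif(nrow(tb)) < config$condition_shift_frac
    tb$true_phase[hit] <- (tb$true_phase[hit] +
                             config$condition_shift_hours) %% sc$period_hours
    tb$rna_phase[hit] <- (tb$rna_phase[hit] +
                            config$condition_shift_hours) %% sc$period_hours
    tb
  })
  scB <- do.call(sim_config, modifyList(
    list(n_genes = config$n_genes,
         seed = derive_seed(config$seed, "genotype_B_counts"),
         n_overlap_pairs = sc$n_overlap_pairs), config$sim_overrides))
  rna_B <- simulate_timecourse(truth_B, scB, "rna")
  rna_Bn <- normalize_counts(subset_genes(rna_B, match(shared,
                                                       gene_ids(rna_B))))
  rh_B <- rhythm_analysis(rna_Bn, config$period_range, config$fit_period,
                          config$alpha, raw_counts = rna_B)
  shifts <- compare_phase_between_conditions(
    rh$rna, rh_B, rhythmic_rna, config$similar_tol_hours,
    config$fit_period)
  write_tsv(shifts, out("phase_shift.tsv"))
  stage("phases", length(shared), nrow(shifts))

  # --- summary + manifest ---------------------------------------------------
  gs <- attr(groups, "group_sizes")
  pc <- table(factor(rh$rna$phase_class[rh$rna$rhythmic],
                     c("dawn", "dusk", "other")))
  summary_tab <- data.frame(
    statistic = c("n_genes", "n_after_filters", "n_rhythmic_rna",
                  "n_rhythmic_rnapii", "n_both", "group1", "group2",
                  "group3", "n_robust_oscillators", "dawn_frac_rna",
                  "dusk_frac_rna", "n_de_called", "n_phase_similar",
                  "n_phase_shifted"),
    value = c(config$n_genes, length(shared), length(rhythmic_rna),
              length(rhythmic_chip), ov$n_intersect, gs[["1"]], gs[["2"]],
              gs[["3"]], length(robust),
              round(pc[["dawn"]] / max(1, sum(pc)), 4),
              round(pc[["dusk"]] / max(1, sum(pc)), 4),
              sum(de$call != 0),
              sum(shifts$classification == "similar"),
              sum(shifts$classification == "shifted")))
  write_tsv(summary_tab, out("summary.tsv"))

  files <- setdiff(list.files(config$out_dir), "manifest.json")
  hashes <- tools::md5sum(file.path(config$out_dir, files))
  names(hashes) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("ccgpipe")),
    seed = config$seed,
    parameters = config[c("n_genes", "n_shuffles", "window_bp",
                          "influence_threshold", "low_expr_quantile",
                          "period_range", "fit_period", "alpha",
                          "in_phase_tol_hours", "similar_tol_hours")],
    stages = log_,
    summary = setNames(as.list(summary_tab$value), summary_tab$statistic),
    file_md5 = as.list(hashes))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
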