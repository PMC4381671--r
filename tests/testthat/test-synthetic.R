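test_that("kinetic_rna_response matches the closed form of the linear ODE", {
  w <- 2 * pi / 22
  # k = w: attenuation 1/sqrt(2), delay = period/8
  r <- kinetic_rna_response(w, 22)
  expect_equal(r$attenuation, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(r$delay_hours, 2.75, tolerance = 1e-12)
  # k = w/10: delay = atan(10)/w, attenuation = 1/sqrt(101)
  r <- kinetic_rna_response(w / 10, 22)
  expect_equal(r$delay_hours, atan(10) / w, tolerance = 1e-12)
  expect_equal(r$attenuation, 1 / sqrt(101), tolerance = 1e-12)
  # instantaneous-turnover limit
  r <- kinetic_rna_response(1e8, 22)
  expect_equal(r$attenuation, 1, tolerance = 1e-8)
  expect_lt(r$delay_hours, 1e-6)
  expect_error(kinetic_rna_response(0, 22), "positive")
  expect_error(kinetic_rna_response(1, -3), "positive")
})

test_that("attenuation increases and delay decreases monotonically in k", {
  k <- exp(seq(log(0.01), log(10), length.out = 40))
  r <- kinetic_rna_response(k, 22)
  expect_true(all(diff(r$attenuation) > 0))
  expect_true(all(diff(r$delay_hours) < 0))
  expect_true(all(r$attenuation > 0 & r$attenuation <= 1))
  expect_true(all(r$delay_hours >= 0 & r$delay_hours < 22 / 4))
})

test_that("build_toy_annotation lays out genes and overlaps as requested", {
  cfg <- sim_config(n_genes = 10, n_overlap_pairs = 0, seed = 11)
  ann <- build_toy_annotation(cfg)
  expect_equal(nrow(ann$genes), 10)
  expect_equal(nrow(ann$overlaps), 0)   # disjoint spans

  cfg <- sim_config(n_genes = 4, n_overlap_pairs = 2, seed = 11)
  ann <- build_toy_annotation(cfg)
  # every gene belongs to exactly one overlapping pair
  expect_setequal(ann$overlaps$gene_id, ann$genes$gene_id)
  expect_equal(nrow(ann$overlaps), 4)   # 2 pairs x 2 ordered records
  expect_true(all(ann$overlaps$length == cfg$overlap_bp))

  expect_error(build_toy_annotation(sim_config(n_genes = 3,
                                               n_overlap_pairs = 2)),
               "n_overlap_pairs")
})

test_that("same seed gives byte-identical GFF3 output", {
  cfg <- sim_config(n_genes = 8, n_overlap_pairs = 2, seed = 5)
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  write_gff3(build_toy_annotation(cfg), f1)
  write_gff3(build_toy_annotation(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the GFF3 round-trips
  ann2 <- read_gff3(f1)
  ann1 <- build_toy_annotation(cfg)
  expect_equal(ann2$genes[order(ann2$genes$gene_id), ],
               ann1$genes[order(ann1$genes$gene_id), ],
               ignore_attr = TRUE)
})

test_that("simulate_timecourse honours the truth table", {
  # frac_rhythmic = 0: no fold amplitude above 1
  cfg <- sim_config(n_genes = 50, frac_rhythmic = 0, seed = 2)
  tr <- simulate_truth(cfg)
  expect_true(all(tr$true_fold_amplitude == 1))
  expect_true(all(tr$rna_fold_amplitude == 1))

  # noiseless limit: counts trace the deterministic cosine within rounding
  cfg <- sim_config(n_genes = 6, frac_rhythmic = 1, frac_light_spike = 0,
                    dispersion_fn = function(mu) mu * (1 + 1e-13),
                    mean_expr_dist = function(n) rep(5e5, n),
                    archetype_mix = c(concordant = 1), seed = 3)
  tr <- simulate_truth(cfg)
  y <- simulate_timecourse(tr, cfg, "rnapii")
  t <- y$times
  for (i in 1:6) {
    mu <- tr$baseline_mean[i] *
      exp(log(tr$true_fold_amplitude[i]) / 2 *
            cos(2 * pi / 22 * (t - tr$true_phase[i])))
    expect_lt(max(abs(y$counts[i, ] - mu) / mu), 0.01)
  }

  # light spike multiplies t = 0 means for flagged genes
  cfg <- sim_config(n_genes = 40, frac_rhythmic = 0, frac_light_spike = 1,
                    dispersion_fn = function(mu) mu * (1 + 1e-13),
                    mean_expr_dist = function(n) rep(1e5, n), seed = 4)
  tr <- simulate_truth(cfg)
  y <- simulate_timecourse(tr, cfg, "rna")
  ratio <- y$counts[, 1] / rowMeans(y$counts[, -1])
  expect_equal(median(ratio), 4, tolerance = 0.05)

  # determinism
  cfg <- sim_config(n_genes = 30, seed = 9)
  tr <- simulate_truth(cfg)
  expect_identical(simulate_timecourse(tr, cfg, "rna")$counts,
                   simulate_timecourse(tr, cfg, "rna")$counts)
})

test_that("NB sampling reproduces the requested moments", {
  # 10,000 draws at mu = 100, variance = 200
  cfg <- sim_config(n_genes = 1, seed = 42,
                    dispersion_fn = function(mu) 2 * mu)
  tr <- data.frame(gene_id = sprintf("g%05d", 1:10000),
                   is_rhythmic = FALSE, group_archetype = "arrhythmic",
                   true_phase = NA_real_, true_fold_amplitude = 1,
                   baseline_mean = 100, light_spike = FALSE, k = 1,
                   rna_phase = NA_real_, rna_fold_amplitude = 1,
                   de_log2fc = 0)
  cfg$n_genes <- 10000
  cfg$n_timepoints <- 1
  y <- simulate_timecourse(tr, cfg, "rna")$counts[, 1]
  expect_equal(mean(y), 100, tolerance = 0.02)
  expect_equal(var(y), 200, tolerance = 0.10)
})

test_that("rhythmic phases are dawn/dusk bimodal", {
  cfg <- sim_config(n_genes = 2000, frac_rhythmic = 1, seed = 8)
  tr <- simulate_truth(cfg)
  ph <- tr$true_phase
  # two modes at the configured centers (CT 0 and CT 11), ~half a period
  # apart: classify by proximity and check both clusters are tight and
  # roughly balanced
  d_dawn <- phase_difference(ph, 0, 22)
  d_dusk <- phase_difference(ph, 11, 22)
  frac_dawn <- mean(d_dawn < d_dusk)
  expect_gt(frac_dawn, 0.4); expect_lt(frac_dawn, 0.6)
  expect_lt(median(pmin(d_dawn, d_dusk)), 2)
})

test_that("read emission is consistent with the emitted count matrix", {
  cfg <- sim_config(n_genes = 16, n_overlap_pairs = 4, seed = 21,
                    mean_expr_dist = function(n) rlnorm(n, log(50), 1))
  tr <- simulate_truth(cfg)
  ann <- build_toy_annotation(cfg)
  y <- simulate_timecourse(tr, cfg, "rna", annotation = ann)
  reads <- simulate_reads(y, ann, cfg)
  rc <- count_exonic(reads, ann, times = y$times)
  expect_equal(rc$counts[rownames(y$counts), ], y$counts,
               ignore_attr = TRUE)
  expect_identical(attr(rc, "unassigned"), 0L)
  # BED round trip preserves the recount
  bed <- tempfile(fileext = ".bed")
  write_bed(reads, bed)
  rc2 <- count_exonic(read_bed(bed), ann, times = y$times)
  expect_equal(rc2$counts, rc$counts)
})

test_that("simulate_condition_pair encodes the requested effects", {
  cfg <- sim_config(n_genes = 400, frac_rhythmic = 0, seed = 13)
  tr <- simulate_truth(cfg)
  lfc <- rep(0, 400); lfc[1:40] <- 2
  pair <- simulate_condition_pair(tr, cfg, effect_model = lfc, n_reps = 6)
  expect_equal(pair$truth$de_log2fc, lfc)
  ratio <- rowMeans(pair$treat$counts[1:40, ]) /
    rowMeans(pair$control$counts[1:40, ])
  expect_equal(median(ratio), 4, tolerance = 0.15)
  # null genes: means agree
  r0 <- rowMeans(pair$treat$counts[41:400, ]) /
    rowMeans(pair$control$counts[41:400, ])
  expect_equal(median(r0), 1, tolerance = 0.1)
  # determinism
  pair2 <- simulate_condition_pair(tr, cfg, effect_model = lfc, n_reps = 6)
  expect_identical(pair$treat$counts, pair2$treat$counts)
})
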