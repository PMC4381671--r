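# ccgpipe

Analysis of clock-controlled gene expression from count time courses, built
for paired RNA-seq and RNAPII-S2P ChIP-seq experiments sampled every 2 h
over one ~22 h free-running circadian cycle in constant darkness (12 time
points including t = 0), as in *Neurospora*-style genome-wide clock studies.
RNA abundance is quantified from exonic reads; active transcription from
elongating-polymerase occupancy in the 500 bp window at each gene's 3' end.

The package is aimed at chronobiologists and computational biologists who
want the full analysis path — counting, filtering, rhythm detection, phase
and amplitude estimation, shuffle-based FDR, exact differential tests, and
transcription/RNA concordance classification — as tested, seeded, reusable
components, plus a synthetic-data generator with ground truth so every stage
can be validated without any sequencing data.

## The model in brief

Expression rhythms are single-harmonic log-linear cosines,

```
mu_g(t) = m_g * exp(A_g * cos(w (t - phi_g))),   w = 2 pi / period,
```

with negative-binomial counts around `mu` and a smooth mean-variance
relation `sigma^2(mu)`. The peak/trough **fold amplitude** is `exp(2 A_g)`;
`phi_g` is the circadian phase in CT hours (CT 0 = subjective dawn). The
main statistics:

- **Detection**: harmonic regression on detrended log counts over a dense
  18–26 h period scan, with the scan statistic's p-value calibrated against
  its Monte-Carlo null distribution; run with and without the t = 0 sample
  (light-inflated for some genes), reporting the smaller p.
- **Phase/amplitude**: NB GLM sine fit at a fixed 22 h period;
  `phase = atan2(b_sin, b_cos)/w`, `fold = exp(2*sqrt(b_cos^2 + b_sin^2))`.
- **Influence factor** for overlap contamination:
  `(G/L_G) / ((G-O)/(L_G-L_O))`, genes above 2 removed.
- **FDR** from 500 time-label shuffles:
  `FDR(x) = f_bg(x)/(f_ob(x)+f_bg(x)) * Weight(x)` with exponential-decay
  occurrence fits in amplitude (or coverage) bins.
- **Differential expression**: two-sided NB exact test (Robinson–Smyth
  style) with the dispersion taken from a loess mean-variance fit.
- **RNA kinetics**: first-order turnover at rate `k` turns a transcription
  rhythm into an RNA rhythm attenuated by `k/sqrt(k^2+w^2)` and delayed by
  `atan(w/k)/w` — slow-turnover genes show blunted, delayed RNA rhythms
  even when transcription cycles strongly.

See `vignettes/ccgpipe-methods.Rmd` for assumptions, calibration details,
numerical choices and known limitations.

## Worked example

```r
library(ccgpipe)

cfg   <- sim_config(n_genes = 400, seed = 11, frac_rhythmic = 0.4)
truth <- simulate_truth(cfg)
rna   <- normalize_counts(simulate_timecourse(truth, cfg, "rna"))
rh    <- rhythm_analysis(rna)
sum(rh$rhythmic)
subset(rh, rhythmic)[1:3, c("gene", "p_value", "run", "period",
                            "phase", "fold_amplitude", "phase_class")]
kinetic_rna_response(k = 2 * pi / 22, period = 22)
```

prints

```
[1] 126
      gene  p_value        run period phase fold_amplitude phase_class
 gene_0001 0.000381 without_t0   18.6  2.55           4.29        dawn
 gene_0002 0.017253 without_t0   26.0 11.48           2.17        dusk
 gene_0003 0.041618 without_t0   18.0 15.00           5.54        dusk
$attenuation
[1] 0.7071068
$delay_hours
[1] 2.75
```

126 of 400 genes are called rhythmic at p < 0.05 (160 are truly rhythmic
here; against the ground truth this run has sensitivity 0.64 at a 0.10
false-call rate — the dual-run minimum-p rule trades some specificity for
rescuing light-spiked genes). Each called gene gets the run that produced
its p-value, the scan-refined period, and the 22 h NB sine fit's phase (CT
hours), peak/trough fold amplitude and dawn/dusk class. The kinetic helper
shows the closed form at `k = w`: an RNA rhythm attenuated to `1/sqrt(2)`
of the transcription amplitude and delayed by `22/8 = 2.75` h.

The full pipeline (simulate → filter → rhythms → FDR → differential
expression → concordance groups and phase shifts) runs from one seeded
config and writes every intermediate plus a manifest with md5 hashes:

```r
manifest <- run_pipeline(pipeline_config(n_genes = 3000, seed = 1,
                                         out_dir = "run1"))
str(manifest$summary)
```

A command-line front end with `simulate`, `count`, `rhythms`, `de` and
`run` subcommands lives at `inst/cli/ccgpipe.R`.

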