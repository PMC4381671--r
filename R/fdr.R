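# Shuffle-based false discovery rates stratified by amplitude or coverage.
#
# The occurrence of rhythmic calls decays roughly exponentially with
# amplitude (and coverage); exponential decay curves are fitted to the
# observed occurrence and to the average occurrence across time-shuffled
# null data sets, and FDR(x) = f_bg(x) / (f_ob(x) + f_bg(x)) * Weight(x).

#' Occurrence histogram of rhythmic calls
#'
#' @param values stratifier values of the genes called rhythmic (log2 fold
#'   amplitude or log10 coverage).
#' @param breaks bin edges (values outside are clamped into the end bins).
#' @param source `"observed"` or `"shuffled"`.
#' @param n_shuffles for shuffled histograms, the number of shuffles the
#'   counts are averaged over.
#' @return an `occurrence_histogram`: list with `breaks`, `mids`, `counts`
#'   (per-shuffle averages for shuffled sources), `source`, `n_shuffles`.
#' @export
occurrence_histogram <- function(values, breaks, source = "observed",
                                 n_shuffles = 1) {
  v <- pmin(pmax(values, breaks[1]), breaks[length(breaks)])
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = length(breaks) - 1)
  structure(list(breaks = breaks,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts / n_shuffles, source = source,
                 n_shuffles = n_shuffles),
            class = "occurrence_histogram")
}

#' Default amplitude/coverage bins
#'
#' 20 equal-width bins spanning the 1st-99th percentile of the observed
#' stratifier values.
#'
#' @param values observed stratifier values.
#' @param n_bins number of bins (default 20).
#' @return numeric vector of bin edges.
#' @export
default_bins <- function(values, n_bins = 20) {
  r <- quantile(values, c(0.01, 0.99), names = FALSE, na.rm = TRUE)
  if (diff(r) <= 0) r <- r + c(-0.5, 0.5)
  seq(r[1], r[2], length.out = n_bins + 1)
}

#' Null occurrence from time-point shuffles
#'
#' For each shuffle, the time labels are permuted (one shared permutation
#' across genes by default, preserving cross-gene structure), the dual
#' with/without-t0 detector is run, NB sine fits give the amplitudes (and
#' coverages) of the genes called rhythmic, and their histogram is
#' accumulated. Returns per-shuffle average occurrences.
#'
#' @param counts normalized `ccg_counts` time course.
#' @param breaks bin edges for the stratifier (from [default_bins()] on the
#'   observed values).
#' @param n_shuffles number of shuffles (the reference protocol uses 500;
#'   scale down for quick runs).
#' @param seed RNG seed.
#' @param alpha rhythmicity call threshold.
#' @param stratify `"amplitude"` (log2 fold) or `"coverage"` (log10 median).
#' @param fit_period fixed sine-fit period.
#' @param variance_model optional mean-variance model for the sine fits.
#' @param per_gene permute each gene independently instead of one shared
#'   permutation per shuffle.
#' @param permutations optional list of explicit permutations (overrides
#'   `n_shuffles`/`seed`; used for degenerate-case testing).
#' @return shuffled `occurrence_histogram`.
#' @export
shuffle_null <- function(counts, breaks, n_shuffles = 500, seed = 1,
                         alpha = 0.05, stratify = c("amplitude", "coverage"),
                         fit_period = 22, variance_model = NULL,
                         per_gene = FALSE, permutations = NULL) {
  stratify <- match.arg(stratify)
  res <- shuffle_occurrence(counts, setNames(list(breaks), stratify),
                            n_shuffles = n_shuffles, seed = seed,
                            alpha = alpha, fit_period = fit_period,
                            variance_model = variance_model,
                            per_gene = per_gene,
                            permutations = permutations)
  res[[stratify]]
}

# Core shuffle loop shared across stratifiers: breaks_list is a named list
# over {"amplitude", "coverage"}; one set of shuffles feeds every histogram.
shuffle_occurrence <- function(counts, breaks_list, n_shuffles = 500,
                               seed = 1, alpha = 0.05, fit_period = 22,
                               variance_model = NULL, per_gene = FALSE,
                               permutations = NULL) {
  stopifnot(inherits(counts, "ccg_counts"), !is.null(counts$times),
            all(names(breaks_list) %in% c("amplitude", "coverage")))
  if (is.null(permutations) && n_shuffles < 1)
    stop("n_shuffles must be >= 1")
  Y <- counts$counts
  nt <- ncol(Y)
  if (nt < 8) stop("need at least 8 time points")
  nsh <- if (is.null(permutations)) n_shuffles else length(permutations)
  acc <- lapply(breaks_list, function(b) numeric(length(b) - 1))
  with_seed(derive_seed(seed, "shuffle_null"), {
    for (b in seq_len(nsh)) {
      Yp <- if (!is.null(permutations)) {
        Y[, permutations[[b]], drop = FALSE]
      } else if (per_gene) {
        t(apply(Y, 1, function(r) r[sample(nt)]))
      } else {
        Y[, sample(nt), drop = FALSE]
      }
      det <- detect_rhythm_dual_matrix(Yp, counts$times, refine = FALSE,
                                       alpha = alpha)
      called <- which(det$rhythmic)
      if (length(called)) {
        fits <- fit_sine_nb_matrix(Yp[called, , drop = FALSE],
                                   counts$times, fit_period,
                                   variance_model)
        for (strat in names(breaks_list)) {
          vals <- if (strat == "amplitude") log2(fits$fold_amplitude)
                  else log10(pmax(fits$coverage, 0.5))
          acc[[strat]] <- acc[[strat]] +
            occurrence_histogram(vals, breaks_list[[strat]])$counts
        }
      }
    }
  })
  out <- lapply(names(breaks_list), function(strat) {
    br <- breaks_list[[strat]]
    structure(list(breaks = br, mids = (br[-1] + br[-length(br)]) / 2,
                   counts = acc[[strat]] / nsh, source = "shuffled",
                   n_shuffles = nsh),
              class = "occurrence_histogram")
  })
  setNames(out, names(breaks_list))
}

#' Fit an exponential decay to an occurrence histogram
#'
#' Fits `f(x) = c exp(-lambda x)` to bin centers vs counts by count-weighted
#' nonlinear least squares (weights = counts; zero bins kept with weight 1).
#' `lambda` is floored at 0. The fit uses the decaying flank only — bins
#' from the histogram mode rightward: occurrence histograms of rhythmic
#' calls rise before they decay (near-zero fitted amplitudes are rare among
#' called genes), and including the rising flank forces a spuriously shallow
#' decay whose extrapolated tail is orders of magnitude too heavy.
#'
#' @param hist an `occurrence_histogram`.
#' @return a `decay_fit`: list with `c`, `lambda`, `domain` (modal bin to
#'   last bin), `rss`, and the evaluator `fn(x)`.
#' @export
fit_decay <- function(hist) {
  i0 <- which.max(hist$counts)
  x <- hist$mids[i0:length(hist$mids)]
  y <- hist$counts[i0:length(hist$counts)]
  if (sum(y > 0) < 3)
    stop("fewer than 3 nonzero bins; widen the bins")
  w <- ifelse(y > 0, y, 1)
  # weighted log-linear start
  pos <- y > 0
  lf <- lm.fit(cbind(1, x[pos]) * sqrt(w[pos]), log(y[pos]) * sqrt(w[pos]))
  c0 <- exp(lf$coefficients[1]); l0 <- max(0, -lf$coefficients[2])
  obj <- function(par) sum(w * (y - exp(par[1]) * exp(-exp(par[2]) * x))^2)
  # optimize on log scale, lambda floored at 0 afterwards
  fit <- tryCatch(
    nls(y ~ cc * exp(-ll * x), start = list(cc = c0, ll = max(l0, 1e-6)),
        weights = w, lower = c(1e-12, 0), algorithm = "port",
        control = list(warnOnly = TRUE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    pars <- coef(fit)
    cc <- unname(pars["cc"]); ll <- max(0, unname(pars["ll"]))
  } else {
    op <- optim(c(log(max(c0, 1e-6)), log(max(l0, 1e-6))), obj)
    cc <- exp(op$par[1]); ll <- exp(op$par[2])
  }
  fn <- function(z) cc * exp(-ll * z)
  structure(list(c = cc, lambda = ll, domain = range(x),
                 rss = sum(w * (y - fn(x))^2), fn = fn),
            class = "decay_fit")
}

#' Weight functions for the FDR formula
#'
#' `weight_identity` is 1 everywhere. `weight_occupancy(hist)` returns
#' `1 - exp(-n_ob(x))`, a saturating function of the raw observed bin
#' occupancy, which shrinks the FDR in sparsely populated high-amplitude
#' bins (the stated purpose of the weight term).
#'
#' @param x stratifier values.
#' @return `weight_identity`: 1s; `weight_occupancy`: a function of x.
#' @export
weight_identity <- function(x) rep(1, length(x))

#' @rdname weight_identity
#' @param hist observed `occurrence_histogram` supplying bin occupancies.
#' @export
weight_occupancy <- function(hist) {
  force(hist)
  function(x) {
    i <- findInterval(x, hist$breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
    1 - exp(-hist$counts[i])
  }
}

#' FDR curve from observed and background decay fits
#'
#' `FDR(x) = f_bg(x) / (f_ob(x) + f_bg(x)) * Weight(x)`, clamped to `[0, 1]`
#' and made monotone non-increasing in `x` by an isotonic pass (documented
#' post-processing: a larger amplitude or coverage never gets a larger FDR).
#' With `denominator = "observed"` the alternative `f_bg / f_ob` form is
#' used (the verbatim form tends to 0.5 rather than 1 on pure-null data).
#'
#' @param observed,background `decay_fit`s on a shared domain.
#' @param weight a weight function of x (default [weight_identity]).
#' @param stratifier `"amplitude"` or `"coverage"` (label only).
#' @param n_grid evaluation grid size.
#' @param denominator `"both"` (printed form, default) or `"observed"`.
#' @return an `fdr_curve`: list with `x`, `fdr`, `fdr_raw` (pre-isotonic),
#'   `stratifier`, the two fits and the weight id.
#' @export
fdr_curve <- function(observed, background, weight = weight_identity,
                      stratifier = "amplitude", n_grid = 200,
                      denominator = c("both", "observed")) {
  denominator <- match.arg(denominator)
  dom <- range(c(observed$domain, background$domain))
  x <- seq(dom[1], dom[2], length.out = n_grid)
  fo <- observed$fn(x); fb <- background$fn(x)
  den <- if (denominator == "both") fo + fb else fo
  raw <- ifelse(den == 0, NA_real_, fb / den * weight(x))
  raw <- pmin(pmax(raw, 0), 1)
  # isotonic non-increasing pass (never increases any value where it was
  # already non-increasing)
  ok <- !is.na(raw)
  iso <- raw
  if (sum(ok) > 1)
    iso[ok] <- -isoreg(x[ok], -raw[ok])$yf
  iso <- pmin(pmax(iso, 0), 1)
  structure(list(x = x, fdr = iso, fdr_raw = raw, stratifier = stratifier,
                 observed = observed, background = background,
                 denominator = denominator),
            class = "fdr_curve")
}

#' Evaluate an FDR curve
#'
#' @param curve an `fdr_curve`.
#' @param x stratifier values; values beyond the fitted domain are clamped
#'   to the domain ends.
#' @return per-value FDR in `[0, 1]`.
#' @export
evaluate_fdr <- function(curve, x) {
  approxfun(curve$x, curve$fdr, rule = 2)(x)
}

#' Assign per-gene FDRs
#'
#' Evaluates the amplitude curve at each gene's log2 fold amplitude and, when
#' a coverage curve is given, the coverage curve at log10 median coverage;
#' the combined assignment is the maximum of the two (conservative).
#'
#' @param fits data.frame of sine fits with `fold_amplitude` and `coverage`
#'   columns (e.g. from [rhythm_analysis()]).
#' @param amplitude_curve `fdr_curve` with amplitude stratifier.
#' @param coverage_curve optional `fdr_curve` with coverage stratifier.
#' @return `fits` with added columns `fdr_amplitude`, `fdr_coverage` (NA if
#'   no coverage curve) and `fdr` (the combined value).
#' @export
assign_fdr <- function(fits, amplitude_curve, coverage_curve = NULL) {
  fa <- evaluate_fdr(amplitude_curve, log2(fits$fold_amplitude))
  fc <- if (is.null(coverage_curve)) rep(NA_real_, nrow(fits)) else
    evaluate_fdr(coverage_curve, log10(pmax(fits$coverage, 0.5)))
  fits$fdr_amplitude <- fa
  fits$fdr_coverage <- fc
  fits$fdr <- pmax(fa, fc, na.rm = TRUE)
  fits
}
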