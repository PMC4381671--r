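# Two-sided NB exact test for condition pairs, with a locally fitted
# mean-variance relationship shared across genes.

#' Fit a smooth mean-variance relationship across genes
#'
#' Counts are modelled as G ~ NB(mu, sigma^2) with sigma^2 a smooth function
#' of mu. Per gene (and condition), the sample mean and variance across
#' replicates are computed; the excess variance is regressed on the mean by
#' local regression (loess) on the dispersion scale (v - mu)/mu^2 across all
#' genes, negative excess values included, which keeps the curve unbiased at
#' small replicate numbers. The fitted function is linearly extrapolated
#' beyond the observed mean range and floored at the Poisson variance.
#'
#' @param counts genes x replicates matrix, a `ccg_counts`, or a list of
#'   per-condition matrices (each with >= 2 replicate columns).
#' @param span loess span (default 0.75).
#' @param min_genes minimum number of genes with positive excess variance
#'   required for an identifiable fit (default 30).
#' @return a `mean_variance_model`: list with evaluator `fn(mu)`, the
#'   observed mean range, and fitting metadata.
#' @export
fit_mean_variance <- function(counts, span = 0.75, min_genes = 30) {
  mats <- if (inherits(counts, "ccg_counts")) list(counts$counts)
          else if (is.list(counts) && !is.data.frame(counts)) {
            lapply(counts, function(m)
              if (inherits(m, "ccg_counts")) m$counts else as.matrix(m))
          } else list(as.matrix(counts))
  mv <- do.call(rbind, lapply(mats, function(m) {
    if (ncol(m) < 2) stop("need >= 2 replicates per condition")
    data.frame(mu = rowMeans(m), v = apply(m, 1, var))
  }))
  mv <- mv[mv$mu > 0, ]
  mv$excess <- mv$v - mv$mu
  if (sum(mv$excess > 0) < min_genes)
    stop(sprintf(paste("only %d genes with positive excess variance",
                       "(need >= %d); mean-variance fit unidentifiable",
                       "- data may be Poisson"), sum(mv$excess > 0),
                 min_genes))
  fit_excess_loess(mv, span)
}

# Shared local-regression core. The fit is done on the dispersion scale,
# phi_hat = (v - mu) / mu^2, over ALL genes (negative values retained):
# truncating at zero or fitting log(excess) would bias the curve upward
# (selection) or downward (Jensen), badly so with few replicates. phi(mu)
# is smoothed by loess against log(mu), linearly extrapolated at the ends,
# clamped at 0, and sigma^2(mu) = mu + phi(mu) mu^2 (Poisson floor).
fit_excess_loess <- function(mv, span) {
  mv$phi_hat <- mv$excess / mv$mu^2
  lo <- loess(phi_hat ~ log(mu), data = mv, span = span, degree = 1,
              control = loess.control(surface = "direct"))
  rng <- range(mv$mu)
  grid <- exp(seq(log(rng[1]), log(rng[2]), length.out = 200))
  pred <- predict(lo, newdata = data.frame(mu = grid))
  interp <- approxfun(log(grid), pred, rule = 2)
  slope_lo <- (pred[2] - pred[1]) / (log(grid[2]) - log(grid[1]))
  slope_hi <- (pred[200] - pred[199]) / (log(grid[200]) - log(grid[199]))
  fn <- function(mu) {
    lmu <- log(pmax(mu, 1e-12))
    phi <- interp(lmu)
    lo_i <- lmu < log(grid[1]); hi_i <- lmu > log(grid[200])
    phi[lo_i] <- pred[1] + slope_lo * (lmu[lo_i] - log(grid[1]))
    phi[hi_i] <- pred[200] + slope_hi * (lmu[hi_i] - log(grid[200]))
    mu + pmax(phi, 0) * mu^2
  }
  structure(list(fn = fn, mean_range = rng, n_genes = nrow(mv),
                 span = span),
            class = "mean_variance_model")
}

#' A mean-variance model from a known dispersion function
#'
#' Convenience wrapper turning `var = fn(mu)` (e.g. the simulator's
#' dispersion) into a `mean_variance_model` usable wherever a fitted one is.
#'
#' @param var_fn function mu -> variance (must satisfy var >= mu).
#' @return a `mean_variance_model`.
#' @export
mean_variance_known <- function(var_fn) {
  structure(list(fn = function(mu) pmax(var_fn(mu), mu),
                 mean_range = c(0, Inf), n_genes = NA_integer_,
                 span = NA_real_),
            class = "mean_variance_model")
}

#' Mean-variance relation from a time course (pseudo-replicate fallback)
#'
#' When no replicated design exists, time points serve as pseudo-replicates
#' after removing the fitted harmonic: per gene, a harmonic regression on the
#' log1p scale at the given period supplies a time-varying mean, and the
#' residual variance around it (on the count scale) is paired with the mean
#' of the fitted values.
#'
#' @param counts `ccg_counts` time course.
#' @param period harmonic period used for detrending (default 22).
#' @inheritParams fit_mean_variance
#' @return a `mean_variance_model`.
#' @export
fit_mean_variance_timecourse <- function(counts, period = 22, span = 0.75,
                                         min_genes = 30) {
  stopifnot(inherits(counts, "ccg_counts"), !is.null(counts$times))
  # drop t = 0: light-inflated samples would masquerade as huge residual
  # variance (same rationale as the dual with/without-t0 detection run)
  keep <- counts$times != 0
  t <- counts$times[keep]
  w <- 2 * pi / period
  X <- cbind(1, cos(w * t), sin(w * t))
  qx <- qr(X)
  Y <- counts$counts[, keep, drop = FALSE]
  Z <- t(log1p(Y))
  fitted_log <- qr.fitted(qx, Z)
  mu_t <- expm1(t(fitted_log))       # genes x times fitted means
  mu <- rowMeans(mu_t)
  d <- ncol(Y) - 3
  v <- rowSums((Y - mu_t)^2) / d
  mv <- data.frame(mu = mu, v = v)
  mv <- mv[mv$mu > 0, ]
  mv$excess <- mv$v - mv$mu
  if (sum(mv$excess > 0) < min_genes)
    stop("too few genes with positive excess variance")
  fit_excess_loess(mv, span)
}

#' Two-sided NB exact test p-value
#'
#' Conditional on the total s = G_treat + G_control, both samples are NB with
#' null mean s/2 and variance sigma^2(s/2) from the mean-variance model. All
#' outcomes (a, b) with a + b = s are enumerated and
#' p = sum of f(a) f(b) over outcomes no more probable than the observed one,
#' divided by the total. When sigma^2 <= mu the Poisson limit is used, where
#' the test reduces to the conditional two-sided binomial(s, 1/2) test.
#'
#' @param G_treat,G_control size-factor-normalized counts rounded to
#'   integers.
#' @param model a `mean_variance_model` (or function mu -> variance).
#' @return two-sided p-value in (0, 1]; 1 when `G_treat == G_control` or
#'   s = 0.
#' @examples
#' m <- mean_variance_known(function(mu) mu)  # Poisson
#' nb_exact_pvalue(1, 3, m)  # 10/16 = 0.625
#' @export
nb_exact_pvalue <- function(G_treat, G_control, model) {
  stopifnot(G_treat >= 0, G_control >= 0,
            G_treat == round(G_treat), G_control == round(G_control))
  s <- G_treat + G_control
  if (s == 0) return(1)
  if (s > 1e6) stop("total count above the 1e6 enumeration cap")
  var_fn <- if (inherits(model, "mean_variance_model")) model$fn else model
  m <- s / 2
  v <- var_fn(m)
  a <- 0:s
  lf <- if (v <= m * (1 + 1e-12)) dpois(a, m, log = TRUE)
        else dnbinom(a, mu = m, size = m^2 / (v - m), log = TRUE)
  lab <- lf + rev(lf)                    # log f(a) + log f(s - a)
  lobs <- lf[G_treat + 1] + lf[G_control + 1]
  keep <- lab <= lobs + 1e-10            # ties included, fp-tolerant
  # normalized sum on the probability scale
  mx <- max(lab)
  sum(exp(lab[keep] - mx)) / sum(exp(lab - mx))
}

#' Differential expression by the NB exact test
#'
#' Size factors are computed on the combined matrix (median-of-ratios),
#' counts are normalized, summed across replicates per condition, rounded
#' half-to-even, and tested per gene with [nb_exact_pvalue()]. P-values are
#' Benjamini-Hochberg adjusted across genes.
#'
#' @param treat,control `ccg_counts` (raw) with matching gene sets.
#' @param model optional `mean_variance_model`; fitted from the normalized
#'   replicates when missing (requires >= 2 replicates per condition).
#' @param alpha adjusted-p call threshold (default 0.05).
#' @return data.frame (DEResult): gene, mean_treat, mean_control, log2fc,
#'   p, p_adj, call (`-1`, `0`, `1`).
#' @export
run_de <- function(treat, control, model = NULL, alpha = 0.05) {
  stopifnot(inherits(treat, "ccg_counts"), inherits(control, "ccg_counts"))
  if (!identical(gene_ids(treat), gene_ids(control)))
    stop("treat and control must share the same gene set")
  comb <- cbind(treat$counts, control$counts)
  sf <- size_factors(comb)
  nt <- ncol(treat$counts)
  nc <- ncol(control$counts)
  if (nt != nc)
    stop("the exact test requires equal replicate numbers per condition")
  Tn <- sweep(treat$counts, 2, sf[seq_len(nt)], "/")
  Cn <- sweep(control$counts, 2, sf[-seq_len(nt)], "/")
  if (is.null(model)) model <- fit_mean_variance(list(Tn, Cn))
  # the tested quantities are replicate sums: a sum of n iid NB counts has
  # variance n * sigma^2(mu/n), not sigma^2(mu)
  var_fn <- if (inherits(model, "mean_variance_model")) model$fn else model
  sum_model <- function(mu) nt * var_fn(mu / nt)
  Gt <- round(rowSums(Tn))
  Gc <- round(rowSums(Cn))
  p <- vapply(seq_along(Gt),
              function(i) nb_exact_pvalue(Gt[i], Gc[i], sum_model),
              numeric(1))
  p_adj <- p.adjust(p, "BH")
  mt <- rowMeans(Tn); mc <- rowMeans(Cn)
  lfc <- log2((mt + 0.5) / (mc + 0.5))
  data.frame(gene = gene_ids(treat), mean_treat = mt, mean_control = mc,
             log2fc = lfc, p = p, p_adj = p_adj,
             call = ifelse(p_adj < alpha, sign(lfc), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}
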