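#' @importFrom stats approxfun coef dnbinom dpois isoreg lm.fit loess
#'   loess.control median nls optim optimize p.adjust pf phyper predict
#'   quantile rlnorm rnbinom rnorm rpois runif setNames var
#' @importFrom utils read.table write.table modifyList packageVersion
NULL

# Deterministic seed splitting: every stage draws from its own stream derived
# from (master seed, label), so stages are independently reproducible and
# inserting a stage never perturbs another stage's draws.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483629L
  as.integer((as.numeric(seed) + h) %% 2147483629L) + 1L
}

# Evaluate `expr` under a local RNG state; the caller's .Random.seed is
# restored afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Minimal circular distance between two phases
#'
#' @param p1,p2 phases in hours, any real values (wrapped modulo `period`).
#' @param period oscillation period in hours (default 22).
#' @return non-negative distance in `[0, period/2]`, vectorized.
#' @examples
#' phase_difference(21, 1, 22)  # 2
#' phase_difference(0, 11, 22)  # 11
#' @export
phase_difference <- function(p1, p2, period = 22) {
  d <- abs(p1 - p2) %% period
  pmin(d, period - d)
}

# Signed circular shift p2 - p1 in (-period/2, period/2].
phase_shift_signed <- function(p1, p2, period = 22) {
  s <- (p2 - p1) %% period
  ifelse(s > period / 2, s - period, s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
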