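# Independent oracles and fixture builders shared across the suite.

# Two-state Bayes by direct product enumeration (no log-space): the
# implementation under test uses log sums, so this is a distinct route.
oracle_posterior <- function(p, prior) {
  num <- prod(p) * prior
  den <- num + prod(1 - p) * (1 - prior)
  num / den
}

# Percentile by explicit sort + linear interpolation between order statistics.
oracle_percentile <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Series whose per-year normal pass probabilities are exactly `p`
# (target 0, sd 1, higher_is_better => mean = qnorm(p)).
series_with_p <- function(id, years, p, sd = 1) {
  indicator_series(id, years, qnorm(p) * sd, sds = sd, target = 0)
}

# Flat series sitting exactly at its target.
series_at_target <- function(id, years, target = 1, sd = 0.1) {
  indicator_series(id, years, rep(target, length(years)), sds = sd,
                   target = target)
}

random_matrix <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("C%02d", seq_len(p))))
  m
}

# Whole-matrix explained variance share of a single selected column under the
# package's selection accounting, derived analytically for an ensemble of p
# exchangeable indicators sharing one factor of variance share s:
# the selected column counts fully, each other column by its squared
# correlation s^2 with the selected one.
oracle_single_pick_share <- function(s, p) (1 + (p - 1) * s^2) / p
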