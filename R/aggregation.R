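#' One-out-all-out verdict and its joint pass probability
#'
#' The exclusive aggregation rule used by several European assessment
#' frameworks: overall status passes only if every single indicator passes.
#' Two faces are exposed: the deterministic verdict (every mean on the good
#' side, i.e. every pass probability above 0.5) and the statistical cost of
#' the rule — the probability that all indicators pass simultaneously, which
#' is the plain product of the individual pass probabilities for
#' conditionally independent indicators.
#'
#' @param p Vector of per-indicator pass probabilities in \[0, 1\].
#' @return List with `verdict` (`"pass"`/`"fail"`) and
#'   `joint_pass_probability`.
#' @examples
#' ooao_verdict(c(0.95, 0.95, 0.95))  # joint 0.857 despite a clear pass
#' @seealso [type2_curve()] for the cost as a function of indicator count.
#' @export
ooao_verdict <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) stop("'p' must not be empty", call. = FALSE)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("pass probabilities must lie in [0, 1]", call. = FALSE)
  list(verdict = if (all(p > 0.5)) "pass" else "fail",
       joint_pass_probability = prod(p))
}

#' Type-II-error cost of the one-out-all-out rule
#'
#' Joint pass probability `p_each^n` for `n = 1..n_max` indicators that each
#' pass with probability `p_each`: even near-certain individual passes decay
#' geometrically, so the probability of rejecting a truly good state grows
#' quickly with the number of assessment elements.
#'
#' @param n_max Maximum number of indicators, `>= 1`.
#' @param p_each Common individual pass probability in (0, 1\].
#' @return Numeric vector of length `n_max`, strictly decreasing for
#'   `p_each < 1`.
#' @examples
#' type2_curve(11, 0.95)  # drops below 0.57 by n = 11
#' @export
type2_curve <- function(n_max, p_each) {
  n_max <- as.integer(n_max)
  if (is.na(n_max) || n_max < 1L) stop("'n_max' must be >= 1", call. = FALSE)
  if (!is.numeric(p_each) || length(p_each) != 1L || p_each <= 0 || p_each > 1)
    stop("'p_each' must lie in (0, 1]", call. = FALSE)
  p_each^seq_len(n_max)
}

#' Weighted additive utility aggregation
#'
#' The classical additive utility model: each indicator value is mapped to a
#' commensurable \[0, 1\] utility by its own value function and the utilities
#' are combined as a weighted mean (weights normalised to sum to one).
#' Included for method comparison; the Bayesian assessment applies no weights.
#'
#' @param values Per-indicator values (or ready-made utilities if
#'   `value_functions` is `NULL`).
#' @param weights Positive weights, one per indicator; default equal.
#' @param value_functions Optional list of monotone functions mapping each
#'   value into \[0, 1\], or a single function applied to all.
#' @return The aggregate utility in \[0, 1\].
#' @examples
#' weighted_additive(c(0.2, 0.8))                 # 0.5
#' weighted_additive(c(1, 0), weights = c(3, 1))  # 0.75
#' @export
weighted_additive <- function(values, weights = NULL, value_functions = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0L) stop("'values' must not be empty", call. = FALSE)
  if (!is.null(value_functions)) {
    if (is.function(value_functions))
      value_functions <- rep(list(value_functions), n)
    if (length(value_functions) != n)
      stop("'value_functions' must match the number of values", call. = FALSE)
    values <- mapply(function(f, v) f(v), value_functions, values)
  }
  if (any(is.na(values)) || any(values < 0 | values > 1))
    stop("utilities must lie in [0, 1]; supply value_functions mapping into [0, 1]",
         call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n)
    stop("'weights' must match the number of values", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  sum(weights * values) / sum(weights)
}

#' Normalize an indicator series, with diagnostics
#'
#' Element-wise normalization creates data with new properties — variances,
#' orderings and distribution shapes all change — so each transform returns a
#' diagnostics record alongside the values. `"zscore"` standardises to zero
#' mean and unit variance (sample SD, n-1 denominator), erasing scale
#' differences between series; `"eqr"` divides by a reference value (the
#' Ecological Quality Ratio convention, reference mapping to exactly 1),
#' turning interval-scale data into ratio-scale; `"range"` maps the observed
#' span onto \[0, 1\].
#'
#' @param x Numeric values.
#' @param method `"zscore"`, `"eqr"` or `"range"`.
#' @param reference Reference value for `"eqr"`; must be non-zero.
#' @return List with `values` and `diagnostics` (pre/post mean and SD plus a
#'   shape-change note).
#' @examples
#' normalize_indicator(c(10, 20, 30), "zscore")$values
#' normalize_indicator(5, "eqr", reference = 10)$values  # 0.5
#' @export
normalize_indicator <- function(x, method = c("zscore", "eqr", "range"),
                                reference = NULL) {
  method <- match.arg(method)
  x <- as.numeric(x)
  if (length(x) == 0L || any(!is.finite(x)))
    stop("'x' must be non-empty and finite", call. = FALSE)
  pre_mean <- mean(x)
  pre_sd <- if (length(x) > 1L) stats::sd(x) else NA_real_
  note <- switch(method,
    zscore = "scale and location removed; shape preserved",
    eqr = "interval scale changed to ratio scale; distribution shape altered relative to the reference",
    range = "distribution compressed onto [0, 1]; shape altered near the observed extremes")
  vals <- switch(method,
    zscore = {
      if (length(x) < 2L || pre_sd == 0)
        stop("zscore needs >= 2 distinct values", call. = FALSE)
      (x - pre_mean) / pre_sd
    },
    eqr = {
      if (is.null(reference) || !is.finite(reference) || reference == 0)
        stop("eqr needs a non-zero 'reference'", call. = FALSE)
      x / reference
    },
    range = {
      r <- range(x)
      if (r[1] == r[2])
        stop("range normalization needs non-constant values", call. = FALSE)
      (x - r[1]) / (r[2] - r[1])
    })
  list(values = vals,
       diagnostics = list(
         method = method,
         pre_mean = pre_mean, pre_sd = pre_sd,
         post_mean = mean(vals),
         post_sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
         note = note))
}
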