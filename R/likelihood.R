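#' Probability that an indicator passes its target
#'
#' The censored-data likelihood at the heart of the assessment: instead of the
#' density of the observed mean, the likelihood of the hypothesis "GES" is the
#' probability mass the sampling distribution of the mean places on the good
#' side of the target. For a symmetric sampling distribution a mean exactly at
#' the target yields 0.5 — the indicator is as likely as not to have passed.
#'
#' Distributions: `"normal"` places `Normal(mean, sd)` on the measurement
#' scale; `"lognormal"` matches the first two moments of a lognormal to
#' `(mean, sd)` (suited to strictly positive, right-skewed concentration data
#' and requiring `mean > 0`, `target > 0`); `"degenerate"` ignores `sd` and
#' scores the mean against the target as a step function. With `sd = 0` every
#' distribution degenerates to the step: 1 strictly on the good side, 0.5 at
#' the target, 0 otherwise.
#'
#' @param mean Observed indicator mean (vectorised).
#' @param sd Sampling standard deviation of the mean, `>= 0`.
#' @param target Target value in indicator units.
#' @param direction `"higher_is_better"` or `"lower_is_better"`.
#' @param distribution `"normal"` (default), `"lognormal"` or `"degenerate"`.
#' @return Pass probability in \[0, 1\], same length as `mean`.
#' @examples
#' ges_likelihood(10, 2, target = 10)                 # 0.5 at target
#' ges_likelihood(12, 2, target = 10)                 # pnorm(1)
#' ges_likelihood(12, 2, target = 10, "lower_is_better")
#' @export
ges_likelihood <- function(mean, sd, target,
                           direction = c("higher_is_better", "lower_is_better"),
                           distribution = c("normal", "lognormal", "degenerate")) {
  direction <- match.arg(direction)
  distribution <- match.arg(distribution)
  n <- max(length(mean), length(sd), length(target))
  mean <- rep_len(as.numeric(mean), n)
  sd <- rep_len(as.numeric(sd), n)
  target <- rep_len(as.numeric(target), n)
  if (any(!is.finite(mean)) || any(!is.finite(sd)) || any(!is.finite(target)))
    stop("mean, sd and target must be finite", call. = FALSE)
  if (any(sd < 0)) stop("sd must be non-negative", call. = FALSE)

  higher <- direction == "higher_is_better"
  # signed distance to target, positive = good side
  delta <- if (higher) mean - target else target - mean
  step <- ifelse(delta > 0, 1, ifelse(delta == 0, 0.5, 0))
  if (distribution == "degenerate") return(step)

  p <- step  # sd == 0 entries keep the step value
  pos <- sd > 0
  if (any(pos)) {
    if (distribution == "normal") {
      p[pos] <- stats::pnorm(delta[pos] / sd[pos])
    } else {
      if (any(mean[pos] <= 0) || any(target[pos] <= 0))
        stop("lognormal likelihood requires mean > 0 and target > 0",
             call. = FALSE)
      cv2 <- (sd[pos] / mean[pos])^2
      sdlog <- sqrt(log1p(cv2))
      meanlog <- log(mean[pos]) - sdlog^2 / 2
      p[pos] <- stats::plnorm(target[pos], meanlog, sdlog,
                              lower.tail = !higher)
    }
  }
  p
}

#' Per-year pass probabilities of one indicator series
#'
#' Evaluates [ges_likelihood()] at every year of a series, optionally with a
#' precautionary target shift: the effective target is moved by
#' `precaution * sd` toward the bad side, so that passing requires stronger
#' evidence. `precaution = 0` reproduces `ges_likelihood` verbatim; with
#' `precaution = 1` an indicator sitting exactly at its nominal target scores
#' `pnorm(-1)`, about 0.159.
#'
#' @param series An [indicator_series()] with a finite target.
#' @param distribution Passed to [ges_likelihood()].
#' @param precaution Non-negative precaution level in sampling-SD units;
#'   default 0.
#' @return An object of class `"likelihood_profile"`: a data frame with
#'   columns `year` and `p_ges` plus attributes `indicator_id` and
#'   `distribution`.
#' @export
likelihood_profile <- function(series,
                               distribution = c("normal", "lognormal", "degenerate"),
                               precaution = 0) {
  stopifnot(inherits(series, "indicator_series"))
  distribution <- match.arg(distribution)
  if (!is.numeric(precaution) || length(precaution) != 1L || precaution < 0)
    stop("'precaution' must be a single non-negative number", call. = FALSE)
  if (is.na(series$target))
    stop("indicator '", series$id, "' has no target; see derive_target()",
         call. = FALSE)
  shift <- precaution * series$sds
  eff_target <- if (series$direction == "higher_is_better")
    series$target + shift else series$target - shift
  p <- ges_likelihood(series$means, series$sds, eff_target,
                      direction = series$direction,
                      distribution = distribution)
  structure(data.frame(year = series$times, p_ges = p),
            indicator_id = series$id, distribution = distribution,
            precaution = precaution,
            class = c("likelihood_profile", "data.frame"))
}

# Clip pass probabilities away from 0/1 so that no single indicator can make
# the Bayes chain absorbing.
clip_p <- function(p, eps = 1e-9) pmin(pmax(p, eps), 1 - eps)
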