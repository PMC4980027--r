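#' Two-state Bayesian posterior probability of GES
#'
#' Combines per-indicator pass probabilities into the posterior probability of
#' Good Environmental Status under the two exclusive hypotheses GES / non-GES:
#' \deqn{P(GES \mid X) = \frac{\prod_i p_i \cdot \pi}
#'   {\prod_i p_i \cdot \pi + \prod_i (1-p_i) \cdot (1-\pi)}}
#' where \eqn{p_i} is the probability that indicator \eqn{i} passes its target
#' and \eqn{\pi} the prior probability of GES. The likelihood of the data
#' under non-GES is the product of the fail probabilities, forced by the
#' censored pass/fail form and the exclusivity of the two states.
#'
#' The computation runs in log space so that long indicator vectors do not
#' underflow. An empty `p` returns the prior unchanged (no evidence), and an
#' indicator with `p = 0.5` never moves the posterior.
#'
#' @param p Vector of per-indicator pass probabilities in \[0, 1\].
#' @param prior Prior probability of GES, strictly inside (0, 1).
#' @return Posterior probability of GES in \[0, 1\].
#' @examples
#' posterior_ges(c(0.5, 0.5), prior = 0.45)  # 0.45: no evidence either way
#' posterior_ges(c(0.9, 0.2), prior = 0.5)   # 0.18/(0.18+0.08)
#' @export
posterior_ges <- function(p, prior) {
  if (!is.numeric(prior) || length(prior) != 1L || is.na(prior) ||
      prior <= 0 || prior >= 1)
    stop("'prior' must lie strictly inside (0, 1)", call. = FALSE)
  p <- as.numeric(p)
  p <- p[!is.na(p)]
  if (length(p) == 0L) return(prior)
  if (any(p < 0 | p > 1))
    stop("pass probabilities must lie in [0, 1]", call. = FALSE)
  lges <- sum(log(p)) + log(prior)
  lnon <- sum(log1p(-p)) + log1p(-prior)
  if (is.infinite(lges) && is.infinite(lnon)) {
    warning("contradictory certain evidence (both p = 0 and p = 1); ",
            "returning NaN — consider clipping", call. = FALSE)
    return(NaN)
  }
  if (is.infinite(lges)) return(0)
  if (is.infinite(lnon)) return(1)
  1 / (1 + exp(lnon - lges))
}

#' Sequential Bayesian GES assessment of an indicator set
#'
#' The central fitting function: for each assessment year it converts every
#' indicator's mean and sampling SD into a pass probability
#' ([likelihood_profile()]), aggregates them with [posterior_ges()], and
#' chains the posterior of one year into the prior of the next. The chaining
#' gives the index trend memory — it "remembers" the former state, rising
#' under sustained improvement and buffering short-lived fluctuations.
#'
#' An optional discount `lambda < 1` relaxes the memory, shrinking the carried
#' prior toward the uninformative 0.5:
#' `prior[t] = lambda * posterior[t-1] + (1 - lambda) * 0.5`. The default
#' `lambda = 1` is full chaining.
#'
#' With `years = "common"` (default) the assessment runs over the years
#' observed by every indicator; `years = "union"` runs over all observed
#' years, and an indicator missing in a year simply contributes no likelihood
#' factor there (equivalent to uninformative evidence `p = 0.5`).
#'
#' @param set An [indicator_set()]; every series needs a finite target
#'   (see [fill_targets()]).
#' @param prior0 Initial prior probability of GES in (0, 1); default 0.5
#'   (uninformative).
#' @param distribution Sampling distribution of the means: `"normal"`,
#'   `"lognormal"` or `"degenerate"`.
#' @param precaution Precautionary target shift in sampling-SD units; see
#'   [likelihood_profile()].
#' @param clip_eps Pass probabilities are clipped to
#'   `[clip_eps, 1 - clip_eps]` before aggregation so no single certain
#'   indicator can make the chain absorbing; default `1e-9`.
#' @param lambda Prior-chaining discount in (0, 1\]; default 1 (no discount).
#' @param years `"common"` or `"union"`, see Details.
#' @param warning_threshold,warning_k Early-warning scan parameters, see
#'   [early_warning()].
#' @param explained_variance Optional share (in \[0, 1\]) of ecosystem
#'   variability represented by the assessed indicators, as returned by
#'   [select_indicators()] or [ges_rda()]; its complement is the unexplained
#'   error term carried alongside the assessment.
#' @return An object of class `"ges_assessment"`: list with `times`,
#'   `posterior`, `prior_chain`, `likelihoods` (years x indicators matrix),
#'   `warnings` (data frame), `explained_variance` and `config`.
#' @examples
#' a <- indicator_series("A", 2007:2008, c(1, 1), sds = 0.1, target = 1)
#' b <- indicator_series("B", 2007:2008, c(2, 2), sds = 0.2, target = 2)
#' fit <- ges_assess(indicator_set(a, b), prior0 = 0.45)
#' fit$posterior  # 0.45 both years: all evidence sits exactly at target
#' @seealso [posterior_ges()], [early_warning()], [ooao_verdict()]
#' @export
ges_assess <- function(set, prior0 = 0.5,
                       distribution = c("normal", "lognormal", "degenerate"),
                       precaution = 0, clip_eps = 1e-9, lambda = 1,
                       years = c("common", "union"),
                       warning_threshold = 0.25, warning_k = 3,
                       explained_variance = NA_real_) {
  stopifnot(inherits(set, "indicator_set"))
  distribution <- match.arg(distribution)
  years <- match.arg(years)
  if (!is.numeric(prior0) || length(prior0) != 1L || prior0 <= 0 || prior0 >= 1)
    stop("'prior0' must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0 || lambda > 1)
    stop("'lambda' must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(clip_eps) || clip_eps < 0 || clip_eps >= 0.5)
    stop("'clip_eps' must lie in [0, 0.5)", call. = FALSE)
  missing_target <- vapply(set$series, function(s) is.na(s$target), logical(1))
  if (any(missing_target))
    stop("indicator(s) without target: ",
         paste(names(which(missing_target)), collapse = ", "),
         "; see fill_targets()", call. = FALSE)

  ids <- names(set$series)
  tt <- if (years == "common") set$common_times else
    sort(unique(unlist(lapply(set$series, `[[`, "times"))))

  L <- matrix(NA_real_, length(tt), length(ids),
              dimnames = list(tt, ids))
  for (s in set$series) {
    prof <- likelihood_profile(s, distribution = distribution,
                               precaution = precaution)
    hit <- match(tt, prof$year)
    L[, s$id] <- prof$p_ges[hit]
  }

  posterior <- prior_chain <- numeric(length(tt))
  prior <- prior0
  for (k in seq_along(tt)) {
    prior_chain[k] <- prior
    pk <- L[k, ]
    pk <- clip_p(pk[!is.na(pk)], eps = clip_eps)
    posterior[k] <- posterior_ges(pk, prior)
    # keep the chain non-absorbing: the carried prior stays inside (0, 1)
    prior <- clip_p(lambda * posterior[k] + (1 - lambda) * 0.5,
                    eps = max(clip_eps, 1e-12))
  }

  out <- structure(
    list(times = tt, posterior = posterior, prior_chain = prior_chain,
         likelihoods = L,
         warnings = NULL,
         explained_variance = as.numeric(explained_variance),
         config = list(prior0 = prior0, distribution = distribution,
                       precaution = precaution, clip_eps = clip_eps,
                       lambda = lambda, years = years,
                       warning_threshold = warning_threshold,
                       warning_k = warning_k)),
    class = "ges_assessment")
  out$warnings <- early_warning(out, threshold = warning_threshold,
                                k = warning_k)
  out
}

#' Early-warning flags from persistent indicator likelihoods
#'
#' A run of `k` or more consecutive years in which one indicator's pass
#' probability stays below `threshold` (or above `1 - threshold`) signals a
#' persistent change in that ecosystem component even while the aggregate
#' posterior may remain unremarkable. Each maximal qualifying run yields one
#' flag.
#'
#' @param a A `"ges_assessment"` from [ges_assess()].
#' @param threshold Likelihood band edge in (0, 1); default 0.25.
#' @param k Minimum run length in years; default 3. If `k` exceeds the number
#'   of assessed years an empty result is returned with a message.
#' @return Data frame with columns `indicator`, `side` (`"low"`/`"high"`),
#'   `from`, `to`, `length`.
#' @export
early_warning <- function(a, threshold = 0.25, k = 3) {
  stopifnot(inherits(a, "ges_assessment"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie in (0, 1)", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  empty <- data.frame(indicator = character(), side = character(),
                      from = integer(), to = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (k > length(a$times)) {
    message("early_warning: k = ", k, " exceeds the ", length(a$times),
            " assessed year(s); no flags possible")
    return(empty)
  }
  scan_side <- function(id, hit, side) {
    r <- rle(hit & !is.na(hit))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- r$values & r$lengths >= k
    if (!any(sel)) return(empty)
    data.frame(indicator = id, side = side,
               from = a$times[starts[sel]], to = a$times[ends[sel]],
               length = r$lengths[sel], stringsAsFactors = FALSE)
  }
  out <- lapply(colnames(a$likelihoods), function(id) {
    p <- a$likelihoods[, id]
    rbind(scan_side(id, p < threshold, "low"),
          scan_side(id, p > 1 - threshold, "high"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.ges_assessment <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<ges_assessment> %d indicator(s), years %d-%d\n",
              ncol(x$likelihoods), min(x$times), max(x$times)))
  cat(sprintf("  prior0 = %.3g, distribution = %s, precaution = %.3g\n",
              x$config$prior0, x$config$distribution, x$config$precaution))
  cat(sprintf("  P(GES) %d: %.1f%%  ->  %d: %.1f%%\n",
              x$times[1], 100 * x$posterior[1],
              x$times[n], 100 * x$posterior[n]))
  if (!is.na(x$explained_variance))
    cat(sprintf("  explained ecosystem variance: %.0f%% (error term: %.0f%%)\n",
                100 * x$explained_variance, 100 * (1 - x$explained_variance)))
  nw <- if (is.null(x$warnings)) 0L else nrow(x$warnings)
  cat(sprintf("  early warnings: %d\n", nw))
  invisible(x)
}

#' @export
summary.ges_assessment <- function(object, ...) {
  df <- as.data.frame(object)
  structure(list(table = df, warnings = object$warnings,
                 config = object$config,
                 explained_variance = object$explained_variance),
            class = "summary.ges_assessment")
}

#' @export
print.summary.ges_assessment <- function(x, ...) {
  cat("Sequential Bayesian GES assessment\n\n")
  tab <- x$table
  tab$prior <- sprintf("%.4f", tab$prior)
  tab$posterior <- sprintf("%.4f", tab$posterior)
  print(tab, row.names = FALSE)
  if (!is.na(x$explained_variance))
    cat(sprintf("\nExplained ecosystem variance: %.1f%%\n",
                100 * x$explained_variance))
  if (!is.null(x$warnings) && nrow(x$warnings)) {
    cat("\nEarly warnings:\n")
    print(x$warnings, row.names = FALSE)
  } else cat("\nNo early warnings.\n")
  invisible(x)
}

#' @export
as.data.frame.ges_assessment <- function(x, ...) {
  data.frame(year = x$times, prior = x$prior_chain, posterior = x$posterior,
             row.names = NULL)
}

#' Plot a GES assessment
#'
#' Draws the posterior probability of GES over time (solid, with the chained
#' prior dashed) above a second panel with the per-indicator likelihood
#' trajectories; the 50% line marks indifference and the dotted lines the
#' early-warning band.
#'
#' @param x A `"ges_assessment"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ges_assessment <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$times, x$posterior, type = "b", ylim = c(0, 1), pch = 16,
                 xlab = "", ylab = "P(GES)", main = "Posterior probability of GES",
                 ...)
  graphics::lines(x$times, x$prior_chain, lty = 2, col = "grey40")
  graphics::abline(h = 0.5, col = "grey70")
  graphics::matplot(x$times, x$likelihoods, type = "l", lty = 1,
                    ylim = c(0, 1), xlab = "year", ylab = "pass probability",
                    main = "Indicator likelihoods")
  graphics::abline(h = c(x$config$warning_threshold,
                         1 - x$config$warning_threshold),
                   lty = 3, col = "grey60")
  graphics::abline(h = 0.5, col = "grey70")
  invisible(x)
}
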