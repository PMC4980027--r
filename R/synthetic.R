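#' Specify a latent-factor synthetic indicator ensemble
#'
#' Recipe for generating correlated indicator time series the way real
#' monitoring ensembles behave: a few latent ecosystem factors (e.g. a
#' dominant policy/pressure response, a second river-load signal) drive many
#' indicators jointly, on top of per-indicator trends, process noise and a
#' reported sampling SD.
#'
#' When `factor_loadings` is not given it is built from `factor_shares`: every
#' indicator assigned to factor f gets loading `sqrt(share_f * p / n_f)`
#' (p = indicator count, n_f = indicators on that factor), so factor f
#' contributes `share_f` of the total variance. When `noise_sd` is `NULL`,
#' per-indicator noise is set to `sqrt(1 - sum of squared loadings)`, giving
#' unit-variance columns: factor shares and noise shares then sum to one by
#' construction.
#'
#' @param n_indicators,n_years Ensemble dimensions.
#' @param factor_shares Target variance shares of the latent factors (e.g.
#'   `c(0.44, 0.13)`); may be empty for pure noise.
#' @param factor_assign Optional integer vector (length `n_indicators`)
#'   assigning each indicator to one factor (0 = none); default: all on
#'   factor 1, or round-robin if that would overload a share.
#' @param factor_loadings Optional explicit indicators x factors loading
#'   matrix, overriding the share construction.
#' @param noise_sd Per-indicator process-noise SD (scalar or vector), or
#'   `NULL` to complete unit variance.
#' @param trend_slopes Per-indicator linear trend per year (scalar recycled);
#'   default 0.
#' @param mean_offsets Per-indicator constant offset; default 0.
#' @param obs_sd Reported sampling SD of each annual mean; default 0.3.
#' @param targets Per-indicator targets, or `NULL` for the long-run
#'   (trend-mid-series) mean so series start near a pass probability of 0.5.
#' @param directions Per-indicator direction, recycled.
#' @param ar AR(1) coefficient of the factors in \[0, 1); 0 (default) gives
#'   independent years.
#' @param ids Indicator ids; default `IND01`, `IND02`, ...
#' @param start_year First year; default 2001.
#' @param seed Default seed used by [generate_indicators()].
#' @return An object of class `"synthetic_spec"`.
#' @seealso [generate_indicators()], [scenario()]
#' @export
synthetic_spec <- function(n_indicators, n_years, factor_shares = numeric(0),
                           factor_assign = NULL, factor_loadings = NULL,
                           noise_sd = NULL, trend_slopes = 0,
                           mean_offsets = 0, obs_sd = 0.3, targets = NULL,
                           directions = "higher_is_better", ar = 0,
                           ids = NULL, start_year = 2001L, seed = 1L) {
  p <- as.integer(n_indicators); ny <- as.integer(n_years)
  if (p < 1L || ny < 2L)
    stop("need n_indicators >= 1 and n_years >= 2", call. = FALSE)
  nf <- if (!is.null(factor_loadings)) ncol(factor_loadings)
        else length(factor_shares)
  if (is.null(factor_loadings)) {
    L <- matrix(0, p, max(nf, 1L))[, seq_len(nf), drop = FALSE]
    if (nf > 0L) {
      if (is.null(factor_assign)) factor_assign <- rep(1L, p)
      factor_assign <- rep_len(as.integer(factor_assign), p)
      for (f in seq_len(nf)) {
        on_f <- which(factor_assign == f)
        if (length(on_f) == 0L)
          stop("factor ", f, " has no assigned indicators", call. = FALSE)
        L[on_f, f] <- sqrt(factor_shares[f] * p / length(on_f))
      }
    }
    factor_loadings <- L
  } else {
    factor_loadings <- as.matrix(factor_loadings)
    if (nrow(factor_loadings) != p)
      stop("factor_loadings must have n_indicators rows", call. = FALSE)
  }
  comm <- rowSums(factor_loadings^2)
  if (is.null(noise_sd)) {
    if (any(comm > 1 + 1e-9))
      stop("squared loadings exceed 1 for indicator(s) ",
           paste(which(comm > 1 + 1e-9), collapse = ", "),
           "; cannot complete unit variance", call. = FALSE)
    noise_sd <- sqrt(pmax(1 - comm, 0))
  } else noise_sd <- rep_len(as.numeric(noise_sd), p)
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative", call. = FALSE)
  if (!is.numeric(ar) || ar < 0 || ar >= 1)
    stop("'ar' must lie in [0, 1)", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("IND%02d", seq_len(p))
  if (anyDuplicated(ids)) stop("ids must be unique", call. = FALSE)
  structure(list(
    n_indicators = p, n_years = ny,
    factor_loadings = factor_loadings,
    factor_shares = if (length(factor_shares)) factor_shares else
      colSums(factor_loadings^2) / p,
    noise_sd = noise_sd,
    trend_slopes = rep_len(as.numeric(trend_slopes), p),
    mean_offsets = rep_len(as.numeric(mean_offsets), p),
    obs_sd = rep_len(as.numeric(obs_sd), p),
    targets = if (is.null(targets)) NULL else rep_len(as.numeric(targets), p),
    directions = rep_len(as.character(directions), p),
    ar = ar, ids = as.character(ids),
    start_year = as.integer(start_year), seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d indicators x %d years, %d factor(s)\n",
              x$n_indicators, x$n_years, ncol(x$factor_loadings)))
  if (ncol(x$factor_loadings))
    cat("  factor variance shares:",
        paste(sprintf("%.2f", x$factor_shares), collapse = ", "), "\n")
  cat(sprintf("  obs_sd %s, ar %.2f, seed %d\n",
              format(x$obs_sd[1]), x$ar, x$seed))
  invisible(x)
}

#' Generate a synthetic indicator ensemble
#'
#' Draws the ensemble defined by a [synthetic_spec()]:
#' `X[t, i] = offset_i + sum_f loading[i, f] * factor_f[t] + trend_i * (t-1)
#' + noise`, with unit-variance Gaussian factors (AR(1) with unit marginal
#' variance when `spec$ar > 0`) and Gaussian process noise. The reported
#' sampling SD of every annual mean is `spec$obs_sd`. The seed fully
#' determines the output.
#'
#' Targets default to the trend-free long-run mean at mid-series (offset +
#' trend at the middle year), so undisturbed scenarios start near a pass
#' probability of one half.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return List with `set` (an [indicator_set()]) and `matrix` (the
#'   years-by-indicators mean matrix with year rownames).
#' @export
generate_indicators <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(seed))
  p <- spec$n_indicators; ny <- spec$n_years
  nf <- ncol(spec$factor_loadings)
  Fm <- matrix(stats::rnorm(ny * nf), ny, nf)
  if (spec$ar > 0 && ny > 1L) {
    for (t in 2:ny)
      Fm[t, ] <- spec$ar * Fm[t - 1L, ] +
        sqrt(1 - spec$ar^2) * Fm[t, ]  # unit marginal variance preserved
  }
  E <- matrix(stats::rnorm(ny * p), ny, p)
  tidx <- seq_len(ny) - 1L
  X <- Fm %*% t(spec$factor_loadings) +
    sweep(E, 2, spec$noise_sd, `*`) +
    outer(tidx, spec$trend_slopes) +
    matrix(spec$mean_offsets, ny, p, byrow = TRUE)
  years <- spec$start_year + tidx
  dimnames(X) <- list(years, spec$ids)
  targets <- if (is.null(spec$targets))
    spec$mean_offsets + spec$trend_slopes * mean(tidx) else spec$targets
  series <- lapply(seq_len(p), function(i)
    indicator_series(spec$ids[i], years, X[, i], sds = spec$obs_sd[i],
                     target = targets[i], direction = spec$directions[i],
                     group = "synthetic"))
  list(set = indicator_set(series), matrix = X)
}

#' Canned assessment scenarios
#'
#' Fully parameterized [synthetic_spec()]s for the archetypal behaviours of a
#' trend-sensitive probabilistic assessment:
#' \describe{
#'   \item{`gradual_approach`}{Two indicators improving steadily past targets
#'     set at their starting level: the posterior climbs year on year.}
#'   \item{`variable_ges`}{Two indicators fluctuating about their targets
#'     with sampling uncertainty dominating the interannual wiggle: the
#'     posterior hovers near one half — variability is buffered, not
#'     amplified.}
#'   \item{`early_warning`}{Three indicators; two healthy, one persistently
#'     about 1.5 sampling SDs on the bad side of its target: only that one
#'     draws an early-warning flag.}
#'   \item{`southern_north_sea_like`}{36 indicators over 20 years: 24 driven
#'     by a dominant common factor carrying 44% of total variance (first id
#'     `LFI_like`) and 12 river-load indicators on a second factor carrying
#'     13% (first id `ppDDE_like`, direction lower-is-better).}
#' }
#'
#' @param name Scenario name.
#' @param n_years Series length in years (default 10; 20 for the
#'   southern-North-Sea ensemble).
#' @param seed Seed stored in the spec.
#' @return A [synthetic_spec()].
#' @export
scenario <- function(name = c("gradual_approach", "variable_ges",
                              "early_warning", "southern_north_sea_like"),
                     n_years = NULL, seed = 1L) {
  name <- match.arg(name)
  switch(name,
    gradual_approach = {
      ny <- if (is.null(n_years)) 10L else n_years
      synthetic_spec(2, ny, trend_slopes = 0.25, noise_sd = 0.05,
                     obs_sd = 1, targets = c(0, 0), seed = seed,
                     ids = c("X1", "X2"))
    },
    variable_ges = {
      ny <- if (is.null(n_years)) 10L else n_years
      synthetic_spec(2, ny, noise_sd = 0.05, obs_sd = 1,
                     targets = c(0, 0), seed = seed, ids = c("X1", "X2"))
    },
    early_warning = {
      ny <- if (is.null(n_years)) 10L else n_years
      synthetic_spec(3, ny, noise_sd = 0.05, obs_sd = 1,
                     mean_offsets = c(0, 0, -1.5), targets = c(0, 0, 0),
                     seed = seed, ids = c("X1", "X2", "X3"))
    },
    southern_north_sea_like = {
      ny <- if (is.null(n_years)) 20L else n_years
      assign <- rep(c(1L, 2L), c(24L, 12L))
      ids <- c("LFI_like", sprintf("ECO%02d", 2:24),
               "ppDDE_like", sprintf("RIV%02d", 2:12))
      dirs <- rep("higher_is_better", 36)
      dirs[25] <- "lower_is_better"
      synthetic_spec(36, ny, factor_shares = c(0.44, 0.13),
                     factor_assign = assign, obs_sd = 0.5,
                     directions = dirs, ids = ids, seed = seed)
    })
}
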