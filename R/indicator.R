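#' Construct a monitored indicator time series
#'
#' An `indicator_series` holds the annual means of one monitored indicator
#' together with the sampling standard deviation of each mean, the indicator's
#' target value and the direction in which "good" lies. It is the atomic input
#' of the GES assessment: the sampling distribution of each annual mean is
#' later converted into a probability of passing the target.
#'
#' Years with a missing mean or SD are dropped with a warning; the remaining
#' series must be non-empty. `sd = 0` is allowed and means the annual mean is
#' known exactly (the pass probability degenerates to a step function).
#'
#' @param id Short unique identifier (e.g. `"LFI"`).
#' @param times Integer years, strictly increasing after removal of missing
#'   observations.
#' @param means Numeric indicator means, one per year, in indicator units.
#' @param sds Non-negative sampling standard deviations of the means, recycled
#'   if of length 1.
#' @param target Target value in indicator units, or `NA` to derive later with
#'   [derive_target()].
#' @param direction `"higher_is_better"` or `"lower_is_better"`.
#' @param label,group,unit Optional descriptive metadata.
#' @param target_basis How the target was obtained: `"fixed"`, `"percentile"`
#'   or `"proxy"` (a user-supplied value converted from a related quantity).
#' @return An object of class `"indicator_series"`.
#' @examples
#' lfi <- indicator_series("LFI", 2001:2008, seq(0.30, 0.44, by = 0.02),
#'                         sds = 0.03, target = 0.485)
#' lfi
#' @export
indicator_series <- function(id, times, means, sds, target = NA_real_,
                             direction = c("higher_is_better", "lower_is_better"),
                             label = id, group = "", unit = "",
                             target_basis = c("fixed", "percentile", "proxy")) {
  direction <- match.arg(direction)
  target_basis <- match.arg(target_basis)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a single non-empty string", call. = FALSE)
  times <- as.integer(times)
  means <- as.numeric(means)
  sds <- as.numeric(sds)
  if (length(sds) == 1L) sds <- rep(sds, length(means))
  if (length(times) != length(means) || length(means) != length(sds))
    stop("indicator '", id, "': times, means and sds must have equal length",
         call. = FALSE)
  keep <- is.finite(means) & is.finite(sds) & !is.na(times)
  if (!all(keep)) {
    warning("indicator '", id, "': dropped ", sum(!keep),
            " year(s) with missing mean or sd", call. = FALSE)
    times <- times[keep]; means <- means[keep]; sds <- sds[keep]
  }
  if (length(times) == 0L)
    stop("indicator '", id, "': no usable observations", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("indicator '", id, "': times must be strictly increasing", call. = FALSE)
  if (any(sds < 0))
    stop("indicator '", id, "': sds must be non-negative", call. = FALSE)
  if (length(target) != 1L)
    stop("indicator '", id, "': target must be a single value", call. = FALSE)
  if (!is.na(target) && !is.finite(target))
    stop("indicator '", id, "': target must be finite or NA", call. = FALSE)
  structure(
    list(id = id, label = label, group = group, times = times, means = means,
         sds = sds, unit = unit, direction = direction,
         target = as.numeric(target), target_basis = target_basis),
    class = "indicator_series")
}

#' @export
print.indicator_series <- function(x, ...) {
  cat(sprintf("<indicator_series> %s (%s)\n", x$id,
              if (nzchar(x$label) && x$label != x$id) x$label else x$direction))
  cat(sprintf("  years %d-%d (n=%d), unit '%s', direction %s\n",
              min(x$times), max(x$times), length(x$times), x$unit, x$direction))
  cat(sprintf("  target %s (%s)\n",
              if (is.na(x$target)) "<unset>" else format(x$target), x$target_basis))
  invisible(x)
}

#' @export
as.data.frame.indicator_series <- function(x, ...) {
  data.frame(id = x$id, label = x$label, group = x$group, year = x$times,
             mean = x$means, sd = x$sds, unit = x$unit,
             direction = x$direction, target = x$target,
             stringsAsFactors = FALSE)
}

#' Bundle indicator series into an assessment set
#'
#' An `indicator_set` is an ordered collection of [indicator_series()] objects
#' with unique ids. A joint assessment uses the years common to all members
#' (at least one common year is required), so the common years are computed and
#' stored at construction time.
#'
#' @param ... `indicator_series` objects, or a single list of them.
#' @return An object of class `"indicator_set"` with elements `series` (named
#'   list) and `common_times`.
#' @seealso [ges_assess()]
#' @export
indicator_set <- function(...) {
  series <- list(...)
  if (length(series) == 1L && is.list(series[[1L]]) &&
      !inherits(series[[1L]], "indicator_series"))
    series <- series[[1L]]
  if (length(series) == 0L)
    stop("an indicator_set needs at least one series", call. = FALSE)
  ok <- vapply(series, inherits, logical(1), "indicator_series")
  if (!all(ok))
    stop("all elements must be indicator_series objects", call. = FALSE)
  ids <- vapply(series, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate indicator ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(series) <- ids
  common <- Reduce(intersect, lapply(series, `[[`, "times"))
  if (length(common) == 0L)
    stop("indicator series share no common year", call. = FALSE)
  structure(list(series = series, common_times = sort(as.integer(common))),
            class = "indicator_set")
}

#' @export
print.indicator_set <- function(x, ...) {
  cat(sprintf("<indicator_set> %d indicator(s), %d common year(s) (%d-%d)\n",
              length(x$series), length(x$common_times),
              min(x$common_times), max(x$common_times)))
  for (s in x$series)
    cat(sprintf("  %-12s %s target=%s n=%d\n", s$id, s$direction,
                if (is.na(s$target)) "<unset>" else format(s$target),
                length(s$times)))
  invisible(x)
}

#' @export
length.indicator_set <- function(x) length(x$series)

#' @export
as.data.frame.indicator_set <- function(x, ...) {
  do.call(rbind, lapply(x$series, as.data.frame))
}

#' Derive an indicator target from its own time series
#'
#' Targets may be pragmatically derived as some percentile of the observed
#' series (linear interpolation between order statistics) or supplied as a
#' fixed value, e.g. an agreed Ecological Quality Objective such as the 0.485
#' target of the large fish indicator. For `lower_is_better` indicators the
#' percentile is taken on the raw value scale — it is not flipped; choose `q`
#' accordingly.
#'
#' @param series An [indicator_series()].
#' @param method `"percentile"` or `"fixed"`.
#' @param q Percentile in (0, 1); default 0.5 (the median). Percentile
#'   derivation needs at least two time points.
#' @param fixed_value Target value for `method = "fixed"`.
#' @return The target value (numeric scalar) in indicator units.
#' @examples
#' s <- indicator_series("x", 2001:2010, 1:10, sds = 1)
#' derive_target(s, "percentile", q = 0.5)  # 5.5
#' @export
derive_target <- function(series, method = c("percentile", "fixed"),
                          q = 0.5, fixed_value = NULL) {
  stopifnot(inherits(series, "indicator_series"))
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_value) || !is.finite(fixed_value))
      stop("method='fixed' requires a finite 'fixed_value'", call. = FALSE)
    return(as.numeric(fixed_value))
  }
  if (length(series$means) < 2L)
    stop("percentile target needs at least 2 time points", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("'q' must lie strictly inside (0, 1)", call. = FALSE)
  unname(stats::quantile(series$means, probs = q, type = 7))
}

#' Set or derive targets on a whole indicator set
#'
#' Convenience wrapper applying [derive_target()] to every series whose target
#' is unset (`NA`), leaving explicitly supplied targets untouched.
#'
#' @param set An [indicator_set()].
#' @param q Percentile used for derivation; default 0.5.
#' @return The set with all targets populated.
#' @export
fill_targets <- function(set, q = 0.5) {
  stopifnot(inherits(set, "indicator_set"))
  set$series <- lapply(set$series, function(s) {
    if (is.na(s$target)) {
      s$target <- derive_target(s, "percentile", q = q)
      s$target_basis <- "percentile"
    }
    s
  })
  set
}
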