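#' Prepare a years-by-indicators observation matrix for ordination
#'
#' Validates and gap-fills the wide matrix used by the ordination functions.
#' Missing cells are filled by per-column linear interpolation inside the
#' observed span (no extrapolation); rows still incomplete afterwards are
#' dropped with a warning. Ordination needs at least 3 rows and 2 columns.
#'
#' @param m Numeric matrix or data frame, rows = years (rownames used as year
#'   labels if present), columns = indicators.
#' @param interpolate Fill interior gaps by linear interpolation; default
#'   `TRUE`.
#' @return A numeric matrix with complete cells.
#' @export
as_indicator_matrix <- function(m, interpolate = TRUE) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("V%02d", seq_len(ncol(m)))
  if (interpolate && anyNA(m)) {
    idx <- seq_len(nrow(m))
    for (j in seq_len(ncol(m))) {
      ok <- !is.na(m[, j])
      if (sum(ok) >= 2L) {
        gap <- !ok & idx >= min(idx[ok]) & idx <= max(idx[ok])
        if (any(gap))
          m[gap, j] <- stats::approx(idx[ok], m[ok, j], xout = idx[gap])$y
      }
    }
  }
  bad <- !stats::complete.cases(m)
  if (any(bad)) {
    warning("dropped ", sum(bad), " incomplete row(s) after interpolation",
            call. = FALSE)
    m <- m[!bad, , drop = FALSE]
  }
  if (nrow(m) < 3L || ncol(m) < 2L)
    stop("ordination needs at least 3 complete rows and 2 columns",
         call. = FALSE)
  m
}

check_no_constant <- function(Z) {
  sds <- apply(Z, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds)))
    stop("constant indicator column(s): ",
         paste(colnames(Z)[sds == 0 | !is.finite(sds)], collapse = ", "),
         call. = FALSE)
}

std_matrix <- function(m, standardize) {
  check_no_constant(m)
  if (standardize) scale(m) else scale(m, scale = FALSE)
}

#' Principal component analysis of an indicator matrix
#'
#' Correlation-matrix PCA: columns are z-scored (indicator units are
#' incommensurable, so the correlation rather than covariance matrix is the
#' meaningful choice) and the correlation matrix is eigen-decomposed. The
#' variance share of axis j is its eigenvalue over the eigenvalue total.
#'
#' @param m Years-by-indicators matrix; passed through
#'   [as_indicator_matrix()].
#' @param standardize Z-score columns first; default `TRUE`. Setting `FALSE`
#'   centres only (covariance PCA) — appropriate when all indicators share one
#'   unit.
#' @return A `"ges_ordination"` object: `eigenvalues`, `variance_share`,
#'   `loadings` (indicators x axes, orthonormal), `scores` (years x axes),
#'   `kind = "pca"`.
#' @export
ges_pca <- function(m, standardize = TRUE) {
  m <- as_indicator_matrix(m)
  Z <- std_matrix(m, standardize)
  S <- crossprod(Z) / (nrow(Z) - 1)
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  ax <- paste0("PC", seq_along(ev))
  loadings <- e$vectors
  dimnames(loadings) <- list(colnames(m), ax)
  scores <- Z %*% loadings
  structure(list(kind = "pca", eigenvalues = ev,
                 variance_share = ev / sum(ev),
                 loadings = loadings, scores = scores,
                 constrained_share = NA_real_, constraint_ids = character()),
            class = "ges_ordination")
}

#' Redundancy analysis constrained by chosen indicators
#'
#' RDA in its regression form: every standardized response column (all
#' columns except the constraints) is regressed on the constraint columns by
#' least squares, the constrained variance share is the total variance of the
#' fitted values over the total variance of the responses, and the
#' constrained axes are the PCA of the fitted values. This measures how much
#' of the remaining ecosystem variability the chosen indicators represent;
#' the constraint columns themselves are excluded from the response side so
#' the share is not trivially inflated (recorded in the result).
#'
#' @param m Years-by-indicators matrix.
#' @param constraints Character vector of constraint column names (or integer
#'   indices), a proper non-empty subset of the columns.
#' @param standardize Z-score columns first; default `TRUE`.
#' @return A `"ges_ordination"` object with `kind = "rda"`,
#'   `constrained_share` in \[0, 1\] and per-axis `variance_share` expressed
#'   relative to total response variance.
#' @export
ges_rda <- function(m, constraints, standardize = TRUE) {
  m <- as_indicator_matrix(m)
  if (is.numeric(constraints)) constraints <- colnames(m)[constraints]
  constraints <- unique(as.character(constraints))
  if (length(constraints) == 0L)
    stop("'constraints' must be non-empty", call. = FALSE)
  missing <- setdiff(constraints, colnames(m))
  if (length(missing))
    stop("unknown constraint column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  responses <- setdiff(colnames(m), constraints)
  if (length(responses) == 0L)
    stop("constraint set covers all columns; no responses left", call. = FALSE)
  if (nrow(m) < length(constraints) + 2L)
    stop("need at least ", length(constraints) + 2L, " rows for ",
         length(constraints), " constraint(s)", call. = FALSE)
  Z <- std_matrix(m, standardize)
  X <- Z[, constraints, drop = FALSE]
  Y <- Z[, responses, drop = FALSE]
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("collinear constraints: rank ", qx$rank, " < ", ncol(X), call. = FALSE)
  Fhat <- qr.fitted(qx, Y)
  share <- sum(Fhat^2) / sum(Y^2)
  e <- eigen(crossprod(Fhat) / (nrow(Z) - 1), symmetric = TRUE)
  nax <- min(qx$rank, ncol(Y))
  ev <- pmax(e$values, 0)[seq_len(nax)]
  ax <- paste0("RDA", seq_len(nax))
  loadings <- e$vectors[, seq_len(nax), drop = FALSE]
  dimnames(loadings) <- list(responses, ax)
  scores <- Fhat %*% loadings
  total_resp_var <- sum(Y^2) / (nrow(Z) - 1)
  structure(list(kind = "rda", eigenvalues = ev,
                 variance_share = ev / total_resp_var,
                 loadings = loadings, scores = scores,
                 constrained_share = share, constraint_ids = constraints),
            class = "ges_ordination")
}

#' @export
print.ges_ordination <- function(x, ...) {
  cat(sprintf("<ges_ordination> %s, %d axis/axes\n", toupper(x$kind),
              length(x$eigenvalues)))
  k <- min(5L, length(x$eigenvalues))
  cat("  variance shares:",
      paste(sprintf("%.1f%%", 100 * x$variance_share[seq_len(k)]),
            collapse = ", "),
      if (length(x$eigenvalues) > k) "..." else "", "\n")
  if (!is.na(x$constrained_share))
    cat(sprintf("  constrained by {%s}: %.1f%% of response variance\n",
                paste(x$constraint_ids, collapse = ", "),
                100 * x$constrained_share))
  invisible(x)
}

#' @export
summary.ges_ordination <- function(object, ...) {
  k <- min(10L, length(object$eigenvalues))
  data.frame(axis = seq_len(k),
             eigenvalue = object$eigenvalues[seq_len(k)],
             variance_share = object$variance_share[seq_len(k)],
             cumulative = cumsum(object$variance_share)[seq_len(k)])
}

#' @export
plot.ges_ordination <- function(x, axes = c(1, 2), ...) {
  sc <- x$scores[, axes, drop = FALSE]
  lab <- sprintf("%s%d (%.0f%%)", toupper(x$kind), axes,
                 100 * x$variance_share[axes])
  graphics::plot(sc, xlab = lab[1], ylab = lab[2], pch = 16, ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  ld <- x$loadings[, axes, drop = FALSE]
  sc_f <- max(abs(sc)) / max(abs(ld))
  graphics::arrows(0, 0, ld[, 1] * sc_f * 0.8, ld[, 2] * sc_f * 0.8,
                   length = 0.05, col = "firebrick")
  graphics::text(ld * sc_f * 0.88, rownames(ld), cex = 0.7, col = "firebrick")
  invisible(x)
}

# Whole-matrix explained share of a constraint set: selected columns count
# fully, the rest by their squared multiple correlation on the selection.
whole_share <- function(Z, sel) {
  p <- ncol(Z)
  if (length(sel) == 0L) return(0)
  if (length(sel) == p) return(1)
  X <- Z[, sel, drop = FALSE]
  Y <- Z[, -sel, drop = FALSE]
  Fhat <- qr.fitted(qr(X), Y)
  denom <- sum(Z^2)  # = p * (n-1) for z-scored columns
  (sum(Z[, sel, drop = FALSE]^2) + sum(Fhat^2)) / denom
}

#' A posteriori indicator selection by explained ecosystem variance
#'
#' Greedy forward selection of the indicator subset that best represents the
#' variability of the whole indicator matrix. At each step the indicator
#' maximising the whole-matrix explained variance share is added — selected
#' columns count fully, the remaining columns through the squared multiple
#' correlation of their regression on the selection. This accounting is
#' monotone non-decreasing and reaches 1 when every column is selected; it
#' differs from [ges_rda()]'s response-only share, which is also reported per
#' step for reference. Ties are broken by column order.
#'
#' @param m Years-by-indicators matrix.
#' @param k_max Maximum number of indicators to select (capped at the column
#'   count with a warning).
#' @param goal_share Optional stopping share in (0, 1\]: selection stops once
#'   the explained share reaches it.
#' @param method `"greedy"` (default) or `"exhaustive"` (best subset of each
#'   size; only for at most 12 columns, as an oracle for the greedy path).
#' @return A `"ges_selection"` object: `selected` ids in selection order,
#'   `share_trajectory` (whole-matrix share after each addition),
#'   `response_share` ([ges_rda()] share of each selection step, `NA` once all
#'   columns are selected).
#' @export
select_indicators <- function(m, k_max, goal_share = NULL,
                              method = c("greedy", "exhaustive")) {
  method <- match.arg(method)
  m <- as_indicator_matrix(m)
  p <- ncol(m)
  k_max <- as.integer(k_max)
  if (k_max < 1L) stop("'k_max' must be >= 1", call. = FALSE)
  if (k_max > p) {
    warning("k_max capped at the ", p, " available indicators", call. = FALSE)
    k_max <- p
  }
  if (!is.null(goal_share) &&
      (!is.numeric(goal_share) || goal_share <= 0 || goal_share > 1))
    stop("'goal_share' must lie in (0, 1]", call. = FALSE)
  Z <- std_matrix(m, TRUE)

  if (method == "exhaustive") {
    if (p > 12L)
      stop("exhaustive search supported for at most 12 columns", call. = FALSE)
    sel_ids <- character(0); traj <- numeric(0); best_prev <- integer(0)
    for (k in seq_len(k_max)) {
      combs <- utils::combn(p, k)
      shares <- apply(combs, 2, function(s) whole_share(Z, s))
      best <- which.max(shares)
      best_prev <- combs[, best]
      traj <- c(traj, shares[best])
      if (!is.null(goal_share) && shares[best] >= goal_share) break
    }
    sel_ids <- colnames(m)[best_prev]
    sel <- best_prev
  } else {
    sel <- integer(0); traj <- numeric(0)
    for (k in seq_len(k_max)) {
      cand <- setdiff(seq_len(p), sel)
      gains <- vapply(cand, function(j) whole_share(Z, c(sel, j)), numeric(1))
      sel <- c(sel, cand[which.max(gains)])  # which.max: first max = column order
      traj <- c(traj, max(gains))
      if (!is.null(goal_share) && traj[k] >= goal_share) break
    }
    sel_ids <- colnames(m)[sel]
  }
  resp <- vapply(seq_along(sel), function(k) {
    if (length(sel) == p && k == length(sel)) return(NA_real_)
    if (k == p) return(NA_real_)
    ges_rda(m, colnames(m)[sel[seq_len(k)]])$constrained_share
  }, numeric(1))
  structure(list(selected = sel_ids, share_trajectory = traj,
                 response_share = resp, method = method,
                 n_indicators = p),
            class = "ges_selection")
}

#' @export
print.ges_selection <- function(x, ...) {
  cat(sprintf("<ges_selection> %d of %d indicator(s) (%s)\n",
              length(x$selected), x$n_indicators, x$method))
  for (k in seq_along(x$selected))
    cat(sprintf("  %d. %-12s share %.1f%%\n", k, x$selected[k],
                100 * x$share_trajectory[k]))
  invisible(x)
}

#' Conditional-independence screen by partial correlations
#'
#' Additive aggregation presumes conditionally independent indicators. For
#' every indicator pair the partial correlation given all remaining columns
#' is computed from the inverse correlation matrix; pairs whose absolute
#' partial correlation exceeds `threshold` are flagged as DEPENDENT —
#' candidates for pruning before aggregation. A chain X -> Z -> Y is not
#' flagged: X and Y are marginally correlated but conditionally independent
#' given Z.
#'
#' Full partial correlations need more rows than columns; otherwise (or when
#' the correlation matrix is numerically singular) the correlation matrix is
#' shrunk toward the identity with intensity `shrink` and a warning.
#'
#' @param m Years-by-indicators matrix.
#' @param threshold Flagging threshold on the absolute partial correlation;
#'   default 0.5.
#' @param shrink Shrinkage intensity in \[0, 1) applied only when needed;
#'   default 0.1.
#' @return Data frame of all pairs with columns `a`, `b`, `partial_cor`,
#'   `flagged`, ordered by decreasing `|partial_cor|`.
#' @export
independence_screen <- function(m, threshold = 0.5, shrink = 0.1) {
  m <- as_indicator_matrix(m)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie in (0, 1)", call. = FALSE)
  R <- stats::cor(m)
  p <- ncol(R)
  need_reg <- nrow(m) <= p
  P <- tryCatch(solve(R), error = function(e) NULL)
  if (need_reg || is.null(P)) {
    warning("correlation matrix under-determined or singular; ",
            "shrinking toward identity (intensity ", shrink, ")",
            call. = FALSE)
    P <- tryCatch(solve((1 - shrink) * R + shrink * diag(p)),
                  error = function(e)
                    stop("correlation matrix singular even after shrinkage; ",
                         "reduce the number of columns", call. = FALSE))
  }
  d <- sqrt(diag(P))
  pc <- -P / tcrossprod(d)
  pairs <- which(upper.tri(pc), arr.ind = TRUE)
  out <- data.frame(a = colnames(m)[pairs[, 1]], b = colnames(m)[pairs[, 2]],
                    partial_cor = pc[pairs],
                    stringsAsFactors = FALSE)
  out$flagged <- abs(out$partial_cor) > threshold
  out[order(-abs(out$partial_cor)), , drop = FALSE]
}
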