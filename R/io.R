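#' Read an indicator monitoring table
#'
#' Reads the long-format delimited table (one row per indicator and year)
#' into an [indicator_set()]. Mandatory columns: `id`, `year`, `mean`, `sd`.
#' Optional columns with defaults: `label`, `group`, `unit`, `direction`
#' (`higher_is_better`), `target` (blank/`NA` to derive later),
#' `target_basis`. The delimiter is taken from the file extension (`.tsv` ->
#' tab, otherwise comma) unless given.
#'
#' In strict mode (default) any malformed row aborts with its line number; in
#' lenient mode malformed rows are skipped with a warning. A duplicated
#' `(id, year)` pair is always an error.
#'
#' @param path Path to a CSV/TSV file with a header row (UTF-8).
#' @param sep Field separator; default by extension.
#' @param strict Abort on malformed rows; default `TRUE`.
#' @return An [indicator_set()].
#' @export
read_indicator_table <- function(path, sep = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8", check.names = TRUE)
  mandatory <- c("id", "year", "mean", "sd")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("label", "group", "unit")) if (is.null(df[[col]])) df[[col]] <- ""
  if (is.null(df$direction)) df$direction <- "higher_is_better"
  if (is.null(df$target)) df$target <- NA_character_
  if (is.null(df$target_basis)) df$target_basis <- "fixed"

  line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  num <- function(x) suppressWarnings(as.numeric(x))
  year <- num(df$year); mn <- num(df$mean); sd_ <- num(df$sd)
  bad <- is.na(year) | is.na(mn) | is.na(sd_) | sd_ < 0 |
    !df$direction %in% c("higher_is_better", "lower_is_better")
  if (any(bad)) {
    msg <- paste0("malformed row(s) at line ", paste(line_no[bad], collapse = ", "),
                  " (non-numeric year/mean/sd, negative sd, or bad direction)")
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; skipped", call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    year <- year[!bad]; mn <- mn[!bad]; sd_ <- sd_[!bad]
  }
  if (nrow(df) == 0L) stop("no usable rows in ", path, call. = FALSE)
  if (anyDuplicated(paste(df$id, year)))
    stop("duplicated (id, year) pair(s): ",
         paste(unique(paste(df$id, year)[duplicated(paste(df$id, year))]),
               collapse = "; "), call. = FALSE)

  series <- lapply(split(seq_len(nrow(df)), factor(df$id, levels = unique(df$id))),
                   function(rows) {
    o <- rows[order(year[rows])]
    tg <- num(df$target[o[1]])
    indicator_series(df$id[o[1]], year[o], mn[o], sd_[o],
                     target = if (is.na(tg)) NA_real_ else tg,
                     direction = df$direction[o[1]],
                     label = df$label[o[1]], group = df$group[o[1]],
                     unit = df$unit[o[1]],
                     target_basis = if (df$target_basis[o[1]] %in%
                                        c("fixed", "percentile", "proxy"))
                       df$target_basis[o[1]] else "fixed")
  })
  indicator_set(unname(series))
}

#' Write an indicator set as a monitoring table
#'
#' Inverse of [read_indicator_table()]: one row per indicator and year, CSV.
#'
#' @param set An [indicator_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_indicator_table <- function(set, path) {
  stopifnot(inherits(set, "indicator_set"))
  df <- as.data.frame(set)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide years-by-indicators matrix
#'
#' First column is the year, remaining columns one indicator each.
#'
#' @param path CSV path.
#' @return Numeric matrix with year rownames (see [as_indicator_matrix()]).
#' @export
read_indicator_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_indicator_matrix(m)
}

#' Run the full ex-post assessment pipeline
#'
#' Binds the modules into one run: read the indicator table (and optionally
#' the wide matrix), optionally select indicators by explained ecosystem
#' variance, derive missing targets, compute likelihood profiles, run the
#' sequential Bayes chain, scan for early warnings, and write a JSON report
#' plus a plain-text summary. Identical configuration and seed give a
#' byte-identical report.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Recognised keys: `indicator_table` (required), `matrix`, `select`
#'   (logical), `k_max`, `goal_share`, `independence_threshold`, `prior0`,
#'   `distribution`, `precaution`, `clip_eps`, `lambda`, `years`,
#'   `warning_threshold`, `warning_k`, `target_q`, `out_dir`, `seed`.
#' @param overrides Named list overriding config keys (CLI flags use this).
#' @return The `"ges_assessment"`, invisibly; report files are written to
#'   `out_dir` (default `"."`): `report.json` and `summary.txt`.
#' @export
run_assessment <- function(config, overrides = list()) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("'config' must be a path or a named list", call. = FALSE)
  cfg[names(overrides)] <- overrides
  get <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  if (is.null(cfg$indicator_table))
    stop("config key 'indicator_table' is required", call. = FALSE)
  seed <- as.integer(get("seed", 1L))
  set.seed(seed)

  set <- read_indicator_table(cfg$indicator_table,
                              strict = isTRUE(get("strict", TRUE)))
  set <- fill_targets(set, q = get("target_q", 0.5))

  selection <- NULL
  explained <- NA_real_
  if (isTRUE(get("select", FALSE))) {
    m <- if (!is.null(cfg$matrix)) read_indicator_matrix(cfg$matrix) else {
      wide <- sapply(set$series, function(s)
        s$means[match(set$common_times, s$times)])
      rownames(wide) <- set$common_times
      wide
    }
    selection <- select_indicators(m, k_max = get("k_max", ncol(m)),
                                   goal_share = get("goal_share", NULL))
    explained <- utils::tail(selection$share_trajectory, 1)
    keep <- intersect(names(set$series), selection$selected)
    set <- indicator_set(set$series[keep])
  }

  fit <- ges_assess(set,
                    prior0 = get("prior0", 0.5),
                    distribution = get("distribution", "normal"),
                    precaution = get("precaution", 0),
                    clip_eps = get("clip_eps", 1e-9),
                    lambda = get("lambda", 1),
                    years = get("years", "common"),
                    warning_threshold = get("warning_threshold", 0.25),
                    warning_k = get("warning_k", 3),
                    explained_variance = explained)

  out_dir <- get("out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    config = c(cfg[setdiff(names(cfg), "out_dir")], list(seed = seed)),
    years = fit$times,
    posterior = fit$posterior,
    prior_chain = fit$prior_chain,
    likelihoods = as.data.frame(fit$likelihoods),
    explained_variance = if (is.na(explained)) NULL else explained,
    selected = if (is.null(selection)) NULL else selection$selected,
    share_trajectory = if (is.null(selection)) NULL else
      selection$share_trajectory,
    warnings = fit$warnings)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", null = "null")
  con <- file(file.path(out_dir, "summary.txt"), "w")
  sink(con); on.exit({ sink(); close(con) })
  print(summary(fit))
  sink(); close(con); on.exit()
  invisible(fit)
}
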