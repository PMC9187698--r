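#' Summarise a minute series into 10-minute intervals
#'
#' Divides a patient's recording into consecutive 10-minute bins starting at
#' the first recorded minute and computes, per bin, the mean ICP (the
#' response statistic) and the third quartile of ICP (the predictor
#' statistic).  The third quartile is discretized into three levels —
#' 1: Q3 < 15 mmHg, 2: 15 <= Q3 < 20, 3: Q3 >= 20 — and the mean into the
#' binary response — class 1 (normal, mean < 20 mmHg) versus class 2
#' (severe, mean >= 20 mmHg).  Bins with fewer than `min_samples` observed
#' minutes are flagged invalid and break any prediction window they fall in.
#'
#' @param s A [minute_series()], normally after [clean_series()].
#' @param interval_minutes Bin width in minutes (default 10).
#' @param min_samples Minimum observed minutes for a bin to be valid
#'   (default 8 of 10, tolerating brief dropouts without biasing the mean).
#' @param q3_type Quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).  With only
#'   10 samples per bin the convention matters at the level boundaries, so
#'   it is fixed and exposed.
#' @param level_breaks Discretization thresholds for Q3, mmHg, strictly
#'   increasing (default `c(15, 20)`).
#' @param severe_threshold Mean-ICP threshold for the severe class, mmHg
#'   (default 20).
#'
#' @return A `data.frame` of class `interval_table` with columns
#'   `patient_id`, `interval` (1-based consecutive index), `n_obs`,
#'   `mean_icp`, `q3_icp`, `q3_level`, `response_class`, `valid`.  A series
#'   shorter than one bin yields a zero-row table.
#' @examples
#' s <- minute_series("A", 1:20, c(rep(14, 5), rep(22, 5), rep(12, 10)))
#' make_intervals(s)
#' @export
make_intervals <- function(s, interval_minutes = 10L, min_samples = 8L,
                           q3_type = 7L, level_breaks = c(15, 20),
                           severe_threshold = 20) {
  stopifnot(inherits(s, "minute_series"))
  if (length(level_breaks) != 2L || diff(level_breaks) <= 0)
    stop("`level_breaks` must be two strictly increasing thresholds")
  interval_minutes <- as.integer(interval_minutes)
  if (interval_minutes < 1L) stop("`interval_minutes` must be >= 1")

  empty <- data.frame(patient_id = character(), interval = integer(),
                      n_obs = integer(), mean_icp = numeric(),
                      q3_icp = numeric(), q3_level = integer(),
                      response_class = integer(), valid = logical(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("interval_table", "data.frame")
  if (!length(s$minutes)) return(empty)

  span <- s$minutes[length(s$minutes)] - s$minutes[1L] + 1L
  n_int <- span %/% interval_minutes
  if (n_int == 0L) return(empty)

  bin <- (s$minutes - s$minutes[1L]) %/% interval_minutes + 1L
  keep <- bin <= n_int & !is.na(s$icp)
  b <- bin[keep]; v <- s$icp[keep]

  n_obs <- integer(n_int)
  tab <- table(factor(b, levels = seq_len(n_int)))
  n_obs <- as.integer(tab)
  mean_icp <- rep(NA_real_, n_int)
  q3_icp <- rep(NA_real_, n_int)
  if (length(v)) {
    sums <- vapply(split(v, factor(b, levels = seq_len(n_int))), sum, 0)
    mean_icp <- ifelse(n_obs > 0L, sums / n_obs, NA_real_)
    q3 <- vapply(split(v, factor(b, levels = seq_len(n_int))),
                 function(x) if (length(x)) stats::quantile(x, 0.75, type = q3_type,
                                                            names = FALSE) else NA_real_,
                 0)
    q3_icp <- as.numeric(q3)
  }
  q3_level <- ifelse(is.na(q3_icp), NA_integer_,
                     1L + (q3_icp >= level_breaks[1L]) + (q3_icp >= level_breaks[2L]))
  response_class <- ifelse(is.na(mean_icp), NA_integer_,
                           1L + (mean_icp >= severe_threshold))
  out <- data.frame(patient_id = s$patient_id, interval = seq_len(n_int),
                    n_obs = n_obs, mean_icp = mean_icp, q3_icp = q3_icp,
                    q3_level = as.integer(q3_level),
                    response_class = as.integer(response_class),
                    valid = n_obs >= min_samples,
                    stringsAsFactors = FALSE)
  class(out) <- c("interval_table", "data.frame")
  out
}

#' Build lagged prediction windows from interval tables
#'
#' For every anchor interval `t` preceded by `d1` consecutive valid
#' intervals (inclusive of `t` itself) and every horizon `k = 1..m` whose
#' response interval `t + k` is valid, emits one training/prediction row:
#' the predictor vector is the Q3 levels of intervals `t - d1 + 1, ..., t`
#' (columns `lag1` = oldest ... `lag<d1>` = the anchor) and the response is
#' the class of interval `t + k`.  Windows never span invalid intervals or
#' patient boundaries; anchors near the end of a recording contribute only
#' the horizons that fit.
#'
#' @param tbl An `interval_table` from [make_intervals()]; may contain
#'   several patients (processed independently, output sorted by patient,
#'   anchor, horizon so it is invariant to input ordering).
#' @param d1 Number of predictor intervals — the window length (default 6,
#'   i.e. the preceding hour).
#' @param m Number of forecast horizons (default 6, i.e. the next hour).
#'
#' @return A `data.frame` of class `windowed_dataset` with columns
#'   `patient_id`, `anchor`, `horizon`, `y` and `lag1..lag<d1>`.
#' @examples
#' s <- minute_series("A", 1:200, rep(12, 200))
#' w <- make_windows(make_intervals(s))
#' nrow(w)
#' @export
make_windows <- function(tbl, d1 = 6L, m = 6L) {
  stopifnot(inherits(tbl, "data.frame"))
  d1 <- as.integer(d1); m <- as.integer(m)
  if (is.na(d1) || d1 < 1L) stop("`d1` must be a positive integer")
  if (is.na(m) || m < 1L) stop("`m` must be a positive integer")

  lag_names <- paste0("lag", seq_len(d1))
  empty <- cbind(
    data.frame(patient_id = character(), anchor = integer(),
               horizon = integer(), y = integer(), stringsAsFactors = FALSE),
    stats::setNames(as.data.frame(matrix(integer(), 0, d1)), lag_names))
  class(empty) <- c("windowed_dataset", "data.frame")
  if (nrow(tbl) == 0L) return(empty)

  pieces <- lapply(split(tbl, tbl$patient_id), function(p) {
    p <- p[order(p$interval), , drop = FALSE]
    n <- nrow(p)
    if (n < d1 + 1L) return(NULL)
    lev <- ifelse(p$valid, p$q3_level, NA_integer_)
    resp <- ifelse(p$valid, p$response_class, NA_integer_)
    # anchors: positions t with d1 consecutive valid predictor intervals
    ok <- !is.na(lev)
    run <- stats::filter(as.numeric(ok), rep(1, d1), sides = 1)  # valid count in window
    anchors <- which(!is.na(run) & run == d1)
    if (!length(anchors)) return(NULL)
    t_rep <- rep(anchors, each = m)
    k_rep <- rep.int(seq_len(m), length(anchors))
    keep <- t_rep + k_rep <= n
    keep[keep] <- !is.na(resp[t_rep[keep] + k_rep[keep]])
    if (!any(keep)) return(NULL)
    t_rep <- t_rep[keep]; k_rep <- k_rep[keep]
    hist_mat <- vapply(seq_len(d1), function(j) lev[t_rep - d1 + j],
                       integer(length(t_rep)))
    if (is.null(dim(hist_mat))) hist_mat <- matrix(hist_mat, nrow = 1L)
    cbind(
      data.frame(patient_id = p$patient_id[1L], anchor = p$interval[t_rep],
                 horizon = k_rep, y = resp[t_rep + k_rep],
                 stringsAsFactors = FALSE),
      stats::setNames(as.data.frame(hist_mat), lag_names))
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces)) return(empty)
  out <- do.call(rbind, pieces)
  out <- out[order(out$patient_id, out$anchor, out$horizon), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("windowed_dataset", "data.frame")
  out
}

#' @rdname make_windows
#' @param x A `windowed_dataset`.
#' @export
window_d1 <- function(x) sum(grepl("^lag[0-9]+$", names(x)))

lag_matrix <- function(x) {
  as.matrix(x[grep("^lag[0-9]+$", names(x), value = TRUE)])
}

#' Write and read interval and window tables as CSV
#'
#' On disk both tables use 0-based `interval`/`anchor` indices; in memory
#' they are 1-based.  Missing levels are written as empty cells.
#'
#' @param x An `interval_table` or `windowed_dataset`.
#' @param path Output CSV path.
#' @return `path` (writers) or the table (readers), invisibly/visibly.
#' @export
write_intervals <- function(x, path) {
  stopifnot(inherits(x, "interval_table"))
  out <- as.data.frame(x)
  out$interval <- out$interval - 1L
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_intervals
#' @export
write_windows <- function(x, path) {
  stopifnot(inherits(x, "windowed_dataset"))
  out <- as.data.frame(x)
  out$anchor <- out$anchor - 1L
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_windows <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "anchor", "horizon", "y")
  if (length(setdiff(need, names(x))))
    stop("not a windowed dataset CSV: ", path)
  x$anchor <- as.integer(x$anchor) + 1L
  x$patient_id <- as.character(x$patient_id)
  class(x) <- c("windowed_dataset", "data.frame")
  x
}
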