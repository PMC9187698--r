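#' Minute-resolution ICP recording for one patient
#'
#' Container for a single patient's intracranial pressure (ICP) stream
#' rescaled to one value per minute.  Missing minutes may be encoded either
#' as `NA` pressures or as gaps in the minute index; [clean_series()]
#' normalises both to an explicit regular grid.
#'
#' @param patient_id Single string identifying the patient.
#' @param minutes Strictly increasing integer minute index.
#' @param icp Numeric ICP in mmHg, one value per minute; `NA` marks a
#'   missing (artifact-removed) minute.
#'
#' @return An object of class `minute_series`: a list with elements
#'   `patient_id`, `minutes` and `icp`.
#' @examples
#' s <- minute_series("P01", 1:5, c(12, 13, NA, 14, 15))
#' s
#' @export
minute_series <- function(patient_id, minutes, icp) {
  if (!is.character(patient_id) || length(patient_id) != 1L || is.na(patient_id))
    stop("`patient_id` must be a single non-missing string")
  minutes <- as.integer(minutes)
  icp <- as.numeric(icp)
  if (length(minutes) != length(icp))
    stop("`minutes` and `icp` must have equal length")
  if (anyNA(minutes))
    stop("`minutes` must not contain NA")
  if (length(minutes) > 1L && any(diff(minutes) <= 0L)) {
    bad <- minutes[which(diff(minutes) <= 0L)[1L] + 1L]
    stop(sprintf("minutes must be strictly increasing (violation at minute %d, patient %s)",
                 bad, patient_id))
  }
  obs <- icp[!is.na(icp)]
  if (any(!is.finite(obs)))
    stop("observed ICP values must be finite")
  # physiologically implausible values are suspicious but not fatal
  if (any(obs < -10 | obs > 150))
    warning(sprintf("patient %s: ICP values outside [-10, 150] mmHg", patient_id))
  structure(list(patient_id = patient_id, minutes = minutes, icp = icp),
            class = "minute_series")
}

#' @export
print.minute_series <- function(x, ...) {
  n <- length(x$minutes)
  nmiss <- sum(is.na(x$icp))
  span <- if (n) x$minutes[n] - x$minutes[1L] + 1L else 0L
  cat(sprintf("<minute_series> patient %s: %d minutes recorded over %d (%d missing)\n",
              x$patient_id, n, span, nmiss))
  if (n) {
    obs <- x$icp[!is.na(x$icp)]
    if (length(obs))
      cat(sprintf("  ICP mmHg: mean %.1f, range [%.1f, %.1f]\n",
                  mean(obs), min(obs), max(obs)))
  }
  invisible(x)
}

#' @export
length.minute_series <- function(x) length(x$minutes)

#' Column dialect for delimited minute-level ICP files
#'
#' Describes how to read a delimited text file of minute-resolution ICP
#' recordings: which columns carry the patient id, the minute index and the
#' pressure, the field separator, and which tokens denote missing values.
#'
#' @param col_patient,col_minute,col_icp Column names in the file.
#' @param sep Field separator (default comma).
#' @param na_strings Tokens read as missing, besides an empty cell.
#' @return A list of class `icp_dialect`.
#' @export
icp_dialect <- function(col_patient = "patient_id", col_minute = "minute",
                        col_icp = "icp", sep = ",",
                        na_strings = c("", "NA", "NaN")) {
  structure(list(col_patient = col_patient, col_minute = col_minute,
                 col_icp = col_icp, sep = sep, na_strings = na_strings),
            class = "icp_dialect")
}

#' Read minute-resolution ICP recordings from delimited text
#'
#' Reads a CSV/TSV file with one row per recorded minute and returns one
#' [minute_series()] per patient, sorted by minute.  Rows whose minute or
#' pressure field cannot be parsed are reported with their row number;
#' duplicated minute indices within a patient are an error.
#'
#' @param path Path to the delimited file.
#' @param dialect An [icp_dialect()] naming the columns.
#' @return Named list of `minute_series`, one per patient, in order of first
#'   appearance in the file.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("patient_id,minute,icp", "A,1,12", "A,2,13.5", "A,3,"), f)
#' load_minute_series(f)
#' @export
load_minute_series <- function(path, dialect = icp_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           blank.lines.skip = FALSE)
  if (nrow(raw) == 0L) stop("no data rows in ", path)
  need <- c(dialect$col_patient, dialect$col_minute, dialect$col_icp)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))

  pid <- raw[[dialect$col_patient]]
  min_chr <- trimws(raw[[dialect$col_minute]])
  icp_chr <- trimws(raw[[dialect$col_icp]])

  mins <- suppressWarnings(as.integer(min_chr))
  bad <- which(is.na(mins))
  if (length(bad))
    stop(sprintf("unparseable minute value %s at data row %d",
                 dQuote(min_chr[bad[1L]]), bad[1L]))
  icp <- suppressWarnings(as.numeric(icp_chr))
  bad <- which(is.na(icp) & !(icp_chr %in% dialect$na_strings))
  if (length(bad))
    stop(sprintf("unparseable ICP value %s at data row %d",
                 dQuote(icp_chr[bad[1L]]), bad[1L]))

  out <- list()
  for (p in unique(pid)) {
    i <- which(pid == p)
    o <- order(mins[i])
    m <- mins[i][o]
    dup <- m[duplicated(m)]
    if (length(dup))
      stop(sprintf("duplicated minute index %d for patient %s", dup[1L], p))
    out[[p]] <- minute_series(p, m, icp[i][o])
  }
  out
}

#' Write a cohort of minute series as delimited text
#'
#' Inverse of [load_minute_series()]; missing minutes are written as empty
#' cells.
#'
#' @param cohort A `minute_series` or list of them.
#' @param path Output file path.
#' @param dialect An [icp_dialect()].
#' @return `path`, invisibly.
#' @export
write_minute_series <- function(cohort, path, dialect = icp_dialect()) {
  if (inherits(cohort, "minute_series")) cohort <- list(cohort)
  df <- do.call(rbind, lapply(cohort, function(s)
    data.frame(p = s$patient_id, m = s$minutes, v = s$icp)))
  names(df) <- c(dialect$col_patient, dialect$col_minute, dialect$col_icp)
  utils::write.table(df, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Interpolate short gaps in a minute series
#'
#' Expands the series to a regular one-minute grid over its recorded span
#' and linearly interpolates missing runs of at most `max_gap_minutes`
#' minutes that are flanked by observations on both sides.  Longer runs (and
#' runs touching either end of the recording) are preserved as missing and
#' will later invalidate the 10-minute intervals they fall in, so prediction
#' windows never bridge a long dropout.
#'
#' @param s A [minute_series()].
#' @param max_gap_minutes Longest missing run that is interpolated
#'   (default 2 minutes, matching the tolerance for brief probe artifacts).
#' @return A new `minute_series` on a regular grid; the input is untouched.
#' @examples
#' s <- minute_series("A", c(1, 2, 4, 5), c(10, 11, 13, 14))
#' clean_series(s)$icp  # minute 3 filled in at 12
#' @export
clean_series <- function(s, max_gap_minutes = 2L) {
  stopifnot(inherits(s, "minute_series"))
  max_gap_minutes <- as.integer(max_gap_minutes)
  if (is.na(max_gap_minutes) || max_gap_minutes < 0L)
    stop("`max_gap_minutes` must be a non-negative integer")
  if (!length(s$minutes)) return(s)
  if (all(is.na(s$icp))) {
    warning(sprintf("patient %s: series is entirely missing; returned unchanged",
                    s$patient_id))
    return(s)
  }
  grid <- seq(s$minutes[1L], s$minutes[length(s$minutes)])
  icp <- rep(NA_real_, length(grid))
  icp[match(s$minutes, grid)] <- s$icp

  miss <- is.na(icp)
  if (any(miss)) {
    runs <- rle(miss)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    fill <- stats::approx(grid[!miss], icp[!miss], xout = grid,
                          method = "linear", rule = 1)$y
    for (r in which(runs$values)) {
      if (runs$lengths[r] > max_gap_minutes) next
      if (starts[r] == 1L || ends[r] == length(grid)) next  # no flank
      idx <- starts[r]:ends[r]
      icp[idx] <- fill[idx]
    }
  }
  minute_series(s$patient_id, grid, icp)
}
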