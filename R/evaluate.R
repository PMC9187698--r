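#' Random per-patient train/test split of prediction windows
#'
#' Samples anchors (not individual rows) within each patient: all horizon
#' rows belonging to one anchor travel together, so the same future
#' interval never appears in both sets.  The train count per patient is
#' `floor(n * fraction + 0.5)` (round half up).  A patient with fewer than
#' two anchors is assigned wholly to the training set with a warning.
#'
#' @param data A `windowed_dataset`.
#' @param fraction Train fraction in (0, 1) (default 0.8).
#' @param seed Integer seed; the split is deterministic given the seed and
#'   the caller's RNG state is untouched.
#' @return List with elements `train` and `test`, both `windowed_dataset`s.
#' @export
split_random <- function(data, fraction = 0.8, seed) {
  stopifnot(inherits(data, "data.frame"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("`fraction` must be in (0, 1)")
  if (missing(seed)) stop("`seed` is required")
  patients <- sort(unique(data$patient_id))
  train_keys <- withr::with_seed(as.integer(seed), {
    unlist(lapply(patients, function(p) {
      anchors <- sort(unique(data$anchor[data$patient_id == p]))
      n <- length(anchors)
      if (n < 2L) {
        warning(sprintf("patient %s has %d anchor(s); assigned wholly to train", p, n))
        sel <- anchors
      } else {
        n_train <- floor(n * fraction + 0.5)
        sel <- sample(anchors, n_train)
      }
      paste(p, sel)
    }))
  })
  key <- paste(data$patient_id, data$anchor)
  in_train <- key %in% train_keys
  out <- list(train = data[in_train, , drop = FALSE],
              test = data[!in_train, , drop = FALSE])
  for (nm in names(out)) {
    rownames(out[[nm]]) <- NULL
    class(out[[nm]]) <- c("windowed_dataset", "data.frame")
  }
  out
}

#' Class-wise prediction accuracy per horizon
#'
#' Specificity is the fraction of true class-1 (normal pressure) rows
#' predicted 1; sensitivity the fraction of true class-2 (severe) rows
#' predicted 2.  A cell with no truths of a class is reported as `NA` with
#' `defined = FALSE`.
#'
#' @param truth,pred Integer class labels in {1, 2}.
#' @param horizon Integer horizon per row (a single value is recycled).
#' @return A `data.frame` with one row per horizon: `horizon`,
#'   `specificity`, `sensitivity`, `n1`, `n2`, `defined`.
#' @export
class_accuracies <- function(truth, pred, horizon = 1L) {
  if (length(pred) != length(truth))
    stop("`truth` and `pred` must have equal length")
  if (length(horizon) == 1L) horizon <- rep(horizon, length(truth))
  if (any(!(truth %in% 1:2)) || any(!(pred %in% 1:2)))
    stop("class labels must be in {1, 2}")
  out <- lapply(sort(unique(horizon)), function(k) {
    i <- horizon == k
    n1 <- sum(truth[i] == 1L); n2 <- sum(truth[i] == 2L)
    data.frame(
      horizon = k,
      specificity = if (n1) mean(pred[i & truth == 1L] == 1L) else NA_real_,
      sensitivity = if (n2) mean(pred[i & truth == 2L] == 2L) else NA_real_,
      n1 = n1, n2 = n2, defined = n1 > 0L & n2 > 0L)
  })
  do.call(rbind, out)
}

#' Nonparametric (percentile) bootstrap CI for an accuracy
#'
#' Resamples the row-level correctness indicators with replacement `B`
#' times, recomputes the mean each time, and returns the percentile
#' interval: exactly the `(1 - level)/2` and `1 - (1 - level)/2` empirical
#' quantiles of the replicates.
#'
#' @param correct Logical (or 0/1) vector: was each prediction correct?
#' @param B Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (so a caller can seed a whole evaluation once).
#' @return List with `lower`, `upper`, `estimate`, `B`, `level`.
#' @export
bootstrap_ci <- function(correct, B = 1000L, level = 0.95, seed = NULL) {
  correct <- as.numeric(correct)
  if (!length(correct)) stop("`correct` is empty; accuracy undefined")
  if (anyNA(correct)) stop("`correct` contains NA")
  if (B < 1L) stop("`B` must be >= 1")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  run <- function() {
    n <- length(correct)
    reps <- colMeans(matrix(correct[sample.int(n, n * B, replace = TRUE)], n, B))
    qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                          type = 7, names = FALSE)
    list(lower = qs[1L], upper = qs[2L], estimate = mean(correct),
         B = as.integer(B), level = level)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Random-split evaluation with bootstrap confidence intervals
#'
#' The pooled-cohort evaluation design: within each patient, 80% of the
#' anchors (with all their horizon rows) are sampled for training and the
#' rest held out; the model is fitted on the training rows, the balancing
#' factor is (optionally) chosen on the training rows by [select_alpha()],
#' and class-wise accuracies of both the plain MAP ("general") and the
#' alpha-weighted ("enhanced") predictions are reported per horizon with
#' percentile-bootstrap confidence intervals.
#'
#' @param data A multi-patient `windowed_dataset`.
#' @param fraction Train fraction (default 0.8).
#' @param seed Integer seed governing the split and the bootstrap.
#' @param mode,lambda Passed to [fit_cpt()].
#' @param alpha Balancing factor for the enhanced predictions, or
#'   `"select"` to choose it on the training split via [select_alpha()]
#'   (never on the test split, to avoid leakage).
#' @param grid,w Passed to [select_alpha()] when `alpha = "select"`.
#' @param B,level Bootstrap replicates and confidence level.
#' @return An `icp_eval` report: `results` has one row per horizon x class
#'   x method with `accuracy`, `ci_lower`, `ci_upper` and `n`.
#' @export
evaluate_split <- function(data, fraction = 0.8, seed = 1L,
                           mode = "per_lag", lambda = 1, alpha = 0.60,
                           grid = seq(0.50, 0.85, by = 0.05), w = 2,
                           B = 1000L, level = 0.95) {
  sp <- split_random(data, fraction, seed = seed)
  model <- fit_cpt(sp$train, mode = mode, lambda = lambda, w = w)
  selection <- NULL
  if (identical(alpha, "select")) {
    selection <- select_alpha(model, sp$train, grid = grid, w = w)
    alpha <- selection$chosen
  }
  check_alpha(alpha)
  pr <- predict(model, sp$test, alpha = alpha)
  results <- withr::with_seed(as.integer(seed) + 1L, {
    rows <- list()
    for (k in sort(unique(pr$horizon))) {
      d <- pr[pr$horizon == k, ]
      for (method in c("general", "enhanced")) {
        lab <- if (method == "general") d$map else d$enhanced
        for (cl in 1:2) {
          i <- d$y == cl
          n <- sum(i)
          if (!n) {
            rows[[length(rows) + 1L]] <- data.frame(
              horizon = k, class = cl, method = method, accuracy = NA_real_,
              ci_lower = NA_real_, ci_upper = NA_real_, n = 0L)
            next
          }
          correct <- lab[i] == cl
          ci <- bootstrap_ci(correct, B = B, level = level)
          rows[[length(rows) + 1L]] <- data.frame(
            horizon = k, class = cl, method = method,
            accuracy = mean(correct), ci_lower = ci$lower,
            ci_upper = ci$upper, n = n)
        }
      }
    }
    do.call(rbind, rows)
  })
  structure(list(design = "split",
                 params = list(fraction = fraction, seed = as.integer(seed),
                               mode = mode, lambda = lambda, alpha = alpha,
                               w = w, B = as.integer(B), level = level,
                               d1 = model$d1, m = model$m),
                 results = results, selection = selection),
            class = "icp_eval")
}

#' Leave-one-patient-out cross-validation
#'
#' For each patient, fits the model on the pooled windows of all other
#' patients and predicts every window of the held-out patient's continuous
#' recording, recording per-horizon class-wise accuracies for the general
#' (MAP) and enhanced rules together with that patient's class proportions.
#' Cohort summaries are proportion-weighted means: each patient's class-c
#' accuracy is weighted by that patient's share of class-c responses
#' (weights normalized over patients), so patients who barely exhibit a
#' class do not dominate its summary; the min-max range across patients is
#' also reported.
#'
#' @param cohort A list of `interval_table`s (one per patient, e.g. from
#'   [make_intervals()]), or a list of `minute_series` which are then
#'   cleaned and discretized with default settings.
#' @param d1,m Window length and number of horizons.
#' @param mode,lambda Passed to [fit_cpt()].
#' @param alpha Balancing factor for the enhanced predictions.
#' @param w Importance weight stored in the report.
#' @return An `icp_eval` report with elements `per_patient` (one row per
#'   patient x horizon x class x method) and `results` (weighted mean,
#'   range and total n per horizon x class x method).
#' @export
loocv <- function(cohort, d1 = 6L, m = 6L, mode = "per_lag", lambda = 1,
                  alpha = 0.60, w = 2) {
  if (inherits(cohort, "interval_table") || inherits(cohort, "minute_series"))
    cohort <- list(cohort)
  if (length(cohort) < 2L) stop("leave-one-out needs at least 2 patients")
  if (all(vapply(cohort, inherits, TRUE, "minute_series")))
    cohort <- lapply(cohort, function(s) make_intervals(clean_series(s)))
  check_alpha(alpha)
  windows <- lapply(cohort, make_windows, d1 = d1, m = m)
  ids <- vapply(cohort, function(tb)
    if (nrow(tb)) tb$patient_id[1L] else NA_character_, "")
  usable <- vapply(windows, nrow, 0L) > 0L
  if (any(!usable))
    warning("excluding patient(s) with no valid windows: ",
            paste(ids[!usable], collapse = ", "))
  windows <- windows[usable]; ids <- ids[usable]
  if (length(windows) < 2L) stop("fewer than 2 patients with valid windows")

  per_patient <- list()
  for (i in seq_along(windows)) {
    train <- do.call(rbind, windows[-i])
    class(train) <- c("windowed_dataset", "data.frame")
    model <- fit_cpt(train, mode = mode, lambda = lambda, m = m,
                     alpha = alpha, w = w)
    pr <- predict(model, windows[[i]], alpha = alpha)
    for (k in sort(unique(pr$horizon))) {
      d <- pr[pr$horizon == k, ]
      for (cl in 1:2) {
        idx <- d$y == cl
        n <- sum(idx)
        for (method in c("general", "enhanced")) {
          lab <- if (method == "general") d$map else d$enhanced
          per_patient[[length(per_patient) + 1L]] <- data.frame(
            patient_id = ids[i], horizon = k, class = cl, method = method,
            accuracy = if (n) mean(lab[idx] == cl) else NA_real_,
            n = n, proportion = mean(idx))
        }
      }
    }
  }
  per_patient <- do.call(rbind, per_patient)

  cells <- unique(per_patient[c("horizon", "class", "method")])
  results <- do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    d <- merge(cells[r, ], per_patient)
    ok <- !is.na(d$accuracy) & d$proportion > 0
    wts <- d$proportion[ok]
    data.frame(cells[r, ],
               weighted_accuracy = if (any(ok)) sum(wts * d$accuracy[ok]) / sum(wts)
                                   else NA_real_,
               min = if (any(ok)) min(d$accuracy[ok]) else NA_real_,
               max = if (any(ok)) max(d$accuracy[ok]) else NA_real_,
               n_patients = sum(ok), n = sum(d$n))
  }))
  results <- results[order(results$horizon, results$class, results$method), ]
  rownames(results) <- NULL
  structure(list(design = "loocv",
                 params = list(d1 = as.integer(d1), m = as.integer(m),
                               mode = mode, lambda = lambda, alpha = alpha, w = w),
                 per_patient = per_patient, results = results),
            class = "icp_eval")
}

#' @export
print.icp_eval <- function(x, ...) {
  cat(sprintf("<icp_eval> design = %s, alpha = %g\n",
              x$design, x$params$alpha))
  if (x$design == "split") {
    wide <- x$results
    acc <- sprintf("%.3f", wide$accuracy)
    cat("  accuracy by horizon/class/method:\n")
    print(data.frame(wide[c("horizon", "class", "method")], accuracy = acc,
                     ci = sprintf("(%.3f; %.3f)", wide$ci_lower, wide$ci_upper)),
          row.names = FALSE)
  } else {
    print(data.frame(x$results[c("horizon", "class", "method")],
                     weighted = sprintf("%.3f", x$results$weighted_accuracy),
                     range = sprintf("(%.2f; %.2f)", x$results$min, x$results$max)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Write an evaluation report to JSON and CSV
#'
#' The JSON file carries the full report (design, resolved parameters,
#' per-cell results, and for leave-one-out the per-patient table); the CSV
#' is the flat `results` table, one row per horizon x class x method.
#'
#' @param report An `icp_eval`.
#' @param json_path,csv_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "icp_eval"))
  if (!is.null(json_path)) {
    obj <- list(design = report$design, params = report$params,
                results = report$results)
    if (!is.null(report$per_patient)) obj$per_patient <- report$per_patient
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows", na = "null")
  }
  if (!is.null(csv_path))
    utils::write.csv(report$results, csv_path, row.names = FALSE, na = "")
  invisible(c(json = json_path, csv = csv_path))
}
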