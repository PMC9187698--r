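#' Fit the dynamic naive Bayes ICP forecaster
#'
#' Estimates, for each forecast horizon `k = 1..m`, the prior probability of
#' the response class (1: mean ICP < 20 mmHg, 2: >= 20 mmHg) and the
#' class-conditional distribution of the discretized one-hour history, by
#' (optionally Laplace-smoothed) maximum likelihood.  Two factorizations of
#' the history likelihood are available:
#'
#' * `per_lag` (default): conditional independence of the `d1` lag positions
#'   given the class — one 3-cell multinomial per lag and class.  Robust at
#'   clinical data sizes.
#' * `joint`: one multinomial over all `3^d1` histories per class — the
#'   unfactorized class-conditional, estimable but sparse for `d1 = 6`.
#'
#' Priors are `(count(y = c) + lambda) / (n_k + 2 lambda)`; conditional cells
#' get the analogous pseudo-count `lambda` (default 1, so unseen histories
#' never have probability zero at prediction time; `lambda = 0` gives pure
#' maximum likelihood).
#'
#' @param data A `windowed_dataset` from [make_windows()]; rows with missing
#'   lag levels are dropped with a warning.
#' @param mode History-likelihood factorization, `"per_lag"` or `"joint"`.
#' @param lambda Pseudo-count smoothing constant, `>= 0`.
#' @param m Number of horizons to fit (default: the largest horizon in
#'   `data`); every horizon `1..m` must have at least one row.
#' @param alpha Default balancing factor stored with the model and used by
#'   [predict_enhanced()] when no `alpha` is given (default 0.60).
#' @param w Importance weight of the severe class stored for
#'   [select_alpha()] (default 2).
#'
#' @return An object of class `cpt_model`: priors (an `m x 2` matrix), per
#'   horizon conditional tables, and the fitting configuration.
#' @examples
#' d <- data.frame(patient_id = "A", anchor = 2:9, horizon = 1L,
#'                 y = rep(1:2, 4), lag1 = rep(1:2, 4), lag2 = c(1,3,1,3,2,3,1,3))
#' class(d) <- c("windowed_dataset", "data.frame")
#' fit_cpt(d, lambda = 0)
#' @export
fit_cpt <- function(data, mode = c("per_lag", "joint"), lambda = 1,
                    m = NULL, alpha = 0.60, w = 2) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "data.frame"))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop("`lambda` must be a single number >= 0")
  check_alpha(alpha)
  if (!is.numeric(w) || w < 1) stop("`w` must be >= 1")

  d1 <- window_d1(data)
  if (d1 < 1L) stop("`data` has no lag columns")
  X <- lag_matrix(data)
  drop <- rowSums(is.na(X)) > 0L
  if (any(drop)) {
    warning(sprintf("dropping %d training row(s) with missing lag levels", sum(drop)))
    data <- data[!drop, , drop = FALSE]
    X <- X[!drop, , drop = FALSE]
  }
  if (any(!(X %in% c(1L, 2L, 3L))))
    stop("lag levels must be in {1, 2, 3}")
  if (is.null(m)) m <- max(data$horizon)
  m <- as.integer(m)

  priors <- matrix(NA_real_, m, 2, dimnames = list(NULL, c("1", "2")))
  cond <- vector("list", m)
  for (k in seq_len(m)) {
    idx <- which(data$horizon == k)
    if (!length(idx))
      stop(sprintf("no training rows for horizon %d", k))
    y <- data$y[idx]
    if (any(!(y %in% 1:2))) stop("response classes must be in {1, 2}")
    nk <- length(idx)
    nc <- c(sum(y == 1L), sum(y == 2L))
    priors[k, ] <- (nc + lambda) / (nk + 2 * lambda)
    Xi <- X[idx, , drop = FALSE]
    if (mode == "per_lag") {
      tabs <- array(NA_real_, c(d1, 3L, 2L),
                    dimnames = list(NULL, c("1", "2", "3"), c("1", "2")))
      for (cl in 1:2) {
        Xc <- Xi[y == cl, , drop = FALSE]
        for (j in seq_len(d1)) {
          cnt <- tabulate(Xc[, j], nbins = 3L)
          tabs[j, , cl] <- (cnt + lambda) / (nc[cl] + 3 * lambda)
        }
      }
      cond[[k]] <- tabs
    } else {
      ncell <- 3L^d1
      h <- history_index(Xi)
      tabs <- matrix(NA_real_, ncell, 2L, dimnames = list(NULL, c("1", "2")))
      for (cl in 1:2) {
        cnt <- tabulate(h[y == cl], nbins = ncell)
        tabs[, cl] <- (cnt + lambda) / (nc[cl] + ncell * lambda)
      }
      cond[[k]] <- tabs
    }
  }
  structure(list(classes = 1:2, d1 = d1, m = m, mode = mode,
                 lambda = lambda, alpha = alpha, w = w,
                 priors = priors, cond = cond),
            class = "cpt_model")
}

# 1-based cell index of a complete history; column 1 is the oldest lag
history_index <- function(X) {
  d1 <- ncol(X)
  as.integer(1L + (X - 1L) %*% 3L^(seq_len(d1) - 1L))
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1)
    stop("`alpha` must be a single number in (0, 1]")
  invisible(alpha)
}

check_history <- function(model, history, allow_missing = FALSE) {
  if (length(history) != model$d1)
    stop(sprintf("`history` must have length d1 = %d", model$d1))
  obs <- history[!is.na(history)]
  if (any(!(obs %in% c(1, 2, 3))))
    stop("history levels must be in {1, 2, 3}")
  if (!allow_missing && anyNA(history))
    stop("`history` contains missing levels; use posterior_with_missing()")
  invisible(history)
}

check_horizon <- function(model, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k > model$m)
    stop(sprintf("`k` must be a horizon in 1..%d", model$m))
  as.integer(k)
}

#' @export
print.cpt_model <- function(x, ...) {
  cat(sprintf("<cpt_model> dynamic naive Bayes ICP forecaster\n"))
  cat(sprintf("  history d1 = %d intervals, horizons m = %d, mode = %s, lambda = %g\n",
              x$d1, x$m, x$mode, x$lambda))
  cat(sprintf("  enhancement: alpha = %g, w = %g\n", x$alpha, x$w))
  cat("  P(severe) by horizon:",
      paste(sprintf("%.3f", x$priors[, 2]), collapse = " "), "\n")
  invisible(x)
}

#' Posterior class probabilities for one history
#'
#' Bayes' rule for the horizon-`k` response given the discretized one-hour
#' history: the prior times the class-conditional history likelihood,
#' normalized over the two classes.  In `per_lag` mode the likelihood is the
#' product of the per-lag conditionals; in `joint` mode it is a single table
#' lookup.  If both unnormalized scores are zero (possible with
#' `lambda = 0` and an unseen history) the prior is returned with a warning.
#'
#' @param model A [fit_cpt()] model.
#' @param history Integer vector of `d1` Q3 levels in {1, 2, 3}, oldest
#'   first; must be fully observed (see [posterior_with_missing()]).
#' @param k Forecast horizon, `1..m`.
#' @return Named numeric vector `c("1" = , "2" = )` summing to 1.
#' @export
posterior <- function(model, history, k) {
  stopifnot(inherits(model, "cpt_model"))
  check_history(model, history, allow_missing = FALSE)
  posterior_with_missing(model, history, k)
}

#' Posterior with partially missing histories
#'
#' Like [posterior()], but missing lag positions are marginalized out: in
#' `per_lag` mode their factors are dropped (each missing lag's conditional
#' sums to one), and in `joint` mode the joint conditional is summed over
#' all completions of the missing positions.  With nothing missing this is
#' identical to [posterior()]; with everything missing the prior is
#' returned, flagged with `attr(, "all_missing")`.
#'
#' @inheritParams posterior
#' @param history As in [posterior()] but `NA` marks a missing lag.
#' @return Named numeric vector `c("1" = , "2" = )` summing to 1.
#' @export
posterior_with_missing <- function(model, history, k) {
  stopifnot(inherits(model, "cpt_model"))
  k <- check_horizon(model, k)
  if (length(history) != model$d1)
    stop(sprintf("`history` must have length d1 = %d", model$d1))
  obs <- !is.na(history)
  if (any(!(history[obs] %in% c(1, 2, 3))))
    stop("history levels must be in {1, 2, 3}")
  pri <- model$priors[k, ]
  if (!any(obs)) {
    out <- pri
    attr(out, "all_missing") <- TRUE
    return(out)
  }
  lik <- c(1, 1)
  if (model$mode == "per_lag") {
    tabs <- model$cond[[k]]
    for (j in which(obs))
      lik <- lik * tabs[j, history[j], ]
  } else {
    tabs <- model$cond[[k]]
    cells <- completion_indices(history, model$d1)
    lik <- c(sum(tabs[cells, 1L]), sum(tabs[cells, 2L]))
  }
  num <- pri * lik
  tot <- sum(num)
  if (tot == 0) {
    warning("history has zero likelihood under both classes; returning the prior")
    return(pri)
  }
  num / tot
}

# all joint-table cell indices compatible with a partially observed history
completion_indices <- function(history, d1) {
  vals <- lapply(seq_len(d1), function(j)
    if (is.na(history[j])) 1:3 else as.integer(history[j]))
  grid <- as.matrix(expand.grid(vals))
  history_index(grid)
}

#' Maximum a posteriori class prediction
#'
#' The class with the larger posterior probability; exact ties go to class 2
#' (the clinically conservative alert).
#'
#' @inheritParams posterior
#' @return Integer class label, 1 or 2.
#' @export
predict_map <- function(model, history, k) {
  p <- posterior(model, history, k)
  if (p[2L] >= p[1L]) 2L else 1L
}

#' The alpha-weighted enhancement decision rule
#'
#' Applies the imbalance-compensating decision rule to a posterior: class 1
#' is chosen only if `alpha * P(1 | history)` exceeds `P(2 | history)`, ties
#' going to class 2.  With `alpha = 1` this is the plain MAP rule; smaller
#' `alpha` handicaps the majority (normal-pressure) class, trading
#' specificity for sensitivity.  For example, with `alpha = 0.65` a
#' posterior of (0.6, 0.4) yields the weighted class-1 score
#' `0.65 * 0.6 = 0.39 < 0.40`, so the severe class is predicted despite
#' being a posteriori less probable.
#'
#' @param post Numeric posterior `c(P(1), P(2))`, non-negative.
#' @param alpha Balancing factor in (0, 1].
#' @return List with `scores` (the compared pair: `alpha * P(1)` and
#'   `P(2)`) and `class` (1 or 2).
#' @examples
#' enhance_decision(c(0.6, 0.4), alpha = 0.65)
#' @export
enhance_decision <- function(post, alpha) {
  check_alpha(alpha)
  if (length(post) != 2L || anyNA(post) || any(post < 0))
    stop("`post` must be two non-negative probabilities")
  scores <- c(alpha * post[1L], post[2L])
  names(scores) <- c("1", "2")
  list(scores = scores, class = if (scores[1L] > scores[2L]) 1L else 2L)
}

#' Enhanced (alpha-weighted) class prediction
#'
#' [predict_map()] with the balancing factor applied to the class-1
#' posterior before the argmax; see [enhance_decision()].
#'
#' @inheritParams posterior
#' @param alpha Balancing factor in (0, 1]; defaults to the value stored in
#'   the model (0.60 unless changed).
#' @return Integer class label, 1 or 2.
#' @export
predict_enhanced <- function(model, history, k, alpha = model$alpha) {
  p <- posterior(model, history, k)
  enhance_decision(p, alpha)$class
}

#' Predict every row of a windowed dataset
#'
#' Vectorized posterior, MAP and enhanced predictions for a whole
#' `windowed_dataset`; missing lags are marginalized as in
#' [posterior_with_missing()].
#'
#' @param object A `cpt_model`.
#' @param newdata A `windowed_dataset` whose lag count matches `object$d1`.
#' @param alpha Balancing factor for the enhanced prediction.
#' @param ... Unused.
#' @return A `data.frame` with the provenance columns of `newdata` plus
#'   `p1`, `p2` (posterior), `map` and `enhanced` class labels.
#' @export
predict.cpt_model <- function(object, newdata, alpha = object$alpha, ...) {
  check_alpha(alpha)
  stopifnot(inherits(newdata, "data.frame"))
  if (window_d1(newdata) != object$d1)
    stop(sprintf("`newdata` has %d lag columns but the model expects d1 = %d",
                 window_d1(newdata), object$d1))
  X <- lag_matrix(newdata)
  n <- nrow(newdata)
  p1 <- numeric(n); p2 <- numeric(n)
  for (k in sort(unique(newdata$horizon))) {
    k <- check_horizon(object, k)
    idx <- which(newdata$horizon == k)
    pri <- object$priors[k, ]
    l1 <- rep(1, length(idx)); l2 <- rep(1, length(idx))
    if (object$mode == "per_lag") {
      tabs <- object$cond[[k]]
      for (j in seq_len(object$d1)) {
        lv <- X[idx, j]
        o <- !is.na(lv)
        l1[o] <- l1[o] * tabs[cbind(j, lv[o], 1L)]
        l2[o] <- l2[o] * tabs[cbind(j, lv[o], 2L)]
      }
    } else {
      tabs <- object$cond[[k]]
      full <- rowSums(is.na(X[idx, , drop = FALSE])) == 0L
      if (any(full)) {
        h <- history_index(X[idx[full], , drop = FALSE])
        l1[full] <- tabs[h, 1L]
        l2[full] <- tabs[h, 2L]
      }
      for (i in which(!full)) {
        cells <- completion_indices(X[idx[i], ], object$d1)
        l1[i] <- sum(tabs[cells, 1L])
        l2[i] <- sum(tabs[cells, 2L])
      }
    }
    num1 <- pri[1L] * l1; num2 <- pri[2L] * l2
    tot <- num1 + num2
    zero <- tot == 0
    if (any(zero)) {  # unseen history under lambda = 0: fall back to the prior
      num1[zero] <- pri[1L]; num2[zero] <- pri[2L]; tot[zero] <- 1
    }
    # rows with every lag missing carry no evidence: posterior = prior
    p1[idx] <- num1 / tot
    p2[idx] <- num2 / tot
  }
  out <- newdata[intersect(c("patient_id", "anchor", "horizon", "y"), names(newdata))]
  out <- as.data.frame(out)
  out$p1 <- p1
  out$p2 <- p2
  out$map <- ifelse(p2 >= p1, 2L, 1L)
  out$enhanced <- ifelse(alpha * p1 > p2, 1L, 2L)
  rownames(out) <- NULL
  out
}

#' Choose the balancing factor by the total-gain criterion
#'
#' Evaluates a grid of balancing factors on a validation set and scores
#' each by the total accuracy gain
#' `T = A f1(alpha) + w (1 - A) f2(alpha)`, where `A` is the fraction of
#' class-1 responses, `f_i(alpha)` is the change in class-`i` accuracy
#' relative to the unweighted rule (`alpha = 1`; `f1 <= 0`, `f2 >= 0`), and
#' `w >= 1` weights the clinical importance of catching severe pressure.
#' The chosen factor maximizes `T` subject to `T > 0`; among maximizers the
#' largest `alpha` (least intervention) wins, and if no grid point achieves
#' `T > 0` the rule falls back to `alpha = 1` (no enhancement).  One shared
#' factor across horizons (maximizing the mean `T`) is the default; the
#' per-horizon maximizers are also reported.
#'
#' @param model A `cpt_model`.
#' @param validation A non-empty `windowed_dataset`; every horizon present
#'   must contain both response classes.
#' @param grid Candidate balancing factors in (0, 1] (default 0.50 to 0.85
#'   in steps of 0.05).
#' @param w Importance weight of class 2 (default: the model's, normally 2).
#' @return An object of class `alpha_selection`: the per-(horizon, alpha)
#'   table of `A`, `f1`, `f2` and `T`, the per-horizon maximizers, and the
#'   shared choice `chosen`.
#' @export
select_alpha <- function(model, validation,
                         grid = seq(0.50, 0.85, by = 0.05), w = model$w) {
  stopifnot(inherits(model, "cpt_model"))
  if (!is.numeric(grid) || !length(grid) || any(is.na(grid)) ||
      any(grid <= 0 | grid > 1))
    stop("`grid` must be balancing factors in (0, 1]")
  if (!is.numeric(w) || w < 1) stop("`w` must be >= 1")
  if (!nrow(validation)) stop("`validation` is empty")
  grid <- sort(unique(grid))

  pr <- predict(model, validation, alpha = 1)
  horizons <- sort(unique(pr$horizon))
  rows <- list()
  for (k in horizons) {
    d <- pr[pr$horizon == k, ]
    i1 <- d$y == 1L; i2 <- d$y == 2L
    if (!any(i1) || !any(i2))
      stop(sprintf("validation lacks class %d rows for horizon %d; accuracy gain undefined",
                   if (any(i1)) 2L else 1L, k))
    A <- mean(i1)
    base1 <- mean(d$map[i1] == 1L)
    base2 <- mean(d$map[i2] == 2L)
    for (a in grid) {
      pred1 <- a * d$p1 > d$p2  # TRUE: predict class 1
      acc1 <- mean(pred1[i1])
      acc2 <- mean(!pred1[i2])
      f1 <- acc1 - base1
      f2 <- acc2 - base2
      rows[[length(rows) + 1L]] <- data.frame(
        horizon = k, alpha = a, A = A, f1 = f1, f2 = f2,
        T = A * f1 + w * (1 - A) * f2)
    }
  }
  tab <- do.call(rbind, rows)

  pick <- function(alphas, Ts) {
    ok <- Ts > 0
    if (!any(ok)) return(NA_real_)
    cand <- which(ok & Ts >= max(Ts[ok]) - 1e-12)
    max(alphas[cand])  # largest alpha among maximizers
  }
  by_h <- vapply(horizons, function(k) {
    d <- tab[tab$horizon == k, ]
    pick(d$alpha, d$T)
  }, 0)
  names(by_h) <- horizons
  overall_T <- vapply(grid, function(a) mean(tab$T[tab$alpha == a]), 0)
  chosen <- pick(grid, overall_T)

  structure(list(grid = grid, w = w, table = tab,
                 chosen_by_horizon = by_h,
                 overall_T = stats::setNames(overall_T, grid),
                 chosen = if (is.na(chosen)) 1 else chosen,
                 enhancement_found = !is.na(chosen)),
            class = "alpha_selection")
}

#' @export
print.alpha_selection <- function(x, ...) {
  cat("<alpha_selection> total-gain criterion T = A f1 + w (1 - A) f2, w =",
      x$w, "\n")
  cat("  grid:", paste(format(x$grid), collapse = " "), "\n")
  cat("  mean T over horizons:",
      paste(sprintf("%.4f", x$overall_T), collapse = " "), "\n")
  if (x$enhancement_found) {
    cat("  chosen alpha (shared):", x$chosen, "\n")
  } else {
    cat("  no grid point achieved T > 0; falling back to alpha = 1\n")
  }
  invisible(x)
}

#' Save or load a fitted model as JSON
#'
#' Serializes every parameter of a `cpt_model` (priors, conditional tables,
#' factorization mode, smoothing, alpha, w, d1, m) to a JSON file at full
#' double precision, and reads it back.  Tables are stored flat
#' (column-major) alongside their dimensions, so the round trip is
#' unambiguous.
#'
#' @param model A `cpt_model`.
#' @param path JSON file path.
#' @return `path` (writer) or the reconstructed `cpt_model` (reader).
#' @export
write_cpt_model <- function(model, path) {
  stopifnot(inherits(model, "cpt_model"))
  obj <- list(
    format = "icpcast-cpt-model", version = 1L,
    d1 = model$d1, m = model$m, mode = model$mode,
    lambda = model$lambda, alpha = model$alpha, w = model$w,
    priors = as.numeric(model$priors),       # column-major m x 2
    cond_dim = as.integer(dim(model$cond[[1L]])),
    cond = lapply(model$cond, as.numeric))   # column-major per horizon
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cpt_model
#' @export
read_cpt_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "icpcast-cpt-model"))
    stop("not an icpcast model file: ", path)
  d1 <- as.integer(obj$d1); m <- as.integer(obj$m)
  priors <- matrix(as.numeric(unlist(obj$priors)), m, 2,
                   dimnames = list(NULL, c("1", "2")))
  dm <- as.integer(unlist(obj$cond_dim))
  cond <- lapply(seq_len(m), function(k) {
    tb <- array(as.numeric(unlist(obj$cond[[k]])), dim = dm)
    dimnames(tb) <- if (length(dm) == 3L)
      list(NULL, c("1", "2", "3"), c("1", "2")) else list(NULL, c("1", "2"))
    tb
  })
  structure(list(classes = 1:2, d1 = d1, m = m, mode = obj$mode,
                 lambda = obj$lambda, alpha = obj$alpha, w = obj$w,
                 priors = priors, cond = cond),
            class = "cpt_model")
}
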