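# Shared fixtures and independent oracles, all built in code at test time.

# A windowed dataset from explicit columns.
make_ws <- function(y, lags, horizon = 1L, patient_id = "A",
                    anchor = seq_along(y)) {
  lags <- as.matrix(lags)
  out <- cbind(
    data.frame(patient_id = patient_id, anchor = anchor,
               horizon = rep_len(horizon, length(y)), y = y,
               stringsAsFactors = FALSE),
    stats::setNames(as.data.frame(lags), paste0("lag", seq_len(ncol(lags)))))
  class(out) <- c("windowed_dataset", "data.frame")
  out
}

# Hand-written 8-row training set, d1 = 2, one horizon.  Counts (lambda = 0):
#   priors (4/8, 4/8)
#   class 1 lag1 (3,1,0)/4  lag2 (3,1,0)/4
#   class 2 lag1 (0,1,3)/4  lag2 (0,1,3)/4
hand8 <- function() {
  make_ws(y = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L),
          lags = rbind(c(1, 1), c(3, 3), c(1, 2), c(3, 3),
                       c(2, 1), c(3, 2), c(1, 1), c(2, 3)))
}

# Brute-force Bayes oracle: posterior from raw contingency counts, without
# any factorization.  Independent of fit_cpt()/posterior().
brute_posterior <- function(data, history, k) {
  X <- as.matrix(data[grep("^lag", names(data))])
  rows <- data$horizon == k
  num <- vapply(1:2, function(cl) {
    sel <- rows & data$y == cl
    p_class <- sum(sel) / sum(rows)
    p_hist <- if (sum(sel)) {
      mean(apply(X[sel, , drop = FALSE], 1L,
                 function(r) all(r == history)))
    } else 0
    p_class * p_hist
  }, 0)
  num / sum(num)
}

# Joint-table cell index of a complete history (oldest lag first).
history_idx <- function(h) {
  d1 <- length(h)
  as.integer(1L + (h - 1L) %*% 3L^(seq_len(d1) - 1L))
}

# Random small windowed datasets for property-style loops.
random_ws <- function(n, d1, m = 1L, seed) {
  withr::with_seed(seed, {
    make_ws(y = sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3)),
            lags = matrix(sample(1:3, n * d1, replace = TRUE), n, d1),
            horizon = sample.int(m, n, replace = TRUE))
  })
}

# A fully specified per-lag model for sampling and hand-posterior tests.
toy_model <- function(m = 1L, d1 = 6L, prior2 = 0.5) {
  probs1 <- c(0.6, 0.3, 0.1)
  probs2 <- c(0.2, 0.3, 0.5)
  cond <- lapply(seq_len(m), function(k) {
    a <- array(NA_real_, c(d1, 3L, 2L))
    for (j in seq_len(d1)) { a[j, , 1L] <- probs1; a[j, , 2L] <- probs2 }
    a
  })
  cpt_model(matrix(rep(c(1 - prior2, prior2), each = m), m, 2), cond)
}

# Generating model for parameter-recovery checks: full six-lag history,
# balanced prior (so both class-conditional tables see ~10,000 draws).
recovery_model <- function() {
  cond <- array(NA_real_, c(6L, 3L, 2L))
  for (j in 1:6) {
    cond[j, , 1L] <- c(0.55, 0.30, 0.15)
    cond[j, , 2L] <- c(0.15, 0.30, 0.55)
  }
  cpt_model(matrix(c(0.5, 0.5), 1), list(cond))
}

# A small synthetic cohort as interval tables (shared by evaluation tests).
small_cohort_tables <- function(n_patients = 4L, hours = 30, seed = 11,
                                ...) {
  cfg <- cohort_config(n_patients = n_patients, hours_per_patient = hours,
                       seed = seed, ...)
  lapply(generate_cohort(cfg), function(s) make_intervals(clean_series(s)))
}

rbind_tables <- function(tables) {
  tb <- do.call(rbind, tables)
  class(tb) <- c("interval_table", "data.frame")
  rownames(tb) <- NULL
  tb
}
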