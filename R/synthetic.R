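#' Configuration for a synthetic ICP cohort
#'
#' Describes a two-state (normal / elevated) first-order Markov regime chain
#' at minute resolution with Gaussian within-regime noise, plus a
#' missingness process that punches short gaps into the record (mimicking
#' artifact removal around patient transport and probe handling).  Defaults
#' emulate a severe-TBI ICU cohort: normal regime around 13 mmHg, elevated
#' episodes around 24 mmHg lasting tens of minutes, and a stationary
#' elevated fraction near 18%.
#'
#' Regime persistence can be given either as mean dwell times (minutes; the
#' per-minute exit probability is their reciprocal) or directly as
#' transition probabilities `p_up` (normal to elevated, per minute) and
#' `p_down`.  If `elev_frac` is supplied, `p_up` is re-derived from the
#' elevated dwell time so the chain's stationary elevated fraction
#' `p_up / (p_up + p_down)` equals it.
#'
#' @param n_patients Number of patients.
#' @param hours_per_patient Recording length per patient, hours.
#' @param normal_mean,normal_sd,elev_mean,elev_sd Regime emission means and
#'   standard deviations, mmHg.
#' @param dwell_normal,dwell_elev Mean regime dwell times, minutes.
#' @param p_up,p_down Per-minute transition probabilities; override dwells.
#' @param elev_frac Optional target stationary fraction of elevated minutes.
#' @param missing_rate Expected fraction of minutes missing (default 0.025).
#' @param gap_mean Mean length of a missing gap, minutes (geometric).
#' @param seed Mandatory integer seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 10L, hours_per_patient = 200,
                          normal_mean = 13, normal_sd = 2,
                          elev_mean = 24, elev_sd = 3,
                          dwell_normal = 90, dwell_elev = 20,
                          p_up = NULL, p_down = NULL, elev_frac = NULL,
                          missing_rate = 0.025, gap_mean = 3, seed) {
  if (missing(seed) || !is.numeric(seed) || is.na(seed))
    stop("`seed` is required")
  if (is.null(p_down)) p_down <- 1 / dwell_elev
  if (!is.null(elev_frac)) {
    if (elev_frac < 0 || elev_frac >= 1) stop("`elev_frac` must be in [0, 1)")
    p_up <- if (elev_frac == 0) 0 else elev_frac * p_down / (1 - elev_frac)
  } else if (is.null(p_up)) {
    p_up <- 1 / dwell_normal
  }
  cfg <- list(n_patients = as.integer(n_patients),
              hours_per_patient = hours_per_patient,
              normal_mean = normal_mean, normal_sd = normal_sd,
              elev_mean = elev_mean, elev_sd = elev_sd,
              p_up = p_up, p_down = p_down,
              missing_rate = missing_rate, gap_mean = gap_mean,
              seed = as.integer(seed))
  with(cfg, {
    if (n_patients < 1L) stop("`n_patients` must be >= 1")
    if (hours_per_patient <= 0) stop("`hours_per_patient` must be > 0")
    if (p_up < 0 || p_up > 1 || p_down < 0 || p_down > 1)
      stop("transition probabilities must be in [0, 1]")
    if (normal_sd <= 0 || elev_sd <= 0) stop("emission sds must be > 0")
    if (elev_mean <= normal_mean) stop("`elev_mean` must exceed `normal_mean`")
    if (missing_rate < 0 || missing_rate >= 1) stop("`missing_rate` must be in [0, 1)")
    if (gap_mean < 1) stop("`gap_mean` must be >= 1 minute")
  })
  structure(cfg, class = "cohort_config")
}

#' Stationary elevated-minute fraction of a cohort configuration
#'
#' Closed form for the two-state chain: `p_up / (p_up + p_down)` (0 if the
#' chain never leaves the normal regime).
#'
#' @param cfg A [cohort_config()].
#' @return The stationary probability of the elevated regime.
#' @export
stationary_elevated <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  tot <- cfg$p_up + cfg$p_down
  if (tot == 0) 0 else cfg$p_up / tot
}

# one regime path of length n, simulated by alternating geometric dwells
simulate_regimes <- function(n, p_up, p_down, start) {
  state <- integer(n)
  pos <- 1L
  cur <- start
  while (pos <= n) {
    p_exit <- if (cur == 1L) p_up else p_down
    dwell <- if (p_exit <= 0) n else stats::rgeom(1L, p_exit) + 1L
    end <- min(n, pos + dwell - 1L)
    state[pos:end] <- cur
    pos <- end + 1L
    cur <- 3L - cur
  }
  state
}

#' Generate a synthetic minute-resolution ICP cohort
#'
#' Simulates each patient's regime chain (initial state drawn from the
#' stationary distribution), adds Gaussian emission noise, clips at 0 mmHg
#' (negative pressures are never emitted), and injects missing gaps whose
#' starts are Bernoulli per minute and whose lengths are geometric with the
#' configured mean.  Bit-identical given the config seed.
#'
#' @param cfg A [cohort_config()].
#' @return Named list of [minute_series()], `P01`, `P02`, ...
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 2,
#'   hours_per_patient = 5, seed = 42))
#' cohort[[1]]
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n_min <- as.integer(round(cfg$hours_per_patient * 60))
  pi2 <- stationary_elevated(cfg)
  withr::with_seed(cfg$seed, {
    out <- list()
    for (i in seq_len(cfg$n_patients)) {
      id <- sprintf("P%02d", i)
      start <- if (stats::runif(1L) < pi2) 2L else 1L
      st <- simulate_regimes(n_min, cfg$p_up, cfg$p_down, start)
      mu <- ifelse(st == 1L, cfg$normal_mean, cfg$elev_mean)
      sd <- ifelse(st == 1L, cfg$normal_sd, cfg$elev_sd)
      icp <- pmax(0, stats::rnorm(n_min, mu, sd))
      if (cfg$missing_rate > 0) {
        p_start <- cfg$missing_rate / cfg$gap_mean
        starts <- which(stats::runif(n_min) < p_start)
        if (length(starts)) {
          lens <- stats::rgeom(length(starts), 1 / cfg$gap_mean) + 1L
          for (g in seq_along(starts))
            icp[starts[g]:min(n_min, starts[g] + lens[g] - 1L)] <- NA_real_
        }
      }
      out[[id]] <- minute_series(id, seq_len(n_min), icp)
    }
    out
  })
}

#' Sample prediction windows directly from a per-lag model
#'
#' Draws `n` rows from the generative process the per-lag naive Bayes model
#' assumes: a horizon is drawn uniformly, the response class from that
#' horizon's prior, and each lag level independently from its
#' class-conditional distribution.  Used for parameter-recovery testing of
#' [fit_cpt()].
#'
#' @param model A per-lag `cpt_model` supplying priors and conditionals.
#' @param n Number of windows to draw; `n = 0` gives an empty dataset.
#' @param seed Mandatory integer seed.
#' @return A `windowed_dataset` with synthetic provenance
#'   (`patient_id = "SIM"`, `anchor` = row number).
#' @export
generate_interval_windows <- function(model, n, seed) {
  stopifnot(inherits(model, "cpt_model"))
  if (model$mode != "per_lag")
    stop("sampling is defined for per-lag models")
  if (missing(seed) || !is.numeric(seed) || is.na(seed)) stop("`seed` is required")
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("`n` must be a non-negative integer")
  d1 <- model$d1
  lag_names <- paste0("lag", seq_len(d1))
  if (n == 0L) {
    out <- cbind(
      data.frame(patient_id = character(), anchor = integer(),
                 horizon = integer(), y = integer(), stringsAsFactors = FALSE),
      stats::setNames(as.data.frame(matrix(integer(), 0, d1)), lag_names))
    class(out) <- c("windowed_dataset", "data.frame")
    return(out)
  }
  withr::with_seed(as.integer(seed), {
    k <- sample.int(model$m, n, replace = TRUE)
    y <- integer(n)
    X <- matrix(NA_integer_, n, d1)
    for (kk in seq_len(model$m)) {
      idx <- which(k == kk)
      if (!length(idx)) next
      y[idx] <- ifelse(stats::runif(length(idx)) < model$priors[kk, 1L], 1L, 2L)
      tabs <- model$cond[[kk]]
      for (cl in 1:2) {
        rows <- idx[y[idx] == cl]
        if (!length(rows)) next
        for (j in seq_len(d1))
          X[rows, j] <- sample.int(3L, length(rows), replace = TRUE,
                                   prob = tabs[j, , cl])
      }
    }
    out <- cbind(
      data.frame(patient_id = "SIM", anchor = seq_len(n), horizon = k, y = y,
                 stringsAsFactors = FALSE),
      stats::setNames(as.data.frame(X), lag_names))
    class(out) <- c("windowed_dataset", "data.frame")
    out
  })
}

#' Build a fully specified per-lag model without fitting
#'
#' Convenience constructor for a `cpt_model` from explicit priors and
#' conditional tables, used to drive [generate_interval_windows()] and to
#' hand-craft models in examples.
#'
#' @param priors `m x 2` matrix of class priors (rows sum to 1).
#' @param cond List of length `m`; element `k` is a `d1 x 3 x 2` array of
#'   class-conditional lag-level probabilities.
#' @param alpha,w Stored enhancement parameters.
#' @return A `cpt_model` of mode `per_lag`.
#' @export
cpt_model <- function(priors, cond, alpha = 0.60, w = 2) {
  priors <- as.matrix(priors)
  if (ncol(priors) != 2L) stop("`priors` must have two columns")
  if (any(abs(rowSums(priors) - 1) > 1e-8)) stop("prior rows must sum to 1")
  m <- nrow(priors)
  if (!is.list(cond) || length(cond) != m)
    stop("`cond` must be a list with one array per horizon")
  d1 <- dim(cond[[1L]])[1L]
  for (k in seq_len(m)) {
    dm <- dim(cond[[k]])
    if (length(dm) != 3L || !all(dm == c(d1, 3L, 2L)))
      stop("each conditional array must be d1 x 3 x 2")
    sums <- apply(cond[[k]], c(1L, 3L), sum)
    if (any(abs(sums - 1) > 1e-8))
      stop("each lag-conditional distribution must sum to 1")
  }
  colnames(priors) <- c("1", "2")
  structure(list(classes = 1:2, d1 = d1, m = m, mode = "per_lag",
                 lambda = NA_real_, alpha = alpha, w = w,
                 priors = priors, cond = cond),
            class = "cpt_model")
}
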