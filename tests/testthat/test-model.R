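test_that("maximum-likelihood fitting reproduces hand counts exactly", {
  d <- hand8()
  m0 <- fit_cpt(d, lambda = 0)
  expect_equal(as.numeric(m0$priors), c(0.5, 0.5))
  # class-1 lag tables: (3,1,0)/4 at both lags; class 2: (0,1,3)/4
  expect_equal(as.numeric(m0$cond[[1]][1, , 1]), c(3, 1, 0) / 4)
  expect_equal(as.numeric(m0$cond[[1]][2, , 1]), c(3, 1, 0) / 4)
  expect_equal(as.numeric(m0$cond[[1]][1, , 2]), c(0, 1, 3) / 4)
  expect_equal(as.numeric(m0$cond[[1]][2, , 2]), c(0, 1, 3) / 4)

  # joint mode: P((1,1) | 1) = 2/4, P((3,3) | 2) = 2/4
  mj <- fit_cpt(d, mode = "joint", lambda = 0)
  expect_equal(mj$cond[[1]][history_idx(c(1, 1)), "1"], 0.5, ignore_attr = TRUE)
  expect_equal(mj$cond[[1]][history_idx(c(3, 3)), "2"], 0.5, ignore_attr = TRUE)

  # degenerate counts: every y = 2 row has an all-level-3 history
  d2 <- make_ws(y = c(1L, 1L, 2L, 2L), lags = rbind(c(1, 2), c(2, 1),
                                                    c(3, 3), c(3, 3)))
  mdeg <- fit_cpt(d2, lambda = 0)
  expect_equal(as.numeric(mdeg$cond[[1]][, 3, 2]), c(1, 1))

  # add-one smoothing gives every cell strictly positive mass
  m1 <- fit_cpt(d2, lambda = 1)
  expect_true(all(unlist(m1$cond) > 0))
  expect_equal(as.numeric(m1$cond[[1]][1, , 2]), c(0 + 1, 0 + 1, 2 + 1) / (2 + 3))

  # error paths
  expect_error(fit_cpt(d, lambda = -1), "lambda")
  d_gap <- d; d_gap$horizon[1:4] <- 3L
  expect_error(fit_cpt(d_gap), "horizon 2")
})

test_that("posterior matches brute-force Bayes on raw counts", {
  d <- hand8()
  m0 <- fit_cpt(d, lambda = 0)
  mj <- fit_cpt(d, mode = "joint", lambda = 0)

  # hand arithmetic for history (1, 1), per-lag factorization:
  # num1 = 0.5 * 3/4 * 3/4, num2 = 0.5 * 0 * 0
  expect_equal(as.numeric(posterior(m0, c(1, 1), 1)), c(1, 0))
  # history (2, 2): both classes give 0.5 * 1/4 * 1/4 -> (0.5, 0.5)
  expect_equal(as.numeric(posterior(m0, c(2, 2), 1)), c(0.5, 0.5))

  # joint lambda = 0 equals the contingency-count oracle on seen histories
  seen <- unique(as.matrix(d[paste0("lag", 1:2)]))
  for (r in seq_len(nrow(seen))) {
    h <- seen[r, ]
    expect_equal(as.numeric(posterior(mj, h, 1)),
                 as.numeric(brute_posterior(d, h, 1)), tolerance = 1e-12)
  }

  # symmetry: identical conditionals and equal priors -> (0.5, 0.5)
  sym <- toy_model(d1 = 2)
  sym$cond[[1]][, , 2] <- sym$cond[[1]][, , 1]
  expect_equal(as.numeric(posterior(sym, c(1, 3), 1)), c(0.5, 0.5))

  expect_error(posterior(m0, c(1, 4), 1), "levels")
  expect_error(posterior(m0, c(1, NA), 1), "missing")
  expect_error(posterior(m0, c(1, 1, 1), 1), "length")
})

test_that("joint-mode posterior equals the count oracle on random data", {
  for (seed in 1:5) {
    d1 <- 1L + seed %% 3L
    d <- random_ws(n = 150, d1 = d1, seed = seed)
    mj <- fit_cpt(d, mode = "joint", lambda = 0)
    X <- unique(as.matrix(d[paste0("lag", seq_len(d1))]))
    for (r in seq_len(nrow(X))) {
      expect_equal(as.numeric(posterior(mj, X[r, ], 1)),
                   as.numeric(brute_posterior(d, X[r, ], 1)),
                   tolerance = 1e-12)
    }
  }
})

test_that("posteriors normalize to one for arbitrary models and inputs", {
  for (seed in 1:10) {
    d <- random_ws(n = 60, d1 = 3, m = 2, seed = 100 + seed)
    for (mode in c("per_lag", "joint")) {
      m <- fit_cpt(d, mode = mode, lambda = 1)
      h <- withr::with_seed(seed, sample(1:3, 3, replace = TRUE))
      p <- posterior(m, h, 1 + seed %% 2)
      expect_true(all(p >= 0 & p <= 1))
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
})

test_that("missing lags are marginalized out of the posterior", {
  d <- random_ws(n = 200, d1 = 3, seed = 42)
  for (mode in c("per_lag", "joint")) {
    m <- fit_cpt(d, mode = mode, lambda = 1)

    # fully observed history: identical to the plain posterior
    expect_equal(posterior_with_missing(m, c(1, 2, 3), 1),
                 posterior(m, c(1, 2, 3), 1))

    # one missing lag: equals the explicit sum over its 3 completions
    h <- c(2, NA, 3)
    pri <- m$priors[1, ]
    lik <- c(0, 0)
    for (lv in 1:3) {
      full <- c(2, lv, 3)
      if (mode == "per_lag") {
        contrib <- sapply(1:2, function(cl) prod(m$cond[[1]][cbind(1:3, full, cl)]))
      } else {
        contrib <- m$cond[[1]][history_idx(full), ]
      }
      lik <- lik + contrib
    }
    expected <- pri * lik / sum(pri * lik)
    expect_equal(as.numeric(posterior_with_missing(m, h, 1)),
                 as.numeric(expected), tolerance = 1e-12)

    # all missing: the prior, flagged
    p <- posterior_with_missing(m, c(NA, NA, NA), 1)
    expect_equal(as.numeric(p), as.numeric(m$priors[1, ]))
    expect_true(attr(p, "all_missing"))
  }
})

test_that("MAP prediction takes the argmax and breaks ties to class 2", {
  m <- toy_model(d1 = 1)
  # level 1: posterior (0.75, 0.25) -> class 1; level 3: (1/6, 5/6) -> class 2
  expect_identical(predict_map(m, 1, 1), 1L)
  expect_identical(predict_map(m, 3, 1), 2L)
  # level 2: exact tie (0.5, 0.5) -> the conservative alert, class 2
  expect_equal(as.numeric(posterior(m, 2, 1)), c(0.5, 0.5))
  expect_identical(predict_map(m, 2, 1), 2L)
})

test_that("the enhancement rule reweights class 1 before the argmax", {
  # the worked example: alpha = 0.65, posterior (0.6, 0.4):
  # 0.65 * 0.6 = 0.39 < 0.40, so the severe class is predicted
  dec <- enhance_decision(c(0.6, 0.4), alpha = 0.65)
  expect_equal(as.numeric(dec$scores), c(0.39, 0.40))
  expect_identical(dec$class, 2L)

  # alpha = 0.6, posterior (0.9, 0.1): 0.54 > 0.10 -> class 1
  expect_identical(enhance_decision(c(0.9, 0.1), 0.6)$class, 1L)

  expect_error(enhance_decision(c(0.6, 0.4), 0), "alpha")
  expect_error(enhance_decision(c(0.6, 0.4), 1.2), "alpha")

  m <- toy_model(d1 = 1)
  expect_error(predict_enhanced(m, 1, 1, alpha = -0.1), "alpha")
})

test_that("alpha = 1 enhancement is identical to the MAP rule everywhere", {
  d <- random_ws(n = 300, d1 = 3, m = 2, seed = 9)
  for (mode in c("per_lag", "joint")) {
    m <- fit_cpt(d, mode = mode, lambda = 1)
    pr <- predict(m, d, alpha = 1)
    expect_identical(pr$enhanced, pr$map)
  }
})

test_that("dataset-level predict agrees with the scalar operations", {
  d <- random_ws(n = 120, d1 = 3, m = 2, seed = 5)
  m <- fit_cpt(d, lambda = 1)
  pr <- predict(m, d, alpha = 0.6)
  for (i in c(1L, 7L, 50L, 120L)) {
    h <- as.numeric(d[i, paste0("lag", 1:3)])
    p <- posterior(m, h, d$horizon[i])
    expect_equal(c(pr$p1[i], pr$p2[i]), as.numeric(p), tolerance = 1e-12)
    expect_identical(pr$map[i], predict_map(m, h, d$horizon[i]))
    expect_identical(pr$enhanced[i],
                     predict_enhanced(m, h, d$horizon[i], alpha = 0.6))
  }
})

test_that("select_alpha computes the total-gain criterion by hand arithmetic", {
  m <- toy_model(d1 = 1)
  # posteriors by level: p1 = 0.75 (level 1), 0.5 (level 2), 1/6 (level 3)
  val <- make_ws(y = c(rep(1L, 12), rep(2L, 8)),
                 lags = c(rep(1, 8), rep(2, 3), 3,   # truths 1
                          rep(1, 2), rep(2, 2), rep(3, 4)))  # truths 2
  sel <- select_alpha(m, val, grid = c(0.5, 0.6, 1/3), w = 2)

  # independent re-derivation from the frozen posteriors
  p1 <- c(`1` = 0.75, `2` = 0.5, `3` = 1 / 6)[as.character(val$lag1)]
  A <- mean(val$y == 1)
  base_pred1 <- p1 > 0.5
  base1 <- mean(base_pred1[val$y == 1]); base2 <- mean(!base_pred1[val$y == 2])
  for (a in c(1/3, 0.5, 0.6)) {
    pred1 <- a * p1 > (1 - p1)
    f1 <- mean(pred1[val$y == 1]) - base1
    f2 <- mean(!pred1[val$y == 2]) - base2
    Texp <- A * f1 + 2 * (1 - A) * f2
    got <- sel$table[abs(sel$table$alpha - a) < 1e-9, ]
    expect_equal(got$f1, f1)
    expect_equal(got$f2, f2)
    expect_equal(got$T, Texp)
    expect_equal(got$A, A)
  }
})

test_that("select_alpha maximizes T > 0 and falls back to alpha = 1", {
  m <- toy_model(d1 = 1)
  val <- make_ws(y = c(rep(1L, 12), rep(2L, 8)),
                 lags = c(rep(1, 10), 2, 3, rep(1, 2), 2, rep(3, 5)))

  # grid {1}: the baseline is itself, f1 = f2 = 0, T = 0, no enhancement
  sel1 <- select_alpha(m, val, grid = 1)
  expect_equal(sel1$table$f1, 0)
  expect_equal(sel1$table$f2, 0)
  expect_equal(sel1$table$T, 0)
  expect_false(sel1$enhancement_found)
  expect_equal(sel1$chosen, 1)

  # a grid where no prediction changes (all alphas keep the same decisions):
  # posteriors are 0.75 / 0.5 / 1/6, so alpha in (0.34, 0.99) flips nothing
  # relative to alpha = 0.95 except via the level-1 and level-2 boundaries
  sel2 <- select_alpha(m, val, grid = c(0.95, 0.9))
  expect_true(all(sel2$table$T == 0))
  expect_equal(sel2$chosen, 1)  # fallback: nothing beats the baseline

  # validation lacking one class entirely is an error
  val1 <- make_ws(y = rep(1L, 10), lags = rep(1, 10))
  expect_error(select_alpha(m, val1), "lacks class 2")

  # ties among maximizers resolve to the largest alpha (least intervention):
  # level 2 has p1 = 0.4/0.66 ~ 0.606, so it flips to class 2 for any
  # alpha <= 0.65 -- both grid points make the same (beneficial) change
  cond <- array(NA_real_, c(1, 3, 2))
  cond[1, , 1] <- c(0.50, 0.40, 0.10)
  cond[1, , 2] <- c(0.64, 0.26, 0.10)
  m2 <- cpt_model(matrix(c(0.5, 0.5), 1), list(cond))
  val3 <- make_ws(y = c(rep(1L, 6), rep(2L, 6)),
                  lags = c(rep(1, 6), rep(2, 4), 3, 3))
  sel3 <- select_alpha(m2, val3, grid = c(0.5, 0.6))
  expect_equal(sel3$table$T[1], sel3$table$T[2])
  expect_true(all(sel3$table$T > 0))
  expect_equal(sel3$chosen, 0.6)
})

test_that("decreasing alpha trades specificity for sensitivity monotonically", {
  d <- random_ws(n = 500, d1 = 3, seed = 77)
  m <- fit_cpt(d, lambda = 1)
  test_set <- random_ws(n = 400, d1 = 3, seed = 78)
  grid <- seq(0.50, 1.00, by = 0.05)
  sens <- spec <- numeric(length(grid))
  pr <- predict(m, test_set, alpha = 1)
  for (i in seq_along(grid)) {
    pred1 <- grid[i] * pr$p1 > pr$p2
    spec[i] <- mean(pred1[test_set$y == 1])
    sens[i] <- mean(!pred1[test_set$y == 2])
  }
  # as alpha decreases (reverse order of the grid)
  expect_true(all(diff(rev(sens)) >= 0))
  expect_true(all(diff(rev(spec)) <= 0))
})

test_that("parameters of a known per-lag model are recovered from samples", {
  truth <- toy_model(m = 1, d1 = 4)
  d <- generate_interval_windows(truth, n = 20000, seed = 31)
  refit <- fit_cpt(d, lambda = 0, m = 1)
  expect_lt(max(abs(refit$priors - truth$priors)), 0.02)
  expect_lt(max(abs(refit$cond[[1]] - truth$cond[[1]])), 0.02)
})

test_that("models round-trip through their JSON schema", {
  d <- random_ws(n = 100, d1 = 3, m = 2, seed = 3)
  for (mode in c("per_lag", "joint")) {
    m <- fit_cpt(d, mode = mode, lambda = 0.5, alpha = 0.6, w = 2)
    f <- withr::local_tempfile(fileext = ".json")
    write_cpt_model(m, f)
    back <- read_cpt_model(f)
    expect_equal(back$priors, m$priors)
    expect_equal(back$cond, m$cond)
    expect_identical(back$mode, m$mode)
    expect_equal(back[c("d1", "m", "lambda", "alpha", "w")],
                 m[c("d1", "m", "lambda", "alpha", "w")])
    # predictions from the reloaded model are unchanged
    expect_equal(predict(back, d), predict(m, d))
  }
  expect_error(read_cpt_model(withr::local_tempfile()), "not found")
})
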