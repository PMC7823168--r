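test_that("parameter constructor enforces the model invariants", {
  expect_error(drift_params(0, 0.1), "n_stem")
  expect_error(drift_params(5.5, 0.1), "n_stem")
  expect_error(drift_params(5, 0), "repl_rate")
  expect_error(drift_params(5, -0.1), "repl_rate")
  expect_error(drift_params(5, 0.1, -1), "delay")
  p <- drift_params(5, 0.1, 2.45)
  expect_identical(p$n_stem, 5L)
})

test_that("rate generator is a conservative chain with absorbing boundaries", {
  Q <- rate_generator(drift_params(2, 0.3))
  expect_equal(unname(Q[2, ]), c(0.3, -0.6, 0.3))
  for (N in c(2, 5, 9)) {
    Q <- rate_generator(drift_params(N, 0.17))
    expect_equal(unname(rowSums(Q)), rep(0, N + 1))
    expect_equal(unname(Q[1, ]), rep(0, N + 1))       # extinction absorbs
    expect_equal(unname(Q[N + 1, ]), rep(0, N + 1))   # fixation absorbs
  }
})

test_that("closed-form pmf agrees with the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  for (N in c(2, 3, 5, 8, 12)) {
    for (lam in c(0.05, 0.3, 1)) {
      for (t in c(1, 10, 100)) {
        p <- clone_size_pmf(drift_params(N, lam), t)
        expect_lt(max(abs(p$probs - expm_pmf(drift_params(N, lam), t))),
                  1e-8)
      }
    }
  }
  # delay shifts the effective time the same way in both routes
  par <- drift_params(5, 0.1, 2.45)
  expect_lt(max(abs(clone_size_pmf(par, 13)$probs - expm_pmf(par, 13))),
            1e-8)
})

test_that("pmf satisfies initial condition, conservation and martingale", {
  p <- clone_size_pmf(drift_params(5, 0.1), 0)
  expect_equal(unname(p$probs), c(0, 1, 0, 0, 0, 0))
  # before the delay has elapsed the clone is still a single labelled cell
  p <- clone_size_pmf(drift_params(5, 0.1, 2.45), 2)
  expect_equal(unname(p$probs[2]), 1)
  for (N in c(2, 5, 12)) {
    for (lam in c(0.1, 1)) {
      for (t in c(0.5, 5, 50, 100)) {
        pr <- clone_size_pmf(drift_params(N, lam), t)$probs
        expect_equal(sum(pr), 1, tolerance = 1e-10)
        expect_true(all(pr >= 0 & pr <= 1))
        # neutral drift conserves the expected clone size
        expect_equal(sum((0:N) * pr), 1, tolerance = 1e-8)
      }
    }
  }
  expect_error(clone_size_pmf(drift_params(5, 0.1), -1), "non-negative")
})

test_that("long-time limits give the neutral fixation probability 1/N", {
  for (N in c(2, 5, 8)) {
    pr <- clone_size_pmf(drift_params(N, 0.1), 1e4 / 0.1)$probs
    expect_equal(unname(pr[N + 1]), 1 / N, tolerance = 1e-6)
    expect_equal(unname(pr[1]), (N - 1) / N, tolerance = 1e-6)
  }
})

test_that("absorbed masses and monoclonal fraction are monotone in time", {
  par <- drift_params(5, 0.1, 2.45)
  ts <- seq(0, 80, by = 2)
  p0 <- vapply(ts, function(t) clone_size_pmf(par, t)$probs[[1]], numeric(1))
  pN <- vapply(ts, function(t) clone_size_pmf(par, t)$probs[[6]], numeric(1))
  expect_true(all(diff(p0) >= -1e-12))
  expect_true(all(diff(pN) >= -1e-12))
  expect_true(all(diff(monoclonal_fraction(par, ts)) >= -1e-12))
})

test_that("survival conditioning rescales by the surviving mass", {
  d <- clone_size_pmf(drift_params(2, 0.25), 3)
  d$probs <- c(0.5, 0.25, 0.25)
  out <- condition_on_survival(d)
  expect_equal(unname(out$probs), c(0, 0.5, 0.5))
  expect_true(out$conditioned)
  # P0 = 0 leaves the distribution unchanged
  d0 <- clone_size_pmf(drift_params(5, 0.1), 0)
  expect_equal(condition_on_survival(d0)$probs, d0$probs)
  # random valid distributions stay normalised
  set.seed(42)
  for (i in 1:20) {
    N <- sample(2:10, 1)
    pr <- stats::runif(N + 1)
    d$probs <- pr / sum(pr)
    d$params <- drift_params(N, 0.1)
    d$conditioned <- FALSE
    out <- condition_on_survival(d)
    expect_equal(sum(out$probs), 1, tolerance = 1e-12)
    expect_identical(unname(out$probs[1]), 0)
  }
  # fully extinct distribution cannot be conditioned
  d$probs <- c(1, rep(0, N))
  d$conditioned <- FALSE
  expect_error(condition_on_survival(d), "extinct")
})

test_that("eighths binning preserves monoclonal identity and unit mass", {
  expect_error(bin_to_eighths(clone_size_pmf(drift_params(5, 0.1), 10)),
               "conditioned")
  # N = 8: states coincide with eighths
  d <- condition_on_survival(clone_size_pmf(drift_params(8, 0.2), 12))
  b <- bin_to_eighths(d)
  expect_equal(unname(b$bin_probs), unname(d$probs[-1]), tolerance = 1e-12)
  # all mass monoclonal maps to bin 8 for any N
  for (N in c(3, 5, 8, 11)) {
    d <- condition_on_survival(clone_size_pmf(drift_params(N, 0.3), 5))
    d$probs <- c(0, rep(0, N - 1), 1)
    expect_equal(unname(bin_to_eighths(d)$bin_probs),
                 c(0, 0, 0, 0, 0, 0, 0, 1))
  }
  # interval-overlap oracle on a uniform surviving distribution, N = 5
  d <- condition_on_survival(clone_size_pmf(drift_params(5, 0.1), 10))
  d$probs <- c(0, rep(0.2, 5))
  expected <- drop(rep(0.2, 5) %*% grid_eighth_weights(5))
  expect_equal(unname(bin_to_eighths(d)$bin_probs), expected,
               tolerance = 1e-3)
  # and across N against the same oracle on the model distribution
  for (N in c(3, 6, 9, 12)) {
    d <- condition_on_survival(clone_size_pmf(drift_params(N, 0.2), 15))
    got <- unname(bin_to_eighths(d)$bin_probs)
    expected <- drop(d$probs[-1] %*% grid_eighth_weights(N))
    expect_equal(got, expected, tolerance = 1e-3)
    expect_equal(sum(got), 1, tolerance = 1e-10)
    expect_equal(got[8], unname(d$probs[N + 1]), tolerance = 1e-12)
  }
})

test_that("monoclonal fraction reproduces wild-type predictions", {
  wt <- wt_drift_params()
  # no conversions can have happened at or before the accrual delay
  expect_equal(monoclonal_fraction(wt, 2.45), 0)
  expect_equal(monoclonal_fraction(drift_params(7, 0.3, 1), 1), 0)
  # every surviving clone is eventually monoclonal
  expect_equal(monoclonal_fraction(wt, 1e4), 1, tolerance = 1e-6)
  # wild-type small-intestine predictions at the tumour time points
  expect_equal(100 * monoclonal_fraction(wt, 13), 2.2, tolerance = 0.05)
  expect_equal(100 * monoclonal_fraction(wt, 17), 5.5, tolerance = 0.05)
  expect_equal(100 * monoclonal_fraction(wt, 19), 7.8, tolerance = 0.1)
})

test_that("a single stem cell is born fixed", {
  par <- drift_params(1, 0.5)
  expect_equal(unname(clone_size_pmf(par, 7)$probs), c(0, 1))
  expect_equal(monoclonal_fraction(par, c(0, 3, 100)), c(1, 1, 1))
})

test_that("predicted average clone size runs from the single-cell bin to 8", {
  par <- drift_params(5, 0.1)
  # at effective time zero the clone occupies (0, 1/5]: the binned
  # single-cell state, a pure function of N
  w <- grid_eighth_weights(5)[1, ]
  expect_equal(predicted_average_clone_size(par, 0), sum(w * (1:8)),
               tolerance = 1e-3)
  expect_equal(predicted_average_clone_size(par, 1e4), 8, tolerance = 1e-4)
  avg <- predicted_average_clone_size(par, seq(0, 100, 5))
  expect_true(all(avg >= 1 & avg <= 8))
  expect_true(all(diff(avg) >= -1e-10))
})
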