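#' Neutral-drift model parameters
#'
#' A clone founded by a single labelled stem cell in a crypt (or tumour gland)
#' of `n_stem` equipotent stem cells evolves by neutral drift: each stem cell
#' replaces a neighbour, or is itself replaced, at a daily rate `repl_rate`.
#' Clone size performs a symmetric continuous-time random walk on
#' `0, 1, ..., n_stem` with absorbing boundaries at 0 (extinction) and
#' `n_stem` (monoclonal conversion). `delay` is the lag, in days, between
#' inducer administration and heritable accrual of the label: no replacement
#' events are counted before it, so all dynamics run at effective time
#' `max(t - delay, 0)`.
#'
#' @param n_stem Number of functional stem cells per crypt (integer >= 1).
#' @param repl_rate Replacement rate per stem cell per day (> 0).
#' @param delay Label-accrual delay in days (>= 0).
#' @return An object of class `drift_params`.
#' @examples
#' drift_params(n_stem = 5, repl_rate = 0.1, delay = 2.45)
#' @export
drift_params <- function(n_stem, repl_rate, delay = 0) {
  if (length(n_stem) != 1L || !is.finite(n_stem) || n_stem < 1 ||
      n_stem != round(n_stem)) {
    stop("'n_stem' must be a single integer >= 1", call. = FALSE)
  }
  if (length(repl_rate) != 1L || !is.finite(repl_rate) || repl_rate <= 0) {
    stop("'repl_rate' must be a single positive number", call. = FALSE)
  }
  if (length(delay) != 1L || !is.finite(delay) || delay < 0) {
    stop("'delay' must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(n_stem = as.integer(n_stem), repl_rate = repl_rate, delay = delay),
    class = "drift_params"
  )
}

#' @export
print.drift_params <- function(x, ...) {
  cat(sprintf("Neutral-drift parameters: N = %d, lambda = %g /day, tau = %g d\n",
              x$n_stem, x$repl_rate, x$delay))
  invisible(x)
}

#' Wild-type baseline parameters for the proximal small intestine
#'
#' The reference neutral-drift behaviour used as the null model in the
#' tumour-proximity analyses: N = 5 stem cells, lambda = 0.1 replacements per
#' stem cell per day. The delay defaults to the technology-intrinsic
#' label-accrual delay [tau_glob()] inferred from control pulse-chase data.
#'
#' @param delay Label-accrual delay in days.
#' @return A `drift_params` object.
#' @export
wt_drift_params <- function(delay = tau_glob()) {
  drift_params(n_stem = 5L, repl_rate = 0.1, delay = delay)
}

#' Global label-accrual delay
#'
#' Point estimate of the delay between inducer administration and heritable
#' label accrual (days), inferred from control pulse-chase data and reused,
#' fixed, in all tumour-field analyses.
#'
#' @return 2.45 (days).
#' @export
tau_glob <- function() 2.45

# cache of per-N trigonometric constants and eighths weight matrices;
# keyed by as.character(N)
.drift_cache <- new.env(parent = emptyenv())

.theory_constants <- function(N) {
  key <- as.character(N)
  cached <- .drift_cache[[key]]
  if (!is.null(cached)) return(cached)
  if (N >= 2L) {
    k <- seq_len(N - 1L)
    kcos <- cos(k * pi / N)
    # interior modes: row k, column n; P_n(t) = e(t) %*% smat for n = 1..N-1
    smat <- (2 / N) * sin(k * pi / N) *
      outer(k, seq_len(N - 1L), function(k, n) sin(k * n * pi / N))
    coef0 <- (1 + kcos) / N                    # extinction flux weights
    coefN <- (-1)^(k + 1L) * (1 + kcos) / N    # fixation flux weights
  } else {
    kcos <- numeric(0); smat <- NULL; coef0 <- numeric(0); coefN <- numeric(0)
  }
  out <- list(kcos = kcos, smat = smat, coef0 = coef0, coefN = coefN,
              w8 = .eighth_weights(N))
  assign(key, out, envir = .drift_cache)
  out
}

# raw pmf over states 0..N at effective time t_eff (delay already removed)
.drift_pmf <- function(N, lam, t_eff) {
  if (N == 1L) return(c(0, 1))  # born fixed: both boundaries absorbing
  if (t_eff <= 0) return(c(0, 1, numeric(N - 1L)))
  cst <- .theory_constants(N)
  e <- exp(-2 * lam * (1 - cst$kcos) * t_eff)
  p_int <- drop(e %*% cst$smat)
  p0 <- sum(cst$coef0 * (1 - e))
  pN <- sum(cst$coefN * (1 - e))
  p <- c(p0, p_int, pN)
  # clip eigen-expansion round-off; anything larger signals a real defect
  s <- sum(p)
  if (abs(s - 1) > 1e-9) stop("clone-size pmf drifted from unit mass")
  pmax(p, 0) / s
}

#' Transition-rate generator of the clone-size random walk
#'
#' Builds the `(N+1) x (N+1)` infinitesimal generator of the clone-size chain
#' on states `0..N`. States 0 and N are absorbing; every transient state
#' `1 <= n <= N-1` jumps to `n-1` and to `n+1` each at rate `repl_rate`
#' (total exit rate `2 * repl_rate`), the convention under which the model
#' reproduces the wild-type monoclonal-conversion predictions.
#'
#' @param params A [drift_params()] object.
#' @return A square numeric matrix with dimnames `0..N`; rows sum to zero.
#' @export
rate_generator <- function(params) {
  stopifnot(inherits(params, "drift_params"))
  N <- params$n_stem
  lam <- params$repl_rate
  Q <- matrix(0, N + 1L, N + 1L, dimnames = list(0:N, 0:N))
  if (N >= 2L) {
    for (n in seq_len(N - 1L)) {
      i <- n + 1L
      Q[i, i - 1L] <- lam
      Q[i, i + 1L] <- lam
      Q[i, i] <- -2 * lam
    }
  }
  Q
}

#' Clone-size probability distribution under neutral drift
#'
#' Evaluates the closed-form solution of the master equation for the
#' absorbing random walk at chase time `t`, started from a single labelled
#' stem cell (`P_1 = 1` at effective time zero). The solution is the
#' eigen-expansion of the tridiagonal generator: for transient sizes
#' `1 <= n <= N-1`,
#' `P_n(t) = (2/N) * sum_k sin(k pi / N) sin(k n pi / N) exp(-mu_k t_eff)`
#' with relaxation rates `mu_k = 2 lambda (1 - cos(k pi / N))`, and the
#' absorbed masses at 0 and N follow by analytic integration of the boundary
#' fluxes. The label-accrual delay enters as `t_eff = max(t - delay, 0)`.
#'
#' @param params A [drift_params()] object.
#' @param t Chase time in days (>= 0).
#' @return A `clone_size_distribution`: list with `probs` (named vector over
#'   sizes `0..N`), `time`, `params` and the `conditioned` flag (`FALSE`).
#' @export
clone_size_pmf <- function(params, t) {
  stopifnot(inherits(params, "drift_params"))
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("'t' must be a single non-negative time in days", call. = FALSE)
  }
  p <- .drift_pmf(params$n_stem, params$repl_rate, t - params$delay)
  names(p) <- 0:params$n_stem
  structure(
    list(probs = p, time = t, params = params, conditioned = FALSE),
    class = "clone_size_distribution"
  )
}

#' @export
print.clone_size_distribution <- function(x, ...) {
  cat(sprintf("Clone-size distribution at t = %g d (N = %d%s)\n", x$time,
              x$params$n_stem,
              if (x$conditioned) ", survival-conditioned" else ""))
  print(round(x$probs, 4))
  invisible(x)
}

#' Condition a clone-size distribution on survival
#'
#' All scored clones are surviving clones, so the raw distribution is
#' rescaled to `P'_n = P_n / (1 - P_0)` for `n > 0`, with zero mass at
#' extinction.
#'
#' @param dist A `clone_size_distribution` from [clone_size_pmf()].
#' @return The survival-conditioned `clone_size_distribution`.
#' @export
condition_on_survival <- function(dist) {
  stopifnot(inherits(dist, "clone_size_distribution"))
  if (dist$conditioned) return(dist)
  p0 <- dist$probs[[1L]]
  if (p0 >= 1 - 1e-12) {
    stop("all clones extinct: cannot condition on survival", call. = FALSE)
  }
  p <- dist$probs / (1 - p0)
  p[1L] <- 0
  dist$probs <- p / sum(p)
  dist$conditioned <- TRUE
  dist
}

# Interval-overlap weights mapping discrete sizes 1..N to eighths 1..8.
# Size n < N occupies the crypt fraction ((n-1)/N, n/N]; its mass is spread
# over eighths by interval overlap restricted to bins 1..7 (renormalised),
# while the fixed size n = N maps entirely to bin 8 so monoclonals keep
# their identity. Returns an N x 8 matrix with unit row sums.
.eighth_weights <- function(N) {
  W <- matrix(0, N, 8L)
  lo8 <- (0:7) / 8
  hi8 <- (1:8) / 8
  for (n in seq_len(N)) {
    if (n == N) {
      W[n, 8L] <- 1
      next
    }
    lo <- (n - 1) / N
    hi <- n / N
    ov <- pmax(0, pmin(hi, hi8) - pmax(lo, lo8))
    ov[8L] <- 0  # bin 8 is reserved for monoclonals
    if (sum(ov) <= 0) {
      # interval entirely inside (7/8, 1): partial clone scored as 7/8
      W[n, 7L] <- 1
    } else {
      W[n, ] <- ov / sum(ov)
    }
  }
  W
}

#' Redistribute a survival-conditioned distribution into eighths
#'
#' Clone sizes are scored as the fraction of the crypt or gland circumference
#' occupied, in eighths. The theoretical mass of discrete size `n` (out of
#' `N`) is spread over eighth-bins by symmetric interval overlap of
#' `((n-1)/N, n/N]` against `((b-1)/8, b/8]`, except that the symmetry is
#' broken for the fixed state: all mass at `n = N` is assigned to bin 8 and
#' bin 8 receives nothing else, so the monoclonal identity is preserved.
#' Non-monoclonal overlaps are renormalised over bins 1..7.
#'
#' @param dist A survival-conditioned `clone_size_distribution`.
#' @return A `binned_distribution`: list with `bin_probs` (length 8),
#'   `time` and `params`.
#' @export
bin_to_eighths <- function(dist) {
  stopifnot(inherits(dist, "clone_size_distribution"))
  if (!dist$conditioned) {
    stop("bin_to_eighths() requires a survival-conditioned distribution",
         call. = FALSE)
  }
  N <- dist$params$n_stem
  W <- .theory_constants(N)$w8
  bp <- drop(dist$probs[-1L] %*% W)
  names(bp) <- 1:8
  structure(
    list(bin_probs = bp, time = dist$time, params = dist$params),
    class = "binned_distribution"
  )
}

#' @export
print.binned_distribution <- function(x, ...) {
  cat(sprintf("Eighths-binned clone-size distribution at t = %g d (N = %d)\n",
              x$time, x$params$n_stem))
  print(round(x$bin_probs, 4))
  invisible(x)
}

# hot path for the likelihood: eighths probabilities without S3 plumbing
.eighth_probs <- function(N, lam, tau, t) {
  p <- .drift_pmf(N, lam, t - tau)
  q <- p[-1L] / (1 - p[1L])
  drop(q %*% .theory_constants(N)$w8)
}

#' Predicted fraction of surviving clones that are monoclonal
#'
#' The survival-conditioned probability that a clone has monoclonally
#' converged (occupies the whole crypt, size `N`) by chase time `t`.
#'
#' @param params A [drift_params()] object.
#' @param t Chase time in days.
#' @return A probability in `[0, 1]`; vectorised over `t`.
#' @examples
#' # wild-type small-intestine predictions at the tumour-study time points
#' round(100 * monoclonal_fraction(wt_drift_params(), c(13, 17, 19)), 1)
#' @export
monoclonal_fraction <- function(params, t) {
  stopifnot(inherits(params, "drift_params"))
  vapply(t, function(ti) {
    d <- condition_on_survival(clone_size_pmf(params, ti))
    unname(d$probs[[params$n_stem + 1L]])
  }, numeric(1))
}

#' Predicted average clone size in eighths
#'
#' Expectation of the eighth-bin index under the survival-conditioned,
#' eighths-binned clone-size distribution: the model curve drawn through
#' average scored clone sizes over the chase.
#'
#' @param params A [drift_params()] object.
#' @param t Chase time in days; vectorised.
#' @return Average clone size in eighths, in `[1, 8]`.
#' @export
predicted_average_clone_size <- function(params, t) {
  stopifnot(inherits(params, "drift_params"))
  vapply(t, function(ti) {
    b <- bin_to_eighths(condition_on_survival(clone_size_pmf(params, ti)))
    sum(b$bin_probs * (1:8))
  }, numeric(1))
}
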