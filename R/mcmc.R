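#' Eighths-binned clone counts
#'
#' Count vectors of scored clone sizes (in eighths, 1..8) at one or more
#' chase time points: the data object the multinomial likelihood is
#' evaluated on.
#'
#' @param times Numeric vector of chase times in days.
#' @param counts Integer matrix, one row per time point, 8 columns (eighths
#'   1..8); a single time point may be given as a vector of length 8.
#' @return A `clone_counts` object.
#' @export
clone_counts <- function(times, counts) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1L)
  counts <- as.matrix(counts)
  if (ncol(counts) != 8L) stop("'counts' must have 8 columns", call. = FALSE)
  if (nrow(counts) != length(times)) {
    stop("one row of counts per time point required", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0)) {
    stop("every included time point needs at least one clone", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(times, 1:8)
  structure(list(times = as.numeric(times), counts = counts),
            class = "clone_counts")
}

#' Tabulate clone records into eighths-binned counts
#'
#' @param records A clone-record `data.frame` with columns `time_days` and
#'   `size_eighths` (see [read_clone_table()]).
#' @return A [clone_counts()] object with one row per distinct time.
#' @export
as_clone_counts <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("no clone records", call. = FALSE)
  times <- sort(unique(records$time_days))
  m <- t(vapply(times, function(t) {
    tabulate(records$size_eighths[records$time_days == t], nbins = 8L)
  }, numeric(8)))
  clone_counts(times, m)
}

#' @export
print.clone_counts <- function(x, ...) {
  cat("Eighths-binned clone counts:\n")
  print(x$counts)
  invisible(x)
}

#' Uninformative prior specification
#'
#' Independent uninformative priors for the drift parameters: discrete
#' uniform for the stem-cell number over `n_min..n_max`, uniform for the
#' replacement rate on `(0, rate_max]`, and uniform for the delay on
#' `[0, delay_max)`. `delay_max` defaults, at fit time, to the earliest
#' observation time so that every time point retains a positive effective
#' chase time.
#'
#' @param n_min,n_max Support of the stem-cell number prior.
#' @param rate_max Upper bound of the replacement-rate prior (per day).
#' @param delay_max Upper bound of the delay prior (days); `NULL` means the
#'   earliest observed time point.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(n_min = 2L, n_max = 15L, rate_max = 1,
                       delay_max = NULL) {
  if (n_min < 1L || n_max < n_min) stop("empty N prior support", call. = FALSE)
  if (rate_max <= 0) stop("'rate_max' must be positive", call. = FALSE)
  if (!is.null(delay_max) && delay_max <= 0) {
    stop("'delay_max' must be positive", call. = FALSE)
  }
  structure(list(n_min = as.integer(n_min), n_max = as.integer(n_max),
                 rate_max = rate_max, delay_max = delay_max),
            class = "prior_spec")
}

#' MCMC sampler configuration
#'
#' Defaults follow the inference protocol used throughout: 40,000 iterations
#' on two parallel chains, burn-in 5,000, thinned by a factor of 20.
#' Proposal scales are adapted during burn-in only (towards an acceptance
#' rate between 0.2 and 0.5) and frozen afterwards.
#'
#' @param iterations Iterations per chain.
#' @param chains Number of independent chains.
#' @param burn_in Burn-in iterations discarded per chain.
#' @param thin Thinning factor applied after burn-in.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param prop_rate,prop_delay Initial Gaussian random-walk proposal
#'   standard deviations for the rate and the delay.
#' @return An `mcmc_config` object.
#' @export
mcmc_config <- function(iterations = 40000L, chains = 2L, burn_in = 5000L,
                        thin = 20L, seed = 1L, prop_rate = 0.02,
                        prop_delay = 0.5) {
  if (burn_in >= iterations) stop("'burn_in' must be < 'iterations'",
                                  call. = FALSE)
  if (thin < 1L) stop("'thin' must be >= 1", call. = FALSE)
  if (chains < 1L) stop("'chains' must be >= 1", call. = FALSE)
  structure(list(iterations = as.integer(iterations),
                 chains = as.integer(chains),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), prop_rate = prop_rate,
                 prop_delay = prop_delay),
            class = "mcmc_config")
}

#' Multinomial log-likelihood of clone counts under neutral drift
#'
#' At each time point the observed count vector over eighths is multinomial
#' with the model's survival-conditioned, eighths-binned probabilities as
#' case probabilities; time points are independent, so the total
#' log-likelihood is the sum. Returns `-Inf` when a positive count sits on a
#' zero-probability bin.
#'
#' @param counts A [clone_counts()] object.
#' @param params A [drift_params()] object.
#' @return The log-likelihood (a single number).
#' @export
multinomial_loglik <- function(counts, params) {
  stopifnot(inherits(counts, "clone_counts"),
            inherits(params, "drift_params"))
  ll <- 0
  for (i in seq_along(counts$times)) {
    p <- .eighth_probs(params$n_stem, params$repl_rate, params$delay,
                       counts$times[i])
    x <- counts$counts[i, ]
    pos <- x > 0L
    if (any(p[pos] == 0)) return(-Inf)
    ll <- ll + lgamma(sum(x) + 1) - sum(lgamma(x + 1)) +
      sum(x[pos] * log(p[pos]))
  }
  ll
}

# log prior density; -Inf outside support
.log_prior <- function(n_stem, repl_rate, delay, priors, delay_max) {
  if (n_stem < priors$n_min || n_stem > priors$n_max ||
      repl_rate <= 0 || repl_rate > priors$rate_max ||
      delay < 0 || delay >= delay_max) {
    return(-Inf)
  }
  -log(priors$n_max - priors$n_min + 1) - log(priors$rate_max) -
    log(delay_max)
}

#' Log posterior density of the drift parameters
#'
#' Multinomial log-likelihood plus log prior density; `-Inf` outside the
#' prior support. With `counts = NULL` the likelihood term is zero, so the
#' posterior reduces to the prior (useful for sampler validation).
#'
#' @param counts A [clone_counts()] object, or `NULL`.
#' @param params A [drift_params()] object.
#' @param priors A [prior_spec()].
#' @return The unnormalised log posterior density.
#' @export
log_posterior <- function(counts, params, priors = prior_spec()) {
  stopifnot(inherits(params, "drift_params"), inherits(priors, "prior_spec"))
  delay_max <- .resolve_delay_max(priors, counts)
  lp <- .log_prior(params$n_stem, params$repl_rate, params$delay,
                   priors, delay_max)
  if (!is.finite(lp)) return(-Inf)
  if (is.null(counts)) return(lp)
  lp + multinomial_loglik(counts, params)
}

.resolve_delay_max <- function(priors, counts) {
  if (!is.null(priors$delay_max)) return(priors$delay_max)
  if (is.null(counts)) return(4)  # prior-only runs need a finite support
  min(counts$times)
}

#' Fit the neutral-drift model by Markov chain Monte Carlo
#'
#' Metropolis-within-Gibbs sampling of the posterior of `(N, lambda, tau)`
#' given eighths-binned clone counts: Gaussian random-walk proposals for the
#' replacement rate and the delay, a +-1 discrete random walk for the
#' stem-cell number. Any subset of parameters can be held fixed (e.g. the
#' rate-only fits used near tumours fix `n_stem` and `delay`). Proposal
#' scales adapt during burn-in only. With `counts = NULL` the sampler
#' targets the prior.
#'
#' @param counts A [clone_counts()] object, or `NULL` to sample the prior.
#' @param priors A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param fixed Named list fixing a subset of `n_stem`, `repl_rate`,
#'   `delay` at given values.
#' @return A `posterior_draws` object: `data.frame` with columns `chain`,
#'   `iteration`, `n_stem`, `repl_rate`, `delay`, `log_post`, carrying
#'   acceptance rates and the configuration as attributes.
#' @export
run_mcmc <- function(counts, priors = prior_spec(), config = mcmc_config(),
                     fixed = list()) {
  stopifnot(inherits(priors, "prior_spec"), inherits(config, "mcmc_config"))
  if (!is.null(counts)) stopifnot(inherits(counts, "clone_counts"))
  par_names <- c("n_stem", "repl_rate", "delay")
  if (length(fixed) && !all(names(fixed) %in% par_names)) {
    stop("'fixed' may only name n_stem, repl_rate, delay", call. = FALSE)
  }
  free <- setdiff(par_names, names(fixed))
  if (length(free) == 0L) {
    stop("all parameters fixed: nothing to sample", call. = FALSE)
  }
  delay_max <- .resolve_delay_max(priors, counts)

  log_post <- function(n, lam, tau) {
    lp <- .log_prior(n, lam, tau, priors, delay_max)
    if (!is.finite(lp) || is.null(counts)) return(lp)
    ll <- 0
    for (i in seq_along(counts$times)) {
      p <- .eighth_probs(n, lam, tau, counts$times[i])
      x <- counts$counts[i, ]
      pos <- x > 0L
      if (any(p[pos] == 0)) return(-Inf)
      ll <- ll + sum(x[pos] * log(p[pos]))
    }
    lp + ll  # multinomial coefficients are parameter-free
  }

  draw_init <- function() {
    n <- if ("n_stem" %in% names(fixed)) fixed$n_stem else
      sample(priors$n_min:priors$n_max, 1L)
    lam <- if ("repl_rate" %in% names(fixed)) fixed$repl_rate else
      stats::runif(1, 0, priors$rate_max)
    tau <- if ("delay" %in% names(fixed)) fixed$delay else
      stats::runif(1, 0, delay_max)
    c(n = n, lam = lam, tau = tau)
  }

  keep_iter <- seq.int(config$burn_in + config$thin, config$iterations,
                       by = config$thin)
  all_draws <- vector("list", config$chains)
  acc <- matrix(0, config$chains, 3L,
                dimnames = list(NULL, par_names))
  prop <- matrix(0, config$chains, 3L, dimnames = list(NULL, par_names))

  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + ch - 1L)
    init <- draw_init()
    lp <- log_post(init["n"], init["lam"], init["tau"])
    tries <- 0L
    while (!is.finite(lp)) {
      tries <- tries + 1L
      if (tries > 100L) stop("could not find a finite starting point",
                             call. = FALSE)
      init <- draw_init()
      lp <- log_post(init["n"], init["lam"], init["tau"])
    }
    n <- init[["n"]]; lam <- init[["lam"]]; tau <- init[["tau"]]
    s_rate <- config$prop_rate
    s_delay <- config$prop_delay
    # burn-in adaptation bookkeeping
    win_acc <- c(n_stem = 0, repl_rate = 0, delay = 0)
    win_try <- win_acc
    out <- matrix(NA_real_, length(keep_iter), 4L)
    kept <- 0L
    for (it in seq_len(config$iterations)) {
      if ("n_stem" %in% free) {
        n2 <- n + sample(c(-1L, 1L), 1L)
        prop[ch, 1L] <- prop[ch, 1L] + 1
        win_try[1L] <- win_try[1L] + 1
        if ("repl_rate" %in% free) {
          # ridge move: the binned distribution is near-invariant along
          # lambda ~ N^2 (absorption time scales as N^2 / lambda), so a
          # +-1 step in N rescales lambda quadratically with a log-normal
          # jitter; the asymmetric proposal needs the lam2/lam Hastings
          # correction
          lam2 <- lam * (n2 / n)^2 * exp(stats::rnorm(1, 0, 0.05))
          lp2 <- log_post(n2, lam2, tau)
          if (is.finite(lp2) &&
              log(stats::runif(1)) < lp2 - lp + log(lam2 / lam)) {
            n <- n2; lam <- lam2; lp <- lp2
            acc[ch, 1L] <- acc[ch, 1L] + 1; win_acc[1L] <- win_acc[1L] + 1
          }
        } else {
          lp2 <- log_post(n2, lam, tau)
          if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp) {
            n <- n2; lp <- lp2
            acc[ch, 1L] <- acc[ch, 1L] + 1; win_acc[1L] <- win_acc[1L] + 1
          }
        }
      }
      if ("repl_rate" %in% free) {
        lam2 <- lam + stats::rnorm(1, 0, s_rate)
        lp2 <- log_post(n, lam2, tau)
        prop[ch, 2L] <- prop[ch, 2L] + 1
        win_try[2L] <- win_try[2L] + 1
        if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp) {
          lam <- lam2; lp <- lp2
          acc[ch, 2L] <- acc[ch, 2L] + 1; win_acc[2L] <- win_acc[2L] + 1
        }
      }
      if ("delay" %in% free) {
        tau2 <- tau + stats::rnorm(1, 0, s_delay)
        lp2 <- log_post(n, lam, tau2)
        prop[ch, 3L] <- prop[ch, 3L] + 1
        win_try[3L] <- win_try[3L] + 1
        if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp) {
          tau <- tau2; lp <- lp2
          acc[ch, 3L] <- acc[ch, 3L] + 1; win_acc[3L] <- win_acc[3L] + 1
        }
      }
      if (it <= config$burn_in && it %% 200L == 0L) {
        if (win_try[2L] > 0) {
          r <- win_acc[2L] / win_try[2L]
          if (r < 0.2) s_rate <- s_rate * 0.7
          if (r > 0.5) s_rate <- s_rate * 1.4
        }
        if (win_try[3L] > 0) {
          r <- win_acc[3L] / win_try[3L]
          if (r < 0.2) s_delay <- s_delay * 0.7
          if (r > 0.5) s_delay <- s_delay * 1.4
        }
        win_acc[] <- 0; win_try[] <- 0
      }
      if (it > config$burn_in &&
          (it - config$burn_in) %% config$thin == 0L) {
        kept <- kept + 1L
        out[kept, ] <- c(n, lam, tau, lp)
      }
    }
    all_draws[[ch]] <- data.frame(
      chain = ch, iteration = keep_iter,
      n_stem = as.integer(out[, 1L]), repl_rate = out[, 2L],
      delay = out[, 3L], log_post = out[, 4L]
    )
  }
  draws <- do.call(rbind, all_draws)
  structure(draws,
            class = c("posterior_draws", "data.frame"),
            acceptance = ifelse(prop > 0, acc / prop, NA_real_),
            config = config, priors = priors, fixed = fixed)
}

# split-chain potential-scale-reduction diagnostic for one parameter
.split_rhat <- function(x, chain) {
  halves <- unlist(lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2L
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(v) v[seq_len(n)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarise posterior draws
#'
#' Pooled posterior summaries in the form the analyses quote: the posterior
#' mode for the discrete stem-cell number, medians and equal-tailed 80% and
#' 95% credible intervals for the continuous parameters, per-parameter
#' acceptance rates, and a split-chain convergence diagnostic.
#'
#' @param object A `posterior_draws` object from [run_mcmc()].
#' @param ... Unused.
#' @return A `drift_fit_summary` list with components `n_stem_mode`,
#'   `table` (one row per parameter: median, ci80/ci95 bounds, rhat) and
#'   `acceptance`.
#' @export
summary.posterior_draws <- function(object, ...) {
  if (nrow(object) == 0L) stop("empty posterior draws", call. = FALSE)
  qs <- function(x) stats::quantile(x, c(0.025, 0.1, 0.5, 0.9, 0.975),
                                    names = FALSE, type = 7)
  pars <- c("n_stem", "repl_rate", "delay")
  tab <- do.call(rbind, lapply(pars, function(p) {
    x <- object[[p]]
    q <- qs(x)
    data.frame(parameter = p, median = q[3L],
               ci80_lo = q[2L], ci80_hi = q[4L],
               ci95_lo = q[1L], ci95_hi = q[5L],
               rhat = if (stats::var(x) > 0)
                 .split_rhat(x, object$chain) else NA_real_)
  }))
  rownames(tab) <- NULL
  tb <- table(object$n_stem)
  structure(
    list(n_stem_mode = as.integer(names(tb)[which.max(tb)]),
         table = tab,
         acceptance = attr(object, "acceptance"),
         n_draws = nrow(object)),
    class = "drift_fit_summary"
  )
}

#' @export
print.drift_fit_summary <- function(x, ...) {
  cat(sprintf("Posterior summary (%d pooled draws)\n", x$n_draws))
  cat(sprintf("  stem-cell number: posterior mode N = %d\n", x$n_stem_mode))
  print(transform(x$table,
                  median = signif(median, 4),
                  ci80_lo = signif(ci80_lo, 4), ci80_hi = signif(ci80_hi, 4),
                  ci95_lo = signif(ci95_lo, 4), ci95_hi = signif(ci95_hi, 4),
                  rhat = round(rhat, 3)))
  invisible(x)
}
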