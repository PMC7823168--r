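#' Pulse-chase sampling schedule
#'
#' Times post induction at which clones are scored and the number of
#' surviving clones scored at each. Defaults reproduce the control
#' small-intestine pulse-chase design: 692, 595, 592, 457 and 302 clones at
#' 4, 7, 10, 14 and 21 days.
#'
#' @param time_points Strictly increasing chase times in days.
#' @param clones_per_time Positive integer count of surviving clones scored
#'   at each time point.
#' @return A `simulation_schedule` object.
#' @export
simulation_schedule <- function(time_points = c(4, 7, 10, 14, 21),
                                clones_per_time = c(692, 595, 592, 457, 302)) {
  if (length(time_points) != length(clones_per_time)) {
    stop("'time_points' and 'clones_per_time' must have equal length",
         call. = FALSE)
  }
  if (length(time_points) == 0L || any(!is.finite(time_points)) ||
      any(diff(time_points) <= 0)) {
    stop("'time_points' must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(clones_per_time)) || any(clones_per_time < 1) ||
      any(clones_per_time != round(clones_per_time))) {
    stop("'clones_per_time' must be positive integers", call. = FALSE)
  }
  structure(
    list(time_points = as.numeric(time_points),
         clones_per_time = as.integer(clones_per_time)),
    class = "simulation_schedule"
  )
}

# exact event-driven simulation of the absorbing walk: vectorised over
# clones; each transient clone waits Exp(2*lambda) then steps +-1 with
# probability 1/2 until absorbed at 0 or N or the clock runs out
.sim_walk <- function(N, lam, t_eff, n, start = 1L) {
  state <- rep.int(as.integer(start), n)
  if (N == 1L || t_eff <= 0) return(state)
  left <- rep.int(as.numeric(t_eff), n)
  active <- which(state > 0L & state < N)
  while (length(active)) {
    dt <- stats::rexp(length(active), rate = 2 * lam)
    left[active] <- left[active] - dt
    hit <- left[active] > 0
    moved <- active[hit]
    if (length(moved)) {
      state[moved] <- state[moved] +
        sample(c(-1L, 1L), length(moved), replace = TRUE)
    }
    active <- moved[state[moved] > 0L & state[moved] < N]
  }
  state
}

#' Simulate clone sizes under neutral drift
#'
#' Draws exact samples of the clone-size random walk at chase time `t`,
#' started from a single labelled stem cell. Simulation is event-driven:
#' a transient clone of size `n` waits an exponential time with total rate
#' `2 * repl_rate`, then grows or shrinks by one cell with equal
#' probability; sizes 0 and `n_stem` are absorbing. No events occur before
#' the label-accrual delay.
#'
#' @param params A [drift_params()] object.
#' @param t Chase time in days.
#' @param n Number of independent clones to simulate.
#' @return Integer vector of clone sizes in `0..n_stem` (0 = extinct).
#' @export
simulate_clone_sizes <- function(params, t, n = 1L) {
  stopifnot(inherits(params, "drift_params"))
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("'t' must be a single non-negative time in days", call. = FALSE)
  }
  .sim_walk(params$n_stem, params$repl_rate, t - params$delay, n)
}

# score a discrete size n (of N) as an eighth: monoclonals are eighth 8,
# partial clones sample an eighth proportional to interval overlap, the
# stochastic counterpart of the deterministic redistribution in
# bin_to_eighths()
.score_eighths <- function(sizes, N) {
  W <- .theory_constants(N)$w8
  out <- integer(length(sizes))
  for (n in unique(sizes)) {
    idx <- sizes == n
    w <- W[n, ]
    if (w[8L] == 1) {
      out[idx] <- 8L
    } else {
      out[idx] <- sample.int(8L, sum(idx), replace = TRUE, prob = w)
    }
  }
  out
}

#' Simulate an eighths-scored pulse-chase count dataset
#'
#' At each scheduled time point, surviving clones are accumulated until the
#' requested total is reached (extinct draws are discarded and redrawn, as
#' extinct clones are invisible in scored tissue), and each clone's discrete
#' size is scored as an eighth of the crypt circumference.
#'
#' @param params A [drift_params()] object.
#' @param schedule A [simulation_schedule()].
#' @return A [clone_counts()] object; attribute `extinct_draws` records how
#'   many extinct clones were discarded per time point.
#' @export
simulate_count_dataset <- function(params, schedule = simulation_schedule()) {
  stopifnot(inherits(params, "drift_params"),
            inherits(schedule, "simulation_schedule"))
  if (params$n_stem > 1L && any(schedule$time_points <= params$delay)) {
    warning("time points at or before the label-accrual delay: ",
            "all clones there are single cells", call. = FALSE)
  }
  K <- length(schedule$time_points)
  counts <- matrix(0L, K, 8L,
                   dimnames = list(schedule$time_points, 1:8))
  extinct <- integer(K)
  for (i in seq_len(K)) {
    need <- schedule$clones_per_time[i]
    sizes <- integer(0)
    while (length(sizes) < need) {
      draw <- simulate_clone_sizes(params, schedule$time_points[i],
                                   n = max(need - length(sizes), 32L))
      extinct[i] <- extinct[i] + sum(draw == 0L)
      sizes <- c(sizes, draw[draw > 0L])
    }
    sizes <- sizes[seq_len(need)]
    eighths <- .score_eighths(sizes, params$n_stem)
    counts[i, ] <- tabulate(eighths, nbins = 8L)
  }
  out <- clone_counts(schedule$time_points, counts)
  attr(out, "extinct_draws") <- extinct
  out
}

#' Simulate wild-type null count datasets
#'
#' Draws replicate count datasets from the theoretical multinomial model:
#' for each time point, counts over eighths are multinomial with the
#' wild-type eighths probabilities and a total equal to that time point's
#' share of the composition, so every replicate preserves the per-time
#' composition of the observed data.
#'
#' @param wt_params Wild-type [drift_params()].
#' @param composition A [clone_counts()] object, or a named numeric vector of
#'   per-time clone totals (names are times in days).
#' @param n_sims Number of replicate datasets (default 1000).
#' @return A list of `n_sims` count matrices (times x eighths).
#' @export
simulate_wt_null_counts <- function(wt_params, composition, n_sims = 1000L) {
  stopifnot(inherits(wt_params, "drift_params"))
  if (inherits(composition, "clone_counts")) {
    times <- composition$times
    totals <- rowSums(composition$counts)
  } else {
    if (is.null(names(composition))) {
      stop("'composition' must be clone_counts or a named per-time vector",
           call. = FALSE)
    }
    times <- as.numeric(names(composition))
    totals <- as.numeric(composition)
  }
  probs <- lapply(times, function(t) {
    .eighth_probs(wt_params$n_stem, wt_params$repl_rate, wt_params$delay, t)
  })
  lapply(seq_len(n_sims), function(s) {
    m <- t(vapply(seq_along(times), function(i) {
      drop(stats::rmultinom(1L, size = totals[i], prob = probs[[i]]))
    }, numeric(8)))
    dimnames(m) <- list(times, 1:8)
    m
  })
}

#' Tumour-field scenario for synthetic clone tables
#'
#' Parameters of the synthetic spatial dataset emulating lineage tracing in
#' tumour-bearing intestine: disc-shaped tumours, clones in adjacent tissue
#' whose replacement rate depends on distance from the tumour edge
#' (`lambda_near` within `cutoff_cd` crypt diameters, `lambda_far` beyond),
#' and intra-tumour glands following a two-component mixture in which a
#' fraction `intra_monoclonal_excess` of glands is monoclonally converted
#' and the remainder drifts at the accelerated rate `lambda_intra`.
#'
#' Defaults mirror the tumour study: inference on tumour-adjacent crypts
#' gave lambda = 0.07 within 7 crypt diameters of the tumour edge and 0.09
#' beyond, against the wild-type baseline N = 5, lambda = 0.1; sampling at
#' 13, 17 and 19 days post induction.
#'
#' @param n_tumours Number of tumours.
#' @param tumour_radius_cd Mean tumour radius in crypt diameters.
#' @param lambda_near,lambda_far Replacement rates (per day) for adjacent
#'   crypts nearer/farther than `cutoff_cd` from the tumour edge.
#' @param cutoff_cd Distance cutoff in crypt diameters.
#' @param intra_monoclonal_excess Fraction of intra-tumour glands forced
#'   monoclonal, in `[0, 1]`.
#' @param lambda_intra Accelerated drift rate for the remaining intra-tumour
#'   glands.
#' @param n_stem Stem cells per crypt/gland.
#' @param delay Label-accrual delay in days.
#' @param sampling_times Chase times in days.
#' @param adjacent_per_time,intra_per_time Clones generated per time point in
#'   the adjacent and intra-tumour compartments (defaults match the scored
#'   totals 130/71/64 outside and 273/81/86 inside tumours).
#' @param max_dist_cd Maximum distance from tumour edge for adjacent clones.
#' @param crypt_diameter_um Microns per crypt diameter (default 65).
#' @return A `tumour_field_scenario` object.
#' @export
tumour_field_scenario <- function(n_tumours = 25L,
                                  tumour_radius_cd = 5,
                                  lambda_near = 0.07,
                                  lambda_far = 0.09,
                                  cutoff_cd = 7,
                                  intra_monoclonal_excess = 0.19,
                                  lambda_intra = 0.15,
                                  n_stem = 5L,
                                  delay = tau_glob(),
                                  sampling_times = c(13, 17, 19),
                                  adjacent_per_time = c(130L, 71L, 64L),
                                  intra_per_time = c(273L, 81L, 86L),
                                  max_dist_cd = 20,
                                  crypt_diameter_um = 65) {
  if (lambda_near <= 0 || lambda_far <= 0 || lambda_intra <= 0) {
    stop("replacement rates must be positive", call. = FALSE)
  }
  if (cutoff_cd <= 0 || tumour_radius_cd <= 0 || max_dist_cd <= cutoff_cd) {
    stop("invalid tumour geometry", call. = FALSE)
  }
  if (intra_monoclonal_excess < 0 || intra_monoclonal_excess > 1) {
    stop("'intra_monoclonal_excess' must be in [0, 1]", call. = FALSE)
  }
  if (length(adjacent_per_time) != length(sampling_times) ||
      length(intra_per_time) != length(sampling_times)) {
    stop("per-time clone counts must match 'sampling_times'", call. = FALSE)
  }
  structure(
    list(n_tumours = as.integer(n_tumours),
         tumour_radius_cd = tumour_radius_cd,
         lambda_near = lambda_near, lambda_far = lambda_far,
         cutoff_cd = cutoff_cd,
         intra_monoclonal_excess = intra_monoclonal_excess,
         lambda_intra = lambda_intra,
         n_stem = as.integer(n_stem), delay = delay,
         sampling_times = as.numeric(sampling_times),
         adjacent_per_time = as.integer(adjacent_per_time),
         intra_per_time = as.integer(intra_per_time),
         max_dist_cd = max_dist_cd,
         crypt_diameter_um = crypt_diameter_um),
    class = "tumour_field_scenario"
  )
}

# surviving scored eighths for n clones at rate lam (redraw extinct)
.surviving_eighths <- function(N, lam, tau, t, n) {
  sizes <- integer(0)
  par <- drift_params(N, lam, tau)
  while (length(sizes) < n) {
    draw <- simulate_clone_sizes(par, t, n = max(n - length(sizes), 32L))
    sizes <- c(sizes, draw[draw > 0L])
  }
  .score_eighths(sizes[seq_len(n)], N)
}

#' Generate a synthetic tumour-field clone table
#'
#' Emits one row per traced clone, with the spatial metadata recorded in the
#' tumour analyses: tumour id, distance of intra-tumour clones to the tumour
#' centre, distance of adjacent clones to the tumour edge (in crypt
#' diameters), tumour area and crypt diameter. Adjacent clones are placed
#' uniformly in an annulus around a disc-shaped tumour and drift at
#' `lambda_near` or `lambda_far` according to the distance cutoff;
#' intra-tumour glands follow the monoclonal-excess mixture.
#'
#' @param scenario A [tumour_field_scenario()].
#' @param seed Optional integer seed for reproducibility.
#' @return A `data.frame` of clone records (see [read_clone_table()] for the
#'   column schema).
#' @export
generate_tumour_field <- function(scenario = tumour_field_scenario(),
                                  seed = NULL) {
  stopifnot(inherits(scenario, "tumour_field_scenario"))
  if (!is.null(seed)) set.seed(seed)
  sc <- scenario
  radius_um <- sc$tumour_radius_cd * sc$crypt_diameter_um
  # per-tumour radii jittered +-20% around the scenario mean
  tum_radius <- radius_um * stats::runif(sc$n_tumours, 0.8, 1.2)
  rows <- list()
  id <- 0L
  for (i in seq_along(sc$sampling_times)) {
    t <- sc$sampling_times[i]
    # adjacent compartment: uniform annulus placement, rate set by distance
    n_adj <- sc$adjacent_per_time[i]
    dist_cd <- stats::runif(n_adj, 0, sc$max_dist_cd)
    near <- dist_cd < sc$cutoff_cd
    eighth <- integer(n_adj)
    if (any(near)) {
      eighth[near] <- .surviving_eighths(sc$n_stem, sc$lambda_near,
                                         sc$delay, t, sum(near))
    }
    if (any(!near)) {
      eighth[!near] <- .surviving_eighths(sc$n_stem, sc$lambda_far,
                                          sc$delay, t, sum(!near))
    }
    tum <- sample.int(sc$n_tumours, n_adj, replace = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      clone_id = sprintf("c%05d", id + seq_len(n_adj)),
      mouse_id = sprintf("m%d", (tum - 1L) %/% 7L + 1L),
      time_days = t,
      size_eighths = eighth,
      compartment = "adjacent",
      tumour_id = sprintf("t%03d", tum),
      dist_centre_um = NA_real_,
      dist_edge_cd = dist_cd,
      tumour_area_um2 = pi * tum_radius[tum]^2,
      crypt_diameter_um = sc$crypt_diameter_um,
      stringsAsFactors = FALSE
    )
    id <- id + n_adj
    # intra-tumour compartment: monoclonal-excess mixture
    n_int <- sc$intra_per_time[i]
    forced <- stats::runif(n_int) < sc$intra_monoclonal_excess
    eighth <- integer(n_int)
    eighth[forced] <- 8L
    if (any(!forced)) {
      eighth[!forced] <- .surviving_eighths(sc$n_stem, sc$lambda_intra,
                                            sc$delay, t, sum(!forced))
    }
    tum <- sample.int(sc$n_tumours, n_int, replace = TRUE)
    r_frac <- sqrt(stats::runif(n_int))  # uniform over the disc
    rows[[length(rows) + 1L]] <- data.frame(
      clone_id = sprintf("c%05d", id + seq_len(n_int)),
      mouse_id = sprintf("m%d", (tum - 1L) %/% 7L + 1L),
      time_days = t,
      size_eighths = eighth,
      compartment = "intra_tumour",
      tumour_id = sprintf("t%03d", tum),
      dist_centre_um = r_frac * tum_radius[tum],
      dist_edge_cd = NA_real_,
      tumour_area_um2 = pi * tum_radius[tum]^2,
      crypt_diameter_um = sc$crypt_diameter_um,
      stringsAsFactors = FALSE
    )
    id <- id + n_int
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
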