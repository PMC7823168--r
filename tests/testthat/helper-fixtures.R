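# shared fixtures: all synthetic, generated in code at test time

# small matrix-exponential oracle for the clone-size distribution; kept
# independent of the closed-form implementation (uses Matrix::expm on the
# generator and scales time by hand for the delay)
expm_pmf <- function(params, t) {
  Q <- rate_generator(params)
  t_eff <- max(t - params$delay, 0)
  p0 <- c(0, 1, rep(0, params$n_stem - 1L))
  as.numeric(p0 %*% as.matrix(Matrix::expm(Matrix::Matrix(Q * t_eff))))
}

# brute-force interval-overlap oracle for the eighths redistribution:
# numerical overlap on a fine grid rather than closed-form interval
# arithmetic
grid_eighth_weights <- function(N, grid = 4e4L) {
  u <- (seq_len(grid) - 0.5) / grid
  W <- matrix(0, N, 8L)
  for (n in seq_len(N)) {
    if (n == N) { W[n, 8L] <- 1; next }
    inside <- u > (n - 1) / N & u <= n / N
    b <- pmin(ceiling(u[inside] * 8), 8L)
    cnt <- tabulate(b, nbins = 8L)
    cnt[8L] <- 0
    W[n, ] <- cnt / sum(cnt)
  }
  W
}

# compact count fixture used across mcmc/spatial tests
tiny_counts <- function() {
  clone_counts(c(10, 14), rbind(c(12, 9, 6, 4, 2, 1, 1, 0),
                                c(8, 9, 7, 6, 4, 2, 1, 2)))
}

# a fast sampler configuration for tests that only need a mixed chain,
# not the full production protocol
fast_config <- function(seed = 1L, iterations = 6000L, chains = 1L,
                        burn_in = 1000L, thin = 5L) {
  mcmc_config(iterations = iterations, chains = chains, burn_in = burn_in,
              thin = thin, seed = seed)
}

# adjacent-compartment records at fixed distances, sizes drawn under a
# given rate; used by binning/divergence tests
adjacent_records <- function(n, lambda, dist, times = c(13, 17, 19),
                             n_stem = 5L, delay = tau_glob()) {
  time <- rep_len(times, n)
  size <- integer(n)
  for (t in unique(time)) {
    idx <- time == t
    size[idx] <- cryptdrift:::.surviving_eighths(n_stem, lambda, delay, t,
                                                 sum(idx))
  }
  data.frame(
    clone_id = sprintf("a%05d", seq_len(n)),
    mouse_id = "m1",
    time_days = time,
    size_eighths = size,
    compartment = "adjacent",
    tumour_id = "t001",
    dist_centre_um = NA_real_,
    dist_edge_cd = dist,
    tumour_area_um2 = 3e5,
    crypt_diameter_um = 65,
    stringsAsFactors = FALSE
  )
}
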