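test_that("rolling bins advance by stride and keep constant size", {
  rec <- adjacent_records(150, 0.1, dist = sort(stats::runif(150, 0, 20)))
  bins <- assign_rolling_bins(rec, bin_size = 100, stride = 25)
  expect_length(bins, 3)
  ranks <- lapply(bins, function(b) match(b$clone_ids, rec$clone_id))
  expect_equal(range(ranks[[1]]), c(1, 100))
  expect_equal(range(ranks[[2]]), c(26, 125))
  expect_equal(range(ranks[[3]]), c(51, 150))
  expect_true(all(lengths(ranks) == 100))
  # exactly bin_size records: a single bin holding everything
  rec1 <- adjacent_records(100, 0.1, dist = stats::runif(100, 0, 20))
  b1 <- assign_rolling_bins(rec1, bin_size = 100, stride = 25)
  expect_length(b1, 1)
  expect_setequal(b1[[1]]$clone_ids, rec1$clone_id)
  expect_error(assign_rolling_bins(rec1, bin_size = 200), "exceeds")
})

test_that("rolling-bin median distances are non-decreasing", {
  set.seed(33)
  for (r in 1:5) {
    n <- sample(120:400, 1)
    rec <- adjacent_records(n, 0.1, dist = stats::runif(n, 0, 30))
    bins <- assign_rolling_bins(rec, bin_size = 100, stride = 20)
    med <- vapply(bins, function(b) b$median_distance_cd, numeric(1))
    expect_true(all(diff(med) >= 0))
  }
})

test_that("equal-width binning partitions the distance range", {
  set.seed(4)
  rec <- adjacent_records(200, 0.1, dist = stats::runif(200, 0, 30))
  bins <- assign_rolling_bins(rec, method = "equal_width", n_bins = 5)
  ids <- unlist(lapply(bins, function(b) b$clone_ids))
  expect_setequal(ids, rec$clone_id)   # every record in exactly one bin
  expect_equal(length(ids), 200)
})

test_that("bin likelihood equals the multinomial likelihood of its counts", {
  set.seed(8)
  rec <- adjacent_records(120, 0.1, dist = stats::runif(120, 0, 20))
  bins <- assign_rolling_bins(rec, bin_size = 120, stride = 10)
  wt <- wt_drift_params()
  ll <- bin_wt_loglik(bins[[1]], wt)
  expect_equal(ll, multinomial_loglik(bins[[1]]$counts, wt))
  # brute-force oracle over the pooled per-time counts
  oracle <- 0
  for (i in seq_along(bins[[1]]$counts$times)) {
    t <- bins[[1]]$counts$times[i]
    p <- bin_to_eighths(condition_on_survival(
      clone_size_pmf(wt, t)))$bin_probs
    oracle <- oracle + stats::dmultinom(bins[[1]]$counts$counts[i, ],
                                        prob = p, log = TRUE)
  }
  expect_equal(ll, oracle, tolerance = 1e-10)
})

test_that("null likelihood distribution has ordered quantiles and is calibrated", {
  comp <- c(`13` = 40, `17` = 30, `19` = 30)
  set.seed(61)
  nd <- null_loglik_distribution(comp, n_sims = 500)
  q <- nd$quantiles
  expect_true(all(diff(q) >= 0))
  expect_equal(nd$n_sims, 500)
  # wild-type data should be flagged at close to the nominal 5% rate:
  # draw fresh wild-type count sets and compare to the same null
  sims <- simulate_wt_null_counts(wt_drift_params(), comp, n_sims = 1000)
  wt <- wt_drift_params()
  ll <- vapply(sims, function(m) {
    multinomial_loglik(clone_counts(as.numeric(rownames(m)), m), wt)
  }, numeric(1))
  flagged <- mean(ll < q[["2.5%"]] | ll > q[["97.5%"]])
  # binomial tolerance around 0.05 at 1000 trials, plus Monte-Carlo error
  # in the null quantiles themselves
  expect_lt(abs(flagged - 0.05), 0.035)
})

test_that("divergence splitting flags slowed near-tumour clones", {
  # a strong slowdown near the tumour (0.03 vs the wild-type 0.1; the
  # likelihood test at 100-clone bins has high power at this contrast)
  # while far clones drift at exactly the wild-type rate
  sc <- tumour_field_scenario(lambda_near = 0.03, lambda_far = 0.1,
                              adjacent_per_time = c(500L, 400L, 400L),
                              intra_per_time = c(1L, 1L, 1L))
  tab <- generate_tumour_field(sc, seed = 19)
  adj <- tab[tab$compartment == "adjacent", ]
  bins <- assign_rolling_bins(adj, bin_size = 100, stride = 50)
  set.seed(20)
  bins <- evaluate_bin_divergence(bins, n_sims = 400)
  med <- vapply(bins, function(b) b$median_distance_cd, numeric(1))
  div <- vapply(bins, function(b) b$divergent, logical(1))
  expect_gt(mean(div[med < sc$cutoff_cd]), 0.7)
  expect_lt(mean(div[med > sc$cutoff_cd + 2]), 0.3)
  split <- split_by_divergence(adj, bins)
  expect_equal(nrow(split$divergent) + nrow(split$consistent), nrow(adj))
  # divergent clones concentrate near the tumour
  expect_lt(stats::median(split$divergent$dist_edge_cd),
            stats::median(split$consistent$dist_edge_cd))
  expect_true(is.finite(split$cutoff_cd) || all(div))
})

test_that("all-consistent bins give an empty divergent set", {
  rec <- adjacent_records(100, 0.1, dist = stats::runif(100, 0, 20))
  bins <- assign_rolling_bins(rec, bin_size = 100)
  bins <- lapply(bins, function(b) {
    b$observed_loglik <- 0
    b$null_quantiles <- c(`2.5%` = -10, `10%` = -5, `50%` = 0, `90%` = 5,
                          `97.5%` = 10)
    b$divergent <- FALSE
    b
  })
  split <- split_by_divergence(rec, bins)
  expect_equal(nrow(split$divergent), 0)
  expect_equal(split$cutoff_cd, 0)
  # records in no bin fall to the consistent set with a warning
  extra <- rec[1, ]
  extra$clone_id <- "orphan"
  expect_warning(split_by_divergence(rbind(rec, extra), bins), "no bin")
})

test_that("subset rate inference fixes N and tau and recovers the rate", {
  set.seed(55)
  rec <- adjacent_records(300, 0.07, dist = stats::runif(300, 0, 6))
  fit <- infer_lambda_subset(rec, wt_n = 5, tau = tau_glob(),
                             config = fast_config(seed = 2,
                                                  iterations = 5000L,
                                                  burn_in = 1000L))
  expect_true(all(fit$draws$n_stem == 5L))
  expect_true(all(fit$draws$delay == tau_glob()))
  row <- fit$summary$table[fit$summary$table$parameter == "repl_rate", ]
  expect_true(row$ci95_lo <= 0.07 && 0.07 <= row$ci95_hi)
  expect_error(infer_lambda_subset(rec[0, ]), "empty")
})

test_that("near/far rate ordering is recovered from the default field", {
  correct <- 0
  for (r in 1:6) {
    sc <- tumour_field_scenario(adjacent_per_time = c(160L, 120L, 120L),
                                intra_per_time = c(1L, 1L, 1L))
    tab <- generate_tumour_field(sc, seed = 300 + r)
    adj <- tab[tab$compartment == "adjacent", ]
    near <- adj[adj$dist_edge_cd < sc$cutoff_cd, ]
    far <- adj[adj$dist_edge_cd >= sc$cutoff_cd, ]
    cfg <- fast_config(seed = r, iterations = 4000L, burn_in = 800L,
                       thin = 4L)
    m_near <- infer_lambda_subset(near, config = cfg)$summary
    m_far <- infer_lambda_subset(far, config = cfg)$summary
    if (m_near$table$median[2] < m_far$table$median[2]) correct <- correct + 1
  }
  expect_gte(correct, 5)
})

test_that("monoclonal proportions reproduce the worked intra/external values", {
  # day-13 intra-tumour: 69 monoclonal of 273 surviving clones
  intra13 <- c(rep(8L, 69), rep(4L, 204))
  expect_equal(round(100 * observed_monoclonal_proportion(intra13), 1), 25.3)
  # day-19 external: 8 of 64
  ext19 <- c(rep(8L, 8), rep(2L, 56))
  expect_equal(round(100 * observed_monoclonal_proportion(ext19), 1), 12.5)
  expect_equal(observed_monoclonal_proportion(c(1L, 3L)), 0)
  expect_error(observed_monoclonal_proportion(integer(0)), "no surviving")
  # counts container route agrees
  cc <- clone_counts(13, c(0, 204, 0, 0, 0, 0, 0, 69))
  expect_equal(observed_monoclonal_proportion(cc), 69 / 273)
})

test_that("monoclonal rescaling pins bin 8 and preserves partial ratios", {
  C <- c(0, 0, 0, 0, 0, 0, 0.5, 0.5)
  expect_equal(unname(rescale_monoclonals(C, 0.1)),
               c(0, 0, 0, 0, 0, 0, 0.9, 0.1))
  # identity when the monoclonal mass already matches
  C2 <- c(0.1, 0.2, 0.2, 0.1, 0.1, 0.1, 0.1, 0.1)
  expect_equal(unname(rescale_monoclonals(C2, 0.1)), C2)
  set.seed(77)
  for (i in 1:25) {
    C <- stats::runif(8); C <- C / sum(C)
    m <- stats::runif(1, 0, 0.9)
    out <- rescale_monoclonals(C, m)
    expect_equal(sum(out), 1, tolerance = 1e-12)
    expect_equal(unname(out[8]), m)
    # partial-clone proportions keep their ratios
    expect_equal(out[1:7] / sum(out[1:7]), C[1:7] / sum(C[1:7]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(rescale_monoclonals(c(rep(0, 7), 1), 0.1), "monoclonal")
  expect_error(rescale_monoclonals(C, 1), "m_ext")
})

test_that("intra-tumour clones classify by 75% of the average radius", {
  rec <- data.frame(dist_centre_um = c(0, 100, 299, 301, 400),
                    tumour_area_um2 = pi * 400^2)
  got <- classify_intratumour_position(rec)
  expect_equal(got, c("centre", "centre", "centre", "edge", "edge"))
  # a clone at exactly the average radius is at the edge
  rec2 <- data.frame(dist_centre_um = 400, tumour_area_um2 = pi * 400^2)
  expect_equal(classify_intratumour_position(rec2), "edge")
  expect_error(classify_intratumour_position(
    data.frame(dist_centre_um = NA_real_)), "centre")
})
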