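# Dwell-time kinetics: extraction oracles, exponential fits, survival,
# medians with order-statistic CIs, the nucleation power law.

make_dwells <- function(dwell_s, censored = FALSE) {
  d <- data.frame(track_id = seq_along(dwell_s), start_frame = 1L,
                  n_frames = as.integer(round(dwell_s / 30)),
                  dwell_s = dwell_s,
                  censored = rep_len(censored, length(dwell_s)),
                  position = 0)
  class(d) <- c("dwell_records", "data.frame")
  d
}

test_that("dwell extraction applies the run, censoring and drift rules", {
  # single detected frame = one 30 s interval
  one <- extract_dwells(matrix(c(FALSE, TRUE, FALSE), nrow = 1))
  expect_equal(one$dwell_s, 30)
  expect_false(one$censored)

  # [1,1,0,1]: two records, 60 s then a censored 30 s
  two <- extract_dwells(matrix(c(TRUE, TRUE, FALSE, TRUE), nrow = 1))
  expect_equal(two$dwell_s, c(60, 30))
  expect_equal(two$censored, c(FALSE, TRUE))

  # positional drift beyond tolerance splits the run
  drift <- data.frame(track_id = 1, frame = 1:3, detected = TRUE,
                      position_px = c(0, 2, 2))
  expect_identical(nrow(extract_dwells(drift, position_tol_px = 1)), 2L)
  expect_identical(nrow(extract_dwells(drift, position_tol_px = 2)), 1L)
})

test_that("dwell extraction agrees exactly with the run-length oracle", {
  set.seed(21)
  for (i in 1:200) {
    m <- matrix(runif(40) < 0.45, nrow = 4)
    got <- extract_dwells(m)
    want <- list()
    for (r in seq_len(nrow(m))) {
      for (run in brute_runs(m[r, ])) {
        want[[length(want) + 1L]] <- c(r, run[1], run[2],
                                       run[1] + run[2] - 1L == ncol(m))
      }
    }
    expect_identical(nrow(got), length(want))
    if (length(want)) {
      wm <- do.call(rbind, want)
      ord <- order(wm[, 1], wm[, 2])
      wm <- wm[ord, , drop = FALSE]
      got <- got[order(got$track_id, got$start_frame), ]
      expect_equal(got$track_id, wm[, 1])
      expect_equal(got$start_frame, wm[, 2])
      expect_equal(got$n_frames, wm[, 3])
      expect_equal(got$dwell_s, 30 * wm[, 3])
      expect_equal(as.integer(got$censored), wm[, 4])
    }
  }
})

test_that("exponential dwell fit recovers tau at the published sample size", {
  # at n = 87 the sampling SD of tau-hat is ~15%, so judge the typical
  # (median) error over a handful of fixed seeds
  errs <- vapply(1:31, function(s) {
    set.seed(s)
    tv <- 30 * pmax(1, ceiling(rexp(87, 1 / 150) / 30))
    abs(fit_dwell_exponential(make_dwells(tv))$tau_s - 150) / 150
  }, numeric(1))
  expect_lt(median(errs), 0.20)
  set.seed(5)
  tv <- 30 * pmax(1, ceiling(rexp(87, 1 / 150) / 30))
  ef <- fit_dwell_exponential(make_dwells(tv))
  expect_equal(ef$n, 87)
  expect_gt(ef$r_squared, 0.5)

  expect_error(fit_dwell_exponential(make_dwells(rep(60, 50))),
               "degenerate")
  expect_error(fit_dwell_exponential(make_dwells(c(30, 60, 90))),
               "at least 20")
})

test_that("histogram tau estimator is nearly unbiased for n >= 100", {
  set.seed(1)
  taus <- vapply(1:100, function(i) {
    tv <- 30 * ceiling(rexp(150, 1 / 120) / 30)
    fit_dwell_exponential(make_dwells(tv))$tau_s
  }, numeric(1))
  expect_lt(abs(mean(taus) - 120) / 120, 0.05)
})

test_that("excluding censored records shortens the fitted tau", {
  set.seed(3)
  tv <- 30 * pmax(1, ceiling(rexp(300, 1 / 200) / 30))
  cens <- tv >= 360                      # long dwells run into the last frame
  tv_obs <- pmin(tv, 360)
  d <- make_dwells(tv_obs, censored = cens)
  tau_excl <- fit_dwell_exponential(d, exclude_censored = TRUE)$tau_s
  tau_incl <- fit_dwell_exponential(d, exclude_censored = FALSE)$tau_s
  expect_lt(tau_excl, tau_incl)
})

test_that("survival curves are proper and match exponential data", {
  one <- make_dwells(60)
  sc <- survival_curve(one, times = c(0, 30, 60, 90))
  expect_equal(sc$survival, c(1, 1, 1, 0))

  set.seed(11)
  tv <- rexp(400, 1 / 100)
  sc2 <- survival_curve(tv, times = seq(0, 400, by = 10))
  expect_equal(sc2$survival[1], 1)
  expect_true(all(diff(sc2$survival) <= 0))
  expect_true(all(sc2$survival <= 1))
  # Dvoretzky-Kiefer-Wolfowitz band at alpha = 0.05
  eps <- sqrt(log(2 / 0.05) / (2 * 400))
  expect_true(all(abs(sc2$survival - exp(-sc2$time_s / 100)) <= eps))
  expect_lt(abs(attr(sc2, "tau_s") - 100) / 100, 0.10)
})

test_that("median CI uses achievable order-statistic levels", {
  mc <- median_with_ci(c(10, 20, 30), conf = 0.5)
  expect_equal(mc$median, 20)

  x10 <- c(3, 7, 11, 19, 23, 29, 31, 37, 41, 47)
  mc10 <- median_with_ci(x10, conf = 0.95)
  # exact coverage of [X_(2), X_(9)] for n = 10: 1 - 2 P(Bin(10,.5) <= 1)
  expect_equal(mc10$achieved_level, 1 - 2 * pbinom(1, 10, 0.5))
  expect_equal(mc10$ci, c(x10[2], x10[9]))

  # Monte Carlo coverage agrees with the reported achievable level
  set.seed(2)
  hits <- vapply(1:4000, function(i) {
    x <- rexp(10)
    ci <- sort(x)[c(2, 9)]
    ci[1] <= log(2) && log(2) <= ci[2]
  }, logical(1))
  expect_lt(abs(mean(hits) - mc10$achieved_level), 0.025)

  expect_error(median_with_ci(1:2), "at least 3")
})

test_that("power-law fit recovers exact and noisy exponents", {
  pf <- fit_power_law(c(50, 100, 200, 400), 1e-4 * c(50, 100, 200, 400)^2)
  expect_equal(pf$n, 2, tolerance = 1e-9)
  expect_equal(pf$J, 1e-4, tolerance = 1e-9)
  expect_error(fit_power_law(c(-1, 2, 3), c(1, 2, 3)), "positive")

  # Poisson-noised dipping counts: fitted exponent tracks the apparent
  # exponent of the expected counts
  concs <- c(50, 100, 200, 400, 800)
  expected <- vapply(concs, function(cc) {
    cfg <- sim_config(rad51_conc = cc)
    rates <- rad51kin:::nucleation_rates(cfg)
    (rates[["monomer"]] + rates[["dimer"]]) * 48502 * 0.5
  }, numeric(1))
  n_apparent <- fit_power_law(concs, expected)$n
  set.seed(9)
  noisy <- vapply(expected, function(m) mean(rpois(60, m)), numeric(1))
  expect_lt(abs(fit_power_law(concs, noisy)$n - n_apparent), 0.2)
})

test_that("simulated paralog capping lengthens cluster dwell times", {
  base <- list(lattice_length_nt = 48502, rad51_conc = 470,
               nucleation_rate_const_J = 0.03,
               monomer_nucleation_fraction = 1,
               add_rate_5p = 0, add_rate_3p = 0,
               off_attempt_rate = 1.2, burst_mean_protomers = 1e9,
               duration_min = 10)
  dwells_for <- function(cap_on, seed) {
    cfg <- do.call(sim_config, c(base, list(cap_on_rate = cap_on,
                                            cap_dwell_tau_s = 1e6,
                                            seed = seed)))
    dip <- simulate_dipping(cfg, n_cycles = 20, incubation_s = 30,
                            incubate_each_cycle = FALSE)
    cl <- dip$clusters[!dip$clusters$censored, ]
    30 * (cl$disappear_frame - cl$appear_frame + 1)
  }
  alone <- dwells_for(0, 41)
  with_cap <- dwells_for(60, 42)
  t_alone <- fit_dwell_exponential(make_dwells(alone))$tau_s
  t_cap <- fit_dwell_exponential(make_dwells(with_cap))$tau_s
  expect_gt(t_cap, t_alone)
})
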