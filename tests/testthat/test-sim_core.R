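# Kinetic Monte Carlo simulator: analytic oracles, conservation and
# determinism invariants, dipping protocol.

test_that("zero-rate configs give empty logs and validation rejects bad input", {
  cfg <- sim_config(lattice_length_nt = 1000, nucleation_rate_const_J = 0,
                    duration_min = 5, seed = 1)
  log <- simulate_assembly(cfg)
  expect_s3_class(log, "event_log")
  expect_identical(nrow(log$events), 0L)
  occ <- occupancy_timeseries(log, c(0, 2.5, 5))
  expect_equal(vapply(occ, `[[`, numeric(1), "coverage"), c(0, 0, 0))

  expect_error(sim_config(nucleation_rate_const_J = -1), "nonnegative")
  expect_error(sim_config(nucleation_rate_const_J = NaN), "finite")
  expect_error(sim_config(lattice_length_nt = 2), "footprint")
  expect_error(sim_config(nucleation_exponent_n = 4), "n <= 3")
  expect_error(sim_config(monomer_nucleation_fraction = 1.2), "\\[0, 1\\]")
})

test_that("nucleation-only event counts match the analytic Poisson mean", {
  # monomer-only nucleation at the reference concentration: per-nt rate = J
  J <- 2e-3; L <- 2000L; T <- 1
  lam_expected <- J * L * T      # occupancy exclusion is < 2% at this density
  counts <- vapply(1:100, function(s) {
    cfg <- sim_config(lattice_length_nt = L, rad51_conc = 470,
                      nucleation_rate_const_J = J,
                      monomer_nucleation_fraction = 1,
                      add_rate_5p = 0, add_rate_3p = 0, off_attempt_rate = 0,
                      duration_min = T, seed = 1000 + s)
    nrow(simulate_assembly(cfg)$events)
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - lam_expected), 3 * se + 0.02 * lam_expected)
})

test_that("a seeded nucleus grows linearly at rate 2 g", {
  g <- 5; T <- 2
  finals <- vapply(1:100, function(s) {
    cfg <- sim_config(lattice_length_nt = 5000, nucleation_rate_const_J = 0,
                      add_rate_5p = g, add_rate_3p = g, off_attempt_rate = 0,
                      duration_min = T, seed = 2000 + s)
    log <- simulate_assembly(cfg, initial_filaments = data.frame(
      start_nt = 2400, protomers = 10))
    tail(protomer_balance(log), 1)
  }, numeric(1))
  expected <- 10 + 2 * g * T
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * se)
})

test_that("occupancy matches hand counts and the brute-force replay oracle", {
  # nucleate(2 protomers) + 4 adds -> one 18 nt interval
  ev <- data.frame(
    time_min = c(0, 0.1, 0.2, 0.3, 0.4),
    kind = c("nucleate", "add", "add", "add", "add"),
    position_nt = c(300L, 297L, 306L, 294L, 309L),
    protomer_count = c(2L, 1L, 1L, 1L, 1L),
    end = c("n/a", "5p", "3p", "5p", "3p"),
    filament_id = rep(1L, 5))
  cfg <- sim_config(lattice_length_nt = 1000, duration_min = 1, seed = 1)
  log <- rad51kin:::new_event_log(ev, cfg)
  occ <- occupancy_timeseries(log, 1)[[1]]
  expect_identical(nrow(occ$intervals), 1L)
  expect_equal(occ$intervals$end_nt - occ$intervals$start_nt, 18)
  expect_equal(occ$coverage, 18 / 1000)

  # replay consistency on a dynamic simulation
  log2 <- simulate_assembly(sim_preset("RFS1RIP1_WT", lattice_length_nt = 5000,
                                       duration_min = 4, seed = 11))
  for (t in c(1, 2.5, 4)) {
    occ_t <- occupancy_timeseries(log2, t)[[1]]
    expect_equal(occ_t$coverage,
                 brute_occupancy(log2$events, 3, 5000, t), tolerance = 1e-12)
  }
})

test_that("simulator invariants hold across presets and seeds", {
  for (cond in c("none", "BRC2", "RFS1RIP1_WT", "K56A", "combined")) {
    cfg <- sim_preset(cond, lattice_length_nt = 4000, duration_min = 4,
                      seed = 42)
    log <- simulate_assembly(cfg)
    ev <- log$events
    # time-ordered and protomer-conserving
    expect_false(is.unsorted(ev$time_min))
    bal <- protomer_balance(log)
    expect_true(all(bal >= 0))
    # final balance equals total occupied nt / footprint
    occ <- occupancy_timeseries(log, 4)[[1]]
    expect_equal(sum(occ$intervals$end_nt - occ$intervals$start_nt) / 3,
                 tail(bal, 1))
    # occupancy intervals pairwise disjoint
    iv <- occ$intervals
    if (nrow(iv) > 1)
      expect_true(all(iv$start_nt[-1] >= iv$end_nt[-nrow(iv)]))
    # bit-stable determinism
    expect_identical(simulate_assembly(cfg)$events, ev)
  }
})

test_that("a permanently capped 5' end never bursts", {
  cfg <- sim_config(lattice_length_nt = 4000, nucleation_rate_const_J = 0,
                    add_rate_5p = 10, add_rate_3p = 10, off_attempt_rate = 5,
                    cap_on_rate = 1e6, cap_dwell_tau_s = 1e12,
                    duration_min = 3, seed = 7)
  log <- simulate_assembly(cfg, initial_filaments = data.frame(
    start_nt = 2000, protomers = 50))
  ev <- log$events
  expect_identical(sum(ev$kind == "burst" & ev$end == "5p"), 0L)
  expect_gt(sum(ev$kind == "burst" & ev$end == "3p"), 0L)
})

test_that("nucleation counts scale as c^n and doubling J doubles them", {
  concs <- c(50, 100, 200, 400, 800)
  mean_counts <- function(J, f, n_exp, seeds) {
    vapply(concs, function(cc) {
      mean(vapply(seeds, function(s) {
        cfg <- sim_config(lattice_length_nt = 20000, rad51_conc = cc,
                          nucleation_rate_const_J = J,
                          monomer_nucleation_fraction = f,
                          nucleation_exponent_n = n_exp,
                          add_rate_5p = 0, add_rate_3p = 0,
                          off_attempt_rate = 0, duration_min = 0.5,
                          seed = s + round(cc))
        nrow(simulate_assembly(cfg)$events)
      }, numeric(1)))
    }, numeric(1))
  }
  # pure monomer channel: exponent 1; pure dimer channel: exponent 2
  for (spec in list(list(f = 1, n = 1), list(f = 0, n = 2))) {
    y <- mean_counts(2e-3, spec$f, 2, 1:20)
    slope <- coef(lm(log(y) ~ log(concs)))[[2]]
    expect_lt(abs(slope - spec$n), 0.15)
  }
  # doubling J doubles the mean count
  c1 <- vapply(1:60, function(s) {
    cfg <- sim_config(lattice_length_nt = 10000, rad51_conc = 470,
                      nucleation_rate_const_J = 1e-3,
                      monomer_nucleation_fraction = 1, add_rate_5p = 0,
                      add_rate_3p = 0, off_attempt_rate = 0,
                      duration_min = 1, seed = 3000 + s)
    nrow(simulate_assembly(cfg)$events)
  }, numeric(1))
  c2 <- vapply(1:60, function(s) {
    cfg <- sim_config(lattice_length_nt = 10000, rad51_conc = 470,
                      nucleation_rate_const_J = 2e-3,
                      monomer_nucleation_fraction = 1, add_rate_5p = 0,
                      add_rate_3p = 0, off_attempt_rate = 0,
                      duration_min = 1, seed = 4000 + s)
    nrow(simulate_assembly(cfg)$events)
  }, numeric(1))
  se <- sqrt(var(c2) / 60 + 4 * var(c1) / 60)
  expect_lt(abs(mean(c2) - 2 * mean(c1)), 3 * se)
})

test_that("dipping protocol: trivial cases and exponential cluster survival", {
  cfg <- sim_preset("dipping", seed = 5)
  expect_identical(nrow(simulate_dipping(cfg, n_cycles = 3,
                                         incubation_s = 0)$clusters), 0L)

  # immortal clusters persist to the final frame, censored
  cfg0 <- sim_config(lattice_length_nt = 20000, rad51_conc = 470,
                     nucleation_rate_const_J = 5e-4,
                     add_rate_5p = 0, add_rate_3p = 0, off_attempt_rate = 0,
                     duration_min = 1, seed = 6)
  dip0 <- simulate_dipping(cfg0, n_cycles = 5, incubation_s = 30)
  expect_gt(nrow(dip0$clusters), 0)
  expect_true(all(dip0$clusters$disappear_frame == 5L))
  expect_true(all(dip0$clusters$censored))

  # with every burst attempt fatal, cluster lifetimes are Exp(2 * off);
  # 1 s frames keep quantization small relative to the 30 s mean
  off <- 1
  cfg1 <- sim_config(lattice_length_nt = 48502, rad51_conc = 470,
                     nucleation_rate_const_J = 0.8,
                     monomer_nucleation_fraction = 1,
                     add_rate_5p = 0, add_rate_3p = 0,
                     off_attempt_rate = off, burst_mean_protomers = 1e9,
                     duration_min = 5, seed = 8)
  dip1 <- simulate_dipping(cfg1, n_cycles = 240, incubation_s = 1,
                           frame_interval_s = 1,
                           incubate_each_cycle = FALSE)
  cl <- dip1$clusters[!dip1$clusters$censored, ]
  expect_gt(nrow(cl), 500)
  dwell_s <- (cl$disappear_frame - cl$appear_frame + 1)
  ks <- suppressWarnings(stats::ks.test(dwell_s, "pexp", rate = 2 * off / 60))
  expect_gt(ks$p.value, 0.01)
})

test_that("event logs round-trip through CSV + JSON sidecar", {
  log <- simulate_assembly(sim_preset("K56A", lattice_length_nt = 4000,
                                      duration_min = 3, seed = 9))
  path <- file.path(tempdir(), "events_rt.csv")
  write_event_log(log, path)
  log2 <- read_event_log(path)
  expect_identical(log2$events, log$events)
  for (nm in names(unclass(log$config)))
    expect_equal(log2$config[[nm]], log$config[[nm]])
  expect_identical(attr(log2$config, "condition"), "K56A")

  empty <- simulate_assembly(sim_config(lattice_length_nt = 100,
                                        nucleation_rate_const_J = 0,
                                        duration_min = 1, seed = 1))
  write_event_log(empty, path)
  expect_identical(read_event_log(path)$events, empty$events)
})
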