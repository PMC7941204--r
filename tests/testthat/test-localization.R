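# Filament localization and mediator end-binding classification.

# synthetic RPA profile with a Gaussian depression
depression_profile <- function(n_px = 100, center_px = 50, sigma_px = 5,
                               depth = 80, base = 100) {
  p <- (seq_len(n_px) - 0.5) * 100
  y <- base - depth * exp(-((seq_len(n_px) - center_px)^2) / (2 * sigma_px^2))
  data.frame(position_nm = p, intensity = y)
}

test_that("filament localization finds a synthetic depression center", {
  prof <- depression_profile(center_px = 50)
  loc <- locate_filament(prof)
  expect_true(loc$found)
  expect_lt(abs(loc$center_nm - 49.5 * 100), 50)   # within half a pixel
  # edges at the fitted HWHM
  expect_equal(loc$edges_nm,
               loc$center_nm + c(-1, 1) * loc$half_width_nm)
  expect_equal(loc$half_width_nm, 5 * 100 * sqrt(2 * log(2)),
               tolerance = 0.02)
})

test_that("flat or shallow profiles return not-found without an error", {
  flat <- data.frame(position_nm = (1:50) * 100, intensity = rep(5, 50))
  expect_false(locate_filament(flat)$found)
  set.seed(3)
  noisy_flat <- data.frame(position_nm = (1:80) * 100,
                           intensity = 100 + rnorm(80, 0, 1.5))
  loc <- locate_filament(noisy_flat)
  if (loc$found) expect_lt(loc$depth, 20)  # never a deep spurious filament
})

test_that("localization error stays below half a pixel at SNR >= 5", {
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    center <- runif(1, 40, 60)
    p <- (1:100 - 0.5) * 100
    y <- 100 - 80 * exp(-((1:100 - center)^2) / (2 * 4^2)) + rnorm(100, 0, 8)
    loc <- locate_filament(data.frame(position_nm = p, intensity = y))
    if (!loc$found) return(NA_real_)
    abs(loc$center_nm - (center - 0.5) * 100)
  }, numeric(1))
  expect_lt(mean(is.na(errs)), 0.05)
  expect_lt(median(errs, na.rm = TRUE), 50)
})

test_that("binding classification follows the distance rules", {
  fil <- structure(list(found = TRUE, center_nm = 5000,
                        half_width_nm = 1000, edges_nm = c(4000, 6000),
                        depth = 1, fit = NULL), class = "filament_location")
  expect_identical(classify_binding(5000, fil)$label, "internal")
  expect_identical(classify_binding(4100, fil)$label, "5p-end")
  expect_identical(classify_binding(6150, fil)$label, "3p-end")
  expect_identical(classify_binding(8000, fil)$label, "RPA/ssDNA")
  expect_identical(classify_binding(1000, fil)$label, "RPA/ssDNA")
  # orientation flips the end labels
  expect_identical(classify_binding(4100, fil,
                                    orientation = "5p_high")$label, "3p-end")
  # tie at the exact center of a narrow filament is flagged
  narrow <- structure(list(found = TRUE, center_nm = 5000,
                           half_width_nm = 150, edges_nm = c(4850, 5150),
                           depth = 1, fit = NULL),
                      class = "filament_location")
  call <- classify_binding(5000, narrow)
  expect_true(call$tie)
})

test_that("mirror symmetry: flipping the axis swaps 5' and 3' labels", {
  fil <- structure(list(found = TRUE, center_nm = 5000,
                        half_width_nm = 1000, edges_nm = c(4000, 6000),
                        depth = 1, fit = NULL), class = "filament_location")
  axis_max <- 10000
  for (spot in c(4100, 5950, 5000, 800, 9100)) {
    a <- classify_binding(spot, fil)$label
    fil_m <- fil
    fil_m$center_nm <- axis_max - fil$center_nm
    fil_m$edges_nm <- sort(axis_max - fil$edges_nm)
    b <- classify_binding(axis_max - spot, fil_m)$label
    swap <- c("5p-end" = "3p-end", "3p-end" = "5p-end",
              internal = "internal", "RPA/ssDNA" = "RPA/ssDNA")
    expect_identical(b, unname(swap[a]))
  }
})

test_that("classification confusion matrix diagonal is >= 0.9 on noisy truth", {
  set.seed(14)
  fil <- structure(list(found = TRUE, center_nm = 5000,
                        half_width_nm = 1500, edges_nm = c(3500, 6500),
                        depth = 1, fit = NULL), class = "filament_location")
  truth <- list("5p-end" = function() 3500 + rnorm(1, 0, 60),
                "3p-end" = function() 6500 + rnorm(1, 0, 60),
                internal = function() runif(1, 3900, 6100),
                "RPA/ssDNA" = function() sample(c(runif(1, 500, 3100),
                                                  runif(1, 6900, 9500)), 1))
  for (lbl in names(truth)) {
    calls <- vapply(1:200, function(i)
      classify_binding(truth[[lbl]](), fil)$label, character(1))
    expect_gte(mean(calls == lbl), 0.9)
  }
})

test_that("capped 5' ends in rendered simulations are called 5p-end", {
  # permanently capped seeded filament; red channel marks the cap
  calls <- character(0)
  for (s in 1:6) {
    cfg <- sim_config(lattice_length_nt = 10000,
                      nucleation_rate_const_J = 0, add_rate_5p = 0,
                      add_rate_3p = 0, off_attempt_rate = 0,
                      cap_on_rate = 1e6, cap_dwell_tau_s = 1e12,
                      duration_min = 2, seed = 100 + s)
    log <- simulate_assembly(cfg, initial_filaments = data.frame(
      start_nt = 3000 + 400 * s, protomers = 500))
    ky <- render_kymograph(log, render_config(seed = 200 + s))
    for (fr in c(10, 40, 70)) {
      loc <- locate_filament(kymo_linescan(ky, fr, "blue"))
      spot <- locate_spot(kymo_linescan(ky, fr, "red"))
      if (loc$found && spot$found)
        calls <- c(calls, classify_binding(spot$center_nm, loc)$label)
    }
  }
  expect_gt(length(calls), 10)
  expect_gte(mean(calls == "5p-end"), 0.95)
})

test_that("colocalization fractions are per molecule with NA for no spots", {
  spots <- data.frame(molecule_id = c(1, 1, 2, 2, 2),
                      position_nm = c(100, 2000, 300, 5000, 5100))
  clusters <- data.frame(molecule_id = c(1, 1, 2, 3),
                         position_nm = c(120, 2100, 310, 700))
  cf <- colocalization_fraction(spots, clusters)
  expect_equal(cf$frac_on_cluster[cf$molecule_id == 1], 1)
  expect_equal(cf$frac_on_cluster[cf$molecule_id == 2], 1 / 3)
  expect_true(is.na(cf$frac_on_cluster[cf$molecule_id == 3]))
  expect_equal(cf$frac_on_ssdna[cf$molecule_id == 2], 2 / 3)

  # geometric null: random spots colocalize at about the covered fraction
  set.seed(4)
  L <- 20000
  cl_pos <- seq(500, L - 500, by = 2000)   # 10 clusters
  sp_pos <- runif(2000, 0, L)
  cf2 <- colocalization_fraction(
    data.frame(molecule_id = 1, position_nm = sp_pos),
    data.frame(molecule_id = 1, position_nm = cl_pos),
    psf_sigma_nm = 150)
  p_expected <- length(cl_pos) * 300 / L
  se <- sqrt(p_expected * (1 - p_expected) / 2000)
  expect_lt(abs(cf2$frac_on_cluster - p_expected), 4 * se)
})
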