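# Rendering of event logs into observable data: multi-channel kymographs
# (position x time), trap force traces, and photobleaching staircases.
# Channel convention follows the confocal detection filters of the assay:
# blue = RPA-eGFP (bright on uncovered ssDNA, dark under filaments),
# green = FAM-labeled protomers, red = mediator caps at 5' filament ends.

#' Rendering parameters for kymographs
#'
#' Defaults emulate the published imaging conditions: 100 nm pixels,
#' 0.1 ms per-pixel dwell during the line scan, and a 1.5 s inter-frame
#' wait, so the frame interval is `n_pixels * 1e-4 + 1.5` seconds.  The
#' point-spread function is a 1-D Gaussian of sigma 150 nm (approximately
#' confocal at 488 nm); photon budgets default to a single-fluorophore
#' signal-to-noise ratio of about 5 (30 photons against shot noise plus
#' read noise of SD 3).
#'
#' @param pixel_size_nm Pixel size along the DNA axis, nm (> 0).
#' @param inter_frame_wait_s Wait time between line scans, seconds.
#' @param pixel_dwell_s Per-pixel scan dwell, seconds.
#' @param psf_sigma_nm Gaussian PSF sigma, nm; 0 disables blurring.
#' @param photons_per_nt_rpa Expected RPA-eGFP photons per uncovered
#'   nucleotide per frame.
#' @param photons_per_fluor Expected photons per labeled protomer per frame
#'   (green channel) and per bound cap (red channel).
#' @param read_noise_sd Additive Gaussian read noise SD (photons).
#' @param bleach_rate_per_s Mean-field fluorophore bleaching rate applied to
#'   the green channel as `exp(-rate * t)`; 0 disables.
#' @param labeled_fraction Fraction of protomers carrying a fluorophore.
#' @param red_nonspecific_per_frame Expected number (Poisson) of transient
#'   nonspecifically bound mediator spots per frame, placed uniformly over
#'   the lattice (bare ssDNA and filament interiors alike).  The labeled
#'   mediator binds weakly outside filament 5' ends, and scored binding
#'   events in this assay include such off-end events; 0 disables.
#' @param noise If `FALSE`, return noiseless expected intensities.
#' @param orientation `"5p_top"` (image row 1 = ssDNA 5' end, the default)
#'   or `"5p_bottom"`.
#' @param seed RNG seed for the noise draws, or `NULL`.
#' @return A list of class `render_config`.
#' @export
render_config <- function(pixel_size_nm = 100,
                          inter_frame_wait_s = 1.5,
                          pixel_dwell_s = 1e-4,
                          psf_sigma_nm = 150,
                          photons_per_nt_rpa = 1,
                          photons_per_fluor = 30,
                          read_noise_sd = 3,
                          bleach_rate_per_s = 0,
                          labeled_fraction = 1,
                          red_nonspecific_per_frame = 0,
                          noise = TRUE,
                          orientation = c("5p_top", "5p_bottom"),
                          seed = NULL) {
  if (!is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be positive", call. = FALSE)
  if (!is.finite(inter_frame_wait_s) || inter_frame_wait_s < 0 ||
      !is.finite(pixel_dwell_s) || pixel_dwell_s < 0 ||
      inter_frame_wait_s + pixel_dwell_s <= 0)
    stop("line time must be positive", call. = FALSE)
  structure(list(pixel_size_nm = pixel_size_nm,
                 inter_frame_wait_s = inter_frame_wait_s,
                 pixel_dwell_s = pixel_dwell_s,
                 psf_sigma_nm = psf_sigma_nm,
                 photons_per_nt_rpa = photons_per_nt_rpa,
                 photons_per_fluor = photons_per_fluor,
                 read_noise_sd = read_noise_sd,
                 bleach_rate_per_s = bleach_rate_per_s,
                 labeled_fraction = labeled_fraction,
                 red_nonspecific_per_frame = red_nonspecific_per_frame,
                 noise = isTRUE(noise),
                 orientation = match.arg(orientation),
                 seed = seed),
            class = "render_config")
}

new_kymograph <- function(channels, pixel_size_nm, line_time_s, orientation,
                          metadata = list()) {
  stopifnot(length(unique(lapply(channels, dim))) == 1L, pixel_size_nm > 0)
  structure(list(channels = channels, pixel_size_nm = pixel_size_nm,
                 line_time_s = line_time_s, orientation = orientation,
                 metadata = metadata),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<kymograph> %d px x %d frames (%s), %g nm/px, %g s/frame, 5' at %s\n",
              d[1], d[2], paste(names(x$channels), collapse = "/"),
              x$pixel_size_nm, x$line_time_s,
              if (x$orientation == "5p_top") "top" else "bottom"))
  invisible(x)
}

# distribute covered nucleotides of half-open nt intervals over pixels of
# width `nt_per_px` (continuous overlap, in nt)
coverage_per_pixel <- function(intervals, n_px, nt_per_px) {
  cov <- numeric(n_px)
  for (r in seq_len(nrow(intervals))) {
    a <- intervals$start_nt[r] / nt_per_px
    b <- intervals$end_nt[r] / nt_per_px
    lo <- max(0L, floor(a))
    hi <- min(n_px - 1L, ceiling(b) - 1L)
    if (hi < lo) next
    px <- lo:hi
    cov[px + 1L] <- cov[px + 1L] +
      (pmin(px + 1, b) - pmax(px, a)) * nt_per_px
  }
  cov
}

gaussian_blur_1d <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_px))
  k <- dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' Render an event log into a multi-channel kymograph
#'
#' Produces position-by-time intensity images: the blue channel is
#' RPA-eGFP, proportional to uncovered ssDNA per pixel (filaments appear as
#' dark wedges); the green channel carries FAM-labeled protomers; the red
#' channel shows mediator caps as diffraction-limited spots at 5' filament
#' ends.  A 1-D Gaussian PSF is applied along the position axis, followed by
#' Poisson shot noise and Gaussian read noise (unless `config$noise` is
#' `FALSE`).
#'
#' @param log An `event_log` from [simulate_assembly()].
#' @param config A [render_config()].
#' @return A `kymograph` object: named channel matrices (rows = position
#'   pixels, columns = frames), `pixel_size_nm`, `line_time_s` (frame
#'   interval) and `orientation` metadata.
#' @export
render_kymograph <- function(log, config = render_config()) {
  stopifnot(inherits(log, "event_log"), inherits(config, "render_config"))
  scfg <- log$config
  nm_per_nt <- rad51kin_constants[["nm_per_nt_at_imaging_force"]]
  fp <- scfg$footprint_nt
  L_nm <- scfg$lattice_length_nt * nm_per_nt
  n_px <- max(2L, ceiling(L_nm / config$pixel_size_nm))
  nt_per_px <- config$pixel_size_nm / nm_per_nt
  line_time_s <- n_px * config$pixel_dwell_s + config$inter_frame_wait_s
  t_frames_min <- seq(0, scfg$duration_min, by = line_time_s / 60)
  n_fr <- length(t_frames_min)
  snaps <- sweep_snapshots(log$events, fp, t_frames_min)

  channels <- with_seed(config$seed, {
  blue <- matrix(0, n_px, n_fr)
  green <- matrix(0, n_px, n_fr)
  red <- matrix(0, n_px, n_fr)
  for (j in seq_len(n_fr)) {
    st <- snaps[[j]]
    cov <- if (nrow(st) > 0) {
      iv <- data.frame(start_nt = st$start_nt,
                       end_nt = st$start_nt + st$protomers * fp)
      coverage_per_pixel(iv, n_px, nt_per_px)
    } else numeric(n_px)
    blue[, j] <- config$photons_per_nt_rpa * pmax(0, nt_per_px - cov)
    if (nrow(st) > 0 && config$labeled_fraction > 0) {
      # one fluorophore per labeled protomer, binned at the protomer center
      centers <- unlist(lapply(seq_len(nrow(st)), function(r)
        st$start_nt[r] + fp * (seq_len(st$protomers[r]) - 0.5)))
      px <- pmin(n_px - 1L, floor(centers / nt_per_px)) + 1L
      cnt <- tabulate(px, nbins = n_px)
      fade <- if (config$bleach_rate_per_s > 0)
        exp(-config$bleach_rate_per_s * t_frames_min[j] * 60) else 1
      green[, j] <- config$photons_per_fluor * config$labeled_fraction *
        fade * cnt
    }
    capped <- st[st$capped %||% FALSE, , drop = FALSE]
    if (nrow(capped) > 0) {
      px <- pmin(n_px - 1L, pmax(0L, floor(capped$start_nt / nt_per_px))) + 1L
      red[, j] <- red[, j] + config$photons_per_fluor * tabulate(px, nbins = n_px)
    }
    if (config$red_nonspecific_per_frame > 0) {
      n_ns <- rpois(1L, config$red_nonspecific_per_frame)
      if (n_ns > 0) {
        px <- floor(runif(n_ns) * n_px) + 1L
        red[, j] <- red[, j] + config$photons_per_fluor *
          tabulate(px, nbins = n_px)
      }
    }
  }
  sigma_px <- config$psf_sigma_nm / config$pixel_size_nm
  if (sigma_px > 0) {
    for (j in seq_len(n_fr)) {
      blue[, j] <- gaussian_blur_1d(blue[, j], sigma_px)
      green[, j] <- gaussian_blur_1d(green[, j], sigma_px)
      red[, j] <- gaussian_blur_1d(red[, j], sigma_px)
    }
  }
  if (config$noise) {
    lapply(list(blue = blue, green = green, red = red), function(m) {
      shot <- matrix(rpois(length(m), pmax(m, 0)), nrow(m))
      pmax(shot + matrix(rnorm(length(m), 0, config$read_noise_sd),
                         nrow(m)), 0)
    })
  } else {
    list(blue = blue, green = green, red = red)
  }
  })
  if (config$orientation == "5p_bottom")
    channels <- lapply(channels, function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])
  new_kymograph(channels, config$pixel_size_nm, line_time_s,
                config$orientation,
                metadata = list(
                  lattice_length_nt = scfg$lattice_length_nt,
                  nm_per_nt = nm_per_nt,
                  condition = attr(scfg, "condition") %||% NA_character_,
                  seed = scfg$seed %||% NA_integer_,
                  frame_times_min = t_frames_min))
}

#' Render the trap force trace implied by an event log
#'
#' Maps lattice coverage linearly onto the force between the optical traps:
#' bare RPA-coated ssDNA at `F_bare` (15 pN) falling to `F_full` (1 pN) at
#' full filament coverage, plus optional Gaussian noise.
#'
#' @param log An `event_log`.
#' @param F_bare,F_full Endpoint forces in pN.
#' @param sample_rate_hz Output sampling rate.
#' @param noise_sd Gaussian force noise SD in pN (0 disables).
#' @param seed RNG seed for the noise draws.
#' @return A `force_trace`: data frame with `time_s`, `force_pN` and a
#'   `sample_rate_hz` attribute.
#' @export
render_force <- function(log, F_bare = 15, F_full = 1, sample_rate_hz = 30,
                         noise_sd = 0, seed = NULL) {
  stopifnot(inherits(log, "event_log"), is.finite(F_bare), is.finite(F_full),
            sample_rate_hz > 0, noise_sd >= 0)
  t_s <- seq(0, log$config$duration_min * 60, by = 1 / sample_rate_hz)
  occ <- occupancy_timeseries(log, t_s / 60)
  cov <- vapply(occ, `[[`, numeric(1), "coverage")
  f <- F_bare + (F_full - F_bare) * cov
  if (noise_sd > 0)
    f <- f + with_seed(seed, rnorm(length(f), 0, noise_sd))
  new_force_trace(t_s, f, sample_rate_hz)
}

new_force_trace <- function(time_s, force_pN, sample_rate_hz) {
  stopifnot(all(is.finite(force_pN)), !is.unsorted(time_s, strictly = TRUE))
  structure(data.frame(time_s = time_s, force_pN = force_pN),
            sample_rate_hz = sample_rate_hz,
            class = c("force_trace", "data.frame"))
}

#' Simulate a photobleaching staircase trace
#'
#' `n_fluorophores` fluorophores each bleach after an independent
#' exponential time; the recorded intensity is the number still fluorescing
#' times `unit_intensity`, plus Gaussian noise.  The true bleach frames are
#' recorded for step-detection benchmarking.
#'
#' @param n_fluorophores Number of fluorophores at frame 1 (`>= 0`).
#' @param unit_intensity Intensity contributed by one fluorophore.
#' @param bleach_rate Bleaching rate per second.
#' @param noise_sigma Gaussian noise SD.
#' @param seed RNG seed.
#' @param n_frames Number of frames.
#' @param frame_dt_s Frame duration, seconds.
#' @return An `intensity_trace`: data frame with `frame`, `time_s`,
#'   `intensity` and `true_count`, plus a `true_change_frames` attribute
#'   (frame after which each bleach step takes effect).
#' @export
render_bleach_trace <- function(n_fluorophores, unit_intensity = 1,
                                bleach_rate = 0.5, noise_sigma = 0,
                                seed = NULL, n_frames = 200,
                                frame_dt_s = 0.1) {
  stopifnot(n_fluorophores >= 0, unit_intensity > 0, bleach_rate >= 0,
            noise_sigma >= 0, n_frames >= 1)
  with_seed(seed, {
    t <- (seq_len(n_frames) - 1) * frame_dt_s
    bleach_t <- if (n_fluorophores > 0 && bleach_rate > 0)
      sort(rexp(n_fluorophores, bleach_rate)) else numeric(0)
    count <- n_fluorophores - vapply(t, function(tt) sum(bleach_t <= tt),
                                     integer(1))
    intensity <- unit_intensity * count
    if (noise_sigma > 0)
      intensity <- intensity + rnorm(n_frames, 0, noise_sigma)
    cp <- unique(vapply(bleach_t[bleach_t <= max(t)],
                        function(bt) sum(t < bt), integer(1)))
    structure(data.frame(frame = seq_len(n_frames), time_s = t,
                         intensity = intensity, true_count = count),
              true_change_frames = cp[cp >= 1 & cp < n_frames],
              unit_intensity = unit_intensity,
              class = c("intensity_trace", "data.frame"))
  })
}
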