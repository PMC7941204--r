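# Kymograph quantification: RPA-displacement decay fits, the
# nucleation-counting image pipeline (median filter -> inversion ->
# convolution smoothing -> per-frame peak detection -> saturating
# exponential fit), growth-rate measurement from displaced-signal
# boundaries, and force downsampling.

rpa_channel <- function(kymo) {
  stopifnot(inherits(kymo, "kymograph"))
  kymo$channels$blue
}

frame_times_min <- function(kymo) {
  n_fr <- ncol(kymo$channels[[1]])
  tm <- kymo$metadata$frame_times_min
  if (!is.null(tm) && length(tm) == n_fr) tm
  else (seq_len(n_fr) - 1) * kymo$line_time_s / 60
}

#' Quantify RPA displacement from a kymograph
#'
#' Sums the RPA (blue) channel per frame, normalizes to the mean of the
#' first 3 frames, and fits the decay
#' \deqn{y(t) = (1-b)\,e^{-kt} + b}
#' with a floating baseline `b >= 0` (RPA-eGFP never reaches exactly zero
#' in noisy data).  The assembly half-time is defined as `ln 2 / k`.
#'
#' @param kymo A `kymograph` with the RPA signal in the blue channel.
#' @return A `displacement_trace`: data frame with `time_min` and
#'   `intensity` (normalized), plus attributes `k_per_min`, `k_ci`
#'   (approximate 95% Wald interval), `baseline` and `half_time_min`.
#' @export
quantify_displacement <- function(kymo) {
  img <- rpa_channel(kymo)
  tm <- frame_times_min(kymo)
  tot <- colSums(img)
  norm0 <- mean(tot[seq_len(min(3L, length(tot)))])
  if (norm0 <= 0) stop("RPA channel is empty", call. = FALSE)
  y <- tot / norm0
  d <- data.frame(t = tm, y = y)
  k0 <- {
    # crude initial rate from the early log-slope
    yc <- pmax(y - min(y), 1e-3)
    max(1e-4, -coef(lm(log(yc) ~ t, data = data.frame(t = tm, yc = yc)))[[2]])
  }
  fit <- tryCatch(
    nls(y ~ (1 - b) * exp(-k * t) + b, data = d,
        start = list(k = k0, b = max(0, min(y))),
        lower = c(k = 0, b = 0), upper = c(k = Inf, b = 1),
        algorithm = "port"),
    error = function(e) NULL)
  # with a floating baseline, (k, b) is unidentifiable on a trace that
  # barely decays (b -> 1 lets any k fit, and the optimizer may fail
  # outright); refit with b = 0, where a flat trace honestly gives k ~ 0
  if (is.null(fit) || 1 - coef(fit)[["b"]] < 0.05) {
    fit2 <- tryCatch(
      nls(y ~ exp(-k * t), data = d, start = list(k = k0),
          lower = c(k = 0), algorithm = "port",
          control = nls.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit2)) fit <- fit2
    if (is.null(fit))
      stop("displacement fit did not converge", call. = FALSE)
  }
  k <- coef(fit)[["k"]]
  baseline <- if ("b" %in% names(coef(fit))) coef(fit)[["b"]] else 0
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  structure(data.frame(time_min = tm, intensity = y),
            k_per_min = k,
            k_ci = k + c(-1.96, 1.96) * se,
            baseline = baseline,
            half_time_min = log(2) / k,
            class = c("displacement_trace", "data.frame"))
}

# simple 1-D local-maximum peak detector with prominence and separation
# thresholds (prominence = height above the higher of the two bounding
# valleys toward the nearest higher point or signal edge)
find_peaks <- function(x, min_prominence = 0, min_separation = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    left <- if (i > 1) x[seq_len(i - 1)] else numeric(0)
    right <- if (i < n) x[(i + 1):n] else numeric(0)
    hl <- which(left >= h); hr <- which(right >= h)
    j1 <- if (length(hl)) max(hl) + 1L else 1L
    lmin <- if (j1 <= length(left)) min(left[j1:length(left)]) else h
    j2 <- if (length(hr)) min(hr) - 1L else length(right)
    rmin <- if (j2 >= 1L) min(right[1:j2]) else h
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  promk <- prom[prom >= min_prominence]
  # enforce minimum separation, keeping the most prominent first
  sel <- integer(0)
  for (i in order(promk, decreasing = TRUE)) {
    if (all(abs(keep[i] - sel) >= min_separation)) sel <- c(sel, keep[i])
  }
  sort(sel)
}

boxcar_smooth <- function(x, width = 5L) {
  # reflect-padded moving average
  half <- width %/% 2L
  n <- length(x)
  xp <- c(x[half:1], x, x[n:(n - half + 1L)])
  k <- rep(1 / width, width)
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

# running median along a vector with reflect padding, window must be odd
median_filter <- function(x, width = 25L) {
  if (width %% 2L == 0L) width <- width + 1L
  half <- width %/% 2L
  n <- length(x)
  if (n <= half) return(rep(median(x), n))
  xp <- c(x[half:1], x, x[n:(n - half + 1L)])
  as.numeric(runmed(xp, width)[(half + 1):(half + n)])
}

#' Count filaments over time in an RPA-displacement kymograph
#'
#' Applies, in order: (1) contrast normalization of the blue channel to
#' [0, 1] by its 1st/99th percentiles; (2) a running median along the time
#' axis (25-frame window) for every position row; (3) intensity inversion;
#' (4) boxcar convolution smoothing (5-pixel window) along the position
#' axis and then along the time axis; (5) per-frame peak detection (local
#' maxima with prominence at least 20% of the frame's dynamic range and
#' minimum separation 3 px); (6) a saturating exponential fit of the
#' per-frame counts, \eqn{y = A_{max}(1 - e^{-kt})}.
#'
#' @param kymo A `kymograph` with at least 25 frames.
#' @param median_window Frames in the running-median window (default 25).
#' @param smooth_window Pixels in the boxcar smoothing window (default 5).
#' @param min_prominence_frac Peak prominence threshold as a fraction of
#'   the frame's dynamic range (default 0.2).
#' @param min_separation_px Minimum peak separation (default 3).
#' @param min_range Detectability floor: a processed frame whose dynamic
#'   range (on the contrast-normalized [0, 1] scale) is below this value
#'   contributes zero counts, so filament-free noise does not register.
#' @return A `nucleation_series`: data frame with `time_min` and `count`,
#'   plus attributes `A_max`, `k_per_min`, `degenerate` (TRUE when no
#'   filament was ever detected) and the `nls` fit (or NULL).
#' @export
count_filaments_over_time <- function(kymo, median_window = 25L,
                                      smooth_window = 5L,
                                      min_prominence_frac = 0.2,
                                      min_separation_px = 3L,
                                      min_range = 0.15) {
  img <- rpa_channel(kymo)
  if (ncol(img) < median_window)
    stop(sprintf("need at least %d frames", median_window), call. = FALSE)
  tm <- frame_times_min(kymo)
  # (1) contrast normalization
  qs <- quantile(img, c(0.01, 0.99), names = FALSE)
  if (qs[2] <= qs[1]) qs[2] <- qs[1] + 1
  img <- pmin(pmax((img - qs[1]) / (qs[2] - qs[1]), 0), 1)
  # (2) median filter along time for each position row
  img <- t(apply(img, 1L, median_filter, width = median_window))
  # (3) inversion: filaments become peaks
  img <- 1 - img
  # (4) smoothing along position, then along time
  img <- apply(img, 2L, boxcar_smooth, width = smooth_window)
  img <- t(apply(img, 1L, boxcar_smooth, width = smooth_window))
  # (5) per-frame peak detection
  counts <- vapply(seq_len(ncol(img)), function(j) {
    col <- img[, j]
    rng <- diff(range(col))
    if (rng <= min_range) return(0L)
    length(find_peaks(col, min_prominence = min_prominence_frac * rng,
                      min_separation = min_separation_px))
  }, integer(1))
  # (6) saturating exponential fit
  if (all(counts == 0L)) {
    return(structure(data.frame(time_min = tm, count = counts),
                     A_max = 0, k_per_min = NA_real_, degenerate = TRUE,
                     fit = NULL, class = c("nucleation_series", "data.frame")))
  }
  d <- data.frame(t = tm, y = counts)
  fit <- tryCatch(
    nls(y ~ A * (1 - exp(-k * t)), data = d,
        start = list(A = max(counts), k = 1 / max(tm[2], mean(tm))),
        lower = c(A = 0, k = 0), algorithm = "port"),
    error = function(e) NULL)
  structure(data.frame(time_min = tm, count = counts),
            A_max = if (is.null(fit)) NA_real_ else coef(fit)[["A"]],
            k_per_min = if (is.null(fit)) NA_real_ else coef(fit)[["k"]],
            degenerate = FALSE, fit = fit,
            class = c("nucleation_series", "data.frame"))
}

#' Measure filament growth rates from displaced-signal boundaries
#'
#' For each supplied filament region, localizes the two edges of the dark
#' (displaced) region in every frame at the half-depth crossing of the
#' smoothed intensity profile (subpixel, linear interpolation), fits a
#' least-squares line to edge position versus time, and converts the slope
#' from nm/min to nt/min.  Growth direction is assigned from the kymograph
#' orientation: the edge moving toward the ssDNA 5' end grows 3'->5'.
#'
#' @param kymo A `kymograph`.
#' @param filament_regions A list of regions, each
#'   `list(rows = <pixel range>, frames = <frame range>)` bracketing one
#'   dark filament (rows in image coordinates).
#' @param smooth_window Boxcar width (px) for profile smoothing.
#' @return A data frame of class `growth_events`, one row per edge:
#'   `region`, `edge` (`"5p-side"`/`"3p-side"`), `slope_nm_per_min`
#'   (positive = growth, i.e. dark region expanding), `slope_nt_per_min`,
#'   `direction` (`"3'->5'"` or `"5'->3'"`), `n_frames`.
#' @export
measure_growth_rates <- function(kymo, filament_regions, smooth_window = 5L) {
  img <- rpa_channel(kymo)
  tm <- frame_times_min(kymo)
  px <- kymo$pixel_size_nm
  five_prime_at_top <- kymo$orientation == "5p_top"
  out <- list()
  for (ri in seq_along(filament_regions)) {
    reg <- filament_regions[[ri]]
    rows <- reg$rows
    frames <- reg$frames %||% seq_len(ncol(img))
    if (length(frames) < 5)
      stop("a filament region must persist for at least 5 frames",
           call. = FALSE)
    upper <- lower <- rep(NA_real_, length(frames))
    for (fi in seq_along(frames)) {
      prof <- boxcar_smooth(img[rows, frames[fi]], smooth_window)
      edges <- half_depth_edges(prof)
      if (!is.null(edges)) {
        upper[fi] <- rows[1] - 1 + edges[1]   # image row coordinate, subpixel
        lower[fi] <- rows[1] - 1 + edges[2]
      }
    }
    ok <- !is.na(upper)
    if (sum(ok) < 5) next
    t_min <- tm[frames][ok]
    # slope sign: positive = dark region expanding at that edge
    up_fit <- lm(y ~ t, data = data.frame(t = t_min, y = upper[ok] * px))
    lo_fit <- lm(y ~ t, data = data.frame(t = t_min, y = lower[ok] * px))
    slopes <- c(-coef(up_fit)[[2]], coef(lo_fit)[[2]])  # nm/min, growth > 0
    edge_is_5p <- if (five_prime_at_top) c(TRUE, FALSE) else c(FALSE, TRUE)
    out[[length(out) + 1L]] <- data.frame(
      region = ri,
      edge = ifelse(edge_is_5p, "5p-side", "3p-side"),
      slope_nm_per_min = slopes,
      slope_nt_per_min = sign(slopes) * nm_rate_to_nt_rate(abs(slopes)),
      direction = ifelse(edge_is_5p, "3'->5'", "5'->3'"),
      n_frames = sum(ok))
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(region = integer(0), edge = character(0),
                  slope_nm_per_min = numeric(0), slope_nt_per_min = numeric(0),
                  direction = character(0), n_frames = integer(0))
  class(res) <- c("growth_events", "data.frame")
  res
}

# subpixel half-depth crossings of a valley profile; returns c(upper, lower)
# positions (1-based, fractional) or NULL when no depression is resolvable
half_depth_edges <- function(prof) {
  n <- length(prof)
  imin <- which.min(prof)
  baseline <- max(prof)
  depth <- baseline - prof[imin]
  if (depth <= 0) return(NULL)
  level <- prof[imin] + depth / 2
  # walk outward from the minimum to the first crossing on each side
  up <- NA_real_
  if (imin > 1) {
    for (i in imin:2) {
      if (prof[i - 1] >= level && prof[i] < level) {
        up <- (i - 1) + (prof[i - 1] - level) / (prof[i - 1] - prof[i])
        break
      }
    }
  }
  lo <- NA_real_
  if (imin < n) {
    for (i in imin:(n - 1)) {
      if (prof[i + 1] >= level && prof[i] < level) {
        lo <- (i + 1) - (prof[i + 1] - level) / (prof[i + 1] - prof[i])
        break
      }
    }
  }
  if (is.na(up) || is.na(lo)) return(NULL)
  c(up, lo)
}

#' Downsample a force trace by block averaging
#'
#' Non-overlapping block means; a trailing partial block is dropped.
#'
#' @param trace A `force_trace` (see [render_force()]) or any data frame
#'   with `time_s` and `force_pN` plus a `sample_rate_hz` attribute.
#' @param target_hz Output rate; must not exceed the source rate (default
#'   3 Hz, the conventional plotting rate for these experiments).
#' @return A `force_trace` at `target_hz` (block-mean force, block-start
#'   times).
#' @export
downsample_force <- function(trace, target_hz = 3) {
  src_hz <- attr(trace, "sample_rate_hz")
  stopifnot(!is.null(src_hz))
  if (target_hz > src_hz)
    stop("target rate exceeds source sample rate", call. = FALSE)
  block <- floor(src_hz / target_hz)
  n <- (nrow(trace) %/% block) * block
  if (n == 0) stop("trace shorter than one block", call. = FALSE)
  idx <- rep(seq_len(n %/% block), each = block)
  f <- as.numeric(tapply(trace$force_pN[seq_len(n)], idx, mean))
  t <- trace$time_s[seq(1, n, by = block)]
  new_force_trace(t, f, src_hz / block)
}
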