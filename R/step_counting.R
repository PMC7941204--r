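# Photobleaching step analysis: change-point detection by greedy binary
# segmentation under a Gaussian likelihood with a BIC acceptance rule,
# unit-intensity calibration from double-Gaussian step-size histograms,
# protomer counting, and cluster growth-event detection.

# best single split of x[lo..hi]: returns c(index of last point of the left
# segment, RSS reduction); NA when the segment cannot be split
best_split <- function(x, lo, hi, min_seg = 2L) {
  n <- hi - lo + 1L
  if (n < 2L * min_seg) return(c(NA_real_, 0))
  seg <- x[lo:hi]
  cs <- cumsum(seg)
  cs2 <- cumsum(seg^2)
  k <- seq.int(min_seg, n - min_seg)     # left segment sizes
  rss_l <- cs2[k] - cs[k]^2 / k
  rss_r <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  rss0 <- cs2[n] - cs[n]^2 / n
  red <- rss0 - (rss_l + rss_r)
  i <- which.max(red)
  c(lo + k[i] - 1L, red[i])
}

#' Detect photobleaching steps by change-point fitting
#'
#' Greedy binary segmentation: repeatedly places the change point giving
#' the largest global reduction in residual sum of squares (the
#' maximum-likelihood split under i.i.d. Gaussian noise) and accepts it
#' while the penalized criterion
#' `N log(RSS/N) + penalty_mult * n_cp * log N` improves.  The default
#' `penalty_mult = 3` is stricter than the textbook BIC (1 per change
#' point): the candidate split position is itself optimized within every
#' segment, which inflates the best spurious reduction well above the
#' chi-squared scale the plain BIC assumes, and the stricter penalty
#' suppresses the resulting over-segmentation (see the package vignette).
#' Zero accepted change points is a valid result for a flat trace.
#'
#' @param trace An `intensity_trace` (see [render_bleach_trace()]) or any
#'   data frame with an `intensity` column, or a bare numeric vector.
#'   At least 10 frames.
#' @param min_seg Minimum segment length in frames.
#' @param penalty_mult Penalty per change point, in units of `log N`.
#' @return A `step_model`: list with `change_points` (frame index of the
#'   last frame before each jump, strictly increasing), `levels` (segment
#'   means, one more than change points), `step_sizes` (level differences,
#'   negative for bleaching), `bic` and `n_frames`.
#' @export
find_steps <- function(trace, min_seg = 2L, penalty_mult = 3) {
  x <- if (is.numeric(trace)) trace else trace$intensity
  n <- length(x)
  if (n < 10) stop("need at least 10 frames", call. = FALSE)
  # numerical floor: reductions at the rounding-error scale are not splits
  scale <- max(abs(x - mean(x)), abs(mean(x)), 1)
  tol <- n * (1e-7 * scale)^2
  rss0 <- max(sum(x^2) - sum(x)^2 / n, 0)
  # phase 1: full greedy expansion (no acceptance test) recording the RSS
  # path; a weak early split must not block strong deeper ones
  segs <- list(c(1L, n))
  cp_seq <- integer(0)
  rss_path <- rss0
  rss <- rss0
  repeat {
    cands <- lapply(segs, function(s) best_split(x, s[1], s[2], min_seg))
    reds <- vapply(cands, `[`, numeric(1), 2)
    reds[is.na(vapply(cands, `[`, numeric(1), 1))] <- -Inf
    j <- which.max(reds)
    if (!is.finite(reds[j]) || reds[j] <= tol) break
    split_at <- as.integer(cands[[j]][1])
    s <- segs[[j]]
    segs[[j]] <- c(s[1], split_at)
    segs[[length(segs) + 1L]] <- c(split_at + 1L, s[2])
    cp_seq <- c(cp_seq, split_at)
    rss <- max(rss - reds[j], 0)
    rss_path <- c(rss_path, rss)
  }
  # phase 2: global model selection over the greedy prefix
  k_seq <- seq_along(rss_path) - 1L
  cost <- n * log(pmax(rss_path, tol) / n) + penalty_mult * k_seq * log(n)
  k_best <- k_seq[which.min(cost)]
  cp <- sort(cp_seq[seq_len(k_best)])
  bounds <- c(0L, cp, n)
  levels <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(x[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  structure(list(change_points = cp,
                 levels = levels,
                 step_sizes = diff(levels),
                 bic = min(cost),
                 n_frames = n),
            class = "step_model")
}

#' @export
print.step_model <- function(x, ...) {
  cat(sprintf("<step_model> %d change point(s) in %d frames; levels: %s\n",
              length(x$change_points), x$n_frames,
              paste(signif(x$levels, 4), collapse = " -> ")))
  invisible(x)
}

#' Calibrate the single-fluorophore intensity from step sizes
#'
#' Bins the magnitudes of bleaching steps (Freedman-Diaconis bin width) and
#' fits the histogram to a double-Gaussian with the second mean constrained
#' to twice the first: single-fluorophore steps around `mu` and
#' double-bleach events around `2 mu`.  If the fitted weight of the second
#' component is below 0.02 (or the two-component fit fails), the
#' calibration falls back to a single Gaussian and flags it.
#'
#' @param step_sizes Numeric vector of step magnitudes (signs are dropped);
#'   at least 30 values.
#' @return A `calibration`: list with `unit_intensity` (mu), `sigma`,
#'   `weights` (normalized component weights), `double_mean` (2 mu),
#'   `r_squared` of the histogram fit, and `single_component` flag.
#' @export
calibrate_unit <- function(step_sizes) {
  s <- abs(step_sizes[is.finite(step_sizes) & step_sizes != 0])
  if (length(s) < 30)
    stop("need at least 30 step sizes", call. = FALSE)
  bw <- 2 * stats::IQR(s) / length(s)^(1 / 3)
  if (bw <= 0) bw <- diff(range(s)) / 10
  breaks <- seq(min(s) - bw, max(s) + bw, by = bw)
  h <- graphics::hist(s, breaks = breaks, plot = FALSE)
  d <- data.frame(x = h$mids, y = h$counts)
  mu0 <- stats::median(s)
  sd0 <- max(stats::mad(s), bw)
  two_gauss <- tryCatch(
    nls(y ~ A1 * exp(-(x - mu)^2 / (2 * s1^2)) +
          A2 * exp(-(x - 2 * mu)^2 / (2 * (s1 * sqrt(2))^2)),
        data = d,
        start = list(A1 = max(d$y), A2 = max(d$y) / 4, mu = mu0, s1 = sd0),
        lower = c(A1 = 0, A2 = 0, mu = bw / 2, s1 = bw / 10),
        algorithm = "port"),
    error = function(e) NULL)
  r2 <- function(fit) {
    if (is.null(fit)) return(NA_real_)
    1 - sum(stats::resid(fit)^2) / sum((d$y - mean(d$y))^2)
  }
  # component weights from predicted counts over the observed bins: the
  # amplitude of a component centered outside the data support is not
  # identifiable, so raw amplitudes cannot be compared directly
  to_weights <- function(A1, A2, mu, s1) {
    c1 <- sum(A1 * exp(-(d$x - mu)^2 / (2 * s1^2)))
    c2 <- sum(A2 * exp(-(d$x - 2 * mu)^2 / (4 * s1^2)))
    c(c1, c2) / (c1 + c2)
  }
  if (!is.null(two_gauss)) {
    cf <- as.list(coef(two_gauss))
    w <- to_weights(cf$A1, cf$A2, cf$mu, cf$s1)
    if (w[2] >= 0.02) {
      return(structure(list(unit_intensity = cf$mu, sigma = cf$s1,
                            weights = w, double_mean = 2 * cf$mu,
                            r_squared = r2(two_gauss),
                            single_component = FALSE),
                       class = "calibration"))
    }
  }
  one_gauss <- tryCatch(
    nls(y ~ A1 * exp(-(x - mu)^2 / (2 * s1^2)), data = d,
        start = list(A1 = max(d$y), mu = mu0, s1 = sd0),
        lower = c(A1 = 0, mu = bw / 2, s1 = bw / 10),
        algorithm = "port"),
    error = function(e) NULL)
  if (is.null(one_gauss))
    stop("calibration fit did not converge", call. = FALSE)
  cf <- as.list(coef(one_gauss))
  structure(list(unit_intensity = cf$mu, sigma = cf$s1,
                 weights = c(1, 0), double_mean = 2 * cf$mu,
                 r_squared = r2(one_gauss), single_component = TRUE),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> unit = %.4g (sigma %.3g), weights %.2f/%.2f%s, R2 = %.3f\n",
              x$unit_intensity, x$sigma, x$weights[1], x$weights[2],
              if (x$single_component) " [single-Gaussian fallback]" else "",
              x$r_squared))
  invisible(x)
}

#' Count protomers in a cluster from its intensity
#'
#' `round(intensity / unit)`, with a floor of 1: a detected cluster cannot
#' contain zero protomers.
#'
#' @param cluster_intensity Numeric vector of cluster intensities.
#' @param calibration A `calibration` from [calibrate_unit()], or a single
#'   positive number taken as the unit intensity.
#' @return Integer protomer counts.
#' @export
count_protomers <- function(cluster_intensity, calibration) {
  mu <- if (inherits(calibration, "calibration"))
    calibration$unit_intensity else calibration
  stopifnot(is.numeric(mu), length(mu) == 1L, mu > 0)
  pmax(1L, as.integer(round(cluster_intensity / mu)))
}

#' Detect cluster growth events and per-molecule growth frequency
#'
#' A cluster grows if its protomer count increases by at least 1 between
#' any two consecutive occupied frames.  The growth frequency of a
#' molecule is the fraction of its clusters that grew at least once.
#'
#' @param tracks A data frame with columns `cluster_id`, `frame`,
#'   `protomers`, and optionally `molecule_id` (single molecule assumed
#'   otherwise).  Rows are the occupied frames of each cluster.
#' @return A list with `events` (data frame: one row per growth event,
#'   columns `molecule_id`, `cluster_id`, `frame`, `delta`), `clusters`
#'   (per-cluster `grew` flag) and `growth_frequency` (per molecule).
#' @export
detect_growth <- function(tracks) {
  stopifnot(all(c("cluster_id", "frame", "protomers") %in% names(tracks)))
  if (is.null(tracks$molecule_id)) tracks$molecule_id <- 1L
  tracks <- tracks[order(tracks$molecule_id, tracks$cluster_id,
                         tracks$frame), , drop = FALSE]
  ev <- list(); grew <- list()
  for (key in split(seq_len(nrow(tracks)),
                    interaction(tracks$molecule_id, tracks$cluster_id,
                                drop = TRUE))) {
    d <- tracks[key, , drop = FALSE]
    if (nrow(d) < 2) {
      grew[[length(grew) + 1L]] <- data.frame(
        molecule_id = d$molecule_id[1], cluster_id = d$cluster_id[1],
        grew = FALSE)
      next
    }
    dp <- diff(d$protomers)
    idx <- which(dp >= 1)
    if (length(idx))
      ev[[length(ev) + 1L]] <- data.frame(
        molecule_id = d$molecule_id[1], cluster_id = d$cluster_id[1],
        frame = d$frame[idx + 1L], delta = dp[idx])
    grew[[length(grew) + 1L]] <- data.frame(
      molecule_id = d$molecule_id[1], cluster_id = d$cluster_id[1],
      grew = length(idx) > 0)
  }
  events <- if (length(ev)) do.call(rbind, ev)
  else data.frame(molecule_id = integer(0), cluster_id = integer(0),
                  frame = integer(0), delta = integer(0))
  clusters <- do.call(rbind, grew)
  freq <- vapply(split(clusters$grew, clusters$molecule_id), mean, numeric(1))
  list(events = events, clusters = clusters, growth_frequency = freq)
}
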