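# Dwell-time kinetics: extraction of dwell records from presence tracks,
# histogram-based exponential fits, cumulative survival curves, medians
# with order-statistic confidence intervals, and the nucleation power law
# k_obs = J c^n.

#' Extract dwell records from presence tracks
#'
#' A dwell is a maximal run of consecutive frames in which a cluster is
#' detected at the same genomic position (positional drift between
#' consecutive detected frames at most `position_tol_px`).  A drift beyond
#' tolerance, or a missed frame, ends the record.  Records touching the
#' final frame are censored: the molecule left the field of view with the
#' cluster still present.
#'
#' @param presence_tracks A data frame with columns `track_id`, `frame`
#'   (integer), `detected` (logical) and `position_px`, or a logical
#'   matrix (tracks x frames) for fixed-position tracks.
#' @param frame_interval_s Seconds per frame (default 30).
#' @param position_tol_px Positional drift tolerance between consecutive
#'   frames (default 1).
#' @return A data frame of class `dwell_records`: `track_id`,
#'   `start_frame`, `n_frames`, `dwell_s` (`n_frames * frame_interval_s`;
#'   a single detected frame counts one interval), `censored`, `position`.
#' @export
extract_dwells <- function(presence_tracks, frame_interval_s = 30,
                           position_tol_px = 1) {
  if (is.matrix(presence_tracks)) {
    m <- presence_tracks
    presence_tracks <- data.frame(
      track_id = rep(seq_len(nrow(m)), ncol(m)),
      frame = rep(seq_len(ncol(m)), each = nrow(m)),
      detected = as.logical(m),
      position_px = 0)
  }
  stopifnot(all(c("track_id", "frame", "detected") %in%
                  names(presence_tracks)))
  if (is.null(presence_tracks$position_px)) presence_tracks$position_px <- 0
  out <- list()
  for (d in split(presence_tracks, presence_tracks$track_id)) {
    d <- d[order(d$frame), , drop = FALSE]
    last_frame <- max(d$frame)
    det <- d[d$detected, , drop = FALSE]
    if (nrow(det) == 0) next
    # a run breaks on a frame gap or a positional jump
    brk <- c(TRUE, diff(det$frame) != 1L |
               abs(diff(det$position_px)) > position_tol_px)
    run <- cumsum(brk)
    for (r in split(det, run)) {
      out[[length(out) + 1L]] <- data.frame(
        track_id = r$track_id[1],
        start_frame = r$frame[1],
        n_frames = nrow(r),
        dwell_s = nrow(r) * frame_interval_s,
        censored = max(r$frame) == last_frame,
        position = mean(r$position_px))
    }
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(track_id = integer(0), start_frame = integer(0),
                  n_frames = integer(0), dwell_s = numeric(0),
                  censored = logical(0), position = numeric(0))
  rownames(res) <- NULL
  class(res) <- c("dwell_records", "data.frame")
  res
}

#' Fit an exponential dwell-time distribution
#'
#' Histogram-based fit, mirroring the conventional analysis of these
#' experiments: dwell times are binned at the frame interval and the bin
#' counts are fitted to `A exp(-t / tau)` by nonlinear least squares.
#' Censored records are excluded by default (their true dwell exceeds the
#' recorded one).
#'
#' @param dwells A `dwell_records` data frame.
#' @param exclude_censored Drop censored records before fitting.
#' @param method `"histogram"` (default) or `"mle"`; the MLE of tau for
#'   exponential data is the sample mean, offered as a cross-check.
#' @param min_records Minimum number of usable records (default 20).
#' @return An `exp_fit`: list with `tau_s`, `r_squared`, `n`, `method`;
#'   degenerate input (all dwells identical) raises an error identifying
#'   the condition.
#' @export
fit_dwell_exponential <- function(dwells, exclude_censored = TRUE,
                                  method = c("histogram", "mle"),
                                  min_records = 20L) {
  method <- match.arg(method)
  d <- if (exclude_censored) dwells[!dwells$censored, , drop = FALSE]
  else dwells
  if (nrow(d) < min_records)
    stop(sprintf("need at least %d uncensored dwell records, have %d",
                 min_records, nrow(d)), call. = FALSE)
  tv <- d$dwell_s
  if (length(unique(tv)) == 1L)
    stop("degenerate dwell distribution: all records identical",
         call. = FALSE)
  frame_s <- min(diff(sort(unique(c(0, tv)))))
  if (method == "mle") {
    return(structure(list(tau_s = mean(tv), r_squared = NA_real_,
                          n = length(tv), method = "mle"),
                     class = "exp_fit"))
  }
  k <- round(tv / frame_s)
  if (all(abs(tv - k * frame_s) < 1e-6 * frame_s)) {
    # frame-quantized dwells: one bin per frame multiple, empty bins kept
    bins <- seq_len(max(k)) * frame_s
    counts <- tabulate(k, nbins = max(k))
  } else {
    bins <- sort(unique(tv))
    counts <- vapply(bins, function(b) sum(tv == b), numeric(1))
  }
  dd <- data.frame(t = bins, y = counts)
  tau0 <- max(mean(tv), frame_s)
  fit <- tryCatch(
    nls(y ~ A * exp(-t / tau), data = dd,
        start = list(A = max(counts) * exp(bins[1] / tau0), tau = tau0),
        lower = c(A = 0, tau = frame_s / 10), algorithm = "port"),
    error = function(e)
      stop("exponential fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((dd$y - mean(dd$y))^2)
  structure(list(tau_s = coef(fit)[["tau"]], r_squared = r2,
                 n = length(tv), method = "histogram"),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> tau = %.4g s (R2 = %s, n = %d, %s)\n",
              x$tau_s, ifelse(is.na(x$r_squared), "-",
                              sprintf("%.3f", x$r_squared)),
              x$n, x$method))
  invisible(x)
}

#' Cumulative survival curve of dwell times
#'
#' `S(t)` is the fraction of records with dwell at least `t`; `S(0) = 1`
#' and the curve is nonincreasing.  Censored records are included: a
#' censored dwell of length `d` is known to survive to `d`, so it
#' contributes to `S(t)` for all `t <= d` (and the curve slightly
#' underestimates late survival, which is reported rather than corrected).
#'
#' @param dwells A `dwell_records` data frame (at least 1 record).
#' @param times Evaluation times in seconds; defaults to frame-interval
#'   multiples covering the data.
#' @return A data frame `time_s`, `survival`, with attribute `tau_s` of an
#'   exponential overlay fitted by least squares on `log S` (NA when
#'   undefined).
#' @export
survival_curve <- function(dwells, times = NULL) {
  tv <- if (is.numeric(dwells)) dwells else dwells$dwell_s
  stopifnot(length(tv) >= 1)
  if (is.null(times)) {
    dt <- min(diff(sort(unique(c(0, tv)))))
    times <- seq(0, max(tv) + dt, by = dt)
  }
  s <- vapply(times, function(t) mean(tv >= t), numeric(1))
  ok <- s > 0 & times > 0
  tau <- if (sum(ok) >= 2) {
    -1 / coef(lm(log(s[ok]) ~ 0 + times[ok]))[[1]]
  } else NA_real_
  structure(data.frame(time_s = times, survival = s),
            tau_s = tau, class = c("survival_curve", "data.frame"))
}

#' Median with an order-statistic confidence interval
#'
#' The interval `[X_(j), X_(n+1-j)]` covers the population median with
#' probability `1 - 2 P(Binom(n, 1/2) < j)`; only a discrete set of
#' levels is achievable for a given `n`, which is why published intervals
#' of this kind carry levels like 96% or 97.6%.  The achievable level
#' closest to (and at least) the request is used and reported.
#'
#' @param dwells A `dwell_records` data frame or a numeric vector
#'   (at least 3 values; intervals are wide and their achievable level low
#'   until n grows).
#' @param conf Requested confidence level (default 0.95).
#' @param n_boot,seed If `n_boot > 0`, a bootstrap percentile interval is
#'   also computed as a cross-check and returned as `boot_ci`.
#' @return List with `median`, `ci` (order-statistic interval),
#'   `achieved_level`, `n`, and optionally `boot_ci`.
#' @export
median_with_ci <- function(dwells, conf = 0.95, n_boot = 0L, seed = NULL) {
  x <- if (is.data.frame(dwells)) dwells$dwell_s else dwells
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 3) stop("need at least 3 records", call. = FALSE)
  j <- seq_len(floor(n / 2))
  lev <- 1 - 2 * pbinom(j - 1, n, 0.5)
  ok <- which(lev >= conf)
  jj <- if (length(ok)) max(ok) else 1L
  res <- list(median = median(x),
              ci = c(x[jj], x[n + 1 - jj]),
              achieved_level = lev[jj],
              n = n)
  if (n_boot > 0) {
    res$boot_ci <- with_seed(seed, {
      meds <- vapply(seq_len(n_boot), function(i)
        median(x[sample.int(n, n, replace = TRUE)]), numeric(1))
      quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    })
  }
  res
}

#' Fit the nucleation power law k_obs = J c^n
#'
#' Nonlinear least squares on the raw scale (the convention used for
#' nucleation-frequency analyses of this kind), started from the log-log
#' regression slope.
#'
#' @param concs_nM Concentrations in nM (at least 3, positive).
#' @param kobs Observed nucleation frequencies (positive).
#' @return A `power_law_fit`: list with `J`, `n`, `n_ci` (approximate 95%
#'   Wald), `r_squared` and the `nls` object.
#' @examples
#' fit <- fit_power_law(c(50, 100, 200), 1e-4 * c(50, 100, 200)^2)
#' fit$n  # 2
#' @export
fit_power_law <- function(concs_nM, kobs) {
  stopifnot(length(concs_nM) == length(kobs), length(concs_nM) >= 3)
  if (any(!is.finite(concs_nM)) || any(concs_nM <= 0) ||
      any(!is.finite(kobs)) || any(kobs <= 0))
    stop("concentrations and rates must be positive and finite",
         call. = FALSE)
  st <- coef(lm(log(kobs) ~ log(concs_nM)))
  d <- data.frame(c = concs_nM, k = kobs)
  pred0 <- exp(st[[1]]) * concs_nM^st[[2]]
  if (max(abs(pred0 - kobs) / kobs) < 1e-10) {
    # data lie exactly on a power law; nls cannot iterate from a perfect fit
    return(structure(list(J = exp(st[[1]]), n = st[[2]],
                          n_ci = c(st[[2]], st[[2]]), r_squared = 1,
                          fit = NULL),
                     class = "power_law_fit"))
  }
  fit <- nls(k ~ exp(lJ) * c^n, data = d,
             start = list(lJ = st[[1]], n = st[[2]]),
             control = nls.control(maxiter = 200))
  cf <- coef(fit)
  se_n <- tryCatch(summary(fit)$coefficients["n", "Std. Error"],
                   error = function(e) NA_real_)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((d$k - mean(d$k))^2)
  structure(list(J = exp(cf[["lJ"]]), n = cf[["n"]],
                 n_ci = cf[["n"]] + c(-1.96, 1.96) * se_n,
                 r_squared = r2, fit = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> k = J c^n with J = %.3g, n = %.3f [%.2f, %.2f]\n",
              x$J, x$n, x$n_ci[1], x$n_ci[2]))
  invisible(x)
}
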