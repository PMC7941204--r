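# Filament localization from RPA-eGFP intensity depressions and
# classification of mediator-spot binding relative to filament ends.

#' Locate a filament from a line-scan intensity profile
#'
#' The filament appears as a depression in the RPA-eGFP channel.  The
#' inverted profile (`max - I`) is fitted with a Gaussian plus constant;
#' the filament center is the fitted mean and the edges are placed at the
#' half-width-at-half-maximum on either side.
#'
#' @param profile A data frame with `position_nm` and `intensity` (the
#'   RPA/eGFP channel), or a `linescan_profile` from
#'   [kymo_linescan()].
#' @param min_depth_frac Minimum depression depth as a fraction of the
#'   profile's intensity range for a detection (default 0.2).
#' @return A `filament_location`: list with `found`, `center_nm`,
#'   `half_width_nm` (HWHM), `edges_nm` (sorted low/high), `depth`, and
#'   the `nls` fit; `found = FALSE` (no error) when no usable depression
#'   exists.
#' @export
locate_filament <- function(profile, min_depth_frac = 0.2) {
  stopifnot(all(c("position_nm", "intensity") %in% names(profile)))
  p <- profile$position_nm
  y <- profile$intensity
  not_found <- structure(list(found = FALSE, center_nm = NA_real_,
                              half_width_nm = NA_real_,
                              edges_nm = c(NA_real_, NA_real_),
                              depth = NA_real_, fit = NULL),
                         class = "filament_location")
  rng <- diff(range(y))
  if (rng <= 0) return(not_found)
  inv <- max(y) - y
  imax <- which.max(inv)
  if (inv[imax] < min_depth_frac * rng) return(not_found)
  # crude width estimate from the half-height crossing around the peak
  above <- inv >= inv[imax] / 2
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  seg <- which(run$values & starts <= imax & ends >= imax)
  w0 <- max(abs(p[ends[seg]] - p[starts[seg]]) / 2, diff(range(p)) / 50)
  fit <- tryCatch(
    nls(inv ~ A * exp(-(p - mu)^2 / (2 * s^2)) + c0,
        data = data.frame(p = p, inv = inv),
        start = list(A = inv[imax], mu = p[imax], s = w0, c0 = min(inv)),
        lower = c(A = 0, mu = min(p), s = 1e-6, c0 = 0),
        upper = c(A = Inf, mu = max(p), s = diff(range(p)), c0 = max(inv)),
        algorithm = "port"),
    error = function(e) NULL)
  if (is.null(fit)) return(not_found)
  cf <- as.list(coef(fit))
  if (cf$A < min_depth_frac * rng) return(not_found)
  hwhm <- cf$s * sqrt(2 * log(2))
  structure(list(found = TRUE, center_nm = cf$mu, half_width_nm = hwhm,
                 edges_nm = c(cf$mu - hwhm, cf$mu + hwhm),
                 depth = cf$A, fit = fit),
            class = "filament_location")
}

#' @export
print.filament_location <- function(x, ...) {
  if (!x$found) cat("<filament_location> not found\n")
  else cat(sprintf("<filament_location> center %.0f nm, edges [%.0f, %.0f] nm\n",
                   x$center_nm, x$edges_nm[1], x$edges_nm[2]))
  invisible(x)
}

#' Classify a mediator spot relative to a filament
#'
#' The spot is called a 5' or 3' end binder when its peak lies within
#' `edge_tol_nm` of the corresponding filament edge (the nearer edge wins
#' if both qualify; an exact tie is flagged), `internal` when strictly
#' between the edges beyond tolerance, and `RPA/ssDNA` when outside the
#' filament beyond tolerance.  Which physical edge is the 5' one follows
#' from the construct orientation.
#'
#' @param spot_peak_nm Fitted peak position of the mediator spot (nm, same
#'   axis as the filament location).
#' @param filament A `filament_location` (must be `found`).
#' @param edge_tol_nm Proximity tolerance (default 200 nm = 2 px).
#' @param orientation `"5p_low"` if the ssDNA 5' end lies at lower
#'   coordinates (default) or `"5p_high"`.
#' @return An `end_binding_call`: list with `label` (one of `"5p-end"`,
#'   `"3p-end"`, `"internal"`, `"RPA/ssDNA"`), `distance_nm` to the
#'   nearest edge, `tie` flag.
#' @export
classify_binding <- function(spot_peak_nm, filament, edge_tol_nm = 200,
                             orientation = c("5p_low", "5p_high")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(filament, "filament_location"), filament$found,
            is.finite(spot_peak_nm), edge_tol_nm >= 0)
  e <- sort(filament$edges_nm)
  d_low <- abs(spot_peak_nm - e[1])
  d_high <- abs(spot_peak_nm - e[2])
  low_is_5p <- orientation == "5p_low"
  near <- min(d_low, d_high)
  tie <- d_low == d_high && d_low <= edge_tol_nm
  label <- if (near <= edge_tol_nm) {
    at_low <- d_low <= d_high
    if (xor(at_low, !low_is_5p)) "5p-end" else "3p-end"
  } else if (spot_peak_nm > e[1] && spot_peak_nm < e[2]) {
    "internal"
  } else {
    "RPA/ssDNA"
  }
  structure(list(label = label, distance_nm = near, tie = tie,
                 spot_peak_nm = spot_peak_nm),
            class = "end_binding_call")
}

#' Colocalization fractions of mediator spots with clusters
#'
#' A spot colocalizes with a cluster when their peak separation is at most
#' one PSF sigma.  Fractions are reported per molecule; molecules with no
#' spots get `NA` (undefined, not zero).
#'
#' @param red_spots Data frame with `molecule_id` and `position_nm` of
#'   mediator spot peaks.
#' @param clusters Data frame with `molecule_id` and `position_nm` of
#'   cluster peaks (or RPA-free patch centers).
#' @param psf_sigma_nm Colocalization radius (default 150).
#' @return Data frame per molecule: `molecule_id`, `n_spots`,
#'   `frac_on_cluster`, `frac_on_ssdna` (= 1 - on-cluster; `NA` when the
#'   molecule has no spots).
#' @export
colocalization_fraction <- function(red_spots, clusters,
                                    psf_sigma_nm = 150) {
  stopifnot(all(c("molecule_id", "position_nm") %in% names(red_spots)),
            all(c("molecule_id", "position_nm") %in% names(clusters)))
  mols <- unique(c(red_spots$molecule_id, clusters$molecule_id))
  out <- lapply(mols, function(m) {
    sp <- red_spots$position_nm[red_spots$molecule_id == m]
    cl <- clusters$position_nm[clusters$molecule_id == m]
    if (length(sp) == 0)
      return(data.frame(molecule_id = m, n_spots = 0L,
                        frac_on_cluster = NA_real_, frac_on_ssdna = NA_real_))
    on <- vapply(sp, function(s)
      length(cl) > 0 && min(abs(cl - s)) <= psf_sigma_nm, logical(1))
    data.frame(molecule_id = m, n_spots = length(sp),
               frac_on_cluster = mean(on), frac_on_ssdna = mean(!on))
  })
  do.call(rbind, out)
}

#' Extract a line-scan profile from one kymograph frame
#'
#' @param kymo A `kymograph`.
#' @param frame Frame (column) index.
#' @param channel Channel name (default `"blue"`).
#' @return A `linescan_profile` data frame with `position_nm` and
#'   `intensity`.
#' @export
kymo_linescan <- function(kymo, frame, channel = "blue") {
  stopifnot(inherits(kymo, "kymograph"))
  v <- kymo$channels[[channel]][, frame]
  structure(data.frame(
    position_nm = (seq_along(v) - 0.5) * kymo$pixel_size_nm,
    intensity = v),
    class = c("linescan_profile", "data.frame"))
}

#' Locate a fluorescent spot in a line-scan profile
#'
#' Gaussian peak fit (plus constant background) of a diffraction-limited
#' spot, e.g. a labeled mediator complex in the red channel.
#'
#' @param profile A data frame with `position_nm` and `intensity`.
#' @param min_height_frac Minimum peak height as a fraction of the
#'   intensity range for a detection.
#' @return List with `found`, `center_nm`, `sigma_nm`, `height`.
#' @export
locate_spot <- function(profile, min_height_frac = 0.2) {
  stopifnot(all(c("position_nm", "intensity") %in% names(profile)))
  p <- profile$position_nm
  y <- profile$intensity
  rng <- diff(range(y))
  if (rng <= 0) return(list(found = FALSE, center_nm = NA_real_,
                            sigma_nm = NA_real_, height = NA_real_))
  imax <- which.max(y)
  fit <- tryCatch(
    nls(y ~ A * exp(-(p - mu)^2 / (2 * s^2)) + c0,
        data = data.frame(p = p, y = y),
        start = list(A = y[imax] - min(y), mu = p[imax],
                     s = diff(range(p)) / 20, c0 = min(y)),
        lower = c(A = 0, mu = min(p), s = 1e-6, c0 = 0),
        algorithm = "port"),
    error = function(e) NULL)
  if (is.null(fit)) return(list(found = FALSE, center_nm = NA_real_,
                                sigma_nm = NA_real_, height = NA_real_))
  cf <- as.list(coef(fit))
  if (cf$A < min_height_frac * rng)
    return(list(found = FALSE, center_nm = NA_real_, sigma_nm = NA_real_,
                height = NA_real_))
  list(found = TRUE, center_nm = cf$mu, sigma_nm = cf$s, height = cf$A)
}
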