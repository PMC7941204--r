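# Polymer elasticity: Marko-Siggia worm-like chain (dsDNA), extensible
# freely-jointed chain (ssDNA), series combinations for gapped molecules,
# force-extension curve generation and fitting, and ssDNA gap-length
# inference from contour-length increases.

#' Worm-like chain force at a given extension (Marko-Siggia)
#'
#' \deqn{F = (k_BT/L_p)\left[\frac{1}{4(1-x/L_c)^2} - \frac14 +
#'   \frac{x}{L_c}\right]}
#'
#' @param extension Extension(s) `x`, same length unit as `Lc`;
#'   `0 <= x < Lc`.
#' @param Lc Contour length.
#' @param Lp Persistence length in nm (default 50 for B-form dsDNA).
#' @param kBT Thermal energy in pN nm (default 4.11, 25 degrees C).
#' @param length_unit_nm How many nm one unit of `extension`/`Lc`
#'   represents (1 = nm, 1000 = um).
#' @return Force(s) in pN.
#' @examples
#' wlc_force(25, Lc = 50, Lp = 50) # x/Lc = 0.5 -> 0.10275 pN
#' @export
wlc_force <- function(extension, Lc, Lp = 50, kBT = 4.11,
                      length_unit_nm = 1) {
  stopifnot(Lc > 0, Lp > 0, kBT > 0, length_unit_nm > 0)
  if (any(!is.finite(extension)) || any(extension < 0))
    stop("`extension` must be finite and >= 0", call. = FALSE)
  if (any(extension >= Lc))
    stop("`extension` must be < Lc (WLC diverges at full extension)",
         call. = FALSE)
  x <- extension / Lc
  (kBT / Lp) * (1 / (4 * (1 - x)^2) - 0.25 + x) * 1
}

# numerically invert Marko-Siggia: extension at given force(s)
wlc_extension <- function(force, Lc, Lp = 50, kBT = 4.11) {
  stopifnot(all(force >= 0), Lc > 0)
  vapply(force, function(f) {
    if (f == 0) return(0)
    uniroot(function(x) wlc_force(x, Lc, Lp, kBT) - f,
            lower = 0, upper = Lc * (1 - 1e-9), tol = 1e-12 * Lc)$root
  }, numeric(1))
}

#' Extensible freely-jointed chain extension at a given force
#'
#' \deqn{x = L_c\left[\coth\frac{Fb}{k_BT} - \frac{k_BT}{Fb}\right]
#'   \left(1 + F/S\right)}
#'
#' @param force Force(s) in pN, `> 0`.
#' @param Lc Contour length.
#' @param kuhn_length Kuhn length `b` in nm (default 1.5 for ssDNA).
#' @param stretch_modulus Stretch modulus `S` in pN (default 800);
#'   `Inf` gives the inextensible FJC.
#' @param kBT Thermal energy in pN nm.
#' @return Extension(s), same unit as `Lc`.
#' @export
fjc_extension <- function(force, Lc, kuhn_length = 1.5,
                          stretch_modulus = 800, kBT = 4.11) {
  if (any(!is.finite(force)) || any(force <= 0))
    stop("`force` must be finite and > 0", call. = FALSE)
  if (Lc <= 0 || kuhn_length <= 0 || stretch_modulus <= 0 || kBT <= 0)
    stop("FJC parameters must be positive", call. = FALSE)
  u <- force * kuhn_length / kBT
  langevin <- 1 / tanh(u) - 1 / u
  Lc * langevin * (1 + force / stretch_modulus)
}

#' Generate a synthetic force-extension curve
#'
#' A gapped molecule is a series combination: at each force the total
#' extension is the WLC extension of the duplex part (contour
#' 0.34 nm/bp) plus the FJC extension of the single-stranded part
#' (contour 0.56 nm/nt).  Gaussian noise is added to the force values.
#'
#' @param ds_bp Base pairs of duplex DNA.
#' @param ss_nt Nucleotides of ssDNA.
#' @param forces_pN Forces at which points are generated.
#' @param Lp_nm,kuhn_nm,stretch_pN Model parameters (see [wlc_force()],
#'   [fjc_extension()]).
#' @param noise_sigma Gaussian SD added to the recorded force, pN.
#' @param seed RNG seed.
#' @return A `fe_curve`: data frame with `extension_um`, `force_pN`, and
#'   attributes `ds_bp`, `ss_nt` (ground truth).
#' @examples
#' fe <- generate_fe_curve(ds_bp = 48502, ss_nt = 0)  # lambda dsDNA
#' @export
generate_fe_curve <- function(ds_bp, ss_nt, forces_pN = seq(0.25, 40, by = 0.25),
                              Lp_nm = 50, kuhn_nm = 1.5, stretch_pN = 800,
                              noise_sigma = 0, seed = NULL) {
  stopifnot(ds_bp >= 0, ss_nt >= 0, ds_bp + ss_nt > 0, all(forces_pN > 0))
  cst <- rad51kin_constants
  Lc_ds_nm <- ds_bp * cst[["ds_rise_nm_per_bp"]]
  Lc_ss_nm <- ss_nt * cst[["ss_contour_nm_per_nt"]]
  x_nm <- numeric(length(forces_pN))
  if (Lc_ds_nm > 0)
    x_nm <- x_nm + wlc_extension(forces_pN, Lc_ds_nm, Lp_nm)
  if (Lc_ss_nm > 0)
    x_nm <- x_nm + fjc_extension(forces_pN, Lc_ss_nm, kuhn_nm, stretch_pN)
  f <- if (noise_sigma > 0)
    forces_pN + with_seed(seed, rnorm(length(forces_pN), 0, noise_sigma))
  else forces_pN
  structure(data.frame(extension_um = x_nm / 1000, force_pN = f),
            ds_bp = ds_bp, ss_nt = ss_nt,
            class = c("fe_curve", "data.frame"))
}

#' Fit a polymer elasticity model to a force-extension curve
#'
#' `model = "WLC"` fits the Marko-Siggia force at the measured extensions
#' (contour length free, persistence length optionally free);
#' `model = "FJC"` and `model = "series"` fit the predicted extension at the
#' measured forces.  The series model is duplex WLC plus ssDNA FJC with
#' both contour lengths free, as appropriate for a gapped molecule.
#' Only points with force inside `force_window` are used (default
#' 2--30 pN, below the overstretching transition).
#'
#' @param curve A data frame with `extension_um` and `force_pN` (e.g. from
#'   [generate_fe_curve()] or [read_fe_curve()]).
#' @param model `"WLC"`, `"FJC"`, or `"series"`.
#' @param force_window Numeric length-2: forces (pN) used in the fit.
#' @param Lp_nm Persistence length; `NULL` frees it (WLC only).
#' @param kuhn_nm,stretch_pN FJC parameters (fixed).
#' @return A `polymer_fit`: list with `model`, `Lc_um` (total contour
#'   length), `Lc_bp`/`Lc_nt` equivalents, `Lp_nm`, for the series model
#'   `Lc_ds_um`/`Lc_ss_um`, `residual_norm`, `n_points` and the `nls` fit.
#' @export
fit_polymer <- function(curve, model = c("WLC", "FJC", "series"),
                        force_window = c(2, 30), Lp_nm = 50,
                        kuhn_nm = 1.5, stretch_pN = 800) {
  model <- match.arg(model)
  stopifnot(all(c("extension_um", "force_pN") %in% names(curve)))
  sel <- curve$force_pN >= force_window[1] & curve$force_pN <= force_window[2] &
    curve$extension_um > 0
  d <- curve[sel, , drop = FALSE]
  if (nrow(d) < 10)
    stop("need at least 10 points inside the force window", call. = FALSE)
  cst <- rad51kin_constants
  x_nm <- d$extension_um * 1000
  f <- d$force_pN
  fit <- switch(model,
    WLC = {
      start <- list(Lc = max(x_nm) * 1.05)
      if (is.null(Lp_nm)) {
        try_fit(nls(f ~ wlc_force(x_nm, Lc, Lp),
                    start = c(start, list(Lp = 50)),
                    lower = c(Lc = max(x_nm) * 1.0001, Lp = 1),
                    algorithm = "port"))
      } else {
        try_fit(nls(f ~ wlc_force(x_nm, Lc, Lp_nm),
                    start = start, lower = c(Lc = max(x_nm) * 1.0001),
                    algorithm = "port"))
      }
    },
    FJC = try_fit(nls(x_nm ~ fjc_extension(f, Lc, kuhn_nm, stretch_pN),
                      start = list(Lc = max(x_nm)),
                      lower = c(Lc = 1), algorithm = "port")),
    series = try_fit(nls(
      x_nm ~ wlc_extension(f, Lc_ds, Lp_nm) +
        fjc_extension(f, Lc_ss, kuhn_nm, stretch_pN),
      start = list(Lc_ds = max(x_nm) * 0.8, Lc_ss = max(x_nm) * 0.2),
      lower = c(Lc_ds = 1, Lc_ss = 0.001), algorithm = "port"))
  )
  cf <- coef(fit)
  res <- switch(model,
    WLC = list(Lc_nm = cf[["Lc"]],
               Lp_nm = if (is.null(Lp_nm)) cf[["Lp"]] else Lp_nm),
    FJC = list(Lc_nm = cf[["Lc"]], Lp_nm = NA_real_),
    series = list(Lc_nm = cf[["Lc_ds"]] + cf[["Lc_ss"]], Lp_nm = Lp_nm,
                  Lc_ds_nm = cf[["Lc_ds"]], Lc_ss_nm = cf[["Lc_ss"]]))
  out <- list(model = model,
              Lc_um = res$Lc_nm / 1000,
              Lc_bp = res$Lc_nm / cst[["ds_rise_nm_per_bp"]],
              Lc_nt = res$Lc_nm / cst[["ss_contour_nm_per_nt"]],
              Lp_nm = res$Lp_nm,
              Lc_ds_um = (res$Lc_ds_nm %||% NA_real_) / 1000,
              Lc_ss_um = (res$Lc_ss_nm %||% NA_real_) / 1000,
              residual_norm = sqrt(sum(stats::resid(fit)^2)),
              n_points = nrow(d),
              fit = fit)
  class(out) <- "polymer_fit"
  out
}

try_fit <- function(expr) {
  fit <- tryCatch(expr, error = function(e)
    stop("fit did not converge: ", conditionMessage(e), call. = FALSE))
  fit
}

#' @export
print.polymer_fit <- function(x, ...) {
  cat(sprintf("<polymer_fit %s> Lc = %.3f um (%.0f bp / %.0f nt), Lp = %s nm, rss = %.3g (n = %d)\n",
              x$model, x$Lc_um, x$Lc_bp, x$Lc_nt,
              if (is.na(x$Lp_nm)) "-" else format(x$Lp_nm, digits = 4),
              x$residual_norm, x$n_points))
  invisible(x)
}

#' Infer the ssDNA gap length from contour-length increase
#'
#' Converting `g` base pairs of duplex into `g` nucleotides of ssDNA
#' changes the total contour length by `g * (0.56 - 0.34)` nm, so the gap
#' length follows from the contour-length difference between the gapped
#' molecule and the intact duplex reference:
#' \deqn{g = \Delta L_c / (0.56 - 0.34)\ \mathrm{nt}}
#'
#' @param gapped_fit A `polymer_fit` of the gapped molecule (the `"series"`
#'   model measures total contour length most accurately).
#' @param reference_ds_fit A `polymer_fit` of the intact duplex reference.
#' @return Gap length in nucleotides (a warning flags negative estimates).
#' @export
gap_length <- function(gapped_fit, reference_ds_fit) {
  stopifnot(inherits(gapped_fit, "polymer_fit"),
            inherits(reference_ds_fit, "polymer_fit"))
  cst <- rad51kin_constants
  dLc_nm <- (gapped_fit$Lc_um - reference_ds_fit$Lc_um) * 1000
  g <- dLc_nm / (cst[["ss_contour_nm_per_nt"]] - cst[["ds_rise_nm_per_bp"]])
  if (g < 0) warning("negative inferred gap length; check the fits")
  g
}

#' Read and write force-extension curves
#'
#' Two-column CSV (`extension_um`, `force_pN`) with `#`-prefixed metadata
#' header lines carrying the ground-truth construct when known.
#'
#' @param curve An `fe_curve` data frame.
#' @param path CSV file path.
#' @export
write_fe_curve <- function(curve, path) {
  stopifnot(all(c("extension_um", "force_pN") %in% names(curve)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ds_bp=%s", attr(curve, "ds_bp") %||% NA), con)
  writeLines(sprintf("# ss_nt=%s", attr(curve, "ss_nt") %||% NA), con)
  writeLines("extension_um,force_pN", con)
  writeLines(sprintf("%.17g,%.17g", curve$extension_um, curve$force_pN), con)
  invisible(path)
}

#' @rdname write_fe_curve
#' @export
read_fe_curve <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- read.csv(text = lines[!grepl("^#", lines)])
  getm <- function(key) {
    m <- sub(sprintf("^# %s=", key), "", grep(sprintf("^# %s=", key), meta,
                                              value = TRUE))
    if (length(m) == 0 || m == "NA") NA_real_ else as.numeric(m)
  }
  structure(data.frame(extension_um = body$extension_um,
                       force_pN = body$force_pN),
            ds_bp = getm("ds_bp"), ss_nt = getm("ss_nt"),
            class = c("fe_curve", "data.frame"))
}
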