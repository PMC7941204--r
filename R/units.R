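#' Physical constants used throughout the package
#'
#' `kBT_pN_nm` is the thermal energy at 25 degrees C in pN nm.
#' `nm_per_nt_at_imaging_force` converts filament-axis distances measured in
#' nm on a kymograph (ssDNA held near 15 pN) into nucleotides.  The single
#' value 0.464 nm/nt reproduces, to within 2%, every published nm/min to
#' nt/min growth-rate pair for this assay (17.9 -> 38.6, 26.4 -> 56.9,
#' 38.1 -> 82.1, 43.8 -> 94.4), and coincides with the freely-jointed-chain
#' extension per nucleotide of ssDNA at 15 pN with the defaults used here
#' (Kuhn length 1.5 nm, contour 0.56 nm/nt, stretch modulus 800 pN).
#'
#' `ds_rise_nm_per_bp` (0.34) and `ss_contour_nm_per_nt` (0.56) are the
#' crystallographic B-form rise and the ssDNA contour length per nucleotide
#' used for gap-length inference from contour-length increases.
#'
#' @format Named numeric scalars.
#' @export
rad51kin_constants <- c(
  kBT_pN_nm                  = 4.11,
  nm_per_nt_at_imaging_force = 0.464,
  ds_rise_nm_per_bp          = 0.34,
  ss_contour_nm_per_nt       = 0.56,
  footprint_nt               = 3
)

#' Convert a growth rate from nm/min to nt/min
#'
#' Distances along the DNA axis in a kymograph are physical (nm); filament
#' growth is naturally expressed in nucleotides occluded per minute.  The
#' conversion divides by the ssDNA extension per nucleotide at the imaging
#' force (see [rad51kin_constants]).
#'
#' @param v_nm_per_min Growth rate(s) in nm/min, `>= 0`.
#' @param nm_per_nt nm of extension per nucleotide; default 0.464.
#' @return Rate(s) in nt/min.
#' @examples
#' nm_rate_to_nt_rate(17.9) # ~38.6 nt/min
#' @export
nm_rate_to_nt_rate <- function(v_nm_per_min,
                               nm_per_nt = rad51kin_constants[["nm_per_nt_at_imaging_force"]]) {
  stopifnot(is.numeric(v_nm_per_min), all(is.finite(v_nm_per_min)),
            all(v_nm_per_min >= 0), nm_per_nt > 0)
  v_nm_per_min / nm_per_nt
}

#' @rdname nm_rate_to_nt_rate
#' @export
nt_rate_to_nm_rate <- function(v_nm_per_min,
                               nm_per_nt = rad51kin_constants[["nm_per_nt_at_imaging_force"]]) {
  stopifnot(is.numeric(v_nm_per_min), all(is.finite(v_nm_per_min)), nm_per_nt > 0)
  v_nm_per_min * nm_per_nt
}
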