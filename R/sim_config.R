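# total nucleation rate per nt per min at the reference concentration with
# no RPA; 0.1 x this on RPA-coated ssDNA reproduces the ~10 min assembly
# half-time of recombinase alone at 500 nM on a full lambda lattice
DEFAULT_J <- 1.2e-3

#' Configuration for the filament-assembly simulator
#'
#' Describes one stochastic assembly experiment: an exposed ssDNA lattice of
#' `lattice_length_nt` nucleotides on which recombinase protomers (footprint
#' `footprint_nt` = 3 nt) nucleate, add at filament ends, dissociate in
#' bursts, and on whose filament 5' ends a mediator complex can transiently
#' "cap", suppressing burst dissociation there.
#'
#' @section Nucleation model:
#' Nucleation deposits either a monomer (1 protomer) or a dimer
#' (2 protomers).  The monomer channel scales linearly with recombinase
#' concentration `c`, the dimer channel with `c^nucleation_exponent_n`
#' (default 2), so the apparent power-law exponent of nucleation counts
#' versus concentration lies between 1 and 2 and is not an integer, in line
#' with a minimal nucleation unit that is a mixture of monomers and dimers.
#' Per free lattice site the two propensities (per nt per min) are
#' \deqn{\lambda_m = J f (c/c_{ref}), \qquad
#'       \lambda_d = J (1-f) (c/c_{ref})^{n}}
#' with `f = monomer_nucleation_fraction` (the fraction of nucleation
#' events that are monomeric at the reference concentration
#' `nucleation_ref_conc_nM`) and `J = nucleation_rate_const_J` the total
#' nucleation rate per nt per min at the reference concentration.  The
#' default `f = 0.4` and reference 470 nM are calibrated so that the
#' fitted apparent exponent of single-round dipping counts over
#' 50--800 nM is about 1.6.
#'
#' @param lattice_length_nt Exposed ssDNA length in nucleotides (default
#'   48502, a fully melted lambda molecule).
#' @param rad51_conc Recombinase concentration in nM.
#' @param nucleation_rate_const_J Total nucleation rate per nt per min at
#'   the reference concentration.
#' @param nucleation_exponent_n Exponent of the dimer nucleation channel;
#'   `0 < n <= 3`.
#' @param monomer_nucleation_fraction Probability that a nucleation event
#'   deposits 1 protomer (else 2) at the reference concentration; in [0,1].
#' @param nucleation_ref_conc_nM Reference concentration (nM) at which
#'   `monomer_nucleation_fraction` applies and at which the total
#'   nucleation rate equals `nucleation_rate_const_J`.
#' @param rpa_suppression Multiplier on the nucleation rate modelling RPA
#'   competition implicitly (1 = no RPA, 0.1 = RPA-coated default).
#' @param footprint_nt Nucleotides occluded per protomer (default 3).
#' @param add_rate_5p,add_rate_3p Protomer additions per min per exposed
#'   filament end (5'-facing and 3'-facing end respectively).
#' @param off_attempt_rate Burst initiations per min per uncapped end.
#' @param burst_mean_protomers Mean of the geometric burst-size law.
#' @param cap_on_rate Mediator bindings per min per exposed, uncapped 5'
#'   filament end.
#' @param cap_dwell_tau_s Mean capped dwell in seconds (condition
#'   dependent; about 11.3 s for the wild-type mediator with ATP, about
#'   20-fold longer for the Walker-box mutant).
#' @param cap_blocks_addition If `TRUE`, a capped 5' end can neither burst
#'   nor accept new protomers (Walker-box-mutant-like behaviour).
#' @param duration_min Simulated time in minutes.
#' @param seed Integer RNG seed or `NULL`.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [sim_preset()] for the mediator condition presets,
#'   [simulate_assembly()].
#' @export
sim_config <- function(lattice_length_nt = 48502L,
                       rad51_conc = 500,
                       nucleation_rate_const_J = DEFAULT_J,
                       nucleation_exponent_n = 2,
                       monomer_nucleation_fraction = 0.4,
                       nucleation_ref_conc_nM = 470,
                       rpa_suppression = 1,
                       footprint_nt = 3L,
                       add_rate_5p = 27.4,
                       add_rate_3p = 27.4,
                       off_attempt_rate = 3.6,
                       burst_mean_protomers = 4,
                       cap_on_rate = 0,
                       cap_dwell_tau_s = 11.3,
                       cap_blocks_addition = FALSE,
                       duration_min = 10,
                       seed = NULL) {
  cfg <- list(
    lattice_length_nt = as.integer(lattice_length_nt),
    rad51_conc = rad51_conc,
    nucleation_rate_const_J = nucleation_rate_const_J,
    nucleation_exponent_n = nucleation_exponent_n,
    monomer_nucleation_fraction = monomer_nucleation_fraction,
    nucleation_ref_conc_nM = nucleation_ref_conc_nM,
    rpa_suppression = rpa_suppression,
    footprint_nt = as.integer(footprint_nt),
    add_rate_5p = add_rate_5p,
    add_rate_3p = add_rate_3p,
    off_attempt_rate = off_attempt_rate,
    burst_mean_protomers = burst_mean_protomers,
    cap_on_rate = cap_on_rate,
    cap_dwell_tau_s = cap_dwell_tau_s,
    cap_blocks_addition = isTRUE(cap_blocks_addition),
    duration_min = duration_min,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  rates <- c("rad51_conc", "nucleation_rate_const_J", "rpa_suppression",
             "add_rate_5p", "add_rate_3p", "off_attempt_rate", "cap_on_rate")
  for (nm in rates) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("`%s` must be a single finite nonnegative number", nm),
           call. = FALSE)
  }
  if (!is.finite(cfg$nucleation_exponent_n) ||
      cfg$nucleation_exponent_n <= 0 || cfg$nucleation_exponent_n > 3)
    stop("`nucleation_exponent_n` must satisfy 0 < n <= 3", call. = FALSE)
  f <- cfg$monomer_nucleation_fraction
  if (!is.finite(f) || f < 0 || f > 1)
    stop("`monomer_nucleation_fraction` must lie in [0, 1]", call. = FALSE)
  if (cfg$footprint_nt < 1L)
    stop("`footprint_nt` must be a positive integer", call. = FALSE)
  if (cfg$lattice_length_nt < cfg$footprint_nt)
    stop("lattice shorter than one protomer footprint", call. = FALSE)
  if (!is.finite(cfg$burst_mean_protomers) || cfg$burst_mean_protomers < 1)
    stop("`burst_mean_protomers` must be >= 1", call. = FALSE)
  if (!is.finite(cfg$cap_dwell_tau_s) || cfg$cap_dwell_tau_s <= 0)
    stop("`cap_dwell_tau_s` must be positive", call. = FALSE)
  if (!is.finite(cfg$duration_min) || cfg$duration_min < 0)
    stop("`duration_min` must be nonnegative", call. = FALSE)
  if (!is.finite(cfg$nucleation_ref_conc_nM) || cfg$nucleation_ref_conc_nM <= 0)
    stop("`nucleation_ref_conc_nM` must be positive", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  lattice: %d nt, [RAD-51] = %g nM, %g min, seed %s\n",
              x$lattice_length_nt, x$rad51_conc, x$duration_min,
              if (is.null(x$seed)) "NULL" else x$seed))
  cat(sprintf("  nucleation: J = %g /nt/min (ref %g nM), dimer exponent %g, monomer fraction %g, RPA factor %g\n",
              x$nucleation_rate_const_J, x$nucleation_ref_conc_nM,
              x$nucleation_exponent_n, x$monomer_nucleation_fraction,
              x$rpa_suppression))
  cat(sprintf("  growth: add 5' %g, 3' %g /min; bursts %g /min (mean %g protomers)\n",
              x$add_rate_5p, x$add_rate_3p, x$off_attempt_rate,
              x$burst_mean_protomers))
  cat(sprintf("  capping: on %g /min, dwell %g s, blocks addition: %s\n",
              x$cap_on_rate, x$cap_dwell_tau_s, x$cap_blocks_addition))
  invisible(x)
}

#' Mediator condition presets for the simulator
#'
#' Returns a [sim_config()] with rate multipliers emulating the qualitative
#' action of the two mediator classes:
#'
#' * `"none"`: recombinase alone on RPA-coated ssDNA (slow nucleation,
#'   symmetric slow net growth of about 18 nm/min per end).
#' * `"BRC2"`: nucleation mediator; nucleation rate x4, growth x1.4.
#' * `"RFS1RIP1_WT"`: growth mediator; transient 5'-end capping
#'   (mean dwell 11.3 s) that suppresses burst dissociation at the capped
#'   end, roughly doubling net 5'-ward growth.
#' * `"K56A"`: Walker-box mutant mediator; capped dwell 20-fold longer and
#'   the cap blocks further protomer addition.
#' * `"combined"`: `"BRC2"` nucleation stimulation plus `"RFS1RIP1_WT"`
#'   capping; fastest overall assembly.
#' * `"dipping"`: bare-ssDNA single-round dipping conditions (no RPA
#'   suppression); used for nucleation power-law measurements.
#'
#' @param condition One of `"none"`, `"BRC2"`, `"RFS1RIP1_WT"`, `"K56A"`,
#'   `"combined"`, `"dipping"`.
#' @param ... Overrides passed on to [sim_config()] after the preset
#'   multipliers are applied.
#' @return A `sim_config`.
#' @examples
#' sim_preset("combined", duration_min = 5, seed = 1)
#' @export
sim_preset <- function(condition = c("none", "BRC2", "RFS1RIP1_WT", "K56A",
                                     "combined", "dipping"),
                       ...) {
  condition <- match.arg(condition)
  base <- list(rpa_suppression = 0.1)  # RPA-coated ssDNA unless dipping
  tweak <- switch(condition,
    none = list(),
    BRC2 = list(nucleation_rate_const_J = 4 * DEFAULT_J,
                add_rate_5p = 1.4 * 27.4, add_rate_3p = 1.4 * 27.4),
    RFS1RIP1_WT = list(cap_on_rate = 50, cap_dwell_tau_s = 11.3,
                       cap_blocks_addition = FALSE),
    K56A = list(cap_on_rate = 50, cap_dwell_tau_s = 11.3 * 20,
                cap_blocks_addition = TRUE),
    combined = list(nucleation_rate_const_J = 4 * DEFAULT_J,
                    add_rate_5p = 1.4 * 27.4, add_rate_3p = 1.4 * 27.4,
                    cap_on_rate = 50, cap_dwell_tau_s = 11.3,
                    cap_blocks_addition = FALSE),
    dipping = list(rpa_suppression = 1, rad51_conc = 200, duration_min = 0.5)
  )
  args <- modifyList(modifyList(base, tweak), list(...))
  cfg <- do.call(sim_config, args)
  attr(cfg, "condition") <- condition
  cfg
}
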