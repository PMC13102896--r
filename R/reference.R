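#' Reference digital-twin configuration
#'
#' All per-patient parameters are dimensionless multiples of a tuned
#' reference configuration (the "reference patient" is the model at the
#' mean scaling factors of [distribution_spec()]). The shipped defaults
#' were tuned so that the mean-factor patient on [fixture_tree()]
#' approximates average adult hemodynamics: aortic pressure near
#' 113/76 mmHg and cardiac output near 4.6 l/min. Use
#' [sensitivity_matrix()] when re-tuning to a different topology.
#'
#' Units are SI throughout: pressures Pa, resistances Pa s/m^3,
#' compliances m^3/Pa, inertances Pa s^2/m^3, elastances Pa/m^3,
#' volumes m^3, heart rate 1/s.
#'
#' @return nested named list of class `cvpd_reference`.
#' @export
default_reference <- function() {
  ref <- list(
    blood = list(rho = 1055, mu = 4.5e-3, gamma_profile = 9),
    wall = list(k1 = 1.2e7, k2 = -2253, k3 = 7.7e4, p0 = 1.0e4),
    heart = list(
      hr = 70 / 60,
      t_rise_frac = 0.35,   # elastance rise fraction of the period
      t_relax_frac = 0.19,  # elastance relaxation fraction
      lv = list(e_min = 1.07e7, e_max = 2.8e8, v0 = 1.0e-5),
      rv = list(e_min = 6.65e6, e_max = 7.5e7, v0 = 1.0e-5),
      la = list(e_la = 2.66e7, v0 = 3.0e-5),
      p_ra = 550,
      # atrioventricular valves open wide (low R, fast filling); the
      # arterial valves carry a larger viscous drop which also damps
      # beat-to-beat afterload oscillation
      valve = list(r_av = 2.5e6, l_av = 5.0e4, r_mv = 5.0e5, l_mv = 1.0e4)
    ),
    pulmonary = list(r_p = 8.0e6, c_pul = 2.0e-7, r_pv_frac = 0.25),
    peripheral = list(
      # four RLC compartments: arteriolar, capillary, venular, venous.
      # Each compartment is a capacitor node followed by a series R-L
      # branch; the arteriolar capacitor sits at the 1D interface and
      # lumps the compliance of the truncated distal vasculature.
      r_ratios = c(0.40, 0.30, 0.20, 0.10),  # fixed resistance ratios
      taus = c(0.60, 0.10, 0.15, 0.30),      # R_i * C_i per compartment [s]
      l_over_r = 5e-4,                       # L_i / R_i [s]
      p_ven = 667
    ),
    coronary = list(alpha = 1.0, beta = 0.5, p_lv_norm = 1.6e4),
    numerics = list(dx = 0.015, safety = 0.5, max_cycles = 40,
                    periodicity_tol = 1e-3, init_p = 1.2e4)
  )
  class(ref) <- "cvpd_reference"
  ref
}

#' @export
print.cvpd_reference <- function(x, ...) {
  cat("<cvpd_reference> reference digital-twin configuration\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Read and write reference configurations
#'
#' YAML serialisation of the reference configuration; round-trips to
#' identical in-memory values.
#'
#' @param reference a `cvpd_reference`.
#' @param path file path.
#' @name reference_io
#' @export
write_reference <- function(reference, path) {
  yaml::write_yaml(unclass(reference), path, precision = 15)
  invisible(path)
}

#' @rdname reference_io
#' @export
read_reference <- function(path) {
  ref <- yaml::read_yaml(path)
  # yaml flattens length-one vectors; restore numeric vectors
  ref$peripheral$r_ratios <- as.numeric(ref$peripheral$r_ratios)
  ref$peripheral$taus <- as.numeric(ref$peripheral$taus)
  class(ref) <- "cvpd_reference"
  ref
}
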