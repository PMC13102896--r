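#' Unit conversion helpers
#'
#' All internal computation uses SI units (Pa, m, s, m^3/s). Reported
#' quantities of interest use conventional clinical units: pressures in
#' mmHg, cardiac output in ml/min, pulse wave velocity in m/s.
#'
#' @param x numeric vector.
#' @return numeric vector in the converted unit.
#' @name units
NULL

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / 133.322

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * 133.322

#' @rdname units
#' @export
m3s_to_mlmin <- function(x) x * 6e7
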