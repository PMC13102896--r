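#' Canonical quantity-of-interest names
#'
#' The eleven QOIs extracted per virtual patient, in their fixed
#' canonical order: six pressure extrema (mmHg), four diagnostic pulse
#' wave velocities (m/s), and cardiac output (ml/min).
#' @export
qoi_names <- function() {
  c("p_rad_dia", "p_rad_sys", "p_ao_dia", "p_ao_sys",
    "p_car_dia", "p_car_sys",
    "pwv_ao", "pwv_cf", "pwv_br", "pwv_fa", "co")
}

#' Systolic and diastolic pressure of one site series
#'
#' @param series pressure series in Pa over one converged cycle.
#' @return named numeric `c(dia, sys)` in mmHg.
#' @export
pressure_extrema <- function(series) {
  if (any(!is.finite(series))) {
    stop("non-finite pressure samples", call. = FALSE)
  }
  c(dia = pa_to_mmhg(min(series)), sys = pa_to_mmhg(max(series)))
}

#' Cardiac output from the aortic root flow
#'
#' Cycle-mean volumetric flow converted to ml/min.
#'
#' @param flow aortic-root flow series in m^3/s over one cycle.
#' @param period cycle duration in s (unused beyond validation; the
#'   series is assumed to span exactly one cycle uniformly).
#' @export
cardiac_output <- function(flow, period = NULL) {
  m3s_to_mlmin(mean(flow))
}

#' Locate the foot of a pulse wave
#'
#' Intersecting-tangent method: the foot is the intersection of the
#' horizontal through the diastolic minimum with the tangent at the
#' point of maximal upstroke slope. The series is treated as cyclic;
#' the returned foot time is in `[0, n*dt)`. A `method = "minimum"`
#' variant returns the time of the diastolic minimum itself.
#'
#' @param series pressure series (one cycle, uniform sampling).
#' @param dt sampling period in s.
#' @param method `"tangent"` (default) or `"minimum"`.
#' @return foot time in s.
#' @export
wave_foot <- function(series, dt, method = c("tangent", "minimum")) {
  method <- match.arg(method)
  n <- length(series)
  imin <- which.min(series)
  if (method == "minimum") return((imin - 1) * dt)
  # rotate so the cycle starts at the diastolic minimum
  rot <- c(series[imin:n], series[seq_len(imin - 1)])
  # upstroke: from the minimum to the (rotated) systolic peak
  ipk <- which.max(rot)
  if (ipk < 3) ipk <- n  # degenerate ordering; search the whole cycle
  slope <- diff(rot[1:ipk]) / dt
  is <- which.max(slope)          # steepest tangent between samples
  t_s <- (is - 0.5) * dt          # midpoint time of that interval
  p_s <- (rot[is] + rot[is + 1]) / 2
  s <- slope[is]
  if (!is.finite(s) || s <= 0) return((imin - 1) * dt)
  t_foot_rot <- t_s - (p_s - rot[1]) / s
  ((t_foot_rot + (imin - 1) * dt) %% (n * dt))
}

#' Foot-to-foot pulse wave velocity
#'
#' Transit time between the feet of the proximal and distal pressure
#' waves (cyclic difference mapped to `(-T/2, T/2]`), divided into the
#' centerline path length.
#'
#' @param p_prox,p_dist pressure series (Pa) over the same cycle with
#'   the same uniform sampling.
#' @param path_length centerline distance between the two sites in m.
#' @param dt sampling period in s.
#' @param method foot detection method, see [wave_foot()].
#' @return PWV in m/s; `NA` (with a warning-free failed marker) when the
#'   transit time is non-positive.
#' @export
pwv_foot_to_foot <- function(p_prox, p_dist, path_length, dt,
                             method = "tangent") {
  stopifnot(length(p_prox) == length(p_dist), path_length > 0)
  T_cyc <- length(p_prox) * dt
  t1 <- wave_foot(p_prox, dt, method)
  t2 <- wave_foot(p_dist, dt, method)
  transit <- (t2 - t1) %% T_cyc
  if (transit > T_cyc / 2) transit <- transit - T_cyc
  if (!is.finite(transit) || transit <= 0) return(NA_real_)
  path_length / transit
}

#' Extract the eleven QOIs from a simulation
#'
#' @param sim a `cvpd_sim` from [run_patient()].
#' @param topology the `cvpd_topology` the patient was built on; used
#'   for the PWV path lengths (cached per topology).
#' @param id patient identifier stored in the record.
#' @param method PWV foot detection method, see [wave_foot()].
#' @return one-row tibble: `id`, the eleven QOI columns of
#'   [qoi_names()], and `failed`.
#' @export
extract_qoi <- function(sim, topology = sim$patient$topology, id = 1L,
                        method = "tangent") {
  empty <- tibble::as_tibble(c(list(id = id),
    stats::setNames(as.list(rep(NA_real_, 11)), qoi_names()),
    list(failed = TRUE)))
  if (sim$failed || !sim$converged) return(empty)
  p <- sim$site_p
  q <- sim$site_q
  if (any(!is.finite(p))) return(empty)
  paths <- pwv_paths(topology)
  plen <- stats::setNames(paths$path_length, paths$pwv)
  site_of <- list(pwv_ao = c("aortic_root", "aortic_distal"),
                  pwv_cf = c("carotid", "femoral"),
                  pwv_br = c("brachial", "radial"),
                  pwv_fa = c("femoral", "ankle"))
  pwv <- vapply(names(site_of), function(nm) {
    pr <- site_of[[nm]]
    pwv_foot_to_foot(p[, pr[1]], p[, pr[2]], plen[[nm]], sim$dt, method)
  }, 0)
  rad <- pressure_extrema(p[, "radial"])
  ao <- pressure_extrema(p[, "aortic_root"])
  car <- pressure_extrema(p[, "carotid"])
  rec <- tibble::tibble(
    id = id,
    p_rad_dia = rad[["dia"]], p_rad_sys = rad[["sys"]],
    p_ao_dia = ao[["dia"]], p_ao_sys = ao[["sys"]],
    p_car_dia = car[["dia"]], p_car_sys = car[["sys"]],
    pwv_ao = pwv[["pwv_ao"]], pwv_cf = pwv[["pwv_cf"]],
    pwv_br = pwv[["pwv_br"]], pwv_fa = pwv[["pwv_fa"]],
    co = cardiac_output(q[, "aortic_root"]),
    failed = FALSE)
  if (any(!is.finite(unlist(rec[qoi_names()])))) rec$failed <- TRUE
  rec
}

#' Read and write QOI tables
#'
#' Tab-delimited table with the canonical header (`id`, the eleven
#' QOI columns, `failed`, plus any label columns added downstream).
#'
#' @param qoi tibble of QOI records.
#' @param path file path.
#' @name qoi_io
#' @export
write_qoi_table <- function(qoi, path) {
  readr::write_tsv(qoi, path)
  invisible(path)
}

#' @rdname qoi_io
#' @export
read_qoi_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
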