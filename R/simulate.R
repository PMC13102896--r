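#' Discretise a patient model for the 1D solver
#'
#' Internal: converts a `cvpd_patient` into the flat structure consumed
#' by the compiled solver (per-node reference areas and wall stiffness,
#' 0-based node indexing, junction/terminal/heart attachments).
#'
#' @param patient a `cvpd_patient` from [apply_parameters()].
#' @param dx target grid spacing in m.
#' @keywords internal
build_solver_model <- function(patient, dx = patient$blood$dx %||% 0.015) {
  seg <- patient$segments
  wall <- patient$wall
  nodes <- unique(c(seg$prox_node, seg$dist_node))
  nid <- stats::setNames(seq_along(nodes) - 1L, nodes)

  segments <- purrr::pmap(seg, function(id, prox_node, dist_node, length,
                                        radius_prox, radius_dist,
                                        body_location) {
    n <- max(3L, as.integer(round(length / dx)) + 1L)
    r <- seq(radius_prox, radius_dist, length.out = n)
    list(n = n, dx = length / (n - 1), A0 = pi * r^2,
         f0 = olufsen_stiffness(r, wall),
         prox_node = unname(nid[prox_node]),
         dist_node = unname(nid[dist_node]))
  })

  ends <- c(seg$prox_node, seg$dist_node)
  deg <- table(ends)
  junction_nodes <- setdiff(names(deg[deg >= 2]), patient$topology$heart_node)
  junctions <- lapply(junction_nodes, function(nd) {
    rows <- rbind(
      cbind(which(seg$prox_node == nd) - 1L, 0L),
      cbind(which(seg$dist_node == nd) - 1L, 1L))
    list(ends = matrix(as.integer(rows), ncol = 2),
         r_node = unname(patient$r_node[nd]))
  })

  beds <- lapply(patient$terminals, function(tm) {
    k <- which(seg$dist_node == tm$node)
    if (length(k) != 1) {
      stop("terminal bed must attach to exactly one distal segment end")
    }
    list(seg = k - 1L, r = tm$r, c = tm$c, l = tm$l,
         p_ven = tm$p_ven, coronary = tm$bed == "coronary",
         alpha = tm$alpha, beta = tm$beta)
  })

  root_seg <- which(seg$prox_node == patient$topology$heart_node)
  if (length(root_seg) != 1) stop("exactly one segment must leave the heart")
  h <- patient$heart
  heart <- list(
    hr = h$hr, t_rise_frac = h$t_rise_frac, t_relax_frac = h$t_relax_frac,
    e_min_lv = h$lv$e_min, e_max_lv = h$lv$e_max, v0_lv = h$lv$v0,
    e_min_rv = h$rv$e_min, e_max_rv = h$rv$e_max, v0_rv = h$rv$v0,
    e_la = h$la$e_la, v0_la = h$la$v0, p_ra = h$p_ra,
    r_av = h$valve$r_av, l_av = h$valve$l_av,
    r_mv = h$valve$r_mv, l_mv = h$valve$l_mv,
    r_p = patient$pulmonary$r_p, c_pul = patient$pulmonary$c_pul,
    r_pv = patient$pulmonary$r_pv_frac * patient$pulmonary$r_p,
    root_seg = root_seg - 1L)

  sites <- purrr::pmap(patient$topology$sites, function(site, segment,
                                                        position) {
    k <- which(seg$id == segment)
    n <- segments[[k]]$n
    list(seg = k - 1L, node = as.integer(round(position * (n - 1))))
  })

  nu <- patient$blood$mu / patient$blood$rho
  list(
    segments = segments,
    junctions = junctions,
    beds = beds,
    heart = heart,
    sites = sites,
    constants = list(
      rho = patient$blood$rho, p0 = wall$p0,
      kr = 2 * (patient$blood$gamma_profile + 2) * pi * nu,
      coronary_p_norm = patient$coronary_p_norm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one digital twin to a periodic solution
#'
#' Advances the coupled 0D-1D model over repeated cardiac cycles until
#' the relative L2 difference of the aortic-root pressure between
#' consecutive cycles drops below `periodicity_tol`, or `max_cycles` is
#' reached. Any numerical failure (divergence, characteristic foot
#' leaving the segment, 0D solver breakdown) is captured as a failed
#' result, never an R error.
#'
#' @param patient a `cvpd_patient` from [apply_parameters()].
#' @param max_cycles maximum number of cardiac cycles.
#' @param periodicity_tol relative L2 cycle-to-cycle tolerance on the
#'   aortic root pressure.
#' @param safety CFL safety factor for the explicit time step.
#' @param dx target grid spacing in m.
#' @param init_p initial arterial pressure (Pa) used to warm-start the
#'   tree and bed states near the operating point.
#' @return an object of class `cvpd_sim`: converged flag, cycle count,
#'   per-site pressure/flow series over the final cycle (tidy tibble via
#'   [generics::tidy()]), cardiac output, lumped-heart series and
#'   conservation diagnostics.
#' @export
run_patient <- function(patient, max_cycles = 40, periodicity_tol = 1e-3,
                        safety = 0.5, dx = 0.015, init_p = 1.2e4) {
  model <- build_solver_model(patient, dx = dx)
  raw <- cpp_run_patient(model, list(max_cycles = as.integer(max_cycles),
                                     periodicity_tol = periodicity_tol,
                                     safety = safety, init_p = init_p))
  site_names <- patient$topology$sites$site
  colnames(raw$site_p) <- site_names
  colnames(raw$site_q) <- site_names
  res <- list(
    converged = raw$converged && !raw$failed,
    failed = raw$failed,
    reason = if (raw$failed) raw$reason else
      if (!raw$converged) "no periodic convergence within max_cycles" else "",
    cycles = raw$cycles,
    dt = raw$dt,
    period = raw$period,
    periodicity_err = raw$periodicity_err,
    time = seq_len(nrow(raw$site_p)) * raw$dt,
    site_p = raw$site_p,
    site_q = raw$site_q,
    co = raw$co,
    bed_inflow = raw$bed_inflow,
    bed_outflow = raw$bed_outflow,
    junction_resid = raw$junction_resid,
    heart = raw$heart,
    patient = patient)
  class(res) <- "cvpd_sim"
  res
}

#' @export
print.cvpd_sim <- function(x, ...) {
  cat("<cvpd_sim> ", if (x$converged) "converged" else
    paste0("NOT converged (", x$reason, ")"),
    " after ", x$cycles, " cycles; CO ",
    signif(m3s_to_mlmin(x$co) / 1000, 3), " l/min\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation result into a long series tibble
#'
#' @param x a `cvpd_sim`.
#' @param ... unused.
#' @return tibble with columns `time` (s), `site`, `pressure_mmhg`,
#'   `flow_mls`.
#' @method tidy cvpd_sim
#' @export
tidy.cvpd_sim <- function(x, ...) {
  p <- tibble::as_tibble(x$site_p)
  q <- tibble::as_tibble(x$site_q)
  p$time <- x$time
  long_p <- tidyr::pivot_longer(p, -"time", names_to = "site",
                                values_to = "pressure_pa")
  q$time <- x$time
  long_q <- tidyr::pivot_longer(q, -"time", names_to = "site",
                                values_to = "flow_m3s")
  out <- dplyr::left_join(long_p, long_q, by = c("time", "site"))
  dplyr::transmute(out, time = .data$time, site = .data$site,
                   pressure_mmhg = pa_to_mmhg(.data$pressure_pa),
                   flow_mls = .data$flow_m3s * 1e6)
}

#' @rdname tidy.cvpd_sim
#' @method glance cvpd_sim
#' @export
glance.cvpd_sim <- function(x, ...) {
  tibble::tibble(converged = x$converged, failed = x$failed,
                 cycles = x$cycles, dt = x$dt, period = x$period,
                 periodicity_err = x$periodicity_err,
                 co_mlmin = m3s_to_mlmin(x$co),
                 junction_resid = x$junction_resid)
}

#' Plot the final-cycle waveforms of a simulation
#'
#' @param object a `cvpd_sim`.
#' @param ... unused.
#' @method autoplot cvpd_sim
#' @export
autoplot.cvpd_sim <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$pressure_mmhg,
                                  colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "pressure [mmHg]",
                  colour = "site") +
    ggplot2::theme_minimal()
}

#' Stable explicit time step for the current state
#'
#' CFL bound `safety * min(dx / (|u| + c))` evaluated over the reference
#' (diastolic) state of a patient's discretised tree.
#'
#' @inheritParams run_patient
#' @export
cfl_dt <- function(patient, safety = 0.5, dx = 0.015) {
  model <- build_solver_model(patient, dx = dx)
  min(vapply(model$segments, function(s) {
    cpp_cfl_dt(s$dx, s$A0, rep(0, s$n), s$A0, s$f0,
               model$constants$rho, model$constants$p0, safety)
  }, 0))
}
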