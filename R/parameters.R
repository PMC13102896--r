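#' Stochastic input-parameter distributions
#'
#' The 17 independent dimensionless scaling factors that define a
#' digital twin, with their default sampling distributions. Resistance
#' factors (`R_perif`, `R_node`, `R_c`) are lognormal to guarantee
#' positivity; all others are normal. Means and standard deviations are
#' on the factor scale; lognormal draws are moment-matched so that the
#' sample mean/sd of the factor reproduce the listed values.
#'
#' Vessel-related factors (`D`, `l`, `R_perif`, `R_node`) additionally
#' receive a per-body-location additive offset, drawn per patient and
#' location as N(0, `offset_multiplier` * sd of the global factor). A
#' physical parameter composes as
#' `value = (factor + offset_bodylocation) * reference`.
#'
#' @return tibble with columns `parameter`, `family`, `mean`, `sd`.
#' @export
distribution_spec <- function() {
  tibble::tribble(
    ~parameter, ~family,     ~mean, ~sd,
    "D",        "normal",    1.05,  0.08,
    "l",        "normal",    1.00,  0.06,
    "R_node",   "lognormal", 1.00,  0.10,
    "k1",       "normal",    1.14,  0.10,
    "k2",       "normal",    0.97,  0.10,
    "k3",       "normal",    1.18,  0.35,
    "R_perif",  "lognormal", 1.05,  0.10,
    "V_ra",     "normal",    1.00,  0.10,
    "E_min",    "normal",    1.00,  0.02,
    "E_max",    "normal",    1.00,  0.02,
    "E_la",     "normal",    1.00,  0.03,
    "R_h",      "normal",    1.00,  0.04,
    "HR",       "normal",    1.00,  0.20,
    "R_p",      "normal",    1.00,  0.04,
    "R_c",      "lognormal", 1.00,  0.20,
    "alpha_c",  "normal",    1.00,  0.10,
    "beta_c",   "normal",    1.00,  0.10
  )
}

#' Parameters that carry body-location offsets
#' @export
offset_parameters <- function() c("D", "l", "R_perif", "R_node")

#' Mean-factor parameter set
#'
#' One-row parameter tibble at the distribution means with all
#' body-location offsets zero; applying it reproduces the reference
#' patient.
#'
#' @param spec a [distribution_spec()] tibble.
#' @param locations body locations to carry offset columns for.
#' @export
mean_parameter_set <- function(spec = distribution_spec(),
                               locations = body_locations()) {
  ps <- tibble::as_tibble(as.list(stats::setNames(spec$mean, spec$parameter)))
  for (p in offset_parameters()) {
    for (loc in locations) ps[[paste0("off_", p, "_", loc)]] <- 0
  }
  ps
}

#' Sample digital-twin parameter sets
#'
#' Draws `n` parameter sets from the factor distributions, including
#' one additive offset per (offset parameter, body location) pair with
#' standard deviation `offset_multiplier` times the factor's sd.
#' Lognormal families are parameterised by moment matching on the
#' factor scale.
#'
#' @inheritParams mean_parameter_set
#' @param n number of parameter sets.
#' @param offset_multiplier multiplier on the factor sd for the
#'   body-location offsets (default 0.15).
#' @return tibble with `n` rows: the 17 factor columns plus
#'   `off_<parameter>_<location>` columns.
#' @export
sample_parameter_sets <- function(n, spec = distribution_spec(),
                                  locations = body_locations(),
                                  offset_multiplier = 0.15) {
  stopifnot(n >= 1)
  draws <- purrr::pmap(spec, function(parameter, family, mean, sd) {
    if (family == "lognormal") {
      if (sd == 0) return(rep(mean, n))
      sdlog <- sqrt(log(1 + (sd / mean)^2))
      meanlog <- log(mean) - sdlog^2 / 2
      stats::rlnorm(n, meanlog, sdlog)
    } else {
      stats::rnorm(n, mean, sd)
    }
  })
  out <- tibble::as_tibble(stats::setNames(draws, spec$parameter))
  for (p in offset_parameters()) {
    s <- spec$sd[spec$parameter == p]
    for (loc in locations) {
      out[[paste0("off_", p, "_", loc)]] <-
        stats::rnorm(n, 0, offset_multiplier * s)
    }
  }
  out
}

ps_offset <- function(params, parameter, location) {
  col <- paste0("off_", parameter, "_", location)
  if (col %in% names(params)) params[[col]] else 0
}

#' Build a patient model from a parameter set
#'
#' Composes the reference configuration with one sampled parameter set:
#' every vessel diameter and length becomes
#' `(factor + offset_bodylocation) * reference`, the Olufsen wall
#' coefficients are scaled globally, and the lumped elements are scaled
#' under the structural constraints: peripheral compartments keep their
#' resistance ratios and RC / L-over-R time constants; the pulmonary and
#' coronary capacitances scale reciprocally to their resistance factors;
#' the valve resistance and inertance share one factor.
#'
#' @param topology a `cvpd_topology`.
#' @param params one-row tibble (or named list) as produced by
#'   [sample_parameter_sets()] or [mean_parameter_set()].
#' @param reference a `cvpd_reference`.
#' @return list of class `cvpd_patient` with resolved physical values.
#' @export
apply_parameters <- function(topology, params,
                             reference = default_reference()) {
  params <- as.list(params)
  fail <- function(field, value) {
    stop(structure(class = c("cvpd_invalid_patient", "error", "condition"),
                   list(message = sprintf(
                     "invalid patient: non-positive %s (%.4g)", field, value),
                     call = NULL, field = field, value = value)))
  }
  seg <- topology$segments
  d_scale <- params$D + unname(vapply(seg$body_location,
                                      function(b) ps_offset(params, "D", b),
                                      0))
  l_scale <- params$l + unname(vapply(seg$body_location,
                                      function(b) ps_offset(params, "l", b),
                                      0))
  lengths <- l_scale * seg$length
  r_prox <- d_scale * seg$radius_prox
  r_dist <- d_scale * seg$radius_dist
  if (any(r_prox <= 0) || any(r_dist <= 0)) {
    i <- which(c(r_prox, r_dist) <= 0)[1] %% nrow(seg)
    i <- if (i == 0) nrow(seg) else i
    fail(paste0("diameter:", seg$id[i]), 2 * min(r_prox[i], r_dist[i]))
  }
  if (any(lengths <= 0)) {
    i <- which(lengths <= 0)[1]
    fail(paste0("length:", seg$id[i]), lengths[i])
  }

  wall <- wall_model(k1 = params$k1 * reference$wall$k1,
                     k2 = params$k2 * reference$wall$k2,
                     k3 = params$k3 * reference$wall$k3,
                     rho = reference$blood$rho,
                     p0 = reference$wall$p0)
  # the stiffness invariant must hold at every applied reference radius
  tryCatch(olufsen_stiffness(c(r_prox, r_dist), wall),
           error = function(e) fail("wall stiffness", params$k3))

  # junction nodal resistance: location of the parent segment (the one
  # whose distal end feeds the junction)
  ends <- c(seg$prox_node, seg$dist_node)
  junction_nodes <- setdiff(names(which(table(ends) >= 2)), topology$heart_node)
  r_node <- vapply(junction_nodes, function(nd) {
    parent <- which(seg$dist_node == nd)
    loc <- seg$body_location[if (length(parent)) parent[1]
                             else which(seg$prox_node == nd)[1]]
    f <- params$R_node + ps_offset(params, "R_node", loc)
    if (f <= 0) fail(paste0("nodal resistance:", nd), f)
    f * topology$r_node_ref
  }, 0)

  per <- reference$peripheral
  term_tbl <- topology$terminals
  if (is.null(term_tbl$tau1)) term_tbl$tau1 <- per$taus[1]
  terminals <- purrr::pmap(term_tbl,
    function(node, r_total, bed, body_location, tau1) {
      if (bed == "coronary") {
        f <- params$R_c
        if (f <= 0) fail(paste0("coronary resistance:", node), f)
        r_tot <- f * r_total
        alpha <- params$alpha_c * reference$coronary$alpha
        beta <- params$beta_c * reference$coronary$beta
      } else {
        f <- params$R_perif + ps_offset(params, "R_perif", body_location)
        if (f <= 0) fail(paste0("peripheral resistance:", node), f)
        r_tot <- f * r_total
        alpha <- 0
        beta <- 0
      }
      r_i <- per$r_ratios * r_tot
      taus <- c(tau1, per$taus[2:4])
      list(node = node, bed = bed,
           r = r_i,
           # RC time constants invariant under resistance scaling, so
           # every capacitance carries the reciprocal of its bed's
           # resistance factor automatically
           c = taus / r_i,
           l = per$l_over_r * r_i,
           p_ven = params$V_ra * per$p_ven,
           alpha = alpha, beta = beta)
    })

  h <- reference$heart
  if (params$HR <= 0) fail("heart rate", params$HR)
  if (params$R_h <= 0) fail("valve resistance", params$R_h)
  e_min_lv <- params$E_min * h$lv$e_min
  e_max_lv <- params$E_max * h$lv$e_max
  if (e_min_lv <= 0 || e_max_lv <= e_min_lv) fail("elastance", e_max_lv)
  heart <- list(
    hr = params$HR * h$hr,
    t_rise_frac = h$t_rise_frac, t_relax_frac = h$t_relax_frac,
    lv = list(e_min = e_min_lv, e_max = e_max_lv, v0 = h$lv$v0),
    rv = list(e_min = params$E_min * h$rv$e_min,
              e_max = params$E_max * h$rv$e_max, v0 = h$rv$v0),
    la = list(e_la = params$E_la * h$la$e_la, v0 = h$la$v0),
    p_ra = params$V_ra * h$p_ra,
    # all valve resistances and inertances share the single R_h factor
    valve = list(r_av = params$R_h * h$valve$r_av,
                 l_av = params$R_h * h$valve$l_av,
                 r_mv = params$R_h * h$valve$r_mv,
                 l_mv = params$R_h * h$valve$l_mv))
  if (params$R_p <= 0) fail("pulmonary resistance", params$R_p)
  pulmonary <- list(r_p = params$R_p * reference$pulmonary$r_p,
                    # reciprocal scaling keeps R*C invariant
                    c_pul = reference$pulmonary$c_pul / params$R_p,
                    r_pv_frac = reference$pulmonary$r_pv_frac)

  structure(list(
    topology = topology,
    segments = tibble::tibble(
      id = seg$id, prox_node = seg$prox_node, dist_node = seg$dist_node,
      length = lengths, radius_prox = r_prox, radius_dist = r_dist,
      body_location = seg$body_location),
    wall = wall,
    r_node = r_node,
    terminals = terminals,
    heart = heart,
    pulmonary = pulmonary,
    blood = reference$blood,
    coronary_p_norm = reference$coronary$p_lv_norm,
    params = tibble::as_tibble(params)
  ), class = "cvpd_patient")
}

#' @export
print.cvpd_patient <- function(x, ...) {
  cat("<cvpd_patient> ", nrow(x$segments), " vessels, HR ",
      signif(x$heart$hr * 60, 3), " bpm\n", sep = "")
  invisible(x)
}
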