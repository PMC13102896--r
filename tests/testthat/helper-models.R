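# shared builders for solver-level tests

# single straight elastic tube as a raw solver model (no heart/beds)
tube_spec <- function(n = 301, length = 1.5, r0 = 0.01, f0 = 8e4,
                      rho = 1055, p0 = 1e4) {
  dx <- length / (n - 1)
  list(n = n, dx = dx, A0 = rep(pi * r0^2, n), f0 = rep(f0, n),
       rho = rho, p0 = p0, r0 = r0, length = length)
}

# run the compiled single-tube experiment
run_tube <- function(tube, nsteps, inflow = numeric(1), prox_bc = 0L,
                     dist_bc = 0L, r_dist = 0, p_out = 667,
                     A_init = NULL, kr = 0, safety = 0.5) {
  dt <- cardiovpd:::cpp_cfl_dt(tube$dx, tube$A0, rep(0, tube$n), tube$A0, tube$f0,
                   tube$rho, tube$p0, safety)
  cardiovpd:::cpp_tube_sim(tube$n, tube$dx, tube$A0, tube$f0, tube$rho, tube$p0,
               kr, dt, as.integer(nsteps), as.integer(prox_bc), inflow,
               as.integer(dist_bc), r_dist, p_out, A_init)
}

# smooth single inflow pulse [m^3/s]
inflow_pulse <- function(nsteps, dt, amplitude = 5e-6, t0 = 0.05,
                         width = 0.02) {
  t <- seq_len(nsteps) * dt
  amplitude * exp(-((t - t0) / width)^2)
}

# straight-line topology: heart -> tube (1 or 2 segments) -> one bed
line_topology <- function(two_segments = FALSE, r_node_ref = 0,
                          length = 0.8, r0 = 0.008) {
  segs <- if (two_segments) {
    tibble::tibble(
      id = c("tube_a", "tube_b"),
      prox_node = c("n0", "n1"), dist_node = c("n1", "n2"),
      length = c(length / 2, length / 2),
      radius_prox = r0, radius_dist = r0,
      body_location = "trunk")
  } else {
    tibble::tibble(id = "tube_a", prox_node = "n0", dist_node = "n2",
                   length = length, radius_prox = r0, radius_dist = r0,
                   body_location = "trunk")
  }
  sites <- if (two_segments) {
    tibble::tibble(site = c("aortic_root", "a_end", "mid", "distal"),
                   segment = c("tube_a", "tube_a", "tube_b", "tube_b"),
                   position = c(0, 1, 0, 1))
  } else {
    tibble::tibble(site = c("aortic_root", "mid", "distal"),
                   segment = "tube_a", position = c(0, 0.5, 1))
  }
  terminals <- tibble::tibble(node = "n2", r_total = 1.4e8,
                              bed = "systemic", body_location = "trunk",
                              tau1 = 0.6)
  arterial_topology(segs, terminals, sites, heart_node = "n0",
                    r_node_ref = r_node_ref)
}

reference_sim <- local({
  cache <- NULL
  function(...) {
    if (is.null(cache)) {
      pat <- apply_parameters(fixture_tree(), mean_parameter_set(),
                              default_reference())
      cache <<- run_patient(pat, ...)
    }
    cache
  }
})
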