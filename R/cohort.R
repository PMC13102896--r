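#' Validate a sampled parameter set against a topology
#'
#' A draw is rejected when the Eq-style composition
#' `(factor + offset) * reference` yields a non-positive physical
#' parameter anywhere in the model (negative diameters, lengths or
#' resistances), mirroring the pre-execution screening of the cohort
#' builder.
#'
#' @inheritParams apply_parameters
#' @return a list with `valid` (logical) and `reason` (string, `""`
#'   when valid).
#' @export
validate_draw <- function(topology, params, reference = default_reference()) {
  tryCatch({
    apply_parameters(topology, params, reference)
    list(valid = TRUE, reason = "")
  }, cvpd_invalid_patient = function(e) {
    list(valid = FALSE, reason = conditionMessage(e))
  })
}

#' Build an initial virtual-patient cohort
#'
#' Samples `n` parameter sets from the factor distributions, rejects
#' draws with non-positive physical parameters before execution, runs
#' every remaining digital twin to a periodic solution, and extracts
#' the eleven QOIs per patient. Simulation failures are recorded as
#' failed rows, never raised.
#'
#' Reproducibility: all random draws derive from `seed`; per-patient
#' simulation is deterministic, so the result is identical for any
#' `workers` count.
#'
#' @param topology a `cvpd_topology`.
#' @param n number of draws attempted (the initial database size N_0).
#' @param seed integer seed for the cohort.
#' @param spec distribution table, see [distribution_spec()].
#' @param reference a `cvpd_reference`.
#' @param workers number of parallel workers (forked; results do not
#'   depend on it).
#' @param controls named list overriding [run_patient()] arguments
#'   (`max_cycles`, `periodicity_tol`, `safety`, `dx`, `init_p`).
#' @return list with `qoi` (tibble: one row per attempted draw that
#'   passed validation), `params` (the sampled factor tibble),
#'   `manifest` (counts + seed), class `cvpd_cohort`.
#' @export
build_cohort <- function(topology, n, seed = 1L,
                         spec = distribution_spec(),
                         reference = default_reference(),
                         workers = 1L, controls = list()) {
  stopifnot(n >= 1)
  set.seed(seed)
  params <- sample_parameter_sets(n, spec,
                                  locations = unique(
                                    topology$segments$body_location))
  ok <- logical(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    v <- validate_draw(topology, params[i, ], reference)
    ok[i] <- v$valid
    reasons[i] <- v$reason
  }
  idx <- which(ok)
  run_one <- function(i) {
    pat <- apply_parameters(topology, params[i, ], reference)
    sim <- do.call(run_patient, c(list(pat), controls))
    extract_qoi(sim, topology, id = i)
  }
  rows <- if (workers > 1) {
    parallel::mclapply(idx, run_one, mc.cores = workers)
  } else {
    lapply(idx, run_one)
  }
  qoi <- dplyr::bind_rows(rows)
  manifest <- tibble::tibble(
    requested = n,
    rejected = sum(!ok),
    failed = sum(qoi$failed),
    completed = sum(!qoi$failed),
    seed = seed)
  stopifnot(manifest$requested ==
              manifest$rejected + manifest$failed + manifest$completed)
  structure(list(qoi = qoi, params = params, manifest = manifest,
                 reject_reasons = reasons[!ok]),
            class = "cvpd_cohort")
}

#' @export
print.cvpd_cohort <- function(x, ...) {
  m <- x$manifest
  cat("<cvpd_cohort> ", m$requested, " requested: ", m$completed,
      " completed, ", m$rejected, " rejected, ", m$failed,
      " failed (seed ", m$seed, ")\n", sep = "")
  invisible(x)
}

#' @method glance cvpd_cohort
#' @export
glance.cvpd_cohort <- function(x, ...) x$manifest

#' @method tidy cvpd_cohort
#' @export
tidy.cvpd_cohort <- function(x, ...) x$qoi

#' Completed (non-failed) QOI records of a cohort
#' @param cohort a `cvpd_cohort` or a QOI tibble.
#' @export
completed_qoi <- function(cohort) {
  qoi <- if (inherits(cohort, "cvpd_cohort")) cohort$qoi else cohort
  dplyr::filter(qoi, !.data$failed)
}

#' Distribution of cohort QOIs against literature targets
#'
#' Density plot of each QOI over the cohort with the literature normal
#' density overlaid.
#'
#' @param qoi QOI tibble (completed records are used).
#' @param literature a [literature_spec()] tibble.
#' @export
plot_qoi_distributions <- function(qoi, literature = literature_spec()) {
  d <- tidyr::pivot_longer(completed_qoi(qoi)[, qoi_names()],
                           dplyr::everything(),
                           names_to = "qoi", values_to = "value")
  ref <- dplyr::group_by(d, .data$qoi)
  ref <- dplyr::summarise(ref, lo = min(.data$value), hi = max(.data$value))
  ref <- dplyr::left_join(ref, literature, by = "qoi")
  curves <- dplyr::reframe(ref, value = seq(min(.data$lo, .data$mean - 3 *
      .data$sd), max(.data$hi, .data$mean + 3 * .data$sd), length.out = 200),
    dens = stats::dnorm(.data$value, .data$mean, .data$sd),
    .by = "qoi")
  ggplot2::ggplot(d, ggplot2::aes(.data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(.data$value, .data$dens),
                       colour = "grey30", linetype = 2) +
    ggplot2::facet_wrap(~qoi, scales = "free") +
    ggplot2::labs(x = NULL, y = "density") +
    ggplot2::theme_minimal()
}
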