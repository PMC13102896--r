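#' Run the full virtual-patient-database pipeline
#'
#' Executes the cohort steps in order: sample and simulate an initial
#' cohort of `n` digital twins, resample it against the literature
#' targets, and assign sex and age labels. Returns the labelled VPD
#' table and a run report.
#'
#' @param topology a `cvpd_topology` (default: the reduced fixture
#'   tree).
#' @param n initial cohort size (N_0 role).
#' @param seed master seed; stage seeds derive from it.
#' @param nl_fraction literature dataset size as a fraction of the
#'   completed cohort (default 0.75).
#' @param k_th resampling threshold (default 8).
#' @param spec distribution table, see [distribution_spec()].
#' @param literature literature targets, see [literature_spec()].
#' @param reference a `cvpd_reference`.
#' @param workers parallel workers for the simulations.
#' @param controls solver control overrides, see [build_cohort()].
#' @param out_dir optional directory: when given, all stage outputs are
#'   written as delimited text (QOI tables, manifest, report).
#' @return list of class `cvpd_pipeline`: `vpd` (labelled QOI tibble),
#'   `cohort`, `resample`, `report` (one-row tibble of stage counts and
#'   scores).
#' @export
run_pipeline <- function(topology = fixture_tree(), n = 200, seed = 1L,
                         nl_fraction = 0.75, k_th = 8,
                         spec = distribution_spec(),
                         literature = literature_spec(),
                         reference = default_reference(),
                         workers = 1L, controls = list(),
                         out_dir = NULL) {
  stopifnot(nl_fraction > 0, nl_fraction <= 1, k_th >= 0, k_th <= 11)
  cohort <- build_cohort(topology, n, seed = seed, spec = spec,
                         reference = reference, workers = workers,
                         controls = controls)
  ok <- completed_qoi(cohort)
  if (nrow(ok) < 1) stop("pipeline stage 'cohort': no completed runs")
  n_l <- max(1L, floor(nl_fraction * nrow(ok)))
  rs <- resample_vpd(cohort$qoi, n_l = n_l, k_th = k_th,
                     spec = literature, seed = seed + 1L)
  vpd <- rs$selected
  if (nrow(vpd) >= 4) {
    vpd <- classify_vpd(vpd, "sex", seed = seed + 2L)
    attr(vpd, "assignment") <- NULL
    age <- classify_vpd(vpd, "age", seed = seed + 3L)
    vpd$age <- age$age
  } else {
    vpd$sex <- NA_character_
    vpd$age <- NA_character_
  }
  report <- dplyr::bind_cols(
    cohort$manifest,
    tibble::tibble(n_l = rs$n_l, k_th = k_th,
                   n_vpd = nrow(vpd),
                   f_rs_before = rs$f_rs_before,
                   f_rs_after = rs$f_rs_after))
  out <- structure(list(vpd = vpd, cohort = cohort, resample = rs,
                        report = report), class = "cvpd_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_qoi_table(cohort$qoi, file.path(out_dir, "cohort_qoi.tsv"))
    write_qoi_table(vpd, file.path(out_dir, "vpd.tsv"))
    readr::write_tsv(report, file.path(out_dir, "report.tsv"))
    readr::write_tsv(group_moments(vpd, "sex"),
                     file.path(out_dir, "moments_sex.tsv"))
    readr::write_tsv(group_moments(vpd, "age"),
                     file.path(out_dir, "moments_age.tsv"))
  }
  out
}

#' @export
print.cvpd_pipeline <- function(x, ...) {
  r <- x$report
  cat("<cvpd_pipeline> ", r$requested, " requested -> ", r$completed,
      " completed -> ", r$n_vpd, " in final VPD (F_rs ",
      signif(r$f_rs_before, 4), " -> ", signif(r$f_rs_after, 4), ")\n",
      sep = "")
  invisible(x)
}

#' @method glance cvpd_pipeline
#' @export
glance.cvpd_pipeline <- function(x, ...) x$report

#' Sensitivity matrix of the QOIs to the input factors
#'
#' Central-difference relative sensitivities around the mean-factor
#' reference patient: entry (q, p) approximates the percent change of
#' QOI q per percent change of factor p. Intended for re-tuning the
#' reference configuration to a new topology. Perturbed runs that fail
#' yield `NA` entries.
#'
#' @param topology a `cvpd_topology`.
#' @param reference a `cvpd_reference`.
#' @param parameters which factors to perturb (default: all 17).
#' @param perturbation relative perturbation (default 0.01, i.e. 1%).
#' @param controls solver control overrides.
#' @return matrix: rows = the eleven QOIs, columns = parameters.
#' @export
sensitivity_matrix <- function(topology = fixture_tree(),
                               reference = default_reference(),
                               parameters = distribution_spec()$parameter,
                               perturbation = 0.01, controls = list()) {
  base_ps <- mean_parameter_set()
  run_qoi <- function(ps) {
    sim <- tryCatch(
      do.call(run_patient,
              c(list(apply_parameters(topology, ps, reference)), controls)),
      error = function(e) NULL)
    if (is.null(sim)) return(rep(NA_real_, 11))
    q <- extract_qoi(sim, topology)
    if (q$failed) rep(NA_real_, 11) else unlist(q[, qoi_names()])
  }
  q0 <- run_qoi(base_ps)
  out <- matrix(NA_real_, nrow = 11, ncol = length(parameters),
                dimnames = list(qoi_names(), parameters))
  for (p in parameters) {
    up <- base_ps; up[[p]] <- up[[p]] * (1 + perturbation)
    dn <- base_ps; dn[[p]] <- dn[[p]] * (1 - perturbation)
    qu <- run_qoi(up)
    qd <- run_qoi(dn)
    out[, p] <- (qu - qd) / (2 * perturbation * q0)
  }
  out
}

#' Write the reduced fixture tree to a topology file
#'
#' @param path output file path.
#' @return the path, invisibly.
#' @export
make_fixture_tree <- function(path) {
  write_topology(fixture_tree(), path)
}
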