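#' Literature targets for the eleven QOIs
#'
#' Population mean and standard deviation per QOI, used both to draw
#' the synthetic literature datasets for resampling and as the
#' normalisation of the resampling quality score. The carotid and
#' radial diastolic targets are set 2 mmHg below the aortic diastolic
#' mean with an assumed 10 mmHg standard deviation, following the
#' invasive observation that diastolic pressure falls only slightly
#' towards the periphery.
#'
#' @return tibble with columns `qoi`, `mean`, `sd`.
#' @export
literature_spec <- function() {
  tibble::tribble(
    ~qoi,        ~mean,  ~sd,
    "p_rad_dia",  73.6,  10,
    "p_rad_sys", 128.0,  20,
    "p_ao_dia",   75.6,  12.7,
    "p_ao_sys",  113.0,  11.2,
    "p_car_dia",  73.6,  10,
    "p_car_sys", 116.0,  15.1,
    "pwv_ao",      7.63,  1.56,
    "pwv_cf",      8.1,   1.80,
    "pwv_br",     10.43,  1.66,
    "pwv_fa",      9.79,  1.78,
    "co",       4570,  1090
  )
}

#' Read and write literature target tables
#' @param spec tibble as returned by [literature_spec()].
#' @param path file path.
#' @name literature_io
#' @export
write_literature_spec <- function(spec, path) {
  readr::write_tsv(spec, path)
  invisible(path)
}

#' @rdname literature_io
#' @export
read_literature_spec <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Draw a synthetic literature dataset per QOI
#'
#' For each QOI, `n_l` independent normal draws at the literature mean
#' and standard deviation, independent of the virtual cohort.
#'
#' @param n_l number of draws per QOI (the maximum size of the
#'   resampled database).
#' @param spec a [literature_spec()] tibble.
#' @return tibble with `n_l` rows, one column per QOI.
#' @export
generate_literature_dataset <- function(n_l, spec = literature_spec()) {
  stopifnot(n_l >= 1)
  draws <- purrr::pmap(spec, function(qoi, mean, sd) {
    stats::rnorm(n_l, mean, sd)
  })
  tibble::as_tibble(stats::setNames(draws, spec$qoi))
}

#' Match literature values to their closest cohort values
#'
#' Greedy nearest-value matching without replacement: literature values
#' are processed in ascending order and each is matched to the nearest
#' not-yet-matched cohort value (ties resolved to the lower cohort
#' index). Every cohort value is matched at most once.
#'
#' @param lit_values numeric vector of literature draws.
#' @param vpd_values numeric vector of cohort values.
#' @return integer vector, same length as `lit_values`: the matched
#'   index into `vpd_values` per literature value (in the original,
#'   unsorted order of `lit_values`).
#' @export
match_closest <- function(lit_values, vpd_values) {
  n_l <- length(lit_values)
  n_0 <- length(vpd_values)
  if (n_l > n_0) stop("more literature values than cohort values")
  ord <- order(lit_values)
  avail <- rep(TRUE, n_0)
  out <- integer(n_l)
  for (j in ord) {
    d <- abs(vpd_values - lit_values[j])
    d[!avail] <- Inf
    k <- which.min(d)  # ties: lowest index
    out[j] <- k
    avail[k] <- FALSE
  }
  out
}

#' Resample a cohort against literature datasets
#'
#' For each of the eleven QOIs a literature dataset of size `n_l` is
#' drawn and matched (without replacement) to the cohort; a patient's
#' match count `K_j` is the number of QOIs in which one of its values
#' was selected. Patients with `K_j >= k_th` form the resampled
#' database. Failed patients are excluded before matching.
#'
#' @param qoi cohort QOI tibble (as from [build_cohort()]`$qoi`).
#' @param n_l literature dataset size per QOI; defaults to 75% of the
#'   completed cohort size.
#' @param k_th selection threshold on the match count (0..11).
#' @param spec a [literature_spec()] tibble.
#' @param seed integer seed for the literature draws.
#' @return list of class `cvpd_resample`: `selected` (QOI tibble of
#'   the selected patients), `k` (tibble `id`, `k_j`), `n_l`, `k_th`,
#'   `f_rs_before`, `f_rs_after`.
#' @export
resample_vpd <- function(qoi, n_l = NULL, k_th = 8,
                         spec = literature_spec(), seed = 1L) {
  stopifnot(k_th >= 0)
  ok <- completed_qoi(qoi)
  n_0 <- nrow(ok)
  if (is.null(n_l)) n_l <- floor(0.75 * n_0)
  stopifnot(n_l <= n_0)
  set.seed(seed)
  lit <- generate_literature_dataset(n_l, spec)
  k_j <- integer(n_0)
  for (q in spec$qoi) {
    hit <- match_closest(lit[[q]], ok[[q]])
    k_j[unique(hit)] <- k_j[unique(hit)] + 1L
  }
  sel <- k_j >= k_th
  structure(list(
    selected = ok[sel, ],
    k = tibble::tibble(id = ok$id, k_j = k_j),
    n_l = n_l, k_th = k_th, seed = seed,
    f_rs_before = if (n_0 >= 2) f_rs(ok, spec) else NA_real_,
    f_rs_after = if (sum(sel) >= 2) f_rs(ok[sel, ], spec) else NA_real_),
    class = "cvpd_resample")
}

#' @export
print.cvpd_resample <- function(x, ...) {
  cat("<cvpd_resample> ", nrow(x$selected), " of ", nrow(x$k),
      " patients selected (N_l = ", x$n_l, ", K_th = ", x$k_th,
      "); F_rs ", signif(x$f_rs_before, 4), " -> ",
      signif(x$f_rs_after, 4), "\n", sep = "")
  invisible(x)
}

#' @method glance cvpd_resample
#' @export
glance.cvpd_resample <- function(x, ...) {
  tibble::tibble(n_0 = nrow(x$k), n_l = x$n_l, k_th = x$k_th,
                 n_selected = nrow(x$selected),
                 f_rs_before = x$f_rs_before, f_rs_after = x$f_rs_after)
}

#' Resampling quality score
#'
#' Sum over the QOIs of the absolute relative deviations of the cohort
#' standard deviation and mean from their literature values:
#' \deqn{F^{rs} = \sum_i |(\sigma_i - \sigma_{l,i})/\sigma_{l,i}| +
#'   |(\mu_i - \mu_{l,i})/\mu_{l,i}|.}
#' Lower is better; zero means exact moment agreement.
#'
#' @param qoi QOI tibble (completed records are used).
#' @param spec a [literature_spec()] tibble.
#' @return scalar score.
#' @export
f_rs <- function(qoi, spec = literature_spec()) {
  ok <- completed_qoi(qoi)
  stopifnot(nrow(ok) >= 2)
  sum(vapply(seq_len(nrow(spec)), function(i) {
    v <- ok[[spec$qoi[i]]]
    abs((stats::sd(v) - spec$sd[i]) / spec$sd[i]) +
      abs((mean(v) - spec$mean[i]) / spec$mean[i])
  }, 0))
}
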