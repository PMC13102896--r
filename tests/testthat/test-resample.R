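# literal transcription of the matching rule, used as an oracle for the
# vectorised implementation: ascending literature order, nearest
# available cohort value, lowest index on ties
match_oracle <- function(lit, vpd) {
  taken <- rep(FALSE, length(vpd))
  out <- integer(length(lit))
  for (j in order(lit)) {
    best <- NA_integer_
    best_d <- Inf
    for (k in seq_along(vpd)) {
      if (taken[k]) next
      d <- abs(vpd[k] - lit[j])
      if (d < best_d - 1e-15) {
        best <- k
        best_d <- d
      }
    }
    out[j] <- best
    taken[best] <- TRUE
  }
  out
}

test_that("closest-value matching follows the stated rule", {
  # hand-checkable example
  expect_equal(match_closest(c(1, 2), c(0.9, 2.2, 7)), c(1, 2))
  # identical multisets pair off exactly
  v <- c(3, 1, 4, 1, 5)
  m <- match_closest(v, v)
  expect_equal(sort(m), 1:5)
  expect_true(all(abs(v - v[m]) == 0))
  # every cohort value used at most once
  set.seed(9)
  lit <- rnorm(40)
  vpd <- rnorm(60)
  m2 <- match_closest(lit, vpd)
  expect_equal(anyDuplicated(m2), 0)
  expect_error(match_closest(rnorm(5), rnorm(3)), "more literature")
})

test_that("matching agrees with a brute-force oracle on small cases", {
  set.seed(77)
  for (rep in 1:60) {
    n_l <- sample(1:8, 1)
    n_0 <- n_l + sample(0:4, 1)
    lit <- round(rnorm(n_l), 2)
    vpd <- round(rnorm(n_0), 2)
    expect_identical(match_closest(lit, vpd), match_oracle(lit, vpd))
  }
})

test_that("literature datasets reproduce their generating moments", {
  set.seed(1)
  d <- generate_literature_dataset(10000)
  lit <- literature_spec()
  i <- which(lit$qoi == "p_ao_sys")
  expect_lt(abs(mean(d$p_ao_sys) - 113.0), 3 * 11.2 / sqrt(10000))
  expect_equal(sd(d$p_ao_sys), 11.2, tolerance = 0.05)
  # zero spread degenerates to the mean
  spec0 <- lit
  spec0$sd <- 0
  expect_true(all(generate_literature_dataset(5, spec0)$co == 4570))
  # seeded determinism
  set.seed(42)
  a <- generate_literature_dataset(50)
  set.seed(42)
  b <- generate_literature_dataset(50)
  expect_identical(a, b)
})

# small synthetic cohort with plausible QOI scales
synthetic_cohort <- function(n, seed = 1, shift = 0, widen = 1) {
  set.seed(seed)
  lit <- literature_spec()
  cols <- lapply(seq_len(nrow(lit)), function(i) {
    stats::rnorm(n, lit$mean[i] * (1 + shift), lit$sd[i] * widen)
  })
  out <- tibble::as_tibble(stats::setNames(cols, lit$qoi))
  out$id <- seq_len(n)
  out$failed <- FALSE
  out
}

test_that("resampling identities hold exactly", {
  qoi <- synthetic_cohort(120, seed = 3)
  # N_l = N_0 with K_th = 0 removes nobody
  rs <- resample_vpd(qoi, n_l = 120, k_th = 0, seed = 11)
  expect_equal(nrow(rs$selected), 120)
  # sum of match counts is exactly 11 * N_l
  rs2 <- resample_vpd(qoi, n_l = 90, k_th = 8, seed = 11)
  expect_equal(sum(rs2$k$k_j), 11 * 90)
  # unreachable threshold empties the selection
  rs3 <- resample_vpd(qoi, n_l = 90, k_th = 12, seed = 11)
  expect_equal(nrow(rs3$selected), 0)
})

test_that("selection shrinks as K_th rises or N_l falls", {
  qoi <- synthetic_cohort(150, seed = 5, shift = 0.05, widen = 1.3)
  # K_th monotonicity is exact for one matching
  sizes_k <- vapply(0:12, function(k) {
    nrow(resample_vpd(qoi, n_l = 110, k_th = k, seed = 21)$selected)
  }, 0L)
  expect_true(all(diff(sizes_k) <= 0))
  expect_equal(sizes_k[1], 150)
  # N_l sweep: fewer literature values select fewer patients
  sizes_n <- vapply(c(150, 110, 70, 30), function(nl) {
    nrow(resample_vpd(qoi, n_l = nl, k_th = 8, seed = 21)$selected)
  }, 0L)
  expect_true(all(diff(sizes_n) <= 0))
  # selected fraction strictly inside (0, 1) at the working point
  mid <- resample_vpd(qoi, n_l = 112, k_th = 8, seed = 21)
  expect_gt(nrow(mid$selected), 0)
  expect_lt(nrow(mid$selected), 150)
})

test_that("the resampling score is zero at exact moment agreement", {
  lit <- literature_spec()
  # two-point samples with exactly the literature mean and sd
  qoi <- tibble::as_tibble(stats::setNames(
    lapply(seq_len(nrow(lit)), function(i) {
      lit$mean[i] + c(-1, 1) * lit$sd[i] / sqrt(2)
    }), lit$qoi))
  qoi$id <- 1:2
  qoi$failed <- FALSE
  expect_equal(f_rs(qoi, lit), 0, tolerance = 1e-12)
})

test_that("the resampling score reproduces hand arithmetic", {
  spec <- tibble::tibble(qoi = "x", mean = 100, sd = 10)
  qoi <- tibble::tibble(x = 110 + c(-10, 10) / sqrt(2),
                        id = 1:2, failed = FALSE)
  # mean off by 10% of the literature mean, sd exactly matched
  expect_equal(f_rs(qoi, spec), 0.1, tolerance = 1e-12)
})

test_that("the score is invariant to a per-QOI rescaling", {
  spec <- tibble::tibble(qoi = "x", mean = 50, sd = 5)
  qoi <- synthetic_cohort(80, seed = 8)[, c("id", "failed")]
  set.seed(8)
  qoi$x <- rnorm(80, 60, 7)
  base <- f_rs(qoi, spec)
  for (k in c(0.1, 3, 40)) {
    spec_k <- spec
    spec_k$mean <- spec$mean * k
    spec_k$sd <- spec$sd * k
    qoi_k <- qoi
    qoi_k$x <- qoi$x * k
    expect_equal(f_rs(qoi_k, spec_k), base, tolerance = 1e-12)
  }
})

test_that("resampling improves the score on biased synthetic cohorts", {
  improved <- vapply(1:20, function(s) {
    qoi <- synthetic_cohort(150, seed = 1000 + s, shift = 0.2, widen = 1.5)
    rs <- resample_vpd(qoi, n_l = 112, k_th = 8, seed = 2000 + s)
    if (nrow(rs$selected) < 2) return(NA)
    rs$f_rs_after <= rs$f_rs_before
  }, TRUE)
  expect_true(all(improved, na.rm = TRUE))
})
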