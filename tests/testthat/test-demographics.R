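# small labelled mixture shared across demographic tests
mixture_cohort <- function(n, seed, groups = c("A", "B"), sep = 2,
                           nq = 2, sds = c(1, 1), fracs = NULL) {
  set.seed(seed)
  if (is.null(fracs)) fracs <- rep(1 / length(groups), length(groups))
  counts <- round(n * fracs)
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  truth <- rep(groups, counts)
  qn <- paste0("q", seq_len(nq))
  mus <- stats::setNames(10 + sep * (seq_along(groups) - 1), groups)
  sdv <- stats::setNames(sds, groups)
  qoi <- tibble::as_tibble(stats::setNames(lapply(qn, function(q) {
    stats::rnorm(n, mus[truth], sdv[truth])
  }), qn))
  qoi$id <- seq_len(n)
  qoi$failed <- FALSE
  targets <- dplyr::bind_rows(lapply(groups, function(g) {
    tibble::tibble(group = g, qoi = qn, mean = mus[[g]], sd = sdv[[g]])
  }))
  list(qoi = qoi, truth = truth, targets = targets)
}

test_that("the per-patient group distance behaves as defined", {
  tg <- group_targets("sex")
  rec <- stats::setNames(as.list(tg$mean[tg$group == "male"]),
                         tg$qoi[tg$group == "male"])
  expect_equal(f_dt(rec, "male", tg), 0)
  # one QOI off by exactly one target sd contributes exactly 1
  rec$pwv_ao <- rec$pwv_ao + tg$sd[tg$group == "male" &
                                     tg$qoi == "pwv_ao"]
  expect_equal(f_dt(rec, "male", tg), 1)
  expect_error(f_dt(rec, "unknown", tg), "no targets")
})

test_that("patients generated at a group's means are assigned to it", {
  mix <- mixture_cohort(300, seed = 1, sep = 6)  # well separated
  init <- initial_assignment(mix$qoi, mix$targets)
  expect_equal(init, mix$truth)
  # argmin self-consistency for every group of the shipped age table
  tg <- group_targets("age")
  for (g in age_groups()) {
    rec <- stats::setNames(as.list(tg$mean[tg$group == g]),
                           tg$qoi[tg$group == g])
    d <- vapply(age_groups(), function(h) f_dt(rec, h, tg), 0)
    expect_equal(names(which.min(d)), g)
  }
  # identical targets for all groups: ties go to the first group
  flat <- mix$targets
  flat$mean <- 10
  flat$sd <- 1
  expect_true(all(initial_assignment(mix$qoi, flat) == "A"))
})

test_that("initial assignment recovers moderately separated mixtures", {
  mix <- mixture_cohort(600, seed = 7, sep = 2)
  init <- initial_assignment(mix$qoi, mix$targets)
  expect_gt(mean(init == mix$truth), 0.8)
})

test_that("the population objective reproduces hand arithmetic", {
  # 6 patients, 2 groups, 2 QOIs, worked independently:
  # group A = rows 1-3, group B = rows 4-6
  qoi <- tibble::tibble(q1 = c(9, 10, 11, 19, 20, 21),
                        q2 = c(4, 5, 6, 9, 10, 11),
                        id = 1:6, failed = FALSE)
  targets <- dplyr::bind_rows(
    tibble::tibble(group = "A", qoi = c("q1", "q2"), mean = c(10, 5),
                   sd = c(1, 1)),
    tibble::tibble(group = "B", qoi = c("q1", "q2"), mean = c(20, 10),
                   sd = c(2, 2)))
  lab <- c("A", "A", "A", "B", "B", "B")
  # empirical: both groups mean-exact; sample sd of {x-1,x,x+1} = 1
  # A: sd terms ((1-1)/1)^2 = 0 twice; mean terms 0
  # B: sd terms ((1-2)/2)^2 = 0.25 twice; mean terms 0
  expect_equal(f_vpd(lab, qoi, targets, s_coef = 0), 0.5,
               tolerance = 1e-12)
  # penalty: one patient to no-data, s_coef = 0.1 adds exactly 0.1
  lab2 <- c("A", "A", "A", "B", "B", no_data_label())
  # B becomes {19, 20}: mean 19.5, sd ~0.7071; q2 {9, 10}: mean 9.5
  expect_equal(f_vpd(lab2, qoi, targets, s_coef = 0.1),
               0.1 +
                 ((19.5 - 20) / 20)^2 + ((sd(c(19, 20)) - 2) / 2)^2 +
                 ((9.5 - 10) / 10)^2 + ((sd(c(9, 10)) - 2) / 2)^2,
               tolerance = 1e-12)
  # moment-exact grouping with empty no-data scores zero
  targets0 <- targets
  targets0$sd[targets0$group == "B"] <- 1
  expect_equal(f_vpd(lab, qoi, targets0, s_coef = 1), 0, tolerance = 1e-12)
  # degenerate group errors
  expect_error(f_vpd(c("A", "A", "A", "A", "A", "B"), qoi, targets),
               "degenerate")
})

test_that("refinement decreases the objective monotonically", {
  mix <- mixture_cohort(400, seed = 3, sep = 1.5)
  init <- initial_assignment(mix$qoi, mix$targets)
  f0 <- f_vpd(init, mix$qoi, mix$targets, s_coef = 0.02)
  ref <- refine_assignment(init, mix$qoi, mix$targets, s_coef = 0.02,
                           seed = 9)
  expect_lte(ref$objective, f0)
  if (length(ref$trace) > 1) {
    expect_true(all(diff(ref$trace) < 0))
  }
  expect_equal(ref$trace[length(ref$trace)], ref$objective)
})

test_that("incremental objective updates match full recomputation", {
  mix <- mixture_cohort(200, seed = 5, sep = 1.5)
  init <- initial_assignment(mix$qoi, mix$targets)
  ref <- refine_assignment(init, mix$qoi, mix$targets, s_coef = 0.05,
                           seed = 13)
  full <- f_vpd(ref$labels, mix$qoi, mix$targets, s_coef = 0.05)
  expect_equal(ref$objective, full, tolerance = 1e-9)
})

test_that("a local optimum is returned unchanged", {
  # two tight, far-apart clusters: nearest assignment is already
  # moment-optimal, so no move improves
  mix <- mixture_cohort(100, seed = 21, sep = 30, sds = c(0.5, 0.5))
  init <- initial_assignment(mix$qoi, mix$targets)
  ref <- refine_assignment(init, mix$qoi, mix$targets, s_coef = 1,
                           seed = 2)
  expect_identical(ref$labels, init)
  expect_equal(length(ref$trace), 0)
  expect_equal(ref$passes, 1)
})

test_that("age-classified group means preserve monotone target order", {
  # synthetic cohort drawn from the age targets themselves: after
  # assignment and refinement the group means of the stiffness-driven
  # QOIs must rise with age (the population trend the targets encode)
  tg <- group_targets("age")
  set.seed(33)
  n_per <- 80
  rows <- lapply(age_groups(), function(g) {
    t1 <- tg[tg$group == g, ]
    out <- tibble::as_tibble(stats::setNames(
      lapply(seq_len(nrow(t1)), function(i) {
        stats::rnorm(n_per, t1$mean[i], t1$sd[i])
      }), t1$qoi))
    out
  })
  qoi <- dplyr::bind_rows(rows)
  qoi$id <- seq_len(nrow(qoi))
  qoi$failed <- FALSE
  lab <- classify_vpd(qoi, "age", seed = 4)
  mom <- group_moments(lab, "age")
  for (q in c("pwv_ao", "pwv_cf", "p_ao_sys")) {
    m <- mom$mean[mom$qoi == q][match(age_groups(),
                                      mom$age[mom$qoi == q])]
    expect_true(all(diff(m[!is.na(m)]) > 0))
  }
})

test_that("labelled target tables round-trip through disk", {
  tg <- group_targets("age")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_group_targets(tg, f)
  expect_equal(as.data.frame(read_group_targets(f)), as.data.frame(tg),
               tolerance = 1e-12)
})
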