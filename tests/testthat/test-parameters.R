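test_that("mean factors with zero offsets reproduce the reference patient", {
  topo <- fixture_tree()
  ref <- default_reference()
  pat <- apply_parameters(topo, mean_parameter_set(), ref)
  # diameters and lengths: (factor + 0) * reference
  expect_equal(pat$segments$radius_prox, 1.05 * topo$segments$radius_prox)
  expect_equal(pat$segments$length, 1.00 * topo$segments$length)
  expect_equal(pat$wall$k1, 1.14 * ref$wall$k1)
  expect_equal(pat$heart$hr, ref$heart$hr)
})

test_that("factor-offset composition is linear and reversible", {
  topo <- fixture_tree()
  ps <- mean_parameter_set()
  ps$off_D_arms <- 0.07
  pat_up <- apply_parameters(topo, ps)
  ps$off_D_arms <- -0.07
  pat_dn <- apply_parameters(topo, ps)
  arms <- topo$segments$body_location == "arms"
  base <- apply_parameters(topo, mean_parameter_set())
  # +x then -x averages back to the reference exactly
  expect_equal((pat_up$segments$radius_prox + pat_dn$segments$radius_prox) / 2,
               base$segments$radius_prox, tolerance = 1e-14)
  # only the tagged location moves
  expect_equal(pat_up$segments$radius_prox[!arms],
               base$segments$radius_prox[!arms])
  # worked diameter: factor 1.05 on a 10 mm reference diameter -> 10.5 mm
  t1 <- line_topology(r0 = 0.005)
  p1 <- apply_parameters(t1, mean_parameter_set())
  expect_equal(2 * p1$segments$radius_prox[1], 1.05 * 0.010)
})

test_that("non-positive applied parameters raise invalid-patient errors", {
  topo <- fixture_tree()
  ps <- mean_parameter_set()
  ps$D <- 0.9
  ps$off_D_arms <- -1.0   # (0.9 - 1.0) * D_ref < 0
  err <- tryCatch(apply_parameters(topo, ps), condition = identity)
  expect_s3_class(err, "cvpd_invalid_patient")
  expect_match(conditionMessage(err), "diameter")
  ps2 <- mean_parameter_set()
  ps2$HR <- -0.1
  expect_error(apply_parameters(topo, ps2), "heart rate")
})

test_that("peripheral beds keep time constants and resistance ratios", {
  topo <- fixture_tree()
  ref <- default_reference()
  base <- apply_parameters(topo, mean_parameter_set(), ref)
  set.seed(11)
  draws <- sample_parameter_sets(25)
  for (i in seq_len(nrow(draws))) {
    pat <- try(apply_parameters(topo, draws[i, ], ref), silent = TRUE)
    if (inherits(pat, "try-error")) next
    for (k in seq_along(pat$terminals)) {
      tm <- pat$terminals[[k]]
      tb <- base$terminals[[k]]
      # R_i * C_i and L_i / R_i invariant to 1e-12 relative
      expect_equal(tm$r * tm$c, tb$r * tb$c, tolerance = 1e-12)
      expect_equal(tm$l / tm$r, tb$l / tb$r, tolerance = 1e-12)
      # resistance ratios fixed across patients
      expect_equal(tm$r / tm$r[1], tb$r / tb$r[1], tolerance = 1e-12)
    }
  }
})

test_that("pulmonary RC product is invariant across random patients", {
  topo <- fixture_tree()
  ref <- default_reference()
  rc_ref <- ref$pulmonary$r_p * ref$pulmonary$c_pul
  set.seed(12)
  draws <- sample_parameter_sets(1000)
  rc <- vapply(seq_len(nrow(draws)), function(i) {
    pat <- try(apply_parameters(topo, draws[i, ], ref), silent = TRUE)
    if (inherits(pat, "try-error")) return(NA_real_)
    pat$pulmonary$r_p * pat$pulmonary$c_pul
  }, 0)
  expect_true(all(abs(rc[!is.na(rc)] / rc_ref - 1) < 1e-12))
})

test_that("valve resistance and inertance share the R_h factor", {
  topo <- fixture_tree()
  ref <- default_reference()
  ps <- mean_parameter_set()
  ps$R_h <- 1.3
  pat <- apply_parameters(topo, ps, ref)
  expect_equal(pat$heart$valve$r_av / ref$heart$valve$r_av, 1.3)
  expect_equal(pat$heart$valve$l_av / ref$heart$valve$l_av, 1.3)
  expect_equal(pat$heart$valve$r_mv / ref$heart$valve$r_mv, 1.3)
})

test_that("coronary bed capacitance scales reciprocally to R_c", {
  topo <- fixture_tree()
  ps <- mean_parameter_set()
  ps$R_c <- 2
  pat <- apply_parameters(topo, ps)
  base <- apply_parameters(topo, mean_parameter_set())
  cor_i <- which(vapply(pat$terminals, function(t) t$bed == "coronary",
                        TRUE))
  expect_equal(pat$terminals[[cor_i]]$r, 2 * base$terminals[[cor_i]]$r)
  expect_equal(pat$terminals[[cor_i]]$c, base$terminals[[cor_i]]$c / 2)
})
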