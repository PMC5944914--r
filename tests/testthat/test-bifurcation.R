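test_that("Hopf threshold has its closed-form limits", {
  expect_equal(hopf_threshold(rescaled_params(0.8, 0, 0.2, eps = 0.1)), 0.4)
  expect_identical(hopf_threshold(red_marker(eps = 0)), 0)
  eps_seq <- c(0.1, 0.01, 0.001)
  fc <- vapply(eps_seq, function(e) hopf_threshold(red_marker(eps = e)), 0)
  expect_true(all(diff(fc) < 0))  # shrinks toward 0 with eps
})

test_that("homoclinic transition velocities follow the radicand formula", {
  rp <- rescaled_params(0.8, 0.1, 0.4, eps = 0)   # f_ind = n/2
  v <- homoclinic_velocity(rp)
  expect_equal(unname(v), c(0.1, -0.1))
  rp2 <- rescaled_params(0.8, 0.1, 0.2, eps = 0)
  v2 <- homoclinic_velocity(rp2)
  expect_equal(unname(v2["v_plus"]), 0.1 - sqrt(0.4 * (0.4 - 0.2)))
  expect_equal(unname(v2["v_plus"]), -unname(v2["v_minus"]))
  expect_error(homoclinic_velocity(rescaled_params(0.8, 0.1, 0.5, eps = 0)),
               "radicand")
})

test_that("homoclinic threshold solves the transcendental condition", {
  hom <- homoclinic_threshold(0.8, 0.1)
  expect_lt(abs(hom$residual), 1e-10)
  expect_gt(hom$f_c2, 0.18)
  expect_lt(hom$f_c2, 0.21)
  # independent check: escape-vs-return bisection of the piecewise flow
  f_sim <- homoclinic_threshold_sim(0.8, 0.1, tol = 1e-4)
  expect_equal(hom$f_c2, f_sim, tolerance = 1e-3)
})

test_that("saddle-node of cycles closes the bistable band", {
  hom <- homoclinic_threshold(0.8, 0.1)
  sn <- saddle_node_threshold(0.8, 0.1)
  expect_gt(sn$f_c3, hom$f_c2)          # nonempty bistable band
  expect_gte(sn$f_c3, 0.25)
  expect_lte(sn$f_c3, 0.28)
  expect_lte(diff(sn$bracket), 1e-3)
  # just below: stable cycle and separatrix coexist on the section;
  # just above: both gone
  below <- poincare_fixed_points(rescaled_params(0.8, 0.1, sn$f_c3 - 0.002, eps = 0))
  above <- poincare_fixed_points(rescaled_params(0.8, 0.1, sn$f_c3 + 0.002, eps = 0))
  expect_false(is.null(below$v_stable))
  expect_false(is.null(below$v_unstable))
  expect_gt(below$v_stable, below$v_unstable)
  expect_null(above$v_stable)
  expect_null(above$v_unstable)
})

test_that("transition velocities match the nullcline gap at the threshold", {
  hom <- homoclinic_threshold(0.8, 0.1)
  # just below the transition the two approaching branches straddle the
  # predicted merge velocity; just above they are gone
  rp <- rescaled_params(0.8, 0.1, hom$f_c2 - 1e-4, eps = 0)
  nb <- nullcline_branches(rp, 5, n_scan = 8001)
  pair <- sort(nb$v[nb$v > 0])
  expect_identical(length(pair), 2L)
  v_merge <- abs(hom$v_transition["v_plus"])
  expect_gt(v_merge, pair[1]); expect_lt(v_merge, pair[2])
  expect_lt(pair[2] - pair[1], 0.02)
  rp_up <- rescaled_params(0.8, 0.1, hom$f_c2 + 1e-4, eps = 0)
  expect_identical(sum(nullcline_branches(rp_up, 5, n_scan = 8001)$v > 0), 0L)
})

test_that("the three reference points fall in phases i, ii, iii", {
  hom <- homoclinic_threshold(0.8, 0.1)
  sn <- saddle_node_threshold(0.8, 0.1)
  expect_identical(classify_phase(0.1, 0.18, n = 0.8, f_c2 = hom$f_c2, f_c3 = sn$f_c3),
                   "phase_i")
  expect_identical(classify_phase(0.1, 0.23, n = 0.8, f_c2 = hom$f_c2, f_c3 = sn$f_c3),
                   "phase_ii")
  expect_identical(classify_phase(0.1, 0.28, n = 0.8, f_c2 = hom$f_c2, f_c3 = sn$f_c3),
                   "phase_iii")
  expect_identical(classify_phase(0.1, 5, n = 0.8, f_c2 = hom$f_c2, f_c3 = sn$f_c3),
                   "phase_iii")
  expect_error(classify_phase(-0.1, 0.2, n = 0.8), "non-negative")
})

test_that("finite smoothing widens the unstable region; the homoclinic line does not move", {
  fs <- seq(0.06, 0.3, by = 0.02)
  unstable <- function(eps) sum(vapply(fs, function(f)
    classify_phase(0.1, f, n = 0.8, eps = eps, f_c2 = 0.2076, f_c3 = 0.2575) ==
      "unstable_no_bistability", TRUE))
  expect_gt(unstable(0.1), unstable(0.001))
  # the homoclinic threshold is a property of the sharp-limit field and is
  # shared by the finite-eps diagrams
  expect_equal(homoclinic_threshold(0.8, 0.1)$f_c2, 0.2076, tolerance = 1e-3)
})

test_that("phase diagram grids are consistent and carry the critical curves", {
  pd <- phase_diagram(g_range = c(0.05, 0.15), f_range = c(0.15, 0.3),
                      resolution = c(3, 8))
  expect_identical(nrow(pd$grid), 24L)
  expect_true(all(pd$grid$label %in%
    c("phase_i", "phase_ii", "phase_iii", "unstable_no_bistability")))
  expect_true(all(is.finite(pd$curves$f_c2)))
  expect_true(all(pd$curves$f_c3 > pd$curves$f_c2, na.rm = TRUE))
  expect_true(all(pd$curves$f_c1 == 0))   # sharp limit: no Hopf line
  # labels are monotone in f_ind within each g column
  for (g in unique(pd$grid$g)) {
    lab <- pd$grid$label[pd$grid$g == g]
    ord <- match(lab, c("phase_i", "phase_ii", "phase_iii"))
    expect_true(all(diff(ord) >= 0))
  }
})
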