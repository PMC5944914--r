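test_that("restoring-force profiles vanish at the opening and saturate", {
  for (mode in c("tanh", "sign", "projection2d"))
    expect_equal(restoring_force(0, g = 0.1, eps = 1, mode = mode, r = 1), 0)
  expect_equal(restoring_force(50, g = 0.1, eps = 0.1), 0.1, tolerance = 1e-8)
  expect_equal(restoring_force(-50, g = 0.1, mode = "sign"), -0.1)
  expect_error(restoring_force(1, 0.1, eps = 0, mode = "tanh"), "sign")
})

test_that("smooth profile matches the 2D ring projection (eps ~ r)", {
  xs <- seq(-5, 5, length.out = 501)
  dev <- abs(restoring_force(xs, 1, eps = 1) -
             restoring_force(xs, 1, mode = "projection2d", r = 1))
  expect_lt(max(dev), 0.1)
})

test_that("acceleration field has the printed form and its symmetries", {
  rp <- red_marker(eps = 0.1)
  expect_identical(q_eval(0, 0, rp), 0)    # fixed point
  # arithmetic oracle: independent transcription
  expect_equal(q_eval(1, 0.2, rp), q_oracle(1, 0.2, 0.8, 0.1, 0.23, 1, 0.1),
               tolerance = 1e-14)
  set.seed(3)
  for (i in 1:20) {
    x <- runif(1, -3, 3); v <- runif(1, -0.6, 0.6)
    expect_equal(q_eval(-x, -v, rp), -q_eval(x, v, rp), tolerance = 1e-12)
  }
  rp0 <- red_marker(eps = 0)
  expect_equal(q_eval(2, 0.1, rp0), q_oracle(2, 0.1, 0.8, 0.1, 0.23, 1, 0),
               tolerance = 1e-14)
})

test_that("origin Jacobian matches finite differences of the field", {
  rp <- red_marker(eps = 0.1)
  J <- jacobian_origin(rp)
  h <- 1e-6
  qx_fd <- (q_eval(h, 0, rp) - q_eval(-h, 0, rp)) / (2 * h)
  qv_fd <- (q_eval(0, h, rp) - q_eval(0, -h, rp)) / (2 * h)
  expect_equal(J["v", "x"], qx_fd, tolerance = 1e-6)
  expect_equal(J["v", "v"], qv_fd, tolerance = 1e-6)
  expect_identical(J["x", "x"], 0); expect_identical(J["x", "v"], 1)
  # no restoring force -> no position coupling
  Jg0 <- jacobian_origin(rescaled_params(0.8, 0, 0.23, eps = 0.1))
  expect_identical(Jg0["v", "x"], 0)
  expect_error(jacobian_origin(red_marker(eps = 0)), "eps = 0")
})

test_that("trace of the linearization vanishes at the Hopf threshold", {
  for (eps in c(0.01, 0.05, 0.1)) {
    rp <- red_marker(eps = eps)
    fc1 <- hopf_threshold(rp)
    Jc <- jacobian_origin(rescaled_params(rp$n, rp$g, fc1, eps, rp$k_c))
    expect_lt(abs(sum(diag(Jc))), 1e-10)
  }
})

test_that("the origin is the unique rest position for g > 0", {
  rp <- red_marker(eps = 0)
  xs <- setdiff(seq(-5, 5, by = 0.1), 0)
  expect_true(all(sign(q_eval(xs, 0, rp)) == -sign(xs)))
})

test_that("deterministic flow: fixed point, spiral convergence, limit cycle", {
  rp3 <- rescaled_params(0.8, 0.1, 0.28, eps = 0)
  still <- integrate_meanfield(rp3, 0, 0, T = 10)
  expect_true(all(still$x == 0) && all(still$v == 0))
  # above the saddle-node every initial condition spirals in
  for (ic in list(c(3, 0.5), c(-2, -0.4), c(0, 0.45))) {
    tr <- integrate_meanfield(rp3, ic[1], ic[2], T = 400)
    expect_lt(max(abs(tr$x[tr$t > 350])), 1e-3)
    expect_lt(max(abs(tr$v[tr$t > 350])), 1e-3)
  }
  # in the bistable band a far initial condition settles on the cycle whose
  # peak speed matches the nullcline branch
  rp2 <- red_marker()
  tr2 <- integrate_meanfield(rp2, 4, 1, T = 300)
  v_null <- nullcline_branches(rp2, 5)$v
  expect_equal(max(abs(tr2$v[tr2$t > 200])), max(abs(v_null)), tolerance = 0.01)
})

test_that("the flow is equivariant under reflection through the origin", {
  rp <- red_marker()
  a <- integrate_meanfield(rp, 2, 0.3, T = 60, dt = 0.05)
  b <- integrate_meanfield(rp, -2, -0.3, T = 60, dt = 0.05)
  expect_equal(a$x, -b$x, tolerance = 1e-6)
  expect_equal(a$v, -b$v, tolerance = 1e-6)
})

test_that("nullcline branches pair antisymmetrically and match scalar roots", {
  rp <- red_marker()
  nb_p <- nullcline_branches(rp, c(4, 8))
  nb_m <- nullcline_branches(rp, c(-4, -8))
  expect_equal(sort(nb_p$v), sort(-nb_m$v), tolerance = 1e-9)
  expect_true(all(abs(q_eval(nb_p$x, nb_p$v, rp)) < 1e-8))
  # far from the opening the roots solve the saturated balance, checked by
  # an independent bisection
  f <- function(v) 0.8 * sinh(v / 0.23) - 2 * (v + 0.1) * cosh(v / 0.23)
  root <- uniroot(f, c(-0.6, -0.3), tol = 1e-12)$root
  expect_equal(min(nb_p$v[nb_p$x == 8]), root, tolerance = 1e-8)
})

test_that("nullcline branches in a half-space merge above the homoclinic threshold", {
  count_roots <- function(f_ind) {
    nrow(nullcline_branches(rescaled_params(0.8, 0.1, f_ind, eps = 0), 5))
  }
  expect_identical(count_roots(0.18), 3L)   # free-motion branch present
  expect_identical(count_roots(0.23), 1L)   # merged: motion confined
})

test_that("orbits inside the separatrix are captured by the origin", {
  rp <- red_marker()
  sep <- separatrix(rp)
  expect_false(is.null(sep))
  for (frac in c(0.3, 0.7, 0.95)) {
    tr <- integrate_meanfield(rp, 0, frac * sep$v_section, T = 150)
    expect_lt(max(abs(tr$x[tr$t > 120])), 1e-3)
  }
  # phase i: initial conditions far outside escape at terminal velocity
  rp1 <- rescaled_params(0.8, 0.1, 0.18, eps = 0)
  tr1 <- integrate_meanfield(rp1, 1, 0.6, T = 150)
  expect_gt(abs(tr1$x[nrow(tr1)]), 10)
  v_term <- nullcline_branches(rp1, 5)$v
  expect_lt(min(abs(v_term - tr1$v[nrow(tr1)])), 0.02)
})
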