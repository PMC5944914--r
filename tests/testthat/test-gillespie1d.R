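test_that("role-switching rates are reciprocal exponentials of the projection", {
  r0 <- role_switch_rates(0, F_ind = 23, k_c = 1)
  expect_equal(r0$r_l_to_p, 1); expect_equal(r0$r_p_to_l, 1)
  r1 <- role_switch_rates(23, F_ind = 23, k_c = 1)
  expect_equal(r1$r_l_to_p, exp(1)); expect_equal(r1$r_p_to_l, exp(-1))
  set.seed(1)
  proj <- runif(20, -60, 60)
  r <- role_switch_rates(proj, F_ind = 17, k_c = 0.7)
  expect_equal(r$r_l_to_p * r$r_p_to_l, rep(0.49, 20))
  expect_error(role_switch_rates(1, F_ind = 0), "F_ind")
})

test_that("1D force balance sums pullers against the informed restoring pull", {
  expect_equal(total_force_1d(5, 3, 2, x = 1), 0)
  expect_equal(total_force_1d(0, 0, 0, x = 2), 0)      # all lifters, G = 0
  f <- total_force_1d(7, 2, 3, x = 0.5, f0 = 2)
  expect_equal(total_force_1d(2, 7, 3, x = -0.5, f0 = 2), -f)  # mirror state
  expect_equal(total_force_1d(0, 0, 4, x = 0.05, f0 = 1,
                              restoring = "tanh", eps = 0.1),
               -4 * tanh(0.5))
})

test_that("equilibrium role assignment has the logistic form", {
  expect_identical(removal_role_assignment(0, 23, 0.499), "puller")
  expect_identical(removal_role_assignment(0, 23, 0.501), "lifter")
  expect_equal(puller_probability(0, 23), 0.5)
  expect_gt(puller_probability(1e4, 23), 1 - 1e-12)   # saturation
  # Monte-Carlo frequency against the analytic probability
  set.seed(5)
  u <- runif(1e5)
  np <- puller_probability(0.3 * 23, 23)
  freq <- mean(removal_role_assignment(0.3 * 23, 23, u) == "puller")
  expect_lt(abs(freq - np), 3 * sqrt(np * (1 - np) / 1e5))
})

test_that("trajectories are reproducible and conserve binding sites", {
  p <- table1_params("process3")
  a <- simulate_cargo_1d(3, p, T = 50, seed = 9)
  b <- simulate_cargo_1d(3, p, T = 50, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  ev <- simulate_cargo_1d(3, p, T = 50, seed = 4, record_dt = 0)
  occupied <- ev$n_p + ev$n_l + ev$n_inf
  expect_true(all(occupied >= 0 & occupied <= p$n_max))
  # overdamped velocity after every event: v = f_tot / gamma at the
  # post-event state
  v_expect <- (ev$n_p_front - ev$n_p_back - ev$n_inf * sign(ev$x)) * p$f0 / p$gamma
  expect_equal(ev$v, v_expect, tolerance = 1e-12)
  # scheme 1 keeps the cargo fully occupied by uninformed ants
  ev1 <- simulate_cargo_1d(1, table1_params("process1"), T = 20, seed = 2,
                           record_dt = 0)
  expect_true(all(ev1$n_p + ev1$n_l == 80))
  expect_error(simulate_cargo_1d(2, table1_params("process1"), T = 1, seed = 1),
               "k_on")
})

test_that("waiting times are exponential and the neutral walk is symmetric", {
  # with an enormous individuality all switch rates equal k_c, so the
  # total rate is constant and waiting times are iid exponential
  p <- cargo_params(f0 = 1, F_ind = 1e12, gamma = 100, n_tot = 80, G = 10,
                    n_max = 80)
  ev <- simulate_cargo_1d(1, p, T = 150, seed = 21, record_dt = 0)
  dts <- diff(ev$t)
  ks <- stats::ks.test(dts, "pexp", 80)
  expect_gt(ks$p.value, 0.01)
  dnp <- ev$n_p_front - ev$n_p_back
  expect_lt(abs(mean(dnp)), 1.5)   # symmetric random walk in the puller gap
})

test_that("a two-site cargo matches the exact master-equation stationary law", {
  # scheme 1, frozen position x > 0, one front and one back site, G = 1:
  # states (front, back) in {P, L}^2 with force f = npf - npb - 1
  p <- cargo_params(f0 = 1, F_ind = 1, gamma = 1, n_tot = 2, G = 1, n_max = 2)
  states <- list(c(1, 1), c(1, 0), c(0, 1), c(0, 0))  # (npf, npb)
  force <- function(s) s[1] - s[2] - 1
  Q <- matrix(0, 4, 4)
  for (i in 1:4) {
    s <- states[[i]]; f <- force(s)
    # front ant: p_i = +1; back ant: p_i = -1
    flips <- list(front = c(1 - s[1], s[2]), back = c(s[1], 1 - s[2]))
    rate_front <- if (s[1] == 1) exp(-f) else exp(f)
    rate_back  <- if (s[2] == 1) exp(f) else exp(-f)
    j_front <- which(vapply(states, identical, TRUE, y = flips$front))
    j_back <- which(vapply(states, identical, TRUE, y = flips$back))
    Q[i, j_front] <- Q[i, j_front] + rate_front
    Q[i, j_back] <- Q[i, j_back] + rate_back
  }
  diag(Q) <- -rowSums(Q)
  pi_exact <- abs(MASS::Null(Q)); pi_exact <- pi_exact / sum(pi_exact)
  ev <- simulate_cargo_1d(1, p, T = 20000, seed = 31, record_dt = 0,
                          x0 = 1, freeze_position = TRUE,
                          init_state = c(1, 1, 0, 0, 0, 0))
  dwell <- diff(ev$t)
  key <- paste(ev$n_p_front, ev$n_p_back)[-nrow(ev)]
  emp <- vapply(c("1 1", "1 0", "0 1", "0 0"),
                function(k) sum(dwell[key == k]), 0) / sum(dwell)
  expect_equal(unname(emp), as.vector(pi_exact), tolerance = 0.03)
})

test_that("ensemble drift of the puller gap follows the mean-field closure", {
  # frozen position, full occupancy: the gap D = npf - npb obeys
  # dD/dt = k_c [ n_tot sinh(phi) - 2 D cosh(phi) ], phi = f_tot / F_ind
  p <- table1_params("process1")
  rhs <- function(t, y, parms) {
    phi <- (y[1] - p$G) / p$F_ind    # x frozen at +1: s(x) = 1
    list(p$k_c * (p$n_tot * sinh(phi) - 2 * y[1] * cosh(phi)))
  }
  ode <- deSolve::lsoda(c(D = 0), seq(0, 1, 0.1), rhs, NULL)
  reps <- 400
  acc <- matrix(0, reps, 11)
  for (i in seq_len(reps)) {
    tr <- simulate_cargo_1d(1, p, T = 1.001, seed = 5000 + i, record_dt = 0.1,
                            x0 = 1, freeze_position = TRUE,
                            init_state = c(20, 20, 20, 20, 0, 0))
    acc[i, ] <- (tr$n_p_front - tr$n_p_back)[1:11]
  }
  # tolerance covers Monte-Carlo error plus the first-order closure bias
  # (sinh is convex, so the mean-field rate slightly lags the ensemble
  # during the fast transient at n_tot = 80)
  expect_lt(max(abs(colMeans(acc) - ode[, "D"])), 2.5)
})

test_that("attachment kinetics reach the predicted mean occupancy", {
  p2 <- table1_params("process2")
  tr <- simulate_cargo_1d(2, p2, T = 4000, seed = 12)
  keep <- tr$t > 300
  n_u <- mean(tr$n_p[keep] + tr$n_l[keep])
  expect_equal(n_u, 0.8 * p2$n_max, tolerance = 0.03)
  # the estimator inverts the simulated occupancy back to the site count
  occ <- occupancy_steady_state(p2$k_on, p2$k_off)
  expect_equal(estimate_binding_sites(n_u, occupancy = occ), p2$n_max,
               tolerance = 0.03)
  # informed-ant kinetics: both populations near their stationary means
  p3 <- table1_params("process3")
  tr3 <- simulate_cargo_1d(3, p3, T = 4000, seed = 13)
  keep3 <- tr3$t > 300
  o3 <- occupancy_steady_state(p3$k_on, p3$k_off, p3$k_forget, "three_state")
  expect_equal(mean(tr3$n_inf[keep3]), o3$P_inf * p3$n_max, tolerance = 0.15)
  expect_equal(mean(tr3$n_p[keep3] + tr3$n_l[keep3]), o3$P_u * p3$n_max,
               tolerance = 0.05)
})

test_that("all kinetic schemes show bi-stable switching at the reference point", {
  th <- threshold_preset("1d")
  for (sc in 1:3) {
    tr <- cached_run_1d(sc)
    dw <- dwell_statistics(segment_modes(tr, th, smooth = 2))
    expect_gt(dw$summary$total[dw$summary$mode == "convergent"], 0)
    expect_gt(dw$summary$total[dw$summary$mode == "oscillatory"], 0)
  }
})

test_that("velocity distribution peaks at the nullcline terminal speeds", {
  tr <- cached_run_1d(1)
  rp <- red_marker()
  v_term <- max(abs(nullcline_branches(rp, 5)$v))
  h <- hist(tr$v, breaks = seq(min(tr$v) - 0.01, max(tr$v) + 0.01, by = 0.02),
            plot = FALSE)
  top <- h$mids[order(-h$counts)[1:4]]
  expect_lt(min(abs(abs(top) - v_term)), 0.03)
  # substantial convergent mass at low speeds as well
  expect_gt(mean(abs(tr$v) < 2 * rp$g), 0.05)
})
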