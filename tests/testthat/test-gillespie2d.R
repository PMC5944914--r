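test_that("ring cargo is built touching the wall with evenly spaced sites", {
  st <- build_cargo(0.5, 16)
  expect_identical(nrow(st$sites), 16L)
  expect_equal(st$y, 0.5)                       # contact at the opening
  expect_equal(diff(st$sites$angle), rep(2 * pi / 16, 15))
  expect_equal(sqrt(st$sites$px^2 + st$sites$py^2), rep(1, 16))
  expect_identical(nrow(build_cargo(2, 96)$sites), 96L)
})

test_that("2D event rates follow the per-process kinetics", {
  p <- table1_params("r0.5")
  st <- build_cargo(0.5, 16)
  rr <- rates_2d(st, p)
  expect_equal(rr$R_att, p$k_on * 16)           # all sites empty
  expect_equal(rr$R_det + rr$R_dec + rr$R_forget + rr$R_orient, 0)
  st$sites$occupancy[1:6] <- c("puller", "puller", "lifter", "informed",
                               "informed", "lifter")
  rr2 <- rates_2d(st, p)
  expect_equal(rr2$R_att, p$k_on * 10)
  expect_equal(rr2$R_det, p$k_off * 4)
  expect_equal(rr2$R_forget, p$k_forget * 2)
  expect_equal(rr2$R_orient, p$k_orient * 2)
  p0 <- p; p0$k_orient <- 0
  expect_equal(rates_2d(st, p0)$R_orient, 0)    # reorientation disabled
  proj <- (rr2$f_tot[1] * st$sites$px + rr2$f_tot[2] * st$sites$py) / p$F_ind
  expect_equal(rr2$site_rates[1], p$k_c * exp(-proj[1]))
  expect_equal(rr2$site_rates[3], p$k_c * exp(+proj[3]))
})

test_that("2D events preserve sites and follow the equilibrium role rule", {
  p <- table1_params("r0.5")
  st <- build_cargo(0.5, 16)
  set.seed(41)
  st <- apply_event_2d(st, "attach", p)
  expect_identical(sum(st$sites$occupancy == "informed"), 1L)
  # forgetting converts the informed ant to an uninformed one in place,
  # with the role drawn from the equilibrium rule (probability 1/2 at zero
  # force projection)
  st_f <- apply_event_2d(st, "forget", p)
  expect_identical(sum(st_f$sites$occupancy == "informed"), 0L)
  expect_identical(sum(st_f$sites$occupancy %in% c("puller", "lifter")), 1L)
  expect_equal(puller_probability(0, p$F_ind), 0.5)
  st_d <- apply_event_2d(st_f, "detach", p)
  expect_true(all(st_d$sites$occupancy == "empty"))
  # orientation at rest is a no-op
  st2 <- build_cargo(0.5, 16)
  st2$sites$occupancy[3] <- "puller"
  st2$vx <- 0; st2$vy <- 0
  p_before <- c(st2$sites$px[3], st2$sites$py[3])
  st3 <- apply_event_2d(st2, "orient", p)
  # velocity is recomputed after the event; the stored axis only changes
  # if the cargo was moving when the event fired
  expect_equal(c(st3$sites$px[3], st3$sites$py[3]), p_before)
})

test_that("wall contact removes only the normal motion component", {
  st <- build_cargo(0.5, 16)
  st$vx <- 0.2; st$vy <- 0.3; st$y <- 2
  st <- advance_and_constrain(st, 1)
  expect_equal(c(st$x, st$y), c(0.2, 2.3))      # free flight off the wall
  st$vx <- 0.1; st$vy <- -5
  st <- advance_and_constrain(st, 1)
  expect_equal(st$y, 0.5)                       # blocked at contact height
  expect_equal(st$vy, 0)                        # normal velocity zeroed
  expect_equal(st$x, 0.3)                       # tangential part preserved
})

test_that("2D trajectories are reproducible and never penetrate the wall", {
  a <- simulate_cargo_2d(0.5, T = 60, seed = 17)
  b <- simulate_cargo_2d(0.5, T = 60, seed = 17)
  expect_identical(as.data.frame(a), as.data.frame(b))
  for (r in c(0.5, 2)) {
    tr <- cached_run_2d(r)
    expect_true(all(tr$y >= r - 1e-9))          # no passage through the opening
    expect_true(all(tr$n_p + tr$n_l + tr$n_inf <= table1_params(
      c("0.5" = "r0.5", "2" = "r2")[as.character(r)])$n_max))
  }
})

test_that("2D carrier populations settle at the three-state stationary law", {
  p <- table1_params("r0.5")
  tr <- simulate_cargo_2d(0.5, T = 4000, seed = 23)
  keep <- tr$t > 300
  o <- occupancy_steady_state(p$k_on, p$k_off, p$k_forget, "three_state")
  expect_equal(mean(tr$n_inf[keep]), o$P_inf * p$n_max, tolerance = 0.2)
  expect_equal(mean(tr$n_p[keep] + tr$n_l[keep]), o$P_u * p$n_max,
               tolerance = 0.12)
})

test_that("small cargoes switch modes while large cargoes oscillate steadily", {
  tr_s <- cached_run_2d(0.5)
  tr_l <- cached_run_2d(2)
  # the small cargo has a central velocity peak absent for the large one
  frac0_s <- mean(abs(tr_s$vx) < 0.1)
  frac0_l <- mean(abs(tr_l$vx) < 0.1)
  expect_gt(frac0_s, 2 * frac0_l)
  # turning times: heavy-tailed for the small cargo, concentrated (quasi
  # periodic) for the large one
  cv <- function(x) stats::sd(x) / mean(x)
  ts_s <- turning_statistics(tr_s)$turning_times
  ts_l <- turning_statistics(tr_l)$turning_times
  expect_gt(cv(ts_s), 1)
  expect_lt(cv(ts_l), 0.8)
  # time near the opening grows as the cargo shrinks (f_ind ~ 1/r)
  near_s <- mean(abs(tr_s$x) < 0.5 & tr_s$y < 1)
  near_l <- mean(abs(tr_l$x) < 2 & tr_l$y < 4)
  expect_gt(near_s, near_l)
})
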