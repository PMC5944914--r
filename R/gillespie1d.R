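#' Force-dependent role-switching rates
#'
#' An uninformed ant switches from lifter to puller at
#' `k_c * exp(+proj / F_ind)` and from puller to lifter at
#' `k_c * exp(-proj / F_ind)`, where `proj` is the projection of the total
#' force on the ant's body axis. Aligned ants rarely stop pulling;
#' opposed ants rarely keep pulling.
#'
#' @param force_projection Projection `f_tot . p_i` of the total force on
#'   the ant's body axis (force units); vectorized.
#' @param F_ind Individuality threshold (> 0).
#' @param k_c Basal switching rate (1/s).
#' @return A list with vectors `r_l_to_p` and `r_p_to_l`.
#' @export
#' @examples
#' role_switch_rates(23, F_ind = 23)  # (e, 1/e)
role_switch_rates <- function(force_projection, F_ind, k_c = 1) {
  if (F_ind <= 0) stop("F_ind must be positive")
  list(r_l_to_p = k_c * exp(force_projection / F_ind),
       r_p_to_l = k_c * exp(-force_projection / F_ind))
}

#' Total force on the 1D cargo
#'
#' Force balance: the tug of war between the uninformed pullers on the two
#' sides plus the restoring pull of the informed ants toward the opening,
#' `f_tot = f0 * (n_p_front - n_p_back - G_effective * s(x))`. Lifters
#' carry no horizontal force (the cargo is fully lifted, friction is
#' neglected).
#'
#' @param n_p_front,n_p_back Puller counts facing +x / -x.
#' @param G_effective Current number (or mean) of informed pullers.
#' @param x Cargo position (cm).
#' @param f0 Single-ant force.
#' @param restoring `"sign"` (sharp) or `"tanh"` (smooth; needs `eps`).
#' @param eps Regularization length for `"tanh"`.
#' @return Total force (force units).
#' @export
total_force_1d <- function(n_p_front, n_p_back, G_effective, x, f0 = 1,
                           restoring = c("sign", "tanh"), eps = NULL) {
  restoring <- match.arg(restoring)
  s <- if (restoring == "sign") sign(x) else {
    if (is.null(eps) || eps <= 0) stop("restoring = 'tanh' requires eps > 0")
    tanh(x / eps)
  }
  f0 * (n_p_front - n_p_back - G_effective * s)
}

#' Role assignment under role-switching equilibrium
#'
#' When an informed ant forgets, or an attachment/detachment must name a
#' puller or lifter, the role is drawn from the local role-switching
#' equilibrium: puller with probability
#' `N_p = 1 / (1 + exp(-2 * force_projection / F_ind))`.
#'
#' @param force_projection Projection of the total force on the site's
#'   body axis.
#' @param F_ind Individuality threshold.
#' @param u Uniform draw in `[0, 1)`.
#' @return `"puller"` or `"lifter"`.
#' @export
removal_role_assignment <- function(force_projection, F_ind, u) {
  if (F_ind <= 0) stop("F_ind must be positive")
  if (any(u < 0 | u >= 1)) stop("u must lie in [0, 1)")
  np <- 1 / (1 + exp(-2 * force_projection / F_ind))
  ifelse(u < np, "puller", "lifter")
}

#' Puller probability at a given force projection
#'
#' @inheritParams removal_role_assignment
#' @return `N_p = 1 / (1 + exp(-2 * force_projection / F_ind))`.
#' @export
puller_probability <- function(force_projection, F_ind) {
  if (F_ind <= 0) stop("F_ind must be positive")
  1 / (1 + exp(-2 * force_projection / F_ind))
}

#' Exact stochastic simulation of the 1D cargo
#'
#' Gillespie simulation of the point cargo under one of three kinetic
#' schemes: `"role_switch"` (scheme 1: sites fully occupied by uninformed
#' ants, constant external restoring force of `G` informed pullers),
#' `"attach_detach"` (scheme 2: plus attachment/detachment of uninformed
#' ants at `k_on`/`k_off`), and `"informed"` (scheme 3: newly attached ants
#' are informed, occupy sites, pull toward the opening and forget at
#' `k_forget`). Between events the cargo moves at constant velocity
#' `v = f_tot / gamma`; the velocity is recomputed after every event.
#'
#' @param scheme `"role_switch"`, `"attach_detach"`, `"informed"`, or 1-3.
#' @param params A [cargo_params()] object (see [table1_params()]).
#' @param T Simulated duration (s).
#' @param seed Integer seed (all randomness flows through R's RNG).
#' @param record_dt Uniform recording grid (s); `0` records every event.
#' @param x0 Initial position (cm).
#' @param restoring `"sign"` (default, the sharp opening) or `"tanh"`.
#' @param eps Regularization length for `"tanh"`.
#' @param init_state Optional integer vector
#'   `c(n_p_front, n_p_back, n_l_front, n_l_back, n_inf_front, n_inf_back)`
#'   overriding the default initial population.
#' @param freeze_position If `TRUE` the cargo position is held fixed
#'   (kinetics only); used for stationary-distribution checks.
#' @param max_events Safety cap on the number of events.
#' @return A 1D [cargo_trajectory()] with columns `t, x, v, n_p_front,
#'   n_p_back, n_l_front, n_l_back, n_inf`; attributes carry event counts.
#' @export
#' @examples
#' tr <- simulate_cargo_1d("role_switch", table1_params("process1"),
#'                         T = 50, seed = 1)
simulate_cargo_1d <- function(scheme, params, T, seed,
                              record_dt = 0.1, x0 = 0,
                              restoring = c("sign", "tanh"), eps = 0.1,
                              init_state = NULL, freeze_position = FALSE,
                              max_events = 5e7) {
  stopifnot(inherits(params, "cargo_params"))
  if (is.character(scheme))
    scheme <- match(match.arg(scheme, c("role_switch", "attach_detach", "informed")),
                    c("role_switch", "attach_detach", "informed"))
  scheme <- as.integer(scheme)
  if (!scheme %in% 1:3) stop("scheme must be 1, 2 or 3")
  restoring <- match.arg(restoring)
  if (T <= 0) stop("T must be positive")
  if (scheme >= 2 && (is.na(params$k_on) || is.na(params$k_off)))
    stop("scheme ", scheme, " requires k_on and k_off")
  if (scheme == 3 && is.na(params$k_forget))
    stop("scheme 3 requires k_forget")
  if (params$n_tot > params$n_max)
    stop("infeasible parameters: n_tot > n_max")
  if (is.null(init_state)) init_state <- integer(0)
  else {
    init_state <- as.integer(init_state)
    stopifnot(length(init_state) == 6, all(init_state >= 0),
              sum(init_state) <= params$n_max)
  }
  set.seed(seed)
  res <- gillespie1d_cpp(scheme, unclass(params), T, record_dt, x0,
                         freeze_position, restoring == "tanh", eps,
                         init_state, max_events)
  df <- as.data.frame(res$records)
  df$n_p <- df$n_p_front + df$n_p_back
  df$n_l <- df$n_l_front + df$n_l_back
  tr <- cargo_trajectory(df, 1L,
                         provenance = list(scheme = scheme, seed = seed,
                                           dt = if (record_dt > 0) record_dt else NULL,
                                           params = unclass(params),
                                           restoring = restoring, eps = eps,
                                           kind = "gillespie1d"))
  attr(tr, "event_counts") <- res$event_counts
  attr(tr, "n_events") <- res$n_events
  attr(tr, "absorbed") <- res$absorbed
  attr(tr, "final_state") <- res$final
  tr
}
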