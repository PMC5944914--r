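#' Build a ring cargo touching the wall at the opening
#'
#' Constructs the 2D cargo state: `n_max` binding sites equally spaced
#' along the ring perimeter, body axes initialized radially outward, and
#' the cargo center placed at the opening in contact with the wall
#' (`y = r`; the wall runs along `y = 0`, transport happens in `y > 0`).
#'
#' @param r Cargo radius (cm).
#' @param n_max Number of binding sites.
#' @return A list of class `cargo_state_2d` with fields `x`, `y`, `vx`,
#'   `vy`, `t`, `r`, and `sites` (data frame: `angle`, `occupancy`,
#'   `px`, `py`).
#' @export
#' @examples
#' build_cargo(0.5, 16)
build_cargo <- function(r, n_max) {
  if (r <= 0) stop("r must be positive")
  if (n_max < 1 || n_max != round(n_max)) stop("n_max must be an integer >= 1")
  ang <- 2 * pi * (seq_len(n_max) - 1) / n_max
  structure(list(x = 0, y = r, vx = 0, vy = 0, t = 0, r = r,
                 sites = data.frame(angle = ang,
                                    occupancy = rep("empty", n_max),
                                    px = cos(ang), py = sin(ang))),
            class = "cargo_state_2d")
}

#' @export
print.cargo_state_2d <- function(x, ...) {
  occ <- table(factor(x$sites$occupancy,
                      levels = c("empty", "puller", "lifter", "informed")))
  cat(sprintf("2D ring cargo (r = %g cm, %d sites) at (%.3f, %.3f), t = %g s\n",
              x$r, nrow(x$sites), x$x, x$y, x$t))
  cat("  occupancy:", paste(names(occ), occ, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# total force on the 2D cargo: pullers along their body axes plus one unit
# pull per informed ant from the center toward the opening center (0, 0)
.force_2d <- function(state, params) {
  s <- state$sites
  pull <- s$occupancy == "puller"
  n_inf <- sum(s$occupancy == "informed")
  fx <- sum(s$px[pull]); fy <- sum(s$py[pull])
  nrm <- sqrt(state$x^2 + state$y^2)
  if (nrm > 0) {
    fx <- fx - n_inf * state$x / nrm
    fy <- fy - n_inf * state$y / nrm
  }
  c(fx, fy) * params$f0
}

#' Event rates of the 2D kinetic scheme
#'
#' @param state A [build_cargo()] state.
#' @param params A [cargo_params()] object (2D column of the standard sets).
#' @return A list with `R_att`, `R_det`, `R_dec`, `R_forget`, `R_orient`,
#'   `R_tot`, the per-site switching rates `site_rates`, and the current
#'   total force `f_tot`.
#' @export
rates_2d <- function(state, params) {
  stopifnot(inherits(state, "cargo_state_2d"), inherits(params, "cargo_params"))
  s <- state$sites
  f <- .force_2d(state, params)
  proj <- (f[1] * s$px + f[2] * s$py) / params$F_ind
  sr <- numeric(nrow(s))
  sr[s$occupancy == "puller"] <- params$k_c * exp(-proj[s$occupancy == "puller"])
  sr[s$occupancy == "lifter"] <- params$k_c * exp(+proj[s$occupancy == "lifter"])
  n_u <- sum(s$occupancy %in% c("puller", "lifter"))
  out <- list(R_att = params$k_on * sum(s$occupancy == "empty"),
              R_det = params$k_off * n_u,
              R_dec = sum(sr),
              R_forget = params$k_forget * sum(s$occupancy == "informed"),
              R_orient = params$k_orient * sum(s$occupancy == "puller"),
              site_rates = sr, f_tot = f)
  out$R_tot <- out$R_att + out$R_det + out$R_dec + out$R_forget + out$R_orient
  out
}

#' Apply one stochastic event to the 2D cargo state
#'
#' Attachment fills a uniformly chosen empty site with an informed ant;
#' detachment empties a uniformly chosen uninformed site; a role switch
#' toggles a site chosen proportionally to its switching rate; forgetting
#' converts a uniformly chosen informed ant to an uninformed one whose
#' role is drawn from the role-switching equilibrium; re-orientation turns
#' a uniformly chosen puller's body axis along the cargo's current
#' direction of motion (a no-op at rest). Velocity is recomputed
#' afterwards.
#'
#' @param state A [build_cargo()] state.
#' @param event One of `"attach"`, `"detach"`, `"switch"`, `"forget"`,
#'   `"orient"`.
#' @param params A [cargo_params()] object.
#' @return The updated state.
#' @export
apply_event_2d <- function(state, event, params) {
  stopifnot(inherits(state, "cargo_state_2d"))
  s <- state$sites
  f <- .force_2d(state, params)
  pick <- function(idx) if (length(idx) == 1L) idx else sample(idx, 1L)
  switch(event,
    attach = {
      idx <- which(s$occupancy == "empty")
      if (!length(idx)) stop("internal inconsistency: attach with no empty site")
      i <- pick(idx)
      s$occupancy[i] <- "informed"
      s$px[i] <- cos(s$angle[i]); s$py[i] <- sin(s$angle[i])
    },
    detach = {
      idx <- which(s$occupancy %in% c("puller", "lifter"))
      if (!length(idx)) stop("internal inconsistency: detach with no uninformed ant")
      s$occupancy[pick(idx)] <- "empty"
    },
    switch = {
      rr <- rates_2d(state, params)
      if (rr$R_dec <= 0) stop("internal inconsistency: switch with no uninformed ant")
      i <- sample(nrow(s), 1L, prob = rr$site_rates)
      s$occupancy[i] <- if (s$occupancy[i] == "puller") "lifter" else "puller"
    },
    forget = {
      idx <- which(s$occupancy == "informed")
      if (!length(idx)) stop("internal inconsistency: forget with no informed ant")
      i <- pick(idx)
      proj <- f[1] * s$px[i] + f[2] * s$py[i]
      s$occupancy[i] <- if (stats::runif(1) < puller_probability(proj, params$F_ind))
        "puller" else "lifter"
    },
    orient = {
      # toward the direction of motion (the constrained velocity): along
      # the wall this is tangential even though the total force is not
      idx <- which(s$occupancy == "puller")
      if (!length(idx)) stop("internal inconsistency: orient with no puller")
      i <- pick(idx)
      vn <- sqrt(state$vx^2 + state$vy^2)
      if (vn > 0) { s$px[i] <- state$vx / vn; s$py[i] <- state$vy / vn }
    },
    stop("unknown event type: ", event))
  state$sites <- s
  f <- .force_2d(state, params)
  state$vx <- f[1] / params$gamma
  state$vy <- f[2] / params$gamma
  if (state$y <= state$r + 1e-12 && state$vy < 0) state$vy <- 0
  state
}

#' Advance the 2D cargo and enforce the wall constraint
#'
#' Moves the center by `v * dt`; if the advance would carry the cargo into
#' the wall (center below the contact height `y = r`), the normal
#' component of the displacement and of the velocity is zeroed (sliding
#' contact). The opening is narrower than the cargo, so the cargo can
#' never pass through it.
#'
#' @param state A [build_cargo()] state.
#' @param dt Time increment (s).
#' @return The advanced state.
#' @export
advance_and_constrain <- function(state, dt) {
  stopifnot(inherits(state, "cargo_state_2d"), dt >= 0)
  state$x <- state$x + state$vx * dt
  state$y <- state$y + state$vy * dt
  if (state$y < state$r) { state$y <- state$r; if (state$vy < 0) state$vy <- 0 }
  state$t <- state$t + dt
  state
}

#' Exact stochastic simulation of the 2D ring cargo
#'
#' Gillespie simulation of a ring cargo carried along a rigid wall with a
#' narrow opening: informed ants attach at empty perimeter sites and pull
#' toward the opening, uninformed ants role-switch under the sensed force,
#' detach, and re-orient toward the total force. Between events the cargo
#' moves at `v = f_tot / gamma` subject to sliding contact with the wall.
#'
#' @param r Cargo radius in cm (0.5, 1 or 2 select the standard parameter
#'   sets; other radii require an explicit `params`).
#' @param T Simulated duration (s).
#' @param seed Integer seed.
#' @param params Optional [cargo_params()] override.
#' @param record_dt Recording grid (s).
#' @param x0,y0 Initial center position (default: at the opening, touching
#'   the wall).
#' @param max_events Safety cap on event count.
#' @return A 2D [cargo_trajectory()] with columns `t, x, y, vx, vy, n_p,
#'   n_l, n_inf`.
#' @export
#' @examples
#' tr <- simulate_cargo_2d(0.5, T = 100, seed = 1)
simulate_cargo_2d <- function(r, T, seed, params = NULL, record_dt = 0.1,
                              x0 = 0, y0 = NULL, max_events = 5e7) {
  if (is.null(params)) {
    set_name <- c("0.5" = "r0.5", "1" = "r1", "2" = "r2")[as.character(r)]
    if (is.na(set_name))
      stop("no standard parameter set for r = ", r, "; supply params")
    params <- table1_params(set_name)
  }
  stopifnot(inherits(params, "cargo_params"))
  if (T <= 0) stop("T must be positive")
  if (is.na(params$r) || params$r <= 0)
    stop("2D simulation requires a positive cargo radius r in params")
  if (any(is.na(c(params$k_on, params$k_off, params$k_forget, params$k_orient))))
    stop("2D simulation requires k_on, k_off, k_forget and k_orient")
  if (is.null(y0)) y0 <- params$r
  set.seed(seed)
  res <- gillespie2d_cpp(unclass(params), T, record_dt, x0, y0, max_events)
  df <- as.data.frame(res$records)
  tr <- cargo_trajectory(df, 2L,
                         provenance = list(scheme = "2d", seed = seed,
                                           dt = record_dt,
                                           params = unclass(params),
                                           kind = "gillespie2d"))
  attr(tr, "event_counts") <- res$event_counts
  attr(tr, "n_events") <- res$n_events
  tr
}
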