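#' Restoring-force profile of the informed ants
#'
#' The informed ants pull the cargo toward the opening at `x = 0`. Their net
#' force is modeled as `g * tanh(x/eps)` (smooth), `g * sign(x)` (sharp
#' limit), or the exact in-plane projection for a ring cargo of radius `r`
#' touching the wall, `g * x / sqrt(x^2 + r^2)`. The smooth profile with
#' `eps ~ r` closely matches the 2D projection.
#'
#' @param x Cargo position(s) (cm).
#' @param g Restoring-force magnitude (velocity units, i.e. force/gamma).
#' @param eps Regularization length (cm); required for `mode = "tanh"`.
#' @param mode One of `"tanh"`, `"sign"`, `"projection2d"`.
#' @param r Cargo radius (cm); required for `mode = "projection2d"`.
#' @return Restoring force toward the origin (same sign as `x`), in
#'   velocity units.
#' @export
#' @examples
#' restoring_force(1, g = 0.1, eps = 0.1)
#' restoring_force(1, g = 0.1, mode = "projection2d", r = 1)
restoring_force <- function(x, g, eps = NULL, mode = c("tanh", "sign", "projection2d"),
                            r = NULL) {
  mode <- match.arg(mode)
  switch(mode,
    tanh = {
      if (is.null(eps) || eps <= 0)
        stop("mode = 'tanh' requires eps > 0; use mode = 'sign' for the sharp limit")
      g * tanh(x / eps)
    },
    sign = g * sign(x),
    projection2d = {
      if (is.null(r) || r <= 0) stop("mode = 'projection2d' requires r > 0")
      g * x / sqrt(x^2 + r^2)
    })
}

#' Acceleration field of the reduced cargo dynamics
#'
#' Evaluates the right-hand side of the velocity equation,
#' `q(x, v) = k_c * (n*sinh(v/f_ind) - 2*(v + g*tanh(x/eps))*cosh(v/f_ind))
#'  - v*(g/eps)*sech(x/eps)^2`.
#' For `eps = 0` the `sech^2` term is dropped and `sign(x)` replaces the
#' `tanh` (the piecewise-smooth limit; its distributional contribution at
#' `x = 0` is the `-2g` velocity jump applied by the integrator at
#' crossings).
#'
#' @param x,v Position (cm) and velocity (cm/s); vectorized.
#' @param rp A [rescaled_params()] object.
#' @return Acceleration(s) `q(x, v)` in cm/s^2.
#' @export
q_eval <- function(x, v, rp) {
  stopifnot(inherits(rp, "rescaled_params"))
  if (rp$f_ind <= 0) stop("f_ind must be positive")
  w <- v / rp$f_ind
  if (rp$eps > 0) {
    rp$k_c * (rp$n * sinh(w) - 2 * (v + rp$g * tanh(x / rp$eps)) * cosh(w)) -
      v * (rp$g / rp$eps) / cosh(x / rp$eps)^2
  } else {
    rp$k_c * (rp$n * sinh(w) - 2 * (v + rp$g * sign(x)) * cosh(w))
  }
}

#' Linearization of the dynamics at the origin
#'
#' Jacobian of `(dx/dt = v, dv/dt = q(x, v))` at the fixed point `(0, 0)`,
#' in closed form: `dq/dx = -2*k_c*g/eps` and
#' `dq/dv = k_c*(n/f_ind - 2) - g/eps`.
#'
#' @param rp A [rescaled_params()] object with `eps > 0` (the piecewise
#'   `eps = 0` field is not differentiable at the origin).
#' @return A 2x2 Jacobian matrix.
#' @export
jacobian_origin <- function(rp) {
  stopifnot(inherits(rp, "rescaled_params"))
  if (rp$eps <= 0)
    stop("linearization undefined for eps = 0 (discontinuous field); ",
         "origin stability in that limit is assessed by simulation")
  qx <- -2 * rp$k_c * rp$g / rp$eps
  qv <- rp$k_c * (rp$n / rp$f_ind - 2) - rp$g / rp$eps
  matrix(c(0, qx, 1, qv), 2, 2,
         dimnames = list(c("x", "v"), c("x", "v")))
}

## ---- piecewise (eps = 0) half-space machinery ------------------------------

# field restricted to one half-space (side = +-1); independent of x
.q_half <- function(v, rp, side) {
  w <- v / rp$f_ind
  rp$k_c * (rp$n * sinh(w) - 2 * (v + rp$g * side) * cosh(w))
}

# Integrate one excursion into half-space `side` from (x = 0, v0), where
# sign(v0) == side. Stops at return to x = 0, at escape (|x| > x_escape),
# or at t = tmax. Returns the pre-jump return velocity and diagnostics.
.half_excursion <- function(v0, rp, side = sign(v0), x_escape = 200,
                            tmax = 1e4, times = NULL,
                            rtol = 1e-10, atol = 1e-12) {
  rhs <- function(t, y, p) list(c(y[2], .q_half(y[2], rp, side)))
  root <- function(t, y, p) c(y[1] * side, x_escape - y[1] * side)
  tt <- if (is.null(times)) c(0, tmax) else unique(c(0, times[times <= tmax], tmax))
  out <- deSolve::lsodar(c(x = side * 1e-12, v = v0), tt, rhs, NULL,
                         rootfunc = root, rtol = rtol, atol = atol)
  fin <- out[nrow(out), ]
  escaped <- fin[["x"]] * side >= x_escape - 1e-6
  returned <- !escaped && fin[["time"]] < tmax - 1e-9
  list(v_return = if (returned) fin[["v"]] else NA_real_,
       t_end = fin[["time"]], escaped = escaped, returned = returned,
       out = out)
}

# Half return map of the symmetric piecewise system on the section x = 0:
# entry speed (post-jump, into half-space) -> next entry speed.
# NA: escape to infinity. <= 0: capture by the origin (chattering).
.half_map <- function(v0, rp, x_escape = 200, tmax = 1e4) {
  exc <- .half_excursion(abs(v0), rp, side = +1, x_escape = x_escape, tmax = tmax)
  if (exc$escaped) return(NA_real_)
  if (!exc$returned) return(0)
  -(exc$v_return + 2 * rp$g)
}

## ---- integration -----------------------------------------------------------

#' Integrate the deterministic cargo dynamics
#'
#' Solves `dx/dt = v`, `dv/dt = q(x, v)` from an initial condition. For
#' `eps > 0` a stiff-capable adaptive solver is used directly; for
#' `eps = 0` the piecewise field is integrated with event location at
#' `x = 0`. The boundary layer of the smooth restoring force acts on a
#' crossing with speed `u` as follows (its distributional limit): for
#' `u > 2g` the cargo crosses and loses `2g` of speed; for `g < u <= 2g`
#' it stalls past the midline and is reflected back into the half-space it
#' came from with speed `u` (the layer does no net work); for `u <= g` it
#' stalls before the midline and slides to the origin (capture). After
#' capture the output is padded with the fixed point.
#'
#' @param rp A [rescaled_params()] object.
#' @param x0,v0 Initial condition.
#' @param T Duration (s).
#' @param dt Output grid spacing (default `T/2000`).
#' @param rtol,atol Solver tolerances.
#' @return A [cargo_trajectory()] with columns `t`, `x`, `v`.
#' @export
#' @examples
#' rp <- rescaled_params(n = 0.8, g = 0.1, f_ind = 0.23, eps = 0)
#' traj <- integrate_meanfield(rp, x0 = 3, v0 = 0.6, T = 100)
integrate_meanfield <- function(rp, x0, v0, T, dt = NULL,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(rp, "rescaled_params"))
  if (T <= 0) stop("T must be positive")
  if (is.null(dt)) dt <- T / 2000
  times <- seq(0, T, by = dt)

  if (rp$eps > 0) {
    rhs <- function(t, y, p) list(c(y[2], q_eval(y[1], y[2], rp)))
    out <- deSolve::lsoda(c(x = x0, v = v0), times, rhs, NULL,
                          rtol = rtol, atol = atol)
    df <- data.frame(t = out[, "time"], x = out[, "x"], v = out[, "v"])
    return(cargo_trajectory(df, dimension = 1L,
                            provenance = list(kind = "meanfield", params = rp)))
  }

  # piecewise eps = 0
  rows <- list(data.frame(t = 0, x = x0, v = v0))
  t_cur <- 0; x_cur <- x0; v_cur <- v0
  side <- if (x_cur != 0) sign(x_cur) else sign(v_cur)
  if (side == 0) {  # exactly at the fixed point
    return(cargo_trajectory(data.frame(t = times, x = 0, v = 0), dimension = 1L,
                            provenance = list(kind = "meanfield", params = rp)))
  }
  captured <- FALSE
  while (t_cur < T - 1e-12 && !captured) {
    rhs <- function(t, y, p) list(c(y[2], .q_half(y[2], rp, side)))
    root <- function(t, y, p) y[1] * side
    seg_times <- unique(c(t_cur, times[times > t_cur + 1e-12], T))
    y0 <- c(x = if (x_cur == 0) side * 1e-12 else x_cur, v = v_cur)
    out <- deSolve::lsodar(y0, seg_times, rhs, NULL, rootfunc = root,
                           rtol = rtol, atol = atol)
    keep <- out[, "time"] > t_cur + 1e-12
    if (any(keep))
      rows[[length(rows) + 1L]] <-
        data.frame(t = out[keep, "time"], x = out[keep, "x"], v = out[keep, "v"])
    fin <- out[nrow(out), ]
    t_cur <- fin[["time"]]; x_cur <- fin[["x"]]; v_cur <- fin[["v"]]
    hit_section <- t_cur < T - 1e-9
    if (!hit_section) break
    if (abs(v_cur) <= rp$g + 1e-12) { captured <- TRUE; break }
    if (abs(v_cur) <= 2 * rp$g) {
      v_cur <- -v_cur               # reflected by the boundary layer
    } else {
      side <- sign(v_cur)           # transmitted into the new half-space
      v_cur <- v_cur - 2 * rp$g * side
    }
    x_cur <- 0
  }
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df$t), , drop = FALSE]
  # resample to the requested grid; pad with the origin after capture
  xi <- stats::approx(df$t, df$x, xout = times, rule = 2)$y
  vi <- stats::approx(df$t, df$v, xout = times, rule = 2)$y
  if (captured) { pad <- times > t_cur; xi[pad] <- 0; vi[pad] <- 0 }
  cargo_trajectory(data.frame(t = times, x = xi, v = vi), dimension = 1L,
                   provenance = list(kind = "meanfield", params = rp,
                                     captured = captured))
}

## ---- nullclines ------------------------------------------------------------

#' Nullcline branches of the acceleration field
#'
#' For each position in `x_grid`, finds all real roots `v` of
#' `q(x, v) = 0` by a sign-bracketed search over a bounded velocity window,
#' and groups them into branches (`lower`/`middle`/`upper` by velocity rank
#' within each half-space).
#'
#' @param rp A [rescaled_params()] object.
#' @param x_grid Positions at which to solve (cm).
#' @param v_window Half-width of the root-search window (default
#'   `n + g + 5*f_ind`, which bounds the terminal velocities).
#' @param n_scan Number of scan points over the window.
#' @return A data frame with columns `x`, `v`, `branch`.
#' @export
nullcline_branches <- function(rp, x_grid, v_window = NULL, n_scan = 801) {
  stopifnot(inherits(rp, "rescaled_params"))
  if (is.null(v_window)) v_window <- rp$n + rp$g + 5 * rp$f_ind
  vs <- seq(-v_window, v_window, length.out = n_scan)
  res <- lapply(x_grid, function(x) {
    qq <- q_eval(x, vs, rp)
    i <- which(qq[-1] * qq[-length(qq)] < 0)
    roots <- vapply(i, function(j)
      stats::uniroot(function(v) q_eval(x, v, rp), c(vs[j], vs[j + 1]),
                     tol = 1e-12)$root, 0)
    roots <- sort(unique(c(roots, vs[qq == 0])))
    if (!length(roots)) return(NULL)
    lab <- if (length(roots) >= 3) c("lower", "middle", "upper")[rank(roots)]
           else if (length(roots) == 2) c("lower", "upper")
           else "middle"
    data.frame(x = x, v = roots, branch = lab)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(x = numeric(), v = numeric(),
                                      branch = character())
  rownames(out) <- NULL
  out
}

#' Unstable limit cycle (separatrix) of the bistable dynamics
#'
#' The separatrix is the unstable periodic orbit separating the basin of
#' the origin from the oscillatory (or escaping) motion. For `eps > 0` it
#' is found by integrating the time-reversed field outward from a small
#' perturbation of the origin (unstable cycles are attractors in reversed
#' time). For `eps = 0` it is the unstable fixed point of the half
#' return map on the section `x = 0` when that exists (near the
#' saddle-node); otherwise the innermost basin boundary is returned: the
#' orbit whose section return speed equals `g`, below which the boundary
#' layer of the restoring force captures the orbit (in the sharp limit
#' the basin acquires a band structure, and this orbit bounds its core).
#' The orbit is assembled from one half-excursion plus its mirror image.
#'
#' @param rp A [rescaled_params()] object.
#' @param T Reverse-integration horizon (`eps > 0` only).
#' @return A list with `v_section` (speed at which the orbit crosses
#'   `x = 0`, post-jump for `eps = 0`) and `orbit` (data frame `t`, `x`,
#'   `v` over one period), or `NULL` if no separatrix exists.
#' @export
separatrix <- function(rp, T = 400) {
  stopifnot(inherits(rp, "rescaled_params"))
  if (rp$eps > 0) {
    rhs <- function(t, y, p) list(c(-y[2], -q_eval(y[1], y[2], rp)))
    out <- deSolve::lsoda(c(x = 1e-3, v = 0), seq(0, T, length.out = 4000),
                          rhs, NULL, rtol = 1e-9, atol = 1e-11)
    n <- nrow(out)
    tail <- out[out[, "time"] > 0.75 * T, , drop = FALSE]
    if (max(abs(tail[, "x"])) > 100) return(NULL)  # reversed flow escaped
    orbit <- data.frame(t = tail[, "time"] - tail[1, "time"],
                        x = tail[, "x"], v = tail[, "v"])
    sec <- tail[which.min(abs(tail[, "x"])), "v"]
    return(list(v_section = abs(sec), orbit = orbit))
  }
  # eps = 0: the basin boundary is either the unstable fixed point of the
  # transmitting return map (near the saddle-node) or, closer to the
  # homoclinic threshold, the stall orbit whose return speed equals g
  # (below which the boundary layer captures the orbit).
  fp <- poincare_fixed_points(rp)
  root <- fp$v_unstable
  if (is.null(root)) {
    h <- function(u) abs(.half_excursion(u, rp, side = +1)$v_return) - rp$g
    root <- tryCatch(stats::uniroot(h, c(1e-3 * rp$g, 2 * rp$g), tol = 1e-9)$root,
                     error = function(e) NULL)
    if (is.null(root)) return(NULL)
  }
  exc <- .half_excursion(root, rp, side = +1)
  half <- data.frame(t = exc$out[, "time"], x = exc$out[, "x"], v = exc$out[, "v"])
  mirror <- data.frame(t = half$t + max(half$t), x = -half$x, v = -half$v)
  list(v_section = root, orbit = rbind(half, mirror))
}
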