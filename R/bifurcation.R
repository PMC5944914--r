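#' Subcritical Hopf threshold of the origin
#'
#' Closed-form critical individuality at which the fixed point at the
#' origin changes stability (trace of the linearization crosses zero):
#' `f_c1 = (n/2) / (1 + g / (2*k_c*eps))`. The fixed point is stable for
#' `f_ind > f_c1`. As `eps -> 0` the threshold vanishes and the origin is
#' always stable.
#'
#' @param rp A [rescaled_params()] object (`f_ind` is ignored).
#' @return The critical `f_ind` value.
#' @export
#' @examples
#' hopf_threshold(rescaled_params(0.8, 0.1, 0.23, eps = 0.1))
hopf_threshold <- function(rp) {
  stopifnot(inherits(rp, "rescaled_params"))
  if (rp$eps == 0) return(0)
  (rp$n / 2) / (1 + rp$g / (2 * rp$k_c * rp$eps))
}

#' Velocity at the homoclinic transition
#'
#' At the homoclinic bifurcation the merging nullclines meet at the
#' velocities `v_plus = g - sqrt((n/2)*(n/2 - f_ind))` (right half-space)
#' and `v_minus = -v_plus`.
#'
#' @param rp A [rescaled_params()] object; requires `f_ind <= n/2`.
#' @return Named vector `c(v_plus, v_minus)` in cm/s.
#' @export
homoclinic_velocity <- function(rp) {
  stopifnot(inherits(rp, "rescaled_params"))
  rad <- (rp$n / 2) * (rp$n / 2 - rp$f_ind)
  if (rad < 0)
    stop("negative radicand: homoclinic velocity requires f_ind <= n/2")
  vp <- rp$g - sqrt(rad)
  c(v_plus = vp, v_minus = -vp)
}

#' Homoclinic bifurcation threshold
#'
#' Solves the transcendental fixed-point condition for the critical
#' individuality at which the two approaching nullcline branches merge and
#' unbounded motion becomes a bounded limit cycle:
#' `f = (n/2) * sech((-g + sqrt((n/2)*(n/2 - f))) / f)^2`.
#' The smallest root on `(0, n/2)` is returned (located by a sign-change
#' scan and bracketed root refinement to residual below `tol`).
#'
#' @param n,g,k_c Reduced parameters (the threshold does not depend on
#'   `k_c`, which only sets the time scale; it is accepted for interface
#'   symmetry).
#' @param tol Root residual tolerance.
#' @return A list of class `homoclinic_root` with `f_c2`, `residual`, and
#'   the search diagnostics.
#' @export
#' @examples
#' homoclinic_threshold(n = 0.8, g = 0.1)$f_c2  # ~0.2076
homoclinic_threshold <- function(n, g, k_c = 1, tol = 1e-10) {
  if (n <= 0) stop("n must be positive")
  if (g < 0) stop("g must be non-negative")
  FF <- function(f) (n / 2) / cosh((-g + sqrt((n / 2) * (n / 2 - f))) / f)^2 - f
  fs <- seq(n / 2 * 1e-3, n / 2 * (1 - 1e-9), length.out = 600)
  Fv <- vapply(fs, FF, 0)
  i <- which(Fv[-1] * Fv[-length(Fv)] < 0)
  if (!length(i))
    stop("no homoclinic threshold in (0, n/2) for these parameters")
  root <- stats::uniroot(FF, c(fs[i[1]], fs[i[1] + 1]), tol = tol / 10)$root
  structure(list(f_c2 = root, residual = FF(root),
                 v_transition = {
                   vp <- g - sqrt((n / 2) * (n / 2 - root))
                   c(v_plus = vp, v_minus = -vp)
                 },
                 n_brackets = length(i)),
            class = "homoclinic_root")
}

#' @export
print.homoclinic_root <- function(x, ...) {
  cat(sprintf("Homoclinic threshold f_c2 = %.6f (residual %.2e)\n",
              x$f_c2, x$residual))
  invisible(x)
}

#' Homoclinic threshold by direct-simulation bisection
#'
#' Independent check of [homoclinic_threshold()]: from a far initial
#' condition on the section `x = 0`, the piecewise (`eps = 0`) flow either
#' escapes to infinity along a nullcline (below the threshold) or returns
#' to the section (above it). Bisection on `f_ind` locates the boundary.
#'
#' @param n,g,k_c Reduced parameters.
#' @param f_lo,f_hi Initial bracket.
#' @param tol Bisection width in `f_ind`.
#' @return The threshold estimate.
#' @export
homoclinic_threshold_sim <- function(n, g, k_c = 1, f_lo = 0.3 * n / 2,
                                     f_hi = n / 2 * 0.999, tol = 1e-4) {
  escapes <- function(f) {
    rp <- rescaled_params(n, g, f, eps = 0, k_c = k_c)
    .half_excursion(2 * n, rp, side = +1)$escaped
  }
  if (!escapes(f_lo)) stop("f_lo is not below the homoclinic threshold")
  if (escapes(f_hi)) stop("f_hi is not above the homoclinic threshold")
  while (f_hi - f_lo > tol) {
    mid <- (f_lo + f_hi) / 2
    if (escapes(mid)) f_lo <- mid else f_hi <- mid
  }
  (f_lo + f_hi) / 2
}

## ---- saddle-node of cycles -------------------------------------------------

# D(v) = P(v) - v of the half return map on a speed grid; the stable cycle
# and the separatrix are the two roots; at the saddle-node max D = 0.
.return_map_gap <- function(rp, n_grid = 31) {
  lo <- 2 * rp$g + 1e-4
  hi <- rp$n + rp$g
  vg <- seq(lo, hi, length.out = n_grid)
  Dv <- vapply(vg, function(v) {
    p <- .half_map(v, rp)
    if (is.na(p)) return(Inf)      # escape: treated as above the cycle
    p - v
  }, 0)
  j <- which.max(Dv)
  # refine the maximum of D around the coarse argmax
  if (is.finite(Dv[j]) && j > 1 && j < n_grid) {
    opt <- stats::optimize(function(v) {
      p <- .half_map(v, rp)
      if (is.na(p)) return(-Inf)
      p - v
    }, c(vg[j - 1], vg[j + 1]), maximum = TRUE, tol = 1e-6)
    return(list(max_gap = opt$objective, v_at_max = opt$maximum, grid = vg, D = Dv))
  }
  list(max_gap = max(Dv), v_at_max = vg[j], grid = vg, D = Dv)
}

#' Saddle-node threshold of the stable limit cycle
#'
#' Locates the individuality at which the stable relaxation-oscillation
#' cycle coalesces with the separatrix and both vanish. Uses the half
#' return map `P` of the piecewise (`eps = 0`) system on the Poincare
#' section `x = 0, v > 0`: a cycle exists while `P(v) - v` attains a
#' positive maximum between the two fixed points; the threshold is located
#' by bisection on `f_ind` over the sign of that maximum.
#'
#' @param n,g,k_c Reduced parameters.
#' @param f_lo Lower bracket (must carry a stable cycle; default just above
#'   the homoclinic threshold).
#' @param f_hi Upper bracket (no cycle; default `n/2`).
#' @param tol Bisection width in `f_ind`.
#' @return A list of class `saddle_node_root` with `f_c3`, the final
#'   bracket, and iteration diagnostics.
#' @export
#' @examples
#' \donttest{
#' saddle_node_threshold(n = 0.8, g = 0.1)$f_c3  # ~0.255
#' }
saddle_node_threshold <- function(n, g, k_c = 1, f_lo = NULL, f_hi = NULL,
                                  tol = 1e-3) {
  if (is.null(f_lo)) f_lo <- homoclinic_threshold(n, g, k_c)$f_c2 + 5 * tol
  if (is.null(f_hi)) f_hi <- n / 2 * 0.999
  has_cycle <- function(f) {
    rp <- rescaled_params(n, g, f, eps = 0, k_c = k_c)
    gp <- .return_map_gap(rp)
    is.finite(gp$max_gap) && gp$max_gap > 0
  }
  if (!has_cycle(f_lo))
    stop("no stable cycle at f_lo = ", f_lo, "; cannot bracket the saddle-node")
  if (has_cycle(f_hi))
    stop("stable cycle persists at f_hi = ", f_hi, "; cannot bracket the saddle-node")
  iters <- 0L
  while (f_hi - f_lo > tol) {
    mid <- (f_lo + f_hi) / 2
    if (has_cycle(mid)) f_lo <- mid else f_hi <- mid
    iters <- iters + 1L
  }
  structure(list(f_c3 = (f_lo + f_hi) / 2, bracket = c(f_lo, f_hi),
                 iterations = iters, tol = tol),
            class = "saddle_node_root")
}

#' @export
print.saddle_node_root <- function(x, ...) {
  cat(sprintf("Saddle-node of cycles at f_c3 = %.4f (bracket [%.4f, %.4f], %d bisections)\n",
              x$f_c3, x$bracket[1], x$bracket[2], x$iterations))
  invisible(x)
}

#' Stable and unstable Poincare fixed points of the return map
#'
#' Returns the section speeds of the stable limit cycle and the separatrix
#' of the piecewise system (fixed points of the half return map), or `NULL`
#' for whichever does not exist.
#'
#' @param rp A [rescaled_params()] object with `eps = 0`.
#' @return List with `v_stable`, `v_unstable` (post-jump section speeds).
#' @export
poincare_fixed_points <- function(rp) {
  stopifnot(inherits(rp, "rescaled_params"), rp$eps == 0)
  D <- function(v) {
    p <- .half_map(v, rp)
    if (is.na(p)) return(Inf)
    p - v
  }
  gp <- .return_map_gap(rp)
  if (!is.finite(gp$max_gap) || gp$max_gap < 0)
    return(list(v_stable = NULL, v_unstable = NULL))
  hi <- rp$n + rp$g
  v_st <- tryCatch(stats::uniroot(D, c(gp$v_at_max, hi), tol = 1e-9)$root,
                   error = function(e) NULL)
  v_un <- tryCatch(stats::uniroot(D, c(2 * rp$g + 1e-4, gp$v_at_max),
                                  tol = 1e-9)$root,
                   error = function(e) NULL)
  list(v_stable = v_st, v_unstable = v_un)
}

## ---- phase classification --------------------------------------------------

#' Classify a point of the restoring-force / individuality plane
#'
#' Returns the dynamical phase at `(g, f_ind)`:
#' `phase_i` (bi-stability between convergence and unbounded motion,
#' `f_ind < f_c2`), `phase_ii` (bi-stability between convergence and a
#' stable limit cycle, `f_c2 <= f_ind < f_c3`), or `phase_iii`
#' (global convergence, `f_ind >= f_c3`). For finite `eps`, points with
#' `f_ind` below the Hopf threshold are flagged
#' `unstable_no_bistability` (the fixed point itself is unstable).
#'
#' @param g,f_ind Coordinates of the point.
#' @param n Rescaled pulling capacity.
#' @param k_c Basal switching rate.
#' @param eps Regularization length (0 = sharp limit).
#' @param f_c2,f_c3 Optional precomputed thresholds at this `g` (computed
#'   if missing; passing them makes grid sweeps cheap).
#' @return A character label.
#' @export
#' @examples
#' classify_phase(0.1, 0.18, n = 0.8)  # "phase_i"
classify_phase <- function(g, f_ind, n, k_c = 1, eps = 0,
                           f_c2 = NULL, f_c3 = NULL) {
  if (g < 0) stop("g must be non-negative")
  if (eps > 0 && f_ind < hopf_threshold(rescaled_params(n, g, max(f_ind, 1e-12), eps, k_c)))
    return("unstable_no_bistability")
  if (is.null(f_c2))
    f_c2 <- tryCatch(homoclinic_threshold(n, g, k_c)$f_c2,
                     error = function(e) NA_real_)
  if (is.na(f_c2)) return("phase_iii")  # no homoclinic in range: no free phase
  if (f_ind < f_c2) return("phase_i")
  if (is.null(f_c3))
    f_c3 <- tryCatch(saddle_node_threshold(n, g, k_c)$f_c3,
                     error = function(e) NA_real_)
  if (!is.na(f_c3) && f_ind >= f_c3) return("phase_iii")
  "phase_ii"
}

#' Phase diagram over the (g, f_ind) plane
#'
#' Computes the homoclinic and saddle-node critical curves per `g` column
#' (and the closed-form Hopf curve for finite `eps`) and classifies every
#' grid point.
#'
#' @param g_range,f_range Length-2 ranges of `g` and `f_ind`.
#' @param n,k_c,eps Reduced parameters.
#' @param resolution Grid points per axis (scalar or length 2:
#'   `c(n_g, n_f)`).
#' @return An object of class `phase_diagram`: list with `grid` (data
#'   frame `g`, `f_ind`, `label`) and `curves` (data frame `g`, `f_c1`,
#'   `f_c2`, `f_c3`).
#' @export
phase_diagram <- function(g_range = c(0.01, 0.3), f_range = c(0.05, 0.4),
                          n = 0.8, k_c = 1, eps = 0, resolution = c(8, 25)) {
  if (any(resolution < 2)) stop("resolution must be at least 2 per axis")
  if (length(resolution) == 1L) resolution <- rep(resolution, 2)
  gs <- seq(g_range[1], g_range[2], length.out = resolution[1])
  fs <- seq(f_range[1], f_range[2], length.out = resolution[2])
  curves <- do.call(rbind, lapply(gs, function(g) {
    f2 <- tryCatch(homoclinic_threshold(n, g, k_c)$f_c2,
                   error = function(e) NA_real_)
    f3 <- if (is.na(f2)) NA_real_ else
      tryCatch(saddle_node_threshold(n, g, k_c)$f_c3,
               error = function(e) NA_real_)
    f1 <- if (eps > 0) (n / 2) / (1 + g / (2 * k_c * eps)) else 0
    data.frame(g = g, f_c1 = f1, f_c2 = f2, f_c3 = f3)
  }))
  grid <- do.call(rbind, lapply(seq_along(gs), function(i) {
    data.frame(g = gs[i], f_ind = fs,
               label = vapply(fs, function(f)
                 classify_phase(gs[i], f, n, k_c, eps,
                                f_c2 = curves$f_c2[i], f_c3 = curves$f_c3[i]),
                 ""))
  }))
  structure(list(grid = grid, curves = curves, n = n, k_c = k_c, eps = eps),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("Phase diagram (n = %g, k_c = %g, eps = %g): %d grid points\n",
              x$n, x$k_c, x$eps, nrow(x$grid)))
  print(table(x$grid$label))
  invisible(x)
}
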