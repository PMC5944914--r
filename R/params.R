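#' Physical parameters of the ant-cargo system
#'
#' Bundles the kinetic and mechanical constants of the cooperative-transport
#' model: the force scale of a single ant, the individuality threshold, the
#' mechanical response coefficient of the cargo, the carrier populations and
#' binding-site count, and the event rates of the stochastic schemes.
#'
#' @param f0 Pulling force of a single ant (force units; 1 in the 1D model).
#' @param F_ind Individuality force threshold: force scale above which an ant
#'   responds to the total force applied by the group.
#' @param gamma Mechanical cargo response coefficient (force·time/length);
#'   total force and velocity are related by `f_tot = gamma * v`.
#' @param n_tot Mean number of uninformed carrying ants.
#' @param G Mean number of informed ants (newly attached ants that pull
#'   toward the opening).
#' @param n_max Total number of binding sites on the cargo.
#' @param k_c Basal role-switching rate (1/s).
#' @param k_on,k_off Attachment/detachment rates (1/s); `NA` when the scheme
#'   has no attachment kinetics.
#' @param k_forget Rate at which informed ants lose their directional
#'   information and become uninformed (1/s).
#' @param k_orient Re-orientation rate of uninformed pullers (1/s; 2D only).
#' @param r Cargo radius (cm; 2D only).
#' @param opening_width Width of the opening in the obstacle (cm).
#'
#' @return An object of class `cargo_params` (a validated named list).
#' @seealso [table1_params()] for the standard parameter sets,
#'   [rescale_parameters()] for the reduced 1D parameters.
#' @export
#' @examples
#' p <- cargo_params(f0 = 1, F_ind = 23, gamma = 100, n_tot = 80, G = 10, n_max = 80)
#' rescale_parameters(p, eps = 0.1)
cargo_params <- function(f0 = 1, F_ind = 23, gamma = 100, n_tot = 80, G = 10,
                         n_max = 80, k_c = 1, k_on = NA_real_, k_off = NA_real_,
                         k_forget = NA_real_, k_orient = NA_real_, r = NA_real_,
                         opening_width = 0.5) {
  p <- list(f0 = f0, F_ind = F_ind, gamma = gamma, n_tot = n_tot, G = G,
            n_max = n_max, k_c = k_c, k_on = k_on, k_off = k_off,
            k_forget = k_forget, k_orient = k_orient, r = r,
            opening_width = opening_width)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L)
      stop("parameter '", nm, "' must be a single numeric value")
  }
  if (!is.finite(f0) || f0 <= 0) stop("f0 must be positive")
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be positive")
  if (!is.finite(F_ind) || F_ind <= 0) stop("F_ind must be positive")
  if (!is.finite(n_max) || n_max < 1 || n_max != round(n_max))
    stop("n_max must be an integer >= 1")
  if (n_tot < 0 || G < 0) stop("n_tot and G must be non-negative")
  if (n_tot > n_max + 1e-9)
    stop("n_tot exceeds the number of binding sites n_max")
  # informed ants occupy binding sites only in the schemes with forgetting
  # kinetics; elsewhere they are an external restoring force
  if (!is.na(k_forget) && n_tot + G > n_max + 1e-9)
    stop("n_tot + G exceeds the number of binding sites n_max")
  rates <- c(k_c = k_c, k_on = k_on, k_off = k_off,
             k_forget = k_forget, k_orient = k_orient)
  bad <- !is.na(rates) & rates < 0
  if (any(bad)) stop("negative rate(s): ", paste(names(rates)[bad], collapse = ", "))
  structure(p, class = "cargo_params")
}

#' @export
print.cargo_params <- function(x, ...) {
  cat("Ant-cargo physical parameters\n")
  v <- unlist(x)
  for (nm in names(v)) cat(sprintf("  %-14s %s\n", nm, format(v[[nm]])))
  invisible(x)
}

#' Standard parameter sets for the 1D and 2D simulations
#'
#' Returns the default parameter columns used throughout the package: the 1D
#' mean-field model, the three 1D stochastic schemes, and the three 2D ring
#' cargoes (radii 2, 1, 0.5 cm).
#'
#' For the schemes with attachment kinetics the listed `n_max` is the
#' binding-site count while `n_tot` and `G` are the stationary target means
#' of the kinetics (the listed rates make the stationary uninformed mean
#' equal 80 and the informed mean equal 10 in 1D). For the 2D cargoes the
#' response coefficient follows `gamma(r) = (f0 / 0.14) * (r / 0.5)`,
#' anchored so a single ant pulls the small cargo at 0.14 cm/s, with
#' `gamma` proportional to `r`; the attribute `"gamma_scale"` records
#' `gamma / 25`.
#'
#' @param set One of `"1d"` (mean-field column), `"process1"`,
#'   `"process2"`, `"process3"` (1D stochastic schemes), or `"r2"`, `"r1"`,
#'   `"r0.5"` (2D cargo radii in cm).
#' @return A [cargo_params()] object.
#' @export
#' @examples
#' table1_params("r0.5")
table1_params <- function(set = c("1d", "process1", "process2", "process3",
                                  "r2", "r1", "r0.5")) {
  set <- match.arg(set)
  p <- switch(set,
    "1d"       = cargo_params(f0 = 1, F_ind = 23, gamma = 100, n_tot = 80,
                              G = 10, n_max = 80, k_c = 1),
    "process1" = cargo_params(f0 = 1, F_ind = 23, gamma = 100, n_tot = 80,
                              G = 10, n_max = 80, k_c = 1),
    "process2" = cargo_params(f0 = 1, F_ind = 23, gamma = 100, n_tot = 80,
                              G = 10, n_max = 100, k_c = 1,
                              k_on = 0.06, k_off = 0.015),
    "process3" = cargo_params(f0 = 1, F_ind = 23, gamma = 100, n_tot = 80,
                              G = 10, n_max = 110, k_c = 1,
                              k_on = 0.06, k_off = 0.015, k_forget = 0.12),
    "r2"   = cargo_params(f0 = 2.8, F_ind = 28, gamma = gamma_2d(2),
                          n_tot = 52.5, G = 8.5, n_max = 96, k_c = 1,
                          k_on = 0.0214, k_off = 0.015, k_forget = 0.09,
                          k_orient = 0.7, r = 2),
    "r1"   = cargo_params(f0 = 2.8, F_ind = 28, gamma = gamma_2d(1),
                          n_tot = 25.8, G = 4.2, n_max = 48, k_c = 1,
                          k_on = 0.0214, k_off = 0.015, k_forget = 0.09,
                          k_orient = 0.7, r = 1),
    "r0.5" = cargo_params(f0 = 2.8, F_ind = 28, gamma = gamma_2d(0.5),
                          n_tot = 8.6, G = 1.4, n_max = 16, k_c = 1,
                          k_on = 0.0214, k_off = 0.015, k_forget = 0.09,
                          k_orient = 0.7, r = 0.5))
  if (set %in% c("r2", "r1", "r0.5"))
    attr(p, "gamma_scale") <- p$gamma / 25
  attr(p, "set") <- set
  p
}

#' Mechanical response coefficient of a 2D ring cargo
#'
#' The response coefficient scales linearly with cargo radius (the number of
#' carriers is proportional to the perimeter), anchored so that a single ant
#' pulling parallel to the wall moves the reference cargo at `v_single`.
#'
#' @param r Cargo radius (cm).
#' @param f0 Single-ant force.
#' @param v_single Single-ant velocity for the reference cargo (cm/s).
#' @param r_ref Reference radius (cm).
#' @return `gamma` in force·s/cm.
#' @export
gamma_2d <- function(r, f0 = 2.8, v_single = 0.14, r_ref = 0.5) {
  if (any(r <= 0)) stop("r must be positive")
  (f0 / v_single) * (r / r_ref)
}

#' Rescale physical parameters to the reduced 1D equations of motion
#'
#' The reduced cargo dynamics depend on three velocity-scale parameters:
#' the total pulling capacity `n = f0 * n_tot / gamma`, the informed
#' restoring force `g = f0 * G / gamma`, and the rescaled individuality
#' `f_ind = F_ind / gamma`, together with the regularization length `eps`
#' of the restoring-force profile and the basal switching rate `k_c`.
#'
#' @param p A [cargo_params()] object.
#' @param eps Regularization length (cm) of the `tanh(x/eps)` restoring
#'   profile; `eps = 0` encodes the sharp `sign(x)` limit.
#' @return An object of class `rescaled_params` with fields `n`, `g`,
#'   `f_ind`, `eps`, `k_c`.
#' @export
#' @examples
#' rescale_parameters(table1_params("1d"), eps = 0)  # n=0.8, g=0.1, f_ind=0.23
rescale_parameters <- function(p, eps = 0) {
  stopifnot(inherits(p, "cargo_params"))
  if (p$gamma <= 0 || p$f0 <= 0) stop("gamma and f0 must be positive")
  rescaled_params(n = p$f0 * p$n_tot / p$gamma,
                  g = p$f0 * p$G / p$gamma,
                  f_ind = p$F_ind / p$gamma,
                  eps = eps, k_c = p$k_c)
}

#' Construct reduced parameters directly
#'
#' @param n Rescaled total pulling capacity (cm/s).
#' @param g Rescaled informed restoring force (cm/s).
#' @param f_ind Rescaled individuality (cm/s).
#' @param eps Regularization length (cm); 0 means the sharp `sign(x)` limit.
#' @param k_c Basal role-switching rate (1/s).
#' @return An object of class `rescaled_params`.
#' @export
rescaled_params <- function(n, g, f_ind, eps = 0, k_c = 1) {
  if (!is.finite(n) || n <= 0) stop("n must be positive")
  if (!is.finite(g) || g < 0) stop("g must be non-negative")
  if (!is.finite(f_ind) || f_ind <= 0) stop("f_ind must be positive")
  if (!is.finite(eps) || eps < 0) stop("eps must be >= 0")
  if (!is.finite(k_c) || k_c <= 0) stop("k_c must be positive")
  structure(list(n = n, g = g, f_ind = f_ind, eps = eps, k_c = k_c),
            class = "rescaled_params")
}

#' @export
print.rescaled_params <- function(x, ...) {
  cat(sprintf("Reduced cargo parameters: n = %g, g = %g, f_ind = %g, eps = %g, k_c = %g\n",
              x$n, x$g, x$f_ind, x$eps, x$k_c))
  invisible(x)
}

#' Stationary site-occupancy fractions of the attachment kinetics
#'
#' For the two-state kinetics (uninformed ants attach at `k_on` and detach
#' at `k_off`) the stationary occupied fraction is
#' `P_u = k_on / (k_on + k_off)`. For the three-state kinetics (attachments
#' are informed, convert to uninformed at `k_forget`, and uninformed ants
#' detach at `k_off`) the stationary fractions are
#' `P_inf = 1 / (1 + kappa1 + kappa2)` and
#' `P_u = kappa1 / (1 + kappa1 + kappa2)` with
#' `kappa1 = k_forget / k_off`, `kappa2 = k_forget / k_on`.
#'
#' @param k_on,k_off Attachment/detachment rates (1/s).
#' @param k_forget Forgetting rate (1/s); required for `"three_state"`.
#' @param scheme `"two_state"` or `"three_state"`.
#' @return A list of class `occupancy` with `P_u`, `P_inf`, `kappa1`,
#'   `kappa2` (the kappas are `NA` for the two-state scheme).
#' @export
#' @examples
#' occupancy_steady_state(0.06, 0.015)             # P_u = 0.8
#' occupancy_steady_state(0.06, 0.015, 0.12, "three_state")
occupancy_steady_state <- function(k_on, k_off, k_forget = NULL,
                                   scheme = c("two_state", "three_state")) {
  scheme <- match.arg(scheme)
  if (k_on < 0 || k_off < 0) stop("rates must be non-negative")
  if (k_on + k_off <= 0) stop("k_on + k_off must be positive")
  if (scheme == "two_state") {
    out <- list(P_u = k_on / (k_on + k_off), P_inf = 0,
                kappa1 = NA_real_, kappa2 = NA_real_)
  } else {
    if (is.null(k_forget) || is.na(k_forget) || k_forget < 0)
      stop("three-state kinetics require a non-negative k_forget")
    if (k_off <= 0 || k_on <= 0)
      stop("three-state kinetics require positive k_on and k_off")
    kappa1 <- k_forget / k_off
    kappa2 <- k_forget / k_on
    denom <- 1 + kappa1 + kappa2
    out <- list(P_u = kappa1 / denom, P_inf = 1 / denom,
                kappa1 = kappa1, kappa2 = kappa2)
  }
  structure(c(out, scheme = scheme), class = "occupancy")
}

#' Estimate the number of binding sites from stationary occupancy
#'
#' Inverts the stationary occupancy relations: for two-state kinetics
#' `n_max = n_tot * (1 + k_off/k_on)`; for three-state kinetics
#' `n_max = (n_tot + G) * (1 + kappa2 / (1 + kappa1))`, i.e.
#' `(n_tot + G) / (P_u + P_inf)`.
#'
#' @param n_tot_mean Observed mean number of uninformed carriers.
#' @param G_mean Observed mean number of informed carriers (three-state).
#' @param occupancy An [occupancy_steady_state()] result.
#' @return Estimated `n_max` (not rounded).
#' @export
estimate_binding_sites <- function(n_tot_mean, G_mean = 0, occupancy) {
  stopifnot(inherits(occupancy, "occupancy"))
  if (occupancy$scheme == "two_state") {
    if (occupancy$P_u <= 0) stop("zero occupancy: cannot estimate n_max")
    n_tot_mean / occupancy$P_u
  } else {
    tot <- occupancy$P_u + occupancy$P_inf
    if (tot <= 0) stop("zero occupancy: cannot estimate n_max")
    (n_tot_mean + G_mean) / tot
  }
}

#' Estimate the forgetting rate from the carrier populations
#'
#' Solves the three-state stationary relations for `k_forget` given the
#' binding-site count, the mean carrier populations and the attachment/
#' detachment rates:
#' `k_forget = (n_max/(G + n_tot) - 1) * k_on / (1 - (k_on/k_off) * (n_max/(G + n_tot) - 1))`.
#'
#' @param n_max Number of binding sites.
#' @param G_mean,n_tot_mean Mean informed/uninformed populations.
#' @param k_on,k_off Attachment/detachment rates (1/s).
#' @return Estimated `k_forget` (1/s).
#' @export
estimate_forget_rate <- function(n_max, G_mean, n_tot_mean, k_on, k_off) {
  if (G_mean + n_tot_mean <= 0) stop("G_mean + n_tot_mean must be positive")
  ratio <- n_max / (G_mean + n_tot_mean) - 1
  denom <- 1 - (k_on / k_off) * ratio
  if (denom <= 0)
    stop("infeasible parameter combination: denominator of the forgetting-rate relation is <= 0")
  ratio * k_on / denom
}

## ---- configuration files ---------------------------------------------------

.config_keys <- c("f0", "F_ind", "gamma", "n_tot", "G", "n_max", "k_c",
                  "k_on", "k_off", "k_forget", "k_orient", "r",
                  "opening_width", "eps", "scheme", "seed", "T")

#' Read / write a flat key-value configuration file
#'
#' The configuration format is a plain-text document of `key = value` lines
#' (`#` starts a comment). Recognised keys are exactly `f0, F_ind, gamma,
#' n_tot, G, n_max, k_c, k_on, k_off, k_forget, k_orient, r, opening_width,
#' eps, scheme, seed, T`; any other key is an error.
#'
#' @param path File path.
#' @return `read_config()` returns a named list of numeric values;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% .config_keys)
      stop("unknown config key: '", key, "'")
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (is.na(num)) val else num
  }
  cfg
}

#' @param cfg Named list of configuration values.
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  bad <- setdiff(names(cfg), .config_keys)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  writeLines(sprintf("%s = %s", names(cfg), vapply(cfg, format, "")), path)
  invisible(path)
}

# cargo_params from a config list (missing keys fall back to defaults)
.params_from_config <- function(cfg) {
  take <- intersect(names(cfg), names(formals(cargo_params)))
  do.call(cargo_params, cfg[take])
}
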