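#' Cargo trajectory container
#'
#' A time series of cargo states: a data frame with a strictly increasing
#' time column `t`, position/velocity columns (`x`, `v` in 1D; `x`, `y`,
#' `vx`, `vy` in 2D) and optional carrier-count columns, plus provenance
#' attributes (generating scheme, seed, parameters).
#'
#' @param df Data frame of state snapshots.
#' @param dimension 1 or 2.
#' @param provenance Named list (scheme, seed, params, dt, ...).
#' @return The data frame with class `cargo_trajectory`.
#' @export
cargo_trajectory <- function(df, dimension = 1L, provenance = list()) {
  stopifnot(is.data.frame(df), "t" %in% names(df))
  need <- if (dimension == 1L) c("x", "v") else c("x", "y", "vx", "vy")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory of dimension ", dimension, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) > 1 && any(diff(df$t) <= 0))
    stop("trajectory times must be strictly increasing")
  structure(df, dimension = as.integer(dimension), provenance = provenance,
            class = c("cargo_trajectory", "data.frame"))
}

#' @export
print.cargo_trajectory <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf("Cargo trajectory (%dD): %d samples over %.6g s",
              attr(x, "dimension"), nrow(x), max(x$t) - min(x$t)))
  if (!is.null(pv$scheme)) cat(", scheme", pv$scheme)
  if (!is.null(pv$seed)) cat(", seed", pv$seed)
  cat("\n")
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Resample a trajectory to a uniform time grid
#'
#' Linear interpolation of every numeric column onto `seq(min(t), max(t),
#' by = dt)`. Event-time Gillespie output must be resampled before mode
#' segmentation.
#'
#' @param traj A [cargo_trajectory()].
#' @param dt Grid spacing (s).
#' @return A resampled `cargo_trajectory`.
#' @export
resample_trajectory <- function(traj, dt = 0.1) {
  stopifnot(inherits(traj, "cargo_trajectory"))
  tt <- seq(min(traj$t), max(traj$t), by = dt)
  out <- data.frame(t = tt)
  for (nm in setdiff(names(traj), "t")) {
    # counts and velocities are piecewise constant between events;
    # positions vary linearly
    meth <- if (grepl("^n_", nm) || nm %in% c("v", "vx", "vy")) "constant" else "linear"
    out[[nm]] <- stats::approx(traj$t, traj[[nm]], xout = tt,
                               method = meth, rule = 2)$y
  }
  pv <- attr(traj, "provenance"); pv$dt <- dt
  cargo_trajectory(out, attr(traj, "dimension"), pv)
}

#' Estimate velocity from positions by central differences
#'
#' For experimental-style input (tracked positions only), computes the
#' velocity column(s) by central finite differences on a uniform grid,
#' optionally after a running-mean smoothing of the positions.
#'
#' @param traj A [cargo_trajectory()] on a uniform grid.
#' @param smooth Odd window length for a running mean (default 1 = none).
#' @return The trajectory with velocity column(s) replaced.
#' @export
derive_velocity <- function(traj, smooth = 1L) {
  stopifnot(inherits(traj, "cargo_trajectory"))
  dt <- diff(traj$t)
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    stop("derive_velocity requires a uniform time grid; resample first")
  cd <- function(p) {
    if (smooth > 1L) p <- stats::filter(p, rep(1 / smooth, smooth), sides = 2)
    n <- length(p)
    v <- c(p[2] - p[1], (p[3:n] - p[1:(n - 2)]) / 2, p[n] - p[n - 1]) / dt[1]
    v[is.na(v)] <- 0
    v
  }
  if (attr(traj, "dimension") == 1L) traj$v <- cd(traj$x)
  else { traj$vx <- cd(traj$x); traj$vy <- cd(traj$y) }
  traj
}

## ---- delimited text I/O ----------------------------------------------------

#' Write / read a trajectory as delimited text
#'
#' Comma-separated values preceded by a commented header block
#' (`# key: value` lines recording dimension, scheme, seed and parameters).
#' The round trip is lossless at 1e-9 relative precision.
#'
#' @param traj A [cargo_trajectory()].
#' @param path Output file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the trajectory.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cargo_trajectory"))
  pv <- attr(traj, "provenance")
  hdr <- c(sprintf("# antcargo trajectory"),
           sprintf("# dimension: %d", attr(traj, "dimension")))
  for (nm in c("scheme", "seed", "dt", "kind")) {
    if (!is.null(pv[[nm]]))
      hdr <- c(hdr, sprintf("# %s: %s", nm, format(pv[[nm]])))
  }
  if (!is.null(pv$params) && is.list(pv$params)) {
    pp <- unlist(pv$params[vapply(pv$params, is.numeric, TRUE)])
    hdr <- c(hdr, sprintf("# params: %s",
                          paste(sprintf("%s=%.10g", names(pp), pp), collapse = ";")))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(traj)
  writeLines(paste(names(df), collapse = ","), con)
  body <- do.call(paste, c(lapply(df, function(col) sprintf("%.12g", col)),
                           sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' @param expect_dimension Optional dimensionality check (1 or 2); reading a
#'   file of the other dimensionality is an error.
#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, expect_dimension = NULL) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- grepl("^#", lines)
  hdr <- lines[is_hdr]
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  dimension <- if (!is.null(meta$dimension)) as.integer(meta$dimension) else NA_integer_
  body <- lines[!is_hdr]
  if (length(body) < 2) stop("malformed trajectory file: no data in ", path)
  cols <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (is.na(dimension)) dimension <- if ("y" %in% cols) 2L else 1L
  need <- if (dimension == 1L) c("t", "x", "v") else c("t", "x", "y", "vx", "vy")
  if (!all(need %in% cols))
    stop("malformed trajectory header: declared dimension ", dimension,
         " but columns are: ", paste(cols, collapse = ", "))
  if (!is.null(expect_dimension) && dimension != expect_dimension)
    stop("dimensionality mismatch: file is ", dimension, "D, expected ",
         expect_dimension, "D")
  df <- utils::read.csv(textConnection(body), header = TRUE)
  bad <- which(diff(df$t) <= 0)
  if (length(bad))
    stop("non-monotone time at data line ", bad[1] + 1L, " of ", path)
  pv <- list()
  for (nm in c("scheme", "seed", "dt"))
    if (!is.null(meta[[nm]])) {
      num <- suppressWarnings(as.numeric(meta[[nm]]))
      pv[[nm]] <- if (is.na(num)) meta[[nm]] else num
    }
  cargo_trajectory(df, dimension, pv)
}

## ---- fixture generator -----------------------------------------------------

#' Synthetic test trajectory with planted convergent episodes
#'
#' Builds a piecewise 1D trajectory that alternates oscillatory excursions
#' (a cosine of amplitude and period chosen to exceed the detection
#' thresholds) with planted convergent episodes (small-amplitude noise
#' around the origin). Emulates the shape of tracked cargo center-of-mass
#' tables and of Gillespie output, so every analysis operation is testable
#' without external data.
#'
#' @param T Total duration (s).
#' @param dt Grid spacing (s).
#' @param episodes Data frame with columns `t_start`, `t_end` of the
#'   planted convergent episodes (non-overlapping, within `[0, T]`).
#' @param noise_sd Noise amplitude inside convergent episodes (cm).
#' @param osc_amplitude,osc_period Oscillation amplitude (cm) and period (s).
#' @param seed RNG seed.
#' @return A 1D [cargo_trajectory()].
#' @export
#' @examples
#' tr <- make_fixture_trajectory(episodes = data.frame(t_start = 100, t_end = 120))
make_fixture_trajectory <- function(T = 600, dt = 0.1,
                                    episodes = data.frame(t_start = numeric(),
                                                          t_end = numeric()),
                                    noise_sd = 0.01, osc_amplitude = 2,
                                    osc_period = 20, seed = 1) {
  stopifnot(is.data.frame(episodes),
            all(c("t_start", "t_end") %in% names(episodes)))
  if (nrow(episodes)) {
    ep <- episodes[order(episodes$t_start), , drop = FALSE]
    if (any(ep$t_end <= ep$t_start)) stop("episodes must have t_end > t_start")
    if (nrow(ep) > 1 && any(ep$t_start[-1] < ep$t_end[-nrow(ep)]))
      stop("overlapping episodes in fixture specification")
    if (min(ep$t_start) < 0 || max(ep$t_end) > T)
      stop("episodes must lie within [0, T]")
    episodes <- ep
  }
  set.seed(seed)
  tt <- seq(0, T, by = dt)
  x <- osc_amplitude * cos(2 * pi * tt / osc_period)
  v <- -osc_amplitude * (2 * pi / osc_period) * sin(2 * pi * tt / osc_period)
  for (i in seq_len(nrow(episodes))) {
    sel <- tt >= episodes$t_start[i] & tt <= episodes$t_end[i]
    ns <- sum(sel)
    x[sel] <- stats::rnorm(ns, 0, noise_sd)
    v[sel] <- stats::rnorm(ns, 0, noise_sd)
  }
  cargo_trajectory(data.frame(t = tt, x = x, v = v), 1L,
                   provenance = list(kind = "fixture", seed = seed, dt = dt,
                                     episodes = episodes))
}
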