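#' Detection thresholds for the convergent mode
#'
#' The convergent mode is detected by simultaneous position, velocity and
#' duration thresholds. The 1D preset uses `|x| < 0.1` cm, `|v| < 0.1`
#' cm/s (the magnitude of the restoring force `g` at the reference
#' parameters) and a minimum duration of 5 s. The 2D preset scales with
#' the cargo: `|x| < r`, `y < 2r`, `|v_x| < 0.1` cm/s (below the
#' single-ant speed of 0.14 cm/s) and a minimum duration of 4 s.
#'
#' @param preset `"1d"` or `"2d"`.
#' @param r Cargo radius (cm), required for the 2D preset.
#' @return A list of class `threshold_set` with `x_bound`, `y_bound`
#'   (`NA` in 1D), `v_bound`, `min_duration`.
#' @export
#' @examples
#' threshold_preset("1d")
#' threshold_preset("2d", r = 0.5)
threshold_preset <- function(preset = c("1d", "2d"), r = NULL) {
  preset <- match.arg(preset)
  th <- if (preset == "1d") {
    list(x_bound = 0.1, y_bound = NA_real_, v_bound = 0.1, min_duration = 5)
  } else {
    if (is.null(r) || r <= 0) stop("the 2D preset requires the cargo radius r")
    list(x_bound = r, y_bound = 2 * r, v_bound = 0.1, min_duration = 4)
  }
  structure(c(th, preset = preset), class = "threshold_set")
}

#' Construct a custom threshold set
#'
#' @param x_bound,v_bound,min_duration Positive thresholds.
#' @param y_bound Positive height threshold (2D) or `NA` (1D).
#' @return A `threshold_set`.
#' @export
threshold_set <- function(x_bound, v_bound, min_duration, y_bound = NA_real_) {
  if (x_bound <= 0 || v_bound <= 0 || min_duration <= 0 ||
      (!is.na(y_bound) && y_bound <= 0))
    stop("all thresholds must be positive")
  structure(list(x_bound = x_bound, y_bound = y_bound, v_bound = v_bound,
                 min_duration = min_duration, preset = "custom"),
            class = "threshold_set")
}

#' Segment a trajectory into convergent and oscillatory modes
#'
#' Labels as `convergent` every maximal interval on which the position
#' (and in 2D the height), and the velocity stay inside the thresholds
#' for longer than the minimum duration; everything else (including
#' sub-threshold intervals that are too short) is `oscillatory`. The
#' segments are non-overlapping, ordered, and jointly cover the analyzed
#' window.
#'
#' In the convergent mode the instantaneous Gillespie velocity chatters
#' (the restoring force flips sign at every origin crossing), so for
#' event-level simulation output the velocity should be assessed on the
#' time scale of a tracking analysis. `smooth` applies a centered running
#' mean of the stated width (seconds) to the velocity before thresholding
#' — with width `2h` this equals the central-difference estimator
#' `(x(t+h) - x(t-h)) / 2h` used on tracked positions. The default `0`
#' thresholds the raw velocity.
#'
#' @param traj A [cargo_trajectory()] on a uniform grid (resample first).
#' @param th A [threshold_preset()] / [threshold_set()].
#' @param smooth Width (s) of the centered running-mean velocity estimator;
#'   `0` uses the stored velocity samples as is.
#' @return A data frame of class `mode_segments` with columns `label`,
#'   `t_start`, `t_end`.
#' @export
segment_modes <- function(traj, th, smooth = 0) {
  stopifnot(inherits(traj, "cargo_trajectory"), inherits(th, "threshold_set"))
  n <- nrow(traj)
  if (n == 0)
    return(structure(data.frame(label = character(), t_start = numeric(),
                                t_end = numeric()),
                     class = c("mode_segments", "data.frame")))
  dt <- diff(traj$t)
  if (n > 2 && (max(dt) - min(dt)) > 1e-6 * max(dt))
    stop("segment_modes requires a uniform time grid; use resample_trajectory()")
  dim2 <- attr(traj, "dimension") == 2L
  v <- if (dim2) traj$vx else traj$v
  if (smooth > 0) {
    w <- max(1L, round(smooth / dt[1]))
    if (w %% 2 == 0) w <- w + 1L
    vs <- stats::filter(v, rep(1 / w, w), sides = 2)
    v <- ifelse(is.na(vs), v, as.numeric(vs))
  }
  below <- abs(traj$x) < th$x_bound & abs(v) < th$v_bound
  if (dim2) {
    if (is.na(th$y_bound)) stop("2D segmentation requires y_bound")
    below <- below & traj$y < th$y_bound
  }
  rl <- rle(below)
  ends <- cumsum(rl$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  t0 <- traj$t[starts]
  t1 <- traj$t[ends]
  dur <- t1 - t0
  conv <- rl$values & dur > th$min_duration
  lab <- ifelse(conv, "convergent", "oscillatory")
  # merge adjacent oscillatory runs (short sub-threshold runs fold in)
  seg <- data.frame(label = lab, t_start = t0, t_end = t1)
  if (nrow(seg) > 1) {
    keep <- c(TRUE, seg$label[-1] != seg$label[-nrow(seg)])
    grp <- factor(cumsum(keep), levels = unique(cumsum(keep)))
    seg <- data.frame(label = seg$label[keep],
                      t_start = as.numeric(tapply(seg$t_start, grp, min)),
                      t_end = as.numeric(tapply(seg$t_end, grp, max)))
  }
  # make segments contiguous: each segment ends where the next begins
  if (nrow(seg) > 1) seg$t_end[-nrow(seg)] <- seg$t_start[-1]
  rownames(seg) <- NULL
  structure(seg, class = c("mode_segments", "data.frame"),
            window = range(traj$t), thresholds = th)
}

#' @export
print.mode_segments <- function(x, ...) {
  cat(sprintf("Mode segmentation: %d segments (%d convergent, %d oscillatory)\n",
              nrow(x), sum(x$label == "convergent"),
              sum(x$label == "oscillatory")))
  print(as.data.frame(utils::head(x, 6)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Turning-point and turning-time statistics
#'
#' Turning events are sign changes of the velocity outside the convergent
#' segments. Turning points are the positions at those events; turning
#' times are the durations between consecutive events.
#'
#' @param traj A [cargo_trajectory()] on a uniform grid.
#' @param segments Optional [segment_modes()] result; turning events inside
#'   convergent segments are discarded. `NULL` uses the whole trajectory.
#' @return A list with `turning_points` (cm) and `turning_times` (s).
#' @export
turning_statistics <- function(traj, segments = NULL) {
  stopifnot(inherits(traj, "cargo_trajectory"))
  v <- if (attr(traj, "dimension") == 2L) traj$vx else traj$v
  x <- traj$x
  tt <- traj$t
  sgn <- sign(v)
  nz <- sgn != 0
  # sign change between consecutive non-zero samples
  idx <- which(nz)
  if (length(idx) < 2)
    return(list(turning_points = numeric(), turning_times = numeric()))
  ch <- idx[c(FALSE, diff(sgn[idx]) != 0)]
  if (!is.null(segments)) {
    conv <- segments[segments$label == "convergent", , drop = FALSE]
    if (nrow(conv)) {
      inside <- vapply(tt[ch], function(t0)
        any(t0 >= conv$t_start & t0 <= conv$t_end), TRUE)
      ch <- ch[!inside]
    }
  }
  list(turning_points = x[ch], turning_times = diff(tt[ch]))
}

#' Dwell-duration statistics per mode
#'
#' @param segments A [segment_modes()] result.
#' @return A list with per-mode duration vectors (`convergent`,
#'   `oscillatory`) and a `summary` data frame (n, mean, variance, total).
#' @export
dwell_statistics <- function(segments) {
  stopifnot(inherits(segments, "mode_segments"))
  if (!nrow(segments)) stop("empty segmentation")
  dur <- segments$t_end - segments$t_start
  out <- list(convergent = dur[segments$label == "convergent"],
              oscillatory = dur[segments$label == "oscillatory"])
  out$summary <- do.call(rbind, lapply(names(out), function(nm) {
    d <- out[[nm]]
    data.frame(mode = nm, n = length(d),
               mean = if (length(d)) mean(d) else NA_real_,
               var = if (length(d) > 1) stats::var(d) else NA_real_,
               total = sum(d))
  }))
  out
}

#' Maximum-likelihood exponential fit to a distribution tail
#'
#' Fits an exponential rate to the exceedances of `samples` over
#' `tail_start` (by memorylessness the shift leaves the rate of a true
#' exponential unchanged). The confidence interval is the exact
#' chi-squared interval for the rate of an exponential sample; the
#' goodness diagnostic is a Kolmogorov-Smirnov statistic against the
#' fitted exponential (with the usual caveat that the rate was estimated
#' from the same data).
#'
#' @param samples Numeric sample (e.g. dwell durations or turning times).
#' @param tail_start Tail threshold; only `samples > tail_start` are used.
#' @param conf Confidence level.
#' @param min_tail Minimum number of tail samples required.
#' @return A list with `rate`, `mean` (of exceedances), `ci` (rate CI),
#'   `n_tail`, `ks_stat`, `ks_p`.
#' @export
exponential_tail_fit <- function(samples, tail_start = 0, conf = 0.95,
                                 min_tail = 20L) {
  y <- samples[samples > tail_start] - tail_start
  n <- length(y)
  if (n < min_tail)
    stop("too few tail samples (", n, " <= ", min_tail, ") above tail_start")
  if (stats::var(y) == 0) stop("degenerate (constant-valued) tail sample")
  m <- mean(y)
  rate <- 1 / m
  a <- (1 - conf) / 2
  ci <- c(stats::qchisq(a, 2 * n), stats::qchisq(1 - a, 2 * n)) / (2 * n * m)
  ks <- suppressWarnings(stats::ks.test(y, "pexp", rate))
  list(rate = rate, mean = m, ci = ci, n_tail = n,
       ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}
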