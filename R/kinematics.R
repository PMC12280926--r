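#' Construct a landmark series
#'
#' Per-frame 3D coordinates of the 15 named body and fin landmarks
#' digitized on a hovering fish (tip of snout, eye, bottom of eye, dorsal
#' fin tip, left/right pectoral base and tip, left/right pelvic base and
#' tip, anal fin tip, caudal peduncle, caudal fin tip). Coordinates follow
#' the package convention: x anterior–posterior, y lateral, z vertical.
#'
#' @param points 3D array \code{[frame, landmark, xyz]} with named
#'   landmark dimension; at least 2 frames, no duplicated landmark name.
#' @param fps Frame rate (frames s^-1), positive.
#' @param bl Body length in the same units as the coordinates, positive.
#' @param truth Optional list of generating parameters (synthetic data).
#' @return Object of class \code{landmark_series}.
#' @export
landmark_series <- function(points, fps, bl, truth = NULL) {
  stopifnot(length(dim(points)) == 3, dim(points)[3] == 3,
            dim(points)[1] >= 2, fps > 0, bl > 0)
  nm <- dimnames(points)[[2]]
  if (is.null(nm) || anyDuplicated(nm))
    stop("landmark names must be present and unique")
  structure(list(points = points, fps = fps, bl = bl, truth = truth),
            class = "landmark_series")
}

#' @export
print.landmark_series <- function(x, ...) {
  cat(sprintf("Landmark series: %d frames x %d landmarks at %g fps (BL %g)\n",
              dim(x$points)[1], dim(x$points)[2], x$fps, x$bl))
  invisible(x)
}

#' Read a landmark series from TSV
#'
#' Long format written by \code{\link{write_landmarks}}: columns
#' \code{frame}, \code{landmark}, \code{x}, \code{y}, \code{z}, with
#' \code{fps} and \code{bl} in \code{# key=value} header comments.
#'
#' @param path TSV file path.
#' @return A \code{\link{landmark_series}}.
#' @export
read_landmarks <- function(path) {
  meta <- read_header_meta(path)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  stopifnot(all(c("frame", "landmark", "x", "y", "z") %in% names(df)))
  frames <- sort(unique(df$frame))
  nms <- unique(df$landmark)
  pts <- array(NA_real_, c(length(frames), length(nms), 3),
               dimnames = list(NULL, nms, c("x", "y", "z")))
  fi <- match(df$frame, frames); li <- match(df$landmark, nms)
  pts[cbind(fi, li, 1)] <- df$x
  pts[cbind(fi, li, 2)] <- df$y
  pts[cbind(fi, li, 3)] <- df$z
  landmark_series(pts, fps = meta$fps, bl = meta$bl)
}

get_lm <- function(series, name) {
  if (!name %in% dimnames(series$points)[[2]])
    stop("required landmark missing: ", name)
  series$points[, name, , drop = TRUE]
}

# Time-mean horizontal heading (yaw) of the snout->peduncle axis, radians.
series_heading <- function(series) {
  ax <- get_lm(series, "caudal_peduncle") - get_lm(series, "snout")
  m <- colMeans(ax)
  atan2(m[2], m[1])
}

#' Roll and pitch angle time series
#'
#' Roll is the angle of the eye-to-bottom-of-eye segment projected on the
#' transverse (y–z) plane, measured from vertical; pitch is the elevation
#' angle of the snout-to-peduncle axis. Before measuring, the series is
#' rotated about the vertical axis to remove the time-mean heading, so
#' both angles are invariant to the yaw orientation of the whole recording.
#' With \code{reference = "mean"} (default) excursions are measured about
#' each angle's time mean — the hovering fish's own equilibrium posture;
#' \code{"absolute"} uses the lab vertical/horizontal instead.
#'
#' @param series A \code{\link{landmark_series}} containing the
#'   \code{eye}, \code{eye_bottom}, \code{snout} and
#'   \code{caudal_peduncle} landmarks.
#' @param reference \code{"mean"} or \code{"absolute"}.
#' @return List with vectors \code{roll}, \code{pitch} (degrees, absolute
#'   frame) and summaries \code{roll_max_excursion}, \code{roll_mean},
#'   \code{pitch_max_excursion}, \code{pitch_mean}.
#' @export
roll_pitch <- function(series, reference = c("mean", "absolute")) {
  reference <- match.arg(reference)
  yaw <- series_heading(series)
  rz <- rbind(c(cos(-yaw), -sin(-yaw), 0),
              c(sin(-yaw), cos(-yaw), 0),
              c(0, 0, 1))
  derot <- function(p) p %*% t(rz)
  v <- derot(get_lm(series, "eye") - get_lm(series, "eye_bottom"))
  if (any(rowSums(v^2) == 0)) stop("degenerate (zero-length) eye segment")
  roll <- atan2(-v[, 2], v[, 3]) * 180 / pi
  u <- derot(get_lm(series, "snout") - get_lm(series, "caudal_peduncle"))
  if (any(rowSums(u^2) == 0)) stop("degenerate (zero-length) body axis")
  pitch <- asin(u[, 3] / sqrt(rowSums(u^2))) * 180 / pi
  rr <- if (reference == "mean") mean(roll) else 0
  pr <- if (reference == "mean") mean(pitch) else 0
  list(roll = roll, pitch = pitch,
       roll_max_excursion = max(abs(roll - rr)),
       roll_mean = mean(roll),
       pitch_max_excursion = max(abs(pitch - pr)),
       pitch_mean = mean(pitch))
}

#' Body angle relative to the horizontal plane
#'
#' Signed elevation (head-up positive) of the eye relative to the caudal
#' peduncle: \code{asin(rise / 3D distance)} per frame, in degrees.
#'
#' @param series A \code{\link{landmark_series}}, or \code{NULL} when
#'   \code{eye} and \code{peduncle} points are given directly.
#' @param eye,peduncle Optional single 3D points (used when
#'   \code{series} is \code{NULL}).
#' @return Numeric vector of angles (degrees), one per frame (scalar for
#'   point input).
#' @examples
#' body_angle(eye = c(0, 0, 2), peduncle = c(10, 0, 1))  # 5.71 deg
#' @export
body_angle <- function(series = NULL, eye = NULL, peduncle = NULL) {
  if (is.null(series)) {
    v <- rbind(eye - peduncle)
  } else {
    v <- get_lm(series, "eye") - get_lm(series, "caudal_peduncle")
  }
  d <- sqrt(rowSums(v^2))
  if (any(d == 0)) stop("eye and peduncle coincide")
  asin(v[, 3] / d) * 180 / pi
}

#' Discrete body curvature through three landmarks (Menger curvature)
#'
#' The curvature of the circle through three points: 4 times the triangle
#' area divided by the product of the three side lengths. This is the
#' parameter-free three-point discretization of kappa = |dT/ds| along the
#' snout–peduncle–caudal-tip transect; it is exact on circular arcs and
#' zero for collinear points.
#'
#' @param p1,p2,p3 Distinct 2D or 3D points.
#' @return Curvature (1/length units).
#' @examples
#' curvature_menger(c(10, 0), c(0, 10), c(-10, 0))  # 0.1
#' @export
curvature_menger <- function(p1, p2, p3) {
  pts <- lapply(list(p1, p2, p3), function(p) {
    p <- as.numeric(p)
    if (length(p) == 2) p <- c(p, 0)
    stopifnot(length(p) == 3)
    p
  })
  if (isTRUE(all.equal(pts[[1]], pts[[2]])) ||
      isTRUE(all.equal(pts[[2]], pts[[3]])) ||
      isTRUE(all.equal(pts[[1]], pts[[3]])))
    stop("duplicated points")
  a <- pts[[2]] - pts[[1]]; b <- pts[[3]] - pts[[1]]
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  area <- 0.5 * sqrt(sum(cr^2))
  s1 <- sqrt(sum(a^2)); s2 <- sqrt(sum(b^2))
  s3 <- sqrt(sum((pts[[3]] - pts[[2]])^2))
  4 * area / (s1 * s2 * s3)
}

# Dominant oscillation period (in samples, possibly fractional) from the
# first local maximum of the unbiased autocorrelation beyond lag 0, refined
# by parabolic interpolation; ties break toward the shorter period. The
# unbiased estimator (dividing by n - k rather than n) avoids the taper of
# the biased acf, which otherwise drags the peak toward longer lags.
dominant_period <- function(x) {
  n <- length(x)
  if (sd(x) == 0) stop("non-oscillatory (flat) signal: period undefined")
  xc <- x - mean(x)
  kmax <- min(n - 2L, 10000L)
  a <- vapply(0:kmax, function(k)
    sum(xc[seq_len(n - k)] * xc[seq_len(n - k) + k]) / (n - k), numeric(1))
  # search only beyond the first zero crossing of the acf, where the
  # oscillation's own period produces the first genuine positive peak
  zc <- which(a <= 0)[1]
  if (is.na(zc)) stop("non-oscillatory signal: autocorrelation never dips")
  lag <- NA_integer_
  for (k in seq(max(zc, 2), length(a) - 1)) {
    if (a[k] > a[k - 1] && a[k] >= a[k + 1] && a[k] > 0) {
      lag <- k - 1L  # index 1 is lag 0
      break
    }
  }
  if (is.na(lag)) stop("non-oscillatory signal: no autocorrelation peak")
  # refine to subsample precision: the acf peak identifies the period but
  # carries an O(1/(n - k)) edge bias of a few samples, so re-estimate it
  # as the median spacing of linearly interpolated upward zero crossings,
  # accepted only when consistent with the acf peak
  up <- which(xc[-n] < 0 & xc[-1] >= 0)
  if (length(up) >= 3) {
    tc <- up + xc[up] / (xc[up] - xc[up + 1])
    sp <- diff(tc)
    sp <- sp[sp > 0.5 * lag & sp < 1.5 * lag]
    if (length(sp) >= 2) {
      ref <- stats::median(sp)
      if (abs(ref - lag) < 0.2 * lag) return(ref)
    }
  }
  lag
}

#' Phase lag between left and right fin oscillations
#'
#' Cross-correlates the two mean-centered abduction signals, takes the
#' time shift maximizing the correlation, converts it to phase via the
#' dominant period (autocorrelation peak of the left signal, ties toward
#' the shorter period) and folds the result into [0, 180] degrees: 0 is
#' in-phase (both fins maximally abducted simultaneously), 180 antiphase
#' (one fin maximally abducted while the other is maximally adducted).
#'
#' @param left,right Equal-length numeric abduction signals covering at
#'   least two oscillation cycles.
#' @param fps Sampling rate (frames s^-1).
#' @return List with \code{phase_deg} in [0, 180], \code{lag_s} (signed
#'   best-correlation shift, s), \code{period_s} and \code{max_corr}.
#' @examples
#' t <- seq(0, 3, by = 1e-3)
#' phase_lag(sin(4 * pi * t), -sin(4 * pi * t), 1000)$phase_deg  # 180
#' @export
phase_lag <- function(left, right, fps) {
  stopifnot(length(left) == length(right), fps > 0)
  period <- dominant_period(left)
  l <- left - mean(left); r <- right - mean(right)
  if (sd(r) == 0) stop("non-oscillatory (flat) signal")
  n <- length(l)
  # windowed, unbiased normalized cross-correlation; lags limited to 3/4
  # of a period so the periodic replicas of the true peak stay outside
  max_lag <- min(n - 3L, as.integer(ceiling(0.75 * period)))
  xcorr <- function(k) {
    if (k >= 0) {
      a <- l[(1 + k):n]; b <- r[1:(n - k)]
    } else {
      a <- l[1:(n + k)]; b <- r[(1 - k):n]
    }
    stats::cor(a, b)  # per-window Pearson, bounded by 1
  }
  ks <- seq(-max_lag, max_lag)
  cc <- vapply(ks, xcorr, numeric(1))
  mx <- max(cc)
  cand <- which(cc >= mx - 1e-9)
  i <- cand[which.min(abs(ks[cand]))]  # smallest |shift| among tied maxima
  lag <- ks[i]
  # parabolic subsample refinement of the correlation peak
  if (i > 1 && i < length(ks)) {
    y1 <- cc[i - 1]; y2 <- cc[i]; y3 <- cc[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) {
      d <- 0.5 * (y1 - y3) / den
      if (abs(d) <= 0.5) lag <- lag + d
    }
  }
  phase <- (360 * abs(lag) / period) %% 360
  if (phase > 180) phase <- 360 - phase
  list(phase_deg = phase, lag_s = lag / fps, period_s = period / fps,
       max_corr = mx)
}

#' Cumulative fin-tip distance per second, in body lengths
#'
#' Sums the inter-frame 3D Euclidean displacements of a fin-tip track and
#' standardizes to a one-second interval and to body length.
#'
#' @param track n x 3 (or n x 2) matrix of fin-tip positions, n >= 2.
#' @param fps Sampling rate (frames s^-1).
#' @param bl Body length in the same units as the track.
#' @return Distance traveled in BL s^-1.
#' @export
fin_distance <- function(track, fps, bl) {
  track <- as.matrix(track)
  stopifnot(nrow(track) >= 2, fps > 0, bl > 0)
  d <- sum(sqrt(rowSums(diff(track)^2)))
  elapsed <- (nrow(track) - 1) / fps
  d / elapsed / bl
}

#' Extract complete oscillation cycles from a signal
#'
#' Cycles are delimited by successive upward zero crossings of the
#' mean-centered signal, detected with hysteresis: a crossing only counts
#' once the signal has dipped below a quarter of its oscillation amplitude
#' since the previous crossing, so measurement noise near the zeros cannot
#' create or destroy cycles. A rising start at the first sample counts as
#' a cycle boundary, and a final cycle is closed at the series end when a
#' full period has elapsed since the last crossing, so exactly 3 periods
#' of a sinusoid yield 3 cycles and 3.5 periods yield 3 complete cycles.
#'
#' @param signal Numeric oscillatory signal.
#' @return List of \code{c(start, end)} index pairs, one per complete
#'   cycle; error if the signal contains less than one full cycle.
#' @export
extract_cycles <- function(signal) {
  period <- dominant_period(signal)
  s <- signal - mean(signal)
  n <- length(s)
  h <- 0.25 * sqrt(2) * sd(s)  # quarter amplitude for a near-sinusoid
  up <- integer(0)
  armed <- s[1] < 0  # must visit the lower half-swing before a crossing
  for (i in seq_len(n)) {
    if (!armed && s[i] < -h) armed <- TRUE
    else if (armed && s[i] >= 0) {
      up <- c(up, i)
      armed <- FALSE
    }
  }
  if (n >= 2 && s[1] >= 0 && s[2] > s[1]) up <- c(1L, up)
  # close a final cycle at the series end when a full period has elapsed
  # since the last crossing but the closing crossing falls just outside
  # (or exactly on) the last sample
  if (length(up) >= 1 && n - up[length(up)] >= 0.95 * period)
    up <- c(up, n)
  if (length(up) < 2) stop("less than one complete cycle in signal")
  lapply(seq_len(length(up) - 1),
         function(i) c(start = up[i], end = up[i + 1]))
}

#' Outward abduction signals of the pectoral fin tips
#'
#' Signed lateral (y) displacement of each pectoral fin tip relative to its
#' base, with outward positive on both sides (left side outward is -y).
#'
#' @param series A \code{\link{landmark_series}}.
#' @return List with vectors \code{left} and \code{right}.
#' @export
abduction_signals <- function(series) {
  list(
    left = -(get_lm(series, "pect_tip_l")[, 2] -
               get_lm(series, "pect_base_l")[, 2]),
    right = get_lm(series, "pect_tip_r")[, 2] -
      get_lm(series, "pect_base_r")[, 2])
}

#' Summarize the kinematics of a landmark series
#'
#' Computes the full posture and fin-motion metric set for one recording:
#' roll/pitch excursions and means, mean body angle, mean body curvature
#' along the snout–peduncle–caudal-tip transect, pectoral phase lag, and
#' per-fin distances traveled (BL s^-1).
#'
#' @param series A \code{\link{landmark_series}}.
#' @param reference Passed to \code{\link{roll_pitch}}.
#' @return One-row data frame of class \code{kinematics_summary}.
#' @export
kinematics_summary <- function(series, reference = "mean") {
  rp <- roll_pitch(series, reference = reference)
  ba <- mean(body_angle(series))
  nt <- dim(series$points)[1]
  kap <- mean(vapply(seq_len(nt), function(i)
    curvature_menger(series$points[i, "snout", ],
                     series$points[i, "caudal_peduncle", ],
                     series$points[i, "caudal_fin_tip", ]), numeric(1)))
  ab <- abduction_signals(series)
  pl <- phase_lag(ab$left, ab$right, series$fps)
  fins <- c(pect_l = "pect_tip_l", pect_r = "pect_tip_r",
            pelv_l = "pelv_tip_l", pelv_r = "pelv_tip_r",
            dorsal = "dorsal_fin_tip", anal = "anal_fin_tip",
            caudal = "caudal_fin_tip")
  fd <- vapply(fins, function(nm)
    fin_distance(get_lm(series, nm), series$fps, series$bl), numeric(1))
  out <- data.frame(
    roll_max_excursion = rp$roll_max_excursion, roll_mean = rp$roll_mean,
    pitch_max_excursion = rp$pitch_max_excursion,
    pitch_mean = rp$pitch_mean, body_angle_mean = ba, curvature = kap,
    phase_lag_deg = pl$phase_deg)
  for (nm in names(fd)) out[[paste0("fin_dist_", nm)]] <- fd[[nm]]
  class(out) <- c("kinematics_summary", class(out))
  out
}
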