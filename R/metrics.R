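# Observables: centroid velocity, chemotaxis index, coverage ratio,
# velocity/FilGAP cross-correlation lag.

boxcar <- function(x, n) {
  n <- min(n, length(x))
  if (n %% 2 == 0) n <- n - 1   # odd length: exactly centred window
  if (n <= 1) return(x)
  k <- rep(1 / n, n)
  as.numeric(stats::filter(x, k, sides = 2, circular = FALSE)) ->
    sm
  # shrink the window symmetrically at the edges (unbiased for linear
  # trends) instead of dropping samples
  bad <- is.na(sm)
  if (any(bad)) {
    cs <- cumsum(c(0, x))
    m <- length(x)
    half <- (n - 1) %/% 2
    for (i in which(bad)) {
      h <- min(half, i - 1, m - i)
      sm[i] <- (cs[i + h + 1] - cs[i - h]) / (2 * h + 1)
    }
  }
  sm
}

#' Centroid speed series
#'
#' Speed of the boxcar-smoothed centroid trajectory (positions smoothed over
#' `window`, then central-differenced), reported in um/min.  Smoothing the
#' positions before differencing means stationary jitter reads as ~0 rather
#' than as a spurious sustained speed.
#'
#' @param times sample times (s), uniformly spaced and increasing.
#' @param centroid n x 2 centroid positions (um).
#' @param window smoothing window (s); 0 disables smoothing.
#' @return data frame with columns `t` (s) and `value` (um/min).
#' @export
centroid_velocity <- function(times, centroid, window = 60) {
  n <- length(times)
  stopifnot(n >= 2, all(diff(times) > 0))
  dt <- times[2] - times[1]
  nw <- max(1L, round(window / dt))
  cx <- boxcar(centroid[, 1], nw)
  cy <- boxcar(centroid[, 2], nw)
  vx <- c(cx[2] - cx[1], (cx[3:n] - cx[1:(n - 2)]) / 2, cx[n] - cx[n - 1]) / dt
  vy <- c(cy[2] - cy[1], (cy[3:n] - cy[1:(n - 2)]) / 2, cy[n] - cy[n - 1]) / dt
  data.frame(t = times, value = sqrt(vx^2 + vy^2) * 60)
}

#' Chemotaxis index series
#'
#' Windowed mean cosine between the direction of centroid motion and the
#' unit vector pointing from the centroid to the source.  The trajectory is
#' resampled at `sample_dt` so the direction estimate is not dominated by
#' step-level jitter; samples slower than `speed_floor` are excluded (NA
#' gap).  CI is +1 for motion straight at the source and -1 for motion
#' straight away.
#'
#' @param times sample times (s).
#' @param centroid n x 2 centroid positions (um).
#' @param source_position attractant source (um, length-2).
#' @param window averaging window (s).
#' @param sample_dt direction-sampling interval (s).
#' @param speed_floor minimum speed (um/min) for a defined direction.
#' @return data frame with columns `t` and `value` (CI in [-1, 1]).
#' @export
chemotaxis_index <- function(times, centroid, source_position, window = 60,
                             sample_dt = 10, speed_floor = 0.2) {
  stopifnot(window > 0, length(times) >= 3)
  tt <- seq(times[1], times[length(times)], by = sample_dt)
  if (length(tt) < 3) stop("evaluation window too short")
  cx <- stats::approx(times, centroid[, 1], tt)$y
  cy <- stats::approx(times, centroid[, 2], tt)$y
  n <- length(tt)
  dx <- cx[-1] - cx[-n]
  dy <- cy[-1] - cy[-n]
  step <- sqrt(dx^2 + dy^2)
  mx <- (cx[-1] + cx[-n]) / 2
  my <- (cy[-1] + cy[-n]) / 2
  ux <- source_position[1] - mx
  uy <- source_position[2] - my
  un <- sqrt(ux^2 + uy^2)
  cosang <- (dx * ux + dy * uy) / (step * un)
  cosang[step / sample_dt * 60 < speed_floor] <- NA
  nwin <- max(1L, round(window / sample_dt))
  val <- vapply(seq_along(cosang), function(i) {
    lo <- max(1, i - nwin + 1)
    mean(cosang[lo:i], na.rm = TRUE)
  }, 0)
  val[is.nan(val)] <- NA
  data.frame(t = tt[-1], value = pmin(pmax(val, -1), 1))
}

#' Coverage ratio of a region by the cell footprint
#'
#' Fraction of a region (a disk minus obstacle disks) swept by the union of
#' the cell polygons up to each snapshot time, computed on a raster of pitch
#' `pitch`.  Monotone non-decreasing in time.
#'
#' @param snapshots list of membrane polygons (n x 2 matrices).
#' @param times snapshot times (s).
#' @param region list with `center`, `radius` and optionally `obstacles`
#'   (data frame `x`, `y`, `r`).
#' @param pitch raster pitch (um).
#' @return data frame with columns `t` and `value` (coverage ratio in
#'   [0, 1]).
#' @export
coverage_ratio <- function(snapshots, times, region, pitch = 0.25) {
  cx <- seq(region$center[1] - region$radius, region$center[1] + region$radius,
            by = pitch)
  cy <- seq(region$center[2] - region$radius, region$center[2] + region$radius,
            by = pitch)
  g <- expand.grid(x = cx, y = cy)
  inreg <- (g$x - region$center[1])^2 + (g$y - region$center[2])^2 <=
    region$radius^2
  if (!is.null(region$obstacles)) {
    ob <- region$obstacles
    for (i in seq_len(nrow(ob)))
      inreg <- inreg & ((g$x - ob$x[i])^2 + (g$y - ob$y[i])^2 > ob$r[i]^2)
  }
  if (!any(inreg)) stop("empty region")
  gx <- g$x[inreg]; gy <- g$y[inreg]
  covered <- rep(FALSE, length(gx))
  value <- numeric(length(snapshots))
  for (k in seq_along(snapshots)) {
    poly <- snapshots[[k]]
    todo <- which(!covered)
    if (length(todo)) {
      hit <- points_in_polygon_cpp(gx[todo], gy[todo], poly[, 1], poly[, 2])
      covered[todo[hit]] <- TRUE
    }
    value[k] <- mean(covered)
  }
  data.frame(t = times, value = value)
}

#' Lag between centroid speed and cytosolic FilGAP
#'
#' Lag (s) at which the cross-correlation between the speed series and the
#' delayed cytosolic FilGAP series is maximal, searched over `0..max_lag`.
#' A positive lag means FilGAP peaks after the speed does.
#'
#' @param speed speed series values (uniform sampling).
#' @param filgap cytosolic FilGAP series on the same time base.
#' @param dt sampling interval (s).
#' @param max_lag maximum lag searched (s).
#' @return lag in seconds.
#' @export
velocity_filgap_lag <- function(speed, filgap, dt, max_lag = 300) {
  n <- length(speed)
  stopifnot(length(filgap) == n, n > 10)
  kmax <- min(n - 5L, as.integer(round(max_lag / dt)))
  cc <- vapply(0:kmax, function(k)
    suppressWarnings(stats::cor(speed[1:(n - k)], filgap[(k + 1):n])), 0)
  cc[is.na(cc)] <- -Inf
  (which.max(cc) - 1L) * dt
}
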