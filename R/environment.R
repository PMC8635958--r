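# Extracellular environment: chemoattractant point sources with scheduled
# release, circular obstacles and optional circular confinement.

#' Chemoattractant point source
#'
#' Steady far-field of a point source: `C(r) = C0 * r0 / max(r, r0)`
#' (inverse-distance decay, the default) or
#' `C(r) = C0 * exp(-(r - r0)/lambda)` (exponential decay), zero before the
#' onset time.
#'
#' @param position source position (um, length-2).
#' @param onset release time (s).
#' @param strength core concentration `C0` (stimulus units).
#' @param core_radius core radius `r0` (um) inside which the field is capped.
#' @param decay `"inverse"` or `"exponential"`.
#' @param decay_length e-folding length for exponential decay (um).
#' @return a list of class `chemo_source`.
#' @export
chemo_source <- function(position, onset = 0, strength = 1, core_radius = 1,
                         decay = c("inverse", "exponential"),
                         decay_length = 50) {
  stopifnot(length(position) == 2, onset >= 0, strength >= 0, core_radius > 0)
  s <- list(position = as.numeric(position), onset = onset,
            strength = strength, core_radius = core_radius,
            decay = match.arg(decay), decay_length = decay_length)
  class(s) <- "chemo_source"
  s
}

#' Extracellular environment container
#'
#' @param sources list of [chemo_source()] objects.
#' @param obstacles data frame with columns `x`, `y`, `r` (um), or `NULL`.
#' @param confinement optional list `list(center, radius)` keeping all nodes
#'   inside a disk.
#' @return a list of class `chemo_environment`.
#' @export
chemo_environment <- function(sources = list(), obstacles = NULL,
                              confinement = NULL) {
  if (!is.null(obstacles)) {
    stopifnot(all(c("x", "y", "r") %in% names(obstacles)),
              all(obstacles$r > 0))
  }
  env <- list(sources = sources, obstacles = obstacles,
              confinement = confinement)
  class(env) <- "chemo_environment"
  env
}

#' Attractant concentration at points
#'
#' Sum over all sources active at time `t`.
#'
#' @param points n x 2 matrix of positions (um), or a length-2 vector.
#' @param t time (s), >= 0.
#' @param env a `chemo_environment`.
#' @return concentration per point.
#' @export
attractant_at <- function(points, t, env) {
  stopifnot(t >= 0)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  out <- numeric(nrow(points))
  for (s in env$sources) {
    if (t < s$onset) next
    r <- sqrt((points[, 1] - s$position[1])^2 + (points[, 2] - s$position[2])^2)
    out <- out + if (s$decay == "inverse")
      s$strength * s$core_radius / pmax(r, s$core_radius)
    else
      s$strength * exp(-pmax(r - s$core_radius, 0) / s$decay_length)
  }
  out
}

#' Gradient strength across a cell, in percent
#'
#' `p = 100 (C_front - C_back) / C_mid` where front/back are the points of
#' the cell circle nearest/farthest from the (single active) source and
#' `C_mid` is taken at the centroid.
#'
#' @param env a `chemo_environment` with one active source.
#' @param cell_centroid centroid (um).
#' @param cell_diameter cell diameter (um).
#' @param t evaluation time (s).
#' @return percent gradient across the cell.
#' @export
gradient_percentage <- function(env, cell_centroid, cell_diameter, t = Inf) {
  act <- Filter(function(s) t >= s$onset, env$sources)
  stopifnot(length(act) == 1)
  s <- act[[1]]
  dvec <- s$position - cell_centroid
  dist <- sqrt(sum(dvec^2))
  w <- cell_diameter / 2
  if (dist - w <= s$core_radius)
    stop("cell overlaps the source core; gradient percentage undefined")
  u <- dvec / dist
  front <- cell_centroid + u * w
  back <- cell_centroid - u * w
  cc <- attractant_at(rbind(front, back, cell_centroid), t = max(t, s$onset), env = env)
  unname(100 * (cc[1] - cc[2]) / cc[3])
}

#' Source distance achieving a target gradient percentage
#'
#' Inverse of [gradient_percentage()] for a single inverse-distance source:
#' the closed form `p = 200 d w / (d^2 - w^2)` (w the cell radius) is solved
#' analytically, with a bisection fallback cross-checking the closed form.
#' An exponential source has a distance-independent percentage
#' (`p = 200 sinh(w / lambda)` in its far field), so the gradient strength
#' is set by [decay_length_for_gradient()] instead.
#'
#' @param percent target gradient strength (percent), > 0.
#' @param cell_diameter cell diameter (um).
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @return distance (um) from centroid to source.
#' @export
source_distance_for_gradient <- function(percent, cell_diameter,
                                         method = c("closed_form",
                                                    "bisection")) {
  stopifnot(percent > 0)
  method <- match.arg(method)
  w <- cell_diameter / 2
  a <- percent / 100
  if (method == "closed_form")
    return((2 * w + sqrt(4 * w^2 + 4 * a^2 * w^2)) / (2 * a))
  f <- function(d) {
    env <- chemo_environment(list(chemo_source(c(d, 0), strength = 1)))
    gradient_percentage(env, c(0, 0), cell_diameter) - percent
  }
  stats::uniroot(f, c(cell_diameter, 1e6), tol = 1e-9)$root
}

#' Decay length giving a target gradient percentage for exponential sources
#'
#' @param percent target gradient strength (percent), > 0.
#' @param cell_diameter cell diameter (um).
#' @return e-folding length (um).
#' @export
decay_length_for_gradient <- function(percent, cell_diameter) {
  stopifnot(percent > 0)
  (cell_diameter / 2) / asinh(percent / 200)
}

#' Project nodes out of obstacles (and into the confinement region)
#'
#' Any node strictly inside an obstacle disk is moved to the nearest point of
#' the circle; nodes within a contact tolerance are flagged.  The projection
#' is idempotent.
#'
#' @param positions n x 2 node positions (um).
#' @param env a `chemo_environment`.
#' @param contact_tol contact flag tolerance (um).
#' @return list with `positions` and logical `contact` flags.
#' @export
project_out_of_obstacles <- function(positions, env, contact_tol = 0.05) {
  contact <- rep(FALSE, nrow(positions))
  ob <- env$obstacles
  if (!is.null(ob)) {
    for (i in seq_len(nrow(ob))) {
      dx <- positions[, 1] - ob$x[i]
      dy <- positions[, 2] - ob$y[i]
      r <- sqrt(dx^2 + dy^2)
      inside <- r < ob$r[i]
      if (any(inside)) {
        deg <- inside & r < 1e-12    # at the centre: push along +x
        if (any(deg)) { dx[deg] <- 1; dy[deg] <- 0; r[deg] <- 1 }
        positions[inside, 1] <- ob$x[i] + dx[inside] / r[inside] * ob$r[i]
        positions[inside, 2] <- ob$y[i] + dy[inside] / r[inside] * ob$r[i]
      }
      contact <- contact | (r <= ob$r[i] + contact_tol)
    }
  }
  cf <- env$confinement
  if (!is.null(cf)) {
    dx <- positions[, 1] - cf$center[1]
    dy <- positions[, 2] - cf$center[2]
    r <- sqrt(dx^2 + dy^2)
    out <- r > cf$radius
    if (any(out)) {
      positions[out, 1] <- cf$center[1] + dx[out] / r[out] * cf$radius
      positions[out, 2] <- cf$center[2] + dy[out] / r[out] * cf$radius
      contact <- contact | out
    }
  }
  list(positions = positions, contact = contact)
}

#' Equally spaced ring of circular obstacles
#'
#' @param center ring centre (um).
#' @param ring_radius radius of the circle of obstacle centres (um).
#' @param n number of obstacles.
#' @param obstacle_radius radius of each obstacle (um).
#' @return obstacle data frame usable in [chemo_environment()].
#' @export
obstacle_ring <- function(center = c(0, 0), ring_radius = 20, n = 6,
                          obstacle_radius = 4) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  data.frame(x = center[1] + ring_radius * cos(th),
             y = center[2] + ring_radius * sin(th),
             r = obstacle_radius)
}
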