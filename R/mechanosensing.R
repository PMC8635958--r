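# FLNa-FilGAP mechanosensing: strain-gated release of crosslink-bound FilGAP
# into the cytosol and availability-gated return, with an exactly conserved
# global FilGAP budget (bound + cytosolic).
#
# Each (triangle, corner) of the lamellipodial network is an FLNa crosslink
# carrying m bound FilGAP (uM-equivalents) with capacity m0.  A corner whose
# angular strain sits inside the band [beta1, beta2] releases slowly
# (conformationally protected state); outside the band it releases fast.
# Release is first order in m; return is proportional to the local free
# capacity and to the cytosolic availability.

#' Mechanosensing parameter set
#'
#' @param A_ret return-rate constant (uM-equivalents/s at full cytosolic
#'   availability).
#' @param k_slow,k_fast slow/fast release rate constants (1/s),
#'   `0 <= k_slow < k_fast`.
#' @param beta1,beta2 strain band bounds (rad), `beta1 < beta2`; strains
#'   inside the closed band release slowly.
#' @param filgap_total total FilGAP budget (uM); conserved.
#' @param bound_frac fraction of the budget bound to crosslinks at t = 0.
#' @param capacity_frac total capacity as a fraction of the budget
#'   (`>= bound_frac`).
#' @return a list of class `mechano_params`.
#' @export
mechano_params <- function(A_ret = 0.02, k_slow = 0.005, k_fast = 0.3,
                           beta1 = -0.35, beta2 = 0.35, filgap_total = 0.6,
                           bound_frac = 0.8, capacity_frac = 0.9) {
  stopifnot(A_ret >= 0, k_slow >= 0, k_slow < k_fast, beta1 < beta2,
            filgap_total >= 0, bound_frac >= 0, bound_frac <= capacity_frac)
  p <- list(A_ret = A_ret, k_slow = k_slow, k_fast = k_fast, beta1 = beta1,
            beta2 = beta2, filgap_total = filgap_total,
            bound_frac = bound_frac, capacity_frac = capacity_frac)
  class(p) <- "mechano_params"
  p
}

#' Classify corner strains into slow/fast release modes
#'
#' @param delta_theta angular strain(s), rad.
#' @param beta1,beta2 band bounds (rad, closed interval).
#' @return integer 0 (inside band: slow release) or 1 (outside: fast),
#'   same shape as `delta_theta`.
#' @export
classify_strain <- function(delta_theta, beta1, beta2) {
  if (beta1 >= beta2) stop("beta1 must be below beta2")
  out <- 1L - (delta_theta >= beta1 & delta_theta <= beta2)
  storage.mode(out) <- "integer"
  if (is.matrix(delta_theta)) dim(out) <- dim(delta_theta)
  out
}

# fresh crosslink state for a mesh (uniform capacities, 80/20 bound/cytosol)
init_crosslinks <- function(mesh, params) {
  nc <- length(mesh$ref_angles)
  dims <- dim(mesh$ref_angles)
  m0v <- params$capacity_frac * params$filgap_total / max(nc, 1)
  mv <- params$bound_frac * params$filgap_total / max(nc, 1)
  cross <- list(keys = mesh$tri_keys_v,
                m = matrix(mv, dims[1], 3),
                m0 = matrix(m0v, dims[1], 3))
  class(cross) <- "crosslink_state"
  cross
}

#' Strain-gated FilGAP release and return
#'
#' Advances the bound-FilGAP occupancies by
#' `dm_i/dt = A_ret w (m0_i - m_i) / (sum m0 - sum m) -
#'  (k_slow + (k_fast - k_slow) sng_i) m_i`
#' with `sng_i` the band classification of the supplied strains and
#' `w = FilGAP_c / FilGAP_total` the cytosolic availability; the return term
#' is zero when the network is saturated.  Every released uM-equivalent is
#' credited to the cytosolic pool and every rebound one debited, so the
#' budget transfer is exact.
#'
#' @param crosslinks a `crosslink_state`.
#' @param filgap_c cytosolic FilGAP concentration (uM).
#' @param strains per-corner angular strain matrix (rad).
#' @param params a `mechano_params`.
#' @param dt time step (s).
#' @return list with updated `crosslinks` and `filgap_c`.
#' @export
filgap_step <- function(crosslinks, filgap_c, strains, params, dt) {
  m <- crosslinks$m
  m0 <- crosslinks$m0
  total <- sum(m) + filgap_c
  if (total <= 0) return(list(crosslinks = crosslinks, filgap_c = filgap_c))
  sng <- classify_strain(strains, params$beta1, params$beta2)
  krel <- params$k_slow + (params$k_fast - params$k_slow) * sng
  # sub-step bound: fastest release constant, and the per-corner return rate
  # A_ret w / deficit evaluated at the current deficit (floored at 5% of the
  # budget so a nearly saturated network cannot demand unbounded resolution;
  # the clip to [0, m0] catches the remainder)
  def0 <- max(sum(m0) - sum(m), 0.05 * total)
  nsub <- max(1L, ceiling(dt * max(params$k_fast, params$A_ret / def0) / 0.1))
  dts <- dt / nsub
  fc <- filgap_c
  rhs <- function(m, fc) {
    def <- sum(m0) - sum(m)
    ret <- if (def > 1e-12)
      params$A_ret * (fc / total) * (m0 - m) / def else 0 * m
    dm <- ret - krel * m
    list(dm = dm, dfc = -sum(dm))
  }
  for (s in seq_len(nsub)) {
    k1 <- rhs(m, fc)
    k2 <- rhs(m + dts * k1$dm, fc + dts * k1$dfc)
    m <- m + dts * (k1$dm + k2$dm) / 2
    m <- pmin(pmax(m, 0), m0)
    fc <- total - sum(m)           # exact budget transfer
  }
  crosslinks$m <- m
  list(crosslinks = crosslinks, filgap_c = fc)
}

#' Carry crosslink occupancies across a retriangulation
#'
#' Persisting (triangle, corner) entries keep their occupancy and capacity;
#' entries whose triangle vanished surrender their bound FilGAP to the
#' cytosol (exact budget transfer); new entries get the global mean capacity
#' and zero occupancy.
#'
#' @param old_crosslinks the `crosslink_state` before retriangulation.
#' @param mesh the mesh *after* [retriangulate()].
#' @param filgap_c cytosolic FilGAP concentration (uM).
#' @return list with the new `crosslinks` and updated `filgap_c`.
#' @export
rebind_capacity <- function(old_crosslinks, mesh, filgap_c) {
  keys <- mesh$tri_keys_v
  nt <- length(keys)
  idx <- match(keys, old_crosslinks$keys)
  hit <- !is.na(idx)
  m0bar <- if (length(old_crosslinks$m0)) mean(old_crosslinks$m0) else 0
  m <- matrix(0, nt, 3)
  m0 <- matrix(m0bar, nt, 3)
  if (any(hit)) {
    m[hit, ] <- old_crosslinks$m[idx[hit], , drop = FALSE]
    m0[hit, ] <- old_crosslinks$m0[idx[hit], , drop = FALSE]
  }
  lost <- sum(old_crosslinks$m) - sum(m[hit, ])
  cross <- list(keys = keys, m = m, m0 = m0)
  class(cross) <- "crosslink_state"
  list(crosslinks = cross, filgap_c = filgap_c + lost)
}
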