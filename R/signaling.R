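# Membrane signalling network on the periodic 1D membrane lattice.
#
# Species live on the membrane nodes as per-node *amounts* (concentration x
# node-centred arc length): membrane stretching then dilutes and compression
# concentrates species with no artificial mass change.  Three layers:
#   (i)  receptor layer (balanced inactivation): activator A (G_betagamma
#        derived) produced locally by the attractant signal, inhibitor B
#        produced at the same total rate but routed through the well-mixed
#        cytosol before re-binding the membrane; mutual annihilation makes A
#        localise to the up-gradient edge and membrane-bound B to the
#        down-gradient edge.
#   (ii) Rac/RhoA layer: activation from the conserved cytosolic pools with
#        rates biased by the receptor layer (PAK1 = A, Lsc1 = B_m),
#        first-order inactivation, and the FilGAP-mediated antagonism Q
#        (sink for Rac, source for RhoA).
#   (iii) phosphoinositide layer: PIP2 <-> PIP3 interconversion catalysed by
#        membrane-bound PI3K/PTEN whose translocation from the cytosol is
#        sampled by a Monte-Carlo scheme (binding biased by PIP3 + active Rac
#        for PI3K, PIP2 + active RhoA for PTEN).
#
# Deterministic parts integrate with an explicit Heun scheme (sub-stepped for
# diffusive/kinetic stability, clipped at zero); translocation is a separate
# stochastic (or optionally mean-field) sub-operator.

#' Signalling parameter set
#'
#' Rates of the three-layer membrane network.  Totals are absolute amounts
#' (uM x um, i.e. concentration integrated along the membrane); enzyme
#' numbers are molecule counts with `n_per_uM` converting a nominal cytosolic
#' concentration into a count.
#'
#' @param D_m membrane diffusivity (um^2/s), shared by all membrane species.
#' @param I_R,I_rho baseline activation rates of Rac and RhoA (1/s).
#' @param alpha,tau activation of Rac by PAK1 and of RhoA by Lsc1
#'   (1/(uM s)).
#' @param delta_G baseline (GAP-mediated) inactivation rate (1/s); must
#'   exceed 1/s so the FilGAP antagonism source on RhoA stays bounded.
#' @param A_G steepness of the FilGAP antagonism sigmoid (dimensionless).
#' @param b signal impact of the FilGAP*PIP3 product (1/uM^2).
#' @param k_s receptor production rate of activator and inhibitor (1/s).
#' @param k_deg degradation rate of membrane activator/inhibitor (1/s).
#' @param k_ann mutual annihilation rate of activator and membrane inhibitor
#'   (1/(uM s)).
#' @param k_onB membrane re-binding rate of the cytosolic inhibitor (1/s).
#' @param k_cat3 PIP2 -> PIP3 catalytic rate per bound PI3K molecule
#'   (um/s/molecule); `k_cat2` the PTEN mirror.
#' @param act_K_R half-activation concentration (uM) of PI3K catalysis by
#'   local active Rac (Hill with exponent `act_h`): PI3K is an effector
#'   *activated by* Rac, so suppressing Rac at a PIP3 patch shuts the
#'   patch's lipid production down.  `act_K_rho` is the PTEN/RhoA mirror.
#' @param act_h Hill exponent of the effector activation gates; steep
#'   (default 4) so the moderate Rac suppression achievable by the FilGAP
#'   antagonism translates into a decisive loss of PI3K activity.
#' @param k_on,k_off enzyme membrane binding/unbinding rates (1/s).
#' @param w_R3 bias of PI3K binding by local active Rac (1/uM); `w_rho2` the
#'   PTEN/RhoA mirror.
#' @param bind_coop cooperativity exponent of the enzyme binding preference
#'   for its lipid (2 = cooperative recruitment, the minimal
#'   winner-take-all closure yielding a single dominant patch; 1 =
#'   proportional binding).
#' @param sigma_noise amplitude of the zero-mean multiplicative noise on the
#'   Rac/RhoA activation propensities (the endogenous stochastic signal).
#' @param R_tot,rho_tot,PI_tot conserved totals (uM um).
#' @param pi3k_conc,pten_conc nominal enzyme concentrations (uM).
#' @param n_per_uM molecules per uM of enzyme.
#' @param eps_bind floor on the binding weight (amount) preventing an
#'   absorbing zero-PIP state.
#' @param dt_chem chemistry master step (s).
#' @return a list of class `signaling_params`.
#' @export
signaling_params <- function(D_m = 0.05, I_R = 1, I_rho = 1, alpha = 6,
                             tau = 6, delta_G = 0.5, A_G = 10, b = 400,
                             k_s = 0.3, k_deg = 0.05, k_ann = 100,
                             k_onB = 2, k_cat3 = 0.22, k_cat2 = 0.9,
                             k_on = 0.5, k_off = 0.08, w_R3 = 2, w_rho2 = 2,
                             act_K_R = 1, act_K_rho = 1, act_h = 4,
                             bind_coop = 4, sigma_noise = 0.25, R_tot = 60,
                             rho_tot = 60, PI_tot = 400, pi3k_conc = 0.06,
                             pten_conc = 0.06, n_per_uM = 2000,
                             eps_bind = 1e-6, dt_chem = 0.5) {
  p <- as.list(environment())
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x >= 0, TRUE)),
            A_G > 0, dt_chem > 0)
  class(p) <- "signaling_params"
  p
}

# -- 1D periodic diffusion ---------------------------------------------------

# flux-form Laplacian on amounts; exactly conservative
lap_amount <- function(a, d, D) {
  n <- length(a)
  nxt <- c(2:n, 1)
  prv <- c(n, 1:(n - 1))
  conc <- a / d
  h <- (d + d[nxt]) / 2
  flux <- D * (conc[nxt] - conc) / h    # flux from node i+1 into node i (>0)
  flux - flux[prv]
}

#' Conservative diffusion on the periodic membrane lattice
#'
#' Flux-form finite differences on the non-uniform node-centred lattice,
#' sub-stepped to the explicit stability bound.  The length-weighted total
#' amount is conserved to machine precision.
#'
#' @param field per-node amounts (concentration x arc length).
#' @param arc_lengths node-centred arc lengths (um).
#' @param D diffusivity (um^2/s).
#' @param dt time step (s).
#' @return updated amounts.
#' @export
diffuse_periodic_1d <- function(field, arc_lengths, D, dt) {
  if (any(arc_lengths <= 0))
    stop("integrity error: non-positive segment length")
  if (D <= 0 || dt <= 0) return(field)
  n <- length(field)
  nxt <- c(2:n, 1)
  h <- (arc_lengths + arc_lengths[nxt]) / 2
  dt_stable <- 0.4 * min(arc_lengths * pmin(h, h[c(n, 1:(n - 1))])) / D
  nsub <- max(1L, ceiling(dt / dt_stable))
  dts <- dt / nsub
  for (s in seq_len(nsub)) field <- field + dts * lap_amount(field, arc_lengths, D)
  field
}

# shared sub-step count for a Heun reaction-diffusion integration
n_substeps <- function(dt, d, D, max_rate) {
  n <- length(d)
  nxt <- c(2:n, 1)
  h <- (d + d[nxt]) / 2
  dt_diff <- if (D > 0) 0.4 * min(d * pmin(h, h[c(n, 1:(n - 1))])) / D else Inf
  # Heun (explicit trapezoid) is stable to dt * rate < 2; keep a 2x margin
  dt_react <- if (max_rate > 0) 1 / max_rate else Inf
  max(1L, ceiling(dt / min(dt_diff, dt_react)))
}

# -- receptor layer (balanced inactivation) ---------------------------------

#' Receptor-layer step (balanced inactivation)
#'
#' Advances the membrane activator A, membrane-bound inhibitor B_m and
#' cytosolic inhibitor B_c under the attractant signal `stimulus`, and sets
#' the effector fields `E_p` (PAK1, = A) and `E_rho` (Lsc1, = B_m).  The
#' layer is only meaningful while a stimulus schedule is active; with
#' `stimulus = 0` everywhere all species decay to zero.
#'
#' @param state membrane state list (fields `A`, `Bm` as amounts, `d` arc
#'   lengths).
#' @param cytosol cytosol state list (field `Bc`, uM).
#' @param stimulus per-node attractant concentration (>= 0).
#' @param params a `signaling_params`.
#' @param dt time step (s).
#' @return list with updated `state` and `cytosol`.
#' @export
gpcr_step <- function(state, cytosol, stimulus, params, dt) {
  if (any(stimulus < 0)) stop("integrity error: negative stimulus")
  d <- state$d
  L <- sum(d)
  rate_cap <- params$k_deg + params$k_ann *
    max(max(state$A / d), max(state$Bm / d), 1e-12) + params$k_onB
  nsub <- n_substeps(dt, d, params$D_m, rate_cap)
  dts <- dt / nsub
  A <- state$A; Bm <- state$Bm; Bc <- cytosol$Bc
  rhs <- function(A, Bm, Bc) {
    cA <- A / d; cB <- Bm / d
    list(
      dA = lap_amount(A, d, params$D_m) +
        d * (params$k_s * stimulus - params$k_deg * cA - params$k_ann * cA * cB),
      dBm = lap_amount(Bm, d, params$D_m) +
        d * (params$k_onB * Bc - params$k_deg * cB - params$k_ann * cA * cB),
      dBc = params$k_s * sum(stimulus * d) / L - params$k_onB * Bc)
  }
  for (s in seq_len(nsub)) {
    k1 <- rhs(A, Bm, Bc)
    k2 <- rhs(A + dts * k1$dA, Bm + dts * k1$dBm, Bc + dts * k1$dBc)
    A <- pmax(A + dts * (k1$dA + k2$dA) / 2, 0)
    Bm <- pmax(Bm + dts * (k1$dBm + k2$dBm) / 2, 0)
    Bc <- max(Bc + dts * (k1$dBc + k2$dBc) / 2, 0)
  }
  state$A <- A; state$Bm <- Bm
  state$E_p <- A / d; state$E_rho <- Bm / d
  cytosol$Bc <- Bc
  list(state = state, cytosol = cytosol)
}

# -- FilGAP antagonism (ultrasensitive switch) ------------------------------

#' FilGAP-mediated Rac/RhoA antagonism
#'
#' First-order ultrasensitive switch driven by the product of the cytosolic
#' FilGAP concentration and the local PIP3 concentration:
#' `Q_R = -1 / (1 + A_G exp(-b [FilGAP] [PIP3]))`, `Q_rho = -Q_R`.
#' `Q_R` ranges over (-1, -1/(1+A_G)): a sink on active Rac that saturates as
#' the released FilGAP binds PIP3-rich membrane, mirrored as a source on
#' active RhoA.
#'
#' @param filgap_c cytosolic FilGAP concentration (uM).
#' @param pip3 per-node PIP3 concentration (uM).
#' @param params a `signaling_params`.
#' @return list with per-node `Q_R` and `Q_rho` (1/s).
#' @export
filgap_antagonism <- function(filgap_c, pip3, params) {
  if (filgap_c < 0 || any(pip3 < 0))
    stop("integrity error: negative FilGAP or PIP3 concentration")
  Q_R <- -1 / (1 + params$A_G * exp(-params$b * filgap_c * pip3))
  list(Q_R = Q_R, Q_rho = -Q_R)
}

# conserved cytosolic pools by the conservation law (concentrations)
cytosolic_pools <- function(state, params) {
  L <- sum(state$d)
  list(R_cyt = (params$R_tot - sum(state$R)) / L,
       rho_cyt = (params$rho_tot - sum(state$rho)) / L, L = L)
}

#' Rac/RhoA layer step
#'
#' Reaction-diffusion update of active Rac and RhoA amounts:
#' activation from the conserved cytosolic pools at rate
#' `(I + alpha E)(1 + xi)` (xi the endogenous multiplicative noise),
#' first-order inactivation `delta_G`, and the FilGAP antagonism `Q` acting
#' as a Rac sink and RhoA source.  Inactive pools follow from conservation.
#'
#' @param state membrane state (fields `R`, `rho` amounts; `E_p`, `E_rho`
#'   concentrations; `d`).
#' @param cytosol cytosol state (inactive pools are derived, not stored).
#' @param Q_R,Q_rho antagonism fields from [filgap_antagonism()].
#' @param params a `signaling_params`.
#' @param dt time step (s).
#' @param xi per-node noise realisation (defaults to zero; drawn by the
#'   simulator from its dedicated noise stream).
#' @return the updated `state`.
#' @export
rac_rho_step <- function(state, cytosol, Q_R, Q_rho, params, dt, xi = NULL) {
  d <- state$d
  L <- sum(d)
  if (is.null(xi)) xi <- numeric(length(d))
  actR <- (params$I_R + params$alpha * state$E_p) * pmax(1 + xi, 0)
  actr <- (params$I_rho + params$tau * state$E_rho) * pmax(1 + xi, 0)
  # activation draws on the shared cytosolic pool, so its contribution to
  # any eigenvalue is ~ act_i d_i / L (Gershgorin), not max(act)
  rate_cap <- params$delta_G + 1 +
    2 * max(c(actR, actr)) * max(d) / L
  nsub <- n_substeps(dt, d, params$D_m, rate_cap)
  R <- state$R; rho <- state$rho
  for (try in 1:6) {
    dts <- dt / nsub
    Rw <- R; rw <- rho; ok <- TRUE
    # the antagonism *source* (positive Q) converts inactive protein and is
    # therefore gated by cytosolic availability; without the gate the source
    # term would create active protein from nothing once the pool empties
    rhs <- function(R, rho) {
      R_cyt <- (params$R_tot - sum(R)) / L
      rho_cyt <- (params$rho_tot - sum(rho)) / L
      pfR <- min(max(R_cyt / (params$R_tot / L), 0), 1)
      pfr <- min(max(rho_cyt / (params$rho_tot / L), 0), 1)
      qR <- pmin(Q_R, 0) + pmax(Q_R, 0) * pfR
      qr <- pmin(Q_rho, 0) + pmax(Q_rho, 0) * pfr
      list(dR = lap_amount(R, d, params$D_m) + d * actR * max(R_cyt, 0) -
             params$delta_G * R + qR * R,
           drho = lap_amount(rho, d, params$D_m) + d * actr * max(rho_cyt, 0) -
             params$delta_G * rho + qr * rho)
    }
    for (s in seq_len(nsub)) {
      k1 <- rhs(Rw, rw)
      k2 <- rhs(Rw + dts * k1$dR, rw + dts * k1$drho)
      Rw <- pmax(Rw + dts * (k1$dR + k2$dR) / 2, 0)
      rw <- pmax(rw + dts * (k1$drho + k2$drho) / 2, 0)
      # a species riding the pool boundary (all active) can overshoot by a
      # small amount in any sub-step; project back onto the pool.  Larger
      # excursions mean the step is too coarse: halve it.
      if (sum(Rw) > params$R_tot) {
        if (sum(Rw) > params$R_tot * 1.01) { ok <- FALSE; break }
        Rw <- Rw * (params$R_tot / sum(Rw))
      }
      if (sum(rw) > params$rho_tot) {
        if (sum(rw) > params$rho_tot * 1.01) { ok <- FALSE; break }
        rw <- rw * (params$rho_tot / sum(rw))
      }
    }
    if (ok) break
    nsub <- nsub * 2L   # pool exhaustion: halve the sub-step
  }
  if (!ok) stop("integrity error: inactive Rac/RhoA pool exhausted")
  state$R <- Rw; state$rho <- rw
  state
}

# -- phosphoinositide layer -------------------------------------------------

#' Phosphoinositide layer step (reactions + enzyme translocation)
#'
#' Deterministic part: PIP2 -> PIP3 conversion at rate `k_cat3 n_PI3K,i c2`
#' and the PTEN mirror, plus membrane diffusion of both lipids; the
#' length-weighted PIP3 + PIP2 total is conserved exactly.  Stochastic part:
#' each free PI3K molecule binds node i with probability
#' `dt k_on share_i (1 + w_R3 Rac_i)` (multinomial placement) and unbinds
#' with probability `dt k_off`; PTEN is the PIP2/RhoA mirror.  Enzyme counts
#' are integers in Monte-Carlo mode; `mean_field = TRUE` replaces the draws
#' by their expectations (deterministic, used for symmetry analyses).
#'
#' @param state membrane state (fields `P3`, `P2` amounts; `n3`, `nP`
#'   enzyme counts; `R`, `rho`; `d`).
#' @param cytosol cytosol state (fields `pi3k_free`, `pten_free`).
#' @param params a `signaling_params`.
#' @param dt time step (s).
#' @param mean_field use expected-value translocation instead of sampling.
#' @return list with updated `state` and `cytosol`.
#' @export
pi_step <- function(state, cytosol, params, dt, mean_field = FALSE) {
  d <- state$d
  P3 <- state$P3; P2 <- state$P2
  n3 <- state$n3; nP <- state$nP
  # deterministic conversion + diffusion (Heun); catalysis gated by the
  # local GTPases (PI3K an effector of Rac, PTEN of RhoA)
  cR <- state$R / d
  crho <- state$rho / d
  h <- params$act_h
  g3 <- if (params$act_K_R > 0)
    cR^h / (cR^h + params$act_K_R^h) else 1
  g2 <- if (params$act_K_rho > 0)
    crho^h / (crho^h + params$act_K_rho^h) else 1
  max_rate <- max(params$k_cat3 * max(n3 * g3),
                  params$k_cat2 * max(nP * g2), 1e-12)
  nsub <- n_substeps(dt, d, params$D_m, max_rate)
  dts <- dt / nsub
  rhs <- function(P3, P2) {
    conv <- params$k_cat3 * g3 * n3 * (P2 / d) -
      params$k_cat2 * g2 * nP * (P3 / d)
    list(d3 = lap_amount(P3, d, params$D_m) + conv,
         d2 = lap_amount(P2, d, params$D_m) - conv)
  }
  for (s in seq_len(nsub)) {
    k1 <- rhs(P3, P2)
    k2 <- rhs(P3 + dts * k1$d3, P2 + dts * k1$d2)
    P3 <- P3 + dts * (k1$d3 + k2$d3) / 2
    P2 <- P2 + dts * (k1$d2 + k2$d2) / 2
    # positivity clip as a mass-preserving back-transfer
    neg <- pmin(P3, 0); P3 <- P3 - neg; P2 <- P2 + neg
    neg <- pmin(P2, 0); P2 <- P2 - neg; P3 <- P3 + neg
    P3 <- pmax(P3, 0)
  }
  # enzyme translocation; binding share cooperative in the lipid
  # concentration (amount-weighted), biased by the local GTPase
  cR <- state$R / d; crho <- state$rho / d
  s3 <- (P3 / d)^params$bind_coop * d + params$eps_bind * d
  sP <- (P2 / d)^params$bind_coop * d + params$eps_bind * d
  q3 <- params$k_on * dt * s3 / sum(s3) * (1 + params$w_R3 * cR)
  qP <- params$k_on * dt * sP / sum(sP) * (1 + params$w_rho2 * crho)
  nsub_mc <- max(1L, ceiling(max(sum(q3), sum(qP), params$k_off * dt) / 0.5))
  for (s in seq_len(nsub_mc)) {
    q3s <- q3 / nsub_mc; qPs <- qP / nsub_mc
    p_off <- params$k_off * dt / nsub_mc
    if (mean_field) {
      bind3 <- cytosol$pi3k_free * q3s
      bindP <- cytosol$pten_free * qPs
      un3 <- n3 * p_off
      unP <- nP * p_off
    } else {
      nb3 <- rbinom(1L, cytosol$pi3k_free, min(sum(q3s), 1))
      nbP <- rbinom(1L, cytosol$pten_free, min(sum(qPs), 1))
      bind3 <- if (nb3 > 0) as.numeric(stats::rmultinom(1L, nb3, q3s)) else numeric(length(d))
      bindP <- if (nbP > 0) as.numeric(stats::rmultinom(1L, nbP, qPs)) else numeric(length(d))
      un3 <- rbinom(length(d), as.integer(round(n3)), p_off)
      unP <- rbinom(length(d), as.integer(round(nP)), p_off)
    }
    n3 <- n3 + bind3 - un3
    nP <- nP + bindP - unP
    cytosol$pi3k_free <- cytosol$pi3k_free - sum(bind3) + sum(un3)
    cytosol$pten_free <- cytosol$pten_free - sum(bindP) + sum(unP)
  }
  state$P3 <- P3; state$P2 <- P2; state$n3 <- n3; state$nP <- nP
  list(state = state, cytosol = cytosol)
}
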