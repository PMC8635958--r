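# Membrane mechanics: overdamped force balance on the membrane ring and
# quasi-static relaxation of the lamellipodial network.
#
# Force balance per membrane node:  mu * v_i = F_elas + F_vis + F_pro +
# F_cont + F_area + F_drag.  Elastic/viscous forces come from the
# spring-dashpot membrane elements (Kelvin-Voigt in parallel), protrusive and
# contractile forces are slaved to the PIP3/PIP2 polarity, the area term
# restores the enclosed area and the drag term couples the membrane to the
# lamellipod.

#' Mechanical parameter set
#'
#' @param mu substrate friction coefficient (nN s/um).
#' @param k membrane spring stiffness (nN/um).
#' @param eta_m membrane dashpot viscosity (nN s/um).
#' @param K_lam lamellipodial spring stiffness (nN/um, rest length zero);
#'   formal - the interior network is relaxed quasi-statically, so only the
#'   equilibrium (not the stiffness scale) enters.
#' @param f_pro_max maximal protrusive force per node (nN).
#' @param f_cont_max maximal contractile force per node (nN).
#' @param c_drag membrane-lamellipod relative-velocity coupling (nN s/um).
#' @param k_area area-restoring modulus (nN/um^3).
#' @param rest_edge_length membrane spring rest length (um); `NULL` means the
#'   initial membrane spacing of the mesh.
#' @param dt_mech mechanics time step (s).
#' @param hill_n Hill exponent of the force-response to PIP3/PIP2.
#' @param c_half3,c_half2 Hill half-saturation concentrations (uM) for the
#'   protrusive (PIP3) and contractile (PIP2) response.
#' @return a list of class `mechanics_params`.
#' @export
mechanics_params <- function(mu = 1, k = 6, eta_m = 1, K_lam = 1,
                             f_pro_max = 1.15, f_cont_max = 0.5,
                             c_drag = 0.2, k_area = 0.05,
                             rest_edge_length = NULL, dt_mech = 0.5,
                             hill_n = 2, c_half3 = 8, c_half2 = 10) {
  p <- list(mu = mu, k = k, eta_m = eta_m, K_lam = K_lam,
            f_pro_max = f_pro_max, f_cont_max = f_cont_max, c_drag = c_drag,
            k_area = k_area, rest_edge_length = rest_edge_length,
            dt_mech = dt_mech, hill_n = hill_n,
            c_half3 = c_half3, c_half2 = c_half2)
  stopifnot(all(vapply(p[c("mu", "k", "eta_m", "K_lam", "f_pro_max",
                           "f_cont_max", "c_drag", "k_area")], function(x)
                       x >= 0, TRUE)), dt_mech > 0)
  class(p) <- "mechanics_params"
  p
}

# tensions along each membrane edge -> equal and opposite end forces
edge_forces <- function(mem, tension, unit) {
  n <- nrow(mem)
  prv <- c(n, 1:(n - 1))
  f <- tension * unit
  f - f[prv, , drop = FALSE]
}

# light per-substep ring geometry (no integrity checks)
ring_area <- function(mem) {
  n <- nrow(mem)
  nxt <- c(2:n, 1)
  sum(mem[, 1] * mem[nxt, 2] - mem[nxt, 1] * mem[, 2]) / 2
}

# exact area gradient: dA/dX_i = rot(X_{i+1} - X_{i-1}) / 2; the resulting
# per-node forces telescope to zero over the closed ring
area_gradient <- function(mem) {
  n <- nrow(mem)
  nxt <- c(2:n, 1)
  prv <- c(n, 1:(n - 1))
  cbind(mem[nxt, 2] - mem[prv, 2], mem[prv, 1] - mem[nxt, 1]) / 2
}

#' Passive membrane forces (spring + dashpot)
#'
#' Elastic force from Hookean membrane springs about their rest length and a
#' viscous force proportional to the edge elongation rate (finite difference
#' against the previous positions over `dt_mech`).  Both are pairwise equal
#' and opposite, so they sum to zero over the closed ring.
#'
#' @param mesh a `cell_mesh`.
#' @param prev_positions membrane positions at the previous step.
#' @param params a `mechanics_params`.
#' @return list with per-node force matrices `elastic` and `viscous` (nN).
#' @export
membrane_passive_forces <- function(mesh, prev_positions, params) {
  mem <- mesh$membrane
  n <- nrow(mem)
  nxt <- c(2:n, 1)
  e <- mem[nxt, , drop = FALSE] - mem
  len <- sqrt(rowSums(e^2))
  if (any(len < 1e-12)) stop("integrity error: zero-length membrane edge")
  u <- e / len
  l0 <- params$rest_edge_length %||% mesh$rest_spacing
  ep <- prev_positions[nxt, , drop = FALSE] - prev_positions
  lenp <- sqrt(rowSums(ep^2))
  rate <- (len - lenp) / params$dt_mech
  list(elastic = edge_forces(mem, params$k * (len - l0), u),
       viscous = edge_forces(mem, params$eta_m * rate, u))
}

#' Active protrusive and contractile forces
#'
#' Protrusion pushes outward along the node normal where the PIP3
#' concentration exceeds its length-weighted spatial mean; contraction pulls
#' inward where PIP2 exceeds its mean.  Both saturate through a Hill
#' response, bounding each force by its maximum.
#'
#' @param mesh a `cell_mesh`.
#' @param geom geometry cache from [compute_geometry()].
#' @param pip3,pip2 per-node membrane concentrations (uM).
#' @param params a `mechanics_params`.
#' @return list with force matrices `protrusive` and `contractile` (nN).
#' @export
active_forces <- function(mesh, geom, pip3, pip2, params) {
  if (any(pip3 < 0) || any(pip2 < 0))
    stop("integrity error: negative phosphoinositide concentration")
  d <- geom$node_lengths
  # strict relative margin so an exactly uniform field exerts no force
  m3 <- pip3 > weighted_mean_conc(pip3, d) * (1 + 1e-9)
  m2 <- pip2 > weighted_mean_conc(pip2, d) * (1 + 1e-9)
  fp <- params$f_pro_max * hill(pip3, params$c_half3, params$hill_n) * m3
  fc <- params$f_cont_max * hill(pip2, params$c_half2, params$hill_n) * m2
  list(protrusive = fp * geom$normals, contractile = -fc * geom$normals)
}

#' Area-restoring and membrane-lamellipod drag forces
#'
#' The area term pushes every node outward (inward) when the enclosed area is
#' below (above) target; the drag term penalises relative motion between a
#' membrane node and its lamellipodial neighbourhood.
#'
#' @param mesh a `cell_mesh`.
#' @param geom geometry cache.
#' @param v_membrane per-node membrane velocity estimate (um/s).
#' @param v_lamellipod per-membrane-node lamellipodial velocity estimate
#'   (um/s; mean over adjacent interior nodes).
#' @param params a `mechanics_params`.
#' @param area_target target enclosed area (um^2).
#' @return list with force matrices `area` and `drag` (nN).
#' @export
area_drag_forces <- function(mesh, geom, v_membrane, v_lamellipod, params,
                             area_target) {
  fa <- params$k_area * (area_target - geom$area) * area_gradient(mesh$membrane)
  fd <- -params$c_drag * (v_membrane - v_lamellipod)
  list(area = fa, drag = fd)
}

#' Short-range self-repulsion between non-adjacent membrane nodes
#'
#' Excluded-volume force preventing the membrane from self-intersecting when
#' the rear pinches: nodes closer than `r_rep` (and not edge neighbours)
#' repel linearly with stiffness `k_rep`.  Pairwise equal and opposite.
#'
#' @param mem membrane positions (n x 2).
#' @param r_rep interaction range (um).
#' @param k_rep repulsion stiffness (nN/um).
#' @return per-node force matrix (nN).
#' @export
membrane_repulsion <- function(mem, r_rep, k_rep) {
  n <- nrow(mem)
  dx <- outer(mem[, 1], mem[, 1], "-")
  dy <- outer(mem[, 2], mem[, 2], "-")
  dist <- sqrt(dx^2 + dy^2)
  idx <- abs(outer(seq_len(n), seq_len(n), "-"))
  near <- dist < r_rep & idx > 1 & idx < n - 1
  if (!any(near)) return(matrix(0, n, 2))
  dist[!near] <- Inf
  mag <- k_rep * (r_rep - dist) / pmax(dist, 1e-6)   # per pair, along (i - j)
  mag[!near] <- 0
  cbind(rowSums(mag * dx), rowSums(mag * dy))
}

#' Advance the membrane by the overdamped force balance
#'
#' `v_i = F_i / mu` over `dt_mech`, with each node's displacement capped at
#' 0.2 membrane spacings (capped nodes are counted in the returned
#' `n_capped`), followed by the obstacle/confinement projection.  When
#' `prev_positions` and `area_target` are supplied, the step is linearly
#' implicit (backward Euler) in the stiff passive terms: velocities solve
#' `(mu I + C + dt K) v = F_ext + F_elas + F_area` with `C` the dashpot
#' damping matrix and `K` the current spring stiffness; this is stable for
#' stiff membrane springs at the master step size, where an explicit
#' treatment of the edge dashpots is unconditionally unstable for short-
#' wavelength modes.
#'
#' @param mesh a `cell_mesh`.
#' @param total_forces per-node force matrix (nN): the full force balance
#'   (plain explicit mode) or the external active/drag forces (implicit
#'   mode).
#' @param env a `chemo_environment` (or `NULL` for free space).
#' @param params a `mechanics_params`.
#' @param prev_positions membrane positions at the previous master step
#'   (enables implicit mode).
#' @param area_target target enclosed area (um^2, implicit mode).
#' @return list with the updated mesh, realised `velocity` (um/s), obstacle
#'   `contact` flags and `n_capped`.
#' @export
step_membrane <- function(mesh, total_forces, env, params,
                          prev_positions = NULL, area_target = NULL) {
  dt <- params$dt_mech
  cap <- 0.2 * mesh$rest_spacing
  start <- mesh$membrane
  n <- nrow(start)
  if (is.null(prev_positions)) {
    v <- total_forces / params$mu
  } else {
    nxt <- c(2:n, 1)
    e <- start[nxt, , drop = FALSE] - start
    len <- sqrt(rowSums(e^2))
    if (any(len < 1e-12)) stop("integrity error: zero-length membrane edge")
    u <- e / len
    l0 <- params$rest_edge_length %||% mesh$rest_spacing
    tension <- params$k * (len - l0)
    f_elas <- edge_forces(start, tension, u)
    f_area <- params$k_area * (area_target - ring_area(start)) *
      area_gradient(start)
    F <- total_forces + f_elas + f_area
    # M = mu I + C + dt K over the interleaved (x1,y1,x2,y2,...)
    M <- membrane_matrix_cpp(u, len, tension, params$k, params$eta_m, dt,
                             params$mu)
    v <- matrix(solve(M, as.vector(t(F))), ncol = 2, byrow = TRUE)
  }
  disp <- sqrt(rowSums(v^2)) * dt
  over <- disp > cap
  if (any(over)) v[over, ] <- v[over, , drop = FALSE] * (cap / disp[over] / dt)
  newpos <- start + v * dt
  n_capped <- sum(over)
  contact <- rep(FALSE, n)
  if (!is.null(env)) {
    pr <- project_out_of_obstacles(newpos, env)
    newpos <- pr$positions
    contact <- pr$contact
  }
  velocity <- (newpos - start) / dt
  mesh$membrane <- newpos
  list(mesh = mesh, velocity = velocity, contact = contact,
       n_capped = n_capped)
}

#' Relax the lamellipodial network to its spring equilibrium
#'
#' Solves `sum_j (X_j - X_i) = 0` for every interior node (each node at the
#' arithmetic mean of its Delaunay neighbours) with the membrane ring fixed,
#' by conjugate gradients on the interior graph Laplacian.  The converged
#' residual satisfies `max |sum_j (X_j - X_i)| < 1e-8` um.
#'
#' @param mesh a `cell_mesh` with a current triangulation.
#' @param tol residual tolerance (infinity norm, um).
#' @param maxit maximum CG iterations.
#' @return the mesh with relaxed interior positions.
#' @export
relax_interior <- function(mesh, tol = 5e-9, maxit = 2000) {
  pos <- relax_interior_cpp(mesh$triangles, all_positions(mesh),
                            mesh$n_membrane, tol, maxit)
  mesh$interior <- pos[(mesh$n_membrane + 1):nrow(pos), , drop = FALSE]
  mesh
}
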