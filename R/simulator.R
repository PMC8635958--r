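# Master loop coupling mesh, mechanics, signalling, mechanosensing and
# environment, plus the experiment protocols (spontaneous migration,
# gradient/mutant runs, obstacle ring).

rotate2 <- function(v, angle_deg) {
  a <- angle_deg * pi / 180
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}

#' Simulation configuration
#'
#' Bundles mesh geometry, the three parameter sets, the environment, the
#' stimulus schedule and output cadence.  The parameter defaults are the
#' package's calibrated profile for a 10 um cell (45 membrane nodes, 421
#' interior nodes); every value can be overridden.
#'
#' @param t_end simulated time (s).
#' @param mesh list with `diameter`, `n_membrane`, `n_interior`.
#' @param mechanics a [mechanics_params()].
#' @param signaling a [signaling_params()].
#' @param mechano a [mechano_params()].
#' @param env a [chemo_environment()].
#' @param onset gradient onset time (s) when `gradient_percent` is set; the
#'   source is placed at onset relative to the cell's polarity at that
#'   moment.
#' @param gradient_percent gradient strength across the cell (percent), or
#'   `NULL` for no scheduled source.
#' @param gradient_angle_deg angle between the established polarity and the
#'   source direction (90 = perpendicular, 180 = opposite).
#' @param remesh_every retriangulation cadence (master steps).  Node
#'   displacements are capped at 0.2 membrane spacings per step, so the
#'   Delaunay topology rarely changes between consecutive steps; the default
#'   of 2 halves the triangulation cost with no measurable effect on the
#'   dynamics.  Set to 1 to retriangulate every step.
#' @param record_every scalar-series recording cadence (steps).
#' @param kymo_every kymograph recording cadence (steps).
#' @param deterministic use mean-field enzyme translocation (no MC
#'   sampling); combined with `sigma_noise = 0` this makes runs fully
#'   deterministic and symmetry-preserving.
#' @param master_seed integer master seed; all RNG streams derive from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(t_end = 900, mesh = list(diameter = 10,
                                                n_membrane = 45L,
                                                n_interior = 421L),
                       mechanics = mechanics_params(),
                       signaling = signaling_params(),
                       mechano = mechano_params(),
                       env = chemo_environment(),
                       onset = NULL, gradient_percent = NULL,
                       gradient_angle_deg = 90,
                       remesh_every = 2L, record_every = 1L, kymo_every = 4L,
                       deterministic = FALSE, master_seed = 1L) {
  stopifnot(t_end > 0)
  cfg <- list(t_end = t_end, mesh = mesh, mechanics = mechanics,
              signaling = signaling, mechano = mechano, env = env,
              schedule = list(onset = onset,
                              gradient_percent = gradient_percent,
                              gradient_angle_deg = gradient_angle_deg),
              remesh_every = as.integer(remesh_every),
              record_every = as.integer(record_every),
              kymo_every = as.integer(kymo_every),
              deterministic = deterministic,
              master_seed = as.integer(master_seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Serialize / restore a configuration
#'
#' @param config a `sim_config`.
#' @param path optional output file.
#' @return JSON string (or the path, invisibly).
#' @export
config_to_json <- function(config, path = NULL) {
  strip <- function(x) {
    if (is.list(x) && !is.data.frame(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  js <- jsonlite::toJSON(strip(unclass(config)),
                         auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname config_to_json
#' @param json JSON string or file produced by [config_to_json()].
#' @export
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  if (!is.null(x$env$obstacles))
    x$env$obstacles <- as.data.frame(x$env$obstacles)
  cfg <- sim_config(
    t_end = x$t_end, mesh = x$mesh,
    mechanics = do.call(mechanics_params,
                        x$mechanics[names(x$mechanics) != ""]),
    signaling = do.call(signaling_params, x$signaling),
    mechano = do.call(mechano_params, x$mechano),
    env = chemo_environment(
      sources = lapply(x$env$sources, function(s)
        do.call(chemo_source, s)),
      obstacles = x$env$obstacles, confinement = x$env$confinement),
    onset = x$schedule$onset, gradient_percent = x$schedule$gradient_percent,
    gradient_angle_deg = x$schedule$gradient_angle_deg,
    remesh_every = x$remesh_every %||% 2L,
    record_every = x$record_every, kymo_every = x$kymo_every,
    deterministic = x$deterministic, master_seed = x$master_seed)
  cfg
}

# initial simulation state: fresh mesh, uniform fields at their homogeneous
# steady state, enzymes cytosolic, crosslinks at the 80/20 bound split
init_state <- function(config) {
  sg <- config$signaling
  mo <- config$mechano
  mesh <- build_disk_mesh(config$mesh$diameter, config$mesh$n_membrane,
                          config$mesh$n_interior,
                          seed = derive_seed(config$master_seed, 2L))
  geom <- compute_geometry(mesh)
  d <- geom$node_lengths
  L <- geom$perimeter
  nm <- mesh$n_membrane
  c_pi <- sg$PI_tot / (2 * L)
  fc0 <- (1 - mo$bound_frac) * mo$filgap_total
  q0 <- -filgap_antagonism(fc0, c_pi, sg)$Q_R[1]
  cR0 <- sg$I_R * (sg$R_tot / L) / (sg$I_R + sg$delta_G + q0)
  # when the antagonism source exceeds baseline inactivation the RhoA steady
  # state sits at the pool boundary (all active)
  crho0 <- if (sg$delta_G - q0 <= 0.02 * sg$I_rho)
    0.98 * sg$rho_tot / L
  else
    sg$I_rho * (sg$rho_tot / L) / (sg$I_rho + sg$delta_G - q0)
  memb <- list(A = numeric(nm), Bm = numeric(nm), R = cR0 * d,
               rho = crho0 * d, P3 = c_pi * d, P2 = c_pi * d,
               n3 = numeric(nm), nP = numeric(nm),
               E_p = numeric(nm), E_rho = numeric(nm), d = d)
  cyt <- list(Bc = 0, filgap_c = fc0,
              pi3k_free = round(sg$pi3k_conc * sg$n_per_uM),
              pten_free = round(sg$pten_conc * sg$n_per_uM))
  cross <- init_crosslinks(mesh, mo)
  state <- list(time = 0, mesh = mesh, geom = geom, memb = memb, cyt = cyt,
                cross = cross, env = config$env,
                v_mem = matrix(0, nm, 2), v_lam_node = matrix(0, nm, 2),
                prev_membrane = mesh$membrane, area_target = geom$area,
                source_placed = FALSE, recent = list(),
                rng = list(noise = rng_stream_new(derive_seed(config$master_seed, 0L)),
                           mc = rng_stream_new(derive_seed(config$master_seed, 1L))),
                counters = list(n_capped = 0L, n_contact = 0L))
  state
}

# polarity = direction of centroid motion over the trailing `horizon` seconds
current_polarity <- function(state, horizon = 60) {
  rec <- state$recent
  if (!length(rec)) return(c(1, 0))
  now <- state$geom$centroid
  t <- state$time
  old <- rec[[1]]$centroid
  for (r in rec) if (t - r$t <= horizon) { old <- r$centroid; break }
  v <- now - old
  n <- sqrt(sum(v^2))
  if (n < 1e-9) c(1, 0) else v / n
}

place_gradient_source <- function(state, config) {
  sch <- config$schedule
  pol <- current_polarity(state)
  dir <- rotate2(pol, sch$gradient_angle_deg)
  dist <- source_distance_for_gradient(sch$gradient_percent,
                                       config$mesh$diameter)
  pos <- state$geom$centroid + dir * dist
  core <- 1
  strength <- dist / core          # normalises C at the cell to 1
  src <- chemo_source(pos, onset = state$time, strength = strength,
                      core_radius = core)
  state$env$sources <- c(state$env$sources, list(src))
  state$source_placed <- TRUE
  state
}

#' One master step of the coupled model
#'
#' Order of operations: environment sampling, signalling (receptor layer ->
#' Rac/RhoA -> phosphoinositides), angular strain -> FilGAP release,
#' mechanics (passive + active + area/drag forces, membrane step, obstacle
#' projection), interior relaxation, retriangulation with crosslink carry
#' over, geometry refresh.  All module invariants hold on exit; any module
#' integrity error aborts the run.
#'
#' @param state simulation state from `init_state` or a previous step.
#' @param config a `sim_config`.
#' @return the advanced state.
#' @export
master_step <- function(state, config) {
  mech <- config$mechanics
  sg <- config$signaling
  mo <- config$mechano
  dt <- mech$dt_mech
  t <- state$time
  nm <- state$mesh$n_membrane

  # scheduled gradient release relative to the current polarity
  if (!is.null(config$schedule$gradient_percent) && !state$source_placed &&
      t >= (config$schedule$onset %||% 0))
    state <- place_gradient_source(state, config)

  # (1) environment sampling at membrane nodes
  S <- attractant_at(state$mesh$membrane, t, state$env)
  stimulus_on <- any(S > 0)

  # (2) signalling
  state$memb$d <- state$geom$node_lengths
  if (stimulus_on) {
    up <- gpcr_step(state$memb, state$cyt, S, sg, dt)
    state$memb <- up$state
    state$cyt <- up$cytosol
  }
  c3 <- state$memb$P3 / state$memb$d
  Q <- filgap_antagonism(state$cyt$filgap_c, c3, sg)
  if (sg$sigma_noise > 0) {
    sw <- with_stream(state, "noise", function() rnorm(nm, 0, sg$sigma_noise))
    state <- sw$state
    xi <- sw$value
  } else xi <- numeric(nm)
  state$memb <- rac_rho_step(state$memb, state$cyt, Q$Q_R, Q$Q_rho, sg, dt, xi)
  if (config$deterministic) {
    up <- pi_step(state$memb, state$cyt, sg, dt, mean_field = TRUE)
  } else {
    sw <- with_stream(state, "mc", function()
      pi_step(state$memb, state$cyt, sg, dt, mean_field = FALSE))
    state <- sw$state
    up <- sw$value
  }
  state$memb <- up$state
  state$cyt <- up$cytosol

  # (3) mechanosensing
  strains <- angle_strain(state$mesh)
  fg <- filgap_step(state$cross, state$cyt$filgap_c, strains, mo, dt)
  state$cross <- fg$crosslinks
  state$cyt$filgap_c <- fg$filgap_c
  state$fast_frac <- mean(classify_strain(strains, mo$beta1, mo$beta2))

  # (4) mechanics
  c3 <- state$memb$P3 / state$memb$d
  c2 <- state$memb$P2 / state$memb$d
  act <- active_forces(state$mesh, state$geom, c3, c2, mech)
  fd <- -mech$c_drag * (state$v_mem - state$v_lam_node)
  frep <- membrane_repulsion(state$mesh$membrane,
                             1.2 * state$mesh$rest_spacing, 4 * mech$k)
  external <- act$protrusive + act$contractile + fd + frep
  prev <- state$prev_membrane
  state$prev_membrane <- state$mesh$membrane
  st <- step_membrane(state$mesh, external, state$env, mech,
                      prev_positions = prev, area_target = state$area_target)
  state$mesh <- st$mesh
  state$v_mem <- st$velocity
  state$counters$n_capped <- state$counters$n_capped + st$n_capped
  state$counters$n_contact <- state$counters$n_contact + sum(st$contact)

  # (5) interior relaxation + lamellipod velocity estimate per membrane node
  prev_int <- state$mesh$interior
  state$mesh <- relax_interior(state$mesh)
  state$mesh <- confine_interior(state$mesh)
  v_int <- (state$mesh$interior - prev_int) / dt
  tri <- state$mesh$triangles
  a <- c(tri[, 1], tri[, 2], tri[, 3], tri[, 1], tri[, 2], tri[, 3])
  b <- c(tri[, 2], tri[, 3], tri[, 1], tri[, 3], tri[, 1], tri[, 2])
  sel <- a <= nm & b > nm
  if (any(sel)) {
    am <- a[sel]; bi <- b[sel] - nm
    cnt <- accumulate_by_index_cpp(nm, am, rep(1, length(am)))
    cnt[cnt == 0] <- 1
    state$v_lam_node <- cbind(accumulate_by_index_cpp(nm, am, v_int[bi, 1]),
                              accumulate_by_index_cpp(nm, am, v_int[bi, 2])) / cnt
  }

  # (6) retriangulate + carry crosslinks, refresh geometry
  state$step_count <- (state$step_count %||% 0L) + 1L
  if (state$step_count %% (config$remesh_every %||% 1L) == 0L) {
    state$mesh <- retriangulate(state$mesh)
    rb <- rebind_capacity(state$cross, state$mesh, state$cyt$filgap_c)
    state$cross <- rb$crosslinks
    state$cyt$filgap_c <- rb$filgap_c
  }
  state$geom <- compute_geometry(state$mesh)

  # (7) clock + trailing-centroid buffer for polarity estimates
  state$time <- t + dt
  state$recent <- c(state$recent, list(list(t = state$time,
                                            centroid = state$geom$centroid)))
  while (length(state$recent) && state$time - state$recent[[1]]$t > 90)
    state$recent <- state$recent[-1]
  state
}

#' Run a configured simulation
#'
#' Advances the coupled model to `t_end`, recording the centroid trajectory,
#' scalar series (cytosolic FilGAP, bound FilGAP, fast-mode fraction, area,
#' perimeter) every `record_every` steps and per-species kymographs every
#' `kymo_every` steps.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_output`: `times`, `centroid`, scalar
#'   series, `kymo` (list of node x time concentration matrices with
#'   `kymo_times` and `kymo_arc`), shape `snapshots`, the final `state`, and
#'   provenance (`config`, `master_seed`).
#' @export
run_simulation <- function(config) {
  # pin the session RNG too: library internals (e.g. degenerate-triangulation
  # retries) must not depend on ambient state
  set.seed(derive_seed(config$master_seed, 3L))
  state <- init_state(config)
  dt <- config$mechanics$dt_mech
  nstep <- as.integer(round(config$t_end / dt))
  rec_i <- seq(0L, nstep, by = config$record_every)
  nrec <- length(rec_i)
  kym_i <- seq(0L, nstep, by = config$kymo_every)
  nkym <- length(kym_i)
  nm <- config$mesh$n_membrane
  times <- numeric(nrec)
  centroid <- matrix(NA_real_, nrec, 2)
  filgap_c <- bound <- fastf <- area <- perim <- numeric(nrec)
  species <- c("PIP3", "PIP2", "Rac", "RhoA", "A", "Bm")
  kymo <- lapply(species, function(s) matrix(NA_real_, nm, nkym))
  names(kymo) <- species
  kymo_times <- numeric(nkym)
  kymo_arc <- matrix(NA_real_, nm, nkym)
  snapshots <- vector("list", nkym)
  ri <- ki <- 1L
  record <- function(step) {
    if (ri <= nrec && step == rec_i[ri]) {
      times[ri] <<- state$time
      centroid[ri, ] <<- state$geom$centroid
      filgap_c[ri] <<- state$cyt$filgap_c
      bound[ri] <<- sum(state$cross$m)
      fastf[ri] <<- state$fast_frac %||% 0
      area[ri] <<- state$geom$area
      perim[ri] <<- state$geom$perimeter
      ri <<- ri + 1L
    }
    if (ki <= nkym && step == kym_i[ki]) {
      d <- state$geom$node_lengths
      kymo$PIP3[, ki] <<- state$memb$P3 / d
      kymo$PIP2[, ki] <<- state$memb$P2 / d
      kymo$Rac[, ki] <<- state$memb$R / d
      kymo$RhoA[, ki] <<- state$memb$rho / d
      kymo$A[, ki] <<- state$memb$A / d
      kymo$Bm[, ki] <<- state$memb$Bm / d
      kymo_times[ki] <<- state$time
      kymo_arc[, ki] <<- cumsum(state$geom$node_lengths) -
        state$geom$node_lengths / 2
      snapshots[[ki]] <<- state$mesh$membrane
      ki <<- ki + 1L
    }
  }
  record(0L)
  for (step in seq_len(nstep)) {
    state <- tryCatch(master_step(state, config), error = function(e) {
      e$sim_state <- state
      stop(errorCondition(
        sprintf("run aborted at t = %.1f s (seed %d): %s",
                state$time, config$master_seed, conditionMessage(e)),
        class = "chemomech_abort", state = state))
    })
    record(step)
  }
  out <- list(times = times, centroid = centroid, filgap_c = filgap_c,
              bound_filgap = bound, fast_frac = fastf, area = area,
              perimeter = perim, kymo = kymo, kymo_times = kymo_times,
              kymo_arc = kymo_arc, snapshots = snapshots,
              snapshot_times = kymo_times, state = state, config = config,
              master_seed = config$master_seed,
              counters = state$counters)
  class(out) <- "sim_output"
  out
}

#' @export
print.sim_output <- function(x, ...) {
  disp <- sqrt(sum((x$centroid[nrow(x$centroid), ] - x$centroid[1, ])^2))
  cat(sprintf("<sim_output> %.0f s, net displacement %.2f um, FilGAP_c %.3f -> %.3f uM\n",
              max(x$times), disp, x$filgap_c[1], tail(x$filgap_c, 1)))
  invisible(x)
}

#' Run one of the study protocols
#'
#' Protocols: `random_migration` (spontaneous, stimulus-free, 900 s);
#' `gradient` (spontaneous until `onset = 500` s, then a point source giving
#' `percent` gradient across the cell at `angle_deg` to the established
#' polarity); `mutant_sweep` (gradient protocol across a vector of total
#' FilGAP or PI3K levels, aggregated over seeds); `obstacle_ring`
#' (spontaneous inside an obstacle ring, then a gradient from outside).
#'
#' @param protocol protocol name.
#' @param overrides named list of parameter overrides; names can address
#'   `mechanics`, `signaling`, `mechano` entries directly (e.g.
#'   `list(filgap_total = 0, pi3k_conc = 0.12)`), or `t_end`, `onset`,
#'   `percent`, `angle_deg`.
#' @param master_seed integer seed (one run), or a vector of seeds for
#'   `mutant_sweep`.
#' @param ... protocol-specific arguments: `percent`, `angle_deg`, `t_end`,
#'   `onset`; for `mutant_sweep` also `param` ("filgap" or "pi3k") and
#'   `values`; for `obstacle_ring` also `ring_radius`, `n_obstacles`,
#'   `obstacle_radius`.
#' @return a `sim_output` (single protocols) or a data frame of aggregated
#'   metrics (`mutant_sweep`).
#' @export
run_experiment <- function(protocol = c("random_migration", "gradient",
                                        "mutant_sweep", "obstacle_ring"),
                           overrides = list(), master_seed = 1L, ...) {
  protocol <- match.arg(protocol)
  dots <- list(...)
  build_cfg <- function(extra = list()) {
    ov <- utils::modifyList(as.list(overrides), extra)
    sg <- do.call(signaling_params,
                  ov[names(ov) %in% names(formals(signaling_params))])
    me <- do.call(mechanics_params,
                  ov[names(ov) %in% names(formals(mechanics_params))])
    mo <- do.call(mechano_params,
                  ov[names(ov) %in% names(formals(mechano_params))])
    list(sg = sg, me = me, mo = mo, ov = ov)
  }
  if (protocol == "random_migration") {
    pp <- build_cfg()
    cfg <- sim_config(t_end = pp$ov$t_end %||% dots$t_end %||% 900,
                      mechanics = pp$me, signaling = pp$sg, mechano = pp$mo,
                      master_seed = master_seed)
    return(run_simulation(cfg))
  }
  if (protocol == "gradient") {
    pp <- build_cfg()
    cfg <- sim_config(t_end = pp$ov$t_end %||% dots$t_end %||% 1500,
                      mechanics = pp$me, signaling = pp$sg, mechano = pp$mo,
                      onset = pp$ov$onset %||% dots$onset %||% 500,
                      gradient_percent = pp$ov$percent %||% dots$percent %||% 2,
                      gradient_angle_deg = pp$ov$angle_deg %||% dots$angle_deg %||% 90,
                      master_seed = master_seed)
    return(run_simulation(cfg))
  }
  if (protocol == "obstacle_ring") {
    pp <- build_cfg()
    ring <- obstacle_ring(ring_radius = dots$ring_radius %||% 20,
                          n = dots$n_obstacles %||% 6,
                          obstacle_radius = dots$obstacle_radius %||% 4)
    cfg <- sim_config(t_end = pp$ov$t_end %||% dots$t_end %||% 1500,
                      env = chemo_environment(obstacles = ring),
                      mechanics = pp$me, signaling = pp$sg, mechano = pp$mo,
                      onset = pp$ov$onset %||% dots$onset %||% 500,
                      gradient_percent = pp$ov$percent %||% dots$percent %||% 5,
                      gradient_angle_deg = pp$ov$angle_deg %||% dots$angle_deg %||% 0,
                      master_seed = master_seed)
    return(run_simulation(cfg))
  }
  # mutant_sweep
  param <- dots$param %||% "filgap"
  values <- dots$values %||% if (param == "filgap")
    c(0, 0.12, 0.4, 0.6, 1.2, 1.4) else c(0, 0.03, 0.06, 0.12)
  seeds <- if (length(master_seed) > 1) master_seed else seq_len(10) + master_seed
  res <- list()
  for (v in values) {
    ov <- as.list(overrides)
    if (param == "filgap") ov$filgap_total <- v else ov$pi3k_conc <- v
    for (sd in seeds) {
      out <- run_experiment("gradient", overrides = ov, master_seed = sd, ...)
      met <- late_stage_metrics(out)
      res[[length(res) + 1L]] <- data.frame(param = param, value = v,
                                            seed = sd,
                                            speed = met$speed,
                                            ci = met$ci)
    }
  }
  do.call(rbind, res)
}

#' Late-stage speed and chemotaxis index of a gradient run
#'
#' Mean boxcar-smoothed centroid speed and mean chemotaxis index over the
#' final `window_s` seconds of a run (the late chemotactic stage).
#'
#' @param out a `sim_output` from a gradient protocol.
#' @param window_s length of the terminal averaging window (s).
#' @return list with `speed` (um/min) and `ci`.
#' @export
late_stage_metrics <- function(out, window_s = 500) {
  v <- centroid_velocity(out$times, out$centroid)
  sel <- v$t >= max(out$times) - window_s
  speed <- mean(v$value[sel], na.rm = TRUE)
  ci <- NA_real_
  src <- active_source_position(out)
  if (!is.null(src)) {
    cis <- chemotaxis_index(out$times, out$centroid, src)
    sel <- cis$t >= max(out$times) - window_s
    ci <- mean(cis$value[sel], na.rm = TRUE)
  }
  list(speed = speed, ci = ci)
}

active_source_position <- function(out) {
  srcs <- out$state$env$sources
  if (!length(srcs)) return(NULL)
  srcs[[length(srcs)]]$position
}
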