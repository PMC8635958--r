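test_that("passive forces vanish at rest and obey Hooke's law", {
  m <- tiny_mesh(n_membrane = 16L)
  p <- mechanics_params()
  f <- membrane_passive_forces(m, m$membrane, p)
  expect_equal(max(abs(f$elastic)), 0, tolerance = 1e-12)
  expect_equal(max(abs(f$viscous)), 0, tolerance = 1e-12)

  # uniformly dilated static ring: inward forces, zero vector sum
  m2 <- m
  m2$membrane <- m$membrane * 1.1
  f2 <- membrane_passive_forces(m2, m2$membrane, p)
  g2 <- compute_geometry(m2)
  expect_true(all(rowSums(f2$elastic * g2$normals) < 0))
  expect_lt(max(abs(colSums(f2$elastic))), 1e-9)
  # Hooke magnitude: per-node restoring force of a regular n-gon ring
  n <- nrow(m$membrane)
  l0 <- m$rest_spacing
  delta <- 0.1 * l0
  expected <- 2 * p$k * delta * sin(pi / n)   # two edge tensions, bisected
  expect_equal(sqrt(rowSums(f2$elastic^2)), rep(expected, n),
               tolerance = 1e-9)
})

test_that("active forces follow the Hill response and its limits", {
  m <- tiny_mesh(n_membrane = 16L)
  g <- compute_geometry(m)
  p <- mechanics_params(f_pro_max = 1, f_cont_max = 0.5)
  z <- rep(0, 16)
  f0 <- active_forces(m, g, z, z, p)
  expect_equal(max(abs(f0$protrusive)), 0)
  expect_equal(max(abs(f0$contractile)), 0)

  # single node far above mean: protrusion saturates at f_pro_max
  hi <- z; hi[5] <- 1e9
  fh <- active_forces(m, g, hi, z, p)
  expect_equal(sqrt(sum(fh$protrusive[5, ]^2)), 1, tolerance = 1e-6)
  # Hill midpoint: c = c_half gives half-maximal force
  mid <- z; mid[3] <- p$c_half3
  fm <- active_forces(m, g, mid, z, p)
  expect_equal(sqrt(sum(fm$protrusive[3, ]^2)), 0.5, tolerance = 1e-9)
  expect_error(active_forces(m, g, z - 1, z, p), "negative")
})

test_that("area and drag forces are zero in equilibrium and linear in deficit", {
  m <- tiny_mesh(n_membrane = 16L)
  g <- compute_geometry(m)
  p <- mechanics_params(k_area = 0.1, c_drag = 0.3)
  v0 <- matrix(0, 16, 2)
  f <- area_drag_forces(m, g, v0, v0, p, area_target = g$area)
  expect_equal(max(abs(f$area)), 0, tolerance = 1e-12)
  expect_equal(max(abs(f$drag)), 0)

  # 10% deficit: net outward force, exact gradient telescopes to zero sum
  f2 <- area_drag_forces(m, g, v0, v0, p, area_target = g$area / 0.9)
  expect_true(all(rowSums(f2$area * g$normals) > 0))
  expect_lt(max(abs(colSums(f2$area))), 1e-12)

  # rigid translation: drag vanishes
  vt <- matrix(1, 16, 2)
  f3 <- area_drag_forces(m, g, vt, vt, p, area_target = g$area)
  expect_equal(max(abs(f3$drag)), 0)
})

test_that("membrane step obeys the overdamped law and relaxes a perturbed ring", {
  m <- tiny_mesh(n_membrane = 16L)
  p <- mechanics_params(mu = 2, dt_mech = 0.1)
  # zero force: stationary
  st <- step_membrane(m, matrix(0, 16, 2), NULL, p)
  expect_equal(st$mesh$membrane, m$membrane)
  # constant small force: displacement (F/mu) dt
  fx <- matrix(0, 16, 2); fx[, 1] <- 0.04
  st2 <- step_membrane(m, fx, NULL, p)
  expect_equal(st2$mesh$membrane[, 1] - m$membrane[, 1],
               rep(0.04 / 2 * 0.1, 16), tolerance = 1e-12)

  # perturbed unloaded ring relaxes: kinetic proxy decreases monotonically
  set.seed(1)
  m3 <- m
  m3$membrane <- m$membrane + matrix(rnorm(32, 0, 0.03), 16)
  g0 <- compute_geometry(m3)
  prev <- m3$membrane
  p2 <- mechanics_params(dt_mech = 0.5)
  energy <- numeric(100)
  for (i in 1:100) {
    st <- step_membrane(m3, matrix(0, 16, 2), NULL, p2,
                        prev_positions = prev, area_target = g0$area)
    prev <- m3$membrane
    m3 <- st$mesh
    energy[i] <- sum(st$velocity^2)
  }
  expect_lt(energy[100], 1e-7)
  late <- energy[20:100]
  expect_true(all(diff(late) <= 1e-12))
  per <- compute_geometry(m3)$perimeter
  expect_lt(abs(per - 16 * m$rest_spacing) / (16 * m$rest_spacing), 0.01)
})

test_that("interior relaxation solves the neighbour-mean system", {
  sq <- square_mesh()
  r <- relax_interior(sq)
  expect_equal(as.numeric(r$interior), c(0, 0), tolerance = 1e-8)

  # idempotence
  m <- tiny_mesh(n_membrane = 20L, n_interior = 25L, seed = 2L)
  m1 <- relax_interior(m)
  m2 <- relax_interior(m1)
  expect_lt(max(abs(m2$interior - m1$interior)), 1e-10)

  # affine equivariance: harmonicity is preserved under affine maps
  A <- matrix(c(1.3, 0.2, -0.1, 0.8), 2)
  b <- c(0.5, -0.2)
  ma <- m1
  ma$membrane <- sweep(m1$membrane %*% A, 2, b, "+")
  ma$interior <- sweep(m1$interior %*% A, 2, b, "+")
  ra <- relax_interior(ma)
  expect_lt(max(abs(ra$interior - ma$interior)), 1e-7)

  # Jacobi oracle on a small mesh
  mj <- tiny_mesh(n_membrane = 14L, n_interior = 10L, seed = 5L)
  mj$interior <- mj$interior + matrix(runif(20, -0.1, 0.1), 10)
  sol <- relax_interior(mj)
  pos <- rbind(mj$membrane, mj$interior)
  nm <- 14L
  edges <- unique(rbind(mj$triangles[, c(1, 2)], mj$triangles[, c(2, 3)],
                        mj$triangles[, c(1, 3)]))
  nbr <- lapply(seq_len(nrow(pos)), function(i)
    sort(unique(c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))))
  jac <- pos
  for (it in 1:1000) {
    nxt <- jac
    for (i in (nm + 1):nrow(pos))
      nxt[i, ] <- colMeans(jac[nbr[[i]], , drop = FALSE])
    jac <- nxt
  }
  expect_lt(max(abs(jac[(nm + 1):nrow(pos), ] - sol$interior)), 1e-6)
})

test_that("membrane self-repulsion is pairwise balanced and short-ranged", {
  mem <- rbind(c(0, 0), c(1, 0), c(0.1, 0.05), c(1, 1), c(0, 1))
  f <- membrane_repulsion(mem, r_rep = 0.3, k_rep = 2)
  expect_gt(max(abs(f)), 0)            # nodes 1 and 3 interact
  expect_lt(max(abs(colSums(f))), 1e-12)
  far <- membrane_repulsion(mem * 10, r_rep = 0.3, k_rep = 2)
  expect_equal(max(abs(far)), 0)
})
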