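test_that("periodic diffusion conserves mass, damps the cosine mode, and respects the maximum principle", {
  n <- 32
  d <- rep(0.5, n)
  L <- sum(d)
  # uniform field unchanged
  u <- rep(2, n) * d
  expect_equal(diffuse_periodic_1d(u, d, D = 0.1, dt = 1), u, tolerance = 1e-14)

  # cosine eigenmode decay vs the continuum closed form
  s <- (cumsum(d) - d / 2)
  conc <- 1 + 0.5 * cos(2 * pi * s / L)
  a <- conc * d
  D <- 0.05; dt <- 0.1
  for (i in 1:100) a <- diffuse_periodic_1d(a, d, D, dt)
  amp <- (max(a / d) - min(a / d)) / 2
  expect_equal(amp, 0.5 * exp(-D * (2 * pi / L)^2 * 10), tolerance = 0.01)

  # delta spike: exact mass conservation, monotone max
  a2 <- numeric(n); a2[7] <- 5
  mx <- max(a2 / d)
  for (i in 1:50) {
    a2 <- diffuse_periodic_1d(a2, d, D = 0.2, dt = 0.5)
    expect_lte(max(a2 / d), mx + 1e-12)
    mx <- max(a2 / d)
  }
  expect_equal(sum(a2), 5, tolerance = 1e-12)
  expect_error(diffuse_periodic_1d(a2, d * 0, 0.1, 0.1), "segment")
})

test_that("receptor layer localises activator up-gradient and inhibitor down-gradient", {
  n <- 8
  d <- rep(1, n)
  prm <- signaling_params(D_m = 0.02)
  st <- list(A = numeric(n), Bm = numeric(n), d = d)
  cy <- list(Bc = 0)
  S <- 1 + 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)   # max at node 1

  # S = 0 keeps everything at zero
  z <- gpcr_step(st, cy, rep(0, n), prm, 1)
  expect_equal(max(abs(z$state$A)), 0)
  expect_equal(z$cytosol$Bc, 0)

  # uniform S: uniform fields, zero front-back difference
  for (i in 1:400) {
    u <- gpcr_step(st, cy, rep(1, n), prm, 0.5)
    st <- u$state; cy <- u$cytosol
  }
  expect_lt(diff(range(st$A)), 1e-12)

  # graded S: A maximal up-gradient, Bm maximal at the antipode
  st <- list(A = numeric(n), Bm = numeric(n), d = d)
  cy <- list(Bc = 0)
  for (i in 1:2000) {
    u <- gpcr_step(st, cy, S, prm, 0.5)
    st <- u$state; cy <- u$cytosol
  }
  expect_equal(which.max(st$A), 1L)
  expect_equal(which.max(st$Bm), 5L)

  # small-N steady state against a dense ODE oracle
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, p) {
    A <- y[1:n]; Bm <- y[(n + 1):(2 * n)]; Bc <- y[2 * n + 1]
    nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
    lap <- function(x) prm$D_m * (x[nxt] - 2 * x + x[prv])  # d = 1
    dA <- lap(A) + prm$k_s * S - prm$k_deg * A - prm$k_ann * A * Bm
    dBm <- lap(Bm) + prm$k_onB * Bc - prm$k_deg * Bm - prm$k_ann * A * Bm
    dBc <- prm$k_s * mean(S) * n / n - prm$k_onB * Bc
    list(c(dA, dBm, dBc))
  }
  sol <- deSolve::ode(c(numeric(2 * n), 0), c(0, 1000), rhs, NULL,
                      rtol = 1e-10, atol = 1e-12, maxsteps = 1e5)
  ode_A <- sol[2, 2:(n + 1)]
  expect_equal(unname(st$A), unname(ode_A), tolerance = 0.005)
})

test_that("FilGAP antagonism matches the ultrasensitive switch algebra", {
  prm <- signaling_params(A_G = 7, b = 12)
  q0 <- filgap_antagonism(0, rep(0, 4), prm)
  expect_equal(q0$Q_R, rep(-1 / (1 + 7), 4))
  qi <- filgap_antagonism(50, rep(50, 4), prm)
  expect_equal(qi$Q_R, rep(-1, 4), tolerance = 1e-12)
  set.seed(3)
  p3 <- runif(16, 0, 5)
  q <- filgap_antagonism(0.37, p3, prm)
  expect_identical(q$Q_R + q$Q_rho, rep(0, 16))
  expect_true(all(q$Q_R > -1 & q$Q_R < 0))
})

test_that("Rac/RhoA layer conserves totals, keeps positivity, and matches an ODE oracle", {
  n <- 8
  d <- rep(1.2, n)
  prm <- signaling_params(sigma_noise = 0, R_tot = 20, rho_tot = 20,
                          D_m = 0.03)
  Ep <- c(0.4, 0.3, 0.1, 0, 0, 0, 0.1, 0.2)
  st <- list(R = rep(0.5, n) * d, rho = rep(0.5, n) * d,
             E_p = Ep, E_rho = rev(Ep), d = d)
  QR <- -0.2 - 0.1 * cos(2 * pi * (1:n) / n)
  # uniform init, uniform drivers: stays uniform
  stu <- st; stu$E_p <- rep(0.2, n); stu$E_rho <- rep(0.2, n)
  r1 <- rac_rho_step(stu, list(), rep(-0.3, n), rep(0.3, n), prm, 5)
  expect_lt(diff(range(r1$R)), 1e-12)
  expect_lt(diff(range(r1$rho)), 1e-12)

  # ODE oracle with fixed Q and E fields
  skip_if_not_installed("deSolve")
  L <- sum(d)
  rhs <- function(t, y, p) {
    R <- y[1:n]; rho <- y[(n + 1):(2 * n)]
    nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
    lap <- function(a) {
      conc <- a / d
      h <- (d + d[nxt]) / 2
      flux <- prm$D_m * (conc[nxt] - conc) / h
      flux - flux[prv]
    }
    Rc <- (prm$R_tot - sum(R)) / L
    rc <- (prm$rho_tot - sum(rho)) / L
    pfr <- min(max(rc / (prm$rho_tot / L), 0), 1)   # source availability gate
    dR <- lap(R) + d * (prm$I_R + prm$alpha * Ep) * max(Rc, 0) -
      prm$delta_G * R + QR * R
    drho <- lap(rho) + d * (prm$I_rho + prm$tau * rev(Ep)) * max(rc, 0) -
      prm$delta_G * rho - QR * rho * pfr
    list(c(dR, drho))
  }
  y0 <- c(st$R, st$rho)
  sol <- deSolve::ode(y0, seq(0, 1, by = 0.5), rhs, NULL,
                      rtol = 1e-12, atol = 1e-14)
  mine <- st
  nstep <- 1000
  for (i in seq_len(nstep))
    mine <- rac_rho_step(mine, list(), QR, -QR, prm, 1 / nstep)
  expect_equal(mine$R, unname(sol[3, 2:(n + 1)]), tolerance = 1e-6)
  expect_equal(mine$rho, unname(sol[3, (n + 2):(2 * n + 1)]), tolerance = 1e-6)

  # conservation with delta_G = 0, Q = 0: active pool approaches the total
  prm2 <- signaling_params(sigma_noise = 0, R_tot = 10, rho_tot = 10,
                           delta_G = 0, D_m = 0)
  st2 <- list(R = rep(0.1, n), rho = rep(0.1, n),
              E_p = numeric(n), E_rho = numeric(n), d = d)
  for (i in 1:600) st2 <- rac_rho_step(st2, list(), numeric(n), numeric(n),
                                       prm2, 0.5)
  expect_equal(sum(st2$R), 10, tolerance = 1e-6)
  expect_true(all(st2$R >= 0))
})

test_that("PI layer conserves lipid totals and enzyme counts; mirror patterns emerge", {
  n <- 10
  d <- rep(0.8, n)
  prm <- signaling_params(PI_tot = 16, k_cat3 = 0.2, k_cat2 = 0.2,
                          k_on = 0.4, k_off = 0.05)
  mk <- function() list(P3 = rep(1, n) * d, P2 = rep(1, n) * d,
                        n3 = numeric(n), nP = numeric(n),
                        R = rep(1, n) * d, rho = rep(1, n) * d, d = d)
  cy <- list(pi3k_free = 40, pten_free = 40)

  # no enzymes bound, k_on = 0: pure diffusion conserves totals
  prm0 <- signaling_params(k_on = 0, PI_tot = 16)
  st <- mk()
  st$P3 <- c(rep(2, 5), rep(0.5, 5)) * d
  tot0 <- sum(st$P3 + st$P2)
  up <- pi_step(st, list(pi3k_free = 0, pten_free = 0), prm0, 5)
  expect_equal(sum(up$state$P3 + up$state$P2), tot0, tolerance = 1e-12)

  # k_cat2 = 0, all PI3K at one node: local PIP2 -> PIP3 conversion
  prm1 <- signaling_params(k_on = 0, k_off = 0, k_cat2 = 0, k_cat3 = 0.5,
                           D_m = 0)
  st <- mk()
  st$n3[4] <- 10
  for (i in 1:40) {
    up <- pi_step(st, cy, prm1, 1)
    st <- up$state
  }
  expect_lt(st$P2[4], 1e-8)
  expect_equal(st$P3[4], 2 * d[4], tolerance = 1e-6)

  # stochastic mode: integer enzyme bookkeeping is exact
  set.seed(99)
  st <- mk()
  cnt0 <- 40 + sum(st$n3)
  for (i in 1:50) {
    up <- pi_step(st, cy, prm, 0.5)
    st <- up$state; cy <- up$cytosol
    expect_equal(sum(st$n3) + cy$pi3k_free, cnt0)
    expect_true(all(st$P3 >= 0) && all(st$P2 >= 0))
  }
  expect_equal(sum(st$P3 + st$P2), 16, tolerance = 1e-9)

  # PIP2 pattern mirrors PIP3 (high-PIP3 nodes are low-PIP2 nodes)
  expect_lt(cor(st$P3, st$P2), 0)
})

test_that("mean-field translocation matches the Monte-Carlo average", {
  n <- 6
  d <- rep(1, n)
  prm <- signaling_params(k_on = 0.3, k_off = 0, w_R3 = 1, bind_coop = 2)
  st <- list(P3 = c(3, 2, 1, 1, 0.5, 0.5), P2 = rep(1, n),
             n3 = numeric(n), nP = numeric(n),
             R = rep(1, n), rho = rep(1, n), d = d)
  prm$k_cat3 <- 0; prm$k_cat2 <- 0
  mf <- pi_step(st, list(pi3k_free = 100, pten_free = 0), prm, 0.5,
                mean_field = TRUE)
  set.seed(11)
  acc <- numeric(n)
  nrep <- 3000
  for (r in seq_len(nrep)) {
    up <- pi_step(st, list(pi3k_free = 100, pten_free = 0), prm, 0.5)
    acc <- acc + up$state$n3
  }
  mc_mean <- acc / nrep
  se <- sqrt(pmax(mf$state$n3, 1e-9) / nrep)   # Poisson-scale standard error
  expect_true(all(abs(mc_mean - mf$state$n3) < 3 * se + 0.02))
})
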