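test_that("identical config and seed give bit-identical runs", {
  cfg <- fast_config(t_end = 15, master_seed = 42L)
  o1 <- run_simulation(cfg)
  o2 <- run_simulation(cfg)
  expect_identical(o1$centroid, o2$centroid)
  expect_identical(o1$filgap_c, o2$filgap_c)
  expect_identical(o1$kymo$PIP3, o2$kymo$PIP3)
  o3 <- run_simulation(fast_config(t_end = 15, master_seed = 43L))
  expect_false(identical(o3$centroid, o1$centroid))
})

test_that("zero-noise deterministic runs preserve full symmetry", {
  cfg <- fast_config(t_end = 20, master_seed = 1L,
                     signaling = signaling_params(sigma_noise = 0),
                     deterministic = TRUE)
  out <- run_simulation(cfg)
  drift <- sqrt(rowSums((out$centroid -
                         matrix(out$centroid[1, ], nrow(out$centroid), 2,
                                byrow = TRUE))^2))
  expect_lt(max(drift), 1e-9)
  for (sp in c("PIP3", "PIP2", "Rac", "RhoA")) {
    k <- out$kymo[[sp]]
    expect_lt(max(apply(k, 2, function(x) diff(range(x)))), 1e-12)
  }
})

test_that("conserved totals hold over a coupled run with moving membrane", {
  cfg <- fast_config(t_end = 40, master_seed = 5L)
  out <- run_simulation(cfg)
  st <- out$state
  sg <- cfg$signaling
  # lipid pool: closed, equal to its initial total for the whole run
  expect_equal(sum(st$memb$P3 + st$memb$P2), sg$PI_tot, tolerance = 1e-9)
  # enzyme counts are integers and conserved
  expect_equal(sum(st$memb$n3) + st$cyt$pi3k_free,
               round(sg$pi3k_conc * sg$n_per_uM))
  expect_equal(sum(st$memb$nP) + st$cyt$pten_free,
               round(sg$pten_conc * sg$n_per_uM))
  # FilGAP budget
  expect_equal(sum(st$cross$m) + st$cyt$filgap_c,
               cfg$mechano$filgap_total, tolerance = 1e-9)
  # Rac/RhoA active amounts never exceed their totals
  expect_lte(sum(st$memb$R), sg$R_tot)
  expect_lte(sum(st$memb$rho), sg$rho_tot)
  expect_true(all(st$memb$R >= 0) && all(st$memb$rho >= 0))
})

test_that("configuration serialises losslessly through JSON", {
  cfg <- sim_config(t_end = 123, gradient_percent = 2.5, onset = 45,
                    gradient_angle_deg = 180,
                    mechanics = mechanics_params(f_pro_max = 0.77),
                    signaling = signaling_params(b = 41),
                    mechano = mechano_params(k_fast = 0.11),
                    env = chemo_environment(
                      sources = list(chemo_source(c(3, 4), onset = 7)),
                      obstacles = data.frame(x = 1, y = 2, r = 3)),
                    master_seed = 9L)
  js <- config_to_json(cfg)
  cfg2 <- config_from_json(js)
  expect_equal(cfg2$t_end, 123)
  expect_equal(cfg2$mechanics$f_pro_max, 0.77)
  expect_equal(cfg2$signaling$b, 41)
  expect_equal(cfg2$mechano$k_fast, 0.11)
  expect_equal(cfg2$schedule$gradient_percent, 2.5)
  expect_equal(cfg2$env$sources[[1]]$position, c(3, 4))
  expect_equal(cfg2$env$obstacles$r, 3)
  expect_equal(cfg2$master_seed, 9L)
})

test_that("gradient protocol places the source at onset with the requested strength", {
  out <- run_experiment("gradient", master_seed = 3L,
                        overrides = list(t_end = 80, onset = 40, percent = 5),
                        angle_deg = 90)
  srcs <- out$state$env$sources
  expect_equal(length(srcs), 1L)
  expect_equal(srcs[[1]]$onset, 40)
  d <- sqrt(sum((srcs[[1]]$position - out$centroid[81, ])^2))
  expect_equal(d, source_distance_for_gradient(5, 10), tolerance = 2)
  # stimulus normalised to ~1 at the cell at placement
  conc <- attractant_at(matrix(out$centroid[81, ], 1), 80, out$state$env)
  expect_equal(conc, 1, tolerance = 0.1)
})

test_that("obstacle contact keeps membrane outside and raises local corner strain", {
  # head-on collision scenario: a cell pressed against a wall-like obstacle
  ob <- data.frame(x = 7.5, y = 0, r = 2)
  cfg <- fast_config(t_end = 25, master_seed = 2L,
                     env = chemo_environment(obstacles = ob))
  state <- chemomech:::init_state(cfg)
  # drive the membrane toward the obstacle with a rightward bias
  push <- matrix(0, 24, 2)
  push[, 1] <- 0.3
  for (i in seq_len(40)) {
    st <- step_membrane(state$mesh, push, state$env, cfg$mechanics,
                        prev_positions = state$prev_membrane,
                        area_target = state$area_target)
    state$prev_membrane <- state$mesh$membrane
    state$mesh <- st$mesh
    state$mesh <- relax_interior(state$mesh)
    state$mesh <- retriangulate(state$mesh)
  }
  pos <- state$mesh$membrane
  dist_ob <- sqrt((pos[, 1] - 7.5)^2 + pos[, 2]^2)
  expect_true(all(dist_ob >= 2 - 1e-6))
  contact <- dist_ob <= 2 + 0.2
  expect_gt(sum(contact), 0)
  s <- abs(angle_strain(state$mesh))
  tri <- state$mesh$triangles
  cn <- which(contact)
  touch <- (tri[, 1] %in% cn) | (tri[, 2] %in% cn) | (tri[, 3] %in% cn)
  expect_gt(mean(s[touch, ]), mean(s[!touch, ]))
})

test_that("late-stage metrics and output writing work end to end", {
  out <- run_experiment("gradient", master_seed = 1L,
                        overrides = list(t_end = 60, onset = 30, percent = 5))
  met <- late_stage_metrics(out, window_s = 20)
  expect_true(is.finite(met$speed) && met$speed >= 0)
  expect_true(is.na(met$ci) || (met$ci >= -1 && met$ci <= 1))
  dir <- file.path(tempdir(), "chemomech-out")
  write_sim_output(out, dir)
  expect_true(all(file.exists(file.path(dir,
    c("trajectory.csv", "scalars.csv", "kymo_PIP3.csv", "kymo_meta.json",
      "snapshots.csv", "config.json", "provenance.json")))))
  tr <- read.csv(file.path(dir, "trajectory.csv"))
  expect_equal(nrow(tr), length(out$times))
  unlink(dir, recursive = TRUE)
})
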