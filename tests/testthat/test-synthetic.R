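# Agent-based trajectory generators.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_bats = 0), "n_bats")
  expect_error(sim_config(t_d = 6000, t_s = 5400), "t_d")
  expect_error(sim_config(step = 500, D = 100, R0 = 2000), "under-resolved")
  expect_error(sim_config(mechanism = "pull", chi_c = -1e-5), "chi_c")
  expect_error(detection_model(failure_prob = 1.5), "failure_prob")
  # default gamma interval distribution has its mode inside [0, 400] s
  dm <- detection_model()
  expect_gte(max(0, (dm$shape - 1) * dm$scale), 0)
  expect_lte(max(0, (dm$shape - 1) * dm$scale), 400)
})

test_that("zero diffusion keeps all walkers at the roost", {
  cfg <- sim_config(n_bats = 4, night_length = 600, step = 10, D = 0,
                    t_s = 500, t_d = 0, seed = 5)
  tr <- simulate_dispersal_walkers(cfg)
  expect_true(all(tr$x == 0 & tr$y == 0))
})

test_that("dispersal walkers reproduce free diffusion and respect the boundary", {
  # 20 seeded replicates of 500 walkers; ensemble MSD at t = 1000 s vs 4Dt
  n_rep <- 20
  d2_end <- numeric(0)
  slopes <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_bats = 500, night_length = 1000, step = 1, D = 100,
                      R0 = 2000, t_s = 999, t_d = 0, record_every = 100,
                      seed = 100 + r)
    tr <- simulate_dispersal_walkers(cfg)
    expect_lte(max(sqrt(tr$x^2 + tr$y^2)), 2000 + 1e-9)
    msd_t <- tapply(tr$x^2 + tr$y^2, tr$t, mean)
    tt <- as.numeric(names(msd_t))
    slopes[r] <- unname(coef(lm(msd_t ~ tt))[2])
    d2_end <- c(d2_end, tr$x[tr$t == 1000]^2 + tr$y[tr$t == 1000]^2)
  }
  # within 3 standard errors of 4Dt at t = 1000 s
  se <- sd(d2_end) / sqrt(length(d2_end))
  expect_lt(abs(mean(d2_end) - 4 * 100 * 1000), 3 * se)
  # diffusive calibration: mean slope estimates 4D within 10%
  expect_lt(abs(mean(slopes) / (4 * 100) - 1), 0.10)
})

test_that("departure delay holds walkers at the roost until t_d", {
  cfg <- sim_config(n_bats = 10, night_length = 2000, step = 10, D = 100,
                    t_s = 1500, t_d = 700, seed = 2)
  tr <- simulate_dispersal_walkers(cfg)
  expect_true(all(tr$x[tr$t <= 700] == 0))
  expect_true(any(tr$x[tr$t > 800] != 0))
})

test_that("per-bat streams are stable when n_bats grows", {
  cfg5 <- sim_config(n_bats = 5, night_length = 500, step = 5, t_s = 400,
                     t_d = 0, seed = 9)
  cfg8 <- sim_config(n_bats = 8, night_length = 500, step = 5, t_s = 400,
                     t_d = 0, seed = 9)
  t5 <- simulate_dispersal_walkers(cfg5)
  t8 <- simulate_dispersal_walkers(cfg8)
  expect_identical(t5[t5$bat_id <= 5, ], t8[t8$bat_id <= 5, ])
})

test_that("simulations are deterministic given config and seed", {
  cfg <- sim_config(n_bats = 6, step = 4, mechanism = "leapfrog", seed = 21,
                    record_every = 400)
  expect_identical(simulate_leapfrog_night(cfg), simulate_leapfrog_night(cfg))
})

test_that("single-bat leap frog is pure inward convection after t_s", {
  # the lone bat convects from its radius at t_s to the roost at speed c
  cfg <- suppressWarnings(
    sim_config(n_bats = 1, night_length = 28800, step = 4, D = 100,
               R0 = 2000, t_s = 5400, t_d = 0, mechanism = "leapfrog",
               leapfrog_speed = 0.15, seed = 33, record_every = 4,
               condition_on_return = FALSE))
  expect_warning(tr <- simulate_leapfrog_night(cfg), "n_bats = 1")
  r <- sqrt(tr$x^2 + tr$y^2)
  r0 <- r[tr$t == 5400]
  arrival_pred <- 5400 + (r0 - cfg$capture_radius) / 0.15
  arrival_obs <- min(tr$t[tr$t > 5400 & r <= cfg$capture_radius])
  expect_lt(abs(arrival_obs - arrival_pred), 2 * cfg$step)
})

test_that("leap-frog envelope is non-increasing and the night ends home", {
  cfg <- sim_config(n_bats = 20, step = 4, D = 100, R0 = 2000,
                    mechanism = "leapfrog", seed = 7, record_every = 400,
                    condition_on_return = FALSE)
  tr <- simulate_leapfrog_night(cfg)
  r <- sqrt(tr$x^2 + tr$y^2)
  expect_lte(max(r), 2000 + 1e-9)
  env <- tapply(r, tr$t, max)
  tt <- as.numeric(names(env))
  env2 <- env[tt >= 5400]
  expect_true(all(diff(env2) <= 1e-9))
  # default speed empties the domain by dawn
  expect_true(all(r[tr$t == 28800] == 0))
})

test_that("leap-frog ensemble MSD is convex in phase 2 and collapses by dawn", {
  # envelope schedule tracking R0^2 (1 - ((t-t_s)/(8h-t_s))^2)
  pr <- parabolic_radius(2000, 5400, 28800, t_max = 28400)
  agg <- 0
  n_rep <- 10
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_bats = 25, step = 4, D = 100, R0 = 2000,
                      mechanism = "leapfrog", R_t = pr$R, seed = 40 + r,
                      record_every = 800)
    tr <- simulate_leapfrog_night(cfg)
    agg <- agg + tapply(tr$x^2 + tr$y^2, tr$t, mean) / n_rep
  }
  tt <- as.numeric(names(agg))
  peak <- max(agg)
  # convex return: MSD holds near its peak well after t_s before collapsing
  expect_gt(agg[tt == 10400], 0.8 * peak)
  expect_lt(agg[tt == 28800] / peak, 0.05)
})

test_that("pull mechanism degenerates to dispersal when chi_c = 0, t_c = Inf", {
  base <- list(n_bats = 8, night_length = 3000, step = 5, D = 100,
               R0 = 2000, t_s = 1500, t_d = 0, seed = 12,
               capture_radius = 0, condition_on_return = FALSE)
  cfg_p <- do.call(sim_config, c(base, list(mechanism = "pull",
                                            D_c = 100, t_c = Inf, chi_c = 0)))
  cfg_d <- do.call(sim_config, c(base, list(mechanism = "dispersal_only")))
  tp <- simulate_pull_night(cfg_p)
  td <- simulate_dispersal_walkers(cfg_d)
  expect_equal(tp$x, td$x, tolerance = 1e-12)
  expect_equal(tp$y, td$y, tolerance = 1e-12)
})

test_that("pull walkers agree with their Fokker-Planck description", {
  # ensemble MSD of the agent-based pull night vs the non-autonomous PDE
  # solved with the same coefficients (independent discretisations)
  cfg <- sim_config(n_bats = 3000, step = 4, mechanism = "pull",
                    D_c = 100, t_c = 8.23 * 3600, chi_c = 0.83e-5,
                    t_d = 0, seed = 99, capture_radius = 0,
                    condition_on_return = FALSE, record_every = 3600)
  tr <- simulate_pull_night(cfg)
  msd_abm <- tapply(tr$x^2 + tr$y^2, tr$t, mean)
  tt <- as.numeric(names(msd_abm))
  tt <- tt[tt > 0]
  s <- solve_nonautonomous(100, 8.23 * 3600, 0.83e-5, t_s = 5400, R = 2000,
                           t_out = tt, n_cells = 200)
  msd_pde <- density_msd(s)$msd
  # compare where the MSD is not collapsing to zero (relative error there
  # is dominated by Monte-Carlo noise on a vanishing quantity)
  sel <- msd_pde > 1e5
  expect_lt(max(abs(msd_abm[as.character(tt)][sel] / msd_pde[sel] - 1)), 0.08)
})

test_that("pull ensemble MSD is concave-decreasing after ~2 h at fitted values", {
  agg <- 0
  n_rep <- 5
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_bats = 100, step = 4, mechanism = "pull",
                      D_c = 100, t_c = 8.23 * 3600, chi_c = 0.83e-5,
                      seed = 300 + r, record_every = 1800)
    tr <- simulate_pull_night(cfg)
    agg <- agg + tapply(tr$x^2 + tr$y^2, tr$t, mean) / n_rep
  }
  tt <- as.numeric(names(agg))
  late <- agg[tt >= 7200]
  expect_true(all(diff(late) < 0))
  expect_lt(agg[tt == 28800], 0.02 * max(agg))
})

test_that("detection sampling counts, retention and mode behave", {
  cfg <- sim_config(n_bats = 1, night_length = 28800, step = 400, D = 100,
                    t_d = 0, seed = 3, record_every = 400)
  tr <- simulate_dispersal_walkers(cfg)
  # deterministic 200 s interval on an 8 h track: 1 + floor(28800/200) fixes
  det <- sample_detections(tr, detection_model(family = "constant",
                                               interval = 200))
  expect_equal(nrow(det), 145L)
  # failure probability 1 keeps only the roost record
  det0 <- sample_detections(tr, detection_model(failure_prob = 1))
  expect_equal(det0$t, 0)
  # default gamma intervals: modal 400 s bin within [0, 400] s
  cfg2 <- sim_config(n_bats = 120, night_length = 28800, step = 400, D = 100,
                     t_d = 0, seed = 4, record_every = 400)
  tracks2 <- simulate_dispersal_walkers(cfg2)
  det2 <- sample_detections(tracks2, detection_model(seed = 8))
  iv <- unlist(lapply(split(det2$t, det2$bat_id), diff))
  expect_gte(length(iv), 1000)
  hist_counts <- table(cut(iv, breaks = seq(0, max(iv) + 400, by = 400)))
  expect_equal(unname(which.max(hist_counts)), 1L)
  # positions are read off the track: detections at recorded times match
  sub <- det2[det2$t %% 400 == 0 & det2$bat_id == 1, ]
  tr1 <- tracks2[tracks2$bat_id == 1, ]
  expect_equal(sub$x, tr1$x[match(sub$t, tr1$t)])
})
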