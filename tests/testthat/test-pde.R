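# Radial finite-volume solvers, moments and steady states.

test_that("radial grids have exact geometry and a resolution guard", {
  g <- build_radial_grid(2000, 400)
  expect_equal(g$h, 5)
  expect_equal(g$areas[1], pi * 5^2)
  expect_equal(sum(g$areas), pi * 2000^2)
  expect_equal(sum(g$m2), pi / 2 * 2000^4)
  expect_error(build_radial_grid(2000, 10), "n_cells")
})

test_that("bounded diffusion matches its short- and long-time laws", {
  t_out <- c(100, 2000, 20000, 30000)
  s <- solve_diffusion(100, 2000, t_out)
  m <- density_msd(s)$msd
  expect_equal(total_mass(s), rep(1, 4), tolerance = 1e-8)
  expect_lt(abs(m[1] / msd_short_time(100, 100) - 1), 0.02)
  expect_lt(abs(m[4] / msd_uniform_limit(2000) - 1), 0.01)
  # long-time density uniform at 1/(pi R^2) within 1%
  unif <- 1 / (pi * 2000^2)
  expect_lt(max(abs(s$phi[, 4] / unif - 1)), 0.01)
  # delta initial condition: MSD at t -> 0 below a cell width squared
  s0 <- solve_diffusion(100, 2000, 1e-6)
  expect_lt(density_msd(s0)$msd, 5^2)
})

test_that("solver failure and argument guards raise errors", {
  expect_error(solve_diffusion(-1, 2000, 100), "positive")
  expect_error(solve_nonautonomous(100, -5, 1e-5, t_out = 100), "t_c")
  expect_error(convection_spec("uniform", chi = -1), "chi")
  expect_error(msd_bounded(100, 2000, c(0, 1), c(0, -1)), "non-negative")
})

test_that("moment identity from the boundary trace matches the quadrature MSD", {
  tt <- seq(200, 30000, by = 200)
  s <- solve_diffusion(100, 2000, tt)
  mb <- msd_bounded(100, 2000, c(0, tt), c(0, boundary_density(s)))[-1]
  md <- density_msd(s)$msd
  expect_lt(max(abs(mb / md - 1)), 0.02)
  # trivial reductions
  expect_equal(msd_bounded(100, 2000, c(0, 10, 20), rep(0, 3)),
               4 * 100 * c(0, 10, 20))
  unif <- rep(1 / (pi * 2000^2), 3)
  expect_equal(msd_bounded(100, 2000, c(0, 10, 20), unif), rep(0, 3),
               tolerance = 1e-12)
})

test_that("zero convection degenerates to plain diffusion", {
  g <- build_radial_grid(2000, 200)
  t_out <- c(1000, 10000)
  s0 <- solve_diffusion(100, 2000, t_out, grid = g)
  s1 <- solve_convection_diffusion(100, convection_spec("uniform", chi = 0),
                                   2000, t_out, grid = g)
  expect_lt(max(abs(s1$phi - s0$phi)), 1e-10 * max(s0$phi))
})

test_that("inward convection gives a concave MSD decaying to its steady state", {
  cv <- convection_spec("uniform", chi = 1, t_s = 5400)
  tt <- c(5400, 6000, 7000, 9000, 12000, 20000)
  s <- solve_convection_diffusion(100, cv, 2000, tt, n_cells = 200)
  m <- density_msd(s)$msd
  expect_true(all(diff(m) < 0))          # decreasing once drift is on
  expect_true(all(diff(diff(m)) > 0))    # concave toward the plateau
  ss <- steady_state_msd(100, cv, 2000)
  expect_gt(ss, 0)
  expect_lt(abs(m[length(m)] / ss - 1), 0.01)
  expect_equal(total_mass(s), rep(1, length(tt)), tolerance = 1e-8)
})

test_that("steady-state profile and MSD follow the quadrature forms", {
  # chi = 0: uniform profile, MSD = R^2/2
  cv0 <- convection_spec("uniform", chi = 0)
  expect_equal(steady_state_msd(100, cv0, 2000), 2000^2 / 2, tolerance = 1e-8)
  prof <- steady_state_density(100, cv0, 2000)
  expect_equal(prof$phi, rep(1 / (pi * 2000^2), nrow(prof)), tolerance = 1e-8)
  # monotone: stronger pull concentrates mass; faster diffusion spreads it
  cv1 <- convection_spec("uniform", chi = 1)
  cv2 <- convection_spec("uniform", chi = 2)
  expect_lt(steady_state_msd(100, cv2, 2000), steady_state_msd(100, cv1, 2000))
  expect_gt(steady_state_msd(200, cv1, 2000), steady_state_msd(100, cv1, 2000))
})

test_that("the non-autonomous solver reduces to diffusion and matches its narrative", {
  g <- build_radial_grid(2000, 200)
  t_out <- c(1000, 5000, 20000)
  s0 <- solve_diffusion(100, 2000, t_out, grid = g)
  s1 <- solve_nonautonomous(100, 1e300, 0, t_s = 5400, R = 2000,
                            t_out = t_out, grid = g)
  expect_lt(max(abs(s1$phi - s0$phi)), 1e-8 * max(s0$phi))

  # fitted parameters: MSD rises roughly linearly, then falls to near zero
  # by 8 h with the density peaking at the roost
  tt <- c(seq(1200, 28800, by = 2400), 28800)
  sf <- solve_nonautonomous(100, 8.23 * 3600, 0.83e-5, t_s = 5400, R = 2000,
                            t_out = tt, n_cells = 400)
  m <- density_msd(sf)$msd
  expect_gt(m[2] / m[1], 1.5)                       # early rise
  expect_lt(m[length(m)], 0.02 * max(m))            # near-zero by dawn
  last <- sf$phi[, length(tt)]
  expect_equal(which.max(last), 1L)                 # peak at the roost
  expect_equal(total_mass(sf), rep(1, length(tt)), tolerance = 1e-8)
})

test_that("the shrinking-domain solver reduces to fixed-domain diffusion", {
  const <- domain_radius(function(t) rep_len(2000, length(t)),
                         dR = function(t) rep_len(0, length(t)),
                         t_max = 3e4)
  t_out <- c(500, 5000, 30000)
  s1 <- solve_shrinking_domain(100, const, t_out, n_cells = 200)
  s2 <- solve_diffusion(100, 2000, t_out, n_cells = 200)
  # compare on matching physical cells: rho grid maps to r = 2000 rho
  expect_lt(max(abs(s1$phi - s2$phi)), 1e-8 * max(s2$phi))
  expect_equal(total_mass(s1), rep(1, 3), tolerance = 1e-6)
})

test_that("apical shrinkage tracks R(t)^2/2 and piles density at the boundary", {
  pr <- parabolic_radius(2000, 5400, 28800, t_max = 28440)
  tt <- seq(600, 28440, by = 600)
  s <- solve_shrinking_domain(100, pr, tt, n_cells = 400)
  m <- density_msd(s)$msd
  ref <- pr$R(tt)^2 / 2
  sel <- tt > 3 * 3600
  # the uniform-density estimate R(t)^2/2 underestimates the true MSD by up
  # to ~5% of the curve's peak (density piles at the shrinking boundary;
  # verified against an independent walker simulation), vanishing at dawn
  expect_lt(max(abs(m[sel] - ref[sel])) / max(m), 0.055)
  expect_true(all(m[sel] >= ref[sel]))
  expect_equal(total_mass(s), rep(1, length(tt)), tolerance = 1e-6)
  # density increases toward the moving boundary mid-way through the return
  j <- which.min(abs(tt - 18000))
  expect_gte(s$phi[400, j], s$phi[1, j])
  # guards
  expect_error(solve_shrinking_domain(100, pr, c(600, 28700)), "validity")
  expect_error(parabolic_radius(2000, 5400, 28800, t_max = 28800), "t_max")
})

test_that("density MSD is grid-converged", {
  t_out <- c(2000, 10000, 28800)
  m1 <- density_msd(solve_nonautonomous(100, 8.23 * 3600, 0.83e-5,
                                        t_out = t_out, n_cells = 200))$msd
  m2 <- density_msd(solve_nonautonomous(100, 8.23 * 3600, 0.83e-5,
                                        t_out = t_out, n_cells = 400))$msd
  expect_lt(max(abs(m1 / m2 - 1)), 0.005)
})
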