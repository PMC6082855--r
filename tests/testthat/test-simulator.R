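test_that("extended starts are reproducible, stretched and overlap-free", {
  m <- tiny_model(10)
  x <- init_extended(m, seed = 1)
  expect_identical(x, init_extended(m, seed = 1))
  expect_gt(sqrt(sum((x[10, ] - x[1, ])^2)), 8)  # end-to-end >= 8 sigma
  d <- stats::dist(x)
  expect_gt(min(d), 0.9)
  bonds <- sqrt(rowSums((x[-1, ] - x[-10, ])^2))
  expect_true(all(bonds < 1.4))  # inside the FENE domain
  expect_silent(total_energy(x, m))
})

test_that("Brownian free diffusion matches the closed form", {
  # epsilon = 0, 2 beads far apart (no interactions in range): free diffusion
  msds <- vapply(1:10, function(s) {
    p <- ccm_parameters(n_beads = 2, epsilon = 0)
    m <- energy_model(p, epigenome_annotation(c("A", "B")), ideal = TRUE,
                      bond = list(harm_k = 0))
    x0 <- cbind(c(0, 1e4), 0, 0)
    tr <- run_brownian(x0, m, 20000, dt = 1e-3, friction = 1, seed = s,
                       save_every = 20)
    # short lags with many origins: the long-lag tail of a single-particle
    # MSD has too few independent samples for a stable slope
    sm <- single_locus_msd(tr, 1, lags = 2:10, max_origins = 500)
    mean(sm$msd / sm$t)
  }, numeric(1))
  # slope = 6 D = 6 kT / friction
  expect_lt(abs(mean(msds) - 6) / 6, 0.05)
})

test_that("same seed gives bit-identical trajectories", {
  m <- tiny_model(20)
  x0 <- init_extended(m, seed = 3)
  t1 <- run_brownian(x0, m, 2000, seed = 9)
  t2 <- run_brownian(x0, m, 2000, seed = 9)
  expect_identical(t1$frames, t2$frames)
  t3 <- run_brownian(x0, m, 2000, seed = 10)
  expect_false(identical(t3$frames, t1$frames))
  l1 <- run_langevin(x0, m, 2000, seed = 9)
  l2 <- run_langevin(x0, m, 2000, seed = 9)
  expect_identical(l1$frames, l2$frames)
})

test_that("ideal-chain Rouse scaling emerges for the middle monomer", {
  p <- ccm_parameters(n_beads = 64, epsilon = 0)
  m <- energy_model(p, epigenome_annotation(rep(c("A", "B"), 32)),
                    ideal = TRUE)
  x0 <- init_extended(m, seed = 2)
  eq <- run_brownian(x0, m, 30000, dt = 2e-3, seed = 4, save_every = 30000)
  tr <- run_brownian(traj_frame(eq, n_frames(eq)), m, 60000, dt = 2e-3,
                     seed = 5, save_every = 20)
  sm <- single_locus_msd(tr, 32, max_origins = 150)
  # Rouse regime: between the monomer time and the chain relaxation time
  f <- fit_alpha(sm, lag_range = c(0.5, 30))
  expect_lt(abs(f$alpha - 0.5), 0.12)
})

test_that("Langevin thermostat satisfies equipartition", {
  m <- tiny_model(50)
  x0 <- init_extended(m, seed = 6)
  # pre-thermalize, then measure <E_kin> = (3/2) N kT
  tr <- run_langevin(x0, m, 30000, dt = 0.01, friction = 0.5, seed = 7,
                     save_every = 50)
  kin <- tr$ekin[-(1:200)]
  expect_lt(abs(mean(kin) / (1.5 * 50) - 1), 0.02)
})

test_that("zero-noise zero-friction Langevin conserves energy (symplectic core)", {
  m <- tiny_model(10, epsilon = 1)
  x0 <- init_extended(m, seed = 8)
  # relax a little first so forces are moderate, then NVE
  rel <- run_brownian(x0, m, 2000, dt = 1e-4, seed = 1, save_every = 2000)
  p0 <- ccm_parameters(n_beads = 10, epsilon = 1, temperature = 1e-12)
  m0 <- energy_model(p0, m$annotation)
  tr <- run_langevin(traj_frame(rel, n_frames(rel)), m0, 2000, dt = 1e-3,
                     friction = 0, seed = 1, save_every = 10)
  etot <- tr$ekin + vapply(seq_len(n_frames(tr)), function(k)
    total_energy(traj_frame(tr, k), m0)$E, numeric(1))
  drift <- abs(etot[length(etot)] - etot[1]) / 2000
  expect_lt(drift, 1e-4)
})

test_that("chain connectivity is preserved along dynamic trajectories", {
  m <- tiny_model(40, loops = cbind(5, 25))
  x0 <- init_extended(m, seed = 11)
  pre <- run_brownian(x0, m, 20000, dt = 1e-4, seed = 11, save_every = 100)
  for (k in seq(1, n_frames(pre), by = 20)) {
    x <- traj_frame(pre, k)
    bonds <- sqrt(rowSums((x[-1, ] - x[-40, ])^2))
    expect_true(all(bonds < 1.5))
  }
})

test_that("time mapping is Stokes-drag arithmetic", {
  p <- default_parameters()
  tau <- map_time(p, viscosity = 1)
  expect_true(is.finite(tau) && tau > 0)
  expect_equal(map_time(p, viscosity = 2), 2 * tau, tolerance = 1e-12)
  p2 <- ccm_parameters(sigma = 140)
  # tau ~ sigma^3 at fixed viscosity (Stokes friction grows with sigma)
  expect_equal(map_time(p2, viscosity = 1) / tau, 8, tolerance = 1e-12)
})

test_that("collapse is attraction-driven and epsilon-dependent", {
  # reduced block copolymer: at eps = 2.4 the chain compacts to a globule
  # whose Rg falls monotonically (after smoothing) to a plateau; the weaker
  # eps = 1.0 globule stays larger
  runs <- lapply(c(1.0, 2.4), function(eps) {
    p <- ccm_parameters(n_beads = 100, epsilon = eps)
    ann <- synth_annotation(100, 20, 0.24, seed = 13)
    m <- energy_model(p, ann)
    x0 <- init_extended(m, seed = 13)
    run_langevin(x0, m, 60000, dt = 0.01, friction = 0.1, seed = 13,
                 save_every = 1000)
  })
  rgs <- lapply(runs, traj_rg)
  smooth <- function(v) stats::filter(v, rep(1 / 5, 5), sides = 1)[-(1:4)]
  s24 <- smooth(rgs[[2]])
  # monotone decrease to plateau: no smoothed value rises above its
  # predecessor by more than noise
  expect_true(all(diff(s24) < 0.5))
  expect_lt(s24[length(s24)], 4)
  expect_gt(mean(tail(rgs[[1]], 10)), mean(tail(rgs[[2]], 10)))
})

test_that("same-type contact enrichment follows collapse (A/B segregation)", {
  p <- ccm_parameters(n_beads = 120, epsilon = 2.4)
  ann <- synth_annotation(120, 25, 0.4, seed = 17)
  m <- energy_model(p, ann)
  x0 <- init_extended(m, seed = 17)
  col <- run_langevin(x0, m, 50000, dt = 0.01, friction = 0.1, seed = 17,
                      save_every = 25000)
  prod <- run_brownian(traj_frame(col, n_frames(col)), m, 20000, dt = 1e-4,
                       seed = 18, save_every = 500)
  gAA <- radial_distribution(prod, ann, "AA", dr = 0.2)
  gBB <- radial_distribution(prod, ann, "BB", dr = 0.2)
  gAB <- radial_distribution(prod, ann, "AB", dr = 0.2)
  peak <- function(g) max(g$g$g[g$g$r < 1.5], na.rm = TRUE)
  expect_gt(peak(gAA), peak(gAB))
  expect_gt(peak(gBB), peak(gAB))
})

test_that("trajectories are independent of the neighbor-list skin", {
  m <- tiny_model(60, loops = cbind(10, 40))
  x0 <- init_extended(m, seed = 21)
  eq <- run_brownian(x0, m, 5000, dt = 1e-4, seed = 21, save_every = 5000)
  xc <- traj_frame(eq, n_frames(eq))
  t1 <- run_brownian(xc, m, 3000, dt = 1e-4, seed = 22, skin = 0.3)
  t2 <- run_brownian(xc, m, 3000, dt = 1e-4, seed = 22, skin = 0.7)
  expect_identical(t1$frames, t2$frames)
})

test_that("binary trajectory container round-trips losslessly", {
  tr <- synth_trajectory("brownian", n_beads = 8, n_frames = 6, seed = 2)
  f <- tempfile(fileext = ".traj.rds")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_identical(back$frames, tr$frames)
  expect_identical(back$seed, tr$seed)
})
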