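test_that("mean distance maps average frames and ensembles correctly", {
  x <- rod_conformation(6)
  tr <- static_traj(x)
  dm <- mean_distance_map(tr)
  expect_equal(dm$R, as.matrix(stats::dist(x)), ignore_attr = TRUE,
               tolerance = 1e-12)
  # two-frame toy against hand averaging
  x2 <- x; x2[, 2] <- 1
  fr <- array(c(x, x2), dim = c(6, 3, 2))
  tr2 <- trajectory(fr, c(0, 1))
  d1 <- as.matrix(stats::dist(x)); d2 <- as.matrix(stats::dist(x2))
  dm2 <- mean_distance_map(tr2)
  expect_equal(dm2$R, (d1 + d2) / 2, ignore_attr = TRUE, tolerance = 1e-12)
  # ensemble of identical trajectories equals the single-cell result
  dm3 <- mean_distance_map(list(tr2, tr2), mode = "ensemble")
  expect_equal(dm3$R, dm2$R, tolerance = 1e-14)
})

test_that("R(s) is exact on a rod and dR(s) vanishes for static structures", {
  b <- 0.8
  tr <- static_traj(rod_conformation(40, spacing = b))
  rs <- r_of_s(tr, bin_bp = 1200)
  expect_equal(rs$R, b * rs$s, tolerance = 1e-12)
  expect_true(all(rs$dR < 1e-12))
  expect_equal(rs$s_bp, rs$s * 1200)
})

test_that("R(s) recovers ideal-chain scaling on planted Gaussian chains", {
  set.seed(5)
  n <- 150; nf <- 60
  fr <- array(0, dim = c(n, 3, nf))
  for (k in seq_len(nf))
    fr[, , k] <- apply(matrix(stats::rnorm(n * 3), n, 3), 2, cumsum)
  rs <- r_of_s(trajectory(fr, seq_len(nf)))
  f <- fit_power_law(rs$s, rs$R, fit_range = c(1, 50))
  expect_lt(abs(f$exponent - 0.5), 0.02)
})

test_that("Ward linkage matrices are ultrametric cophenetic summaries", {
  # 3 points, one tight pair: hand agglomeration
  D <- matrix(c(0, 1, 5, 1, 0, 4.8, 5, 4.8, 0), 3, 3)
  W <- ward_linkage_matrix(D)
  expect_lt(W[1, 2], W[1, 3])
  expect_lt(W[1, 2], W[2, 3])
  expect_equal(W[1, 3], W[2, 3], tolerance = 1e-12)  # merged at same height
  # identical points: all-zero
  W0 <- ward_linkage_matrix(matrix(0, 4, 4))
  expect_true(all(W0 == 0))
  expect_equal(wlm_similarity(W, W), 1)
  # ultrametric inequality on random distance matrices
  set.seed(9)
  for (rep in 1:5) {
    n <- 20
    X <- matrix(stats::rnorm(3 * n), n, 3)
    Wr <- ward_linkage_matrix(as.matrix(stats::dist(X)))
    worst <- max(vapply(1:n, function(j)
      max(Wr - outer(Wr[, j], Wr[j, ], pmax)), numeric(1)))
    expect_lte(worst, 1e-9)  # W_ik <= max(W_ij, W_jk) for every triple
  }
})

test_that("Hi-C to distance conversion is a homogeneous power map", {
  P <- matrix(c(0, 4, 1, 4, 0, 16, 1, 16, 0), 3, 3)
  R1 <- hic_to_distance(P, exponent = 4.1)
  R2 <- hic_to_distance(2 * P, exponent = 4.1)
  off <- upper.tri(P)
  expect_equal(R2[off], R1[off] * 2^(-1 / 4.1), tolerance = 1e-12)
  expect_equal(R1[1, 2] / R1[2, 3], (4 / 16)^(-1 / 4.1), tolerance = 1e-12)
  # zeros are floored with a warning
  P0 <- P; P0[1, 3] <- P0[3, 1] <- 0
  expect_warning(R3 <- hic_to_distance(P0), "floored")
  expect_true(all(is.finite(R3)))
})

test_that("contact-distance exponent recovers planted scaling laws", {
  set.seed(6)
  n <- 80
  R <- matrix(0, n, n)
  R[upper.tri(R)] <- stats::runif(n * (n - 1) / 2, 0.5, 20)
  R <- R + t(R)
  for (lam in c(4, 3)) {
    C <- R^(-lam); diag(C) <- 0
    got <- contact_distance_exponent(C, R)
    expect_lt(abs(got$lambda - lam), 1e-6)
  }
  Cc <- matrix(1, n, n); diag(Cc) <- 0
  expect_lt(abs(contact_distance_exponent(Cc, R)$lambda), 1e-9)
})

test_that("WLM similarity is scale-invariant with a small-null population", {
  set.seed(10)
  X <- matrix(stats::rnorm(60), 20, 3)
  W <- ward_linkage_matrix(as.matrix(stats::dist(X)))
  expect_equal(wlm_similarity(W, 3 * W + 2), 1, tolerance = 1e-12)
  # independent random geometries decorrelate
  wlms <- lapply(1:12, function(s) {
    set.seed(100 + s)
    ward_linkage_matrix(as.matrix(stats::dist(matrix(stats::rnorm(150), 50, 3))))
  })
  pop <- wlm_similarity_matrix(wlms)
  expect_equal(length(pop$rho), choose(12, 2))
  expect_lt(abs(pop$mean_rho), 0.35)
  expect_equal(pop$P, t(pop$P))
})

test_that("gyration shapes follow the rod and isotropic limits", {
  rod <- cbind(seq_len(10), 0, 0)
  gs <- gyration_shape(rod)
  expect_equal(gs$kappa2, 1, tolerance = 1e-12)
  expect_equal(gs$S, 2, tolerance = 1e-12)
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  gso <- gyration_shape(octa)
  expect_lt(gso$kappa2, 1e-12)
  # hand-computed 4-point tensor
  pts <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0), c(0, 0, 3))
  xc <- sweep(pts, 2, colMeans(pts))
  ev <- sort(eigen(crossprod(xc) / 4)$values, decreasing = TRUE)
  gs4 <- gyration_shape(pts)
  expect_equal(gs4$Rg, sqrt(sum(ev)), tolerance = 1e-12)
  expect_equal(gs4$eigenvalues, ev, tolerance = 1e-12)
  expect_gte(gs4$S, -0.25); expect_lte(gs4$S, 2)
})

test_that("TAD shape statistics normalize per TAD and detect planted mixtures", {
  loops <- loop_set(rbind(c(1, 10), c(15, 30)), 40)
  tr <- static_traj(rod_conformation(40))
  # identical trajectories: all normalized mass at 1
  st <- tad_shape_stats(list(tr, tr, tr), loops)
  expect_true(all(abs(st$normalized$rg2 - 1) < 1e-12))
  # planted compact/extended mixture is bimodal in normalized Rg^2
  set.seed(12)
  cells <- lapply(1:12, function(i) {
    x <- rod_conformation(40, spacing = if (i %% 2) 1 else 0.25)
    static_traj(x + matrix(stats::rnorm(120, sd = 0.01), 40, 3))
  })
  stm <- tad_shape_stats(cells, loops)
  v <- stm$normalized$rg2[stm$normalized$tad == 1]
  expect_gt(diff(range(v)), 1)  # two well-separated states
})

test_that("droplet detection clusters blobs and growth traces coalescence", {
  blob <- function(center, n, seed) {
    set.seed(seed)
    sweep(matrix(stats::rnorm(3 * n, sd = 0.55), n, 3), 2, center, "+")
  }
  x <- rbind(blob(c(0, 0, 0), 30, 1), blob(c(20, 0, 0), 30, 2))
  cl <- detect_droplets(x, linkage_radius = 2, min_size = 10)
  expect_equal(length(cl), 2)
  expect_equal(sort(vapply(cl, length, integer(1))), c(30, 30))
  # one dense globule: a single cluster holding all beads
  cl1 <- detect_droplets(blob(c(0, 0, 0), 60, 3), 2, 10)
  expect_equal(length(cl1), 1)
  expect_equal(length(cl1[[1]]), 60)
  # planted coalescence schedule: k blobs merging pairwise over frames
  centers <- list(seq(0, 90, by = 30),        # 4 blobs
                  c(0, 0.5, 60, 60.5),        # 2 pairs merged -> 2 blobs
                  c(0, 0.5, 1, 1.5))          # all merged -> 1 blob
  fr <- array(0, dim = c(48, 3, 3))
  for (f in 1:3) {
    xs <- do.call(rbind, lapply(seq_along(centers[[f]]), function(i)
      blob(c(centers[[f]][i], 0, 0), 12, seed = 10 * f + i)))
    fr[, , f] <- xs
  }
  tr <- trajectory(fr, c(1, 2, 4))
  dg <- droplet_growth(tr, linkage_radius = 2, min_size = 5, bead_bp = 1200,
                       window = c(0, 1))
  expect_equal(dg$trace$n_droplets, c(4, 2, 1))
  expect_equal(dg$trace$n_bp, c(12, 24, 48) * 1200)
})

test_that("single-cell WLMs are heterogeneous while half-ensembles agree", {
  # many short glassy runs at small N stand in for single cells: pairwise
  # WLM correlations stay well below 1, while the WLMs of two disjoint
  # half-ensembles (better-averaged structures) agree more strongly
  n <- 120L
  params <- ccm_parameters(n_beads = n, epsilon = 2.4)
  ann <- synth_annotation(n, 25, 0.24, seed = 200)
  loops <- synth_loops(n, 3, 15, seed = 200)
  model <- energy_model(params, ann, loops)
  cells <- lapply(1:20, function(s) {
    x0 <- init_extended(model, seed = 200 + s)
    pre <- run_brownian(x0, model, 10000L, dt = 1e-4, seed = 200 + s,
                        save_every = 10000L)
    col <- run_langevin(traj_frame(pre, n_frames(pre)), model, 30000L,
                        dt = 0.01, friction = 0.1, seed = 200 + s,
                        save_every = 30000L)
    run_brownian(traj_frame(col, n_frames(col)), model, 20000L, dt = 1e-4,
                 seed = 700 + s, save_every = 400L)
  })
  wlms <- lapply(cells, function(tr) ward_linkage_matrix(mean_distance_map(tr)))
  pop <- wlm_similarity_matrix(wlms)
  expect_lt(pop$mean_rho, 0.6)
  half_a <- ward_linkage_matrix(mean_distance_map(cells[1:10], "ensemble"))
  half_b <- ward_linkage_matrix(mean_distance_map(cells[11:20], "ensemble"))
  expect_gt(wlm_similarity(half_a, half_b), pop$mean_rho)
})
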