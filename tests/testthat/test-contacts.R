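test_that("contact map equals brute force and respects geometry", {
  # straight rod with unit spacing and r_c = 2: contacts exactly |i-j| <= 1
  p <- ccm_parameters(n_beads = 8, r_contact = 2)
  tr <- static_traj(rod_conformation(8, spacing = 1))
  cm <- contact_map(tr, p)
  sep <- abs(row(cm$C) - col(cm$C))
  expect_true(all(cm$C[sep == 1] == 1))
  expect_true(all(cm$C[sep >= 2] == 0))
  # random small trajectories match the O(N^2 F) oracle exactly
  set.seed(7)
  for (rc in c(0.5, 1.5, 2)) {
    tr2 <- synth_trajectory("brownian", n_beads = 40, n_frames = 15, D = 0.2,
                            spacing = 0.5, seed = rc * 10)
    p2 <- ccm_parameters(n_beads = 40, r_contact = rc)
    expect_identical(contact_map(tr2, p2)$C, brute_contacts(tr2, rc))
  }
  # vanishing contact radius gives an empty map
  p0 <- ccm_parameters(n_beads = 8, r_contact = 1e-9)
  expect_true(all(contact_map(tr, p0)$C == 0))
})

test_that("P(s) averages anti-diagonals and handles edge cases", {
  p <- ccm_parameters(n_beads = 8, r_contact = 2)
  tr <- static_traj(rod_conformation(8, spacing = 1))
  ps <- contact_probability(contact_map(tr, p), log_bin = FALSE)
  expect_equal(ps$P[ps$s == 1], 1)
  expect_true(all(ps$P[ps$s >= 3] == 0))
  # all-ones probability matrix
  ones <- matrix(1, 6, 6)
  expect_true(all(contact_probability(ones, log_bin = FALSE)$P == 1))
  # planted power law is recovered by the fit
  n <- 200
  M <- outer(seq_len(n), seq_len(n), function(i, j)
    ifelse(i == j, 1, abs(i - j)^(-1)))
  ps2 <- contact_probability(M, log_bin = FALSE)
  f <- fit_power_law(ps2$s, ps2$P)
  expect_equal(f$exponent, -1, tolerance = 1e-10)
})

test_that("power-law fits are exact on noiseless planted laws", {
  x <- seq(1, 100, length.out = 50)
  expect_lt(abs(fit_power_law(x, 3 * x^(-0.75))$exponent + 0.75), 1e-12)
  expect_lt(abs(fit_power_law(x, rep(2, 50))$exponent), 1e-12)
  expect_lt(abs(fit_power_law(x, x)$exponent - 1), 1e-12)
  # noisy: within 2 standard errors
  set.seed(1)
  y <- x^(-1.25) * exp(stats::rnorm(50, sd = 0.1))
  f <- fit_power_law(x, y)
  expect_lt(abs(f$exponent + 1.25), 2 * f$stderr + 0.05)
})

test_that("crossover detection finds a planted two-regime break", {
  s <- unique(round(10^seq(0, 3, length.out = 80)))
  brk <- 400
  P <- ifelse(s <= brk, s^(-0.75), brk^(0.5) * s^(-1.25))
  cs <- crossover_scale(s, P, bin_bp = 1200)
  expect_false(cs$no_crossover)
  expect_lt(abs(log10(cs$s_star) - log10(brk)), 0.06)
  expect_equal(cs$slope_small, -0.75, tolerance = 0.05)
  expect_equal(cs$slope_large, -1.25, tolerance = 0.05)
  expect_equal(cs$s_star_bp, cs$s_star * 1200)
  # a pure power law is flagged as having no crossover
  cs2 <- crossover_scale(s, s^(-1.0))
  expect_true(cs2$no_crossover)
})

test_that("subchain contact counts match the combinatorial closed form", {
  C0 <- matrix(0, 30, 30)
  expect_true(all(subchain_contacts(C0)$A == 0))
  # all-ones counts: window of size s contacts s * (n - s) pairs
  n <- 25
  C1 <- matrix(1, n, n); diag(C1) <- 0
  as_curve <- subchain_contacts(C1, s = c(1, 3, 7, 12))
  expect_equal(as_curve$A, as_curve$s * (n - as_curve$s), tolerance = 1e-12)
})

test_that("spearman map is symmetric with unit diagonal and block structure", {
  labels <- rep(c("A", "B"), each = 25)
  M <- planted_checkerboard(50, labels, noise = 0.05)
  S <- spearman_map(M)
  expect_equal(S, t(S))
  expect_true(all(diag(S) == 1))
  expect_true(all(S >= -1 - 1e-12 & S <= 1 + 1e-12))
  same <- outer(labels, labels, "==") & upper.tri(S)
  diff <- (!outer(labels, labels, "==")) & upper.tri(S)
  expect_gt(mean(S[same]), mean(S[diff]))
  # identical vs anti-ranked rows
  M2 <- rbind(c(0, 1, 2, 3), c(0, 1, 2, 3), c(3, 2, 1, 0), c(0, 1, 2, 3))
  M2 <- (M2 + t(M2)) / 2
  S2 <- spearman_map(M2, exclude_band = 0)
  expect_gt(S2[1, 2], 0.99 - 1)  # sanity: finite
})

test_that("spectral co-clustering recovers planted compartments exactly", {
  labels <- rep(rep(c("A", "B"), 5), each = 50)  # interleaved blocks, n = 500
  S <- planted_checkerboard(500, labels, hi = 2, lo = 1, noise = 0.02)
  got <- compartments_cocluster(S, 2, seed = 1)
  expect_equal(ami(got, labels), 1)
  # permutation invariance of the pipeline result
  perm <- sample(500)
  got_p <- compartments_cocluster(S[perm, perm], 2, seed = 1)
  expect_equal(ami(got_p, labels[perm]), 1)
  expect_error(compartments_cocluster(matrix(1, 20, 20)), "degenerate")
})

test_that("AMI is 1 for identical partitions and ~0 under independence", {
  a <- rep(1:3, each = 20)
  expect_equal(ami(a, a), 1)
  expect_equal(ami(a, c("x", "y", "z")[a]), 1)  # label permutation
  set.seed(11)
  vals <- replicate(100, ami(sample(2, 1000, replace = TRUE),
                             sample(2, 1000, replace = TRUE)))
  expect_lt(abs(mean(vals)), 0.01)
})

test_that("directionality index flags planted block boundaries", {
  n <- 100
  C <- matrix(0, n, n)
  blocks <- list(1:50, 51:100)
  for (b in blocks) C[b, b] <- 5
  diag(C) <- 0
  di <- directionality_index(C, window = 20)
  expect_gt(di[2], 0)    # start of first block: downstream-biased
  expect_lt(di[49], 0)   # end of first block: upstream-biased
  tads <- call_tads(di, window = 20, bin_bp = 1200)
  expect_equal(nrow(tads), 2)
  expect_lt(abs(tads$start_bead[2] - 51), 1.5)
  # uniform matrix: DI identically zero, no TADs
  U <- matrix(1, n, n); diag(U) <- 0
  di_u <- directionality_index(U, window = 20)
  expect_true(all(abs(di_u[21:80]) < 1e-9))
  expect_lte(nrow(call_tads(di_u, window = 20)), 1)
})

test_that("radial distribution is flat for ideal-gas points and peaked for pairs", {
  set.seed(3)
  R <- 10
  n <- 400; nf <- 25
  fr <- array(0, dim = c(n, 3, nf))
  for (k in seq_len(nf)) {
    # uniform points in a sphere of radius R
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2)) * R * stats::runif(n)^(1 / 3)
    fr[, , k] <- u
  }
  tr <- trajectory(fr, seq_len(nf))
  g <- radial_distribution(tr, pair = "all", R_ref = R, r_max = 8, dr = 0.4)
  mid <- g$g[g$g$r > 1 & g$g$r < 8, ]
  expect_true(all(abs(mid$g - 1) < 0.2))
  expect_lt(abs(mean(mid$g) - 1), 0.03)
  # two-point system: single bin peak at the separation
  x2 <- rbind(c(0, 0, 0), c(3, 0, 0))
  g2 <- radial_distribution(static_traj(x2), pair = "all", R_ref = 4,
                            r_max = 5, dr = 0.5)
  expect_lt(abs(g2$g$r[which.max(g2$g$g)] - 3), 0.5)
})

test_that("radial density profile is ~1 inside a uniform sphere, delta at origin", {
  set.seed(4)
  R <- 6; n <- 2000
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2)) * R * stats::runif(n)^(1 / 3)
  ann <- epigenome_annotation(rep("A", n))
  fr <- array(0, dim = c(n, 3, 5))
  for (k in 1:5) {
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2)) * R * stats::runif(n)^(1 / 3)
    fr[, , k] <- u
  }
  rp <- radial_density_profile(trajectory(fr, 1:5), ann, r_max = R, dr = 1)
  inside <- rp[rp$r > 1 & rp$r < R - 1, ]
  expect_true(all(abs(inside$rho - 1) < 0.2))
  # all beads at the origin: everything lands in the first shell
  x0 <- matrix(1e-6 * seq_len(30), 10, 3)
  rp0 <- radial_density_profile(static_traj(x0),
                                epigenome_annotation(rep("B", 10)),
                                r_max = 2, dr = 0.5)
  expect_gt(rp0$rho[1], 10)
  expect_true(all(rp0$rho[-1] < 1e-9))
})

test_that("the homopolymer control forms no compartments", {
  # with equal cross-type attraction (eps_AB = eps) the labels are
  # energetically invisible: co-clustered compartments carry no information
  # about the planted A/B annotation
  n <- 250L
  params <- ccm_parameters(n_beads = n, epsilon = 2.4, eps_ratio = 1)
  ann <- synth_annotation(n, 40, 0.3, seed = 77)
  model <- energy_model(params, ann)
  x0 <- init_extended(model, seed = 77)
  col <- run_langevin(x0, model, 50000L, dt = 0.01, friction = 0.1,
                      seed = 77, save_every = 50000L)
  prod <- run_brownian(traj_frame(col, n_frames(col)), model, 60000L,
                       dt = 1e-4, seed = 78, save_every = 200L)
  cm <- contact_map(prod, params)
  labels <- compartments_cocluster(spearman_map(cm), 2, seed = 1)
  observed <- abs(ami(labels, ann$labels))
  # chance level for blocky labels is set by the number of blocks, not the
  # number of beads: calibrate the null by circularly shifting the labels
  # (which preserves the block structure but destroys any correspondence)
  null <- vapply(seq(10, 240, by = 26), function(k) {
    shifted <- ann$labels[((seq_len(n) + k - 1) %% n) + 1]
    abs(ami(labels, shifted))
  }, numeric(1))
  expect_lt(observed, max(null) + 0.05)
})
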