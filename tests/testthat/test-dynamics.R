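test_that("ensemble MSD is zero for static and rigidly translating chains", {
  st <- synth_trajectory("static", n_beads = 15, n_frames = 20)
  expect_true(all(msd(st)$msd == 0))
  # rigid-body translation: com subtraction removes all displacement
  fr <- st$frames
  for (k in seq_len(dim(fr)[3])) fr[, 1, k] <- fr[, 1, k] + 3 * k
  moving <- trajectory(fr, st$times)
  expect_true(all(msd(moving)$msd < 1e-18))
})

test_that("MSD estimators recover ballistic and diffusive closed forms", {
  ba <- synth_trajectory("ballistic", n_beads = 40, n_frames = 60, dt = 0.25,
                         speed = 1.5, seed = 2)
  f <- fit_alpha(single_locus_msd(ba, 11))
  expect_lt(abs(f$alpha - 2), 0.01)
  br <- synth_trajectory("brownian", n_beads = 150, n_frames = 800, dt = 1,
                         D = 1, seed = 3)
  ad <- alpha_distribution(br, lag_range = c(2, 100),
                           loci = seq(1, 150, by = 2), max_origins = 40)
  expect_lt(abs(mean(ad$alpha) - 1), 0.05)
  expect_lt(stats::sd(ad$alpha), 0.25)  # narrow for homogeneous diffusion
  expect_equal(sum(ad$hist$density) * 0.1, 1, tolerance = 1e-6)
})

test_that("the scaling relation maps Flory exponents to diffusion exponents", {
  expect_identical(alpha_from_nu(0.5), 0.5)
  expect_equal(alpha_from_nu(1 / 3), 0.4, tolerance = 1e-15)
  expect_equal(alpha_from_nu(0.6), 0.6 / 1.1, tolerance = 1e-15)
  # the printed self-avoiding value 0.54 corresponds to nu just below 0.6
  expect_lt(abs(alpha_from_nu(0.6) - 0.54), 0.01)
  expect_equal(alpha_from_nu(1e9), 1, tolerance = 1e-8)
  expect_error(alpha_from_nu(0))
})

test_that("scattering function starts at 1 and decays as the Gaussian form", {
  st <- synth_trajectory("static", n_beads = 10, n_frames = 10)
  fs0 <- intermediate_scattering(st, k = 1)
  expect_true(all(fs0$Fs == 1))
  expect_true(stretched_fit(fs0)$degenerate)
  # brownian: F_s = exp(-k^2 D t) and beta = 1
  br <- synth_trajectory("brownian", n_beads = 400, n_frames = 400, dt = 0.05,
                         D = 1, seed = 4)
  k <- 1.3
  fs <- intermediate_scattering(br, k = k, max_origins = 60)
  expect_identical(fs$Fs[1], 1)
  ref <- exp(-k^2 * 1 * fs$t)
  expect_lt(max(abs(fs$Fs - ref)[ref > 0.05]), 0.05)
  sf <- stretched_fit(fs)
  expect_lt(abs(sf$beta - 1), 0.05)
  expect_lt(abs(sf$tau - 1 / k^2), 0.1 / k^2)
})

test_that("stretched-exponential fits recover planted parameters", {
  t <- 10^seq(-2, 2, length.out = 60)
  for (pars in list(c(0.27, 5), c(0.6, 1), c(1, 12))) {
    curve <- data.frame(t = t, Fs = exp(-(t / pars[2])^pars[1]))
    got <- stretched_fit(curve, refine = TRUE)
    expect_lt(abs(got$beta - pars[1]), 1e-6)
    expect_lt(abs(got$tau - pars[2]) / pars[2], 1e-6)
  }
})

test_that("chi4 vanishes for identical ensembles and stays small for liquids", {
  br <- synth_trajectory("brownian", n_beads = 100, n_frames = 150, dt = 0.1,
                         seed = 5)
  x4 <- chi4(list(br, br, br), k = 1)
  expect_identical(x4$curve$chi4[1], 0)
  expect_true(all(x4$curve$chi4 < 1e-18))
  # independent free-diffusion ensembles: chi4 remains within the null band
  ens <- lapply(1:6, function(s)
    synth_trajectory("brownian", n_beads = 100, n_frames = 150, dt = 0.1,
                     D = 1, seed = 10 + s))
  x4i <- chi4(ens, k = 1, max_origins = 40)
  expect_identical(x4i$curve$chi4[1], 0)
  expect_true(all(x4i$curve$chi4 >= 0))
  # variance of F_s across N = 100 independent beads is O(1/N); chi4 = N var
  # stays O(1) with no large cooperative peak
  expect_lt(max(x4i$curve$chi4), 3)
  # the single-trajectory block estimator runs but is flagged as biased
  expect_warning(x4b <- chi4_blocks(ens[[1]], k = 1, n_blocks = 3), "biased")
  expect_identical(x4b$curve$chi4[1], 0)
})

test_that("Van Hove histograms are normalized and Gaussian for free diffusion", {
  br <- synth_trajectory("brownian", n_beads = 300, n_frames = 120, dt = 1,
                         D = 0.7, seed = 6)
  vh <- van_hove(br, lags = c(1, 5, 20), max_origins = 20)
  for (h in vh$histograms) {
    dx <- diff(h$x[1:2])
    expect_equal(sum(h$density) * dx, 1, tolerance = 1e-6)
  }
  # Kolmogorov-Smirnov at 1%: displacements at one lag are Gaussian
  d <- as.vector(br$frames[, , 21] - br$frames[, , 1])
  ks <- stats::ks.test(d, "pnorm", sd = stats::sd(d))
  expect_gt(ks$p.value, 0.01)
  # planted fast/slow mixture produces a heavy (exponential-like) tail
  set.seed(7)
  n <- 400; nf <- 80
  sds <- rep(c(0.1, 1.5), each = n / 2)
  fr <- array(0, dim = c(n, 3, nf))
  for (k in 2:nf) fr[, , k] <- fr[, , k - 1] +
    matrix(stats::rnorm(3 * n, sd = sds), n, 3)
  mix <- trajectory(fr, seq_len(nf))
  vmix <- van_hove(mix, lags = c(4, 16), max_origins = 15)
  vbr <- van_hove(br, lags = c(4, 16), max_origins = 15)
  # excess kurtosis view: mixture decays slower than its matched Gaussian
  expect_gt(vmix$eta, 0)
  expect_lt(vmix$eta, 2)       # exponential-like, far from Gaussian tails
  # mixture carries far more mass beyond 3 gamma than its matched Gaussian
  h <- vmix$histograms[["16"]]
  gam <- vmix$gamma[["16"]]
  dx <- diff(h$x[1:2])
  tail_mass <- sum(h$density[abs(h$x) > 3 * gam]) * dx
  expect_gt(tail_mass, 4 * 2 * stats::pnorm(-3))
  expect_true(is.finite(vbr$eta))
})

test_that("mobility profiles are flat for uniform diffusion and detect shells", {
  br <- synth_trajectory("brownian", n_beads = 300, n_frames = 100, dt = 0.5,
                         D = 1, spacing = 0.2, seed = 8)
  ann <- epigenome_annotation(rep(c("A", "B"), 150))
  mp <- mobility_profiles(br, ann, lag = 2, n_shells = 6)
  expect_true(all(abs(mp$radial$mobility - 1) < 0.25))
  expect_lt(abs(mp$ratio - 1), 0.3)
  # planted shell-fast/core-slow: mobility increases at the planted radius
  set.seed(9)
  n <- 400; nf <- 60
  x0 <- matrix(stats::rnorm(3 * n), n, 3)
  x0 <- x0 / sqrt(rowSums(x0^2)) * 5 * stats::runif(n)^(1 / 3)
  rad <- sqrt(rowSums(x0^2))
  sds <- ifelse(rad > 3.5, 0.8, 0.05)
  fr <- array(0, dim = c(n, 3, nf)); fr[, , 1] <- x0
  for (k in 2:nf) fr[, , k] <- fr[, , k - 1] +
    matrix(stats::rnorm(3 * n, sd = sds), n, 3)
  shell <- trajectory(fr, seq_len(nf))
  ann2 <- epigenome_annotation(ifelse(rad > 3.5, "A", "B"))
  mp2 <- mobility_profiles(shell, ann2, lag = 1, n_shells = 8)
  prof <- mp2$radial
  expect_gt(mean(prof$mobility[prof$r > 4]), 2 * mean(prof$mobility[prof$r < 2]))
  expect_gt(mp2$ratio, 1)
})
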