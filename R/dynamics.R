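# Time-dependent observables: mean square displacements, diffusion-exponent
# distributions, intermediate scattering functions, fourth-order
# susceptibility, Van Hove functions and mobility profiles.

# log-spaced subset of frame lags for a trajectory of nf frames
default_lags <- function(nf, n_lags = 40) {
  lags <- unique(round(10^seq(0, log10(nf - 1), length.out = n_lags)))
  lags[lags >= 1 & lags <= nf - 1]
}

#' Ensemble mean square displacement (center-of-mass subtracted)
#'
#' `Delta(t)` averages, over beads and time origins, the squared
#' displacement of each bead measured relative to the chain's center of
#' mass, `(r_j(t0+t) - r_com(t0+t)) - (r_j(t0) - r_com(t0))`. Subtracting
#' the center of mass removes rigid-body drift, so a translating rigid body
#' has `Delta(t) = 0`.
#'
#' @param traj a [trajectory()] (>= 2 frames).
#' @param lags integer frame lags (default: log-spaced).
#' @param max_origins cap on the number of time origins per lag.
#' @return Data frame with columns `lag` (frames), `t` (reduced time),
#'   `msd` (sigma^2).
#' @export
msd <- function(traj, lags = NULL, max_origins = 50) {
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least 2 frames")
  if (is.null(lags)) lags <- default_lags(nf)
  coms <- traj_com(traj)
  rel <- traj$frames
  for (k in seq_len(nf)) rel[, , k] <- sweep(rel[, , k], 2, coms[k, ])
  out <- vapply(lags, function(L) {
    origins <- origin_index(nf, L, max_origins)
    mean(vapply(origins, function(t0) {
      d <- rel[, , t0 + L] - rel[, , t0]
      mean(rowSums(d^2))
    }, numeric(1)))
  }, numeric(1))
  data.frame(lag = lags, t = traj$times[1 + lags] - traj$times[1], msd = out)
}

origin_index <- function(nf, lag, max_origins) {
  origins <- seq_len(nf - lag)
  if (length(origins) > max_origins)
    origins <- unique(round(seq(1, nf - lag, length.out = max_origins)))
  origins
}

#' Single-locus mean square displacement and diffusion exponents
#'
#' `single_locus_msd` computes the time-origin-averaged MSD of one locus,
#' `Delta_i(t) = <(r_i(t0+t) - r_i(t0))^2>_{t0}` (no center-of-mass
#' subtraction). `fit_alpha` extracts the effective diffusion exponent
#' alpha_i and coefficient D_i from a log-log fit of `Delta_i ~ D t^alpha`
#' restricted to a lag window; `alpha_distribution` does this for every
#' locus and returns the normalized histogram P(alpha), whose width
#' separates liquid-like (narrow, alpha ~ const) from glassy (broad,
#' coexisting fast and slow loci) dynamics.
#'
#' @param traj a [trajectory()].
#' @param locus bead index.
#' @inheritParams msd
#' @return `single_locus_msd`: data frame `lag`, `t`, `msd`.
#' @export
single_locus_msd <- function(traj, locus, lags = NULL, max_origins = 50) {
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least 2 frames")
  if (is.null(lags)) lags <- default_lags(nf)
  x <- t(traj$frames[locus, , ])  # nf x 3
  out <- vapply(lags, function(L) {
    origins <- origin_index(nf, L, max_origins)
    d <- x[origins + L, , drop = FALSE] - x[origins, , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  data.frame(lag = lags, t = traj$times[1 + lags] - traj$times[1], msd = out)
}

#' @rdname single_locus_msd
#' @param curve data frame with `t` and `msd` columns.
#' @param lag_range inclusive time window (same units as `t`) for the fit.
#' @return `fit_alpha`: list with `alpha`, `D`, `stderr`.
#' @export
fit_alpha <- function(curve, lag_range = range(curve$t[curve$t > 0])) {
  keep <- curve$t > 0 & curve$msd > 0
  fit <- fit_power_law(curve$t[keep], curve$msd[keep], fit_range = lag_range)
  list(alpha = fit$exponent, D = fit$prefactor, stderr = fit$stderr)
}

#' @rdname single_locus_msd
#' @param loci bead indices to include (default all).
#' @param breaks histogram breaks for P(alpha).
#' @return `alpha_distribution`: list with `alpha` (per-locus exponents),
#'   `D` (per-locus coefficients), `hist` (density-normalized histogram).
#' @export
alpha_distribution <- function(traj, lag_range, loci = NULL, lags = NULL,
                               max_origins = 25, breaks = seq(-0.25, 2.25, 0.1)) {
  if (is.null(loci)) loci <- seq_len(n_beads(traj))
  fits <- lapply(loci, function(i) {
    cv <- single_locus_msd(traj, i, lags = lags, max_origins = max_origins)
    tryCatch(fit_alpha(cv, lag_range), error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  alpha <- vapply(fits[ok], `[[`, numeric(1), "alpha")
  D <- vapply(fits[ok], `[[`, numeric(1), "D")
  h <- graphics::hist(pmin(pmax(alpha, min(breaks)), max(breaks)),
                      breaks = breaks, plot = FALSE)
  list(alpha = alpha, D = D,
       hist = data.frame(mid = h$mids, density = h$density))
}

#' Diffusion exponent from the Flory exponent
#'
#' The scaling argument equating the time for a monomer to diffuse a
#' distance of order the chain size with the whole-chain diffusion time
#' gives `alpha = 2 nu / (2 nu + 1)` for the monomer MSD exponent of a
#' polymer with size exponent nu: 0.5 for an ideal chain (nu = 1/2, the
#' Rouse result), about 0.54 for a self-avoiding chain (nu ~ 0.6), and 0.4
#' for a maximally condensed chain (nu = 1/3).
#'
#' @param nu Flory exponent (> 0).
#' @return alpha = 2 nu / (2 nu + 1).
#' @export
alpha_from_nu <- function(nu) {
  stopifnot(all(nu > 0))
  2 * nu / (2 * nu + 1)
}

#' Self-intermediate scattering function
#'
#' `F_s(k, t) = (1/N) < sum_j exp(i k . (r_j(t0+t) - r_j(t0))) >` with an
#' isotropic average over wavevector directions, implemented exactly as
#' `sinc(k |dr|) = sin(k |dr|) / (k |dr|)`. `F_s(k, 0) = 1` exactly. The
#' default wavevector is `k = 1 / r_s` with r_s the first peak of the
#' radial distribution function (pass `two_pi = TRUE` for `2 pi / r_s`).
#'
#' @param traj a [trajectory()] (or list; curves are averaged).
#' @param k wavevector magnitude in 1/sigma.
#' @inheritParams msd
#' @return Data frame with `lag`, `t`, `Fs`, including lag 0.
#' @export
intermediate_scattering <- function(traj, k, lags = NULL, max_origins = 50) {
  stopifnot(k > 0)
  if (inherits(traj, "ccm_trajectory")) traj <- list(traj)
  curves <- lapply(traj, function(tr) {
    nf <- n_frames(tr)
    if (is.null(lags)) lags <- default_lags(nf)
    lags <- lags[lags <= nf - 1]
    fs <- vapply(lags, function(L) {
      origins <- origin_index(nf, L, max_origins)
      mean(vapply(origins, function(t0) {
        d <- tr$frames[, , t0 + L] - tr$frames[, , t0]
        kr <- k * sqrt(rowSums(d^2))
        mean(ifelse(kr < 1e-12, 1, sin(kr) / kr))
      }, numeric(1)))
    }, numeric(1))
    data.frame(lag = c(0L, lags),
               t = c(0, tr$times[1 + lags] - tr$times[1]), Fs = c(1, fs))
  })
  if (length(curves) == 1) return(curves[[1]])
  out <- curves[[1]]
  out$Fs <- rowMeans(do.call(cbind, lapply(curves, `[[`, "Fs")))
  out
}

#' Stretched-exponential fit of a relaxation curve
#'
#' Fits `F(t) = exp(-(t / tau)^beta)` by linear regression of
#' `log(-log F)` on `log t` over the informative part of the decay
#' (`fs_range`, default F in `[0.02, 0.95]`), optionally refined by
#' nonlinear least squares. `beta = 1` is simple exponential (liquid-like)
#' relaxation; `beta << 1` signals glassy, stretched relaxation. A curve
#' that never leaves the `fs_range` upper bound is degenerate and is
#' flagged.
#'
#' @param curve data frame with `t` and `Fs` columns.
#' @param fs_range F values included in the fit.
#' @param refine run an `nls` refinement after the linearized fit.
#' @return List with `beta`, `tau`, `degenerate`.
#' @export
stretched_fit <- function(curve, fs_range = c(0.02, 0.95), refine = TRUE) {
  keep <- curve$t > 0 & is.finite(curve$Fs) &
    curve$Fs > fs_range[1] & curve$Fs < fs_range[2]
  if (sum(keep) < 3)
    return(list(beta = NA_real_, tau = NA_real_, degenerate = TRUE))
  lt <- log(curve$t[keep])
  ll <- log(-log(curve$Fs[keep]))
  fit <- stats::lm(ll ~ lt)
  beta <- unname(stats::coef(fit)[2])
  tau <- exp(-unname(stats::coef(fit)[1]) / beta)
  if (refine) {
    nl <- tryCatch(
      suppressWarnings(stats::nls(Fs ~ exp(-(t / tau)^beta),
                 data = curve[keep, , drop = FALSE],
                 start = list(tau = tau, beta = beta),
                 control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(nl)) {
      cf <- stats::coef(nl)
      beta <- unname(cf["beta"]); tau <- unname(cf["tau"])
    }
  }
  list(beta = beta, tau = tau, degenerate = FALSE)
}

#' Fourth-order susceptibility from an ensemble of trajectories
#'
#' `chi4(t) = N * Var[F_s(k, t)]` where the variance is taken across
#' independent trajectories of the per-trajectory (time-origin averaged)
#' scattering function. `chi4(0) = 0` exactly. An interior peak at t_M is
#' the signature of dynamic heterogeneity; liquid-like ensembles stay flat
#' and small.
#'
#' @param trajs list of >= 2 independent [trajectory()] objects.
#' @param k wavevector magnitude.
#' @inheritParams msd
#' @return List with `curve` (data frame `t`, `chi4`, `Fs_mean`) and `t_M`
#'   (argmax of chi4).
#' @export
chi4 <- function(trajs, k, lags = NULL, max_origins = 50) {
  stopifnot(length(trajs) >= 2)

  curves <- lapply(trajs, intermediate_scattering, k = k, lags = lags,
                   max_origins = max_origins)
  FS <- do.call(cbind, lapply(curves, `[[`, "Fs"))
  N <- n_beads(trajs[[1]])
  v <- apply(FS, 1, stats::var)
  curve <- data.frame(t = curves[[1]]$t, chi4 = N * v, Fs_mean = rowMeans(FS))
  list(curve = curve, t_M = curve$t[which.max(curve$chi4)])
}

#' @rdname chi4
#' @param traj single [trajectory()] for the block estimator.
#' @param n_blocks number of contiguous time blocks treated as
#'   pseudo-independent replicas. This single-trajectory estimator is
#'   biased: blocks share history and slow modes, so it underestimates the
#'   true ensemble variance at long lags. Prefer `chi4()` over independent
#'   runs whenever possible.
#' @export
chi4_blocks <- function(traj, k, n_blocks = 4, lags = NULL,
                        max_origins = 25) {
  nf <- n_frames(traj)
  stopifnot(n_blocks >= 2, nf >= 2 * n_blocks)
  edges <- floor(seq(1, nf + 1, length.out = n_blocks + 1))
  blocks <- lapply(seq_len(n_blocks), function(b) {
    idx <- edges[b]:(edges[b + 1] - 1)
    trajectory(traj$frames[, , idx, drop = FALSE],
               traj$times[idx], seed = traj$seed, model = traj$model,
               integrator = traj$integrator)
  })
  warning("single-trajectory block chi4 is a biased estimator; ",
          "use independent trajectories where possible")
  chi4(blocks, k = k, lags = lags, max_origins = max_origins)
}

#' Van Hove displacement distributions
#'
#' Histograms of single-coordinate displacements `Delta x` over all loci,
#' coordinates and time origins at each requested lag, each normalized to
#' integrate to 1, together with the per-lag standard deviation `gamma`,
#' the collapse variable `Delta x / gamma`, a matched Gaussian reference,
#' and the exponential tail exponent eta fitted on
#' `P(|Delta x| / gamma) ~ exp(-eta |Delta x| / gamma)` beyond the
#' `tail_quantile` quantile. Gaussian displacements (liquid) give eta fits
#' that track the Gaussian; glassy dynamics produce exponential fat tails.
#'
#' @param traj a [trajectory()].
#' @param lags integer frame lags.
#' @param n_bins histogram bins per lag.
#' @param tail_quantile start of the tail fit on |dx|/gamma.
#' @inheritParams msd
#' @return List with `histograms` (per lag: data frame `x`, `density`,
#'   `gaussian`), `gamma` (per lag), `collapse` (data frame `u`, `density`,
#'   `lag`), `eta`.
#' @export
van_hove <- function(traj, lags, n_bins = 61, tail_quantile = 0.95,
                     max_origins = 25) {
  nf <- n_frames(traj)
  stopifnot(all(lags >= 1), all(lags <= nf - 1))
  hists <- list(); gam <- numeric(0); collapse <- list()
  for (L in lags) {
    origins <- origin_index(nf, L, max_origins)
    dx <- unlist(lapply(origins, function(t0)
      as.vector(traj$frames[, , t0 + L] - traj$frames[, , t0])))
    g <- stats::sd(dx)
    br <- seq(-max(abs(dx)) - 1e-9, max(abs(dx)) + 1e-9, length.out = n_bins)
    h <- graphics::hist(dx, breaks = br, plot = FALSE)
    hists[[as.character(L)]] <-
      data.frame(x = h$mids, density = h$density,
                 gaussian = stats::dnorm(h$mids, 0, g))
    gam <- c(gam, g)
    u <- dx / g
    bu <- seq(-max(abs(u)) - 1e-9, max(abs(u)) + 1e-9, length.out = n_bins)
    hu <- graphics::hist(u, breaks = bu, plot = FALSE)
    collapse[[as.character(L)]] <-
      data.frame(u = hu$mids, density = hu$density, lag = L)
  }
  names(gam) <- as.character(lags)
  coll <- do.call(rbind, c(collapse, list(make.row.names = FALSE)))
  # tail exponent on pooled |u|
  tail_pts <- coll[abs(coll$u) >= stats::quantile(abs(coll$u)[coll$density > 0],
                                                  tail_quantile) &
                     coll$density > 0, ]
  eta <- NA_real_
  if (nrow(tail_pts) >= 3) {
    fit <- stats::lm(log(density) ~ abs(u), data = tail_pts)
    eta <- -unname(stats::coef(fit)[2])
  }
  list(histograms = hists, gamma = gam, collapse = coll, eta = eta)
}

#' Radial and type-resolved mobility
#'
#' Quantifies where the mobile loci sit: per-locus displacement magnitude
#' over a lag window, normalized by its mean and binned by the locus'
#' radial position (distance from the center of mass at the origin frame),
#' plus type-resolved MSD fits `Delta_a(t) = D_a t^alpha_a` for A and B
#' loci and their diffusion-coefficient ratio. In the glassy collapsed
#' state the periphery (A-rich) is more mobile than the core, giving
#' `D_A / D_B > 1`; a liquid is radially flat with ratio near 1.
#'
#' @param traj a [trajectory()].
#' @param annotation a [epigenome_annotation()].
#' @param lag frame lag for the displacement field.
#' @param n_shells number of radial bins.
#' @param lag_range time window for the type-resolved MSD fits (default:
#'   central two decades of available lags).
#' @inheritParams msd
#' @return List with `radial` (data frame `r`, `mobility`), `D_A`, `D_B`,
#'   `ratio`, `alpha_A`, `alpha_B`, `displacements` (per-locus data frame).
#' @export
mobility_profiles <- function(traj, annotation, lag = 1, n_shells = 12,
                              lag_range = NULL, max_origins = 25) {
  nf <- n_frames(traj)
  stopifnot(lag >= 1, lag <= nf - 1)
  lab <- annotation$labels
  coms <- traj_com(traj)
  origins <- origin_index(nf, lag, max_origins)
  n <- n_beads(traj)
  disp <- numeric(n); rad <- numeric(n)
  cnt <- 0
  for (t0 in origins) {
    d <- traj$frames[, , t0 + lag] - traj$frames[, , t0]
    disp <- disp + sqrt(rowSums(d^2))
    x0 <- sweep(traj$frames[, , t0], 2, coms[t0, ])
    rad <- rad + sqrt(rowSums(x0^2))
    cnt <- cnt + 1
  }
  disp <- disp / cnt; rad <- rad / cnt
  shells <- cut(rad, breaks = n_shells)
  radial <- data.frame(
    r = as.numeric(tapply(rad, shells, mean)),
    mobility = as.numeric(tapply(disp, shells, mean)) / mean(disp))
  radial <- radial[is.finite(radial$r), ]
  # type-resolved MSD fits
  fit_type <- function(type) {
    idx <- which(lab == type)
    curves <- lapply(idx, function(i)
      single_locus_msd(traj, i, max_origins = max_origins))
    m <- Reduce(`+`, lapply(curves, `[[`, "msd")) / length(idx)
    cv <- data.frame(t = curves[[1]]$t, msd = m)
    if (is.null(lag_range)) {
      tt <- cv$t[cv$t > 0]
      lag_range <- exp(stats::quantile(log(tt), c(0.25, 0.95)))
    }
    fit_alpha(cv, lag_range)
  }
  fa <- fit_type("A"); fb <- fit_type("B")
  list(radial = radial, D_A = fa$D, D_B = fb$D, ratio = fa$D / fb$D,
       alpha_A = fa$alpha, alpha_B = fb$alpha,
       displacements = data.frame(locus = seq_len(n), r = rad, disp = disp,
                                  label = lab))
}
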