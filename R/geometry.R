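#' Mean spatial distance map
#'
#' `R_ij = <|r_i - r_j|>`: in `single_cell` mode the average runs over the
#' frames of one trajectory (the single-cell, time-averaged distance map);
#' in `ensemble` mode it runs over the frames of all supplied trajectories.
#'
#' @param trajectories a [trajectory()] or list of them.
#' @param mode "single_cell" (first/only trajectory) or "ensemble".
#' @return List of class `ccm_distances` with `R` (mean distances), `R2`
#'   (mean squared distances) and `n_frames`.
#' @export
mean_distance_map <- function(trajectories,
                              mode = c("single_cell", "ensemble")) {
  mode <- match.arg(mode)
  if (inherits(trajectories, "ccm_trajectory"))
    trajectories <- list(trajectories)
  if (mode == "single_cell") trajectories <- trajectories[1]
  S <- NULL; S2 <- NULL; nf <- 0
  for (tr in trajectories) {
    d <- .cpp_distance_sums(tr$frames)
    if (is.null(S)) { S <- d$sum; S2 <- d$sumsq } else {
      S <- S + d$sum; S2 <- S2 + d$sumsq
    }
    nf <- nf + d$n_frames
  }
  structure(list(R = S / nf, R2 = S2 / nf, n_frames = nf),
            class = "ccm_distances")
}

#' Distance scaling R(s) and its coefficient of variation dR(s)
#'
#' `R(s)` is the root mean squared spatial distance between loci at genomic
#' separation s, the mean running over all pairs with `|i - j| = s` and over
#' frames (and trajectories). `dR(s)` is the coefficient of variation
#' `sqrt(<R_s^2> - <R_s>^2) / <R_s>`, where the variance is taken over the
#' frame/ensemble fluctuations of each pair's distance and then averaged
#' over the pairs at separation s. It measures structural (cell-to-cell and
#' temporal) heterogeneity: a deterministic single-frame structure has
#' `dR(s) = 0` identically.
#'
#' @param x a `ccm_distances` (from [mean_distance_map()]), a
#'   [trajectory()], or a list of trajectories.
#' @param bin_bp bp per bead for the bp-valued abscissa.
#' @return Data frame with columns `s`, `s_bp`, `R` (root mean square
#'   distance), `dR`.
#' @export
r_of_s <- function(x, bin_bp = 1200) {
  if (!inherits(x, "ccm_distances")) x <- mean_distance_map(x, "ensemble")
  n <- nrow(x$R)
  s <- seq_len(n - 1)
  out <- vapply(s, function(k) {
    idx <- cbind(seq_len(n - k), seq_len(n - k) + k)
    m2 <- mean(x$R2[idx])                       # <R_s^2> over pairs+frames
    var_pair <- x$R2[idx] - x$R[idx]^2          # per-pair variance over frames
    m1 <- mean(x$R[idx])
    c(sqrt(m2), sqrt(max(mean(var_pair), 0)) / m1)
  }, numeric(2))
  data.frame(s = s, s_bp = s * bin_bp, R = out[1, ], dR = out[2, ])
}

#' Ward linkage (cophenetic) matrix
#'
#' Applies Ward agglomerative clustering directly to a mean spatial-distance
#' matrix and returns the cophenetic matrix: entry (i, j) is the merge
#' height of the lowest cluster containing both i and j. The result is a
#' symmetric non-negative ultrametric (`W_ik <= max(W_ij, W_jk)` for all
#' triples) summarizing the hierarchical spatial organization. Note Ward's
#' variance interpretation assumes Euclidean input; applied to a
#' non-Euclidean mean-distance matrix it is used as a (well-defined)
#' hierarchical summary.
#'
#' @param D square symmetric distance matrix (or `ccm_distances`).
#' @param source tag recorded on the result ("simulation", "hic", ...).
#' @return Matrix of class `ccm_wlm` with attribute `source`.
#' @export
ward_linkage_matrix <- function(D, source = "simulation") {
  if (inherits(D, "ccm_distances")) D <- D$R
  D <- as.matrix(D)
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  W <- as.matrix(stats::cophenetic(hc))
  dimnames(W) <- NULL
  attr(W, "source") <- source
  class(W) <- c("ccm_wlm", class(W))
  W
}

#' Convert a Hi-C contact map to relative distances
#'
#' Inverts the empirical contact-distance scaling `P_ij ~ R_ij^(-lambda)`
#' (lambda = 4.1 from imaging data): `R_ij = P_ij^(-1/lambda)` up to an
#' arbitrary prefactor. Zero or negative entries are floored at the smallest
#' positive entry (with a warning) before inversion. Because Ward linkage
#' followed by Pearson comparison is invariant to the overall scale, the
#' unit prefactor does not affect WLM comparisons.
#'
#' @param P probability (or count) matrix.
#' @param exponent scaling exponent lambda.
#' @param floor value substituted for non-positive entries (default:
#'   smallest positive entry).
#' @return Symmetric relative-distance matrix with zero diagonal.
#' @export
hic_to_distance <- function(P, exponent = 4.1, floor = NULL) {
  P <- as.matrix(P)
  pos <- P > 0
  offdiag <- !diag(nrow(P))
  if (any(!pos & offdiag)) {
    if (is.null(floor)) floor <- min(P[pos & offdiag])
    warning(sprintf("%d non-positive entries floored at %g",
                    sum(!pos & offdiag), floor))
    P[!pos] <- floor
  }
  R <- P^(-1 / exponent)
  diag(R) <- 0
  (R + t(R)) / 2
}

#' Contact-distance scaling exponent lambda
#'
#' Estimates lambda in `1/C_ij ~ R_ij^lambda` from the ridge of the 2-D
#' histogram of (log R_ij, log 1/C_ij): pairs are binned by log R, the ridge
#' is traced by the per-bin median of both coordinates, and lambda is the
#' OLS slope through the ridge points. Using the binned ridge rather than
#' the raw pair scatter limits the heteroscedastic spread of low-count
#' pairs.
#'
#' @param C contact counts (matrix or `ccm_contacts`).
#' @param R mean distances (matrix or `ccm_distances`).
#' @param fit_range inclusive range of R values to use (default all).
#' @param n_bins number of log-R bins.
#' @param min_sep minimum genomic separation |i-j| of pairs entering the
#'   fit (excludes the trivially bonded near-diagonal).
#' @param saturation maximum count treated as informative: pairs in contact
#'   in (nearly) every frame have censored counts and flatten the ridge at
#'   small R, so pass about half the frame count when `C` holds per-frame
#'   counts (done automatically for `ccm_contacts` input). `Inf` disables.
#' @param min_count minimum count; single-event pairs are shot-noise
#'   dominated. 0 disables.
#' @return List with `lambda`, `stderr`, `ridge` (data frame).
#' @export
contact_distance_exponent <- function(C, R, fit_range = NULL, n_bins = 40,
                                      min_sep = 2, saturation = NULL,
                                      min_count = 0) {
  if (is.null(saturation))
    saturation <- if (inherits(C, "ccm_contacts")) 0.5 * C$n_frames else Inf
  C <- as_contact_counts(C)
  if (inherits(R, "ccm_distances")) R <- R$R
  n <- nrow(C)
  sep <- abs(row(C) - col(C))
  keep <- upper.tri(C) & sep >= min_sep & C > 0 & R > 0 &
    C <= saturation & C >= min_count
  r <- R[keep]; invc <- 1 / C[keep]
  if (!is.null(fit_range)) {
    sel <- r >= fit_range[1] & r <= fit_range[2]
    r <- r[sel]; invc <- invc[sel]
  }
  if (length(r) < 10) stop("too few informative pairs")
  lx <- log(r); ly <- log(invc)
  bins <- cut(lx, breaks = n_bins)
  xb <- tapply(lx, bins, stats::median)
  yb <- tapply(ly, bins, stats::median)
  ok <- is.finite(xb) & is.finite(yb)
  fit <- stats::lm(yb[ok] ~ xb[ok])
  cf <- suppressWarnings(summary(fit))$coefficients
  list(lambda = unname(cf[2, "Estimate"]), stderr = unname(cf[2, "Std. Error"]),
       ridge = data.frame(logR = as.numeric(xb[ok]),
                          log_invC = as.numeric(yb[ok])))
}

#' Pearson similarity between Ward linkage matrices
#'
#' `wlm_similarity` is the Pearson correlation over upper-triangle entries
#' of two WLMs; `wlm_similarity_matrix` computes it for every unordered pair
#' of single-cell WLMs and returns the population P(rho) together with its
#' mean, the summary used to quantify cell-to-cell structural
#' heterogeneity.
#'
#' @param W_a,W_b equal-dimension WLMs (any matrices).
#' @return `wlm_similarity`: scalar Pearson rho.
#' @export
wlm_similarity <- function(W_a, W_b) {
  stopifnot(all(dim(W_a) == dim(W_b)))
  ut <- upper.tri(W_a)
  stats::cor(W_a[ut], W_b[ut])
}

#' @rdname wlm_similarity
#' @param wlms list of single-cell WLMs.
#' @return `wlm_similarity_matrix`: list with `rho` (vector over unordered
#'   pairs), `mean_rho`, and the full pairwise matrix `P`.
#' @export
wlm_similarity_matrix <- function(wlms) {
  m <- length(wlms)
  P <- diag(1, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    P[i, j] <- P[j, i] <- wlm_similarity(wlms[[i]], wlms[[j]])
  }
  rho <- P[upper.tri(P)]
  list(rho = rho, mean_rho = mean(rho), P = P)
}

#' Gyration tensor size and shape descriptors
#'
#' Computes the gyration tensor of a point set and derives the squared
#' radius of gyration `Rg^2 = l1 + l2 + l3` (eigenvalues `l1 >= l2 >= l3`),
#' the relative shape anisotropy
#' `kappa^2 = 1 - 3 (l1 l2 + l2 l3 + l3 l1) / (l1 + l2 + l3)^2` (0 for
#' isotropic shapes, 1 for a rod) and the shape parameter
#' `S = 27 (l1 - lbar)(l2 - lbar)(l3 - lbar) / (l1 + l2 + l3)^3`
#' (prolate S > 0, oblate S < 0, bounded in `[-1/4, 2]`).
#'
#' @param points `n x 3` coordinate matrix (n >= 2).
#' @return List with `Rg`, `kappa2`, `S`, `eigenvalues`.
#' @export
gyration_shape <- function(points) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 2, ncol(points) == 3)
  xc <- sweep(points, 2, colMeans(points))
  G <- crossprod(xc) / nrow(points)
  ev <- sort(eigen(G, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  tr <- sum(ev)
  lbar <- tr / 3
  kappa2 <- if (tr > 0) 1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] +
                                   ev[1] * ev[3]) / tr^2 else 0
  S <- if (tr > 0) 27 * prod(ev - lbar) / tr^3 else 0
  list(Rg = sqrt(tr), kappa2 = kappa2, S = S, eigenvalues = ev)
}

#' Cell-to-cell variation of TAD size and shape
#'
#' Treats each bead span between the anchors of a loop as a TAD, computes
#' time-averaged `<Rg^2>`, `<kappa^2>` and `<S>` per TAD per trajectory, and
#' normalizes each by its cross-trajectory mean, yielding the distributions
#' whose width measures how strongly TAD conformations vary between cells.
#'
#' @param trajectories list of [trajectory()] objects ("cells").
#' @param loops a [loop_set()] delimiting the TADs.
#' @return List with `per_cell` (data frame: trajectory, tad, rg2, kappa2,
#'   S) and `normalized` (same with each value divided by the TAD's
#'   cross-trajectory mean).
#' @export
tad_shape_stats <- function(trajectories, loops) {
  if (inherits(trajectories, "ccm_trajectory"))
    trajectories <- list(trajectories)
  a <- loops$anchors
  if (nrow(a) == 0) stop("empty loop set: no TADs to analyze")
  rows <- list()
  for (ci in seq_along(trajectories)) {
    tr <- trajectories[[ci]]
    for (ti in seq_len(nrow(a))) {
      beads <- a[ti, 1]:a[ti, 2]
      vals <- vapply(seq_len(n_frames(tr)), function(k) {
        gs <- gyration_shape(traj_frame(tr, k)[beads, , drop = FALSE])
        c(gs$Rg^2, gs$kappa2, gs$S)
      }, numeric(3))
      rows[[length(rows) + 1]] <-
        data.frame(cell = ci, tad = ti, rg2 = mean(vals[1, ]),
                   kappa2 = mean(vals[2, ]), S = mean(vals[3, ]))
    }
  }
  per_cell <- do.call(rbind, rows)
  normalized <- per_cell
  for (col in c("rg2", "kappa2", "S")) {
    mu <- stats::ave(per_cell[[col]], per_cell$tad)
    normalized[[col]] <- ifelse(abs(mu) > 0, per_cell[[col]] / mu, NA_real_)
  }
  list(per_cell = per_cell, normalized = normalized)
}

#' Chromosome droplet detection and coarsening
#'
#' `detect_droplets` partitions the beads of one conformation into
#' chromosome droplets: connected components of the graph whose edges join
#' bead pairs closer than `linkage_radius` with genomic separation
#' `|i - j| > 1` (so a fully extended chain contains no droplet), keeping
#' components of at least `min_size` beads. `droplet_growth` applies the
#' detector to every frame and reports `n(t)`, the mean number of base
#' pairs per droplet, together with the power-law growth exponent fitted
#' over the intermediate coarsening window (droplet mass between
#' `window[1]` and `window[2]` of the chain total); coalescence-driven
#' coarsening gives `n(t) ~ t`.
#'
#' @param conformation `n x 3` coordinate matrix.
#' @param linkage_radius edge threshold in sigma (default the contact
#'   radius, 2 sigma).
#' @param min_size minimum droplet size in beads.
#' @return `detect_droplets`: list of integer vectors (bead indices per
#'   droplet).
#' @export
detect_droplets <- function(conformation, linkage_radius = 2, min_size = 10) {
  x <- as.matrix(conformation)
  labels <- .cpp_droplet_components(x, linkage_radius)
  comps <- split(seq_len(nrow(x)), labels)
  comps <- comps[vapply(comps, length, integer(1)) >= min_size]
  names(comps) <- NULL
  comps
}

#' @rdname detect_droplets
#' @param traj a [trajectory()] of a collapsing chain.
#' @param bead_bp bp per bead.
#' @param window intermediate coarsening window as fractions of total chain
#'   mass spanned by the mean droplet.
#' @return `droplet_growth`: list with `trace` (data frame t, n_droplets,
#'   n_bp; NA where no droplet exceeds `min_size`), `exponent`, `stderr`,
#'   `fit_window`.
#' @export
droplet_growth <- function(traj, linkage_radius = 2, min_size = 10,
                           bead_bp = 1200, window = c(0.05, 0.30)) {
  nf <- n_frames(traj)
  nb <- n_beads(traj)
  res <- vapply(seq_len(nf), function(k) {
    comps <- detect_droplets(traj_frame(traj, k), linkage_radius, min_size)
    if (length(comps) == 0) return(c(0, NA_real_))
    sizes <- vapply(comps, length, integer(1))
    c(length(comps), mean(sizes) * bead_bp)
  }, numeric(2))
  trace <- data.frame(t = traj$times, n_droplets = res[1, ], n_bp = res[2, ])
  total_bp <- nb * bead_bp
  sel <- is.finite(trace$n_bp) & trace$t > 0 &
    trace$n_bp >= window[1] * total_bp & trace$n_bp <= window[2] * total_bp
  exponent <- NA_real_; stderr <- NA_real_
  if (sum(sel) >= 3) {
    fit <- fit_power_law(trace$t[sel], trace$n_bp[sel])
    exponent <- fit$exponent; stderr <- fit$stderr
  }
  list(trace = trace, exponent = exponent, stderr = stderr,
       fit_window = window)
}
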