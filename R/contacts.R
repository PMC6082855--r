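#' Contact map from a trajectory
#'
#' Counts, for every bead pair (i < j, |i-j| >= 1), the number of
#' (frame, pair) events with distance below the contact radius
#' `r_contact * sigma` (2 sigma by default). The probability matrix is
#' `P_ij = C_ij / n_frames`. Each pair is counted once per frame.
#'
#' @param traj a [trajectory()].
#' @param params a [ccm_parameters()] supplying `r_contact` and `bead_bp`
#'   (defaults to the trajectory's model parameters if present).
#' @return List of class `ccm_contacts` with elements `C` (counts),
#'   `P` (probabilities), `n_frames`, `bin_bp`.
#' @export
contact_map <- function(traj, params = NULL) {
  if (is.null(params)) {
    if (is.null(traj$model)) stop("supply params or a trajectory with a model")
    params <- traj$model$params
  }
  if (n_frames(traj) < 1) stop("empty trajectory")
  C <- .cpp_contact_counts(traj$frames, params$r_contact)
  diag(C) <- 0
  structure(list(C = C, P = C / n_frames(traj), n_frames = n_frames(traj),
                 bin_bp = params$bead_bp), class = "ccm_contacts")
}

as_contact_counts <- function(x) {
  if (inherits(x, "ccm_contacts")) x$C
  else if (inherits(x, "ccm_contact_matrix")) x$mat
  else as.matrix(x)
}

#' Contact probability versus genomic separation
#'
#' `P(s)` is the mean of `P_ij` over all pairs with `|i - j| = s`. A
#' log-binned variant (default 20 bins per decade) reduces noise at large s.
#'
#' @param contacts a `ccm_contacts` (from [contact_map()]) or a probability
#'   matrix.
#' @param log_bin logical; also return a log-binned curve.
#' @param bins_per_decade log-bin density.
#' @param bin_bp bp per bin, used for the bp-valued abscissa.
#' @return Data frame with columns `s` (beads), `s_bp`, `P`, and (in the
#'   attribute `"log_binned"`) the binned curve.
#' @export
contact_probability <- function(contacts, log_bin = TRUE,
                                bins_per_decade = 20, bin_bp = NULL) {
  if (inherits(contacts, "ccm_contacts")) {
    P <- contacts$P
    if (is.null(bin_bp)) bin_bp <- contacts$bin_bp
  } else {
    P <- as.matrix(contacts)
    if (is.null(bin_bp)) bin_bp <- 1200
  }
  n <- nrow(P)
  s <- seq_len(n - 1)
  ps <- vapply(s, function(k) {
    idx <- seq_len(n - k)
    mean(P[cbind(idx, idx + k)])
  }, numeric(1))
  out <- data.frame(s = s, s_bp = s * bin_bp, P = ps)
  if (log_bin) {
    lb <- log_bin_curve(out$s, out$P, bins_per_decade)
    lb$s_bp <- lb$x * bin_bp
    attr(out, "log_binned") <- data.frame(s = lb$x, s_bp = lb$s_bp, P = lb$y)
  }
  out
}

log_bin_curve <- function(x, y, bins_per_decade = 20) {
  keep <- x > 0 & is.finite(y)
  x <- x[keep]; y <- y[keep]
  b <- floor(log10(x) * bins_per_decade)
  xb <- tapply(x, b, function(v) exp(mean(log(v))))
  yb <- tapply(y, b, mean)
  data.frame(x = as.numeric(xb), y = as.numeric(yb))
}

#' Least-squares power-law exponent in log-log space
#'
#' Fits `log(y) ~ log(x)` by ordinary least squares over `fit_range` and
#' returns the slope (the power-law exponent) with its standard error.
#' Exact on noiseless planted power laws.
#'
#' @param x,y positive numeric vectors.
#' @param fit_range length-2 numeric, inclusive range of `x` to fit.
#' @return List with `exponent`, `stderr`, `prefactor`, `n_points`.
#' @export
fit_power_law <- function(x, y, fit_range = range(x)) {
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0 &
    x >= fit_range[1] & x <= fit_range[2]
  if (sum(keep) < 2) stop("fewer than 2 positive points in fit range")
  lx <- log(x[keep]); ly <- log(y[keep])
  fit <- stats::lm(ly ~ lx)
  cf <- suppressWarnings(summary(fit))$coefficients
  list(exponent = unname(cf["lx", "Estimate"]),
       stderr = unname(cf["lx", "Std. Error"]),
       prefactor = exp(unname(cf["(Intercept)", "Estimate"])),
       n_points = sum(keep))
}

#' Crossover scale of a two-regime contact probability curve
#'
#' Fits a continuous two-segment power law (a hinge in log-log space) to
#' `P(s)`, scanning all interior breakpoints and minimizing total squared
#' error. Returns the breakpoint (the crossover scale s*) in beads and bp
#' together with the two slopes. When the best breakpoint lands within
#' `edge` of either end of the fitted range, or the slope change is
#' negligible, the curve is flagged as having no crossover.
#'
#' @param s,P positive vectors (typically the log-binned `P(s)` curve).
#' @param bin_bp bp per bead for the bp-valued result.
#' @param edge fraction of the (log) range treated as boundary.
#' @return List with `s_star`, `s_star_bp`, `slope_small`, `slope_large`,
#'   `no_crossover`.
#' @export
crossover_scale <- function(s, P, bin_bp = 1200, edge = 0.1) {
  keep <- is.finite(s) & is.finite(P) & s > 0 & P > 0
  x <- log(s[keep]); y <- log(P[keep])
  o <- order(x); x <- x[o]; y <- y[o]
  if (diff(range(x)) < 1.5 * log(10))
    stop("curve must span at least 1.5 decades")
  cand <- x[x > stats::quantile(x, 0.05) & x < stats::quantile(x, 0.95)]
  best <- NULL
  for (b in unique(cand)) {
    h <- pmax(x - b, 0)
    fit <- stats::lm(y ~ x + h)
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, b = b, coef = stats::coef(fit))
  }
  slope1 <- unname(best$coef["x"])
  slope2 <- slope1 + unname(best$coef["h"])
  xr <- range(x)
  near_edge <- (best$b - xr[1]) < edge * diff(xr) ||
    (xr[2] - best$b) < edge * diff(xr)
  no_crossover <- near_edge || abs(slope2 - slope1) < 0.05
  list(s_star = exp(best$b), s_star_bp = exp(best$b) * bin_bp,
       slope_small = slope1, slope_large = slope2,
       no_crossover = no_crossover)
}

#' Subchain contact number A(s)
#'
#' For each window size s, the mean over all windows `[k, k+s)` of the
#' number of contacts the window forms with the rest of the chain. For a
#' chain that is compact on all scales `A(s) ~ s^(2/3)`; an ideal chain
#' gives `A(s) ~ s`.
#'
#' @param contacts a `ccm_contacts` or a counts matrix.
#' @param s window sizes (beads); defaults to a log-spaced grid.
#' @return Data frame with columns `s` and `A`.
#' @export
subchain_contacts <- function(contacts, s = NULL) {
  C <- as_contact_counts(contacts)
  n <- nrow(C)
  if (is.null(s))
    s <- unique(round(10^seq(0, log10(n - 1), length.out = 30)))
  stopifnot(all(s >= 1), all(s < n))
  # 2-D prefix sums for O(1) window-vs-rest contact sums
  S <- apply(apply(C, 2, cumsum), 1, cumsum)  # S[j, i] = sum C[1:i, 1:j]
  block <- function(a, b, cc, d) {  # sum of C[a:b, cc:d]
    S0 <- function(i, j) if (i < 1 || j < 1) 0 else S[j, i]
    S0(b, d) - S0(a - 1, d) - S0(b, cc - 1) + S0(a - 1, cc - 1)
  }
  A <- vapply(s, function(sz) {
    ks <- seq_len(n - sz + 1)
    vals <- vapply(ks, function(k) {
      tot <- block(k, k + sz - 1, 1, n)
      within <- block(k, k + sz - 1, k, k + sz - 1)
      tot - within
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  data.frame(s = s, A = A)
}

#' Spearman correlation map of a contact matrix
#'
#' Entry (i, j) is the Spearman rank correlation of rows i and j of the
#' contact matrix, computed after masking a diagonal band (default width 1
#' bead on each side, plus the diagonal itself) whose near-deterministic
#' contacts would otherwise dominate the ranks. The map is symmetric with a
#' unit diagonal; checkerboard compartment patterns appear as blocks of
#' positive correlation.
#'
#' @param contacts a `ccm_contacts`, `ccm_contact_matrix` or square matrix.
#' @param exclude_band half-width (in beads) of the diagonal band excluded
#'   from each row before ranking.
#' @return Symmetric correlation matrix with entries in `[-1, 1]`.
#' @export
spearman_map <- function(contacts, exclude_band = 1) {
  M <- as_contact_counts(contacts)
  n <- nrow(M)
  Mna <- M
  for (d in 0:exclude_band) {
    idx <- seq_len(n - d)
    Mna[cbind(idx, idx + d)] <- NA
    Mna[cbind(idx + d, idx)] <- NA
  }
  R <- apply(Mna, 1, rank, na.last = "keep")  # column k = ranks of row k
  S <- suppressWarnings(stats::cor(R, use = "pairwise.complete.obs",
                                   method = "pearson"))
  S[!is.finite(S)] <- 0
  diag(S) <- 1
  (S + t(S)) / 2
}

#' Two-way compartment assignment by spectral co-clustering
#'
#' Bi-clusters the (shifted non-negative) Spearman correlation map with the
#' bipartite spectral graph partitioning algorithm: normalize
#' `A_n = D_r^(-1/2) A D_c^(-1/2)`, take the second left/right singular
#' vectors, and k-means the normalized spectral coordinates into
#' `n_clusters` groups. For a symmetric map the row and column partitions
#' coincide and the result is a per-bead compartment labeling.
#'
#' @param map symmetric correlation (or affinity) matrix.
#' @param n_clusters number of clusters (2 for A/B compartments).
#' @param seed seed for the k-means step.
#' @return Integer vector of cluster labels (1-based). A constant input map
#'   is degenerate and raises an error.
#' @export
compartments_cocluster <- function(map, n_clusters = 2, seed = 1L) {
  A <- as.matrix(map)
  A <- A - min(A)  # shift to non-negative
  if (max(A) <= 0 || stats::sd(A) == 0)
    stop("degenerate (constant) correlation map: no compartment structure")
  r <- rowSums(A); c <- colSums(A)
  r[r <= 0] <- min(r[r > 0]); c[c <= 0] <- min(c[c > 0])
  An <- sweep(sweep(A, 1, sqrt(r), "/"), 2, sqrt(c), "/")
  nsv <- 1 + ceiling(log2(n_clusters))
  sv <- svd(An, nu = nsv, nv = nsv)
  z <- cbind(sv$u[, 2:nsv, drop = FALSE] / sqrt(r),
             sv$v[, 2:nsv, drop = FALSE] / sqrt(c))
  km <- with_seed(seed, stats::kmeans(z, centers = n_clusters, nstart = 25))
  km$cluster
}

#' Adjusted mutual information between two labelings
#'
#' Mutual information between two partitions corrected by its expectation
#' under random labelings with the same cluster sizes (hypergeometric
#' model), normalized by `max(H_U, H_V) - E[MI]`. Identical partitions (up
#' to label permutation) score 1; independent random partitions score about
#' 0.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @param average normalization denominator: "max" (default) or "mean".
#' @return AMI score in (-1, 1].
#' @export
ami <- function(labels_a, labels_b, average = c("max", "mean")) {
  average <- match.arg(average)
  stopifnot(length(labels_a) == length(labels_b))
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  a <- rowSums(tab); b <- colSums(tab)
  # observed MI (natural log)
  p <- tab / n
  pa <- a / n; pb <- b / n
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (tab[i, j] > 0)
      mi <- mi + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
  }
  # expected MI under the permutation (hypergeometric) model
  emi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    ai <- a[i]; bj <- b[j]
    nij_min <- max(1, ai + bj - n)
    nij_max <- min(ai, bj)
    if (nij_min > nij_max) next
    nij <- nij_min:nij_max
    lw <- lchoose(bj, nij) + lchoose(n - bj, ai - nij) - lchoose(n, ai)
    term <- (nij / n) * log(n * nij / (ai * bj))
    emi <- emi + sum(exp(lw) * term)
  }
  hu <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hv <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  denom <- switch(average, max = max(hu, hv), mean = (hu + hv) / 2) - emi
  if (abs(denom) < 1e-15) return(1)  # both partitions trivial
  unname((mi - emi) / denom)
}

#' Directionality index profile and TAD calling
#'
#' For each bead, the directionality index contrasts its upstream contact
#' sum A (within `window` beads) with its downstream sum B:
#' `DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)` with
#' `E = (A + B) / 2`; `DI = 0` when `A = B = 0`. TAD boundaries are called
#' at persistent sign changes of the DI profile: a switch from negative to
#' positive that persists for at least `persistence` beads on each side
#' opens a new domain. This deterministic sign-persistence caller replaces
#' the HMM post-processing of the original directionality-index method.
#'
#' @param contacts a `ccm_contacts` or counts matrix.
#' @param window window size in beads (the classical choice is the
#'   2 Mb-equivalent).
#' @param persistence minimum run length (beads) of a consistent DI sign for
#'   a boundary call; defaults to `max(2, window / 4)`.
#' @return `directionality_index` returns a numeric DI vector; `call_tads`
#'   returns a data frame of intervals with bead and bp coordinates.
#' @export
directionality_index <- function(contacts, window = 100) {
  C <- as_contact_counts(contacts)
  n <- nrow(C)
  if (window >= n / 2) stop("window must be smaller than half the chain")
  di <- numeric(n)
  for (i in seq_len(n)) {
    up <- max(1, i - window):max(1, i - 1)
    dn <- min(n, i + 1):min(n, i + window)
    A <- if (i == 1) 0 else sum(C[i, up])
    B <- if (i == n) 0 else sum(C[i, dn])
    E <- (A + B) / 2
    di[i] <- if (E == 0) 0 else sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
  }
  di
}

#' @rdname directionality_index
#' @param di DI profile from [directionality_index()].
#' @param bin_bp bp per bead.
#' @param start genomic start of bead 1 (bp).
#' @export
call_tads <- function(di, persistence = NULL, bin_bp = 1200, start = 0,
                      window = 100) {
  n <- length(di)
  if (is.null(persistence)) persistence <- max(2, floor(window / 4))
  sgn <- sign(di)
  # run-length view of the sign sequence, ignoring zeros
  runs <- rle(sgn)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  # boundaries: start of a persistent positive run that follows a persistent
  # negative run (downstream-bias onset after upstream-bias tail)
  bounds <- integer(0)
  neg_ok <- FALSE
  for (k in seq_along(runs$values)) {
    v <- runs$values[k]; len <- runs$lengths[k]
    if (v < 0 && len >= persistence) neg_ok <- TRUE
    else if (v > 0 && len >= persistence) {
      if (neg_ok) bounds <- c(bounds, starts[k])
      neg_ok <- FALSE
    }
  }
  edges <- sort(unique(c(1L, bounds, n + 1L)))
  if (length(edges) < 2) return(data.frame())
  out <- data.frame(start_bead = utils::head(edges, -1),
                    end_bead = utils::tail(edges, -1) - 1L)
  # keep only domains with interior DI signal
  keep <- out$end_bead - out$start_bead + 1 >= persistence
  out <- out[keep, , drop = FALSE]
  out$start_bp <- start + (out$start_bead - 1) * bin_bp
  out$end_bp <- start + out$end_bead * bin_bp
  rownames(out) <- NULL
  out
}
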