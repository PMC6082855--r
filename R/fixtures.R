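# Synthetic inputs and analytic test trajectories.
#
# These generators stand in for real ChromHMM tracks, CTCF loop calls and
# simulated trajectories so that the whole pipeline can run and be tested
# without external data. All are deterministic under a fixed seed; the seed
# is applied to a locally scoped RNG state so callers' RNG streams are not
# disturbed.

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic block-copolymer annotation
#'
#' Generates alternating A/B blocks with geometrically distributed block
#' lengths, emulating the blocky arrangement of active and repressive
#' chromatin along a chromosome. Mean A- and B-block lengths are
#' `2 * fraction_A * mean_block_len` and `2 * (1-fraction_A) * mean_block_len`
#' so that the expected overall block length is `mean_block_len` and the
#' expected A fraction is `fraction_A`. The default A fraction 0.24 mirrors
#' the active/repressive ratio of the 12 Mbp chromosome-5 region used to
#' calibrate the model (2369 active vs 7631 repressive 1200-bp loci).
#'
#' @param n_beads number of beads.
#' @param mean_block_len mean block length in beads.
#' @param fraction_A expected fraction of A beads, in `[0, 1]`.
#' @param seed RNG seed.
#' @param bead_bp base pairs per bead (metadata only).
#' @return A [epigenome_annotation()].
#' @export
synth_annotation <- function(n_beads, mean_block_len = 50,
                             fraction_A = 2369 / (2369 + 7631), seed = 1L,
                             bead_bp = 1200) {
  stopifnot(fraction_A >= 0, fraction_A <= 1, n_beads >= 1,
            mean_block_len >= 1)
  if (fraction_A == 0)
    return(epigenome_annotation(rep("B", n_beads), bead_bp = bead_bp))
  if (fraction_A == 1)
    return(epigenome_annotation(rep("A", n_beads), bead_bp = bead_bp))
  mA <- max(1, 2 * fraction_A * mean_block_len)
  mB <- max(1, 2 * (1 - fraction_A) * mean_block_len)
  labels <- with_seed(seed, {
    out <- character(0)
    cur <- if (stats::runif(1) < fraction_A) "A" else "B"
    while (length(out) < n_beads) {
      m <- if (cur == "A") mA else mB
      len <- stats::rgeom(1, prob = 1 / m) + 1L
      out <- c(out, rep(cur, len))
      cur <- if (cur == "A") "B" else "A"
    }
    out[seq_len(n_beads)]
  })
  epigenome_annotation(labels, bead_bp = bead_bp)
}

#' Synthetic loop-anchor set
#'
#' Draws anchor pairs with uniformly placed upstream anchors and
#' exponentially distributed spans (mean `mean_span`, minimum 2 beads),
#' emulating CTCF loop calls. With `nested = FALSE` the loops are laid down
#' left to right without overlap, giving a TAD-like tiling; with
#' `nested = TRUE` placement is unconstrained.
#'
#' @param n_beads chain length.
#' @param n_loops number of loops requested (the non-nested mode may place
#'   fewer if the chain fills up).
#' @param mean_span mean anchor separation in beads.
#' @param seed RNG seed.
#' @param nested allow overlapping/nested loops (default FALSE).
#' @return A [loop_set()].
#' @export
synth_loops <- function(n_beads, n_loops, mean_span = 20, seed = 1L,
                        nested = FALSE) {
  stopifnot(n_loops >= 0, mean_span >= 2)
  if (n_loops == 0)
    return(loop_set(matrix(integer(0), ncol = 2), n_beads))
  with_seed(seed, {
    if (nested) {
      pairs <- matrix(NA_integer_, 0, 2)
      tries <- 0
      while (nrow(pairs) < n_loops && tries < 50) {
        tries <- tries + 1
        m <- 2L * (n_loops - nrow(pairs))
        span <- pmax(2L, as.integer(round(stats::rexp(m, 1 / mean_span))))
        i <- vapply(pmax(1L, n_beads - span),
                    function(mx) sample.int(mx, 1), integer(1))
        ok <- i + span <= n_beads
        pairs <- unique(rbind(pairs, cbind(i[ok], i[ok] + span[ok])))
      }
      if (nrow(pairs) > n_loops) pairs <- pairs[seq_len(n_loops), , drop = FALSE]
      loop_set(pairs, n_beads)
    } else {
      pairs <- matrix(NA_integer_, 0, 2)
      pos <- 1L
      gaps <- stats::rexp(n_loops, 1 / mean_span)  # spacing between loops
      spans <- pmax(2L, as.integer(round(stats::rexp(n_loops, 1 / mean_span))))
      for (k in seq_len(n_loops)) {
        i <- pos + as.integer(round(gaps[k] * 0.25))
        j <- i + spans[k]
        if (j > n_beads) break
        pairs <- rbind(pairs, c(i, j))
        pos <- j + 1L
      }
      loop_set(pairs, n_beads)
    }
  })
}

#' Analytic test trajectories
#'
#' Generates trajectories with known dynamical properties, used to validate
#' the dynamics estimators: `static` (zero displacement), `ballistic`
#' (`r_i(t) = r_i(0) + v t` with per-bead random directions), `brownian`
#' (independent Gaussian increments of variance `2 D dt` per coordinate) and
#' `caged` (discrete Ornstein-Uhlenbeck / AR(1) walk of relaxation time
#' `tau` and cage size `cage`, a bounded stand-in for caged loci).
#'
#' @param kind one of "static", "ballistic", "brownian", "caged".
#' @param n_beads number of independent beads.
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing in reduced time.
#' @param speed ballistic speed (sigma per unit time).
#' @param D diffusion coefficient for the brownian kind.
#' @param tau,cage OU relaxation time and cage standard deviation.
#' @param spacing initial bead spacing along x.
#' @param seed RNG seed.
#' @return A [trajectory()].
#' @export
synth_trajectory <- function(kind = c("static", "ballistic", "brownian",
                                      "caged"),
                             n_beads = 100, n_frames = 100, dt = 1,
                             speed = 1, D = 1, tau = 10, cage = 1,
                             spacing = 1, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_frames >= 2)
  x0 <- cbind(spacing * (seq_len(n_beads) - 1), 0, 0)
  fr <- array(0, dim = c(n_beads, 3, n_frames))
  tt <- dt * (seq_len(n_frames) - 1)
  with_seed(seed, {
    if (kind == "static") {
      for (k in seq_len(n_frames)) fr[, , k] <- x0
    } else if (kind == "ballistic") {
      v <- matrix(stats::rnorm(3 * n_beads), n_beads, 3)
      v <- speed * v / sqrt(rowSums(v^2))
      for (k in seq_len(n_frames)) fr[, , k] <- x0 + v * tt[k]
    } else if (kind == "brownian") {
      sd_inc <- sqrt(2 * D * dt)
      cur <- x0
      fr[, , 1] <- cur
      for (k in 2:n_frames) {
        cur <- cur + matrix(stats::rnorm(3 * n_beads, sd = sd_inc),
                            n_beads, 3)
        fr[, , k] <- cur
      }
    } else {  # caged: AR(1) with stationary sd = cage
      a <- exp(-dt / tau)
      sd_inc <- cage * sqrt(1 - a^2)
      dx <- matrix(stats::rnorm(3 * n_beads, sd = cage), n_beads, 3)
      fr[, , 1] <- x0 + dx
      for (k in 2:n_frames) {
        dx <- a * dx + matrix(stats::rnorm(3 * n_beads, sd = sd_inc),
                              n_beads, 3)
        fr[, , k] <- x0 + dx
      }
    }
  })
  trajectory(fr, tt, seed = seed, integrator = kind)
}
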