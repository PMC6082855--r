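#' Trajectory container
#'
#' A time-ordered set of conformations. Frames are stored as an
#' `n_beads x 3 x n_frames` array in sigma units, with strictly increasing
#' reduced-unit frame times; the seed and integrator used to generate the
#' trajectory are recorded for provenance.
#'
#' @param frames numeric array `n_beads x 3 x n_frames`.
#' @param times numeric vector of reduced-unit frame times.
#' @param seed integer seed recorded for provenance (NA for analytic
#'   fixtures).
#' @param model optional [energy_model()] reference.
#' @param integrator character tag ("brownian", "langevin", or a fixture
#'   kind).
#' @param ekin optional per-frame kinetic energy (Langevin runs).
#' @return An object of class `ccm_trajectory`.
#' @export
trajectory <- function(frames, times, seed = NA_integer_, model = NULL,
                       integrator = "unknown", ekin = NULL) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[2] == 3,
            dim(frames)[3] == length(times), length(times) >= 1)
  if (any(!is.finite(frames))) stop("non-finite coordinates in trajectory")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(frames = frames, times = as.numeric(times), seed = seed,
                 model = model, integrator = integrator, ekin = ekin),
            class = "ccm_trajectory")
}

#' @export
print.ccm_trajectory <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("CCM trajectory: %d beads, %d frames, t in [%g, %g] (%s, seed %s)\n",
              d[1], d[3], x$times[1], x$times[length(x$times)],
              x$integrator, as.character(x$seed)))
  invisible(x)
}

#' Number of frames / beads in a trajectory
#' @param traj a `ccm_trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' @rdname n_frames
#' @export
n_beads <- function(traj) dim(traj$frames)[1]

#' Extract one frame as an n x 3 matrix
#' @param traj a `ccm_trajectory`.
#' @param k frame index (1-based).
#' @return Numeric matrix `n_beads x 3`.
#' @export
traj_frame <- function(traj, k) traj$frames[, , k, drop = TRUE]

#' Center-of-mass of every frame
#' @param traj a `ccm_trajectory`.
#' @return `n_frames x 3` matrix of center-of-mass coordinates.
#' @export
traj_com <- function(traj) {
  t(apply(traj$frames, c(2, 3), mean))
}

#' Radius of gyration of every frame
#' @param traj a `ccm_trajectory`.
#' @return Numeric vector of length `n_frames`.
#' @export
traj_rg <- function(traj) {
  vapply(seq_len(n_frames(traj)), function(k) {
    x <- traj_frame(traj, k)
    xc <- sweep(x, 2, colMeans(x))
    sqrt(sum(xc^2) / nrow(x))
  }, numeric(1))
}

#' Concatenate the frames of several trajectories of equal bead count
#' @param trajs list of `ccm_trajectory` objects.
#' @return A single `ccm_trajectory` (times are taken from the first; only
#'   meaningful for equal-length, equal-timing ensembles).
#' @keywords internal
bind_trajectories <- function(trajs) {
  stopifnot(length(trajs) >= 1)
  n <- n_beads(trajs[[1]])
  fr <- array(unlist(lapply(trajs, function(t) t$frames)),
              dim = c(n, 3, sum(vapply(trajs, n_frames, integer(1)))))
  tt <- seq_len(dim(fr)[3])
  trajectory(fr, tt, seed = trajs[[1]]$seed, model = trajs[[1]]$model,
             integrator = "bound")
}

#' Write / read a trajectory as XYZ text
#'
#' Plain multi-frame XYZ: per frame a bead-count line, a comment line holding
#' the frame time, then one `<label> x y z` line per bead. Coordinates stay
#' in sigma units.
#'
#' @param traj a `ccm_trajectory`.
#' @param path file path.
#' @param labels optional per-bead labels used as atom names (default "C").
#' @export
write_xyz <- function(traj, path, labels = NULL) {
  n <- n_beads(traj)
  if (is.null(labels)) labels <- rep("C", n)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    x <- traj_frame(traj, k)
    writeLines(c(sprintf("%d", n), sprintf("t= %.10g", traj$times[k]),
                 sprintf("%s %.8f %.8f %.8f", labels, x[, 1], x[, 2], x[, 3])),
               con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @return `read_xyz` returns a `ccm_trajectory`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  times <- numeric(0)
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) stop("malformed XYZ: expected bead count at line ", i)
    tm <- suppressWarnings(as.numeric(sub("^t= *", "", lines[i + 1L])))
    body <- lines[(i + 2L):(i + 1L + n)]
    m <- do.call(rbind, lapply(strsplit(body, "[[:space:]]+"), function(f)
      as.numeric(f[2:4])))
    frames[[length(frames) + 1L]] <- m
    times <- c(times, if (is.na(tm)) length(frames) else tm)
    i <- i + 2L + n
  }
  fr <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  trajectory(fr, times, integrator = "xyz")
}

#' Binary trajectory container
#'
#' Serializes the full trajectory object (frames, times, seed, integrator
#' and model reference) to a single binary file via R's serialization.
#' Compact and lossless, for working storage; use [write_xyz()] for
#' interoperable text output.
#'
#' @param traj a `ccm_trajectory`.
#' @param path file path (conventionally `.traj.rds`).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ccm_trajectory"))
  saveRDS(traj, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory` returns the `ccm_trajectory`.
#' @export
read_trajectory <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "ccm_trajectory"))
  obj
}
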