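#' Extended initial conformation
#'
#' Builds a self-avoiding near-straight chain: consecutive bonds at the
#' FENE/WCA rest length (about 0.97 sigma) pointing along x with a small
#' random transverse jitter, so no pair comes closer than 0.9 sigma. Chains
#' are collapsed by running dynamics from this extended start.
#'
#' @param model a [energy_model()].
#' @param seed RNG seed.
#' @param jitter transverse jitter amplitude in sigma.
#' @return `n_beads x 3` numeric matrix.
#' @export
init_extended <- function(model, seed = 1L, jitter = 0.1) {
  n <- model$params$n_beads
  b0 <- 0.97  # FENE + WCA rest length
  with_seed(seed, {
    dy <- stats::runif(n, -jitter, jitter)
    dz <- stats::runif(n, -jitter, jitter)
    x <- b0 * sqrt(1 - (jitter * 2)^2) * (seq_len(n) - 1)
    cbind(x = x, y = dy, z = dz)
  })
}

#' Brownian dynamics (overdamped, high friction)
#'
#' First-order Euler-Maruyama integration of the overdamped Langevin
#' equation: `x <- x + dt * F / friction + sqrt(2 kT dt / friction) * noise`.
#' This is the integrator used for dynamical observables (MSD, scattering
#' functions, Van Hove), where the physically relevant high-friction limit
#' matters. Runs are bit-exact reproducible for a given seed.
#'
#' The timestep must resolve the stiffest force; with the default FENE
#' constants and unit friction, `dt <= 1e-3` is stable and `dt = 1e-4` is
#' the conservative default.
#'
#' @param conformation starting `n_beads x 3` matrix (sigma units).
#' @param model a [energy_model()].
#' @param n_steps number of integration steps.
#' @param dt timestep in reduced time units.
#' @param friction friction coefficient (reduced units; monomer diffusion
#'   constant is kT / friction).
#' @param seed RNG seed (recorded in the trajectory).
#' @param save_every store a frame every this many steps.
#' @param skin Verlet-list skin in sigma; results are skin-independent (the
#'   pair list is exact within the cutoff), it only tunes rebuild frequency.
#' @return A [trajectory()].
#' @export
run_brownian <- function(conformation, model, n_steps, dt = 1e-4,
                         friction = 1, seed = 1L, save_every = 100L,
                         skin = 0.4) {
  conformation <- as.matrix(conformation)
  stopifnot(nrow(conformation) == model$params$n_beads, n_steps >= 1,
            dt > 0, friction > 0, skin > 0)
  out <- .cpp_run_bd(conformation, labels_cpp(model), loops_cpp(model),
                     model_pars_cpp(model), as.integer(n_steps), dt, friction,
                     model$params$temperature, as.numeric(seed),
                     as.integer(save_every), model$ideal, skin)
  trajectory(out$frames, out$times, seed = seed, model = model,
             integrator = "brownian")
}

#' Langevin dynamics (inertial, low friction)
#'
#' BAOAB-split velocity Langevin integration with unit bead mass. Low
#' friction accelerates conformational sampling and is the integrator of
#' choice for generating equilibrated collapsed structures; dynamical
#' observables should use [run_brownian()]. Per-frame kinetic energy is
#' recorded so the thermostat can be checked against equipartition
#' (`<E_kin> = (3/2) N kT`).
#'
#' @inheritParams run_brownian
#' @param friction Langevin friction (collision rate); 0 gives pure
#'   velocity-Verlet (NVE).
#' @return A [trajectory()] with an `ekin` field.
#' @export
run_langevin <- function(conformation, model, n_steps, dt = 0.01,
                         friction = 0.1, seed = 1L, save_every = 100L,
                         skin = 0.4) {
  conformation <- as.matrix(conformation)
  stopifnot(nrow(conformation) == model$params$n_beads, n_steps >= 1,
            dt > 0, friction >= 0, skin > 0)
  out <- .cpp_run_langevin(conformation, labels_cpp(model), loops_cpp(model),
                           model_pars_cpp(model), as.integer(n_steps), dt,
                           friction, model$params$temperature,
                           as.numeric(seed), as.integer(save_every),
                           model$ideal, skin)
  trajectory(out$frames, out$times, seed = seed, model = model,
             integrator = "langevin", ekin = out$ekin)
}

#' Seconds per reduced time unit
#'
#' Maps the reduced Brownian time unit `tau = friction * sigma^2 / kT` to
#' seconds, with the friction coefficient taken from Stokes drag on a sphere
#' of diameter sigma: `friction = 6 pi eta (sigma / 2)`. Used to express
#' simulated dynamics in physical time.
#'
#' @param params a [ccm_parameters()] (sigma in nm).
#' @param viscosity nucleoplasm viscosity in Pa s.
#' @param kT thermal energy in joules (default room temperature).
#' @return Seconds per reduced time unit.
#' @export
map_time <- function(params, viscosity = 1, kT = 4.11e-21) {
  stopifnot(viscosity > 0, kT > 0)
  sigma_m <- params$sigma * 1e-9
  friction <- 6 * pi * viscosity * (sigma_m / 2)
  friction * sigma_m^2 / kT
}

#' Collapse a chain from an extended start (standard protocol)
#'
#' Runs the package's standard three-stage preparation: an extended start,
#' a short Brownian pre-run that closes far-apart loop bonds without
#' inertial overshoot, then low-friction Langevin annealing in chunks until
#' the radius of gyration plateaus (relative change below `tol` between
#' consecutive chunks), up to `max_chunks` chunks.
#'
#' @param model a [energy_model()].
#' @param seed RNG seed (chunk c uses `seed + c`).
#' @param pre_steps Brownian loop-closing steps (dt 1e-4).
#' @param chunk_steps Langevin steps per annealing chunk.
#' @param max_chunks annealing chunk cap.
#' @param dt,friction Langevin timestep and friction.
#' @param tol relative Rg change defining the plateau.
#' @return List with `conformation` (the collapsed frame), `rg` (per-chunk
#'   Rg trace) and `n_steps` (Langevin steps used).
#' @export
collapse_chain <- function(model, seed = 1L, pre_steps = 20000L,
                           chunk_steps = 50000L, max_chunks = 6L,
                           dt = 0.01, friction = 0.1, tol = 0.05) {
  x <- init_extended(model, seed = seed)
  if (pre_steps > 0) {
    pre <- run_brownian(x, model, pre_steps, dt = 1e-4, seed = seed,
                        save_every = as.integer(pre_steps))
    x <- traj_frame(pre, n_frames(pre))
  }
  rg <- numeric(0)
  used <- 0L
  for (chunk in seq_len(max_chunks)) {
    tr <- run_langevin(x, model, chunk_steps, dt = dt, friction = friction,
                       seed = seed + chunk, save_every = as.integer(chunk_steps))
    x <- traj_frame(tr, n_frames(tr))
    rg <- c(rg, traj_rg(tr)[n_frames(tr)])
    used <- used + as.integer(chunk_steps)
    compact <- rg[chunk] < 1.5 * model$params$n_beads^(1 / 3)
    if (chunk >= 2 && compact &&
        abs(rg[chunk] - rg[chunk - 1]) / rg[chunk - 1] < tol) break
  }
  list(conformation = x, rg = rg, n_steps = used)
}
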