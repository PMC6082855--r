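# End-to-end pipelines: configuration, run manifests, and the cmd_*()
# entry points the command-line script (inst/cli/ccm.R) dispatches to.

#' Read a pipeline configuration
#'
#' A single YAML file with sections `model` (any [ccm_parameters()] field
#' plus `bond`, `cutoff`), `fixtures` (`mean_block_len`, `fraction_A`,
#' `n_loops`, `mean_span`), `simulate` (`integrator`, `n_steps`, `dt`,
#' `friction`, `save_every`) and `analyze` (`di_window`, `n_clusters`).
#' Unknown keys fail fast with their key path.
#'
#' @param path YAML file path (NULL returns the defaults).
#' @return Nested named list of settings.
#' @export
read_ccm_config <- function(path = NULL) {
  defaults <- list(
    model = list(n_beads = 500L, bead_bp = 1200, sigma = 70, epsilon = 2.4,
                 eps_ratio = 11 / 9, r_contact = 2, temperature = 1,
                 cutoff = 2.5),
    fixtures = list(mean_block_len = 50, fraction_A = 2369 / 10000,
                    n_loops = 12L, mean_span = 20),
    simulate = list(integrator = "langevin", n_steps = 200000L, dt = 0.01,
                    friction = 0.1, save_every = 500L, pre_steps = 20000L),
    analyze = list(di_window = 40L, n_clusters = 2L))
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  for (sec in names(user)) {
    if (!sec %in% names(defaults))
      stop(sprintf("unknown config section '%s'", sec))
    for (key in names(user[[sec]])) {
      if (!key %in% names(defaults[[sec]]))
        stop(sprintf("unknown config key '%s.%s'", sec, key))
      defaults[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  defaults
}

config_model <- function(cfg, annotation = NULL, loops = NULL, seed = 1L) {
  m <- cfg$model
  params <- ccm_parameters(n_beads = m$n_beads, bead_bp = m$bead_bp,
                           sigma = m$sigma, epsilon = m$epsilon,
                           eps_ratio = m$eps_ratio, r_contact = m$r_contact,
                           temperature = m$temperature)
  if (is.null(annotation))
    annotation <- synth_annotation(m$n_beads, cfg$fixtures$mean_block_len,
                                   cfg$fixtures$fraction_A, seed = seed)
  if (is.null(loops))
    loops <- synth_loops(m$n_beads, cfg$fixtures$n_loops,
                         cfg$fixtures$mean_span, seed = seed)
  energy_model(params, annotation, loops, cutoff = m$cutoff)
}

write_manifest <- function(out_dir, cfg, seed, inputs = character(0),
                           outputs = character(0)) {
  manifest <- list(
    config = cfg, seed = seed,
    version = as.character(utils::packageVersion("ccm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_digests = as.list(tools::md5sum(inputs)),
    outputs = basename(outputs))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Pipeline commands
#'
#' Orchestration entry points mirroring the command-line interface
#' (`inst/cli/ccm.R`). Each writes its outputs plus a JSON run manifest
#' (config snapshot, seed, package version, input digests, output
#' inventory) into `out_dir` and returns the paths invisibly.
#'
#' * `cmd_fixtures` writes a synthetic annotation (BED-like TSV), loop set
#'   (TSV) or analytic trajectory (XYZ).
#' * `cmd_simulate` builds a model from the config (+ optional annotation /
#'   loop files), runs the chosen integrator and writes the trajectory.
#' * `cmd_analyze_contacts` computes the contact map, P(s) (+ crossover),
#'   A(s), the Spearman map, co-clustered compartment labels and DI/TADs.
#' * `cmd_analyze_geometry` computes R_ij, R(s)/dR(s), the WLM, the
#'   contact-distance exponent and droplet trace.
#' * `cmd_analyze_dynamics` computes Delta(t) (+ exponent), F_s(k, t) with
#'   stretched fit, chi4 across trajectories, and a Van Hove summary.
#' * `cmd_compare_hic` ingests a Hi-C matrix (TSV), converts it to
#'   distances, and compares against a simulated trajectory via
#'   Pearson(WLM) and compartment AMI.
#'
#' @param cfg configuration list from [read_ccm_config()].
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for all randomness in the command.
#' @return Invisibly, a named list of output paths (plus key scalar results
#'   where applicable).
#' @name ccm_pipeline
NULL

#' @rdname ccm_pipeline
#' @param kind fixture kind: "annotation", "loops" or "trajectory".
#' @param traj_kind trajectory fixture kind (see [synth_trajectory()]).
#' @export
cmd_fixtures <- function(cfg, out_dir, kind = c("annotation", "loops",
                                                "trajectory"),
                         traj_kind = "brownian", seed = 1L) {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- cfg$model$n_beads
  paths <- character(0)
  if (kind == "annotation") {
    ann <- synth_annotation(n, cfg$fixtures$mean_block_len,
                            cfg$fixtures$fraction_A, seed = seed)
    p <- file.path(out_dir, "annotation.tsv")
    utils::write.table(data.frame(bead = seq_len(n), label = ann$labels),
                       p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- p
  } else if (kind == "loops") {
    lp <- synth_loops(n, cfg$fixtures$n_loops, cfg$fixtures$mean_span,
                      seed = seed)
    p <- file.path(out_dir, "loops.tsv")
    utils::write.table(as.data.frame(lp$anchors), p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- p
  } else {
    tr <- synth_trajectory(traj_kind, n_beads = n, n_frames = 100,
                           seed = seed)
    p <- file.path(out_dir, "trajectory.xyz")
    write_xyz(tr, p)
    paths <- p
  }
  manifest <- write_manifest(out_dir, cfg, seed, outputs = paths)
  invisible(list(outputs = paths, manifest = manifest))
}

#' @rdname ccm_pipeline
#' @param integrator "langevin" or "brownian" (overrides the config).
#' @param n_steps step count override.
#' @export
cmd_simulate <- function(cfg, out_dir, integrator = NULL, n_steps = NULL,
                         seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- config_model(cfg, seed = seed)
  sim <- cfg$simulate
  if (!is.null(integrator)) sim$integrator <- integrator
  if (!is.null(n_steps)) sim$n_steps <- n_steps
  x0 <- init_extended(model, seed = seed)
  # overdamped pre-run closes far-apart loop bonds before the main stage
  if (sim$pre_steps > 0) {
    pre <- run_brownian(x0, model, sim$pre_steps, dt = 1e-4, seed = seed,
                        save_every = as.integer(sim$pre_steps))
    x0 <- traj_frame(pre, n_frames(pre))
  }
  traj <- if (sim$integrator == "brownian") {
    run_brownian(x0, model, sim$n_steps, dt = sim$dt,
                 friction = sim$friction, seed = seed,
                 save_every = sim$save_every)
  } else {
    run_langevin(x0, model, sim$n_steps, dt = sim$dt,
                 friction = sim$friction, seed = seed,
                 save_every = sim$save_every)
  }
  p <- file.path(out_dir, "trajectory.xyz")
  write_xyz(traj, p, labels = model$annotation$labels)
  rg <- traj_rg(traj)
  prg <- file.path(out_dir, "rg.tsv")
  utils::write.table(data.frame(t = traj$times, rg = rg), prg, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- write_manifest(out_dir, cfg, seed, outputs = c(p, prg))
  invisible(list(outputs = c(p, prg), manifest = manifest, trajectory = traj,
                 model = model))
}

#' @rdname ccm_pipeline
#' @param traj a [trajectory()] (or path to an XYZ file).
#' @export
cmd_analyze_contacts <- function(cfg, traj, out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(traj)) traj <- read_xyz(traj)
  params <- do.call(ccm_parameters, cfg$model[setdiff(names(cfg$model),
                                                      "cutoff")])
  cm <- contact_map(traj, params)
  ps <- contact_probability(cm)
  lb <- attr(ps, "log_binned")
  cs <- tryCatch(crossover_scale(lb$s, lb$P, bin_bp = params$bead_bp),
                 error = function(e) NULL)
  as_curve <- subchain_contacts(cm)
  sp <- spearman_map(cm)
  labels <- tryCatch(compartments_cocluster(sp, cfg$analyze$n_clusters,
                                            seed = seed),
                     error = function(e) rep(NA_integer_, nrow(sp)))
  di_window <- min(cfg$analyze$di_window, nrow(cm$C) %/% 2 - 1L)
  di <- directionality_index(cm, window = di_window)
  tads <- call_tads(di, bin_bp = params$bead_bp, window = di_window)
  paths <- c(contacts = file.path(out_dir, "contacts.tsv"),
             ps = file.path(out_dir, "contact_probability.tsv"),
             as = file.path(out_dir, "subchain_contacts.tsv"),
             comp = file.path(out_dir, "compartments.bed"),
             tads = file.path(out_dir, "tads.bed"))
  write_contact_matrix(contact_matrix(cm$C, bin_bp = params$bead_bp),
                       paths["contacts"])
  utils::write.table(ps, paths["ps"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(as_curve, paths["as"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  n <- nrow(sp)
  utils::write.table(
    data.frame(chrom = "synthetic", start = (seq_len(n) - 1) * params$bead_bp,
               end = seq_len(n) * params$bead_bp, label = labels),
    paths["comp"], sep = "\t", row.names = FALSE, col.names = FALSE,
    quote = FALSE)
  utils::write.table(
    if (nrow(tads)) data.frame(chrom = "synthetic", start = tads$start_bp,
                               end = tads$end_bp) else data.frame(),
    paths["tads"], sep = "\t", row.names = FALSE, col.names = FALSE,
    quote = FALSE)
  manifest <- write_manifest(out_dir, cfg, seed, outputs = paths)
  invisible(list(outputs = paths, manifest = manifest, contacts = cm,
                 crossover = cs, compartments = labels, tads = tads))
}

#' @rdname ccm_pipeline
#' @param annotation optional [epigenome_annotation()] for type-resolved
#'   analyses.
#' @export
cmd_analyze_geometry <- function(cfg, traj, out_dir, annotation = NULL,
                                 seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(traj)) traj <- read_xyz(traj)
  params <- do.call(ccm_parameters, cfg$model[setdiff(names(cfg$model),
                                                      "cutoff")])
  dm <- mean_distance_map(traj)
  rs <- r_of_s(dm, bin_bp = params$bead_bp)
  W <- ward_linkage_matrix(dm)
  cm <- contact_map(traj, params)
  cde <- tryCatch(contact_distance_exponent(cm, dm), error = function(e) NULL)
  dg <- droplet_growth(traj, linkage_radius = params$r_contact,
                       bead_bp = params$bead_bp)
  paths <- c(R = file.path(out_dir, "distance_map.tsv"),
             rs = file.path(out_dir, "r_of_s.tsv"),
             wlm = file.path(out_dir, "wlm.tsv"),
             droplets = file.path(out_dir, "droplets.tsv"))
  utils::write.table(dm$R, paths["R"], sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(rs, paths["rs"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(unclass(W), paths["wlm"], sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(dg$trace, paths["droplets"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- write_manifest(out_dir, cfg, seed, outputs = paths)
  invisible(list(outputs = paths, manifest = manifest, distances = dm,
                 wlm = W, contact_distance = cde, droplets = dg))
}

#' @rdname ccm_pipeline
#' @param trajs list of trajectories (>= 1; chi4 needs >= 2).
#' @param k wavevector ("auto" uses 1 / r_s from the first trajectory).
#' @export
cmd_analyze_dynamics <- function(cfg, trajs, out_dir, annotation = NULL,
                                 k = "auto", seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(trajs, "ccm_trajectory")) trajs <- list(trajs)
  trajs <- lapply(trajs, function(t) if (is.character(t)) read_xyz(t) else t)
  if (identical(k, "auto")) {
    pair <- "all"
    if (!is.null(annotation) && sum(annotation$labels == "A") >= 2)
      pair <- "AA"
    rd <- radial_distribution(trajs[[1]], annotation, pair = pair)
    k <- 1 / rd$r_s
  }
  delta <- msd(trajs[[1]])
  fs <- intermediate_scattering(trajs, k = k)
  sf <- stretched_fit(fs)
  x4 <- if (length(trajs) >= 2) chi4(trajs, k = k) else NULL
  vh_lags <- default_lags(n_frames(trajs[[1]]), 4)
  vh <- van_hove(trajs[[1]], lags = vh_lags)
  paths <- c(msd = file.path(out_dir, "msd.tsv"),
             fs = file.path(out_dir, "fs.tsv"),
             vh = file.path(out_dir, "van_hove_collapse.tsv"))
  utils::write.table(delta, paths["msd"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(fs, paths["fs"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(vh$collapse, paths["vh"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(x4)) {
    paths["chi4"] <- file.path(out_dir, "chi4.tsv")
    utils::write.table(x4$curve, paths["chi4"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  manifest <- write_manifest(out_dir, cfg, seed, outputs = paths)
  invisible(list(outputs = paths, manifest = manifest, msd = delta,
                 Fs = fs, stretched = sf, chi4 = x4, van_hove = vh, k = k))
}

#' @rdname ccm_pipeline
#' @param hic_path path to a Hi-C contact matrix (dense TSV).
#' @export
cmd_compare_hic <- function(cfg, traj, hic_path, out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(traj)) traj <- read_xyz(traj)
  params <- do.call(ccm_parameters, cfg$model[setdiff(names(cfg$model),
                                                      "cutoff")])
  hic <- read_contact_matrix(hic_path)
  if (nrow(hic$mat) != n_beads(traj))
    stop("Hi-C matrix dimension does not match the trajectory")
  # both sides go through the same contacts -> distances -> WLM pipeline so
  # that identical maps compare to exactly 1
  R_exp <- suppressWarnings(hic_to_distance(hic$mat))
  W_exp <- ward_linkage_matrix(R_exp, source = "hic")
  lab_exp <- compartments_cocluster(spearman_map(hic$mat), seed = seed)
  cm <- contact_map(traj, params)
  R_sim <- suppressWarnings(hic_to_distance(cm$C))
  W_sim <- ward_linkage_matrix(R_sim)
  lab_sim <- compartments_cocluster(spearman_map(cm), seed = seed)
  rho <- wlm_similarity(W_sim, W_exp)
  score <- ami(lab_sim, lab_exp)
  res <- data.frame(metric = c("pearson_wlm", "ami_compartments"),
                    value = c(rho, score))
  p <- file.path(out_dir, "comparison.tsv")
  utils::write.table(res, p, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- write_manifest(out_dir, cfg, seed, inputs = hic_path,
                             outputs = p)
  invisible(list(outputs = p, manifest = manifest, pearson_wlm = rho,
                 ami = score))
}
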