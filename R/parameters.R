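#' Model parameters for the chromosome copolymer model
#'
#' The chromosome copolymer model (CCM) represents a chromatin fiber as a
#' self-avoiding bead-spring chain with two bead types, A (active chromatin)
#' and B (repressive chromatin), plus permanent bonds between CTCF loop-anchor
#' pairs. Each bead coarse-grains `bead_bp` base pairs of chromatin
#' (about six nucleosomes at the default resolution) into a sphere of diameter
#' `sigma`. Same-type pairs attract with well depth `epsilon` (in units of
#' k_B*T); the cross-type well depth is `epsilon / eps_ratio`. Two beads are
#' counted as being in contact when their distance is below
#' `r_contact * sigma`.
#'
#' Internally all computations use reduced units (`sigma` = 1, k_B*T = 1);
#' `sigma`, `bead_bp` and `time_calibration` only enter when converting to
#' physical units at input/output boundaries.
#'
#' @param n_beads number of beads in the chain (N >= 2).
#' @param bead_bp base pairs represented by one bead.
#' @param sigma bead (monomer) diameter in nanometers.
#' @param epsilon same-type (AA and BB) well depth in units of k_B*T.
#' @param eps_ratio ratio epsilon / epsilon_AB; the default 11/9 makes
#'   cross-type attraction weaker than same-type attraction, which drives
#'   micro-phase separation of A and B loci.
#' @param r_contact contact threshold in multiples of sigma.
#' @param temperature thermal energy k_B*T in reduced units.
#' @param time_calibration seconds per reduced time unit; see [map_time()].
#' @return An object of class `ccm_parameters`.
#' @seealso [energy_model()], [estimate_monomer_size()]
#' @examples
#' p <- ccm_parameters()
#' p$sigma * p$r_contact  # contact radius in nm
#' @export
ccm_parameters <- function(n_beads = 1000L, bead_bp = 1200L, sigma = 70,
                           epsilon = 2.4, eps_ratio = 11 / 9, r_contact = 2,
                           temperature = 1, time_calibration = NULL) {
  n_beads <- as.integer(n_beads)
  stopifnot(n_beads >= 2L, sigma > 0, eps_ratio > 0, r_contact > 0,
            epsilon >= 0, bead_bp >= 1, temperature > 0)
  structure(list(n_beads = n_beads, bead_bp = as.numeric(bead_bp),
                 sigma = sigma, epsilon = epsilon, eps_ratio = eps_ratio,
                 r_contact = r_contact, temperature = temperature,
                 time_calibration = time_calibration),
            class = "ccm_parameters")
}

#' Default CCM parameters
#'
#' Returns the calibrated defaults: 1200 bp per bead, sigma = 70 nm,
#' epsilon = 2.4 k_B*T, epsilon/epsilon_AB = 11/9 and contact threshold
#' r_c = 2*sigma.
#'
#' @param n_beads chain length; the only free choice, defaults to 1000.
#' @return A `ccm_parameters` object.
#' @export
default_parameters <- function(n_beads = 1000L) {
  ccm_parameters(n_beads = n_beads)
}

#' @export
print.ccm_parameters <- function(x, ...) {
  cat("CCM parameters\n")
  cat(sprintf("  N = %d beads (%.3g bp, %d bp/bead)\n", x$n_beads,
              x$n_beads * x$bead_bp, as.integer(x$bead_bp)))
  cat(sprintf("  sigma = %g nm, epsilon = %g kT, eps/eps_AB = %.4g, r_c = %g sigma\n",
              x$sigma, x$epsilon, x$eps_ratio, x$r_contact))
  invisible(x)
}

#' Bracket the coarse-grained monomer diameter
#'
#' Estimates lower and upper bounds for the diameter of a bead that
#' coarse-grains `nucleosomes_per_bead` nucleosomes. The lower bound assumes
#' compact packing (volume equivalence): `nucleosomes_per_bead^(1/3)` times
#' the nucleosome size. The upper bound treats the nucleosome array as a
#' worm-like chain whose persistence length is comparable to its contour
#' length L = nucleosomes_per_bead * (linker_length + nucleosome_radius),
#' for which the mean end-to-end distance is R = L * sqrt(2/e).
#'
#' With the defaults (10 nm nucleosomes, 16.5 nm linkers, six nucleosomes)
#' the bracket is about 18-136 nm, motivating the 70 nm default for `sigma`
#' as an approximate midpoint.
#'
#' @param nucleosome_radius nucleosome size in nm.
#' @param linker_length linker DNA length in nm.
#' @param nucleosomes_per_bead nucleosomes per coarse-grained bead.
#' @return Named numeric vector with elements `lower` and `upper` (nm),
#'   unrounded.
#' @export
estimate_monomer_size <- function(nucleosome_radius = 10, linker_length = 16.5,
                                  nucleosomes_per_bead = 6) {
  stopifnot(nucleosome_radius > 0, linker_length >= 0,
            nucleosomes_per_bead > 0)
  lower <- nucleosomes_per_bead^(1 / 3) * nucleosome_radius
  L <- nucleosomes_per_bead * (linker_length + nucleosome_radius)
  upper <- L * sqrt(2 / exp(1))
  c(lower = lower, upper = upper)
}

#' Per-bead epigenetic annotation
#'
#' Holds one label per bead, A for active chromatin and B for repressive
#' chromatin, optionally together with the underlying ChromHMM state
#' (states 1-11 collapse to A, 12-15 to B) and the genomic origin of bead 0.
#'
#' @param labels character vector of "A"/"B" labels, one per bead.
#' @param states optional integer vector of ChromHMM states (1-15).
#' @param chrom,start optional genomic origin; bead k covers the 0-based
#'   half-open interval `[start + k*bead_bp, start + (k+1)*bead_bp)`.
#' @param bead_bp base pairs per bead (for coordinate conversion).
#' @return An object of class `ccm_annotation`.
#' @export
epigenome_annotation <- function(labels, states = NULL, chrom = NA_character_,
                                 start = 0, bead_bp = 1200) {
  labels <- as.character(labels)
  if (!all(labels %in% c("A", "B")))
    stop("labels must all be 'A' or 'B'")
  if (!is.null(states)) {
    stopifnot(length(states) == length(labels),
              all(states >= 1 & states <= 15))
  }
  structure(list(labels = labels, states = states, chrom = chrom,
                 start = start, bead_bp = bead_bp),
            class = "ccm_annotation")
}

#' @export
print.ccm_annotation <- function(x, ...) {
  nA <- sum(x$labels == "A")
  cat(sprintf("CCM annotation: %d beads, %d A (%.1f%%), %d B\n",
              length(x$labels), nA, 100 * nA / length(x$labels),
              length(x$labels) - nA))
  invisible(x)
}

#' Loop-anchor pair set
#'
#' Pairs of bead indices (1-based, i < j) joined by permanent loop bonds,
#' corresponding to CTCF-mediated loops called from Hi-C maps.
#'
#' @param anchors two-column integer matrix of bead index pairs (may have
#'   zero rows).
#' @param n_beads chain length the pairs refer to.
#' @return An object of class `ccm_loops`.
#' @export
loop_set <- function(anchors, n_beads) {
  anchors <- matrix(as.integer(anchors), ncol = 2)
  n_beads <- as.integer(n_beads)
  if (nrow(anchors) > 0) {
    anchors <- t(apply(anchors, 1, sort))
    if (any(anchors[, 1] < 1L) || any(anchors[, 2] > n_beads))
      stop("loop anchors outside [1, n_beads]")
    if (any(anchors[, 2] - anchors[, 1] < 2L))
      stop("loop anchors must be separated by at least 2 beads")
    anchors <- unique(anchors)
    anchors <- anchors[order(anchors[, 1], anchors[, 2]), , drop = FALSE]
  }
  colnames(anchors) <- c("i", "j")
  structure(list(anchors = anchors, n_beads = n_beads), class = "ccm_loops")
}

#' @export
print.ccm_loops <- function(x, ...) {
  cat(sprintf("CCM loop set: %d anchor pairs on %d beads\n",
              nrow(x$anchors), x$n_beads))
  invisible(x)
}

#' Assemble the CCM energy model
#'
#' Combines parameters, annotation and loop set with the interaction
#' specification. The total energy is E = U_C + U_LJ where U_C contains the
#' chain bond term U^S and the loop bond term U^L (both FENE springs with a
#' WCA core, Kremer-Grest constants: spring 30 k_B*T/sigma^2, maximum
#' extension 1.5 sigma), and U_LJ is the truncated-and-shifted 12-6
#' Lennard-Jones pair interaction with well depth epsilon for AA and BB
#' pairs and epsilon * 9/11 (in general epsilon / eps_ratio) for AB pairs.
#' Pair LJ is not applied between directly bonded pairs (chain neighbors and
#' loop anchors), whose excluded volume is carried by the WCA core of the
#' bond term.
#'
#' Setting `eps_ratio = 1` makes the model a pseudo-homopolymer (label-blind
#' energies), the control under which compartments disappear.
#'
#' @param params a [ccm_parameters()] object.
#' @param annotation a [epigenome_annotation()] object of matching length.
#' @param loops a [loop_set()]; defaults to no loops.
#' @param bond list of bond constants: `fene_k`, `fene_r0`, `wca_eps`
#'   (FENE + WCA), `loop_fcap` (loop bonds switch from FENE to a constant
#'   restoring force of this magnitude once the FENE force would exceed it,
#'   keeping far-apart anchors well-defined while loops close), and
#'   `harm_k`, `harm_r0` used only in `ideal` mode.
#' @param cutoff LJ cutoff in sigma units (truncated and shifted).
#' @param ideal logical; if TRUE, harmonic bonds and no pair interactions
#'   (an ideal-chain reference useful for Rouse-scaling checks).
#' @return An object of class `ccm_model`.
#' @export
energy_model <- function(params, annotation, loops = NULL,
                         bond = list(fene_k = 30, fene_r0 = 1.5, wca_eps = 1,
                                     harm_k = 30, harm_r0 = 1, loop_fcap = 60),
                         cutoff = 2.5, ideal = FALSE) {
  stopifnot(inherits(params, "ccm_parameters"),
            inherits(annotation, "ccm_annotation"))
  if (length(annotation$labels) != params$n_beads)
    stop("annotation length must equal n_beads")
  if (is.null(loops))
    loops <- loop_set(matrix(integer(0), ncol = 2), params$n_beads)
  stopifnot(inherits(loops, "ccm_loops"))
  if (loops$n_beads != params$n_beads)
    stop("loop set refers to a different chain length")
  defaults <- list(fene_k = 30, fene_r0 = 1.5, wca_eps = 1,
                   harm_k = 30, harm_r0 = 1, loop_fcap = 60)
  bond <- utils::modifyList(defaults, bond)
  eps <- params$epsilon
  structure(list(params = params, annotation = annotation, loops = loops,
                 bond = bond, cutoff = cutoff, ideal = ideal,
                 eps_aa = eps, eps_bb = eps, eps_ab = eps / params$eps_ratio),
            class = "ccm_model")
}

#' @export
print.ccm_model <- function(x, ...) {
  cat("CCM energy model\n")
  print(x$params)
  cat(sprintf("  eps_AA = eps_BB = %g, eps_AB = %.4g kT; LJ cutoff %g sigma\n",
              x$eps_aa, x$eps_ab, x$cutoff))
  cat(sprintf("  %d loop bonds; bond: %s\n", nrow(x$loops$anchors),
              if (x$ideal) "harmonic (ideal mode)" else
                sprintf("FENE k=%g R0=%g + WCA", x$bond$fene_k, x$bond$fene_r0)))
  invisible(x)
}

# interaction constants in the form the C++ kernel expects
model_pars_cpp <- function(model) {
  list(eps_aa = model$eps_aa, eps_bb = model$eps_bb, eps_ab = model$eps_ab,
       cutoff = model$cutoff, fene_k = model$bond$fene_k,
       fene_r0 = model$bond$fene_r0, wca_eps = model$bond$wca_eps,
       harm_k = model$bond$harm_k, harm_r0 = model$bond$harm_r0,
       loop_fcap = model$bond$loop_fcap)
}

labels_cpp <- function(model) as.integer(model$annotation$labels == "B")

loops_cpp <- function(model) {
  a <- model$loops$anchors
  matrix(as.integer(a - 1L), ncol = 2)
}
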