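#' Pairwise Lennard-Jones energy between two beads
#'
#' Standard 12-6 Lennard-Jones interaction with the well depth selected by
#' the label pair (AA/BB: epsilon; AB: epsilon / eps_ratio), truncated at the
#' model cutoff and, by default, shifted so the potential is continuous
#' (zero) at the cutoff. Beyond the cutoff the energy is exactly 0.
#'
#' @param label_a,label_b bead labels, "A" or "B".
#' @param r center-to-center distance in sigma units (> 0).
#' @param model a [energy_model()].
#' @param shift if FALSE, return the bare truncated LJ energy (no shift);
#'   the analytic minimum is then -eps_ab at r = 2^(1/6).
#' @return Energy in k_B*T.
#' @export
pair_energy <- function(label_a, label_b, r, model, shift = TRUE) {
  stopifnot(label_a %in% c("A", "B"), label_b %in% c("A", "B"))
  if (any(r <= 0)) stop("r must be positive")
  eps <- if (label_a == label_b) {
    if (label_a == "A") model$eps_aa else model$eps_bb
  } else model$eps_ab
  rc <- model$cutoff
  lj <- function(x) 4 * eps * (x^-12 - x^-6)
  u <- ifelse(r >= rc, 0, lj(r) - if (shift) lj(rc) else 0)
  u
}

#' Total energy of a conformation, by term
#'
#' Evaluates E = U^S + U^L + U_LJ for a conformation under the model:
#' U^S sums the chain bonds, U^L the loop bonds, and U_LJ the non-bonded
#' pair interactions (bonded pairs excluded). An overstretched bond (outside
#' the FENE domain) is an error reporting the offending bond index.
#'
#' @param conformation numeric matrix, `n_beads` x 3, positions in sigma
#'   units.
#' @param model a [energy_model()].
#' @param shift if FALSE, report U_LJ without the cutoff shift.
#' @return Named list with `U_S`, `U_L`, `U_LJ` and `E` (k_B*T).
#' @export
total_energy <- function(conformation, model, shift = TRUE) {
  conformation <- as.matrix(conformation)
  if (nrow(conformation) != model$params$n_beads)
    stop("conformation must have n_beads rows")
  out <- .cpp_total_energy(conformation, labels_cpp(model), loops_cpp(model),
                           model_pars_cpp(model), model$ideal, shift)
  if (out$bad_bond > 0)
    stop(sprintf("bond %d is outside the FENE domain (overstretched)",
                 out$bad_bond))
  out$bad_bond <- NULL
  out
}
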