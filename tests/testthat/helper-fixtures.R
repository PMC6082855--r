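# Shared builders for small models and conformations used across tests.

tiny_model <- function(n = 10, epsilon = 2.4, eps_ratio = 11 / 9,
                       labels = NULL, loops = NULL, ...) {
  p <- ccm_parameters(n_beads = n, epsilon = epsilon, eps_ratio = eps_ratio)
  ann <- if (is.null(labels)) {
    epigenome_annotation(rep(c("A", "B"), length.out = n))
  } else epigenome_annotation(labels)
  lp <- if (is.null(loops)) NULL else loop_set(loops, n)
  energy_model(p, ann, lp, ...)
}

# straight chain along x with given spacing
rod_conformation <- function(n, spacing = 0.97) {
  cbind(spacing * (seq_len(n) - 1), 0, 0)
}

# single-frame trajectory from a conformation
static_traj <- function(x, times = 0) {
  trajectory(array(rep(as.matrix(x), length(times)),
                   dim = c(nrow(x), 3, length(times))),
             times = times, integrator = "static")
}

# O(N^2) brute-force total energy oracle, independent of the C++ kernel
brute_energy <- function(x, model, shift = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  lab <- model$annotation$labels
  k <- model$bond$fene_k; r0 <- model$bond$fene_r0
  wca <- function(r, eps0 = model$bond$wca_eps) {
    if (r >= 2^(1 / 6)) return(0)
    4 * eps0 * (r^-12 - r^-6) + eps0
  }
  fene <- function(r) -0.5 * k * r0^2 * log(1 - (r / r0)^2)
  # loop bonds: FENE with capped-force linear continuation beyond r_switch
  fcap <- model$bond$loop_fcap
  a <- fcap / r0^2
  r_switch <- (-k + sqrt(k^2 + 4 * a * fcap)) / (2 * a)
  loop_bond <- function(r) {
    if (r < r_switch) fene(r) + wca(r)
    else fene(r_switch) + fcap * (r - r_switch)
  }
  lj <- function(r, eps) {
    rc <- model$cutoff
    if (r >= rc) return(0)
    u <- 4 * eps * (r^-12 - r^-6)
    if (shift) u <- u - 4 * eps * (rc^-12 - rc^-6)
    u
  }
  dmat <- as.matrix(stats::dist(x))
  us <- 0
  for (i in seq_len(n - 1)) us <- us + fene(dmat[i, i + 1]) +
    wca(dmat[i, i + 1])
  ul <- 0
  anchors <- model$loops$anchors
  for (q in seq_len(nrow(anchors)))
    ul <- ul + loop_bond(dmat[anchors[q, 1], anchors[q, 2]])
  bonded <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) bonded[i, i + 1] <- TRUE
  for (q in seq_len(nrow(anchors)))
    bonded[anchors[q, 1], anchors[q, 2]] <- TRUE
  ulj <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bonded[i, j]) next
    eps <- if (lab[i] == lab[j]) model$eps_aa else model$eps_ab
    if (eps > 0) ulj <- ulj + lj(dmat[i, j], eps)
    else ulj <- ulj + wca(dmat[i, j])
  }
  list(U_S = us, U_L = ul, U_LJ = ulj, E = us + ul + ulj)
}

# brute-force contact counting oracle
brute_contacts <- function(traj, rc) {
  n <- n_beads(traj)
  C <- matrix(0, n, n)
  for (f in seq_len(n_frames(traj))) {
    d <- as.matrix(stats::dist(traj_frame(traj, f)))
    C <- C + (d < rc)
  }
  diag(C) <- 0
  dimnames(C) <- NULL
  C
}

# planted checkerboard correlation-like matrix with two blocks
planted_checkerboard <- function(n, labels, hi = 2, lo = 1, noise = 0,
                                 seed = 1) {
  same <- outer(labels, labels, "==")
  M <- ifelse(same, hi, lo)
  if (noise > 0) {
    set.seed(seed)
    E <- matrix(stats::rnorm(n * n, sd = noise), n, n)
    M <- M + (E + t(E)) / 2
  }
  diag(M) <- hi
  M
}
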