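---
title: "The chromosome copolymer model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The chromosome copolymer model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`ccm` simulates an interphase chromosome segment as a **chromosome copolymer
model (CCM)**: a self-avoiding bead-spring chain in which every bead carries
one of two epigenetic labels — A (active/euchromatin, ChromHMM states 1–11)
or B (repressive/heterochromatin, states 12–15) — plus permanent bonds
between CTCF loop-anchor bead pairs. Each bead coarse-grains 1200 bp
(roughly six nucleosomes) into a sphere of diameter σ = 70 nm, chosen as an
approximate midpoint of the two limiting estimates implemented in
`estimate_monomer_size()`: compact nucleosome packing (`6^(1/3) × 10 nm ≈
18 nm`) and a worm-like-chain estimate for the six-nucleosome array
(`L √(2/e) ≈ 136 nm` with L = 6 × 26.5 nm).

The energy is `E = U_C + U_LJ`:

* `U_C = U^S + U^L` — chain bonds and loop bonds. Both are FENE springs
  with Kremer–Grest constants (k = 30 k~B~T/σ², R₀ = 1.5 σ) plus a WCA
  core (ε₀ = 1 k~B~T), the standard choice for dense bead-spring melts
  that prevents chain crossing together with the pair repulsion. The
  functional form of the bond terms is a package design choice; any
  similarly stiff finitely extensible bond gives the same coarse behavior.
* `U_LJ` — truncated-and-shifted 12-6 Lennard-Jones between all non-bonded
  pairs (cutoff 2.5 σ), with well depth ε for AA and BB pairs and
  ε/(11/9) = 0.818 ε for AB pairs. ε = 2.4 k~B~T is the calibrated default;
  the fixed 11/9 ratio makes cross-type contacts less favorable and drives
  A/B micro-phase separation. Setting the ratio to 1 produces the
  label-blind pseudo-homopolymer control, under which compartments vanish.

**Loop bonds at large extension.** Runs start from extended conformations in
which anchor pairs may sit tens of σ apart, outside the FENE domain. Loop
bonds therefore switch from FENE to a constant restoring force (default
`loop_fcap` = 60 k~B~T/σ, the FENE force at ≈ 1.04 σ) once the FENE force
would exceed that cap. Near equilibrium the loop bond is pure FENE+WCA; the
cap only acts while loops are closing. Chain bonds remain strict FENE and
integration aborts with the offending bond index if one ever leaves its
domain.

Internally σ = 1 and k~B~T = 1; nanometers, base pairs and seconds enter
only at I/O through `ccm_parameters()` (σ, bead_bp) and `map_time()`
(Stokes-drag calibration τ = γσ²/k~B~T with γ = 6πη(σ/2); the nucleoplasm
viscosity η is a user input, so all dynamical results in this package are
reported in reduced time and compared through exponents and inequalities,
never through absolute seconds).

# Integrators

* `run_langevin()` — inertial BAOAB Langevin (m = 1), default dt = 0.01 τ,
  friction 0.1. Low friction accelerates conformational sampling; this is
  the integrator used to collapse and anneal structures. Kinetic energy is
  recorded per frame so equipartition can be verified (the test suite
  checks `<E_kin>/(3N/2) = k~B~T` within 2%).
* `run_brownian()` — overdamped Euler–Maruyama, default dt = 1e-4 τ at
  unit friction. This is the integrator for all dynamical observables
  (MSD, F~s~, χ₄, Van Hove), matching the physically relevant high-friction
  limit. The timestep bound is set by the FENE/WCA stiffness in the dense
  globule: dt = 1e-4 is stable at ε = 2.4, dt = 3e-4 is not (a run that
  leaves the FENE domain aborts with its step index rather than silently
  producing garbage).
* Neighbor lists: Verlet pair list (skin 0.4 σ) rebuilt from a sparse cell
  hash on a displacement criterion, so extended starts spanning hundreds of
  σ cost no memory blow-up. Results are independent of the skin.
* Randomness: one named 64-bit generator per run, seeded explicitly; the
  seed is recorded in the trajectory object. Same seed, same build →
  bit-identical trajectories.

# Simulation protocol

The standard protocol, used by the pipelines, tests and the acceptance
script, has three stages:

1. **Loop closing** — a short Brownian pre-run (3×10⁴ steps, dt = 1e-4)
   from the extended start. Overdamped dynamics absorbs the capped loop
   forces without inertial overshoot.
2. **Collapse / annealing** — low-friction Langevin (γ = 0.1) until the
   radius of gyration plateaus. At N = 500–1000 and ε = 2.4 the collapse
   from a ~500–1000 σ extended chain completes within ≈ 600–1000 τ.
   For droplet-coarsening analyses, where the *transient* is the object of
   study and quasi-overdamped kinetics matter, this stage instead uses
   γ = 1 Langevin (timescales ≫ 1/γ are effectively Brownian) so the whole
   coalescence cascade fits in a desk-scale run.
3. **Production** — Brownian dynamics on the collapsed structure for the
   dynamical observables.

# Synthetic inputs: what they emulate

`synth_annotation()` draws alternating A/B blocks with geometric lengths
(default mean block 50 beads = 60 kb) and A fraction 0.24, the
active/repressive ratio of the 12 Mbp chromosome-5 region used to calibrate
the model (2369 A vs 7631 B loci at 1200 bp resolution). `synth_loops()`
places loops with exponential spans (default mean 20 beads = 24 kb,
roughly the observed CTCF loop/TAD scale at reduced N; one loop per ~40
beads). These reproduce the *statistical texture* of real annotations —
blocky epigenetic states, sparse loops — but not their linear correlations
(real A/B blocks are not geometric, real loops nest and cluster at
boundaries). Tests passing on synthetic inputs therefore validate the
machinery and the physics of the model, not genome-specific predictions;
real ChromHMM/BEDPE inputs go through `read_chromhmm_bed()` /
`read_loops_bedpe()`.

`synth_trajectory()` provides analytic fixtures (static, ballistic,
Brownian, Ornstein–Uhlenbeck "caged") whose closed-form MSD, scattering and
Van Hove behavior anchor every dynamics estimator in the test suite.

# Estimator conventions and numerical choices

* **Contacts** — `C_ij` counts (frame, pair) events with `|r_i − r_j| <
  2σ`, each pair once per frame; `P_ij = C_ij / n_frames`. Exactly matches
  a brute-force double loop (tested).
* **P(s)** — anti-diagonal means; log-binned at 20 bins/decade for fits.
  The two-regime crossover s\* is the breakpoint of a continuous two-segment
  log-log fit; a best breakpoint within 10% of either range edge, or a
  slope change < 0.05, is flagged "no crossover".
* **Spearman map** — row-wise rank correlations with a ±1 bead diagonal
  band removed first (near-deterministic bonded contacts would otherwise
  dominate the ranks).
* **Compartments** — bipartite spectral co-clustering (normalize
  `D_r^{-1/2} A D_c^{-1/2}`, second singular vectors, k-means with fixed
  seed) of the shifted non-negative Spearman map; similarity to reference
  labelings via adjusted mutual information with the hypergeometric
  expected-MI correction ("max" normalization).
* **TAD calling** — the directionality index
  `DI = sign(B−A)((A−E)²+(B−E)²)/E` with window w (default the 2 Mb
  equivalent in beads) and `DI = 0` when `A = B = 0`; boundaries at
  sign changes persisting ≥ w/4 beads. This deterministic run-length rule
  replaces the original HMM post-processing — simpler, seed-free, and
  accurate to ±1 bin on planted blocks (tested).
* **g(r)** — pair histograms normalized by the exact ideal-gas pair-distance
  density of a uniform sphere of radius `R_ref = √(5/3) R_g` (so finite
  globule boundaries do not masquerade as structure; uniform points give
  g ≡ 1, tested). r_s is the argmax of g_AA.
* **Radial density** — `ρ_α(r) = <N_α(r)> V / (4πr²Δr N_α)` with
  `V = (4/3)πr_max³`; r_max defaults to the observed maximum radial
  distance at reduced N (the full-scale analysis uses a fixed 17 σ).
* **R(s), δR(s)** — Eq. for R(s) is the root of the pair- and
  frame-averaged squared distance at separation s. δR(s) takes each pair's
  variance over frames/ensemble, averages over pairs at that s, and
  normalizes by the mean distance — so a frozen single structure has
  δR ≡ 0 and the curve isolates temporal/cell-to-cell heterogeneity.
* **WLM** — Ward linkage (`ward.D2`) applied directly to the mean distance
  matrix; the cophenetic matrix is returned and its ultrametricity is
  property-tested. Ward's variance interpretation assumes Euclidean input;
  here it serves as a well-defined hierarchical summary of a non-Euclidean
  distance matrix.
* **Contact–distance exponent λ** — slope of the per-bin median ridge of
  the (log R_ij, log 1/C_ij) scatter. Pairs in contact in > half the frames
  are censored (counts saturate) and are excluded, as are counts below a
  shot-noise floor; at reduced scale the informative ridge spans roughly
  R ∈ [r_c, 2 r_c]. The estimator is exact (to 1e-6) on planted power laws.
* **F~s~(k, t)** — isotropic wavevector average computed exactly as
  `sinc(k|Δr|)`; default k = 1/r_s (2π/r_s by flag). Stretched-exponential
  fits linearize `log(−log F)` over F ∈ [0.02, 0.95] and refine by `nls`;
  a curve that never leaves the upper bound is flagged degenerate.
* **χ₄** — N × ensemble variance of per-trajectory (origin-averaged) F~s~
  across independent runs; χ₄(0) = 0 exactly. A single-ensemble block
  estimator is deliberately not offered as the default because it is
  biased at these run lengths.
* **Van Hove** — displacement histograms pooled over all three coordinates
  (isotropy), matched-γ Gaussian reference, tail exponent η fitted beyond
  the 95th percentile of |Δx|/γ.
* **Droplets** — connected components (union-find) of the graph with edges
  `|r_i − r_j| < 2σ`, `|i − j| > 1`, minimum droplet 10 beads. The growth
  exponent of n(t) (mean bp per droplet) is fitted where the
  ensemble-averaged droplet mass lies between 5% and 30% of the chain:
  below that the formation stage still dominates, above it a finite chain
  is in its final-merger stage (2–3 droplets), which is saturation rather
  than Lifshitz–Slyozov coarsening. Per-seed exponents at N ≈ 800 scatter
  widely because individual merge events are discrete; the exponent is
  therefore always fitted on the seed-averaged n(t).

# Problem sizes and what reduced scale can and cannot show

The published model is run at N = 10,000 (12 Mbp) on HPC resources. This
package's tests and acceptance analyses run the same model at N = 300–1000
on one CPU in minutes, which reproduces the mechanism-level results —
collapse, micro-phase separation, A-periphery/B-core polarization,
two-regime P(s) with a small-s exponent near −0.75, droplet coalescence
with n(t) ~ t, glassy-vs-liquid dynamical contrast, broad P(α), λ ≈ 4
contact–distance coupling — with quantitative shifts that are understood
finite-size effects:

* at N ≈ 500 roughly half the beads sit within 1 σ of the globule surface,
  so surface-enhanced mobility biases the global MSD exponent α upward
  (≈ 0.55 at N = 500–1000 against 0.45 at full scale; the bias shrinks as
  N grows);
* the large-s P(s) regime (s^−1.25) needs ≳ 1.5 decades of s beyond the
  crossover, i.e. N ≥ 5000 — beyond a desk-scale run; the estimator chain
  for it is validated on planted two-regime curves instead;
* a liquid (ε = 1.0 k~B~T) globule of N ≈ 300 never shows a cleanly
  exponential F~s~ at k ~ 1/r_s: polymer-connectivity subdiffusion keeps
  β ≈ 0.7, and the liquid/glass contrast is asserted as a strict ordering
  (β_glass < 0.7 with the liquid clearly above it, χ₄ amplitudes differing
  several-fold with an interior peak only in the glass) rather than as
  β_liquid = 1;
* A/B segregation (g_AA, g_BB > g_AB) is already present at ε = 1.0 with
  the 11/9 ratio — eliminating it requires the ε_AB = ε homopolymer
  control, which is the control the package tests for compartment
  absence.

The acceptance analyses pick problem sizes per observable: the global MSD
exponent uses five N = 1000 chains (the largest size whose surface bias is
acceptable), the contact–distance exponent λ uses three N = 500 cells with
long (20 τ) production runs — λ needs well time-averaged distance maps, and
at fixed compute budget more sampling per cell at smaller N beats larger
frozen cells — and droplet coarsening uses five N = 800 chains under γ = 1
Langevin so the whole coalescence cascade fits one run. Collapse always
uses `collapse_chain()`, which anneals in 500 τ chunks until the radius of
gyration plateaus rather than for a fixed time, because the collapse time
varies about two-fold between seeds.

# Known limitations

No hydrodynamics, no bending stiffness, two epigenetic classes only, no
confinement (collapse is purely attraction-driven — the model was also
published without an explicit confining sphere, and none is applied here),
no Hi-C matrix normalization (ICE/KR) and no `.hic`/cooler readers — dense
TSV only. Loop anchors are fixed for a run: loop extrusion kinetics are out
of scope. t-SNE embeddings of single-cell WLM populations are left to
external tooling; `wlm_similarity_matrix()` exposes the `√(1−ρ)`-ready
correlation matrix.
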