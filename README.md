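# ccm — chromosome copolymer model

`ccm` simulates a segment of an interphase chromosome as a **two-state
bead–spring copolymer with fixed loop anchors** and quantifies everything the
model predicts about chromatin organization and dynamics: contact maps and
their P(s) scaling, A/B compartments, TADs, radial micro-phase separation,
Ward-linkage structural heterogeneity, and the glassy dynamics of individual
loci.

It is aimed at chromatin biophysicists and computational genomicists who
want a self-contained, desk-scale implementation of the copolymer picture of
genome organization: every bead represents 1200 bp (~six nucleosomes,
diameter σ = 70 nm) and carries an epigenetic label — A (active, ChromHMM
states 1–11) or B (repressive, states 12–15). The energy is

```
E = U^S + U^L + U_LJ
```

with FENE+WCA chain bonds `U^S`, identical permanent bonds `U^L` between
CTCF loop-anchor pairs, and a truncated-shifted Lennard-Jones pair term
`U_LJ` whose well depth is ε = 2.4 k_BT for same-type pairs and ε·9/11 for
cross-type pairs (ratio ε/ε_AB = 11/9). That single asymmetry drives A/B
micro-phase separation; contacts are scored at r_c = 2σ. Brownian dynamics
(overdamped, for dynamical observables) and low-friction Langevin dynamics
(for sampling/collapse) run on a compiled kernel with cell-list neighbor
search; chains collapse from extended conformations with no confinement.

The analysis suite implements, among others: contact probability `P(s)` with
two-regime crossover detection, subchain contacts `A(s)`, Spearman
correlation maps with spectral co-clustering and adjusted mutual
information, directionality-index TAD calling, radial distribution
functions `g_AA/g_BB/g_AB(r)` and radial density profiles, mean distance
maps with `R(s)`/`δR(s)`, Ward linkage (cophenetic) matrices and their
cell-to-cell Pearson population `P(ρ)`, Hi-C→distance conversion
(`R ∝ P^(-1/4.1)`), the contact–distance exponent λ, gyration-tensor TAD
shapes, droplet (CD) detection with coalescence growth `n(t)`,
center-of-mass-subtracted MSD `Δ(t)`, per-locus exponents `P(α)` and the
scaling relation `α = 2ν/(2ν+1)`, the self-intermediate scattering function
`F_s(k,t)` with stretched-exponential fits, the fourth-order susceptibility
`χ₄(t)`, Van Hove functions, and radial/type-resolved mobility.

## Worked example

Collapse a 500-bead copolymer (24% A, sparse loops) and look at its
structure:

```r
library(ccm)

params <- ccm_parameters(n_beads = 500)          # sigma 70 nm, eps 2.4 kT
ann    <- synth_annotation(500, mean_block_len = 50, fraction_A = 0.24, seed = 1)
loops  <- synth_loops(500, n_loops = 12, mean_span = 20, seed = 1)
model  <- energy_model(params, ann, loops)

x0  <- init_extended(model, seed = 1)
pre <- run_brownian(x0, model, 30000, dt = 1e-4, seed = 1)       # close loops
col <- run_langevin(traj_frame(pre, n_frames(pre)), model,
                    60000, dt = 0.01, friction = 0.1, seed = 1)  # collapse
tail(traj_rg(col), 1)
#> [1] 3.892942            # collapsed globule, Rg in sigma (~272 nm)

prod <- run_brownian(traj_frame(col, n_frames(col)), model,
                     100000, dt = 1e-4, seed = 2, save_every = 100)

cm <- contact_map(prod, params)
ps <- attr(contact_probability(cm), "log_binned")
fit_power_law(ps$s, ps$P, fit_range = c(2, 100))$exponent
#> [1] -0.8915907          # small-s contact probability decay, P(s) ~ s^-0.89

g  <- lapply(c("AA", "BB", "AB"), function(p)
  max(radial_distribution(prod, ann, p, dr = 0.2)$g$g[1:8], na.rm = TRUE))
unlist(g)
#> [1] 4.5829825 3.4357099 0.7151452   # g_AA, g_BB >> g_AB: micro-phase separation

fit_alpha(msd(prod), lag_range = c(1, 10))$alpha
#> [1] 0.6977153           # subdiffusive loci
```

The numbers above are what the code printed for these seeds on one CPU
(about two minutes): the chain compacts from an extended ~480 σ start to an
Rg ≈ 3.9 σ globule, the small-s contact probability decays with an exponent
near the Hi-C value −0.75, and the same-type g(r) peaks dominate the
cross-type peak (micro-phase separation). The single-run MSD exponent is
well above the condensed-chain prediction 0.4–0.45 because a 500-bead
globule is mostly surface and one short run is noisy; the seed-averaged
N = 1000 ensembles of the acceptance script give ≈ 0.55 (see the methods
vignette for the finite-size discussion).

A thin command-line front end wraps the same pipelines:

```sh
Rscript inst/cli/ccm.R simulate --seed 1 --out run1
Rscript inst/cli/ccm.R analyze-contacts --traj run1/trajectory.xyz --out run1/contacts
```

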