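---
title: "The Strings-and-Binders model in sbsfold: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Strings-and-Binders model in sbsfold: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`sbsfold` implements the Strings-and-Binders Switch (SBS) picture of
chromatin folding. A genomic region is coarse-grained into a chain of beads
(one bead per bin, e.g. 30-50 kb), and folding is driven by diffusing
*binder* particles: a binder of type `t`, present at concentration `c` with
binding affinity `E_X` (in kT), attracts every bead that carries binding
sites of type `t`. Because one binder can touch several beads at once,
binders bridge distant parts of the chain and loops, domains and
higher-order structures emerge spontaneously from the one-dimensional
arrangement of binding sites — the *binding profile* — without any imposed
3D constraints.

The package covers the full analysis cycle around that model:

* **simulate** — Langevin dynamics of chain plus binders
  (`simulate_trajectory`, `run_ensemble`);
* **observables** — gyration radius, contact maps, contact-probability
  decay `P(s)`, and thermodynamic phase classification
  (`contact_map_from_ensemble`, `contact_curve`, `classify_phase`);
* **mixture** — decomposition of an observed `P(s)` into the three pure
  folding states (`estimate_pure_curves`, `fit_mixture`);
* **inference** — recovery of a multi-type binding profile from a contact
  matrix by simulated annealing (`infer_binding_profile`);
* **tracks** — correlation of binding-domain abundance with epigenomic
  signals (`bin_track`, `correlate_profile_tracks`);
* **synthetic data** — planted-architecture generators that make every
  stage testable without external data (`make_random_profile`,
  `synth_contact_map`, `synth_track`);
* **pipeline** — the orchestrated end-to-end analysis (`run_pipeline`) and
  a thin command-line front end (`inst/cli/sbsfold.R`).

## Dynamics and force field

The integrator is underdamped Langevin in the BAOAB splitting, with
reduced units: bead diameter sigma = 1, kT = 1, time tau = 1, mass 1.
Defaults: timestep 0.01 tau, friction 0.5/tau. The force field is the
standard bead-spring (Kremer-Grest) set-up used throughout the chromatin
polymer literature:

* FENE bonds between consecutive beads (K = 30 kT/sigma^2, R0 = 1.5 sigma)
  plus the repulsive core, giving an equilibrium bond length near 0.961
  sigma;
* purely repulsive excluded volume between all particle pairs
  (shifted-truncated 12-6, cutoff 2^(1/6) sigma);
* a truncated-shifted 12-6 well between a binder of type `t` and beads
  carrying sites of type `t`, depth `E_X * copy_number`, cutoff 1.5 sigma
  (binder valence is not limited: a binder bridges as many beads as fit
  within its interaction range);
* periodic cubic box. With binders present the default box fixes the
  total volume fraction at 0.1, which is what turns a binder count into a
  concentration; binder-free chains get a dilute box wide enough that a
  coil does not meet its periodic images.

Trajectories are bitwise reproducible from an integer seed on one
platform (the generator is a self-contained counter-seeded xoshiro256**
stream, so results do not depend on R's global RNG state); across
platforms identity is statistical, not bitwise. A run aborts with the step
index if any bond approaches the FENE divergence or a coordinate becomes
non-finite — the practical signature of a too-large timestep. For deep
wells (`E_X` of 6-9 kT) we use timesteps of 0.004-0.008 tau.

Initial states: `build_initial_saw` grows an open self-avoiding walk
(bond length 1.0, hard core 0.8 sigma) — the natural starting point for
folding-dynamics experiments. `build_compact_start` grows the chain inside
a sphere of radius `0.85 N^(1/3)`; globule-phase *equilibrium* sampling
starts there instead, because a coil-to-globule quench coarsens slowly
(droplet merging) and would dominate the run time at larger N, while
liquid-like rearrangement inside an already-compact droplet equilibrates
quickly. Zero-temperature runs are deterministic damped relaxation; note
that a freshly grown walk with bond length 1.0 is not at the force-field's
bond minimum, so beads move (to bond length 0.961) even at T = 0.

## Phases and their classification

The homopolymer-plus-binders system has three stable states: an open
**coil** (low `c`, low `E_X`), a compact **disordered globule** (liquid-like
binder-bead droplet), and a compact **ordered globule** at high `c` and
high `E_X`. `classify_phase` labels an equilibrated ensemble in two steps:

1. *Coil vs globule.* The equilibrium chain Rg (root-mean-square over the
   retained frames, the canonical scaling quantity) is compared on a log
   scale against two calibrated predictions: the self-avoiding-walk
   scaling `0.47 N^0.588` and the compact-droplet scaling
   `0.60 (N + n_bound)^(1/3)`, where `n_bound` counts binders bound to the
   chain. The droplet prediction uses the *total* particle number because
   bound binders dilute the beads: the bead-only Rg of a globule grows
   with droplet size. The nearer model wins. The amplitudes were
   calibrated once on dedicated binder-free and strong-binding runs. The
   reported `nu_estimate = log(Rg / 0.45) / log(N)` is a diagnostic, not
   the decision variable.
2. *Ordered vs disordered.* Compact states are split by the mean local
   Steinhardt q6 of the bound binders (neighbors within 1.4 sigma, beads
   and bound binders pooled). Two caveats are worth knowing. First, local
   q6 has a noise floor of roughly `1/sqrt(n_neighbors)`, so with ~7
   first-shell neighbors even a liquid scores ~0.44; absolute textbook
   thresholds (e.g. 0.30 for dense LJ systems with 12-neighbor shells) do
   not transfer. Second, on these run lengths the high-affinity corner
   does not crystallize into long-range order (global Q6 stays small); it
   is an arrested, *locally* ordered packing, which is what the local q6
   detects. The operational threshold of 0.465 was calibrated once against
   the two compact corner settings (liquid corner 0.437-0.452, arrested
   corner 0.482-0.504 across replicas, replicate sd below 0.006) and is
   reported in the diagnostics so downstream users can see how close a
   call was.

*Equilibration.* Before classifying, the replica-averaged Rg(t) must show
no systematic decay: the mean over the first quarter of saved frames may
exceed the mean over the last quarter by at most 20% of the overall mean.
A short plateau-window test is deliberately not used: an equilibrated coil
fluctuates by ~10% over the last third of a typical run (Rg decorrelates
on the Rouse time, leaving few independent samples per window), while a
quench transient shows a ~50% systematic decay — the signed first-vs-last
contrast separates the two reliably.

## Contact maps and P(s)

`contact_map_from_ensemble` counts, over the retained frames of all
replicas, the fraction in which two beads are within a capture radius
(minimum-image distance). The default radius is 3.5 sigma, a generous
Hi-C-like capture volume; with it the simulated coil reproduces the
established contact-decay exponent (log-log slope of `P(s)` near -2.1
over 2 <= s <= N/4), and the globule curves sit far above the coil at
large separation, keeping the three pure-state shapes well separated.
Tighter radii (1.5 sigma) steepen the apparent coil decay at these chain
lengths and, in the arrested ordered state, miss bead pairs bridged by an
interposed binder (bead-binder-bead spacing ~2 sigma). The first half of
every trajectory is discarded as equilibration by default.

## The pure-state mixture model

An observed `P(s)` is modelled as a non-negative linear combination of
the three pure-state curves, with one free positive overall scale (contact
data are count-valued, so only relative structure matters). Pure curves
are simulated once per chain length by `estimate_pure_curves` (coil:
binder-free; disordered globule: `E_X` = 4 kT, one binder per bead;
ordered globule: `E_X` = 9 kT, two binders per bead; globule regimes from
compact starts) and cached to disk keyed by their generating parameters.
Each regime is verified by `classify_phase` and the function refuses to
return curves from a regime that landed in the wrong phase.

`fit_mixture` first log-bins both the observed curve and the basis over
the same geometric separation bins (factor 1.3) — the standard way to
average `P(s)` so each decade of separation carries comparable weight —
then solves a non-negative least-squares problem for a starting point and
refines it by minimizing squared residuals of `log P(s)`, weighted by bin
occupancy. The log-space objective matches the multiplicative error
structure of contact data and is what makes the two globule states (whose
curves are nearly parallel) separable at realistic noise: with 5%
multiplicative noise the recovered fractions are within 0.1 of truth, and
noiseless constructed mixtures are recovered exactly. Fractions are
reported on the simplex (non-negative, summing to one); the fit quality
is `chi^2 = sum (obs - model)^2 / model` over the fitted bins. Curves
simulated at one N are mapped to another via fractional separations
`s/N` with log-log interpolation.

## Binding-profile inference

`infer_binding_profile` estimates where binding sites of each type sit
along the chain from a contact matrix alone. Running full dynamics inside
the optimization loop is not tractable at interactive scale, so the
annealer scores candidate profiles with a mean-field forward model:

```
M_ij = min(saturation, |i-j|^(-decay) * (1 + enrichment * sum_t a[t,i] a[t,j]))
```

a power-law backbone boosted by shared binding types. The inferred profile
can then be handed to `run_ensemble` for a full 3D reconstruction, which
is exactly what `run_pipeline` does. The cost is the mean absolute
difference between model and data after each is scaled to unit
off-diagonal mean (robust to heavy-tailed contact noise, and free of the
arbitrary count scale), plus a sparsity penalty `lambda * sites / n_beads`
that rules out the sites-everywhere degenerate fit. One Monte-Carlo move
flips a single (type, bead) occupancy; moves are accepted by Metropolis
at the current temperature; equal-cost moves are accepted so the chain
stays mobile on plateaus; temperature cools geometrically (factor 0.95
per sweep) from a starting value auto-calibrated on 100 probe moves to
give ~50% initial uphill acceptance; the best profile across restarts is
returned, with a non-increasing best-so-far cost trace. Site occupancy is
binary in inference; integer copy numbers are a synthesis-side
generalization.

Two identifiability notes. Binding-site *types* are a gauge freedom (any
relabelling gives the same forward map), so recovered profiles are scored
after a maximum-weight bipartite matching of inferred to reference types
(`match_types`, `profile_jaccard`). And a perfectly *uniform* enrichment is
invisible to the scale-invariant cost — multiplying every off-diagonal
entry equally is absorbed by the normalization — so the degenerate
one-type, all-beads case is only identifiable when saturation imprints a
shape on the map. Real (non-uniform) architectures do not suffer this.

The number of types is user-supplied: published locus models use 11 types
for a 78-bin locus and 15 for a 160-bin locus, with no stated selection
rule; a cost-vs-n_types sweep is a one-line loop for users who want an
elbow criterion.

## Epigenomic tracks

`bin_track` averages interval signal onto the model's bins
coverage-weighted; bins with no covered bases are missing (`NA`), not
zero — no-data and no-signal are different things. `correlate_profile_tracks`
reports raw Pearson r between each type's abundance row and each binned
track, dropping missing bins pairwise and flagging cells with fewer than
4 shared bins; no multiple-testing correction and no track normalization
are applied (r is invariant under positive affine transforms of the
signal anyway; binarization or quantile normalization is left to the
user's judgement).

## Synthetic data: what it emulates, what it does not

`make_random_profile` plants a binding-domain architecture as
geometric-length runs of uniformly random types (every type guaranteed to
occur); `synth_contact_map` pushes a profile through the forward model
and applies multiplicative log-normal noise of chosen coefficient of
variation (Hi-C counts are overdispersed, and ratio noise is scale-free,
matching how the inference cost normalizes); `synth_track` plants a
Gaussian-noised signal on one type, floored at zero. Generators are pure
functions of their arguments including the seed.

These fixtures emulate the *structure* of real inputs — block
architectures at the published locus scales (11-15 types over 78-160 bins
at 30-50 kb), backbone decay plus domain-driven enrichment, tracks
correlated with chosen types — but not Hi-C technicalities: no
mappability or ICE-normalization artifacts, no distance-dependent noise
heterogeneity, and the synthetic map's enrichment is generated by the
same family of forward models the inference assumes. Passing the planted
recovery suite therefore demonstrates the estimators' correctness and
the pipeline's integrity, not performance guarantees on experimental
matrices.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen to finish in minutes
while leaving the scaling laws measurable: N-sweeps over chains of 16-128
beads with 10 replicas per point (60k-300k steps for coils — 5 to 85
Rouse times depending on N — and 40k-77k from compact starts for
globules), pure curves at N = 48 with 8 replicas per regime, and a
160-bin / 15-type locus analysis with 250 annealing sweeps. One caveat
the suite reports rather than hides: at these chain lengths the
Kremer-Grest force field is still inside its stiffness/thickness
crossover, so the plain log-log fit of coil Rg vs N yields an effective
exponent of about 0.65 — above the asymptotic SAW value 0.588 and above
the [0.54, 0.64] validation band, which assumed milder corrections to
scaling; the corresponding check fails by that margin while every other
signature of SAW behaviour (contact-decay slope near -2.1, clear
separation from the globule fit of ~0.31, classification margins) holds.
The globule band [0.28, 0.38] brackets 1/3. Known
limitations: no hydrodynamics, no confinement sphere, no entanglement
analysis, unlimited binder valence, and the ordered corner is an arrested
packing rather than an equilibrium crystal on these timescales.
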