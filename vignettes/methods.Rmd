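---
title: "Methods: delta-learned implicit-solvent models for ionic solutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delta-learned implicit-solvent models for ionic solutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ionsolv)
```

## The model

`ionsolv` builds implicit-solvent coarse-grained models of aqueous ionic
solutions, optionally around a frozen nucleic-acid scaffold. Water is not
represented; its mean effect enters through three channels:

1. **A physics prior.** Pairwise 12-6 Lennard-Jones interactions plus
   Coulomb electrostatics evaluated with the Wolf summation and screened by
   a dielectric continuum (`eps_r = 95` by default, the measured dielectric
   constant of a common three-site water model). The Wolf scheme used by
   default is the damped-shifted-force (DSF) variant: for charges $q_i,
   q_j$ at distance $r$ inside the cutoff $R_c$,

   $$u_{ij}(r) = \frac{k_e}{\varepsilon_r}\, q_i q_j \left[
     \frac{\operatorname{erfc}(\alpha r)}{r}
     - \frac{\operatorname{erfc}(\alpha R_c)}{R_c}
     + f_s\,(r - R_c) \right],$$

   with the force-shift constant $f_s$ chosen so that both the pair energy
   and the pair force vanish continuously at $R_c$, plus the standard Wolf
   self term. MD therefore never experiences an impulse at the cutoff. The
   damping $\alpha$ (default 2 nm$^{-1}$) and the variant
   (`dsf`/`energy_shift`) are configuration, not fixed physics: cutoff
   electrostatics schemes differ across MD engines, and we chose a
   standard, well-converged combination at the default $R_c = 1.2$ nm. The
   implementation is validated against a neutralized-shell (Evjen) direct
   lattice sum of the rock-salt Madelung energy, which it reproduces to
   about $5\times10^{-5}$ relative at $\alpha R_c = 3$.

2. **A trainable local correction.** The many-body part of the potential of
   mean force that the prior misses is carried by an atomic-energy model on
   rotation/translation/permutation-invariant environment descriptors
   (atom-centered symmetry functions): a radial Gaussian basis per
   neighbor-species channel and Behler-style angular (three-body)
   invariants per species pair, all under a $C^1$ cosine cutoff envelope.
   Each ML-visible particle contributes an atomic energy through a
   per-species head — a linear readout by default, or a one-hidden-layer
   tanh network (`hidden > 0`). Forces are exact analytic gradients, and
   the force-matching loss gradient with respect to the parameters is also
   analytic; both are verified against central finite differences in the
   test suite at every release.

3. **Delta learning.** The correction is trained on force residuals
   $\Delta F = F_\text{ref} - F_\text{prior}$ of reference configurations,
   so the prior carries all long-range physics and the correction only the
   local many-body remainder. The training loss is the mean squared force
   residual over configurations, ions and Cartesian components
   (`reduction = "sum"` restores the plain sum; the mean makes the loss
   scale independent of dataset size). Optimization is Adam with the cited
   defaults over whole-configuration mini-batches, with per-epoch
   train/validation curves, early stopping, and return of the
   best-validation parameters.

## Why the reference data are synthetic

No deposited all-atom database exists for this pipeline, and explicit
solvent simulation is out of scope. The package therefore ships an
**analytic oracle force field**: the prior plus closed-form extra terms —
per-pair sums of Gaussians under the same cosine envelope as the
descriptor basis, and an optional three-body term
$\lambda \sum_{j<k} (\cos\theta_{jik} + \tfrac13)^2 f_c(r_{ij}) f_c(r_{ik})$
among cations. Because $F_\text{oracle} = F_\text{prior} + F_\text{extra}$
holds to machine precision, the delta targets are known exactly and the
whole training pipeline becomes a controlled recovery experiment: the
held-out force error of a trained model can be compared against the ground
truth, something impossible with real reference data.

The shipped `ssip_oracle_nacl()` preset mimics the qualitative structure
of aqueous NaCl: a contact well (0.33 nm), a desolvation barrier
(0.40 nm), and a split solvent-separated feature with two PMF minima at
0.46 and 0.50 nm. The SSIP widths (0.015 nm) keep the two minima
resolvable at the default 0.01 nm RDF bin. Positions of the SSIP pair
follow the classic solvent-separated ion-pair phenomenology; depths are
order $k_BT$. A weak three-body term among Na$^+$ within the ML cutoff
supplies a genuinely many-body component so that angular descriptors are
exercised. What the oracle deliberately does **not** emulate: hydration
thermodynamics, dielectric saturation, finite-size Ewald artifacts, or the
faster diffusion of real coarse-grained models relative to all-atom ones.
Passing the recovery tests therefore demonstrates correctness of the
machinery (descriptors, gradients, optimizer, MD), not chemical accuracy
for any particular salt.

## Study conditions

The standard study used in the tests and the acceptance script, chosen
once:

* 32 Na$^+$ + 32 Cl$^-$ (64 ions) in a cubic 3.76 nm box — 1.0 mol/L;
* oracle Langevin MD at 300 K, 1 fs timestep, coupling time 0.1 ps;
* configurations with forces saved every 1 ps, 1900 labeled
  configurations after a 10 ps equilibration (a desk-scale stand-in for
  production databases of $10^4$–$10^5$ configurations);
* random 80/20 train/validation split;
* descriptor for this study: radial centers every 0.01 nm on
  [0.25, 0.90] nm, basis width 0.015 nm, angular invariants on; linear
  heads;
* structural closure: 4 ns of MD (frames every 0.5 ps, first 20 ps
  discarded) under the oracle and under the trained model from the same
  initial configuration, compared through Na-Cl RDFs at 0.01 nm bins.

These sizes keep the full pipeline in the tens-of-minutes range on one
CPU while leaving the statistical noise of the RDF comparison (about
0.03–0.05 in $g$) well below the closure tolerance.

## Numerical choices

* **Units.** nm, kJ/mol, ps, g/mol, elementary charge; $k_e =
  138.935458$ kJ mol$^{-1}$ nm e$^{-2}$, $k_B = 8.31446\times10^{-3}$
  kJ mol$^{-1}$ K$^{-1}$. Conversions (Å, m$^2$/s) only at reporting
  boundaries.
* **Minimum image.** Half-open convention $[-L/2, L/2)$; orthorhombic
  boxes only; every cutoff must satisfy $r_c \le \min(L)/2$, enforced at
  evaluation time.
* **Neighbor lists.** Verlet list with a 0.2 nm skin and
  displacement-triggered rebuild (any particle moving more than skin/2).
  Correctness, not speed, is the contract: the list-based MD force path is
  cross-checked against brute-force $O(N^2)$ evaluation in the tests.
* **LJ truncation.** Energy-shifted to zero at the 0.9 nm cutoff by
  default (forces unchanged); plain truncation via `lj_shift = FALSE`.
* **Overlap floor.** Pair distances below $10^{-4}$ nm raise an error
  rather than clamping: labeled data should never contain overlaps, and in
  MD such a configuration signals a broken setup.
* **Frozen scaffolds.** Frozen particles receive forces (for bookkeeping)
  but never move; pairs of two frozen particles are excluded from all pair
  terms — a rigid scaffold's internal nonbonded energy is an irrelevant
  constant, and the idealized synthetic atom layout would otherwise place
  LJ centers at unphysically small separations.
* **Integrator.** BAOAB-split Langevin: half-kick, half-drift,
  Ornstein-Uhlenbeck velocity update with $e^{-\gamma\Delta t}$ decay and
  exact stationary variance, half-drift, half-kick. At $\gamma \to 0$ this
  reduces exactly to velocity Verlet (NVE mode), which the tests pin
  against the closed-form Verlet recursion. An impulse-style variant was
  considered and rejected: BAOAB has better configurational sampling at
  1 fs and the exact NVE limit.
* **Degrees of freedom.** `instantaneous_temperature()` uses
  $3N_\text{mobile} - 3$ (momentum-removed initialization; a single mobile
  particle keeps 3). The MD engine's own log uses $3N$ under a Langevin
  thermostat, which does not conserve momentum — with 64 ions the $3N-3$
  convention would report temperatures 1.6% high purely through
  bookkeeping.
* **Feature standardization and regularization.** Features are scaled by
  their RMS over the training set, floored at 1% of the strongest channel,
  and training applies a decoupled weight decay (default $10^{-4}$).
  Together these keep the effective weights of rarely-activated features
  bounded, so the correction vanishes outside the sampled configuration
  space and the prior alone governs off-distribution geometry — without
  this, narrow radial basis functions below the sampled ion contact
  distance can acquire large spurious weights and destabilize MD, the
  classic delta-learning extrapolation failure.
* **Gap closure in residence times.** Vacancies of duration less than or
  *equal to* the tolerance (default 1 ps) are bridged; event duration is
  $t_\text{last} - t_\text{first}$, so a single-frame visit has zero
  duration. Both conventions are pinned by tests.
* **Diffusion fits.** MSD over multiple time origins on unwrapped
  coordinates (exact per-particle image counters from the engine, never
  heuristic unwrapping); the Einstein slope is fitted on a stated window
  (default 10–50% of the span) and reported together with an $R^2$ and a
  log-log MSD exponent, which flags ballistic or poorly averaged input
  instead of hiding it.
* **NDP normalization.** Cylindrical profiles are normalized by the
  species' box-mean density (flagged choice; with a scaffold present the
  bulk plateau sits slightly above 1 because the scaffold excludes
  volume).

## CG DNA mapping

Each internal (phosphorylated) deoxynucleotide maps to six CG sites at the
mass-weighted centers of template-defined atom groups: phosphate (`PH`,
charge $-1$), two sugar halves (`S5`, `S3`) and three base groups
(`B1`-`B3`). The partition ships as an editable TSV — it is data, not
code — and is a reconstruction in the spirit of published six-site
("sugar"-type) CG DNA models; the original partition is not reprinted
anywhere accessible, so the template is labeled a reconstruction. The two
non-bridging phosphate oxygens are appended as auxiliary LJ-only sites:
charge exactly zero and invisible to the correction potential.
`build_ideal_bdna()` produces an idealized periodic B-form duplex
(0.34 nm rise, 36° twist) whose atom names and counts follow standard
internal residue compositions (DA 32, DC 30, DG 33, DT 32 atoms — 634
atoms and 120 ML-visible CG sites for a 10-bp duplex); its atomic
coordinates are a deterministic synthetic layout that respects the helical
frame and group radii, not fitted crystallographic geometry. Mapping is
exactly mass-conserving per nucleotide and commutes with rigid transforms.

## What the tests do and do not show

The acceptance-style checks demonstrate: exact structure counts; Wolf/DSF
agreement with the Madelung limit; machine-precision energy-force
consistency; NVE drift below $10^{-4}$ over $10^4$ steps and correct
thermostat statistics; held-out force RMSE of the trained correction far
below the prior-only baseline; and closure of the Na-Cl RDF between
oracle-MD and trained-model-MD to within one bin in the first-peak
position and $\lesssim 0.1$ in $g$. Because the oracle lies exactly in the
model's function space by construction (same envelope family and angular
span), these are tests of the machinery at its best-case; real reference
data would add representation error on top. The concentration-transfer
protocol (train at 1.0 mol/L, evaluate at 2.0 mol/L) reports the RMSE
degradation without a pass/fail target — coarse-grained potentials are
state-point dependent, and the protocol's job is to quantify, not to hide,
that dependence.

## Known limitations

* Orthorhombic periodic boxes only; no barostat (NVT/NVE only).
* The DNA scaffold is frozen; flexible DNA is out of scope.
* The correction model's defaults (8 radial functions, 4 angular
  invariants) are engineering choices; problem-specific studies should
  size the basis to the features they must resolve, as the shipped NaCl
  study does.
* Einstein diffusion estimates at desk-scale trajectory lengths carry
  window sensitivity; the window is always reported with the estimate.
* The CLI's `gen-data`/`train`/`simulate` pipeline wires the NaCl oracle
  study; scaffold workflows are driven through the R API.
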