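---
title: "Locating mobile domains by SAXS / iCM-SANS rigid-body screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating mobile domains by SAXS / iCM-SANS rigid-body screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large symmetric assemblies often carry domains that fluctuate too much
to be resolved by crystallography or cryo-EM: the map simply has no
density where the domain spends its time.  Solution scattering sees
*all* the mass, so a 1-D SAXS profile constrains where the missing
domains are on average — but one profile is far too degenerate to place
twelve domains.  Inverse contrast-matching SANS (iCM-SANS) breaks the
degeneracy: if every component except the one of interest is ~75%
deuterated and the buffer is 100% D2O, the deuterated components have
the same neutron scattering-length density as the solvent and vanish,
and the measured curve reports the visible component alone.

`contrastscreen` implements the computational side of this strategy for
a C6-symmetric assembly with two mobile domains per asymmetric unit
(twelve in total, tethered by a ~20-residue linker): assemble a rigid
core from known structures, enumerate rigid-body poses of the mobile
domains under the C6 symmetry, screen the candidates by reduced
chi-square against both channels, classify survivors by where the
mobile domains sit, and verify models at trajectory level.

## Representation and scattering model

Structures are coarse-grained to **one bead per residue** (residue
centre of mass by default; the alpha-carbon as a fast alternative).
Each bead carries a residue name, mass, component and domain labels,
and a deuteration fraction.  Profiles come from the Debye sum

$$ I(Q) \;=\; \sum_i \sum_j b_i\, b_j\, \frac{\sin(Q d_{ij})}{Q d_{ij}}, $$

with per-bead excess scattering lengths

* x-ray: residue electron count minus solvent electron density
  (0.334 e/A^3 for water) times displaced residue volume;
* neutron: tabulated coherent scattering lengths, with non-exchangeable
  hydrogens mixed as $(1-d)\,b_H + d\,b_D$ for deuteration fraction
  $d$, exchangeable hydrogens (backbone amides plus side-chain O-H,
  N-H, S-H) mixed by the solvent D2O fraction, minus solvent
  scattering-length density times displaced volume.

Residue volumes are the Fraser–MacRae–Suzuki displaced-solvent volumes,
the table solution-scattering software descends from.  The displaced
volume — not a crystal-packing volume — is the quantity that belongs in
the excess scattering length; with packing volumes the match point of a
75%-deuterated protein lands visibly off 100% D2O, contradicting the
design of the experiment the package models.  The tables ship as code
(`residue_table()`), including a pseudo-residue `AVE` (abundance-
weighted mean composition) used by the synthetic models.

Beads are point scatterers by default.  A Gaussian bead form factor
(radius of the sphere with the residue's volume) can be switched on,
but at the Q-ranges used here (Q < 0.2 /A) it is a near-constant
factor and the chi-square fit absorbs it.

Two evaluation paths exist for the Debye sum: an exact double loop
(`method = "direct"`) and a contrast-weighted pair-distance histogram
(`method = "histogram"`, default bin 0.5 A, phase error ~ Q x bin / 2).
The histogram path makes screening thousands of ~1000-bead candidates
cheap; the direct path is the reference the histogram is tested
against.  No hydration shell is modelled — a deliberate simplification,
so absolute chi-square values against *real* data are comparable only
in rank and order of magnitude.

## Fits and scores

**Guinier.** `guinier_fit()` fits ln I against Q^2 from the low-Q end
and shrinks the window until $Q_{max} R_g \le$ `limit` (default 1.3,
the conventional working limit).  One caveat discovered by validating
against the analytic sphere: for a homogeneous sphere the Guinier
expansion itself is biased by +1.7–1.9% at $Q R_g = 1.3$, under any
point weighting.  Validation against closed forms therefore fits within
$Q R_g \le 0.8$, where the truncation bias of the law is ~0.7%; for
noisy experimental profiles the wider 1.3 window remains the default
because statistical error dominates there.

**Chi-square.** `chi2_score()` interpolates the computed curve onto the
experimental grid (linear in (Q, log I)), applies the closed-form
optimal scale factor, and reports
$\chi^2 = \tfrac{1}{N-1}\sum_k \big[(c\,I_{calc}(Q_k) -
I_{exp}(Q_k))/\sigma_k\big]^2$.  A constant-background term exists
behind a flag and is off by default.  The score is invariant to any
positive rescaling of the computed curve.

**Resolution smearing.** Gaussian convolution in Q with a constant,
per-point or functional width; zero width is the identity exactly.

## Candidate generation and screening

The rigid core ("Complex 1") is assembled by least-squares
superposition (Kabsch, proper rotations only) of a ternary unit onto
each CI domain of the hexamer; adding full-length dimers in their
crystal arrangement ("Complex 2") is done *without* clash resolution,
because the steric overlap of the rigidly placed N2A domains with the
B ring is precisely the observation that forces a pose search.

Candidates place the two mobile domains of one asymmetric unit on a
cylindrical grid (r, theta, z, finite orientation set) and replicate
the identical pose to all six sectors.  A candidate is kept only if no
two beads of different rigid bodies come closer than the clash cutoff
(default 3.5 A — an effective heavy-atom exclusion distance at
residue-bead resolution), counted with a linear-time cell list.
Screening is staged exactly as the study design prescribes: stage A
keeps $\chi^2_{SAXS} < 10$, stage B evaluates
$\chi^2_{SANS}$ *only* for stage-A survivors and keeps $< 3$; the
refined (6.0 / 1.5) and post-linker (5.0 / 1.5) stages reuse recorded
scores via `rethreshold()`.  Raising any threshold can only add
survivors (tested as a property).

**Linkers.** Feasibility is a geometric test: anchors at most
`n_res` x 3.8 A apart (boundary inclusive; 3.8 A is the virtual
CA–CA bond).  `build_linker()` grows up to 100 conformers by a guided
self-avoiding random walk (step 3.8 A, clash-checked, bias towards the
far anchor that tightens as slack runs out, closing bead on the
two-sphere intersection circle) and returns the conformer minimizing
$\chi^2_{SAXS}$ of the completed model when an experimental profile is
supplied, otherwise the most direct conformer.  This replaces
fragment-library loop modelling with a transparent geometric
surrogate; it makes no claim about linker *conformation*, only about
bridgeability and its effect on the profile.

## Classification

The complex frame puts the origin at the core centre of mass, the
z-axis along the symmetry axis (oriented CII-side to B-side), the
azimuth origin at the first B protomer, and the reference plane z0 at
the top of the B ring (maximum frame-z among B-domain centres of
mass).  Types: both mobile-domain COMs strictly below z0 (Type 1),
one below (Type 2), none (Type 3); "below" is strict, so a COM exactly
on the plane is not below it.  Cells are half-open boxes
`[lo, hi)` in (r, theta mod 60, z) — two rings U/L, two cells each.
The shipped toy grid is designed; `fit_cell_grid()` offers a
data-driven alternative (U/L split at mid-height, then 2-means per
ring) for exploratory use.  Group labels depend only on the cell pair
and on which C-domain each N-domain links to, encoded as an azimuthal
sector offset; the offset table distinguishing the groups that share a
cell pair is configurable, with a documented default mapping offsets
0/+1/−1 to the first/second/third label of each pair — the original
scheme's exact offsets are not published at this level of detail, so
the table is a best-effort default, not a claim.

## Trajectory verification

`make_jiggle_trajectory()` is the stand-in for MD: the core is frozen
and each mobile-domain copy's COM follows an independent stationary
AR(1) walk whose 3-D RMS amplitude is the requested value (per-
coordinate sd $a/\sqrt3$, per-frame memory phi = 0.9), plus a small
orientation wobble.  It reproduces the qualitative signature that
motivates trajectory verification — mobile domains fluctuate, the core
does not — and supports exact expectations (requested RMS vs measured
COM-RMSF).  It does not model physical forces, solvent, or correlated
inter-domain motion; a conclusion that depends on *why* domains move
cannot be drawn from it.

`rmsf_com()` aligns frames on the rigid core (so a global rigid motion
of every frame changes nothing) and reports per-domain COM
fluctuations.  `dccm()` computes the normalized fluctuation covariance
$c_{ij}/\sqrt{c_{ii}c_{jj}}$ after global or per-group (per-dimer)
alignment; zero-variance beads are masked as NA with a warning instead
of poisoning the matrix.  `profile_series()` evaluates per-frame
profiles on the experimental grids, chi-square time series, the
unweighted ensemble-average profile and its chi-square, and per-frame
Guinier radii.  `grade_model()` applies the asterisk rules: for
chi-square, 0/1/2 asterisks for $\chi^2 \le \chi_0^2$,
$\le 1.2\chi_0^2$, beyond (with $\chi_0^2$ = 5.0 SAXS / 1.5 SANS); for
Rg, thresholds at one and two experimental errors.

## What the synthetic data do and do not show

`make_toy_complex()` builds the study geometry at residue-bead scale:
two stacked hexameric rings (component C), a B ring whose top defines
the reference plane, a peripheral collar of paired small domains
(component A), and two mobile domains per dimer whose ground-truth
poses sit in the U1/L1 cells just below the reference plane, linkable
to their C-domains within 20 residues.  Pseudo-domains are
deterministic quasi-uniform bead spheres (low-discrepancy volume
fill), chosen over surface shells because a filled sphere is the
better stand-in for a compact folded domain and still has a closed-form
radius of gyration ($\sqrt{3/5}\,\rho$).  All beads are the `AVE`
pseudo-residue, making contrasts exact rather than
sequence-fluctuating.

Simulated experiments multiply the true curve by Gaussian noise,
2% relative at low Q growing linearly to 10% (SAXS) and 3–12% (SANS)
at high Q — typical of size-exclusion-coupled data — and report the
generating sigma honestly.  Decoy candidates displace both mobile
domains by 10–40 A (a floor keeps decoys genuinely wrong) with random
reorientation, kept clash-free.

Passing tests on these conditions shows the machinery is correct and
the information content of the two channels suffices to recover a pose
of this magnitude under this noise.  It does not show that real data
of a particular quality determine a unique pose, nor anything about
hydration, interparticle effects, flexibility of the core, or absolute
intensity calibration, all of which are outside the model.

## Problem sizes and numerical choices

The shipped study conditions, chosen once as desk-scale versions of
the workflow: toy complex of ~1000 beads (24 beads per domain),
simulated profiles of 200 (SAXS) and 150 (SANS) points, decoy sets of
500 + truth over 5 noise replicates, jiggle trajectories of 10^4
frames for fluctuation statistics and ~10^2 frames for profile
averaging, Debye histogram bin 0.25–0.5 A, sphere oracle at 10^4
beads.  Enumeration grids default to ~10^2–10^4 pose pairs; the
full-scale grid of the original study (~2 x 10^7) is the same logic at
a larger constant.

Degenerate inputs are errors, not guesses: fewer than 3 superposition
pairs, collinear point sets, empty selections, non-positive
intensities in a Guinier window, profiles without sigma, infeasible
linker anchors, all-zero contrast.  On-axis points get theta = 0 by
convention and are never assigned to a cell.

## Reproducing the numbers

`scripts/acceptance.R --seed N --out file.json` regenerates every
headline quantity from scratch (sphere-oracle deviations, contrast
residuals, disk slope, recovery statistics, grading-rule check,
trajectory metrics) with all randomness derived from the seed.  The
numbered drivers under `analysis/` run the same pipeline as a readable
narrative and write their tables under `results/`.
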