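---
title: "Methods: desk-scale NPC structural pipelines with porekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale NPC structural pipelines with porekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porekit)
```

# Scope and model

`porekit` implements, at desk scale, the computational chain used to derive
in situ nuclear pore complex (NPC) structures and their molecular
inventories: subtomogram averaging (STA) with eightfold symmetry handling,
Fourier shell correlation (FSC) resolution estimation, pore-geometry
estimation from subunit coordinates, composite scaffold assembly with
stoichiometry accounting, multi-restraint rigid-body refinement against a
density map, TM-score structure comparison, and emPAI-based proteomics
bookkeeping. Every stage runs on synthetic inputs generated by the package
itself, so the whole chain is testable on one CPU without any external data.

All lengths are Angstrom internally; reports may convert to nm. Rotations
use intrinsic ZYZ Euler angles (degrees, right-handed) for tables and grids,
but every pose stores an explicit 3x3 matrix which is authoritative.
Volume resampling is trilinear with a stated relative tolerance of 1e-3 for
"equality" checks; Fourier work uses plain DFT conventions (`stats::fft`).

# The synthetic world

`ground_truth_complex()` + `make_complex()` render a C_n-symmetric ring of
Gaussian blobs (default n = 8, matching the NPC's octagonal symmetry)
embedded between two parallel membrane slabs, the stand-in for the nuclear
envelope. Two rendering choices matter:

* The membrane slabs are bounded by a soft radial disc. Infinite slabs
  would be clipped at the box corners under rotation, spuriously breaking
  the C8 invariance the generator guarantees (correlation > 0.999 under a
  360/n rotation).
* Blob widths should be kept at or above ~2.5 voxels; sharper features make
  trilinear interpolation, not the geometry, the accuracy limit.

`simulate_particles()` applies a ground-truth pose, zeroes Fourier
components inside a single-tilt-axis missing wedge (tilt axis = second
volume axis; a component is inside the wedge iff the angle between its
(axis1, axis3)-plane projection and axis3 falls outside the tilt range),
and adds i.i.d. Gaussian noise. SNR is defined as var(signal)/var(noise)
over the reference grid; `snr_to_sigma()` converts. The default acquisition
range is ±60°, a typical dose-symmetric single-axis scheme.

What the generator does *not* emulate: CTF modulation, dose-dependent
damage, tomographic reconstruction artifacts beyond the wedge, structural
heterogeneity, and crowding by neighbouring complexes. A green STA test
therefore establishes the correctness of the alignment/averaging machinery
under its stated noise model, not performance on raw cellular tomograms.

`simulate_subunit_table()` emulates the coordinate tables STA leaves
behind: subunits on a randomly oriented ring of known diameter with
isotropic positional noise; inward unit vectors point from each *noisy*
position to the true centre so direction noise is consistent with
positional noise. Pore occupancy is drawn from a stated distribution.

`simulate_peptide_table()` draws each tryptic peptide of each catalogue
protein as an independent Bernoulli detection per replicate — the minimal
generative model behind replicate presence tables.

# Subtomogram averaging

`align_subtomogram()` does an exhaustive rotation-grid search with
FFT-based translational scoring. For each candidate rotation the reference
is rotated, degraded by the particle's wedge, mean/variance-normalized
under the real-space mask, and correlated with the particle (normalized the
same way). Two caveats are deliberate:

* The particle is normalized once under the mask rather than re-normalized
  for every shift (the stationary-mask approximation); with the soft masks
  and modest shift limits used here the approximation is standard practice.
* Ties are broken by the first-encountered pose in the deterministic grid
  order.

The constrained cross-correlation is computed over Fourier components
outside the particle's missing wedge by construction (the wedge-degraded
reference has no power inside it). On a symmetric whole pore, in-plane
alignment is ill-posed — any rotation in the symmetry orbit scores equally —
so pose-recovery benchmarks (and, in practice, focused refinement) operate
on a single asymmetric unit, matching how spoke-level alignment is done
after symmetry expansion (`symmetry_expand()`).

`average_subtomograms()` maps each particle back through the inverse of its
pose and divides the summed Fourier terms by the summed (rotated) wedge
sampling masks, floored at one sample; Fourier voxels no particle covers
are zeroed. `iterative_refine()` alternates alignment and averaging with a
fixed per-iteration low-pass schedule (determinism over FSC-adaptive
filtering), splits particles even/odd by index for the final FSC, and
aborts if the mean constrained correlation drops by more than 0.2 in one
iteration. Gold-standard (fully independent half-set) refinement is not
attempted: at the scale of tens of particles a single-reference refinement
with post-hoc half-map FSC is the honest desk-scale variant, and the FSC it
produces should be read accordingly.

`fsc()` uses per-shell correlation with one-Fourier-voxel shells by
default; innermost shells hold few Fourier voxels, so noise-floor checks
are more stable at 1.5-voxel shells. `resolution_at()` reports 1/frequency
at the first downward crossing of the threshold (0.143 half-map
convention), linearly interpolated, with an explicit beyond-Nyquist
sentinel (`NA` plus attribute) when the curve never crosses.

Two practical effects show up even at desk scale and shape how the
refinement tests are posed. First, with in-plane-only particle
orientations (complexes standing in a membrane), an equatorial band of
Fourier space is inside the missing wedge for *every* particle, so the
average can never reach correlation 1 with the unfiltered truth — the
24-particle averages here plateau near 0.67 for geometric, not
statistical, reasons. Second, aligning particles against their own
average biases each particle toward its own noise (reference bias); the
per-iteration low-pass schedule suppresses it, and without a low-pass the
iteration visibly stalls. The refinement-improvement check therefore
starts from an average at coarse "manually picked" orientations and runs
the alignment against low-passed references, mirroring actual workflows.

# Pore geometry

Each subunit defines a line through its position along its inward normal.
The pore centre is the least-squares point minimizing summed squared
perpendicular distances to these lines (normal equations; exact
intersection when the lines are concurrent; a degenerate-geometry error
when all lines are parallel). The pore radius is the mean distance from
that centre to the subunits, and only pores with at least five observed
subunits are reported — the occupancy rule used for diameter statistics.
Distances between opposing subunits (i vs i+4 mod 8) are reported as
diagnostics but do not enter the headline diameter, whose definition via
the mean radius is explicit. Published diameters are quoted
membrane-to-membrane; this module measures subunit-centre diameters and
exposes a constant `membrane_offset` (default 0, documented) rather than
guessing a conversion.

# Scaffold composition and stoichiometry

The packaged composition encodes the AtNPC scaffold architecture: one
Y-complex ring at the CR (one Y-complex per asymmetric unit), two
concentric Y-complex rings at the NR (two per asymmetric unit, hence 16 in
the whole pore), a NUP214 complex and two NUP205–NUP93 complexes per CR
unit, one NUP205–NUP93 per NR unit, NUP155 connectors and a NUP62-complex
channel in the inner ring. HOS1, the plant functional homologue of ELYS,
is a Y-complex member, giving one copy per CR unit and two per NR unit.
Alternatives such as NUP93A|NUP93B are modelled as a single placement, and
with SEC13A|SEC13B likewise grouped the default model contains exactly 20
distinct species. Inner-ring copy numbers beyond the published statements
(4 NUP155, 2-fold IR core, 4-fold channel per spoke) follow the
human-NPC-like architecture and live in the editable JSON config, as do two
deliberately disabled entries: the speculative NR position of NUP93A/B and
the unmodelled NUP133 beta-propeller bridge at the NR outer Y-complex
head-to-tail contact.

`stoichiometry()` counts chains by species or subcomplex instances — a
subcomplex instance is a distinct (ring, asymmetric unit, subcomplex, copy
index) — and scales counts to the whole pore by symmetry order when the
model holds fewer asymmetric units, so conservation (whole = per-unit x
order) holds by construction and is asserted in tests.

# Rigid-body refinement

The scoring function has four classes, matching integrative NPC modelling
practice: an EM fit (1 − normalized cross-correlation between the map and
a Gaussian rendering of the 10-residue coarse beads; the Calpha
representation is used for everything else), a soft-sphere clash score
between Calpha beads of different bodies (uniform 2.0 A radius, k = 1,
configurable; the source protocol names no values), connectivity upper
bounds of 3.8 A x (linker residues + 1) between sequence-neighbouring
domains, and an elastic network freezing all inter-body Calpha pairs
within 10 A of the reference interfaces (k = 0.1 per pair). The total is
exactly the weighted component sum; `em_weight` defaults to 50, chosen
once so the components are commensurate on the packaged toy problem.

The optimizer is Metropolis simulated annealing over rigid-body poses:
5 geometric temperatures (2 to 0.02) x 2000 steps, move sizes annealed
with sqrt(T/T0), and — importantly — 25% of proposals move *all* bodies as
one rigid unit. The collective moves exist because the elastic and
connectivity terms are invariant under rigid motion of the whole assembly:
only the (blurred) EM term sees those modes, and single-body steps must
pay elastic penalties to move along them, which stalled recovery at 5-6 A
RMSD. With collective moves the packaged two-body problem returns from
<= 15 A / <= 10 degree perturbations to ~1 A in 10/10 seeded restarts.
The refiner scores incrementally (cached per-body renderings and pairwise
clash blocks) but its final answer is re-scored by the public
`score_breakdown()`, so the fast and reference paths check each other.

The packaged toy problem itself is designed to have a unique optimum:
four helical chains of distinct lengths, tilts and axial offsets (no body
is internally pseudo-symmetric; the coarse-bead lattices share no
translation period), sequence connectivity across consecutive chains with
linker lengths satisfied (with margin) at the reference geometry, and an
interface elastic network derived at a 12 A cutoff for this geometry.

# Structure comparison

`kabsch_superpose()` is the SVD solution with reflection correction;
degenerate (collinear) inputs warn and return the SVD optimum, whose
in-plane component is then arbitrary. `tm_score()` evaluates
TM = (1/L) Σ 1/(1+(d_i/d0)^2) with d0 = 1.24 (L−15)^(1/3) − 1.8 (floored
at 0.5 A for L <= 21), maximized over superpositions seeded from contiguous
fragments with iterative re-superposition on close pairs — the score
refinement of TM-align at a *fixed* correspondence. The full
sequence-independent alignment search is a stated non-goal; for homologue
comparisons the default correspondence is 1:1 by residue order, with
L_target = length of the reference (second) structure. Flexible multidomain
chains (the NUP133 beta-propeller/alpha-solenoid case) are handled by
`split_domains()` and per-domain scoring, which a hinge-bent toy shows must
exceed the whole-chain score.

# Proteomics bookkeeping

`tryptic_digest()` cleaves after K/R except before P; observability is a
6-30 residue length window — a documented proxy for the instrument's m/z
range. emPAI is 10^(n_observed/n_observable) − 1. Presence calls replace
the probabilistic two-peptide validation of search engines with the
deterministic rule the workflow reduces to: a protein is detected in a
replicate iff at least two distinct peptides were observed there. The
packaged inventory fixture transcribes the published per-replicate emPAI
table (31 nucleoporins); replicate detection is derived from non-zero
emPAI values and cross-checked against the printed presence column. The
census restricted to the packaged 37-entry catalogue yields 31 detected
NUPs, and the Y-complex overlap after homologue mapping (HOS1 -> ELYS)
yields 9 shared members of 10, the human-specific NUP37 being the
difference.

# Numerical choices and limitations

* Determinism: every stochastic operation takes one integer seed and
  restores the caller's RNG state; the demo report is byte-identical across
  runs at fixed config. Reproducibility is guaranteed within this
  implementation, not across languages or BLAS builds.
* The published map resolutions (~35 A) and absolute pore diameters
  (70/92/102 nm across organisms) require the original tilt series or
  deposited maps and are out of reach from scratch; the package's tests
  substitute parameter-recovery and property checks at stated tolerances
  (diameter recovery within 2%, band-limit recovery within ±2 FSC shells,
  90% pose recovery at SNR 0.5, 8/10 refinement restarts under 5 A).
* Binning is integer Fourier cropping; a factor-4 binning of a 2.176 A
  pixel reproduces the conventional 8.704 A binned pixel.
* `align_subtomogram()` cost scales linearly with the rotation count;
  full ZYZ grids at fine steps are feasible only for small boxes. In-plane
  grids after symmetry expansion are the intended desk-scale path.
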