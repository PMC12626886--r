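# porekit

Desk-scale structural pipelines for nuclear pore complexes (NPCs), in R.

The NPC is the ~C8-symmetric channel spanning the nuclear envelope, built
from ~30 nucleoporins (NUPs) arranged in three stacked rings (cytoplasmic
ring CR, inner ring IR, nuclear ring NR). In situ structures of such
complexes are derived by a now-standard computational chain: subtomogram
averaging (STA) of particles picked from cryo-electron tomograms, Fourier
shell correlation (FSC) resolution estimation, pore-diameter measurement
from the aligned subunit coordinates, composite model assembly by C8
symmetry with per-ring stoichiometry accounting, integrative rigid-body
refinement of predicted subunit models against the density, TM-score
comparison of homologous NUP structures, and emPAI-based mass-spectrometry
inventories. `porekit` implements that chain end to end at desk scale, with
a synthetic-data module that generates every input it needs, so the whole
pipeline runs and is tested on one CPU with no downloads.

It is aimed at method developers and students who want transparent,
seed-deterministic reference implementations of these operations — not a
replacement for production STA packages.

## The statistics at the core

* **Constrained cross-correlation alignment.** For particle $p$ with
  missing wedge $W$ and rotation candidate $R$,
  $cc(R, s) = \langle \hat a, \hat p_s \rangle$ where $a = W[R\,\text{ref}]$,
  both volumes mean/variance-normalized under the alignment mask and the
  shift $s$ searched by FFT. The wedge is the unsampled Fourier region of
  single-axis tilting; correlation is computed only over sampled components.
* **Wedge-compensated averaging.**
  $\hat A = \sum_i \hat p_i^{aligned} / \max(1, \sum_i W_i^{rotated})$,
  with uncovered Fourier voxels set to zero.
* **FSC.** Per shell,
  $\mathrm{FSC}(k) = \Re\sum \hat F_1 \hat F_2^* / \sqrt{\sum|\hat F_1|^2 \sum|\hat F_2|^2}$;
  the resolution is $1/k$ at the first downward crossing of 0.143.
* **Pore geometry.** Each subunit defines a line along its inward normal;
  the centre is the least-squares intersection
  $\left[\sum_i (I - d_i d_i^\top)\right] c = \sum_i (I - d_i d_i^\top) p_i$,
  the radius the mean centre-to-subunit distance; pores with fewer than 5
  observed subunits are rejected.
* **Integrative refinement.** Simulated-annealing Monte Carlo over
  rigid-body poses scored by
  $E = w_{em}(1 - \mathrm{NCC}) + \sum k\,\max(0, 2r - d)^2 +
  \sum k\,\max(0, d - L_{max})^2 + \sum k\,(d - d_0)^2$
  (EM fit on 10-residue coarse beads; soft-sphere clash; connectivity;
  elastic network).
* **TM-score.** $\mathrm{TM} = \frac{1}{L}\sum_i 1/(1 + (d_i/d_0)^2)$ with
  $d_0 = 1.24(L-15)^{1/3} - 1.8$, maximized over fragment-seeded
  superpositions at fixed correspondence.
* **emPAI.** $10^{\,n_{observed}/n_{observable}} - 1$ over tryptic peptides
  (cleave after K/R except before P, 6–30 residue observability window),
  with presence calls requiring ≥ 2 distinct peptides per replicate.

## Worked example

```r
library(porekit)
report <- run_demo(demo_config(seed = 1), "demo_out")
```

The demo generates a C8 ground-truth complex between membrane slabs,
simulates 8 wedge-degraded subtomograms at SNR 0.5, aligns and averages
them, measures synthetic pore diameters, builds the composite AtNPC-style
scaffold and counts its stoichiometry, refines a perturbed toy assembly
against its own rendered map, compares a hinge-bent two-domain chain by
whole-chain and per-domain TM-score, and runs the proteomics census. With
seed 1 it prints (`demo_out/report.json`):

```
sta.frac_within_step        1        # all 8 poses within one 30-deg grid step
sta.map_truth_correlation   0.69     # 8-particle average vs ground truth
geometry.mean_diameter_A    699.98   # truth 700 A, 10 A positional noise
geometry.sd_diameter_A      7.47
scaffold.n_species          20       # distinct NUPs in the default model
scaffold.y_complexes_cr     8        # one Y-complex ring at the CR
scaffold.y_complexes_nr     16       # two concentric Y-complex rings at the NR
refine.start_rmsd_A         7.96     # perturbed toy assembly
refine.final_rmsd_A         4.56     # after the short demo schedule
compare.whole_chain_tm      0.54     # hinge-bent chain, whole-chain TM
compare.per_domain_tm       1, 1     # per-domain TM: rigid domains match
proteomics.census_n_detected 31      # catalogued NUPs detected >= 1 replicate
proteomics.y_complex_shared 9        # of 10 Y-complex members, via HOS1->ELYS
```

The numbers mean: pose recovery and averaging work at the stated noise
level (an 8-particle average correlates 0.69 with truth; more particles
raise it); diameters are recovered to 0.002% at this seed; the packaged
composition reproduces the published ring architecture (8 CR / 16 NR
Y-complexes from 20 NUP species); the short demo refinement halves the
perturbation (the full schedule in `refine_schedule()` reaches ~1 Å, see
the acceptance tests); a flexible two-domain chain scores poorly as a whole
but perfectly per domain; and the packaged inventory yields the published
census and Y-complex overlap.

Longer-running recoveries (50-particle STA at SNR 0.5, 10-restart
refinement recovery) live in `tests/testthat/test-acceptance.R`.

A thin CLI wrapper with `simulate / align / average / fsc / geometry /
composite / census / demo` subcommands is installed at
`system.file("cli", "porekit.R", package = "porekit")`.

## Layout

| path | contents |
| --- | --- |
| `R/synthetic.R` | ground-truth complexes, particle/subunit/peptide simulators |
| `R/sta.R`, `R/volume.R`, `R/wedge.R`, `R/mrc.R` | alignment, averaging, symmetry expansion, FSC, volume + MRC2014 I/O |
| `R/geometry.R` | pore centre/diameter estimation |
| `R/scaffold.R` | composition config, toy placement, composite assembly, stoichiometry |
| `R/refine.R` | restraints and simulated-annealing rigid-body refinement |
| `R/compare.R` | Kabsch superposition, TM-score, domain splitting |
| `R/proteomics.R` | digestion, emPAI, presence calls, census, Y-complex overlap |
| `R/pipeline.R` | demo orchestration, toy problems, config hashing |
| `inst/extdata/` | packaged composition JSON, NUP inventory + catalogue TSVs, Y-complex sets |
| `vignettes/porekit-methods.Rmd` | the methods vignette: models, assumptions, parameter choices, limitations |
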