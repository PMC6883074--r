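---
title: "Methods: valve-anchored hydration and geometry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: valve-anchored hydration and geometry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvewatch)
```

## The scientific problem

ABCG2 is a homodimeric multidrug exporter whose substrate path runs from a
large central cavity, through a narrow constriction formed by the di-leucine
motif (L554/L555 of both monomers), into a small upper cavity capped by an
extracellular "roof" (ECL1, ECL2, the re-entry helix and ECL3, stabilized by
disulfide bonds and the R426–E585 salt bridge). The functional hypothesis
this package serves is that the di-leucine motif acts as a hydrophobic
*valve* — a seal that admits essentially no water in the wild type and leaks
when mutated — and that the roof acts as a lid over the upper cavity.

`valvewatch` implements the trajectory analyses with which that hypothesis
is interrogated: water-flux counting through valve-anchored compartment
boxes, voxelized water density and mean-displacement maps, salt-bridge and
valve-geometry distance statistics, per-residue RMSF, and hydrophobic
solvent-accessible surface area (SASA) of the upper cavity. Because the
quantities of interest come from multi-hundred-nanosecond atomistic
membrane simulations that cannot be regenerated on a desktop, the package
pairs every analysis with a *synthetic-trajectory generator with logged
ground truth*, so that each stage is verified against exactly known answers.

## Units, frames and conventions

All lengths are nm and all times ps internally; nanoseconds appear only in
user-facing arguments suffixed `_ns`. Boxes are orthorhombic; triclinic
cells are rejected with an explicit error, since both the target systems
and all synthetic systems are orthorhombic. Residue numbers follow the
topology's author numbering (554 means ABCG2 residue 554; no renumbering),
and analyses that report "both transporter halves" iterate chains in
topology order. Trajectories are held in memory as dense arrays: at the
problem sizes the package targets (10^3–10^4 frames of 10^2–10^3 particles)
this is a few hundred MB at most and keeps frame access trivial.

PDB files are read through bio3d (Å converted to nm); GRO files (single- or
multi-frame, with `t=` time stamps) are parsed by the package; DCD is read
through bio3d and written by the package (DCD carries no reliable per-frame
times, so a frame spacing must be declared when loading). XTC/TRR are not
supported — no installed R-side reader exists — and are rejected with a
clear message rather than mis-parsed.

The default equilibration trim is 25 ns, matching the convention of
discarding the first 25 ns of 175-ns (mutant) and 525-ns (wild-type)
production runs, which leaves 150-ns and 500-ns analysis windows.

## The flux analysis

The analysis volume is anchored on the valve: the anchor is the centroid of
the Cα atoms of residues 554 and 555 of both chains (the only residue-wise
construction available; selectable), the *valve plane* is the axial
coordinate of that centroid, and two boxes are placed around it:

* a **density box** of 4 × 4 × 6 nm for the spatial maps, and
* a **flux box** of 2 × 2 × 4 nm split at the valve plane into an *upper*
  and a *central* 2 × 2 × 2 nm sub-box.

Waters (one site per molecule — the oxygen on real systems, the single
particle on synthetic ones) are labelled `upper`, `central` or `outside`
by axis-aligned, half-open box membership evaluated on the minimum-image
displacement from the anchor, so wrapped coordinates are handled and the
partition is exhaustive and exclusive. A **crossing event** is a water
labelled `upper` at one analyzed frame and `central` at the next (or vice
versa), with analyzed frames 10 ps apart by default; passages through
`outside` are ignored — a literal reading of "exchange between the
cavities in consecutive frames". Both directions are summed in the
reported total; directional tallies, per-event water identities and the
number of distinct waters are retained because "events" and "molecules"
can differ when one water shuttles repeatedly.

Two conventions were genuinely open and are therefore explicit options:

* **Re-anchoring.** The boxes are re-anchored on the valve selection at
  every analyzed frame by default (the protein drifts; re-anchoring keeps
  the box boundary coincident with the valve throughout); a fixed-anchor
  mode exists. Which the original analysis used is unknown.
* **Wrapping.** Classification via minimum-image displacement from the
  anchor is equivalent to wrapping the system with the valve centred; the
  original wrapping convention is unstated.

Replicate summaries report mean ± SEM with the n−1 denominator and refuse
a single replicate rather than emitting SEM = 0.

## Density and displacement maps

The density grid divides the density box into voxels (default edge 0.1 nm,
which resolves the ~0.3 nm water diameter at 40 × 40 × 60 voxels; the
examples here use coarser voxels for speed) and reports the time-averaged
water count per voxel divided by the voxel volume. By construction, the
voxel sum times the voxel volume equals the time-averaged number of waters
inside the box *exactly* — this "mass consistency" is asserted in the
tests rather than merely documented.

"Mean water displacement" is not a standard estimator, so the definition
is explicit and configurable: for lag `dt` (default the 10-ps analysis
stride), each water inside the box at time *t* contributes the
minimum-image magnitude |r(t+dt) − r(t)| to the voxel of its *starting*
position; voxel values are means over frames and waters. For free Brownian
motion with per-coordinate step σ over the lag, this mean is the chi(3)
expectation σ·2√2/√π, which the tests verify against a direct simulation.
Replicate grids are averaged voxel-wise; grids export to OpenDX for
volume viewers, and axial/lateral slices to CSV.

## Geometry

Distance time series between named atom pairs (e.g. `585:CD-426:CZ`,
`585:CA-500:CA`, `426:CA-417:CA`) are sampled at 1 ns by default, one
series per chain unless the pair specification pins chains. Boxplot
statistics follow the mean-as-centre convention — the centre line is the
arithmetic mean, not the median, and whiskers reach the extremes — with
quartiles by inclusive linear interpolation (type 7), verified against a
sort-based oracle. Distance probability distributions pool replicate
series into a normalized histogram while retaining per-series histograms
so the composition stays auditable.

Salt bridges are detected as a minimum distance below 0.4 nm (the
conventional criterion; configurable) between side-chain charged heavy
atoms (guanidinium/amine nitrogens of Arg/Lys/His, carboxylate oxygens of
Glu/Asp). Distance specifications that reference side-chain atoms absent
from a mutated residue fail loudly, naming the residue, rather than
silently falling back to Cα — silent substitution would corrupt
mutant-versus-wild-type comparisons.

The **valve axial shift** between two conformational states is the signed
difference of the valve-selection centroid along the membrane normal.
Structures are assumed pre-aligned; passing an alignment selection
(conventionally the transmembrane-core Cα atoms, since the shift must be
measured in a common frame and the core is the rigid part) superposes the
second structure onto the first by least-squares (Kabsch) before
measuring. The "distance between the backbones at the valve" is
implemented as the distance between per-chain centroids of the
N/CA/C/O atoms of residues 554–555 (configurable), one reasonable reading
of an underspecified quantity.

## Flexibility and SASA

RMSF is computed per atom as √⟨|r − ⟨r⟩|²⟩ after removing rigid-body
motion by least-squares superposition onto the trajectory mean structure
(two-pass: fit to the first frame, build the mean, refit to the mean),
reported on the target Cα atoms and averaged over replicates. The fit
selection defaults to the protein Cα set and should be the rigid core;
`fit_selection = NULL` skips the fit for trajectories that carry no
rigid-body motion, such as the tethered synthetic systems, where the
expected RMSF has the closed form √3·σ.

SASA uses the Shrake–Rupley sphere-point method with 960 deterministic
(golden-spiral) points per atom, probe radius 0.14 nm and Bondi-type van
der Waals radii; exactly coincident duplicate atoms contribute no extra
surface. The implementation is validated against the closed-form isolated
sphere 4π(r+probe)² and a Monte-Carlo surface-point oracle on random
multi-sphere toys. The upper-cavity hydrophobic SASA sums, per frame, the
areas of atoms in a user-supplied cavity residue list whose residue class
is hydrophobic, computed against the whole protein; the default residue
list (`UPPER_CAVITY_RESIDUES`) is an editorial reconstruction from the
residues the analyses name (valve stretch 553–559, F431, R426/E585,
K417/K500, C592/C603/C608) and is flagged as such — there is no automatic
cavity detection. Polarity classes put ALA/VAL/LEU/ILE/PHE/MET/TRP/PRO in
`hydrophobic`, ARG/LYS/HIS in `positive`, ASP/GLU in `negative` and the
rest — including GLY and CYS, a deliberate, overridable choice — in
`polar`. Series are smoothed by a centred running average (default 1 ns)
whose window shrinks at the series edges.

## The synthetic generators and what they do (not) show

* **Barrier system** — point waters under reflected Brownian motion in an
  orthorhombic box with a planar slab barrier. A proposed step across the
  barrier plane is an *attempt*; attempts succeed with probability *p*
  (pass through) and otherwise reflect off the slab face. With slab
  half-thickness 0 and *p* = 1 the dynamics reduce exactly to free
  diffusion. The emitted event log records precisely the sign changes of
  z − z_barrier between consecutive frames, so the flux counter can be
  checked event-for-event (identity, direction, frame). A static 8-atom
  scaffold named like the valve (L554/L555, CA/CB, chains A/B) anchors the
  standard selections. In the rare-crossing regime a seal emulates
  (*p* ≲ 0.05), per-window event counts are Poisson-like; at high *p*,
  immediate recrossings overdisperse the counts — a property of the
  physics, not a generator defect.
* **Calibration.** For the zero-thickness barrier the expected counted
  event rate per frame inside a footprint of area A is
  p·ρ·A·σ·√(2/π), which `calibrate_crossing_probability()` inverts. The
  wild-type-like condition of one transition per ~5 ns over a 150-ns
  window (≈30 events) is reproduced this way, with defaults of 200 waters
  in a 6 × 6 × 12 nm box and σ = 0.05 nm per 10-ps frame.
* **Tethered system** — particles drawn i.i.d. per frame from isotropic
  Gaussians about fixed, well-separated anchors, with known per-particle σ
  (RMSF ground truth √3·σ), plus a rigid scaffold for fit-based tests.
* **Distance-pair system** — two atoms placed at a separation drawn from a
  1–2-component Gaussian mixture (truncated positive) along a random
  direction; emulates unimodal inward-like (mean ~1.05 nm) and bimodal
  outward-like (1.1/1.5 nm) valve distance distributions.
* **Shifted pair** — a rigid translation with known vector, optionally of
  a sub-selection only, for the axial-shift recovery checks.

These generators reproduce the *statistical structure* the analyses assume
— compartment exchange as rare point events, Gaussian positional
fluctuation, prescribed separation laws — and none of the physics of real
hydration: no electrostatics, no hydrogen-bond network, no lipid
environment, no absolute water counts. Green tests therefore certify that
the measurement machinery is correct, not that any particular biological
number is reproduced; full-scale MD input is consumed through exactly the
same code path, unchanged.

## Numerical choices and degenerate inputs

Half-open voxel and box bins make partitions exact; a water exactly on the
valve plane counts as `upper`. Grid construction requires the voxel edge
to divide the box dimensions and refuses otherwise. Quartiles use type-7
interpolation; ties in selections resolve in topology order; the Kabsch
fit handles reflection degeneracy via the determinant sign. Empty
selections are an error by default (a warning when `empty_ok = TRUE`);
single-atom anchors warn; single-replicate SEM is refused; a running
average shorter than the sampling interval is an error. Generator seeds
make every synthetic system and the full pipeline bit-reproducible.

## Problem sizes

The shipped drivers and tests run synthetic systems of 40–1000 particles
and 10²–1.5·10⁴ frames — chosen as the smallest sizes at which the
statistical assertions (3σ Poisson bands, 5% RMSF recovery, 3% SASA
agreement) are sharp. The analyses themselves are O(waters × frames) and
accept user-supplied trajectories of arbitrary length.

## Known limitations

No permeability coefficients, ion counting, kernel-smoothed densities,
free-energy conversion of densities, hydrogen-bond angle criteria, cavity
volume or automatic pocket detection: these are outside the analysis
repertoire this package reimplements. The cryo-EM-structure check
(`valve_calpha_distances()` on the inward-facing experimental structure,
accession 6ETI) requires the user to supply the PDB file; the packaged
stand-in (`inst/extdata/valve_inward_synthetic.pdb`) is a labelled
synthetic caricature for exercising the code, never a substitute for the
experimental coordinates.
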