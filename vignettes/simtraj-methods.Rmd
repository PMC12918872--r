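---
title: "Methods and design notes for simtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for simtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions, numerical choices and
limitations behind each analysis family, in the spirit of the long-form
methods sections that mature analysis packages ship with their code.  It
states no empirical result that the test suite does not itself compute.

## Trajectory model and conventions

A trajectory is a sequence of frames, each an N×3 coordinate matrix in
Ångström plus an orthorhombic box `(Lx, Ly, Lz)`.  Frames are indexed
0-based and globally across file boundaries; the analysis window
`[frame_start, frame_stop)` is half-open with `frame_stride ≥ 1`,
matching slice semantics so windows compose without off-by-one drift.
Triclinic cells are rejected with an explicit unsupported-feature error
rather than silently mis-wrapping: every periodic operation here
(minimum image, Voronoi replication, RDF normalization) assumes a
rectangular cell.  Units are Å, degrees, ps, K and amu throughout;
`K_A` is reported in mN/m and diffusion constants in both Å²/ps and
cm²/s (1 Å²/ps = 10⁻⁴ cm²/s).

Trajectory files are CHARMM/X-PLOR-style DCD (single-precision
coordinates, unit-cell record written as lengths and 90° angles, read
tolerantly as either angles or cosines) or multi-model PDB.  The DCD
reader/writer was validated against an independent, widely used Python
trajectory reader on a small fixture during development; at run time the
package depends on nothing outside base R and jsonlite.

The selection language is deliberately minimal — `name`, `resname`,
`resid N[:M]`, `segid`, `element`, `protein`, `water`, with
`and`/`or`/`not` and parentheses — so that its behavior is fully
specified and portable.  `protein` means the 20 standard amino-acid
residue names; `water` means TIP3/HOH/WAT/SPC/TIP4.  An empty selection
result is not an error; each analysis decides whether emptiness is
fatal.

## Periodic Voronoi tessellation

Area per lipid and shell composition rest on a periodic 2-D Voronoi
tessellation.  Sites (one per lipid, from a user selection such as the
phosphate) are wrapped into the box and replicated into the 8
surrounding periodic images; each central cell is the intersection of
bisector half-planes against all other imaged sites, clipped
nearest-first with the standard pruning bound (a site farther than twice
the current maximal vertex distance cannot cut the cell).  This is exact
for any configuration, conserves total area by construction (asserted to
1e-6 relative in the tests), and avoids the clipped-infinite-cell
bookkeeping of unreplicated approaches.  Duplicate sites are jittered by
1e-6 Å with a warning.  Two sites are neighbors only if they share an
edge of positive length (two distinct equidistant vertices, separated by
more than 1e-5 Å); degenerate corner contacts — e.g. the diagonal
meeting points of a perfect square lattice — do not count, which is why
a checkerboard lattice reports exactly 4 first-shell neighbors.  A
single site owns the whole box and has no neighbors.

One representative site per lipid is used (not one per acyl chain);
with multi-site schemes the per-lipid areas would no longer sum to the
box area per leaflet, which is the invariant the tests lean on.

## Membrane observables

*Leaflets.*  The midplane is the mean head-group z of the selection,
recomputed per frame (not the box center, which drifts under barostats);
a lipid is "upper" iff its head z is at or above the midplane, ties
upper.  This is a flat-bilayer assumption — curved or vesicular
membranes are out of scope.

*S_CD.*  The order parameter uses the global +z axis as the membrane
normal and reports the magnitude |S_CD|, matching the convention of
plotted profiles.  The two analytic limits — all C–H along z gives 1,
all C–H in the xy plane gives 0.5 — are exercised exactly by the
bilayer fixture, and isotropic orientations give |S| < 0.01 at 10⁵
samples.  Explicit hydrogens are required; there is no united-atom H
reconstruction.

*K_A.*  Computed from total lateral box-area fluctuations,
`K_A = kB·T·⟨A⟩/var(A)` with the population variance, converted from
J/Å² to mN/m (×10²³).  Box-area (rather than per-leaflet Voronoi)
fluctuations were chosen because the fluctuating quantity under an
NPT barostat is the box itself; a 5-block standard error accompanies the
estimate when the series is long enough.  A constant area series is a
hard error, not a zero.

*Diffusion.*  Per-lipid COM positions are unwrapped by accumulating
minimum-image increments — valid only while per-frame displacements stay
below half the box, which the random-walk fixtures respect by
construction.  MSD uses all time origins.  For the 2-D membrane case the
diffusion coefficient is fitted on the early lags (default window
[0, 25%] of the maximum lag): long lags average very few independent
origins and dominate the variance of an unweighted fit; across six
generator seeds the early-lag estimator stayed within 6% of the known
σ²/(2Δt) while mid-window fits strayed past 20%.  The 3-D solution
estimator keeps the conventional middle window ([20%, 80%]) with
`D = slope/6`, which is stable at its stated scale (500 particles, 1000
frames).  No COM-drift removal is applied by default; a flag subtracts
the selection's mean lateral motion.

*Density profiles.*  z-histograms are recentered per frame on an
optional midplane selection, weighted by count, mass, or electrons
(atomic number minus partial charge; falls back to number mode with a
warning when charges are absent), and divided by the bin volume.  The
sum of density × bin volume reproduces the selected atom count exactly.

## Protein observables

*Superposition.*  Kabsch via SVD of the weighted cross-covariance with
determinant sign correction, so reflections are never returned; weights
default to atomic masses.  Collinear or degenerate point sets warn and
return one minimizer.  RMSF uses a two-pass scheme — align to the first
frame, form the mean, re-align to the mean — rather than iterating to
convergence; the residual effect is below the fluctuation scales of
interest, and a purely rigid trajectory yields RMSF < 1e-6 Å.  An
`align = FALSE` path exists for pre-aligned input; note that with
alignment on, a single moving atom among N anchored ones necessarily
shows slightly less than its raw amplitude, since superposition absorbs
~1/N of any isolated motion.

*DSSP.*  Hydrogen bonds use the Kabsch–Sander electrostatic energy with
the 0.084·332 kcal/mol prefactor and the −0.5 kcal/mol threshold;
amide hydrogens are reconstructed anti to the preceding carbonyl
(`H = N + 1.01 Å · unit(C_prev − O_prev)`), the first residue donating
nothing.  n-turns (n = 3, 4, 5) require two consecutive turns to seed a
helix; bridges require |i−j| ≥ 3 and follow the standard
parallel/antiparallel patterns, with ladders (consecutive bridges)
coded E and isolated bridges B; remaining turn interiors are T and
backbone bends over 70° are S.  Overlaps resolve by the fixed priority
H > G > I > E > B > T > S > '-'.  Residues with missing backbone atoms
are coded '-' with a warning.  The ideal-helix fixture (φ = −57°,
ψ = −47°) yields H for all interior residues and the constructed
antiparallel sheet yields E; both assignments are invariant under rigid
motion, which the acceptance suite checks over 20 random motions.

*Pore radius.*  A deliberately simple per-bin estimator: within each z
bin, the minimum over atoms of (lateral distance to the axis − vdW
radius), clamped at zero, with the axis defaulting to the selection's
lateral centroid per frame.  This is a variant, not a Monte-Carlo
sphere-fitting method; it is exact for the ring fixtures and cheap, but
it underestimates radii of strongly off-axis or tortuous pores.  vdW
radii are a fixed in-code table (H 1.2, C 1.7, N 1.55, O 1.52, S/P 1.8
Å); unknown elements get 1.7 Å with a warning.

## Contacts and non-bonded detectors

Residue contacts use minimum heavy-atom distance with a 4.5 Å default
cutoff; residence times are maximal runs of contact frames, with runs
touching either trajectory end counted as observed — no censoring
correction, so mean durations are biased low when contacts persist
beyond the sampled window.  A `--gap-tolerance k` option merges runs
separated by ≤ k absent frames.  SDs over runs are population SDs;
single-event pairs report 0.

The RDF normalizes pair counts by `N_A · ρ_B · 4πr²Δr` with
minimum-image distances and self-pair exclusion; `r_max` beyond half the
smallest box edge is an error because minimum-image distances are no
longer unique there.  The counting identity
`ρ_B ∫ g(r) 4πr² dr = ⟨neighbors within r_max⟩` is asserted to 1% in the
tests.

Detector cutoffs are geometric conventions, not fitted values: hydrogen
bonds at donor–acceptor ≤ 3.5 Å and D–H···A ≥ 150°, with donors
identified as N/O/S/F atoms carrying a covalent hydrogen (≤ 1.2 Å, same
residue — name-independent, since PDB input has no bond records); salt
bridges at ≤ 4.0 Å between basic nitrogens (Arg NH1/NH2/NE, Lys NZ, His
ND1/NE2, N-terminal amine) and acidic oxygens (Asp OD1/OD2, Glu OE1/OE2,
C-terminal O/OXT); π-stacking at centroid distance ≤ 6.0 Å with classes
parallel (α ≤ 30°), t-shaped (α ≥ 60°) and oblique between, the ring
normal being the smallest-singular-vector of the centered ring atoms.
Trp contributes its five- and six-membered rings separately, labeled;
His counts as both potential cation and aromatic, since the analyses are
independent outputs.  All cutoffs are flag-adjustable, and the fixtures
place motifs far from the thresholds so the gate tests are insensitive
to small convention differences.  Water bridges require one single water
hydrogen-bonded (either direction) to both sides in the same frame;
two-water chains deliberately do not count.

## Reproducibility

Every CLI invocation appends one shell-quoted line to `commands.log`
before the analysis runs; the log is append-only.  Outputs are TSV with
a single `#`-prefixed header, written in binary mode with fixed
formatting, so replaying a logged command reproduces deterministic
outputs byte-for-byte — this is asserted, not assumed.  Fixture
generation takes one RNG stream seeded from its `seed` argument (the
global RNG state is saved and restored), so the same spec and seed yield
byte-identical PDB/DCD/metadata files.

## What the synthetic fixtures do and do not establish

The generators produce the stated worlds exactly: lattice bilayers with
heads at ±19 Å (thickness 38 Å, APL = box area / N), prescribed C–H
orientations (S_CD limits), Gaussian random walks (D = σ²/(2Δt) per
axis), uniform ideal gases (g(r) = 1, density N/V), ideal secondary
structures, and interaction motifs built at stated distances and angles.
Noise magnitudes, where used, are chosen at realistic scales for
atomistic membrane simulations: ±0.3–1 Å positional jitter, ~1% lateral
box fluctuation, 0.3–0.5 Å per-frame diffusion steps.

A green test therefore establishes that the estimators recover known
ground truth under the model's own assumptions — flat bilayers, ideal
geometry, uncorrelated noise.  It does not establish behavior on real
force-field output: curved membranes, correlated undulations,
united-atom topologies, protonation variants, or disordered loops are
outside what these fixtures emulate, and the pore estimator and
residence-time censoring caveats above apply to real data with full
force.

## Known limitations

- Orthorhombic boxes only; no velocities; no trajectory writing beyond
  the fixture generators.
- DSSP omits β-bulge special cases and any PPII extension.
- No finite-size (hydrodynamic) corrections to diffusion constants.
- Electron-density profiles approximate electrons as atomic number
  minus partial charge.
- The whole-trajectory frame list is materialized in memory; at the
  desk scales this package targets (≤ 10⁶ atom-frames in tests) this is
  deliberate simplicity, not an oversight.
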