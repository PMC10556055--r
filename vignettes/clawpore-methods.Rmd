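---
title: "Models and methods behind clawpore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clawpore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clawpore` analyses claudin-built paracellular channels at desk scale:
rigid one-bead-per-residue models, rotational cis-association energy
landscapes, symmetric trans tetramer assembly, sphere-probe pore
profiling, pore-lining charge tallies, and Goldman–Hodgkin–Katz (GHK)
barrier arithmetic. This vignette records the models, the parameters that
matter, the numerical choices, and what the synthetic test systems do and
do not establish.

## The coarse-grained structural model

Every structure is reduced to one bead per residue, placed at the centroid
of the side-chain heavy atoms (the Cα for glycine). Two considerations fix
this resolution. First, pore-lining identification is defined on side-chain
proximity to the channel, so the bead must represent the side chain, not
the backbone. Second, a residue-level model keeps a complete 360° × 360°
rotational landscape (129,600 contact placements plus energy evaluations)
tractable on one CPU while preserving the residue-level charge geometry
that the analysis interprets.

Formal charges follow the pH 7.4 scheme: LYS and ARG +1, ASP and GLU −1,
everything else 0. The polar class is exactly {ASN, GLN, SER, THR, TYR}.
Histidine (pKa ≈ 6) is treated as neutral and apolar; a different
protonation can be emulated by editing the residue names of a bead table.
Bead radii default to a single generic 2.64 Å — half of a MARTINI-like
5.28 Å bead diameter — and can be overridden per residue type
(`load_structure(radii = ...)`); no per-residue radius set is assumed
because the energetics are interpreted comparatively, not absolutely.
Cytosolic C-terminal tails are truncated before analysis
(`truncate_cterm()`); any bead still flagged `cterm` is excluded from all
energetics rather than silently included.

Coordinates are Å in a right-handed frame with the membrane normal along
+z; residue indices are 1-based as in PDB. `align_to_membrane_frame()`
maps the largest-variance axis of the transmembrane beads onto +z (sign
chosen so annotated extracellular segments point up) and rejects
degenerate, collinear bead clouds.

## Non-bonded energy and contact placement

The interaction energy between two rigid bead models is

$$E = \sum_{ij} 4\varepsilon\left[\left(\tfrac{\sigma}{r_{ij}}\right)^{12}
 - \left(\tfrac{\sigma}{r_{ij}}\right)^{6}\right]
 + \sum_{ij} \frac{f\,q_i q_j}{\varepsilon_r\, r_{ij}},
 \qquad f = 138.935458\ \mathrm{kJ\,mol^{-1}\,nm\,e^{-2}},$$

summed over inter-model pairs within the cutoff (the Coulomb term takes r
in nm). Defaults are MARTINI-like magnitudes: σ = 4.7 Å, ε = 2.0 kJ/mol,
ε_r = 15, cutoff 12 Å — all exposed through `energy_params()`, since only
the landscape's shape, not its absolute scale, carries meaning here.
Distances below 0.1 Å are refused as a singularity guard. Negative totals
indicate stable association.

A rotational pose (θ₁, θ₂) is realised by rotating each monomer about its
own vertical axis and sliding the second monomer along +x until the
minimal inter-model *surface* separation (centre distance minus both
radii) equals the contact gap, 0.5 Å by default. The slide distance is
found by monotone bisection to an interval below 0.005 Å (the separation
is 1-Lipschitz in the offset, so this brackets the gap to well within the
0.01 Å contract); a fixed geometric contact rule is used because it makes
the landscape a pure, reproducible function of the two structures. The
grid, placement and energy loop are implemented in C++ (Rcpp); a 1° grid
on two 66-bead toy monomers completes in under a minute.

`stable_states()` ranks cells by energy (ties broken lexicographically by
angles) and keeps the lowest ⌊p/100 · N⌋ — rank-based so the decile of a
1° grid holds exactly 12,960 states. The pore-forming window is the
half-open interval [center − h, center + h) per axis, 20 values at 1°
with the defaults (270°, h = 10°), hence exactly 400 cells; a closed
21-value window is available via `closed = TRUE`. The half-open convention
was chosen because a closed ±10° window at 1° necessarily has 441 cells,
which does not match the 400-cell window this analysis standardises on.

## Trans tetramer assembly and refinement

`build_tetramer()` reflects the second cis dimer 180° about an in-membrane
axis so the extracellular segments of the two dimers face each other,
centres it laterally, and lowers it until the minimal inter-dimer surface
separation equals the gap (default 2 Å; the inter-membrane spacing of a
paracellular junction is not a fixed number, so it is a config knob).
Both dimers move only rigidly — internal pairwise distances are preserved
to machine precision — because the cis geometries being compared are the
object of study and must not relax away.

`refine_tetramer()` minimises the trans interface energy over four rigid
degrees of freedom of the second dimer (vertical gap, x/y shift, twist
about z) with Nelder–Mead from the symmetric start, overlap and
out-of-bounds poses rejected by penalty. Nelder–Mead is restarted from the
running best with a fresh simplex until it stops improving (at most 10
rounds): a single pass can stall on a shrunken simplex, and the restart
loop is a cheap deterministic escape. The refinement is exactly as
deterministic as its start pose; no stochastic search is used. When the
optimum lies strictly inside the search box the refined pose is a fixed
point of re-refinement; an optimum pinned to the box boundary can descend
further if refined again with a re-centred box, which is the expected
behaviour of a local search, not an error. Interface energy is computed by
grouping the two cis dimers as separate energy groups and summing only
cross-group pairs; Lennard-Jones and Coulomb components are reported
separately so electrostatic complementarity (or repulsion) at the trans
interface is visible on its own.

## Pore profiling

The profiler is a slice-chained maximal-ball search in the spirit of
tunnel-profiling software. At each z slice it maximises the clearance
c(p) = minᵢ(|p − bᵢ| − radiusᵢ) over in-plane points p, seeded from the
previous slice's centre (the first slice from the structure axis) with one
restart on the local slice centroid; the probe radius is max(c, 0) and the
pore diameter twice that. Defaults: z-step 0.5 Å; minimum probe radius
0.9 Å (a common minimum-probe choice in tunnel software — the paper trail
for any given channel can re-apply a different threshold because raw radii
are always reported).

Two safeguards matter in practice:

* **Probe escape.** Outside the structure's footprint the clearance grows
  without bound, so an unconstrained maximiser can run away into open
  space. The search is therefore clamped to the structure's in-plane
  bounding box. Genuine channel centres are interior points and are
  unaffected.
* **Path connectivity.** If successive slice centres jump more than
  2 × z-step laterally, there is no continuous tunnel through the
  structure; the profile is declared broken. Broken or blocked channels
  report `min_diameter` 0 Å and `pore_exists = FALSE` — they are never
  silently omitted, and the residue report refuses to run on them rather
  than returning an empty table.

In-plane maximisation uses Nelder–Mead (tolerance 1e−12, one restart);
ties in `min_diameter_report()` resolve to the smallest z.

## Electrophysiology arithmetic

Only the monovalent ions Na⁺, Cl⁻ and Li⁺ enter the GHK expressions;
divalents and buffer species of a physiological Ringer are excluded, and
activity coefficients are taken as 1. The 1:4 saline:mannitol basolateral
replacement is modelled as 28 mM NaCl. Temperature defaults to 310.15 K.
Potentials are basal minus apical (flippable by flag, since instrument
conventions differ).

* `correct_teer()`: TEER = (R − R_blank) · A, in Ω·cm².
* `dilution_ratio()`: solves V = (RT/F) ln[(β[Na]_b + [Cl]_a)/(β[Na]_a +
  [Cl]_b)] for β = P_Na/P_Cl in closed form. The potential must lie
  strictly between the two single-ion Nernst limits; at the cation-only
  limit the ratio is unbounded and is returned as `Inf` with a warning.
* `biionic_ratio()`: solves the three-ion relation V = (RT/F)
  ln[(P_Li[Li]_b + P_Cl[Cl]_a)/(P_Na[Na]_a + P_Cl[Cl]_b)] for P_Li/P_Na
  given β, requiring symmetric Cl⁻.
* `absolute_permeabilities()`: the conductance route is pinned to the
  Kimizuka–Koketsu form P_Na = (RT/F²) G β/((1+β)c) with c in mol/cm³,
  giving cm/s; P_Na/(P_Na+P_Cl) = β/(1+β) holds exactly by construction.
* `apparent_permeability()`: least-squares slope of receiver amount vs
  time divided by (area × donor concentration), under the sink assumption;
  receiver concentrations above 10% of donor trigger a warning, and
  negative slopes are flagged but returned.

## Synthetic test systems: what they do and do not show

The generators exist so that every stage has a ground truth:

* `make_toy_monomer()` builds the claudin topology — four TM bead columns
  spanning a membrane slab, a long ECS1 arc and a shorter ECS2 arc above
  it — with charges planted at chosen arc positions (beads named LYS/ASP
  so classification stays consistent) and a small seeded jitter
  (SD 0.15 Å) to make landscapes non-degenerate. It emulates fold
  topology and charge placement, not claudin sequences, side-chain
  packing, or β-sheet trans interfaces.
* `make_ring_stack()` places beads on circles centred on the z-axis. On
  the axis the clearance at height z is exactly
  min_k √(r_k² + (z − z_k)²) − r_bead, and the axis is the in-plane
  maximiser, so the profiler has a closed-form oracle. This reduces to
  r_ring − r_bead whenever a slice's own ring governs; the exact
  min-over-rings form is recorded because closely stacked narrow rings
  also constrict their neighbours' planes. Walls whose inter-bead gap
  exceeds the bead diameter are flagged leaky instead of being given a
  fake truth.
* `make_ephys_record()` and `make_flux_series()` forward-simulate the GHK
  potentials (dilution and Li⁺-replacement protocols at 37 °C) and linear
  sink-condition flux, with Gaussian noise and the generating truth
  attached. Defaults mirror standard practice: 140 mM NaCl Ringer, 1:4
  mannitol dilution, 140 mM LiCl replacement, 30-min sampling over 3 h,
  1.12 cm² inserts.

All generators are seed-deterministic and leave the session RNG
untouched. Passing the oracle suites establishes that the geometry,
energetics and inversion arithmetic are implemented correctly — it does
not establish that real claudin complexes behave like the toys. In
particular, claudin-specific quantities (interface energies of specific
pairs, pore diameters, net pore charges of real channels) depend on
homology models and extensive conformational sampling that are outside
this package's scope; with user-supplied structures the pipeline computes
them, but no claim is inherited from the toy systems.

## Problem sizes and determinism

The shipped test suite and acceptance script use: a full 1° × 1° landscape
(129,600 cells) on two 66-bead toy monomers; coarse 5–45° grids
elsewhere; 100 randomized ring stacks (24 beads/ring) for the profiler
against analytic truth, with brute-force 0.02 Å grid cross-checks on
random slices; 500 noisy GHK records and 200 noisy flux series for the
recovery statistics; and a 4-bead tetramer toy for the exhaustive
0.1 Å/1° refinement oracle. These sizes keep a complete run in the
minutes range on a single CPU while exercising every code path at full
resolution where the combinatorial counts (12,960 decile states, 400
window cells) are the point. Analysis stages are deterministic; the only
randomness anywhere is in the generators, always behind an explicit seed
(pipeline default 1729).

## Known limitations

* Rigid bodies only: no side-chain flexibility, no conformational
  relaxation, no fluctuation-averaged energies.
* No solvent, membrane, entropy or pKa shifts; energies are comparative
  scores, not binding free energies.
* Rotation-only cis sampling (no tilt or z-offset), matching the
  landscape's two-angle parameterisation.
* The pore profiler assumes a single roughly vertical tunnel; branched
  networks and strongly tilted channels are out of scope.
* GHK inversion models three monovalent ions with unit activity
  coefficients; junction potentials and divalent contributions are
  ignored.
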