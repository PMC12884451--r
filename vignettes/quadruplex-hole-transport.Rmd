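---
title: "Models and methods: hole transport through an interfacial tryptophan quadruplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: hole transport through an interfacial tryptophan quadruplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadhop)
```

## The system and the problem

Azurin constructs carrying a Re(I) photosensitizer and engineered
tryptophans dimerize through a protein–protein interface in which four
tryptophan indole side chains form a *quadruplex*: two indoles per chain
(residues 122 and 124 on chains A and D of PDB entry 6MJS), mutually
T-oriented and in van der Waals contact. Photo-oxidation injects an
electron hole that migrates through this quadruplex on a nanosecond time
scale before oxidizing a Cu(I) center. `quadhop` implements the
*post-simulation analysis* of that process: it consumes structures,
coordinate trajectories with explicit waters, per-fragment charge/spin
time series, and tables of step free energies ΔG and electronic couplings
H~ab~, and turns them into the observables that characterize
hole transport. It performs no molecular dynamics and no electronic-
structure computation.

All inter-site distances follow a single convention: the minimum over all
cross pairs of the nine C/N heavy atoms of the indole ring (CG, CD1, CD2,
NE1, CE2, CE3, CZ2, CZ3, CH2), disregarding hydrogens, CB and backbone.
The six quadruplex pairs split into intramolecular *sides* (124A–122A,
122D–124D), interfacial *edges* (124A–122D, 122A–124D) and two
*diagonals*; in the crystal interface the short diagonal (122D–122A) is
3.7 Å and the long one (124A–124D) 5.4 Å.

## Conformer classification

Two threshold classifiers operate on shortest distances:

* `classify_re_conformer()`: the Re chromophore's dmp ligand sits either
  near the proximal tryptophan ("in", distance distribution peaking at
  3–4 Å) or away from it ("out", 5–6 Å). The decision boundary defaults
  to the midpoint, 4.5 Å, with `in` strictly below; the value is a
  package choice (the underlying distributions are well separated) and is
  configurable.
* `classify_quad_shape()`: a side counts as "short" below 4.0 Å — the
  same criterion used to select nearly-rhombic subpopulations for the
  hydration analysis. Both sides short is *rhombic*; one short side gives
  a *trapezoid* named by the (124A–122A, 122D–124D) ordering; both-long
  frames keep the ordering label and carry a `both_long` flag rather than
  a fourth class.

Frame selection (`select_frames()`) evaluates conjunctions of distance
predicates and reports per-predicate pass counts, so subpopulation
filters (e.g. both sides < 4 Å and both SAL–122 separations > 3.5 Å) are
reproducible and auditable.

## Hydration observables

Waters are represented by their oxygen positions. The central convention
is the *exclusive* assignment: each water belongs to the single closest
indole (ties to the earlier site in the fixed order 124A, 122A, 122D,
124D), either by whole-indole distance or by distance to the NE1 nitrogen
("NH-only"). Published coordination figures exist in both variants and do
not state which assignment the counting used, so both modes are computed;
the synthetic generator pins its planted guarantees to the NH metric.

Density maps (`density_map()`) are 0.1 Å-lattice voxel counts of water
oxygens, normalized to molecules/Å³, after least-squares (Kabsch)
superposition of each frame's quadruplex heavy atoms onto the first
frame. Grids are built in a canonical pose (principal axes of the
reference quadruplex, signs fixed by the 124A NE1 position), which makes
the lattice — and therefore every grid-derived number — independent of
the global orientation of the input trajectory. A boolean mask marks
voxels within 4 Å of any NE1; difference maps (`difference_map()`) report
connected voxel regions (26-neighbor connectivity) beyond ±2.5 ρ₀, with
ρ₀ = 0.0334 molecules/Å³ (bulk water at 298 K; the source analysis uses
ρ₀ without quoting a number, so the standard value is the default and is
configurable).

`measure_shift()` quantifies the sub-Ångström water displacement that
accompanies forced hole transfer: the displacement of the nearest-water
density centroid projected on the unit vector toward the site's NE1
(positive = toward the site). In grid mode the "nearest water" peak is
the substantial-density voxel closest to the NH, not the globally
strongest peak — the site's own first-shell water would otherwise mask
the moving bridge water.

## Hole localization

Charge/spin series carry six fragments (four indoles, dmpA, Re(CO)₃);
per-frame conservation of total charge and spin within 10⁻³ is asserted
on construction. The localization criterion follows the "≥ 90%" usage:
the dominant indole's mean charge must reach 0.9 of the total mean indole
hole charge (configurable; the source states the percentage without a
formula). Partial delocalization episodes are maximal runs in which a
non-dominant indole holds at least 0.2 e for at least 5 fs; both numbers
are package conventions, flagged as such, because "partial
delocalization" is reported qualitatively only. Complete transfers
require the new dominant site to persist for 50 fs, so a transfer
followed by back-transfer ~30 fs later counts at persistence 10 fs but
not at 50 fs. Durations are computed from time stamps, so non-uniform
cadence is handled.

## Energetics

Electrostatic potentials at indoles are vacuum Coulomb sums over
point-charge environments (K = 14.3996 V·Å/e), with no cutoff and no
periodic correction — appropriate for finite snapshot environments, a
documented limitation for periodic inputs. The site potential is the
unweighted mean over the nine ring atoms (the evaluation point used by
the source is not stated; NE1-only evaluation is available as a flag).
Per-component potentials (protein, ReA⁻, ReD, solvent, counterions, …)
are computed by restricting the sum and add up to the total exactly.
Environment particles closer than 0.5 Å to a site atom signal mis-tagged
input and are rejected.

Reaction free energies use the two-ensemble linear-response estimator on
vertical energy gaps ΔE = E(product) − E(reactant):

ΔG = (⟨ΔE⟩~A~ + ⟨ΔE⟩~B~)/2,  λ = (⟨ΔE⟩~A~ − ⟨ΔE⟩~B~)/2.

The exact estimator behind the published table is cited to a reference
whose formula is not reproduced in the text; the two-ensemble average is
the standard Marcus-picture choice consistent with the way λ is used, and
the choice is recorded in every result object. Uncertainty comes from a
block bootstrap (serial correlation safe). `dg_table()` audits a step
table for antisymmetry and cycle closure; the shipped reference table is
exactly antisymmetric but its 3-cycles close only to within −230 … +91
meV, which matters below.

## The hopping network

Nonadiabatic Marcus rates,
k = (2π/ħ) H~ab~² (4πλk~B~T)^−1/2^ exp(−(ΔG+λ)²/4λk~B~T),
use λ = 800 meV and T = 298 K by default (k~B~T = 25.68 meV). The
feasibility screen applies strict thresholds ΔG < +70 meV and
H~ab~ > 0.2 meV; the discussion-text variant ΔG ≤ +100 meV ships as an
alternative preset, and neither is privileged as "the" published value.
On the reference tables, seven of twelve directed edges survive and every
feasible path terminates at 122D⁺ (the only terminal strongly connected
component), with 124A→122D feasible and 124A→124D excluded on both
counts.

Couplings are direction-dependent medians; detailed balance is exact only
in symmetric-coupling mode, which uses the geometric mean of the two
directional medians (so that the H² products preserve pairwise balance).
Asymmetric mode uses the directional values and reports its balance
residual.

`master_equation()` propagates dp/dt = Kp by eigen-decomposition (series
fallback for defective K) and obtains the stationary state from a
bordered linear solve (one balance row replaced by normalization), which
resolves populations down to ~10⁻⁹; for reducible networks the long-time
limit from the supplied initial distribution is used instead, with a
residual check of 10⁻¹⁰ (relative).

**A caveat the package reports rather than hides:** the printed ΔG matrix
is an ensemble estimate and does not derive from a potential — its
3-cycles do not close. The stationary state of the corresponding rate
network therefore carries a circulating flux and is *not* Boltzmann: with
the reference tables it is maximal at 122D⁺, as expected, but its minimum
falls on 124A⁺ (≈4×10⁻⁶) rather than on the thermodynamically least
stable 124D⁺ (≈3×10⁻⁵, far above its ≈5×10⁻⁹ Boltzmann weight).
The thermodynamic ranking itself is recovered by
`node_free_energies()`, the least-squares potential fit to the step
table, which orders 122D < 124A < 122A < 124D. Both numbers are honest
answers to different questions, and the test suite asserts each against
its own computation.

The adiabaticity diagnostic κ = 2π H~ab~²/(ħ ν~eff~ (4πλk~B~T)^1/2^)
compares the electronic transition rate at zero activation with the
nuclear attempt frequency; with H~ab~ = 31 meV, λ = 800 meV and
ν~eff~⁻¹ = 100 fs it gives κ ≈ 1.8, i.e. (at least partly) adiabatic
transfer, matching the qualitative published assessment. The specific
Landau–Zener-type form is a documented package convention.

## Tryptophan-cluster mining

`find_clusters()` links tryptophans whose minimal indole C/N distance is
within 10 Å (inclusive, "within"), takes connected components of size ≥ 2
(singletons go to a diagnostics attribute), and classifies clusters as
intramolecular (one chain) or interfacial, with a dimer flag for exactly
two chains. The tight-quadruplex test asks for all six pairwise minima
strictly below 5 Å ("below"); the crystal-interface quadruplex itself
fails it through its 5.4 Å long diagonal, reproducing the finding that no
PDB structure matches the construct's tightness. Whether the published
10 Å rule used indole–indole minima, Cβ–Cβ, or centroids is not stated;
the indole C/N minimum keeps one distance convention across the package
and alternatives are a parameter away. Only the deposited asymmetric unit
and the first model are scanned; sequence-identity deduplication is the
caller's responsibility via an id list.

## The synthetic-data generators

Every input class can be generated with planted ground truth
(`gen_quadruplex()`, `gen_trajectory()`, `gen_charge_series()`,
`gen_energy_gaps()`, `gen_planted_pdb()`), making the full pipeline
testable offline. Generators are pure functions of (spec, seed); a single
global seed is split per generator by fixed documented offsets.

*Structures.* Indole rings are ideal fused pentagon/hexagon rings (bond
1.40 Å) — distance analysis needs rigid planar geometry, nothing more.
Because the rings are larger than the prescribed 3.7–5.4 Å separations,
ring placement is an inverse problem solved by rigid-body optimization
(18 degrees of freedom, Nelder–Mead polished by BFGS with seeded
restarts) driving the six realized minimal distances onto the requested
values within 0.05 Å; a soft penalty keeps NE1–NE1 separations within
0.5 Å of the ring minima, mimicking the crystal arrangement in which the
NH groups face the hydrated interface. Point-infeasible length sets
(violating the triangle inequalities of a 3D embedding) are rejected with
a diagnostic.

*Trajectories.* The stated world follows the forced-transfer protocol:
one block of frames in the initially oxidized state, one block after the
switch. Waters are quasi-structural: one second-shell water per site
(3.5 Å from its NE1) and one bridging water H-bonded between the donor
and acceptor NH groups, biased slightly toward the donor. On the switch
the bridge moves `shift_magnitude` (default 0.15 Å, the middle of the
reported 0.1–0.2 Å range) toward the acceptor NE1 — the single-water
mechanism reported for interfacial transfer — which flips its exclusive
NH-metric assignment, reproducing the "acceptor coordination up, donor
coordination down" signature with a single moving molecule. Per-frame
jitter (default σ = 0.05 Å) reuses one common random-number stream across
the two blocks: quasi-structural waters keep their thermal noise pattern
across the redox switch, so the zero-shift null case yields an *exactly*
zero difference density and the planted shift yields exactly one positive
and one negative isocontour region. What a green test therefore
establishes is correct recovery of a planted, low-noise, single-water
displacement; it does not establish robustness to bulk-water exchange,
hydrogen positions, or the solvational heterogeneity of real ensembles,
none of which the generator emulates. System size (8 waters by default)
is deliberately arbitrary — no target depends on it.

*Charge series.* The hole (total indole charge 1.0 e) sits on the hot
site (mean 0.9 e, the reported magnitude); the three neutral indoles
share the per-frame remainder equally, making their fluctuations
anticorrelated with the hot site by construction and conservation exact.
dmpA (−0.4 e) and Re(CO)₃ (+0.2 e) fluctuate in exact anticorrelation,
mirroring the reported dπ(Re)/π*(dmp) mixing signature. Delocalization
events move a planted fraction of the hot charge to a partner for a
planted interval; fraction 1.0 is a complete transfer.

*Energy gaps.* Gaussian ensembles with means ΔG ± λ and variance 2λk~B~T
— the linear-response-consistent construction that makes (ΔG, λ) recovery
well posed.

*Cluster structures.* Anchors on a regular simplex (or line for n > 4)
rescaled until the smallest realized inter-residue minimal distance
equals the requested spacing; decoys are isolated by > 25 Å; cofactors
are planted at exact minimal distances along an extremal ray.

## Numerical choices and degenerate inputs

* Constants are CODATA: ħ = 6.582×10⁻¹³ meV·s, k~B~ = 0.08617 meV/K,
  K = 14.3996 V·Å/e, centralized in `quad_constants`.
* Comparisons with printed distances use 0.1 Å rounding (one decimal is
  what the figures print); internal values keep full precision.
* Classifier boundaries are strict (`<`), so a frame exactly at 4.5 Å is
  "out" and exactly 4.0 Å is "long".
* Multi-model files: model k is frame k−1 internally (0-based), 1-based
  in files and reports. Crystal altlocs: highest occupancy wins, ties go
  to altloc A.
* No periodic-boundary imaging anywhere: the analysis region is a compact
  interface. Documented limitation for wrapped trajectories.
* Degenerate superposition (rank-deficient reference atoms) and
  non-normalized initial distributions are rejected, not repaired.

## The deposited crystal structure

The two deterministic crystal-distance checks (3.7 Å and 5.4 Å diagonals)
run against a synthetic stand-in
(`inst/extdata/quadruplex_6mjs_synthetic.pdb`, labelled as such in its
REMARK records) built by `gen_quadruplex()` from the published interface
distances, because the test environment has no network access to fetch
the deposited 6MJS coordinates. Against the stand-in the check is a
round trip of the generator plus the full file-reading and
distance-measurement pipeline — not an independent check of the deposited
coordinates. `fetch_structure("6MJS")` retrieves the real entry when a
network is available, and `find_clusters()`/`distance_table()` run on it
unchanged.

## Interfaces

The package's interface is its functions, this vignette, and the test
suite; the analyses are library calls (no shell entry point is shipped —
scripts/acceptance.R shows the end-to-end pipeline as a worked script).
Readers/writers cover PDB v3.3, a restricted mmCIF `atom_site` loop, XYZ,
multi-model PDB trajectories, long-format charge-series CSV, step-table
CSV in the published row/column layout, OpenDX scalar fields for density
grids, and DOT for network graphs.
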