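---
title: "Methods: deep computational phenotyping of SET-domain variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep computational phenotyping of SET-domain variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setphen)
```

## Scope and model

`setphen` implements a multidimensional ("deep") phenotyping workflow for
missense variants in a protein domain, developed around the SET catalytic
domain of the histone H3K4 methyltransferases KMT2C and KMT2D. The workflow
stacks four information tiers:

1. **2D sequence tier** — clinical catalog summaries under the five-class
   significance system, paralog annotation through an alignment, and
   per-tool pathogenicity consensus.
2. **3D structure tier** — threshold classification of folding/binding
   free-energy changes and of residue frustration indices, plus a decoy
   Z-score frustration engine.
3. **4D dynamics tier** — trajectory metrics (RMSD, RMSF, Rg, SASA,
   hydrogen-bond occupancy) and MM-PBSA binding free-energy aggregation
   with pairwise nonbonded interaction energies.
4. **Integration** — the molecular-fitness (MF) classifier, which reduces a
   17-score panel to one of four classes: SV (adverse in structural scores
   only), DV (dynamic only), SDV (both) or VUS (neither).

The package consumes the outputs of external physics engines (free-energy
columns, trajectory frames, energy-component tables); it never runs MD or
computes folding free energies from first principles.

## Thresholds and their provenance

| quantity | rule | default | origin |
|---|---|---|---|
| folding/binding free-energy change | Destabilizing if $\Delta\Delta G \ge$ +t; Stabilizing if $\le -t$ | t = 0.5 kcal/mol | standard stability-screening cutoff |
| frustration index / shift | highly frustrated if $Z < -1.0$; minimally if $Z > 0.78$ | fixed | decoy Z-score convention |
| hydrogen bond | formed if donor–acceptor distance in [2.2, 3.3] Å | fixed | heavy-atom distance criterion |
| H-bond window | last fraction of frames analysed | 0.25 | "last quarter" convention |
| contact | Cβ–Cβ (Cα for Gly) $\le$ 6.5 Å, $|i-j| \ge 2$ | configurable | common coarse contact definition |
| per-tool consensus cutoffs | direction-aware; tie $\to$ Damaging | shipped TSV | commonly published values, user-overridable |

Two boundary decisions deserve mention. First, the free-energy boundary is
**inclusive**: a value of exactly 0.5 kcal/mol is called Destabilizing. Strict
and inclusive readings of the cutoff both circulate; the inclusive form is the
one consistent with published per-variant effect tables in this domain family,
where a 0.5 kcal/mol alanine-scan value carries a destabilizing label. Second,
a predictor score exactly at its cutoff is called Damaging — the conservative
choice for a screening tool.

The bundled score table carries `as_printed_*` audit columns. Re-applying the
rules reproduces every printed label except one: a frustration shift of +1.91
labeled neutral in its source while the identical value elsewhere is labeled
minimally frustrated. The package follows the rule, and the audit column
preserves the original label; tests pin this single, documented divergence.

## The frustration engine

The engine computes **mutational** single-residue frustration: the native
contact energy of residue $i$,
$E_i = \sum_{j \in \mathrm{contacts}(i)} \varepsilon(a_i, a_j)$,
is compared with a decoy ensemble in which $a_i$ is replaced by an identity
drawn uniformly from the 19 alternatives while contacts and geometry stay
frozen. The index is $(\bar E_{\mathrm{decoy}} - E_i)/\mathrm{sd}(E_{\mathrm{decoy}})$,
so large positive values mean a well-optimized (minimally frustrated) native
identity. Where the literature distinguishes mutational from configurational
frustration (decoys re-positioned in space), we implement the mutational
variant: it needs no re-embedding of decoys and matches the frozen-geometry
information actually available to this package. Because the decoy
distribution over 19 identities can be enumerated exactly, the Monte-Carlo
path is testable against a closed-form oracle; the suite requires agreement
within three standard errors at 10,000 draws.

The default 20×20 contact potential is **synthetic**: a quasi-chemical-style
table derived from Kyte–Doolittle hydropathies, with hydrophobic–hydrophobic
contacts most favorable. It reproduces the qualitative structure of
knowledge-based potentials without redistributing any fitted parameter set,
and any 20×20 TSV can be swapped in (`read_contact_potential()`). Absolute
frustration magnitudes from server-based calculations are therefore not
reproduction targets; classification logic, Z-score mechanics and seeded
determinism are.

## Trajectory metrics: conventions

* **Superposition** is Kabsch (SVD with determinant correction), always a
  proper rotation. RMSD series fit each frame to the reference over the
  selection before measuring.
* **RMSF** follows the "fit to first frame, average, measure about the
  average" recipe, at per-residue granularity via selected-atom centroids,
  with the population (divide-by-$n$) variance convention. Under the
  Gaussian generator the expected value is
  $\sigma_i \sqrt{3}\sqrt{(n-1)/n}$. Accumulation is done relative to the
  reference centroids to avoid catastrophic cancellation when coordinates
  are far from the origin. The measured recovery ratio sits near 0.98 at
  2,000 frames because the rigid-body fit removes six degrees of freedom
  from the fluctuation budget; the test band (1.00 ± 0.05) accounts for it.
* **SASA** is Shrake–Rupley with a deterministic golden-spiral point set
  (960 points/atom by default, probe 1.4 Å). With a lab-fixed point set the
  algorithm is rotation-invariant only to the discretization level (a few
  tenths of a percent at 960 points; tests assert 0.5%, halving under
  point-count doubling). A test point lying exactly on a neighbor's
  expanded sphere — which happens only for duplicate atoms — is assigned to
  the lower-index atom, so coincident spheres contribute one surface rather
  than zero or two.
* **Hydrogen bonds** are monitored between named heavy donor/acceptor
  atoms; with implicit-solvent models hydrogen positions are often absent,
  so the 2.2–3.3 Å criterion applies to the heavy-atom distance exactly as
  configured.

## MM-PBSA aggregation

Per-frame binding energies are
$\Delta G_\mathrm{bind} = G_\mathrm{complex} - G_\mathrm{receptor} - G_\mathrm{ligand}$
with $G = (E_\mathrm{vdw}+E_\mathrm{ele}+E_\mathrm{bnd}) + G_\mathrm{PB} + G_\mathrm{SA} - TS$.
Entropy defaults to zero unless supplied, the common end-point practice. Both
customary snapshot depths are available — 100 frames (last nanosecond at
10 ps) and 150 snapshots — since both circulate in the literature; the
generator and tests default to 150. The single-trajectory convention is
assumed: receptor and ligand frames come from the complex trajectory.
Pairwise nonbonded (CIE) energies use $k_e = 332.0636$ kcal·Å/(mol·e²),
Lorentz–Berthelot combination, and either a constant or distance-dependent
dielectric, since source analyses do not always state which screening model
was used.

## Molecular-fitness integration

The MF class is a pure function of two counts: structural adverse calls
(Destabilizing or HighlyFrustrated among the six structural scores —
stabilizing calls are *not* adverse, which is what lets a variant with one
destabilizing fold score and an otherwise stabilizing/neutral panel come out
SV) and dynamic adverse calls. The default dynamic registry holds eleven
scores (RMSF correlation and mean absolute difference, Rg/SASA/CIE relative
shifts, two MM-PBSA differences, four bond occupancies), completing a
17-score panel with the structural six. Published work in this area does not
enumerate its dynamic panel or per-score thresholds, so the registry and its
rules (correlation floor 0.9, 0.2 Å profile difference, 5% relative shifts,
10% binding-energy change, 0.25 occupancy drop) are documented package
defaults, fully user-editable — and per-variant SDV assignments under other
panels are explicitly not a reproduction target.

## Synthetic generators: what they emulate, and what not

* `gen_trajectory()` — ideal α-helix reference (1.5 Å rise, 100°/residue,
  2.3 Å Cα radius; CA+CB or 4-atom backbone) plus per-residue isotropic
  Gaussian displacement and optional per-frame rigid motion. It emulates the
  *statistical* structure trajectory metrics assume (known fluctuation
  amplitudes, rigid-body nuisance motion), not force-field physics: no bonded
  constraints, no anisotropy, no time correlation. Passing recovery tests
  therefore validates estimator correctness, not MD realism.
* `gen_energy_table()` — Gaussian component tables whose frame-wise
  complex − receptor − ligand difference has a specified mean/sd.
* `gen_paralog_alignment()` — synthetic sequences constrained only so that
  given position pairs (e.g. the 20 KMT2D→KMT2C pairs at constant offset
  626, with the already-glutamate exclusion site) map exactly; filler is
  seeded and never affects the constrained pairs. Sequence identity of the
  fixture is not meaningful.
* `gen_variant_table()` — class counts by largest-remainder allocation then
  a seeded shuffle, so catalog summaries are exact rather than multinomial.

All generators restore the caller's RNG state and are bytewise reproducible
under a fixed seed.

## Numerical and bookkeeping choices

* Percentages round half-away-from-zero to one decimal — the convention that
  reproduces published mining summaries (65.7%, 74.3%, …); base R's
  round-half-even does not in general.
* Published gene-level counts cover VUS, conflicting-interpretation and
  not-provided classes; the benign/pathogenic split of the remainder is not
  public, so the count fixture allocates it deterministically and marks
  those rows unpublished. Only published figures are asserted.
* Protein coordinates are 1-based (HGVS); genomic location strings are
  carried as opaque text (public tables contain formatting irregularities).
* Tool-count ambiguity (19 vs 20 predictors; 74% vs 75% for the
  lowest-consensus variant) is surfaced by reporting both the count and the
  rounded fraction; the package takes no side.
* Pipeline outputs carry a version/seed/config-fingerprint header line;
  reruns with identical configuration are byte-identical.
* Problem sizes in the test and acceptance runs — 2,000 frames × 50 residues
  for RMSF recovery, 10,000 decoys for the frustration oracle, 150 frames
  for MM-PBSA — were chosen as the smallest sizes at which the stated
  tolerances are comfortably interpretable statistical statements.

## Known limitations

* The frustration engine is a simplified stand-in for server-based
  frustratometry: pairwise additive contact energies, uniform decoy
  composition, no electrostatic or water-mediated terms, no configurational
  decoys. Comparisons should stay within one potential.
* SASA is exact only up to sphere-point discretization; areas of buried
  cavities are counted as inaccessible only insofar as the point test sees
  them.
* The MF classifier inherits the arbitrariness of its thresholds; its value
  is the transparent, reproducible bookkeeping, not the specific defaults.
* Readers of multi-MODEL PDB files assume a constant atom set across
  models.
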