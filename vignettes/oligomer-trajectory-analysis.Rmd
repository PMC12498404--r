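---
title: "Methods: trajectory analysis of peptide/lipid co-oligomerization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of peptide/lipid co-oligomerization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligotraj)
```

This vignette explains the models and procedures behind each analysis
stage, the parameters a user may want to change, the design choices made
where the methodology was genuinely open, and what the synthetic-data
validation does and does not establish about real trajectories.

## Data model

A `topology` is a per-atom table (name, chain, 1-based residue number,
residue name, mass in amu, van der Waals radius in nm) plus a chain table
with half-open atom index ranges. Chain kind is inferred from residue
names: `POPC` residues make a lipid chain, the twenty amino acids a
peptide chain; anything else is an error rather than a guess. Lipid atoms
additionally carry one of four region labels — choline, phosphate,
glycerol (including both ester linkages) or tail — from a packaged table
keyed by CHARMM36 POPC atom names. The atom-level boundaries of those
regions are a package convention: the headgroup bracketing (choline
nitrogen and its methyls/methylenes; the phosphate and its four oxygens;
the glycerol backbone with the ester carbonyls; everything else acyl
tail) follows the standard chemical decomposition of the lipid, and
unknown atom names are fatal so silent misassignment cannot occur.

Frames carry nm coordinates, an orthorhombic box and a time in ns.
Triclinic boxes are rejected: the minimum-image distance for an
orthorhombic box reduces to a per-component fold
(`d - box * round(d / box)`), which is provably the minimum over all
periodic images; supporting triclinic cells would trade that correctness
argument for generality the studied systems do not need.

File IO supports a plain-text "test dialect" (JSON topology, whitespace
frame blocks, 17 significant digits so load–write–load round-trips
bit-identically) used by all fixtures, plus GRO/PDB topologies and DCD
trajectories through bio3d. Compressed MD formats (XTC/TRR) have no
reader in plain R and are out of scope; converting to DCD or the text
dialect is the supported route.

## Aggregation states

Per frame, the distance between two peptides is the minimum over their
atom pairs of the minimum-image distance (all atoms by default, matching
the convention of common `mindist` tools; a heavy-atom mode is
available). Peptides are nodes; an edge joins a pair when d < 0.6 nm
(strictly — the cutoff itself is not a contact). Connected components of
that graph are the N-mers, so connectivity is transitive: A–B and B–C
contacts make {A, B, C} a trimer regardless of the A–C distance.

The aggregation time is the earliest time from which the full N-mer
persists to the final frame. "Persists" is deliberately not literal:
transient dissociations shorter than a dwell tolerance (default 1 ns) are
bridged, because single-frame flickers across a hard distance cutoff are
noise, not dissociation events. The tolerance is a parameter, and results
that depend on it should report it; gap duration is measured as the
number of gap frames times the frame spacing.

## Shape

The radius of gyration is mass-weighted,
\(R_g = (\sum_i m_i \lVert r_i\rVert^2 / \sum_i m_i)^{1/2}\), with
positions relative to the selection's centre of mass, and requires whole
(unwrapped) molecules — `unwrap_molecule()` walks each chain and picks,
per atom, the periodic image nearest its predecessor.

Eccentricity is computed from the eigenvalues of the mass-weighted
inertia tensor, sorted ascending, as
\(e = 1 - (I_1 + I_2 - I_3)/(-I_1 + I_2 + I_3)\). Two conventions needed
fixing:

* **Moment order.** The moments are ascending with \(I_1\) assigned to
  the major (longest) axis — the longest axis has the *smallest* moment.
  This is the only assignment under which the formula stays in [0, 1]
  with 0 for a sphere, which is how the statistic is interpreted.
* **Mass weighting.** Moments are mass-weighted, consistent with the
  mass-weighted \(R_g\) and with what MD analysis suites compute.
  Unit-mass moments would differ for heteronuclear systems; for the
  bead fixtures used in validation the two coincide.

The identity \(e = 1 - \langle c^2\rangle/\langle a^2\rangle\) (ratio of
mass-weighted squared extents along the minor and major principal axes)
follows algebraically and is enforced in the tests to 1e-10 as an
independent check of the formula's sign conventions. For a solid
ellipsoid with semi-axes \(a \ge b \ge c\), \(I_a = M(b^2+c^2)/5\) etc.,
giving e.g. \(e = 8/9\) for a 3:1:1 ellipsoid.

The ellipsoid generator samples points uniformly in the ellipsoid and
then affinely standardizes the cloud so its sample second moments equal
the analytic values exactly. The planted ground truth therefore holds for
the realized points rather than only in expectation, and shape-recovery
tests measure implementation error, not Monte-Carlo noise. An
unstandardized rejection-sampling oracle in the test suite confirms the
closed-form moments independently.

## Conformational clustering

`kabsch_rmsd()` computes the least-squares RMSD after optimal translation
and proper rotation (SVD with determinant correction, so mirror images
are never superposed). Collinear structures make the optimal rotation
non-unique and are rejected. `gromos_cluster()` implements neighbor-count
clustering: repeatedly take the structure with the most neighbors at
RMSD < cutoff (strictly), remove it and its neighbors as a cluster, and
recount. Ties go to the lowest structure index, which makes output
deterministic. Windowed clustering (default 200 ns windows, 0.3 nm
cutoff) concatenates the peptide backbone (N, CA, C, O) in chain order;
for bead models without full backbones it falls back to all peptide
atoms. No chain-permutation minimization is attempted: multi-peptide RMSD
treats chains as labelled, which overestimates RMSD between frames that
differ by a peptide relabelling. This is a known limitation; exact
permutation-RMSD is factorially expensive and not implemented. A trailing
window below half occupancy is dropped rather than reported from too few
frames.

## Interaction maps

The residue-pair interaction frequency compresses three observations into
one number in [0, 1]: how many distinct molecule pairs ever show the
contact, how often it is present, and how tight it is. The combination
used is multiplicative,
\(F = \frac{\text{pairs observed}}{\text{pairs possible}} \times
\text{frame fraction} \times (1 - \bar d/\text{cutoff})\),
chosen because it preserves all three monotonicities (more pairs, more
frames, tighter contact each increase F), is exactly 0 when a contact
never occurs and approaches 1 only at saturation. It is a package
definition, isolated in `interaction_frequency()` so an alternative
weighting can be swapped in without touching the contact statistics. For
residue pairs (i, j) with i ≠ j the two orientations across a peptide
pair are collapsed by taking the closer one, which keeps the map
symmetric by construction. Region maps use (peptide, lipid) molecule
pairs with the contact evaluated against the atoms of one lipid region.

Hydrogen bonds use the geometric criterion
r < 3.3 Å − 0.00044 θ², with r the donor–acceptor distance and θ the
H–donor–acceptor angle in degrees. Donors are N/O atoms with a hydrogen
within 1.2 Å; acceptors are any other N/O; intra-residue pairs are
excluded. Hydrogens must be present in the topology — a united-atom or
bead topology is a hard error with guidance, not a silent empty result.

## Surface area and secondary structure

SASA uses Shrake–Rupley sphere-point quadrature with a deterministic
golden-spiral point set (default 960 points, probe 0.14 nm, Bondi-type
element radii). Determinism matters: reruns are bit-identical, and
convergence can be studied by raising the point count (96/960/9600 in the
tests, converging to the two-sphere closed form). Hydrophobic SASA sums
residue areas over Ala/Val/Leu/Ile/Met/Phe — 19 of the 42 residues of the
amyloid-beta (1-42) sequence. Normalized solvent contact divides chain
SASA by its heavy-atom count so exposure is comparable between a
42-residue peptide and a 134-atom lipid.

Secondary structure is consumed, not computed: the parser accepts a
frames × residues grid of 8-state DSSP letters and collapses H/G/I to
helix, E/B to strand and everything else to coil. System percentages are
means over frames and residues; replicate tables give a standard
deviation.

## Energetics

FoldX SequenceDetail text is parsed into per-residue total energies; the
energy matrix is residues × time windows with replicate energies averaged
per cell *before* differencing, and missing cells kept as NA rather than
zero. ΔΔG is treated minus control, so positive values mean the residue
is less favorable in the lipid-exposed condition. Residue classes follow
the conventional grouping with two decisions made explicit: Phe and Tyr
are aromatic (aromatic takes precedence over hydrophobic for Phe), and
His is polar rather than aromatic. Both are configurable readings of an
ambiguous convention; tests pin the chosen one. The ΔΔG–ΔSASA
relationship is an ordinary least-squares fit reporting slope and R².

## Statistical framework

Frames of one trajectory are autocorrelated, so group comparisons draw n
values (default 100) at uniformly random time indices without
replacement. Random index sampling decorrelates the draw, but only makes
the draws representative when the series is long relative to its
correlation time: for an AR(1) process with lag-1 correlation ρ the
integrated correlation time is τ ≈ (1+ρ)/(1−ρ) frames, and the realized
mean of a series of length L fluctuates with variance ≈ τ/L. For the
group comparison to hold its nominal size, that fluctuation must be small
against the subsample-mean noise 1/n, i.e. L ≫ n·τ. The null calibration
uses ρ = 0.9 (τ ≈ 19) with L = 50 000 ≫ 100·19, where the measured
rejection rate sits at the nominal 0.05; short series inflate the type-I
error for reasons no subsampling can repair, and users comparing short
trajectories should treat per-replicate means, not frames, as the unit.

Test selection is assumption-driven: Shapiro–Wilk per group and Levene
(mean-centered, the classical form) across groups, both at α = 0.05;
normal and homoscedastic data get ANOVA + Tukey HSD (two groups: pooled
t-test), anything else Kruskal–Wallis + Dunn (two groups: Mann–Whitney).
Dunn's rank-based post-hoc test is implemented in-package (pairwise z
statistics on mean ranks with tie correction) since no installed package
provides it. p-values are Benjamini–Hochberg adjusted
(Benjamini–Yekutieli available); significance is FDR-adjusted p < 0.05.
Groups that are identical constants short-circuit to "not significant,
with a warning" instead of producing NaN statistics.

## Synthetic data: what it does and does not establish

The generators script geometry; they do not integrate dynamics. The
aggregation generator places rigid bead-chain peptides on a slot grid:
members of one planted component are stacked 0.4 nm apart (minimum
distance < 0.45 nm even under jitter), distinct components are separated
by > 1.2 nm, and Gaussian jitter (σ = 0.01 nm by default, bounded below
0.05 nm) never closes the ≥ 0.6 nm margin between those regimes — so
detector correctness is tested, not tolerance luck. Lipids (1:1 with
peptides by default, matching the studied peptide:lipid ratio) are placed
away from the aggregate so the peptide partition ground truth is
unaffected; lipid-binding behavior is exercised by dedicated scripted
fixtures instead. Passing on these fixtures establishes that the graph
detection, dwell bridging, shape formulas, clustering, contact weighting,
H-bond criterion, SASA quadrature and statistics are implemented
correctly. It does not establish anything about force fields, sampling
convergence, or the biology of real aggregation — the synthetic
trajectories have no physics in them by design.

## Problem sizes and runtime choices

The packaged study uses 6 peptides (5 beads each) with 6 four-bead
lipids, 200 frames at 0.5 ns spacing, three replicates per condition;
clustering windows are 20 ns on these trajectories. Ellipsoid validation
uses 10^5-point clouds; oracle comparisons use 200 random 10-peptide
frames and 100 random clustering trials; the null calibration runs 1000
replicates of 3 × 50 000-frame series. These sizes keep a full validation
run in tens of seconds on one core while leaving every code path
exercised; all of them scale up by argument without code changes.

## Interfaces

The package's functions are the interface; the numbered scripts under
`analysis/` are thin drivers that reproduce the packaged study and write
CSV tables under `results/`, and `run_pipeline()` orchestrates all stages
from one validated configuration with a single root seed and a JSON
provenance record (config hash, seed, package version). A separate shell
CLI would add nothing for an analysis package of this shape, so none is
provided.
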