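---
title: "Residue-level interface analysis with ppiface: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-level interface analysis with ppiface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiface)
```

## The scientific question

When two proteins associate, the patch of surface they bury — the
interface — can be driven mainly by the hydrophobic effect (nonpolar
residues clustering away from water) or, in a substantial minority of
heterodimers, by polar and charged contacts. `ppiface` quantifies this at
residue level for a two-chain complex: it measures the percentage of polar
residues on the interface (I) and on the rest of the solvent-exposed
surface (S), and assigns the complex to **class A** when the interface is
less polar than the surface (S > I, the classical hydrophobic-core-like
interface) or **class B** when it is more polar (S < I). Around this
classification the package computes the physicochemical features that
co-vary with it — interface area, polar-minus-nonpolar abundance, charged
residue percentage, solvation free-energy gain, a knowledge-based binding
energy, hydrogen-bond and salt-bridge counts, and an electrostatic
complementarity score — and tests which features discriminate the two
classes.

## Accessible surface area and interface detection

Solvent-accessible surface area (ASA) is computed by Shrake–Rupley point
quadrature: each atom is inflated by the probe radius (water, 1.4 Å) and
sampled on a spherical Fibonacci lattice (default 960 points per atom); a
point is accessible when it lies outside every neighbouring inflated
sphere, and the atom's area is the accessible point fraction times
$4\pi (r + r_\mathrm{probe})^2$. The lattice is deterministic, which has
two consequences worth stating:

* results are bit-reproducible for fixed parameters, and
* the per-residue difference between two computations run with the same
  parameters (a chain in isolation versus in the complex) carries **no
  lattice noise**: an atom whose occluder set is unchanged gets exactly
  the same area in both runs.

The second property is what makes the interface threshold workable. A
residue is an **interface residue** when its ASA drops by more than
0.1 Å² between the isolated chain and the complex (ΔASA > 0.1 Å²); with a
noise-free difference this tiny threshold is meaningful even at a
quadrature density where absolute per-atom areas are only accurate to
about 0.5–1%. The total interface area is the un-halved sum of per-residue
ΔASA over both chains (configurable to the halved, one-sided convention).

Quadrature accuracy was characterised against closed-form oracles: an
isolated sphere is exact up to floating-point error, and two-sphere
contact geometries match the analytic spherical-cap formula to within
0.5% at 3 840 points per atom; the coarser 960-point default can exceed
that band on individual atoms in unfavourable contact geometries but
stays within 1% of a 4 000-point computation on whole complexes (both
properties are asserted in the test suite). Analytic-agreement tests
therefore run at 3 840 points; everything pipeline-facing uses the
960-point default.

**Surface residues** are the comparison set for interface polarity: any
residue with relative accessibility ≥ 5% in the bound complex that is not
an interface residue. The 5% threshold and the interface exclusion are
both options (`detect_surface()`), because neither choice is forced by the
classification idea itself; relative accessibility uses the Tien et al.
(2013) theoretical maximal ASA values per residue type, clipped at 1.

Radii follow a Chothia-class protein set (aliphatic/carbonyl C 1.87/1.76,
aromatic C 1.76, N 1.65, O 1.40, S 1.85 Å) with element fallbacks.
Hydrogens, when present, are kept in the structure but excluded from area
and contact calculations — the criteria are heavy-atom criteria
throughout, appropriate for typical crystal structures. Alternate
locations resolve to the highest-occupancy conformer; modified residues
with a clear parent (MSE → MET and similar) are renamed so the 20-residue
polar/nonpolar partition stays well defined, and other non-standard
residues are retained for occlusion but left out of polarity percentages.

## Polarity classes

Polar residues are R, N, D, E, Q, H, K, S, T, Y; nonpolar are A, C, G, I,
L, M, F, P, V, W; the charged subset defaults to D, E, K, R with
histidine optional. Percentages are residue counts over the standard
residues of each region, pooled across both chains (a buried-area-weighted
variant is available). The headline composition statistic is the
interface polarity abundance P% − NP%, and classification compares S with
I directly: S > I gives class A, S < I class B, and exact ties (within an
optional `tie_epsilon` band, default 0) are reported as `"tie"` and
excluded from class statistics rather than forced into a class.

## Contacts

Intermolecular hydrogen bonds are donor–acceptor heavy-atom pairs on
different chains strictly closer than 4 Å; salt bridges are oppositely
charged side-chain atoms (Asp/Glu carboxylate oxygens or terminal OXT
versus Lys NZ, Arg NE/NH1/NH2, optionally His ring nitrogens) within 4 Å
inclusive. The asymmetric strict/inclusive defaults mirror the usual
phrasing of the two criteria and are configurable. No angular filters are
applied by default — with heavy atoms only, a distance criterion is the
reproducible core, and any angle term can only remove pairs. Salt bridges
are reported both as atom pairs and as unique residue pairs; the residue
pair count is the headline number, so an ion pair touching through both
carboxylate oxygens still counts once. All detections are validated
against an all-pairs brute-force scan in the test suite.

## Energetics

**Solvation free-energy gain** on interface formation uses an atomic
solvation parameter model: Δ<sup>i</sup>G = Σ<sub>atoms</sub> σ(class) ×
(−ΔASA<sub>atom</sub>), with Eisenberg–McLachlan-style σ values per atom
class (C +0.016, neutral N/O −0.006, charged O −0.024, charged N −0.050,
S +0.021 kcal mol⁻¹ Å⁻²). Burying nonpolar carbon area therefore gives
negative values — the signature of a hydrophobic, class-A-like interface —
while burying charged groups is penalised.

**Binding energy** uses a distance-dependent pairwise potential of mean
force ū(i, j, r) over atom types. The score is half the sum of ū over
ordered cross-chain atom pairs within the cutoff, i.e. exactly the plain
sum over unordered pairs; the half factor exists to undo the
double-counting of a directional enumeration. This interface sum is
algebraically identical to the thermodynamic-cycle difference
G(complex) − (G(A) + G(B)) because intra-chain contributions cancel, and
the test suite asserts that identity to 10⁻⁹ relative for arbitrary
tables. (As printed in some descriptions the cycle formula omits the
minus sign; the difference form is the only thermodynamically sensible
reading and is what is implemented.)

Tables can be trained from any structure collection with
`train_potential()`, using a distance-scaled reference state:
ū = −η log[N(r) / ((r/r<sub>cut</sub>)<sup>α</sup> N(r<sub>cut</sub>))]
with 0.5 Å bins to a 10 Å cutoff, α = 1.61 (the finite-size exponent used
by distance-scaled reference states; α = 2 recovers the exact uniform
ideal-gas reference, under which a random point gas trains to a null
potential within counting noise), and a small pseudocount to tame empty
bins. Atom types collapse (residue, atom) to a ~13-label alphabet
(backbone N/CA/C/O, aliphatic/aromatic carbon, hydroxyl, amide O/N,
carboxylate O, positive N, ring N, S) so that small training sets keep
their bins populated. The packaged table is trained on the synthetic
fixture set and is meant for tests and examples: it demonstrates the
formalism, and no numeric comparability with externally trained
binding-energy scales is claimed — which is also why cohort-level
binding-energy values here are on the scale of the shipped table, not of
published tools.

## Electrostatic complementarity

Instead of a full Poisson–Boltzmann surface map, `ppiface` uses a
screened-Coulomb model as a quantitative stand-in for the visual
inspection such maps support: φ(x) = Σ 332 q / (ε r) e^(−κr) with
interior dielectric ε = 4, screening κ = 0.1 Å⁻¹ by default (κ is a free
parameter; the qualitative behaviour is insensitive to it), and formal
charges −0.5 per carboxylate oxygen, +1 on Lys NZ, +1/3 on each Arg
guanidinium nitrogen. Distances are floored at 1 Å to avoid self-atom
singularities.

At every interface atom position both chains' potentials are evaluated
separately. The **complementarity score** is the Pearson correlation
between the field a point's *own* chain generates there and the field the
*partner* chain impresses on it. The pairing matters: the naive
correlation of (φ_A, φ_B) over sample points is dominated by
own-proximity (points near a chain-A lysine have a large φ_A whatever
chain B carries) and does not discriminate charge layouts. Correlating
own field against partner field removes that trivial signal: planted
opposite-charge interfaces score strongly negative (measured ≈ −0.96 on
fixtures) and same-charge interfaces strongly positive (≈ +0.89),
matching the intuition that class-B-like polar interfaces pair positive
patches with negative ones. The score is invariant to rigid-body motion,
chain relabelling and overall charge scaling, and is `NA` for interfaces
without charges (zero field variance).

## Class-comparison statistics

Features are compared between classes with the two-sided Wilcoxon
rank-sum (Mann–Whitney) test. The two classes are independent groups of
generally unequal size, which is why the rank-sum test — not the paired
signed-rank test — is the default; a paired variant is available for
genuinely paired designs. The exact mode enumerates the null distribution
of the rank sum over all $\binom{n}{n_A}$ group assignments using a
shift-algorithm dynamic program over doubled mid-ranks, so it is exact
with ties, and is used automatically up to a combined n of 30; beyond
that a tie-corrected normal approximation with continuity correction
takes over. Exactness is verified against exhaustive enumeration for all
group sizes up to 8 and against the reference implementation for tie-free
samples, and the test holds its nominal 5% size across simulated null
cohorts. The family of per-feature p-values in one report is adjusted by
Benjamini–Hochberg (reported as q-values), and Pearson correlations are
reported for the canonical pairs (H-bonds, binding energy and solvation
gain against interface area; binding energy against solvation gain),
overall and within each class.

## The synthetic generator, and what it does and does not emulate

Real heterodimer cohorts require curated crystal structures; for
validation the package instead generates toy heterodimers whose ground
truth is known **by construction**. Chains are built from rigid residue
stubs (CA, CB and one or two representative terminal atoms — e.g. Lys NZ,
Asp OD1/OD2, Ser OG) placed on two planes:

* **interface residues** sit on a 5 Å grid, tips facing their counterpart
  across the contact plane at controlled gaps: 2.9 Å for planted
  Ser–Ser hydrogen bonds, 3.5 Å for planted Lys–Asp salt bridges, and
  4.5 Å for generic contacts — beyond both contact cutoffs yet within
  mutual occlusion range, so every planted interface residue loses well
  over 0.1 Å² of accessible area while forming no unplanned contacts
  (grid neighbours are ≥ 5 Å apart across chains);
* **surface residues** sit on a 6 Å grid at least 10 Å behind the contact
  plane, outside occlusion range of the partner chain, so their ΔASA is
  exactly zero and their exposure keeps them far above the 5% surface
  threshold.

Because of this layout the manifest (region labels, composition
percentages, planted contact list, expected class) is an exact oracle,
and the pipeline must reproduce it *exactly* — not approximately — which
the test suite asserts for interface sets, surface sets, polarity
percentages and contact counts. Note one chemical inevitability: a
planted salt bridge is also a donor–acceptor pair within 4 Å, so the
expected hydrogen-bond count of a dimer is the planted hydrogen bonds
plus the planted salt bridges.

Cohorts emulate the two classes: class-A-like members draw surface polar
fraction from Normal(0.55, noise) and interface polar fraction from
Normal(0.35, noise), class-B-like members the reverse (noise defaults to
0.05 and the master seed derives per-member seeds); class A members get
larger contact patches (12 vs 8 interface residues per chain) and fewer
charged interface residues (10% vs 40%, 1 vs 2 salt bridges), mirroring
the qualitative contrasts reported for real heterodimer cohorts: larger,
more hydrophobic interfaces in class A, smaller, more polar and charged
interfaces in class B. Infeasible draws are reconciled by construction
(planted contact counts never exceed the polar budget).

What the generator does **not** emulate: real backbone connectivity and
rotamer geometry (stub atoms are collinear within a residue, so they
mutually occlude somewhat more than real side chains — the reason
relative-accessibility checks are phrased against stub-derived
references rather than the real-protein maximal ASA table), buried cores
(every non-interface residue is exposed), irregular interface shapes,
crystallographic noise, and any evolutionary signal. Passing the suite
therefore demonstrates the correctness of the computational chain —
detection thresholds, counting conventions, identities and statistics —
not calibration against experimental structures. On real PDB files the
same functions apply unchanged (`read_complex()` handles fixed-column
PDB with altlocs, waters, hydrogens and modified residues), but numeric
agreement with any specific published tool chain is not claimed: a
different ASA engine, different radii, or an angular hydrogen-bond
definition will shift feature values, which is why every such choice here
is explicit and configurable.

## Numerical and degenerate-input policy

* Negative per-residue ΔASA within quadrature noise is clamped to zero.
* Chains without inter-chain contact analyse to a valid zero-interface
  result (class `"not applicable"`), with a warning, and are excluded
  from class statistics.
* Exactly coincident atoms split their shared area equally, with a
  warning.
* All-identical samples give p = 1; zero-variance fields give an `NA`
  complementarity score.
* Cohort analysis isolates per-complex failures (log and skip) so one
  malformed file cannot abort a large run.
* Problem sizes in the shipped tests and in `scripts/acceptance.R` —
  cohorts of 60 complexes of 30 residues per chain, 960-point quadrature,
  3 840 points for analytic-oracle checks — were chosen as the smallest
  sizes at which every property under test is comfortably resolved.

## Reproducing a cohort analysis

```{r, eval = FALSE}
library(ppiface)
cohort <- build_cohort(n_class_a = 30, n_class_b = 30,
                       noise = 0.05, seed = 1)
res <- analyze_cohort(cohort$complexes)
res$report         # Wilcoxon rank-sum tests with BH q-values
res$features       # one feature row per complex
```

`scripts/acceptance.R --seed <int> --out <path>` runs this end to end —
quadrature oracle, cohort build, feature extraction, class comparison,
contact recovery, the binding-energy identity and the complementarity
fixtures — and writes the headline numbers as JSON.
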