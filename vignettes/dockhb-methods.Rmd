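---
title: "Post-docking hydrogen-bond analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-docking hydrogen-bond analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockhb)
```

## The problem

Phosphodiesterase-4 (PDE4) inhibitors are anti-inflammatory drug
candidates whose potency differences are often invisible in static
binding modes: potent and weak inhibitors of the PDE4B1 subtype can
occupy the catalytic site in nearly the same way. A recurring
observation in modeling studies of this family is that the
*water-mediated* interaction pattern at the catalytic site — fourteen
ordered waters, two of them (numbers 1 and 13) coordinated by the Zn
and Mg ions — discriminates the classes: low-active ligands anchor
their 5-acetyl carbonyl oxygen to the site waters with short, strong
hydrogen bonds, while active ligands preferentially engage the
side-chain amide of a catalytic-site glutamine (residue 443).

`dockhb` packages the post-docking half of such a study as a tested,
reusable pipeline: reading minimized ligand–enzyme complexes, clustering
docking poses, surveying hydrogen bonds geometrically, summarising them
per ligand, and comparing an active against a low-active class
statistically. The docking search and the force-field minimization
themselves are out of scope; the pipeline consumes their outputs (or
synthetic stand-ins).

## The hydrogen-bond criterion

A hydrogen bond is collected when the hydrogen–acceptor distance is
**strictly below 3.5 Å** and the donor–hydrogen–acceptor angle (vertex
at the hydrogen) lies **inclusively between 120° and 170°**. Both
directions are surveyed: ligand-donates (ligand–D–H···A–enzyme) and
ligand-accepts (ligand–A···H–D–enzyme). Donors are N/O/S heavy atoms
with covalently bound hydrogens; acceptors are N and O atoms (S
optional); carbons and metal ions never participate. Only
ligand↔(protein|water) pairs are reported; "vacuum" mode drops water
partners.

Three conventions deserve a note:

* **Angle vertex at the hydrogen.** The source criterion names the two
  bond directions but not the vertex; ∠D–H···A is the field standard.
* **Distance is H···A**, per the criterion's explicit wording — not the
  donor–acceptor heavy-atom distance. Whether published per-pose tables
  use H···A or heavy-atom distances is not stated; this package
  interprets them as H···A throughout.
* **The 170° upper bound is implemented literally and inclusively.**
  Excluding near-linear bonds is unusual (it may be a typo for 180°),
  but the printed bound is honoured; `hbond_criteria(angle_max = 180)`
  restores the conventional window.

Numerically, comparisons carry a 1e-9 guard (strict-less on distance,
inclusive on angles) so that geometry constructed *exactly* at a
printed boundary resolves deterministically instead of depending on the
last bit of a square root. 1e-9 Å is far below any physical precision.

The per-ligand survey reduces to the study's two parameters: the
**number of hydrogen bonds per conformation (pose)** and the
**arithmetic mean of the H···A distance** over all bonds of all poses,
computed in vacuum and with waters, plus the same quantities for the
focused subset (the ligand acetyl oxygen against Gln443 and waters
1/13).

## Pose clustering

Docking ensembles (100 poses per ligand in the emulated workflow) are
grouped into clusters "within 5 RMSD" and the lowest-energy clusters
covering at least 70% of all poses are retained. The source names no
algorithm; this package uses **greedy energy-seeded single-pass
assignment** — repeatedly seed a new cluster with the lowest-energy
unassigned pose and absorb every unassigned pose within the threshold —
the classic docking convention, chosen because it is deterministic and
pairs naturally with "clusters at the lowest energy". RMSD is computed
**without superposition** (poses share the receptor frame) over heavy
atoms only; energy ties break by pose index; "at least 70%" uses a
ceiling on the pose count. Whether downstream statistics should use all
poses of the selected clusters or only representatives is not stated;
both are supported (`pose_use`), defaulting to all poses.

## Class statistics

The study's modeling classes are eight active ligands (Roflumilast, 2c,
2e, 2f, 2n, 2p, 3a, 3k; PDE4B1 IC50 0.69–19.54 nM) and eight very
low-active ligands (Rolipram, 2i, 2h, 2o, 4f, 5d, 7, 10a; 520–6700 nM).
Membership lists are authoritative in `assign_modeling_class()`: the
IC50 windows also contain potent compounds that were simply not
selected for modeling (e.g. 2t at 7.20 nM), so the window fallback is
opt-in (`use_ranges = TRUE`).

Class comparisons use **Welch's unequal-variance two-sample t-test**,
two-sided (the source reports p-values without naming a test; Welch is
the robust default), with a Wilcoxon rank-sum alternative behind
`method = "wilcoxon"`. The unit of analysis is the pooled per-bond
distance within each class by default; per-ligand means can be supplied
instead — the source does not state which pooling it used, and the
reported p-values cannot be reproduced exactly without the original
minimized complexes.

The activity layer stores IC50s in nM ("nd" cells are absent values,
never zeros — compounds that failed the 100 nM PDE4B1 screen were not
advanced), converts to molar inside `pic50()`, and reproduces the
printed best-in-series potencies, selectivity ratios, the inclusive
≤ 100 nM potency filter, and the ferret maximal-not-emetic-dose folds
(3a: 2.7/0.3 = 9.0×; 3k: 1.1/0.3 ≈ 3.7×, both inside the printed
3–10× band).

## The synthetic world

The original complexes cannot be rebuilt at desk scale — they require a
docking search against the 1.75 Å crystal structure and a force-field
minimization, both out of scope. The generator therefore emulates the
**statistical structure** of the reported results, not the pocket's
crystallographic geometry, and the acceptance surface is statistical
recovery.

`build_toy_pocket()` constructs an abstract catalytic site: five
protein residues including a glutamine-like probe numbered 443, 14
waters (residues 1–14), one Zn and one Mg ion near waters 1 and 13, and
a small ligand whose acetyl carbonyl oxygen (`OAC`) is its only polar
atom. The resting pocket is "quiet" — zero hydrogen bonds — so every
bond in a simulated pose is a planted one, and planted counts and
distances are recovered *exactly* by the survey (a closure property the
tests assert).

`simulate_class_dataset()` gives each synthetic ligand 100 poses in
which:

* ligand–water bonds are planted at a **Poisson** count per pose at the
  class rate (defaults **1.47** bonds/pose for class A, **2.13** for
  class I), with **truncated-normal** H···A distances at the class mean
  (defaults **2.64 Å** vs **2.18 Å**, sd **0.2 Å**, window 1.6–3.45 Å);
* a glutamine-amide bond is planted as a **Bernoulli** event at the
  class rate (defaults **0.8** vs **0.6**) and class distance
  (**2.77 Å** vs **2.81 Å**).

The rate and mean defaults are the printed class statistics of the
emulated study; the distributional forms and the 0.2 Å spread are
generator choices (the source prints means only) and stay configurable.
Two truncations are deliberate: distances are drawn inside
(1.6, 3.45) Å so every planted bond is detectable, and at most 7 water
bonds are planted simultaneously so the planting rays stay ≥ 46° apart
and covalent typing can never cross-assign a hydrogen
(P(Poisson(2.13) > 7) ≈ 1.3 × 10⁻³, a < 0.004 shift of the mean).
Gln-bond counts are Bernoulli rather than truncated Poisson because the
construction plants at most one amide bond per pose and Bernoulli
preserves the configured mean exactly.

What a green test establishes: the pipeline *recovers what was
planted* — detection equals an exhaustive oracle, configured class
means come back within 3 standard errors, the class-equality null is
rejected with ≥ 90% power at the default effect size, and a planted
null rejects at ≈ 5%. What it does not establish: anything about real
PDE4 pockets — pose diversity, competing interactions, protonation,
crystallographic water networks. The printed headline statistics enter
as the generator's *inputs*, so recovering them is a consistency check
of the pipeline, not a reproduction of the docking study.

Monte-Carlo power (100 replicates) and size (1000 replicates) run at
the statistical level (`simulate_class_statistics()` draws from the
same Poisson/truncated-normal laws without building structures);
building ~10⁵ pockets would add hours and no coverage. The full
geometric pipeline runs once at full 8+8 × 100 scale.

## Structure I/O choices

Minimized complexes arrive as fixed-column PDB (single complexes, or
MODEL/ENDMDL ensembles with a `model  energy_kcal_mol` sidecar TSV) —
no structure format is mandated by the emulated workflow, and docking
outputs convert trivially to PDB. Covalent bonds are inferred by
distance (H to nearest heavy atom within 1.2 Å, 1.5 Å for S;
heavy–heavy within the covalent-radii sum + 0.4 Å) because CONECT
records are unreliable in minimization outputs; metal ions are excluded
from the heavy–heavy rule since their ~2 Å coordination contacts are
not covalent. Waters are recognised by residue name (HOH/SOL/WAT — the
"SOL" numbering of site waters is a simulation-package convention),
ions as single-atom residues of common elements, remaining HETATM
records as ligand, remaining ATOM records as protein. Occupancy and
B-factor are ignored on read and written as 1.00/0.00; residue numbers
are preserved verbatim. Structures must arrive with explicit hydrogens;
whether ligand carboxylates carry acidic protons is decided by whatever
hydrogens the input contains.

## Degenerate inputs and determinism

Identical constant samples in both classes return statistic 0, p = 1
(Welch's test is undefined there, but "no difference" is well-defined).
Ensembles of one pose cluster trivially; a complex without hydrogens
yields a warning and an empty survey rather than an error. All
generators are deterministic given a seed, restore the caller's RNG
state, and re-running a pipeline configuration reproduces its TSV
outputs byte-for-byte; every output names the configuration hash and
seed in a header comment.

## Known limitations

* No symmetry-corrected RMSD; automorphic ligands would need it.
* No energetic H-bond scoring, π–π or hydrophobic contact detection,
  or salt-bridge classification.
* The published per-class p-values (p < 0.007 with waters) are not
  reproducible without the original minimized complexes; the test
  identity and pooling level are assumptions, stated above.
* mmCIF, bond-order perception and protonation assignment are
  out of scope.
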