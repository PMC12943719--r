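# dockhb

Post-docking hydrogen-bond and pose-cluster analysis for protein–ligand
complexes, built around the question that separates potent from weak
PDE4B1 (phosphodiesterase-4, subtype B1) inhibitors: **how does the
ligand's acetyl oxygen share itself between the catalytic-site waters
and the Gln443 side-chain amide?**

Low-active inhibitors of this family bind the fourteen ordered
catalytic-site waters — especially waters 1 and 13, coordinated by the
Zn and Mg ions — with short, strong hydrogen bonds; active inhibitors
instead engage the glutamine amide. `dockhb` turns that analysis into a
tested pipeline for anyone with minimized docking poses:

* **Structure I/O** — fixed-column PDB reader/writer (single complexes
  and MODEL/ENDMDL pose ensembles with a sidecar energy TSV), atom-role
  partition (ligand / protein / water / ion), distance-based covalent
  inference, donor/acceptor typing.
* **Hydrogen-bond survey** — the geometric criterion
  *d*(H···A) < 3.5 Å with 120° ≤ ∠D–H···A ≤ 170°, in both directions
  (ligand donates / accepts), with or without waters ("vacuum" mode),
  plus a focused survey of one ligand atom against named partners
  (default: acetyl O vs Gln443 and waters 1/13). Per-ligand summary:
  bonds/pose and mean H···A distance.
* **Pose clustering** — no-superposition heavy-atom RMSD, greedy
  energy-seeded clusters within 5 Å, lowest-energy clusters covering
  ≥ 70 % of poses.
* **Activity/SAR table** — the study's printed IC50 / HARBS / TNFα /
  CaCo-2 / MNED values as a typed TSV, with pIC50, selectivity ratios,
  the ≤ 100 nM potency screen, MNED folds, and the 8-active /
  8-low-active modeling classes.
* **Class statistics** — Welch's t-test (Wilcoxon optional) comparing
  pooled bond distances or counts between classes.
* **Synthetic complexes** — a deterministic toy pocket (Gln443 probe,
  14 waters, Zn/Mg, acetyl-bearing ligand), exact hydrogen-bond
  planting, pose ensembles with planted cluster structure, and a
  two-class dataset generator whose defaults are the published class
  statistics (2.64 / 2.18 Å water-bond distances, 1.47 / 2.13
  bonds/pose, Gln rates 0.8 / 0.6) — so the whole pipeline is testable
  offline.

## Worked example

Simulate the two-class world at its published defaults, run the full
pipeline (cluster → survey → summarize → compare), and look at the
class contrast:

```r
library(dockhb)

ds  <- simulate_class_dataset(class_geometry_model(),
                              n_ligands_per_class = 8, seed = 1)
res <- run_pipeline(run_config(dataset = ds, seed = 1))

res$comparisons$water_distance
#> <dockhb_comparison> water_h_a_distance_A: mean A 2.642 vs mean I 2.189
#>   (n=1269/1691), welch p = <2e-16 *

head(subset(res$tables$summary, mode == "with_water"), 4)
#>   ligand_id       mode n_poses bonds_per_pose mean_distance_A
#> 2       A01 with_water     100           2.36           2.689
#> 4       A02 with_water     100           2.42           2.672
#> 6       A03 with_water     100           2.42           2.672
#> 8       A04 with_water     100           2.37           2.686
#>   focus_bonds_per_pose focus_mean_distance_A
#> 2                 1.02                 2.746
#> 4                 0.99                 2.736
#> 6                 1.08                 2.725
#> 8                 1.02                 2.758
```

The class-A ligands recover the configured water-bond distance
(2.64 Å) and the low-active class its shorter 2.18 Å, and the Welch
test separates them decisively — the pipeline end-to-end recovers the
statistical structure it was fed. `focus_bonds_per_pose` counts only
acetyl-O bonds to Gln443 and waters 1/13.

The SAR layer reproduces printed numbers directly:

```r
act <- load_activity_table()
series_extreme(act, "3", "pde4b1_nM", "min")
#> $compound_id
#> [1] "3f"
#> $value
#> [1] 0.36                      # nM, the printed best-in-series potency

pic50(act$pde4b1_nM[act$compound_id == "2f"])
#> [1] 9.1367                    # -log10(0.73 nM in molar)
```

## Command line

```sh
Rscript inst/cli/dockhb.R simulate --seed 0 --out-dir poses/
Rscript inst/cli/dockhb.R cluster  --poses poses/A01_poses.pdb \
                                   --energies poses/A01_energies.tsv
Rscript inst/cli/dockhb.R survey   --pdb complex.pdb --mode vacuum
Rscript inst/cli/dockhb.R sar
Rscript inst/cli/dockhb.R run      --seed 0 --out-dir report/
```

`run` writes the report bundle (`summary.tsv`, `bonds.tsv`,
`clusters.tsv`, `comparison.tsv`, `run.log`), each file headed by the
configuration hash and seed; re-running an identical configuration is
byte-identical.

## Documentation

The methods vignette (`vignettes/dockhb-methods.Rmd`) explains the
model and its assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, the
numerical choices (boundary guards, tie-breaks, degenerate inputs) and
known limitations.
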