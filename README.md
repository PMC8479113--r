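# hexadyn

Comparative dynamics analysis of hexameric protein trajectories in R.

Oxygen-transport metalloproteins such as arthropod hemocyanin function as
homo-hexamers — two stacked trimeric rings ("dimer-of-trimers") around a
central channel, with a buried binuclear copper site per subunit
coordinated by six histidines. Their deoxygenated (open) and oxygenated
(closed) conformations are nearly indistinguishable as static structures;
the difference lives in the dynamics: collective ring motions, buried
interface area, solvent cavities, and the tunnels oxygen uses to reach the
metal sites. `hexadyn` implements the full comparative trajectory-analysis
sequence needed to tell two such states apart, plus a seeded synthetic
hexamer generator and analytic toy geometries that make every stage
testable against ground truth.

## What it computes

| Stage | Key functions | Statistic |
|---|---|---|
| Superposition & drift | `kabsch_superpose()`, `conventional_rmsd()`, `core_align()` | RMSD; robust core RMSD aligning the fraction φ of atoms with the smallest displacements |
| Mobility & compactness | `rmsf()`, `radius_of_gyration()` | RMSF_i = √⟨\|r_i − ⟨r_i⟩\|²⟩; Rg(t) |
| Correlated motions | `compute_dccm()`, `dccm_block_summary()` | σ_ij = ⟨Δr_i·Δr_j⟩ / √(⟨\|Δr_i\|²⟩⟨\|Δr_j\|²⟩) |
| Essential dynamics | `fit_pca()`, `compare_subspaces()`, `porcupine()` | eigenmodes; RMSIP = √(Σᵢⱼ(vᵢ·wⱼ)²/k), reported as subspace overlap % |
| Surface & interface | `sasa()`, `iasa()`, `sasa_series()` | Shrake–Rupley ASA; IASA = ASA_A + ASA_B − ASA_AB |
| Solvent cavities | `detect_pockets()`, `pocket_volume_series()` | per-voxel opening frequency; per-frame and cumulative pocket volume |
| Tunnels | `find_tunnels()`, `cluster_tunnels()`, `lining_residues()` | clearance profile r(l); bottleneck = min r(l); cost = ∫ r(l)⁻² dl; throughput = e^(−cost) |
| Latent-state separation | `build_dataset()`, `train_cvae()`, `scan_latent_dims()`, `embed_frames()` | convolutional VAE over 36×36 site distance matrices; silhouette of states in latent space |
| Orchestration | `pipeline_config()`, `run_pipeline()`, `make_fixtures()` | end-to-end two-state comparison report |

Trajectories are multi-model PDB (read/written via `bio3d`); a seeded
generator (`generate_hexamer_trajectory()`) produces pseudo-hexamers with
planted "deoxy" (counter-rotating rings, open packing) and "oxy"
(clam-shell, closed packing) modes over Gaussian thermal noise, and
`generate_toy_geometry()` builds spheres, shells, channels and hourglasses
whose areas, volumes and tunnel scores are known in closed form.

## Worked example

```r
library(hexadyn)

tr_open   <- generate_hexamer_trajectory(hexamer_state_spec("deoxy", n_frames = 40, seed = 1))
tr_closed <- generate_hexamer_trajectory(hexamer_state_spec("oxy",   n_frames = 40, seed = 2))
tr_open
#> <hxd_trajectory> 40 frames, 408 atoms, 6 chains

cas <- atom_select(tr_open, name = "CA")
core_align(tr_open, fraction = 0.7, atoms = cas)
#> <hxd_core_align> fraction 0.70 (252 core atoms), 4 iteration(s)
#>   mean core RMSD 0.783 A, mean non-core RMSD 1.138 A

compare_subspaces(fit_pca(tr_open, atoms = cas),
                  fit_pca(tr_closed, atoms = cas), k = 10)
#> <hxd_subspace> k = 10; RMSIP 0.102 (subspace overlap 10.2%), average max dot 0.06

ia <- iasa(tr_open,   c("A","B","C"), c("D","E","F"), n_points = 240, frames = c(1, 20))
ic <- iasa(tr_closed, c("A","B","C"), c("D","E","F"), n_points = 240, frames = c(1, 20))
c(iasa_open = mean(ia$iasa), iasa_closed = mean(ic$iasa))
#>   iasa_open iasa_closed
#>        86.3       749.2

detect_pockets(tr_open, spacing = 0.8,
               grid_bounds = cbind(c(-6,-6,-11), c(6,6,11)), frames = c(1, 20, 40))
#> <hxd_pocket_grid> 15 x 15 x 28 at 0.80 A; mean volume 426.2 A^3, cumulative 585.2 A^3 over 3 frames

tn <- find_tunnels(tr_open, c(0, 0, 0), spacing = 0.8,
                   grid_bounds = cbind(c(-8.4,-8.4,-13), c(8.4,8.4,13)), frames = 1)
tunnel_summary(cluster_tunnels(tn))
#>   cluster n_members n_snapshots avg_bottleneck max_bottleneck avg_throughput
#> 1       1         2           1       2.374316       2.422453      0.3178408
```

Reading these numbers: the two planted modes share almost no essential
subspace (overlap ~10% at k = 10, against ~24% expected for unrelated
random subspaces of this size — the states move differently, not just
noisily). The open state buries an order of magnitude less inter-ring
interface than the closed state (86 vs 749 Å²), its axial pore carries
~430 Å³ of detected cavity per frame, and the pore admits a tunnel with a
2.4 Å bottleneck — all three effects in the direction that distinguishes
an open, oxygen-ready conformation from a sealed, oxygenated one. On the
same data the autoencoder separates the two states in latent space with a
silhouette near 0.9 while label-shuffled controls stay near 0.

The methods vignette (`vignettes/hexamer-dynamics.Rmd`) documents the
model behind each stage, the defaults and their units, and what the
synthetic generator does and does not emulate.

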