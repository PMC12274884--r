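# dendronet

Comparative analysis of cortical micro-architecture for mouse and human
layer 2/3, as a tested R pipeline. The puzzle it addresses: human temporal
cortex holds ~25,700 neurons/mm³ against ~137,600/mm³ in mouse, yet human
pyramidal-cell networks are reported to form *richer* high-order
connectivity. `dendronet` implements every quantitative step needed to study
that claim — dendritic topology, anatomy-derived spatial statistics, model
circuit construction with potential-synapse (apposition) connectivity,
directed-clique network statistics, and dendritic memory capacity — with a
seeded synthetic-morphology generator so the whole pipeline runs end-to-end
without any external reconstructions. It is aimed at computational
neuroanatomists and network neuroscientists who want the individual methods
as reusable, tested functions.

## What it computes

* **Topological morphology descriptor.** A neurite tree with filtration
  `f` (radial or path distance from the soma) maps to a persistence barcode
  `PB = {(bᵢ, tᵢ)}` by the elder rule, one bar per leaf
  (`extract_barcode`). Vectorizations: persistence images (sums of Gaussian
  kernels on the diagram; `persistence_image`) and the scale-invariant
  topological entropy `E = −Σ (lᵢ/L)·log(lᵢ/L)` of normalized bar lengths
  (`barcode_entropy`). Population scaling transforms
  `(α·bᵢ, α·tᵢ)` / `(α·bᵢ, β·tᵢ)` are fitted by minimizing population
  image distance (`fit_scaling`), and diagrams are summarized by
  3-component Gaussian mixtures (`fit_diagram_mixture`).
* **Anatomy.** Mean nearest-neighbour distance `⟨R⟩ = 0.554·N_v^(−1/3)`
  closed-form and by 100-instance uniform point-process simulation
  (`nn_distance_formula`, `nn_distance_simulated`); neuropil length density
  `d_dend = S_v / d_syn`; clipped-sphere neighbour-count expectations. All
  species parameters ship in a versioned JSON registry (`species_params`).
* **Circuits.** Hexagonal-column placement (side 476 µm, 7-column tiling,
  central-column analysis), morphology cloning with rotation and jitter,
  and axo-dendritic apposition detection at a 2 µm segment-to-segment
  threshold, with a spatial hash proven identical to brute force
  (`build_circuit`, `assign_morphologies`, `compute_appositions`,
  `build_hybrid_circuit`).
* **Networks.** Random pruning to the 4% density implied by printed synapse
  counts (3,750 expected in-degree), subnetwork densities and in-degrees,
  exact directed simplex counting (a directed k-simplex = k+1 all-to-all
  connected cells with one source, one sink), and Erdős–Rényi /
  Watts–Strogatz null models (`prune_to_density`,
  `count_directed_simplices`, `erdos_renyi_directed`,
  `watts_strogatz_directed`).
* **Capacity & statistics.** Linear and non-linear dendritic memory
  capacity `C_L = 2·log₂ C(s+d−1, s)`,
  `C_N = 2·log₂ C(C(k+d−1, k)+m−1, m)`; capacity–complexity rank
  correlation; Kolmogorov–Smirnov comparisons; within- vs between-subject
  barcode variability (`memory_capacity_nonlinear`,
  `capacity_complexity_correlation`, `ks_compare`, `group_variability`).
* **Synthetic cohorts.** Species presets encode the published branch
  statistics (human apical 54 ± 21 bars vs mouse 36 ± 11, total dendritic
  length ~12 mm vs ~6 mm, and the human-specific 200–500 µm perisomatic
  branch-density excess); barcodes sampled from the preset mixtures are
  realized as 3D trees whose path-distance barcodes match exactly
  (`default_preset`, `sample_barcode`, `synthesize_tree`,
  `generate_population`).

## Worked example

```r
library(dendronet)

h <- species_params("human"); m <- species_params("mouse")
nn_h <- nn_distance_simulated(h$neuron_density,
                              c(1000, 1000, h$layer_thickness), 100, seed = 1)
nn_m <- nn_distance_simulated(m$neuron_density,
                              c(1000, 1000, m$layer_thickness), 100, seed = 1)

human <- generate_population(default_preset("human", "PC"), 10, seed = 1)
mouse <- generate_population(default_preset("mouse", "PC"), 10, seed = 2)
profile_h <- complexity_profile(lapply(human, neuron_barcode, "path"),
                                seq(0, 1000, 100))
profile_m <- complexity_profile(lapply(mouse, neuron_barcode, "path"),
                                seq(0, 1000, 100))
```

Output (one CPU, ~20 s):

```
NN distance, all neurons: human 19.0 um (formula 18.8), mouse 10.9 um (formula 10.7)
neuropil density: human 1341 m/mm3, mouse 1235 m/mm3
dendritic entropy: human-like 4.43 +/- 0.23, mouse-like 4.13 +/- 0.27
bars alive 200-500 um, human-like: 52 52.5 33.2
bars alive 200-500 um, mouse-like: 26.4 6 0.8
```

Reading: despite nearly twice the inter-neuronal distance, the human-like
cohort keeps the same cable length per tissue volume by growing longer,
more entropic dendrites, and concentrates its extra branches 200–500 µm
from the soma — the signature the circuit-level analyses build on. The
end-to-end circuit comparison is one call:

```r
pipe <- desk_pipeline(n_total = 750, seed = 1)
pipe$human$pc_simplices   # 525 13184 24998 4235 58
pipe$er_control$simplices # 525 13280 16129 901  (density-matched ER)
```

The structured human-like column forms ~4.7× the ER count of dimension-3
simplices and reaches dimension 4, which the matched random control at the
same density barely does. See the methods vignette
(`vignettes/dendritic-architecture.Rmd`) for model details, parameter
rationale, and the documented limits of the desk-scale synthetic system.

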