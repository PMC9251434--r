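# corelandscape

Conformational landscapes, rigid-body modes, pore geometry and peptide
release kinetics of barrel-shaped protein assemblies, analysed from
coarse-grained particle ensembles.

Cryo-EM datasets of large machines like the 26S proteasome are
populations: each particle is a snapshot of one conformation. Once
per-particle conformational coordinates exist, three quantitative
questions follow, and this package answers each with tested, reusable
code:

1. **Which rigid-body motions, and how large?** Ensembles are superposed
   on an anchor group (Kabsch least squares), decomposed by PCA, and
   individual group motions are expressed as screw motions — rotation
   angle, axis, pivot, translation, maximum displacement — and
   classified (rotation / tilt / compression / translation / mixed).
2. **How is the population distributed?** Particle counts over two mode
   coordinates are Boltzmann-inverted, `ΔG_i = -k_BT ln(N_i / N_max)`,
   into a free-energy landscape; basins are found by watershed with
   persistence merging, state fractions by assignment, and barriers as
   the minimax saddle — over all 8-connected paths between two basins,
   the minimum of the path-maximum energy above the starting minimum.
3. **Can products escape through wall pores?** A probe-inflated
   occupancy grid yields the wall channels; each is measured
   (constriction `d_min`/`d_max` via percolation bottleneck plus exact
   refinement), characterised (formal charge, Kyte–Doolittle
   hydropathy), and filtered by the strict `d_min > 7 Å` release
   threshold. A hindered-diffusion model,
   `τ_pore = L² · x² / (2D)`, compares pore transit with the
   product-generation time `L / v`.

Because deposited maps cannot be re-processed at desk scale, the package
ships a first-class synthetic-ensemble generator: a sevenfold-symmetric
closed barrel with a configurable annular gate and drilled elliptical
wall pores whose free axes are exact by construction, a four-mode
catalogue (lid rotation 0–35°, lid tilt 4–10°, core compression 0–12 Å,
RPN1 swing 1–25 Å), and a two-basin free-energy surface with exact
ground-truth state masses (58% resting / 35% rotated / 7% compressed)
and calibrated 5.6 k_BT saddles. Every analysis is validated as
parameter recovery against this constructed truth.

## Worked example

```r
library(corelandscape)

res <- run_pipeline(default_config(n = 1e5, seed = 20220311), "out")
print(res$summary, n = 14)
#> # A tibble: 14 × 2
#>    quantity                            value
#>    <chr>                               <dbl>
#>  1 resting_fraction                   0.577
#>  2 rotated_fraction                   0.352
#>  3 compressed_fraction                0.0704
#>  4 barrier_resting_to_rotated_kT      5.38
#>  5 barrier_resting_to_compressed_kT   5.80
#>  6 lid_rotation_deg                  35
#>  7 compression_A                     12
#>  8 rpn1_swing_max_A                  25
#>  9 gate_diameter_A                   14
#> 10 n_pores                            4
#> 11 n_releasing_pores                  3
#> 12 tau_free_ns                      167.
#> 13 tau_pore_us                       16.7
#> 14 orders_of_magnitude                4
```

Reading the output: of 100,000 particles sampled from the default
surface, 57.7% land in the resting basin, 35.2% in the rotated basin and
7.0% in the compressed basin (ground truth 58/35/7), and the recovered
barriers bracket the constructed 5.6 k_BT saddle. The three mode
endpoints are recovered exactly (35° lid rotation, 12 Å compression,
25 Å RPN1 swing), the 14 Å gate is measured at 14 Å, and of the four
drilled wall pores the three wider than 7 Å count as release-capable. A
10-residue product crosses a 1 nm pore in 16.7 µs, four orders of
magnitude faster than the 0.25 s the machine needs to produce it —
passive pore release is kinetically sufficient if the pores are inert.

`out/` then contains the conformer ensemble (`ensemble.pdb`,
`particles.tsv`), per-stage tables (`landscape.tsv`,
`state_fractions.tsv`, `barriers.tsv`, `pores.tsv`,
`mode_descriptors.tsv`, `projections.tsv`, `kinetics.tsv`), a YAML config
echo, a log, and the `summary.tsv` shown above. Individual stages are
ordinary pipeable functions:

```r
surface   <- two_basin_surface()
particles <- sample_particles(surface, 1e5, seed = 1)
grid <- particles |>
  bin_particles(c(30, 30)) |>
  boltzmann_invert() |>
  find_basins()
autoplot(grid)                      # energy heatmap, k_BT
state_fractions(assign_states(particles, grid))
```

See `vignettes/conformational-landscape.Rmd` for the model, the
numerical choices, and what the synthetic generator does and does not
emulate.

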