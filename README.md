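# dorsalcode

Quantification of multiplex FISH neuropeptide expression in the spinal
dorsal horn, as an R package.

Excitatory interneurons of the dorsal horn are patterned by a
"neuropeptide code": a small set of neuropeptide genes (Tac1, Tac2,
Grp, Nmu, Nts, Cck, Trh, Ucn3, Npff, ...) with largely non-overlapping,
lamina-specific expression. Measuring that code from multiplex RNAscope
images is a counting problem with several coupled stages, and this
package implements the full chain:

* **Segmentation** — nuclei as primary objects (Otsu threshold ×
  correction factor, clipped to bounds; distance-transform watershed
  declumping; diameter filters), expanded into somata by
  nearest-nucleus Euclidean growth (`detect_nuclei()`,
  `expand_to_soma()`, `filter_objects()`).
* **Spot quantification** — per-channel Laplacian-of-Gaussian dot
  detection with non-maximum suppression, spot-to-cell assignment by
  label lookup, and integer dots-per-cell tables (`detect_spots()`,
  `relate_spots_to_cells()`, `dots_per_cell()`).
* **Positivity calling** — per-channel background thresholds as the
  nearest-rank 90th percentile of dots/cell in a matched
  negative-control section; a cell is *positive* strictly above that
  threshold and *high* strictly above 20 dots/cell
  (`background_threshold()`, `call_positive()`).
* **Co-expression** — triple-probe Venn counts pooled per animal, and
  pairwise matrices `F[g,h] = 100 · N_gh / N_g` computed per animal and
  averaged unweighted across animals (`venn_counts()`,
  `pairwise_matrix()`, `per_animal_average()`).
* **Laminar mapping** — landmark-based least-squares affine alignment
  to a lamina template, point-in-polygon lamina assignment
  (dorsal-most wins on boundaries), per-hemisection counts
  (`fit_alignment()`, `assign_lamina()`, `lamina_counts()`).
* **Translatome filtering** — reads-per-kilobase-per-million
  normalisation, expressed-gene screens (> 10 and > 100 normalised
  counts), enrichment filtering (FDR ≤ 0.05, fold ≥ 2) and congruence
  between two screens (`normalize_counts()`, `count_expressed()`,
  `de_filter()`, `congruence()`).
* **Synthetic tissue** — a dorsal-horn simulator with exhaustive ground
  truth: nuclei placed in laminar bands, per-cell dot counts drawn from
  a configurable population mixture (the generative co-expression
  model), Poisson background dots, rendered multi-channel images and
  matched negative controls (`simulation_config()`,
  `generate_tissue()`, `generate_negative_control()`,
  `simulate_combination()`, `expected_coexpression()`).

Everything operates on plain data structures (matrices, data frames)
and standard text formats: multi-page TIFF with JSON sidecars, GeoJSON
templates and landmarks, CSV tables, YAML configs.

## Worked example

Simulate a three-probe study (3 animals × 2 hemisections, 260 cells per
hemisection, 0.5 background dots per cell) with a mixture in which a
superficial Tac2 population partially co-expresses Nmu and a deeper
population expresses Nts, then quantify it:

```r
library(dorsalcode)

pops <- list(
  population_spec("Tac2_Nmu", weight = 0.4,
                  expr_prob = c(Tac2 = 0.95, Nmu = 0.70, Nts = 0.05),
                  dot_mean = 60, dot_dispersion = 0.125,
                  lamina_weights = c(I = 0.2, II = 0.7, III = 0.1)),
  population_spec("Nts_deep", weight = 0.3,
                  expr_prob = c(Tac2 = 0.05, Nmu = 0.05, Nts = 0.9),
                  dot_mean = 60, dot_dispersion = 0.125,
                  lamina_weights = c(III = 0.6, IV = 0.4)),
  population_spec("other", weight = 0.3,
                  expr_prob = c(Tac2 = 0.05, Nmu = 0.02, Nts = 0.1),
                  dot_mean = 60, dot_dispersion = 0.125,
                  lamina_weights = c(III = 0.2, IV = 0.4, V = 0.4)))
cfg <- simulation_config(populations = pops, n_cells = 260,
                         nucleus_radius_mean = 3, nucleus_radius_sd = 0.5,
                         background_dot_rate = 0.5, n_animals = 3,
                         hemisections_per_animal = 2, seed = 1)
study <- simulate_combination(cfg, seed = 2024)

thresholds <- background_threshold(study$negctrl, percentile = 90)
thresholds
#>   gene threshold percentile n_cells
#> 1 Tac2         1         90     260
#> 2  Nmu         1         90     260
#> 3  Nts         2         90     260

calls <- call_positive(study$cells, thresholds, high_threshold = 20)
venn  <- venn_counts(calls, c("Tac2", "Nmu", "Nts"), level = "high")
head(venn[venn$animal == 1, ], 8)
#>    animal       region count
#> 1       1         Tac2    65
#> 4       1          Nmu    12
#> 7       1          Nts   149
#> 10      1     Tac2&Nmu   130
#> 13      1     Tac2&Nts     8
#> 16      1      Nmu&Nts     7
#> 19      1 Tac2&Nmu&Nts     9
#> 22      1         none   140

pairwise_matrix(list(calls), level = "high")
#> coexpression_matrix (level = high , 3 animals): % of row-gene cells also expressing the column gene
#>       Tac2   Nmu   Nts
#> Tac2 100.0  66.6   8.5
#> Nmu   88.3 100.0   9.8
#> Nts   10.8   9.3 100.0

calls <- assign_lamina(calls, cfg$template)
lamina_summary(lamina_counts(calls, "Nts", level = "high"))
#>   gene  lamina      mean        sd n
#> 1  Nts       I  0.500000 0.5477226 6
#> 2  Nts      II  4.166667 1.9407902 6
#> 3  Nts     III 44.500000 7.4766303 6
#> 4  Nts      IV 30.000000 6.5421709 6
#> 5  Nts       V  3.166667 1.3291601 6
#> 6  Nts outside  0.000000 0.0000000 6
```

Reading the output: the negative-control calibration puts the
positivity threshold at 1–2 dots/cell; at the stringent (> 20
dots/cell) level most Nmu-high cells are also Tac2-high (88 %) while
only 67 % of Tac2-high cells are Nmu-high — a nested-subpopulation
signature — and Nts-high cells sit almost entirely in laminae III–IV,
about 45 and 30 cells per hemisection respectively. All three readouts
recover the structure that was planted in the generative mixture.

The full imaging path (rendered images rather than simulated tables)
is exercised the same way: `generate_tissue()` returns a multi-channel
`image_stack` plus ground truth, `detect_nuclei()` /
`expand_to_soma()` / `detect_spots()` take it from pixels to
dots-per-cell. See the methods vignette
(`vignettes/dorsalcode-methods.Rmd`) for the model behind each stage,
parameter meanings and defaults, and the simulator's assumptions.

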