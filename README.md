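# spharmcell

Static and dynamic spherical-harmonic (SPHARM) classification of 3D
cell-migration shape patterns.

Migrating cells change shape continuously, and two populations can be
indistinguishable in any single snapshot while moving in recognisably
different ways — for example when every cell cycles through the same shape
phases but populations cycle at different speeds. `spharmcell` is for
researchers who want to test, in an objective and statistically controlled
way, whether an experimental condition or a model parameter changes 3D
cell shape *or its dynamics*: it quantifies each cell as a rotation-
invariant spherical-harmonic descriptor, extends the descriptor along
time, and asks a cross-validated classifier whether two conditions can be
told apart better than a naive control.

## The method in brief

A cell surface at one time point, re-centred at its centroid, is a radial
function on the sphere, sampled on an N×N equiangular grid and expanded in
complex spherical harmonics (exact for band-limited shapes; a
Driscoll–Healy-type sampling theorem). The per-degree power

    F(l) = sum over m of |A(l, m)|^2,   l = 0 .. l_max - 1

is invariant under 3D rotation of the cell and is the **static** shape
descriptor. Stacking the first T frames gives the **dynamic time map**
F(l, t); its per-degree DFT magnitudes along t give the **dynamic
frequency map** F(l, f). Each feature kind feeds a linear-kernel SVM,
evaluated over 150 rounds of stratified shuffle-split (or held-out-series
group-shuffle) cross-validation, and the resulting accuracy distribution
is compared to a naive control — a label-shuffle random classifier for
balanced data, the majority classifier for unbalanced data — with a
one-sided Mann–Whitney test.

The package also ships its own synthetic data source: a lattice
Monte-Carlo cell-migration simulator in which a cell of ~1000 spatial
units (SU) migrates by moving one SU per iteration from its rear surface
to a free front site, with acceptance-rejection sampling on the scores

    S_r = |P|^PW * (6 - N)^NW * D^DW      (rear removal)
    S_f = |P|^PW * N^NW                   (front insertion)

where P is the SU's position along the migration axis, N its occupied
6-neighbour count and D its distance to the centre of mass. The exponents
control elongation (PW), surface roughness (NW) and protrusion size (DW);
the threshold FR sets the front/rear split.

## Worked example

Classify cells generated with two values of the position-weight exponent
(PW = 1: round cells; PW = 4: elongated cells), at reduced problem sizes
so the example runs in about a minute:

```r
library(spharmcell)

cfg <- experiment_config(
  "pw", values = c(1, 4), n_cells_per_class = 12,
  base_params = cms_params(radius_su = 5, n_iterations = 5000,
                           save_interval = 500, start_iteration = 0),
  l_max = 8, n_time = 10, grid_size = 60,
  cv = cv_config("shuffle", n_rounds = 50, n_train_per_class = 8,
                 n_test_per_class = 4, seed = 7),
  seed = 7)
report <- run_experiment(cfg)
report
```

```
Classification report (pw = 1/4, 12 cells/class, scheme shuffle)

       pair feature_kind mean_accuracy mean_control p_vs_control sig_vs_control
 pw1 vs pw4       static         0.877        0.510       <2e-16            ***
 pw1 vs pw4         time         0.965        0.580       <2e-16            ***
 pw1 vs pw4    frequency         0.988        0.490       <2e-16            ***
```

Reading the table: a static snapshot already separates the two parameter
values well above the label-shuffle control (mean accuracy 0.877 vs 0.510,
`***` = p < 0.001), and the dynamic descriptors — which see how the shape
evolves over the first 10 frames — push the accuracy higher still. The
full report object carries the per-round accuracies, the control samples
and the dynamic-vs-static p-values; `write_report()` exports the table as
CSV.

The converse demonstration — conditions that a snapshot *cannot*
distinguish — uses the built-in oscillating-ellipsoid fixtures
(`make_oscillating_dataset()`): two classes of cells traverse identical
shape sets at different frequencies, static accuracy stays at chance, and
the frequency-map classifier separates them essentially perfectly (see
the methods vignette, `vignettes/spharmcell-methods.Rmd`).

A thin command-line front end over the same functions is installed at
`inst/scripts/spharmcell` (subcommands `simulate`, `make-oscillating`,
`classify`, `pipeline`).

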