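# matrixflock

Agent-based simulation of how fibroblasts pattern the extracellular matrix
(ECM) — and are patterned by it. Tissues show strikingly different collagen
topologies (aligned stomach, corralled liver, swirled dermis, strand-like
spleen), and the question the package addresses is how such mesoscale
diversity can emerge from simple local rules of cell migration and fiber
turnover. It is aimed at computational biologists and biophysicists studying
collective cell behaviour, matrix remodeling in fibrosis/cancer, and
quantitative matrix phenotyping.

## The model

A two-layer nematic flocking (Vicsek-type) model:

* **Cell layer.** Cells are self-propelled four-bead agents (3:1 aspect
  ratio) with heading θᵢ and constant speed sᵢ. Per step the heading becomes
  the angle of

  ```
  X = [ w_p cos(θᵢ + η) + w_c X_c + w_m X_m ] / (w_p + w_c + w_m)
  Y = [ w_p sin(θᵢ + η) + w_c Y_c + w_m Y_m ] / (w_p + w_c + w_m)
  ```

  with w_p = 1 − w_c − w_m, η ~ N(0, Var(η)) the individual migratory
  noise, (X_c, Y_c) the mean nematic direction of contacting cells, and
  (X_m, Y_m) the nematic direction of a fiber bin under the head, chosen by
  a Gillespie draw proportional to fiber counts. Alignment is *nematic*:
  neighbours and fibers are apolar, so an antiparallel neighbour reinforces
  alignment. Absent terms have their weight zeroed; the sum is renormalised.
  Movement is slowed to v_e = 0.25 of the speed while the head bead overlaps
  another cell (volume exclusion).

* **Matrix layer.** Each grid point holds fiber counts in 8 apolar
  orientation bins of width π/8. The grid point under a cell's head gains
  `deposition_rate` fibers in the heading bin, loses `degradation_rate` from
  every bin, and pulls up to `rearrangement_rate` fibers from each
  neighbouring bin into the heading bin. Optionally the matrix feedback
  weight is scaled by the density response f(d), linear with f(5) = 0 and
  f(10) = 1, so sparse matrix exerts no guidance.

Five matrix-topology metrics quantify the result: long- and short-range
alignment (LRA/SRA, 1 = aligned, 0.5 = isotropic), percentage of
high-density matrix (HDM), skeleton curvature (degrees per 10-px chord) and
box-counting fractal dimension (Frac). They apply to simulated grids and to
grayscale images. A fixture generator provides patterns with analytically
known metric values, and analysis helpers cover migration persistence,
parameter sweeps with PCA, persistence-based calibration of Var(η) and w_m,
and a two-phase matrix-interconversion experiment.

## Worked example

Low-noise cells with modest cell-cell guidance, with and without matrix
feedback:

```r
library(matrixflock)

p <- sim_params(n_cells = 200, domain_size = c(500, 500),
                grid_shape = c(50, 50), noise_variance = 0, w_c = 0.03,
                w_m = 0.2, duration = 7)
st <- run_simulation(p, seed = 1)
st
#> <sim_state> 200 cells, t = 10080 min, 134400 fibers on a 50x50 grid
compute_metric_set(st)
#> # A tibble: 1 × 5
#>     lra   sra   hdm  curv  frac
#>   <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 0.532 0.725  19.8  18.8  1.79

p0 <- p; p0$w_m <- 0
compute_metric_set(run_simulation(p0, seed = 1))
#> # A tibble: 1 × 5
#>     lra   sra   hdm  curv  frac
#>   <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 0.899 0.899  43.4  10.8  1.97
```

Without feedback (`w_m = 0`) the cells align globally: LRA ≈ SRA ≈ 0.9 with
low curvature — a stomach-like aligned matrix. With feedback (`w_m = 0.2`)
the same cells are corralled by their own early deposits: long-range
alignment collapses to ≈ 0.53 while short-range alignment stays high
(≈ 0.73) and curvature rises — the swirl-like patterning seen in dermis.
`render_matrix()` turns a grid into a grayscale image
(`write_gray_png(render_matrix(st$grid, st$last_selected), "matrix.png")`),
and `tissue_preset("dermis")` etc. carry published parameter triples.

A thin command-line interface is included
(`inst/cli/matrixflock simulate --config cfg.yaml --seed 7 --out run/`,
with `metrics`, `sweep`, `remodel`, `calibrate` and `fixtures`
subcommands).

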