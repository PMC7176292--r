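# mabpr

Mollified adaptive biasing potential (mABP) enhanced sampling with
overfill protection, in R.

## The problem

Rare events — a ligand finding its way into a receptor's orthosteric
pocket, a torsion hopping between rotameric states — sit far beyond the
reach of plain molecular dynamics. Flooding-type adaptive biasing methods
accelerate them by accumulating a repulsive bias along a small set of
collective variables (CVs) as the simulation runs, progressively pushing
the system out of the regions it has already seen. `mabpr` implements the
grid-based mABP flavor of this idea for 1D and 2D CVs, together with the
surrounding machinery a ligand-binding study needs: CV construction,
flat-bottom restraints, fill-limit calibration, landscape analysis and
pose extraction. The dynamics substrate is a set of analytic toy systems
with exactly known free energies, so every estimate the package produces
can be checked against a closed-form answer.

## The method

Sampling accumulates mollified weight on a CV-space grid: each step
deposits a compact quartic-bump kernel of half-width `alpha` bins
(product form in 2D) at the current CV cell. The bias of a cell with
accumulated weight `S` is

```
V = b * kT * ln(c * S + 1)
```

with bias fraction `b` in (0,1) and deposition rate `c` per time step.
Two safeguards implement *overfill protection*: each deposit is scaled by
`g = clip(1 - V_center / flim, 0, 1)`, and the evaluated bias is capped
at the fill-limit `flim` (kcal/mol), so the adaptive bias can never drive
the system over unphysically high barriers. At stationary growth the bias
tracks `V = b/(1+b) * (C - F)`, giving the free-energy estimator

```
F_hat = -(1 + b)/b * V        (min-shifted over visited cells)
```

Binding CVs are RMS distances of ligand atom groups to single
center-of-geometry reference points recomputed from the receptor at every
evaluation; a cylindrical flat-bottom restraint and a maximal allowable CV
value keep the ligand from diffusing away. Binding and unbinding events
are counted by a two-threshold hysteresis rule (bound < 4 Å,
unbound > 10 Å), and bound poses are picked as the medoid of the largest
DBSCAN cluster (eps 0.7 Å, minimum 25 points) of basin frames.

## Worked example

Recover the free energy of a double well `U(x) = 2 (x^2 - 1)^2` kcal/mol
at kT = 0.6 kcal/mol (a 3.3 kT barrier) from a biased run:

```r
library(mabpr)

sys  <- toy_double_well(h = 2)            # kT = 0.6, friction 10/ps, dt 0.01 ps
grid <- system_grid(sys, flim = 6)        # 480 bins, b = 0.9, alpha = 20
res  <- run_mabp(sys, grid, n_steps = 2e6, stride = 100, seed = 1)
fes  <- free_energy_estimate(res$grid)

h <- 4 / 480                              # 8.3 mA bins
x <- seq(-2 + h / 2, 2, by = h)           # cell centers
w <- fes$visited & abs(x) <= 1.3
U <- system_potential(sys, x)
sqrt(mean(((fes$F[w] - min(fes$F[w])) - (U[w] - min(U[w])))^2))
#> [1] 0.07327583
```

The estimated landscape matches the analytic potential to 0.073 kcal/mol
RMS over the sampled region — an order of magnitude below the barrier
height and well inside chemical accuracy. The same pipeline drives the
3D host-guest binding toy:

```r
hg   <- toy_host_guest()
scan <- flim_scan(hg, c(0, 0.5, 10), n_steps = 2e6, seeds = 1:5)
scan$table
#>  flim seed bindings unbindings events_per_us basin_found
#>   0.0    1        0          0             0       FALSE
#>   ...
#>  10.0    1        1          0            50        TRUE
#>  10.0    3        2          1           150        TRUE
#>   ...
```

At a vanishing fill-limit the bias saturates below the pocket's entrance
barrier and no binding occurs; at the calibrated fill-limit every seed
binds and the averaged landscape's global minimum falls in the
constructed pocket — the two calibration regimes that make fill-limit
scans a necessary first step of a binding study.

A command-line surface (`inst/cli/mabp`) exposes the pipeline as
`fixture`, `run`, `fes`, `extract`, `occupancy`, `events` and `calibrate`
subcommands over YAML run configurations.

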