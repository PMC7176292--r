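---
title: "Adaptive biasing with overfill protection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive biasing with overfill protection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biasing model

`mabpr` implements a flooding-type adaptive biasing potential on a grid
over one or two collective variables (CVs). Every dynamics step deposits
a smooth kernel of (at most) unit mass at the current CV position; the
accumulated, mollified weight $S$ of a cell defines its bias

$$ V = b\,k_BT\,\ln(c\,S + 1), $$

where $b \in (0,1)$ is the fraction of the log-density applied as bias
and $c$ (per time step) sets the deposition rate. The force on the
dynamics is the analytic gradient of the multilinear interpolant of $V$
over cell centers, chained through the CV gradients.

**The estimator.** At stationary growth, the sampling density under the
current bias is $\rho \propto e^{-\beta(F+V)}$ and the bias grows as
$\dot V \propto c\,\rho\,e^{-\beta V/b}$ (because $cS+1 = e^{\beta V/b}$).
Requiring uniform growth gives the fixed-shape solution

$$ V \;\to\; \frac{b}{1+b}\,\bigl(C(t) - F\bigr), $$

so the package estimates $\hat F = -\tfrac{1+b}{b} V$, shifted to zero at
its minimum over visited cells. A commonly quoted alternative,
$\hat F = -V/b$, is *not* consistent with per-step visitation deposits:
on the 1D double well below it misses the analytic answer by a factor
$1/(1+b) \approx 0.53$ in the landscape amplitude (0.55 kcal/mol RMS
versus 0.07 for the estimator used here). Recovery of analytic free
energies is the package's correctness anchor, so the derived form wins.

**The mollifier.** Deposits use a quartic bump
$w(r) \propto (1-(r/\alpha)^2)^2$ on $|r| \le \alpha$ bins (product form
in 2D), normalized to unit mass: smooth, compactly supported, cheap. The
kernel's variance is $\alpha^2/7$ bins$^2$, so the smoothing bias it adds
to the landscape is $\approx \tfrac{1}{2}\sigma^2 F''$ — about
0.03 kcal/mol for the default binding configuration, negligible against
the statistical error.

**Overfill protection.** Two mechanisms bound the bias by the fill-limit
`flim`. Each deposit is scaled by $g = \mathrm{clip}(1 - V_\mathrm{center}/f_\mathrm{lim},\,0,\,1)$
evaluated at the pre-deposit center cell — a linear ramp that saturates
deposition smoothly. On top of that, the *evaluated* bias is hard-capped
at `flim`. The cap is necessary, not cosmetic: center-cell gating alone
cannot bound a cell that keeps receiving kernel *tails* from deposits
centered nearby, so without the cap the invariant "bias never exceeds the
fill-limit" would fail by a kernel-tail correction (we measured
$\sim$0.09 kcal/mol overshoot at tiny fill-limits under heavy traffic).
With the cap it holds everywhere, exactly, for any deposit sequence.

The cost of capping is information loss: wherever $V$ saturates, the
landscape contrast freezes. Long runs at a fill-limit far above every
barrier slowly flatten the *estimate* (not the physics) as outer regions
catch up — one more reason the fill-limit must be calibrated rather than
simply set high.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `b` | — | 0.9 (binding), 0.8 (dihedral) | fraction of log-density applied as bias |
| `c` | 1/step | 0.005 (binding), 0.1 (dihedral) | deposition rate; toys use larger values to converge in desk-scale step counts |
| `alpha` | bins | 20 (binding), 5 (dihedral) | mollifier half-width |
| `flim` | kcal/mol | calibrated per system | overfill fill-limit |
| `kT` | kcal/mol | 0.6163 (310 K); toys 0.6 | thermal energy |
| grid | — | 480×480 over 0–60 Å (binding); 300 over 0–2π (dihedral) | CV discretization (0.125 Å bins) |

Binding-simulation geometry: the two CVs are RMS distances of two ligand
atom groups to dynamically recomputed center-of-geometry reference
points; a flat-bottom cylinder (default radius 18 Å, axis the membrane
normal $+z$, force constant 10 kcal/mol/Å²) plus a CV cap (default 22 Å)
confine the search volume. The restraint force constants are package
choices (the flat-bottom form fixes the physics; the stiffness only sets
the wall softness).

## Dynamics

Toy systems are integrated with BAOAB-discretized Langevin dynamics
(unit masses, constant volume). BAOAB is stable at the friction values
used (5–10 ps⁻¹) and samples configurational averages accurately at
dt = 0.005–0.01 ps; the unbiased harmonic-well variance reproduces
$k_BT/k$ within sampling error and unbiased double-well histograms match
the potential to < 0.1 kcal/mol RMS. Every run is a pure function of
(configuration, seed): the noise stream is drawn from R's RNG up front,
so reruns are bit-identical. Trajectories abort with a diagnostic if any
coordinate exceeds 10³ Å.

An external-engine adapter is specified at the level of the CV/restraint
contract — given coordinates, the package returns bias and restraint
energies, forces and CV gradients (`bias_potential_and_force`,
`rms_distance_gradient`, `restraint_energy_force`) — but no engine is
bundled.

## What the synthetic systems emulate

* `toy_double_well`, `toy_mueller_brown`, `toy_cosine_well` — 1D/2D
  systems whose coordinates *are* the CVs, with closed-form free
  energies. They anchor the estimator: biased runs must recover the
  analytic landscape (0.3 kcal/mol RMS on the double well; 0.5 on the
  scaled Müller–Brown surface over cells below 3 kcal/mol).
* `toy_host_guest` — a four-particle semi-rigid ligand (two labelled
  two-atom groups, mirroring a flexible/rigid moiety decomposition)
  diffusing above two fixed receptor reference points. Per-atom Gaussian
  wells at a constructed pose form the pocket (1.5 kcal/mol per atom,
  width 0.9 Å); a Gaussian shell on the ligand centroid (5 kcal/mol at
  5 Å) is the entrance barrier; a shallow off-axis decoy well provides a
  spurious-escape channel; a half-space wall stands in for the receptor
  body. The confinement (cylinder radius 4 Å, CV cap 12 Å over a 28×28
  grid of 0.5 Å cells, c = 100/step) is deliberately tight so that the
  calibration phenomenology plays out within $2\times10^6$ steps per run
  on one CPU.

The toys reproduce the *mechanisms* — kernel deposition, overfill
gating, restraint geometry, hysteresis event counting, landscape
averaging — not the scale of membrane-protein systems: no solvent, no
explicit receptor flexibility, no force field. Passing tests therefore
demonstrate the correctness of the sampler and analysis chain, not
production readiness on real receptors; production settings (2 fs steps,
310 K, NPT, 8 Å cutoffs) enter run configurations as metadata only.

**The calibration protocol.** The barrier heights, pocket depth and the
scanned fill-limits were fixed together, once, by the same scan the
package exposes to users: at `flim` = 0.5 the bias saturates below the
5 kcal/mol entrance barrier and runs are indistinguishable from unbiased
(no binding within the run length); at the calibrated `flim` = 10 all of
15 validation seeds bound, and the replicate-averaged landscape placed
its global minimum in the pocket region. Unbinding additionally requires
filling the 6 kcal/mol pocket and re-crossing the barrier, so bound-state
escapes occur in a minority of runs — event counts at the calibrated
fill-limit are dominated by first-binding events, which is what the
regime comparison uses.

## Numerical choices and degenerate inputs

* Interpolation is multilinear with the analytic in-cell gradient;
  outside a non-periodic range the edge value is returned with zero
  outward gradient, and deposits beyond the range clamp to the edge cell
  (counted, not fatal). Periodic dimensions wrap indices modulo the bin
  count.
* The RMS-distance CV is singular at 0; its gradient is defined as the
  zero vector there. "RMSD to a single point" admits no superposition,
  so no fitting is performed — the only self-consistent reading.
* Torsions use the standard atan2 form mapped to $[0, 2\pi)$; collinear
  triples are an error.
* Basin detection reports local minima below a depth threshold expanded
  to the connected region within 1 kcal/mol of the local minimum; on a
  thermally broadened landscape the free-energy minimum sits at slightly
  *larger* RMS-distance CV than the frozen construction pose (convexity
  of the RMS distance), about one 0.5 Å cell for the host–guest toy —
  pocket checks therefore use a declared target region around the pose,
  not a single cell.
* DBSCAN uses the textbook semantics (core point: ≥ `min_pts` neighbors
  within `eps` counting itself); border points are assigned to the first
  cluster that reaches them, which is the standard order dependence and
  immaterial for separated clusters. The pose metric is ligand-atom RMSD
  without re-fitting, assuming receptor-aligned frames upstream.
* Hysteresis event states in the dead zone inherit the previous state;
  series start unbound (ligands start in solvent), configurable.
* Replicate averaging is the visited-cell mean of min-shifted landscapes,
  re-shifted. Because replicate errors share the deposition protocol's
  systematic component, averaging reliably avoids degradation (not worse
  than the poorer replicate in ≥ 9/10 pairs at the tested run length) but
  does not halve the error the way independent noise would — the
  vignette's own tests assert the former, not the latter.
* Landscape files (TSV) carry contour levels 1, 3 and 5 kcal/mol in
  their header as the conventional rendering levels; checkpoints (.mabp)
  are a one-line JSON header plus a little-endian float64 weight block.

## Problem sizes used in tests

Module and acceptance tests run $10^6$–$2\times10^6$ steps per
trajectory, 5-seed calibration scans, $10^6$ stress deposits and 50
randomized clustering fixtures — sizes chosen so the full suite and the
reproduction script each complete in minutes on a single CPU while
leaving every statistical assertion a comfortable margin.

## Known limitations

* Grids are 1D/2D only, matching the CV constructions supported.
* The free-energy estimate is quantitative only where $V$ has not
  saturated at `flim`; heavily capped regions flatten.
* The unbinding phenomenology of the host–guest toy at very high
  fill-limits (landscape degradation without trajectory "spoiling"
  through a receptor, which has no desk-scale analog) is qualitative.
* No explicit solvent, NPT, constraints or PME — engine facts for real
  systems are configuration metadata, not simulated physics.
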