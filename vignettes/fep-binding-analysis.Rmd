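---
title: "Alchemical binding free-energy analysis for cAMP-CNBD systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alchemical binding free-energy analysis for cAMP-CNBD systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campfep)
```

## The problem

HCN ("pacemaker") channels are modulated by cyclic AMP binding to an
intracellular cyclic-nucleotide-binding domain (CNBD). Comparing how tightly
cAMP binds to the CNBDs of the four isoforms HCN1-4 requires an absolute
binding free energy per isoform, typically obtained by double decoupling: the
ligand is alchemically annihilated once in water (the solvation leg,
$\Delta G_{solv}$) and once in the bound complex (the protein leg,
$\Delta G_{protein}$), each across a schedule of coupling-parameter windows.
The binding free energy is the difference

$$\Delta G_{bind} = \Delta G_{solv} - \Delta G_{protein},$$

with more negative values meaning tighter binding. `campfep` implements
everything downstream of the molecular-dynamics engine: parsing the
per-window energy-difference records, estimating window and total free
energies, a per-residue interaction decomposition, the trajectory
quality-control (QC) metrics used to decide which replicates are trustworthy
enough to seed the alchemical stage, and the isoform-level aggregation.
Running MD itself is out of scope.

## Free-energy estimators

Each window contributes forward samples $\Delta U_F$ (annihilation
direction) and backward samples $\Delta U_B$ (restoration). Two estimators
are provided:

* **Exponential averaging** (`exp_estimator()`), the one-sided Zwanzig
  formula $\Delta G = -RT \ln \langle e^{-\Delta U/RT}\rangle$, computed with
  a log-sum-exp so that $|\Delta U|/RT$ up to at least 700 cannot overflow.
  It is used as a cross-check and as the initial bracket for BAR.
* **Bennett Acceptance Ratio** (`bar_estimator()`), the statistically optimal
  two-state estimator. The self-consistency residual (Fermi-weighted forward
  sum minus Fermi-weighted backward sum, with the $RT\ln(n_F/n_B)$ offset) is
  monotone in $\Delta G$, so the root is found by a sign-change bracket with
  safeguarded Newton refinement (tolerance $10^{-8}$ kcal/mol, at most 500
  iterations, then two Newton polish steps). The standard error is Bennett's
  asymptotic variance evaluated at the solution.

`total_free_energy()` applies BAR per window over the full schedule (default:
20 windows of width 0.05, electrostatics fully decoupled by $\lambda = 0.5$)
and sums. Windows are treated as independent when combining variances: at 25
production samples per window, time-series autocorrelation estimators are too
unreliable to be worth applying, and the synthetic generator draws i.i.d.
samples anyway.

A numerical caution that shaped the test suite: the folk rule that BAR always
lies *between* the forward and backward exponential-averaging estimates is
only true in expectation. The Jensen biases $E[\Delta G_{EXP,F}] \ge \Delta G
\ge E[\Delta G_{EXP,B}]$ are exact, but on any single finite sample BAR can
land slightly outside the two one-sided values (we verified a counterexample
against a 50-digit root of the Bennett equation). The suite therefore asserts
the expectation-level bracket and BAR's calibration ($|$estimate $-$ truth$|
< 3\,$stderr across seeds) rather than a per-realization sandwich.

## Per-residue decomposition

The alchemical transformation is treated as an equilibrium between the
fully-present and fully-annihilated ligand. For one residue and window $i$,
an equilibrium constant is the average of exponentials of the scaled
residue-ligand pair energies,

$$K_i = \left\langle e^{-(0.1\,U_{elec} + 0.05\,U_{vdw})/RT}\right\rangle
\quad (i \le 10), \qquad
K_i = \left\langle e^{-0.05\,U_{vdw}/RT}\right\rangle \quad (i \ge 11),$$

because electrostatics are fully off in the second half of the schedule while
van der Waals terms persist throughout; the residue's relative interaction
free energy is $\Delta G = -RT\sum_{i=1}^{20} \ln K_i$ with $RT =
0.616$ kcal/mol (310 K, configurable). The scale factors are fixed constants
of the method as printed, not per-window $\lambda$ values; we considered the
$\lambda$-dependent alternative and rejected it because the printed equations
are explicit and the fixed factors are what the decoupling statement implies.
This is a ranking tool, not a rigorous free-energy partition: non-additivity
is inherent to the approximation, so only relative magnitudes across residues
and isoforms should be interpreted. Non-finite energy samples are rejected
rather than skipped, since silently dropping samples would bias the
exponential average.

## Trajectory QC metrics

Five metrics (`traj_metrics`) judge whether a bound-ligand replicate is
stable enough to seed the alchemical stage:

* **Ligand COM displacement** and **ligand RMSD**, both measured after
  superposing each frame onto the reference frame using the beta-sheet
  C-alpha atoms (Kabsch superposition with proper-rotation sign correction).
  Aligning both metrics on the same rigid core means whole-domain drift is
  not mistaken for ligand motion; an unaligned COM mode exists behind a flag.
  COM masses default to unit masses with a message unless masses are given.
* **Lid distance**: the frame-internal C-alpha distance between a
  beta-jelly-roll loop residue and a C/D-helix-turn residue (per-isoform
  pairs S527/I594, N596/I663, A480/I547, N647/I714), a proxy for the C-helix
  lid staying closed over the nucleotide.
* **Helix B/C angle**: each helix axis is the smallest-moment eigenvector of
  the inertia tensor of its C-alpha atoms (unit masses), oriented from first
  to last residue; the angle is folded to $[0°, 90°]$ via the absolute dot
  product (a signed variant is available). A degenerate inertia tensor
  (smallest moment not unique to $10^{-9}$ relative) is an error naming the
  frame rather than a silent arbitrary axis.
* **Hydrogen-bond geometry**: a bond is present when the donor-acceptor
  distance is at most 3.0 Å and the donor-hydrogen-acceptor angle deviates
  from linearity by at most 20°, the semantics of the common
  trajectory-viewer H-bond plugin.

## Replicate selection

Published practice applies the bounds by eye; `evaluate_replicate()`
operationalises "stable" as a required fraction (default 0.9) of production
frames within bound: COM $\le 2$ Å and RMSD $\le 3$ Å as absolute cutoffs,
and — because no numeric cutoffs are published for them — lid distance and
helix angle as excursion-from-median stability checks with configurable
limits, disabled unless a limit is supplied and flagged as package defaults
in the report notes. Overall pass is the conjunction of enabled criteria,
which makes the verdict monotone: tightening any threshold can only turn
passes into fails (property-tested on randomized fixtures).
`rank_replicates()` orders passing replicates by mean COM plus mean RMSD,
each normalised by its threshold, with deterministic id tie-breaks.

## Aggregation

`isoform_binding_energy()` averages pose-level protein-leg values and
subtracts from the solvation leg (default $118.63 \pm 0.39$ kcal/mol for cAMP
in water at 310 K). The reported error is the sample standard deviation of
the pose values combined in quadrature with the solvation-leg error — a
deliberate, documented convention: published summary errors are not generally
reproducible from pose-level errors by any simple rule we tested, so the
package states its own. `rank_isoforms()` sorts by binding free energy and
flags pairs closer than their combined errors as statistically comparable.
The packaged residue-offset map (`hcn_offset_map()`) resolves 27 homologous
positions (+0 to +90) to residue labels in all four isoforms; pose-level
protein-leg inputs ship as `hcn_pose_energies()`.

## Synthetic data and what passing tests mean

The generator module replaces the MD engine at desk scale:

* `gen_gaussian_work()` draws forward work from $N(\mu, \sigma^2)$ and
  backward work from $N(-\mu + \sigma^2/RT, \sigma^2)$, which satisfies the
  Crooks fluctuation relation exactly with per-window ground truth $\mu -
  \sigma^2/(2RT)$ (the suite checks the Crooks slope $1/RT$ by histogram
  regression at $n = 10^5$).
* `gen_pair_energies()` produces Gaussian pair-energy streams; zero-variance
  mode carries the closed-form decomposition with the data.
* `gen_toy_trajectory()` builds a static 24-atom beta-sheet scaffold, two
  18-residue ideal-helix rods (rise 1.5 Å, twist 100°; 18 residues = 5 full
  turns, so the rod's inertia axis is symmetric), a 5-atom rigid ligand
  (static, linear drift, or random walk), a lid pair, and a
  donor-hydrogen-acceptor triplet whose deviation-from-linearity schedule is
  solved exactly by root-finding. The scaffold is static so superposition is
  the identity and every scheduled series is the exact expected answer.

All generators are deterministic given a seed and store their ground truth
with the data. These fixtures are geometry and sampling statistics only — no
force field, no solvent, no correlated dynamics — so green tests demonstrate
that the estimators, decomposition and metrics compute what they claim on
data with known answers, not that any particular MD system is converged.
Published MD-derived numbers (pose-level $\Delta G$ values, per-residue
tables, metric traces) require the original trajectories and are out of
reach by construction; what is reproduced exactly is the isoform-level
arithmetic and ranking from the pose-level inputs, and the residue-offset
table.

## Problem sizes and numerical choices

The test and acceptance workloads were sized for a laptop-class single core:
BAR calibration uses 20 windows × 1000 samples/leg × 50 seeds; the Jensen
property is checked on 1000 random streams; geometry oracles use 50-atom
point sets over 20 noisy instances; the end-to-end pipeline bundle uses 3
replicates × 30 frames and 200 samples/leg. Root-finding tolerances, the
proper-rotation sign correction, the collinearity guard in Kabsch, and the
unique-smallest-eigenvalue guard in the helix axis are all stated above and
enforced as errors, not warnings.

## A worked example

```{r}
work <- gen_gaussian_work(mu = 1, sigma = 0.5, n_samples = 200, seed = 7)
est <- total_free_energy(pair_windows(work$forward, work$backward))
est
work$ground_truth_total

summaries <- binding_energy_table(hcn_pose_energies())
rank_isoforms(summaries)$ranking

offset_to_residues(47)
```

## Known limitations

* No autocorrelation correction in window-error combination (flagged above).
* The decomposition reproduces the printed equations; its thermodynamic
  status is approximate by design.
* QC cutoffs for lid distance and helix angle are package conventions, not
  published values, and are reported as such.
* No standard-state/restraint volume corrections: binding energies are raw
  $\Delta G_{solv} - \Delta G_{protein}$ differences.
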