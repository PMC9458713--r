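---
title: "Dynamic integrated/segregated brain states and structural control energy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic integrated/segregated brain states and structural control energy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynstates)
```

## The model and the pipeline

Resting-state functional brain organisation fluctuates on the scale of tens
of seconds between configurations dominated by within-module connectivity
("Segregated") and configurations with strong between-module communication
("Integrated"). `dynstates` implements the full analysis chain that
quantifies these dynamics from parcel-level BOLD timeseries and asks what
they cost energetically on the individual's structural connectome:

1. **Sliding-window dynamic FC.** Windows of fixed length (default 63 TRs)
   advance by one TR; each window yields a signed Pearson correlation
   matrix with zero diagonal.
2. **Cartographic profile per window.** Community structure is detected by
   Louvain under the *signed asymmetric* modularity
   $$Q=\frac{1}{v^+}\sum_{ij}\left(w^+_{ij}-e^+_{ij}\right)\delta_{M_iM_j}
     -\frac{1}{v^++v^-}\sum_{ij}\left(w^-_{ij}-e^-_{ij}\right)\delta_{M_iM_j},$$
   with per-sign configuration nulls
   $e^\pm_{ij}=\gamma\, s^\pm_i s^\pm_j/v^\pm$ (resolution $\gamma=1$,
   best of 100 restarts). Each node gets a participation coefficient
   $P_i = 1-\sum_s (\kappa_{is}/k_i)^2$ (positive weights) and a
   within-module degree z-score
   $z_i = (\kappa_{is}-\bar\kappa_{is})/\sigma_{\kappa_{is}}$
   (population SD over the module's nodes). The window is summarised by the
   joint $(P, z)$ histogram (10 x 10 bins, $z\in[-5,5]$, mass 1).
3. **Two states per participant.** k-means (k = 2, Euclidean, 50 restarts)
   on the flattened histograms; the cluster with the strictly higher mean
   participation coefficient is named *Integrated*. Temporal metrics follow
   from the label sequence: fraction of time per state, mean dwell time
   (windows), and transition counts split by direction.
4. **Network control energy.** Each state is represented by its sum
   connectivity profile $x_i=\sum_j w_{ij}$ of the state-mean FC. The
   structural connectome $A$ is stabilized as
   $A_{\mathrm{stab}} = A/(1+\lambda_{\max}(A)) - I$ and drives the linear
   system $\dot x = A_{\mathrm{stab}}x + Bu$ with $B=I$. The minimal
   control energy of a transition solves
   $$\min_u \int_0^T (x_T-x)^\top S\,(x_T-x) + \rho\,u^\top u \,dt,
     \qquad x(0)=x_0,\; x(T)=x_T,$$
   with $S=I$, $\rho=1$, $T=1$. Four problems are solved per subject:
   the two transitions (I to S, S to I) and the two persistence problems
   (x_0 = x_T). Reported energy is the input cost $\int u_i^2\,dt$ per node
   (natural-log transformed for totals); the full objective value is also
   stored.
5. **Statistics.** Group contrasts of temporal metrics and energies route
   through Shapiro-Wilk (alpha = 0.05) to parametric or rank-based tests,
   with Hedges' g for the I-to-S energy contrast; state-level connectomes
   are compared by the network-based statistic (|t| >= 2.7, edge-extent
   components, max-component permutation null, Freedman-Lane residual
   permutation when covariates are present); nodal energy maps are
   correlated with receptor-density maps under spatial spin permutations
   (mirrored random rotations, nearest-neighbour reassignment, two-sided on
   |rho|, BH-FDR within each map family) and with the cortical hierarchy
   rank (Spearman, cortex only).

## The control solver

The fixed-endpoint problem is solved in continuous time through its
Hamiltonian two-point boundary system: stacking state and costate
$z=(x,p)$ gives $\dot z = Mz + c$ with a constant forcing from the
target-tracking term, so $z(T)$ is an affine function of $z(0)$ through the
matrix exponential of the $2N\times 2N$ block matrix. The terminal
condition $x(T)=x_T$ is a linear solve for $p(0)$ (its reciprocal condition
number is checked, floor 1e-12), the optimal input is
$u(t) = -B^\top p(t)/(2\rho)$ on a uniform grid (default 1001 points), and
nodal energies are trapezoid-rule integrals of $u_i^2$. The terminal
residual $\|x(T)-x_T\|$ is recorded and results are flagged above 1e-6.
Doubling the grid changes totals by well under 0.1%; energies are
quadratically homogeneous in the endpoint scale; a persistence solve never
exceeds the analytic hold-at-target bound $\rho T\|A_{\mathrm{stab}}x_T\|^2$.
The test suite verifies the solver against an independent discrete-time
benchmark: exact zero-order-hold discretization with piecewise-constant
inputs on 400 intervals, minimised as an equality-constrained quadratic
program through its sparse KKT system (agreement within 0.5% relative).

## What the synthetic cohorts emulate

The package generates complete cohorts (atlas, BOLD, structural
connectomes, receptor maps, group labels) so the whole pipeline is testable
without any imaging data.

**Atlas.** 200 cortical parcels on the unit sphere (deterministic
Fibonacci spiral, left hemisphere mirrored into the right so spin rotations
can be mirrored exactly) plus 32 subcortical parcels on an interior shell;
seven cortical networks in a fixed unimodal-to-transmodal hierarchy order
plus a subcortical block.

**BOLD.** A hidden two-state Markov chain (stay probability 0.98 per state
by default, TR 0.7 s, 101 retained timepoints) selects which regime
generates each timepoint; samples are i.i.d. multivariate normal given the
regime, plus white observation noise (SD 0.2). There is no hemodynamic
convolution, scanner noise model or motion structure: passing tests show
the statistical machinery recovers planted covariance dynamics, not that it
is robust to realistic fMRI artefacts.

**Regimes.** Both regimes share four contiguous macro-modules (coarse
functional systems) with within-module correlation 0.6. The integrated
regime couples the macro-modules at +0.15; the segregated regime
anticorrelates them at -0.15. This mirror-image design was chosen for three
reasons. First, the positive-weight participation coefficient leaves its
floor exactly where the between-module coupling of a regime mixture crosses
zero - the 50% mixture point - so the per-participant k-means boundary is
anchored at the point where window-majority ground truth flips. Second,
windowed sample estimates of module-to-module coupling fluctuate by about
$w/\sqrt{63}\approx 0.08$; against an all-positive background this noise
routinely pushes block pairs above the modularity null and makes Louvain
merge modules (which inverts the participation-based state naming), while
negative between-module edges make merging strictly unfavourable under the
signed null. Third, anticorrelated macro-systems are a genuine feature of
resting-state FC computed without global-signal regression. Designs with
nonnegative between-module correlations were measured at median
window-recovery 0.62-0.83; the mirror design reaches about 0.9.

**Window-level ground truth and conditioning.** True window labels are the
majority of the hidden per-timepoint labels in each window. At the study
geometry (101 timepoints, 63-TR windows) every window overlaps every other
and a run can express at most one clean majority switch; a stationary
Markov draw frequently yields runs where one regime dominates every window,
for which a forced k = 2 split is meaningless. `make_cohort` therefore
redraws each subject's hidden chain (label sequence only; cheap) until the
run satisfies a conditioning rule: the default `"switch"` rule requires
some window to be at least 75-78% pure in each regime, which selects the
single-near-mid-run-switch realizations - the only ones whose
window-majority truth is unambiguous - and is the ensemble on which state
recovery is assessed. The `"both_states"` rule only requires at least 6
windows of each majority label; it leaves the groups' stay-probability
contrasts intact and is the ensemble used for planted group-effect
experiments (the `"switch"` rule conditions on the very statistic those
effects change, and would erase them). Both are the Markov law conditioned
on an acceptance event, mirroring the study design in which every
participant expresses both states.

**Planted group effects.** The hallucinator-like (VH) group differs in two
ways: a stickier Segregated state (stay probability 0.995 vs 0.98
baseline) and structural weakening of all edges incident to a planted hub
set (15% of parcels, factor 0.6). Group-effect experiments use runs of 220
timepoints (about 2.6 min at TR 0.7 s, a realistic resting-state duration)
with baseline stay probability 0.97 and a more pronounced weakening factor
(0.4), because a 101-timepoint run can express at most one majority
transition, which leaves no room for group differences in transition
counts; the printed window counts of the source geometry are internally
inconsistent in any case, and the generator deliberately exposes
`n_timepoints`.

**Energy comparisons across subjects.** Raw sum-connectivity state vectors
scale with how many and how pure the windows entering each state mean were,
which differs systematically between groups; this estimation magnitude
confounds cross-subject energy comparisons (and swamps the structural
effect of interest). Group-level energy experiments therefore unit-normalize
the state vectors (`normalize = TRUE` in `transition_suite()` /
`subject_energies()`), comparing the cost of moving between state
*directions* on each subject's own connectome. The default remains the raw
definition.

**Receptor maps.** Gaussian-process draws on great-circle distances
(exponential kernel, correlation length 0.3 rad - smooth enough for
realistic spatial autocorrelation, with enough effective degrees of
freedom that moderate correlations remain detectable under the spin
null); anchoring to a target
Spearman correlation mixes the gaussianized ranks of the anchor with an
independent draw using the bivariate-normal identity
$\rho_P = 2\sin(\pi\rho_S/6)$.

## Numerical choices and degenerate inputs

- Regime matrices are repaired to valid correlation matrices by eigenvalue
  clipping at 1e-10 and diagonal renormalization.
- A parcel constant within a window gets zero edges and a warning (failing
  the subject for one flat window would be disproportionate).
- Stabilization makes the largest drift eigenvalue exactly
  $-1/(1+\lambda_{\max})$; the zero connectome maps to $-I$.
- Louvain move gains use tolerance 1e-10; ties across restarts keep the
  earliest run; realized Q is re-evaluated through `signed_modularity()`.
- k-means degeneracies (all windows identical, tied cluster mean
  participation) raise errors rather than guessing; silhouette evaluation
  skips infeasible k with a warning.
- Within-module z uses the population SD; zero-dispersion modules give z=0;
  zero-strength nodes give P=0.
- Spin permutations reassign nearest neighbours within hemisphere
  (duplicates permitted); subcortical parcels are uniformly permuted among
  themselves, since they cannot be rotated on the cortical sphere.
- Permutation p-values use the +1 smoothing, so they are valid and never 0.
- NBS uses |t| (two-sided) at the primary threshold and edge-count
  components.

## Problem sizes used by the test suite

The acceptance experiments run at sizes chosen to finish on a single CPU
while leaving the compared quantities meaningful: graph-metric oracles on
100 random graphs with up to 6 nodes and exhaustive partition enumeration
up to 10 nodes; control-oracle comparisons on 100 random 5-node systems
(grid 1001 vs QP benchmark with 400 intervals); state recovery on 20
default-geometry subjects (232 parcels); group-direction experiments on 50
cohorts of 60 parcels and 12 subjects per group with 10 Louvain restarts
per window and a 251-point control grid (directions are insensitive to
both); spin calibration with 200 null draws at 500 permutations; NBS
calibration with 200 null datasets at 500 permutations.

## Known limitations

- The BOLD generator has no hemodynamics, autocorrelation in time, motion,
  or physiological noise; recovery results bound what the statistics can do
  under the model's assumptions, not under real-data artefacts.
- At the default window geometry (63 of 101 TRs) all windows are regime
  mixtures; window-level recovery is intrinsically capped near 90% because
  majority labels near the 50% mixture point flip on single timepoints.
  Runs must be conditioned on expressing both states for per-participant
  clustering to be meaningful at all.
- The equicorrelated-block regimes make module-coupling estimates
  fluctuate coherently (factor-level noise ~ $1/\sqrt{63}$); richer
  within-module structure would change the detection landscape.
- Spin permutations operate on parcel centroids, not surface vertices.
- The NBS implementation covers two-group contrasts with optional
  covariates; paired or factorial designs are out of scope.
- Between-group comparisons of transition energy carry an estimation-purity
  confound when states are defined per participant: the group that dwells
  longer in a state estimates a purer (more extreme) vector for it, and a
  purer segregated target is less aligned with the connectome's dominant
  slow eigenmode and hence costlier to reach. In the synthetic cohorts this
  confound is roughly an order of magnitude larger than the plantable
  structural hub-weakening effect (whose influence on the stabilized drift
  is largely cancelled by the spectral renormalization), so the
  hallucinator-like group shows *higher*, not lower, I-to-S energy in most
  replicates. Unit-normalizing the state vectors removes the magnitude part
  of the confound but not the directional part. Interpret cross-group
  energy contrasts on individually-defined states with this in mind.
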