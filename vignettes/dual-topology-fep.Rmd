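---
title: "Dual-topology free energy perturbation with dualfep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-topology free energy perturbation with dualfep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualfep)
```

## The model

A relative free energy between two ligands A and B is obtained by
transforming one into the other along an alchemical pathway. `dualfep`
uses a *dual-topology* representation: both molecules are present in the
simulated system with their own coordinates, and the mixed potential at
coupling parameter $\lambda \in [0,1]$ is the linear combination

$$U_i = (1-\lambda_i)\,U_A + \lambda_i\,U_B,$$

so that at $\lambda = 0$ ligand B is fully decoupled (all its atoms are
*dummies* with zero charge and zero Lennard-Jones interaction) and at
$\lambda = 1$ ligand A is. Because each ligand keeps its own intact
bonded terms in both states and the two molecules never interact, no
bond needs to be made or broken even when the pair differs in bond
topology — which is what makes scaffold-hopping perturbations (ring
opening/closure, ring-size changes) tractable.

The relative binding free energy closes a thermodynamic cycle,

$$\Delta\Delta G_{A\to B} = \Delta G^{\text{bound}}_{A\to B} -
  \Delta G^{\text{water}}_{A\to B},$$

with the water leg replaced by a vacuum/water pair for relative
hydration free energies. Each leg is estimated from per-window samples
of $U_A$ and $U_B$ by one of three estimators (section *Estimators*).

## System preparation under spherical boundary conditions

Simulations are intended for a finite droplet of water around the
region of interest. `sphere_center()` defaults to the unweighted center
of geometry of the two superposed ligands, so both end states sit
centrally; the default radius is 25 Å, a reasonable envelope for
drug-sized ligands. Atoms beyond the sphere are restrained
(200 kcal/mol/Å² in the emitted input decks) and excluded from
nonbonded work by the engine, so ionizable residues whose charged-group
centroid falls outside the sphere or within the restrained boundary
shell are switched to neutral library variants by
`neutralize_outside()`. The shell width (default 3 Å), the water-clash
cutoff of `remove_overlapping_waters()` (default 2.4 Å, heavy atoms)
and the solvation grid spacing (default 3.1 Å, approximating bulk water
density with rigid TIP3P geometry) are package choices, exposed as
arguments: the droplet construction itself does not prescribe them.
The sphere boundary is closed ($d \le r$ counts as inside) purely as a
deterministic tie-break.

## Dual-topology construction and restraints

`build_dual_topology()` concatenates the two atom sets, assigns
per-state types/charges with the off-state as a dummy, and applies a
softcore depth (default 20 kcal/mol) to the dummy-state van der Waals
so end-point singularities are avoided. How equivalent atoms are
matched is genuinely open; the package uses greedy nearest-distance
matching over the pre-aligned poses with a 0.25 Å cutoff and element
identity required by default, both configurable. Matched pairs get
half-harmonic distance restraints

$$E(d) = \tfrac12 k\,(d - d_0)^2 \quad (d > d_0), \qquad
  E(d) = 0 \quad (d \le d_0),$$

with $k = 2.0$ kcal/mol/Å² and a flat window of 0.0–0.2 Å (so
$d_0 = 0.2$ Å). Note the explicit factor $\tfrac12$ in front of $k$ —
force-constant conventions differ between codes. Since every pair
couples one atom that is a dummy in each end state, the restraint
energy cancels between end states and needs no correction; the
structural precondition is asserted by `validate_dual_topology()`.
Two staging schemes are provided: a single transformation (default),
and a three-stage scheme (discharge A, softcore vdW swap, charge B)
for difficult perturbations; both emit the same text FEP-file dialect.

## Protocol and schedules

The default protocol plan is 10 replicate simulations (differing only
in their initial velocity seeds, derived deterministically from a
master seed, default 42), each with 131 ps of equilibration — a 31 ps
heating ramp from 0.1 K to 298 K discretized into five stages (1, 2, 4,
8, 16 ps) while a 25 kcal/mol/Å² solute restraint is stepwise
released, then 100 ps unrestrained — followed by 51 λ windows of 10 ps
production with a 1 fs time step. That bookkeeping gives
`total_sampling_time()` = 6.41 ns per leg, 12.82 ns per perturbation.

Schedules can start at λ = 1 (annihilation), λ = 0 (growth) or at the
mixed midpoint λ = 0.5 propagating towards both end states, in which
case `combine_branches()` forms
$\Delta G(0\to1) = \Delta G(0.5\to1) - \Delta G(0.5\to0)$. The
midpoint scheme is the recommended default: pure growth of a large
substituent converges poorly. The `"sigmoidal"` spacing uses
$\lambda(u) = \tfrac12\!\left(1 + \tanh(s(2u-1))/\tanh(s)\right)$ with
sharpness $s = 2$ and exact endpoints; the functional form is a package
choice (only "denser near the end points" is physically required).
Window accounting treats $n$ λ values as $n$ production windows.

## Estimators

With $\Delta U$ the per-sample perturbation energy between
neighbouring windows (for linear mixing simply
$(\lambda_j - \lambda_i)(U_B - U_A)$), the package implements:

* **Zwanzig**: $\Delta G = -k_BT\,\ln\langle e^{-\Delta U/k_BT}\rangle$,
  one-sided, max-shift stabilized.
* **Overlap sampling**: $\Delta G = -k_BT \ln\!\left[
  \langle e^{-\Delta U_f/2k_BT}\rangle_f /
  \langle e^{-\Delta U_r/2k_BT}\rangle_r \right]$.
* **BAR** (the recommended default): the self-consistent solution of
  Bennett's implicit equation with Fermi functions, including the
  $\ln(n_f/n_r)$ term for unequal sample counts. The residual is
  strictly monotone in $\Delta G$, so the solver brackets around the
  overlap-sampling estimate and bisects to `tol` (default $10^{-7}$
  kcal/mol, at most 500 iterations; non-convergence is an error
  carrying the last iterate). This construction makes
  $\Delta G(A\to B) = -\Delta G(B\to A)$ exact to solver tolerance.

$k_BT$ uses $R = 1.9872\times10^{-3}$ kcal/mol/K with a default
temperature of 298 K. Adjacent-window estimates are summed along a
branch; nothing is estimated across non-adjacent windows (no MBAR —
out of scope). Replicate means and SEMs ($s/\sqrt{n}$, undefined and
flagged for $n = 1$) come from `combine_replicates()`, and cycle SEMs
propagate in quadrature.

When the transformation changes the net charge of the droplet, the
Born charging correction

$$\Delta G_{\text{Born}} = -332\,\frac{Q_I^2}{2\,r_{\text{Born}}}
  \left(1 - \frac{1}{\varepsilon}\right)$$

is added (kcal/mol; $Q_I$ in e, $r_{\text{Born}}$ in Å). The package
defaults $r_{\text{Born}}$ to the simulation sphere radius — the cavity
radius is not uniquely defined by the setup, so the choice is logged
and configurable.

## Synthetic data and what passing tests mean

Because the MD engine is out of scope, correctness is demonstrated on
synthetic samples with analytic ground truth:

* `gen_gaussian_work()` draws forward work from
  $N(\Delta G + \sigma^2/2k_BT,\ \sigma^2)$ and reverse work from
  $N(-\Delta G + \sigma^2/2k_BT,\ \sigma^2)$, the unique Gaussian pair
  satisfying the Crooks fluctuation relation, so every estimator must
  recover $\Delta G$.
* `gen_harmonic_pair()` samples each λ window of a one-dimensional
  harmonic pair $U_X = \tfrac12 k_X x^2$ exactly (the mixed potential
  is again harmonic), with
  $\Delta F = \tfrac{k_BT}{2}\ln(k_B/k_A)$ in closed form. The test
  suite and the acceptance script run the full window pipeline at 51
  windows and $10^4$ samples per window.
* `gen_toy_ligand_pair()` / `gen_toy_system()` build superposed ligand
  pairs (common-atom jitter < 0.05 Å) and protein-like droplet
  contents for the preparation modules.

Windows are sampled independently: there is no autocorrelation, no
conformational barrier, no water reorganization. Passing these tests
therefore validates the estimators, bookkeeping and file formats — not
the convergence behaviour of real MD sampling, which must still be
judged per system (a large replicate SEM being the practical
diagnostic).

## Benchmark statistics

`mae()`, `pearson_r2()`, `fisher_ci()` (Fisher-z interval,
$\tanh(\operatorname{artanh} r \pm z_{1-\alpha/2}/\sqrt{n-3})$, suited
to the small series typical of FEP studies) and `ols_fit()` operate on
`benchmark_table()` objects. Experimental IC50 ratios convert via
$\Delta\Delta G = RT\ln(\mathrm{IC}_{50,B}/\mathrm{IC}_{50,A})$. Two
conventions are exposed as flags because published tables differ: the
radial-design reference ligand can be counted as zero deviation in the
MAE, and the regression response defaults to the calculated column.
Four published benchmark tables (side-chain hydration mimics, CDK2
inhibitors, A2A adenosine-receptor antagonists, Chk1 scaffold hops)
ship as plain-text data; `scripts/acceptance.R` recomputes their
summary statistics from the raw columns. Per-row hysteresis values
recomputed from the 2-decimal printed direction columns can differ from
the tabulated (unrounded-source) column by a few hundredths of a
kcal/mol; the dataset means agree to 2 decimals.

## Problem sizes and numerical choices

The shipped validation uses 5000 work samples per direction for the
Gaussian fixtures and 4 replicates of 51 windows × $10^4$ samples for
the harmonic pipeline — sizes at which the 3-standard-error acceptance
bands are a fraction of 0.01 kcal/mol while the whole suite runs in
well under a minute. Statistical checks compare against 3 Monte-Carlo
standard errors computed by delta-method/Bennett asymptotics, not
against fixed tolerances. Text formats round-trip at 1e-9 (parameters)
to 1e-8 (charges, 9 printed decimals); degenerate inputs (empty
selections, single replicates, identical λ, |r| = 1) raise typed errors
or flags rather than silent NAs.

## Known limitations

No MBAR across all windows; no automated equilibration detection or
decorrelation analysis; no maximum-common-substructure pair-list
design (pair lists are user input); Q-engine grammar compatibility of
the emitted `.lib`/`.prm`/FEP/input dialects is best effort — the
formats are documented by their readers/writers in this package and
round-trip exactly within it.
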