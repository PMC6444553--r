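# dualfep

Dual-topology free energy perturbation (FEP) workflow tools for R.

Relative binding and hydration free energies of ligand pairs are among
the few rigorously computable quantities in structure-based drug
design, but setting the calculations up by hand — merging force-field
files, building the alchemical topology, writing hundreds of
per-window MD inputs, and combining the resulting energy samples into
a statistically honest ΔΔG — is tedious and error prone. `dualfep`
automates that workflow for a *dual-topology* representation under
spherical boundary conditions: both ligands are present with their own
coordinates, each fully non-interacting ("dummy") in the opposite end
state, so the perturbation pathway is unambiguous and even changes in
bond topology (scaffold hopping) need no bond making or breaking.

The core model is the linear mixing of the two end-state potentials,

    U_i = (1 - λ_i) U_A + λ_i U_B,      λ ∈ [0, 1],

sampled over a schedule of λ windows, with each leg's free energy
estimated from per-window samples of `U_A`/`U_B` by Zwanzig exponential
averaging, overlap sampling, or the Bennett acceptance ratio (BAR, the
recommended default), and combined over a thermodynamic cycle:
ΔΔG = ΔG(bound) − ΔG(water). Net-charge-changing perturbations get the
Born correction ΔG_Born = −332 Q²/(2 r)(1 − 1/ε). Matched atoms of the
two ligands are held together by half-harmonic restraints
(½·k·(d − 0.2 Å)² with k = 2.0 kcal/mol/Å²) that cancel between end
states by construction.

The package covers:

* **Ligand I/O** — PDB coordinates, Q-style `.lib`/`.prm` text
  dialects, a self-contained ligand interchange format, parameter-set
  merging and validation.
* **System preparation** — sphere placement (center of geometry of the
  two ligands by default, radius 25 Å), atom classification,
  water-overlap removal, boundary neutralization of ionizable
  residues, grid solvation.
* **Dual topology & protocol** — equivalent-atom pairing, the merged
  alchemical specification, FEP stage files, λ schedules (linear or
  sigmoidal; start at 0, 1, or the 0.5 midpoint propagating both
  ways), replicate MD input decks with deterministic seeds.
* **Analysis & statistics** — BAR/OS/Zwanzig, replicate SEMs, cycle
  ΔΔG with error propagation, hysteresis, MAE, Pearson R² with
  Fisher-z confidence intervals, OLS, IC50 → ΔΔG conversion, CSV/JSON
  reports.
* **Synthetic data** — Gaussian work distributions and a 1-D
  harmonic-oscillator window series with exact analytic free energies,
  plus toy ligands/systems, so everything is testable without an MD
  engine.

## Worked example

```r
library(dualfep)

# a superposed toy ligand pair: 5 shared atoms + 3/2 unique substituents
pair <- gen_toy_ligand_pair(n_common = 5, n_unique_A = 3, n_unique_B = 2,
                            seed = 1)
spec <- build_dual_topology(pair$A, pair$B)
spec
#> <dual_topology_spec> 8+7 atoms, 5 restraint pairs, scheme 'single'

# protocol: 10 replicates, 131 ps equilibration, 51 windows x 10 ps
sch  <- make_lambda_schedule(51, "linear", start = 0.5)
tt   <- total_sampling_time(protocol_plan(), sch)
#> 6.41 ns per leg, 12.82 ns per perturbation
write_md_inputs(protocol_plan(), sch, spec, outdir = "fep_inputs")

# analysis on synthetic samples with a known answer:
# dF = (kT/2) log(k_B/k_A) = 0.4105 kcal/mol for k_B = 4 k_A at 298 K
win <- gen_harmonic_pair(k_A = 1, k_B = 4, n_windows = 51, n = 5000,
                         seed = 1)
analyze_leg(win, "bar")$dG
#> BAR estimate: 0.4117 kcal/mol (analytic 0.4105)

born_correction(-1, 25, 80)
#> -6.557 kcal/mol

# benchmark statistics on the bundled side-chain hydration table
h  <- hydration_benchmark()
tb <- benchmark_table(h$mimic, h$experimental, h$forward, h$forward_sem)
c(mae = mae(tb), r2 = pearson_r2(tb),
  hyst = mean(hysteresis(h$forward, h$backward)))
#> MAE 1.46 kcal/mol, R2 1.00, mean hysteresis 0.47
```

The numbers mean: the planned sampling budget is 6.41 ns per cycle
leg; the estimator pipeline recovers the analytic harmonic free energy
to ~0.001 kcal/mol at this sample size; and against experimental
hydration free energies of the 23 bundled side-chain mimics, the
annihilation-direction calculations have a mean absolute error of
1.46 kcal/mol, an R² of 1.00 over the > 80 kcal/mol span, and a mean
forward/backward hysteresis of 0.47 kcal/mol.

A thin CLI wraps the same functions:

```sh
exec/dualfep genfep --ligand-a A.pdb --ligand-b B.pdb --outdir fep_inputs
exec/dualfep analyze --samples windows.csv --estimator bar
exec/dualfep fixtures --kind harmonic --out harmonic.csv
```

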