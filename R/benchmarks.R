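# Bundled benchmark tables: experimental free energies and previously
# published calculated values for four widely used ligand series. All
# energies in kcal/mol; `*_sem` columns are standard errors of the mean
# over replicate simulations.

.extdata <- function(name) {
  p <- system.file("extdata", name, package = "dualfep")
  if (!nzchar(p)) stop("bundled table not found: ", name)
  utils::read.csv(p, stringsAsFactors = FALSE)
}

#' Relative hydration free energies of amino-acid side-chain mimics
#'
#' The classic Wolfenden set of 23 side-chain mimics (18 neutral, 5
#' charged), as relative hydration free energies of mimic X versus
#' methane. Columns: `experimental`; `forward` (side-chain annihilation,
#' X to methane) and `backward` (growth) with SEMs; their `average`;
#' the `hysteresis` between the two directions; and the `midpoint`
#' scheme started from the mixed lambda = 0.5 state, with SEM.
#'
#' @return data.frame, one row per mimic; `charged` flags the ionized
#'   species.
#' @export
hydration_benchmark <- function() .extdata("sidechain_hydration.csv")

#' CDK2 inhibitor binding free energies (16 ligands)
#'
#' Absolute binding free energies of a series of 16 CDK2 inhibitors,
#' scaled to the reference compound 1h1q (whose calculated columns for
#' the dual-topology workflow are `NA`: it is the radial-design
#' reference). Calculated columns cover two published FEP+ force-field
#' variants and the spherical-boundary dual-topology results with
#' OPLS2005, AMBER and CHARMM parameters.
#'
#' @return data.frame, one row per ligand.
#' @export
cdk2_benchmark <- function() .extdata("cdk2_binding.csv")

#' A2A adenosine-receptor antagonist relative binding free energies
#'
#' Shifts in binding free energy of 8 analogs relative to the parent
#' compound 11 (reference row with `NA` calculated values).
#'
#' @return data.frame, one row per compound.
#' @export
a2a_benchmark <- function() .extdata("a2a_binding.csv")

#' Chk1 scaffold-hopping relative binding free energies
#'
#' Six perturbations between five Chk1 inhibitors differing in their
#' core scaffold (ring opening/closure, ring-size change, in-ring atom
#' substitution).
#'
#' @return data.frame, one row per perturbation pair.
#' @export
chk1_benchmark <- function() .extdata("chk1_scaffold.csv")
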