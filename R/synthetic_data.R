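# Synthetic fixtures with analytic ground truth: toy ligand pairs, toy
# protein/water systems, Gaussian work distributions and a 1-D
# harmonic-oscillator pair. These let the whole pipeline be exercised and
# validated without an MD engine. All generators are pure functions of
# (parameters, seed): the same seed reproduces the same fixture.

#' Generate a superposed toy ligand pair
#'
#' Two ligands sharing `n_common` atoms at near-identical coordinates
#' (per-atom jitter below 0.05 Angstrom on the B copy) plus
#' `n_unique_A`/`n_unique_B` unique substituent atoms, with valid type
#' codes and charges summing exactly to zero. Atoms lie on a zigzag
#' chain with bonds between neighbours; unique atoms attach to the last
#' common atom.
#'
#' @param n_common shared atom count (>= 1).
#' @param n_unique_A,n_unique_B unique atom counts (>= 0).
#' @param seed RNG seed.
#' @return list `A`, `B` of [ligand_topology()] objects.
#' @export
gen_toy_ligand_pair <- function(n_common, n_unique_A = 0, n_unique_B = 0,
                                seed = 1) {
  stopifnot(n_common >= 1, n_unique_A >= 0, n_unique_B >= 0)
  set.seed(seed)
  chain_xyz <- function(n, origin = c(0, 0, 0), dir = 1)
    cbind(x = origin[1] + dir * 1.5 * seq_len(n),
          y = origin[2] + 0.4 * (seq_len(n) %% 2),
          z = origin[3] + 0)
  common <- chain_xyz(n_common)
  build <- function(res, n_uni, jitter, branch_dir) {
    xyz <- common
    if (jitter)
      xyz <- xyz + matrix(stats::runif(3 * n_common, -0.028, 0.028),
                          ncol = 3)
    if (n_uni > 0) {
      # unique substituents grow on opposite sides so they never superpose
      u <- chain_xyz(n_uni,
                     origin = common[n_common, ] + c(0, branch_dir * 1.4, 0.3))
      xyz <- rbind(xyz, u)
    }
    n <- n_common + n_uni
    q <- stats::runif(n, -0.3, 0.3)
    q <- q - mean(q)                       # exact zero net charge
    atoms <- data.frame(
      name = paste0("C", seq_len(n)), element = "C", type_code = "CT",
      charge = q, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE)
    bonds <- if (n > 1)
      cbind(c(seq_len(n_common - 1),
              if (n_uni > 0) c(n_common, seq_len(n_uni - 1) + n_common)),
            c(seq_len(n_common - 1) + 1,
              if (n_uni > 0) seq_len(n_uni) + n_common))
    else NULL
    ligand_topology(res, atoms, bonds = bonds)
  }
  A <- build("LGA", n_unique_A, jitter = FALSE, branch_dir = 1)
  B <- build("LGB", n_unique_B, jitter = TRUE, branch_dir = -1)
  list(A = A, B = B)
}

#' Parameter set covering a set of toy ligands
#'
#' @param ligs list of [ligand_topology()] objects.
#' @return a [parameter_set()] resolving every type code they use, with
#'   generic Lennard-Jones and bonded entries.
#' @export
gen_toy_parameters <- function(ligs) {
  types <- unique(unlist(lapply(ligs, function(l) l$atoms$type_code)))
  types <- types[!is.na(types)]
  parameter_set(
    vdw = data.frame(type_code = types, epsilon = 0.066, radius = 1.9087,
                     mass = 12.011, stringsAsFactors = FALSE),
    bonds = data.frame(ti = types[1], tj = types[1], k = 310, r0 = 1.526,
                       stringsAsFactors = FALSE),
    angles = data.frame(ti = types[1], tj = types[1], tk = types[1],
                        k = 40, theta0 = 109.5, stringsAsFactors = FALSE))
}

#' Generate Crooks-consistent Gaussian work distributions
#'
#' Forward samples are `N(dG_true + sigma^2/(2 kT), sigma^2)` and reverse
#' samples `N(-dG_true + sigma^2/(2 kT), sigma^2)`, which satisfy the
#' Crooks fluctuation relation for a true free energy `dG_true`, so BAR,
#' overlap sampling and Zwanzig all estimate `dG_true` (exactly in the
#' degenerate `sigma = 0` case).
#'
#' @param dG_true true free energy difference, kcal/mol.
#' @param sigma work standard deviation, kcal/mol (>= 0).
#' @param n samples per direction.
#' @param temperature Kelvin.
#' @param seed RNG seed.
#' @return list `dU_f`, `dU_r`, `dG_true`, `temperature`.
#' @export
gen_gaussian_work <- function(dG_true, sigma, n, temperature = 298,
                              seed = 1) {
  stopifnot(sigma >= 0, n >= 1)
  set.seed(seed)
  kT <- thermal_energy(temperature)
  shift <- sigma^2 / (2 * kT)
  list(dU_f = stats::rnorm(n, dG_true + shift, sigma),
       dU_r = stats::rnorm(n, -dG_true + shift, sigma),
       dG_true = dG_true, temperature = temperature)
}

#' Analytic free energy difference of two 1-D harmonic oscillators
#'
#' `dF = (kT / 2) * log(k_B / k_A)` from the ratio of Gaussian partition
#' functions.
#'
#' @param k_A,k_B force constants (kcal/mol/Angstrom^2, > 0).
#' @param temperature Kelvin.
#' @return dF in kcal/mol.
#' @export
harmonic_delta_f <- function(k_A, k_B, temperature = 298) {
  stopifnot(k_A > 0, k_B > 0)
  thermal_energy(temperature) / 2 * log(k_B / k_A)
}

#' Sample a lambda-window series from a 1-D harmonic pair
#'
#' End states `U_A = k_A x^2 / 2` and `U_B = k_B x^2 / 2`; at each window
#' the mixed potential is again harmonic with force constant
#' `(1 - lambda) k_A + lambda k_B`, so exact independent Gaussian samples
#' are drawn per window (no MD autocorrelation, isolating estimator
#' correctness from sampling dynamics). The analytic answer is
#' [harmonic_delta_f()].
#'
#' @param k_A,k_B force constants (> 0).
#' @param n_windows number of lambda windows (linear schedule 0 to 1).
#' @param n samples per window.
#' @param temperature Kelvin.
#' @param seed RNG seed.
#' @return list of [window_samples()], lambda ascending.
#' @export
gen_harmonic_pair <- function(k_A, k_B, n_windows = 51, n = 1000,
                              temperature = 298, seed = 1) {
  stopifnot(k_A > 0, k_B > 0, n_windows >= 2, n >= 1)
  set.seed(seed)
  kT <- thermal_energy(temperature)
  lams <- seq(0, 1, length.out = n_windows)
  lapply(lams, function(l) {
    k_mix <- (1 - l) * k_A + l * k_B
    x <- stats::rnorm(n, 0, sqrt(kT / k_mix))
    window_samples(l, 0.5 * k_A * x^2, 0.5 * k_B * x^2, temperature)
  })
}

.TOY_RESNAMES <- c("ALA", "ASP", "LYS", "SER", "GLU", "ARG", "HIP",
                   "GLY", "THR", "VAL")

# extra sidechain atoms per toy residue (ionizable ones carry their
# charged-group atoms so that boundary neutralization has something to
# measure)
.TOY_SIDECHAINS <- list(ASP = c("CG", "OD1", "OD2"),
                        GLU = c("CD", "OE1", "OE2"),
                        LYS = "NZ",
                        ARG = c("CZ", "NE", "NH1", "NH2"),
                        HIP = c("ND1", "NE2"))

#' Number of atoms gen_toy_system will produce
#' @param n_residues,n_waters as for [gen_toy_system()].
#' @return the deterministic atom count.
#' @export
toy_system_atom_count <- function(n_residues, n_waters) {
  res <- rep(.TOY_RESNAMES, length.out = n_residues)
  extra <- vapply(res, function(r)
    length(.TOY_SIDECHAINS[[r]] %||% character()), 0L)
  as.integer(sum(3L + extra) + 3L * n_waters)
}

#' Generate a toy protein-like system with waters
#'
#' A chain of backbone-only residues (N, CA, C) cycling through residue
#' names that include the ionizable set (ASP, GLU, LYS, ARG, HIP, each
#' with its charged-group atoms present), placed randomly within 1.2x
#' the sphere radius so that some residues fall in the boundary shell or
#' outside, plus `n_waters` waters on a lattice.
#'
#' @param n_residues residue count (>= 0).
#' @param n_waters water count (>= 0).
#' @param sphere a [simulation_sphere()].
#' @param seed RNG seed.
#' @return an [md_structure()] with
#'   [toy_system_atom_count()]`(n_residues, n_waters)` atoms.
#' @export
gen_toy_system <- function(n_residues, n_waters, sphere, seed = 1) {
  stopifnot(n_residues >= 0, n_waters >= 0,
            inherits(sphere, "simulation_sphere"))
  set.seed(seed)
  rows <- list()
  res <- rep(.TOY_RESNAMES, length.out = n_residues)
  for (i in seq_len(n_residues)) {
    u <- stats::runif(3, -1, 1)
    c0 <- sphere$center + 1.2 * sphere$radius * u
    names <- c("N", "CA", "C", .TOY_SIDECHAINS[[res[i]]])
    off <- matrix(stats::runif(3 * length(names), -1, 1), ncol = 3)
    rows[[length(rows) + 1]] <- data.frame(
      name = names, resname = res[i], resid = i,
      x = c0[1] + off[, 1], y = c0[2] + off[, 2], z = c0[3] + off[, 3],
      element = substr(names, 1, 1), stringsAsFactors = FALSE)
  }
  if (n_waters > 0) {
    m <- ceiling(n_waters^(1 / 3))
    g <- expand.grid(x = seq_len(m), y = seq_len(m), z = seq_len(m))
    g <- g[seq_len(n_waters), , drop = FALSE] * 3.1
    for (i in seq_len(n_waters)) {
      o <- sphere$center + as.numeric(g[i, ]) - 1.55 * m
      rows[[length(rows) + 1]] <- data.frame(
        name = c("O", "H1", "H2"), resname = "HOH",
        resid = n_residues + i,
        x = c(o[1], o[1] + .TIP3P_H[, 1]),
        y = c(o[2], o[2] + .TIP3P_H[, 2]),
        z = c(o[3], o[3] + .TIP3P_H[, 3]),
        element = c("O", "H", "H"), stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(name = character(), resname = character(),
                      resid = integer(), x = numeric(), y = numeric(),
                      z = numeric(), element = character(),
                      stringsAsFactors = FALSE)
  md_structure(if (length(rows)) do.call(rbind, rows) else empty)
}
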