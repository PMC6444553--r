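# Free-energy estimation from per-window end-state energy samples:
# Zwanzig exponential averaging, overlap sampling (OS) and the Bennett
# acceptance ratio (BAR), plus replicate statistics, Born charging
# correction and thermodynamic-cycle combination.
#
# Conventions: energies in kcal/mol, kT = 1.9872e-3 * T kcal/mol,
# lambda = 0 is state A and lambda = 1 is state B; all estimators return
# the free energy of the j-th (target) state minus the i-th (source).

#' Per-window end-state energy samples
#'
#' @param lambda window mixing coefficient in `[0, 1]`.
#' @param U_A,U_B equal-length sample arrays of the two end-state
#'   potentials (kcal/mol) collected at this window.
#' @param temperature temperature in Kelvin.
#' @return object of class `window_samples`.
#' @export
window_samples <- function(lambda, U_A, U_B, temperature = 298) {
  stopifnot(lambda >= 0, lambda <= 1, length(U_A) >= 1,
            length(U_A) == length(U_B), temperature > 0)
  structure(list(lambda = lambda, U_A = as.numeric(U_A),
                 U_B = as.numeric(U_B), temperature = temperature),
            class = "window_samples")
}

#' Forward/backward perturbation energies between neighbouring windows
#'
#' With linear mixing `U(lambda) = (1 - lambda) U_A + lambda U_B`, the
#' per-sample energy difference from window i to window j is
#' `(lambda_j - lambda_i) * (U_B - U_A)`, evaluated on each window's own
#' samples: forward on window i's, backward on window j's.
#'
#' @param w_i,w_j [window_samples()] at distinct lambdas and the same
#'   temperature.
#' @return list `forward` (ΔU_ij on w_i samples), `backward` (ΔU_ji on
#'   w_j samples), `dlambda`, `temperature`.
#' @export
neighbor_delta_u <- function(w_i, w_j) {
  stopifnot(inherits(w_i, "window_samples"), inherits(w_j, "window_samples"))
  if (w_i$lambda == w_j$lambda) stop("windows have identical lambda")
  if (w_i$temperature != w_j$temperature)
    stop("windows differ in temperature")
  dl <- w_j$lambda - w_i$lambda
  list(forward = dl * (w_i$U_B - w_i$U_A),
       backward = -dl * (w_j$U_B - w_j$U_A),
       dlambda = dl, temperature = w_i$temperature)
}

#' Zwanzig exponential-averaging free energy estimator
#'
#' `dG = -kT * log(mean(exp(-dU / kT)))`, stabilized against overflow by
#' a max shift. One-sided: uses only samples of the source state.
#'
#' @param dU perturbation energy samples, kcal/mol.
#' @param temperature Kelvin.
#' @return free energy difference in kcal/mol.
#' @export
zwanzig <- function(dU, temperature = 298) {
  stopifnot(length(dU) >= 1)
  kT <- thermal_energy(temperature)
  -kT * .logmeanexp(-dU / kT)
}

#' Overlap-sampling free energy estimator
#'
#' `dG = -kT * log( mean(exp(-dU_f / 2kT)) / mean(exp(-dU_r / 2kT)) )`:
#' half-exponential averages from both neighbouring windows, a symmetric
#' precursor of BAR.
#'
#' @param dU_f forward perturbation energies (source-window samples).
#' @param dU_r backward perturbation energies (target-window samples).
#' @param temperature Kelvin.
#' @return free energy difference in kcal/mol.
#' @export
overlap_sampling <- function(dU_f, dU_r, temperature = 298) {
  stopifnot(length(dU_f) >= 1, length(dU_r) >= 1)
  kT <- thermal_energy(temperature)
  -kT * (.logmeanexp(-dU_f / (2 * kT)) - .logmeanexp(-dU_r / (2 * kT)))
}

#' Bennett acceptance ratio (BAR) free energy estimator
#'
#' Solves Bennett's implicit equation with Fermi functions,
#' `sum_f 1 / (1 + exp(M + (dU_f - dG)/kT)) =
#'  sum_r 1 / (1 + exp(-M + (dU_r + dG)/kT))` with
#' `M = log(n_f / n_r)` accounting for unequal sample counts. The
#' left-hand side minus the right-hand side is strictly monotone in
#' `dG`, so the self-consistent solution is found by deterministic
#' bracketing and bisection starting from the overlap-sampling estimate;
#' iteration stops when successive iterates differ by less than `tol`.
#'
#' @param dU_f forward perturbation energies (source-window samples).
#' @param dU_r backward perturbation energies (target-window samples).
#' @param temperature Kelvin.
#' @param tol convergence tolerance in kcal/mol (default 1e-7).
#' @param max_iter maximal number of bisection iterations (default 500);
#'   non-convergence raises an error carrying the last iterate in its
#'   condition field `last`.
#' @return free energy difference in kcal/mol.
#' @export
bar <- function(dU_f, dU_r, temperature = 298, tol = 1e-7, max_iter = 500L) {
  stopifnot(length(dU_f) >= 1, length(dU_r) >= 1)
  kT <- thermal_energy(temperature)
  M <- log(length(dU_f) / length(dU_r))
  h <- function(x)
    sum(stats::plogis(-(M + (dU_f - x) / kT))) -
      sum(stats::plogis(-(-M + (dU_r + x) / kT)))
  x0 <- overlap_sampling(dU_f, dU_r, temperature)
  if (!is.finite(x0)) x0 <- (mean(dU_f) - mean(dU_r)) / 2
  # bracket the root symmetrically around the OS estimate
  d <- max(kT, tol)
  it <- 0L
  lo <- x0 - d; hi <- x0 + d
  while (h(lo) > 0 && it < max_iter) { lo <- lo - d; d <- 2 * d; it <- it + 1L }
  d <- max(kT, tol)
  while (h(hi) < 0 && it < max_iter) { hi <- hi + d; d <- 2 * d; it <- it + 1L }
  mid <- (lo + hi) / 2
  while (hi - lo > tol) {
    it <- it + 1L
    if (it > max_iter)
      stop(errorCondition(
        paste0("BAR did not converge within ", max_iter, " iterations"),
        class = c("dualfep_bar_nonconvergence", "error"), last = mid))
    if (h(mid) > 0) hi <- mid else lo <- mid
    mid <- (lo + hi) / 2
  }
  mid
}

#' Sum per-window free energies along one branch
#' @param dG_windows ordered numeric vector of per-interval free energies.
#' @return the leg free energy (arithmetic sum, kcal/mol).
#' @export
sum_windows <- function(dG_windows) sum(dG_windows)

#' Combine the two branches of a midpoint-start schedule
#'
#' For a schedule propagating from lambda = 0.5 towards both end states,
#' `dG(0 -> 1) = dG(0.5 -> 1) - dG(0.5 -> 0)`.
#'
#' @param dG_up free energy of the 0.5 -> 1 branch.
#' @param dG_down free energy of the 0.5 -> 0 branch.
#' @return `dG(0 -> 1)` in kcal/mol.
#' @export
combine_branches <- function(dG_up, dG_down) dG_up - dG_down

#' Analyze one FEP leg from per-window samples
#'
#' Applies the chosen estimator over every neighbouring window pair along
#' the branch (in the given order) and sums. For a two-branch
#' midpoint-start dataset call once per branch and use
#' [combine_branches()].
#'
#' @param windows list of [window_samples()] ordered along one branch.
#' @param estimator `"bar"`, `"os"` or `"zwanzig"` (one-sided forward).
#' @param ... passed to the estimator (e.g. `tol` for BAR).
#' @return list `dG` (leg total, kcal/mol), `window_dG` (per interval),
#'   `estimator`.
#' @export
analyze_leg <- function(windows, estimator = c("bar", "os", "zwanzig"), ...) {
  estimator <- match.arg(estimator)
  stopifnot(length(windows) >= 2)
  per <- vapply(seq_len(length(windows) - 1), function(i) {
    du <- neighbor_delta_u(windows[[i]], windows[[i + 1]])
    switch(estimator,
           bar = bar(du$forward, du$backward, du$temperature, ...),
           os = overlap_sampling(du$forward, du$backward, du$temperature),
           zwanzig = zwanzig(du$forward, du$temperature))
  }, 0)
  list(dG = sum_windows(per), window_dG = per, estimator = estimator)
}

#' Born charging correction for a net-charge change in a finite droplet
#'
#' `dG_Born = -332 * Q^2 / (2 * r_Born) * (1 - 1/eps)` in kcal/mol, the
#' polarization free energy of a net charge `Q` (e) in a cavity of radius
#' `r_Born` (Angstrom) embedded in a dielectric `eps`. Applied to a
#' perturbation iff the transformation changes the net charge of the
#' simulation sphere; a natural default for `r_Born` is the sphere
#' radius.
#'
#' @param Q_net net solute charge in elementary charges.
#' @param r_born cavity radius in Angstrom (> 0).
#' @param epsilon dielectric constant (>= 1; default 80, water).
#' @return correction in kcal/mol (zero for `Q_net = 0` or `epsilon = 1`).
#' @export
#' @examples
#' born_correction(-1, 25, 80)  # -6.557
born_correction <- function(Q_net, r_born, epsilon = 80) {
  stopifnot(r_born > 0, epsilon >= 1)
  -.COULOMB_KCAL * Q_net^2 / (2 * r_born) * (1 - 1 / epsilon)
}

#' Mean and standard error over replicate simulations
#'
#' @param dG_replicates per-replicate free energies (kcal/mol).
#' @return list `mean`, `sem` (`NA` with `sem_defined = FALSE` for a
#'   single replicate), `n`, `values`.
#' @export
combine_replicates <- function(dG_replicates) {
  n <- length(dG_replicates)
  if (n < 1) stop("no replicate values")
  list(mean = mean(dG_replicates),
       sem = if (n >= 2) stats::sd(dG_replicates) / sqrt(n) else NA_real_,
       sem_defined = n >= 2, n = n, values = dG_replicates)
}

#' Bundle per-replicate results of one perturbation leg
#'
#' @param dG_replicates per-replicate leg free energies, kcal/mol.
#' @param estimator estimator tag (`"bar"`, `"os"`, `"zwanzig"`).
#' @param leg `"bound"`, `"water"` or `"vacuum"`.
#' @param direction transformation label, e.g. `"A->B"`.
#' @param born Born correction added to the leg free energy (default 0).
#' @return object of class `perturbation_result` with `dG` =
#'   replicate mean + `born`.
#' @export
perturbation_result <- function(dG_replicates, estimator = "bar",
                                leg = c("bound", "water", "vacuum"),
                                direction = "A->B", born = 0) {
  leg <- match.arg(leg)
  cr <- combine_replicates(dG_replicates)
  structure(list(replicates = dG_replicates, mean = cr$mean, sem = cr$sem,
                 sem_defined = cr$sem_defined, estimator = estimator,
                 leg = leg, direction = direction, born = born,
                 dG = cr$mean + born),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("<perturbation_result> %s leg (%s, %s): dG = %.3f%s kcal/mol (n = %d%s)\n",
              x$leg, x$estimator, x$direction, x$dG,
              if (x$sem_defined) sprintf(" +/- %.3f", x$sem) else "",
              length(x$replicates),
              if (x$born != 0) sprintf(", Born %+.3f", x$born) else ""))
  invisible(x)
}

#' Relative free energy from a thermodynamic cycle
#'
#' `ddG = dG(bound leg) - dG(reference leg)` with the SEMs propagated in
#' quadrature. The reference leg is the ligand pair in water for relative
#' binding, or the vacuum/water pair for relative hydration.
#'
#' @param leg_bound,leg_reference [perturbation_result()] objects with
#'   the same estimator and direction.
#' @return list `ddG`, `sem`.
#' @export
cycle_ddg <- function(leg_bound, leg_reference) {
  stopifnot(inherits(leg_bound, "perturbation_result"),
            inherits(leg_reference, "perturbation_result"))
  if (!identical(leg_bound$estimator, leg_reference$estimator))
    stop("legs were analyzed with different estimators")
  if (!identical(leg_bound$direction, leg_reference$direction))
    stop("direction mismatch between legs")
  list(ddG = leg_bound$dG - leg_reference$dG,
       sem = sqrt((leg_bound$sem %||% NA_real_)^2 + leg_reference$sem^2))
}

#' Hysteresis between forward and backward transformations
#'
#' The absolute discrepancy between the free energy of the forward
#' (annihilation) direction and the sign-corrected backward (creation)
#' direction of the same transformation: `|dG_forward + dG_backward|`,
#' where `dG_backward` is the backward-direction estimate as computed
#' (opposite sign convention to the forward one).
#'
#' @param dG_forward forward-direction free energy, kcal/mol.
#' @param dG_backward backward-direction free energy, kcal/mol.
#' @return non-negative hysteresis in kcal/mol.
#' @export
#' @examples
#' hysteresis(0.20, -0.19)  # 0.01
hysteresis <- function(dG_forward, dG_backward) abs(dG_forward + dG_backward)

# ---------------------------------------------------------------------------
# Energy-sample CSV dialect: columns lambda, sample, U_A, U_B, temperature.

#' Write window samples to the energy-sample CSV dialect
#'
#' @param windows list of [window_samples()].
#' @param path output CSV with columns `lambda`, `sample`, `U_A`, `U_B`,
#'   `temperature`.
#' @export
write_window_samples <- function(windows, path) {
  df <- do.call(rbind, lapply(windows, function(w)
    data.frame(lambda = w$lambda, sample = seq_along(w$U_A),
               U_A = w$U_A, U_B = w$U_B, temperature = w$temperature)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read window samples from the energy-sample CSV dialect
#'
#' @param path CSV written by [write_window_samples()] (or by any engine
#'   converter emitting the same columns).
#' @return list of [window_samples()], ordered by ascending lambda.
#' @export
read_window_samples <- function(path) {
  df <- utils::read.csv(path)
  need <- c("lambda", "U_A", "U_B")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$temperature)) df$temperature <- 298
  lams <- sort(unique(df$lambda))
  lapply(lams, function(l) {
    d <- df[df$lambda == l, ]
    window_samples(l, d$U_A, d$U_B, d$temperature[1])
  })
}
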