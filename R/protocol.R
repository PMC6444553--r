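# Lambda-window schedules, equilibration/production protocol plans,
# MD input-deck generation and simulation-time accounting.

#' Build a lambda-window schedule
#'
#' The alchemical pathway mixes the two end-state potentials as
#' `U_i = (1 - lambda_i) * U_A + lambda_i * U_B`. Schedules can run in
#' one branch from 0 to 1 (`start = 0`), from 1 to 0 (`start = 1`, the
#' classical annihilation direction), or in two branches propagating from
#' the mixed midpoint `lambda = 0.5` towards each end state
#' (`start = 0.5`; `n` must then be odd and the two branches share the
#' midpoint window). `"linear"` spacing is even; `"sigmoidal"` spacing
#' uses the warp `0.5 * (1 + tanh(s * (2u - 1)) / tanh(s))` with
#' sharpness `s`, which concentrates windows near the branch end points
#' where phase-space overlap between neighbours is poorest.
#'
#' @param n total number of lambda windows (>= 2; odd when `start = 0.5`).
#' @param mode `"linear"` or `"sigmoidal"`.
#' @param start 0, 1 or 0.5.
#' @param sharpness sigmoid sharpness `s` (default 2).
#' @return object of class `lambda_schedule` with `values` (all distinct
#'   lambdas, ascending), `branches` (list of 1 or 2 ordered branches in
#'   propagation order), `mode`, `start`.
#' @export
#' @examples
#' make_lambda_schedule(51, "linear", start = 1)$branches[[1]][1:3]
make_lambda_schedule <- function(n, mode = c("linear", "sigmoidal"),
                                 start = 1, sharpness = 2) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || n < 2) stop("need at least 2 lambda windows")
  if (!start %in% c(0, 0.5, 1)) stop("start must be 0, 0.5 or 1")
  warp <- function(m) {
    u <- seq(0, 1, length.out = m)
    if (mode == "linear") u else {
      v <- 0.5 * (1 + tanh(sharpness * (2 * u - 1)) / tanh(sharpness))
      v[1] <- 0; v[m] <- 1
      v
    }
  }
  if (start == 0.5) {
    if (n %% 2 == 0) stop("start = 0.5 needs an odd number of windows")
    m <- (n + 1) / 2
    up <- 0.5 + 0.5 * warp(m)        # 0.5 -> 1
    down <- 0.5 - 0.5 * warp(m)      # 0.5 -> 0
    branches <- list(up = up, down = down)
    values <- sort(unique(c(up, down)))
  } else {
    v <- warp(n)
    if (start == 1) v <- rev(v)
    branches <- list(main = v)
    values <- sort(v)
  }
  structure(list(values = values, branches = branches, mode = mode,
                 start = start, n = as.integer(n)),
            class = "lambda_schedule")
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat("<lambda_schedule> ", x$n, " windows, ", x$mode, ", start ", x$start,
      ", ", length(x$branches), " branch(es)\n", sep = "")
  invisible(x)
}

#' Linear mixing of the end-state potentials
#'
#' `U = (1 - lambda) * U_A + lambda * U_B`; lambda = 0 is pure state A,
#' lambda = 1 pure state B.
#'
#' @param U_A,U_B end-state potential energies (kcal/mol), vectorized.
#' @param lambda mixing coefficient in `[0, 1]`.
#' @return mixed potential in kcal/mol.
#' @export
mixed_potential <- function(U_A, U_B, lambda) {
  if (any(lambda < 0 | lambda > 1)) stop("lambda must lie in [0, 1]")
  (1 - lambda) * U_A + lambda * U_B
}

#' Default equilibration scheme
#'
#' A 31 ps heating phase from 0.1 to 298 K (five stages of 1, 2, 4, 8,
#' 16 ps) during which an initial 25 kcal/mol/Angstrom^2 positional
#' restraint on solute heavy atoms is stepwise released, followed by
#' 100 ps of unbiased, unrestrained equilibration at 298 K.
#'
#' @return data.frame `duration_ps`, `temperature_K`, `restraint`.
#' @export
default_equilibration <- function() {
  data.frame(
    duration_ps = c(1, 2, 4, 8, 16, 100),
    temperature_K = c(seq(0.1, 298, length.out = 5), 298),
    restraint = c(25, 12.5, 6.25, 2.5, 1, 0))
}

#' Construct a simulation protocol plan
#'
#' @param replicates number of parallel replicate simulations differing
#'   only in initial random velocities (default 10).
#' @param equilibration data.frame of stages (`duration_ps`,
#'   `temperature_K`, `restraint`), default [default_equilibration()]
#'   (131 ps total).
#' @param production_ps MD sampling per lambda window, ps (default 10).
#' @param timestep_fs integration time step, fs (default 1).
#' @param temperature_K production temperature (default 298).
#' @param sphere_restraint force constant restraining atoms outside the
#'   sphere, kcal/mol/Angstrom^2 (default 200).
#' @param cutoff nonbonded cutoff, Angstrom (default 10); atoms under
#'   alchemical transformation are always computed without cutoff.
#' @param shake_solvent constrain solvent bonds/angles (default TRUE).
#' @param master_seed master random seed from which distinct per-replicate
#'   velocity seeds are derived deterministically (default 42).
#' @return object of class `protocol_plan`.
#' @export
protocol_plan <- function(replicates = 10,
                          equilibration = default_equilibration(),
                          production_ps = 10, timestep_fs = 1,
                          temperature_K = 298,
                          sphere_restraint = 200, cutoff = 10,
                          shake_solvent = TRUE, master_seed = 42) {
  stopifnot(replicates >= 1, production_ps > 0, timestep_fs > 0,
            all(equilibration$duration_ps > 0))
  structure(list(replicates = as.integer(replicates),
                 equilibration = equilibration,
                 production_ps = production_ps, timestep_fs = timestep_fs,
                 temperature_K = temperature_K,
                 sphere_restraint = sphere_restraint, cutoff = cutoff,
                 shake_solvent = shake_solvent,
                 master_seed = as.integer(master_seed)),
            class = "protocol_plan")
}

# distinct deterministic per-replicate seeds below 2^31
replicate_seeds <- function(master_seed, replicates) {
  (as.integer(master_seed) + 104729L * seq_len(replicates)) %%
    .Machine$integer.max
}

#' Total simulation-time accounting
#'
#' Per leg: `replicates * (total equilibration + n_windows * production)`.
#' A relative free energy closes a thermodynamic cycle with two legs
#' (bound and reference), hence per perturbation twice the per-leg time.
#' With the defaults (10 replicates, 131 ps equilibration, 51 windows of
#' 10 ps) this gives 6.41 ns per leg and 12.82 ns per perturbation.
#'
#' @param plan a [protocol_plan()].
#' @param schedule a [lambda_schedule()] (its `n` is the window count).
#' @return list `per_leg_ns`, `per_perturbation_ns`, `windows`.
#' @export
total_sampling_time <- function(plan, schedule) {
  stopifnot(inherits(plan, "protocol_plan"),
            inherits(schedule, "lambda_schedule"))
  per_rep_ps <- sum(plan$equilibration$duration_ps) +
    schedule$n * plan$production_ps
  per_leg <- plan$replicates * per_rep_ps / 1000
  list(per_leg_ns = per_leg, per_perturbation_ns = 2 * per_leg,
       windows = schedule$n)
}

.fmt_lambda <- function(l) formatC(l, digits = 4, format = "f")

.inp_lines <- function(plan, lambda, steps, stepsize_fs, temperature,
                       restraint, seed = NULL, kind) {
  c(sprintf("! dualfep %s input", kind),
    "[MD]",
    sprintf("steps        %d", steps),
    sprintf("stepsize     %g", stepsize_fs),
    sprintf("temperature  %g", temperature),
    if (!is.null(seed)) sprintf("random_seed  %d", seed),
    "[cut-offs]",
    sprintf("solute_solute   %g", plan$cutoff),
    sprintf("solvent_solvent %g", plan$cutoff),
    sprintf("solute_solvent  %g", plan$cutoff),
    "q_atom          0   ! no cutoff for FEP atoms",
    "[sphere]",
    sprintf("shell_force  %g", plan$sphere_restraint),
    "[solvent]",
    if (plan$shake_solvent) "shake_solvent on" else "shake_solvent off",
    "[intervals]",
    "energy       10",
    if (restraint > 0) c("[sequence_restraints]",
                         sprintf("solute_heavy %g", restraint)),
    "[lambdas]",
    sprintf("%s %s", .fmt_lambda(1 - lambda), .fmt_lambda(lambda)))
}

#' Write the MD input deck for an FEP leg
#'
#' One subdirectory per replicate (and per branch for midpoint-start
#' schedules) containing the equilibration inputs followed by one
#' production input per lambda window. Each replicate gets a distinct
#' random-velocity seed derived from the plan's master seed, so two calls
#' with the same plan produce byte-identical decks.
#'
#' @param plan a [protocol_plan()].
#' @param schedule a [lambda_schedule()].
#' @param spec optional `dual_topology_spec`; when given, its FEP file is
#'   written alongside the deck.
#' @param outdir output directory (created if needed).
#' @param cluster_template optional path to a submission-script template;
#'   occurrences of `{jobname}` and `{ntasks}` are substituted and the
#'   result written as `submit.sh`.
#' @return data.frame manifest (`path`, `replicate`, `branch`, `kind`,
#'   `window`, `lambda`), invisibly.
#' @export
write_md_inputs <- function(plan, schedule, spec = NULL, outdir,
                            cluster_template = NULL) {
  stopifnot(inherits(plan, "protocol_plan"),
            inherits(schedule, "lambda_schedule"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  if (!is.null(spec)) write_fep_file(spec, file.path(outdir, "dualtop.fep"))
  seeds <- replicate_seeds(plan$master_seed, plan$replicates)
  eq <- plan$equilibration
  manifest <- list()
  for (r in seq_len(plan$replicates)) {
    for (b in names(schedule$branches)) {
      lam <- schedule$branches[[b]]
      dir <- file.path(outdir, sprintf("rep_%02d", r),
                       if (length(schedule$branches) > 1) b else "")
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      l0 <- lam[1]
      for (e in seq_len(nrow(eq))) {
        p <- file.path(dir, sprintf("eq_%d.inp", e))
        writeLines(.inp_lines(plan, l0,
                              steps = round(1000 * eq$duration_ps[e] /
                                              plan$timestep_fs),
                              stepsize_fs = plan$timestep_fs,
                              temperature = eq$temperature_K[e],
                              restraint = eq$restraint[e],
                              seed = if (e == 1) seeds[r], "equilibration"), p)
        manifest[[length(manifest) + 1]] <- data.frame(
          path = p, replicate = r, branch = b, kind = "equilibration",
          window = NA_integer_, lambda = l0, stringsAsFactors = FALSE)
      }
      for (w in seq_along(lam)) {
        p <- file.path(dir, sprintf("md_%03d_%s.inp", w, .fmt_lambda(lam[w])))
        writeLines(.inp_lines(plan, lam[w],
                              steps = round(1000 * plan$production_ps /
                                              plan$timestep_fs),
                              stepsize_fs = plan$timestep_fs,
                              temperature = plan$temperature_K,
                              restraint = 0, seed = NULL, "production"), p)
        manifest[[length(manifest) + 1]] <- data.frame(
          path = p, replicate = r, branch = b, kind = "production",
          window = w, lambda = lam[w], stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(cluster_template)) {
    tpl <- readLines(cluster_template, warn = FALSE)
    tpl <- gsub("{jobname}", basename(outdir), tpl, fixed = TRUE)
    tpl <- gsub("{ntasks}", plan$replicates, tpl, fixed = TRUE)
    writeLines(tpl, file.path(outdir, "submit.sh"))
  }
  invisible(do.call(rbind, manifest))
}
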