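# Benchmark statistics between calculated and experimental free energies:
# MAE, Pearson R^2 with Fisher-z confidence intervals, OLS regression,
# IC50-ratio conversion and report rendering.

#' Construct a benchmark table
#'
#' Pairs calculated against experimental free energies (dG or ddG,
#' kcal/mol) for a ligand series. The reference ligand of a radial
#' perturbation design may lack a calculated value (`NA`): it is dropped
#' from statistics unless explicitly counted as zero deviation.
#'
#' @param id ligand identifiers.
#' @param experimental experimental values, kcal/mol.
#' @param calculated calculated values, kcal/mol (`NA` for the reference
#'   row).
#' @param sem optional SEMs of the calculated values.
#' @param reference optional id of the reference ligand.
#' @return data.frame of class `benchmark_table`.
#' @export
benchmark_table <- function(id, experimental, calculated, sem = NA,
                            reference = NULL) {
  stopifnot(length(id) == length(experimental),
            length(experimental) == length(calculated))
  df <- data.frame(id = as.character(id), experimental = experimental,
                   calculated = calculated, sem = sem,
                   stringsAsFactors = FALSE)
  paired <- !is.na(df$calculated)
  if (any(paired & !is.finite(df$experimental)))
    stop("paired experimental values must be finite")
  attr(df, "reference") <- reference
  class(df) <- c("benchmark_table", "data.frame")
  df
}

#' Convert an IC50 ratio to a relative binding free energy
#'
#' `ddG = RT * log(IC50_B / IC50_A)` with R = 1.9872e-3 kcal/mol/K: a
#' tenfold potency loss of B relative to A costs about 1.36 kcal/mol at
#' 298 K.
#'
#' @param ic50_A,ic50_B IC50 concentrations (same units, > 0).
#' @param temperature Kelvin (default 298).
#' @return ddG(A to B) in kcal/mol.
#' @export
ic50_to_ddg <- function(ic50_A, ic50_B, temperature = 298) {
  if (any(ic50_A <= 0) || any(ic50_B <= 0))
    stop("IC50 values must be positive")
  thermal_energy(temperature) * log(ic50_B / ic50_A)
}

#' Mean absolute error between calculated and experimental columns
#'
#' @param table a [benchmark_table()] (or data.frame with `experimental`
#'   and `calculated` columns).
#' @param include_reference_as_zero count rows without a calculated value
#'   (the reference ligand) as zero deviation instead of dropping them.
#' @return MAE in kcal/mol.
#' @export
mae <- function(table, include_reference_as_zero = FALSE) {
  dev <- abs(table$calculated - table$experimental)
  if (include_reference_as_zero) dev[is.na(dev)] <- 0
  dev <- dev[!is.na(dev)]
  if (!length(dev)) stop("no paired rows")
  mean(dev)
}

#' Squared Pearson correlation of calculated vs experimental values
#'
#' @param table a [benchmark_table()]; rows without a calculated value
#'   are dropped.
#' @return R^2.
#' @export
pearson_r2 <- function(table) {
  ok <- stats::complete.cases(table$experimental, table$calculated)
  x <- table$experimental[ok]; y <- table$calculated[ok]
  if (length(x) < 3) stop("need at least 3 paired rows")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a column")
  stats::cor(x, y)^2
}

#' Fisher-z confidence interval for a Pearson correlation
#'
#' `tanh(atanh(r) +/- z_(1-alpha/2) / sqrt(n - 3))`, appropriate for the
#' small ligand series typical of FEP benchmarks.
#'
#' @param r Pearson correlation coefficient.
#' @param n number of paired observations (>= 4).
#' @param alpha significance level (default 0.05 for a 95 percent CI).
#' @return numeric `c(lower, upper)`; for `|r| = 1` the degenerate
#'   interval `c(r, r)` with attribute `degenerate = TRUE`.
#' @export
fisher_ci <- function(r, n, alpha = 0.05) {
  if (n < 4) stop("Fisher-z interval needs n >= 4")
  stopifnot(abs(r) <= 1)
  if (abs(r) == 1)
    return(structure(c(r, r), degenerate = TRUE))
  z <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
  tanh(atanh(r) + c(-z, z))
}

#' Ordinary least-squares fit of one column on the other
#'
#' Default regresses the calculated values on the experimental ones (the
#' usual benchmark scatter-plot orientation); set
#' `response = "experimental"` for the opposite convention.
#'
#' @param table a [benchmark_table()].
#' @param response which column is the response.
#' @return list `slope`, `intercept`, `fit` (the `lm` object).
#' @export
ols_fit <- function(table, response = c("calculated", "experimental")) {
  response <- match.arg(response)
  ok <- stats::complete.cases(table$experimental, table$calculated)
  d <- as.data.frame(table)[ok, ]
  if (nrow(d) < 2) stop("need at least 2 paired rows")
  pred <- setdiff(c("calculated", "experimental"), response)
  if (stats::sd(d[[pred]]) == 0) stop("degenerate predictor variance")
  fit <- stats::lm(stats::reformulate(pred, response), data = d)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]), fit = fit)
}

#' Summary statistics of a benchmark table
#'
#' @param table a [benchmark_table()].
#' @param include_reference_as_zero passed to [mae()].
#' @param alpha significance level for the Fisher-z CI.
#' @return list `n`, `mae`, `r2`, `r2_ci`, `slope`, `intercept`.
#' @export
benchmark_stats <- function(table, include_reference_as_zero = FALSE,
                            alpha = 0.05) {
  ok <- stats::complete.cases(table$experimental, table$calculated)
  r2 <- pearson_r2(table)
  fit <- ols_fit(table)
  list(n = sum(ok) + if (include_reference_as_zero) sum(!ok) else 0L,
       mae = mae(table, include_reference_as_zero),
       r2 = r2,
       r2_ci = fisher_ci(sign(stats::cor(table$experimental[ok],
                                         table$calculated[ok])) * sqrt(r2),
                         sum(ok), alpha),
       slope = fit$slope, intercept = fit$intercept)
}

#' Render a benchmark report as CSV, JSON and plain text
#'
#' Writes `<base>.csv` (the table plus the +/-1 and +/-2 kcal/mol
#' agreement bands around the experimental values used in the standard
#' scatter plot), `<base>.json` (tables and statistics, round-trippable),
#' and `<base>.txt` (human-readable summary, values shown at 2 decimals).
#'
#' @param tables named list of [benchmark_table()] objects (may be
#'   empty).
#' @param base output path prefix.
#' @param include_reference_as_zero passed to [mae()].
#' @return list of per-table statistics, invisibly.
#' @export
render_report <- function(tables, base, include_reference_as_zero = FALSE) {
  stats_list <- list()
  rows <- list()
  txt <- character()
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    st <- tryCatch(benchmark_stats(tb, include_reference_as_zero),
                   error = function(e) NULL)
    stats_list[[nm]] <- st
    d <- as.data.frame(tb)
    d$dataset <- nm
    d$band1_lo <- d$experimental - 1; d$band1_hi <- d$experimental + 1
    d$band2_lo <- d$experimental - 2; d$band2_hi <- d$experimental + 2
    rows[[nm]] <- d
    txt <- c(txt, sprintf("== %s ==", nm),
             if (is.null(st)) "  (too few rows for statistics)" else
               sprintf("  n = %d  MAE = %.2f  R2 = %.2f [%.2f-%.2f]  slope = %.2f  intercept = %.2f",
                       st$n, st$mae, st$r2, st$r2_ci[1], st$r2_ci[2],
                       st$slope, st$intercept))
  }
  all <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), experimental = numeric(),
               calculated = numeric(), sem = numeric(), dataset = character())
  utils::write.csv(all, paste0(base, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(tables = lapply(tables, as.data.frame),
         statistics = lapply(stats_list, function(s)
           if (is.null(s)) NULL else s[c("n", "mae", "r2", "r2_ci",
                                         "slope", "intercept")])),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(if (length(txt)) txt else "empty report", paste0(base, ".txt"))
  invisible(stats_list)
}
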