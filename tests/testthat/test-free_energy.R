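# Free-energy estimators and their statistical combination.

test_that("neighbour perturbation energies follow the linear mixing rule", {
  w1 <- window_samples(0.10, U_A = c(1, 2, 3), U_B = c(1, 2, 3))
  w2 <- window_samples(0.12, U_A = c(0, 1, 2), U_B = c(5, 6, 7))
  expect_equal(neighbor_delta_u(w1, w2)$forward, c(0, 0, 0))
  du <- neighbor_delta_u(w2, window_samples(0.14, 1, 2))
  expect_equal(du$forward, 0.02 * (w2$U_B - w2$U_A), tolerance = 1e-12)

  set.seed(30)
  wa <- window_samples(0.3, rnorm(50), rnorm(50))
  wb <- window_samples(0.7, rnorm(50), rnorm(50))
  du <- neighbor_delta_u(wa, wb)
  # brute-force oracle: U(lambda_j) - U(lambda_i) on each sample
  fwd <- mixed_potential(wa$U_A, wa$U_B, 0.7) -
    mixed_potential(wa$U_A, wa$U_B, 0.3)
  bwd <- mixed_potential(wb$U_A, wb$U_B, 0.3) -
    mixed_potential(wb$U_A, wb$U_B, 0.7)
  expect_equal(du$forward, fwd, tolerance = 1e-12)
  expect_equal(du$backward, bwd, tolerance = 1e-12)
  expect_error(neighbor_delta_u(wa, window_samples(0.3, 1, 2)), "identical")
})

test_that("Zwanzig and overlap sampling reproduce closed forms", {
  expect_equal(zwanzig(rep(0, 10)), 0)
  expect_equal(zwanzig(rep(2.5, 10)), 2.5)
  kT <- kB * 298
  c0 <- 1.7
  expect_equal(zwanzig(c(0, c0)), -kT * log((1 + exp(-c0 / kT)) / 2),
               tolerance = 1e-12)
  expect_equal(overlap_sampling(rep(0, 5), rep(0, 5)), 0)
  expect_equal(overlap_sampling(rep(3.2, 5), rep(-3.2, 5)), 3.2)
})

test_that("BAR solves Bennett's implicit equation", {
  expect_equal(bar(rep(0, 8), rep(0, 8)), 0, tolerance = 1e-7)

  # tiny sample set vs a brute-force 1-D root scan of the implicit equation
  set.seed(41)
  duf <- rnorm(5, 1.1, 0.7); dur <- rnorm(5, -0.8, 0.7)
  kT <- kB * 298
  M <- log(5 / 5)
  imp <- function(x)
    sum(1 / (1 + exp(M + (duf - x) / kT))) -
      sum(1 / (1 + exp(-M + (dur + x) / kT)))
  grid <- seq(-5, 5, 1e-5)
  root <- grid[which.min(abs(vapply(grid, imp, 0)))]
  expect_equal(bar(duf, dur, tol = 1e-9), root, tolerance = 2e-5)

  # unequal sample counts engage the log(n_f/n_r) term
  set.seed(42)
  g <- gen_gaussian_work(0.5, kT, 4000, seed = 9)
  est <- bar(g$dU_f[1:4000], g$dU_r[1:1000])
  se <- bar_se(g$dU_f[1:4000], g$dU_r[1:1000], est)
  expect_lt(abs(est - 0.5), 3 * se)

  # Gaussian work with known answer: dG_true = mu - sigma^2 / (2 kT)
  sig <- 1.5 * kT
  set.seed(13)
  n <- 5000
  duf <- rnorm(n, 2.0 + sig^2 / (2 * kT), sig)
  dur <- rnorm(n, -2.0 + sig^2 / (2 * kT), sig)
  est <- bar(duf, dur)
  expect_lt(abs(est - 2.0), 3 * bar_se(duf, dur, est))

  # antisymmetry under swapping forward and reverse
  expect_equal(bar(duf, dur), -bar(dur, duf), tolerance = 1e-9)

  # non-convergence carries the last iterate
  err <- tryCatch(bar(duf, dur, max_iter = 2L),
                  dualfep_bar_nonconvergence = function(e) e)
  expect_s3_class(err, "dualfep_bar_nonconvergence")
  expect_true(is.numeric(err$last))
})

test_that("estimators agree within Monte-Carlo error at high overlap", {
  kT <- kB * 298
  g <- gen_gaussian_work(0.8, kT, 5000, seed = 21)
  b <- bar(g$dU_f, g$dU_r)
  o <- overlap_sampling(g$dU_f, g$dU_r)
  zf <- zwanzig(g$dU_f)
  zr <- -zwanzig(g$dU_r)
  tol <- 3 * (zwanzig_se(g$dU_f) + zwanzig_se(g$dU_r) +
                os_se(g$dU_f, g$dU_r))
  expect_lt(abs(zf - b), tol)
  expect_lt(abs(zr - b), tol)
  expect_lt(abs(o - b), tol)
})

test_that("window summation and branch combination are plain arithmetic", {
  expect_equal(sum_windows(3.2), 3.2)
  expect_equal(combine_branches(2, -3), 5)
  expect_equal(combine_branches(1.4, 1.4), 0)

  # reversed branch negates the sum
  hw <- gen_harmonic_pair(1, 4, n_windows = 11, n = 800, seed = 6)
  fwd <- analyze_leg(hw, "bar")
  bwd <- analyze_leg(rev(hw), "bar")
  expect_equal(fwd$dG, -bwd$dG, tolerance = 1e-7)

  # midpoint route agrees with the direct route on the same samples
  hw51 <- gen_harmonic_pair(1, 4, n_windows = 51, n = 1500, seed = 2)
  direct <- analyze_leg(hw51, "bar")$dG
  up <- analyze_leg(hw51[26:51], "bar")$dG       # 0.5 -> 1
  down <- analyze_leg(hw51[26:1], "bar")$dG      # 0.5 -> 0
  expect_equal(combine_branches(up, down), direct, tolerance = 1e-9)
  expect_lt(abs(combine_branches(up, down) - harmonic_delta_f(1, 4)), 0.05)
})

test_that("Born correction evaluates exactly and is monotone", {
  expect_equal(born_correction(0, 25), 0)
  expect_equal(born_correction(-1, 25, epsilon = 1), 0)
  expect_equal(born_correction(-1, 25, 80), -332 / 50 * (79 / 80))
  expect_equal(born_correction(-1, 25, 80), -6.557, tolerance = 1e-4)
  # magnitude grows with |Q| and shrinks with r_Born
  qs <- seq(0.5, 3, 0.5)
  expect_true(all(diff(abs(born_correction(qs, 25, 80))) > 0))
  rs <- seq(10, 40, 5)
  expect_true(all(diff(abs(born_correction(-1, rs, 80))) < 0))
})

test_that("replicate and cycle statistics propagate correctly", {
  cr <- combine_replicates(rep(1.5, 6))
  expect_equal(cr$mean, 1.5)
  expect_equal(cr$sem, 0)
  ab <- combine_replicates(c(2, 5))
  expect_equal(ab$mean, 3.5)
  expect_equal(ab$sem, abs(2 - 5) / 2)
  one <- combine_replicates(4.2)
  expect_false(one$sem_defined)
  expect_error(combine_replicates(numeric()), "no replicate")

  bound <- perturbation_result(c(-5.3, -4.7), leg = "bound")
  water <- perturbation_result(c(-5.3, -4.7), leg = "water")
  expect_equal(cycle_ddg(bound, water)$ddG, 0)
  b2 <- perturbation_result(-5.0 + c(-0.3, 0.3), leg = "bound")  # SEM 0.3
  w2 <- perturbation_result(-3.0 + c(-0.4, 0.4), leg = "water")  # SEM 0.4
  cc <- cycle_ddg(b2, w2)
  expect_equal(cc$ddG, -2.0)
  expect_equal(cc$sem, 0.5)
  wrong <- perturbation_result(c(-3, -3), leg = "water", direction = "B->A")
  expect_error(cycle_ddg(b2, wrong), "direction")

  # null self-perturbation cycle is zero within 3 SEM
  legs <- lapply(1:2, function(k) {
    reps <- vapply(1:6, function(r) {
      g <- gen_gaussian_work(0, kB * 298, 2000, seed = 100 * k + r)
      bar(g$dU_f, g$dU_r)
    }, 0)
    perturbation_result(reps, leg = c("bound", "water")[k])
  })
  cc <- cycle_ddg(legs[[1]], legs[[2]])
  expect_lt(abs(cc$ddG), 3 * cc$sem + 1e-12)
})

test_that("hysteresis is the sign-corrected forward/backward discrepancy", {
  expect_equal(hysteresis(0.20, -0.19), 0.01)
  expect_equal(hysteresis(1.3, -1.3), 0)
  expect_equal(hysteresis(8.16, -7.20), 0.96)
})

test_that("triangle cycle closure holds within propagated error", {
  kT <- kB * 298
  truths <- c(AB = 0.9, BC = -1.4, CA = 0.5)  # sums to zero
  n <- 4000
  est <- se <- numeric(3)
  for (i in 1:3) {
    g <- gen_gaussian_work(truths[i], 1.2 * kT, n, seed = 60 + i)
    est[i] <- bar(g$dU_f, g$dU_r)
    se[i] <- bar_se(g$dU_f, g$dU_r, est[i])
  }
  expect_lt(abs(sum(est)), 3 * sqrt(sum(se^2)))
})

test_that("energy-sample CSV files round-trip", {
  hw <- gen_harmonic_pair(1, 2, n_windows = 5, n = 20, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_window_samples(hw, f)
  back <- read_window_samples(f)
  expect_length(back, 5)
  for (i in 1:5) {
    expect_equal(back[[i]]$lambda, hw[[i]]$lambda)
    expect_equal(back[[i]]$U_A, hw[[i]]$U_A, tolerance = 1e-12)
    expect_equal(back[[i]]$U_B, hw[[i]]$U_B, tolerance = 1e-12)
  }
  expect_error(read_window_samples({
    f2 <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), f2); f2
  }), "missing column")
})
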