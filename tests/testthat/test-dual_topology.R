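# Dual-topology specification building, atom pairing and restraints.

test_that("self-perturbation pairs every atom at distance zero", {
  lig <- gen_toy_ligand_pair(5, 0, 0, seed = 4)$A
  p <- pair_equivalent_atoms(lig, lig, cutoff = 0.25)
  expect_equal(nrow(p), 5)
  expect_equal(p$distance, rep(0, 5))
  expect_equal(p$index_A, p$index_B)
})

test_that("pairing honours cutoff, element identity and greedy order", {
  mk <- function(xyz, el) ligand_topology("L", data.frame(
    name = paste0("A", seq_len(nrow(xyz))), element = el, type_code = "CT",
    charge = 0, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  a <- mk(rbind(c(0, 0, 0), c(5, 0, 0)), "C")
  b <- mk(rbind(c(0.1, 0, 0), c(5.5, 0, 0)), "C")
  p <- pair_equivalent_atoms(a, b, cutoff = 0.25)
  expect_equal(nrow(p), 1)
  expect_equal(c(p$index_A, p$index_B), c(1, 1))
  # element mismatch blocks the pair
  b2 <- mk(rbind(c(0.1, 0, 0), c(5.5, 0, 0)), c("N", "C"))
  expect_warning(p2 <- pair_equivalent_atoms(a, b2, cutoff = 0.25), "unrestrained")
  expect_equal(nrow(p2), 0)
  expect_equal(nrow(pair_equivalent_atoms(a, b2, cutoff = 0.25,
                                          require_element_match = FALSE)), 1)

  # random clouds match a brute-force greedy oracle
  set.seed(17)
  A <- matrix(runif(24, 0, 4), ncol = 3)
  B <- matrix(runif(30, 0, 4), ncol = 3)
  la <- mk(A, "C"); lb <- mk(B, "C")
  got <- pair_equivalent_atoms(la, lb, cutoff = 1.0)
  want <- greedy_match_oracle(A, B, rep("C", 8), rep("C", 10), 1.0)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got[order(got$index_A), c("index_A", "index_B")],
               as.data.frame(want[order(want[, 1]), , drop = FALSE]),
               ignore_attr = TRUE)
})

test_that("half-harmonic restraint energy is flat then quadratic", {
  r <- restraint_spec(2.0, c(0, 0.2))
  expect_equal(restraint_energy(0.1, r), 0)
  expect_equal(restraint_energy(0.2, r), 0)
  expect_equal(restraint_energy(1.2, r), 0.5 * 2.0 * 1.0^2)
  # continuous and once-differentiable at the window edge
  eps <- 1e-8
  expect_lt(restraint_energy(0.2 + eps, r), 1e-12)
  expect_lt((restraint_energy(0.2 + eps, r) - 0) / eps, 1e-6)
  expect_error(restraint_energy(-0.1, r))
})

test_that("build_dual_topology keeps per-state bookkeeping exact", {
  pr <- gen_toy_ligand_pair(5, 3, 2, seed = 8)
  spec <- build_dual_topology(pr$A, pr$B)
  # 5 common + 3 unique and 5 common + 2 unique concatenate to 15 atoms
  expect_equal(nrow(spec$atoms), 15)
  expect_equal(spec$n_A, 8)
  expect_equal(spec$n_B, 7)
  expect_equal(sum(spec$state_A$charge), net_charge(pr$A))
  expect_equal(sum(spec$state_B$charge), net_charge(pr$B))
  isA <- spec$atoms$lig == "A"
  expect_true(all(spec$state_A$type_code[!isA] == "DUM"))
  expect_true(all(spec$state_B$type_code[isA] == "DUM"))
  expect_true(all(spec$state_A$charge[!isA] == 0))
  # softcore sits on the dummy-state vdW of each ligand
  expect_true(all(spec$softcore$state_B[isA] > 0))
  expect_true(all(spec$softcore$state_A[isA] == 0))
  expect_false(spec$needs_born)

  # a net-charge change flags the Born correction
  chgA <- pr$A
  chgA$atoms$charge <- chgA$atoms$charge - 1 / nrow(chgA$atoms)
  spec2 <- build_dual_topology(chgA, pr$B)
  expect_true(spec2$needs_born)
  expect_equal(spec2$net_charge_A, -1, tolerance = 1e-9)
  expect_equal(spec2$net_charge_B, 0, tolerance = 1e-9)
  expect_error(build_dual_topology(pr$A, pr$B, max_atoms = 10L),
               "format limit")
})

test_that("spec is symmetric under swapping the two ligands", {
  pr <- gen_toy_ligand_pair(4, 2, 1, seed = 12)
  ab <- build_dual_topology(pr$A, pr$B)
  ba <- build_dual_topology(pr$B, pr$A)
  # swapping state labels of (B,A) reproduces (A,B) up to atom order
  ordAB <- order(spec_key <- paste(ab$atoms$orig_name, ab$atoms$lig))
  ordBA <- order(paste(ba$atoms$orig_name,
                       ifelse(ba$atoms$lig == "A", "B", "A")))
  expect_equal(ab$state_A$charge[ordAB], ba$state_B$charge[ordBA])
  expect_equal(ab$state_B$charge[ordAB], ba$state_A$charge[ordBA])
  expect_equal(ab$state_A$type_code[ordAB], ba$state_B$type_code[ordBA])
  expect_equal(ab$needs_born, ba$needs_born)
})

test_that("no bonded term crosses the partition; restraints cancel by construction", {
  pr <- gen_toy_ligand_pair(6, 2, 3, seed = 5)
  spec <- build_dual_topology(pr$A, pr$B)
  isA <- spec$atoms$lig == "A"
  for (term in c("bonds", "angles", "torsions", "impropers")) {
    m <- spec[[term]]
    if (nrow(m))
      expect_true(all(apply(m, 1, function(i) length(unique(isA[i])) == 1)))
  }
  rp <- spec$restraint_pairs
  expect_gt(nrow(rp), 0)
  # each pair couples one A and one B atom: one member is a dummy in
  # every end state, so the restraint term cancels between end states
  expect_true(all(isA[rp$i] & !isA[rp$j]))
  expect_true(all(spec$state_B$type_code[rp$i] == "DUM"))
  expect_true(all(spec$state_A$type_code[rp$j] == "DUM"))
  expect_equal(anyDuplicated(c(rp$i, rp$j)), 0)
  expect_true(validate_dual_topology(spec))
})

test_that("FEP stage files round-trip and count correctly", {
  pr <- gen_toy_ligand_pair(5, 3, 2, seed = 8)
  spec <- build_dual_topology(pr$A, pr$B)
  f <- tempfile(fileext = ".fep")
  write_fep_file(spec, f)
  back <- read_fep_file(f)
  expect_equal(back$atoms$name, spec$atoms$name)
  expect_equal(back$state_A$charge, spec$state_A$charge, tolerance = 1e-8)
  expect_equal(back$state_B$type_code, spec$state_B$type_code)
  expect_equal(back$restraint_pairs[, c("i", "j")],
               spec$restraint_pairs[, c("i", "j")], ignore_attr = TRUE)
  expect_equal(back$net_charge_A, spec$net_charge_A, tolerance = 1e-6)

  # counting oracle on the emitted file
  lines <- readLines(f)
  n <- nrow(spec$atoms)
  expect_equal(sum(grepl("^\\s*\\d", lines[(which(lines == "[atoms]") + 1):
                                             (which(lines == "[change_charges]") - 1)])), n)
  expect_equal(length(lines[(which(lines == "[distance_restraints]") + 1):
                              length(lines)]), nrow(spec$restraint_pairs))

  # self-perturbation: the two state columns describe the same system
  pr0 <- gen_toy_ligand_pair(4, 0, 0, seed = 3)
  self <- build_dual_topology(pr0$A, pr0$A)
  qA <- self$state_A$charge; qB <- self$state_B$charge
  expect_equal(sort(qA), sort(qB))
  expect_equal(sort(self$state_A$type_code), sort(self$state_B$type_code))

  # three-stage scheme emits one file per stage
  f3 <- tempfile(fileext = ".fep")
  spec3 <- build_dual_topology(pr$A, pr$B, stage_scheme = "three_stage")
  paths <- write_fep_file(spec3, f3)
  expect_length(paths, 3)
  expect_true(all(file.exists(paths)))
  st1 <- read_fep_file(paths[1])
  expect_true(all(st1$state_B$charge == 0))  # stage 1 ends fully discharged

  # tampered restraint index is an integrity error
  broken <- spec
  broken$restraint_pairs$j[1] <- 999L
  expect_error(write_fep_file(broken, f), "integrity")
})
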