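# Spherical-boundary system preparation.

mk_lig <- function(xyz, element = "C") {
  n <- nrow(xyz)
  ligand_topology("LIG", data.frame(
    name = paste0("X", seq_len(n)), element = element, type_code = "CT",
    charge = 0, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

test_that("sphere_center modes reduce to the expected centroids", {
  a <- mk_lig(rbind(c(0, 0, 0)))
  b <- mk_lig(rbind(c(2, 0, 0)))
  expect_equal(sphere_center("cog_two_ligands", a, b), c(1, 0, 0))
  expect_equal(sphere_center("cog_two_ligands", a, a), c(0, 0, 0))
  set.seed(3)
  xyz <- matrix(runif(18, -5, 5), ncol = 3)
  two <- list(mk_lig(xyz[1:3, , drop = FALSE]),
              mk_lig(xyz[4:6, , drop = FALSE]))
  expect_equal(sphere_center("cog_two_ligands", two[[1]], two[[2]]),
               colMeans(xyz), ignore_attr = TRUE)
  expect_equal(sphere_center("cartesian", xyz = c(1, 2, 3)), c(1, 2, 3))
  expect_error(sphere_center("ligand_atom", ligA = a, atom_name = "Q9"),
               "empty selection")
})

test_that("classify_atoms partitions by distance with a closed boundary", {
  sph <- simulation_sphere(c(0, 0, 0), 25)
  at <- data.frame(name = "X", resname = "ALA", resid = 1,
                   x = c(25, 23, 10, 26), y = 0, z = 0, element = "C")
  s <- classify_atoms(md_structure(at), sph, shell_width = 3)
  expect_equal(s$atoms$in_sphere, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(s$atoms$region, c("shell", "shell", "inside", "outside"))

  set.seed(21)
  cloud <- data.frame(name = "X", resname = "ALA", resid = 1,
                      x = runif(100, -30, 30), y = runif(100, -30, 30),
                      z = runif(100, -30, 30), element = "C")
  s <- classify_atoms(md_structure(cloud), sph, shell_width = 3)
  d <- sqrt(cloud$x^2 + cloud$y^2 + cloud$z^2)     # brute-force oracle
  expect_equal(sum(s$atoms$region == "inside"), sum(d <= 22))
  expect_equal(sum(s$atoms$region == "shell"), sum(d > 22 & d <= 25))
  expect_equal(sum(s$atoms$region == "outside"), sum(d > 25))
  # partition property and rigid-translation invariance
  expect_equal(sort(unique(s$atoms$region)) %in%
                 c("inside", "outside", "shell"), rep(TRUE, 3))
  shift <- c(7, -4, 11)
  cloud2 <- cloud
  cloud2[, c("x", "y", "z")] <- cloud[, c("x", "y", "z")] +
    rep(shift, each = 100)
  s2 <- classify_atoms(md_structure(cloud2),
                       simulation_sphere(shift, 25), shell_width = 3)
  expect_equal(s2$atoms$region, s$atoms$region)
})

test_that("water-overlap removal is whole-residue and matches brute force", {
  lig <- mk_lig(rbind(c(0, 0, 0), c(1.5, 0, 0)))
  mk_waters <- function(oxy) {
    oxy <- unname(as.matrix(oxy))
    md_structure(do.call(rbind, lapply(seq_len(nrow(oxy)), function(i)
      data.frame(name = c("O", "H1", "H2"), resname = "HOH", resid = i,
                 x = oxy[i, 1] + c(0, 0.96, -0.24),
                 y = oxy[i, 2] + c(0, 0, 0.93), z = rep(oxy[i, 3], 3),
                 element = c("O", "H", "H"), row.names = NULL))))
  }
  far <- mk_waters(rbind(c(10, 10, 10), c(-9, 0, 4)))
  kept <- remove_overlapping_waters(far, lig, lig, cutoff = 2.4)
  expect_equal(kept$atoms, far$atoms)
  expect_equal(attr(kept, "n_removed"), 0L)

  near <- mk_waters(rbind(c(1.0, 0, 0), c(9, 9, 9)))
  kept <- remove_overlapping_waters(near, lig, lig, cutoff = 2.4)
  expect_equal(unique(kept$atoms$resid), 2)
  expect_equal(nrow(kept$atoms), 3)  # whole residues, never single atoms

  set.seed(9)
  grid <- as.matrix(expand.grid(x = seq(-6, 6, 3), y = seq(-6, 6, 3),
                                z = c(0, 3)))[1:50, ]
  waters <- mk_waters(grid)
  ligB <- mk_lig(rbind(c(3, 3, 0), c(4.5, 3, 0.4)))
  out <- remove_overlapping_waters(waters, lig, ligB, cutoff = 2.4)
  # brute-force oracle over every (water atom, ligand heavy atom) pair
  heavy <- rbind(as.matrix(lig$atoms[, c("x", "y", "z")]),
                 as.matrix(ligB$atoms[, c("x", "y", "z")]))
  wa <- waters$atoms
  clash <- vapply(unique(wa$resid), function(r) {
    w <- as.matrix(wa[wa$resid == r, c("x", "y", "z")])
    any(as.matrix(stats::dist(rbind(w, heavy)))[1:3, -(1:3)] <= 2.4)
  }, TRUE)
  expect_setequal(unique(out$atoms$resid), unique(wa$resid)[!clash])
  # subset + monotonicity: a larger cutoff never retains more waters
  for (cut in c(1, 2.4, 4, 8)) {
    o1 <- remove_overlapping_waters(waters, lig, ligB, cutoff = cut)
    o2 <- remove_overlapping_waters(waters, lig, ligB, cutoff = cut + 1)
    expect_true(all(o1$atoms$resid %in% wa$resid))
    expect_true(all(o2$atoms$resid %in% o1$atoms$resid))
  }
})

test_that("boundary neutralization renames exactly the exposed residues", {
  sph <- simulation_sphere(c(0, 0, 0), 25)
  mk_res <- function(resname, resid, at) {
    grp <- list(ASP = c("CG", "OD1", "OD2"), LYS = "NZ", GLU = c("CD", "OE1", "OE2"),
                ARG = c("CZ", "NE", "NH1", "NH2"), HIP = c("ND1", "NE2"))[[resname]]
    nm <- c("N", "CA", "C", grp)
    data.frame(name = nm, resname = resname, resid = resid,
               x = at[1] + seq_along(nm) * 0.3, y = at[2], z = at[3],
               element = substr(nm, 1, 1))
  }
  inside <- md_structure(mk_res("ASP", 1, c(0, 0, 0)))
  out <- neutralize_outside(inside, sph)
  expect_equal(out$structure$atoms$resname, inside$atoms$resname)
  expect_equal(nrow(out$log), 0)

  outside <- md_structure(mk_res("LYS", 1, c(30, 0, 0)))
  out <- neutralize_outside(outside, sph)
  expect_true(all(out$structure$atoms$resname == "LYN"))
  expect_equal(out$log$old, "LYS")
  expect_equal(out$log$new, "LYN")

  # mixed toy protein: the changed set equals a brute-force centroid test
  set.seed(2)
  names10 <- c("ASP", "ALA", "LYS", "GLU", "SER", "ARG", "HIP", "GLY",
               "ASP", "LYS")
  pos <- matrix(runif(30, -1, 1), ncol = 3) * 30
  s <- md_structure(do.call(rbind, lapply(1:10, function(i)
    if (names10[i] %in% c("ASP", "LYS", "GLU", "ARG", "HIP"))
      mk_res(names10[i], i, pos[i, ])
    else data.frame(name = c("N", "CA", "C"), resname = names10[i],
                    resid = i, x = pos[i, 1] + c(0, .3, .6), y = pos[i, 2],
                    z = pos[i, 3], element = c("N", "C", "C")))))
  out <- neutralize_outside(s, sph, shell_width = 3)
  grp_names <- list(ASP = c("CG", "OD1", "OD2"), LYS = "NZ",
                    GLU = c("CD", "OE1", "OE2"),
                    ARG = c("CZ", "NE", "NH1", "NH2"),
                    HIP = c("ND1", "NE2"))
  expected <- vapply(1:10, function(i) {
    g <- grp_names[[names10[i]]]
    if (is.null(g)) return(FALSE)
    a <- s$atoms[s$atoms$resid == i & s$atoms$name %in% g, ]
    sqrt(sum(colMeans(a[, c("x", "y", "z")])^2)) > 25 - 3
  }, TRUE)
  expect_setequal(out$log$resid, which(expected))
  # names change, coordinates and atom counts never
  expect_equal(out$structure$atoms[, c("name", "x", "y", "z")],
               s$atoms[, c("name", "x", "y", "z")])
  expect_warning(
    neutralize_outside(md_structure(data.frame(
      name = "X1", resname = "XYZ", resid = 1, x = 0, y = 0, z = 0,
      element = "X")), sph),
    "XYZ")
})

test_that("grid solvation matches brute-force enumeration and is idempotent", {
  sph <- simulation_sphere(c(0, 0, 0), 6)
  sol <- solvate_sphere(sph, grid_spacing = 3.1)
  # brute-force oracle: enumerate all grid nodes within the radius
  m <- ceiling(6 / 3.1) + 1
  g <- expand.grid(x = seq(-m, m) * 3.1, y = seq(-m, m) * 3.1,
                   z = seq(-m, m) * 3.1)
  n_oracle <- sum(sqrt(g$x^2 + g$y^2 + g$z^2) <= 6)
  expect_equal(attr(sol, "n_added"), n_oracle)
  expect_equal(sum(sol$atoms$name == "O"), n_oracle)
  # every oxygen is inside, every water has 3 atoms
  o <- sol$atoms[sol$atoms$name == "O", ]
  expect_true(all(sqrt(o$x^2 + o$y^2 + o$z^2) <= 6))
  expect_true(all(table(sol$atoms$resid) == 3))

  # offset grid so no node falls inside a tiny sphere
  tiny <- simulation_sphere(c(0, 0, 0), 1.0)
  none <- solvate_sphere(tiny, grid_spacing = 3.1,
                         grid_offset = c(1.55, 1.55, 1.55))
  expect_equal(attr(none, "n_added"), 0L)

  # solvating a solvated sphere adds nothing (all nodes clash)
  again <- solvate_sphere(sph, existing = sol, grid_spacing = 3.1)
  expect_equal(attr(again, "n_added"), 0L)
  expect_equal(nrow(again$atoms), nrow(sol$atoms))
})
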