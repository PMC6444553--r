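# Independent oracles used across the suite. These re-derive expected
# values by brute force / closed form and must stay independent of the
# implementation paths they check.

kB <- 1.9872e-3  # kcal/mol/K

# fixed-column PDB ATOM/HETATM line
pdb_line <- function(serial, name, resname, resid, x, y, z,
                     record = "HETATM", element = "") {
  sprintf("%-6s%5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resname, "A", resid, x, y, z, 1, 0, element)
}

# small hand-built ligand with explicit everything
toy_ligand <- function(residue = "LIG") {
  atoms <- data.frame(
    name = c("C1", "C2", "O1", "H1"),
    element = c("C", "C", "O", "H"),
    type_code = c("CT", "CT", "OH", "HO"),
    charge = c(0.10, 0.05, -0.45, 0.30),
    x = c(0, 1.5, 2.2, 3.0), y = c(0, 0.4, 1.2, 1.1), z = c(0, 0, 0.2, 0.5),
    stringsAsFactors = FALSE)
  ligand_topology(residue, atoms,
                  bonds = rbind(c(1, 2), c(2, 3), c(3, 4)),
                  angles = rbind(c(1, 2, 3), c(2, 3, 4)),
                  torsions = rbind(c(1, 2, 3, 4)),
                  charge_groups = list(1:2, 3:4))
}

toy_params <- function() {
  parameter_set(
    vdw = data.frame(type_code = c("CT", "OH", "HO"),
                     epsilon = c(0.066, 0.21, 0),
                     radius = c(1.9087, 1.72, 0.3),
                     mass = c(12.011, 15.999, 1.008),
                     stringsAsFactors = FALSE),
    bonds = data.frame(ti = c("CT", "CT", "OH"), tj = c("CT", "OH", "HO"),
                       k = c(310, 320, 553), r0 = c(1.526, 1.41, 0.96),
                       stringsAsFactors = FALSE))
}

# structural equality of ligand topologies (order-sensitive)
expect_same_topology <- function(a, b, check_coords = TRUE) {
  expect_equal(a$residue_name, b$residue_name)
  cols <- c("name", "type_code", "charge",
            if (check_coords) c("x", "y", "z"))
  for (cl in cols)
    expect_equal(a$atoms[[cl]], b$atoms[[cl]], tolerance = 1e-9)
  for (term in c("bonds", "angles", "torsions", "impropers"))
    expect_equal(unname(a[[term]]), unname(b[[term]]))
  expect_equal(a$charge_groups, b$charge_groups)
}

# brute-force greedy nearest-distance matching oracle
greedy_match_oracle <- function(A, B, elemA, elemB, cutoff,
                                match_elements = TRUE) {
  dm <- as.matrix(stats::dist(rbind(A, B)))[seq_len(nrow(A)),
                                            nrow(A) + seq_len(nrow(B)),
                                            drop = FALSE]
  if (match_elements) dm[outer(elemA, elemB, `!=`)] <- Inf
  dm[dm > cutoff] <- Inf
  out <- NULL
  while (any(is.finite(dm))) {
    k <- arrayInd(which.min(dm), dim(dm))
    out <- rbind(out, k)
    dm[k[1], ] <- Inf; dm[, k[2]] <- Inf
  }
  out
}

# asymptotic standard error of the Zwanzig estimator (delta method)
zwanzig_se <- function(dU, T = 298) {
  kT <- kB * T
  w <- exp(-(dU - min(dU)) / kT)
  kT * stats::sd(w) / (mean(w) * sqrt(length(w)))
}

# asymptotic SE of overlap sampling: independent numerator/denominator
os_se <- function(dU_f, dU_r, T = 298) {
  kT <- kB * T
  wf <- exp(-(dU_f - min(dU_f)) / (2 * kT))
  wr <- exp(-(dU_r - min(dU_r)) / (2 * kT))
  kT * sqrt(stats::var(wf) / (mean(wf)^2 * length(wf)) +
              stats::var(wr) / (mean(wr)^2 * length(wr)))
}

# Bennett's asymptotic variance of the BAR estimate at the solution dG
bar_se <- function(dU_f, dU_r, dG, T = 298) {
  kT <- kB * T
  M <- log(length(dU_f) / length(dU_r))
  ff <- stats::plogis(-(M + (dU_f - dG) / kT))
  fr <- stats::plogis(-(-M + (dU_r + dG) / kT))
  kT * sqrt((mean(ff^2) / mean(ff)^2 - 1) / length(ff) +
              (mean(fr^2) / mean(fr)^2 - 1) / length(fr))
}
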