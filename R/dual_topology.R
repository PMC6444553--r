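# Dual-topology alchemical specification: both end-state ligands are
# present with their own coordinates; in end state A every atom of ligand
# B is a dummy (zero charge, zero Lennard-Jones) and vice versa. The two
# molecules never share bonded terms, so changes in bond topology
# (scaffold hops, ring opening/closure) need no bond making or breaking.

#' Distance-restraint specification for equivalent atom pairs
#'
#' Half-harmonic restraints keep pairs of equivalent atoms of the two
#' ligands together. The energy is zero while the pair distance lies in
#' the flat window and grows as `0.5 * k * (d - upper)^2` beyond it
#' (note the 1/2 convention in front of `k`). Because each pair couples
#' one real and one dummy atom in every end state, the restraint term
#' cancels between end states and needs no free-energy correction.
#'
#' @param force_constant k in kcal/mol/Angstrom^2 (default 2.0).
#' @param window flat-bottom interval in Angstrom (default `c(0, 0.2)`).
#' @return object of class `restraint_spec`.
#' @export
restraint_spec <- function(force_constant = 2.0, window = c(0, 0.2)) {
  stopifnot(force_constant >= 0, length(window) == 2, window[1] <= window[2])
  structure(list(force_constant = force_constant, window = as.numeric(window)),
            class = "restraint_spec")
}

#' Half-harmonic restraint energy
#'
#' @param d distance(s) in Angstrom (>= 0).
#' @param restraint a [restraint_spec()].
#' @return energy in kcal/mol; zero inside the window, continuous and
#'   once-differentiable at the boundary.
#' @export
#' @examples
#' restraint_energy(1.2, restraint_spec(2.0, c(0, 0.2)))  # 0.5*2*(1.0)^2 = 1
restraint_energy <- function(d, restraint = restraint_spec()) {
  stopifnot(all(d >= 0))
  upper <- restraint$window[2]
  ifelse(d <= upper, 0, 0.5 * restraint$force_constant * (d - upper)^2)
}

#' Pair equivalent atoms between two superposed ligands
#'
#' Greedy matching by ascending inter-atom distance over the pre-aligned
#' (docked or crystallographic) poses: the closest unpaired pair is
#' accepted while its distance is at most `cutoff` and, when
#' `require_element_match`, the elements agree. Each atom joins at most
#' one pair.
#'
#' @param ligA,ligB [ligand_topology()] objects with coordinates in the
#'   same frame.
#' @param cutoff maximal pair distance in Angstrom (default 0.25).
#' @param require_element_match require identical elements (default TRUE).
#' @return data.frame `index_A`, `index_B`, `distance`; zero rows (with a
#'   warning) when no pair qualifies — the perturbation is then legal but
#'   unrestrained.
#' @export
pair_equivalent_atoms <- function(ligA, ligB, cutoff = 0.25,
                                  require_element_match = TRUE) {
  A <- .xyz(ligA); B <- .xyz(ligB)
  dm <- outer(seq_len(nrow(A)), seq_len(nrow(B)), Vectorize(function(i, j)
    sqrt(sum((A[i, ] - B[j, ])^2))))
  if (require_element_match) {
    bad <- outer(ligA$atoms$element, ligB$atoms$element, `!=`)
    dm[bad] <- Inf
  }
  dm[dm > cutoff] <- Inf
  pairs <- data.frame(index_A = integer(), index_B = integer(),
                      distance = numeric())
  while (any(is.finite(dm))) {
    k <- arrayInd(which.min(dm), dim(dm))
    pairs <- rbind(pairs, data.frame(index_A = k[1], index_B = k[2],
                                     distance = dm[k]))
    dm[k[1], ] <- Inf
    dm[, k[2]] <- Inf
  }
  if (!nrow(pairs))
    warning("no equivalent atom pairs within ", cutoff,
            " Angstrom; perturbation will be unrestrained")
  pairs[order(pairs$index_A), , drop = FALSE]
}

# dummy placeholders used in the off state
.DUMMY_TYPE <- "DUM"

#' Build a dual-topology FEP specification from two ligands
#'
#' Concatenates the atoms of ligand A then ligand B under unique names
#' (suffixes `_A`/`_B`), assigns per-state types and charges (the
#' off-state of every atom is a dummy: zero charge, zero Lennard-Jones),
#' attaches softcore depths to the dummy-state van der Waals, keeps each
#' ligand's own bonded terms in both states, and records equivalent-atom
#' restraint pairs.
#'
#' @param ligA,ligB validated [ligand_topology()] objects with
#'   coordinates and type codes.
#' @param restraints a [restraint_spec()].
#' @param stage_scheme `"single"` (one transformation; softcore on the
#'   dummy-state vdW throughout) or `"three_stage"` (discharge A, swap
#'   softcore vdW, charge B).
#' @param pair_cutoff,require_element_match passed to
#'   [pair_equivalent_atoms()].
#' @param softcore_depth softcore depth parameter applied to dummy-state
#'   van der Waals (kcal/mol, default 20).
#' @param max_atoms format limit on the combined atom count.
#' @return object of class `dual_topology_spec` with elements `atoms`
#'   (name, orig_name, lig, element, x, y, z), `state_A`/`state_B`
#'   (type_code, charge per atom), `softcore`, `restraint_pairs`,
#'   `restraints`, `stages`, `net_charge_A`, `net_charge_B`,
#'   `needs_born` (TRUE iff the net charge of the sphere changes, in
#'   which case a Born correction applies to the free energies).
#' @export
build_dual_topology <- function(ligA, ligB, restraints = restraint_spec(),
                                stage_scheme = c("single", "three_stage"),
                                pair_cutoff = 0.25,
                                require_element_match = TRUE,
                                softcore_depth = 20,
                                max_atoms = 999L) {
  stage_scheme <- match.arg(stage_scheme)
  stopifnot(inherits(ligA, "ligand_topology"), inherits(ligB, "ligand_topology"))
  nA <- nrow(ligA$atoms); nB <- nrow(ligB$atoms)
  if (nA + nB > max_atoms)
    stop("combined atom count ", nA + nB, " exceeds format limit ", max_atoms)
  atoms <- rbind(
    data.frame(name = paste0(ligA$atoms$name, "_A"),
               orig_name = ligA$atoms$name, lig = "A",
               element = ligA$atoms$element,
               x = ligA$atoms$x, y = ligA$atoms$y, z = ligA$atoms$z,
               stringsAsFactors = FALSE),
    data.frame(name = paste0(ligB$atoms$name, "_B"),
               orig_name = ligB$atoms$name, lig = "B",
               element = ligB$atoms$element,
               x = ligB$atoms$x, y = ligB$atoms$y, z = ligB$atoms$z,
               stringsAsFactors = FALSE))
  state_A <- data.frame(
    type_code = c(ligA$atoms$type_code, rep(.DUMMY_TYPE, nB)),
    charge = c(ligA$atoms$charge, rep(0, nB)), stringsAsFactors = FALSE)
  state_B <- data.frame(
    type_code = c(rep(.DUMMY_TYPE, nA), ligB$atoms$type_code),
    charge = c(rep(0, nA), ligB$atoms$charge), stringsAsFactors = FALSE)
  softcore <- data.frame(
    state_A = ifelse(state_A$type_code == .DUMMY_TYPE, softcore_depth, 0),
    state_B = ifelse(state_B$type_code == .DUMMY_TYPE, softcore_depth, 0))
  pairs <- pair_equivalent_atoms(ligA, ligB, cutoff = pair_cutoff,
                                 require_element_match = require_element_match)
  restraint_pairs <- if (nrow(pairs))
    data.frame(i = pairs$index_A, j = nA + pairs$index_B,
               distance = pairs$distance)
  else data.frame(i = integer(), j = integer(), distance = numeric())
  stages <- if (stage_scheme == "single") {
    data.frame(stage = 1L, name = "transform",
               description = "full charge+vdW interpolation, softcore on dummy-state vdW",
               stringsAsFactors = FALSE)
  } else {
    data.frame(stage = 1:3,
               name = c("discharge_A", "vdw_swap", "charge_B"),
               description = c("charges of A scaled to zero (B dummy)",
                               "softcore vdW of A off, of B on (both uncharged)",
                               "charges of B scaled from zero"),
               stringsAsFactors = FALSE)
  }
  offset <- function(m, by) if (nrow(m)) m + by else m
  spec <- structure(list(
    atoms = atoms, state_A = state_A, state_B = state_B,
    softcore = softcore, restraint_pairs = restraint_pairs,
    restraints = restraints, stages = stages, stage_scheme = stage_scheme,
    bonds = rbind(ligA$bonds, offset(ligB$bonds, nA)),
    angles = rbind(ligA$angles, offset(ligB$angles, nA)),
    torsions = rbind(ligA$torsions, offset(ligB$torsions, nA)),
    impropers = rbind(ligA$impropers, offset(ligB$impropers, nA)),
    n_A = nA, n_B = nB,
    net_charge_A = net_charge(ligA), net_charge_B = net_charge(ligB),
    needs_born = abs(net_charge(ligA) - net_charge(ligB)) > 1e-6),
    class = "dual_topology_spec")
  validate_dual_topology(spec)
  spec
}

#' Check the structural invariants of a dual-topology specification
#'
#' Asserts that: every ligand-B atom is a dummy in state A and vice
#' versa; state charges sum to the respective ligand net charges; no
#' bonded term crosses the A/B partition (the two molecules do not
#' interact); each atom appears in at most one restraint pair; and every
#' restraint pair couples one A atom with one B atom, so one member is a
#' dummy in each end state and the restraint energy cancels between end
#' states.
#'
#' @param spec a `dual_topology_spec`.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_dual_topology <- function(spec) {
  a <- spec$atoms
  isA <- a$lig == "A"
  if (any(spec$state_A$type_code[!isA] != .DUMMY_TYPE) ||
      any(spec$state_A$charge[!isA] != 0))
    stop("ligand-B atoms must be dummy in state A")
  if (any(spec$state_B$type_code[isA] != .DUMMY_TYPE) ||
      any(spec$state_B$charge[isA] != 0))
    stop("ligand-A atoms must be dummy in state B")
  if (abs(sum(spec$state_A$charge) - spec$net_charge_A) > 1e-6 ||
      abs(sum(spec$state_B$charge) - spec$net_charge_B) > 1e-6)
    stop("state charge sums do not match ligand net charges")
  for (term in c("bonds", "angles", "torsions", "impropers")) {
    m <- spec[[term]]
    if (nrow(m) && any(apply(m, 1, function(i) length(unique(isA[i])) > 1)))
      stop("bonded term crosses the A/B partition: ", term)
  }
  rp <- spec$restraint_pairs
  if (nrow(rp)) {
    if (anyDuplicated(c(rp$i, rp$j)))
      stop("atom appears in more than one restraint pair")
    if (any(!isA[rp$i]) || any(isA[rp$j]))
      stop("restraint pair must couple one A atom with one B atom")
  }
  invisible(TRUE)
}

#' @export
print.dual_topology_spec <- function(x, ...) {
  cat("<dual_topology_spec> ", x$n_A, "+", x$n_B, " atoms, ",
      nrow(x$restraint_pairs), " restraint pairs, scheme '",
      x$stage_scheme, "'", if (x$needs_born) ", net-charge change (Born)",
      "\n", sep = "")
  invisible(x)
}

# per-stage end points of (charges, softcore-active) used by write_fep_file
.stage_endpoints <- function(spec, stage) {
  qa <- spec$state_A$charge; qb <- spec$state_B$charge
  if (spec$stage_scheme == "single" || nrow(spec$stages) == 1)
    return(list(q1 = qa, q2 = qb,
                t1 = spec$state_A$type_code, t2 = spec$state_B$type_code))
  zero <- rep(0, nrow(spec$atoms))
  switch(stage,
    list(q1 = qa, q2 = zero, t1 = spec$state_A$type_code,
         t2 = spec$state_A$type_code),
    list(q1 = zero, q2 = zero, t1 = spec$state_A$type_code,
         t2 = spec$state_B$type_code),
    list(q1 = zero, q2 = qb, t1 = spec$state_B$type_code,
         t2 = spec$state_B$type_code))
}

#' Write a dual-topology specification as Q-style FEP stage file(s)
#'
#' Emits the atom list, per-state charge and type pairs, softcore
#' assignments and distance-restraint pairs in a section text format that
#' [read_fep_file()] parses back. With the three-stage scheme one file
#' per stage is written (`<path minus extension>_stageN.fep`).
#'
#' @param spec a `dual_topology_spec`.
#' @param path output file (single stage) or prefix for stage files.
#' @return character vector of the written path(s), invisibly.
#' @export
write_fep_file <- function(spec, path) {
  stopifnot(inherits(spec, "dual_topology_spec"))
  rp <- spec$restraint_pairs
  if (nrow(rp) && (any(rp$i > nrow(spec$atoms)) || any(rp$j > nrow(spec$atoms))))
    stop("integrity error: restraint pair references unknown atom index")
  n_st <- nrow(spec$stages)
  paths <- if (n_st == 1) path else
    paste0(sub("\\.fep$", "", path), "_stage", spec$stages$stage, ".fep")
  for (s in seq_len(n_st)) {
    ep <- .stage_endpoints(spec, s)
    a <- spec$atoms
    lines <- c(
      "[FEP]",
      paste("states 2"),
      paste("stage", spec$stages$stage[s], spec$stages$name[s]),
      paste("net_charge_A", format(spec$net_charge_A)),
      paste("net_charge_B", format(spec$net_charge_B)),
      paste("n_A", spec$n_A), paste("n_B", spec$n_B),
      "[atoms]",
      sprintf("%4d %-8s %-2s %s %12.6f %12.6f %12.6f",
              seq_len(nrow(a)), a$name, a$lig, a$element, a$x, a$y, a$z),
      "[change_charges]",
      sprintf("%4d %14.9f %14.9f", seq_len(nrow(a)), ep$q1, ep$q2),
      "[change_atoms]",
      sprintf("%4d %-8s %-8s", seq_len(nrow(a)), ep$t1, ep$t2),
      "[softcore]",
      sprintf("%4d %8.3f %8.3f", seq_len(nrow(a)),
              spec$softcore$state_A, spec$softcore$state_B),
      "[distance_restraints]",
      if (nrow(rp)) sprintf("%4d %4d %8.3f %8.3f %8.3f", rp$i, rp$j,
                            spec$restraints$force_constant,
                            spec$restraints$window[1],
                            spec$restraints$window[2]))
    writeLines(lines, paths[s])
  }
  invisible(paths)
}

#' Read a Q-style FEP stage file
#'
#' @param path file written by [write_fep_file()].
#' @return a `dual_topology_spec`-like list (single stage).
#' @export
read_fep_file <- function(path) {
  ps <- .read_sections(readLines(path, warn = FALSE))$sections
  hdr <- .tokens(ps$FEP %||% character())
  meta <- list()
  for (h in hdr) meta[[h[1]]] <- h[-1]
  tok <- .tokens(ps$atoms)
  atoms <- data.frame(name = vapply(tok, `[`, "", 2),
                      lig = vapply(tok, `[`, "", 3),
                      element = vapply(tok, `[`, "", 4),
                      x = as.numeric(vapply(tok, `[`, "", 5)),
                      y = as.numeric(vapply(tok, `[`, "", 6)),
                      z = as.numeric(vapply(tok, `[`, "", 7)),
                      stringsAsFactors = FALSE)
  atoms$orig_name <- sub("_[AB]$", "", atoms$name)
  qt <- .tokens(ps$change_charges)
  at <- .tokens(ps$change_atoms)
  sc <- .tokens(ps$softcore)
  state_A <- data.frame(type_code = vapply(at, `[`, "", 2),
                        charge = as.numeric(vapply(qt, `[`, "", 2)),
                        stringsAsFactors = FALSE)
  state_B <- data.frame(type_code = vapply(at, `[`, "", 3),
                        charge = as.numeric(vapply(qt, `[`, "", 3)),
                        stringsAsFactors = FALSE)
  softcore <- data.frame(state_A = as.numeric(vapply(sc, `[`, "", 2)),
                         state_B = as.numeric(vapply(sc, `[`, "", 3)))
  dr <- ps$distance_restraints
  rp <- if (is.null(dr) || !length(dr))
    data.frame(i = integer(), j = integer(), distance = numeric())
  else {
    t2 <- .tokens(dr)
    data.frame(i = as.integer(vapply(t2, `[`, "", 1)),
               j = as.integer(vapply(t2, `[`, "", 2)),
               distance = NA_real_)
  }
  k <- if (!is.null(dr) && length(dr))
    as.numeric(.tokens(dr)[[1]][3]) else 2.0
  win <- if (!is.null(dr) && length(dr))
    as.numeric(.tokens(dr)[[1]][4:5]) else c(0, 0.2)
  structure(list(atoms = atoms, state_A = state_A, state_B = state_B,
                 softcore = softcore, restraint_pairs = rp,
                 restraints = restraint_spec(k, win),
                 stages = data.frame(stage = as.integer(meta$stage[1] %||% 1L),
                                     name = meta$stage[2] %||% "transform",
                                     description = NA_character_,
                                     stringsAsFactors = FALSE),
                 stage_scheme = "single",
                 n_A = as.integer(meta$n_A %||% sum(atoms$lig == "A")),
                 n_B = as.integer(meta$n_B %||% sum(atoms$lig == "B")),
                 net_charge_A = as.numeric(meta$net_charge_A %||% NA),
                 net_charge_B = as.numeric(meta$net_charge_B %||% NA),
                 needs_born = abs(as.numeric(meta$net_charge_A %||% 0) -
                                    as.numeric(meta$net_charge_B %||% 0)) > 1e-6),
            class = "dual_topology_spec")
}
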