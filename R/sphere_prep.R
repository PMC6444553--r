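# Spherical-boundary system preparation: sphere placement, atom
# classification, water-overlap removal, boundary neutralization and grid
# solvation. The simulated system is a finite droplet: atoms beyond the
# sphere are restrained and excluded from nonbonded work by the MD engine,
# so residues left charged at or outside the boundary would be poorly
# screened; they are therefore switched to neutral library variants.

#' Construct a simulation sphere
#'
#' @param center numeric length-3 Cartesian center (Angstrom).
#' @param radius sphere radius in Angstrom (> 0); 25 Angstrom is a good
#'   default for drug-sized ligands.
#' @return an object of class `simulation_sphere`.
#' @export
simulation_sphere <- function(center, radius = 25) {
  stopifnot(is.numeric(center), length(center) == 3, all(is.finite(center)),
            is.numeric(radius), length(radius) == 1, radius > 0)
  structure(list(center = as.numeric(center), radius = radius),
            class = "simulation_sphere")
}

#' Construct an MD structure
#'
#' Light container for a protein/water/ligand system: a data.frame of
#' atoms with columns `name`, `resname`, `resid`, `x`, `y`, `z` and
#' optionally `element`, `chain`, `record`, `region`.
#'
#' @param atoms the atom data.frame.
#' @return object of class `md_structure`.
#' @export
md_structure <- function(atoms) {
  need <- c("name", "resname", "resid", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$element))
    atoms$element <- toupper(substr(gsub("[^A-Za-z].*$", "", atoms$name), 1, 1))
  structure(list(atoms = atoms), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat("<md_structure> ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$resname, x$atoms$resid))), " residues\n",
      sep = "")
  invisible(x)
}

#' Read an MD structure from a PDB file
#' @param path PDB file with ATOM/HETATM records.
#' @return an [md_structure()].
#' @export
read_structure_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  md_structure(.parse_pdb_atoms(readLines(path, warn = FALSE), path))
}

.xyz <- function(obj) {
  if (inherits(obj, "md_structure")) obj <- obj$atoms
  if (inherits(obj, "ligand_topology")) obj <- obj$atoms
  as.matrix(obj[, c("x", "y", "z")])
}

.dist_to <- function(xyz, center)
  sqrt(colSums((t(xyz) - center)^2))

#' Choose the center of the simulation sphere
#'
#' The recommended mode for a dual-topology perturbation is
#' `"cog_two_ligands"`: the unweighted mean over all atom coordinates of
#' both superposed ligands, so that both end states sit centrally in the
#' droplet. Alternatives: explicit Cartesian coordinates, the centroid of
#' a protein residue, or a single named ligand atom.
#'
#' @param mode one of `"cog_two_ligands"`, `"cartesian"`, `"residue"`,
#'   `"ligand_atom"`.
#' @param ligA,ligB [ligand_topology()] objects (for `cog_two_ligands`,
#'   and `ligA` for `ligand_atom`).
#' @param xyz numeric length-3 (for `cartesian`).
#' @param structure an [md_structure()] (for `residue`).
#' @param resid residue id within `structure` (for `residue`).
#' @param atom_name atom name within `ligA` (for `ligand_atom`).
#' @return numeric length-3 center (Angstrom).
#' @export
sphere_center <- function(mode = c("cog_two_ligands", "cartesian", "residue",
                                   "ligand_atom"),
                          ligA = NULL, ligB = NULL, xyz = NULL,
                          structure = NULL, resid = NULL, atom_name = NULL) {
  mode <- match.arg(mode)
  sel <- switch(mode,
    cog_two_ligands = {
      stopifnot(!is.null(ligA), !is.null(ligB))
      rbind(.xyz(ligA), .xyz(ligB))
    },
    cartesian = {
      stopifnot(is.numeric(xyz), length(xyz) == 3)
      return(as.numeric(xyz))
    },
    residue = {
      stopifnot(!is.null(structure), !is.null(resid))
      .xyz(structure)[structure$atoms$resid %in% resid, , drop = FALSE]
    },
    ligand_atom = {
      stopifnot(!is.null(ligA), !is.null(atom_name))
      .xyz(ligA)[ligA$atoms$name %in% atom_name, , drop = FALSE]
    })
  if (!nrow(sel) || anyNA(sel)) stop("empty selection for sphere center")
  unname(colMeans(sel))
}

#' Classify atoms relative to the simulation sphere
#'
#' Adds a `region` column partitioning the atoms into `"inside"`
#' (distance to center <= radius - shell_width), `"shell"`
#' (radius - shell_width < distance <= radius) and `"outside"`
#' (distance > radius), plus a logical `in_sphere` column (closed
#' boundary: distance exactly equal to the radius counts as in-sphere).
#'
#' @param s an [md_structure()].
#' @param sphere a [simulation_sphere()].
#' @param shell_width boundary-shell width in Angstrom (>= 0, default 3).
#' @return the structure with `region` and `in_sphere` columns.
#' @export
classify_atoms <- function(s, sphere, shell_width = 3) {
  stopifnot(inherits(s, "md_structure"), inherits(sphere, "simulation_sphere"),
            shell_width >= 0)
  d <- .dist_to(.xyz(s), sphere$center)
  region <- ifelse(d > sphere$radius, "outside",
                   ifelse(d > sphere$radius - shell_width, "shell", "inside"))
  s$atoms$region <- region
  s$atoms$in_sphere <- d <= sphere$radius
  s
}

#' Remove waters overlapping either ligand
#'
#' A water residue is removed as a whole iff any of its atoms lies within
#' `cutoff` of any heavy (non-hydrogen) atom of either ligand.
#'
#' @param waters an [md_structure()] of water residues.
#' @param ligA,ligB [ligand_topology()] objects with coordinates.
#' @param cutoff overlap distance in Angstrom (> 0, default 2.4).
#' @return the surviving waters as an [md_structure()]; the number of
#'   removed residues is attached as attribute `n_removed`.
#' @export
remove_overlapping_waters <- function(waters, ligA, ligB, cutoff = 2.4) {
  stopifnot(inherits(waters, "md_structure"), cutoff > 0)
  lig <- rbind(
    cbind(.xyz(ligA), h = ligA$atoms$element == "H"),
    cbind(.xyz(ligB), h = ligB$atoms$element == "H"))
  heavy <- lig[lig[, "h"] == 0, c("x", "y", "z"), drop = FALSE]
  wa <- waters$atoms
  if (!nrow(wa) || !nrow(heavy)) {
    out <- md_structure(wa)
    attr(out, "n_removed") <- 0L
    return(out)
  }
  wxyz <- .xyz(waters)
  mind <- vapply(seq_len(nrow(wxyz)), function(i)
    min(.dist_to(heavy, wxyz[i, ])), 0)
  clash_atom <- mind <= cutoff
  key <- paste(wa$resname, wa$resid)
  clash_res <- unique(key[clash_atom])
  out <- md_structure(wa[!(key %in% clash_res), , drop = FALSE])
  attr(out, "n_removed") <- length(clash_res)
  out
}

# Neutral library variants and the atoms defining the charged group whose
# centroid decides inside/outside. Protonation states follow residue-name
# conventions (HID/HIE/HIP etc.).
.IONIZABLE <- list(
  ASP = list(neutral = "ASH", group = c("CG", "OD1", "OD2")),
  GLU = list(neutral = "GLH", group = c("CD", "OE1", "OE2")),
  LYS = list(neutral = "LYN", group = "NZ"),
  ARG = list(neutral = "ARN", group = c("CZ", "NE", "NH1", "NH2")),
  HIP = list(neutral = "HID", group = c("ND1", "NE2")))

.KNOWN_RES <- c(names(.IONIZABLE),
                "ALA", "ARN", "ASH", "ASN", "CYS", "GLH", "GLN", "GLY",
                "HID", "HIE", "ILE", "LEU", "LYN", "MET", "PHE", "PRO",
                "SER", "THR", "TRP", "TYR", "VAL", "HOH", "WAT", "TIP")

#' Neutralize ionizable residues at or beyond the sphere boundary
#'
#' Ionizable residues whose charged-group centroid lies outside the
#' sphere, or within the restrained boundary shell, are renamed to their
#' neutral library variant (ASP to ASH, GLU to GLH, LYS to LYN, ARG to
#' ARN, HIP to HID). Only residue names change; coordinates and atom
#' counts are untouched. Residues with names outside the known library
#' produce a warning and are left unchanged.
#'
#' @param s an [md_structure()].
#' @param sphere a [simulation_sphere()].
#' @param shell_width restrained boundary-shell width in Angstrom
#'   (default 3).
#' @return list with `structure` (renamed) and `log` (data.frame:
#'   `resid`, `old`, `new`, `distance`, `reason`).
#' @export
neutralize_outside <- function(s, sphere, shell_width = 3) {
  stopifnot(inherits(s, "md_structure"), inherits(sphere, "simulation_sphere"))
  at <- s$atoms
  key <- paste(at$resname, at$resid)
  log <- data.frame(resid = integer(), old = character(), new = character(),
                    distance = numeric(), reason = character(),
                    stringsAsFactors = FALSE)
  unknown <- setdiff(unique(at$resname), .KNOWN_RES)
  if (length(unknown))
    warning("unknown residue name(s), left unchanged: ",
            paste(unknown, collapse = ", "))
  for (k in unique(key)) {
    rows <- which(key == k)
    rn <- at$resname[rows[1]]
    ion <- .IONIZABLE[[rn]]
    if (is.null(ion)) next
    grp <- rows[at$name[rows] %in% ion$group]
    if (!length(grp)) grp <- rows
    d <- sqrt(sum((colMeans(.xyz(s)[grp, , drop = FALSE]) - sphere$center)^2))
    if (d > sphere$radius - shell_width) {
      at$resname[rows] <- ion$neutral
      log <- rbind(log, data.frame(
        resid = at$resid[rows[1]], old = rn, new = ion$neutral,
        distance = d,
        reason = if (d > sphere$radius) "outside sphere" else "boundary shell",
        stringsAsFactors = FALSE))
    }
  }
  list(structure = md_structure(at), log = log)
}

#' Write a neutralization change-log as a plain-text table
#' @param log data.frame as returned by [neutralize_outside()].
#' @param path output file.
#' @export
write_change_log <- function(log, path) {
  utils::write.table(format(log, digits = 4), path, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(path)
}

# Rigid TIP3P geometry: O-H 0.9572 Angstrom, H-O-H 104.52 degrees.
.TIP3P_H <- local({
  r <- 0.9572; a <- 104.52 * pi / 180
  rbind(c(r, 0, 0), c(r * cos(a), r * sin(a), 0))
})

#' Solvate the simulation sphere with a cubic water grid
#'
#' Water oxygens are placed on a cubic grid (spacing `grid_spacing`,
#' approximating bulk density at the default 3.1 Angstrom) centered on the
#' sphere center. A water is kept iff its oxygen lies within the sphere
#' and no existing heavy atom is within `clash_cutoff`. Hydrogens are
#' added in a fixed rigid-TIP3P orientation, so the result is fully
#' deterministic.
#'
#' @param sphere a [simulation_sphere()].
#' @param existing optional [md_structure()] of already-present atoms.
#' @param grid_spacing grid spacing in Angstrom (> 0, default 3.1).
#' @param clash_cutoff heavy-atom clash distance in Angstrom (default 2.4).
#' @param grid_offset numeric length-3 shift of the grid origin relative
#'   to the sphere center (Angstrom).
#' @return an [md_structure()] with the existing atoms plus added waters
#'   (resname `HOH`); the number of added water residues is attached as
#'   attribute `n_added`.
#' @export
solvate_sphere <- function(sphere, existing = NULL, grid_spacing = 3.1,
                           clash_cutoff = 2.4, grid_offset = c(0, 0, 0)) {
  stopifnot(inherits(sphere, "simulation_sphere"), grid_spacing > 0,
            length(grid_offset) == 3)
  m <- ceiling(sphere$radius / grid_spacing) + 1
  g <- seq(-m, m) * grid_spacing
  nodes <- as.matrix(expand.grid(x = g, y = g, z = g))
  nodes <- nodes[order(nodes[, 3], nodes[, 2], nodes[, 1]), , drop = FALSE]
  nodes <- sweep(nodes, 2, -(sphere$center + grid_offset))
  inside <- .dist_to(nodes, sphere$center) <= sphere$radius
  nodes <- nodes[inside, , drop = FALSE]
  ex_atoms <- if (is.null(existing)) NULL else existing$atoms
  if (!is.null(ex_atoms) && nrow(ex_atoms)) {
    heavy <- .xyz(existing)[ex_atoms$element != "H", , drop = FALSE]
    if (nrow(heavy)) {
      ok <- vapply(seq_len(nrow(nodes)), function(i)
        min(.dist_to(heavy, nodes[i, ])) > clash_cutoff, TRUE)
      nodes <- nodes[ok, , drop = FALSE]
    }
  }
  nw <- nrow(nodes)
  base_resid <- if (is.null(ex_atoms) || !nrow(ex_atoms)) 0L else
    max(ex_atoms$resid)
  waters <- if (nw) do.call(rbind, lapply(seq_len(nw), function(i) {
    o <- nodes[i, ]
    data.frame(name = c("O", "H1", "H2"), resname = "HOH",
               resid = base_resid + i,
               x = c(o[1], o[1] + .TIP3P_H[, 1]),
               y = c(o[2], o[2] + .TIP3P_H[, 2]),
               z = c(o[3], o[3] + .TIP3P_H[, 3]),
               element = c("O", "H", "H"), stringsAsFactors = FALSE)
  })) else NULL
  cols <- c("name", "resname", "resid", "x", "y", "z", "element")
  empty <- data.frame(name = character(), resname = character(),
                      resid = integer(), x = numeric(), y = numeric(),
                      z = numeric(), element = character(),
                      stringsAsFactors = FALSE)
  parts <- list(
    if (!is.null(ex_atoms) && nrow(ex_atoms)) ex_atoms[cols],
    if (!is.null(waters)) waters[cols])
  parts <- Filter(Negate(is.null), parts)
  out <- md_structure(if (length(parts)) do.call(rbind, parts) else empty)
  attr(out, "n_added") <- nw
  out
}
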