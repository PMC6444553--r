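# Ligand topologies, Q-style library/parameter text dialects, and PDB I/O.
#
# The `.lib` and `.prm` dialects written here are documented, plain-text
# section formats (see the package vignette); compatibility with the Q MD
# engine's own grammar is best effort, since that grammar is not formally
# specified.

#' Construct a ligand topology
#'
#' A ligand topology holds one end-state molecule of an alchemical
#' transformation: its atoms (names, elements, force-field type codes,
#' partial charges, optional Cartesian coordinates), bonded terms as index
#' tuples, and a charge-group partition.
#'
#' @param residue_name 3-4 character residue code.
#' @param atoms data.frame with columns `name`, `element`, `type_code`,
#'   `charge`, `x`, `y`, `z` (coordinates in Angstrom; may be `NA` for a
#'   coordinate-free topology as read from a library file).
#' @param bonds,angles,torsions,impropers integer matrices with 2, 3, 4
#'   and 4 columns of 1-based atom indices (or `NULL`).
#' @param charge_groups list of integer vectors partitioning the atom
#'   indices; defaults to a single group containing every atom.
#' @return an object of class `ligand_topology`.
#' @export
ligand_topology <- function(residue_name, atoms, bonds = NULL, angles = NULL,
                            torsions = NULL, impropers = NULL,
                            charge_groups = NULL) {
  stopifnot(is.character(residue_name), nchar(residue_name) >= 1,
            is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("name", "element", "type_code", "charge", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$name))
    stop("duplicate atom names: ",
         paste(unique(atoms$name[duplicated(atoms$name)]), collapse = ", "))
  n <- nrow(atoms)
  as_idx <- function(x, k, what) {
    if (is.null(x) || NROW(x) == 0) return(matrix(integer(), 0, k))
    x <- matrix(as.integer(x), ncol = k)
    if (any(x < 1 | x > n))
      stop(what, " references atom index outside 1..", n)
    x
  }
  bonds <- as_idx(bonds, 2, "bond")
  angles <- as_idx(angles, 3, "angle")
  torsions <- as_idx(torsions, 4, "torsion")
  impropers <- as_idx(impropers, 4, "improper")
  if (is.null(charge_groups)) charge_groups <- list(seq_len(n))
  cg <- sort(unlist(charge_groups))
  if (!identical(as.integer(cg), seq_len(n)))
    stop("charge_groups must partition atom indices 1..", n, " exactly")
  structure(list(residue_name = residue_name,
                 atoms = atoms, bonds = bonds, angles = angles,
                 torsions = torsions, impropers = impropers,
                 charge_groups = lapply(charge_groups, as.integer)),
            class = "ligand_topology")
}

#' @export
print.ligand_topology <- function(x, ...) {
  cat("<ligand_topology> ", x$residue_name, ": ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds, net charge ",
      format(net_charge(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Net charge of a ligand topology (elementary charges)
#' @param lig a `ligand_topology`.
#' @export
net_charge <- function(lig) sum(lig$atoms$charge)

# ---------------------------------------------------------------------------
# PDB records

# Fixed-column parse of ATOM/HETATM records, whitespace fallback per line.
# Returns data.frame(record, serial, name, resname, chain, resid, x, y, z,
# element).
.parse_pdb_atoms <- function(lines, path = "<pdb>") {
  keep <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("no ATOM/HETATM records in ", path)
  f <- function(ln, from, to) trimws(substr(ln, from, to))
  num <- function(s) suppressWarnings(as.numeric(s))
  out <- lapply(idx, function(i) {
    ln <- lines[i]
    x <- num(f(ln, 31, 38)); y <- num(f(ln, 39, 46)); z <- num(f(ln, 47, 54))
    name <- f(ln, 13, 16); resname <- f(ln, 18, 21)
    chain <- f(ln, 22, 22); serial <- num(f(ln, 7, 11))
    resid <- num(f(ln, 23, 26)); element <- f(ln, 77, 78)
    if (anyNA(c(x, y, z))) {
      # Malformed fixed columns: fall back to whitespace tokens, expecting
      # "record serial name resname [chain] resid x y z" (no occupancy/B).
      # x,y,z are the last three of the trailing run of numeric tokens.
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      co <- num(tok)
      ci <- which(!is.na(co))
      runs <- if (length(ci)) split(ci, cumsum(c(1, diff(ci) != 1))) else list()
      runs <- Filter(function(r) length(r) >= 3 && r[1] > 3, runs)
      if (length(runs)) {
        r <- runs[[length(runs)]]
        pos <- r[seq(length(r) - 2, length(r))]
        x <- co[pos[1]]; y <- co[pos[2]]; z <- co[pos[3]]
        if (length(tok) >= 4) { name <- tok[3]; resname <- tok[4] }
        serial <- co[ci[1]]
        if (is.na(resid)) resid <- if (length(r) > 3) co[pos[1] - 1] else 1
      }
      if (anyNA(c(x, y, z)))
        stop("cannot parse coordinates at line ", i, " of ", path, ": ",
             trimws(ln))
    }
    if (!nzchar(element)) {
      a <- gsub("[^A-Za-z]", "", name)
      element <- toupper(substr(a, 1, 1))
      if (grepl("^(CL|BR|NA|MG|ZN|FE|CA)", toupper(a)))
        element <- substr(toupper(a), 1, 2)
    }
    data.frame(record = substr(ln, 1, 6), serial = serial, name = name,
               resname = resname, chain = chain, resid = resid,
               x = x, y = y, z = z,
               element = toupper(element), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read ligand coordinates from a PDB file
#'
#' Parses ATOM/HETATM records by fixed columns with a whitespace fallback
#' for malformed lines; occupancy and B-factor are ignored. No
#' protonation, enantiomer or tautomer enumeration is performed: the
#' coordinates in the file are the coordinates used.
#'
#' @param path PDB file.
#' @param residue_name residue code for the resulting topology; defaults
#'   to the residue name of the first record.
#' @return a [ligand_topology()] with atoms in file order, `type_code`
#'   `NA` and `charge` 0 (types/charges come from a library file).
#' @export
read_ligand_pdb <- function(path, residue_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  at <- .parse_pdb_atoms(readLines(path, warn = FALSE), path)
  atoms <- data.frame(name = at$name, element = at$element,
                      type_code = NA_character_, charge = 0,
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  if (anyDuplicated(atoms$name))
    atoms$name <- make.unique(atoms$name, sep = "")
  ligand_topology(residue_name %||% at$resname[1], atoms)
}

#' Write atoms to a PDB file
#'
#' @param atoms data.frame with columns `name`, `resname`, `resid`, `x`,
#'   `y`, `z` and optionally `element`, `record`, `chain`; or an
#'   `md_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  if (inherits(atoms, "md_structure")) atoms <- atoms$atoms
  if (inherits(atoms, "ligand_topology")) {
    a <- atoms$atoms
    atoms <- data.frame(record = "HETATM", name = a$name,
                        resname = atoms$residue_name, resid = 1L,
                        x = a$x, y = a$y, z = a$z, element = a$element,
                        stringsAsFactors = FALSE)
  }
  rec <- atoms$record %||% NULL
  if (is.null(rec)) rec <- rep("ATOM", nrow(atoms))
  ch <- atoms$chain %||% rep("A", nrow(atoms))
  el <- atoms$element %||% toupper(substr(atoms$name, 1, 1))
  lines <- sprintf("%-6s%5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   substr(rec, 1, 6), seq_len(nrow(atoms)),
                   substr(atoms$name, 1, 4), substr(atoms$resname, 1, 4),
                   substr(ch, 1, 1), atoms$resid %% 10000L,
                   atoms$x, atoms$y, atoms$z, 1, 0, el)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Section-format helpers shared by the .lib/.prm/FEP dialects

# Split lines into named sections "[name]"; '#' and '!' start comments.
.read_sections <- function(lines) {
  lines <- sub("[#!].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^\\[[A-Za-z_]+\\]$", lines)
  sec <- cumsum(hdr)
  pre <- lines[sec == 0]
  out <- list()
  for (k in seq_len(max(sec, 0))) {
    body <- lines[sec == k]
    out[[gsub("\\[|\\]", "", body[1])]] <- body[-1]
  }
  list(preamble = pre, sections = out)
}

.tokens <- function(lines) lapply(strsplit(lines, "\\s+"), identity)

# ---------------------------------------------------------------------------
# Q-style library files

#' Read a ligand topology from a Q-style library file
#'
#' The dialect is section based: a `{RES}` header, `[atoms]`
#' (`index name type charge`), `[bonds]` (atom-name pairs), optional
#' `[angles]`, `[torsions]`, `[impropers]` (atom-name tuples) and
#' `[charge_groups]` (one group of atom names per line). Unknown sections
#' produce a warning and are skipped; bonded terms naming an atom absent
#' from `[atoms]` are an integrity error.
#'
#' @param path library file.
#' @return a [ligand_topology()] without coordinates.
#' @export
read_q_library <- function(path) {
  ps <- .read_sections(readLines(path, warn = FALSE))
  known <- c("atoms", "bonds", "angles", "torsions", "impropers",
             "charge_groups", "info")
  unk <- setdiff(names(ps$sections), known)
  if (length(unk))
    warning("skipping unknown section(s): ", paste(unk, collapse = ", "))
  res <- gsub("[{}]", "", ps$preamble[1] %||% "LIG")
  at <- ps$sections$atoms
  if (is.null(at) || !length(at)) stop("library has no [atoms] section: ", path)
  tok <- .tokens(at)
  atoms <- data.frame(
    name = vapply(tok, `[`, "", 2),
    element = NA_character_,
    type_code = vapply(tok, `[`, "", 3),
    charge = as.numeric(vapply(tok, `[`, "", 4)),
    x = NA_real_, y = NA_real_, z = NA_real_, stringsAsFactors = FALSE)
  atoms$element <- toupper(gsub("[^A-Za-z].*$", "", atoms$name))
  atoms$element <- substr(atoms$element, 1, 1)
  name2idx <- function(nm, what) {
    i <- match(nm, atoms$name)
    if (anyNA(i))
      stop("integrity error: ", what, " references atom(s) not in [atoms]: ",
           paste(unique(nm[is.na(i)]), collapse = ", "))
    i
  }
  tuple <- function(sec, k, what) {
    lines <- ps$sections[[sec]]
    if (is.null(lines) || !length(lines)) return(NULL)
    t(vapply(.tokens(lines),
             function(v) name2idx(v[seq_len(k)], what), integer(k)))
  }
  cg <- ps$sections$charge_groups
  groups <- if (is.null(cg) || !length(cg)) NULL else
    lapply(.tokens(cg), name2idx, what = "charge group")
  ligand_topology(res, atoms,
                  bonds = tuple("bonds", 2, "bond"),
                  angles = tuple("angles", 3, "angle"),
                  torsions = tuple("torsions", 4, "torsion"),
                  impropers = tuple("impropers", 4, "improper"),
                  charge_groups = groups)
}

#' Write a ligand topology as a Q-style library file
#'
#' Inverse of [read_q_library()]: `read_q_library(write_q_library(t))`
#' reproduces the same structured topology (coordinates are not part of
#' the library format). Empty bonded sections are still written so the
#' file always parses.
#'
#' @param lig a [ligand_topology()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_q_library <- function(lig, path) {
  stopifnot(inherits(lig, "ligand_topology"))
  a <- lig$atoms
  if (anyNA(a$type_code))
    stop("missing-parameter error: atoms without type_code: ",
         paste(a$name[is.na(a$type_code)], collapse = ", "))
  nm <- function(idx) apply(idx, 1, function(i) paste(a$name[i], collapse = " "))
  sec <- function(title, body)
    c(sprintf("[%s]", title), if (length(body)) paste("   ", body))
  lines <- c(
    sprintf("{%s}", lig$residue_name),
    sec("atoms", sprintf("%4d %-5s %-8s %12.6f",
                         seq_len(nrow(a)), a$name, a$type_code, a$charge)),
    sec("bonds", if (nrow(lig$bonds)) nm(lig$bonds)),
    sec("angles", if (nrow(lig$angles)) nm(lig$angles)),
    sec("torsions", if (nrow(lig$torsions)) nm(lig$torsions)),
    sec("impropers", if (nrow(lig$impropers)) nm(lig$impropers)),
    sec("charge_groups",
        vapply(lig$charge_groups,
               function(g) paste(a$name[g], collapse = " "), "")))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Parameter sets

.empty_vdw <- function()
  data.frame(type_code = character(), epsilon = numeric(),
             radius = numeric(), mass = numeric(), stringsAsFactors = FALSE)

#' Construct a force-field parameter set
#'
#' @param vdw data.frame `type_code`, `epsilon` (Lennard-Jones well depth,
#'   kcal/mol), `radius` (Rmin/2, Angstrom), `mass` (amu).
#' @param bonds data.frame `ti`, `tj`, `k`, `r0`.
#' @param angles data.frame `ti`, `tj`, `tk`, `k`, `theta0`.
#' @param torsions data.frame `ti`, `tj`, `tk`, `tl`, `k`, `periodicity`,
#'   `phase`.
#' @param impropers data.frame `ti`, `tj`, `tk`, `tl`, `k`, `phase`.
#' @return an object of class `parameter_set`.
#' @export
parameter_set <- function(vdw = .empty_vdw(),
                          bonds = NULL, angles = NULL,
                          torsions = NULL, impropers = NULL) {
  df0 <- function(x, cols) {
    if (is.null(x)) {
      x <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                         cols), stringsAsFactors = FALSE)
      num <- !grepl("^t[ijkl]$", cols)
      x[num] <- lapply(x[num], as.numeric)
    }
    stopifnot(all(cols %in% names(x)))
    x[cols]
  }
  vdw <- df0(vdw, c("type_code", "epsilon", "radius", "mass"))
  if (anyDuplicated(vdw$type_code)) {
    d <- vdw[order(vdw$type_code), ]
    ok <- !any(tapply(seq_len(nrow(d)), d$type_code, function(i)
      nrow(unique(d[i, -1])) > 1))
    if (!ok) stop("conflicting duplicate vdw entries")
    vdw <- vdw[!duplicated(vdw$type_code), ]
  }
  structure(list(vdw = vdw,
                 bonds = df0(bonds, c("ti", "tj", "k", "r0")),
                 angles = df0(angles, c("ti", "tj", "tk", "k", "theta0")),
                 torsions = df0(torsions, c("ti", "tj", "tk", "tl", "k",
                                            "periodicity", "phase")),
                 impropers = df0(impropers, c("ti", "tj", "tk", "tl", "k",
                                              "phase"))),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> ", nrow(x$vdw), " atom types, ", nrow(x$bonds),
      " bond / ", nrow(x$angles), " angle / ", nrow(x$torsions),
      " torsion / ", nrow(x$impropers), " improper entries\n", sep = "")
  invisible(x)
}

# canonical string key per table row (bonded keys are direction-insensitive)
.param_keys <- function(df, tcols) {
  if (!nrow(df)) return(character())
  apply(df[tcols], 1, function(v) {
    w <- rev(v)
    paste(if (paste(v, collapse = " ") <= paste(w, collapse = " ")) v else w,
          collapse = " ")
  })
}

#' Merge force-field parameter sets
#'
#' Takes the union of all tables across the given sets (e.g. per-ligand
#' parameters merged with a general force-field set). Identical duplicate
#' entries are deduplicated; the same key with different numeric values is
#' a conflict error naming the key and both values.
#'
#' @param ... two or more `parameter_set` objects (at least one).
#' @param tol numeric tolerance for deciding that duplicate values agree.
#' @return a merged `parameter_set`.
#' @export
merge_parameter_sets <- function(..., tol = 1e-9) {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  lapply(sets, function(s) stopifnot(inherits(s, "parameter_set")))
  tabs <- c("vdw", "bonds", "angles", "torsions", "impropers")
  tcols <- list(vdw = "type_code", bonds = c("ti", "tj"),
                angles = c("ti", "tj", "tk"),
                torsions = c("ti", "tj", "tk", "tl"),
                impropers = c("ti", "tj", "tk", "tl"))
  out <- list()
  for (tb in tabs) {
    all <- do.call(rbind, lapply(sets, `[[`, tb))
    if (!nrow(all)) { out[[tb]] <- all; next }
    key <- .param_keys(all, tcols[[tb]])
    keep <- !duplicated(key)
    for (k in unique(key[duplicated(key)])) {
      rows <- all[key == k, setdiff(names(all), tcols[[tb]]), drop = FALSE]
      rng <- apply(as.matrix(rows), 2, function(v) diff(range(v)))
      if (any(rng > tol))
        stop("parameter conflict for key '", k, "': ",
             paste(apply(unique(rows), 1, paste, collapse = "/"),
                   collapse = " vs "))
    }
    out[[tb]] <- all[keep, , drop = FALSE]
  }
  parameter_set(out$vdw, out$bonds, out$angles, out$torsions, out$impropers)
}

#' Write a parameter set as a Q-style parameter file
#'
#' @param params a [parameter_set()].
#' @param path output file.
#' @param topology optional [ligand_topology()]; if given, every
#'   `type_code` it references must resolve in `params`, otherwise a
#'   missing-parameter error listing the codes is raised.
#' @return `path`, invisibly.
#' @export
write_q_parameters <- function(params, path, topology = NULL) {
  stopifnot(inherits(params, "parameter_set"))
  if (!is.null(topology)) {
    miss <- setdiff(stats::na.omit(unique(topology$atoms$type_code)),
                    params$vdw$type_code)
    if (length(miss))
      stop("missing-parameter error: unresolved type code(s): ",
           paste(miss, collapse = ", "))
  }
  fmt <- function(df) {
    if (!nrow(df)) return(character())
    apply(df, 1, function(r) paste0("    ", paste(trimws(r), collapse = "  ")))
  }
  lines <- c("[options]", "    dialect dualfep-prm-1",
             "[atom_types]", fmt(params$vdw),
             "[bonds]", fmt(params$bonds),
             "[angles]", fmt(params$angles),
             "[torsions]", fmt(params$torsions),
             "[impropers]", fmt(params$impropers))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Q-style parameter file
#'
#' @param path parameter file written by [write_q_parameters()].
#' @return a [parameter_set()].
#' @export
read_q_parameters <- function(path) {
  ps <- .read_sections(readLines(path, warn = FALSE))$sections
  grab <- function(sec, cols, ntypes) {
    lines <- ps[[sec]]
    if (is.null(lines) || !length(lines)) return(NULL)
    tok <- .tokens(lines)
    df <- as.data.frame(do.call(rbind, tok), stringsAsFactors = FALSE)
    names(df) <- cols
    for (j in seq(ntypes + 1, length(cols))) df[[j]] <- as.numeric(df[[j]])
    df
  }
  parameter_set(
    vdw = grab("atom_types", c("type_code", "epsilon", "radius", "mass"), 1),
    bonds = grab("bonds", c("ti", "tj", "k", "r0"), 2),
    angles = grab("angles", c("ti", "tj", "tk", "k", "theta0"), 3),
    torsions = grab("torsions", c("ti", "tj", "tk", "tl", "k",
                                  "periodicity", "phase"), 4),
    impropers = grab("impropers", c("ti", "tj", "tk", "tl", "k", "phase"), 4))
}

# ---------------------------------------------------------------------------

#' Validate a ligand topology against a parameter set
#'
#' Report-only check: net charge and whether it is integral within
#' `charge_tol` (published charge sets are rounded, hence the loose
#' default of 1e-3 e), force-field type codes that do not resolve in the
#' parameter set, and atoms not involved in any bond.
#'
#' @param lig a [ligand_topology()].
#' @param params optional [parameter_set()].
#' @param charge_tol tolerance (e) for the integer net-charge flag.
#' @return list with `net_charge`, `integer_charge` flag,
#'   `missing_types`, `disconnected_atoms` (names), and `ok`.
#' @export
validate_ligand <- function(lig, params = NULL, charge_tol = 1e-3) {
  stopifnot(inherits(lig, "ligand_topology"))
  q <- net_charge(lig)
  missing_types <- character()
  if (!is.null(params))
    missing_types <- setdiff(stats::na.omit(unique(lig$atoms$type_code)),
                             params$vdw$type_code)
  n <- nrow(lig$atoms)
  deg <- tabulate(as.vector(lig$bonds), nbins = n)
  disconnected <- if (n > 1) lig$atoms$name[deg == 0] else character()
  rep <- list(net_charge = q,
              integer_charge = abs(q - round(q)) <= charge_tol,
              missing_types = missing_types,
              disconnected_atoms = disconnected)
  rep$ok <- rep$integer_charge && !length(missing_types) &&
    !length(disconnected)
  class(rep) <- "ligand_validation"
  rep
}

#' @export
print.ligand_validation <- function(x, ...) {
  cat("ligand validation:", if (x$ok) "OK" else "issues found", "\n")
  cat("  net charge:", format(x$net_charge, digits = 6),
      if (!x$integer_charge) " (non-integer!)", "\n")
  if (length(x$missing_types))
    cat("  unresolved types:", paste(x$missing_types, collapse = ", "), "\n")
  if (length(x$disconnected_atoms))
    cat("  disconnected atoms:",
        paste(x$disconnected_atoms, collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Ligand interchange format: one self-contained text file carrying atoms
# (with coordinates, types and charges), bonded lists and parameter tables,
# so that any external parameterizer (or a human) can hand a ligand to the
# workflow without Q-specific tooling.

#' Write a ligand and its parameters as one interchange file
#'
#' @param lig a [ligand_topology()] with coordinates.
#' @param params a [parameter_set()] resolving every type the ligand uses.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ligand_interchange <- function(lig, params, path) {
  stopifnot(inherits(lig, "ligand_topology"), inherits(params, "parameter_set"))
  a <- lig$atoms
  idx <- function(m) if (nrow(m)) apply(m, 1, paste, collapse = " ") else character()
  fmt <- function(df) if (nrow(df)) apply(df, 1, function(r)
    paste(trimws(r), collapse = "  ")) else character()
  lines <- c("# dualfep ligand interchange v1",
             "[meta]", paste("residue_name", lig$residue_name),
             "[atoms]",
             sprintf("%d %s %s %s %.6f %.6f %.6f %.6f",
                     seq_len(nrow(a)), a$name, a$element, a$type_code,
                     a$charge, a$x, a$y, a$z),
             "[bonds]", idx(lig$bonds),
             "[angles]", idx(lig$angles),
             "[torsions]", idx(lig$torsions),
             "[impropers]", idx(lig$impropers),
             "[charge_groups]",
             vapply(lig$charge_groups, paste, "", collapse = " "),
             "[vdw]", fmt(params$vdw),
             "[bond_params]", fmt(params$bonds),
             "[angle_params]", fmt(params$angles),
             "[torsion_params]", fmt(params$torsions),
             "[improper_params]", fmt(params$impropers))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ligand interchange file
#'
#' @param path file written by [write_ligand_interchange()].
#' @return list with elements `topology` and `parameters`.
#' @export
read_ligand_interchange <- function(path) {
  ps <- .read_sections(readLines(path, warn = FALSE))$sections
  meta <- .tokens(ps$meta %||% character())
  res <- "LIG"
  for (m in meta) if (m[1] == "residue_name") res <- m[2]
  tok <- .tokens(ps$atoms)
  atoms <- data.frame(name = vapply(tok, `[`, "", 2),
                      element = vapply(tok, `[`, "", 3),
                      type_code = vapply(tok, `[`, "", 4),
                      charge = as.numeric(vapply(tok, `[`, "", 5)),
                      x = as.numeric(vapply(tok, `[`, "", 6)),
                      y = as.numeric(vapply(tok, `[`, "", 7)),
                      z = as.numeric(vapply(tok, `[`, "", 8)),
                      stringsAsFactors = FALSE)
  ints <- function(sec, k) {
    lines <- ps[[sec]]
    if (is.null(lines) || !length(lines)) return(NULL)
    t(vapply(.tokens(lines), function(v) as.integer(v[seq_len(k)]),
             integer(k)))
  }
  grab <- function(sec, cols, ntypes) {
    lines <- ps[[sec]]
    if (is.null(lines) || !length(lines)) return(NULL)
    df <- as.data.frame(do.call(rbind, .tokens(lines)),
                        stringsAsFactors = FALSE)
    names(df) <- cols
    for (j in seq(ntypes + 1, length(cols))) df[[j]] <- as.numeric(df[[j]])
    df
  }
  cg <- ps$charge_groups
  groups <- if (is.null(cg) || !length(cg)) NULL else
    lapply(.tokens(cg), as.integer)
  lig <- ligand_topology(res, atoms, bonds = ints("bonds", 2),
                         angles = ints("angles", 3),
                         torsions = ints("torsions", 4),
                         impropers = ints("impropers", 4),
                         charge_groups = groups)
  params <- parameter_set(
    vdw = grab("vdw", c("type_code", "epsilon", "radius", "mass"), 1),
    bonds = grab("bond_params", c("ti", "tj", "k", "r0"), 2),
    angles = grab("angle_params", c("ti", "tj", "tk", "k", "theta0"), 3),
    torsions = grab("torsion_params",
                    c("ti", "tj", "tk", "tl", "k", "periodicity", "phase"), 4),
    impropers = grab("improper_params",
                     c("ti", "tj", "tk", "tl", "k", "phase"), 4))
  list(topology = lig, parameters = params)
}
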