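# Internal units: nm, ps, kJ/mol, K. Coordinates are converted on ingest
# (PDB Angstrom -> nm); all public functions speak nm.

ROLE_LEVELS <- c("protein_backbone_N", "protein_backbone_CA", "protein_backbone_C",
                 "cd_primary_rim", "cd_secondary_rim", "water", "other")

ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, M = 0.0)

#' Construct a topology
#'
#' A topology is a data frame with one row per atom holding identity,
#' residue and molecule bookkeeping, plus an interface-analysis `role`
#' tag (see [assign_roles()]).
#'
#' @param atom_name character atom names.
#' @param residue_name character residue names.
#' @param residue_index 1-based integer residue index per atom.
#' @param molecule_id integer molecule id per atom.
#' @param element element symbols; guessed from `atom_name` if missing.
#' @param mass atomic masses (amu); looked up from `element` if missing.
#' @param role role tags; `"other"` until [assign_roles()] is run.
#' @param frozen logical per atom; marks an explicitly frozen group
#'   (e.g. an ice slab). Never inferred from coordinates.
#' @return object of class `cdx_topology` (a data frame).
#' @export
cdx_topology <- function(atom_name, residue_name, residue_index,
                         molecule_id = NULL, element = NULL, mass = NULL,
                         role = NULL, frozen = NULL) {
  n <- length(atom_name)
  residue_index <- as.integer(residue_index)
  if (any(residue_index < 1L)) stop("residue_index must be >= 1 (1-based)")
  if (is.null(element)) element <- guess_element(atom_name)
  if (is.null(mass)) {
    mass <- unname(ATOMIC_MASSES[element])
    mass[is.na(mass)] <- 12.011
  }
  if (any(mass < 0)) stop("mass must be >= 0")
  if (is.null(molecule_id)) molecule_id <- residue_index
  if (is.null(role)) role <- rep("other", n)
  stopifnot(all(role %in% ROLE_LEVELS))
  if (is.null(frozen)) frozen <- rep(FALSE, n)
  top <- data.frame(atom_name = as.character(atom_name),
                    residue_name = as.character(residue_name),
                    residue_index = residue_index,
                    molecule_id = as.integer(molecule_id),
                    element = as.character(element),
                    mass = as.numeric(mass),
                    role = as.character(role),
                    frozen = as.logical(frozen),
                    stringsAsFactors = FALSE)
  class(top) <- c("cdx_topology", "data.frame")
  top
}

guess_element <- function(atom_name) {
  e <- sub("^[0-9]*", "", atom_name)
  substr(e, 1L, 1L)
}

#' Construct a single coordinate frame
#'
#' @param coords numeric n x 3 matrix of coordinates in nm.
#' @param box orthorhombic box lengths `c(Lx, Ly, Lz)` in nm.
#' @param time frame time in ps.
#' @param periodic logical length-3: which axes are treated as periodic.
#'   Slab defaults: x and y periodic, z not (the vacuum or frozen slab
#'   along z breaks the symmetry even in a formally periodic box).
#' @return object of class `cdx_frame`.
#' @export
cdx_frame <- function(coords, box, time = 0,
                      periodic = c(TRUE, TRUE, FALSE)) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive lengths (nm)")
  structure(list(coords = coords, box = box, time = as.numeric(time),
                 periodic = as.logical(periodic)),
            class = "cdx_frame")
}

#' Construct a trajectory
#'
#' @param topology a [cdx_topology()].
#' @param frames list of [cdx_frame()] sharing that topology.
#' @return object of class `cdx_trajectory`.
#' @export
cdx_trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "cdx_topology"), length(frames) >= 1L)
  n <- nrow(topology)
  for (fr in frames) {
    if (!inherits(fr, "cdx_frame")) stop("frames must be cdx_frame objects")
    if (nrow(fr$coords) != n) stop("frame atom count does not match topology")
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames),
            class = "cdx_trajectory")
}

#' @export
print.cdx_trajectory <- function(x, ...) {
  cat(sprintf("cdx_trajectory: %d frames, %d atoms, %d molecules\n",
              length(x$frames), nrow(x$topology),
              length(unique(x$topology$molecule_id))))
  invisible(x)
}

#' @export
print.cdx_topology <- function(x, ...) {
  cat(sprintf("cdx_topology: %d atoms, %d residues\n", nrow(x),
              length(unique(x$residue_index))))
  print(table(x$role))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

# ---------------------------------------------------------------- structure IO

#' Read a structure file (PDB or GRO)
#'
#' Coordinates are stored in nm regardless of the source unit
#' (PDB Angstrom values are divided by 10). Atom order is preserved.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @return list with elements `topology` ([cdx_topology()]) and
#'   `frame` ([cdx_frame()]).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", gro = "gro",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  switch(format, gro = read_gro(path), pdb = read_pdb_structure(path))
}

# GRO fixed-column reader (no installed R package reads GROMACS .gro).
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed GRO file (fewer than 3 lines): ", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(natoms)) stop("malformed GRO file at line 2: atom count expected")
  if (length(lines) < natoms + 3L) stop("GRO file truncated: expected ",
                                        natoms, " atom lines")
  al <- lines[3:(natoms + 2L)]
  parse_field <- function(from, to) substr(al, from, to)
  resno <- suppressWarnings(as.integer(parse_field(1, 5)))
  resnm <- trimws(parse_field(6, 10))
  atnm <- trimws(parse_field(11, 15))
  x <- suppressWarnings(as.numeric(parse_field(21, 28)))
  y <- suppressWarnings(as.numeric(parse_field(29, 36)))
  z <- suppressWarnings(as.numeric(parse_field(37, 44)))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) stop("malformed GRO atom record at line ", bad[1L] + 2L)
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[natoms + 3L]),
                                               "\\s+")[[1L]]))
  if (length(boxv) < 3L || anyNA(boxv[1:3]))
    stop("malformed GRO box line at line ", natoms + 3L)
  # GRO residue numbers wrap at 99999; rebuild a monotone 1-based index
  ridx <- cumsum(c(1L, diff(resno) != 0L | diff(seq_along(resno)) < 0L))
  top <- cdx_topology(atnm, resnm, ridx)
  list(topology = top,
       frame = cdx_frame(cbind(x, y, z), boxv[1:3], time = 0))
}

read_pdb_structure <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("malformed PDB file ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  ridx <- cumsum(c(1L, (diff(a$resno) != 0L) |
                        (a$chain[-1L] != a$chain[-nrow(a)]) * 1L) != 0L)
  coords <- cbind(a$x, a$y, a$z) / 10  # Angstrom -> nm
  box <- infer_pdb_box(path, coords)
  top <- cdx_topology(a$elety, a$resid, ridx)
  list(topology = top, frame = cdx_frame(coords, box, time = 0))
}

infer_pdb_box <- function(path, coords) {
  cry <- grep("^CRYST1", readLines(path, n = 50L), value = TRUE)
  if (length(cry)) {
    b <- suppressWarnings(as.numeric(c(substr(cry[1], 7, 15),
                                       substr(cry[1], 16, 24),
                                       substr(cry[1], 25, 33)))) / 10
    if (!anyNA(b) && all(b > 0)) return(b)
  }
  pmax(apply(coords, 2, function(v) diff(range(v))) + 2, 1)
}

#' Write a GRO structure file
#'
#' @param topology,frame the structure to write.
#' @param path output path.
#' @export
write_gro <- function(topology, frame, path) {
  n <- nrow(topology)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("generated by cdslab", sprintf("%5d", n)), con)
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   topology$residue_index %% 100000L,
                   substr(topology$residue_name, 1, 5),
                   substr(topology$atom_name, 1, 5),
                   seq_len(n) %% 100000L,
                   frame$coords[, 1], frame$coords[, 2], frame$coords[, 3])
  writeLines(lines, con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
                     frame$box[3]), con)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' Plain-text fallback trajectory format: one MODEL block per frame,
#' coordinates written in Angstrom.
#'
#' @param trajectory a [cdx_trajectory()].
#' @param path output path.
#' @export
write_multimodel_pdb <- function(trajectory, path) {
  top <- trajectory$topology
  n <- nrow(top)
  con <- file(path, "w")
  on.exit(close(con))
  box <- trajectory$frames[[1L]]$box * 10
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     box[1], box[2], box[3]), con)
  for (k in seq_along(trajectory$frames)) {
    fr <- trajectory$frames[[k]]
    writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- fr$coords * 10
    writeLines(sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                       seq_len(n) %% 100000L,
                       substr(top$atom_name, 1, 4),
                       substr(top$residue_name, 1, 3),
                       top$residue_index %% 10000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a trajectory
#'
#' Supports a plain multi-model PDB (the package's text fixture format)
#' and binary DCD via `bio3d::read.dcd`. XTC is not readable in this
#' stack; convert to DCD or multi-model PDB first.
#'
#' @param path trajectory file.
#' @param topology optional [cdx_topology()]; required for DCD, inferred
#'   from the first model for PDB input.
#' @param dt frame spacing in ps used when the file stores no times.
#' @param format `"auto"`, `"pdb"` or `"dcd"`.
#' @return a [cdx_trajectory()].
#' @export
read_trajectory <- function(path, topology = NULL, dt = 1,
                            format = c("auto", "pdb", "dcd")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", dcd = "dcd",
                     xtc = stop("XTC is not supported; convert to DCD or multi-model PDB"),
                     stop("cannot infer trajectory format from '", ext, "'"))
  }
  if (format == "dcd") {
    if (is.null(topology)) stop("DCD input requires an explicit topology")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    coords_list <- lapply(seq_len(nrow(xyz)), function(i)
      matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10)
    box <- pmax(apply(coords_list[[1L]], 2, function(v) diff(range(v))) + 2, 1)
    frames <- lapply(seq_along(coords_list), function(i)
      cdx_frame(coords_list[[i]], box, time = (i - 1) * dt))
    return(cdx_trajectory(topology, frames))
  }
  read_multimodel_pdb(path, topology = topology, dt = dt)
}

read_multimodel_pdb <- function(path, topology = NULL, dt = 1) {
  lines <- readLines(path)
  cry <- grep("^CRYST1", lines, value = TRUE)
  box <- c(10, 10, 10)
  if (length(cry)) {
    b <- suppressWarnings(as.numeric(c(substr(cry[1], 7, 15),
                                       substr(cry[1], 16, 24),
                                       substr(cry[1], 25, 33)))) / 10
    if (!anyNA(b)) box <- b
  }
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (!length(starts)) { starts <- 0L; ends <- length(lines) + 1L }
  if (length(starts) != length(ends)) stop("unbalanced MODEL/ENDMDL records")
  frames <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    blk <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    at <- grep("^(ATOM|HETATM)", blk, value = TRUE)
    xyz <- cbind(as.numeric(substr(at, 31, 38)),
                 as.numeric(substr(at, 39, 46)),
                 as.numeric(substr(at, 47, 54))) / 10
    if (anyNA(xyz)) stop("malformed ATOM record in model ", k)
    if (k == 1L && is.null(topology)) {
      topology <- cdx_topology(trimws(substr(at, 13, 16)),
                               trimws(substr(at, 18, 21)),
                               rebuild_residue_index(as.integer(substr(at, 23, 26))))
    }
    frames[[k]] <- cdx_frame(xyz, box, time = (k - 1) * dt)
  }
  cdx_trajectory(topology, frames)
}

rebuild_residue_index <- function(resno) {
  cumsum(c(1L, as.integer(diff(resno) != 0L)))
}

# ------------------------------------------------------------------- roles

#' Default atom/residue naming scheme
#'
#' Maps residue and atom names to interface-analysis roles. The defaults
#' cover CHARMM-style names: glucose residues of a cyclodextrin carry C6
#' on the primary rim and C2/C3 on the secondary rim; protein backbone
#' is N/CA/C; common water residue names are recognised. Override any
#' entry, or load a YAML file with [read_naming_scheme()], when a
#' topology uses a different convention.
#'
#' @return named list with entries `protein_residues`, `cd_residues`,
#'   `water_residues`, `primary_rim_atoms`, `secondary_rim_atoms`,
#'   `backbone_atoms`, `glucose_per_cd`.
#' @export
default_naming_scheme <- function() {
  list(protein_residues = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                            "GLY", "HIS", "HSD", "HSE", "ILE", "LEU", "LYS",
                            "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR",
                            "VAL"),
       cd_residues = c("GLC", "BGLC", "AGLC", "BCD", "MGLC", "GCU"),
       water_residues = c("SOL", "HOH", "TIP3", "WAT", "SPC", "ICE"),
       primary_rim_atoms = c("C6"),
       secondary_rim_atoms = c("C2", "C3"),
       backbone_atoms = c(N = "N", CA = "CA", C = "C"),
       glucose_per_cd = 7L)
}

#' Read a naming scheme from YAML
#'
#' @param path YAML file whose keys override [default_naming_scheme()].
#' @export
read_naming_scheme <- function(path) {
  usr <- yaml::read_yaml(path)
  utils::modifyList(default_naming_scheme(), usr)
}

#' Assign molecular roles to a topology
#'
#' Tags every atom with one of: `protein_backbone_N`,
#' `protein_backbone_CA`, `protein_backbone_C`, `cd_primary_rim`,
#' `cd_secondary_rim`, `water`, `other`. Consecutive glucose residues are
#' grouped into cyclodextrin molecules of `glucose_per_cd` units (7 for a
#' beta-cyclodextrin: 7 C6 primary-rim atoms, 14 C2/C3 secondary-rim
#' atoms); a run not divisible by 7 is a structural error. Molecule ids
#' are rebuilt so one cyclodextrin (and one contiguous protein chain) is
#' one molecule. Idempotent.
#'
#' @param topology a [cdx_topology()].
#' @param scheme naming scheme, see [default_naming_scheme()].
#' @return the topology with `role` and `molecule_id` filled in.
#' @export
assign_roles <- function(topology, scheme = default_naming_scheme()) {
  res <- topology$residue_name
  is_prot <- res %in% scheme$protein_residues
  is_cd <- res %in% scheme$cd_residues
  is_wat <- res %in% scheme$water_residues

  role <- rep("other", nrow(topology))
  bb <- scheme$backbone_atoms
  role[is_prot & topology$atom_name == bb[["N"]]] <- "protein_backbone_N"
  role[is_prot & topology$atom_name == bb[["CA"]]] <- "protein_backbone_CA"
  role[is_prot & topology$atom_name == bb[["C"]]] <- "protein_backbone_C"
  role[is_cd & topology$atom_name %in% scheme$primary_rim_atoms] <- "cd_primary_rim"
  role[is_cd & topology$atom_name %in% scheme$secondary_rim_atoms] <- "cd_secondary_rim"
  role[is_wat] <- "water"

  unknown <- !(is_prot | is_cd | is_wat)
  n_unk <- sum(unknown & role == "other")
  if (n_unk > 0L && !all(res[unknown] %in% res[is_prot | is_cd | is_wat]))
    warning(n_unk, " atoms in unrecognised residues tagged 'other'")

  # molecule ids: contiguous protein stretch = 1 molecule; every
  # glucose_per_cd consecutive glucose residues = 1 CD; else 1 per residue
  rle_res <- rle(topology$residue_index)
  res_first <- cumsum(c(1L, utils::head(rle_res$lengths, -1L)))
  res_kind <- ifelse(is_prot[res_first], "P",
                     ifelse(is_cd[res_first], "C", "O"))
  kind_runs <- rle(res_kind)
  mol_of_res <- integer(length(res_kind))
  mol <- 0L
  pos <- 1L
  for (r in seq_along(kind_runs$lengths)) {
    len <- kind_runs$lengths[r]
    idx <- pos:(pos + len - 1L)
    if (kind_runs$values[r] == "P") {
      mol <- mol + 1L
      mol_of_res[idx] <- mol
    } else if (kind_runs$values[r] == "C") {
      g <- scheme$glucose_per_cd
      if (len %% g != 0L)
        stop("cyclodextrin with ", len, " glucose residues; expected a multiple of ", g)
      mol_of_res[idx] <- mol + ceiling(seq_len(len) / g)
      mol <- mol + len %/% g
    } else {
      mol_of_res[idx] <- mol + seq_len(len)
      mol <- mol + len
    }
    pos <- pos + len
  }
  topology$molecule_id <- rep(mol_of_res, rle_res$lengths)
  topology$role <- role
  topology
}

# --------------------------------------------------------------- geometry

#' Minimum-image distance between two points
#'
#' Euclidean distance honouring periodicity only on the frame's periodic
#' axes (z is non-periodic in slab systems).
#'
#' @param a,b numeric length-3 points (nm).
#' @param frame a [cdx_frame()] supplying box and periodic axes.
#' @return distance in nm.
#' @export
minimum_image_distance <- function(a, b, frame) {
  d <- as.numeric(b) - as.numeric(a)
  p <- frame$periodic
  d[p] <- d[p] - frame$box[p] * round(d[p] / frame$box[p])
  sqrt(sum(d^2))
}

# Vectorised minimum-image displacement for an n x 3 matrix of deltas.
min_image_delta <- function(d, box, periodic) {
  for (ax in which(periodic))
    d[, ax] <- d[, ax] - box[ax] * round(d[, ax] / box[ax])
  d
}

# Min distance between every row-block: returns min over all pairs (A x B).
min_cross_distance <- function(A, B, box, periodic) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    d <- sweep(B, 2, A[i, ])
    d <- min_image_delta(d, box, periodic)
    best <- min(best, min(rowSums(d^2)))
  }
  sqrt(best)
}

# ------------------------------------------------------------- selections

#' Select atom indices by group label
#'
#' @param topology a role-assigned [cdx_topology()].
#' @param group `"protein"`, `"cd"`, `"water"`, `"frozen"`, a logical
#'   mask, or integer atom indices (returned as-is).
#' @param heavy_only drop hydrogens.
#' @return integer atom indices.
#' @export
select_atoms <- function(topology, group, heavy_only = FALSE) {
  idx <- if (is.numeric(group)) {
    as.integer(group)
  } else if (is.logical(group)) {
    which(group)
  } else {
    switch(match.arg(group, c("protein", "cd", "water", "frozen")),
      protein = which(startsWith(topology$role, "protein_backbone") |
                        topology$residue_name %in%
                          default_naming_scheme()$protein_residues),
      cd = which(topology$role %in% c("cd_primary_rim", "cd_secondary_rim") |
                   topology$residue_name %in%
                     default_naming_scheme()$cd_residues),
      water = which(topology$role == "water" & !topology$frozen),
      frozen = which(topology$frozen))
  }
  if (heavy_only) idx <- idx[topology$element[idx] != "H"]
  idx
}

# Molecule ids belonging to a group selection.
group_molecules <- function(topology, group) {
  sort(unique(topology$molecule_id[select_atoms(topology, group)]))
}

# Heavy-atom (optionally mass-weighted) centre of mass of one molecule.
molecule_com <- function(topology, frame, mol_id, mass_weighted = TRUE) {
  idx <- which(topology$molecule_id == mol_id & topology$element != "H")
  w <- if (mass_weighted) topology$mass[idx] else rep(1, length(idx))
  colSums(frame$coords[idx, , drop = FALSE] * w) / sum(w)
}

# COM z of every molecule in `mol_ids` for one frame (vectorised).
molecule_com_z <- function(topology, frame, mol_ids, mass_weighted = TRUE) {
  heavy <- topology$element != "H" & topology$molecule_id %in% mol_ids
  w <- if (mass_weighted) topology$mass[heavy] else rep(1, sum(heavy))
  z <- frame$coords[heavy, 3]
  mid <- topology$molecule_id[heavy]
  num <- tapply(z * w, mid, sum)
  den <- tapply(w, mid, sum)
  out <- as.numeric(num / den)
  names(out) <- names(num)
  out[as.character(mol_ids)]
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
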