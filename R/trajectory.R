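## Multi-model PDB trajectory I/O and covalent topology inference.
##
## A trajectory is a fixed set of atoms observed at ticks t_i = i * delta
## (delta in ps). One PDB MODEL block = one tick. Covalent topology is
## inferred once, on the first conformation, and held fixed: bonded atoms
## do not change along a classical MD trajectory.

## Covalent radii (Angstrom), single-bond values. Unlisted elements fall
## back to the carbon radius.
.covalent_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20,
  FE = 1.32, ZN = 1.22, MG = 1.41, MN = 1.39, CU = 1.32, CA = 1.76,
  "NA" = 1.66, K = 2.03
)

.covalent_tolerance <- 0.4

covalent_radius <- function(element) {
  r <- .covalent_radii[toupper(element)]
  r[is.na(r)] <- 0.76
  unname(r)
}

.main_chain_names <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3", "HA")

## Derive an element symbol from a PDB atom name when columns 77-78 are
## blank: strip digits, take the leading one- or two-letter symbol.
element_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "SE"),
                two, substr(nm, 1, 1))
  out[nchar(out) == 0] <- "C"
  out
}

#' Construct a trajectory object
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resnum`, `chain`, `is_main_chain`.
#' @param coords numeric array `n_atoms x 3 x n_ticks` (Angstrom); the atom
#'   order matches `atoms`.
#' @param delta_ps tick spacing in picoseconds.
#' @param protein_label label used in data tables built from this trajectory.
#' @param topology optional precomputed topology (see [infer_topology()]);
#'   inferred from the first conformation when `NULL`.
#' @return An object of class `hb_trajectory`.
#' @export
hb_trajectory <- function(atoms, coords, delta_ps = 1, protein_label = "traj",
                          topology = NULL) {
  stopifnot(is.data.frame(atoms), length(dim(coords)) == 3,
            dim(coords)[1] == nrow(atoms), dim(coords)[2] == 3,
            delta_ps > 0, dim(coords)[3] >= 1)
  if (anyDuplicated(atoms$serial))
    stop("atom serials must be unique within a conformation")
  if (is.null(topology)) topology <- infer_topology(atoms, coords[, , 1])
  structure(list(atoms = atoms, coords = coords, delta_ps = delta_ps,
                 protein_label = protein_label, topology = topology),
            class = "hb_trajectory")
}

#' @export
print.hb_trajectory <- function(x, ...) {
  cat(sprintf("<hb_trajectory '%s': %d atoms, %d ticks, delta = %g ps>\n",
              x$protein_label, nrow(x$atoms), n_ticks(x), x$delta_ps))
  invisible(x)
}

#' Number of ticks in a trajectory
#' @param trajectory an `hb_trajectory`.
#' @export
n_ticks <- function(trajectory) dim(trajectory$coords)[3]

#' Infer covalent topology from one conformation
#'
#' Two atoms are covalently bonded iff their distance is at most the sum of
#' their covalent radii plus a 0.4 Angstrom tolerance. Every hydrogen must
#' have exactly one heavy-atom neighbour (its donor); hydrogens violating
#' this are excluded from donor pairing with a warning.
#'
#' @param atoms atom table (see [hb_trajectory()]).
#' @param xyz numeric `n_atoms x 3` coordinate matrix.
#' @return list with `neighbors` (per-atom integer index lists),
#'   `h_donor` (integer vector: for each atom, the index of its covalent
#'   heavy partner if the atom is a paired hydrogen, else `NA`).
#' @export
infer_topology <- function(atoms, xyz) {
  n <- nrow(atoms)
  rad <- covalent_radius(atoms$element)
  neighbors <- vector("list", n)
  if (n > 1) {
    d <- as.matrix(stats::dist(xyz))
    cut <- outer(rad, rad, "+") + .covalent_tolerance
    bonded <- d <= cut & d > 0
    diag(bonded) <- FALSE
    for (i in seq_len(n)) neighbors[[i]] <- unname(which(bonded[i, ]))
  } else {
    neighbors[[1]] <- integer(0)
  }
  is_h <- toupper(atoms$element) == "H"
  h_donor <- rep(NA_integer_, n)
  for (i in which(is_h)) {
    heavy <- neighbors[[i]][!is_h[neighbors[[i]]]]
    if (length(heavy) == 1L) {
      h_donor[i] <- heavy
    } else {
      warning(sprintf(
        "hydrogen serial %d has %d heavy-atom neighbors; excluded from donor pairing",
        atoms$serial[i], length(heavy)))
    }
  }
  list(neighbors = neighbors, h_donor = h_donor)
}

parse_pdb_model <- function(lines) {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0) return(NULL)
  serial <- as.integer(substr(lines, 7, 11))
  name <- trimws(substr(lines, 13, 16))
  resname <- trimws(substr(lines, 18, 20))
  chain <- substr(lines, 22, 22)
  resnum <- as.integer(substr(lines, 23, 26))
  x <- as.numeric(substr(lines, 31, 38))
  y <- as.numeric(substr(lines, 39, 46))
  z <- as.numeric(substr(lines, 47, 54))
  element <- trimws(substr(lines, 77, 78))
  blank <- is.na(element) | element == ""
  element[blank] <- element_from_name(name[blank])
  list(atoms = data.frame(serial = serial, name = name,
                          element = toupper(element),
                          resname = resname, resnum = resnum, chain = chain,
                          is_main_chain = name %in% .main_chain_names,
                          stringsAsFactors = FALSE),
       xyz = cbind(x, y, z))
}

#' Read a multi-model PDB trajectory
#'
#' One `MODEL` block is one tick; a file without `MODEL` records is a
#' single-tick trajectory. `path` may also be a directory of single-model
#' PDB files, ordered by their (zero-padded) numeric suffix.
#'
#' @param path PDB file or directory of per-tick PDB files.
#' @param delta_ps tick spacing in picoseconds (default 1).
#' @param protein_label trajectory label; defaults to the file stem.
#' @return An `hb_trajectory`.
#' @export
read_trajectory <- function(path, delta_ps = 1, protein_label = NULL) {
  if (is.null(protein_label))
    protein_label <- sub("\\.[^.]*$", "", basename(path))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.pdb$", full.names = TRUE)
    files <- files[order(files)]
    if (length(files) == 0) stop("no .pdb files found in directory: ", path)
    chunks <- lapply(files, readLines)
  } else {
    lines <- readLines(path)
    starts <- grep("^MODEL", lines)
    if (length(starts) == 0) {
      chunks <- list(lines)
    } else {
      ends <- grep("^ENDMDL", lines)
      if (length(ends) != length(starts))
        stop("unbalanced MODEL/ENDMDL records in ", path)
      chunks <- mapply(function(s, e) {
        if (e - s <= 1) character(0) else lines[(s + 1):(e - 1)]
      }, starts, ends, SIMPLIFY = FALSE)
    }
  }
  models <- lapply(chunks, parse_pdb_model)
  if (any(vapply(models, is.null, TRUE)))
    stop("model ", which(vapply(models, is.null, TRUE))[1],
         " contains no atoms")
  ref <- models[[1]]$atoms
  nt <- length(models)
  coords <- array(NA_real_, dim = c(nrow(ref), 3, nt))
  for (k in seq_len(nt)) {
    m <- models[[k]]
    if (!identical(sort(m$atoms$serial), sort(ref$serial)))
      stop(sprintf("model %d has a different atom set than model 1", k))
    coords[, , k] <- m$xyz[match(ref$serial, m$atoms$serial), , drop = FALSE]
  }
  hb_trajectory(ref, coords, delta_ps = delta_ps,
                protein_label = protein_label)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param trajectory an `hb_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  a <- trajectory$atoms
  nt <- n_ticks(trajectory)
  con <- file(path, "w")
  on.exit(close(con))
  name_fmt <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                     sprintf("%-4s", a$name))
  for (k in seq_len(nt)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- trajectory$coords[, , k, drop = FALSE]
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      a$serial, name_fmt, a$resname, a$chain, a$resnum,
      xyz[, 1, 1], xyz[, 2, 1], xyz[, 3, 1], a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
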