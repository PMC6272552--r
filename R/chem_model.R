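# Molecular system container, file I/O, connectivity and QM/MM partitioning.

#' Construct a molecular system
#'
#' The central container: an atom table plus bonded-topology index lists.
#' Coordinates are stored in bohr; every reader converts from Angstrom on
#' the way in. Atoms carry an optional MM type, partial charge and
#' Lennard-Jones parameters (epsilon in hartree, R_min in bohr) used by the
#' force-field and QM/MM coupling layers. `Z = 0` is reserved for Drude or
#' virtual sites, which are excluded from automatic connectivity detection.
#'
#' @param element character vector of element symbols ("X" for virtual sites)
#' @param xyz n x 3 matrix of positions in bohr
#' @param region atom region labels, "QM", "MM" or "LINK"
#' @param mm_type MM atom type strings (NA allowed until typed)
#' @param mm_charge partial charges in e
#' @param lj_eps,lj_rmin Lennard-Jones well depth (hartree) and minimum
#'   position (bohr)
#' @param bonds integer matrix (m x 2) of 0-based? No: 1-based atom index
#'   pairs with i < j. Angles, dihedrals and Urey-Bradley 1-3 pairs are
#'   derived with [derive_bonded_terms()] unless supplied.
#' @param Z,mass optional overrides for nuclear charge and mass (amu)
#' @return an object of class `qmm_system`
#' @export
molecular_system <- function(element, xyz, region = "MM", mm_type = NA_character_,
                             mm_charge = 0, lj_eps = 0, lj_rmin = 0,
                             bonds = NULL, Z = NULL, mass = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  stopifnot(length(element) == n, all(is.finite(xyz)))
  virt <- element == "X"
  if (is.null(Z)) {
    Z <- integer(n)
    if (any(!virt)) Z[!virt] <- element_info(element[!virt])$Z
  }
  if (is.null(mass)) {
    mass <- numeric(n)
    if (any(!virt)) mass[!virt] <- element_info(element[!virt])$mass
  }
  atoms <- data.frame(
    element = element, Z = as.integer(Z),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    mass = mass,
    region = rep_len(region, n),
    mm_type = rep_len(mm_type, n),
    mm_charge = rep_len(mm_charge, n),
    lj_eps = rep_len(lj_eps, n),
    lj_rmin = rep_len(lj_rmin, n),
    stringsAsFactors = FALSE
  )
  sys <- structure(list(atoms = atoms,
                        bonds = empty_bonds(), angles = NULL,
                        dihedrals = NULL, ureys = NULL),
                   class = "qmm_system")
  if (!is.null(bonds) && length(bonds)) sys <- set_bonds(sys, bonds)
  sys
}

empty_bonds <- function() matrix(integer(0), ncol = 2)

#' @export
print.qmm_system <- function(x, ...) {
  cat(sprintf("<qmm_system> %d atoms (%d QM, %d MM, %d link), %d bonds\n",
              nrow(x$atoms), sum(x$atoms$region == "QM"),
              sum(x$atoms$region == "MM"), sum(x$atoms$region == "LINK"),
              nrow(x$bonds)))
  invisible(x)
}

#' Atomic positions as a matrix
#' @param sys a `qmm_system`
#' @return n x 3 matrix in bohr
#' @export
positions <- function(sys) {
  as.matrix(sys$atoms[, c("x", "y", "z")])
}

#' Replace atomic positions
#' @param sys a `qmm_system`
#' @param xyz n x 3 matrix in bohr
#' @export
set_positions <- function(sys, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  stopifnot(nrow(xyz) == nrow(sys$atoms))
  sys$atoms$x <- xyz[, 1]; sys$atoms$y <- xyz[, 2]; sys$atoms$z <- xyz[, 3]
  sys
}

normalize_bonds <- function(bonds) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  swap <- bonds[, 1] > bonds[, 2]
  bonds[swap, ] <- bonds[swap, c(2, 1)]
  bonds <- unique(bonds)
  bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
}

set_bonds <- function(sys, bonds) {
  bonds <- normalize_bonds(bonds)
  n <- nrow(sys$atoms)
  if (length(bonds) && (min(bonds) < 1 || max(bonds) > n))
    stop("bond index out of range")
  if (length(bonds) && any(bonds[, 1] == bonds[, 2]))
    stop("self-bond not allowed")
  sys$bonds <- bonds
  derive_bonded_terms(sys)
}

#' Derive angles, dihedrals and Urey-Bradley pairs from the bond graph
#'
#' Angles are all i-j-k paths with i < k; dihedrals all i-j-k-l paths over
#' a central bond j-k; Urey-Bradley terms are the 1-3 pairs of each angle.
#'
#' @param sys a `qmm_system` with bonds set
#' @return the system with `angles`, `dihedrals`, `ureys` filled in
#' @export
derive_bonded_terms <- function(sys) {
  n <- nrow(sys$atoms)
  nb <- vector("list", n)
  if (nrow(sys$bonds)) {
    for (r in seq_len(nrow(sys$bonds))) {
      i <- sys$bonds[r, 1]; j <- sys$bonds[r, 2]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  angles <- list(); dihedrals <- list()
  for (j in seq_len(n)) {
    nbs <- sort(nb[[j]])
    if (length(nbs) >= 2) {
      cmb <- utils::combn(nbs, 2)
      for (c2 in seq_len(ncol(cmb)))
        angles[[length(angles) + 1]] <- c(cmb[1, c2], j, cmb[2, c2])
    }
  }
  if (nrow(sys$bonds)) {
    for (r in seq_len(nrow(sys$bonds))) {
      j <- sys$bonds[r, 1]; k <- sys$bonds[r, 2]
      for (i in setdiff(nb[[j]], k)) for (l in setdiff(nb[[k]], j)) {
        if (i == l) next
        dihedrals[[length(dihedrals) + 1]] <- c(i, j, k, l)
      }
    }
  }
  sys$angles <- if (length(angles)) do.call(rbind, angles) else matrix(integer(0), ncol = 3)
  sys$dihedrals <- if (length(dihedrals)) do.call(rbind, dihedrals) else matrix(integer(0), ncol = 4)
  sys$ureys <- if (nrow(sys$angles)) sys$angles[, c(1, 3), drop = FALSE] else empty_bonds()
  sys
}

# ------------------------------------------------------------------ file I/O

#' Read an XYZ file
#'
#' Standard XYZ: atom count, comment, then `element x y z` rows in Angstrom.
#' Positions are converted to bohr.
#'
#' @param path file path
#' @return a `qmm_system` (no bonds)
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("read_xyz: empty file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("read_xyz: malformed atom count on line 1 of ", path)
  if (length(lines) < n + 2) stop("read_xyz: fewer atom records than declared")
  el <- character(n); xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
    if (length(tok) < 4) stop("read_xyz: malformed atom record on line ", i + 2)
    el[i] <- tok[1]
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(v)) stop("read_xyz: non-numeric coordinate on line ", i + 2)
    xyz[i, ] <- v
  }
  element_info(el)  # validates symbols, errors name the offender
  molecular_system(el, ang2bohr(xyz))
}

#' Write an XYZ file
#'
#' Coordinates are written in Angstrom with 6 decimals; output is
#' deterministic.
#'
#' @param sys a `qmm_system`
#' @param path output path
#' @param comment comment line (may be empty)
#' @export
write_xyz <- function(sys, path, comment = "") {
  stopifnot(nrow(sys$atoms) > 0)
  xyz <- bohr2ang(positions(sys))
  rows <- sprintf("%-3s %14.6f %14.6f %14.6f",
                  sys$atoms$element, xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(as.character(nrow(sys$atoms)), comment, rows), path)
  invisible(path)
}

#' Read a point-charge file
#'
#' Whitespace-separated `x y z q` rows (Angstrom, e). Blank lines and
#' `#` comments are ignored.
#'
#' @param path file path
#' @return data.frame with columns x, y, z (bohr) and q (e)
#' @export
read_point_charges <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  keep <- nzchar(trimws(lines))
  out <- list()
  rowno <- 0
  for (i in which(keep)) {
    rowno <- rowno + 1
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(tok))
    if (length(v) != 4 || anyNA(v))
      stop("read_point_charges: non-numeric or malformed row ", i)
    out[[rowno]] <- v
  }
  if (!length(out))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      q = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(x = ang2bohr(m[, 1]), y = ang2bohr(m[, 2]), z = ang2bohr(m[, 3]),
             q = m[, 4])
}

#' Minimal PDB reader
#'
#' Reads ATOM/HETATM records only (fixed columns per PDB v3.3); occupancy
#' and B-factor are ignored. The element is taken from columns 77-78 when
#' present, otherwise from the leading letters of the atom name.
#'
#' @param path file path
#' @return a `qmm_system`
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) stop("read_pdb: no ATOM/HETATM records in ", path)
  el <- character(length(rec)); xyz <- matrix(0, length(rec), 3)
  for (i in seq_along(rec)) {
    ln <- rec[i]
    xyz[i, ] <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                              substr(ln, 39, 46),
                                              substr(ln, 47, 54))))
    if (anyNA(xyz[i, ])) stop("read_pdb: bad coordinates in record ", i)
    e <- trimws(substr(ln, 77, 78))
    if (!nzchar(e)) {
      nm <- trimws(substr(ln, 13, 16))
      e <- sub("[^A-Za-z].*", "", nm)
      e <- paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, 2)))
      if (!(e %in% .elements$symbol)) e <- substr(e, 1, 1)
    } else {
      e <- paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, 2)))
    }
    el[i] <- e
  }
  element_info(el)
  molecular_system(el, ang2bohr(xyz))
}

#' Write a multi-frame XYZ trajectory
#' @param frames list of n x 3 coordinate matrices (bohr)
#' @param elements element symbols
#' @param path output path
#' @param comments per-frame comment lines (recycled)
#' @export
write_xyz_trajectory <- function(frames, elements, path, comments = "") {
  comments <- rep_len(comments, length(frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    xyz <- bohr2ang(frames[[f]])
    writeLines(c(as.character(length(elements)), comments[f],
                 sprintf("%-3s %14.6f %14.6f %14.6f", elements,
                         xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}

# ------------------------------------------------------------- connectivity

#' Detect covalent bonds from interatomic distances
#'
#' A bond (i, j) is assigned when the distance does not exceed
#' `scale * (rcov_i + rcov_j)`. The default scale 1.3 accommodates
#' stretched bonds (a 0.74 Angstrom H-H bond is missed at 1.2). Virtual
#' sites (Z = 0) never bond. Angles, dihedrals and Urey pairs are derived
#' from the resulting graph.
#'
#' @param sys a `qmm_system`
#' @param scale covalent-radius scale factor (default 1.3)
#' @return the system with bonds and derived terms set
#' @export
build_connectivity <- function(sys, scale = 1.3) {
  real <- which(sys$atoms$Z >= 1)
  if (!length(real)) return(set_bonds(sys, NULL))
  info <- element_info(sys$atoms$element[real])
  rcov <- ang2bohr(info$rcov)
  xyz <- positions(sys)[real, , drop = FALSE]
  bonds <- list()
  for (a in seq_along(real)) {
    if (a == length(real)) break
    rest <- (a + 1):length(real)
    d <- sqrt(rowSums((xyz[rest, , drop = FALSE] -
                         matrix(xyz[a, ], length(rest), 3, byrow = TRUE))^2))
    hit <- rest[d <= scale * (rcov[a] + rcov[rest])]
    if (length(hit)) bonds[[length(bonds) + 1]] <- cbind(real[a], real[hit])
  }
  set_bonds(sys, if (length(bonds)) do.call(rbind, bonds) else NULL)
}

# ------------------------------------------------------------- partitioning

#' Partition a system into QM and MM regions
#'
#' @param sys a `qmm_system`
#' @param qm_selector either an integer vector of atom indices, or a list
#'   `list(center = index or 3-vector, radius = bohr)` selecting all atoms
#'   of molecules whose nearest atom lies within `radius` of the center.
#' @return a `qmm_partition`: `qm_indices`, `mm_indices`,
#'   `boundary_pairs` (matrix: QM boundary atom, MM boundary atom) --
#'   exactly the bonds crossing the cut.
#' @export
partition_by_selection <- function(sys, qm_selector) {
  n <- nrow(sys$atoms)
  real <- which(sys$atoms$Z >= 1)
  if (is.list(qm_selector)) {
    ctr <- qm_selector$center
    if (length(ctr) == 1) ctr <- positions(sys)[ctr, ]
    d <- sqrt(rowSums((positions(sys) -
                         matrix(ctr, n, 3, byrow = TRUE))^2))
    qm <- which(d <= qm_selector$radius & sys$atoms$Z >= 1)
  } else {
    qm <- as.integer(qm_selector)
  }
  qm <- sort(unique(qm))
  if (!length(qm)) stop("partition_by_selection: selector selects no atoms")
  if (min(qm) < 1 || max(qm) > n) stop("selector index out of range")
  mm <- setdiff(real, qm)
  bp <- matrix(integer(0), ncol = 2)
  if (nrow(sys$bonds)) {
    in_qm <- matrix(sys$bonds %in% qm, ncol = 2)
    cross <- xor(in_qm[, 1], in_qm[, 2])
    if (any(cross)) {
      b <- sys$bonds[cross, , drop = FALSE]
      qba <- ifelse(b[, 1] %in% qm, b[, 1], b[, 2])
      mba <- ifelse(b[, 1] %in% qm, b[, 2], b[, 1])
      bp <- cbind(qba, mba)
    }
  }
  structure(list(qm_indices = qm, mm_indices = mm, boundary_pairs = bp,
                 link_atoms = NULL),
            class = "qmm_partition")
}

#' @export
print.qmm_partition <- function(x, ...) {
  cat(sprintf("<qmm_partition> %d QM / %d MM atoms, %d boundary bond(s)\n",
              length(x$qm_indices), length(x$mm_indices),
              nrow(x$boundary_pairs)))
  invisible(x)
}
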