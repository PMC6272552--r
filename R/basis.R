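# Orbital basis sets (contracted Cartesian Gaussians, Gaussian94-style text
# dialect) and Hermite Gaussian auxiliary functions.
#
# Normalization conventions (documented here, used consistently throughout):
#  * every Cartesian primitive component is individually normalized to unit
#    self-overlap; contractions are renormalized to unit self-overlap;
#  * auxiliary Hermite Gaussians are normalized to unit self-overlap, with
#    the closed-form 1-D factor [ (z/2)^t (2t)!/t! sqrt(pi/(2z)) ]^(-1/2).

.dfact <- function(n) { # n!! with (-1)!! = 0!! = 1
  vapply(n, function(k) if (k < 2) 1 else prod(seq(k, 2, by = -2)), 1.0)
}

.cart_comps <- function(l) {
  out <- NULL
  for (lx in l:0) for (ly in (l - lx):0) out <- rbind(out, c(lx, ly, l - lx - ly))
  out
}

.prim_norm <- function(zeta, comp) {
  l <- sum(comp)
  (2 * zeta / pi)^0.75 * (4 * zeta)^(l / 2) /
    sqrt(prod(.dfact(2 * comp - 1)))
}

#' Construct a contracted Cartesian Gaussian shell
#'
#' All Cartesian components of the shell share exponents and contraction
#' coefficients. Components are individually normalized and the
#' contraction is renormalized to unit self-overlap. Angular momenta above
#' d (l = 2) are not supported.
#'
#' @param center 3-vector, bohr
#' @param l total angular momentum (0, 1 or 2)
#' @param exps primitive exponents, bohr^-2
#' @param coefs contraction coefficients (same length as `exps`)
#' @return a shell object (list) consumed by the integral routines
#' @export
gto_shell <- function(center, l, exps, coefs) {
  if (l > 2) stop("angular momenta above d (l = 2) are not supported")
  stopifnot(l >= 0, length(exps) == length(coefs), all(exps > 0))
  comps <- .cart_comps(l)
  # contraction self-overlap of per-primitive-normalized functions
  zi <- outer(exps, exps, function(a, b) (2 * sqrt(a * b) / (a + b))^(l + 1.5))
  renorm <- 1 / sqrt(sum(outer(coefs, coefs) * zi))
  coefn <- matrix(0, nrow(comps), length(exps))
  for (ci in seq_len(nrow(comps)))
    coefn[ci, ] <- renorm * coefs * vapply(exps, .prim_norm, 1.0,
                                           comp = comps[ci, ])
  list(center = as.numeric(center), l = as.integer(l),
       comps = matrix(as.integer(comps), ncol = 3), exps = as.numeric(exps),
       coefn = coefn, ncomp = nrow(comps))
}

.herm_norm1d <- function(zeta, t) {
  1 / sqrt((zeta / 2)^t * factorial(2 * t) / factorial(t) * sqrt(pi / (2 * zeta)))
}

#' Construct a primitive Hermite Gaussian auxiliary function
#'
#' A Hermite Gaussian of index (tx, ty, tz) is the corresponding
#' center-derivative of a spherical Gaussian. Total Hermite index is
#' limited to 2 (s, p, d-type fitting functions).
#'
#' @param center 3-vector, bohr
#' @param herm non-negative integer triple (Hermite index)
#' @param zeta exponent, bohr^-2
#' @return an auxiliary-function object (list)
#' @export
aux_hermite <- function(center, herm, zeta) {
  herm <- as.integer(herm)
  if (sum(herm) > 2) stop("Hermite indices above 2 are not supported")
  stopifnot(zeta > 0, all(herm >= 0))
  list(center = as.numeric(center), herm = herm, zeta = zeta,
       norm = prod(vapply(herm, .herm_norm1d, 1.0, zeta = zeta)))
}

# ------------------------------------------------------ Gaussian94 dialect

#' Read a basis set in the Gaussian94 text dialect
#'
#' Blocks are separated by `****`; each block starts with `<element> 0`
#' followed by shell cards `<L> <nprim> <scale>` and primitive rows.
#' `SP` cards carry two coefficient columns and are split into an S and a
#' P shell.
#'
#' @param path basis file
#' @return a basis library: named list (per element) of lists with `l`,
#'   `exps`, `coefs`
#' @export
read_basis_g94 <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(lines)]
  lib <- list()
  i <- 1
  lmap <- c(S = 0L, P = 1L, D = 2L)
  while (i <= length(lines)) {
    if (lines[i] == "****") { i <- i + 1; next }
    hdr <- strsplit(lines[i], "\\s+")[[1]]
    el <- hdr[1]
    i <- i + 1
    shells <- list()
    while (i <= length(lines) && lines[i] != "****") {
      card <- strsplit(lines[i], "\\s+")[[1]]
      ltag <- toupper(card[1]); np <- as.integer(card[2])
      if (is.na(np)) stop("read_basis_g94: bad shell card: ", lines[i])
      rows <- lines[(i + 1):(i + np)]
      m <- do.call(rbind, lapply(rows, function(r)
        as.numeric(strsplit(gsub("[DdE]([+-])", "e\\1", r), "\\s+")[[1]])))
      if (ltag == "SP") {
        shells[[length(shells) + 1]] <- list(l = 0L, exps = m[, 1], coefs = m[, 2])
        shells[[length(shells) + 1]] <- list(l = 1L, exps = m[, 1], coefs = m[, 3])
      } else {
        if (!ltag %in% names(lmap))
          stop("read_basis_g94: unsupported shell type ", ltag)
        shells[[length(shells) + 1]] <- list(l = lmap[[ltag]], exps = m[, 1],
                                             coefs = m[, 2])
      }
      i <- i + np + 1
    }
    lib[[el]] <- shells
  }
  structure(lib, class = "basis_library")
}

#' Load a shipped basis set by name
#'
#' Two small built-in sets are shipped: `"sto3g"` (minimal) and `"dzvp"`
#' (double-zeta plus polarization quality; the exponents are the
#' package's own). A path to a Gaussian94-dialect file is also accepted.
#'
#' @param name basis name or file path
#' @export
load_basis <- function(name) {
  if (file.exists(name)) return(read_basis_g94(name))
  f <- system.file("extdata", "basis", paste0(name, ".g94"),
                   package = "auxqmmm")
  if (!nzchar(f)) stop("unknown basis set: ", name)
  read_basis_g94(f)
}

#' Build the orbital shell list for (a subset of) a system
#'
#' @param sys a `qmm_system`
#' @param basis a `basis_library` or basis name
#' @param indices atom indices to cover (default: all real atoms)
#' @return list of shells; each carries an `atom` attribute (index into
#'   `indices` order) and the shells are ordered atom-major
#' @export
build_shells <- function(sys, basis, indices = which(sys$atoms$Z >= 1)) {
  if (is.character(basis)) basis <- load_basis(basis)
  xyz <- positions(sys)
  shells <- list()
  for (k in seq_along(indices)) {
    ia <- indices[k]
    el <- sys$atoms$element[ia]
    if (is.null(basis[[el]]))
      stop("basis set has no entry for element ", el)
    for (s in basis[[el]]) {
      sh <- gto_shell(xyz[ia, ], s$l, s$exps, s$coefs)
      sh$atom <- k
      shells[[length(shells) + 1]] <- sh
    }
  }
  shells
}

n_basis_functions <- function(shells) sum(vapply(shells, `[[`, 0L, "ncomp"))

# ------------------------------------------------- auxiliary set generation

#' Generate an even-tempered Hermite auxiliary set
#'
#' For each atom, exponents form a geometric progression with the given
#' ratio spanning [zmin, 2 zmax] of the atom's orbital exponents (orbital
#' products have exponents up to 2 zmax). s-type Hermite functions are
#' placed at every exponent; with `kind = "ET-spd"`, p- and d-type Hermite
#' functions are added at every second exponent.
#'
#' @param sys a `qmm_system`
#' @param shells orbital shells from [build_shells()]
#' @param kind `"ET-s"` or `"ET-spd"`
#' @param ratio progression ratio (default 2.5)
#' @return list of auxiliary functions, each carrying an `atom` attribute
#' @export
make_aux_basis <- function(sys, shells, kind = c("ET-spd", "ET-s"),
                           ratio = 2.5) {
  kind <- match.arg(kind)
  atoms <- vapply(shells, `[[`, 0L, "atom")
  aux <- list()
  for (k in sort(unique(atoms))) {
    ash <- shells[atoms == k]
    ctr <- ash[[1]]$center
    ex <- unlist(lapply(ash, `[[`, "exps"))
    zmin <- min(ex); zmax <- 2 * max(ex)
    nz <- max(2, ceiling(log(zmax / zmin) / log(ratio)) + 1)
    zs <- zmin * ratio^(seq_len(nz) - 1)
    for (iz in seq_along(zs)) {
      a <- aux_hermite(ctr, c(0L, 0L, 0L), zs[iz]); a$atom <- k
      aux[[length(aux) + 1]] <- a
      if (kind == "ET-spd" && iz %% 2 == 1) {
        hs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                    c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),
                    c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
        for (r in seq_len(nrow(hs))) {
          a <- aux_hermite(ctr, hs[r, ], zs[iz]); a$atom <- k
          aux[[length(aux) + 1]] <- a
        }
      }
    }
  }
  aux
}
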