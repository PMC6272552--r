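#' @useDynLib auxqmmm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif optim uniroot setNames sd var
#' @importFrom utils head tail
NULL

# Internal unit system: hartree, bohr, elementary charge, electron mass,
# atomic unit of time. File interfaces use Angstrom; MM parameter files use
# kcal/mol, Angstrom and degrees and are converted on read.

#' Physical constants and unit conversions
#'
#' Conversion factors used throughout the package. All internal quantities
#' are in Hartree atomic units.
#'
#' @format A named list: `bohr_per_ang`, `kcalmol_per_hartree`,
#'   `me_per_amu` (electron masses per unified amu), `aut_per_fs`
#'   (atomic time units per femtosecond), `kb` (Boltzmann constant,
#'   hartree/K).
#' @export
#' @examples
#' units_au$bohr_per_ang * 1.0  # one Angstrom in bohr
units_au <- list(
  bohr_per_ang       = 1.8897261254578281,
  kcalmol_per_hartree = 627.5094740631,
  me_per_amu         = 1822.888486209,
  aut_per_fs         = 41.341374575751,
  kb                 = 3.166811563e-6
)

#' Unit conversion helpers
#'
#' Angstrom/bohr and kcal/mol / hartree conversions used at every file
#' interface.
#' @param x numeric
#' @name unit-conversions
#' @export
ang2bohr <- function(x) x * units_au$bohr_per_ang

#' @rdname unit-conversions
#' @export
bohr2ang <- function(x) x / units_au$bohr_per_ang

#' @rdname unit-conversions
#' @export
kcal2hartree <- function(x) x / units_au$kcalmol_per_hartree

deg2rad <- function(x) x * pi / 180

# Element data: Z, atomic mass (amu), covalent radius (Angstrom,
# Cordero-type values), Bragg-Slater-like grid radius (Angstrom).
.elements <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "P", "S", "Cl", "K", "Ca", "Br"),
  Z      = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 15, 16, 17, 19, 20, 35),
  mass   = c(1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999,
             18.998, 20.180, 22.990, 24.305, 30.974, 32.06, 35.453,
             39.098, 40.078, 79.904),
  rcov   = c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
             1.66, 1.41, 1.07, 1.05, 1.02, 2.03, 1.76, 1.20),
  rgrid  = c(0.35, 0.30, 1.45, 1.05, 0.85, 0.70, 0.65, 0.60, 0.50, 0.45,
             1.80, 1.50, 1.00, 1.00, 1.00, 2.20, 1.80, 1.15),
  stringsAsFactors = FALSE
)

element_info <- function(symbol) {
  i <- match(symbol, .elements$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "))
  }
  .elements[i, , drop = FALSE]
}

symbol_from_z <- function(Z) {
  i <- match(Z, .elements$Z)
  if (anyNA(i)) stop("no element with Z = ", paste(Z[is.na(i)], collapse = ","))
  .elements$symbol[i]
}
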