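# User-facing integral interfaces over the compiled McMurchie-Davidson core.

#' Boys function
#'
#' F_n(x) = integral of t^(2n) exp(-x t^2) over [0, 1], the kernel of all
#' Gaussian Coulomb integrals. Evaluated by a downward-recursion series for
#' small arguments and the asymptotic branch with upward recursion for
#' large ones (switch point x = 40).
#'
#' @param n order (scalar, >= 0)
#' @param x argument (>= 0)
#' @return F_n(x)
#' @export
#' @examples
#' boys(0, 0)  # 1
boys <- function(n, x) {
  if (n < 0 || x < 0) stop("boys: arguments must be non-negative")
  cpp_boys(as.integer(n), x)[n + 1]
}

#' Overlap integrals with optionally raised angular momentum
#'
#' Returns the block of <a+m|b> over the Cartesian components of the two
#' shells; `shift` is the raise index m applied to shell `a`.
#'
#' @param a,b shells from [gto_shell()]
#' @param shift non-negative integer triple (default no raise)
#' @return ncomp_a x ncomp_b matrix
#' @export
overlap <- function(a, b, shift = c(0L, 0L, 0L)) {
  stopifnot(all(shift >= 0))
  m <- matrix(as.integer(shift), 1, 3)
  out <- cpp_ov_block_upto(a, b, m)
  matrix(out, a$ncomp, b$ncomp)
}

# all raised overlaps for a list of m triples: array (na, nb, nm)
overlap_raised <- function(a, b, mlist) {
  cpp_ov_block_upto(a, b, matrix(as.integer(mlist), ncol = 3))
}

#' Kinetic-energy integrals
#' @param a,b shells
#' @return ncomp_a x ncomp_b matrix of -1/2 <a|del^2|b>
#' @export
kinetic <- function(a, b) cpp_kin_block(a, b)

#' Exact nuclear-attraction integrals
#'
#' <a| 1/|r - D| |b> over shell components, evaluated by Hermite Coulomb
#' recursion over Boys functions.
#'
#' @param a,b shells
#' @param D site position, 3-vector (bohr)
#' @return ncomp_a x ncomp_b matrix
#' @export
nai_exact <- function(a, b, D) {
  stopifnot(all(is.finite(D)))
  cpp_nai_sites_block(a, b, matrix(as.numeric(D), 1, 3), 1.0)
}

# summed site contributions: sum_D q_D <a|1/|r-D||b>
nai_sites <- function(a, b, sites, q) {
  if (!nrow(sites)) return(matrix(0, a$ncomp, b$ncomp))
  cpp_nai_sites_block(a, b, as.matrix(sites), as.numeric(q))
}

#' Two-center repulsion integral over auxiliary functions
#' @param c1,c2 auxiliary functions from [aux_hermite()]
#' @return scalar <c1 || c2>
#' @export
eri2 <- function(c1, c2) cpp_eri2(c1, c2)

#' Three-center repulsion integrals
#' @param a,b shells
#' @param caux auxiliary function
#' @return ncomp_a x ncomp_b matrix of <ab || caux>
#' @export
eri3 <- function(a, b, caux) cpp_eri3_block(a, b, caux)

#' Four-center repulsion integrals (reference oracle)
#'
#' Dense (ab|cd) block used as the brute-force Coulomb/exchange oracle in
#' validation; not part of the SCF path, which is density-fitted.
#'
#' @param a,b,c,d shells
#' @return array (na, nb, nc, nd)
#' @export
eri4_reference <- function(a, b, c, d) cpp_eri4_block(a, b, c, d)

# ------------------------------------------------------- matrix assemblers

shell_offsets <- function(shells) {
  nc <- vapply(shells, `[[`, 0L, "ncomp")
  off <- cumsum(c(0L, nc[-length(nc)]))
  list(off = off, nc = nc, nbf = sum(nc))
}

assemble_symmetric <- function(shells, blockfun) {
  so <- shell_offsets(shells)
  M <- matrix(0, so$nbf, so$nbf)
  for (i in seq_along(shells)) for (j in i:length(shells)) {
    blk <- blockfun(shells[[i]], shells[[j]])
    ri <- so$off[i] + seq_len(so$nc[i]); rj <- so$off[j] + seq_len(so$nc[j])
    M[ri, rj] <- blk
    if (i != j) M[rj, ri] <- t(blk)
  }
  M
}

overlap_matrix <- function(shells)
  assemble_symmetric(shells, function(a, b) overlap(a, b))

kinetic_matrix <- function(shells) assemble_symmetric(shells, kinetic)

# nuclear attraction of shells to a set of (site, charge): sum_D q_D <ab|A_D>
nai_matrix <- function(shells, sites, q) {
  sites <- as.matrix(sites)
  assemble_symmetric(shells, function(a, b) nai_sites(a, b, sites, q))
}

# full 3-index tensor (nbf x nbf x naux), exact integrals
eri3_tensor <- function(shells, aux) {
  so <- shell_offsets(shells)
  TT <- array(0, c(so$nbf, so$nbf, length(aux)))
  for (k in seq_along(aux)) {
    for (i in seq_along(shells)) for (j in i:length(shells)) {
      blk <- eri3(shells[[i]], shells[[j]], aux[[k]])
      ri <- so$off[i] + seq_len(so$nc[i]); rj <- so$off[j] + seq_len(so$nc[j])
      TT[ri, rj, k] <- blk
      if (i != j) TT[rj, ri, k] <- t(blk)
    }
  }
  TT
}

# Coulomb metric G_{cd} = <c||d> over an auxiliary set
eri2_matrix <- function(aux) {
  n <- length(aux)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    G[i, j] <- G[j, i] <- eri2(aux[[i]], aux[[j]])
  }
  G
}
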