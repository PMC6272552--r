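# Near/far-field machinery: numerical orbital extents, classification of
# embedding sites, derivative tensors of 1/R, asymptotic expansions of
# nuclear-attraction and three-center repulsion integrals, and assembly of
# the embedded core Hamiltonian with far-field charge sums factorized out
# of the orbital loops.

# enumerate Cartesian triples with |m| <= order, with expansion coefficients
# (-1)^|m| / (mx! my! mz!)
.m_triples <- function(order) {
  out <- NULL
  for (tot in 0:order)
    for (mx in tot:0) for (my in (tot - mx):0)
      out <- rbind(out, c(mx, my, tot - mx - my))
  list(m = out,
       coef = (-1)^rowSums(out) /
         apply(out, 1, function(r) prod(factorial(r))))
}

# pull T values for a list of m triples (optionally offset by a Hermite
# index) out of a T-tensor cube
.t_values <- function(tt, mlist, offset = c(0L, 0L, 0L)) {
  idx <- cbind(mlist[, 1] + offset[1] + 1L, mlist[, 2] + offset[2] + 1L,
               mlist[, 3] + offset[3] + 1L)
  tt[idx]
}

#' Derivative tensors of 1/R
#'
#' All mixed partial derivatives of 1/|A - D| with respect to the
#' components of D, up to total order `m_max`. These depend only on the
#' two centers, so in the embedded-Hamiltonian assembly their charge sums
#' are accumulated per QM atom outside the orbital loops.
#'
#' @param A,D 3-vectors (bohr); must not coincide
#' @param m_max maximum total derivative order (default 8)
#' @return cube `(m_max+1)^3`; element `[mx+1, my+1, mz+1]` is T(m)
#' @export
#' @examples
#' t_tensor(c(0, 0, 0), c(2, 0, 0), 2)[1, 1, 1]  # 1/R = 0.5
t_tensor <- function(A, D, m_max = 8) {
  if (sqrt(sum((A - D)^2)) < 1e-12) stop("t_tensor: coincident centers")
  cpp_ttensor(as.numeric(A), as.numeric(D), as.integer(m_max))
}

#' Numerical extent radius of a shell
#'
#' The smallest radius beyond which the shell's radial amplitude
#' `sum_k |c_k| R^l exp(-zeta_k R^2)` stays below the integral accuracy
#' threshold tau. Solved numerically (bracketing + root refinement) on the
#' monotone tail beyond the amplitude maximum of the most diffuse
#' primitive.
#'
#' @param shell a shell from [gto_shell()]
#' @param tau integral accuracy threshold (a.u.), 0 < tau < 1;
#'   default 1e-10
#' @return extent radius in bohr
#' @export
shell_extent <- function(shell, tau = 1e-10) {
  if (tau <= 0 || tau >= 1) stop("shell_extent: tau must be in (0, 1)")
  cf <- abs(shell$coefn[1, ])
  l <- shell$l
  amp <- function(R) sum(cf * R^l * exp(-shell$exps * R^2))
  zmin <- min(shell$exps)
  r0 <- max(sqrt(l / (2 * zmin)), 0.1)   # beyond every primitive's maximum
  r1 <- r0
  while (amp(r1) > tau) r1 <- r1 * 1.5
  if (amp(r0) <= tau) return(r0)
  uniroot(function(R) amp(R) - tau, c(r0, r1), tol = 1e-10)$root
}

#' Potential extent radius of an auxiliary function
#'
#' The radius beyond which the electrostatic potential of the auxiliary
#' function is represented by its multipolar expansion to within tau: the
#' non-multipole remainder of an s-type Hermite potential decays as
#' `N (pi/zeta)^(3/2) erfc(sqrt(zeta) R)/R`.
#'
#' @param aux auxiliary function from [aux_hermite()]
#' @param tau accuracy threshold (a.u.)
#' @return extent radius in bohr
#' @export
aux_extent <- function(aux, tau = 1e-10) {
  if (tau <= 0 || tau >= 1) stop("aux_extent: tau must be in (0, 1)")
  pref <- aux$norm * (pi / aux$zeta)^1.5
  amp <- function(R) pref * erfc_(sqrt(aux$zeta) * R) / R
  r1 <- 1
  while (amp(r1) > tau) r1 <- r1 * 1.5
  uniroot(function(R) amp(R) - tau, c(1e-3, r1), tol = 1e-10)$root
}

erfc_ <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Classify embedding sites into near and far field
#'
#' A site is near-field for an orbital shell pair iff it lies inside the
#' extent sphere of either shell (distance equal to the extent counts as
#' near). Per-atom site lists (the auxiliary fields) are precomputed so
#' the orbital-pair resolution is a union of two per-atom lists.
#'
#' The classification radius is the amplitude extent of [shell_extent()]
#' scaled by `conv_factor`: amplitude decay alone does not bound the
#' truncation error of the order-8 multipolar expansion (the Taylor
#' convergence radius is limiting), and the scaled radius restores the
#' guarantee that far-classified sites are expanded to within tau.
#'
#' @param shells orbital shells (with `atom` attributes)
#' @param mm_sites matrix or data.frame with columns x, y, z (bohr)
#' @param tau accuracy threshold
#' @param conv_factor convergence safety factor on the amplitude radius
#'   (default 3)
#' @return a `near_far_map`: per-shell classification radii and per-shell
#'   and per-atom near-site index lists; an orbital pair's near set is the
#'   union of its two per-atom lists
#' @export
classify_mm <- function(shells, mm_sites, tau = 1e-10, conv_factor = 3) {
  sites <- as.matrix(as.data.frame(mm_sites)[, c("x", "y", "z")])
  ext <- conv_factor * vapply(shells, shell_extent, 1.0, tau = tau)
  atoms <- vapply(shells, `[[`, 0L, "atom")
  shell_near <- vector("list", length(shells))
  for (i in seq_along(shells)) {
    d <- sqrt(colSums((t(sites) - shells[[i]]$center)^2))
    shell_near[[i]] <- which(d <= ext[i])
  }
  atom_ids <- sort(unique(atoms))
  atom_near <- lapply(atom_ids, function(k)
    sort(unique(unlist(shell_near[atoms == k]))))
  names(atom_near) <- as.character(atom_ids)
  structure(list(extents = ext, shell_near = shell_near,
                 atom_near = atom_near, atoms = atoms,
                 n_sites = nrow(sites), tau = tau),
            class = "near_far_map")
}

#' @export
print.near_far_map <- function(x, ...) {
  nn <- length(unique(unlist(x$shell_near)))
  cat(sprintf("<near_far_map> %d shells, %d sites (%d near for some shell)\n",
              length(x$extents), x$n_sites, nn))
  invisible(x)
}

# ------------------------------------------------------ asymptotic kernels

#' Asymptotic far-field nuclear-attraction integral
#'
#' Multipolar expansion of <ab|1/|r-D||b> about the center of shell `a`
#' (or `b`): a sum of raised-angular-momentum overlaps weighted by 1/R
#' derivative tensors, truncated at the given total order. Valid when D is
#' classified far-field for the pair; no Boys function is involved.
#'
#' @param a,b shells
#' @param D site position (bohr)
#' @param order expansion order (default 8)
#' @param center expansion center, `"a"` or `"b"`
#' @return ncomp_a x ncomp_b matrix
#' @export
nai_asymptotic <- function(a, b, D, order = 8, center = c("a", "b")) {
  center <- match.arg(center)
  if (center == "b") return(t(nai_asymptotic(b, a, D, order, "a")))
  mt <- .m_triples(order)
  ov <- overlap_raised(a, b, mt$m)                    # (na, nb, nm)
  tt <- t_tensor(a$center, D, order)
  w <- mt$coef * .t_values(tt, mt$m)
  matrix(matrix(ov, a$ncomp * b$ncomp) %*% w, a$ncomp, b$ncomp)
}

#' Double asymptotic three-center repulsion integral
#'
#' Far-field <ab||caux> from the multipolar expansion of the auxiliary
#' function's potential combined with the Taylor expansion about the
#' center of `a`: the T-tensor index is offset by the Hermite index of the
#' auxiliary function.
#'
#' @param a,b shells
#' @param caux auxiliary function, classified far from the pair
#' @param order expansion order (default 8)
#' @return ncomp_a x ncomp_b matrix
#' @export
eri3_asymptotic <- function(a, b, caux, order = 8) {
  mt <- .m_triples(order)
  ov <- overlap_raised(a, b, mt$m)
  h <- caux$herm
  tt <- t_tensor(a$center, caux$center, order + sum(h))
  w <- mt$coef * .t_values(tt, mt$m, offset = h)
  pref <- caux$norm * (pi / caux$zeta)^1.5
  pref * matrix(matrix(ov, a$ncomp * b$ncomp) %*% w, a$ncomp, b$ncomp)
}

# ----------------------------------------------- embedded core Hamiltonian

#' Embed point charges into the core Hamiltonian
#'
#' H_ab = H0_ab - sum_near <ab|1/|r-D|> Q_D - far-field expansion, with
#' the far-field charge sums `sum_D Q_D T_AD(m)` accumulated once per
#' (QM atom, m) outside the orbital loops; the small near-list differences
#' between the two atoms of a pair are corrected per pair. With
#' `factorize = FALSE` the far sites are instead expanded site by site
#' inside the pair loop (same numbers, used as a cross-check).
#'
#' @param H0 unembedded core Hamiltonian (nbf x nbf)
#' @param shells orbital shells
#' @param charges data.frame with x, y, z (bohr) and q (e)
#' @param near_far a `near_far_map` from [classify_mm()] (computed here if
#'   NULL)
#' @param order expansion order (default 8)
#' @param tau classification threshold (used when `near_far` is NULL)
#' @param conv_factor classification safety factor (see [classify_mm()])
#' @param factorize accumulate far-field T sums per atom (default) or per
#'   site
#' @return H matrix with attribute `counts` = c(near, far) site-pair counts
#' @export
embed_core_hamiltonian <- function(H0, shells, charges, near_far = NULL,
                                   order = 8, tau = 1e-10, conv_factor = 3,
                                   factorize = TRUE) {
  if (!nrow(charges)) return(H0)
  sites <- as.matrix(charges[, c("x", "y", "z")])
  q <- charges$q
  if (is.null(near_far)) near_far <- classify_mm(shells, charges, tau,
                                                 conv_factor)
  so <- shell_offsets(shells)
  H <- H0
  mt <- .m_triples(order)
  atoms <- near_far$atoms
  atom_ids <- sort(unique(atoms))
  # per-atom far-field T sums and atom centers
  acenter <- lapply(atom_ids, function(k) shells[[which(atoms == k)[1]]]$center)
  names(acenter) <- as.character(atom_ids)
  tsum_far <- list()
  if (factorize) {
    for (k in atom_ids) {
      nr <- near_far$atom_near[[as.character(k)]]
      far <- if (length(nr)) seq_len(nrow(sites))[-nr] else seq_len(nrow(sites))
      tsum_far[[as.character(k)]] <-
        if (length(far)) cpp_tsum_sites(acenter[[as.character(k)]],
                                        sites[far, , drop = FALSE], q[far],
                                        order)
        else array(0, rep(order + 1, 3))
    }
  }
  ncount <- 0; fcount <- 0
  for (i in seq_along(shells)) for (j in i:length(shells)) {
    ai <- atoms[i]; aj <- atoms[j]
    near_ij <- sort(unique(c(near_far$atom_near[[as.character(ai)]],
                             near_far$atom_near[[as.character(aj)]])))
    nfar <- nrow(sites) - length(near_ij)
    ncount <- ncount + length(near_ij); fcount <- fcount + nfar
    blk <- matrix(0, shells[[i]]$ncomp, shells[[j]]$ncomp)
    if (length(near_ij))
      blk <- blk - nai_sites(shells[[i]], shells[[j]],
                             sites[near_ij, , drop = FALSE], q[near_ij])
    if (nfar > 0) {
      ov <- overlap_raised(shells[[i]], shells[[j]], mt$m)
      if (factorize) {
        # far(pair) = far(ai) minus the sites near aj but far from ai
        corr <- setdiff(near_ij, near_far$atom_near[[as.character(ai)]])
        tp <- tsum_far[[as.character(ai)]]
        if (length(corr))
          tp <- tp - cpp_tsum_sites(acenter[[as.character(ai)]],
                                    sites[corr, , drop = FALSE], q[corr],
                                    order)
        w <- mt$coef * .t_values(tp, mt$m)
        blk <- blk - matrix(matrix(ov, shells[[i]]$ncomp * shells[[j]]$ncomp) %*% w,
                            shells[[i]]$ncomp, shells[[j]]$ncomp)
      } else {
        far_ij <- seq_len(nrow(sites))[-near_ij]
        if (!length(near_ij)) far_ij <- seq_len(nrow(sites))
        for (s in far_ij) {
          tt <- t_tensor(shells[[i]]$center, sites[s, ], order)
          w <- mt$coef * .t_values(tt, mt$m)
          blk <- blk - q[s] *
            matrix(matrix(ov, shells[[i]]$ncomp * shells[[j]]$ncomp) %*% w,
                   shells[[i]]$ncomp, shells[[j]]$ncomp)
        }
      }
    }
    ri <- so$off[i] + seq_len(so$nc[i]); rj <- so$off[j] + seq_len(so$nc[j])
    H[ri, rj] <- H[ri, rj] + blk
    if (i != j) H[rj, ri] <- H[rj, ri] + t(blk)
  }
  attr(H, "counts") <- c(near = ncount, far = fcount)
  H
}

#' Count near- and far-field three-center repulsion integrals
#'
#' Applies the mixed-SCF classification to a system's shell/auxiliary
#' sets: shell pairs whose extent spheres do not overlap are screened out;
#' for the remaining pairs an auxiliary function is near-field iff its
#' potential extent sphere overlaps either shell's extent sphere. Counts
#' are per Cartesian component.
#'
#' @param shells orbital shells
#' @param aux auxiliary functions
#' @param tau accuracy threshold
#' @param conv_factor classification safety factor (see [classify_mm()])
#' @return named vector c(near, far)
#' @export
count_near_eri <- function(shells, aux, tau = 1e-10, conv_factor = 3) {
  shcen <- do.call(rbind, lapply(shells, `[[`, "center"))
  amp <- vapply(shells, shell_extent, 1.0, tau = tau)
  shnc <- vapply(shells, `[[`, 0L, "ncomp")
  auxcen <- do.call(rbind, lapply(aux, `[[`, "center"))
  auxext <- vapply(aux, aux_extent, 1.0, tau = tau)
  out <- cpp_count_near_eri(shcen, amp, conv_factor * amp, shnc, auxcen,
                            auxext)
  c(near = out[1], far = out[2])
}
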