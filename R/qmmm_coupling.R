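# QM/MM coupling: link-atom placement and force projection, embedding
# field construction, additive (electrostatic embedding + LJ) and
# subtractive (ONIOM) total energies, and the FIRES flexible solvent
# boundary restraint.

# default equilibrium bond lengths (Angstrom) used for link-atom alpha =
# r_eq(QBA-H) / r_eq(QBA-MBA)
.eq_len <- c("C-H" = 1.090, "C-C" = 1.530, "C-N" = 1.470, "C-O" = 1.430,
             "N-H" = 1.010, "O-H" = 0.960)

.alpha_default <- function(el_qba, el_mba) {
  num <- .eq_len[paste0(el_qba, "-H")]
  den <- .eq_len[paste(sort(c(el_qba, el_mba))[1],
                       sort(c(el_qba, el_mba))[2], sep = "-")]
  if (is.na(num) || is.na(den)) return(0.7124)  # C-C cut ratio
  unname(num / den)
}

#' Place hydrogen link atoms on boundary bonds
#'
#' R_LA = R_QBA + alpha (R_MBA - R_QBA). The scale alpha is the ratio of
#' the QBA-H and QBA-MBA equilibrium bond lengths, overridable per
#' boundary through `alpha`.
#'
#' @param sys a `qmm_system`
#' @param partition a `qmm_partition`
#' @param alpha numeric vector (recycled over boundary pairs) or NULL for
#'   the built-in equilibrium-length table
#' @return the partition with `link_atoms`: list of (qba, mba, alpha,
#'   element, position)
#' @export
place_link_atoms <- function(sys, partition, alpha = NULL) {
  bp <- partition$boundary_pairs
  links <- list()
  if (nrow(bp)) {
    xyz <- positions(sys)
    if (!is.null(alpha)) alpha <- rep_len(alpha, nrow(bp))
    for (r in seq_len(nrow(bp))) {
      qba <- bp[r, 1]; mba <- bp[r, 2]
      a <- if (is.null(alpha))
        .alpha_default(sys$atoms$element[qba], sys$atoms$element[mba])
      else alpha[r]
      if (a <= 0 || a >= 1) stop("place_link_atoms: alpha must be in (0,1)")
      d <- xyz[mba, ] - xyz[qba, ]
      if (sqrt(sum(d^2)) < 1e-10)
        stop("place_link_atoms: coincident boundary atoms")
      links[[r]] <- list(qba = qba, mba = mba, alpha = a, element = "H",
                         position = xyz[qba, ] + a * d)
    }
  }
  partition$link_atoms <- links
  partition
}

#' Project link-atom forces onto the real atoms
#'
#' Chain rule of the link-atom placement: F_QBA += (1 - alpha) F_LA,
#' F_MBA += alpha F_LA.
#'
#' @param F_LA 3-vector (or nl x 3 matrix) of link-atom forces/gradients
#' @param alpha link scale(s)
#' @return list with `F_QBA` and `F_MBA` increments (same shape as F_LA)
#' @export
project_link_forces <- function(F_LA, alpha) {
  F_LA <- matrix(F_LA, ncol = 3)
  list(F_QBA = (1 - alpha) * F_LA, F_MBA = alpha * F_LA)
}

#' Build the embedding point-charge field seen by the QM region
#'
#' All MM partial charges, excluding (by default) the MM boundary atoms
#' directly bonded to the QM region (the closest-charge overpolarization
#' guard), optionally truncated by a distance cutoff around the QM
#' centroid.
#'
#' @param sys a `qmm_system`
#' @param partition a `qmm_partition`
#' @param exclude_mba drop MM boundary-atom charges (default TRUE)
#' @param cutoff optional radius (bohr) around the QM centroid
#' @return data.frame x, y, z, q with attribute `indices` (atom indices)
#' @export
embedding_field <- function(sys, partition, exclude_mba = TRUE,
                            cutoff = NULL) {
  mm <- partition$mm_indices
  if (exclude_mba && nrow(partition$boundary_pairs))
    mm <- setdiff(mm, partition$boundary_pairs[, 2])
  if (!is.null(cutoff) && length(mm)) {
    ctr <- colMeans(positions(sys)[partition$qm_indices, , drop = FALSE])
    d <- sqrt(rowSums(sweep(positions(sys)[mm, , drop = FALSE], 2, ctr)^2))
    mm <- mm[d <= cutoff]
  }
  out <- system_point_charges(sys, mm)
  attr(out, "indices") <- mm
  out
}

# capped QM subsystem: QM atoms plus link hydrogens; returns the system
# and the index maps back into the full system
capped_qm_system <- function(sys, partition) {
  qm <- partition$qm_indices
  el <- sys$atoms$element[qm]
  xyz <- positions(sys)[qm, , drop = FALSE]
  links <- partition$link_atoms
  if (length(links)) {
    el <- c(el, vapply(links, `[[`, "", "element"))
    xyz <- rbind(xyz, do.call(rbind, lapply(links, `[[`, "position")))
  }
  sub <- molecular_system(el, xyz, region = "QM",
                          mm_type = c(sys$atoms$mm_type[qm],
                                      rep("HL", length(links))),
                          mm_charge = c(sys$atoms$mm_charge[qm],
                                        rep(0, length(links))),
                          lj_eps = c(sys$atoms$lj_eps[qm],
                                     rep(0, length(links))),
                          lj_rmin = c(sys$atoms$lj_rmin[qm],
                                      rep(0, length(links))))
  list(sys = sub, map = qm, n_link = length(links))
}

#' Additive QM/MM energy (and gradient)
#'
#' E = E_QM + E_QMMM + E_MM: the embedded SCF energy of the (capped) QM
#' region including the charge-augmented nuclear repulsion, the QM-MM
#' Lennard-Jones coupling, and the MM energy of all terms not internal to
#' the QM region (bonded terms crossing the boundary are kept; nonbonded
#' pairs touching a QM atom are not, their electrostatics being carried by
#' the embedding and their dispersion by the coupling term).
#'
#' QM-atom gradients are central finite differences of the SCF energy
#' (with link-atom forces projected onto QBA/MBA); MM-site gradients are
#' analytic (Hellmann-Feynman embedding terms + force field + LJ).
#'
#' @param sys a `qmm_system`
#' @param partition a `qmm_partition` (link atoms placed automatically)
#' @param ff an `ff_params` object for the MM region
#' @param basis orbital basis for the QM region
#' @param settings SCF settings
#' @param gradient also compute the total gradient (costs 6 SCF per QM
#'   atom)
#' @param fd_step finite-difference step for QM nuclear gradients (bohr)
#' @return an `additive_energy`: breakdown E_QM, E_QMMM, E_MM, E_total,
#'   the `scf_result`, and optionally `gradient` (n x 3)
#' @export
additive_qmmm <- function(sys, partition, ff, basis = "sto3g",
                          settings = scf_settings(), gradient = FALSE,
                          fd_step = 1e-4) {
  if (is.null(partition$link_atoms))
    partition <- place_link_atoms(sys, partition)
  field <- embedding_field(sys, partition)
  cap <- capped_qm_system(sys, partition)
  scf <- run_scf(cap$sys, basis = basis, charges = field,
                 settings = settings)
  if (!scf$converged) stop("additive_qmmm: SCF did not converge")
  lj <- qm_mm_lj(sys, partition)
  qm_mask <- rep(FALSE, nrow(sys$atoms))
  qm_mask[partition$qm_indices] <- TRUE
  mm <- mm_energy_gradient(sys, ff, qm_mask = qm_mask, gradient = gradient)
  E_QM <- scf$E_total
  out <- list(E_QM = E_QM, E_QMMM = lj$energy, E_MM = mm$energy,
              E_total = E_QM + lj$energy + mm$energy, scf = scf,
              mm_breakdown = mm$breakdown, field = field,
              partition = partition)
  if (gradient) {
    n <- nrow(sys$atoms)
    grad <- lj$gradient + mm$gradient
    # analytic embedding gradient on the MM charge sites
    gemb <- embedding_site_gradient(scf, field)
    idx <- attr(field, "indices")
    grad[idx, ] <- grad[idx, ] + gemb
    # FD gradients of the SCF energy over QM + link coordinates
    scf_e <- function(subsys) {
      r <- run_scf(subsys, basis = basis, charges = field,
                   settings = settings)
      if (!r$converged) stop("additive_qmmm: SCF did not converge in FD")
      r$E_total
    }
    sub <- cap$sys
    nq <- length(cap$map)
    for (k in seq_len(nq + cap$n_link)) for (d in 1:3) {
      xp <- positions(sub); xp[k, d] <- xp[k, d] + fd_step
      xm <- positions(sub); xm[k, d] <- xm[k, d] - fd_step
      g <- (scf_e(set_positions(sub, xp)) - scf_e(set_positions(sub, xm))) /
        (2 * fd_step)
      if (k <= nq) {
        grad[cap$map[k], d] <- grad[cap$map[k], d] + g
      } else {
        la <- partition$link_atoms[[k - nq]]
        grad[la$qba, d] <- grad[la$qba, d] + (1 - la$alpha) * g
        grad[la$mba, d] <- grad[la$mba, d] + la$alpha * g
      }
    }
    out$gradient <- grad
  }
  class(out) <- "additive_energy"
  out
}

#' @export
print.additive_energy <- function(x, ...) {
  cat(sprintf("<additive_energy> E_QM %.8f + E_QMMM %.8f + E_MM %.8f = %.8f\n",
              x$E_QM, x$E_QMMM, x$E_MM, x$E_total))
  invisible(x)
}

# Hellmann-Feynman + nuclear gradient of the embedded SCF energy with
# respect to the embedding charge positions
embedding_site_gradient <- function(scf, field) {
  shells <- scf$shells
  P <- scf$density
  so <- shell_offsets(shells)
  ns <- nrow(field)
  grad <- matrix(0, ns, 3)
  for (s in seq_len(ns)) {
    D <- c(field$x[s], field$y[s], field$z[s])
    g <- c(0, 0, 0)
    for (i in seq_along(shells)) for (j in i:length(shells)) {
      blk <- cpp_nai_grad_block(shells[[i]], shells[[j]], D)
      ri <- so$off[i] + seq_len(so$nc[i]); rj <- so$off[j] + seq_len(so$nc[j])
      w <- if (i == j) 1 else 2
      for (d in 1:3)
        g[d] <- g[d] + w * sum(P[ri, rj] * blk[, , d])
    }
    grad[s, ] <- -field$q[s] * g  # electronic part of -sum Q <ab|A_D>
    # nuclear part of the charge-augmented repulsion:
    # d/dD sum_A Z_A Q / |A - D| = Z_A Q (A - D)/R^3
    dA <- sweep(scf$qm_xyz, 2, D)
    R3 <- rowSums(dA^2)^1.5
    grad[s, ] <- grad[s, ] + field$q[s] * colSums(scf$Z * dA / R3)
  }
  grad
}

#' Subtractive (ONIOM-style) QM/MM energy
#'
#' E = E_MM(system) - E_MM(model) + E_QM(model), the model being the
#' capped QM region. The embedding charges extracted from the MM region
#' enter both model calculations identically: the QM model through the
#' embedded core Hamiltonian and nuclear repulsion, the MM model through
#' explicit charge-charge Coulomb sums, so their electrostatics cancel in
#' the difference.
#'
#' @param sys,partition,ff,basis,settings as in [additive_qmmm()]
#' @param embed include the extracted point-charge field (default TRUE)
#' @param qm_evaluator function(model_sys, charges) -> energy; defaults
#'   to the embedded SCF. Passing the MM model evaluator reproduces
#'   E_MM(system) exactly.
#' @return an `oniom_energy` with the three components and `E_total`
#' @export
subtractive_oniom <- function(sys, partition, ff, basis = "sto3g",
                              settings = scf_settings(), embed = TRUE,
                              qm_evaluator = NULL) {
  if (is.null(partition$link_atoms))
    partition <- place_link_atoms(sys, partition)
  field <- if (embed) embedding_field(sys, partition, exclude_mba = FALSE)
           else data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                           q = numeric(0))
  cap <- capped_qm_system(sys, partition)
  model <- build_connectivity(cap$sys)
  E_MM_system <- mm_energy_gradient(sys, ff, gradient = FALSE)$energy
  mm_model <- function(msys, charges) {
    e <- mm_energy_gradient(msys, ff, gradient = FALSE)$energy
    if (nrow(charges)) {
      xyz <- positions(msys)
      for (i in seq_len(nrow(xyz))) {
        r <- sqrt((charges$x - xyz[i, 1])^2 + (charges$y - xyz[i, 2])^2 +
                    (charges$z - xyz[i, 3])^2)
        e <- e + sum(msys$atoms$mm_charge[i] * charges$q / r)
      }
    }
    e
  }
  E_MM_model <- mm_model(model, field)
  if (is.null(qm_evaluator)) {
    qm_evaluator <- function(msys, charges) {
      r <- run_scf(msys, basis = basis,
                   charges = if (nrow(charges)) charges else NULL,
                   settings = settings)
      if (!r$converged) stop("subtractive_oniom: SCF did not converge")
      r$E_total
    }
  }
  E_QM_model <- qm_evaluator(model, field)
  structure(list(E_MM_system = E_MM_system, E_MM_model = E_MM_model,
                 E_QM_model = E_QM_model,
                 E_total = E_MM_system - E_MM_model + E_QM_model,
                 partition = partition, model = model, field = field),
            class = "oniom_energy")
}

#' @export
print.oniom_energy <- function(x, ...) {
  cat(sprintf(
    "<oniom_energy> E_MM(sys) %.8f - E_MM(model) %.8f + E_QM(model) %.8f = %.8f\n",
    x$E_MM_system, x$E_MM_model, x$E_QM_model, x$E_total))
  invisible(x)
}

# ---------------------------------------------------------------- FIRES

#' FIRES flexible-boundary state
#'
#' @param inner_tags tag-atom indices of the inner (QM) solvent molecules
#'   (e.g. water oxygens)
#' @param outer_tags tag-atom indices of the outer (MM) solvent molecules
#' @param ref reference atom index (e.g. the solute ion), held as the
#'   sphere center
#' @param k force constant (hartree/bohr^2)
#' @return a `fires_state`
#' @export
fires_state <- function(inner_tags, outer_tags, ref, k) {
  stopifnot(length(inner_tags) >= 1, k > 0)
  structure(list(inner = as.integer(inner_tags),
                 outer = as.integer(outer_tags), ref = as.integer(ref),
                 k = k), class = "fires_state")
}

#' FIRES restraint energy and gradient
#'
#' The inner radius R_in is the largest distance between an inner tag
#' atom and the reference atom. Outer tag atoms inside the sphere
#' (intruders, r_j < R_in) are pushed out by harmonic penalties
#' k/2 (r_j - R_in)^2; the reaction force acts on the boundary inner atom
#' (the one defining R_in), so the total FIRES force vanishes.
#'
#' @param state a `fires_state`
#' @param xyz full coordinate matrix (n x 3, bohr)
#' @return list: `energy`, `gradient` (n x 3), `R_in`, `intruders`,
#'   `boundary_atom`
#' @export
fires_energy_gradient <- function(state, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  ref <- xyz[state$ref, ]
  ri <- sqrt(rowSums(sweep(xyz[state$inner, , drop = FALSE], 2, ref)^2))
  bidx <- state$inner[which.max(ri)]
  R_in <- max(ri)
  grad <- matrix(0, nrow(xyz), 3)
  E <- 0
  intr <- integer(0)
  if (length(state$outer)) {
    ro <- sqrt(rowSums(sweep(xyz[state$outer, , drop = FALSE], 2, ref)^2))
    sel <- which(ro < R_in)
    intr <- state$outer[sel]
    if (length(sel)) {
      dr <- ro[sel] - R_in
      E <- sum(0.5 * state$k * dr^2)
      ub <- (xyz[bidx, ] - ref) / R_in
      for (m in seq_along(sel)) {
        j <- intr[m]
        uj <- (xyz[j, ] - ref) / ro[sel[m]]
        gj <- state$k * dr[m] * uj
        grad[j, ] <- grad[j, ] + gj
        grad[bidx, ] <- grad[bidx, ] - state$k * dr[m] * ub
        grad[state$ref, ] <- grad[state$ref, ] - gj +
          state$k * dr[m] * ub
      }
    }
  }
  list(energy = E, gradient = grad, R_in = R_in, intruders = intr,
       boundary_atom = bidx)
}
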