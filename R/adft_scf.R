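# Auxiliary density functional SCF: variational Coulomb fitting, LDA
# exchange-correlation evaluated on the fitted density, Kohn-Sham assembly
# through the fitting metric, and conventional / direct / mixed integral
# schemes for the three-center repulsion integrals and the embedding.

#' SCF settings
#'
#' @param scheme integral handling: `"conventional"` (all 3-center ERIs
#'   and embedding NAIs exact, stored), `"direct"` (exact, recomputed
#'   every cycle), `"mixed"` (near-field ERIs exact and stored, far-field
#'   ERIs and embedding NAIs by the asymptotic expansions every cycle)
#' @param max_iter maximum SCF cycles
#' @param tol convergence threshold on the RMS density-matrix change
#' @param diis_depth number of Fock matrices kept for DIIS
#' @param damping linear mixing factor used before DIIS takes over
#' @param order asymptotic expansion order (default 8)
#' @param tau integral accuracy / classification threshold (default 1e-10)
#' @param conv_factor classification safety factor (see [classify_mm()])
#' @param charge total molecular charge (closed-shell electron count)
#' @param n_radial,n_theta grid sizes (see [becke_grid()])
#' @param aux_kind auxiliary set generation flavor (see [make_aux_basis()])
#' @param xc `"lda"` (Dirac exchange + VWN correlation) or `"none"`
#' @export
scf_settings <- function(scheme = c("conventional", "direct", "mixed"),
                         max_iter = 120, tol = 1e-7, diis_depth = 8,
                         damping = 0.3, order = 8, tau = 1e-10,
                         conv_factor = 3, charge = 0, n_radial = 40,
                         n_theta = 9, aux_kind = "ET-spd", xc = "lda") {
  stopifnot(tol > 0)
  list(scheme = match.arg(scheme), max_iter = max_iter, tol = tol,
       diis_depth = diis_depth, damping = damping, order = order, tau = tau,
       conv_factor = conv_factor, charge = charge, n_radial = n_radial,
       n_theta = n_theta, aux_kind = aux_kind, xc = xc)
}

# ------------------------------------------------------------- density fit

#' Variational Coulomb density fit
#'
#' Solves G x = J with J_c = sum_ab P_ab <ab||c> through an
#' eigen-pseudoinverse of the Coulomb metric (relative cutoff 1e-10). The
#' fitted Coulomb energy x.J - x.G.x/2 approaches the exact electronic
#' Coulomb repulsion from below.
#'
#' @param P density matrix
#' @param T3 three-index ERI array (nbf x nbf x naux)
#' @param G Coulomb metric over the auxiliary set
#' @return list: `x` (coefficients), `J` (right-hand side), `E_J` (fitted
#'   Coulomb energy), `Ginv` (pseudoinverse, reused by the XC chain rule)
#' @export
fit_density <- function(P, T3, G) {
  naux <- dim(T3)[3]
  J <- as.numeric(crossprod(matrix(T3, ncol = naux), as.numeric(P)))
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values)))
    stop("fit_density: Coulomb metric is not positive semidefinite")
  keep <- eg$values > 1e-10 * max(eg$values)
  Ginv <- eg$vectors[, keep, drop = FALSE] %*%
    (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
  x <- as.numeric(Ginv %*% J)
  list(x = x, J = J, E_J = sum(x * J) - 0.5 * sum(x * (G %*% x)),
       Ginv = Ginv)
}

# ------------------------------------------------------------- LDA kernels

# Dirac exchange + VWN (V) correlation; rho is a non-negative vector.
lda_exc_vxc <- function(rho) {
  eps_x <- v_x <- eps_c <- v_c <- numeric(length(rho))
  pos <- rho > 1e-30
  r <- rho[pos]
  cx <- (3 / 4) * (3 / pi)^(1 / 3)
  eps_x[pos] <- -cx * r^(1 / 3)
  v_x[pos] <- -(3 / pi)^(1 / 3) * r^(1 / 3)
  # VWN parameterization V (paramagnetic)
  A <- 0.0310907; b <- 3.72744; cc <- 12.9352; x0 <- -0.10498
  rs <- (3 / (4 * pi * r))^(1 / 3)
  x <- sqrt(rs)
  X <- x^2 + b * x + cc
  X0 <- x0^2 + b * x0 + cc
  Q <- sqrt(4 * cc - b^2)
  atn <- atan(Q / (2 * x + b))
  ec <- A * (log(x^2 / X) + 2 * b / Q * atn -
               b * x0 / X0 * (log((x - x0)^2 / X) +
                                2 * (b + 2 * x0) / Q * atn))
  dX <- 2 * x + b
  datn <- -2 * Q / ((2 * x + b)^2 + Q^2)
  dec <- A * (2 / x - dX / X + 2 * b / Q * datn -
                b * x0 / X0 * (2 / (x - x0) - dX / X +
                                 2 * (b + 2 * x0) / Q * datn))
  eps_c[pos] <- ec
  v_c[pos] <- ec - x / 6 * dec
  list(eps = eps_x + eps_c, v = v_x + v_c)
}

#' LDA exchange-correlation on the fitted density
#'
#' Evaluates E_xc = integral of eps_xc(rho~) rho~ and the potential vector
#' v_c = integral of v_xc(rho~) c(r) for every auxiliary function, on a
#' fixed grid. Points where the fitted density is negative are clamped to
#' zero and counted.
#'
#' @param x fitting coefficients
#' @param grid list from [becke_grid()]
#' @param aux_vals matrix (npoints x naux) of auxiliary function values
#' @param xc `"lda"` or `"none"`
#' @return list: `E_xc`, `v_aux` (length naux), `n_clamped`
#' @export
xc_lda <- function(x, grid, aux_vals, xc = "lda") {
  if (!length(grid$weights)) stop("xc_lda: empty grid")
  if (xc == "none")
    return(list(E_xc = 0, v_aux = numeric(length(x)), n_clamped = 0L))
  rho <- as.numeric(aux_vals %*% x)
  ncl <- sum(rho < 0)
  rho[rho < 0] <- 0
  k <- lda_exc_vxc(rho)
  list(E_xc = sum(grid$weights * k$eps * rho),
       v_aux = as.numeric(crossprod(aux_vals, grid$weights * k$v)),
       n_clamped = ncl)
}

aux_value_matrix <- function(aux, points) {
  vapply(aux, function(a) cpp_aux_values(a, points), numeric(nrow(points)))
}

# analytic integral of each auxiliary function (s-type only are nonzero)
aux_integrals <- function(aux) {
  vapply(aux, function(a) {
    if (sum(a$herm) == 0) a$norm * (pi / a$zeta)^1.5 else 0
  }, 1.0)
}

# --------------------------------------------------------------- KS matrix

#' Assemble the Kohn-Sham matrix
#'
#' K = H_embedded + sum_c <ab||c> (x + z)_c with z = Ginv v_xc: the
#' derivative of the ADFT energy with respect to the density matrix. The
#' binding contract is agreement with central finite differences of the
#' energy, tested on small systems.
#'
#' @param H_embedded embedded core Hamiltonian
#' @param T3 three-index ERI array
#' @param fit result of [fit_density()]
#' @param v_aux XC potential vector from [xc_lda()]
#' @return symmetric KS matrix
#' @export
build_ks_matrix <- function(H_embedded, T3, fit, v_aux) {
  naux <- dim(T3)[3]
  z <- as.numeric(fit$Ginv %*% v_aux)
  K <- H_embedded + matrix(matrix(T3, ncol = naux) %*% (fit$x + z),
                           nrow(H_embedded))
  (K + t(K)) / 2
}

#' Nuclear repulsion augmented by the embedding charges
#'
#' sum_{A>B} Z_A Z_B / R_AB + sum_A sum_D Z_A Q_D / R_AD.
#'
#' @param qm_xyz n x 3 QM nuclear positions (bohr)
#' @param Z nuclear charges
#' @param charges embedding charge data.frame (x, y, z, q) or NULL
#' @return energy in hartree
#' @export
nuclear_embedded_repulsion <- function(qm_xyz, Z, charges = NULL) {
  qm_xyz <- matrix(qm_xyz, ncol = 3)
  n <- nrow(qm_xyz)
  E <- 0
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      R <- sqrt(sum((qm_xyz[i, ] - qm_xyz[j, ])^2))
      if (R < 1e-10) stop("nuclear_embedded_repulsion: coincident nuclei")
      E <- E + Z[i] * Z[j] / R
    }
  }
  if (!is.null(charges) && nrow(charges)) {
    for (i in seq_len(n)) {
      R <- sqrt((charges$x - qm_xyz[i, 1])^2 + (charges$y - qm_xyz[i, 2])^2 +
                  (charges$z - qm_xyz[i, 3])^2)
      if (any(R < 1e-10 & abs(charges$q) > 0))
        stop("nuclear_embedded_repulsion: charge coincident with nucleus")
      E <- E + sum(Z[i] * charges$q / R)
    }
  }
  E
}

# ---------------------------------------------------------- ERI providers

# classification of (shell pair, aux) triples for the mixed scheme
classify_eri3 <- function(shells, aux, tau, conv_factor) {
  shext <- conv_factor * vapply(shells, shell_extent, 1.0, tau = tau)
  auxext <- vapply(aux, aux_extent, 1.0, tau = tau)
  shcen <- do.call(rbind, lapply(shells, `[[`, "center"))
  auxcen <- do.call(rbind, lapply(aux, `[[`, "center"))
  near <- vector("list", length(shells) * (length(shells) + 1) / 2)
  key <- 0
  pairs <- NULL
  for (i in seq_along(shells)) for (j in i:length(shells)) {
    key <- key + 1
    di <- sqrt(colSums((t(auxcen) - shcen[i, ])^2))
    dj <- sqrt(colSums((t(auxcen) - shcen[j, ])^2))
    near[[key]] <- which(di <= shext[i] + auxext | dj <= shext[j] + auxext)
    pairs <- rbind(pairs, c(i, j))
  }
  list(pairs = pairs, near = near)
}

# build the T3 tensor under a scheme; `stored` holds near-field exact
# values for the mixed scheme, far-field entries are expanded on the fly
eri3_provider <- function(shells, aux, settings) {
  so <- shell_offsets(shells)
  naux <- length(aux)
  scheme <- settings$scheme
  if (scheme == "conventional") {
    T3 <- eri3_tensor(shells, aux)
    counts <- c(near = so$nbf^2 * naux, far = 0)
    list(get = function() T3, counts = counts)
  } else if (scheme == "direct") {
    counts <- c(near = so$nbf^2 * naux, far = 0)
    list(get = function() eri3_tensor(shells, aux), counts = counts)
  } else {
    cls <- classify_eri3(shells, aux, settings$tau, settings$conv_factor)
    Tnear <- array(0, c(so$nbf, so$nbf, naux))
    key <- 0
    for (i in seq_along(shells)) for (j in i:length(shells)) {
      key <- key + 1
      ri <- so$off[i] + seq_len(so$nc[i]); rj <- so$off[j] + seq_len(so$nc[j])
      for (k in cls$near[[key]]) {
        blk <- eri3(shells[[i]], shells[[j]], aux[[k]])
        Tnear[ri, rj, k] <- blk
        if (i != j) Tnear[rj, ri, k] <- t(blk)
      }
    }
    nnear <- sum(lengths(cls$near))
    counts <- c(near = nnear,
                far = length(cls$near) * naux - nnear)
    mt <- .m_triples(settings$order)
    get_mixed <- function() {
      T3 <- Tnear
      key <- 0
      for (i in seq_along(shells)) for (j in i:length(shells)) {
        key <- key + 1
        far <- setdiff(seq_len(naux), cls$near[[key]])
        if (!length(far)) next
        ov <- overlap_raised(shells[[i]], shells[[j]], mt$m)
        ovm <- matrix(ov, shells[[i]]$ncomp * shells[[j]]$ncomp)
        ri <- so$off[i] + seq_len(so$nc[i])
        rj <- so$off[j] + seq_len(so$nc[j])
        for (k in far) {
          ca <- aux[[k]]
          tt <- t_tensor(shells[[i]]$center, ca$center,
                         settings$order + sum(ca$herm))
          w <- mt$coef * .t_values(tt, mt$m, offset = ca$herm)
          blk <- ca$norm * (pi / ca$zeta)^1.5 *
            matrix(ovm %*% w, shells[[i]]$ncomp, shells[[j]]$ncomp)
          T3[ri, rj, k] <- blk
          if (i != j) T3[rj, ri, k] <- t(blk)
        }
      }
      T3
    }
    list(get = get_mixed, counts = counts)
  }
}

# ------------------------------------------------------------------- SCF

#' Run a restricted closed-shell ADFT SCF
#'
#' Energy model: E = sum_ab P_ab H_ab + x.J - x.G.x/2 + E_xc[rho~] (+
#' embedded nuclear repulsion), with the Coulomb term from the variational
#' density fit and the exchange-correlation term evaluated on the fitted
#' density. Convergence is accelerated by DIIS with damped mixing as a
#' fallback. The `scheme` setting controls how 3-center ERIs and the
#' embedding NAIs are evaluated; all schemes converge to the same energy
#' to well below 1e-8 hartree.
#'
#' @param sys a `qmm_system` (or NULL when `shells` given directly)
#' @param basis basis name or `basis_library`
#' @param aux auxiliary function list (auto-generated when NULL)
#' @param charges embedding point charges (data.frame x, y, z, q) or NULL
#' @param settings from [scf_settings()]
#' @param qm_indices atoms to treat quantum mechanically (default: all
#'   atoms of `sys` with region `"QM"`, or all atoms if none is marked)
#' @return an `scf_result`: total energy, component breakdown, MO
#'   coefficients/energies, convergence trace
#' @export
run_scf <- function(sys, basis = "sto3g", aux = NULL, charges = NULL,
                    settings = scf_settings(), qm_indices = NULL) {
  if (is.null(qm_indices)) {
    qm_indices <- which(sys$atoms$region %in% c("QM", "LINK") & sys$atoms$Z >= 1)
    if (!length(qm_indices)) qm_indices <- which(sys$atoms$Z >= 1)
  }
  shells <- build_shells(sys, basis, qm_indices)
  if (is.null(aux)) aux <- make_aux_basis(sys, shells, settings$aux_kind)
  Zq <- sys$atoms$Z[qm_indices]
  qm_xyz <- positions(sys)[qm_indices, , drop = FALSE]
  nelec <- sum(Zq) - settings$charge
  if (nelec <= 0 || nelec %% 2 != 0)
    stop("run_scf: closed-shell electron count required, got ", nelec)
  nocc <- nelec / 2

  S <- overlap_matrix(shells)
  H0 <- kinetic_matrix(shells) - nai_matrix(shells, qm_xyz, Zq)
  has_embed <- !is.null(charges) && nrow(charges) > 0
  if (has_embed) {
    if (settings$scheme == "mixed") {
      H <- embed_core_hamiltonian(H0, shells, charges, order = settings$order,
                                  tau = settings$tau,
                                  conv_factor = settings$conv_factor)
      nai_counts <- attr(H, "counts")
    } else {
      H <- H0 - nai_matrix(shells, charges[, c("x", "y", "z")], charges$q)
      nai_counts <- c(near = length(shells)^2 * nrow(charges), far = 0)
    }
  } else {
    H <- H0
    nai_counts <- c(near = 0, far = 0)
  }
  E_NN <- nuclear_embedded_repulsion(qm_xyz, Zq, if (has_embed) charges)

  G <- eri2_matrix(aux)
  provider <- eri3_provider(shells, aux, settings)
  grid <- becke_grid(qm_xyz, sys$atoms$element[qm_indices],
                     settings$n_radial, settings$n_theta)
  AV <- aux_value_matrix(aux, grid$points)

  # orthogonalizer
  es <- eigen(S, symmetric = TRUE)
  keep <- es$values > 1e-10 * max(es$values)
  X <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))

  solve_fock <- function(K) {
    Kp <- crossprod(X, K %*% X)
    ev <- eigen((Kp + t(Kp)) / 2, symmetric = TRUE)
    ord <- order(ev$values)  # eigen() sorts decreasing; occupy from below
    list(C = X %*% ev$vectors[, ord, drop = FALSE], eps = ev$values[ord])
  }
  density_of <- function(C) {
    Co <- C[, seq_len(nocc), drop = FALSE]
    2 * tcrossprod(Co)
  }

  # core guess
  mo <- solve_fock(H)
  P <- density_of(mo$C)
  log <- NULL
  diis_F <- list(); diis_E <- list()
  converged <- FALSE
  E_old <- Inf
  n_clamped <- 0L
  for (it in seq_len(settings$max_iter)) {
    T3 <- provider$get()
    fit <- fit_density(P, T3, G)
    xc <- xc_lda(fit$x, grid, AV, settings$xc)
    n_clamped <- n_clamped + xc$n_clamped
    E_core <- sum(P * H)
    E <- E_core + fit$E_J + xc$E_xc + E_NN
    K <- build_ks_matrix(H, T3, fit, xc$v_aux)
    # DIIS on the orthonormal-basis commutator; once the density change is
    # small the plain Roothaan map is contractive and free of
    # extrapolation noise, so DIIS is only used for the coarse phase
    err <- crossprod(X, (K %*% P %*% S - S %*% P %*% K) %*% X)
    diis_F[[length(diis_F) + 1]] <- K
    diis_E[[length(diis_E) + 1]] <- err
    if (length(diis_F) > settings$diis_depth) {
      diis_F <- diis_F[-1]; diis_E <- diis_E[-1]
    }
    # drop stale vectors while the (scaled) B block is ill-conditioned --
    # old near-collinear errors otherwise amplify noise at convergence
    repeat {
      nD <- length(diis_F)
      if (nD <= 2) break
      Bb <- matrix(0, nD, nD)
      for (i in seq_len(nD)) for (j in seq_len(nD))
        Bb[i, j] <- sum(diis_E[[i]] * diis_E[[j]])
      ev <- eigen(Bb, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) > 1e-10 * max(ev)) break
      diis_F <- diis_F[-1]; diis_E <- diis_E[-1]
    }
    nD <- length(diis_F)
    Kuse <- K
    if (nD >= 2) {
      B <- matrix(0, nD + 1, nD + 1)
      for (i in seq_len(nD)) for (j in seq_len(nD))
        B[i, j] <- sum(diis_E[[i]] * diis_E[[j]])
      sc <- max(abs(diag(B)[seq_len(nD)]), 1e-300)
      B[seq_len(nD), seq_len(nD)] <- B[seq_len(nD), seq_len(nD)] / sc
      B[nD + 1, seq_len(nD)] <- B[seq_len(nD), nD + 1] <- -1
      rhs <- c(numeric(nD), -1)
      cf <- tryCatch(solve(B, rhs)[seq_len(nD)], error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf)))
        Kuse <- Reduce(`+`, Map(`*`, diis_F, cf))
    }
    mo <- solve_fock(Kuse)
    P_new <- density_of(mo$C)
    if (nD < 2) # damped start
      P_new <- (1 - settings$damping) * P_new + settings$damping * P
    dP <- sqrt(mean((P_new - P)^2))
    log <- rbind(log, data.frame(iter = it, energy = E, dP = dP,
                                 near_eri = provider$counts["near"],
                                 far_eri = provider$counts["far"]))
    P <- P_new
    if (dP <= settings$tol && abs(E - E_old) < 1e-9) { converged <- TRUE; break }
    E_old <- E
  }
  # final consistent energy at the converged density
  T3 <- provider$get()
  fit <- fit_density(P, T3, G)
  xc <- xc_lda(fit$x, grid, AV, settings$xc)
  E_core <- sum(P * H)
  components <- c(E_core = E_core, E_J_fitted = fit$E_J, E_xc = xc$E_xc,
                  E_NN_embedded = E_NN)
  res <- structure(list(
    E_total = sum(components), components = components,
    mo_coefficients = mo$C, mo_energies = mo$eps, n_occupied = nocc,
    density = P, fit = fit, converged = converged, cycles = log,
    shells = shells, aux = aux, overlap = S, H_embedded = H, G = G,
    grid = grid, aux_values = AV, n_clamped = n_clamped,
    qm_xyz = qm_xyz, Z = Zq,
    nai_counts = nai_counts, eri_counts = provider$counts,
    settings = settings), class = "scf_result")
  res
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("<scf_result> E = %.10f hartree (%s after %d cycles)\n",
              x$E_total, if (x$converged) "converged" else "NOT CONVERGED",
              nrow(x$cycles)))
  comp <- x$components
  cat(sprintf("  core %.8f  J(fit) %.8f  xc %.8f  NN(embedded) %.8f\n",
              comp[1], comp[2], comp[3], comp[4]))
  invisible(x)
}

# ----------------------------------------------------- density-fitted K

#' Density-fitted exact exchange (full-domain limit)
#'
#' E_x = -1/2 sum_ab P_ab X_ab with X built from fitted occupied-orbital
#' products: X_ab = sum_i sum_cd <ai||c> Ginv_cd <d||ib>. In the
#' full-domain limit with an auxiliary set spanning the orbital products
#' this equals brute-force four-center exchange. Energy-only option; not
#' used inside the SCF.
#'
#' @param scf an `scf_result`
#' @return list: `E_x` (hartree, non-positive), `X` matrix
#' @export
fitted_exchange <- function(scf) {
  T3 <- eri3_tensor(scf$shells, scf$aux)
  naux <- dim(T3)[3]
  nbf <- dim(T3)[1]
  Ginv <- scf$fit$Ginv
  Co <- scf$mo_coefficients[, seq_len(scf$n_occupied), drop = FALSE]
  Xm <- matrix(0, nbf, nbf)
  for (i in seq_len(ncol(Co))) {
    # B_{a,c} = sum_b T3[a,b,c] C_bi
    B <- matrix(0, nbf, naux)
    for (c in seq_len(naux)) B[, c] <- T3[, , c] %*% Co[, i]
    Xm <- Xm + B %*% Ginv %*% t(B)
  }
  E_x <- -0.5 * sum(scf$density * Xm)
  list(E_x = E_x, X = Xm)
}
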