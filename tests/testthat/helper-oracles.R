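# Independent numerical oracles used across the test suite. These share no
# code with the package's Hermite-recursion integral paths: quadrature is
# Gauss-Hermite (Golub-Welsch nodes), Coulomb closed forms go through
# erf/pnorm, and 1/R derivative tensors through base R's symbolic D().

gh_rule <- function(n = 48) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (sqrt(pi) * e$vectors[1, ]^2)[ord])
}

.GH <- gh_rule(48)

gl_rule <- function(n = 200) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (2 * e$vectors[1, ]^2)[ord])
}

.GL <- gl_rule(200)

# reference Boys function by dense Gauss-Legendre quadrature on [0, 1]
boys_quad <- function(n, x) {
  t <- 0.5 * (.GL$x + 1)
  0.5 * sum(.GL$w * t^(2 * n) * exp(-x * t^2))
}

# 1-D integral of (x-A)^i (x-B)^j exp(-za (x-A)^2 - zb (x-B)^2)
ov1d_quad <- function(i, j, A, B, za, zb) {
  p <- za + zb
  P <- (za * A + zb * B) / p
  K <- exp(-za * zb / p * (A - B)^2)
  x <- P + .GH$x / sqrt(p)
  K / sqrt(p) * sum(.GH$w * (x - A)^i * (x - B)^j)
}

# overlap block of two shells (components x components) by quadrature,
# including the optional raise index on shell a
ov_quad <- function(a, b, shift = c(0, 0, 0)) {
  out <- matrix(0, a$ncomp, b$ncomp)
  for (ka in seq_along(a$exps)) for (kb in seq_along(b$exps)) {
    for (ca in seq_len(a$ncomp)) for (cb in seq_len(b$ncomp)) {
      v <- 1
      for (d in 1:3)
        v <- v * ov1d_quad(a$comps[ca, d] + shift[d], b$comps[cb, d],
                           a$center[d], b$center[d], a$exps[ka], b$exps[kb])
      out[ca, cb] <- out[ca, cb] + a$coefn[ca, ka] * b$coefn[cb, kb] * v
    }
  }
  out
}

# kinetic energy by quadrature through (1/2) grad a . grad b; the
# derivative of (x-C)^i e^{-z(x-C)^2} is i (x-C)^{i-1} - 2z (x-C)^{i+1}
kin_quad <- function(a, b) {
  out <- matrix(0, a$ncomp, b$ncomp)
  for (ka in seq_along(a$exps)) for (kb in seq_along(b$exps)) {
    for (ca in seq_len(a$ncomp)) for (cb in seq_len(b$ncomp)) {
      tot <- 0
      for (dd in 1:3) {
        v <- 1
        for (d in 1:3) {
          i <- a$comps[ca, d]; j <- b$comps[cb, d]
          A <- a$center[d]; B <- b$center[d]
          if (d == dd) {
            # int (d/dx a)(d/dx b): expand both derivative polynomials
            za <- a$exps[ka]; zb <- b$exps[kb]
            term <- 4 * za * zb * ov1d_quad(i + 1, j + 1, A, B, za, zb)
            if (i > 0) term <- term - 2 * zb * i * ov1d_quad(i - 1, j + 1, A, B, za, zb)
            if (j > 0) term <- term - 2 * za * j * ov1d_quad(i + 1, j - 1, A, B, za, zb)
            if (i > 0 && j > 0) term <- term + i * j * ov1d_quad(i - 1, j - 1, A, B, za, zb)
            v <- v * term
          } else {
            v <- v * ov1d_quad(i, j, A, B, a$exps[ka], b$exps[kb])
          }
        }
        tot <- tot + v
      }
      out[ca, cb] <- out[ca, cb] + 0.5 * a$coefn[ca, ka] * b$coefn[cb, kb] * tot
    }
  }
  out
}

erf_ <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# closed-form s-s nuclear attraction through the product-Gaussian potential
nai_ss_closed <- function(a, b, D) {
  stopifnot(a$l == 0, b$l == 0)
  v <- 0
  for (ka in seq_along(a$exps)) for (kb in seq_along(b$exps)) {
    za <- a$exps[ka]; zb <- b$exps[kb]; p <- za + zb
    P <- (za * a$center + zb * b$center) / p
    K <- exp(-za * zb / p * sum((a$center - b$center)^2))
    chg <- a$coefn[1, ka] * b$coefn[1, kb] * K * (pi / p)^1.5
    R <- sqrt(sum((P - D)^2))
    v <- v + chg * if (R < 1e-12) 2 * sqrt(p / pi) else erf_(sqrt(p) * R) / R
  }
  v
}

# closed-form all-s three-center repulsion: product Gaussian vs s-Hermite
eri3_sss_closed <- function(a, b, caux) {
  stopifnot(a$l == 0, b$l == 0, sum(caux$herm) == 0)
  v <- 0
  g <- caux$zeta
  qc <- caux$norm * (pi / g)^1.5
  for (ka in seq_along(a$exps)) for (kb in seq_along(b$exps)) {
    za <- a$exps[ka]; zb <- b$exps[kb]; p <- za + zb
    P <- (za * a$center + zb * b$center) / p
    K <- exp(-za * zb / p * sum((a$center - b$center)^2))
    chg <- a$coefn[1, ka] * b$coefn[1, kb] * K * (pi / p)^1.5
    om <- p * g / (p + g)
    R <- sqrt(sum((P - caux$center)^2))
    v <- v + chg * qc * if (R < 1e-12) 2 * sqrt(om / pi)
                        else erf_(sqrt(om) * R) / R
  }
  v
}

eri2_ss_closed <- function(c1, c2) {
  stopifnot(sum(c1$herm) == 0, sum(c2$herm) == 0)
  q1 <- c1$norm * (pi / c1$zeta)^1.5
  q2 <- c2$norm * (pi / c2$zeta)^1.5
  om <- c1$zeta * c2$zeta / (c1$zeta + c2$zeta)
  R <- sqrt(sum((c1$center - c2$center)^2))
  q1 * q2 * if (R < 1e-12) 2 * sqrt(om / pi) else erf_(sqrt(om) * R) / R
}

# symbolic derivative tensors of 1/|A - D| with respect to D, base R D()
t_symbolic <- function(m, A, D) {
  ex <- quote(1 / sqrt((ax - dx)^2 + (ay - dy)^2 + (az - dz)^2))
  for (k in seq_len(m[1])) ex <- D(ex, "dx")
  for (k in seq_len(m[2])) ex <- D(ex, "dy")
  for (k in seq_len(m[3])) ex <- D(ex, "dz")
  eval(ex, list(ax = A[1], ay = A[2], az = A[3],
                dx = D[1], dy = D[2], dz = D[3]))
}

# independent dense assembly of the same ADFT energy model (naive loops,
# no near/far machinery, svd pseudoinverse, plain damped fixed point)
naive_adft_scf <- function(sys, basis, aux = NULL, charges = NULL,
                           charge = 0, n_radial = 40, n_theta = 9,
                           max_iter = 200) {
  shells <- build_shells(sys, basis)
  if (is.null(aux)) aux <- make_aux_basis(sys, shells)
  qm <- which(sys$atoms$Z >= 1)
  Z <- sys$atoms$Z[qm]
  xyz <- positions(sys)[qm, , drop = FALSE]
  so <- auxqmmm:::shell_offsets(shells)
  nbf <- so$nbf
  S <- matrix(0, nbf, nbf); Tm <- S; V <- S
  for (i in seq_along(shells)) for (j in seq_along(shells)) {
    ri <- so$off[i] + seq_len(so$nc[i]); rj <- so$off[j] + seq_len(so$nc[j])
    S[ri, rj] <- overlap(shells[[i]], shells[[j]])
    Tm[ri, rj] <- kinetic(shells[[i]], shells[[j]])
    blk <- matrix(0, so$nc[i], so$nc[j])
    for (k in seq_along(Z))
      blk <- blk - Z[k] * nai_exact(shells[[i]], shells[[j]], xyz[k, ])
    if (!is.null(charges) && nrow(charges))
      for (s in seq_len(nrow(charges)))
        blk <- blk - charges$q[s] *
          nai_exact(shells[[i]], shells[[j]],
                    c(charges$x[s], charges$y[s], charges$z[s]))
    V[ri, rj] <- blk
  }
  H <- Tm + V
  naux <- length(aux)
  G <- matrix(0, naux, naux)
  for (i in seq_len(naux)) for (j in seq_len(naux))
    G[i, j] <- eri2(aux[[i]], aux[[j]])
  T3 <- array(0, c(nbf, nbf, naux))
  for (k in seq_len(naux))
    for (i in seq_along(shells)) for (j in seq_along(shells)) {
      ri <- so$off[i] + seq_len(so$nc[i]); rj <- so$off[j] + seq_len(so$nc[j])
      T3[ri, rj, k] <- eri3(shells[[i]], shells[[j]], aux[[k]])
    }
  sv <- svd(G)
  keep <- sv$d > 1e-10 * max(sv$d)
  Ginv <- sv$v[, keep] %*% (t(sv$u[, keep]) / sv$d[keep])
  grid <- becke_grid(xyz, sys$atoms$element[qm], n_radial, n_theta)
  AV <- sapply(aux, function(a) auxqmmm:::cpp_aux_values(a, grid$points))
  nelec <- sum(Z) - charge
  nocc <- nelec / 2
  es <- eigen(S, symmetric = TRUE)
  Xo <- es$vectors %*% diag(1 / sqrt(es$values), nbf)
  energy_of <- function(P) {
    J <- numeric(naux)
    for (k in seq_len(naux)) J[k] <- sum(P * T3[, , k])
    x <- as.numeric(Ginv %*% J)
    EJ <- sum(x * J) - 0.5 * sum(x * (G %*% x))
    rho <- pmax(0, as.numeric(AV %*% x))
    kk <- auxqmmm:::lda_exc_vxc(rho)
    Exc <- sum(grid$weights * kk$eps * rho)
    vv <- as.numeric(crossprod(AV, grid$weights * kk$v))
    z <- as.numeric(Ginv %*% vv)
    Kmat <- H
    for (k in seq_len(naux)) Kmat <- Kmat + (x[k] + z[k]) * T3[, , k]
    list(E = sum(P * H) + EJ + Exc, K = Kmat)
  }
  # core guess + damped fixed point
  Kp <- crossprod(Xo, H %*% Xo)
  ev <- eigen((Kp + t(Kp)) / 2, symmetric = TRUE)
  C <- Xo %*% ev$vectors[, order(ev$values), drop = FALSE]
  P <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
  E_old <- Inf
  for (it in seq_len(max_iter)) {
    r <- energy_of(P)
    Kp <- crossprod(Xo, r$K %*% Xo)
    ev <- eigen((Kp + t(Kp)) / 2, symmetric = TRUE)
    C <- Xo %*% ev$vectors[, order(ev$values), drop = FALSE]
    Pn <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
    done <- abs(r$E - E_old) < 5e-14 && sqrt(mean((Pn - P)^2)) < 1e-12
    P <- if (done) Pn else 0.5 * P + 0.5 * Pn
    if (done) break
    E_old <- r$E
  }
  ENN <- nuclear_embedded_repulsion(xyz, Z, charges)
  energy_of(P)$E + ENN
}

# exact 4-center Coulomb and exchange energies over a shell list
eri4_full <- function(shells) {
  so <- auxqmmm:::shell_offsets(shells)
  nbf <- so$nbf
  out <- array(0, c(nbf, nbf, nbf, nbf))
  for (i in seq_along(shells)) for (j in seq_along(shells))
    for (k in seq_along(shells)) for (l in seq_along(shells)) {
      blk <- eri4_reference(shells[[i]], shells[[j]], shells[[k]],
                            shells[[l]])
      ri <- so$off[i] + seq_len(so$nc[i]); rj <- so$off[j] + seq_len(so$nc[j])
      rk <- so$off[k] + seq_len(so$nc[k]); rl <- so$off[l] + seq_len(so$nc[l])
      out[ri, rj, rk, rl] <- blk
    }
  out
}

# Coulomb matrix J_ab = sum_cd (ab|cd) P_cd from a full 4-index tensor
tensor_jp <- function(V4, P) {
  n <- dim(V4)[1]
  J <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n))
    J[a, b] <- sum(V4[a, b, , ] * P)
  J
}

water_monomer <- function() {
  molecular_system(c("O", "H", "H"),
                   ang2bohr(rbind(c(0, 0, 0.1173),
                                  c(0, 0.7572, -0.4692),
                                  c(0, -0.7572, -0.4692))))
}

fast_scf <- function(...) scf_settings(..., n_radial = 30, n_theta = 7)
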