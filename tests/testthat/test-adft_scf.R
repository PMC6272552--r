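# Density fitting, LDA kernels, grid, Kohn-Sham assembly and the SCF
# schemes, validated against brute-force four-center and dense-assembly
# oracles.

test_that("variational fit is exact for an in-span density and bounded in general", {
  # a single normalized s primitive: its square is a Gaussian of twice the
  # exponent, so an aux set containing that exponent fits it exactly
  z <- 0.9
  s <- gto_shell(c(0, 0, 0), 0, z, 1)
  aux <- list(aux_hermite(c(0, 0, 0), c(0, 0, 0), 2 * z))
  G <- matrix(eri2(aux[[1]], aux[[1]]), 1, 1)
  T3 <- array(eri3(s, s, aux[[1]]), c(1, 1, 1))
  P <- matrix(1, 1, 1)
  fit <- fit_density(P, T3, G)
  Eexact <- 0.5 * eri4_reference(s, s, s, s)[1, 1, 1, 1]
  expect_equal(fit$E_J, Eexact, tolerance = 1e-10)

  # variational bound on random densities over water/minimal
  w <- water_monomer()
  shells <- build_shells(w, "sto3g")
  aux <- make_aux_basis(w, shells)
  G <- auxqmmm:::eri2_matrix(aux)
  T3 <- auxqmmm:::eri3_tensor(shells, aux)
  V4 <- eri4_full(shells)
  nbf <- dim(T3)[1]
  set.seed(21)
  worst_gap <- Inf
  for (rep in 1:12) {
    C <- matrix(rnorm(nbf * 5), nbf, 5)
    P <- 2 * tcrossprod(C)
    fit <- fit_density(P, T3, G)
    Eex <- 0.5 * sum(tensor_jp(V4, P) * P)
    expect_lte(fit$E_J, Eex + 1e-10)
    worst_gap <- min(worst_gap, Eex - fit$E_J)
  }
  # halving the aux set never increases the fitted Coulomb energy
  P <- 2 * tcrossprod(matrix(rnorm(nbf * 5), nbf, 5))
  half <- seq(1, length(aux), by = 2)
  fit_full <- fit_density(P, T3, G)
  fit_half <- fit_density(P, T3[, , half, drop = FALSE],
                          G[half, half, drop = FALSE])
  expect_lte(fit_half$E_J, fit_full$E_J + 1e-10)
})

test_that("LDA kernels: Dirac closed form and consistent potential", {
  rho <- c(1e-6, 0.01, 0.3, 2.7)
  k <- auxqmmm:::lda_exc_vxc(rho)
  # exchange part: subtract a correlation-only evaluation via the closed form
  ex <- -(3 / 4) * (3 / pi)^(1 / 3) * rho^(1 / 3)
  expect_true(all(k$eps < ex + 1e-12))  # correlation lowers the energy
  # v = d(rho eps)/drho by numerical differentiation
  h <- 1e-7
  for (r in rho[-1]) {
    up <- auxqmmm:::lda_exc_vxc(r + h); dn <- auxqmmm:::lda_exc_vxc(r - h)
    fd <- ((r + h) * up$eps - (r - h) * dn$eps) / (2 * h)
    expect_equal(auxqmmm:::lda_exc_vxc(r)$v, fd, tolerance = 1e-6)
  }
  expect_equal(xc_lda(numeric(3), list(weights = 1),
                      matrix(0, 1, 3))$E_xc, 0)
})

test_that("integration grid integrates Gaussians and fitted densities", {
  # single-center rule: normalized s-Gaussians integrate to 1 within 1e-6
  g1 <- becke_grid(matrix(0, 1, 3), "O")
  for (z in c(0.2, 1, 7, 40)) {
    aa <- aux_hermite(c(0, 0, 0), c(0, 0, 0), z)
    vals <- auxqmmm:::cpp_aux_values(aa, g1$points)
    ref <- aa$norm * (pi / z)^1.5
    expect_equal(sum(g1$weights * vals), ref, tolerance = 1e-6 * ref)
  }
  expect_true(all(g1$weights > 0))
  # Becke-partitioned two-center grid: atom-centered Gaussians to 1e-4
  g2 <- becke_grid(rbind(c(0, 0, 0), c(0, 0, 2.5)), c("O", "H"))
  for (ctr in list(c(0, 0, 0), c(0, 0, 2.5))) for (z in c(0.2, 1, 7)) {
    aa <- aux_hermite(ctr, c(0, 0, 0), z)
    vals <- auxqmmm:::cpp_aux_values(aa, g2$points)
    ref <- aa$norm * (pi / z)^1.5
    expect_equal(sum(g2$weights * vals), ref, tolerance = 1e-4 * ref)
  }
  # grid integral of a fitted water density matches the analytic aux norms
  w <- water_monomer()
  r <- run_scf(w, "sto3g")
  ngrid <- sum(r$grid$weights * as.numeric(r$aux_values %*% r$fit$x))
  nanalytic <- sum(auxqmmm:::aux_integrals(r$aux) * r$fit$x)
  expect_equal(ngrid, nanalytic, tolerance = 1e-5 * abs(nanalytic))
})

test_that("KS matrix is the density-matrix derivative of the energy", {
  sys <- molecular_system(c("He", "H"), rbind(c(0, 0, 0), c(0, 0, 1.5)))
  r <- run_scf(sys, "sto3g", settings = fast_scf(charge = 1))
  expect_true(r$converged)
  T3 <- auxqmmm:::eri3_tensor(r$shells, r$aux)
  efun <- function(P) {
    fit <- fit_density(P, T3, r$G)
    xc <- xc_lda(fit$x, r$grid, r$aux_values)
    sum(P * r$H_embedded) + fit$E_J + xc$E_xc
  }
  fit <- fit_density(r$density, T3, r$G)
  K <- build_ks_matrix(r$H_embedded, T3, fit,
                       xc_lda(fit$x, r$grid, r$aux_values)$v_aux)
  expect_lt(max(abs(K - t(K))), 1e-12)
  h <- 1e-5
  n <- nrow(r$density)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    Pp <- r$density; Pp[a, b] <- Pp[a, b] + h
    Pm <- r$density; Pm[a, b] <- Pm[a, b] - h
    expect_lt(abs((efun(Pp) - efun(Pm)) / (2 * h) - K[a, b]), 1e-6)
  }
  # with P = 0 and no charges the KS matrix reduces to the core Hamiltonian
  fit0 <- fit_density(matrix(0, n, n), T3, r$G)
  K0 <- build_ks_matrix(r$H_embedded, T3, fit0,
                        xc_lda(fit0$x, r$grid, r$aux_values)$v_aux)
  expect_equal(K0, r$H_embedded, tolerance = 1e-12)
})

test_that("SCF energies match an independent dense assembly of the same model", {
  # a well-conditioned s-only auxiliary set keeps the metric solve
  # reproducible between the two independent assemblies at the 1e-12 level
  he <- molecular_system("He", matrix(0, 1, 3))
  aux_he <- make_aux_basis(he, build_shells(he, "sto3g"), kind = "ET-s")
  r <- run_scf(he, "sto3g", aux = aux_he,
               settings = scf_settings(scheme = "conventional"))
  expect_true(r$converged)
  expect_equal(r$E_total, naive_adft_scf(he, "sto3g", aux = aux_he),
               tolerance = 1e-10)
  h2 <- molecular_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)))
  aux_h2 <- make_aux_basis(h2, build_shells(h2, "sto3g"), kind = "ET-s")
  r2 <- run_scf(h2, "sto3g", aux = aux_h2,
                settings = scf_settings(scheme = "conventional"))
  expect_equal(r2$E_total, naive_adft_scf(h2, "sto3g", aux = aux_h2),
               tolerance = 1e-10)
  # electron count at convergence
  expect_equal(sum(r2$density * r2$overlap), 2, tolerance = 1e-8)
})

test_that("conventional, direct and mixed schemes give the same energy", {
  h2 <- molecular_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)))
  es <- vapply(c("conventional", "direct", "mixed"), function(sc)
    run_scf(h2, "sto3g", settings = fast_scf(scheme = sc))$E_total, 1.0)
  expect_lt(max(es) - min(es), 1e-8)
})

test_that("embedding with all-zero charges reproduces the gas phase exactly", {
  w <- water_monomer()
  ch <- data.frame(x = c(8, -5, 3), y = c(1, 2, -6), z = c(0, 4, 2),
                   q = c(0, 0, 0))
  r0 <- run_scf(w, "sto3g", settings = fast_scf())
  r1 <- run_scf(w, "sto3g", charges = ch, settings = fast_scf())
  expect_equal(r1$E_total, r0$E_total, tolerance = 1e-12)
})

test_that("charge-augmented nuclear repulsion has the stated closed forms", {
  expect_equal(nuclear_embedded_repulsion(rbind(c(0, 0, 0), c(0, 0, 1)),
                                          c(1, 1)), 1)
  ch <- data.frame(x = 2, y = 0, z = 0, q = -1)
  expect_equal(nuclear_embedded_repulsion(matrix(0, 1, 3), 1, ch), -0.5)
  # translation invariance
  sh <- rbind(c(1, 2, 3), c(1, 2, 4))
  chs <- data.frame(x = 3, y = 2, z = 3, q = -1)
  chs2 <- data.frame(x = chs$x + 5, y = chs$y + 5, z = chs$z + 5, q = chs$q)
  expect_equal(nuclear_embedded_repulsion(sh, c(1, 1), chs),
               nuclear_embedded_repulsion(sh + 5, c(1, 1), chs2),
               tolerance = 1e-12)
  expect_error(nuclear_embedded_repulsion(rbind(c(0, 0, 0), c(0, 0, 0)),
                                          c(1, 1)), "coincident")
})

test_that("density-fitted exchange reproduces four-center exchange on H2", {
  h2 <- molecular_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)))
  # a product-spanning aux set for the minimal H2 basis: s Hermites at the
  # atoms and the bond midpoint covering all primitive-pair exponents
  sh <- build_shells(h2, "sto3g")
  ae <- sh[[1]]$exps
  aux <- list()
  for (z1 in ae) for (z2 in ae) {
    p <- z1 + z2
    for (ctr in list(c(0, 0, 0), c(0, 0, 1.4),
                     c(0, 0, 1.4 * z2 / p), c(0, 0, 1.4 * z1 / p))) {
      aux[[length(aux) + 1]] <- aux_hermite(ctr, c(0, 0, 0), p)
      aux[[length(aux) + 1]] <- aux_hermite(ctr, c(0, 0, 1), p)
      aux[[length(aux) + 1]] <- aux_hermite(ctr, c(0, 0, 2), p)
    }
  }
  r <- run_scf(h2, "sto3g", aux = aux, settings = fast_scf())
  fx <- fitted_exchange(r)
  # brute-force exchange: -sum_ij (ij|ij) over occupied MOs
  V4 <- eri4_full(r$shells)
  Co <- r$mo_coefficients[, 1, drop = FALSE]
  mo_eri <- 0
  for (a in 1:2) for (b in 1:2) for (c in 1:2) for (d in 1:2)
    mo_eri <- mo_eri + Co[a] * Co[b] * Co[c] * Co[d] * V4[a, b, c, d]
  expect_equal(fx$E_x, -mo_eri, tolerance = 1e-8)
  expect_lte(fx$E_x, 0)
  # one-electron limit: exchange cancels half the self-Coulomb of the MO
  expect_equal(fx$E_x, -0.25 * sum(tensor_jp(V4, r$density) * r$density),
               tolerance = 1e-8)
})
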