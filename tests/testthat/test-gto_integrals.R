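# Exact molecular integrals against independent oracles: Gauss-Hermite
# quadrature, erf closed forms, and structural invariants.

test_that("Boys function matches direct quadrature to 1e-13", {
  expect_equal(boys(0, 0), 1)
  for (n in c(0, 1, 3, 8, 17, 32))
    expect_equal(boys(n, 0), 1 / (2 * n + 1), tolerance = 1e-14)
  # closed form at x = 1
  expect_equal(boys(0, 1), 0.5 * sqrt(pi) * erf_(1), tolerance = 1e-13)
  for (n in c(0, 2, 5, 13, 32)) for (x in c(1e-4, 0.5, 5, 39.9, 40.1, 120, 200))
    expect_lt(abs(boys(n, x) - boys_quad(n, x)), 1e-13)
  expect_error(boys(-1, 0))
  expect_error(boys(0, -1))
})

test_that("overlap: normalization, translation invariance, raised momenta vs quadrature", {
  s <- gto_shell(c(0.3, -0.2, 0.5), 0, 1.7, 1)
  expect_equal(overlap(s, s)[1, 1], 1, tolerance = 1e-12)
  # spec example: two unit-exponent s at 1 bohr, raised by (2,0,0)
  a <- gto_shell(c(0, 0, 0), 0, 1, 1)
  b <- gto_shell(c(1, 0, 0), 0, 1, 1)
  expect_equal(overlap(a, b, shift = c(2, 0, 0))[1, 1],
               ov_quad(a, b, shift = c(2, 0, 0))[1, 1], tolerance = 1e-8)
  set.seed(42)
  for (rep in 1:40) {
    la <- sample(0:2, 1); lb <- sample(0:2, 1)
    A <- runif(3, -2, 2); B <- runif(3, -2, 2)
    a <- gto_shell(A, la, exp(runif(1, log(0.1), log(50))), 1)
    b <- gto_shell(B, lb, exp(runif(1, log(0.1), log(50))), 1)
    m <- sample(0:3, 3, replace = TRUE)
    expect_lt(max(abs(overlap(a, b, m) - ov_quad(a, b, m))), 1e-8)
    # translation invariance
    t0 <- runif(3, -5, 5)
    at <- gto_shell(A + t0, la, a$exps, 1); bt <- gto_shell(B + t0, lb, b$exps, 1)
    expect_lt(max(abs(overlap(a, b, m) - overlap(at, bt, m))), 1e-11)
  }
})

test_that("kinetic energy: closed form, symmetry, quadrature oracle", {
  z <- 2.31
  s <- gto_shell(c(0, 0, 0), 0, z, 1)
  expect_equal(kinetic(s, s)[1, 1], 1.5 * z, tolerance = 1e-12)
  set.seed(7)
  for (rep in 1:25) {
    a <- gto_shell(runif(3, -1, 1), sample(0:2, 1),
                   exp(runif(1, log(0.1), log(20))), 1)
    b <- gto_shell(runif(3, -1, 1), sample(0:2, 1),
                   exp(runif(1, log(0.1), log(20))), 1)
    Tab <- kinetic(a, b)
    expect_lt(max(abs(Tab - t(kinetic(b, a)))), 1e-12)
    expect_lt(max(abs(Tab - kin_quad(a, b))), 1e-8)
  }
})

test_that("nuclear attraction: closed form, 1/R decay, delta-function limit", {
  set.seed(11)
  for (rep in 1:30) {
    a <- gto_shell(runif(3, -1, 1), 0, exp(runif(1, log(0.2), log(10))), 1)
    b <- gto_shell(runif(3, -1, 1), 0, exp(runif(1, log(0.2), log(10))), 1)
    D <- runif(3, -3, 3)
    expect_equal(nai_exact(a, b, D)[1, 1], nai_ss_closed(a, b, D),
                 tolerance = 1e-10)
  }
  s <- gto_shell(c(0, 0, 0), 0, 1, 1)
  # site on top of both centers stays finite
  expect_true(is.finite(nai_exact(s, s, c(0, 0, 0))[1, 1]))
  # 1/R decay
  v2 <- nai_exact(s, s, c(2, 0, 0))[1, 1]
  vfar <- nai_exact(s, s, c(1e6, 0, 0))[1, 1]
  expect_lt(vfar, 1e-5 * v2)
  # NAI as the tight-exponent limit of a 3-center ERI
  p <- gto_shell(c(0.2, 0, 0), 1, 1.3, 1)
  d <- gto_shell(c(-0.1, 0.4, 0), 2, 0.9, 1)
  D <- c(1.7, -0.6, 0.8)
  zc <- 1e6
  cc <- aux_hermite(D, c(0, 0, 0), zc)
  lim <- eri3(p, d, cc) * (zc / pi)^1.5 / cc$norm
  expect_lt(max(abs(lim - nai_exact(p, d, D))), 1e-6)
})

test_that("two-center repulsion: closed form, positivity, PSD metric", {
  c1 <- aux_hermite(c(0, 0, 0), c(0, 0, 0), 0.7)
  c2 <- aux_hermite(c(0, 1.3, -2), c(0, 0, 0), 2.2)
  expect_equal(eri2(c1, c2), eri2_ss_closed(c1, c2), tolerance = 1e-12)
  expect_gt(eri2(c1, c1), 0)
  expect_equal(eri2(c1, c2), eri2(c2, c1), tolerance = 1e-14)
  # Coulomb metric of a random 10-function set is symmetric PSD
  set.seed(3)
  aux <- lapply(1:10, function(i)
    aux_hermite(runif(3, -2, 2),
                sample(list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1)), 1)[[1]],
                exp(runif(1, log(0.2), log(5)))))
  G <- auxqmmm:::eri2_matrix(aux)
  expect_lt(max(abs(G - t(G))), 1e-12)
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
})

test_that("three-center repulsion: closed-form oracle, symmetry, far-field limit", {
  set.seed(19)
  for (rep in 1:25) {
    a <- gto_shell(runif(3, -1, 1), 0, exp(runif(1, log(0.2), log(10))), 1)
    b <- gto_shell(runif(3, -1, 1), 0, exp(runif(1, log(0.2), log(10))), 1)
    cc <- aux_hermite(runif(3, -3, 3), c(0, 0, 0),
                      exp(runif(1, log(0.2), log(5))))
    expect_equal(eri3(a, b, cc)[1, 1], eri3_sss_closed(a, b, cc),
                 tolerance = 1e-7)
  }
  # a <-> b symmetry for higher momenta
  a <- gto_shell(c(0.3, 0, 0), 2, 1.4, 1)
  b <- gto_shell(c(-0.4, 0.5, 0), 1, 0.8, 1)
  cc <- aux_hermite(c(1, 1, 1), c(2, 0, 0), 1.1)
  expect_lt(max(abs(eri3(a, b, cc) - t(eri3(b, a, cc)))), 1e-12)
  # far-separated s aux: <a|b> (pi/z)^{3/2} N / R with R measured from the
  # (spherical) product-Gaussian center -- exact up to Gaussian tails
  cfar <- aux_hermite(c(50, 0, 0), c(0, 0, 0), 0.9)
  a <- gto_shell(c(0, 0, 0), 0, 1.2, 1)
  b <- gto_shell(c(0.4, 0, 0), 0, 0.7, 1)
  P <- (1.2 * a$center + 0.7 * b$center) / 1.9
  R <- sqrt(sum((P - cfar$center)^2))
  lead <- overlap(a, b)[1, 1] * (pi / 0.9)^1.5 * cfar$norm / R
  expect_equal(eri3(a, b, cfar)[1, 1] / lead, 1, tolerance = 1e-9)
})

test_that("s-set integrals are invariant under global rotation", {
  set.seed(23)
  th <- 0.83
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  A <- c(0.5, -0.3, 0.8); B <- c(-0.6, 0.2, 0.1); D <- c(2, 1, -1)
  a <- gto_shell(A, 0, 1.3, 1); b <- gto_shell(B, 0, 0.6, 1)
  ar <- gto_shell(as.numeric(Rz %*% A), 0, 1.3, 1)
  br <- gto_shell(as.numeric(Rz %*% B), 0, 0.6, 1)
  expect_equal(nai_exact(a, b, D)[1, 1],
               nai_exact(ar, br, as.numeric(Rz %*% D))[1, 1],
               tolerance = 1e-12)
  cc <- aux_hermite(D, c(0, 0, 0), 0.8)
  ccr <- aux_hermite(as.numeric(Rz %*% D), c(0, 0, 0), 0.8)
  expect_equal(eri3(a, b, cc)[1, 1], eri3(ar, br, ccr)[1, 1],
               tolerance = 1e-12)
})

test_that("basis I/O: Gaussian94 dialect parses and f functions are refused", {
  lib <- load_basis("sto3g")
  expect_true(all(c("H", "He", "C", "N", "O") %in% names(lib)))
  expect_equal(length(lib$O), 3)  # 1s, 2s (from SP), 2p
  expect_error(gto_shell(c(0, 0, 0), 3, 1, 1), "not supported")
  expect_error(aux_hermite(c(0, 0, 0), c(2, 1, 0), 1), "not supported")
  # a contracted shell from the library is normalized
  sh <- build_shells(water_monomer(), "sto3g")
  for (s in sh) expect_equal(diag(overlap(s, s)),
                             rep(1, s$ncomp), tolerance = 1e-10)
})
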