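# Near/far-field machinery: extents, classification, 1/R derivative
# tensors, asymptotic expansions, embedded core Hamiltonian.

test_that("shell extents solve the amplitude condition and behave monotonically", {
  s <- gto_shell(c(0, 0, 0), 0, 1, 1)
  R <- shell_extent(s, 1e-10)
  # bisection oracle on the amplitude of the normalized unit-zeta s
  N <- s$coefn[1, 1]
  Rref <- uniroot(function(r) N * exp(-r^2) - 1e-10, c(0.5, 30),
                  tol = 1e-10)$root
  expect_equal(R, Rref, tolerance = 1e-6)
  expect_equal(Rref, sqrt(log(N / 1e-10)), tolerance = 1e-6)
  expect_gt(shell_extent(s, 1e-12), shell_extent(s, 1e-8))
  tight <- gto_shell(c(0, 0, 0), 0, 1000, 1)
  diffuse <- gto_shell(c(0, 0, 0), 0, 0.1, 1)
  expect_lt(shell_extent(tight), shell_extent(diffuse))
  expect_error(shell_extent(s, 1), "tau")
})

test_that("site classification matches a brute-force per-pair rule", {
  w <- water_monomer()
  shells <- build_shells(w, "sto3g")
  set.seed(8)
  sites <- data.frame(x = runif(1000, -40, 40), y = runif(1000, -40, 40),
                      z = runif(1000, -40, 40))
  nf <- classify_mm(shells, sites, tau = 1e-10)
  # brute force with the same classification radii
  for (i in seq_along(shells)) {
    d <- sqrt(colSums((t(as.matrix(sites)) - shells[[i]]$center)^2))
    expect_identical(nf$shell_near[[i]], which(d <= nf$extents[i]))
  }
  # extreme cases
  far_site <- data.frame(x = 1000, y = 0, z = 0)
  nf2 <- classify_mm(shells, far_site)
  expect_true(all(lengths(nf2$shell_near) == 0))
  on_atom <- data.frame(x = shells[[1]]$center[1], y = shells[[1]]$center[2],
                        z = shells[[1]]$center[3])
  nf3 <- classify_mm(shells, on_atom)
  expect_true(all(lengths(nf3$shell_near) == 1))
})

test_that("1/R derivative tensors match symbolic differentiation", {
  A <- c(0.37, -1.1, 0.64); D <- c(2.3, 1.7, -0.9)
  tt <- t_tensor(A, D, 6)
  R <- sqrt(sum((A - D)^2))
  expect_equal(tt[1, 1, 1], 1 / R, tolerance = 1e-14)
  expect_equal(tt[2, 1, 1], (A[1] - D[1]) / R^3, tolerance = 1e-12)
  for (tot in 0:6) for (mx in tot:0) for (my in (tot - mx):0) {
    m <- c(mx, my, tot - mx - my)
    ref <- t_symbolic(m, A, D)
    expect_equal(tt[m[1] + 1, m[2] + 1, m[3] + 1], ref,
                 tolerance = 1e-10 * max(1, abs(ref)))
  }
  # Laplacian identity at order 8
  t8 <- t_tensor(A, D, 8)
  expect_lt(abs(t8[3, 1, 1] + t8[1, 3, 1] + t8[1, 1, 3]),
            1e-10 * abs(t8[3, 1, 1]))
  expect_error(t_tensor(A, A, 4), "coincident")
})

test_that("asymptotic NAI matches the exact integral in the far field", {
  a <- gto_shell(c(0, 0, 0), 1, 0.9, 1)
  b <- gto_shell(c(0.7, -0.2, 0.3), 2, 1.8, 1)
  D <- c(50, 3, -8)
  expect_lt(max(abs(nai_asymptotic(a, b, D, 8) - nai_exact(a, b, D))), 1e-10)
  # center-b variant agrees in the far field too
  expect_lt(max(abs(nai_asymptotic(a, b, D, 8, center = "b") -
                      nai_exact(a, b, D))), 1e-10)
  # order 0 is exactly S_ab / R  (expansion about the center of a)
  D2 <- c(20, 0, 0)
  lead <- overlap(a, b) / sqrt(sum((a$center - D2)^2))
  expect_equal(nai_asymptotic(a, b, D2, 0), lead, tolerance = 1e-14)
  # truncation error decreases monotonically with order at 20 bohr
  errs <- vapply(c(2, 4, 6, 8), function(o)
    max(abs(nai_asymptotic(a, b, D2, o) - nai_exact(a, b, D2))), 1.0)
  expect_true(all(diff(errs) < 0))
})

test_that("double asymptotic ERI matches exact far-field 3-center integrals", {
  a <- gto_shell(c(0, 0, 0), 0, 0.8, 1)
  b <- gto_shell(c(0.9, 0.1, 0), 1, 1.1, 1)
  cs <- aux_hermite(c(50, -4, 6), c(0, 0, 0), 0.7)
  expect_lt(max(abs(eri3_asymptotic(a, b, cs, 8) - eri3(a, b, cs))), 1e-10)
  # s-type aux at order 0: <a|b> (pi/zeta)^{3/2} N / R
  cs2 <- aux_hermite(c(30, 0, 0), c(0, 0, 0), 0.7)
  lead <- overlap(a, b) * (pi / 0.7)^1.5 * cs2$norm / 30
  expect_equal(eri3_asymptotic(a, b, cs2, 0), lead, tolerance = 1e-13)
  # Hermite-index-1 aux equals the center-derivative of the s-type value
  h <- 1e-4
  cup <- aux_hermite(c(30, 0, 0 + h), c(0, 0, 0), 0.7)
  cdn <- aux_hermite(c(30, 0, 0 - h), c(0, 0, 0), 0.7)
  c1 <- aux_hermite(c(30, 0, 0), c(0, 0, 1), 0.7)
  fd <- (eri3(a, b, cup) / cup$norm - eri3(a, b, cdn) / cdn$norm) / (2 * h)
  expect_lt(max(abs(fd - eri3(a, b, c1) / c1$norm)), 1e-8)
})

test_that("asymptotic and exact integrals agree below tolerance outside the extents", {
  set.seed(31)
  for (rep in 1:40) {
    la <- sample(0:2, 1); lb <- sample(0:2, 1)
    A <- runif(3, -1, 1); B <- A + runif(3, -1, 1)
    a <- gto_shell(A, la, exp(runif(1, log(0.1), log(50))), 1)
    b <- gto_shell(B, lb, exp(runif(1, log(0.1), log(50))), 1)
    ea <- 3 * shell_extent(a); eb <- 3 * shell_extent(b)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    D <- A + u * ea * runif(1, 1.0001, 2)
    if (sqrt(sum((D - B)^2)) <= eb)
      D <- B + (D - B) / sqrt(sum((D - B)^2)) * eb * 1.0001
    expect_lt(max(abs(nai_asymptotic(a, b, D, 8) - nai_exact(a, b, D))),
              2e-10)
  }
})

test_that("embedded core Hamiltonian: limits, factorization identity, accuracy", {
  w <- water_monomer()
  shells <- build_shells(w, "sto3g")
  H0 <- auxqmmm:::kinetic_matrix(shells) -
    auxqmmm:::nai_matrix(shells, positions(w), w$atoms$Z)
  # zero charges leave H unchanged
  zq <- data.frame(x = c(5, -7), y = c(0, 2), z = c(1, 1), q = c(0, 0))
  expect_equal(unname(embed_core_hamiltonian(H0, shells, zq)),
               unname(H0), tolerance = 1e-14, ignore_attr = TRUE)
  # a single far charge shifts each element by -Q x asymptotic NAI
  fq <- data.frame(x = 60, y = 10, z = -5, q = 0.37)
  H1 <- embed_core_hamiltonian(H0, shells, fq)
  so <- auxqmmm:::shell_offsets(shells)
  i <- 2; j <- 4
  blk <- nai_asymptotic(shells[[i]], shells[[j]], c(60, 10, -5), 8)
  ri <- so$off[i] + seq_len(so$nc[i]); rj <- so$off[j] + seq_len(so$nc[j])
  expect_lt(max(abs(H1[ri, rj, drop = FALSE] - H0[ri, rj, drop = FALSE] +
                      0.37 * blk)), 1e-12)
  # mixed near/far vs all-exact on a 300-charge cloud
  set.seed(12)
  n <- 300
  pts <- matrix(runif(3 * n, -1, 1), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(n, 5, 60)
  ch <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                   q = runif(n, -0.8, 0.8))
  Hmix <- embed_core_hamiltonian(H0, shells, ch)
  Hex <- H0 - auxqmmm:::nai_matrix(shells, ch[, 1:3], ch$q)
  expect_lt(max(abs(Hmix - Hex)), n * 1e-10)
  expect_gt(attr(Hmix, "counts")["far"], 0)
  # per-site and factorized far-field accumulation agree to 1e-12
  Hsite <- embed_core_hamiltonian(H0, shells, ch, factorize = FALSE)
  expect_lt(max(abs(Hmix - Hsite)), 1e-12)
})
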