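# Link atoms, additive and subtractive coupling, FIRES restraint.

test_that("link atoms sit on the boundary bond at the prescribed fraction", {
  but <- build_connectivity(make_fixture("alkane", list(n_carbons = 4)))
  qm <- sort(unique(c(1, but$bonds[but$bonds[, 1] == 1 & but$bonds[, 2] > 4, 2])))
  p <- partition_by_selection(but, qm)
  # explicit alpha = 0.5: midpoint
  p5 <- place_link_atoms(but, p, alpha = 0.5)
  la <- p5$link_atoms[[1]]
  xyz <- positions(but)
  expect_equal(la$position, (xyz[la$qba, ] + xyz[la$mba, ]) / 2,
               tolerance = 1e-12)
  # default C-C cut: alpha = 1.090/1.530, so |LA - QBA| = 1.090 A at the
  # equilibrium C-C distance of the fixture
  pd <- place_link_atoms(but, p)
  la <- pd$link_atoms[[1]]
  expect_equal(la$alpha, 1.090 / 1.530, tolerance = 1e-12)
  expect_equal(sqrt(sum((la$position - xyz[la$qba, ])^2)),
               ang2bohr(1.090), tolerance = 1e-10)
  # collinearity for random geometries
  set.seed(3)
  for (rep in 1:10) {
    s <- molecular_system(c("C", "C"), matrix(rnorm(6, sd = 2), 2, 3),
                          bonds = rbind(c(1, 2)))
    pr <- place_link_atoms(s, partition_by_selection(s, 1), alpha = 0.31)
    v1 <- pr$link_atoms[[1]]$position - positions(s)[1, ]
    v2 <- positions(s)[2, ] - positions(s)[1, ]
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    expect_lt(max(abs(cr)), 1e-10)
  }
  # force projection limits
  f <- c(0.1, -0.2, 0.3)
  expect_equal(project_link_forces(f, 1)$F_MBA[1, ], f)
  expect_equal(project_link_forces(f, 1)$F_QBA[1, ], c(0, 0, 0))
  expect_equal(project_link_forces(f, 0)$F_QBA[1, ], f)
})

test_that("additive coupling decouples exactly when charges and epsilon vanish", {
  w <- make_fixture("water_droplet", list(n = 3), seed = 21)
  # zero out everything that couples electrostatics / dispersion
  w$atoms$mm_charge <- 0
  w$atoms$lj_eps <- 0
  p <- partition_by_selection(w, 1:3)
  pp <- load_ff_params("water-spc")
  # neutral epsilon-free parameter table
  pp$nonbonded$q <- 0; pp$nonbonded$eps <- 0
  st <- fast_scf(scheme = "conventional")
  add <- additive_qmmm(w, p, pp, basis = "sto3g", settings = st)
  qm1 <- molecular_system(c("O", "H", "H"), positions(w)[1:3, ])
  gas <- run_scf(qm1, "sto3g", settings = st)
  mm_only <- mm_energy_gradient(w, pp, qm_mask = seq_len(9) <= 3,
                                gradient = FALSE)
  expect_equal(add$E_QM, gas$E_total, tolerance = 1e-12)
  expect_equal(add$E_QMMM, 0)
  expect_equal(add$E_total, gas$E_total + mm_only$energy, tolerance = 1e-12)
})

test_that("embedding energy follows the dipole-field distance scaling", {
  w <- water_monomer()
  st <- fast_scf(scheme = "conventional")
  e0 <- run_scf(w, "sto3g", settings = st)$E_total
  eat <- function(R) {
    ch <- data.frame(x = 0, y = 0, z = R, q = 0.5)
    run_scf(w, "sto3g", charges = ch, settings = st)$E_total - e0
  }
  # interaction with a neutral-molecule dipole falls off ~ R^-2: doubling
  # the distance reduces the interaction by ~4
  u20 <- eat(20); u40 <- eat(40)
  expect_equal(u20 / u40, 4, tolerance = 0.15)
})

test_that("total additive gradient on MM sites matches finite differences", {
  set.seed(31)
  w <- make_fixture("water_droplet", list(n = 3), seed = 8)
  p <- partition_by_selection(w, 1:3)
  pp <- load_ff_params("water-spc")
  st <- fast_scf(scheme = "conventional", tol = 1e-9, aux_kind = "ET-s")
  add <- additive_qmmm(w, p, pp, basis = "sto3g", settings = st,
                       gradient = TRUE)
  etot <- function(sys) {
    a <- additive_qmmm(sys, p, pp, basis = "sto3g", settings = st)
    a$E_total
  }
  xyz <- positions(w)
  h <- 1e-4
  for (k in sample(10:27, 4)) {  # MM-atom coordinates only (analytic path)
    xp <- xyz; xp[k] <- xp[k] + h
    xm <- xyz; xm[k] <- xm[k] - h
    fd <- (etot(set_positions(w, xp)) - etot(set_positions(w, xm))) / (2 * h)
    expect_lt(abs(fd - add$gradient[k]), 1e-5)
  }
})

test_that("same-level ONIOM collapses to the plain MM energy", {
  w <- make_fixture("water_droplet", list(n = 4), seed = 5)
  p <- partition_by_selection(w, 1:3)
  pp <- load_ff_params("water-spc")
  mm_eval <- function(msys, charges) {
    e <- mm_energy_gradient(msys, pp, gradient = FALSE)$energy
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
  on <- subtractive_oniom(w, p, pp, qm_evaluator = mm_eval)
  ref <- mm_energy_gradient(w, pp, gradient = FALSE)$energy
  expect_equal(on$E_total, ref, tolerance = 1e-12)
  # empty MM region: E_total = E_QM(model)
  pall <- partition_by_selection(w, seq_len(nrow(w$atoms)))
  on2 <- subtractive_oniom(w, pall, pp, settings = fast_scf())
  expect_equal(on2$E_total, on2$E_QM_model, tolerance = 1e-12)
})

test_that("link-force projection closes the total-energy gradient across an ethane cut", {
  eth <- build_connectivity(make_fixture("alkane", list(n_carbons = 2)))
  qm <- c(1, which(vapply(seq_len(nrow(eth$atoms)), function(i)
    any(eth$bonds[, 1] == 1 & eth$bonds[, 2] == i) && eth$atoms$element[i] == "H",
    TRUE)))
  p <- partition_by_selection(eth, qm)
  pp <- load_ff_params("alkane")
  st <- fast_scf(scheme = "conventional", tol = 1e-9, aux_kind = "ET-s")
  add <- additive_qmmm(eth, p, pp, basis = "sto3g", settings = st,
                       gradient = TRUE)
  mba <- p$boundary_pairs[1, 2]
  etot <- function(sys) additive_qmmm(sys, partition_by_selection(sys, qm),
                                      pp, basis = "sto3g",
                                      settings = st)$E_total
  xyz <- positions(eth)
  h <- 1e-4
  d <- 3
  xp <- xyz; xp[mba, d] <- xp[mba, d] + h
  xm <- xyz; xm[mba, d] <- xm[mba, d] - h
  fd <- (etot(set_positions(eth, xp)) - etot(set_positions(eth, xm))) /
    (2 * h)
  expect_lt(abs(fd - add$gradient[mba, d]), 1e-5)
})

test_that("FIRES restraint: intruder energetics and zero total force", {
  # geometry: reference at origin, 2 inner tags, 2 outer tags, 1 intruder
  xyz <- rbind(c(0, 0, 0),      # reference
               c(2, 0, 0),      # inner
               c(0, 3, 0),      # inner boundary (R_in = 3)
               c(0, 0, 2.5),    # outer intruder, r - R_in = -0.5
               c(6, 0, 0))      # outer, outside
  st <- fires_state(inner_tags = c(2, 3), outer_tags = c(4, 5), ref = 1,
                    k = 2)
  r <- fires_energy_gradient(st, xyz)
  expect_equal(r$R_in, 3)
  expect_equal(r$intruders, 4L)
  expect_equal(r$energy, 0.5 * 2 * 0.5^2)   # 0.25 hartree
  expect_lt(max(abs(colSums(r$gradient))), 1e-12)
  expect_equal(r$boundary_atom, 3L)
  # no intruders: zero energy and gradient
  xyz2 <- xyz; xyz2[4, ] <- c(0, 0, 9)
  r2 <- fires_energy_gradient(st, xyz2)
  expect_equal(r2$energy, 0)
  expect_equal(max(abs(r2$gradient)), 0)
  # gradient matches finite differences (including reference and boundary)
  h <- 1e-6
  for (k in c(1, 3, 4)) for (d in 1:3) {
    xp <- xyz; xp[k, d] <- xp[k, d] + h
    xm <- xyz; xm[k, d] <- xm[k, d] - h
    fd <- (fires_energy_gradient(st, xp)$energy -
             fires_energy_gradient(st, xm)$energy) / (2 * h)
    expect_lt(abs(fd - r$gradient[k, d]), 1e-7)
  }
})

test_that("FIRES preserves the inner-set identity over droplet dynamics", {
  ion <- make_fixture("ion_droplet", list(ion = "Na+", n_waters = 8),
                      seed = 17)
  pp <- merge_ff_params(load_ff_params("water-spc"), load_ff_params("ions"))
  ox <- which(ion$atoms$element == "O")
  d <- sqrt(rowSums(sweep(positions(ion)[ox, ], 2, positions(ion)[1, ])^2))
  inner <- ox[order(d)][1:3]
  outer <- setdiff(ox, inner)
  fs <- fires_state(inner, outer, ref = 1, k = kcal2hartree(100) / ang2bohr(1)^2)
  eng <- mm_engine(ion, pp, fires = fs)
  st0 <- md_state(positions(ion), ion$atoms$mass)
  tr <- run_md(st0, eng, 300, dt_fs = 1, thermostat = "langevin",
               temperature = 300, seed = 4, stride = 50)
  # identity preserved: every inner tag closer than every outer tag beyond
  # a 0.5 A transient overlap depth
  xyz <- tr$state$xyz
  din <- sqrt(rowSums(sweep(xyz[inner, , drop = FALSE], 2, xyz[1, ])^2))
  dout <- sqrt(rowSums(sweep(xyz[outer, , drop = FALSE], 2, xyz[1, ])^2))
  expect_lt(max(din), min(dout) + ang2bohr(0.5))
  # restraint force sums to zero along the trajectory end point
  fr <- fires_energy_gradient(fs, xyz)
  expect_lt(max(abs(colSums(fr$gradient))), 1e-10)
})
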