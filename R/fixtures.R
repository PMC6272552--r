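# Deterministic fixture systems: rigid-geometry water droplets packed by
# rejection sampling at liquid-like density, ideal-geometry n-alkanes,
# ion-in-droplet systems and harmonic toy models.

.water_geom <- function() {
  # 3-site rigid geometry: r(OH) = 0.9572 A, HOH = 104.52 deg; SPC charges.
  r <- ang2bohr(0.9572); th <- deg2rad(104.52)
  rbind(O  = c(0, 0, 0),
        H1 = c(r * sin(th / 2),  r * cos(th / 2), 0),
        H2 = c(-r * sin(th / 2), r * cos(th / 2), 0))
}

.water_mm <- function() {
  list(type = c("OW", "HW", "HW"), q = c(-0.82, 0.41, 0.41),
       eps = kcal2hartree(c(0.1553, 0, 0)),
       rmin = ang2bohr(c(3.5532, 0.4, 0.4)))
}

.rand_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

pack_waters <- function(n, radius, existing = NULL, min_dist = ang2bohr(1.5),
                        oo_min = ang2bohr(2.7), max_tries = 20000) {
  geom <- .water_geom()
  placed <- list(); all_xyz <- existing
  tries <- 0
  while (length(placed) < n) {
    tries <- tries + 1
    if (tries > max_tries) stop("pack_waters: rejection sampling failed")
    ctr <- runif(3, -1, 1) * radius
    if (sqrt(sum(ctr^2)) > radius) next
    mol <- geom %*% t(.rand_rotation())
    mol <- sweep(mol, 2, ctr - colMeans(mol), "+")
    ok <- TRUE
    if (!is.null(all_xyz) && nrow(all_xyz)) {
      for (k in 1:3) {
        d2 <- rowSums(sweep(all_xyz, 2, mol[k, ])^2)
        if (min(d2) < min_dist^2) { ok <- FALSE; break }
      }
      if (ok && length(placed)) {
        oo <- do.call(rbind, lapply(placed, function(m) m[1, , drop = FALSE]))
        if (min(rowSums(sweep(oo, 2, mol[1, ])^2)) < oo_min^2) ok <- FALSE
      }
    }
    if (!ok) next
    placed[[length(placed) + 1]] <- mol
    all_xyz <- rbind(all_xyz, mol)
  }
  placed
}

water_droplet_system <- function(n_waters, seed = 1) {
  stopifnot(n_waters >= 1)
  set.seed(seed)
  # liquid-water number density ~0.0334 molecules/A^3, with headroom
  vol <- n_waters / 0.0334 * 2.0
  radius <- ang2bohr((3 * vol / (4 * pi))^(1 / 3))
  mols <- pack_waters(n_waters, radius)
  xyz <- do.call(rbind, mols)
  mm <- .water_mm()
  sys <- molecular_system(rep(c("O", "H", "H"), n_waters), xyz,
                          region = "MM",
                          mm_type = rep(mm$type, n_waters),
                          mm_charge = rep(mm$q, n_waters),
                          lj_eps = rep(mm$eps, n_waters),
                          lj_rmin = rep(mm$rmin, n_waters))
  b <- do.call(rbind, lapply(seq_len(n_waters) - 1L,
                             function(m) rbind(c(3 * m + 1, 3 * m + 2),
                                               c(3 * m + 1, 3 * m + 3))))
  set_bonds(sys, b)
}

alkane_system <- function(n_carbons) {
  stopifnot(n_carbons >= 1)
  dcc <- ang2bohr(1.530); dch <- ang2bohr(1.090)
  th <- deg2rad(109.471)
  cpos <- matrix(0, n_carbons, 3)
  if (n_carbons > 1) {
    bx <- dcc * sin(th / 2); bz <- dcc * cos(th / 2)
    for (i in seq_len(n_carbons))
      cpos[i, ] <- c((i - 1) * bx, 0, ((i - 1) %% 2) * bz)
  }
  el <- character(0); xyz <- NULL; bonds <- NULL
  hcount <- integer(n_carbons)
  tetra_two <- function(u1, u2) {
    v <- -(u1 + u2); v <- v / sqrt(sum(v^2))
    w <- c(u1[2] * u2[3] - u1[3] * u2[2], u1[3] * u2[1] - u1[1] * u2[3],
           u1[1] * u2[2] - u1[2] * u2[1])
    w <- w / sqrt(sum(w^2))
    a <- deg2rad(109.471) / 2
    list(cos(a) * v + sin(a) * w, cos(a) * v - sin(a) * w)
  }
  tetra_three <- function(u1) {
    e1 <- if (abs(u1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * u1) * u1; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u1[2] * e1[3] - u1[3] * e1[2], u1[3] * e1[1] - u1[1] * e1[3],
            u1[1] * e1[2] - u1[2] * e1[1])
    lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi)
      -u1 / 3 + sqrt(8) / 3 * (cos(phi) * e1 + sin(phi) * e2))
  }
  el <- rep("C", n_carbons); xyz <- cpos
  for (i in seq_len(n_carbons)) {
    nbrs <- list()
    if (i > 1) nbrs <- c(nbrs, list((cpos[i - 1, ] - cpos[i, ]) / dcc))
    if (i < n_carbons) nbrs <- c(nbrs, list((cpos[i + 1, ] - cpos[i, ]) / dcc))
    dirs <- if (length(nbrs) == 2) tetra_two(nbrs[[1]], nbrs[[2]])
            else if (length(nbrs) == 1) tetra_three(nbrs[[1]])
            else { # methane
              list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) |>
                lapply(function(v) v / sqrt(3))
            }
    for (d in dirs) {
      el <- c(el, "H"); xyz <- rbind(xyz, cpos[i, ] + dch * d)
      hcount[i] <- hcount[i] + 1L
      bonds <- rbind(bonds, c(i, length(el)))
    }
  }
  if (n_carbons > 1)
    bonds <- rbind(bonds, cbind(seq_len(n_carbons - 1), 2:n_carbons))
  ctype <- ifelse(hcount >= 3, "CT3", "CT2")
  cq <- ifelse(hcount >= 3, -0.18, -0.12)
  mm_type <- c(ctype, rep("HC", length(el) - n_carbons))
  mm_q <- c(cq, rep(0.06, length(el) - n_carbons))
  eps <- kcal2hartree(ifelse(mm_type == "HC", 0.030, 0.066))
  rmin <- ang2bohr(ifelse(mm_type == "HC", 2.81, 3.93)) # sigma*2^(1/6)
  sys <- molecular_system(el, xyz, region = "MM", mm_type = mm_type,
                          mm_charge = mm_q, lj_eps = eps, lj_rmin = rmin)
  set_bonds(sys, bonds)
}

.ion_table <- list(
  "Na+" = list(el = "Na", q = 1, eps = kcal2hartree(0.0469),
               rmin = ang2bohr(2.8215)),
  "K+"  = list(el = "K", q = 1, eps = kcal2hartree(0.0870),
               rmin = ang2bohr(3.5275)),
  "Cl-" = list(el = "Cl", q = -1, eps = kcal2hartree(0.1500),
               rmin = ang2bohr(4.5400)),
  "Br-" = list(el = "Br", q = -1, eps = kcal2hartree(0.1600),
               rmin = ang2bohr(4.9000))
)

ion_droplet_system <- function(ion = "Na+", n_waters = 21, seed = 1) {
  stopifnot(n_waters >= 1)
  if (!ion %in% names(.ion_table)) stop("unknown ion: ", ion)
  set.seed(seed)
  par <- .ion_table[[ion]]
  vol <- (n_waters + 1) / 0.0334 * 2.0
  radius <- ang2bohr((3 * vol / (4 * pi))^(1 / 3))
  mols <- pack_waters(n_waters, radius, existing = matrix(0, 1, 3),
                      min_dist = ang2bohr(2.2))
  xyz <- rbind(c(0, 0, 0), do.call(rbind, mols))
  mm <- .water_mm()
  sys <- molecular_system(c(par$el, rep(c("O", "H", "H"), n_waters)), xyz,
                          region = "MM",
                          mm_type = c(toupper(par$el), rep(mm$type, n_waters)),
                          mm_charge = c(par$q, rep(mm$q, n_waters)),
                          lj_eps = c(par$eps, rep(mm$eps, n_waters)),
                          lj_rmin = c(par$rmin, rep(mm$rmin, n_waters)))
  b <- do.call(rbind, lapply(seq_len(n_waters) - 1L,
                             function(m) rbind(c(3 * m + 2, 3 * m + 3),
                                               c(3 * m + 2, 3 * m + 4))))
  set_bonds(sys, b)
}

harmonic_toy <- function(k = 1, n_dim = 1, mass = 1) {
  stopifnot(k > 0, n_dim >= 1)
  list(k = k, n_dim = n_dim, mass = mass,
       energy_gradient = function(x) list(energy = 0.5 * k * sum(x^2),
                                          gradient = k * x))
}

#' Generate a deterministic fixture system
#'
#' @param kind one of `"water_droplet"`, `"alkane"`, `"ion_droplet"`,
#'   `"harmonic_toy"`
#' @param params list of parameters: `n` (waters) for water_droplet;
#'   `n_carbons` for alkane; `ion` and `n_waters` for ion_droplet;
#'   `k`, `n_dim` for harmonic_toy
#' @param seed RNG seed; the same seed reproduces the fixture bit for bit
#' @return a `qmm_system` (or, for `harmonic_toy`, an engine list with an
#'   `energy_gradient` closure)
#' @export
#' @examples
#' w <- make_fixture("water_droplet", list(n = 3), seed = 7)
#' nrow(w$atoms)  # 9
make_fixture <- function(kind, params = list(), seed = 1) {
  switch(kind,
    water_droplet = water_droplet_system(params$n %||% 21, seed),
    alkane        = alkane_system(params$n_carbons %||% 8),
    ion_droplet   = ion_droplet_system(params$ion %||% "Na+",
                                       params$n_waters %||% 21, seed),
    harmonic_toy  = harmonic_toy(params$k %||% 1, params$n_dim %||% 1,
                                 params$mass %||% 1),
    stop("unknown fixture kind: ", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract MM point charges from a system
#'
#' Returns the partial charges of the selected atoms as an embedding
#' point-charge table (positions in bohr).
#'
#' @param sys a `qmm_system`
#' @param indices atom indices (default: all MM-region atoms)
#' @export
system_point_charges <- function(sys, indices = which(sys$atoms$region == "MM")) {
  data.frame(x = sys$atoms$x[indices], y = sys$atoms$y[indices],
             z = sys$atoms$z[indices], q = sys$atoms$mm_charge[indices])
}
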