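# Numerical integration grid for the exchange-correlation term: per-atom
# Gauss-Legendre radial shells under the Becke mapping, a product angular
# rule (Gauss-Legendre in cos(theta) x uniform azimuth), and Becke fuzzy
# partitioning of space among atoms.

gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (2 * e$vectors[1, ]^2)[ord])
}

#' Build a Becke-partitioned molecular integration grid
#'
#' Radial points follow the Becke transformation r = R_m (1+x)/(1-x) of a
#' Gauss-Legendre rule (R_m is a per-element scale radius); the angular
#' rule is a product of Gauss-Legendre in cos(theta) with a uniform
#' azimuthal rule, exact for spherical harmonics up to degree
#' 2 n_theta - 1. Atomic weights use the standard Becke fuzzy-cell switch
#' (three iterations, no atomic-size adjustment).
#'
#' @param centers n x 3 matrix of atomic positions (bohr)
#' @param elements element symbols (sets the radial scale radius)
#' @param n_radial radial points per atom (default 40)
#' @param n_theta polar points (default 9; azimuth gets 2 n_theta)
#' @return list with `points` (N x 3) and `weights` (length N); the
#'   weights integrate smooth densities, e.g. a normalized s-Gaussian to
#'   1 within 1e-6
#' @export
becke_grid <- function(centers, elements, n_radial = 40, n_theta = 9) {
  centers <- matrix(centers, ncol = 3)
  nat <- nrow(centers)
  stopifnot(length(elements) == nat, n_radial > 1, n_theta > 1)
  rm_tab <- ang2bohr(element_info(elements)$rgrid)
  gl <- gauss_legendre(n_radial)
  glt <- gauss_legendre(n_theta)
  nphi <- 2 * n_theta
  phi <- 2 * pi * (seq_len(nphi) - 0.5) / nphi
  # unit sphere directions and angular weights (sum = 4 pi)
  ct <- glt$x; st <- sqrt(pmax(0, 1 - ct^2))
  dirs <- NULL; wang <- NULL
  for (it in seq_len(n_theta)) {
    dirs <- rbind(dirs, cbind(st[it] * cos(phi), st[it] * sin(phi), ct[it]))
    wang <- c(wang, rep(glt$w[it] * 2 * pi / nphi, nphi))
  }
  pts <- NULL; w0 <- NULL; owner <- NULL
  for (a in seq_len(nat)) {
    rm <- rm_tab[a]
    r <- rm * (1 + gl$x) / (1 - gl$x)
    wr <- gl$w * 2 * rm / (1 - gl$x)^2 * r^2
    for (ir in seq_len(n_radial)) {
      pts <- rbind(pts, sweep(dirs * r[ir], 2, centers[a, ], "+"))
      w0 <- c(w0, wr[ir] * wang)
      owner <- c(owner, rep(a, nrow(dirs)))
    }
  }
  if (nat > 1) {
    # Becke cell functions
    f3 <- function(mu) { for (k in 1:3) mu <- 1.5 * mu - 0.5 * mu^3; mu }
    Pcell <- matrix(1, nrow(pts), nat)
    d_at <- vapply(seq_len(nat), function(a)
      sqrt(rowSums(sweep(pts, 2, centers[a, ])^2)), numeric(nrow(pts)))
    for (a in seq_len(nat)) for (b in seq_len(nat)) {
      if (a == b) next
      Rab <- sqrt(sum((centers[a, ] - centers[b, ])^2))
      mu <- (d_at[, a] - d_at[, b]) / Rab
      Pcell[, a] <- Pcell[, a] * 0.5 * (1 - f3(mu))
    }
    wb <- Pcell[cbind(seq_len(nrow(pts)), owner)] / rowSums(Pcell)
    w0 <- w0 * wb
  }
  list(points = pts, weights = w0)
}
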