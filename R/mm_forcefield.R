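# Classical force field: harmonic bonds/angles/Urey-Bradley, cosine
# dihedrals, 12-6 Lennard-Jones in epsilon/R_min form and point-charge
# Coulomb over explicit double loops (no cutoff by default), with analytic
# gradients. Also the QM-MM Lennard-Jones coupling and the Drude
# polarizable-site model with self-consistent Drude relaxation.

#' Read a force-field parameter file
#'
#' Plain-text dialect with sections NONBONDED, BONDS, ANGLES, UREY,
#' DIHEDRALS. Input units are kcal/mol, Angstrom and degrees; everything
#' is converted to atomic units on read. Harmonic terms use the
#' E = k/2 (x - x0)^2 convention; dihedrals are V (1 + cos(n phi - delta)).
#' `X` acts as a wildcard in dihedral end positions.
#'
#' @param path parameter file
#' @return an `ff_params` object
#' @export
read_ff_params <- function(path) {
  lines <- trimws(readLines(path))
  lines <- sub("#.*", "", lines); lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sec <- NULL
  nb <- list(); bd <- list(); an <- list(); ur <- list(); dh <- list()
  for (ln in lines) {
    up <- toupper(ln)
    if (up %in% c("NONBONDED", "BONDS", "ANGLES", "UREY", "DIHEDRALS")) {
      sec <- up; next
    }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (is.null(sec)) stop("read_ff_params: data before any section header")
    if (sec == "NONBONDED") {
      nb[[length(nb) + 1]] <- data.frame(
        type = tok[1], q = as.numeric(tok[2]),
        eps = kcal2hartree(as.numeric(tok[3])),
        rmin = ang2bohr(as.numeric(tok[4])), stringsAsFactors = FALSE)
    } else if (sec == "BONDS") {
      bd[[length(bd) + 1]] <- data.frame(
        t1 = tok[1], t2 = tok[2],
        k = kcal2hartree(as.numeric(tok[3])) / ang2bohr(1)^2,
        r0 = ang2bohr(as.numeric(tok[4])), stringsAsFactors = FALSE)
    } else if (sec == "ANGLES") {
      an[[length(an) + 1]] <- data.frame(
        t1 = tok[1], t2 = tok[2], t3 = tok[3],
        k = kcal2hartree(as.numeric(tok[4])),
        theta0 = deg2rad(as.numeric(tok[5])), stringsAsFactors = FALSE)
    } else if (sec == "UREY") {
      ur[[length(ur) + 1]] <- data.frame(
        t1 = tok[1], t2 = tok[2], t3 = tok[3],
        k = kcal2hartree(as.numeric(tok[4])) / ang2bohr(1)^2,
        s0 = ang2bohr(as.numeric(tok[5])), stringsAsFactors = FALSE)
    } else if (sec == "DIHEDRALS") {
      dh[[length(dh) + 1]] <- data.frame(
        t1 = tok[1], t2 = tok[2], t3 = tok[3], t4 = tok[4],
        V = kcal2hartree(as.numeric(tok[5])), n = as.integer(tok[6]),
        delta = deg2rad(as.numeric(tok[7])), stringsAsFactors = FALSE)
    }
  }
  structure(list(nonbonded = do.call(rbind, nb), bonds = do.call(rbind, bd),
                 angles = do.call(rbind, an), ureys = do.call(rbind, ur),
                 dihedrals = do.call(rbind, dh)), class = "ff_params")
}

#' Load a shipped force-field parameter set
#' @param name `"water-spc"`, `"alkane"` or a file path
#' @export
load_ff_params <- function(name) {
  if (file.exists(name)) return(read_ff_params(name))
  f <- system.file("extdata", "mm", paste0(name, ".prm"), package = "auxqmmm")
  if (!nzchar(f)) stop("unknown parameter set: ", name)
  read_ff_params(f)
}

#' Merge force-field parameter sets
#' @param ... `ff_params` objects
#' @export
merge_ff_params <- function(...) {
  ps <- list(...)
  out <- lapply(c("nonbonded", "bonds", "angles", "ureys", "dihedrals"),
                function(f) do.call(rbind, lapply(ps, `[[`, f)))
  names(out) <- c("nonbonded", "bonds", "angles", "ureys", "dihedrals")
  structure(out, class = "ff_params")
}

.tm <- function(col, t) col == t | col == "X"

.lookup_bond <- function(tab, t1, t2) {
  if (is.null(tab)) return(NA_integer_)
  i <- which((.tm(tab$t1, t1) & .tm(tab$t2, t2)) |
               (.tm(tab$t1, t2) & .tm(tab$t2, t1)))
  if (length(i)) i[1] else NA_integer_
}

.lookup_angle <- function(tab, t1, t2, t3) {
  if (is.null(tab)) return(NA_integer_)
  i <- which((.tm(tab$t1, t1) & .tm(tab$t2, t2) & .tm(tab$t3, t3)) |
               (.tm(tab$t1, t3) & .tm(tab$t2, t2) & .tm(tab$t3, t1)))
  if (length(i)) i[1] else NA_integer_
}

.lookup_dihedral <- function(tab, t1, t2, t3, t4) {
  if (is.null(tab)) return(integer(0))
  fwd <- (tab$t1 %in% c(t1, "X") & tab$t2 == t2 & tab$t3 == t3 &
            tab$t4 %in% c(t4, "X"))
  rev <- (tab$t1 %in% c(t4, "X") & tab$t2 == t3 & tab$t3 == t2 &
            tab$t4 %in% c(t1, "X"))
  which(fwd | rev)
}

# 1-2 and 1-3 pairs from the bond graph (1-4 kept at full strength)
exclusion_pairs <- function(sys) {
  ex <- rbind(sys$bonds, sys$ureys)
  if (!nrow(ex)) return(empty_bonds())
  normalize_bonds(ex)
}

#' MM energy and analytic gradient
#'
#' Harmonic bonds, angles and Urey-Bradley terms, cosine dihedrals,
#' 12-6 van der Waals in the epsilon/R_min form and Coulomb interactions
#' over a full double loop. 1-2 and 1-3 pairs are excluded from the
#' nonbonded sums; 1-4 pairs enter at full strength. Lennard-Jones
#' parameters come from the per-atom fields when set, otherwise from the
#' parameter table by atom type; combination rules are arithmetic in
#' R_min, geometric in epsilon.
#'
#' @param sys a `qmm_system` with `mm_type`/`mm_charge` set
#' @param params an `ff_params` object
#' @param include optional logical mask of atoms: only terms with ALL
#'   atoms inside the mask contribute (used to evaluate subsystems)
#' @param qm_mask optional logical mask marking QM atoms for the additive
#'   coupling convention: bonded terms fully inside the QM region and
#'   nonbonded pairs touching any QM atom are skipped (their physics is
#'   carried by the QM Hamiltonian, the embedding and the LJ coupling)
#' @param gradient compute the analytic gradient (default TRUE)
#' @return list: `breakdown` (E_bond, E_bend, E_tors, E_urey, E_vdW,
#'   E_QQ), `energy`, `gradient` (n x 3, hartree/bohr)
#' @export
mm_energy_gradient <- function(sys, params, include = NULL, qm_mask = NULL,
                               gradient = TRUE) {
  xyz <- positions(sys)
  n <- nrow(xyz)
  if (is.null(include)) include <- rep(TRUE, n)
  if (is.null(qm_mask)) qm_mask <- rep(FALSE, n)
  virt <- sys$atoms$Z == 0
  grad <- matrix(0, n, 3)
  Eb <- Ea <- Et <- Eu <- Ev <- Eq <- 0
  ty <- sys$atoms$mm_type
  term_ok <- function(idx) all(include[idx]) && !all(qm_mask[idx])

  # bonds
  if (nrow(sys$bonds)) for (r in seq_len(nrow(sys$bonds))) {
    i <- sys$bonds[r, 1]; j <- sys$bonds[r, 2]
    if (!term_ok(c(i, j))) next
    pi_ <- .lookup_bond(params$bonds, ty[i], ty[j])
    if (is.na(pi_)) stop("missing bond parameters for ", ty[i], "-", ty[j])
    d <- xyz[i, ] - xyz[j, ]; rlen <- sqrt(sum(d^2))
    k <- params$bonds$k[pi_]; r0 <- params$bonds$r0[pi_]
    Eb <- Eb + 0.5 * k * (rlen - r0)^2
    if (gradient) {
      g <- k * (rlen - r0) * d / rlen
      grad[i, ] <- grad[i, ] + g; grad[j, ] <- grad[j, ] - g
    }
  }
  # angles
  if (!is.null(sys$angles) && nrow(sys$angles)) for (r in seq_len(nrow(sys$angles))) {
    i <- sys$angles[r, 1]; j <- sys$angles[r, 2]; k2 <- sys$angles[r, 3]
    if (!term_ok(c(i, j, k2))) next
    pi_ <- .lookup_angle(params$angles, ty[i], ty[j], ty[k2])
    if (is.na(pi_)) stop("missing angle parameters for ",
                         ty[i], "-", ty[j], "-", ty[k2])
    kth <- params$angles$k[pi_]; th0 <- params$angles$theta0[pi_]
    rij <- xyz[i, ] - xyz[j, ]; rkj <- xyz[k2, ] - xyz[j, ]
    lij <- sqrt(sum(rij^2)); lkj <- sqrt(sum(rkj^2))
    cth <- sum(rij * rkj) / (lij * lkj)
    cth <- max(-1, min(1, cth))
    th <- acos(cth)
    Ea <- Ea + 0.5 * kth * (th - th0)^2
    if (gradient) {
      sth <- sqrt(max(1e-12, 1 - cth^2))
      dth <- kth * (th - th0)
      gi <- -dth / sth * (rkj / (lij * lkj) - cth * rij / lij^2)
      gk <- -dth / sth * (rij / (lij * lkj) - cth * rkj / lkj^2)
      grad[i, ] <- grad[i, ] + gi
      grad[k2, ] <- grad[k2, ] + gk
      grad[j, ] <- grad[j, ] - gi - gk
    }
    # Urey-Bradley 1-3 term keyed by the same triple
    pu <- .lookup_angle(params$ureys, ty[i], ty[j], ty[k2])
    if (!is.na(pu) && params$ureys$k[pu] > 0) {
      ku <- params$ureys$k[pu]; s0 <- params$ureys$s0[pu]
      d13 <- xyz[i, ] - xyz[k2, ]; s <- sqrt(sum(d13^2))
      Eu <- Eu + 0.5 * ku * (s - s0)^2
      if (gradient) {
        g <- ku * (s - s0) * d13 / s
        grad[i, ] <- grad[i, ] + g; grad[k2, ] <- grad[k2, ] - g
      }
    }
  }
  # dihedrals
  if (!is.null(sys$dihedrals) && nrow(sys$dihedrals))
    for (r in seq_len(nrow(sys$dihedrals))) {
      ii <- sys$dihedrals[r, ]
      if (!term_ok(ii)) next
      rows <- .lookup_dihedral(params$dihedrals, ty[ii[1]], ty[ii[2]],
                               ty[ii[3]], ty[ii[4]])
      if (!length(rows)) next  # unparameterized torsions contribute zero
      b1 <- xyz[ii[2], ] - xyz[ii[1], ]
      b2 <- xyz[ii[3], ] - xyz[ii[2], ]
      b3 <- xyz[ii[4], ] - xyz[ii[3], ]
      n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
              b1[1] * b2[2] - b1[2] * b2[1])
      n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
              b2[1] * b3[2] - b2[2] * b3[1])
      lb2 <- sqrt(sum(b2^2))
      phi <- atan2(sum((c(n1[2] * n2[3] - n1[3] * n2[2],
                          n1[3] * n2[1] - n1[1] * n2[3],
                          n1[1] * n2[2] - n1[2] * n2[1])) * b2) / lb2,
                   sum(n1 * n2))
      for (pr in rows) {
        V <- params$dihedrals$V[pr]; nn <- params$dihedrals$n[pr]
        dl <- params$dihedrals$delta[pr]
        Et <- Et + V * (1 + cos(nn * phi - dl))
        if (gradient) {
          dEdphi <- -V * nn * sin(nn * phi - dl)
          gi <- -dEdphi * lb2 / sum(n1^2) * n1
          gl <- dEdphi * lb2 / sum(n2^2) * n2
          s12 <- sum(b1 * b2) / lb2^2; s32 <- sum(b3 * b2) / lb2^2
          gj <- (s12 - 1) * gi - s32 * gl
          gk <- (s32 - 1) * gl - s12 * gi
          grad[ii[1], ] <- grad[ii[1], ] + gi
          grad[ii[2], ] <- grad[ii[2], ] + gj
          grad[ii[3], ] <- grad[ii[3], ] + gk
          grad[ii[4], ] <- grad[ii[4], ] + gl
        }
      }
    }
  # nonbonded (vectorized double loop over included non-QM atoms)
  sel <- which(include & !qm_mask)
  if (length(sel) > 1) {
    prs <- t(utils::combn(sel, 2))
    ex <- exclusion_pairs(sys)
    if (nrow(ex)) {
      keyp <- prs[, 1] * (n + 1) + prs[, 2]
      keye <- ex[, 1] * (n + 1) + ex[, 2]
      prs <- prs[!(keyp %in% keye), , drop = FALSE]
    }
    if (nrow(prs)) {
      qv <- sys$atoms$mm_charge
      epsv <- sys$atoms$lj_eps; rmv <- sys$atoms$lj_rmin
      if (!is.null(params$nonbonded)) {
        need <- which(epsv == 0 & !virt & !is.na(ty))
        mi <- match(ty[need], params$nonbonded$type)
        got <- !is.na(mi)
        epsv[need[got]] <- params$nonbonded$eps[mi[got]]
        rmv[need[got]] <- params$nonbonded$rmin[mi[got]]
      }
      dvec <- xyz[prs[, 1], , drop = FALSE] - xyz[prs[, 2], , drop = FALSE]
      r2 <- rowSums(dvec^2); rr <- sqrt(r2)
      qq <- qv[prs[, 1]] * qv[prs[, 2]]
      Eq <- sum(qq / rr)
      epsij <- sqrt(epsv[prs[, 1]] * epsv[prs[, 2]])
      rmij <- 0.5 * (rmv[prs[, 1]] + rmv[prs[, 2]])
      s6 <- ifelse(epsij > 0, (rmij / rr)^6, 0)
      Ev <- sum(epsij * (s6^2 - 2 * s6))
      if (gradient) {
        # dE/dr: Coulomb -qq/r^2 ; LJ -12 eps (s12 - s6)/r
        dEdr <- -qq / r2 - 12 * epsij * (s6^2 - s6) / rr
        gx <- dvec * (dEdr / rr)
        g1 <- rowsum(gx, prs[, 1])
        i1 <- as.integer(rownames(g1))
        grad[i1, ] <- grad[i1, ] + g1
        g2 <- rowsum(gx, prs[, 2])
        i2 <- as.integer(rownames(g2))
        grad[i2, ] <- grad[i2, ] - g2
      }
    }
  }
  breakdown <- c(E_bond = Eb, E_bend = Ea, E_tors = Et, E_urey = Eu,
                 E_vdW = Ev, E_QQ = Eq)
  list(breakdown = breakdown, energy = sum(breakdown),
       gradient = if (gradient) grad else NULL)
}

#' QM-MM Lennard-Jones coupling
#'
#' Pair sum over QM x MM atoms of eps_AD [(R_AD/r)^12 - 2 (R_AD/r)^6],
#' with R_AD the arithmetic and eps_AD the geometric combination of the
#' per-atom parameters. QM atoms must carry MM typing (their `lj_eps` and
#' `lj_rmin` fields). Pairs on the system's 1-2/1-3 exclusion list
#' (bonded across the QM/MM boundary) are skipped, as in the underlying
#' force field.
#'
#' @param sys a `qmm_system`
#' @param partition a `qmm_partition`
#' @return list: `energy`, `gradient` (n x 3 over all atoms)
#' @export
qm_mm_lj <- function(sys, partition) {
  qm <- partition$qm_indices; mm <- partition$mm_indices
  if (any(is.na(sys$atoms$mm_type[qm])))
    stop("qm_mm_lj: QM atom(s) without MM type assignment: ",
         paste(qm[is.na(sys$atoms$mm_type[qm])], collapse = ","))
  xyz <- positions(sys)
  n <- nrow(xyz)
  grad <- matrix(0, n, 3)
  E <- 0
  if (!length(mm)) return(list(energy = 0, gradient = grad))
  ex <- exclusion_pairs(sys)
  exkey <- if (nrow(ex)) ex[, 1] * (n + 1) + ex[, 2] else integer(0)
  for (a in qm) {
    keep <- !(pmin(a, mm) * (n + 1) + pmax(a, mm)) %in% exkey
    mmk <- mm[keep]
    if (!length(mmk)) next
    d <- xyz[mmk, , drop = FALSE] -
      matrix(xyz[a, ], length(mmk), 3, byrow = TRUE)
    rr <- sqrt(rowSums(d^2))
    eps <- sqrt(sys$atoms$lj_eps[a] * sys$atoms$lj_eps[mmk])
    rmin <- 0.5 * (sys$atoms$lj_rmin[a] + sys$atoms$lj_rmin[mmk])
    s6 <- ifelse(eps > 0, (rmin / rr)^6, 0)
    E <- E + sum(eps * (s6^2 - 2 * s6))
    dEdr <- -12 * eps * (s6^2 - s6) / rr
    g <- d * (dEdr / rr)
    grad[mmk, ] <- grad[mmk, ] + g
    grad[a, ] <- grad[a, ] - colSums(g)
  }
  list(energy = E, gradient = grad)
}

# ----------------------------------------------------------------- Drudes

#' Construct a Drude particle set
#'
#' Each Drude is a massless charge q' bound to a heavy (non-hydrogen)
#' anchor atom by a harmonic spring k_d; the anchor charge is offset by
#' -q' so the total charge is conserved. The induced polarizability is
#' alpha = q'^2 / k_d.
#'
#' @param anchors atom indices (heavy atoms)
#' @param q_prime Drude charges (e)
#' @param k_d spring constants (hartree/bohr^2)
#' @return a `drude_set`
#' @export
drude_set <- function(anchors, q_prime, k_d) {
  stopifnot(all(k_d > 0), length(anchors) == length(q_prime),
            length(anchors) == length(k_d))
  structure(list(anchors = as.integer(anchors), q_prime = q_prime,
                 k_d = k_d), class = "drude_set")
}

#' Electrostatic energy of a system with Drude particles
#'
#' Coulomb sums over real-real, real-Drude and Drude-Drude pairs plus the
#' oscillator self-energy sum of k_d d^2 / 2. Exclusions: real-real pairs
#' follow the system's 1-2/1-3 list; a Drude inherits its anchor's
#' exclusions and never interacts with its own anchor.
#'
#' @param sys a `qmm_system` (real atoms, charges in `mm_charge`)
#' @param drudes a `drude_set`
#' @param drude_xyz nd x 3 Drude positions (bohr)
#' @param efield optional uniform external field (hartree/(e bohr),
#'   3-vector) acting on all charges
#' @return list: `energy`, `self_energy`, `gradient_drude` (nd x 3)
#' @export
drude_energy <- function(sys, drudes, drude_xyz, efield = c(0, 0, 0)) {
  xyz <- positions(sys)
  n <- nrow(xyz); nd <- length(drudes$anchors)
  drude_xyz <- matrix(drude_xyz, nd, 3)
  q <- sys$atoms$mm_charge
  # anchor charges offset by -q' (charge conservation)
  qreal <- q; qreal[drudes$anchors] <- qreal[drudes$anchors] - drudes$q_prime
  ex <- exclusion_pairs(sys)
  exkey <- if (nrow(ex)) ex[, 1] * (n + 1) + ex[, 2] else integer(0)
  excluded <- function(i, j) {
    k <- min(i, j) * (n + 1) + max(i, j)
    k %in% exkey
  }
  E <- 0; gd <- matrix(0, nd, 3)
  # real-real
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (excluded(i, j)) next
    E <- E + qreal[i] * qreal[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  }
  # real-Drude (Drude inherits anchor exclusions; skip own anchor)
  for (a in seq_len(nd)) for (i in seq_len(n)) {
    anc <- drudes$anchors[a]
    if (i == anc || excluded(i, anc)) next
    d <- drude_xyz[a, ] - xyz[i, ]; r <- sqrt(sum(d^2))
    E <- E + drudes$q_prime[a] * qreal[i] / r
    gd[a, ] <- gd[a, ] - drudes$q_prime[a] * qreal[i] * d / r^3
  }
  # Drude-Drude
  if (nd > 1) for (a in 1:(nd - 1)) for (b in (a + 1):nd) {
    if (excluded(drudes$anchors[a], drudes$anchors[b]) ||
        drudes$anchors[a] == drudes$anchors[b]) next
    d <- drude_xyz[a, ] - drude_xyz[b, ]; r <- sqrt(sum(d^2))
    E <- E + drudes$q_prime[a] * drudes$q_prime[b] / r
    g <- -drudes$q_prime[a] * drudes$q_prime[b] * d / r^3
    gd[a, ] <- gd[a, ] + g; gd[b, ] <- gd[b, ] - g
  }
  # external field: -q E.r for Drudes and real atoms (real part constant
  # w.r.t. Drude positions; included for energy completeness)
  if (any(efield != 0)) {
    E <- E - sum(qreal * (xyz %*% efield))
    E <- E - sum(drudes$q_prime * (drude_xyz %*% efield))
    gd <- gd - outer(drudes$q_prime, efield)
  }
  # self energy
  disp <- drude_xyz - xyz[drudes$anchors, , drop = FALSE]
  Eself <- 0.5 * sum(drudes$k_d * rowSums(disp^2))
  gd <- gd + disp * drudes$k_d
  list(energy = E + Eself, self_energy = Eself, gradient_drude = gd)
}

#' Relax Drude particles at fixed real atoms
#'
#' Minimizes the Drude electrostatic + self energy with respect to the
#' Drude positions (replacing extended-Lagrangian propagation). BFGS on
#' the analytic gradient; convergence requires max |gradient| <= tol.
#'
#' @param sys,drudes,efield see [drude_energy()]
#' @param start starting Drude positions (default: on the anchors)
#' @param tol gradient tolerance (default 1e-8)
#' @return list: `drude_xyz`, `energy`, `iterations`
#' @export
relax_drudes <- function(sys, drudes, efield = c(0, 0, 0), start = NULL,
                         tol = 1e-8) {
  nd <- length(drudes$anchors)
  x0 <- if (is.null(start)) positions(sys)[drudes$anchors, , drop = FALSE]
        else matrix(start, nd, 3)
  fn <- function(v) drude_energy(sys, drudes, matrix(v, nd, 3),
                                 efield)$energy
  gr <- function(v) as.numeric(drude_energy(sys, drudes, matrix(v, nd, 3),
                                            efield)$gradient_drude)
  opt <- optim(as.numeric(x0), fn, gr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-16))
  g <- gr(opt$par)
  if (max(abs(g)) > tol) {
    # polish with a few Newton-like steps on the dominant spring term
    v <- opt$par
    for (it in 1:200) {
      g <- gr(v)
      if (max(abs(g)) <= tol) break
      v <- v - g / rep(drudes$k_d, 3)
    }
    opt$par <- v
    if (max(abs(g)) > tol)
      stop("relax_drudes: not converged, residual gradient ", max(abs(g)))
  }
  list(drude_xyz = matrix(opt$par, nd, 3), energy = fn(opt$par),
       iterations = opt$counts[1])
}
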