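# Born-Oppenheimer MD (velocity Verlet, optional Langevin thermostat),
# dual-topology free energy perturbation with exponential averaging and
# 3-block standard errors, and Hamiltonian replica exchange with the
# alternating odd/even neighbor schedule.

#' Construct an MD state
#'
#' @param xyz n x 3 positions (bohr)
#' @param masses_amu atomic masses (amu; converted to electron masses)
#' @param vel optional n x 3 velocities (bohr per a.u. time); default zero
#' @return an `md_state`
#' @export
md_state <- function(xyz, masses_amu, vel = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  stopifnot(all(is.finite(xyz)), all(masses_amu > 0),
            length(masses_amu) == nrow(xyz))
  if (is.null(vel)) vel <- matrix(0, nrow(xyz), 3)
  structure(list(xyz = xyz, vel = matrix(vel, ncol = 3),
                 mass = masses_amu * units_au$me_per_amu,
                 step = 0L, time_fs = 0), class = "md_state")
}

#' One velocity-Verlet step
#'
#' Deterministic symplectic update; forces from any energy/gradient
#' engine (a function of the coordinate matrix returning `energy` and
#' `gradient`).
#'
#' @param state an `md_state`
#' @param engine function(xyz) -> list(energy, gradient)
#' @param dt_fs time step in femtoseconds
#' @param force0 optional cached force at the current positions
#' @return updated `md_state` with attributes `energy` and `force`
#' @export
vv_step <- function(state, engine, dt_fs, force0 = NULL) {
  stopifnot(dt_fs > 0)
  dt <- dt_fs * units_au$aut_per_fs
  if (is.null(force0)) force0 <- -engine(state$xyz)$gradient
  vh <- state$vel + 0.5 * dt * force0 / state$mass
  xyz <- state$xyz + dt * vh
  eg <- engine(xyz)
  f1 <- -eg$gradient
  state$vel <- vh + 0.5 * dt * f1 / state$mass
  state$xyz <- xyz
  state$step <- state$step + 1L
  state$time_fs <- state$time_fs + dt_fs
  attr(state, "energy") <- eg$energy
  attr(state, "force") <- f1
  state
}

#' Run molecular dynamics
#'
#' Velocity Verlet, optionally with a Langevin thermostat in the BAOAB
#' splitting (kick - drift - Ornstein-Uhlenbeck - drift - kick). With
#' `thermostat = "none"` the propagation is NVE and time-reversible.
#'
#' @param state an `md_state`
#' @param engine function(xyz) -> list(energy, gradient)
#' @param n_steps number of steps
#' @param dt_fs time step (fs), default 1
#' @param thermostat `"none"` or `"langevin"`
#' @param temperature target temperature (K)
#' @param gamma_fs friction (fs^-1), default 0.1
#' @param seed RNG seed (fixed seed gives a bit-identical trajectory)
#' @param stride store every `stride`-th frame (default 10)
#' @param max_force abort threshold on |F| (hartree/bohr)
#' @return list: final `state`, `frames` (list of coordinate matrices),
#'   `log` data.frame (step, time_fs, potential, kinetic, temperature)
#' @export
run_md <- function(state, engine, n_steps, dt_fs = 1,
                   thermostat = c("none", "langevin"), temperature = 300,
                   gamma_fs = 0.1, seed = 1, stride = 10,
                   max_force = 10) {
  thermostat <- match.arg(thermostat)
  stopifnot(temperature >= 0)
  set.seed(seed)
  dt <- dt_fs * units_au$aut_per_fs
  kT <- units_au$kb * temperature
  n <- nrow(state$xyz)
  c1 <- exp(-gamma_fs * dt_fs)
  c2 <- sqrt((1 - c1^2) * kT)
  eg <- engine(state$xyz)
  f <- -eg$gradient
  frames <- list(); log <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    if (max(abs(f)) > max_force)
      stop("run_md: divergent force at step ", s, " (|F| = ",
           signif(max(abs(f)), 3), "); frame dumped in the error object")
    v <- state$vel + 0.5 * dt * f / state$mass
    x <- state$xyz + 0.5 * dt * v
    if (thermostat == "langevin")
      v <- c1 * v + c2 / sqrt(state$mass) * matrix(rnorm(3 * n), n, 3)
    x <- x + 0.5 * dt * v
    eg <- engine(x)
    f <- -eg$gradient
    state$vel <- v + 0.5 * dt * f / state$mass
    state$xyz <- x
    state$step <- state$step + 1L
    state$time_fs <- state$time_fs + dt_fs
    ke <- 0.5 * sum(state$mass * rowSums(state$vel^2))
    log[[s]] <- c(step = state$step, time_fs = state$time_fs,
                  potential = eg$energy, kinetic = ke,
                  temperature = 2 * ke / (3 * n * units_au$kb))
    if (s %% stride == 0) frames[[length(frames) + 1]] <- state$xyz
  }
  list(state = state, frames = frames,
       log = as.data.frame(do.call(rbind, log)))
}

#' Mix two endpoint Hamiltonians
#'
#' H(lambda) = lambda H_A + (1 - lambda) H_B; lambda = 1 is state A,
#' lambda = 0 is state B. Energies and gradients mix identically.
#'
#' @param lambda mixing parameter in [0, 1]
#' @param E_A,E_B endpoint energies (or gradients)
#' @return mixed value
#' @export
mixed_hamiltonian <- function(lambda, E_A, E_B) {
  if (lambda < 0 || lambda > 1) stop("mixed_hamiltonian: lambda outside [0,1]")
  lambda * E_A + (1 - lambda) * E_B
}

#' Dual-topology mixed engine
#'
#' Wraps two energy/gradient engines over a shared coordinate set into
#' the lambda-mixed Hamiltonian.
#'
#' @param engine_A,engine_B endpoint engines
#' @param lambda mixing parameter
#' @return an engine function
#' @export
dual_topology_engine <- function(engine_A, engine_B, lambda) {
  force(lambda)
  function(xyz) {
    a <- engine_A(xyz); b <- engine_B(xyz)
    list(energy = mixed_hamiltonian(lambda, a$energy, b$energy),
         gradient = mixed_hamiltonian(lambda, a$gradient, b$gradient))
  }
}

#' Free energy perturbation estimate
#'
#' Exponential averaging per window, Delta F_w = -kT ln <exp(-Delta U/kT)>,
#' with standard errors from block averaging (default 3 blocks) and the
#' total as the sum over windows.
#'
#' @param delta_u list over windows of Delta U samples (E_next - E_current,
#'   hartree, sampled in the current window)
#' @param kT thermal energy (hartree)
#' @param n_blocks blocks for the standard error (default 3)
#' @return a `fep_estimate`: data.frame `windows` (dF, se), `total`,
#'   `se_total` (hartree) and kcal/mol copies
#' @export
fep_estimate <- function(delta_u, kT, n_blocks = 3) {
  stopifnot(length(delta_u) >= 1)
  rows <- lapply(seq_along(delta_u), function(w) {
    du <- delta_u[[w]]
    if (!length(du)) stop("fep_estimate: empty window ", w)
    dF <- -kT * log(mean(exp(-du / kT)))
    blk <- split(du, cut(seq_along(du), n_blocks, labels = FALSE))
    bF <- vapply(blk, function(b) -kT * log(mean(exp(-b / kT))), 1.0)
    data.frame(window = w, dF = dF, se = sd(bF) / sqrt(length(bF)))
  })
  win <- do.call(rbind, rows)
  structure(list(windows = win, total = sum(win$dF),
                 se_total = sqrt(sum(win$se^2)),
                 total_kcal = sum(win$dF) * units_au$kcalmol_per_hartree,
                 kT = kT), class = "fep_estimate")
}

#' @export
print.fep_estimate <- function(x, ...) {
  cat(sprintf("<fep_estimate> dF = %.6f +/- %.6f hartree (%d windows)\n",
              x$total, x$se_total, nrow(x$windows)))
  invisible(x)
}

#' Harmonic alchemy FEP (closed-form benchmark)
#'
#' Dual-topology perturbation between two 1-D harmonic wells k_A -> k_B
#' at fixed temperature: windows interpolate k(lambda) = lambda k_A +
#' (1 - lambda) k_B, each window is sampled exactly from its Boltzmann
#' distribution, and forward/backward estimates are returned together
#' with the analytic result Delta F = (kT/2) ln(k_B/k_A).
#'
#' @param k_A,k_B endpoint force constants (a.u.)
#' @param kT thermal energy (default 1)
#' @param n_windows number of lambda windows (default 11)
#' @param n_samples samples per window
#' @param seed RNG seed
#' @return list: `forward`, `backward` (both `fep_estimate`), `exact`,
#'   `hysteresis` (forward + backward total, expected 0)
#' @export
fep_harmonic_alchemy <- function(k_A, k_B, kT = 1, n_windows = 11,
                                 n_samples = 1e5, seed = 1) {
  set.seed(seed)
  lam <- seq(1, 0, length.out = n_windows)  # state A -> state B
  kof <- function(l) mixed_hamiltonian(l, k_A, k_B)
  run_dir <- function(lams) {
    du <- vector("list", length(lams) - 1)
    for (w in seq_len(length(lams) - 1)) {
      kcur <- kof(lams[w]); knext <- kof(lams[w + 1])
      x <- rnorm(n_samples, 0, sqrt(kT / kcur))
      du[[w]] <- 0.5 * (knext - kcur) * x^2
    }
    fep_estimate(du, kT)
  }
  fwd <- run_dir(lam)
  bwd <- run_dir(rev(lam))
  list(forward = fwd, backward = bwd,
       exact = 0.5 * kT * log(k_B / k_A),
       hysteresis = fwd$total + bwd$total)
}

# ------------------------------------------------------------------ H-REMD

#' Construct a replica set
#'
#' Replicas are ordered along the parameter ladder so nearest neighbors
#' have the smallest parameter difference.
#'
#' @param states list of initial configurations
#' @param params numeric parameter ladder (e.g. lambda values), same
#'   length
#' @param U function(q, param) -> potential energy
#' @param beta inverse temperature 1/kT used in the exchange criterion
#' @return a `replica_set`
#' @export
replica_set <- function(states, params, U, beta = 1) {
  stopifnot(length(states) == length(params), length(states) >= 2)
  ord <- order(params)
  structure(list(states = states[ord], params = params[ord], U = U,
                 beta = beta,
                 log = data.frame(attempts = 0, accepts = 0)),
            class = "replica_set")
}

#' One sweep of neighbor exchange attempts
#'
#' Pairs follow the alternating schedule: phase `"odd"` attempts
#' 1-2, 3-4, ...; phase `"even"` attempts 2-3, 4-5, ... Acceptance is
#' Metropolis with exponent beta [U_i(q_j) + U_j(q_i) - U_i(q_i) -
#' U_j(q_j)]; on acceptance the configurations of the pair are swapped.
#'
#' @param reps a `replica_set`
#' @param phase `"odd"` or `"even"`
#' @return updated `replica_set` (exchange log accumulated)
#' @export
hremd_attempt <- function(reps, phase = c("odd", "even")) {
  phase <- match.arg(phase)
  n <- length(reps$states)
  if (n < 2) stop("hremd_attempt: need at least 2 replicas")
  first <- if (phase == "odd") 1 else 2
  if (first > n - 1) return(reps)  # even phase with 2 replicas: no pairs
  i <- seq(first, n - 1, by = 2)
  for (ii in i) {
    jj <- ii + 1
    qi <- reps$states[[ii]]; qj <- reps$states[[jj]]
    d <- reps$U(qj, reps$params[ii]) + reps$U(qi, reps$params[jj]) -
      reps$U(qi, reps$params[ii]) - reps$U(qj, reps$params[jj])
    p <- min(1, exp(-reps$beta * d))
    reps$log$attempts <- reps$log$attempts + 1
    if (runif(1) < p) {
      reps$states[[ii]] <- qj; reps$states[[jj]] <- qi
      reps$log$accepts <- reps$log$accepts + 1
    }
  }
  reps
}

#' Run H-REMD over a Monte Carlo propagator
#'
#' Alternates `n_prop` local Monte Carlo moves per replica with one
#' exchange sweep, the phase alternating odd/even between sweeps.
#'
#' @param reps a `replica_set`
#' @param mc_move function(q, param) -> new q (local sampler at the
#'   replica's parameter)
#' @param n_sweeps number of exchange sweeps
#' @param n_prop MC moves between sweeps (default 1)
#' @param seed RNG seed
#' @return list: final `reps`, `samples` (list per replica slot of
#'   configuration traces), acceptance rate
#' @export
hremd_run <- function(reps, mc_move, n_sweeps, n_prop = 1, seed = 1) {
  set.seed(seed)
  nr <- length(reps$states)
  samples <- replicate(nr, vector("list", n_sweeps), simplify = FALSE)
  phase <- "odd"
  for (s in seq_len(n_sweeps)) {
    for (r in seq_len(nr))
      for (p in seq_len(n_prop))
        reps$states[[r]] <- mc_move(reps$states[[r]], reps$params[r])
    reps <- hremd_attempt(reps, phase)
    phase <- if (phase == "odd") "even" else "odd"
    for (r in seq_len(nr)) samples[[r]][[s]] <- reps$states[[r]]
  }
  list(reps = reps, samples = samples,
       acceptance = reps$log$accepts / max(1, reps$log$attempts))
}

#' MM energy/gradient engine for MD
#'
#' Bundles the force field (and optional FIRES restraint and QM-MM LJ
#' coupling additions) into an engine closure over the coordinate matrix.
#'
#' @param sys a `qmm_system`
#' @param ff an `ff_params`
#' @param fires optional `fires_state`
#' @return function(xyz) -> list(energy, gradient)
#' @export
mm_engine <- function(sys, ff, fires = NULL) {
  function(xyz) {
    s <- set_positions(sys, xyz)
    r <- mm_energy_gradient(s, ff)
    if (!is.null(fires)) {
      fr <- fires_energy_gradient(fires, xyz)
      r$energy <- r$energy + fr$energy
      r$gradient <- r$gradient + fr$gradient
    }
    list(energy = r$energy, gradient = r$gradient)
  }
}
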