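#' Ground-state sampling of initial conditions
#'
#' Frames for excited-state trajectories are drawn from a ground-state
#' thermal ensemble: the full system (chromophore plus charge bath) is
#' propagated with Langevin dynamics on the lowest adiabatic surface and
#' snapshots are recorded at fixed strides, emulating equilibrium sampling
#' of a solvated chromophore before vertical excitation.
#'
#' @param spec an [oracle_spec()]
#' @param bath a [bath_spec()]
#' @param n number of frames to return (>= 1)
#' @param temperature target temperature (K), must be positive
#' @param seed integer seed; the ensemble is deterministic given the seed
#' @param dt Langevin time step (fs)
#' @param burn_in equilibration steps before the first snapshot
#' @param stride steps between recorded snapshots
#' @return list of [system_frame()] objects of length `n`
#' @export
sample_initial_conditions <- function(spec, bath, n, temperature, seed = 1L,
                                      dt = 0.5, burn_in = 100L, stride = 20L) {
  stopifnot(inherits(spec, "oracle_spec"), inherits(bath, "bath_spec"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(fh_seed(seed, "sampling"))

  frame <- reference_frame(spec, bath, seed)
  nml <- spec$n_ml_atoms
  nmm <- nrow(frame$mm_positions)
  # steepest-descent relaxation of the freshly placed bath: removes the
  # condensation energy a random placement would otherwise dump into the
  # thermostatted dynamics
  if (nmm > 0) {
    for (it in 1:150) {
      lab <- oracle_labels(spec, bath, frame)
      f_mm <- matrix(lab$forces_mm[1, , ], nmm, 3) + lab$lj$f_mm +
        lab$mm_coul$f_mm
      fmax <- max(abs(f_mm))
      if (fmax < 0.02) break
      step <- pmin(0.05 / fmax, 0.02)
      frame$mm_positions <- frame$mm_positions + step * f_mm
    }
  }
  kT <- fh_const$kB_ev * temperature
  # thermal velocity scale per coordinate: 0.5 m v^2 / acc_conv = 0.5 kT
  sig_ml <- sqrt(kT * fh_const$acc_conv / frame$masses)
  sig_mm <- if (nmm > 0) sqrt(kT * fh_const$acc_conv / frame$mm_masses) else numeric(0)
  frame$ml_velocities <- matrix(stats::rnorm(3 * nml), nml, 3) * sig_ml
  if (nmm > 0)
    frame$mm_velocities <- matrix(stats::rnorm(3 * nmm), nmm, 3) * sig_mm

  gamma <- bath$friction / 1000  # ps^-1 -> fs^-1
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(1 - c1^2)

  forces <- function(fr) {
    lab <- oracle_labels(spec, bath, fr)
    list(
      ml = matrix(lab$forces_ml[1, , ], nml, 3) + lab$lj$f_ml,
      mm = if (nmm > 0)
        matrix(lab$forces_mm[1, , ], nmm, 3) + lab$lj$f_mm + lab$mm_coul$f_mm
      else matrix(0.0, 0, 3))
  }
  f <- forces(frame)
  acc <- fh_const$acc_conv
  out <- vector("list", n)
  taken <- 0L
  total_steps <- burn_in + n * stride
  for (step in seq_len(total_steps)) {
    # BAOAB: half kick, half drift, thermostat, half drift, half kick
    frame$ml_velocities <- frame$ml_velocities + 0.5 * dt * acc * f$ml / frame$masses
    if (nmm > 0)
      frame$mm_velocities <- frame$mm_velocities + 0.5 * dt * acc * f$mm / frame$mm_masses
    frame$ml_positions <- frame$ml_positions + 0.5 * dt * frame$ml_velocities
    if (nmm > 0)
      frame$mm_positions <- frame$mm_positions + 0.5 * dt * frame$mm_velocities
    frame$ml_velocities <- c1 * frame$ml_velocities +
      c2 * matrix(stats::rnorm(3 * nml), nml, 3) * sig_ml
    if (nmm > 0)
      frame$mm_velocities <- c1 * frame$mm_velocities +
        c2 * matrix(stats::rnorm(3 * nmm), nmm, 3) * sig_mm
    frame$ml_positions <- frame$ml_positions + 0.5 * dt * frame$ml_velocities
    if (nmm > 0)
      frame$mm_positions <- frame$mm_positions + 0.5 * dt * frame$mm_velocities
    f <- forces(frame)
    frame$ml_velocities <- frame$ml_velocities + 0.5 * dt * acc * f$ml / frame$masses
    if (nmm > 0)
      frame$mm_velocities <- frame$mm_velocities + 0.5 * dt * acc * f$mm / frame$mm_masses
    if (step == burn_in ||
        (step > burn_in && (step - burn_in) %% stride == 0L)) {
      # Andersen-style full velocity resampling: recorded frames carry exact
      # Maxwell-Boltzmann velocities and successive snapshots decorrelate,
      # independent of how slowly the bath dissipates association energy
      frame$ml_velocities <- matrix(stats::rnorm(3 * nml), nml, 3) * sig_ml
      if (nmm > 0)
        frame$mm_velocities <- matrix(stats::rnorm(3 * nmm), nmm, 3) * sig_mm
      if (step > burn_in) {
        taken <- taken + 1L
        out[[taken]] <- frame
        if (taken == n) break
      }
    }
  }
  out
}

#' Stochastic selection of the initially excited state
#'
#' For each frame, the states whose excitation energy (energy above the
#' frame's ground state) falls inside the window are candidates; one is
#' drawn with probability proportional to its oscillator strength.  Frames
#' with no in-window state (or only dark in-window states) return `NA`.
#'
#' @param energies n_frames x n_states matrix of per-state energies (eV);
#'   excitation energies are taken relative to column 1
#' @param osc_strengths matrix of the same shape, non-negative oscillator
#'   strengths (column 1 is ignored)
#' @param window numeric pair `c(lower, upper)` in eV, lower < upper
#' @param seed integer seed
#' @return integer vector of selected 1-based state indices, `NA` where no
#'   selection was possible
#' @export
select_initial_states <- function(energies, osc_strengths, window, seed = 1L) {
  energies <- as.matrix(energies)
  osc_strengths <- as.matrix(osc_strengths)
  stopifnot(all(dim(energies) == dim(osc_strengths)),
            length(window) == 2L)
  if (window[1] >= window[2]) stop("window lower bound must be below upper")
  if (any(osc_strengths < 0)) stop("oscillator strengths must be non-negative")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(fh_seed(seed, "state_selection"))
  nf <- nrow(energies); ns <- ncol(energies)
  out <- rep(NA_integer_, nf)
  for (i in seq_len(nf)) {
    exc <- energies[i, ] - energies[i, 1]
    cand <- which(exc > window[1] & exc < window[2] & seq_len(ns) > 1L)
    cand <- cand[osc_strengths[i, cand] > 0]
    if (length(cand) == 0L) next
    w <- osc_strengths[i, cand]
    out[i] <- if (length(cand) == 1L) cand else
      sample(cand, 1L, prob = w / sum(w))
  }
  out
}
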