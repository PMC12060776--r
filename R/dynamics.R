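#' Fewest-switches surface hopping
#'
#' Mixed quantum-classical dynamics: nuclei follow Newton's equations on one
#' adiabatic surface (velocity Verlet), electronic coefficients follow the
#' time-dependent Schroedinger equation in the adiabatic basis (unitary
#' exponential-midpoint integrator on an interpolated Hamiltonian), and
#' stochastic hops between surfaces are drawn from the fewest-switches
#' probabilities.  Couplings come either from exact analytic nonadiabatic
#' coupling vectors (oracle potentials) or from the curvature-driven
#' surrogate built from the second time derivative of the energy gaps,
#' which needs energies only and therefore also works with learned
#' potentials.
#'
#' @name dynamics
NULL

#' Surface-hopping run configuration
#'
#' @param dt_nuclear nuclear time step (fs)
#' @param dt_electronic electronic sub-step (fs); must divide `dt_nuclear`
#' @param horizon total propagation time (fs)
#' @param forced_hop_gap S1/S0 gap (eV) below which a hop to the ground
#'   state is forced
#' @param allow_back_from_ground allow upward hops out of the ground state
#' @param coupling_scheme "exact_nac" or "curvature"
#' @param seed integer RNG seed for the hopping random numbers
#' @param blowup_ev total-energy drift (eV) beyond which a trajectory is
#'   truncated and flagged
#' @return an object of class `tsh_config`
#' @export
tsh_config <- function(dt_nuclear = 0.5, dt_electronic = 0.025, horizon = 330,
                       forced_hop_gap = 0.1, allow_back_from_ground = FALSE,
                       coupling_scheme = c("curvature", "exact_nac"),
                       seed = 1L, blowup_ev = 5) {
  coupling_scheme <- match.arg(coupling_scheme)
  stopifnot(dt_nuclear > 0, dt_electronic > 0, horizon >= 0,
            forced_hop_gap > 0, blowup_ev > 0)
  n_sub <- dt_nuclear / dt_electronic
  if (abs(n_sub - round(n_sub)) > 1e-9)
    stop("dt_electronic must divide dt_nuclear")
  structure(list(dt_nuclear = dt_nuclear, dt_electronic = dt_electronic,
                 horizon = horizon, forced_hop_gap = forced_hop_gap,
                 allow_back_from_ground = allow_back_from_ground,
                 coupling_scheme = coupling_scheme, seed = as.integer(seed),
                 n_substeps = as.integer(round(n_sub)), blowup_ev = blowup_ev),
            class = "tsh_config")
}

#' Dynamical state of one surface-hopping trajectory
#'
#' @param frame a [system_frame()] with velocities
#' @param active_state 1-based index of the active adiabatic state
#' @param n_states number of electronic states
#' @param coefficients complex coefficient vector (default: pure active
#'   state); must have unit norm
#' @param time current time (fs)
#' @return an object of class `tsh_state`
#' @export
tsh_state <- function(frame, active_state, n_states, coefficients = NULL,
                      time = 0) {
  stopifnot(inherits(frame, "system_frame"),
            active_state >= 1L, active_state <= n_states)
  if (is.null(coefficients)) {
    coefficients <- complex(n_states)
    coefficients[active_state] <- 1 + 0i
  }
  nrm <- sum(Mod(coefficients)^2)
  if (abs(nrm - 1) > 1e-8) stop("coefficients must have unit norm")
  structure(list(frame = frame, active_state = as.integer(active_state),
                 n_states = as.integer(n_states),
                 coefficients = coefficients, time = time,
                 energy_history = NULL, cache = NULL, reached_ground = FALSE),
            class = "tsh_state")
}

#' Oracle-backed potential interface for the dynamics engine
#'
#' Wraps an analytic oracle so the propagator can ask for per-state
#' embedded energies and forces, the classical bath terms, and (exactly)
#' the nonadiabatic coupling matrix elements.
#'
#' @param spec an [oracle_spec()]
#' @param bath a [bath_spec()]
#' @return an object of class `fh_potential`
#' @export
oracle_potential <- function(spec, bath) {
  force(spec); force(bath)
  evalfun <- function(frame, need_nac = FALSE, prev_vectors = NULL) {
    lab <- oracle_labels(spec, bath, frame, prev_vectors)
    nml <- spec$n_ml_atoms; ns <- spec$n_states
    out <- list(
      energies = lab$energies,
      forces_ml = lab$forces_ml,
      forces_mm = lab$forces_mm,
      bath_f_ml = lab$lj$f_ml,
      bath_f_mm = lab$lj$f_mm + lab$mm_coul$f_mm,
      bath_energy = lab$lj$energy + lab$mm_coul$energy,
      vectors = lab$vectors, labels = lab)
    if (need_nac) {
      derivs <- diabatic_derivatives(spec, frame$ml_positions)
      nac <- vector("list", ns * ns)
      dim(nac) <- c(ns, ns)
      for (k in seq_len(ns - 1L)) for (l in (k + 1L):ns) {
        gap <- lab$energies[l] - lab$energies[k]
        if (abs(gap) <= 1e-8) { nac[[k, l]] <- NULL; next }
        g <- sandwich_gradient(derivs, lab$vectors, k, l)
        wt <- lab$vectors[, k] * lab$vectors[, l]
        if (!is.null(lab$jac) && nrow(frame$mm_positions) > 0) {
          for (i in seq_len(nml)) {
            de <- numeric(3)
            for (a in seq_len(ns)) de <- de + wt[a] * derivs$dH_deps[a, i, ]
            g[i, ] <- g[i, ] + as.numeric(de %*% lab$jac$d_field_d_ml[i, , ])
          }
        }
        nac[[k, l]] <- g / gap
        nac[[l, k]] <- -g / gap
      }
      out$nac <- nac
    }
    out
  }
  structure(list(n_states = spec$n_states, has_nac = TRUE,
                 eval = evalfun, spec = spec, bath = bath),
            class = "fh_potential")
}

#' Coupling matrix v . d from exact coupling vectors
#' @noRd
nac_coupling_matrix <- function(nac, velocities, n_states) {
  Tm <- matrix(0.0, n_states, n_states)
  for (k in seq_len(n_states - 1L)) for (l in (k + 1L):n_states) {
    d <- nac[[k, l]]
    if (is.null(d)) next
    Tm[k, l] <- sum(velocities * d)
    Tm[l, k] <- -Tm[k, l]
  }
  Tm
}

#' Curvature-driven coupling magnitudes
#'
#' Baeck-An style surrogate for the scalar coupling |v . d_kl| built from
#' the second time derivative of the adiabatic gaps:
#' `sigma_kl = 0.5 * sqrt(gapddot / gap)` where
#' `gapddot = (g(t - dt) - 2 g(t) + g(t + dt)) / dt^2` is the exact
#' three-point stencil on the gap `g = |E_k - E_l|` and the gap is taken at
#' the central point.  A negative argument (no curvature-driven transition)
#' clamps the coupling to zero.
#'
#' @param energy_history 3 x n_states matrix of per-state energies at three
#'   consecutive, uniformly spaced times (oldest row first)
#' @param dt spacing of the history (fs)
#' @return symmetric-in-magnitude coupling matrix (fs^-1): entry `[k, l]`
#'   is `+sigma` for k < l and `-sigma` for k > l, zero diagonal
#' @export
curvature_coupling <- function(energy_history, dt) {
  if (!is.matrix(energy_history) || nrow(energy_history) != 3L)
    stop("energy_history must be a 3 x n_states matrix (uniform spacing)")
  stopifnot(dt > 0)
  ns <- ncol(energy_history)
  Tm <- matrix(0.0, ns, ns)
  for (k in seq_len(ns - 1L)) for (l in (k + 1L):ns) {
    g <- abs(energy_history[, k] - energy_history[, l])
    gap <- g[2]
    gdd <- (g[1] - 2 * g[2] + g[3]) / dt^2
    arg <- if (gap > 0) gdd / gap else 0
    sig <- if (arg > 0) 0.5 * sqrt(arg) else 0
    Tm[k, l] <- sig
    Tm[l, k] <- -sig
  }
  Tm
}

#' Unitary electronic propagation across one nuclear step
#'
#' Integrates the coefficient equation i hbar dc/dt = (diag(E) - i hbar T) c
#' with `n_substeps` exponential-midpoint steps, interpolating the energies
#' linearly between the two ends of the nuclear step and holding the
#' coupling matrix fixed.  Each substep propagator is the exact exponential
#' of an anti-Hermitian generator, so the norm is conserved to rounding.
#'
#' @param coefficients complex vector, unit norm on entry
#' @param energies_t,energies_tdt per-state energies (eV) at the start and
#'   end of the nuclear step
#' @param couplings real antisymmetric coupling matrix T (fs^-1)
#' @param dt_nuclear nuclear step (fs)
#' @param n_substeps number of electronic substeps
#' @return complex coefficient vector at t + dt
#' @export
electronic_step <- function(coefficients, energies_t, energies_tdt, couplings,
                            dt_nuclear, n_substeps) {
  ns <- length(coefficients)
  stopifnot(length(energies_t) == ns, length(energies_tdt) == ns,
            all(dim(couplings) == c(ns, ns)))
  nrm0 <- sum(Mod(coefficients)^2)
  if (abs(nrm0 - 1) > 1e-6)
    stop("electronic coefficients lost unit norm before propagation")
  hbar <- fh_const$hbar_ev_fs
  tau <- dt_nuclear / n_substeps
  c_vec <- coefficients
  dE <- energies_tdt - energies_t
  if (ns == 2L) {
    # closed-form 2x2 propagator via the Pauli decomposition
    w <- couplings[1, 2]
    for (s in seq_len(n_substeps)) {
      Em <- energies_t + dE * (s - 0.5) / n_substeps
      c0 <- (Em[1] + Em[2]) / 2
      mz <- (Em[1] - Em[2]) / 2
      mx <- 0; my <- -(-hbar * w)  # b = -i hbar w = mx - i my
      mm <- sqrt(mx^2 + my^2 + mz^2)
      ph <- exp(-1i * c0 * tau / hbar)
      if (mm == 0) { c_vec <- ph * c_vec; next }
      th <- mm * tau / hbar
      ct <- cos(th); st <- sin(th)
      nx <- mx / mm; ny <- my / mm; nz <- mz / mm
      U <- matrix(c(ct - 1i * st * nz, -1i * st * (nx + 1i * ny),
                    -1i * st * (nx - 1i * ny), ct + 1i * st * nz), 2, 2)
      c_vec <- ph * (U %*% c_vec)[, 1]
    }
  } else {
    for (s in seq_len(n_substeps)) {
      Em <- energies_t + dE * (s - 0.5) / n_substeps
      Hm <- diag(Em) - 1i * hbar * couplings
      e <- eigen(Hm)  # Hermitian by construction
      U <- e$vectors %*% diag(exp(-1i * Re(e$values) * tau / hbar)) %*%
        Conj(t(e$vectors))
      c_vec <- (U %*% c_vec)[, 1]
    }
  }
  nrm <- sum(Mod(c_vec)^2)
  if (abs(nrm - 1) > 1e-6)
    stop("electronic integrator norm drift beyond 1e-6")
  c_vec
}

#' Fewest-switches hop probabilities out of the active state
#'
#' P(active -> m) = max(0, 2 T_am Re(c_a* c_m) dt / |c_a|^2): the fraction
#' of the active-state population that flowed to state m over the nuclear
#' step, clipped at zero when the net flux is into the active state.
#'
#' @param coefficients complex coefficient vector
#' @param couplings antisymmetric coupling matrix T (fs^-1)
#' @param active 1-based active state index
#' @param dt nuclear time step (fs)
#' @return numeric vector of probabilities (zero at the active position)
#' @export
hop_probabilities <- function(coefficients, couplings, active, dt) {
  ns <- length(coefficients)
  pop_a <- Mod(coefficients[active])^2
  if (pop_a < 1e-12)
    stop("active-state population below 1e-12: probabilities undefined")
  p <- numeric(ns)
  for (m in seq_len(ns)) {
    if (m == active) next
    flux <- 2 * couplings[active, m] *
      Re(Conj(coefficients[active]) * coefficients[m])
    p[m] <- max(0, flux * dt / pop_a)
  }
  pmin(p, 1)
}

#' Draw a hop target from the fewest-switches probabilities
#'
#' A single uniform random number xi selects a target by the cumulative-
#' interval rule; if xi falls beyond the total hop probability no hop is
#' proposed.  Uses (and advances) the current RNG stream.
#'
#' @param probabilities vector from [hop_probabilities()]
#' @return 1-based target index, or `NA` for no hop
#' @export
attempt_hop <- function(probabilities) {
  if (any(probabilities < 0)) stop("negative hop probability")
  tot <- sum(probabilities)
  if (tot > 1 + 1e-9) stop("hop probabilities sum beyond 1")
  xi <- stats::runif(1)
  cum <- cumsum(probabilities)
  hit <- which(xi < cum)
  if (length(hit) == 0L) NA_integer_ else hit[1]
}

#' Execute (or frustrate) a surface hop
#'
#' On acceptance the ML-atom velocities are rescaled by a uniform factor so
#' that the ML kinetic energy absorbs exactly the potential-energy change
#' (total energy conserved); bath velocities are untouched.  If the ML
#' kinetic energy cannot cover an uphill gap the hop is frustrated: the
#' state is unchanged and a frustrated event is recorded.
#'
#' @param state a [tsh_state()] with a cached potential evaluation
#' @param target 1-based target state (different from the active state)
#' @param kind event label: "stochastic" or "forced"
#' @return list with `state` (possibly updated) and `event` (a one-row
#'   data.frame: time, from, to, kind)
#' @export
execute_hop <- function(state, target, kind = "stochastic") {
  stopifnot(inherits(state, "tsh_state"), target != state$active_state)
  cache <- state$cache
  if (is.null(cache)) stop("state has no cached potential evaluation")
  from <- state$active_state
  dE <- cache$energies[target] - cache$energies[from]
  ke_ml <- kinetic_energy(state$frame, "ml")
  accepted <- ke_ml >= dE && ke_ml > 0
  if (accepted) {
    scale <- sqrt(1 - dE / ke_ml)
    state$frame$ml_velocities <- state$frame$ml_velocities * scale
    state$active_state <- as.integer(target)
    if (target == 1L) state$reached_ground <- TRUE
  }
  event <- data.frame(time = state$time, from = from,
                      to = if (accepted) as.integer(target) else from,
                      kind = if (accepted) kind else "frustrated",
                      stringsAsFactors = FALSE)
  list(state = state, event = event, accepted = accepted)
}

#' Forced ground-state channel
#'
#' When the active state is the first excited state and its gap to the
#' ground state falls below `forced_hop_gap`, a hop to the ground state is
#' executed with the same velocity-rescaling rules (it is downhill, so it is
#' always accepted), mirroring the treatment of intersection regions that
#' the reference electronic structure cannot describe.
#'
#' @param state a [tsh_state()] with cached energies
#' @param cfg a [tsh_config()]
#' @return list with `state` and `event` (NULL when no action taken)
#' @export
forced_ground_state_check <- function(state, cfg) {
  if (state$active_state != 2L) return(list(state = state, event = NULL))
  gap <- state$cache$energies[2] - state$cache$energies[1]
  if (gap >= cfg$forced_hop_gap) return(list(state = state, event = NULL))
  res <- execute_hop(state, 1L, kind = "forced")
  list(state = res$state, event = res$event)
}

#' Advance the nuclei by one velocity-Verlet step
#'
#' Propagates ML atoms and bath sites on the active adiabatic surface
#' (embedded state forces plus classical bath forces) and refreshes the
#' cached potential evaluation at the new geometry.
#'
#' @param state a [tsh_state()]
#' @param potential an `fh_potential`
#' @param cfg a [tsh_config()]
#' @return the advanced [tsh_state()]
#' @export
nuclear_step <- function(state, potential, cfg) {
  if (is.null(state$cache))
    state$cache <- potential$eval(state$frame,
                                  need_nac = cfg$coupling_scheme == "exact_nac")
  dt <- cfg$dt_nuclear
  acc <- fh_const$acc_conv
  fr <- state$frame
  k <- state$active_state
  nml <- nrow(fr$ml_positions); nmm <- nrow(fr$mm_positions)
  f_ml <- matrix(state$cache$forces_ml[k, , ], nml, 3) + state$cache$bath_f_ml
  a_ml <- acc * f_ml / fr$masses
  fr$ml_positions <- fr$ml_positions + dt * fr$ml_velocities + 0.5 * dt^2 * a_ml
  if (nmm > 0) {
    f_mm <- matrix(state$cache$forces_mm[k, , ], nmm, 3) + state$cache$bath_f_mm
    a_mm <- acc * f_mm / fr$mm_masses
    fr$mm_positions <- fr$mm_positions + dt * fr$mm_velocities + 0.5 * dt^2 * a_mm
  }
  new_cache <- potential$eval(fr, need_nac = cfg$coupling_scheme == "exact_nac",
                              prev_vectors = state$cache$vectors)
  f_ml_new <- matrix(new_cache$forces_ml[k, , ], nml, 3) + new_cache$bath_f_ml
  fr$ml_velocities <- fr$ml_velocities +
    0.5 * dt * (a_ml + acc * f_ml_new / fr$masses)
  if (nmm > 0) {
    f_mm_new <- matrix(new_cache$forces_mm[k, , ], nmm, 3) + new_cache$bath_f_mm
    fr$mm_velocities <- fr$mm_velocities +
      0.5 * dt * (a_mm + acc * f_mm_new / fr$mm_masses)
  }
  state$prev_cache <- state$cache
  state$frame <- fr
  state$cache <- new_cache
  state$time <- state$time + dt
  state
}

#' Run one surface-hopping trajectory
#'
#' Per nuclear step: velocity-Verlet propagation on the active surface,
#' electronic substeps on the interpolated Hamiltonian, a stochastic
#' fewest-switches hop attempt, then the forced ground-state check (last,
#' so the small-gap rule is never preempted).  Records per-step energies,
#' active state, coefficient populations and total energy, plus a hop-event
#' table with the ML geometry at every event.  Bit-reproducible for a fixed
#' seed and potential.
#'
#' @param frame initial [system_frame()] (with velocities)
#' @param initial_state 1-based initial adiabatic state
#' @param potential an `fh_potential`
#' @param cfg a [tsh_config()]
#' @param keep_labels also store the full per-step labels (oracle
#'   potentials only); used when archiving reference datasets
#' @return an object of class `fh_trajectory`: list with `steps`
#'   (data.frame: time, active, total_energy, norm), `energies` and
#'   `populations` (matrices, one row per step), `hops` (data.frame),
#'   `hop_geometries` (list of ML coordinate matrices), `truncated`,
#'   `n_states`, `dt`, `seed`
#' @export
run_trajectory <- function(frame, initial_state, potential, cfg,
                           keep_labels = FALSE) {
  stopifnot(inherits(cfg, "tsh_config"), inherits(potential, "fh_potential"))
  if (cfg$coupling_scheme == "exact_nac" && !isTRUE(potential$has_nac))
    stop("potential does not provide exact nonadiabatic couplings")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(fh_seed(cfg$seed, "tsh_rng"))
  ns <- potential$n_states
  state <- tsh_state(frame, initial_state, ns)
  state$cache <- potential$eval(frame,
                                need_nac = cfg$coupling_scheme == "exact_nac")
  n_steps <- as.integer(round(cfg$horizon / cfg$dt_nuclear))
  nml <- nrow(frame$ml_positions)

  times <- numeric(n_steps + 1L)
  actives <- integer(n_steps + 1L)
  etot <- numeric(n_steps + 1L)
  norms <- numeric(n_steps + 1L)
  energies <- matrix(0.0, n_steps + 1L, ns)
  pops <- matrix(0.0, n_steps + 1L, ns)
  hops <- list()
  hop_geoms <- list()
  labels <- if (keep_labels) vector("list", n_steps + 1L) else NULL
  truncated <- FALSE

  total_energy <- function(st) {
    st$cache$energies[st$active_state] + st$cache$bath_energy +
      kinetic_energy(st$frame, "all")
  }
  record <- function(i, st) {
    times[i] <<- st$time
    actives[i] <<- st$active_state
    energies[i, ] <<- st$cache$energies
    pops[i, ] <<- Mod(st$coefficients)^2
    etot[i] <<- total_energy(st)
    norms[i] <<- sum(Mod(st$coefficients)^2)
    if (keep_labels) {
      lab <- st$cache$labels
      if (is.null(lab)) stop("keep_labels requires a label-producing potential")
      labels[[i]] <<- lab
    }
  }
  push_event <- function(ev, st) {
    hops[[length(hops) + 1L]] <<- ev
    hop_geoms[[length(hop_geoms) + 1L]] <<- st$frame$ml_positions
  }
  record(1L, state)
  e_ref <- etot[1]
  hist <- matrix(state$cache$energies, 1L, ns)

  if (n_steps > 0) for (step in seq_len(n_steps)) {
    e_prev <- state$cache$energies
    state <- nuclear_step(state, potential, cfg)
    e_now <- state$cache$energies
    hist <- rbind(hist, matrix(e_now, 1L, ns))
    if (nrow(hist) > 3L) hist <- hist[(nrow(hist) - 2L):nrow(hist), , drop = FALSE]

    Tm <- if (cfg$coupling_scheme == "exact_nac") {
      nac_coupling_matrix(state$cache$nac, state$frame$ml_velocities, ns)
    } else if (nrow(hist) == 3L) {
      curvature_coupling(hist, cfg$dt_nuclear)
    } else matrix(0.0, ns, ns)

    state$coefficients <- electronic_step(state$coefficients, e_prev, e_now,
                                          Tm, cfg$dt_nuclear, cfg$n_substeps)

    block_up <- state$active_state == 1L && state$reached_ground &&
      !cfg$allow_back_from_ground
    if (!block_up && Mod(state$coefficients[state$active_state])^2 >= 1e-12) {
      p <- hop_probabilities(state$coefficients, Tm, state$active_state,
                             cfg$dt_nuclear)
      if (state$active_state == 1L && !cfg$allow_back_from_ground)
        p[] <- 0
      target <- attempt_hop(p)
      if (!is.na(target)) {
        res <- execute_hop(state, target, kind = "stochastic")
        state <- res$state
        push_event(res$event, state)
      }
    } else {
      # consume one random number regardless, keeping streams comparable
      invisible(stats::runif(1))
    }
    fg <- forced_ground_state_check(state, cfg)
    if (!is.null(fg$event)) {
      state <- fg$state
      push_event(fg$event, state)
    }
    record(step + 1L, state)
    if (!all(is.finite(etot[step + 1L])) ||
        abs(etot[step + 1L] - e_ref) > cfg$blowup_ev) {
      truncated <- TRUE
      times <- times[seq_len(step + 1L)]
      actives <- actives[seq_len(step + 1L)]
      etot <- etot[seq_len(step + 1L)]
      norms <- norms[seq_len(step + 1L)]
      energies <- energies[seq_len(step + 1L), , drop = FALSE]
      pops <- pops[seq_len(step + 1L), , drop = FALSE]
      if (keep_labels) labels <- labels[seq_len(step + 1L)]
      break
    }
  }
  structure(list(
    labels = labels,
    steps = data.frame(time = times, active = actives,
                       total_energy = etot, norm = norms),
    energies = energies, populations = pops,
    hops = if (length(hops)) do.call(rbind, hops) else
      data.frame(time = numeric(0), from = integer(0), to = integer(0),
                 kind = character(0)),
    hop_geometries = hop_geoms, truncated = truncated,
    n_states = ns, dt = cfg$dt_nuclear, seed = cfg$seed),
    class = "fh_trajectory")
}
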