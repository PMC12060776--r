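# Shared fixtures and independent oracles for the test suite.

# Small three-atom, three-state oracle with nonzero couplings and dipoles;
# deterministic construction.
make_test_spec <- function(n_states = 3L) {
  elements <- c(8L, 6L, 1L)
  geom <- matrix(c(0, 0, 0,
                   1.2, 0, 0,
                   1.8, 0.9, 0), 3, 3, byrow = TRUE)
  minima <- array(0.0, c(n_states, 3L, 3L))
  fc <- matrix(0.0, n_states, 3L)
  for (k in seq_len(n_states)) {
    g <- geom
    g[2, 1] <- g[2, 1] + 0.08 * (k - 1)   # stretch the O-C bond per state
    minima[k, , ] <- g
    fc[k, ] <- c(25, 25, 18) * (1 - 0.05 * (k - 1))
  }
  coup <- matrix(0.0, n_states, n_states)
  for (k in seq_len(n_states)) for (l in seq_len(n_states))
    if (abs(k - l) == 1) coup[k, l] <- 0.08
  dip <- array(0.0, c(n_states, 3L, 3L))
  for (k in seq_len(n_states))
    dip[k, , ] <- 0.04 * k * matrix(c(1, 0, 0.3, -1, 0.2, 0, 0, -0.5, 0.1),
                                    3, 3, byrow = TRUE)
  tdip <- array(0.0, c(n_states, n_states, 3))
  for (k in 2:n_states) {
    tdip[1, k, ] <- c(0.3, 0.1, 0) / k
    tdip[k, 1, ] <- tdip[1, k, ]
  }
  oracle_spec(n_states, elements, diabatic_minima = minima,
              force_constants = fc, vertical_shifts = (seq_len(n_states) - 1) * 2.5,
              diabatic_couplings = coup, state_dipoles = dip,
              transition_dipoles = tdip)
}

# A thermally jittered frame of a spec in a charge bath.
jittered_frame <- function(spec, bath, seed = 1L, sd = 0.04) {
  fr <- reference_frame(spec, bath, seed = seed)
  set.seed(seed + 1000L)
  fr$ml_positions <- fr$ml_positions +
    matrix(rnorm(3 * spec$n_ml_atoms, sd = sd), spec$n_ml_atoms, 3)
  fr
}

# Central finite differences of a scalar function of an n x 3 matrix.
fd_gradient <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_len(nrow(x))) for (a in 1:3) {
    x1 <- x; x1[i, a] <- x1[i, a] + h
    x0 <- x; x0[i, a] <- x0[i, a] - h
    g[i, a] <- (f(x1) - f(x0)) / (2 * h)
  }
  g
}

# Total potential energy of a frame on one adiabatic surface (for force
# finite differences).
oracle_total_energy <- function(spec, bath, frame, k) {
  l <- oracle_labels(spec, bath, frame)
  l$energies[k] + l$lj$energy + l$mm_coul$energy
}

# Build an archive from a list of labelled frames treated as one
# "trajectory" with unit time spacing (training fixtures).
archive_from_labels <- function(labs, n_states, traj_id = 1L) {
  arch <- archive_new(n_states)
  rec <- list(steps = data.frame(time = seq_along(labs) - 1,
                                 active = 1L),
              truncated = FALSE)
  archive_append(arch, labs, rec, traj_id)
}

# Labelled thermal dataset of the field-coupled two-state diatomic.
diatomic_dataset <- function(n, seed = 11L, field_dipole = 0.3,
                             n_charges = 8L, temperature = 300) {
  spec <- two_state_spec(field_dipole = field_dipole)
  bath <- bath_spec(n_charges)
  ics <- sample_initial_conditions(spec, bath, n, temperature, seed = seed,
                                   burn_in = 50L, stride = 5L)
  labs <- lapply(ics, function(f) oracle_labels(spec, bath, f))
  list(spec = spec, bath = bath,
       archive = archive_from_labels(labs, 2L))
}

# Independent minimal FSSH reference for the 1D two-state diatomic: fine
# time step, direct ODE integration of the coefficients, plain R.  Shares
# no code with the package's engine.
reference_fssh_1d <- function(spec, bond0, dt = 0.05, horizon = 30,
                              seed = 1L) {
  set.seed(seed)
  kap <- spec$pair_kappa[, 1, 2]
  r0 <- spec$pair_r0[, 1, 2]
  c12 <- spec$diabatic_couplings[1, 2]
  mu_red <- prod(spec$masses) / sum(spec$masses)
  acc_c <- fieldhop::fh_const$acc_conv
  hbar <- fieldhop::fh_const$hbar_ev_fs
  adi <- function(r) {
    H <- matrix(c(0.5 * kap[1] * (r - r0[1])^2, c12,
                  c12, 0.5 * kap[2] * (r - r0[2])^2), 2, 2)
    e <- eigen(H, symmetric = TRUE)
    ord <- order(e$values)
    list(E = e$values[ord], U = e$vectors[, ord])
  }
  # analytic d12 along the bond coordinate for the 2x2 diabatic model
  nac <- function(r, a) {
    dH <- diag(c(kap[1] * (r - r0[1]), kap[2] * (r - r0[2])))
    num <- as.numeric(t(a$U[, 1]) %*% dH %*% a$U[, 2])
    num / (a$E[2] - a$E[1])
  }
  r <- bond0; v <- 0
  active <- 2L
  cc <- c(0 + 0i, 1 + 0i)
  a <- adi(r)
  prevU <- a$U
  forceon <- function(a, r, st) {
    dH <- diag(c(kap[1] * (r - r0[1]), kap[2] * (r - r0[2])))
    -as.numeric(t(a$U[, st]) %*% dH %*% a$U[, st])
  }
  f <- forceon(a, r, active)
  nstep <- round(horizon / dt)
  for (s in seq_len(nstep)) {
    acc <- acc_c * f / mu_red
    r <- r + v * dt + 0.5 * acc * dt^2
    a2 <- adi(r)
    for (k in 1:2) if (sum(a2$U[, k] * prevU[, k]) < 0) a2$U[, k] <- -a2$U[, k]
    prevU <- a2$U
    f2 <- forceon(a2, r, active)
    v <- v + 0.5 * (acc + acc_c * f2 / mu_red) * dt
    a <- a2; f <- f2
    d12 <- nac(r, a)
    Tm <- v * d12
    # one exact substep (dt is already fine)
    Hm <- matrix(c(a$E[1], 1i * hbar * Tm, -1i * hbar * Tm, a$E[2]), 2, 2)
    ee <- eigen(Hm)
    U <- ee$vectors %*% diag(exp(-1i * Re(ee$values) * dt / hbar)) %*%
      Conj(t(ee$vectors))
    cc <- as.vector(U %*% cc)
    other <- 3L - active
    flux <- 2 * (if (active == 1L) Tm else -Tm) *
      Re(Conj(cc[active]) * cc[other])
    p <- max(0, flux * dt / Mod(cc[active])^2)
    if (stats::runif(1) < p) {
      dE <- a$E[other] - a$E[active]
      ke <- 0.5 * mu_red * v^2 / acc_c
      if (ke >= dE) {
        v <- v * sqrt(1 - dE / ke)
        active <- other
        f <- forceon(a, r, active)
      }
    }
  }
  active
}

# Synthetic Markov-hop trajectory records with exact sequential-decay rates
# (for kinetic-fit coverage tests); mimics the fh_trajectory contract.
markov_records <- function(n_traj, tau21, tau10, dt = 0.5, horizon = 330,
                           seed = 1L) {
  set.seed(seed)
  nstep <- round(horizon / dt)
  lapply(seq_len(n_traj), function(i) {
    s <- 3L
    active <- integer(nstep + 1L)
    active[1] <- s
    for (j in seq_len(nstep)) {
      if (s == 3L && runif(1) < dt / tau21) s <- 2L
      else if (s == 2L && runif(1) < dt / tau10) s <- 1L
      active[j + 1L] <- s
    }
    structure(list(steps = data.frame(time = (0:nstep) * dt, active = active,
                                      total_energy = 0, norm = 1),
                   energies = matrix(0, nstep + 1L, 3),
                   populations = matrix(0, nstep + 1L, 3),
                   hops = data.frame(), hop_geometries = list(),
                   truncated = FALSE, n_states = 3L, dt = dt, seed = i),
              class = "fh_trajectory")
  })
}
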