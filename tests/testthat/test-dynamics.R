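# Surface-hopping engine: integrators, couplings, hopping rules,
# trajectories.

test_that("nuclear step: statics, harmonic period, and reversibility", {
  # zero coupling so the adiabats coincide with the harmonic diabats
  spec <- two_state_spec(coupling = 0)
  bath <- bath_spec(0L)
  pot <- oracle_potential(spec, bath)
  cfg <- tsh_config(horizon = 50, coupling_scheme = "curvature", seed = 1)
  # at the state-1 minimum with zero velocity, positions stay put
  st0 <- tsh_state(diatomic_frame(spec, 1.2), 1L, 2L)
  st1 <- nuclear_step(st0, pot, cfg)
  expect_equal(st1$frame$ml_positions, st0$frame$ml_positions,
               tolerance = 1e-12)
  # small-amplitude bond oscillation: period 2*pi*sqrt(mu/k_eff)
  st <- tsh_state(diatomic_frame(spec, 1.26), 1L, 2L)
  bonds <- numeric(400)
  for (s in 1:400) {
    st <- nuclear_step(st, pot, cfg)
    bonds[s] <- sqrt(sum((st$frame$ml_positions[1, ] -
                            st$frame$ml_positions[2, ])^2))
  }
  # period from successive maxima of the bond length
  pk <- which(diff(sign(diff(bonds))) < 0) + 1L
  period <- mean(diff(pk)) * cfg$dt_nuclear
  mu_red <- prod(spec$masses) / sum(spec$masses)
  k_eff <- spec$pair_kappa[1, 1, 2]
  period_exact <- 2 * pi * sqrt(mu_red / (k_eff * fh_const$acc_conv))
  expect_lt(abs(period - period_exact) / period_exact, 0.001)
  # velocity Verlet is time reversible
  st_a <- tsh_state(diatomic_frame(spec, 1.3), 1L, 2L)
  st_a$frame$ml_velocities <- matrix(c(0.01, 0, 0, -0.01, 0, 0), 2, 3,
                                     byrow = TRUE)
  st_b <- nuclear_step(st_a, pot, cfg)
  st_b$frame$ml_velocities <- -st_b$frame$ml_velocities
  st_b$cache <- NULL
  st_c <- nuclear_step(st_b, pot, cfg)
  expect_equal(st_c$frame$ml_positions, st_a$frame$ml_positions,
               tolerance = 1e-10)
  expect_equal(-st_c$frame$ml_velocities, st_a$frame$ml_velocities,
               tolerance = 1e-10)
})

test_that("electronic propagation: phase-only limit, Rabi solution, and a
           fine-step refinement oracle", {
  hbar <- fh_const$hbar_ev_fs
  # zero couplings, flat energies: populations frozen
  cc <- sqrt(c(0.5, 0.3, 0.2)) * exp(1i * c(0.1, -0.4, 2))
  out <- electronic_step(cc, c(0, 1, 2), c(0, 1, 2), matrix(0, 3, 3), 0.5, 20)
  expect_equal(Mod(out)^2, Mod(cc)^2, tolerance = 1e-12)
  # two-level constant coupling: closed-form Rabi populations
  E <- c(0, 0.5); V <- 0.05
  Tm <- matrix(c(0, V / hbar, -V / hbar, 0), 2, 2)
  cc <- c(1 + 0i, 0i)
  p2 <- numeric(120)
  for (s in 1:120) {
    cc <- electronic_step(cc, E, E, Tm, 0.5, 20)
    p2[s] <- Mod(cc[2])^2
  }
  t <- (1:120) * 0.5
  Delta <- (E[2] - E[1]) / 2
  Om <- sqrt(Delta^2 + V^2)
  expect_lt(max(abs(p2 - V^2 / Om^2 * sin(Om * t / hbar)^2)), 1e-6)
  # time-dependent 3-level H: coarse substeps vs dt/100 reference
  set.seed(44)
  E0 <- sort(runif(3, 0, 2)); E1 <- E0 + rnorm(3, sd = 0.1)
  W <- matrix(rnorm(9, sd = 0.05), 3, 3); W <- W - t(W)
  cc0 <- c(1 + 0i, 0, 0)
  c_coarse <- cc0; c_fine <- cc0
  for (s in 1:20) {
    Ea <- E0 + (E1 - E0) * (s - 1) / 20
    Eb <- E0 + (E1 - E0) * s / 20
    c_coarse <- electronic_step(c_coarse, Ea, Eb, W, 0.5, 20)
    c_fine <- electronic_step(c_fine, Ea, Eb, W, 0.5, 2000)
  }
  expect_lt(max(Mod(c_coarse - c_fine)), 1e-6)
  expect_equal(sum(Mod(c_coarse)^2), 1, tolerance = 1e-10)
})

test_that("curvature couplings: stencil, clamping, and input checks", {
  # constant gap in time -> zero coupling
  eh <- rbind(c(0, 1), c(0.2, 1.2), c(0.1, 1.1))
  expect_equal(max(abs(curvature_coupling(eh, 0.5))), 0)
  # widening parabolic gap (negative curvature argument) clamps to zero
  g <- c(1.0, 1.3, 1.2)  # gap curvature (1.0 - 2*1.3 + 1.2) < 0
  eh2 <- cbind(0, g)
  expect_equal(max(abs(curvature_coupling(eh2, 0.5))), 0)
  # narrowing gap: sigma = 0.5 sqrt(gapddot / gap) at the central point
  g3 <- c(1.0, 0.6, 1.0)
  eh3 <- cbind(0, g3)
  gdd <- (g3[1] - 2 * g3[2] + g3[3]) / 0.25
  expect_equal(curvature_coupling(eh3, 0.5)[1, 2], 0.5 * sqrt(gdd / 0.6))
  expect_equal(curvature_coupling(eh3, 0.5)[2, 1], -0.5 * sqrt(gdd / 0.6))
  expect_error(curvature_coupling(eh3[1:2, ], 0.5), "3 x n_states")
})

test_that("fewest-switches probabilities: clipping, bounds, and empirical
           hop frequencies over many draws", {
  cc <- c(sqrt(0.7) + 0i, sqrt(0.2) + 0i, sqrt(0.1) + 0i)
  # zero couplings: all zero
  expect_equal(hop_probabilities(cc, matrix(0, 3, 3), 1L, 0.5), rep(0, 3))
  # flux into the active state clips to zero
  Tm <- matrix(0, 3, 3)
  Tm[1, 2] <- -0.3; Tm[2, 1] <- 0.3  # inflow from 2 into 1
  p <- hop_probabilities(cc, Tm, 1L, 0.5)
  expect_equal(p, rep(0, 3))
  # outflow gives the textbook expression
  Tm2 <- matrix(0, 3, 3)
  Tm2[1, 2] <- 0.3; Tm2[2, 1] <- -0.3
  Tm2[1, 3] <- 0.05; Tm2[3, 1] <- -0.05
  p2 <- hop_probabilities(cc, Tm2, 1L, 0.5)
  expect_equal(p2[2], 2 * 0.3 * sqrt(0.7) * sqrt(0.2) * 0.5 / 0.7)
  expect_true(all(p2 >= 0 & p2 <= 1))
  expect_error(hop_probabilities(c(0 + 0i, 1 + 0i), matrix(0, 2, 2), 1L, 0.5),
               "population")
  # attempt_hop: degenerate cases and long-run frequencies
  expect_true(is.na(attempt_hop(c(0, 0, 0))))
  expect_equal(attempt_hop(c(0, 1, 0)), 2L)
  expect_error(attempt_hop(c(0.8, 0.8, 0)), "sum")
  probs <- c(0, 0.12, 0.05)
  set.seed(99)
  draws <- replicate(1e5, attempt_hop(probs))
  for (m in 2:3) {
    p_hat <- mean(!is.na(draws) & draws == m)
    se <- sqrt(probs[m] * (1 - probs[m]) / 1e5)
    expect_lt(abs(p_hat - probs[m]), 3 * se)
  }
  expect_equal(mean(is.na(draws)), 1 - sum(probs), tolerance = 3 * sqrt(0.17 * 0.83 / 1e5))
})

test_that("hop execution conserves total energy, frustrates uphill hops
           without kinetic energy, and rescales only ML velocities", {
  spec <- make_test_spec()
  bath <- bath_spec(8L)
  pot <- oracle_potential(spec, bath)
  fr <- jittered_frame(spec, bath, seed = 3)
  set.seed(10)
  fr$ml_velocities <- matrix(rnorm(9, sd = 0.02), 3, 3)
  fr$mm_velocities <- matrix(rnorm(bath$n_charges * 3, sd = 0.005),
                             bath$n_charges, 3)
  st <- tsh_state(fr, 2L, 3L)
  st$cache <- pot$eval(fr)
  e_before <- st$cache$energies[2] + kinetic_energy(fr, "all")
  # downhill hop 2 -> 1 always accepted; speeds increase by the exact factor
  res <- execute_hop(st, 1L)
  expect_true(res$accepted)
  expect_equal(res$event$kind, "stochastic")
  expect_equal(res$event$from, 2L)
  dE <- st$cache$energies[1] - st$cache$energies[2]
  ke <- kinetic_energy(fr, "ml")
  expect_equal(res$state$frame$ml_velocities,
               fr$ml_velocities * sqrt(1 - dE / ke), tolerance = 1e-12)
  expect_identical(res$state$frame$mm_velocities, fr$mm_velocities)
  e_after <- st$cache$energies[1] + kinetic_energy(res$state$frame, "all")
  expect_lt(abs(e_after - e_before), 1e-8)
  # uphill hop with insufficient ML kinetic energy is frustrated
  slow <- fr
  slow$ml_velocities <- matrix(1e-4, 3, 3)
  st2 <- tsh_state(slow, 1L, 3L)
  st2$cache <- pot$eval(slow)
  res2 <- execute_hop(st2, 3L)
  expect_false(res2$accepted)
  expect_equal(res2$event$kind, "frustrated")
  expect_equal(res2$state$active_state, 1L)
  expect_identical(res2$state$frame$ml_velocities, slow$ml_velocities)
})

test_that("forced ground-state channel fires exactly below the gap
           threshold", {
  # small-coupling diatomic: minimum gap 2 * 0.03 = 0.06 eV < 0.1 eV
  spec <- two_state_spec(coupling = 0.03)
  pot <- oracle_potential(spec, bath_spec(0L))
  cfg <- tsh_config(forced_hop_gap = 0.1, horizon = 1)
  # frame near the diabatic crossing: gap below threshold
  fr_seam <- diatomic_frame(spec, 1.6)
  fr_seam$ml_velocities <- matrix(c(0.05, 0, 0, -0.05, 0, 0), 2, 3,
                                  byrow = TRUE)
  st <- tsh_state(fr_seam, 2L, 2L)
  st$cache <- pot$eval(fr_seam)
  expect_lt(st$cache$energies[2] - st$cache$energies[1], 0.1)
  out <- forced_ground_state_check(st, cfg)
  expect_equal(out$event$kind, "forced")
  expect_equal(out$state$active_state, 1L)
  # away from the seam (gap 0.2 eV or more): no action
  fr_far <- diatomic_frame(spec, 1.35)
  st2 <- tsh_state(fr_far, 2L, 2L)
  st2$cache <- pot$eval(fr_far)
  expect_gt(st2$cache$energies[2] - st2$cache$energies[1], 0.1)
  out2 <- forced_ground_state_check(st2, cfg)
  expect_null(out2$event)
  # not applicable when the active state is not the first excited state
  st3 <- tsh_state(fr_seam, 1L, 2L)
  st3$cache <- pot$eval(fr_seam)
  expect_null(forced_ground_state_check(st3, cfg)$event)
})

test_that("trajectories: zero horizon, determinism, NVE drift, norm", {
  spec <- make_test_spec()
  bath <- bath_spec(8L)
  pot <- oracle_potential(spec, bath)
  ic <- sample_initial_conditions(spec, bath, 1, 300, seed = 3,
                                  burn_in = 30L, stride = 5L)[[1]]
  # horizon 0: a single recorded entry
  r0 <- run_trajectory(ic, 1L, pot, tsh_config(horizon = 0, seed = 1))
  expect_equal(nrow(r0$steps), 1L)
  # same seed, same potential: identical records
  cfg <- tsh_config(horizon = 20, coupling_scheme = "exact_nac", seed = 7)
  ra <- run_trajectory(ic, 3L, pot, cfg)
  rb <- run_trajectory(ic, 3L, pot, cfg)
  expect_identical(ra$steps, rb$steps)
  expect_identical(ra$hops, rb$hops)
  # NVE contract on the ground state over 300 fs: < 2 meV per 100 fs, and
  # the electronic norm is conserved per step
  cfgN <- tsh_config(horizon = 300, coupling_scheme = "curvature", seed = 2)
  rn <- run_trajectory(ic, 1L, pot, cfgN)
  drift <- max(abs(rn$steps$total_energy - rn$steps$total_energy[1]))
  expect_lt(drift, 0.002 * 3)
  expect_lt(max(abs(rn$steps$norm - 1)), 1e-8)
  expect_false(rn$truncated)
})

test_that("every sub-threshold S1/S0 gap coincides with a forced hop and
           no back transitions occur after reaching the ground state", {
  spec <- two_state_spec(coupling = 0.03)
  pot <- oracle_potential(spec, bath_spec(0L))
  n_forced <- 0L
  for (i in 1:20) {
    set.seed(500 + i)
    fr <- diatomic_frame(spec, 1.2 + rnorm(1, sd = 0.03))
    cfg <- tsh_config(horizon = 25, coupling_scheme = "exact_nac",
                      seed = 131 + i)
    rec <- run_trajectory(fr, 2L, pot, cfg)
    gaps <- rec$energies[, 2] - rec$energies[, 1]
    active <- rec$steps$active
    # whenever the active state is S1 and the *recorded* gap is below the
    # threshold, the forced channel must already have fired at that step
    viol <- which(active == 2L & gaps < cfg$forced_hop_gap)
    expect_length(viol, 0)
    n_forced <- n_forced + sum(rec$hops$kind == "forced")
    # once in the ground state, the active state never goes back up
    t_g <- which(active == 1L)
    if (length(t_g)) expect_true(all(active[min(t_g):length(active)] == 1L))
  }
  expect_gt(n_forced, 0L)
})

test_that("curvature-driven ensembles reproduce exact-coupling final
           populations on the avoided-crossing model", {
  spec <- two_state_spec()
  pot <- oracle_potential(spec, bath_spec(0L))
  run_ens <- function(n, scheme) {
    final <- integer(n)
    for (i in seq_len(n)) {
      set.seed(1000 + i)
      fr <- diatomic_frame(spec, 1.2 + rnorm(1, sd = 0.03))
      cfg <- tsh_config(horizon = 30, coupling_scheme = scheme,
                        seed = 37 * i + 1)
      rec <- run_trajectory(fr, 2L, pot, cfg)
      final[i] <- rec$steps$active[nrow(rec$steps)]
    }
    mean(final == 1L)
  }
  p_exact <- run_ens(150, "exact_nac")
  p_curv <- run_ens(150, "curvature")
  expect_lt(abs(p_exact - p_curv), 0.1)
})

test_that("single-passage hop statistics agree with an independent
           fine-timestep reference implementation", {
  spec <- two_state_spec()
  pot <- oracle_potential(spec, bath_spec(0L))
  n <- 150
  final <- integer(n)
  for (i in seq_len(n)) {
    fr <- diatomic_frame(spec, 1.2)
    cfg <- tsh_config(dt_nuclear = 0.05, dt_electronic = 0.0025,
                      horizon = 5, coupling_scheme = "exact_nac",
                      seed = 37 * i + 1)
    final[i] <- utils::tail(run_trajectory(fr, 2L, pot, cfg)$steps$active, 1)
  }
  p_pkg <- mean(final == 1L)
  ref <- vapply(seq_len(n), function(i)
    reference_fssh_1d(spec, 1.2, dt = 0.01, horizon = 5, seed = 7000 + i), 0L)
  p_ref <- mean(ref == 1L)
  se <- sqrt(p_pkg * (1 - p_pkg) / n + p_ref * (1 - p_ref) / n)
  expect_lt(abs(p_pkg - p_ref), 3 * max(se, 0.02))
})

test_that("a learned potential plugs into the engine and run records stay
           reproducible", {
  # train on excited-state reference dynamics so the learned surface covers
  # the region the trajectory will visit
  spec <- two_state_spec(field_dipole = 0.2)
  bath <- bath_spec(6L)
  ref <- generate_reference_dataset(spec, bath, n_traj = 4, horizon_fs = 15,
                                    seed = 61, coupling_scheme = "curvature",
                                    initial_state = 2L)
  arch <- ref$archive
  nfr <- archive_size(arch)
  set.seed(1); idx <- sample(nfr)
  mc <- model_config(cutoff = 6, n_radial_basis = 14L, n_states = 2L)
  fit <- train_potential(arch,
                         list(train = idx[1:round(0.8 * nfr)],
                              validation = idx[(round(0.8 * nfr) + 1):nfr]),
                         mc, train_config(lr0 = 2e-2, max_epochs = 300L,
                                          seed = 4))
  ds <- list(spec = spec, bath = bath)
  pot_ml <- model_potential(fit, ds$bath)
  expect_false(pot_ml$has_nac)
  expect_error(tsh_config(coupling_scheme = "exact_nac", horizon = 5) |>
                 (\(cfg) run_trajectory(reference_frame(ds$spec, ds$bath, 1),
                                        2L, pot_ml, cfg))(),
               "exact nonadiabatic couplings|provide")
  ic <- sample_initial_conditions(ds$spec, ds$bath, 1, 300, seed = 3,
                                  burn_in = 20L, stride = 5L)[[1]]
  cfg <- tsh_config(horizon = 10, coupling_scheme = "curvature", seed = 11)
  r1 <- run_trajectory(ic, 2L, pot_ml, cfg)
  r2 <- run_trajectory(ic, 2L, pot_ml, cfg)
  expect_identical(r1$steps, r2$steps)
  expect_false(r1$truncated)
})
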