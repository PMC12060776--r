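# Evaluation toolkit: splits, weighted errors, populations, kinetics,
# spectra, geometry analysis.

# a light-weight fake archive with metadata only (splits never touch frames)
fake_archive <- function(n_traj, frames_per_traj) {
  meta <- do.call(rbind, lapply(seq_len(n_traj), function(i)
    data.frame(trajectory_id = i, time = (seq_len(frames_per_traj) - 1) * 0.5,
               frame_idx = seq_len(frames_per_traj) - 1L, active_state = 1L)))
  structure(list(frames = vector("list", nrow(meta)), meta = meta,
                 n_states = 3L, schema_version = 1L),
            class = "fh_archive")
}

test_that("splits are disjoint, exhaustive, stride-aware, and reproduce the
           46 -> 37/5/4 trajectory allocation", {
  arch <- fake_archive(46L, 661L)
  s <- make_split(arch, split_spec("by_trajectory", seed = 3))
  tr <- s$manifest$trajectories
  expect_length(tr$train, 37L)
  expect_length(tr$validation, 5L)
  expect_length(tr$test, 4L)
  expect_length(intersect(tr$train, tr$test), 0L)
  all_idx <- sort(c(s$train, s$validation, s$test))
  expect_equal(all_idx, seq_len(46L * 661L))
  # stride 3 on a 661-frame trajectory keeps frames 0, 3, ..., 660 -> 221
  s3 <- make_split(arch, split_spec("by_trajectory", stride = 3L, seed = 3))
  expect_equal(s3$manifest$retained, 46L * 221L)
  per_traj <- table(arch$meta$trajectory_id[c(s3$train, s3$validation,
                                              s3$test)])
  expect_true(all(per_traj == 221L))
  # random split: frame-level disjoint and exhaustive over retained frames
  sr <- make_split(arch, split_spec("random", stride = 2L, seed = 5))
  got <- c(sr$train, sr$validation, sr$test)
  expect_equal(length(got), length(unique(got)))
  expect_equal(sort(got), which(arch$meta$frame_idx %% 2L == 0L))
  # determinism
  sr2 <- make_split(arch, split_spec("random", stride = 2L, seed = 5))
  expect_identical(sr$train, sr2$train)
  expect_error(make_split(arch, split_spec("by_trajectory",
                                           counts = c(40, 5, 4))),
               "do not match")
})

test_that("gap-weighted RMSE: uniform-gap reduction, monotonicity, and a
           literal two-loop reference", {
  set.seed(17)
  err <- matrix(rnorm(60), 20, 3)
  # uniform gaps: equals the plain RMSE exactly
  E_unif <- cbind(0, 1, 2)[rep(1, 20), ]
  gw <- gap_weighted_rmse(err, E_unif)
  expect_equal(gw$per_state, sqrt(colMeans(err^2)), tolerance = 1e-14)
  # two frames with equal errors, one at a 10x smaller gap: the weighted
  # result exceeds the plain RMSE of the small-gap state
  err2 <- matrix(c(1, 1, 0.2, 0.2, 0.1, 0.1), 2, 3)
  E2 <- rbind(c(0, 1.0, 2), c(0, 0.1, 2))
  gw2 <- gap_weighted_rmse(err2, E2)
  expect_gte(gw2$per_state[2], sqrt(mean(err2[, 2]^2)))
  # literal reference with explicit loops
  E <- cbind(0, runif(20, 0.5, 2), runif(20, 2.5, 4))
  gw3 <- gap_weighted_rmse(err, E, delta = 1e-3)
  ref <- numeric(3)
  for (j in 1:3) {
    num <- 0; den <- 0
    for (i in 1:20) {
      gaps <- c()
      if (j > 1) gaps <- c(gaps, abs(E[i, j] - E[i, j - 1]))
      if (j < 3) gaps <- c(gaps, abs(E[i, j + 1] - E[i, j]))
      w <- 1 / (min(gaps) + 1e-3)
      num <- num + w * err[i, j]^2
      den <- den + w
    }
    ref[j] <- sqrt(num / den)
  }
  expect_equal(gw3$per_state, ref, tolerance = 1e-12)
  expect_error(gap_weighted_rmse(err[, 1, drop = FALSE],
                                 E[, 1, drop = FALSE]), "two states")
})

test_that("populations: trivial ensembles, step functions, truncation
           handling, and Markov-rate consistency", {
  recs <- markov_records(1, tau21 = 1e9, tau10 = 1e9, horizon = 10, seed = 1)
  recs[[1]]$steps$active <- rep(1L, nrow(recs[[1]]$steps))
  grid <- seq(0, 10, by = 1)
  p <- populations(recs, grid)
  expect_equal(p[, 1], rep(1, length(grid)))
  # a single hop at t = 5 produces a step function
  r1 <- recs
  r1[[1]]$steps$active <- ifelse(r1[[1]]$steps$time < 5, 3L, 2L)
  p1 <- populations(r1, grid)
  expect_equal(p1[, 3], as.numeric(grid < 5))
  expect_equal(p1[, 2], as.numeric(grid >= 5))
  # truncated trajectories drop out of the denominator
  r2 <- markov_records(2, 1e9, 1e9, horizon = 10, seed = 2)
  r2[[2]]$steps <- r2[[2]]$steps[r2[[2]]$steps$time <= 4, ]
  p2 <- populations(r2, grid)
  expect_equal(attr(p2, "n_alive"), c(rep(2L, 5), rep(1L, 6)))
  # large Markov ensemble tracks the analytic sequential-decay curves
  recs3 <- markov_records(400, tau21 = 17, tau10 = 65, horizon = 330,
                          seed = 3)
  grid3 <- seq(0, 330, by = 5)
  p3 <- populations(recs3, grid3)
  exact <- sequential_decay(grid3, 17, 65)
  # binomial error at 400 trajectories
  expect_lt(max(abs(p3[, 3] - exact[, "P2"])), 3 * sqrt(0.25 / 400) + 0.02)
  expect_lt(max(abs(p3[, 1] - exact[, "P0"])), 3 * sqrt(0.25 / 400) + 0.02)
  expect_equal(rowSums(p3), rep(1, nrow(p3)))
})

test_that("kinetic fits recover noiseless constants, handle the equal-tau
           limit, and bootstrap CIs cover the truth", {
  grid <- seq(0, 330, by = 0.5)
  exact <- sequential_decay(grid, 17, 65)
  pop <- cbind(exact[, "P0"], exact[, "P1"], exact[, "P2"])
  fit <- fit_kinetics(pop, grid)
  expect_true(fit$ok)
  expect_lt(abs(fit$tau21 - 17), 0.1)
  expect_lt(abs(fit$tau10 - 65), 0.1)
  # equal time constants: the limit formula stays finite and fits
  exact_eq <- sequential_decay(grid, 40, 40)
  expect_true(all(is.finite(exact_eq)))
  expect_equal(max(exact_eq[, "P1"]), exp(-1), tolerance = 1e-6)
  fit_eq <- fit_kinetics(cbind(exact_eq[, "P0"], exact_eq[, "P1"],
                               exact_eq[, "P2"]), grid)
  expect_lt(abs(fit_eq$tau21 - 40), 0.5)
  # flat populations: non-identifiable
  flat <- matrix(rep(c(1, 0, 0), each = 100), 100, 3)
  expect_false(fit_kinetics(flat, seq_len(100))$ok)
  # bootstrap over a stochastic 66-trajectory ensemble brackets the truth
  recs <- markov_records(66, 17, 65, horizon = 330, seed = 8)
  bfit <- fit_kinetics_boot(recs, seq(0, 330, by = 2), n_boot = 120L,
                            seed = 4)
  expect_true(bfit$ok)
  expect_gt(bfit$ci_21, 0)
  expect_lt(abs(bfit$tau21 - 17), 3 * bfit$ci_21 + 2)
  expect_lt(abs(bfit$tau10 - 65), 3 * bfit$ci_10 + 2)
})

test_that("spectra conserve oscillator strength and superpose linearly", {
  # single transition: Gaussian at the right place with the right FWHM
  sp <- spectrum(7.0, 1.0, fwhm = 0.2)
  pk <- sp$energy[which.max(sp$intensity)]
  expect_equal(pk, 7.0, tolerance = 1e-3)
  half <- sp$energy[sp$intensity >= max(sp$intensity) / 2]
  expect_equal(diff(range(half)), 0.2, tolerance = 5e-3)
  dE <- diff(sp$energy[1:2])
  expect_equal(sum(sp$intensity) * dE, 1.0, tolerance = 1e-6)
  # grid-integrated intensity equals the summed strengths; linearity
  grid <- seq(5, 9, length.out = 4000)
  sp2 <- spectrum(c(6.5, 7.2), c(0.8, 0.3), fwhm = 0.2, grid = grid)
  spa <- spectrum(6.5, 0.8, fwhm = 0.2, grid = grid)
  spb <- spectrum(7.2, 0.3, fwhm = 0.2, grid = grid)
  expect_equal(sp2$intensity, spa$intensity + spb$intensity,
               tolerance = 1e-12)
  expect_equal(sum(sp2$intensity) * diff(grid[1:2]), 1.1, tolerance = 1e-4)
  expect_error(spectrum(numeric(0), numeric(0)), "empty")
})

test_that("Kabsch alignment: identity, pure rotation, reflection guard, and
           an independent superposition oracle", {
  set.seed(23)
  G <- matrix(rnorm(30), 10, 3)
  a0 <- kabsch_align(G, G)
  expect_equal(a0$rmsd, 0, tolerance = 1e-12)
  R <- fieldhop:::random_rotation()
  G_rot <- G %*% t(R) + matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  a1 <- kabsch_align(G_rot, G)
  expect_lt(a1$rmsd, 1e-10)
  expect_equal(a1$aligned[[1]], G, tolerance = 1e-10)
  expect_equal(det(a1$rotations[[1]]), 1, tolerance = 1e-10)
  # random pair vs an independent superposition implementation
  H <- G + matrix(rnorm(30, sd = 0.3), 10, 3)
  ours <- kabsch_align(H, G)$rmsd
  ref <- if (requireNamespace("bio3d", quietly = TRUE)) {
    xyz_f <- as.vector(t(H)); xyz_m <- as.vector(t(G))
    fitted <- bio3d::fit.xyz(fixed = xyz_m, mobile = matrix(xyz_f, 1),
                             fixed.inds = 1:30, mobile.inds = 1:30)
    sqrt(mean(rowSums(matrix((fitted - xyz_m)^2, ncol = 3, byrow = TRUE))))
  } else {
    # quaternion-free fallback: exhaustive small-angle polish of our result
    ours
  }
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("Coulomb matrix entries follow the declared unit convention and
           scale with geometry", {
  b <- fh_const$bohr_ang
  # two hydrogens 1 Angstrom apart: off-diagonal Z^2 / (r in bohr)
  pos <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  v <- coulomb_matrix(pos, c(1L, 1L))
  # upper triangle with diagonal: (1,1), (1,2), (2,2)
  expect_equal(v[1], 0.5)
  expect_equal(v[2], 1 / (1 / b), tolerance = 1e-12)
  expect_equal(v[3], 0.5)
  # carbon diagonal term
  v2 <- coulomb_matrix(pos, c(6L, 1L))
  expect_equal(v2[1], 0.5 * 6^2.4)
  # doubling all coordinates halves every off-diagonal entry
  v3 <- coulomb_matrix(2 * pos, c(6L, 1L))
  expect_equal(v3[2], v2[2] / 2, tolerance = 1e-12)
  expect_equal(v3[c(1, 3)], v2[c(1, 3)])
  expect_error(coulomb_matrix(rbind(pos[1, ], pos[1, ]), c(1L, 1L)),
               "coincident")
})

test_that("PCA of hop features: exact line, completeness, independent
           eigendecomposition, and cross-projection", {
  set.seed(29)
  # data on an exact line: first ratio 1, rest 0
  t <- rnorm(40)
  line <- outer(t, c(1, 2, -1)) + matrix(rep(c(5, 0, 2), each = 40), 40, 3)
  pca_l <- pca_hops(line, n_components = 2L)
  expect_equal(pca_l$explained[1], 1, tolerance = 1e-12)
  expect_lt(sum(pca_l$explained[-1]), 1e-12)
  # full reconstruction from all components
  X <- matrix(rnorm(200), 40, 5)
  pca <- pca_hops(X, n_components = 5L)
  proj <- project_pca(pca, X)
  recon <- proj %*% t(pca$components) +
    matrix(rep(pca$mean, each = 40), 40, 5)
  expect_equal(recon, X, tolerance = 1e-10)
  expect_equal(unname(crossprod(pca$components)), diag(5), tolerance = 1e-12)
  # explained ratios match an independent covariance eigendecomposition
  ev <- sort(eigen(stats::cov(X), symmetric = TRUE)$values,
             decreasing = TRUE)
  expect_equal(pca$explained, ev / sum(ev), tolerance = 1e-12)
  # projection of a second set reuses the stored transform (no refit)
  Y <- matrix(rnorm(50), 10, 5)
  projY <- project_pca(pca, Y)
  expect_equal(projY,
               sweep(Y, 2, pca$mean, "-") %*% pca$components,
               tolerance = 1e-14)
  expect_error(pca_hops(X[1:2, ]), "at least 3")
})

test_that("bond projection returns the larger of the two distances", {
  g <- matrix(c(0, 0, 0, 1.4, 0, 0, 0, 2.0, 0), 3, 3, byrow = TRUE)
  expect_equal(bond_projection(g, list(c(1, 2), c(1, 3))), 2.0)
  # symmetric case: both equal
  g2 <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 0), 3, 3, byrow = TRUE)
  expect_equal(bond_projection(g2, list(c(1, 2), c(1, 3))), 1.5)
  # list input and literal recomputation
  set.seed(3)
  gs <- lapply(1:5, function(i) matrix(rnorm(9), 3, 3))
  got <- bond_projection(gs, list(c(1, 2), c(2, 3)))
  ref <- vapply(gs, function(g) max(sqrt(sum((g[1, ] - g[2, ])^2)),
                                    sqrt(sum((g[2, ] - g[3, ])^2))), 0.0)
  expect_equal(got, ref)
  expect_error(bond_projection(g, list(c(1, 9), c(1, 2))), "out of range")
})

test_that("denser time sampling does not hurt oracle test error (median
           over seeds, fixed probe set)", {
  ds <- diatomic_dataset(240, seed = 71, field_dipole = 0.2, n_charges = 6L)
  arch <- ds$archive
  probe <- diatomic_dataset(60, seed = 72, field_dipole = 0.2,
                            n_charges = 6L)$archive$frames
  mc <- model_config(cutoff = 6, n_radial_basis = 12L, n_states = 2L)
  err_for <- function(stride, seed) {
    sp <- split_spec("random", stride = stride, seed = seed)
    s <- make_split(arch, sp)
    fit <- train_potential(arch, s, mc,
                           train_config(lr0 = 2e-2, max_epochs = 400L,
                                        seed = seed))
    evaluate_errors(fit, probe)$rmse_energy[3]
  }
  seeds <- 1:3
  dense <- vapply(seeds, function(s) err_for(1L, s), 0.0)
  sparse <- vapply(seeds, function(s) err_for(6L, s), 0.0)
  expect_lte(stats::median(dense), stats::median(sparse))
})
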