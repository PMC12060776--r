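#' Model-assessment toolkit
#'
#' Dataset splitting with time subsampling, plain and gap-weighted error
#' statistics, active-state population extraction with sequential-decay
#' kinetic fits and trajectory bootstrap, Gaussian-convolved absorption
#' spectra, and hopping-geometry analysis (Kabsch alignment, Coulomb-matrix
#' PCA, bond-distance projections).
#'
#' @name evaluation
NULL

#' Dataset split specification
#'
#' @param scheme "by_trajectory" (whole trajectories per subset, avoiding
#'   temporal leakage) or "random" (frame-level assignment)
#' @param fractions train/validation/test fractions, sum 1 (random scheme
#'   and trajectory-count derivation)
#' @param counts optional integer triple of trajectory counts for
#'   "by_trajectory" (overrides `fractions`)
#' @param stride time-subsampling stride: 1 keeps all frames, 2 every
#'   second, 3 every third; applied before assignment
#' @param seed integer seed for the shuffling
#' @return an object of class `split_spec`
#' @export
split_spec <- function(scheme = c("by_trajectory", "random"),
                       fractions = c(0.8, 0.1, 0.1), counts = NULL,
                       stride = 1L, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9,
            stride >= 1L)
  if (!is.null(counts)) stopifnot(length(counts) == 3L, all(counts >= 0))
  structure(list(scheme = scheme, fractions = fractions, counts = counts,
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "split_spec")
}

#' Split an archive into train/validation/test
#'
#' Time subsampling (keep frames whose within-trajectory index is a
#' multiple of the stride, counting from zero) is applied before the
#' assignment.  "by_trajectory" allocates whole trajectories: for 46
#' trajectories the default fractions give 37/5/4.  "random" pools retained
#' frames and assigns them frame-wise.  Assignments are disjoint and
#' exhaustive over retained frames, and deterministic given the seed.
#'
#' @param archive an `fh_archive`
#' @param spec a [split_spec()]
#' @return list with integer frame-index vectors `train`, `validation`,
#'   `test` and a `manifest` (scheme, seed, stride, per-subset trajectory
#'   ids and frame counts)
#' @export
make_split <- function(archive, spec) {
  stopifnot(inherits(spec, "split_spec"))
  meta <- archive$meta
  if (is.null(meta$trajectory_id) || is.null(meta$frame_idx))
    stop("archive metadata must carry trajectory_id and frame_idx")
  keep <- which(meta$frame_idx %% spec$stride == 0L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(fh_seed(spec$seed, "split"))
  if (spec$scheme == "by_trajectory") {
    ids <- unique(meta$trajectory_id)
    nt <- length(ids)
    counts <- spec$counts
    if (is.null(counts)) {
      n_tr <- round(spec$fractions[1] * nt)
      n_va <- round(spec$fractions[2] * nt)
      counts <- c(n_tr, n_va, nt - n_tr - n_va)
    }
    if (sum(counts) != nt)
      stop("requested trajectory counts (", sum(counts),
           ") do not match the ", nt, " available trajectories")
    ids <- sample(ids)
    id_tr <- ids[seq_len(counts[1])]
    id_va <- ids[counts[1] + seq_len(counts[2])]
    id_te <- ids[counts[1] + counts[2] + seq_len(counts[3])]
    train <- keep[meta$trajectory_id[keep] %in% id_tr]
    validation <- keep[meta$trajectory_id[keep] %in% id_va]
    test <- keep[meta$trajectory_id[keep] %in% id_te]
    traj_sets <- list(train = id_tr, validation = id_va, test = id_te)
  } else {
    perm <- sample(keep)
    nf <- length(perm)
    n_tr <- round(spec$fractions[1] * nf)
    n_va <- round(spec$fractions[2] * nf)
    train <- sort(perm[seq_len(n_tr)])
    validation <- sort(perm[n_tr + seq_len(n_va)])
    test <- sort(perm[(n_tr + n_va + 1):nf])
    traj_sets <- NULL
  }
  list(train = train, validation = validation, test = test,
       manifest = list(scheme = spec$scheme, seed = spec$seed,
                       stride = spec$stride, trajectories = traj_sets,
                       n_frames = c(train = length(train),
                                    validation = length(validation),
                                    test = length(test)),
                       retained = length(keep)))
}

#' Gap-weighted RMSE (core form)
#'
#' Configurations are weighted by the inverse of the state's smallest
#' adjacent energy gap, `w_i^j = 1 / (min adjacent gap + delta)`, and the
#' weighted root mean squared error is
#' `sqrt(sum_i w_i e_i^2 / sum_i w_i)` per state.  With uniform gaps the
#' weights cancel and the plain RMSE is recovered exactly.
#'
#' @param errors n_frames x n_states matrix of per-configuration errors
#'   (e.g. energy residuals, or per-configuration force RMS values)
#' @param label_energies n_frames x n_states matrix of ground-truth state
#'   energies (eV), used to compute adjacent gaps
#' @param delta gap regulariser (eV)
#' @return list with `per_state` (weighted RMSE by state) and `average`
#' @export
gap_weighted_rmse <- function(errors, label_energies, delta = 1e-3) {
  errors <- as.matrix(errors)
  label_energies <- as.matrix(label_energies)
  stopifnot(all(dim(errors) == dim(label_energies)))
  ns <- ncol(errors)
  if (ns < 2L) stop("gap weighting needs at least two states")
  out <- numeric(ns)
  for (j in seq_len(ns)) {
    gaps <- if (j == 1L) abs(label_energies[, 2] - label_energies[, 1])
    else if (j == ns) abs(label_energies[, ns] - label_energies[, ns - 1])
    else pmin(abs(label_energies[, j] - label_energies[, j - 1]),
              abs(label_energies[, j + 1] - label_energies[, j]))
    w <- 1 / (gaps + delta)
    out[j] <- sqrt(sum(w * errors[, j]^2) / sum(w))
  }
  list(per_state = out, average = mean(out))
}

#' Gap-weighted error of a model on labelled frames
#'
#' @param model an `fh_model` or `fh_fit`
#' @param frames list of `labelled_frame`s
#' @param quantity "energy" or "force" (field-corrected total forces)
#' @param delta gap regulariser (eV)
#' @return list with `per_state` and `average`, in kcal/mol or
#'   kcal/(mol*Angstrom)
#' @export
gap_weighted_error <- function(model, frames, quantity = c("energy", "force"),
                               delta = 1e-3) {
  quantity <- match.arg(quantity)
  if (inherits(model, "fh_fit")) model <- model$model
  ns <- model$config$n_states
  nf <- length(frames)
  if (nf == 0L) stop("empty frame set")
  err <- matrix(0.0, nf, ns)
  lab_e <- matrix(0.0, nf, ns)
  for (t in seq_len(nf)) {
    l <- frames[[t]]
    lab_e[t, ] <- l$energies
    p <- predict_bundle(model, l$frame$ml_positions, l$frame$ml_elements,
                        l$field)
    if (quantity == "energy") {
      err[t, ] <- p$energies - l$energies
    } else {
      n <- nrow(l$frame$ml_positions)
      for (k in seq_len(ns)) {
        fhat <- ml_forces(p, l$jac, k)$f_ml
        err[t, k] <- sqrt(mean((fhat - matrix(l$forces_ml[k, , ], n, 3))^2))
      }
    }
  }
  r <- gap_weighted_rmse(err, lab_e, delta)
  r$per_state <- r$per_state * fh_const$ev_kcalmol
  r$average <- r$average * fh_const$ev_kcalmol
  r
}

#' Active-state populations of a trajectory ensemble
#'
#' Fractions of trajectories in each electronic state at the grid times,
#' based on the active state.  Trajectories that ended early (truncation)
#' drop out of the denominator after their last recorded frame.
#'
#' @param records list of `fh_trajectory` objects (same state count)
#' @param grid time grid (fs)
#' @return matrix `length(grid) x n_states` of occupation fractions, with
#'   attribute `n_alive` (denominator per grid point)
#' @export
populations <- function(records, grid) {
  if (length(records) == 0L) stop("empty trajectory ensemble")
  ns <- records[[1]]$n_states
  if (!all(vapply(records, function(r) r$n_states, 0L) == ns))
    stop("records disagree on the state count")
  pop <- matrix(0.0, length(grid), ns)
  alive <- integer(length(grid))
  for (r in records) {
    tmax <- max(r$steps$time)
    idx <- findInterval(grid + 1e-9, r$steps$time)
    ok <- grid <= tmax + 1e-9 & idx >= 1L
    if (!any(ok)) next
    alive[ok] <- alive[ok] + 1L
    cells <- cbind(which(ok), r$steps$active[idx[ok]])
    pop[cells] <- pop[cells] + 1
  }
  nz <- alive > 0L
  pop[nz, ] <- pop[nz, , drop = FALSE] / alive[nz]
  attr(pop, "n_alive") <- alive
  pop
}

#' Sequential-decay population model
#'
#' Closed-form solution of the first-order cascade start -> middle ->
#' ground: `P2 = exp(-t/tau21)`,
#' `P1 = tau10/(tau10 - tau21) (exp(-t/tau10) - exp(-t/tau21))` (with the
#' continuous limit at tau10 = tau21), `P0 = 1 - P1 - P2`.
#'
#' @param t time vector (fs)
#' @param tau21,tau10 time constants (fs)
#' @return matrix length(t) x 3 with columns P0, P1, P2
#' @export
sequential_decay <- function(t, tau21, tau10) {
  p2 <- exp(-t / tau21)
  # bounded form: both exponentials are <= 1, so p1 never overflows; the
  # removable singularity at tau10 = tau21 uses the analytic limit
  p1 <- if (abs(tau10 - tau21) < 1e-9 * tau10) {
    (t / tau21) * exp(-t / tau10)
  } else {
    tau10 / (tau10 - tau21) * (exp(-t / tau10) - exp(-t / tau21))
  }
  cbind(P0 = 1 - p1 - p2, P1 = p1, P2 = p2)
}

#' Fit the two-constant kinetic model to populations
#'
#' Least-squares fit of the sequential-decay solution to the three
#' population curves jointly, on log time constants (L-BFGS-B).
#'
#' @param pop population matrix from [populations()] (columns are states,
#'   ground first)
#' @param grid time grid (fs)
#' @param states 1-based column indices of (start, middle, ground), default
#'   `c(3, 2, 1)`: ensemble starting in the second excited state
#' @return an object of class `fh_kinetic_fit`: list with `tau21`, `tau10`
#'   (fs), `ci_21`, `ci_10` (NA unless bootstrapped), `residual`, `ok`
#' @export
fit_kinetics <- function(pop, grid, states = c(3L, 2L, 1L)) {
  pop <- as.matrix(pop)
  stopifnot(length(states) == 3L, max(states) <= ncol(pop),
            nrow(pop) == length(grid))
  p2 <- pop[, states[1]]; p1 <- pop[, states[2]]; p0 <- pop[, states[3]]
  if (stats::sd(p2) < 1e-10 && stats::sd(p0) < 1e-10)
    return(structure(list(tau21 = NA_real_, tau10 = NA_real_,
                          ci_21 = NA_real_, ci_10 = NA_real_,
                          residual = NA_real_, ok = FALSE),
                     class = "fh_kinetic_fit"))
  ssr <- function(lg) {
    m <- sequential_decay(grid, exp(lg[1]), exp(lg[2]))
    sum((m[, "P2"] - p2)^2 + (m[, "P1"] - p1)^2 + (m[, "P0"] - p0)^2)
  }
  # crude 1/e starting guesses
  t_half <- function(p) {
    idx <- which(p <= exp(-1))
    if (length(idx) == 0L) max(grid) else grid[idx[1]]
  }
  g1 <- max(t_half(p2), grid[2])
  g2 <- max(t_half(1 - p0), g1)
  fit <- stats::optim(log(c(g1, g2)), ssr, method = "L-BFGS-B",
                      lower = log(c(1e-3, 1e-3)), upper = log(c(1e6, 1e6)))
  structure(list(tau21 = exp(fit$par[1]), tau10 = exp(fit$par[2]),
                 ci_21 = NA_real_, ci_10 = NA_real_,
                 residual = fit$value, ok = fit$convergence == 0),
            class = "fh_kinetic_fit")
}

#' Kinetic fit with trajectory bootstrap
#'
#' Trajectories (the independent units) are resampled with replacement;
#' populations are recomputed and refitted per replicate, and the
#' confidence half-widths are percentile based.
#'
#' @param records list of `fh_trajectory`
#' @param grid time grid (fs)
#' @param n_boot bootstrap replicates
#' @param seed integer seed
#' @param states column indices as in [fit_kinetics()]
#' @param level confidence level
#' @return `fh_kinetic_fit` with `ci_21`, `ci_10` filled and the bootstrap
#'   draws in `boot`
#' @export
fit_kinetics_boot <- function(records, grid, n_boot = 200L, seed = 1L,
                              states = c(3L, 2L, 1L), level = 0.95) {
  fit <- fit_kinetics(populations(records, grid), grid, states)
  if (!fit$ok) return(fit)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(fh_seed(seed, "bootstrap"))
  nr <- length(records)
  draws <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nr, nr, replace = TRUE)
    f <- fit_kinetics(populations(records[idx], grid), grid, states)
    if (f$ok) draws[b, ] <- c(f$tau21, f$tau10)
  }
  a <- (1 - level) / 2
  q1 <- stats::quantile(draws[, 1], c(a, 1 - a), na.rm = TRUE)
  q2 <- stats::quantile(draws[, 2], c(a, 1 - a), na.rm = TRUE)
  fit$ci_21 <- unname(q1[2] - q1[1]) / 2
  fit$ci_10 <- unname(q2[2] - q2[1]) / 2
  fit$boot <- draws
  fit$ci_bounds <- list(tau21 = unname(q1), tau10 = unname(q2))
  fit
}

#' Gaussian-convolved absorption spectrum
#'
#' Each transition contributes a Gaussian of the stated full width at half
#' maximum centred at its energy, weighted by its oscillator strength; the
#' integrated intensity equals the summed oscillator strength.
#'
#' @param energies transition energies (eV)
#' @param osc_strengths matching oscillator strengths
#' @param fwhm full width at half maximum (eV)
#' @param grid optional energy grid; default spans the transitions plus
#'   five standard deviations at 2000 points
#' @return data.frame with columns `energy` (eV) and `intensity` (per eV)
#' @export
spectrum <- function(energies, osc_strengths, fwhm = 0.2, grid = NULL) {
  stopifnot(length(energies) == length(osc_strengths), fwhm > 0)
  if (length(energies) == 0L) stop("empty transition list")
  sg <- fwhm / (2 * sqrt(2 * log(2)))
  if (is.null(grid))
    grid <- seq(min(energies) - 5 * sg, max(energies) + 5 * sg,
                length.out = 2000L)
  intensity <- numeric(length(grid))
  for (t in seq_along(energies))
    intensity <- intensity +
      osc_strengths[t] * stats::dnorm(grid, energies[t], sg)
  data.frame(energy = grid, intensity = intensity)
}

#' Kabsch superposition of geometries onto a reference
#'
#' Optimal rotation + translation minimising the coordinate RMSD, with the
#' SVD determinant correction for degenerate/reflective cases.
#'
#' @param geometries a single n x 3 matrix or a list of them
#' @param reference n x 3 reference matrix
#' @return list with `aligned` (list of matrices), `rmsd` (vector), and
#'   `rotations` (list of 3 x 3 matrices)
#' @export
kabsch_align <- function(geometries, reference) {
  if (is.matrix(geometries)) geometries <- list(geometries)
  n <- nrow(reference)
  ref0 <- sweep(reference, 2, colMeans(reference), "-")
  out_a <- vector("list", length(geometries))
  out_r <- numeric(length(geometries))
  out_R <- vector("list", length(geometries))
  for (t in seq_along(geometries)) {
    G <- geometries[[t]]
    if (nrow(G) != n) stop("geometry ", t, " has a different atom count")
    G0 <- sweep(G, 2, colMeans(G), "-")
    s <- svd(crossprod(G0, ref0))
    d <- sign(det(s$u) * det(s$v))
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    A <- G0 %*% R
    out_a[[t]] <- sweep(A, 2, colMeans(reference), "+")
    out_r[t] <- sqrt(mean(rowSums((A - ref0)^2)))
    out_R[[t]] <- R
  }
  list(aligned = out_a, rmsd = out_r, rotations = out_R)
}

#' Coulomb-matrix feature vector of a geometry
#'
#' Off-diagonal entries Z_i Z_j / r_ij with distances in bohr, diagonal
#' 0.5 Z^2.4; the flattened upper triangle (including the diagonal) in
#' fixed atom order.  No row-norm sorting: the chromophore's atom identity
#' is constant, and permuting same-element atoms changes the vector by
#' convention.
#'
#' @param positions n x 3 matrix (Angstrom)
#' @param atomic_numbers integer vector of length n
#' @return numeric feature vector of length n(n+1)/2
#' @export
coulomb_matrix <- function(positions, atomic_numbers) {
  n <- nrow(positions)
  stopifnot(n >= 2L, length(atomic_numbers) == n)
  M <- matrix(0.0, n, n)
  for (i in seq_len(n)) {
    M[i, i] <- 0.5 * atomic_numbers[i]^2.4
    for (j in seq_len(n)) {
      if (j <= i) next
      r <- sqrt(sum((positions[i, ] - positions[j, ])^2)) / fh_const$bohr_ang
      if (r < 1e-10) stop("coincident atoms ", i, " and ", j)
      M[i, j] <- M[j, i] <- atomic_numbers[i] * atomic_numbers[j] / r
    }
  }
  M[upper.tri(M, diag = TRUE)]
}

#' Principal components of hopping-geometry features
#'
#' Components are computed from the reference set only (centred, not
#' scaled); other sets are projected with the stored transform, never
#' refitted, so reference and comparison sets share one coordinate system.
#'
#' @param features n x p matrix of feature vectors (n >= 3)
#' @param n_components number of components to retain
#' @return an object of class `fh_pca`: list with `mean`, `components`
#'   (p x n_components, orthonormal columns), `explained` (variance ratios
#'   for all components)
#' @export
pca_hops <- function(features, n_components = 2L) {
  features <- as.matrix(features)
  if (nrow(features) < 3L) stop("need at least 3 samples")
  if (n_components > min(dim(features)))
    stop("fewer samples/features than requested components")
  mu <- colMeans(features)
  pr <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  structure(list(mean = mu,
                 components = pr$rotation[, seq_len(n_components), drop = FALSE],
                 explained = ev / sum(ev),
                 rotation_full = pr$rotation),
            class = "fh_pca")
}

#' Project features with a stored PCA transform
#'
#' @param pca an `fh_pca`
#' @param features m x p matrix
#' @return m x n_components coordinate matrix
#' @export
project_pca <- function(pca, features) {
  features <- as.matrix(features)
  sweep(features, 2, pca$mean, "-") %*% pca$components
}

#' Maximum of two bond distances per geometry
#'
#' Projects geometries onto `max(r(a1, a2), r(b1, b2))` -- e.g. the larger
#' of the two ring C-O distances, the natural coordinate of a symmetric
#' ring-opening.
#'
#' @param geometries a single n x 3 matrix or list of them
#' @param bond_pairs list of two atom-index pairs, e.g.
#'   `list(c(1, 2), c(1, 5))`
#' @return numeric vector of per-geometry maxima (Angstrom)
#' @export
bond_projection <- function(geometries, bond_pairs) {
  if (is.matrix(geometries)) geometries <- list(geometries)
  stopifnot(length(bond_pairs) == 2L,
            all(vapply(bond_pairs, length, 0L) == 2L))
  vapply(geometries, function(g) {
    n <- nrow(g)
    idx <- unlist(bond_pairs)
    if (any(idx < 1L | idx > n)) stop("bond index out of range")
    r1 <- sqrt(sum((g[bond_pairs[[1]][1], ] - g[bond_pairs[[1]][2], ])^2))
    r2 <- sqrt(sum((g[bond_pairs[[2]][1], ] - g[bond_pairs[[2]][2], ])^2))
    max(r1, r2)
  }, 0.0)
}
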