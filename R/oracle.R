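#' Analytic oracle Hamiltonian: types and constructors
#'
#' The oracle is a multi-state diabatic Hamiltonian built from per-state
#' shifted harmonic surfaces, constant (optionally Gaussian) inter-state
#' couplings, and a linear dipole-field coupling to the embedding field.
#' It is the smallest model with avoided crossings, field response, and
#' analytic everything: energies, forces, field derivatives and nonadiabatic
#' couplings are all available in closed form, so it can generate exact
#' reference labels and reference dynamics against which both the embedding
#' algebra and the learned potentials are tested.
#'
#' @param n_states number of electronic states (>= 2)
#' @param elements atomic numbers of the ML atoms
#' @param masses per-atom masses (amu); defaults to standard masses
#' @param diabatic_minima array `n_states x n_atoms x 3` of per-state
#'   equilibrium positions (Angstrom)
#' @param force_constants matrix `n_states x n_atoms` of isotropic harmonic
#'   constants (eV/Angstrom^2), all positive
#' @param vertical_shifts per-state energy offsets (eV), non-decreasing
#' @param diabatic_couplings symmetric `n_states x n_states` matrix of
#'   constant couplings (eV) with zero diagonal
#' @param state_dipoles array `n_states x n_atoms x 3` of dipole-coupling
#'   vectors (e*Angstrom); the diagonal diabatic energies carry a term
#'   `- mu_{k,i} . eps_i`
#' @param transition_dipoles array `n_states x n_states x 3` (e*Angstrom)
#'   of state-pair transition dipoles used for oscillator strengths
#' @param gaussian_couplings optional list of Gaussian coupling terms, each
#'   `list(pair = c(k, l), atoms = c(i, j), amplitude, center, width)`
#'   adding `amplitude * exp(-(r_ij - center)^2 / (2 width^2))` (eV) to
#'   `H[k, l]`
#' @return an object of class `oracle_spec`
#' @export
oracle_spec <- function(n_states, elements, masses = NULL,
                        diabatic_minima, force_constants, vertical_shifts,
                        diabatic_couplings, state_dipoles,
                        transition_dipoles = NULL, gaussian_couplings = NULL) {
  n_states <- as.integer(n_states)
  n <- length(elements)
  if (is.null(masses)) masses <- element_mass(elements)
  stopifnot(n_states >= 2, n >= 1, length(masses) == n, all(masses > 0))
  stopifnot(identical(dim(diabatic_minima), c(n_states, n, 3L)) ||
              identical(dim(diabatic_minima), as.integer(c(n_states, n, 3))))
  stopifnot(all(dim(force_constants) == c(n_states, n)), all(force_constants > 0))
  stopifnot(length(vertical_shifts) == n_states,
            !is.unsorted(vertical_shifts))
  stopifnot(all(dim(diabatic_couplings) == c(n_states, n_states)))
  if (max(abs(diabatic_couplings - t(diabatic_couplings))) > 1e-12)
    stop("diabatic coupling matrix must be symmetric")
  if (max(abs(diag(diabatic_couplings))) > 0)
    stop("diabatic coupling matrix must have zero diagonal")
  stopifnot(all(dim(state_dipoles) == c(n_states, n, 3)))
  if (is.null(transition_dipoles))
    transition_dipoles <- array(0.0, c(n_states, n_states, 3))
  stopifnot(all(dim(transition_dipoles) == c(n_states, n_states, 3)))
  for (g in gaussian_couplings %||% list()) {
    stopifnot(length(g$pair) == 2L, g$pair[1] != g$pair[2],
              length(g$atoms) == 2L, g$width > 0)
  }
  # pairwise bond-network parameters derived from the per-state minima:
  # equilibrium distances r0 and pair constants kappa_ij, chosen so each
  # atom's aggregate stiffness matches its per-atom force constant
  r0 <- array(0.0, c(n_states, n, n))
  kappa <- array(0.0, c(n_states, n, n))
  if (n >= 2L) {
    for (k in seq_len(n_states)) {
      g <- diabatic_minima[k, , , drop = TRUE]
      if (n == 1L) g <- matrix(g, 1, 3)
      dm <- as.matrix(stats::dist(g))
      r0[k, , ] <- dm
      kap <- outer(force_constants[k, ], force_constants[k, ], "+") /
        (2 * (n - 1))
      diag(kap) <- 0
      kappa[k, , ] <- kap
    }
  }
  structure(list(n_states = n_states, n_ml_atoms = n,
                 pair_r0 = r0, pair_kappa = kappa,
                 elements = as.integer(elements), masses = as.numeric(masses),
                 diabatic_minima = diabatic_minima,
                 force_constants = force_constants,
                 vertical_shifts = as.numeric(vertical_shifts),
                 diabatic_couplings = diabatic_couplings,
                 state_dipoles = state_dipoles,
                 transition_dipoles = transition_dipoles,
                 gaussian_couplings = gaussian_couplings),
            class = "oracle_spec")
}

#' Point-charge bath specification
#'
#' A finite cluster of mobile point charges surrounding the chromophore.
#' The charges interact with the ML atoms through Lennard-Jones potentials
#' and through the embedding field (Coulomb), and with one another through
#' plain Coulomb forces.  No periodic images: a finite droplet keeps the
#' cutoff-free field sum exact.
#'
#' @param n_charges number of charge sites
#' @param charges per-site partial charges (e); recycled if scalar
#' @param lj_epsilon,lj_sigma Lennard-Jones pair parameters between ML atoms
#'   and bath sites (eV, Angstrom)
#' @param box_length droplet diameter used when placing charges (Angstrom)
#' @param temperature bath temperature (K) used by the sampler
#' @param friction Langevin friction for bath thermalisation (ps^-1)
#' @return an object of class `bath_spec`
#' @export
bath_spec <- function(n_charges, charges = 0.4, lj_epsilon = 0.0103,
                      lj_sigma = 3.166, box_length = 18, temperature = 300,
                      friction = 2) {
  n_charges <- as.integer(n_charges)
  stopifnot(n_charges >= 0, lj_sigma > 0, lj_epsilon >= 0, box_length > 0,
            temperature >= 0, friction >= 0)
  if (n_charges == 0L) charges <- numeric(0)
  else if (length(charges) == 1L)
    charges <- charges * rep_len(c(1, -1), n_charges)
  stopifnot(length(charges) == n_charges, all(is.finite(charges)))
  if (n_charges > 0 && box_length < 2 * lj_sigma)
    stop("box_length too small: minimum-image distances would fall below lj_sigma")
  structure(list(n_charges = n_charges, charges = as.numeric(charges),
                 lj_epsilon = lj_epsilon, lj_sigma = lj_sigma,
                 box_length = box_length, temperature = temperature,
                 friction = friction),
            class = "bath_spec")
}

#' One configuration of the combined ML + charge-bath system
#'
#' @param ml_positions n_ml x 3 matrix (Angstrom)
#' @param ml_elements atomic numbers of the ML atoms
#' @param mm_positions n_mm x 3 matrix (Angstrom)
#' @param mm_charges per-site charges (e)
#' @param ml_velocities,mm_velocities optional velocity matrices (Angstrom/fs)
#' @param masses ML-atom masses (amu); defaults to standard masses
#' @param mm_masses bath-site masses (amu); default 18 (water-like)
#' @return an object of class `system_frame`
#' @export
system_frame <- function(ml_positions, ml_elements, mm_positions, mm_charges,
                         ml_velocities = NULL, mm_velocities = NULL,
                         masses = NULL, mm_masses = NULL) {
  n <- nrow(ml_positions)
  m <- nrow(mm_positions)
  check_mat3(ml_positions, n, "ml_positions")
  check_mat3(mm_positions, m, "mm_positions")
  stopifnot(length(ml_elements) == n, length(mm_charges) == m)
  if (is.null(masses)) masses <- element_mass(ml_elements)
  if (is.null(mm_masses)) mm_masses <- rep(18.01528, m)
  if (is.null(ml_velocities)) ml_velocities <- matrix(0.0, n, 3)
  if (is.null(mm_velocities)) mm_velocities <- matrix(0.0, m, 3)
  check_mat3(ml_velocities, n, "ml_velocities")
  check_mat3(mm_velocities, m, "mm_velocities")
  if (m > 0) {
    for (i in seq_len(n)) {
      d <- sweep(mm_positions, 2, ml_positions[i, ], "-")
      if (any(row_norms(d) < .FH_MIN_DIST))
        stop("frame invalid: ML atom ", i, " coincides with a charge site")
    }
  }
  structure(list(ml_positions = ml_positions,
                 ml_elements = as.integer(ml_elements),
                 mm_positions = mm_positions, mm_charges = as.numeric(mm_charges),
                 ml_velocities = ml_velocities, mm_velocities = mm_velocities,
                 masses = as.numeric(masses), mm_masses = as.numeric(mm_masses)),
            class = "system_frame")
}

#' Diabatic Hamiltonian matrix of the oracle
#'
#' Diagonal entries are the shifted harmonic diabats minus the dipole-field
#' coupling, `V_k(R) - sum_i mu_{k,i} . eps_i`.  The harmonic term is a
#' bond-network potential, `sum_{i<j} kappa_ij (r_ij - r0_ij^k)^2 / 2`,
#' over all interatomic distances with per-state equilibrium distances
#' taken from the state's minimum geometry -- exactly invariant under rigid
#' translations and rotations, with zero net force and torque.
#' Off-diagonal entries are the constant plus Gaussian diabatic couplings.
#'
#' @param spec an [oracle_spec()]
#' @param ml_positions n_ml x 3 matrix (Angstrom)
#' @param field n_ml x 3 matrix of per-atom field vectors (atomic units), or
#'   an `fh_field`
#' @return symmetric `n_states x n_states` matrix (eV)
#' @export
diabatic_hamiltonian <- function(spec, ml_positions, field) {
  stopifnot(inherits(spec, "oracle_spec"))
  if (inherits(field, "fh_field")) field <- field$field
  n <- spec$n_ml_atoms
  check_mat3(ml_positions, n, "ml_positions")
  check_mat3(field, n, "field")
  ns <- spec$n_states
  H <- spec$diabatic_couplings
  dm <- if (n >= 2L) as.matrix(stats::dist(ml_positions)) else NULL
  for (k in seq_len(ns)) {
    harm <- if (n >= 2L) {
      dd <- dm - spec$pair_r0[k, , ]
      0.5 * sum(spec$pair_kappa[k, , ] * dd^2) / 2  # each pair counted twice
    } else 0.0
    dip <- sum(spec$state_dipoles[k, , ] * field) * fh_const$field_au_ev
    H[k, k] <- spec$vertical_shifts[k] + harm - dip
  }
  for (g in spec$gaussian_couplings %||% list()) {
    r <- sqrt(sum((ml_positions[g$atoms[1], ] - ml_positions[g$atoms[2], ])^2))
    val <- g$amplitude * exp(-(r - g$center)^2 / (2 * g$width^2))
    H[g$pair[1], g$pair[2]] <- H[g$pair[1], g$pair[2]] + val
    H[g$pair[2], g$pair[1]] <- H[g$pair[2], g$pair[1]] + val
  }
  H
}

#' Derivatives of the diabatic Hamiltonian
#'
#' Returns the nonzero blocks of dH/dR (at fixed field) and dH/deps.
#' dH/dR is diagonal (harmonic terms) except for Gaussian couplings;
#' dH/deps is purely diagonal (linear dipole coupling).
#'
#' @return list with `diag_grad` (array ns x n x 3: dH_kk/dR at fixed field),
#'   `coupling_grads` (list of `list(pair, grad)` for Gaussian couplings),
#'   and `dH_deps` (array ns x n x 3: dH_kk/deps_i, eV per a.u. field)
#' @noRd
diabatic_derivatives <- function(spec, ml_positions) {
  ns <- spec$n_states; n <- spec$n_ml_atoms
  dg <- array(0.0, c(ns, n, 3))
  if (n >= 2L) {
    dm <- as.matrix(stats::dist(ml_positions))
    for (k in seq_len(ns)) {
      for (i in seq_len(n)) {
        acc <- numeric(3)
        for (j in seq_len(n)) {
          if (j == i) next
          u <- (ml_positions[i, ] - ml_positions[j, ]) / dm[i, j]
          acc <- acc + spec$pair_kappa[k, i, j] *
            (dm[i, j] - spec$pair_r0[k, i, j]) * u
        }
        dg[k, i, ] <- acc
      }
    }
  }
  cg <- list()
  for (g in spec$gaussian_couplings %||% list()) {
    d <- ml_positions[g$atoms[1], ] - ml_positions[g$atoms[2], ]
    r <- sqrt(sum(d^2))
    val <- g$amplitude * exp(-(r - g$center)^2 / (2 * g$width^2))
    dval_dr <- -val * (r - g$center) / g$width^2
    grad <- matrix(0.0, n, 3)
    grad[g$atoms[1], ] <- dval_dr * d / r
    grad[g$atoms[2], ] <- -dval_dr * d / r
    cg[[length(cg) + 1L]] <- list(pair = g$pair, grad = grad)
  }
  deps <- array(0.0, c(ns, n, 3))
  for (k in seq_len(ns))
    deps[k, , ] <- -spec$state_dipoles[k, , ] * fh_const$field_au_ev
  list(diag_grad = dg, coupling_grads = cg, dH_deps = deps)
}

#' Matrix element <k| dH/dx |l> for all ML coordinates at fixed field
#' @param derivs result of diabatic_derivatives
#' @param U eigenvector matrix (columns = adiabatic states)
#' @param k,l adiabatic state indices (1-based)
#' @return n x 3 matrix (eV/Angstrom)
#' @noRd
sandwich_gradient <- function(derivs, U, k, l) {
  ns <- dim(derivs$diag_grad)[1]; n <- dim(derivs$diag_grad)[2]
  out <- matrix(0.0, n, 3)
  wt <- U[, k] * U[, l]
  for (a in seq_len(ns))
    if (wt[a] != 0) out <- out + wt[a] * derivs$diag_grad[a, , ]
  for (cgr in derivs$coupling_grads) {
    p <- cgr$pair
    w <- U[p[1], k] * U[p[2], l] + U[p[2], k] * U[p[1], l]
    if (w != 0) out <- out + w * cgr$grad
  }
  out
}

#' Adiabatize a diabatic Hamiltonian
#'
#' Diagonalises a symmetric Hamiltonian, returning energies in ascending
#' order and eigenvector columns with a continuity contract: when
#' `previous_eigenvectors` is given, each column's sign is chosen to
#' maximise its overlap with the corresponding previous column; otherwise
#' the largest-magnitude component is made positive.
#'
#' @param H symmetric matrix (eV)
#' @param previous_eigenvectors optional matrix of reference columns
#' @return list with `energies` (ascending, eV) and `vectors` (columns)
#' @export
adiabatize <- function(H, previous_eigenvectors = NULL) {
  if (!is.matrix(H) || nrow(H) != ncol(H) ||
      max(abs(H - t(H))) > 1e-9 * max(1, max(abs(H))))
    stop("H must be a symmetric matrix")
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(vecs))) {
    s <- if (!is.null(previous_eigenvectors))
      sum(vecs[, k] * previous_eigenvectors[, k])
    else vecs[which.max(abs(vecs[, k])), k]
    if (s < 0) vecs[, k] <- -vecs[, k]
  }
  list(energies = vals, vectors = vecs)
}

#' Lennard-Jones energy and forces between ML atoms and bath sites
#' @return list(energy, f_ml, f_mm)
#' @noRd
lj_interaction <- function(ml_positions, mm_positions, eps, sigma) {
  n <- nrow(ml_positions); m <- nrow(mm_positions)
  f_ml <- matrix(0.0, n, 3); f_mm <- matrix(0.0, m, 3)
  en <- 0.0
  if (m == 0L || eps == 0)
    return(list(energy = en, f_ml = f_ml, f_mm = f_mm))
  for (i in seq_len(n)) {
    d <- sweep(-mm_positions, 2, ml_positions[i, ], "+")  # R_i - R_j
    r <- row_norms(d)
    sr6 <- (sigma / r)^6
    en <- en + sum(4 * eps * (sr6^2 - sr6))
    # dE/dr = 4 eps (-12 sr12 + 6 sr6)/r ; force on i = -dE/dr * d/r
    coef <- 4 * eps * (12 * sr6^2 - 6 * sr6) / r^2
    fi <- d * coef
    f_ml[i, ] <- f_ml[i, ] + colSums(fi)
    f_mm <- f_mm - fi
  }
  list(energy = en, f_ml = f_ml, f_mm = f_mm)
}

#' Coulomb plus Lennard-Jones energy and forces among the bath charges
#'
#' The short-range repulsion keeps opposite charges from collapsing onto
#' each other, the role the solvent force field plays for real point-charge
#' environments.
#' @return list(energy, f_mm)
#' @noRd
mm_coulomb <- function(mm_positions, mm_charges, eps = 0, sigma = 1) {
  m <- nrow(mm_positions)
  f <- matrix(0.0, m, 3); en <- 0.0
  if (m >= 2L) {
    kC <- fh_const$coulomb_ev_ang
    for (j in seq_len(m - 1L)) {
      d <- sweep(mm_positions[(j + 1L):m, , drop = FALSE], 2,
                 mm_positions[j, ], "-")  # R_j' - R_j
      r <- row_norms(d)
      qq <- kC * mm_charges[j] * mm_charges[(j + 1L):m]
      en <- en + sum(qq / r)
      coef <- qq / r^3
      if (eps > 0) {
        sr6 <- (sigma / r)^6
        en <- en + sum(4 * eps * (sr6^2 - sr6))
        coef <- coef + 4 * eps * (12 * sr6^2 - 6 * sr6) / r^2
      }
      fj <- d * coef             # force on j' (repulsive for like signs)
      f[(j + 1L):m, ] <- f[(j + 1L):m, ] + fj
      f[j, ] <- f[j, ] - colSums(fj)
    }
  }
  list(energy = en, f_mm = f)
}

#' Exact oracle labels for one frame
#'
#' Computes, for every adiabatic state: the embedded chromophore energy, the
#' fixed-field (direct) energy gradient on the ML atoms, the Hellmann-Feynman
#' derivative of the energy with respect to the per-atom field, the
#' field-corrected total ML force (direct plus field chain term), and the
#' field-mediated forces on the charge sites.  Bath-level terms
#' (Lennard-Jones and charge-charge Coulomb) are returned separately: they
#' belong to the classical region, not to the learned energy.
#'
#' @param spec an [oracle_spec()]
#' @param bath a [bath_spec()] (supplies the Lennard-Jones parameters)
#' @param frame a [system_frame()]
#' @param prev_vectors optional eigenvector matrix from the previous step;
#'   passed to [adiabatize()] to keep eigenvector signs continuous along a
#'   trajectory
#' @return an object of class `labelled_frame`: list with elements `frame`,
#'   `energies` (eV), `field` (n_ml x 3, a.u.), `direct_gradient`
#'   (ns x n_ml x 3, eV/A), `dE_dfield` (ns x n_ml x 3, eV per a.u.),
#'   `forces_ml` (ns x n_ml x 3, eV/A, field-corrected), `forces_mm`
#'   (ns x n_mm x 3, eV/A, field-mediated), `lj`, `mm_coul`, `vectors`,
#'   `osc_strengths`, `near_degenerate`
#' @export
oracle_labels <- function(spec, bath, frame, prev_vectors = NULL) {
  stopifnot(inherits(spec, "oracle_spec"), inherits(bath, "bath_spec"),
            inherits(frame, "system_frame"))
  n <- spec$n_ml_atoms; ns <- spec$n_states
  m <- nrow(frame$mm_positions)
  if (m > 0L) {
    fs <- electric_field(frame$ml_positions, frame$mm_positions, frame$mm_charges)
    jac <- field_jacobians(frame$ml_positions, frame$mm_positions, frame$mm_charges)
    field <- fs$field
  } else {
    field <- matrix(0.0, n, 3)
    jac <- structure(list(d_field_d_ml = array(0.0, c(n, 3, 3)),
                          d_field_d_mm = array(0.0, c(n, 3, 0, 3))),
                     class = "fh_field_jac")
  }
  H <- diabatic_hamiltonian(spec, frame$ml_positions, field)
  ad <- adiabatize(H, prev_vectors)
  U <- ad$vectors
  derivs <- diabatic_derivatives(spec, frame$ml_positions)
  direct <- array(0.0, c(ns, n, 3))
  deps <- array(0.0, c(ns, n, 3))
  f_ml <- array(0.0, c(ns, n, 3))
  f_mm <- array(0.0, c(ns, m, 3))
  for (k in seq_len(ns)) {
    direct[k, , ] <- sandwich_gradient(derivs, U, k, k)
    w <- U[, k]^2
    dk <- matrix(0.0, n, 3)
    for (a in seq_len(ns)) dk <- dk + w[a] * derivs$dH_deps[a, , ]
    deps[k, , ] <- dk
    f_ml[k, , ] <- assemble_ml_forces(matrix(direct[k, , ], n, 3),
                                      matrix(deps[k, , ], n, 3), jac)
    if (m > 0L)
      f_mm[k, , ] <- assemble_mm_forces(matrix(deps[k, , ], n, 3), jac)
  }
  lj <- lj_interaction(frame$ml_positions, frame$mm_positions,
                       bath$lj_epsilon, bath$lj_sigma)
  mc <- mm_coulomb(frame$mm_positions, frame$mm_charges,
                   bath$lj_epsilon, bath$lj_sigma)
  gaps <- diff(ad$energies)
  structure(list(frame = frame, energies = ad$energies, field = field,
                 direct_gradient = direct, dE_dfield = deps,
                 forces_ml = f_ml, forces_mm = f_mm,
                 lj = lj, mm_coul = mc, vectors = U, jac = jac,
                 osc_strengths = oscillator_strengths(spec, ad),
                 near_degenerate = any(gaps < 1e-10)),
            class = "labelled_frame")
}

#' Oscillator strengths from the oracle transition dipoles
#'
#' f_{0->k} = (2/3) dE |mu_tr|^2 in atomic units, with the fixed diabatic
#' transition dipoles rotated into the adiabatic basis.
#'
#' @param spec an [oracle_spec()]
#' @param ad result of [adiabatize()]
#' @return numeric vector of length n_states (f[1] = 0 for the ground state)
#' @export
oscillator_strengths <- function(spec, ad) {
  ns <- spec$n_states
  U <- ad$vectors
  f <- numeric(ns)
  for (k in 2:ns) {
    mu <- numeric(3)
    for (a in seq_len(ns)) for (b in seq_len(ns))
      mu <- mu + U[a, 1] * U[b, k] * spec$transition_dipoles[a, b, ]
    mu_au <- mu / fh_const$bohr_ang
    de_au <- (ad$energies[k] - ad$energies[1]) / fh_const$hartree_ev
    f[k] <- (2 / 3) * de_au * sum(mu_au^2)
  }
  f
}

#' Exact nonadiabatic coupling vector between two adiabatic states
#'
#' d_kl = <k| dH/dR |l> / (E_l - E_k) on the ML atoms, including the
#' field-mediated position dependence of the Hamiltonian (the chain term
#' through the embedding field).  Antisymmetric under state exchange.
#'
#' @param spec an [oracle_spec()]
#' @param frame a [system_frame()]
#' @param state_pair integer pair `c(k, l)` of 1-based adiabatic indices
#' @return n_ml x 3 matrix (1/Angstrom)
#' @export
oracle_nac <- function(spec, frame, state_pair) {
  stopifnot(length(state_pair) == 2L, state_pair[1] != state_pair[2])
  k <- state_pair[1]; l <- state_pair[2]
  n <- spec$n_ml_atoms
  m <- nrow(frame$mm_positions)
  if (m > 0L) {
    field <- electric_field(frame$ml_positions, frame$mm_positions,
                            frame$mm_charges)$field
    jac <- field_jacobians(frame$ml_positions, frame$mm_positions,
                           frame$mm_charges)
  } else {
    field <- matrix(0.0, n, 3); jac <- NULL
  }
  H <- diabatic_hamiltonian(spec, frame$ml_positions, field)
  ad <- adiabatize(H)
  gap <- ad$energies[l] - ad$energies[k]
  if (abs(gap) <= 1e-8)
    stop("nonadiabatic coupling undefined: states ", k, " and ", l,
         " are degenerate (|gap| <= 1e-8 eV)")
  derivs <- diabatic_derivatives(spec, frame$ml_positions)
  g <- sandwich_gradient(derivs, ad$vectors, k, l)
  # field chain: <k| dH/deps_i |l> . d eps_i / d R_i  (diagonal dipole term)
  if (!is.null(jac)) {
    wt <- ad$vectors[, k] * ad$vectors[, l]
    for (i in seq_len(n)) {
      de <- numeric(3)
      for (a in seq_len(spec$n_states))
        de <- de + wt[a] * derivs$dH_deps[a, i, ]
      g[i, ] <- g[i, ] + as.numeric(de %*% jac$d_field_d_ml[i, , ])
    }
  }
  g / gap
}

#' Total potential energy of a frame on one adiabatic surface
#'
#' Embedded chromophore energy of the active state plus the classical bath
#' terms (ML-MM Lennard-Jones and MM-MM Coulomb).
#'
#' @param labels a `labelled_frame`
#' @param state 1-based adiabatic state index
#' @return scalar energy (eV)
#' @export
total_potential_energy <- function(labels, state) {
  labels$energies[state] + labels$lj$energy + labels$mm_coul$energy
}

#' Kinetic energy of a frame (eV)
#'
#' @param frame a [system_frame()]
#' @param region "ml", "mm" or "all"
#' @return scalar kinetic energy in eV
#' @export
kinetic_energy <- function(frame, region = c("all", "ml", "mm")) {
  region <- match.arg(region)
  ke_ml <- 0.5 * sum(frame$masses * rowSums(frame$ml_velocities^2)) / fh_const$acc_conv
  ke_mm <- if (nrow(frame$mm_positions) > 0)
    0.5 * sum(frame$mm_masses * rowSums(frame$mm_velocities^2)) / fh_const$acc_conv
  else 0.0
  switch(region, all = ke_ml + ke_mm, ml = ke_ml, mm = ke_mm)
}
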