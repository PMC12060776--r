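#' Built-in oracle systems
#'
#' Two ready-made oracle Hamiltonians ship with the package: a five-state,
#' nine-atom furan-like chromophore used as the default study system, and a
#' one-dimensional two-state avoided-crossing model used for integrator and
#' coupling-scheme studies.  Both are fully analytic; their parameters are
#' fixed constructor defaults, not tuning knobs.
#'
#' @name builtin_specs
NULL

#' Furan-like five-state oracle
#'
#' A planar C4H4O ring with per-state shifted harmonic diabats.  Excited
#' minima displace the two alpha carbons away from the oxygen (a ring-opening
#' coordinate) with softened force constants; vertical shifts put the second
#' excited state in a 6-7 eV excitation window and the third in a
#' 7.3-7.5 eV window; the third state carries the largest transition dipole.
#' State dipoles grow with the state index so the embedding field shifts the
#' gaps between surfaces.
#'
#' @param n_states number of states (default 5)
#' @return an [oracle_spec()]
#' @export
default_oracle_spec <- function(n_states = 5L) {
  n_states <- as.integer(n_states)
  stopifnot(n_states >= 2, n_states <= 5)
  geom <- matrix(c(
     0.0000,  1.1637, 0,
     1.0945,  0.3481, 0,
     0.7190, -0.9612, 0,
    -0.7190, -0.9612, 0,
    -1.0945,  0.3481, 0,
     2.0720,  0.8110, 0,
     1.3755, -1.8210, 0,
    -1.3755, -1.8210, 0,
    -2.0720,  0.8110, 0), ncol = 3, byrow = TRUE)
  elements <- c(8L, 6L, 6L, 6L, 6L, 1L, 1L, 1L, 1L)
  n <- nrow(geom)
  fc0 <- ifelse(elements == 1L, 22, 28)
  minima <- array(0.0, c(n_states, n, 3))
  fc <- matrix(0.0, n_states, n)
  # ring-opening displacement: alpha carbons (2, 5) and their hydrogens
  # (6, 9) move away from the oxygen
  dir_c1 <- (geom[2, ] - geom[1, ]) / sqrt(sum((geom[2, ] - geom[1, ])^2))
  dir_c4 <- (geom[5, ] - geom[1, ]) / sqrt(sum((geom[5, ] - geom[1, ])^2))
  for (k in seq_len(n_states)) {
    g <- geom
    d <- 0.06 * (k - 1)
    g[2, ] <- g[2, ] + d * dir_c1; g[6, ] <- g[6, ] + d * dir_c1
    g[5, ] <- g[5, ] + d * dir_c4; g[9, ] <- g[9, ] + d * dir_c4
    minima[k, , ] <- g
    fc[k, ] <- fc0 * (1 - 0.06 * (k - 1))
  }
  shifts <- c(0, 6.2, 6.6, 7.4, 7.8)[seq_len(n_states)]
  coup <- matrix(0.0, n_states, n_states)
  for (k in seq_len(n_states)) for (l in seq_len(n_states)) {
    if (abs(k - l) == 1) coup[k, l] <- 0.06
    if (abs(k - l) == 2) coup[k, l] <- 0.02
  }
  centroid <- colMeans(geom[1:5, ])
  dip <- array(0.0, c(n_states, n, 3))
  for (k in seq_len(n_states)) for (i in seq_len(n)) {
    u <- geom[i, ] - centroid
    u <- u / sqrt(sum(u^2))
    dip[k, i, ] <- (0.05 + 0.03 * (k - 1)) * u + c(0, 0, 0.02 * (-1)^i)
  }
  tdip <- array(0.0, c(n_states, n_states, 3))
  bright <- list(c(0.10, 0, 0), c(0, 0.50, 0), c(0.45, 0, 0), c(0, 0.10, 0))
  for (k in 2:n_states) {
    tdip[1, k, ] <- bright[[k - 1]]
    tdip[k, 1, ] <- bright[[k - 1]]
  }
  for (k in 2:n_states) for (l in 2:n_states) if (k != l) {
    tdip[k, l, ] <- c(0.05, 0.05, 0)
  }
  oracle_spec(n_states, elements, diabatic_minima = minima,
              force_constants = fc, vertical_shifts = shifts,
              diabatic_couplings = coup, state_dipoles = dip,
              transition_dipoles = tdip)
}

#' One-dimensional two-state avoided-crossing oracle
#'
#' A hydrogen diatomic whose two diabats are harmonic in the bond length
#' with different equilibrium separations, split by a constant coupling
#' (gap `2 * coupling` at the crossing).  Started at the short-bond minimum
#' on the upper adiabat, the bond oscillates through the crossing in the
#' mixed Landau-Zener regime (roughly half the population transfers per
#' passage with the defaults) -- the regime where exact and
#' curvature-driven couplings can meaningfully be compared.
#'
#' @param coupling constant diabatic coupling (eV)
#' @param bond_lengths equilibrium separations of the two diabats (Angstrom)
#' @param force_constant per-atom harmonic constant of both diabats
#'   (eV/Angstrom^2)
#' @param field_dipole magnitude of the excited-state dipole along the bond
#'   (e*Angstrom); zero decouples the model from the embedding field
#' @return an [oracle_spec()]
#' @export
two_state_spec <- function(coupling = 0.15, bond_lengths = c(1.2, 2.0),
                           force_constant = 8, field_dipole = 0) {
  stopifnot(length(bond_lengths) == 2L, all(bond_lengths > 0))
  minima <- array(0.0, c(2L, 2L, 3L))
  for (k in 1:2) {
    minima[k, 1, ] <- c(-bond_lengths[k] / 2, 0, 0)
    minima[k, 2, ] <- c(bond_lengths[k] / 2, 0, 0)
  }
  fc <- matrix(force_constant, 2, 2)
  coup <- matrix(c(0, coupling, coupling, 0), 2, 2)
  dip <- array(0.0, c(2, 2, 3))
  dip[2, 1, ] <- c(-field_dipole, 0, 0)
  dip[2, 2, ] <- c(field_dipole, 0, 0)
  tdip <- array(0.0, c(2, 2, 3))
  tdip[1, 2, ] <- c(0.3, 0, 0); tdip[2, 1, ] <- c(0.3, 0, 0)
  oracle_spec(2L, elements = c(1L, 1L), diabatic_minima = minima,
              force_constants = fc, vertical_shifts = c(0, 0),
              diabatic_couplings = coup, state_dipoles = dip,
              transition_dipoles = tdip)
}

#' Frame of the two-state diatomic at a given bond length
#'
#' @param spec a [two_state_spec()]
#' @param bond bond length (Angstrom)
#' @param mm_positions,mm_charges optional charge environment
#' @return a [system_frame()]
#' @export
diatomic_frame <- function(spec, bond, mm_positions = matrix(0, 0, 3),
                           mm_charges = numeric(0)) {
  system_frame(matrix(c(-bond / 2, 0, 0, bond / 2, 0, 0), 2, 3, byrow = TRUE),
               spec$elements, mm_positions, mm_charges, masses = spec$masses)
}

#' Place bath charges in a shell around the chromophore
#'
#' Charges are scattered uniformly in a spherical shell between an inner
#' radius (chromophore extent plus the Lennard-Jones contact distance) and
#' the droplet radius, with a minimum inter-site spacing.
#'
#' @param spec an [oracle_spec()]
#' @param bath a [bath_spec()]
#' @param seed integer RNG seed
#' @return n_charges x 3 matrix of positions (Angstrom)
#' @export
place_bath_charges <- function(spec, bath, seed = 1L) {
  m <- bath$n_charges
  if (m == 0L) return(matrix(0.0, 0, 3))
  geom <- spec$diabatic_minima[1, , , drop = TRUE]
  if (spec$n_ml_atoms == 1L) geom <- matrix(geom, 1, 3)
  centre <- colMeans(geom)
  extent <- max(row_norms(sweep(geom, 2, centre, "-")))
  r_in <- extent + 0.95 * bath$lj_sigma
  r_out <- max(bath$box_length / 2, r_in + 1.5)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(fh_seed(seed, "bath_placement"))
  pos <- matrix(0.0, m, 3)
  placed <- 0L
  tries <- 0L
  min_sep <- bath$lj_sigma  # never start inside the Lennard-Jones wall
  while (placed < m && tries < 20000L) {
    tries <- tries + 1L
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    r <- (r_in^3 + stats::runif(1) * (r_out^3 - r_in^3))^(1 / 3)
    p <- centre + r * u
    ok <- placed == 0L ||
      min(row_norms(sweep(pos[seq_len(placed), , drop = FALSE], 2, p, "-"))) > min_sep
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- p
    }
  }
  if (placed < m) stop("could not place ", m, " charges; enlarge box_length")
  pos
}

#' Reference frame: chromophore at its ground-state minimum in a fresh bath
#'
#' @inheritParams place_bath_charges
#' @return a [system_frame()]
#' @export
reference_frame <- function(spec, bath, seed = 1L) {
  geom <- spec$diabatic_minima[1, , , drop = TRUE]
  if (spec$n_ml_atoms == 1L) geom <- matrix(geom, 1, 3)
  system_frame(ml_positions = geom, ml_elements = spec$elements,
               mm_positions = place_bath_charges(spec, bath, seed),
               mm_charges = bath$charges, masses = spec$masses)
}

# Save/restore the global RNG state so constructors with internal seeding
# do not perturb the caller's random stream.
#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
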