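#' Electrostatic embedding algebra
#'
#' The environment enters the chromophore ("ML region") Hamiltonian only
#' through the electric field created by its point charges at the ML-atom
#' positions.  This file implements that field, the electrostatic potential
#' it derives from, the analytic Jacobians of the field with respect to ML
#' and MM coordinates, and the assembly of the field-corrected forces on
#' both regions.  The field sum runs over *all* charges with no cutoff, so a
#' finite charge cluster makes the algebra exact.
#'
#' Unit conventions: positions in Angstrom, charges in elementary charges,
#' fields in atomic units (Hartree/(e*bohr)).  With v the potential in
#' atomic units, the field obeys eps = -bohr_ang * d v / d R[Angstrom].
#'
#' @name embedding
NULL

.FH_MIN_DIST <- 1e-6  # Angstrom; frames with closer ML-MM pairs are rejected

#' Electrostatic potential of a point-charge set
#'
#' v(r) = sum_j q_j / |r - R_j| in atomic units (Hartree per elementary
#' charge), with inputs in Angstrom and elementary charges.
#'
#' @param point numeric length-3 position (Angstrom)
#' @param mm_positions n_mm x 3 matrix of charge positions (Angstrom)
#' @param mm_charges numeric vector of partial charges (e)
#' @return scalar potential in atomic units
#' @export
electrostatic_potential <- function(point, mm_positions, mm_charges) {
  stopifnot(length(point) == 3L)
  check_mat3(mm_positions, length(mm_charges), "mm_positions")
  d <- sweep(mm_positions, 2, point, "-")
  r <- row_norms(d)
  if (any(r < .FH_MIN_DIST))
    stop("singularity: evaluation point coincides with a charge site")
  fh_const$bohr_ang * sum(mm_charges / r)
}

#' Electric field of the charge environment at the ML atoms
#'
#' eps_i = sum_j q_j (R_i - R_j) / |R_i - R_j|^3 in atomic units; the sum
#' runs over every charge site (no cutoff).
#'
#' @param ml_positions n_ml x 3 matrix (Angstrom)
#' @param mm_positions n_mm x 3 matrix (Angstrom)
#' @param mm_charges numeric vector (e)
#' @return object of class `fh_field`: list with `field` (n_ml x 3 matrix,
#'   atomic units) and `source_hash` identifying the generating environment
#' @export
electric_field <- function(ml_positions, mm_positions, mm_charges) {
  n_ml <- nrow(ml_positions)
  check_mat3(ml_positions, n_ml, "ml_positions")
  check_mat3(mm_positions, length(mm_charges), "mm_positions")
  b2 <- fh_const$bohr_ang^2
  f <- matrix(0.0, n_ml, 3)
  for (i in seq_len(n_ml)) {
    d <- sweep(-mm_positions, 2, ml_positions[i, ], "+")  # R_i - R_j
    r <- row_norms(d)
    if (any(r < .FH_MIN_DIST))
      stop("singularity: ML atom ", i, " coincides with a charge site")
    f[i, ] <- b2 * colSums(d * (mm_charges / r^3))
  }
  structure(list(field = f,
                 source_hash = fh_hash(list(mm_positions, mm_charges))),
            class = "fh_field")
}

#' Analytic Jacobians of the embedding field
#'
#' Closed-form dipole-tensor blocks of d eps_i / d R.  Among ML atoms,
#' eps_i depends only on R_i, so the ML Jacobian is stored as one 3 x 3
#' block per atom.  The blocks satisfy the translation identity
#' d eps_i / d R_i^ML = - sum_j d eps_i / d R_j^MM.
#'
#' @inheritParams electric_field
#' @return object of class `fh_field_jac`: list with
#'   `d_field_d_ml` (array n_ml x 3 x 3; [i, a, b] = d eps_{i,a} / d R_{i,b})
#'   and `d_field_d_mm` (array n_ml x 3 x n_mm x 3), both in atomic-unit
#'   field per Angstrom
#' @export
field_jacobians <- function(ml_positions, mm_positions, mm_charges) {
  n_ml <- nrow(ml_positions)
  n_mm <- nrow(mm_positions)
  check_mat3(ml_positions, n_ml, "ml_positions")
  check_mat3(mm_positions, length(mm_charges), "mm_positions")
  b2 <- fh_const$bohr_ang^2
  jml <- array(0.0, c(n_ml, 3, 3))
  jmm <- array(0.0, c(n_ml, 3, n_mm, 3))
  I3 <- diag(3)
  for (i in seq_len(n_ml)) {
    d <- sweep(-mm_positions, 2, ml_positions[i, ], "+")
    r <- row_norms(d)
    if (any(r < .FH_MIN_DIST))
      stop("singularity: ML atom ", i, " coincides with a charge site")
    for (j in seq_len(n_mm)) {
      blk <- b2 * mm_charges[j] *
        (I3 / r[j]^3 - 3 * tcrossprod(d[j, ]) / r[j]^5)
      jml[i, , ] <- jml[i, , ] + blk
      jmm[i, , j, ] <- -blk
    }
  }
  structure(list(d_field_d_ml = jml, d_field_d_mm = jmm),
            class = "fh_field_jac")
}

#' Assemble field-corrected forces on the ML atoms
#'
#' F_ML = -dE/dR_ML - sum_i (dE/deps_i) . (d eps_i / d R_ML): the direct
#' (fixed-field) gradient plus the chain-rule term through the embedding
#' field.  With zero field gradients this reduces to the plain negative
#' gradient.
#'
#' @param direct_gradient n_ml x 3 matrix, dE/dR at fixed field (eV/Angstrom)
#' @param dE_dfield n_ml x 3 matrix, dE/deps (eV per atomic-unit field)
#' @param jac `fh_field_jac` from [field_jacobians()]
#' @return n_ml x 3 force matrix (eV/Angstrom)
#' @export
assemble_ml_forces <- function(direct_gradient, dE_dfield, jac) {
  n_ml <- nrow(direct_gradient)
  check_mat3(direct_gradient, n_ml, "direct_gradient")
  check_mat3(dE_dfield, n_ml, "dE_dfield")
  if (!inherits(jac, "fh_field_jac") || dim(jac$d_field_d_ml)[1] != n_ml)
    stop("jac must be an fh_field_jac for the same frame")
  chain <- matrix(0.0, n_ml, 3)
  for (i in seq_len(n_ml))
    chain[i, ] <- as.numeric(dE_dfield[i, ] %*% jac$d_field_d_ml[i, , ])
  -(direct_gradient + chain)
}

#' Assemble the field-mediated forces on the MM charges
#'
#' F_MM,j = - sum_i (dE/deps_i) . (d eps_i / d R_j): the contribution of the
#' ML-region energy to the forces on the environment sites.  Together with
#' the chain term of [assemble_ml_forces()] these sum to zero (the embedding
#' field is translation invariant).
#'
#' @inheritParams assemble_ml_forces
#' @return n_mm x 3 force matrix (eV/Angstrom)
#' @export
assemble_mm_forces <- function(dE_dfield, jac) {
  if (!inherits(jac, "fh_field_jac")) stop("jac must be an fh_field_jac")
  dims <- dim(jac$d_field_d_mm)
  n_ml <- dims[1]; n_mm <- dims[3]
  check_mat3(dE_dfield, n_ml, "dE_dfield")
  f <- matrix(0.0, n_mm, 3)
  for (j in seq_len(n_mm)) {
    acc <- numeric(3)
    for (i in seq_len(n_ml))
      acc <- acc + as.numeric(dE_dfield[i, ] %*% jac$d_field_d_mm[i, , j, ])
    f[j, ] <- -acc
  }
  f
}
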