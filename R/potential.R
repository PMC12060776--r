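#' Field-aware multi-state potential
#'
#' The regressor maps ML-region coordinates plus the per-atom embedding
#' field to all adiabatic state energies at once.  Atoms are featurised by
#' smooth rotation-invariant descriptors -- a radial Gaussian basis of
#' neighbour distances resolved by neighbour element, the projections of the
#' atom's field vector onto the interatomic unit vectors in the same radial
#' basis, and the squared field norm -- and a per-element linear multi-state
#' readout maps descriptors to energies.  Everything is analytic: energy
#' gradients with respect to positions (at fixed field) and with respect to
#' the field are closed-form, which keeps the training losses and the
#' dynamics forces exactly consistent.  Energies are invariant under rigid
#' rotations (applied to positions and field vectors together),
#' translations, and permutations of same-element atoms.
#'
#' @name potential
NULL

#' Regressor hyperparameters
#'
#' @param cutoff radial cutoff for the neighbour featurisation (Angstrom)
#' @param n_radial_basis number of equidistant Gaussians on `[0, cutoff]`
#' @param n_interactions,feature_width,readout_widths accepted and recorded
#'   for completeness; the linear readout over fixed invariant descriptors
#'   does not consume them
#' @param n_states number of electronic states predicted jointly
#' @return an object of class `model_config`
#' @export
model_config <- function(cutoff = 10, n_radial_basis = 50L,
                         n_interactions = 6L, feature_width = 256L,
                         readout_widths = c(256L, 128L, 64L, 32L, 16L),
                         n_states = 5L) {
  stopifnot(cutoff > 0, n_radial_basis >= 2, n_states >= 2,
            all(readout_widths > 0), !is.unsorted(rev(readout_widths)))
  structure(list(cutoff = cutoff, n_radial_basis = as.integer(n_radial_basis),
                 n_interactions = as.integer(n_interactions),
                 feature_width = as.integer(feature_width),
                 readout_widths = as.integer(readout_widths),
                 n_states = as.integer(n_states)),
            class = "model_config")
}

#' Training hyperparameters
#'
#' Defaults: energy weight 1, force weight 10, Adam with starting step size
#' 1e-5 and moments 0.9/0.999, plateau scheduler that multiplies the step
#' size by 0.8 after 20 stale validation epochs, early stop below 1e-6, at
#' most 5000 epochs, batches of 10 frames.
#'
#' @param w_energy,w_force loss weights (>= 0)
#' @param lr0 initial Adam step size
#' @param plateau_patience epochs without validation improvement before decay
#' @param lr_decay multiplicative step-size decay in (0, 1)
#' @param lr_floor stop training once the step size falls below this
#' @param max_epochs maximum training epochs
#' @param batch_size frames per mini-batch
#' @param seed integer seed (initialisation and batch shuffling)
#' @param loss "augmented" (force term includes the field-mediated gradient)
#'   or "standard"
#' @return an object of class `train_config`
#' @export
train_config <- function(w_energy = 1, w_force = 10, lr0 = 1e-5,
                         plateau_patience = 20L, lr_decay = 0.8,
                         lr_floor = 1e-6, max_epochs = 5000L, batch_size = 10L,
                         seed = 1L, loss = c("augmented", "standard")) {
  loss <- match.arg(loss)
  stopifnot(w_energy >= 0, w_force >= 0, lr0 > 0, lr_decay > 0, lr_decay < 1,
            lr_floor > 0, max_epochs >= 1, batch_size >= 1)
  structure(list(w_energy = w_energy, w_force = w_force, lr0 = lr0,
                 plateau_patience = as.integer(plateau_patience),
                 lr_decay = lr_decay, lr_floor = lr_floor,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss = loss),
            class = "train_config")
}

#' Build an untrained model
#'
#' Weights start at zero (constant energies, zero gradients); training
#' initialises them from its seed.
#'
#' @param config a [model_config()]
#' @param elements atomic numbers the model will accept
#' @return an object of class `fh_model`
#' @export
build_model <- function(config, elements) {
  stopifnot(inherits(config, "model_config"))
  alphabet <- sort(unique(as.integer(elements)))
  ne <- length(alphabet)
  nb <- config$n_radial_basis
  n_feat <- nb * ne + nb + 1L
  centers <- seq(0, config$cutoff, length.out = nb)
  gamma <- 1 / (2 * (centers[2] - centers[1])^2)
  structure(list(config = config, alphabet = alphabet,
                 n_feat = n_feat, centers = centers, gamma = gamma,
                 weights = array(0.0, c(config$n_states, ne, n_feat)),
                 bias = matrix(0.0, config$n_states, ne),
                 scale = rep(1.0, n_feat),
                 units = "eV, Angstrom, atomic-unit field"),
            class = "fh_model")
}

#' Invariant descriptors and their analytic derivatives for one frame
#'
#' @return list with `d` (n x n_feat), `grad_pos` (n x n_feat x n x 3),
#'   `grad_field` (n x n_feat x 3)
#' @noRd
fh_descriptors <- function(model, ml_positions, ml_elements, field) {
  n <- nrow(ml_positions)
  nb <- model$config$n_radial_basis
  ne <- length(model$alphabet)
  nf <- model$n_feat
  rc <- model$config$cutoff
  mu <- model$centers; gam <- model$gamma
  d <- matrix(0.0, n, nf)
  gp <- array(0.0, c(n, nf, n, 3))
  gf <- array(0.0, c(n, nf, 3))
  eidx <- match(ml_elements, model$alphabet)
  if (anyNA(eidx)) stop("element not in the model's training alphabet")
  q_slot <- nf
  for (i in seq_len(n)) {
    eps_i <- field[i, ]
    d[i, q_slot] <- sum(eps_i^2)
    gf[i, q_slot, ] <- 2 * eps_i
    for (j in seq_len(n)) {
      if (j == i) next
      dv <- ml_positions[i, ] - ml_positions[j, ]
      r <- sqrt(sum(dv^2))
      if (r >= rc) next
      u <- dv / r
      fc <- 0.5 * (cos(pi * r / rc) + 1)
      dfc <- -0.5 * pi / rc * sin(pi * r / rc)
      g <- exp(-gam * (r - mu)^2)
      phi <- g * fc
      dphi <- g * (-2 * gam * (r - mu) * fc + dfc)
      slots_r <- (eidx[j] - 1L) * nb + seq_len(nb)
      d[i, slots_r] <- d[i, slots_r] + phi
      for (b in seq_len(nb)) {
        s <- slots_r[b]
        gp[i, s, i, ] <- gp[i, s, i, ] + dphi[b] * u
        gp[i, s, j, ] <- gp[i, s, j, ] - dphi[b] * u
      }
      slots_p <- ne * nb + seq_len(nb)
      pe <- sum(eps_i * u)
      d[i, slots_p] <- d[i, slots_p] + pe * phi
      perp <- (eps_i - pe * u) / r
      for (b in seq_len(nb)) {
        s <- slots_p[b]
        vec <- pe * dphi[b] * u + phi[b] * perp
        gp[i, s, i, ] <- gp[i, s, i, ] + vec
        gp[i, s, j, ] <- gp[i, s, j, ] - vec
        gf[i, s, ] <- gf[i, s, ] + u * phi[b]
      }
    }
  }
  list(d = d, grad_pos = gp, grad_field = gf, eidx = eidx)
}

#' Predict energies and analytic gradients for one frame
#'
#' @param model an `fh_model`
#' @param ml_positions n x 3 matrix (Angstrom)
#' @param ml_elements atomic numbers (must be in the model alphabet)
#' @param field n x 3 per-atom field matrix (atomic units) or an `fh_field`
#' @return an object of class `prediction_bundle`: list with `energies`
#'   (eV), `direct_gradients` (ns x n x 3: dE/dR at fixed field, eV/A) and
#'   `field_gradients` (ns x n x 3: dE/deps, eV per a.u. field)
#' @export
predict_bundle <- function(model, ml_positions, ml_elements, field) {
  stopifnot(inherits(model, "fh_model"))
  if (inherits(field, "fh_field")) field <- field$field
  n <- nrow(ml_positions)
  check_mat3(field, n, "field")
  ns <- model$config$n_states
  ds <- fh_descriptors(model, ml_positions, ml_elements, field)
  dsc <- sweep(ds$d, 2, model$scale, "/")
  energies <- numeric(ns)
  dgrad <- array(0.0, c(ns, n, 3))
  fgrad <- array(0.0, c(ns, n, 3))
  for (k in seq_len(ns)) {
    for (i in seq_len(n)) {
      w <- model$weights[k, ds$eidx[i], ] / model$scale
      energies[k] <- energies[k] + sum(model$weights[k, ds$eidx[i], ] * dsc[i, ]) +
        model$bias[k, ds$eidx[i]]
      for (a in seq_len(3))
        dgrad[k, , a] <- dgrad[k, , a] + as.numeric(w %*% ds$grad_pos[i, , , a])
      fgrad[k, i, ] <- fgrad[k, i, ] + as.numeric(w %*% ds$grad_field[i, , ])
    }
  }
  structure(list(energies = energies, direct_gradients = dgrad,
                 field_gradients = fgrad),
            class = "prediction_bundle")
}

#' Field-corrected per-state forces from a prediction
#'
#' Delegates to the embedding module: the ML forces are the negative direct
#' gradient plus the field chain term; the MM forces carry only the
#' field-mediated term.
#'
#' @param bundle a [predict_bundle()] result
#' @param jac `fh_field_jac` for the same frame
#' @param state 1-based state index
#' @return list with `f_ml` (n_ml x 3) and `f_mm` (n_mm x 3), eV/Angstrom
#' @export
ml_forces <- function(bundle, jac, state) {
  ns <- length(bundle$energies)
  if (state < 1 || state > ns) stop("state index out of range")
  n <- dim(bundle$direct_gradients)[2]
  dg <- matrix(bundle$direct_gradients[state, , ], n, 3)
  fg <- matrix(bundle$field_gradients[state, , ], n, 3)
  list(f_ml = assemble_ml_forces(dg, fg, jac),
       f_mm = assemble_mm_forces(fg, jac))
}

#' @noRd
.force_ref <- function(lab) {
  ns <- dim(lab$forces_ml)[1]
  lab$forces_ml
}

#' Standard energy + force loss
#'
#' Mean squared error over states of the energies plus the weighted mean
#' squared error over states and all 3 N_ML components of the forces, where
#' the predicted force is the plain negative direct gradient (no field
#' chain term) and the reference is the full embedded force.  Averaging
#' convention: mean over frames, states and force components.
#'
#' @param preds list of [predict_bundle()] results
#' @param labels list of `labelled_frame`s, matched to `preds`
#' @param weights numeric pair `c(w_energy, w_force)`
#' @return list with `total`, `energy_term`, `force_term`
#' @export
loss_standard <- function(preds, labels, weights = c(1, 10)) {
  if (length(preds) != length(labels)) stop("preds/labels length mismatch")
  e_acc <- 0.0; f_acc <- 0.0
  for (t in seq_along(preds)) {
    p <- preds[[t]]; l <- labels[[t]]
    ns <- length(p$energies)
    e_acc <- e_acc + mean((p$energies - l$energies)^2)
    fhat <- -p$direct_gradients
    f_acc <- f_acc + mean((fhat - .force_ref(l))^2)
  }
  nfrm <- length(preds)
  et <- weights[1] * e_acc / nfrm
  ft <- weights[2] * f_acc / nfrm
  list(total = et + ft, energy_term = et, force_term = ft)
}

#' Augmented (field-consistent) loss
#'
#' Same as [loss_standard()] but the predicted force includes the
#' field-mediated chain term, matching the forces actually used in
#' dynamics.  Reduces exactly to the standard loss when all field gradients
#' vanish.
#'
#' @inheritParams loss_standard
#' @param jacobians list of `fh_field_jac`, matched to the frames
#' @return list with `total`, `energy_term`, `force_term`
#' @export
loss_augmented <- function(preds, labels, weights = c(1, 10), jacobians) {
  if (missing(jacobians) || is.null(jacobians))
    stop("augmented loss requires the field Jacobians")
  if (length(preds) != length(labels) || length(jacobians) != length(preds))
    stop("preds/labels/jacobians length mismatch")
  e_acc <- 0.0; f_acc <- 0.0
  for (t in seq_along(preds)) {
    p <- preds[[t]]; l <- labels[[t]]
    ns <- length(p$energies)
    n <- dim(p$direct_gradients)[2]
    e_acc <- e_acc + mean((p$energies - l$energies)^2)
    sq <- 0.0
    for (k in seq_len(ns)) {
      f <- ml_forces(p, jacobians[[t]], k)$f_ml
      sq <- sq + mean((f - matrix(.force_ref(l)[k, , ], n, 3))^2)
    }
    f_acc <- f_acc + sq / ns
  }
  nfrm <- length(preds)
  et <- weights[1] * e_acc / nfrm
  ft <- weights[2] * f_acc / nfrm
  list(total = et + ft, energy_term = et, force_term = ft)
}

#' Per-frame design matrices for linear training
#' @noRd
fh_design <- function(model, lab) {
  fr <- lab$frame
  n <- nrow(fr$ml_positions)
  ne <- length(model$alphabet)
  nf <- model$n_feat
  P <- ne * nf + ne
  ds <- fh_descriptors(model, fr$ml_positions, fr$ml_elements, lab$field)
  a <- numeric(P)
  for (i in seq_len(n)) {
    off <- (ds$eidx[i] - 1L) * nf
    a[off + seq_len(nf)] <- a[off + seq_len(nf)] + ds$d[i, ] / model$scale
    a[ne * nf + ds$eidx[i]] <- a[ne * nf + ds$eidx[i]] + 1
  }
  B <- matrix(0.0, 3L * n, P)   # dE/dx = B theta (fixed field)
  C <- matrix(0.0, 3L * n, P)   # field chain term = C theta
  for (i in seq_len(n)) {
    off <- (ds$eidx[i] - 1L) * nf
    for (f in seq_len(nf)) {
      col <- off + f
      sc <- model$scale[f]
      B[, col] <- B[, col] + as.vector(t(ds$grad_pos[i, f, , ])) / sc
      gfv <- ds$grad_field[i, f, ]
      if (any(gfv != 0)) {
        rows <- (i - 1L) * 3L + 1:3
        C[rows, col] <- C[rows, col] +
          as.numeric(gfv %*% lab$jac$d_field_d_ml[i, , ]) / sc
      }
    }
  }
  list(a = a, B = B, C = C,
       E = lab$energies,
       Fref = t(apply(lab$forces_ml, 1, function(m) as.vector(t(m)))))
}

#' Train the multi-state potential
#'
#' Adam on the standard or augmented loss with mini-batches of frames, a
#' plateau step-size scheduler driven by the validation value of the same
#' loss, early stopping at the step-size floor, and best-validation
#' checkpoint selection.  Deterministic for a fixed seed.
#'
#' @param archive an `fh_archive` of labelled frames (see
#'   [generate_reference_dataset()])
#' @param split list with integer index vectors `train` and `validation`
#'   (disjoint), e.g. from [make_split()]
#' @param model_cfg a [model_config()]
#' @param train_cfg a [train_config()]
#' @return an object of class `fh_fit`: list with `model` (best-validation
#'   `fh_model`), `history` (data.frame epoch/train_loss/val_loss/lr),
#'   `train_cfg`, `split_hash`
#' @export
train_potential <- function(archive, split, model_cfg, train_cfg) {
  stopifnot(inherits(model_cfg, "model_config"),
            inherits(train_cfg, "train_config"))
  idx_tr <- split$train; idx_va <- split$validation
  if (length(idx_tr) == 0L) stop("empty training split")
  if (length(intersect(idx_tr, idx_va)) > 0L)
    stop("train/validation splits overlap")
  labs <- archive$frames
  elements <- labs[[1]]$frame$ml_elements
  model <- build_model(model_cfg, elements)
  ns <- model_cfg$n_states
  if (length(labs[[1]]$energies) != ns)
    stop("archive state count does not match model_cfg$n_states")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(fh_seed(train_cfg$seed, "train"))

  # feature scale from the raw training descriptors
  raw <- lapply(idx_tr, function(t) {
    l <- labs[[t]]
    fh_descriptors(model, l$frame$ml_positions, l$frame$ml_elements, l$field)$d
  })
  pool <- do.call(rbind, raw)
  model$scale <- pmax(apply(pool, 2, stats::sd), 1e-8)

  des_tr <- lapply(labs[idx_tr], function(l) fh_design(model, l))
  des_va <- lapply(labs[idx_va], function(l) fh_design(model, l))
  P <- length(des_tr[[1]]$a)
  n3 <- nrow(des_tr[[1]]$B)
  use_aug <- train_cfg$loss == "augmented"
  M_tr <- lapply(des_tr, function(d) if (use_aug) d$B + d$C else d$B)
  M_va <- lapply(des_va, function(d) if (use_aug) d$B + d$C else d$B)

  theta <- matrix(stats::rnorm(ns * P, sd = 1e-3), ns, P)
  wE <- train_cfg$w_energy; wF <- train_cfg$w_force

  loss_of <- function(des, M, th) {
    if (length(des) == 0L) return(NA_real_)
    acc <- 0.0
    for (t in seq_along(des)) {
      d <- des[[t]]
      for (k in seq_len(ns)) {
        eh <- sum(d$a * th[k, ])
        fres <- -(M[[t]] %*% th[k, ])[, 1] - d$Fref[k, ]
        acc <- acc + wE * (eh - d$E[k])^2 / ns + wF * mean(fres^2) / ns
      }
    }
    acc / length(des)
  }
  grad_of <- function(batch, th) {
    g <- matrix(0.0, ns, P)
    for (t in batch) {
      d <- des_tr[[t]]; M <- M_tr[[t]]
      for (k in seq_len(ns)) {
        eh <- sum(d$a * th[k, ])
        g[k, ] <- g[k, ] + (2 * wE / ns) * (eh - d$E[k]) * d$a
        fres <- (M %*% th[k, ])[, 1] + d$Fref[k, ]
        g[k, ] <- g[k, ] + (2 * wF / (ns * n3)) * as.numeric(crossprod(M, fres))
      }
    }
    g / length(batch)
  }

  m1 <- matrix(0.0, ns, P); m2 <- matrix(0.0, ns, P)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  lr <- train_cfg$lr0
  best_val <- Inf; best_theta <- theta; stale <- 0L; it <- 0L
  hist <- vector("list", train_cfg$max_epochs)
  ntr <- length(des_tr)
  for (epoch in seq_len(train_cfg$max_epochs)) {
    perm <- sample.int(ntr)
    batches <- split(perm, ceiling(seq_along(perm) / train_cfg$batch_size))
    for (b in batches) {
      it <- it + 1L
      g <- grad_of(b, theta)
      m1 <- b1 * m1 + (1 - b1) * g
      m2 <- b2 * m2 + (1 - b2) * g^2
      mh <- m1 / (1 - b1^it); vh <- m2 / (1 - b2^it)
      theta <- theta - lr * mh / (sqrt(vh) + epsA)
    }
    tr_loss <- loss_of(des_tr, M_tr, theta)
    va_loss <- loss_of(des_va, M_va, theta)
    if (!is.finite(tr_loss))
      stop("training loss became non-finite at epoch ", epoch)
    hist[[epoch]] <- c(epoch = epoch, train_loss = tr_loss,
                       val_loss = va_loss, lr = lr)
    metric <- if (is.na(va_loss)) tr_loss else va_loss
    if (metric < best_val - 1e-15) {
      best_val <- metric; best_theta <- theta; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= train_cfg$plateau_patience) {
        lr <- lr * train_cfg$lr_decay
        stale <- 0L
        if (lr < train_cfg$lr_floor) break
      }
    }
  }
  hist <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
  ne <- length(model$alphabet); nf <- model$n_feat
  for (k in seq_len(ns)) {
    model$weights[k, , ] <- matrix(best_theta[k, seq_len(ne * nf)], ne, nf,
                                   byrow = TRUE)
    model$bias[k, ] <- best_theta[k, ne * nf + seq_len(ne)]
  }
  structure(list(model = model, history = hist, train_cfg = train_cfg,
                 best_val = best_val,
                 split_hash = fh_hash(split)),
            class = "fh_fit")
}

#' Error statistics of a model on labelled frames
#'
#' Per-state and state-averaged MAE and RMSE for energies (kcal/mol) and
#' for the field-corrected total forces (kcal/(mol*Angstrom)).
#'
#' @param model an `fh_model` (or an `fh_fit`)
#' @param frames list of `labelled_frame`s
#' @return an object of class `fh_error_report`: data.frame with one row
#'   per state plus an "average" row
#' @export
evaluate_errors <- function(model, frames) {
  if (inherits(model, "fh_fit")) model <- model$model
  if (length(frames) == 0L) stop("empty frame set")
  ns <- model$config$n_states
  e_err <- matrix(0.0, length(frames), ns)
  f_sq <- matrix(0.0, length(frames), ns)
  f_abs <- matrix(0.0, length(frames), ns)
  for (t in seq_along(frames)) {
    l <- frames[[t]]
    n <- nrow(l$frame$ml_positions)
    p <- predict_bundle(model, l$frame$ml_positions, l$frame$ml_elements,
                        l$field)
    for (k in seq_len(ns)) {
      e_err[t, k] <- p$energies[k] - l$energies[k]
      fhat <- ml_forces(p, l$jac, k)$f_ml
      dd <- fhat - matrix(l$forces_ml[k, , ], n, 3)
      f_sq[t, k] <- mean(dd^2)
      f_abs[t, k] <- mean(abs(dd))
    }
  }
  kc <- fh_const$ev_kcalmol
  per_state <- data.frame(
    state = seq_len(ns),
    mae_energy = colMeans(abs(e_err)) * kc,
    rmse_energy = sqrt(colMeans(e_err^2)) * kc,
    mae_force = colMeans(f_abs) * kc,
    rmse_force = sqrt(colMeans(f_sq)) * kc)
  avg <- data.frame(state = NA_integer_,
                    mae_energy = mean(per_state$mae_energy),
                    rmse_energy = mean(per_state$rmse_energy),
                    mae_force = mean(per_state$mae_force),
                    rmse_force = mean(per_state$rmse_force))
  structure(rbind(per_state, avg), class = c("fh_error_report", "data.frame"))
}

#' Wrap a trained model as a dynamics potential
#'
#' The model supplies the embedded state energies and field-corrected
#' forces; the classical bath terms (Lennard-Jones, charge-charge Coulomb)
#' are evaluated analytically from the bath parameters.  No exact couplings
#' are available: use the curvature-driven scheme.
#'
#' @param model an `fh_model` (or `fh_fit`)
#' @param bath a [bath_spec()]
#' @return an object of class `fh_potential`
#' @export
model_potential <- function(model, bath) {
  if (inherits(model, "fh_fit")) model <- model$model
  force(bath)
  ns <- model$config$n_states
  evalfun <- function(frame, need_nac = FALSE, prev_vectors = NULL) {
    if (need_nac) stop("learned potential provides no exact couplings")
    n <- nrow(frame$ml_positions)
    m <- nrow(frame$mm_positions)
    if (m > 0L) {
      field <- electric_field(frame$ml_positions, frame$mm_positions,
                              frame$mm_charges)$field
      jac <- field_jacobians(frame$ml_positions, frame$mm_positions,
                             frame$mm_charges)
    } else {
      field <- matrix(0.0, n, 3)
      jac <- structure(list(d_field_d_ml = array(0.0, c(n, 3, 3)),
                            d_field_d_mm = array(0.0, c(n, 3, 0, 3))),
                       class = "fh_field_jac")
    }
    p <- predict_bundle(model, frame$ml_positions, frame$ml_elements, field)
    f_ml <- array(0.0, c(ns, n, 3))
    f_mm <- array(0.0, c(ns, m, 3))
    for (k in seq_len(ns)) {
      fk <- ml_forces(p, jac, k)
      f_ml[k, , ] <- fk$f_ml
      if (m > 0L) f_mm[k, , ] <- fk$f_mm
    }
    lj <- lj_interaction(frame$ml_positions, frame$mm_positions,
                         bath$lj_epsilon, bath$lj_sigma)
    mc <- mm_coulomb(frame$mm_positions, frame$mm_charges,
                   bath$lj_epsilon, bath$lj_sigma)
    list(energies = p$energies, forces_ml = f_ml, forces_mm = f_mm,
         bath_f_ml = lj$f_ml, bath_f_mm = lj$f_mm + mc$f_mm,
         bath_energy = lj$energy + mc$energy, vectors = NULL)
  }
  structure(list(n_states = ns, has_nac = FALSE, eval = evalfun,
                 model = model, bath = bath),
            class = "fh_potential")
}
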