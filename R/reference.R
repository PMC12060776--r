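#' Reference datasets from oracle surface-hopping dynamics
#'
#' Runs the surface-hopping engine with the analytic oracle as the
#' potential, archiving every visited frame with its exact labels
#' (energies, forces, fields, field derivatives).  These archives stand in
#' for expensive electronic-structure reference trajectories and feed the
#' training and evaluation modules.
#'
#' @name reference
NULL

#' Empty labelled-frame archive
#'
#' @param n_states number of electronic states the labels carry
#' @param spec_hash identifier of the generating oracle/bath
#' @return an object of class `fh_archive`: `frames` (list of
#'   `labelled_frame`), `meta` (data.frame: trajectory_id, time, frame_idx,
#'   active_state), `traj_meta` (per-trajectory seed/truncation table),
#'   `n_states`, `spec_hash`, `schema_version`
#' @export
archive_new <- function(n_states, spec_hash = "") {
  structure(list(frames = list(),
                 meta = data.frame(trajectory_id = integer(0),
                                   time = numeric(0),
                                   frame_idx = integer(0),
                                   active_state = integer(0)),
                 traj_meta = data.frame(trajectory_id = integer(0),
                                        seed = integer(0),
                                        truncated = logical(0),
                                        n_frames = integer(0)),
                 n_states = as.integer(n_states), spec_hash = spec_hash,
                 schema_version = 1L),
            class = "fh_archive")
}

#' Number of frames in an archive
#' @param archive an `fh_archive`
#' @return integer frame count
#' @export
archive_size <- function(archive) length(archive$frames)

#' Append the labelled frames of one trajectory to an archive
#'
#' @param archive an `fh_archive`
#' @param labels list of `labelled_frame`s (one per recorded step)
#' @param record the `fh_trajectory` they came from
#' @param trajectory_id unique integer id
#' @param seed the seed the trajectory ran with
#' @return the extended archive (stable ordering)
#' @export
archive_append <- function(archive, labels, record, trajectory_id, seed = NA_integer_) {
  stopifnot(inherits(archive, "fh_archive"))
  nf <- length(labels)
  if (trajectory_id %in% archive$traj_meta$trajectory_id)
    stop("trajectory id ", trajectory_id, " already archived")
  archive$frames <- c(archive$frames, labels)
  archive$meta <- rbind(archive$meta, data.frame(
    trajectory_id = rep(as.integer(trajectory_id), nf),
    time = record$steps$time[seq_len(nf)],
    frame_idx = seq_len(nf) - 1L,
    active_state = record$steps$active[seq_len(nf)]))
  archive$traj_meta <- rbind(archive$traj_meta, data.frame(
    trajectory_id = as.integer(trajectory_id), seed = as.integer(seed),
    truncated = isTRUE(record$truncated), n_frames = as.integer(nf)))
  archive
}

#' Generate a reference dataset of oracle trajectories
#'
#' Samples ground-state initial conditions, selects the initially excited
#' state (fixed, or stochastically from oscillator strengths inside an
#' excitation window), runs one surface-hopping trajectory per initial
#' condition with the oracle potential, and archives every frame's exact
#' labels.  Trajectories whose total energy blows up are truncated and
#' flagged rather than discarded.  Deterministic for a fixed seed.
#'
#' @param spec an [oracle_spec()]
#' @param bath a [bath_spec()]
#' @param n_traj number of trajectories
#' @param horizon_fs propagation time per trajectory (fs)
#' @param seed global seed (fans out per stage and per trajectory)
#' @param coupling_scheme "exact_nac" or "curvature"
#' @param initial_state fixed 1-based starting state for all trajectories;
#'   ignored when `window` is given
#' @param window optional excitation window `c(lower, upper)` (eV) for
#'   stochastic initial-state selection; frames with no in-window state are
#'   skipped (more initial conditions are drawn to compensate, up to 4x)
#' @param temperature sampling temperature (K)
#' @param dt_nuclear,dt_electronic time steps (fs)
#' @return list with `records` (list of `fh_trajectory`) and `archive`
#'   (`fh_archive`)
#' @export
generate_reference_dataset <- function(spec, bath, n_traj, horizon_fs,
                                       seed = 1L,
                                       coupling_scheme = "exact_nac",
                                       initial_state = NULL, window = NULL,
                                       temperature = 300,
                                       dt_nuclear = 0.5, dt_electronic = 0.025) {
  stopifnot(inherits(spec, "oracle_spec"), inherits(bath, "bath_spec"),
            n_traj >= 1)
  pot <- oracle_potential(spec, bath)
  if (is.null(initial_state) && is.null(window))
    initial_state <- min(3L, spec$n_states)
  n_draw <- if (is.null(window)) n_traj else 4L * n_traj
  ics <- sample_initial_conditions(spec, bath, n_draw, temperature,
                                   seed = fh_seed(seed, "reference_ics"))
  starts <- integer(0)
  frames <- list()
  if (is.null(window)) {
    frames <- ics[seq_len(n_traj)]
    starts <- rep(as.integer(initial_state), n_traj)
  } else {
    e_mat <- matrix(0.0, n_draw, spec$n_states)
    f_mat <- matrix(0.0, n_draw, spec$n_states)
    for (i in seq_len(n_draw)) {
      lab <- oracle_labels(spec, bath, ics[[i]])
      e_mat[i, ] <- lab$energies
      f_mat[i, ] <- lab$osc_strengths
    }
    sel <- select_initial_states(e_mat, f_mat, window,
                                 seed = fh_seed(seed, "reference_sel"))
    ok <- which(!is.na(sel))
    if (length(ok) < n_traj)
      stop("only ", length(ok), " of ", n_draw,
           " sampled frames have an excitation inside the window")
    ok <- ok[seq_len(n_traj)]
    frames <- ics[ok]
    starts <- sel[ok]
  }
  archive <- archive_new(spec$n_states, fh_hash(list(spec, bath)))
  records <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    traj_seed <- fh_seed(seed, "reference_traj", i)
    cfg <- tsh_config(dt_nuclear = dt_nuclear, dt_electronic = dt_electronic,
                      horizon = horizon_fs, coupling_scheme = coupling_scheme,
                      seed = traj_seed)
    rec <- run_trajectory(frames[[i]], starts[i], pot, cfg, keep_labels = TRUE)
    records[[i]] <- rec
    archive <- archive_append(archive, rec$labels, rec, i, traj_seed)
    records[[i]]$labels <- NULL  # labels live in the archive
  }
  list(records = records, archive = archive)
}
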