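#' File formats
#'
#' Extended-XYZ frames (positions plus optional velocity and field columns,
#' per-state energies on the comment line), whitespace charge-environment
#' files, native-serialised dataset archives, and delimited trajectory
#' tables.  Text numbers are written at full precision so write/read
#' round-trips are lossless to 1e-12 and regression artifacts are
#' byte-stable.
#'
#' @name io
NULL

#' Write frames to an extended-XYZ file
#'
#' Columns: species, position; velocities and per-atom field vectors are
#' written when present.  The comment line carries a Properties descriptor
#' plus optional `energies`, `time` and `active_state` entries.
#'
#' @param frames a [system_frame()], a list of them, or a list of plain
#'   lists with elements `elements`, `positions`, optional `velocities`,
#'   `field`, `energies`, `time`, `active_state`
#' @param path output file
#' @return invisibly, the path
#' @export
write_extended_xyz <- function(frames, path) {
  if (inherits(frames, "system_frame") ||
      (!is.null(frames$positions) && !is.null(frames$elements)))
    frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    if (inherits(fr, "system_frame"))
      fr <- list(elements = fr$ml_elements, positions = fr$ml_positions,
                 velocities = if (any(fr$ml_velocities != 0)) fr$ml_velocities)
    n <- nrow(fr$positions)
    props <- "species:S:1:pos:R:3"
    cols <- list(element_symbol(fr$elements),
                 apply(fr$positions, 1, function(x) paste(sprintf("%.15e", x), collapse = " ")))
    if (!is.null(fr$velocities)) {
      props <- paste0(props, ":vel:R:3")
      cols <- c(cols, list(apply(fr$velocities, 1, function(x)
        paste(sprintf("%.15e", x), collapse = " "))))
    }
    if (!is.null(fr$field)) {
      props <- paste0(props, ":field:R:3")
      cols <- c(cols, list(apply(fr$field, 1, function(x)
        paste(sprintf("%.15e", x), collapse = " "))))
    }
    comment <- paste0("Properties=", props)
    if (!is.null(fr$energies))
      comment <- paste0(comment, ' energies="',
                        paste(sprintf("%.15e", fr$energies), collapse = " "), '"')
    if (!is.null(fr$time))
      comment <- paste0(comment, " time=", sprintf("%.15e", fr$time))
    if (!is.null(fr$active_state))
      comment <- paste0(comment, " active_state=", as.integer(fr$active_state))
    writeLines(c(as.character(n), comment), con)
    for (i in seq_len(n))
      writeLines(paste(vapply(cols, function(cc) cc[i], ""), collapse = " "), con)
  }
  invisible(path)
}

#' Read frames from an extended-XYZ file
#'
#' Missing velocity or field columns yield `NULL` entries (absence, not
#' zeros).  Malformed headers or short atom blocks raise a parse error
#' naming the offending line.
#'
#' @param path input file
#' @return list of frames: each a list with `elements` (atomic numbers),
#'   `positions`, and (when present) `velocities`, `field`, `energies`,
#'   `time`, `active_state`
#' @export
read_extended_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*[0-9]+\\s*$", lines[i]))
      stop("parse error at line ", i, ": expected an atom count")
    n <- as.integer(lines[i])
    if (i + 1L + n > length(lines) + 0L && n > 0L)
      stop("parse error at line ", i, ": truncated frame")
    comment <- lines[i + 1L]
    pm <- regmatches(comment, regexpr("Properties=[^ ]+", comment))
    if (length(pm) == 0L)
      stop("parse error at line ", i + 1L, ": missing Properties descriptor")
    fields <- strsplit(sub("Properties=", "", pm), ":")[[1]]
    spec_names <- fields[seq(1, length(fields), by = 3)]
    spec_width <- as.integer(fields[seq(3, length(fields), by = 3)])
    has_vel <- "vel" %in% spec_names
    has_field <- "field" %in% spec_names
    ncol_expect <- sum(spec_width)
    block <- lines[i + 1L + seq_len(n)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(toks, length, 0L) != ncol_expect)
    if (length(bad))
      stop("parse error at line ", i + 1L + bad[1], ": expected ",
           ncol_expect, " columns")
    tab <- do.call(rbind, toks)
    col <- 1L
    fr <- list()
    fr$elements <- element_number(tab[, col]); col <- col + 1L
    fr$positions <- matrix(as.numeric(tab[, col:(col + 2L)]), n, 3); col <- col + 3L
    if (has_vel) {
      fr$velocities <- matrix(as.numeric(tab[, col:(col + 2L)]), n, 3)
      col <- col + 3L
    }
    if (has_field)
      fr$field <- matrix(as.numeric(tab[, col:(col + 2L)]), n, 3)
    em <- regmatches(comment, regexpr('energies="[^"]*"', comment))
    if (length(em))
      fr$energies <- as.numeric(strsplit(trimws(sub('energies="', "",
                                                    sub('"$', "", em))), "\\s+")[[1]])
    tm <- regmatches(comment, regexpr("time=[^ ]+", comment))
    if (length(tm)) fr$time <- as.numeric(sub("time=", "", tm))
    am <- regmatches(comment, regexpr("active_state=[^ ]+", comment))
    if (length(am)) fr$active_state <- as.integer(sub("active_state=", "", am))
    frames[[length(frames) + 1L]] <- fr
    i <- i + 2L + n
  }
  frames
}

#' Read a charge-environment file
#'
#' Whitespace-separated columns x y z q (Angstrom, e); `#` starts a comment.
#'
#' @param path input file
#' @return list with `positions` (n x 3) and `charges`
#' @export
read_charges <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")
  bad <- which(vapply(toks, length, 0L) != 4L)
  if (length(bad)) stop("charge file: expected 4 columns on data line ", bad[1])
  tab <- matrix(as.numeric(unlist(toks)), ncol = 4, byrow = TRUE)
  list(positions = tab[, 1:3, drop = FALSE], charges = tab[, 4])
}

#' Write a charge-environment file
#' @param positions n x 3 matrix (Angstrom)
#' @param charges numeric vector (e)
#' @param path output file
#' @return invisibly, the path
#' @export
write_charges <- function(positions, charges, path) {
  check_mat3(positions, length(charges), "positions")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# x y z q  (Angstrom, e)", con)
  for (i in seq_along(charges))
    writeLines(paste(sprintf("%.15e", c(positions[i, ], charges[i])),
                     collapse = " "), con)
  invisible(path)
}

#' Save / load a dataset archive
#'
#' Archives are runtime artifacts serialised with R's native format; the
#' schema version and content hash are checked on load.
#'
#' @param archive an `fh_archive`
#' @param path file path (conventionally `.rds`)
#' @return invisibly, the path
#' @export
save_archive <- function(archive, path) {
  stopifnot(inherits(archive, "fh_archive"))
  saveRDS(archive, path, version = 3)
  invisible(path)
}

#' @rdname save_archive
#' @export
load_archive <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "fh_archive")) stop("not a dataset archive: ", path)
  if (is.null(x$schema_version) || x$schema_version != 1L)
    stop("archive schema version mismatch")
  x
}

#' Export a trajectory record as delimited text
#'
#' One row per step: time, active state, per-state energies, coefficient
#' populations and total energy, followed by a hop-event table.
#'
#' @param record an `fh_trajectory`
#' @param path output file
#' @return invisibly, the path
#' @export
write_trajectory_table <- function(record, path) {
  ns <- record$n_states
  tab <- data.frame(time_fs = fh_num(record$steps$time),
                    active_state = record$steps$active)
  for (k in seq_len(ns)) tab[[paste0("E_", k - 1)]] <- fh_num(record$energies[, k])
  for (k in seq_len(ns)) tab[[paste0("pop_", k - 1)]] <- fh_num(record$populations[, k])
  tab$total_energy <- fh_num(record$steps$total_energy)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# surface-hopping record; states=", ns,
                    " dt_fs=", record$dt, " seed=", record$seed,
                    " truncated=", record$truncated), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("# hop events", con)
  utils::write.table(record$hops, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' A single structured (YAML) file with optional sections `oracle`, `bath`,
#' `tsh`, `model`, `train`, `split` and a global `seed`; unknown keys in a
#' section raise an error naming the key.  Returns constructed config
#' objects plus the raw list and its hash.
#'
#' @param path YAML file
#' @return list with elements `spec`, `bath`, `tsh`, `model`, `train`,
#'   `split`, `seed`, `raw`, `hash`
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 1L
  build <- function(section, fn, extra = list()) {
    args <- raw[[section]] %||% list()
    known <- names(formals(fn))
    bad <- setdiff(names(args), known)
    if (length(bad))
      stop("config error in section '", section, "': unknown key '",
           bad[1], "'")
    do.call(fn, c(args, extra))
  }
  spec <- if (!is.null(raw$oracle) && identical(raw$oracle$system, "two_state")) {
    args <- raw$oracle; args$system <- NULL
    do.call(two_state_spec, args)
  } else {
    args <- raw$oracle %||% list(); args$system <- NULL
    do.call(default_oracle_spec, args)
  }
  bath <- build("bath", bath_spec,
                if (is.null(raw$bath$n_charges %||% NULL))
                  list(n_charges = 16L) else list())
  list(spec = spec, bath = bath,
       tsh = build("tsh", tsh_config),
       model = build("model", model_config),
       train = build("train", train_config),
       split = build("split", split_spec),
       seed = as.integer(seed), raw = raw, hash = fh_hash(raw))
}
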