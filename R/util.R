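# Internal helpers shared across modules.

#' Derive a module-level seed from a global seed
#'
#' One global seed fans out to per-module seeds through a fixed counter
#' scheme, so that every stochastic stage of a pipeline is reproducible from
#' a single integer while remaining decoupled from the others.
#'
#' @param global_seed integer global seed
#' @param module character scope label, e.g. "sampling" or "train"
#' @param counter non-negative integer sub-index (e.g. trajectory number)
#' @return an integer seed in [0, 2^31 - 2]
#' @export
fh_seed <- function(global_seed, module, counter = 0L) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L)
  h <- sum(utf8ToInt(module) * seq_along(utf8ToInt(module)))
  s <- (as.double(global_seed) * 2654435.0 + h * 97003.0 + as.double(counter) * 7919.0)
  as.integer(s %% 2147483647)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check that x is an n x 3 numeric matrix
#' @noRd
check_mat3 <- function(x, n, what) {
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) != 3L || nrow(x) != n)
    stop(what, " must be a ", n, " x 3 numeric matrix")
  invisible(TRUE)
}

#' Row-wise Euclidean norms
#' @noRd
row_norms <- function(x) sqrt(rowSums(x * x))

#' Random rotation matrix (uniform over SO(3)) drawn from the current RNG
#' @noRd
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Stable content hash of an R object (text-serialised), used to stamp
#' artifacts with the configuration that produced them.
#' @noRd
fh_hash <- function(x) {
  txt <- paste(utils::capture.output(utils::str(x, digits.d = 12, vec.len = 1e6)),
               collapse = "\n")
  v <- utf8ToInt(txt)
  h1 <- 5381; h2 <- 52711
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    h1 <- (h1 * 33 + sum(chunk * (seq_along(chunk) %% 251 + 1))) %% 4294967291
    h2 <- (h2 * 31 + sum(chunk * chunk %% 65521)) %% 4294967279
  }
  sprintf("%08x%08x", as.integer(h1 %% 2147483647), as.integer(h2 %% 2147483647))
}

#' Format numbers at fixed precision for byte-stable text artifacts
#' @noRd
fh_num <- function(x) formatC(x, format = "e", digits = 12)
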