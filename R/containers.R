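#' Per-frame feature matrix for one simulation replica
#'
#' The universal currency between pipeline stages: a frames x features numeric
#' matrix with unique feature names, a frame interval in nanoseconds, a replica
#' identifier and an ensemble label (for example `"neutral"` or `"H294+"`).
#' Frames are 0-based; the time of frame `i` is `i * dt_ns`.
#'
#' @param data numeric matrix (frames x features) or data.frame; no missing
#'   values allowed.
#' @param dt_ns frame interval in ns (> 0).
#' @param replica replica identifier (character or integer).
#' @param ensemble ensemble label, e.g. the protonation state.
#' @return an object of class `feature_trajectory` (a numeric matrix with
#'   attributes `dt_ns`, `replica`, `ensemble`).
#' @export
feature_trajectory <- function(data, dt_ns = 1, replica = "r1",
                               ensemble = "default") {
  x <- as.matrix(data)
  if (!is.numeric(x)) stop_("feature data must be numeric")
  if (anyNA(x) || any(!is.finite(x))) stop_("feature data contains missing or non-finite values")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) stop_("feature names must be unique")
  if (!is.numeric(dt_ns) || length(dt_ns) != 1L || dt_ns <= 0)
    stop_("dt_ns must be a single positive number")
  structure(x, dt_ns = dt_ns, replica = replica, ensemble = ensemble,
            class = c("feature_trajectory", "matrix", "array"))
}

#' @export
print.feature_trajectory <- function(x, ...) {
  cat(sprintf("<feature_trajectory> %d frames x %d features, dt = %g ns, replica %s, ensemble %s\n",
              nrow(x), ncol(x), attr(x, "dt_ns"), attr(x, "replica"),
              attr(x, "ensemble")))
  cat("features:", paste(utils::head(colnames(x), 8), collapse = ", "),
      if (ncol(x) > 8) "...", "\n")
  invisible(x)
}

# strip class but keep the data for matrix maths
ft_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "dt_ns") <- NULL; attr(y, "replica") <- NULL; attr(y, "ensemble") <- NULL
  y
}

ft_dt <- function(x) attr(x, "dt_ns") %||% 1

#' Write / read a feature trajectory as CSV
#'
#' Header row of feature names, one row per frame. The frame interval,
#' replica and ensemble are stored in `#`-prefixed comment lines.
#'
#' @param x a [feature_trajectory()].
#' @param path file path.
#' @export
write_feature_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt_ns=%.12g replica=%s ensemble=%s",
                     attr(x, "dt_ns"), attr(x, "replica"), attr(x, "ensemble")), con)
  utils::write.csv(as.data.frame(ft_matrix(x)), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- list(dt_ns = 1, replica = "r1", ensemble = "default")
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[^ ]+", first))[[1]]
    for (p in kv) {
      k <- sub("=.*", "", p); v <- sub("^[a-z_]+=", "", p)
      meta[[k]] <- if (k == "dt_ns") as.numeric(v) else v
    }
  }
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  feature_trajectory(as.matrix(d), dt_ns = meta$dt_ns, replica = meta$replica,
                     ensemble = meta$ensemble)
}

#' Coordinate trajectory container
#'
#' Positions are stored in nanometres as a frames x atoms x 3 array together
#' with an atom table (index, name, residue number, residue name).
#'
#' @param xyz numeric array (frames x atoms x 3), in nm.
#' @param atoms data.frame with columns `eleno`, `elety`, `resno`, `resid`.
#' @param dt_ns frame interval in ns.
#' @param replica replica identifier.
#' @return an object of class `coord_trajectory`.
#' @export
coord_trajectory <- function(xyz, atoms, dt_ns = 1, replica = "r1") {
  if (length(dim(xyz)) != 3L || dim(xyz)[3] != 3L)
    stop_("xyz must be a frames x atoms x 3 array")
  if (any(!is.finite(xyz))) stop_("coordinates contain non-finite values")
  need <- c("eleno", "elety", "resno", "resid")
  if (!all(need %in% names(atoms)))
    stop_("atom table must have columns: %s", paste(need, collapse = ", "))
  if (nrow(atoms) != dim(xyz)[2])
    stop_("atom table has %d rows but xyz has %d atoms", nrow(atoms), dim(xyz)[2])
  structure(list(xyz = xyz, atoms = atoms, dt_ns = dt_ns, replica = replica),
            class = "coord_trajectory")
}

#' @export
print.coord_trajectory <- function(x, ...) {
  cat(sprintf("<coord_trajectory> %d frames, %d atoms, dt = %g ns, replica %s\n",
              dim(x$xyz)[1], dim(x$xyz)[2], x$dt_ns, x$replica))
  invisible(x)
}

#' @export
dim.coord_trajectory <- function(x) dim(x$xyz)

n_frames <- function(traj) dim(traj$xyz)[1]
n_atoms <- function(traj) dim(traj$xyz)[2]
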