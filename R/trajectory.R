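#' Load a coordinate trajectory from standard structure formats
#'
#' Reads a multi-model PDB, a (possibly multi-frame) GRO file, or a
#' topology + DCD pair into a [coord_trajectory()]. Positions are converted
#' to nanometres regardless of the source convention (PDB and DCD store
#' Angstrom; GRO stores nm).
#'
#' @param topology path to a PDB or GRO file providing the atom table (and,
#'   for PDB/GRO, the frames themselves).
#' @param frames optional path(s) to coordinate frames (DCD); when given, the
#'   atom count must match the topology.
#' @param dt_ns frame interval in ns.
#' @param replica replica identifier.
#' @return a [coord_trajectory()].
#' @export
load_trajectory <- function(topology, frames = NULL, dt_ns = 1,
                            replica = "r1") {
  if (!file.exists(topology)) stop_("topology file not found: %s", topology)
  ext <- tolower(tools::file_ext(topology))
  if (ext == "gro") {
    traj <- read_gro(topology, dt_ns = dt_ns, replica = replica)
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(topology, multi = TRUE, verbose = FALSE)
    at <- pdb$atom
    atoms <- data.frame(eleno = at$eleno, elety = at$elety,
                        resno = at$resno, resid = at$resid)
    xyzm <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1)
    nf <- nrow(xyzm); na <- ncol(xyzm) / 3
    xyz <- aperm(array(t(xyzm), c(3, na, nf)), c(3, 2, 1)) / 10  # A -> nm
    traj <- coord_trajectory(xyz, atoms, dt_ns = dt_ns, replica = replica)
  } else if (ext %in% c("xtc", "trr")) {
    stop_("format '%s' is not supported; use multi-model PDB, GRO or DCD", ext)
  } else {
    stop_("unrecognized topology format: .%s", ext)
  }
  if (!is.null(frames)) {
    fext <- tolower(tools::file_ext(frames[1]))
    if (fext != "dcd")
      stop_("frame format '.%s' is not supported; use DCD (or frames embedded in PDB/GRO)", fext)
    xyzm <- do.call(rbind, lapply(frames, bio3d::read.dcd, verbose = FALSE))
    na <- ncol(xyzm) / 3
    if (na != n_atoms(traj))
      stop_("atom count mismatch: topology has %d atoms, frames have %d",
            n_atoms(traj), na)
    nf <- nrow(xyzm)
    xyz <- aperm(array(t(xyzm), c(3, na, nf)), c(3, 2, 1)) / 10
    traj <- coord_trajectory(xyz, traj$atoms, dt_ns = dt_ns, replica = replica)
  }
  traj
}

#' Read / write (multi-frame) GRO coordinate files
#'
#' Fixed-column GROMACS coordinate format, positions in nm with 0.001 nm
#' precision. Multiple frames are stored as concatenated blocks.
#'
#' @param path file path.
#' @param dt_ns,replica metadata attached to the result.
#' @export
read_gro <- function(path, dt_ns = 1, replica = "r1") {
  lines <- readLines(path)
  i <- 1L; frames <- list(); atoms <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(na)) stop_("malformed GRO file at line %d", i + 1L)
    block <- lines[(i + 2L):(i + 1L + na)]
    xyz <- matrix(NA_real_, na, 3)
    resno <- integer(na); resid <- character(na); elety <- character(na)
    eleno <- integer(na)
    for (j in seq_len(na)) {
      ln <- block[j]
      resno[j] <- as.integer(substr(ln, 1, 5))
      resid[j] <- trimws(substr(ln, 6, 10))
      elety[j] <- trimws(substr(ln, 11, 15))
      eleno[j] <- as.integer(substr(ln, 16, 20))
      xyz[j, ] <- as.numeric(c(substr(ln, 21, 28), substr(ln, 29, 36),
                               substr(ln, 37, 44)))
    }
    if (is.null(atoms)) {
      atoms <- data.frame(eleno = eleno, elety = elety, resno = resno,
                          resid = resid)
    } else if (nrow(atoms) != na) {
      stop_("atom count changed between GRO frames: %d vs %d", nrow(atoms), na)
    }
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 3L + na     # title + natoms + atoms + box line
  }
  arr <- array(NA_real_, c(length(frames), nrow(atoms), 3))
  for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
  coord_trajectory(arr, atoms, dt_ns = dt_ns, replica = replica)
}

#' @rdname read_gro
#' @param traj a [coord_trajectory()].
#' @param box box vector lengths written on the closing line of each frame, nm.
#' @export
write_gro <- function(traj, path, box = c(10, 10, 10)) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- traj$atoms
  for (t in seq_len(n_frames(traj))) {
    writeLines(sprintf("frame %d", t - 1L), con)
    writeLines(sprintf("%5d", n_atoms(traj)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$resno, substr(a$resid, 1, 5), substr(a$elety, 1, 5),
                       a$eleno, traj$xyz[t, , 1], traj$xyz[t, , 2],
                       traj$xyz[t, , 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  }
  invisible(path)
}

#' Resolve an atom selection
#'
#' Selections are either integer atom indices, a logical mask, or character
#' selectors. Character selectors support atom names (`"CA"`), and the
#' residue mini-grammar used for hydrogen-bond labels: one-letter amino acid
#' code + residue number + `s` (side chain) or `m` (main chain), e.g.
#' `"K257s"` or `"N287m"`. Main chain is the backbone N, H, C, O; side chain
#' is every non-backbone heavy atom plus polar hydrogens (those bound to
#' side-chain N/O, identified by name).
#'
#' @param traj a [coord_trajectory()].
#' @param selection indices, logical mask, or character selector(s).
#' @return integer atom indices.
#' @export
select_atoms <- function(traj, selection) {
  a <- traj$atoms
  if (is.logical(selection)) return(which(selection))
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1 | idx > nrow(a))) stop_("atom index out of range")
    return(idx)
  }
  backbone <- c("N", "H", "C", "O", "OXT", "H1", "H2", "H3")
  mainchain <- c("N", "H", "C", "O")
  out <- integer(0)
  for (sel in selection) {
    m <- regmatches(sel, regexec("^([A-Z])([0-9]+)([sm])$", sel))[[1]]
    if (length(m) == 4L) {
      aa <- .aa3[m[2]]
      resno <- as.integer(m[3])
      rows <- which(a$resno == resno)
      if (length(rows) == 0L) stop_("selector '%s': residue %d not present", sel, resno)
      if (!is.na(aa) && !all(a$resid[rows] %in% c(aa, "HSD", "HSE", "HIP")) &&
          !any(a$resid[rows] == aa))
        stop_("selector '%s': residue %d is %s, not %s", sel, resno,
              a$resid[rows][1], aa)
      if (m[4] == "m") {
        out <- c(out, rows[a$elety[rows] %in% mainchain])
      } else {
        sc <- rows[!(a$elety[rows] %in% c(backbone, "CA", "HA", "HA2", "HA3"))]
        # drop apolar hydrogens: keep H* names typical of N/O-bound protons
        ety <- a$elety[sc]
        keep <- !grepl("^H", ety) |
          grepl("^(HG1|HH|HD1|HD2|HE1|HE2|HZ|HE|HD|HG|HN)", ety)
        out <- c(out, sc[keep])
      }
    } else {
      rows <- which(a$elety == sel)
      if (length(rows) == 0L) stop_("selector '%s' matches no atoms", sel)
      out <- c(out, rows)
    }
  }
  sort(unique(out))
}

# Kabsch optimal rotation R minimizing |x R - y| (both n x 3, centred)
kabsch_rotation <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Least-squares superposition onto a reference frame
#'
#' Rigid-body (Kabsch) fit of every frame onto the reference over the given
#' selection: translations are removed by centring on the selection centroid
#' and the optimal rotation is found by singular value decomposition. The
#' whole frame is transformed; only the selection defines the fit.
#'
#' @param traj a [coord_trajectory()].
#' @param reference reference frame index (1-based) or an atoms x 3 matrix.
#' @param selection fit selection (see [select_atoms()]); default all atoms.
#' @return the superposed [coord_trajectory()].
#' @export
superpose <- function(traj, reference = 1L, selection = NULL) {
  idx <- if (is.null(selection)) seq_len(n_atoms(traj))
         else select_atoms(traj, selection)
  if (length(idx) < 3L) stop_("selection must contain at least 3 atoms")
  ref <- if (is.matrix(reference)) reference else traj$xyz[reference, , ]
  refsel <- ref[idx, , drop = FALSE]
  # reject (near-)collinear fit selections: rotation is not determined
  rc <- sweep(refsel, 2, colMeans(refsel))
  if (svd(rc)$d[2] < 1e-8)
    stop_("degenerate selection: fewer than 3 non-collinear atoms")
  refc <- colMeans(refsel)
  out <- traj$xyz
  for (t in seq_len(n_frames(traj))) {
    fr <- traj$xyz[t, , ]
    fsel <- fr[idx, , drop = FALSE]
    fc <- colMeans(fsel)
    R <- kabsch_rotation(sweep(fsel, 2, fc), sweep(refsel, 2, refc))
    out[t, , ] <- sweep(sweep(fr, 2, fc) %*% R, 2, refc, "+")
  }
  coord_trajectory(out, traj$atoms, dt_ns = traj$dt_ns, replica = traj$replica)
}

rmsd_pair <- function(x, y) sqrt(mean(rowSums((x - y)^2)))

#' Per-frame least-squares-fitted RMSD against a reference
#'
#' Each frame is rigid-body fitted onto the reference over the selection
#' before the root-mean-square deviation over that selection is computed.
#'
#' @inheritParams superpose
#' @return a [feature_trajectory()] with one column `rmsd` (nm).
#' @export
rmsd_timeseries <- function(traj, reference = 1L, selection = NULL) {
  idx <- if (is.null(selection)) seq_len(n_atoms(traj))
         else select_atoms(traj, selection)
  if (length(idx) < 3L) stop_("selection must contain at least 3 atoms")
  ref <- if (is.matrix(reference)) reference else traj$xyz[reference, , ]
  refsel <- sweep(ref[idx, , drop = FALSE], 2,
                  colMeans(ref[idx, , drop = FALSE]))
  if (svd(refsel)$d[2] < 1e-8)
    stop_("degenerate selection: fewer than 3 non-collinear atoms")
  v <- numeric(n_frames(traj))
  for (t in seq_len(n_frames(traj))) {
    fsel <- traj$xyz[t, idx, , drop = TRUE]
    fsel <- sweep(fsel, 2, colMeans(fsel))
    R <- kabsch_rotation(fsel, refsel)
    v[t] <- rmsd_pair(fsel %*% R, refsel)
  }
  feature_trajectory(matrix(v, ncol = 1, dimnames = list(NULL, "rmsd")),
                     dt_ns = traj$dt_ns, replica = traj$replica)
}

#' Root-mean-square fluctuation per selected atom
#'
#' `RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2)` over an already superposed
#' trajectory. A single-frame trajectory has no defined fluctuation and is
#' rejected.
#'
#' @inheritParams superpose
#' @return named numeric vector (nm), one entry per selected atom, named by
#'   residue and atom name.
#' @export
rmsf <- function(traj, selection = NULL) {
  if (n_frames(traj) < 2L) stop_("RMSF undefined for a single-frame trajectory")
  idx <- if (is.null(selection)) seq_len(n_atoms(traj))
         else select_atoms(traj, selection)
  x <- traj$xyz[, idx, , drop = FALSE]
  mu <- apply(x, c(2, 3), mean)
  dev2 <- sweep(x, c(2, 3), mu)^2
  v <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames and coords, x3 for |.|^2
  names(v) <- paste0(traj$atoms$resid[idx], traj$atoms$resno[idx], ".",
                     traj$atoms$elety[idx])
  v
}
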