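# Independent reference implementations used to validate the package code.
# These share no code with the implementation under test.

kB_ref <- 0.0083144621

# brute-force common-nearest-neighbours clustering by dense matrix algebra
brute_cnn <- function(X, r, n_c, min_members = 1) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  A <- (D <= r) & !diag(TRUE, n)
  shared <- crossprod(A)            # counts common neighbours of each pair
  conn <- A & (shared >= n_c)
  R <- conn | diag(TRUE, n)
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  sig <- apply(R, 1, paste, collapse = "")
  comp <- match(sig, unique(sig))
  sizes <- tabulate(comp)
  # isolated vertices (no density-connected edge) are noise by convention
  sizes[unique(comp[rowSums(conn) == 0])] <- 0L
  lab <- rep(-1L, n)
  good <- which(sizes >= min_members)
  if (length(good)) {
    fm <- vapply(good, function(g) which(comp == g)[1], 1L)
    ord <- good[order(-sizes[good], fm)]
    for (k in seq_along(ord)) lab[comp == ord[k]] <- k - 1L
  }
  lab
}

# naive double-loop transition counter
brute_counts <- function(s, lag, K) {
  C <- matrix(0L, K, K)
  for (t in seq_len(length(s) - lag)) {
    a <- s[t]; b <- s[t + lag]
    if (!is.na(a) && !is.na(b)) C[a, b] <- C[a, b] + 1L
  }
  C
}

# naive per-frame pairwise distance
brute_distances <- function(xyz, i, j) {
  nf <- dim(xyz)[1]
  vapply(seq_len(nf), function(t) sqrt(sum((xyz[t, i, ] - xyz[t, j, ])^2)), 1)
}

# two-pass RMSF
brute_rmsf <- function(xyz, idx) {
  vapply(idx, function(i) {
    mu <- colMeans(xyz[, i, , drop = TRUE])
    sqrt(mean(rowSums(sweep(xyz[, i, , drop = TRUE], 2, mu)^2)))
  }, 1)
}

# small multi-model PDB writer for fixtures (coordinates in Angstrom)
write_tiny_pdb <- function(path, frames_xyz_A, names = NULL, resno = NULL,
                           resid = "GLY") {
  na <- dim(frames_xyz_A)[2]
  names <- names %||% rep("CA", na)
  resno <- resno %||% seq_len(na)
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(dim(frames_xyz_A)[1])) {
    writeLines(sprintf("MODEL     %4d", t), con)
    for (i in seq_len(na)) {
      writeLines(sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                         i, names[i], resid, resno[i],
                         frames_xyz_A[t, i, 1], frames_xyz_A[t, i, 2],
                         frames_xyz_A[t, i, 3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal coordinate trajectory built in code
toy_traj <- function(xyz_nm, elety = NULL, resno = NULL, resid = "GLY",
                     dt_ns = 1) {
  na <- dim(xyz_nm)[2]
  atoms <- data.frame(eleno = seq_len(na),
                      elety = elety %||% rep("CA", na),
                      resno = resno %||% seq_len(na),
                      resid = resid)
  coord_trajectory(xyz_nm, atoms, dt_ns = dt_ns)
}
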