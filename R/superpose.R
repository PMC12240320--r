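## Kabsch superposition and RMSD ----------------------------------------------

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of `mobile`
#' onto `target`, via singular value decomposition of the cross-covariance
#' matrix with the usual sign correction so that reflections are never
#' returned.
#'
#' @param mobile,target `k x 3` coordinate matrices over the same `k >= 3`
#'   atoms, Angstrom.
#' @return List with `rotation` (3x3, det +1), `translation` (length 3) such
#'   that `mobile %*% rotation + translation` superposes onto `target`, and
#'   `rmsd` (Angstrom).
#' @export
kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  k <- nrow(mobile)
  if (k != nrow(target) || ncol(mobile) != 3L || ncol(target) != 3L)
    stop("mobile and target must be k x 3 matrices over the same atoms",
         call. = FALSE)
  if (k < 3L)
    stop("superposition is underdetermined: need at least 3 atoms", call. = FALSE)
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  # degenerate (collinear) configurations leave the rotation underdetermined
  if (svd(A, nu = 0, nv = 0)$d[2] < 1e-8 * max(1, svd(A, nu = 0, nv = 0)$d[1]))
    stop("superposition is underdetermined: mobile coordinates are collinear",
         call. = FALSE)
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  R <- t(R)  # so that rotated = A %*% R
  fitted <- A %*% R
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(ct - cm %*% R), rmsd = rmsd)
}

# apply kabsch fit of rows `idx` and return the fully transformed coordinates
superpose_coords <- function(mobile, target, fit_idx = seq_len(nrow(mobile))) {
  f <- kabsch(mobile[fit_idx, , drop = FALSE], target[fit_idx, , drop = FALSE])
  sweep(mobile %*% f$rotation, 2, f$translation, `+`)
}

#' RMSD between two trajectory snapshots
#'
#' Superposition-minimized root-mean-square deviation over the selected
#' atoms.
#'
#' @param traj a [trajectory()].
#' @param i,j snapshot indices.
#' @param sel an [atom_select()] (default backbone, the main-chain convention
#'   of 2D-RMSD analysis).
#' @return RMSD in Angstrom.
#' @export
rmsd_between <- function(traj, i, j, sel = atom_select(atom_class = "backbone")) {
  idx <- resolve_selection(traj, sel)
  a <- frame_coords(traj$xyz, i)[idx, , drop = FALSE]
  b <- frame_coords(traj$xyz, j)[idx, , drop = FALSE]
  kabsch(a, b)$rmsd
}

#' All-versus-all 2D-RMSD matrix
#'
#' Pairwise superposition RMSD between every pair of frames, the input to
#' threshold-based conformational clustering.
#'
#' @param x a [trajectory()] or a [coarsen()] frame set.
#' @param sel an [atom_select()]; default backbone.
#' @return Symmetric matrix of class `"rmsd_matrix"` with zero diagonal and a
#'   `"times_ns"` attribute (frame mid-times).
#' @export
rmsd_matrix <- function(x, sel = atom_select(atom_class = "backbone")) {
  top <- if (inherits(x, "frame_set")) x$topology else x$topology
  xyz <- x$xyz
  idx <- resolve_selection(top, sel)
  n <- nrow(xyz)
  if (n < 2L) stop("need at least 2 frames for an RMSD matrix", call. = FALSE)
  coords <- lapply(seq_len(n), function(i)
    frame_coords(xyz, i)[idx, , drop = FALSE])
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- kabsch(coords[[i]], coords[[j]])$rmsd
    m[j, i] <- m[i, j]
  }
  attr(m, "times_ns") <- if (inherits(x, "frame_set")) x$mid_ns else frame_times(x)
  class(m) <- c("rmsd_matrix", class(m))
  m
}

#' @export
print.rmsd_matrix <- function(x, ...) {
  cat(sprintf("<rmsd_matrix> %d x %d frames, range %.3f..%.3f A\n",
              nrow(x), ncol(x), min(x[upper.tri(x)]), max(x)))
  invisible(x)
}

## Iterative superposition onto the trajectory mean ---------------------------

# Superpose every frame onto the running mean structure, iterating until the
# mean moves by less than `tol` (RMS over aligned atoms) or `max_iter` passes.
# Returns list(xyz, mean, iterations, shift). Standard essential-dynamics
# practice; convergence is usually reached in 2-4 passes.
superpose_to_mean <- function(xyz, align_idx, tol = 1e-6, max_iter = 10L) {
  n <- nrow(xyz)
  natoms <- ncol(xyz) / 3L
  coords <- lapply(seq_len(n), function(i) frame_coords(xyz, i))
  ref <- coords[[1L]]
  shift <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    coords <- lapply(coords, superpose_coords, target = ref, fit_idx = align_idx)
    newmean <- Reduce(`+`, coords) / n
    shift <- sqrt(mean(rowSums((newmean[align_idx, , drop = FALSE] -
                                ref[align_idx, , drop = FALSE])^2)))
    ref <- newmean
    if (shift < tol || it >= max_iter) break
  }
  if (shift >= tol)
    stop(sprintf("mean-structure alignment did not converge in %d iterations (final shift %.2e A)",
                 max_iter, shift), call. = FALSE)
  out <- matrix(0, n, ncol(xyz))
  for (i in seq_len(n)) out[i, ] <- flat_coords(coords[[i]])
  list(xyz = out, mean = ref, iterations = it, shift = shift)
}

## RMSF and flexibility classes -----------------------------------------------

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each selected residue's C-alpha atom about
#' its trajectory-average position, after superposing every snapshot onto the
#' converged mean structure (or, optionally, onto the first snapshot).
#' The relative profile divides by the profile mean, the scale on which
#' flexibility classes are defined.
#'
#' @param traj a [trajectory()].
#' @param sel residue selection; its `calpha` atoms are profiled. Default all
#'   residues.
#' @param align_sel selection used for the superposition fit (default
#'   `calpha`).
#' @param reference `"mean"` (iterated mean structure) or `"initial"` (first
#'   snapshot) as the alignment target; fluctuations are always measured
#'   about the post-alignment mean.
#' @return Data frame of class `"fluct_profile"`: `chain`, `resseq`,
#'   `resname`, `rmsf` (Angstrom), `relative` (unitless, mean 1).
#' @export
rmsf_profile <- function(traj, sel = atom_select(atom_class = "calpha"),
                         align_sel = atom_select(atom_class = "calpha"),
                         reference = c("mean", "initial")) {
  reference <- match.arg(reference)
  if (nrow(traj$xyz) < 2L) stop("need at least 2 snapshots for RMSF", call. = FALSE)
  if (is.character(sel)) sel <- atom_select(atom_class = sel)
  sel$atom_class <- "calpha"
  ca_idx <- resolve_selection(traj, sel)
  align_idx <- resolve_selection(traj, align_sel)
  if (reference == "mean") {
    al <- superpose_to_mean(traj$xyz, align_idx)
    xyz <- al$xyz
  } else {
    ref <- frame_coords(traj$xyz, 1L)
    xyz <- t(vapply(seq_len(nrow(traj$xyz)), function(i)
      flat_coords(superpose_coords(frame_coords(traj$xyz, i), ref, align_idx)),
      numeric(ncol(traj$xyz))))
  }
  cols <- xyz_cols(ca_idx)
  sub <- xyz[, cols, drop = FALSE]
  dev <- sweep(sub, 2, colMeans(sub))
  msf3 <- matrix(colMeans(dev^2), nrow = 3L)        # per-coordinate MSF
  rmsf <- sqrt(colSums(msf3))                        # per-atom over x,y,z
  top <- traj$topology[ca_idx, ]
  out <- data.frame(chain = top$chain, resseq = top$resseq,
                    resname = top$resname, rmsf = rmsf,
                    relative = rmsf / mean(rmsf), row.names = NULL)
  class(out) <- c("fluct_profile", "data.frame")
  out
}

# Relative-RMSF class bins; left-closed, right-open, with open first and last
# bins. Labels carry the conventional color names of flexibility maps.
FLEX_BREAKS <- c(0.5, 1, 1.5, 2, 2.5, 3)
FLEX_LABELS <- c("<0.5 (black)", "0.5-1 (blue)", "1-1.5 (light blue)",
                 "1.5-2 (light green)", "2-2.5 (yellow)", "2.5-3 (orange)",
                 ">3 (red)")

#' Classify residues into relative-flexibility classes
#'
#' Bins the relative RMSF (residue RMSF divided by the profile mean) into
#' seven ordinal classes: below 0.5, then half-unit bins up to 3, then above
#' 3. Bins are left-closed (a relative value exactly on an edge falls in the
#' higher class).
#'
#' @param profile a [rmsf_profile()] result.
#' @return The profile with a `flex_class` ordered factor added.
#' @export
classify_flexibility <- function(profile) {
  stopifnot(is.numeric(profile$relative))
  cls <- findInterval(profile$relative, FLEX_BREAKS) + 1L
  profile$flex_class <- factor(FLEX_LABELS[cls], levels = FLEX_LABELS,
                               ordered = TRUE)
  profile
}

#' @export
print.fluct_profile <- function(x, ...) {
  cat(sprintf("<fluct_profile> %d residues, RMSF %.3f..%.3f A (mean %.3f)\n",
              nrow(x), min(x$rmsf), max(x$rmsf), mean(x$rmsf)))
  if (!is.null(x$flex_class)) print(table(x$flex_class))
  invisible(x)
}

#' @export
plot.fluct_profile <- function(x, ...) {
  plot(seq_len(nrow(x)), x$rmsf, type = "l", xlab = "residue index",
       ylab = "RMSF (A)", ...)
  abline(h = mean(x$rmsf), lty = 2, col = "grey50")
  invisible(x)
}
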