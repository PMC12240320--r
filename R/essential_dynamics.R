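## Essential dynamics: covariance PCA and cross-correlation -------------------

#' Principal component analysis of C-alpha coordinates
#'
#' Essential-dynamics PCA: every snapshot is superposed onto the converged
#' mean structure, the covariance matrix of the 3N selected coordinates is
#' diagonalized, and snapshots are projected onto the modes. Eigenvalues are
#' in square Angstrom and tiny negative values from finite precision are
#' clipped to zero.
#'
#' @param traj a [trajectory()].
#' @param sel an [atom_select()] resolving to the C-alpha set to analyse
#'   (e.g. one chain); default all C-alpha atoms.
#' @param stride_ns optional subsampling interval in ns: snapshots are taken
#'   every `stride_ns` before analysis (projections are computed for the
#'   strided snapshots).
#' @return Object of class `"mode_decomposition"`: `eigenvalues`
#'   (descending), `eigenvectors` (3N x k orthonormal columns),
#'   `variance_fraction`, `projections` (snapshots x k), `residues`,
#'   `mean_xyz`, `times_ns`.
#' @export
traj_pca <- function(traj, sel = atom_select(atom_class = "calpha"),
                     stride_ns = NULL) {
  if (is.character(sel)) sel <- atom_select(atom_class = sel)
  sel$atom_class <- "calpha"
  idx <- resolve_selection(traj, sel)
  times <- frame_times(traj)
  rows <- seq_len(nrow(traj$xyz))
  if (!is.null(stride_ns)) {
    stopifnot(stride_ns > 0)
    step <- max(1L, round(stride_ns / traj$dt_ns))
    rows <- seq.int(1L, nrow(traj$xyz), by = step)
  }
  if (length(rows) < 3L)
    stop("need at least 3 snapshots for PCA", call. = FALSE)
  al <- superpose_to_mean(traj$xyz[rows, , drop = FALSE], idx)
  sub <- al$xyz[, xyz_cols(idx), drop = FALSE]
  centred <- sweep(sub, 2, colMeans(sub))
  cv <- crossprod(centred) / (nrow(centred) - 1L)
  eig <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  top <- traj$topology[idx, ]
  structure(list(
    eigenvalues = ev,
    eigenvectors = eig$vectors,
    variance_fraction = ev / sum(ev),
    projections = centred %*% eig$vectors,
    residues = data.frame(chain = top$chain, resseq = top$resseq,
                          resname = top$resname, row.names = NULL),
    mean_xyz = colMeans(sub),
    times_ns = times[rows]), class = "mode_decomposition")
}

#' @export
print.mode_decomposition <- function(x, ...) {
  cat(sprintf("<mode_decomposition> %d residues, %d snapshots\n",
              nrow(x$residues), nrow(x$projections)))
  k <- min(5L, length(x$eigenvalues))
  cat("  leading variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Per-residue mobility of one principal mode
#'
#' Euclidean norm of each residue's 3-vector components of the mode
#' eigenvector, scaled by the square root of its eigenvalue, i.e. the RMS
#' displacement amplitude that mode contributes per residue. The sum of
#' squared mobilities equals the eigenvalue.
#'
#' @param decomp a [traj_pca()] result.
#' @param mode mode rank (1 = largest eigenvalue).
#' @return Numeric vector, one value per residue, Angstrom.
#' @export
mode_mobility <- function(decomp, mode = 1L) {
  if (mode < 1L || mode > length(decomp$eigenvalues))
    stop(sprintf("mode %d out of range 1..%d", mode,
                 length(decomp$eigenvalues)), call. = FALSE)
  v <- matrix(decomp$eigenvectors[, mode], nrow = 3L)
  sqrt(colSums(v^2)) * sqrt(decomp$eigenvalues[mode])
}

#' Dynamic cross-correlation matrix
#'
#' Normalized covariance of per-residue C-alpha displacement vectors about
#' the mean structure over superposed snapshots:
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, in \[-1, 1\];
#' +1 marks fully correlated, -1 fully anti-correlated motion. Residues
#' with zero variance get zero off-diagonal entries (diagonal 1) with a
#' warning.
#'
#' @param traj a [trajectory()].
#' @param sel an [atom_select()] resolving to C-alpha atoms.
#' @return `n x n` matrix of class `"dccm_matrix"` with residue labels.
#' @export
traj_dccm <- function(traj, sel = atom_select(atom_class = "calpha")) {
  if (is.character(sel)) sel <- atom_select(atom_class = sel)
  sel$atom_class <- "calpha"
  idx <- resolve_selection(traj, sel)
  if (nrow(traj$xyz) < 2L) stop("need at least 2 snapshots", call. = FALSE)
  al <- superpose_to_mean(traj$xyz, idx)
  sub <- al$xyz[, xyz_cols(idx), drop = FALSE]
  centred <- sweep(sub, 2, colMeans(sub))
  nres <- length(idx)
  nfr <- nrow(centred)
  # <dr_i . dr_j> = sum over x,y,z of per-coordinate covariances
  cv <- crossprod(centred) / nfr
  dot <- matrix(0, nres, nres)
  for (k in 0:2)
    dot <- dot + cv[seq(1L + k, 3L * nres, by = 3L),
                    seq(1L + k, 3L * nres, by = 3L)]
  msf <- diag(dot)
  zero <- msf <= 1e-12
  if (any(zero))
    warning(sprintf("%d residue(s) with zero variance; their correlations are set to 0",
                    sum(zero)), call. = FALSE)
  denom <- sqrt(outer(pmax(msf, 1e-300), pmax(msf, 1e-300)))
  cc <- dot / denom
  cc[zero, ] <- 0; cc[, zero] <- 0
  diag(cc) <- 1
  cc <- pmax(pmin(cc, 1), -1)
  top <- traj$topology[idx, ]
  dimnames(cc) <- list(residue_keys(top), residue_keys(top))
  class(cc) <- c("dccm_matrix", class(cc))
  cc
}

#' @export
print.dccm_matrix <- function(x, ...) {
  cat(sprintf("<dccm_matrix> %d x %d residues, range %.2f..%.2f\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}
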