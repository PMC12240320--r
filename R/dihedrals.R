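## Backbone dihedrals and Ramachandran ensembles ------------------------------

# Signed dihedral about the p2-p3 axis by the atan2 cross-product formula,
# degrees in (-180, 180]; -180 is mapped to +180.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  ang <- atan2(sqrt(sum(b2^2)) * sum(b1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# vectorised over frames: pX are n x 3 matrices
dihedral_angles <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  crossm <- function(u, v)
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- crossm(b1, b2); n2 <- crossm(b2, b3)
  ang <- atan2(sqrt(rowSums(b2^2)) * rowSums(b1 * n2),
               rowSums(n1 * n2)) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

#' Backbone phi/psi series for one residue
#'
#' Standard IUPAC backbone dihedrals: phi = C(i-1)-N(i)-CA(i)-C(i) and
#' psi = N(i)-CA(i)-C(i)-N(i+1), right-hand sign convention, degrees in
#' (-180, 180]. At chain termini the undefined angle is `NA` (never zero):
#' phi is undefined at the first residue of a chain, psi at the last.
#'
#' @param traj a [trajectory()].
#' @param chain chain id.
#' @param resseq residue number.
#' @return Data frame of class `"dihedral_series"`: `time_ns`, `phi`, `psi`;
#'   attributes record the residue identity.
#' @export
phi_psi <- function(traj, chain, resseq) {
  top <- traj$topology
  find_atom <- function(rs, name) {
    i <- which(top$chain == chain & top$resseq == rs & trimws(top$name) == name)
    if (length(i) == 1L) i else NA_integer_
  }
  iN <- find_atom(resseq, "N"); iCA <- find_atom(resseq, "CA")
  iC <- find_atom(resseq, "C")
  if (anyNA(c(iN, iCA, iC)))
    stop(sprintf("residue %s:%d lacks backbone atoms", chain, resseq), call. = FALSE)
  res_in_chain <- sort(unique(top$resseq[top$chain == chain]))
  pos <- match(resseq, res_in_chain)
  iCprev <- if (pos > 1L) find_atom(res_in_chain[pos - 1L], "C") else NA_integer_
  iNnext <- if (pos < length(res_in_chain)) find_atom(res_in_chain[pos + 1L], "N") else NA_integer_

  n <- nrow(traj$xyz)
  at <- function(i) traj$xyz[, c(3L * i - 2L, 3L * i - 1L, 3L * i), drop = FALSE]
  phi <- if (is.na(iCprev)) rep(NA_real_, n) else
    dihedral_angles(at(iCprev), at(iN), at(iCA), at(iC))
  psi <- if (is.na(iNnext)) rep(NA_real_, n) else
    dihedral_angles(at(iN), at(iCA), at(iC), at(iNnext))
  out <- data.frame(time_ns = frame_times(traj), phi = phi, psi = psi)
  attr(out, "residue") <- list(chain = chain, resseq = resseq,
                               resname = top$resname[iCA])
  class(out) <- c("dihedral_series", "data.frame")
  out
}

#' Ramachandran occupancy over a trajectory period
#'
#' Normalized 2D histogram of (phi, psi) over a time window, on a regular
#' grid covering (-180, 180] in both angles. Snapshots with an undefined
#' angle are dropped.
#'
#' @param series a [phi_psi()] result.
#' @param period optional `c(t_start_ns, t_end_ns)` inclusive window;
#'   `NULL` uses the whole series.
#' @param grid_size bins per axis; default 36 (10-degree bins).
#' @return `grid_size x grid_size` matrix of class `"rama_occupancy"`
#'   summing to 1, with phi in rows, psi in columns, and bin `breaks` as an
#'   attribute.
#' @export
rama_occupancy <- function(series, period = NULL, grid_size = 36) {
  keep <- !is.na(series$phi) & !is.na(series$psi)
  if (!is.null(period)) {
    stopifnot(length(period) == 2L)
    keep <- keep & series$time_ns >= period[1] & series$time_ns <= period[2]
  }
  if (!any(keep))
    stop("no snapshots fall in the requested period", call. = FALSE)
  breaks <- seq(-180, 180, length.out = grid_size + 1L)
  # bins are (low, high]: left-open to match angles reported in (-180, 180]
  bin <- function(a) {
    i <- findInterval(a, breaks, left.open = TRUE)
    i[i < 1L] <- 1L; i[i > grid_size] <- grid_size
    i
  }
  m <- matrix(0, grid_size, grid_size)
  tab <- table(factor(bin(series$phi[keep]), levels = seq_len(grid_size)),
               factor(bin(series$psi[keep]), levels = seq_len(grid_size)))
  m[] <- as.numeric(tab) / sum(tab)
  attr(m, "breaks") <- breaks
  class(m) <- c("rama_occupancy", class(m))
  m
}

#' Jensen-Shannon divergence between two Ramachandran occupancies
#'
#' Base-2 Jensen-Shannon divergence between two occupancy grids, which lies
#' in \[0, 1\]: 0 for identical distributions, 1 for distributions with
#' disjoint support.
#'
#' @param a,b [rama_occupancy()] grids of identical size.
#' @return A scalar in \[0, 1\].
#' @export
occupancy_divergence <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("occupancy grids have different sizes", call. = FALSE)
  p <- as.numeric(a); q <- as.numeric(b)
  m <- (p + q) / 2
  kl <- function(x, y) {
    nz <- x > 0
    sum(x[nz] * log2(x[nz] / y[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' @export
print.dihedral_series <- function(x, ...) {
  r <- attr(x, "residue")
  cat(sprintf("<dihedral_series> %s %s:%d, %d snapshots\n",
              r$resname, r$chain, r$resseq, nrow(x)))
  invisible(x)
}
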