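# Independent oracles and small fixture builders shared across the suite.

# Brute-force superposition RMSD: exhaustive Euler-angle grid followed by
# Nelder-Mead refinement. Centroids are aligned analytically for every
# candidate rotation, so only the rotation is searched. Deliberately
# independent of the SVD route used by kabsch().
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
euler_rot <- function(p) rot_z(p[1]) %*% rot_y(p[2]) %*% rot_z(p[3])

rmsd_bruteforce <- function(mobile, target, grid_deg = 15) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(target, 2, colMeans(target))
  obj <- function(p) {
    R <- euler_rot(p)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  step <- grid_deg * pi / 180
  alphas <- seq(0, 2 * pi - step, by = step)
  betas <- seq(0, pi, by = step)
  best <- Inf; best_p <- c(0, 0, 0)
  for (a in alphas) for (b in betas) for (g in alphas) {
    v <- obj(c(a, b, g))
    if (v < best) { best <- v; best_p <- c(a, b, g) }
  }
  opt <- stats::optim(best_p, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  min(best, opt$value)
}

# Random well-conditioned coordinate set
random_coords <- function(k, scale = 5) matrix(stats::rnorm(3 * k, 0, scale), k, 3)

# Random proper rotation
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Minimal two-chain structure with named side-chain atoms at prescribed
# positions: `atoms` is a data.frame(chain, resseq, resname, name, x, y, z).
tiny_structure <- function(atoms) as_structure(atoms)

# A glutamate/arginine pair with the acidic O placed `dist` from the basic N;
# backbone atoms included so backbone-only rules can be exercised.
glu_arg_pair <- function(dist) {
  tiny_structure(data.frame(
    chain = c("A", "A", "A", "A", "A", "B", "B", "B", "B", "B"),
    resseq = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    resname = c(rep("GLU", 5), rep("ARG", 5)),
    name = c("N", "CA", "C", "O", "OE2", "N", "CA", "C", "O", "NH1"),
    x = c(0, 1.5, 2.5, 2.5, 1.5, 20, 21.5, 22.5, 22.5, 1.5 + dist),
    y = c(0, 0, 1, 2.2, 2.0, 20, 20, 21, 22.2, 2.0),
    z = c(0, 0, 0, 0, 0, 20, 20, 20, 20, 0)))
}

# Deterministic small trajectory built directly from a coordinate function:
# f(t) returns an natoms x 3 matrix, t = 1..n.
manual_traj <- function(topology, n, f, dt_ns = 1) {
  xyz <- t(vapply(seq_len(n), function(t) as.numeric(t(f(t))),
                  numeric(3 * nrow(topology))))
  trajectory(topology, xyz, dt_ns = dt_ns)
}

ca_topology <- function(n, chain = "A") {
  data.frame(serial = seq_len(n), name = "CA", resname = "ALA", chain = chain,
             resseq = seq_len(n), icode = "", element = "C")
}
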