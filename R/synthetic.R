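## Synthetic two-chain complex trajectories with known ground truth -----------

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic complex trajectory
#'
#' Describes a two-chain complex trajectory with planted, exactly known
#' structure: discrete conformational states with a dwell schedule,
#' per-residue isotropic Gaussian fluctuations, inter-chain contacts present
#' for prescribed fractions of snapshots, and sinusoidal collective-motion
#' modes. [simulate_traj()] realizes it; [ground_truth()] returns what every
#' downstream analysis should recover.
#'
#' Defaults mirror a 2 microsecond run sampled every 2 ns: 1001 snapshots at
#' `dt_ns = 2`.
#'
#' @param n_res_a,n_res_b residues per chain (chains "A" and "B").
#' @param backbone `"calpha_only"` (one CA per residue) or `"full_backbone"`
#'   (N, CA, C, O per residue).
#' @param resnames_a,resnames_b residue names per chain (recycled).
#' @param sigma per-residue isotropic fluctuation standard deviation per
#'   coordinate, Angstrom; scalar or one value per residue (chain A then B).
#' @param states list of per-atom displacement vectors (length `3N` numeric,
#'   or `NULL` for the undisplaced reference state); see
#'   [add_state_displacement()].
#' @param state_schedule integer vector of length `n_snapshots` giving the
#'   state index of each snapshot; default all 1.
#' @param contacts list of contact descriptors
#'   `list(a = "A:5:OE1", b = "B:3:NZ", bound = 3.0, unbound = 8.0,
#'   duty = 0.2, schedule = "random"|"block")`. Atoms named here that do not
#'   exist in the plain backbone are added to the named residue.
#' @param modes list of collective modes
#'   `list(vector = <3N unit vector>, amplitude = A, period = P)`; snapshot
#'   `t` (0-based) is displaced by `A * sin(2 * pi * t / P)` along the
#'   vector. See [add_planted_mode()].
#' @param n_snapshots,dt_ns snapshot count and spacing (ns).
#' @param ar1 optional AR(1) coefficient for temporally correlated noise
#'   (default 0, independent snapshots).
#' @param chain_sep inter-chain offset of the reference geometry, Angstrom.
#' @param seed integer; fixed seed implies bit-identical output.
#' @return Object of class `"sim_spec"`.
#' @export
sim_spec <- function(n_res_a = 30, n_res_b = 30,
                     backbone = c("calpha_only", "full_backbone"),
                     resnames_a = "ALA", resnames_b = "ALA",
                     sigma = 0.5, states = list(), state_schedule = NULL,
                     contacts = list(), modes = list(),
                     n_snapshots = 1001, dt_ns = 2, ar1 = 0,
                     chain_sep = 30, seed = 1) {
  backbone <- match.arg(backbone)
  n_res <- n_res_a + n_res_b
  stopifnot(n_res_a >= 1, n_res_b >= 1, n_snapshots >= 1, dt_ns > 0,
            ar1 >= 0, ar1 < 1, seed == as.integer(seed))
  sigma <- rep_len(sigma, n_res)
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (is.null(state_schedule)) state_schedule <- rep(1L, n_snapshots)
  if (length(state_schedule) != n_snapshots)
    stop("state_schedule length must equal n_snapshots", call. = FALSE)
  n_states <- max(length(states), 1L)
  if (any(state_schedule < 1L | state_schedule > n_states))
    stop("state_schedule references undefined states", call. = FALSE)
  for (ct in contacts) {
    stopifnot(is.character(ct$a), is.character(ct$b),
              ct$bound > 0, ct$unbound > 0)
    if (ct$duty < 0 || ct$duty > 1)
      stop("contact duty cycle must be in [0, 1]", call. = FALSE)
    if (!(ct$schedule %||% "random") %in% c("random", "block"))
      stop("contact schedule must be 'random' or 'block'", call. = FALSE)
  }
  spec <- structure(list(
    n_res_a = n_res_a, n_res_b = n_res_b, backbone = backbone,
    resnames_a = rep_len(resnames_a, n_res_a),
    resnames_b = rep_len(resnames_b, n_res_b),
    sigma = sigma, states = states, state_schedule = as.integer(state_schedule),
    contacts = contacts, modes = modes,
    n_snapshots = as.integer(n_snapshots), dt_ns = dt_ns, ar1 = ar1,
    chain_sep = chain_sep, seed = as.integer(seed)), class = "sim_spec")
  check_mode_orthonormality(spec)
  spec
}

check_mode_orthonormality <- function(spec) {
  if (length(spec$modes) < 1L) return(invisible(TRUE))
  V <- vapply(spec$modes, function(m) as.numeric(m$vector),
              numeric(length(spec$modes[[1]]$vector)))
  G <- crossprod(V)
  if (max(abs(G - diag(ncol(V)))) > 1e-8)
    stop("planted mode vectors must be mutually orthonormal", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("<sim_spec> %d+%d residues (%s), %d snapshots x %g ns, seed %d\n",
              x$n_res_a, x$n_res_b, x$backbone, x$n_snapshots, x$dt_ns, x$seed))
  cat(sprintf("  states: %d, contacts: %d, modes: %d, sigma %.2f..%.2f A\n",
              max(length(x$states), 1L), length(x$contacts), length(x$modes),
              min(x$sigma), max(x$sigma)))
  invisible(x)
}

## Reference geometry ---------------------------------------------------------

# NeRF atom placement: position d such that |c-d| = bond,
# angle(b,c,d) = theta (deg) and dihedral(a,b,c,d) = chi (deg).
nerf_place <- function(a, b, c, bond, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ch), bond * sin(th) * sin(ch))
  bc <- (c - b) / sqrt(sum((c - b)^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(c + M %*% d2)
}

#' Build an ideal peptide backbone
#'
#' Constructs N, CA, C, O coordinates for a chain with uniform backbone
#' dihedrals and ideal bond geometry (N-CA 1.458, CA-C 1.525, C-N 1.329,
#' C=O 1.231 Angstrom; trans peptide bonds). An alpha-helix corresponds to
#' `phi = -57`, `psi = -47`.
#'
#' @param n_res number of residues.
#' @param phi,psi backbone dihedrals, degrees (recycled per residue).
#' @param chain chain id.
#' @param resname residue names (recycled).
#' @param resseq_start first residue number.
#' @return An [as_structure()] object with `4 * n_res` atoms.
#' @export
build_peptide <- function(n_res, phi = -57, psi = -47, chain = "A",
                          resname = "ALA", resseq_start = 1L) {
  stopifnot(n_res >= 2)
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  co <- matrix(0, 4L * n_res, 3L)
  idx <- function(i, k) 4L * (i - 1L) + k   # k: 1=N 2=CA 3=C 4=O
  co[idx(1, 1), ] <- c(0, 0, 0)
  co[idx(1, 2), ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  co[idx(1, 3), ] <- co[idx(1, 2), ] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    if (i > 1L) {
      co[idx(i, 1), ] <- nerf_place(co[idx(i - 1, 1), ], co[idx(i - 1, 2), ],
                                    co[idx(i - 1, 3), ], 1.329, 116.2, psi[i - 1])
      co[idx(i, 2), ] <- nerf_place(co[idx(i - 1, 2), ], co[idx(i - 1, 3), ],
                                    co[idx(i, 1), ], 1.458, 121.7, 180)
      co[idx(i, 3), ] <- nerf_place(co[idx(i - 1, 3), ], co[idx(i, 1), ],
                                    co[idx(i, 2), ], 1.525, 111.2, phi[i])
    }
    opsi <- if (i < n_res) psi[i] + 180 else psi[i] + 180
    co[idx(i, 4), ] <- nerf_place(co[idx(i, 1), ], co[idx(i, 2), ],
                                  co[idx(i, 3), ], 1.231, 120.5,
                                  ((opsi + 180) %% 360) - 180)
  }
  atoms <- data.frame(
    name = rep(c("N", "CA", "C", "O"), n_res),
    resname = rep(rep_len(resname, n_res), each = 4L),
    chain = chain,
    resseq = rep(seq.int(resseq_start, length.out = n_res), each = 4L))
  as_structure(atoms, co, label = sprintf("ideal peptide (%d res)", n_res))
}

#' Build the reference structure of a synthetic complex
#'
#' Chain A along x at the origin; chain B parallel at `chain_sep` Angstrom
#' in y, so the chains share no close contacts except the ones the spec
#' plants. `calpha_only` places consecutive CA atoms exactly 3.8 Angstrom
#' apart; `full_backbone` builds ideal extended peptides. Contact atoms named
#' in the spec that are not backbone atoms are appended to their residue
#' (1.5 Angstrom from the CA), so planted salt bridges and hydrogen bonds can
#' use real side-chain atom names.
#'
#' @param spec a [sim_spec()].
#' @return An [as_structure()] reference snapshot.
#' @export
build_reference <- function(spec) {
  make_chain <- function(n, ch, resnames, y_off) {
    if (spec$backbone == "calpha_only") {
      atoms <- data.frame(name = "CA", resname = resnames, chain = ch,
                          resseq = seq_len(n))
      co <- cbind(3.8 * (seq_len(n) - 1L), y_off, 0)
      as_structure(atoms, co)
    } else {
      s <- build_peptide(n, phi = -120, psi = 130, chain = ch,
                         resname = resnames)
      s$y <- s$y + y_off
      s
    }
  }
  a <- make_chain(spec$n_res_a, "A", spec$resnames_a, 0)
  b <- make_chain(spec$n_res_b, "B", spec$resnames_b, spec$chain_sep)
  s <- rbind(as.data.frame(a), as.data.frame(b))
  # append any contact atoms that are not part of the backbone
  for (ct in spec$contacts) for (key in c(ct$a, ct$b)) {
    p <- strsplit(key, ":", fixed = TRUE)[[1]]
    if (length(p) != 3L) stop("bad atom key: ", key, call. = FALSE)
    have <- s$chain == p[1] & s$resseq == as.integer(p[2]) & s$name == p[3]
    if (any(have)) next
    res <- s$chain == p[1] & s$resseq == as.integer(p[2])
    if (!any(res))
      stop("contact key references missing residue: ", key, call. = FALSE)
    ca <- s[res & s$name == "CA", ][1, ]
    s <- rbind(s, transform(ca, name = p[3], x = ca$x, y = ca$y, z = ca$z + 1.5))
  }
  s <- s[order(s$chain, s$resseq), ]
  s$serial <- seq_len(nrow(s))
  rownames(s) <- NULL
  out <- as_structure(s, label = "synthetic complex reference")
  # planted geometry must keep the chains apart except at contacts
  gap <- min_interchain_distance(out, exclude = contact_atom_keys(spec))
  if (is.finite(gap) && gap < 8)
    stop(sprintf("chains overlap after placement (min inter-chain distance %.1f A)", gap),
         call. = FALSE)
  out
}

contact_atom_keys <- function(spec)
  unlist(lapply(spec$contacts, function(ct) c(ct$a, ct$b)))

min_interchain_distance <- function(s, exclude = NULL) {
  keys <- atom_keys(s)
  keep <- !(keys %in% exclude)
  ia <- which(s$chain == "A" & keep); ib <- which(s$chain == "B" & keep)
  if (!length(ia) || !length(ib)) return(Inf)
  co <- struct_coords(s)
  min(sqrt(pmax(outer(rowSums(co[ia, , drop = FALSE]^2),
                      rowSums(co[ib, , drop = FALSE]^2), `+`) -
                2 * co[ia, , drop = FALSE] %*% t(co[ib, , drop = FALSE]), 0)))
}

## Planted displacement helpers -----------------------------------------------

# Orthonormal basis of the six rigid-body displacement directions (three
# translations, three infinitesimal rotations about the centroid).
rigid_basis <- function(coords) {
  n <- nrow(coords)
  ctr <- sweep(coords, 2, colMeans(coords))
  tr <- vapply(1:3, function(k) {
    v <- matrix(0, n, 3); v[, k] <- 1; flat_coords(v)
  }, numeric(3 * n))
  rot <- vapply(1:3, function(k) {
    ax <- c(0, 0, 0); ax[k] <- 1
    flat_coords(t(apply(ctr, 1, function(r) cross3(ax, r))))
  }, numeric(3 * n))
  qr.Q(qr(cbind(tr, rot)))
}

# Random 3N direction orthogonal to rigid-body motion and to `avoid` columns.
nonrigid_direction <- function(coords, seed, avoid = NULL) {
  n3 <- 3L * nrow(coords)
  B <- cbind(rigid_basis(coords), avoid)
  with_seed(seed, {
    v <- stats::rnorm(n3)
    v <- v - B %*% crossprod(B, v)
    as.numeric(v / sqrt(sum(v^2)))
  })
}

#' Add a planted conformational state to a spec
#'
#' Generates a random per-atom displacement direction orthogonal to all
#' rigid-body motions (so superposition cannot remove it) and scales it so
#' the RMS per-atom displacement from the reference equals `separation`.
#' The superposition RMSD between the two state centres is then close to
#' `separation` by construction.
#'
#' @param spec a [sim_spec()].
#' @param separation target RMS displacement, Angstrom.
#' @param seed seed for the random direction (defaults to the spec seed
#'   offset by the state index).
#' @return The spec with one more entry in `states`.
#' @export
add_state_displacement <- function(spec, separation, seed = NULL) {
  ref <- struct_coords(build_reference(spec))
  if (is.null(seed)) seed <- spec$seed + 1000L + length(spec$states)
  v <- nonrigid_direction(ref, seed)
  if (length(spec$states) == 0L)
    spec$states <- list(NULL)  # state 1 is the undisplaced reference
  spec$states <- c(spec$states, list(v * separation * sqrt(nrow(ref))))
  spec
}

#' Set a contiguous dwell schedule on a spec
#'
#' Convenience wrapper: assigns [dwell_schedule()] proportions to the spec's
#' `state_schedule`, validating against the defined states.
#'
#' @param spec a [sim_spec()].
#' @param proportions state dwell proportions (one per state).
#' @return The spec with `state_schedule` replaced.
#' @export
set_dwell <- function(spec, proportions) {
  if (length(proportions) > max(length(spec$states), 1L))
    stop("more dwell proportions than defined states", call. = FALSE)
  spec$state_schedule <- dwell_schedule(spec$n_snapshots, proportions)
  spec
}

#' Add a planted collective-motion mode to a spec
#'
#' Generates a unit 3N direction orthogonal to rigid-body motions and to all
#' previously planted modes, moved sinusoidally with the given amplitude and
#' period. Over many snapshots the mode contributes a covariance eigenvalue
#' close to `amplitude^2 / 2`.
#'
#' @param spec a [sim_spec()].
#' @param amplitude peak displacement along the mode, Angstrom.
#' @param period oscillation period, snapshots.
#' @param seed seed for the random direction.
#' @return The spec with one more entry in `modes`.
#' @export
add_planted_mode <- function(spec, amplitude, period, seed = NULL) {
  ref <- struct_coords(build_reference(spec))
  if (is.null(seed)) seed <- spec$seed + 2000L + length(spec$modes)
  avoid <- if (length(spec$modes))
    vapply(spec$modes, function(m) m$vector, numeric(3 * nrow(ref))) else NULL
  v <- nonrigid_direction(ref, seed, avoid)
  spec$modes <- c(spec$modes, list(list(vector = v, amplitude = amplitude,
                                        period = period)))
  check_mode_orthonormality(spec)
  spec
}

#' Contiguous dwell schedule from state proportions
#'
#' Builds a state schedule of contiguous blocks with the given proportions
#' (e.g. `c(0.6, 0.4)` dwells in state 1 for the first 60% of snapshots,
#' then state 2).
#'
#' @param n_snapshots schedule length.
#' @param proportions nonnegative weights, one per state; normalized to 1.
#' @return Integer vector of length `n_snapshots`.
#' @export
dwell_schedule <- function(n_snapshots, proportions) {
  stopifnot(all(proportions >= 0), sum(proportions) > 0)
  p <- proportions / sum(proportions)
  edges <- round(cumsum(p) * n_snapshots)
  counts <- diff(c(0L, edges))
  rep(seq_along(counts), times = counts)
}

## Simulation -----------------------------------------------------------------

# Per-contact presence schedule (TRUE = bound), deterministic in spec$seed.
contact_schedules <- function(spec) {
  n <- spec$n_snapshots
  with_seed(spec$seed, lapply(spec$contacts, function(ct) {
    mode <- ct$schedule %||% "random"
    if (mode == "random") {
      stats::runif(n) < ct$duty
    } else {
      len <- round(ct$duty * n)
      if (len == 0L) rep(FALSE, n)
      else {
        start <- sample.int(n - len + 1L, 1L)
        seq_len(n) >= start & seq_len(n) < start + len
      }
    }
  }))
}

#' Realize a synthetic trajectory
#'
#' Snapshot `t` (0-based) is the reference plus the scheduled state
#' displacement, plus each mode's sinusoidal displacement, plus isotropic
#' Gaussian noise (optionally AR(1)-correlated in time); finally each planted
#' contact's second atom is repositioned along the fixed reference direction
#' from the first atom at exactly its bound or unbound distance for that
#' snapshot. Output is bit-identical for a fixed seed.
#'
#' @param spec a [sim_spec()].
#' @return A [trajectory()] with the realized contact schedules attached as
#'   attribute `"contact_schedules"`.
#' @export
simulate_traj <- function(spec) {
  ref_s <- build_reference(spec)
  ref <- struct_coords(ref_s)
  natoms <- nrow(ref)
  n <- spec$n_snapshots
  for (st in spec$states)
    if (!is.null(st) && length(st) != 3L * natoms)
      stop("state displacement length must be 3 x atom count", call. = FALSE)
  for (m in spec$modes)
    if (length(m$vector) != 3L * natoms)
      stop("mode vector length must be 3 x atom count", call. = FALSE)
  # per-atom sigma: residues of chain A then chain B
  res_index <- match(residue_keys(ref_s),
                     unique(residue_keys(ref_s)))
  sig_atom <- spec$sigma[res_index]
  schedules <- contact_schedules(spec)
  keys <- atom_keys(ref_s)
  contact_idx <- lapply(spec$contacts, function(ct) {
    ia <- match(ct$a, keys); ib <- match(ct$b, keys)
    u <- ref[ib, ] - ref[ia, ]
    list(a = ia, b = ib, u = u / sqrt(sum(u^2)))
  })
  sinmat <- if (length(spec$modes))
    vapply(spec$modes, function(m)
      m$amplitude * sin(2 * pi * (seq_len(n) - 1L) / m$period), numeric(n))
  else NULL
  xyz <- matrix(0, n, 3L * natoms)
  ref_flat <- flat_coords(ref)
  with_seed(spec$seed + 1L, {
    noise_prev <- NULL
    sd_flat <- as.numeric(rbind(sig_atom, sig_atom, sig_atom))
    for (t in seq_len(n)) {
      eps <- stats::rnorm(3L * natoms, 0, sd_flat)
      noise <- if (spec$ar1 > 0 && !is.null(noise_prev))
        spec$ar1 * noise_prev + sqrt(1 - spec$ar1^2) * eps else eps
      noise_prev <- noise
      flat <- ref_flat
      st <- if (length(spec$states)) spec$states[[spec$state_schedule[t]]] else NULL
      if (!is.null(st)) flat <- flat + st
      if (!is.null(sinmat)) for (m in seq_along(spec$modes))
        flat <- flat + sinmat[t, m] * spec$modes[[m]]$vector
      flat <- flat + noise
      co <- matrix(flat, ncol = 3L, byrow = TRUE)
      for (k in seq_along(contact_idx)) {
        ci <- contact_idx[[k]]
        dist <- if (schedules[[k]][t]) spec$contacts[[k]]$bound
                else spec$contacts[[k]]$unbound
        co[ci$b, ] <- co[ci$a, ] + ci$u * dist
      }
      xyz[t, ] <- flat_coords(co)
    }
  })
  tr <- trajectory(ref_s[setdiff(names(ref_s), c("x", "y", "z"))], xyz,
                   dt_ns = spec$dt_ns, label = "synthetic complex trajectory")
  attr(tr, "contact_schedules") <- schedules
  tr
}

#' Ground truth of a synthetic trajectory
#'
#' The exactly known quantities a correct analysis should recover:
#' per-snapshot state labels; per-residue expected C-alpha RMSF (noise,
#' planted-mode and state-mixture contributions combined in closed form);
#' per-contact expected and realized occupancy fractions with their
#' persistence tiers; and the planted mode vectors with their expected
#' covariance eigenvalues.
#'
#' Expected RMSF refers to residues whose atoms are not repositioned by a
#' contact schedule.
#'
#' @param spec a [sim_spec()].
#' @return A list with elements `state_labels`, `rmsf` (data frame),
#'   `contacts` (data frame) and `modes` (list).
#' @export
ground_truth <- function(spec) {
  ref_s <- build_reference(spec)
  ref <- struct_coords(ref_s)
  n <- spec$n_snapshots
  ca <- which(trimws(ref_s$name) == "CA")
  res_index <- match(residue_keys(ref_s), unique(residue_keys(ref_s)))
  # per-CA per-coordinate variances
  var_coord <- matrix(0, length(ca), 3L)
  for (m in spec$modes) {
    s <- m$amplitude * sin(2 * pi * (seq_len(n) - 1L) / m$period)
    vs <- stats::var(s) * (n - 1) / n
    vmat <- matrix(m$vector, ncol = 3L, byrow = TRUE)
    var_coord <- var_coord + vs * vmat[ca, , drop = FALSE]^2
  }
  if (length(spec$states) >= 1L && length(unique(spec$state_schedule)) > 1L) {
    disp <- vapply(seq_along(spec$states), function(k) {
      v <- spec$states[[k]] %||% rep(0, 3L * nrow(ref))
      as.numeric(v)
    }, numeric(3L * nrow(ref)))
    sched_disp <- t(disp[, spec$state_schedule, drop = FALSE])
    vc <- apply(sched_disp, 2, function(x) stats::var(x) * (n - 1) / n)
    vmat <- matrix(vc, ncol = 3L, byrow = TRUE)
    var_coord <- var_coord + vmat[ca, , drop = FALSE]
  }
  sig_res <- spec$sigma[res_index[ca]]
  rmsf_expected <- sqrt(rowSums(var_coord) + 3 * sig_res^2)
  rmsf <- data.frame(chain = ref_s$chain[ca], resseq = ref_s$resseq[ca],
                     sigma = sig_res, rmsf_expected = rmsf_expected)
  schedules <- contact_schedules(spec)
  contacts <- if (length(spec$contacts)) {
    keep <- vapply(spec$contacts, function(ct) ct$duty > 0, logical(1))
    data.frame(
      a = vapply(spec$contacts, `[[`, character(1), "a"),
      b = vapply(spec$contacts, `[[`, character(1), "b"),
      duty = vapply(spec$contacts, `[[`, numeric(1), "duty"),
      realized_fraction = vapply(schedules, mean, numeric(1)),
      tier = persistence_tier(vapply(schedules, mean, numeric(1))))[keep, ]
  } else data.frame()
  modes <- lapply(spec$modes, function(m) {
    s <- m$amplitude * sin(2 * pi * (seq_len(n) - 1L) / m$period)
    list(vector = m$vector, amplitude = m$amplitude, period = m$period,
         eigenvalue_expected = stats::var(s) * (n - 1) / n)
  })
  list(state_labels = spec$state_schedule, rmsf = rmsf,
       contacts = contacts, modes = modes)
}
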