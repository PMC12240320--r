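## Contact detection: hydrogen bonds, salt bridges, interfaces ----------------

# Donor and acceptor heavy atoms of the standard amino acids. Backbone N
# donates (except proline) and backbone O accepts for every residue;
# side-chain types below. Hydroxyls (SER/THR/TYR) both donate and accept.
SIDECHAIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH")
SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH")
ACIDIC_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_N <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
BASIC_N_HIS <- c(BASIC_N, list(HIS = c("ND1", "NE2")))
STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' Contact detection criteria
#'
#' Geometric criteria for hydrogen bonds and salt bridges. In `explicit`
#' hydrogen mode a bond requires donor-acceptor heavy-atom distance within
#' `hb_da_cutoff` (default 3.0 Angstrom) and a D-H...A angle within
#' `hb_angle_cutoff` degrees of linearity, the usual VMD-style settings. In
#' `heavy_only` mode (for trajectories stripped of hydrogens) only the
#' donor-acceptor distance is tested, with a more permissive default of
#' 3.5 Angstrom. Salt bridges use the side-chain oxygen of an acidic residue
#' versus the side-chain nitrogen of a basic residue within `sb_cutoff`
#' (default 3.2 Angstrom).
#'
#' @param hydrogen_mode `"heavy_only"` or `"explicit"`.
#' @param hb_da_cutoff donor-acceptor distance cutoff, Angstrom; default 3.5
#'   (`heavy_only`) or 3.0 (`explicit`).
#' @param hb_angle_cutoff maximum deviation of D-H...A from linearity,
#'   degrees (explicit mode only).
#' @param sb_cutoff acidic-O to basic-N distance cutoff, Angstrom.
#' @param include_his count histidine side-chain nitrogens as basic for salt
#'   bridges (off by default: protonation is usually unknown).
#' @return Object of class `"contact_criteria"`.
#' @export
contact_criteria <- function(hydrogen_mode = c("heavy_only", "explicit"),
                             hb_da_cutoff = NULL, hb_angle_cutoff = 20,
                             sb_cutoff = 3.2, include_his = FALSE) {
  hydrogen_mode <- match.arg(hydrogen_mode)
  if (is.null(hb_da_cutoff))
    hb_da_cutoff <- if (hydrogen_mode == "explicit") 3.0 else 3.5
  stopifnot(hb_da_cutoff > 0, hb_angle_cutoff > 0, sb_cutoff > 0)
  structure(list(hydrogen_mode = hydrogen_mode, hb_da_cutoff = hb_da_cutoff,
                 hb_angle_cutoff = hb_angle_cutoff, sb_cutoff = sb_cutoff,
                 include_his = include_his), class = "contact_criteria")
}

# Index donors/acceptors in a topology. Returns integer atom indices.
donor_indices <- function(top) {
  warn_nonstandard(top)
  bb <- trimws(top$name) == "N" & top$resname != "PRO"
  sc <- mapply(function(rn, nm) nm %in% (SIDECHAIN_DONORS[[rn]] %||% character(0)),
               top$resname, trimws(top$name))
  which((bb | sc) & top$resname %in% STANDARD_AA)
}
acceptor_indices <- function(top) {
  bb <- trimws(top$name) %in% c("O", "OXT")
  sc <- mapply(function(rn, nm) nm %in% (SIDECHAIN_ACCEPTORS[[rn]] %||% character(0)),
               top$resname, trimws(top$name))
  which((bb | sc) & top$resname %in% STANDARD_AA)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

warn_nonstandard <- function(top) {
  ns <- setdiff(unique(top$resname), STANDARD_AA)
  if (length(ns))
    warning("non-standard residues skipped in donor/acceptor typing: ",
            paste(ns, collapse = ", "), call. = FALSE)
}

# candidate atom-index pairs (a from set1, b from set2) honouring a
# partition: list(a = chains, b = chains) keeps only inter-partition pairs;
# NULL allows all pairs except those within the same or sequence-adjacent
# residue of one chain (bonded neighbours are not contacts).
candidate_pairs <- function(top, set1, set2, partition = NULL) {
  if (length(set1) == 0L || length(set2) == 0L)
    return(cbind(integer(0), integer(0)))
  pr <- expand.grid(a = set1, b = set2, KEEP.OUT.ATTRS = FALSE)
  if (!is.null(partition)) {
    unknown <- setdiff(c(partition$a, partition$b), unique(top$chain))
    if (length(unknown))
      stop("unknown chain id(s) in partition: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    keep <- (top$chain[pr$a] %in% partition$a & top$chain[pr$b] %in% partition$b) |
            (top$chain[pr$a] %in% partition$b & top$chain[pr$b] %in% partition$a)
    pr <- pr[keep, , drop = FALSE]
  } else {
    same_chain <- top$chain[pr$a] == top$chain[pr$b]
    near <- same_chain & abs(top$resseq[pr$a] - top$resseq[pr$b]) <= 1L
    pr <- pr[!near, , drop = FALSE]
  }
  as.matrix(pr)
}

pair_distances <- function(co, pairs) {
  sqrt(rowSums((co[pairs[, 1], , drop = FALSE] - co[pairs[, 2], , drop = FALSE])^2))
}

#' Detect hydrogen bonds in one snapshot
#'
#' Applies the distance (and, with explicit hydrogens, angle) criteria of
#' [contact_criteria()] to every donor/acceptor pair. With a partition only
#' inter-partition (e.g. chain A versus chain B) bonds are reported; without
#' one, pairs within the same or a sequence-adjacent residue are excluded.
#'
#' @param snapshot an [as_structure()] snapshot (e.g. from [get_frame()]).
#' @param criteria a [contact_criteria()].
#' @param partition optional `list(a = chains, b = chains)`.
#' @return Data frame of detected bonds: donor and acceptor chain, resseq,
#'   resname, atom name, and the D-A distance.
#' @export
hydrogen_bonds <- function(snapshot, criteria = contact_criteria(),
                           partition = NULL) {
  top <- snapshot
  co <- struct_coords(snapshot)
  don <- donor_indices(top)
  acc <- acceptor_indices(top)
  pairs <- candidate_pairs(top, don, acc, partition)
  # a donor atom can also be an acceptor (hydroxyls); drop self pairs
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty_contact_df())
  d <- pair_distances(co, pairs)
  ok <- d <= criteria$hb_da_cutoff
  pairs <- pairs[ok, , drop = FALSE]; d <- d[ok]
  if (criteria$hydrogen_mode == "explicit" && nrow(pairs) > 0L) {
    hyd <- which(top$element == "H")
    if (length(hyd) == 0L)
      stop("explicit hydrogen mode requested but the structure has no hydrogens; use hydrogen_mode = \"heavy_only\"",
           call. = FALSE)
    keep <- vapply(seq_len(nrow(pairs)), function(k) {
      di <- pairs[k, 1]; ai <- pairs[k, 2]
      # hydrogens covalently attached to the donor: same residue, within 1.2 A
      same_res <- hyd[top$chain[hyd] == top$chain[di] &
                      top$resseq[hyd] == top$resseq[di] &
                      top$icode[hyd] == top$icode[di]]
      if (length(same_res) == 0L) return(FALSE)
      hd <- sqrt(rowSums((co[same_res, , drop = FALSE] -
                          matrix(co[di, ], length(same_res), 3, byrow = TRUE))^2))
      hs <- same_res[hd < 1.2]
      if (length(hs) == 0L) return(FALSE)
      ang <- vapply(hs, function(h)
        vec_angle(co[di, ] - co[h, ], co[ai, ] - co[h, ]), numeric(1))
      any(180 - ang <= criteria$hb_angle_cutoff)
    }, logical(1))
    pairs <- pairs[keep, , drop = FALSE]; d <- d[keep]
  }
  contact_df(top, pairs, d)
}

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect salt bridges in one snapshot
#'
#' Side-chain oxygen of an aspartate/glutamate within the cutoff of a
#' side-chain nitrogen of lysine/arginine (histidine optionally). Backbone
#' atoms never qualify.
#'
#' @inheritParams hydrogen_bonds
#' @return Data frame as in [hydrogen_bonds()] with the acidic atom first.
#' @export
salt_bridges <- function(snapshot, criteria = contact_criteria(),
                         partition = NULL) {
  top <- snapshot
  co <- struct_coords(snapshot)
  basic <- if (isTRUE(criteria$include_his)) BASIC_N_HIS else BASIC_N
  ac <- which(mapply(function(rn, nm) nm %in% (ACIDIC_O[[rn]] %||% character(0)),
                     top$resname, trimws(top$name)))
  ba <- which(mapply(function(rn, nm) nm %in% (basic[[rn]] %||% character(0)),
                     top$resname, trimws(top$name)))
  pairs <- candidate_pairs(top, ac, ba, partition)
  if (nrow(pairs) == 0L) return(empty_contact_df())
  d <- pair_distances(co, pairs)
  ok <- d <= criteria$sb_cutoff
  contact_df(top, pairs[ok, , drop = FALSE], d[ok])
}

contact_df <- function(top, pairs, d) {
  if (nrow(pairs) == 0L) return(empty_contact_df())
  data.frame(
    chain_a = top$chain[pairs[, 1]], resseq_a = top$resseq[pairs[, 1]],
    resname_a = top$resname[pairs[, 1]], atom_a = top$name[pairs[, 1]],
    chain_b = top$chain[pairs[, 2]], resseq_b = top$resseq[pairs[, 2]],
    resname_b = top$resname[pairs[, 2]], atom_b = top$name[pairs[, 2]],
    distance = d, row.names = NULL)
}
empty_contact_df <- function() {
  data.frame(chain_a = character(0), resseq_a = integer(0),
             resname_a = character(0), atom_a = character(0),
             chain_b = character(0), resseq_b = integer(0),
             resname_b = character(0), atom_b = character(0),
             distance = numeric(0))
}

## Persistence ----------------------------------------------------------------

PERSISTENCE_TIERS <- c("below", ">0.1%", ">1%", "stable>5%")

persistence_tier <- function(fraction) {
  # strict "more than" comparisons at 5%, 1%, 0.1%
  tier <- ifelse(fraction > 0.05, "stable>5%",
          ifelse(fraction > 0.01, ">1%",
          ifelse(fraction > 0.001, ">0.1%", "below")))
  factor(tier, levels = PERSISTENCE_TIERS, ordered = TRUE)
}

#' Interaction persistence over a trajectory
#'
#' Detects hydrogen bonds and/or salt bridges in every snapshot and
#' aggregates them to residue pairs: a snapshot counts as "present" for a
#' pair when any qualifying atom pair exists. Each record carries the
#' occupied fraction of snapshots, the equivalent duration
#' (fraction x snapshots x dt), and a persistence tier with strict
#' more-than edges at 5%, 1% and 0.1% of the trajectory; over a 2
#' microsecond run sampled every 2 ns these edges correspond to 100, 20 and
#' 2 ns.
#'
#' @param traj a [trajectory()].
#' @param criteria a [contact_criteria()].
#' @param partition optional `list(a = , b = )` chain partition.
#' @param kind `"hbond"`, `"saltbridge"`, or `"both"`.
#' @return Data frame of class `"persistence"`: kind, residue identities,
#'   frames_present, fraction, duration_ns, tier. Pairs never observed are
#'   absent.
#' @export
persistence <- function(traj, criteria = contact_criteria(), partition = NULL,
                        kind = c("hbond", "saltbridge", "both")) {
  kind <- match.arg(kind)
  n <- nrow(traj$xyz)
  counts <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  tally <- function(df, what) {
    if (nrow(df) == 0L) return()
    key <- paste(what, df$chain_a, df$resseq_a, df$chain_b, df$resseq_b)
    for (k in unique(key)) {
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
      if (is.null(meta[[k]])) meta[[k]] <- df[match(k, key), ]
    }
  }
  for (i in seq_len(n)) {
    snap <- get_frame(traj, i)
    if (kind %in% c("hbond", "both"))
      tally(hydrogen_bonds(snap, criteria, partition), "hbond")
    if (kind %in% c("saltbridge", "both"))
      tally(salt_bridges(snap, criteria, partition), "saltbridge")
  }
  keys <- ls(counts)
  if (length(keys) == 0L) {
    out <- data.frame(kind = character(0), chain_a = character(0),
                      resseq_a = integer(0), resname_a = character(0),
                      chain_b = character(0), resseq_b = integer(0),
                      resname_b = character(0), frames_present = integer(0),
                      fraction = numeric(0), duration_ns = numeric(0),
                      tier = persistence_tier(numeric(0)))
    class(out) <- c("persistence", "data.frame")
    return(out)
  }
  rows <- do.call(rbind, lapply(keys, function(k) {
    m <- meta[[k]]
    data.frame(kind = sub(" .*", "", k),
               chain_a = m$chain_a, resseq_a = m$resseq_a, resname_a = m$resname_a,
               chain_b = m$chain_b, resseq_b = m$resseq_b, resname_b = m$resname_b,
               frames_present = counts[[k]])
  }))
  rows <- rows[order(rows$kind, rows$chain_a, rows$resseq_a,
                     rows$chain_b, rows$resseq_b), ]
  rows$fraction <- rows$frames_present / n
  rows$duration_ns <- rows$fraction * n * traj$dt_ns
  rows$tier <- persistence_tier(rows$fraction)
  rownames(rows) <- NULL
  class(rows) <- c("persistence", "data.frame")
  rows
}

#' @export
print.persistence <- function(x, ...) {
  cat(sprintf("<persistence> %d residue-pair interactions\n", nrow(x)))
  print(table(kind = x$kind, tier = x$tier))
  invisible(x)
}

## Interface residues ---------------------------------------------------------

#' Interface residues between two chain groups
#'
#' A residue is at the interface when any of its heavy atoms lies strictly
#' within the cutoff of any heavy atom of the other side. Reported for both
#' sides, with the minimal realized distance per residue.
#'
#' @param snapshot an [as_structure()] snapshot.
#' @param chains_a,chains_b chain id vectors for the two sides.
#' @param cutoff heavy-atom distance cutoff, Angstrom (strict `<`). The
#'   conventions in complex-interface work are 6, 5 or 4 depending on
#'   stringency.
#' @return List with data frames `a` and `b` (chain, resseq, resname,
#'   min_dist), possibly empty.
#' @export
interface_residues <- function(snapshot, chains_a, chains_b, cutoff = 6) {
  top <- snapshot
  unknown <- setdiff(c(chains_a, chains_b), unique(top$chain))
  if (length(unknown))
    stop("unknown chain id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  co <- struct_coords(snapshot)
  ia <- which(top$chain %in% chains_a & top$element != "H")
  ib <- which(top$chain %in% chains_b & top$element != "H")
  dm <- sqrt(pmax(outer(rowSums(co[ia, , drop = FALSE]^2),
                        rowSums(co[ib, , drop = FALSE]^2), `+`) -
                  2 * co[ia, , drop = FALSE] %*% t(co[ib, , drop = FALSE]), 0))
  hit <- which(dm < cutoff, arr.ind = TRUE)
  side <- function(idx_all, hits, d) {
    if (length(hits) == 0L)
      return(data.frame(chain = character(0), resseq = integer(0),
                        resname = character(0), min_dist = numeric(0)))
    rk <- residue_keys(top)[idx_all[hits]]
    agg <- tapply(d, rk, min)
    first <- idx_all[hits][!duplicated(rk)]
    out <- data.frame(chain = top$chain[first], resseq = top$resseq[first],
                      resname = top$resname[first],
                      min_dist = as.numeric(agg[rk[!duplicated(rk)]]))
    out[order(out$chain, out$resseq), , drop = FALSE]
  }
  list(a = side(ia, hit[, 1], dm[hit]), b = side(ib, hit[, 2], dm[hit]))
}

## Distance series ------------------------------------------------------------

#' Residue-pair minimum-distance time series
#'
#' Per-snapshot minimum pairwise distance between two atom groups, e.g. the
#' side-chain oxygens of one residue versus the side-chain nitrogens of
#' another, to follow a salt bridge through time.
#'
#' @param traj a [trajectory()].
#' @param group_a,group_b atom keys `"chain:resseq:name"` (as produced by
#'   internal atom keying) or integer atom indices.
#' @return Data frame of class `"distance_series"`: `time_ns`, `distance`.
#' @export
distance_series <- function(traj, group_a, group_b) {
  resolve_keys <- function(g) {
    if (is.numeric(g)) return(as.integer(g))
    keys <- atom_keys(traj$topology)
    idx <- match(g, keys)
    if (anyNA(idx))
      stop("atom key(s) not in topology: ",
           paste(g[is.na(idx)], collapse = ", "), call. = FALSE)
    idx
  }
  ia <- resolve_keys(group_a); ib <- resolve_keys(group_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("atom groups must be non-empty", call. = FALSE)
  pr <- as.matrix(expand.grid(a = ia, b = ib))
  vals <- vapply(seq_len(nrow(traj$xyz)), function(i) {
    co <- frame_coords(traj$xyz, i)
    min(pair_distances(co, pr))
  }, numeric(1))
  out <- data.frame(time_ns = frame_times(traj), distance = vals)
  class(out) <- c("distance_series", "data.frame")
  out
}

#' @export
plot.distance_series <- function(x, ...) {
  plot(x$time_ns, x$distance, type = "l", xlab = "time (ns)",
       ylab = "distance (A)", ...)
  invisible(x)
}
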