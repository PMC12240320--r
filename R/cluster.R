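## Frame coarsening and threshold clustering ----------------------------------

#' Coarsen snapshots into frames
#'
#' Groups consecutive snapshots into blocks ("frames"). Each frame's
#' structure is the per-atom mean of its snapshots' coordinates after
#' superposing every block member onto the block's first snapshot. Full
#' blocks of `block` snapshots are taken in order; a remainder forms a final
#' smaller frame, so 1001 snapshots at block 10 yield 101 frames (100 full
#' plus one singleton).
#'
#' @param traj a [trajectory()].
#' @param block snapshots per frame (>= 1).
#' @return Object of class `"frame_set"`: `topology`, `xyz` (one row per
#'   frame), `start`, `end` (snapshot indices), `start_ns`, `end_ns`,
#'   `mid_ns`, `dt_ns`.
#' @export
coarsen <- function(traj, block) {
  n <- nrow(traj$xyz)
  if (block < 1L) stop("block must be >= 1", call. = FALSE)
  if (block > n)
    stop(sprintf("block (%d) exceeds snapshot count (%d)", block, n), call. = FALSE)
  starts <- seq.int(1L, n, by = block)
  ends <- pmin(starts + block - 1L, n)
  xyz <- matrix(0, length(starts), ncol(traj$xyz))
  all_idx <- seq_len(nrow(traj$topology))
  for (f in seq_along(starts)) {
    members <- starts[f]:ends[f]
    ref <- frame_coords(traj$xyz, members[1L])
    acc <- ref
    for (s in members[-1L])
      acc <- acc + superpose_coords(frame_coords(traj$xyz, s), ref, all_idx)
    xyz[f, ] <- flat_coords(acc / length(members))
  }
  tm <- frame_times(traj)
  structure(list(topology = traj$topology, xyz = xyz,
                 start = starts, end = ends,
                 start_ns = tm[starts], end_ns = tm[ends],
                 mid_ns = (tm[starts] + tm[ends]) / 2,
                 dt_ns = traj$dt_ns, source = traj$label),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames over %d snapshots (t = %g..%g ns)\n",
              nrow(x$xyz), x$end[length(x$end)], x$start_ns[1],
              x$end_ns[length(x$end_ns)]))
  invisible(x)
}

#' Threshold clustering of an RMSD matrix
#'
#' Frames with pairwise RMSD below the cutoff are placed in the same cluster;
#' clusters are the connected components of that graph (the transitive
#' closure of the pairwise rule). Cluster ids are assigned in order of each
#' cluster's earliest member frame, so the labelling is deterministic. Each
#' cluster's representative is the member with minimal mean RMSD to the other
#' members (ties broken by the earliest frame), and the largest cluster is
#' identified.
#'
#' @param mat an [rmsd_matrix()].
#' @param cutoff RMSD threshold in Angstrom (strict `<`); default 2.
#' @return Object of class `"cluster_assignment"`: `labels` (per-frame id),
#'   `clusters` (list of member index vectors), `sizes`, `largest` (id),
#'   `representative` (per-cluster frame index), `cutoff`.
#' @export
cluster_threshold <- function(mat, cutoff = 2) {
  if (nrow(mat) != ncol(mat)) stop("RMSD matrix must be square", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  adj <- unclass(mat) < cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # relabel so cluster ids follow earliest member frame
  first_seen <- comp[!duplicated(comp)]
  labels <- match(comp, first_seen)
  clusters <- split(seq_along(labels), labels)
  names(clusters) <- seq_along(clusters)
  sizes <- lengths(clusters)
  rep_frames <- vapply(clusters, function(m) representative(mat, m), integer(1))
  structure(list(labels = labels, clusters = clusters, sizes = sizes,
                 largest = unname(which.max(sizes)),
                 representative = rep_frames, cutoff = cutoff,
                 times_ns = attr(mat, "times_ns")),
            class = "cluster_assignment")
}

#' Representative frame of a cluster
#'
#' The member with the minimal mean RMSD to the other members of the
#' cluster; for a singleton, that frame. Exact ties go to the earliest frame.
#'
#' @param mat an [rmsd_matrix()].
#' @param members frame indices of the cluster (non-empty).
#' @return A single frame index.
#' @export
representative <- function(mat, members) {
  if (length(members) == 0L) stop("members must be non-empty", call. = FALSE)
  if (length(members) == 1L) return(as.integer(members))
  sub <- unclass(mat)[members, members, drop = FALSE]
  mean_to_others <- rowSums(sub) / (length(members) - 1L)
  as.integer(members[which.min(mean_to_others)])  # which.min takes first on ties
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d frames, %d clusters (cutoff %g A)\n",
              length(x$labels), length(x$clusters), x$cutoff))
  for (id in seq_along(x$clusters)) {
    star <- if (id == x$largest) " [largest]" else ""
    cat(sprintf("  cluster %d: %d frames, representative frame %d%s\n",
                id, x$sizes[[id]], x$representative[[id]], star))
  }
  invisible(x)
}

#' Tabulate a cluster assignment
#'
#' @param object a [cluster_threshold()] result.
#' @param frames optional [coarsen()] frame set supplying time intervals.
#' @param ... unused.
#' @return Data frame: frame, cluster, is_representative, and (when `frames`
#'   is given) start_ns/end_ns.
#' @export
summary.cluster_assignment <- function(object, frames = NULL, ...) {
  out <- data.frame(frame = seq_along(object$labels), cluster = object$labels,
                    is_representative = seq_along(object$labels) %in%
                      object$representative)
  if (!is.null(frames)) {
    out$start_ns <- frames$start_ns
    out$end_ns <- frames$end_ns
  }
  out
}

#' Expected snapshot count of a regularly saved run
#'
#' A run of `total_ns` with coordinates recorded every `interval_ns`,
#' including the initial snapshot at t = 0, yields
#' `floor(total_ns / interval_ns) + 1` snapshots (a 2 microsecond run saved
#' every 2 ns gives 1001).
#'
#' @param total_ns run length, ns.
#' @param interval_ns save interval, ns.
#' @return Integer snapshot count.
#' @export
snapshot_count <- function(total_ns, interval_ns) {
  stopifnot(total_ns > 0, interval_ns > 0)
  as.integer(floor(total_ns / interval_ns)) + 1L
}
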