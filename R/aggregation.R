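ca_table <- function(traj) {
  top <- traj$topology
  rows <- which(top$is_peptide & top$atom_name == "CA")
  ord <- order(top$chain_id[rows], top$residue_index[rows])
  rows <- rows[ord]
  list(rows = rows,
       chain = top$chain_id[rows],
       resi = top$residue_index[rows],
       label = paste0(top$chain_id[rows], ":", top$residue_index[rows]))
}

#' Residue-level inter-peptide Calpha distance matrix
#'
#' Pairwise Calpha-Calpha Euclidean distances (Angstrom) between all
#' peptide residues in one frame, with the minimum-image convention
#' applied in x and y (the bilayer plane); z is non-periodic.
#' Intra-copy blocks (including the diagonal) are masked with NA so the
#' matrix describes inter-peptide geometry only.
#'
#' @param frame Frame index or frame list.
#' @param traj A `trajectory_set`.
#' @return Symmetric matrix with dimnames "chain:residue"; class
#'   `inter_peptide_heatmap`.
#' @export
ca_distance_matrix <- function(frame, traj) {
  if (is.numeric(frame) && length(frame) == 1L) frame <- traj$frames[[frame]]
  ca <- ca_table(traj)
  if (!length(ca$rows)) stop("no peptide CA atoms in topology")
  xyz <- frame$coords[ca$rows, , drop = FALSE]
  n <- nrow(xyz)
  dx <- outer(xyz[, 1], xyz[, 1], "-")
  dy <- outer(xyz[, 2], xyz[, 2], "-")
  dz <- outer(xyz[, 3], xyz[, 3], "-")
  if (!is.null(frame$box)) {
    dx <- dx - frame$box[1] * round(dx / frame$box[1])
    dy <- dy - frame$box[2] * round(dy / frame$box[2])
  }
  d <- sqrt(dx^2 + dy^2 + dz^2)
  same <- outer(ca$chain, ca$chain, "==")
  d[same] <- NA_real_
  dimnames(d) <- list(ca$label, ca$label)
  structure(d, class = c("inter_peptide_heatmap", "matrix"),
            chain = ca$chain, resi = ca$resi)
}

#' Time-averaged inter-peptide distance heatmap
#'
#' Elementwise mean of per-frame Calpha distance matrices over a frame
#' range; low values flag the residue pairs that mediate self-association.
#'
#' @param traj A `trajectory_set`.
#' @param frame_range Frame indices (default all).
#' @return An `inter_peptide_heatmap` matrix (Angstrom).
#' @export
time_average_heatmap <- function(traj, frame_range = NULL) {
  if (is.null(frame_range)) frame_range <- seq_along(traj$frames)
  if (!length(frame_range)) stop("empty frame range")
  acc <- NULL
  for (fi in frame_range) {
    m <- ca_distance_matrix(fi, traj)
    acc <- if (is.null(acc)) unclass(m) else acc + unclass(m)
  }
  out <- acc / length(frame_range)
  m1 <- ca_distance_matrix(frame_range[1], traj)
  structure(out, class = c("inter_peptide_heatmap", "matrix"),
            chain = attr(m1, "chain"), resi = attr(m1, "resi"))
}

# minimum inter-copy CA-CA distance and contact count per copy pair
pairwise_copy_contacts <- function(dmat, cutoff) {
  chain <- attr(dmat, "chain")
  copies <- unique(chain)
  nc <- length(copies)
  mind <- matrix(Inf, nc, nc, dimnames = list(copies, copies))
  ncon <- matrix(0L, nc, nc, dimnames = list(copies, copies))
  for (a in seq_len(nc - 1L)) for (b in (a + 1L):nc) {
    blk <- dmat[chain == copies[a], chain == copies[b], drop = FALSE]
    mind[a, b] <- mind[b, a] <- min(blk, na.rm = TRUE)
    ncon[a, b] <- ncon[b, a] <- sum(blk <= cutoff, na.rm = TRUE)
  }
  list(copies = copies, min_dist = mind, n_contacts = ncon)
}

#' Oligomer partition of peptide copies in one frame
#'
#' Two copies are in contact when at least `min_contacts` inter-copy
#' Calpha-Calpha distances fall at or below `contact_cutoff`; oligomers are
#' the connected components of the resulting contact graph.
#'
#' @param frame Frame index or frame list.
#' @param traj A `trajectory_set`.
#' @param contact_cutoff Contact distance in Angstrom (default 7).
#' @param min_contacts Minimum number of residue-pair contacts (default 1).
#' @return List of class `oligomer_partition`: `clusters` (list of chain-id
#'   vectors), `sizes`, `time`, and the parameters used.
#' @export
oligomer_partition <- function(frame, traj, contact_cutoff = 7,
                               min_contacts = 1) {
  stopifnot(contact_cutoff > 0)
  tm <- if (is.numeric(frame) && length(frame) == 1L)
    traj$frames[[frame]]$time else frame$time
  dmat <- ca_distance_matrix(frame, traj)
  pc <- pairwise_copy_contacts(dmat, contact_cutoff)
  adj <- pc$n_contacts >= min_contacts
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  clusters <- split(pc$copies, comp$membership)
  names(clusters) <- NULL
  structure(list(clusters = clusters,
                 sizes = vapply(clusters, length, 0L),
                 time = tm,
                 contact_cutoff = contact_cutoff,
                 min_contacts = min_contacts),
            class = "oligomer_partition")
}

#' @export
print.oligomer_partition <- function(x, ...) {
  cat(sprintf("<oligomer_partition> %d cluster(s), sizes: %s\n",
              length(x$clusters), paste(sort(x$sizes, decreasing = TRUE),
                                        collapse = " ")))
  invisible(x)
}

size_histogram <- function(sizes) {
  c(monomer = sum(sizes == 1L), dimer = sum(sizes == 2L),
    trimer = sum(sizes == 3L), tetramer = sum(sizes == 4L),
    ge5 = sum(sizes >= 5L))
}

#' Oligomer-state populations over a trajectory
#'
#' Per-frame cluster-size histograms (monomer/dimer/trimer/tetramer/>=5)
#' plus a "stable" histogram in which an aggregate of two or more copies is
#' counted only while the identical copy set persists for at least
#' `persistence` consecutive frames, excluding transient brushes.
#'
#' @inheritParams oligomer_partition
#' @param traj A `trajectory_set`.
#' @param frame_range Frame indices (default all).
#' @param persistence Minimum consecutive-frame run for a stable
#'   aggregate (default 10 frames).
#' @return List: `per_frame` (data.frame of raw counts), `stable`
#'   (data.frame of persistence-filtered counts), `time_average` (mean raw
#'   counts), `partitions` (list of `oligomer_partition`), `params`.
#' @export
oligomer_populations <- function(traj, contact_cutoff = 7, min_contacts = 1,
                                 persistence = 10, frame_range = NULL) {
  if (is.null(frame_range)) frame_range <- seq_along(traj$frames)
  parts <- lapply(frame_range, oligomer_partition, traj = traj,
                  contact_cutoff = contact_cutoff,
                  min_contacts = min_contacts)
  nf <- length(parts)
  raw <- t(vapply(parts, function(p) size_histogram(p$sizes), numeric(5)))
  # persistence: per aggregate key (sorted member set), find runs of
  # consecutive frames in which the identical set is present
  keys_by_frame <- lapply(parts, function(p)
    vapply(p$clusters[vapply(p$clusters, length, 0L) >= 2L],
           function(cl) paste(sort(cl), collapse = "+"), ""))
  all_keys <- unique(unlist(keys_by_frame))
  stable_flag <- lapply(seq_len(nf), function(i) character(0))
  for (k in all_keys) {
    present <- vapply(keys_by_frame, function(v) k %in% v, TRUE)
    r <- rle(present)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= persistence))
      for (i in starts[j]:ends[j])
        stable_flag[[i]] <- c(stable_flag[[i]], k)
  }
  stable <- t(vapply(seq_len(nf), function(i) {
    sizes <- lengths(strsplit(stable_flag[[i]], "\\+"))
    size_histogram(sizes)
  }, numeric(5)))
  times <- vapply(parts, function(p) if (is.null(p$time)) NA_real_ else p$time,
                  0)
  list(per_frame = data.frame(frame = frame_range, time = times, raw),
       stable = data.frame(frame = frame_range, time = times, stable),
       time_average = colMeans(raw),
       partitions = parts,
       params = list(contact_cutoff = contact_cutoff,
                     min_contacts = min_contacts,
                     persistence = persistence))
}

#' Residue pairs mediating inter-peptide contacts
#'
#' For every copy pair in contact (minimum time-averaged inter-copy
#' distance at or below `contact_cutoff`), ranks the residue pairs by
#' ascending time-averaged Calpha-Calpha distance: the first-ranked pairs
#' are the contacts mediating self-association.
#'
#' @param heatmap An `inter_peptide_heatmap` (usually time-averaged).
#' @param contact_cutoff Contact distance in Angstrom (default 7).
#' @param top_k Ranked pairs reported per copy pair (default 10).
#' @return Named list, one data.frame (`residue_i`, `residue_j`,
#'   `distance`) per contacting copy pair "A-B"; empty list if no pair is
#'   in contact.
#' @export
mediating_residues <- function(heatmap, contact_cutoff = 7, top_k = 10) {
  chain <- attr(heatmap, "chain")
  resi <- attr(heatmap, "resi")
  copies <- unique(chain)
  out <- list()
  for (a in seq_along(copies)) for (b in seq_along(copies)) {
    if (b <= a) next
    blk <- unclass(heatmap)[chain == copies[a], chain == copies[b],
                            drop = FALSE]
    if (!any(blk <= contact_cutoff, na.rm = TRUE)) next
    ri <- resi[chain == copies[a]]
    rj <- resi[chain == copies[b]]
    ord <- order(blk)[seq_len(min(top_k, length(blk)))]
    ij <- arrayInd(ord, dim(blk))
    out[[paste0(copies[a], "-", copies[b])]] <- data.frame(
      residue_i = ri[ij[, 1]], residue_j = rj[ij[, 2]],
      distance = blk[ord])
  }
  out
}
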