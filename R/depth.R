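#' z position of a leaflet's phosphate plane
#'
#' Mean z coordinate of the phosphate atoms assigned to one leaflet in a
#' frame; the reference surface for insertion depths.
#'
#' @param frame Frame index or frame list.
#' @param traj A `trajectory_set`.
#' @param leaflet "upper" (default) or "lower".
#' @return Plane z in Angstrom.
#' @export
phosphate_plane_z <- function(frame, traj, leaflet = c("upper", "lower")) {
  leaflet <- match.arg(leaflet)
  if (is.numeric(frame) && length(frame) == 1L) frame <- traj$frames[[frame]]
  lab <- assign_leaflets(frame, traj)
  idx <- as.integer(names(lab)[lab == leaflet])
  if (!length(idx)) stop("leaflet '", leaflet, "' is empty")
  mean(frame$coords[idx, 3])
}

residue_ref_z <- function(frame, traj, chain, reference_atom = "CA") {
  top <- traj$topology
  rows <- which(top$chain_id == chain & top$is_peptide)
  resi <- sort(unique(top$residue_index[rows]))
  z <- rep(NA_real_, length(resi))
  for (k in seq_along(resi)) {
    sel <- if (identical(reference_atom, "COM")) {
      rows[top$residue_index[rows] == resi[k]]
    } else {
      rows[top$residue_index[rows] == resi[k] &
             top$atom_name[rows] == reference_atom]
    }
    if (length(sel)) z[k] <- mean(frame$coords[sel, 3])
  }
  names(z) <- resi
  z
}

#' Per-residue membrane insertion-depth profile
#'
#' Signed depth of each residue relative to the upper-leaflet phosphate
#' plane: depth = plane_z(upper) - z(reference atom). Positive values mean
#' the residue sits below the plane (inserted into the bilayer), negative
#' above it (solvent side). Averaged over frames and over the requested
#' peptide copies. Peptides that engage the lower leaflet can be analysed
#' with `leaflet = "lower"`, where z is reflected so the same sign
#' convention holds (positive = inserted).
#'
#' @param traj A `trajectory_set`.
#' @param chains Peptide chains to average over (default all).
#' @param reference_atom Atom name used as the residue's reference point
#'   ("CA", default) or "COM" for the residue centre of mass.
#' @param frame_range Optional frame indices.
#' @param leaflet Reference leaflet, "upper" (default) or "lower".
#' @return data.frame with `residue_index`, `mean_depth` (Angstrom),
#'   `sd_depth`, `n` (samples pooled over frames and copies).
#' @export
residue_depth_profile <- function(traj, chains = NULL, reference_atom = "CA",
                                  frame_range = NULL,
                                  leaflet = c("upper", "lower")) {
  leaflet <- match.arg(leaflet)
  if (is.null(chains)) chains <- traj$peptide_chains
  if (is.null(frame_range)) frame_range <- seq_along(traj$frames)
  samples <- list()
  for (fi in frame_range) {
    fr <- traj$frames[[fi]]
    plane <- phosphate_plane_z(fr, traj, leaflet)
    for (ch in chains) {
      z <- residue_ref_z(fr, traj, ch, reference_atom)
      d <- if (leaflet == "upper") plane - z else z - plane
      samples[[length(samples) + 1L]] <- d
    }
  }
  resi <- sort(unique(as.integer(unlist(lapply(samples, names)))))
  mat <- vapply(samples, function(s) s[as.character(resi)],
                numeric(length(resi)))
  mat <- matrix(mat, nrow = length(resi))
  if (anyNA(mat))
    warning("missing reference atom for some residues; flagged as NA")
  data.frame(
    residue_index = resi,
    mean_depth = rowMeans(mat, na.rm = TRUE),
    sd_depth = apply(mat, 1, stats::sd, na.rm = TRUE),
    n = rowSums(!is.na(mat)))
}

#' Windowed depth time series
#'
#' Per-residue mean depth within consecutive frame windows, mirroring
#' depth-versus-time panels.
#'
#' @inheritParams residue_depth_profile
#' @param window_frames Frames per window.
#' @return data.frame with `window`, `time_mid` (ps), `residue_index`,
#'   `mean_depth`.
#' @export
depth_time_series <- function(traj, chains = NULL, reference_atom = "CA",
                              window_frames = 10) {
  nf <- length(traj$frames)
  starts <- seq(1L, nf, by = window_frames)
  out <- list()
  for (w in seq_along(starts)) {
    idx <- starts[w]:min(starts[w] + window_frames - 1L, nf)
    prof <- residue_depth_profile(traj, chains, reference_atom,
                                  frame_range = idx)
    tm <- mean(vapply(traj$frames[idx],
                      function(f) if (is.null(f$time)) NA_real_ else f$time,
                      0))
    out[[w]] <- data.frame(window = w, time_mid = tm,
                           residue_index = prof$residue_index,
                           mean_depth = prof$mean_depth)
  }
  do.call(rbind, out)
}

#' Dominant period of a per-residue depth profile
#'
#' A surface-parallel rigid helix shows a depth oscillation with the
#' helical repeat (~3.6 residues/turn) as residues face alternately into
#' and out of the bilayer. The dominant period is found by least-squares
#' sinusoid regression over a continuous period grid (robust for short
#' profiles where discrete-transform bins are too coarse).
#'
#' @param depths Numeric per-residue depth vector (ordered by residue).
#' @param periods Candidate periods in residues.
#' @return Period (residues) maximizing the fitted sinusoid's R-squared.
#' @export
dominant_depth_period <- function(depths, periods = seq(2, 8, by = 0.01)) {
  depths <- depths[!is.na(depths)]
  x <- seq_along(depths)
  y <- depths - mean(depths)
  r2 <- vapply(periods, function(p) {
    X <- cbind(cos(2 * pi * x / p), sin(2 * pi * x / p))
    f <- stats::lm.fit(cbind(1, X), y)
    1 - sum(f$residuals^2) / sum(y^2)
  }, 0)
  periods[which.max(r2)]
}
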