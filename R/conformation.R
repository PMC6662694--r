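#' Torsion angle for quadruples of points
#'
#' Dihedral angle about the p2-p3 axis for each row of four-point
#' quadruples, IUPAC sign convention, degrees in (-180, 180]. Vectorized
#' over rows.
#'
#' @param p1,p2,p3,p4 n x 3 coordinate matrices (or length-3 vectors).
#' @return Numeric vector of n torsion angles in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 3)
  p1 <- as_m(p1); p2 <- as_m(p2); p3 <- as_m(p3); p4 <- as_m(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  y <- rowSums(cross(n1, n2) * b2) / nb2
  x <- rowSums(n1 * n2)
  ang <- atan2(y, x) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

#' Backbone phi/psi dihedral time series
#'
#' phi(i) is the torsion C(i-1)-N(i)-CA(i)-C(i); psi(i) is
#' N(i)-CA(i)-C(i)-N(i+1). phi is undefined for the first residue and psi
#' for the last; undefined or atom-missing angles are absent (not zero).
#'
#' @param traj A `trajectory_set`.
#' @param chain Chain id (one peptide copy).
#' @param frame_range Optional integer vector of frame indices.
#' @return data.frame with one row per (residue, angle) and columns
#'   `chain_id`, `residue_index`, `angle_type`, plus a list column
#'   `values` of per-frame angles in degrees.
#' @export
backbone_dihedrals <- function(traj, chain, frame_range = NULL) {
  top <- traj$topology
  if (is.null(frame_range)) frame_range <- seq_along(traj$frames)
  rows <- which(top$chain_id == chain & top$is_peptide)
  if (!length(rows)) stop("no peptide atoms in chain ", chain)
  resi <- sort(unique(top$residue_index[rows]))
  key <- paste(top$residue_index, top$atom_name)
  at <- function(r, name) {
    i <- rows[match(paste(r, name), key[rows])]
    i
  }
  quads <- list(); meta <- list()
  for (k in seq_along(resi)) {
    r <- resi[k]
    if (k > 1L) {
      q <- c(at(resi[k - 1L], "C"), at(r, "N"), at(r, "CA"), at(r, "C"))
      if (anyNA(q)) {
        warning(sprintf("chain %s residue %d: missing backbone atom, phi absent",
                        chain, r))
      } else {
        quads[[length(quads) + 1L]] <- q
        meta[[length(meta) + 1L]] <- c(r, "phi")
      }
    }
    if (k < length(resi)) {
      q <- c(at(r, "N"), at(r, "CA"), at(r, "C"), at(resi[k + 1L], "N"))
      if (anyNA(q)) {
        warning(sprintf("chain %s residue %d: missing backbone atom, psi absent",
                        chain, r))
      } else {
        quads[[length(quads) + 1L]] <- q
        meta[[length(meta) + 1L]] <- c(r, "psi")
      }
    }
  }
  if (!length(quads))
    return(data.frame(chain_id = character(), residue_index = integer(),
                      angle_type = character()))
  qm <- do.call(rbind, quads)
  nq <- nrow(qm)
  # stack the selected frames into one tall matrix: one vectorized torsion call
  natoms <- nrow(top)
  big <- do.call(rbind, lapply(traj$frames[frame_range], `[[`, "coords"))
  off <- rep((seq_along(frame_range) - 1L) * natoms, each = nq)
  i1 <- rep(qm[, 1], length(frame_range)) + off
  i2 <- rep(qm[, 2], length(frame_range)) + off
  i3 <- rep(qm[, 3], length(frame_range)) + off
  i4 <- rep(qm[, 4], length(frame_range)) + off
  ang <- torsion_angle(big[i1, , drop = FALSE], big[i2, , drop = FALSE],
                       big[i3, , drop = FALSE], big[i4, , drop = FALSE])
  angm <- matrix(ang, nrow = nq)          # quads x frames
  mm <- do.call(rbind, meta)
  out <- data.frame(chain_id = chain,
                    residue_index = as.integer(mm[, 1]),
                    angle_type = mm[, 2],
                    stringsAsFactors = FALSE)
  out$values <- lapply(seq_len(nq), function(i) angm[i, ])
  out
}

#' Circular mean of angles
#'
#' atan2 of the mean sine and mean cosine, reported in degrees in
#' (-180, 180]. A (numerically) zero resultant leaves the mean undefined:
#' NA is returned with a warning.
#'
#' @param angles Numeric vector of angles in degrees; NAs dropped.
#' @return Circular mean in degrees, or NA if the resultant vanishes.
#' @export
circular_mean <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (!length(angles)) return(NA_real_)
  r <- angles * pi / 180
  S <- mean(sin(r)); C <- mean(cos(r))
  if (sqrt(S^2 + C^2) < 1e-12) {
    warning("zero resultant: circular mean undefined")
    return(NA_real_)
  }
  a <- atan2(S, C) * 180 / pi
  if (a <= -180) a <- a + 360
  a
}

#' Circular variance of angles
#'
#' Var = 1 - R_av with R_av = R/n and
#' R^2 = (sum cos)^2 + (sum sin)^2, so Var lies in [0, 1]: 0 for perfectly
#' ordered angles, 1 for complete dispersion.
#'
#' @inheritParams circular_mean
#' @return Circular variance in [0, 1].
#' @export
circular_variance <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (!length(angles)) return(NA_real_)
  r <- angles * pi / 180
  R <- sqrt(sum(cos(r))^2 + sum(sin(r))^2)
  1 - R / length(angles)
}

#' Circular summary (mean, resultant length, variance)
#'
#' @inheritParams circular_mean
#' @return List with `mean_angle` (degrees), `resultant_mean_length`
#'   (R/n in [0,1]), `variance` (1 - R/n) and `n`.
#' @export
circular_summary <- function(angles) {
  angles <- angles[!is.na(angles)]
  v <- circular_variance(angles)
  list(mean_angle = suppressWarnings(circular_mean(angles)),
       resultant_mean_length = 1 - v,
       variance = v,
       n = length(angles))
}

#' Per-residue conformational flexibility profile
#'
#' For each residue index, pools the per-frame phi or psi samples across
#' peptide copies into one sample and reports the circular mean and
#' variance. Low variance = rigid, high variance = flexible. Per-copy
#' profiles are available with `pooling = "per_copy"`.
#'
#' @param traj A `trajectory_set`.
#' @param angle_type "psi" (default) or "phi".
#' @param chains Peptide chains to include (default all).
#' @param frame_range Optional frame index vector (e.g. to drop an
#'   equilibration window).
#' @param pooling "pooled" (concatenate samples across copies) or
#'   "per_copy".
#' @return data.frame with columns `residue_index`, `angle_type`,
#'   `mean_angle`, `variance`, `n` (and `chain_id` for per-copy output).
#' @export
flexibility_profile <- function(traj, angle_type = c("psi", "phi"),
                                chains = NULL, frame_range = NULL,
                                pooling = c("pooled", "per_copy")) {
  angle_type <- match.arg(angle_type)
  pooling <- match.arg(pooling)
  if (is.null(chains)) chains <- traj$peptide_chains
  series <- do.call(rbind, lapply(chains, function(ch)
    backbone_dihedrals(traj, ch, frame_range)))
  series <- series[series$angle_type == angle_type, , drop = FALSE]
  if (pooling == "per_copy") {
    out <- series[c("chain_id", "residue_index", "angle_type")]
    s <- lapply(series$values, circular_summary)
    out$mean_angle <- vapply(s, `[[`, 0, "mean_angle")
    out$variance <- vapply(s, `[[`, 0, "variance")
    out$n <- vapply(s, `[[`, 0L, "n")
    return(out)
  }
  resi <- sort(unique(series$residue_index))
  n_ch <- length(chains)
  rows <- lapply(resi, function(r) {
    sel <- series$residue_index == r
    if (sum(sel) < n_ch)
      warning(sprintf("residue %d absent in %d chain(s); pooled over the rest",
                      r, n_ch - sum(sel)))
    pooled <- unlist(series$values[sel], use.names = FALSE)
    s <- circular_summary(pooled)
    data.frame(residue_index = r, angle_type = angle_type,
               mean_angle = s$mean_angle, variance = s$variance, n = s$n)
  })
  do.call(rbind, rows)
}
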