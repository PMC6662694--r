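## Synthetic peptide-bilayer trajectories and channel traces with known
## ground truth. The generator emulates the statistical structure the
## analyses assume (von Mises dihedral fluctuation about helical means,
## phosphate planes with jitter, programmed insertion and aggregation,
## multi-level Markov channel gating) -- not force-field physics.

# ideal backbone geometry (Angstrom / degrees); only dihedrals vary
GEOM <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_ca_cb = 1.53,
             a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
             a_c_ca_cb = 110.6, t_n_c_ca_cb = 122.6, omega = 180)

row_cross <- function(a, b)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])

row_unit <- function(v) v / sqrt(rowSums(v^2))

# natural-extension (NeRF) placement of D given A-B-C, vectorized over rows
place_atom <- function(A, B, C, bond, theta_deg, chi_deg) {
  theta <- theta_deg * pi / 180
  chi <- chi_deg * pi / 180
  bc <- row_unit(C - B)
  n <- row_unit(row_cross(B - A, bc))
  m <- row_cross(n, bc)
  C + (-bond * cos(theta)) * bc +
    (bond * sin(theta) * cos(chi)) * m +
    (bond * sin(theta) * sin(chi)) * n
}

wrap_deg <- function(x) {
  x <- ((x + 180) %% 360) - 180
  x[x == -180] <- 180
  x
}

#' Sample from the von Mises circular distribution
#'
#' Best–Fisher rejection sampler; degrees in (-180, 180].
#'
#' @param n Sample count.
#' @param mu Mean direction, degrees.
#' @param kappa Concentration (> 0; near 0 approaches the circular
#'   uniform).
#' @return Numeric vector of angles in degrees.
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa >= 0)
  if (kappa < 1e-8) return(wrap_deg(stats::runif(n, -180, 180)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); got <- 0L
  while (got < n) {
    m <- n - got
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- (sign(stats::runif(m) - 0.5) * acos(pmin(pmax(f, -1), 1)))[ok]
    k <- length(th)
    if (k) { out[(got + 1L):(got + k)] <- th; got <- got + k }
  }
  wrap_deg(mu + out * 180 / pi)
}

#' Specification for a synthetic peptide-bilayer trajectory
#'
#' Defaults mirror the study conditions: eight peptide copies released
#' 30 Angstrom above the upper leaflet of a bilayer whose phosphate planes
#' sit at z = +/-19 Angstrom, frames every 2 ps, alpha-helical dihedral
#' means (phi -57, psi -47 degrees).
#'
#' @param sequence One-letter peptide sequence or `peptide_sequence`.
#' @param n_copies Number of peptide copies (study value 8).
#' @param n_frames Number of frames.
#' @param frame_dt Frame spacing, ps (study value 2).
#' @param phi_mean,psi_mean Per-residue dihedral means, degrees (recycled).
#' @param kappa Per-residue von Mises concentration (recycled).
#' @param plane_z Two phosphate plane z positions, Angstrom (upper, lower).
#' @param phosphates_per_leaflet Pseudo-phosphate count per leaflet
#'   (square-grid).
#' @param phosphate_jitter_sd z jitter of pseudo-phosphates, Angstrom.
#' @param box Orthorhombic box edges, Angstrom (x, y periodic; z not).
#' @param start_depth Initial depth of each copy's CA centroid relative to
#'   the upper plane (positive = below/inserted; default -30 = released
#'   30 Angstrom above, the study's starting height).
#' @param copy_spacing Lateral anchor spacing between copies, Angstrom.
#'   The study released peptides at least 20 Angstrom apart; the default
#'   (36) additionally exceeds the helix length plus the contact cutoff so
#'   that unscheduled copies can never brush into spurious contacts and
#'   the programmed cluster ground truth is exact.
#' @param insertion NULL or list(`residues`, `target_depth` (Angstrom,
#'   recycled), `onset_frame`, `end_frame`): those residues' CA depths
#'   ramp linearly from `start_depth` to target and hold.
#' @param aggregation NULL or list(`groups` (list of copy-index vectors),
#'   `contact_residue` (single residue index clamped into contact),
#'   `onset_frame`): from the onset frame, each group is driven into
#'   contact at the contact residue (helices crossed so the clamp is the
#'   closest approach).
#' @param seed Integer seed; every stream derives from it.
#' @return List of class `trajectory_spec`.
#' @export
trajectory_spec <- function(sequence = "GLFDIVKKVVGAFGSL", n_copies = 8,
                            n_frames = 1000, frame_dt = 2,
                            phi_mean = -57, psi_mean = -47, kappa = 50,
                            plane_z = c(19, -19),
                            phosphates_per_leaflet = 100,
                            phosphate_jitter_sd = 1,
                            box = c(160, 160, 160),
                            start_depth = -30, copy_spacing = 36,
                            insertion = NULL, aggregation = NULL,
                            seed = 1) {
  seq <- as_peptide(sequence)
  n_res <- length(seq$residues)
  stopifnot(n_copies >= 1, n_frames >= 1, all(kappa > 0),
            plane_z[1] != plane_z[2])
  spec <- list(sequence = seq, n_copies = n_copies, n_frames = n_frames,
               frame_dt = frame_dt,
               phi_mean = rep_len(phi_mean, n_res),
               psi_mean = rep_len(psi_mean, n_res),
               kappa = rep_len(kappa, n_res),
               plane_z = sort(plane_z, decreasing = TRUE),
               phosphates_per_leaflet = phosphates_per_leaflet,
               phosphate_jitter_sd = phosphate_jitter_sd,
               box = box, start_depth = start_depth,
               copy_spacing = copy_spacing,
               insertion = insertion, aggregation = aggregation,
               seed = as.integer(seed))
  if (!is.null(insertion)) {
    stopifnot(all(insertion$residues %in% seq_len(n_res)),
              insertion$onset_frame >= 1,
              insertion$end_frame <= n_frames,
              insertion$onset_frame < insertion$end_frame)
    spec$insertion$target_depth <- rep_len(insertion$target_depth,
                                           length(insertion$residues))
  }
  if (!is.null(aggregation)) {
    stopifnot(all(unlist(aggregation$groups) %in% seq_len(n_copies)),
              !anyDuplicated(unlist(aggregation$groups)),
              length(aggregation$contact_residue) == 1,
              aggregation$contact_residue %in% seq_len(n_res),
              aggregation$onset_frame >= 1,
              aggregation$onset_frame <= n_frames)
  }
  class(spec) <- "trajectory_spec"
  spec
}

# backbone for one copy across all frames from sampled dihedrals.
# phi, psi: n_frames x n_res matrices. Returns array [n_frames, n_atoms, 3]
# and the atom metadata (residue_index, atom_name).
build_chain_frames <- function(phi, psi, residues) {
  nf <- nrow(phi); nr <- ncol(phi)
  has_cb <- residues != "G"
  atoms_per_res <- 3L + has_cb
  meta_res <- rep(seq_len(nr), atoms_per_res)
  meta_name <- unlist(lapply(seq_len(nr), function(i)
    c("N", "CA", "C", if (has_cb[i]) "CB")))
  n_atoms <- length(meta_res)
  X <- array(NA_real_, c(nf, n_atoms, 3))
  col_of <- function(r, name) which(meta_res == r & meta_name == name)
  one <- function(v) matrix(v, nf, 3, byrow = TRUE)
  N <- one(c(0, 0, 0))
  CA <- one(c(GEOM$b_n_ca, 0, 0))
  a0 <- (180 - GEOM$a_n_ca_c) * pi / 180
  C <- CA + one(GEOM$b_ca_c * c(cos(a0), sin(a0), 0))
  X[, col_of(1L, "N"), ] <- N
  X[, col_of(1L, "CA"), ] <- CA
  X[, col_of(1L, "C"), ] <- C
  if (has_cb[1])
    X[, col_of(1L, "CB"), ] <- place_atom(N, C, CA, GEOM$b_ca_cb,
                                          GEOM$a_c_ca_cb, GEOM$t_n_c_ca_cb)
  for (i in seq_len(nr - 1L)) {
    N2 <- place_atom(N, CA, C, GEOM$b_c_n, GEOM$a_ca_c_n, psi[, i])
    CA2 <- place_atom(CA, C, N2, GEOM$b_n_ca, GEOM$a_c_n_ca, GEOM$omega)
    C2 <- place_atom(C, N2, CA2, GEOM$b_ca_c, GEOM$a_n_ca_c, phi[, i + 1L])
    X[, col_of(i + 1L, "N"), ] <- N2
    X[, col_of(i + 1L, "CA"), ] <- CA2
    X[, col_of(i + 1L, "C"), ] <- C2
    if (has_cb[i + 1L])
      X[, col_of(i + 1L, "CB"), ] <-
        place_atom(N2, C2, CA2, GEOM$b_ca_cb, GEOM$a_c_ca_cb,
                   GEOM$t_n_c_ca_cb)
    N <- N2; CA <- CA2; C <- C2
  }
  list(coords = X, residue_index = meta_res, atom_name = meta_name)
}

rot_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
              byrow = TRUE)
  diag(3) * c_ + s * K + (1 - c_) * (u %o% u)
}

rot_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); d <- sum(a * b)
  if (s < 1e-12) {
    if (d > 0) return(diag(3))
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rot_about(c(a[2] * p[3] - a[3] * p[2],
                       a[3] * p[1] - a[1] * p[3],
                       a[1] * p[2] - a[2] * p[1]), pi))
  }
  rot_about(v / s, atan2(s, d))
}

#' Generate a synthetic peptide-bilayer trajectory
#'
#' Backbone atoms (N, CA, C, plus CB pseudo-side-chains) are rebuilt every
#' frame from per-residue (phi, psi) angles sampled from von Mises
#' distributions, so the programmed dihedral means and concentrations are
#' the exact ground truth for the circular-statistics analyses. Copies are
#' rigid-body placed parallel to the bilayer on a lateral grid; pseudo-
#' phosphates jitter about the two leaflet planes; insertion and
#' aggregation schedules are imposed as exact per-frame constraints and
#' recorded as ground truth. Deterministic given the spec seed, with an
#' independent stream per copy (adding copies does not perturb existing
#' ones).
#'
#' @param spec A [trajectory_spec()].
#' @return List: `trajectory` (a `trajectory_set`) and `truth` with
#'   `phi`/`psi` (arrays frames x residues x copies; NA where undefined),
#'   `depth` (programmed per-frame depth of scheduled residues),
#'   `clusters` (programmed copy partition per frame) and the `spec`.
#' @export
generate_helix_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  seqres <- spec$sequence$residues
  nr <- length(seqres); nc <- spec$n_copies; nf <- spec$n_frames
  # lateral grid of copy anchor positions
  per_row <- max(1L, floor(spec$box[1] / spec$copy_spacing) - 1L)
  ix <- (seq_len(nc) - 1L) %% per_row
  iy <- (seq_len(nc) - 1L) %/% per_row
  anchors <- cbind(spec$copy_spacing * (ix + 0.75),
                   spec$copy_spacing * (iy + 0.75),
                   spec$plane_z[1] - spec$start_depth)
  if (max(anchors[, 1]) > spec$box[1] || max(anchors[, 2]) > spec$box[2])
    stop("infeasible placement: copies do not fit the box at the requested spacing")
  # orientation: axis parallel to membrane; per-copy random streams so
  # adding copies never perturbs existing ones
  azimuth <- roll <- numeric(nc)
  for (cp in seq_len(nc)) {
    set.seed(spec$seed + cp * 7919L)
    azimuth[cp] <- stats::runif(1, 0, 2 * pi)
    roll[cp] <- stats::runif(1, 0, 2 * pi)
  }
  agg <- spec$aggregation
  in_group <- integer(0)
  face <- integer(nc)   # +1: contact CA rolled to face up; -1: down
  if (!is.null(agg)) {
    for (g in agg$groups) {
      # crossed orientations within a group, and contact residues rolled
      # to face their partner, so the programmed clamp is the closest
      # approach between partners
      face[g[1]] <- 1L
      for (j in seq_along(g)[-1]) {
        azimuth[g[j]] <- azimuth[g[1]] + (j - 1) * pi / 2
        face[g[j]] <- -1L
      }
      in_group <- c(in_group, g)
    }
  }
  phi_t <- array(NA_real_, c(nf, nr, nc))
  psi_t <- array(NA_real_, c(nf, nr, nc))
  coords_by_copy <- vector("list", nc)
  meta <- NULL
  for (cp in seq_len(nc)) {
    set.seed(spec$seed + cp * 7919L + 3571L)
    phi <- matrix(vapply(seq_len(nr), function(i)
      rvonmises(nf, spec$phi_mean[i], spec$kappa[i]), numeric(nf)), nf, nr)
    psi <- matrix(vapply(seq_len(nr), function(i)
      rvonmises(nf, spec$psi_mean[i], spec$kappa[i]), numeric(nf)), nf, nr)
    ch <- build_chain_frames(phi, psi, seqres)
    if (is.null(meta)) meta <- ch[c("residue_index", "atom_name")]
    phi_t[, 2:nr, cp] <- phi[, 2:nr]       # phi undefined at residue 1
    psi_t[, 1:(nr - 1), cp] <- psi[, 1:(nr - 1)]  # psi undefined at last
    ca_cols <- which(meta$atom_name == "CA")
    target_axis <- c(cos(azimuth[cp]), sin(azimuth[cp]), 0)
    for (f in seq_len(nf)) {
      xyz <- ch$coords[f, , ]
      axis <- xyz[ca_cols[nr], ] - xyz[ca_cols[1], ]
      R <- rot_between(axis, target_axis)
      R <- rot_about(target_axis, roll[cp]) %*% R
      xyz <- xyz %*% t(R)
      cen <- colMeans(xyz[ca_cols, , drop = FALSE])
      if (face[cp] != 0L) {
        # roll about the helix axis so the contact CA's radial vector
        # points straight at the partner (+z for the lowest member)
        v <- xyz[ca_cols[agg$contact_residue], ] - cen
        rad <- v - sum(v * target_axis) * target_axis
        des <- c(0, 0, face[cp])
        crx <- c(rad[2] * des[3] - rad[3] * des[2],
                 rad[3] * des[1] - rad[1] * des[3],
                 rad[1] * des[2] - rad[2] * des[1])
        ang <- atan2(sum(crx * target_axis), sum(rad * des))
        xyz <- sweep(sweep(xyz, 2, cen) %*% t(rot_about(target_axis, ang)),
                     2, cen, "+")
      }
      xyz <- sweep(xyz, 2, cen - anchors[cp, ])
      ch$coords[f, , ] <- xyz
    }
    coords_by_copy[[cp]] <- ch$coords
  }
  n_at_pep <- length(meta$residue_index)
  ca_cols <- which(meta$atom_name == "CA")
  # aggregation: clamp each group member's contact-residue CA near the
  # first member's, stacked in z
  truth_clusters <- rep(list(as.list(seq_len(nc))), nf)
  if (!is.null(agg)) {
    cr_col <- ca_cols[agg$contact_residue]
    for (f in agg$onset_frame:nf) {
      for (g in agg$groups) {
        ref <- coords_by_copy[[g[1]]][f, cr_col, ]
        for (j in seq_along(g)[-1]) {
          cp <- g[j]
          tgt <- ref + c(0, 0, 4.5 * (j - 1))
          shift <- tgt - coords_by_copy[[cp]][f, cr_col, ]
          coords_by_copy[[cp]][f, , ] <-
            sweep(coords_by_copy[[cp]][f, , ], 2, -shift)
        }
      }
      singles <- setdiff(seq_len(nc), in_group)
      truth_clusters[[f]] <- c(agg$groups, as.list(singles))
    }
  }
  # insertion schedule: exact per-frame CA depth for scheduled residues
  ins <- spec$insertion
  truth_depth <- NULL
  if (!is.null(ins)) {
    ramp <- pmin(pmax((seq_len(nf) - ins$onset_frame) /
                        (ins$end_frame - ins$onset_frame), 0), 1)
    truth_depth <- outer(ramp, ins$target_depth - spec$start_depth) +
      spec$start_depth                      # frames x scheduled residues
    colnames(truth_depth) <- as.character(ins$residues)
    for (cp in seq_len(nc)) {
      for (k in seq_along(ins$residues)) {
        r <- ins$residues[k]
        rows_r <- which(meta$residue_index == r)
        z_target <- spec$plane_z[1] - truth_depth[, k]
        dz <- z_target - coords_by_copy[[cp]][, ca_cols[r], 3]
        coords_by_copy[[cp]][, rows_r, 3] <-
          coords_by_copy[[cp]][, rows_r, 3] + dz
      }
    }
  }
  # pseudo-phosphate lattice per leaflet, jittered in z each frame
  n_side <- ceiling(sqrt(spec$phosphates_per_leaflet))
  gx <- (rep(seq_len(n_side), n_side) - 0.5) * spec$box[1] / n_side
  gy <- (rep(seq_len(n_side), each = n_side) - 0.5) * spec$box[2] / n_side
  keep <- seq_len(spec$phosphates_per_leaflet)
  gx <- gx[keep]; gy <- gy[keep]
  np <- length(gx)
  set.seed(spec$seed + 104729L)
  jit_u <- matrix(stats::rnorm(nf * np, 0, spec$phosphate_jitter_sd), nf)
  jit_l <- matrix(stats::rnorm(nf * np, 0, spec$phosphate_jitter_sd), nf)
  # topology: peptide chains A.. then phosphate chains X (upper), Y (lower)
  aa3 <- AA3[seqres]
  top <- do.call(rbind, lapply(seq_len(nc), function(cp)
    data.frame(atom_name = meta$atom_name,
               residue_index = meta$residue_index,
               residue_name = aa3[meta$residue_index],
               chain_id = LETTERS[cp],
               stringsAsFactors = FALSE)))
  top <- rbind(top,
               data.frame(atom_name = "P", residue_index = seq_len(np),
                          residue_name = "POPG", chain_id = "X",
                          stringsAsFactors = FALSE),
               data.frame(atom_name = "P", residue_index = seq_len(np),
                          residue_name = "POPG", chain_id = "Y",
                          stringsAsFactors = FALSE))
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    pep <- do.call(rbind, lapply(coords_by_copy, function(a)
      matrix(a[f, , ], n_at_pep, 3)))
    up <- cbind(gx, gy, spec$plane_z[1] + jit_u[f, ])
    lo <- cbind(gx, gy, spec$plane_z[2] + jit_l[f, ])
    frames[[f]] <- list(time = (f - 1) * spec$frame_dt, box = spec$box,
                        coords = rbind(pep, up, lo))
  }
  traj <- trajectory_set(top, frames)
  list(trajectory = traj,
       truth = list(phi = phi_t, psi = psi_t, depth = truth_depth,
                    clusters = truth_clusters, azimuth = azimuth,
                    spec = spec))
}

#' Specification for a synthetic single-channel current trace
#'
#' Defaults mirror the study's recording conditions (50 kHz sampling,
#' +50 mV holding potential) with three open levels of study-like
#' amplitudes.
#'
#' @param amplitudes Open-level amplitudes in pA, strictly increasing.
#' @param opening_rates Closed -> open_k rates, per second (recycled).
#' @param closing_rates Open_k -> closed rates, per second (recycled).
#' @param noise_sd Gaussian noise SD, pA.
#' @param sampling_rate Hz (study value 50000).
#' @param duration Seconds.
#' @param holding_potential mV (study value +50).
#' @param seed Integer seed.
#' @return List of class `trace_spec` including the full transition-rate
#'   matrix `Q` (states: closed, open_1..open_K).
#' @export
trace_spec <- function(amplitudes = c(0.8, 2.5, 5.4),
                       opening_rates = 2, closing_rates = 20,
                       noise_sd = 0.15, sampling_rate = 50000,
                       duration = 5, holding_potential = 50, seed = 1) {
  K <- length(amplitudes)
  stopifnot(K >= 1, !is.unsorted(amplitudes, strictly = TRUE),
            all(amplitudes > 0), noise_sd >= 0, duration > 0)
  op <- rep_len(opening_rates, K)
  cl <- rep_len(closing_rates, K)
  Q <- matrix(0, K + 1, K + 1)
  Q[1, -1] <- op
  Q[cbind(2:(K + 1), 1)] <- cl
  diag(Q) <- -rowSums(Q)
  structure(list(amplitudes = amplitudes, Q = Q, noise_sd = noise_sd,
                 sampling_rate = sampling_rate, duration = duration,
                 holding_potential = holding_potential,
                 seed = as.integer(seed)),
            class = "trace_spec")
}

#' Stationary distribution of a transition-rate matrix
#'
#' @param Q Square rate matrix (rows sum to zero).
#' @return Probability vector over states.
#' @export
stationary_distribution <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  as.numeric(qr.solve(A, b))
}

#' Generate a synthetic single-channel current trace
#'
#' Samples the continuous-time Markov chain exactly (exponential holding
#' times), discretizes the state staircase at the sampling rate, and adds
#' Gaussian noise. The state path is returned as ground truth.
#'
#' @param spec A [trace_spec()].
#' @return List: `trace` (a `current_trace`), `truth` with `path`
#'   (data.frame state/start/end in seconds; state 0 = closed),
#'   `state_per_sample`, `stationary` (chain stationary distribution) and
#'   the `spec`. A trace whose chain never opens is flagged with
#'   `truth$quiet = TRUE`.
#' @export
generate_channel_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  set.seed(spec$seed)
  K <- length(spec$amplitudes)
  amps <- c(0, spec$amplitudes)
  t_now <- 0; s_now <- 1L
  st <- integer(0); t0 <- numeric(0)
  while (t_now < spec$duration) {
    st <- c(st, s_now); t0 <- c(t0, t_now)
    rate <- -spec$Q[s_now, s_now]
    if (rate <= 0) { t_now <- spec$duration; break }
    t_now <- t_now + stats::rexp(1, rate)
    p <- spec$Q[s_now, ]; p[s_now] <- 0
    s_now <- sample.int(K + 1L, 1L, prob = p)
  }
  ends <- c(t0[-1], spec$duration)
  n <- round(spec$duration * spec$sampling_rate)
  t_samp <- (seq_len(n) - 1) / spec$sampling_rate
  idx <- findInterval(t_samp, t0)
  state <- st[idx]
  x <- amps[state] + stats::rnorm(n, 0, spec$noise_sd)
  path <- data.frame(state = st - 1L, start = t0, end = ends)
  quiet <- all(st == 1L)
  if (quiet) warning("chain never opened: quiet trace")
  list(trace = current_trace(x, spec$sampling_rate,
                             spec$holding_potential, "synthetic"),
       truth = list(path = path, state_per_sample = state - 1L,
                    stationary = stationary_distribution(spec$Q),
                    quiet = quiet, spec = spec))
}
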