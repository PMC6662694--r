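# independent torsion oracle: plane-normal acos formulation with explicit
# sign, deliberately distinct from the package's atan2 path
brute_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  n1 <- n1 / sqrt(sum(n1^2)); n2 <- n2 / sqrt(sum(n2^2))
  ang <- acos(pmin(pmax(sum(n1 * n2), -1), 1)) * 180 / pi
  if (sum(cr(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# brute-force connected components by depth-first search on an explicit
# all-pairs adjacency, independent of igraph
brute_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cc <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cc <- cc + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cc
      stack <- c(stack, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# toy trajectory: k single-CA-per-residue peptide copies at given centre
# positions (list of length-3 vectors), each a straight 3-residue rod along
# x with 3.8 A spacing, plus a 2x2 phosphate plane per leaflet
toy_traj <- function(centres, plane_z = c(19, -19), box = NULL,
                     rod_spacing = 3.8) {
  k <- length(centres)
  top <- do.call(rbind, c(
    lapply(seq_len(k), function(i)
      data.frame(atom_name = "CA", residue_index = 1:3,
                 residue_name = "ALA", chain_id = LETTERS[i],
                 stringsAsFactors = FALSE)),
    list(data.frame(atom_name = "P", residue_index = 1:4,
                    residue_name = "POPG", chain_id = "X",
                    stringsAsFactors = FALSE),
         data.frame(atom_name = "P", residue_index = 1:4,
                    residue_name = "POPG", chain_id = "Y",
                    stringsAsFactors = FALSE))))
  coords <- do.call(rbind, c(
    lapply(centres, function(cen)
      cbind(cen[1] + rod_spacing * (-1:1), cen[2], cen[3])),
    list(cbind(c(10, 50, 10, 50), c(10, 10, 50, 50), plane_z[1]),
         cbind(c(10, 50, 10, 50), c(10, 10, 50, 50), plane_z[2]))))
  trajectory_set(top, list(list(time = 0, box = box, coords = coords)))
}

# quick synthetic trajectory small enough for unit tests
small_traj <- function(..., n_copies = 2, n_frames = 10, seed = 42)
  generate_helix_trajectory(trajectory_spec(n_copies = n_copies,
                                            n_frames = n_frames,
                                            seed = seed, ...))

# closed-form von Mises circular variance, 1 - I1(kappa)/I0(kappa)
vm_variance <- function(kappa)
  1 - besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
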