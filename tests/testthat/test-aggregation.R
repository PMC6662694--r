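test_that("hand-placed toy distances match direct computation", {
  tr <- toy_traj(list(c(10, 10, 30), c(10, 17, 30)), box = NULL)
  d <- ca_distance_matrix(1, tr)
  # copies are parallel rods 7 A apart in y: aligned residues at 7 A
  expect_equal(d["A:1", "B:1"], 7)
  expect_equal(d["A:1", "B:2"], sqrt(7^2 + 3.8^2))
  expect_equal(d["A:1", "B:3"], sqrt(7^2 + 7.6^2))
  expect_true(isSymmetric(unclass(d)))
})

test_that("intra-copy blocks are masked", {
  tr <- toy_traj(list(c(10, 10, 30), c(40, 40, 30)))
  d <- ca_distance_matrix(1, tr)
  expect_true(all(is.na(d[1:3, 1:3])))
  expect_true(all(!is.na(d[1:3, 4:6])))
})

test_that("widely separated copies respect the separation bound", {
  tr <- toy_traj(list(c(0, 0, 30), c(100, 0, 30)), box = NULL)
  d <- ca_distance_matrix(1, tr)
  # rod length is 7.6 A; no inter-copy pair can be closer than 100 - 7.6
  expect_gte(min(d, na.rm = TRUE), 100 - 7.6)
})

test_that("the minimum-image convention wraps lateral distances", {
  tr <- toy_traj(list(c(5, 30, 30), c(115, 30, 30)), box = c(120, 120, 160))
  d <- ca_distance_matrix(1, tr)
  # 110 A apart unwrapped, 10 A through the boundary
  expect_equal(d["A:2", "B:2"], 10)
})

test_that("chain-topology contacts give the expected components", {
  tr <- toy_traj(list(c(10, 10, 30), c(10, 16, 30), c(10, 22, 30),
                      c(10, 60, 30)))
  part <- oligomer_partition(1, tr, contact_cutoff = 7)
  sets <- lapply(part$clusters, sort)
  expect_true(list(c("A", "B", "C")) %in% sets || any(
    vapply(sets, identical, TRUE, y = c("A", "B", "C"))))
  expect_true(any(vapply(sets, identical, TRUE, y = "D")))
  expect_equal(sort(part$sizes, decreasing = TRUE), c(3L, 1L))
})

test_that("no contacts means all monomers; full contact one cluster", {
  far <- toy_traj(as.list(lapply(0:3, function(i) c(10 + 40 * i, 10, 30))),
                  box = NULL)
  p1 <- oligomer_partition(1, far)
  expect_true(all(p1$sizes == 1L))
  near <- toy_traj(lapply(0:3, function(i) c(10, 10 + 5 * i, 30)))
  p2 <- oligomer_partition(1, near)
  expect_equal(p2$sizes, 4L)
})

test_that("partitions equal a brute-force DFS oracle on random configurations", {
  set.seed(17)
  for (rep in 1:100) {
    k <- sample(2:8, 1)
    centres <- lapply(seq_len(k), function(i) c(stats::runif(2, 0, 80), 30))
    cutoff <- stats::runif(1, 4, 15)
    tr <- toy_traj(centres, box = NULL)
    part <- oligomer_partition(1, tr, contact_cutoff = cutoff)
    # oracle: explicit adjacency + depth-first search
    d <- ca_distance_matrix(1, tr)
    ch <- attr(d, "chain")
    adj <- matrix(FALSE, k, k)
    for (a in 1:k) for (b in 1:k) if (a != b)
      adj[a, b] <- any(d[ch == LETTERS[a], ch == LETTERS[b]] <= cutoff,
                       na.rm = TRUE)
    comp <- brute_components(adj)
    oracle <- unname(lapply(split(LETTERS[1:k], comp), sort))
    got <- lapply(part$clusters, sort)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(oracle, paste, "", collapse = ","))
  }
})

test_that("increasing the cutoff never increases the cluster count", {
  set.seed(23)
  centres <- lapply(1:6, function(i) c(stats::runif(2, 0, 60), 30))
  tr <- toy_traj(centres, box = NULL)
  n_clusters <- vapply(c(3, 5, 8, 12, 20, 40), function(cut)
    length(oligomer_partition(1, tr, contact_cutoff = cut)$clusters), 0L)
  expect_true(all(diff(n_clusters) <= 0))
})

test_that("heatmap and partition are invariant under rigid rotation", {
  centres <- list(c(10, 10, 30), c(10, 16, 30), c(40, 40, 30))
  tr <- toy_traj(centres, box = NULL)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  tr2 <- tr
  tr2$frames[[1]]$coords <- tr$frames[[1]]$coords %*% t(R)
  expect_equal(unclass(ca_distance_matrix(1, tr2)),
               unclass(ca_distance_matrix(1, tr)), tolerance = 1e-9)
  expect_equal(oligomer_partition(1, tr2)$sizes,
               oligomer_partition(1, tr)$sizes)
})

test_that("a static configuration's heatmap equals its single frame", {
  tr0 <- toy_traj(list(c(10, 10, 30), c(10, 17, 30)))
  tr <- trajectory_set(tr0$topology,
                       rep(tr0$frames, 5))
  expect_equal(unclass(time_average_heatmap(tr)),
               unclass(ca_distance_matrix(1, tr)))
})

test_that("a programmed persistent tetramer is detected post-assembly", {
  sp <- trajectory_spec(n_copies = 8, n_frames = 80, seed = 7,
                        aggregation = list(groups = list(1:4),
                                           contact_residue = 6,
                                           onset_frame = 21))
  g <- generate_helix_trajectory(sp)
  pops <- oligomer_populations(g$trajectory, persistence = 10)
  post <- pops$per_frame[pops$per_frame$frame >= 21, ]
  expect_gte(mean(post$tetramer >= 1), 0.95)
  expect_true(all(post$ge5 == 0))
})

test_that("1-frame brushes are suppressed by the persistence filter", {
  far <- lapply(0:3, function(i) c(10 + 40 * i, 10, 30))
  tr0 <- toy_traj(far, box = NULL)
  frames <- rep(tr0$frames, 20)
  # one transient frame with copies A,B adjacent
  near <- toy_traj(list(c(10, 10, 30), c(10, 16, 30), c(90, 10, 30),
                        c(130, 10, 30)), box = NULL)
  frames[[10]] <- near$frames[[1]]
  tr <- trajectory_set(tr0$topology, frames)
  pops <- oligomer_populations(tr, persistence = 10)
  expect_equal(sum(pops$per_frame$dimer), 1)    # raw counts see the brush
  expect_equal(sum(pops$stable$dimer), 0)       # stable counts do not
})

test_that("programmed contact residues rank first among mediating pairs", {
  sp <- trajectory_spec(n_copies = 4, n_frames = 40, seed = 19,
                        aggregation = list(groups = list(1:2),
                                           contact_residue = 8,
                                           onset_frame = 1))
  g <- generate_helix_trajectory(sp)
  hm <- time_average_heatmap(g$trajectory)
  med <- mediating_residues(hm)
  expect_true("A-B" %in% names(med))
  expect_equal(unlist(med[["A-B"]][1, c("residue_i", "residue_j")],
                      use.names = FALSE), c(8, 8))
})

test_that("mediating-residue ranking is symmetric under copy swap", {
  tr <- toy_traj(list(c(10, 10, 30), c(10, 16, 30)))
  hm <- time_average_heatmap(tr)
  med <- mediating_residues(hm, contact_cutoff = 7, top_k = 9)
  r <- med[["A-B"]]
  swapped <- data.frame(residue_i = r$residue_j, residue_j = r$residue_i,
                        distance = r$distance)
  expect_equal(hm["A:1", "B:2"], hm["A:2", "B:1"])  # parallel rods
  expect_setequal(paste(r$residue_i, r$residue_j),
                  paste(swapped$residue_i, swapped$residue_j))
})

test_that("distant copies yield an empty mediating ranking", {
  tr <- toy_traj(list(c(0, 0, 30), c(100, 0, 30)), box = NULL)
  expect_length(mediating_residues(time_average_heatmap(tr)), 0)
})
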