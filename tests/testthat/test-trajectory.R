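test_that("PDB multi-model round trip preserves coordinates to 3 decimals", {
  g <- small_traj(n_frames = 3)
  f <- tempfile(fileext = ".pdb")
  write_pdb_multimodel(g$trajectory, f)
  tr <- read_trajectory(frames_source = f, format_tag = "pdb_multimodel")
  expect_equal(length(tr$frames), 3L)
  expect_equal(nrow(tr$topology), nrow(g$trajectory$topology))
  for (i in 1:3)
    expect_lt(max(abs(tr$frames[[i]]$coords - g$trajectory$frames[[i]]$coords)),
              5e-4 + 1e-9)
  # writing the re-read trajectory again is idempotent
  f2 <- tempfile(fileext = ".pdb")
  write_pdb_multimodel(tr, f2)
  tr2 <- read_trajectory(frames_source = f2, format_tag = "pdb_multimodel")
  expect_equal(tr2$frames[[2]]$coords, tr$frames[[2]]$coords)
})

test_that("delimited frame format round trips", {
  g <- small_traj(n_frames = 2)
  ft <- tempfile(); ff <- tempfile()
  write_delimited_frames(g$trajectory, ft, ff)
  tr <- read_trajectory(ft, ff, "delimited_frames")
  expect_lt(max(abs(tr$frames[[2]]$coords - g$trajectory$frames[[2]]$coords)),
            5e-4 + 1e-9)
  expect_equal(tr$frames[[2]]$time, g$trajectory$frames[[2]]$time)
})

test_that("GRO coordinates in nm are converted to Angstrom", {
  gro <- c("toy t= 4.0", "    3",
           "    1ALA      N    1   0.100   0.200   0.300",
           "    1ALA     CA    2   0.246   0.200   0.300",
           "    1ALA      C    3   0.300   0.350   0.300",
           "   6.00000   6.00000   6.00000")
  f <- tempfile(fileext = ".gro")
  writeLines(gro, f)
  tr <- suppressWarnings(read_trajectory(frames_source = f,
                                         format_tag = "gro_series"))
  expect_equal(tr$frames[[1]]$coords[1, ], c(1, 2, 3))
  expect_equal(tr$frames[[1]]$coords[2, 1], 2.46)
  expect_equal(tr$frames[[1]]$box, c(60, 60, 60))
  expect_equal(tr$frames[[1]]$time, 4.0)
})

test_that("atom-count mismatch between frames is a hard error naming the frame", {
  g <- small_traj(n_frames = 2)
  frames <- g$trajectory$frames
  frames[[2]]$coords <- frames[[2]]$coords[-1, ]
  expect_error(trajectory_set(g$trajectory$topology, frames), "frame 2")
})

test_that("leaflet assignment splits a symmetric bilayer evenly", {
  tr <- toy_traj(list(c(30, 30, 45)), plane_z = c(19, -19))
  lab <- assign_leaflets(1, tr)
  expect_equal(sum(lab == "upper"), 4L)
  expect_equal(sum(lab == "lower"), 4L)
  expect_equal(attr(lab, "midplane"), 0)
})

test_that("leaflet midplane is the phosphate mean z", {
  top <- data.frame(atom_name = c("CA", "P", "P"),
                    residue_index = c(1, 1, 2),
                    residue_name = c("ALA", "POPG", "POPG"),
                    chain_id = c("A", "X", "X"))
  fr <- list(time = 0, box = NULL,
             coords = rbind(c(0, 0, 70), c(0, 0, 10), c(0, 0, 50)))
  tr <- trajectory_set(top, list(fr))
  lab <- assign_leaflets(1, tr)
  expect_equal(attr(lab, "midplane"), 30)
  expect_equal(as.character(lab), c("lower", "upper"))
})

test_that("degenerate one-sided phosphates fall back to single-leaflet mode", {
  top <- data.frame(atom_name = c("CA", "P", "P"),
                    residue_index = c(1, 1, 2),
                    residue_name = c("ALA", "POPG", "POPG"),
                    chain_id = c("A", "X", "X"))
  fr <- list(time = 0, box = NULL,
             coords = rbind(c(0, 0, 70), c(0, 0, 0), c(0, 0, 0)))
  tr <- trajectory_set(top, list(fr))
  expect_warning(lab <- assign_leaflets(1, tr), "single-leaflet")
  expect_true(all(lab == "lower"))
})

test_that("rigid translation leaves relative quantities unchanged", {
  g <- small_traj(n_frames = 4)
  tr <- g$trajectory
  shifted <- tr
  for (i in seq_along(shifted$frames))
    shifted$frames[[i]]$coords <-
      sweep(shifted$frames[[i]]$coords, 2, c(-3, 11, 27), "+")
  expect_equal(as.character(assign_leaflets(1, shifted)),
               as.character(assign_leaflets(1, tr)))
  expect_equal(flexibility_profile(shifted)$mean_angle,
               flexibility_profile(tr)$mean_angle)
  expect_equal(residue_depth_profile(shifted)$mean_depth,
               residue_depth_profile(tr)$mean_depth, tolerance = 1e-9)
  expect_equal(unclass(ca_distance_matrix(1, shifted)),
               unclass(ca_distance_matrix(1, tr)), tolerance = 1e-9)
})

test_that("shuffled atom ordering gives the same dihedrals", {
  g <- small_traj(n_frames = 3)
  tr <- g$trajectory
  set.seed(1)
  perm <- sample(nrow(tr$topology))
  tr2 <- trajectory_set(tr$topology[perm, ],
                        lapply(tr$frames, function(f) {
                          f$coords <- f$coords[perm, ]; f
                        }))
  expect_equal(flexibility_profile(tr2), flexibility_profile(tr))
})

test_that("unknown format tags are rejected", {
  expect_error(read_trajectory(frames_source = "x", format_tag = "xtc"))
})
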