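# Surface rdf, contact counting and the Buffer Adsorption Index.

test_that("surface_rdf bins nearest-surface distances and conserves counts", {
  ref <- c(5, 5, 5)
  coords <- rbind(ref, c(5.35, 5, 5))
  traj <- make_traj(list(coords), box = 12)
  prof <- surface_rdf(traj, 1L, 2L, bin_width = 0.1, r_max = 1, skip = 0)
  expect_equal(prof$density[4], 10)            # 1 count / 0.1 nm in [0.3,0.4)
  expect_equal(sum(prof$density != 0), 1L)
  expect_equal(sum(prof$density) * 0.1, 1)     # conservation

  # two reference atoms: binned by the nearer one
  coords2 <- rbind(c(5, 5, 5), c(6, 5, 5), c(5.75, 5, 5))
  traj2 <- make_traj(list(coords2), box = 12)
  prof2 <- surface_rdf(traj2, 1:2, 3L, bin_width = 0.1, r_max = 1, skip = 0)
  expect_equal(which(prof2$density != 0), 3L)  # 0.25 nm from atom 2
  expect_error(surface_rdf(traj, integer(0), 2L, skip = 0), "empty")
})

test_that("cumulative_count integrates the profile and matches direct counting", {
  set.seed(21)
  nfr <- 8
  frames <- lapply(seq_len(nfr), function(i)
    rbind(c(6, 6, 6), matrix(runif(30, 3, 9), 10)))
  traj <- make_traj(frames, box = 12)
  prof <- surface_rdf(traj, 1L, 2:11, bin_width = 0.05, r_max = 6, skip = 0)
  expect_equal(cumulative_count(prof, 0), 0)
  # direct per-frame counting oracle at several radii
  for (r in c(0.5, 1.5, 3)) {
    direct <- mean(vapply(frames, function(xyz) {
      d <- vapply(2:11, function(a) bf_min_image(xyz[a, ], xyz[1, ], 12),
                  numeric(1))
      sum(d < r)
    }, numeric(1)))
    expect_equal(cumulative_count(prof, r), direct, tolerance = 1e-9)
  }
  expect_equal(cumulative_count(prof, 6), 10)  # all targets within range
  expect_error(cumulative_count(prof, 7), "outside")
})

test_that("count_contacts is an exact atomic-pair count", {
  sys <- make_system(rbind(c(5, 5, 5), c(5.39, 5, 5)), box = 12)
  expect_identical(unname(count_contacts(sys$coordinates, sys, 1L, 2L,
                                         box_length = 12)), 1L)
  sys2 <- make_system(rbind(c(5, 5, 5), c(5.41, 5, 5)), box = 12)
  expect_identical(unname(count_contacts(sys2$coordinates, sys2, 1L, 2L,
                                         box_length = 12)), 0L)
})

test_that("count_contacts matches the exhaustive double loop on random configs", {
  set.seed(33)
  for (rep in 1:20) {
    coords <- matrix(runif(35 * 3, 0, 4), 35)
    sys <- make_system(coords, box = 4,
                       residue_index = c(rep(1:5, each = 4), 21:35))
    got <- count_contacts(coords, sys, 1:20, 21:35, cutoff = 0.4,
                          box_length = 4)
    ref <- bf_contacts(coords, sys, 1:20, 21:35, 0.4, 4)
    expect_identical(got, ref)
  }
})

test_that("average_contacts averages within then across trajectories", {
  m1 <- matrix(3, 2, 4, dimnames = list(c("1", "2"), NULL))
  expect_equal(average_contacts(list(m1)), c("1" = 3, "2" = 3))
  m2 <- matrix(c(2, 2, 2, 2), 2, 2, dimnames = list(c("1", "2"), NULL))
  m3 <- matrix(4, 2, 6, dimnames = list(c("1", "2"), NULL))
  expect_equal(average_contacts(list(m2, m3)), c("1" = 3, "2" = 3))
  # ragged frame counts, hand-computed
  ma <- matrix(c(1, 0, 3, 0), 1, 4, dimnames = list("7", NULL))
  mb <- matrix(c(2, 4), 1, 2, dimnames = list("7", NULL))
  expect_equal(average_contacts(list(ma, mb)), c("7" = (1 + 3) / 2))
  expect_error(average_contacts(list()), "at least one")
})

test_that("compute_bai applies -ln(N/Nmax) with a shared origin", {
  nav <- data.frame(residue_index = 1:3, residue_name = c("LYS", "ARG", "GLU"),
                    state = "Phos2m", n_avg = c(12, 6, 3))
  bai <- compute_bai(nav)
  expect_equal(bai$table$bai, c(0, log(2), log(4)), tolerance = 1e-9)
  expect_equal(bai$n_max, 12)
  # scale invariance
  nav2 <- nav; nav2$n_avg <- nav2$n_avg * 7.3
  expect_equal(compute_bai(nav2)$table$bai, bai$table$bai, tolerance = 1e-12)
  # zero contacts -> flagged Inf; all-zero -> error
  nav3 <- rbind(nav, data.frame(residue_index = 4, residue_name = "SER",
                                state = "Phos2m", n_avg = 0))
  bai3 <- compute_bai(nav3)
  expect_true(is.infinite(bai3$table$bai[4]) && bai3$zero_contact_flags[4])
  expect_error(compute_bai(data.frame(residue_index = 1, residue_name = "A",
                                      state = "s", n_avg = 0)), "all N_avg")
  # N_max spans all charge states of the species
  two_state <- data.frame(residue_index = c(1, 1), residue_name = "LYS",
                          state = c("m1", "m2"), n_avg = c(5, 10))
  expect_equal(compute_bai(two_state)$table$bai, c(log(2), 0))
})

test_that("species_average_bai gates on SASA and averages per species", {
  tab <- data.frame(residue_index = 1:6,
                    residue_name = c("LYS", "LYS", "ARG", "ARG", "GLU", "GLU"),
                    state = "s", n_avg = c(10, 10, 5, 4, 2, 1))
  bai <- compute_bai(tab)
  area <- data.frame(residue_index = 1:6, residue_name = tab$residue_name,
                     area_nm2 = c(1, 1, 1, 0, 1, 1))
  sasa <- structure(list(per_residue_area = area, probe_radius = 0.14,
                         n_points = 960, total_area = 5),
                    class = "sasa_result")
  avg <- species_average_bai(bai, sasa)
  expect_equal(avg$mean_bai[avg$residue_name == "LYS"], 0)
  # buried ARG residue 4 excluded: mean over residue 3 only
  expect_equal(avg$mean_bai[avg$residue_name == "ARG"], log(2))
  expect_equal(avg$n_residues[avg$residue_name == "ARG"], 1)
  expect_equal(avg$mean_bai[avg$residue_name == "GLU"],
               mean(c(log(5), log(10))))
})

test_that("bai_distribution is a normalised histogram matching hand binning", {
  one <- compute_bai(data.frame(residue_index = 1, residue_name = "A",
                                state = "s", n_avg = 5))
  d1 <- bai_distribution(one, bin_width = 0.5)
  expect_equal(sum(d1$p * 0.5), 1)
  expect_equal(d1$p[1], 1 / 0.5)
  set.seed(4)
  nav <- data.frame(residue_index = 1:100, residue_name = "X", state = "s",
                    n_avg = runif(100, 0.1, 20))
  bai <- compute_bai(nav)
  d <- bai_distribution(bai, bin_width = 0.25)
  expect_equal(sum(d$p * 0.25), 1, tolerance = 1e-12)
  hand <- tabulate(findInterval(bai$table$bai, d$bin_edges),
                   nbins = length(d$bin_edges) - 1) / (100 * 0.25)
  expect_equal(d$p, hand)
})

test_that("surface_rdf default skip drops the first 5% of frames", {
  frames <- c(lapply(1:5, function(i) rbind(c(6, 6, 6), c(11, 6, 6))),
              lapply(1:95, function(i) rbind(c(6, 6, 6), c(6.35, 6, 6))))
  traj <- make_traj(frames, box = 12)
  prof <- surface_rdf(traj, 1L, 2L, bin_width = 0.1, r_max = 1)
  expect_equal(prof$n_frames, 95)
  expect_equal(sum(prof$density) * 0.1, 1)  # the far frames were all skipped
})
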