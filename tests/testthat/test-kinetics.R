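# Contact series, survival probabilities and ionic bridges.

test_that("build_contact_series flags persistent and absent contacts", {
  prot <- c(5, 5, 5)
  near <- lapply(1:4, function(i) rbind(prot, c(5.3, 5, 5), c(5.5, 5, 5)))
  traj <- make_traj(near, box = 12)
  sys <- make_system(near[[1]], box = 12)
  ions <- list(close = 2L, far = 3L)
  cs <- build_contact_series(traj, sys, ions, 1L)
  expect_true(all(cs$occupancy["close" == cs$channels$ion |
                               cs$channels$ion == "close", ]))
  expect_true(all(cs$occupancy[1, ]))
  expect_false(any(cs$occupancy[2, ]))
  expect_error(build_contact_series(traj, sys, list(), 1L), "empty")
})

test_that("contact series matches frame-by-frame brute force", {
  set.seed(17)
  frames <- lapply(1:6, function(i) matrix(runif(27, 0, 3), 9))
  traj <- make_traj(frames, box = 3)
  sys <- make_system(frames[[1]], box = 3)
  ions <- list(a = 4:5, b = 6:7, c = 8:9)
  cs <- build_contact_series(traj, sys, ions, 1:3, cutoff = 0.5)
  for (f in 1:6) for (m in 1:3) {
    ref <- any(vapply(ions[[m]], function(i) any(vapply(1:3, function(p)
      bf_min_image(frames[[f]][i, ], frames[[f]][p, ], 3) <= 0.5,
      logical(1))), logical(1)))
    expect_identical(cs$occupancy[m, f], ref)
  }
})

test_that("survival_probability normalises, is monotone and handles gaps", {
  occ <- matrix(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
                  TRUE, TRUE, TRUE, TRUE, TRUE, TRUE), 2, byrow = TRUE)
  cs <- contact_series(occ, 10)
  s <- survival_probability(cs, max_lag = 30)
  expect_equal(s$S[1], 1)
  expect_true(all(diff(s$S) <= 1e-12))
  # permanently occupied channel alone survives everything
  cs2 <- contact_series(occ[2, , drop = FALSE], 10)
  expect_true(all(survival_probability(cs2, 50)$S == 1))
  # a 1-frame gap is forgiven with gap_tolerance = 1 and S never decreases
  s0 <- survival_probability(cs, 30, gap_tolerance = 0)
  s1 <- survival_probability(cs, 30, gap_tolerance = 1)
  expect_true(all(s1$S >= s0$S - 1e-12))
  expect_true(all(s1$S == 1))
  expect_error(survival_probability(contact_series(matrix(FALSE, 1, 5), 10), 20),
               "no occupied")
})

test_that("telegraph survival matches the exponential law", {
  ts <- simulate_telegraph_contacts(k_on = 2, k_off = 2, dt = 0.01,
                                    n_channels = 3000, n_frames = 120,
                                    seed = 1)
  sc <- survival_probability(ts, max_lag = 500)  # 0.5 ns in ps
  lag_ns <- sc$lag_ps / 1000
  expect_lt(max(abs(sc$S - exp(-2 * lag_ns))), 0.02)
})

test_that("detect_bridges applies the dual-cutoff criterion symmetrically", {
  coords <- rbind(c(5, 5, 5), c(5.6, 5, 5),       # protein tips A, B
                  c(5.3, 5, 5),                   # bridging ion
                  c(5.3, 5.6, 5))                 # near A only
  ions <- list(bridge = 3L, loose = 4L)
  got <- detect_bridges(coords, ions, 1L, 2L, cutoff = 0.4, box_length = 12)
  expect_identical(got, "bridge")
  expect_identical(detect_bridges(coords, ions, 2L, 1L, cutoff = 0.4,
                                  box_length = 12), got)
  expect_error(detect_bridges(coords, ions, 1L, 1L, 0.4, 12), "disjoint")
})

test_that("detect_bridges matches brute force on random two-protein frames", {
  set.seed(77)
  for (rep in 1:20) {
    coords <- rbind(matrix(runif(12, 2, 2.8), 4),   # wall A
                    matrix(runif(12, 3.2, 4), 4),   # wall B
                    matrix(runif(30, 1.5, 4.5), 10))
    ions <- stats::setNames(as.list(9:18), paste0("i", 1:10))
    got <- sort(detect_bridges(coords, ions, 1:4, 5:8, cutoff = 0.5,
                               box_length = 6))
    ref <- sort(bf_bridges(coords, ions, 1:4, 5:8, 0.5, 6))
    expect_identical(got, ref)
  }
})

test_that("bridge_lifetimes extracts maximal intervals", {
  prot <- rbind(c(5, 5, 5), c(5.6, 5, 5))
  mk <- function(bridging) {
    ion <- if (bridging) c(5.3, 5, 5) else c(8, 8, 8)
    rbind(prot, ion)
  }
  frames <- lapply(c(rep(TRUE, 10), rep(FALSE, 5)), mk)
  traj <- make_traj(frames, box = 12, spacing = 100)  # 0.1 ns spacing
  bl <- bridge_lifetimes(traj, list(ion1 = 3L), 1L, 2L)
  expect_equal(nrow(bl$records), 1L)
  expect_equal(bl$records$duration_ps, 900)  # frames 1-10 span 0.9 ns
  expect_true(bl$records$censored)           # starts at frame 1
  # never-bridging ion -> no record
  far <- make_traj(lapply(1:5, function(i) mk(FALSE)), box = 12)
  bl2 <- bridge_lifetimes(far, list(ion1 = 3L), 1L, 2L)
  expect_equal(nrow(bl2$records), 0L)
  expect_null(bl2$survival)
})

test_that("bridge_anchor_residues picks nearest residues with low-index ties", {
  atoms <- make_atoms(5, residue_index = c(1, 2, 3, 4, 5),
                      residue_name = c("ARG", "GLY", "LYS", "GLY", "CIT"))
  coords <- rbind(c(5, 5, 5), c(4, 5, 5),       # A: ARG nearest
                  c(6.0, 5, 5), c(7, 5, 5),     # B: LYS nearest
                  c(5.5, 5, 5))                 # ion
  sys <- molecular_system(atoms, 12, coordinates = coords)
  anch <- bridge_anchor_residues(coords, sys, 5L, 1:2, 3:4, box_length = 12)
  expect_equal(anch$residue_a$residue_name, "ARG")
  expect_equal(anch$residue_b$residue_name, "LYS")
  # symmetric tie resolves to the lower residue index
  coords2 <- coords; coords2[2, ] <- c(4.5, 5.5, 5)
  coords2[1, ] <- c(4.5, 4.5, 5); coords2[5, ] <- c(4.5, 5, 5)
  sys2 <- molecular_system(atoms, 12, coordinates = coords2)
  anch2 <- bridge_anchor_residues(coords2, sys2, 5L, 1:2, 3:4, box_length = 12)
  expect_equal(anch2$residue_a$residue_index, 1)
  # brute-force nearest-residue oracle on a random frame
  set.seed(12)
  rc <- matrix(runif(15, 0, 3), 5)
  sysr <- molecular_system(atoms, 3, coordinates = rc)
  anchr <- bridge_anchor_residues(rc, sysr, 5L, 1:2, 3:4, box_length = 3)
  dists <- vapply(1:4, function(i) bf_min_image(rc[i, ], rc[5, ], 3), numeric(1))
  expect_equal(anchr$residue_a$residue_index, which.min(dists[1:2]))
  expect_equal(anchr$residue_b$residue_index, 2 + which.min(dists[3:4]))
})

test_that("interval survival is unbiased under right-censoring", {
  # deterministic intervals: starts spread through the run, various lengths
  occ <- matrix(FALSE, 3, 30)
  occ[1, 5:8] <- TRUE     # duration 3 frames
  occ[2, 10:25] <- TRUE   # duration 15
  occ[3, 28:30] <- TRUE   # runs into the end: censored but observable to 20 ps
  records <- bridge_records_from_occupancy(occ, spacing = 10)
  expect_equal(records$duration_ps, c(30, 150, 20))
  iv <- interval_survival(records, c(20, 40), n_frames = 30, frame_spacing = 10)
  expect_equal(iv$S[iv$lag_ps == 20], 1)     # all three at risk reach 20 ps
  expect_equal(iv$n[iv$lag_ps == 20], 3)
  expect_equal(iv$n[iv$lag_ps == 40], 2)     # ion 3's window is too short
  expect_equal(iv$S[iv$lag_ps == 40], 0.5)   # only the long interval survives
})
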