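# Generators: determinism, stated-world geometry and kinetic ground truth.

test_that("generate_toy_protein honours charge, shell geometry and determinism", {
  spec <- synthetic_spec("equilibrium", seed = 1, net_charge = 7,
                         n_frames = 10)
  p1 <- generate_toy_protein(spec)
  expect_equal(sum(p1$atoms$formal_charge), 7)
  centre <- rep(spec$box_length / 2, 3)
  radii <- sqrt(rowSums(sweep(p1$coordinates, 2, centre)^2))
  expect_true(all(abs(radii - spec$shell_radius) < 1e-9))
  p2 <- generate_toy_protein(spec)
  expect_identical(p1$atoms, p2$atoms)
  expect_identical(p1$coordinates, p2$coordinates)
  tiny <- synthetic_spec("equilibrium", seed = 1, n_beads = 24,
                         shell_radius = 0.2, n_frames = 10)
  expect_error(generate_toy_protein(tiny), "overlap")
})

test_that("zero-interaction equilibrium sampling is uniform (ideal gas)", {
  spec <- synthetic_spec("equilibrium", seed = 6, box_length = 6,
                         n_beads = 4, shell_radius = 0.5,
                         ion_species = list(list(name = "GAS", count = 25,
                                                 charge = 0)),
                         n_frames = 300,
                         mc = list(burn_in = 50, thin = 2, step = 1.5))
  fx <- quiet_equilibrium(spec)
  ids <- fx$groups$GAS$atom_ids
  # occupancy of the sub-box x < 3 nm: Binomial(n, 1/2) within 3 sigma
  xs <- unlist(lapply(fx$trajectory$coords, function(m) m[ids, 1]))
  n <- length(xs)
  expect_lt(abs(mean(xs < 3) - 0.5), 3 * sqrt(0.25 / n) * 3)  # 3x for thinning
  # and of the octant: p = 1/8
  oct <- mean(vapply(fx$trajectory$coords, function(m)
    mean(m[ids, 1] < 3 & m[ids, 2] < 3 & m[ids, 3] < 3), numeric(1)))
  expect_lt(abs(oct - 1 / 8), 3 * sqrt(1 / 8 * 7 / 8 / n) * 3)
})

test_that("Metropolis kernel satisfies detailed balance on a 3-state toy", {
  # states with energies u_i, uniform proposals between all pairs
  u <- c(0, 1.3, 2.1)
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) if (i != j)
    P[i, j] <- 0.5 * metropolis_acceptance(u[j] - u[i])
  diag(P) <- 1 - rowSums(P)
  pi_ <- exp(-u) / sum(exp(-u))
  flux <- outer(pi_, rep(1, 3)) * P
  expect_equal(flux, t(flux), tolerance = 1e-12)
})

test_that("equilibrium well-depth contrast follows the Boltzmann ratio", {
  spec <- synthetic_spec("equilibrium", seed = 2, box_length = 6,
                         net_charge = 0,
                         well_depths = c(positive = 1, negative = 0,
                                         hydrophobic = 0),
                         ion_species = list(list(name = "BUF", count = 30,
                                                 charge = 0)),
                         n_frames = 600,
                         mc = list(burn_in = 100, thin = 4, step = 1.0))
  fx <- quiet_equilibrium(spec)
  counts <- contact_count_matrix(fx$trajectory, fx$system, fx$groups$protein,
                                 fx$groups$BUF)
  nav <- average_contacts(list(counts))
  cls <- fx$system$residue_class[seq_len(spec$n_beads)]
  ratio <- sum(nav[cls == "positive"]) / sum(nav[cls == "hydrophobic"])
  expect_lt(abs(log(ratio) - 1), 0.35)
})

test_that("telegraph channels obey their stationary law and limits", {
  frozen <- simulate_telegraph_contacts(k_on = 5, k_off = 0, dt = 0.01,
                                        n_channels = 200, n_frames = 50,
                                        seed = 3)
  # once on, never off
  on_at <- apply(frozen$occupancy, 1, function(r) match(TRUE, r))
  for (ch in which(!is.na(on_at)))
    expect_true(all(frozen$occupancy[ch, on_at[ch]:50]))
  sym <- simulate_telegraph_contacts(2, 2, 0.01, 2000, 200, seed = 4)
  occ <- mean(sym$occupancy)
  expect_lt(abs(occ - 0.5), 3 * sqrt(0.25 / 2000) * 2)
  expect_error(simulate_telegraph_contacts(20, 20, 0.01, 10, 10, seed = 1),
               "discretisation")
})

test_that("two-protein generator produces the designed bridge kinetics", {
  spec <- synthetic_spec("two_protein", seed = 5, k_on = 1, k_off = 0,
                         ion_species = list(list(name = "BRI", count = 1,
                                                 charge = -2)),
                         n_frames = 100, separation = 0.6)
  fx <- simulate_two_protein_system(spec)
  bl <- bridge_lifetimes(fx$trajectory, fx$groups$ions, fx$groups$protein_a,
                         fx$groups$protein_b)
  # k_off = 0 and stationary start -> one record spanning the run
  expect_equal(nrow(bl$records), 1L)
  expect_equal(bl$records$start_frame, 1L)
  expect_equal(bl$records$end_frame, 100L)
  expect_error(simulate_two_protein_system(
    synthetic_spec("two_protein", seed = 1, separation = 1.2,
                   ion_species = list(list(name = "B", count = 1,
                                           charge = -1)))),
    "too large")
})

test_that("write_fixture round-trips and is byte-deterministic", {
  spec <- synthetic_spec("equilibrium", seed = 9, box_length = 6, net_charge = 2,
                         ion_species = list(list(name = "CL", count = 2,
                                                 charge = -1, element = "Cl")),
                         n_frames = 3, mc = list(burn_in = 10, thin = 1,
                                                 step = 1.0))
  fx <- quiet_equilibrium(spec)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_fixture(fx$system, fx$trajectory, d1, fx$groups)
  p2 <- write_fixture(fx$system, fx$trajectory, d2, fx$groups)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  sys <- read_structure(p1[["structure"]], box_length = 6)
  expect_identical(sys$atoms$formal_charge, fx$system$atoms$formal_charge)
  traj <- read_trajectory(p1[["trajectory"]], sys)
  expect_equal(n_frames(traj), 3L)
  expect_lt(max(abs(traj$coords[[2]] - fx$trajectory$coords[[2]])), 1e-6)
  groups <- read_selections(p1[["selections"]])
  expect_identical(groups$CL$atom_ids, fx$groups$CL$atom_ids)
})

test_that("generators are reproducible from (spec, seed)", {
  spec <- synthetic_spec("two_protein", seed = 13, k_on = 0.5, k_off = 0.5,
                         ion_species = list(list(name = "BRI", count = 3,
                                                 charge = -1)),
                         n_frames = 40)
  a <- simulate_two_protein_system(spec)
  b <- simulate_two_protein_system(spec)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  t1 <- simulate_telegraph_contacts(1, 1, 0.01, 50, 50, seed = 21)
  t2 <- simulate_telegraph_contacts(1, 1, 0.01, 50, 50, seed = 21)
  expect_identical(t1$occupancy, t2$occupancy)
})
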