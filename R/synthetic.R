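# Synthetic-data generators with known ground truth.
#
# Three modes stand in for the all-atom simulations the analysis targets:
#   equilibrium  - statistically independent-ish Metropolis samples of point
#                  ions around a fixed bead-protein, with residue-class
#                  square-well adsorption (depths in kT) plus a screened-
#                  Coulomb pair term; exercises rdf/BAI/Z_eff recovery.
#   telegraph    - independent two-state Markov contact channels with known
#                  on/off rates; exercises survival kinetics.
#   two_protein  - two fixed bead-proteins with ions hopping between a
#                  bridging site and bulk at known rates, or a dimer distance
#                  sampled from a designed double-well free energy.
# All generators are reproducible from (spec, seed).

#' Specification of a synthetic system
#'
#' @param mode `"equilibrium"`, `"telegraph"` or `"two_protein"`.
#' @param seed integer RNG seed; mandatory for all stochastic modes.
#' @param box_length cubic box edge in nm (default 12, a typical
#'   single-protein production box).
#' @param n_beads number of protein beads (one bead = one residue).
#' @param shell_radius radius of the spherical bead shell (nm).
#' @param net_charge target net formal charge of the toy protein (e).
#' @param class_fractions named fractions of `positive` / `negative` /
#'   `hydrophobic` beads (before the net-charge adjustment).
#' @param well_depths named adsorption well depths in kT per residue class;
#'   a square well of this depth acts within 0.4 nm of each bead of the class.
#' @param ion_species list of species entries
#'   `list(name=, count=, charge=, element=)` (element defaults to "P").
#' @param n_frames number of frames to generate.
#' @param frame_spacing frame spacing in ps (default 10).
#' @param k_on,k_off telegraph rates in 1/ns (telegraph and two-protein
#'   bridge kinetics).
#' @param separation tip-to-tip protein separation in nm (two-protein mode).
#' @param double_well optional designed dimer free-energy landscape:
#'   `list(delta_F=, well1=c(lo,hi), well2=c(lo,hi))` in kT / nm.
#' @param screening_length screened-Coulomb decay length in nm (default 0.8,
#'   the magnitude typical of ~150 mM 1:1 electrolyte).
#' @param mc Metropolis tuning: `list(burn_in=, thin=, step=)` in sweeps /
#'   sweeps / nm.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(mode = c("equilibrium", "telegraph", "two_protein"),
                           seed,
                           box_length = 12, n_beads = 24, shell_radius = 1.4,
                           net_charge = 0,
                           class_fractions = c(positive = 1 / 3,
                                               negative = 1 / 3,
                                               hydrophobic = 1 / 3),
                           well_depths = c(positive = 0, negative = 0,
                                           hydrophobic = 0),
                           ion_species = list(),
                           n_frames = 100, frame_spacing = 10,
                           k_on = 1, k_off = 1,
                           separation = 0.6, double_well = NULL,
                           screening_length = 0.8,
                           mc = list(burn_in = 200, thin = 5, step = 1.0)) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory for synthetic generation")
  if (any(vapply(ion_species, function(s) s$count < 0, logical(1))))
    stop("ion counts must be nonnegative")
  if (!all(is.finite(well_depths))) stop("well depths must be finite")
  structure(list(mode = mode, seed = as.integer(seed),
                 box_length = box_length, n_beads = n_beads,
                 shell_radius = shell_radius, net_charge = net_charge,
                 class_fractions = class_fractions, well_depths = well_depths,
                 ion_species = ion_species, n_frames = n_frames,
                 frame_spacing = frame_spacing, k_on = k_on, k_off = k_off,
                 separation = separation, double_well = double_well,
                 screening_length = screening_length, mc = mc),
            class = "synthetic_spec")
}

.CLASS_RESNAME <- c(positive = "ARG", negative = "ASP", hydrophobic = "LEU")
.CLASS_CHARGE <- c(positive = 1, negative = -1, hydrophobic = 0)

# Residue classes honouring both the target net charge and (approximately)
# the requested class fractions.
assign_bead_classes <- function(n_beads, fractions, net_charge) {
  n_pos <- round(n_beads * fractions[["positive"]])
  n_neg <- n_pos - net_charge
  if (n_neg < 0) { n_pos <- n_pos - n_neg; n_neg <- 0 }
  if (n_pos + n_neg > n_beads || n_pos < max(0, net_charge))
    stop("net charge ", net_charge, " infeasible with ", n_beads, " beads")
  n_hyd <- n_beads - n_pos - n_neg
  # interleave deterministically so classes are spread over the shell
  cls <- rep(NA_character_, n_beads)
  pool <- c(rep("positive", n_pos), rep("negative", n_neg),
            rep("hydrophobic", n_hyd))
  ord <- order(rep(seq_len(n_beads), length.out = n_beads))  # identity
  # round-robin: place classes at stride-spread positions
  idx <- order((seq_len(n_beads) - 1L) %% 3L, seq_len(n_beads))
  cls[idx] <- pool
  cls
}

#' Deterministic toy bead-protein
#'
#' Beads sit on a golden-spiral spherical shell of radius `shell_radius`
#' centred in the box; each bead is one residue, labelled by class
#' (positive ARG +1e, negative ASP -1e, hydrophobic LEU 0e), with classes
#' chosen so the net formal charge equals the spec's target. Construction is
#' deterministic: two calls with the same spec give identical systems.
#'
#' @param spec a [synthetic_spec()].
#' @return a [molecular_system()] with reference coordinates.
#' @export
generate_toy_protein <- function(spec) {
  nb <- spec$n_beads
  if (nb < 1L) stop("need at least one bead")
  centre <- rep(spec$box_length / 2, 3)
  pos <- sweep(sphere_points(nb) * spec$shell_radius, 2L, centre, "+")
  cls <- assign_bead_classes(nb, spec$class_fractions, spec$net_charge)
  radius <- 0.17
  dm <- mic_distmat(pos, pos, NULL)
  diag(dm) <- Inf
  if (min(dm) < 2 * radius)
    stop("beads overlap: shell too small for ", nb, " beads")
  atoms <- data.frame(
    atom_id = seq_len(nb), atom_name = "CA", element = "C",
    residue_index = seq_len(nb), residue_name = .CLASS_RESNAME[cls],
    chain_id = "A", formal_charge = .CLASS_CHARGE[cls], radius = radius,
    stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  sys <- molecular_system(atoms, spec$box_length, coordinates = pos)
  sys$residue_class <- cls
  sys
}

# Append single-atom ion records to a bead-protein system.
append_ions <- function(system, ion_species) {
  atoms <- system$atoms
  coords <- system$coordinates
  groups <- list()
  next_id <- nrow(atoms)
  for (sp in ion_species) {
    if (sp$count == 0) next
    elem <- if (!is.null(sp$element)) sp$element else "P"
    ids <- next_id + seq_len(sp$count)
    atoms <- rbind(atoms, data.frame(
      atom_id = ids, atom_name = toupper(substr(sp$name, 1, 3)),
      element = elem, residue_index = ids,
      residue_name = toupper(substr(sp$name, 1, 3)), chain_id = "B",
      formal_charge = sp$charge, radius = element_radius(elem),
      stringsAsFactors = FALSE))
    coords <- rbind(coords, matrix(0, sp$count, 3))
    role <- if (sp$charge > 0) "cation" else if (sp$charge < 0) "anion"
            else "buffer_state"
    groups[[sp$name]] <- selection_group(sp$name, ids, role)
    next_id <- next_id + sp$count
  }
  sys <- molecular_system(atoms, system$box_length, coordinates = coords)
  sys$residue_class <- c(system$residue_class,
                         rep(NA_character_, nrow(atoms) - length(system$residue_class)))
  list(system = sys, groups = groups)
}

#' Metropolis acceptance probability
#'
#' `min(1, exp(-delta_u))` for an energy change in kT; exposed so the
#' detailed-balance property of the sampler can be tested on discretised toy
#' state spaces.
#'
#' @param delta_u energy change in kT.
#' @return acceptance probability in `[0, 1]`.
#' @export
metropolis_acceptance <- function(delta_u) pmin(1, exp(-delta_u))

# Energy (kT) of ion i at position p, given bead table and other-ion
# positions/charges. Square wells within 0.4 nm of class beads plus
# screened Coulomb lB*qi*qj*exp(-r/lambda)/r (soft-cored below 0.05 nm).
ion_energy <- function(p, qi, bead_pos, bead_charge, bead_depth,
                       other_pos, other_q, box, lambda) {
  dx <- bead_pos[, 1] - p[1]; dx <- dx - box * round(dx / box)
  dy <- bead_pos[, 2] - p[2]; dy <- dy - box * round(dy / box)
  dz <- bead_pos[, 3] - p[3]; dz <- dz - box * round(dz / box)
  d <- sqrt(dx * dx + dy * dy + dz * dz)
  u <- -sum(bead_depth[d < 0.4])
  if (qi != 0) {
    dd <- pmax(d, 0.05)
    u <- u + BJERRUM_NM * qi * sum(bead_charge * exp(-dd / lambda) / dd)
    if (!is.null(other_pos) && nrow(other_pos)) {
      ox <- other_pos[, 1] - p[1]; ox <- ox - box * round(ox / box)
      oy <- other_pos[, 2] - p[2]; oy <- oy - box * round(oy / box)
      oz <- other_pos[, 3] - p[3]; oz <- oz - box * round(oz / box)
      od <- pmax(sqrt(ox * ox + oy * oy + oz * oz), 0.05)
      u <- u + BJERRUM_NM * qi * sum(other_q * exp(-od / lambda) / od)
    }
  }
  u
}

#' Equilibrium ion configurations around a toy protein
#'
#' Single-ion-move Metropolis sampling of point ions in the field of the
#' fixed bead-protein: a square well of the bead class's depth within 0.4 nm
#' of each bead, plus a screened-Coulomb pair interaction (Bjerrum length
#' 0.7 nm, decay length `spec$screening_length`). One long chain is run;
#' after `mc$burn_in` sweeps a frame is recorded every `mc$thin` sweeps
#' (thinned samples of one chain, near-independent for the default step size).
#' The acceptance rate is reported and a warning is raised when it falls
#' outside (0.1, 0.9).
#'
#' @param spec a [synthetic_spec()] with `mode = "equilibrium"`.
#' @return object of class `equilibrium_fixture`: list with `system`
#'   (beads + ions), `trajectory`, `groups` (named [selection_group()]s incl.
#'   `protein`) and `acceptance_rate`.
#' @export
sample_equilibrium_frames <- function(spec) {
  if (spec$mode != "equilibrium") stop("spec mode must be 'equilibrium'")
  set.seed(spec$seed)
  protein <- generate_toy_protein(spec)
  nb <- spec$n_beads
  aug <- append_ions(protein, spec$ion_species)
  sys <- aug$system
  n_ions <- n_atoms(sys) - nb
  if (n_ions == 0L) stop("equilibrium mode needs at least one ion")
  box <- spec$box_length
  bead_pos <- protein$coordinates
  bead_charge <- protein$atoms$formal_charge
  bead_depth <- unname(spec$well_depths[protein$residue_class])
  ion_q <- sys$atoms$formal_charge[(nb + 1L):(nb + n_ions)]
  lambda <- spec$screening_length

  ion_pos <- matrix(stats::runif(3 * n_ions, 0, box), n_ions, 3)
  step <- spec$mc$step
  burn <- spec$mc$burn_in
  thin <- spec$mc$thin
  total_sweeps <- burn + spec$n_frames * thin
  acc <- 0L; tries <- 0L
  frames <- vector("list", spec$n_frames)
  fidx <- 0L
  charged <- any(ion_q != 0)
  for (sweep_i in seq_len(total_sweeps)) {
    for (i in seq_len(n_ions)) {
      old <- ion_pos[i, ]
      new <- (old + stats::runif(3, -step, step)) %% box
      others <- if (charged) ion_pos[-i, , drop = FALSE] else NULL
      oq <- if (charged) ion_q[-i] else NULL
      du <- ion_energy(new, ion_q[i], bead_pos, bead_charge, bead_depth,
                       others, oq, box, lambda) -
            ion_energy(old, ion_q[i], bead_pos, bead_charge, bead_depth,
                       others, oq, box, lambda)
      tries <- tries + 1L
      if (du <= 0 || stats::runif(1) < exp(-du)) {
        ion_pos[i, ] <- new
        acc <- acc + 1L
      }
    }
    if (sweep_i > burn && (sweep_i - burn) %% thin == 0L) {
      fidx <- fidx + 1L
      frames[[fidx]] <- rbind(bead_pos, ion_pos)
    }
  }
  rate <- acc / tries
  message(sprintf("equilibrium sampler: acceptance rate %.2f over %d moves",
                  rate, tries))
  if (rate <= 0.1 || rate >= 0.9)
    warning("Metropolis acceptance rate ", sprintf("%.2f", rate),
            " outside (0.1, 0.9); tune mc$step (larger step lowers the rate)")
  traj <- trajectory(times = (seq_len(spec$n_frames) - 1L) * spec$frame_spacing,
                     coords = frames, box_length = box)
  groups <- c(list(protein = selection_group("protein", seq_len(nb),
                                             "protein_A")),
              aug$groups)
  structure(list(system = sys, trajectory = traj, groups = groups,
                 acceptance_rate = rate, spec = spec),
            class = "equilibrium_fixture")
}

#' Telegraph (two-state Markov) contact channels
#'
#' Independent channels switching between bound and unbound with rates
#' `k_on`/`k_off`; per-step persistence probabilities are `exp(-k dt)`, so
#' strict survival of the bound state is exactly exponential,
#' `S(t) = exp(-k_off t)`, and the stationary occupancy is
#' `k_on / (k_on + k_off)`. Initial states are drawn from the stationary
#' distribution.
#'
#' @param k_on,k_off rates in 1/ns; nonnegative, with `dt * max(k) <= 0.1`.
#' @param dt frame spacing in ns.
#' @param n_channels,n_frames series dimensions.
#' @param seed RNG seed.
#' @return a [contact_series()] (`frame_spacing` in ps).
#' @export
simulate_telegraph_contacts <- function(k_on, k_off, dt, n_channels, n_frames,
                                        seed) {
  if (k_on < 0 || k_off < 0) stop("rates must be nonnegative")
  if (dt * max(k_on, k_off) > 0.1)
    stop("dt * max(k) = ", dt * max(k_on, k_off),
         " > 0.1: discretisation too coarse")
  set.seed(seed)
  p_stay_on <- exp(-k_off * dt)
  p_stay_off <- exp(-k_on * dt)
  p0 <- if (k_on + k_off > 0) k_on / (k_on + k_off) else 0.5
  occ <- matrix(FALSE, n_channels, n_frames)
  occ[, 1] <- stats::runif(n_channels) < p0
  for (f in 2:n_frames) {
    u <- stats::runif(n_channels)
    occ[, f] <- ifelse(occ[, f - 1L], u < p_stay_on, u >= p_stay_off)
  }
  contact_series(occ, frame_spacing_ps = dt * 1000)
}

# Four-bead "arrow" protein: tip plus three back beads 0.5 nm behind it.
arrow_beads <- function(tip, direction) {
  back <- tip - direction * 0.5
  rbind(tip,
        back + c(0, 0.4, 0),
        back + c(0, -0.35, 0.2),
        back + c(0, 0, -0.4))
}

#' Two-protein system with bridging ions or a designed dimer landscape
#'
#' Two four-bead proteins face each other tip-to-tip along x, centred in the
#' box. Two sub-modes:
#' * bridge kinetics (default): the tips stay at `spec$separation` and each
#'   ion alternates between a bridging site at the midpoint (within 0.4 nm of
#'   both tips; requires `separation < 0.8` nm) and a bulk site, with
#'   telegraph rates `k_on`/`k_off`; bridge survival is `exp(-k_off t)`.
#' * `double_well`: the tip-to-tip distance is drawn each frame from a
#'   piecewise-flat two-well density with designed free-energy offset
#'   `delta_F` (kT) between the wells, so the Boltzmann-inverted minimum
#'   distance distribution recovers `delta_F`.
#'
#' @param spec a [synthetic_spec()] with `mode = "two_protein"`.
#' @return object of class `two_protein_fixture`: `system`, `trajectory`,
#'   `groups` (`protein_a`, `protein_b`, `ions` = named list of atom-id
#'   vectors), `bridge_states` (ions x frames logical, bridge sub-mode) and
#'   `designed_distance` (double-well sub-mode).
#' @export
simulate_two_protein_system <- function(spec) {
  if (spec$mode != "two_protein") stop("spec mode must be 'two_protein'")
  set.seed(spec$seed)
  box <- spec$box_length
  centre <- rep(box / 2, 3)
  n_ions <- sum(vapply(spec$ion_species, `[[`, numeric(1), "count"))
  use_dw <- !is.null(spec$double_well)
  if (!use_dw && n_ions > 0 && spec$separation >= 0.8)
    stop("separation ", spec$separation,
         " nm too large for any bridge geometry (need < 0.8 nm)")

  nf <- spec$n_frames
  dirx <- c(1, 0, 0)
  d_series <- if (use_dw) {
    dw <- spec$double_well
    w1 <- dw$well1; w2 <- dw$well2
    p2 <- (diff(w2) * exp(-dw$delta_F)) /
          (diff(w1) + diff(w2) * exp(-dw$delta_F))
    in2 <- stats::runif(nf) < p2
    ifelse(in2, stats::runif(nf, w2[1], w2[2]),
                stats::runif(nf, w1[1], w1[2]))
  } else rep(spec$separation, nf)

  # static atom table; protein A tip left of centre, B tip right
  protoA <- arrow_beads(centre - dirx * d_series[1] / 2, dirx)
  protoB <- arrow_beads(centre + dirx * d_series[1] / 2, -dirx)
  mk_atoms <- function(ids, chain, resoff) data.frame(
    atom_id = ids, atom_name = "CA", element = "C",
    residue_index = resoff + seq_along(ids),
    residue_name = c("ARG", "LYS", "LEU", "ASP"), chain_id = chain,
    formal_charge = c(1, 1, 0, -1), radius = 0.17, stringsAsFactors = FALSE)
  atoms <- rbind(mk_atoms(1:4, "A", 0), mk_atoms(5:8, "B", 4))
  coords0 <- rbind(protoA, protoB)
  base <- molecular_system(atoms, box, coordinates = coords0)
  base$residue_class <- rep(NA_character_, 8)
  aug <- append_ions(base, spec$ion_species)
  sys <- aug$system
  ion_ids <- (9L):(8L + n_ions)

  # telegraph bridge states
  states <- NULL
  if (n_ions > 0) {
    dt_ns <- spec$frame_spacing / 1000
    ts <- simulate_telegraph_contacts(spec$k_on, spec$k_off, dt_ns,
                                      n_ions, nf, seed = spec$seed + 1L)
    states <- ts$occupancy
    if (use_dw) states[] <- FALSE  # ions stay in bulk while proteins roam
  }

  bulk_site <- t(vapply(seq_len(max(n_ions, 1L)), function(i)
    centre + c(3, 3, 3) * (0.8 + 0.1 * (i %% 5)), numeric(3)))
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    tipA <- centre - dirx * d_series[f] / 2
    tipB <- centre + dirx * d_series[f] / 2
    xyz <- rbind(arrow_beads(tipA, dirx), arrow_beads(tipB, -dirx))
    if (n_ions > 0) {
      mid <- (tipA + tipB) / 2
      jit <- matrix(stats::runif(3 * n_ions, -0.03, 0.03), n_ions, 3)
      bulk_jit <- matrix(stats::runif(3 * n_ions, -0.1, 0.1), n_ions, 3)
      ion_xyz <- ifelse(matrix(states[, f], n_ions, 3),
                        matrix(mid, n_ions, 3, byrow = TRUE) + jit,
                        bulk_site[seq_len(n_ions), , drop = FALSE] + bulk_jit)
      xyz <- rbind(xyz, ion_xyz)
    }
    frames[[f]] <- xyz
  }
  traj <- trajectory((seq_len(nf) - 1L) * spec$frame_spacing, frames,
                     box_length = box)
  ion_groups <- if (n_ions > 0)
    stats::setNames(as.list(ion_ids),
                    sys$atoms$residue_name[match(ion_ids, sys$atoms$atom_id)])
  else list()
  if (n_ions > 0)
    names(ion_groups) <- paste0(names(ion_groups), seq_len(n_ions))
  structure(list(system = sys, trajectory = traj,
                 groups = list(
                   protein_a = selection_group("protein_a", 1:4, "protein_A"),
                   protein_b = selection_group("protein_b", 5:8, "protein_B"),
                   ions = ion_groups),
                 bridge_states = states,
                 designed_distance = if (use_dw) d_series else NULL,
                 spec = spec),
            class = "two_protein_fixture")
}

#' Write a synthetic fixture to disk
#'
#' Writes the structure as PDB, the trajectory in the plain-text dialect and
#' the selection groups as TSV. Output is deterministic: identical inputs
#' give byte-identical files.
#'
#' @param system a [molecular_system()].
#' @param traj a [trajectory()].
#' @param out_dir output directory (created if needed).
#' @param groups optional named list of [selection_group()]s.
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture <- function(system, traj, out_dir, groups = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- c(structure = file.path(out_dir, "system.pdb"),
             trajectory = file.path(out_dir, "trajectory.txt"),
             selections = file.path(out_dir, "selections.tsv"))
  write_structure(system, paths[["structure"]],
                  coordinates = if (!is.null(system$coordinates))
                    system$coordinates else frame_coords(traj, 1L))
  write_trajectory(traj, paths[["trajectory"]])
  groups <- Filter(function(g) inherits(g, "selection_group"), groups)
  sel <- if (length(groups)) {
    do.call(rbind, lapply(groups, function(g) data.frame(
      name = g$name, role = g$role,
      atom_ids = paste(g$atom_ids, collapse = ","))))
  } else data.frame(name = character(0), role = character(0),
                    atom_ids = character(0))
  utils::write.table(sel, paths[["selections"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read selection groups written by [write_fixture()]
#'
#' @param path `selections.tsv` path.
#' @return named list of [selection_group()]s.
#' @export
read_selections <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    selection_group(df$name[i],
                    as.integer(strsplit(df$atom_ids[i], ",")[[1]]),
                    df$role[i]))
  stats::setNames(out, df$name)
}
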