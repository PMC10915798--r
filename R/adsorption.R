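# Surface radial distributions, per-residue contact counting and the Buffer
# Adsorption Index (BAI): BAI_i = -kT ln(N_avg_i / N_max), reported
# numerically in kT units. Lower BAI means stronger buffer adsorption on
# residue i; the residue with the most time-averaged contacts defines the
# free-energy origin.

#' Surface radial distribution of target atoms around a reference group
#'
#' For every retained frame and every target atom, the minimum-image distance
#' to the *nearest* reference atom is computed and histogrammed in left-closed
#' bins; counts are divided by `n_frames_used * bin_width`, so the integral of
#' the profile over r equals the mean number of target atoms within range
#' (an unnormalised, surface-referenced rdf in counts/nm).
#'
#' @param traj a [trajectory()].
#' @param reference,target [selection_group()]s or atom-id vectors.
#' @param bin_width bin width in nm (default 0.005).
#' @param r_max histogram range in nm (default 2.5).
#' @param skip number of initial frames to drop as equilibration; default is
#'   the first 5 percent of frames (mirroring discard-the-early-ns practice).
#' @param box_length box edge; defaults to the trajectory's.
#' @return object of class `rdf_profile` with `bin_edges` (length nbins+1),
#'   `density` (counts/nm), `reference`, `target`, `n_frames`.
#' @export
surface_rdf <- function(traj, reference, target, bin_width = 0.005,
                        r_max = 2.5, skip = NULL, box_length = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive")
  ref_ids <- as_atom_ids(reference)
  tgt_ids <- as_atom_ids(target)
  if (!length(ref_ids) || !length(tgt_ids)) stop("empty selection group")
  nf <- n_frames(traj)
  if (is.null(skip)) skip <- floor(0.05 * nf)
  if (skip >= nf) stop("skip must be smaller than the number of frames")
  if (is.null(box_length)) box_length <- traj$box_length
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  frames <- (skip + 1L):nf
  for (i in frames) {
    xyz <- frame_coords(traj, i)
    d <- nearest_ref_distance(xyz[tgt_ids, , drop = FALSE],
                              xyz[ref_ids, , drop = FALSE], box_length)
    d <- d[d < r_max]
    if (length(d))
      counts <- counts + tabulate(findInterval(d, edges), nbins = nb)
  }
  structure(list(bin_edges = edges,
                 density = counts / (length(frames) * bin_width),
                 reference = group_name(reference, "reference"),
                 target = group_name(target, "target"),
                 n_frames = length(frames),
                 bin_width = bin_width, r_max = r_max),
            class = "rdf_profile")
}

#' Cumulative target count within distance r of the surface
#'
#' Integrates an [surface_rdf()] profile bin-by-bin: the sum of
#' `density * bin_width` over all bins whose right edge lies at or below `r`.
#' Nondecreasing in `r`; at `r = r_max` it returns the mean number of target
#' atoms within range.
#'
#' @param profile an `rdf_profile`.
#' @param r distance in nm; must lie within `[0, r_max]`.
#' @return mean cumulative count n(r).
#' @export
cumulative_count <- function(profile, r) {
  if (r < 0 || r > profile$r_max + 1e-12)
    stop("r = ", r, " outside profile range [0, ", profile$r_max, "]")
  right <- profile$bin_edges[-1L]
  keep <- right <= r + 1e-12
  sum(profile$density[keep]) * profile$bin_width
}

#' Per-residue atomic contact counts in one frame
#'
#' A contact is any (protein atom, buffer atom) pair at minimum-image distance
#' `<= cutoff`; the count for residue i is the number of such pairs involving
#' its atoms (an atomic-pair count, not a count of distinct buffer molecules).
#' Hydrogens participate like any other atom.
#'
#' @param coords n_atoms x 3 frame coordinates (nm), indexed by atom id.
#' @param system a [molecular_system()] (residue bookkeeping).
#' @param protein_group,buffer_group [selection_group()]s or atom-id vectors.
#' @param cutoff contact distance in nm (default 0.4).
#' @param box_length box edge or `NULL` for no wrapping.
#' @return named integer vector of per-residue contact counts, one entry per
#'   residue represented in `protein_group` (zeros included); names are
#'   residue indices.
#' @export
count_contacts <- function(coords, system, protein_group, buffer_group,
                           cutoff = 0.4, box_length = NULL) {
  pid <- as_atom_ids(protein_group)
  bid <- as_atom_ids(buffer_group)
  if (!length(pid) || !length(bid)) stop("empty selection group")
  res <- system$atoms$residue_index[match(pid, system$atoms$atom_id)]
  dm <- mic_distmat(coords[pid, , drop = FALSE], coords[bid, , drop = FALSE],
                    box_length)
  per_atom <- rowSums(dm <= cutoff)
  out <- vapply(split(per_atom, res), sum, numeric(1))
  stats::setNames(as.integer(out), names(out))
}

#' Per-frame contact-count matrix over a trajectory
#'
#' Convenience wrapper applying [count_contacts()] to every retained frame.
#'
#' @inheritParams count_contacts
#' @param traj a [trajectory()].
#' @param skip initial frames to drop (default 0).
#' @return residues x frames integer matrix; rownames are residue indices.
#' @export
contact_count_matrix <- function(traj, system, protein_group, buffer_group,
                                 cutoff = 0.4, skip = 0, box_length = NULL) {
  if (is.null(box_length)) box_length <- traj$box_length
  frames <- (skip + 1L):n_frames(traj)
  cols <- lapply(frames, function(i)
    count_contacts(frame_coords(traj, i), system, protein_group, buffer_group,
                   cutoff, box_length))
  do.call(cbind, cols)
}

#' Average contact counts over trajectories
#'
#' Time-averages the per-frame counts within each trajectory, then takes the
#' unweighted mean across trajectories (so runs of different lengths carry
#' equal weight, matching multi-run averaging of independent simulations).
#'
#' @param counts_list list of residues x frames matrices (one per trajectory)
#'   with identical rownames.
#' @return named numeric vector of N_avg per residue.
#' @export
average_contacts <- function(counts_list) {
  if (!length(counts_list)) stop("need at least one trajectory")
  per_traj <- lapply(counts_list, rowMeans)
  rn <- names(per_traj[[1]])
  if (!all(vapply(per_traj, function(x) identical(names(x), rn), logical(1))))
    stop("trajectories disagree on residue sets")
  Reduce(`+`, per_traj) / length(per_traj)
}

#' Buffer Adsorption Index from time-averaged contact counts
#'
#' `BAI_i = -kT ln(N_avg_i / N_max)` in kT units, where `N_max` is the largest
#' `N_avg` over *all* rows (i.e. over every charge state of the buffer
#' species, so all states share one free-energy origin). Residues with zero
#' contacts get `Inf` and are flagged; they are excluded from averages and
#' distributions downstream.
#'
#' @param n_avg data.frame with columns `residue_index`, `residue_name`,
#'   `state`, `n_avg` (or a named numeric vector for a single state).
#' @param temperature analysis temperature in K (bookkeeping; BAI is in kT).
#' @return object of class `bai_result`: the input table with a `bai` column,
#'   plus `n_max`, `temperature` and `zero_contact_flags`.
#' @export
compute_bai <- function(n_avg, temperature = DEFAULT_TEMPERATURE) {
  if (is.numeric(n_avg) && !is.data.frame(n_avg)) {
    n_avg <- data.frame(residue_index = as.integer(names(n_avg)),
                        residue_name = NA_character_,
                        state = "state1", n_avg = as.numeric(n_avg))
  }
  if (any(n_avg$n_avg < 0)) stop("N_avg must be nonnegative")
  n_max <- max(n_avg$n_avg)
  if (n_max <= 0) stop("all N_avg are zero; BAI is undefined")
  n_avg$bai <- -log(n_avg$n_avg / n_max)  # Inf where n_avg == 0
  structure(list(table = n_avg, n_max = n_max, temperature = temperature,
                 zero_contact_flags = n_avg$n_avg == 0),
            class = "bai_result")
}

#' @export
print.bai_result <- function(x, ...) {
  cat("bai_result:", nrow(x$table), "(residue, state) entries; N_max =",
      format(x$n_max), "contacts; T =", x$temperature, "K\n")
  cat("  zero-contact entries:", sum(x$zero_contact_flags), "\n")
  invisible(x)
}

#' Mean BAI per amino-acid species, gated on solvent exposure
#'
#' For each residue species (LYS, ARG, ...), the unweighted mean BAI over
#' residues that have nonzero time-averaged SASA and finite BAI. Species with
#' no eligible residue are omitted (with a message).
#'
#' @param bai a [compute_bai()] result whose table has `residue_name` set.
#' @param sasa a `sasa_result` covering every residue in `bai`.
#' @return data.frame `residue_name`, `mean_bai`, `n_residues`.
#' @export
species_average_bai <- function(bai, sasa) {
  tab <- bai$table
  area <- sasa$per_residue_area
  m <- match(tab$residue_index, area$residue_index)
  if (anyNA(m)) stop("SASA is missing for some residues in the BAI table")
  eligible <- area$area_nm2[m] > 0 & is.finite(tab$bai)
  dropped <- unique(tab$residue_name[!eligible])
  dropped <- setdiff(dropped, unique(tab$residue_name[eligible]))
  if (length(dropped))
    message("species with no eligible residues omitted: ",
            paste(dropped, collapse = ", "))
  sub <- tab[eligible, , drop = FALSE]
  if (!nrow(sub)) stop("no eligible residues (all buried or zero-contact)")
  agg <- stats::aggregate(sub$bai, by = list(residue_name = sub$residue_name),
                          FUN = mean)
  cnt <- stats::aggregate(sub$bai, by = list(residue_name = sub$residue_name),
                          FUN = length)
  data.frame(residue_name = agg$residue_name, mean_bai = agg$x,
             n_residues = cnt$x)
}

#' Normalised probability distribution of BAI values
#'
#' Histogram over the finite BAI values, normalised so that
#' `sum(p * bin_width) == 1`.
#'
#' @param bai a [compute_bai()] result.
#' @param bin_width bin width in kT (default 0.25).
#' @return list with `bin_edges` (kT) and `p` (probability density per kT).
#' @export
bai_distribution <- function(bai, bin_width = 0.25) {
  v <- bai$table$bai[is.finite(bai$table$bai)]
  if (!length(v)) stop("no finite BAI values")
  edges <- seq(0, max(v) + bin_width, by = bin_width)
  counts <- tabulate(findInterval(v, edges), nbins = length(edges) - 1L)
  list(bin_edges = edges, p = counts / (length(v) * bin_width))
}

#' Write an rdf profile to TSV
#' @param profile an `rdf_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rdf_tsv <- function(profile, path) {
  mid <- utils::head(profile$bin_edges, -1L) + profile$bin_width / 2
  utils::write.table(data.frame(r_nm = mid, density_per_nm = profile$density),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-residue BAI table to TSV
#' @param bai a `bai_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bai_tsv <- function(bai, path) {
  tab <- bai$table[, c("residue_index", "residue_name", "state", "n_avg",
                       "bai")]
  names(tab)[5] <- "BAI_kT"
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
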