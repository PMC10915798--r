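# Shared fixtures and independent brute-force oracles.

make_atoms <- function(n, residue_index = seq_len(n), residue_name = "GLY",
                       element = "C", charge = 0, chain = "A") {
  data.frame(atom_id = seq_len(n), atom_name = element, element = element,
             residue_index = residue_index,
             residue_name = rep_len(residue_name, n),
             chain_id = chain, formal_charge = rep_len(charge, n),
             radius = ionbridge::element_radius(rep_len(element, n)),
             stringsAsFactors = FALSE)
}

make_system <- function(coords, box = 12, ...) {
  coords <- as.matrix(coords)
  molecular_system(make_atoms(nrow(coords), ...), box, coordinates = coords)
}

# Minimum-image distance by explicit enumeration of all 27 periodic images
# of the into-cell-wrapped difference vector.
bf_min_image <- function(p, q, box) {
  d0 <- (p - q) %% box
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- sqrt(sum((d0 + box * c(i, j, k))^2))
    best <- min(best, d)
  }
  best
}

# Exhaustive double-loop group minimum distance.
bf_group_min <- function(coords, ia, ib, box) {
  best <- Inf; pair <- c(NA, NA)
  for (a in sort(ia)) for (b in sort(ib)) {
    d <- bf_min_image(coords[a, ], coords[b, ], box)
    if (d < best) { best <- d; pair <- c(a, b) }
  }
  list(d_min = best, pair = pair)
}

# Exhaustive per-residue contact counting.
bf_contacts <- function(coords, system, pid, bid, cutoff, box) {
  res <- system$atoms$residue_index[match(pid, system$atoms$atom_id)]
  out <- stats::setNames(rep(0L, length(unique(res))),
                         sort(unique(res)))
  for (i in seq_along(pid)) for (b in bid) {
    d <- bf_min_image(coords[pid[i], ], coords[b, ], box)
    if (d <= cutoff) {
      key <- as.character(res[i])
      out[key] <- out[key] + 1L
    }
  }
  out
}

# Exhaustive bridge detection.
bf_bridges <- function(coords, ion_molecules, ia, ib, cutoff, box) {
  nms <- names(ion_molecules)
  hits <- character(0)
  for (m in seq_along(ion_molecules)) {
    ids <- ion_molecules[[m]]
    da <- min(vapply(ids, function(i) min(vapply(ia, function(a)
      bf_min_image(coords[i, ], coords[a, ], box), numeric(1))), numeric(1)))
    db <- min(vapply(ids, function(i) min(vapply(ib, function(b)
      bf_min_image(coords[i, ], coords[b, ], box), numeric(1))), numeric(1)))
    if (da < cutoff && db < cutoff) hits <- c(hits, nms[m])
  }
  hits
}

# A tiny static trajectory from a list of coordinate matrices.
make_traj <- function(coord_list, box = 12, spacing = 10) {
  trajectory((seq_along(coord_list) - 1) * spacing, coord_list,
             box_length = box)
}

quiet_equilibrium <- function(spec) {
  suppressWarnings(suppressMessages(sample_equilibrium_frames(spec)))
}
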