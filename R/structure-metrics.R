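# Geometric observables: solvent-accessible surface area (Shrake-Rupley
# quadrature on a deterministic golden-spiral point set) and radius of
# gyration. SASA is computed without periodic wrapping: a molecule is assumed
# not to touch its own periodic image, which holds for the protein sizes and
# boxes this package targets.

# n approximately-uniform unit-sphere points (golden spiral; deterministic).
sphere_points <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  phi <- (k - 1) * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

# Per-atom Shrake-Rupley accessible area (nm^2).
shrake_rupley <- function(coords, radii, probe_radius = 0.14, n_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  pts <- sphere_points(n_points)
  inflated <- radii + probe_radius
  # neighbour cut: two inflated spheres can only intersect within this radius
  dm <- mic_distmat(coords, coords, NULL)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    ri <- inflated[i]
    nb <- which(dm[i, ] < ri + inflated & seq_len(n) != i)
    full <- 4 * pi * ri^2
    if (!length(nb)) { areas[i] <- full; next }
    p <- sweep(pts * ri, 2L, coords[i, ], "+")
    covered <- rep(FALSE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
             (p[, 3] - coords[j, 3])^2
      covered <- covered | dj2 < inflated[j]^2
      if (all(covered)) break
    }
    areas[i] <- full * mean(!covered)
  }
  areas
}

#' Per-residue solvent-accessible surface area
#'
#' Shrake-Rupley quadrature: for each atom, the fraction of `n_points`
#' sphere points at radius `r_atom + probe_radius` not buried inside any
#' other probe-inflated atom, times the inflated sphere area; atom areas are
#' summed per residue. The point set is a deterministic golden spiral.
#' Hydrogens, when present in the structure, are included.
#'
#' @param system a [molecular_system()] supplying radii and residue labels.
#' @param coordinates n_atoms x 3 matrix (nm); defaults to the system's
#'   reference coordinates.
#' @param probe_radius solvent probe radius in nm (default 0.14, a water-size
#'   probe).
#' @param n_points quadrature points per atom (default 960); must be >= 10.
#' @return object of class `sasa_result`: data.frame `per_residue_area`
#'   (`residue_index`, `residue_name`, `area_nm2`) plus `probe_radius`,
#'   `n_points` and `total_area`.
#' @export
sasa_per_residue <- function(system, coordinates = NULL, probe_radius = 0.14,
                             n_points = 960) {
  if (n_points < 10) stop("n_points must be at least 10")
  coords <- if (!is.null(coordinates)) as.matrix(coordinates)
            else system$coordinates
  if (is.null(coords)) stop("no coordinates supplied")
  a <- system$atoms
  atom_area <- shrake_rupley(coords, a$radius, probe_radius, n_points)
  agg <- stats::aggregate(atom_area,
                          by = list(residue_index = a$residue_index),
                          FUN = sum)
  names(agg)[2] <- "area_nm2"
  agg$residue_name <- a$residue_name[match(agg$residue_index, a$residue_index)]
  agg <- agg[order(agg$residue_index), c("residue_index", "residue_name",
                                         "area_nm2")]
  rownames(agg) <- NULL
  structure(list(per_residue_area = agg, probe_radius = probe_radius,
                 n_points = n_points, total_area = sum(atom_area)),
            class = "sasa_result")
}

#' Time-averaged per-residue SASA over a trajectory
#'
#' Arithmetic mean of the per-frame, per-residue Shrake-Rupley areas over
#' frames sampled every `stride` frames.
#'
#' @param traj a [trajectory()].
#' @param system a [molecular_system()].
#' @param stride sample every `stride`-th frame (default 1); must be >= 1.
#' @inheritParams sasa_per_residue
#' @return a `sasa_result` whose areas are time averages.
#' @export
time_averaged_sasa <- function(traj, system, stride = 1, probe_radius = 0.14,
                               n_points = 960) {
  if (stride < 1) stop("stride must be >= 1")
  idx <- seq(1L, n_frames(traj), by = stride)
  acc <- NULL
  for (i in idx) {
    s <- sasa_per_residue(system, frame_coords(traj, i), probe_radius, n_points)
    if (is.null(acc)) {
      acc <- s
      acc$per_residue_area$area_nm2 <- acc$per_residue_area$area_nm2 / length(idx)
      acc$total_area <- acc$total_area / length(idx)
    } else {
      acc$per_residue_area$area_nm2 <- acc$per_residue_area$area_nm2 +
        s$per_residue_area$area_nm2 / length(idx)
      acc$total_area <- acc$total_area + s$total_area / length(idx)
    }
  }
  acc
}

#' Radius of gyration
#'
#' `sqrt(sum(m_i |r_i - r_com|^2) / sum(m_i))`; translation and rotation
#' invariant.
#'
#' @param coordinates n x 3 coordinate matrix (nm).
#' @param masses optional per-atom masses; defaults to unit masses.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(coordinates, masses = NULL) {
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) < 1L) stop("need at least one atom")
  if (is.null(masses)) masses <- rep(1, nrow(coordinates))
  if (any(masses < 0) || sum(masses) <= 0) stop("total mass must be positive")
  com <- colSums(coordinates * masses) / sum(masses)
  dev <- sweep(coordinates, 2L, com)
  sqrt(sum(masses * rowSums(dev^2)) / sum(masses))
}

#' Write per-residue SASA to TSV
#'
#' @param sasa a `sasa_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sasa_tsv <- function(sasa, path) {
  utils::write.table(sasa$per_residue_area, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
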