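# Contact survival kinetics and ionic-bridge detection.
#
# A contact "channel" is an (ion, partner) pair with a boolean occupancy per
# frame. The survival probability S(t) is the fraction of occupied time
# origins whose occupancy persists continuously (up to a configurable gap
# tolerance) for a further lag t, pooled over channels and origins.

#' Contact series container
#'
#' @param occupancy channels x frames logical matrix.
#' @param frame_spacing_ps time between frames in ps; positive.
#' @param channels data.frame describing the channels (e.g. `ion`, `partner`);
#'   defaults to sequential ids.
#' @return object of class `contact_series`.
#' @export
contact_series <- function(occupancy, frame_spacing_ps, channels = NULL) {
  occupancy <- as.matrix(occupancy)
  storage.mode(occupancy) <- "logical"
  if (anyNA(occupancy)) stop("occupancy must be defined for every frame")
  if (!is.numeric(frame_spacing_ps) || frame_spacing_ps <= 0)
    stop("frame_spacing_ps must be positive")
  if (is.null(channels))
    channels <- data.frame(ion = seq_len(nrow(occupancy)), partner = "protein")
  structure(list(occupancy = occupancy, frame_spacing = frame_spacing_ps,
                 channels = channels),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat("contact_series:", nrow(x$occupancy), "channels x",
      ncol(x$occupancy), "frames; dt =", x$frame_spacing, "ps;",
      sprintf("mean occupancy %.3f\n", mean(x$occupancy)))
  invisible(x)
}

# Fill FALSE runs of length <= gap flanked by TRUE on both sides.
fill_gaps <- function(occ_row, gap) {
  if (gap <= 0) return(occ_row)
  r <- rle(occ_row)
  n <- length(r$lengths)
  fill <- !r$values & r$lengths <= gap &
    seq_len(n) > 1L & seq_len(n) < n
  r$values[fill] <- TRUE
  inverse.rle(r)
}

# Remaining consecutive-TRUE run length starting at each frame, per channel.
remaining_run_length <- function(occ) {
  nf <- ncol(occ)
  R <- matrix(0L, nrow(occ), nf)
  R[, nf] <- as.integer(occ[, nf])
  if (nf > 1L)
    for (f in (nf - 1L):1L)
      R[, f] <- ifelse(occ[, f], R[, f + 1L] + 1L, 0L)
  R
}

#' Contact survival probability
#'
#' `S(t)`: of the (channel, origin) pairs occupied at a time origin, the
#' fraction still continuously occupied a lag `t` later, allowing
#' interruptions of at most `gap_tolerance` consecutive frames. Every frame
#' that leaves room for the full lag window serves as an origin, and the
#' normalisation pools survivors and origins over all channels (pooled
#' normalisation has lower variance than averaging per-origin ratios).
#' `S(0) = 1` and S is nonincreasing.
#'
#' @param series a [contact_series()].
#' @param max_lag largest lag in ps; must be smaller than the series span.
#' @param gap_tolerance number of consecutive unoccupied frames that do not
#'   break a contact (default 0: strict survival).
#' @return object of class `survival_curve`: data.frame with `lag_ps` and `S`.
#' @export
survival_probability <- function(series, max_lag, gap_tolerance = 0) {
  dt <- series$frame_spacing
  nf <- ncol(series$occupancy)
  L <- as.integer(round(max_lag / dt))
  if (L < 0L || L >= nf)
    stop("max_lag must be nonnegative and smaller than the trajectory span")
  occ <- series$occupancy
  filled <- if (gap_tolerance > 0)
    t(apply(occ, 1L, fill_gaps, gap = gap_tolerance)) else occ
  R <- remaining_run_length(filled)
  origins <- seq_len(nf - L)
  mask <- occ[, origins, drop = FALSE]
  if (!any(mask)) stop("no occupied time origins")
  v <- R[, origins, drop = FALSE][mask]
  # S(k) = P(v >= k + 1), k = 0..L
  tb <- tabulate(pmin(v, L + 1L), nbins = L + 1L)
  S <- rev(cumsum(rev(tb))) / length(v)
  structure(data.frame(lag_ps = (0:L) * dt, S = S),
            class = c("survival_curve", "data.frame"))
}

#' Build contact occupancy series from a trajectory
#'
#' Occupancy of channel (ion, partner) is TRUE in a frame when any atomic
#' pair between the ion's atoms and the partner's atoms lies within `cutoff`
#' (minimum image). Granularity `"ion-protein"` gives one channel per ion
#' molecule; `"ion-residue"` one channel per (ion, protein residue) pair.
#'
#' @param traj a [trajectory()].
#' @param system a [molecular_system()].
#' @param ion_molecules named list of atom-id vectors, one per ion molecule.
#' @param protein_group [selection_group()] or atom-id vector.
#' @param cutoff contact cutoff in nm (default 0.4).
#' @param granularity `"ion-protein"` or `"ion-residue"`.
#' @param box_length box edge; defaults to the trajectory's.
#' @return a [contact_series()].
#' @export
build_contact_series <- function(traj, system, ion_molecules, protein_group,
                                 cutoff = 0.4,
                                 granularity = c("ion-protein", "ion-residue"),
                                 box_length = NULL) {
  granularity <- match.arg(granularity)
  pid <- as_atom_ids(protein_group)
  if (!length(ion_molecules) || !length(pid)) stop("empty selection group")
  if (is.null(box_length)) box_length <- traj$box_length
  nf <- n_frames(traj)
  ion_names <- names(ion_molecules)
  if (is.null(ion_names)) ion_names <- paste0("ion", seq_along(ion_molecules))
  res <- system$atoms$residue_index[match(pid, system$atoms$atom_id)]
  res_levels <- sort(unique(res))

  if (granularity == "ion-protein") {
    occ <- matrix(FALSE, length(ion_molecules), nf)
    channels <- data.frame(ion = ion_names, partner = "protein")
  } else {
    occ <- matrix(FALSE, length(ion_molecules) * length(res_levels), nf)
    channels <- expand.grid(residue = res_levels, ion = ion_names,
                            stringsAsFactors = FALSE)[, c("ion", "residue")]
  }
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    for (m in seq_along(ion_molecules)) {
      dm <- mic_distmat(xyz[pid, , drop = FALSE],
                        xyz[ion_molecules[[m]], , drop = FALSE], box_length)
      if (granularity == "ion-protein") {
        occ[m, f] <- any(dm <= cutoff)
      } else {
        near <- rowSums(dm <= cutoff) > 0
        hit <- res_levels %in% res[near]
        occ[(m - 1L) * length(res_levels) + seq_along(res_levels), f] <- hit
      }
    }
  }
  contact_series(occ, traj$frame_spacing, channels)
}

#' Detect ionic bridges in one frame
#'
#' An ion molecule bridges two proteins when its minimum atomic distance to
#' protein A *and* to protein B are both below `cutoff`. Symmetric in A and B.
#'
#' @param coords frame coordinates (nm), indexed by atom id.
#' @param ion_molecules named list of atom-id vectors, one per ion molecule.
#' @param group_a,group_b disjoint protein [selection_group()]s or id vectors.
#' @param cutoff bridge cutoff in nm (default 0.4).
#' @param box_length box edge or `NULL`.
#' @return character vector of bridging ion names.
#' @export
detect_bridges <- function(coords, ion_molecules, group_a, group_b,
                           cutoff = 0.4, box_length = NULL) {
  ia <- as_atom_ids(group_a); ib <- as_atom_ids(group_b)
  if (length(intersect(ia, ib))) stop("protein groups must be disjoint")
  ion_names <- names(ion_molecules)
  if (is.null(ion_names)) ion_names <- paste0("ion", seq_along(ion_molecules))
  bridging <- vapply(ion_molecules, function(ids) {
    da <- min(mic_distmat(coords[ids, , drop = FALSE],
                          coords[ia, , drop = FALSE], box_length))
    if (da >= cutoff) return(FALSE)
    db <- min(mic_distmat(coords[ids, , drop = FALSE],
                          coords[ib, , drop = FALSE], box_length))
    db < cutoff
  }, logical(1))
  ion_names[bridging]
}

#' Bridge intervals and bridge survival over a trajectory
#'
#' Scans every frame for ions satisfying the bridge criterion, extracts the
#' maximal frame intervals during which each ion bridges continuously (FALSE
#' gaps up to `gap_tolerance` frames are bridged over) and computes a survival
#' curve from the bridge occupancy series.
#'
#' @inheritParams detect_bridges
#' @param traj a [trajectory()].
#' @param gap_tolerance frames of interruption tolerated inside one record.
#' @param max_lag largest survival lag in ps; defaults to a quarter of the
#'   trajectory span.
#' @return list with `records` (data.frame `ion`, `start_frame`, `end_frame`,
#'   `t_start_ps`, `t_end_ps`, `duration_ps`, `censored`), `series` (the
#'   bridge [contact_series()]) and `survival` (a `survival_curve`, `NULL`
#'   when no ion ever bridges).
#' @export
bridge_lifetimes <- function(traj, ion_molecules, group_a, group_b,
                             cutoff = 0.4, gap_tolerance = 0,
                             max_lag = NULL, box_length = NULL) {
  if (is.null(box_length)) box_length <- traj$box_length
  nf <- n_frames(traj)
  dt <- traj$frame_spacing
  ion_names <- names(ion_molecules)
  if (is.null(ion_names)) {
    ion_names <- paste0("ion", seq_along(ion_molecules))
    names(ion_molecules) <- ion_names
  }
  occ <- matrix(FALSE, length(ion_molecules), nf,
                dimnames = list(ion_names, NULL))
  for (f in seq_len(nf)) {
    hits <- detect_bridges(frame_coords(traj, f), ion_molecules,
                           group_a, group_b, cutoff, box_length)
    occ[hits, f] <- TRUE
  }
  records <- bridge_records_from_occupancy(occ, dt, gap_tolerance,
                                           times = traj$times)
  series <- contact_series(occ, dt,
                           data.frame(ion = ion_names, partner = "bridge"))
  surv <- NULL
  if (any(occ)) {
    if (is.null(max_lag)) max_lag <- (nf - 1L) * dt / 4
    surv <- survival_probability(series, max_lag, gap_tolerance)
  }
  list(records = records, series = series, survival = surv)
}

#' Maximal TRUE intervals of an occupancy matrix as bridge records
#'
#' Extracts, per channel, the maximal frame intervals of continuous occupancy
#' (after bridging FALSE gaps of at most `gap_tolerance` frames). Records
#' touching either trajectory edge are marked `censored`.
#'
#' @param occupancy channels x frames logical matrix (rownames used as ion
#'   labels when present).
#' @param spacing frame spacing in ps.
#' @param gap_tolerance frames of interruption tolerated within one record.
#' @param times optional per-frame times (defaults to `(0:(nf-1)) * spacing`).
#' @return data.frame `ion`, `start_frame`, `end_frame`, `t_start_ps`,
#'   `t_end_ps`, `duration_ps`, `censored`.
#' @export
bridge_records_from_occupancy <- function(occupancy, spacing,
                                          gap_tolerance = 0, times = NULL) {
  occupancy <- as.matrix(occupancy)
  nf <- ncol(occupancy)
  if (is.null(times)) times <- (seq_len(nf) - 1L) * spacing
  ion_names <- rownames(occupancy)
  if (is.null(ion_names)) ion_names <- paste0("ion", seq_len(nrow(occupancy)))
  records <- list()
  for (m in seq_len(nrow(occupancy))) {
    filled <- fill_gaps(occupancy[m, ], gap_tolerance)
    r <- rle(filled)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      records[[length(records) + 1L]] <- data.frame(
        ion = ion_names[m], start_frame = starts[k], end_frame = ends[k],
        t_start_ps = times[starts[k]], t_end_ps = times[ends[k]],
        duration_ps = (ends[k] - starts[k]) * spacing,
        censored = starts[k] == 1L || ends[k] == nf)
    }
  }
  if (length(records)) do.call(rbind, records)
  else data.frame(ion = character(0), start_frame = integer(0),
                  end_frame = integer(0), t_start_ps = numeric(0),
                  t_end_ps = numeric(0), duration_ps = numeric(0),
                  censored = logical(0))
}

#' Survival of bridge records by interval duration
#'
#' Complementary estimator to [survival_probability()]: among freshly formed
#' bridge records (not already present at frame 1), the fraction whose
#' duration reaches each lag. Only records whose observation window covers
#' the lag are at risk, so right-censoring at the trajectory end does not
#' bias the estimate; records are independent events, so binomial statistics
#' apply directly.
#'
#' @param records the `records` data.frame from [bridge_lifetimes()].
#' @param lags_ps lags at which to evaluate.
#' @param n_frames,frame_spacing trajectory length and spacing (ps), used to
#'   determine which records can be observed out to each lag.
#' @return data.frame `lag_ps`, `S`, `n` (records at risk).
#' @export
interval_survival <- function(records, lags_ps, n_frames, frame_spacing) {
  fresh <- records[records$start_frame > 1L, , drop = FALSE]
  if (!nrow(fresh)) stop("no freshly formed bridge records")
  rows <- lapply(lags_ps, function(t) {
    k <- ceiling(t / frame_spacing - 1e-9)
    at_risk <- fresh[fresh$start_frame + k <= n_frames, , drop = FALSE]
    if (!nrow(at_risk)) return(data.frame(lag_ps = t, S = NA_real_, n = 0L))
    data.frame(lag_ps = t, S = mean(at_risk$duration_ps >= t - 1e-9),
               n = nrow(at_risk))
  })
  do.call(rbind, rows)
}

#' Anchor residues of an ionic bridge in one frame
#'
#' For a bridging ion, the residue on each protein containing the atom
#' closest to the ion. Distance ties are resolved toward the lower residue
#' index.
#'
#' @param coords frame coordinates (nm), indexed by atom id.
#' @param system a [molecular_system()].
#' @param ion_atoms atom ids of the bridging ion.
#' @param group_a,group_b protein groups.
#' @param box_length box edge or `NULL`.
#' @return list with `residue_a` and `residue_b`, each
#'   `list(residue_index, residue_name, distance)`.
#' @export
bridge_anchor_residues <- function(coords, system, ion_atoms, group_a, group_b,
                                   box_length = NULL) {
  anchor <- function(pid) {
    res <- system$atoms$residue_index[match(pid, system$atoms$atom_id)]
    dm <- mic_distmat(coords[pid, , drop = FALSE],
                      coords[as_atom_ids(ion_atoms), , drop = FALSE],
                      box_length)
    dmin_atom <- apply(dm, 1L, min)
    best <- min(dmin_atom)
    cand <- which(dmin_atom <= best + 1e-12)
    ri <- min(res[cand])
    list(residue_index = ri,
         residue_name = system$atoms$residue_name[
           match(ri, system$atoms$residue_index)],
         distance = best)
  }
  list(residue_a = anchor(as_atom_ids(group_a)),
       residue_b = anchor(as_atom_ids(group_b)))
}

#' Write a survival curve to TSV
#' @param curve a `survival_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival_tsv <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
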