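#' Minimum-image distance between two points in a cubic periodic box
#'
#' @param p,q numeric length-3 coordinates (nm).
#' @param box_length cubic box edge (nm), positive.
#' @return Euclidean distance (nm) after per-axis minimum-image wrapping;
#'   never exceeds `box_length * sqrt(3) / 2`.
#' @export
minimum_image_distance <- function(p, q, box_length) {
  if (!is.numeric(box_length) || length(box_length) != 1L ||
      !is.finite(box_length) || box_length <= 0)
    stop("box_length must be a single positive number")
  if (!all(is.finite(p)) || !all(is.finite(q)))
    stop("coordinates must be finite")
  d <- p - q
  d <- d - box_length * round(d / box_length)
  sqrt(sum(d * d))
}

# Full pairwise minimum-image distance matrix between coordinate sets
# a (n x 3) and b (m x 3). box = NULL disables wrapping.
mic_distmat <- function(a, b, box = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dx <- outer(a[, k], b[, k], "-")
    if (!is.null(box) && is.finite(box)) dx <- dx - box * round(dx / box)
    d2 <- d2 + dx * dx
  }
  sqrt(d2)
}

# For each row of `target`, the distance to the nearest row of `ref`.
nearest_ref_distance <- function(target, ref, box = NULL) {
  dm <- mic_distmat(ref, target, box)
  if (nrow(ref) == 1L) as.numeric(dm) else apply(dm, 2L, min)
}

#' Minimum distance between two atom groups in one frame
#'
#' Returns the smallest minimum-image pairwise distance between atoms of two
#' disjoint groups and one pair achieving it. Ties are broken in favour of the
#' lowest atom id in the first group, then the lowest in the second.
#'
#' @param coords n_atoms x 3 frame coordinates (nm), indexed by atom id.
#' @param group_a,group_b [selection_group()]s or integer atom-id vectors;
#'   must be nonempty and disjoint.
#' @param box_length box edge (nm) or `NULL` for no wrapping.
#' @return list with `d_min` (nm) and `pair` (atom ids `c(a, b)`).
#' @export
group_min_distance <- function(coords, group_a, group_b, box_length = NULL) {
  ia <- as_atom_ids(group_a)
  ib <- as_atom_ids(group_b)
  if (!length(ia) || !length(ib)) stop("groups must be nonempty")
  if (length(intersect(ia, ib)))
    stop("groups overlap: shared atom id(s) ",
         paste(utils::head(intersect(ia, ib), 5L), collapse = ", "))
  ia <- sort(ia); ib <- sort(ib)
  dm <- mic_distmat(coords[ia, , drop = FALSE], coords[ib, , drop = FALSE],
                    box_length)
  m <- min(dm)
  hit <- which(dm == m, arr.ind = TRUE)
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  list(d_min = m, pair = c(ia[hit[1L, 1L]], ib[hit[1L, 2L]]))
}
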