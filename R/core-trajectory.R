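#' Trajectory container
#'
#' An ordered list of coordinate frames with strictly increasing, uniformly
#' spaced times. Coordinates are stored unwrapped; periodic wrapping is
#' applied on demand by the distance routines.
#'
#' @param times numeric vector of frame times in ps, strictly increasing.
#' @param coords list of n_atoms x 3 coordinate matrices (nm), one per frame.
#' @param box_length cubic box edge in nm.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(times, coords, box_length = NA_real_) {
  if (length(times) == 0L) stop("no frames")
  if (length(times) != length(coords))
    stop("times and coords must have equal length")
  n <- vapply(coords, nrow, integer(1))
  if (length(unique(n)) != 1L)
    stop("all frames must have the same atom count")
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("non-increasing frame times")
    if (max(dt) - min(dt) > 1e-9)
      stop("frame times are not uniformly spaced (max deviation ",
           format(max(dt) - min(dt)), " ps)")
    spacing <- dt[1]
  } else {
    spacing <- NA_real_
  }
  structure(list(times = as.numeric(times),
                 coords = lapply(coords, function(m) {
                   m <- as.matrix(m); dimnames(m) <- NULL; m
                 }),
                 frame_spacing = spacing,
                 box_length = box_length),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frames x", nrow(x$coords[[1]]), "atoms\n")
  cat("  time span:", x$times[1], "-", x$times[n_frames(x)],
      "ps; spacing:", x$frame_spacing, "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @export
n_frames <- function(traj) length(traj$times)

#' Coordinates of one frame
#' @param traj a [trajectory()].
#' @param i frame index (1-based).
#' @return n_atoms x 3 matrix (nm).
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range: ", i)
  traj$coords[[i]]
}

#' Read a plain-text trajectory
#'
#' Format: per frame, a header line `natoms time_ps box_nm` followed by
#' `natoms` lines `x y z` in nm.
#'
#' @param path input file.
#' @param system optional [molecular_system()]; if given, every frame's atom
#'   count is checked against it.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, system = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no frames in ", path)
  times <- numeric(0)
  coords <- list()
  box <- NA_real_
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    frame <- frame + 1L
    hdr <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(hdr) != 3L || anyNA(hdr))
      stop("malformed frame header at frame ", frame, " (line ", i, ")")
    nat <- as.integer(hdr[1])
    if (!is.null(system) && nat != n_atoms(system))
      stop("atom-count mismatch at frame ", frame, ": file has ", nat,
           ", system has ", n_atoms(system))
    if (i + nat > length(lines))
      stop("truncated frame ", frame, ": expected ", nat, " coordinate lines")
    block <- lines[(i + 1L):(i + nat)]
    vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(block), "\\s+"))))
    if (length(vals) != 3L * nat || anyNA(vals))
      stop("malformed coordinates in frame ", frame)
    times <- c(times, hdr[2])
    box <- hdr[3]
    coords[[frame]] <- matrix(vals, ncol = 3L, byrow = TRUE)
    i <- i + nat + 1L
  }
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("non-increasing time between frames")
  trajectory(times, coords, box_length = box)
}

#' Write a trajectory in the plain-text dialect
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param digits decimal digits for coordinates (default 6, i.e. 1e-6 nm).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%.", digits, "f")
  for (i in seq_len(n_frames(traj))) {
    m <- traj$coords[[i]]
    writeLines(sprintf("%d %s %s", nrow(m),
                       sprintf(fmt, traj$times[i]),
                       sprintf(fmt, traj$box_length)), con)
    writeLines(sprintf(paste(fmt, fmt, fmt),
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}
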