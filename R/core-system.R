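#' Molecular system container
#'
#' Holds the static description of a simulated system: one row per atom with
#' residue bookkeeping, formal charges and van der Waals radii, plus the edge
#' length of the (cubic, periodic) simulation box. Coordinates live in a
#' [trajectory]; a reference coordinate set (e.g. the one read from a PDB
#' file) may be attached as the `coordinates` element.
#'
#' @param atoms data.frame with columns `atom_id` (1-based integer),
#'   `atom_name`, `element`, `residue_index`, `residue_name`, `chain_id`,
#'   `formal_charge` (elementary charges) and `radius` (nm).
#' @param box_length cubic box edge in nm; must be positive.
#' @param periodic logical; whether minimum-image wrapping applies.
#' @param coordinates optional n_atoms x 3 matrix of reference coordinates (nm).
#' @return an object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, box_length, periodic = TRUE,
                             coordinates = NULL) {
  required <- c("atom_id", "atom_name", "element", "residue_index",
                "residue_name", "chain_id", "formal_charge", "radius")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.numeric(box_length) || length(box_length) != 1L ||
      !is.finite(box_length) || box_length <= 0)
    stop("box_length must be a single positive number (nm)")
  if (any(atoms$radius < 0)) stop("atom radii must be nonnegative")
  if (anyDuplicated(atoms$atom_id)) stop("duplicate atom_id values")
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    if (nrow(coordinates) != nrow(atoms) || ncol(coordinates) != 3L)
      stop("coordinates must be an n_atoms x 3 matrix")
  }
  structure(
    list(atoms = as.data.frame(atoms), box_length = box_length,
         periodic = isTRUE(periodic), coordinates = coordinates),
    class = "molecular_system"
  )
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("molecular_system:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain_id, x$atoms$residue_index))),
      "residues\n")
  cat("  box:", x$box_length, "nm (cubic,",
      if (x$periodic) "periodic" else "non-periodic", ")\n")
  cat("  net formal charge:", sum(x$atoms$formal_charge), "e\n")
  invisible(x)
}

#' Net formal charge of a system or a subset of its atoms
#'
#' @param system a [molecular_system()].
#' @param atom_ids optional atom ids to restrict to.
#' @return total charge in elementary-charge units.
#' @export
net_charge <- function(system, atom_ids = NULL) {
  a <- system$atoms
  if (!is.null(atom_ids)) a <- a[match(atom_ids, a$atom_id), , drop = FALSE]
  sum(a$formal_charge)
}

n_atoms <- function(system) nrow(system$atoms)

#' Atom selection group
#'
#' A named set of atom ids with a role tag used by the analysis stages.
#'
#' @param name group label.
#' @param atom_ids integer vector of (1-based) atom ids; must be nonempty.
#' @param role one of `"protein_A"`, `"protein_B"`, `"buffer_state"`,
#'   `"cation"`, `"anion"`.
#' @return object of class `selection_group`.
#' @export
selection_group <- function(name, atom_ids,
                            role = c("protein_A", "protein_B", "buffer_state",
                                     "cation", "anion")) {
  role <- match.arg(role)
  atom_ids <- as.integer(atom_ids)
  if (length(atom_ids) == 0L) stop("selection group '", name, "' is empty")
  if (anyDuplicated(atom_ids)) stop("duplicate atom ids in group '", name, "'")
  structure(list(name = name, atom_ids = atom_ids, role = role),
            class = "selection_group")
}

# Accept a selection_group or a bare id vector.
as_atom_ids <- function(x) {
  if (inherits(x, "selection_group")) x$atom_ids else as.integer(x)
}

group_name <- function(x, default = "group") {
  if (inherits(x, "selection_group")) x$name else default
}

#' Validate a selection group against a system
#'
#' @param group a [selection_group()].
#' @param system a [molecular_system()].
#' @return the group, invisibly; errors if any id is absent.
#' @export
validate_selection <- function(group, system) {
  missing_ids <- setdiff(group$atom_ids, system$atoms$atom_id)
  if (length(missing_ids))
    stop("group '", group$name, "' references atoms absent from the system: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  invisible(group)
}

# ---- PDB input/output ------------------------------------------------------

# Parse the "1+" / "2-" formal-charge field of a PDB record.
parse_pdb_charge <- function(x) {
  x <- trimws(x)
  out <- numeric(length(x))
  has <- grepl("^[0-9][+-]$", x)
  out[has] <- as.numeric(substr(x[has], 1L, 1L)) *
    ifelse(substr(x[has], 2L, 2L) == "-", -1, 1)
  out
}

# Infer the element of an ATOM/HETATM record lacking an element column.
# Two-letter elements are left-justified at column 13 in the name field;
# single-letter elements have a blank there.
element_from_name <- function(name_field, line_no) {
  two <- normalize_element(substr(name_field, 1L, 2L))
  if (substr(name_field, 1L, 1L) != " " && two %in% names(.ELEMENT_RADII))
    return(two)
  letters_only <- gsub("[^A-Za-z]", "", name_field)
  if (!nchar(letters_only))
    stop("cannot infer element from atom name at line ", line_no)
  normalize_element(substr(letters_only, 1L, 1L))
}

#' Read a molecular system from a fixed-column PDB file
#'
#' Parses `ATOM`/`HETATM` records; all other record types (`TER`, `CONECT`,
#' `REMARK`, ...) are ignored. Elements are taken from columns 77--78 when
#' present and otherwise inferred from the atom-name field. Radii come from a
#' tabulated per-element list (C 0.17, N 0.155, O 0.152, S 0.18, P 0.18,
#' H 0.12 nm, plus common ions). PDB coordinates (Angstrom) are converted to
#' nm and attached as the system's reference coordinates.
#'
#' @param path PDB file path.
#' @param box_length box edge in nm (not stored in PDB files); default 12.
#' @return a [molecular_system()].
#' @export
read_structure <- function(path, box_length = 12) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(keep)) stop("no ATOM/HETATM records in ", path)

  fields <- lapply(keep, function(i) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop("malformed ATOM/HETATM record at line ", i, ": too short")
    ln <- formatC(ln, width = 80L, flag = "-")
    serial <- suppressWarnings(as.integer(substr(ln, 7L, 11L)))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31L, 38L),
                                         substr(ln, 39L, 46L),
                                         substr(ln, 47L, 54L))))
    resseq <- suppressWarnings(as.integer(substr(ln, 23L, 26L)))
    if (is.na(serial) || anyNA(xyz) || is.na(resseq))
      stop("malformed ATOM/HETATM record at line ", i,
           ": non-numeric serial/coordinate/residue field")
    elem <- normalize_element(substr(ln, 77L, 78L))
    if (!nchar(elem)) elem <- element_from_name(substr(ln, 13L, 16L), i)
    if (!elem %in% names(.ELEMENT_RADII))
      stop("unknown element '", elem, "' for atom ",
           trimws(substr(ln, 13L, 16L)), " (serial ", serial,
           ") at line ", i)
    list(atom_id = serial,
         atom_name = trimws(substr(ln, 13L, 16L)),
         element = elem,
         residue_index = resseq,
         residue_name = trimws(substr(ln, 18L, 20L)),
         chain_id = trimws(substr(ln, 22L, 22L)),
         formal_charge = parse_pdb_charge(substr(ln, 79L, 80L)),
         x = xyz[1], y = xyz[2], z = xyz[3])
  })
  df <- do.call(rbind, lapply(fields, function(f)
    data.frame(f, stringsAsFactors = FALSE)))
  coords <- as.matrix(df[, c("x", "y", "z")]) / 10  # Angstrom -> nm
  dimnames(coords) <- NULL
  atoms <- df[, c("atom_id", "atom_name", "element", "residue_index",
                  "residue_name", "chain_id", "formal_charge")]
  atoms$radius <- element_radius(atoms$element)
  rownames(atoms) <- NULL
  molecular_system(atoms, box_length = box_length, coordinates = coords)
}

#' Write a molecular system to a PDB file
#'
#' Inverse of [read_structure()]: coordinates (nm) are written in Angstrom,
#' elements in columns 77--78 and integer formal charges in columns 79--80.
#'
#' @param system a [molecular_system()] with reference coordinates attached.
#' @param path output path.
#' @param coordinates optional n x 3 matrix (nm) overriding the system's
#'   reference coordinates.
#' @return `path`, invisibly.
#' @export
write_structure <- function(system, path, coordinates = NULL) {
  coords <- if (!is.null(coordinates)) as.matrix(coordinates)
            else system$coordinates
  if (is.null(coords)) stop("no coordinates to write")
  a <- system$atoms
  chg <- ifelse(a$formal_charge == 0, "  ",
                sprintf("%d%s", abs(round(a$formal_charge)),
                        ifelse(a$formal_charge < 0, "-", "+")))
  name4 <- ifelse(nchar(a$atom_name) < 4L & nchar(a$element) == 1L,
                  paste0(" ", a$atom_name), a$atom_name)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%2s",
    a$atom_id, name4, a$residue_name, a$chain_id, a$residue_index,
    coords[, 1] * 10, coords[, 2] * 10, coords[, 3] * 10, 1, 0,
    toupper(a$element), chg)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# ---- experiment manifest ---------------------------------------------------

#' Experiment manifest
#'
#' Bookkeeping table of simulated systems: one row per condition with pH,
#' buffer and salt concentrations, production run length and the number of
#' independent runs.
#'
#' @param rows data.frame with columns `system_name`, `pH`, `buffer_mM`,
#'   `nacl_mM`, `run_ns`, `n_runs`.
#' @return object of class `experiment_manifest`.
#' @export
experiment_manifest <- function(rows) {
  required <- c("system_name", "pH", "buffer_mM", "nacl_mM", "run_ns", "n_runs")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols))
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(rows$n_runs < 1)) stop("n_runs must be >= 1 for every row")
  if (any(rows$run_ns <= 0)) stop("run_ns must be positive for every row")
  structure(list(rows = as.data.frame(rows)), class = "experiment_manifest")
}

#' Read an experiment manifest from TSV
#'
#' @param path TSV file with headers `system_name`, `pH`, `buffer_mM`,
#'   `nacl_mM`, `run_ns`, `n_runs`.
#' @return an [experiment_manifest()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  experiment_manifest(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Totals over an experiment manifest
#'
#' @param manifest an [experiment_manifest()].
#' @return list with `total_runs` (sum of `n_runs`) and `cumulative_time_ns`
#'   (sum of `n_runs * run_ns`).
#' @export
summarize_manifest <- function(manifest) {
  rows <- manifest$rows
  if (nrow(rows) == 0L) stop("empty manifest")
  list(total_runs = sum(rows$n_runs),
       cumulative_time_ns = sum(rows$n_runs * rows$run_ns))
}
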