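## Shared data model: atoms, structures, trajectories, selections.

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL", "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN")

WATER3 <- c("HOH", "WAT", "TIP", "TIP3", "SPC", "H2O")

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT",
                    "H", "H1", "H2", "H3", "HA", "HA2", "HA3", "HN")

is_amino <- function(resname) toupper(resname) %in% AMINO3
is_water <- function(resname) toupper(resname) %in% WATER3

infer_element <- function(name, resname = "") {
  nm <- gsub("[^A-Za-z]", "", name)
  up <- toupper(nm)
  if (nchar(up) == 0) return("X")
  two <- substr(up, 1, 2)
  if (two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "CA", "MN", "CU") &&
      !is_amino(resname)) return(two)
  if (grepl("^[0-9]*H", toupper(name))) return("H")
  substr(up, 1, 1)
}

classify_atom <- function(name, resname) {
  if (!is_amino(resname)) return("hetero")
  nm <- toupper(trimws(name))
  if (nm == "CA") return("calpha")
  if (nm %in% BACKBONE_NAMES) return("backbone")
  "sidechain"
}

#' Build a structure model from an atom table and coordinates
#'
#' The structure model is the topology every analysis selects against:
#' an ordered atom table, a residue table assembled from contiguous
#' (chain, residue label) runs, and named atom groups (e.g. \code{"enzyme"},
#' \code{"cnt"}). Internal residue indices are 0-based and contiguous;
#' the original residue numbers survive as labels so that literature-style
#' residue names (Gly100, Ser125) keep their meaning.
#'
#' @param atoms data.frame with columns \code{serial}, \code{name},
#'   \code{resname}, \code{resno} (residue label, integer), \code{chain};
#'   optional \code{element} (inferred from the atom name when absent).
#' @param coords numeric matrix, one row of x/y/z (\enc{Å}{Angstrom}) per atom.
#' @param groups named list of integer atom-index vectors.
#' @return An object of class \code{structure_model}.
#' @export
structure_model <- function(atoms, coords, groups = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(atoms) == 0L) stopf("empty structure: zero atoms")
  if (nrow(coords) != nrow(atoms) || ncol(coords) != 3L)
    stopf("coords must be a %d x 3 matrix", nrow(atoms))
  if (!all(is.finite(coords)))
    stopf("non-finite coordinates at atom %d",
          which(!apply(is.finite(coords), 1, all))[1])
  need <- c("serial", "name", "resname", "resno", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atom table lacks columns: %s",
                          paste(miss, collapse = ", "))
  atoms$name <- trimws(as.character(atoms$name))
  atoms$resname <- trimws(as.character(atoms$resname))
  atoms$chain <- as.character(atoms$chain)
  if (is.null(atoms$element) || all(is.na(atoms$element)) ||
      all(atoms$element == ""))
    atoms$element <- mapply(infer_element, atoms$name, atoms$resname)
  atoms$element <- trimws(toupper(as.character(atoms$element)))
  blank <- atoms$element == "" | is.na(atoms$element)
  if (any(blank))
    atoms$element[blank] <- mapply(infer_element, atoms$name[blank],
                                   atoms$resname[blank])
  atoms$is_hydrogen <- atoms$element == "H"
  atoms$atom_class <- mapply(classify_atom, atoms$name, atoms$resname)

  key <- paste(atoms$chain, atoms$resno, atoms$resname)
  run <- c(TRUE, key[-1] != key[-length(key)])
  atoms$residue_index <- cumsum(run) - 1L
  first <- which(run)
  last <- c(first[-1] - 1L, nrow(atoms))
  residues <- data.frame(
    residue_index = atoms$residue_index[first],
    resname = atoms$resname[first],
    label = atoms$resno[first],
    chain = atoms$chain[first],
    first = first, last = last,
    stringsAsFactors = FALSE)
  residues$is_amino <- is_amino(residues$resname)
  residues$is_water <- is_water(residues$resname)

  model <- structure(list(atoms = atoms, coords = coords,
                          residues = residues, groups = list()),
                     class = "structure_model")
  for (g in names(groups)) model <- set_group(model, g, groups[[g]])
  model
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d residues (%d amino, %d water)\n",
              nrow(x$atoms), nrow(x$residues), sum(x$residues$is_amino),
              sum(x$residues$is_water)))
  if (length(x$groups))
    cat("  groups:", paste(sprintf("%s[%d]", names(x$groups),
                                   lengths(x$groups)), collapse = " "), "\n")
  invisible(x)
}

n_atoms <- function(model) nrow(model$atoms)

#' Define a named atom group on a structure model
#'
#' @param model structure_model.
#' @param name group name.
#' @param indices integer atom indices (1-based); must be nonempty and valid.
#' @return The updated model.
#' @export
set_group <- function(model, name, indices) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) == 0L) stopf("group '%s' resolves to no atoms", name)
  if (any(indices < 1L | indices > n_atoms(model)))
    stopf("group '%s' has out-of-range atom indices", name)
  model$groups[[name]] <- indices
  model
}

#' Atom indices of a residue (by internal 0-based index)
#' @noRd
residue_atom_indices <- function(model, residue_index) {
  r <- model$residues[model$residues$residue_index == residue_index, ]
  if (nrow(r) == 0L) stopf("unknown residue index %s", residue_index)
  seq.int(r$first, r$last)
}

#' Bind coordinate frames to a structure model
#'
#' @param model structure_model.
#' @param frames list of n_atoms x 3 coordinate matrices (\enc{Å}{Angstrom}).
#' @param frame_interval time between frames, ps (> 0).
#' @return An object of class \code{trajectory}.
#' @export
trajectory <- function(model, frames, frame_interval = 2) {
  if (!inherits(model, "structure_model")) stopf("model must be a structure_model")
  if (!is.list(frames) || length(frames) == 0L) stopf("frames must be a nonempty list")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f); storage.mode(f) <- "double"; f
  })
  ok <- vapply(frames, function(f)
    nrow(f) == n_atoms(model) && ncol(f) == 3L && all(is.finite(f)), TRUE)
  if (!all(ok)) stopf("frame %d does not match the %d-atom topology",
                      which(!ok)[1], n_atoms(model))
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stopf("frame_interval must be > 0 ps")
  structure(list(model = model, frames = frames,
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, %.3g ps/frame\n",
              length(x$frames), n_atoms(x$model), x$frame_interval))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

frame_times <- function(traj) (seq_len(n_frames(traj)) - 1) * traj$frame_interval

#' Frame indices of the trailing analysis window
#'
#' Production analyses (correlation matrices, network paths) are run on the
#' equilibrated tail of a trajectory; the default window is the last 10
#' percent of frames (at least 2).
#' @param traj trajectory.
#' @param fraction trailing fraction of frames to keep, in (0, 1].
#' @return Integer frame indices.
#' @export
window_frames <- function(traj, fraction = 0.1) {
  nf <- n_frames(traj)
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stopf("fraction must be in (0, 1]")
  k <- max(2L, min(nf, ceiling(nf * fraction)))
  seq.int(nf - k + 1L, nf)
}
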