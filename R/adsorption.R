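## Enzyme-nanotube adsorption metrics: adsorbed-atom counts, per-frame
## contact areas, and solvent spatial-density grids.

#' Count adsorbed atoms in one frame
#'
#' An atom is adsorbed when its minimum distance to any surface atom is at
#' most \code{cutoff}; hydrogens are excluded by default (the 6
#' \enc{Å}{Angstrom} heavy-atom criterion commonly used for hydrophobic
#' contact).
#'
#' @param model structure_model.
#' @param coords frame coordinates (n_atoms x 3); default model coords.
#' @param protein_selection,surface_selection selections.
#' @param cutoff distance criterion, \enc{Å}{Angstrom} (default 6.0).
#' @param heavy_only exclude hydrogens from the count (default TRUE).
#' @return Integer count.
#' @export
count_adsorbed <- function(model, coords = NULL,
                           protein_selection = "group:enzyme",
                           surface_selection = "group:cnt",
                           cutoff = 6.0, heavy_only = TRUE) {
  ip <- resolve_selection(model, protein_selection)
  is <- resolve_selection(model, surface_selection)
  if (heavy_only) ip <- ip[!model$atoms$is_hydrogen[ip]]
  if (length(ip) == 0L) return(0L)
  xyz <- coords %||% model$coords
  d2 <- cross_dist2(xyz[ip, , drop = FALSE], xyz[is, , drop = FALSE])
  sum(apply(d2, 1, min) <= cutoff^2)
}

#' Per-frame adsorption metrics over a trajectory
#'
#' @param traj trajectory.
#' @param protein_selection,surface_selection selections.
#' @param cutoff adsorption criterion, \enc{Å}{Angstrom}.
#' @param probe SASA probe radius for the contact area.
#' @param radii_map element radius table.
#' @param n_points SASA quadrature points.
#' @param contact logical: also compute per-frame contact areas (SASA-based,
#'   slower); when FALSE the \code{contact_areas} field is \code{NA}.
#' @param heavy_only exclude hydrogens from counts.
#' @return \code{adsorption_series}: \code{times} (ps),
#'   \code{adsorbed_counts}, \code{contact_areas}
#'   (\enc{Å}{Angstrom}^2), \code{cutoff}.
#' @export
adsorption_series <- function(traj, protein_selection = "group:enzyme",
                              surface_selection = "group:cnt",
                              cutoff = 6.0, probe = 1.4,
                              radii_map = default_radii(), n_points = 240,
                              contact = TRUE, heavy_only = TRUE) {
  counts <- integer(n_frames(traj))
  areas <- rep(NA_real_, n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$frames[[f]]
    counts[f] <- count_adsorbed(traj$model, xyz, protein_selection,
                                surface_selection, cutoff, heavy_only)
    if (contact)
      areas[f] <- contact_area(traj$model, protein_selection,
                               surface_selection, probe, radii_map,
                               n_points, coords = xyz)
  }
  structure(list(times = frame_times(traj), adsorbed_counts = counts,
                 contact_areas = areas, cutoff = cutoff),
            class = "adsorption_series")
}

#' Spatial probability density grid of selected atoms
#'
#' Each used frame is least-squares superposed onto the reference (the
#' first used frame) over \code{fit_selection}, then the positions of
#' \code{target_selection} atoms are binned into cubic voxels
#' (default (0.5 \enc{Å}{Angstrom})^3).
#'
#' @param traj trajectory.
#' @param target_selection atoms to bin (e.g. solvent).
#' @param fit_selection atoms used for the superposition (e.g. all enzyme
#'   atoms).
#' @param voxel voxel edge, \enc{Å}{Angstrom} (default 0.5).
#' @param stride_ps time between used frames, ps; must be a multiple of
#'   the trajectory frame interval.
#' @param normalization \code{"counts"} or \code{"probability"}.
#' @return \code{density_grid}: \code{origin}, \code{voxel}, \code{counts}
#'   (3-D array), \code{normalization}, \code{n_observations}.
#' @export
density_grid <- function(traj, target_selection, fit_selection,
                         voxel = 0.5, stride_ps = NULL,
                         normalization = c("counts", "probability")) {
  normalization <- match.arg(normalization)
  if (voxel <= 0) stopf("voxel must be > 0")
  stride_ps <- stride_ps %||% traj$frame_interval
  step <- stride_ps / traj$frame_interval
  if (abs(step - round(step)) > 1e-9 || round(step) < 1)
    stopf("stride_ps (%g) is not a multiple of the frame interval (%g ps)",
          stride_ps, traj$frame_interval)
  use <- seq(1L, n_frames(traj), by = as.integer(round(step)))
  it <- resolve_selection(traj$model, target_selection)
  if_ <- resolve_selection(traj$model, fit_selection)

  ref <- traj$frames[[use[1]]][if_, , drop = FALSE]
  pos <- vector("list", length(use))
  for (k in seq_along(use)) {
    xyz <- traj$frames[[use[k]]]
    sp <- superpose(xyz[if_, , drop = FALSE], ref)
    fitted <- sweep(xyz %*% sp$rotation, 2, sp$translation, `+`)
    pos[[k]] <- fitted[it, , drop = FALSE]
  }
  all_pos <- do.call(rbind, pos)
  origin <- floor(apply(all_pos, 2, min) / voxel) * voxel
  ijk <- floor(sweep(all_pos, 2, origin, `-`) / voxel) + 1L
  dims <- apply(ijk, 2, max)
  counts <- array(0L, dim = dims)
  lin <- ijk[, 1] + dims[1] * (ijk[, 2] - 1L) +
    dims[1] * dims[2] * (ijk[, 3] - 1L)
  tab <- tabulate(lin, nbins = prod(dims))
  counts[] <- tab
  vals <- if (normalization == "probability") counts / sum(counts) else counts
  structure(list(origin = origin, voxel = voxel, counts = vals,
                 normalization = normalization,
                 n_observations = nrow(all_pos)),
            class = "density_grid")
}

#' Write a density grid as a flat TSV (i, j, k, value)
#' @param grid density_grid.
#' @param path output file.
#' @param keep_zero include empty voxels (default FALSE).
#' @return \code{path}, invisibly.
#' @export
write_density_grid <- function(grid, path, keep_zero = FALSE) {
  idx <- which(grid$counts != 0 | keep_zero, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                   value = grid$counts[idx])
  write_table(df, path)
}
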