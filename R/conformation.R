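## Rigid-body superposition (Kabsch), RMSD/RMSF series and the
## binding-pocket inter-strand distance distribution.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing the (weighted)
#' RMSD of \code{mobile \%*\% R + t} from \code{ref}. Reflections are
#' excluded by construction.
#'
#' @param mobile,ref n x 3 coordinate matrices, n >= 3, non-collinear.
#' @param weights optional non-negative per-atom weights.
#' @return List of class \code{superposition}: \code{rotation} (3 x 3,
#'   det +1), \code{translation} (length 3), \code{rmsd}
#'   (\enc{Å}{Angstrom}).
#' @export
superpose <- function(mobile, ref, weights = NULL) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  n <- nrow(mobile)
  if (n != nrow(ref)) stopf("coordinate sets differ in atom count")
  if (n < 3L) stopf("degenerate geometry: need >= 3 atoms")
  w <- weights %||% rep(1, n)
  if (any(w < 0) || sum(w) <= 0) stopf("weights must be non-negative")
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(ref * w)
  Xm <- sweep(mobile, 2, cm); Xr <- sweep(ref, 2, cr)
  A <- crossprod(Xm * w, Xr)
  sv <- svd(A)
  if (sv$d[2] < 1e-12)
    stopf("degenerate geometry: rank-deficient coordinates")
  s <- sign(det(tcrossprod(sv$u, sv$v)))
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  t_ <- cr - as.vector(cm %*% R)
  moved <- Xm %*% R
  rmsd <- sqrt(sum(w * rowSums((moved - Xr)^2)))
  structure(list(rotation = R, translation = t_, rmsd = rmsd),
            class = "superposition")
}

apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% sp$rotation, 2, sp$translation, `+`)
}

#' Per-frame RMSD from a reference structure
#'
#' Each frame is superposed on the reference over \code{selection}, then
#' the RMSD is measured over the same selection. The default reference is
#' the trajectory's topology coordinates (the crystal structure when the
#' model was read from one).
#'
#' @param traj trajectory.
#' @param selection selection expression (default \code{"calpha"};
#'   \code{"backbone and heavy"} mirrors backbone-atom RMSD).
#' @param reference n_atoms x 3 matrix or a structure_model; default the
#'   trajectory model's coordinates.
#' @return Numeric vector of per-frame RMSD, \enc{Å}{Angstrom}, with frame
#'   times (ps) as names.
#' @export
rmsd_series <- function(traj, selection = "calpha", reference = NULL) {
  idx <- resolve_selection(traj$model, selection)
  ref <- reference %||% traj$model$coords
  if (inherits(ref, "structure_model")) ref <- ref$coords
  if (nrow(ref) != n_atoms(traj$model))
    stopf("reference does not match the trajectory topology")
  refc <- ref[idx, , drop = FALSE]
  out <- vapply(traj$frames, function(f)
    superpose(f[idx, , drop = FALSE], refc)$rmsd, 0)
  names(out) <- frame_times(traj)
  out
}

#' Root-mean-square fluctuation about the time-mean structure
#'
#' Frames are iteratively superposed on the running mean structure over
#' \code{fit_selection} (3 iterations from a first-frame reference), then
#' the per-atom fluctuation about the converged mean is computed over
#' \code{selection}. With \code{per_residue = TRUE} the residue value is
#' the RMSF of its C-alpha atom.
#'
#' @param traj trajectory with >= 2 frames.
#' @param selection atoms to report (default \code{"calpha"}).
#' @param fit_selection atoms used for the superposition (default the
#'   report selection).
#' @param per_residue name the result by residue label via the C-alpha
#'   (default TRUE when selection is \code{"calpha"}).
#' @return Named numeric vector of RMSF, \enc{Å}{Angstrom}.
#' @export
rmsf <- function(traj, selection = "calpha", fit_selection = selection,
                 per_residue = identical(selection, "calpha")) {
  if (n_frames(traj) < 2L)
    stopf("fluctuations undefined for a single-frame trajectory")
  idx <- resolve_selection(traj$model, selection)
  fidx <- resolve_selection(traj$model, fit_selection)
  frames <- traj$frames
  ref <- frames[[1]][fidx, , drop = FALSE]
  for (it in 1:3) {
    frames <- lapply(frames, function(f)
      apply_superposition(f, superpose(f[fidx, , drop = FALSE], ref)))
    mean_all <- Reduce(`+`, frames) / length(frames)
    ref <- mean_all[fidx, , drop = FALSE]
  }
  sel <- lapply(frames, function(f) f[idx, , drop = FALSE])
  mean_sel <- Reduce(`+`, sel) / length(sel)
  msf <- Reduce(`+`, lapply(sel, function(f)
    rowSums((f - mean_sel)^2))) / length(sel)
  out <- sqrt(msf)
  names(out) <- if (per_residue) {
    ri <- traj$model$atoms$residue_index[idx]
    rr <- traj$model$residues
    paste0(rr$resname[match(ri, rr$residue_index)],
           rr$label[match(ri, rr$residue_index)])
  } else traj$model$atoms$name[idx]
  out
}

#' Inter-strand distance distribution
#'
#' Per-frame distance between two residue segments (by default the
#' geometric centers of their heavy backbone atoms), histogrammed in
#' 0.5-\enc{Å}{Angstrom} bins. Alternative modes: minimum heavy-atom
#' distance and C-alpha centroid distance.
#'
#' @param traj trajectory.
#' @param strand_a,strand_b selections for the two segments (defaults are
#'   the subtilisin binding-pocket strands, residues 100-103 and 125-128).
#' @param mode \code{"backbone_center"}, \code{"min_heavy"} or
#'   \code{"calpha_center"}.
#' @param bin_width histogram bin width, \enc{Å}{Angstrom}.
#' @return \code{distance_distribution}: \code{per_frame_distance},
#'   \code{breaks}, \code{counts} (summing to the frame count),
#'   \code{mode}.
#' @export
strand_distance <- function(traj,
                            strand_a = "residues 100-103",
                            strand_b = "residues 125-128",
                            mode = c("backbone_center", "min_heavy",
                                     "calpha_center"),
                            bin_width = 0.5) {
  mode <- match.arg(mode)
  model <- traj$model
  sub_sel <- switch(mode,
                    backbone_center = "backbone and heavy",
                    min_heavy = "heavy",
                    calpha_center = "calpha")
  ia <- intersect(resolve_selection(model, strand_a),
                  resolve_selection(model, sub_sel))
  ib <- intersect(resolve_selection(model, strand_b),
                  resolve_selection(model, sub_sel))
  if (!length(ia) || !length(ib))
    stopf("strand selection resolves to no atoms under mode '%s'", mode)
  d <- vapply(traj$frames, function(f) {
    a <- f[ia, , drop = FALSE]; b <- f[ib, , drop = FALSE]
    if (mode == "min_heavy") sqrt(min(cross_dist2(a, b)))
    else sqrt(sum((colMeans(a) - colMeans(b))^2))
  }, 0)
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- hist(d, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  structure(list(per_frame_distance = d, breaks = h$breaks,
                 counts = h$counts, mode = mode),
            class = "distance_distribution")
}
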