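## Shrake-Rupley solvent-accessible surface area on a deterministic
## Fibonacci sphere, and the buried contact area between two groups.

#' Default element radii (\enc{Å}{Angstrom})
#'
#' Bondi-style van der Waals radii used for SASA when no custom table is
#' supplied; CNT carbon uses the same C radius.
#' @return Named numeric vector.
#' @export
default_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
}

atom_radii <- function(model, indices, radii_map) {
  el <- model$atoms$element[indices]
  r <- unname(radii_map[el])
  if (anyNA(r)) {
    missing <- unique(el[is.na(r)])
    stopf("no radius for element(s): %s", paste(missing, collapse = ", "))
  }
  r
}

## Deterministic molecule-fixed frame (principal axes with canonical
## signs from the third moment), so the quadrature lattice rotates with
## the system and SASA is invariant under rigid motion.
principal_frame <- function(coords) {
  n <- nrow(coords)
  if (n < 2L) return(diag(3))
  Xc <- sweep(coords, 2, colMeans(coords))
  V <- eigen(crossprod(Xc) / n, symmetric = TRUE)$vectors
  for (k in 1:2) {
    s <- sum((Xc %*% V[, k])^3)
    if (abs(s) > 1e-9 && s < 0) V[, k] <- -V[, k]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  V
}

sasa_points <- function(coords, radii, probe, n_points, frame = NULL) {
  ## per-atom exposed fraction of the Fibonacci test sphere, laid out in
  ## the molecule-fixed principal frame
  sph <- fibonacci_sphere(n_points) %*% t(frame %||% principal_frame(coords))
  n <- nrow(coords)
  rr <- radii + probe
  area <- numeric(n)
  d2 <- cross_dist2(coords, coords)
  for (i in seq_len(n)) {
    cut2 <- (rr[i] + rr)^2
    nb <- which(d2[i, ] < cut2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      area[i] <- 4 * pi * rr[i]^2
      next
    }
    pts <- sweep(sph * rr[i], 2, coords[i, ], `+`)
    pd2 <- cross_dist2(pts, coords[nb, , drop = FALSE])
    buried <- rowSums(pd2 < matrix(rr[nb]^2, nrow(pts), length(nb),
                                   byrow = TRUE)) > 0
    area[i] <- (sum(!buried) / n_points) * 4 * pi * rr[i]^2
  }
  area
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom area is the exposed fraction of a deterministic Fibonacci
#' point lattice on the probe-expanded sphere, times
#' \code{4 * pi * (r + probe)^2}. The point set is fixed, so results are
#' exactly reproducible.
#'
#' @param model structure_model (or an n x 3 coordinate matrix, in which
#'   case \code{radii_map} must be a per-atom radius vector).
#' @param selection selection expression or atom indices (default all).
#' @param radii_map named element-to-radius vector
#'   (default \code{\link{default_radii}}), or per-atom radii when
#'   \code{model} is a bare matrix.
#' @param probe probe radius, \enc{Å}{Angstrom} (default 1.4).
#' @param n_points quadrature points per atom (default 960).
#' @param coords optional n_atoms x 3 matrix overriding the model
#'   coordinates (e.g. one trajectory frame).
#' @param frame optional 3 x 3 orientation matrix for the quadrature
#'   lattice; by default the selection's own principal-axes frame.
#'   Difference calculations (buried areas) share one frame across their
#'   component calls so quadrature orientation cancels exactly.
#' @return List of class \code{sasa_result}: \code{per_atom_area},
#'   \code{total}, \code{probe_radius}, \code{n_sphere_points},
#'   \code{indices}.
#' @export
sasa <- function(model, selection = "all", radii_map = default_radii(),
                 probe = 1.4, n_points = 960, coords = NULL,
                 frame = NULL) {
  if (probe < 0) stopf("probe radius must be >= 0")
  if (is.matrix(model) && !inherits(model, "structure_model")) {
    xyz <- model
    idx <- seq_len(nrow(xyz))
    radii <- rep_len(radii_map, nrow(xyz))
  } else {
    idx <- resolve_selection(model, selection)
    xyz <- (coords %||% model$coords)[idx, , drop = FALSE]
    radii <- atom_radii(model, idx, radii_map)
  }
  per_atom <- sasa_points(xyz, radii, probe, n_points, frame)
  structure(list(per_atom_area = per_atom, total = sum(per_atom),
                 probe_radius = probe, n_sphere_points = n_points,
                 indices = idx),
            class = "sasa_result")
}

#' Contact (buried) area between two atom groups
#'
#' Computed from component SASAs:
#' \code{(SAS_a + SAS_b - SAS_complex) / 2} by default (the standard
#' buried-surface convention); with \code{halved = FALSE} the full buried
#' area \code{SAS_a + SAS_b - SAS_complex} is returned. Small negative
#' quadrature residues are clamped to zero.
#'
#' @param model structure_model.
#' @param group_a,group_b disjoint selections.
#' @param probe probe radius, \enc{Å}{Angstrom}.
#' @param radii_map element radius table.
#' @param n_points quadrature points per atom.
#' @param halved logical; see Description.
#' @param coords optional frame coordinates overriding the model's.
#' @return Contact area, \enc{Å}{Angstrom}^2.
#' @export
contact_area <- function(model, group_a, group_b, probe = 1.4,
                         radii_map = default_radii(), n_points = 960,
                         halved = TRUE, coords = NULL) {
  ia <- resolve_selection(model, group_a)
  ib <- resolve_selection(model, group_b)
  if (length(intersect(ia, ib)))
    stopf("groups overlap (%d shared atoms)", length(intersect(ia, ib)))
  xyz <- coords %||% model$coords
  ra <- atom_radii(model, ia, radii_map)
  rb <- atom_radii(model, ib, radii_map)
  V <- principal_frame(xyz[c(ia, ib), , drop = FALSE])
  sa <- sum(sasa_points(xyz[ia, , drop = FALSE], ra, probe, n_points, V))
  sb <- sum(sasa_points(xyz[ib, , drop = FALSE], rb, probe, n_points, V))
  sab <- sum(sasa_points(xyz[c(ia, ib), , drop = FALSE], c(ra, rb),
                         probe, n_points, V))
  buried <- max(sa + sb - sab, 0)
  if (halved) buried / 2 else buried
}
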