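## Armchair single-walled carbon-nanotube coordinate generator.
##
## Rolling convention: graphene bond length is preserved along the sheet
## before rolling, so after rolling onto the cylinder the chord C-C
## distances are slightly shorter than the nominal bond length. This is
## the convention of standard nanotube builders and reproduces both the
## analytic diameter d = sqrt(3) * b * sqrt(n^2 + n*m + m^2) / pi and the
## 4n atoms-per-cell count simultaneously.

#' Specify an armchair nanotube
#'
#' @param n,m chirality indices; only armchair tubes (n = m) are supported.
#' @param bond_length graphene C-C bond length, \enc{Å}{Angstrom}
#'   (default 1.42).
#' @param n_cells number of translational unit cells (each contributes
#'   4n atoms and \code{sqrt(3) * bond_length} of tube length).
#' @param target_length alternative to \code{n_cells}: tube length in
#'   \enc{Å}{Angstrom}; the cell count is \code{round(target_length /
#'   (sqrt(3) * bond_length))}. Exactly one of the two must be given.
#' @return An object of class \code{cnt_spec}.
#' @export
cnt_spec <- function(n, m = n, bond_length = 1.42,
                     n_cells = NULL, target_length = NULL) {
  if (n != m) stopf("unsupported chirality (%d,%d): only armchair n = m", n, m)
  if (!is_count(n)) stopf("n must be a positive integer")
  if (!is.finite(bond_length) || bond_length <= 0)
    stopf("bond_length must be > 0")
  if (is.null(n_cells) == is.null(target_length))
    stopf("give exactly one of n_cells / target_length")
  if (!is.null(target_length)) {
    if (!is.finite(target_length) || target_length <= 0)
      stopf("target_length must be > 0")
    n_cells <- round(target_length / (sqrt(3) * bond_length))
    if (n_cells < 1) stopf("target_length shorter than one unit cell")
  }
  if (!is_count(n_cells)) stopf("n_cells must be a positive integer")
  structure(list(n = as.integer(n), m = as.integer(m),
                 bond_length = bond_length, n_cells = as.integer(n_cells)),
            class = "cnt_spec")
}

#' Analytic diameter of a rolled-graphene (n,m) tube
#' @param n,m chirality indices.
#' @param bond_length C-C bond length, \enc{Å}{Angstrom}.
#' @return Diameter in \enc{Å}{Angstrom}.
#' @export
cnt_diameter <- function(n, m = n, bond_length = 1.42) {
  sqrt(3) * bond_length * sqrt(n^2 + n * m + m^2) / pi
}

#' Build armchair nanotube coordinates
#'
#' Atoms lie exactly on a cylinder of the analytic diameter, axis along z,
#' centered on the origin. Each translational cell contributes two rings
#' of 2n atoms; total atoms = 4 n n_cells. Carbons carry residue name
#' \code{"CNT"} (hetero class, zero formal charge in downstream energy
#' models).
#'
#' @param spec a \code{\link{cnt_spec}}.
#' @return \code{structure_model} with a \code{"cnt"} group.
#' @export
build_cnt <- function(spec) {
  stopifnot(inherits(spec, "cnt_spec"))
  n <- spec$n; b <- spec$bond_length; nc <- spec$n_cells
  R <- cnt_diameter(n, n, b) / 2          # circumference = 3 b n
  period <- sqrt(3) * b                   # translational period along z
  k <- seq_len(n) - 1                     # hexagon index around the tube

  ## arc-length positions of the two ring patterns (preserved sheet metric)
  arc_even <- c(3 * b * k, 3 * b * k + b)         # rows at z = 0 mod period
  arc_odd  <- c(3 * b * k + 1.5 * b, 3 * b * k + 2.5 * b)

  rows <- seq_len(2L * nc) - 1L
  coords <- do.call(rbind, lapply(rows, function(j) {
    arc <- if (j %% 2L == 0L) arc_even else arc_odd
    theta <- sort(arc) / R
    cbind(R * cos(theta), R * sin(theta), j * period / 2)
  }))
  coords[, 3] <- coords[, 3] - mean(range(coords[, 3]))

  natoms <- nrow(coords)
  atoms <- data.frame(serial = seq_len(natoms), name = "C", resname = "CNT",
                      resno = 1L, chain = "X", element = "C",
                      stringsAsFactors = FALSE)
  model <- structure_model(atoms, coords)
  set_group(model, "cnt", seq_len(natoms))
}

#' Geometry report for a built nanotube
#'
#' @param model structure_model from \code{\link{build_cnt}}.
#' @param spec the \code{cnt_spec} used to build it.
#' @return List: \code{radius} (mean), \code{radius_spread} (max - min
#'   radial distance), \code{diameter_analytic}, \code{nn_dist} (summary of
#'   nearest-neighbor distances), \code{neighbor_counts} (table of
#'   within-1.6-\enc{Å}{Angstrom} neighbor counts), \code{length} (z extent).
#' @export
check_geometry <- function(model, spec) {
  xy <- model$coords[, 1:2]
  rad <- sqrt(rowSums(xy^2))
  d2 <- cross_dist2(model$coords, model$coords)
  diag(d2) <- Inf
  nn <- sqrt(apply(d2, 1, min))
  ncount <- rowSums(d2 <= 1.6^2)
  list(radius = mean(rad),
       radius_spread = max(rad) - min(rad),
       diameter_analytic = cnt_diameter(spec$n, spec$m, spec$bond_length),
       nn_dist = summary(nn),
       neighbor_counts = table(ncount),
       length = diff(range(model$coords[, 3])))
}
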