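## PDB reading/writing (bio3d backend) mapped onto the package data model.

#' Read a PDB file into a structure model (and trajectory when multi-model)
#'
#' Atoms are kept in file order; residues are assembled by
#' (chain, resSeq, insertion code); waters and other non-amino records are
#' flagged hetero. The element is taken from the element column when
#' present, otherwise inferred from the atom name. Where alternate
#' locations are present only the highest-occupancy conformer is kept.
#' Multi-model files (MODEL/ENDMDL) become a \code{\link{trajectory}} whose
#' topology is the first model.
#'
#' @param path PDB file path.
#' @param frame_interval time between models in ps, used when the file is
#'   multi-model (default 2 ps).
#' @return A \code{structure_model}; for multi-model files a
#'   \code{trajectory} (its model is accessible as \code{$model}).
#' @export
read_pdb <- function(path, frame_interval = 2) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stopf("PDB parse error in %s: %s",
                              path, conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stopf("empty PDB: zero atoms in %s", path)
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad))
    stopf("malformed coordinate field at atom record %d (serial %s) of %s",
          bad[1], at$eleno[bad[1]], path)

  xyz <- pdb$xyz
  nmod <- if (is.matrix(xyz)) nrow(xyz) else 1L

  ## keep highest-occupancy altLoc per (chain, resno, insert, atom name)
  keep <- seq_len(nrow(at))
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    ord <- order(key, -occ, seq_along(key))
    keep <- sort(ord[!duplicated(key[ord])])
  }
  at <- at[keep, , drop = FALSE]

  chain <- at$chain
  chain[is.na(chain)] <- "A"
  atoms <- data.frame(serial = at$eleno, name = at$elety,
                      resname = at$resid, resno = at$resno,
                      chain = chain,
                      element = if (!is.null(at$elesy)) at$elesy else NA,
                      stringsAsFactors = FALSE)
  coords1 <- cbind(at$x, at$y, at$z)
  model <- structure_model(atoms, coords1)
  ## default groups: enzyme = amino-acid atoms (crystal waters excluded),
  ## cnt = CNT residue atoms, when present
  prot <- which(model$residues$is_amino[match(model$atoms$residue_index,
                                              model$residues$residue_index)])
  if (length(prot)) model <- set_group(model, "enzyme", prot)
  cnt <- which(toupper(model$atoms$resname) == "CNT")
  if (length(cnt)) model <- set_group(model, "cnt", cnt)

  if (nmod > 1L) {
    xyzk <- xyz[, as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep)),
                drop = FALSE]
    frames <- lapply(seq_len(nmod), function(i)
      matrix(xyzk[i, ], ncol = 3, byrow = TRUE))
    return(trajectory(model, frames, frame_interval))
  }
  model
}

#' Write a structure model or trajectory as PDB
#'
#' Trajectories are written as multi-model PDB (MODEL/ENDMDL), the text
#' trajectory format every analysis in the package accepts.
#'
#' @param x structure_model or trajectory.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "trajectory")) {
    model <- x$model
    xyz <- do.call(rbind, lapply(x$frames, function(f) as.vector(t(f))))
  } else if (inherits(x, "structure_model")) {
    model <- x
    xyz <- matrix(as.vector(t(model$coords)), nrow = 1)
  } else stopf("x must be a structure_model or trajectory")
  at <- model$atoms
  hetero <- at$atom_class == "hetero"
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(hetero, "HETATM", "ATOM"),
                   eleno = at$serial, elety = at$name, resid = at$resname,
                   chain = at$chain, resno = at$resno,
                   elesy = at$element)
  invisible(path)
}

#' Download a PDB entry from the RCSB (requires network access)
#'
#' @param id 4-character PDB identifier, e.g. \code{"3UNX"}.
#' @param path destination file (default \code{<id>.pdb} in the working
#'   directory).
#' @return The downloaded file path.
#' @export
fetch_pdb <- function(id, path = paste0(toupper(id), ".pdb")) {
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
  status <- tryCatch(utils::download.file(url, path, quiet = TRUE, mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L)) stopf("could not download %s (network?)", url)
  path
}

#' Count amino-acid residues and water molecules in a structure
#'
#' @param model structure_model.
#' @return Named list with \code{n_amino}, \code{n_water}, \code{n_hetero}.
#' @export
residue_census <- function(model) {
  r <- model$residues
  list(n_amino = sum(r$is_amino), n_water = sum(r$is_water),
       n_hetero = sum(!r$is_amino & !r$is_water))
}
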