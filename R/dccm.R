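## Dynamical cross-correlation matrix of C-alpha positional fluctuations:
## C(i,j) = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>), with dr the
## deviation from the time-mean position after optional iterated
## superposition onto the mean structure.

#' Dynamical cross-correlation matrix (DCCM)
#'
#' @param traj trajectory with >= 2 frames.
#' @param selection one atom per residue (default \code{"calpha"}); >= 2
#'   atoms required.
#' @param fit superpose each frame on the mean structure first (3
#'   fit-to-mean iterations from a first-frame reference). Default TRUE;
#'   disable for pre-aligned or purely synthetic displacement data.
#' @param window frame indices to use (default all; see
#'   \code{\link{window_frames}} for the trailing-window convention).
#' @return Object of class \code{correlation_matrix}: \code{values}
#'   (symmetric, unit diagonal, entries in [-1, 1]), \code{labels},
#'   \code{cutoff}, \code{cutoff_mask} (NULL until a cutoff is applied),
#'   \code{window}.
#' @export
dccm_matrix <- function(traj, selection = "calpha", fit = TRUE,
                        window = NULL) {
  window <- window %||% seq_len(n_frames(traj))
  if (length(window) < 2L) stopf("need >= 2 frames for a DCCM")
  idx <- resolve_selection(traj$model, selection)
  m <- length(idx)
  if (m < 2L) stopf("need >= 2 residues for a DCCM")
  frames <- traj$frames[window]
  if (fit && m >= 3L) {
    ref <- frames[[1]][idx, , drop = FALSE]
    for (it in 1:3) {
      frames <- lapply(frames, function(f)
        apply_superposition(f, superpose(f[idx, , drop = FALSE], ref)))
      ref <- Reduce(`+`, frames)[idx, , drop = FALSE] / length(frames)
    }
  }
  ## nf x 3m matrix of selected coordinates
  X <- do.call(rbind, lapply(frames, function(f) as.vector(t(f[idx, ]))))
  X <- sweep(X, 2, colMeans(X))
  nf <- nrow(X)
  ax <- seq(1, 3 * m, by = 3)
  dot <- (crossprod(X[, ax]) + crossprod(X[, ax + 1]) +
            crossprod(X[, ax + 2])) / nf
  v <- diag(dot)
  zero <- v <= .Machine$double.eps
  C <- matrix(0, m, m)
  nz <- which(!zero)
  if (length(nz))
    C[nz, nz] <- dot[nz, nz, drop = FALSE] /
      sqrt(outer(v[nz], v[nz]))
  if (any(zero)) {
    warnf("%d zero-variance residue(s); their off-diagonal correlations set to 0",
          sum(zero))
  }
  diag(C) <- 1
  C <- pmin(pmax((C + t(C)) / 2, -1), 1)
  ri <- traj$model$atoms$residue_index[idx]
  rr <- traj$model$residues
  labels <- paste0(rr$resname[match(ri, rr$residue_index)],
                   rr$label[match(ri, rr$residue_index)])
  dimnames(C) <- list(labels, labels)
  structure(list(values = C, labels = labels, cutoff = NULL,
                 cutoff_mask = NULL, window = window),
            class = "correlation_matrix")
}

#' Average correlation matrices and apply an absolute-value cutoff
#'
#' Element-wise unweighted mean; the cutoff mask marks entries with
#' \code{|mean| >= cutoff} (default 0.4). Also reports, per input matrix,
#' the consistency with the mean: the fraction of masked off-diagonal
#' entries whose sign agrees with the mean's.
#'
#' @param matrices list of \code{correlation_matrix} objects (or plain
#'   square matrices) sharing dimensions.
#' @param cutoff absolute-correlation threshold (default 0.4).
#' @return \code{correlation_matrix} with \code{cutoff_mask} and a
#'   \code{consistency} vector (one value per input).
#' @export
average_dccm <- function(matrices, cutoff = 0.4) {
  vals <- lapply(matrices, function(x)
    if (inherits(x, "correlation_matrix")) x$values else as.matrix(x))
  dims <- vapply(vals, function(v) paste(dim(v), collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    stopf("matrices differ in dimension: %s", paste(unique(dims), collapse = ", "))
  mean_mat <- Reduce(`+`, vals) / length(vals)
  mask <- abs(mean_mat) >= cutoff
  off <- mask; diag(off) <- FALSE
  consistency <- vapply(vals, function(v) {
    if (!any(off)) return(NA_real_)
    mean(sign(v[off]) == sign(mean_mat[off]))
  }, 0)
  labels <- if (inherits(matrices[[1]], "correlation_matrix"))
    matrices[[1]]$labels else rownames(mean_mat) %||%
      as.character(seq_len(nrow(mean_mat)))
  structure(list(values = mean_mat, labels = labels, cutoff = cutoff,
                 cutoff_mask = mask, consistency = consistency),
            class = "correlation_matrix")
}

#' Write a correlation matrix as a labelled square TSV, and its cutoff
#' mask as a sparse (i, j, value) table
#' @param corr correlation_matrix.
#' @param path matrix file; the sparse mask (when present) goes to
#'   \code{paste0(path, ".mask.tsv")}.
#' @return \code{path}, invisibly.
#' @export
write_dccm <- function(corr, path) {
  df <- as.data.frame(corr$values)
  names(df) <- corr$labels
  write_table(cbind(residue = corr$labels, df), path)
  if (!is.null(corr$cutoff_mask)) {
    idx <- which(corr$cutoff_mask & upper.tri(corr$cutoff_mask), arr.ind = TRUE)
    if (nrow(idx)) {
      write_table(data.frame(i = corr$labels[idx[, 1]],
                             j = corr$labels[idx[, 2]],
                             value = corr$values[idx]),
                  paste0(path, ".mask.tsv"))
    }
  }
  invisible(path)
}
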