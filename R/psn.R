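## Protein structure network: side-chain interaction strengths
## I_ij = 100 * n_ij / sqrt(N_i * N_j), per-frame networks, minimum-hop
## communication paths with a correlation filter, and path statistics.

#' Bundled residue normalization values for PSN interaction strengths
#'
#' Published per-residue-type normalization constants from the PSN
#' literature (derived from a large protein dataset); unknown residue
#' types fall back to \code{default_value}. Fully replaceable via
#' \code{\link{read_norm_table}}.
#'
#' @param default_value normalization for residue types not in the table
#'   (default 99.9).
#' @return Named numeric vector with a \code{default_value} attribute.
#' @export
psn_norm_table <- function(default_value = 99.9) {
  x <- c(ALA = 55.7551, ARG = 93.7891, ASN = 73.4097, ASP = 75.1507,
         CYS = 54.9528, GLN = 78.1301, GLU = 78.8288, GLY = 47.3129,
         HIS = 83.7357, ILE = 67.9452, LEU = 72.2517, LYS = 69.6096,
         MET = 69.2569, PHE = 93.3082, PRO = 51.3310, SER = 61.3946,
         THR = 63.7075, TRP = 106.7030, TYR = 100.7190, VAL = 62.3673)
  if (!is.finite(default_value) || default_value <= 0)
    stopf("default normalization must be > 0")
  attr(x, "default_value") <- default_value
  x
}

#' Read a residue normalization table from TSV
#' @param path TSV with columns \code{resname} and \code{N}.
#' @param default_value fallback for unknown residue types.
#' @return Named numeric vector as in \code{\link{psn_norm_table}}.
#' @export
read_norm_table <- function(path, default_value = 99.9) {
  df <- read_table(path)
  if (!all(c("resname", "N") %in% names(df)))
    stopf("normalization TSV needs columns 'resname' and 'N'")
  x <- as.numeric(df$N)
  names(x) <- toupper(df$resname)
  if (any(!is.finite(x) | x <= 0)) stopf("normalization values must be > 0")
  attr(x, "default_value") <- default_value
  x
}

norm_value <- function(norm_table, resname) {
  v <- unname(norm_table[toupper(resname)])
  v[is.na(v)] <- attr(norm_table, "default_value") %||% 99.9
  v
}

## Heavy side-chain atom indices per residue; glycine uses its C-alpha as
## proxy (standard PSN convention). HIS tautomer names map to HIS.
sidechain_indices <- function(model, residue_index) {
  idx <- residue_atom_indices(model, residue_index)
  at <- model$atoms[idx, ]
  sc <- idx[at$atom_class == "sidechain" & !at$is_hydrogen]
  if (length(sc) == 0L) sc <- idx[toupper(at$name) == "CA"]
  sc
}

#' Count side-chain heavy-atom pairs within a cutoff
#'
#' The PSN edge raw count: distinct (atom in side chain i, atom in side
#' chain j) heavy-atom pairs with distance <= cutoff. Glycine contributes
#' its C-alpha as side-chain proxy. Sequence-adjacent residues are the
#' caller's responsibility to exclude (covalent neighbors are not
#' non-covalent contacts).
#'
#' @param model structure_model.
#' @param res_i,res_j internal residue indices (0-based), distinct.
#' @param coords frame coordinates (default model coords).
#' @param cutoff distance cutoff, \enc{Å}{Angstrom} (default 5.0).
#' @return Integer pair count.
#' @export
count_sidechain_pairs <- function(model, res_i, res_j, coords = NULL,
                                  cutoff = 5.0) {
  if (res_i == res_j) stopf("residues must be distinct")
  xyz <- coords %||% model$coords
  ai <- sidechain_indices(model, res_i)
  aj <- sidechain_indices(model, res_j)
  if (!length(ai) || !length(aj)) return(0L)
  sum(cross_dist2(xyz[ai, , drop = FALSE], xyz[aj, , drop = FALSE]) <=
        cutoff^2)
}

#' PSN interaction strength
#'
#' \code{I_ij = 100 * n_ij / sqrt(N_i * N_j)} (percent), where n_ij is the
#' side-chain atom-pair count and N the residue-type normalization values.
#'
#' @param n_ij atom-pair count (>= 0).
#' @param N_i,N_j positive normalization values.
#' @return Interaction strength in percent.
#' @export
interaction_strength <- function(n_ij, N_i, N_j) {
  if (any(N_i <= 0) || any(N_j <= 0))
    stopf("normalization values must be > 0")
  100 * n_ij / sqrt(N_i * N_j)
}

#' Build the per-frame protein structure network
#'
#' Nodes are amino-acid residues; an edge joins residues i, j (sequence
#' separation > 1 on the same chain; covalent neighbors excluded) when
#' \code{I_ij >= i_min}. The CNT and other hetero residues are not nodes.
#'
#' @param model structure_model.
#' @param coords frame coordinates (default model coords).
#' @param norm_table normalization table
#'   (default \code{\link{psn_norm_table}()}).
#' @param cutoff atom-pair distance cutoff, \enc{Å}{Angstrom}
#'   (default 5.0).
#' @param i_min edge inclusion threshold, percent (default 3.0).
#' @param hub_degree degree at or above which a node is reported as a hub
#'   (default 4).
#' @return \code{interaction_network}: \code{nodes} (labels),
#'   \code{edges} (data.frame \code{i}, \code{j}, \code{n_pairs},
#'   \code{strength}), \code{i_min}, \code{hubs}.
#' @export
build_network <- function(model, coords = NULL,
                          norm_table = psn_norm_table(), cutoff = 5.0,
                          i_min = 3.0, hub_degree = 4L) {
  xyz <- coords %||% model$coords
  rr <- model$residues[model$residues$is_amino, , drop = FALSE]
  nres <- nrow(rr)
  labels <- paste0(rr$resname, rr$label)
  sc <- lapply(rr$residue_index, function(ri) sidechain_indices(model, ri))
  cent <- t(vapply(sc, function(ii)
    colMeans(xyz[ii, , drop = FALSE]), numeric(3)))
  rad <- vapply(seq_len(nres), function(k) {
    p <- xyz[sc[[k]], , drop = FALSE]
    sqrt(max(rowSums(sweep(p, 2, cent[k, ])^2)))
  }, 0)
  Nv <- norm_value(norm_table, rr$resname)

  ei <- integer(); ej <- integer(); en <- integer(); es <- numeric()
  if (nres >= 2) {
    cd <- cross_dist(cent, cent)
    for (a in seq_len(nres - 1)) {
      for (b in seq.int(a + 1, nres)) {
        same_chain <- rr$chain[a] == rr$chain[b]
        if (same_chain && abs(rr$residue_index[a] - rr$residue_index[b]) == 1L)
          next  # covalently linked neighbors
        if (cd[a, b] > cutoff + rad[a] + rad[b]) next
        np <- sum(cross_dist2(xyz[sc[[a]], , drop = FALSE],
                              xyz[sc[[b]], , drop = FALSE]) <= cutoff^2)
        if (np == 0L) next
        I <- interaction_strength(np, Nv[a], Nv[b])
        if (I >= i_min) {
          ei <- c(ei, a); ej <- c(ej, b); en <- c(en, np); es <- c(es, I)
        }
      }
    }
  }
  edges <- data.frame(i = labels[ei], j = labels[ej],
                      n_pairs = en, strength = es,
                      stringsAsFactors = FALSE)
  deg <- table(factor(c(edges$i, edges$j), levels = labels))
  structure(list(nodes = labels, edges = edges, i_min = i_min,
                 hubs = names(deg)[deg >= hub_degree]),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges (i_min = %.2f%%), %d hubs\n",
              length(x$nodes), nrow(x$edges), x$i_min, length(x$hubs)))
  invisible(x)
}

network_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(network$nodes), name = network$nodes)
  if (nrow(network$edges))
    g <- igraph::add_edges(g, rbind(network$edges$i, network$edges$j))
  g
}

#' All minimum-hop paths between two residues
#'
#' Breadth-first geodesics on the retained (unweighted) network edges; an
#' empty list when source and target are disconnected.
#'
#' @param network interaction_network.
#' @param source,target node labels.
#' @return List of character vectors (node label sequences).
#' @export
shortest_paths_psn <- function(network, source, target) {
  if (!(source %in% network$nodes)) stopf("unknown node '%s'", source)
  if (!(target %in% network$nodes)) stopf("unknown node '%s'", target)
  g <- network_igraph(network)
  res <- suppressWarnings(
    igraph::all_shortest_paths(g, from = source, to = target))
  paths <- lapply(res$res %||% res$vpaths, function(p)
    igraph::V(g)$name[as.integer(p)])
  paths[vapply(paths, length, 0L) >= 2L]
}

#' Retain paths correlated with their endpoints
#'
#' A path survives iff at least one intermediate node k has
#' \code{|C(k, source)| >= cutoff} or \code{|C(k, target)| >= cutoff}.
#' Direct two-node paths have no intermediate and are discarded.
#'
#' @param paths list of node-label sequences.
#' @param corr correlation_matrix covering all path nodes (dimnames are
#'   node labels).
#' @param cutoff absolute-correlation threshold (default 0.4).
#' @return Filtered list of paths.
#' @export
filter_paths_by_correlation <- function(paths, corr, cutoff = 0.4) {
  C <- if (inherits(corr, "correlation_matrix")) corr$values else as.matrix(corr)
  keep <- vapply(paths, function(p) {
    if (length(p) < 3L) return(FALSE)
    s <- p[1]; t_ <- p[length(p)]
    mid <- p[-c(1, length(p))]
    if (!all(c(s, t_, mid) %in% rownames(C)))
      stopf("correlation matrix does not cover path nodes")
    any(abs(C[mid, s]) >= cutoff | abs(C[mid, t_]) >= cutoff)
  }, TRUE)
  paths[keep]
}

#' Per-frame communication-path statistics
#'
#' For every frame in the analysis window a PSN is built, all minimum-hop
#' paths between each (source, target) pair are enumerated, filtered by
#' the correlation criterion, and accumulated: a frame with k tied
#' retained paths contributes fractional weight 1/k to each. A path's
#' frequency is its accumulated weight over the number of frames used;
#' paths with frequency above \code{dominance} (default 0.30) are flagged
#' dominant.
#'
#' @param traj trajectory.
#' @param pairs data.frame (or 2-column matrix) of source/target node
#'   labels.
#' @param norm_table residue normalization table.
#' @param i_min PSN edge threshold, percent.
#' @param corr correlation_matrix for the filter, or NULL to skip
#'   filtering.
#' @param dominance dominant-path frequency threshold (default 0.30;
#'   strictly greater than).
#' @param cutoff PSN atom-pair cutoff, \enc{Å}{Angstrom}.
#' @param corr_cutoff correlation filter threshold (default 0.4).
#' @param window frame indices (default \code{\link{window_frames}}:
#'   trailing 10 percent).
#' @return \code{path_ensemble_set}: per-pair data.frames
#'   (\code{path}, \code{frequency}, \code{dominant}),
#'   \code{node_frequency} (per-node appearance frequency, the node-size
#'   quantity of path graphics), and counts of dominant paths per pair
#'   (both (pair, path) combinations and unique paths).
#' @export
path_statistics <- function(traj, pairs, norm_table = psn_norm_table(),
                            i_min = 3.0, corr = NULL, dominance = 0.30,
                            cutoff = 5.0, corr_cutoff = 0.4,
                            window = NULL) {
  window <- window %||% window_frames(traj)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("source", "target")
  acc <- lapply(seq_len(nrow(pairs)), function(i) new.env(parent = emptyenv()))
  for (f in window) {
    net <- build_network(traj$model, traj$frames[[f]], norm_table,
                         cutoff, i_min)
    for (p in seq_len(nrow(pairs))) {
      paths <- shortest_paths_psn(net, pairs$source[p], pairs$target[p])
      if (!is.null(corr))
        paths <- filter_paths_by_correlation(paths, corr, corr_cutoff)
      k <- length(paths)
      if (k == 0L) next
      for (pp in paths) {
        key <- paste(pp, collapse = "=>")
        acc[[p]][[key]] <- (acc[[p]][[key]] %||% 0) + 1 / k
      }
    }
  }
  nfu <- length(window)
  ensembles <- lapply(seq_len(nrow(pairs)), function(p) {
    keys <- ls(acc[[p]])
    if (!length(keys))
      return(data.frame(path = character(), frequency = numeric(),
                        dominant = logical(), stringsAsFactors = FALSE))
    freq <- vapply(keys, function(k) acc[[p]][[k]], 0) / nfu
    o <- order(-freq)
    data.frame(path = keys[o], frequency = unname(freq[o]),
               dominant = unname(freq[o]) > dominance,
               stringsAsFactors = FALSE)
  })
  names(ensembles) <- paste(pairs$source, pairs$target, sep = "->")

  all_paths <- do.call(rbind, lapply(names(ensembles), function(nm)
    if (nrow(ensembles[[nm]])) cbind(pair = nm, ensembles[[nm]])))
  node_freq <- numeric()
  if (!is.null(all_paths) && nrow(all_paths)) {
    for (r in seq_len(nrow(all_paths))) {
      for (nd in strsplit(all_paths$path[r], "=>", fixed = TRUE)[[1]])
        node_freq[nd] <- (if (is.na(node_freq[nd])) 0 else node_freq[nd]) +
          all_paths$frequency[r]
    }
    node_freq <- sort(node_freq, decreasing = TRUE)
  }
  dom <- if (!is.null(all_paths) && nrow(all_paths))
    all_paths[all_paths$dominant, , drop = FALSE] else NULL
  structure(list(
    ensembles = ensembles,
    node_frequency = node_freq,
    n_dominant_combinations = if (is.null(dom)) 0L else nrow(dom),
    n_dominant_unique_paths = if (is.null(dom)) 0L
      else length(unique(dom$path)),
    dominance = dominance, n_frames_used = nfu),
    class = "path_ensemble_set")
}

#' Residues adsorbed in a reference frame and desorbed since
#'
#' A residue is adsorbed when any of its heavy atoms lies within
#' \code{cutoff} of the surface. The desorbed set is
#' \code{adsorbed(reference) \\ adsorbed(now)}: residues that were in
#' contact in the reference frame and have left the surface.
#'
#' @param model structure_model (same topology for both frames).
#' @param frame_ref,frame_now coordinate matrices.
#' @param protein_selection,surface_selection selections.
#' @param cutoff criterion distance, \enc{Å}{Angstrom} (default 6.0).
#' @return List with residue-label vectors \code{adsorbed} (reference
#'   frame) and \code{desorbed}.
#' @export
desorption_nodes <- function(model, frame_ref, frame_now,
                             protein_selection = "protein",
                             surface_selection = "group:cnt",
                             cutoff = 6.0) {
  adsorbed_residues <- function(xyz) {
    ip <- resolve_selection(model, protein_selection)
    ip <- ip[!model$atoms$is_hydrogen[ip]]
    is <- resolve_selection(model, surface_selection)
    d2 <- cross_dist2(xyz[ip, , drop = FALSE], xyz[is, , drop = FALSE])
    near <- apply(d2, 1, min) <= cutoff^2
    ri <- unique(model$atoms$residue_index[ip[near]])
    rr <- model$residues
    paste0(rr$resname, rr$label)[match(ri, rr$residue_index)]
  }
  ads_ref <- adsorbed_residues(frame_ref)
  ads_now <- adsorbed_residues(frame_now)
  list(adsorbed = ads_ref, desorbed = setdiff(ads_ref, ads_now))
}
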