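## Fixture builders and independent oracles shared across tests.

## Write PDB-format records directly (fixed-width, independent of the
## package's writer) so read/write round trips have an outside reference.
write_pdb_records <- function(path, serial, name, resname, chain, resno,
                              coords, element = NULL, hetero = FALSE,
                              models = NULL) {
  fmt_atom <- function(i, xyz) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (hetero) "HETATM" else "ATOM", serial[i],
            if (nchar(name[i]) < 4) paste0(" ", name[i]) else name[i],
            " ", resname[i], chain[i], resno[i], " ",
            xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0,
            if (is.null(element)) "" else element[i])
  }
  con <- file(path, "w"); on.exit(close(con))
  if (is.null(models)) models <- list(coords)
  multi <- length(models) > 1
  for (m in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_along(serial)) writeLines(fmt_atom(i, models[[m]]), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}

## A minimal 3-atom, single-residue PDB text.
tiny_pdb <- function(path = tempfile(fileext = ".pdb"), models = NULL) {
  write_pdb_records(path, serial = 1:3, name = c("N", "CA", "C"),
                    resname = rep("ALA", 3), chain = rep("A", 3),
                    resno = rep(1L, 3),
                    coords = rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.4, 1, 0)),
                    element = c("N", "C", "C"), models = models)
}

## Synthetic stand-in with the residue composition of a subtilisin
## crystal structure: 274 amino-acid residues plus 265 water molecules.
## This is generated, not downloaded; it tests the parser's residue and
## water classification, not the real deposited coordinates.
synthetic_subtilisin_like_pdb <- function(path = tempfile(fileext = ".pdb")) {
  aa <- c("ALA", "GLY", "SER", "THR", "VAL", "LEU", "ILE", "ASN", "ASP",
          "TYR")
  n_res <- 274
  set.seed(42)
  resnames <- sample(aa, n_res, replace = TRUE)
  rows <- list()
  serial <- 0L
  for (r in seq_len(n_res)) {
    for (nm in c("N", "CA", "C", "O")) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(serial = serial, name = nm,
                                   resname = resnames[r], chain = "A",
                                   resno = r, hetero = FALSE)
    }
  }
  n_prot <- serial
  for (w in seq_len(265)) {
    serial <- serial + 1L
    rows[[serial]] <- data.frame(serial = serial, name = "O",
                                 resname = "HOH", chain = "W",
                                 resno = 1000L + w, hetero = TRUE)
  }
  df <- do.call(rbind, rows)
  coords <- cbind(3 * (seq_len(nrow(df)) %% 50), 3 * (seq_len(nrow(df)) %/% 50),
                  as.numeric(seq_len(nrow(df)) %% 7))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(sprintf(
      "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      if (df$hetero[i]) "HETATM" else "ATOM", df$serial[i],
      paste0(" ", df$name[i]), " ", df$resname[i], df$chain[i],
      df$resno[i], " ", coords[i, 1], coords[i, 2], coords[i, 3], 1, 0,
      substr(df$name[i], 1, 1)), con)
  }
  writeLines("END", con)
  path
}

## Closed-form SASA of two intersecting spheres of probe-expanded radii
## R1, R2 at center distance d: each sphere loses a spherical cap.
two_sphere_sasa <- function(r1, r2, probe, d) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  x <- (d^2 + R1^2 - R2^2) / (2 * d)  # distance center1 -> plane
  h1 <- R1 - x
  h2 <- R2 - (d - x)
  4 * pi * R1^2 - 2 * pi * R1 * h1 + 4 * pi * R2^2 - 2 * pi * R2 * h2
}

## Brute-force enumeration of all simple paths between two nodes of an
## undirected graph (adjacency matrix), filtered to minimum hop count.
brute_min_paths <- function(adj, source, target) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == target) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (w in which(adj[v, ] > 0)) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(source)
  if (!length(paths)) return(list())
  len <- vapply(paths, length, 0L)
  paths[len == min(len)]
}

## Build an interaction_network object directly from an adjacency matrix
## (for graph-algorithm tests decoupled from geometry).
adj_to_network <- function(adj, labels = paste0("R", seq_len(nrow(adj)))) {
  idx <- which(adj > 0 & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(i = labels[idx[, 1]], j = labels[idx[, 2]],
                      n_pairs = rep(1L, nrow(idx)),
                      strength = rep(10, nrow(idx)),
                      stringsAsFactors = FALSE)
  structure(list(nodes = labels, edges = edges, i_min = 0,
                 hubs = character()),
            class = "interaction_network")
}

## Bead-grid model: k x k beads in a plane, one single-atom residue each.
bead_grid_model <- function(k = 3, spacing = 5) {
  n <- k * k
  atoms <- data.frame(serial = seq_len(n), name = "CA", resname = "ALA",
                      resno = seq_len(n), chain = "A", element = "C",
                      stringsAsFactors = FALSE)
  g <- expand.grid(x = seq_len(k), y = seq_len(k))
  structure_model(atoms, cbind(g$x * spacing, g$y * spacing, 0))
}

rotation_xyz <- function(a, b, c) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

## Independent rigid-superposition RMSD: minimize over Euler angles with
## general-purpose optimization from multiple starts (no SVD involved).
brute_superpose_rmsd <- function(mobile, ref) {
  cm <- colMeans(mobile); cr <- colMeans(ref)
  Xm <- sweep(mobile, 2, cm); Xr <- sweep(ref, 2, cr)
  obj <- function(ang) {
    R <- rotation_xyz(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Xm %*% R - Xr)^2)))
  }
  best <- Inf
  starts <- as.matrix(expand.grid(a = seq(0, 2 * pi, length.out = 5)[-5],
                                  b = seq(0, pi, length.out = 3),
                                  c = seq(0, 2 * pi, length.out = 5)[-5]))
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, fit$value)
  }
  best
}
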