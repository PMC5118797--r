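## Single-trajectory MM-GB(SA)-style binding free energy:
## dG_bind = dE_gas + dG_solv, dE_gas = dE_ele + dE_vdw + dE_int (dE_int
## vanishes under the single-trajectory protocol), dG_solv = dG_npsolv +
## dG_psolv. The polar term is a pairwise-descreening generalized-Born
## model (pluggable backend); the nonpolar term is gamma * SASA. No
## entropy term is included.

COULOMB_K <- 332.0637  # kcal Angstrom / (mol e^2)

#' Implicit-solvent model presets
#'
#' @param name \code{"water"} (exterior dielectric 80),
#'   \code{"acetonitrile"} (37.5), \code{"heptane"} (1.92) or
#'   \code{"custom"}.
#' @param exterior_dielectric required for \code{"custom"}.
#' @param gamma surface-tension coefficient, kcal/(mol
#'   \enc{Å}{Angstrom}^2) (default 0.0072).
#' @param probe SASA probe radius, \enc{Å}{Angstrom} (default 1.4).
#' @param interior_dielectric solute dielectric (default 1).
#' @return List of class \code{solvent_model}.
#' @export
solvent_model <- function(name = c("water", "acetonitrile", "heptane",
                                   "custom"),
                          exterior_dielectric = NULL, gamma = 0.0072,
                          probe = 1.4, interior_dielectric = 1) {
  name <- match.arg(name)
  eps <- switch(name, water = 80, acetonitrile = 37.5, heptane = 1.92,
                custom = exterior_dielectric)
  if (is.null(eps) || !is.finite(eps) || eps < 1)
    stopf("exterior dielectric must be >= 1")
  structure(list(name = name, exterior_dielectric = eps,
                 interior_dielectric = interior_dielectric,
                 gamma = gamma, probe = probe),
            class = "solvent_model")
}

#' Read a per-atom nonbonded parameter table
#'
#' @param path TSV with columns \code{serial}, \code{charge} (e),
#'   \code{rmin2} (LJ R_min/2, \enc{Å}{Angstrom}), \code{eps} (LJ well
#'   depth, kcal/mol), \code{gb_radius} (\enc{Å}{Angstrom}),
#'   \code{screen} (GB screening factor).
#' @return data.frame ordered by serial.
#' @export
read_params_tsv <- function(path) {
  df <- read_table(path)
  need <- c("serial", "charge", "rmin2", "eps", "gb_radius", "screen")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("parameter table lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (any(df$eps < 0)) stopf("LJ epsilon must be >= 0")
  if (any(df$rmin2 <= 0 | df$gb_radius <= 0))
    stopf("LJ and GB radii must be > 0")
  df[order(df$serial), , drop = FALSE]
}

#' sp2-carbon nonbonded preset for uncharged nanotube atoms
#'
#' Zero charge, sp2 aromatic-carbon Lennard-Jones parameters
#' (R_min/2 = 1.9080 \enc{Å}{Angstrom}, eps = 0.0860 kcal/mol) and a
#' 1.7-\enc{Å}{Angstrom} GB radius.
#'
#' @param n number of atoms.
#' @param serial atom serials (default 1:n).
#' @return Parameter data.frame.
#' @export
cnt_params <- function(n, serial = seq_len(n)) {
  data.frame(serial = serial, charge = 0, rmin2 = 1.9080, eps = 0.0860,
             gb_radius = 1.7, screen = 0.72)
}

check_pair_geometry <- function(xa, xb) {
  d2 <- cross_dist2(xa, xb)
  if (any(d2 < 1e-12))
    stopf("coincident inter-group atoms (r = 0): singular interaction")
  sqrt(d2)
}

#' Inter-group Coulomb energy
#'
#' \code{sum_ij k q_i q_j / (eps_in r_ij)} over all inter-group pairs, no
#' cutoff, k = 332.0637 kcal \enc{Å}{Angstrom} / (mol e^2).
#'
#' @param coords_a,coords_b coordinate matrices.
#' @param charge_a,charge_b charges (e).
#' @param eps_interior interior dielectric (default 1).
#' @return Energy, kcal/mol.
#' @export
coulomb_energy <- function(coords_a, coords_b, charge_a, charge_b,
                           eps_interior = 1) {
  d <- check_pair_geometry(coords_a, coords_b)
  sum(outer(charge_a, charge_b) / d) * COULOMB_K / eps_interior
}

#' Inter-group Lennard-Jones energy
#'
#' \code{sum_ij eps_ij [ (Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6 ]} with
#' \code{Rmin_ij = Rmin2_i + Rmin2_j} and
#' \code{eps_ij = sqrt(eps_i eps_j)}.
#'
#' @param coords_a,coords_b coordinate matrices.
#' @param rmin2_a,rmin2_b per-atom R_min/2, \enc{Å}{Angstrom}.
#' @param eps_a,eps_b per-atom well depths, kcal/mol.
#' @return Energy, kcal/mol.
#' @export
lj_energy <- function(coords_a, coords_b, rmin2_a, eps_a, rmin2_b, eps_b) {
  d <- check_pair_geometry(coords_a, coords_b)
  rmin <- outer(rmin2_a, rmin2_b, `+`)
  epsij <- sqrt(outer(eps_a, eps_b))
  s6 <- (rmin / d)^6
  sum(epsij * (s6^2 - 2 * s6))
}

#' Effective Born radii by pairwise descreening (HCT-style)
#'
#' \code{1/B_i = 1/rho_i - sum_j H(r_ij, S_j rho_j)} with rho the
#' (offset-reduced) intrinsic GB radius. With the default zero offset an
#' isolated atom's Born radius equals its tabulated GB radius, so the
#' single-ion limit reduces exactly to the Born equation.
#'
#' @param coords coordinate matrix.
#' @param gb_radius intrinsic GB radii, \enc{Å}{Angstrom}.
#' @param screen per-atom screening factors.
#' @param offset radius offset, \enc{Å}{Angstrom} (default 0).
#' @return Effective Born radii, \enc{Å}{Angstrom}.
#' @export
born_radii <- function(coords, gb_radius, screen, offset = 0) {
  n <- nrow(coords)
  rho <- gb_radius - offset
  if (any(rho <= 0)) stopf("non-positive reduced GB radius")
  inv <- 1 / rho
  if (n > 1) {
    d <- cross_dist(coords, coords)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        r <- d[i, j]
        sj <- screen[j] * rho[j]
        if (rho[i] >= r + sj) next  # j fully inside i's sphere
        L <- max(rho[i], abs(r - sj))
        U <- r + sj
        I <- 0.5 * (1 / L - 1 / U + (r - sj^2 / r) * (1 / U^2 - 1 / L^2) / 4 +
                      log(L / U) / (2 * r))
        inv[i] <- inv[i] - I
      }
    }
  }
  if (any(inv <= 0)) stopf("non-positive effective Born radius")
  1 / inv
}

#' Generalized-Born polar solvation energy
#'
#' \code{-(k/2) (1/eps_in - 1/eps_ext) sum_ij q_i q_j / f_GB(r_ij, B_i,
#' B_j)} with \code{f_GB = sqrt(r^2 + B_i B_j exp(-r^2 / (4 B_i B_j)))},
#' summed over all ordered pairs including the self terms.
#'
#' @param coords coordinate matrix.
#' @param charge charges (e).
#' @param gb_radius intrinsic GB radii.
#' @param screen screening factors.
#' @param solvent a \code{\link{solvent_model}}.
#' @param offset Born-radius offset (default 0).
#' @return Polar solvation energy, kcal/mol.
#' @export
gb_polar_energy <- function(coords, charge, gb_radius, screen,
                            solvent, offset = 0) {
  eps_in <- solvent$interior_dielectric
  eps_ext <- solvent$exterior_dielectric
  tau <- 1 / eps_in - 1 / eps_ext
  if (abs(tau) < 1e-15) return(0)
  coords <- as.matrix(coords)
  B <- born_radii(coords, gb_radius, screen, offset)
  r2 <- cross_dist2(coords, coords)
  BB <- outer(B, B)
  fgb <- sqrt(r2 + BB * exp(-r2 / (4 * BB)))
  -(COULOMB_K / 2) * tau * sum(outer(charge, charge) / fgb)
}

#' Nonpolar solvation energy gamma * SASA
#'
#' @param model structure_model.
#' @param selection atoms included.
#' @param solvent \code{\link{solvent_model}} (supplies gamma and probe;
#'   the dielectric plays no role in this term).
#' @param radii_map element radius table for the SASA.
#' @param n_points SASA quadrature points.
#' @param coords optional frame coordinates.
#' @return Energy, kcal/mol.
#' @export
npsolv_energy <- function(model, selection = "all",
                          solvent = solvent_model("water"),
                          radii_map = default_radii(), n_points = 960,
                          coords = NULL) {
  s <- sasa(model, selection, radii_map, solvent$probe, n_points, coords)
  solvent$gamma * s$total
}

#' Assemble MM-GB(SA) energy components
#'
#' Derived terms are computed from the primitives, so the additivity
#' identities (gas = ele + vdw + int; solv = npsolv + psolv; ele_total =
#' ele + psolv; binding = gas + solv) hold exactly by construction.
#'
#' @param ele,vdw,int,npsolv,psolv component means, kcal/mol.
#' @param se optional named list/vector of standard errors for the same
#'   five primitives; derived-term SEs are combined in quadrature.
#' @return List of class \code{energy_components}.
#' @export
energy_components <- function(ele, vdw, int = 0, npsolv, psolv, se = NULL) {
  comp <- list(E_ele = ele, E_vdw = vdw, E_int = int,
               E_gas = ele + vdw + int,
               G_npsolv = npsolv, G_psolv = psolv,
               G_solv = npsolv + psolv,
               G_ele = ele + psolv,
               G_binding = ele + vdw + int + npsolv + psolv)
  if (!is.null(se)) {
    se <- as.list(se)
    g <- function(...) sqrt(sum(unlist(list(...))^2))
    comp$se <- list(E_ele = se$ele, E_vdw = se$vdw, E_int = se$int %||% 0,
                    E_gas = g(se$ele, se$vdw, se$int %||% 0),
                    G_npsolv = se$npsolv, G_psolv = se$psolv,
                    G_solv = g(se$npsolv, se$psolv),
                    G_ele = g(se$ele, se$psolv),
                    G_binding = g(se$ele, se$vdw, se$int %||% 0,
                                  se$npsolv, se$psolv))
  }
  structure(comp, class = "energy_components")
}

#' @export
print.energy_components <- function(x, ...) {
  terms <- c("E_ele", "E_vdw", "E_int", "E_gas", "G_npsolv", "G_psolv",
             "G_solv", "G_ele", "G_binding")
  for (t_ in terms) {
    if (!is.null(x$se))
      cat(sprintf("  %-9s %8.2f +/- %.2f kcal/mol\n", t_, x[[t_]],
                  x$se[[t_]]))
    else cat(sprintf("  %-9s %8.2f kcal/mol\n", t_, x[[t_]]))
  }
  invisible(x)
}

frame_delta_terms <- function(model, xyz, ir, il, params, solvent,
                              radii_map, n_points, gb_offset) {
  q <- params$charge; r2 <- params$rmin2; ep <- params$eps
  gbr <- params$gb_radius; sc <- params$screen
  xa <- xyz[ir, , drop = FALSE]; xb <- xyz[il, , drop = FALSE]
  ele <- coulomb_energy(xa, xb, q[ir], q[il], solvent$interior_dielectric)
  vdw <- lj_energy(xa, xb, r2[ir], ep[ir], r2[il], ep[il])
  ic <- c(ir, il)
  psolv <- gb_polar_energy(xyz[ic, , drop = FALSE], q[ic], gbr[ic], sc[ic],
                           solvent, gb_offset) -
    gb_polar_energy(xa, q[ir], gbr[ir], sc[ir], solvent, gb_offset) -
    gb_polar_energy(xb, q[il], gbr[il], sc[il], solvent, gb_offset)
  V <- principal_frame(xyz[ic, , drop = FALSE])
  sas_c <- sasa(model, ic, radii_map, solvent$probe, n_points, xyz, V)
  sas_r <- sasa(model, ir, radii_map, solvent$probe, n_points, xyz, V)
  sas_l <- sasa(model, il, radii_map, solvent$probe, n_points, xyz, V)
  npsolv <- solvent$gamma * (sas_c$total - sas_r$total - sas_l$total)
  list(ele = ele, vdw = vdw, npsolv = npsolv, psolv = psolv,
       sasa = list(complex = sas_c, receptor = sas_r, ligand = sas_l))
}

select_snapshots <- function(traj, snapshots = NULL, stride_ps = NULL) {
  nf <- n_frames(traj)
  idx <- seq_len(nf)
  if (!is.null(stride_ps)) {
    step <- max(1L, as.integer(round(stride_ps / traj$frame_interval)))
    idx <- seq(nf %% step + step, nf, by = step)
    if (!length(idx)) idx <- nf
  }
  if (!is.null(snapshots)) {
    if (length(idx) < snapshots)
      warnf("only %d frames available for %d requested snapshots; using all",
            length(idx), snapshots)
    else idx <- utils::tail(idx, snapshots)
  }
  idx
}

#' Single-trajectory MM-GB(SA) binding free energy
#'
#' Receptor and ligand coordinates are extracted from the complex frames,
#' so the internal-energy difference is identically zero; per-snapshot
#' \code{dG = dE_gas + dG_solv}, reported as means with standard errors
#' (sample SD / sqrt(n)) over the snapshots.
#'
#' @param traj trajectory of the complex.
#' @param receptor_selection,ligand_selection disjoint selections whose
#'   union is the interacting complex.
#' @param params per-atom parameter data.frame
#'   (see \code{\link{read_params_tsv}}), row order = atom order.
#' @param solvent \code{\link{solvent_model}}.
#' @param snapshots number of snapshots (taken from the trajectory tail);
#'   default all frames.
#' @param stride_ps snapshot spacing in ps (default every frame).
#' @param radii_map element radius table for the SASA term.
#' @param n_points SASA quadrature points (default 240; raise for
#'   publication-grade areas).
#' @param gb_offset Born-radius offset.
#' @return \code{energy_components} with standard errors and a
#'   \code{frames} attribute recording the snapshot indices.
#' @export
binding_energy <- function(traj, receptor_selection, ligand_selection,
                           params, solvent, snapshots = NULL,
                           stride_ps = NULL, radii_map = default_radii(),
                           n_points = 240, gb_offset = 0) {
  model <- traj$model
  ir <- resolve_selection(model, receptor_selection)
  il <- resolve_selection(model, ligand_selection)
  if (length(intersect(ir, il)))
    stopf("receptor and ligand selections overlap")
  if (nrow(params) != n_atoms(model))
    stopf("parameter table has %d rows for %d atoms", nrow(params),
          n_atoms(model))
  idx <- select_snapshots(traj, snapshots, stride_ps)
  terms <- lapply(idx, function(f)
    frame_delta_terms(model, traj$frames[[f]], ir, il, params, solvent,
                      radii_map, n_points, gb_offset))
  pull <- function(nm) vapply(terms, `[[`, 0, nm)
  mse <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  ele <- pull("ele"); vdw <- pull("vdw")
  np <- pull("npsolv"); ps <- pull("psolv")
  out <- energy_components(mean(ele), mean(vdw), 0, mean(np), mean(ps),
                           se = list(ele = mse(ele), vdw = mse(vdw),
                                     int = 0, npsolv = mse(np),
                                     psolv = mse(ps)))
  attr(out, "frames") <- idx
  out
}

#' Per-residue decomposition of the binding energy
#'
#' Pairwise terms (Coulomb, LJ, GB cross terms) are split half to each
#' partner atom's residue; SASA shares are assigned per atom. Sums over
#' all residue rows (receptor residues plus the ligand rows) reproduce the
#' corresponding system totals to numerical precision.
#'
#' @inheritParams binding_energy
#' @param report_threshold report filter: residues with |total| above this
#'   value are flagged (default 1.0 kcal/mol); all rows are returned.
#' @return data.frame with per-residue \code{ele}, \code{vdw},
#'   \code{npsolv}, \code{psolv}, \code{total} (snapshot means, kcal/mol)
#'   and a logical \code{above_threshold}.
#' @export
per_residue_decomposition <- function(traj, receptor_selection,
                                      ligand_selection, params, solvent,
                                      snapshots = NULL, stride_ps = NULL,
                                      radii_map = default_radii(),
                                      n_points = 240, gb_offset = 0,
                                      report_threshold = 1.0) {
  model <- traj$model
  ir <- resolve_selection(model, receptor_selection)
  il <- resolve_selection(model, ligand_selection)
  if (length(intersect(ir, il))) stopf("selections overlap")
  idx <- select_snapshots(traj, snapshots, stride_ps)
  ic <- c(ir, il)
  resid_of <- model$atoms$residue_index
  rr <- model$residues
  res_lab <- paste0(rr$resname, rr$label)
  res_ids <- sort(unique(resid_of[ic]))
  nres <- length(res_ids)
  pos <- match(resid_of, res_ids)  # atom -> row index (NA outside complex)

  acc <- matrix(0, nres, 4, dimnames = list(
    res_lab[match(res_ids, rr$residue_index)],
    c("ele", "vdw", "npsolv", "psolv")))
  q <- params$charge; r2p <- params$rmin2; epp <- params$eps
  gbr <- params$gb_radius; scr <- params$screen
  tau <- 1 / solvent$interior_dielectric - 1 / solvent$exterior_dielectric

  gb_atom_share <- function(sub) {
    ## per-atom share of the GB energy of atom subset `sub`
    B <- born_radii(traj_frame[sub, , drop = FALSE], gbr[sub], scr[sub],
                    gb_offset)
    r2m <- cross_dist2(traj_frame[sub, , drop = FALSE],
                       traj_frame[sub, , drop = FALSE])
    BB <- outer(B, B)
    fgb <- sqrt(r2m + BB * exp(-r2m / (4 * BB)))
    -(COULOMB_K / 2) * tau * rowSums(outer(q[sub], q[sub]) / fgb)
  }

  for (f in idx) {
    traj_frame <- traj$frames[[f]]
    xa <- traj_frame[ir, , drop = FALSE]
    xb <- traj_frame[il, , drop = FALSE]
    d <- check_pair_geometry(xa, xb)
    pe <- COULOMB_K * outer(q[ir], q[il]) / d / solvent$interior_dielectric
    rmin <- outer(r2p[ir], r2p[il], `+`)
    s6 <- (rmin / d)^6
    pv <- sqrt(outer(epp[ir], epp[il])) * (s6^2 - 2 * s6)
    ## half of each inter-group pair to each partner's residue
    row_r <- pos[ir]; row_l <- pos[il]
    for (tm in list(list(m = pe, col = "ele"), list(m = pv, col = "vdw"))) {
      by_i <- rowSums(tm$m) / 2
      by_j <- colSums(tm$m) / 2
      acc[, tm$col] <- acc[, tm$col] +
        as.vector(tapply(by_i, factor(row_r, levels = seq_len(nres)), sum,
                         default = 0)) +
        as.vector(tapply(by_j, factor(row_l, levels = seq_len(nres)), sum,
                         default = 0))
    }
    ## GB: per-atom complex share minus isolated-component share
    sh_c <- numeric(n_atoms(model))
    sh_c[ic] <- if (abs(tau) > 1e-15) gb_atom_share(ic) else 0
    sh_i <- numeric(n_atoms(model))
    if (abs(tau) > 1e-15) {
      sh_i[ir] <- gb_atom_share(ir)
      sh_i[il] <- gb_atom_share(il)
    }
    dps <- sh_c - sh_i
    acc[, "psolv"] <- acc[, "psolv"] +
      as.vector(tapply(dps[ic], factor(pos[ic], levels = seq_len(nres)),
                       sum, default = 0))
    ## SASA: per-atom complex area minus isolated-component area, on a
    ## shared quadrature frame so orientation effects cancel
    V <- principal_frame(traj_frame[ic, , drop = FALSE])
    sas_c <- sasa(model, ic, radii_map, solvent$probe, n_points, traj_frame, V)
    sas_r <- sasa(model, ir, radii_map, solvent$probe, n_points, traj_frame, V)
    sas_l <- sasa(model, il, radii_map, solvent$probe, n_points, traj_frame, V)
    da <- numeric(n_atoms(model))
    da[sas_c$indices] <- sas_c$per_atom_area
    da[sas_r$indices] <- da[sas_r$indices] - sas_r$per_atom_area
    da[sas_l$indices] <- da[sas_l$indices] - sas_l$per_atom_area
    acc[, "npsolv"] <- acc[, "npsolv"] + solvent$gamma *
      as.vector(tapply(da[ic], factor(pos[ic], levels = seq_len(nres)),
                       sum, default = 0))
  }
  acc <- acc / length(idx)
  out <- data.frame(residue = rownames(acc), acc, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$total <- out$ele + out$vdw + out$npsolv + out$psolv
  out$above_threshold <- abs(out$total) > report_threshold
  out
}
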