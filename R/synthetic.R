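## Seeded synthetic-trajectory generators with analytically known ground
## truth. They emulate the statistical structure the analyses assume --
## staged adsorption near a cylindrical pseudo-nanotube, Gaussian
## fluctuations with prescribed residue-residue covariance, two-state
## contact switching for path statistics, scheduled strand opening, and
## small charged/LJ systems with hand-computable energies. They are not
## physical simulations.

make_bead_model <- function(n_res, resname = "ALA", atom_name = "CA",
                            chain = "A", start_label = 1L) {
  atoms <- data.frame(serial = seq_len(n_res), name = atom_name,
                      resname = resname,
                      resno = seq.int(start_label, length.out = n_res),
                      chain = chain, element = "C",
                      stringsAsFactors = FALSE)
  atoms
}

pseudo_cnt_coords <- function(radius = 8, n_per_ring = 12, n_rings = 16,
                              ring_spacing = 2.46) {
  th <- 2 * pi * (seq_len(n_per_ring) - 1) / n_per_ring
  z <- (seq_len(n_rings) - (n_rings + 1) / 2) * ring_spacing
  do.call(rbind, lapply(z, function(zz)
    cbind(radius * cos(th), radius * sin(th), zz)))
}

#' Synthetic staged-adsorption trajectory
#'
#' A rigid cylindrical pseudo-nanotube plus a cloud of heavy enzyme-like
#' beads. At every frame exactly the scheduled number of beads sit within
#' \code{cutoff - 0.5} \enc{Å}{Angstrom} of the surface atoms and all
#' others beyond \code{cutoff + 0.5}, so the adsorbed-atom count at the
#' stated cutoff is known exactly per frame.
#'
#' @param schedule integer vector: target adsorbed-bead count per frame.
#' @param n_beads number of enzyme beads (>= max(schedule)).
#' @param cutoff the adsorption criterion the schedule is built for,
#'   \enc{Å}{Angstrom} (default 6).
#' @param frame_interval ps per frame.
#' @param seed integer seed; fixes all randomness.
#' @return List: \code{trajectory}, \code{truth} (the schedule),
#'   \code{cutoff}.
#' @export
gen_adsorption <- function(schedule, n_beads = max(max(schedule), 50L),
                           cutoff = 6.0, frame_interval = 2, seed = 1) {
  schedule <- as.integer(schedule)
  if (any(schedule < 0)) stopf("schedule counts must be >= 0")
  if (max(schedule) > n_beads)
    stopf("infeasible schedule: %d adsorbed > %d beads", max(schedule),
          n_beads)
  set.seed(seed)
  cnt <- pseudo_cnt_coords()
  radius <- 8
  ncnt <- nrow(cnt)
  atoms <- rbind(
    data.frame(serial = seq_len(ncnt), name = "C", resname = "CNT",
               resno = 1L, chain = "X", element = "C",
               stringsAsFactors = FALSE),
    make_bead_model(n_beads, chain = "A"))
  atoms$serial <- seq_len(nrow(atoms))
  near_lo <- 2.5; near_hi <- cutoff - 0.7
  far_lo <- cutoff + 1.0; far_hi <- cutoff + 20
  frames <- lapply(schedule, function(k) {
    bead <- matrix(0, n_beads, 3)
    host <- sample.int(ncnt, n_beads, replace = TRUE)
    d <- c(stats::runif(k, near_lo, near_hi),
           stats::runif(n_beads - k, far_lo, far_hi))
    for (b in seq_len(n_beads)) {
      a <- cnt[host[b], ]
      u <- c(a[1], a[2], 0) / radius        # outward radial unit vector
      bead[b, ] <- a + u * d[b]
    }
    rbind(cnt, bead)
  })
  model <- structure_model(atoms, frames[[1]],
                           groups = list(cnt = seq_len(ncnt),
                                         enzyme = ncnt + seq_len(n_beads)))
  list(trajectory = trajectory(model, frames, frame_interval),
       truth = schedule, cutoff = cutoff)
}

#' Synthetic Gaussian-fluctuation trajectory with known correlation
#'
#' Bead residues on a line; per-frame displacements of each Cartesian
#' axis are independent draws from a multivariate normal with the
#' prescribed residue-residue correlation, so the population
#' cross-correlation matrix is known exactly.
#'
#' @param n_res number of residues.
#' @param n_frames number of frames.
#' @param blocks list of residue-index vectors; within a block the
#'   correlation is \code{rho}, across blocks 0.
#' @param rho within-block correlation in [-1, 1].
#' @param sigma displacement SD per axis, \enc{Å}{Angstrom}.
#' @param correlation full n_res x n_res correlation matrix overriding
#'   \code{blocks}/\code{rho}.
#' @param frame_interval ps per frame.
#' @param seed integer seed.
#' @return List: \code{trajectory}, \code{truth} (the population
#'   correlation matrix).
#' @export
gen_gaussian_fluct <- function(n_res, n_frames, blocks = list(), rho = 0,
                               sigma = 0.5, correlation = NULL,
                               frame_interval = 2, seed = 1) {
  if (is.null(correlation)) {
    correlation <- diag(n_res)
    for (b in blocks)
      correlation[b, b] <- rho
    diag(correlation) <- 1
  }
  correlation <- as.matrix(correlation)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stopf("correlation matrix is not positive semi-definite (min eig %.3g)",
          min(ev))
  set.seed(seed)
  Sigma <- sigma^2 * correlation
  mu <- cbind(10 * (seq_len(n_res) - 1), 0, 0)
  disp <- lapply(1:3, function(a)
    MASS::mvrnorm(n_frames, mu = rep(0, n_res), Sigma = Sigma,
                  tol = 1e-6))
  frames <- lapply(seq_len(n_frames), function(f)
    mu + cbind(disp[[1]][f, ], disp[[2]][f, ], disp[[3]][f, ]))
  model <- structure_model(make_bead_model(n_res), frames[[1]])
  list(trajectory = trajectory(model, frames, frame_interval),
       truth = correlation)
}

two_state_geometry <- function(state) {
  ## residue side-chain center positions; residues 1 (source) and 5
  ## (target) fixed, residue 3 / residue 7 swap between the bridging
  ## position and a remote shelf depending on the state
  bridge <- c(3.5, 0.5, 0)
  shelf3 <- c(3.5, 50, 0); shelf7 <- c(3.5, -50, 0)
  centers <- rbind(
    c(0, 0, 0),        # 1 source
    c(-30, 100, 0),    # 2 spacer
    if (state == "A") bridge else shelf3,   # 3
    c(30, 150, 0),     # 4 spacer
    c(7, 0, 0),        # 5 target
    c(-30, 200, 0),    # 6 spacer
    if (state == "B") bridge else shelf7)   # 7
  centers
}

two_state_frame <- function(state) {
  centers <- two_state_geometry(state)
  ## per residue: CA at center + (0, 0.8, 0); side chain CB/CG at
  ## center +/- 0.25 along z
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    ct <- centers[i, ]
    rbind(ct + c(0, 0.8, 0), ct + c(0, 0, 0.25), ct - c(0, 0, 0.25))
  }))
}

#' Synthetic two-state contact-switching trajectory
#'
#' Seven two-atom-side-chain residues; a bridging residue connects the
#' source (residue 1) to the target (residue 5) through residue 3 in
#' state A and through residue 7 in state B. Frames follow the stated
#' split (state-A frames first), so every path frequency is known
#' exactly, as is the population correlation matrix handed to the path
#' filter (bridging residues are correlated 0.9 with the source).
#'
#' @param n_frames total frames.
#' @param split length-2 non-negative weights for states A and B
#'   (normalized; default c(0.6, 0.4)).
#' @param frame_interval ps per frame.
#' @param seed integer seed (the generator is deterministic; the seed is
#'   accepted for interface uniformity).
#' @return List: \code{trajectory}, \code{correlation}
#'   (a \code{correlation_matrix}), \code{truth} (data.frame of path
#'   strings and exact frequencies), \code{source}, \code{target}.
#' @export
gen_two_state_contacts <- function(n_frames = 50, split = c(0.6, 0.4),
                                   frame_interval = 2, seed = 1) {
  if (length(split) != 2 || any(split < 0) || sum(split) <= 0)
    stopf("split must be two non-negative weights")
  split <- split / sum(split)
  nA <- round(n_frames * split[1])
  nB <- n_frames - nA
  fA <- two_state_frame("A"); fB <- two_state_frame("B")
  frames <- c(replicate(nA, fA, simplify = FALSE),
              replicate(nB, fB, simplify = FALSE))
  atoms <- do.call(rbind, lapply(1:7, function(i)
    data.frame(serial = 0L, name = c("CA", "CB", "CG"), resname = "CYS",
               resno = i, chain = "A", element = "C",
               stringsAsFactors = FALSE)))
  atoms$serial <- seq_len(nrow(atoms))
  model <- structure_model(atoms, frames[[1]])
  labels <- paste0("CYS", 1:7)
  C <- diag(7); dimnames(C) <- list(labels, labels)
  C[1, 3] <- C[3, 1] <- 0.9
  C[1, 7] <- C[7, 1] <- 0.9
  corr <- structure(list(values = C, labels = labels, cutoff = NULL,
                         cutoff_mask = NULL),
                    class = "correlation_matrix")
  truth <- data.frame(
    path = c("CYS1=>CYS3=>CYS5", "CYS1=>CYS7=>CYS5"),
    frequency = c(nA, nB) / n_frames, stringsAsFactors = FALSE)
  truth <- truth[truth$frequency > 0, , drop = FALSE]
  list(trajectory = trajectory(model, frames, frame_interval),
       correlation = corr, truth = truth,
       source = "CYS1", target = "CYS5")
}

#' Synthetic strand-opening trajectory
#'
#' Two rigid 4-residue backbone strands (residue labels 100-103 and
#' 125-128) whose backbone geometric-center separation follows the given
#' schedule exactly along x.
#'
#' @param schedule per-frame center-center distance, \enc{Å}{Angstrom}.
#' @param frame_interval ps per frame.
#' @param seed accepted for interface uniformity (deterministic).
#' @return List: \code{trajectory}, \code{truth} (the schedule).
#' @export
gen_strand_opening <- function(schedule, frame_interval = 2, seed = 1) {
  strand_atoms <- function(labels, chain) {
    do.call(rbind, lapply(labels, function(l)
      data.frame(serial = 0L, name = c("N", "CA", "C"), resname = "GLY",
                 resno = l, chain = chain, element = c("N", "C", "C"),
                 stringsAsFactors = FALSE)))
  }
  ## strand template: 12 backbone atoms whose mean is exactly the origin
  template <- cbind(rep(c(-0.6, 0, 0.6), 4),
                    rep(seq(-4.5, 4.5, length.out = 4), each = 3), 0)
  template <- sweep(template, 2, colMeans(template))
  atoms <- rbind(strand_atoms(100:103, "A"), strand_atoms(125:128, "A"))
  atoms$serial <- seq_len(nrow(atoms))
  frames <- lapply(schedule, function(d)
    rbind(template, sweep(template, 2, c(d, 0, 0), `+`)))
  model <- structure_model(atoms, frames[[1]])
  list(trajectory = trajectory(model, frames, frame_interval),
       truth = as.numeric(schedule))
}

#' Synthetic charged/LJ toy system with brute-force reference energies
#'
#' Random non-coincident atoms with random charges and LJ/GB parameters,
#' split into two groups; the reference inter-group Coulomb and LJ
#' energies are computed by an explicit scalar double loop, independent
#' of the vectorized kernels.
#'
#' @param n_atoms total atoms (>= 2).
#' @param n_group_a size of the first group.
#' @param box edge of the placement cube, \enc{Å}{Angstrom}.
#' @param seed integer seed.
#' @return List: \code{model}, \code{params} (data.frame),
#'   \code{group_a}, \code{group_b} (index vectors), \code{reference}
#'   (list \code{ele}, \code{vdw}, kcal/mol).
#' @export
gen_charged_toy <- function(n_atoms = 20, n_group_a = 5, box = 12,
                            seed = 1) {
  if (n_group_a < 1 || n_group_a >= n_atoms)
    stopf("need 1 <= n_group_a < n_atoms")
  set.seed(seed)
  repeat {
    coords <- matrix(stats::runif(n_atoms * 3, 0, box), ncol = 3)
    d2 <- cross_dist2(coords, coords); diag(d2) <- Inf
    if (min(d2) > 1.0^2) break
  }
  params <- data.frame(serial = seq_len(n_atoms),
                       charge = stats::runif(n_atoms, -1, 1),
                       rmin2 = stats::runif(n_atoms, 1.5, 2.0),
                       eps = stats::runif(n_atoms, 0.05, 0.2),
                       gb_radius = stats::runif(n_atoms, 1.2, 2.0),
                       screen = rep(0.8, n_atoms))
  atoms <- data.frame(serial = seq_len(n_atoms), name = "C",
                      resname = "LIG", resno = seq_len(n_atoms),
                      chain = "L", element = "C", stringsAsFactors = FALSE)
  model <- structure_model(atoms, coords)
  ia <- seq_len(n_group_a); ib <- seq.int(n_group_a + 1, n_atoms)
  ele <- 0; vdw <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    ele <- ele + 332.0637 * params$charge[i] * params$charge[j] / r
    rm <- params$rmin2[i] + params$rmin2[j]
    ej <- sqrt(params$eps[i] * params$eps[j])
    vdw <- vdw + ej * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  list(model = model, params = params, group_a = ia, group_b = ib,
       reference = list(ele = ele, vdw = vdw))
}
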