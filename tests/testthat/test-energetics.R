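pt <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)

test_that("Coulomb and LJ kernels hit their analytic anchor points", {
  expect_equal(coulomb_energy(pt(0, 0, 0), pt(1, 0, 0), 1, 1), 332.0637)
  expect_equal(coulomb_energy(pt(0, 0, 0), pt(2, 0, 0), 1, -1),
               -332.0637 / 2)
  expect_equal(coulomb_energy(pt(0, 0, 0), pt(2, 0, 0), 1, 1,
                              eps_interior = 4), 332.0637 / 8)
  expect_error(coulomb_energy(pt(0, 0, 0), pt(0, 0, 0), 1, 1),
               "coincident")

  ## LJ minimum: r = Rmin_ij gives exactly -eps_ij
  expect_equal(lj_energy(pt(0, 0, 0), pt(3.8, 0, 0), 1.9, 0.1, 1.9, 0.1),
               -0.1)
  expect_equal(lj_energy(pt(0, 0, 0), pt(3.5, 0, 0), 1.5, 0.09, 2.0, 0.16),
               -sqrt(0.09 * 0.16))
  expect_lt(abs(lj_energy(pt(0, 0, 0), pt(500, 0, 0), 1.9, 0.1, 1.9, 0.1)),
            1e-12)
})

test_that("kernels match the generator's scalar double-loop reference", {
  for (seed in c(31, 32, 33)) {
    toy <- gen_charged_toy(20, 6, seed = seed)
    xa <- toy$model$coords[toy$group_a, ]
    xb <- toy$model$coords[toy$group_b, ]
    p <- toy$params
    ele <- coulomb_energy(xa, xb, p$charge[toy$group_a],
                          p$charge[toy$group_b])
    vdw <- lj_energy(xa, xb, p$rmin2[toy$group_a], p$eps[toy$group_a],
                     p$rmin2[toy$group_b], p$eps[toy$group_b])
    expect_equal(ele, toy$reference$ele, tolerance = 1e-9)
    expect_equal(vdw, toy$reference$vdw, tolerance = 1e-9)
  }
})

test_that("inter-group energies are symmetric and rigid-motion invariant", {
  toy <- gen_charged_toy(14, 7, seed = 34)
  x <- toy$model$coords; p <- toy$params
  ia <- toy$group_a; ib <- toy$group_b
  e1 <- coulomb_energy(x[ia, ], x[ib, ], p$charge[ia], p$charge[ib])
  e2 <- coulomb_energy(x[ib, ], x[ia, ], p$charge[ib], p$charge[ia])
  expect_equal(e1, e2, tolerance = 1e-12)
  xr <- sweep(x %*% rotation_xyz(1, -2, 0.5), 2, c(7, 8, 9), `+`)
  expect_equal(coulomb_energy(xr[ia, ], xr[ib, ], p$charge[ia],
                              p$charge[ib]), e1, tolerance = 1e-9)
  l1 <- lj_energy(x[ia, ], x[ib, ], p$rmin2[ia], p$eps[ia],
                  p$rmin2[ib], p$eps[ib])
  expect_equal(lj_energy(xr[ia, ], xr[ib, ], p$rmin2[ia], p$eps[ia],
                         p$rmin2[ib], p$eps[ib]), l1, tolerance = 1e-9)
})

test_that("the GB term reduces to the Born equation and its limits", {
  w <- solvent_model("water")
  got <- gb_polar_energy(pt(0, 0, 0), 1, 2, 0.8, w)
  born <- -(332.0637 / 2) * (1 - 1 / 80) * (1 / 2)
  expect_equal(got, born, tolerance = 1e-9)

  ## no dielectric contrast: zero for any system
  none <- solvent_model("custom", exterior_dielectric = 1)
  toy <- gen_charged_toy(8, 4, seed = 35)
  expect_equal(gb_polar_energy(toy$model$coords, toy$params$charge,
                               toy$params$gb_radius, toy$params$screen,
                               none), 0)

  ## additivity at vast separation
  far <- gb_polar_energy(rbind(c(0, 0, 0), c(1e6, 0, 0)), c(1, -1),
                         c(2, 1.5), c(0.8, 0.8), w)
  sep <- gb_polar_energy(pt(0, 0, 0), 1, 2, 0.8, w) +
    gb_polar_energy(pt(0, 0, 0), -1, 1.5, 0.8, w)
  expect_equal(far, sep, tolerance = 1e-3)

  ## magnitude shrinks monotonically as the dielectric drops 80 -> 1.92
  es <- vapply(c(80, 37.5, 10, 1.92), function(e)
    gb_polar_energy(toy$model$coords, toy$params$charge,
                    toy$params$gb_radius, toy$params$screen,
                    solvent_model("custom", exterior_dielectric = e)), 0)
  expect_true(all(diff(abs(es)) < 0))
  expect_error(born_radii(pt(0, 0, 0), 0.05, 0.8, offset = 0.09),
               "non-positive")
})

test_that("the nonpolar term is gamma times the accessible area", {
  m <- structure_model(data.frame(serial = 1, name = "C", resname = "LIG",
                                  resno = 1, chain = "A", element = "C"),
                       matrix(0, 1, 3))
  w <- solvent_model("water")
  expect_equal(npsolv_energy(m, solvent = w),
               0.0072 * 4 * pi * 3.1^2, tolerance = 1e-9)
  ## independent of the dielectric
  h <- solvent_model("heptane")
  expect_equal(npsolv_energy(m, solvent = h), npsolv_energy(m, solvent = w))
  expect_equal(0.0072 * 1000, 7.2)  # gamma x 1000 A^2
})

test_that("component additivity identities hold for random inputs", {
  set.seed(36)
  for (k in 1:25) {
    v <- rnorm(5, 0, 30)
    ec <- energy_components(v[1], v[2], v[3], v[4], v[5])
    expect_identical(ec$E_gas, ec$E_ele + ec$E_vdw + ec$E_int)
    expect_identical(ec$G_solv, ec$G_npsolv + ec$G_psolv)
    expect_identical(ec$G_ele, ec$E_ele + ec$G_psolv)
    expect_equal(ec$G_binding, ec$E_gas + ec$G_solv, tolerance = 1e-12)
  }
})

make_toy_traj <- function(toy, n_fr = 10, sd = 0.05, seed = 37) {
  set.seed(seed)
  frames <- lapply(seq_len(n_fr), function(f)
    toy$model$coords + matrix(rnorm(3 * nrow(toy$model$coords), 0, sd),
                              ncol = 3))
  trajectory(toy$model, frames, 2)
}

test_that("binding energy equals a frame-by-frame recomputation", {
  toy <- gen_charged_toy(25, 5, seed = 38)
  tr <- make_toy_traj(toy)
  w <- solvent_model("water")
  be <- binding_energy(tr, toy$group_b, toy$group_a, toy$params, w,
                       n_points = 120)
  ## independent recomputation from the primitives, frame by frame
  p <- toy$params
  ele <- vdw <- ps <- np <- numeric(10)
  for (f in 1:10) {
    xyz <- tr$frames[[f]]
    xa <- xyz[toy$group_a, ]; xb <- xyz[toy$group_b, ]
    ele[f] <- coulomb_energy(xb, xa, p$charge[toy$group_b],
                             p$charge[toy$group_a])
    vdw[f] <- lj_energy(xb, xa, p$rmin2[toy$group_b], p$eps[toy$group_b],
                        p$rmin2[toy$group_a], p$eps[toy$group_a])
    all_i <- c(toy$group_b, toy$group_a)
    ps[f] <- gb_polar_energy(xyz[all_i, ], p$charge[all_i],
                             p$gb_radius[all_i], p$screen[all_i], w) -
      gb_polar_energy(xb, p$charge[toy$group_b], p$gb_radius[toy$group_b],
                      p$screen[toy$group_b], w) -
      gb_polar_energy(xa, p$charge[toy$group_a], p$gb_radius[toy$group_a],
                      p$screen[toy$group_a], w)
    V <- immopsn:::principal_frame(xyz[all_i, ])
    np[f] <- 0.0072 * (sasa(toy$model, all_i, probe = 1.4, n_points = 120,
                            coords = xyz, frame = V)$total -
                         sasa(toy$model, toy$group_b, probe = 1.4,
                              n_points = 120, coords = xyz,
                              frame = V)$total -
                         sasa(toy$model, toy$group_a, probe = 1.4,
                              n_points = 120, coords = xyz,
                              frame = V)$total)
  }
  expect_equal(be$E_ele, mean(ele), tolerance = 1e-9)
  expect_equal(be$E_vdw, mean(vdw), tolerance = 1e-9)
  expect_equal(be$G_psolv, mean(ps), tolerance = 1e-9)
  expect_equal(be$G_npsolv, mean(np), tolerance = 1e-9)
  ## single-trajectory protocol: the internal term is identically zero
  expect_identical(be$E_int, 0)
  expect_equal(be$se$E_ele, sd(ele) / sqrt(10), tolerance = 1e-9)
  expect_error(binding_energy(tr, toy$group_b, c(toy$group_a, toy$group_b[1]),
                              toy$params, w), "overlap")
  expect_warning(binding_energy(tr, toy$group_b, toy$group_a, toy$params, w,
                                snapshots = 50, n_points = 60), "using all")
})

test_that("an inert, distant ligand binds with vanishing energy", {
  n <- 8
  coords <- rbind(matrix(runif(15, 0, 5), ncol = 3),
                  matrix(runif(9, 0, 5), ncol = 3) + 500)
  atoms <- data.frame(serial = 1:n, name = "C", resname = "LIG",
                      resno = 1:n, chain = "A", element = "C",
                      stringsAsFactors = FALSE)
  m <- structure_model(atoms, coords)
  params <- data.frame(serial = 1:n, charge = 0, rmin2 = 1.9,
                       eps = c(rep(0.1, 5), rep(0, 3)),
                       gb_radius = 1.7, screen = 0.72)
  tr <- trajectory(m, list(coords), 2)
  be <- binding_energy(tr, 1:5, 6:8, params, solvent_model("water"),
                       n_points = 120)
  expect_equal(be$G_binding, 0, tolerance = 1e-6)
})

test_that("per-residue decomposition conserves every component", {
  toy <- gen_charged_toy(24, 6, seed = 39)
  tr <- make_toy_traj(toy, n_fr = 4)
  h <- solvent_model("heptane")
  be <- binding_energy(tr, toy$group_b, toy$group_a, toy$params, h,
                       n_points = 120)
  dec <- per_residue_decomposition(tr, toy$group_b, toy$group_a,
                                   toy$params, h, n_points = 120)
  expect_equal(sum(dec$ele), be$E_ele, tolerance = 1e-6)
  expect_equal(sum(dec$vdw), be$E_vdw, tolerance = 1e-6)
  expect_equal(sum(dec$psolv), be$G_psolv, tolerance = 1e-6)
  expect_equal(sum(dec$npsolv), be$G_npsolv, tolerance = 1e-6)
  expect_equal(sum(dec$total), be$G_binding, tolerance = 1e-6)
  expect_type(dec$above_threshold, "logical")
})

test_that("a single-residue receptor owns the whole receptor share", {
  ## 2 atoms in one residue + single-atom ligand residue
  atoms <- data.frame(serial = 1:3, name = c("CB", "CG", "C"),
                      resname = c("LEU", "LEU", "LIG"),
                      resno = c(1L, 1L, 9L), chain = c("A", "A", "L"),
                      element = "C", stringsAsFactors = FALSE)
  coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(5, 0, 0))
  m <- structure_model(atoms, coords)
  params <- data.frame(serial = 1:3, charge = c(0.3, -0.2, 0.5),
                       rmin2 = 1.9, eps = 0.1, gb_radius = 1.7,
                       screen = 0.72)
  tr <- trajectory(m, list(coords), 2)
  w <- solvent_model("water")
  be <- binding_energy(tr, 1:2, 3, params, w, n_points = 240)
  dec <- per_residue_decomposition(tr, 1:2, 3, params, w, n_points = 240)
  expect_equal(sum(dec$total), be$G_binding, tolerance = 1e-9)
  expect_equal(nrow(dec), 2L)  # one receptor residue + the ligand
})

test_that("parameter tables round-trip and validate", {
  toy <- gen_charged_toy(6, 3, seed = 40)
  f <- tempfile(fileext = ".tsv")
  write_table(toy$params, f)
  back <- read_params_tsv(f)
  expect_equal(back$charge, toy$params$charge)
  bad <- toy$params; bad$eps[2] <- -1
  write_table(bad, f)
  expect_error(read_params_tsv(f), "epsilon")
  expect_equal(nrow(cnt_params(5)), 5L)
  expect_true(all(cnt_params(5)$charge == 0))
})
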