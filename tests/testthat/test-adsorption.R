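## Fixture: flat "surface" of atoms at z = 0 plus protein atoms at
## prescribed heights, so minimum distances are known exactly.
slab_fixture <- function(heights, names = rep("CA", length(heights)),
                         elements = rep("C", length(heights))) {
  ns <- 25
  g <- expand.grid(x = 1:5, y = 1:5)
  surf <- data.frame(serial = seq_len(ns), name = "C", resname = "CNT",
                     resno = 1L, chain = "X", element = "C",
                     stringsAsFactors = FALSE)
  np <- length(heights)
  prot <- data.frame(serial = ns + seq_len(np), name = names,
                     resname = "ALA", resno = seq_len(np), chain = "A",
                     element = elements, stringsAsFactors = FALSE)
  coords <- rbind(cbind(g$x * 2, g$y * 2, 0),
                  cbind(6, 6, heights))
  structure_model(rbind(surf, prot), coords,
                  groups = list(cnt = seq_len(ns),
                                enzyme = ns + seq_len(np)))
}

test_that("adsorbed-atom count matches a brute-force distance scan", {
  h <- c(seq(3, 5.9, length.out = 7), seq(6.1, 9, length.out = 5))
  m <- slab_fixture(h)
  got <- count_adsorbed(m)
  ## brute force over all protein/surface pairs
  dmin <- apply(cross_dist(m$coords[m$groups$enzyme, ],
                           m$coords[m$groups$cnt, ]), 1, min)
  expect_equal(got, sum(dmin <= 6))
  expect_equal(got, 7L)
  expect_equal(count_adsorbed(slab_fixture(rep(20, 4))), 0L)
})

test_that("hydrogens are excluded unless asked for", {
  m <- slab_fixture(c(3, 3), names = c("CA", "H1"),
                    elements = c("C", "H"))
  expect_equal(count_adsorbed(m), 1L)
  expect_equal(count_adsorbed(m, heavy_only = FALSE), 2L)
})

test_that("the count is monotone non-decreasing in the cutoff", {
  set.seed(8)
  m <- slab_fixture(runif(30, 1, 15))
  counts <- vapply(seq(2, 12, by = 0.5), function(cc)
    count_adsorbed(m, cutoff = cc), 0L)
  expect_true(all(diff(counts) >= 0L))
})

test_that("the series reproduces the generator schedule and reverses", {
  sched <- c(0, 7, 13, 13, 2)
  g <- gen_adsorption(sched, n_beads = 20, seed = 5)
  s <- adsorption_series(g$trajectory, contact = FALSE)
  expect_equal(s$adsorbed_counts, sched)
  expect_equal(s$times, (seq_along(sched) - 1) * 2)

  rev_traj <- trajectory(g$trajectory$model, rev(g$trajectory$frames),
                         g$trajectory$frame_interval)
  expect_equal(adsorption_series(rev_traj, contact = FALSE)$adsorbed_counts,
               rev(sched))

  static <- trajectory(g$trajectory$model,
                       rep(g$trajectory$frames[2], 3), 2)
  s2 <- adsorption_series(static, n_points = 60)
  expect_equal(s2$adsorbed_counts, rep(7L, 3))
  expect_equal(diff(range(s2$contact_areas)), 0)
})

test_that("density grid bins conservatively and respects the stride", {
  ## static single atom: all observations in one voxel
  m <- bead_grid_model(2)
  tr <- trajectory(m, rep(list(m$coords), 5), 2)
  g <- density_grid(tr, "residues 1", "all")
  expect_equal(sum(g$counts), 5L)
  expect_equal(sum(g$counts > 0), 1L)

  expect_error(density_grid(tr, "residues 1", "all", stride_ps = 3),
               "stride")
  g2 <- density_grid(tr, "residues 1-4", "all", stride_ps = 4)
  expect_equal(sum(g2$counts), 3L * 4L)  # 3 used frames x 4 atoms

  gp <- density_grid(tr, "residues 1-4", "all",
                     normalization = "probability")
  expect_equal(sum(gp$counts), 1)
})

test_that("fitting removes rigid motion before binning", {
  set.seed(9)
  m <- bead_grid_model(3)
  base <- m$coords + cbind(0.13, 0.07, runif(9))
  frames <- lapply(1:6, function(f) {
    R <- rotation_xyz(0.1 * f, -0.05 * f, 0.2 * f)
    sweep(base %*% R, 2, c(f, 2 * f, -f), `+`)
  })
  tr <- trajectory(m, frames, 2)
  g <- density_grid(tr, "all", "all")
  ## every atom stays in its own voxel across all fitted frames
  expect_equal(sum(g$counts > 0), 9L)
  expect_true(all(g$counts[g$counts > 0] == 6L))
})

test_that("uniform occupancy is statistically uniform across voxels", {
  set.seed(123)
  n_at <- 100; n_fr <- 1000
  anchors <- rbind(c(-20, 0, 0), c(0, -20, 0), c(0, 0, -20))
  atoms <- data.frame(serial = 1:(3 + n_at), name = "CA", resname = "ALA",
                      resno = 1:(3 + n_at), chain = "A", element = "C",
                      stringsAsFactors = FALSE)
  frames <- lapply(seq_len(n_fr), function(f)
    rbind(anchors, matrix(runif(n_at * 3, 0, 8), ncol = 3)))
  m <- structure_model(atoms, frames[[1]],
                       groups = list(anchor = 1:3,
                                     cloud = 3 + seq_len(n_at)))
  tr <- trajectory(m, frames, 2)
  g <- density_grid(tr, "group:cloud", "group:anchor", voxel = 2)
  counts <- as.vector(g$counts)
  expect_equal(sum(counts), n_at * n_fr)
  expect_length(counts, 64L)
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 0.001)
})
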