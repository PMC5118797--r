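## Hand-built 4-residue fixture with two-atom side chains at chosen
## separations.
four_res_model <- function(centers) {
  atoms <- do.call(rbind, lapply(1:4, function(i)
    data.frame(serial = 0L, name = c("CA", "CB", "CG"), resname = "LEU",
               resno = i, chain = "A", element = "C",
               stringsAsFactors = FALSE)))
  atoms$serial <- seq_len(nrow(atoms))
  coords <- do.call(rbind, lapply(1:4, function(i) {
    ct <- centers[i, ]
    rbind(ct + c(0, 1.2, 0), ct + c(0, 0, 0.25), ct - c(0, 0, 0.25))
  }))
  structure_model(atoms, coords)
}

test_that("interaction strength follows its defining formula", {
  expect_equal(interaction_strength(0, 50, 50), 0)
  expect_equal(interaction_strength(4, 100, 100), 4)
  set.seed(24)
  for (k in 1:20) {
    n <- sample(0:12, 1); Ni <- runif(1, 10, 120); Nj <- runif(1, 10, 120)
    expect_equal(interaction_strength(n, Ni, Nj), 100 * n / sqrt(Ni * Nj))
  }
  expect_error(interaction_strength(1, 0, 50), "> 0")
  ## scale covariance: doubling all N divides I by 2 exactly
  expect_equal(interaction_strength(5, 80, 60),
               2 * interaction_strength(5, 160, 120))
})

test_that("side-chain pair counts match a brute-force double loop", {
  m <- four_res_model(rbind(c(0, 0, 0), c(4.9, 0, 0), c(40, 0, 0),
                            c(60, 0, 0)))
  ## residues 1-2: side-chain atoms 4.9 apart in x, z offsets 0 / +/-0.5
  got <- count_sidechain_pairs(m, 0, 1)
  sc1 <- which(m$atoms$residue_index == 0 & m$atoms$name != "CA")
  sc2 <- which(m$atoms$residue_index == 1 & m$atoms$name != "CA")
  brute <- 0L
  for (a in sc1) for (b in sc2)
    if (sqrt(sum((m$coords[a, ] - m$coords[b, ])^2)) <= 5) brute <- brute + 1L
  expect_equal(got, brute)
  expect_equal(got, 4L)
  expect_equal(count_sidechain_pairs(m, 0, 2), 0L)  # 40 apart
  expect_error(count_sidechain_pairs(m, 1, 1), "distinct")
})

test_that("glycine contributes its C-alpha as side-chain proxy", {
  atoms <- data.frame(serial = 1:4,
                      name = c("CA", "CA", "CB", "CG"),
                      resname = c("GLY", "ALA", "ALA", "ALA"),
                      resno = c(1L, 3L, 3L, 3L), chain = "A",
                      element = "C", stringsAsFactors = FALSE)
  coords <- rbind(c(0, 0, 0), c(10, 0, 0), c(4, 0, 0), c(30, 0, 0))
  m <- structure_model(atoms, coords)
  expect_equal(count_sidechain_pairs(m, 0, 1), 1L)
})

test_that("network edges agree with exhaustive pair evaluation", {
  centers <- rbind(c(0, 0, 0), c(4.5, 0, 0), c(4.5, 4.5, 0), c(20, 0, 0))
  m <- four_res_model(centers)
  nt <- psn_norm_table()
  N_leu <- unname(nt["LEU"])
  net <- build_network(m, i_min = 0.5)
  ## brute force: all non-adjacent residue pairs
  brute <- list()
  for (a in 0:2) for (b in (a + 1):3) {
    if (b - a == 1) next
    n <- count_sidechain_pairs(m, a, b)
    I <- interaction_strength(n, N_leu, N_leu)
    if (n > 0 && I >= 0.5)
      brute[[length(brute) + 1]] <- c(paste0("LEU", a + 1),
                                      paste0("LEU", b + 1))
  }
  want <- vapply(brute, paste, collapse = " ", "")
  expect_setequal(paste(net$edges$i, net$edges$j), want)

  ## sequence-adjacent pairs never form edges even in contact
  expect_false(any(abs(as.integer(sub("LEU", "", net$edges$i)) -
                         as.integer(sub("LEU", "", net$edges$j))) == 1))
})

test_that("raising i_min only removes edges, never adds", {
  centers <- rbind(c(0, 0, 0), c(4.5, 0, 0), c(4.2, 4.2, 0), c(3, -4, 0))
  m <- four_res_model(centers)
  prev <- Inf
  for (im in c(0.5, 2, 4, 8, 1000)) {
    ne <- nrow(build_network(m, i_min = im)$edges)
    expect_lte(ne, prev)
    prev <- ne
  }
  expect_equal(nrow(build_network(m, i_min = 1000)$edges), 0L)
})

test_that("shortest paths equal brute-force enumeration on random graphs", {
  set.seed(25)
  for (k in 1:50) {
    n <- sample(4:12, 1)
    adj <- matrix(rbinom(n * n, 1, 0.3), n)
    adj[lower.tri(adj, diag = TRUE)] <- 0
    adj <- adj + t(adj)
    net <- adj_to_network(adj)
    st <- sample(n, 2)
    got <- shortest_paths_psn(net, paste0("R", st[1]), paste0("R", st[2]))
    want <- brute_min_paths(adj, st[1], st[2])
    got_keys <- sort(vapply(got, paste, collapse = "-", ""))
    want_keys <- sort(vapply(want, function(p)
      paste(paste0("R", p), collapse = "-"), ""))
    expect_equal(got_keys, want_keys)
    if (length(got)) {
      len <- vapply(got, length, 0L)
      expect_true(all(len == len[1]))  # all returned paths are minimal
    }
  }
  net <- adj_to_network(rbind(c(0, 1), c(1, 0)))
  expect_equal(shortest_paths_psn(net, "R1", "R2"), list(c("R1", "R2")))
  expect_error(shortest_paths_psn(net, "R9", "R1"), "unknown node")
})

test_that("the correlation filter keeps exactly correlated-bridge paths", {
  C <- diag(4)
  dimnames(C) <- list(paste0("R", 1:4), paste0("R", 1:4))
  C[2, 1] <- C[1, 2] <- 0.5
  paths <- list(c("R1", "R2", "R4"),   # intermediate R2 correlates source
                c("R1", "R3", "R4"),   # intermediate uncorrelated
                c("R1", "R4"))         # direct: no intermediate
  kept <- filter_paths_by_correlation(paths, C)
  expect_equal(kept, paths[1])
  ## brute-force predicate agreement on random fixtures
  set.seed(26)
  for (k in 1:20) {
    Cr <- matrix(runif(36, -1, 1), 6); Cr <- (Cr + t(Cr)) / 2; diag(Cr) <- 1
    dimnames(Cr) <- list(paste0("R", 1:6), paste0("R", 1:6))
    p <- paste0("R", sample(6, 4))
    keep <- any(abs(Cr[p[2:3], p[1]]) >= 0.4 |
                  abs(Cr[p[2:3], p[4]]) >= 0.4)
    expect_equal(length(filter_paths_by_correlation(list(p), Cr)) == 1, keep)
  }
})

test_that("two-state trajectories yield exact path frequencies", {
  for (split in list(c(0.6, 0.4), c(0.8, 0.2), c(0.95, 0.05))) {
    ts <- gen_two_state_contacts(n_frames = 20, split = split)
    ps <- path_statistics(ts$trajectory,
                          data.frame(source = ts$source,
                                     target = ts$target),
                          corr = ts$correlation,
                          window = seq_len(20))
    ens <- ps$ensembles[[1]]
    expect_equal(ens$path, ts$truth$path)
    expect_equal(ens$frequency, ts$truth$frequency)
    expect_equal(ens$dominant, ts$truth$frequency > 0.30)
    expect_lte(sum(ens$frequency), 1 + 1e-12)
  }
  ## at dominance 0.5 only the majority path survives for the 60/40 split
  ts <- gen_two_state_contacts(n_frames = 20, split = c(0.6, 0.4))
  ps <- path_statistics(ts$trajectory,
                        data.frame(source = ts$source, target = ts$target),
                        corr = ts$correlation, dominance = 0.5,
                        window = seq_len(20))
  expect_equal(ps$ensembles[[1]]$dominant, c(TRUE, FALSE))
  expect_equal(ps$n_dominant_combinations, 1L)
  ## static trajectory: the single retained path has frequency 1
  st <- gen_two_state_contacts(n_frames = 10, split = c(1, 0))
  pss <- path_statistics(st$trajectory,
                         data.frame(source = st$source, target = st$target),
                         corr = st$correlation, window = seq_len(10))
  expect_equal(pss$ensembles[[1]]$frequency, 1)
  ## aggregate counts equal a recount over the stored ensembles
  recount <- sum(vapply(ps$ensembles, function(e) sum(e$dominant), 0L))
  expect_equal(ps$n_dominant_combinations, recount)
  ## node visit frequencies include the bridge residue
  expect_true("CYS3" %in% names(ps$node_frequency))
})

test_that("desorbed residues are the reference contacts that left", {
  g <- gen_adsorption(c(9, 4), n_beads = 12, seed = 27)
  tr <- g$trajectory
  dn <- desorption_nodes(tr$model, tr$frames[[1]], tr$frames[[2]])
  expect_length(dn$adsorbed, 9L)
  ## brute-force recomputation
  brute_set <- function(xyz) {
    ip <- tr$model$groups$enzyme
    is <- tr$model$groups$cnt
    near <- vapply(ip, function(a)
      min(sqrt(colSums((t(xyz[is, ]) - xyz[a, ])^2))) <= 6, TRUE)
    rr <- tr$model$residues
    ri <- unique(tr$model$atoms$residue_index[ip[near]])
    paste0(rr$resname, rr$label)[match(ri, rr$residue_index)]
  }
  a1 <- brute_set(tr$frames[[1]]); a2 <- brute_set(tr$frames[[2]])
  expect_setequal(dn$adsorbed, a1)
  expect_setequal(dn$desorbed, setdiff(a1, a2))
  ## identical frames: nothing desorbs
  same <- desorption_nodes(tr$model, tr$frames[[1]], tr$frames[[1]])
  expect_length(same$desorbed, 0L)
})
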