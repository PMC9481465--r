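test_that("force-to-energy map: intercept, ordering, floor", {
  expect_equal(force_to_contact_energy(0), 16)
  expect_equal(force_to_contact_energy(100), 1)
  # stronger measured adhesion gives the cheaper interface
  expect_lt(force_to_contact_energy(1.94), force_to_contact_energy(0.57))
  expect_error(force_to_contact_energy(-1), ">= 0")
})

test_that("contact-energy matrix is symmetric with configured medium row", {
  cfg <- default_config()
  f <- c(`ES-ES` = 1.94, `TS-ES` = 0.57, `XEN-ES` = 0.83, `TS-TS` = 2.2,
         `XEN-TS` = 0.46, `XEN-XEN` = 0.55)
  J <- contact_energy_matrix(f, cfg)
  expect_true(isSymmetric(J))
  expect_equal(J["ES", "TS"], 16 - 5 * 0.57)
  expect_equal(J["ES", "Medium"], cfg$j_medium$ES)
  expect_equal(J["Medium", "Medium"], 0)
  expect_error(contact_energy_matrix(f[-2], cfg), "ES-TS")
})

test_that("hamiltonian: all-medium lattice, single-cell closed form, oracle", {
  J <- test_J()
  # uniform medium: no boundaries, no constrained cells
  empty <- new_lattice(matrix(0L, 10, 10), integer(0))
  expect_equal(hamiltonian(empty, J, test_params()), 0)

  # 2x2 cell, targets met exactly: energy is the boundary term alone
  g <- matrix(0L, 6, 6); g[3:4, 3:4] <- 1L
  lat <- new_lattice(g, 1L)
  p <- test_params(lambda_a = 1, lambda_p = 1, target_a = 4, target_p = 8)
  Jc <- matrix(1, 4, 4); Jc[4, 4] <- 0
  h <- hamiltonian(lat, Jc, p)
  # each of the 4 sites has 5 Moore neighbours outside the block: 20 links
  expect_equal(h, 20)
  expect_equal(h, oracle_hamiltonian(lat, Jc, p))

  # random lattices match the independent global recomputation
  for (s in 1:10) {
    lat <- random_lattice(n = 14, n_cells = 5, seed = s)
    expect_equal(hamiltonian(lat, J, test_params()),
                 oracle_hamiltonian(lat, J, test_params()),
                 tolerance = 1e-9)
  }
  bad <- new_lattice(matrix(c(0L, 1L, 0L, 0L), 2, 2), 1L)
  bad$cell_type <- 9L
  expect_error(hamiltonian(bad, J, test_params()), "unknown type")
})

test_that("local delta-H equals the global energy difference", {
  J <- test_J()
  prm <- test_params()
  set.seed(31)
  for (case in 1:150) {
    lat <- random_lattice(n = 12, n_cells = 4, seed = case)
    i <- sample(nrow(lat$grid), 1); j <- sample(ncol(lat$grid), 1)
    # candidate drawn from the Moore neighbourhood, as in the dynamics
    di <- sample(-1:1, 1); dj <- sample(-1:1, 1)
    ii <- min(max(i + di, 1), 12); jj <- min(max(j + dj, 1), 12)
    cand <- lat$grid[ii, jj]
    dh <- delta_h(lat, i, j, cand, J, prm)
    after <- lat
    after$grid[i, j] <- cand
    ref <- hamiltonian(after, J, prm) - hamiltonian(lat, J, prm)
    if (is.na(dh)) {
      # forbidden: the copy would have annihilated a cell's last site
      old <- lat$grid[i, j]
      expect_true(old != 0L && sum(lat$grid == old) == 1L)
    } else {
      expect_equal(dh, ref, tolerance = 1e-9)
    }
  }
})

test_that("no-op copies cost nothing and last-site annihilation is blocked", {
  g <- matrix(0L, 5, 5); g[3, 3] <- 1L
  lat <- new_lattice(g, 1L)
  J <- test_J(); prm <- test_params()
  expect_equal(delta_h(lat, 2, 2, 0L, J, prm), 0)         # medium -> medium
  expect_true(is.na(delta_h(lat, 3, 3, 0L, J, prm)))      # last site
})

test_that("aggregate initialization is exact, contiguous and seeded", {
  cfg <- default_config()
  lat <- initialize_aggregate(c(ES = 6, TS = 14, XEN = 5), cfg, seed = 2)
  expect_equal(length(lat$cell_type), 25L)
  expect_equal(sum(lat$cell_type == 1L), 6L)
  expect_equal(sum(lat$cell_type == 2L), 14L)
  expect_equal(sum(lat$cell_type == 3L), 5L)
  for (id in 1:25) {
    mask <- (lat$grid == id) * 1L
    expect_equal(oracle_components(mask, 2L), 1L)
  }
  lat2 <- initialize_aggregate(c(ES = 6, TS = 14, XEN = 5), cfg, seed = 2)
  expect_identical(lat$grid, lat2$grid)
  expect_identical(lat$cell_type, lat2$cell_type)

  single <- initialize_aggregate(c(ES = 1, TS = 0, XEN = 0), cfg, seed = 1)
  expect_equal(length(single$cell_type), 1L)
  ctr_mass <- which(single$grid == 1L, arr.ind = TRUE)
  expect_equal(colMeans(ctr_mass), c(row = 40.5, col = 40.5),
               tolerance = 0.05)

  small <- cfg; small$lattice$width <- 20L; small$lattice$height <- 20L
  expect_error(initialize_aggregate(c(ES = 6, TS = 14, XEN = 5), small, 1),
               "do not fit")
})

test_that("simulation runs are seeded, conservative and energy-consistent", {
  cfg <- default_config()
  cfg$lattice$width <- 50L; cfg$lattice$height <- 50L
  cfg$cells <- list(ES = 3L, TS = 5L, XEN = 2L)
  cfg$n_mcs <- 300L; cfg$record_every <- 100L
  traj <- run_simulation(cfg, seed = 4)
  expect_s3_class(traj, "cpm_trajectory")
  expect_equal(traj$mcs[1], 0L)
  expect_true(all(diff(traj$mcs) > 0))
  # recorded energies re-derivable from the snapshots
  for (i in seq_along(traj$snapshots)) {
    expect_equal(traj$energies[i],
                 hamiltonian(traj$snapshots[[i]], traj$params$J,
                             traj$params$type_params,
                             cfg$lattice$neighbourhood),
                 tolerance = 1e-6)
  }
  # cell-count conservation: every id keeps at least one site
  for (snap in traj$snapshots) {
    expect_setequal(unique(as.vector(snap$grid[snap$grid > 0L])), 1:10)
  }
  # bit-exact reproducibility
  traj2 <- run_simulation(cfg, seed = 4)
  expect_identical(traj$snapshots[[length(traj$snapshots)]]$grid,
                   traj2$snapshots[[length(traj2$snapshots)]]$grid)
  # zero steps: initial state only
  cfg0 <- cfg; cfg0$n_mcs <- 0L
  expect_length(run_simulation(cfg0, seed = 1)$snapshots, 1L)
})

test_that("zero-temperature quench relaxes an oversized cell toward target", {
  g <- matrix(0L, 30, 30); g[8:23, 8:23] <- 1L   # area 256 >> target 24
  lat <- new_lattice(g, 1L)
  cfg <- default_config()
  cfg$lattice$width <- 30L; cfg$lattice$height <- 30L
  cfg$temperature <- 0
  cfg$n_mcs <- 60L; cfg$record_every <- 10L
  traj <- run_simulation(cfg, seed = 3, initial = lat)
  expect_true(all(diff(traj$energies) <= 1e-9))
  expect_lt(traj$energies[length(traj$energies)], traj$energies[1])
})

test_that("two-type differential adhesion drives Steinberg sorting", {
  # heterotypic contact costlier than the homotypic average: long runs
  # must shrink the heterotypic boundary from the mixed start
  cfg <- default_config()
  cfg$lattice$width <- 60L; cfg$lattice$height <- 60L
  cfg$cells <- list(ES = 8L, TS = 8L, XEN = 0L)
  cfg$n_mcs <- 2000L; cfg$record_every <- 2000L
  J <- test_J()
  J["ES", "TS"] <- J["TS", "ES"] <- 14   # > (6 + 5) / 2
  lat0 <- initialize_aggregate(unlist(cfg$cells), cfg, seed = 6)
  traj <- run_simulation(cfg, J = J, seed = 6, initial = lat0)
  before <- contact_lengths(lat0)["ES", "TS"]
  after <- contact_lengths(
    traj$snapshots[[length(traj$snapshots)]])["ES", "TS"]
  expect_lt(after, before)
})
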