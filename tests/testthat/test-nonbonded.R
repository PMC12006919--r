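test_that("cell grid assigns every particle to exactly one cell", {
  g1 <- build_cell_grid(matrix(c(1, 2, 3), 1), 10)
  expect_length(g1$cells, 1)
  expect_equal(g1$cells[[1]], 1L)
  far <- rbind(c(0, 0, 0), c(100, 0, 0))
  g2 <- build_cell_grid(far, 10)
  expect_length(g2$cells, 2)
  set.seed(31)
  close_cloud <- matrix(runif(30, 0, 4), 10, 3)
  g3 <- build_cell_grid(close_cloud, 10)
  expect_length(g3$cells, 1)
  expect_length(g3$cells[[1]], 10)
  expect_error(build_cell_grid(rbind(c(NA, 0, 0)), 5), "finite")
  expect_error(build_cell_grid(far, -1), "positive")
})

test_that("cell-grid neighbour pairs equal the brute-force oracle", {
  set.seed(32)
  for (rep in 1:8) {
    coords <- random_cloud(100, box = 30)
    for (cutoff in c(6, 8, 12)) {
      grid <- build_cell_grid(coords, cell_size = cutoff)
      expect_identical(neighbor_pairs(grid, coords, cutoff),
                       aenm:::brute_force_pairs(coords, cutoff))
    }
  }
})

test_that("exclusions remove spring pairs from the neighbour list", {
  set.seed(33)
  coords <- random_cloud(60, box = 25)
  sys <- toy_system(coords)
  net <- build_springs(sys, cutoff = 8)
  grid <- build_cell_grid(coords, 12)
  pairs <- neighbor_pairs(grid, coords, 12,
                          exclusions = cbind(net$springs$i, net$springs$j))
  got <- paste(pairs[, 1], pairs[, 2])
  excluded <- paste(net$springs$i, net$springs$j)
  expect_length(intersect(got, excluded), 0)
  # and with no exclusions the union is restored
  all_pairs <- neighbor_pairs(grid, coords, 12)
  expect_equal(nrow(all_pairs), nrow(pairs) + nrow(net$springs))
})

test_that("a cutoff above the cell size is a contract violation", {
  coords <- random_cloud(10)
  grid <- build_cell_grid(coords, cell_size = 5)
  expect_error(neighbor_pairs(grid, coords, 6), "cell_size")
})

test_that("single-particle systems yield empty pair lists", {
  one <- matrix(0, 1, 3)
  grid <- build_cell_grid(one, 5)
  expect_equal(nrow(neighbor_pairs(grid, one, 5)), 0)
})

test_that("Lennard-Jones minimum sits at contact distance with depth -epsilon", {
  coords <- rbind(c(0, 0, 0), c(3.3, 0, 0))  # d = r1 + r2 = 3.3
  pairs <- cbind(1L, 2L)
  ef <- lj_energy_forces(pairs, coords, radii = c(1.6, 1.7),
                         epsilons = c(0.2, 0.2), cutoff = Inf)
  expect_equal(ef$energy, -0.2)
  expect_lt(max(abs(ef$forces)), 1e-12)
  # beyond the minimum the tail is attractive and approaches zero from below
  far <- rbind(c(0, 0, 0), c(8, 0, 0))
  ef2 <- lj_energy_forces(pairs, far, c(1.6, 1.7), c(0.2, 0.2), cutoff = Inf)
  expect_lt(ef2$energy, 0)
  expect_gt(ef2$energy, -0.05)
  expect_lt(ef2$forces[2, 1], 0)  # pulled back toward the partner at -x
})

test_that("truncated potentials are shifted to exactly zero at the cutoff", {
  pairs <- cbind(1L, 2L)
  at_cut <- rbind(c(0, 0, 0), c(12, 0, 0))
  lj <- lj_energy_forces(pairs, at_cut, c(2, 2), c(0.3, 0.3), cutoff = 12)
  expect_equal(lj$energy, 0)
  co <- coulomb_energy_forces(pairs, at_cut, c(1, -1), cutoff = 12)
  expect_equal(co$energy, 0)
})

test_that("Coulomb energy follows k_e q1 q2 / (eps_r d)", {
  pairs <- cbind(1L, 2L)
  coords <- rbind(c(0, 0, 0), c(10, 0, 0))
  ef <- coulomb_energy_forces(pairs, coords, charges = c(1, -1),
                              dielectric = 1, cutoff = Inf)
  expect_equal(ef$energy, -33.20637)
  same <- coulomb_energy_forces(pairs, coords, charges = c(1, 1),
                                dielectric = 1, cutoff = Inf)
  expect_equal(same$energy, 33.20637)
  expect_gt(same$forces[2, 1], 0)  # repulsive
  # dielectric screening divides the energy
  scr <- coulomb_energy_forces(pairs, coords, c(1, 1), dielectric = 10,
                               cutoff = Inf)
  expect_equal(scr$energy, 3.320637)
  neutral <- coulomb_energy_forces(pairs, coords, charges = c(0, 1),
                                   cutoff = Inf)
  expect_equal(neutral$energy, 0)
  expect_equal(max(abs(neutral$forces)), 0)
  expect_error(coulomb_energy_forces(pairs, coords, c(1, 1), dielectric = 0),
               "dielectric")
})

test_that("non-bonded forces match numerical gradients and sum to zero", {
  set.seed(34)
  for (rep in 1:5) {
    n <- 12
    coords <- random_cloud(n, box = 14)
    radii <- runif(n, 1.5, 3)
    eps <- runif(n, 0.1, 0.3)
    q <- rnorm(n)
    pairs <- aenm:::brute_force_pairs(coords, 12)
    lj <- lj_energy_forces(pairs, coords, radii, eps, cutoff = 12)
    expect_lt(grad_rel_err(function(cc)
      lj_energy_forces(pairs, cc, radii, eps, 12)$energy,
      lj$forces, coords), 1e-6)
    # Newton's third law, relative to the force scale (steric overlaps in
    # a random cloud can make individual forces huge)
    expect_lt(max(abs(colSums(lj$forces))) / max(abs(lj$forces), 1), 1e-10)
    co <- coulomb_energy_forces(pairs, coords, q, cutoff = 12)
    expect_lt(grad_rel_err(function(cc)
      coulomb_energy_forces(pairs, cc, q, cutoff = 12)$energy,
      co$forces, coords), 1e-6)
    expect_lt(max(abs(colSums(co$forces))), 1e-9)
  }
})

test_that("coincident non-bonded particles are rejected", {
  pairs <- cbind(1L, 2L)
  coords <- matrix(0, 2, 3)
  expect_error(lj_energy_forces(pairs, coords, c(1, 1), c(0.1, 0.1), 12),
               "zero")
  expect_error(coulomb_energy_forces(pairs, coords, c(1, 1)), "zero")
})
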