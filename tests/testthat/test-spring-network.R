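collinear <- function() toy_system(cbind(c(0, 5, 10), 0, 0))

test_that("springs connect all pairs within the cutoff, ties included", {
  net <- build_springs(collinear(), cutoff = 7, stiffness = 1)
  expect_equal(net$springs$i, c(1L, 2L))
  expect_equal(net$springs$j, c(2L, 3L))
  expect_equal(net$springs$rest_length, c(5, 5))
  net12 <- build_springs(collinear(), cutoff = 12, stiffness = 1)
  expect_equal(nrow(net12$springs), 3)
  expect_equal(net12$springs$rest_length[net12$springs$j - net12$springs$i == 2], 10)
  # a tie at exactly the cutoff is included
  tie <- build_springs(collinear(), cutoff = 5, stiffness = 1)
  expect_equal(nrow(tie$springs), 2)
  expect_error(build_springs(collinear(), cutoff = -1), "cutoff")
})

test_that("spring pair set equals the brute-force oracle, including the cell-grid path", {
  set.seed(21)
  for (n in c(50, 250)) {  # 250 exercises the cell-grid builder branch
    coords <- random_cloud(n, box = 40)
    sys <- toy_system(coords)
    for (cutoff in c(5, 9, 14)) {
      net <- build_springs(sys, cutoff = cutoff)
      oracle <- t(utils::combn(n, 2))
      d <- sqrt(rowSums((coords[oracle[, 1], ] - coords[oracle[, 2], ])^2))
      keep <- oracle[d <= cutoff, , drop = FALSE]
      expect_equal(cbind(net$springs$i, net$springs$j),
                   keep[order(keep[, 1], keep[, 2]), , drop = FALSE],
                   ignore_attr = TRUE)
      expect_equal(net$springs$rest_length, d[d <= cutoff],
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("within and between restrict the generated pairs", {
  sys <- toy_system(cbind(0:3 * 4, 0, 0))
  selA <- select_particles(sys, "index 1..2")
  selB <- select_particles(sys, "index 3..4")
  w <- build_springs(sys, cutoff = 20, within = selA)
  expect_equal(nrow(w$springs), 1)
  b <- build_springs(sys, cutoff = 20, between = list(selA, selB))
  expect_true(all(b$springs$i %in% 1:2 & b$springs$j %in% 3:4))
  expect_equal(nrow(b$springs), 4)
})

test_that("layer merging is a union with first-layer-wins on duplicates", {
  sys <- toy_system(cbind(c(0, 5, 10), 0, 0))
  a <- build_springs(sys, cutoff = 7, stiffness = 1, layer = "A")
  b <- build_springs(sys, cutoff = 12, stiffness = 5, layer = "B")
  m <- merge_layers(list(a, b))
  expect_equal(nrow(m$springs), 3)
  k12 <- m$springs$stiffness[m$springs$i == 1 & m$springs$j == 2]
  expect_equal(k12, 1)  # layer A declared first wins
  k13 <- m$springs$stiffness[m$springs$i == 1 & m$springs$j == 3]
  expect_equal(k13, 5)  # only present in layer B
  expect_equal(m$layer_label, "A+B")
  single <- merge_layers(list(a))
  expect_equal(single$springs, a$springs)
})

test_that("spring energy is zero at the build coordinates", {
  # the initial structure is the rest state: every spring is relaxed
  set.seed(22)
  for (rep in 1:5) {
    sys <- toy_system(random_cloud(20))
    net <- build_springs(sys, cutoff = 12)
    ef <- spring_energy_forces(net, get_coords(sys))
    expect_identical(ef$energy, 0)
    expect_lt(max(abs(ef$forces)), 1e-10)
  }
})

test_that("single-spring energetics follow K(d - d0)^2 with no 1/2 factor", {
  sys <- toy_system(rbind(c(0, 0, 0), c(5, 0, 0)))
  net <- build_springs(sys, cutoff = 6, stiffness = 1)
  stretched <- rbind(c(0, 0, 0), c(7, 0, 0))
  ef <- spring_energy_forces(net, stretched)
  expect_equal(ef$energy, 4)  # 1 * (7-5)^2
  expect_equal(ef$forces[2, 1], -4)  # restoring, magnitude 2K(d-d0)
  expect_equal(ef$forces[1, 1], 4)
  compressed <- rbind(c(0, 0, 0), c(3, 0, 0))
  ef2 <- spring_energy_forces(net, compressed)
  expect_equal(ef2$energy, 4)  # quadratic is symmetric
  expect_equal(ef2$forces[2, 1], 4)  # now pushes outward
})

test_that("spring forces are the analytic gradient and obey Newton's third law", {
  set.seed(23)
  sys <- toy_system(random_cloud(15, box = 15))
  net <- build_springs(sys, cutoff = 8)
  for (rep in 1:5) {
    coords <- get_coords(sys) + matrix(rnorm(45, sd = 0.8), 15, 3)
    ef <- spring_energy_forces(net, coords)
    expect_lt(grad_rel_err(function(cc) spring_energy_forces(net, cc)$energy,
                           ef$forces, coords), 1e-6)
    expect_lt(max(abs(colSums(ef$forces))), 1e-10)
    torque <- colSums(cbind(
      coords[, 2] * ef$forces[, 3] - coords[, 3] * ef$forces[, 2],
      coords[, 3] * ef$forces[, 1] - coords[, 1] * ef$forces[, 3],
      coords[, 1] * ef$forces[, 2] - coords[, 2] * ef$forces[, 1]))
    expect_lt(max(abs(torque)), 1e-9)
  }
})

test_that("spring energy is invariant under rigid motion", {
  set.seed(24)
  sys <- toy_system(random_cloud(12, box = 12))
  net <- build_springs(sys, cutoff = 9)
  coords <- get_coords(sys) + matrix(rnorm(36, sd = 0.5), 12, 3)
  e0 <- spring_energy_forces(net, coords)$energy
  shifted <- sweep(coords, 2, c(11, -3, 8), "+")
  expect_equal(spring_energy_forces(net, shifted)$energy, e0)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(spring_energy_forces(net, coords %*% R)$energy, e0)
})

test_that("coincident bonded pairs are rejected", {
  sys <- toy_system(rbind(c(0, 0, 0), c(1, 0, 0)))
  net <- build_springs(sys, cutoff = 2)
  expect_error(spring_energy_forces(net, matrix(0, 2, 3)), "oincident")
})

test_that("spring networks serialize and read back bit-exactly", {
  set.seed(25)
  sys <- toy_system(random_cloud(20))
  net <- build_springs(sys, cutoff = 9.5, stiffness = 0.37, layer = "main")
  path <- tempfile(fileext = ".csv")
  write_spring_network(net, path)
  back <- read_spring_network(path)
  expect_identical(back$springs$i, net$springs$i)
  expect_identical(back$springs$rest_length, net$springs$rest_length)
  expect_identical(back$springs$stiffness, net$springs$stiffness)
  expect_equal(back$cutoff_used, net$cutoff_used)
  expect_equal(back$layer_label, net$layer_label)
  expect_equal(back$n, net$n)
})
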