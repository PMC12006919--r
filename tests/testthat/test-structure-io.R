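test_that("PDB write/read round-trips coordinates at format precision", {
  set.seed(11)
  sys <- toy_system(random_cloud(7))
  path <- tempfile(fileext = ".pdb")
  write_structure(sys, path)
  back <- read_structure(path)
  expect_equal(n_particles(back), 7)
  expect_lt(max(abs(get_coords(back) - get_coords(sys))), 5e-4)
  expect_equal(back$atoms$name, sys$atoms$name)
  expect_equal(back$atoms$chain, sys$atoms$chain)
})

test_that("PQR charge and radius fields are captured", {
  sys <- toy_system(rbind(c(0, 0, 0), c(5, 0, 0)), resname = "ALA")
  sys$atoms$charge <- c(-0.3, 0.5)
  sys$atoms$radius <- c(1.7, 2.0)
  path <- tempfile(fileext = ".pqr")
  write_pqr(sys, path)
  back <- read_structure(path)
  expect_equal(back$atoms$charge, c(-0.3, 0.5))
  expect_equal(back$atoms$radius, c(1.7, 2.0))
})

test_that("degenerate structure files raise descriptive errors", {
  empty <- tempfile(fileext = ".pdb")
  writeLines(character(0), empty)
  expect_error(read_structure(empty), "no atoms")
  noatoms <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER junk", "END"), noatoms)
  expect_error(read_structure(noatoms), "no atoms")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("multi-model input keeps the first model with a warning", {
  sys <- toy_system(rbind(c(0, 0, 0), c(3, 0, 0)))
  path <- tempfile(fileext = ".pdb")
  con <- file(path, "wt")
  write_trajectory_frame(con, sys, get_coords(sys), 1)
  write_trajectory_frame(con, sys, get_coords(sys) + 1, 2)
  close(con)
  expect_warning(back <- read_structure(path), "first model")
  expect_equal(n_particles(back), 2)
  expect_lt(max(abs(get_coords(back) - get_coords(sys))), 5e-4)
})

test_that("trajectory frames are MODEL-delimited with incrementing counters", {
  sys <- toy_system(rbind(c(0, 0, 0), c(3, 0, 0)))
  path <- tempfile(fileext = ".pdb")
  con <- file(path, "wt")
  for (f in 1:3) write_trajectory_frame(con, sys, get_coords(sys) + f, f)
  close(con)
  raw <- readLines(path)
  expect_equal(grep("^MODEL", raw, value = TRUE),
               sprintf("MODEL     %4d", 1:3))
  frames <- read_trajectory(path)
  expect_length(frames, 3)
  expect_lt(max(abs(frames[[2]] - (get_coords(sys) + 2))), 5e-4)
})

test_that("coordinates that overflow the fixed-width field are refused", {
  sys <- toy_system(rbind(c(0, 0, 0), c(12345.6789, 0, 0)))
  con <- textConnection("out", "w", local = TRUE)
  expect_error(write_trajectory_frame(con, sys, get_coords(sys), 1),
               "overflow")
  close(con)
})

test_that("coarse graining places one bead per residue at the representative atom", {
  atoms <- do.call(rbind, lapply(1:3, function(r) data.frame(
    name = c("N", "CA", "C", "O", "CB"), resname = "ALA", resid = r,
    chain = "A", x = r * 10 + (0:4), y = 0, z = 0)))
  ps <- particle_system(atoms)
  cg <- coarse_grain(ps)
  expect_equal(n_particles(cg), 3)
  expect_equal(cg$atoms$x, c(11, 21, 31))  # CA positions
  expect_equal(cg$atoms$name, rep("CA", 3))
})

test_that("coarse graining sums charges and masses and conserves totals", {
  atoms <- data.frame(
    name = c("N", "CA", "CB"), resname = "ALA", resid = 1, chain = "A",
    x = 0:2, y = 0, z = 0, charge = c(0.5, -0.5, 0.2), mass = c(14, 12, 12))
  cg <- coarse_grain(particle_system(atoms))
  expect_equal(cg$atoms$charge, 0.2)
  expect_equal(cg$atoms$mass, 38)
  set.seed(12)
  big <- particle_system(data.frame(
    name = rep(c("N", "CA", "C"), 8), resname = "GLY",
    resid = rep(1:8, each = 3), chain = "A",
    x = rnorm(24), y = rnorm(24), z = rnorm(24),
    charge = rnorm(24), mass = runif(24, 10, 16)))
  cgb <- coarse_grain(big)
  expect_equal(sum(cgb$atoms$charge), sum(big$atoms$charge))
  expect_equal(sum(cgb$atoms$mass), sum(big$atoms$mass))
  expect_equal(n_particles(cgb), 8)
})

test_that("auto scheme uses P for nucleotides and skips incomplete residues", {
  atoms <- rbind(
    data.frame(name = c("P", "C1'"), resname = "DA", resid = 1, chain = "X",
               x = c(1, 2), y = 1, z = 1),
    data.frame(name = c("N", "CA"), resname = "GLY", resid = 2, chain = "X",
               x = c(3, 4), y = 0, z = 0),
    data.frame(name = c("N", "CB"), resname = "ALA", resid = 3, chain = "X",
               x = c(5, 6), y = 0, z = 0))  # no CA: skipped
  cg <- coarse_grain(particle_system(atoms), scheme = "auto")
  expect_equal(n_particles(cg), 2)
  expect_equal(cg$atoms$x, c(1, 4))
  skipped <- attr(cg, "skipped")
  expect_equal(nrow(skipped), 1)
  expect_equal(skipped$resid, 3)
})

test_that("parameter assignment looks up residues with name-over-residue precedence", {
  tab <- default_parameter_table()
  sys <- toy_system(rbind(c(0, 0, 0), c(5, 0, 0)), resname = "LEU")
  sys <- assign_parameters(sys, tab)
  expect_equal(sys$atoms$radius, c(3.1, 3.1))
  expect_true(all(sys$atoms$transfer_energy < 0))
  # a particle-name rule beats the residue-name rule
  tab2 <- rbind(tab, data.frame(name = "CA", charge = 9, radius = 9,
                                epsilon = 9, mass = 9, transfer_energy = 9))
  sys2 <- assign_parameters(toy_system(c(0, 0, 0), resname = "LEU"), tab2)
  expect_equal(sys2$atoms$radius, 9)
})

test_that("unmatched particles get declared defaults and are reported", {
  sys <- toy_system(c(0, 0, 0), resname = "XXX")
  empty_tab <- default_parameter_table()[0, ]
  out <- assign_parameters(sys, empty_tab)
  expect_equal(out$atoms$radius, 3.0)
  expect_equal(out$atoms$mass, 100)
  expect_equal(attr(out, "unmatched"), "XXX")
})
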