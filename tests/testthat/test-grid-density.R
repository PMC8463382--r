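# Cube I/O, grid algebra, charge integration and partitioning.

unit_cube <- function(vals = rep(1, 8)) {
  density_grid(origin = c(0, 0, 0), axes = diag(3), counts = c(2, 2, 2),
               values = vals,
               atoms = data.frame(element = "Fe", x = 0.5, y = 0.5, z = 0.5))
}

test_that("constant field integrates to value times volume", {
  expect_equal(integrate_total(unit_cube()), 8.0)
  expect_equal(integrate_total(unit_cube(rep(0, 8))), 0.0)
})

test_that("cube write/read round-trips, including the MO dialect", {
  g <- unit_cube(seq(0.1, 0.8, by = 0.1))
  f <- withr::local_tempfile(fileext = ".cube")
  write_cube(g, f)
  g2 <- read_cube(f)
  expect_equal(g2$values, g$values, tolerance = 1e-6)
  expect_equal(g2$origin, g$origin, tolerance = 1e-6)
  expect_equal(g2$axes, g$axes, tolerance = 1e-6)
  expect_false(g2$is_orbital)

  g$is_orbital <- TRUE
  write_cube(g, f)
  g3 <- read_cube(f)
  expect_true(g3$is_orbital)
  expect_equal(g3$values, g$values, tolerance = 1e-6)
})

test_that("Angstrom-dialect cube matches its Bohr-native twin", {
  # one analytic Gaussian written in both unit dialects by hand
  at <- data.frame(element = "N", x = 0, y = 0, z = 0)
  gg <- gen_gaussian_density(at, 1.0, 0.8, counts = c(24, 24, 24))$grid
  f <- withr::local_tempfile(fileext = ".cube")
  write_cube(gg, f)
  lines <- readLines(f)
  # rewrite header records 4-6 with negative counts and Angstrom axes
  # (extra digits so the unit conversion, not formatting, is what is tested)
  for (a in 1:3) {
    rec <- scan(text = lines[3 + a], quiet = TRUE)
    lines[3 + a] <- sprintf("%5d %.12f %.12f %.12f", -rec[1],
                            rec[2] * bohr, rec[3] * bohr, rec[4] * bohr)
  }
  f2 <- withr::local_tempfile(fileext = ".cube")
  writeLines(lines, f2)
  twin <- read_cube(f2)
  expect_equal(integrate_total(twin), integrate_total(read_cube(f)),
               tolerance = 1e-6)
})

test_that("truncated value blocks raise a parse error naming the counts", {
  g <- unit_cube()
  f <- withr::local_tempfile(fileext = ".cube")
  write_cube(g, f)
  lines <- readLines(f)
  writeLines(lines[-length(lines)], f)
  expect_error(read_cube(f), "expected 8")
})

test_that("normalized Gaussians integrate to their weights", {
  at <- data.frame(element = c("Fe", "S"),
                   x = c(0, 3), y = c(0, 0), z = c(0, 0))
  g1 <- gen_gaussian_density(at[1, ], 1.0, 1.0, counts = c(40, 40, 40))
  expect_equal(integrate_total(g1$grid), 1.0, tolerance = 1e-4)
  g2 <- gen_gaussian_density(at, c(0.6, 0.4), 1.0, counts = c(40, 40, 40))
  expect_equal(integrate_total(g2$grid), 1.0, tolerance = 2e-4)
})

test_that("subtract_density is exact, refuses mismatched lattices", {
  rp <- gen_redox_pair(counts = c(20, 20, 20))
  z <- subtract_density(rp$ox, rp$ox)
  expect_true(all(z$values == 0))
  expect_equal(integrate_total(z), 0)

  d <- subtract_density(rp$red, rp$ox)
  back <- d
  back$values <- d$values + rp$ox$values
  expect_identical(back$values, rp$red$values)

  shifted <- rp$ox
  shifted$origin <- shifted$origin + 0.5
  expect_error(subtract_density(rp$red, shifted), "lattice")
})

test_that("nearest-atom partition recovers planted per-atom weights", {
  at <- data.frame(element = c("Fe", "S"), x = c(-3, 3), y = 0, z = 0)
  g <- gen_gaussian_density(at, c(0.6, 0.4), 0.5, counts = c(48, 48, 48))
  ct <- partition_charges(g$grid)
  expect_equal(ct$dq_e[1], 0.6, tolerance = 1e-3)
  expect_equal(ct$dq_e[2], 0.4, tolerance = 1e-3)
  # conservation: exhaustive partition sums to the total integral
  expect_equal(sum(ct$dq_e), attr(ct, "total"), tolerance = 1e-10)
})

test_that("single-atom partition equals the total; zero field gives zeros", {
  at <- data.frame(element = "Fe", x = 0, y = 0, z = 0)
  g <- gen_gaussian_density(at, 0.7, 1.0, counts = c(24, 24, 24))$grid
  ct <- partition_charges(g)
  expect_equal(ct$dq_e, integrate_total(g), tolerance = 1e-12)
  g$values[] <- 0
  expect_equal(partition_charges(g)$dq_e, 0)
})

test_that("sphere partition assigns within radius and reports the rest", {
  at <- data.frame(element = c("Fe", "S"), x = c(-3, 3), y = 0, z = 0)
  g <- gen_gaussian_density(at, c(0.6, 0.4), 0.5, counts = c(48, 48, 48))$grid
  ct <- partition_charges(g, "spheres", selection = 1, radius = 3)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$dq_e[1] + attr(ct, "unassigned"), attr(ct, "total"),
               tolerance = 1e-10)
  expect_error(partition_charges(g, "spheres", selection = integer(0),
                                 radius = 2), "selection")
  expect_error(partition_charges(g, "spheres", selection = 1), "radius")
})

test_that("partition is linear in the density", {
  at <- data.frame(element = c("Fe", "S"), x = c(-2, 2), y = 0, z = 0)
  box <- rbind(c(-8, -6, -6), c(8, 6, 6))
  g1 <- gen_gaussian_density(at, c(1, 0), 0.7, counts = c(20, 20, 20),
                             box = box)$grid
  g2 <- gen_gaussian_density(at, c(0, 1), 0.7, counts = c(20, 20, 20),
                             box = box)$grid
  mix <- g1
  mix$values <- 0.3 * g1$values + 0.7 * g2$values
  p1 <- partition_charges(g1)$dq_e
  p2 <- partition_charges(g2)$dq_e
  pm <- partition_charges(mix)$dq_e
  expect_equal(pm, 0.3 * p1 + 0.7 * p2, tolerance = 1e-12)
})

test_that("partition error shrinks monotonically under grid refinement", {
  # coarse enough that discretization (not the ~1e-9 Gaussian tail through
  # the Voronoi plane) dominates at every size in the doubling sequence
  at <- data.frame(element = c("Fe", "S"), x = c(-3, 3), y = 0, z = 0)
  errs <- vapply(c(8, 16, 32), function(n) {
    g <- gen_gaussian_density(at, c(0.6, 0.4), 0.5, counts = rep(n, 3))
    max(abs(partition_charges(g$grid)$dq_e - c(0.6, 0.4)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("group_localization reports orbital fractions that sum to one", {
  at <- data.frame(element = c("Fe", "Fe"), x = c(-3, 3), y = 0, z = 0)
  g <- gen_gaussian_density(at, c(1, 0), 0.5, counts = c(40, 40, 40))$grid
  fr <- group_localization(g, list(fe_y = 1, fe_x = 2))
  expect_equal(unname(fr["fe_y"]), 1.0, tolerance = 1e-3)
  expect_equal(unname(fr["fe_x"]), 0.0, tolerance = 1e-3)

  g2 <- gen_gaussian_density(at, c(0.9, 0.1), 0.5, counts = c(40, 40, 40))$grid
  fr2 <- group_localization(g2, list(a = 1, b = 2))
  expect_equal(as.numeric(fr2), c(0.9, 0.1), tolerance = 2e-3)
  expect_equal(sum(fr2), 1.0, tolerance = 1e-10)

  # uniform field over two symmetric atoms splits exactly in half
  u <- g
  u$values[] <- 1
  fu <- group_localization(u, list(a = 1, b = 2))
  expect_equal(as.numeric(fu), c(0.5, 0.5))

  z <- g
  z$values[] <- 0
  expect_error(group_localization(z, list(a = 1)), "positive")
  expect_error(group_localization(g, list(a = 1, b = c(1, 2))), "disjoint")
})
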