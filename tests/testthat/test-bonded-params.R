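# Seminario extraction, fchk parsing, MK shells and RESP fitting.

test_that("the force-constant unit conversion matches dimensional analysis", {
  hartree_kJmol <- 4.3597447222071e-18 * 6.02214076e23 / 1000
  bohr_nm <- 0.0529177210903
  expect_equal(unname(neet_constants()["hb2_kJmolnm2"]),
               hartree_kJmol / bohr_nm^2, tolerance = 1e-9)
  expect_equal(unname(neet_constants()["hb2_kJmolnm2"]), 9.37582e5,
               tolerance = 1e-5)
})

test_that("Seminario recovers an analytic diatomic bond constant", {
  r0 <- 2.3 * bohr / 10          # nm
  coords <- matrix(c(0, 0, 0, 2.3, 0, 0), 2, 3, byrow = TRUE)
  bonds <- data.frame(i = 1, j = 2, k = 20000, r0 = r0)
  h <- gen_harmonic_hessian(coords, c("Fe", "S"), bonds)
  bp <- seminario_bond_constant(h, 1, 2)
  expect_equal(bp$K_r, 20000, tolerance = 1e-6)
  expect_equal(bp$R_min_nm, r0, tolerance = 1e-12)
  # directional estimates coincide for a pure bond
  expect_equal(bp$k_ij, bp$k_ji, tolerance = 1e-8)
})

test_that("Seminario is invariant under rotation of the molecule", {
  r0 <- 2.3 * bohr / 10
  bonds <- data.frame(i = 1, j = 2, k = 20000, r0 = r0)
  coords <- matrix(c(0, 0, 0, 2.3, 0, 0), 2, 3, byrow = TRUE)
  k1 <- seminario_bond_constant(
    gen_harmonic_hessian(coords, c("Fe", "S"), bonds), 1, 2)$K_r
  k2 <- seminario_bond_constant(
    gen_harmonic_hessian(rotate_coords(coords), c("Fe", "S"), bonds), 1, 2)$K_r
  expect_equal(k1, k2, tolerance = 1e-8)
})

test_that("finite-difference Hessian matches the analytic bond Hessian", {
  k_au <- 20000 / neet_constants()["hb2_kJmolnm2"]
  coords <- matrix(c(0.3, -0.2, 0.5, 2.1, 0.9, -0.4), 2, 3, byrow = TRUE)
  r <- sqrt(sum((coords[2, ] - coords[1, ])^2))
  bonds <- data.frame(i = 1, j = 2, k = 20000, r0 = r * bohr / 10)
  h <- gen_harmonic_hessian(coords, c("Fe", "S"), bonds)
  Ha <- analytic_bond_hessian(coords[1, ], coords[2, ], k_au, r)
  expect_equal(h$H, Ha, tolerance = 1e-7)
})

test_that("water-like toy with an angle term recovers bonds within 2%", {
  coords <- matrix(c(0, 0, 0, 2.3, 0, 0, 3.1, 1.9, 0), 3, 3, byrow = TRUE)
  th0 <- acos(sum(c(-1, 0, 0) * c(0.8, 1.9, 0) / sqrt(0.8^2 + 1.9^2)))
  bonds <- data.frame(i = c(1, 2), j = c(2, 3), k = c(25000, 18000),
                      r0 = c(2.3, sqrt(0.8^2 + 1.9^2)) * bohr / 10)
  angles <- data.frame(i = 1, j = 2, k_atom = 3, k_theta = 25, theta0 = th0)
  h <- gen_harmonic_hessian(coords, c("S", "Fe", "S"), bonds, angles)
  expect_equal(seminario_bond_constant(h, 1, 2)$K_r, 25000,
               tolerance = 0.02)
  expect_equal(seminario_bond_constant(h, 2, 3)$K_r, 18000,
               tolerance = 0.02)
})

test_that("uncoupled atoms raise an error", {
  h <- hessian_matrix(matrix(0, 6, 6),
                      matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE),
                      c("Fe", "S"))
  expect_error(seminario_bond_constant(h, 1, 2), "not coupled")
})

test_that("fchk files round-trip the Hessian and survive atom permutation", {
  coords <- matrix(c(0, 0, 0, 2.3, 0, 0, 3.1, 1.9, 0), 3, 3, byrow = TRUE)
  bonds <- data.frame(i = c(1, 2), j = c(2, 3), k = c(25000, 18000),
                      r0 = c(2.3, sqrt(0.8^2 + 1.9^2)) * bohr / 10)
  h <- gen_harmonic_hessian(coords, c("Fe", "S", "C"), bonds)
  f <- withr::local_tempfile(fileext = ".fchk")
  write_fchk(h, f)
  h2 <- hessian_from_fchk(f)
  expect_equal(h2$H, h$H, tolerance = 1e-10)
  expect_equal(h2$coords, h$coords, tolerance = 1e-10)
  expect_equal(h2$elements, h$elements)

  # permute atom order (1,2,3) -> old atoms (3,1,2): old bond 1-2 becomes
  # 2-3 and old bond 2-3 becomes 3-1
  perm <- c(3, 1, 2)
  bonds_p <- data.frame(i = c(2, 3), j = c(3, 1), k = c(25000, 18000),
                        r0 = bonds$r0)
  hp <- gen_harmonic_hessian(coords[perm, ], c("C", "Fe", "S"), bonds_p)
  expect_equal(seminario_bond_constant(hp, 1, 3)$K_r,
               seminario_bond_constant(h, 2, 3)$K_r, tolerance = 1e-8)

  # corrupt the triangle length -> parse error
  lines <- readLines(f)
  writeLines(lines[-length(lines)], f)
  expect_error(hessian_from_fchk(f), "expected")
})

test_that("MK shells have the right area density, radius and pruning", {
  one <- data.frame(element = "C", x = 0, y = 0, z = 0)
  pts <- mk_probe_shells(one, scales = 1.4, density = 1)
  r <- 1.4 * 1.70
  expect_equal(nrow(pts), 4 * pi * r^2, tolerance = 0.1)
  expect_equal(sqrt(rowSums(pts^2)), rep(r, nrow(pts)), tolerance = 1e-6)

  two <- data.frame(element = c("C", "C"), x = c(0, 1.0), y = 0, z = 0)
  p2 <- mk_probe_shells(two, scales = 1.4, density = 1)
  d1 <- sqrt(rowSums(sweep(p2, 2, c(0, 0, 0))^2))
  d2 <- sqrt(rowSums(sweep(p2, 2, c(1, 0, 0))^2))
  expect_true(all(pmin(d1, d2) >= 1.4 * 1.70 - 1e-9))

  expect_identical(mk_probe_shells(two), mk_probe_shells(two))
  expect_error(mk_probe_shells(data.frame(element = "Xx", x = 0, y = 0,
                                          z = 0)), "Xx")
})

coulomb_grid <- function(atoms_bohr, q, scales = c(1.4, 1.6, 1.8, 2.0),
                         classes = NULL) {
  at_A <- atoms_bohr
  at_A[, c("x", "y", "z")] <- at_A[, c("x", "y", "z")] * bohr
  pts <- mk_probe_shells(at_A, scales = scales, density = 1.5)
  P <- pts / bohr
  axyz <- as.matrix(atoms_bohr[, c("x", "y", "z")])
  V <- apply(P, 1, function(p) sum(q / sqrt(colSums((t(axyz) - p)^2))))
  esp_grid(P, V, atoms_bohr, total_charge = sum(q), classes = classes)
}

test_that("unrestrained ESP fit recovers planted point charges", {
  at <- data.frame(element = "O", x = 0, y = 0, z = 0)
  g <- coulomb_grid(at, -0.834)
  q <- esp_fit_charges(g, restraint_a = 0)
  expect_equal(as.numeric(q), -0.834, tolerance = 1e-8)
})

test_that("symmetry classes force exact equality", {
  at <- data.frame(element = c("H", "H"), x = c(-1.5, 1.5), y = 0, z = 0)
  g <- coulomb_grid(at, c(0.4, 0.4), classes = c(1, 1))
  q <- esp_fit_charges(g, restraint_a = 0)
  expect_equal(as.numeric(q), c(0.4, 0.4), tolerance = 1e-8)
  expect_equal(q[1], q[2], tolerance = 1e-12)
})

test_that("the hyperbolic restraint shrinks magnitudes, constraint exact", {
  at <- data.frame(element = c("O", "C", "N"),
                   x = c(0, 2.3, 4.4), y = c(0, 0.8, -0.4), z = 0)
  q0 <- c(-0.6, 0.45, -0.25)
  g <- coulomb_grid(at, q0)
  qa <- esp_fit_charges(g, restraint_a = 0)
  qb <- esp_fit_charges(g, restraint_a = 0.0005)
  expect_equal(as.numeric(qa), q0, tolerance = 1e-8)
  expect_true(all(abs(qb) <= abs(qa) + 1e-12))
  expect_lt(abs(sum(qa) - sum(q0)), 1e-12)
  expect_lt(abs(sum(qb) - sum(q0)), 1e-12)
})

test_that("a probe on a nucleus is rejected as singular", {
  at <- data.frame(element = "O", x = 0, y = 0, z = 0)
  P <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  expect_error(esp_grid(P[1:2, ], c(1, 1), at, 0) |>
                 esp_fit_charges(), "singular|coincides")
  g <- esp_grid(P, c(1, 0.5, 0.5), at, 0)
  expect_error(esp_fit_charges(g), "coincides")
})
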