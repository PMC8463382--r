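# Site detection, truncated models, geometry tables, superposition.

mock <- mock_neet_pdb(seed = 1)

test_that("the synthetic 3Cys:1His site is detected with its ligand set", {
  sites <- detect_cluster_sites(mock$pdb)
  expect_length(sites, 1)
  s <- sites[[1]]
  expect_equal(s$class, "3Cys:1His")
  expect_setequal(s$ligands$resno, unname(mock$truth$ligand_resnos))
  expect_equal(s$ligands$resid[s$ligands$label == "N_His"], "HIS")
  # Fe_Y is the His-bound iron
  expect_equal(s$ligands$fe_label[s$ligands$label == "N_His"], "Fe_Y")
})

test_that("structures without iron yield no sites", {
  txt <- mock$pdb
  lines <- gen_mock_neet_structure(1)$text
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(grep("FE", lines, invert = TRUE, value = TRUE), f)
  expect_length(detect_cluster_sites(f), 0)
})

test_that("detection is invariant to atom-record order and rigid motion", {
  lines <- gen_mock_neet_structure(1)$text
  body <- lines[lines != "END"]
  set.seed(4)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(sample(body), "END"), f)
  sites <- detect_cluster_sites(f)
  expect_length(sites, 1)
  expect_equal(sites[[1]]$class, "3Cys:1His")

  # rigid motion: rotate + translate every coordinate, geometry unchanged
  pdb <- mock$pdb
  xyz <- as.matrix(pdb$atom[, c("x", "y", "z")])
  xyz2 <- rotate_coords(xyz) + matrix(c(5, -3, 2), nrow(xyz), 3, byrow = TRUE)
  pdb$atom[, c("x", "y", "z")] <- xyz2
  s1 <- detect_cluster_sites(mock$pdb)[[1]]
  s2 <- detect_cluster_sites(pdb)[[1]]
  g1 <- bond_geometry(s1)
  g2 <- bond_geometry(s2)
  expect_equal(g2$R_nm, g1$R_nm, tolerance = 1e-9)
})

test_that("bond_geometry reports the planted distances in nm", {
  s <- detect_cluster_sites(mock$pdb)[[1]]
  g <- bond_geometry(s, state = "oxidized")
  expect_equal(nrow(g), 8)
  planted <- mock$truth$bonds_A / 10    # Angstrom -> nm
  expect_equal(g$R_nm[match(names(planted), g$bond)], unname(planted),
               tolerance = 2e-4)        # PDB fixed-format rounding
  expect_equal(attr(g, "state"), "oxidized")
})

test_that("level-1 models carry no backbone atoms and nest inside level 3", {
  s <- detect_cluster_sites(mock$pdb)[[1]]
  m1 <- build_model(s, mock$pdb, 1)
  m3 <- build_model(s, mock$pdb, 3)
  own <- m1$atoms$source != "cluster" & m1$atoms$source != "cap"
  expect_false(any(m1$atoms$elety[own] %in% c("N", "C", "O", "CA")))
  key1 <- paste(m1$atoms$elety, m1$atoms$resno)[m1$atoms$source != "cap"]
  key3 <- paste(m3$atoms$elety, m3$atoms$resno)
  expect_true(all(key1 %in% key3))
  expect_equal(m1$net_charge, -2L)
  expect_equal(build_model(s, mock$pdb, 1, state = "reduced")$net_charge, -3L)
})

test_that("the 4-A rule includes the 3.9-A residue and excludes the 4.1-A one", {
  s <- detect_cluster_sites(mock$pdb)[[1]]
  m3 <- build_model(s, mock$pdb, 3)
  res <- unique(m3$atoms$resno[m3$atoms$source == "residue"])
  expect_true(mock$truth$probe_resnos[["included"]] %in% res)
  expect_false(mock$truth$probe_resnos[["excluded"]] %in% res)
})

test_that("level-2 spans take backbone only and flag chain breaks", {
  s <- detect_cluster_sites(mock$pdb)[[1]]
  m2 <- build_model(s, mock$pdb, 2)
  span <- m2$atoms[m2$atoms$source == "backbone", ]
  expect_setequal(unique(span$resno), mock$truth$spanning_resnos)
  expect_true(all(span$elety %in% c("N", "CA", "C", "O")))
  expect_true(all(c("ACE", "NME") %in% m2$caps$type))

  # delete one spanning residue -> gap error
  lines <- gen_mock_neet_structure(1)$text
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[!grepl("GLY A  13", lines)], f)
  s2 <- detect_cluster_sites(f)[[1]]
  expect_error(build_model(s2, f, 2), "chain break.*13")
})

test_that("model PDB files round-trip with a manifest", {
  s <- detect_cluster_sites(mock$pdb)[[1]]
  m1 <- build_model(s, mock$pdb, 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(m1, f)
  back <- bio3d::read.pdb(f, verbose = FALSE)
  expect_equal(nrow(back$atom), nrow(m1$atoms))
  expect_true(file.exists(paste0(f, ".manifest.txt")))
  expect_match(paste(readLines(paste0(f, ".manifest.txt")), collapse = " "),
               "net_charge: -2")
})

test_that("redox_delta_report reproduces the published B3LYP comparison", {
  ox <- read_geometry_table(system.file("extdata",
                                        "table1_b3lyp_protonated_ox.csv",
                                        package = "neetkit"), "oxidized")
  red <- read_geometry_table(system.file("extdata",
                                         "table1_b3lyp_protonated_red.csv",
                                         package = "neetkit"), "reduced")
  rep <- redox_delta_report(ox, red)
  his <- rep[rep$bond == "Fe_Y-N_His", ]
  expect_equal(his$dR_nm, 0.012, tolerance = 1e-10)
  expect_equal(his$Kr_ratio, 7740.4 / 16359.4, tolerance = 1e-10)
  # every Fe-ligand donor bond weakens on reduction
  donors <- c("Fe_X-S_Cys1", "Fe_X-S_Cys2", "Fe_Y-S_Cys3", "Fe_Y-N_His")
  expect_true(all(rep$Kr_ratio[rep$bond %in% donors] < 1))
  expect_true(all(rep$weakened[rep$bond %in% donors]))
})

test_that("identical tables give zero deltas and unit ratios", {
  g <- geometry_table(c("a-b", "c-d"), c(0.2, 0.3), Kr = c(100, 200))
  rep <- redox_delta_report(g, g)
  expect_equal(rep$dR_nm, c(0, 0))
  expect_equal(rep$Kr_ratio, c(1, 1))
  g2 <- geometry_table(c("a-b", "x-y"), c(0.2, 0.3))
  expect_error(redox_delta_report(g, g2), "x-y")
})

test_that("superposition removes rigid motions exactly", {
  set.seed(11)
  A <- matrix(rnorm(30), 10, 3)
  B <- rotate_coords(A) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  fit <- superpose_rmsd(A, B)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$B_fit, A, tolerance = 1e-9)
  expect_lt(superpose_rmsd(A, A)$rmsd, 1e-12)
  expect_error(superpose_rmsd(A[1:2, ], B[1:2, ]), "3 points")
})

test_that("Kabsch RMSD agrees with the quaternion oracle on random sets", {
  set.seed(21)
  for (r in 1:20) {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    expect_equal(superpose_rmsd(A, B)$rmsd, quaternion_rmsd(A, B),
                 tolerance = 1e-8)
  }
})

test_that("one displaced atom gives the closed-form RMSD", {
  # regular tetrahedron, atom 1 displaced radially from the centroid:
  # by symmetry the optimal rotation is the identity and
  # RMSD = d sqrt(N - 1) / N
  A <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  d <- 0.4
  B <- A
  B[1, ] <- A[1, ] + d * A[1, ] / sqrt(sum(A[1, ]^2))
  fit <- superpose_rmsd(A, B)
  N <- nrow(A)
  expect_equal(fit$rmsd, d * sqrt(N - 1) / N, tolerance = 1e-10)
  expect_lte(fit$rmsd, d * sqrt(1 / N) + 1e-12)
})

test_that("Kabsch matches bio3d's fitter on a random pair", {
  set.seed(31)
  A <- matrix(rnorm(24), 8, 3)
  B <- matrix(rnorm(24), 8, 3)
  r1 <- superpose_rmsd(A, B)$rmsd
  xyz_a <- as.numeric(t(A)); xyz_b <- as.numeric(t(B))
  fitted <- bio3d::fit.xyz(fixed = xyz_a, mobile = matrix(xyz_b, 1),
                           fixed.inds = 1:24, mobile.inds = 1:24)
  r2 <- sqrt(mean((fitted - xyz_a)^2) * 3)
  expect_equal(r1, r2, tolerance = 1e-6)
})
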