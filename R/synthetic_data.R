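# Seeded synthetic-data generators with machine-readable ground truth.
# Each generator runs on a private random stream (the caller's RNG state is
# untouched) and returns its truth alongside the data, so test oracles stay
# independent of the analysis code paths.

# evaluate `code` under a private RNG stream seeded with `seed`
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Analytic atom-centered Gaussian density on a grid
#'
#' Builds a [density_grid()] holding a sum of normalized isotropic
#' Gaussians, one per atom, and returns the analytic per-atom integrals as
#' ground truth. Deterministic (no random numbers). The grid must span at
#' least `span_sigma` standard deviations beyond the outermost atom so
#' that truncation cannot silently bias integrals.
#'
#' @param atoms Data frame with `element`, `x`, `y`, `z` (Bohr).
#' @param weights Per-atom Gaussian weights (e).
#' @param sigmas Per-atom standard deviations (Bohr), recycled.
#' @param counts Voxel counts per axis (default `c(40, 40, 40)`).
#' @param box Optional 2 x 3 matrix (rows lo, hi, Bohr); default is the
#'   atom bounding box padded by `span_sigma * max(sigmas)`.
#' @param span_sigma Required span beyond the outermost atom, in sigmas
#'   (default 6).
#' @return List with `grid` (a `density_grid`) and `truth` (data frame of
#'   planted per-atom weights).
#' @export
gen_gaussian_density <- function(atoms, weights, sigmas,
                                 counts = c(40, 40, 40), box = NULL,
                                 span_sigma = 6) {
  atoms <- as.data.frame(atoms)
  n <- nrow(atoms)
  weights <- rep_len(weights, n)
  sigmas <- rep_len(sigmas, n)
  axyz <- as.matrix(atoms[, c("x", "y", "z")])
  pad <- span_sigma * max(sigmas)
  if (is.null(box)) {
    box <- rbind(apply(axyz, 2, min) - pad, apply(axyz, 2, max) + pad)
  } else {
    box <- as.matrix(box)
    if (any(box[1, ] > apply(axyz, 2, min) - pad + 1e-9) ||
        any(box[2, ] < apply(axyz, 2, max) + pad - 1e-9)) {
      stop(sprintf("grid box must span >= %g sigma beyond every atom",
                   span_sigma))
    }
  }
  counts <- as.integer(counts)
  step <- (box[2, ] - box[1, ]) / counts
  origin <- box[1, ] + step / 2          # midpoint-rule lattice
  grid0 <- density_grid(origin, diag(step), counts,
                        numeric(prod(counts)), atoms)
  pts <- grid_points(grid0)
  vals <- numeric(nrow(pts))
  for (a in seq_len(n)) {
    r2 <- colSums((t(pts) - axyz[a, ])^2)
    vals <- vals + weights[a] * (2 * pi * sigmas[a]^2)^(-1.5) *
      exp(-r2 / (2 * sigmas[a]^2))
  }
  grid0$values <- vals
  list(grid = grid0,
       truth = data.frame(atom_index = seq_len(n),
                          element = atoms$element,
                          weight_e = weights, sigma_bohr = sigmas))
}

# idealized [2Fe-2S](Cys-S)3(His-N) core used by the density generators;
# positions in Bohr, derived from the mock-site geometry
redox_core_atoms <- function() {
  ab <- 1 / .BOHR_A
  data.frame(
    element = c("Fe", "Fe", "S", "S", "N"),
    label = c("Fe_X", "Fe_Y", "S_1", "S_2", "N_His"),
    x = c(0, 2.70, 1.35, 1.35, 4.88) * ab,
    y = c(0, 0, 1.78, -1.78, 0) * ab,
    z = c(0, 0, 0, 0, 0) * ab)
}

#' Synthetic redox density pair with a planted one-electron difference
#'
#' Emulates a one-electron reduction: the reduced grid equals the oxidized
#' grid plus exactly 1.0 e of added density, distributed over the cluster
#' atoms with the given weights (default: 0.5 on the His-bound iron, 0.2 on
#' each bridging sulfide, 0.1 on the His nitrogen — the localization
#' pattern of the reduction). Both grids share one lattice so subtraction
#' is exact.
#'
#' @param atoms Optional atom data frame (Bohr); default is the idealized
#'   five-atom cluster core.
#' @param extra_electron_weights Planted weights (must sum to 1.0 e),
#'   one per atom.
#' @param sigma_extra Gaussian width of the planted density (Bohr).
#' @param counts Voxel counts (default 40^3).
#' @return List with `ox`, `red` (`density_grid`s) and `truth` (planted
#'   per-atom weights).
#' @export
gen_redox_pair <- function(atoms = NULL,
                           extra_electron_weights = NULL,
                           sigma_extra = 0.5, counts = c(40, 40, 40)) {
  if (is.null(atoms)) atoms <- redox_core_atoms()
  n <- nrow(atoms)
  if (is.null(extra_electron_weights)) {
    extra_electron_weights <- if (n == 5) c(0, 0.5, 0.2, 0.2, 0.1)
    else rep(1 / n, n)
  }
  w <- extra_electron_weights
  if (abs(sum(w) - 1) > 1e-12) {
    stop("extra_electron_weights must sum to 1.0 e")
  }
  # shared baseline density (valence-like blob on every atom)
  base_w <- rep(1.0, n)
  base_s <- rep(0.6, n)
  pad_need <- 6 * max(base_s, sigma_extra)
  axyz <- as.matrix(atoms[, c("x", "y", "z")])
  box <- rbind(apply(axyz, 2, min) - pad_need,
               apply(axyz, 2, max) + pad_need)
  ox <- gen_gaussian_density(atoms, base_w, base_s, counts, box = box)$grid
  extra <- gen_gaussian_density(atoms, w, rep(sigma_extra, n), counts,
                                box = box)$grid
  red <- ox
  red$values <- ox$values + extra$values
  list(ox = ox, red = red,
       truth = data.frame(atom_index = seq_len(n),
                          element = atoms$element,
                          label = if (!is.null(atoms$label)) atoms$label
                                  else as.character(seq_len(n)),
                          extra_e = w))
}

# analytic model energy of a harmonic bond/angle topology (Hartree, Bohr)
harmonic_energy <- function(x, bonds, angles) {
  E <- 0
  if (!is.null(bonds) && nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      d <- x[bonds$j[r], ] - x[bonds$i[r], ]
      rr <- sqrt(sum(d^2))
      k_au <- bonds$k[r] / .HB2_KJMOLNM2          # kJ/mol nm^2 -> Ha/Bohr^2
      r0 <- bonds$r0[r] * 10 / .BOHR_A            # nm -> Bohr
      E <- E + k_au * (rr - r0)^2                 # E = k (r - r0)^2
    }
  }
  if (!is.null(angles) && nrow(angles)) {
    for (r in seq_len(nrow(angles))) {
      v1 <- x[angles$i[r], ] - x[angles$j[r], ]
      v2 <- x[angles$k_atom[r], ] - x[angles$j[r], ]
      ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      th <- acos(pmin(pmax(ct, -1), 1))
      k_au <- angles$k_theta[r] / .HARTREE_KJMOL  # kJ/mol/rad^2 -> Ha/rad^2
      E <- E + k_au * (th - angles$theta0[r])^2
    }
  }
  E
}

#' Finite-difference Hessian of a harmonic bond/angle model
#'
#' Builds the Cartesian Hessian of an analytic harmonic energy
#' `E = sum_bonds k (r - r0)^2 + sum_angles k_theta (theta - theta0)^2`
#' by central finite differences (default step 1e-4 Bohr), symmetrized.
#' Serves as the ground-truth oracle for Seminario extraction.
#'
#' @param coords N x 3 atom coordinates (Bohr).
#' @param elements Element symbols, length N.
#' @param bonds Data frame `i`, `j`, `k` (kJ/mol nm^2, AMBER convention),
#'   `r0` (nm).
#' @param angles Optional data frame `i`, `j` (vertex), `k_atom`,
#'   `k_theta` (kJ/mol/rad^2), `theta0` (rad).
#' @param step Finite-difference step (Bohr).
#' @return A [hessian_matrix()] (Hartree/Bohr^2).
#' @export
gen_harmonic_hessian <- function(coords, elements, bonds, angles = NULL,
                                 step = 1e-4) {
  x0 <- as.matrix(coords)
  n <- nrow(x0)
  if (!is.null(angles) && nrow(angles)) {
    for (r in seq_len(nrow(angles))) {
      v1 <- x0[angles$i[r], ] - x0[angles$j[r], ]
      v2 <- x0[angles$k_atom[r], ] - x0[angles$j[r], ]
      ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      if (abs(ct) > 0.999) {
        warning("near-linear angle term; Hessian may be ill-conditioned")
      }
    }
  }
  en <- function(xv) harmonic_energy(matrix(xv, n, 3), bonds, angles)
  m <- 3L * n
  xv0 <- as.numeric(x0)
  H <- matrix(0, m, m)
  # R stores N x 3 column-major: coordinate index (atom a, dim d) = a + (d-1) n
  for (a in seq_len(m)) {
    for (b in a:m) {
      if (a == b) {
        e0 <- en(xv0)
        xp <- xv0; xp[a] <- xp[a] + step
        xm <- xv0; xm[a] <- xm[a] - step
        H[a, a] <- (en(xp) - 2 * e0 + en(xm)) / step^2
      } else {
        xpp <- xv0; xpp[a] <- xpp[a] + step; xpp[b] <- xpp[b] + step
        xpm <- xv0; xpm[a] <- xpm[a] + step; xpm[b] <- xpm[b] - step
        xmp <- xv0; xmp[a] <- xmp[a] - step; xmp[b] <- xmp[b] + step
        xmm <- xv0; xmm[a] <- xmm[a] - step; xmm[b] <- xmm[b] - step
        H[a, b] <- H[b, a] <-
          (en(xpp) - en(xpm) - en(xmp) + en(xmm)) / (4 * step^2)
      }
    }
  }
  # reorder from R's (atom-major per dimension) to atom blocks (x,y,z)
  perm <- as.numeric(t(matrix(seq_len(m), n, 3)))
  H <- H[perm, perm]
  hessian_matrix((H + t(H)) / 2, x0, elements)
}

#' Write a Hessian as a formatted-checkpoint-style text file
#'
#' Emits the blocks [hessian_from_fchk()] reads: atom count, atomic
#' numbers, Cartesian coordinates (Bohr) and the lower-triangle force
#' constants (Hartree/Bohr^2).
#'
#' @param hess A [hessian_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fchk <- function(hess, path) {
  n <- nrow(hess$coords)
  m <- 3L * n
  z <- element_to_z(hess$elements)
  tri <- hess$H[upper.tri(hess$H, diag = TRUE)]
  blk <- function(x, fmt, per) {
    apply(matrix(c(sprintf(fmt, x), rep("", (-length(x)) %% per)),
                 ncol = per, byrow = TRUE),
          1, paste, collapse = "")
  }
  lines <- c(
    "neetkit synthetic formatted checkpoint",
    "Freq      synthetic-harmonic            none",
    sprintf("Number of atoms                            I %16d", n),
    sprintf("Atomic numbers                             I   N= %11d", n),
    blk(z, "%12d", 6L),
    sprintf("Current cartesian coordinates              R   N= %11d", m),
    blk(as.numeric(t(hess$coords)), "%24.15E", 5L),
    sprintf("Cartesian Force Constants                  R   N= %11d",
            length(tri)),
    blk(tri, "%24.15E", 5L))
  writeLines(lines, path)
  invisible(path)
}

#' Synthetic MSA with planted covarying column pairs
#'
#' Columns are drawn i.i.d. from the background amino-acid distribution,
#' except planted pairs: with probability `coupling` the second column is a
#' fixed random bijective relabeling of the first (perfect covariation),
#' otherwise an independent background draw. `coupling` therefore
#' interpolates independence (0) to deterministic joint mutation (1).
#'
#' @param n_seqs Number of sequences.
#' @param length Alignment length.
#' @param planted_pairs Data frame `i`, `j`, `coupling` (may be empty).
#' @param background Probabilities over the 20 amino acids (default
#'   uniform).
#' @param gap_fraction Fraction of cells replaced by gaps (default 0).
#' @param seed Integer seed (private stream).
#' @return List with `aln` (an `alignment`) and `truth` (the planted
#'   pairs with their coupling and symbol mapping).
#' @export
gen_msa <- function(n_seqs, length, planted_pairs = NULL,
                    background = NULL, gap_fraction = 0, seed = 1) {
  L <- length
  if (is.null(background)) background <- rep(1 / 20, 20)
  if (!is.null(planted_pairs) && nrow(planted_pairs)) {
    idx <- c(planted_pairs$i, planted_pairs$j)
    if (anyDuplicated(idx)) stop("planted column indices collide")
    if (any(idx < 1 | idx > L)) stop("planted index out of range")
  }
  with_seed(seed, {
    M <- matrix(sample.int(20, n_seqs * L, replace = TRUE,
                           prob = background), n_seqs, L)
    maps <- list()
    if (!is.null(planted_pairs) && nrow(planted_pairs)) {
      for (r in seq_len(nrow(planted_pairs))) {
        i <- planted_pairs$i[r]; j <- planted_pairs$j[r]
        cp <- planted_pairs$coupling[r]
        map <- sample.int(20)
        maps[[r]] <- map
        follow <- stats::runif(n_seqs) < cp
        M[follow, j] <- map[M[follow, i]]
      }
    }
    ali <- matrix(.AA20[M], n_seqs, L)
    if (gap_fraction > 0) {
      ngap <- round(gap_fraction * n_seqs * L)
      ali[sample.int(n_seqs * L, ngap)] <- "-"
    }
    list(aln = as_alignment(ali),
         truth = list(planted_pairs = planted_pairs, maps = maps,
                      seed = seed))
  })
}

# random rotation matrix from the generator's stream (quaternion method)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Synthetic conformer ensemble with planted basins
#'
#' Frames are a basin centre (base structure plus a basin displacement)
#' plus isotropic Gaussian noise, then hit with a random rigid motion
#' (rotation + translation) that the clustering metric must undo. Basin
#' labels are returned as ground truth.
#'
#' @param base N x 3 base coordinates (nm).
#' @param basins List of basins, each `list(shift=, spread=)`: `shift` is
#'   either an N x 3 displacement field (nm, used as-is) or a 3-vector,
#'   which is applied to the second half of the atoms only (a hinge
#'   deformation) — a uniform translation of all atoms would be a rigid
#'   motion and invisible to the RMSD metric. `spread` is the
#'   per-coordinate noise sd (nm).
#' @param frames_per_basin Frames per basin (recycled).
#' @param seed Integer seed (private stream).
#' @return List with `set` (a [conformation_set()]) and `truth` (basin
#'   label per frame).
#' @export
gen_conformers <- function(base, basins, frames_per_basin = 4, seed = 1) {
  base <- as.matrix(base)
  N <- nrow(base)
  nb <- length(basins)
  fpb <- rep_len(frames_per_basin, nb)
  with_seed(seed, {
    frames <- list()
    labels <- integer(0)
    for (b in seq_len(nb)) {
      sh <- basins[[b]]$shift
      shm <- if (is.null(dim(sh))) {
        m <- matrix(0, N, 3)
        m[(N %/% 2 + 1):N, ] <- matrix(sh, N - N %/% 2, 3, byrow = TRUE)
        m
      } else as.matrix(sh)
      centre <- base + shm
      for (f in seq_len(fpb[b])) {
        fr <- centre + matrix(stats::rnorm(N * 3, sd = basins[[b]]$spread),
                              N, 3)
        R <- random_rotation()
        tr <- stats::runif(3, -1, 1)
        fr <- fr %*% R + matrix(tr, N, 3, byrow = TRUE)
        frames <- c(frames, list(fr))
        labels <- c(labels, b)
      }
    }
    xyz <- array(NA_real_, c(length(frames), N, 3))
    for (f in seq_along(frames)) xyz[f, , ] <- frames[[f]]
    list(set = conformation_set(xyz), truth = labels)
  })
}

#' Synthetic absorbance decay panel with known rates
#'
#' Generates `A(t) = c + (1 - c) exp(-k t)` plus Gaussian noise for each
#' panel row, emulating 458-nm lability measurements across temperatures.
#'
#' @param panel Data frame with `temperature_K`, `k` (1/min), `plateau`
#'   and optionally `label`.
#' @param n_points Points per trace (default 60).
#' @param t_end Last time point in minutes (default 120).
#' @param sigma Gaussian noise sd (default 0.01).
#' @param seed Integer seed (private stream).
#' @return List with `traces` (list of `decay_trace`) and `truth` (the
#'   panel with the planted parameters).
#' @export
gen_decay_traces <- function(panel, n_points = 60, t_end = 120,
                             sigma = 0.01, seed = 1) {
  panel <- as.data.frame(panel)
  if (is.null(panel$label)) panel$label <- "sample"
  tt <- seq(0, t_end, length.out = n_points)
  with_seed(seed, {
    traces <- lapply(seq_len(nrow(panel)), function(r) {
      mu <- panel$plateau[r] +
        (1 - panel$plateau[r]) * exp(-panel$k[r] * tt)
      decay_trace(tt, mu + stats::rnorm(n_points, sd = sigma),
                  panel$temperature_K[r], panel$label[r])
    })
    list(traces = traces, truth = panel)
  })
}

# fixed-column PDB ATOM/HETATM line
pdb_line <- function(record, serial, name, resid, chain, resno,
                     x, y, z, elem) {
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resid, chain, resno, x, y, z, 1.0, 0.0,
          toupper(elem))
}

unitv <- function(v) v / sqrt(sum(v^2))

#' Synthetic NEET-like structure with an ideal [2Fe-2S] site
#'
#' Builds a small polypeptide-like scaffold (synthetic, not a real PDB
#' entry) carrying an ideal-geometry [2Fe-2S] cluster with three Cys
#' thiolate donors and one His imidazole nitrogen at stated distances
#' (Fe-S(Cys) 2.25 A, Fe-N(His) 2.18 A, Fe-S(bridge) ~2.23 A), spanning
#' residues between the ligands, a distal surface loop mimicking the L2
#' region, and two probe residues whose nearest atoms sit at controlled
#' distances from the cluster core (default 3.9 and 4.1 A) to exercise the
#' 4-A truncation boundary.
#'
#' @param seed Integer seed (present for interface uniformity; the
#'   construction is deterministic).
#' @param extra_residue_dist Length-2: nearest-atom distances (A) of the
#'   two planted probe residues.
#' @return List with `text` (PDB file content), `truth` (ligand residue
#'   numbers, planted bond lengths in A, probe-residue distances) and
#'   `write(path)` convenience via [writeLines()].
#' @export
gen_mock_neet_structure <- function(seed = 1,
                                    extra_residue_dist = c(3.9, 4.1)) {
  fex <- c(0, 0, 0)
  fey <- c(2.70, 0, 0)
  s1 <- c(1.35, 1.78, 0)
  s2 <- c(1.35, -1.78, 0)

  d_cys1 <- unitv(c(-1, 1, 1))
  d_cys2 <- unitv(c(-1, -1, -1))
  d_cys3 <- unitv(c(1, 1, -1))
  d_his <- unitv(c(1, -1, 1))
  sg1 <- fex + 2.25 * d_cys1
  sg2 <- fex + 2.25 * d_cys2
  sg3 <- fey + 2.25 * d_cys3
  ne2 <- fey + 2.18 * d_his

  lines <- character(0)
  serial <- 0L
  emit <- function(name, resid, resno, p, elem) {
    serial <<- serial + 1L
    lines <<- c(lines, pdb_line(if (resid == "FES") "HETATM" else "ATOM",
                                serial, name, resid, "A", resno,
                                p[1], p[2], p[3], elem))
  }
  backbone_out <- function(anchor, d, resid, resno, side = list()) {
    # grow CB -> CA -> N/C/O outward along d; side chain atoms passed in
    cb <- anchor + 1.80 * d
    ca <- cb + 1.53 * d
    perp <- unitv(c(-d[2], d[1], 0) +
                    if (abs(d[3]) > 0.9) c(1, 0, 0) else 0)
    nn <- ca + 1.46 * unitv(d + 0.8 * perp)
    cc <- ca + 1.52 * unitv(d - 0.8 * perp)
    oo <- cc + 1.23 * d
    for (s in side) emit(s$name, resid, resno, s$p, s$elem)
    emit("CB", resid, resno, cb, "C")
    emit("CA", resid, resno, ca, "C")
    emit("N", resid, resno, nn, "N")
    emit("C", resid, resno, cc, "C")
    emit("O", resid, resno, oo, "O")
  }

  # ligand residues: CYS 10, CYS 12, CYS 15, HIS 17
  backbone_out(sg1, d_cys1, "CYS", 10,
               list(list(name = "SG", p = sg1, elem = "S")))
  backbone_out(sg2, d_cys2, "CYS", 12,
               list(list(name = "SG", p = sg2, elem = "S")))
  backbone_out(sg3, d_cys3, "CYS", 15,
               list(list(name = "SG", p = sg3, elem = "S")))
  # His ring outward from NE2
  ce1 <- ne2 + 1.32 * unitv(d_his + c(0, 0.5, 0))
  nd1 <- ce1 + 1.35 * d_his
  cd2 <- ne2 + 1.36 * unitv(d_his + c(0, -0.5, 0))
  cg <- cd2 + 1.37 * d_his
  emit("NE2", "HIS", 17, ne2, "N")
  emit("CE1", "HIS", 17, ce1, "C")
  emit("ND1", "HIS", 17, nd1, "N")
  emit("CD2", "HIS", 17, cd2, "C")
  backbone_out(cg, d_his, "HIS", 17,
               list(list(name = "CG", p = cg, elem = "C")))

  # spanning residues (backbone only) on an arc ~8 A out
  for (rn in c(11, 13, 14, 16)) {
    ang <- rn * 0.7
    centre <- c(1.35, 0, 0) + 8 * c(cos(ang), sin(ang), 0.3)
    emit("N", "GLY", rn, centre + c(-0.7, 0.5, 0), "N")
    emit("CA", "GLY", rn, centre, "C")
    emit("C", "GLY", rn, centre + c(0.7, 0.5, 0), "C")
    emit("O", "GLY", rn, centre + c(0.9, 1.6, 0), "O")
  }

  # distal L2-like loop, ~16-18 A from the core
  for (kk in 0:3) {
    rn <- 30 + kk
    centre <- c(1.35 + 16 + 1.2 * kk, 4 * sin(kk), 6)
    emit("N", "ALA", rn, centre + c(-0.7, 0.5, 0), "N")
    emit("CA", "ALA", rn, centre, "C")
    emit("CB", "ALA", rn, centre + c(0, -1.2, 0.8), "C")
    emit("C", "ALA", rn, centre + c(0.7, 0.5, 0), "C")
    emit("O", "ALA", rn, centre + c(0.9, 1.6, 0), "O")
  }

  # probe residues at controlled nearest-atom distances from the core:
  # nearest atom is CB, placed along +z / -z above Fe_X
  d_in <- extra_residue_dist[1]
  d_out <- extra_residue_dist[2]
  cb40 <- fex + c(0, 0, d_in)
  emit("CB", "ALA", 40, cb40, "C")
  emit("CA", "ALA", 40, cb40 + c(0, 0, 1.53), "C")
  emit("N", "ALA", 40, cb40 + c(-1.0, 0.6, 2.0), "N")
  emit("C", "ALA", 40, cb40 + c(1.0, 0.6, 2.0), "C")
  emit("O", "ALA", 40, cb40 + c(1.2, 1.7, 2.3), "O")
  cb41 <- fex + c(0, 0, -d_out)
  emit("CB", "ALA", 41, cb41, "C")
  emit("CA", "ALA", 41, cb41 - c(0, 0, 1.53), "C")
  emit("N", "ALA", 41, cb41 - c(1.0, -0.6, 2.0), "N")
  emit("C", "ALA", 41, cb41 - c(-1.0, -0.6, 2.0), "C")
  emit("O", "ALA", 41, cb41 - c(-1.2, -1.7, 2.3), "O")

  # the inorganic cluster
  emit("FE1", "FES", 201, fex, "Fe")
  emit("FE2", "FES", 201, fey, "Fe")
  emit("S1", "FES", 201, s1, "S")
  emit("S2", "FES", 201, s2, "S")
  lines <- c(lines, "END")

  dist <- function(a, b) sqrt(sum((a - b)^2))
  truth <- list(
    ligand_resnos = c(Cys1 = 10, Cys2 = 12, Cys3 = 15, His = 17),
    spanning_resnos = c(11, 13, 14, 16),
    distal_loop_resnos = 30:33,
    probe_resnos = c(included = 40, excluded = 41),
    probe_dist_A = c(included = d_in, excluded = d_out),
    bonds_A = c("Fe_X-S_1" = dist(fex, s1), "Fe_X-S_2" = dist(fex, s2),
                "Fe_Y-S_1" = dist(fey, s1), "Fe_Y-S_2" = dist(fey, s2),
                "Fe_X-S_Cys1" = 2.25, "Fe_X-S_Cys2" = 2.25,
                "Fe_Y-S_Cys3" = 2.25, "Fe_Y-N_His" = 2.18))
  list(text = lines, truth = truth)
}

#' Write the synthetic NEET-like structure and read it back
#'
#' Convenience wrapper: writes [gen_mock_neet_structure()] output to
#' `path` (default a temporary file) and returns the parsed bio3d `pdb`
#' together with the ground truth.
#'
#' @param seed Passed through.
#' @param path Output PDB path.
#' @param ... Passed to [gen_mock_neet_structure()].
#' @return List with `pdb`, `path`, `truth`.
#' @export
mock_neet_pdb <- function(seed = 1, path = tempfile(fileext = ".pdb"), ...) {
  g <- gen_mock_neet_structure(seed, ...)
  writeLines(g$text, path)
  list(pdb = bio3d::read.pdb(path, verbose = FALSE), path = path,
       truth = g$truth)
}
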