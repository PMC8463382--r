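# Bonded force-field parameters for the cluster: Seminario bond force
# constants from a Cartesian Hessian, Merz-Kollman ESP probe shells and
# restrained ESP (RESP) charge fitting.
#
# Hessians are Hartree/Bohr^2; emitted force constants are kJ/mol nm^2
# under the AMBER convention E = K_r (r - r0)^2 (no 1/2 factor), so the raw
# curvature d2E/dr2 extracted from the Hessian is halved on output.

#' Construct a Hessian container
#'
#' @param H 3N x 3N symmetric matrix of Cartesian second derivatives
#'   (Hartree/Bohr^2).
#' @param coords N x 3 atom coordinates (Bohr).
#' @param elements Character element symbols, length N.
#' @return A `hessian_matrix` object.
#' @export
hessian_matrix <- function(H, coords, elements) {
  H <- as.matrix(H)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (nrow(H) != 3 * n || ncol(H) != 3 * n) {
    stop("Hessian dimension does not match 3 x atom count")
  }
  if (max(abs(H - t(H))) > 1e-8 * max(1, max(abs(H)))) {
    stop("Hessian is not symmetric")
  }
  structure(list(H = (H + t(H)) / 2, coords = coords,
                 elements = as.character(elements)),
            class = "hessian_matrix")
}

#' Seminario bond force constant from a Cartesian Hessian
#'
#' Extracts the 3x3 interatomic Hessian block between atoms `i` and `j`,
#' eigendecomposes its negative, and projects onto the unit bond vector:
#' `k_raw = sum_m |lambda_m| |v_m . u|`. The i->j and j->i estimates are
#' averaged. Absolute eigenvalues are used (standard MCPB practice; recorded
#' in the result). `k_raw` is the curvature `d2E/dr2`, converted to
#' kJ/mol nm^2 and halved to the AMBER `E = K_r (r - r0)^2` convention.
#'
#' @param hess A [hessian_matrix()].
#' @param i,j Atom indices (1-based, distinct).
#' @return A `bond_param` list: `atoms`, `R_min_nm`, `K_r` (kJ/mol nm^2),
#'   `k_ij`, `k_ji` (the two directional estimates, same units),
#'   `convention`, `eigen_policy`.
#' @export
seminario_bond_constant <- function(hess, i, j) {
  stopifnot(i != j)
  n <- nrow(hess$coords)
  stopifnot(i >= 1, j >= 1, i <= n, j <= n)
  bi <- (3 * (i - 1) + 1):(3 * i)
  bj <- (3 * (j - 1) + 1):(3 * j)
  rij <- hess$coords[j, ] - hess$coords[i, ]
  r <- sqrt(sum(rij^2))
  u <- rij / r

  proj_k <- function(block) {
    if (sqrt(sum(block^2)) < 1e-10) stop("atoms not coupled in Hessian")
    A <- -(block + t(block)) / 2
    e <- eigen(A, symmetric = TRUE)
    sum(abs(e$values) * abs(as.numeric(t(e$vectors) %*% u)))
  }
  k_ij <- proj_k(hess$H[bi, bj])
  k_ji <- proj_k(hess$H[bj, bi])
  k_raw <- (k_ij + k_ji) / 2            # Hartree/Bohr^2, = d2E/dr2
  conv <- .HB2_KJMOLNM2
  structure(list(
    atoms = c(i, j),
    elements = hess$elements[c(i, j)],
    R_min_nm = r * .BOHR_A / 10,
    K_r = k_raw * conv / 2,
    k_ij = k_ij * conv / 2, k_ji = k_ji * conv / 2,
    convention = "E = K_r (r - R_min)^2",
    eigen_policy = "absolute eigenvalues"
  ), class = "bond_param")
}

#' @export
print.bond_param <- function(x, ...) {
  cat(sprintf("bond %s%d-%s%d: R_min = %.4f nm, K_r = %.1f kJ/mol nm^2 [%s]\n",
              x$elements[1], x$atoms[1], x$elements[2], x$atoms[2],
              x$R_min_nm, x$K_r, x$convention))
  invisible(x)
}

#' Read a Hessian from a formatted-checkpoint-style text file
#'
#' Parses the `Number of atoms`, `Atomic numbers`, `Current cartesian
#' coordinates` and `Cartesian Force Constants` (lower-triangle) blocks of
#' a Gaussian formatted-checkpoint file. Units are preserved
#' (Bohr, Hartree/Bohr^2).
#'
#' @param path File path.
#' @return A [hessian_matrix()].
#' @export
hessian_from_fchk <- function(path) {
  lines <- readLines(path)
  read_block <- function(label) {
    hit <- grep(paste0("^", label), lines)
    if (length(hit) == 0) stop("fchk block not found: ", label)
    hdr <- lines[hit[1]]
    nv <- as.integer(sub(".*N=\\s*(\\d+).*", "\\1", hdr))
    vals <- numeric(0)
    k <- hit[1] + 1
    while (length(vals) < nv && k <= length(lines)) {
      vals <- c(vals, scan(text = lines[k], quiet = TRUE))
      k <- k + 1
    }
    if (length(vals) != nv) {
      stop(sprintf("fchk block '%s': expected %d values, found %d",
                   label, nv, length(vals)))
    }
    vals
  }
  natoms_line <- grep("^Number of atoms", lines, value = TRUE)
  if (length(natoms_line) == 0) stop("fchk: 'Number of atoms' missing")
  n <- as.integer(sub(".*?(\\d+)\\s*$", "\\1", natoms_line[1]))
  z <- read_block("Atomic numbers")
  xyz <- matrix(read_block("Current cartesian coordinates"), ncol = 3,
                byrow = TRUE)
  tri <- read_block("Cartesian Force Constants")
  m <- 3L * n
  if (length(tri) != m * (m + 1) / 2) {
    stop(sprintf("fchk force-constant block length %d != 3N(3N+1)/2 = %d",
                 length(tri), m * (m + 1) / 2))
  }
  H <- matrix(0, m, m)
  H[upper.tri(H, diag = TRUE)] <- tri   # row-wise lower triangle = col-wise upper
  H <- H + t(H) - diag(diag(H))
  hessian_matrix(H, xyz, z_to_element(z))
}

# Bondi van der Waals radii (Angstrom); Fe per common MK practice
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
                S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, Fe = 2.00,
                Zn = 1.39, Na = 2.27, K = 2.75, Mg = 1.73, Ca = 2.31)

# deterministic near-uniform points on the unit sphere (Fibonacci spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Merz-Kollman ESP probe shells
#'
#' Lays approximately uniform points (deterministic Fibonacci spiral) on
#' nested shells at multiples of each atom's van der Waals radius, pruning
#' any point that falls inside the same-scale shell of another atom — the
#' Merz-Kollman surface construction used for ESP charge fitting.
#'
#' @param atoms Data frame with `element`, `x`, `y`, `z` (Angstrom).
#' @param scales Shell scale factors (default `c(1.4, 1.6, 1.8, 2.0)`).
#' @param density Target surface density, points per square Angstrom.
#' @param radii Named vdW radii (Angstrom) overriding the built-in table.
#' @return Matrix of probe points (Angstrom) with attribute `shell` giving
#'   each point's scale factor.
#' @export
mk_probe_shells <- function(atoms, scales = c(1.4, 1.6, 1.8, 2.0),
                            density = 1.0, radii = NULL) {
  atoms <- as.data.frame(atoms)
  rv <- .VDW_RADII
  if (!is.null(radii)) rv[names(radii)] <- radii
  unknown <- setdiff(unique(atoms$element), names(rv))
  if (length(unknown)) {
    stop("no van der Waals radius for element: ",
         paste(unknown, collapse = ", "))
  }
  axyz <- as.matrix(atoms[, c("x", "y", "z")])
  r_at <- rv[atoms$element]
  pts <- NULL
  shell <- numeric(0)
  for (f in scales) {
    for (a in seq_len(nrow(atoms))) {
      r <- f * r_at[a]
      npt <- max(4L, round(density * 4 * pi * r^2))
      p <- fibonacci_sphere(npt) * r +
        matrix(axyz[a, ], npt, 3, byrow = TRUE)
      keep <- rep(TRUE, npt)
      for (b in seq_len(nrow(atoms))) {
        if (b == a) next
        d2 <- colSums((t(p) - axyz[b, ])^2)
        keep <- keep & d2 >= (f * r_at[b])^2 * (1 - 1e-12)
      }
      if (any(keep)) {
        pts <- rbind(pts, p[keep, , drop = FALSE])
        shell <- c(shell, rep(f, sum(keep)))
      }
    }
  }
  structure(pts, shell = shell)
}

#' Construct an ESP grid for charge fitting
#'
#' @param points M x 3 probe positions (Bohr).
#' @param v Potential at each probe (Hartree/e).
#' @param atoms Data frame with `element`, `x`, `y`, `z` (Bohr).
#' @param total_charge Net molecular charge constraint (e).
#' @param classes Optional integer vector, one per atom: atoms sharing a
#'   class index are constrained to equal charge (NA = unconstrained).
#' @return An `esp_grid` object.
#' @export
esp_grid <- function(points, v, atoms, total_charge, classes = NULL) {
  points <- as.matrix(points)
  atoms <- as.data.frame(atoms)
  stopifnot(nrow(points) == length(v))
  if (nrow(points) < nrow(atoms)) {
    stop("fewer probe points than atoms: fit underdetermined")
  }
  structure(list(points = points, v = as.numeric(v), atoms = atoms,
                 total_charge = as.numeric(total_charge),
                 classes = classes),
            class = "esp_grid")
}

#' Restrained ESP (RESP) charge fit
#'
#' Least-squares fit of atomic point charges to electrostatic-potential
#' probe values, with a hyperbolic restraint
#' `a * sum_A (sqrt(q_A^2 + b^2) - b)` toward zero on non-hydrogen atoms,
#' the total-charge constraint and any symmetry-class equalities enforced
#' exactly by Lagrange multipliers. Solved by iterated reweighted linear
#' solves; converges deterministically when successive charge sets agree to
#' `tol`.
#'
#' @param grid An [esp_grid()].
#' @param restraint_a Restraint strength in atomic units (default 0.0005;
#'   0 gives the unrestrained ESP fit).
#' @param b Hyperbolic restraint width (e), default 0.1.
#' @param restrain_h Include hydrogens in the restraint (default FALSE).
#' @param tol Convergence threshold on max |delta q| (default 1e-10).
#' @param maxit Maximum reweighting iterations.
#' @return Numeric vector of fitted charges (e), with attributes
#'   `iterations` and `rrms` (relative RMS error of the potential fit).
#' @export
esp_fit_charges <- function(grid, restraint_a = 0.0005, b = 0.1,
                            restrain_h = FALSE, tol = 1e-10, maxit = 200) {
  P <- grid$points
  axyz <- as.matrix(grid$atoms[, c("x", "y", "z")])
  n_at <- nrow(axyz)
  # design matrix: 1/r from each atom to each probe
  A <- matrix(0, nrow(P), n_at)
  for (a in seq_len(n_at)) {
    d <- sqrt(colSums((t(P) - axyz[a, ])^2))
    if (any(d < 1e-8)) {
      stop("probe point ", which(d < 1e-8)[1],
           " coincides with atom ", a, ": singular design")
    }
    A[, a] <- 1 / d
  }
  AtA <- crossprod(A)
  AtV <- crossprod(A, grid$v)

  # constraint rows: total charge, then symmetry-class equalities
  C <- matrix(1, 1, n_at)
  cval <- grid$total_charge
  if (!is.null(grid$classes)) {
    for (cl in unique(stats::na.omit(grid$classes))) {
      mem <- which(grid$classes == cl)
      if (length(mem) > 1) {
        for (m in mem[-1]) {
          row <- numeric(n_at)
          row[mem[1]] <- 1; row[m] <- -1
          C <- rbind(C, row)
          cval <- c(cval, 0)
        }
      }
    }
  }
  nc <- nrow(C)
  restr_mask <- if (restrain_h) rep(TRUE, n_at) else grid$atoms$element != "H"

  q <- rep(grid$total_charge / n_at, n_at)
  it <- 0L
  repeat {
    it <- it + 1L
    w <- numeric(n_at)
    if (restraint_a > 0) {
      w[restr_mask] <- restraint_a / (2 * sqrt(q[restr_mask]^2 + b^2))
    }
    M <- rbind(cbind(AtA + diag(w, n_at), t(C)),
               cbind(C, matrix(0, nc, nc)))
    rhs <- c(AtV, cval)
    sol <- tryCatch(solve(M, rhs),
                    error = function(e) stop("singular RESP system: ",
                                             conditionMessage(e)))
    q_new <- sol[seq_len(n_at)]
    if (max(abs(q_new - q)) < tol || restraint_a == 0 || it >= maxit) {
      q <- q_new
      break
    }
    q <- q_new
  }
  resid <- grid$v - as.numeric(A %*% q)
  rrms <- sqrt(sum(resid^2) / max(sum(grid$v^2), .Machine$double.eps))
  structure(q, iterations = it, rrms = rrms)
}
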