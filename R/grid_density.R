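# Gaussian cube I/O and grid algebra: difference densities, charge
# integration, orbital-localization fractions.
#
# A density_grid stores its voxel values as a single numeric vector in the
# cube file's canonical order (first axis outermost, third axis innermost);
# grid_points() reproduces the matching voxel coordinates. All internal
# lengths are Bohr, all charges e.

#' Construct a density grid
#'
#' A regular voxel lattice with an embedded atom list, the container for
#' electron densities (rho_ox, rho_red) and their difference (delta-rho).
#' Axis vectors need not be orthogonal; the voxel volume is the absolute
#' determinant of the axis matrix.
#'
#' @param origin Numeric length-3, grid origin in Bohr.
#' @param axes 3x3 numeric matrix; row i is the step vector of axis i (Bohr).
#' @param counts Integer length-3, voxels along each axis (all >= 1).
#' @param values Numeric vector of length `prod(counts)` in cube order
#'   (first axis slowest, third fastest), units e/Bohr^3.
#' @param atoms Data frame with columns `element`, `znum`, `x`, `y`, `z`
#'   (positions in Bohr).
#' @param is_orbital Logical, whether the grid came from an MO-style cube.
#' @return An object of class `density_grid`.
#' @export
density_grid <- function(origin, axes, counts, values, atoms,
                         is_orbital = FALSE) {
  origin <- as.numeric(origin)
  axes <- matrix(as.numeric(axes), 3, 3)
  counts <- as.integer(counts)
  stopifnot(length(origin) == 3L, length(counts) == 3L)
  if (any(counts < 1L)) stop("all voxel counts must be >= 1")
  if (length(values) != prod(counts)) {
    stop(sprintf("expected %d voxel values, found %d",
                 prod(counts), length(values)))
  }
  if (abs(det(axes)) <= 0) stop("axis vectors are singular (zero volume)")
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$znum)) atoms$znum <- element_to_z(atoms$element)
  structure(
    list(origin = origin, axes = axes, counts = counts,
         values = as.numeric(values), atoms = atoms,
         is_orbital = isTRUE(is_orbital)),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid: %d x %d x %d voxels, %d atoms%s\n",
              x$counts[1], x$counts[2], x$counts[3], nrow(x$atoms),
              if (x$is_orbital) " (orbital cube)" else ""))
  cat(sprintf("  voxel volume %.6g Bohr^3, total integral %.6g e\n",
              voxel_volume(x), integrate_total(x)))
  invisible(x)
}

#' Voxel volume of a density grid
#'
#' @param grid A `density_grid`.
#' @return Volume of one voxel in Bohr^3 (`|det(axes)|`).
#' @export
voxel_volume <- function(grid) abs(det(grid$axes))

#' Cartesian coordinates of every voxel
#'
#' Returns voxel positions in the same canonical order as `grid$values`.
#'
#' @param grid A `density_grid`.
#' @return `prod(counts)` x 3 matrix of positions (Bohr).
#' @export
grid_points <- function(grid) {
  n <- grid$counts
  # cube order: i (axis 1) slowest, k (axis 3) fastest
  i <- rep(seq_len(n[1]) - 1L, each = n[2] * n[3])
  j <- rep(rep(seq_len(n[2]) - 1L, each = n[3]), times = n[1])
  k <- rep(seq_len(n[3]) - 1L, times = n[1] * n[2])
  cbind(i, j, k) %*% grid$axes +
    matrix(grid$origin, length(i), 3, byrow = TRUE)
}

# minimal symbol <-> Z table; covers the elements seen in these systems
.ELEMENTS <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
               F = 9, Ne = 10, Na = 11, Mg = 12, P = 15, S = 16, Cl = 17,
               K = 19, Ca = 20, Mn = 25, Fe = 26, Co = 27, Ni = 28,
               Cu = 29, Zn = 30, Se = 34, Br = 35, I = 53)

element_to_z <- function(sym) {
  sym <- paste0(toupper(substr(sym, 1, 1)), tolower(substring(sym, 2)))
  z <- .ELEMENTS[sym]
  if (anyNA(z)) stop("unknown element symbol: ",
                     paste(unique(sym[is.na(z)]), collapse = ", "))
  unname(z)
}

z_to_element <- function(z) {
  idx <- match(z, .ELEMENTS)
  out <- names(.ELEMENTS)[idx]
  out[is.na(idx)] <- "X"
  out
}

#' Read a Gaussian cube file
#'
#' Handles both sign dialects of the format: a negative atom count marks an
#' orbital cube (one extra header record is skipped, the orbital flag is
#' set), and negative voxel counts mark axis vectors given in Angstrom
#' (converted to Bohr on read). The returned grid is always in Bohr.
#'
#' @param path Path to a cube file.
#' @return A [density_grid()].
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("cube file too short: ", path)
  hdr <- scan(text = lines[3], quiet = TRUE)
  natoms <- as.integer(hdr[1])
  origin <- hdr[2:4]
  is_orbital <- natoms < 0
  natoms <- abs(natoms)

  axes <- matrix(0, 3, 3)
  counts <- integer(3)
  unit <- c(1, 1, 1)
  for (a in 1:3) {
    rec <- scan(text = lines[3 + a], quiet = TRUE)
    counts[a] <- as.integer(rec[1])
    if (counts[a] < 0) {        # Angstrom dialect
      counts[a] <- -counts[a]
      unit[a] <- 1 / .BOHR_A
    }
    axes[a, ] <- rec[2:4] * unit[a]
  }

  at_lines <- lines[7:(6 + natoms)]
  at <- do.call(rbind, lapply(at_lines, function(l) scan(text = l, quiet = TRUE)))
  atoms <- data.frame(element = z_to_element(at[, 1]),
                      znum = at[, 1],
                      x = at[, 3], y = at[, 4], z = at[, 5])

  body_start <- 7L + natoms
  if (is_orbital) body_start <- body_start + 1L  # skip the MO-id record
  vals <- scan(text = lines[body_start:length(lines)], quiet = TRUE)
  nexp <- prod(counts)
  if (length(vals) != nexp) {
    stop(sprintf("truncated cube value block in %s: expected %d values, found %d",
                 path, nexp, length(vals)))
  }
  density_grid(origin, axes, counts, vals, atoms, is_orbital = is_orbital)
}

#' Write a density grid as a Gaussian cube file
#'
#' Always writes in Bohr with positive voxel counts; the orbital flag is
#' encoded as a negative atom count with the extra MO header record.
#'
#' @param grid A `density_grid`.
#' @param path Output path.
#' @param comment Two-line header comment (character length 1 or 2).
#' @return `path`, invisibly.
#' @export
write_cube <- function(grid, path, comment = "neetkit density grid") {
  comment <- rep_len(comment, 2)
  natoms <- nrow(grid$atoms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  fmt3 <- function(n, v) sprintf("%5d %11.6f %11.6f %11.6f", n, v[1], v[2], v[3])
  writeLines(fmt3(if (grid$is_orbital) -natoms else natoms, grid$origin), con)
  for (a in 1:3) writeLines(fmt3(grid$counts[a], grid$axes[a, ]), con)
  for (r in seq_len(natoms)) {
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                       grid$atoms$znum[r], as.numeric(grid$atoms$znum[r]),
                       grid$atoms$x[r], grid$atoms$y[r], grid$atoms$z[r]), con)
  }
  if (grid$is_orbital) writeLines(sprintf("%5d %5d", 1L, 1L), con)
  v <- grid$values
  # six values per record, %13.5E, in canonical cube order
  pad <- (-length(v)) %% 6
  vp <- c(v, rep(NA_real_, pad))
  m <- matrix(sprintf("%13.5E", vp), ncol = 6, byrow = TRUE)
  if (pad > 0) m[nrow(m), (6 - pad + 1):6] <- ""
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}

lattices_match <- function(a, b, tol = 1e-6) {
  all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$axes - b$axes) < tol) &&
    all(a$counts == b$counts)
}

#' Difference density between two redox states
#'
#' Voxel-wise `red - ox`, the change in electron density on one-electron
#' reduction when both states were evaluated on the same lattice. Lattice
#' mismatch is an error: resampling would silently change integrated
#' charges.
#'
#' @param red,ox `density_grid` objects on identical lattices with the same
#'   atom list.
#' @param tol Lattice comparison tolerance (Bohr).
#' @return A `density_grid` holding the difference density.
#' @export
subtract_density <- function(red, ox, tol = 1e-6) {
  if (!lattices_match(red, ox, tol)) {
    stop("density lattices do not match (origin/axes/counts); ",
         "refusing to resample")
  }
  if (nrow(red$atoms) != nrow(ox$atoms) ||
      max(abs(as.matrix(red$atoms[, c("x", "y", "z")]) -
              as.matrix(ox$atoms[, c("x", "y", "z")]))) > tol) {
    stop("atom lists of the two grids differ")
  }
  out <- red
  out$values <- red$values - ox$values
  out$is_orbital <- FALSE
  out
}

#' Total charge on a grid
#'
#' Midpoint Riemann sum: sum of voxel values times the voxel volume.
#'
#' @param grid A `density_grid`.
#' @return Total integrated charge (e).
#' @export
integrate_total <- function(grid) sum(grid$values) * voxel_volume(grid)

# index of the nearest atom (ties -> lowest atom index) for each point
nearest_atom_index <- function(points, axyz) {
  n <- nrow(points)
  best <- rep.int(1L, n)
  bestd <- colSums((t(points) - axyz[1, ])^2)
  if (nrow(axyz) > 1) {
    for (a in 2:nrow(axyz)) {
      d <- colSums((t(points) - axyz[a, ])^2)
      upd <- d < bestd        # strict: earlier atom keeps ties
      best[upd] <- a
      bestd[upd] <- d[upd]
    }
  }
  list(index = best, dist2 = bestd)
}

#' Partition a density into per-atom charges
#'
#' Integrates the grid around atoms under one of two schemes. The default,
#' `"nearest-atom"`, assigns every voxel to its closest atom (Voronoi cells,
#' ties to the lowest atom index), so the partition is exhaustive and the
#' per-atom charges sum to the total integral exactly. The `"spheres"`
#' scheme assigns only voxels within `radius` of any selected atom (to the
#' closest selected atom) and reports the remainder as unassigned.
#'
#' @param grid A `density_grid` with at least one atom.
#' @param scheme `"nearest-atom"` (default) or `"spheres"`.
#' @param selection Integer atom indices; required for `"spheres"`, ignored
#'   (all atoms) for `"nearest-atom"`.
#' @param radius Sphere radius in Bohr (required for `"spheres"`).
#' @return A `charge_table` data frame with columns `atom_index`, `element`,
#'   `dq_e`, plus attributes `total` (full grid integral), `assigned`,
#'   `unassigned` and `scheme`.
#' @export
partition_charges <- function(grid, scheme = c("nearest-atom", "spheres"),
                              selection = NULL, radius = NULL) {
  scheme <- match.arg(scheme)
  if (nrow(grid$atoms) < 1) stop("grid carries no atoms")
  axyz <- as.matrix(grid$atoms[, c("x", "y", "z")])
  pts <- grid_points(grid)
  vv <- voxel_volume(grid)
  total <- sum(grid$values) * vv

  if (scheme == "nearest-atom") {
    sel <- seq_len(nrow(axyz))
    na <- nearest_atom_index(pts, axyz)
    dq <- vapply(sel, function(a) sum(grid$values[na$index == a]) * vv,
                 numeric(1))
    unassigned <- 0
  } else {
    if (is.null(selection) || length(selection) == 0) {
      stop("'spheres' scheme requires a non-empty atom selection")
    }
    if (is.null(radius) || radius <= 0) stop("'spheres' requires radius > 0")
    sel <- as.integer(selection)
    na <- nearest_atom_index(pts, axyz[sel, , drop = FALSE])
    inside <- na$dist2 <= radius^2
    dq <- vapply(seq_along(sel), function(a) {
      sum(grid$values[inside & na$index == a]) * vv
    }, numeric(1))
    unassigned <- total - sum(dq)
  }

  out <- data.frame(atom_index = sel,
                    element = grid$atoms$element[sel],
                    dq_e = dq)
  structure(out,
            total = total, assigned = sum(dq), unassigned = unassigned,
            scheme = scheme,
            class = c("charge_table", "data.frame"))
}

#' @export
print.charge_table <- function(x, ...) {
  cat(sprintf("charge_table (%s partition): total %.6g e, unassigned %.3g e\n",
              attr(x, "scheme"), attr(x, "total"), attr(x, "unassigned")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Orbital localization fractions over atom groups
#'
#' For an orbital-density (|MO|^2) cube, reports the fraction of the total
#' density that the nearest-atom partition assigns to each named group of
#' atoms. Fractions over all atoms sum to 1; used to ask where a frontier
#' orbital lives (e.g. on the His-bound iron versus the other iron).
#'
#' @param grid A `density_grid` holding a non-negative orbital density.
#' @param groups Named list of integer atom-index vectors (disjoint).
#' @return Named numeric vector of fractions, with attribute `total`.
#' @export
group_localization <- function(grid, groups) {
  stopifnot(is.list(groups), length(groups) >= 1)
  idx <- unlist(groups)
  if (anyDuplicated(idx)) stop("groups must be disjoint")
  tot <- integrate_total(grid)
  if (tot <= 0) stop("total orbital density is not positive; cannot form fractions")
  ct <- partition_charges(grid, "nearest-atom")
  fr <- vapply(groups, function(g) sum(ct$dq_e[match(g, ct$atom_index)]) / tot,
               numeric(1))
  structure(fr, total = tot)
}
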