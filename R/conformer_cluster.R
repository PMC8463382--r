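# GROMOS-style conformational clustering: pairwise Kabsch RMSD matrix,
# greedy neighbor-count clustering at a fixed cutoff, representative
# (cluster-seed) extraction. Coordinates are nm throughout; the default
# backbone selection is N, CA, C.

#' Construct a conformation set
#'
#' @param xyz Numeric array `M x N x 3`: M frames of N selected atoms (nm).
#' @param labels Optional frame labels (default frame index).
#' @return A `conformation_set` object.
#' @export
conformation_set <- function(xyz, labels = NULL) {
  xyz <- unclass(xyz)
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[3] == 3)
  if (is.null(labels)) labels <- seq_len(dim(xyz)[1])
  stopifnot(length(labels) == dim(xyz)[1])
  structure(list(xyz = xyz, labels = labels), class = "conformation_set")
}

#' @export
print.conformation_set <- function(x, ...) {
  cat(sprintf("conformation_set: %d frames x %d atoms\n",
              dim(x$xyz)[1], dim(x$xyz)[2]))
  invisible(x)
}

#' Read conformers from a multi-model PDB or XYZ trajectory
#'
#' PDB models become frames; coordinates are converted from Angstrom to nm.
#' The atom selection follows the clustering metric: `"backbone"` keeps
#' N, CA, C; `"calpha"` keeps CA; `"all"` keeps everything.
#'
#' @param path Trajectory file (multi-model PDB, or plain XYZ with frames
#'   concatenated).
#' @param select Atom selection for PDB input.
#' @return A [conformation_set()] (nm).
#' @export
read_conformers <- function(path, select = c("backbone", "calpha", "all")) {
  select <- match.arg(select)
  first <- readLines(path, n = 1)
  if (grepl("^\\s*[0-9]+\\s*$", first)) {   # XYZ
    lines <- readLines(path)
    nat <- as.integer(trimws(lines[1]))
    per <- nat + 2L
    nframes <- length(lines) %/% per
    xyz <- array(NA_real_, c(nframes, nat, 3))
    for (f in seq_len(nframes)) {
      block <- lines[((f - 1) * per + 3):((f - 1) * per + 2 + nat)]
      m <- do.call(rbind, lapply(block, function(l) {
        scan(text = l, what = list("", 0, 0, 0), quiet = TRUE)[2:4]
      }))
      xyz[f, , ] <- matrix(unlist(m), nat, 3) / 10
    }
    return(conformation_set(xyz))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  elety <- trimws(pdb$atom$elety)
  keep <- switch(select,
                 backbone = which(elety %in% c("N", "CA", "C")),
                 calpha = which(elety == "CA"),
                 all = seq_along(elety))
  nframes <- nrow(pdb$xyz)
  nat <- length(keep)
  xyz <- array(NA_real_, c(nframes, nat, 3))
  for (f in seq_len(nframes)) {
    m <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
    xyz[f, , ] <- m[keep, , drop = FALSE] / 10
  }
  conformation_set(xyz)
}

#' Pairwise RMSD matrix of a conformation set
#'
#' Each entry is the Kabsch-minimized RMSD between two frames (rigid
#' motions removed by [superpose_rmsd()] on the stored selection).
#'
#' @param set A `conformation_set` with >= 2 frames and >= 3 atoms.
#' @return Symmetric M x M matrix (nm) with zero diagonal.
#' @export
pairwise_rmsd <- function(set) {
  stopifnot(inherits(set, "conformation_set"))
  M <- dim(set$xyz)[1]
  if (M < 2) stop("need at least 2 frames")
  if (dim(set$xyz)[2] < 3) stop("need at least 3 atoms per frame")
  D <- matrix(0, M, M)
  for (a in seq_len(M - 1)) {
    for (b in (a + 1):M) {
      D[a, b] <- D[b, a] <-
        superpose_rmsd(set$xyz[a, , ], set$xyz[b, , ])$rmsd
    }
  }
  D
}

#' GROMOS clustering of a distance matrix
#'
#' The greedy neighbor-count algorithm: repeatedly take the frame with the
#' most neighbors within `cutoff` (ties to the lowest frame index), make it
#' and its neighbors a cluster with the seed as representative, remove
#' them, and continue until no frames remain. Neighbors use a non-strict
#' comparison (`<= cutoff`).
#'
#' @param matrix Symmetric distance matrix (nm).
#' @param cutoff RMSD cutoff in nm (default 0.11, the backbone cutoff used
#'   for picking MD representatives).
#' @return A `clustering_result`: `clusters` (list of frame-index vectors,
#'   seed first), `representatives`, `cutoff`.
#' @export
gromos_cluster <- function(matrix, cutoff = 0.11) {
  D <- as.matrix(matrix)
  stopifnot(nrow(D) == ncol(D), cutoff > 0)
  remaining <- seq_len(nrow(D))
  clusters <- list()
  reps <- integer(0)
  while (length(remaining) > 0) {
    sub <- D[remaining, remaining, drop = FALSE]
    ncount <- rowSums(sub <= cutoff)      # includes self
    seed_local <- which.max(ncount)       # which.max takes the first tie
    members_local <- which(sub[seed_local, ] <= cutoff)
    members <- remaining[members_local]
    seed <- remaining[seed_local]
    clusters <- c(clusters, list(c(seed, setdiff(members, seed))))
    reps <- c(reps, seed)
    remaining <- setdiff(remaining, members)
  }
  structure(list(clusters = clusters, representatives = reps,
                 cutoff = cutoff),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("clustering_result: %d cluster(s) at cutoff %.3f nm; sizes %s\n",
              length(x$clusters), x$cutoff, paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Representative conformations ordered by cluster size
#'
#' One representative (the cluster seed) per cluster, with its occupancy
#' fraction; ordered by decreasing cluster size (ties by seed frame index).
#'
#' @param result A `clustering_result`.
#' @param set The `conformation_set` that was clustered.
#' @return List with `frames` (seed frame indices), `occupancy`
#'   (fractions summing to 1), `xyz` (representative coordinates,
#'   R x N x 3 nm) and `cluster_sizes`.
#' @export
representatives <- function(result, set) {
  stopifnot(inherits(result, "clustering_result"),
            inherits(set, "conformation_set"))
  M <- dim(set$xyz)[1]
  sizes <- lengths(result$clusters)
  ord <- order(-sizes, result$representatives)
  frames <- result$representatives[ord]
  xyz <- set$xyz[frames, , , drop = FALSE]
  list(frames = frames, occupancy = sizes[ord] / M, xyz = xyz,
       cluster_sizes = sizes[ord])
}

#' Write a conformation set as a multi-model PDB
#'
#' Frames become MODEL records; atoms are written as glycine C-alpha
#' pseudo-atoms unless atom names are supplied. Coordinates convert nm to
#' Angstrom.
#'
#' @param set A `conformation_set` (nm).
#' @param path Output path.
#' @param elety Atom names recycled over atoms (default `"CA"`).
#' @return `path`, invisibly.
#' @export
write_conformers <- function(set, path, elety = "CA") {
  nat <- dim(set$xyz)[2]
  elety <- rep_len(elety, nat)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(set$xyz)[1])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- set$xyz[f, , ] * 10
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nat), elety, "GLY", "A", seq_len(nat),
      m[, 1], m[, 2], m[, 3], 1.0, 0.0,
      toupper(substr(elety, 1, 1))), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
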