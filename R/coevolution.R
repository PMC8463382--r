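# Weighted chi-squared coevolution scoring over a multiple sequence
# alignment, min-max normalization to [0,1], and the strong-pair allostery
# screen against a 3-D structure (score > 0.7, top 30% of scores, and
# spatially distal).
#
# Alphabet: the 20 amino acids; gaps are pairwise-deleted, never a 21st
# symbol.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct an alignment object
#'
#' Accepts a character matrix (sequences x columns), a bio3d `fasta`
#' object, or a character vector of equal-length sequences.
#'
#' @param x Alignment input.
#' @param id Optional sequence identifiers.
#' @return An `alignment` object: list with `ali` (uppercase character
#'   matrix) and `id`.
#' @export
as_alignment <- function(x, id = NULL) {
  if (inherits(x, "alignment")) return(x)
  if (inherits(x, "fasta")) {
    id <- if (is.null(id)) x$id else id
    x <- x$ali
  }
  if (is.character(x) && is.null(dim(x))) {
    if (length(unique(nchar(x))) != 1) stop("sequences differ in length")
    x <- do.call(rbind, strsplit(x, ""))
  }
  x <- toupper(as.matrix(x))
  x[x %in% c(".", "~", " ")] <- "-"
  if (is.null(id)) id <- rownames(x)
  if (is.null(id)) id <- paste0("seq", seq_len(nrow(x)))
  structure(list(ali = unname(x), id = id), class = "alignment")
}

#' Read an alignment from FASTA or Stockholm
#'
#' FASTA goes through bio3d; Stockholm is parsed minimally
#' (`#` comments and `//` terminator skipped, `name seq` records
#' concatenated across blocks).
#'
#' @param path Alignment file.
#' @param format `"auto"` (sniff first character), `"fasta"` or
#'   `"stockholm"`.
#' @return An [as_alignment()] object.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, ">")) "fasta" else "stockholm"
  }
  if (format == "fasta") {
    return(as_alignment(bio3d::read.fasta(path)))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "//") &
                   nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  ids <- vapply(parts, `[`, "", 1)
  seqs <- vapply(parts, `[`, "", 2)
  agg <- tapply(seqs, factor(ids, levels = unique(ids)), paste, collapse = "")
  as_alignment(as.character(agg), id = names(agg))
}

# integer encoding: 1..20 for amino acids, 0 for gap/unknown
encode_alignment <- function(aln) {
  m <- match(aln$ali, .AA20)
  m[is.na(m)] <- 0L
  matrix(as.integer(m), nrow(aln$ali), ncol(aln$ali))
}

#' Identity-based sequence weights
#'
#' `weight_s = 1 / |{t : identity(s, t) >= cutoff}|` with self included, so
#' a cluster of near-identical sequences shares one unit of weight. Identity
#' is the fraction of matching positions over the full alignment length.
#'
#' @param aln An alignment (anything [as_alignment()] accepts).
#' @param identity_cutoff Clustering identity threshold (default 0.8).
#' @return Numeric weights, one per sequence; attribute `neff` holds their
#'   sum (effective sequence number).
#' @export
sequence_weights <- function(aln, identity_cutoff = 0.8) {
  aln <- as_alignment(aln)
  M <- encode_alignment(aln)
  n <- nrow(M)
  if (n < 2) stop("need at least 2 sequences")
  counts <- integer(n)
  for (s in seq_len(n)) {
    idy <- rowMeans(M == matrix(M[s, ], n, ncol(M), byrow = TRUE))
    counts[s] <- sum(idy >= identity_cutoff)
  }
  w <- 1 / counts
  structure(w, neff = sum(w))
}

chi2_from_counts <- function(O) {
  N <- sum(O)
  r <- rowSums(O); cc <- colSums(O)
  if (N <= 0) return(0)
  E <- outer(r, cc) / N
  ok <- E > 0
  sum((O[ok] - E[ok])^2 / E[ok])
}

#' Weighted chi-squared association between two alignment columns
#'
#' Builds the weighted joint contingency table of columns `i` and `j` over
#' sequences ungapped in both (pairwise deletion), and returns the Pearson
#' chi-squared statistic over cells with positive expectation. For a
#' perfectly covarying pair of binary columns with unit weights this equals
#' the number of paired sequences.
#'
#' @param aln An alignment.
#' @param i,j Column indices.
#' @param weights Optional per-sequence weights (default 1).
#' @return The raw chi-squared score (>= 0).
#' @export
weighted_chi2 <- function(aln, i, j, weights = NULL) {
  aln <- as_alignment(aln)
  M <- encode_alignment(aln)
  if (is.null(weights)) weights <- rep(1, nrow(M))
  a <- M[, i]; b <- M[, j]
  ok <- a > 0L & b > 0L
  if (sum(ok) < 2) {
    warning("fewer than 2 ungapped paired sequences; score 0")
    return(0)
  }
  O <- matrix(0, 20, 20)
  tab <- rowsum(weights[ok], group = (a[ok] - 1L) * 20L + b[ok])
  idx <- as.integer(rownames(tab))
  O[cbind((idx - 1L) %/% 20L + 1L, (idx - 1L) %% 20L + 1L)] <- tab[, 1]
  chi2_from_counts(O)
}

#' All-pairs weighted chi-squared score matrix
#'
#' Computes [weighted_chi2()] for every column pair in one pass: the
#' alignment is one-hot encoded (gap rows are zero rows, so pairwise
#' deletion and per-pair marginals fall out exactly) and all 20x20
#' contingency blocks are obtained from a single cross-product of the
#' weighted indicator matrix.
#'
#' @param aln An alignment.
#' @param weights Optional per-sequence weights (default 1).
#' @return Symmetric L x L matrix of raw chi-squared scores, diagonal `NA`.
#' @export
chi2_matrix <- function(aln, weights = NULL) {
  aln <- as_alignment(aln)
  M <- encode_alignment(aln)
  n <- nrow(M); L <- ncol(M)
  if (is.null(weights)) weights <- rep(1, n)
  E <- matrix(0, n, 20L * L)
  nz <- which(M > 0L, arr.ind = TRUE)
  E[cbind(nz[, 1], (nz[, 2] - 1L) * 20L + M[nz])] <- 1
  G <- crossprod(E * weights, E)     # all contingency blocks at once
  raw <- matrix(NA_real_, L, L)
  for (i in seq_len(L - 1)) {
    ri <- ((i - 1L) * 20L + 1L):(i * 20L)
    for (j in (i + 1L):L) {
      O <- G[ri, ((j - 1L) * 20L + 1L):(j * 20L)]
      raw[i, j] <- raw[j, i] <- if (sum(O) < 2) 0 else chi2_from_counts(O)
    }
  }
  raw
}

#' Normalize a raw score matrix to [0, 1]
#'
#' Min-max rescaling over the off-diagonal entries (the default), or a rank
#' transform (`"rank"`: each score replaced by its quantile among
#' off-diagonal scores). A constant matrix maps to 0.5 everywhere with a
#' warning.
#'
#' @param raw Symmetric L x L matrix of finite raw scores (diagonal
#'   ignored).
#' @param method `"minmax"` (default) or `"rank"`.
#' @return A `coevolution_matrix`: list with `scores` (L x L in \[0, 1\],
#'   diagonal `NA`), `method`, `raw_min`, `raw_max`.
#' @export
normalize_matrix <- function(raw, method = c("minmax", "rank")) {
  method <- match.arg(method)
  raw <- as.matrix(raw)
  L <- nrow(raw)
  off <- raw[upper.tri(raw)]
  if (any(!is.finite(off))) stop("raw scores must be finite")
  scores <- matrix(NA_real_, L, L)
  rng <- range(off)
  if (diff(rng) == 0) {
    warning("constant score matrix; all normalized scores set to 0.5")
    scores[upper.tri(scores)] <- 0.5
  } else if (method == "minmax") {
    scores[upper.tri(scores)] <- (off - rng[1]) / diff(rng)
  } else {
    scores[upper.tri(scores)] <- (rank(off) - 1) / (length(off) - 1)
  }
  scores[lower.tri(scores)] <- t(scores)[lower.tri(scores)]
  structure(list(scores = scores, method = method,
                 raw_min = rng[1], raw_max = rng[2]),
            class = "coevolution_matrix")
}

#' @export
print.coevolution_matrix <- function(x, ...) {
  cat(sprintf("coevolution_matrix: %d columns, %s-normalized (raw %.3g..%.3g)\n",
              nrow(x$scores), x$method, x$raw_min, x$raw_max))
  invisible(x)
}

# minimal heavy-atom distance between every residue pair of a structure
residue_min_distances <- function(pdb) {
  at <- pdb$atom
  elem <- pdb_elements(pdb)
  keep <- at$type == "ATOM" & elem != "H"
  at <- at[keep, ]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  key <- paste(at$chain, at$resno)
  resnos <- at$resno[!duplicated(key)]
  groups <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))
  nres <- length(groups)
  D <- matrix(Inf, nres, nres)
  for (a in seq_len(nres)) {
    pa <- xyz[groups[[a]], , drop = FALSE]
    for (b in seq_len(nres)) {
      if (b <= a) next
      pb <- xyz[groups[[b]], , drop = FALSE]
      d2 <- min(vapply(seq_len(nrow(pa)), function(r) {
        min(colSums((t(pb) - pa[r, ])^2))
      }, numeric(1)))
      D[a, b] <- D[b, a] <- sqrt(d2)
    }
  }
  diag(D) <- 0
  list(D = D, resno = resnos)
}

#' Strong-pair allostery screen
#'
#' Retains residue pairs whose normalized coevolution score exceeds
#' `score_min` AND lies within the top `top_fraction` of all off-diagonal
#' scores AND that are separated in sequence by at least `min_seq_sep` AND
#' whose minimal heavy-atom distance in the structure is at least
#' `min_distance` Angstrom ("not in close proximity"). The conjunction is
#' the default; `mode` relaxes it to either score filter alone.
#'
#' @param m A `coevolution_matrix`.
#' @param structure bio3d `pdb` object or path used for distances.
#' @param column_map Integer vector, length L: residue number of each
#'   alignment column in the structure (NA = unmappable). Default maps
#'   column k to the k-th residue of the structure.
#' @param score_min Absolute score threshold (default 0.7).
#' @param top_fraction Top fraction of scores retained (default 0.30).
#' @param min_seq_sep Minimum |i - j| in sequence (default 5).
#' @param min_distance Minimum heavy-atom distance in Angstrom (default 5).
#' @param mode `"both"` (default), `"score_min"` or `"top_fraction"`.
#' @return An `allostery_report` data frame (columns `col_i`, `col_j`,
#'   `resno_i`, `resno_j`, `score`, `distance_A`, `seq_sep`), sorted by
#'   decreasing score, with the thresholds and any unmappable columns as
#'   attributes.
#' @export
strong_pairs <- function(m, structure, column_map = NULL,
                         score_min = 0.7, top_fraction = 0.30,
                         min_seq_sep = 5, min_distance = 5,
                         mode = c("both", "score_min", "top_fraction")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "coevolution_matrix"))
  pdb <- as_pdb(structure)
  L <- nrow(m$scores)
  rd <- residue_min_distances(pdb)
  if (is.null(column_map)) {
    column_map <- rep(NA_integer_, L)
    column_map[seq_len(min(L, length(rd$resno)))] <-
      rd$resno[seq_len(min(L, length(rd$resno)))]
  }
  off <- m$scores[upper.tri(m$scores)]
  top_cut <- stats::quantile(off, probs = 1 - top_fraction, names = FALSE,
                             type = 7)

  idx <- which(upper.tri(m$scores), arr.ind = TRUE)
  sc <- m$scores[idx]
  pass_score <- switch(mode,
    both = sc > score_min & sc >= top_cut,
    score_min = sc > score_min,
    top_fraction = sc >= top_cut)
  sep <- abs(idx[, 1] - idx[, 2])
  ri <- column_map[idx[, 1]]
  rj <- column_map[idx[, 2]]
  mappable <- !is.na(ri) & !is.na(rj) &
    ri %in% rd$resno & rj %in% rd$resno
  unmapped_cols <- sort(unique(c(idx[!mappable, 1], idx[!mappable, 2])))
  unmapped_cols <- unmapped_cols[is.na(column_map[unmapped_cols]) |
                                   !(column_map[unmapped_cols] %in% rd$resno)]
  dist <- rep(NA_real_, length(sc))
  dist[mappable] <- rd$D[cbind(match(ri[mappable], rd$resno),
                               match(rj[mappable], rd$resno))]
  keep <- pass_score & sep >= min_seq_sep & mappable & dist >= min_distance
  out <- data.frame(col_i = idx[keep, 1], col_j = idx[keep, 2],
                    resno_i = ri[keep], resno_j = rj[keep],
                    score = sc[keep], distance_A = dist[keep],
                    seq_sep = sep[keep])
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            score_min = score_min, top_fraction = top_fraction,
            top_cut = top_cut, min_seq_sep = min_seq_sep,
            min_distance = min_distance, mode = mode,
            unmapped_columns = unmapped_cols,
            class = c("allostery_report", "data.frame"))
}

#' @export
print.allostery_report <- function(x, ...) {
  cat(sprintf(
    "allostery_report: %d pair(s) [score > %.2f, top %.0f%%, sep >= %d, dist >= %.1f A]\n",
    nrow(x), attr(x, "score_min"), 100 * attr(x, "top_fraction"),
    attr(x, "min_seq_sep"), attr(x, "min_distance")))
  print.data.frame(x, ...)
  invisible(x)
}
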