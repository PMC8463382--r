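# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the quaternion superposition, the brute-force
# GROMOS reference and the direct contingency chi-squared are separate
# derivations of the same quantities.

# Horn's closed-form quaternion solution for least-squares superposition.
quaternion_rmsd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  S <- crossprod(Bc, Ac)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# Literal restatement of the greedy neighbor-count algorithm, recomputing
# neighbor counts from the full matrix each round.
brute_gromos <- function(D, cutoff) {
  alive <- rep(TRUE, nrow(D))
  clusters <- list()
  while (any(alive)) {
    best_n <- -1L; best_i <- NA_integer_
    for (i in which(alive)) {
      ni <- sum(D[i, alive] <= cutoff)
      if (ni > best_n) { best_n <- ni; best_i <- i }
    }
    members <- which(alive)[D[best_i, alive] <= cutoff]
    clusters <- c(clusters, list(c(best_i, setdiff(members, best_i))))
    alive[members] <- FALSE
  }
  clusters
}

# Direct weighted contingency chi-squared for two alignment columns,
# via data-frame aggregation rather than the package's encoding.
chi2_direct <- function(ali, i, j, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(ali))
  a <- ali[, i]; b <- ali[, j]
  ok <- a != "-" & b != "-"
  if (sum(ok) < 2) return(0)
  agg <- stats::aggregate(w[ok], list(a = a[ok], b = b[ok]), sum)
  O <- stats::xtabs(x ~ a + b, agg)
  N <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / N
  sum((O[E > 0] - E[E > 0])^2 / E[E > 0])
}

# Analytic Hessian of a single harmonic bond E = k (r - r0)^2 (Hartree,
# Bohr), for cross-checking the finite-difference generator.
analytic_bond_hessian <- function(x1, x2, k_au, r0) {
  d <- x2 - x1
  r <- sqrt(sum(d^2))
  u <- d / r
  P <- diag(3) - tcrossprod(u)
  blk <- 2 * k_au * tcrossprod(u) + (2 * k_au * (r - r0) / r) * P
  H <- matrix(0, 6, 6)
  H[1:3, 1:3] <- blk; H[4:6, 4:6] <- blk
  H[1:3, 4:6] <- -blk; H[4:6, 1:3] <- -blk
  H
}

rotate_coords <- function(x, axis = c(1, 2, 3) / sqrt(14), angle = 0.83) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  as.matrix(x) %*% t(R)
}

bohr <- 0.529177210903
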