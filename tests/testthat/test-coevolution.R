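# Sequence weighting, weighted chi-squared scoring, normalization and the
# strong-pair screen.

test_that("identity weights follow the cluster-size definition", {
  w <- sequence_weights(as_alignment(rep("ACDEF", 4)))
  expect_equal(as.numeric(w), rep(0.25, 4))
  w2 <- sequence_weights(as_alignment(c("AAAA", "AAAA", "WYWY")))
  expect_equal(as.numeric(w2), c(0.5, 0.5, 1.0))
})

test_that("effective sequence number matches a brute-force clustering oracle", {
  g <- gen_msa(40, 30, seed = 8)
  ali <- g$aln$ali
  # make clusters: duplicate some sequences with few substitutions
  ali[31:40, ] <- ali[rep(1:2, 5), ]
  ali[31, 3] <- "W"
  aln <- as_alignment(ali)
  w <- sequence_weights(aln, 0.8)
  n <- nrow(ali)
  brute <- sapply(seq_len(n), function(s) {
    1 / sum(sapply(seq_len(n), function(t) {
      mean(ali[s, ] == ali[t, ]) >= 0.8
    }))
  })
  expect_equal(as.numeric(w), brute)
})

test_that("perfect 2x2 covariation scores chi-squared = N", {
  half <- c(rep("A", 10), rep("C", 10))
  aln <- as_alignment(cbind(half, half))
  expect_equal(weighted_chi2(aln, 1, 2), 20)
  # anti-covarying relabeling scores identically
  aln2 <- as_alignment(cbind(half, rev(half)))
  expect_equal(weighted_chi2(aln2, 1, 2), 20)
})

test_that("a column paired with itself attains the maximal normalized score", {
  g <- gen_msa(80, 10, seed = 5)
  ali <- cbind(g$aln$ali, g$aln$ali[, 1])   # column 11 duplicates column 1
  m <- normalize_matrix(chi2_matrix(as_alignment(ali)))
  expect_equal(m$scores[1, 11], 1.0)
})

test_that("independent columns give a chi-squared mean near its df", {
  # 4-letter background: df = (4-1)^2 = 9 per pair; >= 500 column pairs
  g <- gen_msa(200, 35, background = c(rep(0.25, 4), rep(0, 16)), seed = 17)
  raw <- chi2_matrix(g$aln)
  vals <- raw[upper.tri(raw)]
  expect_gte(length(vals), 500)
  expect_equal(mean(vals), 9, tolerance = 0.1)
})

test_that("matrix scoring equals the direct per-pair computation", {
  g <- gen_msa(50, 8, planted_pairs = data.frame(i = 2, j = 6,
                                                 coupling = 0.8),
               gap_fraction = 0.05, seed = 12)
  w <- sequence_weights(g$aln)
  M <- chi2_matrix(g$aln, w)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      expect_equal(M[i, j], weighted_chi2(g$aln, i, j, w), tolerance = 1e-10)
      expect_equal(M[i, j], chi2_direct(g$aln$ali, i, j, w),
                   tolerance = 1e-10)
    }
  }
})

test_that("scores are symmetric, order- and relabeling-invariant", {
  g <- gen_msa(60, 10, planted_pairs = data.frame(i = 3, j = 8,
                                                  coupling = 1), seed = 2)
  M <- chi2_matrix(g$aln)
  expect_equal(M, t(M))
  # sequence order
  perm <- sample(60)
  M2 <- chi2_matrix(as_alignment(g$aln$ali[perm, ]))
  expect_equal(M2, M, tolerance = 1e-10)
  # column-consistent symbol relabeling
  ali3 <- g$aln$ali
  map <- setNames(sample(LETTERS[1:26])[1:20],
                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  map[] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  ali3[, 4] <- map[ali3[, 4]]
  M3 <- chi2_matrix(as_alignment(ali3))
  expect_equal(M3, M, tolerance = 1e-10)
})

test_that("min-max normalization maps and preserves ranks", {
  raw <- matrix(c(NA, 0, 5, 0, NA, 10, 5, 10, NA), 3, 3)
  diag(raw) <- NA
  m <- normalize_matrix(raw)
  expect_equal(sort(m$scores[upper.tri(m$scores)]), c(0, 0.5, 1))
  set.seed(3)
  r2 <- matrix(rexp(100), 10, 10)
  r2 <- r2 + t(r2)
  m2 <- normalize_matrix(r2)
  o <- upper.tri(r2)
  expect_equal(rank(m2$scores[o]), rank(r2[o]))
  expect_warning(normalize_matrix(matrix(1, 4, 4)), "constant")
})

test_that("null score distribution is calibrated against permutation", {
  g <- gen_msa(100, 30, seed = 77)
  m <- normalize_matrix(chi2_matrix(g$aln))
  frac_null <- mean(m$scores[upper.tri(m$scores)] > 0.7)
  # column-permutation null (destroys any residual coupling)
  set.seed(78)
  ali_p <- apply(g$aln$ali, 2, sample)
  mp <- normalize_matrix(chi2_matrix(as_alignment(ali_p)))
  frac_perm <- mean(mp$scores[upper.tri(mp$scores)] > 0.7)
  expect_lte(frac_null, frac_perm + 0.01)
})

test_that("planted coupling is detected with power monotone in strength", {
  hits <- sapply(c(0.2, 1.0), function(cp) {
    mean(sapply(1:10, function(r) {
      g <- gen_msa(200, 40,
                   planted_pairs = data.frame(i = 5, j = 30, coupling = cp),
                   seed = 100 + r)
      m <- normalize_matrix(chi2_matrix(g$aln, sequence_weights(g$aln)))
      off <- m$scores[upper.tri(m$scores)]
      m$scores[5, 30] >= stats::quantile(off, 0.99)
    }))
  })
  expect_true(hits[2] >= hits[1])
  expect_gte(hits[2], 0.9)
})

test_that("the strong-pair screen applies all filters conjunctively", {
  mock <- mock_neet_pdb(seed = 1)
  # residues in structure order; columns map 1:1 onto them
  L <- 14
  raw <- matrix(0.1, L, L); diag(raw) <- NA
  set.seed(9)
  raw[upper.tri(raw)] <- runif(sum(upper.tri(raw)), 0, 0.2)
  # distal planted pair: col 2 (Cys12, cluster) x col 10 (loop res 31)
  raw[2, 10] <- raw[10, 2] <- 0.95
  # contacting planted pair: col 1 (Cys10) x col 2 (Cys12), ~3.7 A apart
  raw[1, 2] <- raw[2, 1] <- 0.90
  raw <- pmax(raw, t(raw)); diag(raw) <- NA
  m <- normalize_matrix(raw)
  rep <- strong_pairs(m, mock$pdb, min_seq_sep = 1)
  expect_equal(nrow(rep), 1)
  expect_equal(c(rep$col_i, rep$col_j), c(2, 10))
  expect_gte(rep$distance_A, 5)

  # score below 0.7 is excluded regardless of geometry
  raw2 <- raw
  raw2[2, 10] <- raw2[10, 2] <- max(raw2[upper.tri(raw2)], na.rm = TRUE)
  m2 <- normalize_matrix(raw2)
  s <- m2$scores[2, 10]
  stopifnot(s == 1)
  m2$scores[2, 10] <- m2$scores[10, 2] <- 0.69
  expect_equal(nrow(strong_pairs(m2, mock$pdb, min_seq_sep = 1)), 0)
})

test_that("unmappable columns are listed and skipped", {
  mock <- mock_neet_pdb(seed = 1)
  raw <- matrix(0.1, 20, 20); diag(raw) <- NA
  raw[3, 17] <- raw[17, 3] <- 1
  m <- normalize_matrix(raw)
  cmap <- c(rep(NA_integer_, 20))
  cmap[3] <- 12; cmap[17] <- 31
  rep <- strong_pairs(m, mock$pdb, column_map = cmap, min_seq_sep = 1)
  expect_equal(nrow(rep), 1)
  expect_true(length(attr(rep, "unmapped_columns")) > 0)
})

test_that("stockholm and fasta readers agree", {
  g <- gen_msa(5, 12, seed = 4)
  fa <- withr::local_tempfile(fileext = ".fasta")
  con <- file(fa, "w")
  for (s in 1:5) writeLines(c(paste0(">s", s),
                              paste(g$aln$ali[s, ], collapse = "")), con)
  close(con)
  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               sprintf("s%d %s", 1:5,
                       apply(g$aln$ali, 1, paste, collapse = "")),
               "//"), sto)
  a1 <- read_alignment(fa)
  a2 <- read_alignment(sto)
  expect_equal(a1$ali, a2$ali)
})
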