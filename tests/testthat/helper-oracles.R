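# Independent brute-force oracles and fixture builders.  These deliberately
# take the slow, explicit route (frequency tables, double loops) so they
# share no code path with the package implementations they check.

random_alignment <- function(n_seq, n_pos, alphabet = MSA_ALPHABET[1:20],
                             gap_frac = 0) {
  seqs <- matrix(sample(alphabet, n_seq * n_pos, replace = TRUE),
                 n_seq, n_pos)
  if (gap_frac > 0) {
    idx <- sample(length(seqs), round(gap_frac * length(seqs)))
    seqs[idx] <- "-"
  }
  as_msa(seqs)
}

# Shannon entropy in bits from a vector of symbols.
oracle_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

# MI matrix from explicit per-pair frequency tables.
oracle_mi <- function(mat) {
  p <- ncol(mat)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    hij <- oracle_entropy(paste(mat[, i], mat[, j]))
    out[i, j] <- oracle_entropy(mat[, i]) + oracle_entropy(mat[, j]) - hij
  }
  out
}

# MI with pairwise gap exclusion (amino-acid convention).
oracle_mi_nogap <- function(mat) {
  p <- ncol(mat)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    keep <- mat[, i] != "-" & mat[, j] != "-"
    if (sum(keep) < 2) next
    a <- mat[keep, i]; b <- mat[keep, j]
    out[i, j] <- oracle_entropy(a) + oracle_entropy(b) -
      oracle_entropy(paste(a, b))
  }
  out
}

# Textbook pairwise sample covariance, double loop.
oracle_cov <- function(m) {
  p <- ncol(m); n <- nrow(m)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    out[i, j] <- sum((m[, i] - mean(m[, i])) * (m[, j] - mean(m[, j]))) /
      (n - 1)
  }
  out
}

# Average product correction, elementwise loop.
oracle_apc <- function(m) {
  p <- nrow(m)
  rowm <- sapply(seq_len(p), function(i) mean(m[i, -i]))
  grand <- mean(m[row(m) != col(m)])
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    out[i, j] <- m[i, j] - rowm[i] * rowm[j] / grand
  out
}

# ZPX2 via per-row z-scores with explicit loops (population sd over the
# off-diagonal entries of each row).
oracle_zpx2 <- function(m) {
  p <- nrow(m)
  z <- matrix(0, p, p)
  for (i in seq_len(p)) {
    v <- m[i, -i]
    s <- sqrt(mean((v - mean(v))^2))
    for (j in seq_len(p)) {
      if (i == j) next
      z[i, j] <- if (s > 0) (m[i, j] - mean(v)) / s else 0
    }
  }
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    out[i, j] <- (z[i, j] * z[j, i])^2
  out
}

# OMES from explicit contingency tables, pairwise gap exclusion.
oracle_omes <- function(mat) {
  p <- ncol(mat)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    keep <- mat[, i] != "-" & mat[, j] != "-"
    nv <- sum(keep)
    if (nv == 0) next
    a <- mat[keep, i]; b <- mat[keep, j]
    tab <- table(a, b)
    score <- 0
    for (x in rownames(tab)) for (y in colnames(tab)) {
      nobs <- tab[x, y]
      if (nobs > 0) {
        nexp <- sum(a == x) * sum(b == y) / nv
        score <- score + (nobs - nexp)^2 / nv
      }
    }
    out[i, j] <- score
  }
  out
}

off_diag <- function(m) m[row(m) != col(m)]

# Strip classes and attributes down to a plain numeric matrix.
bare <- function(m) matrix(as.numeric(m), nrow(m))

# Minimal PDB text for a single chain of one-atom (or listed-atom)
# residues; coords is a list of 3-column matrices, one per residue.
write_toy_pdb <- function(coords, path, chain = "A",
                          elements = NULL) {
  lines <- character(0)
  serial <- 0
  for (r in seq_along(coords)) {
    xyz <- coords[[r]]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    for (a in seq_len(nrow(xyz))) {
      serial <- serial + 1
      el <- if (is.null(elements)) "C" else elements[[r]][a]
      name <- if (a == 1) "CA" else paste0(el, a)
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, name, chain, r, xyz[a, 1], xyz[a, 2], xyz[a, 3], el))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
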