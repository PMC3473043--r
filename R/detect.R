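## Coevolution score matrices.
##
## All detectors return a symmetric n_pos x n_pos numeric matrix of class
## "coevolution_matrix" with a "method" attribute.  By convention the
## diagonal of a finished score matrix is set to the off-diagonal minimum
## so that self-pairs never enter a ranking.

coev_matrix <- function(m, method) {
  m <- (m + t(m)) / 2
  structure(m, class = c("coevolution_matrix", "matrix"), method = method)
}

#' @export
print.coevolution_matrix <- function(x, ...) {
  cat(sprintf("coevolution matrix [%s]: %d x %d\n",
              attr(x, "method"), nrow(x), ncol(x)))
  invisible(x)
}

## Set the diagonal to the off-diagonal minimum (ranking convention).
set_diag_min <- function(m) {
  offd <- m[row(m) != col(m)]
  diag(m) <- min(offd)
  m
}

## Entropy in bits of a count vector.
count_entropy <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Mutual information matrix of a discrete alignment
#'
#' Plug-in (empirical frequency) mutual information between all column
#' pairs, MI(i;j) = H(i) + H(j) - H(i,j) in bits.  Works on any discrete
#' matrix: an \code{msa}, a \code{binary_msa}, a \code{normal_binary_msa},
#' or a plain matrix of codes/characters.
#'
#' @param x Alignment-like object or discrete matrix.
#' @param exclude_gaps For \code{msa} input only: drop, per pair, the rows
#'   with a gap at either column (default \code{TRUE}).  Binary and
#'   normal/binary inputs always treat every symbol (including the
#'   no-change 0) as informative.
#' @return \code{coevolution_matrix}; the diagonal carries the
#'   off-diagonal minimum.
#' @export
mi_matrix <- function(x, exclude_gaps = TRUE) {
  gap_code <- NA_integer_
  if (inherits(x, "msa")) {
    codes <- encode_msa(x)
    if (exclude_gaps) gap_code <- ALPHA_N
  } else if (inherits(x, "binary_msa")) {
    codes <- x$bits + 1L
  } else if (inherits(x, "normal_binary_msa")) {
    codes <- x$codes + 1L
  } else {
    codes <- as.matrix(x)
    if (!is.numeric(codes))
      codes <- matrix(as.integer(factor(codes)), nrow = nrow(codes))
    codes <- codes - min(codes) + 1L
  }
  storage.mode(codes) <- "integer"
  n <- nrow(codes); p <- ncol(codes)
  if (n < 2L) stop("need at least 2 rows")
  K <- max(codes)
  out <- matrix(0, p, p)
  if (is.na(gap_code)) {
    H <- apply(codes, 2L, function(cl) count_entropy(tabulate(cl, K)))
    for (j in 2:p) {
      cj <- codes[, j]
      base <- (codes[, seq_len(j - 1L), drop = FALSE] - 1L) * K
      for (i in seq_len(j - 1L)) {
        tab <- tabulate(base[, i] + cj, K * K)
        out[i, j] <- H[i] + H[j] - count_entropy(tab)
      }
    }
  } else {
    notgap <- codes != gap_code
    for (j in 2:p) {
      cj <- codes[, j]
      for (i in seq_len(j - 1L)) {
        keep <- notgap[, i] & notgap[, j]
        if (sum(keep) < 2L) next
        a <- codes[keep, i]; b <- cj[keep]
        tab <- tabulate((a - 1L) * K + b, K * K)
        out[i, j] <- count_entropy(tabulate(a, K)) +
          count_entropy(tabulate(b, K)) - count_entropy(tab)
      }
    }
  }
  out <- out + t(out)
  set_diag_min(coev_matrix(out, "MI"))
}

#' Average product correction (APC / MIp)
#'
#' Subtracts mean_i * mean_j / mean_all from every entry, with the row and
#' grand means taken over off-diagonal entries.  Suppresses the
#' phylogenetic/background component of an MI-like matrix.
#'
#' @param m Symmetric score matrix.
#' @return Corrected \code{coevolution_matrix}.
#' @export
apc <- function(m) {
  m <- as.matrix(m)
  p <- nrow(m)
  offd <- row(m) != col(m)
  mean_all <- mean(m[offd])
  if (mean_all == 0) {
    warning("grand mean is 0; returning input unchanged")
    return(coev_matrix(m, "APC"))
  }
  rs <- (rowSums(m) - diag(m)) / (p - 1)
  out <- m - outer(rs, rs) / mean_all
  coev_matrix(out, "APC")
}

#' ZPX2 correction
#'
#' Per-row Z-scores of a symmetric matrix (mean and population standard
#' deviation over each row's off-diagonal entries), cross-multiplied and
#' squared: ZPX(i,j) = Z(i,j) * Z(j,i), ZPX2 = ZPX^2.  Rows with zero
#' spread contribute Z = 0.  The plain square discards the sign of the
#' cross-product; \code{signed = TRUE} keeps it as sign(ZPX) * ZPX^2.
#'
#' @param m Symmetric score matrix with at least 3 positions.
#' @param signed Keep the sign of the Z cross-product (default
#'   \code{FALSE}, the plain square).
#' @return \code{coevolution_matrix}; diagonal set to the off-diagonal
#'   minimum.
#' @export
zpx2 <- function(m, signed = FALSE) {
  m <- as.matrix(m)
  p <- nrow(m)
  if (p < 3L) stop("ZPX2 needs at least 3 positions")
  offd <- row(m) != col(m)
  mu <- (rowSums(m) - diag(m)) / (p - 1)
  dev <- m - mu
  dev[!offd] <- 0
  sd <- sqrt(rowSums(dev^2) / (p - 1))
  z <- dev / ifelse(sd > 0, sd, Inf)
  z[!offd] <- 0
  zpx <- z * t(z)
  out <- if (signed) sign(zpx) * zpx^2 else zpx^2
  set_diag_min(coev_matrix(out, if (signed) "sZPX2" else "ZPX2"))
}

#' Covariance matrix of a differential binary translation
#'
#' Sample covariance (denominator n-1) between the 0/1 columns.
#'
#' @param b A \code{binary_msa} object or 0/1 matrix.
#' @return \code{coevolution_matrix} (diagonal = column variances).
#' @export
binary_covariance <- function(b) {
  bits <- if (inherits(b, "binary_msa")) b$bits else as.matrix(b)
  coev_matrix(stats::cov(bits), "COV")
}

#' Full covariance of a global binary translation
#'
#' @param gb A \code{global_binary_msa} object.
#' @return (21 n_pos) x (21 n_pos) covariance matrix.
#' @export
expanded_covariance <- function(gb) {
  stopifnot(inherits(gb, "global_binary_msa"))
  stats::cov(gb$bits)
}

#' Collapse a global binary covariance by block Frobenius norms
#'
#' Computes the (21 n_pos) x (21 n_pos) covariance of the global binary
#' matrix and collapses it to n_pos x n_pos by taking, for each position
#' pair (i, j), the Frobenius norm of the 21 x 21 block that holds the
#' covariances between the symbol indicators of columns i and j.
#'
#' @param gb A \code{global_binary_msa} object, or a matrix whose column
#'   count is divisible by 21.
#' @return \code{coevolution_matrix} of collapsed (nonnegative) norms.
#' @export
collapse_global_cov <- function(gb) {
  bits <- if (inherits(gb, "global_binary_msa")) gb$bits else as.matrix(gb)
  if (ncol(bits) %% ALPHA_N != 0L)
    stop("column count not divisible by ", ALPHA_N,
         ": not a global binary matrix")
  p <- ncol(bits) %/% ALPHA_N
  cv <- stats::cov(bits)
  blk <- matrix(0, ALPHA_N * p, p)
  blk[cbind(seq_len(ALPHA_N * p), rep(seq_len(p), each = ALPHA_N))] <- 1
  out <- sqrt(t(blk) %*% cv^2 %*% blk)
  coev_matrix(out, "collapsedCOV")
}

#' Merge an MI matrix and a covariance matrix by linear regression
#'
#' Fits mi ~ a * cov + b by ordinary least squares over the off-diagonal
#' upper-triangle entries, rescales the covariance matrix onto the MI
#' scale, and returns the elementwise mean of the MI matrix and the
#' rescaled covariance matrix.
#'
#' @param mi,cov Symmetric matrices of identical shape.
#' @return Merged \code{coevolution_matrix}.
#' @export
merge_mi_cov <- function(mi, cov) {
  mi <- as.matrix(mi); cov <- as.matrix(cov)
  if (!all(dim(mi) == dim(cov))) stop("shape mismatch")
  ut <- upper.tri(mi)
  x <- cov[ut]; y <- mi[ut]
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) {
    warning("degenerate regression (constant covariance); returning MI")
    return(coev_matrix(mi, "MI/COV"))
  }
  a <- stats::cov(x, y) / vx
  b <- mean(y) - a * mean(x)
  coev_matrix((mi + a * cov + b) / 2, "MI/COV")
}

#' Differential binary ZPX2 (dbZPX2)
#'
#' Pipeline: resort the alignment, take the differential binary
#' translation, compute its MI matrix and its column covariance matrix,
#' merge the two by linear regression, and apply the ZPX2 correction to
#' the merged matrix.
#'
#' @param aln An \code{msa} object.
#' @param seed_mode,first Passed to \code{\link{resort_order}}.
#' @param apc_first Apply the average product correction before the
#'   Z-scoring step (default \code{FALSE}).
#' @return \code{coevolution_matrix} labelled \code{"dbZPX2"}.
#' @export
db_zpx2 <- function(aln, seed_mode = "most_similar_pair", first = 1L,
                    apc_first = FALSE) {
  ord <- resort_order(aln, seed_mode, first)
  b <- diff_binary(aln, ord)
  merged <- merge_mi_cov(mi_matrix(b), binary_covariance(b))
  if (apc_first) merged <- apc(merged)
  out <- zpx2(merged)
  attr(out, "method") <- "dbZPX2"
  out
}

#' Differential global binary ZPX2 (dgbZPX2)
#'
#' As \code{\link{db_zpx2}}, but the covariance term is the collapsed
#' (block Frobenius norm) covariance of the global differential binary
#' translation, which reintroduces information on the type of amino acid
#' change.
#'
#' @inheritParams db_zpx2
#' @return \code{coevolution_matrix} labelled \code{"dgbZPX2"}.
#' @export
dgb_zpx2 <- function(aln, seed_mode = "most_similar_pair", first = 1L,
                     apc_first = FALSE) {
  ord <- resort_order(aln, seed_mode, first)
  b <- diff_binary(aln, ord)
  gb <- global_diff_binary(aln, ord)
  merged <- merge_mi_cov(mi_matrix(b), collapse_global_cov(gb))
  if (apc_first) merged <- apc(merged)
  out <- zpx2(merged)
  attr(out, "method") <- "dgbZPX2"
  out
}

#' Normal/binary ZPX2 (nbZPX2)
#'
#' Pipeline: resort the alignment, mask it with its differential binary
#' translation (22-symbol normal/binary form), compute the MI matrix of
#' the masked alignment, and apply the ZPX2 correction.  No covariance
#' merge is involved.
#'
#' @inheritParams db_zpx2
#' @return \code{coevolution_matrix} labelled \code{"nbZPX2"}.
#' @export
nb_zpx2 <- function(aln, seed_mode = "most_similar_pair", first = 1L,
                    apc_first = FALSE) {
  ord <- resort_order(aln, seed_mode, first)
  nb <- normal_binary(aln, ord)
  m <- mi_matrix(nb)
  if (apc_first) m <- apc(m)
  out <- zpx2(m)
  attr(out, "method") <- "nbZPX2"
  out
}

#' Observed minus expected squared covariance (OMES)
#'
#' For each column pair, over the rows with no gap at either column:
#' sum over the observed symbol co-occurrences of
#' (N_obs - N_exp)^2 / N_valid, where N_exp is the product of the marginal
#' counts divided by N_valid.
#'
#' @param aln An \code{msa} object.
#' @return \code{coevolution_matrix} labelled \code{"OMES"}.
#' @export
omes <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  codes <- encode_msa(aln)
  p <- ncol(codes)
  notgap <- codes != ALPHA_N
  out <- matrix(0, p, p)
  warned <- FALSE
  for (j in 2:p) {
    for (i in seq_len(j - 1L)) {
      keep <- notgap[, i] & notgap[, j]
      nv <- sum(keep)
      if (nv == 0L) { warned <- TRUE; next }
      a <- codes[keep, i]; b <- codes[keep, j]
      tab <- tabulate((a - 1L) * ALPHA_N + b, ALPHA_N * ALPHA_N)
      ma <- tabulate(a, ALPHA_N); mb <- tabulate(b, ALPHA_N)
      exp_tab <- as.vector(outer(mb, ma))  # row-major over (a-1)*K+b
      obs <- tab > 0
      out[i, j] <- sum((tab[obs] - exp_tab[obs] / nv)^2) / nv
    }
  }
  if (warned) warning("some pairs had no gap-free rows; scored 0")
  out <- out + t(out)
  set_diag_min(coev_matrix(out, "OMES"))
}
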