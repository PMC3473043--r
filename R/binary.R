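## Differential binary re-encodings of an alignment.
##
## The key primitive is a resorting of the rows that minimizes the number
## of symbol changes between consecutive sequences; the resorted alignment
## is then re-encoded as (i) a 0/1 change matrix, (ii) a one-hot "global"
## change matrix with a 21-column block per position, or (iii) a masked
## alignment keeping the new symbol where a change occurred.

## Pairwise Hamming distance matrix between rows, computed by summing
## per-symbol equality crossproducts (fast for n_seq up to a few thousand).
hamming_matrix <- function(codes) {
  n <- nrow(codes)
  p <- ncol(codes)
  eq <- matrix(0, n, n)
  for (s in seq_len(ALPHA_N)) {
    ind <- codes == s
    if (any(ind)) eq <- eq + tcrossprod(ind)
  }
  p - eq
}

greedy_chain <- function(D, first, second = NULL) {
  n <- nrow(D)
  order <- integer(n)
  used <- logical(n)
  order[1] <- first; used[first] <- TRUE
  k <- 1L
  if (!is.null(second)) {
    order[2] <- second; used[second] <- TRUE
    k <- 2L
  }
  while (k < n) {
    d <- D[order[k], ]
    d[used] <- Inf
    nxt <- which.min(d)           # which.min takes the lowest index on ties
    k <- k + 1L
    order[k] <- nxt
    used[nxt] <- TRUE
  }
  order
}

chain_sum <- function(D, order) {
  n <- length(order)
  sum(D[cbind(order[-n], order[-1])])
}

#' Resort alignment rows to minimize consecutive-row changes
#'
#' Orders the sequences so that the total Hamming distance between
#' consecutive rows (the number of 1s in the differential binary
#' translation) is small.  The ordering is a greedy nearest-neighbour
#' chain; the exact minimum is a travelling-salesman path and is not
#' attempted.
#'
#' @param aln An \code{msa} object.
#' @param seed_mode How the chain is seeded: \describe{
#'   \item{\code{"most_similar_pair"}}{(default) rows 1 and 2 of the
#'     resorted alignment are the two most similar sequences;}
#'   \item{\code{"fixed_index"}}{the chain starts at row \code{first};}
#'   \item{\code{"scan_all"}}{every sequence is tried as the chain seed
#'     and the ordering with the smallest total sum is kept.}}
#' @param first Starting row for \code{seed_mode = "fixed_index"}.
#' @return Integer permutation of \code{1:n_seq} with attribute
#'   \code{total_sum}, the chain Hamming sum of the returned ordering.
#'   Ties are broken by the lowest original row index.
#' @export
resort_order <- function(aln,
                         seed_mode = c("most_similar_pair", "fixed_index",
                                       "scan_all"),
                         first = 1L) {
  stopifnot(inherits(aln, "msa"))
  seed_mode <- match.arg(seed_mode)
  codes <- encode_msa(aln)
  n <- nrow(codes)
  D <- hamming_matrix(codes)
  diag(D) <- Inf
  ord <- switch(seed_mode,
    most_similar_pair = {
      idx <- which(D == min(D), arr.ind = TRUE)
      idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      greedy_chain(D, idx[1, 1], idx[1, 2])
    },
    fixed_index = greedy_chain(D, as.integer(first)),
    scan_all = {
      best <- NULL; best_sum <- Inf
      for (s in seq_len(n)) {
        o <- greedy_chain(D, s)
        cs <- chain_sum(D, o)
        if (cs < best_sum) { best <- o; best_sum <- cs }
      }
      best
    })
  structure(ord, total_sum = chain_sum(D, ord))
}

#' Differential binary translation
#'
#' Re-encodes the (resorted) alignment as a 0/1 matrix: the first row is
#' all zeros, and every later cell is 1 when its symbol differs from the
#' symbol in the same column of the previous row, else 0.
#'
#' @param aln An \code{msa} object.
#' @param order Row permutation (from \code{\link{resort_order}});
#'   default keeps the original order.
#' @return Object of class \code{binary_msa}: list with \code{bits}
#'   (n_seq x n_pos 0/1 integer matrix), \code{order}, and
#'   \code{total_sum} (number of 1s).
#' @export
diff_binary <- function(aln, order = seq_len(nrow(aln$seqs))) {
  stopifnot(inherits(aln, "msa"))
  codes <- encode_msa(aln)[order, , drop = FALSE]
  n <- nrow(codes)
  bits <- matrix(0L, n, ncol(codes))
  bits[-1L, ] <- (codes[-1L, , drop = FALSE] != codes[-n, , drop = FALSE]) * 1L
  structure(list(bits = bits, order = as.integer(order),
                 total_sum = sum(bits)),
            class = "binary_msa")
}

#' Global differential binary translation
#'
#' One-hot expansion of the differential binary translation: each
#' alignment column maps to a 21-column block (one column per alphabet
#' symbol, gap included).  The first row is all zeros; in later rows a
#' changed position carries a single 1 in its block, at the index of the
#' new symbol; unchanged positions have all-zero blocks.  Column \code{c}
#' of the source occupies block columns \code{(c-1)*21 + 1:21}.
#'
#' @inheritParams diff_binary
#' @param onehot If \code{TRUE}, encode a plain one-hot of every residue
#'   (no change masking) instead of the differential form.
#' @return Object of class \code{global_binary_msa}: list with
#'   \code{bits} (n_seq x 21*n_pos integer matrix), \code{order},
#'   \code{n_pos}.
#' @export
global_diff_binary <- function(aln, order = seq_len(nrow(aln$seqs)),
                               onehot = FALSE) {
  stopifnot(inherits(aln, "msa"))
  codes <- encode_msa(aln)[order, , drop = FALSE]
  n <- nrow(codes); p <- ncol(codes)
  bits <- matrix(0L, n, ALPHA_N * p)
  if (onehot) {
    rows <- rep(seq_len(n), p)
    cols <- (rep(seq_len(p), each = n) - 1L) * ALPHA_N + as.vector(codes)
    bits[cbind(rows, cols)] <- 1L
  } else {
    chg <- which(codes[-1L, , drop = FALSE] != codes[-n, , drop = FALSE],
                 arr.ind = TRUE)
    if (nrow(chg) > 0L) {
      r <- chg[, 1] + 1L
      cc <- chg[, 2]
      cols <- (cc - 1L) * ALPHA_N + codes[cbind(r, cc)]
      bits[cbind(r, cols)] <- 1L
    }
  }
  structure(list(bits = bits, order = as.integer(order), n_pos = p),
            class = "global_binary_msa")
}

#' Normal/binary translation
#'
#' Masks the resorted alignment with its differential binary translation:
#' cells that did not change from the previous row become the extra
#' symbol 0, cells that changed keep their (new) residue symbol.  The
#' result is a matrix over a 22-symbol alphabet \{0\} + 21 symbols,
#' returned as integer codes (0 = no change, 1..21 = alphabet index).
#'
#' @inheritParams diff_binary
#' @return Object of class \code{normal_binary_msa}: list with
#'   \code{codes} (n_seq x n_pos integer matrix over 0..21),
#'   \code{order}, \code{n_nonzero}.
#' @export
normal_binary <- function(aln, order = seq_len(nrow(aln$seqs))) {
  stopifnot(inherits(aln, "msa"))
  codes <- encode_msa(aln)[order, , drop = FALSE]
  b <- diff_binary(aln, order)
  nb <- codes * b$bits
  structure(list(codes = nb, order = as.integer(order),
                 n_nonzero = sum(nb != 0L)),
            class = "normal_binary_msa")
}

#' Write a binary translation as a plain 0/1 text matrix
#'
#' One row per line, no separators; the row permutation is written
#' alongside as a two-column TSV (\code{new_rank}, \code{original_index})
#' when \code{order_path} is given.
#'
#' @param b A \code{binary_msa} object.
#' @param path Output path for the 0/1 matrix.
#' @param order_path Optional output path for the permutation TSV.
#' @return \code{path}, invisibly.
#' @export
write_binary_msa <- function(b, path, order_path = NULL) {
  stopifnot(inherits(b, "binary_msa"))
  writeLines(apply(b$bits, 1L, paste, collapse = ""), path)
  if (!is.null(order_path)) {
    utils::write.table(
      data.frame(new_rank = seq_along(b$order), original_index = b$order),
      order_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Mean pairwise entropy summary of a binary translation
#'
#' For all column pairs (i, j) of a 0/1 matrix, computes the mean of
#' H(i)+H(j), the mean joint entropy H(i,j), and the mean mutual
#' information MI(i;j) = H(i)+H(j)-H(i,j), in bits.  Resorting the
#' alignment before binary translation lowers the mean entropy and MI and
#' raises the mean joint entropy relative to the unsorted ordering.
#'
#' @param b A \code{binary_msa} object (or plain 0/1 matrix).
#' @return Named numeric vector \code{c(mean_H_sum, mean_H_joint,
#'   mean_MI)}.
#' @export
pairwise_entropy_summary <- function(b) {
  bits <- if (inherits(b, "binary_msa")) b$bits else as.matrix(b)
  n <- nrow(bits); p <- ncol(bits)
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  f1 <- colSums(bits) / n
  H <- -(plogp(f1) + plogp(1 - f1))
  n11 <- crossprod(bits)
  c1 <- colSums(bits)
  n10 <- outer(c1, rep(1, p)) - n11
  n01 <- t(n10)
  n00 <- n - n11 - n10 - n01
  Hj <- -(plogp(n11 / n) + plogp(n10 / n) + plogp(n01 / n) + plogp(n00 / n))
  ut <- upper.tri(Hj)
  Hsum <- outer(H, H, "+")
  c(mean_H_sum = mean(Hsum[ut]),
    mean_H_joint = mean(Hj[ut]),
    mean_MI = mean(Hsum[ut] - Hj[ut]))
}
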