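## Scoring a coevolution detector against ground truth or structure.

## Upper-triangle pairs of a symmetric matrix ranked by descending value,
## ties broken lexicographically by (i, j).  Returns a data.frame(i, j,
## value) in rank order.
rank_pairs <- function(m) {
  ut <- which(upper.tri(m), arr.ind = TRUE)
  v <- m[ut]
  o <- order(-v, ut[, 1], ut[, 2])
  data.frame(i = ut[o, 1], j = ut[o, 2], value = v[o])
}

#' Cumulative covarion-recovery curve
#'
#' Ranks the method's position pairs by descending score, replaces each
#' ranked pair's value by the ground-truth covCOV count for that same
#' pair, and accumulates: y(k) is the total number of true covariation
#' events captured by the method's top k pairs.  The ideal-observer curve
#' is the cumulative sum of the covCOV counts in their own descending
#' order, the upper bound of any method's curve.
#'
#' @param method Symmetric score matrix (any \code{coevolution_matrix}).
#' @param truth Symmetric count matrix (typically
#'   \code{record$covCOV}).
#' @return Object of class \code{recovery_curve}: data.frame with columns
#'   \code{x} (rank), \code{y} (cumulative true count), \code{ideal}
#'   (ideal-observer cumulative count).
#' @export
recovery_curve <- function(method, truth) {
  method <- as.matrix(method); truth <- as.matrix(truth)
  if (!all(dim(method) == dim(truth))) stop("shape mismatch")
  rk <- rank_pairs(method)
  got <- truth[cbind(rk$i, rk$j)]
  ideal <- cumsum(sort(truth[upper.tri(truth)], decreasing = TRUE))
  structure(data.frame(x = seq_along(got), y = cumsum(got), ideal = ideal),
            class = c("recovery_curve", "data.frame"),
            method = attr(method, "method"))
}

#' Contact-recall curve with sequence-separation filter
#'
#' Restricts both the method's ranking and the contact set to pairs with
#' at least \code{separation} intervening sequence positions (i.e.
#' \code{|i - j| >= separation + 1}), then reports, for k = 1 ..
#' \code{max_pairs}, the percentage of all retained contacts found among
#' the method's top k pairs.  The x axis is normalized so that 100
#' corresponds to a number of pairs equal to the number of positions.
#'
#' @param method Symmetric score matrix.
#' @param contacts A \code{\link{contact_map}} (or logical matrix) of the
#'   same dimension.
#' @param separation Minimum number of intervening positions (0 keeps
#'   every pair, including consecutive residues).
#' @param max_pairs Number of top pairs to scan; defaults to the number
#'   of positions (the "top-L" convention).
#' @return Object of class \code{contact_recall_curve}: data.frame with
#'   \code{k} (pair count), \code{x} (normalized, 100 = n_pos pairs),
#'   \code{y} (percent of retained contacts recovered).
#' @export
contact_recall <- function(method, contacts, separation = 0,
                           max_pairs = NULL) {
  method <- as.matrix(method)
  contacts <- as.matrix(contacts)
  p <- nrow(method)
  if (!all(dim(contacts) == c(p, p))) stop("shape mismatch")
  if (is.null(max_pairs)) max_pairs <- p
  rk <- rank_pairs(method)
  keep <- (rk$j - rk$i) >= separation + 1
  rk <- rk[keep, , drop = FALSE]
  ut <- which(upper.tri(contacts), arr.ind = TRUE)
  cset <- contacts[ut] & ((ut[, 2] - ut[, 1]) >= separation + 1)
  n_contacts <- sum(cset)
  if (n_contacts == 0L)
    stop("no contacts remain after the separation filter")
  max_pairs <- min(max_pairs, nrow(rk))
  hit <- contacts[cbind(rk$i, rk$j)][seq_len(max_pairs)]
  structure(data.frame(k = seq_len(max_pairs),
                       x = 100 * seq_len(max_pairs) / p,
                       y = 100 * cumsum(hit) / n_contacts),
            class = c("contact_recall_curve", "data.frame"),
            separation = separation, n_contacts = n_contacts)
}

#' Merge curves across runs by shape-preserving interpolation
#'
#' Fits each curve with a piecewise cubic Hermite interpolant (PCHIP,
#' shape preserving), rescales every curve's x range onto a common
#' normalized grid, and averages: the result places runs of different
#' lengths on the same axis so they can be compared point by point.
#'
#' @param curves List of curves; each element is a data.frame (or list)
#'   with numeric \code{x} and \code{y} of at least 4 points.
#' @param grid_points Number of points of the common grid (default 100).
#' @return data.frame with columns \code{x} (normalized to [0, 1]),
#'   \code{mean}, and \code{sd} (plain standard deviation across curves
#'   at each grid point; 0 when a single value).
#' @export
merge_curves <- function(curves, grid_points = 100L) {
  if (length(curves) < 2L) stop("need at least 2 curves")
  g <- seq(0, 1, length.out = grid_points)
  ys <- vapply(curves, function(cv) {
    x <- as.numeric(cv$x); y <- as.numeric(cv$y)
    if (length(x) < 4L) stop("each curve needs at least 4 points")
    xr <- (x - min(x)) / (max(x) - min(x))
    ## PCHIP needs strictly increasing knots
    keep <- !duplicated(xr)
    pracma::pchip(xr[keep], y[keep], g)
  }, numeric(grid_points))
  data.frame(x = g, mean = rowMeans(ys), sd = apply(ys, 1L, stats::sd))
}
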